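# Iterated greedy (IG) local search for gene subsets.
#
# Each refinement iteration destroys part of the current subset (removes d
# randomly chosen selected genes), greedily reconstructs it (re-selecting a
# removed gene only when that strictly lowers the fitness), and decides
# acceptance with a simulated-annealing rule at a constant temperature: no
# cooling schedule, T is fixed for the whole run from the mean normalized
# expression level of the dataset.

#' IG configuration
#'
#' @param d destruction size: number of currently selected genes removed per
#'   iteration. `NULL` (default) means proportional destruction,
#'   `max(1, round(destruct_frac * n_selected))`, which scales across
#'   datasets from hundreds to tens of thousands of genes.
#' @param destruct_frac fraction used by proportional destruction
#'   (default 0.2).
#' @param ig_iterations refinement iterations per invocation (default 10;
#'   bounds the evaluation budget of each hybrid handoff).
#' @param t_scale multiplier on the constant acceptance temperature
#'   (default 1; 0 makes acceptance improve-only).
#' @param construct_mode `"greedy"` (default): each removed gene is tested
#'   for re-selection in removal order. `"swap_aware"`: additionally tests
#'   exchanging the removed gene for each currently selected gene — closer
#'   to positional re-insertion, at a much higher evaluation cost.
#' @param seed integer seed used when [run_ig()] is called standalone.
#' @return an object of class `ig_config`.
#' @export
ig_config <- function(d = NULL, destruct_frac = 0.2, ig_iterations = 10,
                      t_scale = 1, construct_mode = c("greedy", "swap_aware"),
                      seed = 1L) {
  if (!is.null(d) && d < 1) stop("d must be >= 1 (or NULL for proportional)")
  if (ig_iterations < 1) stop("ig_iterations must be >= 1")
  if (t_scale < 0) stop("t_scale must be >= 0")
  if (destruct_frac <= 0 || destruct_frac > 1) {
    stop("destruct_frac must be in (0, 1]")
  }
  structure(list(d = if (is.null(d)) NULL else as.integer(d),
                 destruct_frac = destruct_frac,
                 ig_iterations = as.integer(ig_iterations),
                 t_scale = t_scale,
                 construct_mode = match.arg(construct_mode),
                 seed = as.integer(seed)),
            class = "ig_config")
}

#' Constant acceptance temperature of a dataset
#'
#' `T = t_scale * sum(P) / (n * m * 10)` where P is the expression matrix,
#' n the number of samples and m the number of genes — i.e. one tenth of the
#' mean expression level. On a min-max-normalized matrix this lies in
#' \[0, 0.1\], the same order as typical fitness differences, which makes
#' `exp(-dE / T)` a usable acceptance curve. The temperature is constant for
#' the whole run; there is no cooling schedule.
#'
#' @param dataset an [expression_dataset()].
#' @param t_scale non-negative multiplier.
#' @return the temperature, a single non-negative number.
#' @export
compute_temperature <- function(dataset, t_scale = 1) {
  stopifnot(inherits(dataset, "expression_dataset"))
  v <- dataset$values
  if (length(v) == 0) stop("dataset is empty")
  t_scale * sum(v) / (nrow(v) * ncol(v) * 10)
}

#' Destruction: remove d randomly chosen selected genes
#'
#' Picks `min(d, n_selected - 1)` distinct selected genes uniformly at
#' random, records them in removal order, and deselects them in the partial
#' solution (genotype entries set to the lower bound). At least one gene
#' always remains selected. A solution with at most one selected gene is
#' returned unchanged with an empty removal list (a signal, not an error).
#'
#' @param solution a widow with an attached evaluation.
#' @param d requested destruction size.
#' @param threshold binarization cut used to identify selected genes.
#' @param lb value assigned to deselected genotype entries.
#' @return a list with `partial` (widow, unevaluated if changed) and
#'   `removed` (ordered integer vector of removed gene indices).
#' @export
destruct <- function(solution, d, threshold = 0.5, lb = 0) {
  sel <- which(solution$genotype > threshold)
  if (length(sel) <= 1) {
    return(list(partial = solution, removed = integer(0)))
  }
  d_eff <- min(d, length(sel) - 1L)
  removed <- sel[sample.int(length(sel), d_eff)]
  g <- solution$genotype
  g[removed] <- lb
  list(partial = new_widow(g), removed = removed)
}

#' Greedy reconstruction of a destroyed solution
#'
#' For each removed gene, in removal order, forms the candidate with that
#' gene re-selected (genotype entry set to `ub`) and keeps it iff its
#' fitness is strictly lower than the incumbent's (a tie favours the
#' smaller subset, i.e. the incumbent). In `"swap_aware"` mode each removed
#' gene is additionally tested as a one-for-one exchange against every
#' currently selected gene.
#'
#' @param partial widow returned by [destruct()].
#' @param removed ordered integer vector of removed gene indices.
#' @param evaluator a [make_evaluator()] closure.
#' @param ub value assigned to re-selected genotype entries.
#' @param threshold binarization cut.
#' @param mode `"greedy"` or `"swap_aware"`.
#' @return the reconstructed widow, evaluated.
#' @export
construct_greedy <- function(partial, removed, evaluator, ub = 1,
                             threshold = 0.5, mode = "greedy") {
  incumbent <- eval_widow(partial, evaluator)
  for (j in removed) {
    g <- incumbent$genotype
    g[j] <- ub
    cand <- eval_widow(new_widow(g), evaluator)
    if (cand$eval$fitness < incumbent$eval$fitness) incumbent <- cand
    if (mode == "swap_aware") {
      for (s in setdiff(which(incumbent$genotype > threshold), j)) {
        g2 <- incumbent$genotype
        g2[j] <- ub
        g2[s] <- 1 - ub                 # deselect s, select j
        cand2 <- eval_widow(new_widow(g2), evaluator)
        if (cand2$eval$fitness < incumbent$eval$fitness) incumbent <- cand2
      }
    }
  }
  incumbent
}

#' Constant-temperature acceptance rule
#'
#' An improving candidate is always accepted. A non-improving one is
#' accepted with probability `exp(-dE / T)`, `dE = f(candidate) -
#' f(incumbent) >= 0`, with `r` drawn uniform on \[0, 1) from the current
#' RNG state. At `T = 0` every non-improving candidate is rejected.
#'
#' @param incumbent_fitness fitness of the current solution.
#' @param candidate_fitness fitness of the rebuilt solution.
#' @param temperature constant temperature `T >= 0`.
#' @return logical: accept the candidate?
#' @export
accept_candidate <- function(incumbent_fitness, candidate_fitness,
                             temperature) {
  if (temperature < 0) stop("temperature must be >= 0")
  if (candidate_fitness < incumbent_fitness) return(TRUE)
  if (temperature == 0) return(FALSE)
  de <- candidate_fitness - incumbent_fitness
  stats::runif(1) < exp(-de / temperature)
}

#' Run iterated greedy refinement
#'
#' Repeats destruct / greedy-construct / accept for `config$ig_iterations`
#' iterations from `start`, tracking the incumbent (which may worsen through
#' SA acceptance) and the best-so-far separately. The returned best never
#' has fitness above the start's. Consumes the current RNG state unless
#' `use_config_seed = TRUE`, in which case a private stream is derived from
#' `config$seed`.
#'
#' @param start an evaluated widow.
#' @param dataset the normalized dataset (used for the temperature).
#' @param config an [ig_config()].
#' @param evaluator a [make_evaluator()] closure.
#' @param use_config_seed draw all IG randomness from `config$seed` instead
#'   of the current RNG state (standalone use).
#' @return a list with `best` (evaluated widow), `best_fitness_history`
#'   (per-iteration best-so-far, length `ig_iterations + 1`),
#'   `incumbent_fitness_history`, and `sa_accepts` (iterations where a
#'   non-improving candidate was accepted).
#' @export
run_ig <- function(start, dataset, config, evaluator,
                   use_config_seed = FALSE) {
  stopifnot(!is.null(start$eval))
  temperature <- compute_temperature(dataset, config$t_scale)
  spec <- attr(evaluator, "spec")
  threshold <- if (is.null(spec)) 0.5 else spec$threshold
  body <- function() {
    incumbent <- start
    best <- start
    best_hist <- numeric(config$ig_iterations + 1)
    inc_hist <- numeric(config$ig_iterations + 1)
    best_hist[1] <- best$eval$fitness
    inc_hist[1] <- incumbent$eval$fitness
    sa_accepts <- integer(0)
    for (it in seq_len(config$ig_iterations)) {
      d <- config$d
      if (is.null(d)) {
        d <- max(1L, as.integer(round(config$destruct_frac *
                                        incumbent$eval$n_selected)))
      }
      des <- destruct(incumbent, d, threshold = threshold)
      if (length(des$removed) == 0) {
        candidate <- incumbent
      } else {
        candidate <- construct_greedy(des$partial, des$removed, evaluator,
                                      threshold = threshold,
                                      mode = config$construct_mode)
      }
      improving <- candidate$eval$fitness < incumbent$eval$fitness
      if (accept_candidate(incumbent$eval$fitness, candidate$eval$fitness,
                           temperature)) {
        if (!improving && candidate$eval$fitness > incumbent$eval$fitness) {
          sa_accepts <- c(sa_accepts, it)
        }
        incumbent <- candidate
      }
      if (incumbent$eval$fitness < best$eval$fitness ||
          (incumbent$eval$fitness == best$eval$fitness &&
           incumbent$eval$n_selected < best$eval$n_selected)) {
        best <- incumbent
      }
      best_hist[it + 1] <- best$eval$fitness
      inc_hist[it + 1] <- incumbent$eval$fitness
    }
    list(best = best, best_fitness_history = best_hist,
         incumbent_fitness_history = inc_hist, sa_accepts = sa_accepts,
         temperature = temperature)
  }
  if (use_config_seed) with_seed(config$seed, body()) else body()
}
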