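# Black widow optimization (BWO) for wrapper gene selection.
#
# A population of "widows" (continuous genotypes on [lb, ub], decoded to
# binary gene masks) evolves by pairwise procreation (per-coordinate convex
# crossover), cannibalism-style survivor selection (the better parent and
# the better child of each mating survive), and swap mutation. The best
# widow found so far (W*) is tracked across iterations.

#' BWO configuration
#'
#' The defaults are the standard settings for this optimizer on microarray
#' gene selection: population 10, 100 iterations, procreation rate 0.6,
#' mutation rate 0.4, genotype bounds \[0, 1\].
#'
#' Population-size closure: each iteration produces `Nr` procreation
#' survivors (`round(pr * pop_size)` rounded down to even, two survivors per
#' mating) plus `Nm = round(mr * pop_size)` mutants, and `Nr + Nm` must
#' equal `pop_size`. This is checked at construction, never mid-run.
#'
#' @param pop_size population size Npop.
#' @param max_iterations iteration budget (the only hard stopping rule).
#' @param pr procreation rate in \[0, 1\].
#' @param mr mutation rate in \[0, 1\].
#' @param lb,ub genotype bounds.
#' @param seed master seed for the run.
#' @param procreate_repeats how many times the crossover is applied per
#'   chosen pair (each application contributing one mating to the survivor
#'   pool is *not* done; repeats > 1 re-mate the same pair and keep the
#'   final mating, an alternative variant). Default 1.
#' @param patience optional no-improvement stop: end the run early when the
#'   best fitness has not improved by more than `patience_tol` for this many
#'   iterations. `NULL` (default) disables it.
#' @param patience_tol minimum improvement that resets the patience counter.
#' @return an object of class `bwo_config`.
#' @export
bwo_config <- function(pop_size = 10, max_iterations = 100, pr = 0.6,
                       mr = 0.4, lb = 0, ub = 1, seed = 1L,
                       procreate_repeats = 1, patience = NULL,
                       patience_tol = 1e-2) {
  if (pr < 0 || pr > 1 || mr < 0 || mr > 1) stop("pr and mr must be in [0, 1]")
  if (lb > ub) stop("lb must be <= ub")
  if (pop_size < 2) stop("pop_size must be >= 2")
  nr <- round(pr * pop_size)
  nr <- nr - nr %% 2                    # two survivors per mating
  nm <- round(mr * pop_size)
  if (nr + nm != pop_size) {
    stop("population-size closure violated: even(round(pr*Npop)) + ",
         "round(mr*Npop) = ", nr, " + ", nm, " != ", pop_size)
  }
  structure(list(pop_size = as.integer(pop_size),
                 max_iterations = as.integer(max_iterations),
                 pr = pr, mr = mr, lb = lb, ub = ub, seed = as.integer(seed),
                 n_procreate = as.integer(nr), n_mutate = as.integer(nm),
                 procreate_repeats = as.integer(procreate_repeats),
                 patience = patience, patience_tol = patience_tol),
            class = "bwo_config")
}

new_widow <- function(genotype, evaluation = NULL) {
  list(genotype = genotype, eval = evaluation)
}

eval_widow <- function(widow, evaluator) {
  if (is.null(widow$eval)) widow$eval <- evaluator(widow$genotype)
  widow
}

# Sort a population ascending by fitness; ties toward fewer selected genes,
# then original order (stable).
sort_population <- function(population) {
  fit <- vapply(population, function(w) w$eval$fitness, numeric(1))
  size <- vapply(population, function(w) w$eval$n_selected, numeric(1))
  population[order(fit, size)]
}

#' Initialize a BWO population
#'
#' Each genotype entry is drawn uniformly on \[lb, ub\] from the current RNG
#' state; widows are returned unevaluated.
#'
#' @param config a [bwo_config()].
#' @param nvar genotype length (number of genes).
#' @return a list of `pop_size` widows.
#' @export
init_population <- function(config, nvar) {
  lapply(seq_len(config$pop_size), function(i) {
    new_widow(stats::runif(nvar, config$lb, config$ub))
  })
}

#' Fitness-proportional selection probabilities
#'
#' Normalizes a vector of non-negative fitness values to probabilities
#' `f_i / sum(f)`. An all-zero vector yields uniform probabilities
#' (documented degenerate case). Exposed as a utility; the main loop's
#' survivor selection is rank-based, not probability-gated.
#'
#' @param fitness_values non-negative numeric vector.
#' @return probability vector summing to 1.
#' @export
selection_probability <- function(fitness_values) {
  if (any(fitness_values < 0)) stop("fitness values must be >= 0")
  s <- sum(fitness_values)
  if (s == 0) return(rep(1 / length(fitness_values), length(fitness_values)))
  fitness_values / s
}

#' Procreate two offspring from two parent widows
#'
#' Convex per-coordinate crossover: with a fresh random vector a (one
#' uniform \[0,1\] draw per coordinate),
#' `y1 = a*x1 + (1-a)*x2` and `y2 = a*x2 + (1-a)*x1`. Offspring stay within
#' the bounds by convexity, and `y1 + y2 == x1 + x2` exactly.
#'
#' @param x1,x2 parent widows (or bare genotype vectors).
#' @param alpha optional fixed mixing vector (for testing); drawn uniformly
#'   when `NULL`.
#' @return a list of two offspring widows.
#' @export
procreate <- function(x1, x2, alpha = NULL) {
  g1 <- if (is.list(x1)) x1$genotype else x1
  g2 <- if (is.list(x2)) x2$genotype else x2
  if (length(g1) != length(g2)) stop("parent genotypes differ in length")
  if (is.null(alpha)) alpha <- stats::runif(length(g1))
  if (length(alpha) != length(g1)) stop("alpha must match genotype length")
  list(new_widow(alpha * g1 + (1 - alpha) * g2),
       new_widow(alpha * g2 + (1 - alpha) * g1))
}

#' Cannibalism: keep the better parent and the better child
#'
#' Of one mating (parents `x1`, `x2`; children `y1`, `y2`), the
#' lower-fitness parent and lower-fitness child survive. Ties are broken
#' toward fewer selected genes, then toward the first argument.
#'
#' @param x1,x2 evaluated parent widows.
#' @param y1,y2 child widows (evaluated on demand).
#' @param evaluator a [make_evaluator()] closure.
#' @return a list `(survivor_parent, survivor_child)`.
#' @export
cannibalize_pair <- function(x1, x2, y1, y2, evaluator) {
  y1 <- eval_widow(y1, evaluator)
  y2 <- eval_widow(y2, evaluator)
  better <- function(a, b) {
    if (b$eval$fitness < a$eval$fitness) return(b)
    if (b$eval$fitness == a$eval$fitness &&
        b$eval$n_selected < a$eval$n_selected) return(b)
    a
  }
  list(better(x1, x2), better(y1, y2))
}

#' Swap mutation
#'
#' Exchanges the genotype values at two distinct uniformly chosen positions;
#' every other entry is untouched, so the multiset of genotype values is
#' preserved.
#'
#' @param widow a widow (or bare genotype vector).
#' @param positions optional fixed pair of 1-based positions (for testing).
#' @return the mutated widow, unevaluated.
#' @export
mutate_swap <- function(widow, positions = NULL) {
  g <- if (is.list(widow)) widow$genotype else widow
  if (length(g) < 2) stop("genotype must have length >= 2 to swap")
  if (is.null(positions)) positions <- sample.int(length(g), 2)
  if (length(positions) != 2 || positions[1] == positions[2]) {
    stop("positions must be two distinct indices")
  }
  g[positions] <- g[rev(positions)]
  new_widow(g)
}

#' One BWO generation
#'
#' From an evaluated population sorted ascending by fitness (pop1):
#' `n_procreate / 2` matings of two distinct uniformly drawn parents, each
#' contributing its better parent and better child to pop2; then `n_mutate`
#' widows drawn without replacement from pop1, each swap-mutated into pop3.
#' The new population pop2 + pop3 has size exactly `pop_size`, all
#' evaluated. Consumes the current RNG state.
#'
#' @param population evaluated, sorted list of widows.
#' @param config a [bwo_config()].
#' @param evaluator a [make_evaluator()] closure.
#' @return the next population (unsorted), length `pop_size`.
#' @export
bwo_iteration <- function(population, config, evaluator) {
  npop <- length(population)
  pop2 <- vector("list", config$n_procreate)
  if (config$n_procreate > 0) {
    for (p in seq_len(config$n_procreate %/% 2L)) {
      pair <- sample.int(npop, 2)
      x1 <- population[[pair[1]]]
      x2 <- population[[pair[2]]]
      for (r in seq_len(config$procreate_repeats)) {
        children <- procreate(x1, x2)
      }
      surv <- cannibalize_pair(x1, x2, children[[1]], children[[2]], evaluator)
      pop2[[2 * p - 1]] <- surv[[1]]
      pop2[[2 * p]] <- surv[[2]]
    }
  }
  pop3 <- list()
  if (config$n_mutate > 0) {
    mut_idx <- sample.int(npop, config$n_mutate)
    pop3 <- lapply(mut_idx, function(i) {
      eval_widow(mutate_swap(population[[i]]), evaluator)
    })
  }
  c(pop2, pop3)
}

#' Run plain black widow optimization
#'
#' Executes `max_iterations` generations on the wrapper objective, tracking
#' the best widow (W*) over every evaluated solution — including cannibalized
#' children. Fully deterministic for a fixed `config$seed` (the master seed
#' spawns separate streams for initialization and the generation loop, and
#' CV folds are fixed by `spec$cv_seed`).
#'
#' @param dataset a normalized [expression_dataset()].
#' @param config a [bwo_config()].
#' @param spec a [fitness_spec()].
#' @return a `run_trace` (see [run_bwo_ig()] for fields).
#' @export
run_bwo <- function(dataset, config, spec = fitness_spec()) {
  run_engine(dataset, config, spec, ig = NULL, ig_period = Inf,
             final_refine = FALSE, master_seed = config$seed)
}
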