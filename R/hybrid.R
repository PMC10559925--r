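# The BWO-IG hybrid: interleave IG refinement of the best widow (W*) into
# the BWO loop. After every `ig_period` BWO iterations (and once after the
# final iteration), IG refines W*; the refined solution replaces W* and is
# injected into the population in place of the current worst widow, so the
# improvement propagates into subsequent procreation.
#
# Stream isolation: one master seed spawns private random streams for
# initialization, the BWO generation loop, and IG. BWO therefore consumes
# exactly the same random draws whether or not IG fires, and with IG
# disabled the hybrid reduces bit-identically to plain run_bwo().

#' Hybrid BWO-IG configuration
#'
#' @param bwo a [bwo_config()].
#' @param ig an [ig_config()].
#' @param fitness a [fitness_spec()].
#' @param ig_period number of BWO iterations between IG invocations
#'   (default 10: with a 100-iteration budget, ten handoffs per run). A
#'   finite value must not exceed `bwo$max_iterations`; `Inf` disables
#'   periodic refinement.
#' @param final_refine run IG once more after the last BWO iteration
#'   (default TRUE).
#' @param seed master seed from which every stream seed is derived.
#' @return an object of class `hybrid_config`.
#' @export
hybrid_config <- function(bwo = bwo_config(), ig = ig_config(),
                          fitness = fitness_spec(), ig_period = 10,
                          final_refine = TRUE, seed = 1L) {
  if (ig_period < 1) stop("ig_period must be >= 1")
  if (is.finite(ig_period) && ig_period > bwo$max_iterations &&
      bwo$max_iterations > 0) {
    stop("ig_period (", ig_period, ") must not exceed bwo$max_iterations (",
         bwo$max_iterations, "); use ig_period = Inf to disable")
  }
  structure(list(bwo = bwo, ig = ig, fitness = fitness,
                 ig_period = ig_period, final_refine = isTRUE(final_refine),
                 seed = as.integer(seed)),
            class = "hybrid_config")
}

# Shared engine behind run_bwo() and run_bwo_ig().
run_engine <- function(dataset, bwo, spec, ig, ig_period, final_refine,
                       master_seed) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!dataset$normalized) {
    warning("dataset is not min-max normalized; distances may be dominated ",
            "by high-range genes")
  }
  nvar <- n_genes(dataset)
  s_init <- rng_stream(derive_seed(master_seed, "init"))
  s_bwo <- rng_stream(derive_seed(master_seed, "bwo"))
  s_ig <- rng_stream(derive_seed(master_seed, "ig"))
  evaluator <- make_evaluator(dataset, spec)
  state <- attr(evaluator, "state")

  population <- stream_do(s_init, init_population(bwo, nvar))
  population <- lapply(population, eval_widow, evaluator = evaluator)
  population <- sort_population(population)

  best <- function() new_widow(state$best_genotype, state$best)
  best_hist <- numeric(bwo$max_iterations + 1)
  best_size_hist <- integer(bwo$max_iterations + 1)
  pop_fit_hist <- vector("list", bwo$max_iterations + 1)
  best_hist[1] <- state$best$fitness
  best_size_hist[1] <- state$best$n_selected
  pop_fit_hist[[1]] <- vapply(population, function(w) w$eval$fitness,
                              numeric(1))
  ig_iterations <- integer(0)
  ig_evaluations <- 0L
  stagnant <- 0L
  completed <- 0L

  for (it in seq_len(bwo$max_iterations)) {
    population <- stream_do(s_bwo, bwo_iteration(population, bwo, evaluator))
    population <- sort_population(population)
    fire_ig <- !is.null(ig) &&
      ((is.finite(ig_period) && it %% ig_period == 0) ||
         (final_refine && it == bwo$max_iterations))
    if (fire_ig) {
      before <- state$count
      refined <- stream_do(s_ig, run_ig(best(), dataset, ig, evaluator))
      ig_evaluations <- ig_evaluations + (state$count - before)
      ig_iterations <- c(ig_iterations, it)
      # refined$best never degrades W*; inject it over the current worst
      population[[length(population)]] <- refined$best
    }
    best_hist[it + 1] <- state$best$fitness
    best_size_hist[it + 1] <- state$best$n_selected
    pop_fit_hist[[it + 1]] <- vapply(population, function(w) w$eval$fitness,
                                     numeric(1))
    completed <- it
    if (!is.null(bwo$patience)) {
      if (best_hist[it] - best_hist[it + 1] > bwo$patience_tol) {
        stagnant <- 0L
      } else {
        stagnant <- stagnant + 1L
      }
      if (stagnant >= bwo$patience) break
    }
  }
  if (completed < bwo$max_iterations) {
    keep <- seq_len(completed + 1)
    best_hist <- best_hist[keep]
    best_size_hist <- best_size_hist[keep]
    pop_fit_hist <- pop_fit_hist[keep]
  }
  structure(list(best_widow = best(),
                 best_fitness_history = best_hist,
                 best_size_history = best_size_hist,
                 population_fitness_history = pop_fit_hist,
                 ig_iterations = ig_iterations,
                 seed = master_seed,
                 evaluations = state$count,
                 ig_evaluations = ig_evaluations,
                 iterations = completed,
                 gene_ids = dataset$gene_ids),
            class = "run_trace")
}

#' @export
print.run_trace <- function(x, ...) {
  cat(sprintf(paste0("<run_trace: %d iterations, %d evaluations, final ",
                     "fitness %.5f, %d genes selected%s>\n"),
              x$iterations, x$evaluations,
              x$best_widow$eval$fitness, x$best_widow$eval$n_selected,
              if (length(x$ig_iterations))
                sprintf(", IG at {%s}",
                        paste(x$ig_iterations, collapse = ",")) else ""))
  invisible(x)
}

#' Run the hybrid BWO-IG optimizer
#'
#' Runs the BWO loop for `config$bwo$max_iterations` iterations; after every
#' `config$ig_period` iterations (and once after the final iteration when
#' `final_refine` is set), IG refines the current best widow. The refined
#' solution replaces W* and is injected over the current worst population
#' member. IG evaluations are counted separately in the trace.
#'
#' @param dataset a normalized [expression_dataset()].
#' @param config a [hybrid_config()].
#' @return an object of class `run_trace`: `best_widow` (final W*),
#'   `best_fitness_history` (length iterations + 1, entry 1 is the initial
#'   population's best; non-increasing), `best_size_history`,
#'   `population_fitness_history`, `ig_iterations` (iterations at which IG
#'   fired), `seed`, `evaluations`, `ig_evaluations`, `gene_ids`.
#' @export
run_bwo_ig <- function(dataset, config) {
  stopifnot(inherits(config, "hybrid_config"))
  run_engine(dataset, config$bwo, config$fitness, ig = config$ig,
             ig_period = config$ig_period,
             final_refine = config$final_refine, master_seed = config$seed)
}

#' Dispatch a single optimization run by method name
#'
#' @param dataset a normalized [expression_dataset()].
#' @param method one of `"bwo"`, `"ig"`, `"bwo-ig"`.
#' @param config a [hybrid_config()]; its `seed` is the master seed for the
#'   run. `"bwo"` ignores the IG settings; `"ig"` refines a single random
#'   evaluated widow with `config$ig`.
#' @return a `run_trace`.
#' @export
run_method <- function(dataset, method, config = hybrid_config()) {
  stopifnot(inherits(config, "hybrid_config"))
  if (!method %in% c("bwo", "ig", "bwo-ig")) {
    stop("unknown method '", method,
         "'; valid methods are: bwo, ig, bwo-ig")
  }
  if (method == "bwo") {
    bwo <- config$bwo
    bwo$seed <- config$seed
    return(run_bwo(dataset, bwo, config$fitness))
  }
  if (method == "bwo-ig") {
    return(run_bwo_ig(dataset, config))
  }
  # standalone IG from a random evaluated widow
  evaluator <- make_evaluator(dataset, config$fitness)
  state <- attr(evaluator, "state")
  s_init <- rng_stream(derive_seed(config$seed, "init"))
  start <- stream_do(s_init, init_population(config$bwo, n_genes(dataset)))[[1]]
  start <- eval_widow(start, evaluator)
  s_ig <- rng_stream(derive_seed(config$seed, "ig"))
  res <- stream_do(s_ig, run_ig(start, dataset, config$ig, evaluator))
  structure(list(best_widow = res$best,
                 best_fitness_history = res$best_fitness_history,
                 best_size_history = rep(res$best$eval$n_selected,
                                         length(res$best_fitness_history)),
                 population_fitness_history = NULL,
                 ig_iterations = seq_len(config$ig$ig_iterations),
                 seed = config$seed,
                 evaluations = state$count,
                 ig_evaluations = state$count,
                 iterations = config$ig$ig_iterations,
                 gene_ids = dataset$gene_ids),
            class = "run_trace")
}
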