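# The wrapper objective: decode a continuous genotype to a gene mask, score
# the mask by stratified k-fold cross-validated KNN error, and combine error
# and subset size into a single minimized fitness
#
#   fitness = alpha * error_rate + beta * n_selected / N,   beta = 1 - alpha.
#
# Lower is better everywhere in this package.

#' Configuration of the wrapper fitness evaluator
#'
#' @param alpha weight on the classification error term, in \[0, 1\]. The
#'   subset-size weight is `beta = 1 - alpha`. Default 0.99 — the usual
#'   wrapper-FS convention that accuracy dominates and subset size breaks
#'   near-ties.
#' @param knn_k neighbour count for the KNN classifier; must be odd (tie
#'   avoidance). Default 5.
#' @param cv_folds number of stratified CV folds, or `"loo"` for
#'   leave-one-out. Requested fold counts larger than the smallest class are
#'   reduced with a warning.
#' @param cv_seed seed fixing the fold assignment; folds are drawn once per
#'   optimization run and reused for every fitness call, so the objective is
#'   deterministic within a run.
#' @param threshold binarization cut: gene i is selected iff
#'   `genotype[i] > threshold` (strict). Default 0.5.
#' @param empty_mask_penalty fitness assigned when no gene is selected
#'   (default 1, the worst attainable value), so optimizers can traverse the
#'   empty mask without raising an error.
#' @return an object of class `fitness_spec`.
#' @export
fitness_spec <- function(alpha = 0.99, knn_k = 5, cv_folds = 10,
                         cv_seed = 1L, threshold = 0.5,
                         empty_mask_penalty = 1) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (knn_k < 1 || knn_k %% 2 == 0) stop("knn_k must be odd and >= 1")
  if (!identical(cv_folds, "loo")) {
    cv_folds <- as.integer(cv_folds)
    if (cv_folds < 2) stop("cv_folds must be >= 2 (or \"loo\")")
  }
  structure(list(alpha = alpha, beta = 1 - alpha, knn_k = as.integer(knn_k),
                 cv_folds = cv_folds, cv_seed = as.integer(cv_seed),
                 threshold = threshold,
                 empty_mask_penalty = empty_mask_penalty),
            class = "fitness_spec")
}

#' Decode a continuous genotype to a binary gene mask
#'
#' @param genotype numeric vector with entries in the optimizer bounds.
#' @param threshold cut value; `mask[i] = 1` iff `genotype[i] > threshold`.
#' @return integer 0/1 vector of the same length.
#' @export
decode_mask <- function(genotype, threshold = 0.5) {
  as.integer(genotype > threshold)
}

# Resolve the fold assignment for a dataset under a fitness spec, reducing
# the fold count to the smallest class size when needed.
resolve_folds <- function(dataset, spec) {
  n <- n_samples(dataset)
  if (identical(spec$cv_folds, "loo")) {
    return(list(fold_index = seq_len(n) - 1L, k = n))
  }
  smallest <- min(table(dataset$labels))
  k <- spec$cv_folds
  if (k > smallest) {
    warning("cv_folds reduced from ", k, " to ", smallest,
            " (smallest class size)")
    k <- smallest
  }
  make_stratified_folds(dataset$labels, k, spec$cv_seed)
}

#' Cross-validated KNN error of a gene mask
#'
#' Stratified k-fold CV; within each fold every held-out sample is labelled
#' by majority vote of its `knn_k` Euclidean-nearest training samples,
#' restricted to the selected gene columns. Fully deterministic: exact
#' distance ties are broken toward the lower sample index and residual label
#' ties toward the label of the single nearest neighbour.
#'
#' @param dataset a normalized [expression_dataset()].
#' @param mask binary vector with at least one selected gene.
#' @param spec a [fitness_spec()].
#' @param folds optional precomputed fold assignment (as returned by
#'   [make_stratified_folds()]); defaults to folds drawn from `spec$cv_seed`.
#' @return misclassified fraction over all samples, in \[0, 1\].
#' @export
knn_cv_error <- function(dataset, mask, spec = fitness_spec(), folds = NULL) {
  sel <- which(mask > 0)
  if (length(sel) == 0) stop("mask selects no genes; use evaluate_genotype()")
  if (is.null(folds)) folds <- resolve_folds(dataset, spec)
  X <- dataset$values[, sel, drop = FALSE]
  y <- as.integer(dataset$labels)
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  wrong <- 0L
  for (f in unique(folds$fold_index)) {
    test <- which(folds$fold_index == f)
    train <- which(folds$fold_index != f)
    k_eff <- spec$knn_k
    if (length(train) < k_eff) {
      warning("training fold smaller than knn_k; using k = ", length(train))
      k_eff <- length(train)
    }
    for (i in test) {
      ord <- order(D[i, train], train)        # ties -> lower sample index
      nb <- train[ord[seq_len(k_eff)]]
      votes <- tabulate(y[nb], nbins = max(y))
      top <- which(votes == max(votes))
      pred <- if (length(top) == 1L) top else y[nb[1L]]
      if (pred != y[i]) wrong <- wrong + 1L
    }
  }
  wrong / n
}

#' Evaluate a genotype under the wrapper objective
#'
#' Decodes the genotype, scores the mask, and combines error and size. An
#' empty mask receives `empty_mask_penalty` (error recorded as 1) rather
#' than an error, so search can pass through it.
#'
#' @inheritParams knn_cv_error
#' @param genotype numeric vector of length `n_genes(dataset)`.
#' @return an object of class `evaluated_solution`: fields `mask`,
#'   `error_rate`, `n_selected`, `fitness`.
#' @export
evaluate_genotype <- function(dataset, genotype, spec = fitness_spec(),
                              folds = NULL) {
  mask <- decode_mask(genotype, spec$threshold)
  n_sel <- sum(mask)
  if (n_sel == 0) {
    sol <- list(mask = mask, error_rate = 1, n_selected = 0L,
                fitness = spec$empty_mask_penalty)
  } else {
    err <- knn_cv_error(dataset, mask, spec, folds)
    sol <- list(mask = mask, error_rate = err, n_selected = as.integer(n_sel),
                fitness = spec$alpha * err +
                  spec$beta * n_sel / length(mask))
  }
  class(sol) <- "evaluated_solution"
  sol
}

#' Build a cached fitness evaluator for one optimization run
#'
#' Draws the CV folds once (from `spec$cv_seed`), then returns a closure
#' mapping a genotype to its [evaluate_genotype()] result. Results are cached
#' by mask, so re-evaluating a genotype with the same phenotype is free; the
#' closure also counts evaluation requests and tracks the best solution seen.
#'
#' @inheritParams knn_cv_error
#' @return a function `f(genotype)` with attribute `"state"`, an environment
#'   holding `count` (evaluation requests), `best` (best `evaluated_solution`
#'   seen) and `best_genotype`.
#' @export
make_evaluator <- function(dataset, spec = fitness_spec()) {
  folds <- resolve_folds(dataset, spec)
  state <- new.env(parent = emptyenv())
  state$cache <- new.env(parent = emptyenv())
  state$count <- 0L
  state$best <- NULL
  state$best_genotype <- NULL
  f <- function(genotype) {
    state$count <- state$count + 1L
    mask <- decode_mask(genotype, spec$threshold)
    key <- paste0("m", paste(which(mask > 0), collapse = "."))
    sol <- get0(key, envir = state$cache, inherits = FALSE)
    if (is.null(sol)) {
      sol <- evaluate_genotype(dataset, genotype, spec, folds)
      assign(key, sol, envir = state$cache)
    }
    if (is.null(state$best) || sol$fitness < state$best$fitness ||
        (sol$fitness == state$best$fitness &&
         sol$n_selected < state$best$n_selected)) {
      state$best <- sol
      state$best_genotype <- genotype
    }
    sol
  }
  attr(f, "state") <- state
  attr(f, "spec") <- spec
  attr(f, "folds") <- folds
  f
}

#' Exhaustive search over all gene masks
#'
#' Enumerates all 2^m non-empty masks of an at-most-12-gene dataset and
#' returns the optimum of the wrapper objective. Ties are broken toward
#' fewer selected genes, then toward the lexicographically smaller mask.
#' Used as the brute-force oracle that optimizer results are compared to.
#'
#' @inheritParams knn_cv_error
#' @return a list with `mask`, `fitness`, `error_rate`, `n_selected`.
#' @export
exhaustive_search <- function(dataset, spec = fitness_spec()) {
  m <- n_genes(dataset)
  if (m > 12) stop("exhaustive_search supports at most 12 genes (2^m masks)")
  folds <- resolve_folds(dataset, spec)
  best <- NULL
  for (code in seq_len(2^m - 1)) {
    mask <- as.integer(bitwAnd(bitwShiftR(code, seq_len(m) - 1L), 1L))
    err <- knn_cv_error(dataset, mask, spec, folds)
    fit <- spec$alpha * err + spec$beta * sum(mask) / m
    if (is.null(best) || fit < best$fitness ||
        (fit == best$fitness && sum(mask) < best$n_selected)) {
      best <- list(mask = mask, fitness = fit, error_rate = err,
                   n_selected = sum(mask))
    }
  }
  best
}
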