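# Synthetic labelled expression matrices with planted informative genes.
#
# Emulates the shape of public microarray benchmarks (tens of samples,
# thousands of genes, 2-4 classes) with a Gaussian class-conditional model:
# a small planted set of genes carries class signal, everything else is
# class-independent noise. The planted truth is returned alongside the data
# so selection-recovery metrics are computable.

#' Specification for a synthetic expression dataset
#'
#' @param n_samples number of samples.
#' @param n_genes total number of gene columns.
#' @param n_informative number of class-informative genes (`<= n_genes`).
#' @param n_classes number of classes, `>= 2`.
#' @param effect_size separation between adjacent class means of an
#'   informative gene, in units of `noise_sd`.
#' @param noise_sd standard deviation of every gene (informative and not).
#' @param class_proportions probability vector of length `n_classes`
#'   (default balanced); converted to exact class counts by largest
#'   remainder.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples, n_genes, n_informative, n_classes = 2,
                           effect_size = 3, noise_sd = 1,
                           class_proportions = rep(1 / n_classes, n_classes),
                           seed = 1L) {
  if (n_informative > n_genes) stop("n_informative must be <= n_genes")
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (length(class_proportions) != n_classes ||
      abs(sum(class_proportions) - 1) > 1e-8 || any(class_proportions <= 0)) {
    stop("class_proportions must be a positive vector of length n_classes summing to 1")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 n_informative = as.integer(n_informative),
                 n_classes = as.integer(n_classes),
                 effect_size = effect_size, noise_sd = noise_sd,
                 class_proportions = class_proportions,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Largest-remainder apportionment of n samples to class proportions,
# guaranteeing >= 2 per class.
class_counts <- function(n, proportions) {
  raw <- n * proportions
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    order_rem <- order(raw - counts, decreasing = TRUE)
    counts[order_rem[seq_len(rem)]] <- counts[order_rem[seq_len(rem)]] + 1
  }
  while (any(counts < 2)) {
    i <- which.min(counts)
    j <- which.max(counts)
    counts[i] <- counts[i] + 1
    counts[j] <- counts[j] - 1
  }
  as.integer(counts)
}

#' Generate a synthetic labelled expression dataset with planted truth
#'
#' Informative gene j in class c is drawn Normal(mu\[c, j\], noise_sd) with
#' the per-class means of each informative gene spaced `effect_size *
#' noise_sd` apart (class order randomly permuted per gene so the planted
#' genes are not all collinear). Non-informative genes are drawn iid
#' Normal(midpoint, noise_sd), independent of class. The returned dataset is
#' min-max normalized.
#'
#' @param spec a [synthetic_spec()].
#' @return a list with `dataset` (an [expression_dataset()]) and `truth`
#'   (fields `informative_indices`, `class_means` with classes as rows).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_samples
  m <- spec$n_genes
  counts <- class_counts(n, spec$class_proportions)
  sep <- spec$effect_size * spec$noise_sd
  mid <- (spec$n_classes - 1) * sep / 2
  res <- with_seed(spec$seed, {
    y <- rep(seq_len(spec$n_classes) - 1L, counts)
    y <- y[sample.int(n)]
    informative <- sort(sample.int(m, spec$n_informative))
    values <- matrix(stats::rnorm(n * m, mean = mid, sd = spec$noise_sd), n, m)
    class_means <- matrix(NA_real_, spec$n_classes, spec$n_informative)
    for (jj in seq_along(informative)) {
      levels_j <- (sample.int(spec$n_classes) - 1L) * sep
      class_means[, jj] <- levels_j
      j <- informative[jj]
      values[, j] <- stats::rnorm(n, mean = levels_j[y + 1L],
                                  sd = spec$noise_sd)
    }
    list(y = y, informative = informative, values = values,
         class_means = class_means)
  })
  ds <- expression_dataset(res$values, paste0("C", res$y),
                           paste0("g", seq_len(m)),
                           name = sprintf("synthetic_s%d", spec$seed))
  ds <- minmax_normalize(ds)
  list(dataset = ds,
       truth = list(informative_indices = res$informative,
                    class_means = res$class_means))
}

#' Generate a tiny perfectly-separable two-class fixture
#'
#' One designated gene perfectly separates the two classes (class-0 values
#' in \[0.1, 0.2\], class-1 values in \[0.8, 0.9\], so the within-class spread
#' is far smaller than the class gap); all other genes are uniform noise on
#' \[0, 1\]. Gene counts are capped at 12 so that exhaustive enumeration of
#' all 2^n_genes masks stays feasible — this fixture is the oracle substrate
#' for optimizer tests.
#'
#' @param n_samples number of samples (split evenly between two classes).
#' @param n_genes number of genes, `<= 12`.
#' @param informative_index 1-based column index of the separating gene.
#' @param seed integer seed.
#' @return a list with `dataset` and `truth` as in [generate_synthetic()].
#' @export
generate_tiny_separable <- function(n_samples = 20, n_genes = 8,
                                    informative_index = 1, seed = 1L) {
  if (n_genes > 12) {
    stop("n_genes must be <= 12 (exhaustive mask enumeration must be feasible)")
  }
  if (informative_index < 1 || informative_index > n_genes) {
    stop("informative_index out of range [1, ", n_genes, "]")
  }
  n0 <- n_samples %/% 2
  n1 <- n_samples - n0
  res <- with_seed(seed, {
    values <- matrix(stats::runif(n_samples * n_genes), n_samples, n_genes)
    values[, informative_index] <- c(stats::runif(n0, 0.1, 0.2),
                                     stats::runif(n1, 0.8, 0.9))
    ord <- sample.int(n_samples)
    list(values = values[ord, , drop = FALSE],
         y = c(rep(0L, n0), rep(1L, n1))[ord])
  })
  ds <- expression_dataset(res$values, paste0("C", res$y),
                           paste0("g", seq_len(n_genes)),
                           name = "tiny_separable", normalized = TRUE)
  list(dataset = ds,
       truth = list(informative_indices = informative_index,
                    class_means = matrix(c(0.15, 0.85), 2, 1)))
}
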