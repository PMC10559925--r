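# Multi-seed experiment harness: repeated independent optimization runs per
# method, summary statistics (mean / std / standard error of accuracy,
# fitness and selection size), Welch t-test comparisons between methods, and
# plain-text report output.

#' Run a multi-seed gene-selection experiment
#'
#' Executes `n_runs` independently seeded runs of each method on one
#' dataset. Per-run seeds (and per-run CV fold seeds) derive from the master
#' seed in `config`, so the whole experiment is bit-reproducible. Reported
#' accuracy is `1 - error_rate` of the final selected mask under the same
#' stratified CV folds used during the search (a search-time estimate; it
#' shares folds with the optimization and is therefore optimistically
#' biased relative to a held-out protocol).
#'
#' @param dataset a normalized [expression_dataset()].
#' @param methods character vector drawn from `"bwo"`, `"ig"`, `"bwo-ig"`.
#' @param config a [hybrid_config()]; `config$seed` is the master seed.
#' @param n_runs independent runs per method (default 30).
#' @return an object of class `experiment_report`: `per_run` data frame
#'   (method, run, seed, final_accuracy, final_error, n_selected,
#'   final_fitness, iterations_to_best, evaluations), `summary` data frame
#'   of mean/std/std_error per method and metric, `comparisons` data frame
#'   of pairwise Welch t-tests on accuracy, `traces` (best-fitness history
#'   per method/run), `final_masks`, `gene_ids`, `n_runs`, `seed`.
#' @export
run_experiment <- function(dataset, methods = c("bwo", "bwo-ig"),
                           config = hybrid_config(), n_runs = 30) {
  if (n_runs < 2) stop("n_runs must be >= 2")
  per_run <- list()
  traces <- list()
  masks <- list()
  for (method in methods) {
    for (r in seq_len(n_runs)) {
      run_seed <- derive_seed(config$seed, paste0(method, "-run-", r))
      cfg <- config
      cfg$seed <- run_seed
      cfg$fitness$cv_seed <- derive_seed(run_seed, "cv")
      trace <- run_method(dataset, method, cfg)
      ev <- trace$best_widow$eval
      hist <- trace$best_fitness_history
      per_run[[length(per_run) + 1]] <- data.frame(
        method = method, run = r, seed = run_seed,
        final_accuracy = 1 - ev$error_rate,
        final_error = ev$error_rate,
        n_selected = ev$n_selected,
        final_fitness = ev$fitness,
        # 0-based iteration at which the final best fitness was first reached
        iterations_to_best = which(hist == hist[length(hist)])[1] - 1L,
        evaluations = trace$evaluations,
        stringsAsFactors = FALSE)
      traces[[paste0(method, ".", r)]] <- hist
      masks[[paste0(method, ".", r)]] <- which(ev$mask > 0)
    }
  }
  per_run <- do.call(rbind, per_run)
  summary <- summarize_runs(per_run)
  comparisons <- NULL
  if (length(methods) >= 2) {
    pairs <- utils::combn(methods, 2, simplify = FALSE)
    comparisons <- do.call(rbind, lapply(pairs, function(p) {
      a <- per_run$final_accuracy[per_run$method == p[1]]
      b <- per_run$final_accuracy[per_run$method == p[2]]
      tt <- two_sample_t_test(a, b)
      data.frame(method_a = p[1], method_b = p[2],
                 mean_a = mean(a), mean_b = mean(b),
                 t_statistic = tt$statistic, p_value = tt$p_value,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(per_run = per_run, summary = summary,
                 comparisons = comparisons, traces = traces,
                 final_masks = masks, gene_ids = dataset$gene_ids,
                 n_runs = n_runs, seed = config$seed,
                 methods = methods),
            class = "experiment_report")
}

# mean / sample std / standard error per method and metric.
summarize_runs <- function(per_run) {
  metrics <- c("final_accuracy", "final_fitness", "n_selected",
               "iterations_to_best")
  out <- list()
  for (method in unique(per_run$method)) {
    rows <- per_run[per_run$method == method, ]
    for (metric in metrics) {
      x <- rows[[metric]]
      out[[length(out) + 1]] <- data.frame(
        method = method, metric = metric,
        mean = mean(x), std = stats::sd(x),
        std_error = stats::sd(x) / sqrt(length(x)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report: %s; %d runs each>\n",
              paste(x$methods, collapse = " vs "), x$n_runs))
  acc <- x$summary[x$summary$metric == "final_accuracy", ]
  for (i in seq_len(nrow(acc))) {
    cat(sprintf("  %-8s accuracy %.4f +/- %.4f (SE %.4f)\n",
                acc$method[i], acc$mean[i], acc$std[i], acc$std_error[i]))
  }
  if (!is.null(x$comparisons)) {
    for (i in seq_len(nrow(x$comparisons))) {
      cat(sprintf("  %s vs %s: t = %.3f, p = %.4g\n",
                  x$comparisons$method_a[i], x$comparisons$method_b[i],
                  x$comparisons$t_statistic[i], x$comparisons$p_value[i]))
    }
  }
  invisible(x)
}

#' Welch two-sample t-test with a degenerate-variance policy
#'
#' Unequal-variance two-sided t-test. When both samples have zero variance
#' the usual statistic is undefined; the documented policy is `t = 0, p = 1`
#' for equal means and `t = +/-Inf, p = 0` for unequal means.
#'
#' @param a,b numeric sample vectors, each of length >= 2.
#' @return a list with `statistic`, `p_value`, `df`.
#' @export
two_sample_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 observations per sample")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(statistic = 0, p_value = 1, df = NA_real_))
    }
    return(list(statistic = sign(mean(a) - mean(b)) * Inf, p_value = 0,
                df = NA_real_))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}

#' Write an experiment report to plain-text files
#'
#' Emits `summary.json` (summary statistics, comparisons, metadata),
#' `per_run.csv`, `convergence.csv` (method, run, iteration, best_fitness;
#' one row per trace entry), and one `genes_<method>_run<r>.txt` per run
#' listing the selected gene identifiers. [read_report()] reconstructs an
#' equivalent report from the directory.
#'
#' @param report an [run_experiment()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  jsonlite::write_json(
    list(methods = report$methods, n_runs = report$n_runs,
         seed = report$seed, summary = report$summary,
         comparisons = report$comparisons),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  utils::write.csv(report$per_run, file.path(out_dir, "per_run.csv"),
                   row.names = FALSE, quote = FALSE)
  conv <- do.call(rbind, lapply(names(report$traces), function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    hist <- report$traces[[key]]
    data.frame(method = parts[1], run = as.integer(parts[2]),
               iteration = seq_along(hist) - 1L, best_fitness = hist,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(conv, file.path(out_dir, "convergence.csv"),
                   row.names = FALSE, quote = FALSE)
  for (key in names(report$final_masks)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    writeLines(report$gene_ids[report$final_masks[[key]]],
               file.path(out_dir, sprintf("genes_%s_run%s.txt",
                                          parts[1], parts[2])))
  }
  invisible(out_dir)
}

#' Reload an experiment report written by [write_report()]
#'
#' @param out_dir directory written by [write_report()].
#' @return an `experiment_report` (without `final_masks` index positions
#'   when gene identifiers are not unique prefixes; masks are restored from
#'   the per-run gene lists).
#' @export
read_report <- function(out_dir) {
  meta <- jsonlite::read_json(file.path(out_dir, "summary.json"),
                              simplifyVector = TRUE)
  per_run <- utils::read.csv(file.path(out_dir, "per_run.csv"),
                             stringsAsFactors = FALSE)
  conv <- utils::read.csv(file.path(out_dir, "convergence.csv"),
                          stringsAsFactors = FALSE)
  traces <- list()
  for (key in unique(paste0(conv$method, ".", conv$run))) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    rows <- conv[conv$method == parts[1] & conv$run == as.integer(parts[2]), ]
    traces[[key]] <- rows$best_fitness[order(rows$iteration)]
  }
  masks <- list()
  gene_files <- list.files(out_dir, pattern = "^genes_.*\\.txt$")
  for (f in gene_files) {
    key <- sub("^genes_(.*)_run([0-9]+)\\.txt$", "\\1.\\2", f)
    masks[[key]] <- readLines(file.path(out_dir, f))
  }
  structure(list(per_run = per_run, summary = as.data.frame(meta$summary),
                 comparisons = if (is.null(meta$comparisons)) NULL
                               else as.data.frame(meta$comparisons),
                 traces = traces, final_masks = masks, gene_ids = NULL,
                 n_runs = meta$n_runs, seed = meta$seed,
                 methods = meta$methods),
            class = "experiment_report")
}
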