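# Reading, validating and normalizing labelled expression matrices, and
# stratified cross-validation folds.

#' Construct a labelled expression dataset
#'
#' The substrate every evaluator consumes: a numeric samples x genes matrix,
#' one class label per sample, and one identifier per gene column.
#'
#' @param values numeric matrix, n_samples rows x n_genes columns.
#' @param labels vector of class labels, one per row; coerced to factor.
#' @param gene_ids character vector of gene identifiers, one per column;
#'   defaults to the column names of `values`.
#' @param name free-text dataset tag.
#' @param normalized logical; set by [minmax_normalize()].
#' @return an object of class `expression_dataset` with fields `values`,
#'   `labels`, `gene_ids`, `name`, `normalized`.
#' @export
expression_dataset <- function(values, labels, gene_ids = colnames(values),
                               name = "dataset", normalized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  labels <- factor(labels)
  if (nrow(values) != length(labels)) {
    stop("number of rows of `values` (", nrow(values),
         ") must equal number of labels (", length(labels), ")")
  }
  if (ncol(values) != length(gene_ids)) {
    stop("number of columns of `values` (", ncol(values),
         ") must equal number of gene_ids (", length(gene_ids), ")")
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop("non-finite expression value at sample ", bad[1], ", gene ", bad[2])
  }
  if (nlevels(labels) < 2) stop("need at least 2 distinct class labels")
  counts <- table(labels)
  if (any(counts < 2)) {
    stop("every class needs >= 2 samples; offending class(es): ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  dimnames(values) <- list(NULL, gene_ids)
  structure(list(values = values, labels = labels, gene_ids = gene_ids,
                 name = name, normalized = isTRUE(normalized)),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset '%s': %d samples x %d genes, %d classes%s>\n",
              x$name, nrow(x$values), ncol(x$values), nlevels(x$labels),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Number of samples and genes
#' @param dataset an `expression_dataset`.
#' @return integer count.
#' @export
n_samples <- function(dataset) nrow(dataset$values)

#' @rdname n_samples
#' @export
n_genes <- function(dataset) ncol(dataset$values)

#' Load a labelled expression matrix from delimited text
#'
#' Expects samples as rows and genes as columns, with a header row of gene
#' identifiers and one label column. Use `transpose = TRUE` for the common
#' genes-as-rows microarray dump (there the label column becomes a label
#' *row* named `label_column`).
#'
#' @param path file path.
#' @param label_column name of the label column (default `"label"`).
#' @param delimiter field separator (default `","`).
#' @param transpose logical; if TRUE the file is genes-as-rows and is
#'   transposed after reading.
#' @param name dataset tag; defaults to the file name.
#' @param impute_missing if TRUE, missing numeric cells are replaced by the
#'   per-gene mean; by default missing values are rejected.
#' @return an [expression_dataset()].
#' @export
load_expression_delimited <- function(path, label_column = "label",
                                      delimiter = ",", transpose = FALSE,
                                      name = basename(path),
                                      impute_missing = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "",
                           quote = "\"")
  if (transpose) {
    ids <- raw[[1]]
    mat <- t(as.matrix(raw[, -1, drop = FALSE]))
    colnames(mat) <- ids
    raw <- data.frame(mat, check.names = FALSE, stringsAsFactors = FALSE)
  }
  if (!label_column %in% colnames(raw)) {
    stop("label column '", label_column, "' not found; columns are: ",
         paste(utils::head(colnames(raw), 10), collapse = ", "),
         if (ncol(raw) > 10) ", ..." else "")
  }
  labels <- raw[[label_column]]
  genes <- raw[, setdiff(colnames(raw), label_column), drop = FALSE]
  values <- matrix(NA_real_, nrow(genes), ncol(genes),
                   dimnames = list(NULL, colnames(genes)))
  for (j in seq_len(ncol(genes))) {
    col <- genes[[j]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col) & col != "" & toupper(col) != "NA")
    if (length(bad)) {
      stop("cannot parse cell as a number at row ", bad[1],
           ", column '", colnames(genes)[j], "': '", col[bad[1]], "'")
    }
    miss <- which(is.na(num) | col == "" | toupper(col) == "NA")
    if (length(miss)) {
      if (!impute_missing) {
        stop("missing value at row ", miss[1], ", column '",
             colnames(genes)[j],
             "' (set impute_missing = TRUE for per-gene mean imputation)")
      }
      num[miss] <- mean(num, na.rm = TRUE)
    }
    values[, j] <- num
  }
  expression_dataset(values, labels, colnames(genes), name = name)
}

#' Write an expression dataset back to CSV
#'
#' Emits samples-as-rows CSV with a header of gene identifiers plus a final
#' label column, reloadable by [load_expression_delimited()].
#'
#' @param dataset an `expression_dataset`.
#' @param path output file path.
#' @param label_column name for the label column.
#' @return `path`, invisibly.
#' @export
write_expression_csv <- function(dataset, path, label_column = "label") {
  df <- as.data.frame(dataset$values, check.names = FALSE)
  df[[label_column]] <- as.character(dataset$labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Min-max normalize every gene column to [0, 1]
#'
#' Rescales each gene column via (x - min) / (max - min) so that KNN
#' Euclidean distances are scale-comparable across genes and the IG
#' acceptance temperature lands on the same order as fitness differences.
#' Constant columns map to 0 everywhere. Idempotent.
#'
#' @param dataset an `expression_dataset`.
#' @return a normalized `expression_dataset` (`normalized = TRUE`).
#' @export
minmax_normalize <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  v <- dataset$values
  mins <- apply(v, 2, min)
  rng <- apply(v, 2, max) - mins
  keep <- rng > 0
  v <- sweep(v, 2, mins, "-")
  v[, keep] <- sweep(v[, keep, drop = FALSE], 2, rng[keep], "/")
  v[, !keep] <- 0
  out <- dataset
  out$values <- v
  out$normalized <- TRUE
  out
}

#' Stratified k-fold assignment
#'
#' Shuffles each class separately (deterministically from `seed`) and deals
#' its samples round-robin across folds, so per-fold class counts differ from
#' perfect proportionality by at most one sample.
#'
#' @param labels vector of class labels.
#' @param k number of folds, `2 <= k <=` size of the smallest class.
#' @param seed integer seed.
#' @return a list with `fold_index` (0-based fold per sample) and `k`.
#' @export
make_stratified_folds <- function(labels, k, seed) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes to stratify")
  k <- as.integer(k)
  if (k < 2) stop("k must be >= 2")
  smallest <- min(table(labels))
  if (k > smallest) {
    stop("k (", k, ") exceeds the smallest class size (", smallest, ")")
  }
  fold <- integer(length(labels))
  with_seed(seed, {
    offset <- 0L
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      # continue dealing where the previous class left off, so remainder
      # samples spread over different folds instead of piling onto fold 0
      fold[idx] <- (offset + seq_along(idx) - 1L) %% k
      offset <- (offset + length(idx)) %% k
    }
  })
  list(fold_index = fold, k = k)
}
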