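#' Construct a window x sample count matrix
#'
#' Container for capture-based methylation read counts: an integer matrix
#' with windows (`"contig:start-end"` ids) as rows and samples as columns,
#' plus per-sample library sizes. Library sizes default to the column sums
#' at construction and are deliberately preserved through window filtering:
#' sequencing depth is a property of the library, not of the retained
#' window set.
#'
#' @param counts Non-negative integer matrix with row and column names.
#' @param libsize Optional named numeric vector of per-sample library
#'   sizes; defaults to `colSums(counts)`.
#' @return A `meth_counts` object (list with elements `counts`, `libsize`).
#' @export
meth_counts <- function(counts, libsize = NULL) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  if (is.null(colnames(counts)) || (nrow(counts) > 0L && is.null(rownames(counts)))) {
    stop("counts must have window row names and sample column names")
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "double"
  if (is.null(libsize)) {
    libsize <- colSums(counts)
  } else {
    if (is.null(names(libsize))) names(libsize) <- colnames(counts)
    if (!setequal(names(libsize), colnames(counts))) {
      stop("libsize names must match sample names")
    }
    libsize <- libsize[colnames(counts)]
    if (any(libsize <= 0)) stop("library sizes must be positive")
  }
  structure(list(counts = counts, libsize = libsize), class = "meth_counts")
}

#' @export
print.meth_counts <- function(x, ...) {
  cat(
    "meth_counts:", nrow(x$counts), "windows x", ncol(x$counts), "samples;",
    "median library size", format(stats::median(x$libsize), big.mark = ","), "\n"
  )
  invisible(x)
}

#' @export
dim.meth_counts <- function(x) dim(x$counts)

#' Filter low-information windows
#'
#' Keeps the windows with at least `min_total` reads summed over all
#' samples and at least `min_positive` samples with a non-zero count
#' (both thresholds inclusive). Library sizes are not recomputed.
#' The defaults mirror the usual capture-data screen of 10 total reads
#' and 10 individuals with positive counts.
#'
#' @param x A `meth_counts`.
#' @param min_total Minimum total read count per window (default 10).
#' @param min_positive Minimum number of samples with a positive count
#'   (default 10).
#' @return A filtered `meth_counts` with the original library sizes.
#' @export
filter_windows <- function(x, min_total = 10, min_positive = 10) {
  stopifnot(inherits(x, "meth_counts"))
  if (min_total < 0 || min_positive < 0) stop("filter thresholds must be >= 0")
  keep <- rowSums(x$counts) >= min_total &
    rowSums(x$counts > 0) >= min_positive
  out <- x
  out$counts <- x$counts[keep, , drop = FALSE]
  out
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values factors per sample, via the standard recipe:
#' the reference sample is the one whose 75th-percentile scaled count is
#' closest to the mean of those percentiles; pairwise log2 ratios of
#' depth-scaled proportions (M) are trimmed 30% two-sided, average log2
#' proportions (A) 5%, and the factor is 2 to the inverse-variance
#' weighted mean of the retained M values; factors are centred so their
#' product is 1. Depth itself is carried by the library sizes, so factors
#' capture only composition bias.
#'
#' @param x A `meth_counts` (normally after [filter_windows()]).
#' @return Named numeric vector of positive factors, product 1.
#' @export
tmm_factors <- function(x) {
  stopifnot(inherits(x, "meth_counts"))
  if (ncol(x$counts) < 2L) stop("TMM needs at least two samples")
  zero <- colSums(x$counts) == 0
  if (any(zero)) {
    stop(
      "sample(s) with all-zero counts: ",
      paste(colnames(x$counts)[zero], collapse = ", ")
    )
  }
  f <- edgeR::calcNormFactors(x$counts,
    lib.size = x$libsize, method = "TMM"
  )
  setNames(f, colnames(x$counts))
}

#' Counts per million (TMM-adjusted)
#'
#' `CPM_wi = Y_wi / (L_i * f_i) * 1e6`, where `L_i` is the library size and
#' `f_i` the normalization factor. No pseudo-count is added.
#'
#' @param x A `meth_counts`.
#' @param factors Named normalization factors covering all samples
#'   (e.g. from [tmm_factors()]); defaults to 1 for every sample.
#' @return Numeric matrix of the same shape as the counts.
#' @export
cpm_matrix <- function(x, factors = NULL) {
  stopifnot(inherits(x, "meth_counts"))
  factors <- check_factors(x, factors)
  sweep(x$counts, 2L, x$libsize * factors, "/") * 1e6
}

#' Per-sample mean-methylation covariate
#'
#' The normalization-adjusted total count per sample,
#' `sum_w Y_wi / f_i` — the "mean DNA methylation" summary used as a
#' single-variable classifier input.
#'
#' @inheritParams cpm_matrix
#' @return Named numeric vector per sample.
#' @export
mean_methylation <- function(x, factors = NULL) {
  stopifnot(inherits(x, "meth_counts"))
  factors <- check_factors(x, factors)
  colSums(x$counts) / factors
}

check_factors <- function(x, factors) {
  if (is.null(factors)) {
    return(setNames(rep(1, ncol(x$counts)), colnames(x$counts)))
  }
  if (is.null(names(factors))) names(factors) <- colnames(x$counts)
  missing <- setdiff(colnames(x$counts), names(factors))
  if (length(missing)) {
    stop("missing normalization factor for: ", paste(missing, collapse = ", "))
  }
  factors[colnames(x$counts)]
}

#' Read / write count matrices as TSV
#'
#' Rows are keyed `"contig:start-end"` (0-based half-open), columns are
#' sample ids. Library sizes are recomputed from the file unless supplied.
#'
#' @param path TSV file.
#' @param libsize Optional library sizes (see [meth_counts()]).
#' @return A `meth_counts`.
#' @export
read_counts_tsv <- function(path, libsize = NULL) {
  df <- read.delim(path, row.names = 1L, check.names = FALSE)
  meth_counts(as.matrix(df), libsize = libsize)
}

#' @rdname read_counts_tsv
#' @param x A `meth_counts` to write.
#' @export
write_counts_tsv <- function(x, path) {
  stopifnot(inherits(x, "meth_counts"))
  df <- data.frame(window = rownames(x$counts), x$counts,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample metadata table as TSV
#'
#' Columns: `sample_id`, `rank` (high/low), `age` (adult/cub). Factor
#' reference levels are high and adult, so model coefficients are the
#' low-ranking and cub effects.
#'
#' @param path TSV file.
#' @return data.frame with factor columns `rank`, `age`.
#' @export
read_samples_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  as_sample_table(df)
}

#' @rdname read_samples_tsv
#' @param samples Sample table to write.
#' @export
write_samples_tsv <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

as_sample_table <- function(df) {
  req <- c("sample_id", "rank", "age")
  if (!all(req %in% names(df))) {
    stop("sample table needs columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop("sample ids must be unique")
  if (!all(df$rank %in% c("high", "low"))) stop("rank must be high/low")
  if (!all(df$age %in% c("adult", "cub"))) stop("age must be adult/cub")
  df$rank <- factor(df$rank, levels = c("high", "low"))
  df$age <- factor(df$age, levels = c("adult", "cub"))
  df
}
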