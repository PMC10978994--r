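#' Build the classifier feature table
#'
#' One row per sample: the rank class as label, the age class as a
#' covariate, and either one CPM feature per DMR (counts summed over the
#' DMR's member windows, then scaled by the effective library size) or —
#' with `dmrs = "mean"` — the single mean-methylation covariate. These
#' are the design matrices of the four classifiers: total, selected and
#' excluded DMR sets, and mean methylation.
#'
#' @param x A [meth_counts()] containing the DMR windows.
#' @param factors Normalization factors.
#' @param dmrs DMR table from [call_dmrs()], or the string `"mean"`.
#' @param samples Sample table.
#' @param per_window Use one feature per member window instead of the
#'   per-DMR sum (default `FALSE`).
#' @return data.frame with columns `rank` (factor label), `age` and one
#'   numeric column per feature.
#' @export
build_feature_table <- function(x, factors = NULL, dmrs, samples,
                                per_window = FALSE) {
  stopifnot(inherits(x, "meth_counts"))
  samples <- as_sample_table(samples)
  factors <- check_factors(x, factors)
  eff_lib <- (x$libsize * factors)[samples$sample_id]
  counts <- x$counts[, samples$sample_id, drop = FALSE]
  if (identical(dmrs, "mean")) {
    feats <- data.frame(
      mean_methylation = unname(mean_methylation(
        meth_counts(counts, x$libsize[samples$sample_id]),
        factors[samples$sample_id]
      ))
    )
  } else {
    if (!nrow(dmrs)) stop("empty DMR list; use dmrs = \"mean\" for RF4")
    wins <- dmrs$windows
    miss <- setdiff(unlist(wins), rownames(counts))
    if (length(miss)) {
      stop("DMR window(s) absent from the matrix: ", paste(miss, collapse = ", "))
    }
    if (per_window) {
      ids <- unlist(wins)
      feats <- as.data.frame(t(counts[ids, , drop = FALSE]) / eff_lib * 1e6)
      names(feats) <- make.names(ids)
    } else {
      feats <- as.data.frame(vapply(seq_along(wins), function(i) {
        colSums(counts[wins[[i]], , drop = FALSE]) / eff_lib * 1e6
      }, numeric(nrow(samples))))
      names(feats) <- dmrs$dmr_id
    }
  }
  if (anyNA(feats) || any(!is.finite(as.matrix(feats)))) {
    stop("feature table contains missing or non-finite values")
  }
  cbind(
    data.frame(rank = samples$rank, age = samples$age),
    feats
  )
}

#' Out-of-bag error over repeated random forests
#'
#' For each repetition a forest of `n_trees` classification trees is
#' grown (bootstrap bags of size n with replacement, `mtry =
#' floor(sqrt(p))`, Gini splitting, majority vote) and the out-of-bag
#' misclassification rate recorded. Each repetition uses its own RNG
#' stream derived from `seed` plus the repetition index, so reports are
#' reproducible and independent of evaluation order.
#'
#' @param table Feature table from [build_feature_table()].
#' @param n_trees Trees per forest (default 2000).
#' @param n_reps Repetitions (default 1000).
#' @param seed Integer seed.
#' @param label Variable-set label carried into the report (e.g.
#'   "total", "selected", "excluded", "mean_methylation", "control").
#' @return An `rf_report`: list with `errors` (per repetition), `min`,
#'   `max`, `label`, `n_trees`, `n_reps`.
#' @export
oob_error_range <- function(table, n_trees = 2000L, n_reps = 1000L,
                            seed = 1L, label = "total") {
  if (n_trees < 1L || n_reps < 1L) stop("n_trees and n_reps must be >= 1")
  tab <- table(table$rank)
  if (any(tab < 2L)) stop("need at least 2 samples per rank class")
  errors <- vapply(seq_len(n_reps), function(r) {
    fit <- ranger::ranger(
      dependent.variable.name = "rank", data = table,
      num.trees = n_trees, classification = TRUE,
      replace = TRUE, sample.fraction = 1,
      seed = seed + r, num.threads = 1L
    )
    fit$prediction.error
  }, 0)
  structure(
    list(
      errors = errors, min = min(errors), max = max(errors),
      label = label, n_trees = n_trees, n_reps = n_reps
    ),
    class = "rf_report"
  )
}

#' @export
print.rf_report <- function(x, ...) {
  cat(sprintf(
    "rf_report [%s]: oob error range %.1f%%-%.1f%% over %d repetitions x %d trees\n",
    x$label, 100 * x$min, 100 * x$max, x$n_reps, x$n_trees
  ))
  invisible(x)
}

#' Matched-size random-location control
#'
#' For each requested feature count, draws that many windows uniformly
#' without replacement (optionally excluding a set, e.g. the true DMR
#' windows), treats them as single-window pseudo-DMRs, and computes the
#' out-of-bag report. On effect-free locations these controls hover at
#' chance, whatever the number of variables.
#'
#' @param x A [meth_counts()].
#' @param factors Normalization factors.
#' @param samples Sample table.
#' @param sizes Integer vector of feature counts to match.
#' @param n_trees,n_reps,seed As in [oob_error_range()].
#' @param exclude_windows Window ids never sampled (default none).
#' @return List of `rf_report`s, one per size, labelled
#'   `control_<size>`.
#' @export
random_location_control <- function(x, factors = NULL, samples, sizes,
                                    n_trees = 2000L, n_reps = 1000L,
                                    seed = 1L, exclude_windows = NULL) {
  pool <- setdiff(rownames(x$counts), exclude_windows)
  lapply(seq_along(sizes), function(si) {
    size <- sizes[si]
    if (size > length(pool)) stop("size exceeds available windows")
    wins <- with_seed(seed + 7919L * si, sample(pool, size))
    pseudo <- data.frame(
      dmr_id = sprintf("rand_%03d", seq_len(size)),
      stringsAsFactors = FALSE
    )
    pseudo$windows <- as.list(wins)
    tab <- build_feature_table(x, factors, pseudo, samples)
    oob_error_range(tab,
      n_trees = n_trees, n_reps = n_reps,
      seed = seed + si, label = sprintf("control_%d", size)
    )
  })
}

#' Chance band for oob-error assertions
#'
#' The majority-class baseline error plus/minus `k` binomial standard
#' errors at the given sample size; used to decide whether a classifier
#' performs above chance.
#'
#' @param samples Sample table.
#' @param k Half-width in standard errors (default 3).
#' @return Numeric `c(lower, upper)`.
#' @export
chance_band <- function(samples, k = 3) {
  samples <- as_sample_table(samples)
  n <- nrow(samples)
  p_min <- min(table(samples$rank)) / n
  se <- sqrt(p_min * (1 - p_min) / n)
  c(lower = max(0, p_min - k * se), upper = min(1, p_min + k * se))
}
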