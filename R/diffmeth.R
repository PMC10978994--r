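#' Design matrices for the rank model
#'
#' Full model: intercept + age (reference adult, indicator for cub) +
#' rank (reference high, indicator for low). Reduced model drops rank,
#' so the 1-df likelihood-ratio test targets the low-ranking effect and
#' a positive coefficient means hypermethylated in low-ranking samples.
#'
#' @param samples Sample table with factor columns `rank`, `age`.
#' @param include_age Set `FALSE` for the rank-only model used in
#'   per-age-class fits.
#' @return List with `full` and `reduced` design matrices and `coef`,
#'   the name of the rank column.
#' @export
rank_design <- function(samples, include_age = TRUE) {
  samples <- as_sample_table(samples)
  if (include_age) {
    full <- model.matrix(~ age + rank, data = samples)
    reduced <- model.matrix(~age, data = samples)
  } else {
    full <- model.matrix(~rank, data = samples)
    reduced <- model.matrix(~1, data = samples)
  }
  rownames(full) <- rownames(reduced) <- samples$sample_id
  if (qr(full)$rank < ncol(full)) {
    stop("design matrix is not full rank (missing factor level?)")
  }
  list(full = full, reduced = reduced, coef = "ranklow")
}

as_dge <- function(x, factors) {
  factors <- check_factors(x, factors)
  d <- edgeR::DGEList(counts = x$counts, lib.size = x$libsize)
  d$samples$norm.factors <- factors
  d
}

#' Empirical-Bayes dispersion estimation
#'
#' Common dispersion maximizing the summed adjusted profile likelihood,
#' and tagwise (per-window) dispersions shrunk toward it by weighted
#' likelihood empirical Bayes. No abundance trend is fitted by default.
#'
#' @param x A filtered [meth_counts()].
#' @param design Design list from [rank_design()] (the full matrix is
#'   used).
#' @param factors Normalization factors from [tmm_factors()].
#' @param prior_df Shrinkage weight in residual-df units. The default
#'   (`NULL`) estimates it from the spread of the per-window dispersion
#'   estimates, so homogeneous data shrink hard toward the common value
#'   while truly heterogeneous data retain window-specific dispersions.
#'   A fixed prior that over-weights noisy per-window estimates lets
#'   windows with underestimated dispersion leak through the test, which
#'   inflates the realized false-discovery rate.
#' @param trend Fit an abundance-dispersion trend (default `FALSE`).
#' @return List with `common`, `tagwise` (named per window) and
#'   `prior_df` (the estimated value when the default is used).
#' @export
estimate_dispersions <- function(x, design, factors = NULL, prior_df = NULL,
                                 trend = FALSE) {
  stopifnot(inherits(x, "meth_counts"))
  full <- design$full
  if (qr(full)$rank < ncol(full)) stop("design matrix is not full rank")
  if (nrow(full) - ncol(full) < 2L) {
    stop("need at least 2 residual degrees of freedom")
  }
  d <- as_dge(x, factors)
  d <- edgeR::estimateDisp(d, full,
    prior.df = prior_df,
    trend.method = if (trend) "locfit" else "none",
    tagwise = TRUE, robust = FALSE
  )
  list(
    common = d$common.dispersion,
    tagwise = setNames(d$tagwise.dispersion, rownames(x$counts)),
    prior_df = if (is.null(prior_df)) d$prior.df else prior_df
  )
}

#' Fit full and reduced NB GLMs per window
#'
#' Log-link negative-binomial GLMs with offsets `log(L_i * f_i)`, fitted
#' by iteratively reweighted least squares for the full (age + rank) and
#' reduced (rank dropped) designs at the supplied tagwise dispersions.
#' Coefficients are on the natural-log scale internally; reported logFC
#' is base 2.
#'
#' @inheritParams estimate_dispersions
#' @param dispersions Result of [estimate_dispersions()], or a single
#'   dispersion value recycled across windows.
#' @return List with `full`/`reduced` fits (edgeR `DGEGLM` objects) and
#'   `coef`, the tested coefficient name.
#' @export
fit_window_models <- function(x, design, factors = NULL, dispersions) {
  stopifnot(inherits(x, "meth_counts"))
  d <- as_dge(x, factors)
  phi <- if (is.list(dispersions)) dispersions$tagwise else dispersions
  if (length(phi) == 1L) phi <- rep(phi, nrow(x$counts))
  full <- edgeR::glmFit(d, design$full, dispersion = phi, prior.count = 0)
  reduced <- edgeR::glmFit(d, design$reduced, dispersion = phi, prior.count = 0)
  list(full = full, reduced = reduced, coef = design$coef)
}

#' Likelihood-ratio test for the rank effect
#'
#' `lr_stat = deviance_reduced - deviance_full`, referred to a chi-square
#' distribution with 1 df. Small negative statistics (numerical noise up
#' to 1e-6) are clamped to zero; larger ones indicate an inconsistent fit
#' and raise an error.
#'
#' @param fits Result of [fit_window_models()].
#' @return data.frame with `window`, `logFC` (base 2, low vs high),
#'   `lr_stat`, `p`.
#' @export
lrt_rank <- function(fits) {
  lr <- fits$reduced$deviance - fits$full$deviance
  if (any(lr < -1e-6, na.rm = TRUE)) {
    stop("negative likelihood-ratio statistic: full/reduced fits inconsistent")
  }
  lr <- pmax(lr, 0)
  logfc <- fits$full$coefficients[, fits$coef] / log(2)
  data.frame(
    window = rownames(fits$full$coefficients),
    logFC = unname(logfc),
    lr_stat = unname(lr),
    p = pchisq(lr, df = 1, lower.tail = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment, capped at 1; input outside \[0, 1\] is an error.
#'
#' @param p Numeric vector of p-values.
#' @return Vector of adjusted values (q-values) in input order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Full per-window differential-methylation test
#'
#' Convenience wrapper chaining [tmm_factors()], [estimate_dispersions()],
#' [fit_window_models()], [lrt_rank()] and [bh_adjust()] on an already
#' filtered count matrix.
#'
#' @param x A filtered [meth_counts()].
#' @param samples Sample table.
#' @param factors Optional precomputed normalization factors.
#' @param prior_df,trend Passed to [estimate_dispersions()].
#' @param include_age Include the age covariate (default `TRUE`).
#' @return data.frame with `window`, `logFC`, `lr_stat`, `p`, `q`.
#' @export
test_windows <- function(x, samples, factors = NULL, prior_df = NULL,
                         trend = FALSE, include_age = TRUE) {
  if (is.null(factors)) factors <- tmm_factors(x)
  design <- rank_design(samples, include_age = include_age)
  disp <- estimate_dispersions(x, design, factors,
    prior_df = prior_df, trend = trend
  )
  fits <- fit_window_models(x, design, factors, disp)
  res <- lrt_rank(fits)
  res$q <- bh_adjust(res$p)
  res
}

#' Merge adjacent significant windows into DMRs
#'
#' Windows with `q <= q_threshold` are significant; maximal runs of
#' grid-adjacent significant windows (end of one = start of the next, on
#' the same contig) sharing the sign of logFC become one DMR. A window
#' that was filtered out breaks adjacency, as does a sign change. A logFC
#' of exactly 0 joins neither direction. DMR effect is the unweighted
#' mean of member logFCs; significance summary is the minimum q.
#'
#' @param tests data.frame from [test_windows()] (needs `window`,
#'   `logFC`, `q`).
#' @param grid The [tile_windows()] grid the windows live on.
#' @param q_threshold FDR threshold (default 0.05).
#' @return data.frame of DMRs sorted by (contig, start): `dmr_id`,
#'   `contig`, `start`, `end`, `length`, `n_windows`, `direction`
#'   (hyper/hypo in low-ranking), `mean_logFC`, `min_q`, and a `windows`
#'   list-column of member window ids.
#' @export
call_dmrs <- function(tests, grid, q_threshold = 0.05) {
  sig <- tests[tests$q <= q_threshold & tests$logFC != 0, , drop = FALSE]
  if (!nrow(sig)) {
    return(empty_dmrs())
  }
  gi <- match(sig$window, rownames(grid))
  if (anyNA(gi)) stop("test windows missing from the grid")
  o <- order(gi)
  sig <- sig[o, , drop = FALSE]
  gi <- gi[o]
  same_run <- c(
    FALSE,
    diff(gi) == 1L &
      grid$contig[gi[-length(gi)]] == grid$contig[gi[-1L]] &
      sign(sig$logFC[-nrow(sig)]) == sign(sig$logFC[-1L])
  )
  run <- cumsum(!same_run)
  pieces <- lapply(split(seq_len(nrow(sig)), run), function(ix) {
    g <- gi[ix]
    data.frame(
      contig = grid$contig[g[1L]],
      start = grid$start[g[1L]],
      end = grid$end[g[length(g)]],
      length = grid$end[g[length(g)]] - grid$start[g[1L]],
      n_windows = length(ix),
      direction = if (sig$logFC[ix[1L]] > 0) "hyper" else "hypo",
      mean_logFC = mean(sig$logFC[ix]),
      min_q = min(sig$q[ix]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  out$windows <- lapply(split(seq_len(nrow(sig)), run), function(ix) sig$window[ix])
  out <- out[order(out$contig, out$start), , drop = FALSE]
  out$dmr_id <- sprintf("dmr_%03d", seq_len(nrow(out)))
  rownames(out) <- out$dmr_id
  out[, c(
    "dmr_id", "contig", "start", "end", "length", "n_windows",
    "direction", "mean_logFC", "min_q", "windows"
  )]
}

empty_dmrs <- function() {
  data.frame(
    dmr_id = character(), contig = character(), start = integer(),
    end = integer(), length = integer(), n_windows = integer(),
    direction = character(), mean_logFC = numeric(), min_q = numeric(),
    windows = I(list()), stringsAsFactors = FALSE
  )
}

#' Write DMRs as BED6 and as a full TSV
#'
#' BED score is `-10 * log10(min_q)` capped at 1000; the name column is
#' the direction.
#'
#' @param dmrs DMR table from [call_dmrs()].
#' @param bed_path,tsv_path Output paths (either may be `NULL` to skip).
#' @export
write_dmrs <- function(dmrs, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    score <- pmin(round(-10 * log10(pmax(dmrs$min_q, 1e-100))), 1000)
    bed <- data.frame(
      dmrs$contig, dmrs$start, dmrs$end, dmrs$direction, score,
      strand = "."
    )
    write.table(bed, bed_path,
      sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE
    )
  }
  if (!is.null(tsv_path)) {
    flat <- dmrs
    flat$windows <- vapply(flat$windows, paste, "", collapse = ",")
    write.table(flat, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dmrs)
}
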