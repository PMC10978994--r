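#' Per-age-class rank effects
#'
#' Fits the rank-only NB model separately within cubs and within adults
#' (each class gets its own TMM factors and dispersion estimates,
#' mirroring the full analysis with the age covariate dropped) and
#' returns the two logFC vectors at the requested windows.
#'
#' @param x A filtered [meth_counts()].
#' @param samples Sample table; both rank classes must be present within
#'   each age class.
#' @param windows Window ids to report (default: all windows of `x`).
#' @param prior_df Dispersion shrinkage weight (default: estimated).
#' @return data.frame with `window`, `logFC_cub`, `logFC_adult`.
#' @export
ageclass_effects <- function(x, samples, windows = NULL, prior_df = NULL) {
  stopifnot(inherits(x, "meth_counts"))
  samples <- as_sample_table(samples)
  if (is.null(windows)) windows <- rownames(x$counts)
  out <- data.frame(window = windows, stringsAsFactors = FALSE)
  for (cls in c("cub", "adult")) {
    sub_samples <- samples[samples$age == cls, , drop = FALSE]
    if (!all(c("high", "low") %in% sub_samples$rank)) {
      stop("age class ", cls, " lacks a rank class")
    }
    sub <- meth_counts(
      x$counts[, sub_samples$sample_id, drop = FALSE],
      libsize = x$libsize[sub_samples$sample_id]
    )
    res <- test_windows(sub, sub_samples,
      prior_df = prior_df,
      include_age = FALSE
    )
    out[[paste0("logFC_", cls)]] <- res$logFC[match(windows, res$window)]
  }
  out
}

#' Empirical test of cub/adult effect correlation
#'
#' Pearson correlation between the cub and adult logFC vectors at the
#' candidate windows, compared with a null distribution of correlations
#' on `n_draws` random window subsets of the same size drawn (without
#' replacement) from all supplied windows. The empirical p is one-sided
#' (null >= observed) with the +1 correction, so it can never be 0 and
#' its floor is `1/(n_draws + 1)`.
#'
#' @param effects data.frame from [ageclass_effects()] covering the full
#'   window pool.
#' @param candidate_windows Window ids of interest (e.g. DMR members);
#'   must be a subset of `effects$window`.
#' @param n_draws Number of null draws (default 1000).
#' @param seed Integer seed.
#' @return List with `r`, `n_windows`, `n_draws`, `empirical_p`, and
#'   `null_r` (the null distribution).
#' @export
effect_correlation_test <- function(effects, candidate_windows,
                                    n_draws = 1000L, seed = 1L) {
  i <- match(candidate_windows, effects$window)
  if (anyNA(i)) stop("candidate windows missing from the effect table")
  if (length(i) < 3L) stop("need at least 3 candidate windows")
  if (length(i) > nrow(effects)) stop("candidate set larger than the pool")
  r_obs <- cor(effects$logFC_cub[i], effects$logFC_adult[i])
  null_r <- with_seed(seed, {
    vapply(seq_len(n_draws), function(b) {
      j <- sample.int(nrow(effects), length(i))
      cor(effects$logFC_cub[j], effects$logFC_adult[j])
    }, 0)
  })
  list(
    r = r_obs, n_windows = length(i), n_draws = n_draws,
    empirical_p = (1 + sum(null_r >= r_obs)) / (1 + n_draws),
    null_r = null_r
  )
}

#' Wilcoxon signed-rank test (paired)
#'
#' Signed-rank test with the standard conventions: zero differences are
#' dropped; the null is enumerated exactly for up to 25 non-zero pairs
#' without ties, otherwise a normal approximation with tie and continuity
#' corrections is used. The continuity-corrected Z is always reported.
#' All differences zero (or no pairs) is treated as no evidence: p = 1.
#'
#' @param a,b Paired numeric vectors.
#' @return List: `test`, `statistic` (V, sum of positive ranks), `Z`,
#'   `p` (two-sided), `n` (non-zero pairs).
#' @export
signed_rank_test <- function(a, b) {
  if (length(a) != length(b)) stop("unpaired observations: lengths differ")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(
      test = "signed_rank_paired", statistic = NA_real_, Z = 0,
      p = 1, n = 0L
    ))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- table(r)
  mu <- n * (n + 1) / 4
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- if (sigma2 > 0) (v - mu - 0.5 * sign(v - mu)) / sqrt(sigma2) else 0
  exact <- n <= 25L && !any(duplicated(abs(d)))
  p <- suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = TRUE)$p.value
  )
  list(test = "signed_rank_paired", statistic = v, Z = z, p = p, n = n)
}

#' Wilcoxon rank-sum test (independent groups)
#'
#' Two-sided rank-sum test; exact null for small tie-free samples,
#' normal approximation with tie/continuity corrections otherwise. The
#' continuity-corrected Z is always reported.
#'
#' @param a,b Numeric vectors for the two groups.
#' @param exact Force exact (`TRUE`)/approximate (`FALSE`); default
#'   decides like `wilcox.test` (exact when both n < 50 and no ties).
#' @return List: `test`, `statistic` (W), `Z`, `p`, group sizes.
#' @export
rank_sum_test <- function(a, b, exact = NULL) {
  n1 <- length(a)
  n2 <- length(b)
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  mu <- n1 * n2 / 2
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
  z <- if (sigma2 > 0) (w - mu - 0.5 * sign(w - mu)) / sqrt(sigma2) else 0
  args <- list(x = a, y = b, correct = TRUE)
  if (!is.null(exact)) args$exact <- exact
  p <- suppressWarnings(do.call(stats::wilcox.test, args)$p.value)
  list(test = "rank_sum_independent", statistic = w, Z = z, p = p, n1 = n1, n2 = n2)
}

#' Mitochondrial vs nuclear abundance comparison
#'
#' Computes, per individual, the mean CPM over mitochondrial and over
#' nuclear windows (DNA) and genes (RNA), then runs four tests: paired
#' signed-rank mito-vs-nuclear for DNA and for RNA, and independent
#' rank-sum high-vs-low-ranking for overall mean DNA methylation and
#' mean expression.
#'
#' @param meth A [meth_counts()] of windows; `meth_factors` its
#'   normalization factors.
#' @param expr A [meth_counts()] keyed by gene id (e.g. from
#'   [simulate_expression_counts()]); `expr_factors` its factors.
#' @param genome A [gene_model()] providing the mitochondrial contig
#'   flags.
#' @param samples Sample table covering the methylation samples;
#'   expression samples must be a subset.
#' @param meth_factors,expr_factors Optional normalization factors.
#' @return List with `abundance` (per-individual table) and `tests`
#'   (named list of four test results: `dna_mito_vs_nuclear`,
#'   `rna_mito_vs_nuclear`, `dna_high_vs_low`, `rna_high_vs_low`).
#' @export
mito_nuclear_compare <- function(meth, expr, genome, samples,
                                 meth_factors = NULL, expr_factors = NULL) {
  stopifnot(inherits(meth, "meth_counts"), inherits(genome, "gene_model"))
  samples <- as_sample_table(samples)
  mito_contigs <- genome$mito_contigs

  win <- parse_window_id(rownames(meth$counts))
  win_mito <- win$contig %in% mito_contigs
  if (!any(win_mito) || all(win_mito)) {
    stop("need both mitochondrial and nuclear windows")
  }
  meth_cpm <- cpm_matrix(meth, meth_factors)
  dna <- data.frame(
    sample_id = colnames(meth_cpm),
    dna_mito = colMeans(meth_cpm[win_mito, , drop = FALSE]),
    dna_nuclear = colMeans(meth_cpm[!win_mito, , drop = FALSE]),
    dna_mean = colMeans(meth_cpm),
    stringsAsFactors = FALSE
  )

  gene_contig <- genome$genes$contig[
    match(rownames(expr$counts), genome$genes$gene_id)
  ]
  if (anyNA(gene_contig)) stop("expression rows not found in the gene model")
  gene_mito <- gene_contig %in% mito_contigs
  if (!any(gene_mito) || all(gene_mito)) {
    stop("need both mitochondrial and nuclear genes")
  }
  expr_cpm <- cpm_matrix(expr, expr_factors)
  rna <- data.frame(
    sample_id = colnames(expr_cpm),
    rna_mito = colMeans(expr_cpm[gene_mito, , drop = FALSE]),
    rna_nuclear = colMeans(expr_cpm[!gene_mito, , drop = FALSE]),
    rna_mean = colMeans(expr_cpm),
    stringsAsFactors = FALSE
  )

  abundance <- merge(dna, rna, by = "sample_id", all = TRUE)
  abundance$rank <- samples$rank[match(abundance$sample_id, samples$sample_id)]

  rank_of <- function(df) samples$rank[match(df$sample_id, samples$sample_id)]
  dna_rank <- rank_of(dna)
  rna_rank <- rank_of(rna)
  tests <- list(
    dna_mito_vs_nuclear = signed_rank_test(dna$dna_mito, dna$dna_nuclear),
    rna_mito_vs_nuclear = signed_rank_test(rna$rna_mito, rna$rna_nuclear),
    dna_high_vs_low = rank_sum_test(
      dna$dna_mean[dna_rank == "high"], dna$dna_mean[dna_rank == "low"]
    ),
    rna_high_vs_low = rank_sum_test(
      rna$rna_mean[rna_rank == "high"], rna$rna_mean[rna_rank == "low"]
    )
  )
  list(abundance = abundance, tests = tests)
}
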