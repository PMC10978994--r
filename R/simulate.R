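#' Simulation configuration
#'
#' Holds everything the synthetic-data generator needs: the cohort layout,
#' the contigs (with a mitochondrial flag), the window width, the
#' negative-binomial noise model and the planted rank-associated DMRs.
#' Defaults mirror a field cohort of 42 individuals: 9 high-ranking cubs,
#' 9 high-ranking adults, 15 low-ranking cubs and 9 low-ranking adults.
#'
#' The count model for window w and sample i is
#' `Y_wi ~ NB(mu_wi, phi)` with `mu_wi = lambda_w * (L_i/1e6) *
#' 2^(beta_w * [rank_i = low] + gamma * [age_i = cub])` and variance
#' `mu + phi * mu^2` (`phi` is the reciprocal of the gamma-Poisson shape).
#' Per-window baseline rates `lambda_w` (reads per million) are drawn once
#' from a base-2 log-normal; library sizes `L_i` are drawn log-uniformly
#' within `libsize_range` and then treated as fixed offsets. Mitochondrial
#' windows have `lambda_w` multiplied by `mito_multiplier`, emulating the
#' elevated apparent abundance of the mitochondrial compartment.
#'
#' @param seed Integer seed; the same config reproduces identical output.
#' @param n_per_cell Named counts for the four rank x age cells
#'   (`high_cub`, `high_adult`, `low_cub`, `low_adult`).
#' @param contigs data.frame with columns `name`, `length`,
#'   `is_mitochondrial`.
#' @param window_width Window width in bp (default 300).
#' @param baseline_log2_abundance Mean and sd of per-window log2 baseline
#'   abundance (reads per million scale).
#' @param dispersion NB dispersion `phi >= 0`; 0 gives Poisson counts.
#' @param libsize_range Min and max total reads per sample.
#' @param planted_dmrs List of [planted_dmr()] objects.
#' @param age_log2_effect log2 cub-vs-adult shift applied to all windows
#'   (scalar) or a per-window vector; default 0.
#' @param mito_multiplier Abundance multiplier (> 0) for mitochondrial
#'   windows/genes; default 10.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_per_cell = c(
                         high_cub = 9L, high_adult = 9L,
                         low_cub = 15L, low_adult = 9L
                       ),
                       contigs = data.frame(
                         name = c("chr1", "chrM"),
                         length = c(3e5, 16500),
                         is_mitochondrial = c(FALSE, TRUE)
                       ),
                       window_width = 300L,
                       baseline_log2_abundance = c(mean = 3, sd = 1),
                       dispersion = 0.2,
                       libsize_range = c(5e6, 15e6),
                       planted_dmrs = list(),
                       age_log2_effect = 0,
                       mito_multiplier = 10) {
  cells <- c("high_cub", "high_adult", "low_cub", "low_adult")
  if (!all(cells %in% names(n_per_cell))) {
    stop("n_per_cell must name all four rank x age cells")
  }
  n_per_cell <- as.integer(n_per_cell[cells])
  names(n_per_cell) <- cells
  if (any(is.na(n_per_cell)) || any(n_per_cell < 1L)) {
    stop("every rank x age cell must contain at least one sample")
  }
  if (!all(c("name", "length", "is_mitochondrial") %in% names(contigs))) {
    stop("contigs needs columns name, length, is_mitochondrial")
  }
  if (any(contigs$length <= 0)) stop("contig lengths must be positive")
  if (window_width <= 0) stop("window_width must be positive")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (length(libsize_range) != 2L || libsize_range[1] > libsize_range[2] ||
    libsize_range[1] <= 0) {
    stop("libsize_range must be (min, max) with 0 < min <= max")
  }
  if (mito_multiplier <= 0) stop("mito_multiplier must be positive")
  cfg <- structure(
    list(
      seed = as.integer(seed), n_per_cell = n_per_cell, contigs = contigs,
      window_width = as.integer(window_width),
      baseline_log2_abundance = baseline_log2_abundance,
      dispersion = dispersion, libsize_range = libsize_range,
      planted_dmrs = planted_dmrs, age_log2_effect = age_log2_effect,
      mito_multiplier = mito_multiplier
    ),
    class = "sim_config"
  )
  validate_planted(cfg)
  cfg
}

#' A planted differentially methylated region
#'
#' @param contig Contig name.
#' @param first_window 1-based index of the first planted window within
#'   the contig's window grid.
#' @param n_windows Number of consecutive windows (>= 1).
#' @param log2_effect Non-zero log2 fold-change of low- vs high-ranking
#'   samples (positive = hypermethylated in low-ranking).
#' @return A `planted_dmr` list.
#' @export
planted_dmr <- function(contig, first_window, n_windows, log2_effect) {
  if (n_windows < 1L) stop("n_windows must be >= 1")
  if (log2_effect == 0) stop("log2_effect must be non-zero")
  structure(
    list(
      contig = as.character(contig), first_window = as.integer(first_window),
      n_windows = as.integer(n_windows), log2_effect = log2_effect
    ),
    class = "planted_dmr"
  )
}

validate_planted <- function(cfg) {
  if (!length(cfg$planted_dmrs)) {
    return(invisible(cfg))
  }
  per_contig <- split(cfg$planted_dmrs, vapply(cfg$planted_dmrs, `[[`, "", "contig"))
  n_win <- setNames(
    ceiling(cfg$contigs$length / cfg$window_width),
    cfg$contigs$name
  )
  for (nm in names(per_contig)) {
    if (!nm %in% cfg$contigs$name) stop("planted DMR on unknown contig ", nm)
    idx <- lapply(per_contig[[nm]], function(d) {
      if (d$first_window < 1L ||
        d$first_window + d$n_windows - 1L > n_win[[nm]]) {
        stop("planted DMR out of contig bounds on ", nm)
      }
      seq.int(d$first_window, length.out = d$n_windows)
    })
    all_idx <- unlist(idx)
    if (anyDuplicated(all_idx)) stop("planted DMRs overlap on contig ", nm)
  }
  invisible(cfg)
}

#' Generate the sample cohort
#'
#' One sample row per configured rank x age slot; deterministic (no
#' randomness is involved in the cohort itself). The default config
#' yields 42 samples: 18 high-ranking (9 cubs, 9 adults) and 24
#' low-ranking (15 cubs, 9 adults).
#'
#' @param config A [sim_config()].
#' @return Sample table: data.frame with `sample_id`, `rank`, `age`
#'   (factors with reference levels high and adult).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cells <- data.frame(
    cell = names(config$n_per_cell),
    rank = sub("_.*", "", names(config$n_per_cell)),
    age = sub(".*_", "", names(config$n_per_cell)),
    n = config$n_per_cell,
    stringsAsFactors = FALSE
  )
  rows <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(
      sample_id = sprintf("%s%02d", cells$cell[i], seq_len(cells$n[i])),
      rank = cells$rank[i],
      age = cells$age[i],
      stringsAsFactors = FALSE
    )
  }))
  as_sample_table(rows)
}

# Draw one count matrix: rows x samples, NB(mu, phi), given per-row base-2
# log means already including offsets and effects.
draw_nb <- function(log2_mu, phi) {
  mu <- 2^log2_mu
  n <- length(mu)
  y <- if (phi == 0) rpois(n, mu) else rnbinom(n, size = 1 / phi, mu = mu)
  matrix(y, nrow = nrow(log2_mu), dimnames = dimnames(log2_mu))
}

#' Simulate a methylation-capture count matrix with planted DMRs
#'
#' Draws NB window counts under the model described in [sim_config()],
#' with rank effects at the planted windows only, and returns the counts
#' together with a truth ledger. The generator uses its own RNG stream
#' (derived from `config$seed`), so adding other simulations does not
#' perturb the draws, and rerunning with the same config is bit-identical.
#'
#' @param config A [sim_config()].
#' @param samples Sample table from [simulate_cohort()].
#' @return List with elements `counts` (a [meth_counts()]), `grid`
#'   (the [tile_windows()] grid) and `truth` (list: `dmrs` data.frame of
#'   planted coordinates/effects, `window_effects` named per-window true
#'   log2 effect vector).
#' @export
simulate_methylation_counts <- function(config, samples) {
  stopifnot(inherits(config, "sim_config"))
  samples <- as_sample_table(samples)
  grid <- tile_windows(
    setNames(config$contigs$length, config$contigs$name),
    config$window_width
  )
  W <- nrow(grid)
  n <- nrow(samples)
  is_mito_win <- grid$contig %in%
    config$contigs$name[config$contigs$is_mitochondrial]

  beta <- true_window_effects(config, grid)
  gamma <- rep_len(config$age_log2_effect, W)

  mats <- with_seed(config$seed + 101L, {
    libsize <- round(exp(runif(
      n, log(config$libsize_range[1]), log(config$libsize_range[2])
    )))
    lambda <- 2^rnorm(
      W, config$baseline_log2_abundance[["mean"]],
      config$baseline_log2_abundance[["sd"]]
    )
    lambda[is_mito_win] <- lambda[is_mito_win] * config$mito_multiplier
    low <- as.integer(samples$rank == "low")
    cub <- as.integer(samples$age == "cub")
    log2_mu <- outer(log2(lambda), log2(libsize / 1e6), "+") +
      outer(beta, low) + outer(gamma, cub)
    dimnames(log2_mu) <- list(rownames(grid), samples$sample_id)
    y <- draw_nb(log2_mu, config$dispersion)
    list(y = y, libsize = setNames(libsize, samples$sample_id))
  })

  truth_dmrs <- planted_coordinates(config, grid)
  list(
    counts = meth_counts(mats$y, libsize = NULL),
    grid = grid,
    truth = list(dmrs = truth_dmrs, window_effects = beta)
  )
}

# Per-window true rank effect (log2), named by window id.
true_window_effects <- function(config, grid) {
  beta <- setNames(rep(0, nrow(grid)), rownames(grid))
  for (d in config$planted_dmrs) {
    offset <- match(d$contig, unique(grid$contig))
    idx_in_contig <- which(grid$contig == d$contig)
    rows <- idx_in_contig[seq.int(d$first_window, length.out = d$n_windows)]
    beta[rows] <- d$log2_effect
  }
  beta
}

planted_coordinates <- function(config, grid) {
  if (!length(config$planted_dmrs)) {
    return(data.frame(
      contig = character(), start = integer(), end = integer(),
      length = integer(), log2_effect = numeric(), stringsAsFactors = FALSE
    ))
  }
  rows <- lapply(config$planted_dmrs, function(d) {
    idx_in_contig <- which(grid$contig == d$contig)
    rows <- idx_in_contig[seq.int(d$first_window, length.out = d$n_windows)]
    data.frame(
      contig = d$contig,
      start = grid$start[rows[1L]],
      end = grid$end[rows[length(rows)]],
      length = grid$end[rows[length(rows)]] - grid$start[rows[1L]],
      log2_effect = d$log2_effect,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$contig, out$start), , drop = FALSE]
}

#' Simulate a gene x sample expression count matrix
#'
#' Companion RNA counts for the mitochondrial-vs-nuclear comparison: one
#' row per gene, with the summed exon length as the region unit, NB noise
#' as in [simulate_methylation_counts()], and the mitochondrial abundance
#' multiplier shared with the methylation simulation. No rank or age
#' effects are planted in expression.
#'
#' @param config A [sim_config()].
#' @param genome A [gene_model()] with at least one gene.
#' @param samples Sample table (typically a subset of adults).
#' @return A [meth_counts()] keyed by gene id.
#' @export
simulate_expression_counts <- function(config, genome, samples) {
  stopifnot(inherits(config, "sim_config"), inherits(genome, "gene_model"))
  samples <- as_sample_table(samples)
  if (!nrow(genome$genes)) stop("gene model contains no genes")
  exon_len <- vapply(
    split(genome$exons$end - genome$exons$start, genome$exons$gene_id),
    sum, 0
  )[genome$genes$gene_id]
  is_mito <- genome$genes$contig %in% genome$mito_contigs
  G <- nrow(genome$genes)
  n <- nrow(samples)

  with_seed(config$seed + 202L, {
    libsize <- round(exp(runif(
      n, log(config$libsize_range[1]), log(config$libsize_range[2])
    )))
    lambda <- 2^rnorm(
      G, config$baseline_log2_abundance[["mean"]],
      config$baseline_log2_abundance[["sd"]]
    ) * exon_len / config$window_width
    lambda[is_mito] <- lambda[is_mito] * config$mito_multiplier
    log2_mu <- outer(log2(lambda), log2(libsize / 1e6), "+")
    dimnames(log2_mu) <- list(genome$genes$gene_id, samples$sample_id)
    y <- draw_nb(log2_mu, config$dispersion)
    meth_counts(y, libsize = NULL)
  })
}

#' Generate a synthetic gene model on the configured contigs
#'
#' Places non-overlapping multi-exon genes at regular intervals along each
#' contig (alternating strands), giving the annotation and expression
#' modules something structurally realistic to work with. Artifact
#' plumbing: gene placement is deterministic given the seed.
#'
#' @param config A [sim_config()].
#' @param genes_per_contig Number of genes per contig (recycled); contigs
#'   too short for the requested genes get as many as fit.
#' @param seed Seed for exon-structure randomness (default from config).
#' @return A [gene_model()].
#' @export
simulate_gene_model <- function(config, genes_per_contig = 10L, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed + 303L
  genes_per_contig <- rep_len(
    as.integer(genes_per_contig),
    nrow(config$contigs)
  )
  with_seed(seed, {
    genes <- list()
    exons <- list()
    for (ci in seq_len(nrow(config$contigs))) {
      clen <- config$contigs$length[ci]
      cname <- config$contigs$name[ci]
      slot <- floor(clen / max(genes_per_contig[ci], 1L))
      n_genes <- min(genes_per_contig[ci], floor(clen / 3000))
      for (gi in seq_len(n_genes)) {
        g_start <- (gi - 1L) * slot + round(slot * 0.3)
        g_len <- min(round(slot * 0.4), 20000L)
        g_end <- g_start + g_len
        id <- sprintf("%s_g%02d", cname, gi)
        strand <- if (gi %% 2L == 1L) "+" else "-"
        n_ex <- sample(1:4, 1L)
        bounds <- sort(sample(seq(g_start + 50L, g_end - 50L), 2L * (n_ex - 1L)))
        starts <- c(g_start, bounds[seq_along(bounds) %% 2L == 0L])
        ends <- c(bounds[seq_along(bounds) %% 2L == 1L], g_end)
        genes[[id]] <- data.frame(
          gene_id = id, name = id, contig = cname,
          start = g_start, end = g_end, strand = strand,
          stringsAsFactors = FALSE
        )
        exons[[id]] <- data.frame(
          gene_id = id, contig = cname, start = starts, end = ends,
          stringsAsFactors = FALSE
        )
      }
    }
    gene_model(
      genes = do.call(rbind, genes),
      exons = do.call(rbind, exons),
      contigs = config$contigs
    )
  })
}

#' Write the truth ledger as BED plus a JSON sidecar
#'
#' @param truth The `truth` element from [simulate_methylation_counts()].
#' @param bed_path,json_path Output files (0-based half-open BED).
#' @export
write_truth <- function(truth, bed_path, json_path) {
  bed <- truth$dmrs[, c("contig", "start", "end")]
  write.table(bed, bed_path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  jsonlite::write_json(
    list(
      dmrs = truth$dmrs,
      window_effects = as.list(truth$window_effects[truth$window_effects != 0])
    ),
    json_path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(bed_path)
}
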