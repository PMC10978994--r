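#' Constrained leave-one-group-out subsampling scheme
#'
#' Randomly partitions the samples into `K` groups (sizes as equal as
#' possible) under the constraint that every group contains at least one
#' high-ranking, one low-ranking, one cub and one adult sample. Subset k
#' is the complement of group k, so with 42 samples and K = 6 every
#' subset holds 35 samples. Rejection sampling is used; the seed makes
#' the partition reproducible.
#'
#' @param samples Sample table.
#' @param K Number of groups (default 6).
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling budget (default 10000).
#' @return A `subset_scheme`: list with `K`, `assignment` (named group
#'   index per sample), `subsets` (list of K sample-id vectors) and
#'   `seed`.
#' @export
make_subset_scheme <- function(samples, K = 6L, seed = 1L,
                               max_tries = 10000L) {
  samples <- as_sample_table(samples)
  n <- nrow(samples)
  K <- as.integer(K)
  if (n < K) stop("fewer samples than groups")
  for (fac in c("rank", "age")) {
    tab <- table(samples[[fac]])
    if (any(tab < K)) {
      stop(
        "constraint unsatisfiable: level(s) of ", fac,
        " with fewer than K members"
      )
    }
  }
  sizes <- rep(n %/% K, K) + c(rep(1L, n %% K), rep(0L, K - n %% K))
  grp_template <- rep(seq_len(K), times = sizes)
  ok <- function(g) {
    for (k in seq_len(K)) {
      s <- samples[g == k, ]
      if (!all(c("high", "low") %in% s$rank) ||
        !all(c("adult", "cub") %in% s$age)) {
        return(FALSE)
      }
    }
    TRUE
  }
  assignment <- with_seed(seed, {
    if (K == 1L) {
      rep(1L, n)
    } else {
      g <- NULL
      for (try in seq_len(max_tries)) {
        cand <- grp_template[sample.int(n)]
        if (ok(cand)) {
          g <- cand
          break
        }
      }
      if (is.null(g)) {
        stop("no valid partition found in ", max_tries, " tries")
      }
      g
    }
  })
  names(assignment) <- samples$sample_id
  subsets <- lapply(seq_len(K), function(k) {
    if (K == 1L) samples$sample_id else samples$sample_id[assignment != k]
  })
  structure(
    list(K = K, assignment = assignment, subsets = subsets, seed = seed),
    class = "subset_scheme"
  )
}

#' Refit the rank model within each leave-one-group-out subset
#'
#' Reruns the same analysis as the full dataset — TMM factors, dispersion
#' estimation, full/reduced NB fits and the rank LRT — on each subset's
#' samples, over the frozen full-data window set (no re-filtering), and
#' collects logFC and p at the candidate windows.
#'
#' @param x The filtered [meth_counts()] used for the full-data analysis.
#' @param samples Sample table.
#' @param scheme A [make_subset_scheme()] result.
#' @param candidate_windows Window ids at which statistics are retained
#'   (normally the members of the candidate DMRs).
#' @param prior_df Dispersion shrinkage weight (default: estimated, as
#'   in the full analysis).
#' @param include_age Keep the age covariate in subset models (default
#'   `TRUE`).
#' @return A `subset_stats`: list of matrices `logFC` and `p`, windows x
#'   subsets.
#' @export
refit_subsets <- function(x, samples, scheme, candidate_windows,
                          prior_df = NULL, include_age = TRUE) {
  stopifnot(inherits(x, "meth_counts"), inherits(scheme, "subset_scheme"))
  samples <- as_sample_table(samples)
  missing_w <- setdiff(candidate_windows, rownames(x$counts))
  if (length(missing_w)) {
    stop(
      "candidate window(s) absent from the matrix: ",
      paste(head(missing_w, 3L), collapse = ", ")
    )
  }
  K <- scheme$K
  logfc <- p <- matrix(
    NA_real_, length(candidate_windows), K,
    dimnames = list(candidate_windows, paste0("subset", seq_len(K)))
  )
  for (k in seq_len(K)) {
    ids <- scheme$subsets[[k]]
    sub_samples <- samples[samples$sample_id %in% ids, , drop = FALSE]
    stopifnot(
      all(c("high", "low") %in% sub_samples$rank),
      all(c("adult", "cub") %in% sub_samples$age)
    )
    sub <- meth_counts(
      x$counts[, sub_samples$sample_id, drop = FALSE],
      libsize = x$libsize[sub_samples$sample_id]
    )
    res <- test_windows(sub, sub_samples,
      prior_df = prior_df,
      include_age = include_age
    )
    i <- match(candidate_windows, res$window)
    logfc[, k] <- res$logFC[i]
    p[, k] <- res$p[i]
  }
  structure(list(logFC = logfc, p = p), class = "subset_stats")
}

#' Coherence selection of candidate DMRs
#'
#' A candidate DMR is selected when every member window has `p <= alpha`
#' in every subset and a logFC sign that is identical across subsets
#' (and, by default, matches the full-data sign). Everything else is
#' excluded, with the violating window/subset recorded.
#'
#' @param full_tests Full-data window tests from [test_windows()].
#' @param subset_stats A [refit_subsets()] result.
#' @param candidates Candidate DMR table from [call_dmrs()].
#' @param alpha Per-subset significance threshold (default 0.05).
#' @param match_full_sign Require subset signs to match the full-data
#'   sign (default `TRUE`).
#' @return A `coherence_report`: the candidate table with `verdict`
#'   (selected/excluded), `reasons` (character per DMR), `logFC_min`,
#'   `logFC_max` (range over member windows x subsets).
#' @export
coherence_select <- function(full_tests, subset_stats, candidates,
                             alpha = 0.05, match_full_sign = TRUE) {
  stopifnot(inherits(subset_stats, "subset_stats"))
  out <- candidates
  out$verdict <- out$reasons <- character(nrow(candidates))
  out$logFC_min <- out$logFC_max <- numeric(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    wins <- candidates$windows[[i]]
    miss <- setdiff(wins, rownames(subset_stats$p))
    if (length(miss)) {
      stop("no subset statistics for window(s): ", paste(miss, collapse = ", "))
    }
    pm <- subset_stats$p[wins, , drop = FALSE]
    fm <- subset_stats$logFC[wins, , drop = FALSE]
    if (anyNA(pm) || anyNA(fm)) stop("missing subset statistics cell")
    reasons <- character()
    bad_p <- which(pm > alpha, arr.ind = TRUE)
    if (nrow(bad_p)) {
      reasons <- c(reasons, sprintf(
        "p > %.3g at %s in %s", alpha,
        rownames(pm)[bad_p[, 1L]], colnames(pm)[bad_p[, 2L]]
      ))
    }
    for (w in seq_along(wins)) {
      signs <- sign(fm[w, ])
      ref <- if (match_full_sign) {
        sign(full_tests$logFC[match(wins[w], full_tests$window)])
      } else {
        signs[1L]
      }
      if (any(signs != ref)) {
        reasons <- c(reasons, sprintf(
          "incoherent direction at %s in %s", wins[w],
          paste(colnames(fm)[signs != ref], collapse = ",")
        ))
      }
    }
    out$verdict[i] <- if (length(reasons)) "excluded" else "selected"
    out$reasons[i] <- paste(reasons, collapse = "; ")
    out$logFC_min[i] <- min(fm)
    out$logFC_max[i] <- max(fm)
  }
  class(out) <- c("coherence_report", class(candidates))
  out
}

#' Write a subsampling scheme / coherence report
#'
#' @param scheme A `subset_scheme`.
#' @param path Output TSV.
#' @export
write_scheme_tsv <- function(scheme, path) {
  write.table(
    data.frame(
      sample_id = names(scheme$assignment),
      group = unname(scheme$assignment)
    ),
    path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_scheme_tsv
#' @param report A `coherence_report`.
#' @param tsv_path,json_path Output files (either may be `NULL`).
#' @export
write_coherence_report <- function(report, tsv_path = NULL, json_path = NULL) {
  flat <- report
  flat$windows <- vapply(flat$windows, paste, "", collapse = ",")
  if (!is.null(tsv_path)) {
    write.table(flat, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(flat, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
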