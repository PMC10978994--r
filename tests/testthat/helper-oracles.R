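# Independent oracles used to cross-check the pipeline implementations.
# These are written from the published procedures directly and share no
# code with the package internals.

# Trimmed mean of M-values, from the published recipe: depth-scaled
# proportions, zero-count windows excluded, 30% two-sided trim on M and
# 5% on A (rank-based), inverse delta-method variance weights, factors
# centred to geometric mean 1. Reference sample: 75th-percentile scaled
# count closest to the mean of those percentiles.
oracle_tmm <- function(counts, libsize = colSums(counts)) {
  q75 <- apply(counts, 2, quantile, probs = 0.75) / libsize
  ref <- which.min(abs(q75 - mean(q75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    obs <- counts[, j]
    rf <- counts[, ref]
    nO <- libsize[j]
    nR <- libsize[ref]
    m <- log2((obs / nO) / (rf / nR))
    a <- (log2(obs / nO) + log2(rf / nR)) / 2
    v <- (nO - obs) / (nO * obs) + (nR - rf) / (nR * rf)
    keep <- is.finite(m) & is.finite(a)
    m <- m[keep]
    a <- a[keep]
    v <- v[keep]
    if (max(abs(m)) < 1e-6) {
      return(1)
    }
    n <- length(m)
    lo_m <- floor(n * 0.3) + 1
    hi_m <- n + 1 - lo_m
    lo_a <- floor(n * 0.05) + 1
    hi_a <- n + 1 - lo_a
    trim <- rank(m) >= lo_m & rank(m) <= hi_m &
      rank(a) >= lo_a & rank(a) <= hi_a
    2^(sum(m[trim] / v[trim]) / sum(1 / v[trim]))
  }, 0)
  f / exp(mean(log(f)))
}

# NB log-likelihood for one window: y ~ NB(mu = exp(X b + offset), phi),
# phi fixed. Fit by direct numerical maximization (Nelder-Mead refined
# by BFGS), independent of any IRLS code.
oracle_nb_fit <- function(y, X, offset, phi) {
  negll <- function(b) {
    mu <- exp(drop(X %*% b) + offset)
    if (phi == 0) {
      -sum(dpois(y, mu, log = TRUE))
    } else {
      -sum(dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
    }
  }
  b0 <- qr.solve(X, log(y + 0.5) - offset)
  fit <- optim(b0, negll, method = "Nelder-Mead", control = list(maxit = 5000, reltol = 1e-14))
  fit <- optim(fit$par, negll, method = "BFGS", control = list(maxit = 1000, reltol = 1e-14))
  list(coefficients = fit$par, loglik = -fit$value)
}

# Benjamini-Hochberg step-up by hand: sort, p * n / rank, cumulative
# minimum from the largest rank down, cap at 1, original order.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Exact two-sided signed-rank p by enumeration of all 2^n sign
# assignments (zero differences removed by the caller).
oracle_signed_rank_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- drop(signs %*% r)
  mu <- n * (n + 1) / 4
  p <- mean(abs(v_all - mu) >= abs(v_obs - mu))
  min(p, 1)
}

# Exact two-sided rank-sum p by enumeration of all group assignments.
oracle_rank_sum_exact <- function(a, b) {
  n1 <- length(a)
  n <- n1 + length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * (n - n1) / 2
  sets <- combn(n, n1)
  w_all <- apply(sets, 2, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
  min(mean(abs(w_all - mu) >= abs(w_obs - mu)), 1)
}

# Brute-force interval overlap count: for each query, scan all features.
oracle_overlap_scan <- function(dmrs, features) {
  lapply(seq_len(nrow(dmrs)), function(i) {
    hit <- features$contig == dmrs$contig[i] &
      features$start < dmrs$end[i] &
      features$end > dmrs$start[i]
    unique(features[hit, c("feature", "gene_id")])
  })
}
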