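# Small in-code fixtures shared across test files.

toy_samples <- function(n_high_adult = 2, n_high_cub = 2,
                        n_low_adult = 2, n_low_cub = 2) {
  cells <- list(
    c("high", "adult", n_high_adult), c("high", "cub", n_high_cub),
    c("low", "adult", n_low_adult), c("low", "cub", n_low_cub)
  )
  rows <- do.call(rbind, lapply(cells, function(cl) {
    n <- as.integer(cl[3])
    if (n == 0) {
      return(NULL)
    }
    data.frame(
      sample_id = sprintf("%s_%s_%d", cl[1], cl[2], seq_len(n)),
      rank = cl[1], age = cl[2], stringsAsFactors = FALSE
    )
  }))
  rows$rank <- factor(rows$rank, levels = c("high", "low"))
  rows$age <- factor(rows$age, levels = c("adult", "cub"))
  rows
}

# Random count matrix on a tiled grid; names follow window-id convention.
toy_counts <- function(n_windows = 50, samples = toy_samples(), mu = 60,
                       phi = 0.2, seed = 1) {
  set.seed(seed)
  n <- nrow(samples)
  y <- matrix(
    rnbinom(n_windows * n, mu = mu, size = 1 / phi),
    n_windows, n,
    dimnames = list(
      sprintf("chr1:%d-%d", (seq_len(n_windows) - 1) * 300, seq_len(n_windows) * 300),
      samples$sample_id
    )
  )
  meth_counts(y)
}

# Two-contig gene model with known structures used by annotation tests.
toy_gene_model <- function() {
  gene_model(
    genes = data.frame(
      gene_id = c("gplus", "gminus"),
      name = c("gplus", "gminus"),
      contig = c("chr1", "chr1"),
      start = c(9999L, 3000L), end = c(12000L, 4500L),
      strand = c("+", "-"), stringsAsFactors = FALSE
    ),
    exons = data.frame(
      gene_id = c("gplus", "gplus", "gminus", "gminus"),
      contig = "chr1",
      start = c(9999L, 11000L, 3000L, 4000L),
      end = c(10500L, 12000L, 3200L, 4500L),
      stringsAsFactors = FALSE
    ),
    contigs = data.frame(
      name = c("chr1", "chrM"), length = c(50000L, 16500L),
      is_mitochondrial = c(FALSE, TRUE), stringsAsFactors = FALSE
    )
  )
}
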