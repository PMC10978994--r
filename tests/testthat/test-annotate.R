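test_that("plus-strand TSS and 2-kb promoter follow the first-exon rule", {
  gm <- toy_gene_model()
  feats <- derive_features(gm)
  fp <- feats[feats$gene_id == "gplus", ]
  tss <- fp[fp$feature == "TSS", ]
  # first exon starts at 0-based 9999 = 1-based position 10,000
  expect_equal(c(tss$start, tss$end), c(9999L, 10000L))
  prom <- fp[fp$feature == "promoter", ]
  # 2 kb upstream: 1-based 8,000..9,999
  expect_equal(c(prom$start, prom$end), c(7999L, 9999L))
  expect_equal(prom$end - prom$start, 2000L)
  intr <- fp[fp$feature == "intron", ]
  expect_equal(c(intr$start, intr$end), c(10500L, 11000L))
})

test_that("minus-strand features are strand-aware and promoters truncate at bounds", {
  gm <- toy_gene_model()
  feats <- derive_features(gm)
  fm <- feats[feats$gene_id == "gminus", ]
  tss <- fm[fm$feature == "TSS", ]
  expect_equal(c(tss$start, tss$end), c(4499L, 4500L))
  prom <- fm[fm$feature == "promoter", ]
  expect_equal(c(prom$start, prom$end), c(4500L, 6500L))
  intr <- fm[fm$feature == "intron", ]
  expect_equal(c(intr$start, intr$end), c(3200L, 4000L))

  # strand-naive promoters always extend to lower coordinates
  naive <- derive_features(gm, strand_aware = FALSE)
  nm <- naive[naive$gene_id == "gminus", ]
  ntss <- nm[nm$feature == "TSS", ]
  expect_equal(ntss$start, 3000L)
  nprom <- nm[nm$feature == "promoter", ]
  expect_equal(c(nprom$start, nprom$end), c(1000L, 3000L))

  # a gene 500 bp from the contig start gets a truncated promoter
  near <- gene_model(
    genes = data.frame(
      gene_id = "g1", name = "g1", contig = "chr1",
      start = 500L, end = 1500L, strand = "+", stringsAsFactors = FALSE
    ),
    exons = data.frame(
      gene_id = "g1", contig = "chr1", start = 500L, end = 1500L,
      stringsAsFactors = FALSE
    ),
    contigs = data.frame(
      name = "chr1", length = 5000L, is_mitochondrial = FALSE,
      stringsAsFactors = FALSE
    )
  )
  nf <- derive_features(near)
  np <- nf[nf$feature == "promoter", ]
  expect_equal(c(np$start, np$end), c(0L, 500L))
  expect_equal(np$end - np$start, 500L)
})

test_that("per-gene feature geometry is internally consistent", {
  cfg <- sim_config(seed = 13, contigs = data.frame(
    name = c("c1", "c2"), length = c(2e5, 8e4),
    is_mitochondrial = c(FALSE, FALSE)
  ))
  gm <- simulate_gene_model(cfg, genes_per_contig = 6)
  feats <- derive_features(gm)
  for (gid in gm$genes$gene_id) {
    f <- feats[feats$gene_id == gid, ]
    g <- gm$genes[gm$genes$gene_id == gid, ]
    ex <- f[f$feature == "exon", ]
    intr <- f[f$feature == "intron", ]
    # exon and intron sets are disjoint and tile the gene span
    cov <- sum(ex$end - ex$start) + sum(intr$end - intr$start)
    expect_equal(cov, g$end - g$start)
    if (nrow(intr)) {
      ir <- IRanges::IRanges(intr$start + 1, intr$end)
      er <- IRanges::IRanges(ex$start + 1, ex$end)
      expect_equal(sum(IRanges::width(IRanges::intersect(ir, er))), 0L)
    }
    # promoter sits outside the gene body
    prom <- f[f$feature == "promoter", ]
    expect_true(prom$end <= g$start || prom$start >= g$end)
    expect_lte(prom$end - prom$start, 2000L)
    expect_equal(sum(f$feature == "TSS"), 1L)
    expect_equal(f$end[f$feature == "TSS"] - f$start[f$feature == "TSS"], 1L)
  }
  # exon outside gene span is rejected with the gene named
  expect_error(
    gene_model(
      genes = data.frame(
        gene_id = "bad", name = "bad", contig = "c1",
        start = 100L, end = 200L, strand = "+", stringsAsFactors = FALSE
      ),
      exons = data.frame(
        gene_id = "bad", contig = "c1", start = 50L, end = 150L,
        stringsAsFactors = FALSE
      ),
      contigs = data.frame(
        name = "c1", length = 1000L, is_mitochondrial = FALSE,
        stringsAsFactors = FALSE
      )
    ),
    "bad"
  )
})

test_that("DMR annotation records every overlapping feature once and sets locality", {
  gm <- toy_gene_model()
  feats <- derive_features(gm)
  dmrs <- data.frame(
    dmr_id = c("d1", "d2", "d3"),
    contig = c("chr1", "chr1", "chr7"),
    start = c(20000L, 9900L, 100L),
    end = c(20300L, 10600L, 400L),
    stringsAsFactors = FALSE
  )
  expect_warning(ann <- annotate_dmrs(dmrs, feats), "chr7")
  # d1 lies between genes
  expect_equal(ann$locality[1], "intergenic")
  expect_equal(nrow(ann$overlaps[[1]]), 0L)
  # d2 spans the promoter/TSS/first-exon/intron region of gplus: each once
  labs <- ann$overlaps[[2]]$feature
  expect_setequal(labs, c("promoter", "TSS", "exon", "intron", "gene"))
  expect_equal(anyDuplicated(labs), 0L)
  expect_equal(ann$locality[2], "intragenic")
  # unknown contig is intergenic
  expect_equal(ann$locality[3], "intergenic")

  counts <- summarize_overlaps(ann)
  expect_equal(unname(counts["promoter"]), 1L)
  expect_equal(unname(counts["TSS"]), 1L)
  expect_equal(unname(counts["intergenic"]), 2L)
  # intragenic + intergenic = total
  expect_equal(
    sum(ann$locality == "intragenic") + unname(counts["intergenic"]),
    nrow(dmrs)
  )

  empty <- annotate_dmrs(dmrs[0, ], feats)
  expect_equal(unname(summarize_overlaps(empty)), rep(0L, 8))
})

test_that("annotation matches a brute-force interval scan on a random fixture", {
  set.seed(19)
  cfg <- sim_config(seed = 19, contigs = data.frame(
    name = c("c1", "c2"), length = c(3e5, 1e5),
    is_mitochondrial = c(FALSE, FALSE)
  ))
  gm <- simulate_gene_model(cfg, genes_per_contig = 8)
  feats <- derive_features(gm)
  starts <- sample(0:990, 50) * 300
  dmrs <- data.frame(
    dmr_id = sprintf("d%02d", 1:50),
    contig = sample(c("c1", "c2"), 50, replace = TRUE),
    start = starts,
    end = starts + sample(1:4, 50, replace = TRUE) * 300,
    stringsAsFactors = FALSE
  )
  dmrs <- dmrs[dmrs$end <= ifelse(dmrs$contig == "c1", 3e5, 1e5), ]
  ann <- annotate_dmrs(dmrs, feats)
  expected <- oracle_overlap_scan(dmrs, feats)
  for (i in seq_len(nrow(dmrs))) {
    got <- ann$overlaps[[i]][order(
      ann$overlaps[[i]]$feature, ann$overlaps[[i]]$gene_id
    ), ]
    want <- expected[[i]][order(expected[[i]]$feature, expected[[i]]$gene_id), ]
    expect_equal(got$feature, want$feature)
    expect_equal(got$gene_id, want$gene_id)
  }
  expect_equal(
    ann$locality,
    ifelse(vapply(expected, nrow, 0L) > 0, "intragenic", "intergenic")
  )
})

test_that("a constructed 179-DMR fixture splits 42 intragenic / 137 intergenic", {
  # one long contig; 42 DMRs placed inside gene bodies, 137 in the gaps
  n_genes <- 42L
  gene_start <- (seq_len(n_genes) - 1L) * 20000L + 5000L
  gm <- gene_model(
    genes = data.frame(
      gene_id = sprintf("g%02d", seq_len(n_genes)),
      name = sprintf("g%02d", seq_len(n_genes)),
      contig = "c1", start = gene_start, end = gene_start + 4000L,
      strand = "+", stringsAsFactors = FALSE
    ),
    exons = data.frame(
      gene_id = sprintf("g%02d", seq_len(n_genes)),
      contig = "c1", start = gene_start, end = gene_start + 4000L,
      stringsAsFactors = FALSE
    ),
    contigs = data.frame(
      name = "c1", length = 20000L * n_genes + 60000L,
      is_mitochondrial = FALSE, stringsAsFactors = FALSE
    )
  )
  feats <- derive_features(gm)
  inside <- data.frame(
    contig = "c1", start = gene_start + 600L, end = gene_start + 900L
  )
  gap_start <- gene_start[(seq_len(137L) %% n_genes) + 1L] + 10000L +
    (seq_len(137L) %/% n_genes) * 1200L
  outside <- data.frame(contig = "c1", start = gap_start, end = gap_start + 300L)
  dmrs <- rbind(inside, outside)
  dmrs$dmr_id <- sprintf("d%03d", seq_len(nrow(dmrs)))
  ann <- annotate_dmrs(dmrs, feats)
  counts <- summarize_overlaps(ann)
  expect_equal(sum(ann$locality == "intragenic"), 42L)
  expect_equal(unname(counts["intergenic"]), 137L)
  # cross-check with the brute-force scan
  brute <- oracle_overlap_scan(dmrs, feats)
  expect_equal(sum(vapply(brute, nrow, 0L) > 0), 42L)
})

test_that("gene models round-trip through GFF3 with coordinate conversion", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t10000\t12000\t.\t+\t.\tID=gplus;Name=GPLUS",
    "chr1\ttest\tmRNA\t10000\t12000\t.\t+\t.\tID=tplus;Parent=gplus",
    "chr1\ttest\texon\t10000\t10500\t.\t+\t.\tID=eplus1;Parent=tplus",
    "chr1\ttest\texon\t11001\t12000\t.\t+\t.\tID=eplus2;Parent=tplus",
    "chr1\ttest\tstart_codon\t10000\t10002\t.\t+\t.\tID=scplus;Parent=tplus",
    "chrM\ttest\tgene\t301\t900\t.\t-\t.\tID=gmito",
    "chrM\ttest\texon\t301\t900\t.\t-\t.\tID=emito;Parent=gmito"
  ), gff)
  gm <- read_gene_model(gff, mito_contigs = "chrM")
  expect_equal(gm$genes$start[gm$genes$gene_id == "gplus"], 9999L)
  expect_equal(gm$genes$end[gm$genes$gene_id == "gplus"], 12000L)
  expect_equal(gm$genes$name[gm$genes$gene_id == "gplus"], "GPLUS")
  expect_equal(sum(gm$exons$gene_id == "gplus"), 2L)
  expect_equal(gm$exons$start[3], 300L)
  expect_equal(gm$mito_contigs, "chrM")
  expect_equal(gm$start_codons$gene_id, "gplus")
  expect_equal(gm$start_codons$start, 9999L)

  feats <- derive_features(gm)
  out <- withr::local_tempfile(fileext = ".gff3")
  write_features_gff3(feats, out)
  back <- rtracklayer::import(out, format = "gff3")
  tss <- back[back$type == "TSS" & back$ID == "gplus"]
  # 0-based 9999 TSS = 1-based position 10000
  expect_equal(GenomicRanges::start(tss), 10000L)
  expect_equal(GenomicRanges::width(tss), 1L)
})
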