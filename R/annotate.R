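#' Gene model container
#'
#' Minimal single-isoform gene model: gene spans with strand, exons per
#' gene, optional start/stop codons, and the contig table with the
#' mitochondrial flag. All coordinates are 0-based half-open. Multi-exon
#' structure is interpreted on the union of exons; the first exon is the
#' 5'-most in transcription order.
#'
#' @param genes data.frame: `gene_id`, `name`, `contig`, `start`, `end`,
#'   `strand` (`+`/`-`).
#' @param exons data.frame: `gene_id`, `contig`, `start`, `end`.
#' @param contigs data.frame: `name`, `length`, `is_mitochondrial`.
#' @param start_codons,stop_codons Optional data.frames with `gene_id`,
#'   `contig`, `start`, `end`.
#' @return A `gene_model` object.
#' @export
gene_model <- function(genes, exons, contigs,
                       start_codons = NULL, stop_codons = NULL) {
  req <- function(df, cols, what) {
    if (!all(cols %in% names(df))) {
      stop(what, " needs columns: ", paste(cols, collapse = ", "))
    }
  }
  req(genes, c("gene_id", "contig", "start", "end", "strand"), "genes")
  req(exons, c("gene_id", "contig", "start", "end"), "exons")
  req(contigs, c("name", "length", "is_mitochondrial"), "contigs")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be + or -")
  if (!"name" %in% names(genes)) genes$name <- genes$gene_id
  missing_ex <- setdiff(genes$gene_id, exons$gene_id)
  if (length(missing_ex)) {
    stop("gene(s) without exons: ", paste(missing_ex, collapse = ", "))
  }
  span <- genes[match(exons$gene_id, genes$gene_id), ]
  bad <- exons$start < span$start | exons$end > span$end
  if (any(bad)) {
    stop(
      "exon outside gene span for: ",
      paste(unique(exons$gene_id[bad]), collapse = ", ")
    )
  }
  structure(
    list(
      genes = genes, exons = exons, contigs = contigs,
      start_codons = start_codons, stop_codons = stop_codons,
      mito_contigs = contigs$name[contigs$is_mitochondrial]
    ),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(
    "gene_model:", nrow(x$genes), "genes on", nrow(x$contigs), "contigs (",
    length(x$mito_contigs), "mitochondrial )\n"
  )
  invisible(x)
}

#' Derive functional features from a gene model
#'
#' Builds the extended annotation used for DMR classification:
#' \describe{
#'   \item{TSS}{the 5'-most transcribed position of the first exon,
#'     strand-aware, stored as a 1-bp interval;}
#'   \item{promoter}{`promoter_bp` (default 2000, i.e. 2 kb) immediately
#'     upstream of the TSS on the gene's strand, truncated at contig
#'     bounds;}
#'   \item{exon}{the union of the gene's exons;}
#'   \item{intron}{the gene span minus the exon union;}
#'   \item{gene}{the span itself; plus `start_codon`/`stop_codon` when
#'     the model carries them.}
#' }
#' With `strand_aware = FALSE` promoters always extend toward lower
#' coordinates, mimicking annotation pipelines that ignore strand.
#'
#' @param genome A [gene_model()].
#' @param promoter_bp Promoter length upstream of the TSS (default 2000).
#' @param strand_aware Place minus-strand promoters at higher coordinates
#'   (default `TRUE`).
#' @return A `feature_set`: data.frame with `feature`, `gene_id`,
#'   `contig`, `start`, `end` (0-based half-open).
#' @export
derive_features <- function(genome, promoter_bp = 2000, strand_aware = TRUE) {
  stopifnot(inherits(genome, "gene_model"))
  clen <- setNames(genome$contigs$length, genome$contigs$name)
  rows <- list()
  add <- function(feature, gene_id, contig, start, end) {
    keep <- end > start
    if (!any(keep)) {
      return()
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      feature = feature, gene_id = gene_id, contig = contig,
      start = as.integer(start[keep]), end = as.integer(end[keep]),
      stringsAsFactors = FALSE
    )
  }
  for (i in seq_len(nrow(genome$genes))) {
    g <- genome$genes[i, ]
    ex <- genome$exons[genome$exons$gene_id == g$gene_id, , drop = FALSE]
    ex_union <- IRanges::reduce(IRanges::IRanges(ex$start + 1L, ex$end))
    ex_start <- IRanges::start(ex_union) - 1L
    ex_end <- IRanges::end(ex_union)
    add("gene", g$gene_id, g$contig, g$start, g$end)
    for (k in seq_along(ex_start)) {
      add("exon", g$gene_id, g$contig, ex_start[k], ex_end[k])
    }
    introns <- IRanges::setdiff(
      IRanges::IRanges(g$start + 1L, g$end), ex_union
    )
    for (k in seq_along(introns)) {
      add(
        "intron", g$gene_id, g$contig,
        IRanges::start(introns)[k] - 1L, IRanges::end(introns)[k]
      )
    }
    upstream_minus <- strand_aware && g$strand == "-"
    tss <- if (upstream_minus) max(ex_end) - 1L else min(ex_start)
    add("TSS", g$gene_id, g$contig, tss, tss + 1L)
    if (upstream_minus) {
      p_start <- tss + 1L
      p_end <- min(tss + 1L + promoter_bp, clen[[g$contig]])
    } else {
      p_start <- max(tss - promoter_bp, 0L)
      p_end <- tss
    }
    add("promoter", g$gene_id, g$contig, p_start, p_end)
  }
  for (what in c("start_codons", "stop_codons")) {
    df <- genome[[what]]
    if (!is.null(df) && nrow(df)) {
      add(sub("s$", "", what), df$gene_id, df$contig, df$start, df$end)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$contig, out$start, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("feature_set", "data.frame")
  out
}

features_granges <- function(features) {
  GenomicRanges::GRanges(
    seqnames = features$contig,
    ranges = IRanges::IRanges(features$start + 1L, features$end),
    feature = features$feature, gene_id = features$gene_id
  )
}

#' Annotate DMRs against a feature set
#'
#' A DMR overlaps a feature when they share at least one bp. Every
#' overlapping (feature, gene) pair is recorded; DMRs overlapping no
#' gene-linked feature are intergenic. DMRs on contigs that the feature
#' set does not know are marked intergenic with a warning.
#'
#' @param dmrs DMR table from [call_dmrs()] (needs `contig`, `start`,
#'   `end`).
#' @param features A `feature_set` from [derive_features()].
#' @return The DMR table with added columns `overlaps` (list-column of
#'   data.frames with `feature`, `gene_id`) and `locality`
#'   (intragenic/intergenic).
#' @export
annotate_dmrs <- function(dmrs, features) {
  out <- dmrs
  if (!nrow(dmrs)) {
    out$overlaps <- list()
    out$locality <- character()
    return(out)
  }
  known <- unique(features$contig)
  unknown <- !(dmrs$contig %in% known)
  if (any(unknown)) {
    warning(
      "DMR contig(s) absent from the annotation: ",
      paste(unique(dmrs$contig[unknown]), collapse = ", ")
    )
  }
  fgr <- features_granges(features)
  dgr <- GenomicRanges::GRanges(
    seqnames = dmrs$contig,
    ranges = IRanges::IRanges(dmrs$start + 1L, dmrs$end)
  )
  hits <- suppressWarnings(GenomicRanges::findOverlaps(dgr, fgr))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  out$overlaps <- lapply(seq_len(nrow(dmrs)), function(i) {
    j <- sh[qh == i]
    unique(data.frame(
      feature = features$feature[j], gene_id = features$gene_id[j],
      stringsAsFactors = FALSE
    ))
  })
  out$locality <- ifelse(
    vapply(out$overlaps, nrow, 0L) > 0L, "intragenic", "intergenic"
  )
  out
}

#' Count DMRs per feature class
#'
#' For each feature label, the number of DMRs overlapping at least one
#' instance of it (a DMR can count toward several labels), plus the
#' number of intergenic DMRs.
#'
#' @param annotated Output of [annotate_dmrs()].
#' @return Named integer vector over promoter, TSS, start_codon, exon,
#'   intron, stop_codon, gene and intergenic.
#' @export
summarize_overlaps <- function(annotated) {
  labels <- c(
    "promoter", "TSS", "start_codon", "exon", "intron",
    "stop_codon", "gene"
  )
  counts <- vapply(labels, function(lab) {
    sum(vapply(
      annotated$overlaps, function(ov) lab %in% ov$feature, FALSE
    ))
  }, 0L)
  c(counts, intergenic = sum(annotated$locality == "intergenic"))
}

#' Read a gene model from GFF3
#'
#' Expects `gene` and `exon` records; exons are linked to genes through
#' their `Parent` attribute, following one level of transcript nesting
#' when needed. GFF3's 1-based inclusive coordinates are converted to the
#' package's 0-based half-open convention.
#'
#' @param path GFF3 file.
#' @param mito_contigs Character vector naming mitochondrial contigs.
#' @param contig_lengths Optional named lengths; defaults to the maximum
#'   annotated end per contig (promoter truncation at the right edge then
#'   reflects annotation extent, not true contig length).
#' @return A [gene_model()].
#' @export
read_gene_model <- function(path, mito_contigs = character(),
                            contig_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$start0 <- df$start - 1L
  first_chr <- function(x) {
    vapply(x, function(v) if (length(v)) as.character(v)[1L] else NA_character_, "")
  }
  ids <- as.character(df$ID)
  genes <- df[df$type == "gene", , drop = FALSE]
  if (!nrow(genes)) stop("no gene records in ", path)
  gene_ids <- as.character(genes$ID)
  # map any feature ID (gene or transcript) to its gene
  parent_of <- setNames(first_chr(df$Parent), ids)
  to_gene <- function(id) {
    seen <- 0L
    while (!is.na(id) && !(id %in% gene_ids) && seen < 5L) {
      id <- parent_of[[id]]
      seen <- seen + 1L
    }
    if (is.na(id) || !(id %in% gene_ids)) NA_character_ else id
  }
  exons <- df[df$type == "exon", , drop = FALSE]
  if (!nrow(exons)) stop("no exon records in ", path)
  exon_gene <- vapply(first_chr(exons$Parent), to_gene, "")
  if (anyNA(exon_gene)) stop("exon(s) with no resolvable gene parent")
  contig_names <- unique(as.character(df$seqnames))
  if (is.null(contig_lengths)) {
    contig_lengths <- vapply(
      contig_names,
      function(cn) max(df$end[df$seqnames == cn]), 0
    )
  }
  codons <- function(type) {
    cd <- df[df$type == type, , drop = FALSE]
    if (!nrow(cd)) {
      return(NULL)
    }
    data.frame(
      gene_id = vapply(first_chr(cd$Parent), to_gene, ""),
      contig = as.character(cd$seqnames),
      start = cd$start0, end = cd$end, stringsAsFactors = FALSE
    )
  }
  gene_model(
    genes = data.frame(
      gene_id = gene_ids,
      name = if (!is.null(genes$Name)) {
        ifelse(is.na(genes$Name), gene_ids, as.character(genes$Name))
      } else {
        gene_ids
      },
      contig = as.character(genes$seqnames),
      start = genes$start0, end = genes$end,
      strand = as.character(genes$strand),
      stringsAsFactors = FALSE
    ),
    exons = data.frame(
      gene_id = unname(exon_gene),
      contig = as.character(exons$seqnames),
      start = exons$start0, end = exons$end, stringsAsFactors = FALSE
    ),
    contigs = data.frame(
      name = contig_names,
      length = unname(contig_lengths[contig_names]),
      is_mitochondrial = contig_names %in% mito_contigs,
      stringsAsFactors = FALSE
    ),
    start_codons = codons("start_codon"),
    stop_codons = codons("stop_codon")
  )
}

#' Write a feature set as GFF3
#'
#' @param features A `feature_set`.
#' @param path Output file.
#' @export
write_features_gff3 <- function(features, path) {
  gr <- features_granges(features)
  names(S4Vectors::mcols(gr)) <- c("type", "ID")
  S4Vectors::mcols(gr)$source <- "rankmeth"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
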