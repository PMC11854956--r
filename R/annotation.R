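# Transcript annotation container.
#
# Internally coordinates are 0-based half-open; the GTF boundary converts to
# 1-based closed.  `transcripts` has one row per transcript
# (transcript_id, gene_id, chrom, strand, start, end, biotype), `exons` one
# row per exon (transcript_id, exon_rank, start, end) with exon_rank in
# transcript 5'->3' order.

#' Construct a transcript annotation
#'
#' @param transcripts data.frame with columns transcript_id, gene_id, chrom,
#'   strand, start, end, biotype (0-based half-open span).
#' @param exons data.frame with columns transcript_id, exon_rank, start, end.
#' @param genome optional genome sequence: named character vector of
#'   chromosome sequences.
#' @return object of class `tx_annotation`.
#' @export
tx_annotation <- function(transcripts, exons, genome = NULL) {
  need_t <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end", "biotype")
  need_e <- c("transcript_id", "exon_rank", "start", "end")
  if (!all(need_t %in% names(transcripts))) stopf("transcripts missing required columns")
  if (!all(need_e %in% names(exons))) stopf("exons missing required columns")
  if (!all(transcripts$strand %in% c("+", "-"))) stopf("strand must be + or -")
  # exons sorted and disjoint within transcript
  sp <- split(exons, exons$transcript_id)
  for (tid in names(sp)) {
    e <- sp[[tid]][order(sp[[tid]]$start), ]
    if (any(e$end <= e$start)) stopf("empty exon in %s", tid)
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)]))
      stopf("overlapping exons in %s", tid)
  }
  structure(list(transcripts = transcripts, exons = exons, genome = genome),
            class = "tx_annotation")
}

#' @export
print.tx_annotation <- function(x, ...) {
  cat(sprintf("tx_annotation: %d transcripts (%s), %d exons%s\n",
              nrow(x$transcripts),
              paste(names(table(x$transcripts$biotype)), table(x$transcripts$biotype),
                    sep = ":", collapse = " "),
              nrow(x$exons),
              if (is.null(x$genome)) "" else sprintf(", genome %d bp",
                                                     sum(nchar(x$genome)))))
  invisible(x)
}

# exons of one transcript in genomic order
tx_exons <- function(ann, tid) {
  e <- ann$exons[ann$exons$transcript_id == tid, , drop = FALSE]
  e[order(e$start), , drop = FALSE]
}

#' Spliced (exonic) length of transcripts
#' @param ann a [tx_annotation()].
#' @param ids transcript ids (default all).
#' @return named integer vector of spliced lengths.
#' @export
tx_spliced_length <- function(ann, ids = NULL) {
  e <- ann$exons
  len <- tapply(e$end - e$start, e$transcript_id, sum)
  out <- setNames(as.integer(len), names(len))
  if (!is.null(ids)) out <- out[ids]
  out
}

# GRanges of exons (1-based closed) with transcript metadata
exon_granges <- function(ann, ids = NULL) {
  e <- ann$exons
  if (!is.null(ids)) e <- e[e$transcript_id %in% ids, , drop = FALSE]
  t <- ann$transcripts[match(e$transcript_id, ann$transcripts$transcript_id), ]
  GenomicRanges::GRanges(
    seqnames = t$chrom,
    ranges = IRanges::IRanges(start = e$start + 1L, end = e$end),
    strand = t$strand,
    transcript_id = e$transcript_id,
    gene_id = t$gene_id,
    biotype = t$biotype)
}

# GRanges of transcript spans
tx_granges <- function(ann, ids = NULL) {
  t <- ann$transcripts
  if (!is.null(ids)) t <- t[t$transcript_id %in% ids, , drop = FALSE]
  GenomicRanges::GRanges(
    seqnames = t$chrom,
    ranges = IRanges::IRanges(start = t$start + 1L, end = t$end),
    strand = t$strand,
    transcript_id = t$transcript_id,
    gene_id = t$gene_id,
    biotype = t$biotype)
}

#' Extract spliced transcript sequences from the genome
#'
#' @param ann a [tx_annotation()] carrying a genome.
#' @param ids transcript ids (default all).
#' @return named character vector of 5'->3' transcript sequences (DNA
#'   alphabet).
#' @export
extract_tx_seq <- function(ann, ids = NULL) {
  if (is.null(ann$genome)) stopf("annotation carries no genome sequence")
  if (is.null(ids)) ids <- ann$transcripts$transcript_id
  out <- vapply(ids, function(tid) {
    tr <- ann$transcripts[ann$transcripts$transcript_id == tid, ]
    if (nrow(tr) != 1) stopf("unknown transcript '%s'", tid)
    chr_seq <- ann$genome[[tr$chrom]]
    e <- tx_exons(ann, tid)
    s <- paste(substring(chr_seq, e$start + 1L, e$end), collapse = "")
    if (tr$strand == "-") revcomp(s) else s
  }, character(1))
  setNames(out, ids)
}

# Map transcript coordinates (1-based, 5'->3') of a contiguous within-exon
# segment to genomic 0-based half-open coordinates.  Returns list(start, end,
# exon_rank) or errors if the segment spans an exon boundary.
tx_to_genomic <- function(ann, tid, tx_start, tx_end) {
  tr <- ann$transcripts[ann$transcripts$transcript_id == tid, ]
  e <- tx_exons(ann, tid)
  widths <- e$end - e$start
  if (tr$strand == "-") { e <- e[rev(seq_len(nrow(e))), ]; widths <- rev(widths) }
  cum <- cumsum(widths)
  off <- c(0L, cum[-length(cum)])
  k <- which(tx_start > off & tx_end <= cum)
  if (!length(k)) stopf("segment %d-%d of %s spans an exon boundary", tx_start, tx_end, tid)
  k <- k[1]
  within_s <- tx_start - off[k] - 1L  # 0-based within exon (5'->3')
  within_e <- tx_end - off[k]
  if (tr$strand == "+") {
    list(start = e$start[k] + within_s, end = e$start[k] + within_e)
  } else {
    list(start = e$end[k] - within_e, end = e$end[k] - within_s)
  }
}

#' Write an annotation as GTF
#'
#' Exon records only, 1-based closed coordinates, attributes gene_id,
#' transcript_id and biotype.
#'
#' @param ann a [tx_annotation()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_annotation_gtf <- function(ann, path) {
  e <- ann$exons
  t <- ann$transcripts[match(e$transcript_id, ann$transcripts$transcript_id), ]
  lines <- sprintf(
    "%s\tsaltnet\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\"; biotype \"%s\";",
    t$chrom, e$start + 1L, e$end, t$strand, t$gene_id, e$transcript_id,
    t$biotype)
  o <- order(t$chrom, e$start, e$transcript_id)
  writeLines(lines[o], path)
  invisible(path)
}

#' Read an annotation from GTF
#'
#' Inverse of [write_annotation_gtf()]: rebuilds the transcript table from
#' exon records (attribute `biotype` optional, default "other").
#'
#' @param path GTF file.
#' @param genome optional named character vector of chromosome sequences.
#' @return a [tx_annotation()].
#' @export
read_annotation_gtf <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type %in% "exon"]
  df <- data.frame(
    transcript_id = S4Vectors::mcols(gr)$transcript_id,
    gene_id = S4Vectors::mcols(gr)$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    biotype = if ("biotype" %in% names(S4Vectors::mcols(gr)))
      S4Vectors::mcols(gr)$biotype else "other",
    stringsAsFactors = FALSE)
  df <- df[order(df$transcript_id, df$start), ]
  sp <- split(df, df$transcript_id)
  tx <- do.call(rbind, lapply(sp, function(e) data.frame(
    transcript_id = e$transcript_id[1], gene_id = e$gene_id[1],
    chrom = e$chrom[1], strand = e$strand[1],
    start = min(e$start), end = max(e$end), biotype = e$biotype[1],
    stringsAsFactors = FALSE)))
  exons <- do.call(rbind, lapply(sp, function(e) {
    e <- e[order(e$start), ]
    rk <- if (e$strand[1] == "+") seq_len(nrow(e)) else rev(seq_len(nrow(e)))
    data.frame(transcript_id = e$transcript_id, exon_rank = rk,
               start = e$start, end = e$end, stringsAsFactors = FALSE)
  }))
  rownames(tx) <- NULL; rownames(exons) <- NULL
  tx_annotation(tx, exons, genome = genome)
}
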