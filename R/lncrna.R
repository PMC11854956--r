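# lncRNA candidate filtering, positional classification and cis-target
# pairing.
#
# Filter rules (applied in order; the first failing rule is recorded):
#   1. no same-strand exonic overlap with a known mRNA  ("overlap")
#   2. spliced length >= 200 nt                         ("length")
#   3. mean supporting read depth >= 3                  ("coverage")
#   4. CPC score < 0.5                                  ("cpc")
#   5. CNCI score < 0                                   ("cnci")
# Low coding potential on both scores *retains* a candidate: transcripts
# scoring at or above either threshold are treated as coding and removed.

#' Filter lncRNA candidates
#'
#' @param candidates [tx_annotation()] (or transcript/exon pair) of candidate
#'   transcripts.
#' @param scores data.frame with transcript_id, cpc_score, cnci_score,
#'   coverage; one row per candidate.
#' @param known_mrna [tx_annotation()] of known coding transcripts.
#' @param min_length minimum spliced length (default 200 nt).
#' @param min_coverage minimum mean read depth (default 3).
#' @param cpc_max,cnci_max coding-potential thresholds (defaults 0.5, 0).
#' @return list with `retained` (transcript table subset) and `removed`
#'   (transcript_id + reason).
#' @export
filter_lncrna_candidates <- function(candidates, scores, known_mrna,
                                     min_length = 200, min_coverage = 3,
                                     cpc_max = 0.5, cnci_max = 0) {
  tx <- candidates$transcripts
  miss <- setdiff(tx$transcript_id, scores$transcript_id)
  if (length(miss))
    stopf("missing coding-potential score record for transcript '%s'", miss[1])
  sc <- scores[match(tx$transcript_id, scores$transcript_id), ]
  if (any(!is.finite(sc$cpc_score)) || any(!is.finite(sc$cnci_score)) ||
      any(!is.finite(sc$coverage)))
    stopf("non-finite coding-potential scores")

  # same-strand exonic overlap with known mRNA exons
  overlaps <- rep(FALSE, nrow(tx))
  if (nrow(known_mrna$transcripts)) {
    cand_ex <- exon_granges(candidates)
    mrna_ex <- exon_granges(known_mrna)
    hit <- GenomicRanges::findOverlaps(cand_ex, mrna_ex, ignore.strand = FALSE)
    hit_tx <- unique(S4Vectors::mcols(cand_ex)$transcript_id[S4Vectors::queryHits(hit)])
    overlaps <- tx$transcript_id %in% hit_tx
  }
  len <- tx_spliced_length(candidates)[tx$transcript_id]

  reason <- rep(NA_character_, nrow(tx))
  reason[is.na(reason) & overlaps] <- "overlap"
  reason[is.na(reason) & len < min_length] <- "length"
  reason[is.na(reason) & sc$coverage < min_coverage] <- "coverage"
  reason[is.na(reason) & sc$cpc_score >= cpc_max] <- "cpc"
  reason[is.na(reason) & sc$cnci_score >= cnci_max] <- "cnci"

  retained <- tx[is.na(reason), , drop = FALSE]
  retained$biotype <- "lncRNA"
  removed <- data.frame(transcript_id = tx$transcript_id[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  rownames(retained) <- NULL
  list(retained = retained, removed = removed)
}

#' Positional classification of lncRNAs against coding transcripts
#'
#' Assigns one class code per lncRNA with precedence x > o > i > j > u:
#' `x` exonic overlap with a coding exon on the opposite strand; `o` exonic
#' overlap with a coding exon on the same strand; `i` contained entirely
#' within an intron of a same-strand coding transcript; `j` (bidirectional)
#' no exonic overlap but 5' end within `intergenic_window` nt of the 5' end
#' of an opposite-strand coding transcript; `u` intergenic otherwise.
#'
#' @param lnc [tx_annotation()] of retained lncRNAs.
#' @param coding [tx_annotation()] of coding transcripts.
#' @param intergenic_window bidirectional (j) 5'-end distance in nt
#'   (default 1000).
#' @return data.frame transcript_id, class_code.
#' @export
classify_lncrna_position <- function(lnc, coding, intergenic_window = 1000) {
  lt <- lnc$transcripts
  ct <- coding$transcripts
  out <- rep("u", nrow(lt))
  if (!nrow(ct)) {
    return(data.frame(transcript_id = lt$transcript_id, class_code = out,
                      stringsAsFactors = FALSE))
  }
  lex <- exon_granges(lnc)
  cex <- exon_granges(coding)

  # exon-exon overlaps, any strand; split by relative orientation
  hits <- GenomicRanges::findOverlaps(lex, cex, ignore.strand = TRUE)
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    same <- as.character(GenomicRanges::strand(lex))[q] ==
      as.character(GenomicRanges::strand(cex))[s]
    lid <- S4Vectors::mcols(lex)$transcript_id
    anti_ids <- unique(lid[q[!same]])
    sense_ids <- unique(lid[q[same]])
    out[lt$transcript_id %in% sense_ids] <- "o"
    out[lt$transcript_id %in% anti_ids] <- "x"   # x takes precedence over o
  }

  # introns of coding transcripts (same strand containment)
  introns <- do.call(rbind, lapply(unique(ct$transcript_id), function(tid) {
    e <- tx_exons(coding, tid)
    if (nrow(e) < 2) return(NULL)
    tr <- ct[ct$transcript_id == tid, ]
    data.frame(chrom = tr$chrom, strand = tr$strand,
               start = e$end[-nrow(e)], end = e$start[-1],
               stringsAsFactors = FALSE)
  }))
  for (k in which(out == "u")) {
    if (!is.null(introns)) {
      inl <- introns$chrom == lt$chrom[k] & introns$strand == lt$strand[k] &
        introns$start <= lt$start[k] & introns$end >= lt$end[k]
      if (any(inl)) { out[k] <- "i"; next }
    }
    # bidirectional: 5' ends close, opposite strands
    l5 <- if (lt$strand[k] == "+") lt$start[k] else lt$end[k]
    opp <- ct$chrom == lt$chrom[k] & ct$strand != lt$strand[k]
    if (any(opp)) {
      c5 <- ifelse(ct$strand[opp] == "+", ct$start[opp], ct$end[opp])
      if (any(abs(c5 - l5) <= intergenic_window)) out[k] <- "j"
    }
  }
  data.frame(transcript_id = lt$transcript_id, class_code = out,
             stringsAsFactors = FALSE)
}

#' Pair differential lncRNAs with nearby genes as cis targets
#'
#' A (lncRNA, gene) pair is emitted when the minimum genomic distance
#' between the two transcript spans is at most `window` (overlap counts as
#' distance 0; the boundary is inclusive).  Each pair is annotated with the
#' Pearson correlation of log2(expression + 1) across samples.
#'
#' @param de_lnc [tx_annotation()] (or transcript table) of differential
#'   lncRNAs.
#' @param genes [tx_annotation()] of genes to pair against.
#' @param expr numeric matrix of expression values (e.g. FPKM), rows named
#'   by feature id, one column per sample; must cover both pair members.
#' @param window maximum genomic distance in nt (default 100000).
#' @return data.frame lncrna_id, gene_id, distance, correlation, sign.
#' @export
cis_targets <- function(de_lnc, genes, expr, window = 100000) {
  lt <- if (inherits(de_lnc, "tx_annotation")) de_lnc$transcripts else de_lnc
  gt <- if (inherits(genes, "tx_annotation")) genes$transcripts else genes
  rows <- list()
  for (k in seq_len(nrow(lt))) {
    same_chr <- gt$chrom == lt$chrom[k] & gt$transcript_id != lt$transcript_id[k]
    if (!any(same_chr)) next
    g <- gt[same_chr, , drop = FALSE]
    d <- interval_distance(lt$start[k], lt$end[k], g$start, g$end)
    sel <- d <= window
    if (!any(sel)) next
    g <- g[sel, , drop = FALSE]; d <- d[sel]
    for (j in seq_len(nrow(g))) {
      lid <- lt$transcript_id[k]; gid <- g$transcript_id[j]
      if (!(lid %in% rownames(expr)) || !(gid %in% rownames(expr)))
        stopf("expression missing for cis pair (%s, %s)", lid, gid)
      x <- log2(as.numeric(expr[lid, ]) + 1)
      y <- log2(as.numeric(expr[gid, ]) + 1)
      r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else cor(x, y)
      rows[[length(rows) + 1L]] <- data.frame(
        lncrna_id = lid, gene_id = gid, distance = d[j], correlation = r,
        sign = if (is.na(r)) NA_character_ else if (r >= 0) "positive" else "negative",
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lncrna_id = character(0), gene_id = character(0),
               distance = integer(0), correlation = numeric(0),
               sign = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Longest open reading frame
#'
#' Length (in nt, stop codon included) of the longest ATG-initiated,
#' in-frame stop-terminated ORF over the three forward frames of the given
#' stranded transcript sequence.  Ambiguity codes never match start or stop
#' codons.
#'
#' @param sequence nucleotide string (ACGT or ACGU).
#' @return integer ORF length in nt; 0 if none.
#' @export
longest_orf <- function(sequence) {
  s <- toupper(to_dna(sequence))
  n <- nchar(s)
  best <- 0L
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3
    if (ncod < 2) next
    codons <- substring(s, frame + 1 + 3 * (0:(ncod - 1)), frame + 3 + 3 * (0:(ncod - 1)))
    starts <- which(codons == "ATG")
    stops <- which(codons %in% c("TAA", "TAG", "TGA"))
    if (!length(starts) || !length(stops)) next
    for (st in starts) {
      nx <- stops[stops >= st + 1]
      if (!length(nx)) next
      best <- max(best, (nx[1] - st + 1L) * 3L)
    }
  }
  best
}
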