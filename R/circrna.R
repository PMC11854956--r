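# Back-splice junction calling from chimeric-segment alignments.
#
# A back-splice read is a two-segment chimeric alignment in which the 3'
# segment of the read maps upstream of its 5' segment; the junction acceptor
# is the start of the 3' segment, the donor the end of the 5' segment.
# Acceptance criteria: at least one supporting read with <= 2 mismatches,
# and span (donor - acceptor) strictly below 100 kb.  Rejection reasons are
# assigned with precedence mismatches -> support -> span.

#' Detect back-splice junctions
#'
#' @param alignments data.frame of chimeric segments: read_id, chrom,
#'   seg1_start, seg1_end, seg2_start, seg2_end, strand, mismatches
#'   (coordinates 0-based half-open; seg1 is the read 5' segment).  An
#'   optional `chrom2` column marks the second segment's chromosome; records
#'   with `chrom2 != chrom` are skipped as malformed.
#' @param max_mismatches per-read mismatch cap for support (default 2).
#' @param max_span strict span cutoff in nt (default 1e5).
#' @return list with `accepted` (circ_id, chrom, acceptor, donor, strand,
#'   junction_reads, max_read_mismatches, span), `rejected` (same keys +
#'   reason), and counts `n_malformed`, `n_non_backsplice`.
#' @export
detect_backsplice <- function(alignments, max_mismatches = 2, max_span = 1e5) {
  a <- alignments
  need <- c("read_id", "chrom", "seg1_start", "seg1_end", "seg2_start",
            "seg2_end", "strand", "mismatches")
  if (!all(need %in% names(a))) stopf("alignment table missing required columns")
  malformed <- rep(FALSE, nrow(a))
  if ("chrom2" %in% names(a)) malformed <- a$chrom2 != a$chrom
  malformed <- malformed | !is.finite(a$seg1_start) | !is.finite(a$seg2_start)
  a2 <- a[!malformed, , drop = FALSE]
  # back-splice orientation: 3' segment upstream of 5' segment
  bs <- a2$seg2_end <= a2$seg1_start
  n_non_bs <- sum(!bs)
  b <- a2[bs, , drop = FALSE]

  empty <- data.frame(circ_id = character(0), chrom = character(0),
                      acceptor = integer(0), donor = integer(0),
                      strand = character(0), junction_reads = integer(0),
                      max_read_mismatches = integer(0), span = integer(0),
                      stringsAsFactors = FALSE)
  if (!nrow(b)) {
    return(list(accepted = empty,
                rejected = cbind(empty, data.frame(reason = character(0))),
                n_malformed = sum(malformed), n_non_backsplice = n_non_bs))
  }
  key <- paste(b$chrom, b$seg2_start, b$seg1_end, b$strand, sep = "\r")
  groups <- split(seq_len(nrow(b)), key)
  rows <- lapply(groups, function(idx) {
    g <- b[idx, , drop = FALSE]
    support <- g$mismatches <= max_mismatches
    acceptor <- g$seg2_start[1]; donor <- g$seg1_end[1]
    span <- donor - acceptor
    data.frame(
      circ_id = sprintf("circ_%s_%d_%d", g$chrom[1], acceptor, donor),
      chrom = g$chrom[1], acceptor = acceptor, donor = donor,
      strand = g$strand[1],
      junction_reads = sum(support),
      max_read_mismatches = if (any(support)) max(g$mismatches[support]) else
        min(g$mismatches),
      span = span,
      reason = if (!any(support)) "mismatches" else
        if (span >= max_span) "span" else "none",
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$chrom, res$acceptor, res$donor), , drop = FALSE]
  rownames(res) <- NULL
  list(accepted = res[res$reason == "none", setdiff(names(res), "reason"), drop = FALSE],
       rejected = res[res$reason != "none", , drop = FALSE],
       n_malformed = sum(malformed), n_non_backsplice = n_non_bs)
}

#' Classify circRNA type against an annotation
#'
#' `exonic` when acceptor and donor both coincide (within `tol` nt) with
#' exon boundaries of one same-strand transcript (n_exons = number of that
#' transcript's exons enclosed by the junction); `ciRNA` when the junction
#' interval lies wholly within one intron of a same-strand transcript;
#' `intergenic` otherwise (including junctions that overlap annotation
#' without a consistent spliced or intronic origin).  Precedence
#' exonic > ciRNA > intergenic.
#'
#' @param junctions data.frame from [detect_backsplice()]`$accepted`.
#' @param annotation a [tx_annotation()].
#' @param tol exon-boundary matching tolerance in nt (default 2).
#' @return the junction table with circ_type and n_exons columns added.
#' @export
classify_circ <- function(junctions, annotation, tol = 2) {
  tx <- annotation$transcripts
  ctype <- rep("intergenic", nrow(junctions))
  nex <- rep(1L, nrow(junctions))
  tids <- sort(unique(tx$transcript_id))
  for (k in seq_len(nrow(junctions))) {
    acc <- junctions$acceptor[k]; don <- junctions$donor[k]
    chrom <- junctions$chrom[k]; strand <- junctions$strand[k]
    found <- FALSE
    for (tid in tids) {
      tr <- tx[tx$transcript_id == tid, ]
      if (tr$chrom != chrom || tr$strand != strand) next
      e <- tx_exons(annotation, tid)
      if (any(abs(e$start - acc) <= tol) && any(abs(e$end - don) <= tol)) {
        ctype[k] <- "exonic"
        nex[k] <- sum(e$start >= acc - tol & e$end <= don + tol)
        found <- TRUE
        break
      }
    }
    if (found) next
    for (tid in tids) {
      tr <- tx[tx$transcript_id == tid, ]
      if (tr$chrom != chrom || tr$strand != strand) next
      e <- tx_exons(annotation, tid)
      if (nrow(e) < 2) next
      istart <- e$end[-nrow(e)]; iend <- e$start[-1]
      if (any(istart <= acc & iend >= don)) { ctype[k] <- "ciRNA"; break }
    }
  }
  junctions$circ_type <- ctype
  junctions$n_exons <- ifelse(ctype == "exonic", nex, 1L)
  junctions
}

#' SRPBM quantification of circRNA junctions
#'
#' @param junction_counts matrix of junction-read counts, junctions x
#'   samples (rownames = circ ids).
#' @param mapped_reads per-sample total mapped reads.
#' @return numeric matrix of SRPBM values.
#' @export
quantify_circ <- function(junction_counts, mapped_reads) {
  m <- as.matrix(junction_counts)
  if (length(mapped_reads) != ncol(m)) stopf("one mapped-read total per sample")
  if (any(mapped_reads <= 0)) stopf("mapped_reads must be positive")
  t(t(m) * (1e9 / mapped_reads))
}
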