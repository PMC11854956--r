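# Planting back-splice junctions and simulating chimeric-segment reads.

#' Plant back-splice junctions with ground truth
#'
#' Builds `scenario$n_circ` detectable junctions (mixing exonic, intronic
#' ciRNA and intergenic origins) plus undetectable decoys violating one
#' acceptance criterion each: all supporting reads carrying > 2 mismatches,
#' span >= 100 kb, or zero junction reads.
#'
#' @param scenario a [synth_scenario()].
#' @param ann a [tx_annotation()].
#' @return data.frame circ_id, chrom, acceptor, donor, strand, circ_type
#'   (intended), n_exons (intended), n_reads, mm_low/mm_high (per-read
#'   mismatch range), accept, reject_reason.
#' @export
plant_backsplice_junctions <- function(scenario, ann) {
  sc <- scenario
  set.seed(stage_seed(sc$seed, 6L))
  tx <- ann$transcripts[ann$transcripts$biotype == "mRNA", ]
  chrom <- tx$chrom[1]
  chrom_len <- nchar(ann$genome[[chrom]])

  # intergenic gaps for intergenic/span junctions
  occ <- ann$transcripts[order(ann$transcripts$start), ]
  gaps <- data.frame(start = c(0L, occ$end), end = c(occ$start, chrom_len))
  gaps <- gaps[gaps$end - gaps$start >= 1200, , drop = FALSE]

  used <- character(0)
  rows <- list()
  mk <- function(acceptor, donor, strand, type, nex, n_reads, mm_low, mm_high,
                 accept, reason) {
    if (donor <= acceptor)
      stopf("back-splice orientation requires donor > acceptor (%s: %s..%s)",
            type, acceptor, donor)
    key <- paste(acceptor, donor)
    if (key %in% used) return(FALSE)
    used <<- c(used, key)
    rows[[length(rows) + 1L]] <<- data.frame(
      # coordinate-derived id, identical to the detector's naming so planted
      # and detected junctions join without a lookup table
      circ_id = sprintf("circ_%s_%d_%d", chrom, acceptor, donor), chrom = chrom,
      acceptor = acceptor, donor = donor, strand = strand, circ_type = type,
      n_exons = nex, n_reads = n_reads, mm_low = mm_low, mm_high = mm_high,
      accept = accept, reject_reason = reason, stringsAsFactors = FALSE)
    TRUE
  }

  multi <- tx$transcript_id[vapply(tx$transcript_id, function(t)
    nrow(tx_exons(ann, t)), integer(1)) >= 3]
  intronful <- tx$transcript_id[vapply(tx$transcript_id, function(t) {
    e <- tx_exons(ann, t)
    nrow(e) > 1 && max(e$start[-1] - e$end[-nrow(e)]) >= 400
  }, logical(1))]

  add_junction <- function(kind, n_reads, mm_low, mm_high, accept, reason) {
    for (try in 1:50) {
      if (kind == "exonic" && length(multi)) {
        t <- resample(multi)
        e <- tx_exons(ann, t)
        i <- sample(seq_len(nrow(e) - 1), 1)
        j <- resample(seq(i + 1, nrow(e)))
        if (e$end[j] - e$start[i] >= 1e5) next
        if (mk(e$start[i], e$end[j],
               tx$strand[tx$transcript_id == t], "exonic", j - i + 1L,
               n_reads, mm_low, mm_high, accept, reason)) return(TRUE)
      } else if (kind == "ciRNA" && length(intronful)) {
        t <- resample(intronful)
        e <- tx_exons(ann, t)
        ist <- e$end[-nrow(e)]; ien <- e$start[-1]
        ok <- which(ien - ist >= 400)
        w <- resample(ok)
        acc <- ist[w] + 40L
        don <- acc + resample(200:min(700, ien[w] - ist[w] - 80))
        if (mk(acc, don, tx$strand[tx$transcript_id == t], "ciRNA", 1L,
               n_reads, mm_low, mm_high, accept, reason)) return(TRUE)
      } else if (kind == "intergenic" && nrow(gaps)) {
        g <- gaps[sample.int(nrow(gaps), 1), ]
        acc <- g$start + 100L
        don <- acc + resample(200:min(900, g$end - g$start - 250))
        if (mk(acc, don, sample(c("+", "-"), 1), "intergenic", 1L,
               n_reads, mm_low, mm_high, accept, reason)) return(TRUE)
      } else if (kind == "span") {
        acc <- resample(1000:(chrom_len - 200000))
        don <- acc + resample(100000:180000)
        if (mk(acc, don, sample(c("+", "-"), 1), "intergenic", 1L,
               n_reads, mm_low, mm_high, accept, reason)) return(TRUE)
      } else return(FALSE)
    }
    stopf("could not place a %s junction", kind)
  }

  types <- sample(c("ciRNA", "exonic", "intergenic"), sc$n_circ,
                  replace = TRUE, prob = c(0.5, 0.3, 0.2))
  for (k in types)
    add_junction(k, sample(2:8, 1), 0L, 2L, TRUE, "none")
  rej <- sc$n_junction_rejects
  if (!is.na(rej["mismatches"]) && rej["mismatches"] > 0)
    for (z in seq_len(rej["mismatches"]))
      add_junction("ciRNA", sample(1:4, 1), 3L, 5L, FALSE, "mismatches")
  if (!is.na(rej["span"]) && rej["span"] > 0)
    for (z in seq_len(rej["span"]))
      add_junction("span", sample(1:3, 1), 0L, 2L, FALSE, "span")
  if (!is.na(rej["support"]) && rej["support"] > 0)
    for (z in seq_len(rej["support"]))
      add_junction("intergenic", 0L, 0L, 0L, FALSE, "support")

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate chimeric-segment alignments for planted junctions
#'
#' Each junction with `n_reads > 0` is emitted as that many two-segment
#' records in which the read's 3' segment (seg2) maps upstream of its 5'
#' segment (seg1): seg1 ends at the donor, seg2 starts at the acceptor.
#' Per-read mismatch counts are drawn from the junction's mm_low..mm_high
#' range (forced to hit mm_low at least once so the ground-truth label is
#' realised).  A few linear (non-back-splice) chimeric reads are added as
#' negatives.
#'
#' @param scenario a [synth_scenario()].
#' @param junctions output of [plant_backsplice_junctions()].
#' @param n_noise number of linear chimeric decoy reads (default 5).
#' @return data.frame read_id, chrom, seg1_start, seg1_end, seg2_start,
#'   seg2_end, strand, mismatches (0-based half-open coordinates).
#' @export
simulate_backsplice_reads <- function(scenario, junctions, n_noise = 5) {
  set.seed(stage_seed(scenario$seed, 7L))
  rows <- list()
  for (k in seq_len(nrow(junctions))) {
    j <- junctions[k, ]
    if (j$n_reads == 0) next
    span <- j$donor - j$acceptor
    for (r in seq_len(j$n_reads)) {
      lmax <- max(10L, min(40L, span %/% 2 - 2L))
      l1 <- resample(10:lmax); l2 <- resample(10:lmax)
      mm <- if (r == 1) j$mm_low else resample(j$mm_low:j$mm_high)
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = sprintf("%s.read%02d", j$circ_id, r), chrom = j$chrom,
        seg1_start = j$donor - l1, seg1_end = j$donor,
        seg2_start = j$acceptor, seg2_end = j$acceptor + l2,
        strand = j$strand, mismatches = mm, stringsAsFactors = FALSE)
    }
  }
  chrom <- junctions$chrom[1]
  for (z in seq_len(n_noise)) {
    s <- sample(5000:50000, 1)
    rows[[length(rows) + 1L]] <- data.frame(
      read_id = sprintf("linear_read%02d", z), chrom = chrom,
      seg1_start = s, seg1_end = s + 30L,
      seg2_start = s + 500L, seg2_end = s + 530L,
      strand = "+", mismatches = sample(0:2, 1), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Back-splice-joined circRNA sequence
#'
#' Returns the circle's sequence with the first `pad` nucleotides appended
#' after the junction so junction-crossing duplex sites are discoverable.
#' Exonic circRNAs are spliced from the host transcript's exons inside the
#' junction; other types use the genomic span.
#'
#' @param junction one row of an accepted/classified junction table.
#' @param ann a [tx_annotation()] carrying the genome.
#' @param host_tid optional host transcript id for exonic splicing.
#' @param pad junction padding in nt (default 25).
#' @return character sequence (DNA alphabet, transcript orientation).
#' @export
get_circ_sequence <- function(junction, ann, host_tid = NULL, pad = 25) {
  chrom <- junction$chrom
  g <- ann$genome[[chrom]]
  seq <- NULL
  if (!is.null(host_tid)) {
    e <- tx_exons(ann, host_tid)
    e <- e[e$start >= junction$acceptor - 2 & e$end <= junction$donor + 2, ,
           drop = FALSE]
    if (nrow(e))
      seq <- paste(substring(g, e$start + 1L, e$end), collapse = "")
  }
  if (is.null(seq))
    seq <- substring(g, junction$acceptor + 1L, junction$donor)
  if (junction$strand == "-") seq <- revcomp(seq)
  pad <- min(pad, nchar(seq))
  paste0(seq, substring(seq, 1, pad))
}
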