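# Planting miRNA target and mimic sites into the synthetic genome.
#
# Sites are written into transcript exons by editing the genome sequence, so
# ground truth stays re-derivable from the emitted FASTA/GTF alone.  Each
# site occupies its own host transcript, which keeps pair-level labels
# unambiguous.  Decoys violate exactly one named rule.

# a site base that neither Watson-Crick pairs nor wobbles with miRNA base b
non_pairing_bases <- function(b) {
  switch(b,
         A = c("A", "C", "G"),
         C = c("A", "C", "U"),
         G = c("A", "G"),
         U = c("C", "U"),
         stopf("bad base '%s'", b))
}

mismatch_base <- function(b) {
  ch <- non_pairing_bases(b)
  ch[sample.int(length(ch), 1)]
}

# a base pairing with none of the miRNA positions in `window` (falls back to
# the centre position only); anchoring mismatches and bulge insertions this
# way keeps the intended geometry strictly optimal for the aligner
anchored_base <- function(mb, window) {
  window <- window[window >= 1 & window <= length(mb)]
  ch <- Reduce(intersect, lapply(mb[window], non_pairing_bases))
  if (!length(ch)) ch <- non_pairing_bases(mb[window[ceiling(length(window) / 2)]])
  ch[sample.int(length(ch), 1)]
}

# site index complementary to miRNA position i (site 5'->3', miRNA length M)
site_index <- function(i, M) M - i + 1L

# Perfect-complement target site with n_mm single mismatches at miRNA
# positions > 13 (each costs 1 Allen unit, so intended Allen == n_mm).
make_target_site <- function(mirna, n_mm = 0, intended_allen_max = NULL) {
  M <- nchar(mirna)
  if (!is.null(intended_allen_max) && n_mm > intended_allen_max)
    stopf("intended Allen cap %s unachievable with %d mismatches",
          intended_allen_max, n_mm)
  avail <- setdiff(seq(15, M - 1), integer(0))
  if (n_mm > length(avail))
    stopf("site too short for %d 3' mismatches", n_mm)
  site <- strsplit(revcomp(mirna), "")[[1]]
  mb <- strsplit(mirna, "")[[1]]
  if (n_mm > 0) {
    pos <- sort(resample(avail, size = n_mm))
    for (i in pos) site[site_index(i, M)] <- mismatch_base(mb[i])
  }
  list(seq = paste(site, collapse = ""), allen_intended = n_mm)
}

# Target decoy: mismatches at every other position including the 5'-proximal
# doubled region; minimum achievable Allen far exceeds the cutoff.
make_target_decoy <- function(mirna) {
  M <- nchar(mirna)
  site <- strsplit(revcomp(mirna), "")[[1]]
  mb <- strsplit(mirna, "")[[1]]
  for (i in seq(2, M, by = 2)) site[site_index(i, M)] <- mismatch_base(mb[i])
  paste(site, collapse = "")
}

# Mimic site: ncRNA-side bulge of bulge_len nt between miRNA positions
# gap_after and gap_after+1, plus mm_at mismatches (miRNA positions outside
# the middle).  decoy_kind builds a site violating exactly that eTM rule.
make_mimic_site <- function(mirna, bulge_len = 3, gap_after = 10,
                            mm_at = integer(0), decoy_kind = "none") {
  M <- nchar(mirna)
  mb <- strsplit(mirna, "")[[1]]
  site <- strsplit(revcomp(mirna), "")[[1]]

  apply_mm <- function(site, pos) {
    for (i in pos) site[site_index(i, M)] <- anchored_base(mb, (i - 1):(i + 1))
    site
  }
  insert_bulge <- function(site, g, len) {
    # insert after site index M - g (between complements of g and g+1)
    ins <- vapply(seq_len(len), function(z)
      anchored_base(mb, (g - 1):(g + 2)), character(1))
    at <- M - g
    append(site, ins, after = at)
  }
  delete_opposite <- function(site, pos) { # miRNA-side bulge at positions pos
    site[-vapply(pos, site_index, integer(1), M = M)]
  }

  # mismatch positions outside the middle and outside the 5'-proximal
  # doubled region (cost 1 each keeps the intended alignment optimal)
  mm_pool <- function(n, spaced = TRUE) {
    pool <- c(3:7, seq(14L, M - 1L))
    if (!spaced) return(sort(resample(pool, size = n)))
    picked <- integer(0)
    while (length(picked) < n && length(pool)) {
      p <- resample(pool)
      picked <- c(picked, p)
      pool <- setdiff(pool, (p - 1L):(p + 1L))
    }
    sort(picked)
  }

  if (decoy_kind == "none") {
    site <- apply_mm(site, mm_at)
    site <- insert_bulge(site, gap_after, bulge_len)
  } else if (decoy_kind == "bulge_side") {
    site <- delete_opposite(site, c(10L, 11L))
  } else if (decoy_kind == "bulge_position") {
    site <- insert_bulge(site, sample(5:6, 1), bulge_len)
  } else if (decoy_kind == "middle_mismatch") {
    # keep two paired anchors between the mismatch and the bulge
    v <- resample(list(c(gp = 9L, mm = 12L), c(gp = 11L, mm = 9L)))[[1]]
    site <- apply_mm(site, v[["mm"]])
    site <- insert_bulge(site, v[["gp"]], bulge_len)
  } else if (decoy_kind == "mismatch_count") {
    site <- apply_mm(site, mm_pool(5L))
    site <- insert_bulge(site, gap_after, bulge_len)
  } else if (decoy_kind == "consecutive_mismatches") {
    # run sits in the 5'-proximal doubled region, flanked by paired anchors:
    # a 3'-terminal run would let the aligner slide into a different geometry
    p <- resample(4:5)
    site <- apply_mm(site, p:(p + 2L))
    site <- insert_bulge(site, gap_after, bulge_len)
  } else stopf("unknown decoy kind '%s'", decoy_kind)
  paste(site, collapse = "")
}

# replace genome bases at a 0-based half-open interval
edit_genome <- function(genome, chrom, start0, end0, replacement) {
  s <- genome[[chrom]]
  if (nchar(replacement) != end0 - start0) stopf("replacement length mismatch")
  substr(s, start0 + 1L, end0) <- replacement
  genome[[chrom]] <- s
  genome
}

# write a site (transcript-oriented, RNA alphabet) into a host transcript at
# tx coords [a, a+len-1]; returns the edited annotation
write_site_into_tx <- function(ann, tid, a, site_rna) {
  len <- nchar(site_rna)
  g <- tx_to_genomic(ann, tid, a, a + len - 1L)
  tr <- ann$transcripts[ann$transcripts$transcript_id == tid, ]
  seg <- to_dna(if (tr$strand == "+") site_rna else revcomp(site_rna))
  ann$genome <- edit_genome(ann$genome, tr$chrom, g$start, g$end, seg)
  ann
}

#' Plant miRNA target or mimic sites with ground truth
#'
#' Writes constructed duplex sites into host transcript exons (one site per
#' host).  In `target` mode, true sites are near-perfect complements (Allen
#' score at most the number of planted 3' mismatches, 0-1) and decoys carry
#' mismatches across the 5'-proximal doubled region so the Allen cutoff
#' fails; in `mimic` mode, true sites satisfy all eTM rules and each decoy
#' violates exactly one named rule.
#'
#' @param ann a [tx_annotation()] carrying the genome.
#' @param mirnas named character vector of miRNA sequences (RNA).
#' @param mode "target" or "mimic".
#' @param n_true,n_decoy numbers of passing and decoy sites.
#' @param hosts character vector of eligible host transcript ids (each used
#'   at most once).
#' @param seed integer seed.
#' @return list with the edited `ann` and `truth` (one row per site: mode,
#'   mirna_id, transcript_id, site_start/site_end in 1-based transcript
#'   coordinates, intended "pass"/"fail", rule, bulge geometry).
#' @export
plant_duplex_sites <- function(ann, mirnas, mode = c("target", "mimic"),
                               n_true, n_decoy, hosts, seed) {
  mode <- match.arg(mode)
  set.seed(stage_seed(seed, if (mode == "target") 3L else 4L))
  n_total <- n_true + n_decoy
  if (length(hosts) < n_total)
    stopf("%d hosts needed for %d sites, only %d available", n_total, n_total,
          length(hosts))
  hosts <- hosts[seq_len(n_total)]
  decoy_kinds_mimic <- c("bulge_side", "bulge_position", "middle_mismatch",
                         "mismatch_count", "consecutive_mismatches")
  truth <- list()
  for (s in seq_len(n_total)) {
    mid <- names(mirnas)[(s - 1L) %% length(mirnas) + 1L]
    mseq <- mirnas[[mid]]
    tid <- hosts[s]
    is_true <- s <= n_true
    rule <- if (mode == "target") {
      if (is_true) "none" else "allen"
    } else {
      if (is_true) "none" else
        decoy_kinds_mimic[(s - n_true - 1L) %% 5L + 1L]
    }
    # slot in the largest exon of the host
    e <- tx_exons(ann, tid)
    tr <- ann$transcripts[ann$transcripts$transcript_id == tid, ]
    widths <- e$end - e$start
    if (tr$strand == "-") widths <- rev(widths)
    cum <- cumsum(widths); off <- c(0L, cum[-length(cum)])
    k <- which.max(widths)

    # rejection-sample a construction until the duplex module realises the
    # intended label: the dynamic program is the arbiter (ties between a
    # bulge and a same-cost mismatch path can defeat a naive construction)
    done <- FALSE
    for (try in 1:60) {
      bl <- sample(1:3, 1); gp <- sample(9:11, 1)
      if (mode == "target") {
        site <- if (is_true) make_target_site(mseq, sample(0:1, 1))$seq
        else make_target_decoy(mseq)
        bl <- NA_integer_; gp <- NA_integer_
      } else {
        if (is_true) {
          mm <- if (runif(1) < 0.5 && nchar(mseq) >= 19)
            sort(sample(seq(14L, nchar(mseq) - 1L), sample(1:2, 1))) else integer(0)
          site <- make_mimic_site(mseq, bulge_len = bl, gap_after = gp,
                                  mm_at = mm)
        } else {
          site <- make_mimic_site(mseq, bulge_len = bl, gap_after = gp,
                                  decoy_kind = rule)
        }
      }
      len <- nchar(site)
      if (widths[k] < len + 12)
        stopf("host %s has no exon large enough for a %d nt site", tid, len)
      a <- off[k] + 7L
      cand_ann <- write_site_into_tx(ann, tid, a, site)
      txseq <- to_rna(extract_tx_seq(cand_ann, tid)[[1]])

      if (mode == "target") {
        hits <- predict_targets(setNames(mseq, mid), setNames(txseq, tid))
        ok <- if (is_true) nrow(hits) == 1 else nrow(hits) == 0
      } else {
        aln <- align_duplex(mseq, substr(txseq, a, a + len - 1L), mid, tid)
        call <- etm_check(aln)
        site_ok <- if (is_true) call$verdict == "pass" else
          (call$verdict == "fail" && call$fail_reason == rule)
        # judge the scan at the planted interval only: short windows over a
        # random lncRNA can legitimately contain background mimic sites
        scan <- scan_mimics(setNames(mseq, mid), setNames(txseq, tid))
        ov <- scan[scan$site_end >= a & scan$site_start <= a + len - 1L, ,
                   drop = FALSE]
        ok <- site_ok && (if (is_true) nrow(ov) >= 1 else nrow(ov) == 0)
      }
      if (ok) { ann <- cand_ann; done <- TRUE; break }
    }
    if (!done)
      stopf("could not construct a %s '%s' site for %s in %s after 60 draws",
            mode, rule, mid, tid)
    truth[[s]] <- data.frame(
      mode = mode, mirna_id = mid, transcript_id = tid,
      site_start = a, site_end = a + len - 1L,
      intended = if (is_true) "pass" else "fail", rule = rule,
      bulge_length = bl, bulge_position = gp, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(ann = ann, truth = truth)
}
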