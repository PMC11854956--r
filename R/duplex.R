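# miRNA-target duplex scoring.
#
# A duplex alignment is found by a dynamic program (C++ core) minimising the
# Allen complementarity penalty; its free energy is then evaluated with a
# fixed nearest-neighbor stack model.  Both scoring schemes are part of this
# package's documented contract:
#
#   Allen penalty: WC pair 0, G:U wobble 0.5, mismatch 1, each bulged
#   nucleotide 1; penalties are doubled when the miRNA position involved
#   (or, for site-side bulges, both flanking miRNA positions) lies in
#   positions 2-13 from the miRNA 5' end.
#
#   Energy model: stack free energies for adjacent paired positions from the
#   16-entry Watson-Crick table below (kcal/mol, keyed by the miRNA-strand
#   dinucleotide), +1.0 kcal/mol per G:U pair in a stack (capped so a stack
#   is never destabilising), +3.0 kcal/mol per internal loop/bulge event.

# Watson-Crick nearest-neighbor stack free energies (kcal/mol, 37 C),
# rows = 5' miRNA base of the stack, cols = 3' miRNA base.  Version 1;
# fixed constants, not tunable.
STACK_WC <- matrix(
  c(-0.93, -2.24, -2.08, -1.10,
    -2.11, -3.26, -2.36, -2.08,
    -2.35, -3.42, -3.26, -2.24,
    -1.33, -2.35, -2.11, -0.93),
  nrow = 4, byrow = TRUE,
  dimnames = list(c("A", "C", "G", "U"), c("A", "C", "G", "U")))

GU_STACK_PENALTY <- 1.0   # kcal/mol per wobble pair in a stack
STACK_CAP <- -0.1         # a stack never destabilises beyond this
LOOP_PENALTY <- 3.0       # kcal/mol per internal loop/bulge event

stack_energy <- function(b1, b2, wobble1, wobble2) {
  e <- STACK_WC[b1, b2] + GU_STACK_PENALTY * (wobble1 + wobble2)
  pmin(e, STACK_CAP)
}

#' Align a miRNA against a candidate binding site
#'
#' Finds the duplex alignment minimising the Allen penalty (semi-global: the
#' whole miRNA is consumed, site overhangs are free; ties broken toward fewer
#' bulges, then the 5'-most site placement).  Position states, Allen score
#' and the nearest-neighbor duplex energies are returned.
#'
#' @param mirna miRNA sequence 5'->3' (18-25 nt typical; ACGU or ACGT).
#' @param site candidate site sequence 5'->3'.
#' @param mirna_id,target_id optional identifiers carried into the result.
#' @return an object of class `duplex_alignment`: list with `states`
#'   (data.frame op/mirna_pos/site_pos/mirna_base/site_base), `allen_score`,
#'   `mfe`, `mfe_perfect`, `mfe_ratio`, `site_start`, `site_end` (1-based,
#'   inclusive, on the site as given).
#' @export
align_duplex <- function(mirna, site, mirna_id = NA_character_,
                         target_id = NA_character_) {
  mirna <- toupper(to_rna(mirna)); site <- toupper(to_rna(site))
  m <- nchar(mirna); s <- nchar(site)
  if (m < 1) stopf("empty miRNA")
  if (s < m - 3) stopf("site (%d nt) shorter than miRNA - 3 (%d nt): unalignable", s, m - 3)
  sc <- .scan_duplex_cpp(mirna, site, s, 1L)
  build_alignment(mirna, site, sc, 1L, mirna_id, target_id)
}

# Assemble a duplex_alignment from one row of a C++ scan result.
build_alignment <- function(mirna, seq, scan, row, mirna_id, target_id) {
  ops <- strsplit(scan$ops[row], "", fixed = TRUE)[[1]]
  site_start <- scan$site_start[row]
  site_end <- scan$site_end[row]
  mb <- strsplit(mirna, "", fixed = TRUE)[[1]]
  sb <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ops)
  mirna_pos <- integer(n); site_pos <- integer(n)
  mi <- 0L; sp <- if (is.na(site_end)) NA_integer_ else site_end
  for (j in seq_len(n)) {
    if (ops[j] %in% c("=", "o", "x")) {
      mi <- mi + 1L; mirna_pos[j] <- mi; site_pos[j] <- sp; sp <- sp - 1L
    } else if (ops[j] == "m") {
      mi <- mi + 1L; mirna_pos[j] <- mi; site_pos[j] <- NA_integer_
    } else { # 't': site-side bulge
      mirna_pos[j] <- NA_integer_; site_pos[j] <- sp; sp <- sp - 1L
    }
  }
  state_names <- c("=" = "WC_pair", "o" = "GU_wobble", "x" = "mismatch",
                   "m" = "bulge_mirna", "t" = "bulge_target")
  states <- data.frame(
    op = ops,
    state = unname(state_names[ops]),
    mirna_pos = mirna_pos,
    site_pos = site_pos,
    mirna_base = ifelse(is.na(mirna_pos), NA_character_, mb[pmax(mirna_pos, 1L)]),
    site_base = ifelse(is.na(site_pos), NA_character_, sb[pmax(site_pos, 1L)]),
    stringsAsFactors = FALSE)
  allen <- allen_score(states)
  en <- duplex_mfe(states, mirna)
  structure(list(mirna_id = mirna_id, target_id = target_id,
                 mirna = mirna, site = seq,
                 site_start = site_start, site_end = site_end,
                 states = states, allen_score = allen,
                 n_bulges = scan$bulges[row],
                 mfe = en$mfe, mfe_perfect = en$mfe_perfect,
                 mfe_ratio = en$mfe_ratio),
            class = "duplex_alignment")
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat(sprintf("duplex_alignment: %s vs %s [site %d-%d]\n",
              x$mirna_id, x$target_id, x$site_start, x$site_end))
  cat(sprintf("  allen = %.1f  mfe = %.2f  mfe_ratio = %.3f\n",
              x$allen_score, x$mfe, x$mfe_ratio))
  cat("  ops: ", paste(x$states$op, collapse = ""), "\n")
  invisible(x)
}

#' Allen complementarity score of a duplex state list
#'
#' @param states data.frame as produced by [align_duplex()] (columns `op`
#'   and `mirna_pos`).
#' @return non-negative half-integer penalty.
#' @export
allen_score <- function(states) {
  op <- states$op
  mpos <- states$mirna_pos
  # preceding miRNA position for site-side bulges
  prev <- mpos
  for (j in seq_along(prev)) if (is.na(prev[j])) prev[j] <- if (j > 1) prev[j - 1] else 0L
  mult <- ifelse(mpos >= 2 & mpos <= 13, 2, 1)
  mult_b <- ifelse(prev >= 2 & prev <= 12, 2, 1)
  cost <- numeric(length(op))
  cost[op == "o"] <- 0.5 * mult[op == "o"]
  cost[op == "x"] <- 1 * mult[op == "x"]
  cost[op == "m"] <- 1 * mult[op == "m"]
  cost[op == "t"] <- 1 * mult_b[op == "t"]
  sum(cost)
}

#' Nearest-neighbor duplex free energy and MFE ratio
#'
#' Sums stack energies over consecutive paired positions and adds a fixed
#' penalty per internal loop/bulge event; the MFE ratio divides by the same
#' model evaluated on the fully Watson-Crick-paired miRNA, clamped to
#' the unit interval.
#'
#' @param states duplex state data.frame (see [align_duplex()]).
#' @param mirna the miRNA sequence (ACGU).
#' @return list with `mfe`, `mfe_perfect`, `mfe_ratio`.
#' @export
duplex_mfe <- function(states, mirna) {
  mirna <- toupper(to_rna(mirna))
  mb <- strsplit(mirna, "", fixed = TRUE)[[1]]
  mfe_perfect <- 0
  if (length(mb) > 1) {
    for (i in seq_len(length(mb) - 1)) {
      mfe_perfect <- mfe_perfect + stack_energy(mb[i], mb[i + 1], 0, 0)
    }
  }
  paired <- states$op %in% c("=", "o")
  if (!any(paired)) {
    return(list(mfe = 0, mfe_perfect = mfe_perfect, mfe_ratio = 0))
  }
  mfe <- 0
  idx <- which(paired)
  first <- idx[1]; last <- idx[length(idx)]
  # stacks: adjacent columns both paired
  for (j in seq_len(nrow(states) - 1)) {
    if (paired[j] && paired[j + 1]) {
      mfe <- mfe + stack_energy(states$mirna_base[j], states$mirna_base[j + 1],
                                as.integer(states$op[j] == "o"),
                                as.integer(states$op[j + 1] == "o"))
    }
  }
  # internal loop/bulge events: maximal unpaired runs between paired columns
  if (last > first + 1) {
    inner <- paired[first:last]
    r <- rle(inner)
    mfe <- mfe + LOOP_PENALTY * sum(!r$values)
  }
  mfe <- min(mfe, 0)
  ratio <- if (mfe_perfect < 0) mfe / mfe_perfect else 0
  list(mfe = mfe, mfe_perfect = mfe_perfect,
       mfe_ratio = min(max(ratio, 0), 1))
}

#' Predict miRNA targets across a transcript set
#'
#' Scans every window (miRNA length + 3, step 1) of each transcript, keeps
#' the best site per (miRNA, transcript) pair (lowest Allen score, ties by
#' lowest MFE then 5'-most), and reports pairs whose best site satisfies
#' `allen_score <= allen_max` and `mfe_ratio > mfe_ratio_min`.
#'
#' @param mirnas named character vector of miRNA sequences (names = ids).
#' @param transcripts named character vector of transcript sequences.
#' @param allen_max Allen score cutoff (default 7).
#' @param mfe_ratio_min MFE ratio cutoff, strict > (default 0.65).
#' @param all_sites report every qualifying site instead of only the best
#'   one per pair.
#' @param window_extra window length minus miRNA length (default 3).
#' @return data.frame mirna_id, target_id, site_start, site_end,
#'   allen_score, mfe, mfe_ratio, pairing (op string, miRNA 5'->3').
#'   Transcripts too short to scan are recorded in attribute `skipped`.
#' @export
predict_targets <- function(mirnas, transcripts, allen_max = 7,
                            mfe_ratio_min = 0.65, all_sites = FALSE,
                            window_extra = 3) {
  mirnas <- toupper(to_rna(unlist(mirnas)))
  transcripts <- toupper(to_rna(unlist(transcripts)))
  if (is.null(names(mirnas)) || is.null(names(transcripts)))
    stopf("mirnas and transcripts must be named")
  rows <- list(); skipped <- character(0)
  for (mid in names(mirnas)) {
    mseq <- mirnas[[mid]]
    M <- nchar(mseq)
    for (tid in names(transcripts)) {
      tseq <- transcripts[[tid]]
      if (nchar(tseq) < M - 3) { skipped <- c(skipped, tid); next }
      win <- min(M + window_extra, nchar(tseq))
      sc <- .scan_duplex_cpp(mseq, tseq, win, 1L)
      hits <- best_sites(mseq, tseq, sc, mid, tid, allen_max, mfe_ratio_min,
                         all_sites)
      if (length(hits)) rows <- c(rows, hits)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna_id = character(0), target_id = character(0),
               site_start = integer(0), site_end = integer(0),
               allen_score = numeric(0), mfe = numeric(0),
               mfe_ratio = numeric(0), pairing = character(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- unique(skipped)
  out
}

# Pick qualifying site(s) from a scan: evaluate MFE only for windows whose
# Allen score can still pass the cutoff.
best_sites <- function(mseq, tseq, sc, mid, tid, allen_max, mfe_ratio_min,
                       all_sites) {
  allen2 <- sc$allen2
  amin <- min(allen2)
  if (amin > 2 * allen_max) return(list())
  cand <- if (all_sites) which(allen2 <= 2 * allen_max) else
    which(allen2 == amin)
  # dedupe windows that found the same site
  cand <- cand[!duplicated(sc$site_start[cand])]
  alns <- lapply(cand, function(i) build_alignment(mseq, tseq, sc, i, mid, tid))
  keep <- vapply(alns, function(a)
    a$allen_score <= allen_max && a$mfe_ratio > mfe_ratio_min, logical(1))
  alns <- alns[keep]
  if (!length(alns)) return(list())
  if (!all_sites) {
    o <- order(vapply(alns, `[[`, numeric(1), "allen_score"),
               vapply(alns, `[[`, numeric(1), "mfe"),
               vapply(alns, `[[`, integer(1), "site_start"))
    alns <- alns[o[1]]
  } else {
    o <- order(vapply(alns, `[[`, integer(1), "site_start"))
    alns <- alns[o]
  }
  lapply(alns, function(a)
    data.frame(mirna_id = mid, target_id = tid,
               site_start = a$site_start, site_end = a$site_end,
               allen_score = a$allen_score, mfe = a$mfe,
               mfe_ratio = a$mfe_ratio,
               pairing = paste(a$states$op, collapse = ""),
               stringsAsFactors = FALSE))
}
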