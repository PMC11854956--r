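# Endogenous target mimic (miRNA sponge) detection.
#
# A passing mimic site must show (rule order = reporting order of the first
# violation):
#   1. exactly one bulge, on the ncRNA side, 1-5 nt long, located between
#      two miRNA positions that both lie in the "middle" set (default 9-12)
#      -> violations: bulge_side (miRNA-side bulge, or no bulge at all),
#         bulge_position (wrong place, wrong size or multiple bulges)
#   2. no mismatch at any middle position        -> middle_mismatch
#   3. at most 4 mismatches outside the middle   -> mismatch_count
#   4. no run of >= 3 consecutive mismatches     -> consecutive_mismatches
# G:U wobbles count as pairs, not mismatches; mismatch runs are counted
# over miRNA positions and bulges do not interrupt a run.

#' Endogenous-target-mimic check of a duplex alignment
#'
#' @param alignment a [align_duplex()] result for a miRNA vs an ncRNA site.
#' @param middle miRNA positions forming the central region (default 9:12).
#' @param max_mismatches_outside maximum mismatches outside the middle
#'   (default 4).
#' @param max_consecutive maximum run of consecutive mismatches (default 2).
#' @param bulge_range allowed ncRNA bulge length (default 1 to 5 nt).
#' @return object of class `mimic_call`: list with mirna_id, ncrna_id,
#'   site_start, site_end, bulge_position (miRNA position preceding the
#'   bulge, NA if none), bulge_length, n_mismatches_outside_middle,
#'   max_consecutive_mismatches, verdict ("pass"/"fail"), fail_reason.
#' @export
etm_check <- function(alignment, middle = 9:12, max_mismatches_outside = 4,
                      max_consecutive = 2, bulge_range = c(1, 5)) {
  st <- alignment$states
  op <- st$op

  # ncRNA-side bulge events: maximal runs of 't'
  r <- rle(op == "t")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  t_events <- which(r$values)
  n_t_events <- length(t_events)
  bulge_len <- NA_integer_; bulge_pos <- NA_integer_
  if (n_t_events >= 1) {
    ev <- t_events[1]
    bulge_len <- r$lengths[ev]
    before <- st$mirna_pos[seq_len(starts[ev] - 1L)]
    bulge_pos <- if (any(!is.na(before))) max(before, na.rm = TRUE) else 0L
  }
  has_mirna_bulge <- any(op == "m")

  # mismatch statistics over miRNA positions (bulges do not break runs)
  mm_pos <- st$mirna_pos[op == "x"]
  n_outside <- sum(!(mm_pos %in% middle))
  by_pos <- op[op %in% c("=", "o", "x", "m")]  # one entry per miRNA position
  rr <- rle(by_pos == "x")
  max_run <- if (any(rr$values)) max(rr$lengths[rr$values]) else 0L

  reason <- "none"
  if (has_mirna_bulge || n_t_events == 0) {
    reason <- "bulge_side"
  } else if (n_t_events > 1 ||
             bulge_len < bulge_range[1] || bulge_len > bulge_range[2] ||
             !(bulge_pos %in% middle) || !((bulge_pos + 1L) %in% middle)) {
    reason <- "bulge_position"
  } else if (any(mm_pos %in% middle)) {
    reason <- "middle_mismatch"
  } else if (n_outside > max_mismatches_outside) {
    reason <- "mismatch_count"
  } else if (max_run > max_consecutive) {
    reason <- "consecutive_mismatches"
  }

  structure(list(
    mirna_id = alignment$mirna_id, ncrna_id = alignment$target_id,
    site_start = alignment$site_start, site_end = alignment$site_end,
    bulge_position = bulge_pos, bulge_length = bulge_len,
    n_mismatches_outside_middle = n_outside,
    max_consecutive_mismatches = max_run,
    verdict = if (reason == "none") "pass" else "fail",
    fail_reason = reason), class = "mimic_call")
}

#' @export
print.mimic_call <- function(x, ...) {
  cat(sprintf("mimic_call %s vs %s [%s-%s]: %s%s\n", x$mirna_id, x$ncrna_id,
              x$site_start, x$site_end, x$verdict,
              if (x$verdict == "fail") paste0(" (", x$fail_reason, ")") else ""))
  invisible(x)
}

mimic_call_row <- function(call) {
  data.frame(mirna_id = call$mirna_id, ncrna_id = call$ncrna_id,
             site_start = call$site_start, site_end = call$site_end,
             bulge_position = call$bulge_position,
             bulge_length = call$bulge_length,
             n_mismatches_outside_middle = call$n_mismatches_outside_middle,
             max_consecutive_mismatches = call$max_consecutive_mismatches,
             verdict = call$verdict, fail_reason = call$fail_reason,
             stringsAsFactors = FALSE)
}

#' Scan ncRNAs for endogenous target mimic sites
#'
#' Slides a window (miRNA length + maximum bulge length, step 1) over each
#' ncRNA, aligns each window with [align_duplex()]'s bulge-permissive
#' dynamic program, and reports every (miRNA, ncRNA) pair with at least one
#' site passing [etm_check()].  circRNA sequences should be supplied as the
#' back-splice-joined sequence so junction-crossing sites are discoverable.
#'
#' @param mirnas named character vector of miRNA sequences.
#' @param ncrnas named character vector of ncRNA (lncRNA/circRNA) sequences.
#' @inheritParams etm_check
#' @return data.frame of passing sites (one row per site, deterministic
#'   order by mirna_id, ncrna_id, site_start) with the mimic statistics;
#'   attribute `summary` carries pair/site counts.
#' @export
scan_mimics <- function(mirnas, ncrnas, middle = 9:12,
                        max_mismatches_outside = 4, max_consecutive = 2,
                        bulge_range = c(1, 5)) {
  mirnas <- toupper(to_rna(unlist(mirnas)))
  ncrnas <- toupper(to_rna(unlist(ncrnas)))
  rows <- list()
  n_pairs <- 0L
  for (mid in sort(names(mirnas))) {
    mseq <- mirnas[[mid]]
    M <- nchar(mseq)
    win <- M + bulge_range[2]
    for (nid in sort(names(ncrnas))) {
      nseq <- ncrnas[[nid]]
      if (nchar(nseq) < M - 3) next
      n_pairs <- n_pairs + 1L
      w <- min(win, nchar(nseq))
      sc <- .scan_duplex_cpp(mseq, nseq, w, 1L)
      # rule 1 prefilter: a passing site needs a site-side bulge and no
      # miRNA-side bulge in its optimal alignment
      cand <- which(grepl("t", sc$ops, fixed = TRUE) &
                      !grepl("m", sc$ops, fixed = TRUE))
      if (!length(cand)) next
      seen <- character(0)
      for (i in cand) {
        skey <- paste(sc$site_start[i], sc$site_end[i], sc$ops[i])
        if (skey %in% seen) next
        seen <- c(seen, skey)
        aln <- build_alignment(mseq, nseq, sc, i, mid, nid)
        call <- etm_check(aln, middle = middle,
                          max_mismatches_outside = max_mismatches_outside,
                          max_consecutive = max_consecutive,
                          bulge_range = bulge_range)
        if (call$verdict == "pass")
          rows[[length(rows) + 1L]] <- mimic_call_row(call)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna_id = character(0), ncrna_id = character(0),
               site_start = integer(0), site_end = integer(0),
               bulge_position = integer(0), bulge_length = integer(0),
               n_mismatches_outside_middle = integer(0),
               max_consecutive_mismatches = integer(0),
               verdict = character(0), fail_reason = character(0),
               stringsAsFactors = FALSE)
  if (nrow(out)) {
    out <- out[order(out$mirna_id, out$ncrna_id, out$site_start), , drop = FALSE]
    out <- out[!duplicated(out[c("mirna_id", "ncrna_id", "site_start", "site_end")]), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "summary") <- list(
    n_pairs_scanned = n_pairs,
    n_pairs_passing = nrow(unique(out[c("mirna_id", "ncrna_id")])),
    n_sites = nrow(out))
  out
}
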