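# Independent oracles used across the suite.  These deliberately re-derive
# the package's scoring conventions from scratch (different code paths,
# frozen copies of contract constants) so agreement is informative.

# ---- duplex alignment oracle -------------------------------------------

o_mult <- function(i) if (i >= 2 && i <= 13) 2L else 1L
o_multb <- function(i) if (i >= 2 && i <= 12) 2L else 1L  # flank before bulge

o_pair_class <- function(a, b) {
  if ((a == "A" && b == "U") || (a == "U" && b == "A") ||
      (a == "G" && b == "C") || (a == "C" && b == "G")) return(2L)
  if ((a == "G" && b == "U") || (a == "U" && b == "G")) return(1L)
  0L
}

# Minimal (allen2, bulges) over all semi-global alignments, by top-down
# memoised recursion on (miRNA suffix, site prefix remaining).  miRNA
# position i pairs site position j with j decreasing as i increases; site
# overhangs at both ends are free.  Tuples are encoded allen2 * 1000 +
# bulges (bulges < 1000 always holds here).
oracle_align2 <- function(mirna, site) {
  mb <- strsplit(mirna, "")[[1]]; sb <- strsplit(site, "")[[1]]
  M <- length(mb); S <- length(sb)
  memo <- array(NA_real_, dim = c(M + 2L, S + 1L))
  h <- function(i, j) {
    if (i == M + 1L) return(0)           # trailing site overhang free
    if (!is.na(memo[i, j + 1L])) return(memo[i, j + 1L])
    best <- Inf
    if (j >= 1L) {
      pc <- o_pair_class(mb[i], sb[j])
      cd <- if (pc == 2L) 0 else if (pc == 1L) o_mult(i) else 2L * o_mult(i)
      best <- min(best, cd * 1000 + h(i + 1L, j - 1L))
    }
    best <- min(best, (2L * o_mult(i)) * 1000 + 1 + h(i + 1L, j))
    if (j >= 1L && i >= 2L)
      best <- min(best, (2L * o_multb(i - 1L)) * 1000 + 1 + h(i, j - 1L))
    memo[i, j + 1L] <<- best
    best
  }
  best <- min(vapply(seq(0, S), function(j0) h(1L, j0), numeric(1)))
  list(allen2 = floor(best / 1000), bulges = best %% 1000)
}

# True exhaustive enumeration over every alignment path (tiny inputs only):
# returns the minimum allen2.
enum_align_allen2 <- function(mirna, site) {
  mb <- strsplit(mirna, "")[[1]]; sb <- strsplit(site, "")[[1]]
  M <- length(mb); S <- length(sb)
  best <- Inf
  rec <- function(i, j, acc) {
    if (acc >= best) return(invisible())
    if (i > M) { best <<- min(best, acc); return(invisible()) }
    if (j >= 1L) {
      pc <- o_pair_class(mb[i], sb[j])
      cd <- if (pc == 2L) 0 else if (pc == 1L) o_mult(i) else 2L * o_mult(i)
      rec(i + 1L, j - 1L, acc + cd)
      if (i >= 2L) rec(i, j - 1L, acc + 2L * o_multb(i - 1L))
    }
    rec(i + 1L, j, acc + 2L * o_mult(i))
  }
  for (j0 in seq(0, S)) rec(1L, j0, 0)
  best
}

# per-position Allen summation over a state table (independent of
# saltnet::allen_score)
oracle_allen_states <- function(states) {
  total <- 0
  prev_mir <- 0L
  for (r in seq_len(nrow(states))) {
    op <- states$op[r]
    if (op %in% c("=", "o", "x", "m")) {
      i <- states$mirna_pos[r]
      if (op == "o") total <- total + 0.5 * o_mult(i)
      if (op == "x") total <- total + 1 * o_mult(i)
      if (op == "m") total <- total + 1 * o_mult(i)
      prev_mir <- i
    } else {
      total <- total + 1 * o_multb(prev_mir)
    }
  }
  total
}

# ---- nearest-neighbor energy oracle ------------------------------------
# Frozen copy of the contract constants; a stack-walk over the state table.
O_STACK <- matrix(
  c(-0.93, -2.24, -2.08, -1.10,
    -2.11, -3.26, -2.36, -2.08,
    -2.35, -3.42, -3.26, -2.24,
    -1.33, -2.35, -2.11, -0.93),
  nrow = 4, byrow = TRUE,
  dimnames = list(c("A", "C", "G", "U"), c("A", "C", "G", "U")))

oracle_mfe <- function(states, mirna) {
  mb <- strsplit(toupper(chartr("Tt", "Uu", mirna)), "")[[1]]
  perfect <- 0
  if (length(mb) > 1)
    for (i in seq_len(length(mb) - 1))
      perfect <- perfect + min(O_STACK[mb[i], mb[i + 1]], -0.1)
  paired <- states$op %in% c("=", "o")
  if (!any(paired)) return(list(mfe = 0, mfe_perfect = perfect, mfe_ratio = 0))
  e <- 0
  for (r in seq_len(nrow(states) - 1)) {
    if (paired[r] && paired[r + 1]) {
      s <- O_STACK[states$mirna_base[r], states$mirna_base[r + 1]] +
        1.0 * ((states$op[r] == "o") + (states$op[r + 1] == "o"))
      e <- e + min(s, -0.1)
    }
  }
  idx <- which(paired)
  span <- paired[idx[1]:idx[length(idx)]]
  runs <- rle(span)
  e <- e + 3.0 * sum(!runs$values)
  e <- min(e, 0)
  ratio <- if (perfect < 0) min(max(e / perfect, 0), 1) else 0
  list(mfe = e, mfe_perfect = perfect, mfe_ratio = ratio)
}

# ---- BH step-up oracle --------------------------------------------------
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    r <- which(o == i)  # rank of p[i]
    q[i] <- min(1, min(p[o][r:n] * n / (r:n)))
  }
  q
}

# ---- longest ORF oracle (all-substrings scan) ---------------------------
oracle_orf <- function(s) {
  s <- toupper(chartr("Uu", "Tt", s))
  n <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  for (i in seq_len(max(0, n - 5))) {
    if (substr(s, i, i + 2) != "ATG") next
    for (j in seq(i + 5, n, by = 3)) {
      cod <- substr(s, j - 2, j)
      if (cod %in% stops) { best <- max(best, j - i + 1L); break }
    }
  }
  best
}

# ---- per-base lncRNA positional class oracle ----------------------------
# Works on the same transcript/exon tables as the package but via explicit
# base sets.
oracle_lnc_class <- function(lnc_tx, lnc_ex, cod_tx, cod_ex, window = 1000) {
  bases <- function(st, en) if (en > st) seq(st, en - 1L) else integer(0)
  lnc_bases <- unlist(Map(bases, lnc_ex$start, lnc_ex$end))
  # x / o: exon-exon overlap by strand
  hit_x <- FALSE; hit_o <- FALSE
  for (t in unique(cod_tx$transcript_id)) {
    tr <- cod_tx[cod_tx$transcript_id == t, ]
    if (tr$chrom != lnc_tx$chrom) next
    e <- cod_ex[cod_ex$transcript_id == t, ]
    eb <- unlist(Map(bases, e$start, e$end))
    if (length(intersect(lnc_bases, eb))) {
      if (tr$strand == lnc_tx$strand) hit_o <- TRUE else hit_x <- TRUE
    }
  }
  if (hit_x) return("x")
  if (hit_o) return("o")
  # i: whole span inside one intron, same strand
  for (t in unique(cod_tx$transcript_id)) {
    tr <- cod_tx[cod_tx$transcript_id == t, ]
    if (tr$chrom != lnc_tx$chrom || tr$strand != lnc_tx$strand) next
    e <- cod_ex[cod_ex$transcript_id == t, ]
    e <- e[order(e$start), ]
    if (nrow(e) < 2) next
    for (w in seq_len(nrow(e) - 1)) {
      if (lnc_tx$start >= e$end[w] && lnc_tx$end <= e$start[w + 1]) return("i")
    }
  }
  # j: 5' ends within window, opposite strand
  l5 <- if (lnc_tx$strand == "+") lnc_tx$start else lnc_tx$end
  for (t in unique(cod_tx$transcript_id)) {
    tr <- cod_tx[cod_tx$transcript_id == t, ]
    if (tr$chrom != lnc_tx$chrom || tr$strand == lnc_tx$strand) next
    c5 <- if (tr$strand == "+") tr$start else tr$end
    if (abs(c5 - l5) <= window) return("j")
  }
  "u"
}

# ---- circRNA type oracle ------------------------------------------------
oracle_circ_type <- function(junction, tx, ex, tol = 2) {
  tids <- sort(unique(tx$transcript_id))
  for (t in tids) {
    tr <- tx[tx$transcript_id == t, ]
    if (tr$chrom != junction$chrom || tr$strand != junction$strand) next
    e <- ex[ex$transcript_id == t, ]
    ok_a <- any(abs(e$start - junction$acceptor) <= tol)
    ok_d <- any(abs(e$end - junction$donor) <= tol)
    if (ok_a && ok_d) {
      nex <- sum(e$start >= junction$acceptor - tol &
                   e$end <= junction$donor + tol)
      return(list(type = "exonic", n_exons = nex))
    }
  }
  for (t in tids) {
    tr <- tx[tx$transcript_id == t, ]
    if (tr$chrom != junction$chrom || tr$strand != junction$strand) next
    e <- ex[ex$transcript_id == t, ]
    e <- e[order(e$start), ]
    if (nrow(e) < 2) next
    for (w in seq_len(nrow(e) - 1)) {
      if (junction$acceptor >= e$end[w] && junction$donor <= e$start[w + 1])
        return(list(type = "ciRNA", n_exons = 1L))
    }
  }
  list(type = "intergenic", n_exons = 1L)
}

# random RNA sequence
rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = "")
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
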