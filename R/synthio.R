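# Synthetic fixture generation with known ground truth.
#
# The generator emulates a two-condition (control vs salt), three-replicate
# whole-transcriptome design on one synthetic chromosome: multi-exon mRNAs
# (mostly > 1000 nt), short 1-2 exon lncRNA candidates (mostly < 600 nt),
# 18-25 nt miRNAs, NB-distributed counts with planted log2 fold changes,
# planted miRNA target and mimic sites, and planted back-splice junctions.
# Everything is deterministic under the scenario seed and re-derivable from
# the emitted files.

#' Define a synthetic scenario
#'
#' Holds every knob of the generator; the defaults are the package's
#' reference study conditions (3 vs 3 replicates, NB dispersion 0.1,
#' planted |log2FC| = 2).
#'
#' @param seed integer master seed; all stages derive their streams from it.
#' @param n_genes number of protein-coding genes.
#' @param n_lncrna number of well-formed lncRNA candidates.
#' @param n_mirna number of miRNAs (lengths drawn from 18-25 nt).
#' @param n_circ number of detectable planted back-splice junctions.
#' @param n_samples_per_group replicates per condition (default 3).
#' @param dispersion NB dispersion phi (variance = mu + phi mu^2).
#' @param de_fraction fraction of features per class with a planted fold
#'   change.
#' @param planted_log2fc absolute planted log2 fold change.
#' @param chrom_len synthetic chromosome length in nt (default 2 Mb).
#' @param n_target_sites,n_target_decoys planted miRNA target sites passing
#'   the target rules, and decoy sites violating the Allen cutoff.
#' @param n_mimic_sites,n_mimic_decoys planted mimic sites passing all eTM
#'   rules, and decoys each violating exactly one rule.
#' @param n_lnc_decoys lncRNA candidates each violating exactly one filter
#'   rule.
#' @param n_junction_rejects named integer vector of undetectable planted
#'   junctions per violated criterion (mismatches, span, support).
#' @param n_cis_pairs lncRNA-gene pairs whose counts share a latent
#'   per-sample factor (positive cis correlation).
#' @param cis_latent_sd log-scale sd of the shared latent factor (default
#'   1.0: a strong shared regulatory signal, so planted pairs separate
#'   clearly from NB sampling noise at 3 vs 3 replicates).
#' @return object of class `synth_scenario`.
#' @export
synth_scenario <- function(seed = 42, n_genes = 40, n_lncrna = 50,
                           n_mirna = 10, n_circ = 12,
                           n_samples_per_group = 3, dispersion = 0.1,
                           de_fraction = 0.4, planted_log2fc = 2,
                           chrom_len = 2e6,
                           n_target_sites = 12, n_target_decoys = 12,
                           n_mimic_sites = 10, n_mimic_decoys = 10,
                           n_lnc_decoys = 8,
                           n_junction_rejects = c(mismatches = 3, span = 3,
                                                  support = 2),
                           n_cis_pairs = 10, cis_latent_sd = 1.0) {
  if (n_genes < 1 || n_lncrna < 0) stopf("n_genes >= 1 and n_lncrna >= 0 required")
  if (dispersion <= 0) stopf("dispersion must be positive")
  if (de_fraction < 0 || de_fraction > 1) stopf("de_fraction must be in [0,1]")
  if (n_samples_per_group < 2) stopf("at least 2 replicates per group required")
  structure(list(seed = as.integer(seed), n_genes = n_genes,
                 n_lncrna = n_lncrna, n_mirna = n_mirna, n_circ = n_circ,
                 n_samples_per_group = n_samples_per_group,
                 dispersion = dispersion, de_fraction = de_fraction,
                 planted_log2fc = planted_log2fc, chrom_len = chrom_len,
                 n_target_sites = n_target_sites,
                 n_target_decoys = n_target_decoys,
                 n_mimic_sites = n_mimic_sites,
                 n_mimic_decoys = n_mimic_decoys,
                 n_lnc_decoys = n_lnc_decoys,
                 n_junction_rejects = n_junction_rejects,
                 n_cis_pairs = n_cis_pairs, cis_latent_sd = cis_latent_sd),
            class = "synth_scenario")
}

# length model for lncRNA candidates: 35% < 300 nt, most < 600 nt
draw_lnc_len <- function(n) {
  u <- runif(n)
  len <- integer(n)
  len[u < 0.35] <- round(runif(sum(u < 0.35), 200, 299))
  m <- u >= 0.35 & u < 0.85
  len[m] <- round(runif(sum(m), 300, 600))
  len[u >= 0.85] <- round(runif(sum(u >= 0.85), 601, 1300))
  len
}

#' Generate the synthetic annotation, genome and miRNA set
#'
#' Places multi-exon mRNA genes and lncRNA candidates left-to-right on one
#' chromosome with random gaps.  Most lncRNA candidates are intergenic;
#' fixed fractions are placed antisense to exons, inside introns, sense
#' overlapping, or divergently head-to-head with a gene 5' end so that
#' every positional class occurs.  Filter-rule decoy candidates (short
#' length) are placed intergenic; score-based decoys are marked in the
#' ground truth and realised by [make_coding_potential_scores()].
#'
#' @param scenario a [synth_scenario()].
#' @return list with `ann` (a [tx_annotation()] carrying the genome),
#'   `mirnas` (named character vector, RNA alphabet) and `lnc_truth`
#'   (intended class and intended filter failure per candidate).
#' @export
make_annotation <- function(scenario) {
  sc <- scenario
  set.seed(stage_seed(sc$seed, 1L))
  chrom <- "chr1"

  tx_rows <- list(); ex_rows <- list()
  add_tx <- function(tid, gid, strand, exon_starts, exon_ends, biotype) {
    o <- order(exon_starts)
    exon_starts <- exon_starts[o]; exon_ends <- exon_ends[o]
    rk <- if (strand == "+") seq_along(exon_starts) else rev(seq_along(exon_starts))
    tx_rows[[length(tx_rows) + 1L]] <<- data.frame(
      transcript_id = tid, gene_id = gid, chrom = chrom, strand = strand,
      start = min(exon_starts), end = max(exon_ends), biotype = biotype,
      stringsAsFactors = FALSE)
    ex_rows[[length(ex_rows) + 1L]] <<- data.frame(
      transcript_id = tid, exon_rank = rk, start = exon_starts,
      end = exon_ends, stringsAsFactors = FALSE)
  }

  # intended lncRNA classes and filter decoys
  n_lnc <- sc$n_lncrna
  classes <- if (n_lnc > 0)
    sample(c("u", "x", "i", "j", "o"), n_lnc, replace = TRUE,
           prob = c(0.55, 0.12, 0.11, 0.12, 0.10)) else character(0)
  decoy_kinds <- if (sc$n_lnc_decoys > 0)
    rep(c("length", "coverage", "cpc", "cnci"), length.out = sc$n_lnc_decoys)
  else character(0)

  # pass 1: genes and intergenic (u) candidates interleaved left-to-right
  u_idx <- which(classes == "u")
  decoy_ids <- if (length(decoy_kinds))
    sprintf("lnc_decoy%03d", seq_along(decoy_kinds)) else character(0)
  queue <- c(rep("gene", sc$n_genes), rep("u", length(u_idx)),
             rep("decoy", length(decoy_kinds)))
  queue <- sample(queue)
  cursor <- 5000
  gene_meta <- list()   # per gene: strand, exon table, span
  gi <- 0L; ui <- 0L; di <- 0L
  lnc_truth <- list()
  for (item in queue) {
    gap <- round(runif(1, 2600, 6000))
    if (item == "gene") {
      gi <- gi + 1L
      k <- max(1L, 1L + stats::rpois(1, 6))
      ex_len <- round(runif(k, 100, 400))
      in_len <- if (k > 1) round(runif(k - 1, 200, 2000)) else integer(0)
      strand <- sample(c("+", "-"), 1)
      starts <- cursor + cumsum(c(0, head(ex_len, -1) + in_len))
      ends <- starts + ex_len
      tid <- sprintf("mRNA%03d", gi)
      add_tx(tid, sprintf("gene%03d", gi), strand, starts, ends, "mRNA")
      gene_meta[[gi]] <- list(tid = tid, strand = strand,
                              starts = starts, ends = ends)
      cursor <- max(ends) + gap
    } else {
      len <- if (item == "decoy" && decoy_kinds[di + 1L] == "length")
        round(runif(1, 120, 199)) else draw_lnc_len(1)
      if (item == "u") {
        ui <- ui + 1L
        tid <- sprintf("lnc%03d", u_idx[ui])
        n_ex <- sample(c(1L, 2L, 3L), 1, prob = c(0.65, 0.25, 0.10))
        truth_reason <- "none"; truth_class <- "u"
      } else {
        di <- di + 1L
        tid <- decoy_ids[di]
        n_ex <- 1L
        truth_reason <- decoy_kinds[di]; truth_class <- "u"
      }
      if (n_ex == 1L || len < 260) {
        starts <- cursor; ends <- cursor + len
      } else {
        parts <- diff(round(seq(0, len, length.out = n_ex + 1)))
        in_len <- round(runif(n_ex - 1, 80, 400))
        starts <- cursor + cumsum(c(0, head(parts, -1) + in_len))
        ends <- starts + parts
      }
      strand <- sample(c("+", "-"), 1)
      add_tx(tid, paste0("g_", tid), strand, starts, ends, "lncRNA_candidate")
      lnc_truth[[length(lnc_truth) + 1L]] <- data.frame(
        transcript_id = tid, intended_class = truth_class,
        intended_filter_reason = truth_reason, stringsAsFactors = FALSE)
      cursor <- max(ends) + gap
    }
    if (cursor > sc$chrom_len - 8000)
      stopf("infeasible packing: %d features do not fit on a %g nt chromosome",
            length(queue), sc$chrom_len)
  }

  # pass 2: gene-linked candidates (antisense x, intronic i, divergent j,
  # sense-overlapping o); each uses a distinct random gene where possible
  dep_idx <- which(classes != "u")
  if (length(dep_idx) && gi == 0)
    stopf("gene-linked lncRNA classes require at least one gene")
  gene_pick <- if (length(dep_idx))
    resample(rep(seq_len(gi), length.out = length(dep_idx)),
             size = length(dep_idx)) else integer(0)
  for (z in seq_along(dep_idx)) {
    idx <- dep_idx[z]
    cls <- classes[idx]
    tid <- sprintf("lnc%03d", idx)
    g <- gene_meta[[gene_pick[z]]]
    len <- min(draw_lnc_len(1), 900L)
    placed <- FALSE
    if (cls %in% c("x", "o")) {
      strand <- if (cls == "x") setdiff(c("+", "-"), g$strand) else g$strand
      e <- resample(seq_along(g$starts))
      s0 <- g$starts[e] + 5L
      add_tx(tid, paste0("g_", tid), strand, s0, s0 + len, "lncRNA_candidate")
      placed <- TRUE
    } else if (cls == "i") {
      if (length(g$starts) > 1) {
        ist <- g$ends[-length(g$ends)]; ien <- g$starts[-1]
        ok <- which(ien - ist >= len + 60)
        if (length(ok)) {
          w <- ok[1]
          s0 <- ist[w] + 30L
          add_tx(tid, paste0("g_", tid), g$strand, s0, s0 + len,
                 "lncRNA_candidate")
          placed <- TRUE
        }
      }
      if (!placed) { # fall back: shrink to fit the widest intron
        if (length(g$starts) > 1) {
          ist <- g$ends[-length(g$ends)]; ien <- g$starts[-1]
          w <- which.max(ien - ist)
          if (ien[w] - ist[w] >= 260) {
            s0 <- ist[w] + 30L
            add_tx(tid, paste0("g_", tid), g$strand, s0,
                   s0 + (ien[w] - ist[w] - 60L), "lncRNA_candidate")
            placed <- TRUE
          }
        }
      }
      if (!placed) cls <- "x"  # single-exon host gene: place antisense instead
      if (!placed) {
        strand <- setdiff(c("+", "-"), g$strand)
        s0 <- g$starts[1] + 5L
        add_tx(tid, paste0("g_", tid), strand, s0, s0 + len, "lncRNA_candidate")
        placed <- TRUE
      }
    } else { # j: divergent, 5' ends within 1 kb, no overlap
      len <- min(len, 1200L)
      d <- round(runif(1, 60, 800))
      if (g$strand == "+") {
        # gene 5' at its start; lncRNA on '-' upstream, 5' (its end) near it
        e1 <- g$starts[1] - d
        add_tx(tid, paste0("g_", tid), "-", e1 - len, e1, "lncRNA_candidate")
      } else {
        s1 <- max(g$ends) + d
        add_tx(tid, paste0("g_", tid), "+", s1, s1 + len, "lncRNA_candidate")
      }
      placed <- TRUE
    }
    lnc_truth[[length(lnc_truth) + 1L]] <- data.frame(
      transcript_id = tid, intended_class = cls,
      intended_filter_reason = if (cls == "o") "overlap" else "none",
      stringsAsFactors = FALSE)
  }

  genome_len <- sc$chrom_len
  genome <- paste(sample(c("A", "C", "G", "T"), genome_len, replace = TRUE),
                  collapse = "")
  mirnas <- character(0)
  if (sc$n_mirna > 0) {
    lens <- sample(18:25, sc$n_mirna, replace = TRUE)
    mirnas <- vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = ""),
      character(1))
    names(mirnas) <- sprintf("miR%03d", seq_len(sc$n_mirna))
  }

  transcripts <- do.call(rbind, tx_rows)
  exons <- do.call(rbind, ex_rows)
  rownames(transcripts) <- NULL; rownames(exons) <- NULL
  ann <- tx_annotation(transcripts, exons, genome = setNames(genome, chrom))
  lnc_truth <- if (length(lnc_truth)) do.call(rbind, lnc_truth) else
    data.frame(transcript_id = character(0), intended_class = character(0),
               intended_filter_reason = character(0), stringsAsFactors = FALSE)
  rownames(lnc_truth) <- NULL
  list(ann = ann, mirnas = mirnas, lnc_truth = lnc_truth)
}

#' Coding-potential scores for synthetic lncRNA candidates
#'
#' Emits one CPC/CNCI/coverage record per candidate: retained candidates
#' score safely below both thresholds with coverage above 3; decoys marked
#' `cpc`, `cnci` or `coverage` in the ground truth violate exactly that rule.
#'
#' @param ann a [tx_annotation()] from [make_annotation()].
#' @param lnc_truth the matching ground-truth table.
#' @param seed integer seed.
#' @return data.frame transcript_id, cpc_score, cnci_score, coverage.
#' @export
make_coding_potential_scores <- function(ann, lnc_truth, seed) {
  set.seed(stage_seed(seed, 2L))
  cand <- ann$transcripts$transcript_id[ann$transcripts$biotype == "lncRNA_candidate"]
  reason <- lnc_truth$intended_filter_reason[match(cand, lnc_truth$transcript_id)]
  n <- length(cand)
  cpc <- round(runif(n, -1.5, 0.35), 3)
  cnci <- round(runif(n, -1.3, -0.05), 3)
  cov <- round(runif(n, 4, 60), 2)
  cpc[reason == "cpc"] <- round(runif(sum(reason == "cpc"), 0.55, 2), 3)
  cnci[reason == "cnci"] <- round(runif(sum(reason == "cnci"), 0.05, 1), 3)
  cov[reason == "coverage"] <- round(runif(sum(reason == "coverage"), 0.2, 2.5), 2)
  data.frame(transcript_id = cand, cpc_score = cpc, cnci_score = cnci,
             coverage = cov, stringsAsFactors = FALSE)
}
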