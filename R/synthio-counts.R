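# NB count simulation with planted fold changes and cis-correlated pairs.

#' Simulate per-class count matrices with DE ground truth
#'
#' Draws NB(mu, phi) counts for every feature (mRNAs, lncRNA candidates,
#' miRNAs, circRNAs) over a two-group design.  A `de_fraction` of features
#' per class has its treated-group mean multiplied by
#' `2^(+/- planted_log2fc)`; planted cis pairs additionally share a
#' per-sample lognormal latent factor so their expression correlates
#' positively.
#'
#' @param scenario a [synth_scenario()].
#' @param ann a [tx_annotation()] (provides mRNA/lncRNA feature ids and cis
#'   pair geometry).
#' @param mirna_ids,circ_ids feature ids of the small-RNA and circRNA
#'   classes.
#' @param cis_hosts optional transcript ids eligible as cis lncRNAs
#'   (default: all lncRNA candidates).
#' @param prefer_de ids given priority when drawing the DE subset (planted
#'   interaction partners, so the downstream network is non-trivial); the
#'   per-class DE fraction is unchanged.
#' @return list with `counts` (named list of [count_matrix()] per class),
#'   `de_truth` (feature_id, class, is_de, lfc), `cis_truth`
#'   (lncrna_id, gene_id).
#' @export
simulate_counts <- function(scenario, ann, mirna_ids = character(0),
                            circ_ids = character(0), cis_hosts = NULL,
                            prefer_de = character(0)) {
  sc <- scenario
  set.seed(stage_seed(sc$seed, 5L))
  if (sc$dispersion <= 0) stopf("dispersion must be positive")
  n1 <- sc$n_samples_per_group
  samples <- c(sprintf("CTRL_%d", seq_len(n1)), sprintf("NaCl_%d", seq_len(n1)))
  group <- factor(rep(c("control", "treated"), each = n1),
                  levels = c("control", "treated"))

  tx <- ann$transcripts
  feats <- list(
    mRNA = tx$transcript_id[tx$biotype == "mRNA"],
    lncRNA = tx$transcript_id[tx$biotype %in% c("lncRNA_candidate", "lncRNA")],
    miRNA = mirna_ids,
    circRNA = circ_ids)

  # choose cis pairs: lncRNA within 100 kb of a gene
  if (is.null(cis_hosts)) cis_hosts <- feats$lncRNA
  cis <- data.frame(lncrna_id = character(0), gene_id = character(0),
                    stringsAsFactors = FALSE)
  if (sc$n_cis_pairs > 0 && length(cis_hosts) && length(feats$mRNA)) {
    lt <- tx[tx$transcript_id %in% cis_hosts, ]
    gt <- tx[tx$transcript_id %in% feats$mRNA, ]
    cand <- list()
    for (k in seq_len(nrow(lt))) {
      d <- interval_distance(lt$start[k], lt$end[k], gt$start, gt$end)
      j <- which(gt$chrom == lt$chrom[k] & d <= 1e5)
      if (length(j))
        cand[[length(cand) + 1L]] <- data.frame(
          lncrna_id = lt$transcript_id[k],
          gene_id = gt$transcript_id[j[which.min(d[j])]],
          stringsAsFactors = FALSE)
    }
    if (length(cand)) {
      cand <- do.call(rbind, cand)
      cand <- cand[!duplicated(cand$gene_id), , drop = FALSE]
      cis <- utils::head(cand, sc$n_cis_pairs)
    }
  }

  de_truth <- list(); counts <- list()
  latent <- matrix(1, nrow = nrow(cis), ncol = 2 * n1)
  if (nrow(cis)) latent <- matrix(rlnorm(nrow(cis) * 2 * n1, 0, sc$cis_latent_sd),
                                  nrow = nrow(cis))
  for (cls in names(feats)) {
    ids <- feats[[cls]]
    n <- length(ids)
    if (!n) { counts[[cls]] <- NULL; next }
    mu <- exp(runif(n, log(30), log(2000)))
    n_de <- round(sc$de_fraction * n)
    pref <- which(ids %in% prefer_de)
    de_idx <- if (n_de > 0) {
      first <- if (length(pref)) pref[sample.int(length(pref))] else integer(0)
      first <- utils::head(first, n_de)
      rest <- setdiff(seq_len(n), first)
      sort(c(first, resample(rest, size = n_de - length(first))))
    } else integer(0)
    lfc <- numeric(n)
    if (length(de_idx))
      lfc[de_idx] <- sc$planted_log2fc *
        rep_len(c(1, -1), length(de_idx))[sample.int(length(de_idx))]
    mum <- matrix(mu, nrow = n, ncol = 2 * n1)
    mum[, group == "treated"] <- mum[, group == "treated"] * 2^lfc
    # shared latent factors for cis pair members
    if (nrow(cis)) {
      for (p in seq_len(nrow(cis))) {
        for (fid in c(cis$lncrna_id[p], cis$gene_id[p])) {
          i <- match(fid, ids)
          if (!is.na(i)) mum[i, ] <- mum[i, ] * latent[p, ]
        }
      }
    }
    cm <- matrix(rnbinom(n * 2 * n1, mu = as.vector(mum),
                         size = 1 / sc$dispersion),
                 nrow = n, dimnames = list(ids, samples))
    counts[[cls]] <- count_matrix(cm, group)
    de_truth[[cls]] <- data.frame(feature_id = ids, class = cls,
                                  is_de = seq_len(n) %in% de_idx, lfc = lfc,
                                  stringsAsFactors = FALSE)
  }
  de_truth <- do.call(rbind, de_truth)
  rownames(de_truth) <- NULL
  list(counts = counts, de_truth = de_truth, cis_truth = cis)
}
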