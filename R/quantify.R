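# Normalization and per-class differential expression.
#
# Expression units follow the field's conventions: FPKM for linear RNAs,
# SRPBM (split reads per billion mapped reads) for back-splice junctions,
# CPM as the scale on which fold changes are computed.  Differential calls
# use a negative-binomial exact test with one common moment-estimated
# dispersion, conditional on the per-feature two-group total.

#' Build a count matrix container
#'
#' @param counts integer matrix, features x samples (rownames = feature ids,
#'   colnames = sample ids).
#' @param group factor or character of length `ncol(counts)` with two levels,
#'   reference (control) level first.
#' @param library_sizes optional per-sample library sizes; defaults to column
#'   sums.  When supplied, each must be at least the corresponding column sum.
#' @return a `count_matrix` object (list with `counts`, `group`,
#'   `library_sizes`).
#' @export
count_matrix <- function(counts, group, library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stopf("counts must have feature ids as rownames")
  if (any(!is.finite(counts)) || any(counts < 0))
    stopf("counts must be finite and non-negative")
  if (length(group) != ncol(counts)) stopf("one group label per sample required")
  group <- as.factor(group)
  if (nlevels(group) != 2L) stopf("exactly two groups required")
  csum <- colSums(counts)
  if (is.null(library_sizes)) {
    library_sizes <- csum
  } else {
    if (length(library_sizes) != ncol(counts)) stopf("one library size per sample")
    if (any(library_sizes < csum)) stopf("library_sizes must be >= column sums")
  }
  structure(list(counts = counts, group = group,
                 library_sizes = as.numeric(library_sizes)),
            class = "count_matrix")
}

#' Fragments per kilobase per million mapped reads
#'
#' FPKM = reads * 1e9 / (length * library size).
#'
#' @param counts matrix or `count_matrix` of raw counts.
#' @param effective_lengths positive feature lengths (nt), recycled by name
#'   against rownames of the counts.
#' @param library_sizes per-sample totals; default column sums.
#' @return numeric matrix of FPKM values, same shape as counts.
#' @export
fpkm <- function(counts, effective_lengths, library_sizes = NULL) {
  if (inherits(counts, "count_matrix")) {
    if (is.null(library_sizes)) library_sizes <- counts$library_sizes
    counts <- counts$counts
  }
  counts <- as.matrix(counts)
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  if (any(library_sizes <= 0)) stopf("zero library size: cannot normalize")
  if (!is.null(names(effective_lengths)) && !is.null(rownames(counts)))
    effective_lengths <- effective_lengths[rownames(counts)]
  if (length(effective_lengths) != nrow(counts))
    stopf("one effective length per feature required")
  if (any(!is.finite(effective_lengths)) || any(effective_lengths <= 0))
    stopf("effective lengths must be positive")
  sweep(counts / effective_lengths, 2, library_sizes, "/") * 1e9
}

#' Counts per million
#' @inheritParams fpkm
#' @return numeric matrix of CPM values.
#' @export
cpm <- function(counts, library_sizes = NULL) {
  if (inherits(counts, "count_matrix")) {
    if (is.null(library_sizes)) library_sizes <- counts$library_sizes
    counts <- counts$counts
  }
  counts <- as.matrix(counts)
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  if (any(library_sizes <= 0)) stopf("zero library size: cannot normalize")
  sweep(counts, 2, library_sizes, "/") * 1e6
}

#' Split reads per billion mappings
#'
#' SRPBM = junction reads * 1e9 / mapped reads.
#'
#' @param junction_reads non-negative counts of back-splice junction reads.
#' @param mapped_reads positive total mapped reads.
#' @return numeric vector of SRPBM values.
#' @export
srpbm <- function(junction_reads, mapped_reads) {
  if (any(mapped_reads <= 0)) stopf("mapped_reads must be positive")
  junction_reads * 1e9 / mapped_reads
}

# Common NB dispersion by method of moments on library-size-scaled counts:
# pooled across groups and features, var = mu + phi mu^2  =>
# phi = sum(var_i - mu_i) / sum(mu_i^2).
estimate_common_dispersion <- function(scaled, group) {
  lv <- levels(group)
  num <- 0; den <- 0
  for (g in lv) {
    m <- scaled[, group == g, drop = FALSE]
    if (ncol(m) < 2L) stopf("dispersion not estimable: group '%s' has a single replicate", g)
    mu <- rowMeans(m)
    v <- apply(m, 1, stats::var)
    keep <- mu > 0
    num <- num + sum(v[keep] - mu[keep])
    den <- den + sum(mu[keep]^2)
  }
  max(num / den, 1e-8)
}

# Exact two-sided NB test conditional on the two-group total.
# Group sums of n iid NB(mu, phi) are NB(n*mu, phi/n); conditioning on
# s = s1 + s2 under the null of equal means gives a distribution over
# s1 = 0..s enumerated directly.  p = total probability of outcomes no more
# likely than the observed one (standard exact-test tail definition).
nb_exact_p <- function(s1, s2, n1, n2, phi) {
  s <- s1 + s2
  if (s == 0) return(1)
  a <- 0:s
  mu1 <- s * n1 / (n1 + n2)
  mu2 <- s * n2 / (n1 + n2)
  lp <- dnbinom(a, size = n1 / phi, mu = mu1, log = TRUE) +
    dnbinom(s - a, size = n2 / phi, mu = mu2, log = TRUE)
  lp <- lp - max(lp)
  p <- exp(lp)
  p <- p / sum(p)
  pobs <- p[s1 + 1]
  min(1, sum(p[p <= pobs * (1 + 1e-10)]))
}

#' Differential expression by NB exact test
#'
#' Calls up/down/ns status per feature between two groups using a
#' negative-binomial exact test with a single common dispersion estimated by
#' the method of moments across features.  The significance rule is the raw
#' p-value for mRNA, circRNA and miRNA and the Benjamini-Hochberg FDR for
#' lncRNA (configurable via `sig_on`), always combined with an absolute
#' log2 fold-change threshold.
#'
#' @param counts a [count_matrix()] (or raw matrix plus `group`).
#' @param rna_class one of "mRNA", "lncRNA", "circRNA", "miRNA"; selects the
#'   default significance rule.
#' @param group required when `counts` is a bare matrix.
#' @param sig_on "p" or "fdr"; default "fdr" for lncRNA, "p" otherwise.
#' @param lfc_min absolute log2FC threshold (default 1).
#' @param alpha significance level (default 0.05).
#' @param min_total features with total count below this are reported ns with
#'   p = 1 and excluded from testing (default 10).
#' @param pseudo_cpm pseudocount on the CPM scale for fold changes
#'   (default 0.5).
#' @return data.frame with feature_id, baseMean_ctrl, baseMean_trt, log2FC,
#'   p, fdr, status; attribute `dispersion` carries the common estimate.
#' @export
de_test <- function(counts, rna_class = c("mRNA", "lncRNA", "circRNA", "miRNA"),
                    group = NULL, sig_on = NULL, lfc_min = 1, alpha = 0.05,
                    min_total = 10, pseudo_cpm = 0.5) {
  rna_class <- match.arg(rna_class)
  if (!inherits(counts, "count_matrix")) {
    if (is.null(group)) stopf("group labels required")
    counts <- count_matrix(counts, group)
  }
  if (is.null(sig_on)) sig_on <- if (rna_class == "lncRNA") "fdr" else "p"
  sig_on <- match.arg(sig_on, c("p", "fdr"))
  grp <- counts$group
  for (g in levels(grp)) {
    if (sum(grp == g) < 2L)
      stopf("dispersion not estimable: group '%s' has fewer than 2 replicates", g)
  }
  m <- counts$counts
  libs <- counts$library_sizes
  # scale to the mean library size so the exact test can condition on totals
  scaled <- sweep(m, 2, mean(libs) / libs, "*")
  ids <- rownames(m)
  ord <- order(ids)  # stable, id-ranked processing (ties in p resolved by id)
  m <- m[ord, , drop = FALSE]; scaled <- scaled[ord, , drop = FALSE]; ids <- ids[ord]

  phi <- estimate_common_dispersion(scaled, grp)
  ctrl <- grp == levels(grp)[1]
  n1 <- sum(ctrl); n2 <- sum(!ctrl)

  cpm_m <- cpm(m, libs)
  base_ctrl <- rowMeans(cpm_m[, ctrl, drop = FALSE])
  base_trt <- rowMeans(cpm_m[, !ctrl, drop = FALSE])
  log2fc <- log2((base_trt + pseudo_cpm) / (base_ctrl + pseudo_cpm))

  rs <- round(scaled)
  s1 <- rowSums(rs[, ctrl, drop = FALSE])
  s2 <- rowSums(rs[, !ctrl, drop = FALSE])
  testable <- (s1 + s2) >= min_total
  p <- rep(1, length(ids))
  p[testable] <- vapply(which(testable), function(i)
    nb_exact_p(s1[i], s2[i], n1, n2, phi), numeric(1))
  fdr <- rep(NA_real_, length(ids))
  fdr[testable] <- p.adjust(p[testable], method = "BH")
  fdr[!testable] <- 1

  crit <- if (sig_on == "p") p < alpha else fdr < alpha
  status <- rep("ns", length(ids))
  status[testable & crit & log2fc >= lfc_min] <- "up"
  status[testable & crit & log2fc <= -lfc_min] <- "down"

  out <- data.frame(feature_id = ids, baseMean_ctrl = base_ctrl,
                    baseMean_trt = base_trt, log2FC = log2fc,
                    p = p, fdr = fdr, status = status,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "dispersion") <- phi
  attr(out, "sig_on") <- sig_on
  out
}
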