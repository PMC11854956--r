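# Shared fixtures, built once per test session.

.fix_cache <- new.env(parent = emptyenv())

# reference fixture (default scenario, seed 42)
shared_fixture <- function() {
  if (is.null(.fix_cache$default))
    .fix_cache$default <- synth_fixture(synth_scenario(seed = 42))
  .fix_cache$default
}

# large planted-site fixture for the attributability checks: 50 true + 50
# decoy sites for both targets and mimics, one host transcript per site
attribution_fixture <- function() {
  if (is.null(.fix_cache$attr)) {
    sc <- synth_scenario(seed = 42, n_genes = 100, n_lncrna = 220,
                         n_mirna = 12, chrom_len = 4e6,
                         n_target_sites = 50, n_target_decoys = 50,
                         n_mimic_sites = 50, n_mimic_decoys = 50,
                         n_lnc_decoys = 8)
    .fix_cache$attr <- synth_fixture(sc)
  }
  .fix_cache$attr
}

# random small annotation for interval-logic tests: a handful of coding
# transcripts plus one lncRNA placed by a random strategy covering all
# positional classes
random_lnc_config <- function() {
  n_cod <- sample(1:3, 1)
  tx <- list(); ex <- list()
  cursor <- sample(500:2000, 1)
  for (g in seq_len(n_cod)) {
    k <- sample(1:4, 1)
    el <- sample(80:300, k, replace = TRUE)
    il <- if (k > 1) sample(150:900, k - 1, replace = TRUE) else integer(0)
    starts <- cursor + cumsum(c(0, utils::head(el, -1) + il))
    ends <- starts + el
    strand <- sample(c("+", "-"), 1)
    tid <- sprintf("cod%d", g)
    tx[[g]] <- data.frame(transcript_id = tid, gene_id = tid, chrom = "c",
                          strand = strand, start = min(starts),
                          end = max(ends), biotype = "mRNA",
                          stringsAsFactors = FALSE)
    ex[[g]] <- data.frame(transcript_id = tid,
                          exon_rank = seq_len(k),
                          start = starts, end = ends,
                          stringsAsFactors = FALSE)
    cursor <- max(ends) + sample(400:3000, 1)
  }
  cod_tx <- do.call(rbind, tx); cod_ex <- do.call(rbind, ex)
  g <- sample(seq_len(n_cod), 1)
  gtx <- tx[[g]]; gex <- ex[[g]]
  len <- sample(150:700, 1)
  mode <- sample(c("overlap", "intron", "near5", "random"), 1,
                 prob = c(0.3, 0.2, 0.2, 0.3))
  if (mode == "overlap") {
    s0 <- sample(gex$start, 1) + sample(0:40, 1)
  } else if (mode == "intron" && nrow(gex) > 1) {
    w <- sample(seq_len(nrow(gex) - 1), 1)
    s0 <- gex$end[w] + sample(1:30, 1)
    len <- min(len, max(10, gex$start[w + 1] - s0 - 1))
  } else if (mode == "near5") {
    a5 <- if (gtx$strand == "+") gtx$start else gtx$end
    s0 <- max(0, a5 + sample(-1200:1200, 1))
  } else {
    s0 <- sample(0:(cursor + 2000), 1)
  }
  strand <- sample(c("+", "-"), 1)
  lnc_tx <- data.frame(transcript_id = "lnc", gene_id = "lnc", chrom = "c",
                       strand = strand, start = s0, end = s0 + len,
                       biotype = "lncRNA", stringsAsFactors = FALSE)
  lnc_ex <- data.frame(transcript_id = "lnc", exon_rank = 1L,
                       start = s0, end = s0 + len, stringsAsFactors = FALSE)
  list(cod_tx = cod_tx, cod_ex = cod_ex, lnc_tx = lnc_tx, lnc_ex = lnc_ex)
}

# tiny deterministic annotation used by several unit tests: one 5-exon "+"
# transcript, one 2-exon "-" transcript
toy_annotation <- function(genome_len = 0) {
  ex1 <- data.frame(transcript_id = "tA", exon_rank = 1:5,
                    start = c(1000, 1500, 2100, 2800, 3600),
                    end = c(1200, 1700, 2300, 3000, 3900),
                    stringsAsFactors = FALSE)
  ex2 <- data.frame(transcript_id = "tB", exon_rank = 2:1,
                    start = c(6000, 7000), end = c(6400, 7500),
                    stringsAsFactors = FALSE)
  tx <- data.frame(
    transcript_id = c("tA", "tB"), gene_id = c("gA", "gB"),
    chrom = "chr1", strand = c("+", "-"),
    start = c(1000, 6000), end = c(3900, 7500),
    biotype = c("mRNA", "mRNA"), stringsAsFactors = FALSE)
  genome <- NULL
  if (genome_len > 0)
    genome <- c(chr1 = paste(sample(c("A", "C", "G", "T"), genome_len, TRUE),
                             collapse = ""))
  tx_annotation(tx, rbind(ex1, ex2), genome = genome)
}
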