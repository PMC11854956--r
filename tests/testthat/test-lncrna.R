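# lncRNA filtering, positional classification, cis pairing and ORF search.

mk_cand <- function(ids, lens, chrom = "chr1", strand = "+", start0 = 50000,
                    gap = 5000) {
  starts <- start0 + cumsum(c(0, utils::head(lens, -1) + gap))
  tx <- data.frame(transcript_id = ids, gene_id = ids, chrom = chrom,
                   strand = strand, start = starts, end = starts + lens,
                   biotype = "lncRNA_candidate", stringsAsFactors = FALSE)
  ex <- data.frame(transcript_id = ids, exon_rank = 1L, start = starts,
                   end = starts + lens, stringsAsFactors = FALSE)
  tx_annotation(tx, ex)
}

ok_scores <- function(ids) data.frame(
  transcript_id = ids, cpc_score = -1, cnci_score = -0.5, coverage = 5,
  stringsAsFactors = FALSE)

test_that("each filter rule removes with its own reason, in order", {
  cand <- mk_cand(c("short", "good", "lowcov", "coding1", "coding2"),
                  c(150, 300, 400, 400, 400))
  sc <- ok_scores(cand$transcripts$transcript_id)
  sc$coverage[sc$transcript_id == "lowcov"] <- 1
  sc$cpc_score[sc$transcript_id == "coding1"] <- 0.9
  sc$cnci_score[sc$transcript_id == "coding2"] <- 0.3
  empty_mrna <- tx_annotation(cand$transcripts[0, ], cand$exons[0, ])
  res <- filter_lncrna_candidates(cand, sc, empty_mrna)
  expect_setequal(res$retained$transcript_id, "good")
  expect_equal(res$removed$reason[res$removed$transcript_id == "short"], "length")
  expect_equal(res$removed$reason[res$removed$transcript_id == "lowcov"], "coverage")
  expect_equal(res$removed$reason[res$removed$transcript_id == "coding1"], "cpc")
  expect_equal(res$removed$reason[res$removed$transcript_id == "coding2"], "cnci")
  expect_true(all(res$retained$biotype == "lncRNA"))
})

test_that("same-strand mRNA overlap removes a candidate; antisense survives", {
  cand <- mk_cand(c("sense", "anti"), c(300, 300), strand = "+")
  cand$transcripts$strand[2] <- "-"
  cand$exons$start[2] <- cand$exons$start[1]
  cand$exons$end[2] <- cand$exons$end[1]
  cand$transcripts$start[2] <- cand$transcripts$start[1]
  cand$transcripts$end[2] <- cand$transcripts$end[1]
  mrna <- mk_cand("m1", 1000, strand = "+", start0 = cand$transcripts$start[1] - 100)
  mrna$transcripts$biotype <- "mRNA"
  res <- filter_lncrna_candidates(cand, ok_scores(c("sense", "anti")), mrna)
  expect_setequal(res$retained$transcript_id, "anti")
  expect_equal(res$removed$reason, "overlap")
})

test_that("a missing score record is an error naming the transcript", {
  cand <- mk_cand(c("a1", "a2"), c(300, 300))
  expect_error(
    filter_lncrna_candidates(cand, ok_scores("a1"),
                             tx_annotation(cand$transcripts[0, ], cand$exons[0, ])),
    "a2")
})

test_that("filtering is order-independent", {
  set.seed(31)
  cand <- mk_cand(sprintf("c%02d", 1:30),
                  sample(c(120, 150, 250, 400, 800), 30, TRUE))
  sc <- ok_scores(cand$transcripts$transcript_id)
  sc$cpc_score <- runif(30, -1, 1.2)
  sc$cnci_score <- runif(30, -1, 0.5)
  sc$coverage <- runif(30, 0, 10)
  empty <- tx_annotation(cand$transcripts[0, ], cand$exons[0, ])
  r1 <- filter_lncrna_candidates(cand, sc, empty)
  perm <- sample(30)
  cand2 <- tx_annotation(cand$transcripts[perm, ], cand$exons[perm, ])
  r2 <- filter_lncrna_candidates(cand2, sc, empty)
  expect_setequal(r1$retained$transcript_id, r2$retained$transcript_id)
})

test_that("filter agrees with a rule-by-rule oracle on random candidates", {
  set.seed(32)
  n <- 200
  cand <- mk_cand(sprintf("r%03d", 1:n),
                  sample(100:900, n, TRUE))
  sc <- data.frame(transcript_id = cand$transcripts$transcript_id,
                   cpc_score = runif(n, -1.5, 1.5),
                   cnci_score = runif(n, -1.5, 1),
                   coverage = runif(n, 0, 12), stringsAsFactors = FALSE)
  empty <- tx_annotation(cand$transcripts[0, ], cand$exons[0, ])
  res <- filter_lncrna_candidates(cand, sc, empty)
  lens <- tx_spliced_length(cand)
  keep_oracle <- lens >= 200 & sc$coverage >= 3 & sc$cpc_score < 0.5 &
    sc$cnci_score < 0
  expect_setequal(res$retained$transcript_id,
                  cand$transcripts$transcript_id[keep_oracle])
})

test_that("definition cases: intronic lncRNA is i, isolated lncRNA is u", {
  ann <- toy_annotation()
  # tA introns: [1200,1500), [1700,2100), ... place one inside, same strand
  lnc <- tx_annotation(
    data.frame(transcript_id = c("li", "lu"), gene_id = c("li", "lu"),
               chrom = "chr1", strand = "+", start = c(1250, 56000),
               end = c(1450, 56300), biotype = "lncRNA",
               stringsAsFactors = FALSE),
    data.frame(transcript_id = c("li", "lu"), exon_rank = 1L,
               start = c(1250, 56000), end = c(1450, 56300),
               stringsAsFactors = FALSE))
  cl <- classify_lncrna_position(lnc, ann)
  expect_equal(cl$class_code[cl$transcript_id == "li"], "i")
  expect_equal(cl$class_code[cl$transcript_id == "lu"], "u")
})

test_that("classification is invariant under coordinate translation", {
  set.seed(33)
  for (z in 1:20) {
    cfg <- random_lnc_config()
    lnc <- tx_annotation(cfg$lnc_tx, cfg$lnc_ex)
    cod <- tx_annotation(cfg$cod_tx, cfg$cod_ex)
    c0 <- classify_lncrna_position(lnc, cod)$class_code
    shift <- 7777L
    sh <- function(df) { df$start <- df$start + shift; df$end <- df$end + shift; df }
    c1 <- classify_lncrna_position(tx_annotation(sh(cfg$lnc_tx), sh(cfg$lnc_ex)),
                                   tx_annotation(sh(cfg$cod_tx), sh(cfg$cod_ex)))$class_code
    expect_identical(c0, c1)
  }
})

test_that("class codes agree with the per-base oracle on random configurations", {
  set.seed(34)
  got <- character(0)
  for (z in 1:150) {
    cfg <- random_lnc_config()
    cl <- classify_lncrna_position(tx_annotation(cfg$lnc_tx, cfg$lnc_ex),
                                   tx_annotation(cfg$cod_tx, cfg$cod_ex))
    ora <- oracle_lnc_class(cfg$lnc_tx, cfg$lnc_ex, cfg$cod_tx, cfg$cod_ex)
    expect_identical(cl$class_code, ora)
    got <- c(got, ora)
  }
  expect_true(all(c("u", "x", "i", "j", "o") %in% got))
})

test_that("cis pairing window is boundary-inclusive at 100 kb", {
  lnc <- data.frame(transcript_id = "L", gene_id = "L", chrom = "chr1",
                    strand = "+", start = 0, end = 1000, biotype = "lncRNA",
                    stringsAsFactors = FALSE)
  genes <- data.frame(
    transcript_id = c("at_limit", "beyond"), gene_id = c("g1", "g2"),
    chrom = "chr1", strand = "+",
    start = c(1000 + 100000, 1000 + 150000),
    end = c(1000 + 100000 + 2000, 1000 + 150000 + 2000),
    biotype = "mRNA", stringsAsFactors = FALSE)
  expr <- matrix(rep(c(1, 2, 3, 4, 5, 6), 3), nrow = 3, byrow = TRUE,
                 dimnames = list(c("L", "at_limit", "beyond"), NULL))
  res <- cis_targets(lnc, genes, expr)
  expect_setequal(res$gene_id, "at_limit")
  expect_equal(res$distance, 100000)
  # constant expression: correlation NA rather than error
  expr["at_limit", ] <- 7
  res2 <- cis_targets(lnc, genes, expr)
  expect_true(is.na(res2$correlation))
})

test_that("cis correlation sign recovers planted co-expression", {
  fix <- synth_fixture(synth_scenario(seed = 9, n_cis_pairs = 40,
                                      de_fraction = 0))
  cis <- fix$cis_truth
  expect_gte(nrow(cis), 10)
  lens <- tx_spliced_length(fix$ann)
  expr <- rbind(
    fpkm(fix$counts$mRNA, lens[rownames(fix$counts$mRNA$counts)]),
    fpkm(fix$counts$lncRNA, lens[rownames(fix$counts$lncRNA$counts)]))
  r <- vapply(seq_len(nrow(cis)), function(k)
    cor(log2(expr[cis$lncrna_id[k], ] + 1), log2(expr[cis$gene_id[k], ] + 1)),
    numeric(1))
  expect_gte(mean(r > 0), 0.95)
})

test_that("longest ORF handles canonical and degenerate cases", {
  expect_equal(longest_orf("ATGAAATAA"), 9)
  expect_equal(longest_orf("CCCCCC"), 0)
  expect_equal(longest_orf("ATGTAA"), 6)
  expect_equal(longest_orf("AUGAAAUAA"), 9)   # RNA alphabet
  expect_equal(longest_orf("ATGNNNTAA"), 9)   # ambiguity inside the frame
  expect_equal(longest_orf("NTGAAATAA"), 0)   # ambiguity breaks the start
})

test_that("longest ORF equals the all-substring oracle on random sequences", {
  set.seed(35)
  for (z in 1:200) {
    s <- rand_dna(sample(30:200, 1))
    expect_equal(longest_orf(s), oracle_orf(s))
  }
})
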