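# Synthetic-data generator: determinism, structure, count model.

test_that("a fixed seed reproduces every emitted file byte for byte", {
  sc <- synth_scenario(seed = 5, n_genes = 12, n_lncrna = 20, n_mirna = 4,
                       n_circ = 4, n_target_sites = 3, n_target_decoys = 3,
                       n_mimic_sites = 3, n_mimic_decoys = 3, n_lnc_decoys = 4,
                       n_cis_pairs = 4)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_synth_fixture(synth_fixture(sc), d1)
  write_synth_fixture(synth_fixture(sc), d2)
  f <- list.files(d1)
  expect_setequal(f, list.files(d2))
  m1 <- tools::md5sum(file.path(d1, sort(f)))
  m2 <- tools::md5sum(file.path(d2, sort(f)))
  expect_identical(unname(m1), unname(m2))
})

test_that("no lncRNA candidates are emitted when n_lncrna is 0", {
  sc <- synth_scenario(seed = 3, n_genes = 8, n_lncrna = 0, n_lnc_decoys = 0,
                       n_mimic_sites = 0, n_mimic_decoys = 0,
                       n_target_sites = 2, n_target_decoys = 2,
                       n_cis_pairs = 0)
  mk <- make_annotation(sc)
  expect_false(any(mk$ann$transcripts$biotype == "lncRNA_candidate"))
})

test_that("generated lncRNA candidates are shorter than mRNAs overall", {
  sc <- synth_scenario(seed = 8, n_genes = 150, n_lncrna = 300,
                       chrom_len = 6e6, n_lnc_decoys = 0)
  mk <- make_annotation(sc)
  lens <- tx_spliced_length(mk$ann)
  tx <- mk$ann$transcripts
  med_lnc <- median(lens[tx$transcript_id[tx$biotype == "lncRNA_candidate"]])
  med_mrna <- median(lens[tx$transcript_id[tx$biotype == "mRNA"]])
  expect_lt(med_lnc, med_mrna)
  expect_lt(med_lnc, 600)
  expect_gt(med_mrna, 1000)
  # miRNAs respect the 18-25 nt window
  expect_true(all(nchar(mk$mirnas) >= 18 & nchar(mk$mirnas) <= 25))
})

test_that("requesting more features than the chromosome holds is an error", {
  sc <- synth_scenario(seed = 1, n_genes = 200, n_lncrna = 200,
                       chrom_len = 1e5)
  expect_error(make_annotation(sc), "infeasible packing")
})

test_that("exons are sorted, disjoint and sequences extractable", {
  fix <- shared_fixture()
  for (tid in sample(fix$ann$transcripts$transcript_id, 20)) {
    e <- fix$ann$exons[fix$ann$exons$transcript_id == tid, ]
    e <- e[order(e$start), ]
    expect_true(all(e$end > e$start))
    if (nrow(e) > 1) expect_true(all(e$start[-1] >= e$end[-nrow(e)]))
  }
  seqs <- extract_tx_seq(fix$ann, fix$ann$transcripts$transcript_id[1:10])
  expect_identical(unname(nchar(seqs)),
                   unname(tx_spliced_length(fix$ann)[names(seqs)]))
})

test_that("zero planted fold change gives an empty DE ground truth", {
  sc <- synth_scenario(seed = 4, n_genes = 10, n_lncrna = 10, n_mirna = 3,
                       de_fraction = 0, n_target_sites = 0, n_target_decoys = 0,
                       n_mimic_sites = 0, n_mimic_decoys = 0, n_lnc_decoys = 0,
                       n_cis_pairs = 0)
  mk <- make_annotation(sc)
  cnt <- simulate_counts(sc, mk$ann, mirna_ids = names(mk$mirnas))
  expect_false(any(cnt$de_truth$is_de))
  expect_true(all(cnt$de_truth$lfc == 0))
})

test_that("NB count draws match their first two moments", {
  # two groups with identical means act as 10,000 exchangeable replicates
  sc <- synth_scenario(seed = 6, n_genes = 30, n_lncrna = 0, n_lnc_decoys = 0,
                       n_mirna = 0, n_samples_per_group = 5000,
                       dispersion = 0.05, de_fraction = 0,
                       n_target_sites = 0, n_target_decoys = 0,
                       n_mimic_sites = 0, n_mimic_decoys = 0, n_cis_pairs = 0)
  mk <- make_annotation(sc)
  cnt <- simulate_counts(sc, mk$ann)
  m <- cnt$counts$mRNA$counts
  grp <- cnt$counts$mRNA$group
  g1 <- rowMeans(m[, grp == "control"]); g2 <- rowMeans(m[, grp == "treated"])
  # equal underlying means: group ratio within 2% for well-expressed features
  hi <- g1 > 500
  expect_true(any(hi))
  expect_true(all(abs(g2[hi] / g1[hi] - 1) < 0.02))
  phihat <- (apply(m, 1, var) - rowMeans(m)) / rowMeans(m)^2
  expect_true(all(abs(phihat[hi] / 0.05 - 1) < 0.3))
})

test_that("planted twofold-squared changes concentrate near a ratio of 4", {
  sc <- synth_scenario(seed = 7, n_genes = 250, n_lncrna = 0, n_lnc_decoys = 0,
                       n_mirna = 0, de_fraction = 1, planted_log2fc = 2,
                       chrom_len = 4e6,
                       n_target_sites = 0, n_target_decoys = 0,
                       n_mimic_sites = 0, n_mimic_decoys = 0, n_cis_pairs = 0)
  mk <- make_annotation(sc)
  cnt <- simulate_counts(sc, mk$ann)
  m <- cnt$counts$mRNA$counts
  grp <- cnt$counts$mRNA$group
  tr <- cnt$de_truth
  up <- tr$feature_id[tr$lfc > 0]
  expect_gte(length(up), 100)
  ratio <- rowMeans(m[up, grp == "treated"]) / pmax(rowMeans(m[up, grp == "control"]), 1e-9)
  expect_lt(abs(mean(ratio) - 4) / 4, 0.1)
})

test_that("planted junctions are back-splice oriented; zero-read junctions emit nothing", {
  fix <- shared_fixture()
  expect_true(all(fix$junctions$donor > fix$junctions$acceptor))
  j0 <- fix$junctions[fix$junctions$n_reads == 0, ]
  expect_gt(nrow(j0), 0)
  expect_identical(j0$reject_reason, rep("support", nrow(j0)))
  expect_false(any(grepl(paste(j0$circ_id, collapse = "|"),
                         fix$chimeric$read_id)))
  # every emitted back-splice read has its 3' segment upstream of its 5'
  bs <- fix$chimeric[!grepl("^linear", fix$chimeric$read_id), ]
  expect_true(all(bs$seg2_end <= bs$seg1_start))
})

test_that("ground truth is re-derivable from the emitted files alone", {
  fix <- shared_fixture()
  dir <- withr::local_tempdir()
  write_synth_fixture(fix, dir)
  back <- read_synth_fixture(dir)
  # annotation round trip
  expect_setequal(back$ann$transcripts$transcript_id,
                  fix$ann$transcripts$transcript_id)
  expect_identical(back$ann$genome[["chr1"]], fix$ann$genome[["chr1"]])
  expect_identical(back$mirnas, fix$mirnas)
  # planted target sites are present in the re-read transcript sequences
  tt <- fix$site_truth[fix$site_truth$intended == "pass" &
                         fix$site_truth$mode == "target", ][1:3, ]
  for (k in 1:3) {
    s1 <- substr(extract_tx_seq(back$ann, tt$transcript_id[k])[[1]],
                 tt$site_start[k], tt$site_end[k])
    s2 <- substr(extract_tx_seq(fix$ann, tt$transcript_id[k])[[1]],
                 tt$site_start[k], tt$site_end[k])
    expect_identical(s1, s2)
  }
  # counts round trip
  expect_identical(back$counts$mRNA$counts, fix$counts$mRNA$counts)
})
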