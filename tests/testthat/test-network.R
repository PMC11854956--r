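# ceRNA network assembly, hub/sponge flags and export round trips.

de_tab <- function(ids, status = "up") {
  n <- length(ids)
  data.frame(feature_id = ids, baseMean_ctrl = rep(10, n),
             baseMean_trt = rep(40, n), log2FC = rep(2, n),
             p = rep(0.001, n), fdr = rep(0.01, n),
             status = rep(status, length.out = n), stringsAsFactors = FALSE)
}

target_row <- function(mir, tgt, allen = 2, ratio = 0.9) data.frame(
  mirna_id = mir, target_id = tgt, site_start = 10L, site_end = 31L,
  allen_score = allen, mfe = -30, mfe_ratio = ratio, pairing = "",
  stringsAsFactors = FALSE)

mimic_row <- function(mir, nc, start = 5L) data.frame(
  mirna_id = mir, ncrna_id = nc, site_start = start, site_end = start + 24L,
  bulge_position = 10L, bulge_length = 3L, n_mismatches_outside_middle = 1L,
  max_consecutive_mismatches = 1L, verdict = "pass", fail_reason = "none",
  stringsAsFactors = FALSE)

test_that("the minimal ceRNA motif gives 3 nodes, 2 edges, 1 triple", {
  de <- list(miRNA = de_tab("mir1"), mRNA = de_tab("gene1", "down"),
             lncRNA = de_tab("lnc1"), circRNA = de_tab(character(0))[0, ])
  net <- build_network(de, target_row("mir1", "gene1"),
                       mimic_row("mir1", "lnc1"))
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$edges), 2)
  expect_equal(nrow(net$triples), 1)
  expect_equal(net$triples$mrna_id, "gene1")
  expect_equal(net$triples$ncrna_id, "lnc1")
})

test_that("empty DE sets give an empty network", {
  de <- list(miRNA = de_tab("mir1", "ns"), mRNA = de_tab("gene1", "ns"))
  net <- build_network(de, target_row("mir1", "gene1"), NULL)
  expect_equal(nrow(net$nodes), 0)
  expect_equal(nrow(net$edges), 0)
})

test_that("edges keep only pairs with both endpoints differential", {
  de <- list(miRNA = de_tab(c("mir1", "mir2"), c("up", "ns")),
             mRNA = de_tab(c("g1", "g2"), c("up", "ns")))
  tg <- rbind(target_row("mir1", "g1"), target_row("mir1", "g2"),
              target_row("mir2", "g1"))
  net <- build_network(de, tg, NULL)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$partner_id, "g1")
  # every node participates in an edge
  expect_true(all(net$nodes$id %in% c(net$edges$mirna_id, net$edges$partner_id)))
})

test_that("an edge referencing an unknown id is an integrity error", {
  de <- list(miRNA = de_tab("mir1"), mRNA = de_tab("g1"))
  expect_error(build_network(de, target_row("mir1", "ghost"), NULL),
               "integrity error.*ghost")
})

test_that("multiple sites between one pair collapse to one edge", {
  de <- list(miRNA = de_tab("mir1"), lncRNA = de_tab("lnc1"))
  mm <- rbind(mimic_row("mir1", "lnc1", 5L), mimic_row("mir1", "lnc1", 80L))
  net <- build_network(de, NULL, mm)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$n_sites, 2L)
})

test_that("hub threshold is strict: degree 7 is a hub, degree 6 is not", {
  de <- list(miRNA = de_tab(c("mir7", "mir6")),
             mRNA = de_tab(sprintf("g%02d", 1:13)))
  tg <- rbind(
    do.call(rbind, lapply(sprintf("g%02d", 1:7), function(g) target_row("mir7", g))),
    do.call(rbind, lapply(sprintf("g%02d", 8:13), function(g) target_row("mir6", g))))
  net <- annotate_hubs(build_network(de, tg, NULL))
  expect_true(net$nodes$hub[net$nodes$id == "mir7"])
  expect_false(net$nodes$hub[net$nodes$id == "mir6"])
})

test_that("sponges need mimic edges to at least two distinct miRNAs", {
  de <- list(miRNA = de_tab(c("mir1", "mir2", "mir3")),
             circRNA = de_tab(c("circA", "circB")))
  mm <- rbind(mimic_row("mir1", "circA"), mimic_row("mir2", "circA"),
              mimic_row("mir3", "circA"), mimic_row("mir1", "circB"))
  net <- annotate_hubs(build_network(de, NULL, mm))
  expect_true(net$nodes$sponge[net$nodes$id == "circA"])
  expect_false(net$nodes$sponge[net$nodes$id == "circB"])
})

random_net <- function(seed) {
  set.seed(seed)
  mirs <- sprintf("mir%02d", 1:8)
  genes <- sprintf("g%02d", 1:20)
  lncs <- sprintf("l%02d", 1:8)
  de <- list(miRNA = de_tab(mirs), mRNA = de_tab(genes), lncRNA = de_tab(lncs))
  tg <- do.call(rbind, lapply(1:40, function(i)
    target_row(sample(mirs, 1), sample(genes, 1))))
  tg <- tg[!duplicated(tg[c("mirna_id", "target_id")]), ]
  mm <- do.call(rbind, lapply(1:15, function(i)
    mimic_row(sample(mirs, 1), sample(lncs, 1))))
  mm <- mm[!duplicated(mm[c("mirna_id", "ncrna_id")]), ]
  annotate_hubs(build_network(de, tg, mm))
}

test_that("hub and sponge flags equal a brute-force degree recount", {
  for (seed in 1:5) {
    net <- random_net(seed)
    for (k in seq_len(nrow(net$nodes))) {
      id <- net$nodes$id[k]
      deg <- sum(net$edges$mirna_id == id) + sum(net$edges$partner_id == id)
      if (net$nodes$rna_class[k] == "miRNA")
        expect_identical(net$nodes$hub[k], deg > 6)
      nm <- length(unique(net$edges$mirna_id[net$edges$edge_kind == "mimic" &
                                               net$edges$partner_id == id]))
      if (net$nodes$rna_class[k] != "miRNA")
        expect_identical(net$nodes$sponge[k], nm >= 2)
      expect_gte(deg, 1)  # no isolated nodes
    }
    # triples equal the brute-force join
    te <- net$edges[net$edges$edge_kind == "target", ]
    me <- net$edges[net$edges$edge_kind == "mimic", ]
    n_expected <- sum(vapply(unique(net$edges$mirna_id), function(m)
      sum(te$mirna_id == m) * sum(me$mirna_id == m), numeric(1)))
    expect_equal(nrow(net$triples), n_expected)
  }
})

test_that("network assembly is a pure function of its input tables", {
  n1 <- random_net(99)
  set.seed(99)
  n2 <- random_net(99)
  expect_identical(n1, n2)
})

test_that("removing a miRNA removes exactly its edges and triples", {
  net <- random_net(7)
  mir <- net$edges$mirna_id[1]
  all_mirs <- sprintf("mir%02d", 1:8)
  de <- list(miRNA = de_tab(all_mirs, ifelse(all_mirs == mir, "ns", "up")),
             mRNA = de_tab(sprintf("g%02d", 1:20)),
             lncRNA = de_tab(sprintf("l%02d", 1:8)))
  tg <- net$edges[net$edges$edge_kind == "target", ]
  tg2 <- data.frame(mirna_id = tg$mirna_id, target_id = tg$partner_id,
                    site_start = 1L, site_end = 22L,
                    allen_score = tg$allen_score, mfe = -30,
                    mfe_ratio = tg$mfe_ratio, pairing = "",
                    stringsAsFactors = FALSE)
  mm <- net$edges[net$edges$edge_kind == "mimic", ]
  mm2 <- mimic_row(mm$mirna_id, mm$partner_id)
  net2 <- build_network(de, tg2, mm2)
  expect_equal(nrow(net2$edges), sum(net$edges$mirna_id != mir))
  expect_equal(nrow(net2$triples), sum(net$triples$mirna_id != mir))
})

test_that("SIF export writes one typed line per edge", {
  de <- list(miRNA = de_tab("mir1"), mRNA = de_tab("g1"),
             lncRNA = de_tab("l1"))
  net <- annotate_hubs(build_network(de, target_row("mir1", "g1"),
                                     mimic_row("mir1", "l1")))
  dir <- withr::local_tempdir()
  paths <- export_network(net, dir, formats = "SIF")
  lines <- readLines(paths[["SIF"]])
  expect_length(lines, 2)
  expect_setequal(lines, c("mir1\ttargets\tg1", "mir1\tsponged_by\tl1"))
  expect_error(export_network(net, dir, formats = "DOT"), "unknown export format")
})

test_that("GraphML export round-trips nodes, edges and attributes", {
  net <- random_net(3)
  dir <- withr::local_tempdir()
  paths <- export_network(net, dir, formats = "GraphML")
  back <- import_network_graphml(paths[["GraphML"]])
  expect_identical(back$nodes, net$nodes)
  cols <- c("mirna_id", "partner_id", "edge_kind", "n_sites")
  e1 <- net$edges[cols]; e2 <- back$edges[cols]
  rownames(e1) <- NULL; rownames(e2) <- NULL
  expect_identical(e1, e2)
  expect_identical(back$triples, net$triples)
  # the XML itself is well-formed and namespaced GraphML
  doc <- xml2::read_xml(paths[["GraphML"]])
  expect_equal(xml2::xml_name(doc), "graphml")
})
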