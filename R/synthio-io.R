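# End-to-end fixture assembly and on-disk round trip.

#' Build a complete synthetic fixture in memory
#'
#' Runs every generator stage in a fixed order: annotation + genome +
#' miRNAs, coding-potential scores, planted target sites, planted mimic
#' sites, planted back-splice junctions, chimeric reads, and counts.
#'
#' @param scenario a [synth_scenario()].
#' @return list of class `synth_fixture`: scenario, ann, mirnas, scores,
#'   lnc_truth, site_truth, junctions, chimeric, counts, de_truth,
#'   cis_truth, samples.
#' @export
synth_fixture <- function(scenario) {
  sc <- scenario
  mk <- make_annotation(sc)
  ann <- mk$ann
  scores <- make_coding_potential_scores(ann, mk$lnc_truth, sc$seed)

  good_u <- mk$lnc_truth$transcript_id[
    mk$lnc_truth$intended_filter_reason == "none" &
      mk$lnc_truth$intended_class == "u"]
  mrna_ids <- ann$transcripts$transcript_id[ann$transcripts$biotype == "mRNA"]

  site_truth <- NULL
  if (sc$n_target_sites + sc$n_target_decoys > 0) {
    pt <- plant_duplex_sites(ann, mk$mirnas, "target",
                             sc$n_target_sites, sc$n_target_decoys,
                             hosts = mrna_ids, seed = sc$seed)
    ann <- pt$ann; site_truth <- pt$truth
  }
  if (sc$n_mimic_sites + sc$n_mimic_decoys > 0) {
    pm <- plant_duplex_sites(ann, mk$mirnas, "mimic",
                             sc$n_mimic_sites, sc$n_mimic_decoys,
                             hosts = good_u, seed = sc$seed)
    ann <- pm$ann; site_truth <- rbind(site_truth, pm$truth)
  }

  junctions <- plant_backsplice_junctions(sc, ann)
  chimeric <- simulate_backsplice_reads(sc, junctions)
  circ_ids <- junctions$circ_id[junctions$accept]

  prefer_de <- unique(c(site_truth$transcript_id[site_truth$intended == "pass"],
                        site_truth$mirna_id[site_truth$intended == "pass"],
                        circ_ids))
  cnt <- simulate_counts(sc, ann, mirna_ids = names(mk$mirnas),
                         circ_ids = circ_ids, cis_hosts = good_u,
                         prefer_de = prefer_de)
  lib_all <- Reduce(`+`, lapply(cnt$counts, function(cm) cm$library_sizes))
  samples <- data.frame(
    sample = colnames(cnt$counts[[1]]$counts),
    group = as.character(cnt$counts[[1]]$group),
    mapped_reads = round(lib_all),
    stringsAsFactors = FALSE)

  structure(list(scenario = sc, ann = ann, mirnas = mk$mirnas,
                 scores = scores, lnc_truth = mk$lnc_truth,
                 site_truth = site_truth, junctions = junctions,
                 chimeric = chimeric, counts = cnt$counts,
                 de_truth = cnt$de_truth, cis_truth = cnt$cis_truth,
                 samples = samples),
            class = "synth_fixture")
}

#' Write a synthetic fixture to a directory
#'
#' Emits genome.fa, annotation.gtf, mirnas.fa, scores.tsv,
#' counts_<class>.tsv, samples.tsv, chimeric.tsv and truth.json; every file
#' is byte-deterministic under the scenario seed.
#'
#' @param fix a [synth_fixture()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_synth_fixture <- function(fix, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  genome <- Biostrings::DNAStringSet(fix$ann$genome)
  Biostrings::writeXStringSet(genome, p("genome.fa"))
  write_annotation_gtf(fix$ann, p("annotation.gtf"))
  mir <- Biostrings::RNAStringSet(fix$mirnas)
  Biostrings::writeXStringSet(mir, p("mirnas.fa"))
  write_tsv(fix$scores, p("scores.tsv"))
  for (cls in names(fix$counts)) {
    cm <- fix$counts[[cls]]
    df <- data.frame(feature_id = rownames(cm$counts), cm$counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(df, p(sprintf("counts_%s.tsv", cls)))
  }
  write_tsv(fix$samples, p("samples.tsv"))
  write_tsv(fix$chimeric, p("chimeric.tsv"))
  truth <- list(scenario = unclass(fix$scenario),
                lnc_truth = fix$lnc_truth, site_truth = fix$site_truth,
                junctions = fix$junctions, de_truth = fix$de_truth,
                cis_truth = fix$cis_truth)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read counts TSV written by [write_synth_fixture()]
#'
#' @param path counts TSV (feature_id column + one column per sample).
#' @param samples data.frame with columns sample and group.
#' @return a [count_matrix()].
#' @export
read_counts_tsv <- function(path, samples) {
  df <- read_tsv(path)
  m <- as.matrix(df[, samples$sample, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$feature_id
  count_matrix(m, factor(samples$group, levels = unique(samples$group)))
}

#' Read a synthetic fixture back from disk
#'
#' @param dir directory written by [write_synth_fixture()].
#' @return list with ann (genome attached), mirnas, scores, counts,
#'   samples, chimeric, truth.
#' @export
read_synth_fixture <- function(dir) {
  p <- function(f) file.path(dir, f)
  genome <- Biostrings::readDNAStringSet(p("genome.fa"))
  genome <- setNames(as.character(genome), names(genome))
  ann <- read_annotation_gtf(p("annotation.gtf"), genome = genome)
  mir <- Biostrings::readRNAStringSet(p("mirnas.fa"))
  mirnas <- setNames(as.character(mir), names(mir))
  samples <- read_tsv(p("samples.tsv"))
  counts <- list()
  for (cls in c("mRNA", "lncRNA", "miRNA", "circRNA")) {
    f <- p(sprintf("counts_%s.tsv", cls))
    if (file.exists(f)) counts[[cls]] <- read_counts_tsv(f, samples)
  }
  truth <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  list(ann = ann, mirnas = mirnas, scores = read_tsv(p("scores.tsv")),
       counts = counts, samples = samples,
       chimeric = read_tsv(p("chimeric.tsv")), truth = truth)
}
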