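# End-to-end orchestration: quantify -> lncrna -> circrna -> duplex ->
# mimic -> network, from a single configuration.  Every stage reads and
# writes declared files only, so the pipeline is restartable and
# byte-reproducible.

#' Assemble a pipeline configuration
#'
#' @param input_dir directory holding the input files (annotation.gtf,
#'   genome.fa, mirnas.fa, scores.tsv, samples.tsv, counts_<class>.tsv,
#'   chimeric.tsv -- the layout written by [write_synth_fixture()]).
#' @param outdir output directory.
#' @param seed integer seed recorded in the manifest.
#' @param de_alpha significance level for DE (default 0.05).
#' @param de_lfc_min absolute log2FC threshold (default 1).
#' @param lncrna_sig_on "fdr" (default) or "p" for the lncRNA class;
#'   other classes use the raw p-value.
#' @param allen_max,mfe_ratio_min target-prediction cutoffs (7, 0.65).
#' @param mimic_middle miRNA middle positions for the eTM rules (9:12).
#' @param hub_min_degree,sponge_min_mirnas network annotation thresholds
#'   (6 strict >, 2 >=).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, outdir, seed = 1,
                            de_alpha = 0.05, de_lfc_min = 1,
                            lncrna_sig_on = "fdr",
                            allen_max = 7, mfe_ratio_min = 0.65,
                            mimic_middle = 9:12,
                            hub_min_degree = 6, sponge_min_mirnas = 2) {
  structure(list(input_dir = input_dir, outdir = outdir, seed = seed,
                 de_alpha = de_alpha, de_lfc_min = de_lfc_min,
                 lncrna_sig_on = lncrna_sig_on, allen_max = allen_max,
                 mfe_ratio_min = mfe_ratio_min, mimic_middle = mimic_middle,
                 hub_min_degree = hub_min_degree,
                 sponge_min_mirnas = sponge_min_mirnas),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file.
#' @param config a [pipeline_config()].
#' @return `read_pipeline_config` returns the config; `write_pipeline_config`
#'   the path, invisibly.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, y)
  cfg
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

required_inputs <- function(cfg) {
  file.path(cfg$input_dir,
            c("annotation.gtf", "genome.fa", "mirnas.fa", "scores.tsv",
              "samples.tsv", "counts_mRNA.tsv", "counts_lncRNA.tsv",
              "counts_miRNA.tsv", "counts_circRNA.tsv", "chimeric.tsv"))
}

#' Run the full ceRNA pipeline
#'
#' Executes differential expression per RNA class, lncRNA filtering /
#' classification / cis pairing, back-splice detection and typing, miRNA
#' target prediction, mimic scanning and network assembly, writing one
#' result file per stage plus a run manifest into `config$outdir`.
#'
#' @param config a [pipeline_config()] (or path to its YAML form).
#' @return invisible list with the per-stage tables, the network and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- config
  inputs <- required_inputs(cfg)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    stopf("input path does not exist: %s", missing[1])
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  outp <- function(f) file.path(cfg$outdir, f)
  counts_stage <- list()

  fx <- read_synth_fixture(cfg$input_dir)
  ann <- fx$ann

  # --- quantify: DE per class ------------------------------------------
  de <- list()
  for (cls in names(fx$counts)) {
    sig <- if (cls == "lncRNA") cfg$lncrna_sig_on else "p"
    de[[cls]] <- de_test(fx$counts[[cls]], rna_class = cls, sig_on = sig,
                         lfc_min = cfg$de_lfc_min, alpha = cfg$de_alpha)
    write_tsv(de[[cls]], outp(sprintf("de_%s.tsv", cls)))
    counts_stage[[sprintf("de_%s", cls)]] <- sum(de[[cls]]$status != "ns")
  }

  # --- lncrna ----------------------------------------------------------
  tx <- ann$transcripts
  cand_ids <- tx$transcript_id[tx$biotype %in% c("lncRNA_candidate", "lncRNA")]
  cand <- tx_annotation(tx[tx$transcript_id %in% cand_ids, ],
                        ann$exons[ann$exons$transcript_id %in% cand_ids, ],
                        genome = ann$genome)
  mrna_ids <- tx$transcript_id[tx$biotype == "mRNA"]
  coding <- tx_annotation(tx[tx$transcript_id %in% mrna_ids, ],
                          ann$exons[ann$exons$transcript_id %in% mrna_ids, ],
                          genome = ann$genome)
  filt <- filter_lncrna_candidates(cand, fx$scores, coding)
  retained_ids <- filt$retained$transcript_id
  ret_ann <- tx_annotation(filt$retained,
                           ann$exons[ann$exons$transcript_id %in% retained_ids, ],
                           genome = ann$genome)
  cls_tab <- classify_lncrna_position(ret_ann, coding)
  write_tsv(merge(filt$retained, cls_tab, by = "transcript_id"),
            outp("lncrna_retained.tsv"))
  write_tsv(filt$removed, outp("lncrna_removed.tsv"))
  counts_stage$lncrna_retained <- length(retained_ids)

  # restrict lncRNA DE to retained transcripts
  de$lncRNA <- de$lncRNA[de$lncRNA$feature_id %in% retained_ids, , drop = FALSE]
  de_lnc_ids <- de_ids(de$lncRNA)

  # cis pairs of DE lncRNAs with genes, on FPKM
  lens <- tx_spliced_length(ann)
  expr <- rbind(fpkm(fx$counts$mRNA, lens[rownames(fx$counts$mRNA$counts)]),
                fpkm(fx$counts$lncRNA, lens[rownames(fx$counts$lncRNA$counts)]))
  cis <- cis_targets(tx[tx$transcript_id %in% de_lnc_ids, ], coding, expr)
  write_tsv(cis, outp("cis_pairs.tsv"))
  counts_stage$cis_pairs <- nrow(cis)

  # --- circrna ---------------------------------------------------------
  det <- detect_backsplice(fx$chimeric)
  acc <- classify_circ(det$accepted, ann)
  # match detected junctions to quantified circ ids by coordinates
  circ_counts <- fx$counts$circRNA
  write_tsv(acc, outp("circ_junctions.tsv"))
  write_tsv(det$rejected, outp("circ_rejected.tsv"))
  counts_stage$circ_accepted <- nrow(acc)
  srp <- quantify_circ(circ_counts$counts, fx$samples$mapped_reads)
  write_tsv(data.frame(circ_id = rownames(srp), srp, check.names = FALSE),
            outp("circ_srpbm.tsv"))

  # --- duplex: DE miRNA vs DE mRNA targets -----------------------------
  de_mir <- de_ids(de$miRNA)
  de_mrna <- de_ids(de$mRNA)
  targets <- predict_targets(
    fx$mirnas[de_mir],
    to_rna(extract_tx_seq(ann, de_mrna)),
    allen_max = cfg$allen_max, mfe_ratio_min = cfg$mfe_ratio_min)
  write_tsv(targets, outp("targets.tsv"))
  counts_stage$target_pairs <- nrow(targets)

  # --- mimic: DE miRNA vs DE lncRNA + DE circRNA -----------------------
  de_circ <- de_ids(de$circRNA)
  nc_seqs <- character(0)
  if (length(de_lnc_ids))
    nc_seqs <- c(nc_seqs, to_rna(extract_tx_seq(ann, de_lnc_ids)))
  if (length(de_circ)) {
    # circ ids are coordinate-derived (circ_<chrom>_<acceptor>_<donor>), so
    # DE circRNAs join detected junctions directly
    circ_seq <- vapply(de_circ, function(cid) {
      j <- which(acc$circ_id == cid)
      if (!length(j)) return(NA_character_)
      to_rna(get_circ_sequence(acc[j, ], ann))
    }, character(1))
    circ_seq <- circ_seq[!is.na(circ_seq)]
    nc_seqs <- c(nc_seqs, circ_seq)
  }
  mimics <- scan_mimics(fx$mirnas[de_mir], nc_seqs, middle = cfg$mimic_middle)
  write_tsv(mimics, outp("mimics.tsv"))
  counts_stage$mimic_sites <- nrow(mimics)

  # --- network ---------------------------------------------------------
  net <- build_network(de, targets, mimics)
  net <- annotate_hubs(net, cfg$hub_min_degree, cfg$sponge_min_mirnas)
  export_network(net, cfg$outdir)
  counts_stage$network_nodes <- nrow(net$nodes)
  counts_stage$network_edges <- nrow(net$edges)
  counts_stage$network_triples <- nrow(net$triples)

  manifest <- list(
    package = "saltnet",
    version = as.character(utils::packageVersion("saltnet")),
    seed = cfg$seed,
    input_md5 = as.list(setNames(unname(tools::md5sum(inputs)),
                                 basename(inputs))),
    stage_counts = counts_stage)
  jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(de = de, lncrna = list(retained = filt$retained,
                                        classes = cls_tab, cis = cis),
                 circ = acc, targets = targets, mimics = mimics,
                 network = net, manifest = manifest))
}

#' One-command demo on a synthetic fixture
#'
#' Generates the reference synthetic scenario under the given seed, writes
#' its fixture files, runs the full pipeline on them, and returns the
#' result bundle.  Deterministic: the same seed reproduces every output
#' byte for byte.
#'
#' @param seed integer seed (default 42).
#' @param outdir output directory (fixture under `fixture/`, results under
#'   `results/`).
#' @param scenario optional [synth_scenario()] override (its seed wins).
#' @return invisible result list from [run_pipeline()], plus `fixture_dir`
#'   and `results_dir`.
#' @export
saltnet_demo <- function(seed = 42, outdir = tempfile("saltnet_demo"),
                         scenario = NULL) {
  if (is.null(scenario)) scenario <- synth_scenario(seed = seed)
  fix <- synth_fixture(scenario)
  fdir <- file.path(outdir, "fixture")
  rdir <- file.path(outdir, "results")
  write_synth_fixture(fix, fdir)
  cfg <- pipeline_config(input_dir = fdir, outdir = rdir, seed = scenario$seed)
  write_pipeline_config(cfg, file.path(outdir, "config.yaml"))
  res <- run_pipeline(cfg)
  res$fixture_dir <- fdir
  res$results_dir <- rdir
  res$fixture <- fix
  invisible(res)
}
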