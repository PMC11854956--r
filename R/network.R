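# ceRNA network assembly, hub/sponge annotation and export.
#
# Nodes are differential entities participating in at least one qualifying
# edge; target edges (miRNA-mRNA) and mimic edges (miRNA-lncRNA/circRNA)
# require both endpoints differential.  A ceRNA triple is (miRNA, mRNA,
# ncRNA) with both edges through the shared miRNA.

de_ids <- function(de) de$feature_id[de$status != "ns"]

#' Build the differential ceRNA network
#'
#' @param de named list of [de_test()] result tables, one per RNA class
#'   (names among mRNA, lncRNA, circRNA, miRNA).
#' @param targets interaction table from [predict_targets()] (mirna_id,
#'   target_id, allen_score, mfe_ratio, ...).
#' @param mimics mimic table from [scan_mimics()] (mirna_id, ncrna_id, ...).
#' @return object of class `cerna_network`: list with `nodes` (id,
#'   rna_class, de_status, hub, sponge), `edges` (mirna_id, partner_id,
#'   edge_kind, evidence columns, n_sites) and `triples`.
#' @export
build_network <- function(de, targets, mimics) {
  stopifnot(is.list(de))
  universe <- list()
  for (cls in names(de)) {
    universe[[cls]] <- data.frame(id = de[[cls]]$feature_id,
                                  rna_class = rep(cls, nrow(de[[cls]])),
                                  de_status = de[[cls]]$status,
                                  stringsAsFactors = FALSE)
  }
  uni <- do.call(rbind, universe)
  if (anyDuplicated(uni$id)) stopf("feature id namespaces overlap across classes")
  lookup <- function(ids, what) {
    j <- match(ids, uni$id)
    if (anyNA(j))
      stopf("integrity error: %s references unknown id '%s'", what,
            ids[which(is.na(j))[1]])
    uni[j, , drop = FALSE]
  }

  edges <- list()
  if (!is.null(targets) && nrow(targets)) {
    tm <- lookup(targets$mirna_id, "target edge")
    tp <- lookup(targets$target_id, "target edge")
    keep <- tm$de_status != "ns" & tp$de_status != "ns"
    t2 <- targets[keep, , drop = FALSE]
    if (nrow(t2)) {
      # collapse multiple sites per pair onto the best one
      o <- order(t2$mirna_id, t2$target_id, t2$allen_score, t2$mfe)
      t2 <- t2[o, , drop = FALSE]
      key <- paste(t2$mirna_id, t2$target_id)
      n_sites <- as.vector(table(key)[unique(key)])
      t2u <- t2[!duplicated(key), , drop = FALSE]
      edges[[length(edges) + 1L]] <- data.frame(
        mirna_id = t2u$mirna_id, partner_id = t2u$target_id,
        edge_kind = "target", allen_score = t2u$allen_score,
        mfe_ratio = t2u$mfe_ratio, bulge_length = NA_integer_,
        n_sites = n_sites, stringsAsFactors = FALSE)
    }
  }
  if (!is.null(mimics) && nrow(mimics)) {
    mm <- lookup(mimics$mirna_id, "mimic edge")
    mp <- lookup(mimics$ncrna_id, "mimic edge")
    keep <- mm$de_status != "ns" & mp$de_status != "ns"
    m2 <- mimics[keep, , drop = FALSE]
    if (nrow(m2)) {
      o <- order(m2$mirna_id, m2$ncrna_id, m2$site_start)
      m2 <- m2[o, , drop = FALSE]
      key <- paste(m2$mirna_id, m2$ncrna_id)
      n_sites <- as.vector(table(key)[unique(key)])
      m2u <- m2[!duplicated(key), , drop = FALSE]
      edges[[length(edges) + 1L]] <- data.frame(
        mirna_id = m2u$mirna_id, partner_id = m2u$ncrna_id,
        edge_kind = "mimic", allen_score = NA_real_, mfe_ratio = NA_real_,
        bulge_length = m2u$bulge_length, n_sites = n_sites,
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(mirna_id = character(0), partner_id = character(0),
               edge_kind = character(0), allen_score = numeric(0),
               mfe_ratio = numeric(0), bulge_length = integer(0),
               n_sites = integer(0), stringsAsFactors = FALSE)
  edges <- edges[order(edges$mirna_id, edges$partner_id, edges$edge_kind), ,
                 drop = FALSE]
  rownames(edges) <- NULL

  node_ids <- unique(c(edges$mirna_id, edges$partner_id))
  nodes <- uni[match(sort(node_ids), uni$id), , drop = FALSE]
  nodes$hub <- rep(FALSE, nrow(nodes))
  nodes$sponge <- rep(FALSE, nrow(nodes))
  rownames(nodes) <- NULL

  triples <- data.frame(mirna_id = character(0), mrna_id = character(0),
                        ncrna_id = character(0), stringsAsFactors = FALSE)
  te <- edges[edges$edge_kind == "target", , drop = FALSE]
  me <- edges[edges$edge_kind == "mimic", , drop = FALSE]
  if (nrow(te) && nrow(me)) {
    tr <- merge(te[, c("mirna_id", "partner_id")],
                me[, c("mirna_id", "partner_id")], by = "mirna_id",
                suffixes = c("_mrna", "_ncrna"))
    triples <- data.frame(mirna_id = tr$mirna_id,
                          mrna_id = tr$partner_id_mrna,
                          ncrna_id = tr$partner_id_ncrna,
                          stringsAsFactors = FALSE)
    triples <- triples[order(triples$mirna_id, triples$mrna_id,
                             triples$ncrna_id), , drop = FALSE]
    rownames(triples) <- NULL
  }
  structure(list(nodes = nodes, edges = edges, triples = triples),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  cls <- table(x$nodes$rna_class)
  cat(sprintf("cerna_network: %d nodes (%s), %d edges, %d triples\n",
              nrow(x$nodes),
              paste(names(cls), cls, sep = ":", collapse = " "),
              nrow(x$edges), nrow(x$triples)))
  if (any(x$nodes$hub)) cat("  hubs:", paste(x$nodes$id[x$nodes$hub], collapse = ", "), "\n")
  if (any(x$nodes$sponge)) cat("  sponges:", paste(x$nodes$id[x$nodes$sponge], collapse = ", "), "\n")
  invisible(x)
}

#' Annotate hub miRNAs and sponge ncRNAs
#'
#' A miRNA is a hub when its degree exceeds `mirna_hub_min_degree`
#' (strict >); a lncRNA or circRNA is a sponge when it has mimic edges to at
#' least `sponge_min_mirnas` distinct miRNAs.
#'
#' @param net a [build_network()] result.
#' @param mirna_hub_min_degree hub threshold (default 6, strict >).
#' @param sponge_min_mirnas sponge threshold (default 2, >=).
#' @return the network with hub/sponge flags set.
#' @export
annotate_hubs <- function(net, mirna_hub_min_degree = 6, sponge_min_mirnas = 2) {
  deg <- table(c(net$edges$mirna_id))
  is_mir <- net$nodes$rna_class == "miRNA"
  d <- as.vector(deg[net$nodes$id]); d[is.na(d)] <- 0
  net$nodes$hub <- is_mir & d > mirna_hub_min_degree
  me <- net$edges[net$edges$edge_kind == "mimic", , drop = FALSE]
  nmir <- tapply(me$mirna_id, me$partner_id, function(x) length(unique(x)))
  s <- as.vector(nmir[net$nodes$id]); s[is.na(s)] <- 0
  net$nodes$sponge <- net$nodes$rna_class %in% c("lncRNA", "circRNA") &
    s >= sponge_min_mirnas
  net
}

as_igraph <- function(net) {
  vert <- data.frame(name = net$nodes$id, rna_class = net$nodes$rna_class,
                     de_status = net$nodes$de_status, hub = net$nodes$hub,
                     sponge = net$nodes$sponge, stringsAsFactors = FALSE)
  ed <- data.frame(from = net$edges$mirna_id, to = net$edges$partner_id,
                   edge_kind = net$edges$edge_kind,
                   n_sites = net$edges$n_sites, stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = vert)
}

#' Export a ceRNA network
#'
#' `SIF` writes one line per edge (`mirna TAB targets|sponged_by TAB
#' partner`), `GraphML` a full attribute graph via igraph, `TSV` node and
#' edge tables, `JSON` a class-resolved summary.
#'
#' @param net an annotated [build_network()] result.
#' @param dir output directory.
#' @param formats subset of c("SIF", "GraphML", "TSV", "JSON").
#' @param prefix file name prefix (default "network").
#' @return named vector of written paths, invisibly.
#' @export
export_network <- function(net, dir, formats = c("SIF", "GraphML", "TSV", "JSON"),
                           prefix = "network") {
  bad <- setdiff(formats, c("SIF", "GraphML", "TSV", "JSON"))
  if (length(bad)) stopf("unknown export format '%s'", bad[1])
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- character(0)
  if ("SIF" %in% formats) {
    f <- file.path(dir, paste0(prefix, ".sif"))
    rel <- ifelse(net$edges$edge_kind == "target", "targets", "sponged_by")
    writeLines(sprintf("%s\t%s\t%s", net$edges$mirna_id, rel,
                       net$edges$partner_id), f)
    out["SIF"] <- f
  }
  if ("GraphML" %in% formats) {
    f <- file.path(dir, paste0(prefix, ".graphml"))
    igraph::write_graph(as_igraph(net), f, format = "graphml")
    out["GraphML"] <- f
  }
  if ("TSV" %in% formats) {
    fn <- file.path(dir, paste0(prefix, "_nodes.tsv"))
    fe <- file.path(dir, paste0(prefix, "_edges.tsv"))
    write_tsv(net$nodes, fn)
    write_tsv(net$edges, fe)
    out["TSV_nodes"] <- fn; out["TSV_edges"] <- fe
  }
  if ("JSON" %in% formats) {
    f <- file.path(dir, paste0(prefix, "_summary.json"))
    jsonlite::write_json(network_summary(net), f, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    out["JSON"] <- f
  }
  invisible(out)
}

#' Node/edge/triple counts of a network
#' @param net a `cerna_network`.
#' @return list of summary counts per class and edge kind.
#' @export
network_summary <- function(net) {
  list(n_nodes = nrow(net$nodes),
       nodes_per_class = as.list(table(net$nodes$rna_class)),
       n_edges = nrow(net$edges),
       edges_per_kind = as.list(table(net$edges$edge_kind)),
       n_triples = nrow(net$triples),
       n_hubs = sum(net$nodes$hub),
       n_sponges = sum(net$nodes$sponge))
}

#' Re-import a GraphML export as a ceRNA network
#'
#' Round-trip counterpart of [export_network()]'s GraphML output: node and
#' edge sets plus rna_class/de_status/hub/sponge and edge kind attributes
#' are reconstructed; triples are re-enumerated.
#'
#' @param path GraphML file.
#' @return a `cerna_network`.
#' @export
import_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(id = igraph::V(g)$name,
                      rna_class = igraph::V(g)$rna_class,
                      de_status = igraph::V(g)$de_status,
                      hub = as.logical(igraph::V(g)$hub),
                      sponge = as.logical(igraph::V(g)$sponge),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  el <- igraph::as_data_frame(g, what = "edges")
  edges <- data.frame(mirna_id = el$from, partner_id = el$to,
                      edge_kind = el$edge_kind,
                      allen_score = NA_real_, mfe_ratio = NA_real_,
                      bulge_length = NA_integer_,
                      n_sites = as.integer(el$n_sites),
                      stringsAsFactors = FALSE)
  # orient edges miRNA -> partner
  mir <- nodes$id[nodes$rna_class == "miRNA"]
  flip <- !(edges$mirna_id %in% mir) & edges$partner_id %in% mir
  tmp <- edges$mirna_id[flip]
  edges$mirna_id[flip] <- edges$partner_id[flip]
  edges$partner_id[flip] <- tmp
  edges <- edges[order(edges$mirna_id, edges$partner_id, edges$edge_kind), ,
                 drop = FALSE]
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  te <- edges[edges$edge_kind == "target", , drop = FALSE]
  me <- edges[edges$edge_kind == "mimic", , drop = FALSE]
  triples <- data.frame(mirna_id = character(0), mrna_id = character(0),
                        ncrna_id = character(0), stringsAsFactors = FALSE)
  if (nrow(te) && nrow(me)) {
    tr <- merge(te[, c("mirna_id", "partner_id")],
                me[, c("mirna_id", "partner_id")], by = "mirna_id",
                suffixes = c("_mrna", "_ncrna"))
    triples <- data.frame(mirna_id = tr$mirna_id,
                          mrna_id = tr$partner_id_mrna,
                          ncrna_id = tr$partner_id_ncrna,
                          stringsAsFactors = FALSE)
    triples <- triples[order(triples$mirna_id, triples$mrna_id,
                             triples$ncrna_id), , drop = FALSE]
    rownames(triples) <- NULL
  }
  structure(list(nodes = nodes, edges = edges, triples = triples),
            class = "cerna_network")
}
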