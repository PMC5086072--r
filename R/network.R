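#' Fraction of exons with a significant motif hit in one R region
#'
#' The Ri ratio of a transcript is the number of exons whose Ri window
#' carries a significant motif hit divided by the total number of exons of
#' the transcript (windows missing because a terminal exon has no flanking
#' intron simply count as no hit).
#'
#' @param t a `transcript_model`.
#' @param hits logical vector of per-exon hit flags for one region (indexed
#'   by exon, any length <= n_exons; typically derived from
#'   [best_hit_pvalue()] at p < 0.05).
#' @return numeric in \[0, 1\].
#' @export
compute_ri_ratio <- function(t, hits) {
  sum(hits) / nrow(t$exons)
}

#' Assemble the weighted co-splicing network
#'
#' For every RBP and every transcript co-expressed with it, each of the
#' transcript's R-region sequence sets is scanned with the RBP-group motif
#' for that region (only motifs that passed the significance gate are
#' scanned). If at least one exon's window hits at `p < p_site`, a weighted
#' edge (one per region) links the RBP to the transcript, with weight
#' `-log10(min hit p over exons)` and the transcript's Ri ratio attached.
#' Transcripts with no significant hit in any region are excluded; an RBP
#' whose groups yielded no significant motif contributes no edges.
#'
#' @param rbps character vector of RBP transcript ids.
#' @param coexp_edges data.frame from [build_coexpression_edges()].
#' @param motif_models nested list `motif_models[[rbp]][[region]]` of
#'   `motif_model` objects (entries may be missing or non-significant).
#' @param r_regions data.frame of R regions (from
#'   [extract_r_regions_all()]) covering all co-expressed transcripts.
#' @param catalog the `sv_catalog` (for exon counts).
#' @param p_site per-sequence hit p-value gate (default 0.05).
#' @param super_clusters optional named vector transcript -> super-cluster
#'   label, stored on nodes.
#' @return object of class `cosplice_network`: `nodes` (data.frame: `id`,
#'   `type` SF/transcript, `super_cluster`, `color`) and `edges`
#'   (data.frame: `sf_id`, `transcript_id`, `region`, `weight`,
#'   `n_exons_with_hit`, `ri_ratio`).
#' @export
build_cosplice_network <- function(rbps, coexp_edges, motif_models,
                                   r_regions, catalog, p_site = 0.05,
                                   super_clusters = NULL) {
  regions <- c("R1", "R2", "R3", "R4")
  edge_rows <- list()
  for (rbp in rbps) {
    targets <- coexp_edges$transcript_id[coexp_edges$srp_id == rbp]
    models <- motif_models[[rbp]]
    if (is.null(models)) next
    models <- models[vapply(models, function(m)
      !is.null(m) && isTRUE(m$significance < 0.01), TRUE)]
    if (!length(models)) {
      cosplice_log("build_cosplice_network: no significant motif for ", rbp,
                   "; RBP contributes no edges")
      next
    }
    for (tx in targets) {
      if (!tx %in% names(catalog$transcripts)) next
      n_exons <- nrow(catalog$transcripts[[tx]]$exons)
      for (ri in intersect(regions, names(models))) {
        seqs <- r_regions[r_regions$transcript_id == tx &
                            r_regions$region == ri, , drop = FALSE]
        if (!nrow(seqs)) {
          cosplice_log("build_cosplice_network: no ", ri, " sequences for ",
                       tx, "; region skipped")
          next
        }
        p_exon <- rep(NA_real_, nrow(seqs))
        for (i in seq_len(nrow(seqs))) {
          if (nchar(seqs$sequence[i]) < models[[ri]]$width) next
          hit <- best_hit_pvalue(models[[ri]]$pwm, seqs$sequence[i])
          p_exon[i] <- hit$p_value
        }
        hit_flags <- !is.na(p_exon) & p_exon < p_site
        if (!any(hit_flags)) next
        edge_rows[[length(edge_rows) + 1L]] <- data.frame(
          sf_id = rbp, transcript_id = tx, region = ri,
          weight = -log10(min(p_exon[hit_flags])),
          n_exons_with_hit = sum(hit_flags),
          ri_ratio = sum(hit_flags) / n_exons,
          stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edge_rows)) do.call(rbind, edge_rows) else
    data.frame(sf_id = character(), transcript_id = character(),
               region = character(), weight = numeric(),
               n_exons_with_hit = integer(), ri_ratio = numeric(),
               stringsAsFactors = FALSE)
  edges <- edges[order(edges$sf_id, edges$transcript_id, edges$region), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  node_ids <- unique(c(edges$sf_id, edges$transcript_id))
  nodes <- data.frame(
    id = node_ids,
    type = ifelse(node_ids %in% rbps, "SF", "transcript"),
    super_cluster = if (is.null(super_clusters))
      rep(NA_character_, length(node_ids))
    else unname(super_clusters[node_ids]),
    stringsAsFactors = FALSE)
  colors <- setNames(c("#1b9e77", "#d95f02", "#7570b3",
                       "#e7298a", "#66a61e", "#e6ab02"),
                     super_cluster_labels())
  nodes$color <- ifelse(is.na(nodes$super_cluster), "#cccccc",
                        colors[nodes$super_cluster])
  structure(list(nodes = nodes, edges = edges), class = "cosplice_network")
}

#' @export
print.cosplice_network <- function(x, ...) {
  cat(sprintf("<cosplice_network> %d nodes (%d SFs), %d region edges\n",
              nrow(x$nodes), sum(x$nodes$type == "SF"), nrow(x$edges)))
  invisible(x)
}

#' Report genes whose splice variants are spliced differently
#'
#' A gene is differentially spliced when at least one of its splice
#' variants is linked to an RBP in the co-splicing network and at least one
#' other variant either (a) has edges only to different RBPs whose
#' super-cluster labels are all different, or (b) has no RBP edge at all
#' (including stably expressed variants present only in the full catalog).
#'
#' @param net a `cosplice_network`.
#' @param catalog the full `sv_catalog` (links splice variants to genes).
#' @param super_clusters named vector transcript -> super-cluster label
#'   (used for the RBP nodes).
#' @return data.frame, one row per (gene, splice variant): `gene_id`,
#'   `transcript_id`, `rbps` (comma-joined, "" if none), `rbp_super_clusters`
#'   (comma-joined), `no_rbp_edge` flag. Only genes meeting the criterion
#'   appear; zero rows allowed.
#' @export
find_differentially_spliced_genes <- function(net, catalog, super_clusters) {
  edge_by_tx <- split(net$edges$sf_id, net$edges$transcript_id)
  report <- list()
  for (gene in names(catalog$genes)) {
    svs <- catalog$genes[[gene]]
    if (length(svs) < 2) next
    rbps_of <- lapply(svs, function(tx)
      sort(unique(edge_by_tx[[tx]])))
    names(rbps_of) <- svs
    connected <- svs[lengths(rbps_of) > 0]
    if (!length(connected)) next
    qualifies <- FALSE
    for (a in connected) {
      for (b in setdiff(svs, a)) {
        if (!length(rbps_of[[b]])) { qualifies <- TRUE; break }
        if (!length(intersect(rbps_of[[a]], rbps_of[[b]]))) {
          sc_a <- unique(super_clusters[rbps_of[[a]]])
          sc_b <- unique(super_clusters[rbps_of[[b]]])
          if (!length(intersect(sc_a, sc_b))) { qualifies <- TRUE; break }
        }
      }
      if (qualifies) break
    }
    if (!qualifies) next
    for (tx in svs) {
      rb <- rbps_of[[tx]]
      report[[length(report) + 1L]] <- data.frame(
        gene_id = gene, transcript_id = tx,
        rbps = paste(rb, collapse = ","),
        rbp_super_clusters = paste(unique(super_clusters[rb]),
                                   collapse = ","),
        no_rbp_edge = length(rb) == 0L,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(report))
    return(data.frame(gene_id = character(), transcript_id = character(),
                      rbps = character(), rbp_super_clusters = character(),
                      no_rbp_edge = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, report)
  rownames(out) <- NULL
  out
}

#' Export a co-splicing network
#'
#' Supported formats: `graphml` (Cytoscape-loadable, node and edge
#' attributes preserved; written via igraph), `sif` (one line per edge,
#' `SF r<i> transcript`) and `edge-tsv` / `node-tsv` tables. Element order
#' is deterministic.
#'
#' @param net a `cosplice_network`.
#' @param format one of `"graphml"`, `"sif"`, `"edge-tsv"`, `"node-tsv"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, format = c("graphml", "sif", "edge-tsv",
                                           "node-tsv"), path) {
  format <- match.arg(format)
  if (nrow(net$edges) == 0 && format != "node-tsv")
    stop("cannot export an empty network")
  if (format == "graphml") {
    g <- cosplice_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "sif") {
    writeLines(sprintf("%s %s %s", net$edges$sf_id,
                       tolower(net$edges$region), net$edges$transcript_id),
               path)
  } else if (format == "edge-tsv") {
    write.table(net$edges, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    write.table(net$nodes, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Convert a co-splicing network to an igraph object
#' @param net a `cosplice_network`.
#' @return an [igraph::graph] with node/edge attributes.
#' @export
cosplice_igraph <- function(net) {
  igraph::graph_from_data_frame(
    d = net$edges[, c("sf_id", "transcript_id", "region", "weight",
                      "ri_ratio")],
    directed = TRUE, vertices = net$nodes)
}
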