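#' Fit a co-splicing network
#'
#' Runs the whole inference pipeline: differential-expression filtering,
#' z-score + normal-CDF normalization, restarted k-means++ clustering with
#' super-cluster merging, SRP-centered Spearman co-expression (strict
#' `rho > rho_min`, `p < p_max`, positive edges only), extraction of the
#' four 30-nt splice-junction windows for every RBP's co-expressed
#' transcripts, per-(RBP, region) ZOOPS motif discovery with a
#' shuffled-sequence significance gate, PWM scanning with exact per-site
#' p-values, and assembly of the weighted co-splicing network plus the
#' differential-splicing gene report.
#'
#' @param genome a [Biostrings::DNAStringSet] or FASTA path.
#' @param catalog an `sv_catalog` or GTF path.
#' @param expr an `expr_set`, or path to the expression TSV (then
#'   `sample_map` must be the sample-map path).
#' @param srp_ids character vector (or path to a one-id-per-line file) of
#'   splicing-related-protein transcript ids.
#' @param rbp_ids ids (or path) of the SRP subset with RNA-binding domains;
#'   only these seed motif discovery and co-splicing edges.
#' @param sample_map sample-map path when `expr` is a path.
#' @param de_list optional precomputed differentially-expressed transcript
#'   ids; takes precedence over the built-in filter.
#' @param k,n_init,max_iter k-means parameters (see [kmeans_cluster()]);
#'   `k` is capped at the number of differentially expressed transcripts.
#' @param fold,alpha differential-expression filter parameters.
#' @param rho_min,p_max co-expression thresholds.
#' @param widths candidate motif widths.
#' @param n_null shuffled null sets per motif significance assessment.
#' @param n_starts EM restarts per width.
#' @param p_site per-sequence motif hit p-value gate.
#' @param sig_threshold motif significance gate.
#' @param window splice-junction window width (nt).
#' @param phase_threshold on-phase threshold for super-cluster merging.
#' @param seed integer seed controlling clustering restarts and null
#'   shuffles.
#' @return an object of class `cosplicenet` with components
#'   `de_transcripts`, `profiles`, `clusters`, `super_clusters`,
#'   `transcript_super_cluster`, `coexp_edges`, `motif_models` (nested
#'   `[[rbp]][[region]]`), `r_regions`, `network` (a `cosplice_network`),
#'   `ds_report`, and `params`.
#' @export
cosplicenet <- function(genome, catalog, expr, srp_ids, rbp_ids,
                        sample_map = NULL, de_list = NULL,
                        k = 50L, n_init = 50L, max_iter = 1000L,
                        fold = 2, alpha = 0.001,
                        rho_min = 0.95, p_max = 0.001,
                        widths = 4:7, n_null = 100L, n_starts = 20L,
                        p_site = 0.05, sig_threshold = 0.01,
                        window = 30L, phase_threshold = 0.5, seed = 1L) {
  if (is.character(genome)) genome <- read_genome_fasta(genome)
  if (is.character(catalog)) catalog <- read_gtf(catalog)
  if (is.character(expr)) {
    if (is.null(sample_map)) stop("sample_map path required with an expression path")
    expr <- read_expression(expr, sample_map)
  }
  if (is.character(srp_ids) && length(srp_ids) == 1 && file.exists(srp_ids))
    srp_ids <- readLines(srp_ids)
  if (is.character(rbp_ids) && length(rbp_ids) == 1 && file.exists(rbp_ids))
    rbp_ids <- readLines(rbp_ids)

  de <- differential_filter(expr, fold = fold, alpha = alpha,
                            de_list = de_list)
  if (!length(de)) stop("no differentially expressed transcripts")
  profiles <- normalize_zscore_cdf(expr, de)
  srps <- intersect(srp_ids, de)
  rbps <- intersect(rbp_ids, srps)
  if (!length(rbps))
    stop("no RBP is differentially expressed; nothing to infer")

  k_eff <- min(k, nrow(profiles))
  clusters <- kmeans_cluster(profiles, k = k_eff, n_init = n_init,
                             max_iter = max_iter, seed = seed)
  super_clusters <- assign_super_clusters(clusters, expr,
                                          phase_threshold = phase_threshold)
  tx_sc <- attr(super_clusters, "transcripts")

  coexp <- build_coexpression_edges(srps, de, profiles,
                                    rho_min = rho_min, p_max = p_max)

  motif_models <- list()
  r_regions <- NULL
  group_targets <- list()
  for (ri_idx in seq_along(rbps)) {
    rbp <- rbps[ri_idx]
    targets <- coexp$transcript_id[coexp$srp_id == rbp]
    targets <- intersect(targets, names(catalog$transcripts))
    group_targets[[rbp]] <- targets
    if (!length(targets)) next
    regs <- extract_r_regions_all(catalog, genome, targets, window = window)
    r_regions <- rbind(r_regions, regs[!regs$transcript_id %in%
                                         r_regions$transcript_id, ])
    motif_models[[rbp]] <- list()
    for (ri in c("R1", "R2", "R3", "R4")) {
      seqs <- regs$sequence[regs$region == ri &
                              nchar(regs$sequence) >= max(widths)]
      if (length(seqs) < 5) {
        cosplice_log("cosplicenet: <5 usable ", ri, " sequences for ", rbp,
                     "; region skipped")
        next
      }
      model <- tryCatch(
        select_best_motif(seqs, widths = widths,
                          seed = seed + 13L * ri_idx + match(ri, paste0("R", 1:4)),
                          n_null = n_null, n_starts = n_starts,
                          sig_threshold = sig_threshold),
        error = function(e) {
          cosplice_log("cosplicenet: motif fit failed for ", rbp, " ", ri,
                       ": ", conditionMessage(e))
          NULL
        })
      if (!is.null(model)) motif_models[[rbp]][[ri]] <- model
    }
  }

  network <- build_cosplice_network(rbps, coexp, motif_models, r_regions,
                                    catalog, p_site = p_site,
                                    super_clusters = tx_sc)
  ds_report <- find_differentially_spliced_genes(network, catalog, tx_sc)

  structure(list(
    de_transcripts = de, profiles = profiles, clusters = clusters,
    super_clusters = super_clusters, transcript_super_cluster = tx_sc,
    coexp_edges = coexp, motif_models = motif_models,
    r_regions = r_regions, network = network, ds_report = ds_report,
    srps = srps, rbps = rbps,
    params = list(k = k_eff, n_init = n_init, fold = fold, alpha = alpha,
                  rho_min = rho_min, p_max = p_max, widths = widths,
                  n_null = n_null, n_starts = n_starts, p_site = p_site,
                  sig_threshold = sig_threshold, window = window,
                  seed = seed)),
    class = "cosplicenet")
}

#' @export
print.cosplicenet <- function(x, ...) {
  cat("Co-splicing network fit\n")
  cat(sprintf("  differentially expressed transcripts: %d\n",
              length(x$de_transcripts)))
  cat(sprintf("  SRPs retained: %d (RBPs: %d)\n", length(x$srps),
              length(x$rbps)))
  cat(sprintf("  co-expression edges: %d\n", nrow(x$coexp_edges)))
  n_sig <- sum(vapply(x$motif_models, function(ms)
    sum(vapply(ms, function(m) isTRUE(m$significance < x$params$sig_threshold),
               TRUE)), 0L))
  cat(sprintf("  significant (RBP, region) motifs: %d\n", n_sig))
  cat(sprintf("  co-splicing edges: %d across %d transcripts\n",
              nrow(x$network$edges),
              length(unique(x$network$edges$transcript_id))))
  cat(sprintf("  differentially spliced genes: %d\n",
              length(unique(x$ds_report$gene_id))))
  invisible(x)
}

#' @export
summary.cosplicenet <- function(object, ...) {
  sc_tab <- table(object$transcript_super_cluster)
  motifs <- do.call(rbind, lapply(names(object$motif_models), function(rbp) {
    ms <- object$motif_models[[rbp]]
    if (!length(ms)) return(NULL)
    data.frame(rbp = rbp, region = names(ms),
               width = vapply(ms, `[[`, 0L, "width"),
               consensus = vapply(ms, `[[`, "", "consensus_rna"),
               lambda = vapply(ms, `[[`, 0, "zoops_lambda"),
               significance = vapply(ms, `[[`, 0, "significance"),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  edges_per_region <- table(factor(object$network$edges$region,
                                   levels = paste0("R", 1:4)))
  out <- list(super_cluster_sizes = sc_tab, motifs = motifs,
              edges_per_region = edges_per_region,
              ds_genes = unique(object$ds_report$gene_id))
  class(out) <- "summary.cosplicenet"
  out
}

#' @export
print.summary.cosplicenet <- function(x, ...) {
  cat("Super-cluster sizes:\n"); print(x$super_cluster_sizes)
  cat("\nFitted motifs per (RBP, region):\n")
  if (is.null(x$motifs)) cat("  none\n") else print(x$motifs)
  cat("\nCo-splicing edges per region:\n"); print(x$edges_per_region)
  cat("\nDifferentially spliced genes: ",
      if (length(x$ds_genes)) paste(x$ds_genes, collapse = ", ") else "none",
      "\n", sep = "")
  invisible(x)
}

#' Plot a fitted co-splicing network
#'
#' Draws the SF-to-transcript network (SFs as squares, transcripts as
#' circles, nodes tinted by super-cluster, edge width by `-log10(p)`
#' weight) or, with `type = "profiles"`, the normalized cluster centroids.
#'
#' @param x a `cosplicenet` object.
#' @param type `"network"` or `"profiles"`.
#' @param ... passed to [igraph::plot.igraph()] / [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.cosplicenet <- function(x, type = c("network", "profiles"), ...) {
  type <- match.arg(type)
  if (type == "network") {
    if (nrow(x$network$edges) == 0) {
      warning("empty network; nothing to plot")
      return(invisible(x))
    }
    g <- cosplice_igraph(x$network)
    shapes <- ifelse(igraph::V(g)$type == "SF", "square", "circle")
    igraph::plot.igraph(
      g, vertex.shape = shapes, vertex.color = igraph::V(g)$color,
      vertex.size = ifelse(igraph::V(g)$type == "SF", 14, 7),
      vertex.label.cex = 0.6,
      edge.width = igraph::E(g)$weight / 2, edge.arrow.size = 0.3, ...)
  } else {
    graphics::matplot(t(x$clusters$centroids), type = "l", lty = 1,
                      xlab = "time point", ylab = "normalized expression",
                      main = "cluster centroids", ...)
  }
  invisible(x)
}
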