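#' Specification of a synthetic co-splicing test world
#'
#' Defines the study conditions emulated by [generate_world()]: a
#' replicated 7-time-point expression course over three developmental
#' phases, a set of splicing-factor (RBP) genes with co-expressed target
#' transcripts carrying a planted junction motif, decoy genes, splice
#' variants with known peptide/domain differences, and stably expressed
#' variants. All values have defaults chosen to mirror the regime the
#' pipeline is designed for; sizes are kept small enough that the full
#' pipeline runs in minutes.
#'
#' @param n_sf number of splicing-factor (RBP) genes.
#' @param n_srp_extra additional SRP genes that are not RBPs.
#' @param targets_per_sf co-expressed target genes per SF.
#' @param n_decoys decoy genes with independent expression.
#' @param n_ds_pairs genes given a second splice variant targeted by a
#'   different SF (differential splicing ground truth).
#' @param n_stable_pairs genes given a second, stably expressed variant.
#' @param n_diversity_pairs decoy genes given a second variant with known
#'   peptide and domain differences.
#' @param exons_per_transcript integer range `c(min, max)`.
#' @param exon_len,intron_len length ranges in nt (introns >= 60 by
#'   default so no R1/R4 window is truncated).
#' @param planted_motif DNA consensus planted in target junctions (length
#'   4-7).
#' @param mutation_rate per-position probability of mutating a planted
#'   motif copy.
#' @param planted_regions which R regions receive the motif (default "R1").
#' @param plant_fraction fraction of a target's eligible junctions that
#'   receive the motif.
#' @param motif_free_sfs number of SFs (taken from the end of the SF list)
#'   whose targets get no planted motif; their groups must yield no
#'   significant motif downstream.
#' @param time_points number of time points (default 7; points 1-2 are
#'   early maturation, 3-5 middle maturation, 6-7 desiccation).
#' @param replicates biological replicates per time point.
#' @param noise_sd replicate noise standard deviation on the unit template
#'   scale.
#' @param seed RNG seed; the bundle is byte-identical under a fixed seed.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_sf = 4L, n_srp_extra = 2L, targets_per_sf = 12L,
                         n_decoys = 18L, n_ds_pairs = 3L,
                         n_stable_pairs = 2L, n_diversity_pairs = 8L,
                         exons_per_transcript = c(4L, 8L),
                         exon_len = c(100L, 200L), intron_len = c(60L, 150L),
                         planted_motif = "AGGTAAG", mutation_rate = 0.1,
                         planted_regions = "R1", plant_fraction = 0.9,
                         motif_free_sfs = 1L, time_points = 7L,
                         replicates = 3L, noise_sd = 0.005, seed = 1L) {
  stopifnot(nchar(planted_motif) >= 4, nchar(planted_motif) <= 7,
            grepl("^[ACGT]+$", planted_motif),
            plant_fraction > 0, plant_fraction <= 1,
            intron_len[1] >= nchar(planted_motif),
            all(planted_regions %in% c("R1", "R2", "R3", "R4")))
  if (nchar(planted_motif) > 30)
    stop("planted motif longer than the 30-nt window")
  structure(as.list(environment()), class = "fixture_spec")
}

#' The six developmental-phase archetype profiles
#'
#' Seven-point templates, one per super-cluster, high during the phase(s)
#' the label names (time points 1-2 early maturation, 3-5 middle
#' maturation, 6-7 desiccation). Values within a template are pairwise
#' distinct so rank-based correlation is well defined, and noise-free
#' copies are separable by k-means with k = 6.
#'
#' @return named list of numeric length-7 templates; names are the
#'   super-cluster labels of [super_cluster_labels()].
#' @export
archetype_profiles <- function() {
  setNames(list(
    c(0.95, 0.85, 0.30, 0.20, 0.25, 0.10, 0.15),
    c(0.90, 0.80, 0.95, 0.85, 0.70, 0.15, 0.05),
    c(0.15, 0.25, 0.90, 0.95, 0.85, 0.20, 0.10),
    c(0.10, 0.20, 0.80, 0.90, 0.70, 0.95, 0.85),
    c(0.15, 0.05, 0.25, 0.10, 0.20, 0.90, 0.95),
    c(0.90, 0.95, 0.20, 0.10, 0.15, 0.80, 0.85)),
    super_cluster_labels())
}

.softplus <- function(x) log1p(exp(x))

# strictly monotone affine-plus-softplus link; exercises rank invariance
.monotone_link <- function(x) {
  a <- runif(1, 0, 0.1); b <- runif(1, 0.8, 1.2); k <- runif(1, 2, 4)
  a + b * .softplus(k * x)
}

.mutate_motif <- function(motif, rate) {
  letters <- strsplit(motif, "")[[1]]
  for (i in seq_along(letters)) {
    if (runif(1) < rate)
      letters[i] <- sample(setdiff(c("A", "C", "G", "T"), letters[i]), 1)
  }
  paste(letters, collapse = "")
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# tryptophan is reserved as the guaranteed-mismatch letter for variant
# peptides, so random peptides draw from the other 19 amino acids
.random_peptide <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

#' Generate a fully self-contained synthetic test world
#'
#' Writes a random genome (FASTA) with multi-exon gene models (GTF), a
#' replicated time-course expression matrix with SF-correlated target
#' groups (TSV + sample map), SRP/RBP id lists, synthetic peptides with
#' conserved-domain hits and coding labels, and ground-truth tables (under
#' `truth/`) sufficient to score every pipeline stage: planted
#' co-expression edges, co-splicing edges, motif positions, expression
#' archetypes, differential-splicing genes and protein-diversity classes.
#'
#' Targets receive a strictly monotone (affine-plus-softplus) transform of
#' their SF's archetype template plus replicate noise, guaranteeing near-1
#' Spearman correlation at low noise; decoys get independent random
#' profiles; stable variants are flat. Planted motif copies are mutated
#' per position at `mutation_rate` and placed at random offsets inside the
#' designated R windows.
#'
#' @param spec a `fixture_spec`.
#' @param dir output directory (created if needed).
#' @return list with file paths (`genome`, `gtf`, `expression`,
#'   `sample_map`, `srp_ids`, `rbp_ids`, `peptides`, `domains`,
#'   `coding_labels`, `truth_dir`) and in-memory ground truth
#'   (`truth$coexp_edges`, `truth$cosplice_edges`, `truth$motif_positions`,
#'   `truth$archetypes`, `truth$ds_genes`, `truth$diversity`,
#'   `truth$stable`).
#' @export
generate_world <- function(spec = fixture_spec(), dir = tempfile("world")) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth_dir <- file.path(dir, "truth")
  dir.create(truth_dir, showWarnings = FALSE)
  w <- nchar(spec$planted_motif)
  arch <- archetype_profiles()

  ## ---- gene roles ----------------------------------------------------
  sf_genes <- sprintf("SF%02d", seq_len(spec$n_sf))
  srp_genes <- if (spec$n_srp_extra > 0)
    sprintf("SRP%02d", seq_len(spec$n_srp_extra)) else character()
  target_genes <- sprintf("TG%03d", seq_len(spec$n_sf * spec$targets_per_sf))
  sf_of_target <- rep(sf_genes, each = spec$targets_per_sf)
  decoy_genes <- sprintf("DC%03d", seq_len(spec$n_decoys))
  all_genes <- c(sf_genes, srp_genes, target_genes, decoy_genes)
  # SF archetypes: spread over the six labels so ds-paired SFs differ
  sf_arch <- setNames(names(arch)[(seq_along(c(sf_genes, srp_genes)) - 1L) %%
                                    length(arch) + 1L],
                      c(sf_genes, srp_genes))
  planting_sfs <- head(sf_genes, spec$n_sf - spec$motif_free_sfs)
  # differential-splicing pairs: first n_ds_pairs targets of SF1 get a
  # second variant targeted by SF2 (shifted acceptor sites -> disjoint
  # junction windows); stable pairs get a flat second variant.
  ds_genes <- head(target_genes[sf_of_target == sf_genes[1]],
                   spec$n_ds_pairs)
  ds_partner_sf <- sf_genes[2]
  stable_genes <- head(target_genes[sf_of_target == sf_genes[min(2, spec$n_sf)]],
                       spec$n_stable_pairs)
  diversity_genes <- head(decoy_genes, spec$n_diversity_pairs)

  ## ---- genome and transcript structures ------------------------------
  chrom <- "chr1"
  spacer <- 100L
  cursor <- spacer
  seq_chunks <- list(.random_dna(spacer))
  transcripts <- list()
  add_tx <- function(id, gene, strand, exons) {
    transcripts[[id]] <<- .new_transcript_model(id, gene, chrom, strand,
                                                exons)
  }
  for (gene in all_genes) {
    strand <- sample(c("+", "-"), 1)
    n_ex <- sample(spec$exons_per_transcript[1]:spec$exons_per_transcript[2], 1)
    elens <- sample(spec$exon_len[1]:spec$exon_len[2], n_ex, replace = TRUE)
    ilens <- if (n_ex > 1)
      sample(spec$intron_len[1]:spec$intron_len[2], n_ex - 1L,
             replace = TRUE) else integer()
    starts <- cursor + c(0L, cumsum(elens[-n_ex] + ilens))
    exons <- cbind(start = starts, end = starts + elens)
    glen <- sum(elens) + sum(ilens)
    seq_chunks[[length(seq_chunks) + 1L]] <- .random_dna(glen + spacer)
    cursor <- cursor + glen + spacer
    add_tx(paste0(gene, ".1"), gene, strand, exons)
    if (gene %in% ds_genes) {
      # alternative acceptors: every exon except the transcript-first one
      # has its acceptor shifted 60 nt into the exon (transcript sense), so
      # SV2 junction windows are disjoint from SV1's
      ex2 <- exons
      if (strand == "+") ex2[-1L, "start"] <- ex2[-1L, "start"] + 60L
      else ex2[-nrow(ex2), "end"] <- ex2[-nrow(ex2), "end"] - 60L
      # genomic order of rows is preserved; re-sorting happens in the model
      add_tx(paste0(gene, ".2"), gene, strand, ex2)
    }
    if (gene %in% stable_genes || gene %in% diversity_genes) {
      # exon-skipping variant: drop one internal exon
      drop <- sample(2:(n_ex - 1L), 1)
      add_tx(paste0(gene, ".2"), gene, strand,
             exons[-drop, , drop = FALSE])
    }
  }
  genome_str <- paste(unlist(seq_chunks), collapse = "")
  catalog <- .new_sv_catalog(transcripts[order(names(transcripts))])

  ## ---- motif planting ------------------------------------------------
  # window coordinates in transcript sense; sequence written back
  # strand-resolved so the motif reads 5'->3' on the pre-mRNA
  plant_rows <- list()
  plant_into <- function(tx_id, sf) {
    t <- catalog$transcripts[[tx_id]]
    ex <- t$exons
    n_ex <- nrow(ex)
    for (i in seq_len(n_ex)) {               # i is transcript-sense index
      for (ri in spec$planted_regions) {
        # junction-adjacent windows only: R1/R2 need an upstream intron,
        # R3/R4 a downstream one
        if (ri %in% c("R1", "R2") && i == 1L) next
        if (ri %in% c("R3", "R4") && i == n_ex) next
        if (runif(1) > spec$plant_fraction) next
        win <- switch(ri,
          R1 = if (t$strand == "+") c(ex[i, "start"] - 30L, ex[i, "start"])
               else c(ex[i, "end"], ex[i, "end"] + 30L),
          R2 = if (t$strand == "+") c(ex[i, "start"], ex[i, "start"] + 30L)
               else c(ex[i, "end"] - 30L, ex[i, "end"]),
          R3 = if (t$strand == "+") c(ex[i, "end"] - 30L, ex[i, "end"])
               else c(ex[i, "start"], ex[i, "start"] + 30L),
          R4 = if (t$strand == "+") c(ex[i, "end"], ex[i, "end"] + 30L)
               else c(ex[i, "start"] - 30L, ex[i, "start"]))
        offset <- sample(0:(30L - w), 1)
        copy <- .mutate_motif(spec$planted_motif, spec$mutation_rate)
        cur <- substr(genome_str, win[1] + 1L, win[2])
        sense <- if (t$strand == "+") cur else revcomp(cur)
        substr(sense, offset + 1L, offset + w) <- copy
        written <- if (t$strand == "+") sense else revcomp(sense)
        substr(genome_str, win[1] + 1L, win[2]) <<- written
        plant_rows[[length(plant_rows) + 1L]] <<- data.frame(
          sf_id = paste0(sf, ".1"), transcript_id = tx_id,
          exon_index = i - 1L, region = ri, offset = offset,
          motif_copy = copy, stringsAsFactors = FALSE)
      }
    }
  }
  for (j in seq_along(target_genes)) {
    sf <- sf_of_target[j]
    if (sf %in% planting_sfs)
      plant_into(paste0(target_genes[j], ".1"), sf)
  }
  if (ds_partner_sf %in% planting_sfs)
    for (g in ds_genes) plant_into(paste0(g, ".2"), ds_partner_sf)
  motif_positions <- if (length(plant_rows)) do.call(rbind, plant_rows) else
    data.frame(sf_id = character(), transcript_id = character(),
               exon_index = integer(), region = character(),
               offset = integer(), motif_copy = character())

  ## ---- expression ----------------------------------------------------
  tps <- seq_len(spec$time_points)
  phase_of <- ifelse(tps <= 2, "early", ifelse(tps <= 5, "middle",
                                               "desiccation"))
  sample_map <- data.frame(
    sample_id = sprintf("t%d_r%d", rep(tps, each = spec$replicates),
                        rep(seq_len(spec$replicates), spec$time_points)),
    time_point = rep(tps, each = spec$replicates),
    replicate = rep(seq_len(spec$replicates), spec$time_points),
    phase = rep(phase_of, each = spec$replicates),
    stringsAsFactors = FALSE)
  template_of <- list()
  arch_of <- character()
  for (g in c(sf_genes, srp_genes)) {
    template_of[[paste0(g, ".1")]] <- arch[[sf_arch[[g]]]][tps]
    arch_of[paste0(g, ".1")] <- sf_arch[[g]]
  }
  for (j in seq_along(target_genes)) {
    sf <- sf_of_target[j]
    tx <- paste0(target_genes[j], ".1")
    template_of[[tx]] <- .monotone_link(arch[[sf_arch[[sf]]]][tps])
    arch_of[tx] <- sf_arch[[sf]]
  }
  for (g in ds_genes) {
    tx <- paste0(g, ".2")
    template_of[[tx]] <- .monotone_link(arch[[sf_arch[[ds_partner_sf]]]][tps])
    arch_of[tx] <- sf_arch[[ds_partner_sf]]
  }
  for (g in stable_genes)
    template_of[[paste0(g, ".2")]] <- rep(0.5, spec$time_points)
  for (g in decoy_genes) {
    template_of[[paste0(g, ".1")]] <- runif(spec$time_points, 0.05, 0.95)
    if (g %in% diversity_genes)
      template_of[[paste0(g, ".2")]] <- runif(spec$time_points, 0.05, 0.95)
  }
  tx_ids <- names(catalog$transcripts)
  values <- matrix(0, nrow = length(tx_ids), ncol = nrow(sample_map),
                   dimnames = list(tx_ids, sample_map$sample_id))
  for (tx in tx_ids) {
    tmpl <- template_of[[tx]]
    for (s in seq_len(nrow(sample_map))) {
      tp <- sample_map$time_point[s]
      values[tx, s] <- max(0, (tmpl[tp] + rnorm(1, 0, spec$noise_sd)) * 100)
    }
  }

  ## ---- peptides, domains, coding labels ------------------------------
  pep_rows <- list(); dom_rows <- list(); div_rows <- list()
  coding <- setNames(rep("coding", length(tx_ids)), tx_ids)
  dom_cycle <- c("identical", "similar", "disparate", "none")
  for (j in seq_along(diversity_genes)) {
    g <- diversity_genes[j]
    canon <- paste0(g, ".1"); var <- paste0(g, ".2")
    dclass <- dom_cycle[(j - 1L) %% 4L + 1L]
    mismatch <- j %% 2L == 0L
    L1 <- sample(150:300, 1)
    x1 <- .random_peptide(L1)
    # short variants (ratio < 0.7) carry domain loss/truncation; long ones
    # keep their domains intact
    cut_len <- if (dclass == "disparate")
      sample(round(0.50 * L1):round(0.55 * L1), 1)
    else if (dclass == "similar")
      sample(round(0.35 * L1):round(0.5 * L1), 1)
    else sample(round(0.05 * L1):round(0.2 * L1), 1)
    cut_at <- sample(seq_len(L1 - cut_len - 10L) + 5L, 1)
    x2 <- paste0(substr(x1, 1, cut_at - 1L),
                 substr(x1, cut_at + cut_len, L1))
    if (mismatch) substr(x2, 3, 3) <- "W"   # W never occurs otherwise
    L2 <- nchar(x2)
    pep_rows[[canon]] <- x1; pep_rows[[var]] <- x2
    if (dclass == "identical") {
      dom_rows[[length(dom_rows) + 1L]] <- data.frame(
        isoform_id = c(canon, var), domain_accession = "pfam001",
        start = c(5L, 5L), end = c(5L + 60L, 5L + 60L),
        hit_class = "specific", stringsAsFactors = FALSE)
    } else if (dclass == "similar") {
      dom_rows[[length(dom_rows) + 1L]] <- data.frame(
        isoform_id = c(canon, var), domain_accession = "pfam001",
        start = c(5L, 5L), end = c(5L + 80L, 5L + 40L),
        hit_class = "specific", stringsAsFactors = FALSE)
    } else if (dclass == "disparate") {
      dom_rows[[length(dom_rows) + 1L]] <- data.frame(
        isoform_id = c(canon, canon, var),
        domain_accession = c("pfam001", "pfam002", "pfam001"),
        start = c(5L, 90L, 5L), end = c(55L, 130L, 55L),
        hit_class = c("specific", "superfamily", "specific"),
        stringsAsFactors = FALSE)
    }
    if (L2 / L1 < 0.5) coding[var] <- "noncoding"
    div_rows[[length(div_rows) + 1L]] <- data.frame(
      gene_id = g, canonical_id = canon, variant_id = var,
      peptide_ratio = L2 / L1,
      alignment_class = if (mismatch) "has_mismatch" else "gaps_only",
      domain_class = dclass, stringsAsFactors = FALSE)
  }
  peptides <- unlist(pep_rows)
  domain_hits <- if (length(dom_rows)) do.call(rbind, dom_rows) else
    data.frame(isoform_id = character(), domain_accession = character(),
               start = integer(), end = integer(), hit_class = character())
  diversity <- if (length(div_rows)) do.call(rbind, div_rows) else NULL

  ## ---- ground truth --------------------------------------------------
  coexp_edges <- rbind(
    data.frame(sf_id = paste0(sf_of_target, ".1"),
               transcript_id = paste0(target_genes, ".1"),
               stringsAsFactors = FALSE),
    data.frame(sf_id = paste0(ds_partner_sf, ".1"),
               transcript_id = paste0(ds_genes, ".2"),
               stringsAsFactors = FALSE))
  planted_pairs <- unique(motif_positions[, c("sf_id", "transcript_id",
                                              "region")])
  ds_truth <- data.frame(gene_id = c(ds_genes, stable_genes),
                         kind = c(rep("two_sfs", length(ds_genes)),
                                  rep("stable_partner", length(stable_genes))),
                         stringsAsFactors = FALSE)

  ## ---- write files ---------------------------------------------------
  paths <- list(
    genome = file.path(dir, "genome.fasta"),
    gtf = file.path(dir, "annotation.gtf"),
    expression = file.path(dir, "expression.tsv"),
    sample_map = file.path(dir, "sample_map.tsv"),
    srp_ids = file.path(dir, "srp_ids.txt"),
    rbp_ids = file.path(dir, "rbp_ids.txt"),
    peptides = file.path(dir, "peptides.fasta"),
    domains = file.path(dir, "domains.tsv"),
    coding_labels = file.path(dir, "coding_labels.tsv"),
    truth_dir = truth_dir)
  gseq <- Biostrings::DNAStringSet(setNames(genome_str, chrom))
  Biostrings::writeXStringSet(gseq, paths$genome)
  write_gtf(catalog, paths$gtf)
  expr_tab <- data.frame(transcript_id = rownames(values),
                         apply(values, 2, function(col) sprintf("%.6f", col)),
                         check.names = FALSE, stringsAsFactors = FALSE)
  write.table(expr_tab, paths$expression, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sample_map, paths$sample_map, sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(paste0(c(sf_genes, srp_genes), ".1"), paths$srp_ids)
  writeLines(paste0(sf_genes, ".1"), paths$rbp_ids)
  if (length(peptides)) {
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(peptides), paths$peptides)
  } else writeLines(character(), paths$peptides)
  write.table(domain_hits, paths$domains, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(isoform_id = names(coding), label = unname(coding)),
              paths$coding_labels, sep = "\t", quote = FALSE,
              row.names = FALSE)
  tw <- function(df, name) write.table(df, file.path(truth_dir, name),
                                       sep = "\t", quote = FALSE,
                                       row.names = FALSE)
  tw(coexp_edges, "coexp_edges.tsv")
  tw(planted_pairs, "cosplice_edges.tsv")
  tw(motif_positions, "motif_positions.tsv")
  tw(data.frame(transcript_id = names(arch_of), archetype = unname(arch_of)),
     "archetypes.tsv")
  tw(ds_truth, "ds_genes.tsv")
  if (!is.null(diversity)) tw(diversity, "diversity.tsv")
  tw(data.frame(transcript_id = paste0(stable_genes, ".2")), "stable.tsv")

  c(paths,
    list(truth = list(coexp_edges = coexp_edges,
                      cosplice_edges = planted_pairs,
                      motif_positions = motif_positions,
                      archetypes = arch_of, ds_genes = ds_truth,
                      diversity = diversity,
                      stable = paste0(stable_genes, ".2")),
         spec = spec, rbps = paste0(sf_genes, ".1"),
         srps = paste0(c(sf_genes, srp_genes), ".1"),
         planting_sfs = paste0(planting_sfs, ".1")))
}
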