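#' Peptide length ratio of a splice-variant isoform pair
#'
#' Length of the non-canonical isoform divided by the length of the
#' canonical isoform.
#'
#' @param x1 canonical peptide (character string).
#' @param x2 variant peptide.
#' @return positive number.
#' @export
peptide_ratio <- function(x1, x2) {
  if (!nzchar(x1) || !nzchar(x2)) stop("empty peptide")
  nchar(x2) / nchar(x1)
}

#' Match-only global alignment score
#'
#' Maximum number of matches in a global alignment with match = 1 and no
#' mismatch or gap penalty; mathematically the length of the longest common
#' subsequence, computed by dynamic programming. Only the score is defined,
#' not a unique alignment.
#'
#' @param x1,x2 non-empty peptide strings.
#' @return integer score, at most `min(nchar(x1), nchar(x2))`.
#' @export
match_only_alignment_score <- function(x1, x2) {
  if (!nzchar(x1) || !nzchar(x2)) stop("empty peptide")
  lcs_length_cpp(x1, x2)
}

#' Classify an isoform pair by its match-only alignment score
#'
#' `gaps_only` when the score equals the length of the shorter peptide (the
#' variant differs from the canonical only by insertions/deletions);
#' `has_mismatch` otherwise. The comparison uses `min(len(X1), len(X2))`;
#' when the variant is longer than the canonical this is logged, as the
#' variant-length rule alone would misclassify that case.
#'
#' @param score score from [match_only_alignment_score()].
#' @param x1,x2 the aligned peptides.
#' @return `"gaps_only"` or `"has_mismatch"`.
#' @export
classify_alignment <- function(score, x1, x2) {
  ref_len <- min(nchar(x1), nchar(x2))
  if (score > ref_len) stop("alignment score exceeds shorter peptide length")
  if (nchar(x2) > nchar(x1))
    cosplice_log("classify_alignment: variant longer than canonical; ",
                 "comparing score to the shorter length")
  if (score == ref_len) "gaps_only" else "has_mismatch"
}

# deduplicate overlapping hits of one accession, preferring specific over
# superfamily
.dedup_domain_hits <- function(hits) {
  if (!nrow(hits)) return(hits)
  hits <- hits[order(hits$domain_accession, hits$start,
                     match(hits$hit_class, c("specific", "superfamily"))), ,
               drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (acc in unique(hits$domain_accession)) {
    idx <- which(hits$domain_accession == acc & keep)
    if (length(idx) < 2) next
    for (a in idx) {
      if (!keep[a]) next
      for (b in idx[idx > a]) {
        if (!keep[b]) next
        if (hits$start[b] <= hits$end[a] && hits$end[b] >= hits$start[a]) {
          # overlap: keep the higher class (specific beats superfamily)
          drop_b <- !(hits$hit_class[b] == "specific" &&
                        hits$hit_class[a] != "specific")
          keep[if (drop_b) b else a] <- FALSE
          cosplice_log("classify_domains: overlapping duplicate hits for ",
                       acc, "; deduplicated")
        }
      }
    }
  }
  hits[keep, , drop = FALSE]
}

#' Compare conserved-domain content of two protein isoforms
#'
#' Hits must already be filtered to specific and superfamily classes.
#' Classes: `none` when both isoforms have no domains; `disparate` when the
#' multisets of domain accessions differ; `identical` when accession
#' multisets match and every per-accession paired hit (paired by start
#' coordinate order) has equal interval length; `similar` when accession
#' multisets match but at least one paired hit is shorter in one isoform
#' (truncated).
#'
#' @param hits1,hits2 data.frames with columns `domain_accession`, `start`,
#'   `end`, `hit_class` for the two isoforms (zero rows allowed).
#' @return one of `"none"`, `"disparate"`, `"identical"`, `"similar"`.
#' @export
classify_domains <- function(hits1, hits2) {
  empty <- data.frame(domain_accession = character(), start = integer(),
                      end = integer(), hit_class = character(),
                      stringsAsFactors = FALSE)
  if (is.null(hits1)) hits1 <- empty
  if (is.null(hits2)) hits2 <- empty
  hits1 <- .dedup_domain_hits(hits1)
  hits2 <- .dedup_domain_hits(hits2)
  if (!nrow(hits1) && !nrow(hits2)) return("none")
  acc1 <- sort(hits1$domain_accession)
  acc2 <- sort(hits2$domain_accession)
  if (length(acc1) != length(acc2) || any(acc1 != acc2)) return("disparate")
  truncated <- FALSE
  for (acc in unique(acc1)) {
    h1 <- hits1[hits1$domain_accession == acc, , drop = FALSE]
    h2 <- hits2[hits2$domain_accession == acc, , drop = FALSE]
    h1 <- h1[order(h1$start), , drop = FALSE]
    h2 <- h2[order(h2$start), , drop = FALSE]
    len1 <- h1$end - h1$start + 1L
    len2 <- h2$end - h2$start + 1L
    if (any(len1 != len2)) truncated <- TRUE
  }
  if (truncated) "similar" else "identical"
}

#' Compare every splice variant of a gene against the canonical isoform
#'
#' @param catalog an `sv_catalog` (defines gene membership and canonical
#'   flags).
#' @param peptides named character vector of peptide sequences keyed by
#'   isoform id.
#' @param domain_hits data.frame with `isoform_id`, `domain_accession`,
#'   `start`, `end`, `hit_class` (pre-filtered to specific/superfamily).
#' @param coding_labels optional named vector isoform -> "coding" or
#'   "noncoding".
#' @return data.frame of class `isoform_comparisons`, one row per
#'   (canonical, variant) pair: `gene_id`, `canonical_id`, `variant_id`,
#'   `peptide_ratio`, `alignment_score`, `alignment_class`, `domain_class`,
#'   `coding_pair`.
#' @export
compare_isoforms <- function(catalog, peptides, domain_hits = NULL,
                             coding_labels = NULL) {
  if (is.null(domain_hits))
    domain_hits <- data.frame(isoform_id = character(),
                              domain_accession = character(),
                              start = integer(), end = integer(),
                              hit_class = character(),
                              stringsAsFactors = FALSE)
  hit_split <- split(domain_hits, domain_hits$isoform_id)
  rows <- list()
  for (gene in names(catalog$genes)) {
    svs <- catalog$genes[[gene]]
    canon <- catalog$canonical[[gene]]
    variants <- setdiff(svs, canon)
    if (!length(variants)) next
    if (!canon %in% names(peptides)) next
    for (v in variants) {
      if (!v %in% names(peptides)) next
      x1 <- peptides[[canon]]; x2 <- peptides[[v]]
      score <- match_only_alignment_score(x1, x2)
      cp <- if (is.null(coding_labels)) NA_character_ else {
        lab <- sort(c(coding_labels[[canon]], coding_labels[[v]]))
        if (all(lab == "coding")) "both_coding"
        else if (all(lab == "noncoding")) "both_noncoding"
        else "coding_noncoding"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene, canonical_id = canon, variant_id = v,
        peptide_ratio = peptide_ratio(x1, x2),
        alignment_score = score,
        alignment_class = classify_alignment(score, x1, x2),
        domain_class = classify_domains(hit_split[[canon]], hit_split[[v]]),
        coding_pair = cp, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), canonical_id = character(),
               variant_id = character(), peptide_ratio = numeric(),
               alignment_score = integer(), alignment_class = character(),
               domain_class = character(), coding_pair = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("isoform_comparisons", class(out))
  out
}

#' Cross-tabulate isoform-diversity classes
#'
#' Dense cross-tabulations (zero rows kept) of domain class against coding
#' pair and against peptide-length-ratio bins.
#'
#' @param comparisons data.frame from [compare_isoforms()].
#' @param ratio_breaks breaks for peptide-ratio binning.
#' @return list of two tables: `by_coding`, `by_ratio`.
#' @export
summarize_diversity <- function(comparisons,
                                ratio_breaks = c(0, 0.25, 0.5, 0.75, 1,
                                                 Inf)) {
  if (!nrow(comparisons)) stop("no comparisons to summarize")
  dom <- factor(comparisons$domain_class,
                levels = c("identical", "similar", "disparate", "none"))
  coding <- factor(comparisons$coding_pair,
                   levels = c("both_coding", "coding_noncoding",
                              "both_noncoding"))
  ratio_bin <- cut(comparisons$peptide_ratio, breaks = ratio_breaks,
                   include.lowest = FALSE, right = TRUE)
  list(by_coding = table(domain_class = dom, coding_pair = coding),
       by_ratio = table(domain_class = dom, peptide_ratio = ratio_bin))
}

#' Read peptide sequences from FASTA
#' @param path FASTA path.
#' @return named character vector of peptide strings.
#' @export
read_peptides <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
}

#' Read a conserved-domain hit table
#'
#' TSV with columns `isoform_id`, `domain_accession`, `start`, `end`,
#' `hit_class` (CD-Search-style; keep only specific and superfamily hits
#' upstream).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_domain_hits <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("isoform_id", "domain_accession", "start", "end", "hit_class")
  if (!all(need %in% names(tab)))
    stop("domain table needs columns: ", paste(need, collapse = ", "))
  bad <- tab$start < 1 | tab$end < tab$start
  if (any(bad)) stop("invalid domain interval at row ", which(bad)[1])
  tab
}

#' Translate the longest open reading frame of a transcript sequence
#'
#' Convenience only: scans the three sense-strand frames for the longest
#' ATG..stop open reading frame and translates it with the standard code.
#' Annotated or predicted peptides should be preferred when available;
#' peptides produced this way are flagged by the `predicted` attribute.
#'
#' @param seq mRNA/cDNA sequence (DNA alphabet, sense strand).
#' @return peptide string (possibly empty if no ORF), with attribute
#'   `predicted = TRUE`.
#' @export
translate_longest_orf <- function(seq) {
  dna <- Biostrings::DNAString(seq)
  best <- ""
  for (frame in 0:2) {
    sub <- Biostrings::subseq(dna, start = frame + 1L)
    sub <- Biostrings::subseq(sub, 1L, 3L * (length(sub) %/% 3L))
    if (length(sub) < 3L) next
    aa <- as.character(Biostrings::translate(sub, no.init.codon = TRUE))
    # ORFs: from each M to the next stop (or sequence end)
    starts <- gregexpr("M", aa)[[1]]
    if (starts[1] == -1) next
    stops <- c(gregexpr("\\*", aa)[[1]], nchar(aa) + 1L)
    for (s in starts) {
      e <- stops[stops >= s][1]
      orf <- substr(aa, s, e - 1L)
      if (nchar(orf) > nchar(best)) best <- orf
    }
  }
  structure(best, predicted = TRUE)
}
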