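#' Transcript models and the splice-variant catalog
#'
#' A transcript model records the ordered exon structure of one splice
#' variant: `transcript_id`, `gene_id`, `chrom`, `strand` and an exon matrix
#' (columns `start`, `end`; 0-based half-open genomic coordinates) sorted in
#' transcription order, i.e. 5'->3' along the transcript. A catalog groups
#' all transcript models by gene and flags one canonical splice variant per
#' gene: the known transcript with the lowest isoform suffix number. Novel
#' variants (suffix `.N<k>`) sort after all numeric suffixes and can never be
#' canonical.
#'
#' @name sv_catalog
NULL

# Sort key for isoform suffixes: numeric suffixes ascending, then N<k>
# suffixes by k, then anything else lexicographically.
.isoform_rank <- function(transcript_ids) {
  suffix <- sub("^.*\\.", "", transcript_ids)
  has_dot <- grepl("\\.", transcript_ids)
  suffix[!has_dot] <- ""
  num <- suppressWarnings(as.numeric(suffix))
  nk <- suppressWarnings(as.numeric(sub("^N", "", suffix)))
  nk[!grepl("^N[0-9]+$", suffix)] <- NA
  cls <- ifelse(!is.na(num), 0L, ifelse(!is.na(nk), 1L, 2L))
  ord <- order(cls, ifelse(is.na(num), ifelse(is.na(nk), NA, nk), num),
               transcript_ids, na.last = TRUE)
  rank <- integer(length(transcript_ids))
  rank[ord] <- seq_along(transcript_ids)
  rank
}

.new_transcript_model <- function(transcript_id, gene_id, chrom, strand, exons) {
  stopifnot(strand %in% c("+", "-"), is.matrix(exons), ncol(exons) == 2)
  colnames(exons) <- c("start", "end")
  if (any(exons[, "end"] <= exons[, "start"]))
    stop("transcript ", transcript_id, ": empty or inverted exon interval")
  # sort genomically, check non-overlap, then flip to transcription order
  o <- order(exons[, "start"])
  exons <- exons[o, , drop = FALSE]
  if (nrow(exons) > 1 &&
      any(exons[-1, "start"] < exons[-nrow(exons), "end"]))
    stop("transcript ", transcript_id, ": overlapping exons")
  if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id,
         chrom = chrom, strand = strand, exons = exons),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (gene %s) %s%s, %d exon(s)\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand, nrow(x$exons)))
  invisible(x)
}

.new_sv_catalog <- function(transcripts) {
  gene_ids <- vapply(transcripts, `[[`, "", "gene_id")
  genes <- split(names(transcripts), gene_ids)
  canonical <- vapply(genes, function(txs) {
    known <- txs[!grepl("\\.N[0-9]+$", txs)]
    pool <- if (length(known)) known else txs
    pool[which.min(.isoform_rank(pool))]
  }, "")
  structure(list(transcripts = transcripts, genes = genes,
                 canonical = canonical),
            class = "sv_catalog")
}

#' @export
print.sv_catalog <- function(x, ...) {
  cat(sprintf("<sv_catalog> %d transcripts in %d genes\n",
              length(x$transcripts), length(x$genes)))
  invisible(x)
}

#' Read exon models from a GTF file
#'
#' Parses exon features (attributes `gene_id`, `transcript_id`) into a
#' splice-variant catalog. Exons are grouped per transcript and stored in
#' transcription order with 0-based half-open coordinates (GTF is 1-based
#' closed on disk). Transcript features with no exon records are rejected and
#' logged. One canonical transcript per gene is flagged by lowest isoform
#' suffix number.
#'
#' @param path path to a GTF file (plain or gzip).
#' @return an object of class `sv_catalog` with elements `transcripts`
#'   (named list of `transcript_model`), `genes` (gene -> transcript ids)
#'   and `canonical` (gene -> canonical transcript id).
#' @export
read_gtf <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) {
      lines <- readLines(path, warn = FALSE)
      body <- !grepl("^#", lines) & nzchar(lines)
      nfield <- lengths(strsplit(lines, "\t", fixed = TRUE))
      bad <- which(body & nfield < 9L)
      if (length(bad))
        stop("malformed GTF line ", bad[1], " in ", path, call. = FALSE)
      stop("failed to parse GTF ", path, ": ", conditionMessage(e),
           call. = FALSE)
    })
  meta <- S4Vectors::mcols(gr)
  is_exon <- meta$type == "exon"
  if (!any(is_exon)) stop("no exon features in ", path)
  ex <- gr[is_exon]
  exm <- S4Vectors::mcols(ex)
  if (is.null(exm$transcript_id) || is.null(exm$gene_id) ||
      anyNA(exm$transcript_id) || anyNA(exm$gene_id))
    stop("exon feature missing gene_id/transcript_id attribute in ", path)
  # transcript feature lines with zero exon children -> rejected, logged
  declared <- unique(S4Vectors::mcols(gr)$transcript_id[meta$type == "transcript"])
  declared <- declared[!is.na(declared)]
  orphans <- setdiff(declared, unique(exm$transcript_id))
  for (tx in orphans)
    cosplice_log("read_gtf: transcript ", tx, " has zero exons; rejected")

  idx <- split(seq_along(ex), exm$transcript_id)
  transcripts <- lapply(names(idx), function(tx) {
    i <- idx[[tx]]
    .new_transcript_model(
      transcript_id = tx,
      gene_id = exm$gene_id[i[1]],
      chrom = as.character(GenomicRanges::seqnames(ex)[i[1]]),
      strand = as.character(GenomicRanges::strand(ex)[i[1]]),
      exons = cbind(start = GenomicRanges::start(ex)[i] - 1L,
                    end = GenomicRanges::end(ex)[i]))
  })
  names(transcripts) <- names(idx)
  .new_sv_catalog(transcripts[order(names(transcripts))])
}

#' Write a catalog back to GTF
#'
#' Emits one exon line per exon with `gene_id`/`transcript_id` attributes,
#' 1-based closed coordinates, deterministic order (transcript id, then
#' genomic start). Re-reading the file reproduces the catalog.
#'
#' @param catalog an `sv_catalog`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(catalog, path) {
  lines <- unlist(lapply(catalog$transcripts[order(names(catalog$transcripts))],
                         function(t) {
    ex <- t$exons[order(t$exons[, "start"]), , drop = FALSE]
    sprintf("%s\tcosplice\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
            t$chrom, ex[, "start"] + 1L, ex[, "end"], t$strand,
            t$gene_id, t$transcript_id)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Introns of a transcript model
#'
#' Gaps between transcription-adjacent exons, in transcription order and
#' 0-based half-open genomic coordinates. A single-exon transcript has no
#' introns.
#'
#' @param t a `transcript_model`.
#' @return a matrix with columns `start`, `end` and `n_exons - 1` rows.
#' @export
introns_of <- function(t) {
  ex <- t$exons
  n <- nrow(ex)
  if (n < 2)
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  if (t$strand == "+") {
    cbind(start = ex[-n, "end"], end = ex[-1, "start"])
  } else {
    cbind(start = ex[-1, "end"], end = ex[-n, "start"])
  }
}

#' Genomic span of a transcript
#' @param t a `transcript_model`.
#' @return numeric vector `c(start, end)`, 0-based half-open.
#' @export
transcript_span <- function(t) {
  c(start = min(t$exons[, "start"]), end = max(t$exons[, "end"]))
}
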