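#' Splice-junction window (R-region) extraction
#'
#' Every exon of a multi-exon transcript is flanked by up to four
#' 30-nucleotide windows anchored flush against its splice junctions:
#' * **R1** — the last `window` intronic nucleotides of the upstream intron
#'   (absent for the first exon, which has no upstream splice site);
#' * **R2** — the first `window` exonic nucleotides of the exon;
#' * **R3** — the last `window` exonic nucleotides of the exon;
#' * **R4** — the first `window` intronic nucleotides of the downstream
#'   intron (absent for the last exon).
#'
#' "First"/"last"/"upstream"/"downstream" are in transcript sense; all
#' sequences are strand-resolved so they read 5'->3' along the pre-mRNA.
#' Windows truncated by a short exon or intron keep the available length and
#' are flagged; exons shorter than `window` yield overlapping R2/R3.
#'
#' @param t a `transcript_model`.
#' @param genome a [Biostrings::DNAStringSet].
#' @param window window width in nucleotides (default 30).
#' @return a data.frame with one row per region: `transcript_id`,
#'   `exon_index` (0-based, transcription order), `region` (R1..R4),
#'   `chrom`, `start`, `end` (0-based half-open genomic), `strand`,
#'   `truncated`, `sequence`.
#' @export
extract_r_regions <- function(t, genome, window = 30L) {
  stopifnot(window >= 1)
  ex <- t$exons
  n <- nrow(ex)
  introns <- introns_of(t)
  plus <- t$strand == "+"
  rows <- vector("list", 4L * n)
  k <- 0L
  add <- function(exon_index, region, gstart, gend, full_width) {
    k <<- k + 1L
    rows[[k]] <<- data.frame(
      transcript_id = t$transcript_id, exon_index = exon_index,
      region = region, chrom = t$chrom, start = gstart, end = gend,
      strand = t$strand, truncated = (gend - gstart) < full_width,
      sequence = fetch_seq(genome, t$chrom, gstart, gend, t$strand),
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    s <- ex[i, "start"]; e <- ex[i, "end"]
    elen <- e - s
    w_ex <- min(window, elen)
    if (i > 1L) {                       # upstream intron exists -> R1
      up <- introns[i - 1L, ]
      w_in <- min(window, up["end"] - up["start"])
      if (plus) add(i - 1L, "R1", s - w_in, s, window)
      else      add(i - 1L, "R1", e, e + w_in, window)
    }
    if (plus) {
      add(i - 1L, "R2", s, s + w_ex, window)
      add(i - 1L, "R3", e - w_ex, e, window)
    } else {
      add(i - 1L, "R2", e - w_ex, e, window)
      add(i - 1L, "R3", s, s + w_ex, window)
    }
    if (i < n) {                        # downstream intron exists -> R4
      dn <- introns[i, ]
      w_in <- min(window, dn["end"] - dn["start"])
      if (plus) add(i - 1L, "R4", e, e + w_in, window)
      else      add(i - 1L, "R4", s - w_in, s, window)
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  rownames(out) <- NULL
  out
}

#' Extract R regions for many transcripts
#'
#' @param catalog an `sv_catalog`.
#' @param genome a [Biostrings::DNAStringSet].
#' @param transcript_ids subset of transcripts (default: all).
#' @inheritParams extract_r_regions
#' @return row-bound data.frame as from [extract_r_regions()].
#' @export
extract_r_regions_all <- function(catalog, genome,
                                  transcript_ids = names(catalog$transcripts),
                                  window = 30L) {
  do.call(rbind, lapply(catalog$transcripts[transcript_ids],
                        extract_r_regions, genome = genome, window = window))
}

.region_header <- function(df) {
  sprintf("%s|%d|%s|%s:%d-%d(%s)", df$transcript_id, df$exon_index,
          df$region, df$chrom, df$start, df$end, df$strand)
}

#' Parse a FASTA header written by [write_region_fasta()]
#' @param header header string (without the leading `>`).
#' @return data.frame with `transcript_id`, `exon_index`, `region`, `chrom`,
#'   `start`, `end`, `strand`.
#' @export
parse_region_header <- function(header) {
  m <- regmatches(header,
    regexec("^(.+)\\|([0-9]+)\\|(R[1-4])\\|(.+):([0-9]+)-([0-9]+)\\(([+-])\\)$",
            header))
  bad <- lengths(m) == 0
  if (any(bad)) stop("unparseable region header: ", header[bad][1])
  m <- do.call(rbind, m)
  data.frame(transcript_id = m[, 2], exon_index = as.integer(m[, 3]),
             region = m[, 4], chrom = m[, 5], start = as.integer(m[, 6]),
             end = as.integer(m[, 7]), strand = m[, 8],
             stringsAsFactors = FALSE)
}

#' Write one (group, Ri) sequence set as FASTA
#'
#' Record order is deterministic (transcript id, then exon index); headers
#' encode `transcript|exon_index|region|chrom:start-end(strand)` and
#' round-trip through [parse_region_header()]. Duplicate sequences are kept:
#' one record per exon occurrence.
#'
#' @param regions data.frame as from [extract_r_regions()].
#' @param group_id label of the sequence group (e.g. an RBP id).
#' @param region one of `"R1".."R4"`.
#' @param path output FASTA path; defaults to `<group_id>_<region>.fasta`
#'   in the current directory.
#' @return the path, or `NULL` (with a logged warning) if the set is empty.
#' @export
write_region_fasta <- function(regions, group_id, region,
                               path = paste0(group_id, "_", region, ".fasta")) {
  sel <- regions[regions$region == region, , drop = FALSE]
  if (nrow(sel) == 0) {
    cosplice_log("write_region_fasta: no ", region, " regions for group ",
                 group_id, "; no file written")
    return(invisible(NULL))
  }
  sel <- sel[order(sel$transcript_id, sel$exon_index), , drop = FALSE]
  seqs <- Biostrings::DNAStringSet(sel$sequence)
  names(seqs) <- .region_header(sel)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
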