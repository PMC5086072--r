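#' Read a genome FASTA into a DNAStringSet
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that trims FASTA
#' headers to the first whitespace-delimited token (the chromosome id) and
#' validates that every sequence is non-empty.
#'
#' @param path path to a FASTA file (plain or gzip).
#' @return a [Biostrings::DNAStringSet] named by chromosome id.
#' @export
read_genome_fasta <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (any(Biostrings::width(genome) == 0L))
    stop("genome contains an empty sequence: ",
         paste(names(genome)[Biostrings::width(genome) == 0L], collapse = ", "))
  genome
}

#' Fetch a strand-resolved genomic subsequence
#'
#' Coordinates are 0-based half-open. On the minus strand the reverse
#' complement of the slice is returned, i.e. the sequence reads 5'->3' in
#' transcript sense.
#'
#' @param genome a [Biostrings::DNAStringSet] as from [read_genome_fasta()].
#' @param chrom chromosome id.
#' @param start,end 0-based half-open interval, `0 <= start < end <= length`.
#' @param strand `"+"` or `"-"`.
#' @return a character DNA string of length `end - start`.
#' @export
fetch_seq <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome))
    stop("unknown chromosome: ", chrom)
  len <- length(genome[[chrom]])
  if (start < 0 || end > len || start >= end)
    stop(sprintf("interval [%d,%d) out of bounds for %s (length %d)",
                 start, end, chrom, len))
  s <- Biostrings::subseq(genome[[chrom]], start = start + 1L, end = end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

#' Reverse complement of a DNA string
#' @param x character DNA string over A,C,G,T,N.
#' @return character string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Display a DNA motif string in the RNA alphabet
#' @param x character DNA string.
#' @return character string with T replaced by U.
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", x)
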