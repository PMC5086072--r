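# brute-force oracle: slice the raw chromosome string and reverse-complement
# by hand, independent of fetch_seq / extract_r_regions
slice_oracle <- function(chrom_str, start, end, strand) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  chars <- strsplit(chrom_str, "")[[1]][(start + 1):end]
  if (strand == "-") chars <- rev(comp[chars])
  paste(chars, collapse = "")
}

# independent window-coordinate oracle from first principles
region_coords_oracle <- function(t, window = 30) {
  ex <- t$exons[order(t$exons[, 1]), , drop = FALSE]  # genomic order
  n <- nrow(ex)
  plus <- t$strand == "+"
  tx_order <- if (plus) seq_len(n) else rev(seq_len(n))
  out <- list()
  for (k in seq_len(n)) {
    gi <- tx_order[k]                       # genomic row of the k-th exon
    s <- ex[gi, 1]; e <- ex[gi, 2]
    up_intron <- if (k > 1) {
      pg <- tx_order[k - 1]
      if (plus) c(ex[pg, 2], s) else c(e, ex[pg, 1])
    } else NULL
    dn_intron <- if (k < n) {
      ng <- tx_order[k + 1]
      if (plus) c(e, ex[ng, 1]) else c(ex[ng, 2], s)
    } else NULL
    add <- function(region, a, b) {
      out[[length(out) + 1L]] <<- data.frame(
        exon_index = k - 1L, region = region, start = a, end = b)
    }
    if (!is.null(up_intron)) {
      wi <- min(window, up_intron[2] - up_intron[1])
      if (plus) add("R1", s - wi, s) else add("R1", e, e + wi)
    }
    we <- min(window, e - s)
    if (plus) add("R2", s, s + we) else add("R2", e - we, e)
    if (plus) add("R3", e - we, e) else add("R3", s, s + we)
    if (!is.null(dn_intron)) {
      wi <- min(window, dn_intron[2] - dn_intron[1])
      if (plus) add("R4", e, e + wi) else add("R4", s - wi, s)
    }
  }
  do.call(rbind, out)
}


# brute-force LCS oracle: enumerate every subsequence of the shorter string
# and keep the longest that is also a subsequence of the other
lcs_oracle <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  is_subseq <- function(sub, big) {
    j <- 1L
    for (ch in big) {
      if (j <= length(sub) && ch == sub[j]) j <- j + 1L
    }
    j > length(sub)
  }
  best <- 0L
  for (mask in 0:(2^length(av) - 1L)) {
    sub <- av[bitwAnd(bitwShiftR(mask, seq_along(av) - 1L), 1L) == 1L]
    if (length(sub) > best && is_subseq(sub, bv)) best <- length(sub)
  }
  best
}

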