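# shared fixture builders; everything is generated in code at test time

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

make_genome <- function(seqs) Biostrings::DNAStringSet(seqs)

# a transcript model without going through GTF I/O
make_tx <- function(id, gene, chrom, strand, exons) {
  cosplice:::.new_transcript_model(id, gene, chrom, strand, exons)
}

make_catalog <- function(tx_list) {
  names(tx_list) <- vapply(tx_list, `[[`, "", "transcript_id")
  cosplice:::.new_sv_catalog(tx_list)
}

# write a tiny GTF from (chrom, start0, end0, strand, gene, tx) rows
write_mini_gtf <- function(rows, path) {
  lines <- sprintf(
    "%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    rows$chrom, rows$start + 1L, rows$end, rows$strand, rows$gene, rows$tx)
  writeLines(lines, path)
  path
}

# random multi-exon transcript on a given chromosome string length
random_transcript <- function(id, chrom_len, strand,
                              n_exons = sample(2:5, 1)) {
  pos <- 50L
  exons <- matrix(0L, n_exons, 2)
  for (i in seq_len(n_exons)) {
    elen <- sample(20:80, 1)
    exons[i, ] <- c(pos, pos + elen)
    pos <- pos + elen + sample(35:90, 1)
  }
  stopifnot(pos < chrom_len - 50)
  make_tx(id, paste0("G_", id), "chr1", strand, exons)
}

# expression set with explicit per-time-point replicate values
make_expr <- function(values_by_tp, replicates = 3, noise = 0,
                      phases = c("early", "early", "middle", "middle",
                                 "middle", "desiccation", "desiccation")) {
  n_tp <- ncol(values_by_tp)
  map <- data.frame(
    sample_id = sprintf("t%d_r%d", rep(seq_len(n_tp), each = replicates),
                        rep(seq_len(replicates), n_tp)),
    time_point = rep(seq_len(n_tp), each = replicates),
    replicate = rep(seq_len(replicates), n_tp),
    phase = rep(phases[seq_len(n_tp)], each = replicates),
    stringsAsFactors = FALSE)
  vals <- values_by_tp[, rep(seq_len(n_tp), each = replicates),
                       drop = FALSE]
  colnames(vals) <- map$sample_id
  if (noise > 0) vals <- pmax(vals + rnorm(length(vals), 0, noise), 0)
  expr_set(vals, map)
}

# sequences of length len with a motif planted at random offsets
planted_seqs <- function(n, motif, len = 30, lambda = 1,
                         mutation_rate = 0) {
  w <- nchar(motif)
  vapply(seq_len(n), function(i) {
    s <- random_dna(len)
    if (runif(1) <= lambda) {
      copy <- strsplit(motif, "")[[1]]
      mut <- runif(w) < mutation_rate
      copy[mut] <- vapply(copy[mut], function(l)
        sample(setdiff(c("A", "C", "G", "T"), l), 1), "")
      o <- sample(0:(len - w), 1)
      substr(s, o + 1, o + w) <- paste(copy, collapse = "")
    }
    s
  }, "")
}

# a deliberately sharp PWM whose consensus is `motif`
sharp_pwm <- function(motif, match_prob = 0.97) {
  letters <- match(strsplit(motif, "")[[1]], c("A", "C", "G", "T"))
  mat <- matrix((1 - match_prob) / 3, 4, length(letters))
  for (k in seq_along(letters)) mat[letters[k], k] <- match_prob
  pwm(mat)
}

# hand-built motif-model stand-in for network assembly tests
mock_motif_model <- function(motif, significance = 1 / 101) {
  list(pwm = sharp_pwm(motif), width = nchar(motif),
       consensus = motif, consensus_rna = dna_to_rna(motif),
       significance = significance, zoops_lambda = 0.9)
}

# independent permutation enumerator (recursive, distinct from the
# implementation's iterative builder)
perms_oracle <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms_oracle(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}
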