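#' @rdname zoops_em_fit
#' @name motif-discovery
NULL

.DNA <- c("A", "C", "G", "T")

# encode DNA strings as 0-based integer vectors; N and other ambiguity
# codes become -1
.encode_dna <- function(seqs) {
  lapply(strsplit(toupper(seqs), ""), function(ch) {
    v <- match(ch, .DNA) - 1L
    v[is.na(v)] <- -1L
    v
  })
}

.decode_dna <- function(v) paste(.DNA[v + 1L], collapse = "")

# 0-order background letter frequencies of a sequence set (ACGT only)
.background_freq <- function(enc) {
  counts <- tabulate(unlist(enc) + 1L, nbins = 4L)
  if (sum(counts) == 0) stop("no ACGT letters in sequence set")
  setNames(counts / sum(counts), .DNA)
}

# log-likelihood of the set under the 0-order background-only model
.background_loglik <- function(enc) {
  counts <- tabulate(unlist(enc) + 1L, nbins = 4L)
  freq <- counts / sum(counts)
  sum(counts[counts > 0] * log(freq[counts > 0]))
}

# the n_starts most over-represented exact k-mers (observed / expected under
# the 0-order background), deterministic tie-break by count then k-mer
.seed_kmers <- function(enc, w, n_starts, bg) {
  kmers <- unlist(lapply(enc, function(x) {
    n <- length(x)
    if (n < w) return(character())
    s <- paste(c(.DNA, "N")[ifelse(x < 0, 5L, x + 1L)], collapse = "")
    substring(s, 1:(n - w + 1L), w:n)
  }))
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  counts <- table(kmers)
  expected <- vapply(names(counts), function(km) {
    prod(bg[strsplit(km, "")[[1]]])
  }, 0) * length(kmers)
  ratio <- as.numeric(counts) / expected
  ord <- order(-ratio, -as.numeric(counts), names(counts))
  names(counts)[ord][seq_len(min(n_starts, length(counts)))]
}

.pwm_from_kmer <- function(kmer, match_prob = 0.7) {
  letters <- match(strsplit(kmer, "")[[1]], .DNA)
  w <- length(letters)
  mat <- matrix((1 - match_prob) / 3, nrow = 4, ncol = w,
                dimnames = list(.DNA, NULL))
  for (k in seq_len(w)) mat[letters[k], k] <- match_prob
  mat
}

#' Construct a position weight matrix object
#'
#' @param mat 4 x w probability matrix (rows A, C, G, T; columns sum to 1).
#' @param background length-4 background probabilities.
#' @param pseudocount pseudocount used during estimation (metadata).
#' @return object of class `pwm`.
#' @export
pwm <- function(mat, background = rep(0.25, 4), pseudocount = 0.1) {
  stopifnot(nrow(mat) == 4, all(abs(colSums(mat) - 1) < 1e-9),
            abs(sum(background) - 1) < 1e-9, all(mat > 0),
            all(background > 0))
  rownames(mat) <- .DNA
  structure(list(width = ncol(mat), mat = mat,
                 background = setNames(as.numeric(background), .DNA),
                 pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> width %d, consensus %s\n", x$width,
              dna_to_rna(.pwm_consensus(x))))
  print(round(x$mat, 3))
  invisible(x)
}

.pwm_consensus <- function(pwm) {
  paste(.DNA[apply(pwm$mat, 2, which.max)], collapse = "")
}

# total information content (bits, summed over columns) relative to the
# background; used to rank equally significant candidate widths, where a
# longer informative motif should beat its own enriched sub-k-mers
.pwm_information <- function(pwm) {
  sum(colSums(pwm$mat * log2(pwm$mat / pwm$background)))
}

#' Fit a ZOOPS motif model by expectation-maximization
#'
#' Under the ZOOPS (zero-or-one-occurrence-per-sequence) generative model a
#' sequence carries, with probability `lambda`, exactly one motif site at a
#' uniformly chosen offset, letters drawn column-wise from a PWM, all other
#' letters from a 0-order background; otherwise it is pure background. EM
#' restarts are seeded deterministically from the most over-represented
#' exact k-mers, and the best-log-likelihood fit is kept, so results are
#' reproducible under a fixed seed.
#'
#' @param seqs character vector of DNA sequences (>= 5, each >= `w` long).
#' @param w motif width.
#' @param seed integer RNG seed (restart seeding is deterministic; the seed
#'   guards any residual randomness).
#' @param n_starts number of k-mer-seeded restarts (default 20).
#' @param max_iter EM iteration cap for the converging run (default 200).
#' @param start_iters EM iterations given to every seeded start before the
#'   best one is run to convergence (default 8).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param pseudocount PWM pseudocount per cell (default 0.1).
#' @return object of class `motif_model`: `pwm`, `zoops_lambda`,
#'   `log_likelihood`, `llr` (vs the background-only model), `consensus`
#'   (DNA), `consensus_rna`, `significance` (NA until
#'   [assess_significance()]), `ll_trace`, and the fit settings.
#' @export
zoops_em_fit <- function(seqs, w, seed = 1L, n_starts = 20L, max_iter = 200L,
                         tol = 1e-6, pseudocount = 0.1, start_iters = 8L) {
  if (length(seqs) < 5) stop("need >= 5 sequences")
  enc <- .encode_dna(seqs)
  if (any(vapply(enc, function(x) any(x < 0), TRUE))) {
    drop <- vapply(enc, function(x) any(x < 0), TRUE)
    cosplice_log("zoops_em_fit: dropping ", sum(drop),
                 " sequence(s) with ambiguous letters")
    enc <- enc[!drop]
    if (length(enc) < 5) stop("fewer than 5 unambiguous sequences")
  }
  if (any(lengths(enc) < w)) stop("all sequences must be >= w long")
  bg <- .background_freq(enc)
  if (any(bg >= 1 - 1e-12))
    stop("degenerate single-letter sequence set; no motif model fits")
  # restarts are seeded deterministically from enriched k-mers and EM itself
  # is deterministic, so the fit never consumes RNG state; `seed` is kept in
  # the signature for interface stability.
  starts <- .seed_kmers(enc, w, n_starts, bg)
  if (!length(starts)) stop("no seedable k-mers of width ", w)
  # two-stage multistart: a few EM iterations from every seed, then run the
  # most promising start to convergence
  bg0 <- pmax(bg, 1e-9) / sum(pmax(bg, 1e-9))
  best <- NULL
  for (km in starts) {
    fit <- zoops_em_cpp(enc, w, .pwm_from_kmer(km), 0.5, bg0,
                        start_iters, tol, pseudocount)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  head_trace <- best$ll_trace
  best <- zoops_em_cpp(enc, w, best$pwm, best$lambda, best$bg,
                       max_iter, tol, pseudocount)
  best$ll_trace <- c(head_trace, best$ll_trace)
  p <- pwm(best$pwm, background = best$bg, pseudocount = pseudocount)
  structure(list(
    pwm = p, zoops_lambda = best$lambda,
    log_likelihood = best$loglik,
    llr = best$loglik - .background_loglik(enc),
    consensus = .pwm_consensus(p),
    consensus_rna = dna_to_rna(.pwm_consensus(p)),
    significance = NA_real_, width = w,
    n_seqs = length(enc), ll_trace = best$ll_trace,
    settings = list(n_starts = n_starts, max_iter = max_iter, tol = tol,
                    pseudocount = pseudocount, start_iters = start_iters)),
    class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> width %d consensus %s lambda %.3f%s\n",
              x$width, x$consensus_rna, x$zoops_lambda,
              if (is.na(x$significance)) ""
              else sprintf(" significance %.4g", x$significance)))
  invisible(x)
}

#' Dinucleotide-preserving shuffle of DNA sequences
#'
#' Random Eulerian-path shuffle of the letter-transition multigraph: the
#' returned sequences have exactly the dinucleotide counts (and first/last
#' letters) of the originals. Uses R's RNG, so results are seed-stable.
#'
#' @param seqs character vector of DNA sequences.
#' @return character vector of shuffled sequences.
#' @export
dinuc_shuffle <- function(seqs) {
  enc <- .encode_dna(seqs)
  vapply(enc, function(x) {
    if (any(x < 0)) stop("cannot shuffle sequences with ambiguous letters")
    .decode_dna(dinuc_shuffle_cpp(x))
  }, "")
}

#' Empirical motif significance against a shuffled-sequence null
#'
#' Refits a ZOOPS model of the same width (same restart policy) on `n_null`
#' dinucleotide-shuffled copies of the sequence set and compares
#' log-likelihood ratios (fitted vs background-only). The significance is
#' `(1 + #\{null LLR >= observed\}) / (n_null + 1)`; motifs with
#' significance >= 0.01 are treated as noise downstream.
#'
#' @param model a `motif_model` fitted on `seqs`.
#' @param seqs the sequences the model was fitted on.
#' @param n_null number of shuffled null sets (default 100; must be >= 19).
#' @param seed RNG seed for the shuffles.
#' @return the empirical significance (numeric in (0, 1]).
#' @export
assess_significance <- function(model, seqs, n_null = 100L, seed = 1L) {
  if (n_null < 19) stop("n_null must be >= 19 to resolve p = 0.05")
  set.seed(seed)
  s <- model$settings
  n_ge <- 0L
  for (b in seq_len(n_null)) {
    null_seqs <- dinuc_shuffle(seqs)
    null_fit <- zoops_em_fit(null_seqs, model$width, seed = seed,
                             n_starts = s$n_starts, max_iter = s$max_iter,
                             tol = s$tol, pseudocount = s$pseudocount,
                             start_iters = s$start_iters)
    if (null_fit$llr >= model$llr) n_ge <- n_ge + 1L
  }
  (1 + n_ge) / (n_null + 1)
}

#' Fit motifs across widths and keep the most significant
#'
#' Fits one ZOOPS model per width, scores each by the shuffled-null
#' significance, and returns the model with the smallest significance; ties
#' are broken by larger mean per-column information content, then smaller
#' width. The returned model carries `significance` and a `significant`
#' flag at the `sig_threshold` gate.
#'
#' @inheritParams zoops_em_fit
#' @param widths candidate motif widths (default 4:7).
#' @param n_null shuffled null sets per width (default 100).
#' @param sig_threshold significance gate (default 0.01).
#' @return the selected `motif_model`.
#' @export
select_best_motif <- function(seqs, widths = 4:7, seed = 1L, n_null = 100L,
                              n_starts = 20L, max_iter = 200L,
                              sig_threshold = 0.01) {
  fits <- list()
  for (w in widths) {
    fit <- tryCatch(
      zoops_em_fit(seqs, w, seed = seed, n_starts = n_starts,
                   max_iter = max_iter),
      error = function(e) NULL)
    if (is.null(fit)) next
    fit$significance <- assess_significance(fit, seqs, n_null = n_null,
                                            seed = seed + w)
    fits[[as.character(w)]] <- fit
  }
  if (!length(fits)) stop("no motif width could be fitted")
  sig <- vapply(fits, `[[`, 0, "significance")
  ic <- vapply(fits, function(f) .pwm_information(f$pwm), 0)
  wd <- vapply(fits, `[[`, 0L, "width")
  best <- fits[[order(sig, -ic, wd)[1]]]
  best$significant <- best$significance < sig_threshold
  best
}

# integer (discretized) log-odds matrix; delta is the score bin width
.logodds_int <- function(pwm, delta = 1e-3) {
  lo <- log(pwm$mat / pwm$background)
  matrix(as.integer(round(lo / delta)), nrow = 4,
         dimnames = dimnames(pwm$mat))
}

# exact tail P(score >= s) of the discretized log-odds score of a random
# background k-mer, by dynamic programming over the score distribution
.score_tail_dp <- function(int_lo, background) {
  w <- ncol(int_lo)
  mins <- apply(int_lo, 2, min)
  dist <- c(1)                      # prob vector; index 1 <-> score offset0
  offset0 <- 0L
  for (k in seq_len(w)) {
    shift <- int_lo[, k] - mins[k]
    newlen <- length(dist) + max(shift)
    nd <- numeric(newlen)
    for (l in 1:4) {
      s <- shift[l]
      nd[(1 + s):(length(dist) + s)] <-
        nd[(1 + s):(length(dist) + s)] + background[l] * dist
    }
    dist <- nd
    offset0 <- offset0 + mins[k]
  }
  list(dist = dist, offset0 = offset0)   # score of bin i = offset0 + i - 1
}

#' Best PWM hit in a sequence with an exact scan p-value
#'
#' Scans every sense-strand offset with the discretized log-odds score. The
#' per-position null tail `P(score >= s)` is computed exactly by dynamic
#' programming over the score distribution of background k-mers; the hit
#' p-value accounts for the `m` scan positions via
#' `p = 1 - (1 - p_pos)^m`. Positions overlapping ambiguous letters are
#' skipped; if no position can be scored a no-hit sentinel (`offset = NA`)
#' is returned.
#'
#' @param pwm a `pwm` object.
#' @param seq DNA string, length >= motif width.
#' @param delta score discretization bin (log-odds units; default 1e-3).
#' @return list of class `motif_hit`: `offset` (0-based), `score` (log-odds,
#'   nats), `p_pos`, `p_value`, `n_positions`.
#' @export
best_hit_pvalue <- function(pwm, seq, delta = 1e-3) {
  x <- .encode_dna(seq)[[1]]
  w <- pwm$width
  if (length(x) < w) stop("sequence shorter than motif width")
  int_lo <- .logodds_int(pwm, delta)
  m_all <- length(x) - w + 1L
  scores <- rep(NA_integer_, m_all)
  for (j in seq_len(m_all)) {
    win <- x[j:(j + w - 1L)]
    if (any(win < 0)) next
    scores[j] <- sum(int_lo[cbind(win + 1L, seq_len(w))])
  }
  valid <- which(!is.na(scores))
  if (!length(valid)) {
    cosplice_log("best_hit_pvalue: no scannable position (ambiguous letters)")
    return(structure(list(offset = NA_integer_, score = NA_real_,
                          p_pos = NA_real_, p_value = NA_real_,
                          n_positions = 0L), class = "motif_hit"))
  }
  best_j <- valid[which.max(scores[valid])]
  dp <- .score_tail_dp(int_lo, pwm$background)
  idx_from <- scores[best_j] - dp$offset0 + 1L
  p_pos <- if (idx_from <= 1) 1 else sum(dp$dist[idx_from:length(dp$dist)])
  p_pos <- min(1, max(p_pos, .Machine$double.xmin))
  m <- length(valid)
  structure(list(offset = best_j - 1L,
                 score = scores[best_j] * delta,
                 p_pos = p_pos,
                 p_value = 1 - (1 - p_pos)^m,
                 n_positions = m),
            class = "motif_hit")
}

#' Chi-square test for group specificity of a motif
#'
#' 2x2 Pearson chi-square (1 df, no continuity correction) comparing the
#' fraction of sequences with a significant hit in the target group against
#' all other groups pooled.
#'
#' @param target_hits length-2 counts `c(with_hit, without_hit)` for the
#'   target group.
#' @param other_hits length-2 counts for the pooled remaining groups.
#' @return list with `statistic` and `p_value` (upper tail).
#' @export
chi_square_specificity <- function(target_hits, other_hits) {
  tab <- rbind(target = target_hits, other = other_hits)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1))
    stop("expected cell count < 1; use an exact test instead")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value))
}

#' Write motifs in MEME minimal text format
#'
#' @param models named list of `motif_model` objects (names become motif
#'   ids).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_meme_motifs <- function(models, path) {
  bg <- models[[1]]$pwm$background
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "",
             "Background letter frequencies",
             paste(sprintf("%s %.5f", names(bg), bg), collapse = " "), "")
  for (id in names(models)) {
    m <- models[[id]]
    lines <- c(lines,
               paste0("MOTIF ", id, " ", m$consensus_rna),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= %g",
                       m$width, round(m$zoops_lambda * m$n_seqs),
                       ifelse(is.na(m$significance), 1, m$significance)),
               apply(m$pwm$mat, 2, function(col)
                 paste(sprintf("%.6f", col), collapse = " ")),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}
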