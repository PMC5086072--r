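test_that("ZOOPS EM recovers a planted motif with monotone log-likelihood", {
  set.seed(41)
  seqs <- planted_seqs(50, "AGGTAAG")
  m <- zoops_em_fit(seqs, 7)
  expect_equal(m$consensus, "AGGTAAG")
  expect_equal(m$consensus_rna, "AGGUAAG")
  expect_gte(m$zoops_lambda, 0.9)
  expect_true(all(diff(m$ll_trace) > -1e-6))
  expect_gt(m$llr, 0)
  # PWM column invariants
  expect_equal(colSums(m$pwm$mat), rep(1, 7), ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_true(all(m$pwm$mat > 0))
})

test_that("EM fixed point: identical sequences with one embedded 7-mer", {
  base <- "CACACACACACAGGTAAGACACACACACAC"
  seqs <- rep(base, 10)
  m <- zoops_em_fit(seqs, 7)
  planted <- strsplit("AGGTAAG", "")[[1]]
  probs <- vapply(1:7, function(k) m$pwm$mat[planted[k], k], 0)
  expect_true(all(probs >= 0.9))
  expect_error(zoops_em_fit(rep(strrep("A", 30), 10), 4), "degenerate")
  expect_error(zoops_em_fit(planted_seqs(3, "ACGT"), 4), ">= 5")
})

test_that("dinucleotide shuffling preserves composition exactly", {
  set.seed(42)
  dinucs <- function(s) {
    ch <- strsplit(s, "")[[1]]
    table(paste0(ch[-length(ch)], ch[-1]))
  }
  for (i in 1:20) {
    s <- random_dna(30)
    sh <- dinuc_shuffle(s)
    expect_equal(nchar(sh), 30)
    expect_equal(as.list(dinucs(sh)), as.list(dinucs(s)))
    expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
    expect_equal(substr(sh, 30, 30), substr(s, 30, 30))
  }
  # shuffles are actually random
  set.seed(43)
  s <- random_dna(40)
  expect_gt(length(unique(replicate(20, dinuc_shuffle(s)))), 1)
})

test_that("shuffled-null significance separates planted motifs from background", {
  set.seed(44)
  seqs <- planted_seqs(50, "AGGTAAG")
  m <- zoops_em_fit(seqs, 7)
  sig <- assess_significance(m, seqs, n_null = 100, seed = 2)
  expect_equal(sig, 1 / 101)      # no shuffled set beats a perfect plant

  bgseqs <- vapply(1:50, function(i) random_dna(30), "")
  mb <- zoops_em_fit(bgseqs, 7)
  sigs <- vapply(1:5, function(i)
    assess_significance(mb, bgseqs, n_null = 30, seed = i), 0)
  expect_true(all(sigs >= 0.01))
  expect_gt(mean(sigs), 0.1)
  expect_error(assess_significance(m, seqs, n_null = 10), ">= 19")
})

test_that("width selection recovers the planted width and flags background", {
  set.seed(45)
  seqs5 <- planted_seqs(50, "GACGT")
  best <- select_best_motif(seqs5, widths = 4:7, seed = 7, n_null = 100)
  expect_equal(best$width, 5)
  expect_equal(best$consensus, "GACGT")
  expect_true(best$significant)

  bgseqs <- vapply(1:40, function(i) random_dna(30), "")
  nb <- select_best_motif(bgseqs, widths = 4:5, seed = 8, n_null = 30)
  expect_false(nb$significant)
})

test_that("scan p-values are exact: DP tail equals exhaustive k-mer enumeration", {
  set.seed(46)
  for (w in 4:5) {
    mat <- matrix(rgamma(4 * w, 1), 4)
    mat <- sweep(mat, 2, colSums(mat), "/")
    bgp <- rgamma(4, 1); bgp <- bgp / sum(bgp)
    p <- pwm(mat, background = bgp)
    int_lo <- matrix(as.integer(round(log(mat / bgp) / 1e-3)), 4)
    grid <- as.matrix(expand.grid(rep(list(1:4), w)))
    sc <- vapply(seq_len(nrow(grid)), function(i)
      sum(int_lo[cbind(grid[i, ], 1:w)]), 0)
    pr <- vapply(seq_len(nrow(grid)), function(i) prod(bgp[grid[i, ]]), 0)
    for (trial in 1:5) {
      s <- random_dna(w)           # single scan position: p_value == p_pos
      hit <- best_hit_pvalue(p, s)
      oracle <- sum(pr[sc >= as.integer(round(hit$score / 1e-3))])
      expect_equal(hit$p_pos, oracle, tolerance = 1e-12)
      expect_equal(hit$p_value, oracle, tolerance = 1e-12)
    }
  }
  # the maximum-likelihood k-mer of a sharp PWM is the top of the tail
  sp <- sharp_pwm("ACGT")
  hit <- best_hit_pvalue(sp, "ACGT")
  expect_equal(hit$p_pos, 0.25^4, tolerance = 1e-12)
})

test_that("scan handles uniform PWMs, multiple positions and ambiguous letters", {
  u <- pwm(matrix(0.25, 4, 4))
  expect_equal(best_hit_pvalue(u, "ACGTACGTAC")$p_value, 1)

  sp <- sharp_pwm("AGGTAAG")
  s <- paste0(strrep("C", 10), "AGGTAAG", strrep("C", 10))
  hit <- best_hit_pvalue(sp, s)
  expect_equal(hit$offset, 10L)
  expect_lt(hit$p_value, 0.05)
  expect_equal(hit$n_positions, nchar(s) - 7 + 1)

  # N positions are skipped; all-N yields the sentinel
  hitN <- best_hit_pvalue(sp, paste0("NNNN", "AGGTAAG", "NNNN"))
  expect_equal(hitN$offset, 4L)
  expect_equal(hitN$n_positions, 1L)
  sentinel <- best_hit_pvalue(sp, strrep("N", 12))
  expect_true(is.na(sentinel$offset))
  expect_equal(sentinel$n_positions, 0L)
})

test_that("chi-square specificity matches the 2x2 closed form", {
  res <- chi_square_specificity(c(30, 10), c(10, 30))
  # N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d)) = 80*800^2/40^4 = 20
  expect_equal(res$statistic, 20)
  expect_equal(res$p_value, pchisq(20, 1, lower.tail = FALSE))

  eq <- chi_square_specificity(c(20, 20), c(40, 40))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  expect_error(chi_square_specificity(c(1, 0), c(0, 1)), "expected cell")
})

test_that("motifs export to MEME minimal text", {
  set.seed(47)
  m <- zoops_em_fit(planted_seqs(20, "AGGTAAG"), 7)
  path <- withr::local_tempfile(fileext = ".txt")
  write_meme_motifs(list(grp_R1 = m), path)
  txt <- readLines(path)
  expect_true(any(grepl("^MEME version", txt)))
  expect_true(any(grepl("^MOTIF grp_R1", txt)))
  expect_true(any(grepl("letter-probability matrix: alength= 4 w= 7", txt)))
})
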