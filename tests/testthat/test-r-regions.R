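test_that("R windows sit flush against the junctions of the worked example", {
  set.seed(11)
  g <- make_genome(c(chr1 = random_dna(400)))
  t <- make_tx("T.1", "T", "chr1", "+", cbind(c(100, 200), c(160, 260)))
  r <- extract_r_regions(t, g)
  key <- paste(r$exon_index, r$region)
  ival <- function(k) unlist(r[key == k, c("start", "end")], use.names = FALSE)
  expect_equal(ival("0 R2"), c(100, 130))
  expect_equal(ival("0 R3"), c(130, 160))
  expect_equal(ival("0 R4"), c(160, 190))
  expect_equal(ival("1 R1"), c(170, 200))
  expect_equal(ival("1 R2"), c(200, 230))
  expect_equal(ival("1 R3"), c(230, 260))
  expect_false("0 R1" %in% key)   # first exon: no upstream splice site
  expect_false("1 R4" %in% key)   # last exon: no downstream splice site
  expect_false(any(r$truncated))
  # R1 abuts R2 exactly at the annotated junction
  expect_equal(r$end[key == "1 R1"], r$start[key == "1 R2"])
})

test_that("single-exon transcripts yield only (possibly overlapping) R2/R3", {
  set.seed(12)
  g <- make_genome(c(chr1 = random_dna(200)))
  t <- make_tx("S.1", "S", "chr1", "+", cbind(50, 90))  # 40 nt exon
  r <- extract_r_regions(t, g)
  expect_setequal(r$region, c("R2", "R3"))
  expect_equal(nrow(r), 2)
  # 40 < 60 so the windows overlap
  expect_lt(r$start[r$region == "R3"], r$end[r$region == "R2"])
})

test_that("short exons and introns truncate windows and are flagged", {
  set.seed(13)
  g <- make_genome(c(chr1 = random_dna(300)))
  # 20 nt intron and 15 nt terminal exon
  t <- make_tx("U.1", "U", "chr1", "+", cbind(c(50, 120), c(100, 135)))
  r <- extract_r_regions(t, g)
  r1 <- r[r$exon_index == 1 & r$region == "R1", ]
  expect_equal(r1$end - r1$start, 20)
  expect_true(r1$truncated)
  r2 <- r[r$exon_index == 1 & r$region == "R2", ]
  expect_equal(r2$end - r2$start, 15)
  expect_true(r2$truncated)
})

test_that("a minus-strand mirror transcript yields the identical sequences", {
  set.seed(14)
  fwd <- random_dna(400)
  g_fwd <- make_genome(c(chr1 = fwd))
  g_rev <- make_genome(c(chr1 = revcomp(fwd)))
  t_fwd <- make_tx("F.1", "F", "chr1", "+", cbind(c(100, 200), c(160, 260)))
  # mirrored coordinates on the reverse-complement chromosome
  L <- 400
  t_rev <- make_tx("R.1", "R", "chr1", "-",
                   cbind(L - c(160, 260), L - c(100, 200)))
  r_fwd <- extract_r_regions(t_fwd, g_fwd)
  r_rev <- extract_r_regions(t_rev, g_rev)
  o_fwd <- r_fwd[order(r_fwd$exon_index, r_fwd$region), ]
  o_rev <- r_rev[order(r_rev$exon_index, r_rev$region), ]
  expect_equal(o_rev$sequence, o_fwd$sequence)
  expect_equal(o_rev$region, o_fwd$region)
})

test_that("extracted windows equal the brute-force slicing oracle on random transcripts", {
  set.seed(15)
  chrom <- random_dna(3000)
  g <- make_genome(c(chr1 = chrom))
  for (i in 1:20) {
    strand <- sample(c("+", "-"), 1)
    t <- random_transcript(sprintf("X%d.1", i), 3000, strand)
    r <- extract_r_regions(t, g)
    oracle <- region_coords_oracle(t)
    expect_equal(nrow(r), nrow(oracle))
    m <- merge(r, oracle, by = c("exon_index", "region"))
    expect_equal(nrow(m), nrow(r))
    expect_equal(m$start.x, m$start.y)
    expect_equal(m$end.x, m$end.y)
    for (j in seq_len(nrow(m)))
      expect_equal(m$sequence[j],
                   slice_oracle(chrom, m$start.x[j], m$end.x[j], strand))
    # R1 and R4 counts both equal n_exons - 1
    expect_equal(sum(r$region == "R1"), nrow(t$exons) - 1)
    expect_equal(sum(r$region == "R4"), nrow(t$exons) - 1)
  }
})

test_that("region FASTA sets are sorted, duplicated junctions kept, headers bijective", {
  set.seed(16)
  g <- make_genome(c(chr1 = random_dna(600)))
  t1 <- make_tx("B.2", "B", "chr1", "+", cbind(c(100, 200), c(160, 260)))
  t2 <- make_tx("B.1", "B", "chr1", "+", cbind(c(100, 200), c(160, 260)))
  regions <- rbind(extract_r_regions(t1, g), extract_r_regions(t2, g))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_region_fasta(regions, "grp", "R1", path)
  seqs <- Biostrings::readDNAStringSet(path)
  expect_length(seqs, 2)                      # duplicate junction retained
  parsed <- parse_region_header(names(seqs))
  expect_equal(parsed$transcript_id, c("B.1", "B.2"))  # sorted
  expect_equal(parsed$region, c("R1", "R1"))
  back <- regions[regions$region == "R1" & regions$transcript_id == "B.1", ]
  expect_equal(parsed$start[1], back$start)
  expect_equal(parsed$end[1], back$end)
  expect_equal(parsed$exon_index[1], back$exon_index)

  cosplice_messages(clear = TRUE)
  expect_null(write_region_fasta(regions[0, ], "grp", "R1",
                                 withr::local_tempfile()))
  expect_match(paste(cosplice_messages(), collapse = " "), "no R1 regions")
})
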