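# a tiny deterministic world: one SF, two targets, one decoy; the SF motif
# sits in R1 of target junctions only
make_mini_net_world <- function(motif = "AGGTAAG", plant_regions = "R1") {
  chrom <- random_dna(2500)
  txs <- list(
    make_tx("SF.1", "SF", "chr1", "+", cbind(c(60, 160), c(120, 220))),
    make_tx("TA.1", "TA", "chr1", "+",
            cbind(c(300, 400, 500), c(360, 460, 560))),
    make_tx("TB.1", "TB", "chr1", "+", cbind(c(700, 800), c(760, 860))),
    make_tx("DC.1", "DC", "chr1", "+", cbind(c(1000, 1100), c(1060, 1160))))
  catalog <- make_catalog(txs)
  for (tx in c("TA.1", "TB.1")) {
    ex <- catalog$transcripts[[tx]]$exons
    for (i in 2:nrow(ex)) {
      for (ri in plant_regions) {
        win <- switch(ri,
                      R1 = c(ex[i, 1] - 30, ex[i, 1]),
                      R3 = c(ex[i, 2] - 30, ex[i, 2]))
        substr(chrom, win[1] + 6, win[1] + 5 + nchar(motif)) <- motif
      }
    }
  }
  list(genome = make_genome(c(chr1 = chrom)), catalog = catalog)
}

test_that("Ri ratio is the hit fraction over all exons", {
  t <- make_tx("T.1", "T", "chr1", "+",
               cbind(seq(0, 400, 100), seq(60, 460, 100)))
  expect_equal(compute_ri_ratio(t, c(TRUE, TRUE, FALSE, FALSE)), 0.4)
  expect_equal(compute_ri_ratio(t, rep(TRUE, 5)), 1)
  expect_equal(compute_ri_ratio(t, logical(0)), 0)
})

test_that("co-splicing edges require co-expression, motif significance and a scan hit", {
  set.seed(51)
  w <- make_mini_net_world()
  regions <- extract_r_regions_all(w$catalog, w$genome,
                                   c("TA.1", "TB.1", "DC.1"))
  coexp <- data.frame(srp_id = "SF.1",
                      transcript_id = c("TA.1", "TB.1"),
                      rho = 1, p_value = 1e-4)
  models <- list("SF.1" = list(R1 = mock_motif_model("AGGTAAG")))
  net <- build_cosplice_network("SF.1", coexp, models, regions, w$catalog,
                                super_clusters = c(SF.1 = "early maturation",
                                                   TA.1 = "early maturation",
                                                   TB.1 = "early maturation"))
  expect_s3_class(net, "cosplice_network")
  expect_setequal(net$edges$transcript_id, c("TA.1", "TB.1"))
  expect_true(all(net$edges$region == "R1"))
  # decoy is not co-expressed, so no motif edge may exist for it
  expect_false("DC.1" %in% net$edges$transcript_id)
  # weights exceed the -log10(0.05) floor and Ri ratios count all exons
  expect_true(all(net$edges$weight > -log10(0.05)))
  expect_equal(net$edges$ri_ratio[net$edges$transcript_id == "TA.1"], 2 / 3)
  expect_equal(net$edges$ri_ratio[net$edges$transcript_id == "TB.1"], 1 / 2)
  expect_equal(net$nodes$type[net$nodes$id == "SF.1"], "SF")
})

test_that("hits in two regions give parallel edges; no significant motif, no edges", {
  set.seed(52)
  w <- make_mini_net_world(plant_regions = c("R1", "R3"))
  regions <- extract_r_regions_all(w$catalog, w$genome, c("TA.1", "TB.1"))
  coexp <- data.frame(srp_id = "SF.1", transcript_id = c("TA.1", "TB.1"),
                      rho = 1, p_value = 1e-4)
  models <- list("SF.1" = list(R1 = mock_motif_model("AGGTAAG"),
                               R3 = mock_motif_model("AGGTAAG")))
  net <- build_cosplice_network("SF.1", coexp, models, regions, w$catalog)
  ta <- net$edges[net$edges$transcript_id == "TA.1", ]
  expect_setequal(ta$region, c("R1", "R3"))
  expect_equal(nrow(ta), 2)

  # non-significant model -> the RBP contributes nothing (SCL30 behavior)
  models_ns <- list("SF.1" = list(R1 = mock_motif_model("AGGTAAG",
                                                        significance = 0.2)))
  cosplice_messages(clear = TRUE)
  net_ns <- build_cosplice_network("SF.1", coexp, models_ns, regions,
                                   w$catalog)
  expect_equal(nrow(net_ns$edges), 0)
  expect_match(paste(cosplice_messages(), collapse = " "),
               "no significant motif")
})

test_that("differential-splicing report implements the two qualifying patterns", {
  catalog <- make_catalog(list(
    make_tx("G.1", "G", "chr1", "+", cbind(c(0, 100), c(60, 160))),
    make_tx("G.2", "G", "chr1", "+", cbind(c(0, 100), c(40, 160))),
    make_tx("H.1", "H", "chr1", "+", cbind(c(300, 400), c(360, 460))),
    make_tx("H.2", "H", "chr1", "+", cbind(c(300, 400), c(340, 460))),
    make_tx("K.1", "K", "chr1", "+", cbind(c(600, 700), c(660, 760))),
    make_tx("K.2", "K", "chr1", "+", cbind(c(600, 700), c(640, 760)))))
  edges <- data.frame(
    sf_id = c("SF_A", "SF_B", "SF_A", "SF_A", "SF_A"),
    transcript_id = c("G.1", "G.2", "H.1", "H.2", "K.1"),
    region = "R1", weight = 3, n_exons_with_hit = 1, ri_ratio = 0.5,
    stringsAsFactors = FALSE)
  net <- structure(list(nodes = data.frame(), edges = edges),
                   class = "cosplice_network")
  sc <- c(SF_A = "early maturation", SF_B = "desiccation")
  rep <- find_differentially_spliced_genes(net, catalog, sc)
  # G: two SVs on different SFs in different super-clusters -> reported
  expect_true("G" %in% rep$gene_id)
  # H: both SVs on the same SF -> not reported
  expect_false("H" %in% rep$gene_id)
  # K: second SV stable/unconnected -> reported and flagged
  expect_true("K" %in% rep$gene_id)
  expect_true(rep$no_rbp_edge[rep$transcript_id == "K.2"])
  expect_equal(rep$rbps[rep$transcript_id == "G.2"], "SF_B")

  # same super-cluster despite different SFs -> not differential
  sc_same <- c(SF_A = "early maturation", SF_B = "early maturation")
  rep2 <- find_differentially_spliced_genes(net, catalog, sc_same)
  expect_false("G" %in% rep2$gene_id)
  expect_true("K" %in% rep2$gene_id)   # the stable pattern is unaffected
})

test_that("network exports round-trip and honor the declared formats", {
  set.seed(53)
  w <- make_mini_net_world()
  regions <- extract_r_regions_all(w$catalog, w$genome, c("TA.1", "TB.1"))
  coexp <- data.frame(srp_id = "SF.1", transcript_id = c("TA.1", "TB.1"),
                      rho = 1, p_value = 1e-4)
  models <- list("SF.1" = list(R1 = mock_motif_model("AGGTAAG")))
  net <- build_cosplice_network("SF.1", coexp, models, regions, w$catalog)

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, "graphml", gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_setequal(igraph::V(g)$name, net$nodes$id)
  expect_equal(sort(igraph::E(g)$weight), sort(net$edges$weight))

  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(net, "sif", sif)
  lines <- readLines(sif)
  expect_length(lines, nrow(net$edges))
  expect_true(all(grepl("^SF\\.1 r1 T[AB]\\.1$", lines)))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, "edge-tsv", tsv)
  expect_equal(nrow(read.delim(tsv)), nrow(net$edges))

  expect_error(export_network(net, "xml", withr::local_tempfile()))
  empty <- structure(list(nodes = data.frame(), edges = net$edges[0, ]),
                     class = "cosplice_network")
  expect_error(export_network(empty, "sif", withr::local_tempfile()),
               "empty")
})
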