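test_that("differential filter needs both the fold change and a consecutive t-test", {
  set.seed(21)
  flat <- matrix(10, 1, 7)
  step <- matrix(c(10, 40, 40, 40, 40, 40, 40), 1)        # 4-fold jump t1->t2
  vals <- rbind(flat, step)
  rownames(vals) <- c("flat", "step")
  m <- make_expr(vals, noise = 0.1)
  de <- differential_filter(m)
  expect_false("flat" %in% de)
  expect_true("step" %in% de)

  # hand-computed oracle for the step transcript: replicate noise sd 0.1,
  # group means ~10 vs ~40 -> t is astronomically significant, fold = 4
  a <- m$values["step", m$sample_map$time_point == 1]
  b <- m$values["step", m$sample_map$time_point == 2]
  expect_lt(t.test(a, b)$p.value, 1e-4)

  # >= 2-fold change whose consecutive tests are all insignificant
  # (huge within-group spread) -> excluded
  vals2 <- matrix(c(2, 10, 22, 5, 28, 40, 1, 30, 42, 6, 11, 25,
                    30, 2, 9, 28, 41, 3, 22, 6, 13), 1)
  map <- data.frame(sample_id = sprintf("t%d_r%d", rep(1:7, each = 3),
                                        rep(1:3, 7)),
                    time_point = rep(1:7, each = 3),
                    replicate = rep(1:3, 7),
                    phase = rep(c("early", "early", "middle", "middle",
                                  "middle", "desiccation", "desiccation"),
                                each = 3))
  colnames(vals2) <- map$sample_id
  rownames(vals2) <- "spread"
  ms <- expr_set(vals2, map)
  ps <- vapply(1:6, function(j) {
    t.test(vals2[1, map$time_point == j],
           vals2[1, map$time_point == j + 1])$p.value
  }, 0)
  expect_true(all(ps > 0.001))                 # oracle: no consecutive pair
  mu <- vapply(1:7, function(j) mean(vals2[1, map$time_point == j]), 0)
  expect_gte(max(mu) / min(mu), 2)             # fold criterion alone passes
  expect_false("spread" %in% differential_filter(ms))
})

test_that("differential filter is monotone in fold and alpha and honors a DE list", {
  set.seed(22)
  vals <- matrix(rgamma(20 * 7, 4, 0.5), 20)
  rownames(vals) <- sprintf("tx%02d", 1:20)
  m <- make_expr(vals, noise = 0.3)
  strict <- differential_filter(m, fold = 3, alpha = 1e-4)
  loose <- differential_filter(m, fold = 1.5, alpha = 0.01)
  expect_true(all(strict %in% loose))
  expect_equal(differential_filter(m, de_list = c("tx01", "zzz")), "tx01")
})

test_that("z-score + CDF normalization matches closed forms and an erf oracle", {
  # one point exactly one sd above the mean -> Phi(1)
  prof <- c(1, 1, 1, 1, 1, 1, 1 + sqrt(7))  # mean 1 + k, engineered below
  vals <- matrix(c(2, 4, 6, 8, 10, 12, 14), 1)  # linear ramp
  rownames(vals) <- "ramp"
  m <- make_expr(vals)
  z <- (vals[1, ] - mean(vals[1, ])) / sd(vals[1, ])
  erf_oracle <- 0.5 * (1 + pracma::erf(z / sqrt(2)))
  norm <- normalize_zscore_cdf(m)
  expect_equal(unname(norm["ramp", ]), unname(erf_oracle), tolerance = 1e-12)
  expect_true(all(norm > 0 & norm < 1))
  expect_equal(order(norm["ramp", ]), order(vals[1, ]))

  # affine rescaling of the profile leaves the output unchanged
  vals2 <- vals * 37 + 11
  rownames(vals2) <- "ramp"
  m2 <- make_expr(vals2)
  expect_equal(normalize_zscore_cdf(m2), norm, tolerance = 1e-12)

  # a profile sitting exactly 1 sd up at one time point hits Phi(1)
  x <- c(0, 0, 0, 0, 0, 0, 1)
  z1 <- (1 - mean(x)) / sd(x)
  vals3 <- matrix(x * 10 + 5, 1); rownames(vals3) <- "spike"
  expect_equal(unname(normalize_zscore_cdf(make_expr(vals3))["spike", 7]),
               pnorm(z1), tolerance = 1e-12)

  flat <- matrix(3, 1, 7); rownames(flat) <- "flat"
  expect_error(normalize_zscore_cdf(make_expr(flat)), "zero-variance")
})

test_that("k-means++ clustering separates blobs, is deterministic, handles k=1", {
  set.seed(23)
  centers <- rbind(c(0, 0, 0), c(5, 5, 5), c(-5, 5, -5))
  x <- do.call(rbind, lapply(1:3, function(i)
    sweep(matrix(rnorm(60, 0, 0.3), 20), 2, centers[i, ], `+`)))
  rownames(x) <- sprintf("p%02d", 1:60)
  truth <- rep(0:2, each = 20)
  ca <- kmeans_cluster(x, k = 3, n_init = 10, seed = 5)
  # agreement up to relabeling: try all 6 label permutations
  best <- max(vapply(combinat_perms <- list(c(0,1,2), c(0,2,1), c(1,0,2),
                                            c(1,2,0), c(2,0,1), c(2,1,0)),
                     function(p) mean(p[truth + 1] == ca$cluster), 0))
  expect_equal(best, 1)
  ca2 <- kmeans_cluster(x, k = 3, n_init = 10, seed = 5)
  expect_identical(ca$cluster, ca2$cluster)

  one <- kmeans_cluster(x, k = 1, n_init = 2, seed = 1)
  expect_true(all(one$cluster == 0))
  expect_equal(unname(one$centroids[1, ]), unname(colMeans(x)))
  expect_error(kmeans_cluster(x, k = 100), "exceeds")
})

test_that("super-cluster assignment maps archetypes to their own labels and partitions", {
  arch <- archetype_profiles()
  vals <- do.call(rbind, arch) * 100
  rownames(vals) <- paste0("a", seq_along(arch))
  m <- make_expr(vals, noise = 0.01)
  norm <- normalize_zscore_cdf(m)
  ca <- kmeans_cluster(norm, k = 6, n_init = 20, seed = 3)
  sc <- assign_super_clusters(ca, m)
  tx_labels <- attr(sc, "transcripts")
  expect_setequal(sc$super_cluster, super_cluster_labels())
  for (i in seq_along(arch))
    expect_equal(unname(tx_labels[paste0("a", i)]), names(arch)[i])
  # partition: every clustered transcript gets exactly one label
  expect_setequal(names(tx_labels), rownames(vals))
  expect_false(anyNA(tx_labels))
})

test_that("phaseless centroids fall back to the maximal phase, all-on reduces by containment", {
  # constant centroid 0.5: all phases tie at threshold -> all-on, reduced
  vals <- rbind(seq(1, 2, length.out = 7) + c(0, .5, 0, .6, 0, .7, .1))
  rownames(vals) <- "t1"
  m <- make_expr(vals)
  ca <- list(cluster = c(t1 = 0L), k = 1L,
             centroids = matrix(0.5, 1, 7))
  class(ca) <- "cluster_assignment"
  cosplice_messages(clear = TRUE)
  sc <- assign_super_clusters(ca, m)
  expect_true(sc$super_cluster %in% super_cluster_labels())
  expect_match(paste(cosplice_messages(), collapse = " "), "all phases")

  ca$centroids <- matrix(c(0.4, 0.45, 0.3, 0.2, 0.3, 0.1, 0.2), 1)
  cosplice_messages(clear = TRUE)
  sc2 <- assign_super_clusters(ca, m)
  expect_equal(sc2$super_cluster, "early maturation")
  expect_match(paste(cosplice_messages(), collapse = " "), "no on-phase")
})
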