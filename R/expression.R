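#' Read an expression matrix and its sample map
#'
#' The expression TSV has a `transcript_id` column plus one column per
#' sample; the sample map TSV has columns `sample_id`, `time_point`
#' (ordinal), `replicate` (integer) and `phase` (categorical). Every sample
#' column must be described by the map, values must be non-negative and
#' complete, and at least two time points are required.
#'
#' @param expr_path path to the expression TSV.
#' @param map_path path to the sample map TSV.
#' @return a list of class `expr_set`: `values` (matrix, transcripts x
#'   samples) and `sample_map` (data.frame).
#' @export
read_expression <- function(expr_path, map_path) {
  tab <- read.delim(expr_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"transcript_id" %in% names(tab))
    stop("expression table lacks a transcript_id column")
  values <- as.matrix(tab[, setdiff(names(tab), "transcript_id"), drop = FALSE])
  rownames(values) <- tab$transcript_id
  map <- read.delim(map_path, stringsAsFactors = FALSE)
  expr_set(values, map)
}

#' Construct an `expr_set` from in-memory objects
#' @param values numeric matrix, transcripts x samples (non-negative).
#' @param sample_map data.frame with `sample_id`, `time_point`, `replicate`,
#'   `phase`.
#' @return an `expr_set`.
#' @export
expr_set <- function(values, sample_map) {
  need <- c("sample_id", "time_point", "replicate", "phase")
  if (!all(need %in% names(sample_map)))
    stop("sample map needs columns: ", paste(need, collapse = ", "))
  if (!setequal(colnames(values), sample_map$sample_id))
    stop("sample columns and sample map disagree")
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (any(values < 0)) stop("expression values must be non-negative")
  sample_map <- sample_map[match(colnames(values), sample_map$sample_id), ]
  if (length(unique(sample_map$time_point)) < 2)
    stop("need at least two time points")
  structure(list(values = values, sample_map = sample_map),
            class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("<expr_set> %d transcripts x %d samples (%d time points, phases: %s)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$sample_map$time_point)),
              paste(unique(x$sample_map$phase), collapse = ", ")))
  invisible(x)
}

# replicate-averaged profile matrix: transcripts x time points (sorted)
.timepoint_means <- function(m, transcripts = rownames(m$values)) {
  tps <- sort(unique(m$sample_map$time_point))
  out <- sapply(tps, function(tp) {
    cols <- m$sample_map$sample_id[m$sample_map$time_point == tp]
    rowMeans(m$values[transcripts, cols, drop = FALSE])
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = length(transcripts))
  dimnames(out) <- list(transcripts, as.character(tps))
  out
}

#' Filter differentially expressed transcripts
#'
#' A transcript is differentially expressed if (i) its replicate-averaged
#' abundance changes at least `fold`-fold between some pair of time points
#' (any pair) and (ii) a two-sample t-test on raw replicate values between
#' some pair of *consecutive* time points gives p < `alpha`. A precomputed
#' list, when supplied, takes precedence over the built-in filter.
#'
#' @param m an `expr_set`.
#' @param fold minimal fold change (default 2).
#' @param alpha t-test significance level (default 0.001).
#' @param de_list optional character vector of transcript ids; returned
#'   (intersected with the matrix) unchanged if given.
#' @return character vector of transcript ids.
#' @export
differential_filter <- function(m, fold = 2, alpha = 0.001, de_list = NULL) {
  if (!is.null(de_list)) return(intersect(rownames(m$values), de_list))
  tps <- sort(unique(m$sample_map$time_point))
  reps <- table(m$sample_map$time_point)
  if (any(reps < 2))
    stop("differential_filter: every time point needs >= 2 replicates for the t-test")
  means <- .timepoint_means(m)
  cols_by_tp <- lapply(tps, function(tp)
    m$sample_map$sample_id[m$sample_map$time_point == tp])
  keep <- vapply(rownames(m$values), function(tx) {
    mu <- means[tx, ]
    # (i) any-pair fold change on time-point means (0/0 treated as no change)
    hi <- max(mu); lo <- min(mu)
    fold_ok <- (lo == 0 && hi > 0) || (lo > 0 && hi / lo >= fold)
    if (!fold_ok) return(FALSE)
    # (ii) consecutive-pair t-test on raw replicates
    for (j in seq_len(length(tps) - 1L)) {
      a <- m$values[tx, cols_by_tp[[j]]]
      b <- m$values[tx, cols_by_tp[[j + 1L]]]
      if (stats::sd(c(a, b)) == 0) next
      p <- tryCatch(t.test(a, b)$p.value, error = function(e) NA_real_)
      if (!is.na(p) && p < alpha) return(TRUE)
    }
    FALSE
  }, logical(1))
  rownames(m$values)[keep]
}

#' Z-score + normal-CDF normalization of expression profiles
#'
#' Replicates are averaged per time point, each transcript's 7-point (or
#' n-point) profile is z-scored across time points, and each z value is
#' mapped through the standard normal CDF, yielding values strictly inside
#' (0, 1) with rank order preserved. The transform is invariant to affine
#' rescaling of the input profile.
#'
#' @param m an `expr_set`.
#' @param transcripts transcripts to normalize (default: all).
#' @return matrix of normalized profiles, transcripts x time points.
#' @export
normalize_zscore_cdf <- function(m, transcripts = rownames(m$values)) {
  prof <- .timepoint_means(m, transcripts)
  sds <- apply(prof, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance profile(s): ",
         paste(head(transcripts[sds == 0], 5), collapse = ", "),
         " (run differential_filter first)")
  z <- (prof - rowMeans(prof)) / sds
  pnorm(z)
}

# k-means++ seeding (Arthur & Vassilvitskii): first center uniform, then
# each next center sampled with probability proportional to squared
# distance to the nearest chosen center.
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L)) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1L] <- sample.int(n, 1L, prob = prob)
    nd2 <- rowSums((x - matrix(x[centers[j + 1L], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, nd2)
  }
  x[centers, , drop = FALSE]
}

#' Cluster normalized expression profiles with restarted k-means++
#'
#' Runs `n_init` independent k-means++ seedings, refines each with Lloyd
#' iterations ([stats::kmeans()]), and keeps the solution with the smallest
#' total within-cluster sum of squares. Deterministic under a fixed seed.
#'
#' @param profiles matrix of profiles (rows clustered).
#' @param k number of clusters (default 50).
#' @param n_init number of restarts (default 1000).
#' @param max_iter Lloyd iteration cap per restart (default 1000).
#' @param seed integer RNG seed.
#' @return list of class `cluster_assignment`: `cluster` (named integer,
#'   0-based ids), `k`, `centroids` (k x time points), `tot_withinss`.
#' @export
kmeans_cluster <- function(profiles, k = 50L, n_init = 1000L,
                           max_iter = 1000L, seed = 1L) {
  n <- nrow(profiles)
  if (k > n) stop("k (", k, ") exceeds number of profiles (", n, ")")
  set.seed(seed)
  best <- NULL
  for (i in seq_len(n_init)) {
    centers <- .kmeanspp_centers(profiles, k)
    fit <- suppressWarnings(
      kmeans(profiles, centers = centers, iter.max = max_iter,
             algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  structure(list(cluster = setNames(best$cluster - 1L, rownames(profiles)),
                 k = k, centroids = best$centers,
                 tot_withinss = best$tot.withinss),
            class = "cluster_assignment")
}

.phase_order <- c("early", "middle", "desiccation")

#' The six developmental-phase super-cluster labels
#' @return character vector of the six labels, in canonical order.
#' @export
super_cluster_labels <- function() {
  c("early maturation", "early and middle maturation", "middle maturation",
    "middle maturation and desiccation", "desiccation",
    "early maturation and desiccation")
}

.label_for_phases <- function(on) {
  key <- paste(sort(match(on, .phase_order)), collapse = ",")
  switch(key,
         "1" = "early maturation",
         "1,2" = "early and middle maturation",
         "2" = "middle maturation",
         "2,3" = "middle maturation and desiccation",
         "3" = "desiccation",
         "1,3" = "early maturation and desiccation",
         NA_character_)
}

#' Merge k-means clusters into developmental super-clusters
#'
#' A phase is "on" for a cluster when the centroid's mean normalized value
#' over that phase's time points is at least `phase_threshold` (0.5 on
#' CDF-transformed profiles means above the transcript's own mean). The
#' on-phase set maps to one of the six phase-combination labels; an empty
#' set falls back to the phase with maximal mean, and the all-three set is
#' reduced to the contained pair dropping the weakest phase. Both fallbacks
#' are logged.
#'
#' @param ca a `cluster_assignment`.
#' @param m the `expr_set` the clustering was computed from (provides the
#'   time point -> phase map).
#' @param phase_threshold on-phase threshold on normalized centroids.
#' @return data.frame with one row per cluster: `cluster`, `super_cluster`,
#'   `color`, plus an attribute `transcripts`: named character vector
#'   mapping each transcript to its super-cluster label.
#' @export
assign_super_clusters <- function(ca, m, phase_threshold = 0.5) {
  tps <- sort(unique(m$sample_map$time_point))
  phase_of_tp <- vapply(tps, function(tp)
    unique(m$sample_map$phase[m$sample_map$time_point == tp])[1], "")
  labels <- character(ca$k)
  for (cl in seq_len(ca$k)) {
    cen <- ca$centroids[cl, ]
    ph_mean <- vapply(.phase_order, function(ph) {
      idx <- which(phase_of_tp == ph)
      if (!length(idx)) return(NA_real_)
      mean(cen[idx])
    }, 0)
    ph_mean <- ph_mean[!is.na(ph_mean)]
    on <- names(ph_mean)[ph_mean >= phase_threshold]
    if (!length(on)) {
      on <- names(which.max(ph_mean))
      cosplice_log("assign_super_clusters: cluster ", cl - 1L,
                   " has no on-phase; using maximal phase ", on)
    } else if (length(on) == 3L) {
      on <- setdiff(on, names(which.min(ph_mean)))
      cosplice_log("assign_super_clusters: cluster ", cl - 1L,
                   " is on in all phases; reduced to {",
                   paste(on, collapse = ","), "}")
    }
    labels[cl] <- .label_for_phases(on)
  }
  colors <- setNames(c("#1b9e77", "#d95f02", "#7570b3",
                       "#e7298a", "#66a61e", "#e6ab02"),
                     super_cluster_labels())
  out <- data.frame(cluster = seq_len(ca$k) - 1L, super_cluster = labels,
                    color = unname(colors[labels]), stringsAsFactors = FALSE)
  attr(out, "transcripts") <- setNames(labels[ca$cluster + 1L],
                                       names(ca$cluster))
  out
}
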