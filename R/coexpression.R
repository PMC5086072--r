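#' Spearman rank correlation
#'
#' Pearson correlation of rank vectors with average ranks for ties. Constant
#' vectors have no rank correlation and raise an error.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return rho in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("profiles differ in length")
  if (length(x) < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("spearman_rho undefined for a constant profile")
  cor(rank(x), rank(y), method = "pearson")
}

# Null distribution of rho over all permutations of 1..n against 1..n,
# cached per n. Returns a sorted numeric vector of length n!.
.spearman_null <- function(n) {
  key <- paste0("spearman_null_", n)
  cached <- get0(key, envir = .cosplice_env, ifnotfound = NULL)
  if (!is.null(cached)) return(cached)
  perms <- .permutations(n)                 # n! x n matrix
  rc <- seq_len(n) - (n + 1) / 2
  # cor(p, 1..n) = (p . rc) / sum(rc^2) because sum(rc) = 0
  rho <- sort(as.vector(perms %*% rc) / sum(rc^2))
  assign(key, rho, envir = .cosplice_env)
  rho
}

# all permutations of 1..n as an n! x n integer matrix (n <= 9)
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Two-sided p-value for a Spearman correlation
#'
#' For n <= 9 the p-value is exact: the fraction of all n! rank orderings
#' whose |rho| reaches |rho| (both tails counted by magnitude). For larger n
#' the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on n-2 degrees of
#' freedom is used.
#'
#' @param rho observed correlation.
#' @param n number of paired observations (n >= 3).
#' @return p-value in (0, 1].
#' @export
spearman_pvalue <- function(rho, n) {
  if (n < 3) stop("need n >= 3")
  if (abs(rho) > 1 + 1e-9) stop("|rho| > 1")
  if (n <= 9) {
    null <- .spearman_null(n)
    mean(abs(null) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1) return(.Machine$double.xmin)
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(t), df = n - 2)
  }
}

#' Build SRP-centered co-expression edges
#'
#' Tests every SRP x transcript pair by Spearman correlation of their
#' profiles and keeps positively correlated pairs with `rho > rho_min` and
#' `p < p_max` (both strict, as in the thresholding this mirrors). Pairs of
#' a transcript with itself are skipped; an SRP may correlate with another
#' SRP.
#'
#' @param srps character vector of SRP transcript ids.
#' @param transcripts character vector of candidate transcript ids.
#' @param profiles numeric matrix (rows = transcripts, columns = time
#'   points), typically the output of [normalize_zscore_cdf()].
#' @param rho_min correlation threshold (default 0.95).
#' @param p_max p-value threshold (default 0.001).
#' @param positive_only keep only rho > 0 edges (default TRUE).
#' @return data.frame with columns `srp_id`, `transcript_id`, `rho`,
#'   `p_value`; zero rows allowed.
#' @export
build_coexpression_edges <- function(srps, transcripts, profiles,
                                     rho_min = 0.95, p_max = 0.001,
                                     positive_only = TRUE) {
  missing <- setdiff(c(srps, transcripts), rownames(profiles))
  if (length(missing))
    stop("profiles missing for: ", paste(head(missing, 5), collapse = ", "))
  n <- ncol(profiles)
  ranks <- t(apply(profiles[unique(c(srps, transcripts)), , drop = FALSE],
                   1, rank))
  rows <- list()
  for (s in srps) {
    for (tx in transcripts) {
      if (identical(s, tx)) next
      rho <- cor(ranks[s, ], ranks[tx, ])
      if (positive_only && rho <= 0) next
      if (rho <= rho_min) next
      p <- spearman_pvalue(rho, n)
      if (p < p_max)
        rows[[length(rows) + 1L]] <- data.frame(
          srp_id = s, transcript_id = tx, rho = rho, p_value = p,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(srp_id = character(), transcript_id = character(),
                      rho = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write co-expression edges as a Cytoscape-loadable TSV
#' @param edges data.frame from [build_coexpression_edges()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_tsv <- function(edges, path) {
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
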