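#' Per-gene correlation distribution summaries
#'
#' Computes, for every gene, the Pearson correlation to each of the other
#' G - 1 genes across all samples, and reduces those correlations to the
#' bin-count histogram of the scheme plus mean, SD, skewness and kurtosis.
#' These 8 + 4 observed values are what the template distance compares
#' against each shape's expected values.
#'
#' Correlations are evaluated in row blocks (standardized rows times the
#' transposed standardized matrix), so peak memory is O(G x block_size)
#' rather than O(G^2), and the result is independent of the block size and
#' of gene order.
#'
#' @param mat Numeric genes-by-samples matrix (see [as_expression_matrix()]);
#'   at least 2 genes and 3 samples.
#' @param scheme A [bin_scheme()].
#' @param block_size Rows per correlation block. Affects memory only, never
#'   results.
#' @param zero_variance `"error"` (default) stops at the first gene whose
#'   expression is constant across samples; `"drop"` removes such genes with
#'   a message.
#' @param estimator Moment convention, see [corr_moments()].
#' @param method `"pearson"` (default) or `"spearman"` (rank-transform the
#'   rows first; offered as a documented extension).
#'
#' @return A data frame of class `coex_summaries` with one row per gene:
#'   `gene_id`, `count_1..count_B` (bin counts, summing to G - 1),
#'   `prop_1..prop_B` (bin proportions, summing to 1), `mean`, `sd`,
#'   `skewness`, `kurtosis`, and `degenerate` (constant-correlation flag).
#'   The scheme and gene total are attached as attributes `scheme` and
#'   `n_genes`.
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(40), 8, 5,
#'             dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
#' s <- correlation_summaries(m)
#' rowSums(s[, paste0("count_", 1:8)])   # always G - 1 = 7
#' @export
correlation_summaries <- function(mat, scheme = bin_scheme(),
                                  block_size = 256L,
                                  zero_variance = c("error", "drop"),
                                  estimator = c("population", "sample"),
                                  method = c("pearson", "spearman")) {
  mat <- as_expression_matrix(mat)
  zero_variance <- match.arg(zero_variance)
  estimator <- match.arg(estimator)
  method <- match.arg(method)
  if (ncol(mat) < 3L)
    stop("at least 3 samples are required for meaningful Pearson correlations")
  if (nrow(mat) < 2L) stop("at least 2 genes are required")
  if (method == "spearman")
    mat <- t(apply(mat, 1L, rank))

  Z <- .standardize_rows(mat, zero_variance)
  G <- nrow(Z)
  if (G < 2L) stop("fewer than 2 genes remain after zero-variance filtering")
  ids <- rownames(Z)
  nb <- scheme$n_bins

  counts <- matrix(0L, G, nb)
  mom <- matrix(NA_real_, G, 4L)
  degen <- logical(G)
  starts <- seq(1L, G, by = as.integer(block_size))
  for (s in starts) {
    idx <- s:min(s + block_size - 1L, G)
    R <- Z[idx, , drop = FALSE] %*% t(Z)
    R[R > 1] <- 1
    R[R < -1] <- -1
    for (j in seq_along(idx)) {
      g <- idx[j]
      r <- R[j, -g]
      counts[g, ] <- bin_counts(r, scheme)
      m <- corr_moments(r, estimator)
      mom[g, ] <- c(m$mean, m$sd, m$skewness, m$kurtosis)
      degen[g] <- m$degenerate
    }
  }
  if (any(degen))
    message(sum(degen), " gene(s) with a degenerate (constant) correlation ",
            "distribution: ", paste(head(ids[degen], 5L), collapse = ", "))

  out <- data.frame(gene_id = ids, counts, counts / (G - 1L), mom,
                    degenerate = degen,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c("gene_id", paste0("count_", seq_len(nb)),
                  paste0("prop_", seq_len(nb)),
                  "mean", "sd", "skewness", "kurtosis", "degenerate")
  rownames(out) <- NULL
  attr(out, "scheme") <- scheme
  attr(out, "n_genes") <- G
  class(out) <- c("coex_summaries", "data.frame")
  out
}

.standardize_rows <- function(mat, zero_variance) {
  ctr <- mat - rowMeans(mat)
  ss <- sqrt(rowSums(ctr^2))
  zv <- ss == 0 | !is.finite(ss)
  if (any(zv)) {
    if (zero_variance == "error")
      stop("zero-variance gene(s): ",
           paste(head(rownames(mat)[zv], 5L), collapse = ", "))
    message("dropping ", sum(zv), " zero-variance gene(s): ",
            paste(head(rownames(mat)[zv], 5L), collapse = ", "))
    ctr <- ctr[!zv, , drop = FALSE]
    ss <- ss[!zv]
  }
  ctr / ss
}

#' Pooled correlation histogram over all gene pairs
#'
#' The overall frequency distribution of all G(G-1)/2 pairwise correlations,
#' the whole-transcriptome view that the per-gene distributions decompose.
#'
#' @inheritParams correlation_summaries
#' @return List with `counts`, `proportions` (per bin), `n_pairs`, `mean`
#'   and `sd` of the pooled correlations.
#' @export
pooled_correlation_histogram <- function(mat, scheme = bin_scheme(),
                                         block_size = 256L,
                                         zero_variance = c("error", "drop")) {
  mat <- as_expression_matrix(mat)
  zero_variance <- match.arg(zero_variance)
  if (ncol(mat) < 3L) stop("at least 3 samples are required")
  Z <- .standardize_rows(mat, zero_variance)
  G <- nrow(Z)
  counts <- integer(scheme$n_bins)
  s1 <- 0; s2 <- 0; n <- 0
  starts <- seq(1L, G, by = as.integer(block_size))
  for (s in starts) {
    idx <- s:min(s + block_size - 1L, G)
    R <- Z[idx, , drop = FALSE] %*% t(Z)
    R[R > 1] <- 1
    R[R < -1] <- -1
    for (j in seq_along(idx)) {
      g <- idx[j]
      if (g == G) next
      r <- R[j, (g + 1L):G]
      counts <- counts + bin_counts(r, scheme)
      s1 <- s1 + sum(r)
      s2 <- s2 + sum(r^2)
      n <- n + length(r)
    }
  }
  mu <- s1 / n
  list(counts = counts, proportions = counts / n, n_pairs = n,
       mean = mu, sd = sqrt(max(s2 / n - mu^2, 0)))
}
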