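#' First-order partial correlation
#'
#' Correlation between x and y after removing the linear effect of z:
#' \deqn{r_{xy.z} = (r_{xy} - r_{xz} r_{yz}) /
#'   \sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}.}
#'
#' @param r_xy,r_xz,r_yz Correlations; the conditioning correlations must
#'   lie strictly inside (-1, 1). Vectorized.
#' @return The partial correlation(s).
#' @examples
#' partial_correlation(0.9, 0, 0)        # no conditioning effect: 0.9
#' partial_correlation(0.9, 0.9, 0.81)   # ~0.669
#' @export
partial_correlation <- function(r_xy, r_xz, r_yz) {
  if (any(abs(r_xz) >= 1) || any(abs(r_yz) >= 1))
    stop("partial correlation undefined: a conditioning correlation is +/-1")
  (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
}

#' PCIT network filtering
#'
#' Partial Correlation and Information Theory filtering of a gene-gene
#' correlation matrix. For every gene trio (x, y, z), the three first-order
#' partial correlations are computed and the trio's local tolerance is the
#' mean absolute ratio of partial to direct correlation,
#' \deqn{\epsilon = \frac{1}{3}\left(\left|\frac{r_{xy.z}}{r_{xy}}\right| +
#'   \left|\frac{r_{xz.y}}{r_{xz}}\right| +
#'   \left|\frac{r_{yz.x}}{r_{yz}}\right|\right).}
#' The connection between x and y is eliminated by that trio if
#' \eqn{|r_{xy}| \le \epsilon |r_{xz}|} and
#' \eqn{|r_{xy}| \le \epsilon |r_{yz}|}; an edge is significant only if no
#' trio eliminates it. Edges with exactly zero correlation are never
#' reported.
#'
#' The scan is evaluated one conditioning gene at a time with dense matrix
#' operations, so time is O(G^3) but memory stays O(G^2). Results are
#' deterministic and independent of gene ordering (up to relabeling of the
#' edge list). Runs comfortably to a few thousand genes; beyond
#' `max_genes` the cubic cost is refused with a pointer to subsetting.
#'
#' @param R Symmetric correlation matrix with unit diagonal, G >= 3;
#'   off-diagonal entries must lie strictly inside (-1, 1).
#' @param max_genes Guard against accidentally cubic-sized inputs.
#' @return Object of class `pcit_network`: list with `edges` (data frame
#'   `gene_a`, `gene_b`, `r` for kept pairs, a < b in matrix order),
#'   `degree` (named integer vector over all genes) and `n_genes`.
#' @export
pcit <- function(R, max_genes = 5000L) {
  if (!is.matrix(R) || nrow(R) != ncol(R))
    stop("'R' must be a square correlation matrix")
  G <- nrow(R)
  if (G < 3L) stop("PCIT needs at least 3 genes")
  if (G > max_genes)
    stop("matrix has ", G, " genes; PCIT is O(G^3) -- subset the genes or ",
         "raise 'max_genes' explicitly")
  if (any(!is.finite(R))) stop("correlation matrix has non-finite entries")
  if (max(abs(R - t(R))) > 1e-8) stop("correlation matrix is not symmetric")
  if (max(abs(diag(R) - 1)) > 1e-8) stop("diagonal must be 1")
  od <- abs(R[upper.tri(R)])
  if (length(od) && max(od) >= 1)
    stop("an off-diagonal correlation is +/-1 (duplicated gene?); ",
         "partial correlations are undefined")
  ids <- rownames(R)
  if (is.null(ids)) ids <- paste0("g", seq_len(G))
  R <- (R + t(R)) / 2
  diag(R) <- 1

  absR <- abs(R)
  sig <- matrix(TRUE, G, G)
  for (z in seq_len(G)) {
    rz <- R[, z]
    Mx <- matrix(rz, G, G)                  # r_xz, constant along rows
    My <- matrix(rz, G, G, byrow = TRUE)    # r_yz, constant along columns
    pxy <- (R - tcrossprod(rz)) / sqrt((1 - Mx^2) * (1 - My^2))
    pxz <- (Mx - R * My) / sqrt((1 - R^2) * (1 - My^2))
    pyz <- (My - R * Mx) / sqrt((1 - R^2) * (1 - Mx^2))
    eps <- (abs(pxy / R) + abs(pxz / Mx) + abs(pyz / My)) / 3
    drop <- absR <= eps * abs(Mx) & absR <= eps * abs(My)
    drop[is.na(drop)] <- FALSE
    drop[z, ] <- FALSE
    drop[, z] <- FALSE
    sig <- sig & !drop
  }
  keep <- sig & upper.tri(sig) & absR > 0
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(gene_a = ids[idx[, 1L]], gene_b = ids[idx[, 2L]],
                      r = R[keep], stringsAsFactors = FALSE)
  degree <- tabulate(c(idx[, 1L], idx[, 2L]), nbins = G)
  names(degree) <- ids
  structure(list(edges = edges, degree = degree, n_genes = G),
            class = "pcit_network")
}

#' @export
print.pcit_network <- function(x, ...) {
  cat("PCIT network:", x$n_genes, "genes,", nrow(x$edges),
      "significant edges; mean degree",
      format(round(mean(x$degree), 2)), "\n")
  invisible(x)
}
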