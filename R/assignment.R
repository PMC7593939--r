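#' Distances from observed summaries to every template
#'
#' Euclidean distance of each gene's observed correlation-distribution
#' summary to each template shape, over 12 commensurate components: the
#' `n_bins` bin proportions and the four moments,
#' \deqn{D_{ij} = \sqrt{\sum_k (OBP_{ik}-EBP_{jk})^2 + (OMN_i-EMN_j)^2 +
#'   (OSD_i-ESD_j)^2 + (OSK_i-ESK_j)^2 + (OKU_i-EKU_j)^2}.}
#'
#' Bin terms are compared on the fraction scale (summing to 1), so the bin
#' and moment terms have comparable magnitude; `percent_scale = TRUE`
#' compares bins on the percent scale (summing to 100) instead, under which
#' the bin terms dominate the distance by roughly four orders of magnitude.
#'
#' @param summaries A [correlation_summaries()] result, or any data frame
#'   with columns `prop_1..prop_B`, `mean`, `sd`, `skewness`, `kurtosis`
#'   and `gene_id`.
#' @param registry A `template_registry` on the same bin scheme.
#' @param percent_scale Compare bin proportions on the percent scale.
#' @return Numeric genes-by-8 matrix of distances (rownames = gene IDs).
#' @export
shape_distances <- function(summaries, registry, percent_scale = FALSE) {
  stopifnot(inherits(registry, "template_registry"))
  nb <- ncol(registry$ebp)
  pcols <- paste0("prop_", seq_len(nb))
  if (!all(pcols %in% names(summaries)))
    stop("summaries have a different bin count than the registry (need ",
         "columns ", pcols[1L], "..", pcols[nb], ")")
  obs_b <- as.matrix(summaries[pcols])
  obs_m <- as.matrix(summaries[c("mean", "sd", "skewness", "kurtosis")])
  sc <- if (percent_scale) 100 else 1
  D <- matrix(NA_real_, nrow(obs_b), 8L,
              dimnames = list(summaries$gene_id, rownames(registry$ebp)))
  for (j in 1:8) {
    db <- sweep(obs_b, 2L, registry$ebp[j, ]) * sc
    dm <- sweep(obs_m, 2L, registry$moments[j, ])
    D[, j] <- sqrt(rowSums(db^2) + rowSums(dm^2))
  }
  D
}

#' Similarities from distances
#'
#' Per gene, rescales the 8 template distances linearly so the closest
#' template scores 1 and the farthest 0:
#' \deqn{S_j = 1 - (D_j - \min D) / (\max D - \min D).}
#' When all 8 distances are identical the range is zero; by convention all
#' similarities are then 1 (flagged downstream as a tie).
#'
#' @param D Numeric matrix of distances (genes x 8) or a single gene's
#'   vector of 8 distances.
#' @return Similarities of the same shape as `D`, each row in \[0, 1\].
#' @export
similarities_from_distances <- function(D) {
  vec <- is.null(dim(D))
  if (vec) D <- matrix(D, nrow = 1L)
  lo <- apply(D, 1L, min)
  rng <- apply(D, 1L, max) - lo
  S <- 1 - (D - lo) / ifelse(rng == 0, 1, rng)
  S[rng == 0, ] <- 1
  if (vec) S[1L, ] else S
}

#' Probabilities from similarities
#'
#' Normalizes each gene's similarities to sum to one:
#' \deqn{P_j = S_j / \sum_j S_j.}
#'
#' @param S Similarity matrix (genes x 8) or vector of 8.
#' @return Probabilities of the same shape as `S`; rows sum to 1.
#' @export
probabilities_from_similarities <- function(S) {
  vec <- is.null(dim(S))
  if (vec) S <- matrix(S, nrow = 1L)
  tot <- rowSums(S)
  # the minimum-distance template always has similarity 1, so the total is
  # positive by construction; assert defensively
  stopifnot(all(tot > 0))
  P <- S / tot
  if (vec) P[1L, ] else P
}

#' Assign every gene to a template shape
#'
#' Runs the distance, similarity and probability transformations and assigns
#' each gene to the template with the largest probability. Exact ties on the
#' maximum (including the degenerate all-equal-distance case) are broken
#' toward the lowest shape ID and flagged.
#'
#' @inheritParams shape_distances
#' @return Data frame of class `coex_assignment` with `gene_id`,
#'   `prob_1..prob_8`, `shape` (1..8), and `tie` (logical). The full
#'   distance and similarity matrices are attached as attributes
#'   `distances` and `similarities`.
#' @examples
#' reg <- default_templates()
#' # a synthetic summary equal to template 7 recovers shape 7 with D = 0
#' s <- data.frame(gene_id = "g", t(setNames(reg$ebp[7, ], paste0("prop_", 1:8))),
#'                 t(reg$moments[7, ]))
#' a <- assign_shapes(s, reg)
#' a$shape
#' @export
assign_shapes <- function(summaries, registry = default_templates(),
                          percent_scale = FALSE) {
  D <- shape_distances(summaries, registry, percent_scale)
  S <- similarities_from_distances(D)
  P <- probabilities_from_similarities(S)
  shape <- max.col(P, ties.method = "first")
  pmax_val <- P[cbind(seq_len(nrow(P)), shape)]
  tie <- rowSums(P == pmax_val) > 1L
  out <- data.frame(gene_id = summaries$gene_id, P, shape = shape, tie = tie,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c("gene_id", paste0("prob_", 1:8), "shape", "tie")
  rownames(out) <- NULL
  attr(out, "distances") <- D
  attr(out, "similarities") <- S
  class(out) <- c("coex_assignment", "data.frame")
  out
}

#' Dichotomy transitions between two shape assignments
#'
#' Classifies per-gene shape changes by the fixed flag partition: whether
#' the pair crosses the null/non-null, unimodal/bimodal and
#' symmetric/skewed dichotomies.
#'
#' @param shape_a,shape_b Integer vectors of shape IDs (1..8), recycled to
#'   a common length.
#' @return Data frame with `changed`, `null_nonnull`, `unimodal_bimodal`,
#'   `symmetric_skewed` logical columns.
#' @export
transition_classes <- function(shape_a, shape_b) {
  stopifnot(all(shape_a %in% 1:8), all(shape_b %in% 1:8))
  fl <- .shape_flag_table
  data.frame(
    changed = shape_a != shape_b,
    null_nonnull = fl$is_null[shape_a] != fl$is_null[shape_b],
    unimodal_bimodal = fl$modality[shape_a] != fl$modality[shape_b],
    symmetric_skewed = fl$symmetry[shape_a] != fl$symmetry[shape_b])
}
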