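#' Compare shape assignments between two conditions
#'
#' Splits the samples by a two-level condition map, reruns the full
#' correlation-summary and shape-assignment pipeline independently within
#' each condition on the same gene set, and reports which genes change
#' shape and which dichotomies (null/non-null, unimodal/bimodal,
#' symmetric/skewed) each change crosses. Correlations are recomputed from
#' scratch within each condition; nothing is residualized across
#' conditions.
#'
#' Genes whose expression is constant within either condition have no
#' defined correlations there; they are excluded from the comparison and
#' listed in the `excluded` attribute.
#'
#' @param mat Genes-by-samples matrix covering both conditions.
#' @param condition_map Named character vector mapping every sample ID in
#'   `mat` to one of exactly two condition labels; each condition must keep
#'   at least 3 samples.
#' @param scheme A [bin_scheme()].
#' @param registry A `template_registry` (defaults to the shipped one).
#' @param percent_scale Passed to [assign_shapes()].
#' @return Data frame of class `coex_shift`: `gene_id`, `shape_a`,
#'   `shape_b` (shapes under the first and second condition label, sorted),
#'   `changed`, `null_nonnull`, `unimodal_bimodal`, `symmetric_skewed`.
#'   Attributes: `conditions` (the two labels), `excluded` (dropped gene
#'   IDs) and `summary` (counts and percentages of changed genes and of
#'   each transition class among them).
#' @export
compare_conditions <- function(mat, condition_map, scheme = bin_scheme(),
                               registry = default_templates(scheme),
                               percent_scale = FALSE) {
  mat <- as_expression_matrix(mat)
  if (is.null(names(condition_map)))
    stop("'condition_map' must be a named vector (sample ID -> condition)")
  missing_samples <- setdiff(colnames(mat), names(condition_map))
  if (length(missing_samples))
    stop("samples without a condition label: ",
         paste(head(missing_samples, 5L), collapse = ", "))
  cm <- condition_map[colnames(mat)]
  conds <- sort(unique(cm))
  if (length(conds) != 2L)
    stop("condition comparison needs exactly 2 conditions, got ",
         length(conds))
  if (any(table(cm) < 3L))
    stop("each condition must retain at least 3 samples")

  mats <- lapply(conds, function(cc) mat[, cm == cc, drop = FALSE])

  # genes constant within either condition are excluded from the comparison
  ok <- Reduce(`&`, lapply(mats, function(m) {
    v <- rowSums((m - rowMeans(m))^2)
    v > 0 & is.finite(v)
  }))
  excluded <- rownames(mat)[!ok]
  if (length(excluded))
    message("excluding ", length(excluded), " gene(s) with zero variance ",
            "in one condition: ", paste(head(excluded, 5L), collapse = ", "))
  if (sum(ok) < 2L) stop("fewer than 2 genes usable in both conditions")

  shapes <- lapply(mats, function(m) {
    s <- correlation_summaries(m[ok, , drop = FALSE], scheme = scheme)
    assign_shapes(s, registry, percent_scale)$shape
  })

  out <- data.frame(gene_id = rownames(mat)[ok],
                    shape_a = shapes[[1L]], shape_b = shapes[[2L]],
                    transition_classes(shapes[[1L]], shapes[[2L]]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  n_changed <- sum(out$changed)
  attr(out, "conditions") <- conds
  attr(out, "excluded") <- excluded
  attr(out, "summary") <- list(
    n_genes = nrow(out),
    n_changed = n_changed,
    pct_changed = 100 * n_changed / nrow(out),
    pct_null_nonnull = if (n_changed) 100 * sum(out$null_nonnull) / n_changed else 0,
    pct_unimodal_bimodal = if (n_changed) 100 * sum(out$unimodal_bimodal) / n_changed else 0,
    pct_symmetric_skewed = if (n_changed) 100 * sum(out$symmetric_skewed) / n_changed else 0)
  class(out) <- c("coex_shift", "data.frame")
  out
}
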