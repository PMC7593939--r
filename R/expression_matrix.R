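#' Validate an expression matrix
#'
#' Checks the invariants every pipeline stage relies on: a numeric
#' genes-by-samples matrix with unique gene IDs as row names, unique sample
#' IDs as column names, and all values finite. Values are assumed already
#' normalized/log-scaled by the user (e.g. log2 FPKM or TPM).
#'
#' @param x Numeric matrix (genes in rows, samples in columns).
#' @return The validated matrix, invisibly unchanged apart from class checks.
#' @export
as_expression_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression data must be a numeric matrix (genes x samples)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix needs gene IDs as rownames and sample IDs as colnames")
  dup <- rownames(x)[duplicated(rownames(x))]
  if (length(dup))
    stop("duplicate gene ID: ", dup[1L])
  dup <- colnames(x)[duplicated(colnames(x))]
  if (length(dup))
    stop("duplicate sample ID: ", dup[1L])
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at gene '%s', sample '%s'",
                 rownames(x)[bad[1L]], colnames(x)[bad[2L]]))
  }
  x
}
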