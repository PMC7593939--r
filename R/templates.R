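## Fixed partition of the 8 shapes into the three dichotomies:
## null = {1,2}; unimodal = {1..4}, bimodal = {5..8};
## symmetric = {1,2,5,6}, skewed = {3,4,7,8};
## positive skew = {3,7} (excess negative correlations),
## negative skew = {4,8} (excess positive correlations).
.shape_flag_table <- data.frame(
  shape = 1:8,
  is_null = c(TRUE, TRUE, rep(FALSE, 6L)),
  modality = rep(c("unimodal", "bimodal"), each = 4L),
  symmetry = rep(c("symmetric", "symmetric", "skewed", "skewed"), 2L),
  skew_direction = rep(c("none", "none", "positive", "negative"), 2L),
  stringsAsFactors = FALSE)

## Shipped nominal bin proportions (fractions summing to 1). These encode
## the qualitative definition of each shape -- narrow/wide null, unimodal
## skewed mirror pair, inner/outer-mode bimodal, bimodal skewed mirror
## pair -- and are deliberately plain package constants: any study with its
## own calibrated table restores it through load_templates().
.default_ebp <- local({
  s3 <- c(.10, .30, .34, .15, .07, .03, .01, 0)
  s7 <- c(.28, .17, .07, .04, .04, .06, .13, .21)
  m <- rbind(
    c(0, 0, .05, .45, .45, .05, 0, 0),        # 1 null, narrow
    c(.02, .08, .15, .25, .25, .15, .08, .02), # 2 null, wide
    s3,                                        # 3 unimodal, positive skew
    rev(s3),                                   # 4 unimodal, negative skew
    c(.01, .15, .30, .04, .04, .30, .15, .01), # 5 bimodal, inner modes
    c(.22, .15, .08, .05, .05, .08, .15, .22), # 6 bimodal, outer modes
    s7,                                        # 7 bimodal, positive skew
    rev(s7))                                   # 8 bimodal, negative skew
  dimnames(m) <- list(paste0("shape_", 1:8), paste0("bin_", 1:8))
  m
})

#' Shape dichotomy flags
#'
#' The fixed partition of the eight template shapes: shapes 1-2 are null
#' (correlations concentrated near zero), 1-4 unimodal versus 5-8 bimodal,
#' and 1, 2, 5, 6 symmetric versus 3, 4, 7, 8 skewed, with positive skew
#' (excess negative correlations) for shapes 3 and 7 and negative skew
#' (excess positive correlations) for shapes 4 and 8.
#'
#' @return Data frame with columns `shape`, `is_null`, `modality`,
#'   `symmetry`, `skew_direction`.
#' @export
shape_flags <- function() .shape_flag_table

#' Expected moments of a template shape
#'
#' Moments of the discrete distribution that places mass `ebp[k]` at the
#' k-th bin midpoint, using the same population convention as
#' [corr_moments()], so observed and expected moments entering the template
#' distance share one definition.
#'
#' @param ebp Expected bin proportions, summing to 1.
#' @param scheme A [bin_scheme()] with `length(ebp)` bins.
#' @return Named numeric vector `mean`, `sd`, `skewness`, `kurtosis`
#'   (excess).
#' @examples
#' sc <- bin_scheme()
#' # all mass in the top bin: mean = its midpoint, sd = 0
#' template_moments(c(0, 0, 0, 0, 0, 0, 0, 1), sc)
#' # two-point distribution at -0.875 / +0.875: sd = 0.875, kurtosis = -2
#' template_moments(c(.5, 0, 0, 0, 0, 0, 0, .5), sc)
#' @export
template_moments <- function(ebp, scheme = bin_scheme()) {
  stopifnot(inherits(scheme, "bin_scheme"))
  if (length(ebp) != scheme$n_bins)
    stop("expected ", scheme$n_bins, " bin proportions, got ", length(ebp))
  if (any(ebp < 0)) stop("bin proportions must be non-negative")
  if (abs(sum(ebp) - 1) > 1e-6)
    stop("bin proportions must sum to 1 (got ", format(sum(ebp)), ")")
  x <- scheme$midpoints
  m <- sum(ebp * x)
  d <- x - m
  m2 <- sum(ebp * d^2)
  if (m2 < 1e-28)
    return(c(mean = m, sd = 0, skewness = 0, kurtosis = 0))
  c(mean = m, sd = sqrt(m2),
    skewness = sum(ebp * d^3) / m2^1.5,
    kurtosis = sum(ebp * d^4) / m2^2 - 3)
}

.build_registry <- function(ebp, scheme, provenance,
                            explicit_moments = NULL) {
  moments <- t(apply(ebp, 1L, template_moments, scheme = scheme))
  colnames(moments) <- c("mean", "sd", "skewness", "kurtosis")
  if (!is.null(explicit_moments)) {
    keep <- !is.na(explicit_moments)
    moments[keep] <- explicit_moments[keep]
  }
  rownames(moments) <- rownames(ebp)
  reg <- structure(
    list(ebp = ebp, moments = moments, flags = .shape_flag_table,
         scheme = scheme, provenance = provenance),
    class = "template_registry")
  validate_templates(reg)
  reg
}

#' Default template registry
#'
#' The eight shipped template shapes at the given bin scheme: expected bin
#' proportions, expected moments derived via [template_moments()], and the
#' fixed dichotomy flags. The nominal proportions are package constants
#' chosen to realize each shape's qualitative definition; they are
#' documented, printable and fully replaceable through [load_templates()]
#' when a study has its own calibrated table.
#'
#' @param scheme A [bin_scheme()] with 8 bins.
#' @return A `template_registry`: list with `ebp` (8 x 8 matrix), `moments`
#'   (8 x 4), `flags` (see [shape_flags()]), `scheme`, `provenance`.
#' @export
default_templates <- function(scheme = bin_scheme()) {
  if (scheme$n_bins != 8L)
    stop("default templates are defined for the 8-bin scheme; supply your ",
         "own table via load_templates() for other schemes")
  .build_registry(.default_ebp, scheme, "default")
}

#' @export
print.template_registry <- function(x, ...) {
  cat("Template registry (", x$provenance, "), ",
      nrow(x$ebp), " shapes x ", ncol(x$ebp), " bins\n", sep = "")
  print(round(cbind(x$ebp, x$moments), 3))
  invisible(x)
}

## Number of modes of a bin-proportion profile. Plateaus (equal adjacent
## bins) collapse to a single candidate; a mode is a run strictly above
## both neighbors (profile ends count as one-sided maxima).
.count_modes <- function(p) {
  v <- rle(as.numeric(p))$values
  k <- length(v)
  if (k == 1L) return(1L)
  up <- c(TRUE, v[-1L] > v[-k])
  down <- c(v[-k] > v[-1L], TRUE)
  sum(up & down)
}

#' Validate a template registry
#'
#' Machine-checks the contract every registry must satisfy: exactly 8
#' shapes; proportions summing to 1; the null predicate (at least
#' `null_fraction` of mass within |r| < 0.5, i.e. the central bins) holding
#' exactly for shapes flagged null; unimodal shapes having a single mode
#' and bimodal shapes at least two modes separated by a strict local
#' minimum; skewness sign matching the flagged direction for skewed shapes
#' and near zero for symmetric shapes. For the shipped defaults the mirror
#' pairing of shapes (3,4) and (7,8) is also enforced.
#'
#' @param registry A `template_registry`.
#' @param null_fraction Minimum central-mass fraction for null shapes.
#' @param symmetric_tol Largest |skewness| accepted for a symmetric shape.
#' @return The registry, invisibly, or an error naming the failed predicate.
#' @export
validate_templates <- function(registry, null_fraction = 0.80,
                               symmetric_tol = 0.05) {
  ebp <- registry$ebp
  mom <- registry$moments
  fl <- registry$flags
  sc <- registry$scheme
  if (nrow(ebp) != 8L)
    stop("a registry must define exactly 8 shapes, got ", nrow(ebp))
  if (ncol(ebp) != sc$n_bins)
    stop("templates have ", ncol(ebp), " bins but the scheme has ", sc$n_bins)
  bad <- which(abs(rowSums(ebp) - 1) > 1e-9)
  if (length(bad))
    stop("shape ", bad[1L], ": bin proportions do not sum to 1")
  central <- abs(sc$midpoints) < 0.5
  for (j in 1:8) {
    cm <- sum(ebp[j, central])
    if (fl$is_null[j] && cm < null_fraction - 1e-9)
      stop(sprintf("shape %d is flagged null but only %.2f of its mass lies in |r| < 0.5 (need >= %.2f)",
                   j, cm, null_fraction))
    if (!fl$is_null[j] && cm >= null_fraction - 1e-9)
      stop(sprintf("shape %d is flagged non-null but %.2f of its mass lies in |r| < 0.5",
                   j, cm))
    nm <- .count_modes(ebp[j, ])
    if (fl$modality[j] == "unimodal" && nm != 1L)
      stop(sprintf("shape %d is flagged unimodal but has %d modes", j, nm))
    if (fl$modality[j] == "bimodal" && nm < 2L)
      stop(sprintf("shape %d is flagged bimodal but has %d mode(s)", j, nm))
    sk <- mom[j, "skewness"]
    if (fl$skew_direction[j] == "positive" && sk <= 0)
      stop(sprintf("shape %d is flagged positively skewed but its skewness is %.3f", j, sk))
    if (fl$skew_direction[j] == "negative" && sk >= 0)
      stop(sprintf("shape %d is flagged negatively skewed but its skewness is %.3f", j, sk))
    if (fl$skew_direction[j] == "none" && abs(sk) > symmetric_tol)
      stop(sprintf("shape %d is flagged symmetric but its skewness is %.3f", j, sk))
  }
  if (identical(registry$provenance, "default")) {
    for (pair in list(c(3L, 4L), c(7L, 8L))) {
      if (any(abs(ebp[pair[1L], ] - rev(ebp[pair[2L], ])) > 1e-12))
        stop("default shapes ", pair[1L], " and ", pair[2L],
             " must be bin-reverses of each other")
    }
  }
  invisible(registry)
}

#' Read a template table
#'
#' Reads a tab-separated table of 8 rows (shapes 1..8) by `n_bins` bin
#' columns, on either the fraction (sum 1) or percent (sum 100) scale; rows
#' are normalized to fractions. Optional `mean`, `sd`, `skewness`,
#' `kurtosis` columns override the moments derived from the bin midpoints,
#' which supports exact replication of an externally calibrated template
#' set. The result is re-validated against the fixed flag partition.
#'
#' @param path Path to the TSV written by [write_templates()] or assembled
#'   by hand (optional leading `shape` column, then `bin_1..bin_B`).
#' @param scheme A [bin_scheme()].
#' @return A `template_registry` with `provenance = "user"`.
#' @export
load_templates <- function(path, scheme = bin_scheme()) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if ("shape" %in% names(tab)) {
    tab <- tab[order(tab$shape), setdiff(names(tab), "shape"), drop = FALSE]
  }
  momcols <- intersect(c("mean", "sd", "skewness", "kurtosis"), names(tab))
  bincols <- setdiff(names(tab), momcols)
  if (nrow(tab) != 8L)
    stop("template table must have 8 rows (one per shape), got ", nrow(tab))
  if (length(bincols) != scheme$n_bins)
    stop("template table has ", length(bincols), " bin columns but the ",
         "scheme has ", scheme$n_bins)
  ebp <- as.matrix(tab[bincols])
  if (!is.numeric(ebp) || any(!is.finite(ebp)) || any(ebp < 0))
    stop("bin columns must be finite non-negative numbers")
  rs <- rowSums(ebp)
  if (any(rs <= 0)) stop("a template row sums to zero")
  ebp <- ebp / rs  # fraction or percent scale both normalize to 1
  dimnames(ebp) <- list(paste0("shape_", 1:8),
                        paste0("bin_", seq_len(scheme$n_bins)))
  explicit <- NULL
  if (length(momcols)) {
    explicit <- matrix(NA_real_, 8L, 4L,
                       dimnames = list(NULL, c("mean", "sd", "skewness", "kurtosis")))
    for (cc in momcols) explicit[, cc] <- tab[[cc]]
  }
  .build_registry(ebp, scheme, "user", explicit)
}

#' Write a template table
#'
#' @param registry A `template_registry`.
#' @param path Output TSV path; [load_templates()] on the written file
#'   reproduces the registry.
#' @return `path`, invisibly.
#' @export
write_templates <- function(registry, path) {
  stopifnot(inherits(registry, "template_registry"))
  tab <- data.frame(shape = 1:8, registry$ebp, registry$moments,
                    check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
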