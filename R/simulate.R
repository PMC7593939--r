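#' Specification of a synthetic expression fixture
#'
#' Describes a latent-factor expression matrix with known co-expression
#' structure: each module draws its genes as
#' \eqn{x_g = w_g f_m + \sqrt{1 - w_g^2}\,\varepsilon_g} with a shared
#' standard-normal latent sample vector \eqn{f_m} per factor and
#' independent noise \eqn{\varepsilon_g}, so that two genes with weights
#' \eqn{w_a, w_b} on the same factor have expected correlation
#' \eqn{w_a w_b} (exactly, when `noise_sd = 1`). Genes with negative
#' weights anti-correlate with positive-weight genes on the same factor.
#' Noise genes are pure independent Gaussians.
#'
#' @param n_samples Number of samples (>= 3).
#' @param modules List of module descriptions, each a list/vector with
#'   `size` (genes), `weight` (signed, in (-1, 1), nonzero) and optionally
#'   `factor` (latent factor ID; modules sharing a factor are mutually
#'   correlated; defaults to one factor per module).
#' @param n_noise_genes Number of independent noise genes.
#' @param noise_sd SD of the idiosyncratic noise; values other than 1
#'   attenuate (or inflate) the implied correlations.
#' @param seed Mandatory RNG seed; regeneration with the same spec is
#'   bit-identical.
#' @param heavy_tails Draw noise from a t distribution (df = 3, scaled to
#'   unit variance) instead of a Gaussian, to probe Pearson robustness.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_samples, modules = list(), n_noise_genes = 0L,
                         noise_sd = 1, seed, heavy_tails = FALSE) {
  if (missing(seed) || length(seed) != 1L || is.na(seed))
    stop("a single integer 'seed' is mandatory")
  if (n_samples < 3L) stop("'n_samples' must be at least 3")
  modules <- lapply(modules, function(m) {
    m <- as.list(m)
    if (is.null(m$size) || m$size < 1L) stop("module 'size' must be >= 1")
    if (is.null(m$weight) || abs(m$weight) >= 1 || m$weight == 0)
      stop("module 'weight' must be nonzero and strictly inside (-1, 1)")
    m
  })
  for (i in seq_along(modules))
    if (is.null(modules[[i]]$factor)) modules[[i]]$factor <- i
  if (length(modules) + n_noise_genes == 0L)
    stop("the fixture must contain at least one gene")
  if (noise_sd <= 0) stop("'noise_sd' must be positive")
  structure(list(n_samples = as.integer(n_samples), modules = modules,
                 n_noise_genes = as.integer(n_noise_genes),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 heavy_tails = isTRUE(heavy_tails)),
            class = "fixture_spec")
}

.spec_truth <- function(spec) {
  sizes <- vapply(spec$modules, function(m) as.integer(m$size), 1L)
  n_mod_genes <- sum(sizes)
  G <- n_mod_genes + spec$n_noise_genes
  ids <- sprintf("gene_%0*d", nchar(G), seq_len(G))
  module <- rep(c(seq_along(sizes), NA_integer_),
                c(sizes, spec$n_noise_genes))
  weight <- rep(c(vapply(spec$modules, function(m) m$weight, 1), 0),
                c(sizes, spec$n_noise_genes))
  fac <- rep(c(vapply(spec$modules, function(m) as.integer(m$factor), 1L),
               NA_integer_), c(sizes, spec$n_noise_genes))
  # expected correlation-sign balance of each gene: how many strong
  # positive / negative partners its factor structure implies
  pos <- integer(G); neg <- integer(G)
  for (g in which(!is.na(module))) {
    same <- !is.na(fac) & fac == fac[g]
    sgn <- sign(weight[g] * weight[same])
    pos[g] <- sum(sgn > 0) - 1L  # exclude self
    neg[g] <- sum(sgn < 0)
  }
  expected_class <- ifelse(is.na(module), "null",
                    ifelse(pos > 0L & neg > 0L, "bimodal",
                    ifelse(pos > 0L, "positive", "negative")))
  data.frame(gene_id = ids, module = module, factor = fac, weight = weight,
             n_positive_partners = pos, n_negative_partners = neg,
             expected_class = expected_class, stringsAsFactors = FALSE)
}

#' Generate a synthetic expression matrix
#'
#' Draws the matrix described by a [fixture_spec()] and returns it with a
#' per-gene ground-truth table. The truth labels each gene's expected
#' co-expression character at the dichotomy level -- `"null"` (no strong
#' partners), `"positive"`/`"negative"` (one-sided strong correlations) or
#' `"bimodal"` (strong partners of both signs) -- rather than an exact
#' shape ID, since exact IDs depend on the template numerics in use.
#'
#' @param spec A [fixture_spec()].
#' @return List with `matrix` (genes x samples, dimnames set) and `truth`
#'   (data frame: `gene_id`, `module`, `factor`, `weight`,
#'   `n_positive_partners`, `n_negative_partners`, `expected_class`).
#' @examples
#' sp <- fixture_spec(20, modules = list(list(size = 5, weight = 0.9)),
#'                    n_noise_genes = 10, seed = 42)
#' sim <- simulate_expression(sp)
#' dim(sim$matrix)
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  truth <- .spec_truth(spec)
  G <- nrow(truth)
  n <- spec$n_samples
  set.seed(spec$seed)
  fac_ids <- unique(truth$factor[!is.na(truth$factor)])
  factors <- matrix(rnorm(length(fac_ids) * n), length(fac_ids), n,
                    dimnames = list(as.character(fac_ids), NULL))
  rnoise <- if (spec$heavy_tails) {
    function(n) stats::rt(n, df = 3) / sqrt(3)  # unit variance
  } else rnorm
  X <- matrix(NA_real_, G, n,
              dimnames = list(truth$gene_id, sprintf("s%03d", seq_len(n))))
  for (g in seq_len(G)) {
    e <- spec$noise_sd * rnoise(n)
    if (is.na(truth$module[g])) {
      X[g, ] <- e
    } else {
      w <- truth$weight[g]
      X[g, ] <- w * factors[as.character(truth$factor[g]), ] +
        sqrt(1 - w^2) * e
    }
  }
  list(matrix = X, truth = truth)
}

#' Generate a paired two-condition fixture
#'
#' Simulates the same gene set under two structural specifications (e.g.
#' genes that are noise in condition A but join a module in condition B),
#' column-binds the matrices with condition-prefixed sample IDs, and marks
#' which genes are rewired (expected co-expression class differs).
#'
#' @param spec_a,spec_b [fixture_spec()]s with identical total gene counts.
#' @param conditions Two condition labels. Default `c("A", "B")`.
#' @return List with `matrix`, `condition_map` (named vector sample ->
#'   condition), `truth_a`, `truth_b`, and `rewired` (logical per gene).
#' @export
simulate_two_condition <- function(spec_a, spec_b,
                                   conditions = c("A", "B")) {
  stopifnot(inherits(spec_a, "fixture_spec"),
            inherits(spec_b, "fixture_spec"),
            length(conditions) == 2L, conditions[1L] != conditions[2L])
  sim_a <- simulate_expression(spec_a)
  sim_b <- simulate_expression(spec_b)
  if (!identical(sim_a$truth$gene_id, sim_b$truth$gene_id))
    stop("the two specs imply different gene sets (sizes must match)")
  colnames(sim_a$matrix) <- paste0(conditions[1L], "_", colnames(sim_a$matrix))
  colnames(sim_b$matrix) <- paste0(conditions[2L], "_", colnames(sim_b$matrix))
  mat <- cbind(sim_a$matrix, sim_b$matrix)
  cmap <- setNames(rep(conditions, c(ncol(sim_a$matrix), ncol(sim_b$matrix))),
                   colnames(mat))
  list(matrix = mat, condition_map = cmap,
       truth_a = sim_a$truth, truth_b = sim_b$truth,
       rewired = sim_a$truth$expected_class != sim_b$truth$expected_class)
}
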