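#' Hypergeometric enrichment and depletion tails
#'
#' For a category of K genes among N, and a shape (or any gene set) of n
#' genes containing k category members, the enrichment p-value is the upper
#' tail P(X >= k) and the depletion p-value the lower tail P(X <= k) of
#' X ~ Hypergeometric(N, K, n). The upper tail is evaluated at k - 1 with
#' `lower.tail = FALSE` (the classic off-by-one of `phyper`); both tails
#' therefore satisfy the identity
#' `p_enrich + p_deplete = 1 + P(X = k)`.
#'
#' @param N Total genes. @param K Category genes among them.
#' @param n Genes in the shape/set. @param k Category genes in the set.
#' @return List with `p_enrich` and `p_deplete`.
#' @examples
#' hypergeometric_test(20, 5, 4, 4)  # 5/choose(20, 4) = 1.032e-3
#' @export
hypergeometric_test <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N)
    stop("need 0 <= K <= N and 0 <= n <= N")
  if (k > min(K, n) || k < max(0, n + K - N))
    stop("k = ", k, " outside the hypergeometric support [",
         max(0, n + K - N), ", ", min(K, n), "]")
  list(p_enrich = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
       p_deplete = phyper(k, K, N - K, n))
}

## normalize an annotation (long data frame gene_id/category) and warn once
## about annotated genes absent from the background
.annotation_sets <- function(annotation, background, categories = NULL) {
  if (!is.data.frame(annotation) ||
      !all(c("gene_id", "category") %in% names(annotation)))
    stop("'annotation' must be a data frame with columns gene_id, category")
  if (is.null(categories)) categories <- sort(unique(annotation$category))
  absent <- setdiff(unique(annotation$gene_id), background)
  if (length(absent))
    message(length(absent), " annotated gene(s) absent from the expression ",
            "matrix are ignored: ", paste(head(absent, 5L), collapse = ", "))
  lapply(setNames(categories, categories), function(cc)
    intersect(unique(annotation$gene_id[annotation$category == cc]),
              background))
}

## one row of enrichment bookkeeping
.enrich_row <- function(N, K, n, k, alpha) {
  if (K == 0L) {
    p <- list(p_enrich = 1, p_deplete = 1)
  } else {
    p <- hypergeometric_test(N, K, n, k)
  }
  data.frame(N = N, K = K, n = n, k = k,
             fold = if (n > 0L && K > 0L) (k / n) / (K / N) else NA_real_,
             p_enrich = p$p_enrich, p_deplete = p$p_deplete,
             significant = p$p_enrich <= alpha || p$p_deplete <= alpha)
}

#' Category enrichment within each shape
#'
#' For every (category, shape) pair, compares the within-shape proportion
#' of category genes to the overall proportion via both hypergeometric
#' tails. Raw p-values at `alpha` drive the `significant` flag (the
#' published decision rule applies no multiplicity correction to these
#' tests); Benjamini-Hochberg adjusted values over the whole
#' categories-by-shapes family are reported alongside for transparency.
#'
#' @param assignments An [assign_shapes()] result (or data frame with
#'   `gene_id` and `shape`).
#' @param annotation Data frame with `gene_id`, `category` columns (see
#'   [read_categories()]); a gene may carry several categories.
#' @param categories Categories to test; default all present.
#' @param alpha Significance level for the raw p-values. Default 0.05.
#' @return Data frame with one row per category x shape: `category`,
#'   `shape`, `N`, `K`, `n`, `k`, `fold` ((k/n)/(K/N)), `p_enrich`,
#'   `p_deplete`, `p_adj_enrich`, `p_adj_deplete` (BH), `significant`.
#' @export
shape_enrichment <- function(assignments, annotation, categories = NULL,
                             alpha = 0.05) {
  background <- assignments$gene_id
  N <- length(background)
  sets <- .annotation_sets(annotation, background, categories)
  if (!length(sets)) stop("no categories to test")
  empty <- names(sets)[vapply(sets, length, 1L) == 0L]
  if (length(empty))
    warning("category with zero genes in the matrix: ",
            paste(empty, collapse = ", "))
  rows <- list()
  for (cc in names(sets)) {
    K <- length(sets[[cc]])
    incat <- assignments$gene_id %in% sets[[cc]]
    for (s in 1:8) {
      inshape <- assignments$shape == s
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(category = cc, shape = s, stringsAsFactors = FALSE),
        .enrich_row(N, K, sum(inshape), sum(incat & inshape), alpha))
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj_enrich <- p.adjust(out$p_enrich, method = "BH")
  out$p_adj_deplete <- p.adjust(out$p_deplete, method = "BH")
  out <- out[c("category", "shape", "N", "K", "n", "k", "fold",
               "p_enrich", "p_deplete", "p_adj_enrich", "p_adj_deplete",
               "significant")]
  rownames(out) <- NULL
  out
}

#' Category enrichment in an arbitrary gene set
#'
#' Tests each category's representation in a gene subset (for example the
#' genes that change shape between conditions) against a full background.
#'
#' @param genes Character vector, the gene set of interest.
#' @param background Character vector of all eligible gene IDs.
#' @param annotation,categories,alpha As in [shape_enrichment()].
#' @return Data frame with one row per category (`category`, `N`, `K`,
#'   `n`, `k`, `fold`, `p_enrich`, `p_deplete`, `significant`).
#' @export
gene_set_enrichment <- function(genes, background, annotation,
                                categories = NULL, alpha = 0.05) {
  genes <- intersect(unique(genes), background)
  N <- length(background)
  n <- length(genes)
  sets <- .annotation_sets(annotation, background, categories)
  rows <- lapply(names(sets), function(cc)
    cbind(data.frame(category = cc, stringsAsFactors = FALSE),
          .enrich_row(N, length(sets[[cc]]), n,
                      length(intersect(genes, sets[[cc]])), alpha)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.dichotomy_split <- function(shape, dichotomy) {
  fl <- .shape_flag_table
  switch(dichotomy,
         null = factor(ifelse(fl$is_null[shape], "null", "non-null"),
                       levels = c("null", "non-null")),
         modality = factor(fl$modality[shape],
                           levels = c("unimodal", "bimodal")),
         symmetry = factor(fl$symmetry[shape],
                           levels = c("symmetric", "skewed")))
}

#' Chi-square test of a category against a shape dichotomy
#'
#' 2x2 test of independence between category membership and one of the
#' three fixed shape dichotomies: `"null"` (shapes 1-2 vs 3-8),
#' `"modality"` (1-4 vs 5-8) or `"symmetry"` (1,2,5,6 vs 3,4,7,8).
#' Pearson's statistic without continuity correction by default; set
#' `yates = TRUE` for the corrected variant.
#'
#' @inheritParams shape_enrichment
#' @param category Single category label to test.
#' @param dichotomy One of `"null"`, `"modality"`, `"symmetry"`.
#' @param yates Apply Yates continuity correction. Default FALSE.
#' @return List with `table` (2x2 counts), `statistic`, `df` (1),
#'   `p_value`, `category`, `dichotomy`.
#' @export
dichotomy_chisq <- function(assignments, annotation, category,
                            dichotomy = c("null", "modality", "symmetry"),
                            yates = FALSE) {
  dichotomy <- match.arg(dichotomy)
  sets <- .annotation_sets(annotation, assignments$gene_id, category)
  incat <- factor(ifelse(assignments$gene_id %in% sets[[category]],
                         "in", "out"), levels = c("in", "out"))
  cls <- .dichotomy_split(assignments$shape, dichotomy)
  tab <- table(category = incat, class = cls)
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
    stop("chi-square test undefined: a margin of the 2x2 table is zero ",
         "(category '", category, "', dichotomy '", dichotomy, "')")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  list(table = tab, statistic = unname(ct$statistic), df = 1L,
       p_value = ct$p.value, category = category, dichotomy = dichotomy)
}

#' One-way ANOVA of connectivity by shape
#'
#' Tests whether the number of significant connections per gene (degree,
#' e.g. from [pcit()]) differs among the assigned distribution shapes.
#'
#' @param degrees Named numeric vector of per-gene degrees (names are gene
#'   IDs), or a data frame with `gene_id` and `degree`.
#' @param assignments An [assign_shapes()] result.
#' @return List with `f_statistic`, `df_between`, `df_within`, `p_value`,
#'   `degenerate` (TRUE when all degrees are identical, in which case the
#'   F ratio is undefined and the p-value is reported as 1).
#' @export
degree_by_shape_anova <- function(degrees, assignments) {
  if (is.data.frame(degrees))
    degrees <- setNames(degrees$degree, degrees$gene_id)
  common <- intersect(names(degrees), assignments$gene_id)
  if (length(common) < 3L) stop("fewer than 3 genes with both degree and shape")
  deg <- degrees[common]
  shp <- assignments$shape[match(common, assignments$gene_id)]
  ns <- table(shp)
  if (length(ns) < 2L)
    stop("all genes fall in a single shape; ANOVA undefined")
  if (sum(ns >= 2L) < 2L)
    stop("need at least 2 shapes with at least 2 genes each")
  if (stats::var(deg) == 0)
    return(list(f_statistic = 0, df_between = length(ns) - 1L,
                df_within = length(deg) - length(ns), p_value = 1,
                degenerate = TRUE))
  a <- anova(lm(deg ~ factor(shp)))
  list(f_statistic = a$`F value`[1L], df_between = a$Df[1L],
       df_within = a$Df[2L], p_value = a$`Pr(>F)`[1L], degenerate = FALSE)
}

#' Shape enrichment of the most and least connected genes
#'
#' Defines the top and bottom degree sets by quantile (boundary ties are
#' all included, so a set may exceed the nominal fraction) and tests each
#' shape's representation in each set by both hypergeometric tails.
#'
#' @inheritParams degree_by_shape_anova
#' @param fraction Tail fraction in (0, 0.5). Default 0.05.
#' @param alpha Significance level. Default 0.05.
#' @return Data frame with one row per set x shape: `set` ("bottom"/"top"),
#'   `shape`, `N`, `K`, `n`, `k`, `fold`, `p_enrich`, `p_deplete`,
#'   `significant`. Here `K` is the shape size and `n` the degree-set size.
#' @export
extreme_degree_enrichment <- function(degrees, assignments,
                                      fraction = 0.05, alpha = 0.05) {
  if (!(fraction > 0 && fraction < 0.5))
    stop("'fraction' must lie strictly between 0 and 0.5")
  if (is.data.frame(degrees))
    degrees <- setNames(degrees$degree, degrees$gene_id)
  common <- intersect(names(degrees), assignments$gene_id)
  deg <- degrees[common]
  shp <- assignments$shape[match(common, assignments$gene_id)]
  N <- length(common)
  qlo <- quantile(deg, fraction, type = 1L, names = FALSE)
  qhi <- quantile(deg, 1 - fraction, type = 1L, names = FALSE)
  sets <- list(bottom = deg <= qlo, top = deg >= qhi)
  rows <- list()
  for (nm in names(sets)) {
    inset <- sets[[nm]]
    for (s in 1:8) {
      inshape <- shp == s
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(set = nm, shape = s, stringsAsFactors = FALSE),
        .enrich_row(N, sum(inshape), sum(inset), sum(inset & inshape), alpha))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
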