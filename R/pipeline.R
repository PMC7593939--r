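#' Run the full co-expression shape pipeline
#'
#' Orchestrates read -> correlate/bin -> assign -> (optional condition
#' comparison) -> category enrichment and dichotomy tests -> (optional
#' PCIT degree analyses) -> write, logging gene counts at each stage. All
#' inputs may be given as file paths or as the in-memory objects the
#' individual functions accept. The resolved settings are written next to
#' the outputs (`run_config.tsv`) so a run can be reproduced.
#'
#' @param expression Path to a delimited matrix (see
#'   [read_expression_matrix()]) or a genes-by-samples matrix.
#' @param out_dir Output directory.
#' @param categories Optional path or data frame of gene categories; when
#'   absent, enrichment and dichotomy tests are skipped with a message.
#' @param conditions Optional path or named vector mapping samples to two
#'   conditions; triggers the condition-split comparison.
#' @param templates Optional path to a template table or a
#'   `template_registry`; defaults to the shipped templates.
#' @param min_value_filter,log2_transform,delimiter Forwarded to
#'   [read_expression_matrix()] when `expression` is a path.
#' @param scheme A [bin_scheme()].
#' @param alpha Significance level for enrichment flags.
#' @param run_pcit Run PCIT and the degree analyses (O(G^3); off by
#'   default).
#' @param percent_scale Compare template bins on the percent scale.
#' @param zero_variance Forwarded to [correlation_summaries()].
#' @return Invisibly, a list with `summaries`, `assignments`, `enrichment`,
#'   `dichotomies`, `shifts`, `network`, `degree_anova`,
#'   `extreme_degree`, and `files` (written paths).
#' @export
run_pipeline <- function(expression, out_dir, categories = NULL,
                         conditions = NULL, templates = NULL,
                         min_value_filter = NULL, log2_transform = FALSE,
                         delimiter = NULL, scheme = bin_scheme(),
                         alpha = 0.05, run_pcit = FALSE,
                         percent_scale = FALSE,
                         zero_variance = c("error", "drop")) {
  zero_variance <- match.arg(zero_variance)
  mat <- if (is.character(expression)) {
    read_expression_matrix(expression, delimiter = delimiter,
                           min_value_filter = min_value_filter,
                           log2_transform = log2_transform)
  } else as_expression_matrix(expression)
  message("stage read: ", nrow(mat), " genes x ", ncol(mat), " samples")

  registry <- if (is.null(templates)) default_templates(scheme)
              else if (is.character(templates)) load_templates(templates, scheme)
              else templates
  annotation <- if (is.character(categories)) read_categories(categories)
                else categories
  # a bare path reads from disk; a named vector is already a condition map
  cmap <- if (is.character(conditions) && is.null(names(conditions)))
    read_condition_map(conditions) else conditions

  summaries <- correlation_summaries(mat, scheme = scheme,
                                     zero_variance = zero_variance)
  message("stage binning: ", nrow(summaries), " genes summarized")
  assignments <- assign_shapes(summaries, registry, percent_scale)
  stopifnot(nrow(assignments) == nrow(summaries))
  message("stage assignment: ",
          paste(sprintf("shape %d: %d", 1:8,
                        tabulate(assignments$shape, 8L)), collapse = ", "))

  enrichment <- NULL; dichotomies <- NULL
  if (!is.null(annotation)) {
    enrichment <- shape_enrichment(assignments, annotation, alpha = alpha)
    dichotomies <- list()
    for (cc in sort(unique(annotation$category)))
      for (d in c("null", "modality", "symmetry"))
        dichotomies[[paste(cc, d, sep = ".")]] <-
          tryCatch(dichotomy_chisq(assignments, annotation, cc, d),
                   error = function(e) NULL)
  } else {
    message("no category annotation supplied; enrichment skipped")
  }

  shifts <- NULL
  if (!is.null(cmap)) {
    shifts <- compare_conditions(mat, cmap, scheme, registry, percent_scale)
    s <- attr(shifts, "summary")
    message(sprintf(
      "stage conditions: %d of %d genes changed shape (%.1f%%); %.1f%% of changes cross null/non-null, %.1f%% unimodal/bimodal",
      s$n_changed, s$n_genes, s$pct_changed, s$pct_null_nonnull,
      s$pct_unimodal_bimodal))
  }

  network <- NULL; degree_anova <- NULL; extreme_degree <- NULL
  if (run_pcit) {
    Z <- .standardize_rows(mat[summaries$gene_id, , drop = FALSE], "error")
    R <- tcrossprod(Z)
    R[R > 1] <- 1; R[R < -1] <- -1
    diag(R) <- 1
    network <- pcit(R)
    message("stage pcit: ", nrow(network$edges), " significant edges")
    degree_anova <- degree_by_shape_anova(network$degree, assignments)
    extreme_degree <- extreme_degree_enrichment(network$degree, assignments,
                                                alpha = alpha)
  }

  tables <- list()
  if (!is.null(enrichment)) tables$shape_enrichment <- enrichment
  if (!is.null(shifts)) tables$shape_shifts <- as.data.frame(shifts)
  if (!is.null(network)) {
    tables$pcit_edges <- network$edges
    tables$pcit_degree <- data.frame(gene_id = names(network$degree),
                                     degree = unname(network$degree))
    tables$extreme_degree_enrichment <- extreme_degree
  }
  files <- write_results(assignments, out_dir, summaries = summaries,
                         tables = tables)
  cfg <- data.frame(
    setting = c("n_genes", "n_samples", "n_bins", "alpha", "percent_scale",
                "run_pcit", "templates", "min_value_filter",
                "log2_transform"),
    value = c(nrow(mat), ncol(mat), scheme$n_bins, alpha, percent_scale,
              run_pcit, registry$provenance,
              if (is.null(min_value_filter)) "none" else min_value_filter,
              log2_transform))
  cfgf <- file.path(out_dir, "run_config.tsv")
  write.table(cfg, cfgf, sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(summaries = summaries, assignments = assignments,
                 enrichment = enrichment, dichotomies = dichotomies,
                 shifts = shifts, network = network,
                 degree_anova = degree_anova,
                 extreme_degree = extreme_degree,
                 files = c(files, cfgf)))
}
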