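#' Read a gene expression matrix
#'
#' Reads a delimited text matrix with gene IDs in the first column and a
#' header row of sample IDs. Values are taken as provided (assumed already
#' normalized); an optional strict positivity-style row filter and an
#' optional log2 transform reproduce the common preprocessing of FPKM/TPM
#' tables. The filter runs BEFORE the transform, and both decisions are
#' recorded in the `provenance` attribute.
#'
#' The default pseudocount for the log2 transform is 0 when a non-negative
#' `min_value_filter` guarantees strictly positive values, and 1 otherwise.
#'
#' @param path Input file.
#' @param delimiter Field separator; by default auto-detected from the
#'   header line (tab, then comma).
#' @param min_value_filter If non-NULL, keep only genes whose value is
#'   strictly greater than this threshold in EVERY sample.
#' @param log2_transform Apply `log2(x + pseudocount)` after filtering.
#' @param pseudocount Overrides the pseudocount default described above.
#' @return Numeric genes-by-samples matrix with a `provenance` character
#'   attribute; duplicate gene IDs, non-numeric cells and an empty
#'   post-filter matrix are hard errors.
#' @export
read_expression_matrix <- function(path, delimiter = NULL,
                                   min_value_filter = NULL,
                                   log2_transform = FALSE,
                                   pseudocount = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter)) {
    hdr <- readLines(path, n = 1L)
    delimiter <- if (grepl("\t", hdr, fixed = TRUE)) "\t" else ","
  }
  df <- read.table(path, sep = delimiter, header = TRUE,
                   check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character", comment.char = "",
                   quote = "\"")
  if (ncol(df) < 2L) stop("expected a gene ID column plus sample columns")
  gene_ids <- df[[1L]]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) stop("duplicate gene ID: ", dup[1L])
  sample_ids <- colnames(df)[-1L]
  vals <- matrix(NA_real_, nrow(df), length(sample_ids),
                 dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row %d (gene '%s'), column '%s'",
                   col[bad[1L]], bad[1L], gene_ids[bad[1L]], sample_ids[j]))
    vals[, j] <- num
  }
  prov <- sprintf("read %d genes x %d samples from %s (delimiter '%s')",
                  nrow(vals), ncol(vals), path,
                  if (delimiter == "\t") "\\t" else delimiter)
  if (!is.null(min_value_filter)) {
    keep <- rowSums(vals > min_value_filter) == ncol(vals)
    prov <- c(prov, sprintf(
      "filter: value > %s in all samples; %d of %d genes kept",
      format(min_value_filter), sum(keep), length(keep)))
    vals <- vals[keep, , drop = FALSE]
    if (nrow(vals) == 0L)
      stop("no genes remain after the min-value filter")
  }
  if (log2_transform) {
    pc <- if (!is.null(pseudocount)) pseudocount
          else if (!is.null(min_value_filter) && min_value_filter >= 0) 0
          else 1
    vals <- log2(vals + pc)
    prov <- c(prov, sprintf("transform: log2(x + %s)", format(pc)))
    if (any(!is.finite(vals)))
      stop("log2 transform produced non-finite values; use a pseudocount")
  }
  vals <- as_expression_matrix(vals)
  attr(vals, "provenance") <- prov
  vals
}

.read_two_columns <- function(path, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty ", what, " file: ", path)
  delim <- if (grepl("\t", lines[1L], fixed = TRUE)) "\t"
           else if (grepl(",", lines[1L], fixed = TRUE)) ","
           else "[[:space:]]+"
  parts <- strsplit(lines, delim)
  nf <- lengths(parts)
  bad <- which(nf != 2L)
  if (length(bad))
    stop("malformed line ", bad[1L], " in ", path,
         " (expected 2 fields, got ", nf[bad[1L]], ")")
  m <- do.call(rbind, parts)
  # optional header: a first line whose fields look like column names
  if (tolower(m[1L, 1L]) %in% c("gene", "gene_id", "geneid", "id", "sample",
                                "sample_id", "sampleid"))
    m <- m[-1L, , drop = FALSE]
  if (!nrow(m)) stop("no data rows in ", path)
  m
}

#' Read a gene-category annotation
#'
#' Two-column text (gene ID, category label), optional header, tab/comma/
#' whitespace separated. A gene may appear on several lines and so carry
#' several labels.
#'
#' @param path Input file.
#' @return Data frame with `gene_id` and `category` (unique pairs, input
#'   order).
#' @export
read_categories <- function(path) {
  m <- .read_two_columns(path, "annotation")
  out <- unique(data.frame(gene_id = trimws(m[, 1L]),
                           category = trimws(m[, 2L]),
                           stringsAsFactors = FALSE))
  if (any(!nzchar(out$gene_id))) stop("empty gene ID in ", path)
  rownames(out) <- NULL
  out
}

#' Read a sample-to-condition map
#'
#' @param path Two-column text: sample ID, condition label.
#' @return Named character vector mapping sample IDs to conditions.
#' @export
read_condition_map <- function(path) {
  m <- .read_two_columns(path, "condition map")
  if (anyDuplicated(m[, 1L]))
    stop("duplicate sample ID in condition map: ",
         m[duplicated(m[, 1L]), 1L][1L])
  setNames(trimws(m[, 2L]), trimws(m[, 1L]))
}

#' Write pipeline result tables
#'
#' Writes (a) the per-gene table combining bin proportions, moments,
#' template probabilities and the assigned shape; (b) any enrichment /
#' dichotomy / shift tables supplied; and (c) one plain gene-list file per
#' shape (one ID per line), directly usable with external GO tools.
#' Column order is deterministic and numeric values are written with full
#' precision, so re-reading a table reproduces it.
#'
#' @param assignments An [assign_shapes()] result.
#' @param out_dir Output directory, created if needed.
#' @param summaries The matching [correlation_summaries()] (optional; adds
#'   the observed bins and moments to the per-gene table).
#' @param tables Named list of additional data frames to write as
#'   `<name>.tsv` (e.g. enrichment results, shape shifts).
#' @return Character vector of written paths, invisibly.
#' @export
write_results <- function(assignments, out_dir, summaries = NULL,
                          tables = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- character(0L)
  per_gene <- assignments
  if (!is.null(summaries)) {
    stopifnot(identical(summaries$gene_id, assignments$gene_id))
    keep <- setdiff(names(summaries), c("gene_id",
                                        grep("^count_", names(summaries),
                                             value = TRUE)))
    per_gene <- cbind(summaries[c("gene_id", keep)],
                      assignments[setdiff(names(assignments), "gene_id")])
  }
  f <- file.path(out_dir, "gene_shape_assignments.tsv")
  write.table(.format_full(per_gene), f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(paths, f)
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    write.table(.format_full(tables[[nm]]), f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, f)
  }
  for (s in 1:8) {
    f <- file.path(out_dir, sprintf("shape_%d_genes.txt", s))
    writeLines(assignments$gene_id[assignments$shape == s], f)
    paths <- c(paths, f)
  }
  invisible(paths)
}

## full-precision text rendering so written tables round-trip to <= 1e-9
.format_full <- function(df) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  df
}
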