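# Shared builders for test fixtures. Everything is generated in code; no
# files are read from disk except those a test writes itself.

# a random genes x samples matrix with dimnames
random_matrix <- function(G, n, seed = 1) {
  set.seed(seed)
  matrix(rnorm(G * n), G, n,
         dimnames = list(sprintf("g%03d", seq_len(G)),
                         sprintf("s%02d", seq_len(n))))
}

# a one-row summaries data frame built from explicit proportions + moments,
# in the shape assign_shapes() consumes
make_summary <- function(props, mean, sd, skewness, kurtosis,
                         gene_id = "gene") {
  out <- data.frame(gene_id = gene_id, t(props), mean = mean, sd = sd,
                    skewness = skewness, kurtosis = kurtosis,
                    stringsAsFactors = FALSE)
  names(out)[2:(1 + length(props))] <- paste0("prop_", seq_along(props))
  out
}

# the summary that exactly equals template j of a registry
template_summary <- function(registry, j, gene_id = paste0("tpl", j)) {
  m <- registry$moments[j, ]
  make_summary(registry$ebp[j, ], m["mean"], m["sd"], m["skewness"],
               m["kurtosis"], gene_id = gene_id)
}

# random plausible summaries (proportions on the simplex + bounded moments)
random_summaries <- function(n, seed = 1, n_bins = 8) {
  set.seed(seed)
  props <- matrix(stats::rexp(n * n_bins), n, n_bins)
  props <- props / rowSums(props)
  out <- data.frame(gene_id = sprintf("r%03d", seq_len(n)), props,
                    mean = stats::runif(n, -0.5, 0.5),
                    sd = stats::runif(n, 0.05, 0.9),
                    skewness = stats::runif(n, -1.5, 1.5),
                    kurtosis = stats::runif(n, -2, 3),
                    stringsAsFactors = FALSE)
  names(out)[2:(1 + n_bins)] <- paste0("prop_", seq_len(n_bins))
  out
}

# write a small expression matrix to a delimited file
write_matrix_file <- function(mat, path, sep = "\t") {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}
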