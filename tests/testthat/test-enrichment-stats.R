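# exhaustive hypergeometric pmf via binomial coefficients, independent of
# phyper
pmf_oracle <- function(N, K, n, x) choose(K, x) * choose(N - K, n - x) / choose(N, n)

test_that("hypergeometric tails match exhaustive pmf summation", {
  h <- hypergeometric_test(20, 5, 4, 4)
  expect_equal(h$p_enrich, 5 / choose(20, 4), tolerance = 1e-12)
  set.seed(13)
  for (i in 1:120) {
    N <- sample(5:200, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    supp <- max(0, n + K - N):min(K, n)
    k <- sample(rep(supp, 2), 1)
    h <- hypergeometric_test(N, K, n, k)
    expect_equal(h$p_enrich, sum(pmf_oracle(N, K, n, k:min(K, n))),
                 tolerance = 1e-12)
    expect_equal(h$p_deplete, sum(pmf_oracle(N, K, n, supp[supp <= k])),
                 tolerance = 1e-12)
    # two-tail identity and K <-> n symmetry
    expect_equal(h$p_enrich + h$p_deplete, 1 + pmf_oracle(N, K, n, k),
                 tolerance = 1e-12)
    h2 <- hypergeometric_test(N, n, K, k)
    expect_equal(h2$p_enrich, h$p_enrich, tolerance = 1e-12)
    expect_equal(h2$p_deplete, h$p_deplete, tolerance = 1e-12)
  }
})

test_that("hypergeometric edge cases and bounds", {
  h <- hypergeometric_test(50, 0, 10, 0)  # empty category
  expect_equal(h$p_enrich, 1)
  expect_equal(h$p_deplete, 1)
  expect_error(hypergeometric_test(10, 12, 5, 3), "K <= N")
  expect_error(hypergeometric_test(20, 5, 4, 6), "support")
})

test_that("a shape monopolized by a category is strongly enriched", {
  # 50 hub genes all land in shape 4 among 500 genes
  set.seed(1)
  shapes <- c(rep(4L, 50), sample(c(1:3, 5:8), 450, replace = TRUE))
  assignments <- data.frame(gene_id = sprintf("g%03d", 1:500),
                            shape = shapes, stringsAsFactors = FALSE)
  ann <- data.frame(gene_id = sprintf("g%03d", 1:50), category = "HUB",
                    stringsAsFactors = FALSE)
  e <- shape_enrichment(assignments, ann)
  row4 <- e[e$shape == 4, ]
  expect_equal(row4$k, 50)
  expect_lt(row4$p_enrich, 1e-10)
  expect_true(row4$significant)
  expect_gt(row4$fold, 5)
  # shapes with zero category genes are depleted
  expect_true(all(e$p_deplete[e$shape != 4 & e$n > 10] < 0.05))
})

test_that("a category spanning all genes has fold 1 and no significance", {
  set.seed(2)
  assignments <- data.frame(gene_id = sprintf("g%02d", 1:80),
                            shape = sample(1:8, 80, replace = TRUE),
                            stringsAsFactors = FALSE)
  ann <- data.frame(gene_id = assignments$gene_id, category = "ALL",
                    stringsAsFactors = FALSE)
  e <- shape_enrichment(assignments, ann)
  expect_equal(e$fold[e$n > 0], rep(1, sum(e$n > 0)))
  expect_equal(e$p_enrich[e$n > 0], rep(1, sum(e$n > 0)))
})

test_that("annotated genes absent from the matrix are reported, not fatal", {
  assignments <- data.frame(gene_id = c("g1", "g2"), shape = c(1L, 4L))
  ann <- data.frame(gene_id = c("g1", "gX"), category = "DE")
  expect_message(e <- shape_enrichment(assignments, ann), "gX")
  expect_equal(e$K[1], 1L)
})

test_that("random categories are called significant at about the alpha rate", {
  # under the null, P(p_enrich <= 0.05) <= 0.05 per test (sub-uniform
  # because the statistic is discrete); 2000 tests at a fixed seed
  set.seed(99)
  N <- 400
  shapes <- rep(1:8, each = 50)
  hits <- 0L
  for (rep in 1:250) {
    cat_genes <- sample(N, 60)
    for (s in 1:8) {
      k <- sum(cat_genes %in% which(shapes == s))
      p <- hypergeometric_test(N, 60, 50, k)$p_enrich
      hits <- hits + (p <= 0.05)
    }
  }
  frac <- hits / 2000
  expect_lt(frac, 0.05 + 2 * sqrt(0.05 * 0.95 / 2000))
  expect_gt(frac, 0.005)
})

test_that("gene-set enrichment flags over-represented categories", {
  background <- sprintf("g%03d", 1:300)
  ann <- data.frame(gene_id = background[1:60], category = "DE")
  # a 30-gene set of which 25 are DE
  set.seed(4)
  genes <- c(background[1:25], background[250:254])
  e <- gene_set_enrichment(genes, background, ann)
  expect_equal(e$k, 25)
  expect_lt(e$p_enrich, 1e-6)
})

test_that("dichotomy chi-square matches the formula oracle", {
  set.seed(6)
  assignments <- data.frame(gene_id = sprintf("g%03d", 1:200),
                            shape = sample(1:8, 200, replace = TRUE),
                            stringsAsFactors = FALSE)
  ann <- data.frame(gene_id = sample(assignments$gene_id, 70),
                    category = "REG")
  for (d in c("null", "modality", "symmetry")) {
    res <- dichotomy_chisq(assignments, ann, "REG", d)
    O <- res$table
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    expect_equal(res$statistic, sum((O - E)^2 / E), tolerance = 1e-10)
    expect_equal(res$p_value, pchisq(res$statistic, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("balanced and perfectly dependent 2x2 tables behave as known", {
  # balanced: 10 in each cell -> statistic 0, p 1
  assignments <- data.frame(gene_id = sprintf("g%02d", 1:40),
                            shape = rep(c(1L, 5L), each = 20))
  ann <- data.frame(gene_id = sprintf("g%02d", c(1:10, 21:30)),
                    category = "DE")
  res <- dichotomy_chisq(assignments, ann, "DE", "modality")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # perfect dependence: (20,0;0,20) -> statistic 40
  ann2 <- data.frame(gene_id = sprintf("g%02d", 1:20), category = "DE")
  res2 <- dichotomy_chisq(assignments, ann2, "DE", "modality")
  expect_equal(res2$statistic, 40, tolerance = 1e-10)
  expect_lt(res2$p_value, 1e-9)
  # zero margin errors
  ann3 <- data.frame(gene_id = assignments$gene_id, category = "DE")
  expect_error(dichotomy_chisq(assignments, ann3, "DE", "null"), "margin")
})

test_that("degree ANOVA matches the textbook F computation", {
  set.seed(8)
  assignments <- data.frame(gene_id = sprintf("g%02d", 1:30),
                            shape = rep(c(1L, 4L), c(14, 16)))
  deg <- setNames(c(rnorm(14, 5, 1), rnorm(16, 9, 1)), assignments$gene_id)
  res <- degree_by_shape_anova(deg, assignments)
  groups <- split(deg, assignments$shape)
  gm <- mean(deg)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  f_oracle <- (ssb / 1) / (ssw / 28)
  expect_equal(res$f_statistic, f_oracle, tolerance = 1e-10)
  expect_equal(res$df_between, 1L)
  expect_equal(res$df_within, 28L)
})

test_that("degree ANOVA degenerate and error cases", {
  assignments <- data.frame(gene_id = sprintf("g%02d", 1:20),
                            shape = rep(c(1L, 2L), each = 10))
  deg <- setNames(rep(3, 20), assignments$gene_id)
  res <- degree_by_shape_anova(deg, assignments)
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
  one <- data.frame(gene_id = sprintf("g%02d", 1:20), shape = rep(1L, 20))
  expect_error(degree_by_shape_anova(deg, one), "single shape")
})

test_that("extreme-degree sets include boundary ties and reject fraction 0.5", {
  assignments <- data.frame(gene_id = sprintf("g%02d", 1:40),
                            shape = rep(1:8, each = 5))
  deg <- setNames(rep(7, 40), assignments$gene_id)  # uniform degrees
  e <- extreme_degree_enrichment(deg, assignments)
  expect_true(all(e$n == 40))  # ties make both sets cover all genes
  expect_equal(e$fold, rep(1, nrow(e)))
  expect_error(extreme_degree_enrichment(deg, assignments, fraction = 0.5),
               "strictly between")
})

test_that("low-degree null-shape genes enrich the bottom degree set", {
  # the ten least-connected genes are all shape 1 by construction
  set.seed(10)
  shapes <- rep(c(1L, 2L, 4L, 8L), c(80, 20, 50, 50))
  deg <- c(seq(0.1, 1, length.out = 10), runif(90, 5, 10),
           runif(100, 20, 60))
  assignments <- data.frame(gene_id = sprintf("g%03d", 1:200), shape = shapes)
  names(deg) <- assignments$gene_id
  e <- extreme_degree_enrichment(deg, assignments)
  bottom_null <- e[e$set == "bottom" & e$shape %in% 1:2, ]
  expect_lt(min(bottom_null$p_enrich), 0.05)
  # and the hubs sit in the non-null shapes
  top_nonnull <- e[e$set == "top" & e$shape %in% c(4, 8), ]
  expect_lt(min(top_nonnull$p_enrich), 0.05)
})
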