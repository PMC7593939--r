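test_that("bin convention covers [-1, 1] with a closed top bin", {
  sc <- bin_scheme()
  expect_equal(sc$edges, seq(-1, 1, by = 0.25))
  expect_equal(bin_index(c(-1, -0.75, 0, 0.25, 0.75, 1), sc),
               c(1L, 2L, 5L, 6L, 8L, 8L))
  # floating-point overshoot is clamped, not dropped
  expect_equal(bin_index(c(-1 - 1e-15, 1 + 1e-15), sc), c(1L, 8L))
  expect_equal(sum(bin_counts(runif(100, -1, 1), sc)), 100L)
})

test_that("moments match direct formula evaluation and handle symmetry", {
  set.seed(42)
  for (i in 1:20) {
    x <- runif(20, -1, 1)
    m <- corr_moments(x)
    mu <- sum(x) / 20
    m2 <- sum((x - mu)^2) / 20
    expect_equal(m$mean, mu, tolerance = 1e-12)
    expect_equal(m$sd, sqrt(m2), tolerance = 1e-12)
    expect_equal(m$skewness, (sum((x - mu)^3) / 20) / m2^1.5,
                 tolerance = 1e-12)
    expect_equal(m$kurtosis, (sum((x - mu)^4) / 20) / m2^2 - 3,
                 tolerance = 1e-12)
  }
  sym <- corr_moments(c(-1, 0, 1))
  expect_equal(sym$mean, 0)
  expect_equal(sym$skewness, 0)
})

test_that("constant input is flagged degenerate with zero moments", {
  m <- corr_moments(c(0.5, 0.5, 0.5))
  expect_true(m$degenerate)
  expect_equal(m$mean, 0.5)
  expect_equal(m$sd, 0)
  expect_equal(m$skewness, 0)
  expect_equal(m$kurtosis, 0)
})

test_that("sample estimator applies the textbook bias corrections", {
  set.seed(7)
  x <- rnorm(15)
  n <- 15
  m <- corr_moments(x, estimator = "sample")
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  g1 <- mean((x - mu)^3) / m2^1.5
  g2 <- mean((x - mu)^4) / m2^2 - 3
  expect_equal(m$sd, sd(x), tolerance = 1e-12)
  expect_equal(m$skewness, g1 * sqrt(n * (n - 1)) / (n - 2),
               tolerance = 1e-12)
  expect_equal(m$kurtosis, ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3)),
               tolerance = 1e-12)
  expect_error(corr_moments(c(1, 2, 3), estimator = "sample"), "at least 4")
})

test_that("summaries agree with a brute-force per-pair Pearson loop", {
  mat <- random_matrix(10, 12, seed = 3)
  s <- correlation_summaries(mat)
  sc <- bin_scheme()
  for (i in 1:10) {
    r <- vapply(setdiff(1:10, i), function(j) cor(mat[i, ], mat[j, ]), 1)
    expect_equal(unlist(s[i, paste0("count_", 1:8)], use.names = FALSE),
                 bin_counts(r, sc))
    m <- corr_moments(r)
    expect_equal(s$mean[i], m$mean, tolerance = 1e-10)
    expect_equal(s$sd[i], m$sd, tolerance = 1e-10)
    expect_equal(s$skewness[i], m$skewness, tolerance = 1e-10)
    expect_equal(s$kurtosis[i], m$kurtosis, tolerance = 1e-10)
  }
})

test_that("every gene's bin counts sum to G - 1", {
  mat <- random_matrix(25, 8, seed = 9)
  s <- correlation_summaries(mat)
  expect_true(all(rowSums(s[paste0("count_", 1:8)]) == 24L))
  expect_equal(unname(rowSums(s[paste0("prop_", 1:8)])), rep(1, 25),
               tolerance = 1e-9)
})

test_that("results are independent of block size and of gene order", {
  mat <- random_matrix(30, 10, seed = 5)
  s1 <- correlation_summaries(mat, block_size = 3L)
  s2 <- correlation_summaries(mat, block_size = 1000L)
  expect_equal(s1, s2, tolerance = 1e-12)
  perm <- sample(30)
  s3 <- correlation_summaries(mat[perm, ], block_size = 7L)
  expect_equal(s3[match(s1$gene_id, s3$gene_id), ], s1,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("permuting sample columns leaves every summary unchanged", {
  mat <- random_matrix(12, 9, seed = 8)
  perm <- sample(9)
  expect_equal(correlation_summaries(mat),
               correlation_summaries(mat[, perm]), tolerance = 1e-12)
})

test_that("negating one gene reverses its histogram and flips mean/skew", {
  mat <- random_matrix(15, 10, seed = 4)
  s1 <- correlation_summaries(mat)
  mat2 <- mat
  mat2[1, ] <- -mat2[1, ]
  s2 <- correlation_summaries(mat2)
  expect_equal(unlist(s2[1, paste0("count_", 1:8)], use.names = FALSE),
               rev(unlist(s1[1, paste0("count_", 1:8)], use.names = FALSE)))
  expect_equal(s2$mean[1], -s1$mean[1], tolerance = 1e-10)
  expect_equal(s2$skewness[1], -s1$skewness[1], tolerance = 1e-10)
  expect_equal(s2$sd[1], s1$sd[1], tolerance = 1e-10)
  expect_equal(s2$kurtosis[1], s1$kurtosis[1], tolerance = 1e-10)
})

test_that("perfectly collinear genes land in the top bin", {
  mat <- random_matrix(6, 8, seed = 2)
  mat[2, ] <- 2 * mat[1, ]  # Pearson is invariant to affine maps
  s <- correlation_summaries(mat)
  expect_gte(s$count_8[1], 1L)
  r12 <- cor(mat[1, ], mat[2, ])
  expect_equal(r12, 1, tolerance = 1e-12)
})

test_that("degenerate preconditions are enforced", {
  mat <- random_matrix(5, 4, seed = 1)
  mat[3, ] <- 7  # constant row
  expect_error(correlation_summaries(mat), "g003")
  expect_message(s <- correlation_summaries(mat, zero_variance = "drop"),
                 "g003")
  expect_equal(nrow(s), 4L)
  expect_error(correlation_summaries(random_matrix(5, 2)), "3 samples")
})

test_that("spearman option is invariant to monotone transforms", {
  mat <- random_matrix(8, 10, seed = 6)
  mat_t <- exp(mat)  # strictly increasing transform of every row
  expect_equal(correlation_summaries(mat, method = "spearman"),
               correlation_summaries(mat_t, method = "spearman"),
               tolerance = 1e-12)
})

test_that("pooled histogram counts all pairs once and matches moments", {
  mat <- random_matrix(20, 10, seed = 10)
  ph <- pooled_correlation_histogram(mat)
  expect_equal(ph$n_pairs, choose(20, 2))
  expect_equal(sum(ph$counts), choose(20, 2))
  R <- cor(t(mat))
  r <- R[upper.tri(R)]
  expect_equal(ph$mean, mean(r), tolerance = 1e-10)
  expect_equal(ph$counts, bin_counts(r, bin_scheme()))
})
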