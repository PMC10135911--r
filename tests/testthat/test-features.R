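zscored_fixture <- function(n_genes = 12, n_samples = 40, seed = 21) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), nrow = n_genes)
  x <- dplyr::bind_cols(
    tibble::tibble(gene_id = sprintf("G%03d", seq_len(n_genes))),
    tibble::as_tibble(m, .name_repair = ~ sprintf("s%d", seq_len(n_samples))))
  zscore_genes(expression_tibble(x, "microarray"))
}

test_that("z-scoring uses the population convention and drops flat genes", {
  x <- expression_tibble(tibble::tibble(
    gene_id = c("a", "b"), s1 = c(1, 5), s2 = c(2, 5), s3 = c(3, 5)
  ), "microarray")
  expect_warning(z <- zscore_genes(x), "zero-variance")
  expect_identical(attr(z, "excluded_genes"), "b")
  expect_equal(as.numeric(z[1, -1]), c(-1.22474487, 0, 1.22474487),
               tolerance = 1e-8)

  z2 <- zscored_fixture()
  m <- as.matrix(z2[-1])
  expect_equal(unname(rowMeans(m)), rep(0, nrow(m)), tolerance = 1e-12)
  expect_equal(unname(rowMeans(m^2)), rep(1, nrow(m)), tolerance = 1e-12)
  expect_error(zscore_genes(x[, 1:2]), "2 samples")
})

test_that("pair enumeration is canonical, complete and counted in closed form", {
  expect_equal(nrow(enumerate_pairs(c("b", "a"))), 1L)
  p4 <- enumerate_pairs(c("d", "b", "a", "c"))
  expect_equal(nrow(p4), 6L)
  brute <- t(utils::combn(sort(c("a", "b", "c", "d")), 2))
  expect_identical(p4$pair_a, brute[, 1])
  expect_identical(p4$pair_b, brute[, 2])
  expect_true(all(p4$pair_a < p4$pair_b))
  expect_equal(n_pairs(sprintf("g%d", 1:200)), 200 * 199 / 2)
  expect_error(enumerate_pairs(c("a", "a")), "Duplicate")
})

test_that("joint moments match a naive double-loop oracle", {
  z <- zscored_fixture(10, 30, seed = 7)
  mom <- compute_moments(z, chunk_size = 7)  # odd chunk to exercise chunking
  expect_equal(ncol(mom) - 2L, 49L)
  m <- as.matrix(z[-1])
  rownames(m) <- z$gene_id
  spec <- moment_spec()
  set.seed(11)
  for (i in sample(nrow(mom), 20)) {
    x <- m[mom$pair_a[i], ]
    y <- m[mom$pair_b[i], ]
    for (f in sample(nrow(spec), 6)) {
      expect_equal(mom[[spec$name[f]]][i],
                   naive_moment(x, y, spec$n[f], spec$m[f]),
                   tolerance = 1e-10)
    }
  }
})

test_that("moment (1,1) equals the population Pearson correlation", {
  z <- zscored_fixture(16, 50, seed = 13)
  mom <- compute_moments(z)
  m <- as.matrix(z[-1])
  rownames(m) <- z$gene_id
  set.seed(2)
  # Pearson r is ddof-free, and rows carry population mean 0 / variance 1,
  # so the (1,1) moment is the correlation with no finite-sample factor
  for (i in sample(nrow(mom), 100)) {
    r <- stats::cor(m[mom$pair_a[i], ], m[mom$pair_b[i], ])
    expect_equal(mom$m_1_1[i], r, tolerance = 1e-9)
  }
})

test_that("hand-evaluated moments and self-copy correlation are exact", {
  x <- c(-1, 0, 1) * sqrt(3 / 2)
  z <- expression_tibble(tibble::tibble(
    gene_id = c("a", "b"), s1 = x[1], s2 = x[2], s3 = x[3]
  ), "zscored")
  mom <- compute_moments(z)
  expect_equal(mom$m_1_1, 1, tolerance = 1e-9)        # identical copies
  expect_equal(mom$m_2_2, 1.5, tolerance = 1e-6)      # (1/3)(1.5^2 + 0 + 1.5^2)
})

test_that("features are invariant to gene-row order", {
  z <- zscored_fixture(8, 25, seed = 31)
  shuffled <- z[rev(seq_len(nrow(z))), ]
  shuffled <- expression_tibble(shuffled, "zscored")
  expect_equal(as.data.frame(compute_moments(z)),
               as.data.frame(compute_moments(shuffled)))
})

test_that("moment standardization is population-scaled and idempotent", {
  tab <- tibble::tibble(pair_a = c("a", "a"), pair_b = c("b", "c"),
                        m_1_1 = c(1, 3), m_1_2 = c(5, 5))
  expect_warning(std <- standardize_moments(tab), "constant")
  expect_equal(std$m_1_1, c(-1, 1))
  expect_equal(std$m_1_2, c(0, 0))

  z <- zscored_fixture(10, 30, seed = 17)
  mom <- compute_moments(z)
  s1 <- standardize_moments(mom)
  s2 <- standardize_moments(s1)
  expect_equal(as.matrix(s1[moment_cols <- grep("^m_", names(s1))]),
               as.matrix(s2[moment_cols]), tolerance = 1e-12)
})

test_that("PCA conserves variance, is orthonormal and finds low rank", {
  z <- zscored_fixture(14, 60, seed = 23)
  mom <- compute_moments(z)
  k_all <- 49L
  pca <- fit_pca(mom, n_components = k_all)
  expect_equal(crossprod(pca$loadings), diag(k_all), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(pca$explained_variance) <= 1e-12))
  std <- suppressWarnings(standardize_moments(mom))
  total_var <- sum(apply(as.matrix(std[grep("^m_", names(std))]), 2, stats::var))
  expect_equal(sum(pca$explained_variance), total_var, tolerance = 1e-8)

  # reconstruction with all components recovers the standardized features
  red <- transform_pca(pca, mom)
  recon <- as.matrix(red[grep("^pc_", names(red))]) %*% t(pca$loadings)
  expect_equal(recon, as.matrix(std[grep("^m_", names(std))]),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(fit_pca(mom, 50), "exceeds")
})

test_that("a rank-2 moment table has negligible variance past component 2", {
  set.seed(3)
  base <- matrix(rnorm(2 * 49), nrow = 2)
  coef <- matrix(rnorm(200 * 2), ncol = 2)
  m <- coef %*% base
  tab <- dplyr::bind_cols(
    tibble::tibble(pair_a = sprintf("a%03d", 1:200),
                   pair_b = sprintf("b%03d", 1:200)),
    tibble::as_tibble(m, .name_repair = ~ moment_spec()$name))
  pca <- fit_pca(tab, n_components = 10)
  expect_lt(max(pca$explained_variance[3:10]), 1e-10)
})

test_that("the default reduction width is 36", {
  z <- zscored_fixture(12, 40, seed = 41)
  mom <- compute_moments(z)
  red <- transform_pca(fit_pca(mom), mom)
  expect_equal(sum(grepl("^pc_", names(red))), 36L)
})
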