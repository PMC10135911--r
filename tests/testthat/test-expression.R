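test_that("expression matrices round-trip through delimited text", {
  x <- toy_expr()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(x, path)
  back <- read_expression_matrix(path, normalization = "raw_counts")
  expect_equal(dim(back), c(2L, 4L))
  expect_identical(back$gene_id, x$gene_id)
  expect_identical(names(back), names(x))

  rc <- random_counts(10, 5, seed = 3)$counts
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(rc, p2)
  back2 <- read_expression_matrix(p2)
  expect_equal(as.matrix(back2[-1]), as.matrix(rc[-1]), tolerance = 1e-12)
})

test_that("malformed matrices are rejected with the offending location", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "YAL001C\t1\t2", "YAL001C\t3\t4"), path)
  expect_error(read_expression_matrix(path), "YAL001C")

  writeLines(c("gene_id\ts1\ts2", "YAL001C\t1\tx"), path)
  expect_error(read_expression_matrix(path), "row 1.*s2")
})

test_that("gene-id mapping renames, keeps, drops and detects collisions", {
  x <- expression_tibble(tibble::tibble(
    gene_id = c("ADE2", "CLN3"), s1 = c(1, 2), s2 = c(3, 4)
  ), "microarray")
  map <- tibble::tibble(alias = "ADE2", canonical = "YOR128C")
  mapped <- apply_gene_id_map(x, map, on_missing = "keep")
  expect_identical(mapped$gene_id, c("YOR128C", "CLN3"))

  empty <- tibble::tibble(alias = character(), canonical = character())
  expect_identical(apply_gene_id_map(x, empty, "keep")$gene_id, x$gene_id)
  expect_equal(nrow(apply_gene_id_map(x, map, "drop")), 1L)
  expect_error(apply_gene_id_map(x, empty, "fail"), "not in the map")

  clash <- tibble::tibble(alias = c("ADE2", "CLN3"),
                          canonical = c("YOR128C", "YOR128C"))
  expect_error(apply_gene_id_map(x, clash, "keep"), "collision")
})

test_that("TPM matches the hand-computed formula and sums to one million", {
  counts <- expression_tibble(tibble::tibble(
    gene_id = c("a", "b"), s1 = c(10, 20)
  ), "raw_counts")
  lengths <- tibble::tibble(gene_id = c("a", "b"), length_bp = c(1000L, 2000L))
  tpm <- tpm_normalize(counts, lengths)
  expect_equal(tpm$s1, c(500000, 500000))
  expect_identical(expr_normalization(tpm), "tpm")

  rc <- random_counts(30, 8, seed = 5)
  t2 <- tpm_normalize(rc$counts, rc$lengths)
  expect_equal(unname(colSums(as.matrix(t2[-1]))), rep(1e6, 8),
               tolerance = 1e-6)
  # zeros map to zeros
  expect_true(all((as.matrix(t2[-1]) == 0) == (as.matrix(rc$counts[-1]) == 0)))
})

test_that("FPKM matches the hand formula and is depth-scale invariant", {
  counts <- expression_tibble(tibble::tibble(
    gene_id = c("a", "b"), s1 = c(10, 90)
  ), "raw_counts")
  lengths <- tibble::tibble(gene_id = c("a", "b"), length_bp = c(1000L, 500L))
  f <- fpkm_normalize(counts, lengths)
  expect_equal(f$s1[1], 10 * 1e9 / (1000 * 100))

  doubled <- expression_tibble(tibble::tibble(
    gene_id = c("a", "b"), s1 = c(20, 180)
  ), "raw_counts")
  f2 <- fpkm_normalize(doubled, lengths)
  expect_equal(f$s1, f2$s1, tolerance = 1e-12)
})

test_that("TPM and FPKM rank genes identically within a sample", {
  rc <- random_counts(25, 4, seed = 9)
  t <- as.matrix(tpm_normalize(rc$counts, rc$lengths)[-1])
  f <- as.matrix(fpkm_normalize(rc$counts, rc$lengths)[-1])
  for (j in 1:4) expect_identical(order(t[, j]), order(f[, j]))
})

test_that("degenerate all-zero samples are rejected or zeroed per config", {
  counts <- expression_tibble(tibble::tibble(
    gene_id = c("a", "b"), s1 = c(5, 5), s2 = c(0, 0)
  ), "raw_counts")
  lengths <- tibble::tibble(gene_id = c("a", "b"), length_bp = c(100L, 100L))
  expect_error(tpm_normalize(counts, lengths), "s2")
  expect_error(fpkm_normalize(counts, lengths), "s2")
  z <- tpm_normalize(counts, lengths, zero_sample = "zero")
  expect_equal(z$s2, c(0, 0))
})
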