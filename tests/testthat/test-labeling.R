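fake_feature_table <- function(m11) {
  n <- length(m11)
  ids_a <- sprintf("GA%02d", seq_len(n))
  ids_b <- sprintf("GB%02d", seq_len(n))
  tibble::tibble(pair_a = ids_a, pair_b = ids_b, m_1_1 = m11)
}

test_that("gold edge lists parse, dedupe and drop self-edges", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("regulator\ttarget", "TF1\tG1", "TF1\tG2", "TF2\tG1"), path)
  g <- load_gold_edges(path)
  expect_equal(nrow(g), 3L)

  writeLines(c("regulator\ttarget", "TF1\tTF1", "TF1\tG2"), path)
  expect_warning(g2 <- load_gold_edges(path), "self-edge")
  expect_equal(nrow(g2), 1L)
  expect_error(suppressWarnings(load_gold_edges(path, on_self_edge = "error")),
               "self-edge")

  writeLines(c("regulator\ttarget", "TF1\tG2", "TF1\tG2"), path)
  expect_message(g3 <- load_gold_edges(path), "duplicate")
  expect_equal(nrow(g3), 1L)
})

test_that("positives are the undirected gold pairs present in the table", {
  tab <- tibble::tibble(pair_a = c("A", "A", "B"), pair_b = c("B", "C", "C"),
                        m_1_1 = c(0.5, 0.1, 0.2))
  gold <- tibble::tibble(regulator = c("A", "B", "Z"),
                         target = c("B", "A", "Q"))
  pos <- build_positive_set(tab, gold)
  expect_equal(nrow(pos), 1L)         # A->B and B->A collapse to one pair
  expect_identical(pos$pair_a, "A")
  expect_equal(attr(pos, "n_skipped"), 1L)  # Z-Q not in the matrix

  none <- tibble::tibble(regulator = "X", target = "Y")
  expect_error(build_positive_set(tab, none), "No gold pair")
})

test_that("negative selection takes the lowest-|m11| pairs deterministically", {
  tab <- fake_feature_table(c(0.9, 0.05, -0.4, 0.01, 0.3))
  neg <- select_negatives(tab, gold = NULL, k = 2, exclude_gold = FALSE)
  expect_setequal(neg$abs_m11, c(0.01, 0.05))

  # ties broken by canonical pair id
  tie <- tibble::tibble(pair_a = c("B", "A"), pair_b = c("C", "Z"),
                        m_1_1 = c(0.1, -0.1))
  n1 <- select_negatives(tie, gold = NULL, k = 1, exclude_gold = FALSE)
  expect_identical(n1$pair_a, "A")

  expect_equal(nrow(select_negatives(tab, NULL, k = 5, exclude_gold = FALSE)), 5L)
  expect_error(select_negatives(tab, NULL, k = 6, exclude_gold = FALSE),
               "exceeds")
})

test_that("negative selection equals a brute-force sort on a large instance", {
  set.seed(8)
  tab <- fake_feature_table(rnorm(5000))
  k <- 750
  neg <- select_negatives(tab, gold = NULL, k = k, exclude_gold = FALSE)
  brute <- tab[order(abs(tab$m_1_1), tab$pair_a, tab$pair_b), ][seq_len(k), ]
  expect_identical(neg$pair_a, brute$pair_a)
  expect_equal(neg$abs_m11, abs(brute$m_1_1))
})

test_that("gold pairs are excluded from negatives when requested", {
  tab <- tibble::tibble(pair_a = c("A", "A", "B"), pair_b = c("B", "C", "C"),
                        m_1_1 = c(0.001, 0.5, 0.6))
  gold <- tibble::tibble(regulator = "B", target = "A")
  neg <- select_negatives(tab, gold, k = 1, exclude_gold = TRUE)
  expect_false(identical(c(neg$pair_a, neg$pair_b), c("A", "B")))
})

test_that("correlation histogram conserves counts", {
  tab <- fake_feature_table(seq(-1, 1, length.out = 400))
  h <- correlation_histogram(tab, n_bins = 20)
  expect_equal(sum(h$count), 400L)

  flat <- fake_feature_table(rep(0.3, 50))
  h2 <- correlation_histogram(flat, n_bins = 10)
  expect_equal(sum(h2$count > 0), 1L)
})

test_that("density overlap is ~1 for identical and ~0 for disjoint classes", {
  set.seed(4)
  v <- rnorm(4000)
  tab <- fake_feature_table(v)
  pos_same <- tab[sample(4000, 2000), c("pair_a", "pair_b")]
  ov1 <- density_overlap(tab, pos_same)
  expect_gt(ov1$overlap, 0.9)

  tab2 <- fake_feature_table(c(rnorm(2000, -10, 0.1), rnorm(2000, 10, 0.1)))
  ov0 <- density_overlap(tab2, tab2[1:2000, c("pair_a", "pair_b")])
  expect_lt(ov0$overlap, 0.05)
})

test_that("training sets assemble balanced, disjoint and reproducibly", {
  set.seed(6)
  tab <- fake_feature_table(rnorm(60))
  tab$pc_1 <- rnorm(60)
  tab$pc_2 <- rnorm(60)
  pos <- tab[1:20, c("pair_a", "pair_b")]
  neg <- tab[21:60, c("pair_a", "pair_b")]
  tr <- assemble_training_set(pos, neg, tab, n_pos = 5, n_neg = 5, seed = 2)
  expect_equal(nrow(tr), 10L)
  expect_equal(sum(tr$label), 5L)
  expect_identical(sort(unique(tr$provenance)), c("gold", "low-correlation"))
  expect_identical(names(tr)[5:6], c("pc_1", "pc_2"))

  tr2 <- assemble_training_set(pos, neg, tab, n_pos = 5, n_neg = 5, seed = 2)
  expect_identical(as.data.frame(tr), as.data.frame(tr2))

  expect_error(assemble_training_set(pos, neg, tab, n_pos = 21, n_neg = 5),
               "21")
  overlap <- tab[15:25, c("pair_a", "pair_b")]
  expect_error(assemble_training_set(pos, overlap, tab, 3, 3), "overlap")
})
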