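test_that("per-class accuracy and recall/precision match hand counts", {
  acc <- class_accuracies(c(0, 0, 1, 1), c(0, 1, 1, 1))
  expect_equal(acc$accuracy, c(50, 100))
  expect_equal(class_accuracies(c(0, 1), c(0, 1))$accuracy, c(100, 100))
  expect_equal(class_accuracies(c(0, 0, 1), c(1, 1, 1))$accuracy, c(0, 100))
  expect_error(class_accuracies(c(1, 1), c(1, 1)), "Both classes")

  rp <- recall_precision(c(1, 1, 0), c(1, 0, 0))
  expect_equal(rp$recall, 50)
  expect_equal(rp$precision, 100)
  none <- recall_precision(c(1, 0), c(0, 0))
  expect_equal(none$recall, 0)
  expect_true(is.na(none$precision))
})

test_that("perfect and anti-perfect scores give AUC exactly 1 and 0", {
  labels <- rep(c(0, 1), each = 20)
  perfect <- roc_with_error(labels, labels, n_resamples = 20, seed = 1)
  expect_identical(perfect$auc, 1)
  anti <- roc_with_error(labels, 1 - labels, n_resamples = 20, seed = 1)
  expect_identical(anti$auc, 0)
  expect_error(roc_with_error(rep(1, 5), rnorm(5)), "Both classes")
})

test_that("curve AUC matches brute-force concordance on random scores", {
  set.seed(14)
  labels <- rep(c(0, 1), 500)
  scores <- rnorm(1000)
  roc <- roc_with_error(labels, scores, n_resamples = 50, seed = 2)
  expect_gt(roc$auc, 0.45)
  expect_lt(roc$auc, 0.55)
  expect_equal(roc$auc, mw_auc(labels, scores), tolerance = 0.01)

  # and on an informative score
  scores2 <- labels * 1.5 + rnorm(1000)
  roc2 <- roc_with_error(labels, scores2, n_resamples = 50, seed = 2)
  expect_equal(roc2$auc, mw_auc(labels, scores2), tolerance = 0.01)
})

test_that("ROC means are proper rates and TPR is monotone along the sweep", {
  set.seed(5)
  labels <- rep(c(0, 1), 100)
  scores <- labels + rnorm(200)
  roc <- roc_with_error(labels, scores, n_resamples = 100, seed = 3)
  d <- roc$curve[order(roc$curve$x_mean, roc$curve$y_mean), ]
  expect_true(all(diff(d$y_mean) >= -1e-12))
  expect_true(all(d$x_mean >= 0 & d$x_mean <= 1))
  expect_true(all(d$y_mean >= 0 & d$y_mean <= 1))
})

test_that("PR curves match hand evaluation and degenerate cases", {
  labels <- rep(c(0, 1), each = 25)
  perfect <- pr_with_error(labels, as.numeric(labels), n_resamples = 20, seed = 1)
  achieved <- perfect$full[perfect$full$recall > 0, ]
  # every achieved recall is attainable at precision 1 for a perfect scorer
  best <- tapply(achieved$precision, achieved$recall, max, na.rm = TRUE)
  expect_true(all(best == 1))

  same <- pr_with_error(labels, rep(0.7, 50), n_resamples = 20, seed = 1)
  occupied <- unique(stats::na.omit(same$full[c("recall", "precision")]))
  expect_equal(nrow(occupied), 1L)
  expect_equal(occupied$recall, 1)
  expect_equal(occupied$precision, 0.5)  # prevalence

  # 6-point worked example: scores sorted descending -> labels 1,1,0,1,0,0
  lab6 <- c(1, 1, 0, 1, 0, 0)
  sc6 <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.2)
  pr6 <- pr_with_error(lab6, sc6, n_thresholds = 6, n_resamples = 10, seed = 1)
  at <- function(t) pr6$full[pr6$full$threshold == t, ]
  expect_equal(at(0.9)$precision, 1)
  expect_equal(at(0.9)$recall, 1 / 3)
  expect_equal(at(0.6)$precision, 3 / 4)
  expect_equal(at(0.6)$recall, 1)
})

test_that("bootstrap error bars shrink roughly as one over sqrt(n)", {
  sds <- vapply(c(100, 400, 1600), function(n) {
    set.seed(21)
    labels <- rep(c(0, 1), n / 2)
    scores <- labels + rnorm(n)
    roc <- roc_with_error(labels, scores, n_resamples = 100, seed = 4)
    mean(roc$curve$y_sd[is.finite(roc$curve$y_sd)])
  }, numeric(1))
  expect_lt(sds[2], 0.75 * sds[1])
  expect_lt(sds[3], 0.75 * sds[2])
})

test_that("network comparison partitions the union into the four categories", {
  gold <- tibble::tibble(regulator = "TF1", target = "e2")
  a <- tibble::tibble(regulator = "TF1", target = c("e1", "e2", "e3"))
  b <- tibble::tibble(regulator = "TF1", target = c("e2", "e3", "e4"))
  cmp <- compare_networks(a, b, gold, "TF1")
  get <- function(cat) sort(cmp$target[cmp$category == cat])
  expect_identical(get("shared_validated"), "e2")
  expect_identical(get("shared_unvalidated"), "e3")
  expect_identical(get("unique_a"), "e1")
  expect_identical(get("unique_b"), "e4")
  expect_false(any(duplicated(cmp$target)))
  expect_setequal(cmp$target, union(a$target, b$target))

  all_same <- compare_networks(a, a, a, "TF1")
  expect_true(all(all_same$category == "shared_validated"))
  disj <- compare_networks(a, tibble::tibble(regulator = "TF1", target = "z9"),
                           gold, "TF1")
  expect_false(any(grepl("^shared", disj$category)))
})

test_that("network exports round-trip through SIF and TSV", {
  gold <- tibble::tibble(regulator = "TF1", target = "e2")
  a <- tibble::tibble(regulator = "TF1", target = c("e1", "e2"))
  b <- tibble::tibble(regulator = "TF1", target = c("e2", "e4"))
  cmp <- compare_networks(a, b, gold, "TF1")

  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(cmp, sif, "sif")
  expect_length(readLines(sif), nrow(cmp))
  expect_equal(as.data.frame(read_network(sif, "sif")), as.data.frame(cmp))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(cmp, tsv, "tsv")
  expect_equal(as.data.frame(read_network(tsv, "tsv")), as.data.frame(cmp))

  empty <- cmp[0, ]
  export_network(empty, tsv, "tsv")
  expect_identical(readLines(tsv), "regulator\ttarget\tcategory")
})
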