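# shared fixtures and independent oracles, all built in code

toy_expr <- function() {
  expression_tibble(tibble::tibble(
    gene_id = c("YAL001C", "YBR002W"),
    s1 = c(10, 20), s2 = c(0, 5), s3 = c(3, 7)
  ), normalization = "raw_counts")
}

random_counts <- function(n_genes = 20, n_samples = 6, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, lambda = 50), nrow = n_genes)
  x <- tibble::as_tibble(m, .name_repair = ~ sprintf("s%d", seq_len(n_samples)))
  x <- dplyr::bind_cols(tibble::tibble(gene_id = sprintf("G%03d", seq_len(n_genes))), x)
  list(counts = expression_tibble(x, "raw_counts"),
       lengths = tibble::tibble(gene_id = x$gene_id,
                                length_bp = sample(500:5000, n_genes)))
}

# two well-separated Gaussian blobs as a labeled training tibble
blob_training <- function(n_per_class = 25, sep = 1.2, d = 2, seed = 42) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * d, mean = -sep), ncol = d),
             matrix(rnorm(n_per_class * d, mean = sep), ncol = d))
  out <- tibble::as_tibble(X, .name_repair = ~ sprintf("f%d", seq_len(d)))
  out$label <- rep(c(0L, 1L), each = n_per_class)
  out
}

# naive double-loop joint moment oracle
naive_moment <- function(x, y, n, m) {
  s <- 0
  for (k in seq_along(x)) s <- s + unname(x[k])^n * unname(y[k])^m
  s / length(x)
}

# brute-force Mann-Whitney concordance AUC (ties count 1/2)
mw_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# central-difference gradient of the REWKLR objective at a fitted model
rewklr_numeric_grad <- function(model, h = 1e-5) {
  X <- model$support_points
  y <- model$labels
  w <- unname(model$class_weights[y + 1L])
  K <- rbf_kernel(X, X, model$config$sigma, "sigma")
  diag(K) <- diag(K) + model$config$jitter
  lambda <- model$config$lambda
  J <- function(theta) {
    a <- theta[seq_len(nrow(X))]
    b <- theta[nrow(X) + 1L]
    p <- stats::plogis(drop(K %*% a) + b)
    sum(w * ifelse(y == 1, log(p), log(1 - p))) -
      (lambda / 2) * drop(crossprod(a, K %*% a))
  }
  theta <- c(model$alpha, model$intercept)
  vapply(seq_along(theta), function(i) {
    e <- rep(0, length(theta))
    e[i] <- h
    (J(theta + e) - J(theta - e)) / (2 * h)
  }, numeric(1))
}

# REWKLR objective for an arbitrary (alpha, b), used by the optim oracle
rewklr_obj_fn <- function(X, y, w, lambda, sigma, jitter = 1e-8) {
  K <- rbf_kernel(X, X, sigma, "sigma")
  diag(K) <- diag(K) + jitter
  function(theta) {
    a <- theta[seq_len(nrow(X))]
    b <- theta[nrow(X) + 1L]
    p <- stats::plogis(drop(K %*% a) + b)
    sum(w * ifelse(y == 1, log(p), log(1 - p))) -
      (lambda / 2) * drop(crossprod(a, K %*% a))
  }
}
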