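#' Z-score gene expression rows
#'
#' Standardizes every gene row to mean 0, variance 1 using the population
#' (ddof 0) convention, so that the (1,1) joint moment of two z-scored genes
#' equals their Pearson correlation exactly. Zero-variance genes cannot be
#' standardized; they are dropped with a warning and recorded in the
#' `excluded_genes` attribute of the result.
#'
#' @param x An expression table with at least 2 samples.
#' @return An expression table tagged `zscored`, with attribute
#'   `excluded_genes` listing the dropped gene ids.
#' @export
zscore_genes <- function(x) {
  m <- expr_values(x)
  if (ncol(m) < 2L) abort("Z-scoring needs at least 2 samples.")
  mu <- rowMeans(m)
  sd0 <- sqrt(rowMeans((m - mu)^2))
  drop <- sd0 == 0
  excluded <- rownames(m)[drop]
  if (any(drop)) {
    warn(sprintf("Dropping %d zero-variance gene(s): %s%s.",
                 sum(drop), paste(utils::head(excluded, 3), collapse = ", "),
                 if (sum(drop) > 3) ", ..." else ""))
    m <- m[!drop, , drop = FALSE]
    mu <- mu[!drop]
    sd0 <- sd0[!drop]
  }
  z <- (m - mu) / sd0
  out <- dplyr::bind_cols(tibble(gene_id = rownames(m)), as_tibble(z))
  out <- expression_tibble(out, normalization = "zscored")
  attr(out, "excluded_genes") <- excluded
  out
}

#' Enumerate canonical unordered gene pairs
#'
#' All G(G-1)/2 unordered pairs of the given ids, each stored once as
#' `(pair_a, pair_b)` with `pair_a < pair_b` lexicographically (C collation).
#'
#' @param gene_ids Character vector of unique gene ids.
#' @return A tibble with columns `pair_a`, `pair_b`.
#' @export
enumerate_pairs <- function(gene_ids) {
  if (anyDuplicated(gene_ids)) abort("Duplicate gene ids.")
  ids <- sort(gene_ids, method = "radix")
  G <- length(ids)
  if (G < 2L) return(tibble(pair_a = character(), pair_b = character()))
  # row-major over the sorted ids: i < j
  i <- rep.int(seq_len(G - 1L), (G - 1L):1L)
  j <- sequence((G - 1L):1L) + i
  tibble(pair_a = ids[i], pair_b = ids[j])
}

#' Number of unordered pairs
#'
#' @param gene_ids Character vector of unique gene ids (or a single count).
#' @return G(G-1)/2 as a double.
#' @export
n_pairs <- function(gene_ids) {
  if (anyDuplicated(gene_ids)) abort("Duplicate gene ids.")
  G <- if (is.numeric(gene_ids) && length(gene_ids) == 1L) gene_ids
       else length(gene_ids)
  G * (G - 1) / 2
}

#' Joint-moment grid specification
#'
#' The feature grid is all exponent pairs (n, m) with 1 <= n, m <= `max_order`
#' in row-major order, giving `max_order^2` moments; the default 7 yields the
#' 49-moment representation. Moment (1,1) of z-scored genes is the Pearson
#' correlation.
#'
#' @param max_order Largest exponent on either gene.
#' @return A tibble with columns `n`, `m`, `name` (e.g. `"m_2_3"`).
#' @export
moment_spec <- function(max_order = 7L) {
  check_positive_scalar(max_order, "max_order")
  grid <- expand.grid(m = seq_len(max_order), n = seq_len(max_order))
  tibble(n = grid$n, m = grid$m, name = sprintf("m_%d_%d", grid$n, grid$m))
}

#' Compute joint-moment features for gene pairs
#'
#' For a pair (a, b) with z-scored rows x (the lexicographically smaller gene)
#' and y over S samples, moment (n, m) is `mean(x^n * y^m)`. The default
#' 7 x 7 grid yields 49 features per pair. Pairs are processed in chunks to
#' bound memory; results are identical for any chunk size.
#'
#' @param z A z-scored expression table.
#' @param pairs Tibble with columns `pair_a`, `pair_b` (canonical order);
#'   defaults to all pairs of the genes in `z`.
#' @param spec A [moment_spec()].
#' @param chunk_size Number of pairs per processing chunk.
#' @return A pair-feature tibble: `pair_a`, `pair_b`, then one column per
#'   moment (`m_1_1` ... in row-major grid order).
#' @export
compute_moments <- function(z, pairs = NULL, spec = moment_spec(),
                            chunk_size = 5000L) {
  if (expr_normalization(z) != "zscored") {
    abort("`z` must be z-scored (see zscore_genes()).")
  }
  m <- expr_values(z)
  if (is.null(pairs)) pairs <- enumerate_pairs(rownames(m))
  pairs <- canonicalize_pairs(as_tibble(pairs))
  missing <- setdiff(unique(c(pairs$pair_a, pairs$pair_b)), rownames(m))
  if (length(missing) > 0) {
    abort(sprintf("Pair member(s) absent from the matrix: %s%s.",
                  paste(utils::head(missing, 3), collapse = ", "),
                  if (length(missing) > 3) ", ..." else ""))
  }
  P <- nrow(pairs)
  max_order <- max(spec$n, spec$m)
  feat <- matrix(NA_real_, nrow = P, ncol = nrow(spec),
                 dimnames = list(NULL, spec$name))
  starts <- seq(1L, P, by = chunk_size)
  for (s in starts) {
    rows <- s:min(s + chunk_size - 1L, P)
    xa <- m[pairs$pair_a[rows], , drop = FALSE]
    xb <- m[pairs$pair_b[rows], , drop = FALSE]
    # incremental powers: pow_a[[n]] = xa^n
    pow_a <- vector("list", max_order)
    pow_b <- vector("list", max_order)
    pow_a[[1]] <- xa
    pow_b[[1]] <- xb
    for (k in seq(2, length.out = max_order - 1L)) {
      pow_a[[k]] <- pow_a[[k - 1L]] * xa
      pow_b[[k]] <- pow_b[[k - 1L]] * xb
    }
    for (f in seq_len(nrow(spec))) {
      feat[rows, f] <- rowMeans(pow_a[[spec$n[f]]] * pow_b[[spec$m[f]]])
    }
  }
  dplyr::bind_cols(pairs[, c("pair_a", "pair_b")], as_tibble(feat))
}

# put pair columns in canonical orientation (pair_a < pair_b, C collation)
canonicalize_pairs <- function(pairs) {
  swap <- cmp_gt(pairs$pair_a, pairs$pair_b)
  if (any(swap)) {
    tmp <- pairs$pair_a[swap]
    pairs$pair_a[swap] <- pairs$pair_b[swap]
    pairs$pair_b[swap] <- tmp
  }
  pairs
}

# locale-independent string comparison (C collation, matches sort(method="radix"))
cmp_gt <- function(a, b) {
  lev <- sort(unique(c(a, b)), method = "radix")
  match(a, lev) > match(b, lev)
}

moment_columns <- function(table) {
  grep("^m_\\d+_\\d+$", names(table), value = TRUE)
}

reduced_columns <- function(table) {
  grep("^pc_\\d+$", names(table), value = TRUE)
}

#' Standardize moment columns across pairs
#'
#' Centers and scales every moment column to mean 0, SD 1 (population
#' convention) across pairs. Zero-variance columns are set to 0 with a
#' warning. The centering/scaling vectors are attached as attributes
#' `moment_means` and `moment_sds`.
#'
#' @param table A pair-feature tibble from [compute_moments()].
#' @return The table with standardized moment columns.
#' @export
standardize_moments <- function(table) {
  cols <- moment_columns(table)
  if (nrow(table) < 2L) abort("Standardization needs at least 2 pairs.")
  m <- as.matrix(table[cols])
  mu <- colMeans(m)
  sd0 <- sqrt(colMeans(sweep(m, 2, mu)^2))
  flat <- sd0 == 0
  if (any(flat)) {
    warn(sprintf("%d constant moment column(s) set to 0: %s.",
                 sum(flat), paste(cols[flat], collapse = ", ")))
    sd0[flat] <- 1
  }
  std <- sweep(sweep(m, 2, mu), 2, sd0, "/")
  std[, flat] <- 0
  out <- table
  out[cols] <- as_tibble(std)
  attr(out, "moment_means") <- stats::setNames(mu, cols)
  attr(out, "moment_sds") <- stats::setNames(ifelse(flat, 0, sd0), cols)
  out
}

#' Fit a PCA reduction of the moment features
#'
#' Standardizes the moment columns (population convention) and extracts the
#' leading principal components of their covariance. The model stores the
#' standardization vectors so that [transform_pca()] can be applied to any
#' pair table with the same moment grid.
#'
#' @param table A pair-feature tibble (raw moments).
#' @param n_components Number of components to retain (default 36).
#' @return An object of class `moment_pca`: feature means/sds, orthonormal
#'   loadings (moments x components), explained variance per component.
#' @export
fit_pca <- function(table, n_components = 36L) {
  cols <- moment_columns(table)
  if (n_components > length(cols)) {
    abort(sprintf("n_components = %d exceeds the %d moment columns.",
                  n_components, length(cols)))
  }
  std <- standardize_moments(table)
  pc <- stats::prcomp(as.matrix(std[cols]), center = FALSE, scale. = FALSE)
  structure(list(
    feature_means = attr(std, "moment_means"),
    feature_sds = attr(std, "moment_sds"),
    loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
    explained_variance = pc$sdev[seq_len(n_components)]^2,
    total_variance = sum(pc$sdev^2),
    n_components = as.integer(n_components)
  ), class = "moment_pca")
}

#' @export
print.moment_pca <- function(x, ...) {
  cat(sprintf("# PCA of %d moment features -> %d components (%.1f%% variance)\n",
              nrow(x$loadings), x$n_components,
              100 * sum(x$explained_variance) / x$total_variance))
  invisible(x)
}

#' Project pair features onto fitted principal components
#'
#' Applies the model's standardization (zero-variance features map to 0) and
#' the orthonormal loadings, appending columns `pc_1` ... `pc_k`.
#'
#' @param model A `moment_pca` from [fit_pca()].
#' @param table A pair-feature tibble with the same moment columns.
#' @return The table with reduced-feature columns appended.
#' @export
transform_pca <- function(model, table) {
  cols <- names(model$feature_means)
  if (!all(cols %in% names(table))) {
    abort("Moment columns of the table do not match the PCA model.")
  }
  m <- as.matrix(table[cols])
  sds <- ifelse(model$feature_sds == 0, 1, model$feature_sds)
  std <- sweep(sweep(m, 2, model$feature_means), 2, sds, "/")
  std[, model$feature_sds == 0] <- 0
  red <- std %*% model$loadings
  colnames(red) <- sprintf("pc_%d", seq_len(ncol(red)))
  dplyr::bind_cols(table, as_tibble(red))
}
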