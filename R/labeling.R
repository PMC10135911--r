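#' Load a gold-standard edge list
#'
#' Reads a two-column delimited file of directed regulatory edges
#' (regulator, target), optionally passing gene ids through an alias map.
#' Duplicate rows are removed; self-edges are dropped with a warning (or
#' rejected).
#'
#' @param path Two-column TSV (regulator, target), header optional per
#'   `col_names`.
#' @param id_map Optional alias-to-canonical tibble (see [read_gene_id_map()]).
#' @param on_self_edge `"warn"` (drop with a warning) or `"error"`.
#' @param col_names Passed to the reader; default assumes a header row.
#' @return A tibble of directed edges `regulator`, `target`.
#' @export
load_gold_edges <- function(path, id_map = NULL,
                            on_self_edge = c("warn", "error"),
                            col_names = TRUE) {
  on_self_edge <- match.arg(on_self_edge)
  x <- readr::read_tsv(path, col_names = col_names, col_types = "cc",
                       progress = FALSE)
  if (ncol(x) != 2L) abort("Expected exactly two columns (regulator, target).")
  names(x) <- c("regulator", "target")
  bad <- which(is.na(x$regulator) | is.na(x$target) |
                 x$regulator == "" | x$target == "")
  if (length(bad) > 0) {
    abort(sprintf("Malformed edge at line %d of %s.",
                  bad[1] + as.integer(isTRUE(col_names)), path))
  }
  if (!is.null(id_map)) {
    to_canonical <- function(v) {
      i <- match(v, id_map$alias)
      ifelse(is.na(i), v, id_map$canonical[i])
    }
    x$regulator <- to_canonical(x$regulator)
    x$target <- to_canonical(x$target)
  }
  self <- x$regulator == x$target
  if (any(self)) {
    if (on_self_edge == "error") {
      abort(sprintf("%d self-edge(s), e.g. %s.", sum(self),
                    x$regulator[which(self)[1]]))
    }
    warn(sprintf("Dropping %d self-edge(s).", sum(self)))
    x <- x[!self, , drop = FALSE]
  }
  n_dup <- sum(duplicated(x))
  if (n_dup > 0) {
    inform(sprintf("Removed %d duplicate edge(s).", n_dup))
    x <- dplyr::distinct(x)
  }
  x
}

# undirected view of a directed edge list, in canonical pair orientation
gold_pairs <- function(gold) {
  dplyr::distinct(canonicalize_pairs(
    tibble(pair_a = gold$regulator, pair_b = gold$target)))
}

#' Positive training pairs from a gold standard
#'
#' The network is built undirected: an unordered pair is positive when any
#' directed gold edge connects its two genes. Gold edges whose genes are not
#' in the feature table (e.g. not in the expression matrix) are skipped and
#' counted in the `n_skipped` attribute.
#'
#' @param table A pair-feature tibble.
#' @param gold A directed edge tibble (`regulator`, `target`).
#' @return The positive subset of `table`'s pairs (columns `pair_a`,
#'   `pair_b`), with attribute `n_skipped`.
#' @export
build_positive_set <- function(table, gold) {
  gp <- gold_pairs(gold)
  keys <- paste(table$pair_a, table$pair_b, sep = "\r")
  gkeys <- paste(gp$pair_a, gp$pair_b, sep = "\r")
  hit <- gkeys %in% keys
  if (!any(hit)) abort("No gold pair is present in the feature table.")
  out <- table[keys %in% gkeys, c("pair_a", "pair_b")]
  attr(out, "n_skipped") <- sum(!hit)
  out
}

#' Select low-correlation negative pairs
#'
#' Ranks candidate pairs by the absolute (1,1) joint moment — the Pearson
#' correlation of the z-scored genes — in ascending order and takes the `k`
#' least-correlated pairs as the unrelated (negative) class. Ties are broken
#' by canonical pair id so the selection is deterministic. Gold pairs are
#' excluded from the candidates by default.
#'
#' @param table A pair-feature tibble with raw moment `m_1_1`.
#' @param gold Directed gold edges, used for exclusion (may be `NULL` when
#'   `exclude_gold = FALSE`).
#' @param k Number of negatives (the usual full-scale choice is 10,000).
#' @param exclude_gold Drop gold pairs from the candidate set first.
#' @return The selected subset (columns `pair_a`, `pair_b`) with the ranking
#'   moment in column `abs_m11`.
#' @export
select_negatives <- function(table, gold = NULL, k = 10000L,
                             exclude_gold = TRUE) {
  if (!"m_1_1" %in% names(table)) abort("`table` lacks the raw m_1_1 moment.")
  cand <- table[, c("pair_a", "pair_b", "m_1_1")]
  if (exclude_gold) {
    if (is.null(gold)) abort("`gold` is required when exclude_gold = TRUE.")
    gp <- gold_pairs(gold)
    keys <- paste(cand$pair_a, cand$pair_b, sep = "\r")
    cand <- cand[!keys %in% paste(gp$pair_a, gp$pair_b, sep = "\r"), ]
  }
  if (k > nrow(cand)) {
    abort(sprintf("k = %d exceeds the %d eligible candidate pairs.",
                  k, nrow(cand)))
  }
  ord <- order(abs(cand$m_1_1),
               match(cand$pair_a, sort(unique(cand$pair_a), method = "radix")),
               match(cand$pair_b, sort(unique(cand$pair_b), method = "radix")))
  out <- cand[ord[seq_len(k)], ]
  names(out)[3] <- "abs_m11"
  out$abs_m11 <- abs(out$abs_m11)
  out
}

#' Histogram of absolute pair correlations
#'
#' Bins `|m_1_1|` over all pairs in the table; counts sum to the pair count.
#'
#' @param table A pair-feature tibble with `m_1_1`.
#' @param n_bins Number of equal-width bins over the observed range.
#' @return A tibble with `bin_lo`, `bin_hi`, `count`, of class
#'   `correlation_histogram`.
#' @export
correlation_histogram <- function(table, n_bins = 50L) {
  v <- abs(table$m_1_1)
  rng <- range(v)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- graphics::hist(v, breaks = edges, plot = FALSE, include.lowest = TRUE)
  structure(tibble(bin_lo = utils::head(edges, -1),
                   bin_hi = edges[-1],
                   count = h$counts),
            class = c("correlation_histogram", class(tibble())))
}

#' Correlation-density overlap between linked and unlinked pairs
#'
#' Kernel density estimates of the (1,1) moment for the positive pairs and for
#' all remaining pairs, evaluated on a common grid, plus their overlap
#' coefficient (the integral of the pointwise minimum, in [0, 1]). A high
#' overlap means correlation alone cannot separate the classes — the case that
#' motivates higher joint moments.
#'
#' @param table A pair-feature tibble with `m_1_1`.
#' @param positives Pair subset (columns `pair_a`, `pair_b`).
#' @param n_grid Grid size for the density evaluation.
#' @return A list of class `density_overlap`: `grid`, `density_positive`,
#'   `density_rest`, `overlap`.
#' @export
density_overlap <- function(table, positives, n_grid = 512L) {
  if (nrow(positives) == 0) abort("`positives` is empty.")
  keys <- paste(table$pair_a, table$pair_b, sep = "\r")
  pos <- keys %in% paste(positives$pair_a, positives$pair_b, sep = "\r")
  v_pos <- table$m_1_1[pos]
  v_rest <- table$m_1_1[!pos]
  if (length(v_rest) == 0) abort("No non-positive pairs left.")
  lo <- min(v_pos, v_rest)
  hi <- max(v_pos, v_rest)
  pad <- 0.1 * (hi - lo + 1e-12)
  grid <- seq(lo - pad, hi + pad, length.out = n_grid)
  d_pos <- stats::density(v_pos, from = grid[1], to = grid[n_grid], n = n_grid)$y
  d_rest <- stats::density(v_rest, from = grid[1], to = grid[n_grid], n = n_grid)$y
  dx <- grid[2] - grid[1]
  # renormalize on the grid so the overlap coefficient is scale-clean
  d_pos <- d_pos / (sum(d_pos) * dx)
  d_rest <- d_rest / (sum(d_rest) * dx)
  overlap <- min(1, sum(pmin(d_pos, d_rest)) * dx)
  structure(list(grid = grid, density_positive = d_pos,
                 density_rest = d_rest, overlap = overlap),
            class = "density_overlap")
}

#' @export
print.density_overlap <- function(x, ...) {
  cat(sprintf("# Correlation-density overlap: %.3f\n", x$overlap))
  invisible(x)
}

#' Assemble the balanced labeled training set
#'
#' Draws `n_pos` positive and `n_neg` negative pairs (uniformly without
#' replacement under `seed` when the supply exceeds demand), attaches the
#' reduced features when present (columns `pc_*`, otherwise the raw moments),
#' and labels positives 1, negatives 0. Defaults give the 20,000 x 36 design
#' used at full scale. Positives and negatives must be disjoint.
#'
#' @param positives,negatives Pair subsets (columns `pair_a`, `pair_b`).
#' @param table Pair-feature tibble carrying the feature columns.
#' @param n_pos,n_neg Rows drawn per class.
#' @param seed Sampling seed.
#' @return A tibble `pair_a`, `pair_b`, `label` (0/1 integer), `provenance`,
#'   then feature columns.
#' @export
assemble_training_set <- function(positives, negatives, table,
                                  n_pos = 10000L, n_neg = 10000L, seed = 1L) {
  key <- function(d) paste(d$pair_a, d$pair_b, sep = "\r")
  if (length(intersect(key(positives), key(negatives))) > 0) {
    abort("Positive and negative pair sets overlap.")
  }
  if (nrow(positives) < n_pos) {
    abort(sprintf("Need %d positives, only %d available.", n_pos, nrow(positives)))
  }
  if (nrow(negatives) < n_neg) {
    abort(sprintf("Need %d negatives, only %d available.", n_neg, nrow(negatives)))
  }
  feat_cols <- reduced_columns(table)
  if (length(feat_cols) == 0) feat_cols <- moment_columns(table)
  if (length(feat_cols) == 0) abort("`table` carries no feature columns.")
  draw <- function(d, n) d[sort(sample.int(nrow(d), n)), c("pair_a", "pair_b")]
  sets <- with_seed(seed, list(pos = draw(positives, n_pos),
                               neg = draw(negatives, n_neg)))
  sets$pos$label <- 1L
  sets$pos$provenance <- "gold"
  sets$neg$label <- 0L
  sets$neg$provenance <- "low-correlation"
  out <- dplyr::bind_rows(sets$pos, sets$neg)
  out <- dplyr::left_join(out, table[, c("pair_a", "pair_b", feat_cols)],
                          by = c("pair_a", "pair_b"))
  if (anyNA(out[feat_cols])) abort("Some sampled pairs lack features.")
  as_tibble(out)
}
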