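#' Compare two predicted regulons against the gold standard
#'
#' For one transcription factor, partitions the union of two predicted edge
#' sets (e.g. one inferred from RNA-seq, one from microarray) into four
#' disjoint categories: predictions shared by both and validated by the gold
#' standard, shared but unvalidated (new potential targets), and the edges
#' unique to either set.
#'
#' @param pred_a,pred_b Edge tibbles (`regulator`, `target`).
#' @param gold Gold-standard edge tibble (`regulator`, `target`).
#' @param tf Transcription-factor gene id; edges are restricted to this
#'   regulator.
#' @return A tibble of class `network_comparison` with columns `regulator`,
#'   `target`, `category` in {shared_validated, shared_unvalidated, unique_a,
#'   unique_b}.
#' @export
compare_networks <- function(pred_a, pred_b, gold, tf) {
  pick <- function(d) unique(d$target[d$regulator == tf])
  a <- pick(pred_a)
  b <- pick(pred_b)
  g <- pick(gold)
  shared <- intersect(a, b)
  cats <- dplyr::bind_rows(
    tibble(target = intersect(shared, g), category = "shared_validated"),
    tibble(target = setdiff(shared, g), category = "shared_unvalidated"),
    tibble(target = setdiff(a, b), category = "unique_a"),
    tibble(target = setdiff(b, a), category = "unique_b")
  )
  out <- tibble(regulator = rep(tf, nrow(cats)), target = cats$target,
                category = cats$category)
  structure(out, class = c("network_comparison", class(tibble())))
}

#' Export a network comparison for graph viewers
#'
#' SIF lines are `regulator <category> target` (loadable by Cytoscape); TSV
#' carries a header and a category column.
#'
#' @param comparison A `network_comparison` tibble.
#' @param path Output path.
#' @param format `"sif"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(comparison, path, format = c("sif", "tsv")) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- sprintf("%s\t%s\t%s", comparison$regulator,
                     comparison$category, comparison$target)
    writeLines(lines, path)
  } else {
    readr::write_tsv(as_tibble(comparison), path, progress = FALSE)
  }
  invisible(path)
}

#' Read back an exported network comparison
#'
#' @param path File written by [export_network()].
#' @param format `"sif"` or `"tsv"`.
#' @return A `network_comparison` tibble.
#' @export
read_network <- function(path, format = c("sif", "tsv")) {
  format <- match.arg(format)
  if (format == "sif") {
    x <- readr::read_tsv(path, col_names = c("regulator", "category", "target"),
                         col_types = "ccc", progress = FALSE)
    x <- x[, c("regulator", "target", "category")]
  } else {
    x <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  }
  structure(as_tibble(x), class = c("network_comparison", class(tibble())))
}
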