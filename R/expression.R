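#' Expression tables
#'
#' An expression table is a tibble whose first column, `gene_id`, holds unique
#' gene identifiers and whose remaining columns are numeric sample values, one
#' column per sample. A `normalization` attribute tags the scale of the
#' values: `"raw_counts"`, `"tpm"`, `"fpkm"`, `"microarray"` or `"zscored"`.
#'
#' @param x A data frame with a `gene_id` column followed by numeric sample
#'   columns.
#' @param normalization Scale tag for the values.
#' @return A tibble of class `expr_tbl` with the `normalization` attribute set.
#' @export
expression_tibble <- function(x,
                              normalization = c("raw_counts", "tpm", "fpkm",
                                                "microarray", "zscored")) {
  normalization <- match.arg(normalization)
  x <- as_tibble(x)
  class(x) <- setdiff(class(x), "expr_tbl")
  if (!"gene_id" %in% names(x) || names(x)[1] != "gene_id") {
    abort("The first column of an expression table must be `gene_id`.")
  }
  if (ncol(x) < 2L) abort("An expression table needs at least one sample column.")
  dup <- x$gene_id[duplicated(x$gene_id)]
  if (length(dup) > 0) {
    abort(sprintf("Duplicate gene id(s): %s.", paste(unique(dup), collapse = ", ")))
  }
  sample_ids <- names(x)[-1]
  if (anyDuplicated(sample_ids)) abort("Duplicate sample ids in header.")
  numeric_ok <- vapply(x[-1], is.numeric, logical(1))
  if (!all(numeric_ok)) {
    abort(sprintf("Non-numeric sample column(s): %s.",
                  paste(sample_ids[!numeric_ok], collapse = ", ")))
  }
  vals <- as.matrix(x[-1])
  if (normalization == "raw_counts" && any(vals < 0, na.rm = TRUE)) {
    abort("Raw counts must be non-negative.")
  }
  structure(x, normalization = normalization,
            class = c("expr_tbl", class(x)))
}

#' @export
print.expr_tbl <- function(x, ...) {
  cat(sprintf("# Expression table: %d genes x %d samples [%s]\n",
              nrow(x), ncol(x) - 1L, expr_normalization(x)))
  NextMethod()
}

#' Normalization tag of an expression table
#' @param x An expression table.
#' @return The normalization tag as a string.
#' @export
expr_normalization <- function(x) attr(x, "normalization") %||% "raw_counts"

# numeric matrix view, genes in rows (rownames = gene ids)
expr_values <- function(x) {
  m <- as.matrix(x[-1])
  rownames(m) <- x$gene_id
  m
}

#' Read an expression matrix from delimited text
#'
#' Expects a header row of sample ids and a first column of gene ids
#' (GEO-style matrix export). Tab-separated by default.
#'
#' @param path File path.
#' @param delim Field delimiter, `"\t"` or `","`.
#' @param normalization Scale tag to attach (the file does not carry one).
#' @return An expression table (see [expression_tibble()]).
#' @export
read_expression_matrix <- function(path, delim = "\t",
                                   normalization = "raw_counts") {
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(raw) < 2L) abort("Expected a gene-id column plus sample columns.")
  names(raw)[1] <- "gene_id"
  for (j in seq(2L, ncol(raw))) {
    parsed <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(parsed) & !is.na(raw[[j]]))
    if (length(bad) > 0) {
      abort(sprintf("Non-numeric value %s at row %d, column %s.",
                    dQuote(raw[[j]][bad[1]]), bad[1], names(raw)[j]))
    }
    raw[[j]] <- parsed
  }
  expression_tibble(raw, normalization = normalization)
}

#' Write an expression table to delimited text
#'
#' @param x An expression table.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, delim = "\t") {
  readr::write_delim(as_tibble(x), path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Read a two-column gene-length table
#'
#' @param path Path to a TSV with columns `gene_id` and `length_bp`.
#' @return A tibble with columns `gene_id`, `length_bp`.
#' @export
read_gene_lengths <- function(path) {
  x <- readr::read_tsv(path, col_types = "ci", progress = FALSE)
  names(x) <- c("gene_id", "length_bp")
  if (any(x$length_bp <= 0)) abort("Gene lengths must be positive.")
  if (anyDuplicated(x$gene_id)) abort("Duplicate gene id in length table.")
  x
}

#' Read a two-column alias-to-canonical gene-id map
#'
#' @param path Path to a TSV with columns `alias` and `canonical`.
#' @return A tibble with columns `alias`, `canonical`.
#' @export
read_gene_id_map <- function(path) {
  x <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  names(x) <- c("alias", "canonical")
  if (anyDuplicated(x$alias)) abort("An alias maps to more than one canonical id.")
  x
}

#' Standardize gene identifiers via a mapping table
#'
#' Renames every gene whose id appears in the alias column of `id_map` to its
#' canonical (ordered-locus-style) name, so that expression rows and
#' gold-standard edges share one naming scheme.
#'
#' @param x An expression table.
#' @param id_map Tibble with columns `alias`, `canonical` (each alias maps to
#'   exactly one canonical id).
#' @param on_missing What to do with genes absent from the map: keep their
#'   current id, drop the row, or fail.
#' @return An expression table with canonical gene ids.
#' @export
apply_gene_id_map <- function(x, id_map, on_missing = c("keep", "drop", "fail")) {
  on_missing <- match.arg(on_missing)
  if (anyDuplicated(id_map$alias)) {
    abort("`id_map` is not a function: an alias maps to two canonical ids.")
  }
  idx <- match(x$gene_id, id_map$alias)
  missing <- is.na(idx)
  if (on_missing == "fail" && any(missing)) {
    abort(sprintf("%d gene id(s) not in the map, e.g. %s.",
                  sum(missing), x$gene_id[which(missing)[1]]))
  }
  new_id <- ifelse(missing, x$gene_id, id_map$canonical[idx])
  if (on_missing == "drop") {
    x <- x[!missing, , drop = FALSE]
    new_id <- new_id[!missing]
  }
  dup <- new_id[duplicated(new_id)]
  if (length(dup) > 0) {
    abort(sprintf("Gene-id map collision: canonical id(s) %s would appear twice.",
                  paste(unique(dup), collapse = ", ")))
  }
  x$gene_id <- new_id
  expression_tibble(x, normalization = expr_normalization(x))
}

check_lengths_cover <- function(x, lengths) {
  miss <- setdiff(x$gene_id, lengths$gene_id)
  if (length(miss) > 0) {
    abort(sprintf("No length for gene(s): %s%s.",
                  paste(utils::head(miss, 3), collapse = ", "),
                  if (length(miss) > 3) ", ..." else ""))
  }
  lengths$length_bp[match(x$gene_id, lengths$gene_id)]
}

#' TPM normalization from a raw-count matrix
#'
#' Per sample, each gene's count is first converted to a length rate
#' `count / (length_bp / 1000)` (reads per kilobase); rates are then scaled to
#' sum to one million, so every sample column of the result sums to 1e6.
#' The effective length is the annotated gene length.
#'
#' @param counts An expression table tagged `raw_counts`.
#' @param lengths Gene-length tibble covering every gene in `counts`.
#' @param zero_sample Handling of an all-zero sample column: `"error"`
#'   (default) or `"zero"` to emit an all-zero column.
#' @return An expression table tagged `tpm`.
#' @export
tpm_normalize <- function(counts, lengths, zero_sample = c("error", "zero")) {
  zero_sample <- match.arg(zero_sample)
  if (expr_normalization(counts) != "raw_counts") {
    abort("`counts` must be tagged raw_counts.")
  }
  len <- check_lengths_cover(counts, lengths)
  m <- expr_values(counts)
  rate <- m / (len / 1000)
  tot <- colSums(rate)
  if (any(tot == 0)) {
    if (zero_sample == "error") {
      abort(sprintf("All-zero sample column(s): %s.",
                    paste(colnames(m)[tot == 0], collapse = ", ")))
    }
    tot[tot == 0] <- 1  # keeps the column all zero, NaN-free
  }
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  out <- counts
  out[-1] <- as_tibble(tpm)
  expression_tibble(out, normalization = "tpm")
}

#' FPKM normalization from a raw-count matrix
#'
#' Per sample with total count `T`, `fpkm = count * 1e9 / (length_bp * T)`.
#' The per-million-fragments denominator is the column sum of the count
#' matrix, the only depth measure available once quantification is done.
#'
#' @inheritParams tpm_normalize
#' @return An expression table tagged `fpkm`.
#' @export
fpkm_normalize <- function(counts, lengths) {
  if (expr_normalization(counts) != "raw_counts") {
    abort("`counts` must be tagged raw_counts.")
  }
  len <- check_lengths_cover(counts, lengths)
  m <- expr_values(counts)
  tot <- colSums(m)
  if (any(tot == 0)) {
    abort(sprintf("All-zero sample column(s): %s.",
                  paste(colnames(m)[tot == 0], collapse = ", ")))
  }
  fpkm <- sweep(m / len, 2, tot, "/") * 1e9
  out <- counts
  out[-1] <- as_tibble(fpkm)
  expression_tibble(out, normalization = "fpkm")
}
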