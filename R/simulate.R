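#' Configuration for the synthetic regulatory-network simulator
#'
#' Bundles the parameters of the ground-truth network and of the expression
#' model that generates data over it. The simulator exists so that every stage
#' of the pipeline — normalization, moment features, labeling, classification,
#' evaluation — can be exercised end to end on data with a known answer.
#'
#' @param n_genes Total number of genes.
#' @param n_tfs Number of regulator (TF) genes; the first `n_tfs` gene ids.
#' @param targets_per_tf Number of distinct targets drawn per TF, without
#'   replacement from the non-TF genes.
#' @param n_samples Number of samples (conditions).
#' @param link_mix Named proportions over the link types `linear`,
#'   `quadratic`, `saturating`, `repressive`; must sum to 1. Quadratic links
#'   are the motivating case: they carry almost no linear correlation yet are
#'   visible in higher joint moments.
#' @param noise_sd Standard deviation of the additive Gaussian noise on each
#'   regulated gene, on the latent (log) scale.
#' @param seed Integer seed; the simulator is bit-reproducible given the
#'   configuration.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 300, n_tfs = 20, targets_per_tf = 10,
                              n_samples = 300,
                              link_mix = c(linear = 0.25, quadratic = 0.25,
                                           saturating = 0.25, repressive = 0.25),
                              noise_sd = 0.3, seed = 1L) {
  for (nm in c("n_genes", "n_tfs", "targets_per_tf", "n_samples", "noise_sd")) {
    check_positive_scalar(get(nm), nm)
  }
  required <- c("linear", "quadratic", "saturating", "repressive")
  if (!setequal(names(link_mix), required)) {
    abort("`link_mix` must name exactly: linear, quadratic, saturating, repressive.")
  }
  link_mix <- link_mix[required]
  if (abs(sum(link_mix) - 1) > 1e-8 || any(link_mix < 0)) {
    abort("`link_mix` proportions must be non-negative and sum to 1.")
  }
  if (n_tfs >= n_genes) abort("`n_tfs` must be smaller than `n_genes`.")
  if (targets_per_tf > n_genes - n_tfs) {
    abort(sprintf("targets_per_tf = %d exceeds the %d non-TF genes available.",
                  targets_per_tf, n_genes - n_tfs))
  }
  structure(list(n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
                 targets_per_tf = as.integer(targets_per_tf),
                 n_samples = as.integer(n_samples), link_mix = link_mix,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_config")
}

sim_gene_ids <- function(config) {
  sprintf("G%04d", seq_len(config$n_genes))
}

#' Simulate a ground-truth regulatory network
#'
#' Each of the first `n_tfs` genes regulates `targets_per_tf` distinct targets
#' drawn without replacement from the non-TF genes. Different TFs may share a
#' target. Deterministic under `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A tibble of directed edges with columns `regulator`, `target`, plus
#'   a `link` column naming the response type assigned to each edge, and a
#'   `source_tag` attribute `"synthetic"`.
#' @export
simulate_network <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ids <- sim_gene_ids(config)
  tfs <- ids[seq_len(config$n_tfs)]
  pool <- ids[-seq_len(config$n_tfs)]
  link_types <- names(config$link_mix)
  edges <- with_seed(config$seed, {
    purrr::map_dfr(tfs, function(tf) {
      tibble(regulator = tf,
             target = sample(pool, config$targets_per_tf, replace = FALSE))
    }) |>
      dplyr::mutate(link = sample(link_types, dplyr::n(), replace = TRUE,
                                  prob = config$link_mix))
  })
  structure(edges, source_tag = "synthetic")
}

# per-edge response on the latent standard-normal scale
link_response <- function(link, z) {
  switch(link,
         linear     = z,
         quadratic  = z^2 - 1,
         saturating = tanh(2 * z),
         repressive = -z,
         abort(sprintf("Unknown link type %s.", link)))
}

#' Simulate an expression matrix over a ground-truth network
#'
#' Each regulator gets an independent standard-normal latent value per sample.
#' Each regulated gene is the sum, over its incoming edges, of a link response
#' applied to the regulator's latent value — linear `z`, quadratic `z^2 - 1`,
#' saturating `tanh(2z)`, repressive `-z` — plus one Gaussian noise term with
#' standard deviation `noise_sd`. Unregulated genes are independent standard
#' normals. All latent values are exponentiated onto a positive,
#' intensity-like scale and the result is tagged `microarray`.
#'
#' @param gold Edge tibble from [simulate_network()] (columns `regulator`,
#'   `target`, `link`).
#' @param config The same [simulation_config()].
#' @return An expression table, genes x samples, tagged `microarray`.
#' @export
simulate_expression <- function(gold, config) {
  stopifnot(inherits(config, "sim_config"))
  ids <- sim_gene_ids(config)
  if (!all(c(gold$regulator, gold$target) %in% ids)) {
    abort("Gold-standard genes are not a subset of the simulated gene set.")
  }
  G <- config$n_genes
  S <- config$n_samples
  vals <- with_seed(config$seed + 1L, {
    m <- matrix(stats::rnorm(G * S), nrow = G, dimnames = list(ids, NULL))
    targets <- unique(gold$target)
    # regulated rows: overwrite the independent draw with the link responses
    for (tg in targets) {
      inc <- gold[gold$target == tg, , drop = FALSE]
      resp <- rep(0, S)
      for (k in seq_len(nrow(inc))) {
        resp <- resp + link_response(inc$link[k], m[inc$regulator[k], ])
      }
      m[tg, ] <- resp + stats::rnorm(S, sd = config$noise_sd)
    }
    m
  })
  out <- tibble(gene_id = ids)
  mat <- exp(vals)
  colnames(mat) <- sprintf("S%04d", seq_len(S))
  out <- dplyr::bind_cols(out, as_tibble(mat))
  expression_tibble(out, normalization = "microarray")
}

#' Write a gold-standard edge list as two-column TSV
#'
#' @param gold Edge tibble with columns `regulator`, `target`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gold_edges <- function(gold, path) {
  readr::write_tsv(dplyr::select(as_tibble(gold), "regulator", "target"), path,
                   progress = FALSE)
  invisible(path)
}
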