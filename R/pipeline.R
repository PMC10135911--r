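#' Default hyperparameter grids
#'
#' Small lattices spanning the scale of PCA-reduced standardized moment
#' features (total variance about the number of moments, so inter-point
#' distances are of order 10). Table-style published defaults for yeast data
#' (e.g. REWKLR lambda 2.4 / sigma 0.2 for TPM) are accepted anywhere a
#' single parameter is taken; the grids here bracket the desk-scale synthetic
#' regime.
#'
#' @name default_grids
#' @return A tibble grid.
#' @export
default_rewklr_grid <- function() {
  tidyr::expand_grid(lambda = c(0.01, 0.1, 1), sigma = c(2, 5, 10))
}

#' @rdname default_grids
#' @export
default_svm_grid <- function() {
  tidyr::expand_grid(cost = c(1, 10), gamma = c(0.005, 0.02, 0.1))
}

#' @rdname default_grids
#' @export
default_ocsvm_grid <- function() {
  tidyr::expand_grid(nu = c(0.03, 0.1), gamma = c(0.005, 0.02, 0.1))
}

#' Pipeline run configuration
#'
#' Collects every input path, stage parameter and seed of an end-to-end run.
#' Either `sim` (a [simulation_config()], data are generated) or
#' `matrix_path` + `gold_path` (data are read from disk) must be given.
#'
#' @param out_dir Run directory; created if missing.
#' @param sim Optional [simulation_config()] to generate matrix + gold.
#' @param matrix_path,lengths_path,gold_path,id_map_path Input files
#'   (expression matrix, gene lengths, gold edges, alias map).
#' @param matrix_normalization Tag of the input matrix values.
#' @param delim Matrix delimiter.
#' @param normalization `"none"`, `"tpm"` or `"fpkm"` (the latter two need
#'   raw counts + lengths).
#' @param log_transform Apply `log2(x + 1)` before z-scoring (off by
#'   default).
#' @param max_order Moment grid order (7 gives 49 moments).
#' @param n_components PCA width (default 36).
#' @param k_negatives Size of the low-correlation negative pool.
#' @param exclude_gold Exclude gold pairs from the negative pool.
#' @param n_pos,n_neg Per-class training rows; `NULL` takes the balanced
#'   maximum available.
#' @param classifiers Subset of `c("rewklr", "svm", "ocsvm")` to tune, fit
#'   and evaluate.
#' @param rewklr_grid,svm_grid,ocsvm_grid Tuning lattices.
#' @param tau REWKLR prevalence correction; `NULL` uses the prevalence of
#'   gold pairs among all candidate pairs, `"sample"` disables weighting.
#' @param n_boot Bootstrap resamples per grid point during tuning.
#' @param holdout_fraction Stratified fraction of the labeled set held out
#'   for evaluation.
#' @param n_resamples Bootstrap resamples for ROC/PR error bars.
#' @param chunk_size Pairs per moment-computation chunk.
#' @param max_per_class Training cap per class (Gram matrices are quadratic
#'   in the training size).
#' @param seed Master seed; all stage seeds derive from it.
#' @param write_features Also write the full pair-feature table (can be
#'   large).
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       sim = NULL,
                       matrix_path = NULL, lengths_path = NULL,
                       gold_path = NULL, id_map_path = NULL,
                       matrix_normalization = "raw_counts", delim = "\t",
                       normalization = c("none", "tpm", "fpkm"),
                       log_transform = FALSE,
                       max_order = 7L, n_components = 36L,
                       k_negatives = 10000L, exclude_gold = TRUE,
                       n_pos = NULL, n_neg = NULL,
                       classifiers = c("rewklr", "svm"),
                       rewklr_grid = default_rewklr_grid(),
                       svm_grid = default_svm_grid(),
                       ocsvm_grid = default_ocsvm_grid(),
                       tau = "sample", n_boot = 10L,
                       holdout_fraction = 0.25,
                       n_resamples = 500L,
                       chunk_size = 5000L, max_per_class = 4000L,
                       seed = 1L, write_features = FALSE) {
  normalization <- match.arg(normalization)
  classifiers <- match.arg(classifiers, c("rewklr", "svm", "ocsvm"),
                           several.ok = TRUE)
  if (is.null(sim)) {
    for (p in c(matrix_path, gold_path)) {
      if (is.null(p) || !file.exists(p)) {
        abort(sprintf("Input file missing before any compute: %s.",
                      p %||% "(matrix_path/gold_path not set)"))
      }
    }
  }
  structure(as.list(environment()), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; `sim` is given as a nested
#' map of [simulation_config()] arguments, grids as maps of vectors that are
#' crossed.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(simulation_config, y$sim)
  for (g in c("rewklr_grid", "svm_grid", "ocsvm_grid")) {
    if (!is.null(y[[g]])) y[[g]] <- do.call(tidyr::expand_grid, y[[g]])
  }
  do.call(run_config, y)
}

# stratified holdout split; returns list(train=..., test=...) of row indices
holdout_split <- function(labels, fraction, seed) {
  with_seed(seed, {
    test <- unlist(lapply(c(0L, 1L), function(cl) {
      idx <- which(labels == cl)
      sort(sample(idx, max(1L, floor(fraction * length(idx)))))
    }))
    list(train = setdiff(seq_along(labels), test), test = sort(test))
  })
}

#' Persist a REWKLR model as a plain-text archive
#'
#' Writes config, class weights, intercept, dual coefficients and support
#' points as labeled TSV blocks in one file; [read_rewklr_model()] restores
#' an equivalent model.
#'
#' @param model A `rewklr` fit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rewklr_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- model$config
  writeLines(c("#rewklr_model v1",
               sprintf("lambda\t%.17g", cfg$lambda),
               sprintf("sigma\t%.17g", cfg$sigma),
               sprintf("tau\t%s", if (identical(cfg$tau, "sample")) "sample"
                       else sprintf("%.17g", cfg$tau)),
               sprintf("intercept\t%.17g", model$intercept),
               sprintf("w0\t%.17g", model$class_weights[["w0"]]),
               sprintf("w1\t%.17g", model$class_weights[["w1"]]),
               sprintf("features\t%s", paste(model$feature_names, collapse = ","))),
             con)
  writeLines("#alpha", con)
  writeLines(sprintf("%.17g", model$alpha), con)
  writeLines("#support_points", con)
  utils::write.table(model$support_points, con, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Restore a REWKLR model written by [write_rewklr_model()]
#'
#' @param path Archive path.
#' @return A `rewklr` model usable with [predict.rewklr()].
#' @export
read_rewklr_model <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "#rewklr_model v1") abort("Not a rewklr model archive.")
  hdr_end <- which(lines == "#alpha") - 1L
  kv <- strsplit(lines[2:hdr_end], "\t", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  sp_start <- which(lines == "#support_points")
  alpha <- as.numeric(lines[(hdr_end + 2L):(sp_start - 1L)])
  sp <- do.call(rbind, lapply(lines[(sp_start + 1L):length(lines)],
                              function(l) as.numeric(strsplit(l, "\t")[[1]])))
  feature_names <- strsplit(vals[["features"]], ",", fixed = TRUE)[[1]]
  colnames(sp) <- feature_names
  tau <- if (vals[["tau"]] == "sample") "sample" else as.numeric(vals[["tau"]])
  structure(list(
    support_points = sp, alpha = alpha,
    intercept = as.numeric(vals[["intercept"]]),
    class_weights = c(w0 = as.numeric(vals[["w0"]]),
                      w1 = as.numeric(vals[["w1"]])),
    config = list(lambda = as.numeric(vals[["lambda"]]),
                  sigma = as.numeric(vals[["sigma"]]), tau = tau),
    feature_names = feature_names,
    fitted = NULL, labels = NULL, objective = NA_real_,
    grad_norm = NA_real_, n_iter = NA_integer_
  ), class = "rewklr")
}

write_stage <- function(x, dir, name) {
  path <- file.path(dir, name)
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  path
}

#' Run the full inference pipeline
#'
#' Executes the stages in order: load or simulate the expression matrix and
#' gold standard, normalize, z-score, enumerate pairs, compute joint moments,
#' PCA-reduce, build the labeled training set, split off a held-out
#' evaluation set, tune and fit each requested classifier, and evaluate on
#' the held-out pairs. Every stage output is written to the run directory and
#' checksummed in `run_log.yaml`; the run is fully deterministic given the
#' configuration.
#'
#' @param config A [run_config()].
#' @return A list: `expression`, `gold`, `features` (pair table with reduced
#'   columns), `pca`, `training`, `split`, `tuning` (per classifier),
#'   `models`, `reports`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character()

  # --- input stage -------------------------------------------------------
  if (!is.null(config$sim)) {
    gold <- simulate_network(config$sim)
    expr <- simulate_expression(gold, config$sim)
    artifacts["gold"] <- write_stage(
      dplyr::select(as_tibble(gold), "regulator", "target"),
      config$out_dir, "gold_edges.tsv")
    artifacts["expression"] <- file.path(config$out_dir, "expression.tsv")
    write_expression_matrix(expr, artifacts[["expression"]])
  } else {
    expr <- read_expression_matrix(config$matrix_path, delim = config$delim,
                                   normalization = config$matrix_normalization)
    id_map <- if (!is.null(config$id_map_path)) {
      read_gene_id_map(config$id_map_path)
    } else NULL
    if (!is.null(id_map)) expr <- apply_gene_id_map(expr, id_map, "keep")
    gold <- load_gold_edges(config$gold_path, id_map = id_map)
  }

  # --- normalization -----------------------------------------------------
  if (config$normalization != "none") {
    if (is.null(config$lengths_path) && is.null(config$sim)) {
      abort("TPM/FPKM normalization needs `lengths_path`.")
    }
    lengths <- read_gene_lengths(config$lengths_path)
    expr <- switch(config$normalization,
                   tpm = tpm_normalize(expr, lengths),
                   fpkm = fpkm_normalize(expr, lengths))
  }
  if (config$log_transform) {
    vals <- expr_values(expr)
    out <- dplyr::bind_cols(tibble(gene_id = rownames(vals)),
                            as_tibble(log2(vals + 1)))
    expr <- expression_tibble(out, normalization = expr_normalization(expr))
  }

  # --- features ----------------------------------------------------------
  z <- zscore_genes(expr)
  spec <- moment_spec(config$max_order)
  moments <- compute_moments(z, spec = spec, chunk_size = config$chunk_size)
  pca <- fit_pca(moments, n_components = config$n_components)
  features <- transform_pca(pca, moments)
  if (config$write_features) {
    artifacts["features"] <- write_stage(features, config$out_dir,
                                         "pair_features.tsv")
  }

  # --- labeling ----------------------------------------------------------
  positives <- build_positive_set(features, gold)
  negatives <- select_negatives(features, gold, k = config$k_negatives,
                                exclude_gold = config$exclude_gold)
  n_pos <- config$n_pos %||% min(nrow(positives), nrow(negatives))
  n_neg <- config$n_neg %||% n_pos
  training <- assemble_training_set(positives, negatives, features,
                                    n_pos = n_pos, n_neg = n_neg,
                                    seed = config$seed + 11L)
  artifacts["training"] <- write_stage(training, config$out_dir,
                                       "training_set.tsv")
  split <- holdout_split(training$label, config$holdout_fraction,
                         config$seed + 23L)
  train_set <- training[split$train, ]
  test_set <- training[split$test, ]

  tau <- config$tau %||% (nrow(gold_pairs(gold)) / n_pairs(z$gene_id))

  # --- classifiers -------------------------------------------------------
  tuning <- list()
  models <- list()
  reports <- list()
  for (cl in config$classifiers) {
    grid <- switch(cl, rewklr = config$rewklr_grid, svm = config$svm_grid,
                   ocsvm = config$ocsvm_grid)
    tuning[[cl]] <- bootstrap_tune(train_set, classifier = cl, grid = grid,
                                   n_boot = config$n_boot,
                                   seed = config$seed + 31L)
    best <- tuning[[cl]]$best
    if (cl == "rewklr") {
      models[[cl]] <- train_rewklr(train_set, lambda = best$lambda,
                                   sigma = best$sigma, tau = tau,
                                   max_per_class = config$max_per_class)
      scores <- predict(models[[cl]], test_set)
      preds <- as.integer(scores >= 0.5)
      write_rewklr_model(models[[cl]],
                         file.path(config$out_dir, "rewklr_model.txt"))
      artifacts["rewklr_model"] <- file.path(config$out_dir, "rewklr_model.txt")
    } else if (cl == "svm") {
      models[[cl]] <- train_svm(train_set, cost = best$cost,
                                gamma = best$gamma,
                                max_per_class = config$max_per_class)
      p <- predict(models[[cl]], test_set)
      scores <- p$score
      preds <- p$label
    } else {
      pos_rows <- train_set[train_set$label == 1L, ]
      models[[cl]] <- train_ocsvm(
        as.matrix(pos_rows[setdiff(names(pos_rows)[vapply(pos_rows, is.numeric,
                                                          logical(1))],
                                   c("label"))]),
        nu = best$nu, gamma = best$gamma)
      p <- predict(models[[cl]], test_set)
      scores <- p$score
      preds <- as.integer(p$inlier)
    }
    reports[[cl]] <- evaluation_report(
      labels = test_set$label, scores = scores, predictions = preds,
      classifier_tag = cl, dataset_tag = expr_normalization(expr),
      n_resamples = config$n_resamples, seed = config$seed + 41L,
      one_class = cl == "ocsvm")
    artifacts[paste0("report_", cl)] <- write_stage(
      tidy(reports[[cl]]), config$out_dir, sprintf("report_%s.tsv", cl))
    if (!is.null(reports[[cl]]$roc)) {
      artifacts[paste0("roc_", cl)] <- write_stage(
        reports[[cl]]$roc$curve, config$out_dir, sprintf("roc_%s.tsv", cl))
      artifacts[paste0("pr_", cl)] <- write_stage(
        reports[[cl]]$pr$curve, config$out_dir, sprintf("pr_%s.tsv", cl))
    }
  }

  # --- run log -----------------------------------------------------------
  log <- list(
    seed = config$seed,
    normalization = config$normalization,
    n_genes = nrow(z), n_samples = ncol(z) - 1L,
    n_pairs = nrow(features), n_positives = nrow(positives),
    n_negatives = nrow(negatives),
    training_rows = nrow(training), holdout_rows = length(split$test),
    tau = if (identical(tau, "sample")) "sample" else tau,
    checksums = as.list(tools::md5sum(unname(artifacts)))
  )
  yaml::write_yaml(log, file.path(config$out_dir, "run_log.yaml"))

  list(expression = expr, gold = gold, features = features, pca = pca,
       training = training, split = split, tuning = tuning, models = models,
       reports = reports, out_dir = config$out_dir)
}
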