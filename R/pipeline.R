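#' Pipeline configuration
#'
#' Bundles every stage's settings for an end-to-end run. Exactly one of
#' `synth` (a [synth_spec()]) or `recordings` (paths to recording CSVs)
#' must be supplied; all stage seeds are derived from the master seed.
#'
#' @param synth A [synth_spec()] for a synthetic cohort, or `NULL`.
#' @param recordings Character vector of recording CSV paths, or `NULL`.
#' @param n_high,n_low Cohort sizes when generating synthetically.
#' @param window,overlap Sliding-window settings (seconds, fraction).
#' @param n_perm Permutations for the correlation stage.
#' @param alpha_lenient Selection threshold on the permutation p-value.
#' @param rf_grid Named list with `n_trees` and `max_depth` integer grids
#'   for the grid search (`NULL` skips the search and uses `n_trees` /
#'   `max_depth` directly).
#' @param n_trees,max_depth Forest hyperparameters when no grid is given.
#' @param pca_threshold,pca_k Component selection: threshold on cumulative
#'   contribution, or a fixed k (which wins when both are set).
#' @param cnn A [cnn_config()].
#' @param stack,stride Epoch stacking for classifier inputs.
#' @param split_by `"sample"` or `"subject"` CV/test splitting.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synth = synth_spec(), recordings = NULL,
                            n_high = 13, n_low = 12,
                            window = 5, overlap = 0.5,
                            n_perm = 2000, alpha_lenient = 0.1,
                            rf_grid = NULL, n_trees = 11, max_depth = 10,
                            pca_threshold = 0.877, pca_k = NULL,
                            cnn = cnn_config(), stack = 20, stride = 10,
                            split_by = "sample", seed = 1) {
  if (is.null(synth) == is.null(recordings)) {
    stop("exactly one of `synth` or `recordings` must be set", call. = FALSE)
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full identification pipeline
#'
#' Executes every stage in order: cohort acquisition (synthetic generation
#' or CSV loading), line-noise removal and artifact flagging, subject-level
#' metric means and permutation screening, feature extraction for the
#' selected metric-region pairs, random-forest grid search (optional),
#' backward elimination, PCA combination, PCA-fused CNN training, and
#' evaluation. Intermediate artifacts are written to `out_dir` along with
#' a manifest of seeds and settings; deterministic given the config.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory for artifacts (`NULL` = don't write).
#' @return List with every stage's result: `comparisons`, `selected`,
#'   `features`, `grid`, `trace`, `basis`, `k`, `weights`, `model`,
#'   `report`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(name, obj) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, name)
    if (is.data.frame(obj)) utils::write.csv(obj, path, row.names = FALSE)
    else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(NULL)
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  cohort <- stage("cohort", {
    if (!is.null(config$synth)) {
      generate_cohort(config$synth, config$n_high, config$n_low,
                      seed = derive_seed(seed, "cohort"))
    } else {
      lapply(config$recordings, read_recording_csv)
    }
  })

  subject_values <- stage("metrics", subject_metric_means(cohort))
  comparisons <- stage("correlate", evaluate_correlations(
    subject_values, n_perm = config$n_perm,
    seed = derive_seed(seed, "perm")))
  emit("comparisons.csv", as.data.frame(comparisons))

  selected <- stage("select", select_features(
    comparisons, alpha_lenient = config$alpha_lenient))
  if (!length(selected)) {
    stop("pipeline stage 'select' failed: no significant metric-region pairs",
         call. = FALSE)
  }
  emit("selected_features.json", as.list(selected))
  pairs <- attr(selected, "pairs")

  features <- stage("features", purrr::map_dfr(cohort, function(rec) {
    rec <- remove_line_noise(rec)
    extract_features(rec, window = config$window, overlap = config$overlap,
                     metrics = unique(pairs$metric),
                     regions = unique(pairs$region))
  }))
  emit("features.csv", features)

  feat_cols <- setdiff(names(features),
                       c("subject_id", "group", "epoch_index", "window_start_s"))
  y <- factor(features$group)
  groups <- if (config$split_by == "subject") features$subject_id else NULL

  grid <- NULL
  n_trees <- config$n_trees; max_depth <- config$max_depth
  if (!is.null(config$rf_grid)) {
    grid <- stage("grid_search", rf_grid_search(
      features[feat_cols], y,
      n_trees_grid = config$rf_grid$n_trees,
      max_depth_grid = config$rf_grid$max_depth,
      seed = derive_seed(seed, "grid"), groups = groups))
    n_trees <- grid$n_trees; max_depth <- grid$max_depth
    emit("grid_surface.csv", grid$surface)
  }

  trace <- stage("eliminate", backward_eliminate(
    features[feat_cols], y, n_trees, max_depth,
    seed = derive_seed(seed, "elim"), groups = groups))
  emit("elimination_trace.csv",
       dplyr::select(as.data.frame(trace), -"retained"))
  kept <- retained_features(trace)

  basis <- stage("pca", fit_pca(features[kept]))
  k <- stage("pca", select_k(basis, threshold = config$pca_threshold,
                             k = config$pca_k))
  weights <- composite_weights(basis, k)
  emit("pca_basis.csv", tidy(basis))
  emit("composite_weights.json", as.list(weights))

  sc <- pca_scores(basis, features[kept], k)
  colnames(sc) <- paste0("PC", seq_len(k))
  scores <- dplyr::bind_cols(
    features[c("subject_id", "group", "epoch_index")],
    tibble::as_tibble(as.data.frame(sc)))
  inputs <- stage("inputs", build_cnn_inputs(
    scores, shape = config$cnn$input_shape,
    stack = config$stack, stride = config$stride))

  model <- stage("train", train_cnn(
    inputs, config = config$cnn, seed = derive_seed(seed, "cnn"),
    fusion = TRUE, split_by = config$split_by))
  emit("training_curve.csv", model$epoch_trajectory)

  report <- stage("evaluate", {
    te <- model$test_idx
    pred <- predict_cnn(model, inputs$maps[te])
    eval_report(model$labels[te], pred$label, pred$score)
  })
  emit("report.json", c(report$counts, as.list(report$metrics),
                        list(auc = report$auc)))

  manifest <- list(
    package_version = as.character(utils::packageVersion("eegsa")),
    master_seed = seed,
    stage_seeds = list(cohort = derive_seed(seed, "cohort"),
                       perm = derive_seed(seed, "perm"),
                       grid = derive_seed(seed, "grid"),
                       elim = derive_seed(seed, "elim"),
                       cnn = derive_seed(seed, "cnn")),
    n_high = config$n_high, n_low = config$n_low,
    window = config$window, overlap = config$overlap,
    n_perm = config$n_perm, alpha_lenient = config$alpha_lenient,
    n_trees = n_trees, max_depth = max_depth,
    pca_threshold = config$pca_threshold, k = k,
    selected = as.character(selected), retained = kept)
  emit("manifest.json", manifest)

  list(cohort = cohort, subject_values = subject_values,
       comparisons = comparisons, selected = selected, features = features,
       grid = grid, trace = trace, basis = basis, k = k, weights = weights,
       inputs = inputs, model = model, report = report, manifest = manifest)
}
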