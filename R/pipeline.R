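# End-to-end workflow over a synthetic corpus: simulate ratings, aggregate,
# extract features, split, train, predict, evaluate.

#' Configuration of a full pipeline run
#'
#' @param n_materials Corpus size (default 40 for a quick run).
#' @param kind Feature kind `"S"`, `"T"` or `"C"`.
#' @param predictor `"mlp"` or `"knn"`.
#' @param alpha Similarity-metric correlation weight (default 0.5).
#' @param test_fraction Held-out fraction per category (default 0.2).
#' @param size_px Image side length (default 512).
#' @param rater Simulated rater panel, a [rater_config()].
#' @param offset_deg Near-specular frame offset (default 6; recorded for
#'   provenance, frames are generated directly here).
#' @param dpi,crop_px,sample_mm Preprocessing constants (250 DPI, 224 crop,
#'   26 mm sample).
#' @param seeds Named list of integer seeds: `corpus`, `raters`, `split`,
#'   `train`, `backend`.
#' @return A `run_config` list.
#' @export
run_config <- function(n_materials = 40, kind = c("S", "C", "T"),
                       predictor = c("mlp", "knn"), alpha = 0.5,
                       test_fraction = 0.2, size_px = 512,
                       rater = rater_config(),
                       offset_deg = 6, dpi = 250, crop_px = 224,
                       sample_mm = 26,
                       seeds = list(corpus = 11, raters = 12, split = 13,
                                    train = 14, backend = 15)) {
  kind <- match.arg(kind)
  predictor <- match.arg(predictor)
  stopifnot(alpha >= 0, alpha <= 1, n_materials >= 4,
            all(c("corpus", "raters", "split", "train", "backend") %in%
                  names(seeds)))
  structure(list(n_materials = n_materials, kind = kind,
                 predictor = predictor, alpha = alpha,
                 test_fraction = test_fraction, size_px = size_px,
                 rater = rater, offset_deg = offset_deg, dpi = dpi,
                 crop_px = crop_px, sample_mm = sample_mm, seeds = seeds),
            class = "run_config")
}

corpus_features <- function(corpus, kind, backend = NULL) {
  rows <- purrr::map(seq_along(corpus$params), function(i) {
    pair <- corpus_pair(corpus, i)
    switch(kind,
           S = stat_features(pair),
           T = texture_features(pair),
           C = embed_pair(pair, backend))
  })
  dplyr::bind_rows(rows)
}

#' Run the full fingerprint pipeline on a synthetic corpus
#'
#' Generates a stratified procedural corpus, simulates the rating study,
#' aggregates ratings into fingerprints (z-scoring, discordant-rater
#' exclusion, averaging), rescales to the unit range, extracts image features
#' for every material, splits by category, trains the configured predictor on
#' the training split, predicts the held-out materials and evaluates the
#' predictions. Fully deterministic under the seeds in the config.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory: writes `fingerprints.csv`,
#'   `predictions.csv`, `exclusions.json` and `report.json`.
#' @return List with `report` (an `fp_eval`), `model`, `fingerprints`
#'   (aggregated, unit scale), `predictions`, `split`, `corpus`,
#'   `aggregation`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)))
    })
  }
  corpus <- stage("synthesis", make_corpus(config$n_materials,
                                           seed = config$seeds$corpus,
                                           size_px = config$size_px))
  rc <- config$rater
  rc$seed <- config$seeds$raters
  ratings <- stage("rating simulation", simulate_ratings(corpus$truths, rc))
  agg <- stage("aggregation", aggregate_ratings(ratings, corpus$categories))
  human_unit <- stage("rescaling", rescale_to_unit(agg$fingerprints))
  backend <- if (config$kind == "C") {
    projection_backend(seed = config$seeds$backend)
  } else NULL
  feats <- stage("feature extraction",
                 corpus_features(corpus, config$kind, backend))
  split <- stage("split", split_dataset(corpus$categories,
                                        test_fraction = config$test_fraction,
                                        seed = config$seeds$split))
  train_f <- feats[feats$material_id %in% split$train_ids, , drop = FALSE]
  test_f <- feats[feats$material_id %in% split$test_ids, , drop = FALSE]
  train_fp <- human_unit[human_unit$material_id %in% split$train_ids, ,
                         drop = FALSE]
  model <- stage("training", {
    if (config$predictor == "mlp") {
      train_mlp(train_f, train_fp, kind = config$kind,
                policy = augmentation_policy(rotation = config$kind != "S"),
                seed = config$seeds$train)
    } else {
      fit_knn(train_f, train_fp, k = 2)
    }
  })
  preds <- stage("prediction", {
    p <- predict(model, test_f)
    p$category <- corpus$categories$category[
      match(p$material_id, corpus$categories$material_id)]
    p
  })
  human_test <- human_unit[match(preds$material_id, human_unit$material_id), ,
                           drop = FALSE]
  report <- stage("evaluation",
                  evaluate_predictions(preds, human_test,
                                       alpha = config$alpha,
                                       top_n = nrow(preds)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fingerprints(human_unit, file.path(out_dir, "fingerprints.csv"))
    write_fingerprints(preds, file.path(out_dir, "predictions.csv"))
    jsonlite::write_json(agg$excluded, file.path(out_dir, "exclusions.json"))
    jsonlite::write_json(glance(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(report = report, model = model, fingerprints = human_unit,
       predictions = preds, split = split, corpus = corpus, aggregation = agg)
}
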