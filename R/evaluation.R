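# Model-vs-human comparison statistics: similarity-matrix variance explained,
# per-attribute rating variance explained, mean absolute error, top-k
# retrieval overlap, rank correlation over the top-ranked materials, and AIC.

match_sets <- function(pred, human) {
  pred <- validate_fingerprint_set(pred)
  human <- validate_fingerprint_set(human)
  if (!setequal(pred$material_id, human$material_id)) {
    rlang::abort("pred and human must cover the same material ids")
  }
  human <- human[match(pred$material_id, human$material_id), , drop = FALSE]
  list(pred = pred, human = human)
}

#' Similarity-matrix variance explained
#'
#' Squared Pearson correlation between the strict upper-triangle entries of
#' the fingerprint similarity matrices computed from model predictions and
#' from human ratings: how well the model reproduces the pattern of
#' between-material similarities.
#'
#' @param pred,human Unit-scale fingerprint sets over the same materials.
#' @param alpha Correlation weight of the similarity metric.
#' @return Squared correlation in \[0, 1\].
#' @export
rsm_r2 <- function(pred, human, alpha = 0.5) {
  ph <- match_sets(pred, human)
  if (nrow(ph$pred) < 3) rlang::abort("need at least 3 materials")
  mp <- similarity_matrix(ph$pred, alpha)
  mh <- similarity_matrix(ph$human, alpha)
  ut <- upper.tri(mp)
  stats::cor(mp[ut], mh[ut])^2
}

#' Rating-level variance explained per attribute
#'
#' For each of the 16 attributes, the squared Pearson correlation across
#' materials between predicted and human values, plus their mean. An
#' attribute that is constant in either set has undefined correlation; its
#' r-squared is reported as 0 with a warning.
#'
#' @param pred,human Fingerprint sets over the same materials (same scale).
#' @return List with `per_attribute` (tibble `id`, `name`, `r2`) and `mean`.
#' @export
rd_r2 <- function(pred, human) {
  ph <- match_sets(pred, human)
  P <- as.matrix(ph$pred[fp_cols()])
  H <- as.matrix(ph$human[fp_cols()])
  r2 <- vapply(1:16, function(a) {
    if (stats::sd(P[, a]) == 0 || stats::sd(H[, a]) == 0) {
      rlang::warn(sprintf("attribute %d constant: r2 taken as 0", a))
      return(0)
    }
    stats::cor(P[, a], H[, a])^2
  }, numeric(1))
  list(per_attribute = tibble::tibble(id = 1:16,
                                      name = attribute_schema()$name, r2 = r2),
       mean = mean(r2))
}

#' Mean absolute error between predicted and human fingerprints
#'
#' @param pred,human Fingerprint sets over the same materials and scale.
#' @return Mean of |pred - human| over materials x 16 attributes.
#' @export
mae <- function(pred, human) {
  ph <- match_sets(pred, human)
  if (unique(ph$pred$scale) != unique(ph$human$scale)) {
    rlang::abort("pred and human must share a scale")
  }
  mean(abs(as.matrix(ph$pred[fp_cols()]) - as.matrix(ph$human[fp_cols()])))
}

#' Top-k retrieval overlap per attribute
#'
#' For each attribute, the size of the intersection between the k materials
#' ranked highest by the model and by the humans (ties broken by ascending
#' material id).
#'
#' @param pred,human Fingerprint sets over the same materials.
#' @param k Number of top materials (default 5).
#' @return Tibble `id`, `name`, `overlap` (integers in 0..k).
#' @export
topk_overlap <- function(pred, human, k = 5) {
  ph <- match_sets(pred, human)
  n <- nrow(ph$pred)
  if (k > n) rlang::abort("k exceeds the number of materials")
  ids <- ph$pred$material_id
  P <- as.matrix(ph$pred[fp_cols()])
  H <- as.matrix(ph$human[fp_cols()])
  ov <- vapply(1:16, function(a) {
    top_p <- ids[order(-P[, a], ids)][seq_len(k)]
    top_h <- ids[order(-H[, a], ids)][seq_len(k)]
    length(intersect(top_p, top_h))
  }, numeric(1))
  tibble::tibble(id = 1:16, name = attribute_schema()$name,
                 overlap = as.integer(ov))
}

#' Rank correlation over the top-ranked materials (RCI)
#'
#' Per attribute: take the `top_n` materials with the highest human ratings
#' (clamped to the corpus size; ties broken by ascending material id), and
#' compute the Spearman rank correlation between the human and predicted
#' values within that subset. All-tied predictions within a subset give 0
#' with a warning.
#'
#' @param pred,human Fingerprint sets over the same materials.
#' @param top_n Subset size (default 100).
#' @return Tibble `id`, `name`, `rci` in \[-1, 1\].
#' @export
rank_rci <- function(pred, human, top_n = 100) {
  ph <- match_sets(pred, human)
  n <- nrow(ph$pred)
  if (n < 2) rlang::abort("need at least 2 materials")
  top_n <- min(top_n, n)
  ids <- ph$pred$material_id
  P <- as.matrix(ph$pred[fp_cols()])
  H <- as.matrix(ph$human[fp_cols()])
  rci <- vapply(1:16, function(a) {
    sel <- order(-H[, a], ids)[seq_len(top_n)]
    hp <- H[sel, a]
    pp <- P[sel, a]
    if (stats::sd(pp) == 0 || stats::sd(hp) == 0) {
      rlang::warn(sprintf("attribute %d: tied values in the top-%d subset; rci 0",
                          a, top_n))
      return(0)
    }
    stats::cor(hp, pp, method = "spearman")
  }, numeric(1))
  tibble::tibble(id = 1:16, name = attribute_schema()$name, rci = rci)
}

#' Akaike information criterion for fingerprint predictors
#'
#' Gaussian-likelihood AIC over all test residuals:
#' `AIC = 2 * n_params + n * log(RSS / n)` with n = materials x 16.
#'
#' @param models A named list; each element a list with `n_params` and
#'   `residuals` (numeric vector of prediction errors over the test set).
#' @return Tibble `model`, `n_params`, `n`, `rss`, `aic`, sorted by AIC
#'   (lower is better).
#' @export
aic_compare <- function(models) {
  rows <- purrr::imap(models, function(m, name) {
    if (length(m$residuals) == 0) rlang::abort("residuals must be non-empty")
    n <- length(m$residuals)
    rss <- sum(m$residuals^2)
    if (rss <= 0) rlang::abort("degenerate fit: RSS is zero")
    tibble::tibble(model = name, n_params = m$n_params, n = n, rss = rss,
                   aic = 2 * m$n_params + n * log(rss / n))
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$aic)
}

#' Full evaluation report of predicted against human fingerprints
#'
#' Bundles all comparison statistics into one object: similarity-matrix
#' variance explained, per-attribute and mean rating variance explained, mean
#' absolute error, top-k retrieval overlap and the rank correlation index.
#'
#' @param pred,human Unit-scale fingerprint sets over the same materials.
#' @param alpha Similarity-metric correlation weight.
#' @param k Top-k size for retrieval overlap (clamped to corpus size).
#' @param top_n Subset size for the rank correlation index.
#' @return An `fp_eval` object.
#' @export
evaluate_predictions <- function(pred, human, alpha = 0.5, k = 5, top_n = 100) {
  ph <- match_sets(pred, human)
  k <- min(k, nrow(ph$pred))
  rd <- rd_r2(ph$pred, ph$human)
  structure(list(
    rsm_r2 = rsm_r2(ph$pred, ph$human, alpha),
    rd_r2_per_attribute = rd$per_attribute,
    rd_r2_mean = rd$mean,
    mae = mae(ph$pred, ph$human),
    overlap_topk = topk_overlap(ph$pred, ph$human, k),
    k = k,
    rci = rank_rci(ph$pred, ph$human, top_n),
    n_materials = nrow(ph$pred),
    alpha = alpha
  ), class = "fp_eval")
}

#' @export
print.fp_eval <- function(x, ...) {
  cat("Fingerprint prediction evaluation (", x$n_materials, " materials)\n",
      sep = "")
  cat(sprintf("  RSM^2 (similarity matrices): %.3f\n", x$rsm_r2))
  cat(sprintf("  RD^2  (ratings, mean):       %.3f\n", x$rd_r2_mean))
  cat(sprintf("  MAE:                         %.3f\n", x$mae))
  cat(sprintf("  mean top-%d overlap:          %.2f\n", x$k,
              mean(x$overlap_topk$overlap)))
  cat(sprintf("  mean RCI:                    %.3f\n", mean(x$rci$rci)))
  invisible(x)
}

#' @export
tidy.fp_eval <- function(x, ...) {
  dplyr::bind_rows(
    x$rd_r2_per_attribute |>
      dplyr::transmute(.data$id, .data$name, metric = "rd_r2",
                       value = .data$r2),
    x$overlap_topk |>
      dplyr::transmute(.data$id, .data$name, metric = "topk_overlap",
                       value = as.numeric(.data$overlap)),
    x$rci |>
      dplyr::transmute(.data$id, .data$name, metric = "rci", value = .data$rci)
  )
}

#' @export
glance.fp_eval <- function(x, ...) {
  tibble::tibble(
    rsm_r2 = x$rsm_r2, rd_r2_mean = x$rd_r2_mean, mae = x$mae,
    mean_topk_overlap = mean(x$overlap_topk$overlap),
    mean_rci = mean(x$rci$rci), n_materials = x$n_materials,
    alpha = x$alpha
  )
}
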