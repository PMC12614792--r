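# Feature -> fingerprint predictors: inverse-distance k-nearest-neighbour
# interpolation and small multilayer perceptrons with the per-kind
# architectures 1341-256-64-32-16 (T), 28-16-16-16 (S), 1024-512-512-16 (C).

#' Stratified train/test split of a material corpus
#'
#' Draws `round(test_fraction * n)` test members per category (at least one
#' when the category has two or more members, none when it has exactly one),
#' without replacement under the seed, so every category with at least two
#' members is represented in the test set.
#'
#' @param ids_with_categories Tibble with `material_id` and `category`.
#' @param test_fraction Fraction held out per category (default 0.2).
#' @param seed Integer seed.
#' @return List with `train_ids` and `test_ids` (disjoint; union = corpus).
#' @export
split_dataset <- function(ids_with_categories, test_fraction = 0.2, seed = 1) {
  df <- tibble::as_tibble(ids_with_categories)
  stopifnot(all(c("material_id", "category") %in% names(df)))
  if (nrow(df) == 0) rlang::abort("empty corpus")
  if (anyDuplicated(df$material_id)) rlang::abort("duplicate material ids")
  with_local_seed(seed, {
    test_ids <- df |>
      dplyr::group_by(.data$category) |>
      dplyr::group_map(function(g, key) {
        n <- nrow(g)
        n_test <- if (n >= 2) max(1, round(test_fraction * n)) else 0
        if (n_test == 0) character(0) else sample(g$material_id, n_test)
      }) |>
      unlist()
    list(train_ids = sort(setdiff(df$material_id, test_ids)),
         test_ids = sort(test_ids))
  })
}

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(mu = mu, sd = sdv)
}

standardize_apply <- function(X, st) {
  sweep(sweep(X, 2, st$mu), 2, st$sd, "/")
}

align_xy <- function(features, fingerprints) {
  X <- feature_matrix(features)
  fingerprints <- validate_fingerprint_set(fingerprints)
  ids <- rownames(X)
  missing <- setdiff(ids, fingerprints$material_id)
  if (length(missing) > 0) {
    rlang::abort(paste0("fingerprints missing for: ",
                        paste(utils::head(missing, 5), collapse = ", ")))
  }
  Y <- as.matrix(fingerprints[match(ids, fingerprints$material_id), fp_cols()])
  rownames(Y) <- ids
  list(X = X, Y = Y, scale = unique(fingerprints$scale))
}

#' Fit a k-nearest-neighbour fingerprint interpolator
#'
#' Stores the (per-feature standardized) training features and fingerprints.
#' Prediction finds the k nearest training materials in the L2 sense and
#' interpolates their fingerprints with inverse-distance weights
#' `w_i = (1/d_i) / sum_j (1/d_j)`; a query at zero distance returns that
#' neighbour's fingerprint exactly. The default k = 2 interpolates between
#' the two closest exemplars.
#'
#' @param features Feature tibble (rows = training materials, one kind).
#' @param fingerprints Fingerprint set of the same materials.
#' @param k Number of neighbours (default 2).
#' @return A `matfp_knn` model.
#' @export
fit_knn <- function(features, fingerprints, k = 2) {
  xy <- align_xy(features, fingerprints)
  if (k < 1) rlang::abort("k must be >= 1")
  if (nrow(xy$X) < k) rlang::abort("fewer training samples than k")
  st <- standardize_fit(xy$X)
  structure(list(
    Xs = standardize_apply(xy$X, st), Y = xy$Y, st = st, k = as.integer(k),
    kind = unique(features$kind), fp_scale = xy$scale
  ), class = "matfp_knn")
}

query_matrix <- function(model_kind, n_features, query) {
  if (is.data.frame(query)) {
    if (!is.null(model_kind) && "kind" %in% names(query) &&
        !all(query$kind == model_kind)) {
      rlang::abort(sprintf("query kind does not match model kind '%s'", model_kind))
    }
    Q <- feature_matrix(query)
  } else {
    Q <- matrix(as.numeric(query), nrow = 1)
    rownames(Q) <- "query"
  }
  if (ncol(Q) != n_features) {
    rlang::abort(sprintf("query has %d features; model expects %d",
                         ncol(Q), n_features))
  }
  if (!all(is.finite(Q))) rlang::abort("query features must be finite")
  Q
}

#' Predict fingerprints by inverse-distance neighbour interpolation
#'
#' @param model A `matfp_knn` model.
#' @param query Feature tibble (one or more rows) or numeric feature vector.
#' @return Fingerprint-set tibble of predictions on the model's fingerprint
#'   scale.
#' @export
knn_predict <- function(model, query) {
  stopifnot(inherits(model, "matfp_knn"))
  Q <- query_matrix(model$kind, ncol(model$Xs), query)
  Qs <- standardize_apply(Q, model$st)
  preds <- t(apply(Qs, 1, function(q) {
    d <- sqrt(colSums((t(model$Xs) - q)^2))
    ord <- order(d, rownames(model$Xs))
    nb <- ord[seq_len(model$k)]
    dnb <- d[nb]
    if (dnb[1] == 0) return(model$Y[nb[1], ])
    w <- (1 / dnb) / sum(1 / dnb)
    colSums(model$Y[nb, , drop = FALSE] * w)
  }))
  out <- fingerprint_set(rownames(Q), preds, scale = "zscore")
  out$scale <- model$fp_scale
  if (model$fp_scale == "unit") {
    out[fp_cols()] <- tibble::as_tibble(pmin(pmax(as.matrix(out[fp_cols()]), -1), 1))
  }
  validate_fingerprint_set(out)
}

#' @export
predict.matfp_knn <- function(object, newdata, ...) knn_predict(object, newdata)

#' Image-space augmentation policy
#'
#' @param random_crop,rotation Logical switches. Rotation must stay off for
#'   S features, which are rotation-invariant by construction.
#' @param max_scale Maximum relative rescaling (default 0.05).
#' @param max_azimuth_jitter_deg Maximum azimuthal perturbation when a frame
#'   sequence is available (default 2.5; a no-op for bare image pairs).
#' @return An `augmentation_policy` list.
#' @export
augmentation_policy <- function(random_crop = TRUE, rotation = TRUE,
                                max_scale = 0.05,
                                max_azimuth_jitter_deg = 2.5) {
  structure(list(random_crop = random_crop, rotation = rotation,
                 max_scale = max_scale,
                 max_azimuth_jitter_deg = max_azimuth_jitter_deg),
            class = "augmentation_policy")
}

#' Train a fingerprint-regression MLP
#'
#' Fully connected network with rectifier activations on hidden layers and an
#' identity 16-unit output, minimising mean squared error with Adam. The
#' architecture follows the feature kind: 1341-256-64-32-16 (T), 28-16-16-16
#' (S), 1024-512-512-16 (C). Features are standardized over the training set.
#' Training is deterministic under `seed`; by default a 10% validation slice
#' drives early stopping.
#'
#' When `augment_features` is supplied (a function `(material_id, replicate)`
#' returning a feature tibble computed from a perturbed image), each training
#' material contributes `n_augment` extra feature rows; rotation must be
#' disabled in the policy for S features.
#'
#' @param features Feature tibble of the training materials (one kind).
#' @param fingerprints Fingerprint set of the same materials.
#' @param kind Feature kind, `"S"`, `"T"` or `"C"` (default: from
#'   `features$kind`).
#' @param policy An [augmentation_policy()]; consulted by
#'   `augment_features` generators.
#' @param augment_features Optional generator of augmented feature rows.
#' @param n_augment Augmented replicates per material (default 2).
#' @param lr,epochs,batch_size,val_frac,patience,weight_decay Optimiser
#'   settings: Adam learning rate, epoch cap, minibatch size, validation
#'   fraction for early stopping, early-stopping patience, and decoupled L2
#'   weight decay (biases are not decayed).
#' @param seed Integer seed.
#' @return A `matfp_mlp` model.
#' @export
train_mlp <- function(features, fingerprints, kind = NULL,
                      policy = augmentation_policy(),
                      augment_features = NULL, n_augment = 2,
                      lr = 1e-3, epochs = 4000, batch_size = 32,
                      val_frac = 0.1, patience = 300, weight_decay = 1,
                      seed = 1) {
  if (is.null(kind)) kind <- unique(features$kind)
  if (!kind %in% names(mlp_architectures)) {
    rlang::abort("kind must be one of 'S', 'T', 'C'")
  }
  if (kind == "S" && isTRUE(policy$rotation) && !is.null(augment_features)) {
    rlang::abort("rotation augmentation is not applicable to S features")
  }
  xy <- align_xy(features, fingerprints)
  dims <- mlp_architectures[[kind]]
  if (ncol(xy$X) != dims[1]) {
    rlang::abort(sprintf("kind '%s' expects %d features, got %d",
                         kind, dims[1], ncol(xy$X)))
  }
  if (nrow(xy$X) < 2) rlang::abort("need at least 2 training samples")
  X <- xy$X
  Y <- xy$Y
  if (!is.null(augment_features)) {
    extra <- purrr::map(rownames(xy$X), function(id) {
      purrr::map(seq_len(n_augment), function(r) {
        feature_matrix(augment_features(id, r))
      })
    })
    Xa <- do.call(rbind, unlist(extra, recursive = FALSE))
    Ya <- xy$Y[rep(seq_len(nrow(xy$X)), each = n_augment), , drop = FALSE]
    X <- rbind(X, Xa)
    Y <- rbind(Y, Ya)
  }
  st <- standardize_fit(X)
  fit <- mlp_fit(standardize_apply(X, st), Y, dims, lr = lr, epochs = epochs,
                 batch_size = batch_size, val_frac = val_frac,
                 patience = patience, weight_decay = weight_decay, seed = seed)
  structure(list(
    par = fit$par, dims = dims, kind = kind, st = st, fp_scale = xy$scale,
    train_loss = fit$train_loss, val_loss = fit$val_loss,
    epochs_run = fit$epochs_run, seed = seed,
    n_train = nrow(X)
  ), class = "matfp_mlp")
}

#' Predict fingerprints with a trained MLP
#'
#' Deterministic forward pass; returns 16 finite values per query row.
#'
#' @param model A `matfp_mlp` model.
#' @param query Feature tibble or numeric feature vector.
#' @return Fingerprint-set tibble of predictions.
#' @export
mlp_predict <- function(model, query) {
  stopifnot(inherits(model, "matfp_mlp"))
  Q <- query_matrix(model$kind, model$dims[1], query)
  P <- mlp_forward(model$par, standardize_apply(Q, model$st))
  out <- fingerprint_set(rownames(Q), P, scale = "zscore")
  out$scale <- model$fp_scale
  if (model$fp_scale == "unit") {
    out[fp_cols()] <- tibble::as_tibble(pmin(pmax(as.matrix(out[fp_cols()]), -1), 1))
  }
  validate_fingerprint_set(out)
}

#' @export
predict.matfp_mlp <- function(object, newdata, ...) mlp_predict(object, newdata)

#' @export
print.matfp_mlp <- function(x, ...) {
  cat("Fingerprint MLP (", x$kind, "): ",
      paste(x$dims, collapse = "-"), "\n", sep = "")
  cat("  train MSE:", format(x$train_loss, digits = 4),
      " val MSE:", format(x$val_loss, digits = 4),
      " epochs:", x$epochs_run, "\n")
  invisible(x)
}

#' @export
glance.matfp_mlp <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, n_train = x$n_train,
    n_params = mlp_n_params(x$par),
    train_mse = x$train_loss, val_mse = x$val_loss,
    epochs_run = x$epochs_run
  )
}

#' Number of trainable parameters of a predictor
#'
#' For an MLP, the weight and bias count; for the neighbour interpolator, the
#' stored exemplar coordinate count (features + fingerprints).
#'
#' @param model A `matfp_mlp` or `matfp_knn` model.
#' @return Integer parameter count.
#' @export
model_n_params <- function(model) {
  if (inherits(model, "matfp_mlp")) return(mlp_n_params(model$par))
  if (inherits(model, "matfp_knn")) {
    return(length(model$Xs) + length(model$Y))
  }
  rlang::abort("unknown model type")
}
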