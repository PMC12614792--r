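#' Fingerprint similarity: weighted correlation plus L1 agreement
#'
#' Similarity between two unit-scale fingerprints as a weighted combination of
#' the Pearson correlation between their sixteen attribute values and an
#' L1-based amplitude term:
#'
#' \deqn{d(V_1, V_2) = \alpha R(V_1, V_2) +
#'   (1 - \alpha)\left[1 - \frac{1}{2n}\sum_i |V_1(i) - V_2(i)|\right]}
#'
#' with n = 16. The correlation term captures proportional (shape) similarity
#' of the attribute profiles; the L1 term compares absolute amplitudes. With
#' values confined to \[-1, 1\] the L1 term lies in \[0, 1\], so the whole
#' statistic lies in \[-alpha, 1\] and equals 1 only for identical profiles.
#' Higher values mean more similar.
#'
#' If either vector has zero variance the correlation is undefined; its
#' contribution is taken as 0 and a warning is emitted.
#'
#' @param v1,v2 Numeric vectors of length 16 on the unit scale, or one-row
#'   fingerprint-set tibbles.
#' @param alpha Weight in \[0, 1\] on the correlation term (default 0.5).
#' @return A single numeric similarity.
#' @export
#' @examples
#' v <- seq(-1, 1, length.out = 16)
#' fingerprint_similarity(v, v)        # 1
#' fingerprint_similarity(v, -v)       # -0.5 at alpha = 0.5
fingerprint_similarity <- function(v1, v2, alpha = 0.5) {
  v1 <- as_fp_vector(v1)
  v2 <- as_fp_vector(v2)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1) {
    rlang::abort("`alpha` must be a single number in [0, 1]")
  }
  n <- n_attributes()
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    rlang::warn("zero-variance fingerprint: correlation term taken as 0")
    r <- 0
  } else {
    r <- stats::cor(v1, v2)
  }
  l1 <- 1 - sum(abs(v1 - v2)) / (2 * n)
  alpha * r + (1 - alpha) * l1
}

as_fp_vector <- function(v) {
  if (is.data.frame(v)) {
    if (nrow(v) != 1) rlang::abort("expected a single fingerprint (one row)")
    if ("scale" %in% names(v) && v$scale != "unit") {
      rlang::abort("fingerprint must be on the unit scale; see rescale_to_unit()")
    }
    v <- unlist(v[fp_cols()])
  }
  v <- as.numeric(v)
  if (length(v) != n_attributes() || !all(is.finite(v))) {
    rlang::abort("a fingerprint is 16 finite values")
  }
  v
}

#' Pairwise similarity matrix of a fingerprint set
#'
#' @param fps A unit-scale fingerprint-set tibble.
#' @param alpha Correlation weight, see [fingerprint_similarity()].
#' @return An object of class `fp_similarity_matrix`: a symmetric numeric
#'   matrix with material ids as dimnames.
#' @export
similarity_matrix <- function(fps, alpha = 0.5) {
  fps <- validate_fingerprint_set(fps)
  if (unique(fps$scale) != "unit") {
    rlang::abort("similarity needs unit-scale fingerprints; see rescale_to_unit()")
  }
  ids <- fps$material_id
  vals <- as.matrix(fps[fp_cols()])
  n <- length(ids)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        s <- fingerprint_similarity(vals[i, ], vals[j, ], alpha)
        m[i, j] <- s
        m[j, i] <- s
      }
    }
  }
  # diagonal is the self-similarity; 1 unless a fingerprint is constant
  for (i in seq_len(n)) {
    if (stats::sd(vals[i, ]) == 0) {
      m[i, i] <- suppressWarnings(fingerprint_similarity(vals[i, ], vals[i, ], alpha))
    }
  }
  structure(m, class = c("fp_similarity_matrix", "matrix", "array"))
}

#' Retrieve the most similar materials to a query fingerprint
#'
#' Ranks all members of `fps` (minus the query itself, when its id occurs in
#' the set) by descending similarity to the query. Ties are broken by
#' ascending material id so the ordering is deterministic.
#'
#' @param query A unit-scale fingerprint: numeric length-16 vector or one-row
#'   tibble with `material_id`.
#' @param fps Candidate fingerprint set (unit scale).
#' @param k Number of hits to return (>= 1); capped at the number of
#'   candidates.
#' @param alpha Correlation weight.
#' @return Tibble with columns `material_id`, `similarity`, `rank`.
#' @export
retrieve_top_k <- function(query, fps, k = 5, alpha = 0.5) {
  if (!is.numeric(k) || length(k) != 1 || k < 1) rlang::abort("`k` must be >= 1")
  fps <- validate_fingerprint_set(fps)
  query_id <- if (is.data.frame(query) && "material_id" %in% names(query)) {
    query$material_id
  } else NA_character_
  qv <- as_fp_vector(query)
  cand <- fps[is.na(query_id) | fps$material_id != query_id, , drop = FALSE]
  if (nrow(cand) == 0) rlang::abort("no candidates besides the query itself")
  sims <- vapply(seq_len(nrow(cand)), function(i) {
    fingerprint_similarity(qv, unlist(cand[i, fp_cols()]), alpha)
  }, numeric(1))
  ord <- order(-sims, cand$material_id)
  take <- ord[seq_len(min(k, length(ord)))]
  tibble::tibble(
    material_id = cand$material_id[take],
    similarity = sims[take],
    rank = seq_along(take)
  )
}

#' Typicality of a material within a corpus
#'
#' A material's typicality is its mean similarity to the most similar decile
#' (by default) of the other corpus members: the mean of the top
#' `ceiling(fraction * (N - 1))` similarity values, self excluded. Higher
#' values mean the material sits in a densely populated region of fingerprint
#' space.
#'
#' @param material_id Id of the probe material (must be in `fps`).
#' @param fps Unit-scale fingerprint set with at least 2 members.
#' @param fraction Fraction of the other members to average over (default
#'   0.10).
#' @param alpha Correlation weight.
#' @return A single numeric typicality.
#' @export
typicality <- function(material_id, fps, fraction = 0.10, alpha = 0.5) {
  fps <- validate_fingerprint_set(fps)
  if (!material_id %in% fps$material_id) {
    rlang::abort(sprintf("material '%s' not in the set", material_id))
  }
  if (nrow(fps) < 2) rlang::abort("typicality needs at least 2 materials")
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    rlang::abort("`fraction` must be in (0, 1]")
  }
  qv <- fingerprint_values(fps, material_id)
  others <- fps[fps$material_id != material_id, , drop = FALSE]
  sims <- vapply(seq_len(nrow(others)), function(i) {
    fingerprint_similarity(qv, unlist(others[i, fp_cols()]), alpha)
  }, numeric(1))
  n_top <- ceiling(fraction * length(sims))
  mean(sort(sims, decreasing = TRUE)[seq_len(n_top)])
}

#' Median fingerprint profile of a material category
#'
#' Per-attribute median and standard error of the mean across the fingerprints
#' of one category, the numbers behind a category's polar-plot profile (the
#' contour thickness showing the standard error).
#'
#' @param fps Fingerprint set with a `category` column.
#' @param category Category label to profile.
#' @return Tibble with 16 rows: `id`, `name`, `median`, `stderr`, `n`.
#' @export
category_profile <- function(fps, category) {
  fps <- validate_fingerprint_set(fps)
  members <- fps[!is.na(fps$category) & fps$category == category, , drop = FALSE]
  if (nrow(members) == 0) {
    rlang::abort(sprintf("no materials with category '%s'", category))
  }
  vals <- as.matrix(members[fp_cols()])
  med <- apply(vals, 2, stats::median)
  se <- apply(vals, 2, function(x) {
    if (length(x) < 2) 0 else stats::sd(x) / sqrt(length(x))
  })
  tibble::tibble(
    id = 1:16,
    name = attribute_schema()$name,
    median = unname(med),
    stderr = unname(se),
    n = nrow(members)
  )
}

#' Rescale a z-score fingerprint set to the unit range
#'
#' Maps each attribute's \[min, max\] over the set affinely onto \[-1, 1\].
#' This bounds per-attribute differences by 2, which is what lets the
#' 1/(2n) factor of the similarity metric normalise the L1 term into
#' \[0, 1\]. The per-attribute reference ranges are stored in the
#' `"unit_ranges"` attribute of the result so novel fingerprints (e.g. model
#' predictions) can be mapped onto the same scale with [apply_unit_scale()].
#'
#' @param fps A z-score-scale fingerprint set; every attribute must vary
#'   across the set.
#' @return Unit-scale fingerprint set with a `"unit_ranges"` attribute (tibble
#'   `id`, `min`, `max`).
#' @export
rescale_to_unit <- function(fps) {
  fps <- validate_fingerprint_set(fps)
  if (unique(fps$scale) != "zscore") {
    rlang::abort("rescale_to_unit() expects a zscore-scale set")
  }
  vals <- as.matrix(fps[fp_cols()])
  mins <- apply(vals, 2, min)
  maxs <- apply(vals, 2, max)
  flat <- which(maxs - mins <= 0)
  if (length(flat) > 0) {
    rlang::abort(paste0(
      "cannot rescale: constant attribute(s) across the set: ",
      paste(attribute_schema()$name[flat], collapse = ", ")
    ))
  }
  scaled <- sweep(vals, 2, mins)
  scaled <- sweep(scaled, 2, (maxs - mins), "/") * 2 - 1
  out <- fps
  out[fp_cols()] <- tibble::as_tibble(scaled)
  out$scale <- "unit"
  attr(out, "unit_ranges") <- tibble::tibble(id = 1:16, min = unname(mins),
                                             max = unname(maxs))
  out
}

#' Map fingerprints onto a previously fitted unit scale
#'
#' Applies the per-attribute affine maps stored by [rescale_to_unit()] to new
#' fingerprints (values are clamped to \[-1, 1\] if they fall outside the
#' reference range).
#'
#' @param fps A zscore-scale fingerprint set.
#' @param ranges A ranges tibble (`id`, `min`, `max`) as stored in the
#'   `"unit_ranges"` attribute, or a fingerprint set carrying one.
#' @return Unit-scale fingerprint set.
#' @export
apply_unit_scale <- function(fps, ranges) {
  fps <- validate_fingerprint_set(fps)
  if (is.data.frame(ranges) && !is.null(attr(ranges, "unit_ranges"))) {
    ranges <- attr(ranges, "unit_ranges")
  }
  stopifnot(all(c("min", "max") %in% names(ranges)), nrow(ranges) == 16)
  vals <- as.matrix(fps[fp_cols()])
  scaled <- sweep(vals, 2, ranges$min)
  scaled <- sweep(scaled, 2, (ranges$max - ranges$min), "/") * 2 - 1
  scaled <- pmin(pmax(scaled, -1), 1)
  out <- fps
  out[fp_cols()] <- tibble::as_tibble(scaled)
  out$scale <- "unit"
  attr(out, "unit_ranges") <- ranges
  out
}
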