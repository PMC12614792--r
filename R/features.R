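# Image-computable feature sets from a non-specular / near-specular pair:
# S (28 compact statistics), T (1341 texture-synthesis statistics),
# C (1024 embedding features from a pluggable backend).

#' Construct a material image pair
#'
#' @param frame_nonspec,frame_spec H x W x 3 arrays, sRGB in \[0, 1\], same
#'   shape.
#' @param sample_size_mm Physical side length of the depicted square area in
#'   mm (canonical 26).
#' @param material_id Material identifier.
#' @return A `material_image_pair` list.
#' @export
material_image_pair <- function(frame_nonspec, frame_spec,
                                sample_size_mm = 26, material_id = "material") {
  for (f in list(frame_nonspec, frame_spec)) {
    if (length(dim(f)) != 3 || dim(f)[3] != 3) {
      rlang::abort("frames must be H x W x 3 arrays")
    }
    if (min(f) < -1e-9 || max(f) > 1 + 1e-9) {
      rlang::abort("frame values must lie in [0, 1]")
    }
  }
  if (!identical(dim(frame_nonspec), dim(frame_spec))) {
    rlang::abort("both frames must have the same shape")
  }
  if (sample_size_mm <= 0) rlang::abort("sample_size_mm must be positive")
  structure(list(frame_nonspec = frame_nonspec, frame_spec = frame_spec,
                 sample_size_mm = sample_size_mm, material_id = material_id),
            class = "material_image_pair")
}

#' Select the non-specular and near-specular frames of a rotation sequence
#'
#' For a sequence of `n_frames` spanning `span_deg` of azimuthal camera
#' rotation ending at the mirror (ideal specular) configuration, picks the
#' middle frame as the non-specular view and the frame offset by
#' approximately `offset_deg` back from the ideal specular angle as the
#' near-specular view (the ideal angle itself often saturates for shiny
#' materials).
#'
#' @param n_frames Number of frames (>= 2; canonical 60).
#' @param span_deg Angular span covered by the sequence (default 90).
#' @param offset_deg Offset back from the ideal specular angle (default 6).
#' @return Tibble with `index_nonspec`, `index_spec`, `offset_deg`.
#' @export
#' @examples
#' select_frames(60) # frames 30 and 56
select_frames <- function(n_frames, span_deg = 90, offset_deg = 6) {
  if (n_frames < 2) rlang::abort("need at least 2 frames")
  if (offset_deg >= span_deg) rlang::abort("offset must be smaller than the span")
  step <- span_deg / (n_frames - 1)
  idx_ns <- min(max(round(n_frames / 2), 1), n_frames)
  idx_sp <- min(max(n_frames - round(offset_deg / step), 1), n_frames)
  if (idx_sp <= idx_ns) {
    rlang::abort("specular frame does not follow the non-specular frame; offset too large")
  }
  tibble::tibble(index_nonspec = as.integer(idx_ns),
                 index_spec = as.integer(idx_sp),
                 offset_deg = offset_deg)
}

# bilinear resize of a matrix or H x W x 3 array
resize_bilinear <- function(im, out_h, out_w) {
  resize_plane <- function(p) {
    h <- nrow(p); w <- ncol(p)
    yi <- (seq_len(out_h) - 0.5) * h / out_h + 0.5
    xi <- (seq_len(out_w) - 0.5) * w / out_w + 0.5
    y0 <- pmin(pmax(floor(yi), 1), h); y1 <- pmin(y0 + 1, h)
    x0 <- pmin(pmax(floor(xi), 1), w); x1 <- pmin(x0 + 1, w)
    fy <- pmin(pmax(yi - y0, 0), 1); fx <- pmin(pmax(xi - x0, 0), 1)
    p00 <- p[y0, x0, drop = FALSE]; p01 <- p[y0, x1, drop = FALSE]
    p10 <- p[y1, x0, drop = FALSE]; p11 <- p[y1, x1, drop = FALSE]
    wy <- matrix(fy, out_h, out_w); wx <- matrix(fx, out_h, out_w, byrow = TRUE)
    p00 * (1 - wy) * (1 - wx) + p01 * (1 - wy) * wx +
      p10 * wy * (1 - wx) + p11 * wy * wx
  }
  if (length(dim(im)) == 3) {
    out <- array(0, dim = c(out_h, out_w, dim(im)[3]))
    for (ch in seq_len(dim(im)[3])) out[, , ch] <- resize_plane(im[, , ch])
    out
  } else {
    resize_plane(im)
  }
}

centre_crop <- function(im, size) {
  h <- dim(im)[1]; w <- dim(im)[2]
  if (h < size || w < size) rlang::abort("image smaller than the crop size")
  y0 <- floor((h - size) / 2); x0 <- floor((w - size) / 2)
  if (length(dim(im)) == 3) im[y0 + seq_len(size), x0 + seq_len(size), , drop = FALSE]
  else im[y0 + seq_len(size), x0 + seq_len(size), drop = FALSE]
}

#' Resample a pair to physical resolution and crop for embedding
#'
#' Each frame is resampled so that the depicted sample side spans
#' `round(sample_size_mm / 25.4 * dpi)` pixels (250 DPI makes the canonical
#' 26 mm sample 256 px) and then centre-cropped to `crop_px` (default 224),
#' the input size of the embedding backend.
#'
#' @param pair A `material_image_pair`.
#' @param dpi Target print resolution (default 250).
#' @param crop_px Final crop size (default 224).
#' @return A `material_image_pair` with `crop_px`-sized frames.
#' @export
preprocess_for_embedding <- function(pair, dpi = 250, crop_px = 224) {
  stopifnot(inherits(pair, "material_image_pair"))
  target <- round(pair$sample_size_mm / 25.4 * dpi)
  if (target < crop_px) {
    rlang::abort(sprintf(
      "sample too small: %.1f mm resamples to %d px (< %d px crop)",
      pair$sample_size_mm, target, crop_px))
  }
  scale_one <- function(f) {
    h <- dim(f)[1]; w <- dim(f)[2]
    s <- target / min(h, w)
    centre_crop(resize_bilinear(f, round(h * s), round(w * s)), crop_px)
  }
  material_image_pair(scale_one(pair$frame_nonspec), scale_one(pair$frame_spec),
                      sample_size_mm = pair$sample_size_mm,
                      material_id = pair$material_id)
}

luminance <- function(frame) {
  0.2126 * frame[, , 1] + 0.7152 * frame[, , 2] + 0.0722 * frame[, , 3]
}

# orientation-resolved and radial energy of the off-DC power spectrum
spectrum_profiles <- function(lum, n_theta = 16) {
  h <- nrow(lum); w <- ncol(lum)
  p <- Mod(fft2(lum - mean(lum)))^2
  p <- fftshift2(p)
  fx <- ((1:w) - (w / 2 + 1)) / (w / 2)
  fy <- ((1:h) - (h / 2 + 1)) / (h / 2)
  rad <- sqrt(outer(fy^2, fx^2, "+"))
  th <- atan2(outer(fy, rep(1, w)), outer(rep(1, h), fx)) %% pi
  keep <- rad > 0
  total <- sum(p[keep])
  if (total <= 0) {
    return(list(radial = rep(0, 4), theta = rep(0, n_theta), total = 0))
  }
  # four log-spaced bands spanning the full usable range (a 512 px frame
  # resolves pattern periods from 4 px, r = 1/2, up to ~256 px, r = 2^-7)
  edges <- 2^seq(-7, 0, length.out = 5) # units of Nyquist
  radial <- vapply(seq_len(4), function(b) {
    sel <- keep & rad > edges[b] & rad <= edges[b + 1]
    sum(p[sel]) / total
  }, numeric(1))
  tbin <- pmin(floor(th / pi * n_theta) + 1, n_theta)
  theta <- vapply(seq_len(n_theta), function(b) {
    sum(p[keep & tbin == b]) / total
  }, numeric(1))
  list(radial = radial, theta = theta, total = total)
}

# block-average a plane by factor f (trailing rows/cols beyond a full block
# are dropped); used to suppress fine pattern modulation before colour
# quantisation so that spatially coherent colours dominate
block_mean <- function(p, f) {
  h <- (nrow(p) %/% f) * f
  w <- (ncol(p) %/% f) * f
  p <- p[seq_len(h), seq_len(w), drop = FALSE]
  ph <- colMeans(array(p, dim = c(f, h / f, w))) # (h/f) x w
  t(colMeans(array(t(ph), dim = c(f, w / f, h / f))))
}

dominant_colours <- function(frame, max_clusters = 8, min_share = 0.05) {
  f <- max(1, min(dim(frame)[1], dim(frame)[2]) %/% 64)
  px <- cbind(as.vector(block_mean(frame[, , 1], f)),
              as.vector(block_mean(frame[, , 2], f)),
              as.vector(block_mean(frame[, , 3], f)))
  stride <- max(1, floor(nrow(px) / 4096))
  px <- px[seq(1, nrow(px), by = stride), , drop = FALSE]
  # sort pixels so the quantisation is invariant to pixel order (rotations,
  # translations)
  px <- px[order(px[, 1], px[, 2], px[, 3]), , drop = FALSE]
  uniq <- unique(px)
  if (nrow(uniq) <= max_clusters) {
    key <- apply(px, 1, paste, collapse = ",")
    shares <- table(key) / length(key)
    return(sum(shares >= min_share))
  }
  # Lloyd iterations on sorted pixels: deterministic and quiet on the smooth
  # colour continua that trip Hartigan-Wong
  km <- with_local_seed(42, suppressWarnings(
    stats::kmeans(px, centers = max_clusters, nstart = 3, iter.max = 100,
                  algorithm = "Lloyd")))
  sum(km$size / sum(km$size) >= min_share)
}

stat_features_frame <- function(frame) {
  lum <- luminance(frame)
  mu <- mean(lum)
  sdv <- stats::sd(as.vector(lum))
  sk <- skew2(lum)
  sp <- spectrum_profiles(lum)
  # gradient orientation statistics (doubled angles for axial data)
  gx <- (lum[, c(2:ncol(lum), ncol(lum))] - lum[, c(1, 1:(ncol(lum) - 1))]) / 2
  gy <- (lum[c(2:nrow(lum), nrow(lum)), ] - lum[c(1, 1:(nrow(lum) - 1)), ]) / 2
  gmag <- sqrt(gx^2 + gy^2)
  wsum <- sum(gmag)
  if (wsum > 0) {
    ang2 <- 2 * atan2(gy, gx)
    dir_strength <- Mod(sum(gmag * exp(1i * ang2))) / wsum
    ori <- atan2(gy, gx) %% pi
    bins <- pmin(floor(ori / pi * 16) + 1, 16)
    hist_w <- vapply(1:16, function(b) sum(gmag[bins == b]), numeric(1)) / wsum
    nz <- hist_w[hist_w > 0]
    dir_entropy <- -sum(nz * log(nz))
  } else {
    dir_strength <- 0
    dir_entropy <- 0
  }
  n_dom <- dominant_colours(frame)
  # pattern type from the orientation profile of the power spectrum
  e <- sp$theta
  if (sp$total > 0) {
    i1 <- which.max(e)
    e1 <- e[i1]
    ep <- e[((i1 - 1 + 8) %% 16) + 1]
    stripe <- max(0, e1 - ep)
    checker <- if (max(e1, ep) > 0) (e1 + ep) * min(e1, ep) / max(e1, ep) else 0
  } else {
    stripe <- 0
    checker <- 0
  }
  mx <- pmax(frame[, , 1], frame[, , 2], frame[, , 3])
  mn <- pmin(frame[, , 1], frame[, , 2], frame[, , 3])
  chroma <- mx - mn
  mean_chroma <- mean(chroma)
  coloured <- which(chroma > 1e-6)
  # hue statistics on a deterministic subsample; the circular SD stabilises
  # well below this count
  if (length(coloured) > 65536) {
    coloured <- coloured[seq(1, length(coloured),
                             by = ceiling(length(coloured) / 65536))]
  }
  if (length(coloured) > 0) {
    hsvv <- grDevices::rgb2hsv(rbind(as.vector(frame[, , 1])[coloured],
                                     as.vector(frame[, , 2])[coloured],
                                     as.vector(frame[, , 3])[coloured]),
                               maxColorValue = 1)
    hang <- 2 * pi * hsvv[1, ]
    rbar <- Mod(mean(exp(1i * hang)))
    hue_sd <- sqrt(pmax(-2 * log(pmax(rbar, 1e-12)), 0))
  } else {
    hue_sd <- 0
  }
  c(mu, sdv, sk, sp$radial, dir_strength, dir_entropy, n_dom, stripe, checker,
    mean_chroma, hue_sd)
}

#' Names of the 14 per-frame compact statistics
#' @return Character vector of length 14.
#' @export
stat_feature_names <- function() {
  c("lum_mean", "lum_sd", "lum_skew",
    "band_energy_1", "band_energy_2", "band_energy_3", "band_energy_4",
    "dir_strength", "dir_entropy", "n_dominant_colours",
    "stripe_score", "checker_score", "chroma_mean", "hue_circ_sd")
}

feature_tibble <- function(material_id, kind, values) {
  v <- matrix(values, nrow = 1)
  colnames(v) <- sprintf("f%04d", seq_along(values))
  dplyr::bind_cols(tibble::tibble(material_id = material_id, kind = kind),
                   tibble::as_tibble(v))
}

#' Compact image statistics (S features, 28 values per pair)
#'
#' Fourteen deterministic statistics per frame, non-specular frame first:
#' luminance mean, SD and skewness; relative energy in four log-spaced radial
#' frequency bands; directionality strength (resultant length of the
#' magnitude-weighted gradient orientation distribution) and the entropy of a
#' 16-bin orientation histogram; the number of dominant colours (clusters
#' holding at least 5% of pixels after 8-cluster quantisation); stripe and
#' checker pattern scores from the orientation profile of the power spectrum;
#' mean chroma; and the circular SD of hue. Degenerate (constant) frames
#' yield zeros for all contrast-type features, never NaN.
#'
#' @param pair A `material_image_pair`.
#' @return One-row tibble: `material_id`, `kind = "S"`, `f0001` .. `f0028`.
#' @export
stat_features <- function(pair) {
  stopifnot(inherits(pair, "material_image_pair"))
  vals <- c(stat_features_frame(pair$frame_nonspec),
            stat_features_frame(pair$frame_spec))
  feature_tibble(pair$material_id, "S", vals)
}

#' Raw (unmasked) texture-synthesis statistics of a pair
#'
#' Per colour channel, [ps_stats()] is computed on both frames and averaged,
#' giving a 798-slot raw layout per channel; the three channel blocks are
#' concatenated (2394 values). Use [texture_zero_mask()] or the structural
#' mask to prune the zero slots.
#'
#' @param pair A `material_image_pair` with frames at the canonical 512 x 512.
#' @return Numeric vector of length 2394.
#' @export
texture_features_raw <- function(pair) {
  stopifnot(inherits(pair, "material_image_pair"))
  unlist(lapply(1:3, function(ch) {
    (ps_stats(pair$frame_nonspec[, , ch]) + ps_stats(pair$frame_spec[, , ch])) / 2
  }), use.names = FALSE)
}

#' Zero-feature mask estimated over a corpus
#'
#' Marks the raw texture-statistic slots that are identically zero across all
#' rows of a corpus of raw vectors. On any corpus of non-degenerate images
#' this coincides with [ps_structural_mask()] (447 retained per channel).
#'
#' @param raws Matrix of raw vectors (rows = materials, 2394 columns).
#' @return Logical vector of length 2394; `TRUE` = keep.
#' @export
texture_zero_mask <- function(raws) {
  raws <- as.matrix(raws)
  if (ncol(raws) != 3 * 798) rlang::abort("raw texture vectors must have 2394 columns")
  apply(raws != 0, 2, any)
}

#' Texture-synthesis statistics (T features, 1341 values per pair)
#'
#' Steerable-pyramid texture statistics at 3 scales, 3 orientations and a
#' 7 x 7 correlation neighbourhood, computed per colour channel on both
#' frames (averaged), pruned of zero-valued slots: 447 features per channel,
#' 1341 in total.
#'
#' @param pair A `material_image_pair` with 512 x 512 frames.
#' @param mask Zero-feature mask of length 2394 (default: the structural
#'   mask replicated over channels). The mask must retain a fixed number of
#'   features per channel.
#' @return One-row tibble: `material_id`, `kind = "T"`, `f0001` .. `f1341`.
#' @export
texture_features <- function(pair, mask = NULL) {
  raw <- texture_features_raw(pair)
  if (is.null(mask)) mask <- rep(ps_structural_mask(), 3)
  if (length(mask) != length(raw)) {
    rlang::abort(sprintf("mask length %d does not match raw length %d",
                         length(mask), length(raw)))
  }
  feature_tibble(pair$material_id, "T", raw[mask])
}

#' Deterministic projection embedding backend
#'
#' A self-contained embedding backend: each 224 x 224 frame is block-averaged
#' to 32 x 32 per channel and projected with a fixed seeded Gaussian random
#' matrix to 512 dimensions. Deterministic, fast, and adequate for testing
#' the embedding pipeline end to end; a pretrained vision backbone can be
#' plugged in through the same interface.
#'
#' @param seed Seed of the projection matrix.
#' @return An `embedding_backend` list with fields `fn` (function from a
#'   224 x 224 x 3 array to a numeric 512-vector), `dim` (512) and `name`.
#' @export
projection_backend <- function(seed = 2024) {
  proj <- with_local_seed(seed, {
    matrix(stats::rnorm(3072 * 512), 3072, 512) / sqrt(3072)
  })
  fn <- function(img) {
    stopifnot(length(dim(img)) == 3, dim(img)[1] == 224, dim(img)[2] == 224)
    small <- resize_bilinear(img, 32, 32)
    as.numeric(crossprod(matrix(as.vector(small), ncol = 1), proj))
  }
  structure(list(fn = fn, dim = 512L, name = "seeded-projection"),
            class = "embedding_backend")
}

#' Embedding features (C features, 1024 values per pair)
#'
#' Preprocesses the pair to 224 px (see [preprocess_for_embedding()]), embeds
#' each frame with the backend and concatenates the two 512-vectors,
#' non-specular frame first.
#'
#' @param pair A `material_image_pair`.
#' @param backend An `embedding_backend` (default [projection_backend()]).
#' @return One-row tibble: `material_id`, `kind = "C"`, `f0001` .. `f1024`.
#' @export
embed_pair <- function(pair, backend = projection_backend()) {
  stopifnot(inherits(backend, "embedding_backend"))
  pp <- preprocess_for_embedding(pair)
  e1 <- backend$fn(pp$frame_nonspec)
  e2 <- backend$fn(pp$frame_spec)
  if (length(e1) != backend$dim || length(e2) != backend$dim ||
      backend$dim != 512L) {
    rlang::abort("backend must map a frame to a 512-vector")
  }
  feature_tibble(pair$material_id, "C", c(e1, e2))
}

#' Extract the numeric feature matrix from a feature tibble
#'
#' @param features Tibble of stacked feature rows (`material_id`, `kind`,
#'   `f....` columns).
#' @return Numeric matrix with material ids as rownames.
#' @export
feature_matrix <- function(features) {
  fc <- grep("^f[0-9]+$", names(features), value = TRUE)
  m <- as.matrix(features[fc])
  rownames(m) <- features$material_id
  m
}

# rotate a frame by an arbitrary angle about its centre (bilinear sampling,
# edge-clamped)
rotate_bilinear <- function(im, angle_deg) {
  th <- angle_deg * pi / 180
  rot_plane <- function(p) {
    h <- nrow(p); w <- ncol(p)
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    yy <- matrix(seq_len(h) - cy, h, w)
    xx <- matrix(seq_len(w) - cx, h, w, byrow = TRUE)
    ys <- pmin(pmax(cy + cos(th) * yy - sin(th) * xx, 1), h)
    xs <- pmin(pmax(cx + sin(th) * yy + cos(th) * xx, 1), w)
    y0 <- pmin(floor(ys), h - 1); x0 <- pmin(floor(xs), w - 1)
    fy <- ys - y0; fx <- xs - x0
    i00 <- cbind(as.vector(y0), as.vector(x0))
    i01 <- cbind(as.vector(y0), as.vector(x0 + 1))
    i10 <- cbind(as.vector(y0 + 1), as.vector(x0))
    i11 <- cbind(as.vector(y0 + 1), as.vector(x0 + 1))
    v <- p[i00] * as.vector((1 - fy) * (1 - fx)) +
      p[i01] * as.vector((1 - fy) * fx) +
      p[i10] * as.vector(fy * (1 - fx)) +
      p[i11] * as.vector(fy * fx)
    matrix(v, h, w)
  }
  out <- im
  for (ch in seq_len(dim(im)[3])) out[, , ch] <- rot_plane(im[, , ch])
  out
}

#' Apply a random image-space augmentation to a pair
#'
#' Draws one augmentation under the seed and applies it identically to both
#' frames: optional rotation by a uniform angle, a random crop of 85-100% of
#' the frame combined with a scale jitter of up to `max_scale`, resampled
#' back to the original frame size. The azimuthal-angle perturbation of the
#' policy only applies when a full frame sequence is available and is a no-op
#' for bare image pairs.
#'
#' @param pair A `material_image_pair`.
#' @param policy An [augmentation_policy()]; rotation must be disabled when
#'   the features consumed downstream are the rotation-invariant S set.
#' @param seed Integer seed.
#' @return An augmented `material_image_pair`.
#' @export
augment_pair <- function(pair, policy = augmentation_policy(), seed = 1) {
  stopifnot(inherits(pair, "material_image_pair"))
  with_local_seed(seed, {
    h <- dim(pair$frame_nonspec)[1]
    w <- dim(pair$frame_nonspec)[2]
    angle <- if (isTRUE(policy$rotation)) stats::runif(1, 0, 360) else 0
    scale <- 1 + stats::runif(1, -policy$max_scale, policy$max_scale)
    crop_frac <- if (isTRUE(policy$random_crop)) stats::runif(1, 0.85, 1) else 1
    side <- max(32, min(round(min(h, w) * crop_frac / scale), min(h, w)))
    y0 <- if (side < h) sample.int(h - side, 1) else 0
    x0 <- if (side < w) sample.int(w - side, 1) else 0
    tf <- function(f) {
      if (angle != 0) f <- rotate_bilinear(f, angle)
      f <- f[y0 + seq_len(side), x0 + seq_len(side), , drop = FALSE]
      pmin(pmax(resize_bilinear(f, h, w), 0), 1)
    }
    material_image_pair(tf(pair$frame_nonspec), tf(pair$frame_spec),
                        sample_size_mm = pair$sample_size_mm,
                        material_id = pair$material_id)
  })
}
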