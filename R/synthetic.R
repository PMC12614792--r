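# Procedural material image pairs with known ground-truth fingerprints.
# These are deliberately simple layered patterns (grating + checkerboard +
# palette colour field + 1/f^beta noise, plus a highlight/speckle layer on the
# near-specular frame) -- controllable appearance axes, not photorealism.

#' Parameters of one procedural material
#'
#' @param base_rgb Base colour, 3 values in \[0, 1\].
#' @param n_palette Number of palette colours (1--8); >1 gives a blobby
#'   multi-colour field.
#' @param stripe_amp,checker_amp,noise_amp Amplitudes in \[0, 1\] of the
#'   oriented sine grating, checkerboard and 1/f^beta noise luminance layers;
#'   their sum must not exceed 1.
#' @param pattern_period_px Period of the grating/checker cells in pixels
#'   (>= 4).
#' @param orientation_deg Grating orientation in degrees.
#' @param beta Spectral slope of the noise field (amplitude ~ 1/f^beta).
#' @param gloss Strength in \[0, 1\] of the smooth specular highlight added to
#'   the near-specular frame.
#' @param sparkle_density Density in \[0, 1\] of bright speckle on the
#'   near-specular frame.
#' @param brightness Overall brightness scale in \[0, 1\].
#' @param seed Integer seed making the image pair deterministic.
#' @return A `synth_params` list.
#' @export
synth_params <- function(base_rgb = c(0.5, 0.5, 0.5), n_palette = 1,
                         stripe_amp = 0, checker_amp = 0, noise_amp = 0,
                         pattern_period_px = 32, orientation_deg = 0,
                         beta = 1, gloss = 0, sparkle_density = 0,
                         brightness = 0.8, seed = 1) {
  stopifnot(length(base_rgb) == 3, all(base_rgb >= 0 & base_rgb <= 1),
            n_palette >= 1, n_palette <= 8,
            stripe_amp >= 0, checker_amp >= 0, noise_amp >= 0,
            pattern_period_px >= 4, beta >= 0,
            gloss >= 0, gloss <= 1,
            sparkle_density >= 0, sparkle_density <= 1,
            brightness >= 0, brightness <= 1)
  if (stripe_amp + checker_amp + noise_amp > 1 + 1e-9) {
    rlang::abort("stripe_amp + checker_amp + noise_amp must be <= 1")
  }
  structure(list(
    base_rgb = base_rgb, n_palette = as.integer(n_palette),
    stripe_amp = stripe_amp, checker_amp = checker_amp,
    noise_amp = noise_amp, pattern_period_px = pattern_period_px,
    orientation_deg = orientation_deg, beta = beta, gloss = gloss,
    sparkle_density = sparkle_density, brightness = brightness,
    seed = as.integer(seed)
  ), class = "synth_params")
}

# evaluate expr with a local RNG stream, restoring the caller's stream
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# 1/f^beta random field, scaled to [-1, 1]
spectral_noise <- function(n, beta) {
  white <- matrix(stats::rnorm(n * n), n, n)
  fw <- stats::fft(white)
  fx <- c(0:(n / 2), -(n / 2 - 1):-1) / n
  f <- sqrt(outer(fx^2, fx^2, "+"))
  f[1, 1] <- Inf # kill DC
  field <- Re(stats::fft(fw * f^(-beta), inverse = TRUE)) / (n * n)
  m <- max(abs(field))
  if (m > 0) field / m else field
}

palette_colours <- function(params) {
  base <- params$base_rgb
  n <- params$n_palette
  if (n == 1) return(matrix(base, nrow = 1))
  hsv0 <- grDevices::rgb2hsv(base[1], base[2], base[3], maxColorValue = 1)
  hues <- (hsv0[1, 1] + (seq_len(n) - 1) / n) %% 1
  vals <- pmin(1, pmax(0.2, hsv0[3, 1] + 0.25 * sin(2 * pi * seq_len(n) / n)))
  cols <- grDevices::hsv(hues, hsv0[2, 1], vals)
  t(grDevices::col2rgb(cols) / 255)
}

#' Generate a non-specular / near-specular image pair
#'
#' The non-specular frame is a brightness-scaled palette colour field plus
#' luminance layers: an oriented sine grating (`stripe_amp`), an axis-aligned
#' checkerboard (`checker_amp`) and a seeded 1/f^beta noise field
#' (`noise_amp`). The near-specular frame adds a smooth highlight scaled by
#' `gloss` and a bright speckle layer controlled by `sparkle_density`. The
#' pair is bitwise deterministic under `params$seed`.
#'
#' @param params A [synth_params()] object.
#' @param size_px Side length in pixels (default 512, the canonical working
#'   resolution).
#' @param sample_size_mm Physical side length of the depicted area (default
#'   26 mm).
#' @return A `material_image_pair`: list with `frame_nonspec`, `frame_spec`
#'   (H x W x 3 arrays in \[0, 1\]), `sample_size_mm`, `material_id`.
#' @export
generate_pair <- function(params, size_px = 512, sample_size_mm = 26) {
  stopifnot(inherits(params, "synth_params"))
  n <- as.integer(size_px)
  with_local_seed(params$seed, {
    u <- matrix(rep((0:(n - 1)) / n, each = n), n, n) # column coordinate
    v <- matrix(rep((0:(n - 1)) / n, times = n), n, n) # row coordinate
    th <- params$orientation_deg * pi / 180
    freq <- n / params$pattern_period_px
    modul <- matrix(0, n, n)
    if (params$stripe_amp > 0) {
      modul <- modul + params$stripe_amp *
        sin(2 * pi * freq * (u * cos(th) + v * sin(th)))
    }
    if (params$checker_amp > 0) {
      cell <- params$pattern_period_px / 2
      chk <- (floor(u * n / cell) + floor(v * n / cell)) %% 2
      modul <- modul + params$checker_amp * (2 * chk - 1)
    }
    if (params$noise_amp > 0) {
      modul <- modul + params$noise_amp * spectral_noise(n, params$beta)
    }
    pal <- palette_colours(params)
    if (params$n_palette > 1) {
      region_field <- spectral_noise(n, 1.5)
      qs <- stats::quantile(region_field,
                            probs = seq_len(params$n_palette - 1) / params$n_palette)
      region <- matrix(findInterval(region_field, qs) + 1L, n, n)
    } else {
      region <- matrix(1L, n, n)
    }
    nonspec <- array(0, dim = c(n, n, 3))
    for (ch in 1:3) {
      colfield <- matrix(pal[region, ch], n, n)
      nonspec[, , ch] <- pmin(pmax(
        params$brightness * (colfield + 0.5 * modul), 0), 1)
    }
    spec <- nonspec
    if (params$gloss > 0) {
      hl <- exp(-((u - 0.55)^2 + (v - 0.45)^2) / (2 * 0.22^2))
      for (ch in 1:3) {
        spec[, , ch] <- pmin(spec[, , ch] + 0.8 * params$gloss * hl, 1)
      }
    }
    if (params$sparkle_density > 0) {
      mask <- matrix(stats::runif(n * n) < 0.02 * params$sparkle_density, n, n)
      glint <- matrix(stats::runif(n * n, 0.6, 1), n, n)
      for (ch in 1:3) {
        spec[, , ch] <- pmin(spec[, , ch] + mask * glint, 1)
      }
    }
    structure(list(
      frame_nonspec = nonspec, frame_spec = spec,
      sample_size_mm = sample_size_mm,
      material_id = sprintf("synth-%08d", params$seed)
    ), class = "material_image_pair")
  })
}

clamp1 <- function(x) pmin(pmax(x, -1), 1)

#' Attribute ids directly controlled by the generator
#'
#' The ten attributes whose ground truth is a direct monotone map of a single
#' generator parameter (or a simple combination): colour vibrancy, surface
#' roughness, striped/chequered pattern, brightness, shininess, sparkle,
#' movement effect, pattern scale and multicoloured. The remaining six
#' (complexity, hardness, naturalness, thickness, value, warmth) use
#' documented surrogates and carry no claim of perceptual validity.
#'
#' @return Integer vector of attribute ids.
#' @export
generator_controlled_attributes <- function() {
  c(1L, 2L, 4L, 5L, 6L, 7L, 8L, 10L, 11L, 14L)
}

#' Ground-truth fingerprint of a procedural material
#'
#' Deterministic monotone maps from generator parameters to unit-scale
#' (\[-1, 1\]) attribute values. Direct axes: striped <- stripe_amp,
#' chequered <- checker_amp, brightness <- brightness, shininess <- gloss,
#' sparkle <- sparkle_density, multicoloured <- n_palette, colour vibrancy <-
#' palette chroma, pattern scale <- log2 period, surface roughness <-
#' noise_amp * beta, movement effect <- gloss + sparkle. Surrogates for the
#' cognitive attributes: pattern complexity from total pattern energy and
#' palette size, hardness inverse to roughness, naturalness = noise minus
#' checker, thickness from noise and darkness, value from gloss and chroma,
#' warmth from the red-blue balance of the palette.
#'
#' @param params A [synth_params()] object.
#' @return One-row unit-scale fingerprint-set tibble.
#' @export
truth_fingerprint <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  pal <- palette_colours(params)
  chroma <- mean(apply(pal, 1, function(p) max(p) - min(p)))
  rough <- params$noise_amp * params$beta # in [0, 2] over the corpus ranges
  v <- numeric(16)
  v[1] <- clamp1(2 * chroma / 0.8 - 1)                       # colour vibrancy
  v[2] <- clamp1(rough - 1)                                  # surface roughness
  v[3] <- clamp1(2 * (0.7 * (params$stripe_amp + params$checker_amp +
                               params$noise_amp) +
                        0.3 * (params$n_palette - 1) / 7) - 1) # complexity
  v[4] <- clamp1(2 * params$stripe_amp - 1)                  # striped
  v[5] <- clamp1(2 * params$checker_amp - 1)                 # chequered
  v[6] <- clamp1(2 * params$brightness - 1)                  # brightness
  v[7] <- clamp1(2 * params$gloss - 1)                       # shininess
  v[8] <- clamp1(2 * params$sparkle_density - 1)             # sparkle
  v[9] <- clamp1(1 - rough)                                  # hardness
  v[10] <- clamp1(2 * min(params$gloss + params$sparkle_density, 1) - 1) # movement
  v[11] <- clamp1(2 * (log2(params$pattern_period_px) - 2) / 5 - 1) # pattern scale
  v[12] <- clamp1(params$noise_amp - params$checker_amp)     # naturalness
  v[13] <- clamp1(2 * min(0.6 * params$noise_amp +
                            0.4 * (1 - params$brightness), 1) - 1) # thickness
  v[14] <- clamp1(2 * (params$n_palette - 1) / 7 - 1)        # multicoloured
  v[15] <- clamp1(2 * min(0.5 * params$gloss + 0.5 * chroma, 1) - 1) # value
  # warmth from the base colour's warm-cool balance (palette means cancel
  # for multi-hue palettes, which would collapse the axis into ties)
  v[16] <- clamp1(params$base_rgb[1] - params$base_rgb[3])

  fingerprint_set(sprintf("synth-%08d", params$seed), matrix(v, nrow = 1),
                  scale = "unit")
}

#' Configuration of a simulated rater panel
#'
#' Defaults are the reference simulation conditions used throughout the
#' package's recovery tests: 10 raters with response noise SD 0.2 (on the
#' \[-1, 1\] truth scale), per-participant gains in \[0.7, 1.3\] and biases in
#' \[-0.2, 0.2\], and one adversarial rater who answers with the negated
#' truth.
#'
#' @param n_participants Number of raters (>= 1).
#' @param response_noise_sd Gaussian response noise SD on the truth scale.
#' @param participant_gain_range,participant_bias_range Uniform ranges for the
#'   per-participant gain and bias.
#' @param n_adversarial Number of adversarial raters (responding with the
#'   negated truth; guaranteed negative correlation with the consensus).
#' @param slider_range Raw slider range (fixed at \[0, 100\]).
#' @param seed Integer seed.
#' @return A `rater_config` list.
#' @export
rater_config <- function(n_participants = 10, response_noise_sd = 0.2,
                         participant_gain_range = c(0.7, 1.3),
                         participant_bias_range = c(-0.2, 0.2),
                         n_adversarial = 1, slider_range = c(0, 100),
                         seed = 1) {
  stopifnot(n_participants >= 1, n_adversarial >= 0,
            n_adversarial <= n_participants, response_noise_sd >= 0)
  structure(list(
    n_participants = as.integer(n_participants),
    response_noise_sd = response_noise_sd,
    participant_gain_range = participant_gain_range,
    participant_bias_range = participant_bias_range,
    n_adversarial = as.integer(n_adversarial),
    slider_range = slider_range, seed = as.integer(seed)
  ), class = "rater_config")
}

#' Simulate a slider rating study over known fingerprints
#'
#' Honest participant p responds to truth t with
#' `clamp(50 + 40 * (gain_p * t + bias_p + N(0, sd)), slider_range)`;
#' adversarial participants respond with the negated truth (noise-free), so
#' their per-attribute correlation with the consensus is negative whenever
#' the truth varies. Deterministic under `config$seed`.
#'
#' @param truths A unit-scale fingerprint set of ground-truth fingerprints.
#' @param config A [rater_config()].
#' @return A raw ratings table (tibble) in slider units, with the adversarial
#'   participant ids recorded in the `"adversarial_ids"` attribute.
#' @export
simulate_ratings <- function(truths, config = rater_config()) {
  truths <- validate_fingerprint_set(truths)
  stopifnot(inherits(config, "rater_config"))
  tvals <- as.matrix(truths[fp_cols()])
  n_mat <- nrow(tvals)
  lo <- config$slider_range[1]
  hi <- config$slider_range[2]
  mid <- (lo + hi) / 2
  half <- (hi - lo) / 2
  with_local_seed(config$seed, {
    gains <- stats::runif(config$n_participants,
                          config$participant_gain_range[1],
                          config$participant_gain_range[2])
    biases <- stats::runif(config$n_participants,
                           config$participant_bias_range[1],
                           config$participant_bias_range[2])
    adversarial <- if (config$n_adversarial > 0) {
      seq(config$n_participants - config$n_adversarial + 1,
          config$n_participants)
    } else integer(0)
    rows <- purrr::map(seq_len(config$n_participants), function(p) {
      if (p %in% adversarial) {
        resp <- mid + 0.8 * half * (-tvals)
      } else {
        noise <- matrix(stats::rnorm(length(tvals), 0, config$response_noise_sd),
                        n_mat, 16)
        resp <- mid + 0.8 * half * (gains[p] * tvals + biases[p] + noise)
      }
      resp <- pmin(pmax(resp, lo), hi)
      tibble::tibble(
        participant_id = sprintf("p%02d", p),
        material_id = rep(truths$material_id, times = 16),
        attribute_id = rep(1:16, each = n_mat),
        response = as.vector(resp)
      )
    })
    out <- dplyr::bind_rows(rows)
    attr(out, "adversarial_ids") <- sprintf("p%02d", adversarial)
    out
  })
}

#' Draw a stratified corpus of procedural materials
#'
#' Draws `n` parameter sets stratified over four pseudo-categories
#' (striped-fabric-like, wood-grain-like, glossy-coating-like,
#' noisy-matte-like) whose parameter ranges jointly make every
#' generator-controlled attribute span most of \[-1, 1\]. Image pairs are
#' generated on demand with [corpus_pair()] to keep memory flat.
#'
#' @param n Number of materials (>= 1); assigned to categories round-robin.
#' @param seed Integer seed; the whole corpus is deterministic under it.
#' @param size_px Image side length used when pairs are realised.
#' @return A `synth_corpus` list: `params` (list of [synth_params()]),
#'   `truths` (unit-scale fingerprint set with categories), `categories`
#'   (tibble `material_id`, `category`), `size_px`.
#' @export
make_corpus <- function(n, seed = 1, size_px = 512) {
  stopifnot(n >= 1)
  cats <- c("striped-fabric-like", "wood-grain-like",
            "glossy-coating-like", "noisy-matte-like")
  with_local_seed(seed, {
    params <- vector("list", n)
    for (i in seq_len(n)) {
      cat_i <- cats[((i - 1) %% 4) + 1]
      base <- grDevices::hsv(stats::runif(1), stats::runif(1, 0, 1),
                             stats::runif(1, 0.3, 1))
      base_rgb <- as.numeric(grDevices::col2rgb(base)) / 255
      brightness <- stats::runif(1, 0.15, 1)
      period <- 2^stats::runif(1, 2, 7)
      mat_seed <- sample.int(.Machine$integer.max - 1, 1)
      p <- switch(cat_i,
        "striped-fabric-like" = {
          amp <- stats::runif(1, 0.5, 0.95)
          mix <- stats::runif(1)
          synth_params(
            base_rgb = base_rgb, n_palette = sample(1:6, 1),
            stripe_amp = mix * amp, checker_amp = (1 - mix) * amp,
            noise_amp = stats::runif(1, 0, 1 - amp),
            pattern_period_px = period,
            orientation_deg = stats::runif(1, 0, 180),
            beta = stats::runif(1, 0.5, 1.5),
            gloss = stats::runif(1, 0, 0.3),
            sparkle_density = stats::runif(1, 0, 0.2),
            brightness = brightness, seed = mat_seed
          )
        },
        "wood-grain-like" = {
          stripe <- stats::runif(1, 0.2, 0.45)
          synth_params(
            base_rgb = base_rgb, n_palette = sample(2:4, 1),
            stripe_amp = stripe, checker_amp = 0,
            noise_amp = stats::runif(1, 0.3, min(0.55, 1 - stripe)),
            pattern_period_px = period,
            orientation_deg = stats::runif(1, 0, 180),
            beta = stats::runif(1, 1.2, 2),
            gloss = stats::runif(1, 0, 0.4),
            sparkle_density = stats::runif(1, 0, 0.1),
            brightness = brightness, seed = mat_seed
          )
        },
        "glossy-coating-like" = {
          synth_params(
            base_rgb = base_rgb, n_palette = sample(1:8, 1),
            stripe_amp = stats::runif(1, 0, 0.2),
            checker_amp = stats::runif(1, 0, 0.2),
            noise_amp = stats::runif(1, 0, 0.3),
            pattern_period_px = period,
            orientation_deg = stats::runif(1, 0, 180),
            beta = stats::runif(1, 0.5, 1.5),
            gloss = stats::runif(1, 0.6, 1),
            sparkle_density = stats::runif(1, 0.3, 1),
            brightness = brightness, seed = mat_seed
          )
        },
        "noisy-matte-like" = {
          noise <- stats::runif(1, 0.5, 0.95)
          synth_params(
            base_rgb = base_rgb, n_palette = sample(1:8, 1),
            stripe_amp = stats::runif(1, 0, (1 - noise) / 2),
            checker_amp = stats::runif(1, 0, (1 - noise) / 2),
            noise_amp = noise,
            pattern_period_px = period,
            orientation_deg = stats::runif(1, 0, 180),
            beta = stats::runif(1, 1, 2),
            gloss = stats::runif(1, 0, 0.2),
            sparkle_density = stats::runif(1, 0, 0.1),
            brightness = brightness, seed = mat_seed
          )
        }
      )
      params[[i]] <- p
    }
    truths <- dplyr::bind_rows(purrr::map(params, truth_fingerprint))
    # guard against seed collisions making ids non-unique
    if (anyDuplicated(truths$material_id)) {
      dup <- which(duplicated(truths$material_id))
      for (i in dup) {
        params[[i]]$seed <- params[[i]]$seed + i
        truths$material_id[i] <- sprintf("synth-%08d", params[[i]]$seed)
      }
    }
    categories <- tibble::tibble(
      material_id = truths$material_id,
      category = cats[((seq_len(n) - 1) %% 4) + 1]
    )
    truths$category <- categories$category
    structure(list(params = params, truths = truths, categories = categories,
                   size_px = size_px), class = "synth_corpus")
  })
}

#' Realise the image pair of one corpus member
#'
#' @param corpus A [make_corpus()] object.
#' @param i Index or material id.
#' @return A `material_image_pair`.
#' @export
corpus_pair <- function(corpus, i) {
  stopifnot(inherits(corpus, "synth_corpus"))
  if (is.character(i)) i <- match(i, corpus$truths$material_id)
  generate_pair(corpus$params[[i]], size_px = corpus$size_px)
}
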