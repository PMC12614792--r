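# Independent oracles and small fixture builders shared across the suite.
# Oracles are written from the defining formulas, independent of the package
# code paths they check.

# similarity metric evaluated directly from its formula
oracle_similarity <- function(a, b, alpha) {
  am <- a - mean(a)
  bm <- b - mean(b)
  r <- sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
  alpha * r + (1 - alpha) * (1 - sum(abs(a - b)) / (2 * length(a)))
}

# Pearson correlation from first principles (no stats::cor)
oracle_pearson <- function(x, y) {
  xm <- x - sum(x) / length(x)
  ym <- y - sum(y) / length(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# Spearman correlation as Pearson on midranks
oracle_spearman <- function(x, y) oracle_pearson(rank(x), rank(y))

# Fleiss kappa from the published formula, via explicit loops
oracle_fleiss <- function(assignments, n_categories = 16) {
  resp <- sort(unique(assignments$response_id))
  counts <- matrix(0, length(resp), n_categories)
  for (i in seq_len(nrow(assignments))) {
    r <- match(assignments$response_id[i], resp)
    counts[r, assignments$attribute_id[i]] <-
      counts[r, assignments$attribute_id[i]] + 1
  }
  r <- sum(counts[1, ])
  n <- nrow(counts)
  P_i <- numeric(n)
  for (i in seq_len(n)) {
    P_i[i] <- (sum(counts[i, ]^2) - r) / (r * (r - 1))
  }
  p_j <- colSums(counts) / (n * r)
  Pbar <- mean(P_i)
  Pe <- sum(p_j^2)
  (Pbar - Pe) / (1 - Pe)
}

# random unit-scale fingerprint set
random_fps <- function(n, seed, categories = NA_character_) {
  set.seed(seed)
  fingerprint_set(sprintf("m%03d", seq_len(n)),
                  matrix(stats::runif(n * 16, -1, 1), n, 16),
                  scale = "unit", category = categories)
}

# single-colour pair with a vertical sinusoidal luminance grating
grating_pair <- function(amp = 0.8, period = 32, size = 128,
                         orientation_deg = 0) {
  p <- synth_params(stripe_amp = amp, pattern_period_px = period,
                    orientation_deg = orientation_deg, brightness = 0.6,
                    seed = 99)
  generate_pair(p, size_px = size)
}

# two-tone checkerboard pair
checker_pair <- function(amp = 0.9, period = 64, size = 128) {
  p <- synth_params(checker_amp = amp, pattern_period_px = period,
                    brightness = 0.6, seed = 98)
  generate_pair(p, size_px = size)
}

constant_pair <- function(value = 0.5, size = 64) {
  f <- array(value, dim = c(size, size, 3))
  material_image_pair(f, f, material_id = "constant")
}

# ratings table from explicit per-participant response matrices
ratings_from_matrix <- function(mats, attribute_id = 1) {
  # mats: named list participant -> named numeric vector (materials)
  rows <- lapply(names(mats), function(p) {
    tibble::tibble(participant_id = p,
                   material_id = names(mats[[p]]),
                   attribute_id = attribute_id,
                   response = unname(mats[[p]]))
  })
  dplyr::bind_rows(rows)
}
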