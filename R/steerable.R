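# Complex steerable pyramid (frequency-domain construction) and the
# texture-synthesis statistic set computed from it. The pyramid follows the
# classic raised-cosine design: a highpass residual above pi/2, oriented
# complex (analytic) bands one octave wide per scale, and a lowpass residual,
# with the lowpass subsampled by two between scales.

fftshift2 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  m[c((h / 2 + 1):h, 1:(h / 2)), c((w / 2 + 1):w, 1:(w / 2))]
}

ifftshift2 <- fftshift2 # even sizes only: shift is its own inverse

fft2 <- function(m) stats::fft(m)
ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

# frequency grids for an even-sized h x w spectrum with DC at (h/2+1, w/2+1)
freq_grids <- function(h, w) {
  fx <- ((1:w) - (w / 2 + 1)) / (w / 2) # -1 .. <1, units of pi
  fy <- ((1:h) - (h / 2 + 1)) / (h / 2)
  rad <- sqrt(outer(fy^2, fx^2, "+"))
  rad[h / 2 + 1, w / 2 + 1] <- rad[h / 2 + 1, w / 2]
  list(log_rad = log2(rad), angle = atan2(outer(fy, rep(1, w)),
                                          outer(rep(1, h), fx)))
}

# raised-cosine radial masks; X = log2(r / pi), transition over [-1, 0]
hi_mask <- function(log_rad) cos(pi / 2 * pmin(pmax(-log_rad, 0), 1))
lo_mask <- function(log_rad) sin(pi / 2 * pmin(pmax(-log_rad, 0), 1))

# single-sided angular masks for K orientations (analytic bands)
angle_masks <- function(angle, K) {
  order <- K - 1
  const <- (2^(2 * order)) * factorial(order)^2 / (K * factorial(2 * order))
  lapply(seq_len(K), function(k) {
    th <- pi * (k - 1) / K
    da <- ((angle - th + pi) %% (2 * pi)) - pi
    2 * sqrt(const) * (cos(da)^order) * (abs(da) < pi / 2)
  })
}

# upsample by 2 in each dimension via Fourier zero-padding; exact for signals
# with no energy at or above half-Nyquist (true for all pyramid lowpass and
# band content fed through it)
expand2 <- function(im) {
  h <- nrow(im); w <- ncol(im)
  Fc <- fftshift2(fft2(im))
  big <- matrix(0 + 0i, 2 * h, 2 * w)
  big[(h / 2 + 1):(h / 2 + h), (w / 2 + 1):(w / 2 + w)] <- Fc
  out <- ifft2(ifftshift2(big)) * 4
  if (is.complex(im)) out else Re(out)
}

#' Build a complex steerable pyramid
#'
#' @param im Real matrix (even, square sizes; canonical 512 x 512).
#' @param n_scales Number of bandpass scales (default 3).
#' @param n_orientations Orientations per scale (default 3).
#' @return List with `highpass` (real matrix), `bands` (list over scales of
#'   lists of complex matrices), `bandpass` (per-scale real bandpass
#'   reconstruction at that scale's resolution), `lowpass` (real matrix).
#' @keywords internal
build_csp <- function(im, n_scales = 3, n_orientations = 3) {
  h <- nrow(im); w <- ncol(im)
  stopifnot(h %% 2^(n_scales + 1) == 0, w %% 2^(n_scales + 1) == 0)
  g <- freq_grids(h, w)
  ft <- fftshift2(fft2(im))
  hp <- Re(ifft2(ifftshift2(ft * hi_mask(g$log_rad))))
  lodft <- ft * lo_mask(g$log_rad)
  log_rad <- g$log_rad
  angle <- g$angle
  order <- n_orientations - 1
  phase_fac <- (complex(real = 0, imaginary = -1))^order
  bands <- vector("list", n_scales)
  bandpass <- vector("list", n_scales)
  for (s in seq_len(n_scales)) {
    hm <- hi_mask(log_rad + 1)
    am <- angle_masks(angle, n_orientations)
    bands[[s]] <- lapply(am, function(a) {
      ifft2(ifftshift2(lodft * hm * a * phase_fac))
    })
    bandpass[[s]] <- Re(ifft2(ifftshift2(lodft * hm^2)))
    # subsample the lowpass by two
    hh <- nrow(lodft); ww <- ncol(lodft)
    rows <- (hh / 4 + 1):(3 * hh / 4)
    cols <- (ww / 4 + 1):(3 * ww / 4)
    log_rad <- log_rad[rows, cols] + 1
    angle <- angle[rows, cols]
    lodft <- lodft[rows, cols] * lo_mask(log_rad) / 4
  }
  lowpass <- Re(ifft2(ifftshift2(lodft)))
  list(highpass = hp, bands = bands, bandpass = bandpass, lowpass = lowpass)
}

# central (2a+1) x (2a+1) window of the biased autocovariance
central_autocorr <- function(x, half_width = 3) {
  x <- x - mean(x)
  h <- nrow(x); w <- ncol(x)
  ac <- Re(ifft2(Mod(fft2(x))^2)) / (h * w)
  ac <- fftshift2(ac)
  cy <- h / 2 + 1; cx <- w / 2 + 1
  ac[(cy - half_width):(cy + half_width), (cx - half_width):(cx + half_width)]
}

# moment helpers; zero-variance inputs give 0 by convention
skew2 <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 <= 0) return(0)
  mean((x - mean(x))^3) / m2^1.5
}
kurt2 <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 <= 0) return(0)
  mean((x - mean(x))^4) / m2^2
}

phase_double <- function(z) {
  m <- Mod(z)
  zz <- z * z
  mz <- Mod(zz)
  out <- zz
  nz <- mz > 0
  out[nz] <- zz[nz] / mz[nz] * m[nz]
  out[!nz] <- 0
  out
}

ps_na <- 7L # spatial neighbourhood (7 x 7)

#' Texture-synthesis statistics of one image channel
#'
#' Computes the package's steerable-pyramid statistic set at 3 scales,
#' 3 orientations and a 7 x 7 autocorrelation neighbourhood: pixel moments,
#' highpass variance, skewness/kurtosis and central autocorrelation of the
#' partially reconstructed lowpass image at every scale, magnitude means and
#' central autocorrelations of the oriented bands, cross-orientation
#' covariances of band magnitudes and real parts within each scale, and
#' cross-scale covariances of magnitudes and real parts against phase-doubled
#' parents (with the lowpass residual and its one-pixel shifts acting as
#' parents at the coarsest scale).
#'
#' The statistics are returned in a fixed 798-slot layout in which redundant
#' entries are stored as exact zeros: the point-symmetric half of every
#' autocorrelation, the magnitude cross-orientation diagonal (an exact
#' duplicate of the magnitude autocorrelation centre), the lower triangles of
#' symmetric covariance blocks, and slots for parents that do not exist.
#' Exactly 447 slots per channel are generically non-zero.
#'
#' @param im Real matrix in \[0, 1\] (canonical 512 x 512).
#' @param n_scales,n_orientations Pyramid configuration (defaults 3, 3).
#' @return Numeric vector of length 798.
#' @keywords internal
ps_stats <- function(im, n_scales = 3, n_orientations = 3) {
  N <- n_scales; K <- n_orientations
  a <- ps_na; half <- (a - 1) / 2
  pyr <- build_csp(im, N, K)

  pixel <- c(mean(im), mean((im - mean(im))^2), skew2(im), kurt2(im),
             min(im), max(im))
  var_hp <- mean((pyr$highpass - mean(pyr$highpass))^2)

  # partial reconstructions, coarse to fine: lowpass, then +bandpass per scale
  recon <- vector("list", N + 1)
  recon[[N + 1]] <- pyr$lowpass
  for (s in N:1) {
    recon[[s]] <- expand2(recon[[s + 1]]) + pyr$bandpass[[s]]
  }
  skew_rec <- vapply(recon, skew2, numeric(1))
  kurt_rec <- vapply(recon, kurt2, numeric(1))
  acr <- lapply(recon, central_autocorr, half_width = half)

  mags <- lapply(pyr$bands, function(bs) lapply(bs, Mod))
  mag_means <- c(mean(abs(pyr$highpass)),
                 unlist(lapply(mags, vapply, mean, numeric(1))),
                 mean(abs(pyr$lowpass)))
  cmags <- lapply(mags, function(ms) lapply(ms, function(m) m - mean(m)))
  acm <- lapply(cmags, function(ms) lapply(ms, central_autocorr, half_width = half))

  # within-scale covariances
  cousin_mag <- vector("list", N)
  cousin_real <- vector("list", N)
  for (s in seq_len(N)) {
    Mm <- sapply(cmags[[s]], as.vector)
    Rr <- sapply(pyr$bands[[s]], function(b) as.vector(Re(b)))
    np <- nrow(Mm)
    cousin_mag[[s]] <- crossprod(Mm) / np
    cousin_real[[s]] <- crossprod(Rr) / np
  }

  # cross-scale covariances against phase-doubled parents
  parent_mag <- vector("list", N)
  parent_real <- vector("list", N)
  for (s in seq_len(N)) {
    if (s < N) {
      parents <- lapply(pyr$bands[[s + 1]], expand2)
      pd <- lapply(parents, phase_double)
      Pm <- sapply(parents, function(p) {
        m <- Mod(p); as.vector(m - mean(m))
      })
      Mm <- sapply(cmags[[s]], as.vector)
      np <- nrow(Mm)
      parent_mag[[s]] <- crossprod(Mm, Pm) / np
      Pr <- cbind(sapply(pd, function(p) as.vector(Re(p))),
                  sapply(pd, function(p) as.vector(Im(p))))
      Rr <- sapply(pyr$bands[[s]], function(b) as.vector(Re(b)))
      parent_real[[s]] <- crossprod(Rr, Pr) / np # K x 2K
    } else {
      lo <- expand2(pyr$lowpass)
      shifts <- list(
        lo,
        lo[c(2:nrow(lo), 1), ], lo[c(nrow(lo), 1:(nrow(lo) - 1)), ],
        lo[, c(2:ncol(lo), 1)], lo[, c(ncol(lo), 1:(ncol(lo) - 1))]
      )
      Pr <- sapply(shifts, as.vector)
      Rr <- sapply(pyr$bands[[s]], function(b) as.vector(Re(b)))
      np <- nrow(Rr)
      parent_real[[s]] <- crossprod(Rr, Pr) / np # K x 5
      parent_mag[[s]] <- matrix(0, K, K) # no magnitude parent at the coarsest scale
    }
  }

  ps_flatten(list(
    pixel = pixel, var_hp = var_hp, skew_rec = skew_rec, kurt_rec = kurt_rec,
    acr = acr, acm = acm, mag_means = mag_means, cousin_mag = cousin_mag,
    cousin_real = cousin_real, parent_mag = parent_mag,
    parent_real = parent_real
  ), N = N, K = K)
}

# zero out the point-symmetric redundant half of an a x a autocorrelation,
# keeping the first (a^2+1)/2 entries in column-major order
ac_unique <- function(ac) {
  v <- as.vector(ac)
  keep <- (length(v) + 1) / 2
  v[(keep + 1):length(v)] <- 0
  v
}

upper_tri_keep <- function(m, diag = TRUE) {
  m[lower.tri(m, diag = !diag)] <- 0
  m
}

ps_flatten <- function(b, N = 3, K = 3) {
  a2 <- ps_na^2
  out <- c(
    b$pixel,                                   # 6
    b$var_hp,                                  # 1
    b$skew_rec,                                # N + 1
    b$kurt_rec,                                # N + 1
    unlist(lapply(b$acr, ac_unique)),          # a2 * (N + 1)
    unlist(lapply(b$acm, function(ms) lapply(ms, ac_unique))), # a2 * N * K
    b$mag_means,                               # N * K + 2
    unlist(lapply(b$cousin_mag, function(m) {
      as.vector(upper_tri_keep(m, diag = FALSE)) # diagonal duplicates acm centre
    })),                                       # K^2 * N
    unlist(lapply(b$cousin_real, function(m) {
      as.vector(upper_tri_keep(m, diag = TRUE))
    })),                                       # K^2 * N
    unlist(lapply(b$parent_mag, as.vector)),   # K^2 * N (last slice zero)
    unlist(lapply(seq_len(N), function(s) {
      m <- matrix(0, K, 2 * K)
      pr <- b$parent_real[[s]]
      m[, seq_len(ncol(pr))] <- pr
      as.vector(m)
    }))                                        # 2K^2 * N (coarsest: K x 5 used)
  )
  unname(out)
}

#' Structural non-zero mask of the per-channel statistic layout
#'
#' Identifies the slots of the 798-entry layout of [ps_stats()] that are
#' generically non-zero: 447 per channel. A corpus-estimated mask (see
#' [texture_zero_mask()]) coincides with this on any corpus of non-degenerate
#' images.
#'
#' @param n_scales,n_orientations Pyramid configuration.
#' @return Logical vector of length 798 with 447 `TRUE` entries.
#' @export
ps_structural_mask <- function(n_scales = 3, n_orientations = 3) {
  N <- n_scales; K <- n_orientations
  a2 <- ps_na^2
  keep_ac <- c(rep(TRUE, (a2 + 1) / 2), rep(FALSE, (a2 - 1) / 2))
  ut_nodiag <- as.vector(upper.tri(matrix(0, K, K), diag = FALSE))
  ut_diag <- as.vector(upper.tri(matrix(0, K, K), diag = TRUE))
  pr_full <- rep(TRUE, 2 * K * K)
  pr_coarse <- as.vector(matrix(seq_len(2 * K * K), K, 2 * K) <= K * 5)
  c(
    rep(TRUE, 6), TRUE,
    rep(TRUE, N + 1), rep(TRUE, N + 1),
    rep(keep_ac, N + 1),
    rep(keep_ac, N * K),
    rep(TRUE, N * K + 2),
    rep(ut_nodiag, N),
    rep(ut_diag, N),
    c(rep(TRUE, K * K * (N - 1)), rep(FALSE, K * K)),
    c(rep(pr_full, N - 1), pr_coarse)
  )
}
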