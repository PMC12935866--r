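# Synthetic treadmill trials: pelvis markers + vertical GRF with a known
# phase-dependent stride-to-stride covariance of COM velocity.

# rigid marker offsets (mm) from the pelvis origin; their mean is constant,
# so averaging the five markers recovers the perturbed origin exactly
PELVIS_OFFSETS <- list(
  SACR = c(-140,    0,  10),
  LASI = c(  80,  120,   0),
  RASI = c(  80, -120,   0),
  LPSI = c(-120,   60,  30),
  RPSI = c(-120,  -60,  30)
)

#' Generate one synthetic treadmill trial
#'
#' Draws a trial from a [gait_profile()]: the pelvis origin moves so that
#' its frame-wise velocity equals the profile's mean-velocity template plus
#' stride-level correlated Gaussian perturbations whose pointwise SD equals
#' the profile's SD envelopes; the five pelvis markers are rigid offsets of
#' the origin, and the vertical GRF is a stance-shaped pulse train whose
#' rising edges are the true heel strikes.
#'
#' The stride-level noise on axis \eqn{a} within stride \eqn{s} is
#' \deqn{ e_{s,a}(u) = \mathrm{env}_a(u)\,[z^{(0)}_{s,a}\cos 2\pi u +
#'        z^{(1)}_{s,a}\sin 2\pi u ], \quad u \in [0,1), }
#' with \eqn{(z^{(0)}_s, z^{(1)}_s)} independent N(0, R) draws (R the
#' profile's inter-axis correlation).  Because
#' \eqn{\cos^2 + \sin^2 = 1}, the pointwise stride-to-stride SD equals the
#' envelope at every cycle instant while the perturbation stays smooth
#' within a stride.
#'
#' A trial with `n_strides` complete gait cycles carries `n_strides + 1`
#' heel strikes (and GRF pulses); roughly one extra stride of lead-in and
#' tail is simulated around them so filtering transients never touch the
#' analyzed cycles.
#'
#' @param profile a [gait_profile()].
#' @param n_strides number of complete gait cycles to simulate (>= 2).
#' @param seed integer RNG seed; identical calls are bit-identical.
#' @return an object of class `synthetic_trial` with elements
#'   `markers` (a `marker_series`), `vgrf` (a `force_signal`),
#'   `truth` (profile, true heel-strike indices, realized noise draws) and
#'   `seed`.
#' @export
generate_trial <- function(profile, n_strides = 90, seed = 1) {
  stopifnot(inherits(profile, "gait_profile"))
  if (n_strides < 2) stop("n_strides must be at least 2")
  rate <- profile$rate
  fps <- round(profile$stride_period * rate)   # frames per stride
  if (fps < 8) stop("invalid profile: stride_period too short for the sampling rate")
  dt <- 1 / rate

  pad0 <- fps                                   # one stride of lead-in
  pad1 <- fps                                   # one stride of tail
  n_frames <- pad0 + n_strides * fps + pad1 + 1
  i <- seq_len(n_frames)
  phi <- (i - 1 - pad0) / fps                   # global cycle phase, HS at integers
  k <- floor(phi)                               # stride index (-1 .. n_strides+1)
  u <- phi - k                                  # within-stride phase

  tpl <- template_fun(profile$template)
  env <- envelope_fun(profile$sd_envelope)

  set.seed(seed)
  n_noise <- n_strides + 3                      # strides -1 .. n_strides+1
  L <- t(chol(profile$inter_axis_correlation + diag(1e-12, 3)))
  Z0 <- t(L %*% matrix(stats::rnorm(3 * n_noise), 3, n_noise))
  Z1 <- t(L %*% matrix(stats::rnorm(3 * n_noise), 3, n_noise))

  row <- k + 2                                  # map stride index to draw row
  Ev <- env(u)
  noise <- Ev * (Z0[row, , drop = FALSE] * cos(2 * pi * u) +
                 Z1[row, , drop = FALSE] * sin(2 * pi * u))
  v <- tpl(u) + noise                           # COM velocity, mm/s

  # integrate (trapezoid) to pelvis-origin position
  p <- apply(v, 2, function(col) cumsum(c(0, (col[-1] + col[-length(col)]) / 2 * dt)))
  p <- sweep(p, 2, c(0, 0, 950), "+")
  colnames(p) <- GT_AXES

  positions <- lapply(PELVIS_OFFSETS, function(off) sweep(p, 2, off, "+"))
  markers <- marker_series(rate = rate, positions = positions)

  # stance-shaped GRF pulses starting exactly at each heel strike
  events <- pad0 + (0:n_strides) * fps + 1
  stance_len <- round(profile$stance_fraction * fps)
  fz <- numeric(n_frames)
  us <- (seq_len(stance_len) - 1) / stance_len
  pulse <- profile$body_weight * (0.06 + 1.0 * sin(pi * us))
  for (e in events) fz[e + seq_len(stance_len) - 1] <- pulse
  vgrf <- force_signal(rate = rate, fz = fz)

  structure(list(
    markers = markers,
    vgrf = vgrf,
    truth = list(profile = profile, events = events, fps = fps,
                 Z0 = Z0, Z1 = Z1, pad0 = pad0),
    seed = seed
  ), class = "synthetic_trial")
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf("<synthetic_trial '%s'> %d frames @ %g Hz, %d heel strikes, seed %d\n",
              x$truth$profile$name, nrow(x$markers$positions[[1]]),
              x$markers$rate, length(x$truth$events), x$seed))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Draws `n_subjects` independent trials from one profile.  Per-subject
#' seeds are derived deterministically from the cohort seed, and each
#' subject's SD envelopes are jittered by independent multiplicative
#' factors `1 + cv * N(0,1)` per axis (truncated below at 0.05), where `cv`
#' is the profile's `subject_heterogeneity_cv`.
#'
#' @param profile a [gait_profile()].
#' @param n_subjects number of subjects (>= 1).
#' @param n_strides complete gait cycles per subject.
#' @param seed cohort RNG seed.
#' @return list of `synthetic_trial` objects (one per subject).
#' @export
generate_cohort <- function(profile, n_subjects, n_strides = 90, seed = 1) {
  stopifnot(inherits(profile, "gait_profile"), n_subjects >= 1)
  set.seed(seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  cv <- profile$subject_heterogeneity_cv
  jitter <- matrix(pmax(0.05, 1 + cv * stats::rnorm(3 * n_subjects)),
                   n_subjects, 3)
  lapply(seq_len(n_subjects), function(s) {
    prof_s <- profile
    prof_s$sd_envelope <- sweep(profile$sd_envelope, 2, jitter[s, ], "*")
    trial <- generate_trial(prof_s, n_strides = n_strides,
                            seed = subject_seeds[s])
    trial$truth$subject <- s
    trial$truth$envelope_jitter <- jitter[s, ]
    trial
  })
}
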