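#' @keywords internal
"_PACKAGE"

# Canonical axis order used throughout: x = AP (+forward), y = ML (+left),
# z = VT (+up).  All positions are mm, velocities mm/s, forces N, times s.
GT_AXES <- c("ap", "ml", "vt")

#' Gait profile: the statistical truth a synthetic trial is drawn from
#'
#' A gait profile bundles everything the synthetic generator needs to draw
#' treadmill trials with a known, phase-dependent stride-to-stride
#' covariance structure of center-of-mass (COM) velocity: per-axis periodic
#' mean-velocity templates, per-axis non-negative SD envelopes over the gait
#' cycle, an inter-axis correlation matrix for the stride-level noise, and
#' timing/anthropometric constants.
#'
#' Templates and envelopes are sampled on an evenly spaced grid covering
#' 0--100\% of the gait cycle (first and last rows describe the same cycle
#' instant, so template first and last rows must match).  Between grid
#' points the template is interpolated with a periodic cubic spline and the
#' envelope with periodic linear interpolation (which preserves
#' non-negativity for sharp-edged envelopes).
#'
#' @param stride_period stride duration in seconds (> 0).
#' @param belt_speed treadmill belt speed in m/s; metadata only, the AP
#'   velocity template is expressed in the lab frame about zero mean.
#' @param stance_fraction fraction of the stride spent in stance, in (0,1);
#'   shapes the synthetic vertical ground-reaction-force pulse.
#' @param rate sampling rate in Hz for both markers and GRF.
#' @param template numeric matrix (grid x 3, columns AP/ML/VT) of mean COM
#'   velocity in mm/s over one cycle; must be cycle-periodic.
#' @param sd_envelope numeric matrix (grid x 3) of stride-to-stride SD in
#'   mm/s over the cycle; non-negative.
#' @param inter_axis_correlation 3x3 correlation matrix for the stride-level
#'   noise amplitudes (symmetric, unit diagonal, positive semidefinite).
#' @param subject_heterogeneity_cv coefficient of variation of the
#'   multiplicative per-subject, per-axis envelope jitter used by
#'   [generate_cohort()].
#' @param body_weight body weight in N (GRF pulse amplitude).
#' @param name short label carried through outputs.
#' @return an object of class `gait_profile`.
#' @seealso [preset_profile()], [generate_trial()], [generate_cohort()]
#' @export
gait_profile <- function(stride_period, belt_speed, stance_fraction,
                         rate = 60, template, sd_envelope,
                         inter_axis_correlation = diag(3),
                         subject_heterogeneity_cv = 0,
                         body_weight = 820, name = "custom") {
  if (!is.numeric(stride_period) || length(stride_period) != 1 ||
      !is.finite(stride_period) || stride_period <= 0) {
    stop("invalid profile: stride_period must be a positive number")
  }
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) || rate <= 0) {
    stop("invalid profile: rate must be a positive number")
  }
  if (!is.numeric(stance_fraction) || length(stance_fraction) != 1 ||
      stance_fraction <= 0 || stance_fraction >= 1) {
    stop("invalid profile: stance_fraction must lie in (0, 1)")
  }
  template <- as.matrix(template)
  sd_envelope <- as.matrix(sd_envelope)
  if (ncol(template) != 3 || ncol(sd_envelope) != 3) {
    stop("template and sd_envelope must have 3 columns (AP, ML, VT)")
  }
  if (nrow(template) < 5 || nrow(sd_envelope) < 5) {
    stop("template and sd_envelope need at least 5 grid rows")
  }
  scale <- max(abs(template), 1)
  if (any(abs(template[1, ] - template[nrow(template), ]) > 1e-6 * scale)) {
    stop("template must be cycle-periodic (first row equal to last row)")
  }
  template[nrow(template), ] <- template[1, ]   # snap away rounding noise
  if (any(sd_envelope < 0)) stop("sd_envelope must be non-negative everywhere")
  R <- as.matrix(inter_axis_correlation)
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-8)) ||
      any(abs(diag(R) - 1) > 1e-8)) {
    stop("inter_axis_correlation must be symmetric with unit diagonal")
  }
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("inter_axis_correlation must be positive semidefinite")
  }
  colnames(template) <- colnames(sd_envelope) <- GT_AXES
  structure(list(
    stride_period = stride_period,
    belt_speed = belt_speed,
    stance_fraction = stance_fraction,
    rate = rate,
    template = template,
    sd_envelope = sd_envelope,
    inter_axis_correlation = R,
    subject_heterogeneity_cv = subject_heterogeneity_cv,
    body_weight = body_weight,
    name = name
  ), class = "gait_profile")
}

#' @export
print.gait_profile <- function(x, ...) {
  cat(sprintf("<gait_profile '%s'>\n", x$name))
  cat(sprintf("  stride period %.3f s, rate %g Hz, stance fraction %.2f\n",
              x$stride_period, x$rate, x$stance_fraction))
  m <- colMeans(x$sd_envelope[-nrow(x$sd_envelope), , drop = FALSE])
  cat(sprintf("  cycle-mean SD envelopes (AP/ML/VT): %.2f / %.2f / %.2f mm/s\n",
              m[1], m[2], m[3]))
  invisible(x)
}

# circular (wrap-around) Gaussian bump on the unit cycle
circ_bump <- function(phi, center, width) {
  d <- abs(phi - center)
  d <- pmin(d, 1 - d)
  exp(-0.5 * (d / width)^2)
}

# scale a positive shape so its cycle mean (excluding the duplicated
# endpoint) equals `target`
scale_to_mean <- function(shape, target) {
  shape * target / mean(shape[-length(shape)])
}

#' Preset cohort profiles
#'
#' Two ready-made profiles emulating the statistical contrast between an
#' older healthy control cohort and a peripheral-artery-disease (PAD)
#' cohort: the control preset carries large vertical (VT) stride-to-stride
#' COM-velocity variability (cycle-mean SD 93.60 mm/s) whereas the PAD
#' preset's VT variability is suppressed (40.29 mm/s); AP and ML cycle-mean
#' SDs are 75.07/51.58 mm/s (control) and 49.99/39.70 mm/s (PAD).  All SD
#' envelopes are phase-dependent, with the VT envelope peaking near 15\% of
#' the cycle (weight acceptance), so the largest group difference falls in
#' the 10--20\% window.
#'
#' @param name `"control"` or `"pad"`.
#' @param grid number of cycle grid points for templates and envelopes.
#' @return a [gait_profile()].
#' @export
preset_profile <- function(name = c("control", "pad"), grid = 101) {
  name <- match.arg(name)
  phi <- seq(0, 1, length.out = grid)
  # mean-velocity templates: VT two-lobed, AP biphasic about zero (lab
  # frame), ML one-lobed alternating; phase offsets keep the 3D loop
  # non-planar so Frenet frames are well defined
  template <- cbind(
    ap = 120 * sin(4 * pi * phi + 0.40),
    ml = 70 * sin(2 * pi * phi + 0.30),
    vt = 160 * sin(4 * pi * phi - 0.80)
  )
  if (name == "control") {
    env <- cbind(
      ap = scale_to_mean(1 + 0.35 * circ_bump(phi, 0.15, 0.10), 75.07),
      ml = scale_to_mean(1 + 0.25 * circ_bump(phi, 0.50, 0.12), 51.58),
      vt = scale_to_mean(1 + 0.90 * circ_bump(phi, 0.15, 0.08), 93.60)
    )
    gait_profile(stride_period = 1.20, belt_speed = 0.68,
                 stance_fraction = 0.62, rate = 60,
                 template = template, sd_envelope = env,
                 subject_heterogeneity_cv = 0.15,
                 body_weight = 820, name = "control")
  } else {
    env <- cbind(
      ap = scale_to_mean(1 + 0.20 * circ_bump(phi, 0.15, 0.10), 49.99),
      ml = scale_to_mean(1 + 0.15 * circ_bump(phi, 0.50, 0.12), 39.70),
      vt = scale_to_mean(1 + 0.25 * circ_bump(phi, 0.15, 0.08), 40.29)
    )
    gait_profile(stride_period = 1.30, belt_speed = 0.56,
                 stance_fraction = 0.62, rate = 60,
                 template = template, sd_envelope = env,
                 subject_heterogeneity_cv = 0.15,
                 body_weight = 870, name = "pad")
  }
}

# periodic evaluation helpers -------------------------------------------------

# periodic cubic-spline evaluator for a cycle-periodic waveform matrix
template_fun <- function(mat) {
  grid <- seq(0, 1, length.out = nrow(mat))
  funs <- lapply(seq_len(ncol(mat)), function(a) {
    stats::splinefun(grid, mat[, a], method = "periodic")
  })
  function(phi) {
    u <- phi %% 1
    out <- vapply(funs, function(f) f(u), numeric(length(phi)))
    if (!is.matrix(out)) out <- matrix(out, nrow = length(phi))
    out
  }
}

# periodic linear evaluator (preserves non-negativity of envelopes)
envelope_fun <- function(mat) {
  grid <- seq(0, 1, length.out = nrow(mat))
  function(phi) {
    u <- phi %% 1
    out <- vapply(seq_len(ncol(mat)), function(a) {
      stats::approx(grid, mat[, a], xout = u, rule = 2)$y
    }, numeric(length(phi)))
    if (!is.matrix(out)) out <- matrix(out, nrow = length(phi))
    pmax(out, 0)
  }
}
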