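# Gait-tube core: phase-dependent covariance of stride-to-stride COM
# velocity, variability ellipsoids and volumes, cycle-averaged summaries.

# determinant of a symmetric 3x3 by cofactor expansion (kept local so the
# volume path does not depend on base det(), which tests use as an oracle)
det3 <- function(S) {
  S[1, 1] * (S[2, 2] * S[3, 3] - S[2, 3] * S[3, 2]) -
  S[1, 2] * (S[2, 1] * S[3, 3] - S[2, 3] * S[3, 1]) +
  S[1, 3] * (S[2, 1] * S[3, 2] - S[2, 2] * S[3, 1])
}

#' Phase-wise covariance of stride-to-stride COM velocity
#'
#' At every normalized time point, the unbiased (S-1 denominator) sample
#' covariance of the S stride velocity vectors across the three anatomical
#' directions (AP, ML, VT) is computed, yielding a T-long series of 3x3
#' covariance matrices in mm^2/s^2.
#'
#' @param strides a `stride_set` with S >= 2 strides.
#' @return object of class `covariance_series`: `Sigma` is a 3 x 3 x T
#'   array, `n_strides` the stride count.
#' @export
stride_covariance <- function(strides) {
  stopifnot(inherits(strides, "stride_set"))
  v <- strides$values
  S <- dim(v)[1]; T <- dim(v)[2]
  if (S < 2) stop("need at least 2 strides for a covariance")
  centered <- lapply(1:3, function(a) {
    m <- v[, , a, drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = S)
    m - rep(colMeans(m), each = S)
  })
  Sigma <- array(0, dim = c(3, 3, T), dimnames = list(GT_AXES, GT_AXES, NULL))
  for (a in 1:3) for (b in a:3) {
    cab <- colSums(centered[[a]] * centered[[b]]) / (S - 1)
    Sigma[a, b, ] <- cab
    Sigma[b, a, ] <- cab
  }
  structure(list(Sigma = Sigma, n_strides = S), class = "covariance_series")
}

#' Variability ellipsoid of one covariance matrix
#'
#' Eigendecomposition of a symmetric positive-semidefinite 3x3 covariance:
#' semi-axis i equals \eqn{k\sqrt{\lambda_i}} (descending), the orientation
#' matrix holds the eigenvectors (right-handed), and the volume is
#' \eqn{(4/3)\pi k^3 \sqrt{\det\Sigma}}.
#'
#' @param Sigma symmetric PSD 3x3 matrix (mm^2/s^2).
#' @param k SD-scaling constant (k = 1: one-SD ellipsoid).
#' @param tol relative tolerance for symmetry / negative-eigenvalue clamping.
#' @return list with `semi_axes` (mm/s, descending), `orientation`
#'   (3x3, columns = eigenvectors, det +1), `volume` (mm^3/s^3) and `k`.
#' @export
ellipsoid_from_covariance <- function(Sigma, k = 1, tol = 1e-8) {
  Sigma <- as.matrix(Sigma)
  scale <- max(abs(Sigma), .Machine$double.eps)
  if (max(abs(Sigma - t(Sigma))) > tol * scale) {
    stop("Sigma must be symmetric")
  }
  e <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  lam <- e$values
  if (any(lam < -tol * scale)) stop("Sigma must be positive semidefinite")
  lam <- pmax(lam, 0)
  Q <- e$vectors
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  semi <- k * sqrt(lam)
  list(semi_axes = semi, orientation = Q,
       volume = 4 / 3 * pi * prod(semi), k = k)
}

#' Ellipsoid series over the gait cycle
#'
#' Applies [ellipsoid_from_covariance()] at every normalized time point of
#' a covariance series (or computes the series from a `stride_set` first).
#'
#' @param x a `covariance_series` or `stride_set`.
#' @param k SD-scaling constant.
#' @return object of class `ellipsoid_series` with `semi_axes` (T x 3,
#'   descending per point), `orientations` (3 x 3 x T), `volume` (length T,
#'   mm^3/s^3) and `k`.
#' @export
ellipsoid_series <- function(x, k = 1) {
  cs <- if (inherits(x, "stride_set")) stride_covariance(x) else x
  stopifnot(inherits(cs, "covariance_series"))
  T <- dim(cs$Sigma)[3]
  semi <- matrix(0, T, 3)
  ori <- array(0, dim = c(3, 3, T))
  vol <- numeric(T)
  for (t in seq_len(T)) {
    el <- ellipsoid_from_covariance(cs$Sigma[, , t], k = k)
    semi[t, ] <- el$semi_axes
    ori[, , t] <- el$orientation
    vol[t] <- el$volume
  }
  structure(list(semi_axes = semi, orientations = ori, volume = vol, k = k),
            class = "ellipsoid_series")
}

#' Ellipsoid-volume waveform
#'
#' Fast path for the T-long volume waveform
#' \eqn{V_t = (4/3)\pi k^3\sqrt{\det\Sigma_t}} without the full
#' eigendecomposition.
#'
#' @param x a `covariance_series` or `stride_set`.
#' @param k SD-scaling constant.
#' @return numeric vector of length T (mm^3/s^3).
#' @export
volume_waveform <- function(x, k = 1) {
  cs <- if (inherits(x, "stride_set")) stride_covariance(x) else x
  stopifnot(inherits(cs, "covariance_series"))
  T <- dim(cs$Sigma)[3]
  vapply(seq_len(T), function(t) {
    d <- det3(cs$Sigma[, , t])
    4 / 3 * pi * k^3 * sqrt(max(d, 0))
  }, numeric(1))
}

#' Direction-specific variability waveforms
#'
#' Pointwise stride-to-stride SD per anatomical axis: the square roots of
#' the diagonal of the phase-wise covariance.
#'
#' @param strides a `stride_set`.
#' @return T x 3 matrix of SDs (mm/s), columns AP/ML/VT.
#' @export
directional_variability <- function(strides) {
  cs <- stride_covariance(strides)
  out <- t(apply(cs$Sigma, 3, diag))
  colnames(out) <- GT_AXES
  sqrt(out)
}

#' Cycle-averaged subject summary
#'
#' Cycle means of the ellipsoid-volume waveform and of the three
#' directional SD waveforms, plus the total variability (the sum of the
#' three cycle-mean directional SDs).
#'
#' @param strides a `stride_set`.
#' @param k SD-scaling constant for the ellipsoid volume.
#' @return object of class `subject_summary` with fields
#'   `mean_ellipsoid_volume` (mm^3/s^3), `var_ap`, `var_ml`, `var_vt`,
#'   `total_variability` (mm/s) and `volume_waveform` (length T).
#' @export
subject_summary <- function(strides, k = 1) {
  vw <- volume_waveform(strides, k = k)
  dv <- directional_variability(strides)
  m <- colMeans(dv)
  structure(list(
    mean_ellipsoid_volume = mean(vw),
    var_ap = m[["ap"]], var_ml = m[["ml"]], var_vt = m[["vt"]],
    total_variability = sum(m),
    volume_waveform = vw,
    n_strides = dim(strides$values)[1]
  ), class = "subject_summary")
}

#' @export
print.subject_summary <- function(x, ...) {
  cat(sprintf(paste0("<subject_summary> volume %.3g mm^3/s^3 | SD AP %.2f ",
                     "ML %.2f VT %.2f | total %.2f mm/s (%d strides)\n"),
              x$mean_ellipsoid_volume, x$var_ap, x$var_ml, x$var_vt,
              x$total_variability, x$n_strides))
  invisible(x)
}

#' Circular moving-average smoothing over the gait cycle
#'
#' Centered moving average with cycle-periodic (circular) boundary
#' handling.  The window is expressed in percent of the gait cycle and
#' converted to an odd number of points; a window of 0 is the identity.
#'
#' @param x numeric vector or matrix (T rows; columns smoothed separately).
#' @param window window width in percent of the cycle (0--100).
#' @return smoothed series, same shape.
#' @export
smooth_waveform <- function(x, window) {
  if (window < 0 || window > 100) stop("window must lie in [0, 100] percent")
  n <- if (is.matrix(x)) nrow(x) else length(x)
  npts <- round(window / 100 * (n - 1))
  if (npts %% 2 == 0) npts <- npts + 1
  if (window == 0 || npts <= 1) return(x)
  sm <- stats::filter(x, rep(1 / npts, npts), method = "convolution",
                      sides = 2, circular = TRUE)
  if (is.matrix(x)) {
    out <- matrix(as.numeric(sm), nrow = n)
    dimnames(out) <- dimnames(x)
    out
  } else {
    as.numeric(sm)
  }
}

#' Project a covariance onto a Frenet cross-sectional plane
#'
#' The marginal covariance in the plane spanned by the normal and binormal
#' is \eqn{P\Sigma P^\top} with P the 2x3 matrix of (normal, binormal)
#' rows; the cross-sectional ellipse comes from its eigendecomposition with
#' the same k-scaling as the 3D ellipsoid.
#'
#' @param Sigma symmetric PSD 3x3 covariance (mm^2/s^2).
#' @param frame list with unit vectors `tangent`, `normal`, `binormal`
#'   (orthonormal to 1e-6).
#' @param k SD-scaling constant.
#' @return list with `semi_axes` (length 2, descending, mm/s), `angle`
#'   (radians of the major axis from the normal direction), `area`
#'   (mm^2/s^2 scaled by k^2) and `cov2` (the 2x2 marginal covariance).
#' @export
project_covariance_to_plane <- function(Sigma, frame, k = 1) {
  B <- cbind(frame$tangent, frame$normal, frame$binormal)
  if (max(abs(crossprod(B) - diag(3))) > 1e-6) {
    stop("frame must be orthonormal")
  }
  P <- rbind(frame$normal, frame$binormal)
  C2 <- P %*% as.matrix(Sigma) %*% t(P)
  C2 <- (C2 + t(C2)) / 2
  e <- eigen(C2, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  semi <- k * sqrt(lam)
  list(semi_axes = semi,
       angle = atan2(e$vectors[2, 1], e$vectors[1, 1]),
       area = pi * prod(semi),
       cov2 = C2)
}

#' Assemble the gait tube
#'
#' The gait tube is the mean COM-velocity trajectory over the cycle
#' together with smoothed cross-sectional variability ellipses in the local
#' Frenet (normal-binormal) planes.  Ellipsoids are computed from the
#' unsmoothed phase-wise covariance; smoothing (circular moving average) is
#' applied afterwards, to the projected 2x2 covariances and to the mean
#' trajectory used for frame construction, purely as a visualization layer.
#'
#' @param strides a `stride_set`.
#' @param k SD-scaling constant.
#' @param window smoothing window, percent of cycle.
#' @return object of class `gait_tube` with `mean_trajectory` (T x 3,
#'   mm/s), `frames` (a `frenet_frames` object), `cross_sections`
#'   (data.frame: `t_pct`, `semi_major`, `semi_minor`, `angle`, `area`),
#'   `smoothing_window` and `k`.
#' @export
build_gait_tube <- function(strides, k = 1, window = 5) {
  stopifnot(inherits(strides, "stride_set"))
  mean_traj <- apply(strides$values, c(2, 3), mean)
  colnames(mean_traj) <- GT_AXES
  cs <- stride_covariance(strides)
  gait_tube_from_parts(mean_traj, cs$Sigma, k = k, window = window)
}

# shared tube assembly for subject-level and group-level tubes
gait_tube_from_parts <- function(mean_traj, Sigma, k = 1, window = 5) {
  T <- nrow(mean_traj)
  smooth_traj <- smooth_waveform(mean_traj, window)
  frames <- frenet_frames(smooth_traj, closed = TRUE)
  # project, then smooth the planar covariance entries circularly
  # (averages of PSD matrices stay PSD, so areas remain non-negative)
  ents <- matrix(0, T, 3)   # c11, c22, c12
  for (t in seq_len(T)) {
    P <- rbind(frames$normal[t, ], frames$binormal[t, ])
    C2 <- P %*% Sigma[, , t] %*% t(P)
    ents[t, ] <- c(C2[1, 1], C2[2, 2], (C2[1, 2] + C2[2, 1]) / 2)
  }
  ents <- smooth_waveform(ents, window)
  cross <- data.frame(t_pct = seq(0, 100, length.out = T),
                      semi_major = 0, semi_minor = 0, angle = 0, area = 0)
  for (t in seq_len(T)) {
    C2 <- matrix(c(ents[t, 1], ents[t, 3], ents[t, 3], ents[t, 2]), 2, 2)
    e <- eigen(C2, symmetric = TRUE)
    lam <- pmax(e$values, 0)
    semi <- k * sqrt(lam)
    cross$semi_major[t] <- semi[1]
    cross$semi_minor[t] <- semi[2]
    cross$angle[t] <- atan2(e$vectors[2, 1], e$vectors[1, 1])
    cross$area[t] <- pi * prod(semi)
  }
  structure(list(mean_trajectory = mean_traj, frames = frames,
                 cross_sections = cross, smoothing_window = window, k = k),
            class = "gait_tube")
}

#' @export
print.gait_tube <- function(x, ...) {
  cat(sprintf("<gait_tube> T = %d, k = %g, smoothing window %g%%, mean cross-section area %.3g\n",
              nrow(x$mean_trajectory), x$k, x$smoothing_window,
              mean(x$cross_sections$area)))
  invisible(x)
}

#' Point-wise group mean and SD of subject waveforms
#'
#' @param waveforms list of equal-length numeric vectors (or equal-sized
#'   matrices) -- one per subject.
#' @return list with `mean` and `sd`, each shaped like one input element.
#' @export
group_mean_waveforms <- function(waveforms) {
  if (length(waveforms) < 1) stop("need at least 1 subject")
  dims <- lapply(waveforms, function(w) if (is.matrix(w)) dim(w) else length(w))
  if (length(unique(dims)) != 1) stop("all subject waveforms must share dimensions")
  if (length(waveforms) == 1) {
    w <- waveforms[[1]]
    return(list(mean = w, sd = if (is.matrix(w)) array(0, dim(w)) else rep(0, length(w))))
  }
  arr <- simplify2array(waveforms)
  nd <- length(dim(arr))
  if (nd == 2) {
    list(mean = rowMeans(arr),
         sd = apply(arr, 1, stats::sd))
  } else {
    list(mean = apply(arr, c(1, 2), mean),
         sd = apply(arr, c(1, 2), stats::sd))
  }
}
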