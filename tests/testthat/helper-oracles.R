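# Independent oracles and fixture builders used across the suite.
# Oracles deliberately avoid the code paths they check.

# exact two-sided Mann-Whitney p by full enumeration of all group splits
# of the pooled sample (distinct values assumed)
oracle_rank_sum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  splits <- utils::combn(n, n1)
  u_of <- function(xi) {
    xs <- pooled[xi]; ys <- pooled[-xi]
    sum(outer(xs, ys, ">"))
  }
  u_null <- apply(splits, 2, u_of)
  u_obs <- u_of(seq_len(n1))
  mn <- n1 * (n - n1)
  p <- if (u_obs > mn / 2) 2 * mean(u_null >= u_obs) else 2 * mean(u_null <= u_obs)
  min(p, 1)
}

# random symmetric positive-definite 3x3 matrix (conditioning bounded so
# comparisons against reference routines are not dominated by round-off)
random_spd3 <- function() {
  A <- matrix(stats::rnorm(9), 3, 3)
  A %*% t(A) + diag(0.05, 3)
}

# random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation3 <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# stride_set built directly from an S x T x 3 array (bypasses the signal
# chain; used for tests of the covariance/ellipsoid layer alone)
make_stride_set <- function(values, rate = 60) {
  dimnames(values) <- list(NULL, NULL, c("ap", "ml", "vt"))
  structure(list(values = values, T = dim(values)[2], rate = rate,
                 stride_times = seq_len(dim(values)[1])),
            class = "stride_set",
            dropped = data.frame(cycle = integer(0), duration = numeric(0),
                                 reason = character(0)))
}

# rotate every stride velocity vector of a stride_set by R
rotate_stride_set <- function(strides, R) {
  v <- strides$values
  d <- dim(v)
  flat <- matrix(aperm(v, c(1, 2, 3)), nrow = d[1] * d[2], ncol = 3)
  rot <- flat %*% t(R)
  strides$values <- array(rot, dim = d, dimnames = dimnames(v))
  strides
}

# profile with all SD envelopes set to zero (deterministic template gait)
zero_noise_profile <- function(base = preset_profile("control")) {
  base$sd_envelope[] <- 0
  base
}

# control-like profile with a chosen constant VT envelope except inside a
# cycle window [lo, hi] where it is raised to sd_in; AP/ML constant
windowed_vt_profile <- function(sd_out = 40, sd_in = 150, lo = 0.10, hi = 0.31,
                                sd_apml = 45) {
  base <- preset_profile("control")
  grid <- seq(0, 1, length.out = nrow(base$sd_envelope))
  env <- cbind(ap = rep(sd_apml, length(grid)),
               ml = rep(sd_apml, length(grid)),
               vt = ifelse(grid >= lo & grid <= hi, sd_in, sd_out))
  base$sd_envelope <- env
  base$subject_heterogeneity_cv <- 0
  base
}

# smooth random gait-like waveforms (subjects x T): low-order Fourier
# series with iid N(0,1) coefficients
random_smooth_waveforms <- function(n_subjects, T = 101, n_harmonics = 3) {
  tt <- seq(0, 1, length.out = T)
  B <- cbind(1, do.call(cbind, lapply(seq_len(n_harmonics), function(h) {
    cbind(cos(2 * pi * h * tt), sin(2 * pi * h * tt))
  })))
  Z <- matrix(stats::rnorm(n_subjects * ncol(B)), n_subjects)
  Z %*% t(B)
}

# minimal spm_result skeleton for phase-aggregation tests
fake_spm_result <- function(clusters) {
  structure(list(t_waveform = rep(0, 101), critical_threshold = 3,
                 clusters = clusters, per_phase = NULL,
                 n_permutations = 1000, enumerated = FALSE,
                 alpha = 0.05, seed = NULL),
            class = "spm_result")
}
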