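# Gait-tube core: covariance, ellipsoids, summaries, smoothing, tube.

test_that("phase-wise covariance matches hand-computable cases", {
  # identical strides: zero covariance everywhere
  v <- array(rep(c(1, 2, 3), each = 12), dim = c(4, 3, 3))
  cs <- stride_covariance(make_stride_set(v))
  expect_equal(max(abs(cs$Sigma)), 0)

  # two strides +v / -v at a point: covariance 2 v v^T
  vec <- c(3, -1, 2)
  v <- array(0, dim = c(2, 5, 3))
  v[1, 3, ] <- vec; v[2, 3, ] <- -vec
  cs <- stride_covariance(make_stride_set(v))
  expect_equal(cs$Sigma[, , 3], 2 * outer(vec, vec),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(stride_covariance(make_stride_set(v[1, , , drop = FALSE])),
               "2 strides")
})

test_that("covariance of isotropic noise converges to sigma^2 I", {
  set.seed(10)
  S <- 5000
  v <- array(rnorm(S * 4 * 3, sd = 10), dim = c(S, 4, 3))
  cs <- stride_covariance(make_stride_set(v))
  se_var <- 100 * sqrt(2 / (S - 1))
  se_cov <- 100 / sqrt(S)
  for (t in 1:4) {
    expect_true(all(abs(diag(cs$Sigma[, , t]) - 100) < 3 * se_var))
    off <- cs$Sigma[, , t][upper.tri(diag(3))]
    expect_true(all(abs(off) < 3 * se_cov))
  }
})

test_that("ellipsoid geometry: unit sphere, diagonal case, and symmetry guard", {
  el <- ellipsoid_from_covariance(diag(3), k = 1)
  expect_equal(el$semi_axes, c(1, 1, 1))
  expect_equal(el$volume, 4 * pi / 3, tolerance = 1e-12)

  el <- ellipsoid_from_covariance(diag(c(4, 9, 16)), k = 1)
  expect_equal(el$semi_axes, c(4, 3, 2))
  expect_equal(el$volume, 32 * pi, tolerance = 1e-12)
  expect_equal(det(el$orientation), 1, tolerance = 1e-12)

  expect_error(ellipsoid_from_covariance(matrix(c(1, 2, 0, 0, 1, 0, 0, 0, 1), 3)),
               "symmetric")
  expect_error(ellipsoid_from_covariance(diag(c(1, 1, -1))), "semidefinite")
})

test_that("directional SDs are the square roots of the covariance diagonal", {
  set.seed(2)
  v <- array(rnorm(40 * 7 * 3), dim = c(40, 7, 3))
  st <- make_stride_set(v)
  dv <- directional_variability(st)
  cs <- stride_covariance(st)
  for (t in 1:7) {
    expect_equal(unname(dv[t, ]), unname(sqrt(diag(cs$Sigma[, , t]))),
                 tolerance = 1e-12)
  }
  # axis-permutation equivariance
  perm <- c(3, 1, 2)
  dv_p <- directional_variability(make_stride_set(v[, , perm]))
  expect_equal(unname(dv_p), unname(dv[, perm]), tolerance = 1e-12)
})

test_that("subject summary sums directional means into total variability", {
  set.seed(3)
  v <- array(rnorm(30 * 11 * 3), dim = c(30, 11, 3))
  ss <- subject_summary(make_stride_set(v))
  expect_equal(ss$total_variability, ss$var_ap + ss$var_ml + ss$var_vt,
               tolerance = 1e-12)
  expect_equal(ss$mean_ellipsoid_volume, mean(ss$volume_waveform),
               tolerance = 1e-12)

  # hand case: cycle-mean SDs (75.07, 51.58, 93.60) give total 220.25
  expect_equal(75.07 + 51.58 + 93.60, 220.25)
  zn <- subject_summary(extract_strides(
    generate_trial(zero_noise_profile(), n_strides = 4, seed = 1)))
  expect_lt(zn$total_variability, 1)          # mm/s; numerical residue only
  expect_lt(zn$mean_ellipsoid_volume, 1e-2)
})

test_that("doubling the noise envelope doubles SDs and scales volume by 8", {
  base <- preset_profile("control")
  doubled <- base
  doubled$sd_envelope <- 2 * base$sd_envelope
  s1 <- subject_summary(extract_strides(generate_trial(base, 60, seed = 5)))
  s2 <- subject_summary(extract_strides(generate_trial(doubled, 60, seed = 5)))
  # same seed: identical noise draws, so scaling is exact up to the linear
  # signal chain
  expect_equal(s2$var_vt / s1$var_vt, 2, tolerance = 1e-6)
  expect_equal(s2$var_ap / s1$var_ap, 2, tolerance = 1e-6)
  expect_equal(s2$mean_ellipsoid_volume / s1$mean_ellipsoid_volume, 8,
               tolerance = 1e-6)
})

test_that("volume waveform is invariant under rotation of all velocities", {
  set.seed(4)
  v <- array(rnorm(25 * 21 * 3, sd = 5), dim = c(25, 21, 3))
  st <- make_stride_set(v)
  vol <- volume_waveform(st)
  R <- random_rotation3()
  vol_r <- volume_waveform(rotate_stride_set(st, R))
  expect_equal(vol_r, vol, tolerance = 1e-9)
  # and ellipsoid orientations rotate by R (compare spanned quadratic forms)
  es <- ellipsoid_series(st)
  es_r <- ellipsoid_series(rotate_stride_set(st, R))
  for (t in c(1, 10, 21)) {
    Q1 <- es$orientations[, , t] %*% diag(es$semi_axes[t, ]^2) %*%
      t(es$orientations[, , t])
    Q2 <- es_r$orientations[, , t] %*% diag(es_r$semi_axes[t, ]^2) %*%
      t(es_r$orientations[, , t])
    expect_equal(Q2, R %*% Q1 %*% t(R), tolerance = 1e-9)
  }
})

test_that("near-diagonal presets keep volume consistent with the SD product", {
  trial <- generate_trial(preset_profile("control"), n_strides = 200, seed = 8)
  st <- extract_strides(trial)
  ss <- subject_summary(st)
  approx_vol <- 4 / 3 * pi * ss$var_ap * ss$var_ml * ss$var_vt
  expect_lt(abs(ss$mean_ellipsoid_volume - approx_vol) / approx_vol, 0.25)
  # order of magnitude ~ 1e6 mm^3/s^3 for the control-like preset
  expect_gt(ss$mean_ellipsoid_volume, 5e5)
  expect_lt(ss$mean_ellipsoid_volume, 5e6)
})

test_that("covariance projection onto a plane matches aligned and sampled cases", {
  frame_id <- list(tangent = c(1, 0, 0), normal = c(0, 1, 0),
                   binormal = c(0, 0, 1))
  pr <- project_covariance_to_plane(diag(3), frame_id)
  expect_equal(pr$semi_axes, c(1, 1))
  expect_equal(pr$area, pi, tolerance = 1e-12)

  pr <- project_covariance_to_plane(diag(c(4, 9, 16)), frame_id)
  expect_equal(pr$semi_axes, c(4, 3))

  expect_error(project_covariance_to_plane(diag(3),
               list(tangent = c(1, 0, 0), normal = c(1, 0, 0),
                    binormal = c(0, 0, 1))), "orthonormal")

  # sampling oracle: covariance of 1e5 projected samples
  set.seed(6)
  Sig <- random_spd3()
  R <- random_rotation3()
  frame <- list(tangent = R[, 1], normal = R[, 2], binormal = R[, 3])
  pr <- project_covariance_to_plane(Sig, frame)
  L <- t(chol(Sig))
  X <- t(L %*% matrix(rnorm(3 * 1e5), 3))
  P2 <- X %*% t(rbind(frame$normal, frame$binormal))
  Chat <- stats::cov(P2)
  for (i in 1:2) for (j in 1:2) {
    se <- sqrt((pr$cov2[i, i] * pr$cov2[j, j] + pr$cov2[i, j]^2) / 1e5)
    expect_lt(abs(Chat[i, j] - pr$cov2[i, j]), 3 * se)
  }
})

test_that("circular smoothing preserves constants, identity and mass", {
  x <- rep(4.2, 101)
  expect_equal(smooth_waveform(x, 11), x)
  y <- rnorm(101)
  expect_equal(smooth_waveform(y, 0), y)
  imp <- rep(0, 101); imp[51] <- 1
  sm <- smooth_waveform(imp, 5)           # 5-point window at T = 101
  expect_equal(sum(sm), 1, tolerance = 1e-12)
  expect_equal(sm[49:53], rep(1 / 5, 5), tolerance = 1e-12)
  expect_equal(sm[48], 0)
  expect_error(smooth_waveform(y, 120), "window")
})

test_that("gait tube composes correctly across noise regimes", {
  # zero noise: cross-section areas collapse
  st0 <- extract_strides(generate_trial(zero_noise_profile(), 6, seed = 2))
  tube0 <- build_gait_tube(st0)
  expect_lt(max(tube0$cross_sections$area), 1e-2)
  expect_equal(nrow(tube0$cross_sections), 101)

  # isotropic noise: cross-sections approximate circles of radius k*sigma
  iso <- preset_profile("control")
  iso$sd_envelope[] <- 50
  st <- extract_strides(generate_trial(iso, 300, seed = 3))
  tube <- build_gait_tube(st, k = 1, window = 5)
  expect_equal(median(tube$cross_sections$semi_major), 50, tolerance = 0.1)
  expect_equal(median(tube$cross_sections$semi_minor), 50, tolerance = 0.1)
  ecc <- tube$cross_sections$semi_major / tube$cross_sections$semi_minor
  expect_lt(max(ecc), 1.35)

  # control-like tube is everywhere fatter than the PAD-like tube
  stc <- extract_strides(generate_trial(preset_profile("control"), 300, seed = 4))
  stp <- extract_strides(generate_trial(preset_profile("pad"), 300, seed = 5))
  tc <- build_gait_tube(stc); tp <- build_gait_tube(stp)
  expect_true(all(tc$cross_sections$area > tp$cross_sections$area))
})

test_that("group mean waveforms average and band correctly", {
  w <- sin(seq(0, 2 * pi, length.out = 50))
  gm <- group_mean_waveforms(list(w))
  expect_equal(gm$mean, w)
  expect_equal(gm$sd, rep(0, 50))

  gm <- group_mean_waveforms(list(w, -w))
  expect_equal(gm$mean, rep(0, 50))

  set.seed(7)
  subj <- lapply(1:200, function(i) rnorm(30, sd = 2))
  gm <- group_mean_waveforms(subj)
  expect_equal(mean(gm$sd), 2, tolerance = 3 * 2 / sqrt(2 * 200) / sqrt(30) * 5)
  expect_true(all(abs(gm$sd - 2) < 3 * 2 / sqrt(2 * 200) * 3))

  expect_error(group_mean_waveforms(list(w, w[-1])), "dimensions")
})
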