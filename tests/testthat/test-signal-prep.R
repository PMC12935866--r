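# Signal preparation: COM averaging, filtering, differentiation,
# heel-strike detection and time normalization.

test_that("COM is the frame-wise mean of the five pelvis markers", {
  mk <- function(rows) marker_series(60, stats::setNames(
    lapply(rows, function(r) matrix(r, 1, 3, byrow = TRUE)),
    c("SACR", "LASI", "RASI", "LPSI", "RPSI")))

  # coincident markers: identity
  com <- com_from_pelvis(mk(rep(list(c(3, -2, 950)), 5)))
  expect_equal(unname(com$position[1, ]), c(3, -2, 950))

  # symmetric constellation averages to the origin
  com <- com_from_pelvis(mk(list(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0),
                                 c(0, 0, 2), c(-2, -2, -2))))
  expect_equal(unname(com$position[1, ]), c(0, 0, 0))

  # a single 5 mm offset moves the mean by 1 mm
  com <- com_from_pelvis(mk(list(c(5, 0, 0), c(0, 0, 0), c(0, 0, 0),
                                 c(0, 0, 0), c(0, 0, 0))))
  expect_equal(unname(com$position[1, ]), c(1, 0, 0))
})

test_that("marker gaps are filled up to the window and rejected beyond it", {
  n <- 100
  base <- cbind(seq_len(n), 0, 950)
  pos <- stats::setNames(rep(list(base), 5),
                         c("SACR", "LASI", "RASI", "LPSI", "RPSI"))
  pos$LASI[40:43, 1] <- NA           # 4-frame gap: fillable
  com <- com_from_pelvis(marker_series(60, pos))
  expect_equal(unname(com$position[41, 1]), 41, tolerance = 1e-12)

  pos$LASI[60:70, 1] <- NA           # 11-frame gap: data-quality error
  expect_error(com_from_pelvis(marker_series(60, pos)), "gap")

  pos$LASI <- NULL
  expect_error(com_from_pelvis(marker_series(60, pos)), "LASI")
})

test_that("zero-phase low-pass preserves the passband and kills the stopband", {
  rate <- 60; t <- (0:599) / rate
  expect_equal(lowpass(rep(5, 600), 6, rate), rep(5, 600), tolerance = 1e-6)

  slow <- sin(2 * pi * 1 * t)
  out <- lowpass(slow, 6, rate)
  mid <- 100:500
  expect_lt(abs(max(abs(out[mid])) - 1), 0.01)

  fast <- sin(2 * pi * 25 * t)
  out <- lowpass(fast, 6, rate)
  expect_lt(max(abs(out[mid])), 0.1)

  expect_error(lowpass(slow, 30, rate), "Nyquist")
})

test_that("differentiation is exact on linear signals and accurate on sines", {
  rate <- 60
  ramp <- 10 * (0:99)                      # 10 mm per frame
  expect_equal(differentiate(ramp, rate), rep(600, 100), tolerance = 1e-9)
  expect_equal(differentiate(rep(7, 50), rate), rep(0, 50))
  expect_error(differentiate(c(1, 2), rate), "3 samples")

  t <- (0:599) / rate
  v <- differentiate(sin(2 * pi * t), rate)
  truth <- 2 * pi * cos(2 * pi * t)
  expect_lt(max(abs(v - truth)) / max(abs(truth)), 0.01)
})

test_that("heel strikes are the first at-threshold samples of each pulse", {
  pulse <- rep(c(rep(0, 30), rep(700, 60), rep(0, 30)), 5)
  ev <- detect_heel_strikes(force_signal(60, pulse), threshold = 20)
  expect_identical(as.integer(ev), as.integer(c(31, 151, 271, 391, 511)))

  expect_identical(detect_heel_strikes(rep(0, 500), 20), integer(0))

  set.seed(1)
  noise <- runif(500, 0, 10)
  expect_identical(detect_heel_strikes(noise, 20), integer(0))

  expect_error(detect_heel_strikes(pulse, threshold = -5), "threshold")
})

test_that("refractory interval suppresses threshold chatter", {
  # first pulse has a bouncy loading edge (cross, dip, cross again 2
  # samples later); later pulses are clean
  fz <- c(rep(0, 50), 30, 10, rep(700, 50), rep(0, 62),
          rep(c(rep(700, 50), rep(0, 63)), 2))
  ev <- detect_heel_strikes(fz, threshold = 20)
  expect_identical(as.integer(ev), c(51L, 165L, 278L))
})

test_that("time normalization spans each cycle exactly and interpolates well", {
  rate <- 60
  # constant velocity: every normalized stride is constant
  com <- structure(list(rate = rate,
                        position = matrix(0, 200, 3),
                        velocity = matrix(rep(c(3, -1, 2), each = 200), 200, 3)),
                   class = "com_trajectory")
  st <- segment_and_normalize(com, c(1, 50, 99, 148), T = 101)
  expect_equal(dim(st$values), c(3, 101, 3))
  expect_true(all(abs(st$values[, , 1] - 3) < 1e-9))

  # linear ramp over one 50-sample cycle, T = 101: endpoints exact
  vel <- matrix(0, 200, 3); vel[, 1] <- seq_len(200)
  com$velocity <- vel
  st <- segment_and_normalize(com, c(1, 50, 99), T = 101)
  expect_equal(unname(st$values[1, 1, 1]), 1, tolerance = 1e-9)
  expect_equal(unname(st$values[1, 101, 1]), 50, tolerance = 1e-9)
  expect_equal(unname(st$values[1, , 1]), seq(1, 50, length.out = 101),
               tolerance = 1e-9)

  # sampled sine interpolated onto 101 points within 0.5%
  n <- 61
  vel <- matrix(0, 200, 3)
  vel[, 2] <- sin(2 * pi * (seq_len(200) - 1) / (n - 1))
  com$velocity <- vel
  st <- segment_and_normalize(com, c(1, n, 2 * n - 1), T = 101)
  truth <- sin(2 * pi * seq(0, 1, length.out = 101))
  expect_lt(max(abs(st$values[1, , 2] - truth)), 0.005)
})

test_that("cycles violating duration sanity bounds are dropped and logged", {
  com <- structure(list(rate = 60, position = matrix(0, 400, 3),
                        velocity = matrix(1, 400, 3)),
                   class = "com_trajectory")
  events <- c(1, 51, 101, 121, 171, 221, 271)  # one 20-sample runt cycle
  st <- segment_and_normalize(com, events, T = 51)
  drops <- attr(st, "dropped")
  expect_equal(nrow(drops), 1)
  expect_equal(drops$cycle, 3)
  expect_match(drops$reason, "sanity")
  expect_equal(dim(st$values)[1], length(events) - 1 - 1)

  expect_error(segment_and_normalize(com, c(1, 50), T = 51), "insufficient")
})

test_that("pipeline heel strikes on synthetic trials equal ground truth", {
  prof <- preset_profile("pad")
  trial <- generate_trial(prof, n_strides = 20, seed = 9)
  strides <- extract_strides(trial)
  expect_equal(dim(strides$values)[1], 20)
  expect_equal(nrow(attr(strides, "dropped")), 0)
})
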