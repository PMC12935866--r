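# From raw marker + GRF streams to a per-subject set of time-normalized
# COM-velocity gait cycles.

PELVIS_MARKERS <- c("SACR", "LASI", "RASI", "LPSI", "RPSI")

#' Marker position series
#'
#' @param rate sampling rate, Hz (> 0).
#' @param positions named list of n x 3 numeric matrices (mm), columns in
#'   AP/ML/VT order; all markers must share the same length.
#' @return object of class `marker_series`.
#' @export
marker_series <- function(rate, positions) {
  if (!is.numeric(rate) || rate <= 0) stop("rate must be > 0")
  if (is.null(names(positions)) || any(names(positions) == "")) {
    stop("positions must be a named list of markers")
  }
  positions <- lapply(positions, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3) stop("each marker needs 3 columns (AP, ML, VT)")
    colnames(m) <- GT_AXES
    m
  })
  n <- vapply(positions, nrow, integer(1))
  if (length(unique(n)) != 1) stop("all markers must share the same length")
  structure(list(rate = rate, positions = positions, axes = GT_AXES),
            class = "marker_series")
}

#' Vertical ground-reaction-force signal
#'
#' @param rate sampling rate, Hz (> 0).
#' @param fz vertical GRF time series, N; finite values.
#' @return object of class `force_signal`.
#' @export
force_signal <- function(rate, fz) {
  if (!is.numeric(rate) || rate <= 0) stop("rate must be > 0")
  fz <- as.numeric(fz)
  if (any(!is.finite(fz))) stop("fz must be finite")
  structure(list(rate = rate, fz = fz), class = "force_signal")
}

#' COM position from the five pelvis markers
#'
#' The center of mass is approximated as the frame-wise arithmetic mean of
#' the sacrum, bilateral ASIS and bilateral PSIS markers.  Short gaps (NA
#' runs up to `fill_max` frames) are filled by linear interpolation; longer
#' gaps raise a data-quality error.
#'
#' @param markers a [marker_series()] containing at least SACR, LASI, RASI,
#'   LPSI and RPSI.
#' @param fill_max longest NA gap (frames) filled by linear interpolation.
#' @return object of class `com_trajectory` with `rate`, `position`
#'   (n x 3 mm) and `velocity` (NULL until [differentiate()] is applied).
#' @export
com_from_pelvis <- function(markers, fill_max = 5) {
  stopifnot(inherits(markers, "marker_series"))
  missing <- setdiff(PELVIS_MARKERS, names(markers$positions))
  if (length(missing) > 0) {
    stop(sprintf("missing pelvis marker(s): %s", paste(missing, collapse = ", ")))
  }
  filled <- lapply(markers$positions[PELVIS_MARKERS], function(m) {
    if (anyNA(m)) {
      m <- apply(m, 2, function(col) {
        zoo::na.approx(col, na.rm = FALSE, maxgap = fill_max)
      })
      if (anyNA(m)) {
        stop(sprintf("marker gap longer than %d frames cannot be filled", fill_max))
      }
    }
    m
  })
  com <- Reduce(`+`, filled) / length(filled)
  colnames(com) <- GT_AXES
  structure(list(rate = markers$rate, position = com, velocity = NULL),
            class = "com_trajectory")
}

#' Zero-phase low-pass filter
#'
#' Butterworth low-pass of the given order applied forward and backward
#' (`signal::filtfilt`), so the output is zero-phase with the same length
#' as the input.
#'
#' @param x numeric vector or matrix (filtered column-wise).
#' @param cutoff cutoff frequency in Hz; must be below the Nyquist rate.
#' @param rate sampling rate in Hz.
#' @param order filter order.
#' @return filtered signal, same shape as `x`.
#' @export
lowpass <- function(x, cutoff, rate, order = 4) {
  if (cutoff >= rate / 2) stop("cutoff must be below the Nyquist frequency")
  if (cutoff <= 0) stop("cutoff must be > 0")
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  b <- bf$b; a <- bf$a
  nb <- length(b) - 1
  # single zero-initial-condition ARMA pass (identical to signal::filter,
  # via the C-level stats::filter primitives)
  arma <- function(v) {
    ma <- stats::filter(c(rep(0, nb), v), b, sides = 1)[-seq_len(nb)]
    as.numeric(stats::filter(ma, -a[-1], method = "recursive"))
  }
  filt1 <- function(col) {
    # reflect about the endpoints so the forward/backward passes settle
    # inside the padding rather than inside the data
    n <- length(col)
    pad <- min(n - 1, ceiling(10 * rate / cutoff))
    ext <- c(2 * col[1] - col[(pad + 1):2],
             col,
             2 * col[n] - col[(n - 1):(n - pad)])
    y <- rev(arma(rev(arma(ext))))
    y[pad + seq_len(n)]
  }
  if (is.matrix(x)) {
    out <- apply(x, 2, filt1)
    dimnames(out) <- dimnames(x)
    out
  } else {
    filt1(x)
  }
}

#' Differentiate a position series to velocity
#'
#' Second-order finite differences: central differences in the interior and
#' three-point one-sided differences at the ends, so linear signals
#' differentiate exactly.
#'
#' @param x numeric vector, matrix, or `com_trajectory` (mm).
#' @param rate sampling rate in Hz (taken from the object when `x` is a
#'   `com_trajectory`).
#' @return velocity with the same shape (mm/s); for a `com_trajectory` the
#'   object is returned with its `velocity` field populated.
#' @export
differentiate <- function(x, rate = NULL) {
  if (inherits(x, "com_trajectory")) {
    x$velocity <- differentiate(x$position, x$rate)
    return(x)
  }
  if (is.matrix(x)) {
    out <- apply(x, 2, differentiate, rate = rate)
    dimnames(out) <- dimnames(x)
    return(out)
  }
  n <- length(x)
  if (n < 3) stop("need at least 3 samples to differentiate")
  if (is.null(rate) || rate <= 0) stop("rate must be > 0")
  v <- numeric(n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  v[1] <- (-3 * x[1] + 4 * x[2] - x[3]) / 2
  v[n] <- (3 * x[n] - 4 * x[n - 1] + x[n - 2]) / 2
  v * rate
}

#' Detect heel strikes from the vertical GRF
#'
#' Heel strikes are upward threshold crossings of the vertical GRF: the
#' first sample at or above `threshold` following a sub-threshold sample.
#' Crossings closer than the refractory interval to the previous accepted
#' event are discarded (guards against chatter during loading).
#'
#' @param vgrf a [force_signal()] or numeric vector of vertical GRF (N).
#' @param threshold detection threshold in N (> 0).
#' @param refractory minimum event separation in samples; default 0.4 times
#'   the median candidate-crossing spacing.
#' @return integer vector of event sample indices (possibly empty).
#' @export
detect_heel_strikes <- function(vgrf, threshold = 20, refractory = NULL) {
  if (threshold <= 0) stop("threshold must be > 0")
  fz <- if (inherits(vgrf, "force_signal")) vgrf$fz else as.numeric(vgrf)
  n <- length(fz)
  if (n < 2) return(integer(0))
  up <- which(fz[-1] >= threshold & fz[-n] < threshold) + 1L
  if (length(up) == 0) return(integer(0))
  if (is.null(refractory)) {
    refractory <- if (length(up) > 1) 0.4 * stats::median(diff(up)) else 0
  }
  keep <- up[1]
  if (length(up) > 1) {
    for (idx in up[-1]) {
      if (idx - keep[length(keep)] >= refractory) keep <- c(keep, idx)
    }
  }
  keep
}

#' Segment COM velocity into time-normalized gait cycles
#'
#' Each gait cycle runs from one heel strike to the next heel strike of the
#' same limb; its COM velocity is interpolated (cubic spline; linear for
#' cycles shorter than 4 samples) onto `T` evenly spaced points spanning
#' 0--100\% of the cycle, endpoints included.  Cycles whose duration falls
#' outside `sanity_bounds` times the trial's median cycle duration are
#' dropped; drops are recorded in the `dropped` attribute with reasons.
#'
#' @param com a `com_trajectory` with velocity populated.
#' @param events heel-strike sample indices (>= 3 events, i.e. >= 2
#'   complete cycles).
#' @param T normalized resolution (number of points per cycle).
#' @param sanity_bounds length-2 multiplier bounds on cycle duration
#'   relative to the median.
#' @return object of class `stride_set`: `values` is an S x T x 3 array of
#'   COM velocity (mm/s), `stride_times` the start times (s) of the kept
#'   cycles.
#' @export
segment_and_normalize <- function(com, events, T = 101,
                                  sanity_bounds = c(0.5, 1.5)) {
  stopifnot(inherits(com, "com_trajectory"))
  if (is.null(com$velocity)) stop("com velocity missing; call differentiate() first")
  events <- sort(as.integer(events))
  if (length(events) < 3) {
    stop("insufficient data: need at least 3 heel strikes (2 complete cycles)")
  }
  durations <- diff(events)
  med <- stats::median(durations)
  ok <- durations >= sanity_bounds[1] * med & durations <= sanity_bounds[2] * med
  dropped <- data.frame(cycle = which(!ok),
                        duration = durations[!ok],
                        reason = if (any(!ok)) "duration outside sanity bounds"
                                 else character(0))
  if (sum(ok) < 2) stop("insufficient data: fewer than 2 valid cycles")
  kept <- which(ok)
  vals <- array(NA_real_, dim = c(length(kept), T, 3),
                dimnames = list(NULL, NULL, GT_AXES))
  for (j in seq_along(kept)) {
    ci <- kept[j]
    idx <- events[ci]:events[ci + 1]
    xout <- seq(events[ci], events[ci + 1], length.out = T)
    for (a in 1:3) {
      y <- com$velocity[idx, a]
      vals[j, , a] <- if (length(idx) >= 4) {
        stats::spline(idx, y, xout = xout, method = "fmm")$y
      } else {
        stats::approx(idx, y, xout = xout)$y
      }
    }
  }
  structure(list(values = vals, T = T, rate = com$rate,
                 stride_times = (events[kept] - 1) / com$rate),
            class = "stride_set", dropped = dropped)
}

#' @export
print.stride_set <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<stride_set> %d strides x %d points x 3 axes (COM velocity, mm/s)\n",
              d[1], d[2]))
  nd <- nrow(attr(x, "dropped"))
  if (!is.null(nd) && nd > 0) cat(sprintf("  %d cycle(s) dropped\n", nd))
  invisible(x)
}

#' Run the signal-preparation chain on one trial
#'
#' Marker positions are zero-phase low-pass filtered, averaged to the COM,
#' differentiated to velocity; heel strikes are detected from the vertical
#' GRF; cycles are segmented and time-normalized.
#'
#' @param trial a `synthetic_trial` or a list with `markers`
#'   (`marker_series`) and `vgrf` (`force_signal`).
#' @param T normalized resolution.
#' @param cutoff,order low-pass settings (Hz / filter order).
#' @param threshold heel-strike threshold (N).
#' @return a [segment_and_normalize()] `stride_set`.
#' @export
extract_strides <- function(trial, T = 101, cutoff = 6, order = 4,
                            threshold = 20) {
  markers <- trial$markers
  stacked <- do.call(cbind, markers$positions)   # one filter pass, 3k columns
  filt <- lowpass(stacked, cutoff = cutoff, rate = markers$rate, order = order)
  filtered <- lapply(seq_along(markers$positions), function(i) {
    filt[, 3 * (i - 1) + 1:3, drop = FALSE]
  })
  names(filtered) <- names(markers$positions)
  com <- com_from_pelvis(marker_series(markers$rate, filtered))
  com <- differentiate(com)
  events <- detect_heel_strikes(trial$vgrf, threshold = threshold)
  segment_and_normalize(com, events, T = T)
}
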