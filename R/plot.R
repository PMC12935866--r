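# Base-graphics views of the gait tube and the SPM result.

ellipse_points <- function(center2, semi, angle, n = 40) {
  th <- seq(0, 2 * pi, length.out = n)
  pts <- cbind(semi[1] * cos(th), semi[2] * sin(th))
  rot <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(pts %*% t(rot), 2, center2, "+")
}

#' Plot planar projections of a gait tube
#'
#' Draws the mean COM-velocity loop in the three anatomical planes
#' (sagittal AP-VT, transverse AP-ML, frontal ML-VT) with cross-sectional
#' variability ellipses (projected into each plotting plane via the
#' Frenet frame) overlaid every few cycle percent.
#'
#' @param x a `gait_tube`.
#' @param every draw an ellipse every `every`-th cycle point.
#' @param col line/ellipse color.
#' @param add overlay on an existing plot of the same layout?
#' @param ... passed to [graphics::matplot()] framework (unused).
#' @export
plot.gait_tube <- function(x, every = 5, col = "black", add = FALSE, ...) {
  planes <- list(sagittal = c(1, 3), transverse = c(1, 2), frontal = c(2, 3))
  labs <- c(ap = "AP velocity (mm/s)", ml = "ML velocity (mm/s)",
            vt = "VT velocity (mm/s)")
  M <- x$mean_trajectory
  T <- nrow(M)
  idx <- seq(1, T, by = every)
  if (!add) {
    graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  }
  for (pn in names(planes)) {
    ax <- planes[[pn]]
    if (!add) {
      pad <- 1.3 * max(x$cross_sections$semi_major)
      graphics::plot(M[, ax[1]], M[, ax[2]], type = "l", col = col,
                     xlab = labs[GT_AXES[ax[1]]], ylab = labs[GT_AXES[ax[2]]],
                     main = pn, asp = 1,
                     xlim = range(M[, ax[1]]) + c(-pad, pad),
                     ylim = range(M[, ax[2]]) + c(-pad, pad))
    } else {
      graphics::lines(M[, ax[1]], M[, ax[2]], col = col)
    }
    for (t in idx) {
      # place the Frenet-plane ellipse into 3D, then project on the plane
      nvec <- x$frames$normal[t, ]; bvec <- x$frames$binormal[t, ]
      cs <- x$cross_sections[t, ]
      th <- seq(0, 2 * pi, length.out = 40)
      u <- cos(cs$angle) * cs$semi_major * cos(th) -
           sin(cs$angle) * cs$semi_minor * sin(th)
      w <- sin(cs$angle) * cs$semi_major * cos(th) +
           cos(cs$angle) * cs$semi_minor * sin(th)
      p3 <- outer(u, nvec) + outer(w, bvec)
      graphics::lines(M[t, ax[1]] + p3[, ax[1]], M[t, ax[2]] + p3[, ax[2]],
                      col = grDevices::adjustcolor(col, alpha.f = 0.45))
    }
  }
  invisible(x)
}

#' Plot an SPM t-waveform with its critical threshold and phases
#'
#' @param x an `spm_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.spm_result <- function(x, ...) {
  T <- length(x$t_waveform)
  pct <- seq(0, 100, length.out = T)
  graphics::plot(pct, x$t_waveform, type = "l",
                 xlab = "gait cycle (%)", ylab = "t statistic", ...)
  graphics::abline(h = c(-1, 1) * x$critical_threshold, lty = 2, col = "red")
  ph <- gait_phases()
  graphics::abline(v = ph$start_pct[-1], col = "grey80", lty = 3)
  if (nrow(x$clusters) > 0) {
    for (i in seq_len(nrow(x$clusters))) {
      graphics::rect(x$clusters$start_pct[i], graphics::par("usr")[3],
                     x$clusters$end_pct[i], graphics::par("usr")[4],
                     col = grDevices::adjustcolor("red", alpha.f = 0.1),
                     border = NA)
    }
  }
  invisible(x)
}
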