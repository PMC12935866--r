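# Frenet-Serret frames along the mean COM-velocity trajectory; the
# normal-binormal plane at each cycle instant is the tube's cross-section.

# second-order finite-difference derivative of each row-curve column;
# circular differences for closed (cycle-periodic) trajectories
fd_deriv <- function(M, closed = FALSE) {
  n <- nrow(M)
  D <- matrix(0, n, ncol(M))
  if (closed) {
    # for a closed curve sampled with duplicated endpoint, wrap over the
    # n-1 distinct points
    idx <- seq_len(n - 1)
    P <- M[idx, , drop = FALSE]
    m <- n - 1
    up <- c(2:m, 1); dn <- c(m, 1:(m - 1))
    Dp <- (P[up, , drop = FALSE] - P[dn, , drop = FALSE]) / 2
    D[idx, ] <- Dp
    D[n, ] <- Dp[1, ]
  } else {
    D[2:(n - 1), ] <- (M[3:n, , drop = FALSE] - M[1:(n - 2), , drop = FALSE]) / 2
    D[1, ] <- (-3 * M[1, ] + 4 * M[2, ] - M[3, ]) / 2
    D[n, ] <- (3 * M[n, ] - 4 * M[n - 1, ] + M[n - 2, ]) / 2
  }
  D
}

row_normalize <- function(M) {
  nrm <- sqrt(rowSums(M^2))
  sweep(M, 1, pmax(nrm, .Machine$double.xmin), "/")
}

#' Frenet-Serret frames along a trajectory
#'
#' Computes the orthonormal tangent/normal/binormal triad at every sample
#' of a space curve: the tangent is the normalized first derivative, the
#' normal the normalized component of the tangent's derivative orthogonal
#' to the tangent (the curvature direction), and the binormal their cross
#' product.  Derivatives are second-order finite differences (circular for
#' closed cycles).  Points with near-zero curvature are flagged degenerate
#' and inherit the frame of the nearest non-degenerate point
#' (re-orthogonalized against the local tangent); if the whole curve is
#' degenerate (a straight line) a constant fallback frame is used.  Normal
#' signs are made continuous by aligning each triad with its predecessor.
#'
#' @param trajectory T x 3 numeric matrix (T >= 5).
#' @param closed treat the curve as cycle-periodic (first row = last row)?
#' @param degenerate_tol curvature threshold relative to the trajectory's
#'   velocity scale below which a point is flagged degenerate.
#' @return object of class `frenet_frames` with T x 3 matrices `tangent`,
#'   `normal`, `binormal` and logical `degenerate_flags`.
#' @export
frenet_frames <- function(trajectory, closed = FALSE, degenerate_tol = 1e-6) {
  M <- as.matrix(trajectory)
  T <- nrow(M)
  if (T < 5) stop("need at least 5 trajectory points")
  if (all(abs(M - matrix(M[1, ], T, 3, byrow = TRUE)) < .Machine$double.eps)) {
    stop("zero-length trajectory")
  }
  d1 <- fd_deriv(M, closed)
  tangent <- row_normalize(d1)
  dT <- fd_deriv(tangent, closed)
  # curvature component: part of dT orthogonal to the tangent
  proj <- rowSums(dT * tangent)
  curv <- dT - tangent * proj
  curv_norm <- sqrt(rowSums(curv^2))
  # flag near-zero curvature relative to the curve's own turning scale
  # (falls back to an absolute threshold for globally straight curves)
  degenerate <- curv_norm < degenerate_tol * max(max(curv_norm), 1)

  normal <- matrix(0, T, 3)
  good <- which(!degenerate)
  if (length(good) == 0) {
    # straight line: constant fallback frame orthogonal to the mean tangent
    t0 <- colMeans(tangent)
    t0 <- t0 / sqrt(sum(t0^2))
    e <- diag(3)[, which.min(abs(t0))]
    n0 <- e - t0 * sum(e * t0)
    n0 <- n0 / sqrt(sum(n0^2))
    tangent <- matrix(t0, T, 3, byrow = TRUE)
    normal <- matrix(n0, T, 3, byrow = TRUE)
    degenerate <- rep(TRUE, T)
  } else {
    normal[good, ] <- row_normalize(curv[good, , drop = FALSE])
    if (length(good) < T) {
      bad <- which(degenerate)
      for (i in bad) {
        j <- good[which.min(abs(good - i))]
        n0 <- normal[j, ]
        n0 <- n0 - tangent[i, ] * sum(n0 * tangent[i, ])
        nn <- sqrt(sum(n0^2))
        if (nn < 1e-12) {  # neighbor normal parallel to local tangent
          e <- diag(3)[, which.min(abs(tangent[i, ]))]
          n0 <- e - tangent[i, ] * sum(e * tangent[i, ])
          nn <- sqrt(sum(n0^2))
        }
        normal[i, ] <- n0 / nn
      }
    }
  }
  # sign continuity along the cycle
  for (i in 2:T) {
    if (sum(normal[i, ] * normal[i - 1, ]) < 0) normal[i, ] <- -normal[i, ]
  }
  binormal <- cbind(
    tangent[, 2] * normal[, 3] - tangent[, 3] * normal[, 2],
    tangent[, 3] * normal[, 1] - tangent[, 1] * normal[, 3],
    tangent[, 1] * normal[, 2] - tangent[, 2] * normal[, 1]
  )
  binormal <- row_normalize(binormal)
  structure(list(tangent = tangent, normal = normal, binormal = binormal,
                 degenerate_flags = degenerate),
            class = "frenet_frames")
}
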