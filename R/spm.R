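# Phase-resolved group comparison of gait-cycle waveforms: point-wise t
# statistic with permutation-based suprathreshold-cluster inference
# (max-statistic family-wise control), aggregated over the eight clinical
# gait phases.

#' The eight clinical gait phases
#'
#' Named percent ranges subdividing the 0--100\% gait cycle: Initial
#' Contact 0--2, Loading Response 2--12, Mid Stance 12--31, Terminal Stance
#' 31--50, Pre-Swing 50--62, Initial Swing 62--75, Mid Swing 75--87,
#' Terminal Swing 87--100.
#'
#' @return data.frame with columns `phase`, `start_pct`, `end_pct`.
#' @export
gait_phases <- function() {
  data.frame(
    phase = c("Initial Contact", "Loading Response", "Mid Stance",
              "Terminal Stance", "Pre-Swing", "Initial Swing",
              "Mid Swing", "Terminal Swing"),
    start_pct = c(0, 2, 12, 31, 50, 62, 75, 87),
    end_pct = c(2, 12, 31, 50, 62, 75, 87, 100),
    stringsAsFactors = FALSE
  )
}

# build the M x N group-1 indicator matrix for a set of permutations
perm_indicator <- function(idx_mat, N) {
  M <- nrow(idx_mat)
  I1 <- matrix(0, M, N)
  I1[cbind(rep(seq_len(M), each = ncol(idx_mat)), as.vector(t(idx_mat)))] <- 1
  I1
}

#' Two-sample permutation SPM over the gait cycle
#'
#' Computes the point-wise two-sample t statistic (pooled variance by
#' default) between two groups of subject waveforms and controls the
#' family-wise error across the whole cycle with the permutation
#' distribution of the maximum absolute t: group labels are permuted (full
#' enumeration when the number of distinct label arrangements is at most
#' `n_perm`, otherwise `n_perm` random permutations that always include
#' the observed labelling), the critical threshold is the (1 - alpha)
#' quantile of the max-|t| distribution, and each suprathreshold cluster
#' receives the p-value "fraction of permutations whose max |t| reaches
#' the cluster's maximum".  Per-phase significance is aggregated with
#' [phase_aggregate()] over the eight clinical gait phases.
#'
#' With full enumeration the result is deterministic and independent of
#' `seed`.
#'
#' @param waveA,waveB numeric matrices, subjects x T (equal T, >= 2
#'   subjects each).
#' @param alpha family-wise significance level.
#' @param n_perm permutation budget (a warning is issued below 100).
#' @param seed integer seed for the random-permutation branch.
#' @param var_equal pooled-variance t (TRUE, default) or Welch t.
#' @return object of class `spm_result` with `t_waveform`,
#'   `critical_threshold`, `clusters` (data.frame `start_pct`, `end_pct`,
#'   `max_t`, `p`), `per_phase` (see [phase_aggregate()]), `n_permutations`,
#'   `enumerated`, `alpha`, `seed`.
#' @export
spm_two_sample <- function(waveA, waveB, alpha = 0.05, n_perm = 10000,
                           seed = NULL, var_equal = TRUE) {
  waveA <- as.matrix(waveA); waveB <- as.matrix(waveB)
  if (ncol(waveA) != ncol(waveB)) stop("waveforms must share T")
  n1 <- nrow(waveA); n2 <- nrow(waveB)
  if (n1 < 2 || n2 < 2) stop("need at least 2 subjects per group")
  if (n_perm < 100) warning("n_perm below 100: p-values will be very coarse")
  T <- ncol(waveA)
  X <- rbind(waveA, waveB)
  N <- n1 + n2

  total <- choose(N, n1)
  enumerated <- is.finite(total) && total <= n_perm
  if (enumerated) {
    idx_mat <- t(utils::combn(N, n1))          # row 1 is the identity 1:n1
  } else {
    if (!is.null(seed)) set.seed(seed)
    idx_mat <- rbind(seq_len(n1),
                     t(replicate(n_perm - 1, sample.int(N, n1))))
  }
  M <- nrow(idx_mat)
  I1 <- perm_indicator(idx_mat, N)

  X2 <- X * X
  s_tot <- colSums(X); q_tot <- colSums(X2)
  S1 <- I1 %*% X;  Q1 <- I1 %*% X2
  S2 <- matrix(s_tot, M, T, byrow = TRUE) - S1
  Q2 <- matrix(q_tot, M, T, byrow = TRUE) - Q1
  m1 <- S1 / n1; m2 <- S2 / n2
  v1 <- pmax(Q1 - S1^2 / n1, 0) / (n1 - 1)
  v2 <- pmax(Q2 - S2^2 / n2, 0) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (N - 2)
    denom <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    denom <- sqrt(v1 / n1 + v2 / n2)
  }
  tmat <- (m1 - m2) / denom
  tmat[!is.finite(tmat)] <- 0

  at <- abs(tmat)
  maxabs <- at[, 1]
  if (T > 1) for (j in 2:T) maxabs <- pmax(maxabs, at[, j])
  t_obs <- tmat[1, ]
  crit <- sort(maxabs)[ceiling((1 - alpha) * M)]

  pct <- seq(0, 100, length.out = T)
  supra <- abs(t_obs) > crit
  clusters <- data.frame(start_pct = numeric(0), end_pct = numeric(0),
                         max_t = numeric(0), p = numeric(0))
  if (any(supra)) {
    r <- rle(supra)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (ci in which(r$values)) {
      seg <- starts[ci]:ends[ci]
      cmax <- max(abs(t_obs[seg]))
      clusters <- rbind(clusters, data.frame(
        start_pct = pct[starts[ci]], end_pct = pct[ends[ci]],
        max_t = cmax, p = mean(maxabs >= cmax)))
    }
  }
  res <- structure(list(
    t_waveform = t_obs, critical_threshold = crit, clusters = clusters,
    per_phase = NULL, n_permutations = M, enumerated = enumerated,
    alpha = alpha, seed = seed
  ), class = "spm_result")
  res$per_phase <- phase_aggregate(res)
  res
}

#' @export
print.spm_result <- function(x, ...) {
  cat(sprintf("<spm_result> max |t| = %.2f, critical threshold %.2f (alpha %.3g, %d perms%s)\n",
              max(abs(x$t_waveform)), x$critical_threshold, x$alpha,
              x$n_permutations, if (x$enumerated) ", enumerated" else ""))
  if (nrow(x$clusters) > 0) {
    for (i in seq_len(nrow(x$clusters))) {
      cat(sprintf("  cluster %.0f%%-%.0f%%: max |t| %.2f, p = %.4g\n",
                  x$clusters$start_pct[i], x$clusters$end_pct[i],
                  x$clusters$max_t[i], x$clusters$p[i]))
    }
  } else cat("  no suprathreshold clusters\n")
  invisible(x)
}

#' Aggregate SPM clusters over the clinical gait phases
#'
#' One row per phase: a phase is significant when any suprathreshold
#' cluster overlaps its percent range, and its p-value is the minimum
#' cluster p among overlapping clusters (1.0 when none overlaps).
#'
#' @param result an `spm_result`.
#' @param phases phase table as from [gait_phases()].
#' @return data.frame `phase`, `start_pct`, `end_pct`, `significant`, `p`.
#' @export
phase_aggregate <- function(result, phases = gait_phases()) {
  cl <- result$clusters
  out <- phases
  out$significant <- FALSE
  out$p <- 1.0
  if (nrow(cl) > 0) {
    for (i in seq_len(nrow(out))) {
      ov <- cl$start_pct <= out$end_pct[i] & cl$end_pct >= out$start_pct[i]
      if (any(ov)) {
        out$significant[i] <- TRUE
        out$p[i] <- min(cl$p[ov])
      }
    }
  }
  out
}

#' Between-group difference waveform
#'
#' Point-wise difference of two group-mean waveforms (conventionally
#' control minus patient group, so positive values indicate larger values
#' in the control group).
#'
#' @param groupA_mean,groupB_mean equal-length numeric vectors.
#' @return numeric vector `groupA_mean - groupB_mean`.
#' @export
difference_waveform <- function(groupA_mean, groupB_mean) {
  if (length(groupA_mean) != length(groupB_mean)) {
    stop("waveforms must share T")
  }
  groupA_mean - groupB_mean
}
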