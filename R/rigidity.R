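#' Ground-truth rigidity assessment of a trajectory
#'
#' A motion is rigid when every pairwise inter-vertex distance is conserved
#' across frames in the trajectory's native dimension. The oracle computes,
#' per frame, the maximum relative deviation of any pairwise distance from
#' its frame-0 value, and additionally the RMSD of each frame after
#' least-squares alignment onto frame 0 by a proper rotation plus
#' translation (Kabsch in d dimensions, reflections excluded since physical
#' motion cannot mirror the object). With per-vertex jitter enabled the
#' tolerance must exceed the jitter-induced deviation; the pipeline default
#' is `3 * jitter_amplitude / side_length`, treating jittered rigid stimuli
#' as rigid by design.
#'
#' @param traj A `trajectory_set` (>= 2 frames, >= 2 vertices).
#' @param tol Relative distance-deviation tolerance; `NULL` selects
#'   `max(1e-9, 3 * jitter_amplitude / side_length)` from the trajectory's
#'   own spec.
#' @return A `rigidity_report`: list with `is_rigid`,
#'   `max_distance_deviation` (relative), `per_frame_deviation`,
#'   `per_frame_fit_residual` (cm) and `tol`.
#' @export
assess_rigidity <- function(traj, tol = NULL) {
  stopifnot(inherits(traj, "trajectory_set"))
  n_frames <- dim(traj$frames)[1]
  n_vert <- dim(traj$frames)[2]
  if (n_frames < 2L) stop("trajectory must have at least 2 frames", call. = FALSE)
  if (n_vert < 2L) stop("trajectory must have at least 2 vertices", call. = FALSE)
  if (is.null(tol)) {
    tol <- max(1e-9, 3 * traj$spec$jitter_amplitude / traj$object$side_length)
  }
  ref <- traj$frames[1, , ]
  d0 <- pairwise_distances(ref)
  scale0 <- pmax(d0, .Machine$double.eps)
  dev <- numeric(n_frames)
  resid <- numeric(n_frames)
  for (k in seq_len(n_frames)) {
    fk <- traj$frames[k, , ]
    dev[k] <- max(abs(pairwise_distances(fk) - d0) / scale0)
    resid[k] <- kabsch_rmsd(fk, ref)
  }
  structure(
    list(is_rigid = max(dev) <= tol,
         max_distance_deviation = max(dev),
         per_frame_deviation = dev,
         per_frame_fit_residual = resid,
         tol = tol),
    class = "rigidity_report"
  )
}

# RMSD of x onto ref after optimal proper rotation + translation (Kabsch,
# any dimension; reflection corrected by flipping the smallest singular
# direction).
kabsch_rmsd <- function(x, ref) {
  xc <- sweep(x, 2, colMeans(x))
  rc <- sweep(ref, 2, colMeans(ref))
  s <- svd(crossprod(xc, rc)) # minimize |xc %*% R - rc|
  sgn <- sign(det(s$u %*% t(s$v)))
  d <- ncol(x)
  corr <- diag(c(rep(1, d - 1), sgn))
  R <- s$u %*% corr %*% t(s$v)
  sqrt(mean(rowSums((xc %*% R - rc)^2)))
}

#' @export
print.rigidity_report <- function(x, ...) {
  cat(sprintf("<rigidity_report> %s (max distance deviation %.3g, tol %.3g; max fit residual %.3g cm)\n",
              if (x$is_rigid) "RIGID" else "NON-RIGID",
              x$max_distance_deviation, x$tol,
              max(x$per_frame_fit_residual)))
  invisible(x)
}
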