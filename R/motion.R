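#' Specify a rigid or non-rigid stimulus motion
#'
#' A motion is built from oscillating plane rotations (the rigid backbone)
#' plus, for non-rigid motion, a time-varying per-vertex deformation along
#' fixed random directions and an axial shear displacement. Each rotation
#' plane's angle follows `theta_i(t) = A_i * sin(2*pi*f_i*t + phi_i)`, so
#' the object sweeps repeatedly over a fixed angular range. In 3D a
#' rotation is named by its fixed axis; in 4D by the invariant coordinate
#' plane (the plane that stays pointwise fixed while the complementary pair
#' of coordinates rotates).
#'
#' @param kind `"rigid"` or `"nonrigid"`.
#' @param rotation_planes A list of plane specs, each a list with `axis`
#'   (character vector of invariant coordinate names: one name in 3D, two
#'   in 4D), `amplitude` (deg), `frequency` (Hz) and optional `phase`
#'   (rad, default 0). `NULL` selects defaults: rotations about x and y for
#'   3D, and about the y-z, x-z and x-y invariant planes for 4D, all at
#'   30 deg amplitude and 0.25 Hz with staggered phases.
#' @param dimension Object dimension the defaults are built for.
#' @param shear_axis `"x"`, `"y"` or `"z"`: the axis that receives the shear
#'   displacement (non-rigid only).
#' @param shear_amplitude Dimensionless shear gain (default 0.2).
#' @param deform_amplitude Per-vertex deformation amplitude, cm (default 5).
#' @param deform_frequency,shear_frequency Hz for the deformation and shear
#'   oscillations (defaults 0.5 and 0.5).
#' @param jitter_amplitude Amplitude, cm, of the slight per-vertex random
#'   motion added to every stimulus to enhance stereoscopy (default 0.5;
#'   set 0 to disable).
#' @param jitter_frequency Hz of the per-vertex jitter oscillation.
#' @param duration Presentation duration, s (default 3, the response window).
#' @param frame_rate Hz (default 90, the headset refresh rate).
#' @param angle_schedule `"sine"` (default) or `"triangle"`: waveform of the
#'   oscillating rotation angle.
#' @param plane_convention `"invariant"` (default: the named plane/axis stays
#'   fixed) or `"rotating"` (the named pair of coordinates rotates).
#' @return A `motion_spec` object.
#' @export
motion_spec <- function(kind = c("rigid", "nonrigid"),
                        rotation_planes = NULL,
                        dimension = 3,
                        shear_axis = NULL,
                        shear_amplitude = 0.2,
                        deform_amplitude = 5,
                        deform_frequency = 0.5,
                        shear_frequency = 0.5,
                        jitter_amplitude = 0.5,
                        jitter_frequency = 2,
                        duration = 3,
                        frame_rate = 90,
                        angle_schedule = c("sine", "triangle"),
                        plane_convention = c("invariant", "rotating")) {
  kind <- match.arg(kind)
  angle_schedule <- match.arg(angle_schedule)
  plane_convention <- match.arg(plane_convention)
  stopifnot(duration > 0, frame_rate > 0)
  if (is.null(rotation_planes)) {
    rotation_planes <- default_rotation_planes(dimension)
  }
  rotation_planes <- lapply(rotation_planes, function(p) {
    stopifnot(is.list(p), !is.null(p$axis), !is.null(p$amplitude),
              !is.null(p$frequency))
    p$phase <- p$phase %||% 0
    p
  })
  if (kind == "rigid") {
    shear_axis <- NULL
    shear_amplitude <- 0
    deform_amplitude <- 0
  } else {
    if (is.null(shear_axis)) {
      stop("non-rigid motion requires `shear_axis`", call. = FALSE)
    }
    shear_axis <- match.arg(shear_axis, c("x", "y", "z"))
  }
  structure(
    list(kind = kind, rotation_planes = rotation_planes,
         shear_axis = shear_axis, shear_amplitude = shear_amplitude,
         deform_amplitude = deform_amplitude,
         deform_frequency = deform_frequency,
         shear_frequency = shear_frequency,
         jitter_amplitude = jitter_amplitude,
         jitter_frequency = jitter_frequency,
         duration = duration, frame_rate = frame_rate,
         angle_schedule = angle_schedule,
         plane_convention = plane_convention),
    class = "motion_spec"
  )
}

# 3D: rotations about the x and y axes. 4D: all three of the y-z, x-z and
# x-y invariant planes composed simultaneously, with staggered phases so the
# three plane angles are not locked together.
default_rotation_planes <- function(dimension) {
  if (dimension <= 3) {
    list(list(axis = "x", amplitude = 30, frequency = 0.25, phase = 0),
         list(axis = "y", amplitude = 30, frequency = 0.25, phase = pi / 3))
  } else {
    list(list(axis = c("y", "z"), amplitude = 30, frequency = 0.25, phase = 0),
         list(axis = c("x", "z"), amplitude = 30, frequency = 0.25, phase = pi / 3),
         list(axis = c("x", "y"), amplitude = 30, frequency = 0.25, phase = 2 * pi / 3))
  }
}

#' Plane rotation operator in d dimensions
#'
#' Returns the `dimension x dimension` orthonormal matrix (det +1) that
#' rotates the pair of coordinates complementary to the named invariant
#' coordinates by `angle`, leaving the named coordinates fixed. In 3D the
#' invariant set is a single axis (the familiar rotation axis); in 4D it is
#' a coordinate plane — the generalisation in which a plane, not a line,
#' serves as the rotation axis.
#'
#' @param dimension Ambient dimension.
#' @param invariant Character vector of coordinate names (from x, y, z, w)
#'   that remain fixed; must leave exactly two free coordinates.
#' @param angle Rotation angle in degrees.
#' @param convention `"invariant"` (default) or `"rotating"`: whether
#'   `invariant` names the fixed coordinates or the rotating pair.
#' @return A `dimension x dimension` rotation matrix.
#' @examples
#' rotation_operator(4, c("x", "y"), 90) %*% c(0, 0, 1, 0) # -> (0, 0, 0, 1)
#' @export
rotation_operator <- function(dimension, invariant, angle,
                              convention = c("invariant", "rotating")) {
  convention <- match.arg(convention)
  d <- as.integer(dimension)
  idx <- axis_index(invariant, d)
  if (anyDuplicated(idx)) stop("duplicate coordinate names", call. = FALSE)
  rot <- if (convention == "invariant") setdiff(seq_len(d), idx) else idx
  if (length(rot) != 2L) {
    stop("rotation requires exactly two free coordinates; got ",
         length(rot), call. = FALSE)
  }
  i <- rot[1]; j <- rot[2]
  th <- angle * pi / 180
  R <- diag(d)
  R[i, i] <- cos(th); R[j, j] <- cos(th)
  R[i, j] <- -sin(th); R[j, i] <- sin(th)
  R
}

# Oscillation waveform in [-1, 1].
osc_wave <- function(t, frequency, phase, schedule) {
  u <- 2 * pi * frequency * t + phase
  if (schedule == "sine") sin(u)
  else 2 / pi * asin(sin(u)) # triangle wave, same amplitude and period
}

# Composed rotation matrix of a spec at time t.
pose_rotation <- function(dimension, spec, t) {
  R <- diag(dimension)
  for (p in spec$rotation_planes) {
    ang <- p$amplitude * osc_wave(t, p$frequency, p$phase, spec$angle_schedule)
    R <- rotation_operator(dimension, p$axis, ang, spec$plane_convention) %*% R
  }
  R
}

#' Rigid pose of a wireframe at time t
#'
#' Applies the composed oscillating plane rotations of `spec` to the
#' object's vertices. Being a pure rotation, the pose preserves every
#' pairwise inter-vertex distance in the native dimension.
#'
#' @param obj A `wireframe`.
#' @param spec A `motion_spec` (its rotation planes are used; kind may be
#'   rigid or non-rigid — this is the rigid backbone).
#' @param t Time in seconds.
#' @return A vertex snapshot (matrix, same shape as `obj$vertices`).
#' @export
rigid_pose <- function(obj, spec, t) {
  stopifnot(inherits(obj, "wireframe"), inherits(spec, "motion_spec"))
  R <- pose_rotation(obj$dimension, spec, t)
  out <- obj$vertices %*% t(R)
  colnames(out) <- colnames(obj$vertices)
  out
}

# Fixed per-vertex deformation directions (unit vectors), drawn once per
# seed in the same 3D-level subspace used for the irregularity shifts.
deformation_directions <- function(n, dimension, seed) {
  pd <- min(dimension, 3L)
  u <- with_seed(seed, random_unit_vectors(n, pd))
  if (pd < dimension) u <- cbind(u, matrix(0, n, dimension - pd))
  u
}

# x -> y -> z cyclic successor, the transverse coordinate driving the shear.
shear_transverse <- function(axis) c(x = "y", y = "z", z = "x")[[axis]]

#' Non-rigid pose of a wireframe at time t
#'
#' Starts from [rigid_pose()] and adds (a) a per-vertex deformation along a
#' fixed random unit direction with time-varying magnitude
#' `deform_amplitude * sin(2*pi*f_d*t)`, and (b) a shear: the shear-axis
#' coordinate of each vertex is incremented by
#' `shear_amplitude * sin(2*pi*f_s*t)` times the vertex's transverse
#' coordinate (the cyclic successor x->y->z->x of the shear axis). At
#' generic times this violates distance preservation.
#'
#' @inheritParams rigid_pose
#' @param seed Seed fixing the per-vertex deformation directions.
#' @return A vertex snapshot matrix.
#' @export
nonrigid_pose <- function(obj, spec, t, seed = NULL) {
  stopifnot(inherits(obj, "wireframe"), inherits(spec, "motion_spec"))
  if (spec$kind == "nonrigid" && is.null(spec$shear_axis)) {
    stop("non-rigid spec has no `shear_axis`", call. = FALSE)
  }
  snap <- rigid_pose(obj, spec, t)
  n <- nrow(snap)
  if (spec$deform_amplitude > 0) {
    u <- deformation_directions(n, obj$dimension, seed)
    snap <- snap + u * (spec$deform_amplitude * sin(2 * pi * spec$deform_frequency * t))
  }
  if (spec$shear_amplitude > 0) {
    a <- axis_index(spec$shear_axis, obj$dimension)
    tr <- axis_index(shear_transverse(spec$shear_axis), obj$dimension)
    snap[, a] <- snap[, a] +
      spec$shear_amplitude * sin(2 * pi * spec$shear_frequency * t) * snap[, tr]
  }
  snap
}

#' Generate a full stimulus trajectory
#'
#' Samples `round(duration * frame_rate)` frames at uniform times, each a
#' rigid or non-rigid pose of the object, then adds the slight per-vertex
#' random motion (jitter): each vertex oscillates along a fixed random unit
#' direction with a random phase and amplitude `jitter_amplitude`, a
#' zero-mean displacement bounded by `jitter_amplitude` at all times.
#'
#' @inheritParams rigid_pose
#' @param seed Seed for the deformation directions and jitter; trajectories
#'   are bit-reproducible given the seed.
#' @return A `trajectory_set`: list with `frames` (T x V x d array, cm),
#'   `frame_times` (s), `spec` and `object`.
#' @export
generate_trajectory <- function(obj, spec, seed = NULL) {
  stopifnot(inherits(obj, "wireframe"), inherits(spec, "motion_spec"))
  n_frames <- round(spec$duration * spec$frame_rate)
  times <- (seq_len(n_frames) - 1L) / spec$frame_rate
  n <- nrow(obj$vertices)
  d <- obj$dimension
  seeds <- derive_seeds(seed, 2L)
  jitter <- NULL
  if (spec$jitter_amplitude > 0) {
    jitter <- with_seed(seeds[[2]], list(
      dir = random_unit_vectors(n, d),
      phase = runif(n, 0, 2 * pi)
    ))
  }
  frames <- array(NA_real_, c(n_frames, n, d),
                  dimnames = list(NULL, NULL, colnames(obj$vertices)))
  for (k in seq_len(n_frames)) {
    t <- times[k]
    snap <- if (spec$kind == "rigid") rigid_pose(obj, spec, t)
            else nonrigid_pose(obj, spec, t, seed = seeds[[1]])
    if (!is.null(jitter)) {
      mag <- spec$jitter_amplitude *
        sin(2 * pi * spec$jitter_frequency * t + jitter$phase)
      snap <- snap + jitter$dir * mag
    }
    frames[k, , ] <- snap
  }
  structure(
    list(frames = frames, frame_times = times, spec = spec, object = obj,
         seed = seed),
    class = "trajectory_set"
  )
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> %d frames x %d vertices x %dD, %s motion, %.3g s @ %g Hz\n",
              dim(x$frames)[1], dim(x$frames)[2], dim(x$frames)[3],
              x$spec$kind, x$spec$duration, x$spec$frame_rate))
  invisible(x)
}
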