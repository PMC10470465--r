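#' Viewing and projection parameters
#'
#' Collects the headset-derived viewing geometry: per-eye screens of
#' 1,200 x 1,080 pixels at 90 Hz with an approximate pupil-to-lens distance
#' of 18 mm, plus the virtual viewing distance and the 4D-to-3D projection
#' settings. The viewer looks down the -z direction (x rightward, y
#' downward on screen, z out of the screen toward the viewer), with the
#' object centred at the origin and the eyes at `z = view_distance`.
#'
#' @param eye_separation Interocular distance, mm (default 63, a typical
#'   adult IPD; the study does not print the per-subject value).
#' @param view_distance Eye-to-object-centre distance, cm (default 150;
#'   fixed but unprinted in the study).
#' @param screen_resolution Per-eye pixel resolution, `c(width, height)`.
#' @param screen_diagonal Physical per-eye screen diagonal, mm (91.4).
#' @param refresh_rate Display refresh, Hz.
#' @param pupil_to_lens Pupil-to-lens distance, mm; used as the pinhole
#'   focal distance of the symmetric view frustum.
#' @param projection_4d `"perspective"` (default: vertices farther in +w
#'   inflate, giving the nested inner/outer-cube tesseract look) or
#'   `"orthographic"` (drop the w coordinate).
#' @param w_eye_distance 4D viewpoint distance along w, cm (perspective-4D
#'   only; default 250).
#' @return A `camera_params` object.
#' @export
camera_params <- function(eye_separation = 63,
                          view_distance = 150,
                          screen_resolution = c(1200L, 1080L),
                          screen_diagonal = 91.4,
                          refresh_rate = 90,
                          pupil_to_lens = 18,
                          projection_4d = c("perspective", "orthographic"),
                          w_eye_distance = 250) {
  projection_4d <- match.arg(projection_4d)
  stopifnot(eye_separation >= 0, view_distance > 0,
            length(screen_resolution) == 2L, all(screen_resolution > 0),
            screen_diagonal > 0, refresh_rate > 0, pupil_to_lens > 0,
            w_eye_distance > 0)
  mm_per_px <- screen_diagonal / sqrt(sum(as.numeric(screen_resolution)^2))
  structure(
    list(eye_separation = eye_separation, view_distance = view_distance,
         screen_resolution = as.integer(screen_resolution),
         screen_diagonal = screen_diagonal, refresh_rate = refresh_rate,
         pupil_to_lens = pupil_to_lens,
         focal_px = pupil_to_lens / mm_per_px,
         projection_4d = projection_4d, w_eye_distance = w_eye_distance),
    class = "camera_params"
  )
}

#' Project a 4D vertex snapshot (or trajectory) to 3D
#'
#' Orthographic mode drops the fourth (w) coordinate. Perspective mode
#' places a 4D viewpoint at `w = w_eye_distance` and scales (x, y, z) by
#' `w_eye_distance / (w_eye_distance - w)`, so the two w-halves of a
#' tesseract project to nested inner and outer cubes; every vertex must
#' satisfy `w < w_eye_distance`.
#'
#' @param x A V x 4 vertex snapshot matrix, or a 4D `trajectory_set`
#'   (projected frame by frame, edges carried through).
#' @param params A [camera_params()] object.
#' @return A V x 3 matrix, or a 3D `trajectory_set`.
#' @export
project_4d_to_3d <- function(x, params = camera_params()) {
  UseMethod("project_4d_to_3d")
}

#' @export
project_4d_to_3d.default <- function(x, params = camera_params()) {
  snap <- as.matrix(x)
  if (ncol(snap) != 4L) stop("snapshot must have 4 columns", call. = FALSE)
  if (params$projection_4d == "orthographic") {
    out <- snap[, 1:3, drop = FALSE]
  } else {
    w <- snap[, 4]
    if (any(w >= params$w_eye_distance)) {
      stop("projection singularity: vertex at or beyond the 4D viewpoint ",
           "(w >= ", params$w_eye_distance, ")", call. = FALSE)
    }
    out <- snap[, 1:3, drop = FALSE] * (params$w_eye_distance / (params$w_eye_distance - w))
  }
  colnames(out) <- AXIS_NAMES[1:3]
  out
}

#' @export
project_4d_to_3d.trajectory_set <- function(x, params = camera_params()) {
  stopifnot(dim(x$frames)[3] == 4L)
  n_frames <- dim(x$frames)[1]
  frames3 <- array(NA_real_, c(n_frames, dim(x$frames)[2], 3L),
                   dimnames = list(NULL, NULL, AXIS_NAMES[1:3]))
  for (k in seq_len(n_frames)) {
    frames3[k, , ] <- project_4d_to_3d.default(x$frames[k, , ], params)
  }
  obj3 <- x$object
  obj3$dimension <- 3L
  obj3$vertices <- project_4d_to_3d.default(x$object$vertices, params)
  out <- x
  out$frames <- frames3
  out$object <- obj3
  out
}

# Pinhole projection of 3D points onto one eye's screen (pixel coords).
# Eye at (ex, 0, view_distance) looking along -z; y is already screen-down.
project_one_eye <- function(snap, ex, params) {
  dz <- params$view_distance - snap[, 3]
  if (any(dz <= 0)) {
    stop("projection singularity: vertex at or behind the eye plane",
         call. = FALSE)
  }
  cx <- params$screen_resolution[1] / 2
  cy <- params$screen_resolution[2] / 2
  cbind(u = params$focal_px * (snap[, 1] - ex) / dz + cx,
        v = params$focal_px * snap[, 2] / dz + cy)
}

#' Project a 3D snapshot to left/right-eye image coordinates
#'
#' Standard pinhole perspective per eye, the eyes displaced by
#' `+/- eye_separation / 2` along x at `z = view_distance`, with a symmetric
#' frustum whose focal distance is the pupil-to-lens distance expressed in
#' pixels. Horizontal disparity (left u minus right u) grows with proximity
#' to the viewer and flips sign across the fixation depth.
#'
#' @param snap A V x 3 vertex snapshot, cm.
#' @param params A [camera_params()] object.
#' @return List with `left` and `right` V x 2 pixel-coordinate matrices.
#' @export
project_3d_to_stereo <- function(snap, params = camera_params()) {
  snap <- as.matrix(snap)
  if (ncol(snap) != 3L) stop("snapshot must have 3 columns", call. = FALSE)
  half <- params$eye_separation / 2 / 10 # mm -> cm, same units as vertices
  list(left = project_one_eye(snap, -half, params),
       right = project_one_eye(snap, +half, params))
}

#' Horizontal disparity per vertex
#'
#' Convenience wrapper: left-eye minus right-eye horizontal pixel
#' coordinate for each vertex of a 3D snapshot.
#'
#' @inheritParams project_3d_to_stereo
#' @return Numeric vector of disparities, px.
#' @export
stereo_disparity <- function(snap, params = camera_params()) {
  pr <- project_3d_to_stereo(snap, params)
  pr$left[, "u"] - pr$right[, "u"]
}
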