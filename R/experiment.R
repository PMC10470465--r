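#' Factor grid of a rigidity-discrimination experiment
#'
#' Experiment 1 (fixed headset) crosses dimension (3D, 4D) x displacement
#' axis (x, y, z) x irregularity (0.12, 0.18, 0.24), each cell repeated 3
#' times: 54 trials. Experiment 2 (active headset) drops the x-axis
#' displacement and repeats each of the 12 remaining cells 7 times: 84
#' trials.
#'
#' @param experiment 1 or 2.
#' @return A data frame of condition cells with a `reps` attribute.
#' @export
condition_grid <- function(experiment) {
  if (!experiment %in% c(1, 2)) {
    stop("unknown experiment id: ", experiment, call. = FALSE)
  }
  axes <- if (experiment == 1) c("x", "y", "z") else c("y", "z")
  grid <- expand.grid(dimension = c(3L, 4L), axis = axes,
                      irregularity = c(0.12, 0.18, 0.24),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  attr(grid, "reps") <- if (experiment == 1) 3L else 7L
  grid
}

#' Build a counterbalanced 2AFC session
#'
#' Lays out one session: the full condition grid repeated `reps` times,
#' split into a 3D block and a 4D block (the two dimensionalities were
#' presented in separate, instruction-delimited blocks), with the trial
#' order randomized within each block under equal per-cell counts. The
#' rigid stimulus's top/bottom placement is balanced across the repetitions
#' of each cell, with any odd remainder assigned by a seeded coin flip.
#'
#' @param experiment 1 or 2.
#' @param seed Integer seed; the same seed reproduces the same order.
#' @param subject Optional subject label carried into results.
#' @param session Session number; block order (3D-first vs 4D-first)
#'   alternates with it.
#' @param training Flag marking a training session (Experiment 1's first
#'   session; excluded from analysis by default).
#' @return A `session` object whose `trials` data frame has one row per
#'   trial: `trial`, `block`, `dimension`, `axis`, `irregularity`,
#'   `rigid_position`.
#' @export
build_session <- function(experiment, seed = NULL, subject = "S1",
                          session = 1L, training = FALSE) {
  grid <- condition_grid(experiment)
  reps <- attr(grid, "reps")
  seeds <- derive_seeds(seed, 4L)
  cells <- grid[rep(seq_len(nrow(grid)), each = reps), , drop = FALSE]
  # balanced top/bottom within each cell, remainder by coin flip
  pos <- with_seed(seeds[[1]], unlist(lapply(seq_len(nrow(grid)), function(i) {
    half <- reps %/% 2L
    p <- c(rep("top", half), rep("bottom", half))
    if (reps %% 2L) p <- c(p, sample(c("top", "bottom"), 1L))
    sample(p)
  })))
  cells$rigid_position <- pos
  dims <- if (session %% 2L == 1L) c(3L, 4L) else c(4L, 3L)
  blocks <- lapply(seq_along(dims), function(b) {
    blk <- cells[cells$dimension == dims[b], , drop = FALSE]
    blk <- with_seed(seeds[[1L + b]], blk[sample(nrow(blk)), , drop = FALSE])
    blk$block <- b
    blk
  })
  trials <- do.call(rbind, blocks)
  trials$trial <- seq_len(nrow(trials))
  rownames(trials) <- NULL
  trials <- trials[, c("trial", "block", "dimension", "axis", "irregularity",
                       "rigid_position")]
  structure(
    list(experiment = experiment, subject = subject, session = session,
         training = training, trials = trials, seed = seed,
         stimulus_seed = seeds[[4]]),
    class = "session"
  )
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("<session> experiment %d, subject %s, session %d%s: %d trials (%d cells x %d reps)\n",
              x$experiment, x$subject, x$session,
              if (x$training) " [training]" else "",
              nrow(x$trials), nrow(condition_grid(x$experiment)),
              attr(condition_grid(x$experiment), "reps")))
  invisible(x)
}

#' Generate the stimulus pair of one trial
#'
#' Builds the two wireframes of a trial — both perturbed at the trial's
#' irregularity level (independent perturbations) — and animates one
#' rigidly and one non-rigidly with the trial's displacement axis as the
#' shear axis, placing the rigid trajectory at the trial's
#' `rigid_position`.
#'
#' @param trial One row of a session's `trials` data frame (or a list with
#'   the same fields).
#' @param seed Integer seed.
#' @param side_length Side length, cm.
#' @param ... Extra arguments passed to [motion_spec()] (e.g.
#'   `jitter_amplitude = 0`).
#' @return List with `top`, `bottom` (trajectory_sets), and `rigid`
#'   naming which of the two is rigid.
#' @export
make_trial_stimuli <- function(trial, seed = NULL, side_length = 100, ...) {
  seeds <- derive_seeds(seed, 4L)
  d <- trial$dimension
  base <- make_hypercube(d, side_length)
  obj_r <- perturb_vertices(base, trial$irregularity, seed = seeds[[1]])
  obj_n <- perturb_vertices(base, trial$irregularity, seed = seeds[[2]])
  spec_r <- motion_spec("rigid", dimension = d, ...)
  spec_n <- motion_spec("nonrigid", dimension = d, shear_axis = trial$axis, ...)
  traj_r <- generate_trajectory(obj_r, spec_r, seed = seeds[[3]])
  traj_n <- generate_trajectory(obj_n, spec_n, seed = seeds[[4]])
  if (trial$rigid_position == "top") {
    list(top = traj_r, bottom = traj_n, rigid = "top")
  } else {
    list(top = traj_n, bottom = traj_r, rigid = "bottom")
  }
}

RESULT_COLUMNS <- c("subject", "experiment", "session", "training", "block",
                    "trial", "dimension", "axis", "irregularity",
                    "rigid_position", "choice", "correct", "rt_ms",
                    "confidence", "timed_out")

#' Run a session against an observer
#'
#' Presents each trial of the session to `observer` and records the
#' response. Responses slower than the 3,000 ms window are marked timed out
#' with no recorded choice or confidence (the next trial starts
#' automatically on timeout). In `"active"` headset mode every trial is
#' accompanied by a head-pose trace sampled at 18 Hz over the 3 s window
#' (54 samples); in `"fixed"` mode the viewpoint is locked front-view and
#' the trace is constant.
#'
#' @param session A [build_session()] object.
#' @param observer Either a function `trial -> list(choice, rt, confidence)`
#'   (or `NULL` for no response), or a [synthetic_observer()] object.
#' @param headset_mode `"fixed"` (Experiment 1) or `"active"`
#'   (Experiment 2).
#' @param seed Seed for any stochastic observer.
#' @return List with `results` (one row per trial, the trial-log schema)
#'   and `traces` (long data frame: trial, sample_index, t, angle_x,
#'   angle_y, angle_z in deg).
#' @export
run_session <- function(session, observer, headset_mode = c("fixed", "active"),
                        seed = NULL) {
  stopifnot(inherits(session, "session"))
  headset_mode <- match.arg(headset_mode)
  respond_fn <- if (inherits(observer, "observer")) observer$respond else observer
  trace_fn <- if (inherits(observer, "observer")) observer$head_trace else NULL
  stopifnot(is.function(respond_fn))
  trials <- session$trials
  n <- nrow(trials)
  results <- vector("list", n)
  traces <- vector("list", n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      tr <- as.list(trials[i, ])
      resp <- respond_fn(tr)
      timed_out <- is.null(resp) || (!is.null(resp$rt) && resp$rt > 3000)
      if (!timed_out) {
        if (!resp$choice %in% c("top", "bottom")) {
          stop("protocol violation: choice must be 'top' or 'bottom'",
               call. = FALSE)
        }
        conf <- resp$confidence
        if (is.null(conf) || length(conf) != 1L || is.na(conf) ||
            conf != round(conf) || conf < 1 || conf > 5) {
          stop("protocol violation: confidence must be an integer in 1..5",
               call. = FALSE)
        }
      }
      results[[i]] <- data.frame(
        subject = session$subject, experiment = session$experiment,
        session = session$session, training = session$training,
        block = tr$block, trial = tr$trial, dimension = tr$dimension,
        axis = tr$axis, irregularity = tr$irregularity,
        rigid_position = tr$rigid_position,
        choice = if (timed_out) "none" else resp$choice,
        correct = if (timed_out) NA else resp$choice == tr$rigid_position,
        rt_ms = if (timed_out) NA_real_ else as.numeric(resp$rt),
        confidence = if (timed_out) NA_integer_ else as.integer(resp$confidence),
        timed_out = timed_out,
        stringsAsFactors = FALSE
      )
      tri <- if (!is.null(trace_fn)) {
        trace_fn(tr, headset_mode)
      } else {
        constant_head_trace()
      }
      tri$trial <- tr$trial
      traces[[i]] <- tri
    }
  })
  results <- do.call(rbind, results)[, RESULT_COLUMNS]
  traces <- do.call(rbind, traces)
  traces <- traces[, c("trial", "sample_index", "t",
                       "angle_x", "angle_y", "angle_z")]
  list(results = results, traces = traces)
}

# Front-view constant trace: 54 samples at 18 Hz over 3 s, all angles 0.
constant_head_trace <- function(n_samples = 54L, rate = 18) {
  data.frame(sample_index = seq_len(n_samples),
             t = (seq_len(n_samples) - 1L) / rate,
             angle_x = 0, angle_y = 0, angle_z = 0)
}
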