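#' Define a synthetic observer profile
#'
#' An observer profile configures, per condition cell (dimension x
#' displacement axis), the probability of a correct rigidity judgment, the
#' reaction-time distribution (log-normal, parameterized by its mean and SD
#' in ms and truncated to the 3,000 ms response window), and the confidence
#' distribution (latent normal, negatively coupled to the standardized
#' log-RT draw, discretized to the 1..5 scale). Head pose is modelled per
#' axis as a slowly varying AR(1) process around a configured median with a
#' configured within-trial interquartile range.
#'
#' @param cells Data frame with columns `dimension`, `axis`, `accuracy`
#'   (probability), `rt_mean`, `rt_sd` (ms), `conf_mean`, `conf_sd`
#'   (1..5 scale). One row per condition cell the observer can face.
#' @param confidence_rt_coupling Coupling coefficient in [-1, 0]: the
#'   correlation between the latent confidence variable and minus the
#'   standardized log-RT draw. Discretization to 5 levels attenuates the
#'   realized confidence-RT correlation somewhat below this value.
#' @param timeout_rate Probability that a trial times out (no response
#'   within 3 s). Default 0.045, matching the 63/1,380 overtime-trial rate.
#' @param head_median Named vector `c(x=, y=, z=)` of per-axis median view
#'   angles, deg. Default centres the y-angle on 45 deg, with smaller x and
#'   z angles.
#' @param head_iqr Within-trial interquartile range of each angle series,
#'   deg (viewpoint ranges within trials were small).
#' @return An `observer_profile` object.
#' @export
observer_profile <- function(cells,
                             confidence_rt_coupling = -0.6,
                             timeout_rate = 0.045,
                             head_median = c(x = 10, y = 45, z = 10),
                             head_iqr = c(x = 2, y = 2, z = 2)) {
  req <- c("dimension", "axis", "accuracy", "rt_mean", "rt_sd",
           "conf_mean", "conf_sd")
  if (!all(req %in% names(cells))) {
    stop("`cells` must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(cells$accuracy >= 0 & cells$accuracy <= 1),
            all(cells$rt_mean > 0), all(cells$rt_sd >= 0),
            all(cells$conf_mean >= 1 & cells$conf_mean <= 5),
            confidence_rt_coupling <= 0, confidence_rt_coupling >= -1,
            timeout_rate >= 0, timeout_rate <= 1)
  cells <- as.data.frame(cells)[req] # base columns only; recalibrate below
  # Calibrate latent parameters so that the *recorded* responses match the
  # configured cell means: the RT log-normal is shifted so its 3,000
  # ms-truncated mean equals rt_mean, and the latent confidence normal is
  # shifted so its 1..5-discretized mean equals conf_mean (clipping at 5
  # otherwise biases high-confidence cells low).
  cal <- lapply(seq_len(nrow(cells)), function(i) {
    rt <- rt_lnorm_params(cells$rt_mean[i], cells$rt_sd[i])
    c(rt_meanlog = rt$meanlog, rt_sdlog = rt$sdlog,
      conf_latent_mean = conf_latent_mean(cells$conf_mean[i],
                                          cells$conf_sd[i]))
  })
  cells <- cbind(cells, do.call(rbind, cal))
  structure(
    list(cells = cells,
         confidence_rt_coupling = confidence_rt_coupling,
         timeout_rate = timeout_rate,
         head_median = head_median[c("x", "y", "z")],
         head_iqr = head_iqr[c("x", "y", "z")]),
    class = "observer_profile"
  )
}

# Log-normal whose mean truncated at `cap` equals m (SD matched on the
# untruncated scale); closed-form truncated-lognormal mean, root in meanlog.
rt_lnorm_params <- function(m, s, cap = 3000) {
  base <- lnorm_params(m, s)
  sig <- base$sdlog
  if (s == 0) return(base)
  tmean <- function(mu) {
    za <- (log(cap) - mu) / sig
    exp(mu + sig^2 / 2) * stats::pnorm(za - sig) / stats::pnorm(za)
  }
  f <- function(mu) tmean(mu) - m
  mu <- tryCatch(
    stats::uniroot(f, c(base$meanlog, log(cap)), tol = 1e-10)$root,
    error = function(e) base$meanlog)
  list(meanlog = mu, sdlog = sig)
}

# Latent-normal mean whose rounded-and-clipped 1..5 report has mean m.
conf_latent_mean <- function(m, s) {
  if (s == 0) return(m)
  disc_mean <- function(mu) {
    p <- diff(stats::pnorm(c(-Inf, 1.5, 2.5, 3.5, 4.5, Inf), mu, s))
    sum((1:5) * p)
  }
  tryCatch(
    stats::uniroot(function(mu) disc_mean(mu) - m, c(m - 2, m + 4),
                   tol = 1e-10)$root,
    error = function(e) m)
}

#' Built-in observer profiles
#'
#' Two bundles transcribed from the study's per-condition measurement
#' tables: `"table1"` — the fixed-headset condition (Experiment 1; three
#' displacement axes) — and `"table2"` — the active-headset condition
#' (Experiment 2; y and z axes only). Each carries per-cell accuracy, RT
#' mean/SD and confidence mean/SD for 3D and 4D stimuli.
#'
#' @param name `"table1"` or `"table2"`.
#' @param ... Overrides passed on to [observer_profile()].
#' @return An `observer_profile`.
#' @export
default_profile <- function(name = c("table1", "table2"), ...) {
  name <- match.arg(name)
  cells <- if (name == "table1") {
    data.frame(
      dimension = rep(c(3L, 4L), 3),
      axis      = rep(c("x", "z", "y"), each = 2),
      accuracy  = c(.9884, .9759, .6705, .5250, .6184, .7176),
      rt_mean   = c(580.19, 529.45, 782.63, 1019.79, 847.70, 726.29),
      rt_sd     = c(317.86, 256.19, 343.97, 429.32, 354.20, 389.60),
      conf_mean = c(4.94, 4.67, 3.73, 3.35, 4.03, 3.86),
      conf_sd   = c(0.32, 0.87, 1.35, 1.31, 1.12, 1.18)
    )
  } else {
    data.frame(
      dimension = rep(c(3L, 4L), 2),
      axis      = rep(c("z", "y"), each = 2),
      accuracy  = c(.9704, .8921, .9659, .9227),
      rt_mean   = c(543.97, 590.42, 534.33, 627.32),
      rt_sd     = c(289.04, 294.07, 298.23, 318.93),
      conf_mean = c(4.83, 4.32, 4.84, 4.32),
      conf_sd   = c(0.65, 1.12, 0.53, 1.20)
    )
  }
  observer_profile(cells, ...)
}

profile_cell <- function(profile, dimension, axis) {
  row <- profile$cells[profile$cells$dimension == dimension &
                         profile$cells$axis == axis, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("observer profile has no cell for dimension ", dimension,
         ", axis ", axis, call. = FALSE)
  }
  as.list(row)
}

# Log-normal parameters matching a target mean m and SD s.
lnorm_params <- function(m, s) {
  sig2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - sig2 / 2, sdlog = sqrt(sig2))
}

#' Draw one response from an observer profile
#'
#' Samples a choice, reaction time and confidence for a trial: a timeout
#' with probability `timeout_rate`; otherwise the rigid stimulus is chosen
#' with the cell's accuracy probability, the RT is a log-normal draw
#' matched to the cell's mean/SD and truncated (by rejection) to the 3 s
#' window, and confidence is a latent-normal draw coupled negatively to the
#' standardized log-RT, rounded and clipped to 1..5. Uses the current RNG
#' stream; seed at the session level (see [run_session()]).
#'
#' @param trial List or one-row data frame with `dimension`, `axis`,
#'   `rigid_position`.
#' @param profile An [observer_profile()].
#' @return `NULL` on timeout, else `list(choice, rt, confidence)`.
#' @export
respond <- function(trial, profile) {
  stopifnot(inherits(profile, "observer_profile"))
  cell <- profile_cell(profile, trial$dimension, trial$axis)
  if (runif(1) < profile$timeout_rate) return(NULL)
  correct <- runif(1) < cell$accuracy
  choice <- if (correct) trial$rigid_position
            else setdiff(c("top", "bottom"), trial$rigid_position)
  repeat { # truncate to the response window
    z_rt <- rnorm(1)
    rt <- exp(cell$rt_meanlog + cell$rt_sdlog * z_rt)
    if (rt <= 3000) break
  }
  rho <- profile$confidence_rt_coupling
  latent <- cell$conf_latent_mean +
    cell$conf_sd * (rho * z_rt + sqrt(1 - rho^2) * rnorm(1))
  confidence <- min(5L, max(1L, as.integer(round(latent))))
  list(choice = choice, rt = rt, confidence = confidence)
}

#' Simulate a head-pose trace for one trial
#'
#' 54 samples (18 Hz over the 3 s window) of the view angles about x, y
#' and z. Fixed mode returns the constant front view (all angles 0).
#' Active mode returns, per axis, a stationary AR(1) series (lag-1
#' coefficient 0.9) around the profile's median angle, scaled so the
#' marginal interquartile range matches `head_iqr` — slow, small head
#' drifts around a held posture.
#'
#' @param profile An [observer_profile()].
#' @param mode `"fixed"` or `"active"`.
#' @param n_samples,rate Trace length and sampling rate (54 at 18 Hz).
#' @return Data frame: `sample_index`, `t`, `angle_x`, `angle_y`,
#'   `angle_z` (deg).
#' @export
head_trace <- function(profile, mode = c("fixed", "active"),
                       n_samples = 54L, rate = 18) {
  stopifnot(inherits(profile, "observer_profile"))
  mode <- match.arg(mode)
  if (mode == "fixed") return(constant_head_trace(n_samples, rate))
  phi <- 0.9
  out <- lapply(c("x", "y", "z"), function(ax) {
    med <- profile$head_median[[ax]]
    s <- profile$head_iqr[[ax]] / (2 * qnorm(0.75)) # IQR -> marginal SD
    e <- rnorm(n_samples, sd = s * sqrt(1 - phi^2))
    x <- numeric(n_samples)
    x[1] <- rnorm(1, sd = s)
    for (k in 2:n_samples) x[k] <- phi * x[k - 1] + e[k]
    med + x
  })
  data.frame(sample_index = seq_len(n_samples),
             t = (seq_len(n_samples) - 1L) / rate,
             angle_x = out[[1]], angle_y = out[[2]], angle_z = out[[3]])
}

#' Create a synthetic observer for [run_session()]
#'
#' Wraps an [observer_profile()] into the observer interface: a `respond`
#' function drawing choice/RT/confidence per trial and a `head_trace`
#' function drawing the per-trial head-pose trace.
#'
#' @param profile An [observer_profile()] (default: the fixed-headset
#'   bundle `"table1"`).
#' @return An `observer` object.
#' @export
synthetic_observer <- function(profile = default_profile("table1")) {
  stopifnot(inherits(profile, "observer_profile"))
  structure(
    list(profile = profile,
         respond = function(trial) respond(trial, profile),
         head_trace = function(trial, mode) head_trace(profile, mode)),
    class = "observer"
  )
}

#' Simulate a full cohort through both experiments
#'
#' Runs `n_subjects` synthetic subjects through Experiment 1 (three
#' sessions, the first flagged as training, fixed headset, `"table1"`
#' profile) and Experiment 2 (two sessions, active headset, `"table2"`
#' profile), reproducing the study's recorded-trial volume: with 5
#' subjects, 5 x 2 x 54 + 5 x 2 x 84 = 1,380 recorded (non-training)
#' trials.
#'
#' @param n_subjects Number of subjects (default 5).
#' @param seed Master seed.
#' @param profiles List with elements `table1` and `table2` (observer
#'   profiles); defaults to the built-in bundles.
#' @param experiments Which experiments to run (default both).
#' @return List with `results` (row-bound trial logs) and `traces`
#'   (head-pose traces keyed by subject/experiment/session/trial).
#' @export
simulate_cohort <- function(n_subjects = 5, seed = NULL,
                            profiles = list(table1 = default_profile("table1"),
                                            table2 = default_profile("table2")),
                            experiments = c(1, 2)) {
  plan <- expand.grid(subject = seq_len(n_subjects),
                      experiment = experiments, KEEP.OUT.ATTRS = FALSE)
  plan <- plan[order(plan$experiment, plan$subject), ]
  seeds <- derive_seeds(seed, nrow(plan) * 6L) # 2 per session, <= 3 sessions
  results <- list(); traces <- list(); k <- 0L
  for (i in seq_len(nrow(plan))) {
    exp_id <- plan$experiment[i]
    subj <- sprintf("S%02d", plan$subject[i])
    n_sessions <- if (exp_id == 1) 3L else 2L
    mode <- if (exp_id == 1) "fixed" else "active"
    prof <- if (exp_id == 1) profiles$table1 else profiles$table2
    obs <- synthetic_observer(prof)
    for (s in seq_len(n_sessions)) {
      k <- k + 1L
      training <- exp_id == 1 && s == 1L
      ses <- build_session(exp_id, seed = seeds[[2L * k - 1L]],
                           subject = subj, session = s, training = training)
      run <- run_session(ses, obs, headset_mode = mode,
                         seed = seeds[[2L * k]])
      run$traces$subject <- subj
      run$traces$experiment <- exp_id
      run$traces$session <- s
      results[[length(results) + 1L]] <- run$results
      traces[[length(traces) + 1L]] <- run$traces
    }
  }
  list(results = do.call(rbind, results), traces = do.call(rbind, traces))
}
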