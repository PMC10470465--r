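#' Filter a trial log for analysis
#'
#' Applies the study's exclusion pipeline: (1) training sessions dropped
#' (by default); (2) all timed-out trials removed (overtime responses are
#' never recorded); (3) subjects excluded when their overall accuracy is
#' statistically indistinguishable from chance (two-sided exact binomial
#' test against 0.5 at `alpha`) AND their mean reported confidence falls
#' below `confidence_cut` — the formalization of excluding a subject who
#' performed at 54.9% with mean confidence 1.71; (4) an RT-analysis view
#' restricted to correct trials. The operation is idempotent and the
#' exclusion report reconciles exactly with the input row count.
#'
#' @param results Trial-log data frame (schema of [run_session()]).
#' @param drop_training Drop rows with `training == TRUE` (default TRUE).
#' @param alpha Significance level of the chance-level test (default 0.05).
#' @param confidence_cut Mean-confidence threshold for exclusion
#'   (default 2.0).
#' @return List: `trials` (analysable trials), `rt_trials` (correct trials
#'   only, for RT analyses), `excluded_subjects` (data frame with the
#'   per-subject test), `report` (row-count reconciliation).
#' @export
filter_trials <- function(results, drop_training = TRUE, alpha = 0.05,
                          confidence_cut = 2.0) {
  req <- c("subject", "training", "correct", "rt_ms", "confidence", "timed_out")
  if (!all(req %in% names(results))) {
    stop("trial log is missing columns: ",
         paste(setdiff(req, names(results)), collapse = ", "), call. = FALSE)
  }
  n_in <- nrow(results)
  x <- results
  n_training <- 0L
  if (drop_training) {
    n_training <- sum(x$training)
    x <- x[!x$training, , drop = FALSE]
  }
  n_overtime <- sum(x$timed_out)
  x <- x[!x$timed_out, , drop = FALSE]

  subj_tests <- do.call(rbind, lapply(split(x, x$subject), function(d) {
    n_correct <- sum(d$correct)
    bt <- stats::binom.test(n_correct, nrow(d), p = 0.5)
    data.frame(subject = d$subject[1], n_trials = nrow(d),
               accuracy = n_correct / nrow(d),
               p_chance = bt$p.value,
               mean_confidence = mean(d$confidence),
               stringsAsFactors = FALSE)
  }))
  rownames(subj_tests) <- NULL
  subj_tests$excluded <- subj_tests$p_chance > alpha &
    subj_tests$mean_confidence < confidence_cut
  bad <- subj_tests$subject[subj_tests$excluded]
  n_excluded_subj <- sum(x$subject %in% bad)
  x <- x[!x$subject %in% bad, , drop = FALSE]

  list(
    trials = x,
    rt_trials = x[x$correct, , drop = FALSE],
    excluded_subjects = subj_tests,
    report = data.frame(
      stage = c("input", "training", "overtime", "excluded_subjects", "analysable"),
      n = c(n_in, n_training, n_overtime, n_excluded_subj, nrow(x))
    )
  )
}

#' Per-condition summary table
#'
#' Cellwise means and standard deviations of accuracy, reaction time and
#' confidence over trials — the shape of the study's measurement tables.
#' Accuracy is summarized on the per-trial 0/100 indicator (so an SD like
#' "98.84 (10.78)" arises from Bernoulli trials), RT statistics use correct
#' trials only, and an empty cell yields NA, not zero.
#'
#' @param trials Filtered trial log (see [filter_trials()]).
#' @param by Grouping columns (default dimension x displacement axis).
#' @return Data frame with one row per cell: grouping columns, `n_trials`,
#'   `accuracy_pct`, `accuracy_sd`, `rt_mean`, `rt_sd` (ms, correct trials),
#'   `confidence_mean`, `confidence_sd`.
#' @export
summarize_conditions <- function(trials, by = c("dimension", "axis")) {
  stopifnot(all(by %in% names(trials)))
  cells <- unique(trials[, by, drop = FALSE])
  cells <- cells[do.call(order, as.list(cells)), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- rep(TRUE, nrow(trials))
    for (cname in by) sel <- sel & trials[[cname]] == cells[[cname]][i]
    d <- trials[sel, , drop = FALSE]
    acc <- 100 * as.numeric(d$correct)
    rt <- d$rt_ms[d$correct]
    cbind(cells[i, , drop = FALSE],
          data.frame(
            n_trials = nrow(d),
            accuracy_pct = mean(acc),
            accuracy_sd = if (nrow(d) > 1) stats::sd(acc) else NA_real_,
            rt_mean = if (length(rt)) mean(rt) else NA_real_,
            rt_sd = if (length(rt) > 1) stats::sd(rt) else NA_real_,
            confidence_mean = mean(d$confidence),
            confidence_sd = if (nrow(d) > 1) stats::sd(d$confidence) else NA_real_
          ))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Confidence-reaction-time correlation
#'
#' Pearson correlation between trial-level confidence reports and reaction
#' times (the study observed r = -0.52: slower decisions carry lower
#' confidence).
#'
#' @param trials Filtered trial log with `confidence` and `rt_ms`.
#' @return List with `r`, `p`, `n`, and the underlying `htest`.
#' @export
confidence_rt_correlation <- function(trials) {
  ok <- stats::complete.cases(trials[, c("confidence", "rt_ms")])
  d <- trials[ok, ]
  if (nrow(d) < 3L) stop("need >= 3 paired observations", call. = FALSE)
  if (stats::sd(d$confidence) == 0 || stats::sd(d$rt_ms) == 0) {
    stop("undefined correlation: zero variance in confidence or RT",
         call. = FALSE)
  }
  ct <- stats::cor.test(d$confidence, d$rt_ms, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(d), test = ct)
}

#' Per-trial head-movement statistics
#'
#' For each trial and axis, the median view angle and its percentile range
#' — third quartile minus first quartile of the ~54-sample series, a
#' spread measure robust to outliers. Quartiles use R's default type-7
#' interpolation (documented choice; the source is silent on the rule).
#'
#' @param traces Long trace data frame: `trial`, `sample_index`,
#'   `angle_x`, `angle_y`, `angle_z`, plus any key columns (subject,
#'   session, ...) named in `by`.
#' @param by Key columns identifying a trial (default `"trial"`).
#' @return Data frame with one row per trial: key columns, then per axis
#'   `median_<axis>` and `range_<axis>` (Q3 - Q1), deg.
#' @export
head_movement_stats <- function(traces, by = "trial") {
  stopifnot(all(by %in% names(traces)),
            all(c("angle_x", "angle_y", "angle_z") %in% names(traces)))
  key <- interaction(traces[, by, drop = FALSE], drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(traces, key), function(d) {
    if (nrow(d) < 2L) stop("trace must have >= 2 samples", call. = FALSE)
    out <- d[1, by, drop = FALSE]
    for (ax in c("x", "y", "z")) {
      a <- d[[paste0("angle_", ax)]]
      qs <- stats::quantile(a, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      out[[paste0("median_", ax)]] <- qs[2]
      out[[paste0("range_", ax)]] <- qs[3] - qs[1]
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[do.call(order, as.list(out[, by, drop = FALSE])), , drop = FALSE]
}

#' View angles from raw head poses
#'
#' Computes, per sample, the angles about the x, y and z axes between the
#' headset's viewing direction and the vector from the headset's position
#' to the object's position. The per-axis angle is measured between the two
#' vectors after projecting both onto the plane perpendicular to that axis
#' (i.e. the rotation about the axis separating them); samples whose
#' projection degenerates return 0.
#'
#' @param positions N x 3 matrix of headset positions, cm.
#' @param directions N x 3 matrix of unit viewing directions.
#' @param object_position Length-3 object position (default origin).
#' @return N x 3 matrix of angles (deg), columns `angle_x`, `angle_y`,
#'   `angle_z`.
#' @export
visual_angles <- function(positions, directions, object_position = c(0, 0, 0)) {
  positions <- as.matrix(positions)
  directions <- as.matrix(directions)
  stopifnot(ncol(positions) == 3L, ncol(directions) == 3L,
            nrow(positions) == nrow(directions))
  to_obj <- sweep(-positions, 2, -object_position) # object - position
  out <- matrix(0, nrow(positions), 3L,
                dimnames = list(NULL, paste0("angle_", c("x", "y", "z"))))
  for (a in 1:3) {
    keep <- setdiff(1:3, a)
    u <- directions[, keep, drop = FALSE]
    v <- to_obj[, keep, drop = FALSE]
    nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
    ok <- nu > 1e-12 & nv > 1e-12
    cosang <- pmin(1, pmax(-1, rowSums(u * v) / (nu * nv)))
    out[ok, a] <- acos(cosang[ok]) * 180 / pi
  }
  out
}
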