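#' Export / import a wireframe as Wavefront OBJ
#'
#' Writes vertices as `v` records and edges as 2-vertex `l` (polyline)
#' records. OBJ is a 3D format: 4D wireframes must be projected (see
#' [project_4d_to_3d()]) before export.
#'
#' @param obj A 3D `wireframe` (or 2D, padded with z = 0).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wireframe_obj <- function(obj, path) {
  stopifnot(inherits(obj, "wireframe"))
  if (obj$dimension > 3L) {
    stop("OBJ export supports 3D wireframes only; project 4D objects first",
         call. = FALSE)
  }
  v <- obj$vertices
  if (ncol(v) < 3L) v <- cbind(v, matrix(0, nrow(v), 3L - ncol(v)))
  lines <- c(
    sprintf("# rigid4d wireframe: side %g cm, irregularity %g",
            obj$side_length, obj$irregularity),
    sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
    sprintf("l %d %d", obj$edges[, 1], obj$edges[, 2])
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_wireframe_obj
#' @param side_length,irregularity Metadata not carried by OBJ; supplied on
#'   read.
#' @export
read_wireframe_obj <- function(path, side_length = NA_real_,
                               irregularity = 0) {
  lines <- readLines(path)
  vl <- grep("^v ", lines, value = TRUE)
  el <- grep("^l ", lines, value = TRUE)
  vertices <- do.call(rbind, lapply(strsplit(vl, "\\s+"),
                                    function(x) as.numeric(x[2:4])))
  colnames(vertices) <- AXIS_NAMES[1:3]
  edges <- do.call(rbind, lapply(strsplit(el, "\\s+"),
                                 function(x) as.integer(x[2:3])))
  dimnames(edges) <- list(NULL, c("from", "to"))
  structure(
    list(dimension = 3L, vertices = vertices, edges = edges,
         side_length = side_length, irregularity = irregularity, seed = NULL),
    class = "wireframe"
  )
}

#' Export / import a wireframe as JSON
#'
#' A JSON dialect carrying dimension, vertices, edges, side length,
#' irregularity level and seed; lossless for any dimension.
#'
#' @param obj A `wireframe`.
#' @param path Output file path.
#' @return `path` (write) / a `wireframe` (read).
#' @export
write_wireframe_json <- function(obj, path) {
  stopifnot(inherits(obj, "wireframe"))
  jsonlite::write_json(
    list(dimension = obj$dimension,
         vertices = unname(apply(obj$vertices, 1, as.numeric, simplify = FALSE)),
         edges = unname(apply(obj$edges, 1, as.integer, simplify = FALSE)),
         side_length = obj$side_length,
         irregularity = obj$irregularity,
         seed = obj$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_wireframe_json
#' @export
read_wireframe_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  vertices <- matrix(unlist(x$vertices), ncol = x$dimension, byrow = is.list(x$vertices))
  if (!is.list(x$vertices)) vertices <- as.matrix(x$vertices)
  colnames(vertices) <- AXIS_NAMES[seq_len(x$dimension)]
  edges <- if (is.list(x$edges)) matrix(unlist(x$edges), ncol = 2L, byrow = TRUE)
           else as.matrix(x$edges)
  dimnames(edges) <- list(NULL, c("from", "to"))
  structure(
    list(dimension = as.integer(x$dimension), vertices = vertices,
         edges = edges, side_length = x$side_length,
         irregularity = x$irregularity, seed = x$seed),
    class = "wireframe"
  )
}

#' Export a trajectory as a long CSV table
#'
#' One row per (frame, vertex): `frame`, `t`, `vertex`, then one column per
#' coordinate (x, y, z, w as applicable), cm.
#'
#' @param traj A `trajectory_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory_set"))
  dims <- dim(traj$frames)
  coords <- AXIS_NAMES[seq_len(dims[3])]
  grid <- expand.grid(vertex = seq_len(dims[2]), frame = seq_len(dims[1]),
                      KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(frame = grid$frame, t = traj$frame_times[grid$frame],
                    vertex = grid$vertex)
  for (k in seq_along(coords)) {
    out[[coords[k]]] <- traj$frames[cbind(grid$frame, grid$vertex, k)]
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read / write trial logs and head-pose traces as CSV
#'
#' The trial-log schema is one row per trial: subject, experiment, session,
#' training, block, trial, dimension, axis, irregularity, rigid_position,
#' choice, correct, rt_ms, confidence, timed_out. Traces are long-format:
#' key columns plus sample_index, t, angle_x, angle_y, angle_z (deg).
#'
#' @param x Data frame to write.
#' @param path File path.
#' @return `path` (write) / data frame (read).
#' @export
write_results_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cname in intersect(c("training", "correct", "timed_out"), names(x))) {
    x[[cname]] <- as.logical(x[[cname]])
  }
  x
}

#' Read / write observer profiles as YAML
#'
#' @param profile An [observer_profile()].
#' @param path File path.
#' @return `path` (write) / an `observer_profile` (read).
#' @export
write_profile_yaml <- function(profile, path) {
  stopifnot(inherits(profile, "observer_profile"))
  yaml::write_yaml(
    list(cells = lapply(seq_len(nrow(profile$cells)), function(i) {
           as.list(profile$cells[i, c("dimension", "axis", "accuracy",
                                      "rt_mean", "rt_sd", "conf_mean",
                                      "conf_sd")])
         }),
         confidence_rt_coupling = profile$confidence_rt_coupling,
         timeout_rate = profile$timeout_rate,
         head_median = as.list(profile$head_median),
         head_iqr = as.list(profile$head_iqr)),
    path)
  invisible(path)
}

#' @rdname write_profile_yaml
#' @export
read_profile_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  cells <- do.call(rbind, lapply(x$cells, as.data.frame))
  observer_profile(cells,
                   confidence_rt_coupling = x$confidence_rt_coupling,
                   timeout_rate = x$timeout_rate,
                   head_median = unlist(x$head_median),
                   head_iqr = unlist(x$head_iqr))
}

#' Pipeline configuration
#'
#' Bundles every tunable of the generate -> simulate -> analyse pipeline
#' with an explicit master seed, so a configuration maps to exactly one
#' artifact bundle.
#'
#' @param experiments Which experiments to simulate (subset of 1:2).
#' @param n_subjects Cohort size (default 5).
#' @param seed Master seed; all per-session and per-trial seeds derive
#'   from it.
#' @param profiles Observer profile bundle (defaults: table1/table2).
#' @param drop_training,alpha,confidence_cut Filtering options (see
#'   [filter_trials()]).
#' @param lmm_fixed Fixed factors of the mixed-model ANOVA.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(experiments = c(1, 2), n_subjects = 5,
                            seed = 1L,
                            profiles = list(table1 = default_profile("table1"),
                                            table2 = default_profile("table2")),
                            drop_training = TRUE, alpha = 0.05,
                            confidence_cut = 2.0,
                            lmm_fixed = c("axis", "dimension")) {
  if (!all(experiments %in% c(1, 2)) || !length(experiments)) {
    stop("unknown experiment id: ",
         paste(setdiff(experiments, c(1, 2)), collapse = ", "), call. = FALSE)
  }
  stopifnot(n_subjects >= 1)
  structure(
    list(experiments = experiments, n_subjects = n_subjects, seed = seed,
         profiles = profiles, drop_training = drop_training, alpha = alpha,
         confidence_cut = confidence_cut, lmm_fixed = lmm_fixed),
    class = "pipeline_config"
  )
}

#' Run the full pipeline
#'
#' Executes generate -> run-synthetic -> analyse for the configured cohort:
#' builds and runs every session against the synthetic observer, filters
#' the pooled trial log, and computes per-experiment condition summaries,
#' mixed-model ANOVAs (accuracy, RT, confidence), the confidence-RT
#' correlation, and head-movement statistics for the active-headset
#' experiment. Identical configurations produce identical bundles; when
#' `out_dir` is given, the trial log, traces, summaries and a JSON
#' manifest (config echo, seed, package version) are also written there.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return List: `results`, `traces`, `filtered`, `summaries` (per
#'   experiment), `anova` (per experiment and measure), `confidence_rt`,
#'   `head_stats`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- simulate_cohort(n_subjects = config$n_subjects, seed = config$seed,
                         profiles = config$profiles,
                         experiments = config$experiments)
  filt <- filter_trials(sim$results, drop_training = config$drop_training,
                        alpha = config$alpha,
                        confidence_cut = config$confidence_cut)
  summaries <- list(); anovas <- list()
  for (e in config$experiments) {
    d <- filt$trials[filt$trials$experiment == e, , drop = FALSE]
    key <- paste0("experiment", e)
    summaries[[key]] <- summarize_conditions(d)
    anovas[[key]] <- list(
      accuracy = lmm_anova(d, "correct", config$lmm_fixed),
      rt = lmm_anova(d[d$correct, , drop = FALSE], "rt_ms", config$lmm_fixed),
      confidence = lmm_anova(d, "confidence", config$lmm_fixed)
    )
  }
  conf_rt <- confidence_rt_correlation(filt$trials)
  head_stats <- NULL
  if (2 %in% config$experiments) {
    tr2 <- sim$traces[sim$traces$experiment == 2, , drop = FALSE]
    head_stats <- head_movement_stats(tr2, by = c("subject", "session", "trial"))
  }
  bundle <- list(results = sim$results, traces = sim$traces, filtered = filt,
                 summaries = summaries, anova = anovas,
                 confidence_rt = conf_rt, head_stats = head_stats,
                 config = config)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_results_csv(bundle$results, file.path(out_dir, "trials.csv"))
  write_results_csv(bundle$traces, file.path(out_dir, "head_traces.csv"))
  for (key in names(bundle$summaries)) {
    write_results_csv(bundle$summaries[[key]],
                      file.path(out_dir, paste0("summary_", key, ".csv")))
    for (m in names(bundle$anova[[key]])) {
      write_results_csv(bundle$anova[[key]][[m]],
                        file.path(out_dir, paste0("anova_", key, "_", m, ".csv")))
    }
  }
  if (!is.null(bundle$head_stats)) {
    write_results_csv(bundle$head_stats, file.path(out_dir, "head_stats.csv"))
  }
  cfg <- bundle$config
  manifest <- list(
    package = "rigid4d",
    version = as.character(utils::packageVersion("rigid4d")),
    seed = cfg$seed,
    experiments = cfg$experiments,
    n_subjects = cfg$n_subjects,
    drop_training = cfg$drop_training,
    alpha = cfg$alpha,
    confidence_cut = cfg$confidence_cut,
    lmm_fixed = cfg$lmm_fixed,
    ddf_method = "satterthwaite",
    confidence_rt = list(r = bundle$confidence_rt$r,
                         p = bundle$confidence_rt$p,
                         n = bundle$confidence_rt$n),
    exclusion_report = as.list(stats::setNames(bundle$filtered$report$n,
                                               bundle$filtered$report$stage))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
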