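# Shared fixtures: small, fast stimulus specs used across test files.

cube100 <- function() make_hypercube(3, 100)
tess100 <- function() make_hypercube(4, 100)

# Short, jitter-free specs keep property loops cheap.
quick_spec <- function(kind, dimension, shear_axis = NULL, ...) {
  motion_spec(kind, dimension = dimension, shear_axis = shear_axis,
              jitter_amplitude = 0, duration = 0.5, frame_rate = 20, ...)
}

# A tiny hand-made trial log: n trials for one subject/cell.
toy_log <- function(correct, rt = NULL, confidence = NULL, timed_out = NULL,
                    subject = "S1", dimension = 3L, axis = "x",
                    training = FALSE) {
  n <- length(correct)
  data.frame(
    subject = subject, experiment = 1L, session = 2L, training = training,
    block = 1L, trial = seq_len(n), dimension = dimension, axis = axis,
    irregularity = 0.12, rigid_position = "top",
    choice = ifelse(is.na(correct), "none", ifelse(correct, "top", "bottom")),
    correct = correct,
    rt_ms = rt %||% rep(500, n),
    confidence = confidence %||% rep(3L, n),
    timed_out = timed_out %||% rep(FALSE, n),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
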