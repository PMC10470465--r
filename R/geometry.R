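#' Construct a regular d-dimensional hypercube wireframe
#'
#' Builds the wireframe of a regular hypercube of dimension `dimension`
#' centred on the origin: vertices are all sign combinations of
#' `side_length / 2` and edges join every pair of vertices that differ in
#' exactly one coordinate. A cube (d = 3) has 8 vertices and 12 edges; a
#' tesseract (d = 4) has 16 vertices and 32 edges; in general `2^d` vertices
#' and `d * 2^(d - 1)` edges.
#'
#' @param dimension Integer >= 2. The experiments use 3 and 4.
#' @param side_length Edge length in cm (default 100, the stimulus size).
#' @return An object of class `wireframe`: a list with `dimension`,
#'   `vertices` (a `2^d` x `d` matrix, cm), `edges` (an `E` x 2 matrix of
#'   1-based vertex indices), `side_length` and `irregularity` (0 for a
#'   regular object).
#' @examples
#' tess <- make_hypercube(4, 100)
#' nrow(tess$vertices) # 16
#' nrow(tess$edges)    # 32
#' @seealso [perturb_vertices()] for the irregularity manipulation.
#' @export
make_hypercube <- function(dimension, side_length = 100) {
  if (!is.numeric(dimension) || length(dimension) != 1L ||
      dimension != round(dimension) || dimension < 2) {
    stop("`dimension` must be a single integer >= 2", call. = FALSE)
  }
  if (!is.numeric(side_length) || length(side_length) != 1L || side_length <= 0) {
    stop("`side_length` must be a single positive number", call. = FALSE)
  }
  d <- as.integer(dimension)
  n <- 2L^d
  # vertex i has coordinate k = +s/2 when bit k of (i - 1) is set
  bits <- t(vapply(seq_len(n) - 1L,
                   function(i) as.integer(bitwAnd(bitwShiftR(i, 0:(d - 1L)), 1L)),
                   integer(d)))
  vertices <- (bits - 0.5) * side_length
  colnames(vertices) <- AXIS_NAMES[seq_len(d)]
  edges <- which(as.matrix(stats::dist(bits, method = "manhattan")) == 1,
                 arr.ind = TRUE)
  edges <- edges[edges[, 1] < edges[, 2], , drop = FALSE]
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  dimnames(edges) <- list(NULL, c("from", "to"))
  structure(
    list(dimension = d, vertices = vertices, edges = edges,
         side_length = side_length, irregularity = 0, seed = NULL),
    class = "wireframe"
  )
}

#' Apply the irregularity perturbation to a wireframe
#'
#' Displaces every vertex by a vector of exact norm
#' `level * side_length` in a uniformly random direction, producing the
#' irregular ("distorted") stimuli. For 4D objects the displacement is, by
#' default, confined to the first three coordinates (x, y, z) with the
#' fourth coordinate untouched, i.e. the positional shifts act at the
#' three-dimensional level; `space = "full"` instead draws the direction on
#' the full d-sphere for sensitivity studies.
#'
#' @param obj A `wireframe`, normally unperturbed.
#' @param level Displacement as a fraction of side length. The stimulus set
#'   uses 0, 0.12, 0.18 and 0.24 (i.e. 12/18/24 cm at side 100 cm); other
#'   non-negative values are accepted with a warning.
#' @param seed Integer seed; the perturbation is deterministic given `seed`.
#' @param space `"xyz"` (default) or `"full"`; ignored for d <= 3.
#' @return A new `wireframe` with displaced vertices and `irregularity`
#'   set to `level`.
#' @export
perturb_vertices <- function(obj, level, seed = NULL, space = c("xyz", "full")) {
  stopifnot(inherits(obj, "wireframe"))
  space <- match.arg(space)
  if (!is.numeric(level) || length(level) != 1L || level < 0) {
    stop("`level` must be a single non-negative number", call. = FALSE)
  }
  if (!isTRUE(all.equal(level, 0)) &&
      !any(vapply(c(0.12, 0.18, 0.24), function(l) isTRUE(all.equal(level, l)),
                  logical(1)))) {
    warning("irregularity level ", level,
            " is outside the standard set {0, 0.12, 0.18, 0.24}", call. = FALSE)
  }
  if (level == 0) return(obj)
  d <- obj$dimension
  pd <- if (space == "xyz" && d > 3) 3L else d # perturbation subspace
  n <- nrow(obj$vertices)
  disp <- with_seed(seed, random_unit_vectors(n, pd)) * level * obj$side_length
  vertices <- obj$vertices
  vertices[, seq_len(pd)] <- vertices[, seq_len(pd)] + disp
  out <- obj
  out$vertices <- vertices
  out$irregularity <- level
  out$seed <- seed
  out
}

#' @export
print.wireframe <- function(x, ...) {
  cat(sprintf("<wireframe> %dD hypercube: %d vertices, %d edges, side %g cm",
              x$dimension, nrow(x$vertices), nrow(x$edges), x$side_length))
  if (x$irregularity > 0) {
    cat(sprintf(", irregularity %.2f (%g cm)", x$irregularity,
                x$irregularity * x$side_length))
  }
  cat("\n")
  invisible(x)
}

# All pairwise inter-vertex distances (a numeric vector, stable order).
pairwise_distances <- function(vertices) as.numeric(stats::dist(vertices))

edge_lengths <- function(obj) {
  sqrt(rowSums((obj$vertices[obj$edges[, 1], , drop = FALSE] -
                  obj$vertices[obj$edges[, 2], , drop = FALSE])^2))
}
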