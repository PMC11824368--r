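# Reaction paths as piecewise-linear curves in flattened 3N-space, and the
# two exact field oracles (tangent guidance and denoising) computed from them.

#' Build a reaction path from a sequence of frames
#'
#' A reaction path (RP) is a discretized curve in the flattened
#' 3N-dimensional space of atomic Cartesian coordinates, parameterized by
#' arclength `s` from 0 (initial state, IS) to the total length `L` (final
#' state, FS). The path is treated as piecewise linear between stored frames.
#'
#' @param frames either a numeric matrix with one row per frame, or a list of
#'   per-frame coordinate matrices (N atoms x 3). 2D toy frames (two columns)
#'   are padded with a zero third coordinate.
#' @param atomic_numbers optional integer vector of atomic numbers (length N);
#'   absent for abstract toy paths.
#' @param label optional identifier for the path.
#' @return an object of class `reaction_path` with elements `points`
#'   (S x D matrix of flattened coordinates), `arclengths` (length S,
#'   `arclengths[1] == 0`), `total_length`, `n_atoms`, `atomic_numbers`,
#'   `label`.
#' @details Duplicate consecutive frames are collapsed. Arclengths are
#'   cumulative Euclidean distances between consecutive flattened frames, so
#'   they are strictly increasing and the final value equals the path length.
#' @examples
#' p <- build_path(rbind(c(0, 0), c(1, 0), c(1, 1)))
#' p$arclengths  # 0 1 2
#' @export
build_path <- function(frames, atomic_numbers = NULL, label = NULL) {
  pts <- as_frame_matrix(frames)
  dimnames(pts) <- NULL
  if (nrow(pts) < 2L) stop("a reaction path needs at least 2 frames")
  # collapse duplicate consecutive frames
  seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  keep <- c(TRUE, seg > 1e-12)
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < 2L) stop("degenerate path: fewer than 2 distinct frames")
  seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  n_atoms <- ncol(pts) %/% 3L
  if (!is.null(atomic_numbers) && length(atomic_numbers) != n_atoms)
    stop("atomic_numbers length does not match atom count")
  structure(
    list(points = pts, arclengths = s, total_length = s[length(s)],
         n_atoms = n_atoms, atomic_numbers = atomic_numbers, label = label),
    class = "reaction_path")
}

# Coerce frames (list of N x 3 matrices, or S x D matrix, 2 cols padded to 3)
# to an S x D matrix of flattened coordinates.
as_frame_matrix <- function(frames) {
  if (is.list(frames) && !is.data.frame(frames)) {
    dims <- vapply(frames, function(f) length(as_coord_vector(f)), integer(1))
    if (length(unique(dims)) != 1L) stop("inconsistent atom counts across frames")
    return(do.call(rbind, lapply(frames, as_coord_vector)))
  }
  frames <- as.matrix(frames)
  if (ncol(frames) == 2L) frames <- cbind(frames, 0)
  if (ncol(frames) %% 3L != 0L) stop("frame width must be a multiple of 3")
  frames
}

# Coerce a single frame (N x 3 matrix, length-2 point, or flat vector) to a
# flattened coordinate vector (row-major over atoms).
as_coord_vector <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) == 2L) x <- cbind(x, 0)
    if (ncol(x) != 3L) stop("coordinate matrices must have 3 columns")
    return(as.vector(t(x)))
  }
  x <- as.numeric(x)
  if (length(x) == 2L) x <- c(x, 0)
  if (length(x) %% 3L != 0L) stop("coordinate length must be a multiple of 3")
  x
}

# Reshape a flattened coordinate vector into an N x 3 matrix.
coords_to_matrix <- function(x) matrix(x, ncol = 3L, byrow = TRUE)

#' @export
print.reaction_path <- function(x, ...) {
  cat(sprintf("<reaction_path%s: %d frames, %d atom(s), length %.4g>\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              nrow(x$points), x$n_atoms, x$total_length))
  invisible(x)
}

#' Project a coordinate onto a reaction path
#'
#' Finds the nearest point on the piecewise-linear path to `x`, allowing
#' projections into segment interiors (continuous arclength). Projections
#' beyond an endpoint clamp to that endpoint.
#'
#' @param path a `reaction_path`.
#' @param x coordinates (flat vector, N x 3 matrix, or 2D point).
#' @return list with `s_hat` (arclength of nearest point), `x_near`
#'   (flattened nearest coordinates), `distance`, `segment` (1-based index of
#'   the segment containing the foot), `t_seg` (position of the foot within
#'   the segment, in `[0, 1]`; 0 or 1 means the foot is a polyline vertex),
#'   and `clamped` (TRUE when the foot lies exactly on a path endpoint
#'   reached by clamping).
#' @details Ties between equidistant segments are broken by the lowest
#'   segment index, so the result is deterministic.
#' @export
project_path <- function(path, x) {
  x <- as_coord_vector(x)
  pts <- path$points
  if (length(x) != ncol(pts)) stop("coordinate dimension does not match path")
  a <- pts[-nrow(pts), , drop = FALSE]
  b <- pts[-1L, , drop = FALSE]
  d <- b - a
  len2 <- rowSums(d^2)
  xa <- matrix(x, nrow(a), length(x), byrow = TRUE) - a
  tt <- rowSums(xa * d) / len2
  tt <- pmin(pmax(tt, 0), 1)
  foot <- a + d * tt
  dist2 <- rowSums((matrix(x, nrow(a), length(x), byrow = TRUE) - foot)^2)
  k <- which.min(dist2)  # which.min takes the first minimum: lowest index
  s_hat <- unname(path$arclengths[k] + tt[k] * sqrt(len2[k]))
  list(s_hat = s_hat,
       x_near = unname(foot[k, ]),
       distance = unname(sqrt(dist2[k])),
       segment = k,
       t_seg = unname(tt[k]),
       clamped = (k == 1L && tt[k] == 0) || (k == nrow(a) && tt[k] == 1))
}

#' Exact field oracles of a reference path
#'
#' Computes the two training-target fields at a coordinate `x`: the
#' transformation-guidance field `t_t`, the unit tangent of the path at the
#' nearest point oriented from IS to FS, and the denoising field `t_d`, the
#' vector from `x` to the nearest point on the path.
#'
#' @inheritParams project_path
#' @return list with `t_t` (unit flattened vector), `t_d` (flattened vector,
#'   length units), and the projection under `proj`.
#' @details At a vertex the tangent of the following segment is used; at the
#'   final vertex, the preceding segment. Integrating `t_t` from the IS
#'   traces the path; `t_d` restores off-path coordinates, playing the role
#'   of a score-model denoiser.
#' @export
oracle_fields <- function(path, x) {
  x <- as_coord_vector(x)
  pr <- project_path(path, x)
  pts <- path$points
  k <- pr$segment
  tangent <- pts[k + 1L, ] - pts[k, ]
  tangent <- tangent / sqrt(sum(tangent^2))
  list(t_t = tangent, t_d = pr$x_near - x, proj = pr)
}

#' Select the path with the shortest denoising field
#'
#' Among several reference paths sharing an atom count, returns the index of
#' the path whose nearest point is closest to `x` (minimal `\\|t_d\\|`).
#' Ties are broken by the lowest index.
#'
#' @param paths non-empty list of `reaction_path` objects.
#' @param x coordinates.
#' @return integer index into `paths`.
#' @export
select_nearest_path <- function(paths, x) {
  if (length(paths) == 0L) stop("empty path list")
  d <- vapply(paths, function(p) project_path(p, x)$distance, numeric(1))
  which.min(d)
}

#' Integrate a vector field from a starting coordinate
#'
#' Plain explicit Euler integration `x <- x + field_fn(x) * dt`, the
#' deterministic realization of following the combined generation field.
#'
#' @param field_fn function mapping a flattened coordinate vector to a
#'   flattened field vector.
#' @param x0 starting coordinates.
#' @param dt step size (> 0).
#' @param max_steps maximum number of Euler steps (>= 1).
#' @param stop_fn optional predicate on the current coordinates; when it
#'   returns TRUE the integration terminates with reason `stop_predicted`.
#' @return a `trajectory`: list with `frames` (matrix, one row per visited
#'   coordinate including `x0`), `n_steps`, `stop_reason` (one of
#'   `stop_predicted`, `max_steps`, `fixed_point`).
#' @export
integrate_field <- function(field_fn, x0, dt, max_steps, stop_fn = NULL) {
  stopifnot(dt > 0, max_steps >= 1)
  x <- as_coord_vector(x0)
  frames <- matrix(NA_real_, max_steps + 1L, length(x))
  frames[1L, ] <- x
  reason <- "max_steps"
  n <- 0L
  for (i in seq_len(max_steps)) {
    if (!is.null(stop_fn) && isTRUE(stop_fn(x))) { reason <- "stop_predicted"; break }
    v <- field_fn(x)
    if (!all(is.finite(v))) stop(sprintf("non-finite field value at step %d", i))
    step <- v * dt
    x <- x + step
    n <- i
    frames[i + 1L, ] <- x
    if (sqrt(sum(step^2)) < 1e-12) { reason <- "fixed_point"; break }
  }
  if (!is.null(stop_fn) && reason == "max_steps" && isTRUE(stop_fn(x)))
    reason <- "stop_predicted"
  structure(list(frames = frames[seq_len(n + 1L), , drop = FALSE],
                 n_steps = n, stop_reason = reason),
            class = "trajectory")
}
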