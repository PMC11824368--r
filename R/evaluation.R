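# Success criteria for generated paths (termination, correct final state,
# clean path) and basic structure-distance metrics.

diff_pairs_equal <- function(a, b) {
  setequal(pair_keys(a), pair_keys(b))
}

#' Did generation terminate within the step cap?
#'
#' @param gp a `generated_path`.
#' @param cap step cap (default 400).
#' @return TRUE iff the stop head fired and fewer than `cap` steps were
#'   taken.
#' @export
check_termination <- function(gp, cap = 400L) {
  isTRUE(gp$converged) && gp$n_steps < cap
}

#' Does the generated final state realize the expected reaction?
#'
#' Recomputes the bond/dihedral diff between the IS and the generated final
#' frame and compares it with the expected diff: the broken, formed, and
#' rotated pair sets must all match exactly.
#'
#' @param gp a `generated_path` over a molecular system.
#' @param IS the initial `structure3d`.
#' @param expected a `reaction_diff`.
#' @param ... passed to [diff_reaction()] (perception scale, threshold).
#' @return logical.
#' @export
check_final_state <- function(gp, IS, expected, ...) {
  zs <- if (!is.null(gp$atomic_numbers)) gp$atomic_numbers else IS$atomic_numbers
  fs <- structure3d(zs, coords_to_matrix(gp$final_state))
  d <- diff_reaction(IS, fs, ...)
  diff_pairs_equal(d$broken, expected$broken) &&
    diff_pairs_equal(d$formed, expected$formed) &&
    diff_pairs_equal(d$rotated, expected$rotated)
}

#' Is the generated path clean along its whole length?
#'
#' Passes iff [check_final_state()] passes and no intermediate frame shows a
#' bonding change or a large dihedral rotation outside the expected sets:
#' for every frame, the diff against the IS must be a subset of the expected
#' broken/formed/rotated pairs. Transient unrelated changes that heal by the
#' FS still fail.
#'
#' @inheritParams check_final_state
#' @return logical.
#' @export
check_path_clean <- function(gp, IS, expected, ...) {
  if (!check_final_state(gp, IS, expected, ...)) return(FALSE)
  zs <- if (!is.null(gp$atomic_numbers)) gp$atomic_numbers else IS$atomic_numbers
  exp_keys <- list(broken = pair_keys(expected$broken),
                   formed = pair_keys(expected$formed),
                   rotated = pair_keys(expected$rotated))
  frames <- gp$trajectory$frames
  for (k in seq_len(nrow(frames))) {
    d <- diff_reaction(IS, structure3d(zs, coords_to_matrix(frames[k, ])), ...)
    if (!all(pair_keys(d$broken) %in% exp_keys$broken)) return(FALSE)
    if (!all(pair_keys(d$formed) %in% exp_keys$formed)) return(FALSE)
    if (!all(pair_keys(d$rotated) %in% exp_keys$rotated)) return(FALSE)
  }
  TRUE
}

#' Root-sum-square distance between two structures
#'
#' `sqrt(sum_atoms ||a_i - b_i||^2)` with no alignment: frames are compared
#' in the shared coordinate frame of the IS. The companion per-atom RMSD is
#' `path_distance / sqrt(N)`.
#'
#' @param a,b coordinates (N x 3 matrices, `structure3d`, or flattened).
#' @return scalar distance.
#' @export
path_distance <- function(a, b) {
  av <- if (inherits(a, "structure3d")) as.vector(t(a$coords)) else as_coord_vector(a)
  bv <- if (inherits(b, "structure3d")) as.vector(t(b$coords)) else as_coord_vector(b)
  if (length(av) != length(bv)) stop("atom counts differ")
  sqrt(sum((av - bv)^2))
}

#' Minimum distance from a reference frame to any frame of a path
#'
#' Scans all frames of a trajectory/path and returns the smallest
#' [path_distance()] to the reference coordinates (e.g. a transition-state
#' structure).
#'
#' @param frames matrix of flattened frames (or a `reaction_path` /
#'   `trajectory` / `generated_path`).
#' @param ref reference coordinates.
#' @return scalar minimum distance.
#' @export
min_path_distance <- function(frames, ref) {
  if (inherits(frames, "generated_path")) frames <- frames$trajectory$frames
  if (inherits(frames, "trajectory")) frames <- frames$frames
  if (inherits(frames, "reaction_path")) frames <- frames$points
  rv <- if (inherits(ref, "structure3d")) as.vector(t(ref$coords)) else as_coord_vector(ref)
  min(sqrt(rowSums((frames - matrix(rv, nrow(frames), length(rv), byrow = TRUE))^2)))
}
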