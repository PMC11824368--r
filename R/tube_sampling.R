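# Training-data sampling: an Euler-Maruyama SDE that walks along a reference
# path while being pulled back to it, producing a tube-shaped cloud of
# coordinates around the path, plus exact field targets and stop labels.

#' Sample coordinates in a tube around a reference path
#'
#' Iterates the stochastic update
#' `x <- x + (t_t(x) + alpha * t_d(x)) * dt + g * sqrt(dt) * xi`
#' with standard-normal `xi` per coordinate, starting from the IS frame plus
#' one Gaussian perturbation of scale `g`. The drift moves forward along the
#' path while relaxing back onto it; the noise spreads the visited states
#' into a tube whose width is controlled by `g`.
#'
#' @param path a `reaction_path`.
#' @param alpha denoising coefficient in the drift (default 1, the
#'   theoretical Newton step).
#' @param g noise scale (>= 0).
#' @param dt step size (> 0).
#' @param n_steps number of SDE steps.
#' @param seed integer seed; the sampler is fully deterministic given it.
#' @return matrix with `n_steps + 1` rows of visited flattened coordinates.
#' @export
sample_tube <- function(path, alpha = 1, g = 0.1, dt = 0.1, n_steps = 100L,
                        seed = 1L) {
  stopifnot(dt > 0, g >= 0, n_steps >= 1)
  set.seed(seed)
  sample_tube_rng(path, alpha, g, dt, n_steps)
}

# Same as sample_tube but uses the current RNG state (for callers that
# manage seeding themselves, e.g. build_training_set).
sample_tube_rng <- function(path, alpha, g, dt, n_steps) {
  d <- ncol(path$points)
  x <- path$points[1L, ] + g * stats::rnorm(d)
  out <- matrix(NA_real_, n_steps + 1L, d)
  out[1L, ] <- x
  for (i in seq_len(n_steps)) {
    f <- oracle_fields(path, x)
    # the tangent drift is defined on s in [0, L); past the FS only the
    # denoising pull remains, so the endpoint is a convergence point
    tt <- if (f$proj$s_hat >= path$total_length - 1e-12) 0 else f$t_t
    x <- x + (tt + alpha * f$t_d) * dt + g * sqrt(dt) * stats::rnorm(d)
    if (!all(is.finite(x))) stop(sprintf("non-finite state at step %d", i))
    out[i + 1L, ] <- x
  }
  out
}

#' Label one coordinate as a training sample
#'
#' Computes the exact field targets at `x` from the path oracles and the
#' binary stop label: `t_fin = 1` iff the projection of `x` falls within
#' `delta_stop` of the total arclength from the FS end (projections clamped
#' to the final vertex included).
#'
#' @param path a `reaction_path`.
#' @param x coordinates.
#' @param condition optional per-edge condition matrix to attach.
#' @param conditional logical; when FALSE the sample is an unconditional
#'   training example (reaction components of the condition zeroed).
#' @param delta_stop stop-neighborhood size as a fraction of total arclength
#'   (default 0.02).
#' @return a `field_sample`: list with `x`, `x_IS`, `t_t`, `t_d`, `t_fin`,
#'   `conditional`, `condition`, `path_label`.
#' @export
make_sample <- function(path, x, condition = NULL, conditional = TRUE,
                        delta_stop = 0.02) {
  x <- as_coord_vector(x)
  f <- oracle_fields(path, x)
  t_fin <- as.integer(f$proj$s_hat >= path$total_length * (1 - delta_stop))
  structure(list(x = x, x_IS = path$points[1L, ], t_t = f$t_t, t_d = f$t_d,
                 t_fin = t_fin, conditional = isTRUE(conditional),
                 condition = condition, path_label = path$label,
                 atomic_numbers = path$atomic_numbers),
            class = "field_sample")
}

#' Build a balanced training set by tube sampling
#'
#' Repeatedly picks a reference path uniformly at random, draws a fresh
#' noise scale `g ~ U[g_range[1], g_range[2]]`, runs the tube sampler, and
#' labels every visited coordinate with the field targets of the path with
#' the shortest denoising field at that coordinate (the nearest path of the
#' whole family, which may differ from the tube's source path where tubes
#' overlap). Stop labels are rejection-balanced to a 1:1 ratio (within one
#' sample for odd `n_samples`), and each kept sample is marked conditional
#' with probability `p_conditional`.
#'
#' @param paths non-empty list of `reaction_path` objects.
#' @param n_samples number of samples to return (>= 2).
#' @param seed integer seed controlling every random choice.
#' @param g_range range of the per-run noise scale (default `c(0, 0.2)`).
#' @param p_conditional probability a sample is conditional (default 0.7).
#' @param alpha drift denoising coefficient (default 1).
#' @param dt SDE step size (default 0.1).
#' @param delta_stop stop-label neighborhood (see [make_sample()]).
#' @return a `training_set`: list with `samples` (list of `field_sample`),
#'   and `metadata` (seed, per-run g draws, conditional fraction).
#' @export
build_training_set <- function(paths, n_samples, seed = 1L,
                               g_range = c(0, 0.2), p_conditional = 0.7,
                               alpha = 1, dt = 0.1, delta_stop = 0.02) {
  if (length(paths) == 0L) stop("paths list is empty")
  stopifnot(n_samples >= 2L)
  set.seed(seed)
  n_stop <- n_samples %/% 2L
  n_go <- n_samples - n_stop
  pool_go <- list(); pool_stop <- list()
  g_draws <- numeric(0)
  guard <- 0L
  while ((length(pool_go) < n_go || length(pool_stop) < n_stop) && guard < 10000L) {
    guard <- guard + 1L
    pi_ <- sample.int(length(paths), 1L)
    path <- paths[[pi_]]
    g <- stats::runif(1, g_range[1], g_range[2])
    g_draws <- c(g_draws, g)
    # run long enough to traverse the whole path and dwell near the FS
    n_steps <- ceiling(path$total_length / dt * 1.5) + 10L
    xs <- sample_tube_rng(path, alpha, g, dt, n_steps)
    for (i in seq_len(nrow(xs))) {
      lab_path <- paths[[select_nearest_path(paths, xs[i, ])]]
      smp <- make_sample(lab_path, xs[i, ], conditional = TRUE,
                         delta_stop = delta_stop)
      smp$path_label <- path$label   # tube source identity, used for splits
      smp$g_used <- g
      if (smp$t_fin == 1L) {
        if (length(pool_stop) < n_stop) pool_stop[[length(pool_stop) + 1L]] <- smp
      } else {
        if (length(pool_go) < n_go) pool_go[[length(pool_go) + 1L]] <- smp
      }
    }
  }
  if (length(pool_go) < n_go || length(pool_stop) < n_stop)
    stop("could not balance stop labels; paths may be degenerate")
  samples <- c(pool_go, pool_stop)
  cond <- stats::runif(length(samples)) < p_conditional
  for (i in seq_along(samples)) samples[[i]]$conditional <- cond[i]
  structure(list(samples = samples,
                 metadata = list(seed = seed, g_draws = g_draws,
                                 conditional_fraction = mean(cond),
                                 n_samples = length(samples))),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  labs <- vapply(x$samples, `[[`, integer(1), "t_fin")
  cat(sprintf("<training_set: %d samples, %d stop-labeled, %.2f conditional>\n",
              length(x$samples), sum(labs), x$metadata$conditional_fraction))
  invisible(x)
}

#' Serialize / deserialize a training set as flat text files
#'
#' Writes `samples.csv` (one row per sample: coordinates, IS copy, targets,
#' stop label, conditional flag, noise scale, path label) and
#' `metadata.json` into `dir`.
#'
#' @param ts a `training_set`.
#' @param dir output (input) directory; created if needed.
#' @export
write_training_set <- function(ts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- length(ts$samples[[1L]]$x)
  rows <- t(vapply(ts$samples, function(s)
    c(s$x, s$x_IS, s$t_t, s$t_d, s$t_fin, as.integer(s$conditional),
      if (is.null(s$g_used)) NA_real_ else s$g_used), numeric(4L * d + 3L)))
  df <- as.data.frame(rows)
  names(df) <- c(paste0("x", seq_len(d)), paste0("xis", seq_len(d)),
                 paste0("tt", seq_len(d)), paste0("td", seq_len(d)),
                 "tfin", "conditional", "g")
  df$path <- vapply(ts$samples, function(s)
    if (is.null(s$path_label)) NA_character_ else s$path_label, character(1))
  utils::write.csv(df, file.path(dir, "samples.csv"), row.names = FALSE)
  jsonlite::write_json(ts$metadata, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_training_set
#' @export
read_training_set <- function(dir) {
  df <- utils::read.csv(file.path(dir, "samples.csv"), stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"), simplifyVector = TRUE)
  d <- sum(startsWith(names(df), "x") & !startsWith(names(df), "xis"))
  samples <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    structure(list(
      x = as.numeric(r[paste0("x", seq_len(d))]),
      x_IS = as.numeric(r[paste0("xis", seq_len(d))]),
      t_t = as.numeric(r[paste0("tt", seq_len(d))]),
      t_d = as.numeric(r[paste0("td", seq_len(d))]),
      t_fin = as.integer(r$tfin), conditional = as.logical(r$conditional),
      condition = NULL, path_label = if (is.na(r$path)) NULL else r$path,
      g_used = r$g), class = "field_sample")
  })
  structure(list(samples = samples, metadata = meta), class = "training_set")
}
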