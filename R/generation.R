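# Path generation from an IS by integrating predicted fields: plain or
# tangent-orthogonalized denoising, classifier-free guidance, learned
# stopping, and a hard step cap.

#' Generation configuration
#'
#' @param alpha denoising coefficient (1 is the theoretical Newton step;
#'   smaller values soften the pull back onto the path).
#' @param g noise scale of the optional white-noise term (default 0).
#' @param w_cfg classifier-free guidance strength (0 = unconditional,
#'   1 = conditional, larger values sharpen the conditioning).
#' @param dt integration step size (default 0.1).
#' @param max_steps hard step cap (default 400).
#' @param orthogonalize orthogonalize the denoising prediction against the
#'   guidance prediction before stepping (helps when the two predictions
#'   point in conflicting directions on out-of-distribution systems).
#' @param seed seed for the noise term.
#' @return object of class `generation_config`.
#' @export
generation_config <- function(alpha = 1, g = 0, w_cfg = 1, dt = 0.1,
                              max_steps = 400L, orthogonalize = FALSE,
                              seed = 1L) {
  stopifnot(dt > 0, max_steps >= 1L, alpha >= 0, g >= 0)
  structure(list(alpha = alpha, g = g, w_cfg = w_cfg, dt = dt,
                 max_steps = as.integer(max_steps),
                 orthogonalize = isTRUE(orthogonalize), seed = as.integer(seed)),
            class = "generation_config")
}

#' Orthogonalize the denoising prediction against the guidance prediction
#'
#' Removes from `y_d` its component along `y_t`, over the flattened
#' 3N-dimensional vectors: `y_d_perp = y_d - (y_d . y_t_hat) y_t_hat`.
#' A zero `y_t` leaves `y_d` unchanged.
#'
#' @param y_d,y_t per-atom vectors (N x 3 matrices or flattened vectors).
#' @return same shape as `y_d`.
#' @export
orthogonalize_field <- function(y_d, y_t) {
  was_mat <- is.matrix(y_d)
  d <- as_coord_vector(y_d); t_ <- as_coord_vector(y_t)
  nt <- sqrt(sum(t_^2))
  if (nt < 1e-12) return(y_d)
  th <- t_ / nt
  out <- d - sum(d * th) * th
  if (was_mat) coords_to_matrix(out) else out
}

#' Combine conditional and unconditional predictions (classifier-free guidance)
#'
#' Guided field: `y = y_uncond + w * (y_cond - y_uncond)`, applied to both
#' field heads (and, for completeness, to the uncertainty and stop scores).
#' With orthogonalization requested, the denoising head of each prediction
#' is first orthogonalized against its own guidance head, the guided
#' combination is formed, and the combined denoising field is orthogonalized
#' once more against the guided guidance field.
#'
#' @param pred_cond,pred_uncond field predictions on identical coordinates.
#' @param w_cfg guidance strength.
#' @param orthogonalize logical.
#' @return a combined field prediction (same shape as the inputs).
#' @export
cfg_combine <- function(pred_cond, pred_uncond, w_cfg, orthogonalize = FALSE) {
  pc <- pred_cond; pu <- pred_uncond
  if (orthogonalize) {
    pc$y_d <- orthogonalize_field(pc$y_d, pc$y_t)
    pu$y_d <- orthogonalize_field(pu$y_d, pu$y_t)
  }
  mix <- function(a, b) b + w_cfg * (a - b)
  out <- list(y_t = mix(pc$y_t, pu$y_t), y_d = mix(pc$y_d, pu$y_d),
              y_std = mix(pc$y_std, pu$y_std), y_f = mix(pc$y_f, pu$y_f))
  if (orthogonalize) out$y_d <- orthogonalize_field(out$y_d, out$y_t)
  out
}

#' One generation step
#'
#' `x' = x + (y_t + alpha * y_d*) dt + g sqrt(dt) xi`, where `y_d*` is the
#' (optionally orthogonalized) denoising prediction and `xi` is standard
#' normal per coordinate (drawn from the current RNG state).
#'
#' @param x flattened coordinates.
#' @param fields a field prediction (already guided/combined).
#' @param config a `generation_config`.
#' @return updated flattened coordinates.
#' @export
generation_step <- function(x, fields, config) {
  yt <- as_coord_vector(fields$y_t)
  yd <- as_coord_vector(fields$y_d)
  if (config$orthogonalize) yd <- orthogonalize_field(yd, yt)
  xn <- x + (yt + config$alpha * yd) * config$dt
  if (config$g > 0)
    xn <- xn + config$g * sqrt(config$dt) * stats::rnorm(length(x))
  if (!all(is.finite(xn))) stop("non-finite coordinates after generation step")
  xn
}

#' Generate a reaction path from an initial state
#'
#' Starting at the IS, repeatedly evaluates the model (with classifier-free
#' guidance when a condition is supplied and `w_cfg != 1`), applies
#' [generation_step()], and stops when the stop head prefers stopping
#' (`y_f[2] > y_f[1]`, checked after each applied step) or the step cap is
#' reached. Every visited frame becomes part of the generated path, which is
#' the intended chain-of-state initial guess.
#'
#' @param model any model honouring [predict_fields()] (including
#'   [oracle_field_model()] stand-ins).
#' @param IS `structure3d` (molecular models) or flattened coordinates
#'   (toys).
#' @param condition optional `reaction_diff` condition.
#' @param config a `generation_config`.
#' @return object of class `generated_path`: list with `trajectory` (a
#'   `trajectory`), `converged` (stop predicted before the cap),
#'   `final_state` (flattened final coordinates), `n_steps`.
#' @export
generate_path <- function(model, IS, condition = NULL,
                          config = generation_config()) {
  is_struct <- inherits(IS, "structure3d")
  zs <- if (is_struct) IS$atomic_numbers else NULL
  x <- if (is_struct) as.vector(t(IS$coords)) else as_coord_vector(IS)
  x_IS <- x
  set.seed(config$seed)
  frames <- matrix(NA_real_, config$max_steps + 1L, length(x))
  frames[1L, ] <- x
  converged <- FALSE
  n <- 0L
  wrap <- function(xv) if (is_struct) structure3d(zs, coords_to_matrix(xv)) else xv
  wrap_is <- wrap(x_IS)
  for (i in seq_len(config$max_steps + 1L)) {
    use_cfg <- !is.null(condition) && config$w_cfg != 1
    pred <- predict_fields(model, wrap(x), wrap_is, condition = condition)
    if (use_cfg) {
      pred_u <- predict_fields(model, wrap(x), wrap_is, condition = NULL)
      pred <- cfg_combine(pred, pred_u, config$w_cfg, config$orthogonalize)
    }
    if (i > config$max_steps) break
    if (i > 1L && pred$y_f[2L] > pred$y_f[1L]) { converged <- TRUE; break }
    x <- generation_step(x, pred, config)
    n <- i
    frames[i + 1L, ] <- x
  }
  structure(list(
    trajectory = structure(list(frames = frames[seq_len(n + 1L), , drop = FALSE],
                                n_steps = n,
                                stop_reason = if (converged) "stop_predicted" else "max_steps"),
                           class = "trajectory"),
    converged = converged, final_state = x, n_steps = n,
    atomic_numbers = zs), class = "generated_path")
}

#' @export
print.generated_path <- function(x, ...) {
  cat(sprintf("<generated_path: %d steps, %s>\n", x$n_steps,
              if (x$converged) "stop predicted" else "step cap reached"))
  invisible(x)
}
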