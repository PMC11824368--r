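# Training losses (Gaussian NLL with predicted per-atom uncertainty, stop
# cross-entropy) and a desk-scale minibatch training loop for the dense toy
# baseline, with train/validation field-error tracking.

#' Gaussian negative log-likelihood of a field prediction
#'
#' Per-atom isotropic Gaussian model of the field targets: the covariance is
#' diagonal with one predicted standard deviation per atom, shared across
#' the XYZ directions. The loss is
#' `sum_a [ ||t_a - y_a||^2 / (2 sigma_a^2) + 3 log sigma_a ] + (3N/2) log(2 pi)`.
#' Constant terms are included so values are comparable across runs.
#' Predicting the uncertainty lets the model down-weight structures that are
#' hard to fit instead of distorting easy ones.
#'
#' @param y predicted per-atom vectors (N x 3 matrix or flattened vector).
#' @param t target per-atom vectors, same shape.
#' @param std per-atom standard deviations (> 0), length N.
#' @return scalar loss.
#' @details The sigma-stationary point at fixed residual `e_a` is
#'   `sigma_a^2 = ||e_a||^2 / 3`.
#' @export
field_nll <- function(y, t, std) {
  y <- if (is.matrix(y)) y else coords_to_matrix(as_coord_vector(y))
  t <- if (is.matrix(t)) t else coords_to_matrix(as_coord_vector(t))
  if (any(std <= 0)) stop("std must be positive")
  if (length(std) != nrow(y)) stop("one std per atom required")
  e2 <- rowSums((t - y)^2)
  sum(e2 / (2 * std^2) + 3 * log(std)) + (3 * nrow(y) / 2) * log(2 * pi)
}

#' Cross-entropy of the stop scores
#'
#' Softmax cross-entropy of the two stop scores against the binary stop
#' label (`t_fin = 1` means "stop").
#'
#' @param y_f numeric pair of scores (index 1: continue, index 2: stop).
#' @param t_fin 0 or 1.
#' @return scalar loss (`log 2` for equal scores).
#' @export
stop_ce <- function(y_f, t_fin) {
  stopifnot(length(y_f) == 2L, t_fin %in% c(0L, 1L))
  z <- y_f - max(y_f)
  -(z[t_fin + 1L] - log(sum(exp(z))))
}

# ---------------------------------------------------------------------------
# Toy training loop
# ---------------------------------------------------------------------------

# Stack a list of field_samples into batch matrices.
stack_samples <- function(samples) {
  d <- length(samples[[1L]]$x)
  list(X = t(vapply(samples, `[[`, numeric(d), "x")),
       XIS = t(vapply(samples, `[[`, numeric(d), "x_IS")),
       Tt = t(vapply(samples, `[[`, numeric(d), "t_t")),
       Td = t(vapply(samples, `[[`, numeric(d), "t_d")),
       Tf = vapply(samples, `[[`, integer(1), "t_fin"))
}

# Loss and parameter gradients for a toy-model batch. The whole flattened
# coordinate vector is treated as one pseudo-atom of dimension d for the
# uncertainty, matching the toy setting.
toy_loss_grad <- function(model, batch, want_grad = TRUE) {
  fw <- toy_forward(model, batch$X, batch$XIS)
  B <- nrow(batch$X); d <- model$d
  Et <- fw$Yt - batch$Tt
  Ed <- fw$Yd - batch$Td
  sig <- fw$Sig
  e2 <- rowSums(Et^2) + rowSums(Ed^2)
  zf <- fw$Zf - apply(fw$Zf, 1, max)
  logZ <- log(rowSums(exp(zf)))
  ce <- -(zf[cbind(seq_len(B), batch$Tf + 1L)] - logZ)
  loss <- mean(e2 / (2 * sig^2) + 2 * d * log(sig) + d * log(2 * pi) + ce)
  err_t <- mean(sqrt(rowSums(Et^2)))
  err_d <- mean(sqrt(rowSums(Ed^2)))
  if (!want_grad)
    return(list(loss = loss, err_t = err_t, err_d = err_d))

  # clamp backprop: identity inside the norm-2 ball, radial projection outside
  clamp_back <- function(G, R) {
    nr <- sqrt(rowSums(R^2))
    out <- G
    idx <- which(nr > 2)
    for (i in idx) {
      rh <- R[i, ] / nr[i]
      out[i, ] <- (2 / nr[i]) * (G[i, ] - sum(G[i, ] * rh) * rh)
    }
    out
  }
  Gyt <- Et / sig^2 / B
  Gyd <- Ed / sig^2 / B
  Grt <- clamp_back(Gyt, fw$Rt)
  Grd <- clamp_back(Gyd, fw$Rd)
  dsig <- (-e2 / sig^3 + 2 * d / sig) / B
  s01 <- stats::plogis(fw$As)
  Gas <- dsig * 0.9 * s01 * (1 - s01)
  P <- exp(zf) / rowSums(exp(zf))
  Gzf <- P
  Gzf[cbind(seq_len(B), batch$Tf + 1L)] <- Gzf[cbind(seq_len(B), batch$Tf + 1L)] - 1
  Gzf <- Gzf / B

  GZ2 <- Grt %*% model$Wt + Grd %*% model$Wd + outer(Gas, drop(model$ws)) +
    Gzf %*% model$Wf
  GZ2 <- GZ2 * (1 - fw$Z2^2)
  GZ1 <- (GZ2 %*% model$W2) * (1 - fw$Z1^2)

  grads <- list(
    Wt = t(Grt) %*% fw$Z2, bt = colSums(Grt),
    Wd = t(Grd) %*% fw$Z2, bd = colSums(Grd),
    ws = matrix(colSums(fw$Z2 * Gas), 1), bs = sum(Gas),
    Wf = t(Gzf) %*% fw$Z2, bf = colSums(Gzf),
    W2 = t(GZ2) %*% fw$Z1, b2 = colSums(GZ2),
    W1 = t(GZ1) %*% fw$U, b1 = colSums(GZ1))
  list(loss = loss, err_t = err_t, err_d = err_d, grads = grads)
}

#' Train the dense toy baseline on a tube-sampled training set
#'
#' Minibatch adaptive-moment (Adam) descent on the equal-weight sum of the
#' two field NLLs and the stop cross-entropy. The history records the
#' mean field errors `||t_t - y_t||` and `||t_d - y_d||` on the training
#' split and on a validation split held out by path identity.
#'
#' @param model a `toy_field_model`.
#' @param data a `training_set` whose samples carry path labels.
#' @param steps number of minibatch steps (default 2000).
#' @param batch_size minibatch size (default 64).
#' @param lr learning rate (default 1e-3).
#' @param valid_paths character vector of path labels held out for
#'   validation (default: the last label present).
#' @param log_every history logging interval in steps (default 100).
#' @param seed seed for minibatch shuffling.
#' @return list with `model` (trained), `history` (data.frame with columns
#'   step, train_t, valid_t, train_d, valid_d, loss).
#' @export
train_toy_model <- function(model, data, steps = 2000L, batch_size = 64L,
                            lr = 1e-3, valid_paths = NULL, log_every = 100L,
                            seed = 1L) {
  labs <- vapply(data$samples, function(s)
    if (is.null(s$path_label)) "" else s$path_label, character(1))
  if (is.null(valid_paths)) valid_paths <- utils::tail(sort(unique(labs)), 1L)
  valid_idx <- which(labs %in% valid_paths)
  train_idx <- setdiff(seq_along(data$samples), valid_idx)
  if (length(train_idx) == 0L) stop("no training samples after the split")
  train_b <- stack_samples(data$samples[train_idx])
  valid_b <- if (length(valid_idx) > 0L) stack_samples(data$samples[valid_idx]) else NULL

  set.seed(seed)
  pnames <- c("W1", "b1", "W2", "b2", "Wt", "bt", "Wd", "bd", "ws", "bs", "Wf", "bf")
  m1 <- lapply(pnames, function(p) model[[p]] * 0)
  m2 <- m1
  names(m1) <- names(m2) <- pnames
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  hist_rows <- list()
  n_tr <- nrow(train_b$X)
  for (step in seq_len(steps)) {
    idx <- sample.int(n_tr, min(batch_size, n_tr))
    batch <- list(X = train_b$X[idx, , drop = FALSE],
                  XIS = train_b$XIS[idx, , drop = FALSE],
                  Tt = train_b$Tt[idx, , drop = FALSE],
                  Td = train_b$Td[idx, , drop = FALSE],
                  Tf = train_b$Tf[idx])
    lg <- toy_loss_grad(model, batch)
    if (!is.finite(lg$loss)) stop(sprintf("training diverged at step %d", step))
    for (p in pnames) {
      g <- lg$grads[[p]]
      m1[[p]] <- beta1 * m1[[p]] + (1 - beta1) * g
      m2[[p]] <- beta2 * m2[[p]] + (1 - beta2) * g^2
      mh <- m1[[p]] / (1 - beta1^step)
      vh <- m2[[p]] / (1 - beta2^step)
      model[[p]] <- model[[p]] - lr * mh / (sqrt(vh) + eps)
    }
    if (step %% log_every == 0L || step == steps) {
      tr <- toy_loss_grad(model, train_b, want_grad = FALSE)
      va <- if (is.null(valid_b)) list(err_t = NA_real_, err_d = NA_real_) else
        toy_loss_grad(model, valid_b, want_grad = FALSE)
      hist_rows[[length(hist_rows) + 1L]] <-
        data.frame(step = step, train_t = tr$err_t, valid_t = va$err_t,
                   train_d = tr$err_d, valid_d = va$err_d, loss = tr$loss)
    }
  }
  list(model = model, history = do.call(rbind, hist_rows))
}

#' Evaluate the training losses of any field model on a sample batch
#'
#' Computes the equal-weight total loss (two field NLLs plus stop
#' cross-entropy) of a model's predictions on a list of `field_sample`
#' objects, without touching parameters. Works for any model honouring the
#' [predict_fields()] contract, including the equivariant model.
#'
#' @param model a field model.
#' @param samples list of `field_sample` objects.
#' @param ... passed to [predict_fields()].
#' @return list with `loss_t`, `loss_d`, `loss_f`, `total` (their sum).
#' @export
evaluate_losses <- function(model, samples, ...) {
  lt <- ld <- lf <- 0
  needs_struct <- inherits(model, "equivariant_field_model")
  for (s in samples) {
    if (needs_struct) {
      if (is.null(s$atomic_numbers))
        stop("equivariant models need samples with atomic numbers")
      pred <- predict_fields(model,
                             structure3d(s$atomic_numbers, coords_to_matrix(s$x)),
                             structure3d(s$atomic_numbers, coords_to_matrix(s$x_IS)),
                             ...)
    } else {
      pred <- predict_fields(model, s$x, s$x_IS, ...)
    }
    std <- pred$y_std
    if (length(std) == 1L && nrow(pred$y_t) > 1L) std <- rep(std, nrow(pred$y_t))
    lt <- lt + field_nll(pred$y_t, s$t_t, std)
    ld <- ld + field_nll(pred$y_d, s$t_d, std)
    lf <- lf + stop_ce(pred$y_f, s$t_fin)
  }
  n <- length(samples)
  list(loss_t = lt / n, loss_d = ld / n, loss_f = lf / n,
       total = (lt + ld + lf) / n)
}
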