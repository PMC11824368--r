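# Field models: the prediction contract shared by every model, inner-product
# decoding of bounded magnitudes, a dense baseline for low-dimensional toys,
# and a rotation/translation/permutation-equivariant graph-attention model
# operating on scalar (invariant) and vector (covariant) feature channels.

silu <- function(x) x / (1 + exp(-x))

#' Inner-product decoding of a bounded scalar
#'
#' Projects scalar features to logits, applies a softmax, and takes the
#' expectation against an evenly spaced array of bin values. The output is a
#' convex combination of the bins, hence always inside `[min(bins),
#' max(bins)]`. Field-magnitude heads use bins from -2 to 2 Angstrom in
#' steps of 0.1 (negative magnitudes flip the decoded direction);
#' uncertainty heads use bins from 0.1 to 1.0 Angstrom.
#'
#' @param logits numeric vector (one logit per bin) or matrix (rows decoded
#'   independently).
#' @param bins evenly spaced bin values; length must match the logit count.
#' @return scalar, or vector with one value per row.
#' @export
inner_product_decode <- function(logits, bins) {
  if (is.matrix(logits)) {
    if (ncol(logits) != length(bins)) stop("bin count mismatch")
    z <- logits - apply(logits, 1, max)
    p <- exp(z) / rowSums(exp(z))
    return(drop(p %*% bins))
  }
  if (length(logits) != length(bins)) stop("bin count mismatch")
  z <- logits - max(logits)
  p <- exp(z) / sum(exp(z))
  sum(p * bins)
}

magnitude_bins <- function() seq(-2, 2, by = 0.1)
std_bins <- function() seq(0.1, 1.0, by = 0.1)

#' Evaluate a field model
#'
#' Unified prediction contract: every model maps a current structure, its IS
#' copy, and an optional reaction condition to a `field_prediction` with
#' per-atom guidance vectors `y_t`, denoising vectors `y_d`, per-atom
#' positive uncertainty `y_std` in [0.1, 1], and a global pair of stop
#' scores `y_f` (generation stops when `y_f[2] > y_f[1]`).
#'
#' @param model a field model (`toy_field_model`, `equivariant_field_model`,
#'   or `oracle_field_model`).
#' @param x current coordinates (`structure3d` for molecular models;
#'   flattened vector for the toy baseline).
#' @param x_IS IS coordinates, same form as `x`.
#' @param condition optional `reaction_diff` describing the requested
#'   reaction (molecular models), or NULL for unconditional evaluation.
#' @param ... model-specific arguments.
#' @return list with `y_t` (N x 3), `y_d` (N x 3), `y_std` (length N),
#'   `y_f` (length 2).
#' @export
predict_fields <- function(model, x, x_IS, condition = NULL, ...) {
  UseMethod("predict_fields")
}

# ---------------------------------------------------------------------------
# Dense toy baseline
# ---------------------------------------------------------------------------

#' Dense baseline field model for low-dimensional toys
#'
#' A plain feed-forward network on the concatenated flattened coordinates of
#' the current state and the IS. It honours the prediction contract
#' (bounded vector norms, `y_std` in [0.1, 1], two stop scores) but makes no
#' equivariance guarantee; it is intended for the 2D toy paths where the
#' frame is fixed, and for fast desk-scale training experiments.
#'
#' @param d flattened coordinate dimension (3 for a single pseudo-atom toy).
#' @param hidden hidden width (default 64).
#' @param seed integer seed for weight initialization.
#' @return object of class `toy_field_model`.
#' @export
toy_field_model <- function(d, hidden = 64L, seed = 1L) {
  set.seed(seed)
  init <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nc)), nr, nc)
  structure(list(
    d = d, hidden = hidden,
    W1 = init(hidden, 2L * d), b1 = numeric(hidden),
    W2 = init(hidden, hidden), b2 = numeric(hidden),
    Wt = init(d, hidden), bt = numeric(d),
    Wd = init(d, hidden), bd = numeric(d),
    ws = init(1L, hidden), bs = 0,
    Wf = init(2L, hidden), bf = numeric(2L)),
    class = "toy_field_model")
}

# Bound a vector's norm by 2 (identity inside the ball, radial projection
# outside); the toy analogue of magnitude decoding over the [-2, 2] bins.
clamp_norm2 <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv <= 2) v else v * (2 / nv)
}

# Batched forward pass keeping intermediates for backprop.
# X, XIS: B x d matrices of flattened coordinates.
toy_forward <- function(model, X, XIS) {
  U <- cbind(X, XIS)
  Z1 <- tanh(sweep(U %*% t(model$W1), 2, model$b1, `+`))
  Z2 <- tanh(sweep(Z1 %*% t(model$W2), 2, model$b2, `+`))
  Rt <- sweep(Z2 %*% t(model$Wt), 2, model$bt, `+`)
  Rd <- sweep(Z2 %*% t(model$Wd), 2, model$bd, `+`)
  As <- drop(Z2 %*% t(model$ws)) + model$bs
  Zf <- sweep(Z2 %*% t(model$Wf), 2, model$bf, `+`)
  Yt <- matrix(t(apply(Rt, 1, clamp_norm2)), nrow(Rt), ncol(Rt))
  Yd <- matrix(t(apply(Rd, 1, clamp_norm2)), nrow(Rd), ncol(Rd))
  Sig <- 0.1 + 0.9 * stats::plogis(As)
  list(U = U, Z1 = Z1, Z2 = Z2, Rt = Rt, Rd = Rd, As = As, Zf = Zf,
       Yt = Yt, Yd = Yd, Sig = Sig)
}

#' @rdname predict_fields
#' @export
predict_fields.toy_field_model <- function(model, x, x_IS, condition = NULL, ...) {
  if (!is.null(condition))
    stop("the dense toy baseline is unconditional; condition must be NULL")
  x <- as_coord_vector(x); x_IS <- as_coord_vector(x_IS)
  fw <- toy_forward(model, matrix(x, 1L), matrix(x_IS, 1L))
  list(y_t = coords_to_matrix(fw$Yt[1L, ]),
       y_d = coords_to_matrix(fw$Yd[1L, ]),
       y_std = rep(fw$Sig[1L], model$d %/% 3L),
       y_f = fw$Zf[1L, ])
}

# ---------------------------------------------------------------------------
# Equivariant graph-attention model
# ---------------------------------------------------------------------------

#' E(3)-equivariant graph-attention field model
#'
#' A reference implementation of the equivariant field predictor. Node
#' features carry invariant scalar channels and covariant vector channels;
#' only relative coordinates enter the network, so predictions are exactly
#' translation invariant, and every vector-channel operation is built from
#' scalar gates times covariant vectors, so predictions rotate with the
#' input. Edges follow the sparse window/random/supernode construction of
#' [build_edges()] with the 9-component condition vector of
#' [condition_vectors()] as edge input.
#'
#' @param n_scalar scalar channels per node (default 32).
#' @param n_vector vector channels per node (default 8).
#' @param n_rounds attention rounds with fixed edge features (default 5).
#' @param d_qk attention query/key width (default 16).
#' @param hidden edge-block hidden width (default 64).
#' @param n_freq sinusoidal distance-embedding frequency pairs (default 32,
#'   geometric wavelengths 0.25 to 30 Angstrom).
#' @param seed weight-initialization seed.
#' @param edge_seed seed for the random-edge draws at prediction time.
#' @return object of class `equivariant_field_model`.
#' @export
equivariant_field_model <- function(n_scalar = 32L, n_vector = 8L,
                                    n_rounds = 5L, d_qk = 16L, hidden = 64L,
                                    n_freq = 32L, seed = 1L, edge_seed = 1L) {
  set.seed(seed)
  init <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nc)), nr, nc)
  n_emb_in <- length(.covalent_radii) + 3L   # one-hot Z + node-type one-hot
  d_edge_in <- 2L * n_freq + 9L
  edge_block <- function(out_s, with_vec) {
    inp <- 2L * n_scalar + n_scalar + 3L * n_vector
    list(W1 = init(hidden, inp), b1 = numeric(hidden),
         Ws = init(out_s, hidden), bs = numeric(out_s),
         Wg = if (with_vec) init(3L * n_vector, hidden) else NULL)
  }
  rounds <- lapply(seq_len(n_rounds), function(r)
    list(q = edge_block(d_qk, FALSE), k = edge_block(d_qk, FALSE),
         v = edge_block(n_scalar, TRUE)))
  structure(list(
    n_scalar = n_scalar, n_vector = n_vector, n_rounds = n_rounds,
    d_qk = d_qk, hidden = hidden, n_freq = n_freq, edge_seed = edge_seed,
    W_emb = init(n_scalar, n_emb_in), b_emb = numeric(n_scalar),
    W_e1 = init(hidden, d_edge_in), b_e1 = numeric(hidden),
    W_e2 = init(n_scalar, hidden), b_e2 = numeric(n_scalar),
    rounds = rounds,
    w_dir_t = stats::rnorm(n_vector), w_dir_d = stats::rnorm(n_vector),
    W_mag_t = init(41L, n_scalar), b_mag_t = numeric(41L),
    W_mag_d = init(41L, n_scalar), b_mag_d = numeric(41L),
    W_std = init(10L, n_scalar), b_std = numeric(10L),
    W_f1 = init(hidden, n_scalar), b_f1 = numeric(hidden),
    W_f2 = init(2L, hidden), b_f2 = numeric(2L)),
    class = "equivariant_field_model")
}

# geometric sinusoidal embedding of distances
sinusoidal_embed <- function(r, n_freq, lambda_min = 0.25, lambda_max = 30) {
  lam <- exp(seq(log(lambda_min), log(lambda_max), length.out = n_freq))
  ang <- outer(r, 2 * pi / lam)
  cbind(sin(ang), cos(ang))
}

norm_scalars <- function(ns) ns / (sqrt(rowMeans(ns^2)) + 1e-6)

norm_vectors <- function(nv) {
  # nv: nodes x channels x 3; divide per node by rms of channel norms
  rms <- sqrt(apply(nv^2, 1, sum) / dim(nv)[2])
  nv / (array(rms, dim = dim(nv)) + 1e-6)
}

#' Embed structures and edges into the initial graph state
#'
#' Builds node scalar features from the one-hot atomic number (plus a
#' current/IS/supernode type flag), fixed edge scalar features `S_ij` from
#' the sinusoidal distance embedding concatenated with the condition vector,
#' and fixed edge vector features `v_ij` (the normalized relative
#' coordinate; zero for coordinate-free supernode edges).
#'
#' @param model an `equivariant_field_model`.
#' @param current,IS `structure3d` objects.
#' @param edges edge data.frame from [build_edges()].
#' @param conditions per-edge 9-column condition matrix.
#' @return a `graph_state`: list with `ns` (nodes x scalar channels), `nv`
#'   (nodes x vector channels x 3), fixed `S`, `vhat`, `edges`, counts.
#' @export
embed_graph <- function(model, current, IS, edges, conditions) {
  if (any(!is.finite(current$coords)) || any(!is.finite(IS$coords)))
    stop("non-finite coordinates")
  n <- nrow(current$coords)
  n_super <- max(0L, max(edges$src, edges$dst) - 2L * n)
  n_nodes <- 2L * n + n_super
  nz <- length(.covalent_radii)
  feat <- matrix(0, n_nodes, nz + 3L)
  feat[cbind(seq_len(n), current$atomic_numbers)] <- 1
  feat[cbind(n + seq_len(n), IS$atomic_numbers)] <- 1
  feat[seq_len(n), nz + 1L] <- 1
  feat[n + seq_len(n), nz + 2L] <- 1
  if (n_super > 0L) feat[2L * n + seq_len(n_super), nz + 3L] <- 1
  ns <- norm_scalars(silu(sweep(feat %*% t(model$W_emb), 2, model$b_emb, `+`)))
  nv <- array(0, dim = c(n_nodes, model$n_vector, 3L))

  rel <- unname(as.matrix(edges[, c("rx", "ry", "rz")]))
  rn <- sqrt(rowSums(rel^2))
  vhat <- rel / ifelse(rn > 1e-12, rn, 1)
  vhat[rn <= 1e-12, ] <- 0
  se <- sinusoidal_embed(rn, model$n_freq)
  h <- silu(sweep(cbind(se, conditions) %*% t(model$W_e1), 2, model$b_e1, `+`))
  S <- silu(sweep(h %*% t(model$W_e2), 2, model$b_e2, `+`))
  structure(list(ns = ns, nv = nv, S = S, vhat = vhat, edges = edges,
                 n_atoms = n, n_super = n_super, n_nodes = n_nodes),
            class = "graph_state")
}

# Edge feature block: invariant inputs -> hidden -> scalar output and
# (optionally) gated covariant vector output.
edge_features <- function(state, blk, with_vec) {
  e <- state$edges
  i <- e$dst; j <- e$src          # i receives from j
  nv_i <- state$nv[i, , , drop = FALSE]
  nv_j <- state$nv[j, , , drop = FALSE]
  cv <- dim(nv_i)[2]
  ne <- nrow(e)
  slab <- function(a, ax) matrix(a[, , ax], ne, cv)
  vh <- array(0, dim = c(ne, cv, 3L))
  for (ax in 1:3) vh[, , ax] <- state$vhat[, ax]
  dots <- function(a, b) slab(a, 1) * slab(b, 1) + slab(a, 2) * slab(b, 2) +
    slab(a, 3) * slab(b, 3)
  inv <- cbind(state$ns[i, , drop = FALSE], state$ns[j, , drop = FALSE],
               state$S, dots(nv_i, vh), dots(nv_j, vh), dots(nv_i, nv_j))
  h <- silu(sweep(inv %*% t(blk$W1), 2, blk$b1, `+`))
  out_s <- sweep(h %*% t(blk$Ws), 2, blk$bs, `+`)
  if (!with_vec) return(list(s = out_s))
  g <- h %*% t(blk$Wg)                         # E x 3*Cv gates
  g1 <- g[, seq_len(cv), drop = FALSE]
  g2 <- g[, cv + seq_len(cv), drop = FALSE]
  g3 <- g[, 2L * cv + seq_len(cv), drop = FALSE]
  out_v <- array(0, dim = dim(nv_i))
  for (ax in 1:3) {
    out_v[, , ax] <- g1 * state$vhat[, ax] + g2 * nv_i[, , ax] + g3 * nv_j[, , ax]
  }
  list(s = out_s, v = out_v)
}

#' One equivariant attention round
#'
#' Builds query/key/value edge features, computes invariant attention logits
#' `w_ij = q_ij . k_ij`, softmaxes over the incoming edges of each receiver,
#' aggregates the value features, adds them residually to the node features
#' and renormalizes per channel type. `S_ij` and `v_ij` stay fixed.
#'
#' @param state a `graph_state`.
#' @param round_params one element of `model$rounds`.
#' @return updated `graph_state`.
#' @export
interact <- function(state, round_params) {
  q <- edge_features(state, round_params$q, FALSE)$s
  k <- edge_features(state, round_params$k, FALSE)$s
  val <- edge_features(state, round_params$v, TRUE)
  w <- rowSums(q * k) / sqrt(ncol(q))
  recv <- state$edges$dst
  a <- numeric(length(w))
  for (r in unique(recv)) {
    idx <- which(recv == r)
    z <- w[idx] - max(w[idx])
    a[idx] <- exp(z) / sum(exp(z))
  }
  ds <- matrix(0, state$n_nodes, ncol(state$ns))
  dv <- array(0, dim = dim(state$nv))
  agg_s <- rowsum(val$s * a, recv)
  ds[as.integer(rownames(agg_s)), ] <- agg_s
  for (ax in 1:3) {
    agg_v <- rowsum(val$v[, , ax] * a, recv)
    dv[as.integer(rownames(agg_v)), , ax] <- agg_v
  }
  state$ns <- norm_scalars(state$ns + ds)
  state$nv <- norm_vectors(state$nv + dv)
  state
}

#' Read out field predictions from a graph state
#'
#' Vector heads take a learned combination of the node vector channels as
#' the direction and an inner-product-decoded signed magnitude over the
#' [-2, 2] Angstrom bins; `y_std` is decoded over the [0.1, 1] bins; the
#' stop scores come from the mean supernode scalar features through a
#' feed-forward head.
#'
#' @param model an `equivariant_field_model`.
#' @param state a `graph_state` after the interaction rounds.
#' @return a field prediction (see [predict_fields()]).
#' @export
readout <- function(model, state) {
  at <- seq_len(state$n_atoms)
  dir_head <- function(wv) {
    d <- matrix(0, length(at), 3L)
    for (ax in 1:3) d[, ax] <- state$nv[at, , ax, drop = FALSE][, , 1] %*% wv
    nn <- sqrt(rowSums(d^2))
    d / ifelse(nn > 1e-12, nn, 1)
  }
  ns_at <- state$ns[at, , drop = FALSE]
  mag_t <- inner_product_decode(sweep(ns_at %*% t(model$W_mag_t), 2, model$b_mag_t, `+`),
                                magnitude_bins())
  mag_d <- inner_product_decode(sweep(ns_at %*% t(model$W_mag_d), 2, model$b_mag_d, `+`),
                                magnitude_bins())
  y_std <- inner_product_decode(sweep(ns_at %*% t(model$W_std), 2, model$b_std, `+`),
                                std_bins())
  y_t <- dir_head(model$w_dir_t) * mag_t
  y_d <- dir_head(model$w_dir_d) * mag_d
  sup <- if (state$n_super > 0L) 2L * state$n_atoms + seq_len(state$n_super) else at
  pooled <- colMeans(state$ns[sup, , drop = FALSE])
  hf <- silu(model$W_f1 %*% pooled + model$b_f1)
  y_f <- drop(model$W_f2 %*% hf + model$b_f2)
  list(y_t = y_t, y_d = y_d, y_std = y_std, y_f = y_f)
}

#' @rdname predict_fields
#' @param edges optional precomputed edge set (otherwise built with
#'   `model$edge_seed`).
#' @export
predict_fields.equivariant_field_model <- function(model, x, x_IS,
                                                   condition = NULL,
                                                   edges = NULL, ...) {
  stopifnot(inherits(x, "structure3d"), inherits(x_IS, "structure3d"))
  if (is.null(edges)) edges <- build_edges(x, x_IS, seed = model$edge_seed)
  cond <- condition_vectors(edges, condition, conditional_flag = !is.null(condition),
                            n_atoms = nrow(x$coords))
  state <- embed_graph(model, x, x_IS, edges, cond)
  for (r in seq_len(model$n_rounds)) state <- interact(state, model$rounds[[r]])
  readout(model, state)
}

# ---------------------------------------------------------------------------
# Oracle stand-in model
# ---------------------------------------------------------------------------

#' Oracle field "model" backed by reference paths
#'
#' A drop-in for [predict_fields()] that returns the exact oracle fields of
#' the nearest reference path and a stop score pair derived from the
#' projection arclength (`y_f[2] > y_f[1]` once the projection falls within
#' `delta_stop` of the FS). Used to exercise generation and evaluation
#' without a trained network.
#'
#' @param paths list of `reaction_path` objects.
#' @param delta_stop stop-neighborhood fraction of total arclength.
#' @return object of class `oracle_field_model`.
#' @export
oracle_field_model <- function(paths, delta_stop = 0.02) {
  structure(list(paths = paths, delta_stop = delta_stop),
            class = "oracle_field_model")
}

#' @rdname predict_fields
#' @export
predict_fields.oracle_field_model <- function(model, x, x_IS, condition = NULL, ...) {
  xv <- if (inherits(x, "structure3d")) as.vector(t(x$coords)) else as_coord_vector(x)
  k <- select_nearest_path(model$paths, xv)
  path <- model$paths[[k]]
  f <- oracle_fields(path, xv)
  near_end <- f$proj$s_hat >= path$total_length * (1 - model$delta_stop)
  list(y_t = coords_to_matrix(f$t_t), y_d = coords_to_matrix(f$t_d),
       y_std = rep(0.1, length(xv) %/% 3L),
       y_f = if (near_end) c(0, 1) else c(1, 0))
}
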