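test_that("inner-product decoding is a bounded softmax expectation", {
  bins <- magnitude_bins()
  one_hot <- rep(-1e3, length(bins))
  one_hot[which(abs(bins - 1.3) < 1e-9)] <- 1e3
  expect_equal(inner_product_decode(one_hot, bins), 1.3, tolerance = 1e-6)

  expect_equal(inner_product_decode(rep(0.37, length(bins)), bins), 0)

  set.seed(1)
  for (k in 1:20) {
    v <- inner_product_decode(stats::rnorm(length(bins), sd = 5), bins)
    expect_true(v >= -2 && v <= 2)
  }
  expect_error(inner_product_decode(numeric(5), bins), "bin count")
})

test_that("the toy baseline honors the prediction contract", {
  mod <- toy_field_model(3, hidden = 16, seed = 2)
  p <- predict_fields(mod, c(0.3, -0.2, 0), c(0, 0, 0))
  expect_true(all(is.finite(unlist(p))))
  expect_equal(dim(p$y_t), c(1L, 3L))
  expect_equal(dim(p$y_d), c(1L, 3L))
  expect_true(p$y_std >= 0.1 && p$y_std <= 1.0)
  expect_length(p$y_f, 2L)
  expect_lte(sqrt(sum(p$y_t^2)), 2)
  expect_lte(sqrt(sum(p$y_d^2)), 2)
  # bitwise stability
  p2 <- predict_fields(mod, c(0.3, -0.2, 0), c(0, 0, 0))
  expect_identical(p, p2)
  expect_error(predict_fields(mod, c(0, 0, 0), c(0, 0, 0), condition = list()),
               "unconditional")
})

test_that("graph embedding is invariant/equivariant by construction", {
  fx <- butane_rotation_fixture()
  mid <- frame_struct(fx$IS$atomic_numbers, fx$path$points[8, ])
  mod <- equivariant_field_model(n_scalar = 8L, n_vector = 3L, n_rounds = 2L,
                                 d_qk = 4L, hidden = 16L, seed = 3)
  edges <- build_edges(mid, fx$IS, seed = 1)
  cond <- condition_vectors(edges, fx$diff, TRUE, 14L)
  st <- embed_graph(mod, mid, fx$IS, edges, cond)

  set.seed(11)
  R <- random_rotation(); v <- stats::rnorm(3)
  midR <- structure3d(mid$atomic_numbers, sweep(mid$coords %*% t(R), 2, v, `+`))
  isR <- structure3d(fx$IS$atomic_numbers, sweep(fx$IS$coords %*% t(R), 2, v, `+`))
  edgesR <- build_edges(midR, isR, seed = 1)
  stR <- embed_graph(mod, midR, isR, edgesR, cond)
  # edge scalars invariant, edge vectors rotated
  expect_equal(stR$S, st$S, tolerance = 1e-8)
  expect_equal(stR$vhat, st$vhat %*% t(R), tolerance = 1e-8)
  # odd parity: negating a relative coordinate flips its vector part only
  e2 <- edges; e2[, c("rx", "ry", "rz")] <- -e2[, c("rx", "ry", "rz")]
  st2 <- embed_graph(mod, mid, fx$IS, e2, cond)
  expect_equal(st2$S, st$S, tolerance = 1e-12)
  expect_equal(st2$vhat, -st$vhat, tolerance = 1e-12)
  # supernode edges carry zero vector parts
  expect_true(all(st$vhat[edges$kind %in% c("atom_super", "super_super"), ] == 0))

  expect_error(embed_graph(mod, structure3d(1L, matrix(NaN, 1, 3)), fx$IS,
                           edges, cond))
})

test_that("the equivariant model transforms covariantly and predicts in range", {
  fx <- butane_rotation_fixture()
  mid <- frame_struct(fx$IS$atomic_numbers, fx$path$points[8, ])
  mod <- equivariant_field_model(n_scalar = 16L, n_vector = 4L, n_rounds = 3L,
                                 d_qk = 8L, hidden = 32L, seed = 5)
  p <- predict_fields(mod, mid, fx$IS, condition = fx$diff)
  expect_true(all(is.finite(unlist(p))))
  expect_true(all(p$y_std >= 0.1 & p$y_std <= 1.0))
  expect_true(all(sqrt(rowSums(p$y_t^2)) <= 2 + 1e-9))
  expect_true(all(sqrt(rowSums(p$y_d^2)) <= 2 + 1e-9))

  set.seed(21)
  for (k in 1:5) {
    R <- random_rotation(); v <- stats::rnorm(3)
    midT <- structure3d(mid$atomic_numbers, sweep(mid$coords %*% t(R), 2, v, `+`))
    isT <- structure3d(fx$IS$atomic_numbers,
                       sweep(fx$IS$coords %*% t(R), 2, v, `+`))
    pT <- predict_fields(mod, midT, isT, condition = fx$diff)
    expect_equal(pT$y_t, p$y_t %*% t(R), tolerance = 1e-5)
    expect_equal(pT$y_d, p$y_d %*% t(R), tolerance = 1e-5)
    expect_equal(pT$y_std, p$y_std, tolerance = 1e-6)
    expect_equal(pT$y_f, p$y_f, tolerance = 1e-6)
  }

  # permutation equivariance
  set.seed(22)
  perm <- sample(14L)
  inv <- order(perm)
  midP <- structure3d(mid$atomic_numbers[perm], mid$coords[perm, ])
  isP <- structure3d(fx$IS$atomic_numbers[perm], fx$IS$coords[perm, ])
  diffP <- fx$diff
  for (nm in c("broken", "formed", "rotated")) {
    if (nrow(fx$diff[[nm]]) > 0) {
      m <- matrix(inv[fx$diff[[nm]]], ncol = 2)
      diffP[[nm]] <- cbind(i = pmin(m[, 1], m[, 2]), j = pmax(m[, 1], m[, 2]))
    }
  }
  pP <- predict_fields(mod, midP, isP, condition = diffP)
  expect_equal(pP$y_t, p$y_t[perm, ], tolerance = 1e-8)
  expect_equal(pP$y_d, p$y_d[perm, ], tolerance = 1e-8)
  expect_equal(pP$y_std, p$y_std[perm], tolerance = 1e-8)
})

test_that("a fresh equivariant model yields finite losses on tube samples", {
  eth <- build_alkane(2)
  rp <- make_dihedral_rotation_path(eth, central_cc_bond(2), 120, 15)
  set.seed(30)
  xs <- sample_tube(rp, g = 0.05, dt = 0.1, n_steps = 10, seed = 30)
  samples <- lapply(seq_len(nrow(xs)), function(i) make_sample(rp, xs[i, ]))
  mod <- equivariant_field_model(n_scalar = 8L, n_vector = 3L, n_rounds = 2L,
                                 d_qk = 4L, hidden = 16L, seed = 6)
  ls <- evaluate_losses(mod, samples)
  expect_true(all(is.finite(unlist(ls))))
  expect_equal(ls$total, ls$loss_t + ls$loss_d + ls$loss_f)
})

test_that("oracle stand-in model reports fields and stop scores from paths", {
  paths <- make_toy_branches()
  om <- oracle_field_model(paths)
  p <- predict_fields(om, c(0.1, 0.5), c(0, 0))
  expect_equal(dim(p$y_t), c(1L, 3L))
  expect_true(p$y_f[1] > p$y_f[2])  # far from any FS: keep going
  fs <- paths[[1]]$points[nrow(paths[[1]]$points), ]
  p_end <- predict_fields(om, fs, c(0, 0))
  expect_true(p_end$y_f[2] > p_end$y_f[1])
})
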