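test_that("build_path parameterizes by arclength", {
  p <- build_path(rbind(c(0, 0), c(3, 4)))
  expect_equal(p$total_length, 5)

  p2 <- build_path(rbind(c(0, 0), c(1, 0), c(1, 1)))
  expect_equal(p2$arclengths, c(0, 1, 2))
  expect_true(all(diff(p2$arclengths) > 0))

  # polyline length of a dense semicircle converges to the arc length
  semi <- semicircle_path(200)
  expect_equal(semi$total_length, pi, tolerance = 1e-3)

  # consecutive-frame distances match arclength increments
  seg <- sqrt(rowSums((semi$points[-1, ] - semi$points[-nrow(semi$points), ])^2))
  expect_equal(seg, diff(semi$arclengths), tolerance = 1e-9)

  # duplicate frames collapse; degenerate paths are rejected
  p3 <- build_path(rbind(c(0, 0), c(0, 0), c(1, 0)))
  expect_equal(nrow(p3$points), 2L)
  expect_error(build_path(rbind(c(1, 2), c(1, 2))), "degenerate")
  expect_error(build_path(list(matrix(0, 2, 3), matrix(0, 3, 3))), "inconsistent")
})

test_that("projection finds the continuous nearest point, clamping at endpoints", {
  line <- line_path()
  pr <- project_path(line, c(3, 4))
  expect_equal(pr$s_hat, 3)
  expect_equal(pr$x_near, c(3, 0, 0))
  expect_equal(pr$distance, 4)
  expect_false(pr$clamped)

  pr2 <- project_path(line, c(-2, 0))
  expect_equal(pr2$s_hat, 0)
  expect_equal(pr2$x_near, c(0, 0, 0))
  expect_true(pr2$clamped)

  pr3 <- project_path(semicircle_path(400), c(0, 0.5))
  expect_equal(pr3$x_near[1:2], c(0, 1), tolerance = 1e-3)
})

test_that("projection agrees with an exhaustive refined scan on random paths", {
  for (seed in 1:10) {
    p <- random_toy_path(seed)
    set.seed(seed + 1000)
    for (k in 1:10) {
      x <- stats::runif(2, -2, 2)
      pr <- project_path(p, x)
      bf <- brute_project(p, x)
      refined_seg <- max(diff(p$arclengths)) / 10
      expect_lte(abs(pr$distance - bf$distance), refined_seg)
    }
  }
})

test_that("oracle fields give the IS->FS unit tangent and the vector to the path", {
  line <- line_path()
  f <- oracle_fields(line, c(3, 4))
  expect_equal(f$t_t, c(1, 0, 0))
  expect_equal(f$t_d, c(0, -4, 0))

  # on-path coordinate: zero denoising field
  f2 <- oracle_fields(line, c(5, 0))
  expect_equal(sqrt(sum(f2$t_d^2)), 0, tolerance = 1e-12)

  semi <- semicircle_path(400)
  f3 <- oracle_fields(semi, c(0, 0.5))
  expect_equal(f3$t_d[1:2], c(0, 0.5), tolerance = 1e-3)
  expect_equal(sum(f3$t_t * f3$t_d), 0, tolerance = 1e-3)
})

test_that("field invariants hold at random coordinates", {
  for (seed in 1:5) {
    p <- random_toy_path(seed)
    set.seed(seed + 2000)
    for (k in 1:20) {
      x <- stats::runif(2, -2, 2)
      f <- oracle_fields(p, x)
      # unit tangent
      expect_equal(sqrt(sum(f$t_t^2)), 1, tolerance = 1e-12)
      # t_d points exactly at the nearest point
      xv <- c(x, 0)
      expect_equal(sum(f$t_d * (xv - f$proj$x_near)), -sum(f$t_d^2),
                   tolerance = 1e-10)
      # segment-interior projections are perpendicular feet (vertex feet are
      # kinks of the polyline and legitimately non-orthogonal)
      if (f$proj$t_seg > 0 && f$proj$t_seg < 1 && f$proj$distance > 1e-8) {
        expect_lt(abs(sum(f$t_t * f$t_d)) / f$proj$distance, 1e-6)
      }
    }
  }
})

test_that("nearest-path selection minimizes the denoising field with index tie-break", {
  l0 <- line_path(c(0, 0), c(10, 0))
  l3 <- line_path(c(0, 3), c(10, 3))
  expect_equal(select_nearest_path(list(l0, l3), c(5, 1)), 1L)
  expect_equal(select_nearest_path(list(l3, l0), c(5, 1)), 2L)
  # equidistant: lowest index wins
  expect_equal(select_nearest_path(list(l0, l3), c(5, 1.5)), 1L)
  expect_error(select_nearest_path(list(), c(0, 0)), "empty")

  paths <- make_toy_branches()
  set.seed(9)
  for (k in 1:100) {
    x <- stats::runif(2, -2, 2)
    d <- vapply(paths, function(p) brute_project(p, x)$distance, numeric(1))
    expect_equal(select_nearest_path(paths, x), which.min(d))
  }
})

test_that("Euler field integration follows fields and honors stop conditions", {
  tr <- integrate_field(function(x) c(1, 0, 0), c(0, 0), dt = 0.1, max_steps = 50)
  expect_equal(tr$n_steps, 50L)
  expect_equal(tr$frames[nrow(tr$frames), ], c(5, 0, 0), tolerance = 1e-12)
  expect_equal(tr$stop_reason, "max_steps")

  line <- line_path(c(0, 0), c(5, 0))
  tr2 <- integrate_field(function(x) oracle_fields(line, x)$t_t, c(0, 0),
                         dt = 0.1, max_steps = 100,
                         stop_fn = function(x) project_path(line, x)$s_hat >= 5 - 1e-9)
  expect_equal(tr2$stop_reason, "stop_predicted")
  expect_equal(tr2$n_steps, 50L)
  expect_equal(tr2$frames[nrow(tr2$frames), ], c(5, 0, 0), tolerance = 1e-9)

  # zero field: fixed point detected
  tr3 <- integrate_field(function(x) c(0, 0, 0), c(1, 1), dt = 0.1, max_steps = 10)
  expect_equal(tr3$stop_reason, "fixed_point")
  expect_error(integrate_field(function(x) c(NaN, 0, 0), c(0, 0), 0.1, 5),
               "non-finite")
})

test_that("integrating the combined field reproduces the path as dt shrinks", {
  semi <- semicircle_path(400)
  run <- function(dt) {
    fs <- semi$points[nrow(semi$points), ]
    tr <- integrate_field(function(x) {
      f <- oracle_fields(semi, x)
      f$t_t + f$t_d
    }, semi$points[1, ], dt = dt, max_steps = ceiling(1.2 * pi / dt),
    stop_fn = function(x) project_path(semi, x)$s_hat >= semi$total_length - 1e-9)
    tr
  }
  tr_coarse <- run(0.1)
  tr_fine <- run(0.01)
  fs <- semi$points[nrow(semi$points), ]
  expect_lt(sqrt(sum((tr_fine$frames[nrow(tr_fine$frames), ] - fs)^2)), 0.05)
  offpath <- function(tr) max(apply(tr$frames, 1, function(x)
    project_path(semi, x)$distance))
  expect_lt(offpath(tr_fine), offpath(tr_coarse))
})
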