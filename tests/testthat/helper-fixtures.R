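# Shared fixtures, all generated in code.

line_path <- function(from = c(0, 0), to = c(10, 0)) {
  build_path(rbind(from, to))
}

semicircle_path <- function(n = 200L, radius = 1) {
  th <- seq(pi, 0, length.out = n)   # IS at (-r, 0), FS at (r, 0)
  build_path(cbind(radius * cos(th), radius * sin(th)))
}

# A random smooth 2D toy path: cumulative random-walk headings.
random_toy_path <- function(seed, n = 60L, step = 0.1) {
  set.seed(seed)
  th <- cumsum(c(stats::runif(1, 0, 2 * pi), stats::rnorm(n - 2L, 0, 0.3)))
  pts <- rbind(c(0, 0), cbind(cumsum(step * cos(th)), cumsum(step * sin(th))))
  build_path(pts)
}

random_rotation <- function() {
  a <- stats::rnorm(3); a <- a / sqrt(sum(a^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Brute-force nearest point over a k-times refined vertex scan.
brute_project <- function(path, x, refine = 10L) {
  pts <- path$points
  fine <- list()
  for (k in seq_len(nrow(pts) - 1L)) {
    tt <- seq(0, 1, length.out = refine + 1L)[-(refine + 1L)]
    fine[[k]] <- outer(1 - tt, pts[k, ]) + outer(tt, pts[k + 1L, ])
  }
  fine <- rbind(do.call(rbind, fine), pts[nrow(pts), ])
  d <- sqrt(rowSums((fine - matrix(as_c(x, ncol(pts)), nrow(fine), ncol(pts),
                                   byrow = TRUE))^2))
  list(distance = min(d), x_near = fine[which.min(d), ])
}

as_c <- function(x, d) {
  x <- as.numeric(x)
  if (length(x) == 2L && d == 3L) c(x, 0) else x
}

butane_rotation_fixture <- function(n_frames = 21L, delta = 120) {
  but <- build_alkane(4)
  rp <- make_dihedral_rotation_path(but, central_cc_bond(4), delta, n_frames)
  IS <- structure3d(but$atomic_numbers, matrix(rp$points[1L, ], ncol = 3, byrow = TRUE))
  FS <- structure3d(but$atomic_numbers,
                    matrix(rp$points[nrow(rp$points), ], ncol = 3, byrow = TRUE))
  list(path = rp, IS = IS, FS = FS, diff = diff_reaction(IS, FS))
}

frame_struct <- function(z, flat) structure3d(z, matrix(flat, ncol = 3, byrow = TRUE))
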