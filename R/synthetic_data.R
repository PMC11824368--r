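# Synthetic fixtures: the 2D multi-branch toy path family sharing one IS,
# idealized n-alkane builders, and dihedral-rotation / bond-change reference
# paths. All fixtures are generated in code and deterministic.

#' 2D multi-branch toy reaction paths
#'
#' A family of smooth 2D curves all emanating from the origin (the shared
#' IS), discretized as reaction paths. Each branch is a constant-curvature
#' arc with its own heading and curvature, giving curved paths whose fields
#' can be computed exactly by the path oracles. Branches are embedded as a
#' single pseudo-atom with zero third coordinate.
#'
#' @param n_branches number of branches (default 3).
#' @param points_per_branch frames per branch (default 100).
#' @param arc_length length of each branch (default 2).
#' @param headings initial heading angles in radians (default equally spaced
#'   starting at pi/2).
#' @param curvatures signed curvatures (1/length units; default alternating).
#' @return list of `reaction_path` objects, labels `"branch1"`, ...
#' @export
make_toy_branches <- function(n_branches = 3L, points_per_branch = 100L,
                              arc_length = 2,
                              headings = pi / 2 + 2 * pi * (seq_len(n_branches) - 1L) / n_branches,
                              curvatures = 0.45 * (-1)^(seq_len(n_branches)) *
                                seq(1, 1.6, length.out = n_branches)) {
  stopifnot(n_branches >= 1L, points_per_branch >= 2L)
  lapply(seq_len(n_branches), function(b) {
    s <- seq(0, arc_length, length.out = points_per_branch)
    th <- headings[b]; k <- curvatures[b]
    if (abs(k) < 1e-12) {
      xy <- cbind(s * cos(th), s * sin(th))
    } else {
      # constant-curvature arc: heading th + k*s, closed-form integral
      xy <- cbind((sin(th + k * s) - sin(th)) / k,
                  (cos(th) - cos(th + k * s)) / k)
    }
    build_path(xy, label = paste0("branch", b))
  })
}

#' Idealized all-anti n-alkane geometry
#'
#' Builds C_n H_(2n+2) as a planar zig-zag carbon backbone (C-C 1.54
#' Angstrom, tetrahedral backbone angles) with hydrogens placed tetrahedrally
#' (C-H 1.09 Angstrom). Atom order: carbons 1..n, then hydrogens grouped by
#' carbon.
#'
#' @param n_carbons number of carbons (>= 2).
#' @return a `structure3d`.
#' @export
build_alkane <- function(n_carbons) {
  if (n_carbons < 2L) stop("n_carbons must be >= 2")
  n <- as.integer(n_carbons)
  rcc <- 1.54; rch <- 1.09
  theta <- acos(-1 / 3)  # tetrahedral angle, 109.47 deg
  half <- theta / 2
  # zig-zag backbone along x, alternating in z
  cx <- (seq_len(n) - 1L) * rcc * sin(half)
  cz <- rcc * cos(half) / 2 * rep_len(c(0, 1), n)
  carbons <- cbind(cx, 0, cz)

  h_dirs_methylene <- function(u, v) {
    # two H directions completing a tetrahedral center with neighbors u, v
    w1 <- u + v; w1 <- w1 / sqrt(sum(w1^2))
    w2 <- cross3(u, v); w2 <- w2 / sqrt(sum(w2^2))
    a <- half
    list(-w1 * cos(a) + w2 * sin(a), -w1 * cos(a) - w2 * sin(a))
  }
  h_dirs_methyl <- function(u, ref) {
    # three H directions around a terminal carbon bonded along u
    p <- ref - sum(ref * u) * u
    if (sqrt(sum(p^2)) < 1e-8) p <- cross3(u, c(0, 0, 1))
    p <- p / sqrt(sum(p^2))
    q <- cross3(u, p)
    lapply(c(pi, pi / 3, -pi / 3), function(phi) {
      # direction at the tetrahedral angle from u, azimuth phi from p
      cos(theta) * u + sin(theta) * (cos(phi) * p + sin(phi) * q)
    })
  }

  hyds <- list()
  for (i in seq_len(n)) {
    ci <- carbons[i, ]
    if (i == 1L) {
      u <- (carbons[2, ] - ci); u <- u / sqrt(sum(u^2))
      ref <- c(0, 0, if (cz[1] <= cz[2]) -1 else 1)
      dirs <- h_dirs_methyl(u, ref)
    } else if (i == n) {
      u <- (carbons[n - 1L, ] - ci); u <- u / sqrt(sum(u^2))
      ref <- c(0, 0, if (cz[n] <= cz[n - 1L]) -1 else 1)
      dirs <- h_dirs_methyl(u, ref)
    } else {
      u <- carbons[i - 1L, ] - ci; u <- u / sqrt(sum(u^2))
      v <- carbons[i + 1L, ] - ci; v <- v / sqrt(sum(v^2))
      dirs <- h_dirs_methylene(u, v)
    }
    for (d in dirs) hyds[[length(hyds) + 1L]] <- ci + rch * d
  }
  coords <- rbind(carbons, do.call(rbind, hyds))
  structure3d(c(rep(6L, n), rep(1L, length(hyds))), coords)
}

#' Central C-C bond of an alkane backbone
#'
#' For an even carbon count n the central bond connects carbons n/2 and
#' n/2 + 1 (1-based); odd counts use the same floor-halving rule.
#' @param n_carbons carbon count of the chain built by [build_alkane()].
#' @return integer pair of atom indices.
#' @export
central_cc_bond <- function(n_carbons) {
  k <- max(1L, n_carbons %/% 2L)
  c(k, k + 1L)
}

#' Dihedral-rotation reference path
#'
#' Rotates the smaller of the two fragments obtained by cutting `bond` about
#' the bond axis, in equal angular increments totaling `delta_deg`, with all
#' bond lengths unchanged. The visited frames form the reference path.
#'
#' @param s a `structure3d`.
#' @param bond integer pair of bonded atom indices defining the rotation axis.
#' @param delta_deg total rotation in degrees (nonzero).
#' @param n_frames number of frames (>= 2).
#' @param scale bond-perception scale used to split the molecule.
#' @return a `reaction_path` carrying the structure's atomic numbers.
#' @details Cutting a ring bond gives a single connected fragment and is
#'   rejected. Ties in fragment size rotate the fragment containing the
#'   second atom of `bond`.
#' @export
make_dihedral_rotation_path <- function(s, bond, delta_deg, n_frames = 21L,
                                        scale = 1.2) {
  bonds <- perceive_bonds(s, scale)
  if (!(paste(min(bond), max(bond)) %in% pair_keys(bonds)))
    stop("bond ", bond[1], "-", bond[2], " not present in the structure")
  n <- nrow(s$coords)
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  reach <- function(start, blocked_edge) {
    seen <- rep(FALSE, n); seen[start] <- TRUE; queue <- start
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if ((v == blocked_edge[1] && w == blocked_edge[2]) ||
            (v == blocked_edge[2] && w == blocked_edge[1])) next
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    which(seen)
  }
  side1 <- reach(bond[1], bond)
  side2 <- reach(bond[2], bond)
  if (bond[2] %in% side1) stop("bond is in a ring: no unique fragment split")
  moving <- if (length(side2) <= length(side1)) side2 else side1
  axis_from <- if (length(side2) <= length(side1)) bond[1] else bond[2]
  axis_to <- setdiff(bond, axis_from)

  origin <- s$coords[axis_from, ]
  axis <- s$coords[axis_to, ] - origin
  axis <- axis / sqrt(sum(axis^2))
  frames <- lapply(seq_len(n_frames), function(k) {
    ang <- delta_deg * pi / 180 * (k - 1L) / (n_frames - 1L)
    co <- s$coords
    co[moving, ] <- rotate_about_axis(co[moving, , drop = FALSE], origin, axis, ang)
    co
  })
  build_path(frames, atomic_numbers = s$atomic_numbers,
             label = sprintf("rot%g_%d-%d", delta_deg, bond[1], bond[2]))
}

# Rodrigues rotation of points about an axis through origin_pt.
rotate_about_axis <- function(pts, origin_pt, axis, angle) {
  p <- sweep(pts, 2, origin_pt)
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  sweep(p %*% t(R), 2, origin_pt, `+`)
}

#' Bond-break / bond-form reference path
#'
#' Linearly varies the distance of one atom pair between the bonded
#' covalent-radii sum and a dissociated separation of 3.5 Angstrom, keeping
#' all other atoms fixed. `mode = "break"` moves from bonded to dissociated;
#' `mode = "form"` reverses the direction.
#'
#' @param IS a `structure3d` providing the starting geometry.
#' @param pair integer atom pair.
#' @param mode `"break"` (pair must be bonded) or `"form"` (pair within 4
#'   Angstrom).
#' @param n_frames number of frames (>= 2).
#' @param dissociated_distance separation treated as fully broken (default 3.5).
#' @return a `reaction_path`.
#' @export
make_bond_change_path <- function(IS, pair, mode = c("break", "form"),
                                  n_frames = 20L, dissociated_distance = 3.5) {
  mode <- match.arg(mode)
  i <- pair[1]; j <- pair[2]
  d0 <- sqrt(sum((IS$coords[i, ] - IS$coords[j, ])^2))
  bonded_d <- sum(covalent_radius(IS$atomic_numbers[c(i, j)]))
  if (mode == "break") {
    if (!(paste(min(pair), max(pair)) %in% pair_keys(perceive_bonds(IS))))
      stop("pair is not bonded; cannot break")
    targets <- seq(d0, dissociated_distance, length.out = n_frames)
  } else {
    if (d0 > 4) stop("pair is farther than 4 Angstrom; cannot form")
    targets <- seq(d0, bonded_d, length.out = n_frames)
  }
  u <- IS$coords[j, ] - IS$coords[i, ]
  u <- u / sqrt(sum(u^2))
  frames <- lapply(targets, function(d) {
    co <- IS$coords
    co[j, ] <- co[i, ] + u * d
    co
  })
  build_path(frames, atomic_numbers = IS$atomic_numbers,
             label = sprintf("%s_%d-%d", mode, i, j))
}
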