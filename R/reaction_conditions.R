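# Reaction-condition encoding: bond perception, IS/FS change detection
# (broken / formed / rotated bonds), sparse edge construction in the style of
# windowed+random+supernode attention graphs, and the 9-component per-edge
# condition vector.

# Covalent radii (Angstrom), single-bond values, Z = 1..36.
.covalent_radii <- c(
  0.31, 0.28, 1.28, 0.96, 0.84, 0.76, 0.71, 0.66, 0.57, 0.58,
  1.66, 1.41, 1.21, 1.11, 1.07, 1.05, 1.02, 1.06, 2.03, 1.76,
  1.70, 1.60, 1.53, 1.39, 1.61, 1.52, 1.50, 1.24, 1.32, 1.22,
  1.22, 1.20, 1.19, 1.20, 1.20, 1.16)

covalent_radius <- function(z) {
  bad <- z < 1L | z > length(.covalent_radii)
  if (any(bad)) stop("no covalent radius for atomic number: ",
                     paste(unique(z[bad]), collapse = ", "))
  .covalent_radii[z]
}

#' Molecular structure
#'
#' @param atomic_numbers integer vector of atomic numbers.
#' @param coords N x 3 matrix of Cartesian coordinates (Angstrom).
#' @return object of class `structure3d`.
#' @export
structure3d <- function(atomic_numbers, coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be N x 3")
  if (length(atomic_numbers) != nrow(coords)) stop("atom count mismatch")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  structure(list(atomic_numbers = as.integer(atomic_numbers), coords = coords),
            class = "structure3d")
}

#' Perceive bonds from geometry
#'
#' Two atoms are bonded when their distance is at most
#' `scale * (r_cov(Z_i) + r_cov(Z_j))`, the standard covalent-radii
#' neighbor-list rule.
#'
#' @param s a `structure3d`.
#' @param scale multiplier on the covalent-radii sum (default 1.2).
#' @return integer matrix with columns `i`, `j` (i < j), one row per bond.
#' @export
perceive_bonds <- function(s, scale = 1.2) {
  n <- nrow(s$coords)
  r <- covalent_radius(s$atomic_numbers)
  if (n < 2L) return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j"))))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- sqrt(rowSums((s$coords[pairs[, 1], , drop = FALSE] -
                     s$coords[pairs[, 2], , drop = FALSE])^2))
  cut <- scale * (r[pairs[, 1]] + r[pairs[, 2]])
  b <- pairs[d <= cut, , drop = FALSE]
  colnames(b) <- c("i", "j")
  b[order(b[, 1], b[, 2]), , drop = FALSE]
}

pair_keys <- function(pairs) {
  if (nrow(pairs) == 0L) return(character(0))
  paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
}

# Proper dihedral angle a-b-c-d in degrees, in (-180, 180].
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# Absolute dihedral difference wrapped to [0, 180].
wrap_angle_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Detect bonding and dihedral changes between IS and FS
#'
#' Classifies the reaction connecting two structures with identical atom
#' ordering into broken bonds (present in IS, absent in FS), formed bonds
#' (absent in IS, present in FS), and rotated bonds: bonds present in both
#' whose largest substituent dihedral change is at least `rot_threshold`
#' degrees. Rotated excludes pairs already labeled broken or formed.
#'
#' @param IS,FS `structure3d` objects with the same atoms in the same order.
#' @param scale bond-perception scale (see [perceive_bonds()]).
#' @param rot_threshold dihedral-change threshold in degrees (default 105,
#'   below the 120 degrees of a typical sp3 C-C rotation).
#' @return object of class `reaction_diff`: list with integer pair matrices
#'   `broken`, `formed`, `rotated`.
#' @details The dihedral change of a bond (b, c) is the maximum wrapped
#'   difference over all substituent pairs (a, d) with a bonded to b and d
#'   bonded to c in both states, hydrogens included; the maximum over
#'   substituents makes detection independent of which substituent is chosen
#'   as the reference.
#' @export
diff_reaction <- function(IS, FS, scale = 1.2, rot_threshold = 105) {
  if (length(IS$atomic_numbers) != length(FS$atomic_numbers) ||
      !all(IS$atomic_numbers == FS$atomic_numbers))
    stop("IS and FS must contain the same atoms in the same order")
  b1 <- perceive_bonds(IS, scale)
  b2 <- perceive_bonds(FS, scale)
  k1 <- pair_keys(b1); k2 <- pair_keys(b2)
  broken <- b1[!(k1 %in% k2), , drop = FALSE]
  formed <- b2[!(k2 %in% k1), , drop = FALSE]
  common <- b1[k1 %in% k2, , drop = FALSE]

  nbr <- function(bonds) {
    n <- length(IS$atomic_numbers)
    adj <- vector("list", n)
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, 1]; j <- bonds[r, 2]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
    adj
  }
  adj1 <- nbr(b1); adj2 <- nbr(b2)

  rotated <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j")))
  for (r in seq_len(nrow(common))) {
    b <- common[r, 1]; c_ <- common[r, 2]
    subs_b <- setdiff(intersect(adj1[[b]], adj2[[b]]), c_)
    subs_c <- setdiff(intersect(adj1[[c_]], adj2[[c_]]), b)
    if (length(subs_b) == 0L || length(subs_c) == 0L) next
    mx <- 0
    for (a in subs_b) for (d in subs_c) {
      if (a == d) next
      d_is <- dihedral_angle(IS$coords[a, ], IS$coords[b, ], IS$coords[c_, ], IS$coords[d, ])
      d_fs <- dihedral_angle(FS$coords[a, ], FS$coords[b, ], FS$coords[c_, ], FS$coords[d, ])
      mx <- max(mx, wrap_angle_diff(d_is, d_fs))
    }
    if (mx >= rot_threshold) rotated <- rbind(rotated, common[r, , drop = FALSE])
  }
  structure(list(broken = broken, formed = formed, rotated = rotated),
            class = "reaction_diff")
}

#' @export
print.reaction_diff <- function(x, ...) {
  fmt <- function(p) if (nrow(p) == 0L) "-" else
    paste(apply(p, 1, function(r) paste0(r[1], "-", r[2])), collapse = ", ")
  cat("<reaction_diff> broken:", fmt(x$broken),
      "| formed:", fmt(x$formed), "| rotated:", fmt(x$rotated), "\n")
  invisible(x)
}

#' Serialize / deserialize a reaction diff as JSON
#'
#' Pairs are written 0-based for interoperability with XYZ atom indexing
#' conventions used by external tools.
#' @param diff a `reaction_diff`.
#' @param file output (input) path.
#' @export
write_reaction_diff <- function(diff, file) {
  to0 <- function(p) if (nrow(p) == 0L) list() else
    lapply(seq_len(nrow(p)), function(r) as.integer(p[r, ] - 1L))
  jsonlite::write_json(list(broken = to0(diff$broken), formed = to0(diff$formed),
                            rotated = to0(diff$rotated)),
                       file, auto_unbox = FALSE)
  invisible(file)
}

#' @rdname write_reaction_diff
#' @export
read_reaction_diff <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  to1 <- function(p) {
    if (is.null(p) || length(p) == 0L)
      return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j"))))
    m <- matrix(as.integer(unlist(p)), ncol = 2, byrow = TRUE) + 1L
    colnames(m) <- c("i", "j")
    m
  }
  structure(list(broken = to1(j$broken), formed = to1(j$formed),
                 rotated = to1(j$rotated)), class = "reaction_diff")
}

#' Build the sparse attention edge set over current + IS + supernode nodes
#'
#' Nodes 1..N are the atoms of the current structure, N+1..2N the IS copies
#' of the same atoms, and 2N+1..2N+n_super the (coordinate-free) supernodes.
#' Edge kinds:
#' \itemize{
#'   \item `window`: for each receiving atom, directed edges from up to
#'     `window_k` nearest neighbors within `window_cut` Angstrom, built both
#'     among current atoms and among IS copies;
#'   \item `random`: up to `n_random` seeded draws per receiving atom from
#'     the remaining pairs within `random_cut` Angstrom;
#'   \item `is_link`: one directed edge per atom from its IS copy to its
#'     current copy (information flows IS -> current only);
#'   \item `atom_super` / `super_super`: every current atom connected to
#'     every supernode in both directions, and supernodes fully connected;
#'     their relative coordinates are zero.
#' }
#'
#' @param current,IS `structure3d` objects with identical atom ordering.
#' @param seed integer seed for the random edges.
#' @param window_k,window_cut window-edge neighbor cap and distance cutoff.
#' @param n_random,random_cut random-edge count per atom and distance cutoff.
#' @param n_super number of supernodes (default 2).
#' @return data.frame with columns `src`, `dst`, `kind`, and `rx`, `ry`, `rz`
#'   (relative coordinate `x_dst - x_src` in the node pair's frame; zero for
#'   supernode edges).
#' @export
build_edges <- function(current, IS, seed = 1L, window_k = 128L, window_cut = 12,
                        n_random = 32L, random_cut = 30, n_super = 2L) {
  n <- nrow(current$coords)
  if (nrow(IS$coords) != n) stop("current and IS atom counts differ")

  edges_among <- function(coords, offset, rng) {
    # window edges: up to window_k nearest within window_cut, per receiver
    src <- integer(0); dst <- integer(0); kind <- character(0)
    rel <- matrix(numeric(0), 0, 3)
    if (n >= 2L) {
      dmat <- as.matrix(stats::dist(coords))
      for (i in seq_len(n)) {
        d <- dmat[, i]; d[i] <- Inf
        cand <- which(d <= window_cut)
        cand <- cand[order(d[cand], cand)]
        win <- sort(utils::head(cand, window_k))  # canonical (index) order
        pool <- setdiff(which(d <= random_cut), c(i, win))
        nr <- min(n_random, length(pool))
        rnd <- if (nr > 0L) sort(pool[sample.int(length(pool), nr)]) else integer(0)
        js <- c(win, rnd)
        if (length(js) > 0L) {
          src <- c(src, offset + js)
          dst <- c(dst, rep(offset + i, length(js)))
          kind <- c(kind, rep(c("window", "random"), c(length(win), length(rnd))))
          rel <- rbind(rel, coords[rep(i, length(js)), , drop = FALSE] -
                              coords[js, , drop = FALSE])
        }
      }
    }
    list(src = src, dst = dst, kind = kind, rel = rel)
  }

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  cur <- edges_among(current$coords, 0L)
  isc <- edges_among(IS$coords, n)

  src <- c(cur$src, isc$src); dst <- c(cur$dst, isc$dst)
  kind <- c(cur$kind, isc$kind); rel <- rbind(cur$rel, isc$rel)

  # is_link: IS copy -> current copy of the same atom
  src <- c(src, n + seq_len(n)); dst <- c(dst, seq_len(n))
  kind <- c(kind, rep("is_link", n))
  rel <- rbind(rel, current$coords - IS$coords)

  # supernodes: current atoms <-> supernodes both directions, super <-> super
  if (n_super > 0L) {
    supers <- 2L * n + seq_len(n_super)
    for (sup in supers) {
      src <- c(src, seq_len(n), rep(sup, n))
      dst <- c(dst, rep(sup, n), seq_len(n))
      kind <- c(kind, rep("atom_super", 2L * n))
      rel <- rbind(rel, matrix(0, 2L * n, 3))
    }
    if (n_super > 1L) {
      ss <- expand.grid(src = supers, dst = supers)
      ss <- ss[ss$src != ss$dst, ]
      src <- c(src, ss$src); dst <- c(dst, ss$dst)
      kind <- c(kind, rep("super_super", nrow(ss)))
      rel <- rbind(rel, matrix(0, nrow(ss), 3))
    }
  }
  data.frame(src = src, dst = dst, kind = kind,
             rx = rel[, 1], ry = rel[, 2], rz = rel[, 3],
             stringsAsFactors = FALSE)
}

#' The 9-component binary condition vector of one edge
#'
#' Components, in order: (1) the edge's atom pair is a broken bond, (2) a
#' formed bond, (3) a rotated bond (zeroed when 1 or 2 is set), (4) whether
#' components 1-3 are fed to the model (the conditional flag; when 0,
#' components 1-3 are forced to 0), (5) the edge is an IS-to-current link,
#' (6)-(9) one-hot over window / random / atom-supernode /
#' supernode-supernode edge kinds.
#'
#' @param edges edge data.frame from [build_edges()] (any subset of rows).
#' @param diff a `reaction_diff`, or NULL for no reaction labels.
#' @param conditional_flag logical: condition component 4.
#' @param n_atoms atom count N of the underlying structures, used to map IS
#'   node indices back to atom indices.
#' @return integer matrix with one 9-column row per edge.
#' @export
condition_vectors <- function(edges, diff, conditional_flag, n_atoms) {
  keys <- list(
    broken  = if (is.null(diff)) character(0) else pair_keys(diff$broken),
    formed  = if (is.null(diff)) character(0) else pair_keys(diff$formed),
    rotated = if (is.null(diff)) character(0) else pair_keys(diff$rotated))
  out <- matrix(0L, nrow(edges), 9L)
  atom_of <- function(idx) ifelse(idx <= n_atoms, idx,
                                  ifelse(idx <= 2L * n_atoms, idx - n_atoms, NA_integer_))
  a <- atom_of(edges$src); b <- atom_of(edges$dst)
  ek <- ifelse(is.na(a) | is.na(b) | a == b, NA_character_,
               paste(pmin(a, b), pmax(a, b)))
  out[, 1] <- as.integer(!is.na(ek) & ek %in% keys$broken)
  out[, 2] <- as.integer(!is.na(ek) & ek %in% keys$formed)
  out[, 3] <- as.integer(!is.na(ek) & ek %in% keys$rotated &
                           out[, 1] == 0L & out[, 2] == 0L)
  out[, 4] <- as.integer(isTRUE(conditional_flag))
  if (!isTRUE(conditional_flag)) out[, 1:3] <- 0L
  out[, 5] <- as.integer(edges$kind == "is_link")
  out[, 6] <- as.integer(edges$kind == "window")
  out[, 7] <- as.integer(edges$kind == "random")
  out[, 8] <- as.integer(edges$kind == "atom_super")
  out[, 9] <- as.integer(edges$kind == "super_super")
  out
}
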