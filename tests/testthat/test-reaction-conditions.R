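test_that("bond perception follows the covalent-radii rule", {
  h2 <- structure3d(c(1L, 1L), rbind(c(0, 0, 0), c(0.74, 0, 0)))
  expect_equal(nrow(perceive_bonds(h2)), 1L)  # 0.74 <= 1.2*(0.31+0.31)

  cc_far <- structure3d(c(6L, 6L), rbind(c(0, 0, 0), c(5, 0, 0)))
  expect_equal(nrow(perceive_bonds(cc_far)), 0L)

  eth <- build_alkane(2)
  b <- perceive_bonds(eth)
  expect_equal(nrow(b), 7L)  # 1 C-C + 6 C-H
  z <- eth$atomic_numbers
  cc <- sum(z[b[, 1]] == 6 & z[b[, 2]] == 6)
  expect_equal(cc, 1L)

  expect_error(perceive_bonds(structure3d(80L, matrix(0, 1, 3))),
               "no covalent radius")
})

test_that("reaction diffs classify broken, formed, and rotated bonds", {
  eth <- build_alkane(2)
  expect_equal(nrow(diff_reaction(eth, eth)$broken), 0L)
  expect_equal(nrow(diff_reaction(eth, eth)$formed), 0L)
  expect_equal(nrow(diff_reaction(eth, eth)$rotated), 0L)

  fx <- butane_rotation_fixture()
  expect_equal(unname(fx$diff$rotated), matrix(c(2L, 3L), 1), ignore_attr = TRUE)
  expect_equal(nrow(fx$diff$broken), 0L)
  expect_equal(nrow(fx$diff$formed), 0L)

  # C-C stretched past the cutoff counts as broken
  cc <- structure3d(c(6L, 6L), rbind(c(0, 0, 0), c(1.54, 0, 0)))
  cc2 <- structure3d(c(6L, 6L), rbind(c(0, 0, 0), c(3.0, 0, 0)))
  d <- diff_reaction(cc, cc2)
  expect_equal(unname(d$broken), matrix(c(1L, 2L), 1), ignore_attr = TRUE)

  expect_error(diff_reaction(eth, cc), "same atoms")
})

test_that("diff_reaction is antisymmetric in IS and FS", {
  h2 <- structure3d(c(1L, 1L), rbind(c(0, 0, 0), c(0.74, 0, 0)))
  bp <- make_bond_change_path(h2, c(1, 2), "break", 10)
  IS <- frame_struct(h2$atomic_numbers, bp$points[1, ])
  FS <- frame_struct(h2$atomic_numbers, bp$points[10, ])
  fwd <- diff_reaction(IS, FS)
  rev <- diff_reaction(FS, IS)
  expect_equal(fwd$broken, rev$formed)
  expect_equal(fwd$formed, rev$broken)

  fx <- butane_rotation_fixture()
  expect_equal(diff_reaction(fx$FS, fx$IS)$rotated, fx$diff$rotated)
})

test_that("edge construction produces the window/random/link/supernode layout", {
  tri <- structure3d(c(8L, 1L, 1L),
                     rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
  e <- build_edges(tri, tri, seed = 1)
  n <- 3L
  win_in <- table(e$dst[e$kind == "window" & e$dst <= n])
  expect_true(all(win_in == 2L))           # every atom hears 2 window edges
  expect_equal(sum(e$kind == "is_link"), 3L)
  expect_equal(sum(e$kind == "super_super"), 2L)
  expect_equal(sum(e$kind == "atom_super"), 12L)  # 2 supers x 3 atoms x 2 dirs
  # supernode and is_link relative coordinates
  expect_true(all(abs(e[e$kind %in% c("atom_super", "super_super"),
                        c("rx", "ry", "rz")]) == 0))
  e2 <- build_edges(tri, tri, seed = 1)
  expect_identical(e, e2)
})

test_that("edge construction is permutation-consistent", {
  pent <- build_alkane(3)  # 11 atoms; use the first 5 for a compact fixture
  s <- structure3d(pent$atomic_numbers[1:5], pent$coords[1:5, ])
  e <- build_edges(s, s, seed = 3)
  perm <- c(3L, 1L, 5L, 2L, 4L)
  inv <- order(perm)
  sp <- structure3d(s$atomic_numbers[perm], s$coords[perm, ])
  ep <- build_edges(sp, sp, seed = 3)
  # window edges must map under the permutation (random edges are seed-bound
  # to atom identity and may differ; supernode edges are symmetric anyway)
  remap <- function(idx, n = 5L) {
    vapply(idx, function(i) {
      if (i <= n) inv[i] else if (i <= 2L * n) n + inv[i - n] else i
    }, integer(1))
  }
  key <- function(d) sort(paste(d$src, d$dst))
  ew <- e[e$kind == "window", ]
  epw <- ep[ep$kind == "window", ]
  expect_identical(key(data.frame(src = remap(ew$src), dst = remap(ew$dst))),
                   key(epw))
})

test_that("condition vectors encode the nine reaction/topology components", {
  fx <- butane_rotation_fixture()
  # synthetic formed bond on atoms 1-5 for the encoding check
  diff <- structure(list(
    broken = matrix(integer(0), 0, 2),
    formed = matrix(c(1L, 5L), 1, 2),
    rotated = matrix(c(2L, 3L), 1, 2)), class = "reaction_diff")
  edges <- data.frame(src = c(5L, 2L, 15L, 29L, 3L),
                      dst = c(1L, 3L, 1L, 30L, 2L),
                      kind = c("window", "random", "is_link", "super_super", "window"),
                      rx = 0, ry = 0, rz = 0)
  cv <- condition_vectors(edges, diff, conditional_flag = TRUE, n_atoms = 14L)
  expect_equal(cv[1, ], c(0, 1, 0, 1, 0, 1, 0, 0, 0))  # formed, window
  expect_equal(cv[2, ], c(0, 0, 1, 1, 0, 0, 1, 0, 0))  # rotated, random
  expect_equal(cv[3, ], c(0, 0, 0, 1, 1, 0, 0, 0, 0))  # is_link
  expect_equal(cv[4, ], c(0, 0, 0, 1, 0, 0, 0, 0, 1))  # super-super

  cv_u <- condition_vectors(edges, diff, conditional_flag = FALSE, n_atoms = 14L)
  expect_equal(cv_u[1, ], c(0, 0, 0, 0, 0, 1, 0, 0, 0))  # all reaction bits off
  expect_true(all(cv_u[, 1:4] == 0))

  # rotation label suppressed when the pair is also formed
  diff2 <- diff
  diff2$formed <- rbind(diff2$formed, c(2L, 3L))
  cv2 <- condition_vectors(edges, diff2, TRUE, 14L)
  expect_equal(cv2[2, 2:3], c(1, 0))
})

test_that("condition-vector invariants hold on every edge of a real fixture", {
  fx <- butane_rotation_fixture()
  mid <- frame_struct(fx$IS$atomic_numbers, fx$path$points[11, ])
  edges <- build_edges(mid, fx$IS, seed = 2)
  for (flag in c(TRUE, FALSE)) {
    cv <- condition_vectors(edges, fx$diff, flag, n_atoms = 14L)
    expect_true(all(cv %in% c(0L, 1L)))
    expect_true(all(cv[cv[, 1] == 1 | cv[, 2] == 1, 3] == 0))
    if (!flag) expect_true(all(cv[, 1:3] == 0))
    non_link <- edges$kind != "is_link"
    expect_true(all(rowSums(cv[non_link, 6:9, drop = FALSE]) == 1))
    expect_true(all(cv[!non_link, 6:9] == 0))
    expect_true(all(cv[!non_link, 5] == 1))
  }
})

test_that("reaction diffs round-trip through JSON", {
  fx <- butane_rotation_fixture()
  f <- withr::local_tempfile(fileext = ".json")
  write_reaction_diff(fx$diff, f)
  back <- read_reaction_diff(f)
  expect_equal(back$rotated, fx$diff$rotated, ignore_attr = TRUE)
  expect_equal(nrow(back$broken), 0L)
})
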