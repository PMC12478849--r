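test_that("scaffolds have one anchor per tract and tetrad level", {
  s3 <- build_scaffold(3, "RH")
  s2 <- build_scaffold(2, "RH")
  expect_equal(nrow(s3), 12)
  expect_equal(nrow(s2), 8)
  expect_error(build_scaffold(3, "RH", rise = -1), "positive")
  expect_error(build_scaffold(4, "RH"))
  # anchors of one tract are vertically ordered by level
  for (c in 0:3) {
    z <- s3$z[s3$corner == c][order(s3$level[s3$corner == c])]
    expect_true(all(diff(z) > 0))
  }
  # inter-level distance within a tract: rise plus the twist chord
  a1 <- unlist(s3[s3$corner == 0 & s3$level == 1, c("x", "y", "z")])
  a0 <- unlist(s3[s3$corner == 0 & s3$level == 0, c("x", "y", "z")])
  d01 <- sqrt(sum((a1 - a0)^2))
  expect_equal(d01, sqrt(0.34^2 + (2 * 1.0 * sin(15 * pi / 180))^2),
               tolerance = 1e-12)
})

test_that("left-handed scaffolds are mirror images of right-handed ones", {
  rh <- build_scaffold(3, "RH")
  lh <- build_scaffold(3, "LH")
  # mirror through the xz-plane is an isometry mapping one onto the other
  mirrored <- as.matrix(rh[, c("x", "y", "z")]) %*% diag(c(1, -1, 1))
  d_rh <- sort(as.vector(dist(mirrored)))
  d_lh <- sort(as.vector(dist(as.matrix(lh[, c("x", "y", "z")]))))
  expect_equal(d_rh, d_lh, tolerance = 1e-12)
})

test_that("attachment pairs follow the trace; non-propellers error", {
  s <- build_scaffold(3, "RH")
  tr <- trace_topology("-p-p-p")
  ap <- loop_attachment_pair(s, tr, "I")
  expect_equal(ap$winding, "counterclockwise")
  expect_equal(ap$a[["z"]], 2 * 0.34)      # exits at the top level
  expect_equal(ap$b[["z"]], 0)             # enters at the bottom
  tr2 <- trace_topology("+p+p+p")
  expect_equal(loop_attachment_pair(s, tr2, 1)$winding, "clockwise")
  expect_error(loop_attachment_pair(s, trace_topology("-ld+l"), "I"),
               "not a propeller")
})

test_that("constrained surface paths follow the cylinder closed form", {
  s <- build_scaffold(3, "RH", radius = 1.0)
  a <- c(1, 0, 0); b <- c(0, 1, 0)
  p <- shortest_surface_path(s, a, b, "counterclockwise", probe = 0.2)
  expect_equal(p$length, 1.2 * pi / 2, tolerance = 1e-12)
  # winding the other way goes the long way round
  p2 <- shortest_surface_path(s, a, b, "clockwise", probe = 0.2)
  expect_equal(p2$length, 1.2 * 3 * pi / 2, tolerance = 1e-12)
  expect_equal(shortest_surface_path(s, a, a, "clockwise")$length, 0)
  # vertices lie on the guard cylinder
  r <- sqrt(rowSums(p$points[, 1:2]^2))
  expect_true(all(abs(r - 1.2) < 1e-9))
  expect_true(p$length >= sqrt(sum((a - b)^2)))
  # invariant under rotation about the core axis
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  p3 <- shortest_surface_path(s, as.vector(R %*% a), as.vector(R %*% b),
                              "counterclockwise", probe = 0.2)
  expect_equal(p3$length, p$length, tolerance = 1e-12)
})

test_that("LD paths are uniformly longer than SD paths on the scaffold", {
  pp <- propeller_path_lengths(c("RH", "LH"), n_tetrads = 3)
  expect_gt(min(pp$path_length_nm[pp$geometry_label == "LD"]),
            max(pp$path_length_nm[pp$geometry_label == "SD"]))
  # two-tetrad LD paths are shorter than three-tetrad LD paths
  pp2 <- propeller_path_lengths(c("RH", "LH"), n_tetrads = 2)
  expect_lt(max(pp2$path_length_nm[pp2$geometry_label == "LD"]),
            min(pp$path_length_nm[pp$geometry_label == "LD"]))
})

test_that("Kabsch RMSD is zero under rigid motion and matches oracles", {
  set.seed(7)
  A <- matrix(rnorm(15), ncol = 3)
  expect_equal(kabsch_rmsd(A, A), 0, tolerance = 1e-10)
  # proper rotation + translation leaves RMSD at zero
  for (i in 1:5) {
    ang <- runif(3, -pi, pi)
    Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), sin(ang[1]),
                   0, -sin(ang[1]), cos(ang[1])), 3)
    Rz <- matrix(c(cos(ang[2]), sin(ang[2]), 0,
                   -sin(ang[2]), cos(ang[2]), 0, 0, 0, 1), 3)
    B <- A %*% t(Rz %*% Rx) + matrix(runif(3), nrow(A), 3, byrow = TRUE)
    expect_equal(kabsch_rmsd(A, B), 0, tolerance = 1e-9)
  }
  expect_error(kabsch_rmsd(A, A[1:4, ]), "size")
  expect_error(kabsch_rmsd(A[1:2, ], A[1:2, ]), "3 points")

  # two hand-specified 4-point sets: compare against a numeric
  # minimisation over rotations (independent oracle)
  A4 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  B4 <- rbind(c(0.1, 0, 0), c(1, 0.2, 0), c(0, 1.1, -0.1), c(0.1, 0, 0.9))
  oracle <- function(A, B) {
    A0 <- sweep(A, 2, colMeans(A)); B0 <- sweep(B, 2, colMeans(B))
    f <- function(ang) {
      Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), sin(ang[1]),
                     0, -sin(ang[1]), cos(ang[1])), 3)
      Ry <- matrix(c(cos(ang[2]), 0, -sin(ang[2]), 0, 1, 0,
                     sin(ang[2]), 0, cos(ang[2])), 3)
      Rz <- matrix(c(cos(ang[3]), sin(ang[3]), 0,
                     -sin(ang[3]), cos(ang[3]), 0, 0, 0, 1), 3)
      sqrt(mean(rowSums((A0 - B0 %*% t(Rz %*% Ry %*% Rx))^2)))
    }
    grid <- as.matrix(expand.grid(a = seq(-pi, pi, length.out = 7),
                                  b = seq(-pi / 2, pi / 2, length.out = 5),
                                  c = seq(-pi, pi, length.out = 7)))
    best <- Inf
    for (i in seq_len(nrow(grid))) {
      o <- optim(grid[i, ], f, method = "Nelder-Mead")
      best <- min(best, o$value)
    }
    best
  }
  expect_equal(kabsch_rmsd(A4, B4), oracle(A4, B4), tolerance = 1e-5)
  # cross-check against bio3d's superposition
  fit <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(A4)), mobile = as.vector(t(B4))))
  fitted <- matrix(fit, ncol = 3, byrow = TRUE)
  expect_equal(kabsch_rmsd(A4, B4),
               sqrt(mean(rowSums((A4 - fitted)^2))), tolerance = 1e-6)
})

test_that("scaffold PDB files round-trip through a standard parser", {
  s <- build_scaffold(3, "RH")
  f <- tempfile(fileext = ".pdb")
  write_scaffold_pdb(s, f)
  atom_lines <- grep("^ATOM", readLines(f), value = TRUE)
  expect_length(atom_lines, 12)
  back <- read_scaffold_pdb(f)
  ord <- order(back$corner, back$level)
  sord <- order(s$corner, s$level)
  expect_equal(back$x[ord], s$x[sord], tolerance = 1e-4)
  expect_equal(back$y[ord], s$y[sord], tolerance = 1e-4)
  expect_equal(back$z[ord], s$z[sord], tolerance = 1e-4)
  f2 <- tempfile(fileext = ".pdb")
  write_scaffold_pdb(build_scaffold(2, "LH"), f2)
  expect_length(grep("^ATOM", readLines(f2)), 8)
  unlink(c(f, f2))
})
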