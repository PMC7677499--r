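# a bare shell object from coordinates, codes and one atom per residue
shell_from_points <- function(coords, resnames) {
  st <- tiny_structure(coords, radii = 1.7, resname = resnames)
  st$atom$resid <- toupper(rep_len(resnames, nrow(st$atom)))
  res <- structure_residues(st)
  m <- st$atom$mass
  com <- c(sum(m * st$atom$x), sum(m * st$atom$y), sum(m * st$atom$z)) / sum(m)
  structure(list(residues = res, n = nrow(res), com = com, atom = st$atom),
            class = "sb_shell")
}

test_that("shell assignment picks the nearest residue layer only", {
  # two concentric shells; only the inner one faces the void
  inner <- make_hollow_sphere(R_s = 8, resname = "ILE")$structure
  n_in <- nrow(inner$atom)
  outer <- make_hollow_sphere(R_s = 11.5, resname = "ARG")$structure
  outer$atom$resno <- outer$atom$resno + n_in
  outer$atom$serial <- outer$atom$serial + n_in
  both <- inner
  both$atom <- rbind(inner$atom, outer$atom)
  p <- probe_params(n_rotations = 1, seed = 1)
  res <- run_spaceball(both, p)
  met <- surface_metrics(res, p)
  sh <- assign_shell(met$surface, both)
  expect_true(all(sh$residues$resid == "ILE"))
  expect_equal(sh$n, n_in)   # the full inner wall faces the void
})

test_that("H sums the scale additively and permutation-invariantly", {
  pts <- matrix(rnorm(30), ncol = 3)
  sh <- shell_from_points(pts, resnames = rep("ILE", 10))
  expect_equal(hydropathy_H(sh), 45, ignore_attr = TRUE)
  # permutation invariance
  sh2 <- shell_from_points(pts[sample(10), ], rep("ILE", 10))
  expect_equal(hydropathy_H(sh2), hydropathy_H(sh), ignore_attr = TRUE)
  # additivity over a partition
  mix <- shell_from_points(matrix(rnorm(18), ncol = 3), c(rep("ILE", 3), rep("ARG", 3)))
  expect_equal(as.numeric(hydropathy_H(mix)), 3 * 4.5 + 3 * (-4.5))
})

test_that("hydropathy vector: symmetry cancellation, sign flip, direct-sum oracle", {
  fx <- make_hydropathy_shell(scheme = "uniform")
  rec <- cached("hshell_uniform", analyze_structure(fx$structure, probe_params(n_rotations = 1, seed = 4)))
  expect_equal(rec$descriptors$N_CP, 200L)
  expect_equal(rec$descriptors$H, 900)          # 200 x 4.5, exact
  expect_lt(rec$descriptors$h_norm / (200 * 4.5 * 7.5), 0.01)

  fb <- make_hydropathy_shell(scheme = "bipartite")
  recb <- cached("hshell_bipartite", analyze_structure(fb$structure, probe_params(n_rotations = 1, seed = 4)))
  # independent direct summation over the construction coordinates
  expect_equal(recb$descriptors$h_vec, fb$expected$h_vec, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_gt(recb$descriptors$h_vec[3], 0)       # points from ARG side to ILE side
  # flipping all q flips the vector exactly
  sh <- shell_from_points(matrix(rnorm(24), ncol = 3), sample(c("ILE", "ARG", "GLY", "LYS"), 8, TRUE))
  h1 <- hydropathy_vector(sh)$h_vec
  sh_f <- sh
  sh_f$residues$q <- -sh_f$residues$q
  expect_equal(hydropathy_vector(sh_f)$h_vec, -h1)
})

test_that("radius of gyration: constant-radius shells and duplication invariance", {
  u <- make_hollow_sphere(R_s = 8)$structure
  sh <- shell_from_points(as.matrix(u$atom[, c("x", "y", "z")]), "GLY")
  expect_equal(radius_of_gyration(sh), 8, tolerance = 1e-6)
  # duplicating every residue position leaves R_g unchanged
  dup <- rbind(as.matrix(u$atom[, c("x", "y", "z")]), as.matrix(u$atom[, c("x", "y", "z")]))
  sh2 <- shell_from_points(dup, "GLY")
  expect_equal(radius_of_gyration(sh2), radius_of_gyration(sh), tolerance = 1e-9)
})

test_that("shape parameter: sphere ~ 0, cigar positive, disk negative, errors on degenerate", {
  u <- make_hollow_sphere(R_s = 8)$structure
  sh <- shell_from_points(as.matrix(u$atom[, c("x", "y", "z")]), "GLY")
  sp <- shape_parameter(sh)
  expect_lt(abs(sp$w), 0.05)
  expect_equal(sp$radii[1], sp$radii[3], tolerance = 0.05)

  set.seed(1)
  n <- 400
  cigar <- cbind(rnorm(n, sd = 1), rnorm(n, sd = 1), rnorm(n, sd = 8))
  spc <- shape_parameter(shell_from_points(cigar, "GLY"))
  expect_gt(spc$w, 0.3)
  expect_equal(spc$radii[2], spc$radii[3], tolerance = 0.15)

  # flat disks approach the oblate floor w -> (1 - sqrt(2))/(1 + sqrt(2)) ~ -0.17
  disk <- cbind(rnorm(n, sd = 8), rnorm(n, sd = 8), rnorm(n, sd = 0.5))
  spd <- shape_parameter(shell_from_points(disk, "GLY"))
  expect_lt(spd$w, -0.12)

  line <- cbind(seq_len(50), 0, 0)
  expect_error(shape_parameter(shell_from_points(line, "GLY")), "degenerate")
  expect_error(shape_parameter(shell_from_points(rbind(c(0, 0, 0), c(1, 0, 0)), "GLY")),
               "at least 3")
})

test_that("descriptor invariances: |w| < 1, scale behavior, empty shell nulls", {
  set.seed(7)
  for (i in 1:5) {
    pts <- matrix(rnorm(60, sd = runif(1, 1, 6)), ncol = 3)
    sh <- shell_from_points(pts, sample(names(kd_scale()), 20, TRUE))
    sp <- shape_parameter(sh)
    expect_true(abs(sp$w) < 1)
    # uniform scaling: radii and R_g scale linearly, w and H invariant
    sh_scaled <- shell_from_points(pts * 3, sh$residues$resid)
    sp2 <- shape_parameter(sh_scaled)
    expect_equal(sp2$radii, 3 * sp$radii, tolerance = 1e-9)
    expect_equal(sp2$w, sp$w, tolerance = 1e-9)
    expect_equal(radius_of_gyration(sh_scaled), 3 * radius_of_gyration(sh), tolerance = 1e-9)
    expect_equal(hydropathy_H(sh_scaled), hydropathy_H(sh))
  }
  # w = 0 exactly when R2 = (R1 + R3) / 2 by construction of the formula
  empty <- structure(list(residues = structure_residues(tiny_structure(c(0, 0, 0), 1.7))[0, ],
                          n = 0L, com = rep(NA_real_, 3),
                          atom = tiny_structure(c(0, 0, 0), 1.7)$atom[0, ]),
                     class = "sb_shell")
  d <- shell_descriptors(empty)
  expect_equal(d$N_CP, 0L)
  expect_equal(d$H, 0)
  expect_true(is.na(d$R_g))
  expect_true(is.null(hydropathy_vector(empty)))
})

test_that("h_vec rotates covariantly with the structure frame", {
  set.seed(3)
  pts <- matrix(rnorm(45, sd = 4), ncol = 3)
  codes <- sample(c("ILE", "ARG", "GLY"), 15, TRUE)
  sh <- shell_from_points(pts, codes)
  h0 <- hydropathy_vector(sh)$h_vec
  R <- random_rotation(5, 0)
  sh_rot <- shell_from_points(pts %*% t(R), codes)
  expect_equal(hydropathy_vector(sh_rot)$h_vec, as.vector(R %*% h0), tolerance = 1e-9)
  # translation invariance
  sh_tr <- shell_from_points(sweep(pts, 2, c(10, -4, 2), "+"), codes)
  expect_equal(hydropathy_vector(sh_tr)$h_vec, h0, tolerance = 1e-9)
})
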