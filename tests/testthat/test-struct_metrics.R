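test_that("Kabsch superposition recovers rigid motions exactly", {
  set.seed(10)
  X <- matrix(rnorm(60), 20, 3)
  expect_equal(kabsch_superpose(X, X)$rmsd, 0, tolerance = 1e-12)
  R <- rot_z(37)
  Y <- X %*% t(R) + matrix(c(1, 2, 3), 20, 3, byrow = TRUE)
  fit <- kabsch_superpose(X, Y)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$rotation, R, tolerance = 1e-9)
  expect_equal(fit$translation, c(1, 2, 3), tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
})

test_that("Kabsch RMSD equals the quaternion oracle on random clouds", {
  for (seed in 1:100) {
    set.seed(seed)
    X <- matrix(rnorm(30), 10, 3)
    Y <- matrix(rnorm(30), 10, 3)
    fit <- kabsch_superpose(X, Y)
    expect_equal(fit$rmsd, quat_rmsd(X, Y), tolerance = 1e-9,
                 info = paste("seed", seed))
    # never worse than the unaligned distance
    expect_lte(fit$rmsd, sqrt(mean(rowSums((X - Y)^2))) + 1e-12)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  }
})

test_that("degenerate point sets are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "collinear")
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
})

test_that("rmsd is invariant under proper rigid motion of both sets", {
  set.seed(3)
  X <- matrix(rnorm(45), 15, 3)
  Y <- matrix(rnorm(45), 15, 3)
  base <- kabsch_superpose(X, Y)$rmsd
  R <- rot_z(123)
  moved <- kabsch_superpose(X %*% t(R) + 5, Y %*% t(R) + 5)$rmsd
  expect_equal(moved, base, tolerance = 1e-9)
})

test_that("dihedral follows the stated sign convention", {
  expect_equal(dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 1, 1)),
               -90)
  expect_equal(dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0)),
               0)  # A and D eclipsed across the B-C axis: cis
  expect_equal(dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0)),
               180)
})

test_that("backbone torsions invert the ideal-geometry generator", {
  for (ps in list(c(-57, -47), c(-120, 120), c(60, 45))) {
    p <- gen_polypeptide(10, ps[1], ps[2])
    t <- backbone_torsions(p, "A")
    expect_equal(t$phi[2:9], rep(ps[1], 8), tolerance = 1e-6)
    expect_equal(t$psi[2:9], rep(ps[2], 8), tolerance = 1e-6)
    expect_true(is.na(t$phi[1]))
    expect_true(is.na(t$psi[10]))
    expect_equal(t$region[1], "undefined")
  }
})

test_that("torsions are invariant under rigid motion", {
  p <- gen_polypeptide(8, -65, -40)
  moved <- rigid_move(p, rot_z(77), c(3, -2, 9))
  expect_equal(backbone_torsions(moved, "A")$phi,
               backbone_torsions(p, "A")$phi, tolerance = 1e-9)
  expect_equal(backbone_torsions(moved, "A")$psi,
               backbone_torsions(p, "A")$psi, tolerance = 1e-9)
})

test_that("Ramachandran classification uses the bundled regions", {
  p <- gen_polypeptide(6, -60, -45)
  t <- backbone_torsions(p, "A")
  expect_true(all(t$region[2:5] == "favored"))
  # an extended-outlier combination
  p2 <- gen_polypeptide(6, 100, -100)
  t2 <- backbone_torsions(p2, "A")
  expect_true(all(t2$region[2:5] == "outlier"))
})

test_that("missing backbone atoms give undefined torsions with a warning", {
  p <- gen_polypeptide(6, -57, -47)
  p <- p[!(p$res_seq == 3 & p$name == "CA"), ]
  expect_warning(t <- backbone_torsions(p, "A"), "missing backbone")
  expect_true(is.na(t$phi[t$res_seq == 3]))
  expect_equal(t$region[t$res_seq == 3], "undefined")
})

test_that("SASA matches closed forms", {
  carbon <- function(x) {
    s <- gen_pose(4)[2, ]   # a CA carbon row template
    s$x <- x; s$y <- 0; s$z <- 0
    s
  }
  one <- sasa(carbon(0))
  expect_equal(one$per_atom$area, 4 * pi * (1.70 + 1.4)^2,
               tolerance = 0.005)
  # two carbons far apart: no occlusion
  two_far <- sasa(dplyr::bind_rows(carbon(0), carbon(20)))
  expect_equal(two_far$per_atom$area,
               rep(4 * pi * 3.1^2, 2), tolerance = 0.005)
  # overlapping pair: analytic two-cap area
  two_near <- sasa(dplyr::bind_rows(carbon(0), carbon(3)))
  expect_equal(sum(two_near$per_atom$area), two_sphere_sasa(3.1, 3.0),
               tolerance = 0.02)
})

test_that("SASA converges in point count and decreases with occluders", {
  pose <- gen_pose(4.2)
  a <- sasa(pose, n_points = 960)
  b <- sasa(pose, n_points = 4000)
  expect_equal(sum(a$per_atom$area), sum(b$per_atom$area), tolerance = 0.01)
  # adding an occluding atom can only reduce the original atoms' area
  extra <- pose[1, ]
  extra$serial <- 99L; extra$x <- extra$x + 1.5
  withplus <- sasa(dplyr::bind_rows(pose, extra), n_points = 960)
  expect_lte(sum(withplus$per_atom$area[seq_len(nrow(pose))]),
             sum(a$per_atom$area) + 1e-9)
  # per-residue totals sum their atoms
  expect_equal(sum(a$per_residue$area), sum(a$per_atom$area))
  # unknown element fails without an override, passes with one
  odd <- pose[1, ]; odd$element <- "ZZ"
  expect_error(sasa(odd), "no vdW radius")
  expect_s3_class(sasa(odd, radii = c(ZZ = 1.6)), "sasa_result")
})

test_that("atom distances resolve unique selections", {
  pose <- gen_pose(4.2)
  expect_equal(atom_distance(pose,
                             list(chain = "E", res_seq = 25, name = "SG"),
                             list(chain = "P", res_seq = 1, name = "C")),
               4.2, tolerance = 1e-6)
  expect_error(atom_distance(pose, list(chain = "E"),
                             list(chain = "P", res_seq = 1, name = "C")),
               "matches")
  s <- ca_structure(list(A = "GG"))
  s$x <- c(0, 3); s$y <- c(0, 4); s$z <- c(0, 0)
  expect_equal(atom_distance(s, list(res_seq = 1), list(res_seq = 2)), 5)
})

test_that("distance series equals a per-frame recomputation", {
  traj <- gen_trajectory(25, sg_c_profile = seq(3.5, 5.5, length.out = 25),
                         noise_sigma = 0.1, seed = 8)
  sga <- list(chain = "E", res_seq = 25, name = "SG")
  scb <- list(chain = "P", res_seq = 1, name = "C")
  ser <- distance_series(traj, sga, scb)
  brute <- sapply(1:25, function(m) {
    fr <- traj[traj$model == m, ]
    a <- fr[fr$chain == "E" & fr$res_seq == 25 & fr$name == "SG", ]
    b <- fr[fr$chain == "P" & fr$res_seq == 1 & fr$name == "C", ]
    sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
  })
  expect_equal(ser$dist, brute, tolerance = 1e-12)
})

test_that("rmsd series is zero on rigid-motion frames", {
  pose <- gen_pose(4.0)
  frames <- lapply(1:4, function(m) {
    fr <- rigid_move(pose, rot_z(20 * m), c(m, 0, -m))
    fr$model <- m
    fr
  })
  traj <- dplyr::bind_rows(frames)
  ser <- rmsd_series(traj, reference_model = 1)
  expect_equal(ser$rmsd, rep(0, 4), tolerance = 1e-9)
})

test_that("rmsd series matches an independent fitting oracle under noise", {
  set.seed(77)
  pose <- gen_polypeptide(12, -57, -47)
  sigma <- 0.1
  frames <- lapply(1:30, function(m) {
    fr <- pose
    fr$x <- fr$x + rnorm(nrow(fr), 0, sigma)
    fr$y <- fr$y + rnorm(nrow(fr), 0, sigma)
    fr$z <- fr$z + rnorm(nrow(fr), 0, sigma)
    fr$model <- m
    fr
  })
  traj <- dplyr::bind_rows(list(dplyr::mutate(pose, model = 0L)), frames)
  ser <- rmsd_series(traj, reference_model = 0)
  # independent per-frame oracle (quaternion method)
  ref <- as.matrix(pose[, c("x", "y", "z")])
  oracle <- sapply(frames, function(fr)
    quat_rmsd(as.matrix(fr[, c("x", "y", "z")]), ref))
  expect_equal(ser$rmsd[-1], unname(oracle), tolerance = 1e-9)
  # Monte-Carlo expectation of the fitted RMSD under iid Gaussian noise
  mc <- replicate(200, quat_rmsd(ref + matrix(rnorm(length(ref), 0, sigma),
                                              ncol = 3), ref))
  expect_equal(mean(ser$rmsd[-1]), mean(mc), tolerance = 0.1)
})

test_that("stable and relaxing trajectories separate on peptide RMSD", {
  stable <- traj_preset("stable", n_frames = 40, seed = 4)
  relax <- traj_preset("relaxing-peptide", n_frames = 40, seed = 4)
  plateau <- 1.0
  s_pep <- rmsd_series(stable, chain = "P", name = "CB")
  r_pep <- rmsd_series(relax, chain = "P", name = "CB")
  expect_lt(max(s_pep$rmsd), plateau)
  expect_gt(max(r_pep$rmsd), plateau)
  # the enzyme selection stays put in both
  s_enz <- rmsd_series(stable, chain = "E", name = "CA")
  expect_lt(max(s_enz$rmsd), 1e-9)
})

test_that("missing atoms in a frame are reported by frame and atom", {
  traj <- gen_trajectory(3, seed = 1)
  broken <- traj[!(traj$model == 2 & traj$chain == "E" & traj$name == "SG"), ]
  expect_error(rmsd_series(broken, chain = "E"), "frame 2")
})
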