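test_that("pose screening applies the SG-C threshold with <= semantics", {
  expect_equal(screen_pose(gen_pose(4.2))$verdict, "accept")
  expect_equal(screen_pose(gen_pose(7.0))$verdict, "reject")
  expect_equal(screen_pose(gen_pose(5.0))$verdict, "accept")  # boundary
  spec45 <- catalytic_spec(max_sg_c = 4.5)
  expect_equal(screen_pose(gen_pose(4.6), spec45)$verdict, "reject")
  expect_equal(screen_pose(gen_pose(4.6))$verdict, "accept")
  out <- screen_pose(gen_pose(3.3))
  expect_equal(out$sg_c, 3.3, tolerance = 1e-6)
  expect_equal(out$threshold, 5.0)
  expect_error(catalytic_spec(max_sg_c = -1), "positive")
})

test_that("missing catalytic atoms are reported by name", {
  pose <- gen_pose(4.2)
  no_sg <- pose[pose$name != "SG", ]
  expect_error(screen_pose(no_sg), "matches 0 atoms")
})

test_that("hydrogen-bond counting honours distance and angle criteria", {
  mk_frame <- function(da, hda_deg) {
    # donor N at origin with H on +z; acceptor O at distance da, angle hda
    ang <- hda_deg * pi / 180
    dplyr::bind_rows(
      tibble::tibble(model = 1L, serial = 1L, name = "N", alt = " ",
                     res_name = "GLY", chain = "E", res_seq = 1L, ins = " ",
                     x = 0, y = 0, z = 0, element = "N", hetero = FALSE),
      tibble::tibble(model = 1L, serial = 2L, name = "H", alt = " ",
                     res_name = "GLY", chain = "E", res_seq = 1L, ins = " ",
                     x = 0, y = 0, z = 1, element = "H", hetero = FALSE),
      tibble::tibble(model = 1L, serial = 3L, name = "O", alt = " ",
                     res_name = "GLY", chain = "P", res_seq = 9L, ins = " ",
                     x = da * sin(ang), y = 0, z = da * cos(ang),
                     element = "O", hetero = FALSE)
    )
  }
  count_in <- function(fr, ...) {
    hbond_count(fr, fr[fr$name == "N", ], fr[fr$name == "O", ], ...)
  }
  expect_equal(count_in(mk_frame(2.9, 10)), 1L)
  expect_equal(count_in(mk_frame(4.0, 10)), 0L)   # distance cut
  expect_equal(count_in(mk_frame(2.9, 40)), 0L)   # angle cut
  expect_equal(count_in(mk_frame(2.9, 40), use_hydrogens = FALSE), 1L)
  expect_equal(count_in(mk_frame(2.9, 40),
                        criteria = hbond_criteria(max_angle_hda = 45)), 1L)
  expect_error(hbond_count(mk_frame(2.9, 10), mk_frame(2.9, 10)[0, ],
                           mk_frame(2.9, 10)), "non-empty")
})

test_that("hbond_count equals exhaustive enumeration on random frames", {
  for (seed in 1:25) {
    set.seed(seed)
    nd <- 6; na <- 6
    frame <- dplyr::bind_rows(
      purrr::map_dfr(1:nd, function(i) dplyr::bind_rows(
        tibble::tibble(model = 1L, serial = 10L + 2L * i, name = "N",
                       alt = " ", res_name = "GLY", chain = "E",
                       res_seq = i, ins = " ",
                       x = runif(1, 0, 8), y = runif(1, 0, 8),
                       z = runif(1, 0, 8), element = "N", hetero = FALSE),
        tibble::tibble(model = 1L, serial = 11L + 2L * i, name = "H",
                       alt = " ", res_name = "GLY", chain = "E",
                       res_seq = i, ins = " ",
                       x = 0, y = 0, z = 0, element = "H", hetero = FALSE)
      )),
      purrr::map_dfr(1:na, function(i)
        tibble::tibble(model = 1L, serial = 100L + i, name = "O",
                       alt = " ", res_name = "GLY", chain = "P",
                       res_seq = i, ins = " ",
                       x = runif(1, 0, 8), y = runif(1, 0, 8),
                       z = runif(1, 0, 8), element = "O", hetero = FALSE))
    )
    # put each H 1 A from its donor in a random direction
    for (i in 1:nd) {
      dsel <- frame$name == "N" & frame$res_seq == i
      hsel <- frame$name == "H" & frame$res_seq == i
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      frame$x[hsel] <- frame$x[dsel] + dir[1]
      frame$y[hsel] <- frame$y[dsel] + dir[2]
      frame$z[hsel] <- frame$z[dsel] + dir[3]
    }
    donors <- frame[frame$name == "N", ]
    acceptors <- frame[frame$name == "O", ]
    expect_equal(hbond_count(frame, donors, acceptors),
                 brute_hbond(frame, donors, acceptors),
                 info = paste("seed", seed))
  }
})

test_that("bond count is monotone non-increasing as max_da shrinks", {
  traj <- gen_trajectory(5, n_hbonds = 8, seed = 2)
  fr <- traj[traj$model == 1, ]
  donors <- fr[fr$chain == "E" & fr$name == "N", ]
  acceptors <- fr[fr$chain == "P" & fr$name == "O", ]
  cuts <- c(4.0, 3.5, 3.0, 2.5)
  counts <- sapply(cuts, function(dc)
    hbond_count(fr, donors, acceptors, hbond_criteria(max_da = dc)))
  expect_true(all(diff(counts) <= 0))
})

test_that("trajectory summaries report series, mean/se and five numbers", {
  fn <- five_number(c(1, 2, 3, 4, 5))
  expect_equal(unlist(fn), c(min = 1, q1 = 2, median = 3, q3 = 4, max = 5))

  traj <- gen_trajectory(20, sg_c_profile = 4.0, seed = 3)
  s <- traj_summary(traj, "sg_c")
  expect_equal(s$mean, 4.0, tolerance = 1e-9)
  expect_equal(s$se, 0, tolerance = 1e-12)
  expect_equal(unlist(s$five_num), setNames(rep(4, 5),
                                            c("min", "q1", "median", "q3", "max")))
  h <- traj_summary(traj, "hbond",
                    donors_sel = list(chain = "E", name = "N"),
                    acceptors_sel = list(chain = "P", name = "O"))
  expect_equal(h$per_frame$value, rep(3, 20))
  expect_error(traj_summary(traj[traj$model == 1, ], "sg_c"), "2 frames")
  expect_error(traj_summary(traj, "hbond"), "donors_sel")
})

test_that("planted quartiles are recovered from a generated series", {
  prof <- sgc_profile_quartiles(4000, q1 = 3.6, q3 = 4.4, seed = 12)
  traj <- gen_trajectory(4000, sg_c_profile = prof, seed = 12)
  s <- traj_summary(traj, "sg_c")
  expect_equal(s$five_num$q1, 3.6, tolerance = 0.02)
  expect_equal(s$five_num$q3, 4.4, tolerance = 0.02)
})

test_that("deltaG/Kd conversion matches the reported docking table", {
  expect_equal(kd_from_dg(0), 1)
  # gamma.1: -12.3 kcal/mol at 310 K -> 2.1e-9; A-alpha.2: -14.1 -> 1.2e-10
  expect_equal(kd_from_dg(-12.3, 310), 2.1e-9, tolerance = 0.1)
  expect_equal(kd_from_dg(-14.1, 310), 1.2e-10, tolerance = 0.1)
  expect_equal(kd_from_dg(-15.4, 310), 1.5e-11, tolerance = 0.1)
  for (x in seq(-20, 0, length.out = 21)) {
    expect_equal(dg_from_kd(kd_from_dg(x)), x, tolerance = 1e-12)
  }
  expect_true(all(diff(kd_from_dg(seq(-10, -1, 1))) > 0))
  expect_lt(kd_from_dg(-0.001), 1)
  expect_error(dg_from_kd(-1), "positive")
  expect_error(kd_from_dg(-5, temperature = 0), "positive")
})

test_that("hydrogen-bond group comparison produces consistent letters", {
  set.seed(5)
  same <- data.frame(complex = rep(c("a", "b"), each = 50),
                     count = rnorm(100, 5, 1))
  r1 <- compare_hbond_groups(same)
  expect_equal(r1$letters[["a"]], r1$letters[["b"]])

  neg <- data.frame(
    complex = rep(c("good", "control"), each = 100),
    count = c(rnorm(100, 10, 1), rnorm(100, 4, 1)))
  r2 <- compare_hbond_groups(neg, alpha = 0.01)
  expect_false(r2$letters[["good"]] == r2$letters[["control"]])
  expect_lt(r2$posthoc$p_holm[1], 0.01)

  three <- data.frame(
    complex = rep(c("hi", "mid", "lo"), each = 60),
    count = c(rnorm(60, 12, 1), rnorm(60, 8, 1), rnorm(60, 4, 1)))
  r3 <- compare_hbond_groups(three, alpha = 0.01)
  expect_length(unique(r3$letters), 3)
  # letters follow the mean ordering: highest mean gets "a"
  expect_equal(unname(r3$letters[["hi"]]), "a")
})

test_that("negative-control preset has fewer bonds and larger SG-C", {
  good <- traj_preset("good-pose", n_frames = 120, seed = 6)
  bad <- traj_preset("bad-pose", n_frames = 120, seed = 7)
  don <- list(chain = "E", name = "N"); acc <- list(chain = "P", name = "O")
  hb_good <- traj_summary(good, "hbond", donors_sel = don, acceptors_sel = acc)
  hb_bad <- traj_summary(bad, "hbond", donors_sel = don, acceptors_sel = acc)
  expect_gt(hb_good$mean, hb_bad$mean)
  sg_good <- traj_summary(good, "sg_c")
  sg_bad <- traj_summary(bad, "sg_c")
  expect_true(all(unlist(sg_bad$five_num[, c("q1", "median", "q3")]) >
                    unlist(sg_good$five_num[, c("q1", "median", "q3")])))
  cmp <- compare_hbond_groups(
    data.frame(complex = rep(c("good", "control"), each = 120),
               count = c(hb_good$per_frame$value, hb_bad$per_frame$value)),
    alpha = 0.01)
  expect_false(cmp$letters[["good"]] == cmp$letters[["control"]])
})
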