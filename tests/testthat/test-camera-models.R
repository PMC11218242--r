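paper_intr <- function() default_intrinsics()
paper_dist <- function() default_distortion()

test_that("telecentric projection drops depth and preserves YZ geometry", {
  trk <- as_track_tbl(cbind(0.7, 0.2, 1.1))
  out <- telecentric_project(trk)
  expect_equal(c(out$u, out$v), c(0.2, 1.1))
  expect_identical(out$unit, "m")

  circ <- circle_track_yz(n = 200, r = 0.4, depth = 1.3)
  tele <- telecentric_project(circ)
  expect_equal(sqrt(tele$u^2 + tele$v^2), rep(0.4, 200), tolerance = 1e-12)

  shifted <- dplyr::mutate(circ, x_m = x_m + 2.5)
  tele2 <- telecentric_project(shifted)
  expect_identical(tele$u, tele2$u)
  expect_identical(tele$v, tele2$v)
})

test_that("pinhole projection reproduces hand-computed values with the published camera", {
  intr <- paper_intr()
  pose <- aim_camera(matrix(c(0, 0, 0), 1), distance = 2)

  # optical axis: any distortion maps to the principal point
  on_axis <- pinhole_project(matrix(c(0, 0, 0), 1), intr, paper_dist(), pose)
  expect_equal(as.numeric(on_axis), c(705.234, 515.751), tolerance = 1e-9)

  # 0.5 m lateral offset at 2 m depth, zero distortion:
  # u = cx + fx * 0.25
  off <- pinhole_project(matrix(c(0, 0.5, 0), 1), intr,
                         distortion_model(), pose)
  expect_equal(unname(off[1, 1]), 705.234 + 1993.208 * 0.25,
               tolerance = 1e-9)
  expect_equal(unname(off[1, 1]), 1203.536, tolerance = 1e-3)

  # behind-camera points are named
  expect_error(
    pinhole_project(matrix(c(-3, 0, 0), 1), intr, paper_dist(), pose),
    "behind the camera"
  )
})

test_that("pinhole projection matches the independent NumPy oracle to < 1e-6 px", {
  skip_if_not(python_available(), "python not on PATH")
  set.seed(20)
  n_scenes <- 20
  pts_per_scene <- 500
  worst <- 0
  for (s in seq_len(n_scenes)) {
    R <- random_rotation(3000 + s)
    t <- c(runif(2, -0.5, 0.5), runif(1, 1, 3))
    # generate points with guaranteed positive camera-frame depth
    xc <- cbind(runif(pts_per_scene, -1, 1), runif(pts_per_scene, -1, 1),
                runif(pts_per_scene, 0.5, 5))
    pw <- (xc - matrix(t, pts_per_scene, 3, byrow = TRUE)) %*% R
    intr <- camera_intrinsics(fx = runif(1, 500, 3000),
                              fy = runif(1, 500, 3000),
                              cx = runif(1, 300, 900),
                              cy = runif(1, 300, 900))
    dist <- distortion_model(k1 = runif(1, -0.3, 0.3),
                             k2 = runif(1, -0.3, 0.3),
                             p1 = runif(1, -0.01, 0.01),
                             p2 = runif(1, -0.01, 0.01),
                             k3 = runif(1, -0.1, 0.1))
    ours <- pinhole_project(pw, intr, dist, camera_pose(R, t))
    oracle <- run_python_oracle("project_points.py", list(
      points = pw, R = R, t = t,
      fx = intr$fx, fy = intr$fy, cx = intr$cx, cy = intr$cy,
      k1 = dist$k1, k2 = dist$k2, k3 = dist$k3, p1 = dist$p1, p2 = dist$p2
    ))
    worst <- max(worst, max(abs(ours - oracle)))
  }
  expect_lt(worst, 1e-6)
})

test_that("the published distortion coefficients agree with the oracle on a random cloud", {
  skip_if_not(python_available(), "python not on PATH")
  set.seed(77)
  pts <- cbind(runif(1000, -0.5, 0.5), runif(1000, -0.5, 0.5),
               runif(1000, -0.5, 0.5))
  pose <- aim_camera(pts, 2)
  intr <- paper_intr()
  dist <- paper_dist()
  ours <- pinhole_project(pts, intr, dist, pose)
  oracle <- run_python_oracle("project_points.py", list(
    points = pts, R = pose$R, t = pose$t,
    fx = intr$fx, fy = intr$fy, cx = intr$cx, cy = intr$cy,
    k1 = dist$k1, k2 = dist$k2, k3 = 0, p1 = 0, p2 = 0
  ))
  expect_lt(max(abs(ours - oracle)), 1e-6)
})

test_that("aim_camera centres the bounding cuboid on the optical axis", {
  pose <- aim_camera(matrix(c(0, 0, 0), 1), 2)
  px <- pinhole_project(matrix(c(0, 0, 0), 1), paper_intr(),
                        distortion_model(), pose)
  expect_equal(as.numeric(px), c(705.234, 515.751), tolerance = 1e-9)

  # symmetric cuboid centre at origin
  two <- rbind(c(-0.5, -0.5, -0.5), c(0.5, 0.5, 0.5))
  expect_equal(swarmcam:::bounding_cuboid(two)$center, c(0, 0, 0))

  # translating the scene translates the image, geometry otherwise unchanged
  set.seed(8)
  cloud <- cbind(runif(50, -0.3, 0.3), runif(50, -0.3, 0.3),
                 runif(50, -0.3, 0.3))
  p1 <- pinhole_project(cloud, paper_intr(), distortion_model(),
                        aim_camera(cloud, 2))
  shifted <- sweep(cloud, 2, c(0, 1, 0), "+")
  p2 <- pinhole_project(shifted, paper_intr(), distortion_model(),
                        aim_camera(shifted, 2))
  expect_equal(p1, p2, tolerance = 1e-9)

  expect_error(aim_camera(matrix(numeric(0), 0, 3), 2), "empty|bound")
})

test_that("rotating world and pose together leaves pixels unchanged", {
  set.seed(12)
  cloud <- cbind(runif(100, -0.4, 0.4), runif(100, -0.4, 0.4),
                 runif(100, -0.4, 0.4))
  pose <- aim_camera(cloud, 2)
  q <- random_rotation(55)
  pose_rot <- camera_pose(pose$R %*% t(q), pose$t)
  rotated <- cloud %*% t(q)
  p1 <- pinhole_project(cloud, paper_intr(), paper_dist(), pose)
  p2 <- pinhole_project(rotated, paper_intr(), paper_dist(), pose_rot)
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("focal length scales with distance to preserve image extent", {
  intr <- paper_intr()
  expect_identical(focal_length_for_distance(2, 2, intr)$fx, intr$fx)

  scaled <- focal_length_for_distance(15, 2, intr)
  expect_equal(scaled$fx, 14949.06, tolerance = 1e-4)
  expect_equal(scaled$cx, intr$cx)

  # mid-plane object width maps to the same pixel width at every distance
  obj <- rbind(c(0, -0.5, 0), c(0, 0.5, 0))
  ref_px <- pinhole_project(obj, intr, distortion_model(), aim_camera(obj, 2))
  ref_width <- diff(ref_px[, 1])
  for (d in c(1, 4, 9, 15)) {
    intr_d <- focal_length_for_distance(d, 2, intr)
    px <- pinhole_project(obj, intr_d, distortion_model(), aim_camera(obj, d))
    expect_lt(abs(diff(px[, 1]) / ref_width - 1), 0.001)
  }

  # thin-lens refinement agrees with the angular rule to first order
  tl <- focal_length_for_distance(15, 2, intr, method = "thin_lens",
                                  pixel_pitch = 6.45e-6)
  expect_equal(tl$fx, scaled$fx, tolerance = 0.01)
  expect_error(focal_length_for_distance(15, 2, intr, method = "thin_lens"),
               "pixel_pitch")
  expect_error(focal_length_for_distance(-1, 2, intr), "d_new")
})

test_that("thin-lens geometry satisfies its defining equations", {
  g <- lens_geometry(f = 0.0129, u_obj = 2)
  expect_equal(1 / g$f, 1 / g$u_obj + 1 / g$v_img, tolerance = 1e-12)
  expect_equal(g$M, g$v_img / g$u_obj)
  expect_error(lens_geometry(0.05, 0.04), "exceed")
})

test_that("distortion decomposition behaves at its boundary cases", {
  intr <- paper_intr()
  # zero distortion: all displacement is perspective
  d0 <- distortion_decomposition(c(1, 1, 1), intr, distortion_model(), 2)
  expect_equal(d0$lens_share, 0)
  expect_equal(d0$perspective_share, 1)

  # flat mid-plane cuboid with zero distortion: undefined, flagged
  flat <- distortion_decomposition(c(0, 1, 1), intr, distortion_model(), 2)
  expect_false(flat$defined)
  expect_true(is.na(flat$perspective_share))

  # shares conserve whenever defined
  dd <- distortion_decomposition(c(1, 1, 1), intr, paper_dist(), 2)
  expect_equal(dd$perspective_share + dd$lens_share, 1, tolerance = 1e-12)
  expect_true(dd$perspective_share >= 0 && dd$perspective_share <= 1)

  expect_error(distortion_decomposition(c(0, 0, 0), intr, paper_dist(), 2),
               "Degenerate")
  expect_error(distortion_decomposition(c(1, 1, 1), intr, paper_dist(), 2,
                                        grid_n = 1), "grid_n")
})

test_that("stereo subtense angle matches the closed form", {
  expect_equal(stereo_subtense_angle(0.2, 1.5), 7.6, tolerance = 0.05)
  expect_equal(stereo_subtense_angle(0.2, 2.5), 4.6, tolerance = 0.05)
  expect_equal(stereo_subtense_angle(0, 3), 0)
  expect_error(stereo_subtense_angle(0.2, 0), "distance")
  expect_error(stereo_subtense_angle(-0.1, 1), "baseline")
})

test_that("project_bundle preserves identity/timing and telecentric ignores distance", {
  trk <- simulate_track(swarm_sim_config("male"), 3, seed = 9)
  tele <- project_bundle(trk, "telecentric")
  tele2 <- project_bundle(trk, "telecentric", distance = 99)
  expect_identical(tele, tele2)

  single <- project_bundle(trk, "single_camera", distance = 2)
  expect_identical(single$frame, trk$frame)
  expect_identical(single$t_s, trk$t_s)
  expect_identical(unique(single$unit), "px")
})

test_that("far-field limit: normalized pixel tracks converge to telecentric", {
  trk <- simulate_track(swarm_sim_config("male"), 4, seed = 21)
  tele <- telecentric_project(trk)
  # affine-normalize both views and compare shapes
  norm01 <- function(x) (x - mean(x)) / sd(x)
  discrepancy <- purrr::map_dbl(seq(2, 20, by = 2), function(d) {
    px <- project_bundle(trk, "single_camera", distance = d,
                         dist = distortion_model())
    max(abs(norm01(px$u) - norm01(tele$u)),
        abs(norm01(px$v) - norm01(tele$v)))
  })
  expect_true(all(diff(discrepancy) < 0))
  expect_lt(dplyr::last(discrepancy), 0.05)
})
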