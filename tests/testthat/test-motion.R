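test_that("rotation operators are orthonormal with determinant +1", {
  cases <- list(list(d = 3, inv = "x"), list(d = 3, inv = "y"),
                list(d = 4, inv = c("y", "z")), list(d = 4, inv = c("x", "z")),
                list(d = 4, inv = c("x", "y")))
  for (cs in cases) {
    for (ang in c(-170, -30, 0, 15, 45, 90, 133)) {
      R <- rotation_operator(cs$d, cs$inv, ang)
      expect_equal(t(R) %*% R, diag(cs$d), tolerance = 1e-12)
      expect_equal(det(R), 1, tolerance = 1e-12)
    }
  }
  expect_error(rotation_operator(4, c("x", "q"), 10), "invalid coordinate")
  expect_error(rotation_operator(4, "x", 10), "exactly two")
})

test_that("4D quarter-turn about the x-y invariant plane permutes z into w", {
  R <- rotation_operator(4, c("x", "y"), 90)
  expect_equal(drop(R %*% c(0, 0, 1, 0)), c(0, 0, 0, 1), tolerance = 1e-12)
  # the named plane is pointwise fixed
  expect_equal(drop(R %*% c(1, 0, 0, 0)), c(1, 0, 0, 0), tolerance = 1e-12)
  expect_equal(drop(R %*% c(0, 1, 0, 0)), c(0, 1, 0, 0), tolerance = 1e-12)
})

test_that("rotations in the same plane compose additively", {
  # oracle: direct matrix comparison, 15 deg then 30 deg equals 45 deg
  for (cs in list(list(d = 3, inv = "y"), list(d = 4, inv = c("x", "y")))) {
    lhs <- rotation_operator(cs$d, cs$inv, 30) %*%
      rotation_operator(cs$d, cs$inv, 15)
    expect_equal(lhs, rotation_operator(cs$d, cs$inv, 45), tolerance = 1e-12)
  }
})

test_that("rigid pose at t = 0 with zero phases is the identity", {
  obj <- cube100()
  spec <- motion_spec("rigid", rotation_planes = list(
    list(axis = "x", amplitude = 30, frequency = 0.25),
    list(axis = "y", amplitude = 30, frequency = 0.25)))
  expect_equal(rigid_pose(obj, spec, 0), obj$vertices, tolerance = 1e-12)
})

test_that("rigid pose is an isometry at every sampled time", {
  for (d in c(3L, 4L)) {
    obj <- perturb_vertices(make_hypercube(d, 100), 0.18, seed = 2L)
    spec <- motion_spec("rigid", dimension = d)
    d0 <- as.numeric(dist(obj$vertices))
    for (t in c(0.3, 1.1, 2.7)) {
      dt <- as.numeric(dist(rigid_pose(obj, spec, t)))
      expect_equal(dt, d0, tolerance = 1e-9)
    }
  }
})

test_that("single-plane rigid pose matches the closed-form rotation matrix", {
  # A = 30 deg, f = 0.25 Hz, t = 1 s: sin(pi/2) = 1, so exactly 30 deg about x
  obj <- cube100()
  spec <- motion_spec("rigid", rotation_planes = list(
    list(axis = "x", amplitude = 30, frequency = 0.25)))
  th <- 30 * pi / 180
  R_oracle <- rbind(c(1, 0, 0),
                    c(0, cos(th), -sin(th)),
                    c(0, sin(th), cos(th)))
  expect_equal(rigid_pose(obj, spec, 1), obj$vertices %*% t(R_oracle),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("degenerate non-rigid pose (zero shear and deformation) is rigid", {
  obj <- cube100()
  spec <- motion_spec("nonrigid", dimension = 3, shear_axis = "x",
                      shear_amplitude = 0, deform_amplitude = 0)
  spec_r <- motion_spec("rigid", dimension = 3)
  for (t in c(0.4, 1.5)) {
    expect_equal(nonrigid_pose(obj, spec, t, seed = 1L),
                 rigid_pose(obj, spec_r, t), tolerance = 1e-12)
  }
})

test_that("shear at peak phase distorts pairwise distances by > 1% of side", {
  obj <- cube100()
  spec <- motion_spec("nonrigid", dimension = 3, shear_axis = "x",
                      shear_amplitude = 0.2, deform_amplitude = 0,
                      shear_frequency = 0.25)
  snap <- nonrigid_pose(obj, spec, t = 1, seed = 1L) # sin(pi/2) = 1: peak
  dev <- abs(as.numeric(dist(snap)) - as.numeric(dist(obj$vertices)))
  expect_gt(max(dev), 0.01 * obj$side_length)
})

test_that("non-rigid poses are seed-deterministic in their deformation", {
  obj <- cube100()
  spec <- motion_spec("nonrigid", dimension = 3, shear_axis = "y")
  expect_identical(nonrigid_pose(obj, spec, 0.7, seed = 5L),
                   nonrigid_pose(obj, spec, 0.7, seed = 5L))
  expect_false(isTRUE(all.equal(nonrigid_pose(obj, spec, 0.7, seed = 5L),
                                nonrigid_pose(obj, spec, 0.7, seed = 6L))))
})

test_that("trajectories have round(duration x frame_rate) frames", {
  obj <- cube100()
  spec <- motion_spec("rigid", dimension = 3) # 3 s at 90 Hz
  traj <- generate_trajectory(obj, spec, seed = 1L)
  expect_identical(dim(traj$frames)[1], 270L)
  expect_equal(diff(traj$frame_times), rep(1 / 90, 269), tolerance = 1e-12)
})

test_that("jitter-free rigid trajectories are exact isometries every frame", {
  obj <- perturb_vertices(tess100(), 0.12, seed = 4L)
  traj <- generate_trajectory(obj, quick_spec("rigid", 4), seed = 1L)
  d0 <- as.numeric(dist(traj$frames[1, , ]))
  for (k in seq_len(dim(traj$frames)[1])) {
    expect_equal(as.numeric(dist(traj$frames[k, , ])), d0, tolerance = 1e-9)
  }
})

test_that("trajectories are bit-reproducible under a fixed seed", {
  obj <- cube100()
  spec <- motion_spec("nonrigid", dimension = 3, shear_axis = "z",
                      duration = 0.5, frame_rate = 20)
  a <- generate_trajectory(obj, spec, seed = 8L)
  b <- generate_trajectory(obj, spec, seed = 8L)
  expect_identical(a$frames, b$frames)
})

test_that("triangle-wave schedule also sweeps the fixed angular range", {
  obj <- cube100()
  spec <- motion_spec("rigid", rotation_planes = list(
    list(axis = "x", amplitude = 30, frequency = 0.25)),
    angle_schedule = "triangle")
  # at t = 1 s the triangle wave is at its +1 peak, like the sine
  th <- 30 * pi / 180
  R_oracle <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  expect_equal(rigid_pose(obj, spec, 1), obj$vertices %*% t(R_oracle),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("non-rigid motion requires a shear axis", {
  expect_error(motion_spec("nonrigid", dimension = 3), "shear_axis")
})
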