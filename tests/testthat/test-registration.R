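test_that("rigid transforms compose, invert and preserve distances", {
  set.seed(2)
  tf <- random_rigid(5, 30)
  m <- icosphere(2, c(6, 5, 4))
  # T then T^-1 restores the vertices
  back <- apply_transform(apply_transform(m, tf), invert_transform(tf))
  expect_lt(max(abs(back$vertices - m$vertices)), 1e-9)
  # isometry: pairwise distances are preserved
  i <- sample(nrow(m$vertices), 40)
  d0 <- as.matrix(dist(m$vertices[i, ]))
  d1 <- as.matrix(dist(apply_transform(m, tf)$vertices[i, ]))
  expect_lt(max(abs(d0 - d1)), 1e-9)
  # identity leaves the mesh untouched
  expect_identical(apply_transform(m, rigid_transform())$vertices,
                   m$vertices)
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
})

test_that("movement components decompose and recompose the transform", {
  ctr <- c(3, -2, 5)
  # identity -> all six components zero
  c0 <- decompose_transform(rigid_transform(), ctr)
  expect_equal(unlist(c0[1, ]), c(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0,
                                  rz = 0))
  # pure translation
  c1 <- decompose_transform(rigid_transform(diag(3), c(1, 0, 0)), ctr)
  expect_equal(unlist(c1[1, ]), c(tx = 1, ty = 0, tz = 0, rx = 0, ry = 0,
                                  rz = 0))
  # pure 5 degree rotation about z through the centre (constructed
  # explicitly from the angle)
  Rz <- threshsurf:::rotation_about("z", 5)
  tfz <- rigid_transform(Rz, ctr - as.numeric(Rz %*% ctr))
  cz <- decompose_transform(tfz, ctr)
  expect_equal(unlist(cz[1, ]), c(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0,
                                  rz = 5), tolerance = 1e-9)

  # random transforms: recomposition reproduces the action on points
  set.seed(14)
  pts <- icosphere(2, 8)$vertices
  for (rep in 1:5) {
    tf <- random_rigid(8, 60)
    comp <- decompose_transform(tf, ctr)
    tf2 <- recompose_components(comp, ctr)
    expect_lt(max(sqrt(rowSums((transform_points(tf, pts) -
                                  transform_points(tf2, pts))^2))), 1e-6)
  }
})

test_that("gimbal lock is flagged and resolved with rz = 0", {
  R <- threshsurf:::rotation_about("x", 20) %*%
    threshsurf:::rotation_about("y", 90)
  expect_warning(comp <- decompose_transform(rigid_transform(R), c(0, 0, 0)),
                 "gimbal")
  expect_equal(comp$ry, 90, tolerance = 1e-9)
  expect_equal(comp$rz, 0)
  expect_equal(comp$rx, 20, tolerance = 1e-9)
})

test_that("ICP on an already-aligned mesh returns the identity", {
  m <- icosphere(3, c(12, 10, 8))
  tf <- icp_register(m, m, icp_settings(iterations = 10))
  expect_lt(rotation_angle_deg(tf$rotation), 1e-6)
  expect_lt(sqrt(sum(tf$translation^2)), 1e-6)
})

test_that("ICP recovers known rigid perturbations on a clean shell", {
  sp <- phantom_preset("ct", seed = 1)
  sp$noise_sd <- 0; sp$bias_amplitude <- 0
  ph <- generate_phantom(sp)
  mesh <- extract_isosurface(ph$volume, 500)

  # translation-only example: recovered transform is the inverse
  tft <- rigid_transform(diag(3), c(1, 2, 3))
  rec <- icp_register(apply_transform(mesh, tft), mesh)
  expect_lt(max(abs(rec$translation - c(-1, -2, -3))), 0.05)
  expect_lt(rotation_angle_deg(rec$rotation), 0.1)

  # 5 degree rotation about z through the centroid -> recovered rz = -5
  ctr <- colMeans(mesh$vertices)
  Rz <- threshsurf:::rotation_about("z", 5)
  tfz <- rigid_transform(Rz, ctr - as.numeric(Rz %*% ctr))
  recz <- icp_register(apply_transform(mesh, tfz), mesh)
  compz <- decompose_transform(recz, ctr)
  expect_lt(abs(compz$rz + 5), 0.1)

  # random perturbations up to 5 mm / 10 degrees: composed transform is
  # the identity within 0.1 degree / 0.05 mm
  set.seed(31)
  for (rep in 1:3) {
    tf <- random_rigid(5, 10)
    rec <- icp_register(apply_transform(mesh, tf), mesh)
    comp <- compose_transforms(rec, tf)
    expect_lt(rotation_angle_deg(comp$rotation), 0.1)
    expect_lt(transform_deviation(comp, mesh$vertices), 0.05)
  }
})

test_that("point-to-point matching also recovers a known motion", {
  m <- icosphere(3, c(9, 7, 5))
  tf <- rigid_transform(diag(3), c(0.8, -0.6, 0.4))
  rec <- icp_register(apply_transform(m, tf), m,
                      icp_settings(matching = "point_to_point",
                                   iterations = 30))
  comp <- compose_transforms(rec, tf)
  expect_lt(transform_deviation(comp, m$vertices), 0.05)
})

test_that("a purely planar reference triggers the degeneracy warning", {
  p <- plane_mesh(0, nx = 5, ny = 5)
  expect_warning(icp_register(p, p, icp_settings(iterations = 2)),
                 "unidentifiable")
})

test_that("the point-to-plane objective does not increase on clean data", {
  m <- icosphere(3, c(12, 10, 8))
  tf <- random_rigid(3, 5)
  rec <- icp_register(apply_transform(m, tf), m)
  trace <- attr(rec, "objective_trace")
  expect_true(all(diff(trace) <= 1e-9))
})
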