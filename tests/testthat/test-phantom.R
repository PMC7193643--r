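test_that("degenerate blur yields exactly the two material intensities", {
  ph <- generate_phantom(phantom_spec("solid_sphere", radius = 3,
                                      spacing = 0.5, edge_sigma = 0,
                                      noise_sd = 0))
  expect_setequal(unique(as.vector(ph$volume$data)), c(300, 700))
  expect_identical(ph$volume$data == 700, ph$truth$mask)
})

test_that("phantom generation is seed-deterministic", {
  sp <- phantom_spec("solid_sphere", radius = 4, spacing = 0.5,
                     edge_sigma = 0.5, noise_sd = 20, bias_amplitude = 0.05,
                     seed = 42)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$volume$data, b$volume$data)
  sp2 <- sp; sp2$seed <- 43L
  expect_false(identical(generate_phantom(sp2)$volume$data, a$volume$data))
})

test_that("truth mask is the set of voxel centres inside the geometry", {
  sp <- phantom_spec("solid_sphere", radius = 3, spacing = 0.5,
                     edge_sigma = 0.4)
  ph <- generate_phantom(sp)
  d <- dim(ph$truth$mask)
  ctr <- ph$truth$centre
  idx <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                               k = 0:(d[3] - 1)))
  pos <- sweep(idx, 2, c(0.5, 0.5, 0.5), "*")
  inside <- rowSums(sweep(pos, 2, ctr)^2) <= 3^2
  expect_identical(as.vector(ph$truth$mask), inside)
})

test_that("blurred boundary crosses the half-intensity at the true radius", {
  # oracle: dense 1-D profile of a Gaussian-blurred step at r = 10,
  # crossing located by brute-force bracketing
  h <- 0.001
  x <- seq(0, 15, by = h)
  step <- ifelse(x <= 10, 700, 300)
  kr <- ceiling(4 * 0.6 / h)
  ker <- dnorm(seq(-kr, kr) * h, sd = 0.6)
  ker <- ker / sum(ker)
  prof <- stats::filter(c(rep(700, kr), step, rep(300, kr)), ker,
                        sides = 2)[kr + seq_along(x)]
  i <- which(diff(sign(prof - 500)) != 0)[1]
  cross_1d <- x[i] + h * (500 - prof[i]) / (prof[i + 1] - prof[i])
  expect_lt(abs(cross_1d - 10), 0.01)

  # the phantom's own profile along a +x ray through the centre
  ph <- generate_phantom(phantom_spec("solid_sphere", radius = 10,
                                      spacing = 0.4, edge_sigma = 0.6))
  ctr_idx <- round(ph$truth$centre / 0.4) + 1
  ray <- ph$volume$data[ctr_idx[1]:dim(ph$volume$data)[1], ctr_idx[2],
                        ctr_idx[3]]
  r <- (seq_along(ray) - 1) * 0.4
  j <- which(diff(sign(ray - 500)) != 0)[1]
  cross <- r[j] + 0.4 * (500 - ray[j]) / (ray[j + 1] - ray[j])
  expect_lt(abs(cross - 10), 0.4)
})

test_that("presets match the studied acquisition settings", {
  expect_equal(phantom_preset("ct")$spacing, rep(0.5, 3))
  expect_true(all(phantom_preset("cbct_regular")$spacing %in% c(0.3, 0.4)))
  expect_gt(phantom_preset("cbct_low")$noise_sd, phantom_preset("ct")$noise_sd)
  expect_gt(phantom_preset("cbct_low")$noise_sd,
            phantom_preset("cbct_regular")$noise_sd)
  expect_gt(phantom_preset("cbct_low")$bias_amplitude,
            phantom_preset("cbct_regular")$bias_amplitude)
  expect_error(phantom_preset("mri"))
})

test_that("bias field is positive and bounded by its amplitude", {
  sp <- phantom_spec("solid_sphere", radius = 4, spacing = 0.5,
                     bias_amplitude = 0.1, seed = 9)
  grid <- threshsurf:::phantom_grid(sp)
  set.seed(9)
  field <- threshsurf:::phantom_bias_field(sp, grid)
  expect_true(all(field >= 0.9 - 1e-12 & field <= 1.1 + 1e-12))
  expect_true(all(field > 0))
  expect_gt(diff(range(field)), 0)
})

test_that("noise-free isosurface at the boundary intensity matches the geometry", {
  ph <- generate_phantom(phantom_spec("solid_sphere", radius = 8,
                                      spacing = 0.5, edge_sigma = 0.75))
  m <- extract_isosurface(ph$volume, ph$truth$boundary_intensity)
  r <- sqrt(rowSums(sweep(m$vertices, 2, ph$truth$centre)^2))
  expect_lt(mean(abs(r - 8)), 0.5 / 2)
})

test_that("a geometry larger than a requested grid is rejected", {
  expect_error(generate_phantom(
    phantom_spec("solid_sphere", radius = 10, spacing = 0.5,
                 grid_shape = c(20, 20, 20))), "exceeds the grid")
})
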