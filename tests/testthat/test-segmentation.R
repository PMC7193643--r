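# brute-force oracle: interface voxels by exhaustive neighbour enumeration
brute_interface <- function(mask, connectivity) {
  d <- dim(mask)
  offs <- threshsurf:::neighbour_offsets(connectivity)
  out <- array(FALSE, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    for (r in seq_len(nrow(offs))) {
      p <- c(i, j, k) + offs[r, ]
      if (any(p < 1) || any(p > d)) next
      if (mask[p[1], p[2], p[3]] != mask[i, j, k]) {
        out[i, j, k] <- TRUE
        break
      }
    }
  }
  out
}

test_that("interface voxels match exhaustive neighbour enumeration", {
  # centre voxel vs the rest of a 3x3x3 grid: centre + its 6 face
  # neighbours under 6-connectivity
  vol <- voxel_volume(array(seq_len(27), c(3, 3, 3)), 1)
  mask <- array(FALSE, c(3, 3, 3)); mask[2, 2, 2] <- TRUE
  got6 <- interface_voxels(vol, mask, connectivity = 6)
  oracle6 <- vol$data[brute_interface(mask, 6)]
  expect_setequal(got6, oracle6)
  expect_length(got6, 7)

  # 5^3 block inside a 9^3 grid: block interior (3^3) is excluded
  vol9 <- voxel_volume(array(seq_len(729), c(9, 9, 9)), 1)
  mask9 <- array(FALSE, c(9, 9, 9)); mask9[3:7, 3:7, 3:7] <- TRUE
  got <- interface_voxels(vol9, mask9, connectivity = 6)
  oracle <- brute_interface(mask9, 6)
  expect_setequal(got, vol9$data[oracle])
  interior <- array(FALSE, c(9, 9, 9)); interior[4:6, 4:6, 4:6] <- TRUE
  expect_false(any(oracle & interior))

  # randomised masks, both connectivities, vs the brute-force oracle
  set.seed(3)
  for (conn in c(6, 26)) {
    m <- array(runif(6^3) < 0.4, c(6, 6, 6))
    if (!any(m) || all(m)) next
    v <- voxel_volume(array(rnorm(6^3), c(6, 6, 6)), 1)
    expect_setequal(interface_voxels(v, m, conn), v$data[brute_interface(m, conn)])
  }
})

test_that("interface set is label-symmetric and grows with connectivity", {
  set.seed(21)
  v <- voxel_volume(array(seq_len(5^3), c(5, 5, 5)), 1)
  m <- array(runif(5^3) < 0.5, c(5, 5, 5))
  expect_setequal(interface_voxels(v, m, 6), interface_voxels(v, !m, 6))
  expect_true(all(interface_voxels(v, m, 6) %in%
                    interface_voxels(v, m, 26)))
})

test_that("reference threshold is the interface mean and stays in range", {
  # two-intensity case: halves at 200 and 600, every voxel on the interface
  v <- voxel_volume(array(rep(c(200, 600), each = 4), c(2, 2, 2)), 1)
  m <- array(rep(c(TRUE, FALSE), each = 4), c(2, 2, 2))
  expect_equal(reference_threshold(v, m), 400)

  # constant interface intensities give that constant
  vc <- voxel_volume(array(123.4, c(4, 4, 4)), 1)
  mc <- array(FALSE, c(4, 4, 4)); mc[1:2, , ] <- TRUE
  expect_equal(reference_threshold(vc, mc), 123.4)

  set.seed(5)
  vr <- voxel_volume(array(runif(4^3, 0, 1000), c(4, 4, 4)), 1)
  iv <- interface_voxels(vr, mc[seq_len(4), seq_len(4), seq_len(4)])
  expect_gte(reference_threshold(vr, mc), min(iv))
  expect_lte(reference_threshold(vr, mc), max(iv))
})

test_that("interface extraction validates its inputs", {
  v <- voxel_volume(array(0, c(3, 3, 3)), 1)
  expect_error(interface_voxels(v, array(TRUE, c(3, 3, 3))), "non-empty")
  expect_error(interface_voxels(v, array(FALSE, c(2, 2, 2))), "same shape")
  m <- array(FALSE, c(3, 3, 3)); m[1, 1, 1] <- TRUE
  expect_error(interface_voxels(v, m, connectivity = 18), "6 or 26")
})

test_that("interface mean approaches the mid-intensity as the grid refines", {
  err <- vapply(c(0.5, 0.25), function(sp) {
    ph <- generate_phantom(phantom_spec("solid_sphere", radius = 6,
                                        spacing = sp, edge_sigma = 0.6))
    abs(reference_threshold(ph$volume, ph$truth$mask) - 500)
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("threshold families follow the documented layout", {
  ts <- threshold_set(300)
  expect_equal(ts$offsets, c(-60, -40, -20, 0, 20, 40, 60))
  expect_equal(ts$values, c(240, 260, 280, 300, 320, 340, 360))
  expect_equal(as_tibble(ts)$value, ts$values)

  expect_equal(threshold_set(300, step = 0)$values, rep(300, 7))
  expect_error(threshold_set(50), "-60")
  expect_error(threshold_set(970), "60")
})
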