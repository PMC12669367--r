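test_that("distance maps give analytic distances around a single voxel", {
  arr <- array(FALSE, c(7, 7, 7))
  arr[4, 4, 4] <- TRUE
  mask <- make_mask(arr, affine = diag(c(2, 2, 2, 1)))
  dm <- compute_distance_map(mask)
  expect_equal(dm$data[4, 4, 4], 0)
  expect_equal(dm$data[5, 4, 4], 2)                    # face neighbor
  expect_equal(dm$data[5, 5, 4], 2.828427, tolerance = 1e-6)  # in-plane diag
  expect_equal(dm$data[5, 5, 5], 3.464102, tolerance = 1e-6)  # 3D diagonal
})

test_that("a full mask yields an all-zero distance map", {
  mask <- make_mask(array(TRUE, c(4, 5, 6)))
  dm <- compute_distance_map(mask)
  expect_true(all(dm$data == 0))
})

test_that("empty masks are rejected with the source identified", {
  m <- make_mask(array(FALSE, c(3, 3, 3)), source_id = "left nd-DRTT")
  expect_error(compute_distance_map(m), "left nd-DRTT")
  expect_error(oracle_point_to_mask(m, c(0, 0, 0)), "empty")
})

test_that("distance transform equals the brute-force oracle on anisotropic grids", {
  set.seed(31)
  aff <- diag(c(1.5, 1.5, 3.0, 1))
  arr <- array(FALSE, c(15, 15, 15))
  arr[sample(length(arr), 25)] <- TRUE
  mask <- make_mask(arr, affine = aff)
  dm <- compute_distance_map(mask)
  expect_lt(max(abs(dm$data - brute_force_distance_map(mask))), 1e-6)
})

test_that("distance-map values survive zero-padding and provenance relabeling", {
  set.seed(32)
  arr <- array(FALSE, c(8, 8, 8))
  arr[sample(length(arr), 6)] <- TRUE
  mask <- make_mask(arr, affine = diag(c(2, 2, 2, 1)))
  dm <- compute_distance_map(mask)
  padded <- array(FALSE, c(8, 8, 12))   # zero slabs appended on top
  padded[, , 1:8] <- arr
  dmp <- compute_distance_map(make_mask(padded, affine = diag(c(2, 2, 2, 1))))
  expect_equal(dmp$data[, , 1:8], dm$data)
  relabeled <- mask
  relabeled$provenance$source_id <- "other"
  expect_identical(compute_distance_map(relabeled)$data, dm$data)
})

test_that("nearest-neighbor sampling is within half a voxel diagonal of truth", {
  arr <- array(FALSE, c(9, 9, 9))
  arr[5, 5, 5] <- TRUE
  mask <- make_mask(arr, affine = diag(c(2, 2, 2, 1)))
  dm <- compute_distance_map(mask)
  center <- voxel_to_world(mask, c(4, 4, 4))
  expect_equal(distance_at_point(dm, center), 0)
  # 3 mm along +x: nearest voxel is one step over, sampled value 2.0 while
  # the exact point distance is 3.0 — bounded by half the voxel diagonal
  p <- center + c(3, 0, 0)
  expect_equal(distance_at_point(dm, p), 2)
  expect_lte(abs(distance_at_point(dm, p) - oracle_point_to_mask(mask, p)),
             sqrt(sum((c(2, 2, 2) / 2)^2)) + 1e-12)

  set.seed(33)
  arr2 <- array(FALSE, c(10, 12, 9))
  arr2[sample(length(arr2), 12)] <- TRUE
  aff <- diag(c(1.5, 2, 2.5, 1))
  m2 <- make_mask(arr2, affine = aff)
  d2 <- compute_distance_map(m2)
  half_diag <- sqrt(sum((c(1.5, 2, 2.5) / 2)^2))
  lims <- voxel_to_world(m2, dim(arr2) - 1L)
  for (i in 1:50) {
    pt <- runif(3, 0, lims)
    expect_lte(abs(distance_at_point(d2, pt) - oracle_point_to_mask(m2, pt)),
               half_diag + 1e-12)
  }

  expect_error(distance_at_point(dm, c(1e4, 0, 0), id = "contact 3"),
               "contact 3")
})

test_that("map lookup at voxel centers agrees exactly with the oracle", {
  set.seed(34)
  arr <- array(FALSE, c(10, 10, 10))
  arr[sample(length(arr), 8)] <- TRUE
  mask <- make_mask(arr, affine = diag(c(2, 2, 2, 1)))
  dm <- compute_distance_map(mask)
  idx <- which(array(TRUE, dim(arr)), arr.ind = TRUE) - 1L
  for (r in seq_len(nrow(idx))) {
    ctr <- voxel_to_world(mask, idx[r, ])
    expect_equal(distance_at_point(dm, ctr),
                 oracle_point_to_mask(mask, ctr), tolerance = 1e-9)
  }
})

test_that("trilinear sampling interpolates between voxel values", {
  arr <- array(FALSE, c(9, 9, 9))
  arr[5, 5, 5] <- TRUE
  mask <- make_mask(arr, affine = diag(c(2, 2, 2, 1)))
  dm <- compute_distance_map(mask)
  center <- voxel_to_world(mask, c(4, 4, 4))
  p <- center + c(1, 0, 0)  # halfway between a 0 voxel and a 2 mm voxel
  expect_equal(distance_at_point(dm, p, method = "trilinear"), 1)
})

test_that("manual axial measurement reads the in-plane distance or drops out", {
  arr <- array(FALSE, c(20, 20, 20))
  arr[11, 13, 11] <- TRUE  # 0-based (10, 12, 10)
  mask <- make_mask(arr, affine = diag(c(2, 2, 2, 1)))
  contact <- voxel_to_world(mask, c(10, 10, 10))
  expect_equal(manual_axial_distance(mask, contact), 4)  # 2 voxels in-plane

  # tract present only on other slices -> not measurable
  arr2 <- array(FALSE, c(20, 20, 20))
  arr2[11, 11, 15] <- TRUE
  m2 <- make_mask(arr2, affine = diag(c(2, 2, 2, 1)))
  expect_true(is.na(manual_axial_distance(m2, contact)))

  # jitter is seeded, bounded, and floored at zero
  d1 <- manual_axial_distance(mask, contact, jitter_mm = 0.5, seed = 5)
  d2 <- manual_axial_distance(mask, contact, jitter_mm = 0.5, seed = 5)
  expect_identical(d1, d2)
  expect_lte(abs(d1 - 4), 0.5)
})

test_that("axial restriction inflates distances in the 3-voxel worked example", {
  arr <- array(FALSE, c(20, 20, 20))
  arr[11, 11, 11] <- TRUE  # 0-based (10, 10, 10)
  arr[11, 15, 12] <- TRUE  # 0-based (10, 14, 11)
  mask <- make_mask(arr, affine = diag(c(2, 2, 2, 1)))
  contact <- voxel_to_world(mask, c(10, 10, 11))
  dm <- compute_distance_map(mask)
  auto <- distance_at_point(dm, contact)
  manual <- manual_axial_distance(mask, contact)
  expect_equal(auto, 2)     # true nearest voxel sits one slice below
  expect_equal(manual, 8)   # in-slice nearest voxel is 4 steps away
  expect_equal(manual - auto, 6)
})

test_that("measure_contact applies the one-step step-down rule per tract", {
  # engineered probability volume: robust range (0, 10) by construction, a
  # "far" 100-count blob and a "near" 70-count blob, so the near blob is in
  # the 400/600% masks only
  dims <- c(40, 12, 12)
  aff <- diag(c(2, 2, 2, 1))
  build_vol <- function() {
    a <- array(0, dims)
    a[1:30, 1:4, 1] <- 10          # plateau pinning the 98th percentile
    a
  }
  a <- build_vol()
  a[36, 6, 6] <- 100               # far blob: in every mask
  a[8, 6, 6] <- 70                 # near blob: only below the 800% threshold
  vol <- volume3d(a, affine = aff)
  rr <- robust_range(vol)
  expect_equal(rr$rmax, 10)
  contact <- data.frame(patient_id = "P1", hemisphere = "left",
                        contact_index = 0L,
                        x_mm = 2 * 1, y_mm = 2 * 5, z_mm = 2 * 5)
  cand <- c(400, 600, 800, 1000)
  # at 800%: only the far blob (0-based x=35), 34 voxels * 2 mm = 68 mm away
  rec <- measure_contact(list(tract = vol), contact, p_selected = 800,
                         candidates = cand)
  expect_true(rec$stepped_down)
  expect_equal(rec$p_initial, 800)
  expect_equal(rec$p_final, 600)
  expect_equal(rec$d_auto_mm, 2 * (8 - 1 - 1))  # near blob after step-down

  # no step-down when the distance is within the cutoff
  near_contact <- data.frame(patient_id = "P1", hemisphere = "left",
                             contact_index = 1L,
                             x_mm = 2 * 34, y_mm = 2 * 5, z_mm = 2 * 5)
  rec2 <- measure_contact(list(tract = vol), near_contact, p_selected = 800,
                          candidates = cand)
  expect_false(rec2$stepped_down)
  expect_equal(rec2$p_final, 800)
  expect_equal(rec2$d_auto_mm, 2)  # one voxel step from the far blob

  # at the lowest threshold no step is possible
  rec3 <- measure_contact(list(tract = vol), contact, p_selected = 400,
                          candidates = cand)
  expect_false(rec3$stepped_down)
  expect_equal(rec3$p_final, 400)
})

test_that("exactly one step down is taken even if the distance stays large", {
  dims <- c(40, 8, 8)
  a <- array(0, dims)
  a[1:30, 1:4, 1] <- 10
  a[40, 4, 4] <- 100  # only blob; far from the contact at every threshold
  vol <- volume3d(a, affine = diag(c(2, 2, 2, 1)))
  contact <- data.frame(patient_id = "P1", hemisphere = "left",
                        contact_index = 0L, x_mm = 0, y_mm = 2 * 3,
                        z_mm = 2 * 3)
  rec <- measure_contact(list(tract = vol), contact, p_selected = 1000,
                         candidates = c(400, 600, 800, 1000))
  expect_true(rec$stepped_down)
  expect_equal(rec$p_final, 800)   # exactly one step, not a cascade
  expect_gt(rec$d_auto_mm, 10)
})
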