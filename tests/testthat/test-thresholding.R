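vol_of <- function(values, dims = NULL) {
  if (is.null(dims)) dims <- c(length(values), 1, 1)
  volume3d(array(values, dims))
}

test_that("robust range follows the interpolated 2/98 percentile rule", {
  rr <- robust_range(vol_of(rep(5, 64), c(4, 4, 4)))
  expect_equal(rr$rmin, 5)
  expect_equal(rr$rmax, 5)

  rr <- robust_range(vol_of(0:99))
  expect_equal(rr$rmin, 1.98)
  expect_equal(rr$rmax, 97.02)

  # a single extreme voxel among 10^6 zeros is ignored by both percentiles
  v <- rep(0, 1e6)
  v[123456] <- 5000
  rr <- robust_range(vol_of(v, c(100, 100, 100)))
  expect_equal(rr$rmin, 0)
  expect_equal(rr$rmax, 0)

  expect_error(robust_range(vol_of(rep(NaN, 8), c(2, 2, 2))), "NaN")
})

test_that("robust range matches a sort-based oracle and is permutation-invariant", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(50:400, 1)
    x <- round(rexp(n, rate = 1 / 50))
    rr <- robust_range(vol_of(x, c(n, 1, 1)))
    expect_equal(rr$rmin, oracle_percentile(x, 0.02))
    expect_equal(rr$rmax, oracle_percentile(x, 0.98))
    perm <- sample(x)
    rr2 <- robust_range(vol_of(perm, c(n, 1, 1)))
    expect_equal(rr2$rmin, rr$rmin)
    expect_equal(rr2$rmax, rr$rmax)
  }
})

test_that("nonzero-only robust range excludes the zero background", {
  v <- vol_of(c(rep(0, 90), rep(10, 10)), c(100, 1, 1))
  rr_all <- robust_range(v)
  rr_nz <- robust_range(v, nonzero_only = TRUE)
  expect_equal(rr_all$rmax, 10)
  expect_equal(rr_all$rmin, 0)
  expect_equal(rr_nz$rmin, 10)
  expect_equal(rr_nz$rmax, 10)
})

test_that("binarization applies the affine robust-range threshold with >=", {
  v <- vol_of(c(5, 39, 40, 100))
  m <- binarize_thrp(v, 400, range = list(rmin = 0, rmax = 10))
  expect_equal(m$provenance$threshold, 40)
  expect_equal(as.vector(m$data), c(FALSE, FALSE, TRUE, TRUE))

  # degenerate constant volume: threshold collapses to the constant, full mask
  cv <- vol_of(rep(7, 27), c(3, 3, 3))
  mc <- binarize_thrp(cv, 1000)
  expect_equal(mc$provenance$threshold, 7)
  expect_true(all(mc$data))
  expect_false(mc$provenance$empty)

  expect_error(binarize_thrp(v, 0), "positive")
  expect_error(binarize_thrp(v, -400), "positive")

  # empty masks are legal and flagged
  me <- binarize_thrp(v, 400, range = list(rmin = 0, rmax = 1000))
  expect_true(me$provenance$empty)
})

test_that("masks are nested as the threshold percentage grows", {
  cohort <- small_cohort()
  vol <- cohort$patients[[1]]$volumes$right[["c-DRTT"]]
  rr <- robust_range(vol)
  prev <- NULL
  for (p in c(400, 600, 800, 1000)) {
    m <- binarize_thrp(vol, p, range = rr)
    if (!is.null(prev)) {
      expect_true(all(prev$data | !m$data))  # mask(p) subset of mask(p_prev)
    }
    prev <- m
  }
})

test_that("binarization is deterministic given (values, p)", {
  cohort <- small_cohort()
  vol <- cohort$patients[[2]]$volumes$left[["nd-DRTT"]]
  m1 <- binarize_thrp(vol, 600)
  m2 <- binarize_thrp(vol, 600)
  expect_identical(m1$data, m2$data)
  expect_identical(m1$provenance$threshold, m2$provenance$threshold)
})

test_that("threshold selection minimizes mean c/nd Dice over feasible candidates", {
  # heavy-tailed construction: a zero background, a 10-count noise plateau
  # that pins the robust range, and two-level tract cubes whose halos
  # overlap while their cores do not
  blank <- function() array(0, c(30, 30, 8))
  arr_c <- blank()
  arr_n <- blank()
  arr_c[9:13, 9:13, 4:5] <- 50        # faint halo (5x5x2): only in 400% mask
  arr_c[10:12, 10:12, 4:5] <- 100     # strong core (3x3x2): in both masks
  arr_n[12:16, 9:13, 4:5] <- 50
  arr_n[13:15, 10:12, 4:5] <- 100
  noise <- function(a) { a[20:29, 20:29, 1:3] <- 10; a }  # 300 voxels of 10
  arr_c <- noise(arr_c)
  arr_n <- noise(arr_n)
  vc <- volume3d(arr_c)
  vn <- volume3d(arr_n)
  rr <- robust_range(vc)
  expect_equal(rr$rmax, 10)  # pinned by the noise plateau, not the tract
  cand <- c(400, 800)
  sel <- select_discrimination_threshold(
    c_left = vc, c_right = vc, nd_left = vn, nd_right = vn,
    candidates = cand)
  # independent voxel-counting Dice oracle at each candidate threshold
  dice_oracle <- vapply(cand, function(p) {
    thr <- rr$rmin + p / 100 * (rr$rmax - rr$rmin)
    a <- arr_c >= thr
    b <- arr_n >= thr
    2 * sum(a & b) / (sum(a) + sum(b))
  }, numeric(1))
  expect_equal(sel$table$mean_dice, dice_oracle)
  expect_gt(dice_oracle[1], 0)   # halos overlap at the permissive threshold
  expect_equal(dice_oracle[2], 0)  # cores are disjoint at the strict one
  expect_equal(sel$p, cand[which.min(dice_oracle)])
  expect_true(sel$feasible)

  expect_error(select_discrimination_threshold(vc, vc, vn, vn, numeric(0)),
               "non-empty")
})

test_that("selection tie-breaks to the lowest candidate and flags infeasibility", {
  # disjoint tracts: Dice 0 at every candidate -> lowest p wins; a 1-count
  # noise plateau keeps the robust range far below the tract counts
  arr_c <- array(0, c(20, 20, 5))
  arr_n <- array(0, c(20, 20, 5))
  arr_c[2:4, 2:4, 2:3] <- 1000
  arr_n[15:17, 15:17, 2:3] <- 1000
  arr_c[8:13, 8:17, 5] <- 1
  arr_n[8:13, 8:17, 5] <- 1
  vc <- volume3d(arr_c)
  vn <- volume3d(arr_n)
  sel <- select_discrimination_threshold(vc, vc, vn, vn,
                                         candidates = c(400, 600, 800))
  expect_true(all(sel$table$mean_dice == 0))
  expect_equal(sel$p, 400)
  expect_true(sel$feasible)

  # robust range (0, 1) with nothing at or above 4x rmax: every mask empty
  # at every candidate -> lowest candidate, flagged infeasible
  sparse <- volume3d(array(c(rep(0, 96), rep(1, 4)), c(100, 1, 1)))
  sel2 <- select_discrimination_threshold(sparse, sparse, sparse, sparse,
                                          candidates = c(400, 600))
  expect_false(any(sel2$table$all_nonempty))
  expect_false(sel2$feasible)
  expect_equal(sel2$p, 400)
  # volumes whose masks are only non-empty at the lowest candidate
  arr <- array(0, c(100, 1, 1))
  arr[1:50] <- 1   # rmax = 1 -> thresholds 4/6 x rmax
  arr[1] <- 5      # only >= 4, not >= 6
  v <- volume3d(array(arr, c(100, 1, 1)))
  sel3 <- select_discrimination_threshold(v, v, v, v,
                                          candidates = c(400, 600))
  expect_equal(sel3$p, 400)
  expect_true(sel3$feasible)
  expect_equal(sum(sel3$table$all_nonempty), 1L)
})

test_that("step_down moves exactly one candidate lower", {
  cand <- c(400, 600, 800, 1000)
  expect_equal(step_down(800, cand), 600)
  expect_equal(step_down(1000, cand), 800)
  expect_null(step_down(400, cand))
  expect_error(step_down(700, cand), "not among")
})
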