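# Shared fixtures, built in code and memoised for the test session.

.fixture_cache <- new.env(parent = emptyenv())

memoise_fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# Small 2-patient cohort on a 48^3 grid for unit tests.
small_cohort <- function() {
  memoise_fixture("small_cohort", function() {
    cfg <- list(n_patients = 2L, grid_dim = c(48L, 48L, 48L))
    generate_cohort(cfg, seed = 42L)
  })
}

# Default-condition 10-patient cohort (the study-scale phantom) plus its
# measurement sweep, shared across the acceptance properties.
default_cohort_measured <- function() {
  memoise_fixture("default_cohort_measured", function() {
    cohort <- generate_cohort(default_config(), seed = 20260930L %% 100000L)
    list(cohort = cohort, measured = measure_cohort(cohort))
  })
}

# Binary mask from a logical array: thresholds the 0/1 image at 1.
make_mask <- function(arr, affine = diag(4), source_id = "fixture") {
  vol <- volume3d(array(as.numeric(arr), dim = dim(arr)), affine = affine)
  binarize_thrp(vol, p = 100, range = list(rmin = 0, rmax = 1),
                source_id = source_id)
}

# Brute-force distance from every voxel center to the nearest mask voxel
# center (independent of the package's distance transform).
brute_force_distance_map <- function(mask) {
  all_idx <- which(array(TRUE, dim(mask$data)), arr.ind = TRUE) - 1L
  m_idx <- which(mask$data, arr.ind = TRUE) - 1L
  centers <- voxel_to_world(mask, all_idx)
  mc <- t(voxel_to_world(mask, m_idx))
  d <- vapply(seq_len(nrow(centers)), function(i) {
    sqrt(min(colSums((mc - centers[i, ])^2)))
  }, numeric(1))
  array(d, dim = dim(mask$data))
}

# Sort-based percentile oracle: h = (n-1) p + 1, linear interpolation.
oracle_percentile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

random_rigid_affine <- function() {
  repeat {
    M <- matrix(stats::rnorm(9), 3, 3)
    qr_ <- qr(M)
    Q <- qr.Q(qr_)
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    if (abs(det(Q) - 1) < 1e-9) break
  }
  A <- diag(4)
  A[1:3, 1:3] <- Q
  A[1:3, 4] <- stats::runif(3, -20, 20)
  A
}
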