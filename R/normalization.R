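#' Construct a spatial transform (affine plus smooth residual field)
#'
#' Emulates an imperfect normalization into a standard space as
#' `T(x) = A x + w(x)`, where `A` is a 4x4 affine and `w` is a smooth
#' sinusoidal residual displacement field (the warp). Each of the three warp
#' fields drives one world axis:
#' `w_j(x) = a_j * sin(2*pi * <x, u_j> / lambda + phi_j)` with amplitude
#' `a_j` (mm), unit wavevector direction `u_j`, wavelength `lambda` (mm) and
#' phase `phi_j`, so `|w(x)| <= sqrt(3) * max(a)`. A `NULL` warp gives a
#' pure affine.
#'
#' @param affine 4x4 invertible matrix.
#' @param warp `NULL`, or a list with `amplitudes_mm` (length 3),
#'   `wavelength_mm` (> 0), `directions` (3x3, unit rows) and `phases`
#'   (length 3).
#' @return A `spatial_transform` object.
#' @export
spatial_transform <- function(affine, warp = NULL) {
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)))
  storage.mode(affine) <- "double"
  if (abs(det(affine)) < .Machine$double.eps) {
    stop("transform affine must be invertible")
  }
  if (!is.null(warp)) {
    stopifnot(length(warp$amplitudes_mm) == 3L,
              warp$wavelength_mm > 0,
              all(dim(warp$directions) == c(3L, 3L)),
              length(warp$phases) == 3L)
  }
  structure(list(affine = affine, warp = warp), class = "spatial_transform")
}

eval_warp <- function(warp, points) {
  pts <- as_point_matrix(points)
  w <- matrix(0, nrow(pts), 3L)
  for (j in 1:3) {
    phase <- 2 * pi * (pts %*% warp$directions[j, ])[, 1] /
      warp$wavelength_mm + warp$phases[j]
    w[, j] <- warp$amplitudes_mm[j] * sin(phase)
  }
  w
}

#' Apply a spatial transform to world points
#'
#' @param transform A [spatial_transform()].
#' @param point Length-3 vector or n x 3 matrix of world points (mm).
#' @return Transformed point(s), same shape as the input.
#' @export
apply_transform <- function(transform, point) {
  stopifnot(inherits(transform, "spatial_transform"))
  pts <- as_point_matrix(point)
  out <- cbind(pts, 1) %*% t(transform$affine[1:3, , drop = FALSE])
  if (!is.null(transform$warp)) {
    out <- out + eval_warp(transform$warp, pts)
  }
  if (is.null(dim(point))) drop(out) else out
}

#' Generate a seeded imperfect-normalization transform
#'
#' Draws the warp parameters of [spatial_transform()]: per-axis amplitudes
#' uniform on `[0, warp_amplitude_mm]`, random unit wavevector directions,
#' and uniform phases. `warp_amplitude_mm = 0` yields a pure affine.
#'
#' @param seed Integer RNG seed.
#' @param affine_part 4x4 affine component (default identity).
#' @param warp_amplitude_mm Maximum per-axis warp amplitude in mm (>= 0).
#' @param warp_wavelength_mm Spatial wavelength of the residual field in mm.
#' @return A [spatial_transform()].
#' @export
generate_normalization_transform <- function(seed, affine_part = diag(4),
                                             warp_amplitude_mm = 0,
                                             warp_wavelength_mm = 50) {
  stopifnot(warp_amplitude_mm >= 0, warp_wavelength_mm > 0)
  warp <- NULL
  if (warp_amplitude_mm > 0) {
    warp <- with_seed(seed, list(
      amplitudes_mm = runif(3, 0, warp_amplitude_mm),
      wavelength_mm = warp_wavelength_mm,
      directions = t(replicate(3, random_unit_vector())),
      phases = runif(3, 0, 2 * pi)
    ))
  }
  spatial_transform(affine_part, warp = warp)
}

#' Landmark-based normalization error for one patient
#'
#' The landmark protocol: measure the electrode-tip-to-red-nucleus distance
#' in native space (`d_native`), transform the tip into the standard space
#' and measure its distance to the atlas red-nucleus coordinate (`d_norm`),
#' and report the absolute difference of the two scalar distances — not the
#' displacement of the points themselves, mirroring how the two spaces are
#' compared in practice.
#'
#' @param tip_native Electrode tip in native space (mm).
#' @param rn_native Red-nucleus landmark in native space (mm).
#' @param transform The patient's [spatial_transform()] into standard space.
#' @param rn_atlas Atlas red-nucleus coordinate in standard space (mm).
#' @param patient_id Optional identifier copied into the output.
#' @return One-row data.frame: `patient_id`, `d_native_mm`, `d_norm_mm`,
#'   `error_mm`.
#' @export
landmark_error <- function(tip_native, rn_native, transform, rn_atlas,
                           patient_id = NA_character_) {
  d_native <- vnorm(as.numeric(tip_native) - as.numeric(rn_native))
  tip_norm <- apply_transform(transform, tip_native)
  d_norm <- vnorm(as.numeric(tip_norm) - as.numeric(rn_atlas))
  data.frame(patient_id = patient_id,
             d_native_mm = d_native, d_norm_mm = d_norm,
             error_mm = abs(d_norm - d_native),
             stringsAsFactors = FALSE)
}

#' Partition landmark measurements into retained and excluded cases
#'
#' Cases whose normalization error exceeds the cutoff are excluded as
#' presumed misrepresentations of coordinates after normalization; both
#' partitions preserve the input order.
#'
#' @param measurements Data.frame with an `error_mm` column (e.g. rows from
#'   [landmark_error()]).
#' @param cutoff_mm Exclusion cutoff in mm (> 0; default 5).
#' @return List with `retained` and `excluded` data.frames and `flagged`,
#'   the input with an added logical `excluded` column.
#' @export
exclude_outliers <- function(measurements, cutoff_mm = 5) {
  stopifnot(is.numeric(cutoff_mm), cutoff_mm > 0)
  ex <- measurements$error_mm > cutoff_mm
  if (is.null(ex)) ex <- logical(0)
  flagged <- measurements
  flagged$excluded <- ex
  list(retained = measurements[!ex, , drop = FALSE],
       excluded = measurements[ex, , drop = FALSE],
       flagged = flagged)
}

#' Simulate landmark normalization errors over a synthetic cohort
#'
#' Lightweight phantom for the normalization-error properties: each patient
#' gets a random tip and red-nucleus pair, a rigid (or supplied) affine, a
#' seeded warp of the given amplitude, and a perfectly homologous atlas
#' landmark (the image of the native landmark under the SAME transform).
#' With amplitude 0 and a rigid affine the error is identically 0; the mean
#' error grows with the warp amplitude.
#'
#' @param n_patients Number of synthetic patients.
#' @param warp_amplitude_mm Warp amplitude in mm (>= 0).
#' @param warp_wavelength_mm Warp wavelength in mm.
#' @param seed Master seed.
#' @return Data.frame of [landmark_error()] rows.
#' @export
simulate_landmark_errors <- function(n_patients, warp_amplitude_mm,
                                     warp_wavelength_mm = 50, seed = 1L) {
  rows <- lapply(seq_len(n_patients), function(i) {
    ps <- patient_seed(seed, i)
    with_seed(ps, {
      tip <- runif(3, -30, 30)
      rn <- tip + runif(1, 8, 20) * random_unit_vector()
      A <- diag(4)
      A[1:3, 1:3] <- rotation_matrix(runif(3, -pi, pi))
      A[1:3, 4] <- runif(3, -10, 10)
      wseed <- sample.int(2147483646L, 1L)
      tr <- generate_normalization_transform(
        wseed, affine_part = A,
        warp_amplitude_mm = warp_amplitude_mm,
        warp_wavelength_mm = warp_wavelength_mm)
      rn_atlas <- apply_transform(tr, rn)
      landmark_error(tip, rn, tr, rn_atlas,
                     patient_id = sprintf("S%03d", i))
    })
  })
  do.call(rbind, rows)
}
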