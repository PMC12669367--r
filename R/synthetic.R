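#' Specify a synthetic tract
#'
#' Describes one tube-like fiber tract used to emulate a streamline-count
#' probability map: a piecewise-linear centerline in world mm, a Gaussian
#' transverse intensity profile, a peak streamline count, and a fraction of
#' background voxels receiving small spurious counts.
#'
#' @param label Tract label, conventionally `"c-DRTT"` (crossing) or
#'   `"nd-DRTT"` (non-decussating part of the dentato-rubro-thalamic tract).
#' @param hemisphere `"left"` or `"right"`.
#' @param centerline Matrix (>= 2 rows x 3 cols) of ordered control points
#'   (world mm); consecutive points must be distinct.
#' @param sigma_mm Transverse Gaussian width in mm (> 0).
#' @param n_samples Peak streamline count (default 5000, the conventional
#'   number of probabilistic samples per seed voxel).
#' @param noise_fraction Fraction in `[0, 1)` of background (zero) voxels
#'   given small spurious counts.
#' @return A `tract_spec` object.
#' @export
tract_spec <- function(label, hemisphere, centerline, sigma_mm = 2,
                       n_samples = 5000, noise_fraction = 0) {
  centerline <- as_point_matrix(centerline)
  if (nrow(centerline) < 2L) stop("centerline needs >= 2 control points")
  seg <- diff(centerline)
  if (any(rowSums(seg^2) == 0)) {
    stop("consecutive centerline control points must be distinct")
  }
  stopifnot(sigma_mm > 0, n_samples >= 1,
            noise_fraction >= 0, noise_fraction < 1)
  structure(list(label = label, hemisphere = hemisphere,
                 centerline = centerline, sigma_mm = sigma_mm,
                 n_samples = n_samples, noise_fraction = noise_fraction),
            class = "tract_spec")
}

# Shortest world-mm distance from each point (n x 3) to a piecewise-linear
# path given by its control points; vectorized over points per segment.
dist_to_polyline <- function(points, centerline) {
  pts <- as_point_matrix(points)
  best <- rep(Inf, nrow(pts))
  for (s in seq_len(nrow(centerline) - 1L)) {
    a <- centerline[s, ]
    ab <- centerline[s + 1L, ] - a
    len2 <- sum(ab^2)
    pa <- sweep(pts, 2, a)
    t <- pmin(1, pmax(0, (pa %*% ab)[, 1] / len2))
    dx <- pa - outer(t, ab)
    best <- pmin(best, rowSums(dx^2))
  }
  sqrt(best)
}

#' Generate a synthetic tract probability map
#'
#' Emulates a probabilistic-tractography streamline-count image on the given
#' grid: each voxel value is `round(n_samples * exp(-r^2 / (2 sigma^2)))`
#' where `r` is the shortest world-mm distance from the voxel center to the
#' tract centerline; rounded values below 1 are set to 0. A seeded fraction
#' of the remaining zero voxels then receives small spurious counts drawn
#' uniformly from `{1, ..., max(1, n_samples/100)}`, reproducing the
#' heavy-tailed histogram of streamline-count maps (most voxels zero, few
#' large counts).
#'
#' @param spec A [tract_spec()].
#' @param grid A [volume3d()] template supplying shape and affine (its data
#'   are ignored).
#' @param seed Integer seed for the background-noise RNG.
#' @return A [volume3d()] of non-negative integer-valued counts.
#' @export
generate_tract_probability_map <- function(spec, grid, seed) {
  stopifnot(inherits(spec, "tract_spec"), inherits(grid, "volume3d"))
  # reject centerlines that never enter the grid
  probe <- densify_polyline(spec$centerline, step = min(grid$spacing) / 2)
  pv <- world_to_voxel(grid, probe)
  inb <- pv >= -0.5 & sweep(pv, 2, grid$dim - 0.5) < 0
  if (!any(rowSums(inb) == 3L)) {
    stop("tract centerline lies entirely outside the grid")
  }
  centers <- voxel_center_grid(grid)
  r <- dist_to_polyline(centers, spec$centerline)
  v <- round(spec$n_samples * exp(-r^2 / (2 * spec$sigma_mm^2)))
  v[v < 1] <- 0
  if (spec$noise_fraction > 0) {
    zero_idx <- which(v == 0)
    n_noise <- floor(spec$noise_fraction * length(zero_idx))
    if (n_noise > 0) {
      with_seed(seed, {
        chosen <- sample(zero_idx, n_noise)
        v[chosen] <- sample.int(max(1L, floor(spec$n_samples / 100)),
                                n_noise, replace = TRUE)
      })
    }
  }
  volume3d(array(v, dim = grid$dim), affine = grid$affine)
}

# Sample a polyline at roughly `step` mm resolution (control points kept).
densify_polyline <- function(centerline, step) {
  out <- list()
  for (s in seq_len(nrow(centerline) - 1L)) {
    a <- centerline[s, ]
    b <- centerline[s + 1L, ]
    n <- max(2L, ceiling(vnorm(b - a) / step) + 1L)
    t <- seq(0, 1, length.out = n)
    out[[s]] <- cbind(a[1] + t * (b[1] - a[1]),
                      a[2] + t * (b[2] - a[2]),
                      a[3] + t * (b[3] - a[3]))
  }
  do.call(rbind, out)
}

#' Specify a DBS lead
#'
#' @param tip Deepest contact position (world mm, length-3).
#' @param direction Unit 3-vector pointing from the tip toward shallower
#'   contacts (must have unit norm to within 1e-9).
#' @param n_contacts Number of contacts (>= 1); default 4, the conventional
#'   quadripolar lead.
#' @param contact_spacing_mm Center-to-center contact spacing in mm (> 0).
#' @return A `lead_spec` object.
#' @export
lead_spec <- function(tip, direction, n_contacts = 4, contact_spacing_mm = 2) {
  tip <- as.numeric(tip)
  direction <- as.numeric(direction)
  stopifnot(length(tip) == 3L, length(direction) == 3L,
            n_contacts >= 1, contact_spacing_mm > 0)
  if (abs(vnorm(direction) - 1) > 1e-9) {
    stop("lead direction must be a unit vector (|norm - 1| <= 1e-9)")
  }
  structure(list(tip = tip, direction = direction,
                 n_contacts = as.integer(n_contacts),
                 contact_spacing_mm = contact_spacing_mm),
            class = "lead_spec")
}

#' Generate contact positions along a lead
#'
#' Contact `c` (0-based, 0 = deepest) sits at
#' `tip + c * contact_spacing_mm * direction`.
#'
#' @param spec A [lead_spec()].
#' @return Matrix (`n_contacts` x 3) of world-mm contact positions, row `i`
#'   being contact index `i - 1`.
#' @export
generate_lead_contacts <- function(spec) {
  stopifnot(inherits(spec, "lead_spec"))
  steps <- (seq_len(spec$n_contacts) - 1L) * spec$contact_spacing_mm
  t(vapply(steps, function(s) spec$tip + s * spec$direction, numeric(3)))
}

#' Generate a synthetic cohort of phantom patients
#'
#' Builds a deterministic phantom cohort with the structure the error
#' analysis assumes: per patient and hemisphere, a crossing (c-DRTT) and a
#' non-decussating (nd-DRTT) tract probability volume whose centerlines
#' approach each other near the thalamic end (so the binarization threshold
#' genuinely affects their discriminability), a multi-contact lead whose tip
#' is jittered 0--8 mm off the c-DRTT centerline, a red-nucleus-like native
#' landmark placed between the two tracts, and an imperfect normalization
#' transform (affine with mild anisotropic scaling and rotation plus a
#' smooth sinusoidal residual field). A configured fraction of patients
#' receives a grossly wrong transform, emulating failed normalizations.
#'
#' One RNG stream per patient is derived from the master seed, so adding
#' patients never perturbs existing ones.
#'
#' @param config Configuration list, see [default_config()].
#' @param seed Master integer seed.
#' @return A `phantom_cohort`: list with `patients` (each holding
#'   `patient_id`, `volumes[[hemisphere]][[label]]`, `contacts` data.frame,
#'   `rn_native`, `transform`, `rn_atlas`, `misnormalized`), plus `grid`,
#'   `config` and `seed`.
#' @export
generate_cohort <- function(config = default_config(), seed = 1L) {
  config <- validate_config(config)
  grid <- cohort_grid(config)
  patients <- lapply(seq_len(config$n_patients), function(i) {
    generate_patient(i, config, grid, patient_seed(seed, i))
  })
  structure(list(patients = patients, grid = grid,
                 config = config, seed = seed),
            class = "phantom_cohort")
}

# Template grid centered on the world origin.
cohort_grid <- function(config) {
  dimv <- config$grid_dim
  sp <- config$spacing_mm
  aff <- diag(c(sp, 1))
  aff[1:3, 4] <- -(dimv - 1) / 2 * sp
  volume3d(array(0, dim = dimv), affine = aff)
}

# Baseline tract centerlines for one hemisphere (world mm, grid centered at
# the origin). The two tracts run inferior-posterior to superior and converge
# near the thalamic (superior) end without merging.
base_centerlines <- function(hemisphere) {
  sx <- if (hemisphere == "left") -1 else 1
  list(
    "c-DRTT" = rbind(c(sx * 20, -32, -42),
                     c(sx * 12, -22, -12),
                     c(sx * 10, -14, 6)),
    "nd-DRTT" = rbind(c(sx * 34, -38, -42),
                      c(sx * 24, -26, -12),
                      c(sx * 16, -8, 8))
  )
}

generate_patient <- function(i, config, grid, pseed) {
  pid <- sprintf("P%03d", i)
  with_seed(pseed, {
    volumes <- list()
    contacts <- list()
    rn_by_hemi <- list()
    for (hemi in c("left", "right")) {
      cls <- base_centerlines(hemi)
      # per-patient anatomical variability on every control point
      cls <- lapply(cls, function(m) m + matrix(runif(length(m), -2, 2),
                                                nrow = nrow(m)))
      # lead: tip jittered off the c-DRTT centerline near its thalamic end
      cl <- cls[["c-DRTT"]]
      t_on <- runif(1, 0.75, 1)
      anchor <- polyline_point(cl, t_on)
      u <- random_unit_vector()
      tip <- anchor + runif(1, 0, config$lead_max_offset_mm) * u
      sx <- if (hemi == "left") -1 else 1
      dir_raw <- c(sx * 0.25, 0.35, 0.9) + runif(3, -0.05, 0.05)
      direction <- dir_raw / vnorm(dir_raw)
      lead <- lead_spec(tip, direction, config$n_contacts,
                        config$contact_spacing_mm)
      pos <- generate_lead_contacts(lead)
      volumes[[hemi]] <- list()
      for (label in c("c-DRTT", "nd-DRTT")) {
        spec <- tract_spec(label, hemi, cls[[label]],
                           sigma_mm = config$sigma_mm,
                           n_samples = config$n_samples,
                           noise_fraction = config$noise_fraction)
        noise_seed <- sample.int(2147483646L, 1L)
        vol <- generate_tract_probability_map(spec, grid, seed = noise_seed)
        # low-count spurious side branch drawn toward the lead region:
        # visible at permissive thresholds, gone at strict ones — the
        # feature that makes the threshold choice genuinely change measured
        # distances in streamline-count maps
        branch_cl <- spurious_branch(cls[[label]], tip)
        branch <- tract_spec(paste0(label, "-branch"), hemi, branch_cl,
                             sigma_mm = config$sigma_mm,
                             n_samples = max(1L, config$n_samples %/% 16L),
                             noise_fraction = 0)
        bvol <- generate_tract_probability_map(branch, grid, seed = 0L)
        vol$data <- vol$data + bvol$data
        volumes[[hemi]][[label]] <- vol
      }
      contacts[[hemi]] <- data.frame(
        patient_id = pid, hemisphere = hemi,
        contact_index = seq_len(nrow(pos)) - 1L,
        x_mm = pos[, 1], y_mm = pos[, 2], z_mm = pos[, 3],
        stringsAsFactors = FALSE)
      # RN-like landmark between the two tracts, mid-course
      rn_by_hemi[[hemi]] <- (polyline_point(cls[["c-DRTT"]], 0.55) +
                               polyline_point(cls[["nd-DRTT"]], 0.55)) / 2
    }
    # imperfect normalization: mild scaling + rotation + translation
    scales <- runif(3, 0.96, 1.06)
    angles <- runif(3, -3, 3) * pi / 180
    A_ideal <- diag(4)
    A_ideal[1:3, 1:3] <- rotation_matrix(angles) %*% diag(scales)
    A_ideal[1:3, 4] <- runif(3, -5, 5)
    misnormalized <- runif(1) < config$misnormalized_fraction
    A_actual <- A_ideal
    if (misnormalized) {
      # gross registration failure: the patient image lands far from where a
      # correct normalization would have put it
      A_actual[1:3, 4] <- A_actual[1:3, 4] +
        sample(c(-1, 1), 3, replace = TRUE) * runif(3, 8, 18)
    }
    tseed <- sample.int(2147483646L, 1L)
    transform <- generate_normalization_transform(
      seed = tseed, affine_part = A_actual,
      warp_amplitude_mm = config$warp_amplitude_mm,
      warp_wavelength_mm = config$warp_wavelength_mm)
    rn_native <- rn_by_hemi[["right"]]
    # atlas landmark: where a CORRECT normalization (same warp, un-shifted
    # affine) would place the native RN, plus an optional atlas placement
    # offset; a mis-normalized image therefore shows a large discrepancy.
    ideal <- transform
    ideal$affine <- A_ideal
    rn_atlas <- apply_transform(ideal, rn_native)
    if (config$atlas_rn_offset_mm > 0) {
      rn_atlas <- rn_atlas + config$atlas_rn_offset_mm * random_unit_vector()
    }
    list(patient_id = pid, volumes = volumes,
         contacts = do.call(rbind, unname(contacts)),
         rn_native = rn_native, transform = transform,
         rn_atlas = rn_atlas, misnormalized = misnormalized)
  })
}

# Short low-count side branch leaving the upper course of a tract and drawn
# toward the lead region (a false-positive streamline bundle) with seeded
# variability in its take-off point and endpoint.
spurious_branch <- function(centerline, lead_tip) {
  start <- polyline_point(centerline, runif(1, 0.45, 0.75))
  end <- lead_tip + runif(1, 0, 5) * random_unit_vector()
  if (vnorm(end - start) < 1e-6) end <- start + c(0, 0, 5)
  rbind(start, end)
}

# Point at arc-length fraction t in [0,1] along a piecewise-linear path.
polyline_point <- function(centerline, t) {
  seg <- diff(centerline)
  lens <- sqrt(rowSums(seg^2))
  total <- sum(lens)
  s <- t * total
  cum <- c(0, cumsum(lens))
  k <- max(1L, min(findInterval(s, cum, rightmost.closed = TRUE),
                   length(lens)))
  frac <- (s - cum[k]) / lens[k]
  centerline[k, ] + frac * seg[k, ]
}

random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- vnorm(v)
    if (n > 1e-12) return(v / n)
  }
}

# Intrinsic rotation about x, then y, then z.
rotation_matrix <- function(angles) {
  cx <- cos(angles[1]); sxn <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sxn), c(0, sxn, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Write a phantom cohort to disk
#'
#' Writes one NIfTI probability volume per patient/hemisphere/tract
#' (`{patient}_{hemisphere}_{label}.nii.gz`), a `contacts.csv`, a
#' `landmarks.csv` (same CSV dialect, one RN row per patient), and one
#' `transform_{patient}.json` per patient.
#'
#' @param cohort A `phantom_cohort` from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  contacts <- list()
  landmarks <- list()
  for (p in cohort$patients) {
    for (hemi in names(p$volumes)) {
      for (label in names(p$volumes[[hemi]])) {
        fn <- sprintf("%s_%s_%s.nii.gz", p$patient_id, hemi,
                      gsub("-", "", label))
        write_volume(p$volumes[[hemi]][[label]], file.path(dir, fn))
      }
    }
    contacts[[p$patient_id]] <- p$contacts
    landmarks[[p$patient_id]] <- data.frame(
      patient_id = p$patient_id, hemisphere = "right", contact_index = 0L,
      x_mm = p$rn_native[1], y_mm = p$rn_native[2], z_mm = p$rn_native[3],
      stringsAsFactors = FALSE)
    write_transform(p$transform,
                    file.path(dir, sprintf("transform_%s.json", p$patient_id)))
  }
  write_contacts(do.call(rbind, unname(contacts)), file.path(dir, "contacts.csv"))
  write_contacts(do.call(rbind, unname(landmarks)), file.path(dir, "landmarks.csv"))
  invisible(dir)
}
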