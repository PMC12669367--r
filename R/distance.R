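#' Compute the Euclidean distance map of a binary tract mask
#'
#' Produces an image in which each voxel stores the shortest distance in
#' world mm from its center to the center of any mask voxel — the automated
#' measurement substrate for contact-to-tract distances. The transform is
#' the exact separable Euclidean distance transform and honors anisotropic
#' voxel spacing; mask voxels map to exactly 0.
#'
#' The voxel spacing is taken from the mask's affine column norms, so the
#' map is exact for axis-aligned acquisitions (rotated affines preserve
#' distances and are equally fine; sheared affines are not supported).
#'
#' @param mask A non-empty `binary_mask` from [binarize_thrp()].
#' @return A `distance_map`: float array (mm) + affine + provenance.
#' @export
compute_distance_map <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (mask$provenance$empty || !any(mask$data)) {
    stop("cannot compute a distance map of an empty mask (source: ",
         mask$provenance$source_id, ")")
  }
  d <- edt3d(as.logical(mask$data), as.integer(mask$dim),
             as.numeric(mask$spacing))
  structure(
    list(data = array(d, dim = mask$dim), affine = mask$affine,
         spacing = mask$spacing, dim = mask$dim,
         provenance = mask$provenance),
    class = "distance_map"
  )
}

#' @export
print.distance_map <- function(x, ...) {
  cat("distance_map: ", paste(x$dim, collapse = " x "),
      " voxels, max ", signif(max(x$data), 6), " mm\n", sep = "")
  invisible(x)
}

#' Sample a distance map at a world point
#'
#' Nearest-neighbor sampling by default (the value stored at the voxel
#' containing the point), matching how per-coordinate distances are exported
#' from precomputed maps; trilinear interpolation is available for
#' sensitivity analyses. The nearest-neighbor value can differ from the true
#' point-to-mask distance by at most half the voxel diagonal.
#'
#' @param dmap A `distance_map`.
#' @param point Length-3 world point (mm).
#' @param method `"nearest"` (default) or `"trilinear"`.
#' @param id Optional identifier (e.g. a contact label) used in error
#'   messages.
#' @return Distance in mm.
#' @export
distance_at_point <- function(dmap, point, method = c("nearest", "trilinear"),
                              id = NULL) {
  method <- match.arg(method)
  nv <- nearest_voxel(dmap, point)
  if (!nv$in_bounds) {
    stop("point", if (!is.null(id)) paste0(" for ", id),
         " falls outside the distance-map grid: (",
         paste(signif(as.numeric(point), 6), collapse = ", "), ") mm")
  }
  if (method == "nearest") {
    i <- nv$index
    return(dmap$data[i[1] + 1L, i[2] + 1L, i[3] + 1L])
  }
  cont <- world_to_voxel(dmap, point)
  lo <- pmin(pmax(floor(cont), 0), dmap$dim - 1L)
  hi <- pmin(lo + 1, dmap$dim - 1L)
  frac <- pmin(pmax(cont - lo, 0), 1)
  val <- 0
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    w <- (if (cx) frac[1] else 1 - frac[1]) *
      (if (cy) frac[2] else 1 - frac[2]) *
      (if (cz) frac[3] else 1 - frac[3])
    ii <- c(if (cx) hi[1] else lo[1],
            if (cy) hi[2] else lo[2],
            if (cz) hi[3] else lo[3])
    val <- val + w * dmap$data[ii[1] + 1L, ii[2] + 1L, ii[3] + 1L]
  }
  val
}

#' Brute-force point-to-mask distance
#'
#' Independent verification oracle: the minimum over all mask voxels of the
#' Euclidean world distance from the point to the voxel center, computed by
#' direct enumeration with no precomputation. Used to validate
#' [compute_distance_map()] + [distance_at_point()].
#'
#' @param mask A non-empty `binary_mask`.
#' @param point Length-3 world point (mm).
#' @return Distance in mm.
#' @export
oracle_point_to_mask <- function(mask, point) {
  stopifnot(inherits(mask, "binary_mask"))
  idx <- which(mask$data, arr.ind = TRUE) - 1L
  if (nrow(idx) == 0L) stop("oracle distance undefined for an empty mask")
  centers <- voxel_to_world(mask, idx)
  point <- as.numeric(point)
  sqrt(min(rowSums(sweep(centers, 2, point)^2)))
}

#' Emulated manual distance measurement on the contact's axial slice
#'
#' Reproduces the manual technique being assessed: the reader sees only the
#' axial slice through the electrode contact (the k-plane of its nearest
#' voxel) and measures the Euclidean distance from the pole coordinate to
#' the closest tract voxel center visible on that slice. Restricting the
#' candidate tract points to one slice is what inflates the measurement
#' relative to the full 3D distance (the visible tract is a subset of the
#' whole tract, so the manual reading can never undercut the true
#' distance). When the tract does not appear on the slice the distance is
#' not measurable and `NA` is returned — the mechanism by which a subset of
#' contact-tract pairs drops out of manual analysis. Optional seeded
#' zero-mean uniform jitter (half-width `jitter_mm`, floored at 0) emulates
#' human reading error; the default 0 makes the emulation deterministic.
#'
#' @param mask A `binary_mask`.
#' @param point Length-3 world contact position (mm); its nearest voxel must
#'   be in bounds.
#' @param jitter_mm Jitter half-width in mm (>= 0).
#' @param seed Seed for the jitter RNG (ignored when `jitter_mm` is 0).
#' @return In-plane distance in mm, or `NA_real_` when the tract is not
#'   visible on the contact's axial slice.
#' @export
manual_axial_distance <- function(mask, point, jitter_mm = 0, seed = NULL) {
  stopifnot(inherits(mask, "binary_mask"), jitter_mm >= 0)
  nv <- nearest_voxel(mask, point)
  if (!nv$in_bounds) {
    stop("contact at (", paste(signif(as.numeric(point), 6), collapse = ", "),
         ") mm falls outside the mask grid")
  }
  k <- nv$index[3]
  slice <- mask$data[, , k + 1L]
  inplane <- which(slice, arr.ind = TRUE) - 1L
  if (nrow(inplane) == 0L) return(NA_real_)
  centers <- voxel_to_world(mask, cbind(inplane, k))
  point <- as.numeric(point)
  d <- sqrt(min(rowSums(sweep(centers, 2, point)^2)))
  if (jitter_mm > 0) {
    d <- d + with_seed(seed, runif(1, -jitter_mm, jitter_mm))
  }
  max(0, d)
}

#' Measure one contact against each tract, with the step-down rule
#'
#' For each tract probability volume: binarize at the selected threshold,
#' look the automated distance up in the tract's 3D distance map, and — if
#' it exceeds `step_cutoff_mm` (strictly) and a lower candidate threshold
#' exists — re-binarize that tract exactly one step lower and re-measure
#' once, recording the step-down. The emulated manual axial measurement is
#' taken on the final mask. The reported `d_auto_mm` is the distance at the
#' final threshold.
#'
#' @param prob_volumes Named list of tract probability [volume3d()]s (names
#'   are tract labels), all for the contact's hemisphere.
#' @param contact One-row data.frame with `patient_id`, `hemisphere`,
#'   `contact_index`, `x_mm`, `y_mm`, `z_mm`.
#' @param p_selected Threshold percentage selected for the patient.
#' @param candidates Candidate threshold percentages (must contain
#'   `p_selected`).
#' @param step_cutoff_mm Distance cutoff triggering the one-step fallback
#'   (default 10 mm, strict `>`).
#' @param jitter_mm,seed Manual-measurement jitter, see
#'   [manual_axial_distance()].
#' @param nonzero_only Passed to [robust_range()].
#' @param cache Optional environment memoising masks/distance maps across
#'   calls (keyed internally); pass the same environment for all contacts of
#'   one hemisphere to avoid recomputation.
#' @return Data.frame with one row per tract: `patient_id`, `hemisphere`,
#'   `tract`, `contact_index`, `p_initial`, `p_final`, `stepped_down`,
#'   `d_auto_mm`, `d_manual_mm`, `manual_measurable`.
#' @export
measure_contact <- function(prob_volumes, contact, p_selected, candidates,
                            step_cutoff_mm = 10, jitter_mm = 0, seed = NULL,
                            nonzero_only = FALSE, cache = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  point <- c(contact$x_mm, contact$y_mm, contact$z_mm)
  rows <- lapply(names(prob_volumes), function(label) {
    get_md <- function(p) {
      key <- paste0(label, "@", p)
      if (!exists(key, envir = cache, inherits = FALSE)) {
        m <- binarize_thrp(prob_volumes[[label]], p, nonzero_only = nonzero_only,
                           source_id = label)
        dm <- if (m$provenance$empty) NULL else compute_distance_map(m)
        assign(key, list(mask = m, dmap = dm), envir = cache)
      }
      get(key, envir = cache, inherits = FALSE)
    }
    p_final <- p_selected
    stepped <- FALSE
    md <- get_md(p_selected)
    if (is.null(md$dmap)) {
      d_auto <- NA_real_
    } else {
      d_auto <- distance_at_point(md$dmap, point,
                                  id = paste(contact$patient_id, label,
                                             contact$contact_index))
      if (d_auto > step_cutoff_mm) {
        lower <- step_down(p_selected, candidates)
        if (!is.null(lower)) {
          p_final <- lower
          stepped <- TRUE
          md <- get_md(lower)
          d_auto <- distance_at_point(md$dmap, point)
        }
      }
    }
    d_manual <- if (is.null(md$dmap)) {
      NA_real_
    } else {
      manual_axial_distance(md$mask, point, jitter_mm = jitter_mm, seed = seed)
    }
    data.frame(patient_id = contact$patient_id,
               hemisphere = contact$hemisphere,
               tract = label,
               contact_index = contact$contact_index,
               p_initial = p_selected, p_final = p_final,
               stepped_down = stepped,
               d_auto_mm = d_auto, d_manual_mm = d_manual,
               manual_measurable = !is.na(d_manual),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
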