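#' Robust intensity range of a volume
#'
#' The robust range of a streamline-count image is the intensity span between
#' the 2nd and 98th percentile of its histogram, ignoring extreme values.
#' Percentiles use linear interpolation between order statistics and, by
#' default, include ALL voxels (zeros too); `nonzero_only = TRUE` restricts
#' the histogram to positive voxels, since binarization tools differ on this
#' point.
#'
#' @param volume A [volume3d()].
#' @param nonzero_only Compute percentiles over positive voxels only.
#' @return List with `rmin` (2nd percentile) and `rmax` (98th percentile).
#' @export
robust_range <- function(volume, nonzero_only = FALSE) {
  v <- as.vector(volume$data)
  if (all(is.na(v))) stop("cannot compute a robust range of an all-NaN volume")
  if (nonzero_only) {
    v <- v[!is.na(v) & v > 0]
    if (!length(v)) stop("no positive voxels for nonzero-only robust range")
  }
  q <- quantile(v, probs = c(0.02, 0.98), names = FALSE, na.rm = TRUE,
                type = 7)
  list(rmin = q[1], rmax = q[2])
}

#' Binarize a probability map at a percentage of its robust range
#'
#' The threshold value is `rmin + (p/100) * (rmax - rmin)`; voxels whose
#' value is `>=` the threshold are kept. Because the robust range of a
#' heavy-tailed streamline-count map sits far below the global maximum,
#' percentages well above 100 (the conventional 400--1000) are meaningful.
#' An empty mask is legal and flagged in the provenance rather than an
#' error.
#'
#' @param volume A [volume3d()].
#' @param p Threshold percentage of the robust range (> 0).
#' @param range Optional precomputed [robust_range()] of `volume`.
#' @param nonzero_only Passed to [robust_range()] when `range` is NULL.
#' @param source_id Identifier recorded in the mask provenance.
#' @return A `binary_mask`: logical array + affine + provenance
#'   (`source_id`, `p`, `threshold`, `n_voxels`, `empty`).
#' @export
binarize_thrp <- function(volume, p, range = NULL, nonzero_only = FALSE,
                          source_id = "volume") {
  if (!is.numeric(p) || length(p) != 1L || p <= 0) {
    stop("threshold percentage `p` must be a single positive number")
  }
  if (is.null(range)) range <- robust_range(volume, nonzero_only = nonzero_only)
  thr <- range$rmin + (p / 100) * (range$rmax - range$rmin)
  keep <- volume$data >= thr
  keep[is.na(keep)] <- FALSE
  n <- sum(keep)
  structure(
    list(data = array(keep, dim = volume$dim), affine = volume$affine,
         spacing = volume$spacing, dim = volume$dim,
         provenance = list(source_id = source_id, p = p, threshold = thr,
                           n_voxels = n, empty = n == 0L)),
    class = "binary_mask"
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("binary_mask: ", x$provenance$n_voxels, " voxels at p=",
      x$provenance$p, "% (threshold ", signif(x$provenance$threshold, 6),
      ")\n", sep = "")
  invisible(x)
}

#' Dice overlap of two binary masks
#'
#' `2|A & B| / (|A| + |B|)`; defined as 0 when both masks are empty.
#'
#' @param a,b `binary_mask` objects on the same grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_overlap <- function(a, b) {
  stopifnot(all(a$dim == b$dim))
  denom <- sum(a$data) + sum(b$data)
  if (denom == 0) return(0)
  2 * sum(a$data & b$data) / denom
}

#' Select the tract-discrimination threshold for a patient
#'
#' Chooses one threshold percentage for the whole brain (never per
#' hemisphere) from a candidate list, as the explicit stand-in for visual
#' selection of the threshold that best discriminates the crossing from the
#' non-decussating tract: among candidates at which all four masks (c/nd x
#' left/right) are non-empty, the one minimizing the mean of the two
#' per-hemisphere Dice overlaps between the c- and nd-masks is returned.
#' Ties go to the lowest percentage; if no candidate is feasible the lowest
#' candidate is returned, flagged infeasible.
#'
#' @param c_left,c_right,nd_left,nd_right Tract probability [volume3d()]s.
#' @param candidates Numeric vector of threshold percentages (>= 1 entry).
#' @param nonzero_only Passed to [robust_range()].
#' @return List with `p` (selected percentage), `feasible` (logical), and
#'   `table` (one row per candidate: `p`, `dice_left`, `dice_right`,
#'   `mean_dice`, `all_nonempty`).
#' @export
select_discrimination_threshold <- function(c_left, c_right, nd_left,
                                            nd_right, candidates,
                                            nonzero_only = FALSE) {
  if (!length(candidates)) stop("candidate threshold list must be non-empty")
  vols <- list(c_left = c_left, c_right = c_right,
               nd_left = nd_left, nd_right = nd_right)
  ranges <- lapply(vols, robust_range, nonzero_only = nonzero_only)
  rows <- lapply(sort(candidates), function(p) {
    m <- Map(function(v, r, id) binarize_thrp(v, p, range = r, source_id = id),
             vols, ranges, names(vols))
    nonempty <- !vapply(m, function(x) x$provenance$empty, logical(1))
    dl <- dice_overlap(m$c_left, m$nd_left)
    dr <- dice_overlap(m$c_right, m$nd_right)
    data.frame(p = p, dice_left = dl, dice_right = dr,
               mean_dice = (dl + dr) / 2, all_nonempty = all(nonempty))
  })
  tab <- do.call(rbind, rows)
  feasible <- tab[tab$all_nonempty, , drop = FALSE]
  if (nrow(feasible) == 0L) {
    return(list(p = min(candidates), feasible = FALSE, table = tab))
  }
  best <- feasible$p[order(feasible$mean_dice, feasible$p)][1]
  list(p = best, feasible = TRUE, table = tab)
}

#' Step a threshold one candidate lower
#'
#' Implements the measurement fallback rule: when a contact-to-tract
#' distance exceeds the cutoff, the tract's threshold is switched exactly
#' one step lower to obtain a more generous tract representation.
#'
#' @param p Current threshold percentage; must be one of `candidates`.
#' @param candidates Numeric vector of candidate percentages.
#' @return The next lower candidate, or `NULL` when `p` is already the
#'   lowest.
#' @export
step_down <- function(p, candidates) {
  candidates <- sort(candidates)
  i <- match(p, candidates)
  if (is.na(i)) {
    stop("threshold ", p, " is not among the candidates: ",
         paste(candidates, collapse = ", "))
  }
  if (i == 1L) NULL else candidates[i - 1L]
}
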