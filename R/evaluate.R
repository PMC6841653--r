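#' Cortical breach test
#'
#' Criterion 3: the screw must not violate or penetrate the bony borders of
#' the tunnel. At each axis station the trilinearly sampled distance map gives
#' the clearance to the nearest cortex; a station breaches when
#' `clearance + eps < radius`, where `eps` (default half the voxel diagonal)
#' absorbs discretization of the distance map so that an exact-touch screw is
#' not scored as a breach.
#'
#' @param cyl a [cylinder()].
#' @param dmap a [distance_map()].
#' @param step axis sampling step, mm.
#' @param eps discretization tolerance, mm; default
#'   `0.5 * sqrt(sum(spacing^2))`.
#' @return An object of class `breach_report`: `breached`, `stations`
#'   (data.frame of breaching stations with clearance and required radius),
#'   `min_margin` (min clearance minus radius, mm) and `eps`.
#' @export
breach_test <- function(cyl, dmap, step = 1, eps = NULL) {
  stopifnot(inherits(cyl, "cylinder"), inherits(dmap, "distance_map"))
  if (!is.numeric(step) || step <= 0) stop("step must be > 0")
  eps <- eps %||% (0.5 * sqrt(sum(dmap$spacing^2)))
  pts <- sample_axis(cyl, step)
  lo <- dmap$origin - dmap$spacing
  hi <- dmap$origin + (dim(dmap$data) - 1L) * dmap$spacing + dmap$spacing
  in_ext <- pts[, 1] >= lo[1] & pts[, 1] <= hi[1] &
    pts[, 2] >= lo[2] & pts[, 2] <= hi[2] &
    pts[, 3] >= lo[3] & pts[, 3] <= hi[3]
  if (!any(in_ext))
    stop("screw axis lies entirely outside the volume extent")
  clearance <- sample_field(dmap, pts)
  station <- sqrt(rowSums(sweep(pts, 2, cyl$entry_point, `-`)^2))
  bad <- clearance + eps < cyl$radius
  structure(list(breached = any(bad),
                 stations = data.frame(station = station[bad],
                                       clearance = clearance[bad],
                                       required = rep(cyl$radius, sum(bad))),
                 min_margin = min(clearance - cyl$radius),
                 eps = eps),
            class = "breach_report")
}

#' @export
print.breach_report <- function(x, ...) {
  cat(sprintf("<breach_report> %s; min margin %.2f mm (eps %.2f mm)\n",
              if (x$breached) sprintf("BREACHED at %d station(s)",
                                      nrow(x$stations)) else "no breach",
              x$min_margin, x$eps))
  invisible(x)
}

#' Glenoid parallelism test
#'
#' Criterion 2: the screw must be parallel to the glenoid fossa. The
#' deviation is the angle between the screw axis and the glenoid plane,
#' `|90 - acos(dot(axis, normal))|` in degrees; the placement passes when the
#' deviation is within `tol_deg`. The study states the criterion without a
#' numeric tolerance; 10 degrees is the package default and is always
#' recorded in the result.
#'
#' @param cyl a [cylinder()].
#' @param plane_normal unit normal of the glenoid plane.
#' @param tol_deg angular tolerance, degrees.
#' @return `list(ok, angle_deg, tol_deg)`.
#' @export
parallel_test <- function(cyl, plane_normal, tol_deg = 10) {
  stopifnot(inherits(cyl, "cylinder"))
  plane_normal <- as.numeric(plane_normal)
  n <- sqrt(sum(plane_normal^2))
  if (n < 1e-12) stop("plane normal must be nonzero")
  plane_normal <- plane_normal / n
  d <- sum(cyl$axis_dir * plane_normal)
  angle <- abs(90 - acos(pmin(pmax(d, -1), 1)) * 180 / pi)
  list(ok = angle <= tol_deg, angle_deg = angle, tol_deg = tol_deg)
}

#' Tunnel traversal test
#'
#' Criterion 1: the screw must run down the coracoid stalk, through the base
#' and into the neck. The axis is sampled, each point is assigned the label of
#' its nearest voxel (0 outside), consecutive repeats are collapsed, and the
#' placement passes iff stalk (1), base (2), neck (3) occur as a subsequence
#' in that order.
#'
#' @param cyl a [cylinder()].
#' @param labels a region-label volume (e.g. `truth$region_labels`).
#' @param step axis sampling step, mm.
#' @return `list(ok, sequence)` where `sequence` is the collapsed label run.
#' @export
traversal_test <- function(cyl, labels, step = 1) {
  stopifnot(inherits(cyl, "cylinder"))
  pts <- sample_axis(cyl, step)
  ijk <- round(sweep(sweep(pts, 2, labels$origin, `-`), 2, labels$spacing,
                     `/`))
  dm <- dim(labels$data)
  inb <- ijk[, 1] >= 0 & ijk[, 1] < dm[1] & ijk[, 2] >= 0 & ijk[, 2] < dm[2] &
    ijk[, 3] >= 0 & ijk[, 3] < dm[3]
  lab <- integer(nrow(pts))
  idx <- ijk[inb, , drop = FALSE]
  lab[inb] <- labels$data[cbind(idx[, 1] + 1, idx[, 2] + 1, idx[, 3] + 1)]
  seqs <- rle(lab)$values
  ok <- is_subsequence(c(1L, 2L, 3L), seqs)
  list(ok = ok, sequence = seqs)
}

is_subsequence <- function(sub, seqs) {
  j <- 1L
  for (s in seqs) {
    if (s == sub[j]) {
      j <- j + 1L
      if (j > base::length(sub)) return(TRUE)
    }
  }
  FALSE
}

#' Score a virtual screw placement
#'
#' Binary Correct/Incorrect rating against the three predefined criteria:
#' (1) traversal stalk -> base -> neck, (2) parallel to the glenoid plane,
#' (3) no cortical breach. `Correct` requires all three. Screw length and
#' depth do not enter the rating beyond defining the sampled axis span,
#' matching the study's rule that length and depth were not taken into
#' account.
#'
#' The breach criterion concerns the *side walls* of the tunnel: a screw
#' placed from the surface necessarily transits the cortex at its entry point
#' and again where it seats in the far cortex, and that transit is not a
#' violation of the tunnel borders. The breach check therefore excludes the
#' axis span within `entry_exit_trim` (default one screw radius) of either
#' end of the screw; a wall encroachment anywhere along the remaining shaft
#' is still a breach. Set `entry_exit_trim = 0` to apply [breach_test()] to
#' the full axis.
#'
#' @param cyl a [cylinder()].
#' @param truth phantom ground truth (supplies labels and glenoid normal).
#' @param dmap a [distance_map()] of the phantom's bone mask.
#' @param tol_deg parallelism tolerance, degrees.
#' @param step axis sampling step, mm.
#' @param entry_exit_trim axis length (mm) excluded from the breach check at
#'   each end of the screw; default `cyl$radius`.
#' @return An object of class `placement_score` with the three booleans,
#'   `overall` (`"Correct"`/`"Incorrect"`) and per-criterion diagnostics.
#' @export
score_placement <- function(cyl, truth, dmap, tol_deg = 10, step = 1,
                            entry_exit_trim = NULL) {
  trim <- entry_exit_trim %||% cyl$radius
  trav <- traversal_test(cyl, truth$region_labels, step)
  par <- parallel_test(cyl, truth$glenoid_plane_normal, tol_deg)
  shaft <- if (cyl$length > 2 * trim + step)
    cylinder(cyl$entry_point + trim * cyl$axis_dir, cyl$axis_dir,
             cyl$radius, cyl$length - 2 * trim)
  else cyl
  br <- breach_test(shaft, dmap, step)
  ok <- trav$ok && par$ok && !br$breached
  structure(list(traversal_ok = trav$ok, parallel_ok = par$ok,
                 breach_ok = !br$breached,
                 overall = if (ok) "Correct" else "Incorrect",
                 details = list(traversal = trav, parallel = par,
                                breach = br)),
            class = "placement_score")
}

#' @export
print.placement_score <- function(x, ...) {
  cat(sprintf("<placement_score> %s (traversal %s, parallel %s [%.1f deg], breach-free %s [margin %.2f mm])\n",
              x$overall, x$traversal_ok, x$parallel_ok,
              x$details$parallel$angle_deg, x$breach_ok,
              x$details$breach$min_margin))
  invisible(x)
}

#' Score as a JSON record
#'
#' @param score a [score_placement()] result.
#' @param path optional file path.
#' @return JSON string, or `path` invisibly.
#' @export
score_to_json <- function(score, path = NULL) {
  js <- jsonlite::toJSON(list(traversal_ok = score$traversal_ok,
                              parallel_ok = score$parallel_ok,
                              breach_ok = score$breach_ok,
                              angle_deg = score$details$parallel$angle_deg,
                              min_margin_mm = score$details$breach$min_margin,
                              overall = score$overall),
                         auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
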