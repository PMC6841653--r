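#' Voxel volume
#'
#' A 3-D scalar grid with physical geometry: `spacing` (mm per voxel along
#' each axis) and `origin` (world position, in mm, of the centre of voxel
#' index `(0,0,0)`). Volumes are axis-aligned: all rigid orientation lives in
#' the [view_state()], never in the volume, so the world coordinate of voxel
#' index `(i,j,k)` (0-based) is simply `origin + c(i,j,k) * spacing`.
#'
#' @param data numeric 3-D array of intensities (HU-like).
#' @param spacing numeric length-3, mm per voxel; all components `> 0`.
#' @param origin numeric length-3, mm.
#' @param name free-text label.
#' @return An object of class `voxel_volume`.
#' @examples
#' v <- voxel_volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 1))
#' dim(v$data)
#' @export
voxel_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         name = "volume") {
  data <- as.array(data)
  if (length(dim(data)) != 3L || any(dim(data) < 2L))
    stop("volume data must be a 3-D array with every dimension >= 2")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values (mm)")
  structure(list(data = data, spacing = spacing, origin = origin,
                 name = as.character(name)[1]),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("<voxel_volume> '%s'  %s voxels  spacing %s mm  origin %s mm\n",
              x$name, paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              paste(format(x$origin), collapse = ", ")))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' World coordinates of voxel indices
#'
#' @param vol a [voxel_volume()] or mask.
#' @param ijk integer matrix (n x 3) of 0-based voxel indices.
#' @return n x 3 matrix of world coordinates (mm, voxel centres).
#' @export
voxel_to_world <- function(vol, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  sweep(sweep(ijk, 2, vol$spacing, `*`), 2, vol$origin, `+`)
}

#' Physical extent of the grid
#'
#' Lower and upper world coordinates of the outermost voxel centres.
#' @noRd
volume_corners <- function(vol) {
  lo <- vol$origin
  hi <- vol$origin + (dim(vol$data) - 1L) * vol$spacing
  as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                        z = c(lo[3], hi[3])))
}

#' Threshold segmentation of bone
#'
#' Produces the binary bone mask used by every downstream stage: a voxel is
#' bone iff its intensity is `>= threshold`. The original study segmented each
#' scapula from its CT scan; on the CT-like phantoms here (bone about 700,
#' background about -1000) the default threshold of 150 separates the classes
#' with a wide margin.
#'
#' @param volume a [voxel_volume()].
#' @param threshold finite intensity threshold.
#' @return An object of class `bone_mask`: binary `data` plus the source
#'   geometry and `threshold_used`.
#' @export
segment_bone <- function(volume, threshold = 150) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (!is.finite(threshold)) stop("threshold must be finite")
  m <- array(as.integer(volume$data >= threshold), dim(volume$data))
  structure(list(data = m, spacing = volume$spacing, origin = volume$origin,
                 threshold_used = threshold, name = volume$name),
            class = "bone_mask")
}

#' @export
print.bone_mask <- function(x, ...) {
  cat(sprintf("<bone_mask> %s voxels, %d foreground (threshold %g)\n",
              paste(dim(x$data), collapse = "x"), sum(x$data),
              x$threshold_used))
  invisible(x)
}

#' Euclidean distance map of a bone mask
#'
#' Exact Euclidean distance (mm) from every inside voxel centre to the nearest
#' outside voxel centre, respecting anisotropic spacing; 0 on background. This
#' is the geometric backbone of the cortical-breach criterion: a screw of
#' radius r fits at a point iff the map there is at least r.
#'
#' @param mask a [segment_bone()] result.
#' @return An object of class `distance_map` (fields `data`, `spacing`,
#'   `origin`).
#' @export
distance_map <- function(mask) {
  stopifnot(inherits(mask, "bone_mask"))
  d <- .edt_cpp(as.integer(mask$data), dim(mask$data), mask$spacing)
  structure(list(data = d, spacing = mask$spacing, origin = mask$origin,
                 name = mask$name),
            class = "distance_map")
}

#' @export
print.distance_map <- function(x, ...) {
  cat(sprintf("<distance_map> %s voxels, max clearance %.2f mm\n",
              paste(dim(x$data), collapse = "x"), max(x$data)))
  invisible(x)
}

#' Trilinear sampling of a gridded field at world points
#'
#' @param vol a `voxel_volume`, `bone_mask` or `distance_map`.
#' @param pts n x 3 matrix of world coordinates (mm).
#' @param outside value returned beyond the grid (default 0).
#' @return numeric vector of length n.
#' @export
sample_field <- function(vol, pts, outside = 0) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  .trilinear_cpp(as.numeric(vol$data), dim(vol$data), vol$spacing,
                 vol$origin, pts, outside)
}
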