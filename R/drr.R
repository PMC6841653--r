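#' Intensity-to-attenuation mapping
#'
#' Linear water-scaled mapping from HU-like intensity to linear attenuation:
#' `mu = mu_water * max(intensity + 1000, 0) / 1000`, so air-like background
#' (-1000) attenuates nothing and water (0) attenuates `mu_water` per mm.
#'
#' @param intensity numeric array or vector of HU-like values.
#' @param mu_water attenuation of water, mm^-1 (default 0.02).
#' @return attenuation values, same shape as `intensity`.
#' @export
attenuation <- function(intensity, mu_water = 0.02) {
  mu_water * pmax(intensity + 1000, 0) / 1000
}

#' Render a digitally reconstructed radiograph
#'
#' Parallel-beam DRR: each detector pixel holds the line integral of linear
#' attenuation along the ray through that pixel in the view direction, sampled
#' midpoint-wise at `geom$ray_step` with trilinear interpolation (zero
#' attenuation outside the volume). This mimics a fluoroscopic exposure of the
#' volume at the chosen C-arm orientation.
#'
#' @param volume a [voxel_volume()].
#' @param view a [view_state()].
#' @param geom a [projection_geometry()].
#' @param mu_water water attenuation for the intensity mapping, mm^-1.
#' @return A `drr_image`: matrix `data` (`n_v` rows x `n_u` columns, line
#'   integral units: mm^-1 * mm), `pixel_spacing`, `units`, and provenance.
#' @examples
#' sph <- make_sphere_phantom(radius = 10, spacing = 1)
#' img <- render_drr(sph, view_state(), projection_geometry(33, 33, 1, 0.5))
#' max(img$data)  # ~ 0.02 * 20
#' @export
render_drr <- function(volume, view, geom = projection_geometry(),
                       mu_water = 0.02) {
  stopifnot(inherits(volume, "voxel_volume"), inherits(view, "view_state"),
            inherits(geom, "projection_geometry"))
  mu <- attenuation(volume$data, mu_water)
  ax <- detector_axes(view)
  tr <- ray_t_range(volume, view, geom)
  img <- .drr_cpp(as.numeric(mu), dim(volume$data), volume$spacing,
                  volume$origin, view$detector_center, ax$u, ax$v, ax$dir,
                  geom$n_u, geom$n_v, geom$pixel_spacing, geom$ray_step,
                  tr[1], as.integer(tr[2]), 0L)
  drr_image(img, geom$pixel_spacing, units = "line_integral",
            provenance = list(view = view, geom = geom, mu_water = mu_water))
}

# common t-range (mm) along the view direction covering the volume, shared by
# all pixels because detector offsets are perpendicular to the ray
ray_t_range <- function(volume, view, geom) {
  ax <- detector_axes(view)
  corners <- volume_corners(volume)
  rel <- sweep(corners, 2, view$detector_center, `-`)
  t <- rel %*% ax$dir
  pad <- max(volume$spacing)
  t0 <- min(t) - pad
  nsteps <- ceiling((max(t) + pad - t0) / geom$ray_step)
  c(t0, max(nsteps, 1))
}

drr_image <- function(data, pixel_spacing, units, provenance = NULL) {
  structure(list(data = data, pixel_spacing = pixel_spacing, units = units,
                 provenance = provenance),
            class = "drr_image")
}

#' @export
print.drr_image <- function(x, ...) {
  cat(sprintf("<drr_image> %dx%d px @ %g mm, %s, range [%.4g, %.4g]\n",
              nrow(x$data), ncol(x$data), x$pixel_spacing, x$units,
              min(x$data), max(x$data)))
  invisible(x)
}

#' Window/level display mapping
#'
#' Standard fluoroscopy display transform: values at `level` map to 0.5 and a
#' band of width `window` spans the display range, clamped to `[0, 1]`.
#' Monotone in the input.
#'
#' @param image a `drr_image`.
#' @param window window width (> 0), in the image's units.
#' @param level window centre.
#' @return A `drr_image` with `units = "display"` and values in `[0, 1]`.
#' @export
window_level <- function(image, window, level) {
  stopifnot(inherits(image, "drr_image"))
  if (!is.numeric(window) || window <= 0) stop("window must be > 0")
  d <- pmin(pmax((image$data - (level - window / 2)) / window, 0), 1)
  drr_image(d, image$pixel_spacing, units = "display",
            provenance = image$provenance)
}

#' Silhouette area of an object in a view
#'
#' Area (mm^2) of the projection of an object onto the detector, measured by
#' counting detector pixels whose ray intersects the object. For a
#' [cylinder()] the ray-cylinder intersection is computed analytically
#' (flat-ended); for a `bone_mask` a ray intersects wherever the trilinearly
#' interpolated mask exceeds 0.5. The result carries a `partial` attribute set
#' `TRUE` when the silhouette touches the detector border (object possibly
#' outside the field of view).
#'
#' @param object a [cylinder()] or `bone_mask`.
#' @param view a [view_state()].
#' @param geom a [projection_geometry()].
#' @return silhouette area in mm^2 (attribute `partial`: logical).
#' @export
silhouette_area <- function(object, view, geom = projection_geometry()) {
  ax <- detector_axes(view)
  cu <- (geom$n_u - 1) / 2
  cv <- (geom$n_v - 1) / 2
  if (inherits(object, "cylinder")) {
    iu <- rep(seq_len(geom$n_u) - 1, each = geom$n_v)
    iv <- rep(seq_len(geom$n_v) - 1, times = geom$n_u)
    u <- (iu - cu) * geom$pixel_spacing
    v <- (iv - cv) * geom$pixel_spacing
    p0 <- cbind(view$detector_center[1] + u * ax$u[1] + v * ax$v[1],
                view$detector_center[2] + u * ax$u[2] + v * ax$v[2],
                view$detector_center[3] + u * ax$u[3] + v * ax$v[3])
    hit <- ray_hits_cylinder(p0, ax$dir, object)
    hitmat <- matrix(hit, nrow = geom$n_v)
  } else if (inherits(object, "bone_mask")) {
    tr <- ray_t_range(voxel_volume(object$data + 0,  # reuse geometry fields
                                   object$spacing, object$origin),
                      view, geom)
    mx <- .drr_cpp(as.numeric(object$data), dim(object$data), object$spacing,
                   object$origin, view$detector_center, ax$u, ax$v, ax$dir,
                   geom$n_u, geom$n_v, geom$pixel_spacing, geom$ray_step,
                   tr[1], as.integer(tr[2]), 1L)
    hitmat <- mx >= 0.5
  } else {
    stop("silhouette_area expects a cylinder or a bone_mask")
  }
  area <- sum(hitmat) * geom$pixel_spacing^2
  partial <- any(hitmat[1, ]) || any(hitmat[geom$n_v, ]) ||
    any(hitmat[, 1]) || any(hitmat[, geom$n_u])
  if (partial && area > 0)
    warning("silhouette touches the detector border; object may extend ",
            "outside the field of view")
  structure(area, partial = partial)
}

# TRUE for each ray origin p0 (n x 3, direction d) that intersects the finite
# flat-ended cylinder
ray_hits_cylinder <- function(p0, d, cyl) {
  w <- cyl$axis_dir
  L <- cyl$length
  r <- cyl$radius
  m <- sweep(p0, 2, cyl$entry_point, `-`)
  dw <- sum(d * w)
  dperp <- d - dw * w
  mw <- as.numeric(m %*% w)
  mperp <- m - mw %*% t(w)
  a <- sum(dperp^2)
  cc <- rowSums(mperp^2) - r^2
  hit <- logical(nrow(p0))
  if (a < 1e-12) {
    # ray parallel to the cylinder axis: hits iff inside the radius and the
    # axial span [mw, mw + t*dw] can reach [0, L] (it always can, t is free)
    hit <- cc <= 0
  } else {
    b <- as.numeric(mperp %*% dperp)
    disc <- b^2 - a * cc
    ok <- disc >= 0
    sq <- sqrt(pmax(disc, 0))
    t1 <- (-b - sq) / a
    t2 <- (-b + sq) / a
    s1 <- mw + t1 * dw
    s2 <- mw + t2 * dw
    slo <- pmin(s1, s2)
    shi <- pmax(s1, s2)
    hit <- ok & (shi >= 0) & (slo <= L)
  }
  hit
}

#' Write a display image as PGM or PNG
#'
#' 8-bit export of a windowed DRR (values in `[0, 1]`). PGM (binary P5) needs
#' no extra packages; PNG requires the `png` package.
#'
#' @param image a `drr_image` in display units.
#' @param path output path ending in `.pgm` or `.png`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "drr_image"))
  vals <- pmin(pmax(image$data, 0), 1)
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c("P5", paste(ncol(vals), nrow(vals)), "255"), con)
    writeBin(as.integer(round(t(vals) * 255)), con, size = 1)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("PNG output requires the 'png' package")
    png::writePNG(vals, path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(vals)
    RNifti::pixdim(img) <- rep(image$pixel_spacing, 2)
    RNifti::writeNifti(img, path, datatype = "float")
  } else {
    stop("unsupported image format: '", path, "'")
  }
  invisible(path)
}
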