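#' Virtual screw cylinder
#'
#' The screw is modelled as a finite cylinder: entry point on the bone
#' surface, unit axis direction, radius and length (all mm). Default radius
#' 1.75 mm corresponds to a 3.5 mm cortical screw.
#'
#' @param entry_point 3-vector, mm.
#' @param axis_dir direction (normalised internally).
#' @param radius screw radius, mm (> 0).
#' @param length screw length, mm (> 0).
#' @return An object of class `cylinder`.
#' @export
cylinder <- function(entry_point, axis_dir, radius = 1.75, length = 30) {
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  if (!is.numeric(length) || length <= 0) stop("length must be > 0")
  structure(list(entry_point = as.numeric(entry_point),
                 axis_dir = unit(as.numeric(axis_dir)),
                 radius = radius, length = length),
            class = "cylinder")
}

#' @export
print.cylinder <- function(x, ...) {
  cat(sprintf(
    "<cylinder> entry (%s) mm, dir (%s), radius %.2f mm, length %.1f mm\n",
    paste(sprintf("%.2f", x$entry_point), collapse = ", "),
    paste(sprintf("%.3f", x$axis_dir), collapse = ", "),
    x$radius, x$length))
  invisible(x)
}

#' Place a virtual screw at the crosshair, perpendicular to the viewing plane
#'
#' Reproduces the placement interaction of the simulator: the drilling
#' location is marked with a crosshair on the screen, and the screw cylinder
#' is inserted along the central-ray direction (perpendicular to the viewing
#' plane) starting at the first intersection of the crosshair ray with the
#' bone surface. The entry point is refined to sub-voxel precision by
#' bisection between the last outside and first inside ray sample. A ray that
#' merely grazes the surface (a single inside sample) is not a drillable
#' entry and raises the same error as a miss.
#'
#' @param mask a [segment_bone()] mask.
#' @param view a [view_state()] whose `crosshair` is set.
#' @param radius screw radius, mm.
#' @param length screw length in mm, or `"auto"` to extend to the last exit
#'   of the bone within 100 mm of the entry (screw seated to the far cortex).
#' @return A [cylinder()] with `axis_dir = view_dir(view)`.
#' @export
crosshair_to_cylinder <- function(mask, view, radius = 1.75, length = "auto") {
  stopifnot(inherits(mask, "bone_mask"), inherits(view, "view_state"))
  if (is.null(view$crosshair)) stop("view has no crosshair")
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  ax <- detector_axes(view)
  p0 <- view$detector_center + view$crosshair[1] * ax$u +
    view$crosshair[2] * ax$v
  geom <- projection_geometry(1, 1, 1, 0.5 * min(mask$spacing))
  vol_like <- voxel_volume(mask$data + 0, mask$spacing, mask$origin)
  tr <- ray_t_range(vol_like, view_state(view$rotation, p0), geom)
  ts <- tr[1] + (seq_len(tr[2]) - 0.5) * geom$ray_step
  pts <- cbind(p0[1] + ts * ax$dir[1], p0[2] + ts * ax$dir[2],
               p0[3] + ts * ax$dir[3])
  inside <- sample_field(mask, pts) >= 0.5
  if (!any(inside)) stop("crosshair ray does not enter the bone mask")
  runs <- rle(inside)
  if (sum(inside) == 1 && all(runs$lengths[runs$values] == 1))
    stop("crosshair ray does not enter the bone mask (tangential graze)")
  first_in <- which(inside)[1]
  inside_fun <- function(t) {
    p <- matrix(p0 + t * ax$dir, ncol = 3)
    sample_field(mask, p) >= 0.5
  }
  t_entry <- if (first_in == 1) ts[1] else
    bisect_boundary(inside_fun, ts[first_in - 1], ts[first_in])
  entry <- p0 + t_entry * ax$dir

  if (identical(length, "auto")) {
    horizon <- ts <= t_entry + 100
    last_in <- max(which(inside & horizon))
    t_exit <- if (last_in == base::length(ts)) ts[last_in] else
      bisect_boundary(function(t) !inside_fun(t), ts[last_in],
                      ts[last_in + 1])
    len <- t_exit - t_entry
  } else {
    if (!is.numeric(length) || length <= 0) stop("length must be > 0 or 'auto'")
    len <- length
  }
  cylinder(entry, ax$dir, radius, len)
}

# bisection between t_out (predicate FALSE) and t_in (TRUE), to < 0.005 mm
bisect_boundary <- function(is_in, t_out, t_in, tol = 0.005) {
  while (abs(t_in - t_out) > tol) {
    mid <- (t_in + t_out) / 2
    if (is_in(mid)) t_in <- mid else t_out <- mid
  }
  (t_in + t_out) / 2
}

#' Sample points along a screw axis
#'
#' Points `entry_point + t * axis_dir` for `t = 0, step, ...` up to and
#' including the screw length (the endpoint is appended when the step does not
#' divide the length exactly).
#'
#' @param cyl a [cylinder()].
#' @param step station spacing, mm (> 0).
#' @return n x 3 matrix of world points.
#' @export
sample_axis <- function(cyl, step = 1) {
  stopifnot(inherits(cyl, "cylinder"))
  if (!is.numeric(step) || step <= 0) stop("step must be > 0")
  t <- seq(0, cyl$length, by = step)
  if (t[length(t)] < cyl$length - 1e-12) t <- c(t, cyl$length)
  cbind(cyl$entry_point[1] + t * cyl$axis_dir[1],
        cyl$entry_point[2] + t * cyl$axis_dir[2],
        cyl$entry_point[3] + t * cyl$axis_dir[3])
}

#' Serialize a cylinder as JSON
#'
#' @param cyl a [cylinder()].
#' @param path optional file path.
#' @return JSON string, or `path` invisibly.
#' @export
cylinder_to_json <- function(cyl, path = NULL) {
  js <- jsonlite::toJSON(list(entry_point = cyl$entry_point,
                              axis_dir = cyl$axis_dir,
                              radius_mm = cyl$radius,
                              length_mm = cyl$length),
                         auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname cylinder_to_json
#' @param json JSON string or path from [cylinder_to_json()].
#' @export
cylinder_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  cylinder(obj$entry_point, obj$axis_dir, obj$radius_mm, obj$length_mm)
}
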