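# Quaternion helpers (w, x, y, z convention, unit quaternions only).

quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n < 1e-12) stop("degenerate quaternion")
  q / n
}

quat_from_axis_angle <- function(axis, angle_deg) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation axis must be nonzero")
  axis <- axis / n
  h <- angle_deg * pi / 360
  c(cos(h), sin(h) * axis)
}

quat_multiply <- function(p, q) {
  c(p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1])
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

matrix_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, s / 4, (R[1, 2] + R[2, 1]) / s,
             (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, s / 4,
             (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, s / 4)
    }
  }
  quat_normalize(q)
}

#' C-arm view state
#'
#' Rigid view of the virtual fluoroscope: a unit quaternion mapping the
#' canonical view axes to world axes, the detector centre (mm, world), and an
#' optional crosshair in detector-plane coordinates (mm, `(0,0)` at the
#' detector centre). Derived quantities: `view_dir` (central ray direction) is
#' the rotated `+z`, and the detector plane is spanned by the rotated `+x`
#' (`detector_u`) and `+y` (`detector_v`); the three always form a
#' right-handed orthonormal triad.
#'
#' @param rotation unit quaternion `c(w, x, y, z)`.
#' @param detector_center world position of the detector centre, mm.
#' @param crosshair optional `c(u, v)` mm on the detector plane.
#' @return An object of class `view_state`.
#' @examples
#' v <- view_state()
#' view_dir(v)
#' @export
view_state <- function(rotation = c(1, 0, 0, 0), detector_center = c(0, 0, 0),
                       crosshair = NULL) {
  rotation <- as.numeric(rotation)
  if (length(rotation) != 4 || abs(sqrt(sum(rotation^2)) - 1) > 1e-9)
    stop("rotation must be a unit quaternion c(w, x, y, z)")
  if (!is.null(crosshair)) {
    crosshair <- as.numeric(crosshair)
    if (length(crosshair) != 2) stop("crosshair must be c(u, v) in mm")
  }
  structure(list(rotation = rotation,
                 detector_center = as.numeric(detector_center),
                 crosshair = crosshair),
            class = "view_state")
}

#' @rdname view_state
#' @param view a `view_state`.
#' @export
view_dir <- function(view) as.numeric(quat_to_matrix(view$rotation) %*% c(0, 0, 1))

#' @rdname view_state
#' @export
detector_axes <- function(view) {
  R <- quat_to_matrix(view$rotation)
  list(u = as.numeric(R %*% c(1, 0, 0)), v = as.numeric(R %*% c(0, 1, 0)),
       dir = as.numeric(R %*% c(0, 0, 1)))
}

#' @export
print.view_state <- function(x, ...) {
  d <- view_dir(x)
  cat(sprintf("<view_state> dir (%.3f, %.3f, %.3f), detector centre (%s) mm%s\n",
              d[1], d[2], d[3],
              paste(format(x$detector_center, digits = 4), collapse = ", "),
              if (is.null(x$crosshair)) "" else
                sprintf(", crosshair (%.2f, %.2f) mm", x$crosshair[1],
                        x$crosshair[2])))
  invisible(x)
}

#' Rotate a view about a world axis
#'
#' Composes an axis-angle rotation with the current view rotation, mimicking
#' tilting the C-arm; used to sweep viewing angles (e.g. cephalad tilt until
#' the tunnel projects as an oval).
#'
#' @param view a [view_state()].
#' @param axis nonzero rotation axis (world frame).
#' @param angle_deg rotation angle in degrees.
#' @return The rotated `view_state` (crosshair and detector centre preserved).
#' @export
rotate_view <- function(view, axis, angle_deg) {
  q <- quat_from_axis_angle(axis, angle_deg)
  view_state(quat_normalize(quat_multiply(q, view$rotation)),
             view$detector_center, view$crosshair)
}

#' A view looking along a given direction
#'
#' Builds the deterministic view whose central ray is `dir`: `detector_u` is
#' the normalised projection of world `+x` onto the detector plane (world `+y`
#' if `dir` is parallel to `x`), and `detector_v` completes the right-handed
#' triad.
#'
#' @param dir desired view direction (normalised internally).
#' @param detector_center detector centre, mm.
#' @param crosshair optional crosshair `c(u, v)` mm.
#' @return A [view_state()].
#' @export
view_along <- function(dir, detector_center = c(0, 0, 0), crosshair = NULL) {
  w <- unit(as.numeric(dir))
  ref <- c(1, 0, 0)
  u <- ref - sum(ref * w) * w
  if (sqrt(sum(u^2)) < 1e-6) {
    ref <- c(0, 1, 0)
    u <- ref - sum(ref * w) * w
  }
  u <- unit(u)
  v <- cross3(w, u)
  view_state(matrix_to_quat(cbind(u, v, w)), detector_center, crosshair)
}

#' Projection geometry
#'
#' Detector raster and ray sampling for parallel-beam projection.
#'
#' @param n_u,n_v detector pixel counts (columns, rows).
#' @param pixel_spacing detector pixel size, mm.
#' @param ray_step ray sampling step, mm.
#' @return An object of class `projection_geometry`.
#' @export
projection_geometry <- function(n_u = 256, n_v = 256, pixel_spacing = 1,
                                ray_step = 0.5) {
  if (n_u < 1 || n_v < 1) stop("detector must have at least one pixel")
  if (pixel_spacing <= 0 || ray_step <= 0)
    stop("pixel_spacing and ray_step must be > 0")
  structure(list(n_u = as.integer(n_u), n_v = as.integer(n_v),
                 pixel_spacing = pixel_spacing, ray_step = ray_step),
            class = "projection_geometry")
}

#' Serialize / restore a view as JSON
#'
#' @param view a [view_state()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (or `path` invisibly).
#' @export
view_to_json <- function(view, path = NULL) {
  obj <- list(quaternion = setNames(as.list(view$rotation),
                                    c("w", "x", "y", "z")),
              detector_center = view$detector_center,
              crosshair = view$crosshair)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname view_to_json
#' @param json JSON string or file path produced by [view_to_json()].
#' @export
view_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  q <- unlist(obj$quaternion)[c("w", "x", "y", "z")]
  view_state(as.numeric(q), as.numeric(obj$detector_center),
             if (is.null(obj$crosshair)) NULL else as.numeric(obj$crosshair))
}
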