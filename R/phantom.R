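#' Phantom ground truth
#'
#' Bundle describing the known optimal corridor of a synthetic phantom:
#' the axis (start point + unit direction), the clearance profile along it,
#' a region-label volume (0 background, 1 stalk, 2 base, 3 neck, 4 blade,
#' 5 glenoid) and the glenoid plane normal. The ground-truth axis always lies
#' in the glenoid plane, so a screw along it is parallel to the glenoid by
#' construction.
#'
#' @noRd
phantom_truth <- function(axis_point, axis_dir, radius_profile, region_labels,
                          glenoid_plane_normal) {
  axis_dir <- as.numeric(axis_dir)
  if (abs(sqrt(sum(axis_dir^2)) - 1) > 1e-9) stop("axis_dir must be unit norm")
  glenoid_plane_normal <- as.numeric(glenoid_plane_normal)
  if (abs(sqrt(sum(glenoid_plane_normal^2)) - 1) > 1e-9)
    stop("glenoid_plane_normal must be unit norm")
  if (any(radius_profile$clearance <= 0)) stop("all clearances must be > 0")
  structure(list(axis_point = as.numeric(axis_point), axis_dir = axis_dir,
                 radius_profile = radius_profile,
                 region_labels = region_labels,
                 glenoid_plane_normal = glenoid_plane_normal),
            class = "phantom_truth")
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero vector where a direction was required")
  v / n
}

# any unit vector perpendicular to d (deterministic choice)
perp_unit <- function(d) {
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit(ref - sum(ref * d) * d)
}

# distance from each grid point to the segment a -> a + L*d (matrix of points)
dist_to_segment <- function(pts, a, d, L) {
  rel <- sweep(pts, 2, a, `-`)
  t <- pmin(pmax(rel %*% d, 0), L)
  sqrt(rowSums((rel - t %*% t(d))^2))
}

# world-coordinate grid covering [lo, hi] with the given spacing; returns
# list(pts = n x 3 matrix, dim, origin)
make_grid <- function(lo, hi, spacing) {
  nx <- ceiling((hi - lo) / spacing) + 1L
  origin <- lo
  ax <- lapply(1:3, function(i) origin[i] + (seq_len(nx[i]) - 1) * spacing[i])
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  list(pts = pts, dim = as.integer(nx), origin = origin)
}

#' Capsule phantom with known corridor
#'
#' A solid capsule (cylinder of the given radius and length with hemispherical
#' end caps) voxelized onto an isotropic grid, standing in for the tunnel of a
#' macerated scapula. The ground truth records the exact axis, a constant
#' clearance profile, thirds-of-axis region labels (stalk/base/neck) and a
#' glenoid plane containing the axis.
#'
#' @param radius capsule radius, mm (> 0).
#' @param length cylindrical length between cap centres, mm (> 0).
#' @param axis_dir unit axis direction (normalised internally).
#' @param spacing isotropic voxel spacing, mm.
#' @param bone_value,bg_value intensities inside/outside the capsule.
#' @param margin padding beyond the capsule surface, mm.
#' @return `list(volume = voxel_volume, truth = phantom ground truth)`.
#' @examples
#' ph <- make_capsule_phantom(radius = 5, length = 40, spacing = 1)
#' range(ph$volume$data)
#' @export
make_capsule_phantom <- function(radius, length, axis_dir = c(0, 0, 1),
                                 spacing = 1, bone_value = 700,
                                 bg_value = -1000, margin = NULL) {
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  if (!is.numeric(length) || length <= 0) stop("length must be > 0")
  if (!is.numeric(spacing) || spacing <= 0) stop("spacing must be > 0")
  d <- unit(as.numeric(axis_dir))
  margin <- margin %||% (3 * spacing)
  half <- length / 2
  ctr <- c(0, 0, 0)
  a <- ctr - half * d            # start cap centre (stalk end)
  ext <- radius + margin
  lo <- pmin(a, ctr + half * d) - ext
  hi <- pmax(a, ctr + half * d) + ext
  g <- make_grid(lo, hi, rep(spacing, 3))
  dist <- dist_to_segment(g$pts, a, d, length)
  inside <- dist <= radius
  vol <- array(ifelse(inside, bone_value, bg_value), g$dim)
  volume <- voxel_volume(vol, rep(spacing, 3), g$origin, name = "capsule")

  # thirds of the axis -> stalk/base/neck labels inside the capsule
  t <- pmin(pmax(sweep(g$pts, 2, a, `-`) %*% d, 0), length)
  lab <- integer(nrow(g$pts))
  lab[inside] <- 1L + pmin(2L, floor(3 * t[inside] / length))
  labels <- voxel_volume(array(as.numeric(lab), g$dim), rep(spacing, 3),
                         g$origin, name = "capsule-labels")
  prof <- data.frame(station = seq(0, length, by = spacing),
                     clearance = radius)
  truth <- phantom_truth(a, d, prof, labels, perp_unit(d))
  list(volume = volume, truth = truth)
}

#' Sphere phantom
#'
#' Homogeneous solid sphere with an edge-antialiased boundary: voxel values
#' ramp linearly from `bone_value` to `bg_value` across one voxel at the
#' surface, so line integrals through the rendered sphere reproduce analytic
#' chord lengths closely even at 1 mm spacing.
#'
#' @param radius sphere radius, mm.
#' @param spacing isotropic voxel spacing, mm.
#' @param bone_value,bg_value interior / exterior intensity.
#' @param margin padding beyond the surface, mm.
#' @return A [voxel_volume()] centred at the world origin.
#' @export
make_sphere_phantom <- function(radius, spacing = 1, bone_value = 0,
                                bg_value = -1000, margin = NULL) {
  if (radius <= 0 || spacing <= 0) stop("radius and spacing must be > 0")
  margin <- margin %||% (3 * spacing)
  ext <- radius + margin
  g <- make_grid(rep(-ext, 3), rep(ext, 3), rep(spacing, 3))
  r <- sqrt(rowSums(g$pts^2))
  occ <- pmin(pmax((radius - r) / spacing + 0.5, 0), 1)
  vol <- array(bg_value + occ * (bone_value - bg_value), g$dim)
  voxel_volume(vol, rep(spacing, 3), g$origin, name = "sphere")
}

#' Scapula-analog phantom
#'
#' A connected bone phantom emulating the geometry that matters for coracoid
#' screw planning: an oblique corridor capsule (labelled stalk/base/neck in
#' thirds along its axis), a thin blade plate attached at the neck end, and a
#' glenoid disc whose plane contains the corridor axis (so the ground-truth
#' screw is exactly parallel to the glenoid plane). The seed applies small
#' random perturbations to radius, obliquity and blade thickness so that
#' every phantom is distinct while the ground truth stays exact.
#'
#' @param corridor_radius corridor radius, mm (default 4).
#' @param corridor_length corridor length, mm (default 35).
#' @param obliquity_deg length-2 tilt (degrees) of the corridor axis away from
#'   +z, about the world x and y axes.
#' @param blade_thickness blade plate thickness, mm.
#' @param glenoid_radius glenoid disc radius, mm.
#' @param spacing isotropic voxel spacing, mm.
#' @param bone_value,bg_value intensities.
#' @param seed integer; perturbs radius (±5%), obliquity (±3 deg) and blade
#'   thickness (±10%) reproducibly.
#' @return `list(volume, truth)` as for [make_capsule_phantom()].
#' @export
make_scapula_analog <- function(corridor_radius = 4, corridor_length = 35,
                                obliquity_deg = c(20, 10),
                                blade_thickness = 4, glenoid_radius = 12,
                                spacing = 1, bone_value = 700,
                                bg_value = -1000, seed = 1) {
  if (corridor_radius <= 0 || corridor_length <= 0 || spacing <= 0)
    stop("corridor radius/length and spacing must be > 0")
  pert <- with_seed(seed, list(r = runif(1, 0.95, 1.05),
                               ang = runif(2, -3, 3),
                               bt = runif(1, 0.9, 1.1)))
  r <- corridor_radius * pert$r
  L <- corridor_length
  ang <- (obliquity_deg + pert$ang) * pi / 180
  bt <- blade_thickness * pert$bt

  # corridor direction: +z tilted about x then y
  d <- c(0, 0, 1)
  rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
              c(0, sin(ang[1]), cos(ang[1])))
  ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0),
              c(-sin(ang[2]), 0, cos(ang[2])))
  d <- unit(as.numeric(ry %*% rx %*% d))

  a <- c(0, 0, 0)                 # stalk tip (entry end)
  p1 <- a + L * d                 # neck end
  nb <- perp_unit(d)              # blade normal, perpendicular to corridor
  u <- unit(cross3(d, nb))        # in-blade direction perpendicular to axis
  # the blade attaches just beyond the neck end and spreads sideways; it must
  # not engulf the corridor axis, or it would host competing screw corridors
  blade_half <- 18
  blade_c <- p1 + (blade_half - 2) * d
  glen_c <- p1 + 8 * d + (glenoid_radius + 6) * u
  glen_half_th <- 3

  prim_lo <- pmin(a, p1, blade_c - blade_half, glen_c - glenoid_radius) -
    (r + 6)
  prim_hi <- pmax(a, p1, blade_c + blade_half, glen_c + glenoid_radius) +
    (r + 6)
  g <- make_grid(prim_lo, prim_hi, rep(spacing, 3))
  pts <- g$pts

  corr <- dist_to_segment(pts, a, d, L) <= r
  relb <- sweep(pts, 2, blade_c, `-`)
  blade <- abs(relb %*% nb) <= bt / 2 &
    abs(relb %*% d) <= blade_half & abs(relb %*% u) <= blade_half
  relg <- sweep(pts, 2, glen_c, `-`)
  gn <- relg %*% nb
  glen <- abs(gn) <= glen_half_th &
    sqrt(rowSums((relg - gn %*% t(nb))^2)) <= glenoid_radius

  bone <- corr | blade | glen
  vol <- array(ifelse(bone, bone_value, bg_value), g$dim)
  mask_arr <- array(as.integer(bone), g$dim)
  if (.n_components_cpp(as.integer(mask_arr), g$dim) != 1L)
    stop("scapula-analog construction produced a disconnected mask")

  t <- pmin(pmax(sweep(pts, 2, a, `-`) %*% d, 0), L)
  lab <- integer(nrow(pts))
  lab[blade] <- 4L
  lab[glen] <- 5L
  lab[corr] <- 1L + pmin(2L, floor(3 * t[corr] / L))
  labels <- voxel_volume(array(as.numeric(lab), g$dim), rep(spacing, 3),
                         g$origin, name = "scapula-analog-labels")
  prof <- data.frame(station = seq(0, L, by = spacing), clearance = r)
  truth <- phantom_truth(a, d, prof, labels, nb)
  list(volume = voxel_volume(vol, rep(spacing, 3), g$origin,
                             name = "scapula-analog"),
       truth = truth)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
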