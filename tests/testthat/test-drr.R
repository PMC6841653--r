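sphere_geom <- function(n = 33, ps = 1, step = 0.5)
  projection_geometry(n, n, ps, step)

cross3_test <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

test_that("DRR line integrals reproduce analytic chord lengths", {
  sph <- make_sphere_phantom(radius = 20, spacing = 1)  # water-like interior
  g <- sphere_geom(41)
  img <- render_drr(sph, view_state(), g)
  centre <- img$data[21, 21]
  expect_lt(abs(centre - 0.02 * 40) / (0.02 * 40), 0.01)
  # a ray well off the sphere integrates to zero
  expect_equal(img$data[1, 1], 0)
  # off-centre chord at lateral offset 10: 2*sqrt(R^2 - 100)
  chord <- 2 * sqrt(400 - 100)
  expect_lt(abs(img$data[21, 31] - 0.02 * chord) / (0.02 * chord), 0.015)
})

test_that("rendering is linear in attenuation", {
  sph <- make_sphere_phantom(radius = 10, spacing = 1)
  g <- sphere_geom(25)
  v <- view_state()
  i1 <- render_drr(sph, v, g, mu_water = 0.02)
  i3 <- render_drr(sph, v, g, mu_water = 0.06)
  expect_equal(i3$data, 3 * i1$data, tolerance = 1e-12)
})

test_that("halving the ray step changes the sphere image by < 0.5% RMS", {
  sph <- make_sphere_phantom(radius = 20, spacing = 1)
  v <- view_state()
  a <- render_drr(sph, v, sphere_geom(41, 1, 0.5))$data
  b <- render_drr(sph, v, sphere_geom(41, 1, 0.25))$data
  rms <- sqrt(mean((a - b)^2)) / sqrt(mean(a^2))
  expect_lt(rms, 0.005)
})

test_that("sphere projections are rotation invariant", {
  sph <- make_sphere_phantom(radius = 15, spacing = 1)
  g <- sphere_geom(41)
  set.seed(3)
  imgs <- lapply(1:2, function(i) {
    v <- view_state()
    v <- rotate_view(v, rnorm(3), runif(1, 0, 180))
    v <- rotate_view(v, rnorm(3), runif(1, 0, 180))
    render_drr(sph, v, g)$data
  })
  rms <- sqrt(mean((imgs[[1]] - imgs[[2]])^2)) / sqrt(mean(imgs[[1]]^2))
  expect_lt(rms, 0.02)
})

test_that("window/level is the standard clamped affine display map", {
  img <- structure(list(data = matrix(c(-1, 0, 0.25, 0.5, 0.75, 1, 2, 0.5),
                                      2), pixel_spacing = 1,
                        units = "line_integral", provenance = NULL),
                   class = "drr_image")
  w <- window_level(img, window = 1, level = 0.5)
  expect_equal(w$data[2, 2], 0.5)           # value at level -> 0.5
  expect_equal(w$data[1, 1], 0)             # below level - window/2 -> 0
  expect_equal(w$data[1, 2], 0.25)
  expect_equal(w$data[1, 4], 1)             # above level + window/2 -> 1
  # idempotent on [0,1] with window 1, level 0.5
  expect_equal(window_level(w, 1, 0.5)$data, w$data)
  expect_error(window_level(img, -1, 0), "window")
  # monotone in the input
  x <- sort(runif(50, -2, 2))
  imgx <- structure(list(data = matrix(x, 1), pixel_spacing = 1,
                         units = "line_integral", provenance = NULL),
                    class = "drr_image")
  expect_true(all(diff(window_level(imgx, 0.8, 0.3)$data[1, ]) >= 0))
})

test_that("view rotations compose correctly and preserve the triad", {
  v0 <- view_state()
  expect_equal(rotate_view(v0, c(0, 1, 0), 0)$rotation, v0$rotation)
  v <- v0
  for (i in 1:4) v <- rotate_view(v, c(1, 2, 3), 90)
  expect_equal(abs(sum(v$rotation * v0$rotation)), 1, tolerance = 1e-9)
  v <- rotate_view(rotate_view(v0, c(1, 0, 0), 30), c(1, 0, 0), -30)
  expect_equal(abs(sum(v$rotation * v0$rotation)), 1, tolerance = 1e-9)
  expect_error(rotate_view(v0, c(0, 0, 0), 10), "nonzero")
  set.seed(5)
  for (i in 1:20) {
    v <- rotate_view(v0, rnorm(3), runif(1, -360, 360))
    ax <- detector_axes(v)
    expect_lt(abs(sum(ax$u * ax$v)), 1e-9)
    expect_lt(abs(sum(ax$u * ax$dir)), 1e-9)
    expect_lt(abs(sum(ax$v * ax$dir)), 1e-9)
    expect_equal(cross3_test(ax$u, ax$v), ax$dir, tolerance = 1e-9)
    expect_equal(sqrt(sum(v$rotation^2)), 1, tolerance = 1e-9)
  }
})

test_that("view JSON serialization roundtrips", {
  v <- rotate_view(view_state(detector_center = c(1, 2, 3),
                              crosshair = c(4, -5)), c(1, 1, 0), 37)
  b <- view_from_json(view_to_json(v))
  expect_equal(b$rotation, v$rotation, tolerance = 1e-12)
  expect_equal(b$detector_center, v$detector_center)
  expect_equal(b$crosshair, v$crosshair)
})

test_that("silhouette areas match analytic projections of a cylinder", {
  # entry shifted off the pixel lattice: pixel centres exactly on the surface
  # would make the count convention-dependent
  cyl <- cylinder(c(0.123, 0.287, -15.113), c(0, 0, 1), radius = 3,
                  length = 30)
  g <- projection_geometry(101, 101, 0.5, 0.5)
  axial <- as.numeric(silhouette_area(cyl, view_state(), g))
  expect_lt(abs(axial - pi * 9), 2 * 0.5^2 + 0.3)
  side <- as.numeric(silhouette_area(cyl, view_along(c(1, 0, 0)), g))
  expect_lt(abs(side - 180) / 180, 0.03)
  # empty mask projects to zero area
  empty <- structure(list(data = array(0L, c(4, 4, 4)), spacing = c(1, 1, 1),
                          origin = c(0, 0, 0), threshold_used = 0),
                     class = "bone_mask")
  expect_equal(as.numeric(silhouette_area(empty, view_state(),
                                          projection_geometry(16, 16, 1, 0.5))),
               0)
})

test_that("silhouette area is minimal at the axis-aligned view", {
  cyl <- cylinder(c(0.123, 0.287, -15.113), c(0, 0, 1), radius = 3,
                  length = 30)
  g <- projection_geometry(121, 121, 0.5, 0.5)
  angles <- seq(0, 90, by = 7.5)
  areas <- vapply(angles, function(a)
    as.numeric(silhouette_area(cyl, rotate_view(view_state(), c(1, 0, 0), a),
                               g)), 0)
  expect_equal(which.min(areas), 1L)
  # monotone growth away from the axis until the near-degenerate 90 deg limit
  grow <- areas[angles <= 75]
  expect_true(all(diff(grow) > -0.5^2))
  # analytic check: pi r^2 cos(t) + 2 r L sin(t)
  ana <- pi * 9 * cos(angles * pi / 180) + 180 * sin(angles * pi / 180)
  expect_lt(max(abs(areas - ana) / pmax(ana, 1)), 0.05)
})

test_that("a mask silhouette flags partial field-of-view coverage", {
  ph <- make_capsule_phantom(4, 30, spacing = 1)
  m <- segment_bone(ph$volume)
  small <- projection_geometry(6, 6, 1, 0.5)
  expect_warning(a <- silhouette_area(m, view_state(), small), "field of view")
  expect_true(attr(a, "partial"))
})
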