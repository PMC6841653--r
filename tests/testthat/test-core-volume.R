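test_that("MetaImage and NIfTI roundtrips preserve data, spacing and origin", {
  set.seed(11)
  vol <- voxel_volume(array(rnorm(16^3), c(16, 16, 16)),
                      spacing = c(0.45, 0.45, 0.45), origin = c(1, -2, 3.5),
                      name = "rt")
  for (ext in c("mhd", "nii", "nii.gz")) {
    path <- file.path(withr::local_tempdir(), paste0("vol.", ext))
    write_volume(vol, path)
    back <- read_volume(path)
    expect_equal(back$data, vol$data, tolerance = 1e-6)
    expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
    expect_equal(back$origin, vol$origin, tolerance = 1e-5)
  }
  # integer data survive exactly through the MET_SHORT path
  ivol <- voxel_volume(array(sample(-1000:700, 4^3, TRUE), c(4, 4, 4)))
  p <- file.path(withr::local_tempdir(), "ivol.mhd")
  write_volume(ivol, p)
  expect_identical(read_volume(p)$data, ivol$data + 0)
})

test_that("NIfTI output is readable by an independent reader", {
  skip_if_not_installed("oro.nifti")
  vol <- voxel_volume(array(seq_len(8^3) / 10, c(8, 8, 8)),
                      spacing = c(0.45, 0.45, 0.45))
  path <- file.path(withr::local_tempdir(), "x.nii.gz")
  write_volume(vol, path)
  ind <- oro.nifti::readNIfTI(path, reorient = FALSE)
  expect_equal(array(ind@.Data, c(8, 8, 8)), vol$data, tolerance = 1e-5)
  expect_equal(oro.nifti::pixdim(ind)[2:4], c(0.45, 0.45, 0.45),
               tolerance = 1e-6)
})

test_that("format and header errors are reported with context", {
  expect_error(read_volume("vol.txt"), "unsupported volume format")
  expect_error(write_volume(voxel_volume(array(0, c(2, 2, 2))), "a.xyz"),
               "unsupported")
  bad <- file.path(withr::local_tempdir(), "bad.mhd")
  writeLines(c("ObjectType = Image", "ElementType = MET_SHORT",
               "ElementDataFile = bad.raw"), bad)
  expect_error(read_volume(bad), "DimSize")
  expect_error(voxel_volume(array(0, c(2, 2, 2)), spacing = c(1, 0, 1)),
               "spacing")
  expect_error(voxel_volume(array(0, c(4, 4))), "3-D")
})

test_that("threshold segmentation matches analytic phantom volumes", {
  u <- voxel_volume(array(100, c(4, 4, 4)))
  expect_true(all(segment_bone(u, 50)$data == 1))
  expect_true(all(segment_bone(u, 200)$data == 0))
  expect_error(segment_bone(u, Inf), "finite")

  analytic <- function(r, L) pi * r^2 * L + 4 / 3 * pi * r^3
  for (ax in list(c(0, 0, 1), c(1, 1, 1) / sqrt(3))) {
    ph <- make_capsule_phantom(5, 40, axis_dir = ax, spacing = 1)
    m <- segment_bone(ph$volume, 150)
    expect_lt(abs(sum(m$data) - analytic(5, 40)) / analytic(5, 40), 0.05)
  }
  ph <- make_capsule_phantom(5, 20, spacing = 0.25)
  m <- segment_bone(ph$volume, 150)
  expect_lt(abs(sum(m$data) * 0.25^3 - analytic(5, 20)) / analytic(5, 20),
            0.01)
})

test_that("segmentation is stable across a write/read roundtrip", {
  ph <- make_capsule_phantom(4, 15, spacing = 1)
  p <- file.path(withr::local_tempdir(), "caps.mhd")
  write_volume(ph$volume, p)
  expect_identical(segment_bone(read_volume(p))$data,
                   segment_bone(ph$volume)$data)
})

test_that("distance transform is exact against the brute-force oracle", {
  set.seed(7)
  for (d in list(c(6, 6, 6), c(10, 8, 5), c(12, 12, 12))) {
    arr <- array(as.integer(runif(prod(d)) < 0.55), d)
    sp <- c(1, 1, 1)
    m <- structure(list(data = arr, spacing = sp, origin = c(0, 0, 0),
                        threshold_used = 0), class = "bone_mask")
    expect_equal(distance_map(m)$data, brute_force_edt(arr, sp),
                 tolerance = 1e-6)
  }
  # anisotropic spacing is respected (physical mm, not voxels)
  arr <- array(as.integer(runif(7^3) < 0.5), c(7, 7, 7))
  sp <- c(0.5, 1, 2)
  m <- structure(list(data = arr, spacing = sp, origin = c(0, 0, 0),
                      threshold_used = 0), class = "bone_mask")
  expect_equal(distance_map(m)$data, brute_force_edt(arr, sp),
               tolerance = 1e-6)
})

test_that("distance map of simple solids matches geometry", {
  sph <- make_sphere_phantom(10, spacing = 1, bone_value = 700)
  dm <- distance_map(segment_bone(sph, 150))
  expect_lt(abs(max(dm$data) - 10), 1)
  ctr <- matrix(c(0, 0, 0), 1)
  expect_equal(sample_field(dm, ctr), max(dm$data), tolerance = 1e-6)

  empty <- structure(list(data = array(0L, c(4, 4, 4)), spacing = c(1, 1, 1),
                          origin = c(0, 0, 0), threshold_used = 0),
                     class = "bone_mask")
  expect_true(all(distance_map(empty)$data == 0))

  ph <- make_capsule_phantom(5, 40, spacing = 1)
  dm <- distance_map(segment_bone(ph$volume))
  mid <- ph$truth$axis_point + 20 * ph$truth$axis_dir
  cl <- sample_field(dm, matrix(mid, 1))
  expect_gte(cl, 4)
  expect_lte(cl, 5.2)  # voxel-centre quantization can only overshoot by ~sqrt(3)/2
})

test_that("phantom constructors validate their parameters", {
  expect_error(make_capsule_phantom(0, 10), "radius")
  expect_error(make_capsule_phantom(5, -1), "length")
  expect_error(make_capsule_phantom(5, 10, spacing = 0), "spacing")
  expect_error(make_scapula_analog(corridor_radius = -1), "radius")
})

test_that("scapula analog satisfies its construction guarantees", {
  fx <- analog_fixture(seed = 1)
  tr <- fx$ph$truth
  # clearance >= corridor radius - 1 voxel at every stalk/base station
  st <- tr$radius_profile$station
  sb <- st[st <= 2 / 3 * max(st)]
  pts <- cbind(tr$axis_point[1] + sb * tr$axis_dir[1],
               tr$axis_point[2] + sb * tr$axis_dir[2],
               tr$axis_point[3] + sb * tr$axis_dir[3])
  cl <- sample_field(fx$dmap, pts)
  expect_true(all(cl >= tr$radius_profile$clearance[1] - 1))
  # screw along the axis is exactly parallel to the glenoid plane
  expect_lt(abs(90 - acos(abs(sum(tr$axis_dir * tr$glenoid_plane_normal))) *
                  180 / pi), 0.1)
  # distinct seeds give distinct but valid phantoms
  fx2 <- analog_fixture(seed = 2)
  expect_false(identical(fx$ph$volume$data, fx2$ph$volume$data))
  for (f in list(fx, fx2)) {
    t2 <- f$ph$truth
    expect_equal(sqrt(sum(t2$axis_dir^2)), 1, tolerance = 1e-9)
    expect_true(all(t2$radius_profile$clearance > 0))
    expect_identical(dim(t2$region_labels$data), dim(f$ph$volume$data))
    expect_setequal(unique(as.vector(t2$region_labels$data)), 0:5)
  }
})
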