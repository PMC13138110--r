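sphere_at_center <- function(radius_mm, dim = c(40, 40, 40), voxel_mm = 4,
                             intensity = 1, background = 0.05,
                             psf_fwhm_mm = 0, noise_cv = 0) {
  ctr <- dim * voxel_mm / 2
  phantom_spec(dim = dim, voxel_mm = voxel_mm, background = background,
               spheres = list(list(center_mm = ctr, radius_mm = radius_mm,
                                   intensity = intensity)),
               psf_fwhm_mm = psf_fwhm_mm, noise_cv = noise_cv)
}

center_box <- function(dim, half = 12) {
  mid <- round(dim / 2)
  list(lo = pmax(mid - half, 1), hi = pmin(mid + half, dim))
}

test_that("noiseless unblurred phantom holds exactly background and sphere values", {
  spec <- sphere_at_center(30)
  img <- generate_phantom(spec, seed = 1)
  expect_setequal(unique(as.vector(img)), c(0.05, 1))
  # two identical seeds give identical maps (and noiseless maps are
  # seed-independent)
  expect_identical(img, generate_phantom(spec, seed = 1))
  spec_n <- sphere_at_center(30, noise_cv = 0.05)
  expect_identical(generate_phantom(spec_n, 7), generate_phantom(spec_n, 7))
  expect_false(identical(generate_phantom(spec_n, 7), generate_phantom(spec_n, 8)))
})

test_that("the PSF blur conserves total excess signal to 1%", {
  for (fwhm in c(8, 16)) {
    sharp <- generate_phantom(sphere_at_center(30), seed = 1)
    blurred <- generate_phantom(sphere_at_center(30, psf_fwhm_mm = fwhm), seed = 1)
    excess_sharp <- sum(sharp - 0.05)
    excess_blur <- sum(blurred - 0.05)
    expect_equal(excess_blur / excess_sharp, 1, tolerance = 0.01)
  }
})

test_that("spheres outside the grid are rejected at configuration", {
  expect_error(phantom_spec(spheres = list(list(center_mm = c(10, 10, 10),
                                                radius_mm = 20,
                                                intensity = 1))),
               class = "lutadose_config_error")
  expect_error(phantom_spec(background = 0.2,
                            spheres = list(list(center_mm = c(90, 90, 90),
                                                radius_mm = 10,
                                                intensity = 0.1))),
               "intensity", class = "lutadose_config_error")
})

test_that("segmentation of a noiseless unblurred sphere is exact and idempotent", {
  spec <- sphere_at_center(30)
  img <- generate_phantom(spec, seed = 1)
  seg <- adaptive_threshold_segment(img, center_box(spec$dim))
  expect_true(seg$converged)
  # volume equals the voxelized sphere exactly
  expect_equal(seg$volume_cm3, sum(img == 1) * (4 / 10)^3)
  seg2 <- adaptive_threshold_segment(img, center_box(spec$dim))
  expect_identical(seg2$mask, seg$mask)
})

test_that("segmentation of a blurred sphere recovers volume within 15%", {
  radius <- 24
  spec <- sphere_at_center(radius, psf_fwhm_mm = radius / 2)
  img <- generate_phantom(spec, seed = 1)
  seg <- adaptive_threshold_segment(img, center_box(spec$dim))
  true_vol <- 4 / 3 * pi * (radius / 10)^3
  expect_equal(seg$volume_cm3, true_vol, tolerance = 0.15)
})

test_that("segmentation output is invariant to global intensity scaling", {
  spec <- sphere_at_center(24, psf_fwhm_mm = 10, noise_cv = 0.03)
  img <- generate_phantom(spec, seed = 5)
  img2 <- img * 12
  attr(img2, "voxel_mm") <- attr(img, "voxel_mm")
  s1 <- adaptive_threshold_segment(img, center_box(spec$dim))
  s2 <- adaptive_threshold_segment(img2, center_box(spec$dim))
  expect_identical(s1$mask, s2$mask)
  expect_equal(s2$threshold, 12 * s1$threshold, tolerance = 1e-9)
})

test_that("recovery curve closed form, bounds and calibration round trip", {
  rc <- recovery_curve(v0 = 12, b = 1)
  expect_equal(recovery_coefficient(rc, 12), 1 - exp(-1))
  expect_gt(recovery_coefficient(rc, 1e6), 1 - 1e-9)
  v <- c(5, 10, 30, 90, 200, 500)
  expect_true(all(diff(recovery_coefficient(rc, v)) > 0))
  expect_error(recovery_coefficient(rc, -2), class = "lutadose_input_error")
  # self-calibration round trip on 6 spheres with mild measurement scatter
  truth <- recovery_curve(v0 = 9, b = 0.8)
  set.seed(17)
  meas <- recovery_coefficient(truth, v) * exp(rnorm(6, 0, 0.01))
  fit <- fit_recovery_curve(v, meas)
  expect_equal(fit$v0, 9, tolerance = 0.10)
  expect_equal(fit$b, 0.8, tolerance = 0.10)
})

test_that("partial-volume correction divides by the recovery coefficient", {
  expect_equal(apply_pvc(2, 0.5), 4)
  expect_equal(apply_pvc(3.7, 1), 3.7)
  expect_gte(apply_pvc(1.3, 0.8), 1.3)
  expect_error(apply_pvc(1, 0), class = "lutadose_input_error")
  expect_error(apply_pvc(1, 1.2), class = "lutadose_input_error")
})

test_that("PVC round trip: corrected sphere means unbiased, uncorrected biased low and worse for small spheres", {
  # as in physical phantom calibration, the measurement ROI is the known
  # sphere geometry; only the blur degrades the measured mean
  fwhm <- 16
  radii <- c(14, 18, 24, 32, 40)   # 11 to 268 cm^3
  meas <- vapply(radii, function(r) {
    blurred <- generate_phantom(sphere_at_center(r, dim = c(44, 44, 44),
                                                 psf_fwhm_mm = fwhm), seed = 2)
    sharp <- generate_phantom(sphere_at_center(r, dim = c(44, 44, 44)), seed = 2)
    roi <- sharp == 1
    mean(blurred[roi] - 0.05) / (1 - 0.05)
  }, numeric(1))
  vols <- 4 / 3 * pi * (radii / 10)^3
  # uncorrected means are biased low, monotonically worse for small spheres
  expect_true(all(meas < 1))
  expect_true(all(diff(meas) > 0))
  curve <- fit_recovery_curve(vols, meas)
  corrected <- apply_pvc(meas, recovery_coefficient(curve, vols))
  expect_true(all(abs(corrected - 1) < 0.05))
})

test_that("phantom maps and masks survive a NIfTI round trip", {
  spec <- sphere_at_center(20, dim = c(24, 24, 24), noise_cv = 0.05)
  img <- generate_phantom(spec, seed = 3)
  path <- tempfile(fileext = ".nii.gz")
  write_phantom_nifti(img, path)
  back <- read_phantom_nifti(path)
  expect_equal(dim(back), dim(img))
  expect_equal(as.vector(back), as.vector(img), tolerance = 1e-6)
  expect_equal(attr(back, "voxel_mm"), 4)
  unlink(path)
})
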