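#' Specification of a synthetic spherical-insert dose-rate phantom
#'
#' A simplified digital stand-in for the physical phantom measurements that
#' underlie recovery-coefficient partial-volume correction: uniform
#' background, spherical inserts of known volume and intensity, Gaussian
#' blur emulating the scanner point-spread function, and multiplicative
#' noise.
#'
#' World coordinates are in mm with the origin at the grid corner; the
#' center of the voxel with (1-based) index `i` along an axis lies at
#' `(i - 0.5) * voxel_mm`.
#'
#' @param dim integer length-3 grid shape, voxels.
#' @param voxel_mm isotropic voxel edge length, mm.
#' @param background background level, Gy/h (>= 0).
#' @param spheres list of spheres, each a list with `center_mm` (length-3),
#'   `radius_mm` (> 0) and `intensity` (> background), Gy/h.
#' @param psf_fwhm_mm Gaussian PSF full width at half maximum, mm (>= 0).
#' @param noise_cv fractional multiplicative noise (>= 0).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(48, 48, 48), voxel_mm = 4, background = 0.01,
                         spheres = list(), psf_fwhm_mm = 0, noise_cv = 0) {
  if (length(dim) != 3 || any(dim < 1))
    lutadose_config_error("dim must be a length-3 positive integer vector")
  if (voxel_mm <= 0) lutadose_config_error("voxel_mm must be positive")
  if (background < 0) lutadose_config_error("background must be non-negative")
  if (psf_fwhm_mm < 0) lutadose_config_error("psf_fwhm_mm must be non-negative")
  if (noise_cv < 0) lutadose_config_error("noise_cv must be non-negative")
  extent <- dim * voxel_mm
  for (s in spheres) {
    if (s$radius_mm <= 0) lutadose_config_error("sphere radius must be positive")
    if (s$intensity <= background)
      lutadose_config_error("sphere intensity must exceed the background")
    if (any(s$center_mm - s$radius_mm < 0) ||
        any(s$center_mm + s$radius_mm > extent))
      lutadose_config_error("sphere extends outside the phantom grid")
  }
  structure(list(dim = as.integer(dim), voxel_mm = voxel_mm,
                 background = background, spheres = spheres,
                 psf_fwhm_mm = psf_fwhm_mm, noise_cv = noise_cv),
            class = "phantom_spec")
}

# Separable Gaussian convolution along one array dimension, zero-padded.
convolve_dim <- function(a, kernel, dim_i) {
  n <- dim(a)[dim_i]
  half <- (length(kernel) - 1) / 2
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    idx <- j + seq(-half, half)
    ok <- idx >= 1 & idx <= n
    K[cbind(idx[ok], j)] <- kernel[ok]
  }
  perm <- c(dim_i, setdiff(1:3, dim_i))
  ap <- aperm(a, perm)
  out <- K %*% matrix(ap, n)
  dim(out) <- dim(ap)
  aperm(out, order(perm))
}

gaussian_blur3d <- function(a, fwhm_mm, voxel_mm) {
  if (fwhm_mm == 0) return(a)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  half <- max(1L, ceiling(4 * sigma))
  kernel <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  kernel <- kernel / sum(kernel)
  for (d in 1:3) a <- convolve_dim(a, kernel, d)
  a
}

#' Generate a synthetic phantom dose-rate map
#'
#' Builds the background + spheres map, convolves the sphere excess with a
#' normalized Gaussian PSF (so total excess signal is conserved), and
#' applies multiplicative lognormal noise. Deterministic for a fixed seed.
#'
#' @param spec a [phantom_spec()].
#' @param seed RNG seed for the noise.
#' @return 3D numeric array with attributes `voxel_mm` and `spec`.
#' @export
generate_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(seed)
  d <- spec$dim
  centers_mm <- lapply(1:3, function(k) (seq_len(d[k]) - 0.5) * spec$voxel_mm)
  excess <- array(0, d)
  for (s in spec$spheres) {
    dx2 <- (centers_mm[[1]] - s$center_mm[1])^2
    dy2 <- (centers_mm[[2]] - s$center_mm[2])^2
    dz2 <- (centers_mm[[3]] - s$center_mm[3])^2
    r2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    excess[r2 <= s$radius_mm^2] <- s$intensity - spec$background
  }
  img <- spec$background + gaussian_blur3d(excess, spec$psf_fwhm_mm,
                                           spec$voxel_mm)
  if (spec$noise_cv > 0) {
    sdlog <- sqrt(log(1 + spec$noise_cv^2))
    img <- img * array(rlnorm(length(img), -sdlog^2 / 2, sdlog), d)
  }
  attr(img, "voxel_mm") <- spec$voxel_mm
  attr(img, "spec") <- spec
  img
}

#' Adaptive-threshold segmentation within a seed box
#'
#' Fixed-point fractional-threshold contouring: starting from a rough
#' oversized box drawn around the lesion, the threshold is iterated as
#' \deqn{T_{i+1} = f \cdot \mathrm{mean}(\mathrm{map~inside~mask}_i) + (1-f) \cdot \mathrm{background}}
#' with the mask at each step the set of in-box voxels at or above the
#' current threshold, until the mask no longer changes (iteration cap 100,
#' flagged if reached). The initial threshold uses the in-box maximum in
#' place of the mask mean.
#'
#' @param map 3D array from [generate_phantom()] (or any dose-rate map with
#'   a `voxel_mm` attribute).
#' @param seed_box list with integer vectors `lo` and `hi`: 1-based
#'   inclusive voxel index ranges of the oversized bounding box; must
#'   contain the lesion peak.
#' @param f threshold fraction in (0, 1\] applied to the
#'   background-corrected mask mean. The default 0.5 places the converged
#'   contour at the half-level edge crossing, which for symmetric PSF blur
#'   of a sharp-edged object coincides with the true boundary.
#' @param background background level estimate; default: median of the map
#'   outside the seed box.
#' @param max_iter iteration cap.
#' @return object of class `segmentation_mask`: list with `mask` (logical
#'   array), `volume_cm3`, `threshold`, `iterations`, `converged`.
#' @export
adaptive_threshold_segment <- function(map, seed_box, f = 0.5,
                                       background = NULL, max_iter = 100) {
  d <- dim(map)
  lo <- seed_box$lo; hi <- seed_box$hi
  if (any(lo < 1) || any(hi > d) || any(lo > hi))
    lutadose_input_error("seed_box must lie within the map")
  voxel_mm <- attr(map, "voxel_mm")
  if (is.null(voxel_mm)) lutadose_input_error("map lacks a voxel_mm attribute")
  in_box <- array(FALSE, d)
  in_box[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  if (is.null(background)) background <- median(map[!in_box])
  box_vals <- map[in_box]
  thr <- f * max(box_vals) + (1 - f) * background
  mask <- in_box & (map >= thr)
  if (!any(mask))
    lutadose_fit_error("adaptive threshold produced an empty initial mask")
  converged <- FALSE
  iterations <- 0L
  for (i in seq_len(max_iter)) {
    iterations <- i
    thr_new <- f * mean(map[mask]) + (1 - f) * background
    mask_new <- in_box & (map >= thr_new)
    if (!any(mask_new))
      lutadose_fit_error("adaptive threshold emptied the mask")
    thr <- thr_new
    if (identical(mask_new, mask)) { converged <- TRUE; mask <- mask_new; break }
    mask <- mask_new
  }
  structure(list(mask = mask,
                 volume_cm3 = sum(mask) * (voxel_mm / 10)^3,
                 threshold = thr, iterations = iterations,
                 converged = converged),
            class = "segmentation_mask")
}

#' Recovery-coefficient curve for partial-volume correction
#'
#' Parametric saturating curve \eqn{RC(V) = 1 - e^{-(V/v_0)^b}}: strictly
#' increasing in volume, bounded by 1, approaching 1 for objects much larger
#' than the scanner resolution.
#'
#' @param v0 volume scale, cm^3 (> 0).
#' @param b shape exponent (> 0).
#' @return object of class `recovery_curve`.
#' @export
recovery_curve <- function(v0, b) {
  if (v0 <= 0 || b <= 0)
    lutadose_config_error("recovery curve parameters v0 and b must be positive")
  structure(list(v0 = v0, b = b), class = "recovery_curve")
}

#' Recovery coefficient at a given structure volume
#'
#' @param curve a [recovery_curve()].
#' @param volume_cm3 structure volume(s), cm^3 (> 0).
#' @return recovery coefficient(s) in (0, 1\].
#' @export
recovery_coefficient <- function(curve, volume_cm3) {
  if (any(volume_cm3 <= 0))
    lutadose_input_error("volume must be positive")
  1 - exp(-(volume_cm3 / curve$v0)^curve$b)
}

#' Fit a recovery curve to (volume, measured/true) calibration pairs
#'
#' Linearises \eqn{\log(-\log(1 - RC)) = b(\log V - \log v_0)} for the
#' starting values, then refines by least squares on the RC scale.
#'
#' @param volume_cm3 sphere volumes, cm^3.
#' @param rc_measured measured-to-true intensity ratios (clipped into
#'   (0, 1) for the fit).
#' @return a [recovery_curve()].
#' @export
fit_recovery_curve <- function(volume_cm3, rc_measured) {
  if (length(volume_cm3) < 2)
    lutadose_input_error("at least 2 calibration spheres are required")
  rc <- pmin(pmax(rc_measured, 1e-6), 1 - 1e-6)
  z <- log(-log(1 - rc))
  lf <- stats::lm(z ~ log(volume_cm3))
  b0 <- max(unname(coef(lf)[2]), 1e-3)
  v00 <- exp(-unname(coef(lf)[1]) / b0)
  fit <- minpack.lm::nls.lm(
    par = c(log(v00), log(b0)),
    fn = function(th) (1 - exp(-(volume_cm3 / exp(th[1]))^exp(th[2]))) - rc,
    control = minpack.lm::nls.lm.control(maxiter = 500))
  recovery_curve(exp(fit$par[1]), exp(fit$par[2]))
}

#' Apply recovery-coefficient partial-volume correction
#'
#' Divides a measured structure-mean dose rate (or dose) by the recovery
#' coefficient; the corrected value is never smaller than the measured one.
#'
#' @param measured measured structure-mean value.
#' @param rc recovery coefficient in (0, 1\].
#' @return corrected value `measured / rc`.
#' @export
apply_pvc <- function(measured, rc) {
  if (any(rc <= 0 | rc > 1))
    lutadose_input_error("recovery coefficient must lie in (0, 1]")
  measured / rc
}

#' Write / read a phantom map or mask as NIfTI
#'
#' @param img 3D array with a `voxel_mm` attribute (masks are written as
#'   0/1 integers).
#' @param path output `.nii`/`.nii.gz` path.
#' @export
write_phantom_nifti <- function(img, path) {
  voxel <- attr(img, "voxel_mm")
  if (is.null(voxel)) voxel <- 1
  arr <- array(as.numeric(img), dim(img))
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- rep(voxel, 3)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname write_phantom_nifti
#' @export
read_phantom_nifti <- function(path) {
  nii <- RNifti::readNifti(path)
  img <- array(as.numeric(nii), dim(nii))
  attr(img, "voxel_mm") <- RNifti::pixdim(nii)[1]
  img
}
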