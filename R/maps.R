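#' Derived T1w/T2w contrast maps
#'
#' Two voxel-wise contrasts derived from co-registered T1w and T2w volumes:
#'
#' \describe{
#'   \item{ratio map}{`T1wn / (T2wn + alpha)`, where each input is first
#'     intensity-normalized so that the peak (fitted Gaussian mean) of its
#'     within-brain-mask intensities sits at 0.5: voxel values are divided by
#'     twice the fitted mean and clamped below at 0.}
#'   \item{combined map}{`(T1w - b*T2w) / (T1w + b*T2w)` on the raw images,
#'     where the scaling factor `b` (beta) is the ratio of mean ventricle
#'     intensity in T1w to that in T2w. Bounded in \[-1, 1\] wherever both
#'     images are nonnegative and the denominator is positive; the ventricle
#'     mean of the map is 0 by construction of beta.}
#' }
#'
#' @name maps
NULL

#' Fit a Gaussian to within-mask intensities
#'
#' Maximum-likelihood fit of a single Gaussian (sample mean, ML standard
#' deviation) to the voxel intensities inside a mask — the normalization
#' reference for [normalize_intensity()]. An optional robust mode restricts
#' the fit to a central quantile range of the intensities, which resists heavy
#' tumor-intensity tails.
#'
#' @param volume 3D numeric array.
#' @param mask binary 3D array on the same grid; must be nonempty.
#' @param min_voxels minimum number of within-mask voxels required (default
#'   1000).
#' @param robust if `TRUE`, trim to `trim_quantiles` before fitting.
#' @param trim_quantiles lower/upper quantiles kept in robust mode.
#' @return Object of class `normalization_fit` with fields `mu`, `sigma`,
#'   `n_voxels`.
#' @export
fit_intensity_gaussian <- function(volume, mask, min_voxels = 1000,
                                   robust = FALSE,
                                   trim_quantiles = c(0.01, 0.99)) {
  check_same_grid(volume, mask, "volume and mask")
  vals <- volume[mask != 0]
  if (length(vals) == 0) stop("mask is empty", call. = FALSE)
  if (robust) {
    q <- quantile(vals, trim_quantiles, names = FALSE)
    vals <- vals[vals >= q[1] & vals <= q[2]]
  }
  n <- length(vals)
  if (n < min_voxels) {
    stop(sprintf("too few voxels for Gaussian fit: %d < minimum %d",
                 n, min_voxels), call. = FALSE)
  }
  mu <- mean(vals)
  sigma <- sqrt(mean((vals - mu)^2))
  if (sigma <= 0) {
    stop("zero variance: within-mask intensities are constant", call. = FALSE)
  }
  structure(list(mu = mu, sigma = sigma, n_voxels = n),
            class = "normalization_fit")
}

#' @export
print.normalization_fit <- function(x, ...) {
  cat(sprintf("Gaussian intensity fit: mu = %.4g, sigma = %.4g (n = %d voxels)\n",
              x$mu, x$sigma, x$n_voxels))
  invisible(x)
}

#' Normalize intensities to peak 0.5
#'
#' Divides every voxel by twice the fitted Gaussian mean, so the intensity
#' peak of the reference tissue moves to 0.5, and clamps the result below at
#' 0 (MRI magnitude images are nonnegative; any negative input maps to 0).
#'
#' @param volume 3D numeric array.
#' @param fit a `normalization_fit` with `mu > 0`.
#' @return Normalized volume on the same grid.
#' @export
normalize_intensity <- function(volume, fit) {
  stopifnot(inherits(fit, "normalization_fit"))
  if (fit$mu <= 0) stop("normalization requires a positive fitted mean", call. = FALSE)
  out <- pmax(volume / (2 * fit$mu), 0)
  out <- array(out, dim = dim(volume))
  attr(out, "pixdim") <- attr(volume, "pixdim")
  out
}

#' Compute the T1w/T2w ratio map
#'
#' Voxel-wise `t1n / (t2n + alpha)` inside the brain mask, 0 outside. Inputs
#' are expected to be [normalize_intensity()] outputs of co-registered images.
#' The offset `alpha` guards the division; its default 1e-6 is negligible at
#' the normalized intensity scale (peak 0.5).
#'
#' @param t1n,t2n normalized T1w and T2w volumes.
#' @param brain_mask binary 3D array.
#' @param alpha nonnegative denominator offset (default 1e-6).
#' @return Ratio map volume; 0 outside the mask.
#' @export
compute_ratio_map <- function(t1n, t2n, brain_mask, alpha = 1e-6) {
  check_same_grid(t1n, t2n, "T1w and T2w volumes")
  check_same_grid(t1n, brain_mask, "volume and brain mask")
  if (alpha < 0) stop("alpha must be nonnegative", call. = FALSE)
  inside <- brain_mask != 0
  if (alpha == 0 && any(t2n[inside] == 0)) {
    stop("division by zero: alpha = 0 with zero-valued T2w voxels inside the mask",
         call. = FALSE)
  }
  out <- array(0, dim = dim(t1n))
  out[inside] <- t1n[inside] / (t2n[inside] + alpha)
  attr(out, "pixdim") <- attr(t1n, "pixdim")
  out
}

#' Compute the ventricle scaling factor beta
#'
#' Beta is the mean ventricle intensity of the raw (un-normalized) T1w image
#' divided by the same in the raw T2w image; it balances the two contrasts in
#' the combined map so that the map's ventricle mean is 0.
#'
#' @param t1w,t2w raw co-registered volumes.
#' @param ventricle_mask binary 3D array, nonempty.
#' @return Object of class `scaling_factor` with fields `beta`,
#'   `t1_ventricle_mean`, `t2_ventricle_mean`.
#' @export
compute_beta <- function(t1w, t2w, ventricle_mask) {
  check_same_grid(t1w, t2w, "T1w and T2w volumes")
  check_same_grid(t1w, ventricle_mask, "volume and ventricle mask")
  if (!any(ventricle_mask != 0)) stop("ventricle mask is empty", call. = FALSE)
  m1 <- masked_mean(t1w, ventricle_mask)
  m2 <- masked_mean(t2w, ventricle_mask)
  if (m2 == 0) stop("zero T2w ventricle mean: beta undefined", call. = FALSE)
  structure(list(beta = m1 / m2, t1_ventricle_mean = m1, t2_ventricle_mean = m2),
            class = "scaling_factor")
}

#' @export
print.scaling_factor <- function(x, ...) {
  cat(sprintf("beta = %.6g (ventricle means: T1w %.4g / T2w %.4g)\n",
              x$beta, x$t1_ventricle_mean, x$t2_ventricle_mean))
  invisible(x)
}

#' Compute the combined T1w-T2w map
#'
#' Voxel-wise `(t1w - beta*t2w) / (t1w + beta*t2w)` inside the brain mask, 0
#' outside. Zero-denominator voxels (both images 0, typically background
#' included in a loose mask) are set to 0 in-band and counted in the
#' `"n_zero_denominator"` attribute so they can be surfaced in QC output.
#'
#' @param t1w,t2w raw co-registered volumes.
#' @param sf a `scaling_factor` from [compute_beta()], or a positive number.
#' @param brain_mask binary 3D array.
#' @return Combined map volume with attribute `n_zero_denominator`.
#' @export
compute_combined_map <- function(t1w, t2w, sf, brain_mask) {
  check_same_grid(t1w, t2w, "T1w and T2w volumes")
  check_same_grid(t1w, brain_mask, "volume and brain mask")
  beta <- if (inherits(sf, "scaling_factor")) sf$beta else as.numeric(sf)
  if (!is.finite(beta) || beta <= 0) stop("beta must be positive", call. = FALSE)
  inside <- brain_mask != 0
  num <- t1w[inside] - beta * t2w[inside]
  den <- t1w[inside] + beta * t2w[inside]
  zero_den <- den == 0
  vals <- numeric(length(num))
  vals[!zero_den] <- num[!zero_den] / den[!zero_den]
  out <- array(0, dim = dim(t1w))
  out[inside] <- vals
  attr(out, "pixdim") <- attr(t1w, "pixdim")
  attr(out, "n_zero_denominator") <- sum(zero_den)
  out
}

#' Build the input channel stack for a model configuration
#'
#' Channel order is fixed and documented as (T1w, T1w-CE, T2w, T2-FLAIR),
#' with the derived map appended as channel 5 for the augmented
#' configurations:
#' \describe{
#'   \item{baseline}{the four structural channels only;}
#'   \item{ratio}{plus the T1w/T2w ratio map (normalization fitted within the
#'     case's brain mask);}
#'   \item{combined}{plus the combined map (beta from the case's ventricle
#'     mask).}
#' }
#'
#' @param case a `phantom_case` (or any list with `channels`, `brain_mask`,
#'   `ventricle_mask` fields).
#' @param configuration one of `"baseline"`, `"ratio"`, `"combined"`.
#' @param alpha ratio-map denominator offset.
#' @param min_voxels minimum brain-mask voxels for the normalization fit.
#' @return Named list of volumes; the QC parameters of the map stage (fit
#'   means/SDs, beta, zero-denominator count) are attached as attribute
#'   `"qc"` for the augmented configurations.
#' @export
build_channel_stack <- function(case, configuration = c("baseline", "ratio", "combined"),
                                alpha = 1e-6, min_voxels = 1000) {
  configuration <- match.arg(configuration)
  stack <- list(t1w = case$channels$t1w, t1ce = case$channels$t1ce,
                t2w = case$channels$t2w, flair = case$channels$flair)
  if (configuration == "baseline") return(stack)
  if (configuration == "ratio") {
    fit1 <- fit_intensity_gaussian(stack$t1w, case$brain_mask, min_voxels = min_voxels)
    fit2 <- fit_intensity_gaussian(stack$t2w, case$brain_mask, min_voxels = min_voxels)
    t1n <- normalize_intensity(stack$t1w, fit1)
    t2n <- normalize_intensity(stack$t2w, fit2)
    stack$ratio <- compute_ratio_map(t1n, t2n, case$brain_mask, alpha = alpha)
    attr(stack, "qc") <- list(mu_t1 = fit1$mu, sigma_t1 = fit1$sigma,
                              mu_t2 = fit2$mu, sigma_t2 = fit2$sigma)
  } else {
    sf <- compute_beta(stack$t1w, stack$t2w, case$ventricle_mask)
    map <- compute_combined_map(stack$t1w, stack$t2w, sf, case$brain_mask)
    stack$combined <- map
    attr(stack, "qc") <- list(beta = sf$beta,
                              n_zero_denominator = attr(map, "n_zero_denominator"))
  }
  stack
}
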