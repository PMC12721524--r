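test_that("the Gaussian fit recovers known simulation parameters", {
  set.seed(42)
  d <- c(50L, 50L, 50L)
  vol <- array(rnorm(prod(d), 600, 60), dim = d)
  mask <- array(1L, dim = d)
  fit <- fit_intensity_gaussian(vol, mask)
  expect_equal(fit$mu, 600, tolerance = 2 / 600)
  expect_equal(fit$sigma, 60, tolerance = 2 / 60)
  expect_equal(fit$n_voxels, prod(d))
})

test_that("degenerate fits are rejected", {
  d <- c(16L, 16L, 16L)
  mask <- array(1L, dim = d)
  expect_error(fit_intensity_gaussian(array(7, dim = d), mask), "variance")
  small_mask <- array(0L, dim = d)
  small_mask[1:10] <- 1L
  expect_error(fit_intensity_gaussian(array(rnorm(prod(d)), dim = d), small_mask),
               "too few voxels")
  expect_error(fit_intensity_gaussian(array(rnorm(prod(d)), dim = d),
                                      array(0L, dim = d)), "empty")
})

test_that("normalization maps the peak to 0.5 and clamps below at 0", {
  fit <- structure(list(mu = 600, sigma = 60, n_voxels = 5000),
                   class = "normalization_fit")
  vol <- array(c(600, -5, 0, 1200), dim = c(4, 1, 1))
  out <- normalize_intensity(vol, fit)
  expect_equal(out[1, 1, 1], 0.5)   # voxel at the fitted mean
  expect_equal(out[2, 1, 1], 0)     # negative input clamps to 0
  expect_equal(out[3, 1, 1], 0)
  expect_equal(out[4, 1, 1], 1)

  # re-fitting after normalization recovers peak 0.5 (idempotence in the limit)
  set.seed(7)
  d <- c(48L, 48L, 48L)
  vol <- array(rnorm(prod(d), 600, 60), dim = d)
  mask <- array(1L, dim = d)
  n1 <- normalize_intensity(vol, fit_intensity_gaussian(vol, mask))
  refit <- fit_intensity_gaussian(n1, mask)
  expect_equal(refit$mu, 0.5, tolerance = 0.01 / 0.5)
  n2 <- normalize_intensity(n1, refit)
  expect_equal(fit_intensity_gaussian(n2, mask)$mu, 0.5, tolerance = 0.01 / 0.5)
})

test_that("ratio map arithmetic, masking and guards are correct", {
  d <- c(2L, 1L, 1L)
  mask <- array(1L, dim = d)
  t1 <- array(c(0.5, 0.6), dim = d)
  t2 <- array(c(0.5, 0.2), dim = d)
  expect_equal(compute_ratio_map(t1, t2, mask, alpha = 0)[1, 1, 1], 1)
  expect_equal(compute_ratio_map(t1, t2, mask, alpha = 0.1)[2, 1, 1], 2)

  # outside the mask the map is 0
  mask0 <- array(c(1L, 0L), dim = d)
  expect_equal(compute_ratio_map(t1, t2, mask0, alpha = 0)[2, 1, 1], 0)

  t2z <- array(c(0.5, 0), dim = d)
  expect_error(compute_ratio_map(t1, t2z, mask, alpha = 0), "division by zero")
  expect_error(compute_ratio_map(t1, t2, mask, alpha = -1), "nonnegative")
})

test_that("ratio map equals the voxel-loop oracle and is scale invariant", {
  set.seed(101)
  for (trial in 1:20) {
    d <- rep(sample(8:16, 1), 3)
    t1 <- array(runif(prod(d), 0.1, 1), dim = d)
    t2 <- array(runif(prod(d), 0.1, 1), dim = d)
    mask <- array(as.integer(runif(prod(d)) < 0.8), dim = d)
    alpha <- sample(c(0, 1e-6, 0.1), 1)
    got <- compute_ratio_map(t1, t2, mask, alpha = alpha)
    expect_equal(as.vector(got), as.vector(oracle_ratio_map(t1, t2, mask, alpha)))
  }

  # multiplying both raw inputs by c > 0 leaves the normalized ratio unchanged
  set.seed(5)
  d <- c(24L, 24L, 24L)
  mask <- array(1L, dim = d)
  t1 <- array(rnorm(prod(d), 600, 50), dim = d)
  t2 <- array(rnorm(prod(d), 400, 40), dim = d)
  ratio_of <- function(a, b) {
    an <- normalize_intensity(a, fit_intensity_gaussian(a, mask))
    bn <- normalize_intensity(b, fit_intensity_gaussian(b, mask))
    compute_ratio_map(an, bn, mask, alpha = 0)
  }
  r1 <- ratio_of(t1, t2)
  r2 <- ratio_of(t1 * 3.7, t2 * 3.7)
  expect_equal(as.vector(r1), as.vector(r2), tolerance = 1e-12)
})

test_that("beta is the ratio of raw ventricle means", {
  d <- c(4L, 4L, 4L)
  vm <- array(0L, dim = d); vm[1:8] <- 1L
  t1 <- array(100, dim = d)
  t2 <- array(400, dim = d)
  sf <- compute_beta(t1, t2, vm)
  expect_equal(sf$beta, 0.25)
  expect_identical(sf$beta, sf$t1_ventricle_mean / sf$t2_ventricle_mean)
  expect_equal(compute_beta(t2, t2, vm)$beta, 1)
  expect_error(compute_beta(t1, t2, array(0L, dim = d)), "empty")
  expect_error(compute_beta(t1, array(0, dim = d), vm), "zero T2w")
})

test_that("combined map arithmetic, bounds and antisymmetry hold", {
  d <- c(2L, 1L, 1L)
  mask <- array(1L, dim = d)
  t1 <- array(c(2, 3), dim = d)
  t2 <- array(c(1, 1), dim = d)
  out <- compute_combined_map(t1, t2, 2, mask)   # t1 = beta*t2 at voxel 1
  expect_equal(out[1, 1, 1], 0)
  out2 <- compute_combined_map(t1, t2, 1, mask)
  expect_equal(out2[2, 1, 1], 0.5)               # (3-1)/(3+1)

  set.seed(77)
  for (trial in 1:10) {
    dd <- rep(sample(8:16, 1), 3)
    a <- array(runif(prod(dd), 0, 5), dim = dd)
    b <- array(runif(prod(dd), 0.1, 5), dim = dd)
    m <- array(as.integer(runif(prod(dd)) < 0.9), dim = dd)
    beta <- runif(1, 0.2, 3)
    got <- compute_combined_map(a, b, beta, m)
    expect_equal(as.vector(got), as.vector(oracle_combined_map(a, b, beta, m)))
    expect_true(all(got >= -1 & got <= 1))
    # swapping the roles of t1w and beta*t2w negates the map
    neg <- compute_combined_map(beta * b, a / 1, 1, m)
    expect_equal(as.vector(neg), -as.vector(got), tolerance = 1e-12)
  }

  # zero denominators are handled in-band and counted
  z1 <- array(0, dim = d)
  outz <- compute_combined_map(z1, z1, 1, mask)
  expect_equal(as.vector(outz), c(0, 0))
  expect_equal(attr(outz, "n_zero_denominator"), 2)
})

test_that("a shared multiplicative bias field cancels out of the combined map", {
  spec_flat <- small_spec(noise_sd = 0, bias_field_amplitude = 0, seed = 19)
  spec_bias <- small_spec(noise_sd = 0, bias_field_amplitude = 0.4, seed = 19)
  a <- generate_case(spec_flat, 1)
  b <- generate_case(spec_bias, 1)
  expect_identical(a$labels, b$labels)  # geometry unaffected by the field
  map_a <- compute_combined_map(a$channels$t1w, a$channels$t2w,
                                compute_beta(a$channels$t1w, a$channels$t2w, a$ventricle_mask),
                                a$brain_mask)
  map_b <- compute_combined_map(b$channels$t1w, b$channels$t2w,
                                compute_beta(b$channels$t1w, b$channels$t2w, b$ventricle_mask),
                                b$brain_mask)
  expect_equal(as.vector(map_b), as.vector(map_a), tolerance = 1e-12)
})

test_that("channel stacks have the documented order and length", {
  cs <- generate_case(small_spec(seed = 23), 1)
  base <- build_channel_stack(cs, "baseline")
  expect_identical(names(base), c("t1w", "t1ce", "t2w", "flair"))
  ratio <- build_channel_stack(cs, "ratio")
  expect_length(ratio, 5)
  expect_identical(names(ratio)[5], "ratio")
  comb <- build_channel_stack(cs, "combined")
  expect_length(comb, 5)
  expect_identical(names(comb)[5], "combined")
  expect_error(build_channel_stack(cs, "bogus"))

  # channel 5 equals the directly computed maps
  f1 <- fit_intensity_gaussian(cs$channels$t1w, cs$brain_mask)
  f2 <- fit_intensity_gaussian(cs$channels$t2w, cs$brain_mask)
  expect_identical(as.vector(ratio$ratio),
                   as.vector(compute_ratio_map(normalize_intensity(cs$channels$t1w, f1),
                                               normalize_intensity(cs$channels$t2w, f2),
                                               cs$brain_mask, alpha = 1e-6)))
  sf <- compute_beta(cs$channels$t1w, cs$channels$t2w, cs$ventricle_mask)
  expect_identical(as.vector(comb$combined),
                   as.vector(compute_combined_map(cs$channels$t1w, cs$channels$t2w,
                                                  sf, cs$brain_mask)))
  expect_equal(attr(comb, "qc")$beta, sf$beta)
})

test_that("the Otsu fallback mask separates foreground from background", {
  skip_if_not_installed("EBImage")
  cs <- generate_case(small_spec(seed = 31), 1)
  m <- brain_mask_from_otsu(cs$channels$t1w)
  inside <- cs$brain_mask != 0
  expect_gt(mean(m[inside]), 0.95)
  expect_lt(mean(m[!inside]), 0.05)
})
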