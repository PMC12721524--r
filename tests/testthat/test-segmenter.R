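test_that("the classifier recovers noiseless class parameters exactly", {
  d <- c(10L, 10L, 10L)
  labels <- array(0L, dim = d)
  labels[1:300] <- 1L
  labels[301:500] <- 2L
  means <- matrix(c(10, 100,
                    20, 200,
                    30, 300,
                    40, 400,
                    50, 500), nrow = 5, byrow = TRUE)  # classes 0..4, 2 channels
  case <- make_constant_case(labels, means)
  model <- fit_voxel_classifier(list(case), subsample = 100, seed = 4)
  expect_equal(nrow(model$means), 5)
  expect_equal(model$means[1, ], means[1, ])
  expect_equal(model$means[2, ], means[2, ])
  expect_equal(model$means[3, ], means[3, ])
  expect_identical(model$absent_classes, c(3L, 4L))
  expect_true(all(!is.finite(model$log_priors[4:5])))
  expect_equal(sum(exp(model$log_priors[1:3])), 1)

  # priors reflect the voxel counts
  expect_equal(exp(model$log_priors[2]), 300 / 1000)
})

test_that("channel-count mismatches are contract violations", {
  d <- c(6L, 6L, 6L)
  labels <- array(0L, dim = d); labels[1:20] <- 1L
  m2 <- matrix(1:10, nrow = 5)
  case2 <- make_constant_case(labels, m2)
  m3 <- matrix(1:15, nrow = 5)
  case3 <- make_constant_case(labels, m3)
  expect_error(fit_voxel_classifier(list(case2, case3)), "channel-count mismatch")
  model <- fit_voxel_classifier(list(case2))
  expect_error(predict_labels(model, case3$channels, case3$brain_mask),
               "channel-count mismatch")
})

test_that("prediction matches the brute-force posterior oracle", {
  set.seed(202)
  for (trial in 1:20) {
    d <- c(8L, 8L, 8L)
    n_ch <- sample(2:4, 1)
    model <- structure(list(
      means = matrix(rnorm(5 * n_ch, 0, 3), 5, n_ch),
      vars = matrix(runif(5 * n_ch, 0.2, 2), 5, n_ch),
      log_priors = log(as.vector(prop.table(runif(5, 0.5, 1)))),
      n_channels = n_ch,
      absent_classes = integer(0)
    ), class = "voxel_classifier")
    channels <- lapply(seq_len(n_ch), function(i)
      array(rnorm(prod(d), 0, 3), dim = d))
    mask <- array(as.integer(runif(prod(d)) < 0.7), dim = d)
    got <- predict_labels(model, channels, mask)
    expect_identical(as.vector(got), as.vector(oracle_predict(model, channels, mask)))
  }
})

test_that("an empty brain mask yields an all-background prediction", {
  d <- c(6L, 6L, 6L)
  labels <- array(0L, dim = d); labels[1:30] <- 1L
  case <- make_constant_case(labels, matrix(1:10, nrow = 5))
  model <- fit_voxel_classifier(list(case))
  pred <- predict_labels(model, case$channels, array(0L, dim = d))
  expect_true(all(pred == 0L))
})

test_that("majority-vote smoothing removes isolated voxels", {
  d <- c(7L, 7L, 7L)
  labels <- array(0L, dim = d)
  labels[4, 4, 4] <- 2L  # lone voxel inside a uniform region
  mask <- array(1L, dim = d)
  sm <- ratiomapeval:::majority_smooth(labels, mask, 1L)
  expect_equal(sm[4, 4, 4], 0L)
})

test_that("fold assignment is a deterministic partition", {
  ids <- sprintf("case_%02d", 1:10)
  f1 <- assign_folds(ids, 5, seed = 9)
  f2 <- assign_folds(ids, 5, seed = 9)
  expect_identical(f1, f2)
  expect_identical(sort(f1$case_id), sort(ids))          # every case exactly once
  expect_true(all(table(f1$fold) == 2))                  # 10 cases, 5 folds -> 2 each
  expect_error(assign_folds(ids[1:3], 5, seed = 1), "fewer cases")
  expect_error(assign_folds(ids, 1, seed = 1), "at least 2")
})

test_that("a separable noiseless phantom yields held-out Dice 1 for present labels", {
  spec <- small_spec(noise_sd = 0, seed = 33)
  cases <- generate_cases(spec, 8)
  names(cases) <- vapply(cases, `[[`, character(1), "case_id")
  stacks <- lapply(cases, `[[`, "channels")
  refs <- lapply(cases, function(cs) list(labels = cs$labels, brain_mask = cs$brain_mask))
  cv <- cross_validate_cases(stacks, refs, n_folds = 4, seed = 3, subsample = 2000)
  records <- score_records(list(m = cv$predictions), lapply(refs, `[[`, "labels"))
  expect_true(all(records$dice == 1))
  # and specifically the labels actually present in the reference
  present <- records[!records$ref_empty, ]
  expect_gt(nrow(present), 0)
  expect_true(all(present$dice == 1))
})

test_that("a pure-noise extra channel barely perturbs Dice on a separable phantom", {
  spec <- small_spec(noise_sd = 0.5, seed = 44)
  cases <- generate_cases(spec, 8)
  names(cases) <- vapply(cases, `[[`, character(1), "case_id")
  refs <- lapply(cases, function(cs) list(labels = cs$labels, brain_mask = cs$brain_mask))
  stacks <- lapply(cases, `[[`, "channels")
  set.seed(55)
  stacks_noise <- lapply(stacks, function(st)
    c(st, list(extra = array(rnorm(length(st[[1]])), dim = dim(st[[1]])))))
  cv0 <- cross_validate_cases(stacks, refs, n_folds = 4, seed = 3, subsample = 2000)
  cv1 <- cross_validate_cases(stacks_noise, refs, n_folds = 4, seed = 3, subsample = 2000)
  recs <- score_records(list(base = cv0$predictions, noise = cv1$predictions),
                        lapply(refs, `[[`, "labels"))
  wide <- merge(recs[recs$model == "base", c("case_id", "label", "dice")],
                recs[recs$model == "noise", c("case_id", "label", "dice")],
                by = c("case_id", "label"))
  expect_lt(max(abs(wide$dice.x - wide$dice.y)), 0.1)
})
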