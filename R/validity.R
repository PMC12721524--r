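#' Comparison-harness validity checks
#'
#' Self-checks that the end-to-end harness (phantom -> segmenter ->
#' censored Dice -> paired one-tailed Wilcoxon) behaves like a calibrated
#' instrument: a fifth channel of pure noise should almost never be declared
#' a significant improvement (type-I control), while a fifth channel carrying
#' genuine label-correlated signal should be detected reliably (power).
#'
#' @name validity
NULL

#' Run one seeded replicate of the channel-validity experiment
#'
#' Generates a noisy phantom cohort, cross-validates the classifier on the
#' four structural channels (baseline) and on the same four plus a synthetic
#' fifth channel, scores both with censored Dice, and compares augmented vs
#' baseline per subregion with the one-tailed signed-rank protocol.
#'
#' The fifth channel is either `"noise"` — an i.i.d. standard-normal field
#' carrying no information — or `"informative"` — a field whose mean encodes
#' the reference label class (0, 12, 24, 36, 48 for classes 0..4) with unit
#' SD 4 noise, i.e. strongly but imperfectly discriminative, so augmented
#' Dice improves without reaching exactly 1 (which would be censored away).
#'
#' @param seed integer seed for the replicate (drives phantom, extra channel,
#'   folds and classifier subsampling).
#' @param channel `"noise"` or `"informative"`.
#' @param n_cases cohort size (default 40).
#' @param grid voxels per axis of the phantom grid (default 32; small enough
#'   that replicated experiments run in seconds).
#' @param noise_sd phantom noise multiplier (default 2: heavy class overlap,
#'   so the baseline segmenter is imperfect and improvement is possible).
#' @param n_folds cross-validation folds.
#' @param subsample classifier subsampling per class.
#' @param family_alpha family-wise alpha for the Bonferroni threshold.
#' @return List: `comparison` (the [compare_models()] table for
#'   augmented-vs-baseline), `any_significant` (whether any subregion was
#'   declared a significant improvement), `summary` (censored Dice summary).
#' @export
channel_validity_replicate <- function(seed, channel = c("noise", "informative"),
                                       n_cases = 40L, grid = 32L,
                                       noise_sd = 2, n_folds = 5L,
                                       subsample = 3000, family_alpha = 0.05) {
  channel <- match.arg(channel)
  spec <- phantom_spec(grid_shape = rep(as.integer(grid), 3),
                       noise_sd = noise_sd, seed = as.integer(seed))
  cases <- generate_cases(spec, n_cases)
  names(cases) <- vapply(cases, `[[`, character(1), "case_id")
  refs <- lapply(cases, function(cs)
    list(labels = cs$labels, brain_mask = cs$brain_mask))

  base_stacks <- lapply(cases, function(cs) cs$channels)

  inf_means <- c(0, 12, 24, 36, 48)
  inf_sd <- 4
  set.seed(as.integer((seed + 777) %% 2147483647))
  aug_stacks <- lapply(cases, function(cs) {
    d <- dim(cs$labels)
    extra <- if (channel == "noise") {
      array(rnorm(prod(d)), dim = d)
    } else {
      array(inf_means[cs$labels + 1L] + inf_sd * rnorm(prod(d)), dim = d)
    }
    c(cs$channels, list(extra = extra))
  })

  cv_base <- cross_validate_cases(base_stacks, refs, n_folds = n_folds,
                                  seed = seed, subsample = subsample)
  cv_aug <- cross_validate_cases(aug_stacks, refs, n_folds = n_folds,
                                 seed = seed, subsample = subsample)

  records <- score_records(list(baseline = cv_base$predictions,
                                augmented = cv_aug$predictions),
                           lapply(refs, `[[`, "labels"))
  comparison <- compare_models(records, "baseline", "augmented",
                               family_alpha = family_alpha)
  list(comparison = comparison,
       any_significant = any(comparison$significant),
       summary = summarize_dice(records, censor = TRUE))
}

#' Replicate the channel-validity experiment across seeds
#'
#' @param seeds integer vector of replicate seeds.
#' @param channel `"noise"` or `"informative"`.
#' @param ... forwarded to [channel_validity_replicate()].
#' @return List: `significant` (logical per replicate), `rate` (fraction of
#'   replicates declared significant), `n` (number of replicates).
#' @export
channel_validity_study <- function(seeds, channel = c("noise", "informative"), ...) {
  channel <- match.arg(channel)
  sig <- vapply(seeds, function(s)
    channel_validity_replicate(s, channel = channel, ...)$any_significant,
    logical(1))
  list(significant = sig, rate = mean(sig), n = length(seeds))
}
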