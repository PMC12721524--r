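#' Paired one-tailed Wilcoxon comparison protocol
#'
#' Each map-augmented configuration is compared against baseline per tumor
#' subregion with a paired, one-tailed Wilcoxon signed-rank test of the
#' alternative "augmented exceeds baseline". A case contributes a valid pair
#' for a label only if its Dice record is non-censored under BOTH models —
#' censoring is recomputed per comparison, which is why the number of valid
#' pairs differs across labels and model pairs. Bonferroni correction over
#' the subregions gives the per-comparison threshold
#' `alpha_crit = family_alpha / n_labels` (0.05 / 4 = 0.0125 by default).
#'
#' @name comparison
NULL

#' Build valid Dice pairs for one label and model contrast
#'
#' @param records Dice records (see [score_records()]).
#' @param label the label to compare.
#' @param baseline_model,test_model model names present in `records`.
#' @return data.frame with columns `case_id`, `baseline`, `test`, one row per
#'   case whose record is non-censored in both models. May have zero rows.
#' @export
build_pairs <- function(records, label, baseline_model, test_model) {
  if (!label %in% records$label) {
    stop(sprintf("label %s absent from records", label), call. = FALSE)
  }
  b <- records[records$label == label & records$model == baseline_model, ]
  t_ <- records[records$label == label & records$model == test_model, ]
  m <- merge(b[, c("case_id", "dice", "censored")],
             t_[, c("case_id", "dice", "censored")],
             by = "case_id", suffixes = c("_b", "_t"))
  m <- m[!m$censored_b & !m$censored_t, ]
  data.frame(case_id = m$case_id, baseline = m$dice_b, test = m$dice_t,
             stringsAsFactors = FALSE)
}

# exact null distribution of 2*W via the rank-sum characteristic polynomial:
# each (doubled, so integer-valued even under tied average ranks) rank enters
# the positive sum independently with probability 1/2
signed_rank_exact_p <- function(ranks2, w2_obs) {
  total <- sum(ranks2)
  f <- numeric(total + 1)
  f[1] <- 1
  for (s in ranks2) {
    g <- f
    g[(s + 1):(total + 1)] <- g[(s + 1):(total + 1)] + f[1:(total + 1 - s)]
    f <- g
  }
  probs <- f / 2^length(ranks2)
  sum(probs[seq(w2_obs + 1, total + 1)])
}

#' One-tailed paired Wilcoxon signed-rank test
#'
#' Differences `d = test - baseline`; zero differences are dropped before
#' ranking (the classical treatment; the number dropped is reported).
#' Absolute differences are ranked with average ranks for ties, `W` is the
#' sum of ranks of positive differences, and the one-tailed p-value is
#' `P(W' >= W)` under the sign-symmetric null, against the alternative
#' "test exceeds baseline". The null distribution is exact (full
#' enumeration via convolution) for up to `exact_max` post-drop pairs, and a
#' normal approximation with tie and continuity corrections beyond that.
#'
#' @param pairs data.frame with `baseline` and `test` columns (see
#'   [build_pairs()]), or a two-column matrix.
#' @param exact_max largest post-drop sample size for the exact null
#'   (default 25).
#' @return List: `n_pairs` (valid pairs entering, before zero-drop),
#'   `n_used`, `n_zero_dropped`, `W`, `p`, `method`, and `reason` (non-`NA`
#'   when no test is possible, with `W` and `p` then `NA`).
#' @export
wilcoxon_one_tailed <- function(pairs, exact_max = 25L) {
  b <- pairs[["baseline"]]
  t_ <- pairs[["test"]]
  n_pairs <- length(b)
  if (n_pairs == 0) {
    return(list(n_pairs = 0L, n_used = 0L, n_zero_dropped = 0L,
                W = NA_real_, p = NA_real_, method = NA_character_,
                reason = "no valid pairs"))
  }
  d <- t_ - b
  nz <- d != 0
  n_zero <- sum(!nz)
  d <- d[nz]
  n <- length(d)
  if (n == 0) {
    return(list(n_pairs = n_pairs, n_used = 0L, n_zero_dropped = n_zero,
                W = NA_real_, p = NA_real_, method = NA_character_,
                reason = "all differences zero"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    p <- signed_rank_exact_p(as.integer(round(2 * r)), as.integer(round(2 * W)))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu - 0.5) / sqrt(sig2)
    p <- pnorm(z, lower.tail = FALSE)
    method <- "normal_approx"
  }
  list(n_pairs = n_pairs, n_used = n, n_zero_dropped = n_zero,
       W = W, p = min(max(p, 0), 1), method = method, reason = NA_character_)
}

#' Compare augmented models against baseline
#'
#' Runs the censoring-aware pairing and the one-tailed signed-rank test for
#' every (test model, label) combination, with Bonferroni control over the
#' labels.
#'
#' @param records Dice records.
#' @param baseline_model baseline model name.
#' @param test_models character vector of model names to test against
#'   baseline.
#' @param labels labels compared (default the four subregions
#'   ET, NET, CC, ED).
#' @param family_alpha family-wise error rate (default 0.05).
#' @return data.frame with one row per model x label: `model, label, n_pairs,
#'   n_used, n_zero_dropped, W, p, significant, alpha_crit, reason`.
#'   `significant` is `TRUE` iff the test produced a p-value below
#'   `alpha_crit`.
#' @export
compare_models <- function(records, baseline_model, test_models,
                           labels = c("ET", "NET", "CC", "ED"),
                           family_alpha = 0.05) {
  alpha_crit <- family_alpha / length(labels)
  rows <- list()
  for (model in test_models) {
    for (lab in labels) {
      pr <- build_pairs(records, lab, baseline_model, model)
      w <- wilcoxon_one_tailed(pr)
      rows[[length(rows) + 1L]] <- data.frame(
        model = model, label = lab,
        n_pairs = w$n_pairs, n_used = w$n_used,
        n_zero_dropped = w$n_zero_dropped,
        W = w$W, p = w$p,
        significant = !is.na(w$p) && w$p < alpha_crit,
        alpha_crit = alpha_crit, reason = w$reason,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Bonferroni-corrected per-comparison threshold
#'
#' @param family_alpha family-wise error rate.
#' @param n_comparisons number of comparisons in the family.
#' @return `family_alpha / n_comparisons`.
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, n_comparisons = 4L) {
  stopifnot(family_alpha > 0, family_alpha < 1, n_comparisons >= 1)
  family_alpha / n_comparisons
}
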