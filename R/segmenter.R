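#' Per-voxel Gaussian classifier segmenter
#'
#' A deliberately simple, deterministic stand-in for a trained segmentation
#' network: a generative classifier with one diagonal-covariance Gaussian per
#' label class (0 = non-tumor brain, 1 = ET, 2 = NET, 3 = CC, 4 = ED) over
#' the input channel intensities, with class priors estimated from voxel
#' counts. It is sensitive to the information content of the channel stack —
#' which is all the comparison harness needs — and makes no claim of
#' emulating the performance of a deep segmentation model.
#'
#' @name segmenter
NULL

N_CLASSES <- 5L
VAR_FLOOR <- 1e-8  # keeps noiseless (zero-variance) phantoms well-defined

#' Fit the voxel classifier
#'
#' Estimates per-class channel means, diagonal variances and class priors
#' from labeled within-brain voxels, subsampling each class for speed.
#' A class absent from the training data gets the uninformative fallback of
#' prior 0 (it is never predicted); this is reported in the model object.
#'
#' @param training_cases list of cases, each a list with `channels` (named
#'   list of volumes, the channel stack), `labels` and `brain_mask`.
#' @param subsample voxels sampled per class (default 5000).
#' @param seed seed for the subsampling (default 1).
#' @return Object of class `voxel_classifier`: `means` and `vars`
#'   (class x channel matrices), `log_priors`, `n_channels`,
#'   `absent_classes`.
#' @export
fit_voxel_classifier <- function(training_cases, subsample = 5000, seed = 1L) {
  stopifnot(length(training_cases) >= 1)
  n_ch <- length(training_cases[[1]]$channels)
  xs <- vector("list", length(training_cases))
  ys <- vector("list", length(training_cases))
  for (i in seq_along(training_cases)) {
    case <- training_cases[[i]]
    if (length(case$channels) != n_ch) {
      stop(sprintf("channel-count mismatch: case %d has %d channels, expected %d",
                   i, length(case$channels), n_ch), call. = FALSE)
    }
    inside <- case$brain_mask != 0
    xs[[i]] <- vapply(case$channels, function(v) v[inside],
                      numeric(sum(inside)))
    ys[[i]] <- case$labels[inside]
  }
  x <- do.call(rbind, xs)
  y <- do.call(c, ys)

  counts <- vapply(0:(N_CLASSES - 1L), function(k) sum(y == k), numeric(1))
  means <- matrix(0, N_CLASSES, n_ch)
  vars <- matrix(1, N_CLASSES, n_ch)
  set.seed(as.integer(seed))
  for (k in seq_len(N_CLASSES)) {
    idx <- which(y == k - 1L)
    if (length(idx) == 0) next
    if (length(idx) > subsample) idx <- sample(idx, subsample)
    xk <- x[idx, , drop = FALSE]
    means[k, ] <- colMeans(xk)
    vk <- apply(xk, 2, function(col) mean((col - mean(col))^2))
    vars[k, ] <- pmax(vk, VAR_FLOOR)
  }
  log_priors <- ifelse(counts > 0, log(counts / sum(counts)), -Inf)
  structure(list(
    means = means, vars = vars, log_priors = log_priors,
    n_channels = n_ch,
    absent_classes = which(counts == 0) - 1L
  ), class = "voxel_classifier")
}

#' @export
print.voxel_classifier <- function(x, ...) {
  cat(sprintf("voxel classifier: %d classes x %d channels; priors %s\n",
              nrow(x$means), x$n_channels,
              paste(sprintf("%.3f", exp(x$log_priors)), collapse = " ")))
  if (length(x$absent_classes)) {
    cat("absent in training (never predicted):",
        paste(x$absent_classes, collapse = " "), "\n")
  }
  invisible(x)
}

# class x voxel matrix of Gaussian log-posteriors (up to a constant)
voxel_log_posteriors <- function(model, xmat) {
  n <- nrow(xmat)
  ll <- matrix(-Inf, n, N_CLASSES)
  for (k in seq_len(N_CLASSES)) {
    if (!is.finite(model$log_priors[k])) next
    z <- sweep(xmat, 2, model$means[k, ], "-")
    q <- sweep(z^2, 2, model$vars[k, ], "/")
    ll[, k] <- model$log_priors[k] -
      0.5 * sum(log(2 * pi * model$vars[k, ])) - 0.5 * rowSums(q)
  }
  ll
}

#' Predict a label volume
#'
#' Per-voxel argmax of the Gaussian log-posterior within the brain mask
#' (ties broken toward the lowest class code); voxels outside the mask are
#' background. Optional majority-vote smoothing replaces each within-mask
#' label by the most frequent label in its cubic neighborhood.
#'
#' @param model a `voxel_classifier`.
#' @param channels named list of volumes matching the model's channel count.
#' @param brain_mask binary 3D array.
#' @param smooth_radius neighborhood radius in voxels for majority-vote
#'   smoothing; 0 (default) disables.
#' @return Integer `LabelVolume` on the input grid.
#' @export
predict_labels <- function(model, channels, brain_mask, smooth_radius = 0L) {
  stopifnot(inherits(model, "voxel_classifier"))
  if (length(channels) != model$n_channels) {
    stop(sprintf("channel-count mismatch: model fit on %d channels, given %d",
                 model$n_channels, length(channels)), call. = FALSE)
  }
  d <- dim(brain_mask)
  out <- array(0L, dim = d)
  inside <- brain_mask != 0
  if (any(inside)) {
    xmat <- vapply(channels, function(v) v[inside], numeric(sum(inside)))
    if (is.null(dim(xmat))) xmat <- matrix(xmat, nrow = 1)
    ll <- voxel_log_posteriors(model, xmat)
    out[inside] <- max.col(ll, ties.method = "first") - 1L
  }
  if (smooth_radius > 0) out <- majority_smooth(out, brain_mask, smooth_radius)
  attr(out, "pixdim") <- attr(brain_mask, "pixdim")
  out
}

# majority vote over a cubic neighborhood, evaluated by shifted accumulation
majority_smooth <- function(labels, brain_mask, radius) {
  d <- dim(labels)
  counts <- array(0L, dim = c(d, N_CLASSES))
  offs <- expand.grid(dx = -radius:radius, dy = -radius:radius, dz = -radius:radius)
  shift_arr <- function(a, o) {
    src_x <- pmin(pmax(seq_len(d[1]) + o[1], 1L), d[1])
    src_y <- pmin(pmax(seq_len(d[2]) + o[2], 1L), d[2])
    src_z <- pmin(pmax(seq_len(d[3]) + o[3], 1L), d[3])
    a[src_x, src_y, src_z]
  }
  for (i in seq_len(nrow(offs))) {
    sh <- shift_arr(labels, as.integer(offs[i, ]))
    for (k in seq_len(N_CLASSES)) {
      counts[, , , k] <- counts[, , , k] + (sh == k - 1L)
    }
  }
  flat <- matrix(counts, nrow = prod(d), ncol = N_CLASSES)
  out <- array(max.col(flat, ties.method = "first") - 1L, dim = d)
  out[brain_mask == 0] <- 0L
  out
}

#' Assign cases to cross-validation folds
#'
#' Subject-level fold assignment: each case belongs to exactly one held-out
#' fold, deterministic given the seed.
#'
#' @param case_ids character vector of case identifiers.
#' @param n_folds number of folds, at least 2 and at most the number of cases.
#' @param seed integer seed.
#' @return data.frame with columns `case_id`, `fold`.
#' @export
assign_folds <- function(case_ids, n_folds, seed) {
  n <- length(case_ids)
  if (n_folds < 2) stop("n_folds must be at least 2", call. = FALSE)
  if (n < n_folds) {
    stop(sprintf("fewer cases (%d) than folds (%d)", n, n_folds), call. = FALSE)
  }
  set.seed(as.integer(seed))
  data.frame(case_id = case_ids,
             fold = sample(rep(seq_len(n_folds), length.out = n)),
             stringsAsFactors = FALSE)
}

#' Cross-validate the classifier over in-memory cases
#'
#' Each case is predicted by the model fit on the other folds; there is no
#' ensembling — a case's score comes from its held-out-fold prediction only.
#'
#' @param stacks named list (by case_id) of channel stacks.
#' @param refs named list (by case_id) of lists with `labels`, `brain_mask`.
#' @param n_folds number of folds.
#' @param seed seed driving fold assignment and classifier subsampling.
#' @param subsample voxels per class for the classifier fit.
#' @param smooth_radius smoothing radius passed to [predict_labels()].
#' @return List with `predictions` (named list of label volumes) and `folds`
#'   (the assignment data.frame).
#' @export
cross_validate_cases <- function(stacks, refs, n_folds = 5L, seed = 1L,
                                 subsample = 5000, smooth_radius = 0L) {
  ids <- names(stacks)
  stopifnot(!is.null(ids), identical(sort(ids), sort(names(refs))))
  folds <- assign_folds(ids, n_folds, seed)
  preds <- setNames(vector("list", length(ids)), ids)
  for (f in seq_len(n_folds)) {
    held <- folds$case_id[folds$fold == f]
    train_ids <- setdiff(ids, held)
    train <- lapply(train_ids, function(id)
      list(channels = stacks[[id]], labels = refs[[id]]$labels,
           brain_mask = refs[[id]]$brain_mask))
    model <- fit_voxel_classifier(train, subsample = subsample,
                                  seed = as.integer(seed) + f)
    for (id in held) {
      preds[[id]] <- predict_labels(model, stacks[[id]], refs[[id]]$brain_mask,
                                    smooth_radius = smooth_radius)
    }
  }
  list(predictions = preds, folds = folds)
}

#' Cross-validate a configuration over a cohort on disk
#'
#' Reads the cohort from its manifest, builds the channel stack of the
#' requested configuration per case, runs [cross_validate_cases()], and
#' writes each held-out prediction as
#' `<case_id>_pred_<configuration>.nii.gz` plus a `folds_<configuration>.csv`
#' fold-assignment table under `out_dir`.
#'
#' @param manifest cohort manifest data.frame (see [generate_cohort()]).
#' @param configuration `"baseline"`, `"ratio"` or `"combined"`.
#' @param n_folds number of folds (default 5, the standard protocol).
#' @param seed integer seed.
#' @param out_dir output directory for predictions.
#' @param alpha ratio-map offset forwarded to [build_channel_stack()].
#' @param subsample,smooth_radius forwarded to [cross_validate_cases()].
#' @return Invisibly, the in-memory result of [cross_validate_cases()].
#' @export
run_cross_validation <- function(manifest, configuration, n_folds = 5L, seed = 1L,
                                 out_dir, alpha = 1e-6, subsample = 5000,
                                 smooth_radius = 0L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cases <- lapply(seq_len(nrow(manifest)), function(i)
    read_phantom_case(manifest[i, ]))
  names(cases) <- manifest$case_id
  stacks <- lapply(cases, build_channel_stack, configuration = configuration,
                   alpha = alpha)
  refs <- lapply(cases, function(cs)
    list(labels = cs$labels, brain_mask = cs$brain_mask))
  cv <- cross_validate_cases(stacks, refs, n_folds = n_folds, seed = seed,
                             subsample = subsample, smooth_radius = smooth_radius)
  for (id in names(cv$predictions)) {
    write_volume(cv$predictions[[id]],
                 file.path(out_dir, sprintf("%s_pred_%s.nii.gz", id, configuration)),
                 datatype = "int16")
  }
  write.csv(cv$folds, file.path(out_dir, sprintf("folds_%s.csv", configuration)),
            row.names = FALSE)
  invisible(cv)
}
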