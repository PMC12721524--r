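#' Censored Dice evaluation
#'
#' Predictions are scored against reference labels with the Dice similarity
#' coefficient per subregion (ET, NET, CC, ED) and for the composite labels
#' TC (tumor core, ET + NET + CC) and WT (whole tumor, TC + ED), formed by
#' binary union of the subregion masks. When neither mask contains the label,
#' Dice is defined as 1 — the model correctly predicts that there is nothing
#' to segment. Because such scores inflate summaries without reflecting any
#' discrimination, records with Dice = 1 are censored (removed) before
#' descriptive statistics and paired tests; both-empty and exact-match causes
#' are recorded separately so either censoring policy is auditable.
#'
#' @name evaluation
NULL

EVAL_LABELS <- c("ET", "NET", "CC", "ED", "TC", "WT")

#' Dice similarity coefficient of two binary masks
#'
#' `2|P intersect R| / (|P| + |R|)`; defined as 1 when both masks are empty.
#' Any nonzero voxel counts as inside the mask.
#'
#' @param pred,ref binary 3D arrays on the same grid.
#' @return Dice value in \[0, 1\].
#' @export
dice_score <- function(pred, ref) {
  check_same_grid(pred, ref, "prediction and reference")
  p <- pred != 0
  r <- ref != 0
  np <- sum(p)
  nr <- sum(r)
  if (np + nr == 0) return(1)
  2 * sum(p & r) / (np + nr)
}

#' Composite label masks from a label volume
#'
#' TC is the union of ET, NET and CC (codes 1, 2, 3); WT additionally
#' includes ED (code 4).
#'
#' @param labels integer label volume with codes in 0..4.
#' @return List with binary arrays `TC` and `WT`.
#' @export
combine_labels <- function(labels) {
  codes <- unique(as.vector(labels))
  bad <- setdiff(codes, 0:4)
  if (length(bad)) {
    stop("unexpected label codes: ", paste(sort(bad), collapse = ", "),
         call. = FALSE)
  }
  list(TC = array(labels %in% 1:3, dim = dim(labels)),
       WT = array(labels %in% 1:4, dim = dim(labels)))
}

# all six binary masks for a label volume
label_masks <- function(labels) {
  comp <- combine_labels(labels)
  list(ET = array(labels == 1L, dim = dim(labels)),
       NET = array(labels == 2L, dim = dim(labels)),
       CC = array(labels == 3L, dim = dim(labels)),
       ED = array(labels == 4L, dim = dim(labels)),
       TC = comp$TC, WT = comp$WT)
}

#' Score one case for one model
#'
#' @param pred,ref integer label volumes on one grid.
#' @param case_id,model identifiers carried into the records.
#' @param censor_policy `"dice1"` censors every record with Dice = 1 (the
#'   default protocol); `"both_empty"` censors only records where both masks
#'   are empty.
#' @return data.frame of six Dice records (one per label) with columns
#'   `case_id, label, model, dice, censored, pred_empty, ref_empty`.
#' @export
score_case <- function(pred, ref, case_id, model,
                       censor_policy = c("dice1", "both_empty")) {
  censor_policy <- match.arg(censor_policy)
  pm <- label_masks(pred)
  rm_ <- label_masks(ref)
  rows <- lapply(EVAL_LABELS, function(lab) {
    d <- dice_score(pm[[lab]], rm_[[lab]])
    pe <- !any(pm[[lab]])
    re <- !any(rm_[[lab]])
    cens <- if (censor_policy == "dice1") d == 1 else (pe && re)
    data.frame(case_id = case_id, label = lab, model = model, dice = d,
               censored = cens, pred_empty = pe, ref_empty = re,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Score a cohort of predictions
#'
#' In-memory interface: `predictions` is a named list (by model) of named
#' lists (by case_id) of predicted label volumes; `references` a named list
#' (by case_id) of reference label volumes.
#'
#' @param predictions nested list of predicted label volumes.
#' @param references named list of reference label volumes.
#' @param censor_policy see [score_case()].
#' @return Long-format data.frame of Dice records: one row per
#'   case x label x model.
#' @export
score_records <- function(predictions, references,
                          censor_policy = c("dice1", "both_empty")) {
  censor_policy <- match.arg(censor_policy)
  out <- list()
  for (model in names(predictions)) {
    for (id in names(references)) {
      if (is.null(predictions[[model]][[id]])) {
        stop(sprintf("missing prediction for case %s, model %s", id, model),
             call. = FALSE)
      }
      out[[length(out) + 1L]] <- score_case(predictions[[model]][[id]],
                                            references[[id]], id, model,
                                            censor_policy)
    }
  }
  do.call(rbind, out)
}

#' Score predictions stored on disk
#'
#' Accepts any directory of label NIfTIs named
#' `<case_id>_pred_<model>.nii.gz` — including predictions produced outside
#' this package — and scores them against the reference labels listed in a
#' cohort manifest.
#'
#' @param pred_dir directory containing prediction files.
#' @param manifest cohort manifest (see [generate_cohort()]).
#' @param models character vector of model/configuration names to score.
#' @param censor_policy see [score_case()].
#' @return Long-format data.frame of Dice records.
#' @export
score_cohort <- function(pred_dir, manifest, models,
                         censor_policy = c("dice1", "both_empty")) {
  censor_policy <- match.arg(censor_policy)
  refs <- setNames(vector("list", nrow(manifest)), manifest$case_id)
  for (i in seq_len(nrow(manifest))) {
    lab <- read_volume(manifest$labels[i])
    storage.mode(lab) <- "integer"
    refs[[manifest$case_id[i]]] <- lab
  }
  preds <- list()
  for (model in models) {
    preds[[model]] <- list()
    for (id in manifest$case_id) {
      f <- file.path(pred_dir, sprintf("%s_pred_%s.nii.gz", id, model))
      if (!file.exists(f)) {
        stop(sprintf("missing prediction file for case %s, model %s: %s",
                     id, model, f), call. = FALSE)
      }
      p <- read_volume(f)
      storage.mode(p) <- "integer"
      preds[[model]][[id]] <- p
    }
  }
  score_records(preds, refs, censor_policy)
}

#' Summarize Dice records per label and model
#'
#' With `censor = TRUE` (the reporting default) records with Dice = 1 are
#' removed before computing statistics; with `censor = FALSE` all records are
#' included. Cells where censoring removes everything are reported with
#' `n = 0` and missing statistics.
#'
#' @param records Dice records from [score_records()]/[score_cohort()].
#' @param censor whether to remove Dice = 1 records first.
#' @return data.frame with columns
#'   `model, label, mean, sd, median, n, n_censored`.
#' @export
summarize_dice <- function(records, censor = TRUE) {
  stopifnot(nrow(records) > 0)
  cells <- unique(records[, c("model", "label")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- records[records$model == cells$model[i] & records$label == cells$label[i], ]
    n_cens <- sum(sub$dice == 1)
    if (censor) sub <- sub[sub$dice < 1, ]
    n <- nrow(sub)
    data.frame(model = cells$model[i], label = cells$label[i],
               mean = if (n) mean(sub$dice) else NA_real_,
               sd = if (n > 1) sd(sub$dice) else NA_real_,
               median = if (n) median(sub$dice) else NA_real_,
               n = n, n_censored = n_cens, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$model, match(out$label, EVAL_LABELS)), , drop = FALSE]
}
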