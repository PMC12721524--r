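#' Synthetic multiparametric MRI tumor phantom
#'
#' The phantom emulates the statistical structure of a co-registered,
#' 1 mm isotropic pediatric brain tumor dataset: four structural channels
#' (T1w, T1w-CE, T2w, T2-FLAIR) with distinct per-tissue intensity
#' distributions, an ellipsoidal brain, a ventricle region with a known
#' T1w:T2w mean-intensity ratio, and a nested tumor (NET core, ET rim,
#' optional cystic component inside the core, optional edema halo outside),
#' where the optional subregions are absent in a configurable fraction of
#' cases. Intensities are per-tissue Gaussian draws plus optional additive
#' noise and an optional smooth multiplicative bias field.
#'
#' @name phantom
NULL

PHANTOM_CHANNELS <- c("t1w", "t1ce", "t2w", "flair")
LABEL_CODES <- c(ET = 1L, NET = 2L, CC = 3L, ED = 4L)
TISSUE_CLASSES <- c("background", "brain", "ventricle", "ET", "NET", "CC", "ED")

#' Default per-tissue channel intensity table
#'
#' Means and SDs (arbitrary scanner units) per tissue class and channel.
#' Values are invented but qualitatively sensible: CSF bright on T2w and
#' suppressed on FLAIR, enhancing tumor bright on T1w-CE, edema bright on
#' FLAIR, cyst fluid-like. They are configuration, not ground truth about any
#' real cohort, and are fully overridable via [phantom_spec()].
#'
#' @return data.frame with columns `tissue` and `<channel>_mean`,
#'   `<channel>_sd` for each of t1w, t1ce, t2w, flair.
#' @export
default_tissue_table <- function() {
  tab <- data.frame(
    tissue     = TISSUE_CLASSES,
    t1w_mean   = c(0, 600, 200, 650, 540, 300, 500),
    t1w_sd     = c(0,  60,  25,  55,  55,  40,  50),
    t1ce_mean  = c(0, 620, 210, 900, 580, 320, 520),
    t1ce_sd    = c(0,  60,  25,  70,  55,  40,  50),
    t2w_mean   = c(0, 400, 800, 500, 560, 850, 650),
    t2w_sd     = c(0,  50,  60,  50,  55,  60,  55),
    flair_mean = c(0, 450, 150, 560, 600, 200, 760),
    flair_sd   = c(0,  50,  25,  50,  55,  35,  55)
  )
  tab
}

#' Phantom cohort specification
#'
#' @param grid_shape integer length-3, voxels per axis. Default `c(64, 64, 64)`
#'   so a full experiment runs in minutes; spacing metadata is still written as
#'   1 mm isotropic.
#' @param voxel_spacing mm per voxel, length 3.
#' @param tissue_table per-tissue, per-channel intensity means and SDs, in the
#'   format of [default_tissue_table()]. The ventricle T1w mean is overridden
#'   so that `ventricle_t1w_mean = ventricle_t1_t2_ratio * ventricle_t2w_mean`,
#'   making the ground-truth scaling factor exact by construction.
#' @param ventricle_t1_t2_ratio known ratio of mean ventricle intensity in T1w
#'   to that in T2w.
#' @param label_presence_probs named vector of per-subregion presence
#'   probabilities. ET and NET default to 1; CC and ED are below 1 so some
#'   cases lack those labels (this is what exercises Dice censoring).
#' @param noise_sd global multiplier on the per-tissue SD column: a voxel of
#'   tissue class `c` in channel `k` has intensity
#'   `mean[c,k] + noise_sd * sd[c,k] * z`, `z ~ N(0,1)`, clipped at 0.
#'   `noise_sd = 0` gives every voxel its class mean exactly.
#' @param bias_field_amplitude amplitude (in \[0, 1)) of a smooth multiplicative
#'   low-frequency cosine field shared by all channels; 0 disables.
#' @param tumor_scale multiplier on the tumor radii (default 1); values much
#'   above 2 will not fit inside the brain and raise an error at generation.
#' @param seed integer random seed; together with the case index it fully
#'   determines each case.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         voxel_spacing = c(1, 1, 1),
                         tissue_table = default_tissue_table(),
                         ventricle_t1_t2_ratio = 0.25,
                         label_presence_probs = c(ET = 1, NET = 1, CC = 0.5, ED = 0.4),
                         noise_sd = 1,
                         bias_field_amplitude = 0,
                         tumor_scale = 1,
                         seed = 42L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 16),
            length(voxel_spacing) == 3, all(voxel_spacing > 0),
            ventricle_t1_t2_ratio > 0, noise_sd >= 0,
            bias_field_amplitude >= 0, bias_field_amplitude < 1,
            tumor_scale > 0)
  if (!all(names(LABEL_CODES) %in% names(label_presence_probs))) {
    stop("label_presence_probs must name ET, NET, CC and ED", call. = FALSE)
  }
  if (any(label_presence_probs < 0 | label_presence_probs > 1)) {
    stop("label presence probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!identical(tissue_table$tissue, TISSUE_CLASSES)) {
    stop("tissue_table must have rows ", paste(TISSUE_CLASSES, collapse = ", "),
         " in order", call. = FALSE)
  }
  mean_cols <- paste0(PHANTOM_CHANNELS, "_mean")
  if (any(tissue_table[tissue_table$tissue != "background", mean_cols] <= 0)) {
    stop("all non-background tissue mean intensities must be strictly positive",
         call. = FALSE)
  }
  # enforce the ground-truth ventricle ratio in the effective table
  iv <- match("ventricle", tissue_table$tissue)
  tissue_table$t1w_mean[iv] <- ventricle_t1_t2_ratio * tissue_table$t2w_mean[iv]
  structure(list(
    grid_shape = as.integer(grid_shape),
    voxel_spacing = as.numeric(voxel_spacing),
    tissue_table = tissue_table,
    ventricle_t1_t2_ratio = ventricle_t1_t2_ratio,
    label_presence_probs = label_presence_probs[names(LABEL_CODES)],
    noise_sd = noise_sd,
    bias_field_amplitude = bias_field_amplitude,
    tumor_scale = tumor_scale,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

# voxel-center coordinate arrays for a grid
grid_coords <- function(d) {
  list(x = array(rep(seq_len(d[1]), times = d[2] * d[3]), dim = d),
       y = array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), dim = d),
       z = array(rep(seq_len(d[3]), each = d[1] * d[2]), dim = d))
}

ellipsoid_mask <- function(co, center, semi) {
  ((co$x - center[1]) / semi[1])^2 +
    ((co$y - center[2]) / semi[2])^2 +
    ((co$z - center[3]) / semi[3])^2 <= 1
}

sphere_dist <- function(co, center) {
  sqrt((co$x - center[1])^2 + (co$y - center[2])^2 + (co$z - center[3])^2)
}

#' Generate one phantom case
#'
#' Deterministic given `(spec$seed, case_index)`. Geometry: ellipsoidal brain,
#' a small interior ventricle on one side, and a nested tumor on the opposite
#' side whose center and radii are randomized per case within bounds. Label
#' codes: 1 = ET (rim), 2 = NET (core), 3 = CC (blob inside the core,
#' optional), 4 = ED (halo outside the rim, optional).
#'
#' @param spec a [phantom_spec()].
#' @param case_index non-negative integer.
#' @return Object of class `phantom_case`: `case_id`, `channels` (named list
#'   t1w, t1ce, t2w, flair), `labels`, `brain_mask`, `ventricle_mask`,
#'   `labels_present`.
#' @export
generate_case <- function(spec, case_index) {
  stopifnot(inherits(spec, "phantom_spec"), case_index >= 0)
  set.seed(as.integer((spec$seed + 1009 * case_index) %% 2147483647))
  d <- spec$grid_shape
  co <- grid_coords(d)
  scale <- min(d) / 64

  center_brain <- (d + 1) / 2
  semi_brain <- 0.45 * d
  brain <- ellipsoid_mask(co, center_brain, semi_brain)

  center_vent <- center_brain + c(-0.18, 0, 0.04) * d
  semi_vent <- pmax(c(0.055, 0.05, 0.085) * d, 1.5)
  ventricle <- ellipsoid_mask(co, center_vent, semi_vent) & brain

  # presence draws first so they consume a fixed position in the RNG stream
  probs <- spec$label_presence_probs
  present <- setNames(runif(4) < unname(probs[c("CC", "ED", "ET", "NET")]),
                      c("CC", "ED", "ET", "NET"))

  r_net <- spec$tumor_scale * scale * runif(1, 4, 6)
  t_et <- spec$tumor_scale * scale * runif(1, 2, 3)
  t_ed <- spec$tumor_scale * scale * runif(1, 3, 4)
  r_cc <- spec$tumor_scale * scale * runif(1, 1.5, 2.5)
  center_tumor <- center_brain +
    c(runif(1, 0.08, 0.20), runif(1, -0.08, 0.08), runif(1, -0.08, 0.08)) * d

  r_outer <- r_net + t_et + (if (present["ED"]) t_ed else 0)
  # conservative fit check: offset (in ellipsoid metric) plus outer radius
  offset <- sqrt(sum(((center_tumor - center_brain) / semi_brain)^2))
  if (offset + r_outer / min(semi_brain) > 1) {
    stop(sprintf(
      "tumor does not fit inside the brain: outer radius %.1f voxels at offset %.2f",
      r_outer, offset), call. = FALSE)
  }

  dist_t <- sphere_dist(co, center_tumor)
  labels <- array(0L, dim = d)
  labels[brain & dist_t <= r_net] <- LABEL_CODES[["NET"]]
  if (present["ET"]) {
    labels[brain & dist_t > r_net & dist_t <= r_net + t_et] <- LABEL_CODES[["ET"]]
  }
  if (!present["NET"]) labels[labels == LABEL_CODES[["NET"]]] <- 0L
  if (present["CC"]) {
    cc_center <- center_tumor + c(r_net, 0, 0) * 0.3
    labels[brain & sphere_dist(co, cc_center) <= r_cc] <- LABEL_CODES[["CC"]]
  }
  if (present["ED"]) {
    r_et_out <- r_net + t_et
    labels[brain & dist_t > r_et_out & dist_t <= r_et_out + t_ed] <- LABEL_CODES[["ED"]]
  }
  ventricle <- ventricle & labels == 0L

  tissue <- array(1L, dim = d)            # background
  tissue[brain] <- 2L                     # normal brain
  tissue[ventricle] <- 3L                 # ventricle/CSF
  for (lab in names(LABEL_CODES)) {
    tissue[labels == LABEL_CODES[[lab]]] <- 3L + match(lab, names(LABEL_CODES))
  }

  bias <- NULL
  if (spec$bias_field_amplitude > 0) {
    ph <- runif(3, 0, 1)
    bias <- 1 + spec$bias_field_amplitude *
      cos(2 * pi * (co$x / d[1] / 2 + ph[1])) *
      cos(2 * pi * (co$y / d[2] / 2 + ph[2])) *
      cos(2 * pi * (co$z / d[3] / 2 + ph[3]))
  }

  tab <- spec$tissue_table
  channels <- list()
  for (ch in PHANTOM_CHANNELS) {
    mu <- tab[[paste0(ch, "_mean")]][tissue]
    vol <- mu
    if (spec$noise_sd > 0) {
      sdv <- tab[[paste0(ch, "_sd")]][tissue]
      vol <- vol + spec$noise_sd * sdv * rnorm(length(mu))
      vol <- pmax(vol, 0)
    }
    vol <- array(vol, dim = d)
    if (!is.null(bias)) vol <- vol * bias
    attr(vol, "pixdim") <- spec$voxel_spacing
    channels[[ch]] <- vol
  }

  brain_mask <- array(as.integer(brain), dim = d)
  ventricle_mask <- array(as.integer(ventricle), dim = d)
  attr(labels, "pixdim") <- spec$voxel_spacing
  attr(brain_mask, "pixdim") <- spec$voxel_spacing
  attr(ventricle_mask, "pixdim") <- spec$voxel_spacing

  present_labels <- names(LABEL_CODES)[vapply(names(LABEL_CODES), function(l)
    any(labels == LABEL_CODES[[l]]), logical(1))]

  structure(list(
    case_id = sprintf("case_%04d", as.integer(case_index)),
    channels = channels,
    labels = labels,
    brain_mask = brain_mask,
    ventricle_mask = ventricle_mask,
    labels_present = present_labels
  ), class = "phantom_case")
}

#' Generate phantom cases in memory
#'
#' @param spec a [phantom_spec()].
#' @param n_cases number of cases (indices 1..n_cases).
#' @return List of `phantom_case` objects.
#' @export
generate_cases <- function(spec, n_cases) {
  stopifnot(n_cases >= 1)
  lapply(seq_len(n_cases), function(i) generate_case(spec, i))
}

case_file_names <- c(t1w = "t1w.nii.gz", t2w = "t2w.nii.gz",
                     t1ce = "t1ce.nii.gz", flair = "flair.nii.gz",
                     labels = "labels.nii.gz", brain_mask = "brain_mask.nii.gz",
                     ventricle_mask = "ventricle_mask.nii.gz")

#' Write one phantom case as NIfTI files
#'
#' @param case a `phantom_case`.
#' @param dir output directory (created if needed).
#' @return Named character vector of file paths.
#' @export
write_phantom_case <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, case_file_names)
  names(paths) <- names(case_file_names)
  for (ch in PHANTOM_CHANNELS) {
    write_volume(case$channels[[ch]], paths[[ch]], datatype = "double")
  }
  write_volume(case$labels, paths[["labels"]], datatype = "int16")
  write_volume(case$brain_mask, paths[["brain_mask"]], datatype = "int16")
  write_volume(case$ventricle_mask, paths[["ventricle_mask"]], datatype = "int16")
  paths
}

#' Read one phantom case from a manifest row
#'
#' @param manifest_row one row of a cohort manifest (see [generate_cohort()]).
#' @return A `phantom_case`.
#' @export
read_phantom_case <- function(manifest_row) {
  channels <- lapply(setNames(PHANTOM_CHANNELS, PHANTOM_CHANNELS), function(ch)
    read_volume(manifest_row[[ch]]))
  labels <- read_volume(manifest_row$labels)
  storage.mode(labels) <- "integer"
  brain_mask <- read_volume(manifest_row$brain_mask)
  storage.mode(brain_mask) <- "integer"
  ventricle_mask <- read_volume(manifest_row$ventricle_mask)
  storage.mode(ventricle_mask) <- "integer"
  lp <- manifest_row$labels_present
  present <- if (is.na(lp) || !nzchar(lp)) character(0) else
    strsplit(lp, ";", fixed = TRUE)[[1]]
  structure(list(
    case_id = manifest_row$case_id,
    channels = channels,
    labels = labels,
    brain_mask = brain_mask,
    ventricle_mask = ventricle_mask,
    labels_present = present
  ), class = "phantom_case")
}

#' Generate a phantom cohort on disk
#'
#' Writes each case as NIfTI files under `out_dir/<case_id>/` plus a
#' `manifest.csv` with columns
#' `case_id,t1w,t2w,t1ce,flair,labels,brain_mask,ventricle_mask,labels_present`
#' (`labels_present` is `;`-separated).
#'
#' @param spec a [phantom_spec()].
#' @param n_cases number of cases, at least 1.
#' @param out_dir output directory.
#' @return The manifest as a data.frame (also written to
#'   `out_dir/manifest.csv`).
#' @export
generate_cohort <- function(spec, n_cases, out_dir) {
  stopifnot(n_cases >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  rows <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    case <- generate_case(spec, i)
    paths <- write_phantom_case(case, file.path(out_dir, case$case_id))
    rows[[i]] <- data.frame(
      case_id = case$case_id,
      t1w = paths[["t1w"]], t2w = paths[["t2w"]],
      t1ce = paths[["t1ce"]], flair = paths[["flair"]],
      labels = paths[["labels"]],
      brain_mask = paths[["brain_mask"]],
      ventricle_mask = paths[["ventricle_mask"]],
      labels_present = paste(case$labels_present, collapse = ";"),
      stringsAsFactors = FALSE
    )
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}
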