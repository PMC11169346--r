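#' Configuration for the synthetic morphometry cohort
#'
#' The generator emulates the study population the classifiers are built for:
#' ordinal tissue volumes (background/CSF/GM/WM/lesion) on a common coarse
#' lattice, left-hemisphere lesions of variable size, gray-matter atrophy
#' motifs matched on total atrophy but differing in spatial arrangement, and
#' a continuous WAB-AQ-like outcome in \[0, 100\] binned at 25/50/75 with
#' roughly 35% of subjects below 50 (severe aphasia).
#'
#' The outcome model is linear-Gaussian with clipping:
#' `wab_aq = clip(100 - a * lesion_fraction - b * harmful_motif + N(0, sigma), 0, 100)`
#' where `lesion_fraction` is lesion volume over left-hemisphere brain voxels.
#' Default coefficients were calibrated once so that at the default grid and
#' lesion sizes the severe fraction is close to the 35% prevalence target,
#' with all four severity categories represented.
#'
#' @param n_subjects Cohort size (default 231).
#' @param grid_shape Voxel grid triple; first axis (left/right) must be even.
#' @param severe_fraction_target Intended prevalence of severe aphasia.
#' @param lesion_volume_range Integer interval of lesion sizes in voxels.
#' @param motif_catalog Named list of atrophy motifs, see [atrophy_motif()].
#' @param motif_probs Sampling probabilities over the catalog (recycled
#'   uniform if `NULL`).
#' @param atrophy_voxels Number of GM voxels converted to CSF per subject;
#'   identical for every motif so totals are matched by construction.
#' @param outcome_coefficients Named vector `c(a=, b=, sigma=)` on the 0-100
#'   WAB scale.
#' @param seed Integer master seed; each subject draws from its own stream
#'   derived from `(seed, subject index)`.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 231,
                          grid_shape = c(24, 28, 24),
                          severe_fraction_target = 0.35,
                          lesion_volume_range = c(60, 600),
                          motif_catalog = default_motif_catalog(),
                          motif_probs = NULL,
                          atrophy_voxels = 40,
                          outcome_coefficients = c(a = 290, b = 25, sigma = 8),
                          seed = 1L) {
  stopifnot(n_subjects >= 1, length(grid_shape) == 3)
  if (grid_shape[1] %% 2 != 0)
    stop("cohort_config: left/right axis must be even for a midline split")
  if (severe_fraction_target <= 0 || severe_fraction_target >= 1)
    stop("cohort_config: severe_fraction_target must be in (0,1)")
  stopifnot(length(lesion_volume_range) == 2,
            lesion_volume_range[1] >= 1,
            lesion_volume_range[1] <= lesion_volume_range[2])
  if (length(motif_catalog) < 1) stop("cohort_config: empty motif catalog")
  if (is.null(motif_probs))
    motif_probs <- rep(1 / length(motif_catalog), length(motif_catalog))
  stopifnot(length(motif_probs) == length(motif_catalog),
            all(motif_probs >= 0), sum(motif_probs) > 0)
  co <- outcome_coefficients
  stopifnot(all(is.finite(co)), co[["sigma"]] >= 0)
  structure(list(
    n_subjects = as.integer(n_subjects),
    grid_shape = as.integer(grid_shape),
    severe_fraction_target = severe_fraction_target,
    lesion_volume_range = as.integer(lesion_volume_range),
    motif_catalog = motif_catalog,
    motif_probs = motif_probs / sum(motif_probs),
    atrophy_voxels = as.integer(atrophy_voxels),
    outcome_coefficients = co,
    seed = as.integer(seed)), class = "cohort_config")
}

#' Define a spatial atrophy motif
#'
#' A motif names an arrangement of gray-matter atrophy. `"clustered"` picks a
#' random GM center and converts its nearest GM neighbours; `"dispersed"`
#' scatters the same number of conversions uniformly over GM. Both draw from
#' the same support, so any two motifs at equal `n_voxels` produce volumes
#' with identical global GM counts - only the spatial arrangement differs.
#'
#' @param id Motif name.
#' @param arrangement `"clustered"` or `"dispersed"`.
#' @param harmful Logical; harmful motifs depress the simulated WAB-AQ score
#'   by the outcome coefficient `b`.
#' @return An `atrophy_motif` object.
#' @export
atrophy_motif <- function(id, arrangement = c("clustered", "dispersed"),
                          harmful = FALSE) {
  arrangement <- match.arg(arrangement)
  structure(list(id = id, arrangement = arrangement, harmful = harmful),
            class = "atrophy_motif")
}

#' @rdname atrophy_motif
#' @export
default_motif_catalog <- function() {
  list(
    focal   = atrophy_motif("focal", "clustered", harmful = TRUE),
    diffuse = atrophy_motif("diffuse", "dispersed", harmful = FALSE))
}

#' Deterministic tissue template
#'
#' Builds the mirror-symmetric ordinal tissue template shared by all
#' synthetic subjects: a white-matter core wrapped in a gray-matter shell,
#' cerebrospinal fluid at the ventricles and the brain margin, background
#' outside. The template is deterministic given the grid shape; randomness
#' enters the cohort only through lesions, atrophy and outcomes.
#'
#' @param grid_shape Voxel triple with an even first axis.
#' @param seed Ignored (kept for interface stability); the template is
#'   deterministic.
#' @return A 3D integer array with codes 0 (bg), 1 (CSF), 2 (GM), 3 (WM).
#' @export
generate_tissue_template <- function(grid_shape, seed = NULL) {
  d <- as.integer(grid_shape)
  stopifnot(length(d) == 3)
  if (d[1] %% 2 != 0) stop("generate_tissue_template: first axis must be even")
  ctr <- (d + 1) / 2
  semi <- 0.46 * d
  ax <- lapply(1:3, function(a) (seq_len(d[a]) - ctr[a]) / semi[a])
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  r <- sqrt(r2)
  tpl <- array(0L, d)
  tpl[r <= 1.00] <- 1L            # CSF margin
  tpl[r <= 0.88] <- 2L            # gray-matter shell
  tpl[r <= 0.62] <- 3L            # white-matter core
  tpl[r <= 0.18] <- 1L            # ventricles
  counts <- tabulate(tpl + 1L, 4L)
  if (any(counts[2:4] == 0))
    stop("generate_tissue_template: grid too small to contain all tissue shells")
  tpl
}

left_hemi_mask <- function(d) {
  m <- array(FALSE, d)
  m[seq_len(d[1] %/% 2), , ] <- TRUE
  m
}

#' Sample a connected left-hemisphere lesion
#'
#' Grows a connected region (6-connectivity Eden growth) from a lateral left
#' fronto-temporal seed point, emulating the middle-cerebral-artery territory
#' bias of aphasia-causing strokes. Lesion size is uniform over
#' `volume_range`; only left-hemisphere brain voxels are eligible.
#'
#' @param template Tissue template array (codes 0-3).
#' @param volume_range Integer interval of target sizes in voxels.
#' @param seed Integer seed (omit to use the current RNG state).
#' @return Binary 3D array with the lesion mask.
#' @export
sample_lesion <- function(template, volume_range, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- dim(template)
  eligible <- template != 0 & left_hemi_mask(d)
  n_eligible <- sum(eligible)
  if (volume_range[2] > n_eligible)
    stop("sample_lesion: volume_range exceeds left-hemisphere brain voxels")
  target <- if (volume_range[1] == volume_range[2]) volume_range[1]
            else sample(volume_range[1]:volume_range[2], 1)
  # lateral left fronto-temporal anchor, snapped to the nearest eligible voxel
  anchor <- c(0.15 * d[1], 0.62 * d[2], 0.45 * d[3])
  idx <- which(eligible, arr.ind = TRUE)
  seed_vox <- idx[which.min(colSums((t(idx) - anchor)^2)), ]
  for (attempt in 1:25) {
    sel <- array(FALSE, d)
    sel[seed_vox[1], seed_vox[2], seed_vox[3]] <- TRUE
    frontier <- neighbors6(seed_vox, d)
    frontier <- frontier[eligible[frontier]]
    n_sel <- 1L
    while (n_sel < target && length(frontier) > 0) {
      pick <- frontier[sample.int(length(frontier), 1)]
      frontier <- frontier[frontier != pick]
      if (sel[pick]) next
      sel[pick] <- TRUE
      n_sel <- n_sel + 1L
      pv <- arrayInd(pick, d)
      nb <- neighbors6(pv, d)
      nb <- nb[eligible[nb] & !sel[nb]]
      frontier <- unique(c(frontier, nb))
    }
    if (n_sel == target) return(sel)
  }
  stop("sample_lesion: unreachable target size after bounded attempts")
}

# Linear indices of in-grid 6-neighbors of voxel v = (i,j,k).
neighbors6 <- function(v, d) {
  offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  nb <- sweep(offs, 2, as.numeric(v), `+`)
  ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
  nb <- nb[ok, , drop = FALSE]
  nb[, 1] + d[1] * (nb[, 2] - 1) + d[1] * d[2] * (nb[, 3] - 1)
}

#' Plant a gray-matter atrophy motif
#'
#' Converts exactly `n_voxels` gray-matter voxels to CSF inside the motif's
#' spatial support. Clustered motifs convert the neighbourhood of a random GM
#' center; dispersed motifs scatter conversions uniformly over GM. All other
#' voxels are untouched, so atrophy totals are matched exactly across motifs.
#'
#' @param template Tissue template array (codes 0-3).
#' @param motif An [atrophy_motif()].
#' @param n_voxels Number of GM voxels to convert.
#' @param seed Integer seed (omit to use the current RNG state).
#' @return The template with atrophy planted.
#' @export
plant_atrophy <- function(template, motif, n_voxels, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_voxels == 0) return(template)
  gm <- which(template == 2L)
  if (length(gm) < n_voxels)
    stop("plant_atrophy: insufficient GM voxels in motif support")
  if (motif$arrangement == "dispersed") {
    chosen <- sample(gm, n_voxels)
  } else {
    d <- dim(template)
    center <- arrayInd(gm[sample.int(length(gm), 1)], d)
    coords <- arrayInd(gm, d)
    dist2 <- colSums((t(coords) - as.numeric(center))^2)
    chosen <- gm[order(dist2)[seq_len(n_voxels)]]
  }
  out <- template
  out[chosen] <- 1L
  out
}

#' Simulate a WAB-AQ-like outcome
#'
#' @param lesion_volume Lesion size in voxels.
#' @param motif An [atrophy_motif()] (its `harmful` flag enters the model).
#' @param config A [cohort_config()].
#' @param n_left_brain Number of left-hemisphere brain voxels (normalises the
#'   lesion volume).
#' @param seed Integer seed (omit to use the current RNG state).
#' @return List with `wab_aq`, `category4`, `label2`.
#' @export
assign_outcome <- function(lesion_volume, motif, config, n_left_brain,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  co <- config$outcome_coefficients
  frac <- lesion_volume / n_left_brain
  raw <- 100 - co[["a"]] * frac - co[["b"]] * as.numeric(motif$harmful) +
    rnorm(1, 0, co[["sigma"]])
  wab <- min(100, max(0, raw))
  list(wab_aq = wab, category4 = wab_category(wab),
       label2 = if (wab <= 50) "severe" else "nonsevere")
}

#' @rdname assign_outcome
#' @param wab_aq Aphasia-quotient score in \[0, 100\].
#' @export
wab_category <- function(wab_aq) {
  cut(wab_aq, breaks = c(-Inf, 25, 50, 75, Inf),
      labels = c("very severe", "severe", "moderate", "mild")) |>
    as.character()
}

#' Generate a synthetic cohort
#'
#' Draws `n_subjects` subjects, each from an independent RNG stream derived
#' from `(seed, subject index)`: motif assignment, lesion growth, atrophy
#' planting and outcome. The motif assignment is recorded as ground truth for
#' recovery tests.
#'
#' @param config A [cohort_config()].
#' @return An `aphasia_cohort`: list with `subjects`, `config`, `template`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  tpl <- generate_tissue_template(config$grid_shape)
  n_left <- sum(tpl != 0 & left_hemi_mask(dim(tpl)))
  if (config$lesion_volume_range[2] > n_left)
    stop("generate_cohort: lesion_volume_range exceeds left-hemisphere brain")
  subjects <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    set.seed(derive_seed(config$seed, i))
    motif_ix <- sample.int(length(config$motif_catalog), 1,
                           prob = config$motif_probs)
    motif <- config$motif_catalog[[motif_ix]]
    atro <- plant_atrophy(tpl, motif, config$atrophy_voxels)
    lesion <- sample_lesion(tpl, config$lesion_volume_range)
    vol <- merge_tissue_and_lesion(atro, lesion)
    out <- assign_outcome(sum(lesion), motif, config, n_left)
    subjects[[i]] <- structure(list(
      id = sprintf("sub-%04d", i),
      volume = vol,
      lesion_mask = lesion,
      lesion_volume = sum(lesion),
      motif_id = motif$id,
      wab_aq = out$wab_aq,
      category4 = out$category4,
      label2 = out$label2), class = "synthetic_subject")
  }
  structure(list(subjects = subjects, config = config, template = tpl),
            class = "aphasia_cohort")
}

#' Tabulate cohort phenotypes
#'
#' @param cohort An `aphasia_cohort`.
#' @return data.frame with one row per subject.
#' @export
cohort_table <- function(cohort) {
  data.frame(
    subject_id = vapply(cohort$subjects, `[[`, "", "id"),
    wab_aq = vapply(cohort$subjects, `[[`, 0, "wab_aq"),
    category4 = vapply(cohort$subjects, `[[`, "", "category4"),
    label2 = vapply(cohort$subjects, `[[`, "", "label2"),
    lesion_volume = vapply(cohort$subjects, `[[`, 0L, "lesion_volume"),
    motif_id = vapply(cohort$subjects, `[[`, "", "motif_id"),
    stringsAsFactors = FALSE)
}

#' Extract scaled volumes from a cohort
#'
#' Applies [scale_minmax()] to every subject volume and returns the scaled
#' grids as a list of 3D arrays (the CNN input representation).
#'
#' @param cohort An `aphasia_cohort`.
#' @return List of 3D arrays in `[-1, 1]`.
#' @export
cohort_scaled_volumes <- function(cohort) {
  lapply(cohort$subjects, function(s) scale_minmax(s$volume)$scaled)
}

#' Write / read a cohort as NIfTI + CSV + JSON sidecar
#'
#' One int16 NIfTI volume per subject, a phenotype CSV, and a JSON sidecar
#' with the generating configuration (motif catalog flattened to descriptors).
#'
#' @param cohort An `aphasia_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$subjects)
    write_volume_nifti(s$volume, file.path(dir, paste0(s$id, ".nii.gz")))
  write.csv(cohort_table(cohort), file.path(dir, "participants.csv"),
            row.names = FALSE)
  cfg <- cohort$config
  cfg$motif_catalog <- lapply(cfg$motif_catalog, unclass)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
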