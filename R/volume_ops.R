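#' Ordinal morphometry volumes
#'
#' A `morph_volume` is a 3D grid of ordinal tissue codes on a common voxel
#' lattice: 0 background, 1 cerebrospinal fluid, 2 gray matter, 3 white
#' matter, 4 lesion. The first array axis is the left/right axis; the left
#' hemisphere occupies the lower half of that axis and the midsagittal plane
#' lies between columns `d1/2` and `d1/2 + 1`. A `scaled` copy in `[-1, 1]`
#' (the affine image `code/2 - 1`) is attached by [scale_minmax()] and is what
#' the classifiers consume.
#'
#' @param grid 3D integer array with codes in `0:4`.
#' @param voxel_size_mm Isotropic voxel size in millimetres.
#' @param orientation Axis descriptor; only `"LR"` (first axis left-to-right)
#'   is supported.
#' @return An object of class `morph_volume`.
#' @export
morph_volume <- function(grid, voxel_size_mm = 8, orientation = "LR") {
  stopifnot(length(dim(grid)) == 3)
  if (!all(grid %in% 0:4)) stop("morph_volume: codes must be in 0..4")
  structure(
    list(grid = grid, voxel_size_mm = voxel_size_mm,
         orientation = orientation, scaled = NULL),
    class = "morph_volume")
}

as_grid <- function(v) if (inherits(v, "morph_volume")) v$grid else v

#' @export
print.morph_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<morph_volume %dx%dx%d @ %g mm%s>\n", d[1], d[2], d[3],
              x$voxel_size_mm, if (!is.null(x$scaled)) ", scaled" else ""))
  tab <- table(factor(x$grid, levels = 0:4))
  names(tab) <- c("bg", "CSF", "GM", "WM", "lesion")
  print(tab)
  invisible(x)
}

#' Merge tissue codes with a lesion mask
#'
#' Voxels inside the lesion mask are assigned the 4th tissue value (code 4);
#' the lesion supersedes all tissue classes.
#'
#' @param tissue_grid 3D array of codes in `0:3` (or a `morph_volume`).
#' @param lesion_mask Binary 3D array of the same shape.
#' @param voxel_size_mm Voxel size carried into the result.
#' @return A `morph_volume` with codes in `0:4`.
#' @export
merge_tissue_and_lesion <- function(tissue_grid, lesion_mask, voxel_size_mm = 8) {
  g <- as_grid(tissue_grid)
  if (!identical(dim(g), dim(lesion_mask)))
    stop("merge_tissue_and_lesion: shape mismatch")
  m <- lesion_mask != 0
  out <- g
  out[m] <- 4L
  morph_volume(out, voxel_size_mm)
}

#' Enantiomorphic healing on the voxel grid
#'
#' Replaces tissue inside the (dilated) lesion mask with the value found at
#' the mirror position across the midsagittal plane, emulating the healing of
#' unilateral lesions with intact contralateral tissue.
#'
#' @param volume A `morph_volume` or 3D code array.
#' @param lesion_mask Binary 3D array; must be confined to one hemisphere
#'   (not enforced, but reflection then overwrites contralateral tissue).
#' @param smooth_radius Number of dilation steps applied to the mask before
#'   replacement (26-connectivity); 0 uses the raw mask.
#' @return A `morph_volume` with the lesion healed.
#' @export
enantiomorphic_fill <- function(volume, lesion_mask, smooth_radius = 1) {
  g <- as_grid(volume)
  if (!identical(dim(g), dim(lesion_mask)))
    stop("enantiomorphic_fill: shape mismatch")
  m <- dilate_mask(lesion_mask, smooth_radius)
  mg <- mirror_lr(g)
  out <- g
  out[m] <- mg[m]
  v <- morph_volume(out, if (inherits(volume, "morph_volume")) volume$voxel_size_mm else 8)
  v
}

#' Downsample an ordinal volume by modal pooling
#'
#' Each output voxel takes the modal code of its `factor^3` block; ties are
#' broken in favour of the larger code (lesion > WM > GM > CSF > background),
#' so rarer, clinically salient classes survive pooling. Partial edge blocks
#' use the voxels available.
#'
#' @param volume A `morph_volume` or 3D code array.
#' @param factor Integer downsampling factor (>= 1).
#' @return A `morph_volume` with voxel size multiplied by `factor`.
#' @export
downsample_mode <- function(volume, factor) {
  stopifnot(factor >= 1, factor == round(factor))
  g <- as_grid(volume)
  vs <- if (inherits(volume, "morph_volume")) volume$voxel_size_mm else 8
  if (factor == 1) return(morph_volume(g, vs))
  d <- dim(g)
  od <- ceiling(d / factor)
  out <- array(0L, od)
  for (k in seq_len(od[3])) for (j in seq_len(od[2])) for (i in seq_len(od[1])) {
    bi <- ((i - 1) * factor + 1):min(i * factor, d[1])
    bj <- ((j - 1) * factor + 1):min(j * factor, d[2])
    bk <- ((k - 1) * factor + 1):min(k * factor, d[3])
    block <- g[bi, bj, bk]
    counts <- tabulate(block + 1L, nbins = 5L)
    # which.max returns the first maximum; reverse so ties go to larger codes
    out[i, j, k] <- 5L - which.max(rev(counts))
  }
  morph_volume(out, vs * factor)
}

#' Crop a cohort to its common non-empty field of view
#'
#' Removes leading/trailing planes along each axis that are background
#' (code 0) in every subject; the same crop box is applied to all volumes.
#'
#' @param volumes List of `morph_volume`s (or 3D code arrays) sharing a shape.
#' @return List of cropped `morph_volume`s.
#' @export
crop_common <- function(volumes) {
  if (length(volumes) == 0) stop("crop_common: empty cohort")
  grids <- lapply(volumes, as_grid)
  d <- dim(grids[[1]])
  if (!all(vapply(grids, function(g) identical(dim(g), d), logical(1))))
    stop("crop_common: volumes must share a shape")
  occupied <- Reduce(`|`, lapply(grids, function(g) g != 0))
  rng <- lapply(1:3, function(ax) {
    pres <- apply(occupied, ax, any)
    if (!any(pres)) stop("crop_common: cohort entirely background")
    range(which(pres))
  })
  lapply(seq_along(volumes), function(s) {
    vs <- if (inherits(volumes[[s]], "morph_volume")) volumes[[s]]$voxel_size_mm else 8
    morph_volume(grids[[s]][rng[[1]][1]:rng[[1]][2],
                            rng[[2]][1]:rng[[2]][2],
                            rng[[3]][1]:rng[[3]][2], drop = FALSE], vs)
  })
}

#' Scale ordinal codes to \[-1, 1\]
#'
#' Attaches the affine image of the codes with 0 mapping to -1 and the
#' maximum code 4 mapping to +1 (`code/2 - 1`).
#'
#' @param volume A `morph_volume` or 3D code array.
#' @return A `morph_volume` with the `scaled` field populated.
#' @export
scale_minmax <- function(volume) {
  g <- as_grid(volume)
  if (!all(g %in% 0:4)) stop("scale_minmax: codes out of range 0..4")
  v <- if (inherits(volume, "morph_volume")) volume
       else morph_volume(g)
  v$scaled <- g / 2 - 1
  v
}

#' Read / write morphometry volumes as NIfTI
#'
#' Codes are stored as int16; scaled grids (when present) as float32 next to
#' the codes with suffix `_scaled`.
#'
#' @param volume A `morph_volume`.
#' @param path Output `.nii.gz`/`.nii` path.
#' @return `write_volume_nifti` returns `path` invisibly; `read_volume_nifti`
#'   returns a `morph_volume`.
#' @export
write_volume_nifti <- function(volume, path) {
  arr <- array(as.integer(volume$grid), dim(volume$grid))
  attr(arr, "pixdim") <- rep(volume$voxel_size_mm, 3)
  img <- RNifti::asNifti(arr, datatype = "int16")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1]
  morph_volume(array(as.integer(img), dim(img)[1:3]), voxel_size_mm = vs)
}
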