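#' @useDynLib aphasiamorph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd t.test cor cor.test pt quantile median prcomp predict setNames
#' @importFrom utils head write.csv read.csv
NULL

# Deterministic per-stream seed derived from (seed, index); kept < 2^31.
derive_seed <- function(seed, index) {
  ((as.double(seed) %% 1e6) * 104729 + as.double(index) * 7919 + 1) %% 2147483647
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Hash an R object
#'
#' Stable content hash used to assert that independent pipeline stages consume
#' byte-identical inputs (e.g. the shared cross-validation plan).
#'
#' @param x Any R object.
#' @return A character scalar.
#' @export
object_hash <- function(x) rlang::hash(x)

# Mirror a 3D array across the midsagittal plane (first axis = left/right).
mirror_lr <- function(arr) {
  arr[dim(arr)[1]:1, , , drop = FALSE]
}

# Binary dilation of a 3D logical/0-1 mask by `radius` steps.
# connectivity 26 dilates with the full 3x3x3 structuring element,
# connectivity 6 with the face-neighbor cross.
dilate_mask <- function(mask, radius, connectivity = 26) {
  if (radius <= 0) return(mask != 0)
  d <- dim(mask)
  m <- mask != 0
  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  if (connectivity == 6) {
    keep <- (abs(offs$di) + abs(offs$dj) + abs(offs$dk)) == 1
    offs <- offs[keep, ]
  } else {
    offs <- offs[!(offs$di == 0 & offs$dj == 0 & offs$dk == 0), ]
  }
  for (r in seq_len(radius)) {
    grown <- m
    for (t in seq_len(nrow(offs))) {
      sh <- shift_mask(m, offs$di[t], offs$dj[t], offs$dk[t])
      grown <- grown | sh
    }
    m <- grown
  }
  m
}

# Shift a 3D logical array by (di,dj,dk), zero-filling.
shift_mask <- function(m, di, dj, dk) {
  d <- dim(m)
  out <- array(FALSE, d)
  i1 <- max(1, 1 - di); i2 <- min(d[1], d[1] - di)
  j1 <- max(1, 1 - dj); j2 <- min(d[2], d[2] - dj)
  k1 <- max(1, 1 - dk); k2 <- min(d[3], d[3] - dk)
  if (i1 > i2 || j1 > j2 || k1 > k2) return(out)
  out[(i1:i2) + di, (j1:j2) + dj, (k1:k2) + dk] <- m[i1:i2, j1:j2, k1:k2]
  out
}

# Trilinear upsampling of a 3D array to target dims (align-corners style).
upsample_trilinear <- function(arr, out_dims) {
  d <- dim(arr)
  coords <- lapply(1:3, function(ax) {
    if (out_dims[ax] == 1) rep(1, 1)
    else 1 + (seq_len(out_dims[ax]) - 1) * (d[ax] - 1) / (out_dims[ax] - 1)
  })
  interp_axis <- function(x, co, axis) {
    lo <- floor(co); hi <- pmin(lo + 1, dim(x)[axis]); w <- co - lo
    idx <- function(i) switch(axis,
      x[i, , , drop = FALSE], x[, i, , drop = FALSE], x[, , i, drop = FALSE])
    a <- idx(lo); b <- idx(hi)
    # broadcast weights along the chosen axis
    warr <- array(0, dim(a))
    if (axis == 1) { for (i in seq_along(co)) warr[i, , ] <- w[i] }
    if (axis == 2) { for (i in seq_along(co)) warr[, i, ] <- w[i] }
    if (axis == 3) { for (i in seq_along(co)) warr[, , i] <- w[i] }
    a * (1 - warr) + b * warr
  }
  out <- arr
  for (ax in 1:3) out <- interp_axis(out, coords[[ax]], ax)
  out
}
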