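#' Resample a CT volume to isotropic resolution
#'
#' CT series differ in slice thickness and in-plane resolution, so volumes
#' are resampled to a common isotropic grid (1.0 mm by default) before
#' patch extraction and network training. Output dimensions are
#' `round(dim * spacing / target)` (at least 1 per axis); intensities are
#' interpolated trilinearly, label masks with nearest neighbour. The world
#' origin is preserved.
#'
#' @param volume A [ct_volume].
#' @param target_mm Target spacing in mm (> 0), applied to all three axes.
#' @param method `"trilinear"` (intensity images) or `"nearest"` (masks).
#' @return A resampled [ct_volume].
#' @export
resample_isotropic <- function(volume, target_mm = 1.0, method = c("trilinear", "nearest")) {
  stopifnot(inherits(volume, "ct_volume"))
  method <- match.arg(method)
  if (!is.numeric(target_mm) || length(target_mm) != 1L || target_mm <= 0)
    abort("`target_mm` must be a single positive number.")
  din <- dim(volume$voxels)
  dout <- pmax(1L, as.integer(round(din * volume$spacing / target_mm)))
  # continuous source index for each output index, per axis
  src <- lapply(1:3, function(a) (seq_len(dout[a]) - 1) * target_mm / volume$spacing[a])
  arr <- .interp3(volume$voxels, src[[1]], src[[2]], src[[3]], method)
  ct_volume(arr, spacing = rep(target_mm, 3), origin = volume$origin,
            series_id = volume$series_id)
}

# Separable gather interpolation on a (z,y,x) array at continuous 0-based
# per-axis coordinates (full tensor grid).
.interp3 <- function(vol, zi, yi, xi, method) {
  d <- dim(vol)
  if (method == "nearest") {
    iz <- pmin(pmax(round(zi), 0), d[1] - 1) + 1L
    iy <- pmin(pmax(round(yi), 0), d[2] - 1) + 1L
    ix <- pmin(pmax(round(xi), 0), d[3] - 1) + 1L
    return(vol[iz, iy, ix, drop = FALSE])
  }
  lo <- function(ci, n) pmin(pmax(floor(ci), 0), n - 1)
  z0 <- lo(zi, d[1]); y0 <- lo(yi, d[2]); x0 <- lo(xi, d[3])
  z1 <- pmin(z0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1); x1 <- pmin(x0 + 1, d[3] - 1)
  fz <- pmin(pmax(zi - z0, 0), 1); fy <- pmin(pmax(yi - y0, 0), 1); fx <- pmin(pmax(xi - x0, 0), 1)
  nz <- length(zi); ny <- length(yi); nx <- length(xi)
  g <- function(iz, iy, ix) vol[iz + 1L, iy + 1L, ix + 1L, drop = FALSE]
  Fz <- array(fz, c(nz, ny, nx))
  Fy <- aperm(array(fy, c(ny, nz, nx)), c(2, 1, 3))
  Fx <- aperm(array(fx, c(nx, nz, ny)), c(2, 3, 1))
  c00 <- g(z0, y0, x0) * (1 - Fz) + g(z1, y0, x0) * Fz
  c10 <- g(z0, y1, x0) * (1 - Fz) + g(z1, y1, x0) * Fz
  c01 <- g(z0, y0, x1) * (1 - Fz) + g(z1, y0, x1) * Fz
  c11 <- g(z0, y1, x1) * (1 - Fz) + g(z1, y1, x1) * Fz
  c0 <- c00 * (1 - Fy) + c10 * Fy
  c1 <- c01 * (1 - Fy) + c11 * Fy
  c0 * (1 - Fx) + c1 * Fx
}

#' Standardize volume intensities
#'
#' Linearly maps voxel values to `(value - mean) / std`, the gray-value
#' standardization applied before network training. Use the dataset-global
#' training mean/std (the default workflow) or a volume's own statistics
#' via [volume_stats()].
#'
#' @param volume A [ct_volume].
#' @param mean,std Standardization constants; `std` must be > 0.
#' @return A standardized [ct_volume].
#' @export
standardize_intensity <- function(volume, mean, std) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!is.numeric(std) || length(std) != 1L || !is.finite(std) || std <= 0)
    abort("`std` must be a single positive number.")
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean))
    abort("`mean` must be a single finite number.")
  out <- volume
  out$voxels <- (volume$voxels - mean) / std
  out
}

#' Intensity statistics of one or more volumes
#'
#' Pooled mean and standard deviation over every voxel of the supplied
#' volumes, the "dataset-global" statistics used for standardization.
#'
#' @param volumes A [ct_volume] or list of them.
#' @return A tibble with columns `mean`, `std`, `n_voxels`.
#' @export
volume_stats <- function(volumes) {
  if (inherits(volumes, "ct_volume")) volumes <- list(volumes)
  vals_n <- sum(vapply(volumes, function(v) length(v$voxels), numeric(1)))
  s1 <- sum(vapply(volumes, function(v) sum(v$voxels), numeric(1)))
  s2 <- sum(vapply(volumes, function(v) sum(v$voxels^2), numeric(1)))
  m <- s1 / vals_n
  tibble(mean = m, std = sqrt(pmax(s2 / vals_n - m^2, 0)), n_voxels = vals_n)
}

#' Extract a fixed-size 3-D patch around a voxel
#'
#' Cuts a block of `shape` voxels (stated in `(x, y, z)` order; the default
#' 40 x 40 x 26 block is sized to contain any annotated nodule) centred on
#' `center`. The centre voxel lands at index `floor(shape / 2)` per axis.
#' Voxels outside the grid are filled with `pad_value` (-1000, i.e. air).
#'
#' @param volume A [ct_volume].
#' @param center 0-based voxel index triple `(z, y, x)`; must be inside the
#'   grid.
#' @param shape Integer triple `(x, y, z)`; default `c(40, 40, 26)`.
#' @param pad_value Fill value for out-of-grid voxels.
#' @param label Optional binary 3-D array shaped like the volume; the
#'   matching patch is attached as the patch label.
#' @return A `ct_patch`: list with `voxels` (dim `(z, y, x)`), optional
#'   `label`, `source_series`, `source_center`.
#' @export
extract_patch <- function(volume, center, shape = c(40, 40, 26),
                          pad_value = -1000, label = NULL) {
  stopifnot(inherits(volume, "ct_volume"))
  d <- dim(volume$voxels)
  center <- as.integer(round(center))
  if (length(center) != 3L || any(center < 0) || any(center >= d))
    abort("`center` must be a 0-based (z, y, x) voxel index inside the grid.")
  shp_zyx <- rev(as.integer(shape))
  if (length(shp_zyx) != 3L || any(shp_zyx < 1))
    abort("`shape` must be 3 positive integers (x, y, z).")
  start <- center - shp_zyx %/% 2L  # 0-based start
  idx <- lapply(1:3, function(a) start[a] + seq_len(shp_zyx[a]) - 1L)
  inb <- lapply(1:3, function(a) idx[[a]] >= 0L & idx[[a]] < d[a])
  out <- array(pad_value, dim = shp_zyx)
  sub <- volume$voxels[idx[[1]][inb[[1]]] + 1L, idx[[2]][inb[[2]]] + 1L,
                       idx[[3]][inb[[3]]] + 1L, drop = FALSE]
  out[inb[[1]], inb[[2]], inb[[3]]] <- sub
  patch <- list(voxels = out, label = NULL, source_series = volume$series_id,
                source_center = center)
  if (!is.null(label)) {
    stopifnot(identical(dim(label), d))
    lab <- array(0, dim = shp_zyx)
    lab[inb[[1]], inb[[2]], inb[[3]]] <-
      label[idx[[1]][inb[[1]]] + 1L, idx[[2]][inb[[2]]] + 1L,
            idx[[3]][inb[[3]]] + 1L, drop = FALSE]
    patch$label <- lab
  }
  structure(patch, class = "ct_patch")
}
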