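# R-level wrappers around the C++ morphology cores. Masks are logical or
# 0/1 numeric 3-D arrays in (z, y, x) order; structuring elements are offset
# matrices in the same order.

#' Structuring-element offset matrices
#'
#' `se_ball()` returns the voxel offsets of a 3-D ball of radius `r_mm`
#' given per-axis spacing (mm); `se_disc()` the offsets of a 2-D disc in
#' the axial (y, x) plane (zero z offset), which makes every morphology
#' call that uses it slice-wise.
#'
#' @param r_mm Radius in millimetres.
#' @param spacing Voxel spacing `(z, y, x)` in mm.
#' @return Integer matrix with columns `(dz, dy, dx)`.
#' @export
se_ball <- function(r_mm, spacing = c(1, 1, 1)) {
  r <- ceiling(r_mm / spacing)
  g <- expand.grid(dz = -r[1]:r[1], dy = -r[2]:r[2], dx = -r[3]:r[3])
  keep <- (g$dz * spacing[1])^2 + (g$dy * spacing[2])^2 + (g$dx * spacing[3])^2 <= r_mm^2
  as.matrix(g[keep, , drop = FALSE])
}

#' @rdname se_ball
#' @export
se_disc <- function(r_mm, spacing = c(1, 1, 1)) {
  r <- ceiling(r_mm / spacing[2:3])
  g <- expand.grid(dz = 0L, dy = -r[1]:r[1], dx = -r[2]:r[2])
  keep <- (g$dy * spacing[2])^2 + (g$dx * spacing[3])^2 <= r_mm^2
  as.matrix(g[keep, , drop = FALSE])
}

.as_mask <- function(x) {
  if (is.logical(x)) x else array(x != 0, dim = dim(x))
}

#' Label connected components of a binary mask
#'
#' @param mask Logical/0-1 3-D array `(z, y, x)`.
#' @param connectivity 26 (default) or 6. A single-slice array with
#'   26-connectivity reduces to the usual 2-D 8-connectivity.
#' @return Integer array of component labels (0 = background), numbered in
#'   scan order.
#' @export
label_components <- function(mask, connectivity = 26) {
  m <- .as_mask(mask)
  d <- dim(m)
  lab <- cpp_label(as.logical(m), d[1], d[2], d[3], as.integer(connectivity))
  array(lab, dim = d)
}

#' Component voxel counts, largest first
#'
#' @param labels Integer label array from [label_components()].
#' @return Tibble with columns `label`, `voxels`, sorted by decreasing size.
#' @export
component_sizes <- function(labels) {
  tab <- tabulate(labels[labels > 0])
  if (!length(tab)) return(tibble(label = integer(), voxels = integer()))
  tibble(label = seq_along(tab), voxels = tab) |> arrange(desc(.data$voxels))
}

.binary_morph <- function(mask, se, dilate) {
  m <- .as_mask(mask)
  d <- dim(m)
  out <- cpp_binary_morph(as.logical(m), d[1], d[2], d[3],
                          apply(se, 2, as.integer), dilate)
  array(out, dim = d)
}

#' Binary morphology with an explicit structuring element
#'
#' `binary_close()` guarantees extensivity (`output >= input`) by
#' OR-combining the closing with its input, so border effects never remove
#' original voxels.
#'
#' @param mask Logical/0-1 3-D array.
#' @param se Offset matrix from [se_ball()]/[se_disc()].
#' @return Logical array of the same shape.
#' @export
binary_dilate <- function(mask, se) .binary_morph(mask, se, TRUE)

#' @rdname binary_dilate
#' @export
binary_erode <- function(mask, se) .binary_morph(mask, se, FALSE)

#' @rdname binary_dilate
#' @export
binary_close <- function(mask, se) {
  closed <- binary_erode(binary_dilate(mask, se), -se)
  closed | .as_mask(mask)
}

#' @rdname binary_dilate
#' @export
binary_open <- function(mask, se) binary_dilate(binary_erode(mask, se), -se)

.gray_morph <- function(vol, se, dilate) {
  d <- dim(vol)
  out <- cpp_gray_morph(as.numeric(vol), d[1], d[2], d[3],
                        apply(se, 2, as.integer), dilate)
  array(out, dim = d)
}

#' Grayscale morphology and closing-by-reconstruction
#'
#' `gray_close()` is dilation followed by erosion (with the reflected
#' element). `gray_reconstruct_erosion()` performs morphological
#' reconstruction by erosion of `marker` constrained from below by `mask`
#' (6-connected geodesic erosion iterated to stability); the result lies
#' between `mask` and `marker` at every voxel.
#'
#' @param vol,marker,mask Numeric 3-D arrays.
#' @param se Offset matrix.
#' @return Numeric array of the same shape.
#' @export
gray_dilate <- function(vol, se) .gray_morph(vol, se, TRUE)

#' @rdname gray_dilate
#' @export
gray_erode <- function(vol, se) .gray_morph(vol, se, FALSE)

#' @rdname gray_dilate
#' @export
gray_close <- function(vol, se) gray_erode(gray_dilate(vol, se), -se)

#' @rdname gray_dilate
#' @export
gray_reconstruct_erosion <- function(marker, mask, max_pass = 1000) {
  stopifnot(identical(dim(marker), dim(mask)))
  d <- dim(marker)
  out <- cpp_reconstruct_erosion(as.numeric(marker), as.numeric(mask),
                                 d[1], d[2], d[3], as.integer(max_pass))
  array(out, dim = d)
}

#' Fill enclosed holes of a mask, slice by slice
#'
#' Background regions of each axial slice that are not 4-connected to the
#' slice border become foreground.
#'
#' @param mask Logical/0-1 3-D array `(z, y, x)`.
#' @return Logical array.
#' @export
fill_holes_slicewise <- function(mask) {
  m <- .as_mask(mask)
  d <- dim(m)
  array(cpp_fill_holes_slices(as.logical(m), d[1], d[2], d[3]), dim = d)
}

#' Seeded region growing below an intensity threshold
#'
#' 6-connected flood from the seed voxels over all voxels with intensity
#' `<= threshold`; the primitive underlying optimal-threshold trachea
#' growing.
#'
#' @param vol Numeric 3-D array.
#' @param seeds Matrix of 0-based `(z, y, x)` seed indices (or one triple).
#' @param threshold Intensity threshold.
#' @return Logical array of grown voxels.
#' @export
region_grow <- function(vol, seeds, threshold) {
  d <- dim(vol)
  s <- matrix(as.integer(seeds), ncol = 3)
  linear <- s[, 1] + d[1] * (s[, 2] + d[2] * s[, 3])
  out <- cpp_region_grow(as.numeric(vol), d[1], d[2], d[3],
                         as.integer(linear), threshold)
  array(out, dim = d)
}

#' Remove components smaller than a voxel-count threshold
#'
#' @param mask Logical/0-1 3-D array.
#' @param min_voxels Minimum size to keep.
#' @param keep_largest Always retain at least this many largest components.
#' @param connectivity Passed to [label_components()].
#' @return Logical array.
#' @export
remove_small_components <- function(mask, min_voxels, keep_largest = 0,
                                    connectivity = 26) {
  lab <- label_components(mask, connectivity)
  sz <- component_sizes(lab)
  if (!nrow(sz)) return(.as_mask(mask))
  keep <- sz$label[sz$voxels >= min_voxels]
  if (keep_largest > 0)
    keep <- union(keep, head(sz$label, keep_largest))
  array(lab %in% keep, dim = dim(lab))
}
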