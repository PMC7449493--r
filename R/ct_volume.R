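#' CT volume container
#'
#' A `ct_volume` holds a 3-D scalar voxel grid together with the geometry
#' needed to map voxel indices to world (scanner) coordinates. The voxel
#' array uses index order `(z, y, x)` with 0-based indices in all geometry
#' computations, matching the convention of public `.mhd` lung-CT datasets;
#' spacing and origin are stored in the same `(z, y, x)` order, in
#' millimetres. Intensities are Hounsfield-like signed reals (air about
#' -1000 HU, lung parenchyma about -800 HU, soft tissue about +40 HU).
#'
#' @param voxels 3-D numeric array, index order `(z, y, x)`.
#' @param spacing Numeric length-3, mm per voxel along `(z, y, x)`; all > 0.
#' @param origin Numeric length-3, world-mm coordinate of voxel `(0, 0, 0)`
#'   along `(z, y, x)`.
#' @param series_id Opaque identifier string.
#'
#' @return An object of class `ct_volume`.
#' @export
#' @examples
#' v <- ct_volume(array(0, c(4, 5, 6)), spacing = c(2.5, 0.7, 0.7))
#' dim(v$voxels)
ct_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      series_id = "volume") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    abort("`voxels` must be a 3-D array (z, y, x).")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    abort("`spacing` must be 3 strictly positive numbers (z, y, x).")
  if (length(origin) != 3L || any(!is.finite(origin)))
    abort("`origin` must be 3 finite numbers (z, y, x).")
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin,
         series_id = as.character(series_id)),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %s\n", x$series_id))
  cat(sprintf("  dims (z,y,x): %d x %d x %d\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing (mm): %.4g x %.4g x %.4g\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (mm):  %.4g, %.4g, %.4g\n",
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  intensity:    [%.4g, %.4g]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Convert between voxel indices and world coordinates
#'
#' Voxel indices are 0-based `(z, y, x)` triples; world coordinates are in
#' millimetres. `voxel_to_world()` computes `origin + index * spacing`;
#' `world_to_voxel()` inverts it. Both accept a matrix (one triple per row)
#' or a single triple.
#'
#' @param volume A [ct_volume].
#' @param index,world Numeric triple or matrix of triples, `(z, y, x)` order.
#' @return Matrix of converted triples, `(z, y, x)` order.
#' @export
voxel_to_world <- function(volume, index) {
  m <- matrix(as.numeric(index), ncol = 3)
  sweep(sweep(m, 2, volume$spacing, "*"), 2, volume$origin, "+")
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(volume, world) {
  m <- matrix(as.numeric(world), ncol = 3)
  sweep(sweep(m, 2, volume$origin, "-"), 2, volume$spacing, "/")
}

#' Reorder a world-mm (x, y, z) triple to internal (z, y, x) order
#'
#' Annotation CSVs use the LUNA16/TIANCHI world-coordinate order
#' `(coordX, coordY, coordZ)`; internal geometry is `(z, y, x)`. These
#' helpers make the conversion explicit.
#'
#' @param xyz,zyx Numeric triple or matrix of triples.
#' @return Reordered triple(s).
#' @export
xyz_to_zyx <- function(xyz) {
  m <- matrix(as.numeric(xyz), ncol = 3)
  m[, c(3, 2, 1), drop = FALSE]
}

#' @rdname xyz_to_zyx
#' @export
zyx_to_xyz <- function(zyx) xyz_to_zyx(zyx)
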