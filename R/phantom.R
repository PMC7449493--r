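#' Specify a synthetic thorax phantom
#'
#' Builds the parameter set for a stylized thorax CT volume: an air
#' background, an elliptical body with a thin bright bone ring, two
#' ellipsoidal low-intensity lungs, a vertical air-filled trachea with
#' optional detached bronchus stubs (each airway wrapped in a thin
#' soft-tissue wall so airway and parenchyma stay separate structures, as
#' the bronchial wall does anatomically), bright spherical nodules, an
#' optional lung-density bridge fusing the two lungs, and an optional
#' bright pleural indentation that carves a wall-adjacent concavity.
#' Default geometry is 1 mm isotropic so radii in mm map 1:1 to voxels.
#'
#' Default intensity levels follow clinical CT: air -1000, lung parenchyma
#' -800, soft tissue +40, bone +700; nodules sit `contrast` above the lung
#' level (default +700, i.e. about -100, a solid nodule). Gaussian noise of
#' sd `noise_sigma` is added last; the default phantom is noiseless, which
#' is the reference condition for the segmentation checks.
#'
#' @param dims Grid dims `(z, y, x)`; default `c(64, 96, 120)`.
#' @param spacing Voxel spacing mm `(z, y, x)`; default 1 mm isotropic.
#' @param nodules Tibble of nodule specs from [nodule_spec()]; diameters
#'   must lie in the annotated 3-30 mm range.
#' @param fused Insert a lung-density bridge joining the lungs.
#' @param pleural_notch Carve a bright wall-adjacent concavity (radius
#'   `notch_radius_mm`) into the right lung.
#' @param notch_radius_mm Radius of the pleural notch (must stay below the
#'   rolling-ball radius for the repair stage to fill it).
#' @param n_bronchi Number of bronchus stubs (0, 1 or 2).
#' @param noise_sigma Gaussian noise sd (>= 0).
#' @param levels Named intensity levels (`air`, `lung`, `body`, `bone`).
#' @param body_semiaxes,lung_semiaxes,lung_offset_x,trachea_radius_mm,bronchus_radius_mm
#'   Geometry knobs (voxels at unit spacing / mm).
#' @param seed Integer RNG seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(dims = c(64, 96, 120),
                         spacing = c(1, 1, 1),
                         nodules = nodule_spec(),
                         fused = FALSE,
                         pleural_notch = FALSE,
                         notch_radius_mm = 5,
                         n_bronchi = 2,
                         noise_sigma = 0,
                         levels = c(air = -1000, lung = -800, body = 40, bone = 700),
                         body_semiaxes = c(y = 38, x = 52),
                         lung_semiaxes = c(z = 22, y = 24, x = 17),
                         lung_offset_x = 26,
                         trachea_radius_mm = 3.5,
                         bronchus_radius_mm = 2,
                         seed = 1L) {
  stopifnot(length(dims) == 3, all(dims >= 16), noise_sigma >= 0,
            all(c("air", "lung", "body", "bone") %in% names(levels)))
  if (nrow(nodules) &&
      (any(nodules$diameter_mm < 3) || any(nodules$diameter_mm > 30)))
    abort("nodule diameters must lie in the annotated range [3, 30] mm.")
  structure(
    list(dims = as.integer(dims), spacing = as.numeric(spacing),
         nodules = nodules, fused = isTRUE(fused),
         pleural_notch = isTRUE(pleural_notch),
         notch_radius_mm = notch_radius_mm,
         n_bronchi = as.integer(n_bronchi), noise_sigma = noise_sigma,
         levels = levels, body_semiaxes = body_semiaxes,
         lung_semiaxes = lung_semiaxes, lung_offset_x = lung_offset_x,
         trachea_radius_mm = trachea_radius_mm,
         bronchus_radius_mm = bronchus_radius_mm, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Specify phantom nodules
#'
#' Centres are world millimetres `(x, y, z)` in the annotation dialect;
#' with the default unit spacing and zero origin they coincide with voxel
#' coordinates. `kind = "pleural"` places a nodule that merges with the
#' chest wall, producing the juxtapleural concavity the rolling-ball
#' repair stage exists for. `NULL` centre coordinates default to the left
#' lung centre of the default geometry.
#'
#' @param x,y,z World-mm centre coordinates (vectorized).
#' @param diameter_mm Diameters in mm, each in `[3, 30]`.
#' @param kind `"solid"` or `"pleural"`.
#' @param contrast Intensity offset above the lung background.
#' @return Tibble with one row per nodule.
#' @export
nodule_spec <- function(x = 34, y = 48, z = 32, diameter_mm = 10,
                        kind = "solid", contrast = 700) {
  tibble(x = x, y = y, z = z, diameter_mm = diameter_mm,
         kind = kind, contrast = contrast)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic thorax phantom with ground truth
#'
#' Deterministic for a fixed spec (the noise stream is seeded from
#' `spec$seed`). Returns the CT volume and a `phantom_truth` list with the
#' anatomical lung mask (including nodules and any fusion bridge or
#' pleural-notch region, i.e. the target the segmentation pipeline should
#' recover), separate left/right lung masks, trachea and bronchi masks,
#' the nodule mask, the notch mask, and a nodule record table in the
#' annotation CSV dialect.
#'
#' @param spec A [phantom_spec()].
#' @param series_id Identifier written into the volume and records.
#' @return List with elements `volume` ([ct_volume]) and `truth`.
#' @export
generate_phantom <- function(spec, series_id = sprintf("phantom-%04d", spec$seed)) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dims
  lv <- spec$levels
  # index grids, 0-based, (z,y,x) order
  Z <- array(rep(0:(d[1] - 1), times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(0:(d[2] - 1), each = d[1]), times = d[3]), dim = d)
  X <- array(rep(0:(d[3] - 1), each = d[1] * d[2]), dim = d)
  cy <- (d[2] - 1) / 2; cx <- (d[3] - 1) / 2; cz <- (d[1] - 1) / 2
  by <- spec$body_semiaxes[["y"]]; bx <- spec$body_semiaxes[["x"]]
  vol <- array(lv[["air"]], dim = d)

  body <- ((X - cx) / bx)^2 + ((Y - cy) / by)^2 <= 1
  vol[body] <- lv[["body"]]
  ring <- body & (((X - cx) / bx)^2 + ((Y - cy) / by)^2 >= 0.88)
  vol[ring] <- lv[["bone"]]

  lz <- spec$lung_semiaxes[["z"]]; ly <- spec$lung_semiaxes[["y"]]
  lx <- spec$lung_semiaxes[["x"]]; off <- spec$lung_offset_x
  ell <- function(cxi) ((X - cxi) / lx)^2 + ((Y - cy) / ly)^2 + ((Z - cz) / lz)^2 <= 1
  lung_l <- ell(cx - off)
  lung_r <- ell(cx + off)
  lung_all <- lung_l | lung_r

  bridge <- array(FALSE, dim = d)
  if (spec$fused) {
    bridge <- abs(X - cx) <= off & ((Y - cy) / 6)^2 + ((Z - cz) / 6)^2 <= 1
    bridge <- bridge & !lung_all
    lung_all <- lung_all | bridge
  }
  vol[lung_all] <- lv[["lung"]]

  # airway: vertical trachea reaching the top axial slice + bronchus stubs,
  # each detached and wrapped in a soft-tissue wall
  ty <- cy - 6
  carina_z <- round(cz + lz * 0.35)
  trachea <- (Z >= carina_z) &
    ((X - cx)^2 + (Y - ty)^2 <= spec$trachea_radius_mm^2)
  tube <- function(p0, p1, r) {
    # p0/p1 are (z,y,x); distance from segment
    v <- p1 - p0
    L2 <- sum(v^2)
    t <- ((Z - p0[1]) * v[1] + (Y - p0[2]) * v[2] + (X - p0[3]) * v[3]) / L2
    t <- pmin(pmax(t, 0), 1)
    (Z - (p0[1] + t * v[1]))^2 + (Y - (p0[2] + t * v[2]))^2 +
      (X - (p0[3] + t * v[3]))^2 <= r^2
  }
  bronchi <- array(FALSE, dim = d)
  if (spec$n_bronchi >= 1)
    bronchi <- bronchi | tube(c(carina_z - 3, ty + 2, cx - 6),
                              c(carina_z - 8, ty + 4, cx - 11),
                              spec$bronchus_radius_mm)
  if (spec$n_bronchi >= 2)
    bronchi <- bronchi | tube(c(carina_z - 3, ty + 2, cx + 6),
                              c(carina_z - 8, ty + 4, cx + 11),
                              spec$bronchus_radius_mm)
  airway <- trachea | bronchi
  wall <- binary_dilate(airway, se_ball(2.2, spec$spacing)) & !airway
  lung_mask <- lung_all & !airway & !wall
  vol[wall] <- lv[["body"]]
  vol[airway] <- lv[["air"]]

  # nodules
  nodule_mask <- array(FALSE, dim = d)
  nods <- spec$nodules
  if (nrow(nods)) {
    for (i in seq_len(nrow(nods))) {
      r <- nods$diameter_mm[i] / 2
      sph <- (X - nods$x[i])^2 + (Y - nods$y[i])^2 + (Z - nods$z[i])^2 <= r^2
      inside <- sph & lung_mask
      if (nods$kind[i] == "solid" && any(sph & !lung_all))
        abort(sprintf("nodule %d (d = %.1f mm at x=%g y=%g z=%g) is not inside a lung",
                      i, nods$diameter_mm[i], nods$x[i], nods$y[i], nods$z[i]),
              class = "lungcad_spec_error")
      if (nods$kind[i] == "pleural" && !any(sph & lung_all))
        abort(sprintf("pleural nodule %d does not touch a lung", i),
              class = "lungcad_spec_error")
      vol[sph & body] <- lv[["lung"]] + nods$contrast[i]
      nodule_mask <- nodule_mask | inside
    }
  }

  notch_mask <- array(FALSE, dim = d)
  if (spec$pleural_notch) {
    # sphere centre half a radius inside the lateral surface of the right
    # lung: a pit deeper than wide, the shape a juxtapleural nodule leaves
    nx <- cx + off + lx - spec$notch_radius_mm * 0.75
    sph <- (X - nx)^2 + (Y - cy)^2 + (Z - cz)^2 <= spec$notch_radius_mm^2
    notch_mask <- sph & lung_mask
    vol[notch_mask] <- lv[["body"]]
  }

  if (spec$noise_sigma > 0) {
    noise <- .with_seed(spec$seed,
                        array(rnorm(prod(d), 0, spec$noise_sigma), dim = d))
    vol <- vol + noise
  }

  volume <- ct_volume(vol, spacing = spec$spacing, origin = c(0, 0, 0),
                      series_id = series_id)
  records <- tibble(
    seriesuid = rep(series_id, nrow(nods)),
    coordX = nods$x, coordY = nods$y, coordZ = nods$z,
    diameter_mm = nods$diameter_mm, kind = nods$kind
  )
  split_x <- cx
  left_mask <- lung_mask & (X < split_x)
  right_mask <- lung_mask & (X >= split_x)
  truth <- structure(
    list(lung_mask = lung_mask, left_mask = left_mask, right_mask = right_mask,
         trachea_mask = trachea, bronchi_mask = bronchi,
         nodule_mask = nodule_mask, notch_mask = notch_mask,
         fused = spec$fused, records = records),
    class = "phantom_truth"
  )
  list(volume = volume, truth = truth)
}

#' Generate a reproducible phantom dataset
#'
#' Draws i.i.d. nodule diameters from `diameter_sampler` and generates `n`
#' phantoms whose per-item seeds are derived from the master seed by a
#' fixed counter scheme, so items are reproducible independently of
#' generation order.
#'
#' @param n Number of phantoms (>= 1).
#' @param base_spec A [phantom_spec()] used as the template; each item's
#'   nodule diameters are replaced by sampled values.
#' @param diameter_sampler Function `f(k)` returning `k` diameters in mm;
#'   the default samples uniformly on the annotated range `[3, 30]`.
#' @param seed Master seed.
#' @return List of `n` `list(volume, truth)` pairs.
#' @export
generate_dataset <- function(n, base_spec = phantom_spec(),
                             diameter_sampler = function(k) runif(k, 3, 30),
                             seed = 1L) {
  if (!is.numeric(n) || n < 1) abort("`n` must be >= 1.")
  lapply(seq_len(n), function(i) {
    item_seed <- (seed * 1000L + i) %% .Machine$integer.max
    spec_i <- base_spec
    k <- nrow(base_spec$nodules)
    if (k > 0) {
      di <- .with_seed(item_seed, diameter_sampler(k))
      spec_i$nodules$diameter_mm <- pmin(pmax(di, 3), 30)
    }
    spec_i$seed <- item_seed
    generate_phantom(spec_i, series_id = sprintf("phantom-%05d-%03d", seed, i))
  })
}

#' Write a phantom dataset to disk
#'
#' Writes each phantom as a MetaImage pair plus truth masks
#' (`*_lungmask.mhd`, `*_nodulemask.mhd`) and a pooled `annotations.csv`
#' in the standard dialect.
#'
#' @param phantoms List of `list(volume, truth)` pairs.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_dataset <- function(phantoms, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- list()
  for (p in phantoms) {
    id <- p$volume$series_id
    write_metaimage(p$volume, file.path(dir, paste0(id, ".mhd")),
                    element_type = "MET_SHORT")
    msk <- ct_volume(array(as.numeric(p$truth$lung_mask), dim = dim(p$truth$lung_mask)),
                     spacing = p$volume$spacing, origin = p$volume$origin,
                     series_id = paste0(id, "_lungmask"))
    write_metaimage(msk, file.path(dir, paste0(id, "_lungmask.mhd")),
                    element_type = "MET_UCHAR")
    nod <- ct_volume(array(as.numeric(p$truth$nodule_mask), dim = dim(p$truth$nodule_mask)),
                     spacing = p$volume$spacing, origin = p$volume$origin,
                     series_id = paste0(id, "_nodulemask"))
    write_metaimage(nod, file.path(dir, paste0(id, "_nodulemask.mhd")),
                    element_type = "MET_UCHAR")
    recs[[length(recs) + 1]] <- p$truth$records
  }
  allrec <- bind_rows(recs)
  write_annotations(allrec[c("seriesuid", "coordX", "coordY", "coordZ", "diameter_mm")],
                    file.path(dir, "annotations.csv"))
  invisible(dir)
}
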