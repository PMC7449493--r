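#' Lung segmentation configuration
#'
#' Parameters of the four-step lung parenchyma pipeline. The fusion test
#' compares the first and second largest component areas; with
#' `fusion_mode = "ratio"` (the default) the lungs count as fused when
#' `A1 / max(A2, 1) > fusion_threshold` (threshold 4); an absolute-
#' difference reading is available as `fusion_mode = "absolute"`. The
#' rolling-ball repair uses a disc of radius `ball_radius_mm` (12.5 mm)
#' per axial slice and per component; set `ball_3d = TRUE` for a true 3-D
#' ball. Optimal-threshold trachea growing raises the intensity threshold
#' in steps of `growth_increment` and stops before the grown volume jumps
#' by more than `growth_explosion_factor` between steps (leak detection).
#'
#' @param fusion_threshold Fusion test threshold T (> 1), default 4.
#' @param ball_radius_mm Rolling-ball radius r (> 0) in mm, default 12.5.
#' @param growth_explosion_factor Volume-jump factor (> 1) that stops
#'   threshold growing, default 1.5.
#' @param growth_increment Intensity step between growth iterations,
#'   default 20.
#' @param closing_radius_mm Ball radius of the grayscale closing used for
#'   bronchus reconstruction, default 4 mm.
#' @param min_component_voxels Speck-removal threshold, default 64; only
#'   components disjoint from the two principal ones are removed.
#' @param fusion_mode `"ratio"` or `"absolute"`.
#' @param ball_3d Use a 3-D ball instead of per-slice discs for repair.
#' @param bronchi_diff_threshold Positive intensity difference
#'   (reconstruction minus original) above which a voxel counts as
#'   bronchus, default 200.
#' @param trachea_max_threshold Upper bound of the growth threshold sweep,
#'   default -400 (lung/air stays well below soft tissue).
#' @return A `seg_config` list.
#' @export
seg_config <- function(fusion_threshold = 4, ball_radius_mm = 12.5,
                       growth_explosion_factor = 1.5, growth_increment = 20,
                       closing_radius_mm = 4, min_component_voxels = 64,
                       fusion_mode = c("ratio", "absolute"), ball_3d = FALSE,
                       bronchi_diff_threshold = 200,
                       trachea_max_threshold = -400) {
  stopifnot(fusion_threshold > 1, ball_radius_mm > 0,
            growth_explosion_factor > 1, growth_increment > 0)
  structure(list(fusion_threshold = fusion_threshold,
                 ball_radius_mm = ball_radius_mm,
                 growth_explosion_factor = growth_explosion_factor,
                 growth_increment = growth_increment,
                 closing_radius_mm = closing_radius_mm,
                 min_component_voxels = min_component_voxels,
                 fusion_mode = match.arg(fusion_mode), ball_3d = isTRUE(ball_3d),
                 bronchi_diff_threshold = bronchi_diff_threshold,
                 trachea_max_threshold = trachea_max_threshold),
            class = "seg_config")
}

#' Otsu threshold of a numeric vector
#'
#' Exhaustive between-class-variance maximization over a 256-bin histogram
#' of the intensity range; the adaptive threshold used to binarize CT
#' volumes whose histograms are bimodal (dark air/lung vs bright tissue).
#'
#' @param values Numeric vector with at least two distinct values.
#' @param n_bins Histogram bins, default 256.
#' @return The threshold intensity (upper edge of the chosen bin).
#' @export
otsu_threshold <- function(values, n_bins = 256) {
  rng <- range(values)
  if (!is.finite(diff(rng)) || diff(rng) == 0)
    abort("cannot threshold a constant volume", class = "lungcad_degenerate_error")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(values, breaks, all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  k <- which.max(between[-n_bins])
  breaks[k + 1]
}

#' Step 1a: adaptive binarization of a CT volume
#'
#' Marks the dark class (air and lung parenchyma) as foreground using the
#' Otsu threshold of the volume histogram.
#'
#' @param volume A [ct_volume].
#' @return Logical mask, `TRUE` for voxels below the threshold.
#' @export
binarize_adaptive <- function(volume) {
  stopifnot(inherits(volume, "ct_volume"))
  thr <- otsu_threshold(as.vector(volume$voxels))
  volume$voxels < thr
}

#' Step 1b: remove background air and scanner tray
#'
#' Deletes every dark-class component that touches a lateral (x or y)
#' boundary face of the volume - the ambient air surrounding the body and
#' anything on the tray below it. Components are kept if they only reach
#' the axial (z) faces, since the trachea legitimately exits the scan
#' through the top slice.
#'
#' @param mask Logical mask from [binarize_adaptive()].
#' @return Logical mask of interior dark structures (lungs, airway).
#' @export
remove_background <- function(mask) {
  mask <- .as_mask(mask)
  if (!any(mask)) return(mask)
  d <- dim(mask)
  lab <- label_components(mask, 26)
  border_labels <- unique(c(lab[, 1, ], lab[, d[2], ], lab[, , 1], lab[, , d[3]]))
  border_labels <- border_labels[border_labels > 0]
  out <- mask & !(lab %in% border_labels)
  array(out, dim = d)
}

#' Step 1c: fill body-tissue holes to get the rough lung mask
#'
#' Seed-filling of enclosed cavities, slice by slice: bright structures
#' (vessels, nodules) enclosed in the retained dark components become part
#' of the rough lung-region mask.
#'
#' @param mask Logical mask from [remove_background()].
#' @param volume The source [ct_volume] (shape reference).
#' @return Logical rough lung-region mask.
#' @export
fill_body <- function(mask, volume = NULL) {
  fill_holes_slicewise(mask)
}

#' Step 2a: extract the main trachea by optimal-threshold growing
#'
#' Seeds 3-D region growing at the most circular dark region of the top
#' axial slices and raises the intensity threshold in fixed increments.
#' Growth stops at the largest threshold for which the grown volume does
#' not jump by more than `growth_explosion_factor` between iterations -
#' the classic leak-explosion guard. If no tubular dark seed exists near
#' the top of the volume a `lungcad_trachea_not_found` condition is
#' signalled and the pipeline continues without trachea removal.
#'
#' @param volume A [ct_volume].
#' @param rough_mask Logical rough lung mask (used to bound the search).
#' @param config A [seg_config()].
#' @return Logical trachea mask with attributes `threshold` (the accepted
#'   growth threshold) and `seed`, or an error of class
#'   `lungcad_trachea_not_found`.
#' @export
extract_main_trachea <- function(volume, rough_mask, config = seg_config()) {
  d <- dim(volume$voxels)
  seed <- NULL
  for (z in d[1]:(max(1, d[1] - 4))) {
    sl <- rough_mask[z, , ]
    if (!any(sl)) next
    lab <- label_components(array(sl, c(1, d[2], d[3])), 26)
    sizes <- component_sizes(lab)
    best <- NULL; best_circ <- 0
    for (li in sizes$label) {
      comp <- lab[1, , ] == li
      a <- sum(comp)
      if (a < 9) next
      # boundary pixels: in component but 4-neighbour outside
      sh <- function(m, dy, dx) {
        out <- array(FALSE, dim(m))
        ys <- max(1, 1 + dy):min(nrow(m), nrow(m) + dy)
        xs <- max(1, 1 + dx):min(ncol(m), ncol(m) + dx)
        out[ys, xs] <- m[ys - dy, xs - dx]
        out
      }
      interior <- comp & sh(comp, 1, 0) & sh(comp, -1, 0) & sh(comp, 0, 1) & sh(comp, 0, -1)
      perim <- sum(comp & !interior)
      circ <- 4 * pi * a / max(perim, 1)^2
      if (circ > best_circ) { best_circ <- circ; best <- comp }
    }
    if (!is.null(best) && best_circ > 0.5) {
      ctr <- round(c(z - 1,
                     mean(which(best, arr.ind = TRUE)[, 1]) - 1,
                     mean(which(best, arr.ind = TRUE)[, 2]) - 1))
      seed <- ctr
      break
    }
  }
  if (is.null(seed))
    abort("no trachea seed found in the top axial slices",
          class = "lungcad_trachea_not_found")
  seed_val <- volume$voxels[seed[1] + 1, seed[2] + 1, seed[3] + 1]
  thr <- seed_val + config$growth_increment
  grown <- region_grow(volume$voxels, seed, thr)
  vol_prev <- sum(grown)
  accepted <- grown; accepted_thr <- thr
  while (thr + config$growth_increment <= config$trachea_max_threshold) {
    thr <- thr + config$growth_increment
    cand <- region_grow(volume$voxels, seed, thr)
    v <- sum(cand)
    if (vol_prev > 0 && v > config$growth_explosion_factor * vol_prev) break
    accepted <- cand; accepted_thr <- thr; vol_prev <- v
  }
  structure(accepted, threshold = accepted_thr, seed = seed)
}

#' Step 2b: reconstruct and extract the bronchi
#'
#' Grayscale closing-by-reconstruction of the masked intensity image:
#' the marker is a grayscale closing with a ball of `closing_radius_mm`
#' (which erases dark structures thinner than the ball), and
#' reconstruction by erosion under the original image restores everything
#' that is connected to a surviving dark minimum. The voxelwise difference
#' reconstruction - original is large only over thin isolated dark tubes,
#' i.e. the bronchi; thresholding it at `bronchi_diff_threshold` yields
#' the bronchus mask.
#'
#' @param volume A [ct_volume].
#' @param parenchyma_mask Logical mask of the current lung-region estimate.
#' @param config A [seg_config()].
#' @return Logical bronchi mask with attribute `reconstruction`.
#' @export
reconstruct_bronchi <- function(volume, parenchyma_mask, config = seg_config()) {
  m <- .as_mask(parenchyma_mask)
  bright <- max(volume$voxels)
  img <- volume$voxels
  img[!m] <- bright  # outside the mask nothing is dark
  se <- se_ball(config$closing_radius_mm, volume$spacing)
  marker <- gray_close(img, se)
  recon <- gray_reconstruct_erosion(marker, img)
  diffv <- recon - img
  out <- (diffv > config$bronchi_diff_threshold) & m
  structure(out, reconstruction = recon)
}

#' Step 3a: detect left-right lung fusion
#'
#' Compares the largest (A1) and second-largest (A2) component voxel
#' counts; with the default ratio mode the mask counts as fused when
#' `A1 / max(A2, 1) > T` with T = 4 (a single giant component, the
#' signature of adherent lungs). A2 is taken as 0 for a single component.
#'
#' @param lung_mask Logical mask with at least one foreground voxel.
#' @param config A [seg_config()].
#' @return Logical flag; attribute `ratio` carries the tested statistic.
#' @export
detect_fusion <- function(lung_mask, config = seg_config()) {
  m <- .as_mask(lung_mask)
  if (!any(m)) abort("empty mask: nothing to test for fusion")
  sizes <- component_sizes(label_components(m, 26))
  a1 <- sizes$voxels[1]
  a2 <- if (nrow(sizes) >= 2) sizes$voxels[2] else 0
  stat <- if (config$fusion_mode == "ratio") a1 / max(a2, 1) else a1 - a2
  structure(stat > config$fusion_threshold, ratio = stat, a1 = a1, a2 = a2)
}

#' Step 3b: separate fused lungs by vertical integral projection
#'
#' For each axial slice the column-wise foreground sum (vertical integral
#' projection) restricted to the central third of the x-range attains its
#' minimum at the adhesion; the minimizing column per slice defines the
#' dividing line. Line positions are linearly interpolated over slices
#' where undefined, smoothed to unit slope, and the foreground on the
#' two-column dividing band is cleared so the lungs disconnect under
#' 26-connectivity.
#'
#' @param lung_mask Logical mask.
#' @param fused Result of [detect_fusion()]; when `FALSE` the input is
#'   returned unchanged with an empty line.
#' @return List `mask` (separated), `line` (tibble `z`, `column`; 0-based
#'   columns, `NA` where no foreground).
#' @export
separate_lungs <- function(lung_mask, fused = TRUE) {
  m <- .as_mask(lung_mask)
  d <- dim(m)
  if (!isTRUE(as.logical(fused)))
    return(list(mask = m, line = tibble(z = integer(), column = integer())))
  x0 <- floor(d[3] / 3) + 1L
  x1 <- ceiling(2 * d[3] / 3)
  cols <- rep(NA_real_, d[1])
  for (z in seq_len(d[1])) {
    sl <- m[z, , ]
    if (!any(sl)) next
    proj <- colSums(sl)  # foreground count per x column
    band <- proj[x0:x1]
    cols[z] <- x0 + which.min(band) - 1L
  }
  if (all(is.na(cols)))
    return(list(mask = m, line = tibble(z = integer(), column = integer())))
  idx <- which(!is.na(cols))
  interp <- if (length(idx) == 1) rep(cols[idx], d[1])
            else stats::approx(idx, cols[idx], xout = seq_len(d[1]), rule = 2)$y
  k <- if (d[1] >= 5) 5 else if (d[1] >= 3) 3 else 1
  if (k > 1) interp <- stats::runmed(interp, k)
  interp <- round(interp)
  # clamp slice-to-slice slope to 1 so a two-column cut disconnects in 26-conn
  for (z in 2:d[1])
    interp[z] <- min(max(interp[z], interp[z - 1] - 1), interp[z - 1] + 1)
  out <- m
  for (z in seq_len(d[1])) {
    c0 <- interp[z]
    out[z, , c0:min(c0 + 1, d[3])] <- FALSE
  }
  list(mask = out,
       line = tibble(z = seq_len(d[1]) - 1L, column = as.integer(interp) - 1L))
}

#' Step 4: rolling-ball boundary repair
#'
#' Morphological closing with a disc of radius `ball_radius_mm`, applied
#' per axial slice and per connected component, so concavities narrower
#' than the ball (juxtapleural nodule notches) are filled while true
#' inter-lung gaps are never bridged. The output always contains the
#' input.
#'
#' @param lung_mask Logical mask with a small number of components.
#' @param spacing Voxel spacing `(z, y, x)` mm.
#' @param config A [seg_config()].
#' @return Logical repaired mask.
#' @export
repair_boundary <- function(lung_mask, spacing = c(1, 1, 1), config = seg_config()) {
  if (config$ball_radius_mm <= 0) abort("ball radius must be positive")
  m <- .as_mask(lung_mask)
  se <- if (config$ball_3d) se_ball(config$ball_radius_mm, spacing)
        else se_disc(config$ball_radius_mm, spacing)
  lab <- label_components(m, 26)
  sizes <- component_sizes(lab)
  out <- array(FALSE, dim(m))
  for (li in sizes$label)
    out <- out | binary_close(lab == li, se)
  out | m
}

#' Segment the lung parenchyma of a thorax CT volume
#'
#' Runs the full four-step pipeline: adaptive binarization, background
#' removal, body-hole filling, optimal-threshold trachea growing
#' (subtracted), bronchus reconstruction (subtracted), speck removal,
#' fusion detection with integral-projection separation, and rolling-ball
#' boundary repair. All intermediate stage masks are retained.
#'
#' @param volume A [ct_volume].
#' @param config A [seg_config()].
#' @return A `lung_segmentation` object: `lung_mask`, `left_mask`,
#'   `right_mask`, `fused_detected`, `separation_line`, `stages` (named
#'   list of stage masks), `config`.
#' @export
segment_lungs <- function(volume, config = seg_config()) {
  stopifnot(inherits(volume, "ct_volume"))
  stages <- list()
  stages$raw_threshold <- binarize_adaptive(volume)
  stages$background_removed <- remove_background(stages$raw_threshold)
  if (!any(stages$background_removed))
    abort("no interior dark structures: not a thorax-like volume",
          class = "lungcad_degenerate_error")
  stages$body_filled <- fill_body(stages$background_removed, volume)
  trachea <- tryCatch(
    extract_main_trachea(volume, stages$body_filled, config),
    lungcad_trachea_not_found = function(e) array(FALSE, dim(volume$voxels))
  )
  stages$trachea <- .as_mask(trachea)
  after_trachea <- stages$body_filled & !stages$trachea
  bronchi <- reconstruct_bronchi(volume, after_trachea, config)
  stages$bronchi <- .as_mask(bronchi)
  after_bronchi <- after_trachea & !stages$bronchi
  cleaned <- remove_small_components(after_bronchi, config$min_component_voxels,
                                     keep_largest = 2)
  stages$fused_check_input <- cleaned
  fused <- detect_fusion(cleaned, config)
  sep <- separate_lungs(cleaned, fused)
  stages$separated <- sep$mask
  repaired <- repair_boundary(sep$mask, volume$spacing, config)
  stages$repaired <- repaired
  # partition into left/right by component centroid along x
  lab <- label_components(repaired, 26)
  sizes <- component_sizes(lab)
  left <- array(FALSE, dim(repaired)); right <- array(FALSE, dim(repaired))
  if (nrow(sizes)) {
    cents <- vapply(sizes$label, function(li) {
      mean(which(lab == li, arr.ind = TRUE)[, 3])
    }, numeric(1))
    anchors <- head(order(-sizes$voxels), 2)
    split_at <- mean(cents[anchors])
    for (i in seq_along(sizes$label)) {
      if (cents[i] <= split_at) left <- left | (lab == sizes$label[i])
      else right <- right | (lab == sizes$label[i])
    }
  }
  structure(
    list(lung_mask = repaired, left_mask = left, right_mask = right,
         fused_detected = as.logical(fused), fusion_stat = attr(fused, "ratio"),
         separation_line = sep$line, stages = stages, config = config,
         series_id = volume$series_id),
    class = "lung_segmentation"
  )
}

#' @export
print.lung_segmentation <- function(x, ...) {
  cat(sprintf("<lung_segmentation> %s\n", x$series_id))
  cat(sprintf("  lung voxels: %d (left %d / right %d)\n",
              sum(x$lung_mask), sum(x$left_mask), sum(x$right_mask)))
  cat(sprintf("  fusion detected: %s (statistic %.3g)\n",
              x$fused_detected, x$fusion_stat))
  invisible(x)
}

#' Dice similarity of two binary masks
#'
#' @param a,b Logical/0-1 arrays of equal shape.
#' @return `2|A n B| / (|A| + |B|)`; 1 for two empty masks.
#' @export
dice_coefficient <- function(a, b) {
  a <- .as_mask(a); b <- .as_mask(b)
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
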