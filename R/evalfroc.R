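#' Extract nodule candidates from a probability map
#'
#' Thresholds the map, labels connected components (26-connectivity), and
#' emits one candidate per component at its score-weighted centroid with
#' the component maximum as score. Centroids are converted to world
#' millimetres `(coordX, coordY, coordZ)`.
#'
#' @param prob 3-D probability array `(z, y, x)` with values in `[0, 1]`,
#'   or a [ct_volume] of probabilities.
#' @param threshold Detection threshold in `[0, 1]`.
#' @param spacing,origin Geometry `(z, y, x)` used when `prob` is a bare
#'   array.
#' @param series_id Identifier attached to the candidates.
#' @return Tibble `seriesuid, coordX, coordY, coordZ, probability`.
#' @export
extract_candidates <- function(prob, threshold = 0.5, spacing = c(1, 1, 1),
                               origin = c(0, 0, 0), series_id = "series") {
  if (inherits(prob, "ct_volume")) {
    spacing <- prob$spacing; origin <- prob$origin
    series_id <- prob$series_id; prob <- prob$voxels
  }
  if (threshold < 0 || threshold > 1)
    abort("`threshold` must lie in [0, 1]")
  m <- prob > threshold
  if (!any(m))
    return(tibble(seriesuid = character(), coordX = double(), coordY = double(),
                  coordZ = double(), probability = double()))
  lab <- label_components(m, 26)
  labels <- sort(unique(lab[lab > 0]))
  rows <- lapply(labels, function(li) {
    idx <- which(lab == li, arr.ind = TRUE)  # 1-based (z,y,x)
    w <- prob[lab == li]
    ctr0 <- colSums(idx * w) / sum(w) - 1  # 0-based weighted centroid
    world <- origin + ctr0 * spacing       # (z,y,x) mm
    tibble(seriesuid = series_id, coordX = world[3], coordY = world[2],
           coordZ = world[1], probability = max(w))
  })
  bind_rows(rows)
}

#' Classify a nodule diameter into the three size strata
#'
#' Small nodules have diameter below 5 mm, middle nodules between 5 and
#' 15 mm inclusive, large nodules above 15 mm.
#'
#' @param d Diameter(s) in mm, each > 0.
#' @return Character vector: `"small"`, `"middle"` or `"large"`.
#' @export
classify_size <- function(d) {
  if (any(!is.finite(d)) || any(d <= 0)) abort("diameters must be positive")
  ifelse(d < 5, "small", ifelse(d <= 15, "middle", "large"))
}

#' Match candidates against ground-truth nodules
#'
#' A candidate hits a nodule when its distance to the nodule centre is at
#' most the nodule radius (`diameter_mm / 2`). Each truth nodule counts
#' as detected at most once; extra candidates inside an already-hit
#' nodule are neither true nor false positives; candidates hitting no
#' nodule are false positives of their scan.
#'
#' @param candidates Tibble `seriesuid, coordX, coordY, coordZ,
#'   probability`.
#' @param truths Tibble `seriesuid, coordX, coordY, coordZ, diameter_mm`.
#' @param scan_ids Optional character vector of all scans evaluated
#'   (scans without candidates still count in FP/scan); defaults to the
#'   union of series in `candidates` and `truths`.
#' @return A `froc_matches` list: `truths` (with `hit_score`, the best
#'   matched candidate score or `-Inf`), `false_positives` (tibble of FP
#'   scores per scan), `n_scans`.
#' @export
match_candidates <- function(candidates, truths, scan_ids = NULL) {
  scan_ids <- scan_ids %||% union(unique(candidates$seriesuid),
                                  unique(truths$seriesuid))
  truths <- as_tibble(truths)
  truths$hit_score <- -Inf
  fp <- list()
  for (sid in scan_ids) {
    cs <- candidates[candidates$seriesuid == sid, , drop = FALSE]
    ti <- which(truths$seriesuid == sid)
    if (!nrow(cs)) next
    matched_any <- rep(FALSE, nrow(cs))
    for (j in ti) {
      dx <- cs$coordX - truths$coordX[j]
      dy <- cs$coordY - truths$coordY[j]
      dz <- cs$coordZ - truths$coordZ[j]
      inside <- sqrt(dx^2 + dy^2 + dz^2) <= truths$diameter_mm[j] / 2
      if (any(inside)) {
        truths$hit_score[j] <- max(cs$probability[inside])
        matched_any <- matched_any | inside
      }
    }
    if (any(!matched_any))
      fp[[length(fp) + 1]] <- tibble(seriesuid = sid,
                                     probability = cs$probability[!matched_any])
  }
  fp_tbl <- if (length(fp)) bind_rows(fp)
            else tibble(seriesuid = character(), probability = double())
  structure(list(truths = truths, false_positives = fp_tbl,
                 n_scans = length(scan_ids)),
            class = "froc_matches")
}

#' Free-response ROC curve with the seven standard operating points
#'
#' Sweeps the candidate-score threshold over every distinct score and
#' computes (false positives per scan, sensitivity) pairs; sensitivity at
#' each of the seven operating points 0.125, 0.25, 0.5, 1, 2, 4, 8
#' FP/scan is read off the step curve (last value carried forward along
#' the FP/scan axis). The scalar summary `auc` is the arithmetic mean of
#' the seven sensitivities, a score in `[0, 1]`; a trapezoidal variant
#' over log2(FP/scan) is also reported as `auc_trapezoid`.
#'
#' @param matches A `froc_matches` from [match_candidates()].
#' @param operating_points FP/scan operating points.
#' @return A `froc_curve`: `curve` (tibble `threshold`, `fp_per_scan`,
#'   `sensitivity`), `operating` (tibble `fp_per_scan`, `sensitivity`),
#'   `auc`, `auc_trapezoid`, `n_truths`, `n_scans`.
#' @export
froc <- function(matches, operating_points = c(0.125, 0.25, 0.5, 1, 2, 4, 8)) {
  stopifnot(inherits(matches, "froc_matches"))
  n_truth <- nrow(matches$truths)
  if (n_truth == 0)
    abort("no ground-truth nodules: sensitivity undefined",
          class = "lungcad_undefined_sensitivity")
  scores <- sort(unique(c(matches$truths$hit_score,
                          matches$false_positives$probability)))
  scores <- scores[is.finite(scores)]
  thresholds <- c(scores, Inf)
  curve <- lapply(thresholds, function(th) {
    sens <- mean(matches$truths$hit_score >= th)
    fps <- sum(matches$false_positives$probability >= th) / matches$n_scans
    tibble(threshold = th, fp_per_scan = fps, sensitivity = sens)
  })
  curve <- bind_rows(curve) |> arrange(.data$fp_per_scan, .data$sensitivity)
  sens_at <- vapply(operating_points, function(f) {
    ok <- curve$fp_per_scan <= f
    if (!any(ok)) 0 else max(curve$sensitivity[ok])
  }, numeric(1))
  op <- tibble(fp_per_scan = operating_points, sensitivity = sens_at)
  lx <- log2(operating_points)
  auc_trap <- sum(diff(lx) * (head(sens_at, -1) + tail(sens_at, -1)) / 2) /
    (max(lx) - min(lx))
  structure(list(curve = curve, operating = op, auc = mean(sens_at),
                 auc_trapezoid = auc_trap, n_truths = n_truth,
                 n_scans = matches$n_scans),
            class = "froc_curve")
}

#' @export
print.froc_curve <- function(x, ...) {
  cat(sprintf("<froc_curve> %d nodules over %d scan(s)\n", x$n_truths, x$n_scans))
  cat("  sensitivity at FP/scan:\n")
  print(as.data.frame(x$operating), row.names = FALSE)
  cat(sprintf("  AUC (mean of 7 points): %.4f\n", x$auc))
  invisible(x)
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' @param tp,fn,tn,fp Non-negative counts with `tp + fn > 0` and
#'   `tn + fp > 0`.
#' @return Tibble with `acc`, `sn`, `sp`.
#' @export
confusion_summary <- function(tp, fn, tn, fp) {
  counts <- c(tp, fn, tn, fp)
  if (any(counts < 0) || (tp + fn) == 0 || (tn + fp) == 0)
    abort("degenerate confusion counts")
  tibble(acc = (tp + tn) / sum(counts), sn = tp / (tp + fn), sp = tn / (tn + fp))
}

#' Deterministic k-fold split of series identifiers
#'
#' Seeded permutation followed by near-equal partition; every id appears
#' in exactly one test fold. Five folds is the standard protocol.
#'
#' @param ids Character vector of series ids (at least `k`).
#' @param k Number of folds (>= 2).
#' @param seed RNG seed.
#' @return List of `k` lists with elements `train` and `test`.
#' @export
kfold_split <- function(ids, k = 5, seed = 1L) {
  if (k < 2) abort("`k` must be >= 2")
  if (length(ids) < k) abort("fewer series than folds")
  perm <- .with_seed(seed, sample(ids))
  fold_of <- rep(seq_len(k), length.out = length(perm))
  lapply(seq_len(k), function(f)
    list(train = perm[fold_of != f], test = perm[fold_of == f]))
}
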