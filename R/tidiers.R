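# broom-style tidiers and ggplot2 autoplot methods for result objects

#' @export
tidy.froc_curve <- function(x, ...) x$operating

#' @export
glance.froc_curve <- function(x, ...) {
  tibble(auc = x$auc, auc_trapezoid = x$auc_trapezoid,
         n_truths = x$n_truths, n_scans = x$n_scans)
}

#' @export
autoplot.froc_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$fp_per_scan, y = .data$sensitivity)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(data = object$operating, colour = "firebrick") +
    ggplot2::scale_x_continuous(trans = "log2",
                                breaks = object$operating$fp_per_scan) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "false positives per scan", y = "sensitivity",
                  title = "FROC") +
    ggplot2::theme_minimal()
}

#' @export
tidy.lungcad_fit <- function(x, ...) x$metrics

#' @export
glance.lungcad_fit <- function(x, ...) {
  last <- tail(x$metrics, 1)
  tibble(steps = nrow(x$loss_history),
         final_loss = tail(x$loss_history$loss, 1),
         train_dice = if (nrow(last)) last$train_dice else NA_real_,
         train_acc = if (nrow(last)) last$train_acc else NA_real_,
         over_ratio = if (nrow(last)) last$over_ratio else NA_real_,
         stopped = x$stopped)
}

#' @export
autoplot.lungcad_fit <- function(object, ...) {
  ggplot2::ggplot(object$loss_history,
                  ggplot2::aes(x = .data$step, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "step", y = "training loss") +
    ggplot2::theme_minimal()
}

#' @export
tidy.lung_segmentation <- function(x, ...) {
  bind_rows(lapply(names(x$stages), function(nm)
    tibble(stage = nm, voxels = sum(x$stages[[nm]])))) |>
    bind_rows(tibble(stage = c("left", "right"),
                     voxels = c(sum(x$left_mask), sum(x$right_mask))))
}

#' @export
glance.lung_segmentation <- function(x, ...) {
  tibble(lung_voxels = sum(x$lung_mask), fused_detected = x$fused_detected,
         fusion_stat = x$fusion_stat,
         n_components = nrow(component_sizes(label_components(x$lung_mask))))
}

#' Plot an axial slice of a volume with optional mask overlay
#'
#' @param volume A [ct_volume] or 3-D array `(z, y, x)`.
#' @param z Axial slice index (1-based); defaults to the middle slice.
#' @param mask Optional binary mask of the same shape, drawn as contour
#'   fill.
#' @return A ggplot object.
#' @export
plot_slice <- function(volume, z = NULL, mask = NULL) {
  arr <- if (inherits(volume, "ct_volume")) volume$voxels else volume
  z <- z %||% (dim(arr)[1] %/% 2)
  sl <- arr[z, , ]
  df <- tidyr::expand_grid(y = seq_len(nrow(sl)), x = seq_len(ncol(sl)))
  df$intensity <- as.vector(sl[as.matrix(df[, c("y", "x")])])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (!is.null(mask)) {
    msl <- if (length(dim(mask)) == 3) mask[z, , ] else mask
    dm <- df
    dm$m <- as.vector(.as_mask(msl)[as.matrix(df[, c("y", "x")])])
    p <- p + ggplot2::geom_tile(data = dm[dm$m, ],
                                fill = "red", alpha = 0.35)
  }
  p
}

#' @export
tidy.arch_table <- function(x, ...) {
  tibble(name = x$name, kind = x$kind, out_channels = x$out_channels,
         kernel = x$kernel, dilation = x$dilation, scale = x$scale,
         group = x$group)
}
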