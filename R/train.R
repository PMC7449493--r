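#' Adam hyperparameters
#'
#' Defaults follow the reference update rule: first-moment momentum
#' `mu = 0.9`, second-moment momentum `upsilon = 0.9999`, learning rate
#' `eta = 0.01`, denominator offset `eps = 1e-8`. (Network training runs
#' typically override the learning rate with one of 0.00075 / 0.001 /
#' 0.005 via [train_config()].)
#'
#' @param mu,upsilon Momentum factors in `[0, 1)`.
#' @param eta Learning rate (> 0).
#' @param eps Denominator offset (> 0).
#' @return An `adam_hyper` list.
#' @export
adam_hyper <- function(mu = 0.9, upsilon = 0.9999, eta = 0.01, eps = 1e-8) {
  stopifnot(mu >= 0, mu < 1, upsilon >= 0, upsilon < 1, eta > 0, eps > 0)
  structure(list(mu = mu, upsilon = upsilon, eta = eta, eps = eps),
            class = "adam_hyper")
}

#' Initialize Adam state for a parameter tensor
#'
#' @param param Numeric vector/array (shape template).
#' @return An `adam_state` with zero moments and step counter 0.
#' @export
adam_init <- function(param) {
  z <- param; z[] <- 0
  structure(list(m = z, n = z, t = 0L), class = "adam_state")
}

#' One Adam update step
#'
#' Applies the adaptive moment-estimation update:
#' `m <- mu m + (1 - mu) g`, `n <- upsilon n + (1 - upsilon) g^2`, with
#' bias corrections `m_hat = m / (1 - mu^t)`, `n_hat = n / (1 - upsilon^t)`
#' (t the incremented counter), and parameter delta
#' `-eta * m_hat / (sqrt(n_hat) + eps)`.
#'
#' @param state An `adam_state` from [adam_init()].
#' @param grad Gradient, same shape as the state moments.
#' @param hyper An [adam_hyper()].
#' @return List `state` (updated) and `delta` (parameter increment).
#' @export
adam_step <- function(state, grad, hyper = adam_hyper()) {
  if (any(!is.finite(grad)))
    abort("non-finite gradient passed to adam_step", class = "lungcad_numeric_error")
  t <- state$t + 1L
  m <- hyper$mu * state$m + (1 - hyper$mu) * grad
  n <- hyper$upsilon * state$n + (1 - hyper$upsilon) * grad^2
  m_hat <- m / (1 - hyper$mu^t)
  n_hat <- n / (1 - hyper$upsilon^t)
  delta <- -hyper$eta * m_hat / (sqrt(n_hat) + hyper$eps)
  list(state = structure(list(m = m, n = n, t = t), class = "adam_state"),
       delta = delta)
}

#' Masked binary cross-entropy
#'
#' Mean voxelwise binary cross-entropy over voxels not covered by the
#' ignore mask, so background regions marked as "do not score" (e.g.
#' zero-labelled margin or padding) contribute nothing to the loss.
#'
#' @param pred Probability array, values in (0, 1).
#' @param target Binary array, same shape.
#' @param ignore Optional logical array, `TRUE` = excluded; `NULL` keeps
#'   every voxel.
#' @return Scalar loss.
#' @export
masked_cross_entropy <- function(pred, target, ignore = NULL) {
  stopifnot(identical(dim(pred), dim(target)))
  if (any(pred <= 0 | pred >= 1))
    abort("`pred` must lie strictly inside (0, 1)")
  keep <- if (is.null(ignore)) rep(TRUE, length(pred)) else !as.logical(ignore)
  if (!any(keep)) abort("all voxels ignored: loss undefined")
  p <- pred[keep]; t <- as.numeric(target)[keep]
  -mean(t * log(p) + (1 - t) * log(1 - p))
}

#' Six-fold geometric augmentation
#'
#' Expands each item into exactly six: the original, horizontal and
#' vertical in-plane flips, and rotations by 90, 180 and 270 degrees,
#' with labels transformed identically, so the sample count becomes six
#' times the original. Requires square in-plane (y, x) dims for the
#' rotations.
#'
#' @param items List of patches: each a `ct_patch` or a list with 3-D
#'   `(z, y, x)` arrays `voxels` and optionally `label`.
#' @return List of `6 * length(items)` items; each carries attribute
#'   `transform`.
#' @export
augment_six <- function(items) {
  tf <- list(
    identity = function(a) a,
    hflip = function(a) a[, , dim(a)[3]:1, drop = FALSE],
    vflip = function(a) a[, dim(a)[2]:1, , drop = FALSE],
    rot90 = function(a) aperm(a, c(1, 3, 2))[, dim(a)[3]:1, , drop = FALSE],
    rot180 = function(a) a[, dim(a)[2]:1, dim(a)[3]:1, drop = FALSE],
    rot270 = function(a) aperm(a, c(1, 3, 2))[, , dim(a)[2]:1, drop = FALSE]
  )
  out <- list()
  for (it in items) {
    d <- dim(it$voxels)
    if (d[2] != d[3])
      abort("augmentation rotations need square in-plane dims")
    for (nm in names(tf)) {
      new <- it
      new$voxels <- tf[[nm]](it$voxels)
      if (!is.null(it$label)) new$label <- tf[[nm]](it$label)
      attr(new, "transform") <- nm
      out[[length(out) + 1]] <- new
    }
  }
  out
}

#' Training accuracy
#'
#' Ratio of correctly detected images to total training images.
#'
#' @param correct,total Counts, `0 <= correct <= total`, `total > 0`.
#' @return `correct / total`.
#' @export
train_acc <- function(correct, total) {
  if (!is.numeric(total) || total <= 0) abort("`total` must be positive")
  if (correct < 0 || correct > total) abort("`correct` must lie in [0, total]")
  correct / total
}

#' Overfitting ratio
#'
#' `TrainAcc / ValAcc`; values above 1 indicate overfitting (the training
#' set is fit better than the validation set).
#'
#' @param train_acc,val_acc Accuracies; `val_acc > 0`.
#' @return The ratio.
#' @export
over_ratio <- function(train_acc, val_acc) {
  if (!is.numeric(val_acc) || val_acc <= 0) abort("`val_acc` must be positive")
  train_acc / val_acc
}

#' Resolve a transfer-learning freeze group to trainable layers
#'
#' Freeze groups are named spans over the architecture's layer-group
#' sequence (conv1 ... conv5, Up6 ... Up12; the output head belongs to the
#' Up12 group): `"conv1-Up12"` trains everything, `"Up12"` only the final
#' block, `"Up6-Up8"` the deep decoder, and so on. Layers outside the
#' span are frozen (their gradients are not applied).
#'
#' @param table An `arch_table`.
#' @param group Group name, one of the eight fine-tuning spans
#'   (`conv1-Up12`, `conv2-Up10`, `conv3-Up8`, `conv4-Up6`, `conv5`,
#'   `Up6-Up8`, `Up9-Up11`, `Up12`); `"convl"` is accepted for `"conv1"`.
#' @return Character vector of trainable table row names.
#' @export
resolve_freeze_group <- function(table, group) {
  labels <- unique(table$group)
  labels <- labels[!is.na(labels)]
  norm <- function(s) sub("^convl", "conv1", trimws(s))
  group <- norm(group)
  parts <- strsplit(group, "-")[[1]]
  parts <- vapply(parts, norm, character(1))
  if (!all(parts %in% labels))
    abort(sprintf("unknown freeze group '%s' (available: %s)", group,
                  paste(labels, collapse = ", ")))
  i <- match(parts[1], labels)
  j <- match(parts[length(parts)], labels)
  span <- labels[min(i, j):max(i, j)]
  table$name[table$group %in% span]
}

#' Training configuration
#'
#' @param lr Learning rate; training-grid values are 0.00075, 0.001 and
#'   0.005.
#' @param dropout Dropout rate in `[0, 1]`, default 0.5, applied after the
#'   two deepest encoder levels.
#' @param batch_size Mini-batch size (full-scale runs use about 88;
#'   desk-scale runs pass a small value).
#' @param max_steps Optimizer steps.
#' @param checkpoint_every Save a checkpoint every this many steps
#'   (default 10000).
#' @param augment Expand the dataset six-fold with [augment_six()] first.
#' @param freeze_group Optional freeze-group name
#'   (see [resolve_freeze_group()]); `NULL` trains all layers.
#' @param pos_weight Loss weight of positive (nodule) voxels relative to
#'   background, countering extreme class imbalance in patches.
#' @param eval_every,eval_n Evaluate Dice/accuracy every `eval_every`
#'   steps on at most `eval_n` items.
#' @param stop_dice Stop early once training Dice reaches this value
#'   (`NULL` disables).
#' @param overfit_bound,overfit_patience Early stop when the overfitting
#'   ratio exceeds `overfit_bound` for `overfit_patience` consecutive
#'   evaluations (needs a validation set).
#' @param checkpoint_dir Directory for checkpoints (`NULL` disables).
#' @param seed RNG seed for batching and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 0.001, dropout = 0.5, batch_size = 88,
                         max_steps = 1000, checkpoint_every = 10000,
                         augment = FALSE, freeze_group = NULL,
                         pos_weight = 20, eval_every = 20, eval_n = 16,
                         stop_dice = NULL, overfit_bound = 1.15,
                         overfit_patience = 3, checkpoint_dir = NULL,
                         seed = 1L) {
  stopifnot(dropout >= 0, dropout <= 1, lr > 0, batch_size >= 1, max_steps >= 1)
  structure(list(lr = lr, dropout = dropout, batch_size = batch_size,
                 max_steps = max_steps, checkpoint_every = checkpoint_every,
                 augment = isTRUE(augment), freeze_group = freeze_group,
                 pos_weight = pos_weight, eval_every = eval_every,
                 eval_n = eval_n, stop_dice = stop_dice,
                 overfit_bound = overfit_bound,
                 overfit_patience = overfit_patience,
                 checkpoint_dir = checkpoint_dir, seed = as.integer(seed)),
            class = "train_config")
}

# patch -> engine tensors
.prep_item <- function(it) {
  v <- it$voxels
  d <- dim(v)
  x <- array(as.vector(aperm(v, c(3, 2, 1))), c(1L, d[3], d[2], d[1]))
  lab <- if (!is.null(it$label))
    array(as.vector(aperm(.as_mask(it$label), c(3, 2, 1))) * 1,
          c(1L, d[3], d[2], d[1])) else NULL
  list(x = x, label = lab)
}

.eval_dice <- function(net, items, threshold = 0.5) {
  vapply(items, function(it) {
    p <- forward_pass(net, it$x)$out
    dice_coefficient(p > threshold, it$label > 0.5)
  }, numeric(1))
}

#' Train a network on labelled patches
#'
#' Mini-batch training with weighted binary cross-entropy on the sigmoid
#' output, the chosen optimizer (Adam with bias-corrected moments, or
#' plain stochastic gradient descent as used for transfer-learning
#' fine-tuning), optional six-fold augmentation, dropout, layer freezing,
#' periodic checkpoints, and metric tracking. An image counts as
#' "correctly detected" for the accuracy metrics when its prediction
#' reaches Dice >= 0.5 against its label. Training stops early when the
#' overfitting ratio exceeds its bound for several consecutive
#' evaluations (given a validation set) or when `stop_dice` is reached.
#'
#' @param net A `lungcad_net` from [build_network()].
#' @param dataset Non-empty list of labelled patches (`ct_patch` or
#'   `list(voxels, label)`, `(z, y, x)` arrays).
#' @param config A [train_config()].
#' @param optimizer `"adam"` or `"sgd"`.
#' @param validation Optional list of labelled patches.
#' @return A `lungcad_fit`: `net` (trained), `metrics` (tibble per
#'   evaluation), `loss_history` (tibble per step), `stopped` reason.
#' @export
fit <- function(net, dataset, config = train_config(),
                optimizer = c("adam", "sgd"), validation = NULL) {
  optimizer <- match.arg(optimizer)
  if (!length(dataset)) abort("empty dataset")
  if (config$augment) dataset <- augment_six(dataset)
  items <- lapply(dataset, .prep_item)
  val_items <- if (!is.null(validation)) lapply(validation, .prep_item)
  if (any(vapply(items, function(i) is.null(i$label), logical(1))))
    abort("every training item needs a label")
  net$dropout_rate <- config$dropout
  if (!is.null(config$freeze_group))
    net$trainable_rows <- resolve_freeze_group(net$table, config$freeze_group)
  tkeys <- .trainable_keys(net)
  opt_state <- NULL
  if (optimizer == "adam")
    opt_state <- lapply(net$params[tkeys], adam_init)
  hyper <- adam_hyper(eta = config$lr)
  loss_hist <- numeric(0)
  metrics <- list()
  stopped <- "max_steps"
  over_run <- 0L
  .with_seed(config$seed, {
    for (step in seq_len(config$max_steps)) {
      idx <- sample.int(length(items), min(config$batch_size, length(items)))
      gsum <- NULL
      loss <- 0
      for (ii in idx) {
        it <- items[[ii]]
        fwd <- forward_pass(net, it$x, train = TRUE, keep_cache = TRUE)
        p <- fwd$out
        t <- it$label
        w <- ifelse(t > 0.5, config$pos_weight, 1)
        wsum <- sum(w)
        pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
        loss <- loss + sum(w * -(t * log(pc) + (1 - t) * log(1 - pc))) / wsum
        dlogits <- array(w * (p - t) / wsum, dim(p))
        g <- backward_pass(net, fwd$cache, dlogits)
        gsum <- if (is.null(gsum)) g[tkeys]
                else purrr::map2(gsum, g[tkeys], `+`)
      }
      loss <- loss / length(idx)
      loss_hist[step] <- loss
      for (k in tkeys) {
        gk <- gsum[[k]] / length(idx)
        if (optimizer == "adam") {
          st <- adam_step(opt_state[[k]], gk, hyper)
          opt_state[[k]] <- st$state
          net$params[[k]] <- net$params[[k]] + st$delta
        } else {
          net$params[[k]] <- net$params[[k]] - config$lr * gk
        }
      }
      if (step %% config$eval_every == 0 || step == config$max_steps) {
        ev <- items[seq_len(min(config$eval_n, length(items)))]
        dtr <- .eval_dice(net, ev)
        ta <- train_acc(sum(dtr >= 0.5), length(dtr))
        row <- tibble(step = step, loss = loss, train_dice = mean(dtr),
                      train_acc = ta, val_dice = NA_real_,
                      val_acc = NA_real_, over_ratio = NA_real_)
        if (!is.null(val_items)) {
          dva <- .eval_dice(net, val_items)
          va <- train_acc(sum(dva >= 0.5), length(dva))
          row$val_dice <- mean(dva)
          row$val_acc <- va
          if (va > 0) row$over_ratio <- over_ratio(ta, va)
        }
        metrics[[length(metrics) + 1]] <- row
        if (!is.na(row$over_ratio) && row$over_ratio > config$overfit_bound) {
          over_run <- over_run + 1L
          if (over_run >= config$overfit_patience) {
            stopped <- "overfitting"
            break
          }
        } else over_run <- 0L
        if (!is.null(config$stop_dice) && mean(dtr) >= config$stop_dice) {
          stopped <- "dice_target"
          break
        }
      }
      if (!is.null(config$checkpoint_dir) &&
          step %% config$checkpoint_every == 0) {
        dir.create(config$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
        saveRDS(net, file.path(config$checkpoint_dir,
                               sprintf("checkpoint-%06d.rds", step)))
        jsonlite::write_json(
          list(step = step, loss = loss),
          file.path(config$checkpoint_dir, sprintf("checkpoint-%06d.json", step)),
          auto_unbox = TRUE)
      }
    }
  })
  structure(
    list(net = net, config = config, optimizer = optimizer,
         metrics = bind_rows(metrics),
         loss_history = tibble(step = seq_along(loss_hist), loss = loss_hist),
         stopped = stopped),
    class = "lungcad_fit"
  )
}

#' @export
print.lungcad_fit <- function(x, ...) {
  last <- tail(x$metrics, 1)
  cat(sprintf("<lungcad_fit> %s, %d steps (stopped: %s)\n", x$optimizer,
              nrow(x$loss_history), x$stopped))
  if (nrow(last))
    cat(sprintf("  final loss %.4f, train Dice %.3f, train acc %.3f\n",
                last$loss, last$train_dice, last$train_acc))
  invisible(x)
}
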