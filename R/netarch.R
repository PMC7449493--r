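# Architecture tables: a network is described by an ordered tibble of layer
# specs (one row per layer, concat rows naming their two sources) from which
# the trainable network is built and shape-traced. Channel counts of the
# default table reproduce the reference multiscale design exactly:
# Conv1 32; D1/T1 128; dilated branches 96; Conv2/Conv3 concat 224;
# Conv4 concat 480; Conv5 512; Up6 = 512 upconv + Conv4 skip = 992;
# Conv6 480; Up8 = 1376 upconv + Conv3 skip = 1600; Conv8 224; Up12 = 256;
# output head = two 1x1 convolutions with a sigmoid.

.new_arch_row <- function(name, kind, src, out_channels = NA_integer_,
                          kernel = NA_integer_, dilation = 1L, factor = 1L,
                          scale = NA_integer_, group = NA_character_,
                          record = FALSE, act = "relu",
                          growth_rate = NA_integer_, n_layers = NA_integer_,
                          bottleneck = NA_integer_) {
  tibble(name = name, kind = kind, sources = list(src),
         out_channels = as.integer(out_channels), kernel = as.integer(kernel),
         dilation = as.integer(dilation), factor = as.integer(factor),
         scale = as.integer(scale), group = group, record = record, act = act,
         growth_rate = as.integer(growth_rate), n_layers = as.integer(n_layers),
         bottleneck = as.integer(bottleneck))
}

.arch_builder <- function(input_channels) {
  env <- new.env(parent = emptyenv())
  env$rows <- list(.new_arch_row("In", "input", character(),
                                 out_channels = input_channels, scale = 1L,
                                 act = "linear"))
  env$ch <- c(In = as.integer(input_channels))
  env$scale <- c(In = 1L)
  env$add <- function(name, kind, src, out_channels = NA, scale = NA, ...) {
    if (is.na(out_channels)) out_channels <- sum(env$ch[src])
    if (is.na(scale)) scale <- env$scale[[src[1]]]
    env$rows[[length(env$rows) + 1]] <-
      .new_arch_row(name, kind, src, out_channels = out_channels,
                    scale = scale, ...)
    env$ch[name] <- as.integer(out_channels)
    env$scale[name] <- as.integer(scale)
    name
  }
  env
}

.finish_table <- function(b, input_channels, spatial_rank) {
  tab <- bind_rows(b$rows)
  structure(tab, class = c("arch_table", class(tab)),
            input_channels = as.integer(input_channels),
            spatial_rank = as.integer(spatial_rank))
}

#' Multiscale dense/dilated U-Net architecture table
#'
#' Constructs the ordered layer table of the multiscale network: an
#' encoder whose levels each run a dense branch (pool, dense block of
#' growth rate 3, transition, 3x3 conv) in parallel with a dilated branch
#' (pooling followed by a 3x3 convolution of dilation 2), concatenated per
#' level; a bottleneck convolution; and a continuously upsampling decoder
#' (one 2x upconv per halving) with skip concatenations alternating
#' between level concats and dense-block outputs, plus decoder-side dense
#' blocks. The default `levels = 3, level_stride = 4, width = 1` table is
#' the normative full-resolution design (total pooling factor 128,
#' bottleneck at 8x8 then 4x4 for a 512x512 input); reduced tables for
#' patch-scale training shrink depth (`levels`, `level_stride`) and width
#' (`width` multiplies every channel count; the growth rate stays 3).
#'
#' @param levels Number of encoder multiscale levels (>= 1).
#' @param level_stride Downsampling per level: 4 (pool before the dense
#'   block and inside the transition, the full design) or 2.
#' @param width Channel multiplier (e.g. 1/8 for desk-scale training).
#' @param input_channels Input channel count (output head matches it).
#' @return An `arch_table` tibble; attribute `input_channels`,
#'   `spatial_rank` is decided at build time.
#' @export
multiscale_table <- function(levels = 3, level_stride = 4, width = 1,
                             input_channels = 1) {
  stopifnot(levels >= 1, level_stride %in% c(2L, 4L), width > 0)
  ch <- function(x) max(1L, as.integer(round(x * width)))
  full <- level_stride == 4L
  # per-level widths: dense/transition 128, level conv 128 (full) or 64
  # (reduced); the last level's conv is 384 so its concat is 480
  dense_w <- rep(128, levels)
  conv_w <- if (full) rep(128, levels) else rep(64, levels)
  conv_w[levels] <- 384
  dil_w <- rep(96, levels)

  b <- .arch_builder(input_channels)
  add <- b$add
  prev <- add("Conv1", "conv", "In", ch(32), kernel = 3, group = "conv1",
              record = TRUE)
  combs <- character(levels); denses <- character(levels)
  for (l in seq_len(levels)) {
    g <- paste0("conv", l + 1)
    s_in <- b$scale[[prev]]
    poolA <- add(paste0("Pool", l, "a"), "pool", prev, factor = 2,
                 scale = s_in * 2L, group = g, act = "linear")
    Dl <- add(paste0("D", l), "dense_block", poolA, ch(dense_w[l]),
              group = g, record = TRUE, growth_rate = 3,
              n_layers = 4, bottleneck = ch(16))
    Tl <- add(paste0("T", l), "transition", Dl, ch(dense_w[l]), kernel = 1,
              group = g, record = TRUE)
    dense_top <- Tl
    if (full)
      dense_top <- add(paste0("Pool", l, "b"), "pool", Tl, factor = 2,
                       scale = b$scale[[Tl]] * 2L, group = g, act = "linear")
    dconv <- add(paste0("Conv", l + 1, "_dense"), "conv", dense_top,
                 ch(conv_w[l]), kernel = 3, group = g)
    dil_src <- poolA
    if (full)
      dil_src <- add(paste0("Pool", l, "d"), "pool", poolA, factor = 2,
                     scale = b$scale[[poolA]] * 2L, group = g, act = "linear")
    dil <- add(paste0("Conv", l + 1, "_dilated"), "dilated_conv", dil_src,
               ch(dil_w[l]), kernel = 3, dilation = 2, group = g)
    comb <- add(paste0("Conv", l + 1), "concat", c(dconv, dil),
                group = g, record = TRUE, act = "linear")
    combs[l] <- comb; denses[l] <- Dl
    prev <- comb
  }
  prev <- add("Drop1", "dropout", prev, b$ch[[prev]],
              group = paste0("conv", levels + 1), act = "linear")
  poolC <- add("PoolC", "pool", prev, factor = 2,
               scale = b$scale[[prev]] * 2L, group = "conv5", act = "linear")
  conv5 <- add("Conv5", "conv", poolC, ch(512), kernel = 3, group = "conv5",
               record = TRUE)
  prev <- add("Drop2", "dropout", conv5, b$ch[[conv5]], group = "conv5",
              act = "linear")

  # decoder: one 2x upconv per halving; skips from the deepest outward
  skips <- c("Conv1", if (full) as.vector(rbind(denses, combs)) else combs)
  # skips listed shallow -> deep; traverse deep -> shallow
  skips <- rev(skips)
  n_ups <- length(skips)
  first_up <- 13L - n_ups
  up_w <- if (full) c(512, 512, 1376, 128, 128, 128, 224)
          else c(256, rep(128, max(0, n_ups - 2)), 96)
  post <- vector("list", n_ups)
  if (full) {
    post[[1]] <- list(name = "Conv6", kind = "conv", w = 480, record = TRUE)
    post[[3]] <- list(name = "Conv8", kind = "conv", w = 224, record = TRUE)
    post[[4]] <- list(name = "D4", kind = "dense_block", w = 128, record = TRUE)
    post[[5]] <- list(name = "D5", kind = "dense_block", w = 128, record = TRUE)
  } else {
    post[[1]] <- list(name = "ConvB", kind = "conv", w = 224, record = FALSE)
    if (n_ups >= 3)
      for (i in 2:(n_ups - 1))
        post[[i]] <- list(name = paste0("Mix", i), kind = "transition",
                          w = 64, record = FALSE)
    if (levels >= 2)
      post[[2]] <- list(name = "D_dec", kind = "dense_block", w = 128,
                        record = FALSE)
  }
  for (i in seq_len(n_ups)) {
    upname <- paste0("Up", first_up + i - 1L)
    g <- upname
    upsamp <- add(paste0(upname, "_us"), "upsample", prev, b$ch[[prev]],
                  factor = 2, scale = b$scale[[prev]] %/% 2L, group = g,
                  act = "linear")
    upconv <- add(paste0(upname, "_conv"), "conv", upsamp, ch(up_w[i]),
                  kernel = 2, group = g)
    prev <- add(upname, "concat", c(upconv, skips[i]), group = g,
                record = TRUE, act = "linear")
    p <- post[[i]]
    if (!is.null(p)) {
      if (p$kind == "dense_block")
        prev <- add(p$name, "dense_block", prev, ch(p$w), group = g,
                    record = p$record, growth_rate = 3, n_layers = 4,
                    bottleneck = ch(16))
      else
        prev <- add(p$name, p$kind, prev, ch(p$w),
                    kernel = if (p$kind == "conv") 3 else 1,
                    group = g, record = p$record)
    }
  }
  prev <- add("Out1", "conv", prev, ch(32), kernel = 1, group = "Up12")
  add("Out", "output", prev, input_channels, kernel = 1, group = "Up12",
      record = TRUE, act = "sigmoid")
  .finish_table(b, input_channels, 3L)
}

#' The normative default multiscale architecture table
#'
#' Full-width, three-level table whose shape trace on a 512x512
#' single-channel input reproduces the reference channel counts (Conv1 32,
#' D1 128, Conv2/Conv3 224, Conv4 480, Up6 992, Up8 1600, Up12 256, output
#' = input channels).
#'
#' @return An `arch_table`.
#' @export
default_multiscale_table <- function() multiscale_table(3, 4, 1, 1)

#' Plain symmetric U-Net baseline table
#'
#' Encoder/decoder with one 3x3 convolution and 2x pool per resolution
#' level, skip concatenations, no dense blocks and no dilation; the
#' comparison baseline for the multiscale design.
#'
#' @param levels Resolution levels (>= 1).
#' @param base_channels Channels of the first level; doubled per level.
#' @param input_channels Input channel count.
#' @return An `arch_table`.
#' @export
baseline_unet_table <- function(levels = 3, base_channels = 16,
                                input_channels = 1) {
  stopifnot(levels >= 1)
  b <- .arch_builder(input_channels)
  add <- b$add
  prev <- add("Enc1", "conv", "In", base_channels, kernel = 3,
              group = "conv1", record = TRUE)
  skips <- prev
  for (l in seq_len(levels)) {
    pool <- add(paste0("PoolE", l), "pool", prev, factor = 2,
                scale = b$scale[[prev]] * 2L, act = "linear")
    prev <- add(paste0("Enc", l + 1), "conv", pool,
                base_channels * 2^l, kernel = 3, record = TRUE)
    if (l < levels) skips <- c(skips, prev)
  }
  for (l in rev(seq_len(levels))) {
    us <- add(paste0("UpD", l, "_us"), "upsample", prev, b$ch[[prev]],
              factor = 2, scale = b$scale[[prev]] %/% 2L, act = "linear")
    uc <- add(paste0("UpD", l, "_conv"), "conv", us,
              base_channels * 2^(l - 1), kernel = 2)
    cat_ <- add(paste0("UpD", l), "concat", c(uc, skips[l]), act = "linear",
                record = TRUE)
    prev <- add(paste0("Dec", l), "conv", cat_, base_channels * 2^(l - 1),
                kernel = 3, record = TRUE)
  }
  add("Out", "output", prev, input_channels, kernel = 1, group = "Up12",
      record = TRUE, act = "sigmoid")
  .finish_table(b, input_channels, 3L)
}

#' Dense-block internal layer arithmetic
#'
#' A dense block is a 1x1 bottleneck convolution followed by `n_layers`
#' densely connected 3x3 convolutions, each receiving the concatenation
#' of the bottleneck and all previous layer outputs and adding
#' `growth_rate` feature maps, closed by a channel-setting 1x1 projection.
#' Returns the internal layer listing; internal channels after layer `k`
#' equal `bottleneck + k * growth_rate`.
#'
#' @param in_channels Channels entering the block.
#' @param growth_rate Feature maps added per dense layer (default 3).
#' @param n_layers Number of dense 3x3 layers (>= 1).
#' @param out_channels Channels after the closing projection.
#' @param bottleneck Channels of the 1x1 bottleneck (default 16).
#' @return Tibble with columns `layer`, `kind`, `kernel`, `in_channels`,
#'   `out_channels`, `concat_channels`.
#' @export
dense_block <- function(in_channels, growth_rate = 3, n_layers = 4,
                        out_channels = in_channels, bottleneck = 16) {
  stopifnot(n_layers >= 1, growth_rate >= 1)
  rows <- list(tibble(layer = "bottleneck", kind = "conv", kernel = 1L,
                      in_channels = as.integer(in_channels),
                      out_channels = as.integer(bottleneck),
                      concat_channels = as.integer(bottleneck)))
  acc <- bottleneck
  for (k in seq_len(n_layers)) {
    rows[[k + 1]] <- tibble(layer = paste0("dense", k), kind = "conv",
                            kernel = 3L, in_channels = as.integer(acc),
                            out_channels = as.integer(growth_rate),
                            concat_channels = as.integer(acc + growth_rate))
    acc <- acc + growth_rate
  }
  rows[[n_layers + 2]] <- tibble(layer = "projection", kind = "conv",
                                 kernel = 1L, in_channels = as.integer(acc),
                                 out_channels = as.integer(out_channels),
                                 concat_channels = as.integer(out_channels))
  bind_rows(rows)
}

#' Validate concat arithmetic of an architecture table
#'
#' @param table An `arch_table`.
#' @return `TRUE` invisibly; aborts naming the first inconsistent layer.
#' @export
validate_arch_table <- function(table) {
  ch <- setNames(table$out_channels, table$name)
  for (i in seq_len(nrow(table))) {
    if (table$kind[i] != "concat") next
    src <- table$sources[[i]]
    if (length(src) != 2)
      abort(sprintf("concat layer %s must name exactly two sources", table$name[i]))
    s <- sum(ch[src])
    if (s != table$out_channels[i])
      abort(sprintf("concat layer %s declares %d channels but its sources sum to %d",
                    table$name[i], table$out_channels[i], s),
            class = "lungcad_table_error")
  }
  invisible(TRUE)
}

#' Symbolic shape trace of an architecture
#'
#' Propagates spatial dimensions and channel counts through an
#' architecture table (or a built network) for a given input size without
#' running a forward pass: convolutions are same-padded, pools halve,
#' upconvs double. Recorded (named) layers appear as one row each.
#'
#' @param x An `arch_table` or a network from [build_network()].
#' @param input_dim Input spatial dims: `c(x, y)` traces a single-slice
#'   (2-D) input, `c(x, y, z)` a volumetric one. Dims must be divisible by
#'   the cumulative pooling factor.
#' @param all Include every internal layer, not just recorded ones.
#' @return Tibble with columns `name`, `kind`, `dim_x`, `dim_y`, `dim_z`,
#'   `channels`, `scale`.
#' @export
shape_trace <- function(x, input_dim = c(512, 512), all = FALSE) {
  table <- if (inherits(x, "arch_table")) x
           else if (inherits(x, "lungcad_net")) x$table
           else abort("`x` must be an arch_table or a built network")
  validate_arch_table(table)
  input_dim <- as.integer(input_dim)
  stopifnot(length(input_dim) %in% c(2L, 3L))
  dims <- c(input_dim, if (length(input_dim) == 2L) 1L)
  total_factor <- 2L^sum(table$kind == "pool" &
                           !grepl("d$", table$name))  # main-path pools
  maxpool <- max(table$scale, na.rm = TRUE)
  state <- list()
  state[["In"]] <- list(dims = dims, ch = attr(x, "input_channels") %||%
                          attr(table, "input_channels"))
  out <- list()
  for (i in seq_len(nrow(table))) {
    kind <- table$kind[i]; nm <- table$name[i]
    if (kind == "input") { cur <- state[["In"]] }
    else {
      src <- state[[table$sources[[i]][1]]]
      cur <- src
      if (kind == "pool") {
        bad <- src$dims %% 2L != 0L & src$dims > 1L
        if (any(bad)) {
          sug <- ceiling(input_dim / maxpool) * maxpool
          abort(sprintf(
            "input dims not divisible at pool %s; nearest valid size: %s",
            nm, paste(sug, collapse = " x ")), class = "lungcad_shape_error")
        }
        cur$dims <- pmax(1L, src$dims %/% 2L)
      } else if (kind == "upsample") {
        cur$dims <- ifelse(src$dims == 1L & dims == 1L, 1L, src$dims * 2L)
      } else if (kind == "concat") {
        s2 <- state[[table$sources[[i]][2]]]
        if (!identical(cur$dims, s2$dims))
          abort(sprintf("concat %s joins mismatched spatial dims", nm),
                class = "lungcad_table_error")
        cur$ch <- cur$ch + s2$ch
      }
      if (!kind %in% c("concat")) cur$ch <- table$out_channels[i]
      state[[nm]] <- cur
    }
    state[[nm]] <- cur
    if (all || isTRUE(table$record[i]) || kind == "input")
      out[[length(out) + 1]] <- tibble(
        name = nm, kind = kind, dim_x = cur$dims[1], dim_y = cur$dims[2],
        dim_z = cur$dims[3], channels = as.integer(cur$ch),
        scale = max(1L, input_dim[1] %/% cur$dims[1]))
  }
  bind_rows(out)
}

#' Channels recorded at a named layer of a shape trace
#'
#' @param trace Tibble from [shape_trace()].
#' @param name Layer name (e.g. `"Conv1"`, `"Up6"`).
#' @return Integer channel count.
#' @export
trace_channels <- function(trace, name) {
  row <- trace[trace$name == name, ]
  if (!nrow(row)) abort(sprintf("layer %s not in trace", name))
  row$channels[[1]]
}
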