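# Layer-graph engine. An arch_table is compiled into a flat list of
# primitive nodes (conv / pool / upsample / concat / dropout), each holding
# parameter keys into a named parameter list. Feature maps are (C, X, Y, Z)
# arrays; conv weights are (C_out x K) matrices (K = C_in * prod(kernel))
# matching the C++ im2col layout. Dense blocks expand into their bottleneck
# / dense / projection convolutions and running concats at compile time.

.node <- function(id, name, kind, src, table_name, group, act = "linear",
                  kernel = NULL, dilation = 1L, factor = 1L, record = FALSE,
                  in_ch = NA_integer_, out_ch = NA_integer_) {
  list(id = id, name = name, kind = kind, src = src, table_name = table_name,
       group = group, act = act, kernel = kernel, dilation = dilation,
       factor = factor, record = record, in_ch = in_ch, out_ch = out_ch)
}

#' Build a trainable network from an architecture table
#'
#' Instantiates every layer of the table with He-initialized weights.
#' `mode = "3d"` extends all kernels and pools isotropically to the third
#' axis; `mode = "2d"` keeps them single-slice (the configuration in which
#' the published 512x512 shape narrative of the reference design applies). The rectifier is used
#' throughout, max pooling for all pools, and the output head ends in a
#' sigmoid.
#'
#' @param table An `arch_table` (see [multiscale_table()]).
#' @param mode `"3d"` or `"2d"`.
#' @param seed Seed for the weight initialization stream.
#' @return A `lungcad_net` handle.
#' @export
build_network <- function(table, mode = c("3d", "2d"), seed = 1L) {
  mode <- match.arg(mode)
  validate_arch_table(table)
  nodes <- list()
  params <- list()
  by_name <- list()   # table row name -> output node id
  ch_of <- list()
  nid <- 0L
  kdims <- function(k) c(k, k, if (mode == "3d") k else 1L)
  init_seed_env <- new.env()
  init_seed_env$counter <- 0L
  add_node <- function(name, kind, src_ids, table_name, group, act = "linear",
                       kernel = NULL, dilation = 1L, factor = 1L,
                       record = FALSE, in_ch = NA, out_ch = NA) {
    nid <<- nid + 1L
    nodes[[nid]] <<- .node(nid, name, kind, src_ids, table_name, group, act,
                           kernel, dilation, factor, record,
                           as.integer(in_ch), as.integer(out_ch))
    nid
  }
  add_conv <- function(name, src_id, in_ch, out_ch, k, dil, act, table_name,
                       group, record = FALSE) {
    id <- add_node(name, "conv", src_id, table_name, group, act,
                   kernel = kdims(k), dilation = as.integer(dil),
                   record = record, in_ch = in_ch, out_ch = out_ch)
    K <- in_ch * prod(kdims(k))
    init_seed_env$counter <- init_seed_env$counter + 1L
    W <- .with_seed(attr(table, "build_seed") %||% 0L + init_seed_env$counter,
                    matrix(rnorm(out_ch * K, 0, sqrt(2 / K)), out_ch, K))
    params[[paste0("n", id, ".W")]] <<- W
    params[[paste0("n", id, ".b")]] <<- numeric(out_ch)
    id
  }
  attr(table, "build_seed") <- as.integer(seed) * 10000L
  for (i in seq_len(nrow(table))) {
    row <- table[i, ]
    kind <- row$kind; nm <- row$name
    src_names <- row$sources[[1]]
    src_ids <- unlist(by_name[src_names], use.names = FALSE)
    if (kind == "input") {
      id <- add_node(nm, "input", integer(), nm, row$group,
                     out_ch = row$out_channels)
      ch <- row$out_channels
    } else if (kind %in% c("conv", "dilated_conv", "transition", "output")) {
      k <- if (is.na(row$kernel)) 1L else row$kernel
      in_ch <- ch_of[[src_names[1]]]
      id <- add_conv(nm, src_ids[1], in_ch, row$out_channels, k,
                     row$dilation, row$act, nm, row$group, row$record)
      ch <- row$out_channels
    } else if (kind == "pool") {
      id <- add_node(nm, "pool", src_ids[1], nm, row$group,
                     factor = 2L, in_ch = ch_of[[src_names[1]]],
                     out_ch = ch_of[[src_names[1]]])
      ch <- ch_of[[src_names[1]]]
    } else if (kind == "upsample") {
      id <- add_node(nm, "upsample", src_ids[1], nm, row$group,
                     factor = 2L, in_ch = ch_of[[src_names[1]]],
                     out_ch = ch_of[[src_names[1]]])
      ch <- ch_of[[src_names[1]]]
    } else if (kind == "concat") {
      chs <- unlist(ch_of[src_names])
      id <- add_node(nm, "concat", src_ids, nm, row$group, record = row$record,
                     in_ch = sum(chs), out_ch = sum(chs))
      ch <- sum(chs)
    } else if (kind == "dropout") {
      id <- add_node(nm, "dropout", src_ids[1], nm, row$group,
                     in_ch = ch_of[[src_names[1]]], out_ch = ch_of[[src_names[1]]])
      ch <- ch_of[[src_names[1]]]
    } else if (kind == "dense_block") {
      in_ch <- ch_of[[src_names[1]]]
      spec <- dense_block(in_ch, row$growth_rate, row$n_layers,
                          row$out_channels, row$bottleneck)
      acc_id <- add_conv(paste0(nm, ".bneck"), src_ids[1], in_ch,
                         row$bottleneck, 1L, 1L, "relu", nm, row$group)
      acc_ch <- row$bottleneck
      for (kk in seq_len(row$n_layers)) {
        conv_id <- add_conv(paste0(nm, ".d", kk), acc_id, acc_ch,
                            row$growth_rate, 3L, 1L, "relu", nm, row$group)
        cat_id <- add_node(paste0(nm, ".cat", kk), "concat",
                           c(acc_id, conv_id), nm, row$group,
                           in_ch = acc_ch + row$growth_rate,
                           out_ch = acc_ch + row$growth_rate)
        acc_id <- cat_id
        acc_ch <- acc_ch + row$growth_rate
      }
      id <- add_conv(paste0(nm, ".proj"), acc_id, acc_ch, row$out_channels,
                     1L, 1L, "relu", nm, row$group, row$record)
      ch <- row$out_channels
    } else abort(sprintf("unknown layer kind: %s", kind))
    by_name[[nm]] <- id
    ch_of[[nm]] <- ch
  }
  pool_factor <- 2L^sum(vapply(nodes, function(n)
    n$kind == "pool" && !grepl("d$", n$name), logical(1)))
  structure(
    list(nodes = nodes, params = params, table = table, mode = mode,
         input_channels = attr(table, "input_channels"),
         pool_factor = max(table$scale, na.rm = TRUE),
         dropout_rate = 0, trainable_rows = unique(table$name)),
    class = "lungcad_net"
  )
}

#' @export
print.lungcad_net <- function(x, ...) {
  cat(sprintf("<lungcad_net> %s, %d primitive nodes, %s parameters\n",
              x$mode, length(x$nodes),
              format(count_params(x), big.mark = ",")))
  invisible(x)
}

# pad (C,X,Y,Z) tensor at the high end so spatial dims divide `factor`
.pad_tensor <- function(x, factor, mode) {
  d <- dim(x)
  tgt <- d
  tgt[2:3] <- as.integer(ceiling(d[2:3] / factor) * factor)
  if (mode == "3d" && d[4] > 1) tgt[4] <- as.integer(ceiling(d[4] / factor) * factor)
  if (identical(tgt, d)) return(list(x = x, orig = d))
  out <- array(0, tgt)
  out[, seq_len(d[2]), seq_len(d[3]), seq_len(d[4])] <- x
  list(x = out, orig = d)
}

#' Forward pass of a built network
#'
#' @param net A `lungcad_net`.
#' @param x Input tensor `(C, X, Y, Z)` array (or `(C, X, Y)` for 2-D).
#'   Spatial dims are zero-padded up to the network's pooling factor and
#'   the output cropped back.
#' @param train Apply dropout (rate `net$dropout_rate`).
#' @param keep_cache Retain activations for [backward_pass()].
#' @return List `out` (output tensor, input shape, sigmoid probabilities),
#'   `logits`, and `cache` when requested.
#' @export
forward_pass <- function(net, x, train = FALSE, keep_cache = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  padded <- .pad_tensor(x, net$pool_factor, net$mode)
  acts <- vector("list", length(net$nodes))
  masks <- vector("list", length(net$nodes))
  pool_arg <- vector("list", length(net$nodes))
  final_id <- length(net$nodes)
  for (n in net$nodes) {
    a <- switch(
      n$kind,
      input = padded$x,
      conv = {
        src <- acts[[n$src[1]]]
        d <- dim(src)
        W <- net$params[[paste0("n", n$id, ".W")]]
        b <- net$params[[paste0("n", n$id, ".b")]]
        out <- cpp_conv_fwd(src, W, b, d[1], d[2], d[3], d[4],
                            n$kernel[1], n$kernel[2], n$kernel[3], n$dilation)
        if (n$act == "relu") out[out < 0] <- 0
        out
      },
      pool = {
        src <- acts[[n$src[1]]]
        d <- dim(src)
        f <- c(2L, 2L, if (net$mode == "3d" && d[4] > 1) 2L else 1L)
        r <- cpp_maxpool_fwd(src, d[1], d[2], d[3], d[4], f[1], f[2], f[3])
        pool_arg[[n$id]] <- list(argmax = r$argmax, in_dim = d, f = f)
        r$out
      },
      upsample = {
        src <- acts[[n$src[1]]]
        d <- dim(src)
        f <- c(2L, 2L, if (net$mode == "3d" && dim(padded$x)[4] > 1) 2L else 1L)
        pool_arg[[n$id]] <- list(in_dim = d, f = f)
        cpp_upsample_fwd(src, d[1], d[2], d[3], d[4], f[1], f[2], f[3])
      },
      concat = {
        a1 <- acts[[n$src[1]]]; a2 <- acts[[n$src[2]]]
        d1 <- dim(a1); d2 <- dim(a2)
        out <- array(0, c(d1[1] + d2[1], d1[2], d1[3], d1[4]))
        out[seq_len(d1[1]), , , ] <- a1
        out[d1[1] + seq_len(d2[1]), , , ] <- a2
        out
      },
      dropout = {
        src <- acts[[n$src[1]]]
        if (train && net$dropout_rate > 0) {
          keep <- 1 - net$dropout_rate
          m <- array((runif(length(src)) < keep) / keep, dim(src))
          masks[[n$id]] <- m
          src * m
        } else src
      },
      abort(sprintf("unknown node kind %s", n$kind))
    )
    acts[[n$id]] <- a
  }
  logits_full <- acts[[final_id]]
  # final node act is sigmoid: acts holds pre-activation for the head
  probs_full <- 1 / (1 + exp(-logits_full))
  crop <- function(t) {
    d <- padded$orig
    t[, seq_len(d[2]), seq_len(d[3]), seq_len(d[4]), drop = FALSE]
  }
  res <- list(out = crop(probs_full), logits = crop(logits_full))
  if (keep_cache)
    res$cache <- list(acts = acts, masks = masks, pool_arg = pool_arg,
                      padded_dim = dim(padded$x), orig_dim = padded$orig)
  res
}

#' Backward pass: parameter gradients from an output-logit gradient
#'
#' @param net A `lungcad_net`.
#' @param cache Cache from [forward_pass()] with `keep_cache = TRUE`.
#' @param dlogits Gradient of the loss with respect to the output
#'   pre-sigmoid logits, shaped like the (cropped) input.
#' @return Named list of parameter gradients (same keys as `net$params`).
#' @export
backward_pass <- function(net, cache, dlogits) {
  if (length(dim(dlogits)) == 3L) dim(dlogits) <- c(dim(dlogits), 1L)
  grads <- vector("list", length(net$nodes))
  pgrads <- list()
  full <- array(0, cache$padded_dim)
  d0 <- cache$orig_dim
  full[, seq_len(d0[2]), seq_len(d0[3]), seq_len(d0[4])] <- dlogits
  final_id <- length(net$nodes)
  grads[[final_id]] <- full
  for (i in rev(seq_along(net$nodes))) {
    n <- net$nodes[[i]]
    g <- grads[[i]]
    if (is.null(g) || n$kind == "input") next
    if (n$kind == "conv") {
      out <- cache$acts[[n$id]]
      if (n$act == "relu") g <- g * (out > 0)
      # sigmoid head: incoming gradient is already w.r.t. pre-activation
      src <- cache$acts[[n$src[1]]]
      d <- dim(src)
      W <- net$params[[paste0("n", n$id, ".W")]]
      r <- cpp_conv_bwd(src, W, g, d[1], d[2], d[3], d[4],
                        n$kernel[1], n$kernel[2], n$kernel[3], n$dilation)
      pgrads[[paste0("n", n$id, ".W")]] <- r$dW
      pgrads[[paste0("n", n$id, ".b")]] <- r$db
      grads[[n$src[1]]] <- .acc(grads[[n$src[1]]], r$dx)
    } else if (n$kind == "pool") {
      pa <- cache$pool_arg[[n$id]]
      dx <- cpp_maxpool_bwd(g, pa$argmax, pa$in_dim[1], pa$in_dim[2],
                            pa$in_dim[3], pa$in_dim[4])
      grads[[n$src[1]]] <- .acc(grads[[n$src[1]]], dx)
    } else if (n$kind == "upsample") {
      pa <- cache$pool_arg[[n$id]]
      dx <- cpp_upsample_bwd(g, pa$in_dim[1], pa$in_dim[2], pa$in_dim[3],
                             pa$in_dim[4], pa$f[1], pa$f[2], pa$f[3])
      grads[[n$src[1]]] <- .acc(grads[[n$src[1]]], dx)
    } else if (n$kind == "concat") {
      c1 <- dim(cache$acts[[n$src[1]]])[1]
      g1 <- g[seq_len(c1), , , , drop = FALSE]
      g2 <- g[-seq_len(c1), , , , drop = FALSE]
      grads[[n$src[1]]] <- .acc(grads[[n$src[1]]], g1)
      grads[[n$src[2]]] <- .acc(grads[[n$src[2]]], g2)
    } else if (n$kind == "dropout") {
      m <- cache$masks[[n$id]]
      dx <- if (is.null(m)) g else g * m
      grads[[n$src[1]]] <- .acc(grads[[n$src[1]]], dx)
    }
    grads[[i]] <- NULL  # free
  }
  pgrads
}

.acc <- function(a, b) if (is.null(a)) b else a + b

#' Count trainable parameters of a network
#'
#' @param net A `lungcad_net`.
#' @param exclude_frozen Count only parameters of currently trainable
#'   layers (see [resolve_freeze_group()] / [fit()]).
#' @return Integer scalar count.
#' @export
count_params <- function(net, exclude_frozen = FALSE) {
  keys <- names(net$params)
  if (exclude_frozen) keys <- keys[keys %in% .trainable_keys(net)]
  sum(vapply(net$params[keys], length, numeric(1)))
}

.trainable_keys <- function(net) {
  ids <- vapply(net$nodes, function(n)
    if (n$table_name %in% net$trainable_rows) n$id else NA_integer_, integer(1))
  ids <- ids[!is.na(ids)]
  keys <- c(paste0("n", ids, ".W"), paste0("n", ids, ".b"))
  keys[keys %in% names(net$params)]
}

#' Predict a probability map for a patch or volume
#'
#' @param net A `lungcad_net`.
#' @param voxels 3-D array in `(z, y, x)` order (a patch or volume).
#' @return Probability array of the same shape.
#' @export
predict_map <- function(net, voxels) {
  d <- dim(voxels)
  x <- array(as.vector(aperm(voxels, c(3, 2, 1))), c(1L, d[3], d[2], d[1]))
  r <- forward_pass(net, x, train = FALSE)
  aperm(array(r$out, dim(r$out)[2:4]), c(3, 2, 1))
}
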