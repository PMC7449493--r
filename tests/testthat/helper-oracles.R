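# Independent oracles, deliberately written with plain loops / shifts and no
# reuse of the package's own primitives.

# brute-force Otsu over a 256-bin histogram
oracle_otsu <- function(values, n_bins = 256) {
  rng <- range(values)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(values, breaks, all.inside = TRUE), nbins = n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  best <- -Inf; best_k <- 1
  n <- sum(h)
  for (k in 1:(n_bins - 1)) {
    w0 <- sum(h[1:k]) / n
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:k] * mids[1:k]) / sum(h[1:k])
    mu1 <- sum(h[(k + 1):n_bins] * mids[(k + 1):n_bins]) / sum(h[(k + 1):n_bins])
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best) { best <- v; best_k <- k }
  }
  breaks[best_k + 1]
}

# 2-D binary closing by explicit shift loops (disc of radius r, unit spacing)
oracle_close2d <- function(m, r) {
  offs <- list()
  for (dy in -ceiling(r):ceiling(r))
    for (dx in -ceiling(r):ceiling(r))
      if (dy^2 + dx^2 <= r^2) offs[[length(offs) + 1]] <- c(dy, dx)
  shift <- function(mat, dy, dx, fill) {
    out <- matrix(fill, nrow(mat), ncol(mat))
    ys <- max(1, 1 + dy):min(nrow(mat), nrow(mat) + dy)
    xs <- max(1, 1 + dx):min(ncol(mat), ncol(mat) + dx)
    out[ys, xs] <- mat[ys - dy, xs - dx]
    out
  }
  dil <- matrix(FALSE, nrow(m), ncol(m))
  for (o in offs) dil <- dil | shift(m, o[1], o[2], FALSE)
  ero <- matrix(TRUE, nrow(m), ncol(m))
  for (o in offs) ero <- ero & shift(dil, -o[1], -o[2], FALSE)
  ero | m
}

# connected-component count by recursive-free BFS flood fill (26-conn)
oracle_count_components <- function(mask) {
  d <- dim(mask)
  seen <- array(FALSE, d)
  count <- 0
  idx_all <- which(mask)
  for (s in idx_all) {
    if (seen[s]) next
    count <- count + 1
    stack <- s
    seen[s] <- TRUE
    while (length(stack)) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      k <- (cur - 1) %% d[1] + 1
      rem <- (cur - 1) %/% d[1]
      j <- rem %% d[2] + 1
      i <- rem %/% d[2] + 1
      for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
        kk <- k + dk; jj <- j + dj; ii <- i + di
        if (kk < 1 || jj < 1 || ii < 1 || kk > d[1] || jj > d[2] || ii > d[3]) next
        q <- kk + d[1] * ((jj - 1) + d[2] * (ii - 1))
        if (mask[q] && !seen[q]) { seen[q] <- TRUE; stack <- c(stack, q) }
      }
    }
  }
  count
}

# scalar Adam recurrence, written independently step by step
oracle_adam_traj <- function(g_seq, mu = 0.9, up = 0.9999, eta = 0.01,
                             eps = 1e-8) {
  m <- 0; n <- 0
  deltas <- numeric(length(g_seq))
  for (t in seq_along(g_seq)) {
    g <- g_seq[t]
    m <- mu * m + (1 - mu) * g
    n <- up * n + (1 - up) * g^2
    mh <- m / (1 - mu^t)
    nh <- n / (1 - up^t)
    deltas[t] <- -eta * mh / (sqrt(nh) + eps)
  }
  deltas
}

# brute-force FROC: enumerate all distinct score thresholds, re-match with
# plain loops, read sensitivities off at the operating points
oracle_froc <- function(candidates, truths, scan_ids,
                        ops = c(0.125, 0.25, 0.5, 1, 2, 4, 8)) {
  n_scan <- length(scan_ids)
  thr_all <- sort(unique(candidates$probability))
  pts <- lapply(c(thr_all, Inf), function(th) {
    det <- 0; fp <- 0
    for (sid in scan_ids) {
      cs <- candidates[candidates$seriesuid == sid &
                         candidates$probability >= th, , drop = FALSE]
      ts <- truths[truths$seriesuid == sid, , drop = FALSE]
      used <- rep(FALSE, nrow(cs))
      if (nrow(ts)) for (j in seq_len(nrow(ts))) {
        hit <- FALSE
        if (nrow(cs)) for (i in seq_len(nrow(cs))) {
          dd <- sqrt((cs$coordX[i] - ts$coordX[j])^2 +
                     (cs$coordY[i] - ts$coordY[j])^2 +
                     (cs$coordZ[i] - ts$coordZ[j])^2)
          if (dd <= ts$diameter_mm[j] / 2) { hit <- TRUE; used[i] <- TRUE }
        }
        if (hit) det <- det + 1
      }
      if (nrow(cs)) fp <- fp + sum(!used)
    }
    c(sens = det / max(1, nrow(truths)), fps = fp / n_scan)
  })
  pts <- do.call(rbind, pts)
  sens_at <- vapply(ops, function(f) {
    ok <- pts[, "fps"] <= f
    if (!any(ok)) 0 else max(pts[ok, "sens"])
  }, numeric(1))
  list(sens = sens_at, auc = mean(sens_at))
}

# random candidate/truth fixture generator for FROC stress tests
random_froc_fixture <- function(seed) {
  set.seed(seed)
  n_scan <- sample(1:3, 1)
  scan_ids <- paste0("s", seq_len(n_scan))
  truths <- list()
  for (sid in scan_ids) {
    k <- sample(0:3, 1)
    if (k) truths[[sid]] <- tibble::tibble(
      seriesuid = sid, coordX = runif(k, 0, 100), coordY = runif(k, 0, 100),
      coordZ = runif(k, 0, 100), diameter_mm = runif(k, 4, 25))
  }
  truths <- dplyr::bind_rows(truths)
  if (!nrow(truths))
    truths <- tibble::tibble(seriesuid = scan_ids[1], coordX = 50, coordY = 50,
                             coordZ = 50, diameter_mm = 10)
  n_cand <- sample(1:50, 1)
  cand <- tibble::tibble(
    seriesuid = sample(scan_ids, n_cand, replace = TRUE),
    coordX = runif(n_cand, 0, 100), coordY = runif(n_cand, 0, 100),
    coordZ = runif(n_cand, 0, 100),
    probability = round(runif(n_cand), 2))
  # push some candidates inside truths so hits occur
  n_hit <- min(nrow(truths), n_cand)
  for (j in seq_len(n_hit)) {
    cand$seriesuid[j] <- truths$seriesuid[j]
    cand$coordX[j] <- truths$coordX[j] + runif(1, -1, 1)
    cand$coordY[j] <- truths$coordY[j]
    cand$coordZ[j] <- truths$coordZ[j]
  }
  list(candidates = cand, truths = truths, scan_ids = scan_ids)
}
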