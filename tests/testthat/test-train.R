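test_that("adam matches its closed form at t = 1 and fixes zero gradients", {
  h <- adam_hyper()  # mu 0.9, upsilon 0.9999, eta 0.01, eps 1e-8
  s0 <- adam_init(0)
  z <- adam_step(s0, 0, h)
  expect_identical(z$delta, 0)          # zero gradient moves nothing
  r <- adam_step(s0, 2, h)
  # t = 1 bias correction makes m_hat = g, n_hat = g^2
  expect_equal(r$delta, -0.01 * 2 / (2 + 1e-8), tolerance = 1e-12)
  expect_equal(r$state$t, 1L)
  expect_error(adam_step(s0, NaN, h), class = "lungcad_numeric_error")
  expect_error(adam_hyper(mu = 1), "mu")
})

test_that("adam follows the scalar brute-force recurrence for 100 steps", {
  set.seed(31)
  g_seq <- rnorm(100, 0.5, 1)
  oracle <- oracle_adam_traj(g_seq)
  s <- adam_init(0)
  for (t in seq_along(g_seq)) {
    r <- adam_step(s, g_seq[t], adam_hyper())
    expect_lt(abs(r$delta - oracle[t]), 1e-10)
    s <- r$state
  }
  # constant gradient: bias-corrected m_hat equals g exactly at every t
  s <- adam_init(0)
  for (t in 1:50) {
    s <- adam_step(s, 1.7, adam_hyper())$state
    expect_lt(abs(s$m / (1 - 0.9^t) - 1.7), 1e-9)
  }
})

test_that("adam with matched momenta matches the two-step hand recurrence", {
  h <- adam_hyper(mu = 0.9, upsilon = 0.9, eta = 0.01)
  s <- adam_init(0)
  r1 <- adam_step(s, 3, h)
  r2 <- adam_step(r1$state, 3, h)
  d_oracle <- oracle_adam_traj(c(3, 3), mu = 0.9, up = 0.9)
  expect_lt(abs(r1$delta - d_oracle[1]), 1e-12)
  expect_lt(abs(r2$delta - d_oracle[2]), 1e-12)
})

test_that("masked cross-entropy honours its closed forms and the ignore mask", {
  p <- array(0.5, c(2, 4, 4))
  t1 <- array(rbinom(32, 1, 0.5), c(2, 4, 4))
  expect_equal(masked_cross_entropy(p, t1), log(2), tolerance = 1e-9)
  near <- array(ifelse(t1 > 0, 0.9999, 0.0001), c(2, 4, 4))
  expect_lt(masked_cross_entropy(near, t1), 0.001)
  # ignoring half the voxels equals a loop over the kept half
  set.seed(14)
  pr <- array(runif(32, 0.05, 0.95), c(2, 4, 4))
  ig <- array(rep(c(TRUE, FALSE), 16), c(2, 4, 4))
  acc <- 0; n <- 0
  for (i in seq_along(pr)) if (!ig[i]) {
    acc <- acc - (t1[i] * log(pr[i]) + (1 - t1[i]) * log(1 - pr[i]))
    n <- n + 1
  }
  expect_equal(masked_cross_entropy(pr, t1, ig), acc / n, tolerance = 1e-12)
  expect_error(masked_cross_entropy(pr, t1, array(TRUE, c(2, 4, 4))),
               "ignored")
})

test_that("augmentation emits exactly six distinct, volume-preserving views", {
  set.seed(6)
  items <- lapply(1:7, function(i) {
    v <- array(rnorm(3 * 8 * 8), c(3, 8, 8))
    lab <- array(0, c(3, 8, 8)); lab[2, 2:3, 5:7] <- 1  # asymmetric
    list(voxels = v, label = lab)
  })
  aug <- augment_six(items)
  expect_length(aug, 42)
  # all six views of one asymmetric item are pairwise distinct
  six <- aug[1:6]
  for (i in 1:5) for (j in (i + 1):6)
    expect_false(identical(six[[i]]$voxels, six[[j]]$voxels))
  # labels transform identically and foreground counts are preserved
  expect_true(all(vapply(six, function(a) sum(a$label), numeric(1)) ==
                    sum(items[[1]]$label)))
  # 180-degree rotation is the composition of the two flips
  tfs <- vapply(six, function(a) attr(a, "transform"), character(1))
  r180 <- six[[which(tfs == "rot180")]]$voxels
  hv <- six[[which(tfs == "hflip")]]$voxels[, dim(r180)[2]:1, ]
  expect_identical(r180, hv)
  # rotations require square in-plane dims
  expect_error(augment_six(list(list(voxels = array(0, c(2, 4, 6))))),
               "square")
})

test_that("accuracy and overfitting-ratio algebra is exact", {
  expect_equal(train_acc(850, 1000), 0.85)
  expect_equal(train_acc(0, 5), 0)
  expect_equal(train_acc(5, 5), 1)
  expect_error(train_acc(1, 0), "positive")
  expect_equal(over_ratio(0.9348, 0.8728), 1.0710, tolerance = 5e-4)
  expect_equal(over_ratio(0.7, 0.7), 1)
  expect_equal(over_ratio(0.8, 0.9), 0.889, tolerance = 1e-3)
  expect_error(over_ratio(0.8, 0), "positive")
})

test_that("freeze groups resolve to contiguous spans of the layer sequence", {
  tab <- default_multiscale_table()
  all_rows <- resolve_freeze_group(tab, "conv1-Up12")
  expect_setequal(all_rows, tab$name[!is.na(tab$group)])
  up12 <- resolve_freeze_group(tab, "Up12")
  expect_true(all(grepl("^(Up12|Out)", up12)))
  expect_true(length(up12) < length(all_rows))
  mid <- resolve_freeze_group(tab, "Up6-Up8")
  expect_true(all(tab$group[tab$name %in% mid] %in% c("Up6", "Up7", "Up8")))
  # the reference fine-tuning table spells conv1 as "convl"
  expect_identical(resolve_freeze_group(tab, "convl-Up12"), all_rows)
  # spans are contiguous in the group ordering
  groups <- unique(tab$group[!is.na(tab$group)])
  got <- unique(tab$group[tab$name %in% resolve_freeze_group(tab, "conv3-Up8")])
  expect_identical(got, groups[match("conv3", groups):match("Up8", groups)])
  expect_error(resolve_freeze_group(tab, "Up99"), "unknown")
})

test_that("training reduces the loss and is seed-deterministic", {
  tab <- multiscale_table(levels = 1, level_stride = 2, width = 1 / 16)
  net <- build_network(tab, "2d", seed = 4)
  ds <- tiny_patch_set(20)
  cfg <- train_config(lr = 0.005, dropout = 0.5, batch_size = 4,
                      max_steps = 40, pos_weight = 5, eval_every = 20,
                      seed = 11)
  f1 <- fit(net, ds, cfg, optimizer = "adam")
  expect_lt(mean(tail(f1$loss_history$loss, 5)),
            mean(head(f1$loss_history$loss, 5)))
  f2 <- fit(net, ds, cfg, optimizer = "adam")
  expect_identical(f1$loss_history, f2$loss_history)
  expect_identical(f1$net$params, f2$net$params)
  expect_error(fit(net, list(), cfg), "empty")
})

test_that("sgd fine-tuning with a frozen encoder leaves it bit-identical", {
  tab <- multiscale_table(levels = 1, level_stride = 2, width = 1 / 16)
  net <- build_network(tab, "2d", seed = 8)
  ds <- tiny_patch_set(12)
  cfg <- train_config(lr = 0.01, dropout = 0, batch_size = 4, max_steps = 25,
                      pos_weight = 5, eval_every = 25,
                      freeze_group = "Up12", seed = 2)
  f <- fit(net, ds, cfg, optimizer = "sgd")
  trainable <- resolve_freeze_group(tab, "Up12")
  for (n in f$net$nodes) {
    key <- paste0("n", n$id, ".W")
    if (is.null(net$params[[key]])) next
    if (n$table_name %in% trainable) {
      expect_false(identical(f$net$params[[key]], net$params[[key]]),
                   label = paste("trainable", n$name))
    } else {
      expect_identical(f$net$params[[key]], net$params[[key]])
    }
  }
  expect_lt(tail(f$loss_history$loss, 1), f$loss_history$loss[1])
})
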