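test_that("candidate extraction finds blob centroids and scores", {
  prob <- array(0, c(10, 20, 20))
  prob[4:6, 4:6, 4:6] <- 0.9
  prob[7:8, 14:16, 12:15] <- c(0.7)
  cand <- extract_candidates(prob, 0.5, spacing = c(1, 1, 1),
                             origin = c(0, 0, 0), series_id = "s1")
  expect_equal(nrow(cand), 2)
  expect_setequal(round(cand$probability, 2), c(0.9, 0.7))
  # centroid agrees with an explicit-loop oracle within 1e-9 mm
  idx <- which(prob > 0.5, arr.ind = TRUE)
  blob1 <- idx[idx[, 1] <= 6, , drop = FALSE]
  wsum <- c(0, 0, 0); wtot <- 0
  for (r in seq_len(nrow(blob1))) {
    w <- prob[blob1[r, 1], blob1[r, 2], blob1[r, 3]]
    wsum <- wsum + w * (blob1[r, ] - 1)
    wtot <- wtot + w
  }
  ctr <- wsum / wtot  # 0-based (z,y,x) = world mm at unit spacing
  got <- cand[which.max(cand$probability), ]
  expect_lt(max(abs(c(got$coordZ, got$coordY, got$coordX) - ctr)), 1e-9)
  # empty map, out-of-range threshold
  expect_equal(nrow(extract_candidates(array(0, c(4, 4, 4)), 0.5)), 0)
  expect_error(extract_candidates(prob, 1.5), "0, 1")
})

test_that("size classification uses the 5 and 15 mm cut points", {
  expect_equal(classify_size(4.125), "small")
  expect_equal(classify_size(9.125), "middle")
  expect_equal(classify_size(18.773), "large")
  expect_equal(classify_size(c(5, 15)), c("middle", "middle"))  # inclusive
  expect_equal(classify_size(c(4.999, 15.001)), c("small", "large"))
  expect_error(classify_size(0), "positive")
})

test_that("candidate matching follows the within-radius convention", {
  truths <- tibble::tibble(seriesuid = "s1", coordX = 50, coordY = 50,
                           coordZ = 50, diameter_mm = 10)
  hit <- tibble::tibble(seriesuid = "s1", coordX = 50, coordY = 50,
                        coordZ = 50, probability = 0.9)
  m <- match_candidates(hit, truths)
  expect_equal(m$truths$hit_score, 0.9)
  expect_equal(nrow(m$false_positives), 0)
  # two candidates inside one nodule: one detection, zero FPs
  two <- dplyr::bind_rows(hit, tibble::tibble(
    seriesuid = "s1", coordX = 52, coordY = 50, coordZ = 50, probability = 0.4))
  m2 <- match_candidates(two, truths)
  expect_equal(m2$truths$hit_score, 0.9)
  expect_equal(nrow(m2$false_positives), 0)
  # candidate at distance d/2 + epsilon is a false positive
  out <- tibble::tibble(seriesuid = "s1", coordX = 55.001, coordY = 50,
                        coordZ = 50, probability = 0.8)
  m3 <- match_candidates(out, truths)
  expect_equal(m3$truths$hit_score, -Inf)
  expect_equal(nrow(m3$false_positives), 1)
})

test_that("froc handles the perfect and the empty detector", {
  truths <- tibble::tibble(
    seriesuid = rep(c("a", "b"), c(2, 1)),
    coordX = c(10, 40, 20), coordY = c(10, 40, 20), coordZ = c(10, 40, 20),
    diameter_mm = c(8, 10, 6))
  perfect <- tibble::tibble(
    seriesuid = truths$seriesuid, coordX = truths$coordX,
    coordY = truths$coordY, coordZ = truths$coordZ, probability = 1)
  fr <- froc(match_candidates(perfect, truths))
  expect_equal(fr$operating$sensitivity, rep(1, 7))
  expect_equal(fr$auc, 1)
  expect_equal(fr$operating$fp_per_scan, c(0.125, 0.25, 0.5, 1, 2, 4, 8))

  none <- perfect[0, ]
  fr0 <- froc(match_candidates(none, truths, scan_ids = c("a", "b")))
  expect_equal(fr0$operating$sensitivity, rep(0, 7))
  expect_error(froc(match_candidates(perfect, truths[0, ],
                                     scan_ids = c("a", "b"))),
               class = "lungcad_undefined_sensitivity")
})

test_that("froc equals the brute-force threshold-enumeration oracle", {
  # fixed 2-scan, 3-nodule, 5-candidate fixture
  truths <- tibble::tibble(
    seriesuid = c("a", "a", "b"), coordX = c(10, 30, 20),
    coordY = c(10, 30, 20), coordZ = c(10, 30, 20), diameter_mm = c(8, 8, 8))
  cand <- tibble::tibble(
    seriesuid = c("a", "a", "a", "b", "b"),
    coordX = c(10, 30.5, 60, 20, 80), coordY = c(10, 30, 60, 20.5, 10),
    coordZ = c(10.5, 30, 60, 20, 10),
    probability = c(0.9, 0.6, 0.7, 0.5, 0.5))
  got <- froc(match_candidates(cand, truths, scan_ids = c("a", "b")))
  want <- oracle_froc(cand, truths, c("a", "b"))
  expect_identical(got$operating$sensitivity, want$sens)
  expect_identical(got$auc, want$auc)

  # 100 random fixtures of up to 50 candidates: exact agreement + monotone
  for (s in 1:100) {
    fx <- random_froc_fixture(1000 + s)
    got <- froc(match_candidates(fx$candidates, fx$truths, fx$scan_ids))
    want <- oracle_froc(fx$candidates, fx$truths, fx$scan_ids)
    expect_identical(got$operating$sensitivity, want$sens,
                     label = sprintf("fixture %d", s))
    expect_true(all(diff(got$operating$sensitivity) >= 0))
  }
})

test_that("confusion summary arithmetic and symmetry hold", {
  cs <- confusion_summary(9, 1, 8, 2)
  expect_equal(cs$sn, 0.9)
  expect_equal(cs$sp, 0.8)
  expect_equal(cs$acc, 0.85)
  all1 <- confusion_summary(5, 0, 5, 0)
  expect_equal(unlist(all1[1, ]), c(acc = 1, sn = 1, sp = 1))
  # swapping tp<->tn with fn<->fp exchanges SN and SP
  sw <- confusion_summary(8, 2, 9, 1)
  expect_equal(sw$sn, cs$sp)
  expect_equal(sw$sp, cs$sn)
  expect_error(confusion_summary(0, 0, 3, 1), "degenerate")
})

test_that("k-fold splits are balanced, disjoint and reproducible", {
  ids <- paste0("s", 1:10)
  f1 <- kfold_split(ids, 5, seed = 4)
  expect_length(f1, 5)
  test_sets <- lapply(f1, `[[`, "test")
  expect_true(all(lengths(test_sets) == 2))
  expect_setequal(unlist(test_sets), ids)
  expect_equal(anyDuplicated(unlist(test_sets)), 0)
  for (f in f1) expect_setequal(c(f$train, f$test), ids)
  expect_identical(kfold_split(ids, 5, seed = 4), f1)
  expect_false(identical(kfold_split(ids, 5, seed = 5), f1))
  expect_error(kfold_split(ids[1:3], 5), "fewer")
})

test_that("froc tidiers expose the operating table and the auc", {
  truths <- tibble::tibble(seriesuid = "a", coordX = 1, coordY = 1,
                           coordZ = 1, diameter_mm = 10)
  cand <- tibble::tibble(seriesuid = "a", coordX = 1, coordY = 1, coordZ = 1,
                         probability = 0.8)
  fr <- froc(match_candidates(cand, truths))
  expect_identical(tidy(fr), fr$operating)
  expect_equal(glance(fr)$auc, 1)
  expect_s3_class(autoplot(fr), "ggplot")
})
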