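test_that("adaptive binarization matches the brute-force Otsu oracle", {
  set.seed(5)
  vals <- c(rnorm(4000, -800, 60), rnorm(6000, 40, 50))
  expect_equal(otsu_threshold(vals), oracle_otsu(vals))
  # perfectly separable two-level volume
  arr <- array(40, c(10, 10, 10))
  arr[sample(1000, 400)] <- -800
  v <- ct_volume(arr)
  m <- binarize_adaptive(v)
  expect_identical(m, arr == -800)
  expect_error(binarize_adaptive(ct_volume(array(5, c(4, 4, 4)))),
               class = "lungcad_degenerate_error")
})

test_that("background removal keeps interior dark structures only", {
  # phantom without bronchi: dark class = ambient air + 2 lungs + trachea
  ph <- cached("ph_nobronchi",
               generate_phantom(phantom_spec(n_bronchi = 0)))
  m <- binarize_adaptive(ph$volume)
  kept <- remove_background(m)
  expect_equal(oracle_count_components(kept), 3)
  # fully boundary-connected mask vanishes
  all_m <- array(TRUE, c(4, 4, 4))
  expect_equal(sum(remove_background(all_m)), 0)
  # one interior blob is untouched
  blob <- array(FALSE, c(7, 7, 7)); blob[3:5, 3:5, 3:5] <- TRUE
  expect_identical(remove_background(blob), blob)
  expect_equal(sum(remove_background(array(FALSE, c(3, 3, 3)))), 0)
})

test_that("body filling closes cavities and reaches Dice >= 0.95 on the phantom", {
  cav <- array(FALSE, c(3, 9, 9))
  cav[2, 2:8, 2:8] <- TRUE
  cav[2, 4:6, 4:6] <- FALSE  # internal cavity
  filled <- fill_body(cav)
  expect_true(all(filled[2, 2:8, 2:8]))
  solid <- array(FALSE, c(3, 5, 5)); solid[2, 2:4, 2:4] <- TRUE
  expect_identical(fill_body(solid), solid)

  ph <- ph_default()
  rough <- fill_body(remove_background(binarize_adaptive(ph$volume)))
  target <- ph$truth$lung_mask | ph$truth$trachea_mask
  expect_gte(dice_coefficient(rough, target), 0.95)
})

test_that("optimal-threshold growing recovers the trachea without leaking", {
  ph <- ph_default()
  rough <- fill_body(remove_background(binarize_adaptive(ph$volume)))
  tr <- extract_main_trachea(ph$volume, rough)
  truth <- ph$truth$trachea_mask
  expect_gte(sum(tr & truth) / sum(truth), 0.90)
  expect_lte(sum(tr & ph$truth$lung_mask) / max(1, sum(tr)), 0.05)

  # no tubular structure near the top: signalled, not fatal
  flat <- ct_volume(array(40, c(16, 16, 16)))
  rough2 <- array(FALSE, c(16, 16, 16)); rough2[2:4, 8:9, 8:9] <- TRUE
  expect_error(extract_main_trachea(flat, rough2),
               class = "lungcad_trachea_not_found")
})

test_that("growth stops below the neck intensity of a two-chamber fixture", {
  d <- c(30, 30, 30)
  vol <- array(40, d)
  # tube at -1000 from the top down to z index 12
  g <- expand.grid(z = 1:30, y = 1:30, x = 1:30)
  tube <- array(g$z >= 12 & (g$y - 15)^2 + (g$x - 15)^2 <= 4, d)
  vol[tube] <- -1000
  # neck at -600 joins a large -600 chamber below
  neck <- array(g$z %in% 10:11 & g$y == 15 & g$x == 15, d)
  chamber <- array(g$z %in% 3:9 & abs(g$y - 15) <= 9 & abs(g$x - 15) <= 9, d)
  vol[neck] <- -600
  vol[chamber] <- -600
  v <- ct_volume(vol)
  rough <- array(tube | neck | chamber, d)
  tr <- extract_main_trachea(v, rough, seg_config(trachea_max_threshold = -200))
  # exhaustive sweep oracle: find the largest threshold without explosion
  expect_lt(attr(tr, "threshold"), -600)
  expect_equal(sum(tr & chamber), 0)
  expect_gte(sum(tr & tube) / sum(tube), 0.95)
})

test_that("bronchus reconstruction flags thin dark tubes and obeys ordering", {
  ph <- ph_default()
  rough <- fill_body(remove_background(binarize_adaptive(ph$volume)))
  after_tr <- rough & !extract_main_trachea(ph$volume, rough)
  br <- reconstruct_bronchi(ph$volume, after_tr)
  truth <- ph$truth$bronchi_mask
  expect_gte(sum(br & truth) / sum(truth), 0.80)
  # reconstruction lies between the original image and the closing marker
  recon <- attr(br, "reconstruction")
  img <- ph$volume$voxels
  img[!after_tr] <- max(img)
  marker <- gray_close(img, se_ball(4, ph$volume$spacing))
  expect_true(all(recon >= img - 1e-9))
  expect_true(all(recon <= marker + 1e-9))

  # an image without thin dark structures yields an empty bronchi mask
  smooth <- ct_volume(array(-800, c(10, 20, 20)))
  smooth$voxels[, 1:2, ] <- 40
  m <- array(TRUE, c(10, 20, 20))
  expect_equal(sum(reconstruct_bronchi(smooth, m)), 0)
})

test_that("fusion detection implements the T = 4 area-ratio rule", {
  mk <- function(a1, a2) {
    m <- array(FALSE, c(1, 30, 200))
    m[1, 1:10, 1:(a1 / 10)] <- TRUE
    if (a2 > 0) m[1, 15:24, 1:(a2 / 10)] <- TRUE
    m
  }
  expect_true(as.logical(detect_fusion(mk(100, 20))))    # ratio 5 > 4
  expect_false(as.logical(detect_fusion(mk(100, 90))))   # ratio 1.11
  expect_true(as.logical(detect_fusion(mk(100, 0))))     # single component
  expect_error(detect_fusion(array(FALSE, c(2, 2, 2))), "empty")
  # absolute-difference variant stays available
  cfg <- seg_config(fusion_threshold = 50, fusion_mode = "absolute")
  expect_true(as.logical(detect_fusion(mk(100, 20), cfg)))
  expect_false(as.logical(detect_fusion(mk(100, 90), cfg)))
})

test_that("integral projection finds a known bridge column", {
  # two rectangles joined by a 1-voxel-wide bridge at column 25 (0-based 24)
  m <- array(FALSE, c(5, 20, 48))
  m[, 3:18, 5:20] <- TRUE
  m[, 3:18, 30:45] <- TRUE
  m[, 10, 21:29] <- TRUE  # thin bridge through the centre band
  sep <- separate_lungs(m, fused = TRUE)
  expect_equal(oracle_count_components(sep$mask), 2)
  # minimum projection column lies strictly between the rectangles
  expect_true(all(sep$line$column >= 20 & sep$line$column <= 29))
  # not fused: identity with empty line
  id <- separate_lungs(m, fused = FALSE)
  expect_identical(id$mask, m)
  expect_equal(nrow(id$line), 0)
})

test_that("fused phantom separates into two lungs matching the truth", {
  seg <- seg_fused()
  expect_true(seg$fused_detected)
  expect_equal(oracle_count_components(seg$lung_mask), 2)
  tr <- ph_fused()$truth
  expect_gte(dice_coefficient(seg$left_mask, tr$left_mask), 0.9)
  expect_gte(dice_coefficient(seg$right_mask, tr$right_mask), 0.9)
})

test_that("rolling-ball repair fills narrow notches but not wide ones", {
  # disc of radius 20 with notches bitten into the boundary
  g <- expand.grid(y = 1:120, x = 1:120)
  base <- matrix((g$y - 60)^2 + (g$x - 45)^2 <= 30^2, 120, 120)
  bite5 <- matrix((g$y - 60)^2 + (g$x - 73)^2 <= 5^2, 120, 120)
  m5 <- array(base & !bite5, c(1, 120, 120))
  rep5 <- repair_boundary(m5, c(1, 1, 1), seg_config())
  oracle5 <- oracle_close2d(base & !bite5, 12.5)
  expect_identical(rep5[1, , ], oracle5)
  expect_gt(sum(rep5[1, , ] & bite5), 0.5 * sum(base & bite5))

  # wide shallow bite of radius 30 is mostly left open
  bite30 <- matrix((g$y - 60)^2 + (g$x - 100)^2 <= 30^2, 120, 120)
  m30 <- array(base & !bite30, c(1, 120, 120))
  rep30 <- repair_boundary(m30, c(1, 1, 1), seg_config())
  expect_identical(rep30[1, , ], oracle_close2d(base & !bite30, 12.5))
  expect_lt(sum(rep30[1, , ] & bite30), 0.5 * sum(base & bite30))

  # convex component unchanged; output always contains input
  conv <- array(base, c(1, 120, 120))
  expect_identical(repair_boundary(conv, c(1, 1, 1)), conv)
  expect_true(all(rep5[m5]))
  bad_cfg <- seg_config()
  bad_cfg$ball_radius_mm <- -1
  expect_error(repair_boundary(m5, c(1, 1, 1), bad_cfg), "positive")
})

test_that("pleural-notch phantom is repaired by the 12.5 mm ball", {
  seg <- seg_notch()
  notch <- ph_notch()$truth$notch_mask
  expect_gte(sum(seg$lung_mask & notch) / sum(notch), 0.90)
})

test_that("full pipeline meets the phantom accuracy contract", {
  seg <- seg_default()
  tr <- ph_default()$truth
  expect_gte(dice_coefficient(seg$lung_mask, tr$lung_mask), 0.90)
  expect_lte(sum(seg$lung_mask & tr$trachea_mask) / sum(tr$trachea_mask), 0.05)
  expect_false(seg$fused_detected)
  # stage contracts
  expect_true(all(seg$stages$repaired[seg$stages$separated]))   # repair adds only
  expect_true(all(seg$stages$fused_check_input <= seg$stages$body_filled))
  # left/right partition the final mask exactly
  expect_true(all((seg$left_mask | seg$right_mask) == seg$lung_mask))
  expect_equal(sum(seg$left_mask & seg$right_mask), 0)
  # all-air volume is degenerate
  expect_error(segment_lungs(ct_volume(array(-1000, c(8, 8, 8)))),
               class = "lungcad_degenerate_error")
})

test_that("the pipeline is deterministic", {
  v <- ph_default()$volume
  a <- segment_lungs(v)
  expect_identical(a$lung_mask, seg_default()$lung_mask)
  expect_identical(a$fused_detected, seg_default()$fused_detected)
})
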