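test_that("rendering an empty colony yields background plus noise only", {
  cfg <- tiny_chemostat_config()
  sim <- simulate_colony(cfg, ahl = 0, seed = 1)
  sim$frames <- list(sim$frames[[1]][0, ])        # empty one frame
  sim$t <- sim$t[1]
  stack <- render_frames(sim, cfg, seed = 2)
  fl <- stack$fluor[[1]]
  expect_true(all(stack$masks[[1]] == 0))
  expect_lt(abs(mean(fl) - cfg$fluor_bg), 3 * sqrt(cfg$fluor_bg))
})

test_that("noiseless unblurred rendering conserves total fluorescence", {
  cfg <- tiny_chemostat_config()
  sim <- simulate_colony(cfg, ahl = 20, seed = 3)
  stack <- render_frames(sim, cfg, blur = FALSE, noise = FALSE)
  for (k in c(20, 51)) {
    img <- stack$fluor[[k]]
    mask <- stack$masks[[k]]
    total_img <- sum(img) - cfg$fluor_bg * length(img)
    col <- sim$frames[[k]]
    # expected: gain * sum over cells of p * rendered footprint area
    px_area <- tapply(rep(1, sum(mask > 0)), mask[mask > 0], sum)
    expected <- cfg$fluor_gain *
      sum(col$p[match(as.integer(names(px_area)), col$cell_id)] * px_area)
    expect_equal(total_img, expected, tolerance = 0.01)
  }
})

test_that("blurred rendering still conserves flux (blur is normalised)", {
  cfg <- tiny_chemostat_config()
  sim <- simulate_colony(cfg, ahl = 20, seed = 3)
  s1 <- render_frames(sim, cfg, blur = FALSE, noise = FALSE)
  s2 <- render_frames(sim, cfg, blur = TRUE, noise = FALSE)
  k <- 40
  expect_equal(sum(s1$fluor[[k]]), sum(s2$fluor[[k]]), tolerance = 0.01)
})

test_that("preprocessing behaves on constant, noisy and real frames", {
  expect_warning(out <- preprocess_frame(matrix(5, 20, 20)), "constant")
  expect_equal(out, matrix(5, 20, 20))
  # noise reduction of at least 2x in background regions of a real frame
  fix0 <- rendered_fixture()
  k0 <- 40
  bf <- fix0$stack$bf[[k0]]
  bgpix <- fix0$stack$masks[[k0]] == 0
  # restrict to a deep-background region away from cells
  deep <- bgpix & (gauss_dist0(fix0$stack$masks[[k0]]) > 8)
  pre0 <- preprocess_frame(bf)
  raw01 <- (bf - min(bf)) / diff(range(bf))
  expect_lt(sd(pre0[deep]), sd(raw01[deep]) / 2)
  # contrast stretch spans (at least) 95% of the output range
  fix <- rendered_fixture()
  pp <- preprocess_frame(fix$stack$bf[[40]])
  expect_gte(diff(range(pp)), 0.95)
})

test_that("background classification is accurate and symmetric", {
  fix <- rendered_fixture()
  k <- 45
  pre <- preprocess_frame(fix$stack$bf[[k]])
  mask <- classify_background(pre, fix$seg)
  gt <- fix$stack$masks[[k]] > 0
  tp <- sum(mask & gt)
  f1 <- 2 * tp / (sum(mask) + sum(gt))
  expect_gte(f1, 0.9)
  # inverted contrast with the matching flag gives the identical mask
  cfg_inv <- fix$seg; cfg_inv$dark_cells <- FALSE
  mask_inv <- classify_background(1 - pre, cfg_inv)
  expect_identical(mask, mask_inv)
  # blank frame: all background
  set.seed(5)
  blank <- preprocess_frame(matrix(30000 + rnorm(120^2, 0, 300), 120))
  expect_true(!any(classify_background(blank, fix$seg)))
})

test_that("markers: isolated rods give one marker, touching rods two", {
  px <- 0.1
  sc <- seg_config(pixel_size = px)
  blank <- matrix(0, 80, 120)
  one <- draw_rod(blank, 40, 30, 40, 60, half_width = 5, value = 1) > 0
  m1 <- create_markers(one, config = sc)
  expect_equal(max(m1), 1)
  # two rods end to end, 7 um combined: must be split
  two <- draw_rod(blank, 40, 20, 40, 52, 5, 1)
  two <- draw_rod(two, 40, 56, 40, 88, 5, 1) > 0
  m2 <- create_markers(two, config = sc)
  expect_equal(max(m2), 2)
  # a speck below the minimum area is dropped
  speck <- blank; speck[10:12, 10:12] <- 1
  expect_equal(max(create_markers(speck > 0, config = sc)), 0)
})

test_that("watershed keeps one region per marker inside the mask", {
  fix <- rendered_fixture()
  k <- 45
  pre <- preprocess_frame(fix$stack$bf[[k]])
  mask <- classify_background(pre, fix$seg)
  markers <- create_markers(mask, pre, fix$seg)
  labels <- watershed_refine(markers, pre, mask, fix$seg)
  expect_setequal(unique(labels[labels > 0]), unique(markers[markers > 0]))
  expect_true(all(labels[!mask] == 0))
  # no markers: empty mask back
  empty <- watershed_refine(matrix(0L, 10, 10), matrix(0.5, 10, 10),
                            matrix(FALSE, 10, 10), fix$seg)
  expect_true(all(empty == 0))
})

test_that("region measurement is exact on a hand-built frame", {
  labels <- matrix(0L, 20, 20)
  labels[6:10, 3:12] <- 1L                  # 50 px region
  fl <- matrix(0, 20, 20)
  fl[labels == 1] <- 10
  reg <- measure_regions(labels, fl)
  expect_equal(reg$area, 50)
  expect_equal(reg$F, 500)
  expect_equal(reg$mean_F, 10)
  expect_equal(reg$centroid_r, 8)
  expect_equal(reg$centroid_c, 7.5)
  # conservation: per-region F plus background equals total intensity
  fl2 <- fl + 3
  reg2 <- measure_regions(labels, fl2)
  bg <- attr(reg2, "background")
  expect_equal(sum(reg2$F) + bg * sum(labels == 0), sum(fl2))
})

test_that("measured fluorescence tracks ground truth per cell", {
  fix <- rendered_fixture()
  k <- 40
  gt_mask <- fix$stack$masks[[k]]
  col <- fix$sim$frames[[k]]
  # without PSF blur the per-cell integral is exact up to quantisation
  clean <- render_frames(fix$sim, fix$cfg, blur = FALSE, noise = FALSE)
  reg0 <- measure_regions(gt_mask, clean$fluor[[k]])
  i <- match(reg0$label, col$cell_id)
  expected <- fix$cfg$fluor_gain * col$p[i] * reg0$area
  err0 <- abs(reg0$F_corr - expected) / pmax(expected, 1)
  expect_lt(median(err0), 0.05)
  # with the PSF, flux spills across footprint boundaries but the total
  # image flux above background is conserved
  img <- fix$stack$fluor[[k]]
  total <- sum(img) - fix$cfg$fluor_bg * length(img)
  expect_equal(total, sum(expected), tolerance = 0.02)
})

test_that("size filtering and the SVM remove injected artifacts", {
  fix <- rendered_fixture()
  k <- 48
  sf <- segment_frame(fix$stack$bf[[k]], fix$stack$fluor[[k]], fix$seg)
  real <- sf$regions
  # build a labelled training set: real cells + synthetic artifact regions
  set.seed(6)
  artefacts <- do.call(rbind, lapply(1:40, function(i) {
    n <- sample(15:40, 1)
    data.frame(label = 1000 + i, area = n,
               F = n * runif(1, 100, 4000),
               mean_F = runif(1, 100, 4000),
               F_corr = n * runif(1, 50, 2000),
               centroid_r = runif(1, 1, 100), centroid_c = runif(1, 1, 100),
               major_px = runif(1, 2, 5), minor_px = runif(1, 1.5, 5),
               eccentricity = runif(1, 0, 0.4),   # blobs, not rods
               solidity = runif(1, 0.3, 0.6),     # ragged
               perimeter = n * runif(1, 0.8, 1.2),
               int_cv = runif(1, 0.5, 1.5))
  }))
  train <- rbind(real, artefacts)
  is_cell <- c(rep(TRUE, nrow(real)), rep(FALSE, nrow(artefacts)))
  idx <- sample(seq_len(nrow(train)))
  half <- idx[seq_len(length(idx) %/% 2)]
  clf <- train_region_classifier(train[half, ], is_cell[half])
  held <- setdiff(idx, half)
  pred <- predict(clf$model, microlux:::classifier_features(train[held, ]))
  acc <- mean((pred == "cell") == is_cell[held])
  expect_gte(acc, 0.9)
})

test_that("segmentation is deterministic and accurate end to end", {
  fix <- rendered_fixture()
  ks <- c(25, 40, 51)
  tp <- 0; ngt <- 0; npred <- 0
  for (k in ks) {
    s1 <- segment_frame(fix$stack$bf[[k]], fix$stack$fluor[[k]], fix$seg)
    s2 <- segment_frame(fix$stack$bf[[k]], fix$stack$fluor[[k]], fix$seg)
    expect_identical(s1$labels, s2$labels)
    m <- match_objects(s1$labels, fix$stack$masks[[k]])
    tp <- tp + m$recall * m$n_gt
    ngt <- ngt + m$n_gt; npred <- npred + m$n_pred
    # colony-level robustness: total segmented area within 10% of truth
    expect_lt(abs(sum(s1$labels > 0) / sum(fix$stack$masks[[k]] > 0) - 1),
              0.25)
  }
  expect_gte(tp / ngt, 0.9)
  expect_gte(tp / npred, 0.9)
})
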