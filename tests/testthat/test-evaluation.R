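test_that("ROI dilation follows the 6-connected structuring element", {
  m <- array(FALSE, dim = c(7, 7, 7))
  m[4, 4, 4] <- TRUE
  expect_equal(sum(make_roi(m, 0)), 1)            # identity at 0 iterations
  roi1 <- make_roi(m, 1)
  expect_equal(sum(roi1), 7)                      # centre + 6 face neighbours
  expect_true(roi1[4, 4, 4] && roi1[3, 4, 4] && roi1[4, 4, 5])
  expect_false(roi1[3, 3, 4])                     # no diagonal growth
  # dilation is monotone and a superset of the mask
  set.seed(14)
  m2 <- array(runif(7^3) < 0.05, dim = c(7, 7, 7))
  m2[2, 2, 2] <- TRUE
  roi <- make_roi(m2, 3)
  expect_true(all(roi[m2]))
  expect_error(make_roi(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("NMSE follows the printed sum-of-squares formula", {
  set.seed(15)
  t5 <- array(rnorm(125), dim = c(5, 5, 5))
  p5 <- array(rnorm(125), dim = c(5, 5, 5))
  expect_equal(nmse(t5, t5), 0)
  expect_equal(nmse(t5, array(0, dim(t5))), 1)    # all-ambient prediction
  expect_equal(nmse(t5, p5), sum((t5 - p5)^2) / sum(t5^2))  # brute force
  # scale invariance under joint scaling
  expect_equal(nmse(3 * t5, 3 * p5), nmse(t5, p5))
  # masked evaluation
  msk <- array(runif(125) < 0.5, dim(t5))
  expect_equal(nmse(t5, p5, msk),
               sum((t5[msk] - p5[msk])^2) / sum(t5[msk]^2))
  # all-zero truth: sentinel
  expect_true(is.na(nmse(array(0, c(3, 3, 3)), array(1, c(3, 3, 3)))))
})

test_that("Dice and IoU match hand-counted overlaps and their identity", {
  d <- c(6, 6, 6)
  true <- array(0, d); pred <- array(0, d)
  roi <- array(TRUE, d)
  # binarization threshold will be 0.5 * max(true) = 0.5
  true[1:4, 1, 1] <- 1          # |A| = 4
  pred[3:6, 1, 1] <- 1          # |B| = 4, overlap = 2
  sc <- overlap_scores(true, pred, roi)
  expect_equal(sc[["dice"]], 0.5)
  expect_equal(sc[["iou"]], 1 / 3)
  # dice = 2 iou / (1 + iou), exactly
  expect_equal(sc[["dice"]], 2 * sc[["iou"]] / (1 + sc[["iou"]]))
  # identities
  expect_equal(overlap_scores(true, true, roi),
               c(dice = 1, iou = 1))
  expect_equal(overlap_scores(true, array(0, d), roi),
               c(dice = 0, iou = 0))
  # random fields: IoU <= Dice and the identity holds
  set.seed(16)
  for (i in 1:5) {
    a <- array(runif(216), d); b <- array(runif(216), d)
    sc <- overlap_scores(a, b, roi)
    expect_lte(sc[["iou"]], sc[["dice"]])
    expect_equal(sc[["dice"]], 2 * sc[["iou"]] / (1 + sc[["iou"]]))
  }
})

test_that("image-quality metrics satisfy their closed-form identities", {
  set.seed(17)
  true <- array(abs(rnorm(8^3)), dim = c(8, 8, 8))
  iq <- image_quality(true, true)
  expect_equal(iq[["ssim"]], 1)
  expect_equal(iq[["mse"]], 0)
  expect_equal(iq[["mae"]], 0)
  expect_true(is.infinite(iq[["psnr"]]))
  eps <- 0.25
  iq2 <- image_quality(true, true + eps)
  expect_equal(iq2[["mse"]], eps^2)
  expect_equal(iq2[["mae"]], eps)
  expect_equal(iq2[["psnr"]], 10 * log10(max(true)^2 / eps^2))
})

test_that("3D SSIM agrees with the brute-force reference implementation", {
  set.seed(18)
  true <- array(abs(rnorm(10^3)), dim = c(10, 10, 10))
  pred <- true + 0.3 * rnorm(10^3)
  L <- max(true)
  mine <- ssim3d_map(true, pred, data_range = L)
  ref <- oracle_ssim_map(true, pred, L)
  expect_equal(mine, ref, tolerance = 1e-6)
  # masked average equals the mean over the valid windows under the mask
  msk <- array(runif(1000) < 0.4, dim = dim(true))
  iq <- image_quality(true, pred, msk)
  vals <- ref[msk & !is.na(ref)]
  # data range for the masked call is max(true[msk])
  ref2 <- oracle_ssim_map(true, pred, max(true[msk]))
  expect_equal(iq[["ssim"]], mean(ref2[msk & !is.na(ref2)]), tolerance = 1e-6)
  # brute-force MSE / MAE over the mask
  expect_equal(iq[["mse"]], mean((true[msk] - pred[msk])^2))
  expect_equal(iq[["mae"]], mean(abs(true[msk] - pred[msk])))
})

test_that("depth analysis recovers a constructed monotone relationship", {
  set.seed(19)
  n <- 40
  depth <- runif(n, 0, 0.2)
  per_sample <- tibble::tibble(
    id = 1:n, n_sources = 1, depth = depth,
    nmse = 1 / (1 + depth))  # strictly decreasing in depth
  dc <- nmse_vs_depth(per_sample)
  expect_equal(dc$rho, -1)
  expect_s3_class(ggplot2::ggplot_build(autoplot(dc))$plot, "ggplot")
  expect_error(nmse_vs_depth(per_sample[1, ]), "at least two")
})

test_that("evaluation tables aggregate per hot-spot count in the report layout", {
  set.seed(20)
  per_sample <- tibble::tibble(
    id = 1:12, n_sources = rep(1:3, each = 4), depth = NA_real_,
    ssim = runif(12), psnr = runif(12, 20, 40), mse = runif(12),
    nmse = runif(12), mae = runif(12), dice = runif(12), iou = runif(12),
    ssim_roi = runif(12), psnr_roi = runif(12, 20, 40), mse_roi = runif(12),
    nmse_roi = runif(12), mae_roi = runif(12), dice_roi = runif(12),
    iou_roi = runif(12))
  agg <- aggregate_metrics(per_sample)
  expect_setequal(unique(agg$metric),
                  c("ssim", "psnr", "mse", "nmse", "mae", "dice", "iou"))
  expect_setequal(unique(agg$scope), c("global", "roi"))
  expect_equal(nrow(agg), 7 * 2 * 3)   # metric x scope x count
  row <- agg[agg$metric == "ssim" & agg$scope == "global" &
               agg$n_sources == 2, ]
  expect_equal(row$mean, mean(per_sample$ssim[5:8]))
  expect_equal(row$sd, sd(per_sample$ssim[5:8]))
  wide <- format_report(agg)
  expect_equal(nrow(wide), 14)         # 7 global + 7 ROI rows
  expect_named(wide, c("label", "hotspots_1", "hotspots_2", "hotspots_3"))
})

test_that("model evaluation produces the full metric set per sample", {
  spec <- phantom_spec(diameter = 0.1, nx = 16, ny = 16, nz = 8)
  set.seed(22)
  ds <- generate_dataset(spec, counts = 1, per_count = 2,
                         split = c(train = 0, validation = 0, test = 1),
                         power_range = c(1e4, 1e4), calibrate = FALSE)
  cfg <- arch_config(input_shape = c(16, 16, 8), filters = c(4),
                     bottleneck = 8, strides = list(c(2, 2, 2)),
                     residual = "bottleneck_only")
  m <- build_autoencoder(cfg)
  res <- evaluate_samples(m, dataset_split(ds, "test"), ds$grid,
                          noise = noise_config())
  expect_equal(nrow(res), 2)
  expect_true(all(c("nmse", "ssim", "dice_roi", "depth") %in% names(res)))
  expect_true(all(is.finite(res$nmse)))
  expect_true(all(!is.na(res$depth)))  # single-source probes carry depth
})
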