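test_that("sampled sources respect size ranges and containment", {
  spec <- phantom_spec()  # 10 cm
  set.seed(1)
  R <- spec$diameter / 2
  draws <- lapply(1:2000, function(i) {
    sample_sources(sample(1:6, 1), spec, power_range = c(100, 1000))
  })
  all_src <- dplyr::bind_rows(draws)
  expect_gt(nrow(all_src), 5000)
  expect_true(all(all_src$height >= 0.006 & all_src$height <= 0.060))
  expect_true(all(all_src$radius >= 0.002 & all_src$radius <= 0.016))
  # radial and axial containment with the 2 mm margin, exhaustively
  rad <- sqrt((all_src$x - R)^2 + (all_src$y - R)^2) + all_src$radius
  expect_true(all(rad <= R - 0.002 + 1e-12))
  expect_true(all(all_src$z - all_src$height / 2 >= 0.002 - 1e-12))
  expect_true(all(all_src$z + all_src$height / 2 <=
                    spec$height - 0.002 + 1e-12))
  expect_true(all(all_src$power > 0))
})

test_that("source sampling handles edge cases", {
  spec <- phantom_spec()
  expect_equal(nrow(sample_sources(0, spec)), 0)
  expect_error(sample_sources(7, spec), "between 0 and 6")
  # no feasible placement: radii larger than the phantom radius
  tiny <- phantom_spec(diameter = 0.03, nx = 8, ny = 8, nz = 6)
  expect_error(
    sample_sources(1, tiny, radius_range = c(0.02, 0.02),
                   power_range = c(1, 2), max_tries = 50),
    "feasible")
})

test_that("noise model matches its statistical definition", {
  set.seed(9)
  stack <- array(1, dim = c(25, 64, 64))  # constant clean value c = 1
  # fraction 0, zero background: identity
  same <- apply_noise(stack, noise_config(fraction = 0, background = c(0, 0)))
  expect_identical(same, stack)
  # constant background variant: every image offset exactly 0.05 K
  bg <- apply_noise(stack, noise_config(fraction = 0,
                                        background = c(0.05, 0.05)))
  expect_equal(as.numeric(bg - stack), rep(0.05, length(stack)))
  # 10% relative noise: empirical sd of (noisy - clean - background)/c
  noisy <- apply_noise(stack, noise_config(fraction = 0.10,
                                           background = c(0.05, 0.05)))
  resid <- (noisy - stack - 0.05) / 1
  expect_equal(sd(resid), 0.10, tolerance = 0.01)
  expect_equal(mean(resid), 0, tolerance = 0.005)
  # clean input is not mutated, fresh draws differ
  expect_true(all(stack == 1))
  noisy2 <- apply_noise(stack, noise_config())
  expect_false(identical(noisy, noisy2))
  # background is constant within an image but varies across images
  cfg <- noise_config(fraction = 0, background = c(0.05, 0.1))
  offs <- apply_noise(stack, cfg) - stack
  per_image <- apply(offs, c(1, 2), function(v) diff(range(v)))
  expect_true(all(per_image < 1e-12))
  expect_gt(diff(range(offs)), 0.01)
})

test_that("dataset generation is quota-correct, valid and reproducible", {
  spec <- phantom_spec(diameter = 0.1, nx = 12, ny = 12, nz = 8)
  gen <- function() {
    set.seed(77)
    generate_dataset(spec, counts = 1:2, per_count = 3,
                     split = c(train = 4, validation = 1, test = 1),
                     power_range = c(2e3, 2e4), calibrate = FALSE)
  }
  ds <- gen()
  expect_equal(nrow(ds$manifest), 6)
  expect_equal(sum(ds$manifest$split == "train"), 4)
  expect_equal(sum(ds$manifest$split == "validation"), 1)
  expect_equal(sum(ds$manifest$split == "test"), 1)
  expect_equal(as.numeric(table(ds$manifest$n_sources)), c(3, 3))
  # every stored sample is internally consistent
  for (s in ds$samples) {
    expect_true(all(s$source_power >= 0))
    expect_true(all(s$source_power[!ds$grid$mask] == 0))
    expect_identical(s$source_mask, s$source_power > 0)
    expect_gte(min(s$temperature), 0)
    expect_equal(dim(s$sinograms), c(8, 12, 12))
  }
  expect_gt(ds$norm, 0)
  # identical seeds give identical datasets, arrays included
  ds2 <- gen()
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$samples, ds2$samples)
  expect_identical(ds$norm, ds2$norm)
})

test_that("an empty dataset is still a valid dataset", {
  spec <- phantom_spec(diameter = 0.1, nx = 12, ny = 12, nz = 8)
  ds <- generate_dataset(spec, counts = 1, per_count = 0,
                         power_range = c(1, 2), calibrate = FALSE)
  expect_equal(nrow(ds$manifest), 0)
  expect_equal(length(ds$samples), 0)
  expect_equal(ds$norm, 1)
})

test_that("datasets round-trip through disk", {
  spec <- phantom_spec(diameter = 0.1, nx = 12, ny = 12, nz = 8)
  set.seed(3)
  ds <- generate_dataset(spec, counts = 1, per_count = 2,
                         split = c(train = 1, validation = 0, test = 1),
                         power_range = c(2e3, 2e4), calibrate = FALSE)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$manifest$id, ds$manifest$id)
  expect_equal(back$manifest$split, ds$manifest$split)
  expect_equal(back$norm, ds$norm)
  expect_equal(back$samples[[1]]$temperature, ds$samples[[1]]$temperature)
  expect_equal(back$samples[[2]]$sinograms, ds$samples[[2]]$sinograms)
})
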