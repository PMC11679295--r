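test_that("data loss is the voxel-mean squared error", {
  a <- array(rnorm(64), dim = c(4, 4, 4))
  expect_equal(data_loss(a, a), 0)
  expect_equal(data_loss(a + 1, a), 1)
  b <- array(rnorm(64), dim = c(4, 4, 4))
  expect_equal(data_loss(a, b), sum((a - b)^2) / 64)  # brute force
  expect_error(data_loss(a, array(0, c(4, 4, 2))), "mismatch")
})

test_that("physics residual reproduces the hand-computed stencil on a quadratic field", {
  # unit-spaced grid: diameter = nx metres so dx = dy = dz = 1
  spec <- phantom_spec(diameter = 12, nx = 12, ny = 12, nz = 8,
                       height = 8)
  grid <- discretize_phantom(spec)
  X <- array(rep((seq_len(12) - 0.5), times = 12 * 8), dim = grid$dims)
  pred <- X^2
  S0 <- array(0, dim = grid$dims)
  # d2/dx2 (x^2) = 2 on every strictly interior point; residual^2 = 4
  loss <- physics_residual_loss(pred, S0, grid, points = "interior")
  expect_equal(loss, 4)
  # homogeneity of degree 2: doubling pred and S quadruples the loss
  fx <- fixture_small_solve()
  l1 <- physics_residual_loss(fx$tf$values, fx$S, fx$grid)
  l2 <- physics_residual_loss(2 * fx$tf$values, 2 * unclass(fx$S), fx$grid)
  expect_equal(l2, 4 * l1, tolerance = 1e-10)
})

test_that("the physics loss vanishes at the solver's fixed point", {
  set.seed(21)
  spec <- phantom_spec(nx = 12, ny = 12, nz = 8)
  grid <- discretize_phantom(spec)
  tol <- 1e-5
  for (i in 1:3) {
    src <- sample_sources(i, spec, power_range = c(1e4, 1e5))
    S <- rasterize_sources(src, grid)
    tf <- solve_steady_state(S, grid, tol = tol, method = "sor")
    loss <- physics_residual_loss(tf$values, S, grid)
    expect_lt(loss, (10 * tol / grid$dx^2)^2)
  }
})

test_that("training with zero epochs returns the initialized model untouched", {
  spec <- phantom_spec(diameter = 0.1, nx = 8, ny = 8, nz = 4)
  set.seed(5)
  ds <- generate_dataset(spec, counts = 1, per_count = 2,
                         split = c(train = 1, validation = 1, test = 0),
                         power_range = c(2e3, 2e4), calibrate = FALSE,
                         height_range = c(0.004, 0.01),
                         radius_range = c(0.002, 0.008))
  cfg <- arch_config(input_shape = c(8, 8, 4), filters = c(4), bottleneck = 8,
                     strides = list(c(2, 2, 2)), residual = "bottleneck_only")
  m <- build_autoencoder(cfg)
  fit <- train_autoencoder(m, ds, loss_config(), train_config(epochs = 0))
  expect_equal(nrow(fit$history), 0)
  expect_identical(fit$model$params, m$params)
})

test_that("lambda = 0 with the physics term active reduces exactly to the plain regime", {
  spec <- phantom_spec(diameter = 0.1, nx = 8, ny = 8, nz = 4)
  set.seed(6)
  ds <- generate_dataset(spec, counts = 1, per_count = 3,
                         split = c(train = 1, validation = 0, test = 0),
                         power_range = c(2e3, 2e4), calibrate = FALSE,
                         height_range = c(0.004, 0.01),
                         radius_range = c(0.002, 0.008))
  cfg <- arch_config(input_shape = c(8, 8, 4), filters = c(4), bottleneck = 8,
                     strides = list(c(2, 2, 2)), residual = "bottleneck_only")
  set.seed(7); m <- build_autoencoder(cfg)
  set.seed(8)
  plain <- train_autoencoder(m, ds, loss_config(),
                             train_config(epochs = 3, batch_size = 2))
  set.seed(8)
  pinn0 <- train_autoencoder(m, ds,
                             loss_config(lambda = 0, use_pinn = TRUE,
                                         pinn_warmup = 0),
                             train_config(epochs = 3, batch_size = 2))
  expect_equal(plain$model$params, pinn0$model$params, tolerance = 1e-12)
  expect_equal(plain$history$loss_data, pinn0$history$loss_data)
})

test_that("a tiny model memorizes a single sample", {
  spec <- phantom_spec(diameter = 0.1, nx = 16, ny = 16, nz = 8)
  set.seed(10)
  ds <- generate_dataset(spec, counts = 1, per_count = 1,
                         split = c(train = 1, validation = 0, test = 0),
                         power_range = c(1e4, 1e4), calibrate = FALSE)
  cfg <- arch_config(input_shape = c(16, 16, 8), filters = c(8, 16),
                     bottleneck = 32, strides = list(c(1, 1, 1), c(2, 2, 2)),
                     residual = "bottleneck_only")
  m <- build_autoencoder(cfg)
  fit <- train_autoencoder(m, ds, loss_config(),
                           train_config(epochs = 200, batch_size = 1,
                                        patience = 1000))
  expect_lt(min(fit$history$loss_data), 1e-2)
  # and the reconstruction is usable: NMSE well below the all-zero baseline
  s <- ds$samples[[1]]
  pred <- predict(fit$model, s$sinograms)
  expect_lt(nmse(s$temperature, pred), 0.05)
})

test_that("training history is tidy and glance summarizes the fit", {
  spec <- phantom_spec(diameter = 0.1, nx = 8, ny = 8, nz = 4)
  set.seed(12)
  ds <- generate_dataset(spec, counts = 1, per_count = 2,
                         split = c(train = 1, validation = 1, test = 0),
                         power_range = c(2e3, 2e4), calibrate = FALSE,
                         height_range = c(0.004, 0.01),
                         radius_range = c(0.002, 0.008))
  cfg <- arch_config(input_shape = c(8, 8, 4), filters = c(4), bottleneck = 8,
                     strides = list(c(2, 2, 2)), residual = "bottleneck_only")
  fit <- train_autoencoder(build_autoencoder(cfg), ds,
                           loss_config(use_input_noise = TRUE),
                           train_config(epochs = 2, batch_size = 1))
  h <- tidy(fit)
  expect_s3_class(h, "tbl_df")
  expect_named(h, c("epoch", "loss_data", "loss_physics", "loss_total",
                    "val_loss"))
  expect_equal(nrow(h), 2)
  g <- glance(fit)
  expect_equal(g$epochs_run, 2)
  expect_equal(g$n_parameters, n_parameters(fit$model))
})
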