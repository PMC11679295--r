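#' Mean-squared data loss between temperature fields
#'
#' \eqn{L_{data} = \frac{1}{N}\sum_i (T_{pred,i} - T_{true,i})^2} over all
#' N voxels.
#'
#' @param pred,true Numeric arrays (or `temperature_field`s) of equal shape.
#' @return Scalar loss (K^2).
#' @export
data_loss <- function(pred, true) {
  if (inherits(pred, "temperature_field")) pred <- pred$values
  if (inherits(true, "temperature_field")) true <- true$values
  if (!all(dim(pred) == dim(true))) stop("shape mismatch")
  mean((pred - true)^2)
}

#' Physics-informed residual loss
#'
#' The squared residual of the steady-state heat equation evaluated on a
#' predicted field: \eqn{L_{physics} = \frac{1}{M}\sum_j (\nabla^2_h
#' T_{pred} + S/k)_j^2}, where \eqn{\nabla^2_h} is the 7-point
#' finite-difference Laplacian with physical spacings and the same
#' convective ghost closure the forward solver uses. The true source field
#' is required, so this is a training-time regularizer only; inference needs
#' no source knowledge. At the solver's fixed point the loss vanishes (up to
#' the convergence tolerance).
#'
#' @param pred Predicted excess-temperature array (or `temperature_field`).
#' @param S Source power density array (W/m^3).
#' @param grid A [discretize_phantom()] grid.
#' @param points `"all"` evaluates on every interior voxel (boundary voxels
#'   use the Robin closure); `"interior"` restricts to voxels with six
#'   interior neighbours (no boundary closure in the loss).
#' @param sample_frac Optionally evaluate on a random subsample of the
#'   physics points (fraction in (0, 1]); `NULL` uses all of them.
#' @return Scalar loss ((K/m^2)^2).
#' @export
physics_residual_loss <- function(pred, S, grid,
                                  points = c("all", "interior"),
                                  sample_frac = NULL) {
  points <- match.arg(points)
  if (inherits(pred, "temperature_field")) pred <- pred$values
  if (!all(dim(pred) == grid$dims)) stop("mismatched grids")
  sel <- physics_point_mask(grid, points)
  r <- robin_laplacian(pred, grid) + unclass(S) / grid$spec$conductivity
  vals <- r[sel]
  if (!is.null(sample_frac)) {
    m <- max(1L, round(length(vals) * sample_frac))
    vals <- vals[sample.int(length(vals), m)]
  }
  mean(vals^2)
}

physics_point_mask <- function(grid, points) {
  if (points == "all") return(grid$mask)
  m <- grid$mask
  strict <- m
  for (axis in 1:3) {
    for (dir in c(-1L, 1L)) {
      strict <- strict & shift_array(m, axis, dir, fill = FALSE)
    }
  }
  strict
}

# Gradient of physics_residual_loss w.r.t. pred; the Robin Laplacian is
# self-adjoint on the interior, so the adjoint action is the operator itself
# applied to the masked residual.
physics_loss_grad <- function(pred, S, grid, sel) {
  r <- robin_laplacian(pred, grid) + unclass(S) / grid$spec$conductivity
  r[!sel] <- 0
  g <- robin_laplacian(r, grid)
  list(grad = 2 * g / sum(sel), loss = mean(r[sel]^2))
}

#' Loss configuration for training regimes
#'
#' Three regimes are supported: plain (`use_input_noise = FALSE`,
#' `use_pinn = FALSE`), noise-augmented (fresh input-noise realization per
#' sample per epoch; targets stay clean), and noise + physics-informed
#' (adds `lambda * L_physics`).
#'
#' @param lambda Physics-loss weight, or `"auto"`: after the warmup, lambda
#'   is set once so that the physics term's gradient (at the network
#'   output) has the same norm as the data term's, then frozen. Balancing
#'   gradients rather than loss values matters because the physics residual
#'   passes through a second Laplacian, whose gradient norm is orders of
#'   magnitude larger per unit loss; loss-value balancing lets the physics
#'   term swamp the data term and collapse the ReLU output.
#' @param use_pinn Add the physics residual term.
#' @param use_input_noise Perturb training inputs with [apply_noise()].
#' @param noise A [noise_config()].
#' @param physics_points Passed to [physics_residual_loss()].
#' @param physics_sample_frac Fraction of physics points used per batch
#'   (`NULL` = all).
#' @param pinn_warmup Epochs trained on the data loss alone before the
#'   physics term switches on (default 5). Early in training the residual
#'   is dominated by the unexplained source term and its gradient is
#'   destructive; a short warmup gives the network a field worth refining.
#' @return A `loss_config`.
#' @export
loss_config <- function(lambda = "auto", use_pinn = FALSE,
                        use_input_noise = FALSE, noise = noise_config(),
                        physics_points = "all",
                        physics_sample_frac = NULL,
                        pinn_warmup = 5L) {
  if (is.numeric(lambda) && lambda < 0) stop("`lambda` must be >= 0")
  structure(list(lambda = lambda, use_pinn = use_pinn,
                 use_input_noise = use_input_noise, noise = noise,
                 physics_points = physics_points,
                 physics_sample_frac = physics_sample_frac,
                 pinn_warmup = as.integer(pinn_warmup)),
            class = "loss_config")
}

#' Optimizer and schedule configuration
#'
#' @param epochs Training epochs (>= 0).
#' @param batch_size Mini-batch size (default 4).
#' @param lr Adam learning rate (default 1e-3).
#' @param beta1,beta2,eps Adam moment parameters.
#' @param patience Early-stopping patience on validation total loss
#'   (default 20 epochs); the best-validation weights are restored.
#' @param verbose Print per-epoch losses.
#' @return A `train_config`.
#' @export
train_config <- function(epochs = 30L, batch_size = 4L, lr = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         patience = 20L, verbose = FALSE) {
  if (epochs < 0) stop("`epochs` must be >= 0")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 patience = as.integer(patience), verbose = verbose),
            class = "train_config")
}

#' Train the autoencoder on a generated dataset
#'
#' Minimizes \eqn{L_{total} = L_{data} + \lambda L_{physics}} on the
#' training split with Adam. With input noise enabled, a fresh noise
#' realization is drawn for every sample at every epoch (the clean target is
#' unchanged). Validation total loss is tracked per epoch on clean
#' validation inputs (plus the physics term when enabled); the weights of
#' the best validation epoch are returned.
#'
#' @param model A `thermo_autoencoder` built for the dataset's sinogram
#'   shape.
#' @param dataset A [generate_dataset()] result.
#' @param loss_cfg A [loss_config()].
#' @param train_cfg A [train_config()].
#' @return A `thermo_fit`: list with the trained `model` (normalizer
#'   attached), `history` tibble (epoch, loss_data, loss_physics,
#'   loss_total, val_loss), the frozen `lambda`, and the configs.
#' @export
train_autoencoder <- function(model, dataset, loss_cfg = loss_config(),
                              train_cfg = train_config()) {
  stopifnot(inherits(model, "thermo_autoencoder"),
            inherits(dataset, "thermo_dataset"),
            inherits(loss_cfg, "loss_config"),
            inherits(train_cfg, "train_config"))
  grid <- dataset$grid
  model$norm <- dataset$norm
  train <- dataset_split(dataset, "train")
  val <- dataset_split(dataset, "validation")
  if (length(train) == 0 && train_cfg$epochs > 0) {
    stop("dataset has no training split")
  }
  sel <- physics_point_mask(grid, loss_cfg$physics_points)
  nvox <- prod(model$cfg$input_shape)

  as_input <- function(s, noisy) {
    stack <- s$sinograms
    if (noisy) stack <- apply_noise(stack, loss_cfg$noise)
    matrix(as.numeric(sinogram_to_volume(stack)) / model$norm, nrow = 1)
  }
  as_target <- function(s) matrix(as.numeric(s$temperature), nrow = 1)

  lambda <- if (identical(loss_cfg$lambda, "auto")) NA_real_ else
    if (loss_cfg$use_pinn) loss_cfg$lambda else 0

  # Adam state
  mstate <- lapply(model$params, function(p) p * 0)
  vstate <- mstate
  tstep <- 0L

  history <- list()
  best <- list(loss = Inf, params = model$params,
               bn_state = model$bn_state, epoch = 0L)
  wait <- 0L

  # validation matches the training input condition: noise-trained models
  # are selected on noisy validation inputs (fresh realization per epoch)
  val_total <- function(mod) {
    if (length(val) == 0) return(NA_real_)
    tot <- 0
    for (s in val) {
      stack <- s$sinograms
      if (loss_cfg$use_input_noise) stack <- apply_noise(stack, loss_cfg$noise)
      pred <- predict(mod, stack)
      ld <- data_loss(pred, s$temperature)
      lp <- if (loss_cfg$use_pinn) {
        physics_residual_loss(pred, s$source_power, grid,
                              points = loss_cfg$physics_points)
      } else 0
      tot <- tot + ld + (if (is.na(lambda)) 0 else lambda) * lp
    }
    tot / length(val)
  }

  for (epoch in seq_len(train_cfg$epochs)) {
    ord <- sample.int(length(train))
    ep_data <- 0; ep_phys <- 0; nb <- 0
    for (b0 in seq(1, length(train), by = train_cfg$batch_size)) {
      ids <- ord[b0:min(b0 + train_cfg$batch_size - 1L, length(train))]
      batch <- train[ids]
      xs <- lapply(batch, as_input, noisy = loss_cfg$use_input_noise)
      ts <- lapply(batch, as_target)
      fwd <- nn_forward(model, xs, training = TRUE)
      model <- fwd$model
      preds <- fwd$out
      ld <- mean(mapply(function(p, t) mean((p - t)^2), preds, ts))
      if (!is.finite(ld)) stop("NaN/Inf training loss; aborting")
      douts <- Map(function(p, t) 2 * (p - t) / nvox, preds, ts)
      lp <- 0
      if (loss_cfg$use_pinn && epoch > loss_cfg$pinn_warmup) {
        pg <- Map(function(p, s) {
          physics_loss_grad(array(as.numeric(p), dim = model$cfg$input_shape),
                            s$source_power, grid, sel)
        }, preds, batch)
        lp <- mean(vapply(pg, `[[`, numeric(1), "loss"))
        if (is.na(lambda)) {  # balance gradient norms once, post-warmup
          gd <- sqrt(sum(vapply(douts, function(d) sum(d^2), numeric(1))))
          gp <- sqrt(sum(vapply(pg, function(g) sum(g$grad^2), numeric(1))))
          lambda <- if (gp > 0) gd / gp else 0
        }
        douts <- Map(function(d, g) {
          d + lambda * matrix(as.numeric(g$grad), nrow = 1)
        }, douts, pg)
      }
      # batch-mean gradients
      douts <- lapply(douts, function(d) d / length(batch))
      grads <- nn_backward(model, fwd$caches, preds, douts)
      tstep <- tstep + 1L
      corr1 <- 1 - train_cfg$beta1^tstep
      corr2 <- 1 - train_cfg$beta2^tstep
      for (nm in names(grads)) {
        g <- grads[[nm]]
        mstate[[nm]] <- train_cfg$beta1 * mstate[[nm]] +
          (1 - train_cfg$beta1) * g
        vstate[[nm]] <- train_cfg$beta2 * vstate[[nm]] +
          (1 - train_cfg$beta2) * g^2
        model$params[[nm]] <- model$params[[nm]] -
          train_cfg$lr * (mstate[[nm]] / corr1) /
            (sqrt(vstate[[nm]] / corr2) + train_cfg$eps)
      }
      ep_data <- ep_data + ld; ep_phys <- ep_phys + lp; nb <- nb + 1
    }
    lam_now <- if (is.na(lambda)) 0 else lambda
    vl <- val_total(model)
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, loss_data = ep_data / nb, loss_physics = ep_phys / nb,
      loss_total = (ep_data + lam_now * ep_phys) / nb, val_loss = vl)
    if (train_cfg$verbose) {
      message(sprintf("epoch %3d  L_data %.4g  L_phys %.4g  val %.4g",
                      epoch, ep_data / nb, ep_phys / nb, vl))
    }
    track <- if (is.na(vl)) (ep_data + lam_now * ep_phys) / nb else vl
    if (track < best$loss) {
      best <- list(loss = track, params = model$params,
                   bn_state = model$bn_state, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= train_cfg$patience) break
    }
  }

  if (train_cfg$epochs > 0 && best$epoch > 0) {
    model$params <- best$params
    model$bn_state <- best$bn_state
  }
  structure(
    list(model = model,
         history = if (length(history)) dplyr::bind_rows(history) else
           tibble::tibble(epoch = integer(), loss_data = numeric(),
                          loss_physics = numeric(), loss_total = numeric(),
                          val_loss = numeric()),
         lambda = if (is.na(lambda)) 0 else lambda,
         best_epoch = best$epoch,
         loss_cfg = loss_cfg, train_cfg = train_cfg),
    class = "thermo_fit")
}

#' @export
print.thermo_fit <- function(x, ...) {
  cat(sprintf("<thermo_fit> %d epochs (best %d), lambda = %.3g\n",
              nrow(x$history), x$best_epoch, x$lambda))
  invisible(x)
}

#' Tidy the training history of a fit
#' @param x A `thermo_fit`.
#' @param ... Unused.
#' @return The per-epoch history tibble.
#' @export
tidy.thermo_fit <- function(x, ...) x$history

#' One-row summary of a fit
#' @param x A `thermo_fit`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.thermo_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    epochs_run = nrow(h),
    best_epoch = x$best_epoch,
    lambda = x$lambda,
    final_loss_data = if (nrow(h)) h$loss_data[nrow(h)] else NA_real_,
    final_val_loss = if (nrow(h)) h$val_loss[nrow(h)] else NA_real_,
    n_parameters = n_parameters(x$model))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
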