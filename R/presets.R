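#' Experiment presets
#'
#' Named end-to-end experiment configurations:
#'
#' * `ideal_10cm` — 10 cm phantom, clean inputs, full network with residual
#'   blocks at every level (the small-phantom study).
#' * `noisy_50cm_plain` / `noisy_50cm_noise` / `noisy_50cm_noise_pinn` —
#'   50 cm phantom evaluated on noisy inputs, trained respectively with
#'   clean inputs, noise-augmented inputs, and noise + the physics-informed
#'   loss; the simplified architecture (residual block at the bottleneck
#'   only) suits the larger domain.
#'
#' Each preset exists at three problem scales:
#'
#' * `full` — the study scale: 64 x 64 x 40 grid, 1000 samples per hot-spot
#'   count (counts 1-6), 4000/1000/1000 split. Intended for GPU-class
#'   budgets; defined here so the configuration is executable and auditable.
#' * `desk` — 32 x 32 x 20 grid, 100 samples per count, width scale 0.25,
#'   30 epochs: an overnight-CPU configuration.
#' * `micro` — 16 x 16 x 12 grid, counts 1-3 with 16 samples each plus a
#'   24-sample single-source probe set, a narrow two-level network and 25
#'   epochs: minutes on one CPU. Used by the package's own regression
#'   checks; directional findings (regime ordering, depth dependence) are
#'   meaningful at this scale, absolute metric values are not comparable to
#'   the full scale.
#'
#' @param name Preset name (see above).
#' @param scale `"full"`, `"desk"` or `"micro"`.
#' @return An `experiment_preset` list.
#' @export
experiment_preset <- function(name = c("ideal_10cm", "noisy_50cm_plain",
                                       "noisy_50cm_noise",
                                       "noisy_50cm_noise_pinn"),
                              scale = c("full", "desk", "micro")) {
  name <- match.arg(name)
  scale <- match.arg(scale)
  diameter <- if (name == "ideal_10cm") 0.10 else 0.50
  noisy <- name != "ideal_10cm"
  regime <- switch(name,
                   ideal_10cm = "plain",
                   noisy_50cm_plain = "plain",
                   noisy_50cm_noise = "noise",
                   noisy_50cm_noise_pinn = "noise_pinn")
  geom <- switch(scale,
                 full = list(nx = 64L, nz = 40L, counts = 1:6,
                             per_count = 1000L, probe_n = 200L,
                             width = 1, epochs = 200L, batch = 4L),
                 desk = list(nx = 32L, nz = 20L, counts = 1:6,
                             per_count = 100L, probe_n = 60L,
                             width = 0.25, epochs = 30L, batch = 4L),
                 micro = list(nx = 16L, nz = 12L, counts = 1:3,
                              per_count = 60L, probe_n = 24L,
                              width = 1, epochs = 40L, batch = 4L))
  spec <- phantom_spec(diameter = diameter, nx = geom$nx, nz = geom$nz)
  arch <- if (scale == "micro") {
    arch_config(input_shape = c(geom$nx, geom$nx, geom$nz),
                filters = c(4L, 8L), bottleneck = 16L,
                strides = list(c(1L, 1L, 1L), c(2L, 2L, 2L)),
                residual = "bottleneck_only")
  } else {
    arch_config(
      input_shape = c(geom$nx, geom$nx, geom$nz),
      residual = if (name == "ideal_10cm") "every_level" else
        "bottleneck_only",
      width_scale = geom$width)
  }
  noise <- noise_config()
  loss <- loss_config(
    lambda = "auto",
    use_pinn = regime == "noise_pinn",
    use_input_noise = regime %in% c("noise", "noise_pinn"),
    noise = noise)
  structure(
    list(name = name, scale = scale, spec = spec, counts = geom$counts,
         per_count = geom$per_count, probe_n = geom$probe_n,
         split = c(train = 5, validation = 1, test = 0),
         arch = arch, loss = loss,
         train = train_config(epochs = geom$epochs, batch_size = geom$batch,
                              patience = max(20L, geom$epochs)),
         eval_noise = if (noisy) noise else NULL,
         regime = regime),
    class = "experiment_preset")
}

#' @export
print.experiment_preset <- function(x, ...) {
  cat(sprintf("<experiment_preset> %s [%s]: d = %.2g m, %d x %d x %d, %d samples, regime %s\n",
              x$name, x$scale, x$spec$diameter, x$spec$nx, x$spec$ny,
              x$spec$nz, length(x$counts) * x$per_count, x$regime))
  invisible(x)
}

#' Run a complete generate / train / evaluate experiment
#'
#' Deterministic from `seed`: generates the training dataset and a
#' single-source probe set, trains the preset's regime, evaluates on the
#' probe set (with detector noise for the noisy presets) and aggregates the
#' metric tables. When `dir` is given, the manifest, history, per-sample
#' metrics and report tables are written there as CSV/JSON.
#'
#' @param preset An [experiment_preset()].
#' @param seed Integer seed controlling every random draw.
#' @param dir Optional output directory.
#' @param dataset,probe Optionally reuse pre-generated datasets (e.g. to
#'   share one dataset across the three training regimes of a comparison);
#'   both must have been generated from this preset's spec.
#' @return A list with `fit`, `per_sample`, `report` (aggregated tibble),
#'   `depth` (a [nmse_vs_depth()] curve, when enough single-source samples
#'   exist), `dataset` and `probe`.
#' @export
run_experiment <- function(preset, seed = 1L, dir = NULL, dataset = NULL,
                           probe = NULL) {
  stopifnot(inherits(preset, "experiment_preset"))
  set.seed(seed)
  if (is.null(dataset)) {
    dataset <- generate_dataset(
      preset$spec, counts = preset$counts, per_count = preset$per_count,
      split = preset$split)
  }
  if (is.null(probe)) {
    probe <- generate_probe_set(preset$spec, preset$probe_n,
                                dataset$settings$power_range)
  }
  model <- build_autoencoder(preset$arch)
  fit <- train_autoencoder(model, dataset, preset$loss, preset$train)
  per_sample <- evaluate_samples(fit, dataset_split(probe, "test"),
                                 probe$grid, noise = preset$eval_noise)
  report <- aggregate_metrics(per_sample)
  depth <- tryCatch(nmse_vs_depth(per_sample), error = function(e) NULL)
  out <- list(fit = fit, per_sample = per_sample, report = report,
              depth = depth, dataset = dataset, probe = probe,
              preset = preset, seed = seed)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(preset = preset$name, scale = preset$scale, seed = seed,
           regime = preset$regime, lambda = fit$lambda),
      file.path(dir, "run.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(dataset$manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(fit$history, file.path(dir, "history.csv"),
                     row.names = FALSE)
    utils::write.csv(per_sample, file.path(dir, "per_sample.csv"),
                     row.names = FALSE)
    utils::write.csv(report, file.path(dir, "report.csv"), row.names = FALSE)
  }
  out
}

#' Generate a depth-probe test set
#'
#' Single-source samples with a *fixed* median source geometry (midpoint of
#' the phantom's scaled radius and height ranges) and random position and
#' power. Fixing the geometry matters for the depth analysis: containment
#' forces large sources toward the axis, so with random sizes the source
#' radius is confounded with its depth and the depth-error relationship is
#' not identified. A fixed-size source swept over positions isolates the
#' depth effect.
#'
#' Source-centre radii are stratified: evenly spaced from the axis to the
#' outermost feasible radius (with random azimuths), so the depth axis is
#' covered uniformly. Uniform-in-area placement, which is right for
#' training data, leaves the deep region almost unsampled (the area element
#' vanishes at the axis).
#'
#' @param spec A [phantom_spec()].
#' @param n Number of probe samples.
#' @param power_range Power-density range (W/m^3); defaults to the
#'   solve-calibrated range for this phantom.
#' @param tol,method Forward-solver settings.
#' @return A `thermo_dataset` whose samples are all tagged `"test"`.
#' @export
generate_probe_set <- function(spec, n, power_range = NULL,
                               tol = 1e-3, method = "sor") {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- discretize_phantom(spec)
  sc <- spec$diameter / 0.10
  r_src <- mean(c(0.002, 0.016)) * sc
  h_src <- mean(c(0.006, 0.060)) * sc
  if (is.null(power_range)) {
    power_range <- calibrate_power_range(spec, grid)
  }
  R <- spec$diameter / 2
  margin <- 0.002
  r_max <- R - margin - r_src
  depths <- (seq_len(n) - 0.5) / n * r_max
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    phi <- runif(1, 0, 2 * pi)
    z <- runif(1, margin + h_src / 2, spec$height - margin - h_src / 2)
    sources <- source_spec(R + depths[i] * cos(phi), R + depths[i] * sin(phi),
                           z, r_src, h_src,
                           runif(1, power_range[1], power_range[2]))
    S <- rasterize_sources(sources, grid)
    tf <- solve_steady_state(S, grid, tol = tol, method = method)
    stack <- build_sinograms(tf, grid, n_angles = grid$dims[1],
                             n_det = grid$dims[1])
    samples[[i]] <- list(id = i, n_sources = 1, sources = sources,
                         sinograms = stack, temperature = tf$values,
                         source_power = unclass(S),
                         source_mask = unclass(S) > 0,
                         peak = max(tf$values))
  }
  manifest <- tibble::tibble(
    id = seq_len(n), n_sources = 1, split = "test",
    peak = vapply(samples, `[[`, numeric(1), "peak"))
  structure(
    list(samples = samples, manifest = manifest, norm = 1, spec = spec,
         grid = grid,
         settings = list(kind = "depth_probe", n = n, r_src = r_src,
                         h_src = h_src, power_range = power_range,
                         tol = tol, method = method)),
    class = "thermo_dataset")
}

#' Run the three 50 cm training regimes on shared data
#'
#' Generates one training dataset and one single-source probe set, trains
#' the plain, noise-augmented and noise+physics regimes on the *same* data,
#' and evaluates all three on the *same* noisy probe inputs (a paired
#' comparison: differences between regimes are not confounded by sampling).
#'
#' @param scale `"micro"` (default), `"desk"` or `"full"`.
#' @param seed Integer seed.
#' @param dir Optional output directory for the comparison table.
#' @return A list with per-regime results (`plain`, `noise`, `noise_pinn`),
#'   each containing `per_sample`, `report`, `depth`, `fit`; plus a
#'   `comparison` tibble of mean global/ROI NMSE and SSIM per regime.
#' @export
run_regime_comparison <- function(scale = "micro", seed = 1L, dir = NULL) {
  presets <- lapply(c("noisy_50cm_plain", "noisy_50cm_noise",
                      "noisy_50cm_noise_pinn"),
                    experiment_preset, scale = scale)
  set.seed(seed)
  base <- presets[[1]]
  dataset <- generate_dataset(
    base$spec, counts = base$counts, per_count = base$per_count,
    split = base$split)
  probe <- generate_probe_set(base$spec, base$probe_n,
                              dataset$settings$power_range)
  # one fixed noisy realization of the probe inputs, shared by all regimes
  noisy_probe <- probe
  noisy_probe$samples <- lapply(probe$samples, function(s) {
    s$sinograms <- apply_noise(s$sinograms, base$loss$noise)
    s
  })
  out <- list()
  for (p in presets) {
    set.seed(seed + match(p$regime, c("plain", "noise", "noise_pinn")))
    model <- build_autoencoder(p$arch)
    fit <- train_autoencoder(model, dataset, p$loss, p$train)
    per_sample <- evaluate_samples(fit, dataset_split(noisy_probe, "test"),
                                   probe$grid, noise = NULL)
    out[[p$regime]] <- list(
      fit = fit, per_sample = per_sample,
      report = aggregate_metrics(per_sample),
      depth = tryCatch(nmse_vs_depth(per_sample), error = function(e) NULL))
  }
  comparison <- purrr::map_dfr(names(out), function(r) {
    ps <- out[[r]]$per_sample
    tibble::tibble(regime = r,
                   nmse = mean(ps$nmse), nmse_roi = mean(ps$nmse_roi),
                   ssim = mean(ps$ssim), ssim_roi = mean(ps$ssim_roi),
                   depth_rho = if (!is.null(out[[r]]$depth))
                     out[[r]]$depth$rho else NA_real_)
  })
  out$comparison <- comparison
  out$dataset <- dataset
  out$probe <- noisy_probe
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(comparison, file.path(dir, "regime_comparison.csv"),
                     row.names = FALSE)
  }
  out
}
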