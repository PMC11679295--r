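#' Measurement noise model for detector images
#'
#' Two perturbations emulate an infrared detector: zero-mean Gaussian noise
#' with standard deviation equal to `fraction` of each clean pixel's excess
#' value (statistical noise), and one background temperature offset per
#' detector image (each slice-angle pair), drawn uniformly from `background`
#' (systematic error, e.g. ambient drift or emissivity bias).
#'
#' @param fraction Relative noise fraction (default 0.10, i.e. 10%).
#' @param background Length-2 numeric, the background offset range in K
#'   (default `c(0.05, 0.1)`). Use `c(b, b)` for a constant background.
#' @return A `noise_config` list.
#' @export
noise_config <- function(fraction = 0.10, background = c(0.05, 0.1)) {
  if (fraction < 0) stop("`fraction` must be non-negative")
  if (length(background) != 2 || background[1] > background[2]) {
    stop("`background` must be c(low, high) with low <= high")
  }
  structure(list(fraction = fraction, background = background),
            class = "noise_config")
}

#' Apply detector noise to a sinogram stack
#'
#' @param stack A `sinogram_stack` (clean, excess K). Not mutated.
#' @param cfg A [noise_config()].
#' @return A new stack of the same shape with noise and per-image background
#'   offsets added.
#' @export
apply_noise <- function(stack, cfg = noise_config()) {
  stopifnot(inherits(cfg, "noise_config"))
  d <- dim(stack)
  noisy <- stack
  if (cfg$fraction > 0) {
    noisy <- noisy + rnorm(length(stack), mean = 0,
                           sd = cfg$fraction * abs(as.numeric(stack)))
  }
  if (cfg$background[2] > 0) {
    # one offset per detector image = per (slice, angle) pair
    offs <- matrix(runif(d[1] * d[2], cfg$background[1], cfg$background[2]),
                   d[1], d[2])
    noisy <- noisy + array(rep(offs, d[3]), dim = d)
  }
  noisy
}

#' Sample random cylindrical hot-spots inside a phantom
#'
#' Heights, radii and power densities are drawn uniformly from their ranges;
#' centres are drawn uniformly over the feasible region. A candidate that
#' violates containment (source must fit entirely inside the phantom with a
#' `margin` clearance from every boundary) is rejection-resampled. Sources
#' may overlap; no minimum separation is enforced.
#'
#' Default size ranges are the 10 cm phantom's 6-60 mm heights and 2-16 mm
#' radii, scaled linearly with the phantom diameter.
#'
#' @param n Number of sources (0 to 6).
#' @param spec A [phantom_spec()].
#' @param height_range,radius_range Length-2 ranges in metres; defaults scale
#'   with `spec$diameter` (see Details).
#' @param power_range Length-2 range of volumetric power density in W/m^3;
#'   default targets single-source peak excess temperatures of roughly
#'   1-10 K via an infinite-cylinder estimate (see
#'   [calibrate_power_range()] for the solve-based calibration).
#' @param margin Boundary clearance in metres (default 2 mm).
#' @param max_tries Rejection cap per source before erroring.
#' @return A tibble of sources (see [source_spec()]).
#' @export
sample_sources <- function(n, spec, height_range = NULL, radius_range = NULL,
                           power_range = NULL, margin = 0.002,
                           max_tries = 1000L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n < 0 || n > 6) stop("`n` must be between 0 and 6")
  sc <- spec$diameter / 0.10
  if (is.null(height_range)) height_range <- c(0.006, 0.060) * sc
  if (is.null(radius_range)) radius_range <- c(0.002, 0.016) * sc
  if (is.null(power_range)) power_range <- default_power_range(spec, radius_range)
  if (n == 0) return(source_spec(numeric(0), numeric(0), numeric(0),
                                 numeric(0), numeric(0), numeric(0)))
  R <- spec$diameter / 2
  out <- vector("list", n)
  for (s in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      radius <- runif(1, radius_range[1], radius_range[2])
      height <- runif(1, height_range[1], height_range[2])
      r_max <- R - margin - radius
      z_lo <- margin + height / 2
      z_hi <- spec$height - margin - height / 2
      if (r_max <= 0 || z_lo > z_hi) next
      # uniform over the feasible disk
      rc <- r_max * sqrt(runif(1))
      phi <- runif(1, 0, 2 * pi)
      cx <- R + rc * cos(phi); cy <- R + rc * sin(phi)
      z <- runif(1, z_lo, z_hi)
      ok <- TRUE
      out[[s]] <- source_spec(cx, cy, z, radius, height,
                              runif(1, power_range[1], power_range[2]))
      break
    }
    if (!ok) {
      stop(sprintf(
        "no feasible placement for source %d after %d tries (ranges too large for this phantom)",
        s, max_tries))
    }
  }
  dplyr::bind_rows(out)
}

# Analytic order-of-magnitude power scale: centreline excess of an infinite
# cylindrical source of median radius in an infinite cylinder of radius R,
# T0 ~ S r^2/(4k) (1 + 2 log(R/r)) + S_avg R/(2h); targets ~1-10 K peaks.
default_power_range <- function(spec, radius_range) {
  r_med <- mean(radius_range)
  R <- spec$diameter / 2
  k <- spec$conductivity
  dT_unit <- r_med^2 / (4 * k) * (1 + 2 * log(R / r_med))
  c(1, 10) / dT_unit
}

#' Calibrate the source power-density range by a pilot solve
#'
#' Places a single median-sized source at the phantom centre, solves the
#' forward problem at unit power density, and returns the power range that
#' maps the resulting peak excess temperature onto `target_peak` (default
#' 1-10 K, the low-contrast regime of interest).
#'
#' @inheritParams sample_sources
#' @param grid A [discretize_phantom()] grid for `spec`.
#' @param target_peak Length-2 target peak excess range in K.
#' @param tol Solver tolerance for the pilot solve.
#' @return Length-2 power-density range (W/m^3).
#' @export
calibrate_power_range <- function(spec, grid, height_range = NULL,
                                  radius_range = NULL,
                                  target_peak = c(1, 10), tol = 1e-4) {
  sc <- spec$diameter / 0.10
  if (is.null(height_range)) height_range <- c(0.006, 0.060) * sc
  if (is.null(radius_range)) radius_range <- c(0.002, 0.016) * sc
  R <- spec$diameter / 2
  src <- source_spec(R, R, spec$height / 2,
                     mean(radius_range), mean(height_range), 1)
  S <- rasterize_sources(src, grid)
  tf <- solve_steady_state(S, grid, tol = tol, method = "sor")
  peak <- max(tf$values)
  if (peak <= 0) stop("pilot solve produced no excess temperature")
  target_peak / peak
}

#' Generate a reproducible thermal-tomography dataset
#'
#' For each sample: draw sources, rasterize, solve the forward problem, and
#' build the clean sinogram stack. Stores per sample the clean stack, the
#' excess-temperature volume, the source power field and mask, and a
#' manifest row. Samples are shuffled and split into train/validation/test.
#' Everything is driven by R's RNG, so a `set.seed()` before the call makes
#' the dataset fully reproducible.
#'
#' Noise is never baked into the stored stacks: it is drawn on the fly at
#' training/evaluation time so that every epoch sees a fresh realization.
#'
#' @param spec A [phantom_spec()].
#' @param counts Hot-spot counts to cover (default `1:6`).
#' @param per_count Samples per count (paper-scale default is 1000; choose
#'   small values for desk work).
#' @param split Ratios for train/validation/test (default `c(4, 1, 1)`,
#'   the 4000/1000/1000 split at paper scale).
#' @param n_angles,n_det Sinogram geometry (defaults match the grid's nx).
#' @param tol,method Forward-solver settings (SOR by default for speed; the
#'   fixed point is identical to Jacobi).
#' @param calibrate If `TRUE` (default), calibrate the power range with a
#'   pilot solve ([calibrate_power_range()]); otherwise use the analytic
#'   default range.
#' @param ... Passed to [sample_sources()] (e.g. `height_range`).
#' @return A `thermo_dataset`: list with `samples` (list of per-sample
#'   records), `manifest` (tibble: `id`, `n_sources`, `split`, `peak`), the
#'   input normalizer `norm` (99th percentile of training sinogram values),
#'   `spec`, `grid`, and the generation settings.
#' @export
generate_dataset <- function(spec, counts = 1:6, per_count = 1000L,
                             split = c(train = 4, validation = 1, test = 1),
                             n_angles = NULL, n_det = NULL,
                             tol = 1e-3, method = "sor",
                             calibrate = TRUE, ...) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- discretize_phantom(spec)
  if (is.null(n_angles)) n_angles <- grid$dims[1]
  if (is.null(n_det)) n_det <- grid$dims[1]
  dots <- list(...)
  power_range <- dots$power_range
  if (is.null(power_range) && calibrate && per_count > 0) {
    power_range <- calibrate_power_range(
      spec, grid, height_range = dots$height_range,
      radius_range = dots$radius_range)
  }
  total <- length(counts) * per_count
  n_source_seq <- rep(counts, each = per_count)

  samples <- vector("list", total)
  i <- 0L
  while (i < total) {
    i <- i + 1L
    nsrc <- n_source_seq[i]
    args <- c(list(n = nsrc, spec = spec), dots)
    args$power_range <- power_range
    sources <- do.call(sample_sources, args)
    S <- rasterize_sources(sources, grid)
    tf <- tryCatch(
      solve_steady_state(S, grid, tol = tol, method = method),
      error = function(e) NULL)
    if (is.null(tf)) {  # non-convergence: log and resample this slot
      warning(sprintf("sample %d failed to converge; resampled", i))
      i <- i - 1L
      next
    }
    stack <- build_sinograms(tf, grid, n_angles = n_angles, n_det = n_det)
    samples[[i]] <- list(
      id = i, n_sources = nsrc, sources = sources,
      sinograms = stack, temperature = tf$values,
      source_power = unclass(S), source_mask = unclass(S) > 0,
      peak = max(tf$values))
  }

  # randomized split with per-ratio sizes
  split <- split / sum(split)
  n_train <- floor(total * split[1])
  n_val <- floor(total * split[2])
  perm <- sample.int(total)
  tags <- rep("test", total)
  tags[perm[seq_len(n_train)]] <- "train"
  if (n_val > 0) tags[perm[n_train + seq_len(n_val)]] <- "validation"

  manifest <- tibble::tibble(
    id = vapply(samples, `[[`, integer(1), "id"),
    n_sources = vapply(samples, `[[`, numeric(1), "n_sources"),
    split = tags,
    peak = vapply(samples, `[[`, numeric(1), "peak"))

  train_vals <- unlist(lapply(samples[tags == "train"],
                              function(s) as.numeric(s$sinograms)))
  norm <- if (length(train_vals)) {
    q <- as.numeric(quantile(train_vals, 0.99))
    if (q > 0) q else 1
  } else 1

  structure(
    list(samples = samples, manifest = manifest, norm = norm,
         spec = spec, grid = grid,
         settings = list(counts = counts, per_count = per_count,
                         split = split, n_angles = n_angles, n_det = n_det,
                         tol = tol, method = method,
                         power_range = power_range)),
    class = "thermo_dataset")
}

#' @export
print.thermo_dataset <- function(x, ...) {
  tab <- table(x$manifest$split)
  cat(sprintf("<thermo_dataset> %d samples (%s), norm = %.4g K\n",
              nrow(x$manifest),
              paste(names(tab), tab, sep = ":", collapse = ", "), x$norm))
  invisible(x)
}

#' Subset a dataset's samples by split tag
#' @param dataset A `thermo_dataset`.
#' @param split One of `"train"`, `"validation"`, `"test"`.
#' @return List of sample records.
#' @export
dataset_split <- function(dataset, split) {
  stopifnot(inherits(dataset, "thermo_dataset"))
  dataset$samples[dataset$manifest$split == split]
}

#' Write / read a dataset to a directory
#'
#' Arrays are stored as one RDS file per sample plus a JSON manifest carrying
#' the configuration, normalizer and split assignment.
#'
#' @param dataset A `thermo_dataset`.
#' @param dir Output directory (created if missing).
#' @return `write_dataset` the directory invisibly; `read_dataset` a
#'   `thermo_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "thermo_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    spec = unclass(dataset$spec), norm = dataset$norm,
    settings = dataset$settings,
    manifest = as.data.frame(dataset$manifest))
  jsonlite::write_json(meta, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (s in dataset$samples) {
    saveRDS(s, file.path(dir, sprintf("sample_%05d.rds", s$id)))
  }
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "manifest.json"),
                              simplifyVector = TRUE)
  spec <- do.call(phantom_spec, meta$spec[c("diameter", "height", "nx", "ny",
                                            "nz", "conductivity", "convection",
                                            "ambient")])
  manifest <- tibble::as_tibble(meta$manifest)
  samples <- lapply(manifest$id, function(id) {
    readRDS(file.path(dir, sprintf("sample_%05d.rds", id)))
  })
  structure(list(samples = samples, manifest = manifest, norm = meta$norm,
                 spec = spec, grid = discretize_phantom(spec),
                 settings = meta$settings),
            class = "thermo_dataset")
}
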