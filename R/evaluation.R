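#' Region of interest around the hot-spots
#'
#' 6-connected binary dilation of the true source mask, applied
#' `iterations` times and clipped to the phantom interior. The ROI focuses
#' the metrics on the regions influenced by the heat sources; at 0
#' iterations it equals the source mask itself.
#'
#' @param source_mask Logical array (TRUE inside a source).
#' @param iterations Dilation iterations (default 3; about 4.7 mm on the
#'   default 10 cm phantom, enough to cover the warm halo around a source).
#' @param grid Optional [discretize_phantom()] grid; when given, the ROI is
#'   clipped to the cylinder interior.
#' @return Logical array with attribute `iterations`.
#' @export
make_roi <- function(source_mask, iterations = 3L, grid = NULL) {
  if (!any(source_mask)) stop("empty source mask")
  roi <- source_mask
  if (iterations < 0) stop("`iterations` must be >= 0")
  for (it in seq_len(iterations)) {
    grown <- roi
    for (axis in 1:3) {
      for (dir in c(-1L, 1L)) {
        grown <- grown | shift_array(roi, axis, dir, fill = FALSE)
      }
    }
    roi <- grown
  }
  if (!is.null(grid)) roi <- roi & grid$mask
  attr(roi, "iterations") <- as.integer(iterations)
  roi
}

#' Normalized mean squared error
#'
#' \eqn{NMSE = \sum (T_{true} - T_{pred})^2 / \sum T_{true}^2} over the
#' selected voxels. In excess-temperature units an all-ambient (zero)
#' prediction scores exactly 1.
#'
#' @param true,pred Numeric arrays of equal shape (excess K).
#' @param mask Optional logical array selecting voxels (default: all).
#' @return Scalar NMSE, or `NA_real_` when the true field is all zero under
#'   the mask.
#' @export
nmse <- function(true, pred, mask = NULL) {
  if (inherits(true, "temperature_field")) true <- true$values
  if (inherits(pred, "temperature_field")) pred <- pred$values
  if (!all(dim(true) == dim(pred))) stop("shape mismatch")
  if (is.null(mask)) mask <- TRUE
  tt <- true[mask]; pp <- pred[mask]
  denom <- sum(tt^2)
  if (denom == 0) return(NA_real_)
  sum((tt - pp)^2) / denom
}

#' Dice and IoU overlap of binarized hot-spot regions
#'
#' Both fields are binarized at half of the maximum *true* temperature
#' within the ROI (the same threshold for both, so the scores measure
#' localization, not calibration), then overlap is computed inside the ROI
#' (or over the whole volume with `scope = "global"`).
#'
#' @param true,pred Numeric arrays (excess K).
#' @param roi Logical ROI array from [make_roi()].
#' @param scope `"roi"` (default) or `"global"`.
#' @param threshold_from `"true"` (default: both thresholds from the true
#'   field) or `"each"` (each field thresholded at half its own ROI
#'   maximum).
#' @return Named numeric `c(dice, iou)`; `NA`s when the binarized true set
#'   is empty.
#' @export
overlap_scores <- function(true, pred, roi, scope = c("roi", "global"),
                           threshold_from = c("true", "each")) {
  scope <- match.arg(scope)
  threshold_from <- match.arg(threshold_from)
  if (!any(roi)) stop("empty ROI")
  thr_t <- 0.5 * max(true[roi])
  thr_p <- if (threshold_from == "true") thr_t else 0.5 * max(pred[roi])
  sel <- if (scope == "roi") roi else TRUE
  A <- true[sel] >= thr_t
  B <- pred[sel] >= thr_p
  if (!any(A)) return(c(dice = NA_real_, iou = NA_real_))
  inter <- sum(A & B)
  dice <- 2 * inter / (sum(A) + sum(B))
  iou <- inter / sum(A | B)
  c(dice = dice, iou = iou)
}

# windowed sums along one axis (valid positions only)
box_along <- function(a, w, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  m <- aperm(a, perm)
  dm <- dim(m)
  mm <- matrix(m, nrow = dm[1])
  cs <- rbind(0, apply(mm, 2, cumsum))
  n_out <- dm[1] - w + 1L
  res <- cs[(w + 1):(dm[1] + 1), , drop = FALSE] - cs[1:n_out, , drop = FALSE]
  aperm(array(res, dim = c(n_out, dm[2], dm[3])), order(perm))
}

boxsum3d <- function(a, w) {
  for (axis in 1:3) a <- box_along(a, w, axis)
  a
}

#' 3D structural similarity map
#'
#' Windowed SSIM with a uniform cubic window (default 7^3), sample
#' covariance normalization and the standard constants
#' \eqn{C_1 = (0.01 L)^2}, \eqn{C_2 = (0.03 L)^2} for data range L. Only
#' windows fully inside the volume are evaluated; the returned array is
#' padded with `NA` back to the input shape so it aligns voxel-for-voxel
#' with the inputs.
#'
#' @param true,pred Numeric arrays of equal shape.
#' @param data_range Dynamic range L of the data.
#' @param win Window edge length (odd; default 7).
#' @return Array of per-window SSIM values aligned to window centres.
#' @export
ssim3d_map <- function(true, pred, data_range, win = 7L) {
  d <- dim(true)
  if (any(d < win)) stop(sprintf("volume smaller than the %d^3 SSIM window", win))
  N <- win^3
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  sx <- boxsum3d(true, win); sy <- boxsum3d(pred, win)
  sxx <- boxsum3d(true^2, win); syy <- boxsum3d(pred^2, win)
  sxy <- boxsum3d(true * pred, win)
  mx <- sx / N; my <- sy / N
  vx <- (sxx - N * mx^2) / (N - 1)
  vy <- (syy - N * my^2) / (N - 1)
  cxy <- (sxy - N * mx * my) / (N - 1)
  smap <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  out <- array(NA_real_, dim = d)
  off <- (win - 1L) %/% 2L
  idx <- lapply(d, function(n) off + seq_len(n - win + 1L))
  out[idx[[1]], idx[[2]], idx[[3]]] <- smap
  out
}

#' Image-quality metrics between true and predicted fields
#'
#' SSIM (windowed 3D, averaged over the mask), PSNR, MSE and MAE, with the
#' data range taken as the maximum of the true field within the mask.
#'
#' @param true,pred Numeric arrays (excess K).
#' @param mask Optional logical array (default: whole volume).
#' @param win SSIM window (default 7).
#' @return Named numeric `c(ssim, psnr, mse, mae)`. SSIM is `NA` for a
#'   degenerate (non-positive range) true field; PSNR is `Inf` for a
#'   perfect prediction.
#' @export
image_quality <- function(true, pred, mask = NULL, win = 7L) {
  if (inherits(true, "temperature_field")) true <- true$values
  if (inherits(pred, "temperature_field")) pred <- pred$values
  if (!all(dim(true) == dim(pred))) stop("shape mismatch")
  full <- is.null(mask)
  msk <- if (full) array(TRUE, dim = dim(true)) else mask
  dr <- max(true[msk])
  mse <- mean((true[msk] - pred[msk])^2)
  mae <- mean(abs(true[msk] - pred[msk]))
  psnr <- if (mse == 0) Inf else 10 * log10(dr^2 / mse)
  ssim <- if (dr <= 0) NA_real_ else {
    smap <- ssim3d_map(true, pred, data_range = dr, win = win)
    vals <- smap[msk & !is.na(smap)]
    if (length(vals) == 0) NA_real_ else mean(vals)
  }
  c(ssim = ssim, psnr = psnr, mse = mse, mae = mae)
}

#' Evaluate a model over a set of samples
#'
#' Runs the model on each sample's sinogram stack (optionally perturbed with
#' detector noise first) and computes the full metric set globally and
#' within the dilated ROI.
#'
#' @param model A `thermo_autoencoder` or `thermo_fit`.
#' @param samples List of dataset sample records (see [dataset_split()]).
#' @param grid The dataset's grid.
#' @param noise Optional [noise_config()] applied to the inputs (evaluation
#'   under non-ideal conditions); `NULL` evaluates on clean inputs.
#' @param roi_iterations Dilation iterations for the ROI (default 3).
#' @param win SSIM window.
#' @return A tibble with one row per sample: identifiers (`id`,
#'   `n_sources`, `depth` = radial distance of the source centre from the
#'   axis for single-source samples), global metrics (`ssim`, `psnr`,
#'   `mse`, `nmse`, `mae`, `dice`, `iou`) and their `_roi` counterparts.
#' @export
evaluate_samples <- function(model, samples, grid, noise = NULL,
                             roi_iterations = 3L, win = 7L) {
  if (inherits(model, "thermo_fit")) model <- model$model
  R <- grid$spec$diameter / 2
  purrr::map_dfr(samples, function(s) {
    stack <- s$sinograms
    if (!is.null(noise)) stack <- apply_noise(stack, noise)
    pred <- predict(model, stack)
    true <- s$temperature
    roi <- make_roi(s$source_mask, roi_iterations, grid)
    gq <- image_quality(true, pred, mask = NULL, win = win)
    rq <- image_quality(true, pred, mask = roi, win = win)
    ov_g <- overlap_scores(true, pred, roi, scope = "global")
    ov_r <- overlap_scores(true, pred, roi, scope = "roi")
    depth <- if (s$n_sources == 1) {
      sqrt((s$sources$x[1] - R)^2 + (s$sources$y[1] - R)^2)
    } else NA_real_
    tibble::tibble(
      id = s$id, n_sources = s$n_sources, depth = depth,
      ssim = gq[["ssim"]], psnr = gq[["psnr"]], mse = gq[["mse"]],
      nmse = nmse(true, pred), mae = gq[["mae"]],
      dice = ov_g[["dice"]], iou = ov_g[["iou"]],
      ssim_roi = rq[["ssim"]], psnr_roi = rq[["psnr"]],
      mse_roi = rq[["mse"]], nmse_roi = nmse(true, pred, roi),
      mae_roi = rq[["mae"]],
      dice_roi = ov_r[["dice"]], iou_roi = ov_r[["iou"]])
  })
}

#' Aggregate per-sample metrics by hot-spot count
#'
#' @param per_sample Output of [evaluate_samples()].
#' @return A tidy tibble with columns `metric`, `scope` (`global`/`roi`),
#'   `n_sources`, `mean`, `sd`, `n`.
#' @export
aggregate_metrics <- function(per_sample) {
  per_sample |>
    dplyr::select(-dplyr::any_of(c("id", "depth"))) |>
    tidyr::pivot_longer(-"n_sources", names_to = "metric",
                        values_to = "value") |>
    dplyr::mutate(
      scope = ifelse(grepl("_roi$", .data$metric), "roi", "global"),
      metric = sub("_roi$", "", .data$metric)) |>
    dplyr::group_by(.data$metric, .data$scope, .data$n_sources) |>
    dplyr::summarise(mean = mean(.data$value[is.finite(.data$value)]),
                     sd = sd(.data$value[is.finite(.data$value)]),
                     n = dplyr::n(), .groups = "drop")
}

#' Wide report table (metric x hot-spot count)
#'
#' Formats an [aggregate_metrics()] result as a wide table with
#' "mean +- sd" cells, global metrics first and ROI metrics below.
#'
#' @param agg Output of [aggregate_metrics()].
#' @param digits Significant digits (default 2).
#' @return A wide tibble.
#' @export
format_report <- function(agg, digits = 2) {
  agg |>
    dplyr::mutate(cell = sprintf("%s ± %s",
                                 signif(.data$mean, digits),
                                 signif(.data$sd, digits)),
                  label = ifelse(.data$scope == "roi",
                                 paste0(.data$metric, " (ROI)"),
                                 .data$metric)) |>
    dplyr::arrange(dplyr::desc(.data$scope == "global")) |>
    dplyr::select("label", "n_sources", "cell") |>
    tidyr::pivot_wider(names_from = "n_sources", values_from = "cell",
                       names_prefix = "hotspots_")
}

#' Reconstruction error as a function of source depth
#'
#' For single-source samples, bins the per-sample NMSE by the source
#' centre's radial distance from the cylinder axis and reports the Spearman
#' rank correlation between distance and NMSE. A negative correlation means
#' reconstruction degrades toward the centre (deep sources are harder).
#'
#' @param per_sample Output of [evaluate_samples()] (single-source rows are
#'   selected automatically).
#' @param bins Number of equal-width radial bins (default 6).
#' @param metric Column to analyse (default `"nmse"`).
#' @return A `thermo_depth_curve`: list with the binned `curve` tibble, the
#'   Spearman `rho`, and the underlying points.
#' @export
nmse_vs_depth <- function(per_sample, bins = 6L, metric = "nmse") {
  pts <- per_sample |>
    dplyr::filter(.data$n_sources == 1, !is.na(.data$depth),
                  is.finite(.data[[metric]]))
  if (nrow(pts) < 2) stop("need at least two single-source samples")
  breaks <- seq(0, max(pts$depth) * (1 + 1e-9), length.out = bins + 1L)
  curve <- pts |>
    dplyr::mutate(bin = cut(.data$depth, breaks, include.lowest = TRUE)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(depth = mean(.data$depth),
                     mean_value = mean(.data[[metric]]),
                     n = dplyr::n(), .groups = "drop")
  if (nrow(curve) < 2) stop("fewer than 2 non-empty depth bins")
  rho <- cor(pts$depth, pts[[metric]], method = "spearman")
  structure(list(curve = curve, rho = rho, points = pts, metric = metric),
            class = "thermo_depth_curve")
}

#' @export
print.thermo_depth_curve <- function(x, ...) {
  cat(sprintf("<thermo_depth_curve> %s over %d samples, Spearman rho = %.3f\n",
              x$metric, nrow(x$points), x$rho))
  invisible(x)
}

#' Plot a depth-resolved error curve
#' @param object A `thermo_depth_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.thermo_depth_curve <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$depth, y = .data[[object$metric]])) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = object$curve,
                       ggplot2::aes(x = .data$depth, y = .data$mean_value),
                       colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "source distance from axis (m)",
                  y = toupper(object$metric),
                  subtitle = sprintf("Spearman rho = %.2f", object$rho)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
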