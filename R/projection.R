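#' Extract the observable surface temperature
#'
#' Returns, for each axial slice, the lateral boundary voxels (interior
#' voxels with at least one exposed face in x or y) with their azimuth about
#' the cylinder axis and their excess temperature. This is the quantity an
#' infrared detector orbiting the phantom can observe.
#'
#' @param T A `temperature_field` or numeric array on the grid.
#' @param grid A [discretize_phantom()] grid.
#' @return A tibble with columns `slice`, `i`, `j`, `azimuth` (radians in
#'   `[0, 2*pi)`), `px`, `py` (position relative to the axis, m) and `temp`
#'   (excess K).
#' @export
extract_surface <- function(T, grid) {
  stopifnot(inherits(grid, "thermo_grid"))
  if (inherits(T, "temperature_field")) T <- T$values
  if (!all(dim(T) == grid$dims)) stop("field does not conform to the grid")
  geo <- lateral_boundary_geometry(grid)
  if (nrow(geo) == 0) stop("degenerate grid: empty lateral boundary")
  nz <- grid$dims[3]
  nx <- grid$dims[1]
  purrr::map_dfr(seq_len(nz), function(k) {
    cells <- geo$i + nx * (geo$j - 1L) + nx * grid$dims[2] * (k - 1L)
    tibble::tibble(slice = k, i = geo$i, j = geo$j, azimuth = geo$azimuth,
                   px = geo$px, py = geo$py, temp = T[cells])
  })
}

# Lateral boundary cells of one slice (identical for all slices of the
# extruded cylinder): interior cells with an exposed x/y face.
lateral_boundary_geometry <- function(grid) {
  disk <- grid$mask[, , 1]
  nx <- nrow(disk); ny <- ncol(disk)
  pad <- function(m, di, dj) {
    out <- matrix(FALSE, nx, ny)
    si <- seq_len(nx) + di; sj <- seq_len(ny) + dj
    ok_i <- si >= 1 & si <= nx; ok_j <- sj >= 1 & sj <= ny
    out[ok_i, ok_j] <- m[si[ok_i], sj[ok_j]]
    out
  }
  boundary <- disk & !(pad(disk, 1, 0) & pad(disk, -1, 0) &
                         pad(disk, 0, 1) & pad(disk, 0, -1))
  idx <- which(boundary, arr.ind = TRUE)
  R <- grid$spec$diameter / 2
  px <- grid$centers$x[idx[, 1]] - R
  py <- grid$centers$y[idx[, 2]] - R
  az <- atan2(py, px) %% (2 * pi)
  ord <- order(az)
  tibble::tibble(i = as.integer(idx[ord, 1]), j = as.integer(idx[ord, 2]),
                 px = px[ord], py = py[ord], azimuth = az[ord])
}

# For one view angle, the orthographic mapping of visible boundary cells to
# detector pixels: returns a list (length n_det) of boundary-row indices that
# win each pixel (nearest to the detector; depth ties share the pixel).
detector_assignment <- function(geo, theta, n_det, diameter) {
  dirx <- cos(theta); diry <- sin(theta)
  depth <- geo$px * dirx + geo$py * diry
  visible <- depth > 0
  u <- -geo$px * diry + geo$py * dirx
  pix <- floor((u + diameter / 2) / diameter * n_det) + 1L
  pix <- pmin(pmax(pix, 1L), as.integer(n_det))
  assign <- vector("list", n_det)
  vis_idx <- which(visible)
  if (length(vis_idx) == 0) return(assign)
  sp <- split(vis_idx, pix[vis_idx])
  for (nm in names(sp)) {
    rows <- sp[[nm]]
    d <- depth[rows]
    top <- d >= max(d) - 1e-12 * max(abs(d), 1)
    assign[[as.integer(nm)]] <- rows[top]
  }
  assign
}

#' Project one slice's surface trace onto a detector line
#'
#' Orthographic projection: each lateral boundary cell whose outward (radial)
#' normal faces the detector is binned by its signed transverse coordinate
#' onto a detector line spanning exactly the phantom diameter. On collisions
#' the cell nearest the detector wins; exact depth ties average. Pixels not
#' covered by the phantom silhouette are 0 (ambient, in excess units).
#'
#' @param trace One slice of [extract_surface()] output (tibble with `px`,
#'   `py`, `temp`).
#' @param theta View angle in radians (detector azimuth).
#' @param n_det Number of detector pixels.
#' @param diameter Phantom diameter in metres (detector line width).
#' @return Numeric vector of length `n_det` (excess K).
#' @export
project_slice <- function(trace, theta, n_det, diameter) {
  if (n_det < 1) stop("`n_det` must be at least 1")
  assign <- detector_assignment(trace, theta, n_det, diameter)
  vapply(assign, function(rows) {
    if (is.null(rows) || length(rows) == 0) 0 else mean(trace$temp[rows])
  }, numeric(1))
}

#' Build the sinogram stack of a solved phantom
#'
#' Stacks [project_slice()] over every axial slice and `n_angles` uniformly
#' spaced view angles in `[0, 360)` degrees. This is the network input: the
#' complete set of surface-temperature detector readings.
#'
#' @inheritParams extract_surface
#' @param n_angles Number of view angles (default 64).
#' @param n_det Number of detector pixels per view (default 64).
#' @return A `sinogram_stack`: numeric array of shape
#'   `(nz, n_angles, n_det)` in excess K.
#' @export
build_sinograms <- function(T, grid, n_angles = 64L, n_det = 64L) {
  stopifnot(inherits(grid, "thermo_grid"))
  if (inherits(T, "temperature_field")) T <- T$values
  if (!all(dim(T) == grid$dims)) stop("field does not conform to the grid")
  geo <- lateral_boundary_geometry(grid)
  if (nrow(geo) == 0) stop("degenerate grid: empty lateral boundary")
  dims <- grid$dims
  nz <- dims[3]
  thetas <- (seq_len(n_angles) - 1) * 2 * pi / n_angles
  # geometry (visibility, pixel binning, occlusion) is slice-independent:
  # resolve it once per angle, then sweep the temperature values per slice
  assigns <- lapply(thetas, function(th) {
    asg <- detector_assignment(geo, th, n_det, grid$spec$diameter)
    filled <- which(lengths(asg) > 0)
    rows <- unlist(asg[filled], use.names = FALSE)
    list(rows = rows,
         pix = rep.int(filled, lengths(asg[filled])),
         counts = lengths(asg[filled]), filled = filled)
  })
  cell0 <- geo$i + dims[1] * (geo$j - 1L)
  stack <- array(0, dim = c(nz, n_angles, n_det))
  for (k in seq_len(nz)) {
    temps <- T[cell0 + dims[1] * dims[2] * (k - 1L)]
    for (a in seq_len(n_angles)) {
      asg <- assigns[[a]]
      if (length(asg$filled) == 0) next
      sums <- rowsum(temps[asg$rows], asg$pix, reorder = TRUE)
      stack[k, a, asg$filled] <- as.numeric(sums) / asg$counts
    }
  }
  structure(stack, class = c("sinogram_stack", class(stack)))
}
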