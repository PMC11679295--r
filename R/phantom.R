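#' Physical description of a cylindrical phantom
#'
#' A phantom is a gel-like cylinder with tissue-like thermal conductivity,
#' discretized on a rectangular voxel grid. The cylinder axis is the z axis;
#' the grid spans exactly the bounding box of the cylinder, so the voxel
#' spacing in x/y is `diameter / nx`.
#'
#' All temperatures in the package are *excess* temperatures (K above the
#' ambient air temperature), which makes the convective boundary condition
#' homogeneous; add `ambient` to recover absolute temperature.
#'
#' @param diameter Cylinder diameter in metres (default 0.10 m).
#' @param height Cylinder height in metres. Defaults to
#'   `diameter * nz / nx`, i.e. cubic voxels.
#' @param nx,ny,nz Grid resolution (default 64 x 64 x 40). `nx` must equal `ny`.
#' @param conductivity Thermal conductivity k in W/(m K) (default 0.5,
#'   typical of soft tissue / gel).
#' @param convection Convective heat-transfer coefficient h in W/(m^2 K)
#'   for cooling by the ambient air (default 7.5).
#' @param ambient Ambient air temperature in degrees C (default 22). Not used
#'   by the solver (which works in excess units) but carried for output.
#'
#' @return An object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec()
#' spec
#' @export
phantom_spec <- function(diameter = 0.10, height = NULL,
                         nx = 64L, ny = nx, nz = 40L,
                         conductivity = 0.5, convection = 7.5, ambient = 22) {
  nx <- as.integer(nx); ny <- as.integer(ny); nz <- as.integer(nz)
  if (!is.numeric(diameter) || diameter <= 0) stop("`diameter` must be positive")
  if (nx != ny) stop("`nx` must equal `ny` (square cross-section grid)")
  if (nx < 2 || nz < 1) stop("grid dimensions too small")
  if (is.null(height)) height <- diameter * nz / nx
  if (height <= 0) stop("`height` must be positive")
  if (conductivity <= 0 || convection < 0) {
    stop("`conductivity` must be positive and `convection` non-negative")
  }
  structure(
    list(diameter = diameter, height = height, nx = nx, ny = ny, nz = nz,
         conductivity = conductivity, convection = convection,
         ambient = ambient),
    class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> cylinder d = %.3g m, H = %.3g m, grid %d x %d x %d\n",
    x$diameter, x$height, x$nx, x$ny, x$nz))
  cat(sprintf("  k = %.3g W/(m K), h = %.3g W/(m2 K), ambient = %.3g C\n",
              x$conductivity, x$convection, x$ambient))
  invisible(x)
}

#' Discretize a phantom onto its voxel grid
#'
#' Builds the interior mask (voxel centres with
#' \eqn{(x-c_x)^2 + (y-c_y)^2 \le R^2}) of the rasterized ("staircase")
#' cylinder, and enumerates every exposed voxel face: a face joining an
#' interior voxel to an exterior (or out-of-bounds) voxel, including the top
#' and bottom caps. Exposed faces carry the convective (Robin) boundary flux.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `thermo_grid` with elements `spec`, `dims`,
#'   spacings `dx`, `dy`, `dz`, the logical `mask` array, the number of
#'   interior voxels `n_interior`, the voxel volume, and `faces`, a tibble
#'   with one row per exposed face (`cell` linear index, `axis` 1..3, `dir`
#'   +-1, `area` in m^2).
#' @examples
#' grid <- discretize_phantom(phantom_spec(nx = 16, ny = 16, nz = 8))
#' grid$n_interior
#' @export
discretize_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$nx; ny <- spec$ny; nz <- spec$nz
  dx <- spec$diameter / nx
  dy <- spec$diameter / ny
  dz <- spec$height / nz
  R <- spec$diameter / 2
  xc <- (seq_len(nx) - 0.5) * dx
  yc <- (seq_len(ny) - 0.5) * dy
  r2 <- outer((xc - R)^2, (yc - R)^2, `+`)
  disk <- r2 <= R^2 + 1e-12 * R^2
  if (!any(disk)) stop("degenerate grid: no interior voxels")
  mask <- array(disk, dim = c(nx, ny, nz))

  faces <- enumerate_exposed_faces(mask, dx, dy, dz)

  structure(
    list(spec = spec, dims = c(nx, ny, nz), dx = dx, dy = dy, dz = dz,
         mask = mask, n_interior = sum(mask),
         voxel_volume = dx * dy * dz, faces = faces,
         centers = list(x = xc, y = yc, z = (seq_len(nz) - 0.5) * dz)),
    class = "thermo_grid")
}

# All exposed faces by shifting the mask along each axis in both directions.
enumerate_exposed_faces <- function(mask, dx, dy, dz) {
  dims <- dim(mask)
  areas <- c(dy * dz, dx * dz, dx * dy)
  out <- vector("list", 6L)
  n <- 0L
  for (axis in 1:3) {
    for (dir in c(-1L, 1L)) {
      nb <- shift_array(mask, axis, dir, fill = FALSE)
      exposed <- mask & !nb
      cells <- which(exposed)
      ax_col <- rep(axis, length(cells))
      dir_col <- rep(dir, length(cells))
      area_col <- rep(areas[axis], length(cells))
      n <- n + 1L
      out[[n]] <- tibble::tibble(cell = cells, axis = ax_col,
                                 dir = dir_col, area = area_col)
    }
  }
  dplyr::bind_rows(out)
}

# Shift an array by one cell along `axis` toward `dir`; `fill` pads the
# vacated hyperplane. nb[i] = mask[i + dir] so exposed = mask & !nb.
shift_array <- function(x, axis, dir, fill = FALSE) {
  d <- dim(x)
  idx <- lapply(d, seq_len)
  src <- idx
  src[[axis]] <- idx[[axis]] + dir
  keep <- src[[axis]] >= 1 & src[[axis]] <= d[axis]
  out <- array(fill, dim = d)
  dst <- idx
  dst[[axis]] <- idx[[axis]][keep]
  src[[axis]] <- src[[axis]][keep]
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

#' @export
print.thermo_grid <- function(x, ...) {
  cat(sprintf("<thermo_grid> %d x %d x %d, %d interior voxels, %d exposed faces\n",
              x$dims[1], x$dims[2], x$dims[3], x$n_interior, nrow(x$faces)))
  invisible(x)
}

#' Describe cylindrical heat sources as a tibble
#'
#' One row per source: an axis-aligned cylindrical hot-spot of constant
#' volumetric power density.
#'
#' @param x,y,z Centre coordinates in metres (z along the phantom axis).
#' @param radius,height Source cylinder radius and height in metres.
#' @param power Volumetric power density S in W/m^3 (must be positive).
#' @return A tibble with class-checked columns.
#' @export
source_spec <- function(x, y, z, radius, height, power) {
  out <- tibble::tibble(x = x, y = y, z = z, radius = radius,
                        height = height, power = power)
  if (any(out$radius <= 0) || any(out$height <= 0) || any(out$power <= 0)) {
    stop("source radius, height and power density must be positive")
  }
  out
}

#' Rasterize cylindrical sources onto the phantom grid
#'
#' Every voxel whose centre lies inside a source cylinder receives that
#' source's power density; overlapping sources add.
#'
#' @param sources A tibble as returned by [source_spec()] or
#'   [sample_sources()] (columns `x`, `y`, `z`, `radius`, `height`, `power`).
#'   May have zero rows.
#' @param grid A [discretize_phantom()] grid.
#' @return A `source_field`: numeric array of volumetric power density
#'   (W/m^3) on the grid, zero outside the interior.
#' @export
rasterize_sources <- function(sources, grid) {
  stopifnot(inherits(grid, "thermo_grid"))
  spec <- grid$spec
  S <- array(0, dim = grid$dims)
  if (nrow(sources) > 0) {
    R <- spec$diameter / 2
    cx <- R; cy <- R
    for (s in seq_len(nrow(sources))) {
      src <- sources[s, ]
      radial <- sqrt((src$x - cx)^2 + (src$y - cy)^2) + src$radius
      if (radial > R + 1e-9 ||
          src$z - src$height / 2 < -1e-9 ||
          src$z + src$height / 2 > spec$height + 1e-9) {
        stop(sprintf("source %d extends outside the phantom", s))
      }
      # voxels with centre inside the source cylinder
      in_xy <- outer((grid$centers$x - src$x)^2,
                     (grid$centers$y - src$y)^2, `+`) <= src$radius^2
      in_z <- abs(grid$centers$z - src$z) <= src$height / 2
      if (!any(in_xy) || !any(in_z)) next
      sel <- array(FALSE, dim = grid$dims)
      sel[, , which(in_z)] <- in_xy
      S[sel] <- S[sel] + src$power
    }
  }
  if (any(S[!grid$mask] != 0)) stop("internal error: source outside interior mask")
  structure(S, class = c("source_field", class(S)))
}
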