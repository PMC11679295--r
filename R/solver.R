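#' Solve the steady-state heat equation on a phantom
#'
#' Solves the Poisson problem \eqn{\nabla^2 T = -S/k} for the excess
#' temperature on the voxelized cylinder, with a convective (Robin) closure
#' at every exposed face: the ghost value across a face with spacing
#' \eqn{\Delta} is \eqn{T_g = T_b (1 - h\Delta/k)}, which is the discrete
#' form of \eqn{k\,\partial T/\partial n = -h\,T} in excess units. The
#' reference iteration is Jacobi; a red-black SOR accelerator with the same
#' fixed point is available for dataset generation.
#'
#' @param S A `source_field` (or numeric array) of volumetric power density
#'   in W/m^3 on the grid.
#' @param grid A [discretize_phantom()] grid.
#' @param tol Convergence tolerance in kelvin: iteration stops when the
#'   max-norm of the per-sweep update drops below `tol` (default 0.001 K).
#' @param max_iter Iteration cap (default 200000 sweeps).
#' @param method `"jacobi"` (reference) or `"sor"` (red-black successive
#'   over-relaxation; identical fixed point, far fewer sweeps).
#' @param omega SOR relaxation factor; default `2 / (1 + sin(pi / max(dims)))`.
#' @param caps `"convective"` (default; the caps cool like the lateral
#'   surface) or `"insulated"` (zero flux through top and bottom, used for
#'   comparison against the long-cylinder closed form).
#'
#' @return A `temperature_field`: list with the excess-temperature array
#'   `values` (K above ambient, 0 outside the cylinder), `converged`,
#'   `iterations`, `last_update`, and the boundary mode `caps`.
#' @examples
#' grid <- discretize_phantom(phantom_spec(nx = 16, ny = 16, nz = 8))
#' S <- rasterize_sources(source_spec(0.05, 0.05, 0.025, 0.01, 0.02, 5e4), grid)
#' tf <- solve_steady_state(S, grid, tol = 1e-4)
#' max(tf$values)
#' @export
solve_steady_state <- function(S, grid, tol = 1e-3, max_iter = 200000L,
                               method = c("jacobi", "sor"), omega = NULL,
                               caps = c("convective", "insulated")) {
  stopifnot(inherits(grid, "thermo_grid"))
  method <- match.arg(method)
  caps <- match.arg(caps)
  if (!is.numeric(tol) || tol <= 0) stop("`tol` must be positive")
  if (!all(dim(S) == grid$dims)) stop("source field does not conform to the grid")
  spec <- grid$spec
  if (is.null(omega)) omega <- 2 / (1 + sin(pi / max(grid$dims)))

  res <- .cpp_poisson_solve(
    as.numeric(S) / spec$conductivity, as.integer(grid$mask),
    as.integer(grid$dims), c(grid$dx, grid$dy, grid$dz),
    spec$conductivity, spec$convection, tol, as.integer(max_iter),
    method, omega, caps == "insulated")
  if (!res$converged) {
    stop(sprintf("solver did not converge in %d sweeps (last update %.3g K)",
                 max_iter, res$last_update))
  }
  structure(
    list(values = array(res$T, dim = grid$dims),
         converged = res$converged, iterations = res$iterations,
         last_update = res$last_update, tol = tol, caps = caps),
    class = "temperature_field")
}

#' @export
print.temperature_field <- function(x, ...) {
  cat(sprintf("<temperature_field> %s, peak excess %.4g K, %d sweeps\n",
              paste(dim(x$values), collapse = " x "),
              max(x$values), x$iterations))
  invisible(x)
}

#' Discrete Laplacian with the solver's Robin closure
#'
#' Applies the 7-point finite-difference Laplacian (physical spacings) to a
#' field, using the same ghost-cell convective closure as
#' [solve_steady_state()] at exposed faces. Zero outside the interior mask.
#' The operator is self-adjoint on the masked interior.
#'
#' @param field Numeric array (excess K) on the grid, or a
#'   `temperature_field`.
#' @inheritParams solve_steady_state
#' @return Numeric array of \eqn{\nabla^2_h} values (K/m^2).
#' @export
robin_laplacian <- function(field, grid, caps = c("convective", "insulated")) {
  stopifnot(inherits(grid, "thermo_grid"))
  caps <- match.arg(caps)
  if (inherits(field, "temperature_field")) field <- field$values
  if (!all(dim(field) == grid$dims)) stop("field does not conform to the grid")
  spec <- grid$spec
  array(.cpp_robin_laplacian(as.numeric(field), as.integer(grid$mask),
                             as.integer(grid$dims),
                             c(grid$dx, grid$dy, grid$dz),
                             spec$conductivity, spec$convection,
                             caps == "insulated"),
        dim = grid$dims)
}

#' Global energy-balance residual of a converged solution
#'
#' At steady state the total generated power must leave through the surface:
#' \eqn{\sum S V = h \sum_{faces} T_b A}. Returns the relative imbalance
#' \eqn{|\sum S V - h \sum T_b A| / \sum S V}; with zero total source power
#' the balance is undefined and `NA` is returned.
#'
#' @param T A `temperature_field` (or numeric array of excess K).
#' @inheritParams solve_steady_state
#' @return Relative residual (dimensionless), or `NA_real_`.
#' @export
energy_balance <- function(T, S, grid, caps = c("convective", "insulated")) {
  stopifnot(inherits(grid, "thermo_grid"))
  caps <- match.arg(caps)
  if (inherits(T, "temperature_field")) T <- T$values
  power <- sum(S) * grid$voxel_volume
  if (power <= 0) return(NA_real_)
  faces <- grid$faces
  if (caps == "insulated") faces <- faces[faces$axis != 3L, ]
  flux <- grid$spec$convection * sum(T[faces$cell] * faces$area)
  abs(power - flux) / power
}
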