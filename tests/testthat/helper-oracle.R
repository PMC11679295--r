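# Independent oracles used across the suite. Everything here is deliberately
# written the slow, obvious way (explicit loops, direct formulas) so it shares
# no code path with the package internals it checks.

# Direct solve of the discrete Poisson system: assemble the operator row by
# row with an explicit neighbour scan and solve the sparse linear system.
oracle_direct_solve <- function(S, grid, caps = "convective") {
  spec <- grid$spec
  dims <- grid$dims
  mask <- grid$mask
  sp <- c(grid$dx, grid$dy, grid$dz)
  ints <- which(mask)
  idx <- array(0L, dims)
  idx[ints] <- seq_along(ints)
  ai <- arrayInd(ints, dims)
  n <- length(ints)
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  for (m in seq_len(n)) {
    i <- ai[m, 1]; j <- ai[m, 2]; k <- ai[m, 3]
    diagv <- 0
    for (axis in 1:3) {
      for (dir in c(-1L, 1L)) {
        pos <- c(i, j, k); pos[axis] <- pos[axis] + dir
        d <- sp[axis]
        inside <- all(pos >= 1L) && all(pos <= dims) &&
          mask[pos[1], pos[2], pos[3]]
        if (inside) {
          diagv <- diagv + 1 / d^2
          trip_i <- c(trip_i, m)
          trip_j <- c(trip_j, idx[pos[1], pos[2], pos[3]])
          trip_x <- c(trip_x, -1 / d^2)
        } else {
          rb <- if (caps == "insulated" && axis == 3) 0 else
            spec$convection / (spec$conductivity * d)
          diagv <- diagv + rb
        }
      }
    }
    trip_i <- c(trip_i, m); trip_j <- c(trip_j, m); trip_x <- c(trip_x, diagv)
  }
  A <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(n, n))
  x <- as.numeric(Matrix::solve(A, as.numeric(S)[ints] / spec$conductivity))
  out <- array(0, dims)
  out[ints] <- x
  out
}

# Exhaustive exposed-face count by scanning all 6 neighbours of every voxel.
oracle_face_count <- function(mask) {
  dims <- dim(mask)
  cnt <- 0L
  for (k in seq_len(dims[3])) for (j in seq_len(dims[2]))
    for (i in seq_len(dims[1])) {
      if (!mask[i, j, k]) next
      for (axis in 1:3) for (dir in c(-1L, 1L)) {
        pos <- c(i, j, k); pos[axis] <- pos[axis] + dir
        inside <- all(pos >= 1L) && all(pos <= dims) &&
          mask[pos[1], pos[2], pos[3]]
        if (!inside) cnt <- cnt + 1L
      }
    }
  cnt
}

# Exhaustive point-in-cylinder voxel count for a single source.
oracle_source_voxels <- function(grid, cx, cy, cz, radius, height) {
  cnt <- 0L
  for (k in seq_along(grid$centers$z)) for (j in seq_along(grid$centers$y))
    for (i in seq_along(grid$centers$x)) {
      if ((grid$centers$x[i] - cx)^2 + (grid$centers$y[j] - cy)^2 <= radius^2 &&
          abs(grid$centers$z[k] - cz) <= height / 2) {
        cnt <- cnt + 1L
      }
    }
  cnt
}

# Per-window SSIM by direct loops (uniform window, sample covariance).
oracle_ssim_map <- function(x, y, L, win = 7L) {
  d <- dim(x)
  off <- (win - 1L) %/% 2L
  C1 <- (0.01 * L)^2
  C2 <- (0.03 * L)^2
  out <- array(NA_real_, d)
  for (k in seq(off + 1L, d[3] - off)) for (j in seq(off + 1L, d[2] - off))
    for (i in seq(off + 1L, d[1] - off)) {
      wx <- as.numeric(x[(i - off):(i + off), (j - off):(j + off),
                         (k - off):(k + off)])
      wy <- as.numeric(y[(i - off):(i + off), (j - off):(j + off),
                         (k - off):(k + off)])
      mx <- mean(wx); my <- mean(wy)
      vx <- stats::var(wx); vy <- stats::var(wy)
      cxy <- stats::cov(wx, wy)
      out[i, j, k] <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
        ((mx^2 + my^2 + C1) * (vx + vy + C2))
    }
  out
}

# Expected detector pixel of a single surface point at azimuth phi and
# radius r, viewed from angle theta (orthographic camera, width = diameter).
oracle_point_pixel <- function(phi, r, theta, n_det, diameter) {
  if (cos(phi - theta) <= 0) return(NA_integer_)  # back side, invisible
  u <- r * sin(phi - theta)
  min(max(floor((u + diameter / 2) / diameter * n_det) + 1L, 1L),
      as.integer(n_det))
}

# Full projection of one slice by direct per-point loops: visibility by
# outward-radial test, binning by transverse coordinate, occlusion by depth,
# exact ties averaged.
oracle_project_line <- function(px, py, temp, theta, n_det, diameter) {
  line <- numeric(n_det)
  best_depth <- rep(-Inf, n_det)
  acc <- vector("list", n_det)
  for (m in seq_along(px)) {
    depth <- px[m] * cos(theta) + py[m] * sin(theta)
    if (depth <= 0) next
    u <- -px[m] * sin(theta) + py[m] * cos(theta)
    pix <- floor((u + diameter / 2) / diameter * n_det) + 1L
    pix <- min(max(pix, 1L), as.integer(n_det))
    tol <- 1e-12 * max(abs(depth), 1)
    if (depth > best_depth[pix] + tol) {
      best_depth[pix] <- depth
      acc[[pix]] <- temp[m]
    } else if (abs(depth - best_depth[pix]) <= tol) {
      acc[[pix]] <- c(acc[[pix]], temp[m])
    }
  }
  for (p in seq_len(n_det)) if (!is.null(acc[[p]])) line[p] <- mean(acc[[p]])
  line
}
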