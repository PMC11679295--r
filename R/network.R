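#' Architecture configuration for the 3D residual autoencoder
#'
#' The encoder is a stack of strided 3D convolutions (each optionally
#' followed by a residual block), a bottleneck convolution + residual block,
#' and a mirrored transposed-convolution decoder; the output layer is a
#' single-filter 3x3x3 convolution with ReLU, so predictions are always
#' non-negative excess temperatures. The default configuration is the
#' full-resolution network: filters 16/32/64/128, bottleneck 256, strides
#' (1,1,1), (2,2,2), (2,2,2), (2,2,1) on a 64 x 64 x 40 input, giving an
#' 8 x 8 x 10 bottleneck.
#'
#' The sinogram stack `(nz, n_angles, n_det)` is presented to the network as
#' a single-channel volume of shape `(n_det, n_angles, nz)` so that input
#' and output spatial shapes coincide.
#'
#' @param input_shape Integer length-3 spatial input shape.
#' @param filters Encoder filter counts per level.
#' @param bottleneck Bottleneck filter count.
#' @param strides List of length-3 strides per level; every stride must
#'   divide the corresponding spatial extent at that level.
#' @param kernel Convolution kernel size (cubic; default 3).
#' @param residual `"every_level"` (full network, suited to small phantoms)
#'   or `"bottleneck_only"` (simplified variant for large phantoms, where a
#'   residual block at every level over-parameterizes the model).
#' @param width_scale Multiplier applied to all filter counts (rounded,
#'   floored at 1) for desk-scale work.
#' @return An `arch_config`.
#' @export
arch_config <- function(input_shape = c(64L, 64L, 40L),
                        filters = c(16L, 32L, 64L, 128L),
                        bottleneck = 256L,
                        strides = list(c(1L, 1L, 1L), c(2L, 2L, 2L),
                                       c(2L, 2L, 2L), c(2L, 2L, 1L)),
                        kernel = 3L,
                        residual = c("every_level", "bottleneck_only"),
                        width_scale = 1) {
  residual <- match.arg(residual)
  if (length(filters) != length(strides)) {
    stop("`filters` and `strides` must have the same length")
  }
  filters <- pmax(1L, as.integer(round(filters * width_scale)))
  bottleneck <- max(1L, as.integer(round(bottleneck * width_scale)))
  shapes <- vector("list", length(filters) + 1L)
  shapes[[1]] <- as.integer(input_shape)
  for (l in seq_along(filters)) {
    s <- as.integer(strides[[l]])
    if (any(shapes[[l]] %% s != 0)) {
      stop(sprintf("stride (%s) does not divide shape (%s) at level %d",
                   paste(s, collapse = ","),
                   paste(shapes[[l]], collapse = ","), l))
    }
    shapes[[l + 1]] <- shapes[[l]] %/% s
  }
  structure(list(input_shape = as.integer(input_shape), filters = filters,
                 bottleneck = bottleneck,
                 strides = lapply(strides, as.integer),
                 kernel = as.integer(kernel), residual = residual,
                 shapes = shapes),
            class = "arch_config")
}

# ---- layer geometry -------------------------------------------------------

# 'same' padding start offsets (extra padding goes at the end)
pad_same <- function(in_shape, out_shape, stride, k) {
  pt <- pmax((out_shape - 1L) * stride + k - in_shape, 0L)
  pt %/% 2L
}

new_conv_op <- function(name, cin, cout, stride, in_shape, act) {
  out_shape <- in_shape %/% stride
  list(kind = "conv", name = name, cin = cin, cout = cout, stride = stride,
       in_shape = in_shape, out_shape = out_shape, act = act,
       pad = pad_same(in_shape, out_shape, stride, 3L))
}

new_convT_op <- function(name, cin, cout, stride, in_shape, act) {
  out_shape <- in_shape * stride
  # geometry of the matching conv out_shape -> in_shape
  list(kind = "convT", name = name, cin = cin, cout = cout, stride = stride,
       in_shape = in_shape, out_shape = out_shape, act = act,
       pad = pad_same(out_shape, in_shape, stride, 3L))
}

new_res_op <- function(name, channels, shape) {
  list(kind = "resblock", name = name, c = channels, shape = shape,
       cin = channels, cout = channels,
       in_shape = shape, out_shape = shape,
       pad = pad_same(shape, shape, c(1L, 1L, 1L), 3L),
       stride = c(1L, 1L, 1L))
}

#' Build the 3D convolutional residual autoencoder
#'
#' @param cfg An [arch_config()].
#' @return A `thermo_autoencoder` with untrained (He-initialized) weights.
#'   Weight initialization draws from R's RNG; seed beforehand for
#'   reproducibility.
#' @export
build_autoencoder <- function(cfg) {
  stopifnot(inherits(cfg, "arch_config"))
  L <- length(cfg$filters)
  ops <- list()
  add <- function(op) ops[[length(ops) + 1L]] <<- op
  cin <- 1L
  for (l in seq_len(L)) {
    add(new_conv_op(sprintf("enc%d", l), cin, cfg$filters[l],
                    cfg$strides[[l]], cfg$shapes[[l]], "relu"))
    if (cfg$residual == "every_level") {
      add(new_res_op(sprintf("encres%d", l), cfg$filters[l],
                     cfg$shapes[[l + 1]]))
    }
    cin <- cfg$filters[l]
  }
  add(new_conv_op("bottleneck", cin, cfg$bottleneck, c(1L, 1L, 1L),
                  cfg$shapes[[L + 1]], "relu"))
  add(new_res_op("bottleneckres", cfg$bottleneck, cfg$shapes[[L + 1]]))
  cin <- cfg$bottleneck
  for (l in rev(seq_len(L))) {
    add(new_convT_op(sprintf("dec%d", l), cin, cfg$filters[l],
                     cfg$strides[[l]], cfg$shapes[[l + 1]], "relu"))
    if (cfg$residual == "every_level") {
      add(new_res_op(sprintf("decres%d", l), cfg$filters[l], cfg$shapes[[l]]))
    }
    cin <- cfg$filters[l]
  }
  add(new_conv_op("out", cin, 1L, c(1L, 1L, 1L), cfg$shapes[[1]], "relu"))

  params <- list()
  bn_state <- list()
  k3 <- cfg$kernel^3
  he <- function(cout, cin) {
    matrix(rnorm(cout * cin * k3, sd = sqrt(2 / (cin * k3))), cout, cin * k3)
  }
  for (op in ops) {
    nm <- op$name
    if (op$kind == "conv") {
      params[[paste0(nm, ".W")]] <- he(op$cout, op$cin)
      params[[paste0(nm, ".b")]] <- numeric(op$cout)
    } else if (op$kind == "convT") {
      # stored as (cout*k3) x cin so forward is one GEMM + scatter
      params[[paste0(nm, ".W")]] <-
        matrix(rnorm(op$cout * k3 * op$cin, sd = sqrt(2 / (op$cin * k3))),
               op$cout * k3, op$cin)
      params[[paste0(nm, ".b")]] <- numeric(op$cout)
    } else {
      params[[paste0(nm, ".W1")]] <- he(op$c, op$c)
      params[[paste0(nm, ".b1")]] <- numeric(op$c)
      params[[paste0(nm, ".g1")]] <- rep(1, op$c)
      params[[paste0(nm, ".be1")]] <- numeric(op$c)
      params[[paste0(nm, ".W2")]] <- he(op$c, op$c)
      params[[paste0(nm, ".b2")]] <- numeric(op$c)
      params[[paste0(nm, ".g2")]] <- rep(1, op$c)
      params[[paste0(nm, ".be2")]] <- numeric(op$c)
      bn_state[[nm]] <- list(m1 = numeric(op$c), v1 = rep(1, op$c),
                             m2 = numeric(op$c), v2 = rep(1, op$c))
    }
  }
  structure(list(cfg = cfg, ops = ops, params = params, bn_state = bn_state,
                 norm = 1),
            class = "thermo_autoencoder")
}

#' Number of trainable parameters
#' @param model A `thermo_autoencoder`.
#' @return Integer count of trainable scalars (conv weights/biases and batch
#'   norm scale/shift; running statistics excluded).
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "thermo_autoencoder"))
  sum(vapply(model$params, length, numeric(1)))
}

#' @export
print.thermo_autoencoder <- function(x, ...) {
  cat(sprintf("<thermo_autoencoder> input %s, %d ops, %s parameters\n",
              paste(x$cfg$input_shape, collapse = " x "), length(x$ops),
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

# ---- forward / backward ---------------------------------------------------

# x: (cin x nvox) matrix. Caching is only done when training.
conv_forward <- function(x, W, b, op, cache = TRUE) {
  if (cache) {
    col <- .cpp_im2col3d(x, op$in_shape, op$out_shape, 3L, op$stride, op$pad)
    y <- W %*% col + b
    list(y = y, col = col)
  } else {
    nvox <- prod(op$out_shape)
    rows <- nrow(x) * 27
    chunk <- max(1L, floor(4e7 / (rows * prod(op$out_shape[1:2]))))
    oz <- op$out_shape[3]
    y <- matrix(0, nrow(W), nvox)
    z0 <- 0L
    while (z0 < oz) {
      nzc <- min(chunk, oz - z0)
      pad <- op$pad; pad[3] <- pad[3] - z0 * op$stride[3]
      col <- .cpp_im2col3d(x, op$in_shape,
                           c(op$out_shape[1:2], nzc), 3L, op$stride, pad)
      cols <- prod(op$out_shape[1:2]) * z0 + seq_len(ncol(col))
      y[, cols] <- W %*% col
      z0 <- z0 + nzc
    }
    list(y = y + b, col = NULL)
  }
}

conv_backward <- function(dy, x_dummy, col, W, op) {
  dW <- tcrossprod(dy, col)
  db <- rowSums(dy)
  dcol <- crossprod(W, dy)
  dx <- .cpp_col2im3d(dcol, op$cin, op$in_shape, op$out_shape, 3L,
                      op$stride, op$pad)
  list(dx = dx, dW = dW, db = db)
}

convT_forward <- function(x, W, b, op, cache = TRUE) {
  if (cache || ncol(x) * nrow(W) <= 4e7) {
    col <- W %*% x
    y <- .cpp_col2im3d(col, op$cout, op$out_shape, op$in_shape, 3L,
                       op$stride, op$pad)
    list(y = y + b, col = NULL)
  } else {
    ivox <- ncol(x)
    chunk_cols <- max(1L, floor(4e7 / nrow(W)))
    y <- matrix(0, op$cout, prod(op$out_shape))
    i0 <- 0L
    iz_per <- prod(op$in_shape[1:2])
    # chunk over whole input z planes to keep the scatter geometry simple
    zchunk <- max(1L, chunk_cols %/% iz_per)
    z0 <- 0L
    while (z0 < op$in_shape[3]) {
      nzc <- min(zchunk, op$in_shape[3] - z0)
      cols <- iz_per * z0 + seq_len(iz_per * nzc)
      col <- W %*% x[, cols, drop = FALSE]
      pad <- op$pad; pad[3] <- pad[3] - z0 * op$stride[3]
      y <- y + .cpp_col2im3d(col, op$cout, op$out_shape,
                             c(op$in_shape[1:2], nzc), 3L, op$stride, pad)
      z0 <- z0 + nzc
    }
    list(y = y + b, col = NULL)
  }
}

convT_backward <- function(dy, x, W, op) {
  dcol <- .cpp_im2col3d(dy, op$out_shape, op$in_shape, 3L, op$stride, op$pad)
  dW <- tcrossprod(dcol, x)
  dx <- crossprod(W, dcol)
  db <- rowSums(dy)
  list(dx = dx, dW = dW, db = db)
}

# Batch norm across all samples' voxels, per channel.
bn_forward <- function(xs, g, be, state, training, momentum = 0.1,
                       eps = 1e-5) {
  ntot <- sum(vapply(xs, ncol, numeric(1)))
  if (training) {
    mu <- Reduce(`+`, lapply(xs, rowSums)) / ntot
    var <- Reduce(`+`, lapply(xs, function(x) rowSums((x - mu)^2))) / ntot
    state$m <- (1 - momentum) * state$m + momentum * mu
    state$v <- (1 - momentum) * state$v + momentum * var
  } else {
    mu <- state$m; var <- state$v
  }
  sdv <- sqrt(var + eps)
  xhat <- lapply(xs, function(x) (x - mu) / sdv)
  ys <- lapply(xhat, function(h) g * h + be)
  list(ys = ys, xhat = xhat, sd = sdv, state = state, n = ntot)
}

bn_backward <- function(dys, cache, g) {
  xhat <- cache$xhat; sdv <- cache$sd; n <- cache$n
  dg <- Reduce(`+`, Map(function(dy, h) rowSums(dy * h), dys, xhat))
  dbe <- Reduce(`+`, lapply(dys, rowSums))
  dxh <- lapply(dys, function(dy) dy * g)
  m1 <- Reduce(`+`, lapply(dxh, rowSums)) / n
  m2 <- Reduce(`+`, Map(function(d, h) rowSums(d * h), dxh, xhat)) / n
  dxs <- Map(function(d, h) (d - m1 - h * m2) / sdv, dxh, xhat)
  list(dxs = dxs, dg = dg, dbe = dbe)
}

relu <- function(x) (x > 0) * x

# Forward over a batch (list of 1 x nvox input matrices).
nn_forward <- function(model, xs, training = FALSE) {
  p <- model$params
  caches <- vector("list", length(model$ops))
  for (oi in seq_along(model$ops)) {
    op <- model$ops[[oi]]
    nm <- op$name
    if (op$kind %in% c("conv", "convT")) {
      fwd <- if (op$kind == "conv") conv_forward else convT_forward
      res <- lapply(xs, fwd, W = p[[paste0(nm, ".W")]],
                    b = p[[paste0(nm, ".b")]], op = op, cache = training)
      pre <- lapply(res, `[[`, "y")
      ys <- if (op$act == "relu") lapply(pre, relu) else pre
      if (training) {
        caches[[oi]] <- list(xs = xs, cols = lapply(res, `[[`, "col"),
                             pre = pre)
      }
      xs <- ys
    } else {  # resblock: conv-BN-ReLU, conv-BN, add skip, ReLU
      st <- model$bn_state[[nm]]
      c1 <- lapply(xs, conv_forward, W = p[[paste0(nm, ".W1")]],
                   b = p[[paste0(nm, ".b1")]], op = op, cache = training)
      b1 <- bn_forward(lapply(c1, `[[`, "y"), p[[paste0(nm, ".g1")]],
                       p[[paste0(nm, ".be1")]],
                       list(m = st$m1, v = st$v1), training)
      h <- lapply(b1$ys, relu)
      c2 <- lapply(h, conv_forward, W = p[[paste0(nm, ".W2")]],
                   b = p[[paste0(nm, ".b2")]], op = op, cache = training)
      b2 <- bn_forward(lapply(c2, `[[`, "y"), p[[paste0(nm, ".g2")]],
                       p[[paste0(nm, ".be2")]],
                       list(m = st$m2, v = st$v2), training)
      ys <- Map(function(z, x0) relu(z + x0), b2$ys, xs)
      if (training) {
        model$bn_state[[nm]] <- list(m1 = b1$state$m, v1 = b1$state$v,
                                     m2 = b2$state$m, v2 = b2$state$v)
        caches[[oi]] <- list(xs = xs, c1 = c1, b1 = b1, h = h, c2 = c2,
                             b2 = b2, ys = ys)
      }
      xs <- ys
    }
  }
  list(out = xs, caches = caches, model = model)
}

# Backward over the batch; douts is a list matching nn_forward's out.
nn_backward <- function(model, caches, outs, douts) {
  p <- model$params
  grads <- list()
  dxs <- douts
  for (oi in rev(seq_along(model$ops))) {
    op <- model$ops[[oi]]
    nm <- op$name
    cc <- caches[[oi]]
    if (op$kind == "conv") {
      if (op$act == "relu") {
        dxs <- Map(function(d, pre) d * (pre > 0), dxs, cc$pre)
      }
      W <- p[[paste0(nm, ".W")]]
      bk <- Map(function(dy, col) conv_backward(dy, NULL, col, W, op),
                dxs, cc$cols)
      grads[[paste0(nm, ".W")]] <- Reduce(`+`, lapply(bk, `[[`, "dW"))
      grads[[paste0(nm, ".b")]] <- Reduce(`+`, lapply(bk, `[[`, "db"))
      dxs <- lapply(bk, `[[`, "dx")
    } else if (op$kind == "convT") {
      if (op$act == "relu") {
        dxs <- Map(function(d, pre) d * (pre > 0), dxs, cc$pre)
      }
      W <- p[[paste0(nm, ".W")]]
      bk <- Map(function(dy, x) convT_backward(dy, x, W, op), dxs, cc$xs)
      grads[[paste0(nm, ".W")]] <- Reduce(`+`, lapply(bk, `[[`, "dW"))
      grads[[paste0(nm, ".b")]] <- Reduce(`+`, lapply(bk, `[[`, "db"))
      dxs <- lapply(bk, `[[`, "dx")
    } else {
      dz <- Map(function(d, y) d * (y > 0), dxs, cc$ys)
      dskip <- dz
      bb2 <- bn_backward(dz, cc$b2, p[[paste0(nm, ".g2")]])
      grads[[paste0(nm, ".g2")]] <- bb2$dg
      grads[[paste0(nm, ".be2")]] <- bb2$dbe
      W2 <- p[[paste0(nm, ".W2")]]
      bk2 <- Map(function(dy, cv) conv_backward(dy, NULL, cv$col, W2, op),
                 bb2$dxs, cc$c2)
      grads[[paste0(nm, ".W2")]] <- Reduce(`+`, lapply(bk2, `[[`, "dW"))
      grads[[paste0(nm, ".b2")]] <- Reduce(`+`, lapply(bk2, `[[`, "db"))
      dh <- Map(function(d, b1y) d * (b1y > 0), lapply(bk2, `[[`, "dx"),
                cc$b1$ys)
      bb1 <- bn_backward(dh, cc$b1, p[[paste0(nm, ".g1")]])
      grads[[paste0(nm, ".g1")]] <- bb1$dg
      grads[[paste0(nm, ".be1")]] <- bb1$dbe
      W1 <- p[[paste0(nm, ".W1")]]
      bk1 <- Map(function(dy, cv) conv_backward(dy, NULL, cv$col, W1, op),
                 bb1$dxs, cc$c1)
      grads[[paste0(nm, ".W1")]] <- Reduce(`+`, lapply(bk1, `[[`, "dW"))
      grads[[paste0(nm, ".b1")]] <- Reduce(`+`, lapply(bk1, `[[`, "db"))
      dxs <- Map(`+`, lapply(bk1, `[[`, "dx"), dskip)
    }
  }
  grads
}

# ---- prediction -----------------------------------------------------------

#' Reconstruct the 3D temperature field from a sinogram stack
#'
#' The stack `(nz, n_angles, n_det)` is presented to the network as a
#' single-channel `(n_det, n_angles, nz)` volume, divided by the model's
#' input normalizer. The final ReLU guarantees a non-negative excess field.
#'
#' @param object A `thermo_autoencoder` (trained or not).
#' @param stack A `sinogram_stack` (or array) matching the model input.
#' @param ... Unused.
#' @return Numeric array `(nx, ny, nz)` of predicted excess temperature (K).
#' @export
predict.thermo_autoencoder <- function(object, stack, ...) {
  vol <- sinogram_to_volume(stack)
  if (!all(dim(vol) == object$cfg$input_shape)) {
    stop(sprintf("input shape (%s) does not match model input (%s)",
                 paste(dim(vol), collapse = ","),
                 paste(object$cfg$input_shape, collapse = ",")))
  }
  x <- matrix(as.numeric(vol) / object$norm, nrow = 1)
  out <- nn_forward(object, list(x), training = FALSE)$out[[1]]
  array(as.numeric(out), dim = object$cfg$input_shape)
}

# (nz, n_angles, n_det) -> (n_det, n_angles, nz) single-channel volume
sinogram_to_volume <- function(stack) {
  stopifnot(length(dim(stack)) == 3)
  aperm(unclass(stack), c(3, 2, 1))
}
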