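# Minimal convolutional-network engine.
#
# Activations travel between layers as a matrix `x` of M x C (M = H*W*N rows
# ordered y-fastest, then x, then sample; C = channels) together with the
# spatial dims. Convolutions gather patches with precomputed linear indices
# (im2col) and reduce to BLAS matrix products; backward passes scatter-add the
# patch gradients back. Everything is double precision and single-threaded
# deterministic given the RNG seed used at initialization.
#
# Layer objects are environments so batch-norm running statistics and Adam
# updates mutate in place.

act_state <- function(x, H, W, N) list(x = x, H = H, W = W, N = N)

# ---- layer constructors ---------------------------------------------------

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  e$grads <- NULL
  e
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

layer_conv <- function(c_in, c_out, k = 3L, stride = 1L, pad = 1L) {
  K <- k * k * c_in
  new_layer("conv",
            params = list(W = he_init(K, c_out, K), b = numeric(c_out)),
            k = as.integer(k), stride = as.integer(stride),
            pad = as.integer(pad), c_in = as.integer(c_in),
            c_out = as.integer(c_out), cache = NULL, geom = NULL)
}

layer_dwconv <- function(channels, k = 3L, stride = 1L, pad = 1L) {
  new_layer("dwconv",
            params = list(W = he_init(k * k, channels, k * k),
                          b = numeric(channels)),
            k = as.integer(k), stride = as.integer(stride),
            pad = as.integer(pad), channels = as.integer(channels),
            cache = NULL, geom = NULL)
}

layer_bn <- function(channels, momentum = 0.1, eps = 1e-5) {
  new_layer("bn",
            params = list(gamma = rep(1, channels), beta = numeric(channels)),
            running_mean = numeric(channels), running_var = rep(1, channels),
            momentum = momentum, eps = eps, cache = NULL)
}

layer_relu <- function() new_layer("relu", params = NULL, cache = NULL)

layer_gap <- function() new_layer("gap", params = NULL, cache = NULL)

layer_fc <- function(d_in, d_out) {
  new_layer("fc",
            params = list(W = he_init(d_in, d_out, d_in), b = numeric(d_out)),
            cache = NULL)
}

# ---- im2col geometry ------------------------------------------------------

# Precompute gather indices for (H, W, N, C) padded input and a k x k kernel.
conv_geometry <- function(H, W, N, C, k, stride, pad) {
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  s0 <- function(n) seq_len(n) - 1L
  rowbase <- as.vector(outer(outer(s0(Ho) * stride, Hp * s0(Wo) * stride, "+"),
                             Hp * Wp * s0(N), "+"))
  colofs <- as.vector(outer(outer(s0(k), Hp * s0(k), "+"),
                            Hp * Wp * N * s0(C), "+"))
  list(H = H, W = W, N = N, C = C, k = k, stride = stride, pad = pad,
       Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo,
       rowbase = rowbase, colofs = colofs,
       M = length(rowbase), K = length(colofs))
}

get_geom <- function(layer, st, C) {
  g <- layer$geom
  if (is.null(g) || g$H != st$H || g$W != st$W || g$N != st$N || g$C != C)
    layer$geom <- g <- conv_geometry(st$H, st$W, st$N, C, layer$k,
                                     layer$stride, layer$pad)
  g
}

pad_input <- function(st, g) {
  xp <- array(0, c(g$Hp, g$Wp, g$N, g$C))
  xp[g$pad + seq_len(g$H), g$pad + seq_len(g$W), , ] <-
    array(st$x, c(g$H, g$W, g$N, g$C))
  xp
}

im2col <- function(xp, g) {
  idx <- outer(g$rowbase, g$colofs, "+") + 1
  matrix(xp[idx], g$M, g$K)
}

col2im <- function(dcols, g) {
  dxp <- numeric(g$Hp * g$Wp * g$N * g$C)
  for (kk in seq_len(g$K)) {
    ii <- g$rowbase + g$colofs[kk] + 1
    dxp[ii] <- dxp[ii] + dcols[, kk]
  }
  dim(dxp) <- c(g$Hp, g$Wp, g$N, g$C)
  inner <- dxp[g$pad + seq_len(g$H), g$pad + seq_len(g$W), , , drop = FALSE]
  matrix(inner, g$H * g$W * g$N, g$C)
}

rowrep <- function(v, M) matrix(v, M, length(v), byrow = TRUE)

# ---- forward / backward ---------------------------------------------------

layer_forward <- function(layer, st, training = TRUE) {
  switch(layer$type,
    conv = {
      g <- get_geom(layer, st, layer$c_in)
      cols <- if (layer$k == 1L && layer$stride == 1L && layer$pad == 0L)
        st$x else im2col(pad_input(st, g), g)
      y <- cols %*% layer$params$W + rowrep(layer$params$b, g$M)
      layer$cache <- list(cols = cols, g = g)
      act_state(y, g$Ho, g$Wo, g$N)
    },
    dwconv = {
      C <- layer$channels
      g <- get_geom(layer, st, C)
      cols <- im2col(pad_input(st, g), g)
      kk <- layer$k * layer$k
      y <- matrix(0, g$M, C)
      for (c in seq_len(C))
        y[, c] <- cols[, (c - 1L) * kk + seq_len(kk)] %*% layer$params$W[, c]
      y <- y + rowrep(layer$params$b, g$M)
      layer$cache <- list(cols = cols, g = g)
      act_state(y, g$Ho, g$Wo, g$N)
    },
    bn = {
      x <- st$x; M <- nrow(x)
      if (training) {
        mu <- colMeans(x)
        v <- colMeans(x^2) - mu^2
        layer$running_mean <- (1 - layer$momentum) * layer$running_mean +
          layer$momentum * mu
        layer$running_var <- (1 - layer$momentum) * layer$running_var +
          layer$momentum * v
      } else {
        mu <- layer$running_mean; v <- layer$running_var
      }
      invstd <- 1 / sqrt(v + layer$eps)
      xhat <- (x - rowrep(mu, M)) * rowrep(invstd, M)
      y <- xhat * rowrep(layer$params$gamma, M) + rowrep(layer$params$beta, M)
      layer$cache <- list(xhat = xhat, invstd = invstd)
      st$x <- y; st
    },
    relu = {
      mask <- st$x > 0
      layer$cache <- mask
      st$x <- st$x * mask; st
    },
    gap = {
      hw <- st$H * st$W
      grp <- rep(seq_len(st$N), each = hw)
      y <- rowsum(st$x, grp) / hw
      layer$cache <- list(H = st$H, W = st$W, N = st$N)
      act_state(y, 1L, 1L, st$N)
    },
    fc = {
      y <- st$x %*% layer$params$W + rowrep(layer$params$b, nrow(st$x))
      layer$cache <- st$x
      act_state(y, 1L, 1L, st$N)
    },
    stop("unknown layer type ", layer$type))
}

layer_backward <- function(layer, dst) {
  switch(layer$type,
    conv = {
      g <- layer$cache$g; cols <- layer$cache$cols
      dy <- dst$x
      layer$grads <- list(W = crossprod(cols, dy), b = colSums(dy))
      dcols <- tcrossprod(dy, layer$params$W)
      dx <- if (layer$k == 1L && layer$stride == 1L && layer$pad == 0L)
        dcols else col2im(dcols, g)
      act_state(dx, g$H, g$W, g$N)
    },
    dwconv = {
      g <- layer$cache$g; cols <- layer$cache$cols
      C <- layer$channels; kk <- layer$k * layer$k
      dy <- dst$x
      dW <- matrix(0, kk, C)
      dcols <- matrix(0, g$M, g$K)
      for (c in seq_len(C)) {
        jj <- (c - 1L) * kk + seq_len(kk)
        dW[, c] <- crossprod(cols[, jj], dy[, c])
        dcols[, jj] <- outer(dy[, c], layer$params$W[, c])
      }
      layer$grads <- list(W = dW, b = colSums(dy))
      act_state(col2im(dcols, g), g$H, g$W, g$N)
    },
    bn = {
      xhat <- layer$cache$xhat; invstd <- layer$cache$invstd
      dy <- dst$x; M <- nrow(dy)
      layer$grads <- list(gamma = colSums(dy * xhat), beta = colSums(dy))
      dxhat <- dy * rowrep(layer$params$gamma, M)
      dx <- (dxhat - rowrep(colMeans(dxhat), M) -
               xhat * rowrep(colMeans(dxhat * xhat), M)) * rowrep(invstd, M)
      dst$x <- dx; dst
    },
    relu = {
      dst$x <- dst$x * layer$cache; dst
    },
    gap = {
      cc <- layer$cache
      hw <- cc$H * cc$W
      dx <- dst$x[rep(seq_len(cc$N), each = hw), , drop = FALSE] / hw
      act_state(dx, cc$H, cc$W, cc$N)
    },
    fc = {
      x <- layer$cache; dy <- dst$x
      layer$grads <- list(W = crossprod(x, dy), b = colSums(dy))
      dst$x <- tcrossprod(dy, layer$params$W); dst
    },
    stop("unknown layer type ", layer$type))
}

net_forward <- function(net, st, training = TRUE) {
  for (layer in net) st <- layer_forward(layer, st, training)
  st
}

net_backward <- function(net, dst) {
  for (layer in rev(net)) dst <- layer_backward(layer, dst)
  dst
}

# ---- Adam -----------------------------------------------------------------

adam_state <- function() new.env(parent = emptyenv())

# One Adam update over every (layer, param) pair; `key` disambiguates layers.
adam_step <- function(layers, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- (if (is.null(state$t)) 0L else state$t) + 1L
  t <- state$t
  for (i in seq_along(layers)) {
    layer <- layers[[i]]
    if (is.null(layer$params) || is.null(layer$grads)) next
    for (nm in names(layer$params)) {
      g <- layer$grads[[nm]]
      key <- paste0("l", i, ".", nm)
      mv <- state[[key]]
      if (is.null(mv)) mv <- list(m = g * 0, v = g * 0)
      mv$m <- beta1 * mv$m + (1 - beta1) * g
      mv$v <- beta2 * mv$v + (1 - beta2) * g^2
      state[[key]] <- mv
      mhat <- mv$m / (1 - beta1^t)
      vhat <- mv$v / (1 - beta2^t)
      layer$params[[nm]] <- layer$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(state)
}

# ---- misc -----------------------------------------------------------------

# Mean-pool an H x W x C image by an integer factor d (H, W divisible by d).
mean_pool_img <- function(img, d) {
  if (d == 1L) return(img)
  dm <- dim(img)
  H <- dm[1]; W <- dm[2]; C <- dm[3]
  if (H %% d != 0L || W %% d != 0L)
    stop("image sides must be divisible by the pooling factor")
  a <- colMeans(array(img, c(d, H %/% d, W, C)))        # over row blocks
  a <- array(a, c(H %/% d, d, W %/% d, C))
  colMeans(aperm(a, c(2, 1, 3, 4)))                     # over column blocks
}

# Stack a list of H x W x 3 images into an activation state.
images_to_state <- function(images) {
  d <- dim(images[[1]])
  N <- length(images)
  A <- array(0, c(d[1], d[2], N, d[3]))
  for (i in seq_len(N)) A[, , i, ] <- images[[i]]
  act_state(matrix(A, d[1] * d[2] * N, d[3]), d[1], d[2], N)
}

# Run `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
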