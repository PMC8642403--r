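## Compact self-contained 3D CNN engine: valid-mode 3D convolution via
## im2col + BLAS matmul, 2x2x2 max pooling, per-channel batch
## normalization, fully connected layers, weighted cross-entropy and MSE
## losses, SGD-with-momentum and Adam optimizers. Batches are 5D arrays
## (nx, ny, nz, channel, sample). Sized for desk-scale grids, not GPU
## corpora.

## ---- layer constructors ------------------------------------------------

nn_conv3d <- function(in_channels, filters, kernel = 3) {
  fan_in <- kernel^3 * in_channels
  list(type = "conv3d", k = kernel, cin = in_channels, cout = filters,
       W = matrix(stats::rnorm(filters * fan_in, sd = sqrt(2 / fan_in)),
                  nrow = filters),
       b = numeric(filters))
}

nn_batchnorm <- function(channels, eps = 1e-5, momentum = 0.1) {
  list(type = "batchnorm", c = channels, eps = eps, momentum = momentum,
       gamma = rep(1, channels), beta = numeric(channels),
       run_mean = numeric(channels), run_var = rep(1, channels))
}

nn_relu <- function() list(type = "relu")
nn_maxpool <- function(size = 2) list(type = "maxpool", s = size)
nn_flatten <- function() list(type = "flatten")

nn_dense <- function(in_dim, out_dim) {
  list(type = "dense", din = in_dim, dout = out_dim,
       W = matrix(stats::rnorm(out_dim * in_dim, sd = sqrt(2 / in_dim)),
                  nrow = out_dim),
       b = numeric(out_dim))
}

## ---- shape propagation -------------------------------------------------

layer_out_shape <- function(layer, shape) {
  switch(layer$type,
         conv3d = c(shape[1:3] - layer$k + 1, layer$cout),
         maxpool = c(shape[1:3] %/% layer$s, shape[4]),
         batchnorm = shape,
         relu = shape,
         flatten = prod(shape),
         dense = layer$dout,
         shape)
}

## im2col index matrix for one sample of shape (nx,ny,nz,cin):
## rows = kernel offsets x channels, cols = output positions.
im2col_index <- function(shape, k) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]; cin <- shape[4]
  ox <- nx - k + 1; oy <- ny - k + 1; oz <- nz - k + 1
  off <- as.matrix(expand.grid(di = 0:(k - 1), dj = 0:(k - 1),
                               dl = 0:(k - 1), c = 0:(cin - 1)))
  pos <- as.matrix(expand.grid(i = 1:ox, j = 1:oy, l = 1:oz))
  base <- (pos[, 1]) + (pos[, 2] - 1) * nx + (pos[, 3] - 1) * nx * ny
  shift <- off[, 1] + off[, 2] * nx + off[, 3] * nx * ny +
           off[, 4] * nx * ny * nz
  outer(shift, base, "+")   # (k^3*cin) x (ox*oy*oz)
}

## ---- forward / backward ------------------------------------------------

CONV_CHUNK <- 8L   # samples gathered per im2col block

forward_conv3d <- function(layer, x, cache_env) {
  d <- dim(x); B <- d[5]
  idx <- cache_env$idx
  if (is.null(idx) || !identical(cache_env$in_shape, d[1:4])) {
    idx <- im2col_index(d[1:4], layer$k)
    cache_env$idx <- idx
    cache_env$in_shape <- d[1:4]
    cache_env$chunk_idx <- list()
    ## scatter (col2im) operator for the backward pass
    iv <- as.vector(idx)
    cache_env$scatter <- Matrix::sparseMatrix(
      i = iv, j = seq_along(iv), x = 1,
      dims = c(prod(d[1:4]), length(iv)))
  }
  out_sp <- d[1:3] - layer$k + 1
  P <- prod(out_sp)
  n_in <- prod(d[1:4])
  K <- nrow(idx)
  xf <- matrix(x, ncol = B)
  yf <- matrix(0, nrow = P * layer$cout, ncol = B)
  chunks <- split(seq_len(B), ceiling(seq_len(B) / CONV_CHUNK))
  cols <- vector("list", length(chunks))
  for (ci in seq_along(chunks)) {
    sel <- chunks[[ci]]
    m <- length(sel)
    key <- as.character(m)
    if (is.null(cache_env$chunk_idx[[key]]))
      cache_env$chunk_idx[[key]] <-
        rep(as.vector(idx), m) + rep((seq_len(m) - 1L) * n_in,
                                     each = length(idx))
    ## columns: m blocks of P positions side by side
    col <- matrix(as.vector(xf[, sel])[cache_env$chunk_idx[[key]]],
                  nrow = K)
    cols[[ci]] <- col
    out <- layer$W %*% col + layer$b            # cout x (P*m)
    ## per sample: transpose cout x P to position-major vector
    for (j in seq_len(m))
      yf[, sel[j]] <- as.vector(t(out[, ((j - 1) * P + 1):(j * P),
                                      drop = FALSE]))
  }
  y <- array(yf, dim = c(out_sp, layer$cout, B))
  list(out = y, cache = list(cols = cols, chunks = chunks, in_dim = d,
                             P = P, scatter = cache_env$scatter))
}

backward_conv3d <- function(layer, cache, dy) {
  d <- cache$in_dim; B <- d[5]
  P <- cache$P
  dW <- matrix(0, nrow = nrow(layer$W), ncol = ncol(layer$W))
  db <- numeric(layer$cout)
  dxf <- matrix(0, nrow = prod(d[1:4]), ncol = B)
  dyf <- matrix(dy, ncol = B)
  for (ci in seq_along(cache$chunks)) {
    sel <- cache$chunks[[ci]]
    m <- length(sel)
    dys <- do.call(cbind, lapply(seq_len(m), function(j)
      t(matrix(dyf[, sel[j]], nrow = P))))       # cout x (P*m)
    dW <- dW + tcrossprod(dys, cache$cols[[ci]])
    db <- db + rowSums(dys)
    dcol <- crossprod(layer$W, dys)               # K x (P*m)
    ## one sparse scatter per chunk: each sample a column
    dxf[, sel] <- as.matrix(cache$scatter %*%
                            matrix(dcol, nrow = nrow(dcol) * P))
  }
  list(dx = array(dxf, dim = d), grads = list(W = dW, b = db))
}

forward_maxpool <- function(layer, x) {
  d <- dim(x); s <- layer$s
  o <- d[1:3] %/% s
  subs <- vector("list", s^3)
  m <- 1
  for (dl in 0:(s - 1)) for (dj in 0:(s - 1)) for (di in 0:(s - 1)) {
    subs[[m]] <- x[seq(1 + di, by = s, length.out = o[1]),
                   seq(1 + dj, by = s, length.out = o[2]),
                   seq(1 + dl, by = s, length.out = o[3]), , , drop = FALSE]
    m <- m + 1
  }
  y <- Reduce(pmax, subs)
  list(out = y, cache = list(in_dim = d, out_dim = dim(y), subs = subs,
                             y = y))
}

backward_maxpool <- function(layer, cache, dy) {
  d <- cache$in_dim; s <- layer$s
  o <- cache$out_dim[1:3]
  dx <- array(0, dim = d)
  remaining <- array(TRUE, dim = cache$out_dim)
  m <- 1
  for (dl in 0:(s - 1)) for (dj in 0:(s - 1)) for (di in 0:(s - 1)) {
    mask <- (cache$subs[[m]] == cache$y) & remaining
    remaining <- remaining & !mask
    g <- dy * mask
    dx[seq(1 + di, by = s, length.out = o[1]),
       seq(1 + dj, by = s, length.out = o[2]),
       seq(1 + dl, by = s, length.out = o[3]), , ] <-
      dx[seq(1 + di, by = s, length.out = o[1]),
         seq(1 + dj, by = s, length.out = o[2]),
         seq(1 + dl, by = s, length.out = o[3]), , , drop = FALSE] + g
    m <- m + 1
  }
  list(dx = dx, grads = NULL)
}

## channel-last matrix view: rows = spatial*batch, cols = channels
bn_mat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 2, 3, 5, 4)), ncol = d[4])
}

bn_unmat <- function(m, d) {
  aperm(array(m, dim = c(d[1:3], d[5], d[4])), c(1, 2, 3, 5, 4))
}

forward_batchnorm <- function(layer, x, training) {
  d <- dim(x)
  m <- bn_mat(x)
  if (training) {
    mu <- colMeans(m)
    v <- colMeans(sweep(m, 2, mu)^2)
    layer$run_mean <- (1 - layer$momentum) * layer$run_mean + layer$momentum * mu
    layer$run_var <- (1 - layer$momentum) * layer$run_var + layer$momentum * v
  } else {
    mu <- layer$run_mean
    v <- layer$run_var
  }
  inv_sd <- 1 / sqrt(v + layer$eps)
  xhat <- sweep(sweep(m, 2, mu), 2, inv_sd, "*")
  y <- sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+")
  list(out = bn_unmat(y, d), layer = layer,
       cache = list(xhat = xhat, inv_sd = inv_sd, d = d))
}

backward_batchnorm <- function(layer, cache, dy) {
  d <- cache$d
  dym <- bn_mat(dy)
  n <- nrow(dym)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, layer$gamma, "*")
  dxm <- sweep(dxhat - outer(rep(1, n), dbeta * layer$gamma / n) -
               cache$xhat * outer(rep(1, n), dgamma * layer$gamma / n),
               2, cache$inv_sd, "*")
  ## note: dbeta*gamma/n term above uses sum(dxhat)/n = dbeta*gamma/n
  list(dx = bn_unmat(dxm, d), grads = list(gamma = dgamma, beta = dbeta))
}

forward_relu <- function(x) list(out = pmax(x, 0), cache = x > 0)
backward_relu <- function(cache, dy) list(dx = dy * cache, grads = NULL)

forward_flatten <- function(x) {
  d <- dim(x)
  list(out = matrix(x, ncol = d[length(d)]), cache = d)
}
backward_flatten <- function(cache, dy) list(dx = array(dy, dim = cache),
                                             grads = NULL)

forward_dense <- function(layer, x) {
  list(out = layer$W %*% x + layer$b, cache = x)
}
backward_dense <- function(layer, cache, dy) {
  list(dx = crossprod(layer$W, dy),
       grads = list(W = tcrossprod(dy, cache), b = rowSums(dy)))
}

#' Forward pass through a layer stack
#' @noRd
nn_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    r <- switch(ly$type,
                conv3d = forward_conv3d(ly, x, net$conv_cache[[i]]),
                batchnorm = forward_batchnorm(ly, x, training),
                relu = forward_relu(x),
                maxpool = forward_maxpool(ly, x),
                flatten = forward_flatten(x),
                dense = forward_dense(ly, x))
    if (ly$type == "batchnorm" && training) net$layers[[i]] <- r$layer
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches, net = net)
}

#' Backward pass; returns input gradient and per-layer parameter grads
#' @noRd
nn_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  dx <- dout
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    r <- switch(ly$type,
                conv3d = backward_conv3d(ly, caches[[i]], dx),
                batchnorm = backward_batchnorm(ly, caches[[i]], dx),
                relu = backward_relu(caches[[i]], dx),
                maxpool = backward_maxpool(ly, caches[[i]], dx),
                flatten = backward_flatten(caches[[i]], dx),
                dense = backward_dense(ly, caches[[i]], dx))
    dx <- r$dx
    grads[i] <- list(r$grads)   # keep NULL slots (list(NULL) preserves length)
  }
  list(dx = dx, grads = grads)
}

## ---- losses ------------------------------------------------------------

log_softmax <- function(z) {
  zmax <- apply(z, 2, max)
  zc <- sweep(z, 2, zmax)
  sweep(zc, 2, log(colSums(exp(zc))), "-")
}

## Weighted cross-entropy from logits. labels: integer class index
## (1-based). weights: per-class weights. Normalized by the summed weights
## of the batch, so zero-weight classes contribute nothing to loss or
## gradient.
loss_cross_entropy <- function(z, labels, weights) {
  B <- ncol(z)
  lp <- log_softmax(z)
  w <- weights[labels]
  W <- sum(w)
  if (W == 0) return(list(loss = 0, dz = matrix(0, nrow(z), B)))
  pick <- cbind(labels, seq_len(B))
  loss <- -sum(w * lp[pick]) / W
  p <- exp(lp)
  onehot <- matrix(0, nrow(z), B)
  onehot[pick] <- 1
  dz <- sweep(p - onehot, 2, w / W, "*")
  list(loss = loss, dz = dz)
}

loss_mse <- function(z, y) {
  B <- ncol(z)
  diff <- as.vector(z) - y
  list(loss = mean(diff^2), dz = matrix(2 * diff / B, nrow = 1))
}

## ---- optimizers --------------------------------------------------------

param_names <- c("W", "b", "gamma", "beta")

opt_init <- function(net) {
  lapply(net$layers, function(ly) {
    ps <- intersect(param_names, names(ly))
    st <- lapply(ps, function(p) list(m = ly[[p]] * 0, v = ly[[p]] * 0))
    stats::setNames(st, ps)
  })
}

opt_step <- function(net, grads, state, opt, t) {
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (p in names(g)) {
      grad <- g[[p]]
      if (opt$name == "sgd") {
        if (opt$weight_decay > 0 && p %in% c("W", "gamma"))
          grad <- grad + opt$weight_decay * net$layers[[i]][[p]]
        state[[i]][[p]]$m <- opt$momentum * state[[i]][[p]]$m + grad
        net$layers[[i]][[p]] <- net$layers[[i]][[p]] -
          opt$lr * state[[i]][[p]]$m
      } else {  # adam
        state[[i]][[p]]$m <- opt$beta1 * state[[i]][[p]]$m +
          (1 - opt$beta1) * grad
        state[[i]][[p]]$v <- opt$beta2 * state[[i]][[p]]$v +
          (1 - opt$beta2) * grad^2
        mhat <- state[[i]][[p]]$m / (1 - opt$beta1^t)
        vhat <- state[[i]][[p]]$v / (1 - opt$beta2^t)
        net$layers[[i]][[p]] <- net$layers[[i]][[p]] -
          opt$lr * mhat / (sqrt(vhat) + opt$eps)
      }
    }
  }
  list(net = net, state = state)
}

## ---- network assembly --------------------------------------------------

#' Build the layer stack for a model configuration
#'
#' Default architecture: two convolution blocks (8 then 16 filters,
#' kernel 3, batch norm, ReLU, 2x2x2 max pool), then a fully connected
#' layer of width 84 and the output layer (width 2 for classification,
#' 1 for regression). Accepts any grid of at least 12 points per axis
#' and any channel count.
#'
#' @param input_shape c(nx, ny, nz, channels) of one sample.
#' @param config a [model_config()].
#' @return list with `layers`, `conv_cache` (per-layer environments) and
#'   `input_shape`.
#' @noRd
nn_build <- function(input_shape, config) {
  shape <- input_shape
  layers <- list()
  cin <- shape[4]
  for (f in config$conv_filters) {
    layers <- c(layers, list(nn_conv3d(cin, f, config$kernel)))
    shape <- layer_out_shape(layers[[length(layers)]], shape)
    layers <- c(layers, list(nn_batchnorm(f)), list(nn_relu()),
                list(nn_maxpool(2)))
    shape <- shape
    shape <- layer_out_shape(nn_maxpool(2), shape)
    if (any(shape[1:3] < 1))
      stop_ppi("ppi_config_error",
               "grid too small for the convolution stack (shape %s)",
               paste(shape[1:3], collapse = "x"))
    cin <- f
  }
  layers <- c(layers, list(nn_flatten()))
  flat <- prod(shape)
  for (w in config$fc_widths) {
    layers <- c(layers, list(nn_dense(flat, w)), list(nn_relu()))
    flat <- w
  }
  out_dim <- if (config$task == "classification") 2L else 1L
  layers <- c(layers, list(nn_dense(flat, out_dim)))
  list(layers = layers,
       conv_cache = lapply(layers, function(x) new.env(parent = emptyenv())),
       input_shape = input_shape)
}
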