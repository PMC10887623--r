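# Minimal convolutional network stack with exact manual backpropagation.
# Tensors are numeric arrays of dim c(H, W, C); convolutions are im2col +
# GEMM; transposed convolutions are the exact adjoint of a strided
# convolution (including the padding adjoint), so gradient pairs are
# consistent by construction. All kernels use padding 1 (k = 3 stride 1, or
# k = 4 stride 2). Padding along the angular (row) axis is circular when
# operating on polar rasters, reflective otherwise; the radial (column)
# axis is always reflective.

pad_indices <- function(n, mode) {
  switch(mode,
         circular = c(n, seq_len(n), 1L),
         reflect  = c(2L, seq_len(n), n - 1L),
         zero     = c(1L, seq_len(n), n),   # placeholder rows, zeroed after
         stop("unknown pad mode"))
}

pad2d <- function(x, mode_r, mode_c) {
  d <- dim(x)
  ri <- pad_indices(d[1], mode_r)
  ci <- pad_indices(d[2], mode_c)
  xp <- x[ri, ci, , drop = FALSE]
  if (mode_r == "zero") { xp[1, , ] <- 0; xp[d[1] + 2, , ] <- 0 }
  if (mode_c == "zero") { xp[, 1, ] <- 0; xp[, d[2] + 2, ] <- 0 }
  xp
}

# exact adjoint of pad2d: drop the one-pixel frame and scatter-add its
# contributions back onto the rows/columns the forward pad duplicated
pad2d_adj <- function(g, mode_r, mode_c) {
  d <- dim(g)                    # (H+2, W+2, C)
  H <- d[1] - 2L; W <- d[2] - 2L
  # fold the frame columns into the interior first (acting on full rows),
  # then the frame rows
  gi <- g[, 2:(W + 1), , drop = FALSE]
  if (mode_c != "zero") {
    cl <- if (mode_c == "circular") W else 2L   # source col of left frame
    cr <- if (mode_c == "circular") 1L else W - 1L
    gi[, cl, ] <- gi[, cl, ] + g[, 1, ]
    gi[, cr, ] <- gi[, cr, ] + g[, W + 2, ]
  }
  out <- gi[2:(H + 1), , , drop = FALSE]
  if (mode_r != "zero") {
    rt <- if (mode_r == "circular") H else 2L
    rb <- if (mode_r == "circular") 1L else H - 1L
    out[rt, , ] <- out[rt, , ] + gi[1, , ]
    out[rb, , ] <- out[rb, , ] + gi[H + 2, , ]
  }
  out
}

new_layer <- function(type, cin = NULL, cout = NULL, k = NULL, s = NULL,
                      norm = FALSE, act = "none") {
  list(type = type, cin = cin, cout = cout, k = k, s = s,
       norm = norm, act = act, par = list())
}

init_layer <- function(layer, sd = 0.02) {
  if (layer$type %in% c("conv", "convT")) {
    nw <- layer$cout * layer$cin * layer$k * layer$k
    if (layer$type == "conv") {
      layer$par$W <- matrix(rnorm(nw, 0, sd), layer$cout,
                            layer$cin * layer$k * layer$k)
    } else {
      # stored as the underlying conv that maps cout -> cin
      layer$par$W <- matrix(rnorm(nw, 0, sd), layer$cin,
                            layer$cout * layer$k * layer$k)
    }
    layer$par$b <- numeric(layer$cout)
    if (layer$norm) {
      layer$par$gamma <- rep(1, layer$cout)
      layer$par$beta <- numeric(layer$cout)
    }
  }
  layer
}

.EPS_IN <- 1e-5

act_forward <- function(y, act) {
  switch(act,
         none = y,
         relu = pmax(y, 0),
         lrelu = pmax(y, 0) + 0.2 * pmin(y, 0),
         tanh = tanh(y))
}

act_backward <- function(g, y_in, y_out, act) {
  switch(act,
         none = g,
         relu = g * (y_in > 0),
         lrelu = g * (0.2 + 0.8 * (y_in > 0)),
         tanh = g * (1 - y_out^2))
}

in_forward <- function(y, gamma, beta) {
  d <- dim(y); N <- d[1] * d[2]
  ym <- matrix(y, N, d[3])
  mu <- colMeans(ym)
  yc <- ym - rep(mu, each = N)
  v <- colMeans(yc^2)
  istd <- 1 / sqrt(v + .EPS_IN)
  xhat <- yc * rep(istd, each = N)
  out <- xhat * rep(gamma, each = N) + rep(beta, each = N)
  list(y = array(out, d), xhat = xhat, istd = istd)
}

in_backward <- function(g, cache, gamma, d) {
  N <- d[1] * d[2]
  gm <- matrix(g, N, d[3])
  xhat <- cache$xhat
  ggamma <- colSums(gm * xhat)
  gbeta <- colSums(gm)
  gxhat <- gm * rep(gamma, each = N)
  gx <- (gxhat - rep(colMeans(gxhat), each = N) -
           xhat * rep(colMeans(gxhat * xhat), each = N)) *
    rep(cache$istd, each = N)
  list(gx = array(gx, d), gamma = ggamma, beta = gbeta)
}

layer_forward <- function(layer, x, mode_r, mode_c) {
  cache <- list(xdim = dim(x))
  if (layer$type == "conv") {
    xp <- pad2d(x, mode_r, mode_c)
    dp <- dim(xp)
    cols <- im2col_cpp(xp, dp[1], dp[2], dp[3], layer$k, layer$k, layer$s)
    ho <- (dp[1] - layer$k) %/% layer$s + 1L
    wo <- (dp[2] - layer$k) %/% layer$s + 1L
    N <- ho * wo
    ymat <- crossprod(cols, t(layer$par$W)) + rep(layer$par$b, each = N)
    y <- array(ymat, c(ho, wo, layer$cout))
    cache$cols <- cols; cache$pdim <- dp
  } else if (layer$type == "convT") {
    d <- dim(x)
    zmat <- t(matrix(x, d[1] * d[2], d[3]))            # Cz x N
    cols <- crossprod(layer$par$W, zmat)
    H <- d[1] * layer$s; W <- d[2] * layer$s
    yp <- col2im_cpp(cols, H + 2L, W + 2L, layer$cout, layer$k, layer$k,
                     layer$s)
    y <- pad2d_adj(yp, mode_r, mode_c)
    y <- y + rep(layer$par$b, each = H * W)
    cache$zmat <- zmat
  } else stop("unknown layer type")
  cache$pre_norm <- NULL
  if (layer$norm) {
    inr <- in_forward(y, layer$par$gamma, layer$par$beta)
    cache$innorm <- inr[c("xhat", "istd")]
    cache$ndim <- dim(y)
    y <- inr$y
  }
  cache$act_in <- if (layer$act %in% c("relu", "lrelu")) y else NULL
  y <- act_forward(y, layer$act)
  cache$act_out <- if (layer$act == "tanh") y else NULL
  list(y = y, cache = cache)
}

layer_backward <- function(layer, cache, gy, mode_r, mode_c) {
  g <- act_backward(gy, cache$act_in, cache$act_out, layer$act)
  grads <- list()
  if (layer$norm) {
    bn <- in_backward(g, cache$innorm, layer$par$gamma, cache$ndim)
    g <- bn$gx
    grads$gamma <- bn$gamma; grads$beta <- bn$beta
  }
  if (layer$type == "conv") {
    d <- dim(g)
    gmt <- matrix(g, d[1] * d[2], d[3])                # N x Cout
    grads$W <- t(cache$cols %*% gmt)
    grads$b <- colSums(gmt)
    gcols <- tcrossprod(t(layer$par$W), gmt)           # K x N
    dp <- cache$pdim
    gxp <- col2im_cpp(gcols, dp[1], dp[2], dp[3], layer$k, layer$k, layer$s)
    gx <- pad2d_adj(gxp, mode_r, mode_c)
  } else {                                             # convT
    d <- dim(g)
    grads$b <- colSums(matrix(g, d[1] * d[2], d[3]))
    gp <- pad2d(g, mode_r, mode_c)
    dgp <- dim(gp)
    C <- im2col_cpp(gp, dgp[1], dgp[2], dgp[3], layer$k, layer$k, layer$s)
    grads$W <- tcrossprod(cache$zmat, C)
    gzmat <- layer$par$W %*% C
    gx <- array(t(gzmat), cache$xdim)
  }
  list(gx = gx, grads = grads)
}

#' Network architecture configuration
#'
#' Five convolutional layers in the encoder and in each decoder, of which
#' exactly three change resolution (stride-2 down-sampling in the encoder,
#' its transposed counterpart in the decoders). Channel widths are
#' `base_channels * c(1, 2, 4, 4, 4)`; non-resampling layers use 3x3
#' kernels, resampling layers 4x4, all with padding 1. Instance
#' normalization follows every convolution except the output layers; the
#' encoder uses plain ReLU, everything else LeakyReLU(0.2); decoder outputs
#' pass through tanh. Discriminators are 70x70 patch critics: four stride-2
#' convolutions plus a 1-channel scoring convolution.
#'
#' @param base_channels Width multiplier (64 reproduces the full-size
#'   network; 16 is a practical CPU toy size).
#' @param seed Seed for the normal(0, 0.02) weight initialization.
#' @param init_sd Weight init standard deviation.
#' @return An object of class `net_config`.
#' @export
net_config <- function(base_channels = 64, seed = 1L, init_sd = 0.02) {
  stopifnot(base_channels >= 1)
  structure(list(base_channels = as.integer(base_channels),
                 seed = as.integer(seed), init_sd = init_sd,
                 n_layers = 5L, n_resample = 3L),
            class = "net_config")
}

encoder_spec <- function(bc) list(
  new_layer("conv", 1L, bc, 3L, 1L, norm = TRUE, act = "relu"),
  new_layer("conv", bc, 2L * bc, 4L, 2L, norm = TRUE, act = "relu"),
  new_layer("conv", 2L * bc, 4L * bc, 4L, 2L, norm = TRUE, act = "relu"),
  new_layer("conv", 4L * bc, 4L * bc, 4L, 2L, norm = TRUE, act = "relu"),
  new_layer("conv", 4L * bc, 4L * bc, 3L, 1L, norm = TRUE, act = "relu"))

decoder_spec <- function(bc) list(
  new_layer("conv", 4L * bc, 4L * bc, 3L, 1L, norm = TRUE, act = "lrelu"),
  new_layer("convT", 4L * bc, 4L * bc, 4L, 2L, norm = TRUE, act = "lrelu"),
  new_layer("convT", 4L * bc, 2L * bc, 4L, 2L, norm = TRUE, act = "lrelu"),
  new_layer("convT", 2L * bc, bc, 4L, 2L, norm = TRUE, act = "lrelu"),
  new_layer("conv", bc, 1L, 3L, 1L, norm = FALSE, act = "tanh"))

discriminator_spec <- function(bc) list(
  new_layer("conv", 1L, bc, 4L, 2L, norm = FALSE, act = "lrelu"),
  new_layer("conv", bc, 2L * bc, 4L, 2L, norm = TRUE, act = "lrelu"),
  new_layer("conv", 2L * bc, 4L * bc, 4L, 2L, norm = TRUE, act = "lrelu"),
  new_layer("conv", 4L * bc, 8L * bc, 4L, 2L, norm = TRUE, act = "lrelu"),
  new_layer("conv", 8L * bc, 1L, 3L, 1L, norm = FALSE, act = "none"))

build_net <- function(spec, init_sd) {
  list(layers = lapply(spec, init_layer, sd = init_sd))
}

net_forward <- function(net, x, mode_r, mode_c) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    r <- layer_forward(net$layers[[i]], x, mode_r, mode_c)
    x <- r$y
    caches[[i]] <- r$cache
  }
  list(y = x, caches = caches)
}

net_backward <- function(net, caches, gy, mode_r, mode_c) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    r <- layer_backward(net$layers[[i]], caches[[i]], gy, mode_r, mode_c)
    gy <- r$gx
    grads[[i]] <- r$grads
  }
  list(gx = gy, grads = grads)
}

grads_zero <- function(net) {
  lapply(net$layers, function(l) lapply(l$par, function(p) {
    z <- p; z[] <- 0; z
  }))
}

grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (i in seq_along(b)) for (nm in names(b[[i]]))
    a[[i]][[nm]] <- a[[i]][[nm]] + b[[i]][[nm]]
  a
}

grads_scale <- function(a, s) {
  lapply(a, function(l) lapply(l, function(p) p * s))
}

n_params <- function(net) {
  sum(vapply(net$layers, function(l)
    sum(vapply(l$par, length, 1L)), 1))
}
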