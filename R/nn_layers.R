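# Neural-network layers in vectorised base R. Every layer is an environment
# holding parameters, a forward cache and the gradients of the last backward
# pass. Activations travel as 3-D arrays (batch B, length L, channels C).
# Convolutions are computed by im2col + matrix multiplication; transposed
# convolutions reuse the same gather/scatter index plan with the roles of
# gather and scatter swapped, which guarantees the length round trip.

#' Padding geometry for an exact-length strided convolution
#'
#' Returns the padding that makes a strided convolution map length `L` to
#' exactly `L/step`, and the mirrored transposed convolution map `L/step`
#' back to exactly `L`. Total padding is `kernel - step`; it is split as
#' evenly as possible (the extra base, if any, goes right).
#'
#' @param L Input length in bp; must be divisible by `step`.
#' @param kernel Convolution kernel width.
#' @param step Stride (doubles as the pooling factor); `step = 1` gives
#'   same-padding.
#' @return List with `pad_left`, `pad_right`, `L_pad`, `L_out` and a
#'   gather-index matrix `idx` (`L_out` x `kernel`, positions in the padded
#'   input).
#' @export
conv_geometry <- function(L, kernel, step) {
  L <- as.integer(L); kernel <- as.integer(kernel); step <- as.integer(step)
  stopifnot(L > 0L, kernel > 0L, step > 0L)
  if (L %% step != 0L) {
    stop("length ", L, " is not divisible by step ", step)
  }
  p <- kernel - step
  if (p < 0L) {
    stop("no integer padding maps length ", L, " to ", L %/% step,
         " with kernel ", kernel, " and step ", step,
         "; choose kernel >= step")
  }
  pad_left <- p %/% 2L
  pad_right <- p - pad_left
  L_out <- L %/% step
  starts <- (seq_len(L_out) - 1L) * step
  idx <- outer(starts, seq_len(kernel), `+`)   # 1-based in padded coords
  storage.mode(idx) <- "integer"
  list(L = L, kernel = kernel, step = step, pad_left = pad_left,
       pad_right = pad_right, L_pad = L + p, L_out = L_out, idx = idx)
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

# ---- convolution ----------------------------------------------------------

new_conv <- function(L, cin, cout, kernel, step) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "conv"
  ly$plan <- conv_geometry(L, kernel, step)
  ly$cin <- cin; ly$cout <- cout
  ly$params <- list(W = he_init(kernel * cin, cout, kernel * cin),
                    b = numeric(cout))
  ly
}

conv_forward <- function(ly, x, train) {
  pl <- ly$plan
  if (!is.double(x)) storage.mode(x) <- "double"
  B <- dim(x)[1L]
  M <- .Call(C_im2col, x, pl$idx, pl$pad_left)     # (B*L_out, k*cin)
  y <- M %*% ly$params$W
  y <- sweep(y, 2L, ly$params$b, `+`)
  dim(y) <- c(B, pl$L_out, ly$cout)
  ly$cache <- list(M = M, B = B)
  y
}

conv_backward <- function(ly, dy) {
  pl <- ly$plan
  B <- ly$cache$B
  dym <- dy; dim(dym) <- c(B * pl$L_out, ly$cout)
  ly$grads <- list(W = crossprod(ly$cache$M, dym), b = colSums(dym))
  dM <- tcrossprod(dym, ly$params$W)               # (B*L_out, k*cin)
  dx <- .Call(C_col2im, dM, pl$idx, pl$pad_left, pl$L, B)
  ly$cache <- NULL
  dx
}

# ---- transposed convolution ----------------------------------------------
# Maps L/step back to L using the same index plan as the matching conv.

new_tconv <- function(L_out_full, cin, cout, kernel, step) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "tconv"
  ly$plan <- conv_geometry(L_out_full, kernel, step)  # plan of mirrored conv
  ly$cin <- cin; ly$cout <- cout
  ly$params <- list(W = he_init(kernel * cout, cin, kernel * cin),
                    b = numeric(cout))
  ly
}

tconv_forward <- function(ly, z, train) {
  pl <- ly$plan
  if (!is.double(z)) storage.mode(z) <- "double"
  B <- dim(z)[1L]
  zm <- z; dim(zm) <- c(B * pl$L_out, ly$cin)
  G <- tcrossprod(zm, ly$params$W)                 # (B*L_out, k*cout)
  y <- .Call(C_col2im, G, pl$idx, pl$pad_left, pl$L, B)
  y <- sweep(y, 3L, ly$params$b, `+`)
  ly$cache <- list(zm = zm, B = B)
  y
}

tconv_backward <- function(ly, dy) {
  pl <- ly$plan
  B <- ly$cache$B
  dG <- .Call(C_im2col, dy, pl$idx, pl$pad_left)   # (B*L_out, k*cout)
  dz <- dG %*% ly$params$W                         # (B*L_out, cin)
  ly$grads <- list(W = crossprod(dG, ly$cache$zm),
                   b = apply(dy, 3L, sum))
  dim(dz) <- c(B, pl$L_out, ly$cin)
  ly$cache <- NULL
  dz
}

# ---- ReLU -----------------------------------------------------------------

new_relu <- function() {
  ly <- new.env(parent = emptyenv())
  ly$type <- "relu"
  ly$params <- list()
  ly
}

relu_forward <- function(ly, x, train) {
  keep <- x > 0
  ly$cache <- keep
  x * keep
}

relu_backward <- function(ly, dy) {
  dx <- dy * ly$cache
  ly$grads <- list()
  ly$cache <- NULL
  dx
}

# ---- batch normalization --------------------------------------------------
# Per-channel statistics over batch x length; running estimates (momentum
# 0.1) are used in evaluation mode, which makes inference deterministic.

new_batchnorm <- function(channels, eps = 1e-5, momentum = 0.1) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "batchnorm"
  ly$channels <- channels
  ly$eps <- eps; ly$momentum <- momentum
  ly$params <- list(gamma = rep(1, channels), beta = numeric(channels))
  ly$running_mean <- numeric(channels)
  ly$running_var <- rep(1, channels)
  ly
}

batchnorm_forward <- function(ly, x, train) {
  d <- dim(x)
  x2 <- x; dim(x2) <- c(d[1L] * d[2L], d[3L])
  if (train) {
    mu <- colMeans(x2)
    va <- colMeans(sweep(x2, 2L, mu)^2)
    ly$running_mean <- (1 - ly$momentum) * ly$running_mean + ly$momentum * mu
    ly$running_var <- (1 - ly$momentum) * ly$running_var + ly$momentum * va
  } else {
    mu <- ly$running_mean
    va <- ly$running_var
  }
  inv_std <- 1 / sqrt(va + ly$eps)
  xhat <- sweep(sweep(x2, 2L, mu), 2L, inv_std, `*`)
  y <- sweep(sweep(xhat, 2L, ly$params$gamma, `*`), 2L, ly$params$beta, `+`)
  dim(y) <- d
  ly$cache <- list(xhat = xhat, inv_std = inv_std, d = d, train = train)
  y
}

batchnorm_backward <- function(ly, dy) {
  ca <- ly$cache
  d <- ca$d
  dy2 <- dy; dim(dy2) <- c(d[1L] * d[2L], d[3L])
  xhat <- ca$xhat
  ly$grads <- list(gamma = colSums(dy2 * xhat), beta = colSums(dy2))
  dxhat <- sweep(dy2, 2L, ly$params$gamma, `*`)
  if (ca$train) {
    m <- nrow(dy2)
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * xhat)
    dx2 <- sweep(
      m * dxhat - matrix(s1, m, d[3L], byrow = TRUE) -
        xhat * matrix(s2, m, d[3L], byrow = TRUE),
      2L, ca$inv_std / m, `*`)
  } else {
    dx2 <- sweep(dxhat, 2L, ca$inv_std, `*`)
  }
  dim(dx2) <- d
  ly$cache <- NULL
  dx2
}

# ---- LSTM -----------------------------------------------------------------
# Gate order i, f, g, o in the fused weight matrices; forget-gate bias
# initialised to 1. Bidirectional layers run a second cell on the reversed
# sequence and concatenate the two outputs along the channel axis.

new_lstm_cell <- function(cin, units) {
  k <- 1 / sqrt(units)
  b <- stats::runif(4L * units, -k, k)
  b[(units + 1L):(2L * units)] <- 1           # forget gate bias
  list(Wx = matrix(stats::runif(cin * 4L * units, -k, k), cin, 4L * units),
       Wh = matrix(stats::runif(units * 4L * units, -k, k), units,
                   4L * units),
       b = b)
}

new_lstm <- function(cin, units, bidirectional = FALSE) {
  ly <- new.env(parent = emptyenv())
  ly$type <- "lstm"
  ly$cin <- cin; ly$units <- units
  ly$bidirectional <- bidirectional
  ly$params <- if (bidirectional) {
    list(fwd = new_lstm_cell(cin, units), bwd = new_lstm_cell(cin, units))
  } else {
    list(fwd = new_lstm_cell(cin, units))
  }
  ly
}

lstm_cell_forward <- function(cell, x, units) {
  d <- dim(x)                                  # (B, T, cin)
  B <- d[1L]; T_ <- d[2L]
  # hoist the input projection out of the time loop: one large matmul over
  # (B*T, cin), whose row order matches the column-major (B, T, cin) layout
  x2 <- x; dim(x2) <- c(B * T_, d[3L])
  Ax <- x2 %*% cell$Wx                         # (B*T, 4*units)
  Ax <- sweep(Ax, 2L, cell$b, `+`)
  dim(Ax) <- c(B, T_, 4L * units)
  fw <- .Call(C_lstm_forward, Ax, cell$Wh)
  fw$x2 <- x2
  fw
}

lstm_cell_backward <- function(cell, dy, fwd, units, cin) {
  d <- dim(dy)
  B <- d[1L]; T_ <- d[2L]
  res <- .Call(C_lstm_backward, dy, fwd, cell$Wh)
  dA2 <- res$dA; dim(dA2) <- c(B * T_, 4L * units)
  dx <- dA2 %*% t(cell$Wx)                     # (B*T, cin)
  dim(dx) <- c(B, T_, cin)
  list(dx = dx,
       grads = list(Wx = crossprod(fwd$x2, dA2), Wh = res$dWh,
                    b = colSums(dA2)))
}

rev_time <- function(x) {
  x[, rev(seq_len(dim(x)[2L])), , drop = FALSE]
}

lstm_forward <- function(ly, x, train) {
  fw <- lstm_cell_forward(ly$params$fwd, x, ly$units)
  if (!ly$bidirectional) {
    ly$cache <- list(fwd = fw)
    return(fw$y)
  }
  bw <- lstm_cell_forward(ly$params$bwd, rev_time(x), ly$units)
  ly$cache <- list(fwd = fw, bwd = bw)
  y <- array(0, c(dim(x)[1L], dim(x)[2L], 2L * ly$units))
  y[, , seq_len(ly$units)] <- fw$y
  y[, , ly$units + seq_len(ly$units)] <- rev_time(bw$y)
  y
}

lstm_backward <- function(ly, dy) {
  u <- ly$units
  if (!ly$bidirectional) {
    res <- lstm_cell_backward(ly$params$fwd, dy, ly$cache$fwd, u, ly$cin)
    ly$grads <- list(fwd = res$grads)
    ly$cache <- NULL
    return(res$dx)
  }
  dy_f <- dy[, , seq_len(u), drop = FALSE]
  dy_b <- rev_time(dy[, , u + seq_len(u), drop = FALSE])
  res_f <- lstm_cell_backward(ly$params$fwd, dy_f, ly$cache$fwd, u, ly$cin)
  res_b <- lstm_cell_backward(ly$params$bwd, dy_b, ly$cache$bwd, u, ly$cin)
  ly$grads <- list(fwd = res_f$grads, bwd = res_b$grads)
  ly$cache <- NULL
  res_f$dx + rev_time(res_b$dx)
}

# ---- dropout --------------------------------------------------------------

new_dropout <- function(p) {
  stopifnot(p >= 0, p < 1)
  ly <- new.env(parent = emptyenv())
  ly$type <- "dropout"
  ly$p <- p
  ly$params <- list()
  ly
}

dropout_forward <- function(ly, x, train) {
  if (!train || ly$p == 0) {
    ly$cache <- NULL
    return(x)
  }
  keep <- array(stats::runif(length(x)) >= ly$p, dim(x)) / (1 - ly$p)
  ly$cache <- keep
  x * keep
}

dropout_backward <- function(ly, dy) {
  ly$grads <- list()
  if (is.null(ly$cache)) return(dy)
  dx <- dy * ly$cache
  ly$cache <- NULL
  dx
}

# ---- dispatch -------------------------------------------------------------

layer_forward <- function(ly, x, train) {
  switch(ly$type,
         conv = conv_forward(ly, x, train),
         tconv = tconv_forward(ly, x, train),
         relu = relu_forward(ly, x, train),
         batchnorm = batchnorm_forward(ly, x, train),
         lstm = lstm_forward(ly, x, train),
         dropout = dropout_forward(ly, x, train),
         stop("unknown layer type: ", ly$type))
}

layer_backward <- function(ly, dy) {
  switch(ly$type,
         conv = conv_backward(ly, dy),
         tconv = tconv_backward(ly, dy),
         relu = relu_backward(ly, dy),
         batchnorm = batchnorm_backward(ly, dy),
         lstm = lstm_backward(ly, dy),
         dropout = dropout_backward(ly, dy),
         stop("unknown layer type: ", ly$type))
}
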