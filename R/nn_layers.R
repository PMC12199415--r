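# Neural-network primitives: forward passes with caches and hand-derived
# backward passes. All layers operate on plain numeric arrays; batches are
# the leading dimension. Shapes are small (windows of 13-27 positions), so
# base-R matrix arithmetic with loops over the batch where per-example
# softmax is needed is entirely adequate on one CPU.

# ---- linear ---------------------------------------------------------------

linear_fwd <- function(x, W, b = NULL) {
  out <- x %*% W
  if (!is.null(b)) out <- sweep(out, 2, b, "+")
  list(out = out, x = x)
}

linear_bwd <- function(dout, cache, W, has_bias = TRUE) {
  list(dx = dout %*% t(W),
       dW = t(cache$x) %*% dout,
       db = if (has_bias) colSums(dout) else NULL)
}

# ---- activations ----------------------------------------------------------

relu_fwd <- function(x) {
  mask <- x > 0
  list(out = x * mask, mask = mask)
}

relu_bwd <- function(dout, cache) dout * cache$mask

sigmoid <- function(z) 1 / (1 + exp(-z))

# ---- dropout (inverted; identity at inference) -----------------------------

dropout_fwd <- function(x, rate, training, seed) {
  if (!training || rate <= 0) {
    return(list(out = x, mask = NULL))
  }
  mask <- with_seed(seed, {
    array(stats::runif(length(x)) >= rate, dim = dim(x) %||% length(x))
  }) / (1 - rate)
  list(out = x * mask, mask = mask)
}

dropout_bwd <- function(dout, cache) {
  if (is.null(cache$mask)) dout else dout * cache$mask
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- layer normalization (rows = tokens) -----------------------------------

layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  invstd <- 1 / sqrt(v + eps)
  xhat <- xc * invstd
  list(out = sweep(sweep(xhat, 2, g, "*"), 2, b, "+"),
       xhat = xhat, invstd = invstd)
}

layernorm_bwd <- function(dout, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dout, 2, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$invstd * (dxhat - m1 - xhat * m2)
  list(dx = dx, dg = colSums(dout * xhat), db = colSums(dout))
}

# ---- batch normalization (rows = samples x positions, cols = channels) ----

batchnorm_fwd <- function(x, g, b, training, run_mean, run_var,
                          momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu, "-")
    v <- colMeans(xc^2)
    new_mean <- (1 - momentum) * run_mean + momentum * mu
    new_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean
    v <- run_var
    xc <- sweep(x, 2, mu, "-")
    new_mean <- run_mean
    new_var <- run_var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, invstd, "*")
  list(out = sweep(sweep(xhat, 2, g, "*"), 2, b, "+"),
       xhat = xhat, invstd = invstd, training = training,
       run_mean = new_mean, run_var = new_var)
}

batchnorm_bwd <- function(dout, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dout * xhat)
  db <- colSums(dout)
  dxhat <- sweep(dout, 2, g, "*")
  if (cache$training) {
    n <- nrow(xhat)
    dx <- sweep(dxhat - matrix(colMeans(dxhat), n, ncol(xhat),
                               byrow = TRUE) -
                  xhat * matrix(colMeans(dxhat * xhat), n, ncol(xhat),
                                byrow = TRUE),
                2, cache$invstd, "*")
  } else {
    dx <- sweep(dxhat, 2, cache$invstd, "*")
  }
  list(dx = dx, dg = dg, db = db)
}

# ---- multihead self-attention (Q = K = V = X) ------------------------------

# X: B x T x d array; params: Wq, Wk, Wv, Wo (d x d, no biases).
# Scaled dot-product attention per head, heads concatenated, projected.
attention_fwd <- function(X, params, n_heads) {
  dm <- dim(X)
  B <- dm[1]; T_ <- dm[2]; d <- dm[3]
  if (d %% n_heads != 0) stop_config("model_dim must be divisible by heads")
  dk <- d %/% n_heads
  Xm <- matrix(X, B * T_, d)
  Q <- Xm %*% params$Wq
  K <- Xm %*% params$Wk
  V <- Xm %*% params$Wv
  att <- vector("list", B)       # per-example list of per-head weights
  ctx <- matrix(0, B * T_, d)    # concatenated head outputs
  for (b in seq_len(B)) {
    rows <- b + (seq_len(T_) - 1) * B
    ab <- vector("list", n_heads)
    for (h in seq_len(n_heads)) {
      cols <- (h - 1) * dk + seq_len(dk)
      S <- (Q[rows, cols, drop = FALSE] %*%
              t(K[rows, cols, drop = FALSE])) / sqrt(dk)
      S <- sweep(S, 1, apply(S, 1, max), "-")
      A <- exp(S)
      A <- A / rowSums(A)
      ab[[h]] <- A
      ctx[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
    }
    att[[b]] <- ab
  }
  out <- ctx %*% params$Wo
  list(out = array(out, c(B, T_, d)),
       Xm = Xm, Q = Q, K = K, V = V, ctx = ctx, att = att,
       B = B, T_ = T_, d = d, dk = dk, n_heads = n_heads)
}

attention_bwd <- function(dout, cache, params) {
  B <- cache$B; T_ <- cache$T_; d <- cache$d
  dk <- cache$dk; n_heads <- cache$n_heads
  doutm <- matrix(dout, B * T_, d)
  dWo <- t(cache$ctx) %*% doutm
  dctx <- doutm %*% t(params$Wo)
  dQ <- matrix(0, B * T_, d)
  dK <- matrix(0, B * T_, d)
  dV <- matrix(0, B * T_, d)
  for (b in seq_len(B)) {
    rows <- b + (seq_len(T_) - 1) * B
    for (h in seq_len(n_heads)) {
      cols <- (h - 1) * dk + seq_len(dk)
      A <- cache$att[[b]][[h]]
      dctx_h <- dctx[rows, cols, drop = FALSE]
      Vh <- cache$V[rows, cols, drop = FALSE]
      dA <- dctx_h %*% t(Vh)
      dV[rows, cols] <- t(A) %*% dctx_h
      dS <- A * (dA - rowSums(dA * A))
      dQ[rows, cols] <- (dS %*% cache$K[rows, cols, drop = FALSE]) / sqrt(dk)
      dK[rows, cols] <- (t(dS) %*% cache$Q[rows, cols, drop = FALSE]) /
        sqrt(dk)
    }
  }
  dXm <- dQ %*% t(params$Wq) + dK %*% t(params$Wk) + dV %*% t(params$Wv)
  list(dx = array(dXm, c(B, T_, d)),
       dWq = t(cache$Xm) %*% dQ,
       dWk = t(cache$Xm) %*% dK,
       dWv = t(cache$Xm) %*% dV,
       dWo = dWo)
}

# ---- 1D convolution, kernel 2, stride 1 ------------------------------------

# x: B x T x Cin; params W1, W2 (Cin x Cout), b (Cout).
conv1d_fwd <- function(x, params) {
  dm <- dim(x)
  B <- dm[1]; T_ <- dm[2]; Cin <- dm[3]
  Tout <- T_ - 1
  if (Tout < 1) stop_config("window shorter than the convolution kernel")
  xa <- matrix(x[, 1:Tout, , drop = FALSE], B * Tout, Cin)
  xb <- matrix(x[, 2:T_, , drop = FALSE], B * Tout, Cin)
  out <- sweep(xa %*% params$W1 + xb %*% params$W2, 2, params$b, "+")
  list(out = array(out, c(B, Tout, ncol(params$W1))),
       xa = xa, xb = xb, B = B, T_ = T_, Cin = Cin, Tout = Tout)
}

conv1d_bwd <- function(dout, cache, params) {
  B <- cache$B; T_ <- cache$T_; Cin <- cache$Cin; Tout <- cache$Tout
  Cout <- ncol(params$W1)
  doutm <- matrix(dout, B * Tout, Cout)
  dxa <- doutm %*% t(params$W1)
  dxb <- doutm %*% t(params$W2)
  dx <- array(0, c(B, T_, Cin))
  dx[, 1:Tout, ] <- dx[, 1:Tout, , drop = FALSE] +
    array(dxa, c(B, Tout, Cin))
  dx[, 2:T_, ] <- dx[, 2:T_, , drop = FALSE] +
    array(dxb, c(B, Tout, Cin))
  list(dx = dx,
       dW1 = t(cache$xa) %*% doutm,
       dW2 = t(cache$xb) %*% doutm,
       db = colSums(doutm))
}

# ---- 1D max pooling, width 2, stride 2 -------------------------------------

maxpool1d_fwd <- function(x) {
  dm <- dim(x)
  B <- dm[1]; T_ <- dm[2]; C <- dm[3]
  P <- T_ %/% 2
  if (P < 1) stop_config("window too short to max-pool")
  a <- x[, seq(1, 2 * P, 2), , drop = FALSE]
  b <- x[, seq(2, 2 * P, 2), , drop = FALSE]
  take_a <- a >= b
  list(out = ifelse(take_a, a, b), take_a = take_a,
       B = B, T_ = T_, C = C, P = P)
}

maxpool1d_bwd <- function(dout, cache) {
  dx <- array(0, c(cache$B, cache$T_, cache$C))
  dx[, seq(1, 2 * cache$P, 2), ] <- dout * cache$take_a
  dx[, seq(2, 2 * cache$P, 2), ] <- dout * !cache$take_a
  dx
}

# ---- 2D convolution, kernel (2,2), stride 1 --------------------------------

# x: B x H x W x Cin; params$W: 2 x 2 x Cin x Cout array, b (Cout).
conv2d_fwd <- function(x, params) {
  dm <- dim(x)
  B <- dm[1]; H <- dm[2]; W_ <- dm[3]; Cin <- dm[4]
  Ho <- H - 1; Wo <- W_ - 1
  if (Ho < 1 || Wo < 1) stop_config("input smaller than the 2x2 kernel")
  Cout <- dim(params$W)[4]
  outm <- matrix(0, B * Ho * Wo, Cout)
  slabs <- vector("list", 4)
  k <- 0
  for (dj in 1:2) {
    for (di in 1:2) {
      k <- k + 1
      slab <- matrix(x[, di:(Ho + di - 1), dj:(Wo + dj - 1), ,
                       drop = FALSE], B * Ho * Wo, Cin)
      slabs[[k]] <- slab
      outm <- outm + slab %*% matrix(params$W[di, dj, , ], Cin, Cout)
    }
  }
  outm <- sweep(outm, 2, params$b, "+")
  list(out = array(outm, c(B, Ho, Wo, Cout)), slabs = slabs,
       B = B, H = H, W_ = W_, Cin = Cin, Ho = Ho, Wo = Wo)
}

conv2d_bwd <- function(dout, cache, params) {
  B <- cache$B; H <- cache$H; W_ <- cache$W_
  Cin <- cache$Cin; Ho <- cache$Ho; Wo <- cache$Wo
  Cout <- dim(params$W)[4]
  doutm <- matrix(dout, B * Ho * Wo, Cout)
  dW <- array(0, dim(params$W))
  dx <- array(0, c(B, H, W_, Cin))
  k <- 0
  for (dj in 1:2) {
    for (di in 1:2) {
      k <- k + 1
      dW[di, dj, , ] <- t(cache$slabs[[k]]) %*% doutm
      dslab <- doutm %*% t(matrix(params$W[di, dj, , ], Cin, Cout))
      dx[, di:(Ho + di - 1), dj:(Wo + dj - 1), ] <-
        dx[, di:(Ho + di - 1), dj:(Wo + dj - 1), , drop = FALSE] +
        array(dslab, c(B, Ho, Wo, Cin))
    }
  }
  list(dx = dx, dW = dW, db = colSums(doutm))
}

# ---- 2D max pooling, (2,2), stride 2 ---------------------------------------

maxpool2d_fwd <- function(x) {
  dm <- dim(x)
  B <- dm[1]; H <- dm[2]; W_ <- dm[3]; C <- dm[4]
  Ph <- H %/% 2; Pw <- W_ %/% 2
  if (Ph < 1 || Pw < 1) stop_config("feature map too small to max-pool")
  cells <- list(x[, seq(1, 2 * Ph, 2), seq(1, 2 * Pw, 2), , drop = FALSE],
                x[, seq(2, 2 * Ph, 2), seq(1, 2 * Pw, 2), , drop = FALSE],
                x[, seq(1, 2 * Ph, 2), seq(2, 2 * Pw, 2), , drop = FALSE],
                x[, seq(2, 2 * Ph, 2), seq(2, 2 * Pw, 2), , drop = FALSE])
  out <- cells[[1]]
  which_max <- array(1L, dim(out))
  for (k in 2:4) {
    better <- cells[[k]] > out
    out[better] <- cells[[k]][better]
    which_max[better] <- k
  }
  list(out = out, which_max = which_max,
       B = B, H = H, W_ = W_, C = C, Ph = Ph, Pw = Pw)
}

maxpool2d_bwd <- function(dout, cache) {
  dx <- array(0, c(cache$B, cache$H, cache$W_, cache$C))
  rows <- list(seq(1, 2 * cache$Ph, 2), seq(2, 2 * cache$Ph, 2))
  cols <- list(seq(1, 2 * cache$Pw, 2), seq(2, 2 * cache$Pw, 2))
  sel <- list(c(1, 1), c(2, 1), c(1, 2), c(2, 2))
  for (k in 1:4) {
    mask <- cache$which_max == k
    contrib <- dout * mask
    dx[, rows[[sel[[k]][1]]], cols[[sel[[k]][2]]], ] <-
      dx[, rows[[sel[[k]][1]]], cols[[sel[[k]][2]]], , drop = FALSE] +
      contrib
  }
  dx
}
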