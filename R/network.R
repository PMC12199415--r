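# The two-module predictor architecture. Each module (the carbonylation
# sites prediction module, CSPM, and the ligand interaction sites
# prediction module, LISPM) combines:
#   * a TRF block — three stacked transformer encoder layers with multihead
#     self-attention over the PSSM window (long-distance, protein-level
#     evolutionary features), reading the centre token's representation;
#   * a CNN block — two-layer kernel-2 CNN-1D and 2x2-kernel CNN-2D branches
#     over the physicochemical window (short-distance, segment-level
#     features), each conv followed by batch norm, ReLU and max pooling,
#     with dropout on the flattened outputs at training time.
# The CSPM additionally consumes a 10-dimensional reduction of the centre
# residue's language-model embedding (two-layer FCNN reducer). The two
# modules' feature spaces are concatenated into a four-layer fully
# connected fusion head with a sigmoid output. An `attention = FALSE`
# variant replaces the CNN/TRF feature extractors with plain FCNN units
# (the architecture's ablation baseline).

#' Network configuration
#'
#' @param window_size odd segment window length (positions fed to both the
#'   physicochemical and PSSM channels).
#' @param model_dim transformer model dimension (divisible by `n_heads`).
#' @param n_heads number of attention heads.
#' @param n_trf_layers number of stacked transformer layers (default 3).
#' @param conv_channels channels of the two CNN-1D layers.
#' @param conv2d_channels channels of the two CNN-2D layers.
#' @param reducer_hidden hidden width of the embedding reducer.
#' @param reducer_out reducer output dimension (default 10).
#' @param embedding_dim provider embedding dimension.
#' @param fusion_dims hidden widths of the four-layer fusion head (three
#'   hidden layers plus the sigmoid output layer).
#' @param dropout dropout rate on flattened CNN features during training.
#' @param attention `FALSE` swaps the CNN/TRF extractors for FCNN units.
#' @param fcnn_hidden hidden widths of the FCNN variant extractor.
#' @param seed integer seed for weight initialisation.
#' @return a `network_config` list with derived feature dimensions.
#' @export
network_config <- function(window_size = 13L, model_dim = 64L, n_heads = 4L,
                           n_trf_layers = 3L,
                           conv_channels = c(16L, 16L),
                           conv2d_channels = c(8L, 8L),
                           reducer_hidden = 32L, reducer_out = 10L,
                           embedding_dim = 32L,
                           fusion_dims = c(256L, 64L, 16L),
                           dropout = 0.5, attention = TRUE,
                           fcnn_hidden = c(64L, 32L), seed = 1L) {
  if (window_size %% 2 == 0) stop_config("window_size must be odd")
  if (model_dim %% n_heads != 0) {
    stop_config("model_dim must be divisible by n_heads")
  }
  # convolution arithmetic: kernel 2 / stride 1 shrinks by 1, pooling
  # halves (1D pooling is skipped when the extent is already 1; 2D pooling
  # is applied only when both extents are >= 2, mirroring the forward pass)
  shrink1 <- function(n) {
    n <- n - 1L
    if (n < 1) stop_config("window_size ", window_size,
                           " too short for the CNN block")
    if (n >= 2) n %/% 2L else n
  }
  shrink2 <- function(hw) {
    hw <- hw - 1L
    if (any(hw < 1)) stop_config("window_size ", window_size,
                                 " too short for the CNN block")
    if (all(hw >= 2)) hw %/% 2L else hw
  }
  t1 <- shrink1(window_size); t2 <- shrink1(t1)
  hw <- shrink2(shrink2(c(window_size, 10L)))
  flat1 <- t2 * conv_channels[2]
  flat2 <- hw[1] * hw[2] * conv2d_channels[2]
  feat_dim <- if (attention) model_dim + flat1 + flat2 else fcnn_hidden[2]
  structure(list(window_size = as.integer(window_size),
                 model_dim = as.integer(model_dim),
                 n_heads = as.integer(n_heads),
                 n_trf_layers = as.integer(n_trf_layers),
                 conv_channels = as.integer(conv_channels),
                 conv2d_channels = as.integer(conv2d_channels),
                 reducer_hidden = as.integer(reducer_hidden),
                 reducer_out = as.integer(reducer_out),
                 embedding_dim = as.integer(embedding_dim),
                 fusion_dims = as.integer(fusion_dims),
                 dropout = dropout, attention = isTRUE(attention),
                 fcnn_hidden = as.integer(fcnn_hidden),
                 flat1 = flat1, flat2 = flat2, feat_dim = feat_dim,
                 seed = as.integer(seed)),
            class = "network_config")
}

# fan-in uniform initialisation
init_mat <- function(n_in, n_out) {
  s <- sqrt(1 / n_in)
  matrix(stats::runif(n_in * n_out, -s, s), n_in, n_out)
}

init_module <- function(cfg) {
  d <- cfg$model_dim
  T_ <- cfg$window_size
  if (!cfg$attention) {
    n_in <- T_ * 30L  # flattened physicochemical (10) + PSSM (20) channels
    return(list(W1 = init_mat(n_in, cfg$fcnn_hidden[1]),
                b1 = numeric(cfg$fcnn_hidden[1]),
                W2 = init_mat(cfg$fcnn_hidden[1], cfg$fcnn_hidden[2]),
                b2 = numeric(cfg$fcnn_hidden[2])))
  }
  layer <- function() {
    list(att = list(Wq = init_mat(d, d), Wk = init_mat(d, d),
                    Wv = init_mat(d, d), Wo = init_mat(d, d)),
         ln1_g = rep(1, d), ln1_b = numeric(d),
         ffW1 = init_mat(d, 4 * d), ffb1 = numeric(4 * d),
         ffW2 = init_mat(4 * d, d), ffb2 = numeric(d),
         ln2_g = rep(1, d), ln2_b = numeric(d))
  }
  c1 <- cfg$conv_channels
  c2 <- cfg$conv2d_channels
  list(trf = list(proj = init_mat(20, d),
                  pos = matrix(stats::runif(T_ * d, -0.1, 0.1), T_, d),
                  layers = lapply(seq_len(cfg$n_trf_layers),
                                  function(i) layer())),
       c1 = list(l1 = list(W1 = init_mat(10, c1[1]),
                           W2 = init_mat(10, c1[1]), b = numeric(c1[1]),
                           g = rep(1, c1[1]), beta = numeric(c1[1])),
                 l2 = list(W1 = init_mat(c1[1], c1[2]),
                           W2 = init_mat(c1[1], c1[2]), b = numeric(c1[2]),
                           g = rep(1, c1[2]), beta = numeric(c1[2]))),
       c2 = list(l1 = list(W = array(stats::runif(2 * 2 * 1 * c2[1],
                                                  -0.5, 0.5),
                                     c(2, 2, 1, c2[1])),
                           b = numeric(c2[1]),
                           g = rep(1, c2[1]), beta = numeric(c2[1])),
                 l2 = list(W = array(stats::runif(2 * 2 * c2[1] * c2[2],
                                                  -sqrt(1 / (4 * c2[1])),
                                                  sqrt(1 / (4 * c2[1]))),
                                     c(2, 2, c2[1], c2[2])),
                           b = numeric(c2[2]),
                           g = rep(1, c2[2]), beta = numeric(c2[2]))))
}

init_bn_module <- function(cfg) {
  if (!cfg$attention) return(list())
  list(c1 = list(l1 = list(mean = numeric(cfg$conv_channels[1]),
                           var = rep(1, cfg$conv_channels[1])),
                 l2 = list(mean = numeric(cfg$conv_channels[2]),
                           var = rep(1, cfg$conv_channels[2]))),
       c2 = list(l1 = list(mean = numeric(cfg$conv2d_channels[1]),
                           var = rep(1, cfg$conv2d_channels[1])),
                 l2 = list(mean = numeric(cfg$conv2d_channels[2]),
                           var = rep(1, cfg$conv2d_channels[2]))))
}

#' Initialise the full network state
#'
#' @param config a [network_config].
#' @return a `network_state`: parameter tree (`params` with `lispm`,
#'   `cspm`, `reducer`, `lispm_head`, `cspm_head`, `fusion`), batch-norm
#'   running statistics (`bn`), the config, and the `freeze_lispm` flag.
#' @export
init_network <- function(config) {
  with_seed(derive_seed(config$seed, "init"), {
    fd <- config$feat_dim
    ro <- config$reducer_out
    fusion_in <- fd + ro + fd
    dims <- c(fusion_in, config$fusion_dims, 1L)
    fusion <- list()
    for (k in seq_len(length(dims) - 1)) {
      fusion[[paste0("W", k)]] <- init_mat(dims[k], dims[k + 1])
      fusion[[paste0("b", k)]] <- numeric(dims[k + 1])
    }
    params <- list(
      lispm = init_module(config),
      cspm = init_module(config),
      reducer = list(W1 = init_mat(config$embedding_dim,
                                   config$reducer_hidden),
                     b1 = numeric(config$reducer_hidden),
                     W2 = init_mat(config$reducer_hidden, ro),
                     b2 = numeric(ro)),
      lispm_head = list(W = init_mat(fd, 1), b = numeric(1)),
      cspm_head = list(W = init_mat(fd + ro, 1), b = numeric(1)),
      fusion = fusion)
    structure(list(params = params,
                   bn = list(lispm = init_bn_module(config),
                             cspm = init_bn_module(config)),
                   config = config,
                   freeze_lispm = FALSE,
                   version = 1L),
              class = "network_state")
  })
}

# ---- module forward / backward ---------------------------------------------

module_fwd <- function(params, bn, cfg, phys, pssm, training, drop_seed) {
  B <- dim(phys)[1]
  T_ <- cfg$window_size
  cache <- list()
  if (!cfg$attention) {
    xin <- cbind(matrix(phys, B, T_ * 10), matrix(pssm, B, T_ * 20))
    l1 <- linear_fwd(xin, params$W1, params$b1)
    r1 <- relu_fwd(l1$out)
    l2 <- linear_fwd(r1$out, params$W2, params$b2)
    r2 <- relu_fwd(l2$out)
    return(list(features = r2$out,
                cache = list(fcnn = list(l1 = l1, r1 = r1, l2 = l2,
                                         r2 = r2)),
                bn_new = bn))
  }
  d <- cfg$model_dim
  # TRF branch over the PSSM window
  pssm_m <- matrix(pssm, B * T_, 20)
  Xm <- pssm_m %*% params$trf$proj
  Xm <- Xm + params$trf$pos[rep(seq_len(T_), each = B), , drop = FALSE]
  X <- array(Xm, c(B, T_, d))
  trf_caches <- vector("list", length(params$trf$layers))
  for (li in seq_along(params$trf$layers)) {
    lp <- params$trf$layers[[li]]
    at <- attention_fwd(X, lp$att, cfg$n_heads)
    x1m <- matrix(X + at$out, B * T_, d)
    ln1 <- layernorm_fwd(x1m, lp$ln1_g, lp$ln1_b)
    ff1 <- linear_fwd(ln1$out, lp$ffW1, lp$ffb1)
    ffr <- relu_fwd(ff1$out)
    ff2 <- linear_fwd(ffr$out, lp$ffW2, lp$ffb2)
    ln2 <- layernorm_fwd(ln1$out + ff2$out, lp$ln2_g, lp$ln2_b)
    trf_caches[[li]] <- list(at = at, ln1 = ln1, ff1 = ff1, ffr = ffr,
                             ff2 = ff2, ln2 = ln2)
    X <- array(ln2$out, c(B, T_, d))
  }
  t_center <- (T_ + 1L) %/% 2L
  trf_feat <- X[, t_center, , drop = TRUE]
  if (B == 1) trf_feat <- matrix(trf_feat, 1, d)

  # CNN-1D branch over the physicochemical window
  run_conv1 <- function(x, lp, bs, tag) {
    cv <- conv1d_fwd(x, lp)
    sh <- dim(cv$out)
    bnf <- batchnorm_fwd(matrix(cv$out, sh[1] * sh[2], sh[3]), lp$g,
                         lp$beta, training, bs$mean, bs$var)
    rl <- relu_fwd(bnf$out)
    y <- array(rl$out, sh)
    pooled <- sh[2] >= 2
    pl <- if (pooled) maxpool1d_fwd(y) else list(out = y)
    list(out = pl$out, cv = cv, bnf = bnf, rl = rl, pl = pl,
         pooled = pooled, sh = sh)
  }
  s1 <- run_conv1(phys, params$c1$l1, bn$c1$l1, "c1l1")
  s2 <- run_conv1(s1$out, params$c1$l2, bn$c1$l2, "c1l2")
  flat1 <- matrix(s2$out, B, length(s2$out) / B)
  dr1 <- dropout_fwd(flat1, cfg$dropout, training,
                     derive_seed(drop_seed, "c1"))

  # CNN-2D branch, physicochemical window as a 1-channel image
  run_conv2 <- function(x, lp, bs) {
    cv <- conv2d_fwd(x, lp)
    sh <- dim(cv$out)
    bnf <- batchnorm_fwd(matrix(cv$out, prod(sh[1:3]), sh[4]), lp$g,
                         lp$beta, training, bs$mean, bs$var)
    rl <- relu_fwd(bnf$out)
    y <- array(rl$out, sh)
    pooled <- sh[2] >= 2 && sh[3] >= 2
    pl <- if (pooled) maxpool2d_fwd(y) else list(out = y)
    list(out = pl$out, cv = cv, bnf = bnf, rl = rl, pl = pl,
         pooled = pooled, sh = sh)
  }
  x2 <- array(phys, c(B, T_, 10, 1))
  q1 <- run_conv2(x2, params$c2$l1, bn$c2$l1)
  q2 <- run_conv2(q1$out, params$c2$l2, bn$c2$l2)
  flat2 <- matrix(q2$out, B, length(q2$out) / B)
  dr2 <- dropout_fwd(flat2, cfg$dropout, training,
                     derive_seed(drop_seed, "c2"))

  bn_new <- list(c1 = list(l1 = list(mean = s1$bnf$run_mean,
                                     var = s1$bnf$run_var),
                           l2 = list(mean = s2$bnf$run_mean,
                                     var = s2$bnf$run_var)),
                 c2 = list(l1 = list(mean = q1$bnf$run_mean,
                                     var = q1$bnf$run_var),
                           l2 = list(mean = q2$bnf$run_mean,
                                     var = q2$bnf$run_var)))
  list(features = cbind(trf_feat, dr1$out, dr2$out),
       cache = list(trf = trf_caches, s1 = s1, s2 = s2, q1 = q1, q2 = q2,
                    dr1 = dr1, dr2 = dr2, B = B, t_center = t_center,
                    pssm_m = pssm_m),
       bn_new = bn_new)
}

module_bwd <- function(dfeat, fw, params, cfg) {
  B <- dim(dfeat)[1]
  if (!cfg$attention) {
    cc <- fw$cache$fcnn
    d2 <- relu_bwd(dfeat, cc$r2)
    g2 <- linear_bwd(d2, cc$l2, params$W2)
    d1 <- relu_bwd(g2$dx, cc$r1)
    g1 <- linear_bwd(d1, cc$l1, params$W1)
    return(list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db))
  }
  d <- cfg$model_dim
  cc <- fw$cache
  d_trf <- dfeat[, seq_len(d), drop = FALSE]
  dflat1 <- dfeat[, d + seq_len(cfg$flat1), drop = FALSE]
  dflat2 <- dfeat[, d + cfg$flat1 + seq_len(cfg$flat2), drop = FALSE]

  # TRF backward
  T_ <- cfg$window_size
  dX <- array(0, c(B, T_, d))
  dX[, cc$t_center, ] <- d_trf
  grads_layers <- vector("list", length(params$trf$layers))
  for (li in rev(seq_along(params$trf$layers))) {
    lp <- params$trf$layers[[li]]
    tc <- cc$trf[[li]]
    dln2 <- layernorm_bwd(matrix(dX, B * T_, d), tc$ln2, lp$ln2_g)
    dff2 <- linear_bwd(dln2$dx, tc$ff2, lp$ffW2)
    dffr <- relu_bwd(dff2$dx, tc$ffr)
    dff1 <- linear_bwd(dffr, tc$ff1, lp$ffW1)
    dln1_in <- dln2$dx + dff1$dx     # residual around the feedforward
    dln1 <- layernorm_bwd(dln1_in, tc$ln1, lp$ln1_g)
    datt_out <- array(dln1$dx, c(B, T_, d))
    datt <- attention_bwd(datt_out, tc$at, lp$att)
    dX <- datt$dx + datt_out         # residual around the attention
    grads_layers[[li]] <- list(
      att = list(Wq = datt$dWq, Wk = datt$dWk, Wv = datt$dWv,
                 Wo = datt$dWo),
      ln1_g = dln1$dg, ln1_b = dln1$db,
      ffW1 = dff1$dW, ffb1 = dff1$db,
      ffW2 = dff2$dW, ffb2 = dff2$db,
      ln2_g = dln2$dg, ln2_b = dln2$db)
  }
  dXm <- matrix(dX, B * T_, d)
  dproj <- t(cc$pssm_m) %*% dXm
  dpos <- rowsum(dXm, rep(seq_len(T_), each = B))

  # CNN-1D backward
  bwd_conv1 <- function(dout, st, lp) {
    dpool <- if (st$pooled) maxpool1d_bwd(dout, st$pl) else dout
    sh <- st$sh
    drl <- relu_bwd(matrix(dpool, sh[1] * sh[2], sh[3]), st$rl)
    dbn <- batchnorm_bwd(drl, st$bnf, lp$g)
    dcv <- conv1d_bwd(array(dbn$dx, sh), st$cv, lp)
    list(dx = dcv$dx,
         grads = list(W1 = dcv$dW1, W2 = dcv$dW2, b = dcv$db,
                      g = dbn$dg, beta = dbn$db))
  }
  ddr1 <- dropout_bwd(dflat1, cc$dr1)
  d_s2 <- array(ddr1, dim(cc$s2$out))
  b2_ <- bwd_conv1(d_s2, cc$s2, params$c1$l2)
  b1_ <- bwd_conv1(b2_$dx, cc$s1, params$c1$l1)

  # CNN-2D backward
  bwd_conv2 <- function(dout, st, lp) {
    dpool <- if (st$pooled) maxpool2d_bwd(dout, st$pl) else dout
    sh <- st$sh
    drl <- relu_bwd(matrix(dpool, prod(sh[1:3]), sh[4]), st$rl)
    dbn <- batchnorm_bwd(drl, st$bnf, lp$g)
    dcv <- conv2d_bwd(array(dbn$dx, sh), st$cv, lp)
    list(dx = dcv$dx,
         grads = list(W = dcv$dW, b = dcv$db, g = dbn$dg, beta = dbn$db))
  }
  ddr2 <- dropout_bwd(dflat2, cc$dr2)
  d_q2 <- array(ddr2, dim(cc$q2$out))
  p2_ <- bwd_conv2(d_q2, cc$q2, params$c2$l2)
  p1_ <- bwd_conv2(p2_$dx, cc$q1, params$c2$l1)

  list(trf = list(proj = dproj, pos = dpos, layers = grads_layers),
       c1 = list(l1 = b1_$grads, l2 = b2_$grads),
       c2 = list(l1 = p1_$grads, l2 = p2_$grads))
}

# ---- full network ----------------------------------------------------------

#' Forward pass of the network
#'
#' @param state a `network_state`.
#' @param batch feature bundle list with arrays `physchem` (B x T x 10),
#'   `pssm` (B x T x 20) and `embedding` (B x E).
#' @param mode `"lispm"` (ligand module and its own head), `"cspm"`
#'   (carbonylation module, including the reduced embedding, with its own
#'   head) or `"fused"` (both modules' features through the fusion head).
#' @param training logical; enables dropout and batch-statistics batch norm.
#' @param drop_seed seed for the dropout masks (ignored at inference).
#' @return a list with `p` (propensities in (0,1)), `cache` (for backprop)
#'   and `bn_new` (updated running statistics when training).
#' @export
forward_network <- function(state, batch, mode = c("fused", "lispm", "cspm"),
                            training = FALSE, drop_seed = 1L) {
  mode <- match.arg(mode)
  cfg <- state$config
  pr <- state$params
  B <- dim(batch$physchem)[1]
  cache <- list(mode = mode, B = B)
  bn_new <- state$bn
  # a frozen LISPM always runs in inference mode: its features must not
  # drift with batch composition (eval batch norm) or dropout noise
  lispm_training <- training && !isTRUE(state$freeze_lispm)

  if (mode %in% c("lispm")) {
    fl <- module_fwd(pr$lispm, state$bn$lispm, cfg, batch$physchem,
                     batch$pssm, lispm_training,
                     derive_seed(drop_seed, "lispm"))
    bn_new$lispm <- fl$bn_new
    z <- sweep(fl$features %*% pr$lispm_head$W, 2, pr$lispm_head$b, "+")
    cache$fl <- fl
  } else {
    fc <- module_fwd(pr$cspm, state$bn$cspm, cfg, batch$physchem,
                     batch$pssm, training, derive_seed(drop_seed, "cspm"))
    bn_new$cspm <- fc$bn_new
    e1 <- linear_fwd(batch$embedding, pr$reducer$W1, pr$reducer$b1)
    er <- relu_fwd(e1$out)
    e2 <- linear_fwd(er$out, pr$reducer$W2, pr$reducer$b2)
    cspm_feat <- cbind(fc$features, e2$out)
    cache$fc <- fc
    cache$e1 <- e1
    cache$er <- er
    cache$e2 <- e2
    if (mode == "cspm") {
      z <- sweep(cspm_feat %*% pr$cspm_head$W, 2, pr$cspm_head$b, "+")
    } else {
      fl <- module_fwd(pr$lispm, state$bn$lispm, cfg, batch$physchem,
                       batch$pssm, lispm_training,
                       derive_seed(drop_seed, "lispm"))
      bn_new$lispm <- fl$bn_new
      cache$fl <- fl
      h <- cbind(cspm_feat, fl$features)
      fus <- list()
      n_layers <- length(pr$fusion) / 2
      for (k in seq_len(n_layers)) {
        lk <- linear_fwd(h, pr$fusion[[paste0("W", k)]],
                         pr$fusion[[paste0("b", k)]])
        if (k < n_layers) {
          rk <- relu_fwd(lk$out)
          h <- rk$out
          fus[[k]] <- list(lin = lk, relu = rk)
        } else {
          fus[[k]] <- list(lin = lk)
          z <- lk$out
        }
      }
      cache$fus <- fus
    }
  }
  p <- sigmoid(z)
  cache$p <- p
  list(p = as.numeric(p), cache = cache, bn_new = bn_new)
}

# Backward pass from dL/dz (gradient at the pre-sigmoid logit, B x 1).
# Returns a gradient tree mirroring state$params (zero where a component
# was not used by the mode, and for the LISPM when it is frozen — its
# backward pass is skipped entirely).
network_bwd <- function(state, fw, dz) {
  cfg <- state$config
  pr <- state$params
  grads <- tree_zeros(pr)
  cache <- fw$cache
  dz <- matrix(dz, ncol = 1)

  if (cache$mode == "lispm") {
    grads$lispm_head$W <- t(cache$fl$features) %*% dz
    grads$lispm_head$b <- colSums(dz)
    dfeat <- dz %*% t(pr$lispm_head$W)
    grads$lispm <- module_bwd(dfeat, cache$fl, pr$lispm, cfg)
    return(grads)
  }

  fd <- cfg$feat_dim
  ro <- cfg$reducer_out
  if (cache$mode == "cspm") {
    cspm_feat <- cbind(cache$fc$features, cache$e2$out)
    grads$cspm_head$W <- t(cspm_feat) %*% dz
    grads$cspm_head$b <- colSums(dz)
    dcat <- dz %*% t(pr$cspm_head$W)
  } else {
    n_layers <- length(pr$fusion) / 2
    dh <- dz
    for (k in rev(seq_len(n_layers))) {
      lk <- cache$fus[[k]]$lin
      if (k < n_layers) dh <- relu_bwd(dh, cache$fus[[k]]$relu)
      g <- linear_bwd(dh, lk, pr$fusion[[paste0("W", k)]])
      grads$fusion[[paste0("W", k)]] <- g$dW
      grads$fusion[[paste0("b", k)]] <- g$db
      dh <- g$dx
    }
    dcat <- dh[, seq_len(fd + ro), drop = FALSE]
    if (!isTRUE(state$freeze_lispm)) {
      dlispm_feat <- dh[, fd + ro + seq_len(fd), drop = FALSE]
      grads$lispm <- module_bwd(dlispm_feat, cache$fl, pr$lispm, cfg)
    }
  }
  dcspm_feat <- dcat[, seq_len(fd), drop = FALSE]
  dred <- dcat[, fd + seq_len(ro), drop = FALSE]
  grads$cspm <- module_bwd(dcspm_feat, cache$fc, pr$cspm, cfg)
  g2 <- linear_bwd(dred, cache$e2, pr$reducer$W2)
  grads$reducer$W2 <- g2$dW
  grads$reducer$b2 <- g2$db
  dr1 <- relu_bwd(g2$dx, cache$er)
  g1 <- linear_bwd(dr1, cache$e1, pr$reducer$W1)
  grads$reducer$W1 <- g1$dW
  grads$reducer$b1 <- g1$db
  grads
}

#' Predict propensities for a feature bundle
#'
#' Inference is deterministic: dropout is disabled and batch norm uses its
#' running statistics.
#'
#' @param state a trained `network_state`.
#' @param bundles feature bundle list (see [build_feature_bundles()]).
#' @param mode forward mode (default `"fused"`).
#' @param batch_size examples per forward batch.
#' @return numeric vector of propensities in (0, 1).
#' @export
predict_network <- function(state, bundles, mode = "fused",
                            batch_size = 512L) {
  n <- dim(bundles$physchem)[1]
  if (n == 0) return(numeric(0))
  out <- numeric(n)
  starts <- seq(1, n, by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1, n)
    sub <- list(physchem = bundles$physchem[idx, , , drop = FALSE],
                pssm = bundles$pssm[idx, , , drop = FALSE],
                embedding = bundles$embedding[idx, , drop = FALSE])
    out[idx] <- forward_network(state, sub, mode, training = FALSE)$p
  }
  out
}

#' Save / load a network checkpoint
#'
#' The checkpoint embeds the configuration, parameters, batch-norm
#' statistics and a format version in a single file.
#'
#' @param state a `network_state`.
#' @param path checkpoint path.
#' @export
save_checkpoint <- function(state, path) {
  saveRDS(unclass(state), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$version)) stop_data("not a recognised checkpoint file")
  class(obj$config) <- "network_config"
  structure(obj, class = "network_state")
}
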