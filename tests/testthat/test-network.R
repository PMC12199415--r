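test_that("multihead attention matches a brute-force oracle", {
  set.seed(2)
  T_ <- 3; d <- 4; h <- 2; dk <- d / h
  params <- list(Wq = matrix(rnorm(d * d), d, d),
                 Wk = matrix(rnorm(d * d), d, d),
                 Wv = matrix(rnorm(d * d), d, d),
                 Wo = matrix(rnorm(d * d), d, d))
  X <- array(rnorm(2 * T_ * d), c(2, T_, d))
  out <- selcarb:::attention_fwd(X, params, h)$out

  for (b in 1:2) {
    Xb <- matrix(X[b, , ], T_, d)
    Q <- Xb %*% params$Wq
    K <- Xb %*% params$Wk
    V <- Xb %*% params$Wv
    ctx <- matrix(0, T_, d)
    for (head in 1:h) {
      cols <- (head - 1) * dk + seq_len(dk)
      S <- Q[, cols] %*% t(K[, cols]) / sqrt(dk)
      A <- exp(S) / rowSums(exp(S))
      expect_equal(rowSums(A), rep(1, T_))  # softmax rows normalise
      ctx[, cols] <- A %*% V[, cols]
    }
    expect_equal(matrix(out[b, , ], T_, d), ctx %*% params$Wo,
                 tolerance = 1e-12)
  }

  # single token: softmax over one key is 1, so out = X Wv Wo
  X1 <- array(rnorm(1 * 1 * d), c(1, 1, d))
  out1 <- selcarb:::attention_fwd(X1, params, h)$out
  expect_equal(matrix(out1[1, , ], 1, d),
               matrix(X1[1, , ], 1, d) %*% params$Wv %*% params$Wo,
               tolerance = 1e-12)
})

test_that("convolution arithmetic matches the closed form", {
  set.seed(4)
  # kernel 2, stride 1 on length 6: outputs length 5, pooled to 2
  x <- array(rnorm(3 * 6 * 2), c(3, 6, 2))
  params <- list(W1 = matrix(rnorm(2 * 4), 2, 4),
                 W2 = matrix(rnorm(2 * 4), 2, 4), b = rnorm(4))
  cv <- selcarb:::conv1d_fwd(x, params)
  expect_equal(dim(cv$out), c(3, 5, 4))
  expect_equal(cv$out[2, 3, ],
               as.numeric(x[2, 3, ] %*% params$W1 +
                            x[2, 4, ] %*% params$W2 + params$b))
  pooled <- selcarb:::maxpool1d_fwd(cv$out)
  expect_equal(dim(pooled$out), c(3, 2, 4))
  expect_equal(pooled$out[1, 1, 2], max(cv$out[1, 1:2, 2]))

  # ReLU definition
  expect_equal(selcarb:::relu_fwd(c(-3, 2))$out, c(0, 2))

  # all-zero input with zero bias stays zero through conv/BN/ReLU/pool
  z <- array(0, c(2, 6, 2))
  pz <- list(W1 = matrix(rnorm(8), 2, 4), W2 = matrix(rnorm(8), 2, 4),
             b = rep(0, 4))
  expect_true(all(selcarb:::conv1d_fwd(z, pz)$out == 0))
})

test_that("forward output is a propensity for every supported window", {
  for (w in c(5L, 13L, 17L, 21L, 27L)) {
    cfg <- tiny_net_config(window_size = w, seed = 3)
    state <- init_network(cfg)
    bundles <- random_bundles(4, window_size = w, seed = w)
    for (mode in c("fused", "lispm", "cspm")) {
      p <- forward_network(state, bundles, mode)$p
      expect_length(p, 4)
      expect_true(all(p > 0 & p < 1),
                  label = sprintf("window %d mode %s", w, mode))
    }
  }
  expect_error(network_config(window_size = 12L),
               class = "selcarb_config_error")
  expect_error(network_config(model_dim = 15L, n_heads = 4L),
               class = "selcarb_config_error")
})

test_that("zeroed final layers give propensity exactly 0.5", {
  cfg <- tiny_net_config(seed = 1)
  state <- init_network(cfg)
  n_fusion <- length(state$params$fusion) / 2
  state$params$fusion[[paste0("W", n_fusion)]][] <- 0
  state$params$fusion[[paste0("b", n_fusion)]][] <- 0
  bundles <- random_bundles(3, seed = 2)
  expect_equal(forward_network(state, bundles, "fused")$p, rep(0.5, 3))
})

test_that("inference is deterministic; training dropout is seeded", {
  cfg <- tiny_net_config(seed = 6)
  state <- init_network(cfg)
  bundles <- random_bundles(5, seed = 3)
  p1 <- forward_network(state, bundles, "fused", training = FALSE)$p
  p2 <- forward_network(state, bundles, "fused", training = FALSE)$p
  expect_identical(p1, p2)
  t1 <- forward_network(state, bundles, "fused", TRUE, drop_seed = 9)$p
  t2 <- forward_network(state, bundles, "fused", TRUE, drop_seed = 9)$p
  expect_identical(t1, t2)
})

test_that("analytic gradients match finite differences on a tiny net", {
  cfg <- network_config(window_size = 7L, model_dim = 8L, n_heads = 2L,
                        n_trf_layers = 2L, conv_channels = c(3L, 3L),
                        conv2d_channels = c(2L, 2L), reducer_hidden = 5L,
                        embedding_dim = 6L, fusion_dims = c(7L, 5L, 3L),
                        dropout = 0, seed = 3)
  state <- init_network(cfg)
  set.seed(42)
  batch <- random_bundles(3, window_size = 7L, emb_dim = 6L, seed = 5,
                          labels = c("carbonylation", "ligand",
                                     "nonfunctional"))
  lp <- loss_params(2, 1.5, 3)
  loss_of <- function(st) {
    fw <- forward_network(st, batch, "fused", training = TRUE,
                          drop_seed = 7)
    custom_loss(fw$p, batch$labels, lp)
  }
  fw <- forward_network(state, batch, "fused", training = TRUE,
                        drop_seed = 7)
  gp <- selcarb:::custom_loss_grad_p(fw$p, batch$labels, lp)
  dz <- gp * fw$p * (1 - fw$p) / 3
  grads <- selcarb:::network_bwd(state, fw, dz)
  flat_g <- selcarb:::tree_flatten(grads)
  flat_p <- selcarb:::tree_flatten(state$params)
  idx <- sort(sample(length(flat_p), 60))
  eps <- 1e-5
  for (k in idx) {
    pp <- flat_p
    pp[k] <- pp[k] + eps
    sp <- state
    sp$params <- selcarb:::tree_unflatten(state$params, pp)
    lp_ <- loss_of(sp)
    pp[k] <- pp[k] - 2 * eps
    sp$params <- selcarb:::tree_unflatten(state$params, pp)
    lm_ <- loss_of(sp)
    num <- (lp_ - lm_) / (2 * eps)
    expect_lt(abs(num - flat_g[k]) / max(abs(num), abs(flat_g[k]), 1e-6),
              1e-4)
  }
})

test_that("checkpoints round-trip through disk", {
  cfg <- tiny_net_config(seed = 8)
  state <- init_network(cfg)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(state, f)
  back <- load_checkpoint(f)
  bundles <- random_bundles(3, seed = 1)
  expect_identical(forward_network(state, bundles, "fused")$p,
                   forward_network(back, bundles, "fused")$p)
})
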