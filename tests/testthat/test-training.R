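test_that("the customised loss matches its closed form", {
  # ligand label, r = 0, beta = 2, p = 0.5 -> 2 * (-log 0.5)
  expect_equal(custom_loss(0.5, "ligand", loss_params(0, 1, 2)),
               2 * log(2), tolerance = 1e-12)
  # a confident correct positive contributes (almost) nothing
  expect_lt(custom_loss(1 - 1e-8, "carbonylation", loss_params(2, 1, 1)),
            1e-6)
  expect_error(loss_params(-1, 1, 1), class = "selcarb_config_error")
})

test_that("the loss matches symbolic evaluation on random tuples", {
  set.seed(19)
  n <- 1000
  p <- runif(n, 0.01, 0.99)
  labels <- sample(c("carbonylation", "nonfunctional", "ligand"), n, TRUE)
  r <- runif(n, 0, 4)
  alpha <- runif(n, 0, 5)
  beta <- runif(n, 0, 15)
  for (i in seq_len(n)) {
    got <- custom_loss(p[i], labels[i], loss_params(r[i], alpha[i],
                                                    beta[i]))
    lc <- labels[i] == "carbonylation"
    ln <- labels[i] == "nonfunctional"
    li <- labels[i] == "ligand"
    want <- -(1 - p[i])^r[i] * lc * log(p[i]) -
      alpha[i] * p[i]^r[i] * ln * log(1 - p[i]) -
      beta[i] * p[i]^r[i] * li * log(1 - p[i])
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("with r=0, alpha=beta=1 the loss is binary cross-entropy", {
  set.seed(8)
  p <- runif(200, 0.01, 0.99)
  labels <- sample(c("carbonylation", "nonfunctional", "ligand"), 200,
                   TRUE)
  y <- as.numeric(labels == "carbonylation")
  bce <- -(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(custom_loss(p, labels, loss_params(0, 1, 1),
                           reduce = FALSE),
               bce, tolerance = 1e-12)
})

test_that("raising beta strictly raises the loss on scored ligand sites", {
  p <- seq(0.05, 0.95, by = 0.1)
  l_low <- custom_loss(p, rep("ligand", length(p)), loss_params(2, 1, 1),
                       reduce = FALSE)
  l_high <- custom_loss(p, rep("ligand", length(p)), loss_params(2, 1, 8),
                        reduce = FALSE)
  expect_true(all(l_high > l_low))
  # and leaves carbonylation terms untouched
  expect_equal(custom_loss(p, rep("carbonylation", length(p)),
                           loss_params(2, 1, 8), reduce = FALSE),
               custom_loss(p, rep("carbonylation", length(p)),
                           loss_params(2, 1, 1), reduce = FALSE))
})

test_that("loss gradients match finite differences", {
  set.seed(31)
  for (i in 1:50) {
    p <- runif(1, 0.05, 0.95)
    label <- sample(c("carbonylation", "nonfunctional", "ligand"), 1)
    lp <- loss_params(sample(c(0, 1, 2, 3), 1), runif(1, 0, 4),
                      runif(1, 0, 12))
    eps <- 1e-6
    num <- (custom_loss(p + eps, label, lp) -
              custom_loss(p - eps, label, lp)) / (2 * eps)
    ana <- selcarb:::custom_loss_grad_p(p, label, lp)
    expect_equal(ana, num, tolerance = 1e-5)
  }
})

test_that("the grid-cell selection rule reproduces hand-computed picks", {
  grid <- data.frame(alpha = c(1, 1, 2, 2),
                     beta = c(0, 12, 0, 12),
                     auroc = c(0.90, 0.85, 0.88, 0.86),
                     aucpc = c(0.30, 0.10, 0.115, 0.12))
  # minimum AUCPC 0.10; admissible band <= 0.12: rows 2-4; best AUROC 0.88
  sel <- select_loss_cell(grid, band = 0.02)
  expect_equal(sel$alpha, 2)
  expect_equal(sel$beta, 0)
  # the max-AUROC cell (row 1) violates the band and is passed over
  expect_false(sel$auroc == max(grid$auroc))
  # invariance to enumeration order
  sel2 <- select_loss_cell(grid[c(3, 1, 4, 2), ], band = 0.02)
  expect_equal(sel2$alpha, sel$alpha)
  expect_equal(sel2$beta, sel$beta)
  # single cell selects itself
  expect_equal(select_loss_cell(grid[2, , drop = FALSE])$beta, 12)
})

test_that("training is seeded-deterministic and honours freezing", {
  ds <- make_tiny_dataset(seed = 14, n_proteins = 20)
  sp <- split_dataset(ds$segments, c(train = 0.7, validation = 0.3),
                      seed = 14)
  tr <- build_feature_bundles(sp$train, ds$proteins, ds$pssms,
                              window_size = 13L)
  va <- build_feature_bundles(sp$validation, ds$proteins, ds$pssms,
                              window_size = 13L)
  nc <- tiny_net_config(seed = 14, embedding_dim = 32L)
  tc <- train_config(max_epochs = 2, batch_size = 64, seed = 14,
                     auroc_gap_limit = 1)
  pre1 <- pretrain_lispm(tr, va, nc, tc)
  pre2 <- pretrain_lispm(tr, va, nc, tc)
  expect_identical(pre1$history, pre2$history)  # identical loss trajectory

  st <- train_predictor(tr, va, pretrained = pre1, lp = loss_params(2, 2, 12),
                    config = tc)
  # frozen LISPM parameters are bit-identical before and after training
  expect_identical(st$params$lispm, pre1$params$lispm)
  expect_identical(st$params$lispm_head, pre1$params$lispm_head)
  expect_false(identical(st$params$cspm, pre1$params$cspm))

  # the selected epoch satisfies the configured gap guard
  gap <- with(st$history[st$selected_epoch, ],
              abs(train_auroc - val_auroc))
  expect_lte(gap, tc$auroc_gap_limit)

  # zero-epoch training returns the initialised state unchanged
  tc0 <- train_config(max_epochs = 0, seed = 14)
  st0 <- train_predictor(tr, va, net_config = nc, lp = loss_params(),
                     config = tc0)
  expect_identical(st0$params, init_network(nc)$params)
})

test_that("an unsatisfiable gap guard fails with the gap trajectory", {
  ds <- make_tiny_dataset(seed = 26, n_proteins = 12)
  sp <- split_dataset(ds$segments, c(train = 0.7, validation = 0.3),
                      seed = 26)
  tr <- build_feature_bundles(sp$train, ds$proteins, ds$pssms,
                              window_size = 13L)
  va <- build_feature_bundles(sp$validation, ds$proteins, ds$pssms,
                              window_size = 13L)
  nc <- tiny_net_config(seed = 26, embedding_dim = 32L)
  tc <- train_config(max_epochs = 2, batch_size = 64, seed = 26,
                     auroc_gap_limit = 0)  # no epoch can satisfy gap <= 0
  err <- tryCatch(pretrain_lispm(tr, va, nc, tc), error = identity)
  expect_s3_class(err, "selcarb_training_error")
  expect_s3_class(err$trajectory, "data.frame")
})

test_that("window search tables candidates and picks the AUROC maximiser", {
  ds <- make_tiny_dataset(seed = 18, n_proteins = 16)
  sp <- split_dataset(ds$segments, c(train = 0.7, validation = 0.3),
                      seed = 18)
  tc <- train_config(max_epochs = 1, batch_size = 64, seed = 18,
                     auroc_gap_limit = 1)
  res <- window_search(c(9L, 13L), sp$train, sp$validation, ds$proteins,
                       ds$pssms,
                       net_overrides = list(model_dim = 8L, n_heads = 2L,
                                            conv_channels = c(2L, 2L),
                                            conv2d_channels = c(2L, 2L),
                                            fusion_dims = c(8L, 4L, 2L)),
                       config = tc)
  expect_equal(res$table$window, c(9L, 13L))
  expect_equal(res$selected,
               res$table$window[which.max(res$table$val_auroc)])
  expect_error(window_search(c(8L, 13L), sp$train, sp$validation,
                             ds$proteins),
               class = "selcarb_config_error")

  # a single candidate selects itself
  res1 <- window_search(9L, sp$train, sp$validation, ds$proteins,
                        ds$pssms,
                        net_overrides = list(model_dim = 8L,
                                             n_heads = 2L,
                                             conv_channels = c(2L, 2L),
                                             conv2d_channels = c(2L, 2L),
                                             fusion_dims = c(8L, 4L, 2L)),
                        config = tc)
  expect_equal(res1$selected, 9L)
})
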