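# Training: the class-specific focal loss, Adam optimisation, LISPM
# pretraining (ligand-vs-rest, binary cross-entropy), transfer with frozen
# LISPM parameters, the train/validation AUROC-gap overfitting guard, and
# the window-size and loss-parameter search harnesses.

#' Parameters of the customised focal loss
#'
#' The loss applied to a propensity `p` with three-way one-hot labels
#' (carbonylation `l_c`, nonfunctional `l_n`, ligand `l_i`) is
#' `-(1-p)^r * l_c * log(p) - alpha * p^r * l_n * log(1-p)
#'  - beta * p^r * l_i * log(1-p)`.
#' `r` down-weights well-classified examples (the focal exponent); `alpha`
#' scales the penalty for overprediction errors (nonfunctional residues
#' scored high) and `beta` the penalty for cross-prediction errors (ligand
#' interaction sites scored high). With `r = 0, alpha = beta = 1` the loss
#' reduces exactly to binary cross-entropy with carbonylation as the
#' positive class.
#'
#' @param r nonnegative focusing exponent (default 2).
#' @param alpha nonnegative weight on the nonfunctional term.
#' @param beta nonnegative weight on the ligand term.
#' @return a `loss_params` list.
#' @export
loss_params <- function(r = 2, alpha = 1, beta = 1) {
  if (r < 0 || alpha < 0 || beta < 0) {
    stop_config("loss parameters must be nonnegative")
  }
  structure(list(r = r, alpha = alpha, beta = beta), class = "loss_params")
}

#' Customised focal loss
#'
#' @param p propensities in (0, 1); clamped at 1e-7 before logs.
#' @param labels three-level labels (`"carbonylation"`, `"nonfunctional"`,
#'   `"ligand"`).
#' @param params a [loss_params].
#' @param reduce return the batch mean (default) or per-example losses.
#' @return nonnegative loss value(s).
#' @export
custom_loss <- function(p, labels, params = loss_params(), reduce = TRUE) {
  labels <- normalize_labels(labels)
  p <- clamp_prob(p)
  r <- params$r
  lc <- labels == "carbonylation"
  ln <- labels == "nonfunctional"
  li <- labels == "ligand"
  loss <- -(1 - p)^r * lc * log(p) -
    params$alpha * p^r * ln * log(1 - p) -
    params$beta * p^r * li * log(1 - p)
  if (reduce) mean(loss) else loss
}

# dLoss/dp (per example, no reduction)
custom_loss_grad_p <- function(p, labels, params) {
  labels <- normalize_labels(labels)
  p <- clamp_prob(p)
  r <- params$r
  lc <- labels == "carbonylation"
  neg_w <- ifelse(labels == "ligand", params$beta,
                  ifelse(labels == "nonfunctional", params$alpha, 0))
  # focal factor derivatives; the r = 0 case avoids 0^(-1)
  pos_term <- if (r == 0) -1 / p else {
    r * (1 - p)^(r - 1) * log(p) - (1 - p)^r / p
  }
  neg_term <- if (r == 0) 1 / (1 - p) else {
    -r * p^(r - 1) * log(1 - p) + p^r / (1 - p)
  }
  lc * pos_term + neg_w * neg_term
}

# dLoss/dz at the pre-sigmoid logit for the three supported loss types;
# mean reduction is applied by dividing by the batch size at the call site
loss_grad_z <- function(p, labels, loss_type, params, positive_class) {
  p <- clamp_prob(p)
  if (loss_type == "custom") {
    custom_loss_grad_p(p, labels, params) * p * (1 - p)
  } else {
    y <- as.numeric(normalize_labels(labels) == positive_class)
    if (loss_type == "bce") {
      p - y
    } else {  # l2
      2 * (p - y) * p * (1 - p)
    }
  }
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size minibatch size (default 256).
#' @param max_epochs maximum epochs.
#' @param patience early-stopping patience on validation AUROC.
#' @param auroc_gap_limit admissibility guard: the selected epoch must have
#'   |AUROC_train - AUROC_val| at most this value (default 0.03).
#' @param seed integer seed controlling shuffling, dropout and
#'   initialisation order.
#' @param verbose print per-epoch progress.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 256L,
                         max_epochs = 30L, patience = 10L,
                         auroc_gap_limit = 0.03, seed = 1L,
                         verbose = FALSE) {
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 auroc_gap_limit = auroc_gap_limit,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

adam_init <- function(params) {
  list(m = tree_zeros(params), v = tree_zeros(params), t = 0L)
}

adam_step <- function(opt, params, grads, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  opt$m <- tree_map(function(m, g) b1 * m + (1 - b1) * g, opt$m, grads)
  opt$v <- tree_map(function(v, g) b2 * v + (1 - b2) * g^2, opt$v, grads)
  c1 <- 1 - b1^opt$t
  c2 <- 1 - b2^opt$t
  params <- tree_map(function(p, m, v) {
    p - lr * (m / c1) / (sqrt(v / c2) + eps)
  }, params, opt$m, opt$v)
  list(opt = opt, params = params)
}

subset_bundles <- function(bundles, idx) {
  list(physchem = bundles$physchem[idx, , , drop = FALSE],
       pssm = bundles$pssm[idx, , , drop = FALSE],
       embedding = bundles$embedding[idx, , drop = FALSE],
       labels = bundles$labels[idx])
}

# Core optimisation loop shared by pretraining and full training.
# positive_class drives the AUROC used for model selection and early
# stopping (ligand for LISPM pretraining, carbonylation otherwise).
train_network <- function(state, train, validation, mode, loss_type,
                          lp, config, positive_class) {
  n <- dim(train$physchem)[1]
  if (config$max_epochs == 0) {
    state$history <- data.frame()
    state$selected_epoch <- 0L
    state$val_auroc <- NA_real_
    return(state)
  }
  opt <- adam_init(state$params)
  frozen_lispm <- if (state$freeze_lispm) {
    list(lispm = state$params$lispm, head = state$params$lispm_head)
  } else NULL
  history <- data.frame(epoch = integer(), train_auroc = numeric(),
                        val_auroc = numeric(), train_loss = numeric(),
                        admissible = logical())
  best <- list(auroc = -Inf, params = NULL, bn = NULL, epoch = NA_integer_)
  best_any <- -Inf
  since_best <- 0L
  y01 <- function(labels) as.numeric(labels == positive_class)

  for (epoch in seq_len(config$max_epochs)) {
    perm <- with_seed(derive_seed(config$seed, "shuffle", epoch),
                      sample.int(n))
    starts <- seq(1, n, by = config$batch_size)
    epoch_loss <- 0
    for (bi in seq_along(starts)) {
      idx <- perm[starts[bi]:min(starts[bi] + config$batch_size - 1, n)]
      batch <- subset_bundles(train, idx)
      fw <- forward_network(state, batch, mode, training = TRUE,
                            drop_seed = derive_seed(config$seed, "drop",
                                                    epoch, bi))
      state$bn <- fw$bn_new
      p <- fw$p
      loss_val <- if (loss_type == "custom") {
        custom_loss(p, batch$labels, lp)
      } else if (loss_type == "bce") {
        y <- y01(batch$labels)
        -mean(y * log(clamp_prob(p)) + (1 - y) * log(1 - clamp_prob(p)))
      } else {
        mean((p - y01(batch$labels))^2)
      }
      epoch_loss <- epoch_loss + loss_val * length(idx)
      dz <- loss_grad_z(p, batch$labels, loss_type, lp, positive_class) /
        length(idx)
      grads <- network_bwd(state, fw, dz)
      if (state$freeze_lispm) {
        grads$lispm <- tree_zeros(grads$lispm)
        grads$lispm_head <- tree_zeros(grads$lispm_head)
      }
      upd <- adam_step(opt, state$params, grads, config$learning_rate)
      opt <- upd$opt
      state$params <- upd$params
      if (state$freeze_lispm) {
        # belt and braces: frozen parameters are restored bit for bit
        state$params$lispm <- frozen_lispm$lispm
        state$params$lispm_head <- frozen_lispm$head
      }
    }
    p_tr <- predict_network(state, train, mode)
    p_va <- predict_network(state, validation, mode)
    auroc_tr <- curves_and_areas(p_tr, y01(train$labels))$AUROC
    auroc_va <- curves_and_areas(p_va, y01(validation$labels))$AUROC
    gap_ok <- abs(auroc_tr - auroc_va) <= config$auroc_gap_limit
    history <- rbind(history,
                     data.frame(epoch = epoch, train_auroc = auroc_tr,
                                val_auroc = auroc_va,
                                train_loss = epoch_loss / n,
                                admissible = gap_ok))
    if (config$verbose) {
      message(sprintf("epoch %2d  loss %.4f  AUROC train %.3f val %.3f%s",
                      epoch, epoch_loss / n, auroc_tr, auroc_va,
                      if (gap_ok) "" else "  [gap]"))
    }
    if (gap_ok && auroc_va > best$auroc) {
      best <- list(auroc = auroc_va, params = state$params, bn = state$bn,
                   epoch = epoch)
    }
    if (auroc_va > best_any + 1e-12) {
      best_any <- auroc_va
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= config$patience) break
    }
  }
  if (is.null(best$params)) {
    stop_training(paste0("no epoch satisfied the train/validation AUROC ",
                         "gap guard (", config$auroc_gap_limit, ")"),
                  trajectory = history)
  }
  state$params <- best$params
  state$bn <- best$bn
  state$history <- history
  state$selected_epoch <- best$epoch
  state$val_auroc <- best$auroc
  state
}

#' Pretrain the ligand interaction sites prediction module
#'
#' The LISPM (with its own head) is trained with binary cross-entropy on a
#' ligand-vs-rest relabelling of the data — carbonylation sites count as
#' negatives — selecting the epoch with the highest validation AUROC among
#' those satisfying the AUROC gap guard.
#'
#' @param train,validation feature bundles (see [build_feature_bundles()]).
#' @param net_config a [network_config].
#' @param config a [train_config].
#' @return a trained `network_state` (LISPM and its head updated; other
#'   components remain at initialisation).
#' @export
pretrain_lispm <- function(train, validation, net_config,
                           config = train_config()) {
  state <- init_network(net_config)
  train_network(state, train, validation, mode = "lispm",
                loss_type = "bce", lp = loss_params(0, 1, 1),
                config = config, positive_class = "ligand")
}

#' Train the full carbonylation predictor
#'
#' With a pretrained state the LISPM parameters are transferred and frozen
#' (bit-identical before and after training); without one the whole network
#' trains jointly (the no-transfer ablation). Training minimises the
#' customised focal loss (or a common loss for ablations) on the fused
#' output, selecting the epoch with the highest validation AUROC subject to
#' the gap guard.
#'
#' @param train,validation feature bundles.
#' @param net_config a [network_config] (ignored when `pretrained` is
#'   given, whose config is reused).
#' @param pretrained optional `network_state` from [pretrain_lispm()].
#' @param lp a [loss_params].
#' @param config a [train_config].
#' @param loss_type `"custom"` (default), `"bce"` or `"l2"` (ablations).
#' @param mode forward mode; `"fused"` (default) uses both modules,
#'   `"cspm"` the carbonylation module alone.
#' @return a trained `network_state` with `history`, `selected_epoch` and
#'   `val_auroc`.
#' @export
train_predictor <- function(train, validation, net_config = NULL,
                        pretrained = NULL, lp = loss_params(),
                        config = train_config(), loss_type = "custom",
                        mode = "fused") {
  if (!is.null(pretrained)) {
    state <- pretrained
    state$history <- NULL
    state$freeze_lispm <- TRUE
  } else {
    state <- init_network(net_config)
    state$freeze_lispm <- FALSE
  }
  state <- train_network(state, train, validation, mode = mode,
                         loss_type = loss_type, lp = lp, config = config,
                         positive_class = "carbonylation")
  state$loss_params <- lp
  state
}

#' Window-size search
#'
#' Trains one model per candidate window size on windows cropped from the
#' stored segments and reports validation AUROC and AUCPC for each;
#' selection maximises validation AUROC (the gap guard is enforced inside
#' each training run). Candidate sizes default to the nine odd sizes from
#' 5 to 21.
#'
#' @param candidate_sizes odd window sizes to evaluate.
#' @param train_segments,val_segments segment tables (27-residue windows).
#' @param proteins named list of [annotated_protein] objects.
#' @param pssms named list of PSSM profiles (or `NULL`).
#' @param provider embedding provider (or `NULL`).
#' @param net_overrides named list of [network_config] arguments applied at
#'   every size.
#' @param lp a [loss_params].
#' @param config a [train_config].
#' @return a list with `table` (window, val_auroc, val_aucpc,
#'   selected_epoch) and `selected` (the chosen window size).
#' @export
window_search <- function(candidate_sizes = seq(5L, 21L, 2L),
                          train_segments, val_segments, proteins,
                          pssms = NULL, provider = NULL,
                          net_overrides = list(), lp = loss_params(),
                          config = train_config()) {
  if (any(candidate_sizes %% 2 == 0)) {
    stop_config("candidate window sizes must be odd")
  }
  rows <- lapply(candidate_sizes, function(w) {
    tr <- build_feature_bundles(train_segments, proteins, pssms, provider,
                                window_size = w)
    va <- build_feature_bundles(val_segments, proteins, pssms, provider,
                                window_size = w)
    nc <- do.call(network_config,
                  c(list(window_size = w), net_overrides))
    st <- train_predictor(tr, va, net_config = nc, lp = lp, config = config,
                      mode = "cspm")
    p <- predict_network(st, va, mode = "cspm")
    cv <- curves_and_areas(p, va$labels)
    data.frame(window = w, val_auroc = cv$AUROC, val_aucpc = cv$AUCPC,
               selected_epoch = st$selected_epoch)
  })
  table <- do.call(rbind, rows)
  list(table = table,
       selected = table$window[which.max(table$val_auroc)])
}

#' Select a loss-parameter grid cell
#'
#' The printed selection rule: among cells whose AUCPC lies within `band`
#' (absolute, default 0.02) of the grid minimum AUCPC, choose the one with
#' the highest AUROC. Deterministic and invariant to row order: ties on
#' AUROC break toward lower AUCPC, then lower alpha, then lower beta.
#'
#' @param table data frame with columns alpha, beta, auroc, aucpc.
#' @param band admissible AUCPC band above the grid minimum.
#' @return the selected row of `table`.
#' @export
select_loss_cell <- function(table, band = 0.02) {
  if (nrow(table) == 0) stop_config("empty grid")
  admissible <- table[table$aucpc <= min(table$aucpc) + band, , drop = FALSE]
  ord <- order(-admissible$auroc, admissible$aucpc, admissible$alpha,
               admissible$beta)
  admissible[ord[1], , drop = FALSE]
}

#' Grid search over the loss weights alpha and beta
#'
#' Trains one model per (alpha, beta) cell and applies [select_loss_cell()].
#'
#' @param alpha_grid,beta_grid numeric grids.
#' @param train,validation feature bundles.
#' @param net_config a [network_config].
#' @param pretrained optional pretrained state shared by all cells.
#' @param r focal exponent used in every cell.
#' @param config a [train_config].
#' @param band AUCPC admissibility band (default 0.02).
#' @return a list with the full `table` and the `selected` row.
#' @export
loss_grid_search <- function(alpha_grid, beta_grid, train, validation,
                             net_config = NULL, pretrained = NULL, r = 2,
                             config = train_config(), band = 0.02) {
  if (length(alpha_grid) == 0 || length(beta_grid) == 0) {
    stop_config("grids must be nonempty")
  }
  rows <- list()
  for (a in alpha_grid) {
    for (b in beta_grid) {
      st <- train_predictor(train, validation, net_config = net_config,
                        pretrained = pretrained,
                        lp = loss_params(r, a, b), config = config)
      p <- predict_network(st, validation)
      cv <- curves_and_areas(p, validation$labels)
      rows[[length(rows) + 1]] <-
        data.frame(alpha = a, beta = b, auroc = cv$AUROC,
                   aucpc = cv$AUCPC)
    }
  }
  table <- do.call(rbind, rows)
  list(table = table, selected = select_loss_cell(table, band))
}
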