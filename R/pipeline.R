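# End-to-end workflows: simulate -> train -> predict -> evaluate, plus the
# ablation harness. These functions are the programmatic interface; the
# thin command-line wrapper in inst/cli/selcarb maps subcommands onto them.

#' Simulate a dataset to disk
#'
#' @param config a [simulation_config].
#' @param dir output directory.
#' @param embeddings also write embedding matrices.
#' @return the directory, invisibly.
#' @export
run_simulate <- function(config, dir, embeddings = FALSE) {
  write_simulated_dataset(config, dir, pssm = TRUE, embeddings = embeddings)
  invisible(dir)
}

load_dataset <- function(dir) {
  proteins <- read_annotations(file.path(dir, "proteins.fasta"),
                               file.path(dir, "annotations.tsv"))
  pssm_dir <- file.path(dir, "pssm")
  pssms <- NULL
  if (dir.exists(pssm_dir)) {
    files <- list.files(pssm_dir, pattern = "\\.tsv$", full.names = TRUE)
    pssms <- lapply(files, read_pssm_profile)
    names(pssms) <- sub("\\.tsv$", "", basename(files))
  }
  list(proteins = proteins, pssms = pssms)
}

#' Train a carbonylation predictor end to end
#'
#' Reads a dataset directory (FASTA + annotations + optional PSSM
#' profiles), extracts 27-residue segments for the requested residue type,
#' splits 80/20 into train/validation, optionally pretrains and freezes the
#' ligand module, trains the fused model under the customised loss,
#' calibrates the decision threshold at SP = 0.95 on the validation set and
#' writes a checkpoint plus a training log and a validation report.
#'
#' @param data_dir dataset directory (as written by [run_simulate()]).
#' @param out_dir output directory for checkpoint, log and report.
#' @param residue_type one of K/P/R/T.
#' @param window_size odd window size (default 13).
#' @param transfer pretrain and freeze the ligand module (default TRUE).
#' @param lp a [loss_params].
#' @param net_overrides named list of [network_config] overrides.
#' @param config a [train_config].
#' @param provider embedding provider (`NULL` for the zero provider).
#' @param loss_type loss for the fused phase (default `"custom"`).
#' @param sp_anchor specificity anchor for threshold calibration.
#' @return the trained `network_state`, invisibly.
#' @export
run_train <- function(data_dir, out_dir, residue_type = "K",
                      window_size = 13L, transfer = TRUE,
                      lp = loss_params(2, 2, 12),
                      net_overrides = list(), config = train_config(),
                      provider = NULL, loss_type = "custom",
                      sp_anchor = 0.95) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- load_dataset(data_dir)
  segments <- extract_all_segments(ds$proteins, residue_type, 27L)
  if (nrow(segments) == 0) stop_data("no ", residue_type, " segments found")
  split <- split_dataset(segments, c(train = 0.8, validation = 0.2),
                         seed = config$seed)
  emb_dim <- if (is.null(provider)) 32L else provider$dim
  nc <- do.call(network_config,
                c(list(window_size = window_size, embedding_dim = emb_dim,
                       seed = config$seed), net_overrides))
  tr <- build_feature_bundles(split$train, ds$proteins, ds$pssms, provider,
                              window_size)
  va <- build_feature_bundles(split$validation, ds$proteins, ds$pssms,
                              provider, window_size)
  pre <- if (transfer) pretrain_lispm(tr, va, nc, config) else NULL
  state <- train_predictor(tr, va, net_config = nc, pretrained = pre, lp = lp,
                       config = config, loss_type = loss_type)
  p_va <- predict_network(state, va)
  state$residue_type <- residue_type
  state$window_size <- window_size
  state$threshold <- threshold_at_sp(p_va, va$labels, sp_anchor)
  save_checkpoint(state, file.path(out_dir, "checkpoint.rds"))
  utils::write.table(state$history, file.path(out_dir, "training_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report <- evaluation_report(p_va, va$labels)
  jsonlite::write_json(report, file.path(out_dir, "validation_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(state)
}

#' Predict carbonylation propensities for new proteins
#'
#' @param checkpoint_path checkpoint written by [run_train()].
#' @param fasta_path protein FASTA.
#' @param out_path output TSV (`protein_id position score call`).
#' @param pssm_dir optional directory of per-protein PSSM TSVs.
#' @param provider optional embedding provider.
#' @return the prediction data frame, invisibly.
#' @export
run_predict <- function(checkpoint_path, fasta_path, out_path,
                        pssm_dir = NULL, provider = NULL) {
  state <- load_checkpoint(checkpoint_path)
  proteins <- read_annotations(fasta_path)
  pssms <- NULL
  if (!is.null(pssm_dir)) {
    files <- list.files(pssm_dir, pattern = "\\.tsv$", full.names = TRUE)
    pssms <- lapply(files, read_pssm_profile)
    names(pssms) <- sub("\\.tsv$", "", basename(files))
  }
  segments <- extract_all_segments(proteins, state$residue_type, 27L)
  if (is.null(segments) || nrow(segments) == 0) {
    out <- data.frame(protein_id = character(), position = integer(),
                      score = numeric(), call = integer())
  } else {
    bundles <- build_feature_bundles(segments, proteins, pssms, provider,
                                     state$window_size)
    scores <- predict_network(state, bundles)
    thr <- if (is.na(state$threshold)) 0.5 else state$threshold
    out <- data.frame(protein_id = segments$protein_id,
                      position = segments$center_pos,
                      score = scores,
                      call = as.integer(scores >= thr))
  }
  utils::write.table(out, out_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}

#' Evaluate predictions against annotations
#'
#' @param pred_path predictions TSV from [run_predict()].
#' @param fasta_path,annotation_path the labelled data.
#' @param out_path output JSON report.
#' @param pred_b_path optional second predictions TSV; when given, the
#'   bootstrap significance comparison is added to the report.
#' @param seed seed for the bootstrap replicates.
#' @return the report list, invisibly.
#' @export
run_evaluate <- function(pred_path, fasta_path, annotation_path, out_path,
                         pred_b_path = NULL, seed = 1L) {
  pred <- utils::read.delim(pred_path, stringsAsFactors = FALSE)
  proteins <- read_annotations(fasta_path, annotation_path)
  labels <- vapply(seq_len(nrow(pred)), function(i) {
    p <- proteins[[pred$protein_id[i]]]
    if (is.null(p)) stop_data("prediction for unknown protein ",
                              pred$protein_id[i])
    p$labels[pred$position[i]]
  }, "")
  report <- evaluation_report(pred$score, labels)
  if (!is.null(pred_b_path)) {
    pred_b <- utils::read.delim(pred_b_path, stringsAsFactors = FALSE)
    key_a <- paste(pred$protein_id, pred$position)
    key_b <- paste(pred_b$protein_id, pred_b$position)
    if (!identical(sort(key_a), sort(key_b))) {
      stop_data("the two prediction files cover different residues")
    }
    sb <- pred_b$score[match(key_a, key_b)]
    report$comparison <- bootstrap_significance(pred$score, sb, labels,
                                                seed = seed)
    report$comparison$values <- NULL
  }
  jsonlite::write_json(report, out_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(report)
}

ABLATION_VARIANTS <- c("no-embedding", "fcnn-for-attention", "no-transfer",
                       "bce-loss", "l2-loss")

#' Ablation analysis
#'
#' Re-trains the predictor with one innovation removed and reports the
#' validation metrics next to the full model's: `no-embedding` zeroes the
#' embedding channel, `fcnn-for-attention` replaces the CNN/TRF extractors
#' with FCNN units, `no-transfer` skips ligand-module pretraining,
#' `bce-loss` and `l2-loss` swap the customised loss for a common one.
#'
#' @param data_dir dataset directory.
#' @param out_dir output directory.
#' @param variant one of the five ablation variants.
#' @param ... arguments passed on to [run_train()].
#' @return a data frame comparing full and ablated validation metrics.
#' @export
run_ablate <- function(data_dir, out_dir, variant, ...) {
  variant <- match.arg(variant, ABLATION_VARIANTS)
  args <- list(...)
  full <- run_train(data_dir, file.path(out_dir, "full"), ...)
  ab_args <- args
  if (variant == "no-embedding") {
    ab_args$provider <- NULL  # zero embeddings
  } else if (variant == "fcnn-for-attention") {
    ab_args$net_overrides <- c(args$net_overrides %||% list(),
                               list(attention = FALSE))
  } else if (variant == "no-transfer") {
    ab_args$transfer <- FALSE
  } else if (variant == "bce-loss") {
    ab_args$loss_type <- "bce"
  } else if (variant == "l2-loss") {
    ab_args$loss_type <- "l2"
  }
  ablated <- do.call(run_train,
                     c(list(data_dir, file.path(out_dir, variant)),
                       ab_args))
  read_report <- function(d) {
    jsonlite::read_json(file.path(d, "validation_report.json"),
                        simplifyVector = TRUE)
  }
  rf <- read_report(file.path(out_dir, "full"))
  ra <- read_report(file.path(out_dir, variant))
  cmp <- data.frame(metric = c("AUROC", "AUPRC", "AUCPC", "AUOPC"),
                    full = c(rf$AUROC, rf$AUPRC, rf$AUCPC, rf$AUOPC),
                    ablated = c(ra$AUROC, ra$AUPRC, ra$AUCPC, ra$AUOPC))
  utils::write.table(cmp, file.path(out_dir, "ablation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cmp
}
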