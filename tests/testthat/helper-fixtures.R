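# Shared fixture builders. Everything is generated in code under fixed
# seeds; nothing is read from disk except files the tests write themselves.

# a small confusable synthetic dataset with precomputed segments/bundles
make_tiny_dataset <- function(seed = 7L, n_proteins = 30L,
                              class_props = c(0.10, 0.20, 0.70),
                              window_size = 13L) {
  cfg <- simulation_config(n_proteins = n_proteins,
                           length_range = c(120L, 180L),
                           class_props = class_props,
                           plant_prob = 0.9, motif_share = 0.35,
                           ligand_aromatic_rate = 0.5, seed = seed)
  proteins <- simulate_proteins(cfg)
  pssms <- lapply(proteins, simulate_pssm, config = cfg)
  segments <- extract_all_segments(proteins, "K", 27L)
  list(config = cfg, proteins = proteins, pssms = pssms,
       segments = segments, window_size = window_size)
}

# tiny network configuration that keeps forward/backward fast
tiny_net_config <- function(window_size = 13L, seed = 1L,
                            embedding_dim = 8L, ...) {
  network_config(window_size = window_size, model_dim = 16L, n_heads = 2L,
                 conv_channels = c(4L, 4L), conv2d_channels = c(2L, 2L),
                 reducer_hidden = 8L, embedding_dim = embedding_dim,
                 fusion_dims = c(16L, 8L, 4L), seed = seed, ...)
}

# random feature bundles for network-level tests (no biology needed)
random_bundles <- function(n, window_size = 13L, emb_dim = 8L, seed = 1L,
                           labels = NULL) {
  set.seed(seed)
  if (is.null(labels)) {
    labels <- sample(c("carbonylation", "ligand", "nonfunctional"), n,
                     replace = TRUE, prob = c(0.3, 0.3, 0.4))
  }
  list(physchem = array(stats::runif(n * window_size * 10),
                        c(n, window_size, 10)),
       pssm = array(stats::rnorm(n * window_size * 20),
                    c(n, window_size, 20)),
       embedding = matrix(stats::rnorm(n * emb_dim), n, emb_dim),
       labels = labels)
}

# pair-counting (Mann-Whitney) AUROC oracle with half credit for ties
auroc_pair_oracle <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# exhaustive confusion-sweep oracle: metrics at every candidate threshold
sweep_oracle <- function(scores, positive) {
  thresholds <- sort(unique(scores))
  t(vapply(thresholds, function(th) {
    call <- scores >= th
    tp <- sum(call & positive); fp <- sum(call & !positive)
    fn <- sum(!call & positive); tn <- sum(!call & !positive)
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    den <- sqrt(tp + fn) * sqrt(tp + fp) * sqrt(tn + fp) * sqrt(tn + fn)
    mcc <- if (den == 0) 0 else (tp * tn - fn * fp) / den
    c(threshold = th, SN = tp / (tp + fn), SP = tn / (tn + fp),
      F1 = f1, MCC = mcc)
  }, numeric(5)))
}
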