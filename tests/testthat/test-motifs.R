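test_that("entropy matches closed-form values", {
  expect_equal(entropy_bits(c(50, 50)), 1.0)
  expect_equal(entropy_bits(c(100, 0)), 0.0)
  expect_equal(entropy_bits(c(25, 75)),
               -(0.25 * log2(0.25) + 0.75 * log2(0.75)))
  expect_equal(round(entropy_bits(c(25, 75)), 4), 0.8113)
  expect_error(entropy_bits(c(0, 0)), class = "selcarb_data_error")
  expect_error(entropy_bits(c(-1, 5)), class = "selcarb_config_error")
})

test_that("corpus replicates have the positive-set size, deterministically", {
  segs <- data.frame(
    window = replicate(550, paste(sample(c("A", "K", "L"), 9,
                                         replace = TRUE), collapse = "")),
    label = c(rep("carbonylation", 50), rep("nonfunctional", 500)),
    stringsAsFactors = FALSE)
  corpus <- build_corpus(segs, seed = 3)
  expect_length(corpus$d_ncs, 10)
  expect_true(all(vapply(corpus$d_ncs, length, 0L) == 50))
  corpus2 <- build_corpus(segs, seed = 3)
  expect_identical(corpus$d_ncs, corpus2$d_ncs)

  too_few <- segs[c(1:50, 51:90), ]
  expect_error(build_corpus(too_few, seed = 1), "40",
               class = "selcarb_data_error")
})

test_that("pattern generation respects lengths, wildcards and the seed", {
  pats <- generate_patterns(300, c(4, 10), seed = 5, wildcard_prob = 0.3)
  expect_true(all(nchar(pats) >= 4 & nchar(pats) <= 10))
  expect_false(any(grepl("^x|x$", pats)))
  expect_identical(pats, generate_patterns(300, c(4, 10), seed = 5,
                                           wildcard_prob = 0.3))

  no_wc <- generate_patterns(100, c(4, 6), seed = 5, wildcard_prob = 0)
  expect_false(any(grepl("x", no_wc, fixed = TRUE)))

  expect_error(generate_patterns(10, c(2, 5)),
               class = "selcarb_config_error")
  expect_error(generate_patterns(10, c(4, 12)),
               class = "selcarb_config_error")
})

test_that("pattern frequency uses presence/absence substring semantics", {
  expect_equal(pattern_frequency("KxK", c("AKAKA", "CCCCC")), 0.5)
  expect_equal(pattern_frequency("KAKAKAK", c("AKAKA", "CCCCC")), 0)
  # overlapping matches count once
  expect_equal(pattern_frequency("KK", c("KKKK")), 1)
  # wildcard matches residues but not terminal padding 'X'
  expect_equal(pattern_frequency("KxK", c("KXK")), 0)
})

test_that("frequency filtering applies strict inequalities on both sides", {
  segs <- data.frame(
    window = c(rep("AAKLKAA", 12), rep("CCCCCCC", 8),
               rep("GGGGGGG", 100)),
    label = c(rep("carbonylation", 20), rep("nonfunctional", 100)),
    stringsAsFactors = FALSE)
  corpus <- build_corpus(segs, seed = 1)
  # KLK occurs in 60% of positives, never in negatives
  kept <- filter_patterns(c("KLKA", "CCCC", "WWWW"), corpus, 0.05)
  expect_true("KLKA" %in% kept)
  expect_false("WWWW" %in% kept)  # zero positive frequency
  # boundary: frequency exactly T on the positive side is dropped
  segs2 <- data.frame(window = c(rep("KLKA", 1), rep("AAAA", 19),
                                 rep("GGGG", 40)),
                      label = c(rep("carbonylation", 20),
                                rep("nonfunctional", 40)),
                      stringsAsFactors = FALSE)
  corpus2 <- build_corpus(segs2, seed = 1)
  expect_false("KLKA" %in% filter_patterns("KLKA", corpus2, 0.05))
  expect_error(filter_patterns("KLKA", corpus2, 1.5),
               class = "selcarb_config_error")
})

test_that("information gain matches a brute-force contingency oracle", {
  ig_oracle <- function(windows, labels, pattern) {
    rx <- gsub("x", "[ACDEFGHIKLMNPQRSTVWY]", pattern, fixed = TRUE)
    present <- grepl(rx, windows, perl = TRUE)
    h <- function(a, b) {
      tot <- a + b
      if (tot == 0) return(0)
      p <- c(a, b) / tot
      p <- p[p > 0]
      -sum(p * log2(p))
    }
    n <- length(windows)
    h0 <- h(sum(labels), sum(!labels))
    n_in <- sum(present)
    h_in <- h(sum(labels & present), sum(!labels & present))
    h_out <- h(sum(labels & !present), sum(!labels & !present))
    h0 - (n_in / n) * h_in - ((n - n_in) / n) * h_out
  }
  set.seed(17)
  alph <- c("A", "K", "L", "R", "T", "G")
  for (rep in 1:25) {
    n <- sample(20:200, 1)
    windows <- replicate(n, paste(sample(alph, 11, replace = TRUE),
                                  collapse = ""))
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    pattern <- sample(c("KL", "LxT", "RTG", "AA", "KxKxL"), 1)
    expect_lt(abs(information_gain(windows, labels, pattern) -
                    max(ig_oracle(windows, labels, pattern), 0)),
              1e-10)
  }

  # perfect split of a balanced set gains exactly one bit
  windows <- c(rep("AKLKA", 30), rep("GGGGG", 30))
  labels <- rep(c(TRUE, FALSE), each = 30)
  expect_equal(information_gain(windows, labels, "KLK"), 1.0)
  expect_equal(information_gain(windows, labels, "WWW"), 0)
})

test_that("IG is monotone in the positive-set frequency", {
  base_neg <- rep("GGGGGGG", 50)
  igs <- vapply(seq(5, 45, 10), function(k) {
    windows <- c(rep("AKLKAAA", k), rep("AAAAAAA", 50 - k), base_neg)
    labels <- rep(c(TRUE, FALSE), each = 50)
    information_gain(windows, labels, "KLK")
  }, 0)
  expect_true(all(diff(igs) > 0))
})

test_that("ranking recovers a planted motif and orders ties canonically", {
  ds <- make_tiny_dataset(seed = 31, n_proteins = 40,
                          class_props = c(0.10, 0.05, 0.85))
  model <- discover_motifs(ds$segments, q = 20, seed = 31)
  expect_gt(nrow(model$motifs), 0)
  planted_hit <- vapply(ds$config$planted_motifs, function(m) {
    any(grepl(m, model$motifs$pattern, fixed = TRUE) |
          model$motifs$pattern == m)
  }, TRUE)
  expect_true(any(planted_hit))
  expect_true(all(diff(model$motifs$igr) <= 1e-12))
  expect_true(all(model$motifs$category %in%
                    c("highly", "moderately", "marginally", "unfavored")))

  # q larger than the surviving set returns everything
  corpus <- build_corpus(ds$segments, seed = 31)
  kept <- filter_patterns(generate_patterns(50, c(4, 6), seed = 1,
                                            mined_from = corpus$d_cs),
                          corpus)
  model_all <- rank_and_select(kept, corpus, q = 10000)
  expect_equal(nrow(model_all$motifs), length(kept))
  expect_warning(rank_and_select(character(0), corpus, 5), "empty")
})

test_that("motif scores accumulate the IG of matching motifs", {
  model <- structure(list(motifs = data.frame(
    pattern = c("KLK", "RTG"), ig_cs = c(0.3, 0.2),
    ig_ncs_mean = c(0.01, 0.01), igr = c(30, 20),
    category = c("highly", "highly"), stringsAsFactors = FALSE),
    q = 2, seed = 1), class = "motif_model")
  expect_equal(motif_score("AAAAA", model), 0)
  expect_equal(motif_score("KLKAA", model), 0.3)
  expect_equal(motif_score("KLKRTG", model), 0.5)
  expect_equal(motif_score(c("KLKRTG", "GGGG"), model), c(0.5, 0))
})

test_that("motif models survive a TSV round trip", {
  ds <- make_tiny_dataset(seed = 13, n_proteins = 15)
  model <- discover_motifs(ds$segments, q = 10, seed = 13)
  f <- tempfile(fileext = ".tsv")
  write_motif_model(model, f)
  back <- read_motif_model(f)
  expect_equal(back$motifs$pattern, model$motifs$pattern)
  expect_equal(back$motifs$ig_cs, model$motifs$ig_cs, tolerance = 1e-9)
})
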