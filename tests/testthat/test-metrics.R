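test_that("confusion metrics match the closed-form definitions", {
  m <- confusion_metrics(list(TP = 8, FN = 2, TN = 90, FP = 10))
  expect_equal(unname(m["SN"]), 0.8)
  expect_equal(unname(m["SP"]), 0.9)
  expect_equal(unname(m["ACC"]), 98 / 110)
  expect_equal(unname(m["F1"]), 2 * 8 / (2 * 8 + 10 + 2))
  expect_equal(unname(m["MCC"]),
               (8 * 90 - 2 * 10) / sqrt(10) / sqrt(18) / sqrt(100) /
                 sqrt(92))

  perfect <- confusion_metrics(list(TP = 5, FN = 0, TN = 20, FP = 0))
  expect_equal(unname(perfect), rep(1, 5))

  all_neg <- confusion_metrics(list(TP = 0, FN = 5, TN = 20, FP = 0))
  expect_equal(unname(all_neg["SN"]), 0)
  expect_equal(unname(all_neg["SP"]), 1)
  expect_equal(unname(all_neg["MCC"]), 0)

  expect_error(confusion_metrics(list(TP = 0, FN = 0, TN = 5, FP = 1)),
               class = "selcarb_data_error")
})

test_that("cross/over-prediction rates and ratios follow the rate reading", {
  labels <- c(rep("carbonylation", 10), rep("ligand", 10),
              rep("nonfunctional", 20))
  scores <- c(rep(0.9, 6), rep(0.1, 4),     # SN = 0.6
              rep(0.9, 3), rep(0.1, 7),     # CPR = 0.3
              rep(0.9, 2), rep(0.1, 18))    # OPR = 0.1
  r <- cross_over_rates(scores, labels, 0.5)
  expect_equal(r$SN, 0.6)
  expect_equal(r$CPR, 0.3)
  expect_equal(r$OPR, 0.1)
  expect_equal(r$CPRratio, 2)
  expect_equal(r$OPRratio, 6)

  # zero rate is floored at half a count and flagged
  scores2 <- c(rep(0.9, 6), rep(0.1, 4), rep(0.1, 10), rep(0.9, 2),
               rep(0.1, 18))
  r2 <- cross_over_rates(scores2, labels, 0.5)
  expect_true(r2$cpr_floored)
  expect_equal(r2$CPRratio, 0.6 / (1 / 20))

  # absent ligand class: CPR reported as NA, not zero
  lab3 <- c(rep("carbonylation", 5), rep("nonfunctional", 20))
  r3 <- cross_over_rates(runif(25), lab3, 0.5)
  expect_true(is.na(r3$CPR))
  expect_true(is.na(r3$CPRratio))
})

test_that("AUROC equals the pair-counting Mann-Whitney statistic", {
  set.seed(23)
  for (rep in 1:40) {
    n <- sample(20:500, 1)
    # mix of continuous and heavily tied scores
    scores <- if (rep %% 2 == 0) rnorm(n) else sample(1:5, n, TRUE) / 5
    positive <- runif(n) < 0.3
    if (!any(positive) || all(positive)) next
    expect_equal(curves_and_areas(scores, positive)$AUROC,
                 auroc_pair_oracle(scores, positive),
                 tolerance = 1e-10)
  }
})

test_that("curves behave at the perfect and degenerate extremes", {
  labels <- c(rep("carbonylation", 20), rep("ligand", 30),
              rep("nonfunctional", 50))
  perfect <- c(runif(20, 0.8, 1), runif(80, 0, 0.5))
  cv <- curves_and_areas(perfect, labels)
  expect_equal(cv$AUROC, 1)
  expect_equal(cv$AUCPC, 0)
  expect_equal(cv$AUOPC, 0)

  # all scores identical: single threshold, no error
  cv2 <- curves_and_areas(rep(0.5, 100), labels)
  expect_true(is.finite(cv2$AUROC))

  expect_error(curves_and_areas(runif(5), rep("carbonylation", 5)),
               class = "selcarb_data_error")
  expect_error(curves_and_areas(c(1, NA), c("carbonylation",
                                            "nonfunctional")),
               class = "selcarb_data_error")
})

test_that("AUCPC is the complement of carbonylation-vs-ligand AUROC", {
  set.seed(5)
  for (rep in 1:10) {
    labels <- sample(c("carbonylation", "ligand", "nonfunctional"), 300,
                     replace = TRUE, prob = c(0.2, 0.3, 0.5))
    scores <- rnorm(300) + (labels == "carbonylation")
    cv <- curves_and_areas(scores, labels)
    sub <- labels %in% c("carbonylation", "ligand")
    expect_equal(cv$AUCPC,
                 1 - auroc_pair_oracle(scores[sub],
                                       labels[sub] == "carbonylation"),
                 tolerance = 1e-10)
  }
})

test_that("rank metrics are invariant under monotone score transforms", {
  set.seed(9)
  labels <- sample(c("carbonylation", "ligand", "nonfunctional"), 400,
                   replace = TRUE, prob = c(0.1, 0.2, 0.7))
  scores <- rnorm(400) + 0.8 * (labels == "carbonylation")
  a <- curves_and_areas(scores, labels)
  b <- curves_and_areas(plogis(3 * scores + 1), labels)
  for (metric in c("AUROC", "AUPRC", "AUCPC", "AUOPC")) {
    expect_equal(a[[metric]], b[[metric]], tolerance = 1e-12,
                 label = metric)
  }
  expect_equal(aulc_ratio(scores, labels, 0.1)$AULC,
               aulc_ratio(plogis(scores), labels, 0.1)$AULC,
               tolerance = 1e-12)
})

test_that("the partial-AUC ratio calibrates against random and perfect", {
  set.seed(3)
  labels <- c(rep(1, 500), rep(0, 9500))
  # perfect scorer: AULC = cutoff, ratio = 2 / cutoff
  perfect <- c(runif(500, 0.9, 1), runif(9500, 0, 0.5))
  for (cutoff in c(0.05, 0.1, 1)) {
    al <- aulc_ratio(perfect, labels, cutoff)
    expect_equal(al$AULC, cutoff, tolerance = 1e-6)
    expect_equal(al$AULCratio, 2 / cutoff, tolerance = 1e-4)
  }
  # random scorer across the full range: AULC ~ 0.5, ratio ~ 1
  rand <- runif(10000)
  al <- aulc_ratio(rand, labels, 1.0)
  expect_lt(abs(al$AULC - 0.5), 0.05)
  expect_lt(abs(al$AULCratio - 1), 0.1)
  expect_error(aulc_ratio(rand, labels, 0),
               class = "selcarb_config_error")
})

test_that("threshold optima agree with exhaustive enumeration", {
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(30:1000, 1)
    scores <- round(runif(n), 2)  # force ties
    positive <- runif(n) < 0.25
    if (!any(positive) || all(positive)) next
    opt <- threshold_optima(scores, positive)
    oracle <- sweep_oracle(scores, positive)
    expect_equal(opt$MCCmax, max(oracle[, "MCC"]), tolerance = 1e-12)
    expect_equal(opt$F1max, max(oracle[, "F1"]), tolerance = 1e-12)
    for (target in c(0.95, 0.90)) {
      ok <- oracle[, "SP"] >= target
      expected <- if (any(ok)) max(oracle[ok, "SN"]) else NA_real_
      got <- unname(opt$SN_at_SP[paste0("SP", target * 100)])
      expect_equal(got, expected, tolerance = 1e-12)
    }
  }

  # hand-built 6-point table
  scores <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.1)
  positive <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  opt <- threshold_optima(scores, positive)
  # threshold 0.7: TP2 FP1 FN1 TN2; threshold 0.4: TP3 FP1 TN2
  expect_equal(opt$F1max, 2 * 3 / (2 * 3 + 1 + 0))
  expect_equal(opt$MCCmax,
               (3 * 2 - 0 * 1) / sqrt(3) / sqrt(4) / sqrt(3) / sqrt(2))

  # degenerate: all scores equal, SP targets unreachable
  opt2 <- threshold_optima(rep(0.5, 50), c(rep(TRUE, 10), rep(FALSE, 40)))
  expect_true(all(opt2$sp_unreachable))
})

test_that("perfect separation yields unit optima", {
  scores <- c(runif(20, 0.8, 1), runif(80, 0, 0.5))
  positive <- c(rep(TRUE, 20), rep(FALSE, 80))
  opt <- threshold_optima(scores, positive)
  expect_equal(opt$MCCmax, 1)
  expect_equal(opt$F1max, 1)
})

test_that("bootstrap comparison is calibrated and deterministic", {
  set.seed(77)
  labels <- sample(c("carbonylation", "ligand", "nonfunctional"), 600,
                   replace = TRUE, prob = c(0.15, 0.15, 0.7))
  perfect <- as.numeric(labels == "carbonylation") + runif(600, 0, 0.01)
  random <- runif(600)

  # identical methods: no significance
  same <- bootstrap_significance(perfect, perfect, labels, seed = 1)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)

  # perfect vs random separates decisively
  diff <- bootstrap_significance(perfect, random, labels, seed = 1)
  expect_true(diff$significant)
  expect_lt(diff$p_value, 0.001)
  expect_gt(diff$mean["A"], diff$mean["B"])

  # same seed reproduces replicate values and p-value exactly
  diff2 <- bootstrap_significance(perfect, random, labels, seed = 1)
  expect_identical(diff$values, diff2$values)
  expect_identical(diff$p_value, diff2$p_value)

  expect_error(bootstrap_significance(perfect, random, labels, n_reps = 1),
               class = "selcarb_config_error")
})
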