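# Cross-prediction-aware evaluation: confusion metrics, CPR/OPR and their
# ratios, ROC/PR/CP/OP curves with areas, partial-AUC (low-FPR) ratios,
# threshold optima and the bootstrap significance protocol.
#
# Throughout, "positive" means carbonylation; the negative side splits into
# ligand interaction sites (whose false positives are *cross*-predictions)
# and nonfunctional residues (whose false positives are *over*-predictions).

# normalise labels to the three-level character convention; numeric 1/0 is
# treated as carbonylation / nonfunctional
normalize_labels <- function(labels) {
  if (is.numeric(labels) || is.logical(labels)) {
    return(ifelse(as.numeric(labels) > 0, "carbonylation", "nonfunctional"))
  }
  labels <- tolower(as.character(labels))
  bad <- setdiff(unique(labels), LABEL_LEVELS)
  if (length(bad) > 0) {
    stop_data("unknown label(s): ", paste(bad, collapse = ", "))
  }
  labels
}

#' Confusion counts at a threshold
#'
#' Calls are positive when `score >= threshold`. False positives are
#' decomposed into their ligand and nonfunctional components.
#'
#' @param scores numeric propensities.
#' @param labels three-level labels (or 0/1 with 1 = carbonylation).
#' @param threshold decision threshold.
#' @return a list with TP, FP, TN, FN, FP_ligand, FP_nonfunctional.
#' @export
confusion_counts <- function(scores, labels, threshold) {
  labels <- normalize_labels(labels)
  pos_call <- scores >= threshold
  is_pos <- labels == "carbonylation"
  list(TP = sum(pos_call & is_pos),
       FN = sum(!pos_call & is_pos),
       FP = sum(pos_call & !is_pos),
       TN = sum(!pos_call & !is_pos),
       FP_ligand = sum(pos_call & labels == "ligand"),
       FP_nonfunctional = sum(pos_call & labels == "nonfunctional"))
}

#' Binary classification metrics from confusion counts
#'
#' Sensitivity, specificity, accuracy, F1 and the Matthews correlation
#' coefficient, with the usual convention that an MCC with a zero
#' denominator is 0.
#'
#' @param counts list or named vector with TP, FP, TN, FN.
#' @return a named numeric vector (SN, SP, ACC, F1, MCC).
#' @export
confusion_metrics <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  tn <- counts[["TN"]]; fn <- counts[["FN"]]
  n <- tp + fp + tn + fn
  if (n == 0) stop_data("cannot evaluate an empty dataset")
  if (tp + fn == 0 || tn + fp == 0) {
    stop_data("need at least one positive and one negative example")
  }
  sn <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  acc <- (tp + tn) / n
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  denom <- sqrt(tp + fn) * sqrt(tp + fp) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fn * fp) / denom
  c(SN = sn, SP = sp, ACC = acc, F1 = f1, MCC = mcc)
}

#' Cross- and over-prediction rates and their ratios at a threshold
#'
#' CPR is the fraction of ligand-labelled residues called positive; OPR the
#' fraction of nonfunctional residues called positive. The ratios SN/CPR
#' and SN/OPR equal 1 for a random scorer (every class is thinned equally
#' by thresholding) and exceed 1 for a selective predictor. A zero rate is
#' floored at half a count (`1 / (2 * class size)`) before division and the
#' result flagged, since the true ratio is then only bounded from below.
#'
#' @param scores numeric propensities.
#' @param labels three-level labels.
#' @param threshold decision threshold.
#' @return a list with SN, CPR, OPR, CPRratio, OPRratio, and logical flags
#'   `cpr_floored`, `opr_floored`. CPR and its ratio are `NA` when no
#'   ligand-labelled residues exist.
#' @export
cross_over_rates <- function(scores, labels, threshold) {
  labels <- normalize_labels(labels)
  pos_call <- scores >= threshold
  n_carb <- sum(labels == "carbonylation")
  n_lig <- sum(labels == "ligand")
  n_non <- sum(labels == "nonfunctional")
  if (n_carb == 0) stop_data("no carbonylation-labelled residues")
  sn <- sum(pos_call & labels == "carbonylation") / n_carb
  cpr <- if (n_lig > 0) sum(pos_call & labels == "ligand") / n_lig else NA
  opr <- if (n_non > 0) {
    sum(pos_call & labels == "nonfunctional") / n_non
  } else NA
  ratio_of <- function(rate, class_n) {
    if (is.na(rate)) return(list(ratio = NA_real_, floored = FALSE))
    if (rate == 0) {
      list(ratio = sn / (1 / (2 * class_n)), floored = TRUE)
    } else {
      list(ratio = sn / rate, floored = FALSE)
    }
  }
  rc <- ratio_of(cpr, n_lig)
  ro <- ratio_of(opr, n_non)
  list(SN = sn, CPR = cpr, OPR = opr,
       CPRratio = rc$ratio, OPRratio = ro$ratio,
       cpr_floored = rc$floored, opr_floored = ro$floored)
}

# shared threshold sweep: per-class counts of calls at every distinct score
# threshold (descending), with an all-negative anchor above the max score.
# Tied scores move between classes together.
threshold_sweep <- function(scores, labels) {
  labels <- normalize_labels(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  n <- length(s)
  cum_carb <- cumsum(l == "carbonylation")
  cum_lig <- cumsum(l == "ligand")
  cum_non <- cumsum(l == "nonfunctional")
  last_of_tie <- c(s[-n] != s[-1], TRUE)  # last index of each tie block
  idx <- which(last_of_tie)
  data.frame(threshold = c(Inf, s[idx]),
             carb = c(0, cum_carb[idx]),
             lig = c(0, cum_lig[idx]),
             non = c(0, cum_non[idx]))
}

#' Evaluation curves and their areas
#'
#' Computes, over a shared descending threshold sweep: the ROC curve with
#' trapezoidal AUROC, the precision-recall curve with step-interpolated
#' AUPRC, and the cross-/over-prediction curves — CPR (resp. OPR) on the
#' y axis against SN on the x axis — with trapezoidal areas AUCPC and
#' AUOPC. A perfectly separating scorer gives AUROC 1 and AUCPC = AUOPC =
#' 0; a random scorer gives about 0.5 for all four areas.
#'
#' @param scores numeric propensities (finite).
#' @param labels three-level labels.
#' @return a list with data frames `roc`, `pr`, `cp`, `op` and numbers
#'   `AUROC`, `AUPRC`, `AUCPC`, `AUOPC` (`cp`/`AUCPC` are `NULL`/`NA` when
#'   no ligand-labelled residues exist).
#' @export
curves_and_areas <- function(scores, labels) {
  if (any(!is.finite(scores))) stop_data("scores must be finite")
  sw <- threshold_sweep(scores, labels)
  n_carb <- sw$carb[nrow(sw)]
  n_lig <- sw$lig[nrow(sw)]
  n_non <- sw$non[nrow(sw)]
  n_neg <- n_lig + n_non
  if (n_carb == 0 || n_neg == 0) {
    stop_data("curves are undefined with a single class")
  }
  tpr <- sw$carb / n_carb
  fpr <- (sw$lig + sw$non) / n_neg
  n_call <- sw$carb + sw$lig + sw$non
  precision <- ifelse(n_call > 0, sw$carb / n_call, 1)
  trap <- function(x, y) sum(diff(x) * (utils::head(y, -1) +
                                          utils::tail(y, -1)) / 2)
  auroc <- trap(fpr, tpr)
  # step interpolation: precision held at each achieved recall increment
  auprc <- sum(diff(tpr) * utils::tail(precision, -1))
  op <- data.frame(SN = tpr, OPR = sw$non / n_non,
                   threshold = sw$threshold)
  auopc <- trap(op$SN, op$OPR)
  if (n_lig > 0) {
    cp <- data.frame(SN = tpr, CPR = sw$lig / n_lig,
                     threshold = sw$threshold)
    aucpc <- trap(cp$SN, cp$CPR)
  } else {
    cp <- NULL
    aucpc <- NA_real_
  }
  list(roc = data.frame(FPR = fpr, TPR = tpr, threshold = sw$threshold),
       pr = data.frame(recall = tpr, precision = precision,
                       threshold = sw$threshold),
       cp = cp, op = op,
       AUROC = auroc, AUPRC = auprc, AUCPC = aucpc, AUOPC = auopc)
}

#' Partial AUC at low false positive rates, and its random-reference ratio
#'
#' AULC is the trapezoidal area under the ROC curve restricted to FPR in
#' `[0, fpr_cutoff]` (with linear interpolation of TPR at the cutoff). The
#' random reference is `fpr_cutoff^2 / 2` (the area under the diagonal), so
#' AULCratio = 1 for a random scorer and `2 / fpr_cutoff` for a perfect one.
#'
#' @param scores numeric propensities.
#' @param labels labels (three-level or 0/1).
#' @param fpr_cutoff FPR cutoff in (0, 1].
#' @return a list with `AULC` and `AULCratio`.
#' @export
aulc_ratio <- function(scores, labels, fpr_cutoff = 0.10) {
  if (fpr_cutoff <= 0 || fpr_cutoff > 1) {
    stop_config("fpr_cutoff must lie in (0, 1]")
  }
  cv <- curves_and_areas(scores, labels)
  fpr <- cv$roc$FPR
  tpr <- cv$roc$TPR
  keep <- fpr <= fpr_cutoff
  x <- fpr[keep]
  y <- tpr[keep]
  if (max(x) < fpr_cutoff && max(fpr) > fpr_cutoff) {
    # interpolate the curve at the cutoff
    i <- which(fpr > fpr_cutoff)[1]
    x0 <- fpr[i - 1]; y0 <- tpr[i - 1]
    frac <- (fpr_cutoff - x0) / (fpr[i] - x0)
    x <- c(x, fpr_cutoff)
    y <- c(y, y0 + frac * (tpr[i] - y0))
  }
  aulc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  list(AULC = aulc, AULCratio = aulc / (fpr_cutoff^2 / 2))
}

#' Threshold-optimal MCC and F1, and sensitivity at anchored specificity
#'
#' Sweeps every distinct score threshold exhaustively. The SP-anchored
#' sensitivities use the smallest threshold still achieving SP >= target
#' (the operating point closest to the target from above, which maximises
#' SN); the all-negative anchor does not count as an operating point, so the
#' anchored values are `NA` (flagged) when no real threshold reaches the
#' target.
#'
#' @param scores numeric propensities.
#' @param labels labels.
#' @param sp_targets specificity anchors (default 0.95 and 0.90).
#' @return a list with `MCCmax`, `F1max`, their thresholds, and `SN_at_SP`
#'   (named numeric, `NA` where unreachable) with `sp_unreachable` flags.
#' @export
threshold_optima <- function(scores, labels, sp_targets = c(0.95, 0.90)) {
  sw <- threshold_sweep(scores, labels)
  n_carb <- sw$carb[nrow(sw)]
  n_neg <- sw$lig[nrow(sw)] + sw$non[nrow(sw)]
  if (n_carb == 0 || n_neg == 0) {
    stop_data("need both classes to sweep thresholds")
  }
  tp <- sw$carb
  fp <- sw$lig + sw$non
  fn <- n_carb - tp
  tn <- n_neg - fp
  f1 <- ifelse(2 * tp + fp + fn == 0, 0, 2 * tp / (2 * tp + fp + fn))
  denom <- sqrt(tp + fn) * sqrt(tp + fp) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- ifelse(denom == 0, 0, (tp * tn - fn * fp) / denom)
  sn <- tp / n_carb
  sp <- tn / n_neg
  real <- sw$threshold < Inf  # exclude the all-negative anchor
  sn_at <- vapply(sp_targets, function(target) {
    ok <- which(real & sp >= target)
    if (length(ok) == 0) return(NA_real_)
    # sp is nonincreasing down the sweep: the last qualifying row is the
    # smallest threshold with SP >= target, hence the largest SN
    sn[ok[length(ok)]]
  }, 0)
  names(sn_at) <- paste0("SP", sp_targets * 100)
  list(MCCmax = max(mcc), MCC_threshold = sw$threshold[which.max(mcc)],
       F1max = max(f1), F1_threshold = sw$threshold[which.max(f1)],
       SN_at_SP = sn_at, sp_unreachable = is.na(sn_at))
}

#' Threshold achieving a specificity target
#'
#' @inheritParams threshold_optima
#' @param sp_target single specificity target.
#' @return the smallest real threshold with SP >= target (`NA` if none).
#' @export
threshold_at_sp <- function(scores, labels, sp_target = 0.95) {
  sw <- threshold_sweep(scores, labels)
  n_neg <- sw$lig[nrow(sw)] + sw$non[nrow(sw)]
  sp <- (n_neg - (sw$lig + sw$non)) / n_neg
  ok <- which(sw$threshold < Inf & sp >= sp_target)
  if (length(ok) == 0) return(NA_real_)
  sw$threshold[ok[length(ok)]]
}

#' Full evaluation report for one score vector
#'
#' @param scores numeric propensities.
#' @param labels three-level labels.
#' @param sp_targets specificity anchors for rates and ratios.
#' @param fpr_cutoffs FPR cutoffs for the partial-AUC ratios.
#' @return a nested list: areas, threshold optima, and per-anchor
#'   CPR/OPR/ratios.
#' @export
evaluation_report <- function(scores, labels, sp_targets = c(0.95, 0.90),
                              fpr_cutoffs = c(0.05, 0.10)) {
  cv <- curves_and_areas(scores, labels)
  opt <- threshold_optima(scores, labels, sp_targets)
  aulc <- lapply(fpr_cutoffs, function(c0) aulc_ratio(scores, labels, c0))
  names(aulc) <- paste0("FPR", fpr_cutoffs * 100)
  anchors <- lapply(sp_targets, function(target) {
    thr <- threshold_at_sp(scores, labels, target)
    if (is.na(thr)) return(NULL)
    cross_over_rates(scores, labels, thr)
  })
  names(anchors) <- paste0("SP", sp_targets * 100)
  list(AUROC = cv$AUROC, AUPRC = cv$AUPRC, AUCPC = cv$AUCPC,
       AUOPC = cv$AUOPC, optima = opt, aulc = aulc, anchors = anchors)
}

#' Bootstrap significance comparison of two score vectors
#'
#' Stratified subsampling: each class is independently subsampled at
#' fraction `frac` (without replacement), `n_reps` times; the metric is
#' computed for both methods on each replicate. Normality of each method's
#' replicate values is assessed with the Anderson-Darling test at 0.05;
#' when either sample departs from normality the Wilcoxon rank-sum test
#' compares the methods, otherwise Student's t-test does. Significance is
#' declared at p < 0.001.
#'
#' @param scores_a,scores_b score vectors of the two methods on identical
#'   examples.
#' @param labels three-level labels.
#' @param metric_fn function(scores, labels) -> single number (default
#'   AUROC).
#' @param n_reps number of replicates (default 10).
#' @param frac per-class subsampling fraction (default 0.5).
#' @param seed integer seed.
#' @return a list with per-method `mean`, `sd`, the replicate `values`
#'   matrix, `test` used, `p_value` and logical `significant`.
#' @export
bootstrap_significance <- function(scores_a, scores_b, labels,
                                   metric_fn = function(s, l) {
                                     curves_and_areas(s, l)$AUROC
                                   },
                                   n_reps = 10L, frac = 0.5, seed = 1L) {
  if (n_reps < 2) stop_config("n_reps must be at least 2")
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop_data("scores and labels must have identical length")
  }
  labels <- normalize_labels(labels)
  vals <- matrix(NA_real_, n_reps, 2,
                 dimnames = list(NULL, c("A", "B")))
  for (r in seq_len(n_reps)) {
    idx <- with_seed(derive_seed(seed, "bootstrap", r), {
      unlist(lapply(unique(labels), function(lab) {
        members <- which(labels == lab)
        members[sample.int(length(members),
                           max(1, round(frac * length(members))))]
      }))
    })
    vals[r, "A"] <- metric_fn(scores_a[idx], labels[idx])
    vals[r, "B"] <- metric_fn(scores_b[idx], labels[idx])
  }
  if (isTRUE(all.equal(vals[, "A"], vals[, "B"]))) {
    test <- "none (identical replicate values)"
    p <- 1
  } else {
    normal <- vapply(c("A", "B"), function(m) {
      x <- vals[, m]
      if (stats::sd(x) < 1e-12) return(FALSE)
      nortest::ad.test(x)$p.value >= 0.05
    }, TRUE)
    if (all(normal)) {
      test <- "t"
      p <- stats::t.test(vals[, "A"], vals[, "B"])$p.value
    } else {
      test <- "wilcoxon"
      p <- suppressWarnings(
        stats::wilcox.test(vals[, "A"], vals[, "B"])$p.value)
    }
  }
  list(mean = colMeans(vals), sd = apply(vals, 2, stats::sd),
       values = vals, test = test, p_value = p,
       significant = p < 0.001)
}
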