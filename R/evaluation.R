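# Leakage-safe evaluation: stratified patient-level cross-validation with an
# internal validation subset, rank-based discrimination metrics, operating
# point analysis, calibration, bootstrap confidence intervals and subgroup
# robustness.

#' Stratified patient-level folds for multi-label outcomes
#'
#' Iterative multi-label stratification: labels are processed scarcest-first
#' and each patient is placed in the fold with the greatest remaining demand
#' for that label, so every outcome's prevalence is approximately preserved
#' in every fold. All of a patient's records stay in one fold. Each fold also
#' carries an internal validation subset (10% of its training patients,
#' stratified the same way) for early stopping and threshold selection.
#'
#' @param labels patients x outcomes 0/1 matrix.
#' @param K number of folds (>= 2).
#' @param seed RNG seed; identical seeds give identical folds.
#' @param val_fraction fraction of training patients in the internal
#'   validation subset.
#' @return an `agfn_fold_plan`: `assign` (fold index per patient), `folds`
#'   (test indices per fold) and `val` (validation indices per fold, disjoint
#'   from that fold's test set).
#' @export
make_folds <- function(labels, K = 5L, seed = 1L, val_fraction = 0.10) {
  L <- as.matrix(labels)
  n <- nrow(L)
  if (K < 2L) stop("K must be >= 2")
  if (n < K) stop("need at least K patients")
  scarce <- colSums(L)
  low <- scarce < K & scarce > 0
  if (any(low)) {
    warning(sprintf("outcome(s) %s have fewer than K positive patients; %s",
                    paste(which(low), collapse = ", "),
                    "stratification is best-effort"))
  }
  assign <- with_seed(seed, iterative_stratify(L, K))
  folds <- lapply(seq_len(K), function(f) which(assign == f))
  val <- with_seed(seed + 1L, lapply(seq_len(K), function(f) {
    tr <- which(assign != f)
    Kin <- max(2L, round(1 / val_fraction))
    sub <- iterative_stratify(L[tr, , drop = FALSE], Kin)
    tr[sub == 1L]
  }))
  plan <- list(assign = assign, folds = folds, val = val, K = as.integer(K),
               seed = as.integer(seed))
  class(plan) <- "agfn_fold_plan"
  plan
}

# Sechidis-style iterative stratification; returns a fold index per row.
iterative_stratify <- function(L, K) {
  n <- nrow(L)
  cap <- rep(n / K, K)                       # remaining desired fold sizes
  want <- matrix(rep(colSums(L) / K, each = K), K, ncol(L))
  assign <- rep(NA_integer_, n)
  remaining <- rep(TRUE, n)
  repeat {
    counts <- colSums(L[remaining, , drop = FALSE])
    active <- which(counts > 0)
    if (!length(active)) break
    j <- active[which.min(counts[active])]
    for (i in sample(which(remaining & L[, j] == 1))) {
      best <- which(want[, j] == max(want[, j]))
      if (length(best) > 1L) {
        best <- best[cap[best] == max(cap[best])]
        if (length(best) > 1L) best <- sample(best, 1L)
      }
      assign[i] <- best
      remaining[i] <- FALSE
      want[best, L[i, ] == 1] <- want[best, L[i, ] == 1] - 1
      cap[best] <- cap[best] - 1
    }
  }
  for (i in sample(which(remaining))) {
    best <- which(cap == max(cap))
    if (length(best) > 1L) best <- sample(best, 1L)
    assign[i] <- best
    cap[best] <- cap[best] - 1
  }
  assign
}

#' Operating-point metrics from confusion counts
#'
#' `sensitivity = TP/(TP+FN)`, `specificity = TN/(TN+FP)`,
#' `PPV = TP/(TP+FP)`, `NPV = TN/(TN+FN)`, and the number needed to screen
#' `NNS = (TP+FP)/TP`. Metrics with a zero denominator return `NA`.
#'
#' @param tp,fp,tn,fn non-negative confusion counts.
#' @return list of the five metrics.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  rat <- function(a, b) if (b > 0) a / b else NA_real_
  list(sensitivity = rat(tp, tp + fn),
       specificity = rat(tn, tn + fp),
       ppv = rat(tp, tp + fp),
       npv = rat(tn, tn + fn),
       nns = rat(tp + fp, tp))
}

#' Rank-statistic ROC-AUC with half credit for ties
#'
#' @param y 0/1 labels, `scores` numeric predictions.
#' @param scores numeric scores.
#' @return AUC in `[0, 1]`, or `NA` when only one class is present.
#' @export
rank_auc <- function(y, scores) {
  y <- as.integer(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision over distinct score thresholds (ties grouped).
#'
#' @inheritParams rank_auc
#' @return AUPRC in `[0, 1]`, or `NA` with a single class.
#' @export
auprc <- function(y, scores) {
  y <- as.integer(y)
  npos <- sum(y == 1)
  if (npos == 0 || npos == length(y)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  grp <- cumsum(!duplicated(ss))
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tp_g <- tp[last]; fp_g <- fp[last]
  prec <- tp_g / (tp_g + fp_g)
  dtp <- diff(c(0, tp_g))
  sum(dtp * prec) / npos
}

#' Select a decision threshold on the internal validation subset
#'
#' `mode = "f1"` maximizes F1; `mode = "sens92"` picks the highest threshold
#' whose sensitivity still meets `min_sens` (maximizing specificity under the
#' sensitivity constraint), falling back to the lowest candidate when the
#' constraint is infeasible.
#'
#' @param y,scores validation labels and scores.
#' @param mode `"f1"` or `"sens92"`.
#' @param min_sens sensitivity floor for `"sens92"`.
#' @return scalar threshold.
#' @export
select_threshold <- function(y, scores, mode = c("f1", "sens92"),
                             min_sens = 0.92) {
  mode <- match.arg(mode)
  y <- as.integer(y)
  cand <- sort(unique(scores))
  if (length(cand) > 1L) {
    cand <- c(cand[1L] - 1e-9, (cand[-1L] + cand[-length(cand)]) / 2)
  }
  stat <- vapply(cand, function(th) {
    pred <- as.integer(scores >= th)
    tp <- sum(pred & y); fp <- sum(pred & !y); fn <- sum(!pred & y)
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
    c(sens, f1)
  }, numeric(2))
  if (mode == "f1") return(cand[which.max(stat[2L, ])])
  ok <- which(stat[1L, ] >= min_sens)
  if (!length(ok)) return(cand[1L])
  cand[max(ok)]
}

#' Threshold-based discrimination metrics plus AUC/AUPRC
#'
#' @param y,scores test labels and scores.
#' @param threshold decision threshold (select it on validation data with
#'   [select_threshold()], never on the test partition).
#' @return list with `auc`, `auprc`, `precision`, `recall`, `f1` and the
#'   confusion counts.
#' @export
discrimination <- function(y, scores, threshold = 0.5) {
  y <- as.integer(y)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred & y); fp <- sum(pred & !y)
  tn <- sum(!pred & !y); fn <- sum(!pred & y)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
    2 * prec * rec / (prec + rec)
  } else NA_real_
  list(auc = rank_auc(y, scores), auprc = auprc(y, scores),
       precision = prec, recall = rec, f1 = f1,
       counts = c(tp = tp, fp = fp, tn = tn, fn = fn))
}

#' Calibration summary: Brier score, reliability bins, slope, in-the-large
#'
#' Brier is the mean squared difference between predicted probability and
#' outcome. The reliability table uses 10 equal-width probability bins. The
#' calibration slope is the coefficient of a logistic recalibration of `y`
#' on `logit(p)`; calibration-in-the-large is the intercept of the same
#' regression with the slope fixed at 1 (offset fit). Perfect calibration
#' gives slope 1 and in-the-large 0.
#'
#' @param y 0/1 outcomes, `p` predicted probabilities in `[0, 1]` (boundary
#'   values are clamped for the logistic recalibration fit only).
#' @param p predicted probabilities.
#' @param bins number of equal-width reliability bins.
#' @return list with `brier`, `reliability` (data frame), `slope`,
#'   `intercept` and `in_the_large`.
#' @export
calibration <- function(y, p, bins = 10L) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("predicted probabilities must lie in [0, 1]")
  }
  if (length(y) < bins) stop("need at least `bins` observations")
  y <- as.integer(y)
  brier <- mean((p - y)^2)
  cutp <- cut(p, breaks = seq(0, 1, length.out = bins + 1L),
              include.lowest = TRUE)
  rel <- data.frame(
    bin = levels(cutp),
    mean_pred = as.numeric(tapply(p, cutp, mean)),
    event_rate = as.numeric(tapply(y, cutp, mean)),
    n = as.integer(table(cutp)))
  lp <- stats::qlogis(pmin(pmax(p, 1e-8), 1 - 1e-8))
  fit <- stats::glm(y ~ lp, family = stats::binomial())
  off <- stats::glm(y ~ 1 + offset(lp), family = stats::binomial())
  list(brier = brier, reliability = rel,
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       in_the_large = unname(stats::coef(off)[1L]))
}

#' Percentile bootstrap confidence interval for a patient-level metric
#'
#' @param metric_fn function of resampled `data` rows returning a scalar.
#' @param data vector, matrix or data frame resampled by row.
#' @param B bootstrap iterations (>= 100).
#' @param seed RNG seed; same seed, same bounds.
#' @param level confidence level.
#' @return named vector `c(lower, upper)`; `NA` bounds with a warning when
#'   the metric is undefined on more than 10% of resamples.
#' @export
bootstrap_ci <- function(metric_fn, data, B = 1000L, seed = 1L,
                         level = 0.95) {
  if (B < 100L) stop("B must be >= 100")
  n <- if (is.null(dim(data))) length(data) else nrow(data)
  take <- if (is.null(dim(data))) function(i) data[i] else
    function(i) data[i, , drop = FALSE]
  vals <- with_seed(seed, vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    as.numeric(metric_fn(take(idx)))
  }, numeric(1)))
  bad <- mean(!is.finite(vals))
  if (bad > 0.10) {
    warning(sprintf("metric undefined on %.0f%% of resamples", 100 * bad))
    return(c(lower = NA_real_, upper = NA_real_))
  }
  a <- (1 - level) / 2
  q <- stats::quantile(vals[is.finite(vals)], c(a, 1 - a), type = 7,
                       names = FALSE)
  c(lower = q[1L], upper = q[2L])
}

#' Per-subgroup discrimination and calibration
#'
#' Computes AUC and Brier within each level of `group` plus the maximum
#' absolute deviation from the pooled values. Degenerate groups (fewer than
#' 2 members or a single outcome class) are skipped with a warning.
#'
#' @param y,p labels and predicted probabilities.
#' @param group factor-like subgroup labels (sex, age band, site, ...).
#' @return list with `pooled`, `by_group` (data frame) and `max_abs_dev`.
#' @export
subgroup_metrics <- function(y, p, group) {
  y <- as.integer(y)
  pooled <- c(auc = rank_auc(y, p), brier = mean((p - y)^2))
  lv <- unique(as.character(group))
  rows <- lapply(lv, function(g) {
    idx <- which(as.character(group) == g)
    if (length(idx) < 2L || length(unique(y[idx])) < 2L) {
      warning(sprintf("subgroup '%s' is degenerate; skipped", g))
      return(NULL)
    }
    data.frame(group = g, n = length(idx),
               auc = rank_auc(y[idx], p[idx]),
               brier = mean((p[idx] - y[idx])^2))
  })
  by_group <- do.call(rbind, rows)
  dev <- if (is.null(by_group)) NA_real_ else
    max(abs(by_group$auc - pooled["auc"]),
        abs(by_group$brier - pooled["brier"]))
  list(pooled = pooled, by_group = by_group, max_abs_dev = dev)
}

#' Per-outcome metric report with bootstrap confidence intervals
#'
#' Assembles discrimination (threshold chosen on the validation scores),
#' calibration and bootstrap CIs per outcome, plus the arithmetic mean over
#' outcomes of each metric.
#'
#' @param y_test,p_test label/probability matrices (patients x outcomes).
#' @param y_val,p_val validation label/probability matrices used only for
#'   threshold selection.
#' @param mode threshold mode passed to [select_threshold()].
#' @param B bootstrap iterations (0 disables CIs).
#' @param seed RNG seed for the bootstrap.
#' @return an `agfn_metric_report`: data frame `per_outcome`, list `mean`.
#' @export
metric_report <- function(y_test, p_test, y_val, p_val,
                          mode = "f1", B = 1000L, seed = 1L) {
  n_out <- ncol(y_test)
  onames <- colnames(y_test)
  if (is.null(onames)) onames <- paste0("outcome_", seq_len(n_out))
  rows <- vector("list", n_out)
  for (j in seq_len(n_out)) {
    th <- select_threshold(y_val[, j], p_val[, j], mode = mode)
    d <- discrimination(y_test[, j], p_test[, j], threshold = th)
    cal <- calibration(y_test[, j],
                       pmin(pmax(p_test[, j], 1e-8), 1 - 1e-8))
    ci <- if (B >= 100L) {
      dat <- cbind(y_test[, j], p_test[, j])
      bootstrap_ci(function(dd) rank_auc(dd[, 1L], dd[, 2L]), dat,
                   B = B, seed = seed + j)
    } else c(lower = NA_real_, upper = NA_real_)
    rows[[j]] <- data.frame(outcome = onames[j], threshold = th,
                            auc = d$auc, auc_lower = ci["lower"],
                            auc_upper = ci["upper"], auprc = d$auprc,
                            precision = d$precision, recall = d$recall,
                            f1 = d$f1, brier = cal$brier,
                            cal_slope = cal$slope,
                            cal_in_large = cal$in_the_large)
  }
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  rep <- list(per_outcome = per,
              mean = list(auc = mean(per$auc, na.rm = TRUE),
                          auprc = mean(per$auprc, na.rm = TRUE),
                          brier = mean(per$brier, na.rm = TRUE),
                          f1 = mean(per$f1, na.rm = TRUE)))
  class(rep) <- "agfn_metric_report"
  rep
}

#' @export
print.agfn_metric_report <- function(x, ...) {
  cat("Per-outcome metrics:\n")
  print(cbind(x$per_outcome[, "outcome", drop = FALSE],
              round(x$per_outcome[, -1L], 3)))
  cat(sprintf("Mean: AUC %.3f | AUPRC %.3f | Brier %.3f\n",
              x$mean$auc, x$mean$auprc, x$mean$brier))
  invisible(x)
}
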