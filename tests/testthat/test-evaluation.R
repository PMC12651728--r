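test_that("stratified folds partition patients and preserve outcome prevalence", {
  set.seed(1)
  L <- matrix(rbinom(1000 * 6, 1, rep(c(.1, .15, .2, .18, .06, .2),
                                      each = 1000)), 1000, 6)
  plan <- make_folds(L, K = 5, seed = 3)
  sizes <- lengths(plan$folds)
  expect_equal(sum(sizes), 1000L)
  expect_true(all(abs(sizes - 200L) <= 1L))
  expect_setequal(unlist(plan$folds), 1:1000)
  # prevalence preserved per fold (single outcome at 0.10 within [0.08, 0.12])
  prev1 <- mean(L[, 1])
  for (f in 1:5) {
    pf <- colMeans(L[plan$folds[[f]], , drop = FALSE])
    expect_true(all(abs(pf - colMeans(L)) <= 0.2 * pmax(colMeans(L), 0.05)))
  }
  L1 <- cbind(rbinom(1000, 1, 0.10))
  plan1 <- make_folds(L1, K = 5, seed = 3)
  for (f in 1:5) {
    expect_gte(mean(L1[plan1$folds[[f]], ]), 0.08 - 1e-9)
    expect_lte(mean(L1[plan1$folds[[f]], ]), 0.12 + 1e-9)
  }
  # determinism and fold audit: train/val/test disjoint within every fold
  plan2 <- make_folds(L, K = 5, seed = 3)
  expect_identical(plan$assign, plan2$assign)
  for (f in 1:5) {
    test_idx <- plan$folds[[f]]
    val_idx <- plan$val[[f]]
    train_idx <- setdiff(seq_len(1000), c(test_idx, val_idx))
    expect_partition_disjoint(train_idx, val_idx, test_idx)
    expect_equal(sort(c(train_idx, val_idx, test_idx)), 1:1000)
    expect_equal(length(val_idx) / (1000 - length(test_idx)), 0.10,
                 tolerance = 0.03)
  }
  expect_warning(make_folds(cbind(c(1, 1, rep(0, 48))), K = 5, seed = 1),
                 "fewer than K")
})

test_that("operating-point metrics reproduce the printed confusion counts", {
  # counts: 249 of 271 events detected; 1272 of 1429 non-events correct
  m <- confusion_metrics(tp = 249, fp = 1429 - 1272, tn = 1272,
                         fn = 271 - 249)
  expect_equal(round(m$sensitivity, 2), 0.92)
  expect_equal(round(m$specificity, 2), 0.89)
  expect_equal(round(m$ppv, 2), 0.61)
  expect_equal(round(m$npv, 2), 0.98)
  expect_equal(round(m$nns, 1), 1.6)
  # perfect classifier
  p <- confusion_metrics(10, 0, 20, 0)
  expect_equal(unlist(p), c(sensitivity = 1, specificity = 1, ppv = 1,
                            npv = 1, nns = 1))
  # uniform confusion
  u <- confusion_metrics(25, 25, 25, 25)
  expect_equal(u$sensitivity, 0.5)
  expect_equal(u$nns, 2.0)
  # undefined sentinels
  expect_true(is.na(confusion_metrics(0, 0, 5, 5)$ppv))
})

test_that("the rank AUC matches the all-pairs oracle with half-credit ties", {
  pair_auc <- function(y, s) {
    pos <- which(y == 1); neg <- which(y == 0)
    tot <- 0
    for (i in pos) for (j in neg) {
      tot <- tot + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
    }
    tot / (length(pos) * length(neg))
  }
  set.seed(2)
  for (rep in 1:4) {
    n <- 200
    y <- rbinom(n, 1, 0.3)
    s <- round(rnorm(n), 1)                  # coarse scores force ties
    expect_equal(rank_auc(y, s), pair_auc(y, s), tolerance = 1e-12)
  }
  # agreement with an independent library implementation
  y <- rbinom(150, 1, 0.4); s <- rnorm(150)
  expect_equal(rank_auc(y, s),
               as.numeric(suppressMessages(pROC::auc(y, s,
                                                     direction = "<"))),
               tolerance = 1e-10)
  # closed cases
  expect_equal(rank_auc(c(0, 0, 1, 1), c(.1, .2, .8, .9)), 1)
  expect_equal(rank_auc(c(0, 1, 0, 1), rep(0.4, 4)), 0.5)
  expect_true(is.na(rank_auc(c(1, 1), c(.2, .3))))
  # random scores sit near 0.5
  set.seed(3)
  y <- rbinom(4000, 1, 0.5); s <- rnorm(4000)
  se <- sqrt(0.25 / sum(y == 1) + 0.25 / sum(y == 0))
  expect_lt(abs(rank_auc(y, s) - 0.5), 3 * se * 2)
})

test_that("average precision is 1 under perfect separation and sane under ties", {
  expect_equal(auprc(c(0, 0, 1, 1), c(.1, .2, .8, .9)), 1)
  expect_true(is.na(auprc(c(1, 1), c(.5, .6))))
  set.seed(4)
  y <- rbinom(300, 1, 0.3); s <- round(runif(300), 1)
  v <- auprc(y, s)
  expect_gte(v, 0); expect_lte(v, 1)
})

test_that("threshold selection respects its mode and sensitivity is monotone in the threshold", {
  set.seed(5)
  y <- rbinom(400, 1, 0.3)
  s <- y * 0.3 + runif(400) * 0.7
  th_f1 <- select_threshold(y, s, mode = "f1")
  th_sens <- select_threshold(y, s, mode = "sens92")
  d <- discrimination(y, s, th_sens)
  expect_gte(d$recall, 0.92)
  expect_lte(th_sens, th_f1 + 1e-9)          # high sensitivity needs a lower bar
  ths <- seq(0, 1, by = 0.05)
  sens <- vapply(ths, function(th) {
    pred <- as.integer(s >= th)
    sum(pred & y) / sum(y)
  }, numeric(1))
  expect_true(all(diff(sens) <= 1e-12))
})

test_that("calibration summaries match closed forms and recover a known slope", {
  y <- c(rep(1, 5), rep(0, 5))
  expect_equal(calibration(y, as.numeric(y))$brier, 0)     # perfect forecasts
  expect_equal(calibration(y, rep(0.5, 10))$brier, 0.25)   # constant 0.5
  expect_error(calibration(y, c(rep(0.5, 9), 1.2)), "lie in")
  set.seed(6)
  p <- runif(10000, 0.02, 0.98)
  yy <- rbinom(10000, 1, p)                 # y ~ Bernoulli(p): slope 1
  cal <- calibration(yy, p)
  expect_gt(cal$slope, 0.9); expect_lt(cal$slope, 1.1)
  expect_lt(abs(cal$in_the_large), 0.1)
  expect_equal(sum(cal$reliability$n), 10000L)
  expect_true(all(diff(cal$reliability$mean_pred) > 0, na.rm = TRUE))
})

test_that("the percentile bootstrap is deterministic, degenerate on constants, and covers", {
  set.seed(1); x <- rnorm(50)
  a <- bootstrap_ci(mean, x, B = 200, seed = 9)
  b <- bootstrap_ci(mean, x, B = 200, seed = 9)
  expect_identical(a, b)
  cc <- bootstrap_ci(function(v) 1.0, x, B = 150, seed = 1)
  expect_equal(unname(cc[1]), unname(cc[2]))
  expect_warning(nb <- bootstrap_ci(function(v) NA_real_, x, B = 100,
                                    seed = 1), "undefined")
  expect_true(all(is.na(nb)))
  # coverage of the mean of N(0,1), n = 100
  set.seed(10)
  hits <- mean(vapply(1:150, function(r) {
    xx <- rnorm(100)
    ci <- bootstrap_ci(mean, xx, B = 200, seed = r)
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1)))
  expect_gt(hits, 0.92 - 0.03)
  expect_lt(hits, 0.98 + 0.02)
})

test_that("subgroup metrics flag injected miscalibration and skip degenerate groups", {
  set.seed(7)
  n <- 600
  p <- runif(n, 0.05, 0.95)
  y <- rbinom(n, 1, p)
  site <- rep(c("A", "B"), each = n / 2)
  # identical distributions: small deviations
  sg <- subgroup_metrics(y, p, site)
  expect_lt(sg$max_abs_dev, 0.1)
  # inject miscalibration at site B
  p2 <- p
  p2[site == "B"] <- pmin(pmax(p[site == "B"] + 0.35, 0.01), 0.99)
  sg2 <- subgroup_metrics(y, p2, site)
  bB <- sg2$by_group$brier[sg2$by_group$group == "B"]
  expect_gt(bB, sg2$pooled["brier"])
  expect_warning(sg3 <- subgroup_metrics(y[1:11], p[1:11],
                                         c(rep("A", 10), "solo")),
                 "degenerate")
  expect_false("solo" %in% sg3$by_group$group)
})

test_that("the metric report aggregates per-outcome metrics with the arithmetic mean", {
  set.seed(8)
  n <- 150
  y <- matrix(rbinom(n * 3, 1, 0.3), n, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  p <- matrix(pmin(pmax(y * 0.4 + runif(n * 3) * 0.6, 1e-4), 1 - 1e-4), n, 3)
  rep <- metric_report(y, p, y, p, B = 100, seed = 1)
  expect_equal(rep$mean$auc, mean(rep$per_outcome$auc), tolerance = 1e-12)
  expect_true(all(rep$per_outcome$auc_lower <= rep$per_outcome$auc + 1e-9))
  expect_true(all(rep$per_outcome$auc_upper >= rep$per_outcome$auc - 1e-9))
  expect_true(all(rep$per_outcome$brier >= 0 & rep$per_outcome$brier <= 1))
})
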