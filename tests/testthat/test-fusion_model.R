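test_that("neighborhood attention reduces to its closed forms", {
  # single neighbor: softmax of one logit returns that neighbor's value
  one <- neighborhood_attention(q = c(0.3), K = cbind(2), V = cbind(c(7)))
  expect_equal(one$out, 7)
  expect_equal(one$weights, 1)
  # identical keys: uniform weights over the neighborhood
  u <- neighborhood_attention(q = c(1, 1), K = rbind(c(1, 0), c(1, 0), c(1, 0)),
                              V = diag(3))
  expect_equal(u$weights, rep(1 / 3, 3))
  # d_k = 1 with logits (0, ln 3): weights (0.25, 0.75)
  hand <- neighborhood_attention(q = 1, K = rbind(0, log(3)),
                                 V = rbind(10, 20))
  expect_equal(hand$weights, c(0.25, 0.75), tolerance = 1e-12)
  expect_equal(hand$out, 0.25 * 10 + 0.75 * 20)
  expect_equal(sum(hand$weights), 1)
})

test_that("the sigmoid head produces independent probabilities with the expected values", {
  H <- rbind(c(0, 0), c(1, 1))
  W <- matrix(0, 2, 6)
  p0 <- output_probs(H, W)
  expect_true(all(p0 == 0.5))                     # logit 0
  W2 <- matrix(c(2, 0), 2, 1)
  expect_equal(output_probs(rbind(c(1, 0)), W2)[1, 1], 0.8808, tolerance = 1e-4)
  # monotone in the logit
  logits <- seq(-6, 6, by = 0.5)
  probs <- stats::plogis(logits)
  expect_true(all(diff(probs) > 0))
  expect_true(all(probs > 0 & probs < 1))
})

test_that("configurations outside the validated search ranges are rejected", {
  expect_error(fusion_config(heads = 3), "heads")
  expect_error(fusion_config(hidden = 100), "hidden")
  expect_error(fusion_config(lr = 5e-3), "lr")
  expect_error(fusion_config(dropout = 0.9), "dropout")
  cfg <- fusion_config(heads = 4, hidden = 128)
  expect_equal(cfg$d_k, 32L)
})

test_that("training is deterministic, the loss decreases early, and validation labels never reach a gradient", {
  bl <- label_blobs(n = 50, d = 5, shift = 2, seed = 21)
  # build a miniature tensor-like input through the real pipeline
  ch <- simulate_cohort(sim_config(n_patients = 80, seed = 31))
  pts <- ch$statics$patient_id
  tr_ids <- pts[1:60]; va_ids <- pts[61:80]
  pre <- preprocess_fit(ch, tr_ids)
  tr <- preprocess_transform(ch, pre, tr_ids)
  va <- preprocess_transform(ch, pre, va_ids)
  y_tr <- agfn:::outcome_labels(ch, tr_ids)
  y_va <- agfn:::outcome_labels(ch, va_ids)
  enc <- train_encoder(agfn:::tensor_summary_features(tr), y_tr, epochs = 8,
                       seed = 1)
  g <- build_graph(enc$embeddings, k_base = 6, k_max = 12)
  att <- attach_nodes(g, encoder_embed(enc, agfn:::tensor_summary_features(va)))
  cfg <- fusion_config(hidden = 64, channels = 8, gru_hidden = 12, lr = 1e-3,
                       dropout = 0, max_epochs = 8, patience = 20, seed = 4)
  m1 <- train_fold(tr, y_tr, g, cfg, val = va, y_val = y_va, val_attach = att)
  m2 <- train_fold(tr, y_tr, g, cfg, val = va, y_val = y_va, val_attach = att)
  expect_identical(m1$val_auc_trace, m2$val_auc_trace)
  expect_identical(m1$params, m2$params)
  # without dropout the full-batch loss decreases over the first epochs
  expect_true(all(diff(m1$loss_trace[1:5]) < 0))

  # poisoned validation labels: training trajectory (losses) identical;
  # only the early-stopping bookkeeping may differ
  y_poison <- y_va
  y_poison[] <- 1L - y_poison
  m3 <- train_fold(tr, y_tr, g, cfg, val = va, y_val = y_poison,
                   val_attach = att)
  expect_identical(m1$loss_trace, m3$loss_trace)

  # prediction is deterministic, frozen, and permutation equivariant
  p1 <- predict_heldout(m1, va, att)
  snap <- serialize(m1$params, NULL)
  p2 <- predict_heldout(m1, va, att)
  expect_identical(serialize(m1$params, NULL), snap)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 < 1))

  perm <- rev(seq_along(va_ids))
  va_perm <- va
  va_perm$X <- va$X[perm, , , drop = FALSE]
  va_perm$M <- va$M[perm, , , drop = FALSE]
  va_perm$S <- va$S[perm, , drop = FALSE]
  va_perm$patient_ids <- va$patient_ids[perm]
  att_perm <- list(neighbors = att$neighbors[perm], weights = att$weights[perm],
                   k = att$k[perm], rho = att$rho[perm])
  expect_equal(predict_heldout(m1, va_perm, att_perm), p1[perm, ],
               tolerance = 1e-10)
})

test_that("outcomes without positive training labels are skipped with a warning", {
  ch <- simulate_cohort(sim_config(n_patients = 40, seed = 41))
  pts <- ch$statics$patient_id
  pre <- preprocess_fit(ch, pts)
  tr <- preprocess_transform(ch, pre, pts)
  y <- agfn:::outcome_labels(ch, pts)
  y[, 2] <- 0L
  enc <- train_encoder(agfn:::tensor_summary_features(tr), y, epochs = 4,
                       seed = 1)
  g <- build_graph(enc$embeddings, k_base = 5, k_max = 10)
  cfg <- fusion_config(hidden = 64, channels = 8, gru_hidden = 12, lr = 1e-3,
                       dropout = 0, max_epochs = 2, refresh_every = 0, seed = 1)
  expect_warning(train_fold(tr, y, g, cfg), "no positive")
})

test_that("with a frozen trunk the per-outcome heads are decoupled", {
  ad <- asNamespace("agfn")
  set.seed(11)
  H <- matrix(rnorm(40 * 6), 40, 6)                # frozen trunk states
  y <- matrix(rbinom(40 * 3, 1, 0.4), 40, 3)
  train_head <- function(yy) {
    W <- matrix(0, 6, 3); b <- matrix(0, 1, 3)
    for (it in 1:200) {
      logit <- sweep(H %*% W, 2, as.vector(b), "+")
      gl <- (agfn:::sigm(logit) - yy) / 40
      W <- W - 0.5 * crossprod(H, gl)
      b <- b - 0.5 * matrix(colSums(gl), 1)
    }
    stats::plogis(sweep(H %*% W, 2, as.vector(b), "+"))
  }
  base <- train_head(y)
  y2 <- y
  y2[, 2] <- 1L - y2[, 2]                          # perturb only outcome 2
  pert <- train_head(y2)
  expect_equal(pert[, c(1, 3)], base[, c(1, 3)], tolerance = 1e-12)
  expect_gt(max(abs(pert[, 2] - base[, 2])), 0.1)
})

test_that("unknown variables at prediction time are reported", {
  tf <- trained_fold()
  bad <- tf$tensors$val
  bad$variables <- c(bad$variables[-1], "mystery_lab")
  expect_error(predict_heldout(tf$model, bad, tf$attach_val), "mystery_lab")
})
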