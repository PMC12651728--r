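# End-to-end orchestration of one cross-validation fold and the full
# stratified K-fold loop: fold-wise preprocessing, contrastive embedding,
# density-adaptive graph construction, fusion-model training, frozen-state
# prediction and metric aggregation.

#' Run the full pipeline on one patient-level fold
#'
#' Executes the training/evaluation loop for a single fold: fit the
#' preprocessor on the inner-training patients only; transform all three
#' partitions with frozen statistics; train the supervised contrastive
#' encoder and freeze it; build the density-adaptive KNN graph on training
#' embeddings; attach validation/test nodes with frozen statistics; train
#' the fusion model (early stopping on validation AUC); and predict the
#' held-out partitions with everything frozen.
#'
#' @param cohort an `agfn_cohort`.
#' @param train_ids,val_ids,test_ids disjoint patient-id partitions;
#'   `val_ids` is the internal validation subset used for early stopping and
#'   threshold selection.
#' @param fusion an `agfn_fusion_config`.
#' @param embed_dim,tau,embed_epochs contrastive encoder settings.
#' @param k_base,k_max,kde_h graph construction settings.
#' @param alpha imputation decay coefficient.
#' @param censor apply outcome-onset censoring (disable only for the
#'   leakage-control experiment).
#' @param mode threshold selection mode (`"f1"` or `"sens92"`).
#' @param boot_B bootstrap iterations for metric CIs (0 disables).
#' @param seed seed for fold-level randomness.
#' @return a list with the trained `model`, `metrics`
#'   (an `agfn_metric_report` when `test_ids` is non-empty), predicted
#'   probability matrices, frozen artifacts (preprocessor, encoder, graph,
#'   attachments) and the tensors.
#' @export
agfn_fold_run <- function(cohort, train_ids, val_ids, test_ids = integer(0),
                          fusion = fusion_config(), embed_dim = 16L,
                          tau = 0.1, embed_epochs = 30L,
                          k_base = 15L, k_max = 30L, kde_h = 0.25,
                          alpha = 0.7, censor = TRUE, mode = "f1",
                          boot_B = 0L, seed = 1L) {
  stopifnot(inherits(cohort, "agfn_cohort"))
  if (length(intersect(train_ids, val_ids)) ||
        length(intersect(train_ids, test_ids)) ||
        length(intersect(val_ids, test_ids))) {
    stop("train/val/test partitions must be patient-disjoint")
  }
  pre <- preprocess_fit(cohort, train_ids, alpha = alpha, censor = censor,
                        fold_id = seed)
  tr <- preprocess_transform(cohort, pre, train_ids, censor = censor)
  va <- preprocess_transform(cohort, pre, val_ids, censor = censor)
  te <- if (length(test_ids)) {
    preprocess_transform(cohort, pre, test_ids, censor = censor)
  } else NULL

  y_tr <- outcome_labels(cohort, train_ids)
  y_va <- outcome_labels(cohort, val_ids)
  y_te <- if (length(test_ids)) outcome_labels(cohort, test_ids) else NULL

  f_tr <- tensor_summary_features(tr)
  enc <- train_encoder(f_tr, y_tr, dim = embed_dim, tau = tau,
                       epochs = embed_epochs, seed = seed)
  emb_tr <- enc$embeddings
  graph <- build_graph(emb_tr, k_base = k_base, k_max = k_max, h = kde_h)
  att_va <- attach_nodes(graph, encoder_embed(enc, tensor_summary_features(va)))
  att_te <- if (!is.null(te)) {
    attach_nodes(graph, encoder_embed(enc, tensor_summary_features(te)))
  } else NULL

  model <- train_fold(tr, y_tr, graph, fusion, val = va, y_val = y_va,
                      val_attach = att_va)
  p_va <- predict_heldout(model, va, att_va)
  p_te <- if (!is.null(te)) predict_heldout(model, te, att_te) else NULL
  metrics <- if (!is.null(te)) {
    metric_report(y_te, p_te, y_va, p_va, mode = mode, B = boot_B,
                  seed = seed)
  } else NULL

  list(model = model, metrics = metrics,
       probs_test = p_te, probs_val = p_va,
       y_test = y_te, y_val = y_va,
       preprocessor = pre, encoder = enc, graph = graph,
       attach_val = att_va, attach_test = att_te,
       tensors = list(train = tr, val = va, test = te),
       ids = list(train = train_ids, val = val_ids, test = test_ids))
}

#' Stratified K-fold cross-validation of the full pipeline
#'
#' Builds a stratified patient-level fold plan ([make_folds()]) and runs
#' [agfn_fold_run()] on every fold, collecting per-fold metric reports and
#' pooled test predictions.
#'
#' @param cohort an `agfn_cohort`.
#' @param K number of folds.
#' @param seed seed controlling the fold plan and fold-level training.
#' @param ... forwarded to [agfn_fold_run()].
#' @return list with `fold_results`, pooled `predictions`/`labels` and the
#'   `plan`.
#' @export
agfn_crossvalidate <- function(cohort, K = 5L, seed = 1L, ...) {
  L <- outcome_labels(cohort, cohort$statics$patient_id)
  plan <- make_folds(L, K = K, seed = seed)
  pts <- cohort$statics$patient_id
  results <- vector("list", K)
  preds <- labs <- NULL
  for (f in seq_len(K)) {
    test_ids <- pts[plan$folds[[f]]]
    val_ids <- pts[plan$val[[f]]]
    train_ids <- setdiff(pts, c(test_ids, val_ids))
    results[[f]] <- agfn_fold_run(cohort, train_ids, val_ids, test_ids,
                                  seed = seed + f, ...)
    preds <- rbind(preds, results[[f]]$probs_test)
    labs <- rbind(labs, results[[f]]$y_test)
  }
  list(fold_results = results, predictions = preds, labels = labs,
       plan = plan)
}

#' Per-outcome logistic regression baseline on the same features
#'
#' Fits an independent logistic regression per outcome on the encoder input
#' features (statics + pre-censoring temporal summaries) of the training
#' patients and predicts held-out probabilities. Used as the comparative
#' sanity reference for the fusion model.
#'
#' @param features_train,features_test numeric feature matrices.
#' @param y_train training label matrix (patients x outcomes).
#' @return probability matrix for the test rows.
#' @export
logistic_baseline <- function(features_train, y_train, features_test) {
  Xtr <- cbind(1, as.matrix(features_train))
  Xte <- cbind(1, as.matrix(features_test))
  n_out <- ncol(y_train)
  P <- matrix(0.5, nrow(Xte), n_out, dimnames = list(NULL, colnames(y_train)))
  for (j in seq_len(n_out)) {
    y <- y_train[, j]
    if (length(unique(y)) < 2L) next
    fit <- suppressWarnings(stats::glm.fit(Xtr, y,
                                           family = stats::binomial()))
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    P[, j] <- stats::plogis(as.vector(Xte %*% beta))
  }
  P
}
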