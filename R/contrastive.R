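# Supervised contrastive patient embeddings: outcome-aligned representation
# learning with one-vs-rest positives and inverse-prevalence weighting,
# retrained from scratch inside every cross-validation fold and frozen before
# any held-out patient is embedded.

#' Supervised contrastive loss with inverse-prevalence weighting
#'
#' For each anchor i the positive set `P(i)` holds the other patients sharing
#' its binary label for the target outcome (one-vs-rest). The loss is
#' `-(1/N') sum_i w_i / |P(i)| * sum_{p in P(i)} log( exp(sim(h_i,h_p)/tau)
#' / sum_{a != i} exp(sim(h_i,h_a)/tau) )` with `sim` the cosine similarity.
#' Anchors with empty `P(i)` contribute 0 and are excluded from the average
#' (with a warning when every anchor is empty). When `labels` is a matrix the
#' per-outcome losses are summed, with positive-class anchors of outcome j
#' reweighted by the inverse prevalence of that outcome so rare complications
#' are not drowned out.
#'
#' @param embeddings numeric matrix (patients x d); rows are L2-normalized
#'   internally before cosine similarities.
#' @param labels binary vector, or a patients x outcomes 0/1 matrix.
#' @param tau temperature (> 0).
#' @param weights optional per-outcome positive-anchor weights; defaults to
#'   inverse prevalence per outcome, normalized to mean 1.
#' @return scalar loss.
#' @export
contrastive_loss <- function(embeddings, labels, tau = 0.1, weights = NULL) {
  if (tau <= 0) stop("tau must be > 0")
  Z <- as.matrix(embeddings)
  if (nrow(Z) < 2L) stop("contrastive loss needs at least 2 samples")
  Z <- Z / sqrt(rowSums(Z * Z) + 1e-12)
  S <- tcrossprod(Z) / tau
  L <- if (is.matrix(labels)) labels else cbind(labels)
  if (is.null(weights)) weights <- default_anchor_weights(L)
  total <- 0
  any_pos <- FALSE
  for (j in seq_len(ncol(L))) {
    y <- L[, j]
    cl <- supcon_one(S, y, weights[j])
    if (!is.null(cl)) { total <- total + cl; any_pos <- TRUE }
  }
  if (!any_pos) {
    warning("no anchor has a positive set; loss is 0")
    return(0)
  }
  total
}

# inverse-prevalence weights for positive anchors, mean-normalized
default_anchor_weights <- function(L) {
  prev <- pmin(pmax(colMeans(L), 1e-3), 1 - 1e-3)
  w <- 1 / prev
  w / mean(w)
}

# single one-vs-rest term; returns NULL when no anchor has positives
supcon_one <- function(S, y, pos_weight) {
  n <- nrow(S)
  M <- S
  diag(M) <- -Inf
  m <- apply(M, 1L, max)
  lse <- m + log(rowSums(exp(M - m)))
  same <- outer(y, y, "==")
  diag(same) <- FALSE
  npos <- rowSums(same)
  anchors <- which(npos > 0)
  if (!length(anchors)) return(NULL)
  w <- ifelse(y == 1, pos_weight, 1)
  terms <- vapply(anchors, function(i) {
    p <- which(same[i, ])
    w[i] * mean(lse[i] - S[i, p])
  }, numeric(1))
  sum(terms) / length(anchors)
}

#' Train the supervised contrastive encoder on a training fold
#'
#' A two-layer perceptron (tanh hidden layer, L2-normalized output) maps the
#' static + pre-censoring summary feature vector of each patient to a point
#' on the unit sphere in `R^d`, trained full-batch with AdamW on the summed
#' one-vs-rest supervised contrastive objective. Weights are frozen on
#' return; embedding held-out patients with [encoder_embed()] changes
#' nothing.
#'
#' @param features numeric matrix (training patients x features), e.g. from a
#'   training-fold tensor.
#' @param labels patients x outcomes 0/1 matrix (training labels only).
#' @param dim embedding dimension d (>= 2).
#' @param tau temperature (> 0); stable in 0.05-0.2, default 0.1.
#' @param hidden hidden layer width.
#' @param epochs training epochs.
#' @param lr AdamW learning rate.
#' @param seed RNG seed controlling initialization.
#' @return an object of class `agfn_encoder` with frozen weights, the
#'   training embeddings (`$embeddings`) and the loss trace (`$loss_trace`).
#' @export
train_encoder <- function(features, labels, dim = 16L, tau = 0.1,
                          hidden = 32L, epochs = 30L, lr = 1e-2, seed = 1L) {
  X <- as.matrix(features)
  if (nrow(X) < 2L) stop("need at least 2 training patients")
  if (tau <= 0) stop("tau must be > 0")
  if (dim < 2L) stop("embedding dim must be >= 2")
  L <- as.matrix(labels)
  w_anchor <- default_anchor_weights(L)

  # constant coefficient structure of the loss: linear in S and in the
  # per-row off-diagonal log-sum-exp (see contrastive_loss)
  n <- nrow(X)
  Cmat <- matrix(0, n, n)
  bvec <- numeric(n)
  for (j in seq_len(ncol(L))) {
    y <- L[, j]
    same <- outer(y, y, "==")
    diag(same) <- FALSE
    npos <- rowSums(same)
    anchors <- which(npos > 0)
    if (!length(anchors)) next
    w <- ifelse(y == 1, w_anchor[j], 1)
    for (i in anchors) {
      Cmat[i, same[i, ]] <- Cmat[i, same[i, ]] - w[i] / npos[i] / length(anchors)
      bvec[i] <- bvec[i] + w[i] / length(anchors)
    }
  }

  params <- with_seed(seed, list(
    W1 = init_weight(ncol(X), hidden), b1 = matrix(0, 1L, hidden),
    W2 = init_weight(hidden, dim), b2 = matrix(0, 1L, dim)))
  state <- adamw_init(params)
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    tp <- ad_tape()
    ids <- lapply(params, function(p) ad_leaf(tp, p))
    z <- encoder_forward_tape(tp, X, ids)
    S <- ad_scale(tp, ad_matmul_tB(tp, z, z), 1 / tau)
    lse <- ad_row_lse_offdiag(tp, S)
    loss <- ad_add(tp, ad_sum(tp, ad_mulc(tp, S, Cmat)),
                   ad_sum(tp, ad_mulc(tp, lse, cbind(bvec))))
    trace[ep] <- ad_val(tp, loss)[1L]
    gr <- ad_backward(tp, loss)
    grads <- lapply(ids, function(id) gr[[id]])
    upd <- adamw_step(params, grads, state,
                      lr = cosine_lr(lr, ep - 1, epochs))
    params <- upd$params; state <- upd$state
  }
  enc <- list(params = params, dim = dim, tau = tau,
              n_features = ncol(X), loss_trace = trace, seed = seed)
  class(enc) <- "agfn_encoder"
  enc$embeddings <- encoder_embed(enc, X)
  enc
}

encoder_forward_tape <- function(tp, X, ids) {
  xin <- ad_leaf(tp, X, grad = FALSE)
  h <- ad_tanh(tp, ad_addbias(tp, ad_matmul(tp, xin, ids$W1), ids$b1))
  ad_rownorm(tp, ad_addbias(tp, ad_matmul(tp, h, ids$W2), ids$b2))
}

#' @rdname train_encoder
#' @param encoder a frozen `agfn_encoder`.
#' @export
encoder_embed <- function(encoder, features) {
  stopifnot(inherits(encoder, "agfn_encoder"))
  X <- as.matrix(features)
  if (ncol(X) != encoder$n_features) {
    stop(sprintf("encoder expects %d features, got %d",
                 encoder$n_features, ncol(X)))
  }
  p <- encoder$params
  h <- tanh(sweep(X %*% p$W1, 2L, as.vector(p$b1), "+"))
  z <- sweep(h %*% p$W2, 2L, as.vector(p$b2), "+")
  z / sqrt(rowSums(z * z) + 1e-12)
}
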