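# Attention-based message passing over the DA-KNN patient graph, a
# multi-label sigmoid head, and the training loop (AdamW, cosine annealing,
# global-norm gradient clipping, graph refresh, early stopping on validation
# AUC). Held-out patients attach to the frozen training graph and never
# influence a gradient.

#' Fusion model configuration
#'
#' Defaults sit at the midpoints of the validated search ranges: 4 attention
#' heads, hidden width 128 with `d_k = hidden / heads`, dropout 0.3, learning
#' rate 3e-4, gradient clipping at 1.0, early-stopping patience 10.
#'
#' @param heads number of attention heads (2, 4 or 8).
#' @param hidden hidden width (64, 128 or 256).
#' @param dropout dropout probability in `[0.1, 0.5]`.
#' @param lr AdamW learning rate in `[1e-5, 1e-3]`.
#' @param max_epochs training epochs; `patience` epochs without validation
#'   improvement stop earlier.
#' @param patience early-stopping patience.
#' @param layers graph-attention layers (2 gives 2-hop reach).
#' @param window,channels,gru_hidden,beta temporal-encoder settings (see
#'   [temporal_params()]).
#' @param refresh_every refresh the graph every this many epochs during
#'   training (annealed `k_base`, degree-capped).
#' @param weight_decay AdamW decoupled weight decay.
#' @param grad_clip global gradient-norm clip.
#' @param seed RNG seed for initialization and dropout.
#' @return an `agfn_fusion_config` list.
#' @export
fusion_config <- function(heads = 4L, hidden = 128L, dropout = 0.3,
                          lr = 3e-4, max_epochs = 60L, patience = 10L,
                          layers = 2L, window = 6L, channels = 16L,
                          gru_hidden = 24L, beta = 0.9, refresh_every = 5L,
                          weight_decay = 1e-4, grad_clip = 1.0, seed = 1L) {
  if (!heads %in% c(2L, 4L, 8L)) stop("heads must be 2, 4 or 8")
  if (!hidden %in% c(64L, 128L, 256L)) {
    stop("hidden must be one of 64, 128, 256")
  }
  if (dropout < 0 || dropout > 0.5) stop("dropout must lie in [0, 0.5]")
  if (lr < 1e-5 || lr > 1e-3) stop("lr must lie in [1e-5, 1e-3]")
  if (hidden %% heads != 0) stop("hidden must be divisible by heads")
  cfg <- list(heads = as.integer(heads), hidden = as.integer(hidden),
              d_k = as.integer(hidden / heads), dropout = dropout, lr = lr,
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience), layers = as.integer(layers),
              window = as.integer(window), channels = as.integer(channels),
              gru_hidden = as.integer(gru_hidden), beta = beta,
              refresh_every = as.integer(refresh_every),
              weight_decay = weight_decay, grad_clip = grad_clip,
              seed = as.integer(seed))
  class(cfg) <- "agfn_fusion_config"
  cfg
}

#' Attention over one node's graph neighborhood
#'
#' `softmax(q K^T / sqrt(d_k) + bias) V` restricted to the neighbor set; the
#' attention weights are a probability vector over the neighborhood. With a
#' single neighbor the output is that neighbor's value row; identical keys
#' give uniform weights.
#'
#' @param q query vector (length `d_k`).
#' @param K,V key/value matrices, one row per neighborhood member.
#' @param bias optional additive logit bias (e.g. log Gaussian edge weights).
#' @return list with `out` (attended vector) and `weights`.
#' @export
neighborhood_attention <- function(q, K, V, bias = NULL) {
  K <- as.matrix(K); V <- as.matrix(V)
  logits <- as.vector(K %*% q) / sqrt(length(q))
  if (!is.null(bias)) logits <- logits + bias
  w <- exp(logits - max(logits))
  w <- w / sum(w)
  list(out = as.vector(crossprod(V, w)), weights = w)
}

#' Multi-label output probabilities
#'
#' `yhat = sigmoid(W_o^T H + b_o)` -- six independent probabilities per
#' patient; outcomes are multi-label and not constrained to sum to one.
#'
#' @param H attended representation matrix (patients x hidden).
#' @param W_o output weights (hidden x outcomes), `b_o` bias.
#' @param b_o bias vector.
#' @return matrix of probabilities in (0, 1).
#' @export
output_probs <- function(H, W_o, b_o = 0) {
  stats::plogis(sweep(as.matrix(H) %*% W_o, 2L, as.vector(b_o), "+"))
}

# flat named parameter list for the whole fusion model
fusion_params_init <- function(d_in, n_static, n_out, cfg) {
  with_seed(cfg$seed, {
    tpar <- list(
      Wg = init_weight(cfg$window * d_in, cfg$channels),
      Wc = init_weight(cfg$window * d_in, cfg$channels),
      bg = matrix(0, 1L, cfg$channels), bc = matrix(0, 1L, cfg$channels),
      Wz = init_weight(d_in, cfg$gru_hidden),
      Uz = init_weight(cfg$gru_hidden, cfg$gru_hidden),
      Wr = init_weight(d_in, cfg$gru_hidden),
      Ur = init_weight(cfg$gru_hidden, cfg$gru_hidden),
      Wh = init_weight(d_in, cfg$gru_hidden),
      Uh = init_weight(cfg$gru_hidden, cfg$gru_hidden),
      Wg2 = init_weight(d_in, cfg$gru_hidden),
      Ug = init_weight(cfg$gru_hidden, cfg$gru_hidden),
      bz = matrix(0, 1L, cfg$gru_hidden), br = matrix(0, 1L, cfg$gru_hidden),
      bh = matrix(0, 1L, cfg$gru_hidden), bg2 = matrix(0, 1L, cfg$gru_hidden))
    nf <- cfg$channels + cfg$gru_hidden + n_static
    proj <- list(Win = init_weight(nf, cfg$hidden),
                 bin = matrix(0, 1L, cfg$hidden))
    att <- list()
    for (l in seq_len(cfg$layers)) {
      for (hh in seq_len(cfg$heads)) {
        att[[sprintf("Wq_%d_%d", l, hh)]] <- init_weight(cfg$hidden, cfg$d_k)
        att[[sprintf("Wk_%d_%d", l, hh)]] <- init_weight(cfg$hidden, cfg$d_k)
        att[[sprintf("Wv_%d_%d", l, hh)]] <- init_weight(cfg$hidden, cfg$d_k)
      }
      att[[sprintf("Wo_%d", l)]] <- init_weight(cfg$heads * cfg$d_k, cfg$hidden)
      att[[sprintf("bo_%d", l)]] <- matrix(0, 1L, cfg$hidden)
    }
    head <- list(Wout = init_weight(cfg$hidden, n_out),
                 bout = matrix(0, 1L, n_out))
    c(tpar, proj, att, head)
  })
}

# stack an agfn_tensor into the ((N * T) x 2D) encoder input (values + mask)
tensor_input_stack <- function(tensor) {
  d <- dim(tensor$X)
  N <- d[1L]; Tn <- d[2L]; D <- d[3L]
  vals <- matrix(aperm(tensor$X, c(2L, 1L, 3L)), N * Tn, D)
  mask <- matrix(aperm(tensor$M, c(2L, 1L, 3L)), N * Tn, D)
  cbind(vals, mask)
}

# Full fusion forward on a tape. `xin` is the tape id of the stacked input,
# `S` the constant statics matrix, `edges` the (src, dst, logw) table over
# `Ntot` nodes. `dropmasks` (NULL for inference) are constant inverted
# dropout masks per layer. Returns the logits node id.
fusion_forward_tape <- function(tp, pid, xin, S, N, Tn, edges, cfg,
                                dropmasks = NULL, collect = NULL) {
  Htmp <- tape_temporal_encode(tp, xin, N, Tn, pid, cfg$window, cfg$beta)
  H0 <- ad_cbind2(tp, Htmp, ad_leaf(tp, S, grad = FALSE))
  X <- ad_relu(tp, ad_addbias(tp, ad_matmul(tp, H0, pid$Win), pid$bin))
  if (!is.null(collect)) collect$proj <- ad_val(tp, X)
  inv_dk <- 1 / sqrt(cfg$d_k)
  for (l in seq_len(cfg$layers)) {
    heads <- NULL
    for (hh in seq_len(cfg$heads)) {
      q <- ad_matmul(tp, X, pid[[sprintf("Wq_%d_%d", l, hh)]])
      k <- ad_matmul(tp, X, pid[[sprintf("Wk_%d_%d", l, hh)]])
      v <- ad_matmul(tp, X, pid[[sprintf("Wv_%d_%d", l, hh)]])
      logits <- ad_scale(tp, ad_rowsum_prod(tp, ad_rows(tp, q, edges$dst),
                                            ad_rows(tp, k, edges$src)), inv_dk)
      wts <- ad_group_softmax(tp, logits, edges$dst, N, bias = edges$logw)
      msg <- ad_group_sum(tp, ad_colscale(tp, ad_rows(tp, v, edges$src), wts),
                          edges$dst, N)
      heads <- if (is.null(heads)) msg else ad_cbind2(tp, heads, msg)
    }
    upd <- ad_addbias(tp, ad_matmul(tp, heads, pid[[sprintf("Wo_%d", l)]]),
                      pid[[sprintf("bo_%d", l)]])
    X <- ad_relu(tp, ad_add(tp, X, upd))
    if (!is.null(dropmasks)) X <- ad_dropout(tp, X, dropmasks[[l]])
    if (!is.null(collect)) collect$layers[[l]] <- ad_val(tp, X)
  }
  ad_addbias(tp, ad_matmul(tp, X, pid$Wout), pid$bout)
}

# plain forward capturing the post-projection and per-layer node states
fusion_forward_states <- function(params, Xall, Sall, Nall, Tn, edges, cfg) {
  coll <- new.env()
  coll$layers <- list()
  tp <- ad_tape(8192L)
  pid <- lapply(params, function(p) ad_leaf(tp, p, grad = FALSE))
  xin <- ad_leaf(tp, Xall, grad = FALSE)
  logits <- fusion_forward_tape(tp, pid, xin, Sall, Nall, Tn, edges, cfg,
                                collect = coll)
  list(proj = coll$proj, layers = coll$layers,
       probs = stats::plogis(ad_val(tp, logits)))
}

#' Train the fusion model on one cross-validation fold
#'
#' Minimizes summed per-outcome binary cross-entropy (the loss implied by the
#' sigmoid multi-label head) with AdamW, cosine learning-rate annealing and
#' global-norm gradient clipping at 1.0. The graph is refreshed every
#' `refresh_every` epochs with the annealed `k_base` ramp and the
#' `|delta k| <= 2` cap. Validation patients attach to the frozen graph; their
#' labels only drive early stopping on mean validation ROC-AUC, never a
#' gradient. Outcomes without a positive training label are skipped with a
#' warning. Fully reproducible given the config seed.
#'
#' @param train,val `agfn_tensor` objects for the inner-training and internal
#'   validation patients (same frozen preprocessor).
#' @param y_train,y_val 0/1 label matrices (patients x outcomes).
#' @param graph `agfn_graph` built on the inner-training embeddings.
#' @param val_attach attachment of validation nodes ([attach_nodes()]).
#' @param config an `agfn_fusion_config`.
#' @param graph_embeddings embeddings used for graph refreshes (the frozen
#'   contrastive embeddings of the training nodes).
#' @return an `agfn_model`: best-validation parameters, frozen graph, config,
#'   loss/AUC traces, and the constant training-node inputs needed to attach
#'   held-out patients at prediction time.
#' @export
train_fold <- function(train, y_train, graph, config, val = NULL,
                       y_val = NULL, val_attach = NULL,
                       graph_embeddings = graph$embeddings) {
  stopifnot(inherits(train, "agfn_tensor"), inherits(graph, "agfn_graph"))
  cfg <- config
  d <- dim(train$X)
  Ntr <- d[1L]; Tn <- d[2L]; Dv <- d[3L]
  d_in <- 2L * Dv
  n_out <- ncol(y_train)
  has_val <- !is.null(val)

  Xtr <- tensor_input_stack(train)
  Str <- train$S
  if (has_val) {
    Xva <- tensor_input_stack(val)
    Sva <- val$S
    Nva <- dim(val$X)[1L]
  } else { Xva <- NULL; Nva <- 0L }
  Xall <- rbind(Xtr, Xva)
  Sall <- rbind(Str, if (has_val) Sva)
  Nall <- Ntr + Nva

  # per-outcome loss weights; outcomes without training positives are skipped
  pos <- colSums(y_train)
  wcol <- rep(1, n_out)
  if (any(pos == 0)) {
    warning(sprintf("no positive training labels for outcome(s) %s; skipped",
                    paste(which(pos == 0), collapse = ", ")))
    wcol[pos == 0] <- 0
  }
  Wloss <- rbind(matrix(wcol, Ntr, n_out, byrow = TRUE),
                 matrix(0, Nva, n_out))
  Yall <- rbind(y_train, if (has_val) y_val else NULL)

  params <- fusion_params_init(d_in, ncol(Str), n_out, cfg)
  state <- adamw_init(params)
  cur_graph <- graph
  edges <- graph_edge_table(cur_graph, attach = val_attach)
  loss_trace <- numeric(0)
  auc_trace <- numeric(0)
  best <- list(auc = -Inf, params = params, epoch = 0L)
  wait <- 0L

  rng_seed <- cfg$seed + 1000L
  for (ep in seq_len(cfg$max_epochs)) {
    if (cfg$refresh_every > 0L && (ep - 1L) %% cfg$refresh_every == 0L) {
      cur_graph <- refresh_graph(cur_graph, graph_embeddings, ep - 1L,
                                 cfg$max_epochs)
      edges <- graph_edge_table(cur_graph, attach = val_attach)
    }
    dropmasks <- if (cfg$dropout > 0) with_seed(rng_seed + ep, {
      lapply(seq_len(cfg$layers), function(l) {
        keep <- matrix(stats::rbinom(Nall * cfg$hidden, 1L, 1 - cfg$dropout),
                       Nall, cfg$hidden)
        keep / (1 - cfg$dropout)
      })
    }) else NULL

    tp <- ad_tape(8192L)
    pid <- lapply(params, function(p) ad_leaf(tp, p))
    xin <- ad_leaf(tp, Xall, grad = FALSE)
    logits <- fusion_forward_tape(tp, pid, xin, Sall, Nall, Tn, edges, cfg,
                                  dropmasks)
    loss <- ad_bce_logits(tp, logits, Yall, Wloss / max(Ntr, 1L))
    loss_trace[ep] <- ad_val(tp, loss)[1L]
    gr <- ad_backward(tp, loss)
    grads <- lapply(pid, function(id) {
      g <- gr[[id]]
      if (is.null(g)) matrix(0, 1L, 1L) else g
    })
    # keep shapes aligned for parameters that received no gradient
    for (nm in names(params)) {
      if (!identical(dim(grads[[nm]]), dim(as_mat(params[[nm]])))) {
        grads[[nm]] <- array(0, dim = dim(as_mat(params[[nm]])))
      }
    }
    upd <- adamw_step(params, grads, state,
                      lr = cosine_lr(cfg$lr, ep - 1, cfg$max_epochs),
                      weight_decay = cfg$weight_decay, clip = cfg$grad_clip)
    params <- upd$params; state <- upd$state

    if (has_val) {
      probs <- fusion_predict_raw(params, Xall, Sall, Nall, Tn, edges, cfg)
      vp <- probs[Ntr + seq_len(Nva), , drop = FALSE]
      aucs <- vapply(seq_len(n_out), function(j) {
        if (length(unique(y_val[, j])) < 2L) return(NA_real_)
        rank_auc(y_val[, j], vp[, j])
      }, numeric(1))
      mauc <- mean(aucs, na.rm = TRUE)
      auc_trace[ep] <- mauc
      if (mauc > best$auc + 1e-6) {
        best <- list(auc = mauc, params = params, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    } else {
      best <- list(auc = NA_real_, params = params, epoch = ep)
    }
  }

  model <- list(params = best$params, config = cfg, graph = cur_graph,
                n_out = n_out, d_in = d_in, Tn = Tn,
                variables = train$variables,
                train_stack = Xtr, train_statics = Str,
                train_ids = train$patient_ids,
                loss_trace = loss_trace, val_auc_trace = auc_trace,
                best_epoch = best$epoch, best_val_auc = best$auc)
  class(model) <- "agfn_model"
  model
}

#' @export
print.agfn_model <- function(x, ...) {
  cat(sprintf(paste0("agfn_model: %d training nodes, %d outcomes, best ",
                     "epoch %d (val mean AUC %.3f)\n"),
              nrow(x$train_statics), x$n_out, x$best_epoch, x$best_val_auc))
  invisible(x)
}

# inference forward (no dropout) returning probabilities for all nodes
fusion_predict_raw <- function(params, Xall, Sall, Nall, Tn, edges, cfg) {
  tp <- ad_tape(8192L)
  pid <- lapply(params, function(p) ad_leaf(tp, p, grad = FALSE))
  xin <- ad_leaf(tp, Xall, grad = FALSE)
  logits <- fusion_forward_tape(tp, pid, xin, Sall, Nall, Tn, edges, cfg)
  stats::plogis(ad_val(tp, logits))
}

#' Predict outcome probabilities for held-out patients
#'
#' Held-out nodes attach to the frozen training graph ([attach_nodes()] on
#' the frozen contrastive embeddings); messages flow only from training nodes
#' to held-out nodes, so no training-node representation, parameter or edge
#' changes. Row order of the result follows the held-out tensor.
#'
#' @param model a trained `agfn_model`.
#' @param tensor `agfn_tensor` of held-out patients (frozen preprocessor).
#' @param attach attachment info from [attach_nodes()].
#' @return matrix of per-outcome probabilities in (0, 1).
#' @export
predict_heldout <- function(model, tensor, attach) {
  stopifnot(inherits(model, "agfn_model"), inherits(tensor, "agfn_tensor"))
  if (!identical(tensor$variables, model$variables)) {
    bad <- setdiff(tensor$variables, model$variables)
    stop(sprintf("unknown variable(s): %s",
                 paste(if (length(bad)) bad else "(order mismatch)",
                       collapse = ", ")))
  }
  Nhe <- dim(tensor$X)[1L]
  Ntr <- nrow(model$train_statics)
  Xall <- rbind(model$train_stack, tensor_input_stack(tensor))
  Sall <- rbind(model$train_statics, tensor$S)
  edges <- graph_edge_table(model$graph, attach = attach)
  probs <- fusion_predict_raw(model$params, Xall, Sall, Ntr + Nhe,
                              model$Tn, edges, model$config)
  probs[Ntr + seq_len(Nhe), , drop = FALSE]
}
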