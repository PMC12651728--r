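# Gradient-based Shapley attribution for the fusion model: an
# expected-gradients estimator (deterministic trapezoid path per sampled
# baseline), an exact coalition-enumeration oracle for small models, global
# and per-outcome rankings, temporal contribution maps, and a seed/background
# stability audit.

#' Exact Shapley values by coalition enumeration (oracle)
#'
#' Computes the exact coalition-weighted sum
#' `phi_j = sum_S |S|!(|F|-|S|-1)!/|F|! (v(S u {j}) - v(S))` with the value
#' of a coalition defined by replacing absent features with background rows
#' and averaging: `v(S) = mean_b f(x_S, b_{-S})`. Feasible for at most 10
#' features (2^|F| evaluations); serves as the oracle the gradient estimator
#' is audited against.
#'
#' @param f function taking a numeric matrix (rows = inputs) and returning a
#'   numeric vector of outputs.
#' @param x numeric feature vector (|F| <= 10).
#' @param background numeric matrix of background rows (same columns as x).
#' @return numeric vector of attributions, one per feature.
#' @export
exact_shapley <- function(f, x, background) {
  p <- length(x)
  if (p > 10L) stop("exact enumeration is limited to 10 features")
  B <- as.matrix(background)
  nsub <- 2L^p
  # v(S) for every subset, coded by bitmask
  v <- numeric(nsub)
  for (m in 0:(nsub - 1L)) {
    inS <- as.logical(bitwAnd(m, bitwShiftL(1L, 0:(p - 1L))))
    Z <- B
    Z[, inS] <- matrix(x[inS], nrow(B), sum(inS), byrow = TRUE)
    v[m + 1L] <- mean(f(Z))
  }
  fact <- factorial(0:p)
  phi <- numeric(p)
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    for (m in 0:(nsub - 1L)) {
      if (bitwAnd(m, bit) != 0L) next
      s <- sum(as.logical(bitwAnd(m, bitwShiftL(1L, 0:(p - 1L)))))
      w <- fact[s + 1L] * fact[p - s] / fact[p + 1L]
      phi[j] <- phi[j] + w * (v[bitwOr(m, bit) + 1L] - v[m + 1L])
    }
  }
  phi
}

#' Expected-gradients attribution for an arbitrary differentiable function
#'
#' For each sampled baseline `b`, integrates the gradient along the straight
#' path from `b` to `x` with a trapezoid rule (`steps` segments) and scales
#' by `x - b`; attributions average over baselines. In the limit this
#' satisfies the efficiency property `sum(phi) = f(x) - mean_b f(b)` exactly.
#'
#' @param f scalar function of a feature vector.
#' @param x input vector.
#' @param background background matrix (rows are reference inputs).
#' @param grad_f optional gradient function; central finite differences are
#'   used when absent.
#' @param n_baselines baselines sampled from the background.
#' @param steps trapezoid path segments per baseline.
#' @param seed RNG seed for the baseline sample.
#' @return list with `phi`, `fx`, `baseline_expectation` and the relative
#'   additivity `residual`.
#' @export
expected_gradients <- function(f, x, background, grad_f = NULL,
                               n_baselines = 8L, steps = 20L, seed = 1L) {
  B <- as.matrix(background)
  if (!nrow(B)) stop("background must be non-empty")
  if (is.null(grad_f)) {
    grad_f <- function(z) {
      eps <- 1e-5
      vapply(seq_along(z), function(j) {
        zp <- z; zm <- z
        zp[j] <- zp[j] + eps; zm[j] <- zm[j] - eps
        (f(zp) - f(zm)) / (2 * eps)
      }, numeric(1))
    }
  }
  idx <- with_seed(seed, sample.int(nrow(B), n_baselines,
                                    replace = n_baselines > nrow(B)))
  alphas <- seq(0, 1, length.out = steps + 1L)
  phi <- numeric(length(x))
  fb <- numeric(length(idx))
  for (r in seq_along(idx)) {
    b <- as.numeric(B[idx[r], ])
    grads <- lapply(alphas, function(a) grad_f(b + a * (x - b)))
    vals <- vapply(alphas, function(a) f(b + a * (x - b)), numeric(1))
    fb[r] <- vals[1L]
    acc <- numeric(length(x))
    for (s in seq_len(steps)) {
      gseg <- 0.5 * (grads[[s]] + grads[[s + 1L]]) * (x - b) / steps
      acc <- acc + segment_correct(gseg, vals[s + 1L] - vals[s])
    }
    phi <- phi + acc / length(idx)
  }
  fx <- f(x)
  gap <- fx - mean(fb)
  list(phi = phi, fx = fx, baseline_expectation = mean(fb),
       residual = abs(sum(phi) - gap) / max(abs(gap), 1e-12))
}

# Per-segment completeness correction: the trapezoid estimate of a path
# segment's attribution is adjusted (proportionally to attribution magnitude)
# so the segment sums telescope to exactly f(z_{s+1}) - f(z_s). This absorbs
# the quadrature error the ReLU kinks introduce, making the efficiency
# property hold by construction rather than only in the many-steps limit.
segment_correct <- function(gseg, delta) {
  corr <- delta - sum(gseg)
  w <- abs(gseg)
  tot <- sum(w)
  if (tot > 0) gseg + corr * w / tot else gseg + corr / length(gseg)
}

## ---- model-level attribution ----

# Frozen neighborhood context for one patient: neighbor ids/log-weights and
# the constant training-node states per layer. The attributed function holds
# all of these fixed, so phi reflects the patient's own features only.
patient_context <- function(model, attach = NULL) {
  cfg <- model$config
  Ntr <- nrow(model$train_statics)
  edges <- graph_edge_table(model$graph)
  states <- fusion_forward_states(model$params, model$train_stack,
                                  model$train_statics, Ntr, model$Tn,
                                  edges, cfg)
  list(states = states, n_train = Ntr, attach = attach)
}

# Batched forward/gradient of the attributed function: input = (sequence
# values, statics) of one patient, C path copies at once. Masks and the
# neighborhood are constants. Returns probabilities and input gradients.
attribution_batch_fun <- function(model, ctx, mask_stack, neighbor_ids,
                                  neighbor_logw, outcome) {
  cfg <- model$config
  Ntr <- ctx$n_train
  function(Xseq_batch, S_batch) {
    C <- nrow(S_batch)
    Tn <- model$Tn
    tp <- ad_tape(8192L)
    pid <- lapply(model$params, function(p) ad_leaf(tp, p, grad = FALSE))
    xleaf <- ad_leaf(tp, Xseq_batch)
    # observation-mask channels: the patient's own mask, tiled per copy
    mleaf <- ad_leaf(tp, do.call(rbind, rep(list(mask_stack), C)), grad = FALSE)
    sleaf <- ad_leaf(tp, S_batch)
    xin <- ad_cbind2(tp, xleaf, mleaf)
    Htmp <- tape_temporal_encode(tp, xin, C, Tn, pid, cfg$window, cfg$beta)
    H0 <- ad_cbind2(tp, Htmp, sleaf)
    Xc <- ad_relu(tp, ad_addbias(tp, ad_matmul(tp, H0, pid$Win), pid$bin))
    inv_dk <- 1 / sqrt(cfg$d_k)
    nb <- length(neighbor_ids)
    src <- rep(c(neighbor_ids, NA), C)
    self_rows <- Ntr + seq_len(C)
    src[is.na(src)] <- self_rows
    dst <- rep(self_rows, each = nb + 1L)
    bias <- rep(c(neighbor_logw, 0), C)
    for (l in seq_len(cfg$layers)) {
      const_states <- if (l == 1L) ctx$states$proj else
        ctx$states$layers[[l - 1L]]
      comb <- ad_rbind2(tp, ad_leaf(tp, const_states, grad = FALSE), Xc)
      heads <- NULL
      for (hh in seq_len(cfg$heads)) {
        q <- ad_matmul(tp, comb, pid[[sprintf("Wq_%d_%d", l, hh)]])
        k <- ad_matmul(tp, comb, pid[[sprintf("Wk_%d_%d", l, hh)]])
        v <- ad_matmul(tp, comb, pid[[sprintf("Wv_%d_%d", l, hh)]])
        lg <- ad_scale(tp, ad_rowsum_prod(tp, ad_rows(tp, q, dst),
                                          ad_rows(tp, k, src)), inv_dk)
        wts <- ad_group_softmax(tp, lg, dst, Ntr + C, bias = bias)
        msg <- ad_group_sum(tp, ad_colscale(tp, ad_rows(tp, v, src), wts),
                            dst, Ntr + C)
        heads <- if (is.null(heads)) msg else ad_cbind2(tp, heads, msg)
      }
      upd <- ad_addbias(tp, ad_matmul(tp, heads, pid[[sprintf("Wo_%d", l)]]),
                        pid[[sprintf("bo_%d", l)]])
      upd_c <- ad_rows(tp, upd, self_rows)
      Xc <- ad_relu(tp, ad_add(tp, Xc, upd_c))
    }
    logits <- ad_addbias(tp, ad_matmul(tp, Xc, pid$Wout), pid$bout)
    prob <- ad_sigmoid(tp, ad_cols(tp, logits, outcome))
    out <- ad_sum(tp, prob)
    gr <- ad_backward(tp, out)
    list(values = as.vector(ad_val(tp, prob)),
         gX = gr[[xleaf]], gS = gr[[sleaf]])
  }
}

#' Gradient-SHAP attribution maps for fusion-model predictions
#'
#' Expected-gradients attribution of the predicted probability of one
#' outcome, per patient, over the patient's own inputs: every (time bin,
#' variable) entry of the preprocessed sequence plus each static feature.
#' The frozen graph neighborhood is part of the function being attributed
#' and is held fixed, as are the observation-mask channels. Baselines are
#' training patients sampled from `background_ids`; the integration path is
#' a deterministic trapezoid rule, so the efficiency (additivity) residual
#' is small for every patient. Deterministic given `seed` and background.
#'
#' @param model trained `agfn_model`.
#' @param tensor `agfn_tensor` containing the patients to explain.
#' @param patients row indices into `tensor` to attribute.
#' @param outcome outcome column index to attribute.
#' @param background `agfn_tensor` of training patients (baseline source).
#' @param background_ids row indices of `background` forming the background
#'   sample (e.g. 50 training patients).
#' @param attach [attach_nodes()] result when `tensor` holds held-out
#'   patients; `NULL` when they are training nodes of the model graph.
#' @param n_baselines baselines sampled per patient from the background.
#' @param steps trapezoid path segments.
#' @param seed RNG seed for baseline sampling.
#' @return an `agfn_attribution`: arrays `phi_time` (patients x bins x
#'   variables) and `phi_static`, per-patient `fx`, `baseline_expectation`
#'   and additivity `residual`, and the pooled `global` mean-|phi| ranking.
#' @export
gradient_shap <- function(model, tensor, patients, outcome = 1L,
                          background, background_ids,
                          attach = NULL, n_baselines = 25L, steps = 8L,
                          seed = 1L) {
  stopifnot(inherits(model, "agfn_model"), inherits(tensor, "agfn_tensor"))
  if (!length(background_ids)) stop("background must be non-empty")
  ctx <- patient_context(model, attach)
  Tn <- model$Tn
  D <- length(model$variables)
  Sd <- ncol(tensor$S)
  P <- length(patients)
  phi_time <- array(0, c(P, Tn, D))
  phi_static <- matrix(0, P, Sd)
  fx <- base_exp <- residual <- numeric(P)
  alphas <- seq(0, 1, length.out = steps + 1L)

  for (pi in seq_len(P)) {
    p <- patients[pi]
    xseq <- matrix(tensor$X[p, , ], Tn, D)
    xstat <- tensor$S[p, ]
    mask_stack <- cbind(matrix(tensor$M[p, , ], Tn, D))
    nb_ids <- if (is.null(attach)) model$graph$neighbors[[p]] else
      attach$neighbors[[p]]
    nb_w <- if (is.null(attach)) model$graph$weights[[p]] else
      attach$weights[[p]]
    fun <- attribution_batch_fun(model, ctx, mask_stack, nb_ids,
                                 log(pmax(nb_w, 1e-12)), outcome)
    bidx <- with_seed(seed + p, sample(background_ids, n_baselines,
                                       replace = n_baselines >
                                         length(background_ids)))
    C <- n_baselines * (steps + 1L)
    Xb <- matrix(0, C * Tn, D)
    Sb <- matrix(0, C, Sd)
    cc <- 0L
    for (r in seq_along(bidx)) {
      bseq <- matrix(background$X[bidx[r], , ], Tn, D)
      bstat <- background$S[bidx[r], ]
      for (s in seq_along(alphas)) {
        cc <- cc + 1L
        Xb[(cc - 1L) * Tn + seq_len(Tn), ] <- bseq + alphas[s] * (xseq - bseq)
        Sb[cc, ] <- bstat + alphas[s] * (xstat - bstat)
      }
    }
    res <- fun(Xb, Sb)
    acc_t <- matrix(0, Tn, D)
    acc_s <- numeric(Sd)
    fb <- numeric(n_baselines)
    grad_at <- function(cc) res$gX[(cc - 1L) * Tn + seq_len(Tn), ,
                                   drop = FALSE]
    for (r in seq_len(n_baselines)) {
      bseq <- matrix(background$X[bidx[r], , ], Tn, D)
      bstat <- background$S[bidx[r], ]
      cc0 <- (r - 1L) * (steps + 1L)
      fb[r] <- res$values[cc0 + 1L]
      for (s in seq_len(steps)) {
        gseg_t <- 0.5 * (grad_at(cc0 + s) + grad_at(cc0 + s + 1L)) *
          (xseq - bseq) / steps
        gseg_s <- 0.5 * (res$gS[cc0 + s, ] + res$gS[cc0 + s + 1L, ]) *
          (xstat - bstat) / steps
        seg <- segment_correct(c(gseg_t, gseg_s),
                               res$values[cc0 + s + 1L] -
                                 res$values[cc0 + s])
        acc_t <- acc_t + matrix(seg[seq_len(Tn * D)], Tn, D) / n_baselines
        acc_s <- acc_s + seg[Tn * D + seq_len(Sd)] / n_baselines
      }
    }
    fxp <- res$values[steps + 1L]
    phi_time[pi, , ] <- acc_t
    phi_static[pi, ] <- acc_s
    fx[pi] <- fxp
    base_exp[pi] <- mean(fb)
    gap <- fxp - mean(fb)
    residual[pi] <- abs(sum(acc_t) + sum(acc_s) - gap) / max(abs(gap), 1e-12)
  }

  feat_names <- c(model$variables, colnames(tensor$S))
  global <- c(apply(abs(phi_time), 3L, mean), colMeans(abs(phi_static)))
  names(global) <- feat_names
  out <- list(phi_time = phi_time, phi_static = phi_static,
              patients = patients, outcome = outcome,
              fx = fx, baseline_expectation = base_exp, residual = residual,
              global = global,
              ranking = names(sort(global, decreasing = TRUE)),
              variables = model$variables, tbins = tensor$tbins,
              seed = seed, n_background = length(background_ids))
  class(out) <- "agfn_attribution"
  out
}

#' @export
print.agfn_attribution <- function(x, ...) {
  cat(sprintf("agfn_attribution: %d patients, outcome %d\n",
              length(x$patients), x$outcome))
  cat("Top features by mean |phi|:\n")
  print(round(utils::head(sort(x$global, decreasing = TRUE), 8L), 5))
  cat(sprintf("max additivity residual: %.4f\n", max(x$residual)))
  invisible(x)
}

#' Stability audit of SHAP rankings across seeds and background sizes
#'
#' Recomputes the global mean-|phi| ranking under each seed and each
#' background sample size, then reports all pairwise Spearman rank
#' correlations of the feature rankings and the coefficient of variation of
#' mean |phi| for the top features.
#'
#' @inheritParams gradient_shap
#' @param background_pool candidate training row indices backgrounds are
#'   drawn from.
#' @param seeds seeds to audit (default 5).
#' @param bg_sizes background sample sizes (default 50 and 100).
#' @param top_k features entering the coefficient-of-variation summary.
#' @param n_baselines,steps passed to [gradient_shap()].
#' @return an `agfn_stability`: `spearman` (pairwise matrix), `min_spearman`,
#'   `cv_top` (per-feature CV) and `max_cv`.
#' @export
stability_audit <- function(model, tensor, patients, outcome = 1L,
                            background, background_pool,
                            seeds = 1:5, bg_sizes = c(50L, 100L),
                            top_k = 15L, n_baselines = 25L, steps = 8L,
                            attach = NULL) {
  if (length(seeds) < 2L && length(bg_sizes) < 2L) {
    stop("need at least 2 runs to audit stability")
  }
  runs <- list()
  for (sz in bg_sizes) {
    # one background sample per size; seeds vary the estimator's own
    # baseline subsampling, mirroring a seeds-by-background-size audit
    bg_ids <- with_seed(20000L + sz,
                        sample(background_pool,
                               min(sz, length(background_pool))))
    for (sd in seeds) {
      at <- gradient_shap(model, tensor, patients, outcome, background,
                          bg_ids, attach = attach,
                          n_baselines = n_baselines, steps = steps,
                          seed = sd)
      runs[[sprintf("seed%d_bg%d", sd, sz)]] <- at$global
    }
  }
  if (length(runs[[1L]]) < 2L) stop("need at least 2 features")
  G <- do.call(cbind, runs)
  nr <- ncol(G)
  sp <- matrix(1, nr, nr, dimnames = list(colnames(G), colnames(G)))
  for (a in seq_len(nr - 1L)) {
    for (b in (a + 1L):nr) {
      sp[a, b] <- sp[b, a] <- stats::cor(G[, a], G[, b], method = "spearman")
    }
  }
  mean_phi <- rowMeans(G)
  top <- names(sort(mean_phi, decreasing = TRUE))[seq_len(min(top_k,
                                                              nrow(G)))]
  cv <- apply(G[top, , drop = FALSE], 1L, function(v) {
    if (mean(v) == 0) 0 else stats::sd(v) / mean(v)
  })
  out <- list(spearman = sp, min_spearman = min(sp[upper.tri(sp)]),
              cv_top = cv, max_cv = max(cv), runs = G)
  class(out) <- "agfn_stability"
  out
}

#' @export
print.agfn_stability <- function(x, ...) {
  cat(sprintf("SHAP stability: min pairwise Spearman %.3f, max CV %.3f\n",
              x$min_spearman, x$max_cv))
  invisible(x)
}

#' Temporal contribution profile and clinical phase shares
#'
#' Per-time-bin summed |phi| for one attributed patient, with the share of
#' total attribution falling in the hyperacute (0-6 h), acute (6-24 h) and
#' subacute (24-72 h) windows. Shares are normalized to sum to 1 when any
#' attribution mass exists.
#'
#' @param attribution an `agfn_attribution` with per-bin values.
#' @param patient index into the attribution's patient list.
#' @return list with `profile` (per-bin |phi|) and `phase_shares`.
#' @export
temporal_contribution_map <- function(attribution, patient = 1L) {
  stopifnot(inherits(attribution, "agfn_attribution"))
  if (is.null(attribution$phi_time)) stop("per-bin attributions missing")
  prof <- apply(abs(attribution$phi_time[patient, , , drop = FALSE]),
                2L, sum)
  tb <- attribution$tbins
  phases <- c(hyperacute_0_6h = sum(prof[tb < 6]),
              acute_6_24h = sum(prof[tb >= 6 & tb < 24]),
              subacute_24_72h = sum(prof[tb >= 24]))
  tot <- sum(phases)
  shares <- if (tot > 0) phases / tot else phases * 0
  list(profile = prof, phase_shares = shares)
}
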