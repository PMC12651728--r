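# Dual-scale temporal encoding. The short-term branch is a gated 1D
# convolution (acute-event detector, max-pooled over time); the long-term
# branch is a GRU whose extra gate mixes the previous hidden state with an
# exponential moving average of earlier states, stabilizing long-range
# memory. Plain forward functions are exported for direct use and testing;
# the training loop drives the same arithmetic through the autodiff tape.

#' Gated short-term convolution at one window position
#'
#' `y = sigmoid(W_g * X + b_g) (*) relu(W_c * X + b_c)` where `*` is the
#' sliding-window inner product over a window of `w` time steps and `(*)` is
#' elementwise. The gate lies in (0, 1), the content branch in `[0, Inf)`, so
#' the output is non-negative and the gate can silence spurious fluctuations.
#'
#' @param window numeric matrix (w x D): the temporal window, rows = time.
#' @param W_g,W_c gate/content kernels: vectors of length `w * D` or matrices
#'   (`w * D` x channels), flattened time-major (all D channels of the first
#'   time step first).
#' @param b_g,b_c biases (per channel).
#' @return numeric vector of gated channel activations.
#' @export
st_cnn_forward <- function(window, W_g, W_c, b_g = 0, b_c = 0) {
  x <- as.vector(t(as.matrix(window)))
  Wg <- if (is.matrix(W_g)) W_g else cbind(W_g)
  Wc <- if (is.matrix(W_c)) W_c else cbind(W_c)
  if (nrow(Wg) != length(x) || nrow(Wc) != length(x)) {
    stop("kernel size does not match the window (need w * D rows)")
  }
  gate <- stats::plogis(as.vector(crossprod(Wg, x)) + b_g)
  content <- pmax(as.vector(crossprod(Wc, x)) + b_c, 0)
  gate * content
}

#' One step of the long-term GRU with EMA-gated memory
#'
#' Standard GRU gates plus a stabilizer gate
#' `g_t = sigmoid(W_g x_t + U_g (beta * h_{t-1} + (1 - beta) * EMA(h_{t-2})))`
#' which multiplies the update gate, giving
#' `h_t = (1 - z_t (*) g_t) (*) h_{t-1} + (z_t (*) g_t) (*) htilde_t` -- an
#' elementwise convex combination of the previous state and the candidate,
#' so the state can never escape the envelope of its inputs.
#'
#' @param x input vector at time t.
#' @param h_prev previous hidden state `h_{t-1}`.
#' @param ema EMA of hidden states through `t-2` (same length as `h_prev`).
#' @param params list with matrices `Wz, Uz, Wr, Ur, Wh, Uh, Wg, Ug` (inputs
#'   map by `W`, states by `U`) and optional biases `bz, br, bh, bg`.
#' @param beta decay factor in `[0, 1]` shared by the EMA recursion and the
#'   gate mixing weight.
#' @return list with the new state `h`, and the gates `z`, `r`, `g`,
#'   candidate `htilde`.
#' @export
lt_gru_step <- function(x, h_prev, ema, params, beta = 0.9) {
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]")
  p <- params
  b <- function(nm) if (is.null(p[[nm]])) 0 else as.vector(p[[nm]])
  z <- stats::plogis(as.vector(crossprod(p$Wz, x) + crossprod(p$Uz, h_prev)) + b("bz"))
  r <- stats::plogis(as.vector(crossprod(p$Wr, x) + crossprod(p$Ur, h_prev)) + b("br"))
  htilde <- tanh(as.vector(crossprod(p$Wh, x) + crossprod(p$Uh, r * h_prev)) + b("bh"))
  mix <- beta * h_prev + (1 - beta) * ema
  g <- stats::plogis(as.vector(crossprod(p$Wg, x) + crossprod(p$Ug, mix)) + b("bg"))
  zg <- z * g
  h <- (1 - zg) * h_prev + zg * htilde
  list(h = h, z = z, r = r, g = g, htilde = htilde)
}

#' Encode one patient's aligned sequence with both temporal branches
#'
#' Runs the gated convolution over every window position and max-pools over
#' time (acute-event semantics), runs the LT-GRU left to right and keeps the
#' final state (trend semantics), and concatenates `[h_ST ; h_LT]`. The EMA
#' recursion is `EMA_t = beta * h_t + (1 - beta) * EMA_{t-1}` with
#' `EMA_0 = h_0 = 0`; the gate at step t consumes the EMA through `t-2`.
#' An empty time axis returns a zero vector with attribute `fallback = TRUE`.
#'
#' @param X numeric matrix (T x Din): the encoder input sequence (values and
#'   mask channels).
#' @param params a parameter list from [temporal_params()].
#' @return numeric vector of length `channels + hidden`.
#' @export
encode_patient <- function(X, params) {
  X <- as.matrix(X)
  Tn <- nrow(X)
  c_out <- ncol(params$st$Wc)
  hid <- ncol(params$gru$Uz)
  if (Tn == 0L) {
    out <- numeric(c_out + hid)
    attr(out, "fallback") <- TRUE
    return(out)
  }
  w <- params$st$w
  if (w > Tn) stop("window length exceeds the sequence length")
  P <- Tn - w + 1L
  st_acts <- matrix(0, P, c_out)
  for (pos in seq_len(P)) {
    st_acts[pos, ] <- st_cnn_forward(X[pos:(pos + w - 1L), , drop = FALSE],
                                     params$st$Wg, params$st$Wc,
                                     as.vector(params$st$bg),
                                     as.vector(params$st$bc))
  }
  h_st <- apply(st_acts, 2L, max)

  h <- numeric(hid)
  ema_tm2 <- numeric(hid)   # EMA through t-2 (EMA_0 = h_0 = 0)
  ema_tm1 <- numeric(hid)
  gp <- params$gru
  for (t in seq_len(Tn)) {
    res <- lt_gru_step(X[t, ], h, ema_tm2, gp, params$beta)
    ema_tm2 <- ema_tm1
    ema_tm1 <- params$beta * res$h + (1 - params$beta) * ema_tm1
    h <- res$h
  }
  c(h_st, h)
}

#' Initialize dual-scale temporal encoder parameters
#'
#' @param d_in input channels per time step (values + masks).
#' @param window ST-CNN window length in hourly bins (default 6: the
#'   hyperacute 0-6 h phase).
#' @param channels ST-CNN output channels.
#' @param hidden LT-GRU hidden dimension.
#' @param beta EMA decay / gate mixing factor in `[0, 1]`.
#' @param seed RNG seed for the initialization.
#' @return nested parameter list (`$st`, `$gru`, `$beta`).
#' @export
temporal_params <- function(d_in, window = 6L, channels = 16L, hidden = 24L,
                            beta = 0.9, seed = 1L) {
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]")
  with_seed(seed, {
    st <- list(Wg = init_weight(window * d_in, channels),
               Wc = init_weight(window * d_in, channels),
               bg = matrix(0, 1L, channels),
               bc = matrix(0, 1L, channels),
               w = as.integer(window))
    gru <- list(Wz = init_weight(d_in, hidden), Uz = init_weight(hidden, hidden),
                Wr = init_weight(d_in, hidden), Ur = init_weight(hidden, hidden),
                Wh = init_weight(d_in, hidden), Uh = init_weight(hidden, hidden),
                Wg = init_weight(d_in, hidden), Ug = init_weight(hidden, hidden),
                bz = matrix(0, 1L, hidden), br = matrix(0, 1L, hidden),
                bh = matrix(0, 1L, hidden), bg = matrix(0, 1L, hidden))
    list(st = st, gru = gru, beta = beta)
  })
}

# flatten/unflatten temporal params for the optimizer
temporal_param_list <- function(params) {
  c(params$st[c("Wg", "Wc", "bg", "bc")], params$gru)
}

## ---- tape (batched) versions used by the training loop ----

# Batched dual-scale encoding on the tape. `xin` is a tape id holding the
# stacked sequences ((N * T) x Din, patient-major rows); `pid` gives the
# parameter leaf ids. Returns the (N x (channels + hidden)) node id.
tape_temporal_encode <- function(tp, xin, N, Tn, pid, window, beta) {
  P <- Tn - window + 1L
  # unfold: rows r = (i - 1) * P + p pick input rows (i - 1) * T + p + dt
  base <- rep((seq_len(N) - 1L) * Tn, each = P) + rep(seq_len(P), N)
  unf <- NULL
  for (dt in 0:(window - 1L)) {
    g <- ad_rows(tp, xin, base + dt)
    unf <- if (is.null(g) || is.null(unf)) g else ad_cbind2(tp, unf, g)
  }
  gate <- ad_sigmoid(tp, ad_addbias(tp, ad_matmul(tp, unf, pid$Wg), pid$bg))
  content <- ad_relu(tp, ad_addbias(tp, ad_matmul(tp, unf, pid$Wc), pid$bc))
  acts <- ad_mul(tp, gate, content)
  groups <- rep(seq_len(N), each = P)
  h_st <- ad_maxpool_group(tp, acts, groups, N)

  hid <- ncol(ad_val(tp, pid$Uz))
  h <- ad_leaf(tp, matrix(0, N, hid), grad = FALSE)
  ema_tm2 <- ad_leaf(tp, matrix(0, N, hid), grad = FALSE)
  ema_tm1 <- ema_tm2
  for (t in seq_len(Tn)) {
    xt <- ad_rows(tp, xin, (seq_len(N) - 1L) * Tn + t)
    hnew <- ad_gru_step(tp, xt, h, ema_tm2, pid, beta)
    ema_new <- ad_add(tp, ad_scale(tp, hnew, beta),
                      ad_scale(tp, ema_tm1, 1 - beta))
    ema_tm2 <- ema_tm1
    ema_tm1 <- ema_new
    h <- hnew
  }
  ad_cbind2(tp, h_st, h)
}
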