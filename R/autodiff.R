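# Minimal reverse-mode automatic differentiation on matrices.
#
# Every value on the tape is a numeric matrix (scalars are 1x1). Operations
# append a node holding the forward value, parent ids, and a backward closure
# mapping the incoming gradient to parent gradients. This is all the machinery
# the trainable components (contrastive encoder, temporal encoders, graph
# attention) need; it is deliberately small and fully tested against
# numerical gradients.

ad_tape <- function(nalloc = 4096L) {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", nalloc)
  e$n <- 0L
  class(e) <- "ad_tape"
  e
}

ad_node <- function(tape, val, parents = integer(0), back = NULL) {
  force(val); force(parents)   # nested op calls mutate the tape; force first
  parents <- as.integer(parents)
  # gradient pruning: a node whose ancestors are all gradient-free constants
  # needs no backward closure
  needs <- FALSE
  for (p in parents) if (tape$nodes[[p]]$needs) { needs <- TRUE; break }
  if (!needs) back <- NULL
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- list(val = val, parents = parents, back = back,
                          needs = needs)
  tape$n <- n
  n
}

# `grad = FALSE` marks a constant input: no gradient is ever propagated into
# it or through ops that depend on it alone.
ad_leaf <- function(tape, val, grad = TRUE) {
  id <- ad_node(tape, as_mat(val))
  tape$nodes[[id]]$needs <- grad
  id
}

sigm <- function(x) 1 / (1 + exp(-x))

ad_val <- function(tape, id) {
  force(id)                    # force before touching tape$nodes: the id may
  tape$nodes[[id]]$val         # be a nested op call that appends to the tape
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

# Reverse sweep from node `id`; returns a list of gradients indexed by node id
# (NULL where no gradient flows). `seed` defaults to a matrix of ones shaped
# like the output (use the default only on scalar outputs).
ad_backward <- function(tape, id, seed = NULL) {
  force(id)
  grads <- vector("list", tape$n)
  v <- ad_val(tape, id)
  grads[[id]] <- if (is.null(seed)) array(1, dim = dim(v)) else seed
  for (k in seq.int(id, 1L)) {
    g <- grads[[k]]
    if (is.null(g)) next
    nd <- tape$nodes[[k]]
    if (is.null(nd$back)) next
    pg <- nd$back(g)
    for (j in seq_along(nd$parents)) {
      if (is.null(pg[[j]])) next
      p <- nd$parents[[j]]
      if (!isTRUE(tape$nodes[[p]]$needs)) next   # constant subtree
      grads[[p]] <- if (is.null(grads[[p]])) pg[[j]] else grads[[p]] + pg[[j]]
    }
  }
  grads
}

## ---- elementwise and linear-algebra ops ----

ad_add <- function(tape, a, b) {
  ad_node(tape, ad_val(tape, a) + ad_val(tape, b), c(a, b),
          function(g) list(g, g))
}

ad_sub <- function(tape, a, b) {
  ad_node(tape, ad_val(tape, a) - ad_val(tape, b), c(a, b),
          function(g) list(g, -g))
}

ad_mul <- function(tape, a, b) {
  A <- ad_val(tape, a); B <- ad_val(tape, b)
  ad_node(tape, A * B, c(a, b), function(g) list(g * B, g * A))
}

# A [n x k] plus bias stored as a 1 x k matrix, broadcast over rows.
ad_addbias <- function(tape, a, bias) {
  A <- ad_val(tape, a); B <- ad_val(tape, bias)
  ad_node(tape, A + rep(as.vector(B), each = nrow(A)), c(a, bias),
          function(g) list(g, matrix(colSums(g), nrow = 1L)))
}

ad_matmul <- function(tape, a, b) {
  A <- ad_val(tape, a); B <- ad_val(tape, b)
  ad_node(tape, A %*% B, c(a, b),
          function(g) list(tcrossprod(g, B), crossprod(A, g)))
}

# A %*% t(B) without materializing an explicit transpose node.
ad_matmul_tB <- function(tape, a, b) {
  A <- ad_val(tape, a); B <- ad_val(tape, b)
  ad_node(tape, tcrossprod(A, B), c(a, b),
          function(g) list(g %*% B, crossprod(g, A)))
}

ad_scale <- function(tape, a, s) {
  ad_node(tape, ad_val(tape, a) * s, a, function(g) list(g * s))
}

ad_mulc <- function(tape, a, C) {
  ad_node(tape, ad_val(tape, a) * C, a, function(g) list(g * C))
}

ad_addc <- function(tape, a, C) {
  ad_node(tape, ad_val(tape, a) + C, a, function(g) list(g))
}

ad_sigmoid <- function(tape, a) {
  s <- sigm(ad_val(tape, a))
  ad_node(tape, s, a, function(g) list(g * s * (1 - s)))
}

ad_tanh <- function(tape, a) {
  v <- tanh(ad_val(tape, a))
  ad_node(tape, v, a, function(g) list(g * (1 - v * v)))
}

ad_relu <- function(tape, a) {
  A <- ad_val(tape, a)
  ad_node(tape, pmax(A, 0), a, function(g) list(g * (A > 0)))
}

ad_exp <- function(tape, a) {
  v <- exp(ad_val(tape, a))
  ad_node(tape, v, a, function(g) list(g * v))
}

ad_log <- function(tape, a) {
  A <- ad_val(tape, a)
  ad_node(tape, log(A), a, function(g) list(g / A))
}

ad_recip <- function(tape, a) {
  A <- ad_val(tape, a)
  ad_node(tape, 1 / A, a, function(g) list(-g / (A * A)))
}

ad_pow2 <- function(tape, a) {
  A <- ad_val(tape, a)
  ad_node(tape, A * A, a, function(g) list(2 * A * g))
}

ad_sum <- function(tape, a) {
  A <- ad_val(tape, a)
  d <- dim(A)
  ad_node(tape, matrix(sum(A), 1L, 1L), a,
          function(g) list(matrix(g[1L], d[1L], d[2L])))
}

ad_mean <- function(tape, a) {
  A <- ad_val(tape, a)
  d <- dim(A); n <- length(A)
  ad_node(tape, matrix(mean(A), 1L, 1L), a,
          function(g) list(matrix(g[1L] / n, d[1L], d[2L])))
}

## ---- structural ops ----

ad_rows <- function(tape, a, idx) {
  A <- ad_val(tape, a)
  idx <- as.integer(idx)
  nr <- nrow(A); nc <- ncol(A)
  ad_node(tape, A[idx, , drop = FALSE], a, function(g) {
    z <- matrix(0, nr, nc)
    rs <- rowsum(g, idx)
    z[as.integer(rownames(rs)), ] <- rs
    list(z)
  })
}

# Sum rows of A into `ngroups` buckets given integer group labels per row.
ad_group_sum <- function(tape, a, groups, ngroups) {
  A <- ad_val(tape, a)
  groups <- as.integer(groups)
  z <- matrix(0, ngroups, ncol(A))
  rs <- rowsum(A, groups)
  z[as.integer(rownames(rs)), ] <- rs
  ad_node(tape, z, a, function(g) list(g[groups, , drop = FALSE]))
}

ad_cbind2 <- function(tape, a, b) {
  A <- ad_val(tape, a); B <- ad_val(tape, b)
  ka <- ncol(A)
  ad_node(tape, cbind(A, B), c(a, b), function(g) {
    list(g[, seq_len(ka), drop = FALSE],
         g[, -seq_len(ka), drop = FALSE])
  })
}

ad_rbind2 <- function(tape, a, b) {
  A <- ad_val(tape, a); B <- ad_val(tape, b)
  na <- nrow(A)
  ad_node(tape, rbind(A, B), c(a, b), function(g) {
    list(g[seq_len(na), , drop = FALSE],
         g[-seq_len(na), , drop = FALSE])
  })
}

ad_cols <- function(tape, a, cols) {
  A <- ad_val(tape, a)
  cols <- as.integer(cols)
  nr <- nrow(A); nc <- ncol(A)
  ad_node(tape, A[, cols, drop = FALSE], a, function(g) {
    z <- matrix(0, nr, nc)
    z[, cols] <- z[, cols] + g
    list(z)
  })
}

## ---- model-specific fused ops ----

# L2-normalize each row (cosine-similarity ready embeddings).
ad_rownorm <- function(tape, a, eps = 1e-12) {
  A <- ad_val(tape, a)
  nrm <- sqrt(rowSums(A * A) + eps)
  Y <- A / nrm
  ad_node(tape, Y, a, function(g) {
    list(g / nrm - Y * (rowSums(g * Y) / nrm))
  })
}

# Row-wise inner products: returns an E x 1 column of rowSums(A * B).
ad_rowsum_prod <- function(tape, a, b) {
  A <- ad_val(tape, a); B <- ad_val(tape, b)
  ad_node(tape, cbind(rowSums(A * B)), c(a, b), function(g) {
    gv <- as.vector(g)
    list(B * gv, A * gv)
  })
}

# Scale each row of A [E x k] by the E x 1 column w.
ad_colscale <- function(tape, a, w) {
  A <- ad_val(tape, a); W <- as.vector(ad_val(tape, w))
  ad_node(tape, A * W, c(a, w), function(g) {
    list(g * W, cbind(rowSums(g * A)))
  })
}

# Per-row log-sum-exp over off-diagonal entries of a square matrix
# (the denominator of the supervised contrastive objective).
ad_row_lse_offdiag <- function(tape, a) {
  S <- ad_val(tape, a)
  M <- S; diag(M) <- -Inf
  m <- apply(M, 1L, max)
  L <- m + log(rowSums(exp(M - m)))
  P <- exp(M - L)          # softmax over a != i, rows sum to 1
  diag(P) <- 0
  ad_node(tape, cbind(L), a, function(g) list(P * as.vector(g)))
}

# Column-wise max over row groups; `groups` labels each row of A, result has
# `ngroups` rows. Groups are disjoint so scatter indices never collide.
ad_maxpool_group <- function(tape, a, groups, ngroups) {
  A <- ad_val(tape, a)
  groups <- as.integer(groups)
  nc <- ncol(A); nr <- nrow(A)
  out <- matrix(-Inf, ngroups, nc)
  arg <- matrix(NA_integer_, ngroups, nc)
  idx_by_g <- split(seq_len(nr), groups)
  for (gn in names(idx_by_g)) {
    gi <- as.integer(gn)
    rows <- idx_by_g[[gn]]
    sub <- A[rows, , drop = FALSE]
    am <- max.col(t(sub), ties.method = "first")
    out[gi, ] <- sub[cbind(am, seq_len(nc))]
    arg[gi, ] <- rows[am]
  }
  ad_node(tape, out, a, function(g) {
    z <- matrix(0, nr, nc)
    ok <- which(!is.na(arg))
    cols <- ((ok - 1L) %/% ngroups) + 1L
    z[cbind(arg[ok], cols)] <- g[ok]
    list(z)
  })
}

# One fused LT-GRU step (gates, EMA-mixed stabilizer gate, convex state
# update) with a hand-derived backward; fusing the ~25 primitive ops per time
# step into one node keeps 72-step sequences cheap. Parameter order:
# xt, h, ema, Wz, Uz, Wr, Ur, Wh, Uh, Wg2, Ug, bz, br, bh, bg2.
ad_gru_step <- function(tape, xt, h, ema, p, beta) {
  X <- ad_val(tape, xt); H <- ad_val(tape, h); E <- ad_val(tape, ema)
  v <- function(id) ad_val(tape, id)
  Wz <- v(p$Wz); Uz <- v(p$Uz); Wr <- v(p$Wr); Ur <- v(p$Ur)
  Wh <- v(p$Wh); Uh <- v(p$Uh); Wg <- v(p$Wg2); Ug <- v(p$Ug)
  n <- nrow(X)
  ab <- function(M, b) M + rep(as.vector(v(b)), each = n)
  z <- sigm(ab(X %*% Wz + H %*% Uz, p$bz))
  r <- sigm(ab(X %*% Wr + H %*% Ur, p$br))
  rh <- r * H
  cnd <- tanh(ab(X %*% Wh + rh %*% Uh, p$bh))
  mix <- beta * H + (1 - beta) * E
  g <- sigm(ab(X %*% Wg + mix %*% Ug, p$bg2))
  u <- z * g
  hn <- H + u * (cnd - H)
  ad_node(tape, hn,
          c(xt, h, ema, p$Wz, p$Uz, p$Wr, p$Ur, p$Wh, p$Uh, p$Wg2, p$Ug,
            p$bz, p$br, p$bh, p$bg2),
          function(G) {
            dc <- G * u
            du <- G * (cnd - H)
            dH <- G * (1 - u)
            dag <- (du * z) * g * (1 - g)
            dmix <- tcrossprod(dag, Ug)
            dH <- dH + beta * dmix
            dE <- (1 - beta) * dmix
            dah <- dc * (1 - cnd * cnd)
            drh <- tcrossprod(dah, Uh)
            dar <- (drh * H) * r * (1 - r)
            dH <- dH + drh * r + tcrossprod(dar, Ur)
            daz <- (du * g) * z * (1 - z)
            dH <- dH + tcrossprod(daz, Uz)
            dX <- tcrossprod(daz, Wz) + tcrossprod(dar, Wr) +
              tcrossprod(dah, Wh) + tcrossprod(dag, Wg)
            cs <- function(m) matrix(colSums(m), nrow = 1L)
            list(dX, dH, dE,
                 crossprod(X, daz), crossprod(H, daz),
                 crossprod(X, dar), crossprod(H, dar),
                 crossprod(X, dah), crossprod(rh, dah),
                 crossprod(X, dag), crossprod(mix, dag),
                 cs(daz), cs(dar), cs(dah), cs(dag))
          })
}

# Numerically stable summed binary cross-entropy with logits.
# `y` and `w` are constant matrices conformable with the logits; the loss is
# sum(w * (softplus(l) - y * l)) which for y in {0,1} is the usual BCE.
ad_bce_logits <- function(tape, logits, y, w = NULL) {
  L <- ad_val(tape, logits)
  if (is.null(w)) w <- matrix(1, nrow(L), ncol(L))
  sp <- pmax(L, 0) + log1p(exp(-abs(L)))
  val <- sum(w * (sp - y * L))
  ad_node(tape, matrix(val, 1L, 1L), logits, function(g) {
    list(g[1L] * w * (stats::plogis(L) - y))
  })
}

ad_dropout <- function(tape, a, mask) {
  ad_mulc(tape, a, mask)
}

## ---- group softmax built from primitives ----

# Softmax of an E x 1 logit column within destination groups, with an optional
# constant additive bias (log edge weights). Returns the E x 1 weight column.
ad_group_softmax <- function(tape, logits, groups, ngroups, bias = NULL) {
  if (!is.null(bias)) logits <- ad_addc(tape, logits, cbind(bias))
  lv <- as.vector(ad_val(tape, logits))
  shift <- vapply(split(lv, groups), max, numeric(1))[as.character(groups)]
  centered <- ad_addc(tape, logits, cbind(-unname(shift)))
  e <- ad_exp(tape, centered)
  s <- ad_group_sum(tape, e, groups, ngroups)
  ad_mul(tape, e, ad_recip(tape, ad_rows(tape, s, groups)))
}

## ---- optimizer ----

# AdamW with decoupled weight decay and global-norm gradient clipping.
adamw_init <- function(params) {
  zero <- lapply(params, function(p) array(0, dim = dim(as_mat(p))))
  list(m = zero, v = zero, t = 0L)
}

adamw_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       weight_decay = 1e-4, clip = 1.0) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  if (is.finite(clip) && gn > clip) grads <- lapply(grads, function(g) g * (clip / gn))
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    g <- grads[[i]]
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g * g
    mhat <- state$m[[i]] / bc1
    vhat <- state$v[[i]] / bc2
    params[[i]] <- params[[i]] - lr * (mhat / (sqrt(vhat) + eps) +
                                         weight_decay * params[[i]])
  }
  list(params = params, state = state)
}

# Cosine-annealed learning rate over `total` epochs.
cosine_lr <- function(lr0, epoch, total, lr_min = lr0 * 0.01) {
  lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * min(epoch, total) / total))
}

# Run-scoped RNG: evaluates `expr` under `seed` and restores the caller's RNG
# state, so every stochastic stage draws from its own seeded stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# He/Glorot-style initializer used across all trainable blocks.
init_weight <- function(nin, nout, scale = sqrt(2 / (nin + nout))) {
  matrix(stats::rnorm(nin * nout, sd = scale), nin, nout)
}
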