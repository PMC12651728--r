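# Density-adaptive KNN patient graph: Gaussian-kernel density estimates size
# each patient's neighborhood inversely to local embedding density, so rare
# phenotypes in sparse regions get broader relational support while dense
# clusters avoid redundant edges. Topology is built on training embeddings
# only and frozen before held-out patients attach.

#' Gaussian kernel density of patient embeddings
#'
#' `rho_i = 1/(N h^d) * sum_j K(||h_i - h_j|| / h)` with the standard
#' Gaussian kernel `K(u) = (2 pi)^{-d/2} exp(-u^2 / 2)`. The mean density
#' `rho_bar` is taken over the (training) rows of `embeddings`.
#'
#' @param embeddings numeric matrix (patients x d).
#' @param h kernel bandwidth (> 0); defaults to 0.25, inside the stable
#'   0.2-0.3 band for unit-sphere embeddings.
#' @param query optional matrix of held-out embeddings whose density is
#'   evaluated against `embeddings` without entering `rho_bar`.
#' @return an object of class `agfn_density`: `rho`, `rho_bar`, `h`, `d`.
#' @export
kde_density <- function(embeddings, h = 0.25, query = NULL) {
  if (h <= 0) stop("bandwidth h must be > 0")
  E <- as.matrix(embeddings)
  n <- nrow(E); d <- ncol(E)
  gauss <- function(D2) exp(-D2 / (2 * h^2)) * (2 * pi)^(-d / 2)
  rho_of <- function(Q) {
    D2 <- pairwise_sqdist(Q, E)
    rowSums(gauss(D2)) / (n * h^d)
  }
  rho <- rho_of(E)
  out <- list(rho = rho, rho_bar = mean(rho), h = h, d = d)
  if (!is.null(query)) out$rho_query <- rho_of(as.matrix(query))
  class(out) <- "agfn_density"
  out
}

pairwise_sqdist <- function(A, B) {
  an <- rowSums(A * A); bn <- rowSums(B * B)
  D2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(D2, 0)
}

#' Adaptive neighborhood size from relative density
#'
#' `k_i = min(k_max, max(1, floor(k_base * rho_bar / rho_i)))`: sparse
#' patients (low density) receive more neighbors, dense ones fewer, with the
#' population mean anchored near `k_base`. Flooring the ratio is the
#' documented rounding rule. Monotone non-increasing in `rho_i`.
#'
#' @param rho per-patient density (> 0), possibly a vector.
#' @param rho_bar cohort mean density over training patients (> 0).
#' @param k_base reference neighborhood size (>= 1); default 15.
#' @param k_max upper bound (>= k_base is typical); default 30.
#' @return integer vector of neighborhood sizes in `[1, k_max]`.
#' @export
adaptive_k <- function(rho, rho_bar, k_base = 15L, k_max = 30L) {
  if (any(rho <= 0) || rho_bar <= 0) stop("densities must be > 0")
  if (k_base < 1) stop("k_base must be >= 1")
  if (k_max < k_base) stop("k_max must be >= k_base")
  as.integer(pmin(k_max, pmax(1, floor(k_base * rho_bar / rho))))
}

#' Gaussian edge weight between two embeddings
#'
#' `A(i, j) = exp(-||h_i - h_j||^2 / (2 sigma^2))`, symmetric in its
#' arguments, in `(0, 1]`.
#'
#' @param h_i,h_j embedding vectors.
#' @param sigma edge-kernel bandwidth (> 0).
#' @return scalar weight.
#' @export
gaussian_edge_weight <- function(h_i, h_j, sigma) {
  if (sigma <= 0) stop("sigma must be > 0")
  exp(-sum((h_i - h_j)^2) / (2 * sigma^2))
}

#' Build the density-adaptive KNN graph on training embeddings
#'
#' Estimates densities by KDE, sizes each node's neighborhood with
#' [adaptive_k()], links node i to its `k_i` nearest training nodes by
#' embedding distance (directed, stored i -> neighbors(i)), and weights each
#' edge with the Gaussian kernel. `sigma` defaults to the median
#' nearest-neighbor distance among training embeddings. Alternatively,
#' `density_method = "edge_mean"` replaces the KDE by the mean Gaussian edge
#' weight to the `k0` nearest neighbors (a fast estimator; `k0` defaults to
#' `k_base`).
#'
#' @param embeddings training embeddings (patients x d).
#' @param k_base reference neighborhood size; `k_max` its cap.
#' @param k_max upper bound on any `k_i`.
#' @param h KDE bandwidth.
#' @param sigma edge-kernel bandwidth; `NULL` for the median-NN default.
#' @param density_method `"kde"` (default) or `"edge_mean"`.
#' @param k0 neighbor count for the `edge_mean` estimator.
#' @return an object of class `agfn_graph` with per-node neighbor lists,
#'   edge weights, densities and the frozen bandwidths.
#' @export
build_graph <- function(embeddings, k_base = 15L, k_max = 30L, h = 0.25,
                        sigma = NULL, density_method = c("kde", "edge_mean"),
                        k0 = k_base) {
  density_method <- match.arg(density_method)
  E <- as.matrix(embeddings)
  n <- nrow(E)
  D2 <- pairwise_sqdist(E, E)
  diag(D2) <- Inf
  nn_dist <- sqrt(apply(D2, 1L, min))
  if (is.null(sigma)) sigma <- stats::median(nn_dist)
  if (sigma <= 0) sigma <- 1e-6

  if (density_method == "kde") {
    dens <- kde_density(E, h)
    rho <- dens$rho; rho_bar <- dens$rho_bar
  } else {
    k0 <- min(k0, n - 1L)
    rho <- vapply(seq_len(n), function(i) {
      nb <- order(D2[i, ])[seq_len(k0)]
      mean(exp(-D2[i, nb] / (2 * sigma^2)))
    }, numeric(1))
    rho_bar <- mean(rho)
  }

  k <- adaptive_k(rho, rho_bar, k_base, k_max)
  if (any(k > n - 1L)) {
    warning("k_i exceeds available candidates; truncated to N - 1")
    k <- pmin(k, n - 1L)
  }
  ord <- apply(D2, 1L, order)              # columns: neighbor ranking of i
  neighbors <- lapply(seq_len(n), function(i) ord[seq_len(k[i]), i])
  weights <- lapply(seq_len(n), function(i) {
    exp(-D2[i, neighbors[[i]]] / (2 * sigma^2))
  })
  g <- list(n = n, neighbors = neighbors, weights = weights, k = k,
            rho = rho, rho_bar = rho_bar, sigma = sigma, h = h,
            k_base = as.integer(k_base), k_max = as.integer(k_max),
            density_method = density_method, embeddings = E,
            refresh_epoch = 0L)
  class(g) <- "agfn_graph"
  g
}

#' @export
print.agfn_graph <- function(x, ...) {
  cat(sprintf(paste0("agfn_graph: %d nodes, mean k = %.2f (k_base %d, ",
                     "k_max %d), sigma = %.4f\n"),
              x$n, mean(x$k), x$k_base, x$k_max, x$sigma))
  invisible(x)
}

#' Attach held-out patients to a frozen training graph
#'
#' Held-out nodes receive densities from the training-fit KDE (using the
#' frozen `h` and training `rho_bar`), adaptive sizes from the frozen rule,
#' and neighbors drawn exclusively from training nodes. No training edge,
#' density or bandwidth changes.
#'
#' @param graph a frozen `agfn_graph` built on the training partition.
#' @param embeddings held-out embeddings (patients x d).
#' @return list with per-held-out-node `neighbors` (training indices),
#'   `weights`, `k` and `rho`.
#' @export
attach_nodes <- function(graph, embeddings) {
  stopifnot(inherits(graph, "agfn_graph"))
  Q <- as.matrix(embeddings)
  E <- graph$embeddings
  if (graph$density_method == "kde") {
    rho <- kde_density(E, graph$h, query = Q)$rho_query
  } else {
    D2q0 <- pairwise_sqdist(Q, E)
    k0 <- min(graph$k_base, graph$n)
    rho <- vapply(seq_len(nrow(Q)), function(i) {
      nb <- order(D2q0[i, ])[seq_len(k0)]
      mean(exp(-D2q0[i, nb] / (2 * graph$sigma^2)))
    }, numeric(1))
  }
  k <- adaptive_k(pmax(rho, 1e-300), graph$rho_bar, graph$k_base, graph$k_max)
  k <- pmin(k, graph$n)
  D2 <- pairwise_sqdist(Q, E)
  neighbors <- lapply(seq_len(nrow(Q)), function(i) {
    order(D2[i, ])[seq_len(k[i])]
  })
  weights <- lapply(seq_len(nrow(Q)), function(i) {
    exp(-D2[i, neighbors[[i]]] / (2 * graph$sigma^2))
  })
  list(neighbors = neighbors, weights = weights, k = k, rho = rho)
}

#' Refresh the graph during training with annealing and degree caps
#'
#' The effective `k_base` ramps linearly from `k_base_init` to the configured
#' `k_base` over the first 20% of training epochs, then stays constant. Per
#' node, the change in neighborhood size between consecutive refreshes is
#' clipped to `|delta k_i| <= 2` to prevent abrupt topology shifts. With
#' unchanged embeddings and a converged ramp the graph is a fixed point.
#'
#' @param graph the current `agfn_graph`.
#' @param embeddings current embeddings (same node order).
#' @param epoch current epoch (0-based), `total_epochs` the schedule length.
#' @param total_epochs total training epochs.
#' @param k_base_init starting value of the anneal (default 5).
#' @return the refreshed `agfn_graph`.
#' @export
refresh_graph <- function(graph, embeddings, epoch, total_epochs,
                          k_base_init = 5L) {
  stopifnot(inherits(graph, "agfn_graph"))
  kb <- effective_k_base(graph$k_base, epoch, total_epochs, k_base_init)
  E <- as.matrix(embeddings)
  n <- nrow(E)
  D2 <- pairwise_sqdist(E, E)
  diag(D2) <- Inf
  if (graph$density_method == "kde") {
    dens <- kde_density(E, graph$h)
    rho <- dens$rho; rho_bar <- dens$rho_bar
  } else {
    k0 <- min(graph$k_base, n - 1L)
    rho <- vapply(seq_len(n), function(i) {
      nb <- order(D2[i, ])[seq_len(k0)]
      mean(exp(-D2[i, nb] / (2 * graph$sigma^2)))
    }, numeric(1))
    rho_bar <- mean(rho)
  }
  k_new <- adaptive_k(rho, rho_bar, kb, graph$k_max)
  k_new <- pmin(k_new, n - 1L)
  k_new <- pmin(pmax(k_new, graph$k - 2L), graph$k + 2L)   # |delta k| <= 2
  k_new <- pmax(k_new, 1L)
  ord <- apply(D2, 1L, order)
  graph$neighbors <- lapply(seq_len(n), function(i) ord[seq_len(k_new[i]), i])
  graph$weights <- lapply(seq_len(n), function(i) {
    exp(-D2[i, graph$neighbors[[i]]] / (2 * graph$sigma^2))
  })
  graph$k <- k_new
  graph$rho <- rho
  graph$rho_bar <- rho_bar
  graph$embeddings <- E
  graph$refresh_epoch <- as.integer(epoch)
  graph
}

# linear ramp of k_base over the first 20% of epochs
effective_k_base <- function(k_base, epoch, total_epochs, k_base_init = 5L) {
  ramp <- max(1, floor(0.2 * total_epochs))
  if (epoch >= ramp) return(as.integer(k_base))
  frac <- epoch / ramp
  as.integer(round(k_base_init + frac * (k_base - k_base_init)))
}

#' Export a graph as an edge-list TSV plus a JSON statistics sidecar
#'
#' @param graph an `agfn_graph`.
#' @param path output directory (created if missing).
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path) {
  stopifnot(inherits(graph, "agfn_graph"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  edges <- data.frame(
    src = rep(seq_len(graph$n), lengths(graph$neighbors)),
    dst = unlist(graph$neighbors),
    weight = unlist(graph$weights))
  utils::write.table(edges, file.path(path, "edges.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  stats <- list(k = graph$k, rho = graph$rho, rho_bar = graph$rho_bar,
                sigma = graph$sigma, h = graph$h, k_base = graph$k_base,
                k_max = graph$k_max)
  jsonlite::write_json(stats, file.path(path, "graph_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# edge tables used by the fusion model: (src, dst, logw) with self-loops
graph_edge_table <- function(graph, attach = NULL, offset = 0L) {
  src <- unlist(graph$neighbors)
  dst <- rep(seq_len(graph$n), lengths(graph$neighbors))
  logw <- log(pmax(unlist(graph$weights), 1e-12))
  # self-loops: weight 1 -> log bias 0
  src <- c(src, seq_len(graph$n))
  dst <- c(dst, seq_len(graph$n))
  logw <- c(logw, rep(0, graph$n))
  if (!is.null(attach)) {
    m <- length(attach$neighbors)
    asrc <- unlist(attach$neighbors)
    adst <- rep(graph$n + seq_len(m), lengths(attach$neighbors))
    alogw <- log(pmax(unlist(attach$weights), 1e-12))
    src <- c(src, asrc, graph$n + seq_len(m))
    dst <- c(dst, adst, graph$n + seq_len(m))
    logw <- c(logw, alogw, rep(0, m))
  }
  list(src = src + offset, dst = dst + offset, logw = logw)
}
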