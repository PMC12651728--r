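test_that("kernel densities match the closed form and the brute-force pairwise sum", {
  # identical embeddings: all densities equal
  E <- matrix(1, 6, 3)
  d6 <- kde_density(E, h = 0.3)
  expect_equal(length(unique(round(d6$rho, 12))), 1L)
  # single point: rho = K(0) / h^d
  one <- kde_density(matrix(c(0.2, -0.1), 1, 2), h = 0.4)
  expect_equal(one$rho, (2 * pi)^(-1) / 0.4^2, tolerance = 1e-12)
  # dense cluster plus a distant outlier, against an explicit double loop
  set.seed(2)
  X <- rbind(matrix(rnorm(50 * 2, sd = 0.1), 50, 2), c(8, 8))
  est <- kde_density(X, h = 0.25)
  brute <- sapply(seq_len(51), function(i) {
    sum(sapply(seq_len(51), function(j) {
      u <- sqrt(sum((X[i, ] - X[j, ])^2)) / 0.25
      (2 * pi)^(-1) * exp(-u^2 / 2)
    })) / (51 * 0.25^2)
  })
  expect_equal(est$rho, brute, tolerance = 1e-10)
  expect_lt(est$rho[51], min(est$rho[1:50]))
  expect_error(kde_density(X, h = 0), "> 0")
})

test_that("adaptive neighborhood sizes follow the floor/cap arithmetic", {
  expect_equal(adaptive_k(1, 1, k_base = 15, k_max = 30), 15L)
  expect_equal(adaptive_k(1e9, 1, k_base = 15, k_max = 30), 1L)
  expect_equal(adaptive_k(1 / 3, 1, k_base = 15, k_max = 30), 30L)  # min(30, 45)
  expect_equal(adaptive_k(1 / 1.5, 1, k_base = 10, k_max = 30), 15L)
  # monotone non-increasing in density
  rho <- sort(stats::runif(50, 0.1, 5))
  ks <- adaptive_k(rho, 1, 15, 30)
  expect_true(all(diff(ks) <= 0))
  expect_true(all(ks >= 1 & ks <= 30))
  expect_error(adaptive_k(-1, 1), "> 0")
  expect_error(adaptive_k(1, 1, k_base = 10, k_max = 5), "k_max")
})

test_that("Gaussian edge weights follow the kernel and are symmetric", {
  expect_equal(gaussian_edge_weight(c(1, 2), c(1, 2), 0.5), 1)
  sig <- 0.7
  h_i <- c(0, 0); h_j <- c(sqrt(2) * sig, 0)    # squared distance 2 sigma^2
  expect_equal(gaussian_edge_weight(h_i, h_j, sig), exp(-1), tolerance = 1e-12)
  set.seed(1)
  for (k in 1:5) {
    a <- rnorm(4); b <- rnorm(4)
    expect_equal(gaussian_edge_weight(a, b, 0.3),
                 gaussian_edge_weight(b, a, 0.3))
  }
  expect_error(gaussian_edge_weight(1, 2, 0), "> 0")
})

test_that("neighbor lists equal a brute-force all-pairs distance sort", {
  set.seed(7)
  E <- matrix(rnorm(120 * 4), 120, 4)
  g <- build_graph(E, k_base = 8, k_max = 20, h = 0.5)
  for (i in c(1, 17, 55, 120)) {
    d <- sqrt(colSums((t(E) - E[i, ])^2))
    d[i] <- Inf
    expect_equal(g$neighbors[[i]], order(d)[seq_len(g$k[i])])
  }
  expect_true(all(unlist(g$weights) > 0 & unlist(g$weights) <= 1))
  expect_true(all(vapply(seq_len(g$n),
                         function(i) !(i %in% g$neighbors[[i]]), TRUE)))
  expect_true(all(lengths(g$neighbors) >= 1))
})

test_that("two nodes are forced to be mutual neighbors", {
  expect_warning(
    g <- build_graph(rbind(c(0, 0), c(1, 1)), k_base = 15, k_max = 30),
    "truncated")
  expect_equal(g$neighbors[[1]], 2L)
  expect_equal(g$neighbors[[2]], 1L)
})

test_that("sparse regions receive larger neighborhoods and density anti-correlates with k", {
  set.seed(3)
  dense <- matrix(rnorm(150 * 3, sd = 0.2), 150, 3)
  sparse <- matrix(rnorm(15 * 3, sd = 0.2), 15, 3) + 5
  g <- build_graph(rbind(dense, sparse), k_base = 10, k_max = 25, h = 0.4)
  expect_gt(mean(g$k[151:165]), mean(g$k[1:150]))
  expect_lt(stats::cor(g$rho, g$k, method = "spearman"), 0)
})

test_that("attaching held-out nodes uses frozen statistics and changes no training edge", {
  set.seed(4)
  E <- matrix(rnorm(80 * 3), 80, 3)
  g <- build_graph(E, k_base = 6, k_max = 15)
  snap <- serialize(g, NULL)
  att <- attach_nodes(g, matrix(rnorm(10 * 3), 10, 3))
  expect_identical(serialize(g, NULL), snap)
  expect_true(all(unlist(att$neighbors) %in% seq_len(80)))
  expect_true(all(att$k >= 1))
})

test_that("graph refresh anneals k_base and caps per-node degree changes at 2", {
  eff <- agfn:::effective_k_base
  expect_equal(eff(15, 0, 100, k_base_init = 5), 5L)
  expect_equal(eff(15, 10, 100, k_base_init = 5), 10L)
  expect_lt(eff(15, 10, 100, k_base_init = 5), 15L)
  for (ep in c(20, 21, 50, 99)) expect_equal(eff(15, ep, 100), 15L)

  set.seed(5)
  E <- matrix(rnorm(60 * 3), 60, 3)
  g <- build_graph(E, k_base = 15, k_max = 30)
  # force a large demanded jump: current degrees 5, demand ~15 -> realized 7
  g$k <- rep(5L, 60)
  g2 <- refresh_graph(g, E, epoch = 50, total_epochs = 100)
  expect_true(all(abs(g2$k - 5L) <= 2L))
  expect_true(any(g2$k == 7L))
  # fixed point: with unchanged embeddings, degrees climb by at most 2 per
  # refresh until the demanded sizes are reached, then stop moving
  gi <- g2
  for (ep in seq(55, 90, by = 5)) {
    gnext <- refresh_graph(gi, E, epoch = ep, total_epochs = 100)
    expect_true(all(abs(gnext$k - gi$k) <= 2L))
    gi <- gnext
  }
  gfin <- refresh_graph(gi, E, epoch = 95, total_epochs = 100)
  expect_identical(gi$neighbors, gfin$neighbors)
  expect_identical(gi$k, gfin$k)
})

test_that("population mean neighborhood size stays near k_base with unconstrained caps", {
  set.seed(6)
  E <- matrix(rnorm(400 * 4, sd = 1), 400, 4)
  E <- E / sqrt(rowSums(E^2))                     # unit sphere, like embeddings
  g <- build_graph(E, k_base = 15, k_max = 30, h = 0.25)
  expect_gt(mean(g$k), 0.8 * 15)
  expect_lt(mean(g$k), 1.2 * 15)
})

test_that("the optional edge-mean density estimator also adapts k to sparsity", {
  set.seed(8)
  X <- rbind(matrix(rnorm(100 * 3, sd = 0.2), 100, 3),
             matrix(rnorm(10 * 3, sd = 0.2), 10, 3) + 4)
  g <- build_graph(X, k_base = 8, k_max = 20, density_method = "edge_mean")
  expect_gt(mean(g$k[101:110]), mean(g$k[1:100]))
  expect_lt(stats::cor(g$rho, g$k, method = "spearman"), 0)
})

test_that("graphs export as an edge list plus a JSON statistics sidecar", {
  set.seed(9)
  g <- build_graph(matrix(rnorm(20 * 2), 20, 2), k_base = 3, k_max = 6)
  d <- withr::local_tempdir()
  export_graph(g, d)
  edges <- utils::read.delim(file.path(d, "edges.tsv"))
  expect_equal(nrow(edges), sum(lengths(g$neighbors)))
  js <- jsonlite::read_json(file.path(d, "graph_stats.json"),
                            simplifyVector = TRUE)
  expect_equal(js$k_base, 3L)
  expect_equal(js$sigma, g$sigma, tolerance = 1e-9)
  expect_length(js$k, 20L)
})
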