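# Shared heavy fixtures, built once per test run and cached. Everything is
# generated in code from fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# mid-sized cohort for module-level tests
small_cohort <- function() {
  fixture("cohort300", function() {
    simulate_cohort(sim_config(n_patients = 300L, seed = 5L))
  })
}

# the synthetic default cohort (study conditions: n = 2000)
default_cohort <- function() {
  fixture("cohort2000", function() {
    simulate_cohort(sim_config(n_patients = 2000L, seed = 20L))
  })
}

# compact fusion configuration used by the desk-scale training fixtures
test_fusion_config <- function(seed = 7L, max_epochs = 30L, patience = 8L) {
  fusion_config(hidden = 64L, channels = 16L, gru_hidden = 24L, lr = 1e-3,
                max_epochs = max_epochs, patience = patience, seed = seed)
}

# a trained single-fold pipeline on the mid-sized cohort (cached; ~15 s)
trained_fold <- function() {
  fixture("trained300", function() {
    ch <- small_cohort()
    pts <- ch$statics$patient_id
    L <- agfn:::outcome_labels(ch, pts)
    plan <- make_folds(L, K = 10L, seed = 2L)
    val_ids <- pts[plan$val[[1L]]]
    train_ids <- setdiff(pts, val_ids)
    res <- agfn_fold_run(ch, train_ids, val_ids,
                         fusion = test_fusion_config(), seed = 3L)
    res$cohort_train_ids <- train_ids
    res$cohort_val_ids <- val_ids
    res
  })
}

# blob features with label-dependent structure for embedding/graph tests
label_blobs <- function(n = 80L, d = 6L, shift = 3, seed = 11L) {
  agfn:::with_seed(seed, {
    y <- rep(c(0L, 1L), length.out = n)
    X <- matrix(stats::rnorm(n * d), n, d)
    X[y == 1L, 1:2] <- X[y == 1L, 1:2] + shift
    list(X = X, y = y)
  })
}

expect_partition_disjoint <- function(...) {
  sets <- list(...)
  for (a in seq_along(sets)) {
    for (b in seq_along(sets)) {
      if (a < b) expect_length(intersect(sets[[a]], sets[[b]]), 0L)
    }
  }
}
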