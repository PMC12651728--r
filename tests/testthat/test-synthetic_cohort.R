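test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_patients = 0), "positive")
  expect_error(sim_config(horizon_hours = 0), "positive")
  expect_error(sim_config(vital_interval_h = 1.5), "0, 1")
  expect_error(sim_config(outcome_prevalences = rep(0.5, 5)), "length 6")
  expect_error(sim_config(outcome_prevalences = c(0, .1, .1, .1, .1, .1)),
               "lie in")
  expect_error(sim_config(rare_cluster_fraction = 1.2), "proportions")
})

test_that("identical seeds yield identical cohorts and do not disturb the caller's RNG", {
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  a <- simulate_cohort(sim_config(n_patients = 120, seed = 7))
  after <- rnorm(1)
  b <- simulate_cohort(sim_config(n_patients = 120, seed = 7))
  expect_identical(a$timeseries, b$timeseries)
  expect_identical(a$statics, b$statics)
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(before, after)   # generator RNG is scoped, not global
})

test_that("realized prevalences, rare fraction and missingness match the configured regime", {
  ch <- default_cohort()                     # n = 2000, defaults
  cfg <- attr(ch, "latent")$config
  prev <- tapply(ch$outcomes$label, ch$outcomes$outcome, mean)
  for (nm in names(cfg$outcome_prevalences)) {
    expect_lt(abs(prev[[nm]] - cfg$outcome_prevalences[[nm]]), 0.03)
  }
  expect_gt(mean(ch$statics$rare_phenotype), 0.03)
  expect_lt(mean(ch$statics$rare_phenotype), 0.07)

  # vitals: near-complete capture on the sub-hourly grid
  n_grid <- length(seq(0, ch$horizon - 1e-9, by = cfg$vital_interval_h))
  vit <- ch$timeseries[grepl("^vital", ch$timeseries$variable), ]
  vital_missing <- 1 - nrow(vit) / (2000 * cfg$n_vitals * n_grid)
  expect_lt(vital_missing, 0.05)

  # flagged labs: realized missingness above 0.40 at each flagged lab
  lat <- attr(ch, "latent")
  aud <- lat$lab_audit
  for (v in lat$flagged_labs) {
    expect_gt(mean(!aud$observed[aud$variable == v]), 0.40)
  }
  # unflagged labs remain moderately sampled
  for (v in setdiff(unique(aud$variable), lat$flagged_labs)) {
    expect_lt(mean(!aud$observed[aud$variable == v]), 0.40)
  }
})

test_that("lab sampling is informative: observed timepoints are sicker than unobserved ones", {
  aud <- attr(default_cohort(), "latent")$lab_audit
  expect_gt(mean(aud$severity[aud$observed]),
            mean(aud$severity[!aud$observed]))
})

test_that("the rare phenotype cluster is far from the main population", {
  ch <- default_cohort()
  pre <- preprocess_fit(ch)
  tens <- preprocess_transform(ch, pre)
  F <- agfn:::tensor_summary_features(tens)
  F <- scale(F[, apply(F, 2, stats::sd) > 0])
  rare <- ch$statics$rare_phenotype == 1
  centroid_main <- colMeans(F[!rare, ])
  d_rare <- sqrt(rowSums((F[rare, , drop = FALSE] -
                            matrix(centroid_main, sum(rare),
                                   ncol(F), byrow = TRUE))^2))
  d_main <- sqrt(rowSums((F[!rare, ] -
                            matrix(centroid_main, sum(!rare),
                                   ncol(F), byrow = TRUE))^2))
  expect_gt(mean(d_rare), mean(d_main))
})

test_that("onset times are present exactly for positive labels and lie inside the horizon", {
  ch <- small_cohort()
  oc <- ch$outcomes
  expect_true(all((oc$label == 1L) == !is.na(oc$onset_t_hours)))
  on <- oc$onset_t_hours[!is.na(oc$onset_t_hours)]
  expect_true(all(on >= 0 & on < ch$horizon))
  expect_true(all(ch$timeseries$t_hours >= 0 &
                    ch$timeseries$t_hours <= ch$horizon))
  expect_true(all(ch$timeseries$patient_id %in% ch$statics$patient_id))
})

test_that("cohorts round-trip through the CSV interchange format", {
  ch <- simulate_cohort(sim_config(n_patients = 40, seed = 3))
  d <- withr::local_tempdir()
  write_cohort(ch, d)
  back <- read_cohort(d)
  expect_identical(ch$timeseries, back$timeseries)
  expect_identical(ch$statics, back$statics)
  expect_identical(ch$outcomes, back$outcomes)
  expect_identical(ch$horizon, back$horizon)
})

test_that("an empty cohort writes three valid files with headers", {
  empty <- structure(list(
    timeseries = data.frame(patient_id = integer(0), variable = character(0),
                            t_hours = numeric(0), value = numeric(0)),
    statics = data.frame(patient_id = integer(0), age = integer(0),
                         sex = character(0)),
    outcomes = data.frame(patient_id = integer(0), outcome = character(0),
                          label = integer(0), onset_t_hours = numeric(0)),
    horizon = 72L), class = "agfn_cohort")
  d <- withr::local_tempdir()
  write_cohort(empty, d)
  for (f in c("timeseries.csv", "statics.csv", "outcomes.csv")) {
    expect_true(file.exists(file.path(d, f)))
    expect_gt(nchar(readLines(file.path(d, f))[1]), 0)   # header row
  }
  back <- read_cohort(d)
  expect_equal(nrow(back$timeseries), 0L)
})

test_that("malformed files are rejected with the offending row named", {
  ch <- simulate_cohort(sim_config(n_patients = 10, seed = 3))
  d <- withr::local_tempdir()
  write_cohort(ch, d)
  ts <- utils::read.csv(file.path(d, "timeseries.csv"))
  ts$t_hours[5] <- -1
  utils::write.csv(ts, file.path(d, "timeseries.csv"), row.names = FALSE)
  expect_error(read_cohort(d), "row 5")

  write_cohort(ch, d)
  oc <- utils::read.csv(file.path(d, "outcomes.csv"))
  bad <- which(oc$label == 0)[1]
  oc$onset_t_hours[bad] <- 12
  utils::write.csv(oc, file.path(d, "outcomes.csv"), row.names = FALSE)
  expect_error(read_cohort(d), sprintf("row %d", bad))
})
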