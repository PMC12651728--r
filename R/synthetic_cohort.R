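#' Simulation configuration for a synthetic ICU cohort
#'
#' Builds the parameter set for [simulate_cohort()]. The defaults emulate the
#' statistical regime of a multi-center ICU cohort: sub-hourly vitals with
#' near-complete capture, sparsely ordered labs whose sampling is informative
#' (sicker patients get more labs), six correlated binary outcomes with onset
#' times, and a small rare-phenotype subpopulation living in a sparse region
#' of feature space.
#'
#' @param n_patients number of patients.
#' @param horizon_hours observation horizon in hours from admission.
#' @param n_vitals,n_labs number of vital-sign and laboratory variables.
#' @param vital_interval_h sampling interval of vitals in hours (< 1).
#' @param lab_interval_h median sampling interval of labs in hours.
#' @param vital_missing_rate completely-at-random missingness of vitals (< 0.05).
#' @param lab_missing_rate target missingness of the flagged sparse labs
#'   (> 0.40); the remaining labs use a moderate 0.20.
#' @param outcome_prevalences named or unnamed vector of six target
#'   prevalences, each in (0, 1).
#' @param rare_cluster_fraction expected fraction of rare-phenotype patients.
#' @param outcome_noise_sd standard deviation of the per-patient-per-outcome
#'   noise added to the latent severity before thresholding.
#' @param measurement_noise_sd observation noise of vitals/labs on the
#'   severity scale.
#' @param post_onset_boost severity increase (measurement-side only) after a
#'   patient's first outcome onset; gives censoring something real to remove.
#' @param ar_coef hourly first-order autoregressive coefficient of the latent
#'   severity process.
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the configuration including this seed.
#' @return an object of class `agfn_sim_config`.
#' @export
sim_config <- function(n_patients = 2000L,
                       horizon_hours = 72L,
                       n_vitals = 4L,
                       n_labs = 4L,
                       vital_interval_h = 0.5,
                       lab_interval_h = 8,
                       vital_missing_rate = 0.02,
                       lab_missing_rate = 0.45,
                       outcome_prevalences = c(
                         mortality = 0.10, sepsis = 0.15, aki = 0.22,
                         resp_failure = 0.18, cardiac_arrest = 0.06,
                         prolonged_stay = 0.20),
                       rare_cluster_fraction = 0.05,
                       outcome_noise_sd = 0.35,
                       measurement_noise_sd = 0.40,
                       post_onset_boost = 1.5,
                       ar_coef = 0.95,
                       seed = 1L) {
  if (n_patients < 1) stop("n_patients must be positive")
  if (horizon_hours <= 0) stop("horizon_hours must be positive")
  if (vital_interval_h <= 0 || vital_interval_h >= 1) {
    stop("vital_interval_h must lie in (0, 1)")
  }
  if (lab_interval_h <= 0) stop("lab_interval_h must be positive")
  props <- c(vital_missing_rate, lab_missing_rate, rare_cluster_fraction)
  if (any(props < 0 | props > 1)) stop("all proportions must lie in [0, 1]")
  if (length(outcome_prevalences) != 6L) {
    stop("outcome_prevalences must have length 6")
  }
  if (any(outcome_prevalences <= 0 | outcome_prevalences >= 1)) {
    stop("each outcome prevalence must lie in (0, 1)")
  }
  if (is.null(names(outcome_prevalences))) {
    names(outcome_prevalences) <- c("mortality", "sepsis", "aki",
                                    "resp_failure", "cardiac_arrest",
                                    "prolonged_stay")
  }
  cfg <- list(n_patients = as.integer(n_patients),
              horizon_hours = as.integer(horizon_hours),
              n_vitals = as.integer(n_vitals),
              n_labs = as.integer(n_labs),
              vital_interval_h = vital_interval_h,
              lab_interval_h = lab_interval_h,
              vital_missing_rate = vital_missing_rate,
              lab_missing_rate = lab_missing_rate,
              outcome_prevalences = outcome_prevalences,
              rare_cluster_fraction = rare_cluster_fraction,
              outcome_noise_sd = outcome_noise_sd,
              measurement_noise_sd = measurement_noise_sd,
              post_onset_boost = post_onset_boost,
              ar_coef = ar_coef,
              seed = as.integer(seed))
  class(cfg) <- "agfn_sim_config"
  cfg
}

#' Generate a synthetic ICU cohort
#'
#' Each patient carries a latent severity trajectory: an hourly AR(1) process
#' (coefficient `ar_coef`) around a patient-specific baseline with a slow
#' drift, so both acute jumps and gradual deterioration exist for the two
#' temporal encoders to detect. Vitals and labs are noisy linear loadings on
#' severity; lab observation probability increases with concurrent severity
#' (informative missingness). Each of the six outcomes thresholds a noisy
#' copy of the severity trajectory, the onset time being the first threshold
#' crossing, so labels are correlated through the shared severity but not
#' identical. After a patient's first onset the measured (not latent)
#' severity ramps up by `post_onset_boost`, giving outcome-onset censoring a
#' real signal to remove. A rare-phenotype subpopulation draws statics,
#' baselines and loadings from a shifted distribution, creating the sparse
#' region the density-adaptive graph must handle.
#'
#' @param config an `agfn_sim_config` from [sim_config()].
#' @return an object of class `agfn_cohort`: a list with data frames
#'   `timeseries` (patient_id, variable, t_hours, value), `statics` and
#'   `outcomes` (patient_id, outcome, label, onset_t_hours; onset present iff
#'   label = 1), plus the horizon. Latent generator internals are attached as
#'   the `"latent"` attribute for auditing.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "agfn_sim_config"))
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n <- cfg$n_patients
  H <- cfg$horizon_hours
  hours <- seq_len(H) - 1L

  rare <- stats::rbinom(n, 1L, cfg$rare_cluster_fraction)
  baseline <- stats::rnorm(n, 0, 0.8) + 1.5 * rare
  drift <- stats::rnorm(n, 0, 0.3)

  # latent severity: hourly AR(1) around baseline + slow per-day drift
  innov_sd <- 0.25
  stat_sd <- innov_sd / sqrt(1 - cfg$ar_coef^2)
  sev <- matrix(0, n, H)
  u <- stats::rnorm(n, 0, stat_sd)
  sev[, 1L] <- baseline + u
  for (t in 2L:H) {
    u <- cfg$ar_coef * u + stats::rnorm(n, 0, innov_sd)
    sev[, t] <- baseline + drift * (hours[t] / 24) + u
  }

  # outcomes: noisy severity copy, threshold calibrated to target prevalence,
  # onset = first crossing
  onames <- names(cfg$outcome_prevalences)
  labels <- matrix(0L, n, 6L, dimnames = list(NULL, onames))
  onsets <- matrix(NA_real_, n, 6L, dimnames = list(NULL, onames))
  thresholds <- numeric(6L)
  tol <- max(0.01, 2 / n)
  for (j in seq_len(6L)) {
    target <- cfg$outcome_prevalences[j]
    eps <- stats::rnorm(n, 0, cfg$outcome_noise_sd)
    ej <- sev + eps                       # recycled by column: eps is per patient
    peak <- apply(ej, 1L, max)
    cj <- stats::quantile(peak, 1 - target, type = 7, names = FALSE)
    ok <- FALSE
    for (attempt in seq_len(50L)) {
      lab <- as.integer(peak > cj)
      realized <- mean(lab)
      if (abs(realized - target) <= tol) { ok <- TRUE; break }
      # nudge the threshold toward the target prevalence
      cj <- cj - sign(target - realized) * max(1e-6, stats::sd(peak) / 50)
    }
    if (!ok) {
      stop(sprintf(paste0("could not calibrate outcome '%s' to prevalence ",
                          "%.3f at the configured noise level ",
                          "(50 attempts exhausted)"), onames[j], target))
    }
    labels[, j] <- lab
    thresholds[j] <- cj
    pos <- which(lab == 1L)
    if (length(pos)) {
      onsets[pos, j] <- apply(ej[pos, , drop = FALSE] > cj, 1L,
                              function(z) hours[which(z)[1L]])
    }
  }

  # measurement-side severity: deterioration ramp after the earliest onset
  first_onset <- suppressWarnings(apply(onsets, 1L, min, na.rm = TRUE))
  first_onset[!is.finite(first_onset)] <- NA_real_
  sev_obs <- sev
  boosted <- which(!is.na(first_onset))
  for (i in boosted) {
    t0 <- first_onset[i]
    late <- hours >= t0
    sev_obs[i, late] <- sev_obs[i, late] +
      cfg$post_onset_boost * (1 - exp(-(hours[late] - t0 + 1) / 6))
  }

  sev_at <- function(i, tt) sev_obs[i, pmin(H, floor(tt) + 1L)]

  # variable dictionary: cohort-level loadings, rare-phenotype multiplier
  vit_names <- paste0("vital_", seq_len(cfg$n_vitals))
  lab_names <- paste0("lab_", seq_len(cfg$n_labs))
  flagged <- lab_names[seq_len(ceiling(cfg$n_labs / 2))]
  all_vars <- c(vit_names, lab_names)
  load_base <- stats::runif(length(all_vars), 0.5, 1.2) *
    sample(c(-1, 1), length(all_vars), replace = TRUE)
  names(load_base) <- all_vars
  intercepts <- stats::rnorm(length(all_vars), 0, 1)
  names(intercepts) <- all_vars

  # calibrate informative lab-observation intercepts so realized missingness
  # matches the per-lab target on the cohort's severity distribution
  sev_z <- (sev_obs - mean(sev_obs)) / stats::sd(sev_obs)
  obs_slope <- 1.0
  calib_a <- function(target_obs) {
    f <- function(a) mean(stats::plogis(a + obs_slope * sev_z)) - target_obs
    stats::uniroot(f, c(-15, 15))$root
  }
  lab_targets <- ifelse(lab_names %in% flagged, cfg$lab_missing_rate, 0.20)
  names(lab_targets) <- lab_names
  lab_a <- vapply(lab_targets, function(m) calib_a(1 - m), numeric(1))

  # vitals: common sub-hourly grid, vectorized over patients per variable
  vit_times <- seq(0, H - 1e-9, by = cfg$vital_interval_h)
  nt <- length(vit_times)
  mult <- 1 + 0.4 * rare
  sev_grid <- sev_obs[, pmin(H, floor(vit_times) + 1L), drop = FALSE]
  vit_frames <- lapply(vit_names, function(v) {
    vals <- intercepts[v] + (mult * load_base[v]) * sev_grid +
      matrix(stats::rnorm(n * nt, 0, cfg$measurement_noise_sd), n, nt)
    keep <- matrix(stats::runif(n * nt) > cfg$vital_missing_rate, n, nt)
    idx <- which(keep, arr.ind = TRUE)
    data.frame(patient_id = idx[, 1L], variable = v,
               t_hours = round(vit_times[idx[, 2L]], 2),
               value = round(vals[idx], 4))
  })

  # labs: jittered per-patient schedules, observation prob rises with severity
  acc <- list(pid = vector("list", n * length(lab_names)),
              var = vector("list", n * length(lab_names)),
              t = vector("list", n * length(lab_names)),
              val = vector("list", n * length(lab_names)))
  aud_sev <- vector("list", n * length(lab_names))
  aud_obs <- vector("list", n * length(lab_names))
  aud_var <- vector("list", n * length(lab_names))
  slot <- 0L
  for (i in seq_len(n)) {
    for (li in seq_along(lab_names)) {
      v <- lab_names[li]
      slot <- slot + 1L
      tt <- stats::runif(1, 0, 2)
      times <- tt + c(0, cumsum(cfg$lab_interval_h *
                                  stats::runif(ceiling(H / (0.7 * cfg$lab_interval_h)),
                                               0.7, 1.3)))
      times <- times[times < H]
      sl <- sev_at(i, times)
      slz <- (sl - mean(sev_obs)) / stats::sd(sev_obs)
      p_obs <- stats::plogis(lab_a[v] + obs_slope * slz)
      seen <- stats::runif(length(times)) < p_obs
      aud_sev[[slot]] <- sl
      aud_obs[[slot]] <- seen
      aud_var[[slot]] <- rep.int(v, length(times))
      if (any(seen)) {
        acc$pid[[slot]] <- rep.int(i, sum(seen))
        acc$var[[slot]] <- rep.int(v, sum(seen))
        acc$t[[slot]] <- round(times[seen], 2)
        acc$val[[slot]] <- round(intercepts[v] + mult[i] * load_base[v] * sl[seen] +
                                   stats::rnorm(sum(seen), 0,
                                                1.2 * cfg$measurement_noise_sd), 4)
      }
    }
  }
  lab_frame <- data.frame(patient_id = unlist(acc$pid),
                          variable = unlist(acc$var),
                          t_hours = unlist(acc$t),
                          value = unlist(acc$val))
  timeseries <- rbind(do.call(rbind, vit_frames), lab_frame)
  ord <- order(timeseries$patient_id, timeseries$variable, timeseries$t_hours)
  timeseries <- timeseries[ord, ]
  rownames(timeseries) <- NULL
  lab_audit <- data.frame(variable = unlist(aud_var),
                          severity = unlist(aud_sev),
                          observed = unlist(aud_obs))

  # statics: demographics and comorbidities correlated with baseline severity
  bz <- (baseline - mean(baseline)) / stats::sd(baseline)
  age <- as.integer(round(pmin(95, pmax(18, 63.4 + 14.9 *
                                          (0.5 * bz + 0.87 * stats::rnorm(n)) +
                                          8 * rare))))
  sex <- ifelse(stats::runif(n) < 0.547, "male", "female")
  com_p <- function(shift) stats::plogis(-1.2 + 0.5 * bz + shift * rare)
  statics <- data.frame(
    patient_id = seq_len(n),
    age = age,
    sex = sex,
    diabetes = stats::rbinom(n, 1L, com_p(0.8)),
    ckd = stats::rbinom(n, 1L, com_p(1.5)),
    copd = stats::rbinom(n, 1L, com_p(0.5)),
    cvd = stats::rbinom(n, 1L, com_p(1.0)),
    rare_phenotype = rare)

  outcomes <- data.frame(
    patient_id = rep(seq_len(n), times = 6L),
    outcome = rep(onames, each = n),
    label = as.integer(labels),
    onset_t_hours = as.numeric(onsets))

  cohort <- list(timeseries = timeseries, statics = statics,
                 outcomes = outcomes, horizon = H)
  class(cohort) <- "agfn_cohort"
  attr(cohort, "latent") <- list(severity = sev, severity_measured = sev_obs,
                                 baseline = baseline, rare = rare,
                                 thresholds = thresholds,
                                 first_onset = first_onset,
                                 flagged_labs = flagged,
                                 lab_audit = lab_audit,
                                 loadings = load_base, config = cfg)
  cohort
}

#' @export
print.agfn_cohort <- function(x, ...) {
  prev <- tapply(x$outcomes$label, x$outcomes$outcome, mean)
  cat(sprintf("Synthetic ICU cohort: %d patients, %d measurement rows, %d h horizon\n",
              nrow(x$statics), nrow(x$timeseries), x$horizon))
  cat("Outcome prevalences:\n")
  print(round(prev, 3))
  invisible(x)
}

#' Write / read a cohort as delimited text files
#'
#' `write_cohort()` stores the three tables as UTF-8 CSV files
#' (`timeseries.csv`, `statics.csv`, `outcomes.csv`) with mandatory header
#' rows and `.` decimal separator; `read_cohort()` restores them, validating
#' ids and timestamps and reporting the offending row on malformed input.
#'
#' @param cohort an `agfn_cohort`.
#' @param path directory to write to / read from (created if missing).
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   an `agfn_cohort` (without latent generator internals).
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "agfn_cohort"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  utils::write.csv(cohort$timeseries, file.path(path, "timeseries.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$statics, file.path(path, "statics.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$outcomes, file.path(path, "outcomes.csv"),
                   row.names = FALSE)
  writeLines(as.character(cohort$horizon), file.path(path, "horizon.txt"))
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  ts <- utils::read.csv(file.path(path, "timeseries.csv"),
                        stringsAsFactors = FALSE)
  st <- utils::read.csv(file.path(path, "statics.csv"),
                        stringsAsFactors = FALSE)
  oc <- utils::read.csv(file.path(path, "outcomes.csv"),
                        stringsAsFactors = FALSE)
  if (nrow(ts)) {
    ts$t_hours <- as.numeric(ts$t_hours)
    ts$value <- as.numeric(ts$value)
  }
  if (nrow(oc)) {
    oc$label <- as.integer(oc$label)
    oc$onset_t_hours <- as.numeric(oc$onset_t_hours)
  }
  horizon_file <- file.path(path, "horizon.txt")
  horizon <- if (file.exists(horizon_file)) {
    as.integer(readLines(horizon_file)[1L])
  } else if (nrow(ts)) ceiling(max(ts$t_hours)) else 0L

  if (nrow(ts)) {
    bad <- which(is.na(ts$patient_id))
    if (length(bad)) stop(sprintf("timeseries.csv row %d: missing patient_id",
                                  bad[1L]))
    bad <- which(!is.finite(ts$t_hours) | ts$t_hours < 0)
    if (length(bad)) stop(sprintf(
      "timeseries.csv row %d: invalid t_hours (%s)", bad[1L],
      format(ts$t_hours[bad[1L]])))
    orphan <- setdiff(unique(ts$patient_id), st$patient_id)
    if (length(orphan)) stop(sprintf(
      "timeseries patient_id %s absent from statics", orphan[1L]))
  }
  if (nrow(oc)) {
    mism <- which((oc$label == 1L) != !is.na(oc$onset_t_hours))
    if (length(mism)) stop(sprintf(
      "outcomes.csv row %d: onset_t_hours must be present iff label = 1",
      mism[1L]))
  }
  cohort <- list(timeseries = ts, statics = st, outcomes = oc,
                 horizon = horizon)
  class(cohort) <- "agfn_cohort"
  cohort
}
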