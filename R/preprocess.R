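# Fold-safe preprocessing: winsorization, decay-aware imputation, derived
# temporal features, robust scaling and outcome-onset censoring. Every
# data-dependent statistic is fitted on training patients only and frozen.

# Quantile convention used throughout: linear interpolation between order
# statistics (stats::quantile type 7). Winsor/IQR tests depend on it.
agfn_quantile <- function(x, p) {
  stats::quantile(x, p, type = 7, names = FALSE, na.rm = TRUE)
}

#' Winsorize values at fitted extreme-percentile bounds
#'
#' Clips each value to the training-data 0.5th/99.5th percentile band:
#' values inside the band pass through unchanged.
#'
#' @param values numeric vector.
#' @param bounds length-2 numeric `c(lower, upper)` fitted with
#'   [fit_winsor_bounds()] on training data only.
#' @return clipped vector of the same length.
#' @export
winsorize <- function(values, bounds) {
  if (is.null(bounds) || length(bounds) != 2L || any(!is.finite(bounds))) {
    stop("winsorize requires fitted finite bounds c(lower, upper)")
  }
  bad <- which(!is.finite(values))
  if (length(bad)) {
    stop(sprintf("non-finite input value at index %d", bad[1L]))
  }
  pmin(pmax(values, bounds[1L]), bounds[2L])
}

#' @rdname winsorize
#' @param x training values to fit the percentile bounds on.
#' @param probs the two clipping percentiles.
#' @export
fit_winsor_bounds <- function(x, probs = c(0.005, 0.995)) {
  c(agfn_quantile(x, probs[1L]), agfn_quantile(x, probs[2L]))
}

#' Decay-aware exponential-smoothing imputation
#'
#' Observed entries pass through; missing entries blend the previous imputed
#' value with the patient baseline:
#' `x~_t = m_t * x_t + (1 - m_t) * (alpha * x~_{t-1} + (1 - alpha) * xbar)`,
#' applied left to right. The (undefined) predecessor of the first element is
#' the patient baseline `xbar`, so a series that starts missing decays from
#' baseline. Consecutive gaps therefore relax geometrically toward `xbar`.
#'
#' @param values numeric vector; entries at `mask == 0` are ignored.
#' @param mask 0/1 vector, 1 where observed.
#' @param alpha decay coefficient in `[0, 1]`.
#' @param xbar finite patient-specific baseline mean.
#' @return imputed vector of the same length.
#' @export
impute_decay <- function(values, mask, alpha, xbar) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (!is.finite(xbar)) stop("xbar must be finite")
  n <- length(values)
  if (n == 0L) return(numeric(0))
  out <- numeric(n)
  prev <- xbar
  for (t in seq_len(n)) {
    out[t] <- if (mask[t] == 1) values[t] else alpha * prev + (1 - alpha) * xbar
    prev <- out[t]
  }
  out
}

#' Long-range slope of an observed series
#'
#' `s = (x_last - x_first) / (t_last - t_first)` per hour over the observed
#' pre-censoring window. With fewer than two distinct timepoints the slope is
#' undefined; the sentinel 0 is returned with `defined = FALSE` so downstream
#' consumers see "no trend information" rather than an arbitrary magnitude.
#'
#' @param t observation times (hours), `x` values at those times.
#' @param x numeric values.
#' @return list with `slope` and logical `defined`.
#' @export
derive_slope <- function(t, x) {
  if (length(t) < 2L || t[length(t)] == t[1L]) {
    return(list(slope = 0, defined = FALSE))
  }
  list(slope = (x[length(x)] - x[1L]) / (t[length(t)] - t[1L]),
       defined = TRUE)
}

#' Stepwise differences of consecutive values
#'
#' `delta_t = x_t - x_{t-1}` for `t >= 2`; output length is input length - 1.
#'
#' @param series numeric vector of length >= 1.
#' @return numeric vector of consecutive differences.
#' @export
derive_delta <- function(series) {
  if (length(series) < 2L) return(numeric(0))
  diff(series)
}

#' Robust z-score scaling by training median and IQR
#'
#' `z = (x - median) / IQR` with the quartiles fitted on the training
#' partition. A degenerate `IQR = 0` (near-constant variable) maps every
#' value to 0 with a warning rather than dividing by zero.
#'
#' @param values numeric vector.
#' @param center fitted median, `scale` fitted interquartile range.
#' @param scale fitted IQR (>= 0).
#' @return scaled vector.
#' @export
robust_scale <- function(values, center, scale) {
  if (is.null(center) || is.null(scale) || !is.finite(center) ||
        !is.finite(scale)) {
    stop("robust_scale requires fitted finite center and scale")
  }
  if (scale == 0) {
    warning("IQR is zero; scaled values set to 0")
    return(rep(0, length(values)))
  }
  (values - center) / scale
}

#' Mask all measurements at or after an outcome onset
#'
#' Sets `M = 0` for every time bin whose interval reaches `onset_t`, so no
#' feature recorded at or after onset can contribute to imputation, patient
#' baselines, slopes or deltas. Statics are retained. A missing onset
#' (label 0) leaves the tensor unchanged.
#'
#' @param tensor a single-patient tensor: list with matrices `X` (T x D) and
#'   `M` (T x D) and vector `tbins` of bin left edges.
#' @param onset_t onset time in hours, or `NA`/`NULL` for no censoring.
#' @return the tensor with post-onset bins masked.
#' @export
censor_at_onset <- function(tensor, onset_t) {
  if (is.null(onset_t) || is.na(onset_t)) return(tensor)
  if (onset_t < 0) stop("onset_t must be >= 0")
  cut <- tensor$tbins + 1 > onset_t        # bin [b, b+1) must end before onset
  tensor$M[cut, ] <- 0
  tensor$censored_from <- onset_t
  tensor
}

#' Fit a frozen preprocessor on training patients
#'
#' Computes, per variable observed in the training patients: winsor bounds at
#' the 0.5th/99.5th percentiles, then the median and IQR of the winsorized
#' values. Statistics use only pre-censoring observations (censoring at each
#' patient's earliest outcome onset, when `censor = TRUE`). Also fits the
#' static-feature scaling and categorical level maps. The returned object is
#' frozen: `preprocess_transform()` never refits.
#'
#' @param cohort an `agfn_cohort`.
#' @param patient_ids training patient ids the fit is restricted to.
#' @param alpha imputation decay coefficient in `[0, 1]`.
#' @param censor censor training observations at earliest outcome onset
#'   before computing statistics.
#' @param fold_id identifier recorded on the fitted object.
#' @return an object of class `agfn_preprocessor`.
#' @export
preprocess_fit <- function(cohort, patient_ids = cohort$statics$patient_id,
                           alpha = 0.7, censor = TRUE, fold_id = NA) {
  stopifnot(inherits(cohort, "agfn_cohort"))
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  ts <- cohort$timeseries[cohort$timeseries$patient_id %in% patient_ids, ]
  if (censor && nrow(cohort$outcomes)) {
    cut <- earliest_onsets(cohort)
    lim <- cut[match(ts$patient_id, as.integer(names(cut)))]
    keep <- is.na(lim) | ts$t_hours < lim
    ts <- ts[keep, ]
  }
  vars <- sort(unique(ts$variable))
  if (!length(vars)) stop("no training observations to fit on")
  win <- matrix(NA_real_, length(vars), 2L,
                dimnames = list(vars, c("lower", "upper")))
  center <- scale <- stats::setNames(numeric(length(vars)), vars)
  for (v in vars) {
    x <- ts$value[ts$variable == v]
    b <- fit_winsor_bounds(x)
    win[v, ] <- b
    xw <- winsorize(x, b)
    center[v] <- agfn_quantile(xw, 0.5)
    scale[v] <- agfn_quantile(xw, 0.75) - agfn_quantile(xw, 0.25)
  }
  st <- cohort$statics[cohort$statics$patient_id %in% patient_ids, ]
  age_center <- agfn_quantile(st$age, 0.5)
  age_scale <- max(agfn_quantile(st$age, 0.75) - agfn_quantile(st$age, 0.25), 1)
  fit <- list(variables = vars, winsor = win, center = center, scale = scale,
              alpha = alpha, age_center = age_center, age_scale = age_scale,
              sex_levels = sort(unique(as.character(st$sex))),
              static_cols = setdiff(names(st), c("patient_id", "age", "sex")),
              horizon = cohort$horizon, fold_id = fold_id)
  class(fit) <- "agfn_preprocessor"
  fit
}

# earliest onset per patient id (named numeric, NA when no outcome)
earliest_onsets <- function(cohort) {
  oc <- cohort$outcomes
  pts <- cohort$statics$patient_id
  out <- stats::setNames(rep(NA_real_, length(pts)), pts)
  if (!nrow(oc)) return(out)
  on <- oc[!is.na(oc$onset_t_hours), ]
  if (nrow(on)) {
    m <- tapply(on$onset_t_hours, on$patient_id, min)
    out[names(m)] <- as.numeric(m)
  }
  out
}

#' Transform a cohort into aligned patient tensors with frozen statistics
#'
#' Applies the fitted preprocessor: hourly binning over `[0, horizon)` with
#' within-bin duplicates averaged, winsorization, outcome-onset censoring (at
#' each patient's earliest onset), decay-aware imputation from the
#' patient-specific baseline (median of that patient's observed pre-censoring
#' values; training median when none exist), robust scaling, and derived
#' per-variable features (long-range slope with defined-flag, last observed
#' value, observed mean, stepwise-difference variability). Variables absent
#' from the training fit are dropped with a warning. The fitted object is
#' never modified.
#'
#' @param cohort an `agfn_cohort`.
#' @param fitted an `agfn_preprocessor`.
#' @param patient_ids patients to transform (default: all in `cohort`).
#' @param censor apply outcome-onset censoring (disable only for leakage
#'   control experiments).
#' @return an object of class `agfn_tensor`: arrays `X` and `M`
#'   (patients x bins x variables) of scaled imputed values and observation
#'   masks, statics matrix `S`, derived feature matrices, and bookkeeping.
#' @export
preprocess_transform <- function(cohort, fitted,
                                 patient_ids = cohort$statics$patient_id,
                                 censor = TRUE) {
  stopifnot(inherits(cohort, "agfn_cohort"),
            inherits(fitted, "agfn_preprocessor"))
  pts <- patient_ids
  n <- length(pts)
  Tn <- fitted$horizon
  vars <- fitted$variables
  D <- length(vars)

  ts <- cohort$timeseries[cohort$timeseries$patient_id %in% pts, ]
  unknown <- setdiff(unique(ts$variable), vars)
  if (length(unknown)) {
    warning(sprintf("dropping %d variable(s) absent from the training fit: %s",
                    length(unknown), paste(unknown, collapse = ", ")))
    ts <- ts[!(ts$variable %in% unknown), ]
  }
  pid_idx <- match(ts$patient_id, pts)
  vid_idx <- match(ts$variable, vars)
  bin <- pmin(Tn - 1L, floor(ts$t_hours))

  # winsorize raw values with frozen per-variable bounds
  val <- ts$value
  val <- pmin(pmax(val, fitted$winsor[vid_idx, "lower"]),
              fitted$winsor[vid_idx, "upper"])

  onset <- if (censor) earliest_onsets(cohort)[as.character(pts)] else
    rep(NA_real_, n)
  # drop measurements at or after the patient's earliest onset
  lim <- onset[pid_idx]
  keep <- is.na(lim) | ts$t_hours < lim
  pid_idx <- pid_idx[keep]; vid_idx <- vid_idx[keep]
  bin <- bin[keep]; val <- val[keep]
  tvals <- ts$t_hours[keep]

  # within-bin averages
  key <- (as.numeric(pid_idx) - 1) * (D * Tn) +
    (as.numeric(vid_idx) - 1) * Tn + bin + 1
  sums <- rowsum(val, key)
  cnts <- rowsum(rep(1, length(key)), key)
  kk <- as.numeric(rownames(sums))
  Xraw <- array(NA_real_, c(n, Tn, D))
  M <- array(0, c(n, Tn, D))
  p_of <- ((kk - 1) %/% (D * Tn)) + 1
  v_of <- (((kk - 1) %% (D * Tn)) %/% Tn) + 1
  b_of <- ((kk - 1) %% Tn) + 1
  Xraw[cbind(p_of, b_of, v_of)] <- sums / cnts
  M[cbind(p_of, b_of, v_of)] <- 1
  # censored bins must not count as observed even if a bin straddles onset
  for (i in which(!is.na(onset))) {
    cut <- which(seq_len(Tn) - 1 + 1 > onset[i])   # bin end > onset
    if (length(cut)) M[i, cut, ] <- 0
  }
  Xraw[M == 0] <- NA_real_

  # patient baselines, imputation, scaling
  slope <- matrix(0, n, D); slope_ok <- matrix(0, n, D)
  vmean <- matrix(0, n, D); vlast <- matrix(0, n, D); dsd <- matrix(0, n, D)
  xbar <- matrix(rep(fitted$center, each = n), n, D)   # fallback baseline
  for (d in seq_len(D)) {
    Xd <- Xraw[, , d]
    Md <- M[, , d]
    obs_mean <- rowSums(Xd * Md, na.rm = TRUE) / pmax(rowSums(Md), 1)
    has <- rowSums(Md) > 0
    xbar[has, d] <- obs_mean[has]
    for (i in seq_len(n)) {
      ob <- which(Md[i, ] == 1)
      if (length(ob)) {
        x <- Xd[i, ob]
        sl <- derive_slope(ob - 1, x)
        slope[i, d] <- sl$slope
        slope_ok[i, d] <- as.numeric(sl$defined)
        vlast[i, d] <- x[length(x)]
        vmean[i, d] <- mean(x)
        if (length(x) > 2) dsd[i, d] <- stats::sd(derive_delta(x))
      }
    }
  }
  # vectorized left-to-right decay imputation across patients and variables
  Ximp <- array(0, c(n, Tn, D))
  prev <- xbar
  a <- fitted$alpha
  for (t in seq_len(Tn)) {
    mt <- M[, t, ]
    xt <- Xraw[, t, ]
    xt[is.na(xt)] <- 0
    cur <- mt * xt + (1 - mt) * (a * prev + (1 - a) * xbar)
    Ximp[, t, ] <- cur
    prev <- cur
  }
  # robust scaling with frozen stats; zero-IQR variables collapse to 0
  X <- Ximp
  sc <- fitted$scale
  zero_iqr <- sc == 0
  if (any(zero_iqr)) warning("IQR is zero for some variables; scaled to 0")
  for (d in seq_len(D)) {
    if (zero_iqr[d]) {
      X[, , d] <- 0
      slope[, d] <- 0; vmean[, d] <- 0; vlast[, d] <- 0; dsd[, d] <- 0
    } else {
      X[, , d] <- (Ximp[, , d] - fitted$center[d]) / sc[d]
      slope[, d] <- slope[, d] / sc[d]
      vmean[, d] <- (vmean[, d] - fitted$center[d]) / sc[d]
      vlast[, d] <- (vlast[, d] - fitted$center[d]) / sc[d]
      dsd[, d] <- dsd[, d] / sc[d]
    }
  }

  # statics: scaled age, one-hot sex, binary flags
  st <- cohort$statics[match(pts, cohort$statics$patient_id), ]
  sex_cols <- matrix(0, n, max(length(fitted$sex_levels) - 1L, 0L))
  if (length(fitted$sex_levels) > 1L) {
    for (k in seq_along(fitted$sex_levels)[-1L]) {
      sex_cols[, k - 1L] <- as.numeric(st$sex == fitted$sex_levels[k])
    }
    colnames(sex_cols) <- paste0("sex_", fitted$sex_levels[-1L])
  }
  flags <- as.matrix(st[, fitted$static_cols, drop = FALSE])
  S <- cbind(age = (st$age - fitted$age_center) / fitted$age_scale,
             sex_cols, flags)
  rownames(S) <- NULL

  out <- list(X = X, M = M, S = S,
              slope = slope, slope_defined = slope_ok, var_mean = vmean,
              var_last = vlast, delta_sd = dsd,
              patient_ids = pts, variables = vars, tbins = seq_len(Tn) - 1,
              censor_times = onset, censored = censor)
  class(out) <- "agfn_tensor"
  out
}

#' @export
print.agfn_tensor <- function(x, ...) {
  cat(sprintf("agfn_tensor: %d patients x %d bins x %d variables (%s)\n",
              dim(x$X)[1L], dim(x$X)[2L], dim(x$X)[3L],
              if (x$censored) "onset-censored" else "uncensored"))
  invisible(x)
}

#' Patient-level summary features from a transformed tensor
#'
#' Statics plus per-variable pre-censoring summaries (observed mean,
#' long-range slope with defined-flag, last observed value, short-term
#' delta variability). These are the inputs of the contrastive encoder and
#' of the logistic reference model.
#'
#' @param tensor an `agfn_tensor` from [preprocess_transform()].
#' @return numeric matrix, one row per patient.
#' @export
tensor_summary_features <- function(tensor) {
  F <- cbind(tensor$S, tensor$var_mean, tensor$slope, tensor$slope_defined,
             tensor$var_last, tensor$delta_sd)
  colnames(F) <- c(colnames(tensor$S),
                   paste0(tensor$variables, "_mean"),
                   paste0(tensor$variables, "_slope"),
                   paste0(tensor$variables, "_slope_def"),
                   paste0(tensor$variables, "_last"),
                   paste0(tensor$variables, "_delta_sd"))
  F
}

#' Outcome label matrix aligned with a patient order
#'
#' @param cohort an `agfn_cohort`.
#' @param patient_ids patient ids defining the row order.
#' @return integer 0/1 matrix (patients x outcomes) with outcome names.
#' @export
outcome_labels <- function(cohort, patient_ids) {
  oc <- cohort$outcomes
  onames <- unique(oc$outcome)
  L <- matrix(0L, length(patient_ids), length(onames),
              dimnames = list(NULL, onames))
  for (j in seq_along(onames)) {
    sub <- oc[oc$outcome == onames[j], ]
    L[, j] <- sub$label[match(patient_ids, sub$patient_id)]
  }
  L
}
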