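# AUC-by-threshold curve for one feature's fraction vector. Thresholds whose
# binary marker has an empty class are NA. Masks are identical between
# consecutive distinct fraction values, so each distinct marker is scored once.
sweep_curve <- function(frac, ps, denoms, horizon, thresholds) {
  key <- floor(frac * 100 + 1e-9)   # marker at T  <=>  key >= T
  uk <- sort(unique(key))
  auc_by_cut <- rep(NA_real_, length(uk))
  seen <- logical(length(uk))
  out <- rep(NA_real_, length(thresholds))
  for (j in seq_along(thresholds)) {
    i <- findInterval(thresholds[j] - 0.5, uk) + 1L   # first uk >= T
    if (i > length(uk)) next                          # empty positive class
    if (!seen[i]) {
      auc_by_cut[i] <- td_auc_binary(key >= uk[i], ps, horizon, denoms)
      seen[i] <- TRUE
    }
    out[j] <- auc_by_cut[i]
  }
  out
}

sweep_summarise <- function(auc, thresholds, frac) {
  defined <- which(!is.na(auc))
  if (length(defined) == 0) {
    return(list(opt_threshold = NA_real_, max_auc = NA_real_, auc_sd = NA_real_,
                prevalence = NA_real_, n_defined = 0L))
  }
  best <- defined[which.max(auc[defined])]   # which.max: first max = smallest threshold
  opt <- thresholds[best]
  list(opt_threshold = opt,
       max_auc = auc[best],
       auc_sd = if (length(defined) > 1) sd(auc[defined]) else 0,
       prevalence = mean(frac * 100 >= opt - 1e-9),
       n_defined = length(defined))
}

#' AUC sweep across size thresholds for one feature
#'
#' For each size threshold T in 1..99 percent (step configurable), forms
#' the binary marker "fraction x 100 >= T" and scores it with the 5-year
#' time-dependent ROC AUC ([td_auc()]). Thresholds at which either marker
#' class is empty are undefined and excluded from the maximum and the
#' standard deviation; argmax ties break toward the smallest threshold.
#'
#' @param frac Per-sample percent-arm-altered fractions (one feature).
#' @param time,event Survival endpoint aligned with `frac`.
#' @param horizon ROC horizon in years (default 5).
#' @param step Threshold step in percent (default 1).
#' @param feature Optional feature label carried into the result.
#' @return A list with class `cnasd_sweep_feature`: `feature`, `thresholds`,
#'   `auc` (vector with NA where undefined), `opt_threshold`, `max_auc`,
#'   `auc_sd` (SD of AUC over defined thresholds), `prevalence` (at the
#'   optimum), `n_defined`, `all_undefined`.
#' @export
sweep_feature <- function(frac, time, event, horizon = 5, step = 1, feature = NA_character_) {
  stopifnot(length(frac) == length(time))
  thresholds <- seq(1, 99, by = step)
  ps <- surv_presort(time, event)
  n_cases <- sum(event == 1 & time <= horizon)
  n_controls <- sum(time > horizon)
  if (n_cases == 0 || n_controls == 0) {
    auc <- rep(NA_real_, length(thresholds))
  } else {
    denoms <- td_denoms(ps, horizon)
    auc <- sweep_curve(frac, ps, denoms, horizon, thresholds)
  }
  s <- sweep_summarise(auc, thresholds, frac)
  structure(c(list(feature = feature, thresholds = thresholds, auc = auc,
                   all_undefined = s$n_defined == 0L), s),
            class = "cnasd_sweep_feature")
}

#' @export
print.cnasd_sweep_feature <- function(x, ...) {
  cat(sprintf("Threshold sweep%s: ", ifelse(is.na(x$feature), "", paste0(" for ", x$feature))))
  if (x$all_undefined) cat("all thresholds undefined\n")
  else cat(sprintf("max AUC %.3f at %d%% (SD %.4f, prevalence %.3f, %d defined)\n",
                   x$max_auc, x$opt_threshold, x$auc_sd, x$prevalence, x$n_defined))
  invisible(x)
}

#' AUC sweep across size thresholds for all features
#'
#' Runs [sweep_feature()] for every (arm, direction) feature in a fraction
#' matrix against one survival endpoint. The sweep is deterministic: fixed
#' input yields bit-identical output.
#'
#' @param fractions A `cnasd_fractions` tibble (or any tibble with a
#'   `sample` column and one numeric fraction column per feature).
#' @param time,event Survival endpoint aligned with the fraction rows.
#' @param horizon ROC horizon in years.
#' @param step Threshold step in percent.
#' @param endpoint Optional endpoint label stored in the result.
#' @return A tibble with class `cnasd_sweep`: one row per feature with
#'   `feature`, `endpoint`, `opt_threshold`, `max_auc`, `auc_sd`,
#'   `prevalence`, `n_defined` and a list-column `auc` holding the full
#'   curve. Attribute `thresholds` stores the threshold grid.
#' @export
cna_sweep <- function(fractions, time, event, horizon = 5, step = 1,
                      endpoint = NA_character_) {
  m <- fraction_matrix_of(fractions)
  stopifnot(nrow(m) == length(time))
  thresholds <- seq(1, 99, by = step)
  ps <- surv_presort(time, event)
  n_cases <- sum(event == 1 & time <= horizon)
  n_controls <- sum(time > horizon)
  have_classes <- n_cases > 0 && n_controls > 0
  denoms <- if (have_classes) td_denoms(ps, horizon) else NULL
  rows <- purrr::map(colnames(m), function(f) {
    frac <- m[, f]
    auc <- if (have_classes) sweep_curve(frac, ps, denoms, horizon, thresholds)
           else rep(NA_real_, length(thresholds))
    s <- sweep_summarise(auc, thresholds, frac)
    tibble(feature = f, endpoint = endpoint, opt_threshold = s$opt_threshold,
           max_auc = s$max_auc, auc_sd = s$auc_sd, prevalence = s$prevalence,
           n_defined = s$n_defined, auc = list(auc))
  })
  out <- bind_rows(rows)
  class(out) <- c("cnasd_sweep", class(out))
  attr(out, "thresholds") <- thresholds
  attr(out, "horizon") <- horizon
  out
}

#' Size-dependence criteria
#'
#' The three criteria a feature must meet, at one endpoint, to be called a
#' size-dependent CNA: maximum AUC at any threshold of at least `min_auc`
#' (default 0.60), AUC standard deviation across thresholds of at least
#' `min_sd` (default 0.01), and prevalence at the optimal threshold of at
#' least `min_prevalence` (default 2.5%). All comparisons are inclusive.
#'
#' @param min_auc,min_sd,min_prevalence Criterion floors.
#' @param step Threshold step the sweeps were run at.
#' @return A named list with class `cnasd_criteria`.
#' @export
sd_criteria <- function(min_auc = 0.60, min_sd = 0.01, min_prevalence = 0.025, step = 1) {
  stopifnot(min_auc > 0, min_sd > 0, min_prevalence > 0, min_prevalence < 1)
  structure(list(min_auc = min_auc, min_sd = min_sd,
                 min_prevalence = min_prevalence, step = step),
            class = "cnasd_criteria")
}

#' Flag size-dependent features from sweep results
#'
#' A feature is size-dependent if, for at least one endpoint, its maximum
#' AUC, AUC standard deviation and prevalence at the optimal threshold all
#' meet the [sd_criteria()] floors (boundary values pass). Sweeps for
#' multiple endpoints are OR-combined per feature.
#'
#' @param sweeps One `cnasd_sweep` tibble or several row-bound ones (the
#'   `endpoint` column distinguishes them).
#' @param criteria An [sd_criteria()] object.
#' @return A tibble, one row per (feature, endpoint), with the individual
#'   criterion flags `meets_auc`, `meets_sd`, `meets_prevalence`, the
#'   per-endpoint conjunction `meets_all`, and the feature-level
#'   `size_dependent` flag (any endpoint passing).
#' @export
size_dependent_features <- function(sweeps, criteria = sd_criteria()) {
  eps <- 1e-12
  out <- sweeps %>%
    mutate(meets_auc = !is.na(.data$max_auc) & .data$max_auc >= criteria$min_auc - eps,
           meets_sd = !is.na(.data$auc_sd) & .data$auc_sd >= criteria$min_sd - eps,
           meets_prevalence = !is.na(.data$prevalence) &
             .data$prevalence >= criteria$min_prevalence - eps,
           meets_all = .data$meets_auc & .data$meets_sd & .data$meets_prevalence) %>%
    group_by(.data$feature) %>%
    mutate(size_dependent = any(.data$meets_all)) %>%
    ungroup() %>%
    select("feature", "endpoint", "opt_threshold", "max_auc", "auc_sd", "prevalence",
           "meets_auc", "meets_sd", "meets_prevalence", "meets_all", "size_dependent")
  attr(out, "criteria") <- criteria
  out
}

#' Per-feature optimal thresholds from sweep results
#'
#' @param sweeps A `cnasd_sweep` tibble (single endpoint).
#' @param default Threshold substituted where a sweep was all-undefined.
#' @return Named numeric vector of thresholds, one per feature.
#' @export
optimal_thresholds <- function(sweeps, default = 50) {
  thr <- ifelse(is.na(sweeps$opt_threshold), default, sweeps$opt_threshold)
  setNames(thr, sweeps$feature)
}

#' Null distribution of the AUC standard deviation
#'
#' Estimates the null distribution of the per-feature AUC standard
#' deviation across size thresholds by scrambling the sample-to-fraction
#' pairing within each feature -- permutation without replacement or
#' bootstrap resampling with replacement -- so the chromosome-arm-specific
#' background distribution of fractions is maintained while any
#' relationship with outcome is destroyed. The sweep is re-run per
#' replicate and feature; all replicate-by-feature SDs are pooled.
#'
#' @param fractions A `cnasd_fractions` tibble.
#' @param time,event Survival endpoint.
#' @param mode `"permute"` or `"bootstrap"`.
#' @param reps Number of replicates (the reference construction uses 500).
#' @param seed Seed making the scrambling reproducible.
#' @param horizon,step Sweep parameters.
#' @return Tibble with `rep`, `feature`, `auc_sd` (NA where a scrambled
#'   sweep was all-undefined).
#' @export
null_sd_distribution <- function(fractions, time, event, mode = c("permute", "bootstrap"),
                                 reps = 500, seed = NULL, horizon = 5, step = 1) {
  mode <- match.arg(mode)
  if (reps < 1) abort("`reps` must be >= 1.")
  m <- fraction_matrix_of(fractions)
  n <- nrow(m)
  thresholds <- seq(1, 99, by = step)
  ps <- surv_presort(time, event)
  if (sum(event == 1 & time <= horizon) == 0 || sum(time > horizon) == 0) {
    abort("Endpoint has no cases or no controls at the horizon.")
  }
  denoms <- td_denoms(ps, horizon)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
    set.seed(seed)
  }
  res <- vector("list", reps)
  for (r in seq_len(reps)) {
    sds <- vapply(seq_len(ncol(m)), function(j) {
      idx <- if (mode == "permute") sample.int(n) else sample.int(n, replace = TRUE)
      auc <- sweep_curve(m[idx, j], ps, denoms, horizon, thresholds)
      def <- !is.na(auc)
      if (sum(def) > 1) sd(auc[def]) else if (sum(def) == 1) 0 else NA_real_
    }, numeric(1))
    res[[r]] <- tibble(rep = r, feature = colnames(m), auc_sd = sds)
  }
  out <- bind_rows(res)
  attr(out, "mode") <- mode
  out
}

#' Tail false-discovery estimate for an SD cutoff
#'
#' The FDR proxy used for choosing the AUC-SD criterion: the fraction of
#' null (scrambled) AUC standard deviations at or above the cutoff, i.e.
#' the per-test false positive rate of criterion 2 under the null.
#'
#' @param null_sds Numeric vector of null SDs, or the tibble returned by
#'   [null_sd_distribution()] (NA entries dropped).
#' @param cutoff SD cutoff (default 0.01).
#' @return Proportion in \[0, 1\].
#' @export
fdr_at_cutoff <- function(null_sds, cutoff = 0.01) {
  if (is.data.frame(null_sds)) null_sds <- null_sds$auc_sd
  null_sds <- null_sds[!is.na(null_sds)]
  if (length(null_sds) == 0) abort("Empty null SD distribution.")
  mean(null_sds >= cutoff)
}

#' Composite-model AUC across uniform size thresholds
#'
#' Re-creates the behaviour of fixed-membership CNA risk models evaluated
#' at varying size thresholds: at each uniform threshold T the listed
#' features are re-called at T, a multivariable Cox model on the calls
#' (plus optional covariates) is fit on the training samples, and the
#' model's linear predictor is scored by time-dependent AUC on the
#' evaluation samples.
#'
#' @param fractions A `cnasd_fractions` tibble.
#' @param features Character vector of feature names (fixed membership).
#' @param time,event Survival endpoint.
#' @param covariates Optional numeric matrix/data frame of extra model terms.
#' @param train,eval_idx Optional integer row indices for fitting and
#'   scoring (both default to all samples).
#' @param horizon,step Sweep parameters.
#' @return Tibble `threshold`, `auc`, `n_features_used` (features left
#'   after dropping columns constant in training at that threshold); `auc`
#'   is NA where the model could not be fit.
#' @export
composite_threshold_sweep <- function(fractions, features, time, event,
                                      covariates = NULL, train = NULL, eval_idx = NULL,
                                      horizon = 5, step = 1) {
  if (length(features) == 0) abort("Composite sweep needs at least one feature.")
  m <- fraction_matrix_of(fractions)
  miss <- setdiff(features, colnames(m))
  if (length(miss)) abort(sprintf("Unknown feature(s): %s", paste(miss, collapse = ", ")))
  n <- nrow(m)
  train <- train %||% seq_len(n)
  eval_idx <- eval_idx %||% seq_len(n)
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  thresholds <- seq(1, 99, by = step)
  rows <- purrr::map(thresholds, function(T) {
    calls <- sweep_ge(m[, features, drop = FALSE], setNames(rep(T, length(features)), features))
    X <- if (is.null(covariates)) calls else cbind(calls, covariates)
    keep <- apply(X[train, , drop = FALSE], 2, function(col) length(unique(col)) > 1)
    if (!any(keep)) return(tibble(threshold = T, auc = NA_real_, n_features_used = 0L))
    Xk <- X[, keep, drop = FALSE]
    fit <- tryCatch(cox_fit(Xk[train, , drop = FALSE], time[train], event[train]),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      return(tibble(threshold = T, auc = NA_real_, n_features_used = sum(keep)))
    }
    lp <- predict(fit, Xk[eval_idx, , drop = FALSE])
    res <- td_auc(lp, time[eval_idx], event[eval_idx], horizon)
    tibble(threshold = T, auc = ifelse(res$defined, res$auc, NA_real_),
           n_features_used = sum(keep))
  })
  out <- bind_rows(rows)
  class(out) <- c("cnasd_composite_sweep", class(out))
  out
}
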