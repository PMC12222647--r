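# Presorted survival structure shared by the td-ROC estimator and the
# threshold sweep: times ascending, events before censorings at ties, so a
# sequential product over events reproduces the grouped KM factor (r-d)/r.
surv_presort <- function(time, event) {
  stopifnot(length(time) == length(event), all(time > 0), all(event %in% c(0, 1)))
  ord <- order(time, -event)
  list(time = time[ord], event = as.numeric(event[ord]), ord = ord, n = length(time))
}

# Kaplan-Meier survival at `horizon` within the subset given by `mask`
# (logical, original sample order).
km_at <- function(ps, mask, horizon) {
  mm <- mask[ps$ord]
  if (!any(mm)) return(1)
  r <- rev(cumsum(rev(mm)))
  sel <- mm & ps$event == 1 & ps$time <= horizon
  if (!any(sel)) return(1)
  prod(1 - 1 / r[sel])
}

# AUC for a binary marker via the conditional-KM (cumulative/dynamic)
# sensitivity/specificity at the horizon; returns NA when a marker class is
# empty. `denoms` carries 1 - S(h) and S(h) for the whole cohort.
td_auc_binary <- function(mask, ps, horizon, denoms) {
  p <- mean(mask)
  if (p <= 0 || p >= 1) return(NA_real_)
  s_pos <- km_at(ps, mask, horizon)
  s_neg <- km_at(ps, !mask, horizon)
  sens <- min(max(p * (1 - s_pos) / denoms$one_minus_s, 0), 1)
  spec <- min(max((1 - p) * s_neg / denoms$s, 0), 1)
  fpr <- 1 - spec
  fpr * sens / 2 + (1 - fpr) * (sens + 1) / 2
}

td_denoms <- function(ps, horizon) {
  s <- km_at(ps, rep(TRUE, ps$n), horizon)
  list(s = s, one_minus_s = 1 - s)
}

#' Time-dependent ROC AUC at a fixed horizon
#'
#' Estimates the cumulative/dynamic time-dependent ROC curve of a marker
#' for event occurrence by `horizon` years, using Kaplan-Meier-based
#' (Heagerty-Lumley-Pepe) sensitivity and specificity: at each marker
#' cutpoint `c`, sensitivity is `P(X > c | T <= horizon)` and specificity
#' `P(X <= c | T > horizon)`, both estimated from conditional KM curves in
#' the marker-defined subsets so that samples censored before the horizon
#' contribute through the estimator's redistribution (no imputation). The
#' AUC integrates the curve by the trapezoidal rule over all unique marker
#' cutpoints; tied marker comparisons therefore contribute 1/2. In the
#' absence of censoring (horizon after all observed times) the estimate
#' equals the empirical Mann-Whitney concordance of the marker against the
#' event indicator.
#'
#' @param marker Numeric per-sample marker (higher = higher risk).
#' @param time,event Follow-up time (years) and 0/1 event indicator.
#' @param horizon Horizon in years (default 5).
#' @return A list with class `cnasd_tdroc`: `auc`, `horizon`, `n_cases`
#'   (events by horizon), `n_controls` (observed time beyond horizon),
#'   `defined` (FALSE when either class is empty, in which case `auc` is
#'   `NA` and no error is raised), `roc` (tibble of cutoff/fpr/tpr) and
#'   `estimator` metadata.
#' @export
td_auc <- function(marker, time, event, horizon = 5) {
  stopifnot(length(marker) == length(time))
  ps <- surv_presort(time, event)
  n_cases <- sum(event == 1 & time <= horizon)
  n_controls <- sum(time > horizon)
  meta <- list(estimator = "conditional-KM cumulative/dynamic (non-NN), marker ties contribute 1/2")
  if (n_cases == 0 || n_controls == 0) {
    return(structure(list(auc = NA_real_, horizon = horizon, n_cases = n_cases,
                          n_controls = n_controls, defined = FALSE,
                          roc = NULL, estimator = meta$estimator),
                     class = "cnasd_tdroc"))
  }
  denoms <- td_denoms(ps, horizon)
  cuts <- sort(unique(marker), decreasing = TRUE)
  tpr <- fpr <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    pos <- marker >= cuts[i]
    p <- mean(pos)
    s_pos <- km_at(ps, pos, horizon)
    s_neg <- km_at(ps, !pos, horizon)
    tpr[i] <- min(max(p * (1 - s_pos) / denoms$one_minus_s, 0), 1)
    fpr[i] <- 1 - min(max((1 - p) * s_neg / denoms$s, 0), 1)
  }
  roc <- tibble(cutoff = c(Inf, cuts), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  structure(list(auc = auc, horizon = horizon, n_cases = n_cases,
                 n_controls = n_controls, defined = TRUE, roc = roc,
                 estimator = meta$estimator),
            class = "cnasd_tdroc")
}

#' @export
print.cnasd_tdroc <- function(x, ...) {
  cat(sprintf("Time-dependent ROC at %s years: AUC = %s (%d cases, %d controls)\n",
              x$horizon, ifelse(x$defined, sprintf("%.4f", x$auc), "undefined"),
              x$n_cases, x$n_controls))
  invisible(x)
}

#' Cox proportional hazards fit
#'
#' Thin, validated wrapper around [survival::coxph()] returning the pieces
#' the pipeline needs (coefficients, standard errors, log partial
#' likelihood at the optimum and the null, convergence status). Efron tie
#' handling is the default for all directly interpreted fits.
#'
#' @param x Covariate matrix or data frame (samples x p, numeric).
#' @param time,event Survival outcome.
#' @param ties `"efron"` or `"breslow"`.
#' @return Object of class `cnasd_cox` with elements `coef`, `se`,
#'   `loglik`, `loglik_null`, `n`, `n_events`, `converged`, `ties`, `fit`
#'   (the underlying `coxph` object).
#' @export
cox_fit <- function(x, time, event, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  stopifnot(nrow(x) == length(time))
  if (sum(event) == 0) abort("Cox fit needs at least one event.")
  const <- apply(x, 2, function(col) length(unique(col)) == 1)
  if (any(const)) {
    abort(sprintf("Covariate(s) constant across samples (non-identifiable): %s",
                  paste(colnames(x)[const], collapse = ", ")))
  }
  df <- data.frame(x, check.names = FALSE)
  df$.time <- time; df$.event <- event
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(sprintf("`%s`", colnames(x)), collapse = " + ")))
  fit <- suppressWarnings(
    survival::coxph(fml, data = df, ties = ties,
                    control = survival::coxph.control(iter.max = 50, eps = 1e-9))
  )
  beta <- coef(fit)
  converged <- all(is.finite(beta)) && all(abs(beta) <= 15)
  structure(list(
    coef = setNames(as.numeric(beta), colnames(x)),
    se = setNames(sqrt(diag(fit$var)), colnames(x)),
    loglik = fit$loglik[2], loglik_null = fit$loglik[1],
    n = fit$n, n_events = fit$nevent, ties = ties,
    converged = converged, fit = fit
  ), class = "cnasd_cox")
}

#' @export
print.cnasd_cox <- function(x, ...) {
  cat(sprintf("Cox fit (%s ties): %d samples, %d events%s\n", x$ties, x$n, x$n_events,
              if (x$converged) "" else " [NOT converged]"))
  print(round(rbind(coef = x$coef, se = x$se), 4))
  invisible(x)
}

#' Linear predictor from a `cnasd_cox` fit
#' @param object A `cnasd_cox` fit.
#' @param newdata Covariate matrix/data frame with the fit's columns.
#' @param ... Unused.
#' @return Numeric risk score (X beta, NA coefficients treated as 0).
#' @export
predict.cnasd_cox <- function(object, newdata, ...) {
  b <- object$coef
  b[!is.finite(b)] <- 0
  as.numeric(as.matrix(newdata[, names(b), drop = FALSE]) %*% b)
}

#' Kaplan-Meier curves with a log-rank test
#'
#' Product-limit survival estimates per group plus the k-group log-rank
#' chi-square test (k - 1 degrees of freedom).
#'
#' @param group Per-sample group labels (>= 2 non-empty groups).
#' @param time,event Survival outcome.
#' @return Object of class `cnasd_km`: `km` (tibble group/time/n_risk/
#'   n_event/surv), `chisq`, `df`, `p_value`, `n_groups`.
#' @export
km_logrank <- function(group, time, event) {
  group <- as.factor(group)
  group <- droplevels(group)
  if (nlevels(group) < 2) abort("Log-rank test needs at least 2 non-empty groups.")
  df <- data.frame(time = time, event = event, group = group)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  strata_labels <- sub("^group=", "", rep(names(sf$strata), sf$strata))
  km <- tibble(group = strata_labels, time = sf$time, n_risk = sf$n.risk,
               n_event = sf$n.event, surv = sf$surv)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  dfree <- nlevels(group) - 1
  structure(list(km = km, chisq = as.numeric(sd$chisq), df = dfree,
                 p_value = pchisq(as.numeric(sd$chisq), dfree, lower.tail = FALSE),
                 n_groups = nlevels(group)),
            class = "cnasd_km")
}

#' @export
print.cnasd_km <- function(x, ...) {
  cat(sprintf("Kaplan-Meier over %d groups: log-rank chisq = %.3f (df %d), p = %.3g\n",
              x$n_groups, x$chisq, x$df, x$p_value))
  invisible(x)
}

#' KM survival probability at a time point
#' @param km_fit A `cnasd_km` object.
#' @param at Time point (years).
#' @return Tibble `group`, `surv` (step-function value at `at`).
#' @export
km_surv_at <- function(km_fit, at) {
  km_fit$km %>%
    group_by(.data$group) %>%
    summarise(surv = if (any(.data$time <= at)) .data$surv[max(which(.data$time <= at))] else 1,
              .groups = "drop")
}

#' Likelihood-ratio test between nested Cox models
#'
#' @param nested,full `cnasd_cox` fits on identical samples; `full` must
#'   strictly contain the nested model's covariates (equality allowed, in
#'   which case the statistic is 0 and p = 1).
#' @return Tibble with `statistic`, `df`, `p_value`.
#' @export
lr_test <- function(nested, full) {
  stopifnot(inherits(nested, "cnasd_cox"), inherits(full, "cnasd_cox"))
  if (nested$n != full$n || nested$n_events != full$n_events) {
    abort("Models must be fit on identical samples.")
  }
  if (!all(names(nested$coef) %in% names(full$coef))) {
    abort("Models are not nested: the full model must contain all nested covariates.")
  }
  stat <- max(0, 2 * (full$loglik - nested$loglik))
  dfree <- length(full$coef) - length(nested$coef)
  p <- if (dfree == 0) 1 else pchisq(stat, dfree, lower.tail = FALSE)
  tibble(statistic = stat, df = dfree, p_value = p)
}
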