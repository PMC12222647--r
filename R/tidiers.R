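#' @exportS3Method generics::tidy
tidy.cnasd_cox <- function(x, ...) {
  z <- x$coef / x$se
  tibble(term = names(x$coef), estimate = x$coef, std.error = x$se,
         statistic = z, p.value = 2 * stats::pnorm(-abs(z)),
         hazard.ratio = exp(x$coef))
}

#' @exportS3Method generics::glance
glance.cnasd_cox <- function(x, ...) {
  tibble(n = x$n, n.events = x$n_events, logLik = x$loglik,
         logLik.null = x$loglik_null,
         statistic.lrt = 2 * (x$loglik - x$loglik_null),
         ties = x$ties, converged = x$converged)
}

#' @exportS3Method generics::tidy
tidy.cnasd_sweep_feature <- function(x, ...) {
  tibble(feature = x$feature, threshold = x$thresholds, auc = x$auc)
}

#' @exportS3Method generics::glance
glance.cnasd_sweep_feature <- function(x, ...) {
  tibble(feature = x$feature, opt.threshold = x$opt_threshold, max.auc = x$max_auc,
         auc.sd = x$auc_sd, prevalence = x$prevalence, n.defined = x$n_defined)
}

#' @exportS3Method generics::tidy
tidy.cnasd_sweep <- function(x, ...) {
  thresholds <- attr(x, "thresholds")
  tidyr::unnest(
    mutate(select(x, "feature", "endpoint", "auc"),
           threshold = list(thresholds)),
    c("threshold", "auc")
  )
}

#' @exportS3Method generics::tidy
tidy.cnasd_regcox <- function(x, ...) {
  tibble(term = names(x$coef), estimate = x$coef,
         selected = names(x$coef) %in% x$selected)
}

#' @exportS3Method generics::glance
glance.cnasd_regcox <- function(x, ...) {
  tibble(alpha = x$alpha, lambda = x$lambda, best.cvm = x$best_cvm,
         n.selected = length(x$selected), nfolds = x$nfolds)
}

#' @exportS3Method generics::tidy
tidy.cnasd_boost <- function(x, ...) {
  tibble(term = names(x$coef), estimate = x$coef)
}

#' @exportS3Method generics::glance
glance.cnasd_boost <- function(x, ...) {
  tibble(rate = x$rate, rounds = x$rounds, n.features = length(x$coef))
}

#' @exportS3Method generics::tidy
tidy.cnasd_km <- function(x, ...) x$km

#' @exportS3Method generics::glance
glance.cnasd_km <- function(x, ...) {
  tibble(statistic = x$chisq, df = x$df, p.value = x$p_value, n.groups = x$n_groups)
}

#' @exportS3Method ggplot2::autoplot
autoplot.cnasd_tdroc <- function(object, ...) {
  if (!object$defined) abort("ROC undefined (no cases or no controls at the horizon).")
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("Time-dependent ROC at %g years (AUC %.3f)",
                                  object$horizon, object$auc)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.cnasd_sweep_feature <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$auc)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = object$opt_threshold, linetype = "dotted") +
    ggplot2::labs(x = "Size threshold (% of arm)", y = "5-year AUC",
                  title = object$feature %||% "Threshold sweep") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.cnasd_sweep <- function(object, features = NULL, ...) {
  df <- tidy(object)
  if (!is.null(features)) df <- filter(df, .data$feature %in% features)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$auc,
                                   colour = .data$feature)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~endpoint) +
    ggplot2::labs(x = "Size threshold (% of arm)", y = "AUC") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.cnasd_km <- function(object, ...) {
  df <- object$km %>%
    group_by(.data$group) %>%
    dplyr::group_modify(~ bind_rows(tibble(time = 0, n_risk = NA, n_event = NA, surv = 1), .x)) %>%
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv, colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Years", y = "Survival probability",
                  subtitle = sprintf("Log-rank p = %.3g", object$p_value)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.cnasd_bin_auc <- function(object, arm = NULL, ...) {
  df <- if (is.null(arm)) object else filter(object, .data$feature_arm == arm)
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2e6, y = .data$auc)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~feature_arm, scales = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = "Per-bin AUC") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.cnasd_composite_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$threshold, y = .data$auc)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "Uniform size threshold (% of arm)", y = "Composite model AUC") +
    ggplot2::theme_minimal()
}
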