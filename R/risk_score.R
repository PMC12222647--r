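# Gradient of the Cox log partial likelihood with respect to the per-sample
# score (Breslow ties): g_i = d_i - exp(eta_i) * H0(t_i), with H0 the
# Breslow cumulative baseline hazard at the current score.
cox_score_gradient <- function(eta, time, event) {
  n <- length(time)
  ord <- order(time, -event)
  tm <- time[ord]; em <- event[ord]; ee <- exp(eta[ord])
  atrisk <- rev(cumsum(rev(ee)))
  # Breslow: events at tied times share the risk set including the whole tie
  first_at_t <- c(TRUE, tm[-1] != tm[-n])
  tie_id <- cumsum(first_at_t)
  atrisk_t <- atrisk[first_at_t][tie_id]   # at-risk sum at each sample's time
  inc <- ifelse(em == 1, 1 / atrisk_t, 0)
  H0 <- cumsum(inc)
  # H0 at t_i must include all events with t_j <= t_i: take the last index of the tie
  last_of_tie <- cumsum(tabulate(tie_id))[tie_id]
  H0 <- H0[last_of_tie]
  g <- em - ee * H0
  g[ord] <- g
  g
}

#' Boosted linear Cox risk score
#'
#' Gradient boosting with a linear base learner on the Cox partial
#' likelihood: each round computes the gradient of the log partial
#' likelihood with respect to the current per-sample score, fits the
#' gradient by least squares on the features, and adds `rate` times the
#' base-learner coefficients to the model. The final score is a linear
#' function of the inputs; with 0 rounds all coefficients are 0. The
#' defaults (learning rate 0.009, 2 rounds) mirror the configuration used
#' for linear-booster survival models; tree depth has no meaning for a
#' linear booster and no tree parameters exist.
#'
#' @param x Samples-by-features numeric matrix (CNA calls and optional
#'   clinical covariates).
#' @param time,event Survival outcome (at least one event).
#' @param rate Learning rate (default 0.009).
#' @param rounds Boosting rounds (default 2).
#' @return Object of class `cnasd_boost`: `coef` (named), `rate`, `rounds`,
#'   `train_scores`, and frozen `cutpoints` at the 25th/50th training-score
#'   percentiles for [risk_groups()].
#' @export
boosted_cox_fit <- function(x, time, event, rate = 0.009, rounds = 2) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (sum(event) == 0) abort("Boosted Cox fit needs at least one event.")
  stopifnot(rounds >= 0, rate > 0)
  beta <- setNames(rep(0, ncol(x)), colnames(x))
  eta <- rep(0, nrow(x))
  for (r in seq_len(rounds)) {
    g <- cox_score_gradient(eta, time, event)
    b <- lm.fit(x, g)$coefficients
    b[is.na(b)] <- 0
    beta <- beta + rate * b
    eta <- as.numeric(x %*% beta)
  }
  scores <- as.numeric(x %*% beta)
  cut <- if (length(unique(scores)) > 1) quantile(scores, c(0.25, 0.50), type = 7)
         else NULL
  structure(list(coef = beta, rate = rate, rounds = rounds,
                 train_scores = scores, cutpoints = cut,
                 booster = "linear (depth not applicable)"),
            class = "cnasd_boost")
}

#' @export
print.cnasd_boost <- function(x, ...) {
  cat(sprintf("Boosted linear Cox score: %d round(s), rate %.4g\n", x$rounds, x$rate))
  print(round(x$coef, 5))
  invisible(x)
}

#' Score new samples with a boosted model
#' @param object A `cnasd_boost` fit.
#' @param newdata Feature matrix/data frame with the fit's columns.
#' @param ... Unused.
#' @return Numeric risk scores.
#' @export
predict.cnasd_boost <- function(object, newdata, ...) {
  as.numeric(as.matrix(newdata[, names(object$coef), drop = FALSE]) %*% object$coef)
}

#' Percentile-based risk groups
#'
#' Stratifies risk scores into low / intermediate / high groups at the
#' 25th and 50th percentiles of the training-score distribution
#' (linear-interpolation percentiles, frozen from training and applied to
#' new samples). Boundary scores go to the upper group: low < q25 <=
#' intermediate < q50 <= high.
#'
#' @param scores Scores to classify.
#' @param train_scores Training scores defining the percentiles (default:
#'   `scores` themselves; at least 4 required).
#' @param probs Percentile pair (default 25th and 50th).
#' @return Factor with levels low/intermediate/high and attribute
#'   `cutpoints`. Constant training scores collapse to a single group with
#'   a warning.
#' @export
risk_groups <- function(scores, train_scores = scores, probs = c(0.25, 0.50)) {
  if (length(train_scores) < 4) abort("Need at least 4 training scores.")
  if (length(unique(train_scores)) == 1) {
    warn("Training scores are constant; assigning all samples to one group.")
    return(structure(factor(rep("low", length(scores)),
                            levels = c("low", "intermediate", "high")),
                     cutpoints = NULL))
  }
  q <- quantile(train_scores, probs, type = 7)
  lab <- ifelse(scores < q[1], "low", ifelse(scores < q[2], "intermediate", "high"))
  structure(factor(lab, levels = c("low", "intermediate", "high")), cutpoints = q)
}

#' Bidirectional model-addition comparison
#'
#' Fits a baseline model and an augmented model, then tests each direction
#' of improvement by likelihood-ratio test: baseline plus the augmented
#' model's risk score against baseline alone, and vice versa. A score that
#' is collinear with the covariates it is added to is dropped by the Cox
#' fit, yielding a statistic of 0 and p = 1.
#'
#' @param x_base,x_aug Covariate matrices for the two models (identical
#'   samples).
#' @param time,event Survival outcome.
#' @return List: `fit_base`, `fit_aug` (`cnasd_cox`), and `tests`, a tibble
#'   with one row per direction (`aug_adds_to_base`, `base_adds_to_aug`)
#'   and columns `statistic`, `df`, `p_value`.
#' @export
compare_models <- function(x_base, x_aug, time, event) {
  x_base <- as.matrix(x_base); x_aug <- as.matrix(x_aug)
  stopifnot(nrow(x_base) == nrow(x_aug))
  fit_base <- cox_fit(x_base, time, event)
  fit_aug <- cox_fit(x_aug, time, event)
  score_base <- predict(fit_base, x_base)
  score_aug <- predict(fit_aug, x_aug)
  one_way <- function(x0, fit0, score_other, label) {
    X <- cbind(x0, other_score = score_other)
    fit1 <- cox_fit(X, time, event)
    res <- lr_test(fit0, fit1)
    mutate(res, direction = label, .before = 1)
  }
  tests <- bind_rows(
    one_way(x_base, fit_base, score_aug, "aug_adds_to_base"),
    one_way(x_aug, fit_aug, score_base, "base_adds_to_aug")
  )
  list(fit_base = fit_base, fit_aug = fit_aug, tests = tests)
}
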