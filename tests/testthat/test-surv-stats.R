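test_that("cox_fit validates input and respects sign symmetry", {
  set.seed(1)
  x <- rbinom(60, 1, 0.4)
  sv <- draw_surv(0.8 * x)
  f1 <- cox_fit(cbind(g = x), sv$time, sv$event)
  f2 <- cox_fit(cbind(g = 1 - x), sv$time, sv$event)
  expect_equal(unname(f1$coef), -unname(f2$coef), tolerance = 1e-8)
  expect_gte(f1$loglik, f1$loglik_null)

  expect_error(cox_fit(cbind(z = rep(0, 60)), sv$time, sv$event), "constant")
  expect_error(cox_fit(cbind(g = x), sv$time, rep(0, 60)), "at least one event")
})

test_that("cox_fit maximizes the partial likelihood (brute-force oracle, no ties)", {
  x <- c(0, 1, 0, 1, 1, 0, 1, 0)
  time <- c(1.1, 1.7, 2.3, 2.9, 3.6, 4.4, 5.1, 6.3)
  event <- rep(1, 8)
  fit <- cox_fit(cbind(x = x), time, event)
  opt <- optimize(function(b) oracle_log_pl(b, x, time, event),
                  c(-5, 5), maximum = TRUE, tol = 1e-9)
  expect_equal(unname(fit$coef), opt$maximum, tolerance = 1e-4)
  expect_equal(fit$loglik, opt$objective, tolerance = 1e-6)
})

test_that("separation is flagged non-converged rather than raised", {
  time <- c(1, 2, 3, 10, 11, 12)
  event <- rep(1, 6)
  x <- c(1, 1, 1, 0, 0, 0)   # perfect separation
  fit <- cox_fit(cbind(x = x), time, event)
  expect_false(fit$converged)
})

test_that("td_auc reproduces known values and flags degenerate horizons", {
  expect_equal(td_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 2, 10, 11), rep(1, 4), 5)$auc, 1.0)
  expect_equal(td_auc(rep(0.5, 4), c(1, 2, 10, 11), rep(1, 4), 5)$auc, 0.5)
  expect_equal(td_auc(c(0.9, 0.2, 0.8, 0.1), c(1, 2, 10, 11), rep(1, 4), 5)$auc, 0.75)

  res <- td_auc(1:4, c(6, 7, 8, 9), rep(1, 4), 5)   # no cases by horizon
  expect_false(res$defined)
  expect_true(is.na(res$auc))
  res2 <- td_auc(1:4, c(1, 2, 3, 4), rep(1, 4), 5)  # no controls beyond horizon
  expect_false(res2$defined)
})

test_that("td_auc equals empirical concordance without censoring", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    marker <- rnorm(n)
    time <- runif(n, 0.1, 4)
    event <- rep(1, n)
    case <- as.numeric(time <= 2.5)
    if (sum(case) == 0 || sum(case) == n) next
    got <- td_auc(marker, time, event, horizon = 2.5)$auc
    expect_equal(got, oracle_concordance(marker, case), tolerance = 1e-10)
  }
})

test_that("td_auc matches the direct-formula survfit oracle under censoring", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    marker <- rnorm(n)
    sv <- draw_surv(0.5 * marker)
    if (sum(sv$event == 1 & sv$time <= 5) == 0 || sum(sv$time > 5) == 0) next
    got <- td_auc(marker, sv$time, sv$event, horizon = 5)$auc
    expect_equal(got, oracle_td_auc(marker, sv$time, sv$event, 5), tolerance = 1e-10)
  }
})

test_that("td_auc is invariant under strictly monotone marker transforms", {
  set.seed(9)
  marker <- rnorm(40)
  sv <- draw_surv(0.7 * marker)
  a0 <- td_auc(marker, sv$time, sv$event)$auc
  expect_equal(td_auc(exp(marker), sv$time, sv$event)$auc, a0, tolerance = 1e-12)
  expect_equal(td_auc(rank(marker), sv$time, sv$event)$auc, a0, tolerance = 1e-12)
})

test_that("km_logrank handles identical groups, large effects, and single groups", {
  set.seed(10)
  sv <- draw_surv(rep(0, 40))
  dup <- km_logrank(rep(c("a", "b"), each = 40), c(sv$time, sv$time),
                    c(sv$event, sv$event))
  expect_equal(dup$chisq, 0, tolerance = 1e-12)
  expect_equal(dup$p_value, 1)

  g <- rbinom(500, 1, 0.5)
  sv2 <- draw_surv(log(4) * g)
  strong <- km_logrank(g, sv2$time, sv2$event)
  expect_lt(strong$p_value, 0.001)

  expect_error(km_logrank(rep("a", 40), sv$time, sv$event), "at least 2")
})

test_that("KM estimate is constant beyond the last event", {
  km <- km_logrank(c(1, 1, 1, 1, 2), c(1, 2, 3, 8, 5), c(1, 1, 0, 0, 1))
  s1 <- km_surv_at(km, 100); s2 <- km_surv_at(km, 10)
  expect_equal(s1$surv, s2$surv)
})

test_that("lr_test behaves at the boundary and rejects non-nested models", {
  set.seed(12)
  x <- matrix(rnorm(200), ncol = 2, dimnames = list(NULL, c("a", "b")))
  sv <- draw_surv(x[, 1])
  full <- cox_fit(x, sv$time, sv$event)
  nested <- cox_fit(x[, 1, drop = FALSE], sv$time, sv$event)
  res <- lr_test(nested, full)
  expect_gte(res$statistic, 0)
  expect_equal(res$df, 1)

  same <- lr_test(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  other <- cox_fit(matrix(rnorm(100), dimnames = list(NULL, "c")), sv$time, sv$event)
  expect_error(lr_test(other, full), "not nested")
})

test_that("null noise covariates give approximately uniform LRT p-values", {
  set.seed(13)
  ps <- replicate(60, {
    x <- matrix(rnorm(300), ncol = 2, dimnames = list(NULL, c("a", "noise")))
    sv <- draw_surv(0.5 * x[, 1])
    lr_test(cox_fit(x[, 1, drop = FALSE], sv$time, sv$event),
            cox_fit(x, sv$time, sv$event))$p_value
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("cox_fit recovers a planted hazard ratio", {
  set.seed(14)
  x <- rbinom(2000, 1, 0.3)
  sv <- draw_surv(1.1 * x)
  fit <- cox_fit(cbind(x = x), sv$time, sv$event)
  expect_lt(abs(exp(fit$coef) / exp(1.1) - 1), 0.10)
})
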