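test_that("tuple enumeration requires a size-dependent member and multiplies calls", {
  calls <- tibble::tibble(sample = c("S1", "S2"),
                          `1p_loss` = c(1, 1), `22q_loss` = c(1, 0),
                          `9p_loss` = c(1, 0), `4q_loss` = c(0, 0))
  tup <- tuple_features(calls, c("1p_loss", "22q_loss"), min_prevalence = 0)
  # pairs without any size-dependent member (9p+4q) are excluded
  expect_false("9p_loss+4q_loss" %in% tup$features$tuple)
  expect_equal(nrow(tup$features), 5)
  for (p in c("1p_loss+22q_loss", "1p_loss+9p_loss", "22q_loss+9p_loss")) {
    expect_equal(unname(tup$indicator["S1", p]), 1)
  }
  # a sample with one call has all pair indicators 0
  expect_true(all(tup$indicator["S2", setdiff(colnames(tup$indicator), NA)] %in% c(0, 1)))
  expect_equal(sum(tup$indicator["S2", ]), 0)
})

test_that("tuple indicators equal the product of member calls on random matrices", {
  set.seed(40)
  for (i in 1:5) {
    m <- matrix(rbinom(30 * 6, 1, 0.4), ncol = 6,
                dimnames = list(NULL, paste0(1:6, "p_loss")))
    calls <- dplyr::bind_cols(tibble::tibble(sample = sprintf("S%02d", 1:30)),
                              tibble::as_tibble(m))
    tup <- tuple_features(calls, "1p_loss", min_prevalence = 0)
    for (j in seq_len(nrow(tup$features))) {
      mem <- tup$features$members[[j]]
      expect_equal(unname(tup$indicator[, j]),
                   unname(m[, mem[1]] * m[, mem[2]]))
    }
    expect_true(all(tup$features$prevalence == colMeans(tup$indicator)))
  }
})

test_that("triplets are bounded by C(k,3) and the prevalence filter is exact", {
  calls <- tibble::tibble(sample = sprintf("S%02d", 1:40),
                          a_loss = rbinom(40, 1, 0.8), b_loss = rbinom(40, 1, 0.8),
                          c_gain = rbinom(40, 1, 0.8), d_loss = rbinom(40, 1, 0.8))
  tup3 <- tuple_features(calls, c("a_loss", "b_loss", "c_gain", "d_loss"),
                         order = 3, min_prevalence = 0)
  expect_lte(nrow(tup3$features), choose(4, 3))
  tup <- tuple_features(calls, "a_loss", min_prevalence = 0.025)
  expect_true(all(tup$features$prevalence >= 0.025))
  expect_warning(res <- tuple_features(calls, character(0)), "No size-dependent")
  expect_equal(nrow(res$features), 0)
})

test_that("regularized Cox at lambda ~ 0 reproduces the unpenalized fit", {
  set.seed(41)
  n <- 250
  x <- matrix(rnorm(n * 3), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  sv <- draw_surv(0.8 * x[, 1] - 0.5 * x[, 2])
  reg <- regularized_cox_cv(x, sv$time, sv$event, alphas = 1, seed = 5,
                            lambda = exp(seq(log(0.5), log(1e-7), length.out = 60)))
  b_glm <- as.numeric(coef(reg$fit, s = min(reg$fit$lambda)))
  b_cox <- cox_fit(x, sv$time, sv$event, ties = "breslow")$coef
  expect_equal(b_glm, unname(b_cox), tolerance = 1e-3)
  # large lambda end of the path is the empty model
  expect_true(all(as.numeric(coef(reg$fit, s = max(reg$fit$lambda))) == 0))
})

test_that("duplicated features share weight under the elastic net", {
  set.seed(42)
  n <- 300
  x1 <- rnorm(n)
  sv <- draw_surv(x1)
  xs <- cbind(a = x1)
  xd <- cbind(a = x1, a2 = x1, b = rnorm(n))
  rs <- regularized_cox_cv(cbind(xs, b = xd[, "b"]), sv$time, sv$event,
                           alphas = 0.5, seed = 6)
  rd <- regularized_cox_cv(xd, sv$time, sv$event, alphas = 0.5, seed = 6)
  if (rs$coef["a"] != 0 && rd$coef["a"] != 0) {
    expect_lt(abs(rd$coef["a"]), abs(rs$coef["a"]))
    expect_lt(abs(rd$coef["a2"]), abs(rs$coef["a"]))
  }
  expect_error(regularized_cox_cv(xd, sv$time, rep(c(1, 0), c(5, n - 5)), nfolds = 10),
               "fewer folds")
})

test_that("stratified_km builds four strata and validates emptiness", {
  set.seed(43)
  n <- 200
  a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
  sv <- draw_surv(1.5 * a * b)
  res <- stratified_km(a, b, sv$time, sv$event, labels = c("1p_loss", "22q_loss"))
  expect_equal(levels(res$stratum),
               c("neither", "1p_loss only", "22q_loss only", "both"))
  expect_equal(res$overall$n_groups, 4)
  s5 <- km_surv_at(res$overall, 5)
  expect_equal(s5$group[which.min(s5$surv)], "both")

  expect_error(stratified_km(rep(0, n), b, sv$time, sv$event), "'both' stratum")
  expect_error(stratified_km(rep(1, n), rep(1, n), sv$time, sv$event), "single stratum")
})

test_that("pair-with-burden adjusts for burden and degrades gracefully", {
  set.seed(44)
  n <- 400
  pair <- rbinom(n, 1, 0.2)
  burden <- rpois(n, 4)
  sv <- draw_surv(0.9 * pair + 0.05 * burden)
  res <- pair_with_burden_cox(pair, burden, sv$time, sv$event)
  expect_equal(res$wald$term, c("pair", "burden"))
  expect_lt(res$wald$p_value[res$wald$term == "pair"], 0.05)

  expect_warning(uni <- pair_with_burden_cox(pair, rep(3, n), sv$time, sv$event),
                 "constant")
  expect_equal(names(uni$fit$coef), "pair")
})

test_that("clustering recovers three planted prevalence archetypes", {
  skip_if_not_installed("cluster")
  set.seed(45)
  n <- 600
  burden <- sample(0:8, n, replace = TRUE)
  p_high <- rep(0.8, n)                       # constant-high
  p_inc <- pmin(0.05 + 0.1 * burden, 0.9)     # burden-increasing
  p_rare <- rep(0.04, n)                      # rare-flat
  mk <- function(p) rbinom(n, 1, p)
  calls <- tibble::tibble(sample = sprintf("S%03d", 1:n),
                          h1_loss = mk(p_high), h2_loss = mk(p_high), h3_loss = mk(p_high),
                          i1_loss = mk(p_inc), i2_loss = mk(p_inc), i3_loss = mk(p_inc),
                          r1_loss = mk(p_rare), r2_loss = mk(p_rare), r3_loss = mk(p_rare))
  cl <- cluster_cnas(calls, burden = burden)
  expect_equal(cl$k, 3)
  grp <- split(names(cl$cluster), cl$cluster)
  sets <- lapply(grp, function(g) sort(substr(g, 1, 1)))
  expect_setequal(vapply(sets, paste, character(1), collapse = ""),
                  c("hhh", "iii", "rrr"))

  # invariant to feature order
  cl2 <- cluster_cnas(calls[, c(1, sample(2:10))], burden = burden)
  expect_equal(cl2$k, 3)
  expect_error(cluster_cnas(calls[, 1:2], burden = burden), "at least 2")
})

test_that("burden partition respects leaf limits and rejects constant burden", {
  set.seed(46)
  sv <- draw_surv(rep(0, 30))
  res <- burden_partition(rpois(30, 4), sv$time, sv$event, min_leaf = 20)
  expect_equal(length(res$cuts), 0)           # n < 2*min_leaf: single stratum
  expect_equal(unique(res$stratum), "all")
  expect_error(burden_partition(rep(5, 100), sv$time, sv$event), "constant")
})

test_that("burden partition finds a planted change-point and spares the null", {
  set.seed(47)
  burden <- rpois(500, 5)
  sv <- draw_surv(log(4) * (burden >= 5))
  res <- burden_partition(burden, sv$time, sv$event)
  expect_true(res$cuts[1] %in% 4:6)
  expect_lt(res$km$p_value, 0.001)

  nulls <- replicate(10, {
    b <- rpois(300, 5)
    s <- draw_surv(rep(0, 300))
    length(burden_partition(b, s$time, s$event)$cuts) == 0
  })
  expect_gte(mean(nulls), 0.9)
})
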