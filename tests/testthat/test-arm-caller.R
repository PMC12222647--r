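test_that("percent_arm_altered classifies grid points by covering segment", {
  arm <- one_arm(3e6)
  f <- percent_arm_altered(make_segs(0, 1.5e6, -0.5), arm)
  expect_equal(unname(f["loss"]), 0.50)
  expect_equal(unname(f["gain"]), 0.0)

  # two disjoint loss runs sum (non-consecutive alteration)
  f2 <- percent_arm_altered(make_segs(c(0, 2.4e6), c(0.6e6, 3e6), c(-0.3, -0.3)), arm)
  expect_equal(unname(f2["loss"]), 0.40)

  # below-cutoff intensity is neutral
  f3 <- percent_arm_altered(make_segs(0, 3e6, -0.05), arm)
  expect_equal(unname(f3["loss"]), 0.0)

  expect_error(percent_arm_altered(make_segs(0, 1e4, -0.5), one_arm(1e4)), "grid step")
})

test_that("grid fractions match per-base brute force within one grid point", {
  set.seed(42)
  cut <- intensity_cutoffs()
  for (i in 1:50) {
    len <- round(runif(1, 1e6, 8e6) / 3e4) * 3e4   # whole grid steps
    arm <- one_arm(len)
    # one altered segment per direction (disjoint halves, as validated input)
    s1 <- runif(1, 0, len * 0.4); e1 <- runif(1, s1 + 3e4, len * 0.5)
    s2 <- runif(1, len * 0.5, len * 0.9); e2 <- runif(1, s2 + 3e4, len)
    segs <- make_segs(c(s1, s2), c(e1, e2), c(runif(1, -0.6, -0.15), runif(1, 0.2, 0.6)))
    got <- percent_arm_altered(segs, arm, cut)
    tol <- 3e4 / len + 1e-12
    expect_lt(abs(got["loss"] - oracle_arm_fraction(segs, 0, len, cut$loss, "loss")), tol)
    expect_lt(abs(got["gain"] - oracle_arm_fraction(segs, 0, len, cut$gain, "gain")), tol)
  }
})

test_that("fractions are invariant to coordinate scaling and sample order", {
  arm <- one_arm(3e6)
  segs <- make_segs(c(0.2e6, 2e6), c(1e6, 2.9e6), c(-0.5, 0.4))
  f1 <- percent_arm_altered(segs, arm)
  segs2 <- dplyr::mutate(segs, start = start * 2, end = end * 2)
  f2 <- percent_arm_altered(segs2, one_arm(6e6), grid_step = 60000)
  expect_equal(f1, f2)

  arms <- arm_table_toy()
  segsAB <- dplyr::bind_rows(
    make_segs(0, 5e6, -0.5, chrom = "1", sample = "A"),
    make_segs(0, 2e6, 0.4, chrom = "2", sample = "B"))
  fr_ab <- arm_fractions(validate_segments(segsAB, arms), arms)
  fr_ba <- arm_fractions(validate_segments(segsAB[c(2, 1), ], arms), arms)
  expect_equal(fr_ab, fr_ba)
})

test_that("fraction matrix has deterministic 2 x 78 shape; empty profiles are zero", {
  arms <- arm_table_toy()
  segs <- dplyr::bind_rows(
    make_segs(0, 5e6, -0.5, chrom = "1", sample = "A"),
    make_segs(0, 2e6, 0.1, chrom = "2", sample = "B"))  # neutral intensity
  fr <- arm_fractions(validate_segments(segs, arms), arms)
  expect_equal(dim(fr), c(2L, 79L))  # sample + 39*2 features
  expect_equal(names(fr)[2:3], c("1p_loss", "1p_gain"))
  expect_true(all(as.matrix(fr[fr$sample == "B", -1]) == 0))

  expect_warning(
    fr2 <- arm_fractions(validate_segments(segs, arms), arms, samples = c("A", "B", "Z")),
    "no usable segments")
  expect_true(all(as.matrix(fr2[fr2$sample == "Z", -1]) == 0))
})

test_that("neutral profiles yield zero fractions and zero burden", {
  arms <- arm_table_toy()
  inc <- arms[arms$included, ]
  segs <- dplyr::bind_rows(lapply(seq_len(nrow(inc)), function(i) {
    make_segs(inc$start[i], inc$end[i], 0.02, chrom = inc$chrom[i])
  }))
  fr <- arm_fractions(validate_segments(segs, arms), arms)
  expect_true(all(as.matrix(fr[-1]) == 0))
  calls <- cna_calls(fr, 1)
  expect_equal(cna_burden(calls)$burden, 0L)
})

test_that("calls use inclusive >= threshold semantics and monotone prevalence", {
  fr <- tibble::tibble(sample = c("A", "B"), `1p_loss` = c(0.23, 0.229))
  class(fr) <- c("cnasd_fractions", class(fr))
  calls <- cna_calls(fr, c(`1p_loss` = 23))
  expect_equal(calls$`1p_loss`, c(1L, 0L))
  c1 <- cna_calls(fr, 1); c99 <- cna_calls(fr, 99)
  expect_true(all(colSums(as.matrix(c99[-1])) <= colSums(as.matrix(c1[-1]))))
  expect_error(cna_calls(fr, c(nonexistent = 10)), "Unknown feature")
  expect_error(cna_calls(fr, c(`1p_loss` = 100)), "\\[1, 99\\]")
})

test_that("burden is the row sum of calls, bounded by the feature count", {
  calls <- tibble::tibble(sample = c("A", "B"),
                          `1p_loss` = c(1, 0), `22q_loss` = c(1, 0), `1q_gain` = c(1, 0))
  b <- cna_burden(calls)
  expect_equal(b$burden, c(3L, 0L))
  expect_true(all(b$burden <= ncol(calls) - 1))
})

test_that("intensity sensitivity with the default-only grid matches the baseline sweep", {
  set.seed(11)
  arms <- arm_table_toy()
  inc <- arms[arms$included, ]
  segs <- dplyr::bind_rows(lapply(1:30, function(s) {
    i <- sample(nrow(inc), 1)
    w <- runif(1, 0.2, 0.8) * (inc$end[i] - inc$start[i])
    make_segs(inc$start[i], inc$start[i] + w, sample(c(-0.45, 0.3), 1),
              chrom = inc$chrom[i], sample = sprintf("S%02d", s))
  }))
  v <- validate_segments(segs, arms)
  sv <- draw_surv(rep(0, 30))
  fr <- arm_fractions(v, arms, samples = sprintf("S%02d", 1:30))
  base <- cna_sweep(fr, sv$time, sv$event)
  expect_warning(
    sens <- intensity_sensitivity(v, arms, sv$time, sv$event,
                                  loss_grid = -0.1, gain_grid = 0.15),
    "Degenerate")
  merged <- dplyr::left_join(sens, base[, c("feature", "max_auc")],
                             by = "feature", suffix = c("", ".base"))
  expect_equal(merged$max_auc, merged$max_auc.base)
  expect_false(attr(sens, "improved"))
})
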