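toy_track <- function(segs, arms = arm_table_toy(), samples = NULL, width = 2e5) {
  v <- validate_segments(segs, arms)
  bin_intensities(v, bin_grid(arms, width), samples = samples)
}

test_that("bin grids tile arms contiguously with a short final bin", {
  arms <- arm_table_toy()
  grid <- bin_grid(arms, width = 2e5)
  per_arm <- split(grid, grid$feature_arm)
  inc <- arms[arms$included, ]
  for (fa in names(per_arm)) {
    g <- per_arm[[fa]]
    a <- inc[inc$feature_arm == fa, ]
    expect_equal(g$start[1], a$start)
    expect_equal(g$end[nrow(g)], a$end)
    expect_true(all(g$start[-1] == g$end[-nrow(g)])) # contiguous, disjoint
    expect_true(all(g$end - g$start <= 2e5))
  }
})

test_that("bin intensity is the overlap-length x probe-density weighted mean", {
  # two segments overlap the bin [200kb, 400kb) by 100 kb each;
  # densities 1/10kb and 3/10kb give weights 10 and 30
  segs <- make_segs(c(1e5, 3e5), c(3e5, 5e5), c(-0.4, 0.0), probes = c(20, 60))
  bt <- toy_track(segs)
  bin2 <- which(bt$grid$feature_arm == "1p")[2]
  expect_equal(unname(bt$intensity["S1", bin2]), (10 * -0.4 + 30 * 0) / 40)

  # single fully-covering segment: exactly that segment's mean
  bin1 <- which(bt$grid$feature_arm == "1p")[1]
  expect_equal(unname(bt$intensity["S1", bin1]), -0.4)

  # no overlap: missing
  far_bin <- which(bt$grid$feature_arm == "1q")[1]
  expect_true(is.na(bt$intensity["S1", far_bin]))
})

test_that("a whole-arm segment gives identical intensity in every bin of the arm", {
  arms <- arm_table_toy()
  a <- arms[arms$feature_arm == "3q", ]
  segs <- make_segs(a$start, a$end, -0.37, chrom = "3")
  bt <- toy_track(segs)
  vals <- bt$intensity["S1", bt$grid$feature_arm == "3q"]
  expect_true(all(vals == -0.37))
  expect_true(all(bt$loss["S1", bt$grid$feature_arm == "3q"] == 1))
})

test_that("mean bin calls agree with percent_arm_altered on single-segment profiles", {
  set.seed(30)
  arms <- arm_table_toy()
  a <- arms[arms$feature_arm == "5q", ]
  for (i in 1:10) {
    s <- runif(1, a$start, a$end - 1e6)
    e <- runif(1, s + 5e5, a$end)
    # one altered segment plus neutral filler over the rest of the arm
    segs <- make_segs(c(a$start, s, e), c(s, e, a$end), c(0, -0.5, 0))
    segs <- dplyr::filter(segs, start < end)
    segs$chrom <- "5"
    bt <- toy_track(segs)
    sel <- bt$grid$feature_arm == "5q"
    frac_bins <- mean(bt$loss["S1", sel])
    frac_grid <- percent_arm_altered(segs, a)["loss"]
    # each segment boundary can sway its boundary bin, so two bin-widths
    expect_lt(abs(frac_bins - frac_grid), 2 * 2e5 / (a$end - a$start) + 1e-9)
  }
})

test_that("bin AUC profiles flag unaltered bins and track planted prognosis", {
  set.seed(31)
  arms <- arm_table_toy()
  a <- arms[arms$feature_arm == "7q", ]
  n <- 120
  hit <- rbinom(n, 1, 0.3)
  segs <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    if (hit[i] == 1) {
      make_segs(a$start, a$start + 2e6, -0.5, chrom = "7", sample = sprintf("S%03d", i))
    } else {
      make_segs(a$start, a$start + 2e6, 0.0, chrom = "7", sample = sprintf("S%03d", i))
    }
  }))
  bt <- toy_track(segs, samples = sprintf("S%03d", seq_len(n)))
  sv <- draw_surv(1.5 * hit)
  prof <- bin_auc_profile(bt, sv$time, sv$event, "loss")
  sel <- prof$feature_arm == "7q"
  expect_true(all(!is.na(prof$auc[sel][1:10])))   # altered bins defined
  expect_true(all(is.na(prof$auc[!sel])))         # untouched arms undefined
  expect_gt(mean(prof$auc[sel][1:10]), 0.55)      # planted prognostic signal
})

test_that("focal region calling applies the +0.04 margin inclusively", {
  grid <- bin_grid(arm_table_toy())
  arm_bins <- grid[grid$feature_arm == "1p", ][1:11, ]
  mk_prof <- function(auc) {
    out <- dplyr::mutate(arm_bins, direction = "loss", prevalence = 0.1, auc = auc)
    class(out) <- c("cnasd_bin_auc", class(out))
    out
  }
  expect_equal(nrow(focal_regions(mk_prof(rep(0.5, 11)))), 0)     # flat profile
  bump05 <- c(rep(0.5, 5), 0.55, rep(0.5, 5))
  r <- focal_regions(mk_prof(bump05))
  expect_equal(nrow(r), 1)
  expect_equal(r$n_bins, 1L)
  expect_equal(r$peak_auc, 0.55)
  bump03 <- c(rep(0.5, 5), 0.53, rep(0.5, 5))
  expect_equal(nrow(focal_regions(mk_prof(bump03))), 0)
  bump04 <- c(rep(0.5, 5), 0.54, rep(0.5, 5))
  expect_equal(nrow(focal_regions(mk_prof(bump04))), 1)           # boundary passes

  # invariance to adding a constant to every bin AUC
  r2 <- focal_regions(mk_prof(bump05 + 0.1))
  expect_equal(r2$start, r$start)
  expect_equal(r2$end, r$end)
})

test_that("runs break at undefined bins and arms with <3 defined bins warn", {
  grid <- bin_grid(arm_table_toy())
  arm_bins <- grid[grid$feature_arm == "1p", ][1:7, ]
  auc <- c(0.6, 0.6, NA, 0.6, 0.5, 0.5, 0.5)
  prof <- dplyr::mutate(arm_bins, direction = "loss", prevalence = 0.1, auc = auc)
  class(prof) <- c("cnasd_bin_auc", class(prof))
  r <- focal_regions(prof)   # median 0.55; >= 0.59 hits bins 1,2,4
  expect_equal(nrow(r), 2)   # NA bin splits the run
  expect_equal(r$n_bins, c(2L, 1L))

  few <- dplyr::mutate(arm_bins[1:4, ], direction = "loss", prevalence = 0.1,
                       auc = c(0.6, 0.5, NA, NA))
  class(few) <- c("cnasd_bin_auc", class(few))
  expect_warning(r3 <- focal_regions(few), "fewer than 3")
  expect_equal(nrow(r3), 0)
})

test_that("pileup proportions count missing bins as unaltered", {
  arms <- arm_table_toy()
  a <- arms[arms$feature_arm == "2p", ]
  segs <- dplyr::bind_rows(
    make_segs(a$start, a$start + 4e5, -0.5, chrom = "2", sample = "A"),
    make_segs(a$start, a$start + 4e5, -0.5, chrom = "2", sample = "B"))
  bt <- toy_track(segs, samples = c("A", "B"))
  pile <- cna_pileup(bt)
  first2 <- pile[pile$feature_arm == "2p", ][1:2, ]
  expect_equal(first2$prop_loss, c(1, 1))       # both samples delete these bins
  expect_equal(pile$prop_loss[pile$feature_arm == "3p"], rep(0, sum(pile$feature_arm == "3p")))
})
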