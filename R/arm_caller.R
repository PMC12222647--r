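arm_grid_points <- function(arm_start, arm_end, grid_step) {
  len <- arm_end - arm_start
  if (len < grid_step) {
    abort(sprintf("Arm of length %s bp is shorter than one grid step (%s bp).",
                  format(len), format(grid_step)))
  }
  npts <- ceiling(len / grid_step)
  arm_start + grid_step * (0:(npts - 1L))
}

classify_points <- function(pts, seg_start, seg_end, seg_mean, cutoffs) {
  if (length(seg_start) == 0) {
    return(list(loss = logical(length(pts)), gain = logical(length(pts))))
  }
  o <- order(seg_start)
  seg_start <- seg_start[o]; seg_end <- seg_end[o]; seg_mean <- seg_mean[o]
  idx <- findInterval(pts, seg_start)
  covered <- idx >= 1L & pts < seg_end[pmax(idx, 1L)]
  val <- rep(NA_real_, length(pts))
  val[covered] <- seg_mean[idx[covered]]
  list(loss = !is.na(val) & val < cutoffs$loss,
       gain = !is.na(val) & val > cutoffs$gain)
}

#' Percent of a chromosome arm altered for one sample
#'
#' Samples the arm at fixed grid intervals (30 kb by default) anchored at
#' the arm start, classifies each grid point by the mean intensity of the
#' covering segment (loss below the loss cutoff, gain above the gain
#' cutoff, otherwise neutral; uncovered points neutral) and returns the
#' fraction of points lost and gained. Disjoint (non-consecutive) altered
#' runs all contribute, so focal and broad events on the same arm sum.
#'
#' @param segments Segments of one sample (any tibble with `chrom`, `start`,
#'   `end`, `seg_mean`); only rows on `arm`'s chromosome are used.
#' @param arm A single-row arm record with `chrom`, `start`, `end`.
#' @param cutoffs An [intensity_cutoffs()] object.
#' @param grid_step Grid spacing in bp (default 30000).
#' @return Named numeric vector `c(loss = , gain = )`; fractions are
#'   multiples of 1/(number of grid points).
#' @export
percent_arm_altered <- function(segments, arm, cutoffs = intensity_cutoffs(),
                                grid_step = 30000) {
  stopifnot(nrow(arm) == 1)
  pts <- arm_grid_points(arm$start, arm$end, grid_step)
  segs <- segments[segments$chrom == arm$chrom &
                     segments$start < arm$end & segments$end > arm$start, , drop = FALSE]
  cls <- classify_points(pts, segs$start, segs$end, segs$seg_mean, cutoffs)
  c(loss = mean(cls$loss), gain = mean(cls$gain))
}

feature_names_for <- function(arms) {
  inc <- arms[arms$included, , drop = FALSE]
  as.vector(t(outer(inc$feature_arm, c("loss", "gain"), paste, sep = "_")))
}

#' Split a feature name into arm and direction
#' @param feature Character vector like "1p_loss".
#' @return Tibble with `feature`, `feature_arm`, `direction`.
#' @export
parse_feature <- function(feature) {
  m <- stringr::str_match(feature, "^(.+)_(loss|gain)$")
  if (anyNA(m[, 1])) abort(sprintf("Malformed feature name(s): %s",
                                   paste(feature[is.na(m[, 1])], collapse = ", ")))
  tibble(feature = feature, feature_arm = m[, 2], direction = m[, 3])
}

#' Per-arm percent-altered fraction matrix
#'
#' Computes, for every sample and every included (arm, direction) feature,
#' the fraction of the arm altered via [percent_arm_altered()]'s grid
#' classification. Samples with no segments get all-zero fractions (with a
#' warning); uncovered grid points count as neutral and stay in the
#' denominator, so fractions are comparable across samples.
#'
#' @param segments A validated `cnasd_segments` tibble (see
#'   [validate_segments()]); unvalidated segments are validated on the fly.
#' @param arms A `cnasd_arms` tibble.
#' @param cutoffs An [intensity_cutoffs()] object.
#' @param grid_step Grid spacing in bp (default 30000).
#' @param samples Optional character vector fixing the sample universe and
#'   row order (samples absent from `segments` get zero rows).
#' @return A wide tibble with class `cnasd_fractions`: column `sample`
#'   followed by one numeric column per feature ("1p_loss", "1p_gain", ...),
#'   rows ordered by `samples` (or sorted sample ID). Attributes `arms`,
#'   `cutoffs` and `grid_step` record the call.
#' @export
arm_fractions <- function(segments, arms, cutoffs = intensity_cutoffs(),
                          grid_step = 30000, samples = NULL) {
  if (!isTRUE(attr(segments, "validated"))) {
    segments <- validate_segments(segments, arms)
  }
  inc <- arms[arms$included, , drop = FALSE]
  grids <- lapply(seq_len(nrow(inc)), function(i) {
    arm_grid_points(inc$start[i], inc$end[i], grid_step)
  })
  npts <- vapply(grids, length, integer(1))
  segs <- segments[!segments$excluded, , drop = FALSE]
  if (is.null(samples)) samples <- sort(unique(segments$sample))
  empty <- setdiff(samples, unique(segs$sample))
  if (length(empty)) {
    warn(sprintf("%d sample(s) have no usable segments; fractions set to 0.", length(empty)))
  }
  feats <- feature_names_for(arms)
  mat <- matrix(0, nrow = length(samples), ncol = length(feats),
                dimnames = list(samples, feats))
  by_sample <- split(segs, segs$sample)
  for (sid in names(by_sample)) {
    ss <- by_sample[[sid]]
    by_chrom <- split(ss, ss$chrom)
    for (i in seq_len(nrow(inc))) {
      sc <- by_chrom[[inc$chrom[i]]]
      if (is.null(sc)) next
      sa <- sc[sc$start < inc$end[i] & sc$end > inc$start[i], , drop = FALSE]
      if (nrow(sa) == 0) next
      cls <- classify_points(grids[[i]], sa$start, sa$end, sa$seg_mean, cutoffs)
      mat[sid, paste0(inc$feature_arm[i], "_loss")] <- sum(cls$loss) / npts[i]
      mat[sid, paste0(inc$feature_arm[i], "_gain")] <- sum(cls$gain) / npts[i]
    }
  }
  out <- as_tibble(mat)
  out <- dplyr::bind_cols(tibble(sample = samples), out)
  class(out) <- c("cnasd_fractions", class(out))
  attr(out, "arms") <- arms
  attr(out, "cutoffs") <- cutoffs
  attr(out, "grid_step") <- grid_step
  out
}

fraction_matrix_of <- function(fractions) {
  m <- as.matrix(fractions[setdiff(names(fractions), "sample")])
  rownames(m) <- fractions$sample
  m
}

#' Binary CNA calls at size thresholds
#'
#' Calls a feature present when its percent-arm-altered fraction meets or
#' exceeds the threshold: `call = 1` iff `fraction * 100 >= threshold`
#' (a fraction exactly at the threshold counts as present).
#'
#' @param fractions A `cnasd_fractions` tibble.
#' @param thresholds Integer percent threshold(s) in \[1, 99\]: a single
#'   value applied uniformly, or a named vector with one entry per feature
#'   (e.g. per-feature optima from a sweep).
#' @return A tibble with class `cnasd_calls`: `sample` plus one 0/1 column
#'   per feature; attribute `thresholds` stores the per-feature thresholds.
#' @export
cna_calls <- function(fractions, thresholds) {
  feats <- setdiff(names(fractions), "sample")
  if (is.null(names(thresholds))) {
    if (length(thresholds) != 1) {
      abort("`thresholds` must be a single value or a named per-feature vector.")
    }
    thr <- setNames(rep(thresholds, length(feats)), feats)
  } else {
    unknown <- setdiff(names(thresholds), feats)
    if (length(unknown)) abort(sprintf("Unknown feature(s) in thresholds: %s",
                                       paste(unknown, collapse = ", ")))
    thr <- setNames(rep(NA_real_, length(feats)), feats)
    thr[names(thresholds)] <- thresholds
    miss <- feats[is.na(thr)]
    if (length(miss)) abort(sprintf("No threshold supplied for feature(s): %s",
                                    paste(head(miss, 5), collapse = ", ")))
  }
  if (any(thr < 1 | thr > 99)) abort("Thresholds must lie in [1, 99] percent.")
  m <- fraction_matrix_of(fractions)
  calls <- sweep_ge(m, thr)
  out <- dplyr::bind_cols(tibble(sample = fractions$sample), as_tibble(calls))
  class(out) <- c("cnasd_calls", class(out))
  attr(out, "thresholds") <- thr
  out
}

# fraction*100 >= threshold with a tolerance for binary-decimal rounding
sweep_ge <- function(frac_mat, thr_by_col) {
  t_mat <- matrix(thr_by_col[colnames(frac_mat)], nrow = nrow(frac_mat),
                  ncol = ncol(frac_mat), byrow = TRUE)
  (frac_mat * 100 >= t_mat - 1e-9) * 1L
}

#' Per-sample CNA burden
#'
#' Burden is the number of CNA features called present in a sample at the
#' supplied thresholds (typically per-feature optimal size thresholds), a
#' proxy for aneuploidy.
#'
#' @param calls A `cnasd_calls` tibble.
#' @return Tibble with `sample` and integer `burden`.
#' @export
cna_burden <- function(calls) {
  m <- as.matrix(calls[setdiff(names(calls), "sample")])
  tibble(sample = calls$sample, burden = as.integer(rowSums(m)))
}

#' Sensitivity of the threshold sweep to intensity cutoffs
#'
#' Re-runs the fraction computation and per-feature threshold sweep over a
#' grid of loss/gain intensity cutoff pairs (0.05-step grids bracketing the
#' defaults) and reports each feature's maximum AUC per cutoff pair, to
#' check whether any alternative intensity definition of loss/gain improves
#' prognostic value materially.
#'
#' @param segments Validated segments.
#' @param arms Arm table.
#' @param time,event Survival endpoint aligned with the fraction rows.
#' @param loss_grid,gain_grid Numeric cutoff grids (losses negative, gains
#'   positive). Defaults bracket -0.1 and 0.15 in 0.05 steps.
#' @param horizon ROC horizon in years.
#' @param step Sweep threshold step in percent.
#' @param margin Improvement margin: the result is flagged when any
#'   non-default cutoff pair beats the default pair's max AUC by more than
#'   this much for some feature.
#' @param grid_step Grid spacing in bp for fractions.
#' @return Tibble `loss_cutoff`, `gain_cutoff`, `feature`, `max_auc` with
#'   attribute `improved` (logical flag) and `margin`.
#' @export
intensity_sensitivity <- function(segments, arms, time, event,
                                  loss_grid = seq(-0.25, -0.05, by = 0.05),
                                  gain_grid = seq(0.05, 0.25, by = 0.05),
                                  horizon = 5, step = 1, margin = 0.02,
                                  grid_step = 30000) {
  if (length(loss_grid) == 1 && length(gain_grid) == 1) {
    warn("Degenerate intensity grid (single cutoff pair); sensitivity is trivial.")
  }
  pairs <- expand.grid(loss = loss_grid, gain = gain_grid)
  res <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    co <- intensity_cutoffs(pairs$loss[i], pairs$gain[i])
    fr <- arm_fractions(segments, arms, cutoffs = co, grid_step = grid_step)
    sw <- cna_sweep(fr, time = time, event = event, horizon = horizon, step = step)
    tibble(loss_cutoff = pairs$loss[i], gain_cutoff = pairs$gain[i],
           feature = sw$feature, max_auc = sw$max_auc)
  })
  base <- filter(res, .data$loss_cutoff == -0.1, .data$gain_cutoff == 0.15)
  improved <- FALSE
  if (nrow(base) > 0) {
    cmp <- left_join(res, select(base, "feature", base_auc = "max_auc"), by = "feature")
    cmp <- filter(cmp, !(.data$loss_cutoff == -0.1 & .data$gain_cutoff == 0.15))
    improved <- any(cmp$max_auc - cmp$base_auc > margin, na.rm = TRUE)
  }
  attr(res, "improved") <- improved
  attr(res, "margin") <- margin
  res
}
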