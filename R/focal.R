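#' Sliding-window bin grid over chromosome arms
#'
#' Tiles every included arm with contiguous bins of fixed width (200 kb by
#' default, roughly the size of the HLA locus); the last bin of an arm may
#' be shorter.
#'
#' @param arms A `cnasd_arms` tibble.
#' @param width Bin width in bp.
#' @return Tibble with `bin_id`, `chrom`, `arm`, `feature_arm`, `start`,
#'   `end`; class `cnasd_bingrid`.
#' @export
bin_grid <- function(arms, width = 200000) {
  inc <- arms[arms$included, , drop = FALSE]
  rows <- purrr::map(seq_len(nrow(inc)), function(i) {
    starts <- seq(inc$start[i], inc$end[i] - 1, by = width)
    tibble(chrom = inc$chrom[i], arm = inc$arm[i], feature_arm = inc$feature_arm[i],
           start = starts, end = pmin(starts + width, inc$end[i]))
  })
  out <- bind_rows(rows)
  out <- mutate(out, bin_id = row_number(), .before = 1)
  attr(out, "width") <- width
  class(out) <- c("cnasd_bingrid", class(out))
  out
}

#' Weighted bin intensities and bin-level CNA calls
#'
#' For every sample and bin, computes the weighted mean of the mean
#' intensities of all segments overlapping the bin. Each overlapping
#' segment's weight is the overlap length multiplied by the segment's probe
#' density (probes per bp), i.e. the estimated number of probes falling
#' inside the overlap -- honouring both the overlap-length and probe-count
#' weighting factors. Bins with no overlapping segment are missing. Binary
#' loss/gain calls are then made from the weighted means with the standard
#' intensity cutoffs; missing bins are treated as unaltered in the call
#' matrices.
#'
#' @param segments Validated `cnasd_segments`.
#' @param grid A [bin_grid()] tibble.
#' @param cutoffs An [intensity_cutoffs()] object.
#' @param samples Optional sample universe fixing row order.
#' @return A list with class `cnasd_bintrack`: `grid`, and samples-by-bins
#'   matrices `intensity` (NA = missing), `loss`, `gain` (0/1).
#' @export
bin_intensities <- function(segments, grid, cutoffs = intensity_cutoffs(), samples = NULL) {
  stopifnot(inherits(grid, "cnasd_bingrid"))
  width <- attr(grid, "width")
  segs <- as_tibble(segments)
  if ("excluded" %in% names(segs)) segs <- filter(segs, !.data$excluded)
  if (is.null(samples)) samples <- sort(unique(segments$sample))
  if (length(samples) == 0) abort("Empty cohort: no samples in the segment table.")
  nbin <- nrow(grid)
  wsum <- matrix(0, length(samples), nbin, dimnames = list(samples, NULL))
  wtot <- matrix(0, length(samples), nbin)

  arm_info <- grid %>% group_by(.data$feature_arm) %>%
    summarise(first_bin = min(.data$bin_id), arm_start = min(.data$start),
              arm_end = max(.data$end), .groups = "drop")
  segs <- dplyr::inner_join(segs, arm_info, by = "feature_arm")
  segs <- filter(segs, .data$start < .data$arm_end, .data$end > .data$arm_start)
  if (nrow(segs) > 0) {
    s0 <- pmax(segs$start, segs$arm_start)
    e0 <- pmin(segs$end, segs$arm_end)
    first <- floor((s0 - segs$arm_start) / width)
    last <- floor((e0 - 1 - segs$arm_start) / width)
    nb <- last - first + 1L
    row_i <- rep(seq_len(nrow(segs)), nb)
    off <- unlist(lapply(nb, function(k) 0:(k - 1L)), use.names = FALSE)
    bin_id <- segs$first_bin[row_i] + first[row_i] + off
    bs <- segs$arm_start[row_i] + (first[row_i] + off) * width
    be <- pmin(bs + width, segs$arm_end[row_i])
    ov <- pmin(segs$end[row_i], be) - pmax(segs$start[row_i], bs)
    dens <- segs$n_probes[row_i] / (segs$end[row_i] - segs$start[row_i])
    w <- ov * dens
    samp_i <- match(segs$sample[row_i], samples)
    flat <- (bin_id - 1L) * length(samples) + samp_i
    wsum_v <- rowsum(w * segs$seg_mean[row_i], flat)
    wtot_v <- rowsum(w, flat)
    idx <- as.integer(rownames(wsum_v))
    wsum[idx] <- wsum_v
    wtot[idx] <- wtot_v
  }
  intensity <- wsum / wtot
  intensity[wtot == 0] <- NA_real_
  loss <- (!is.na(intensity) & intensity < cutoffs$loss) * 1L
  gain <- (!is.na(intensity) & intensity > cutoffs$gain) * 1L
  structure(list(grid = grid, intensity = intensity, loss = loss, gain = gain,
                 samples = samples, cutoffs = cutoffs),
            class = "cnasd_bintrack")
}

#' @export
print.cnasd_bintrack <- function(x, ...) {
  cat(sprintf("Bin track: %d samples x %d bins (%d kb), %.1f%% bins covered\n",
              length(x$samples), nrow(x$grid), attr(x$grid, "width") / 1000,
              100 * mean(!is.na(x$intensity))))
  invisible(x)
}

#' Per-bin prognostic AUC profile
#'
#' Scores each bin's binary loss (or gain) call with the time-dependent
#' ROC AUC at the horizon. Bins where the call is constant across samples
#' (never or always altered) are undefined and excluded from downstream
#' arm medians.
#'
#' @param bintrack A [bin_intensities()] result.
#' @param time,event Survival endpoint aligned with `bintrack$samples`.
#' @param direction `"loss"` or `"gain"`.
#' @param horizon ROC horizon in years.
#' @return Tibble: the bin grid plus `direction`, `prevalence`, `auc`
#'   (NA where undefined); class `cnasd_bin_auc`.
#' @export
bin_auc_profile <- function(bintrack, time, event, direction = c("loss", "gain"),
                            horizon = 5) {
  direction <- match.arg(direction)
  calls <- bintrack[[direction]]
  stopifnot(nrow(calls) == length(time))
  ps <- surv_presort(time, event)
  n_cases <- sum(event == 1 & time <= horizon)
  n_controls <- sum(time > horizon)
  auc <- rep(NA_real_, ncol(calls))
  if (n_cases > 0 && n_controls > 0) {
    denoms <- td_denoms(ps, horizon)
    for (j in seq_len(ncol(calls))) {
      auc[j] <- td_auc_binary(calls[, j] == 1, ps, horizon, denoms)
    }
  }
  out <- mutate(as_tibble(bintrack$grid), direction = direction,
                prevalence = colMeans(calls), auc = auc)
  class(out) <- c("cnasd_bin_auc", class(out))
  attr(out, "horizon") <- horizon
  out
}

#' Focal prognostic regions from a bin AUC profile
#'
#' On each arm, finds maximal runs of contiguous defined bins whose AUC is
#' at least `margin` (default 0.04) above the median of that arm's defined
#' per-bin AUCs. The margin approximates the AUC peak height of a known
#' focal prognostic deletion (the CDKN2A/B locus); the arm median is taken
#' over defined bin AUCs so the criterion is self-contained per track. An
#' undefined bin terminates a run. Arms with fewer than 3 defined bins are
#' skipped with a warning.
#'
#' @param profile A [bin_auc_profile()] tibble.
#' @param margin AUC excess over the arm median required (inclusive).
#' @return Tibble of regions: `feature_arm`, `chrom`, `direction`, `start`,
#'   `end` (0-based half-open), `n_bins`, `peak_auc`, `median_auc`.
#' @export
focal_regions <- function(profile, margin = 0.04) {
  eps <- 1e-12
  res <- profile %>%
    group_by(.data$feature_arm) %>%
    dplyr::group_map(function(df, key) {
      def <- !is.na(df$auc)
      if (sum(def) == 0) return(NULL)
      if (sum(def) < 3) {
        warn(sprintf("Arm %s has fewer than 3 defined bins; skipped.", key$feature_arm))
        return(NULL)
      }
      med <- median(df$auc[def])
      hit <- def & df$auc >= med + margin - eps
      if (!any(hit)) return(NULL)
      # runs of consecutive bin_ids with hit
      nb <- nrow(df)
      starts_new <- hit & c(TRUE, !hit[-nb] | diff(df$bin_id) != 1)
      run_id <- cumsum(starts_new)
      runs <- split(which(hit), run_id[hit])
      purrr::map_dfr(runs, function(ix) {
        tibble(feature_arm = key$feature_arm, chrom = df$chrom[ix[1]],
               direction = df$direction[ix[1]],
               start = df$start[ix[1]], end = df$end[ix[length(ix)]],
               n_bins = length(ix), peak_auc = max(df$auc[ix]), median_auc = med)
      })
    }) %>% bind_rows()
  if (nrow(res) == 0) {
    res <- tibble(feature_arm = character(), chrom = character(), direction = character(),
                  start = double(), end = double(), n_bins = integer(),
                  peak_auc = double(), median_auc = double())
  }
  attr(res, "margin") <- margin
  res
}

#' Pileup proportion profiles
#'
#' Proportion of samples with a loss (resp. gain) call in each bin; bins
#' missing in a sample count as unaltered, so proportions are cohort-wide
#' statements.
#'
#' @param bintrack A [bin_intensities()] result.
#' @return The bin grid plus `prop_loss`, `prop_gain`.
#' @export
cna_pileup <- function(bintrack) {
  if (length(bintrack$samples) == 0) abort("Empty cohort: no samples in the bin track.")
  mutate(as_tibble(bintrack$grid),
         prop_loss = colMeans(bintrack$loss),
         prop_gain = colMeans(bintrack$gain))
}

#' Write a 4-column bedGraph track
#' @param df Tibble with `chrom`, `start`, `end` and the value column.
#' @param value Name of the value column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(df, value, path) {
  out <- data.frame(chrom = paste0("chr", df$chrom),
                    start = format(df$start, scientific = FALSE, trim = TRUE),
                    end = format(df$end, scientific = FALSE, trim = TRUE),
                    value = signif(df[[value]], 6))
  out <- out[!is.na(df[[value]]), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write focal regions as BED (0-based half-open)
#' @param regions A [focal_regions()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  out <- data.frame(chrom = paste0("chr", regions$chrom),
                    start = format(regions$start, scientific = FALSE, trim = TRUE),
                    end = format(regions$end, scientific = FALSE, trim = TRUE),
                    name = paste0(regions$feature_arm, "_", regions$direction),
                    score = round(1000 * regions$peak_auc))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
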