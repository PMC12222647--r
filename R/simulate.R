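#' Simulation configuration for synthetic CNA cohorts
#'
#' Defines the generative model for a synthetic cohort: per-sample segment
#' profiles with a realistic size mixture (focal kb-Mb events and broad
#' arm-level events), Gaussian intensity levels around the loss/gain/neutral
#' means, probe counts from a uniform probe density, and survival times from
#' a Weibull proportional-hazards model with independent uniform censoring.
#' Prognostic structure is planted explicitly: arm-level effects active only
#' when the true altered fraction reaches an activation fraction,
#' focal-locus effects, pair co-occurrence interactions, and a linear
#' burden effect.
#'
#' @param n Number of samples.
#' @param arms Arm table (default [arm_table_toy()]; use
#'   [arm_table_hg38like()] for genome-scale coordinates).
#' @param alt_prob Background alteration probability per (arm, direction)
#'   feature.
#' @param p_focal Probability that a background alteration is focal rather
#'   than broad.
#' @param focal_width_range Focal event width range in bp (default 0.2-5 Mb).
#' @param broad_beta Beta parameters for the broad-event fraction of arm.
#' @param broad_anchor `"distal"` (anchored at the telomeric end, the
#'   default) or `"random"` placement of broad events.
#' @param loss_mean,gain_mean,alt_sd Intensity model for altered segments.
#' @param neutral_sd Intensity SD of neutral segments (mean 0).
#' @param neutral_chunk_mb Neutral filler is emitted in chunks of at most
#'   this many Mb, emulating segmentation of unaltered regions.
#' @param probe_per_10kb Probe density (probes per 10 kb).
#' @param arm_effects Tibble/data frame of planted size-dependent effects:
#'   columns `feature` ("5p_loss"), `activation` (fraction of arm at which
#'   the hazard effect switches on), `log_hr`, `carrier_prob` (probability
#'   a sample carries a super-threshold alteration), `sub_prob`
#'   (probability of a sub-threshold alteration instead).
#' @param focal_effects Tibble of planted focal effects: `feature_arm`,
#'   `direction`, `center` (bp), `width` (bp), `log_hr`, `prevalence`.
#' @param pair_effects Tibble of co-occurrence interactions: `feature_a`,
#'   `feature_b`, `log_hr` (extra log hazard when both are active).
#' @param burden_coef Linear log-hazard per unit of true burden (count of
#'   features with true fraction >= 0.25).
#' @param shape,scale Named length-2 vectors (`rec`, `os`) of Weibull
#'   baseline shape and scale (years).
#' @param censor_max Upper bound of the uniform censoring distribution
#'   (years).
#' @param seed Mandatory RNG seed.
#' @return A list with class `cnasd_sim_config`.
#' @export
sim_config <- function(n = 400, arms = arm_table_toy(), alt_prob = 0.08,
                       p_focal = 0.3, focal_width_range = c(2e5, 5e6),
                       broad_beta = c(1.2, 1.2), broad_anchor = c("distal", "random"),
                       loss_mean = -0.45, gain_mean = 0.3, alt_sd = 0.1,
                       neutral_sd = 0.05, neutral_chunk_mb = 8, probe_per_10kb = 1,
                       arm_effects = NULL, focal_effects = NULL, pair_effects = NULL,
                       burden_coef = 0,
                       shape = c(rec = 1, os = 1), scale = c(rec = 14, os = 18),
                       censor_max = 12, seed) {
  if (missing(seed)) abort("`seed` is mandatory for reproducible cohorts.")
  broad_anchor <- match.arg(broad_anchor)
  cfg <- list(n = n, arms = arms, alt_prob = alt_prob, p_focal = p_focal,
              focal_width_range = focal_width_range, broad_beta = broad_beta,
              broad_anchor = broad_anchor, loss_mean = loss_mean,
              gain_mean = gain_mean, alt_sd = alt_sd, neutral_sd = neutral_sd,
              neutral_chunk_mb = neutral_chunk_mb, probe_per_10kb = probe_per_10kb,
              arm_effects = if (!is.null(arm_effects)) as_tibble(arm_effects),
              focal_effects = if (!is.null(focal_effects)) as_tibble(focal_effects),
              pair_effects = if (!is.null(pair_effects)) as_tibble(pair_effects),
              burden_coef = burden_coef, shape = shape, scale = scale,
              censor_max = censor_max, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "cnasd_sim_config")
}

validate_sim_config <- function(cfg) {
  inc <- cfg$arms[cfg$arms$included, ]
  feats <- feature_names_for(cfg$arms)
  if (!is.null(cfg$arm_effects)) {
    ae <- cfg$arm_effects
    need <- c("feature", "activation", "log_hr", "carrier_prob")
    miss <- setdiff(need, names(ae))
    if (length(miss)) abort(sprintf("arm_effects missing column(s): %s", paste(miss, collapse = ", ")))
    bad <- setdiff(ae$feature, feats)
    if (length(bad)) abort(sprintf("arm_effects on unknown feature(s): %s", paste(bad, collapse = ", ")))
    if (any(ae$activation <= 0 | ae$activation >= 1)) abort("activation must be in (0,1).")
    if (any(ae$carrier_prob < 0 | ae$carrier_prob > 1)) abort("carrier_prob must be in [0,1].")
  }
  if (!is.null(cfg$focal_effects)) {
    fe <- cfg$focal_effects
    need <- c("feature_arm", "direction", "center", "width", "log_hr", "prevalence")
    miss <- setdiff(need, names(fe))
    if (length(miss)) abort(sprintf("focal_effects missing column(s): %s", paste(miss, collapse = ", ")))
    for (i in seq_len(nrow(fe))) {
      a <- inc[inc$feature_arm == fe$feature_arm[i], ]
      if (nrow(a) == 0) abort(sprintf("focal effect on unknown/excluded arm %s", fe$feature_arm[i]))
      if (fe$width[i] >= a$end - a$start) abort("focal width must be smaller than the arm.")
      if (fe$center[i] - fe$width[i] / 2 < a$start || fe$center[i] + fe$width[i] / 2 > a$end) {
        abort(sprintf("focal locus on %s extends beyond the arm.", fe$feature_arm[i]))
      }
      if (fe$prevalence[i] < 0 || fe$prevalence[i] > 1) abort("focal prevalence must be in [0,1].")
    }
  }
  if (!is.null(cfg$pair_effects)) {
    pe <- cfg$pair_effects
    bad <- setdiff(c(pe$feature_a, pe$feature_b), feats)
    if (length(bad)) abort(sprintf("pair_effects on unknown feature(s): %s", paste(bad, collapse = ", ")))
  }
  invisible(cfg)
}

# subtract intervals `sub` (2-col matrix) from interval [s, e); returns matrix
interval_subtract <- function(s, e, sub) {
  if (is.null(sub) || nrow(sub) == 0) return(cbind(s, e))
  sub <- sub[order(sub[, 1]), , drop = FALSE]
  out <- NULL
  cur <- s
  for (i in seq_len(nrow(sub))) {
    a <- max(sub[i, 1], s); b <- min(sub[i, 2], e)
    if (a >= b) next
    if (a > cur) out <- rbind(out, c(cur, a))
    cur <- max(cur, b)
  }
  if (cur < e) out <- rbind(out, c(cur, e))
  if (is.null(out)) matrix(numeric(0), ncol = 2) else out
}

#' Simulate a synthetic cohort
#'
#' Draws a cohort from a [sim_config()]: per-sample altered intervals per
#' the size mixture and planted effects, neutral filler segments, noisy
#' intensities and probe counts, and two survival endpoints from the
#' Weibull proportional-hazards model with the true linear predictor
#' assembled from the planted arm, focal, pair and burden effects
#' (arm effects are active iff the true altered fraction reaches the
#' activation fraction; pair effects iff both members are active; focal
#' effects iff the locus is deleted). Fully reproducible from the seed.
#'
#' @param config A [sim_config()] object.
#' @return A list with class `cnasd_cohort`: `segments` (validated
#'   `cnasd_segments`), `clinical` (tibble sample/time_rec/event_rec/
#'   time_os/event_os), `truth` (list: `fractions` true altered fraction
#'   matrix, `active` indicator matrix, `lp` linear predictors, `burden`
#'   true burden, `config`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cnasd_sim_config"))
  cfg <- config
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed(cfg$seed)

  inc <- cfg$arms[cfg$arms$included, ]
  feats <- feature_names_for(cfg$arms)
  finfo <- parse_feature(feats)
  finfo <- left_join(finfo, select(inc, "feature_arm", arm_start = "start", arm_end = "end"),
                     by = "feature_arm")
  planted_feats <- if (!is.null(cfg$arm_effects)) cfg$arm_effects$feature else character(0)
  focal_key <- if (!is.null(cfg$focal_effects)) {
    paste0(cfg$focal_effects$feature_arm, "_", cfg$focal_effects$direction)
  } else character(0)

  ids <- sprintf("S%04d", seq_len(cfg$n))
  frac_true <- matrix(0, cfg$n, length(feats), dimnames = list(ids, feats))
  focal_hit <- matrix(0, cfg$n, length(focal_key), dimnames = list(ids, focal_key))
  seg_acc <- vector("list", cfg$n)

  for (si in seq_len(cfg$n)) {
    # per-feature altered interval lists for this sample
    iv <- setNames(vector("list", length(feats)), feats)
    for (fi in seq_len(nrow(finfo))) {
      f <- finfo$feature[fi]
      a0 <- finfo$arm_start[fi]; a1 <- finfo$arm_end[fi]; alen <- a1 - a0
      # telomeric end: arm "p" -> chromosome start side; arm "q" -> end side
      is_p <- grepl("p$", finfo$feature_arm[fi])
      if (f %in% planted_feats) {
        ae <- cfg$arm_effects[cfg$arm_effects$feature == f, ][1, ]
        sub_p <- if ("sub_prob" %in% names(ae)) ae$sub_prob else 0
        if (is.na(sub_p)) sub_p <- 0
        u <- runif(1)
        fr <- if (u < ae$carrier_prob) {
          runif(1, ae$activation, 0.9)
        } else if (u < ae$carrier_prob + sub_p) {
          runif(1, 0.05, ae$activation * 0.95)
        } else 0
        if (fr > 0) {
          w <- fr * alen
          iv[[f]] <- if (cfg$broad_anchor == "distal") {
            if (is_p) cbind(a0, a0 + w) else cbind(a1 - w, a1)
          } else {
            s <- a0 + runif(1) * (alen - w); cbind(s, s + w)
          }
        }
      } else if (runif(1) < cfg$alt_prob) {
        if (runif(1) < cfg$p_focal) {
          w <- runif(1, cfg$focal_width_range[1], min(cfg$focal_width_range[2], alen / 2))
          s <- a0 + runif(1) * (alen - w)
          iv[[f]] <- cbind(s, s + w)
        } else {
          fr <- pmin(pmax(stats::rbeta(1, cfg$broad_beta[1], cfg$broad_beta[2]), 0.02), 0.95)
          w <- fr * alen
          iv[[f]] <- if (cfg$broad_anchor == "distal") {
            if (is_p) cbind(a0, a0 + w) else cbind(a1 - w, a1)
          } else {
            s <- a0 + runif(1) * (alen - w); cbind(s, s + w)
          }
        }
      }
    }
    # planted focal loci
    if (length(focal_key)) {
      for (k in seq_along(focal_key)) {
        fe <- cfg$focal_effects[k, ]
        if (runif(1) < fe$prevalence) {
          f <- focal_key[k]
          locus <- cbind(fe$center - fe$width / 2, fe$center + fe$width / 2)
          iv[[f]] <- rbind(iv[[f]], locus)
          focal_hit[si, k] <- 1
        }
      }
    }
    # resolve loss/gain collisions per arm (loss wins) and merge intervals
    segs_s <- vector("list", length(feats))
    for (fi in seq_len(nrow(finfo))) {
      f <- finfo$feature[fi]
      m <- iv[[f]]
      if (is.null(m) || nrow(m) == 0) next
      m <- merge_intervals(m)
      if (finfo$direction[fi] == "gain") {
        loss_f <- paste0(finfo$feature_arm[fi], "_loss")
        lm_ <- iv[[loss_f]]
        if (!is.null(lm_) && nrow(lm_) > 0) {
          pieces <- NULL
          for (r in seq_len(nrow(m))) {
            pieces <- rbind(pieces, interval_subtract(m[r, 1], m[r, 2], merge_intervals(lm_)))
          }
          m <- if (is.null(pieces)) matrix(numeric(0), ncol = 2) else pieces
        }
      }
      iv[[f]] <- m
      if (nrow(m) > 0) {
        alen <- finfo$arm_end[fi] - finfo$arm_start[fi]
        frac_true[si, f] <- sum(m[, 2] - m[, 1]) / alen
      }
    }
    seg_acc[[si]] <- emit_sample_segments(ids[si], iv, finfo, cfg)
  }

  segments <- bind_rows(seg_acc)
  class(segments) <- c("cnasd_segments", class(segments))
  segments <- validate_segments(segments, cfg$arms)

  # true linear predictor
  lp <- rep(0, cfg$n)
  active <- matrix(0, cfg$n, length(feats), dimnames = list(ids, feats))
  default_act <- 0.25
  act_of <- setNames(rep(default_act, length(feats)), feats)
  if (!is.null(cfg$arm_effects)) {
    act_of[cfg$arm_effects$feature] <- cfg$arm_effects$activation
  }
  for (f in feats) active[, f] <- as.numeric(frac_true[, f] >= act_of[f] - 1e-12)
  if (!is.null(cfg$arm_effects)) {
    for (i in seq_len(nrow(cfg$arm_effects))) {
      ae <- cfg$arm_effects[i, ]
      lp <- lp + ae$log_hr * active[, ae$feature]
    }
  }
  if (length(focal_key)) {
    for (k in seq_along(focal_key)) lp <- lp + cfg$focal_effects$log_hr[k] * focal_hit[, k]
  }
  if (!is.null(cfg$pair_effects)) {
    for (i in seq_len(nrow(cfg$pair_effects))) {
      pe <- cfg$pair_effects[i, ]
      lp <- lp + pe$log_hr * active[, pe$feature_a] * active[, pe$feature_b]
    }
  }
  burden_true <- rowSums(frac_true >= 0.25)
  lp <- lp + cfg$burden_coef * burden_true

  draw_endpoint <- function(shape, scale) {
    t_ev <- scale * (-log(runif(cfg$n)) / exp(lp))^(1 / shape)
    cens <- runif(cfg$n, 0, cfg$censor_max)
    list(time = pmax(pmin(t_ev, cens), 1e-6), event = as.numeric(t_ev <= cens))
  }
  rec <- draw_endpoint(cfg$shape[["rec"]], cfg$scale[["rec"]])
  os <- draw_endpoint(cfg$shape[["os"]], cfg$scale[["os"]])
  clinical <- tibble(sample = ids, time_rec = rec$time, event_rec = rec$event,
                     time_os = os$time, event_os = os$event)
  class(clinical) <- c("cnasd_clinical", class(clinical))

  structure(list(segments = segments, clinical = clinical,
                 truth = list(fractions = frac_true, active = active,
                              focal_hit = focal_hit, lp = lp,
                              burden = burden_true, config = cfg)),
            class = "cnasd_cohort")
}

merge_intervals <- function(m) {
  if (nrow(m) <= 1) return(m)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (i in 2:nrow(m)) {
    if (m[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], m[i, 2])
    } else out <- rbind(out, m[i, ])
  }
  out
}

emit_sample_segments <- function(id, iv, finfo, cfg) {
  rows <- list(); chrom_acc <- list(); ri <- 0
  push <- function(chrom, s, e, mean_) {
    ri <<- ri + 1
    np <- max(1, round((e - s) * cfg$probe_per_10kb / 1e4))
    rows[[ri]] <<- c(s, e, np, mean_)
    chrom_acc[[ri]] <<- chrom
  }
  arms_u <- distinct(finfo[, c("feature_arm", "arm_start", "arm_end")])
  chrom_of <- sub("[pq]$", "", arms_u$feature_arm)
  chunk <- cfg$neutral_chunk_mb * 1e6
  for (ai in seq_len(nrow(arms_u))) {
    fa <- arms_u$feature_arm[ai]
    a0 <- arms_u$arm_start[ai]; a1 <- arms_u$arm_end[ai]
    alt <- NULL
    for (d in c("loss", "gain")) {
      m <- iv[[paste0(fa, "_", d)]]
      if (!is.null(m) && nrow(m) > 0) {
        lv <- if (d == "loss") cfg$loss_mean else cfg$gain_mean
        for (r in seq_len(nrow(m))) {
          push(chrom_of[ai], m[r, 1], m[r, 2], rnorm(1, lv, cfg$alt_sd))
        }
        alt <- rbind(alt, m)
      }
    }
    gaps <- interval_subtract(a0, a1, alt)
    if (nrow(gaps) > 0) {
      for (r in seq_len(nrow(gaps))) {
        len <- gaps[r, 2] - gaps[r, 1]
        k <- max(1, ceiling(len / chunk))
        bnd <- gaps[r, 1] + len * (0:k) / k
        for (j in seq_len(k)) {
          push(chrom_of[ai], bnd[j], bnd[j + 1], rnorm(1, 0, cfg$neutral_sd))
        }
      }
    }
  }
  mat <- do.call(rbind, rows[seq_len(ri)])
  tibble(sample = id, chrom = unlist(chrom_acc[seq_len(ri)]),
         start = round(mat[, 1]), end = round(mat[, 2]),
         n_probes = mat[, 3], seg_mean = mat[, 4])
}

#' Write a simulated cohort to disk
#'
#' Emits the SEG file, clinical CSV and a JSON truth ledger.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seg <- file.path(dir, "cohort.seg")
  cli <- file.path(dir, "clinical.csv")
  tru <- file.path(dir, "truth.json")
  write_seg(cohort$segments, seg)
  utils::write.csv(as.data.frame(cohort$clinical), cli, row.names = FALSE, quote = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(list(
    lp = round(unname(truth$lp), 10), burden = unname(truth$burden),
    active = as.data.frame(truth$active), seed = truth$config$seed
  ), tru, auto_unbox = TRUE, digits = NA)
  invisible(c(seg = seg, clinical = cli, truth = tru))
}

#' Recovery metrics of the pipeline against simulation truth
#'
#' Compares pipeline outputs with the planted ground truth of a simulated
#' cohort: optimal-threshold recovery error for each planted arm effect,
#' sensitivity/specificity of the size-dependence flags, focal localization
#' error, and pair-selection sensitivity. Sections whose outputs are not
#' supplied are skipped.
#'
#' @param cohort A `cnasd_cohort`.
#' @param flags Output of [size_dependent_features()] (optional).
#' @param focal_profile Output of [bin_auc_profile()] (optional).
#' @param selected_pairs Character vector of selected tuple names (optional).
#' @return Tibble of `metric`, `feature`, `value`.
#' @export
truth_recovery_report <- function(cohort, flags = NULL, focal_profile = NULL,
                                  selected_pairs = NULL) {
  cfg <- cohort$truth$config
  if (is.null(flags) && is.null(focal_profile) && is.null(selected_pairs)) {
    abort("No pipeline outputs supplied.")
  }
  out <- list()
  if (!is.null(flags) && !is.null(cfg$arm_effects)) {
    planted <- cfg$arm_effects$feature
    per_feat <- flags %>% distinct(.data$feature, .data$size_dependent)
    for (i in seq_len(nrow(cfg$arm_effects))) {
      f <- planted[i]
      frow <- filter(flags, .data$feature == f)
      err <- suppressWarnings(min(abs(frow$opt_threshold - 100 * cfg$arm_effects$activation[i]),
                                  na.rm = TRUE))
      out[[length(out) + 1]] <- tibble(metric = "threshold_error_pct", feature = f,
                                       value = ifelse(is.finite(err), err, NA_real_))
    }
    sens <- mean(per_feat$size_dependent[per_feat$feature %in% planted])
    spec <- mean(!per_feat$size_dependent[!per_feat$feature %in% planted])
    out[[length(out) + 1]] <- tibble(metric = c("sd_flag_sensitivity", "sd_flag_specificity"),
                                     feature = NA_character_, value = c(sens, spec))
  } else if (!is.null(flags)) {
    per_feat <- flags %>% distinct(.data$feature, .data$size_dependent)
    out[[length(out) + 1]] <- tibble(metric = "sd_false_flag_rate", feature = NA_character_,
                                     value = mean(per_feat$size_dependent))
  }
  if (!is.null(focal_profile) && !is.null(cfg$focal_effects)) {
    for (k in seq_len(nrow(cfg$focal_effects))) {
      fe <- cfg$focal_effects[k, ]
      prof <- filter(focal_profile, .data$feature_arm == fe$feature_arm,
                     .data$direction == fe$direction, !is.na(.data$auc))
      if (nrow(prof) == 0) { val <- NA_real_ } else {
        peak <- prof[which.max(prof$auc), ]
        val <- abs((peak$start + peak$end) / 2 - fe$center)
      }
      out[[length(out) + 1]] <- tibble(metric = "focal_peak_distance_bp",
                                       feature = paste0(fe$feature_arm, "_", fe$direction),
                                       value = val)
    }
  }
  if (!is.null(selected_pairs) && !is.null(cfg$pair_effects)) {
    for (i in seq_len(nrow(cfg$pair_effects))) {
      pe <- cfg$pair_effects[i, ]
      nm1 <- paste(c(pe$feature_a, pe$feature_b), collapse = "+")
      nm2 <- paste(c(pe$feature_b, pe$feature_a), collapse = "+")
      out[[length(out) + 1]] <- tibble(metric = "pair_selected",
                                       feature = nm1,
                                       value = as.numeric(any(c(nm1, nm2) %in% selected_pairs)))
    }
  }
  bind_rows(out)
}
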