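# Independent oracles and small fixture builders used across the suite.

# Per-base brute force: fraction of the arm covered by segments whose mean
# intensity passes the cutoff (interval arithmetic, no grid).
oracle_arm_fraction <- function(segs, arm_start, arm_end, cutoff, direction) {
  hit <- if (direction == "loss") segs$seg_mean < cutoff else segs$seg_mean > cutoff
  segs <- segs[hit, , drop = FALSE]
  if (nrow(segs) == 0) return(0)
  ov <- pmin(segs$end, arm_end) - pmax(segs$start, arm_start)
  sum(pmax(ov, 0)) / (arm_end - arm_start)
}

# Direct-formula KM-estimator td-AUC using survival::survfit for every
# conditional KM curve (independent of the package's internal KM).
oracle_td_auc <- function(marker, time, event, horizon) {
  km_surv <- function(keep) {
    if (!any(keep)) return(1)
    sf <- survival::survfit(survival::Surv(time[keep], event[keep]) ~ 1)
    summary(sf, times = horizon, extend = TRUE)$surv
  }
  S <- km_surv(rep(TRUE, length(time)))
  cuts <- sort(unique(marker), decreasing = TRUE)
  tpr <- fpr <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    pos <- marker >= cuts[i]
    p <- mean(pos)
    sens <- p * (1 - km_surv(pos)) / (1 - S)
    spec <- (1 - p) * km_surv(!pos) / S
    tpr[i] <- min(max(sens, 0), 1)
    fpr[i] <- 1 - min(max(spec, 0), 1)
  }
  f <- c(0, fpr); t <- c(0, tpr)
  sum(diff(f) * (head(t, -1) + tail(t, -1)) / 2)
}

# Empirical Mann-Whitney concordance of a marker against a binary case
# status, ties counting one half.
oracle_concordance <- function(marker, case) {
  pos <- marker[case == 1]; neg <- marker[case == 0]
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

# Hand-coded Cox log partial likelihood for untied data, one covariate.
oracle_log_pl <- function(beta, x, time, event) {
  eta <- x * beta
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

# One-row arm helper and a segments tibble builder on a single toy arm.
one_arm <- function(len = 3e6, chrom = "1") {
  tibble::tibble(chrom = chrom, arm = "q", feature_arm = paste0(chrom, "q"),
                 start = 0, end = len, included = TRUE)
}

make_segs <- function(starts, ends, means, chrom = "1", sample = "S1",
                      probes = NULL) {
  if (is.null(probes)) probes <- pmax(1, round((ends - starts) / 1e4))
  tibble::tibble(sample = sample, chrom = chrom, start = starts, end = ends,
                 n_probes = probes, seg_mean = means)
}

write_tcga_seg <- function(df, path = tempfile(fileext = ".seg")) {
  out <- data.frame(ID = df$sample, chrom = df$chrom, loc.start = df$start,
                    loc.end = df$end, num.mark = df$n_probes, seg.mean = df$seg_mean)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Weibull-PH survival draw used by unit-level simulations in the tests.
draw_surv <- function(lp, shape = 1, scale = 14, censor_max = 12) {
  n <- length(lp)
  t_ev <- scale * (-log(runif(n)) / exp(lp))^(1 / shape)
  cens <- runif(n, 0, censor_max)
  list(time = pmin(t_ev, cens), event = as.numeric(t_ev <= cens))
}
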