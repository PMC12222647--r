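#' Co-occurrent CNA tuple features
#'
#' Builds indicator features for all unordered pairs (or triplets) of CNA
#' features that include at least one size-dependent member. A sample's
#' tuple indicator is 1 iff all member CNAs are called present at their
#' (per-feature optimal) thresholds, i.e. the product of the member calls.
#' Tuples below the minimum prevalence are dropped; the 2.5% default reuses
#' the single-CNA rarity cutoff.
#'
#' @param calls A `cnasd_calls` tibble at per-feature optimal thresholds.
#' @param size_dependent Character vector of size-dependent feature names.
#' @param order 2 (pairs, default) or 3 (triplets).
#' @param min_prevalence Minimum tuple prevalence (default 0.025).
#' @return A list with class `cnasd_tuples`: `features` (tibble `tuple`,
#'   `members` list-column, `prevalence`, `n_size_dependent`) and
#'   `indicator` (samples x tuples 0/1 matrix with `sample` rownames).
#' @export
tuple_features <- function(calls, size_dependent, order = 2, min_prevalence = 0.025) {
  stopifnot(order %in% c(2, 3))
  feats <- setdiff(names(calls), "sample")
  m <- as.matrix(calls[feats])
  rownames(m) <- calls$sample
  size_dependent <- intersect(size_dependent, feats)
  if (length(size_dependent) == 0) {
    warn("No size-dependent features among the calls; returning an empty tuple set.")
    return(structure(list(features = tibble(tuple = character(), members = list(),
                                            prevalence = double(),
                                            n_size_dependent = integer()),
                          indicator = matrix(0, nrow(m), 0,
                                             dimnames = list(rownames(m), NULL))),
                     class = "cnasd_tuples"))
  }
  combos <- combn(feats, order, simplify = FALSE)
  combos <- purrr::keep(combos, ~ any(.x %in% size_dependent))
  ind <- vapply(combos, function(mem) {
    as.numeric(rowSums(m[, mem, drop = FALSE]) == length(mem))   # product of calls
  }, numeric(nrow(m)))
  if (is.null(dim(ind))) ind <- matrix(ind, nrow = nrow(m))
  prev <- colMeans(ind)
  keep <- prev >= min_prevalence - 1e-12
  combos <- combos[keep]
  ind <- ind[, keep, drop = FALSE]
  nm <- vapply(combos, paste, character(1), collapse = "+")
  colnames(ind) <- nm
  rownames(ind) <- rownames(m)
  features <- tibble(tuple = nm, members = combos, prevalence = prev[keep],
                     n_size_dependent = vapply(combos, function(x)
                       sum(x %in% size_dependent), integer(1)))
  structure(list(features = features, indicator = ind), class = "cnasd_tuples")
}

#' @export
print.cnasd_tuples <- function(x, ...) {
  cat(sprintf("%d co-occurrence tuple(s) over %d samples\n",
              nrow(x$features), nrow(x$indicator)))
  invisible(x)
}

#' Cross-validated regularized Cox model with the 1-SE rule
#'
#' Penalized Cox regression (LASSO at `alpha = 1`, elastic net otherwise)
#' over a lambda path per alpha, scored by cross-validated concordance
#' (Harrell's C) with event-stratified, seeded fold assignment shared
#' across the alpha grid. The selected model is the sparsest one within
#' one standard error of the best cross-validated concordance: the best
#' alpha is the one achieving the maximal CV concordance, and within it
#' the largest lambda whose CV concordance is within 1 SE of that optimum.
#'
#' @param x Samples-by-features numeric matrix (e.g. tuple indicators).
#' @param time,event Survival outcome.
#' @param alphas Mixing grid; default `c(seq(0.05, 0.95, 0.05), 1)`.
#' @param nfolds Cross-validation folds (default 10).
#' @param seed Seed for fold assignment.
#' @return Object of class `cnasd_regcox`: `alpha`, `lambda`, `coef`
#'   (named, zeros included), `selected` (nonzero-coefficient feature
#'   names), `cv` (tibble alpha/lambda/cvm/cvsd), `best_cvm`, `fit`
#'   (the glmnet fit at the selected alpha).
#' @export
regularized_cox_cv <- function(x, time, event, alphas = c(seq(0.05, 0.95, by = 0.05), 1),
                               nfolds = 10, seed = NULL, ...) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n_events <- sum(event)
  if (n_events < 2 * nfolds) {
    abort(sprintf("Only %d events for %d folds; use fewer folds (need >= 2 per fold).",
                  n_events, nfolds))
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
    set.seed(seed)
  }
  # event-stratified fold assignment, shared across alphas
  foldid <- integer(length(event))
  for (g in c(0, 1)) {
    ix <- which(event == g)
    foldid[ix] <- sample(rep_len(seq_len(nfolds), length(ix)))
  }
  y <- survival::Surv(time, event)
  cvs <- lapply(alphas, function(a) {
    glmnet::cv.glmnet(x, y, family = "cox", alpha = a, foldid = foldid,
                      type.measure = "C", standardize = FALSE, ...)
  })
  cv_tbl <- bind_rows(purrr::map2(cvs, alphas, function(cv, a) {
    tibble(alpha = a, lambda = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd)
  }))
  best_per_alpha <- vapply(cvs, function(cv) max(cv$cvm), numeric(1))
  bi <- which.max(best_per_alpha)
  cv_best <- cvs[[bi]]
  j <- which.max(cv_best$cvm)
  thr <- cv_best$cvm[j] - cv_best$cvsd[j]
  lambda_1se <- max(cv_best$lambda[cv_best$cvm >= thr])
  beta <- as.numeric(coef(cv_best$glmnet.fit, s = lambda_1se))
  names(beta) <- colnames(x)
  structure(list(alpha = alphas[bi], lambda = lambda_1se, coef = beta,
                 selected = names(beta)[beta != 0], cv = cv_tbl,
                 best_cvm = cv_best$cvm[j], nfolds = nfolds, seed = seed,
                 fit = cv_best$glmnet.fit),
            class = "cnasd_regcox")
}

#' @export
print.cnasd_regcox <- function(x, ...) {
  cat(sprintf("Regularized Cox (alpha = %.2f, lambda = %.4g, 1-SE rule): %d feature(s) selected\n",
              x$alpha, x$lambda, length(x$selected)))
  if (length(x$selected)) print(round(x$coef[x$selected], 4))
  invisible(x)
}

#' Four-stratum KM analysis of a CNA pair
#'
#' Stratifies samples as neither / A only / B only / both from the member
#' calls of a pair and compares survival across the four strata with an
#' overall log-rank test, plus pairwise log-rank tests of "both" against
#' each single-CNA stratum.
#'
#' @param call_a,call_b 0/1 member calls (aligned vectors).
#' @param time,event Survival outcome.
#' @param labels Length-2 feature names used in the stratum labels.
#' @return List with class `cnasd_pairkm`: `stratum` (factor), `overall`
#'   (a `cnasd_km`), `both_vs_a`, `both_vs_b` (pairwise `cnasd_km`, NULL
#'   when a stratum is empty).
#' @export
stratified_km <- function(call_a, call_b, time, event, labels = c("A", "B")) {
  stopifnot(length(call_a) == length(call_b))
  stratum <- factor(
    case_when(call_a == 1 & call_b == 1 ~ "both",
              call_a == 1 ~ paste0(labels[1], " only"),
              call_b == 1 ~ paste0(labels[2], " only"),
              TRUE ~ "neither"),
    levels = c("neither", paste0(labels[1], " only"), paste0(labels[2], " only"), "both")
  )
  if (sum(stratum == "both") == 0) abort("The 'both' stratum is empty.")
  if (nlevels(droplevels(stratum)) < 2) abort("All samples fall in a single stratum.")
  overall <- km_logrank(stratum, time, event)
  pairwise <- function(other) {
    keep <- stratum %in% c("both", other)
    if (sum(stratum[keep] == other) == 0) return(NULL)
    km_logrank(droplevels(stratum[keep]), time[keep], event[keep])
  }
  structure(list(stratum = stratum, overall = overall,
                 both_vs_a = pairwise(paste0(labels[1], " only")),
                 both_vs_b = pairwise(paste0(labels[2], " only")),
                 time = time, event = event),
            class = "cnasd_pairkm")
}

#' @export
print.cnasd_pairkm <- function(x, ...) {
  cat("Four-stratum co-occurrence KM\n  overall: ")
  print(x$overall)
  invisible(x)
}

#' Pair effect adjusted for CNA burden
#'
#' Bivariate Cox model of a co-occurrence pair indicator together with the
#' per-sample CNA burden, testing whether the pair remains prognostic when
#' accounting for the total number of CNAs. Falls back to the univariate
#' pair model (with a warning) when burden is constant.
#'
#' @param pair 0/1 pair indicator.
#' @param burden Integer CNA burden.
#' @param time,event Survival outcome.
#' @return A list with `fit` (`cnasd_cox`) and `wald` (tibble of term,
#'   estimate, se, z, p_value).
#' @export
pair_with_burden_cox <- function(pair, burden, time, event) {
  if (length(unique(burden)) == 1) {
    warn("Burden is constant; falling back to the univariate pair model.")
    X <- cbind(pair = pair)
  } else {
    if (all(pair == burden) || all(pair == 1 - burden)) {
      abort("Pair indicator is collinear with burden (non-identifiable).")
    }
    X <- cbind(pair = pair, burden = burden)
  }
  fit <- cox_fit(X, time, event)
  z <- fit$coef / fit$se
  wald <- tibble(term = names(fit$coef), estimate = fit$coef, se = fit$se,
                 z = z, p_value = 2 * stats::pnorm(-abs(z)))
  list(fit = fit, wald = wald)
}

#' Cluster CNA features by burden-binned prevalence
#'
#' Builds a features-by-burden-bin prevalence matrix (burden bins are the
#' integer burden values, top-coded at the 95th percentile), clusters the
#' features by agglomerative hierarchical clustering (Ward linkage on
#' Euclidean distance), and picks the number of clusters in 2..6 by the
#' mean silhouette width of k-means partitions.
#'
#' @param calls A `cnasd_calls` tibble at optimal thresholds.
#' @param burden Optional burden vector aligned with `calls` rows; computed
#'   from the calls when omitted.
#' @param k_range Candidate cluster counts.
#' @return List with class `cnasd_clusters`: `prevalence` (matrix),
#'   `cluster` (named membership), `k`, `silhouette` (tibble k/width),
#'   `hclust`.
#' @export
cluster_cnas <- function(calls, burden = NULL, k_range = 2:6) {
  feats <- setdiff(names(calls), "sample")
  m <- as.matrix(calls[feats])
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (ncol(m) < 2) abort("Clustering needs at least 2 features with nonzero prevalence.")
  if (is.null(burden)) burden <- as.integer(rowSums(as.matrix(calls[feats])))
  cap <- as.numeric(quantile(burden, 0.95, type = 7))
  bin <- pmin(burden, cap)
  bins <- sort(unique(bin))
  prev <- vapply(bins, function(b) colMeans(m[bin == b, , drop = FALSE]),
                 numeric(ncol(m)))          # features x bins
  colnames(prev) <- paste0("burden_", bins)
  if (all(prev == 0)) abort("All-zero prevalence matrix; nothing to cluster.")
  hc <- hclust(dist(prev), method = "ward.D2")
  k_range <- k_range[k_range < nrow(prev)]
  if (length(k_range) == 0) k_range <- 2
  sil <- purrr::map_dfr(k_range, function(k) {
    km <- kmeans(prev, centers = k, nstart = 10)
    w <- if (requireNamespace("cluster", quietly = TRUE)) {
      mean(cluster::silhouette(km$cluster, dist(prev))[, 3])
    } else {
      -km$tot.withinss   # elbow fallback: prefer compactness
    }
    tibble(k = k, width = w)
  })
  k <- sil$k[which.max(sil$width)]
  membership <- cutree(hc, k = k)
  structure(list(prevalence = prev, cluster = membership, k = k,
                 silhouette = sil, hclust = hc),
            class = "cnasd_clusters")
}

#' @export
print.cnasd_clusters <- function(x, ...) {
  cat(sprintf("CNA clusters: %d features in %d clusters\n", length(x$cluster), x$k))
  invisible(x)
}

logrank_chisq <- function(g, time, event) {
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  as.numeric(sd$chisq)
}

partition_node <- function(burden, time, event, idx, min_leaf, max_depth, alpha, depth) {
  b <- burden[idx]
  cand <- sort(unique(b))
  cand <- cand[-1]   # split "b >= c": smallest value gives an empty left side
  cand <- cand[vapply(cand, function(cc) {
    sum(b >= cc) >= min_leaf && sum(b < cc) >= min_leaf
  }, logical(1))]
  if (depth >= max_depth || length(cand) == 0) return(NULL)
  stats_ <- vapply(cand, function(cc) {
    tryCatch(logrank_chisq(b >= cc, time[idx], event[idx]), error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(stats_))) return(NULL)
  j <- which.max(stats_)
  # Bonferroni over the candidate cutpoints examined, so the stopping rule
  # controls the family-wise split rate rather than the per-cutpoint rate
  p <- min(1, pchisq(stats_[j], 1, lower.tail = FALSE) * sum(!is.na(stats_)))
  if (!(p < alpha)) return(NULL)
  cut <- cand[j]
  left <- idx[b < cut]; right <- idx[b >= cut]
  list(cut = cut, chisq = stats_[j], p_value = p,
       left = partition_node(burden, time, event, left, min_leaf, max_depth, alpha, depth + 1),
       right = partition_node(burden, time, event, right, min_leaf, max_depth, alpha, depth + 1))
}

collect_cuts <- function(node) {
  if (is.null(node)) return(numeric(0))
  c(collect_cuts(node$left), node$cut, collect_cuts(node$right))
}

#' Recursive-partitioning burden strata
#'
#' Stratifies samples by CNA burden with a survival tree: recursive binary
#' splits of the form "burden >= c" chosen to maximize the log-rank
#' statistic, stopping when a leaf would fall below `min_leaf` samples, at
#' `max_depth`, or when the best split's log-rank p-value (Bonferroni
#' corrected for the candidate cutpoints examined) is not below `alpha`.
#'
#' @param burden Integer CNA burden per sample (non-constant).
#' @param time,event Survival outcome.
#' @param min_leaf Minimum samples per leaf (default 20).
#' @param max_depth Maximum split depth (default 3).
#' @param alpha Split significance threshold (default 0.05).
#' @return Object of class `cnasd_burden_tree`: `cuts` (sorted split
#'   points; empty when no split), `stratum` (per-sample stratum label),
#'   `km` (`cnasd_km` across strata, NULL for a single stratum), `tree`.
#' @export
burden_partition <- function(burden, time, event, min_leaf = 20, max_depth = 3,
                             alpha = 0.05) {
  if (length(unique(burden)) == 1) abort("Burden is constant; nothing to partition.")
  n <- length(burden)
  tree <- if (n >= 2 * min_leaf) {
    partition_node(burden, time, event, seq_len(n), min_leaf, max_depth, alpha, 0)
  } else NULL
  cuts <- sort(collect_cuts(tree))
  stratum <- if (length(cuts) == 0) rep("all", n) else {
    lab <- c(paste0("<", cuts[1]),
             if (length(cuts) > 1) paste0("[", cuts[-length(cuts)], ",", cuts[-1], ")"),
             paste0(">=", cuts[length(cuts)]))
    lab[findInterval(burden, cuts) + 1L]
  }
  km <- if (length(cuts) > 0) km_logrank(stratum, time, event) else NULL
  structure(list(cuts = cuts, stratum = stratum, km = km, tree = tree,
                 min_leaf = min_leaf, max_depth = max_depth, alpha = alpha),
            class = "cnasd_burden_tree")
}

#' @export
print.cnasd_burden_tree <- function(x, ...) {
  if (length(x$cuts) == 0) cat("Burden partition: no split (single stratum)\n")
  else cat(sprintf("Burden partition: cutpoint(s) at %s; log-rank p = %.3g\n",
                   paste(x$cuts, collapse = ", "), x$km$p_value))
  invisible(x)
}
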