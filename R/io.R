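#' Intensity cutoffs for calling loss and gain
#'
#' Segment mean log-intensities below the loss cutoff are called lost and
#' above the gain cutoff are called gained; everything between (and any
#' uncovered position) is neutral. Defaults follow the common practice for
#' array-derived segment means of -0.1 (loss) and 0.15 (gain).
#'
#' @param loss Loss cutoff, must be negative.
#' @param gain Gain cutoff, must be positive.
#' @return A named list with class `cnasd_cutoffs`.
#' @export
#' @examples
#' intensity_cutoffs()
intensity_cutoffs <- function(loss = -0.1, gain = 0.15) {
  if (!is.numeric(loss) || !is.numeric(gain) || length(loss) != 1 || length(gain) != 1) {
    abort("`loss` and `gain` must be single numbers.")
  }
  if (!(loss < 0 && gain > 0)) {
    abort("Need loss cutoff < 0 < gain cutoff.")
  }
  structure(list(loss = loss, gain = gain), class = "cnasd_cutoffs")
}

# strip "chr" prefix, keep 1..22/X/Y labels as character
normalize_chrom <- function(x) {
  x <- as.character(x)
  x <- sub("^[Cc][Hh][Rr]", "", x)
  x[x == "23"] <- "X"
  x[x == "24"] <- "Y"
  toupper(x)
}

chrom_rank <- function(chrom) {
  suppressWarnings(r <- as.integer(chrom))
  r[chrom == "X"] <- 23L
  r[chrom == "Y"] <- 24L
  r
}

ACROCENTRIC_P <- c("13", "14", "15", "21", "22")
SEX_CHROMS <- c("X", "Y")

match_seg_column <- function(cols, patterns, role) {
  norm <- tolower(gsub("[. ]", "_", cols))
  hit <- which(norm %in% patterns)
  if (length(hit) == 0) {
    abort(sprintf("SEG format error: no column matching the '%s' role (looked for %s).",
                  role, paste(patterns, collapse = ", ")))
  }
  hit[1]
}

#' Read a SEG-format segment table
#'
#' Reads a tab-delimited segmentation table (sample ID, chromosome, start,
#' end, marker count, segment mean log-intensity) such as the TCGA
#' whitelisted SNP6 SEG files or DNAcopy output. Coordinates are converted
#' from the 1-based inclusive SEG convention to 0-based half-open intervals
#' internally. Chromosome labels are accepted with or without a "chr"
#' prefix. Segments on sex chromosomes are retained but flagged `excluded`.
#'
#' @param path Path to a tab-delimited SEG file with a header row.
#' @param dialect `"tcga"` (columns ID/chrom/loc.start/loc.end/num.mark/
#'   seg.mean or Sample/Chromosome/Start/End/Num_Probes/Segment_Mean) or
#'   `"generic"` (same roles matched loosely by name).
#' @param arms Optional arm table from [read_arm_table()]; when supplied the
#'   segments are immediately passed through [validate_segments()].
#' @return A tibble of segments with class `cnasd_segments`: columns
#'   `sample`, `chrom`, `start`, `end` (0-based half-open bp), `n_probes`,
#'   `seg_mean`, `excluded`.
#' @export
read_seg <- function(path, dialect = c("tcga", "generic"), arms = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("SEG file not found: %s", path))
  raw <- utils::read.delim(path, colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  roles <- list(
    sample   = c("id", "sample", "sample_id", "sampleid"),
    chrom    = c("chrom", "chromosome", "chr"),
    start    = c("loc_start", "start", "chromstart"),
    end      = c("loc_end", "end", "chromend"),
    n_probes = c("num_mark", "num_probes", "n_probes", "markers", "num_markers", "probes"),
    seg_mean = c("seg_mean", "segment_mean", "mean")
  )
  idx <- lapply(names(roles), function(r) match_seg_column(names(raw), roles[[r]], r))
  names(idx) <- names(roles)

  if (nrow(raw) == 0) {
    warn(sprintf("SEG file %s contains a header only; returning an empty segment table.", path))
    out <- tibble(sample = character(), chrom = character(), start = double(),
                  end = double(), n_probes = double(), seg_mean = double(),
                  excluded = logical())
    class(out) <- c("cnasd_segments", class(out))
    return(out)
  }

  num_or_die <- function(col, what) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & raw[[col]] != "")
    if (length(bad)) {
      abort(sprintf("SEG parse error: non-numeric %s at file line %s (value '%s').",
                    what, bad[1] + 1L, raw[[col]][bad[1]]))
    }
    v
  }
  start1 <- num_or_die(idx$start, "start coordinate")
  end1 <- num_or_die(idx$end, "end coordinate")
  out <- tibble(
    sample = as.character(raw[[idx$sample]]),
    chrom = normalize_chrom(raw[[idx$chrom]]),
    start = start1 - 1,   # 1-based inclusive -> 0-based half-open
    end = end1,
    n_probes = num_or_die(idx$n_probes, "probe count"),
    seg_mean = num_or_die(idx$seg_mean, "segment mean")
  )
  bad <- which(!(out$start < out$end))
  if (length(bad)) {
    abort(sprintf("SEG parse error: start >= end at file line %s.", bad[1] + 1L))
  }
  out$excluded <- out$chrom %in% SEX_CHROMS
  out <- arrange(out, chrom_rank(.data$chrom), .data$start, .data$sample)
  out <- arrange(out, .data$sample, chrom_rank(.data$chrom), .data$start)
  class(out) <- c("cnasd_segments", class(out))
  if (!is.null(arms)) out <- validate_segments(out, arms) else out
}

#' Write segments to a SEG file
#'
#' Inverse of [read_seg()]: coordinates are converted back to the 1-based
#' inclusive SEG convention, with TCGA-style column names.
#'
#' @param segments A `cnasd_segments` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segments, path) {
  df <- data.frame(
    ID = segments$sample,
    chrom = segments$chrom,
    loc.start = format(segments$start + 1, scientific = FALSE, trim = TRUE),
    loc.end = format(segments$end, scientific = FALSE, trim = TRUE),
    num.mark = format(segments$n_probes, scientific = FALSE, trim = TRUE),
    seg.mean = sprintf("%.6f", segments$seg_mean),
    check.names = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

apply_arm_exclusions <- function(arms) {
  mutate(arms, included = !(.data$chrom %in% SEX_CHROMS) &
           !(.data$arm == "p" & .data$chrom %in% ACROCENTRIC_P))
}

finish_arm_table <- function(arms) {
  arms <- filter(arms, .data$start < .data$end)   # drop empty arms (acen-first chromosomes)
  arms <- apply_arm_exclusions(arms)
  arms <- mutate(arms, feature_arm = paste0(.data$chrom, .data$arm))
  arms <- arrange(arms, chrom_rank(.data$chrom), .data$arm)
  stopifnot(all(arms$start < arms$end))
  class(arms) <- c("cnasd_arms", setdiff(class(arms), "cnasd_arms"))
  arms
}

#' Read a chromosome-arm coordinate table
#'
#' Accepts either a UCSC `cytoBand.txt`-style file (five tab-separated
#' columns chrom/start/end/band/stain, no header) or a precomputed arm table
#' (header with columns chrom, arm, start, end). From cytoBand input the
#' p arm spans from the chromosome start to the first centromeric (`acen`)
#' band and the q arm from the last `acen` band to the chromosome end.
#' Sex chromosomes and the p arms of the acrocentric chromosomes (13, 14,
#' 15, 21, 22) are marked `included = FALSE`; a standard human build yields
#' 39 included autosomal arms.
#'
#' @param path Path to the file.
#' @return A tibble with class `cnasd_arms`: `chrom`, `arm`, `start`, `end`
#'   (0-based half-open bp), `included`, `feature_arm` (e.g. "1p").
#' @export
read_arm_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("Arm table not found: %s", path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0) abort(sprintf("Empty arm table: %s", path))
  if (grepl("chrom", tolower(first)) && grepl("arm", tolower(first))) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    names(tab) <- tolower(names(tab))
    need <- c("chrom", "arm", "start", "end")
    miss <- setdiff(need, names(tab))
    if (length(miss)) abort(sprintf("Arm table missing column(s): %s", paste(miss, collapse = ", ")))
    arms <- tibble(chrom = normalize_chrom(tab$chrom), arm = tolower(tab$arm),
                   start = as.numeric(tab$start), end = as.numeric(tab$end))
    return(finish_arm_table(arms))
  }
  cb <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(cb) < 5) abort("cytoBand input needs 5 columns (chrom, start, end, band, stain).")
  names(cb)[1:5] <- c("chrom", "start", "end", "band", "stain")
  if (nrow(cb) == 0) abort(sprintf("Empty arm table: %s", path))
  cb$chrom <- normalize_chrom(cb$chrom)
  arms <- cb %>%
    group_by(.data$chrom) %>%
    summarise(
      chrom_start = min(.data$start),
      chrom_end = max(.data$end),
      acen_start = ifelse(any(.data$stain == "acen"), min(.data$start[.data$stain == "acen"]), NA_real_),
      acen_end = ifelse(any(.data$stain == "acen"), max(.data$end[.data$stain == "acen"]), NA_real_),
      .groups = "drop"
    )
  if (anyNA(arms$acen_start)) {
    abort(sprintf("cytoBand chromosome(s) without acen bands: %s",
                  paste(arms$chrom[is.na(arms$acen_start)], collapse = ", ")))
  }
  arms <- bind_rows(
    tibble(chrom = arms$chrom, arm = "p", start = arms$chrom_start, end = arms$acen_start),
    tibble(chrom = arms$chrom, arm = "q", start = arms$acen_end, end = arms$chrom_end)
  )
  finish_arm_table(arms)
}

#' Built-in approximate hg38-scale arm table
#'
#' A synthetic stand-in for an hg38 arm table: chromosome lengths and
#' centromere positions rounded to the nearest 0.1 Mb. Intended for
#' simulation and examples at realistic genomic scale; for real data derive
#' arms from the build's cytoBand file with [read_arm_table()].
#'
#' @return A `cnasd_arms` tibble with 48 arms, 39 of them included.
#' @export
arm_table_hg38like <- function() {
  len_mb <- c(249.0, 242.2, 198.3, 190.2, 181.5, 170.8, 159.3, 145.1, 138.4,
              133.8, 135.1, 133.3, 114.4, 107.0, 102.0, 90.3, 83.3, 80.4,
              58.6, 64.4, 46.7, 50.8)
  cen_mb <- c(123.4, 93.9, 90.9, 50.0, 48.8, 59.8, 60.1, 45.2, 43.0,
              39.8, 53.4, 35.5, 17.7, 17.2, 19.0, 36.8, 25.1, 18.5,
              26.2, 28.1, 12.0, 15.0)
  chrom <- as.character(1:22)
  arms <- bind_rows(
    tibble(chrom = chrom, arm = "p", start = 0, end = cen_mb * 1e6),
    tibble(chrom = chrom, arm = "q", start = (cen_mb + 3) * 1e6, end = len_mb * 1e6)
  )
  finish_arm_table(arms)
}

#' Small toy arm table for fast simulation
#'
#' 22 autosomes with short (tens of Mb) arms and the standard acrocentric
#' p-arm exclusions, so that downstream grids and bins stay small. Arm
#' fractions are scale-free, so analyses on the toy table exercise the same
#' code paths as genome-scale tables at a fraction of the cost.
#'
#' @param p_mb,q_mb Baseline p- and q-arm lengths in Mb; small deterministic
#'   per-chromosome jitter is added so arms differ.
#' @return A `cnasd_arms` tibble with 39 included arms.
#' @export
arm_table_toy <- function(p_mb = 12, q_mb = 20) {
  chrom <- as.character(1:22)
  jit <- ((1:22 * 7) %% 9) - 4   # -4..4 Mb, deterministic
  p_len <- pmax(6, p_mb + jit) * 1e6
  q_len <- pmax(8, q_mb + rev(jit)) * 1e6
  arms <- bind_rows(
    tibble(chrom = chrom, arm = "p", start = 0, end = p_len),
    tibble(chrom = chrom, arm = "q", start = p_len + 3e6, end = p_len + 3e6 + q_len)
  )
  finish_arm_table(arms)
}

#' Validate segments against an arm table
#'
#' Restricts segments to arm intervals: segments are clipped to arms,
#' segments straddling the centromere are split at the arm boundaries, and
#' overlapping segments within one sample and chromosome are repaired by
#' truncating the earlier segment at the start of the later one (with a
#' warning). Segments on excluded arms are retained but flagged.
#'
#' @param segments A `cnasd_segments` tibble from [read_seg()].
#' @param arms A `cnasd_arms` tibble.
#' @return A validated `cnasd_segments` tibble with columns `arm`,
#'   `feature_arm` and `excluded` filled in, sorted by sample, chromosome
#'   and start. Attribute `validated` is set to `TRUE`.
#' @export
validate_segments <- function(segments, arms) {
  stopifnot(is.data.frame(segments), is.data.frame(arms))
  segs <- as_tibble(segments)

  # overlap repair first (within sample+chrom, genomic order)
  segs <- arrange(segs, .data$sample, chrom_rank(.data$chrom), .data$start, .data$end)
  grp <- paste(segs$sample, segs$chrom, sep = "\r")
  new_grp <- c(TRUE, grp[-1] != grp[-length(grp)])
  nxt_start <- c(segs$start[-1], Inf)
  nxt_start[c(new_grp[-1], TRUE)] <- Inf
  clip <- segs$end > nxt_start
  if (any(clip)) {
    warn(sprintf("Truncated %d overlapping segment(s) at the start of the following segment.",
                 sum(clip)))
    segs$end <- pmin(segs$end, nxt_start)
    segs <- filter(segs, .data$start < .data$end)
  }

  # assign to arms, splitting across arm boundaries
  pieces <- left_join(segs, select(arms, "chrom", "arm", arm_start = "start",
                                   arm_end = "end", "included", "feature_arm"),
                      by = "chrom", relationship = "many-to-many")
  off_arm <- filter(pieces, is.na(.data$arm_start))   # chrom absent from arm table
  pieces <- filter(pieces, !is.na(.data$arm_start),
                   .data$start < .data$arm_end, .data$end > .data$arm_start)
  pieces <- mutate(pieces,
                   start = pmax(.data$start, .data$arm_start),
                   end = pmin(.data$end, .data$arm_end),
                   excluded = !.data$included)
  if (nrow(off_arm) > 0) {
    off_arm <- mutate(off_arm, arm = NA_character_, feature_arm = NA_character_,
                      excluded = TRUE)
  }
  out <- bind_rows(pieces, off_arm)
  out <- select(out, "sample", "chrom", "arm", "feature_arm", "start", "end",
                "n_probes", "seg_mean", "excluded")
  out <- arrange(out, .data$sample, chrom_rank(.data$chrom), .data$start)
  class(out) <- c("cnasd_segments", setdiff(class(out), "cnasd_segments"))
  attr(out, "validated") <- TRUE
  attr(out, "arms") <- arms
  out
}

#' Read a clinical survival table
#'
#' Reads a delimited clinical table with per-sample time-to-event data for a
#' recurrence/progression endpoint and an overall-survival endpoint, plus
#' optional covariates. Column names are configured through `column_map`,
#' which maps the canonical roles to the file's column names (e.g.
#' `list(time_recurrence = "PFS.time", event_recurrence = "PFS")` for
#' TCGA-CDR-style files).
#'
#' @param path Path to a CSV/TSV file (delimiter sniffed from the header).
#' @param column_map Named list with entries `sample`, `time_recurrence`,
#'   `event_recurrence`, `time_os`, `event_os` and optionally `covariates`
#'   (character vector of extra columns to carry along). Missing entries
#'   fall back to the canonical names themselves.
#' @param time_scale Divisor applied to the time columns (e.g. `365.25` to
#'   convert days to years). Times are expected in years downstream.
#' @return A tibble with class `cnasd_clinical`: `sample`, `time_rec`,
#'   `event_rec`, `time_os`, `event_os`, plus any covariates.
#' @export
read_clinical <- function(path, column_map = list(), time_scale = 1) {
  if (!file.exists(path)) abort(sprintf("Clinical file not found: %s", path))
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  defaults <- list(sample = "sample", time_recurrence = "time_recurrence",
                   event_recurrence = "event_recurrence",
                   time_os = "time_os", event_os = "event_os")
  map <- utils::modifyList(defaults, column_map[setdiff(names(column_map), "covariates")])
  get_col <- function(role) {
    nm <- map[[role]]
    if (!nm %in% names(tab)) {
      if (role == "sample") abort(sprintf("Clinical table lacks a '%s' column ('%s').", role, nm))
      return(NULL)
    }
    tab[[nm]]
  }
  coerce_event <- function(x, role) {
    if (is.null(x)) return(NULL)
    if (is.logical(x)) return(as.numeric(x))
    if (is.character(x)) {
      xl <- toupper(trimws(x))
      x <- ifelse(xl %in% c("TRUE", "T", "YES"), 1,
                  ifelse(xl %in% c("FALSE", "F", "NO"), 0, suppressWarnings(as.numeric(xl))))
    }
    x <- as.numeric(x)
    bad <- !is.na(x) & !x %in% c(0, 1)
    if (any(bad)) abort(sprintf("Event column '%s' has values outside {0,1}.", role))
    x
  }
  out <- tibble(sample = as.character(get_col("sample")))
  tr <- get_col("time_recurrence"); to <- get_col("time_os")
  out$time_rec <- if (is.null(tr)) NA_real_ else as.numeric(tr) / time_scale
  out$event_rec <- coerce_event(get_col("event_recurrence"), "event_recurrence") %||% NA_real_
  out$time_os <- if (is.null(to)) NA_real_ else as.numeric(to) / time_scale
  out$event_os <- coerce_event(get_col("event_os"), "event_os") %||% NA_real_

  if (anyDuplicated(out$sample)) abort("Clinical table has duplicated sample IDs.")
  bad_t <- (!is.na(out$time_rec) & out$time_rec <= 0) | (!is.na(out$time_os) & out$time_os <= 0)
  if (any(bad_t)) {
    abort(sprintf("Non-positive survival time for sample(s): %s",
                  paste(out$sample[bad_t], collapse = ", ")))
  }
  no_endpoint <- (is.na(out$time_rec) | is.na(out$event_rec)) &
    (is.na(out$time_os) | is.na(out$event_os))
  if (any(no_endpoint)) {
    warn(sprintf("Dropping %d sample(s) with neither endpoint observed.", sum(no_endpoint)))
    out <- out[!no_endpoint, ]
  }
  covs <- column_map$covariates
  if (!is.null(covs)) {
    miss <- setdiff(covs, names(tab))
    if (length(miss)) abort(sprintf("Covariate column(s) missing: %s", paste(miss, collapse = ", ")))
    keep <- tab[[map$sample]] %in% out$sample
    for (cv in covs) out[[cv]] <- tab[[cv]][keep][match(out$sample, tab[[map$sample]][keep])]
  }
  class(out) <- c("cnasd_clinical", class(out))
  out
}
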