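test_that("read_seg parses TCGA-dialect files into per-sample profiles", {
  df <- make_segs(c(100, 2000, 500), c(1000, 5000, 900),
                  c(-0.5, 0.2, 0.0), sample = c("A", "A", "B"))
  path <- write_tcga_seg(df)
  segs <- read_seg(path)
  expect_s3_class(segs, "cnasd_segments")
  expect_equal(sort(unique(segs$sample)), c("A", "B"))
  expect_equal(as.integer(table(segs$sample)), c(2L, 1L))
  # 1-based inclusive -> 0-based half-open
  expect_equal(segs$start[segs$sample == "B"], 499)
  expect_equal(segs$end[segs$sample == "B"], 900)
})

test_that("read_seg handles header-only files, sex chromosomes, chr prefixes", {
  path <- write_tcga_seg(make_segs(numeric(0), numeric(0), numeric(0), sample = character(0)))
  expect_warning(empty <- read_seg(path), "header only")
  expect_equal(nrow(empty), 0)

  df <- make_segs(c(100, 100), c(1000, 1000), c(-0.5, -0.5),
                  chrom = c("chrX", "chr2"), sample = "A")
  segs <- read_seg(write_tcga_seg(df))
  expect_equal(segs$chrom, c("2", "X"))
  expect_equal(segs$excluded, c(FALSE, TRUE))
})

test_that("read_seg raises named format and row-level parse errors", {
  path <- tempfile(fileext = ".seg")
  writeLines(c("ID\tchrom\tloc.start\tloc.end\tnum.mark",
               "A\t1\t1\t100\t5"), path)
  expect_error(read_seg(path), "seg_mean")

  path2 <- tempfile(fileext = ".seg")
  writeLines(c("ID\tchrom\tloc.start\tloc.end\tnum.mark\tseg.mean",
               "A\t1\t1\t100\t5\t-0.2",
               "A\t1\toops\t900\t5\t0.1"), path2)
  expect_error(read_seg(path2), "line 3")
})

test_that("SEG round-trip preserves coordinates, probes and intensities", {
  df <- make_segs(c(0, 1.5e6, 17), c(1.5e6, 3e6, 2e3),
                  c(-0.123456, 0.654321, 0.0), sample = c("A", "A", "B"))
  p1 <- tempfile(fileext = ".seg")
  write_seg(structure(df, class = c("cnasd_segments", class(df))), p1)
  back <- read_seg(p1)
  back <- back[order(back$sample, back$start), ]
  df2 <- df[order(df$sample, df$start), ]
  expect_equal(back$start, df2$start)
  expect_equal(back$end, df2$end)
  expect_equal(back$n_probes, df2$n_probes)
  expect_equal(back$seg_mean, df2$seg_mean, tolerance = 1e-6)
})

test_that("read_arm_table derives arms from cytoBand bands and applies exclusions", {
  path <- tempfile()
  writeLines(c("chr1\t0\t10000000\tp36\tgneg",
               "chr1\t10000000\t12000000\tp11\tacen",
               "chr1\t12000000\t30000000\tq11\tgneg",
               "chr13\t0\t1000000\tp12\tgneg",
               "chr13\t1000000\t5000000\tp11\tacen",
               "chr13\t5000000\t20000000\tq11\tgneg"), path)
  arms <- read_arm_table(path)
  a1p <- arms[arms$feature_arm == "1p", ]
  a1q <- arms[arms$feature_arm == "1q", ]
  expect_equal(c(a1p$start, a1p$end), c(0, 1e7))
  expect_equal(c(a1q$start, a1q$end), c(1.2e7, 3e7))
  expect_true(a1p$included && a1q$included)
  expect_false(arms$included[arms$feature_arm == "13p"])
  expect_true(arms$included[arms$feature_arm == "13q"])
})

test_that("cytoBand chromosomes without acen bands are rejected", {
  path <- tempfile()
  writeLines(c("chr1\t0\t10000000\tp36\tgneg",
               "chr1\t10000000\t30000000\tq11\tgneg"), path)
  expect_error(read_arm_table(path), "acen")
})

test_that("a standard-build arm table carries exactly 39 included autosomal arms", {
  arms <- arm_table_hg38like()
  expect_equal(sum(arms$included), 39)
  expect_equal(sum(!arms$included), 9 - 4)  # 5 acrocentric p arms; no sex chroms in the table
  # precomputed 4-column file path yields the same thing
  path <- tempfile()
  write.table(data.frame(chrom = arms$chrom, arm = arms$arm,
                         start = arms$start, end = arms$end),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  arms2 <- read_arm_table(path)
  expect_equal(sum(arms2$included), 39)
  expect_equal(arms2$start, arms$start)
})

test_that("arms partition each chromosome: p, centromere gap, q tile without overlap", {
  for (arms in list(arm_table_hg38like(), arm_table_toy())) {
    per_chrom <- split(arms, arms$chrom)
    for (ch in per_chrom) {
      p <- ch[ch$arm == "p", ]; q <- ch[ch$arm == "q", ]
      expect_true(p$start < p$end)
      expect_true(q$start < q$end)
      expect_lte(p$end, q$start)
      expect_equal(p$start, 0)
    }
  }
})

test_that("validate_segments splits centromere-straddling segments and repairs overlaps", {
  arms <- arm_table_toy()
  a1 <- arms[arms$chrom == "1", ]
  straddle <- make_segs(a1$start[1] + 1e6, a1$end[2] - 1e6, -0.5)
  v <- validate_segments(straddle, arms)
  expect_equal(nrow(v), 2)
  expect_equal(v$end[1], a1$end[a1$arm == "p"])
  expect_equal(v$start[2], a1$start[a1$arm == "q"])

  over <- make_segs(c(0, 2e6), c(3e6, 5e6), c(-0.5, 0.0))
  expect_warning(v2 <- validate_segments(over, arms), "overlap")
  expect_equal(v2$end[1], 2e6)     # earlier segment truncated at later's start
  expect_true(all(v2$start < v2$end))
})

test_that("read_clinical validates times, coerces events, applies column maps", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(sample = c("A", "B", "C", "D", "E"),
                       PFS.time = c(1.2, 3.4, 0, 2.2, 5.5),
                       PFS = c("TRUE", "FALSE", "TRUE", "FALSE", "TRUE"),
                       OS.time = c(2, 4, 1, 3, 6), OS = c(0, 1, 0, 0, 1)),
            path, row.names = FALSE)
  expect_error(read_clinical(path, list(time_recurrence = "PFS.time",
                                        event_recurrence = "PFS",
                                        time_os = "OS.time", event_os = "OS")),
               "C")
  path2 <- tempfile(fileext = ".csv")
  write.csv(data.frame(sample = c("A", "B"), PFS.time = c(1.2, 3.4),
                       PFS = c(TRUE, FALSE), OS.time = c(2, 4), OS = c(0, 1)),
            path2, row.names = FALSE)
  cl <- read_clinical(path2, list(time_recurrence = "PFS.time", event_recurrence = "PFS",
                                  time_os = "OS.time", event_os = "OS"))
  expect_equal(cl$event_rec, c(1, 0))
  expect_equal(cl$time_rec, c(1.2, 3.4))
})

test_that("samples with neither endpoint are dropped with a warning", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(sample = c("A", "B"), time_recurrence = c(1, NA),
                       event_recurrence = c(1, NA), time_os = c(2, NA),
                       event_os = c(0, NA)), path, row.names = FALSE)
  expect_warning(cl <- read_clinical(path), "neither endpoint")
  expect_equal(cl$sample, "A")
})
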