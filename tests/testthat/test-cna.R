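# Copy-number pipeline: intensity summation, quantile normalization against
# its brute-force oracle, log2 ratios, arm calling and track export.

cna_fixture <- function(n = 40, samples = 3) {
  set.seed(123)
  probes <- data.frame(
    probe_id = sprintf("cg%04d", 1:n),
    chromosome = rep(c("chr1", "chr9"), each = n / 2),
    position = rep(seq(1e6, 4e7, length.out = n / 2), 2),
    stringsAsFactors = FALSE)
  sheet <- data.frame(sample_id = sprintf("s%02d", 1:samples),
                      sample_class = c("ALL", rep("reference", samples - 1)),
                      sex = "F",
                      subtype_label = c("HeH", rep("unknown", samples - 1)),
                      stringsAsFactors = FALSE)
  list(probes = probes, sheet = sheet)
}

test_that("total intensity is the elementwise channel sum", {
  fx <- cna_fixture()
  set.seed(5)
  m <- matrix(runif(120, 10, 100), 40)
  u <- matrix(runif(120, 10, 100), 40)
  meth <- intensity_matrix(m, fx$probes, fx$sheet, "methylated")
  unmeth <- intensity_matrix(u, fx$probes, fx$sheet, "unmethylated")
  tot <- total_intensity(meth, unmeth)
  expect_identical(tot$channel, "total")
  # scalar-loop oracle
  for (i in c(1, 17, 40)) for (j in 1:3)
    expect_identical(tot$values[i, j], m[i, j] + u[i, j])
  expect_identical(total_intensity(meth, meth)$values[1, 1], 2 * m[1, 1])
  short <- intensity_matrix(u[-1, ], fx$probes[-1, ], fx$sheet,
                            "unmethylated")
  expect_error(total_intensity(meth, short), class = "mall_format_error")
})

test_that("quantile normalization matches the mean-of-order-statistics oracle", {
  toy <- matrix(c(5, 2, 3, 4,
                  4, 1, 4, 2,
                  3, 4, 6, 8), 4, 3,
                dimnames = list(paste0("p", 1:4), paste0("s", 1:3)))
  got <- quantile_normalize(toy)
  expect_equal(got, oracle_quantile_normalize(toy), tolerance = 1e-12)
  # frozen by hand: column means of order statistics are (2, 3, 14/3, 17/3)
  # and column 1 has ranks (4, 1, 2, 3)
  expect_equal(unname(got[, 1]), c(17/3, 2, 3, 14/3), tolerance = 1e-12)
  set.seed(31)
  r <- matrix(rlnorm(600), 60, 10)
  expect_equal(quantile_normalize(r), oracle_quantile_normalize(r),
               tolerance = 1e-12)
})

test_that("after normalization all columns share one distribution", {
  set.seed(8)
  m <- matrix(rlnorm(500, sdlog = 1), 100, 5)
  qn <- quantile_normalize(m)
  sorted <- apply(qn, 2, sort)
  for (j in 2:5) expect_lt(max(abs(sorted[, j] - sorted[, 1])), 1e-12)
  # permuted columns end up as identical multisets
  m2 <- cbind(a = m[, 1], b = sample(m[, 1]))
  qn2 <- quantile_normalize(m2)
  expect_equal(sort(qn2[, 1]), sort(qn2[, 2]), tolerance = 1e-12)
  # single sample passes through unchanged
  one <- matrix(c(4, 2, 9), dimnames = list(NULL, "x"))
  expect_equal(quantile_normalize(one), one, tolerance = 1e-12)
  m[1, 1] <- NA
  expect_error(quantile_normalize(m), class = "mall_value_error")
})

test_that("log2 ratios are zero against the panel mean and scale as planted", {
  fx <- cna_fixture(n = 40, samples = 4)
  set.seed(6)
  base <- matrix(rlnorm(160, log(1000), 0.2), 40)
  tot <- intensity_matrix(base, fx$probes, fx$sheet, "total")
  refs <- fx$sheet$sample_id[fx$sheet$sample_class == "reference"]
  refmean <- rowMeans(base[, 2:4])
  # a sample equal to the panel mean maps to the zero vector; 2x maps to 1
  v2 <- cbind(refmean, 2 * refmean, base[, 2:4][, 1:2])
  sheet2 <- fx$sheet
  sheet2$sample_id <- c("mean", "double", "r1", "r2")
  sheet2$sample_class <- c("ALL", "ALL", "reference", "reference")
  sheet2$subtype_label <- c("HeH", "HeH", "unknown", "unknown")
  tr <- log2_ratio(intensity_matrix(v2, fx$probes, sheet2, "total"),
                   c("r1", "r2"))
  ref2 <- rowMeans(v2[, 3:4])
  expect_equal(unname(tr$log2[, "mean"]), log2(refmean / ref2),
               tolerance = 1e-12)
  expect_equal(unname(tr$log2[, "double"] - tr$log2[, "mean"]),
               rep(1, 40), tolerance = 1e-12)
  expect_error(log2_ratio(tot, character(0)), class = "mall_value_error")
  expect_error(log2_ratio(tot, "nope"), class = "mall_value_error")
  # zero-intensity probes are dropped, not propagated as -Inf
  withzero <- base; withzero[3, 1] <- 0
  tz <- suppressWarnings(log2_ratio(
    intensity_matrix(withzero, fx$probes, fx$sheet, "total"), refs))
  expect_identical(nrow(tz$log2), 39L)
  expect_true(all(is.finite(tz$log2)))
})

test_that("an all-zero track is neutral with modeled count 46", {
  set.seed(77)
  n <- 2000
  probes <- data.frame(
    probe_id = sprintf("cg%05d", 1:n),
    chromosome = sample(mall_chromosomes(), n, replace = TRUE),
    position = sample.int(2e7, n), stringsAsFactors = FALSE)
  sheet <- data.frame(sample_id = c("t1", "r1"),
                      sample_class = c("ALL", "reference"), sex = "M",
                      subtype_label = c("HeH", "unknown"),
                      stringsAsFactors = FALSE)
  track <- structure(list(
    log2 = matrix(0, n, 2, dimnames = list(probes$probe_id,
                                           sheet$sample_id)),
    probes = probes, samples = sheet, reference_ids = "r1"),
    class = "cna_track")
  ev <- call_arm_events(track)
  called <- ev$events[ev$events$call != "insufficient", ]
  expect_true(all(called$call == "neutral"))
  expect_true(all(ev$chromosome_counts$modeled_count == 46))
  # arms with too few probes are flagged, not called
  sparse <- ev$events[ev$events$n_probes < 20, ]
  if (nrow(sparse)) expect_true(all(sparse$call == "insufficient"))
})

test_that("planted whole-chromosome trisomies give gains and count 50", {
  counts <- c("T-ALL" = 2, "HeH" = 2, "t(12;21)" = 6, "11q23/MLL" = 2,
              "t(1;19)" = 2, "dic(9;20)" = 2, "t(9;22)" = 2, "iAMP21" = 2)
  ev_cfg <- data.frame(subtype = "t(12;21)",
                       chromosome = c("chr21", "chr14", "chr17", "chr8"),
                       arm = "both", copy_number = 3,
                       stringsAsFactors = FALSE)
  sim <- simulate_cohort(generator_config(
    subtype_sample_counts = counts, n_reference = 30,
    blast_fraction_range = c(1, 1), cna_events = ev_cfg, seed = 19))
  refs <- sim$data$samples$sample_id[sim$data$samples$sample_class ==
                                       "reference"]
  track <- log2_ratio(quantile_normalize(total_intensity(sim$meth,
                                                         sim$unmeth)),
                      refs)
  ev <- call_arm_events(track)
  tum <- sim$data$samples$sample_id[sim$data$samples$subtype_label ==
                                      "t(12;21)"]
  cc <- ev$chromosome_counts
  expect_true(all(cc$modeled_count[cc$sample_id %in% tum] == 50))
  gained <- ev$events[ev$events$sample_id == tum[1] &
                        ev$events$call == "gain", ]
  expect_setequal(unique(gained$chromosome),
                  c("chr21", "chr14", "chr17", "chr8"))
})

test_that("bedGraph export uses 0-based half-open starts", {
  probes <- data.frame(probe_id = c("a", "b", "c"), chromosome = "chr2",
                       position = c(100L, 250L, 4000L),
                       stringsAsFactors = FALSE)
  sheet <- data.frame(sample_id = "s1", sample_class = "ALL", sex = "F",
                      subtype_label = "HeH", stringsAsFactors = FALSE)
  track <- structure(list(
    log2 = matrix(c(0.5, -0.25, 0), 3, 1,
                  dimnames = list(probes$probe_id, "s1")),
    probes = probes, samples = sheet, reference_ids = "r"),
    class = "cna_track")
  dir <- withr::local_tempdir()
  export_track(track, dir, "bedGraph")
  lines <- readLines(file.path(dir, "s1.bedGraph"))
  expect_match(lines[1], "^track type=bedGraph")
  expect_identical(lines[2], "chr2\t99\t100\t0.5")
  expect_identical(lines[3], "chr2\t249\t250\t-0.25")
  expect_length(lines, 4)
  # empty track still writes a valid header-only file
  empty <- track
  empty$log2 <- track$log2[0, , drop = FALSE]
  empty$probes <- probes[0, ]
  export_track(empty, dir, "bedGraph")
  expect_identical(length(readLines(file.path(dir, "s1.bedGraph"))), 1L)
})

test_that("SEG export round-trips arm medians", {
  set.seed(55)
  n <- 300
  probes <- data.frame(
    probe_id = sprintf("cg%04d", 1:n),
    chromosome = sample(c("chr9", "chr20", "chr21"), n, replace = TRUE),
    position = sample.int(3e7, n), stringsAsFactors = FALSE)
  sheet <- data.frame(sample_id = c("s1", "s2"), sample_class = "ALL",
                      sex = "F", subtype_label = "HeH",
                      stringsAsFactors = FALSE)
  track <- structure(list(
    log2 = matrix(rnorm(n * 2, 0, 0.3), n, 2,
                  dimnames = list(probes$probe_id, sheet$sample_id)),
    probes = probes, samples = sheet, reference_ids = "r"),
    class = "cna_track")
  path <- withr::local_tempfile(fileext = ".seg")
  export_track(track, path, "seg")
  seg <- utils::read.delim(path)
  # scalar re-derivation of the per-arm medians from the arm boundaries
  arms <- hg19_arms()
  checked <- 0L
  for (i in seq_len(nrow(seg))) {
    b <- arms[arms$chromosome == seg$chrom[i] &
                seg$loc.start[i] >= arms$start &
                seg$loc.start[i] <= arms$end, ]
    idx <- probes$chromosome == seg$chrom[i] &
      probes$position >= b$start & probes$position <= b$end
    expect_lt(abs(seg$seg.mean[i] - median(track$log2[idx, seg$ID[i]])),
              1e-6)
    expect_identical(seg$num.mark[i], sum(idx))
    checked <- checked + 1L
  }
  expect_gte(checked, 8L)   # 3 chromosomes x 2 arms x 2 samples, minus gaps
  expect_error(export_track(track, path, "cram"))
})

test_that("cytoband-derived arms match the built-in table", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("chr21\t0\t11288129\tp13\tgneg",
               "chr21\t11288129\t14288129\tcen\tacen",
               "chr21\t14288129\t48129895\tq21\tgneg"), path)
  arms <- read_cytoband_arms(path)
  expect_identical(nrow(arms), 2L)
  expect_identical(arms$start[arms$arm == "q"], 14288130L)
  expect_identical(arms$end[arms$arm == "p"], 11288129L)
})
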