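# Containers and on-disk formats: validation, round-trips, order preservation.

make_manifest <- function(n, chrom = "chr1") {
  data.frame(probe_id = sprintf("cg%05d", seq_len(n)),
             chromosome = chrom, position = seq_len(n) * 100L,
             gene = sprintf("G%03d", seq_len(n)),
             cgi_relation = rep(c("island", "shore", "shelf", "open_sea"),
                                length.out = n),
             stringsAsFactors = FALSE)
}

make_sheet <- function(ids, class = "ALL", subtype = "HeH") {
  data.frame(sample_id = ids, sample_class = class, sex = "F",
             subtype_label = ifelse(class == "ALL", subtype, "unknown"),
             stringsAsFactors = FALSE)
}

test_that("manifest validation enforces the probe invariants", {
  ok <- probe_annotation(data.frame(probe_id = "cg001", chromosome = "chr21",
                                    position = 1000, gene = "CLDN14",
                                    cgi_relation = "island"))
  expect_equal(ok$chromosome, "chr21")
  expect_error(probe_annotation(data.frame(probe_id = "a", chromosome = "chr23",
                                           position = 1)),
               class = "mall_format_error")
  expect_error(probe_annotation(data.frame(probe_id = c("a", "a"),
                                           chromosome = "chr1",
                                           position = c(1, 2))),
               class = "mall_format_error")
  expect_error(probe_annotation(data.frame(probe_id = "a", position = 5)),
               class = "mall_format_error")
  expect_error(probe_annotation(data.frame(probe_id = "a", chromosome = "chr1",
                                           position = 0)),
               class = "mall_format_error")
})

test_that("sample sheet validation enforces the sample invariants", {
  expect_error(sample_sheet(data.frame(sample_id = "r1",
                                       sample_class = "reference", sex = "M",
                                       subtype_label = "HeH")),
               class = "mall_format_error")
  expect_error(sample_sheet(data.frame(sample_id = c("a", "a"),
                                       sample_class = "ALL", sex = "M",
                                       subtype_label = "HeH")),
               class = "mall_format_error")
  expect_error(sample_sheet(data.frame(sample_id = "a", sample_class = "ALL",
                                       sex = "X", subtype_label = "HeH")),
               class = "mall_format_error")
})

test_that("beta matrix bounds are enforced with the offending cell named", {
  man <- make_manifest(3)
  sheet <- make_sheet(c("s1", "s2"))
  b <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 1.3), 3)
  err <- tryCatch(methyl_matrix(b, man, sheet), error = function(e) e)
  expect_s3_class(err, "mall_value_error")
  expect_match(conditionMessage(err), "cg00003")
  expect_match(conditionMessage(err), "s2")
  # values within the 1e-9 tolerance are clamped, not rejected
  b[3, 2] <- 1 + 1e-10
  mm <- methyl_matrix(b, man, sheet)
  expect_equal(mm$beta[3, 2], 1)
})

test_that("beta matrix IO round-trips values to 1e-12 and preserves order", {
  set.seed(42)
  man <- make_manifest(100)
  # scramble file order relative to the manifest: reader must keep file order
  ord <- sample(100)
  sheet <- make_sheet(sprintf("smp%02d", 1:10))
  b <- matrix(runif(1000), 100,
              dimnames = list(man$probe_id[ord], sheet$sample_id))
  b[sample(1000, 20)] <- NA
  mm <- methyl_matrix(b, man[ord, ], sheet)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_beta_matrix(mm, path)
  back <- read_beta_matrix(path, man, sheet)
  expect_identical(rownames(back$beta), man$probe_id[ord])
  expect_identical(colnames(back$beta), sheet$sample_id)
  expect_lt(max(abs(back$beta - mm$beta), na.rm = TRUE), 1e-12)
  expect_identical(is.na(back$beta), is.na(mm$beta))
  expect_equal(back$probes$probe_id, man$probe_id[ord])
})

test_that("beta reader rejects out-of-range cells, duplicates and unknown probes", {
  man <- make_manifest(3)
  sheet <- make_sheet(c("s1", "s2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\ts1\ts2",
               "cg00001\t0.2\t0.3",
               "cg00002\t0.1\t1.3",
               "cg00003\t0.5\t0.6"), path)
  err <- tryCatch(read_beta_matrix(path, man, sheet), error = function(e) e)
  expect_s3_class(err, "mall_value_error")
  expect_match(conditionMessage(err), "cg00002")

  writeLines(c("probe_id\ts1\ts2",
               "cg00001\t0.2\t0.3",
               "cg00001\t0.1\t0.2"), path)
  expect_error(read_beta_matrix(path, man, sheet),
               class = "mall_format_error")

  writeLines(c("probe_id\ts1\ts2",
               "cgXXXXX\t0.2\t0.3"), path)
  expect_error(read_beta_matrix(path, man, sheet),
               class = "mall_format_error")
})

test_that("probe manifest round-trips losslessly for 1000 synthetic probes", {
  set.seed(7)
  man <- data.frame(
    probe_id = sprintf("cg%06d", 1:1000),
    chromosome = sample(mall_chromosomes(), 1000, replace = TRUE),
    position = sample.int(1e8, 1000),
    gene = ifelse(runif(1000) < 0.9, sprintf("G%04d", 1:1000), NA),
    cgi_relation = sample(c("island", "shore", "shelf", "open_sea", NA),
                          1000, replace = TRUE),
    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_probe_manifest(man, path)
  back <- read_probe_manifest(path)
  expect_identical(back, probe_annotation(man))
})

test_that("classifier serialization round-trips bit-comparably", {
  clf <- toy_classifier()
  path <- withr::local_tempfile(fileext = ".json")
  save_classifier(clf, path)
  back <- load_classifier(path)
  for (tid in names(clf$tasks)) {
    m1 <- clf$tasks[[tid]]$model; m2 <- back$tasks[[tid]]$model
    expect_identical(m2$feature_ids, m1$feature_ids)
    expect_lt(max(abs(m2$class_centroids - m1$class_centroids)), 1e-12)
    expect_lt(max(abs(m2$shrunken_offsets - m1$shrunken_offsets)), 1e-12)
    expect_lt(max(abs(m2$priors - m1$priors)), 1e-12)
    expect_lt(max(abs(m2$scale - m1$scale)), 1e-12)
    expect_equal(m2$delta, m1$delta, tolerance = 1e-12)
    expect_identical(back$tasks[[tid]]$consensus$consensus_sites,
                     clf$tasks[[tid]]$consensus$consensus_sites)
  }
  # identical predictions after the round-trip
  sim <- small_sim()
  s1 <- score_cohort(clf, impute_missing(sim$data), on_missing = "impute")
  s2 <- score_cohort(back, impute_missing(sim$data), on_missing = "impute")
  expect_lt(max(abs(s1 - s2)), 1e-12)
})

test_that("classifier loading fails loudly on truncation and version mismatch", {
  clf <- toy_classifier()
  path <- withr::local_tempfile(fileext = ".json")
  save_classifier(clf, path)
  txt <- readLines(path)
  writeLines(txt[1:(length(txt) %/% 2)], path)
  expect_error(load_classifier(path), class = "mall_format_error")
  save_classifier(clf, path)
  txt <- readLines(path)
  writeLines(sub("methylALL-classifier/1", "methylALL-classifier/99", txt),
             path)
  err <- tryCatch(load_classifier(path), error = function(e) e)
  expect_s3_class(err, "mall_format_error")
  expect_match(conditionMessage(err), "version")
})

test_that("an empty task list serializes and reloads as empty", {
  sim <- small_sim()
  clf <- build_consensus_classifier(sim$data, tasks = list(), seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  save_classifier(clf, path)
  back <- load_classifier(path)
  expect_length(back$tasks, 0)
  expect_equal(back$threshold, 0.5)
})

test_that("intensity matrices reject negatives and missing values", {
  man <- make_manifest(2)
  sheet <- make_sheet("s1")
  expect_error(intensity_matrix(matrix(c(-1, 2), 2), man, sheet, "total"),
               class = "mall_value_error")
  expect_error(intensity_matrix(matrix(c(NA, 2), 2), man, sheet, "total"),
               class = "mall_value_error")
})
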