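# Readers and writers for the on-disk formats: TAB-separated matrices with a
# literal header row (GEO series-matrix style), CSV/TSV manifests and sample
# sheets, and versioned JSON classifier files. Missing beta values are
# encoded as "NA". Readers never reorder probes or samples relative to file
# order.

read_delim_auto <- function(path) {
  if (!file.exists(path)) mall_format_error(paste0("file not found: ", path))
  as.data.frame(data.table::fread(path, sep = "auto", header = TRUE,
                                  na.strings = c("NA", ""),
                                  data.table = FALSE, showProgress = FALSE))
}

#' Read a probe manifest
#'
#' Delimited text (TSV or CSV) with columns `probe_id`, `chromosome`,
#' `position`, and optionally `gene`, `cgi_relation`. Unknown chromosome
#' strings are rejected.
#'
#' @param path file path.
#' @return validated probe annotation data.frame.
#' @export
read_probe_manifest <- function(path) probe_annotation(read_delim_auto(path))

#' Write a probe manifest
#' @param probes probe annotation table.
#' @param path output file path (TSV).
#' @return `path`, invisibly.
#' @export
write_probe_manifest <- function(probes, path) {
  probes <- probe_annotation(probes)
  data.table::fwrite(probes, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Delimited text with columns `sample_id`, `sample_class` (`ALL` or
#' `reference`), `sex` (`M`/`F`/`unknown`) and `subtype_label`.
#'
#' @param path file path.
#' @return validated sample sheet data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- read_delim_auto(path)
  for (cc in intersect(c("sex", "subtype_label"), names(df)))
    df[[cc]][is.na(df[[cc]])] <- "unknown"
  sample_sheet(df)
}

#' Write a sample sheet
#' @param samples sample sheet table.
#' @param path output file path (TSV).
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(samples, path) {
  data.table::fwrite(sample_sheet(samples), path, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(path)
}

read_matrix_file <- function(path, what = "beta") {
  if (!file.exists(path)) mall_format_error(paste0("file not found: ", path))
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = "NA", data.table = FALSE,
                          showProgress = FALSE)
  if (ncol(dt) < 2)
    mall_format_error(paste0(what, " matrix needs a probe id column plus at ",
                             "least one sample column: ", path))
  ids <- as.character(dt[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    mall_format_error(paste0("duplicate probe id(s) in ", what, " matrix: ",
                             paste(unique(dup)[1:min(5, length(unique(dup)))],
                                   collapse = ", ")))
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

# Align a matrix read from disk with manifest and sample sheet, preserving
# file order for both probes and samples.
align_matrix <- function(m, manifest, samples, what) {
  manifest <- probe_annotation(manifest)
  samples <- sample_sheet(samples)
  absent <- setdiff(rownames(m), manifest$probe_id)
  if (length(absent))
    mall_format_error(paste0("probe(s) absent from manifest: ",
                             paste(absent[1:min(5, length(absent))],
                                   collapse = ", ")))
  unknown <- setdiff(colnames(m), samples$sample_id)
  if (length(unknown))
    mall_format_error(paste0("sample column(s) absent from sample sheet: ",
                             paste(unknown, collapse = ", ")))
  pr <- manifest[match(rownames(m), manifest$probe_id), , drop = FALSE]
  sm <- samples[match(colnames(m), samples$sample_id), , drop = FALSE]
  rownames(pr) <- rownames(sm) <- NULL
  list(m = m, probes = pr, samples = sm)
}

#' Read a beta-value matrix
#'
#' TAB-separated text: header row of sample ids, first column probe ids,
#' missing cells written `NA`. Every probe must appear in the manifest and
#' every sample column in the sample sheet; values outside \[0,1\] beyond
#' `1e-9` raise an error naming probe and sample. Row/column order follows
#' the file.
#'
#' @param path file path.
#' @param manifest probe annotation table (or path readable by
#'   [read_probe_manifest()]).
#' @param samples sample sheet (or path readable by [read_sample_sheet()]).
#' @return a [methyl_matrix()].
#' @export
read_beta_matrix <- function(path, manifest, samples) {
  if (is.character(manifest) && length(manifest) == 1)
    manifest <- read_probe_manifest(manifest)
  if (is.character(samples) && length(samples) == 1)
    samples <- read_sample_sheet(samples)
  al <- align_matrix(read_matrix_file(path, "beta"), manifest, samples, "beta")
  methyl_matrix(al$m, al$probes, al$samples)
}

#' Write a beta-value matrix
#' @param data a `methyl_matrix`.
#' @param path output file path (TSV).
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(data, path) {
  stopifnot(inherits(data, "methyl_matrix"))
  df <- data.frame(probe_id = rownames(data$beta), data$beta,
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read an intensity matrix
#'
#' Same layout as the beta matrix; values must be complete and non-negative.
#'
#' @inheritParams read_beta_matrix
#' @param channel `"methylated"`, `"unmethylated"` or `"total"`.
#' @return an [intensity_matrix()].
#' @export
read_intensity_matrix <- function(path, manifest, samples,
                                  channel = c("methylated", "unmethylated",
                                              "total")) {
  channel <- match.arg(channel)
  if (is.character(manifest) && length(manifest) == 1)
    manifest <- read_probe_manifest(manifest)
  if (is.character(samples) && length(samples) == 1)
    samples <- read_sample_sheet(samples)
  al <- align_matrix(read_matrix_file(path, "intensity"), manifest, samples,
                     "intensity")
  intensity_matrix(al$m, al$probes, al$samples, channel = channel)
}

#' Write an intensity matrix
#' @param x an `intensity_matrix`.
#' @param path output file path (TSV).
#' @return `path`, invisibly.
#' @export
write_intensity_matrix <- function(x, path) {
  stopifnot(inherits(x, "intensity_matrix"))
  df <- data.frame(probe_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

classifier_format_version <- function() "methylALL-classifier/1"

model_to_list <- function(m) {
  if (is.null(m)) return(NULL)
  list(
    feature_ids = as.list(m$feature_ids),
    classes = as.list(m$classes),
    overall_centroid = as.list(unname(m$overall_centroid)),
    class_centroids = lapply(seq_along(m$classes),
                             function(k) as.list(unname(m$class_centroids[, k]))),
    pooled_sd = as.list(unname(m$pooled_sd)),
    fudge = m$fudge,
    scale = as.list(unname(m$scale)),
    class_sizes = as.list(unname(m$class_sizes)),
    priors = as.list(unname(m$priors)),
    delta = m$delta,
    shrunken_offsets = lapply(seq_along(m$classes),
                              function(k) as.list(unname(m$shrunken_offsets[, k])))
  )
}

model_from_list <- function(l) {
  if (is.null(l)) return(NULL)
  classes <- as.character(unlist(l$classes))
  fid <- as.character(unlist(l$feature_ids))
  two_col <- function(x) {
    m <- do.call(cbind, lapply(x, function(v) as.numeric(unlist(v))))
    dimnames(m) <- list(fid, classes)
    m
  }
  m <- list(
    feature_ids = fid,
    classes = classes,
    overall_centroid = stats::setNames(as.numeric(unlist(l$overall_centroid)), fid),
    class_centroids = two_col(l$class_centroids),
    pooled_sd = stats::setNames(as.numeric(unlist(l$pooled_sd)), fid),
    fudge = as.numeric(l$fudge),
    scale = stats::setNames(as.numeric(unlist(l$scale)), fid),
    class_sizes = stats::setNames(as.numeric(unlist(l$class_sizes)), classes),
    priors = stats::setNames(as.numeric(unlist(l$priors)), classes),
    delta = as.numeric(l$delta),
    shrunken_offsets = two_col(l$shrunken_offsets)
  )
  m$shrunken_centroids <- shrunken_centroids_from(m)
  class(m) <- "nsc_model"
  m
}

#' Save / load a trained subtype classifier
#'
#' The on-disk format is versioned, human-readable JSON carrying, per task,
#' the consensus CpG list with fold counts and the full NSC model (centroids,
#' pooled dispersions, fudge factor, priors, shrinkage threshold). A loaded
#' classifier reproduces all numbers of the saved one to better than 1e-12,
#' so predictions round-trip exactly to that precision. Loading a file with a
#' different format version fails loudly.
#'
#' @param classifier a `subtype_classifier` (see
#'   [build_consensus_classifier()]).
#' @param path file path.
#' @return `save_classifier()` returns `path` invisibly; `load_classifier()`
#'   returns the classifier.
#' @export
save_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "subtype_classifier"))
  tasks <- lapply(classifier$tasks, function(tk) {
    list(
      task_id = tk$task$task_id,
      type = tk$task$type,
      chromosome_filter = tk$task$chromosome_filter,
      active = tk$active,
      delta = tk$delta,
      consensus_sites = as.list(tk$consensus$consensus_sites),
      site_counts = as.list(tk$consensus$site_counts[tk$consensus$consensus_sites]),
      min_folds = tk$consensus$min_folds,
      n_total_folds = tk$consensus$n_total_folds,
      model = model_to_list(tk$model)
    )
  })
  payload <- list(
    format = classifier_format_version(),
    threshold = classifier$threshold,
    iamp21_override = classifier$iamp21_override,
    config = classifier$config,
    tasks = unname(tasks)
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  if (!file.exists(path)) mall_format_error(paste0("file not found: ", path))
  payload <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) mall_format_error(
      paste0("cannot parse classifier file '", path, "': ", conditionMessage(e))))
  if (!identical(payload$format, classifier_format_version()))
    mall_format_error(paste0(
      "classifier format version mismatch: file has '",
      payload$format %||% "<missing>", "', this build reads '",
      classifier_format_version(), "'"))
  tasks <- lapply(payload$tasks, function(tk) {
    sites <- as.character(unlist(tk$consensus_sites))
    counts <- stats::setNames(as.integer(unlist(tk$site_counts)), sites)
    list(
      task = mall_task(tk$task_id, tk$type, tk$chromosome_filter),
      active = isTRUE(tk$active),
      delta = if (is.null(tk$delta)) NA_real_ else as.numeric(tk$delta),
      consensus = structure(list(task_id = tk$task_id, site_counts = counts,
                                 consensus_sites = sites,
                                 min_folds = as.integer(tk$min_folds),
                                 n_total_folds = as.integer(tk$n_total_folds)),
                            class = "consensus_set"),
      model = model_from_list(tk$model)
    )
  })
  names(tasks) <- vapply(tasks, function(tk) tk$task$task_id, character(1))
  structure(list(threshold = as.numeric(payload$threshold),
                 iamp21_override = isTRUE(payload$iamp21_override),
                 config = payload$config, tasks = tasks),
            class = "subtype_classifier")
}
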