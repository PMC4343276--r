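# Typed containers for methylation data: probe annotations, sample sheets,
# beta-value matrices and intensity matrices. Coordinates are 1-based, as in
# the Illumina 450k manifest.

#' Chromosome, subtype and task vocabularies
#'
#' `mall_chromosomes()` returns the allowed chromosome names (`chr1`..`chr22`,
#' `chrX`, `chrY`); `mall_subtypes()` the eight recurrent ALL subtypes;
#' `mall_task_ids()` the ten classification tasks (reference, the eight
#' subtypes, and sex).
#'
#' @return character vector.
#' @export
mall_chromosomes <- function() paste0("chr", c(1:22, "X", "Y"))

#' @rdname mall_chromosomes
#' @export
mall_subtypes <- function() {
  c("T-ALL", "HeH", "t(12;21)", "11q23/MLL", "t(1;19)", "dic(9;20)",
    "t(9;22)", "iAMP21")
}

#' @rdname mall_chromosomes
#' @export
mall_task_ids <- function() c("reference", mall_subtypes(), "sex")

cgi_levels <- function() c("island", "shore", "shelf", "open_sea")

#' Validate a probe annotation table
#'
#' Checks the manifest invariants: required columns, unique probe ids,
#' chromosomes from the allowed set, 1-based positions >= 1, and (when
#' present) CpG-island relations from `island`/`shore`/`shelf`/`open_sea`.
#'
#' @param df data.frame with columns `probe_id`, `chromosome`, `position` and
#'   optionally `gene`, `cgi_relation` (either may be `NA`).
#' @return the validated data.frame (optional columns filled with `NA`).
#' @export
probe_annotation <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("probe_id", "chromosome", "position")
  miss <- setdiff(need, names(df))
  if (length(miss))
    mall_format_error(paste0("probe manifest is missing required column(s): ",
                             paste(miss, collapse = ", ")))
  if (!"gene" %in% names(df)) df$gene <- NA_character_
  if (!"cgi_relation" %in% names(df)) df$cgi_relation <- NA_character_
  df <- df[, c(need, "gene", "cgi_relation")]
  df$probe_id <- as.character(df$probe_id)
  df$chromosome <- as.character(df$chromosome)
  df$position <- as.integer(df$position)
  df$gene <- as.character(df$gene)
  df$cgi_relation <- as.character(df$cgi_relation)
  df$gene[!is.na(df$gene) & df$gene == ""] <- NA_character_
  df$cgi_relation[!is.na(df$cgi_relation) & df$cgi_relation == ""] <- NA_character_
  dup <- df$probe_id[duplicated(df$probe_id)]
  if (length(dup))
    mall_format_error(paste0("duplicate probe id(s) in manifest: ",
                             paste(unique(dup)[1:min(5, length(unique(dup)))],
                                   collapse = ", ")))
  bad <- setdiff(unique(df$chromosome), mall_chromosomes())
  if (length(bad))
    mall_format_error(paste0("unknown chromosome(s) in manifest: ",
                             paste(bad, collapse = ", ")))
  if (anyNA(df$position) || any(df$position < 1L))
    mall_format_error("probe positions must be integers >= 1 (1-based)")
  badr <- setdiff(stats::na.omit(unique(df$cgi_relation)), cgi_levels())
  if (length(badr))
    mall_format_error(paste0("unknown cgi_relation value(s): ",
                             paste(badr, collapse = ", ")))
  rownames(df) <- NULL
  df
}

#' Validate a sample sheet
#'
#' Enforces unique sample ids, `sample_class` in `ALL`/`reference`, `sex` in
#' `M`/`F`/`unknown`, subtype labels from [mall_subtypes()] or `unknown`, and
#' that reference samples carry `subtype_label = "unknown"`.
#'
#' @param df data.frame with columns `sample_id`, `sample_class`, `sex`,
#'   `subtype_label`.
#' @return the validated data.frame.
#' @export
sample_sheet <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("sample_id", "sample_class", "sex", "subtype_label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    mall_format_error(paste0("sample sheet is missing required column(s): ",
                             paste(miss, collapse = ", ")))
  df <- df[, need]
  for (cc in need) df[[cc]] <- as.character(df[[cc]])
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    mall_format_error(paste0("duplicate sample id(s): ",
                             paste(unique(dup), collapse = ", ")))
  if (!all(df$sample_class %in% c("ALL", "reference")))
    mall_format_error("sample_class must be 'ALL' or 'reference'")
  if (!all(df$sex %in% c("M", "F", "unknown")))
    mall_format_error("sex must be 'M', 'F' or 'unknown'")
  if (!all(df$subtype_label %in% c(mall_subtypes(), "unknown")))
    mall_format_error("subtype_label must be a known subtype or 'unknown'")
  bad <- df$sample_class == "reference" & df$subtype_label != "unknown"
  if (any(bad))
    mall_format_error(paste0("reference samples must have subtype_label ",
                             "'unknown': ", paste(df$sample_id[bad], collapse = ", ")))
  rownames(df) <- NULL
  df
}

#' Construct a methylation beta-value matrix container
#'
#' Bundles a probes-by-samples matrix of beta values in \[0,1\] with its probe
#' annotations and sample metadata. Missing values are carried as `NA`, never
#' imputed here. Values outside \[0,1\] by more than `tol` raise an error
#' naming the offending cell; values within `tol` are clamped.
#'
#' @param beta numeric matrix, rows = probes, columns = samples.
#' @param probes probe annotation table (see [probe_annotation()]); row order
#'   must match `beta`.
#' @param samples sample sheet (see [sample_sheet()]); row order must match
#'   the columns of `beta`.
#' @param tol numeric bound tolerance (default `1e-9`).
#' @return an object of class `methyl_matrix` with elements `beta`, `probes`,
#'   `samples`.
#' @export
methyl_matrix <- function(beta, probes, samples, tol = 1e-9) {
  probes <- probe_annotation(probes)
  samples <- sample_sheet(samples)
  beta <- as.matrix(beta)
  storage.mode(beta) <- "double"
  if (nrow(beta) != nrow(probes))
    mall_format_error("beta row count does not match probe annotation length")
  if (ncol(beta) != nrow(samples))
    mall_format_error("beta column count does not match sample sheet length")
  dimnames(beta) <- list(probes$probe_id, samples$sample_id)
  bad <- which(!is.na(beta) & (beta < -tol | beta > 1 + tol), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1, 1]; j <- bad[1, 2]
    mall_value_error(sprintf(
      "beta value out of [0,1]: %.6g at probe '%s', sample '%s'",
      beta[i, j], probes$probe_id[i], samples$sample_id[j]))
  }
  beta[!is.na(beta) & beta < 0] <- 0
  beta[!is.na(beta) & beta > 1] <- 1
  structure(list(beta = beta, probes = probes, samples = samples),
            class = "methyl_matrix")
}

#' @export
print.methyl_matrix <- function(x, ...) {
  cat(sprintf("<methyl_matrix> %d probes x %d samples (%.2f%% missing)\n",
              nrow(x$beta), ncol(x$beta), 100 * mean(is.na(x$beta))))
  invisible(x)
}

#' @export
dim.methyl_matrix <- function(x) dim(x$beta)

# Column subset preserving annotations (internal).
mm_subset <- function(x, probes = NULL, samples = NULL) {
  b <- x$beta
  pr <- x$probes
  sm <- x$samples
  if (!is.null(probes)) {
    b <- b[probes, , drop = FALSE]
    pr <- pr[probes, , drop = FALSE]
    rownames(pr) <- NULL
  }
  if (!is.null(samples)) {
    b <- b[, samples, drop = FALSE]
    sm <- sm[samples, , drop = FALSE]
    rownames(sm) <- NULL
  }
  structure(list(beta = b, probes = pr, samples = sm), class = "methyl_matrix")
}

#' Construct an intensity matrix container
#'
#' Non-negative array intensities (methylated, unmethylated, or their total)
#' with linked probe and sample metadata.
#'
#' @param values numeric matrix, rows = probes, columns = samples; must be
#'   non-negative and complete.
#' @param probes probe annotation table.
#' @param samples sample sheet.
#' @param channel one of `"methylated"`, `"unmethylated"`, `"total"`.
#' @return an object of class `intensity_matrix`.
#' @export
intensity_matrix <- function(values, probes, samples,
                             channel = c("methylated", "unmethylated", "total")) {
  channel <- match.arg(channel)
  probes <- probe_annotation(probes)
  samples <- sample_sheet(samples)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != nrow(probes) || ncol(values) != nrow(samples))
    mall_format_error("intensity dimensions do not match annotations")
  if (anyNA(values))
    mall_value_error("intensity matrix must be complete (no missing values)")
  if (any(values < 0))
    mall_value_error("intensity values must be non-negative")
  dimnames(values) <- list(probes$probe_id, samples$sample_id)
  structure(list(values = values, probes = probes, samples = samples,
                 channel = channel),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("<intensity_matrix:%s> %d probes x %d samples\n",
              x$channel, nrow(x$values), ncol(x$values)))
  invisible(x)
}
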