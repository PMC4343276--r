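# Applying the trained classifier: per-task posterior scores, the decision
# taxonomy (reference_flag / single_class / multi_class / non_class), the
# iAMP21-and-HeH override, and the separately reported sex call.

#' Score a cohort against every task of a classifier
#'
#' Returns the positive-class posterior of each active task for each sample.
#' A consensus probe absent from the input (or a missing cell on one) raises
#' an error listing the probes, unless `on_missing = "impute"`, in which
#' case the model's training mean (overall centroid) is substituted.
#'
#' @param classifier a `subtype_classifier`.
#' @param data a `methyl_matrix`.
#' @param on_missing `"error"` (default) or `"impute"`.
#' @return numeric matrix, samples x active tasks.
#' @export
score_cohort <- function(classifier, data, on_missing = c("error", "impute")) {
  stopifnot(inherits(classifier, "subtype_classifier"),
            inherits(data, "methyl_matrix"))
  on_missing <- match.arg(on_missing)
  active <- Filter(function(tk) isTRUE(tk$active), classifier$tasks)
  out <- matrix(NA_real_, ncol(data$beta), length(active),
                dimnames = list(colnames(data$beta),
                                vapply(active, function(tk) tk$task$task_id,
                                       character(1))))
  for (tk in active) {
    fid <- tk$model$feature_ids
    absent <- setdiff(fid, rownames(data$beta))
    present <- intersect(fid, rownames(data$beta))
    x <- matrix(NA_real_, length(fid), ncol(data$beta),
                dimnames = list(fid, colnames(data$beta)))
    x[present, ] <- data$beta[present, , drop = FALSE]
    if (anyNA(x)) {
      if (on_missing == "error") {
        bad <- unique(c(absent, rownames(x)[rowSums(is.na(x)) > 0]))
        mall_prediction_error(paste0(
          "task '", tk$task$task_id, "': missing consensus probe value(s): ",
          paste(bad[1:min(10, length(bad))], collapse = ", ")))
      }
      na_idx <- which(is.na(x))
      x[na_idx] <- tk$model$overall_centroid[(na_idx - 1) %% nrow(x) + 1]
    }
    out[, tk$task$task_id] <- predict_nsc(tk$model, x)[, tk$task$task_id]
  }
  out
}

#' Score a single sample
#'
#' @inheritParams score_cohort
#' @param beta named numeric vector of beta values (probe ids as names), or
#'   a one-column matrix.
#' @return named numeric vector of per-task positive posteriors.
#' @export
score_sample <- function(classifier, beta, on_missing = c("error", "impute")) {
  if (is.null(dim(beta))) {
    beta <- matrix(beta, ncol = 1, dimnames = list(names(beta), "sample"))
  }
  probes <- data.frame(probe_id = rownames(beta), chromosome = "chr1",
                       position = seq_len(nrow(beta)))
  samples <- data.frame(sample_id = colnames(beta), sample_class = "ALL",
                        sex = "unknown", subtype_label = "unknown")
  data <- methyl_matrix(beta, probes, samples)
  drop(score_cohort(classifier, data, on_missing = on_missing)[1, ])
}

#' Decision taxonomy for one sample's task scores
#'
#' Positives are the subtype tasks whose score strictly exceeds `threshold`.
#' Rules, in order of precedence: (1) a reference score above threshold
#' flags the sample (`reference_flag`, suspected low blast count) and
#' preempts subtype assignment; (2) if both iAMP21 and HeH are positive, the
#' sample counts as iAMP21 only (the HeH positive is removed and a note is
#' recorded) — disable with `iamp21_override = FALSE`; (3) exactly one
#' positive gives `single_class`, two or more `multi_class`, none
#' `non_class`. A score exactly at the threshold is not positive. The sex
#' call (`F` if the sex score exceeds the threshold, else `M`) is reported
#' separately and never affects the category.
#'
#' @param scores named numeric vector of task scores (names from
#'   [mall_task_ids()]; subtype tasks required, `reference`/`sex` optional).
#' @param threshold positivity threshold (default 0.5, strict `>`).
#' @param iamp21_override apply rule (2) (default `TRUE`).
#' @return list with `category`, `assigned_subtype` (`NA` unless
#'   `single_class`), `positive_tasks`, `sex_call`, `notes`.
#' @export
assign_category <- function(scores, threshold = 0.5, iamp21_override = TRUE) {
  stopifnot(!is.null(names(scores)))
  subtype_scores <- scores[names(scores) %in% mall_subtypes()]
  positives <- names(subtype_scores)[subtype_scores > threshold]
  notes <- character(0)
  sex_call <- if ("sex" %in% names(scores)) {
    if (scores[["sex"]] > threshold) "F" else "M"
  } else NA_character_
  if ("reference" %in% names(scores) && scores[["reference"]] > threshold) {
    return(list(category = "reference_flag", assigned_subtype = NA_character_,
                positive_tasks = positives, sex_call = sex_call,
                notes = "high reference score: suspected low blast count"))
  }
  if (iamp21_override && all(c("iAMP21", "HeH") %in% positives)) {
    positives <- setdiff(positives, "HeH")
    notes <- c(notes, "iAMP21+HeH pattern counted as iAMP21 only")
  }
  category <- if (length(positives) == 1) "single_class"
  else if (length(positives) >= 2) "multi_class" else "non_class"
  list(category = category,
       assigned_subtype = if (length(positives) == 1) positives else NA_character_,
       positive_tasks = positives, sex_call = sex_call, notes = notes)
}

#' Classify a cohort
#'
#' Scores every sample against every active task and applies the decision
#' taxonomy. When the sample sheet carries a known sex, a disagreement with
#' the methylation sex call is reported in the `sex_qc` column (a guard
#' against sample mix-ups).
#'
#' @inheritParams score_cohort
#' @return a `cohort_calls` object: `outcomes` (one row per sample:
#'   per-task score columns, `positive_tasks`, `category`,
#'   `assigned_subtype`, `sex_call`, `sex_qc`, `notes`) and
#'   `category_counts`.
#' @export
classify_cohort <- function(classifier, data,
                            on_missing = c("error", "impute")) {
  stopifnot(inherits(classifier, "subtype_classifier"))
  scores <- score_cohort(classifier, data, on_missing = on_missing)
  n <- nrow(scores)
  cats <- character(n); assigned <- character(n); sexes <- character(n)
  pos <- character(n); notes <- character(n)
  for (i in seq_len(n)) {
    sc <- stats::setNames(as.numeric(scores[i, ]), colnames(scores))
    a <- assign_category(sc, threshold = classifier$threshold,
                         iamp21_override = classifier$iamp21_override)
    cats[i] <- a$category
    assigned[i] <- a$assigned_subtype
    sexes[i] <- a$sex_call
    pos[i] <- paste(a$positive_tasks, collapse = ";")
    notes[i] <- paste(a$notes, collapse = ";")
  }
  sheet_sex <- data$samples$sex[match(rownames(scores),
                                      data$samples$sample_id)]
  sex_qc <- ifelse(sheet_sex %in% c("M", "F") & !is.na(sexes) &
                     sexes != sheet_sex, "sex_mismatch", "")
  outcomes <- data.frame(sample_id = rownames(scores),
                         stats::setNames(as.data.frame(scores),
                                         paste0("score.", colnames(scores))),
                         positive_tasks = pos, category = cats,
                         assigned_subtype = assigned, sex_call = sexes,
                         sex_qc = sex_qc, notes = notes,
                         check.names = FALSE, stringsAsFactors = FALSE,
                         row.names = NULL)
  counts <- table(factor(cats, levels = c("reference_flag", "single_class",
                                          "multi_class", "non_class")))
  structure(list(outcomes = outcomes, category_counts = counts),
            class = "cohort_calls")
}

#' @export
print.cohort_calls <- function(x, ...) {
  cat(sprintf("<cohort_calls> %d samples\n", nrow(x$outcomes)))
  print(x$category_counts)
  invisible(x)
}

#' Write cohort calls to a TSV report
#' @param calls a `cohort_calls` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  stopifnot(inherits(calls, "cohort_calls"))
  data.table::fwrite(calls$outcomes, path, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(path)
}
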