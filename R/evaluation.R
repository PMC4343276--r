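# External (nested) cross-validation of the whole design procedure, and the
# three-way confusion summary (single-correct / multi-including-correct /
# incorrect-or-none).

#' Nested external cross-validation of the classifier design
#'
#' Outer stratified `n_outer`-fold cross-validation (strata: subtype label,
#' with reference samples as their own stratum). Within each outer training
#' set the full consensus procedure — repeated cross-validation, consensus
#' extraction, final fit — is run from scratch; the held-out samples are
#' then scored and categorized. Test samples never influence consensus
#' selection (asserted). For each task and outer fold, sensitivity is the
#' fraction of true members whose task score exceeds the threshold and
#' specificity the fraction of non-members at or below it (raw scores,
#' before the iAMP21 override, so cross-scoring tasks show up as reduced
#' specificity). A subtype absent from a fold's test set contributes no
#' sensitivity term for that fold (recorded as `NA`, not zero). Because the
#' category taxonomy may count a multi-class call containing the true label
#' either way, the overall summary reports both tallies side by side.
#'
#' @inheritParams build_consensus_classifier
#' @param n_outer outer folds (default 5).
#' @param outer_repeats repeats of the outer loop (default 1).
#' @return a `performance_table`: `per_task` (mean/SD sensitivity and
#'   specificity over outer folds, min/max/mean consensus CpG counts),
#'   `overall` (fractions single-correct, multi-with-correct,
#'   incorrect-or-none over all outer test samples; they sum to 1),
#'   `sensitivity_including_multi` (per-task fraction of true members that
#'   were positive counting multi-class calls), and `per_fold` details.
#' @export
external_cv <- function(data, tasks = default_tasks(), n_outer = 5,
                        outer_repeats = 1, n_repeats = 5, n_folds = 5,
                        min_folds = 17, seed = 1, grid_size = 30,
                        threshold = 0.5, iamp21_override = TRUE,
                        prior_policy = "class", max_missing = 0.05) {
  stopifnot(inherits(data, "methyl_matrix"))
  data <- impute_missing(data, max_missing)
  sm <- data$samples
  eligible <- sm$sample_class == "reference" |
    (sm$sample_class == "ALL" & sm$subtype_label != "unknown")
  if (!all(eligible)) {
    warning(sprintf("%d sample(s) with unknown subtype excluded from external CV",
                    sum(!eligible)), call. = FALSE)
    data <- mm_subset(data, samples = which(eligible))
    sm <- data$samples
  }
  strata <- ifelse(sm$sample_class == "reference", ".reference",
                   sm$subtype_label)
  task_ids <- names(tasks)
  fold_rows <- list()
  outcome_rows <- list()
  truth_all <- character(0)
  fold_no <- 0L
  for (rep_i in seq_len(outer_repeats)) {
    folds <- stratified_folds(sm$sample_id, strata, n_outer,
                              derive_seed(seed, 900000 + rep_i))
    for (f in seq_len(n_outer)) {
      fold_no <- fold_no + 1L
      test_idx <- which(folds == f)
      train_idx <- which(folds != f)
      stopifnot(length(intersect(sm$sample_id[test_idx],
                                 sm$sample_id[train_idx])) == 0)
      train <- mm_subset(data, samples = train_idx)
      test <- mm_subset(data, samples = test_idx)
      clf <- build_consensus_classifier(
        train, tasks = tasks, n_repeats = n_repeats, n_folds = n_folds,
        min_folds = min_folds, seed = derive_seed(seed, 910000 + fold_no),
        grid_size = grid_size, threshold = threshold,
        iamp21_override = iamp21_override, prior_policy = prior_policy,
        max_missing = max_missing)
      scores <- score_cohort(clf, test)
      for (tid in task_ids) {
        tk <- clf$tasks[[tid]]
        in_scope <- task_scope(tk$task, test$samples)
        truth_pos <- task_positive(tk$task, test$samples) & in_scope
        if (!isTRUE(tk$active)) {
          fold_rows[[length(fold_rows) + 1]] <- data.frame(
            fold = fold_no, task = tid, sensitivity = NA_real_,
            specificity = NA_real_, n_cpgs = 0L,
            stringsAsFactors = FALSE)
          next
        }
        sc <- scores[, tid]
        pos_call <- sc > threshold
        sens <- if (any(truth_pos)) mean(pos_call[truth_pos]) else NA_real_
        neg <- in_scope & !truth_pos
        spec <- if (any(neg)) mean(!pos_call[neg]) else NA_real_
        fold_rows[[length(fold_rows) + 1]] <- data.frame(
          fold = fold_no, task = tid, sensitivity = sens,
          specificity = spec,
          n_cpgs = length(tk$consensus$consensus_sites),
          stringsAsFactors = FALSE)
      }
      calls <- classify_cohort(clf, test)
      is_all <- test$samples$sample_class == "ALL"
      oc <- calls$outcomes[is_all, , drop = FALSE]
      outcome_rows[[length(outcome_rows) + 1]] <- oc
      truth_all <- c(truth_all,
                     stats::setNames(test$samples$subtype_label[is_all],
                                     test$samples$sample_id[is_all]))
    }
  }
  per_fold <- do.call(rbind, fold_rows)
  # folds may disagree on score columns when a task went inactive in some
  # training sets; align on the union before stacking
  all_cols <- unique(unlist(lapply(outcome_rows, names)))
  outcome_rows <- lapply(outcome_rows, function(d) {
    for (cc in setdiff(all_cols, names(d))) d[[cc]] <- NA_real_
    d[, all_cols, drop = FALSE]
  })
  outcomes <- do.call(rbind, outcome_rows)
  agg <- lapply(task_ids, function(tid) {
    d <- per_fold[per_fold$task == tid, ]
    data.frame(task = tid,
               mean_sensitivity = mean(d$sensitivity, na.rm = TRUE),
               sd_sensitivity = stats::sd(d$sensitivity[!is.na(d$sensitivity)]),
               mean_specificity = mean(d$specificity, na.rm = TRUE),
               sd_specificity = stats::sd(d$specificity[!is.na(d$specificity)]),
               min_cpgs = min(d$n_cpgs), max_cpgs = max(d$n_cpgs),
               mean_cpgs = mean(d$n_cpgs), stringsAsFactors = FALSE)
  })
  per_task <- do.call(rbind, agg)
  overall <- confusion_summary(outcomes, truth_all)
  sens_multi <- vapply(mall_subtypes(), function(st) {
    members <- outcomes$sample_id[truth_all[outcomes$sample_id] == st]
    if (!length(members)) return(NA_real_)
    rows <- outcomes[outcomes$sample_id %in% members, ]
    hit <- (rows$category == "single_class" & rows$assigned_subtype == st) |
      (rows$category == "multi_class" &
         vapply(strsplit(rows$positive_tasks, ";"),
                function(p) st %in% p, logical(1)))
    mean(hit)
  }, numeric(1))
  structure(list(per_task = per_task, overall = overall,
                 sensitivity_including_multi = sens_multi,
                 per_fold = per_fold, outcomes = outcomes),
            class = "performance_table")
}

#' @export
print.performance_table <- function(x, ...) {
  cat("<performance_table>\n")
  print(x$per_task, digits = 3, row.names = FALSE)
  cat(sprintf("overall: single-correct %.3f, multi-with-correct %.3f, incorrect-or-none %.3f\n",
              x$overall[1], x$overall[2], x$overall[3]))
  invisible(x)
}

#' Write a performance table to TSV
#' @param perf a `performance_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_performance <- function(perf, path) {
  stopifnot(inherits(perf, "performance_table"))
  data.table::fwrite(perf$per_task, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Three-way confusion summary
#'
#' Partitions labeled samples into: assigned to one single correct subtype;
#' assigned to multiple subtypes including the correct one; assigned to an
#' incorrect subtype or none (this also absorbs reference-flagged samples
#' and single assignments to a wrong subtype). The three fractions sum to 1.
#'
#' @param outcomes outcome table from [classify_cohort()] (`$outcomes`), or
#'   a `cohort_calls` object.
#' @param truth named character vector (sample id -> true subtype). Samples
#'   with unknown truth are excluded with a warning.
#' @return named numeric vector `single_correct`, `multi_with_correct`,
#'   `incorrect_or_none`.
#' @export
confusion_summary <- function(outcomes, truth) {
  if (inherits(outcomes, "cohort_calls")) outcomes <- outcomes$outcomes
  stopifnot(!is.null(names(truth)))
  tr <- truth[outcomes$sample_id]
  unknown <- is.na(tr) | !(tr %in% mall_subtypes())
  if (any(unknown)) {
    warning(sprintf("%d sample(s) with unknown truth label excluded",
                    sum(unknown)), call. = FALSE)
    outcomes <- outcomes[!unknown, , drop = FALSE]
    tr <- tr[!unknown]
  }
  n <- nrow(outcomes)
  if (n == 0)
    return(c(single_correct = NA_real_, multi_with_correct = NA_real_,
             incorrect_or_none = NA_real_))
  single <- outcomes$category == "single_class" &
    outcomes$assigned_subtype == tr
  multi <- outcomes$category == "multi_class" &
    mapply(function(p, t) t %in% strsplit(p, ";")[[1]],
           outcomes$positive_tasks, tr)
  c(single_correct = sum(single) / n,
    multi_with_correct = sum(multi) / n,
    incorrect_or_none = (n - sum(single) - sum(multi)) / n)
}
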