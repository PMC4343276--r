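# Consensus feature selection: ten one-vs-rest tasks, 5x5 repeated
# stratified cross-validation per task with per-fold shrinkage tuning, and
# the 17-of-25-folds consensus rule; plus the final classifier trained on
# the consensus CpG sites.

#' Task definitions for the ten one-vs-rest classifiers
#'
#' `mall_task()` builds a single task; `default_tasks()` returns the full
#' set: leukemic-vs-reference, female-vs-male, and each of the eight ALL
#' subtypes against the other subtypes. Subtype and reference tasks use
#' autosomal probes only; the sex task uses all chromosomes except Y.
#'
#' @param task_id one of [mall_task_ids()].
#' @param type `"reference"`, `"subtype"` or `"sex"`; inferred from
#'   `task_id` when omitted.
#' @param chromosome_filter `"autosomes_only"` or `"all_but_Y"`; inferred
#'   when omitted.
#' @return `mall_task()`: a `mall_task` object; `default_tasks()`: a named
#'   list of ten of them.
#' @export
mall_task <- function(task_id, type = NULL, chromosome_filter = NULL) {
  if (!task_id %in% mall_task_ids())
    mall_config_error(paste0("unknown task id: ", task_id))
  type <- type %||% if (task_id == "reference") "reference"
  else if (task_id == "sex") "sex" else "subtype"
  chromosome_filter <- chromosome_filter %||%
    if (type == "sex") "all_but_Y" else "autosomes_only"
  structure(list(task_id = task_id, type = type,
                 chromosome_filter = chromosome_filter),
            class = "mall_task")
}

#' @rdname mall_task
#' @export
default_tasks <- function() {
  ids <- mall_task_ids()
  stats::setNames(lapply(ids, mall_task), ids)
}

# Which samples participate in a task's training, and which are positive.
task_scope <- function(task, samples) {
  switch(task$type,
         reference = rep(TRUE, nrow(samples)),
         sex = samples$sex %in% c("M", "F"),
         subtype = samples$sample_class == "ALL" &
           samples$subtype_label != "unknown")
}

task_positive <- function(task, samples) {
  switch(task$type,
         reference = samples$sample_class == "reference",
         sex = samples$sex == "F",
         subtype = samples$subtype_label == task$task_id)
}

task_probe_filter <- function(task, probes) {
  switch(task$chromosome_filter,
         autosomes_only = !probes$chromosome %in% c("chrX", "chrY"),
         all_but_Y = probes$chromosome != "chrY",
         mall_config_error(paste0("unknown chromosome filter: ",
                                  task$chromosome_filter)))
}

#' Impute missing beta values
#'
#' Probes with more than `max_missing` missing cells are dropped; remaining
#' missing cells are replaced by the probe's mean over observed samples.
#' Fully deterministic; a no-op on complete data.
#'
#' @param data a `methyl_matrix`.
#' @param max_missing maximum tolerated missing fraction per probe
#'   (default 0.05).
#' @return a complete `methyl_matrix`.
#' @export
impute_missing <- function(data, max_missing = 0.05) {
  stopifnot(inherits(data, "methyl_matrix"))
  if (!anyNA(data$beta)) return(data)
  frac <- rowMeans(is.na(data$beta))
  keep <- which(frac <= max_missing)
  data <- mm_subset(data, probes = keep)
  na_idx <- which(is.na(data$beta))
  if (length(na_idx)) {
    rm_ <- rowMeans(data$beta, na.rm = TRUE)
    data$beta[na_idx] <- rm_[(na_idx - 1) %% nrow(data$beta) + 1]
  }
  data
}

#' Consensus CpG sites for one task by repeated cross-validation
#'
#' Runs `n_repeats` rounds of stratified `n_folds`-fold cross-validation on
#' the task's training scope. In each of the `n_repeats * n_folds` folds the
#' shrinkage threshold is tuned by a nested internal cross-validation on the
#' fold's training portion ([select_delta()]), an NSC model is fitted at the
#' tuned threshold, and its surviving CpG sites are tallied. Sites surviving
#' in at least `min_folds` of the folds form the consensus set. Deterministic
#' given `seed`; fold assignment is keyed by sorted sample ids, so the result
#' does not depend on input column order.
#'
#' If the minority class holds fewer than `n_folds` samples, the fold count
#' is reduced so each fold receives one minority sample (with a warning) and
#' `min_folds` is rescaled proportionally to the reduced fold total. An empty
#' consensus set is returned with a warning, not an error.
#'
#' @param data a complete `methyl_matrix` (see [impute_missing()]).
#' @param task a `mall_task`.
#' @param n_repeats repeats of the cross-validation (default 5).
#' @param n_folds folds per repeat (default 5).
#' @param min_folds consensus threshold: minimum number of folds a site must
#'   survive in (default 17 of the 25 folds).
#' @param seed integer seed.
#' @param grid_size size of the shrinkage-threshold grid (default 30).
#' @param prior_policy passed to the NSC fits.
#' @return a `consensus_set`: `task_id`, `site_counts` (named tally over
#'   sites that survived at least once), `consensus_sites`, `min_folds`,
#'   `n_total_folds`, and the per-fold tuned `deltas`.
#' @export
consensus_sites <- function(data, task, n_repeats = 5, n_folds = 5,
                            min_folds = 17, seed = 1, grid_size = 30,
                            prior_policy = "class") {
  stopifnot(inherits(data, "methyl_matrix"), inherits(task, "mall_task"))
  pidx <- which(task_probe_filter(task, data$probes))
  sidx <- which(task_scope(task, data$samples))
  x <- data$beta[pidx, sidx, drop = FALSE]
  if (anyNA(x))
    mall_fit_error("data contain missing values; run impute_missing() first")
  if (min_folds > n_repeats * n_folds)
    mall_config_error(sprintf(
      "min_folds (%d) exceeds the total number of folds (%d x %d)",
      min_folds, n_repeats, n_folds))
  ypos <- task_positive(task, data$samples)[sidx]
  minority <- min(sum(ypos), sum(!ypos))
  if (minority < 2)
    mall_fit_error(sprintf("task '%s': minority class has %d sample(s)",
                           task$task_id, minority))
  n_folds_eff <- n_folds
  min_folds_eff <- min_folds
  if (minority < n_folds) {
    n_folds_eff <- minority
    min_folds_eff <- ceiling(min_folds / (n_repeats * n_folds) *
                               (n_repeats * n_folds_eff))
    warning(sprintf(
      "task '%s': minority class (%d) smaller than n_folds (%d); reduced to %d folds (leave-pair-out), consensus threshold rescaled to %d/%d",
      task$task_id, minority, n_folds, n_folds_eff, min_folds_eff,
      n_repeats * n_folds_eff), call. = FALSE)
  }
  tindex <- match(task$task_id, mall_task_ids())
  counts <- integer(nrow(x))
  deltas <- numeric(0)
  x2 <- x * x
  for (r in seq_len(n_repeats)) {
    folds <- stratified_folds(colnames(x), ypos, n_folds_eff,
                              derive_seed(seed, tindex * 1000 + r))
    for (f in seq_len(n_folds_eff)) {
      tr <- folds != f
      xtr <- x[, tr, drop = FALSE]
      ytr <- ypos[tr]
      inner_m <- min(sum(ytr), sum(!ytr))
      st_tr <- nsc_stats(xtr, ytr, x2 = x2[, tr, drop = FALSE])
      grid <- delta_grid_from_d(st_tr$d, grid_size)
      delta_f <- if (inner_m >= 3) {
        tune_delta_on(xtr, ytr, x2[, tr, drop = FALSE], grid,
                      min(5, inner_m),
                      derive_seed(seed, tindex * 1000 + r * 10 + f),
                      prior_policy)
      } else {
        # too few minority samples to nest another CV: fall back to the
        # resubstitution error for the parsimony sweep
        err <- sweep_errors(st_tr, grid, xtr, ytr, prior_policy)
        max(grid[err == min(err)])
      }
      dshr_max <- pmax(abs(st_tr$d[, 1]), abs(st_tr$d[, 2]))
      counts <- counts + (dshr_max > delta_f)
      deltas <- c(deltas, delta_f)
    }
  }
  names(counts) <- rownames(x)
  counts <- as.integer(counts)
  names(counts) <- rownames(x)
  nonzero <- counts[counts > 0]
  sites <- names(nonzero)[nonzero >= min_folds_eff]
  if (!length(sites))
    warning(sprintf("task '%s': empty consensus set", task$task_id),
            call. = FALSE)
  structure(list(task_id = task$task_id, site_counts = nonzero,
                 consensus_sites = sites,
                 min_folds = as.integer(min_folds_eff),
                 n_total_folds = as.integer(n_repeats * n_folds_eff),
                 deltas = deltas, n_repeats = as.integer(n_repeats),
                 n_folds = as.integer(n_folds_eff)),
            class = "consensus_set")
}

# Internal fast path of select_delta for pre-subset training data.
tune_delta_on <- function(x, ypos, x2, grid, n_folds, seed, prior_policy) {
  folds <- stratified_folds(colnames(x), ypos, n_folds, seed)
  err <- integer(length(grid))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    st <- nsc_stats(x[, tr, drop = FALSE], ypos[tr],
                    x2 = x2[, tr, drop = FALSE])
    err <- err + sweep_errors(st, grid, x[, !tr, drop = FALSE], ypos[!tr],
                              prior_policy)
  }
  max(grid[err == min(err)])
}

#' @export
print.consensus_set <- function(x, ...) {
  cat(sprintf("<consensus_set> task '%s': %d sites in >= %d/%d folds\n",
              x$task_id, length(x$consensus_sites), x$min_folds,
              x$n_total_folds))
  invisible(x)
}

#' Train the consensus classifier
#'
#' For every task, extracts the consensus CpG sites ([consensus_sites()])
#' and refits a final NSC model on all in-scope samples restricted to those
#' sites, at a shrinkage threshold equal to the median of the per-fold tuned
#' thresholds. Tasks with an empty consensus set are marked inactive (with a
#' warning) and the classifier is still built. Deterministic given `seed`.
#'
#' @inheritParams consensus_sites
#' @param tasks named list of `mall_task` (default [default_tasks()]).
#' @param threshold positive-call probability threshold (strict `>`;
#'   default 0.5).
#' @param iamp21_override apply the iAMP21-and-HeH-counts-as-iAMP21 decision
#'   rule at classification time (default `TRUE`).
#' @param max_missing missingness threshold passed to [impute_missing()].
#' @return a `subtype_classifier`: per task the final `nsc_model`, its
#'   `consensus_set` and an active flag, plus the decision-rule parameters
#'   and an echo of the effective configuration.
#' @export
build_consensus_classifier <- function(data, tasks = default_tasks(),
                                       n_repeats = 5, n_folds = 5,
                                       min_folds = 17, seed = 1,
                                       grid_size = 30, threshold = 0.5,
                                       iamp21_override = TRUE,
                                       prior_policy = "class",
                                       max_missing = 0.05) {
  stopifnot(inherits(data, "methyl_matrix"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    mall_value_error("threshold must lie in (0, 1)")
  data <- impute_missing(data, max_missing)
  built <- lapply(tasks, function(task) {
    cs <- consensus_sites(data, task, n_repeats = n_repeats,
                          n_folds = n_folds, min_folds = min_folds,
                          seed = seed, grid_size = grid_size,
                          prior_policy = prior_policy)
    if (!length(cs$consensus_sites)) {
      warning(sprintf("task '%s' is inactive (empty consensus set)",
                      task$task_id), call. = FALSE)
      return(list(task = task, active = FALSE, delta = NA_real_,
                  consensus = cs, model = NULL))
    }
    # refit on all in-scope samples, restricted to the consensus sites but
    # with the fudge factor and scale of the full feature set, so the
    # median tuned threshold keeps its meaning
    pidx <- which(task_probe_filter(task, data$probes))
    sidx <- which(task_scope(task, data$samples))
    x_full <- data$beta[pidx, sidx, drop = FALSE]
    ypos <- task_positive(task, data$samples)[sidx]
    st <- nsc_stats(x_full, ypos)
    delta_final <- stats::median(cs$deltas)
    rows <- match(cs$consensus_sites, rownames(x_full))
    model <- nsc_model_from_stats(st, rows,
                                  classes = c(task$task_id, ".rest"),
                                  delta = delta_final,
                                  prior_policy = prior_policy)
    list(task = task, active = TRUE, delta = delta_final, consensus = cs,
         model = model)
  })
  names(built) <- names(tasks)
  structure(list(threshold = threshold, iamp21_override = iamp21_override,
                 config = list(n_repeats = n_repeats, n_folds = n_folds,
                               min_folds = min_folds, seed = seed,
                               grid_size = grid_size,
                               prior_policy = prior_policy,
                               max_missing = max_missing),
                 tasks = built),
            class = "subtype_classifier")
}

#' @export
print.subtype_classifier <- function(x, ...) {
  cat(sprintf("<subtype_classifier> %d tasks (%d active), threshold > %g\n",
              length(x$tasks),
              sum(vapply(x$tasks, function(t) isTRUE(t$active), logical(1))),
              x$threshold))
  for (tk in x$tasks)
    cat(sprintf("  %-10s %s (%d consensus CpGs)\n", tk$task$task_id,
                if (isTRUE(tk$active)) "active" else "inactive",
                length(tk$consensus$consensus_sites)))
  invisible(x)
}

#' Per-task consensus CpG counts
#'
#' The analog of a performance table's "consensus CpGs (N)" column: how many
#' CpG sites each task's final model uses.
#'
#' @param classifier a `subtype_classifier`.
#' @return named integer vector over tasks.
#' @export
consensus_counts <- function(classifier) {
  stopifnot(inherits(classifier, "subtype_classifier"))
  vapply(classifier$tasks,
         function(tk) length(tk$consensus$consensus_sites), integer(1))
}
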