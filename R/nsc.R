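# Nearest shrunken centroid (NSC) binary classifier: fit, soft-threshold
# shrinkage, posterior scoring, and cross-validated shrinkage tuning.
#
# Construction, for feature j and class k over n training samples:
#   d_kj  = (xbar_kj - xbar_j) / (m_k * (s_j + s0)),  m_k = sqrt(1/n_k - 1/n)
#   d'_kj = sign(d_kj) * max(|d_kj| - delta, 0)
#   c'_kj = xbar_j + m_k * (s_j + s0) * d'_kj
# where s_j is the pooled within-class standard deviation (n - K denominator)
# and s0 a fudge factor (median of s_j by default). Prediction uses the
# Gaussian discriminant
#   delta_k(x) = sum_j (x_j - c'_kj)^2 / (s_j + s0)^2 - 2 log pi_k
# with posteriors exp(-delta_k/2) normalized over the two classes.

# Sufficient statistics for a binary NSC fit. `ypos` is a logical vector over
# columns of x (TRUE = positive class); `x2` may carry a precomputed x^2 to
# avoid re-squaring inside cross-validation loops.
nsc_stats <- function(x, ypos, fudge_policy = "median", x2 = NULL) {
  n <- ncol(x)
  nk <- c(sum(ypos), n - sum(ypos))
  if (any(nk < 2))
    mall_fit_error(sprintf(
      "each class needs >= 2 samples (got %d positive, %d negative)",
      nk[1], nk[2]))
  Y <- cbind(pos = as.numeric(ypos), neg = as.numeric(!ypos))
  sums <- x %*% Y
  cent <- sweep(sums, 2, nk, "/")
  overall <- (sums[, 1] + sums[, 2]) / n
  if (is.null(x2)) x2 <- x * x
  ssq <- x2 %*% Y
  wss <- (ssq[, 1] - nk[1] * cent[, 1]^2) + (ssq[, 2] - nk[2] * cent[, 2]^2)
  # the sum-of-squares shortcut leaves cancellation residue on (near-)
  # constant features; clip it to an exact zero relative to the raw scale
  wss[wss < (ssq[, 1] + ssq[, 2]) * 1e-12] <- 0
  s <- sqrt(pmax(wss, 0) / (n - 2))
  s0 <- if (identical(fudge_policy, "median")) stats::median(s) else 0
  scale <- s + s0
  # Degenerate (zero-dispersion) features: keep them discriminative by
  # flooring the scale at the smallest positive one, or 1 if none exists.
  if (any(scale == 0)) {
    pos <- scale[scale > 0]
    scale[scale == 0] <- if (length(pos)) min(pos) else 1
  }
  mk <- sqrt(1 / nk - 1 / n)
  d <- (cent - overall) / (scale %o% mk)
  list(n = n, nk = nk, cent = cent, overall = overall, s = s, s0 = s0,
       scale = scale, mk = mk, d = d)
}

soft_threshold <- function(d, delta) sign(d) * pmax(abs(d) - delta, 0)

# Model over a subset of the fitted features, inheriting the fudge factor
# and dispersion scale of the full fit so that a threshold tuned on the
# full feature set stays commensurable.
nsc_model_from_stats <- function(st, rows, classes, delta,
                                 prior_policy = "class") {
  fid <- names(st$overall[rows])
  dshr <- soft_threshold(st$d[rows, , drop = FALSE], delta)
  priors <- if (identical(prior_policy, "class")) st$nk / st$n
  else c(0.5, 0.5)
  m <- list(
    feature_ids = fid,
    classes = classes,
    overall_centroid = stats::setNames(st$overall[rows], fid),
    class_centroids = structure(st$cent[rows, , drop = FALSE],
                                dimnames = list(fid, classes)),
    pooled_sd = stats::setNames(st$s[rows], fid),
    fudge = st$s0,
    scale = stats::setNames(st$scale[rows], fid),
    class_sizes = stats::setNames(st$nk, classes),
    priors = stats::setNames(priors, classes),
    delta = delta,
    offsets = structure(st$d[rows, , drop = FALSE],
                        dimnames = list(fid, classes)),
    shrunken_offsets = structure(dshr, dimnames = list(fid, classes))
  )
  m$shrunken_centroids <- shrunken_centroids_from(m)
  class(m) <- "nsc_model"
  m
}

shrunken_centroids_from <- function(m) {
  sc <- m$overall_centroid +
    m$shrunken_offsets * (m$scale %o% sqrt(1 / m$class_sizes - 1 / sum(m$class_sizes)))
  dimnames(sc) <- dimnames(m$shrunken_offsets)
  sc
}

#' Fit a binary nearest shrunken centroid model
#'
#' Computes per-class and overall centroids, pooled within-class dispersions,
#' standardized centroid offsets, and soft-thresholds the offsets at `delta`.
#' With `delta = 0` the shrunken centroids equal the raw class centroids;
#' with `delta >= max |d_kj|` both collapse onto the overall centroid and the
#' model predicts from the priors alone.
#'
#' @param x numeric matrix, rows = features (named), columns = samples; no
#'   missing values (impute/filter first, e.g. [impute_missing()]).
#' @param y class labels, one per column of `x`; exactly two distinct values.
#' @param delta shrinkage threshold, `>= 0`.
#' @param positive which label is the positive class (default: first level of
#'   `factor(y)`).
#' @param fudge_policy `"median"` (fudge factor s0 = median of the pooled
#'   dispersions, the reference-implementation convention) or `"none"`.
#' @param prior_policy `"class"` (training proportions) or `"uniform"`.
#' @return an `nsc_model`: centroids, `pooled_sd`, `fudge`, `scale`
#'   (= pooled_sd + fudge, floored away from zero), `class_sizes`, `priors`,
#'   `delta`, raw `offsets`, `shrunken_offsets`, `shrunken_centroids`.
#' @export
fit_nsc <- function(x, y, delta = 0, positive = NULL,
                    fudge_policy = c("median", "none"),
                    prior_policy = c("class", "uniform")) {
  fudge_policy <- match.arg(fudge_policy)
  prior_policy <- match.arg(prior_policy)
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("f", seq_len(nrow(x)))
  if (anyNA(x)) mall_fit_error("x contains missing values; impute first")
  if (!is.numeric(delta) || length(delta) != 1 || is.na(delta) || delta < 0)
    mall_value_error("delta must be a single number >= 0")
  y <- as.character(y)
  if (length(y) != ncol(x)) mall_fit_error("length(y) must equal ncol(x)")
  lev <- unique(y)
  if (length(lev) != 2) mall_fit_error("y must contain exactly two classes")
  positive <- positive %||% sort(lev)[1]
  if (!positive %in% lev) mall_fit_error("positive label not present in y")
  negative <- setdiff(lev, positive)
  classes <- c(positive, negative)
  st <- nsc_stats(x, y == positive, fudge_policy)
  dshr <- soft_threshold(st$d, delta)
  priors <- if (prior_policy == "class") st$nk / st$n else c(0.5, 0.5)
  m <- list(
    feature_ids = rownames(x),
    classes = classes,
    overall_centroid = stats::setNames(st$overall, rownames(x)),
    class_centroids = structure(st$cent, dimnames = list(rownames(x), classes)),
    pooled_sd = stats::setNames(st$s, rownames(x)),
    fudge = st$s0,
    scale = stats::setNames(st$scale, rownames(x)),
    class_sizes = stats::setNames(st$nk, classes),
    priors = stats::setNames(priors, classes),
    delta = delta,
    offsets = structure(st$d, dimnames = list(rownames(x), classes)),
    shrunken_offsets = structure(dshr, dimnames = list(rownames(x), classes))
  )
  m$shrunken_centroids <- shrunken_centroids_from(m)
  class(m) <- "nsc_model"
  m
}

#' @export
print.nsc_model <- function(x, ...) {
  cat(sprintf("<nsc_model> %s vs %s: %d features (%d surviving), delta = %.4g\n",
              x$classes[1], x$classes[2], length(x$feature_ids),
              length(surviving_features(x)), x$delta))
  invisible(x)
}

#' Posterior class probabilities from an NSC model
#'
#' Evaluates the shrunken-centroid discriminant for each sample and converts
#' to posteriors in a numerically stable way (the smaller discriminant is
#' subtracted before exponentiation). The two per-sample posteriors sum to 1.
#'
#' @param model an `nsc_model`.
#' @param x numeric matrix, rows = features, columns = samples; must contain
#'   every model feature (by row name). Missing features raise an error that
#'   lists the absent probe ids.
#' @return numeric matrix, samples x 2, columns named by class (positive
#'   class first).
#' @export
predict_nsc <- function(model, x) {
  stopifnot(inherits(model, "nsc_model"))
  x <- as.matrix(x)
  absent <- setdiff(model$feature_ids, rownames(x))
  if (length(absent))
    mall_prediction_error(paste0(
      "input is missing model feature(s): ",
      paste(absent[1:min(10, length(absent))], collapse = ", "),
      if (length(absent) > 10) sprintf(" (and %d more)", length(absent) - 10)))
  x <- x[model$feature_ids, , drop = FALSE]
  if (anyNA(x)) mall_prediction_error("x contains missing values")
  w <- model$scale^2
  disc <- vapply(model$classes, function(k) {
    colSums((x - model$shrunken_centroids[, k])^2 / w) - 2 * log(model$priors[k])
  }, numeric(ncol(x)))
  if (ncol(x) == 1) disc <- matrix(disc, nrow = 1,
                                   dimnames = list(colnames(x), model$classes))
  dmin <- pmin(disc[, 1], disc[, 2])
  e <- exp(-(disc - dmin) / 2)
  p <- e / rowSums(e)
  dimnames(p) <- list(colnames(x), model$classes)
  p
}

#' Features surviving shrinkage
#'
#' Probe ids whose shrunken offset is non-zero for at least one class; these
#' are the features NSC selects at the model's shrinkage threshold.
#'
#' @param model an `nsc_model`.
#' @return character vector of probe ids.
#' @export
surviving_features <- function(model) {
  stopifnot(inherits(model, "nsc_model"))
  keep <- rowSums(abs(model$shrunken_offsets) > 0) > 0
  model$feature_ids[keep]
}

#' Default shrinkage-threshold grid
#'
#' 30 points spanning no shrinkage to total shrinkage: 0, then values
#' log-spaced from the 10th percentile of the non-zero |d_kj| up to
#' max |d_kj| on the supplied training data.
#'
#' @inheritParams fit_nsc
#' @param n grid size (default 30).
#' @return ascending numeric vector; `c(0)` if the data carry no offsets.
#' @export
nsc_delta_grid <- function(x, y, positive = NULL, n = 30) {
  x <- as.matrix(x)
  y <- as.character(y)
  positive <- positive %||% sort(unique(y))[1]
  st <- nsc_stats(x, y == positive)
  delta_grid_from_d(st$d, n)
}

delta_grid_from_d <- function(d, n = 30) {
  a <- abs(d)
  dmax <- max(a)
  if (!is.finite(dmax) || dmax == 0) return(0)
  nz <- a[a > 0]
  lo <- stats::quantile(nz, 0.10, names = FALSE)
  if (lo <= 0 || lo >= dmax) lo <- dmax / 1000
  c(0, exp(seq(log(lo), log(dmax), length.out = n - 1)))
}

# Misclassification counts on validation columns for every delta in `grid`,
# from training-fold statistics. Exploits that non-surviving features cancel
# between the two discriminants: delta_pos - delta_neg reduces to an affine
# function of x restricted to surviving features, evaluated for all grid
# points at once via one cross-product.
sweep_errors <- function(st, grid, xval, yval_pos, prior_policy = "class") {
  G <- length(grid)
  p <- nrow(st$d)
  priors <- if (identical(prior_policy, "class")) st$nk / st$n else c(0.5, 0.5)
  U <- matrix(0, p, G)
  const <- numeric(G)
  for (g in seq_len(G)) {
    dshr <- soft_threshold(st$d, grid[g])
    cpos <- st$overall + st$mk[1] * st$scale * dshr[, 1]
    cneg <- st$overall + st$mk[2] * st$scale * dshr[, 2]
    u <- (cpos - cneg) / st$scale^2
    U[, g] <- u
    const[g] <- sum(u * (cpos + cneg)) - 2 * log(priors[1] / priors[2])
  }
  cross <- crossprod(U, xval)                 # G x n_val
  diff <- const - 2 * cross                   # delta_pos - delta_neg
  pred_pos <- diff < 0
  err <- integer(G)
  for (g in seq_len(G)) err[g] <- sum(pred_pos[g, ] != yval_pos)
  err
}

#' Select the shrinkage threshold by internal cross-validation
#'
#' Stratified `n_folds`-fold cross-validation over a threshold grid; returns
#' the largest threshold attaining the minimum total misclassification count
#' (parsimony tie-break). Deterministic given `seed`.
#'
#' @inheritParams fit_nsc
#' @param n_folds number of internal folds (default 5); every class must
#'   have at least `n_folds` samples.
#' @param grid ascending vector of candidate thresholds; default
#'   [nsc_delta_grid()] on the full data.
#' @param seed integer seed controlling fold assignment.
#' @return the selected threshold, with attributes `errors` (per-grid-point
#'   CV misclassification counts) and `grid`.
#' @export
select_delta <- function(x, y, n_folds = 5, grid = NULL, seed = 1,
                         positive = NULL, prior_policy = "class") {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("s", seq_len(ncol(x)))
  y <- as.character(y)
  positive <- positive %||% sort(unique(y))[1]
  ypos <- y == positive
  if (min(sum(ypos), sum(!ypos)) < n_folds)
    mall_fit_error(sprintf(
      "class too small to stratify into %d folds (minority class has %d)",
      n_folds, min(sum(ypos), sum(!ypos))))
  if (is.null(grid)) grid <- nsc_delta_grid(x, y, positive = positive)
  if (!length(grid)) mall_value_error("delta grid must be non-empty")
  if (is.unsorted(grid)) mall_value_error("delta grid must be sorted ascending")
  folds <- stratified_folds(colnames(x), ypos, n_folds, seed)
  x2 <- x * x
  err <- integer(length(grid))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    st <- nsc_stats(x[, tr, drop = FALSE], ypos[tr],
                    x2 = x2[, tr, drop = FALSE])
    err <- err + sweep_errors(st, grid, x[, !tr, drop = FALSE], ypos[!tr],
                              prior_policy)
  }
  best <- max(grid[err == min(err)])
  structure(best, errors = err, grid = grid)
}
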