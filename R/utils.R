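# Internal helpers: error conditions, seeded RNG scoping, stratified folds.

mall_error <- function(msg, class) {
  stop(structure(
    class = c(class, "mall_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

mall_format_error     <- function(msg) mall_error(msg, "mall_format_error")
mall_value_error      <- function(msg) mall_error(msg, "mall_value_error")
mall_fit_error        <- function(msg) mall_error(msg, "mall_fit_error")
mall_prediction_error <- function(msg) mall_error(msg, "mall_prediction_error")
mall_config_error     <- function(msg) mall_error(msg, "mall_config_error")

#' Evaluate an expression under a local RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state, so
#' seeded internals never perturb the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Deterministic sub-seed derivation; exact in double arithmetic (< 2^53) and
# the result stays inside 32-bit integer range.
derive_seed <- function(seed, i) {
  s <- (as.numeric(seed) %% 1000003) * 1048573 + as.numeric(i) * 7919
  as.integer(s %% 2147483629) + 1L
}

# Stratified fold assignment keyed by sample id: ids are sorted before the
# seeded within-stratum shuffle, so the assignment is invariant to the order
# in which samples arrive.
stratified_folds <- function(ids, strata, k, seed) {
  stopifnot(length(ids) == length(strata), k >= 2)
  ord <- order(ids)
  ids_s <- ids[ord]
  strata_s <- as.character(strata)[ord]
  fold <- integer(length(ids_s))
  with_seed(seed, {
    for (st in sort(unique(strata_s))) {
      idx <- which(strata_s == st)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  names(fold) <- ids_s
  fold[ids]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
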