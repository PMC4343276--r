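# Independent long-hand oracles, written as plain scalar loops so they share
# no code path with the package internals.

# Step-by-step NSC fit: centroids, pooled sd, fudge, standardized offsets,
# soft-thresholding, shrunken centroids -- one scalar at a time.
oracle_nsc_fit <- function(x, y, delta, positive,
                           prior_policy = "class") {
  classes <- c(positive, setdiff(unique(y), positive))
  p <- nrow(x); n <- ncol(x)
  nk <- c(sum(y == classes[1]), sum(y == classes[2]))
  cent <- matrix(0, p, 2)
  overall <- numeric(p)
  for (j in 1:p) {
    for (k in 1:2) {
      tot <- 0; cnt <- 0
      for (i in 1:n) if (y[i] == classes[k]) { tot <- tot + x[j, i]; cnt <- cnt + 1 }
      cent[j, k] <- tot / cnt
    }
    overall[j] <- sum(x[j, ]) / n
  }
  s <- numeric(p)
  for (j in 1:p) {
    ss <- 0
    for (i in 1:n) {
      k <- if (y[i] == classes[1]) 1 else 2
      ss <- ss + (x[j, i] - cent[j, k])^2
    }
    s[j] <- sqrt(ss / (n - 2))
  }
  s0 <- median(s)
  mk <- c(sqrt(1 / nk[1] - 1 / n), sqrt(1 / nk[2] - 1 / n))
  d <- matrix(0, p, 2)
  dshr <- matrix(0, p, 2)
  shrunk <- matrix(0, p, 2)
  for (j in 1:p) for (k in 1:2) {
    d[j, k] <- (cent[j, k] - overall[j]) / (mk[k] * (s[j] + s0))
    a <- abs(d[j, k]) - delta
    dshr[j, k] <- sign(d[j, k]) * max(a, 0)
    shrunk[j, k] <- overall[j] + mk[k] * (s[j] + s0) * dshr[j, k]
  }
  priors <- if (prior_policy == "class") nk / n else c(0.5, 0.5)
  list(classes = classes, cent = cent, overall = overall, s = s, s0 = s0,
       mk = mk, d = d, dshr = dshr, shrunk = shrunk, priors = priors,
       survivors = rownames(x)[apply(abs(dshr) > 0, 1, any)])
}

oracle_nsc_predict <- function(fit, x, s_list = NULL) {
  p <- nrow(x); n <- ncol(x)
  post <- matrix(0, n, 2)
  for (i in 1:n) {
    disc <- numeric(2)
    for (k in 1:2) {
      acc <- 0
      for (j in 1:p)
        acc <- acc + (x[j, i] - fit$shrunk[j, k])^2 / (fit$s[j] + fit$s0)^2
      disc[k] <- acc - 2 * log(fit$priors[k])
    }
    m <- min(disc)
    e1 <- exp(-(disc[1] - m) / 2); e2 <- exp(-(disc[2] - m) / 2)
    post[i, ] <- c(e1, e2) / (e1 + e2)
  }
  colnames(post) <- fit$classes
  rownames(post) <- colnames(x)
  post
}

# Mean-of-order-statistics quantile normalization, fully looped; average
# ranks map to the mean of their bracketing target quantiles.
oracle_quantile_normalize <- function(m) {
  p <- nrow(m); n <- ncol(m)
  ref <- numeric(p)
  for (i in 1:p) {
    tot <- 0
    for (j in 1:n) tot <- tot + sort(m[, j])[i]
    ref[i] <- tot / n
  }
  out <- matrix(0, p, n, dimnames = dimnames(m))
  for (j in 1:n) {
    r <- rank(m[, j], ties.method = "average")
    for (i in 1:p)
      out[i, j] <- (ref[floor(r[i])] + ref[ceiling(r[i])]) / 2
  }
  out
}

# Random small NSC problem instances for the oracle-equivalence sweep.
random_nsc_instance <- function(seed) {
  set.seed(seed)
  p <- sample(3:30, 1)
  n1 <- sample(4:20, 1); n2 <- sample(4:20, 1)
  x <- matrix(runif(p * (n1 + n2)), p,
              dimnames = list(sprintf("f%02d", 1:p), NULL))
  shift <- sample(1:p, max(1, p %/% 3))
  x[shift, 1:n1] <- pmin(x[shift, 1:n1] + runif(1, 0.1, 0.5), 1)
  colnames(x) <- sprintf("s%02d", 1:(n1 + n2))
  y <- c(rep("A", n1), rep("B", n2))
  list(x = x, y = y)
}
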