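# Independent oracles used across tests.  These deliberately avoid the code
# paths they check: AUC by all-pairs enumeration, logistic ML by a bare
# Newton-Raphson, PCA by eigendecomposition of the covariance, penalized
# objectives by direct evaluation.

# all-pairs Mann-Whitney AUC, ties = 1/2
allpairs_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (if (p > q) 1 else if (p == q) 0.5 else 0)
  tot / (length(pos) * length(neg))
}

# unpenalized logistic ML via Newton-Raphson with step halving
newton_logistic <- function(X, y, maxit = 100, tol = 1e-12) {
  Xd <- cbind(1, as.matrix(X))
  b <- rep(0, ncol(Xd))
  nll <- function(b) {
    eta <- as.numeric(Xd %*% b)
    sum(log1p(exp(eta)) - y * eta)
  }
  f <- nll(b)
  for (it in seq_len(maxit)) {
    eta <- as.numeric(Xd %*% b)
    p <- plogis(eta)
    g <- crossprod(Xd, p - y)
    H <- crossprod(Xd * (p * (1 - p)), Xd)
    step <- solve(H + diag(1e-10, ncol(Xd)), g)
    lam <- 1
    repeat {
      bn <- b - lam * as.numeric(step)
      fn <- nll(bn)
      if (fn <= f + 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    if (abs(f - fn) < tol) { b <- bn; break }
    b <- bn; f <- fn
  }
  b
}

# elastic-net logistic objective at explicit original-scale coefficients,
# standardized-parameterization penalty (matches the package's contract)
pen_objective <- function(intercept, beta, X, y, lambda, alpha) {
  X <- as.matrix(X)
  n <- nrow(X)
  sc <- sqrt(colMeans(X^2) - colMeans(X)^2)
  sc[sc < .Machine$double.eps] <- 1
  eta <- intercept + as.numeric(X %*% beta)
  bs <- beta * sc
  mean(log1p(exp(eta)) - y * eta) +
    lambda * (alpha * sum(abs(bs)) + (1 - alpha) / 2 * sum(bs^2))
}

# small-volume cohort configuration for fast pipeline tests
tiny_cohort_config <- function(...) {
  args <- modifyList(list(shape = c(6L, 48L, 48L),
                          semi_axes_inplane_mm = c(3, 4.5),
                          semi_axes_slice_mm = c(3, 5),
                          patch_margin = 9L),
                     list(...))
  do.call(synthetic_cohort_config, args)
}

# a small deterministic volume + full-interior mask for patch tests
fixture_volume <- function(dims = c(4L, 30L, 30L), seed = 99) {
  vox <- brcaradiomics:::with_rng_seed(seed,
    array(rnorm(prod(dims)), dim = dims))
  volume_image(vox, spacing = c(3.7, 0.75, 0.75))
}
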