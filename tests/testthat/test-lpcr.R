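# Penalized logistic regression against independent oracles (Newton ML,
# exhaustive objective grid), AUC against all-pairs enumeration, CV
# behavior, importance, ROC bootstrap, confusion arithmetic.

sim_xy <- function(n, p, beta = NULL, seed = 1) {
  brcaradiomics:::with_rng_seed(seed, {
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
    eta <- if (is.null(beta)) rep(0, n) else as.numeric(X %*% beta)
    y <- rbinom(n, 1, plogis(eta))
    if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
    list(X = X, y = y)
  })
}

test_that("full shrinkage: all-zero coefficients and prevalence-logit intercept", {
  d <- sim_xy(50, 4, beta = c(1, -0.5, 0, 0), seed = 2)
  lmax <- lambda_max(d$X, d$y, alpha = 1)
  # exactly at lambda_max the solver itself must return the null model
  for (lam in c(lmax, lmax * 1.5, lmax + 1)) {
    fit <- fit_penalized_logistic(d$X, d$y, lambda = lam, alpha = 1)
    expect_true(all(abs(fit$coefficients) < 1e-8), label = paste("lambda =", lam))
    expect_equal(fit$intercept, qlogis(mean(d$y)), tolerance = 1e-6)
  }
  # just below lambda_max at least one coefficient comes alive
  fit2 <- fit_penalized_logistic(d$X, d$y, lambda = lmax * 0.8, alpha = 1)
  expect_gt(max(abs(fit2$coefficients)), 0)
})

test_that("lambda = 0 matches the independent Newton ML oracle within 1e-4", {
  d <- sim_xy(40, 3, beta = c(0.8, -0.6, 0.2), seed = 5)
  fit <- fit_penalized_logistic(d$X, d$y, lambda = 0)
  oracle <- newton_logistic(d$X, d$y)
  expect_equal(unname(c(fit$intercept, fit$coefficients)), oracle,
               tolerance = 1e-4)
})

test_that("attained objective beats an exhaustive 201x201 coefficient grid", {
  for (seed in c(3, 17)) {
    d <- sim_xy(10, 2, beta = c(1, -1), seed = seed)
    lam <- 0.1
    fit <- fit_penalized_logistic(d$X, d$y, lambda = lam, alpha = 1)
    attained <- logistic_objective(fit, d$X, d$y)
    # oracle: standardized-scale coefficient grid, intercept profiled by
    # vectorized Newton (intercept is unpenalized, so profiling is exact)
    sc <- sqrt(colMeans(d$X^2) - colMeans(d$X)^2)
    Xs <- sweep(sweep(d$X, 2, colMeans(d$X)), 2, sc, "/")
    g <- seq(-5, 5, length.out = 201)
    grid <- as.matrix(expand.grid(b1 = g, b2 = g))
    eta0 <- Xs %*% t(grid)                      # n x 40401
    b0 <- rep(0, ncol(eta0))
    for (it in 1:50) {
      pr <- plogis(sweep(eta0, 2, b0, "+"))
      grad <- colMeans(pr) - mean(d$y)
      hess <- pmax(colMeans(pr * (1 - pr)), 1e-10)
      b0 <- b0 - grad / hess
    }
    pr <- sweep(eta0, 2, b0, "+")
    nll <- colMeans(log1p(exp(pr)) - outer(d$y, rep(1, ncol(pr))) * pr)
    objs <- nll + lam * (abs(grid[, 1]) + abs(grid[, 2]))
    expect_lte(attained, min(objs) + 1e-6)
  }
})

test_that("elastic-net fit is optimal under its own alpha = 0.5 objective", {
  d <- sim_xy(40, 4, beta = c(1, -1, 0.5, 0), seed = 7)
  lam <- 0.2
  fits <- lapply(c(0, 0.5, 1), function(a)
    fit_penalized_logistic(d$X, d$y, lambda = lam, alpha = a))
  obj_half <- function(f) pen_objective(f$intercept, f$coefficients,
                                        d$X, d$y, lam, alpha = 0.5)
  expect_lte(obj_half(fits[[2]]), obj_half(fits[[1]]) + 1e-8)
  expect_lte(obj_half(fits[[2]]), obj_half(fits[[3]]) + 1e-8)
})

test_that("unpenalized path: 2x2 log-odds-ratio closed form and constants", {
  # 2x2 table: exposure x outcome with counts (a,b,c,d) = (20,10,8,22)
  x <- rep(c(1, 1, 0, 0), c(20, 10, 8, 22))
  y <- rep(c(1, 0, 1, 0), c(20, 10, 8, 22))
  fit <- fit_unpenalized_logistic(matrix(x, ncol = 1,
                                         dimnames = list(NULL, "TNBC")), y)
  expect_equal(unname(fit$coefficients), log((20 * 22) / (10 * 8)),
               tolerance = 1e-6)
  # constant predictor: zero coefficient, prevalence-logit intercept
  fitc <- fit_unpenalized_logistic(matrix(1, length(y), 1,
                                          dimnames = list(NULL, "k")), y)
  expect_equal(unname(fitc$coefficients), 0)
  expect_equal(fitc$intercept, qlogis(mean(y)), tolerance = 1e-8)
  expect_error(fit_unpenalized_logistic(matrix(rnorm(30), 10, 3),
                                        rep(c(0L, 1L), 5)),
               "penalized")
})

test_that("AUC equals all-pairs enumeration and satisfies its identities", {
  expect_equal(auc(c(0, 1, 1, 0), c(0, 1, 1, 0)), 1.0)
  expect_equal(auc(rep(0.3, 8), rep(c(0, 1), 4)), 0.5)
  for (seed in 1:5) {
    s <- brcaradiomics:::with_rng_seed(seed, {
      sc <- round(rnorm(30), 2)   # rounding forces some ties
      list(sc = sc, y = rbinom(30, 1, 0.4))
    })
    if (length(unique(s$y)) < 2) s$y[1:2] <- c(0L, 1L)
    expect_equal(auc(s$sc, s$y), allpairs_auc(s$sc, s$y), tolerance = 1e-12)
  }
  # complement identity for tie-free scores
  s <- brcaradiomics:::with_rng_seed(6, list(sc = rnorm(25), y = rep(c(0, 1), c(12, 13))))
  expect_equal(auc(s$sc, s$y) + auc(-s$sc, s$y), 1, tolerance = 1e-12)
  expect_error(auc(1:5, rep(1, 5)), "both classes")
})

test_that("sparsity is non-increasing along the lambda grid", {
  d <- sim_xy(60, 8, beta = c(1.5, -1, 0.7, 0.4, 0, 0, 0, 0), seed = 12)
  nnz <- vapply(default_lambda_grid(), function(l)
    sum(fit_penalized_logistic(d$X, d$y, lambda = l)$coefficients != 0),
    integer(1))
  expect_true(all(diff(nnz) <= 0))
  expect_equal(nnz[length(nnz)], 0L)
})

test_that("cross-validation recovers separable signal and is reproducible", {
  d <- brcaradiomics:::with_rng_seed(30, {
    y <- rep(c(0L, 1L), each = 50)
    X <- cbind(sep = y + rnorm(100, sd = 0.05), noise = rnorm(100))
    list(X = X, y = y)
  })
  cv <- cross_validate(d$X, d$y, grid = seq(0, 3, 0.25), k = 5, L = 3,
                       rng_seed = 44)
  expect_gte(cv$mean_auc[cv$grid == 0], 0.99)
  expect_true(all(cv$mean_auc >= 0 & cv$mean_auc <= 1))
  expect_true(cv$optimal_lambda %in% cv$grid)
  cv2 <- cross_validate(d$X, d$y, grid = seq(0, 3, 0.25), k = 5, L = 3,
                        rng_seed = 44)
  expect_identical(cv, cv2)
})

test_that("leakage-safe mode refits PCA inside each fold", {
  d <- brcaradiomics:::with_rng_seed(60, {
    y <- rep(c(0L, 1L), each = 25)
    base <- matrix(rnorm(50 * 3), 50, 3)
    # signal lives in a low-dimensional subspace of 12 raw features
    X <- base %*% matrix(rnorm(36), 3, 12) + matrix(rnorm(600, sd = 0.1), 50, 12)
    X[, 1] <- X[, 1] + 4 * y
    list(X = X, y = y)
  })
  cv <- cross_validate(d$X, d$y, grid = seq(0, 3, 0.25), k = 5, L = 3,
                       rng_seed = 61, pca_tau = 0.95)
  expect_true(all(cv$mean_auc >= 0 & cv$mean_auc <= 1))
  expect_gte(cv$optimal_auc, 0.8)
  expect_identical(cv, cross_validate(d$X, d$y, grid = seq(0, 3, 0.25),
                                      k = 5, L = 3, rng_seed = 61,
                                      pca_tau = 0.95))
})

test_that("permuted labels put the CV optimum near chance", {
  # single draws can exceed the band through max-over-grid selection noise;
  # the check is on the median over 3 label permutations of one instance
  aucs <- vapply(1:3, function(i) {
    d <- brcaradiomics:::with_rng_seed(30 + i, list(
      X = matrix(rnorm(100 * 10), 100, 10),
      y = sample(rep(c(0L, 1L), each = 50))))
    cross_validate(d$X, d$y, k = 5, L = 20, rng_seed = 90 + i)$optimal_auc
  }, 0)
  expect_gte(median(aucs), 0.40)
  expect_lte(median(aucs), 0.60)
})

test_that("variable importance scales standardized coefficients to 0..100", {
  fit <- structure(list(intercept = 0,
                        coefficients = c(a = 2, b = -1, c = 0),
                        lambda = 0.1, alpha = 1,
                        center = c(a = 0, b = 0, c = 0),
                        scale = c(a = 1, b = 1, c = 1), unpenalized = FALSE),
                   class = "penalized_logistic_fit")
  imp <- variable_importance(fit)
  expect_equal(imp$variable, c("a", "b", "c"))
  expect_equal(imp$score, c(100, 50, 0))
  fit$coefficients <- c(a = 0.4, b = 0, c = 0)
  imp1 <- variable_importance(fit)
  expect_equal(imp1$score[imp1$variable == "a"], 100)
  expect_equal(sum(imp1$score > 0), 1L)
  fit$coefficients[] <- 0
  expect_warning(imp0 <- variable_importance(fit), "zero")
  expect_true(all(imp0$score == 0))
  # planted strong covariate ranks first across seeds
  wins <- 0L
  for (seed in 1:20) {
    d <- sim_xy(120, 5, beta = c(1.5, 0, 0, 0, 0), seed = 100 + seed)
    f <- fit_penalized_logistic(d$X, d$y, lambda = 0.02)
    imp <- suppressWarnings(variable_importance(f))
    wins <- wins + (imp$variable[1] == "x1")
  }
  expect_gte(wins, 18L)
})

test_that("ROC: perfect classifier, internal consistency, monotone curve", {
  y <- rep(c(0L, 1L), c(10, 10))
  r <- roc_with_ci(c(rnorm(10, 0, 0.1), rnorm(10, 5, 0.1)), y,
                   n_boot = 200, rng_seed = 1)
  expect_equal(r$auc, 1)
  expect_equal(unname(r$ci95), c(1, 1))
  s <- brcaradiomics:::with_rng_seed(40, rnorm(20))
  r2 <- roc_with_ci(s, y, n_boot = 200, rng_seed = 2)
  expect_equal(r2$auc, auc(s, y))
  expect_true(all(diff(r2$tpr) >= 0) && all(diff(r2$fpr) >= 0))
  expect_true(r2$ci95[1] <= r2$auc && r2$auc <= r2$ci95[2])
})

test_that("bootstrap CI approximately attains nominal coverage", {
  # scaled down from the 200 x 2000 reference: 150 cohorts x 400 resamples
  true_auc <- pnorm(1 / sqrt(2))   # N(1,1) vs N(0,1)
  covered <- 0L
  for (i in 1:150) {
    s <- brcaradiomics:::with_rng_seed(2000 + i,
      list(sc = c(rnorm(20, 1), rnorm(20, 0)), y = rep(c(1L, 0L), each = 20)))
    ci <- roc_with_ci(s$sc, s$y, n_boot = 400, rng_seed = i)$ci95
    covered <- covered + (ci[1] <= true_auc && true_auc <= ci[2])
  }
  expect_gte(covered / 150, 0.92)
})

test_that("confusion diagnostics match hand arithmetic", {
  y <- rep(c(1, 1, 0, 0), c(3, 2, 1, 5))        # TP 3, FN 2, FP 1, TN 5
  sc <- rep(c(0.9, 0.1, 0.8, 0.2), c(3, 2, 1, 5))
  cd <- confusion_diagnostics(sc, y)
  expect_equal(with(cd, c(TP, FP, TN, FN)), c(3, 1, 5, 2))
  expect_equal(cd$sensitivity, 0.6)
  expect_equal(cd$specificity, 5 / 6)
  expect_equal(cd$ppv, 3 / 4)
  expect_equal(cd$npv, 5 / 7)
  expect_equal(cd$accuracy, 8 / 11)
  expect_equal(cd$TP + cd$FP + cd$TN + cd$FN, length(y))
  # perfect scores; then an all-below-threshold degenerate case
  cd1 <- confusion_diagnostics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(c(cd1$sensitivity, cd1$specificity), c(1, 1))
  cd2 <- confusion_diagnostics(rep(0.4, 6), rep(c(1, 0), 3))
  expect_equal(cd2$sensitivity, 0)
  expect_true(is.na(cd2$ppv))
  expect_error(confusion_diagnostics(sc, y, threshold = 1.2), "threshold")
})
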