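# Penalized logistic regression (lasso / ridge / elastic net), repeated
# stratified k-fold cross-validation over a lambda grid maximizing AUC, ROC
# with stratified-bootstrap confidence interval, variable importance, and
# confusion diagnostics.
#
# Objective (alpha = 1 gives the lasso):
#   (1/n) * sum_i -[y_i eta_i - log(1 + e^{eta_i})]
#     + lambda * [ alpha * ||b||_1 + (1 - alpha)/2 * ||b||_2^2 ]
# with predictors internally standardized to unit (1/n) variance and
# coefficients reported on the original scale.  The solver is glmnet's cyclic
# coordinate descent; oracle tests (exhaustive objective grid, unpenalized
# IRLS at lambda = 0) pin the objective down independently of glmnet.

#' Default lambda grid: 0 to 3 in steps of 0.05 (61 points)
#' @return numeric vector
#' @export
default_lambda_grid <- function() seq(0, 3, by = 0.05)

.validate_xy <- function(X, y) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("data error: non-finite values in the feature matrix")
  y <- as.integer(y)
  if (length(y) != nrow(X)) stop("labels must align with rows")
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (length(unique(y)) < 2L)
    stop("fit error: labels contain a single class")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  list(X = X, y = y)
}

# biased (1/n) per-column SD, the standardization scale glmnet uses
.col_scale <- function(X) {
  n <- nrow(X)
  s <- sqrt(colMeans(X^2) - colMeans(X)^2)
  s[s < .Machine$double.eps] <- 1  # constant columns: leave unscaled
  s
}

#' Smallest lambda giving an all-zero lasso/elastic-net solution
#'
#' \code{max_j |<x_j_std, y - mean(y)>| / (n * max(alpha, 1e-3))} with
#' standardized predictors; above this the penalized fit is the null model.
#'
#' @param X feature matrix
#' @param y binary labels
#' @param alpha penalty mixing parameter
#' @return scalar lambda
#' @export
lambda_max <- function(X, y, alpha = 1) {
  v <- .validate_xy(X, y)
  Xs <- sweep(sweep(v$X, 2L, colMeans(v$X)), 2L, .col_scale(v$X), "/")
  max(abs(crossprod(Xs, v$y - mean(v$y)))) / (nrow(v$X) * max(alpha, 1e-3))
}

# glmnet solution at one lambda, fit along a warm-start path for accuracy
.glmnet_at <- function(X, y, lambda, alpha) {
  if (ncol(X) == 1L) {
    # glmnet requires >= 2 columns; pad with a zero dummy and drop its coef
    sol <- .glmnet_at(cbind(X, `..dummy` = 0), y, lambda, alpha)
    return(list(intercept = sol$intercept, beta = sol$beta[1]))
  }
  lmax <- lambda_max(X, y, alpha)
  top <- max(lambda, lmax) * 1.05 + 1e-6
  floor_l <- max(min(lambda, lmax * 1e-3), 1e-8)
  path <- exp(seq(log(top), log(floor_l), length.out = 40))
  path <- sort(unique(c(path, lambda)), decreasing = TRUE)
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = alpha,
                        lambda = path, standardize = TRUE, thresh = 1e-12,
                        maxit = 1e6)
  co <- as.numeric(coef(fit, s = lambda, exact = FALSE))
  list(intercept = co[1], beta = co[-1])
}

#' Fit an L1/L2-penalized logistic regression at a fixed penalty
#'
#' @param X numeric feature matrix (no missing entries)
#' @param y binary 0/1 labels, both classes present
#' @param lambda penalty weight, >= 0
#' @param alpha penalty mix in [0, 1]: 1 = lasso, 0 = ridge
#' @return object of class \code{penalized_logistic_fit}: \code{intercept},
#'   \code{coefficients} (original scale, named), \code{lambda}, \code{alpha},
#'   \code{center}, \code{scale} (the internal standardization)
#' @export
fit_penalized_logistic <- function(X, y, lambda, alpha = 1) {
  v <- .validate_xy(X, y); X <- v$X; y <- v$y
  if (lambda < 0) stop("`lambda` must be >= 0")
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1]")
  sol <- if (lambda >= lambda_max(X, y, alpha) * (1 + 1e-10) && alpha > 0) {
    list(intercept = qlogis(mean(y)), beta = rep(0, ncol(X)))
  } else {
    suppressWarnings(.glmnet_at(X, y, lambda, alpha))
  }
  structure(list(intercept = sol$intercept,
                 coefficients = setNames(sol$beta, colnames(X)),
                 lambda = lambda, alpha = alpha,
                 center = colMeans(X), scale = .col_scale(X),
                 unpenalized = FALSE),
            class = "penalized_logistic_fit")
}

#' Unpenalized maximum-likelihood logistic regression (<= 2 predictors)
#'
#' The estimator used for the classification problems with at most two
#' parameters; more predictors are deliberately refused here — the routing
#' rule lives in \code{\link{run_experiment}}, which switches to the
#' penalized path.
#'
#' @param X feature matrix with 1 or 2 columns
#' @param y binary labels
#' @return a \code{penalized_logistic_fit} with \code{lambda = 0}
#' @export
fit_unpenalized_logistic <- function(X, y) {
  v <- .validate_xy(X, y); X <- v$X; y <- v$y
  if (ncol(X) > 2L)
    stop("fit_unpenalized_logistic accepts at most 2 predictors (got ",
         ncol(X), "); use the penalized path (see run_experiment routing rule)")
  df <- data.frame(y = y, X, check.names = FALSE)
  g <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
  co <- coef(g)
  co[is.na(co)] <- 0  # aliased (e.g. constant) columns
  structure(list(intercept = unname(co[1]),
                 coefficients = setNames(unname(co[-1]), colnames(X)),
                 lambda = 0, alpha = 1,
                 center = colMeans(X), scale = .col_scale(X),
                 unpenalized = TRUE),
            class = "penalized_logistic_fit")
}

#' Predicted risk (probability scale)
#' @param fit a \code{penalized_logistic_fit}
#' @param X feature matrix with the training columns
#' @return numeric vector of probabilities
#' @export
predict_risk <- function(fit, X) {
  X <- as.matrix(X)
  as.numeric(plogis(fit$intercept + X %*% fit$coefficients))
}

#' Penalized-objective value of a fit (standardized parameterization)
#' @param fit a \code{penalized_logistic_fit}
#' @param X,y the data it was fit on
#' @return scalar objective value
#' @export
logistic_objective <- function(fit, X, y) {
  X <- as.matrix(X); y <- as.integer(y)
  eta <- fit$intercept + as.numeric(X %*% fit$coefficients)
  nll <- mean(log1p(exp(eta)) - y * eta)
  bs <- fit$coefficients * fit$scale  # standardized-scale coefficients
  nll + fit$lambda * (fit$alpha * sum(abs(bs)) +
                        (1 - fit$alpha) / 2 * sum(bs^2))
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a randomly chosen positive is ranked above a randomly
#' chosen negative, ties counted 1/2: the normalized Mann-Whitney U over all
#' positive/negative pairs.
#'
#' @param scores numeric predicted risk per subject
#' @param labels binary 0/1 labels
#' @return scalar in [0, 1]
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L)
    stop("undefined metric: AUC requires both classes present")
  r <- rank(scores)  # average ranks handle ties as 1/2
  (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# stratified fold assignment: within each class, shuffle and deal fold ids
.stratified_folds <- function(y, k, rng_seed) {
  folds <- integer(length(y))
  with_rng_seed(rng_seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Tune lambda by repeated stratified k-fold cross-validation maximizing AUC
#'
#' For each lambda on the grid: within one repeat, the held-out AUC is
#' averaged over the k folds; the curve is the mean of the L per-repeat
#' estimates and \code{se} is their standard deviation / sqrt(L).
#' \code{optimal_lambda} maximizes the mean curve, ties broken toward the
#' larger (sparser) lambda.  Splitting is stratified by class and depends
#' only on \code{y} and \code{rng_seed}, so experiments sharing a seed share
#' folds (paired comparisons).
#'
#' @param X feature matrix
#' @param y binary labels
#' @param grid lambda grid (default 0 to 3 step 0.05)
#' @param k folds (default 5)
#' @param L repeats (default 20)
#' @param alpha penalty mix (default 1, lasso)
#' @param rng_seed integer seed
#' @param unpenalized if TRUE, ignore the grid and cross-validate the
#'   unpenalized (<= 2 predictor) estimator; the curve collapses to one point
#'   at lambda = 0
#' @param pca_tau optional leakage-safe mode: when set, \code{X} is taken as
#'   the raw (pre-PCA) feature matrix and a PCA with this variance threshold
#'   is refit on the training rows of every fold, so the held-out subjects
#'   never influence the component basis.  Default \code{NULL} mirrors the
#'   study protocol (PCA fit once on the full cohort before tuning), which
#'   leaks the unlabeled feature geometry but not the labels.
#' @return object of class \code{cv_curve}: \code{grid}, \code{mean_auc},
#'   \code{se}, \code{per_repeat} (L x length(grid)), \code{k}, \code{L},
#'   \code{alpha}, \code{optimal_lambda}, \code{optimal_auc}, \code{rng_seed}
#' @export
cross_validate <- function(X, y, grid = default_lambda_grid(), k = 5L,
                           L = 20L, alpha = 1, rng_seed = 1L,
                           unpenalized = FALSE, pca_tau = NULL) {
  v <- .validate_xy(X, y); X <- v$X; y <- v$y
  n <- nrow(X)
  if (n < 2L * k) stop("need n >= 2k for ", k, "-fold cross-validation")
  if (!unpenalized && ncol(X) < 2L)
    stop("penalized cross-validation needs >= 2 predictors; ",
         "use `unpenalized = TRUE` for 1-2 predictor designs")
  if (unpenalized) grid <- 0
  grid <- sort(as.numeric(grid))
  gdec <- rev(grid)
  per_repeat <- matrix(NA_real_, nrow = L, ncol = length(grid))
  for (rep_i in seq_len(L)) {
    folds <- .stratified_folds(y, k, derive_seed(rng_seed, "cvfold", rep_i))
    fold_auc <- matrix(NA_real_, nrow = k, ncol = length(grid))
    for (f in seq_len(k)) {
      tr <- folds != f; te <- !tr
      if (length(unique(y[tr])) < 2L || length(unique(y[te])) < 2L)
        stop("resampling error: fold ", f, " lacks both classes (n too small)")
      Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
      if (!is.null(pca_tau)) {
        pm <- fit_pca(Xtr, tau = pca_tau)
        m <- max(2L, pm$retained)  # glmnet needs >= 2 columns
        pm$retained <- min(m, ncol(pm$loadings))
        Xtr <- transform_pca(pm, Xtr)$X
        Xte <- transform_pca(pm, Xte)$X
      }
      if (unpenalized) {
        fit <- fit_unpenalized_logistic(Xtr, y[tr])
        fold_auc[f, 1] <- auc(predict_risk(fit, Xte), y[te])
      } else {
        fit <- suppressWarnings(
          glmnet::glmnet(Xtr, y[tr], family = "binomial",
                         alpha = alpha, lambda = gdec, standardize = TRUE,
                         thresh = 1e-9, maxit = 1e5))
        pr <- predict(fit, Xte, s = gdec, type = "response")
        fold_auc[f, ] <- rev(apply(pr, 2L, auc, labels = y[te]))
      }
    }
    per_repeat[rep_i, ] <- colMeans(fold_auc)
  }
  mean_auc <- colMeans(per_repeat)
  se <- apply(per_repeat, 2L, sd) / sqrt(L)
  best <- max(which(mean_auc == max(mean_auc)))  # tie -> larger lambda
  structure(list(grid = grid, mean_auc = mean_auc, se = se,
                 per_repeat = per_repeat, k = as.integer(k), L = as.integer(L),
                 alpha = alpha, optimal_lambda = grid[best],
                 optimal_auc = mean_auc[best], rng_seed = as.integer(rng_seed)),
            class = "cv_curve")
}

#' @export
print.cv_curve <- function(x, ...) {
  cat("<cv_curve> ", length(x$grid), " lambda points, k = ", x$k, ", L = ",
      x$L, "; optimal lambda = ", x$optimal_lambda, " (mean CV AUC ",
      round(x$optimal_auc, 3), ")\n", sep = "")
  invisible(x)
}

#' Variable importance from standardized coefficient magnitudes
#'
#' \code{|coefficient * internal scale|}, linearly rescaled so the maximum is
#' 100; zero-coefficient variables score 0.  All-zero fits yield all-zero
#' scores with a warning.
#'
#' @param fit a \code{penalized_logistic_fit}
#' @return object of class \code{importance_ranking}: data.frame
#'   (variable, score) in descending score order
#' @export
variable_importance <- function(fit) {
  raw <- abs(fit$coefficients * fit$scale)
  if (max(raw) == 0) {
    warning("all coefficients are zero; importance scores are all 0")
    sc <- raw
  } else sc <- raw / max(raw) * 100
  out <- data.frame(variable = names(sc), score = unname(sc),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$variable), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("importance_ranking", "data.frame"))
}

#' Empirical ROC curve with stratified-bootstrap AUC confidence interval
#'
#' Threshold sweep over the observed scores; the 95% CI is the percentile
#' interval over \code{n_boot} stratified bootstrap resamples (resampling
#' within each class), clipped to [0, 1].
#'
#' @param scores predicted risk per subject
#' @param labels binary labels
#' @param n_boot bootstrap resamples (default 2000)
#' @param rng_seed integer seed
#' @param conf confidence level (default 0.95)
#' @return object of class \code{roc_result}: \code{thresholds}, \code{fpr},
#'   \code{tpr}, \code{auc}, \code{ci95}, \code{n_boot}
#' @export
roc_with_ci <- function(scores, labels, n_boot = 2000L, rng_seed = 1L,
                        conf = 0.95) {
  labels <- as.integer(labels)
  a <- auc(scores, labels)  # validates both classes present
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / npos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / nneg, 0)
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  boot <- with_rng_seed(rng_seed, vapply(seq_len(n_boot), function(b) {
    auc(c(sample(pos, npos, replace = TRUE), sample(neg, nneg, replace = TRUE)),
        c(rep(1L, npos), rep(0L, nneg)))
  }, 0))
  qs <- quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr, auc = a,
                 ci95 = pmin(pmax(qs, 0), 1), n_boot = as.integer(n_boot)),
            class = "roc_result")
}

#' Confusion matrix and derived diagnostics at a probability cutoff
#'
#' Predicted positive when \code{score >= threshold}.  Rates with an empty
#' denominator are reported as \code{NA}.
#'
#' @param scores predicted risk
#' @param labels binary labels
#' @param threshold probability cutoff in (0, 1), default 0.5
#' @return object of class \code{confusion_diagnostics}: TP, FP, TN, FN,
#'   sensitivity, specificity, ppv, npv, accuracy
#' @export
confusion_diagnostics <- function(scores, labels, threshold = 0.5) {
  if (!(threshold > 0 && threshold < 1)) stop("`threshold` must lie in (0, 1)")
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L); fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L); fn <- sum(pred == 0L & labels == 1L)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                 sensitivity = rate(tp, tp + fn),
                 specificity = rate(tn, tn + fp),
                 ppv = rate(tp, tp + fp), npv = rate(tn, tn + fn),
                 accuracy = (tp + tn) / length(labels),
                 threshold = threshold),
            class = "confusion_diagnostics")
}
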