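# The four classification problems and their variable-subset comparisons,
# run as configuration-driven experiments: imaging PCs alone, clinical
# (Age, BBC), family history, TNBC, and their combinations/ablations.
# Designs with <= 2 predictors use the unpenalized maximum-likelihood fit;
# larger designs use the lasso (L-PCR when imaging PCs are present).

.group_columns <- list(
  clinical = c("Age", "BBC"),
  family = c("FDR.BC", "FDR.OC", "SDR.BC", "SDR.OC", "TDR.BC", "TDR.OC", "MBC"),
  tnbc = "TNBC"
)

#' Define an experiment (a variable-subset classification problem)
#'
#' @param name experiment label
#' @param groups subset of \code{c("imaging", "clinical", "family", "tnbc")}
#' @param exclude character vector of column names to drop after assembly
#'   (e.g. \code{c("SDR.BC","SDR.OC","TDR.BC","TDR.OC")} to remove distant
#'   relatives)
#' @return object of class \code{experiment_spec}
#' @export
experiment_spec <- function(name, groups, exclude = character()) {
  groups <- match.arg(groups, c("imaging", "clinical", "family", "tnbc"),
                      several.ok = TRUE)
  structure(list(name = name, groups = groups, exclude = exclude),
            class = "experiment_spec")
}

#' The standard experiment presets
#'
#' The eleven variable-subset comparisons drawn in the study: each single
#' group, imaging paired with each non-imaging group, the all-variables
#' design and its ablations (no imaging, no family history, no distant
#' relatives).
#'
#' @return named list of \code{\link{experiment_spec}} objects
#' @export
experiment_presets <- function() {
  distant <- c("SDR.BC", "SDR.OC", "TDR.BC", "TDR.OC")
  list(
    imaging = experiment_spec("imaging", "imaging"),
    family = experiment_spec("family", "family"),
    clinical = experiment_spec("clinical", "clinical"),
    tnbc = experiment_spec("tnbc", "tnbc"),
    imaging_tnbc = experiment_spec("imaging_tnbc", c("imaging", "tnbc")),
    imaging_clinical = experiment_spec("imaging_clinical", c("imaging", "clinical")),
    imaging_family = experiment_spec("imaging_family", c("imaging", "family")),
    all_minus_imaging = experiment_spec("all_minus_imaging",
                                        c("clinical", "family", "tnbc")),
    all_minus_distant = experiment_spec("all_minus_distant",
                                        c("imaging", "clinical", "family", "tnbc"),
                                        exclude = distant),
    all_minus_family = experiment_spec("all_minus_family",
                                       c("imaging", "clinical", "tnbc")),
    all = experiment_spec("all", c("imaging", "clinical", "family", "tnbc"))
  )
}

#' Assemble a design matrix for an experiment
#'
#' Column-wise concatenation of the requested variable groups, joined by
#' subject id; labels are the mutation status.
#'
#' @param covariates data.frame with \code{subject_id}, \code{label} and the
#'   ten non-imaging covariate columns
#' @param pc_scores a \code{feature_matrix} of imaging PC scores (rownames =
#'   subject ids) or NULL when the spec has no imaging group
#' @param spec an \code{\link{experiment_spec}}
#' @return list with \code{X} (numeric matrix, rownames = subject ids) and
#'   \code{y} (labels)
#' @export
assemble_design <- function(covariates, pc_scores, spec) {
  ids <- covariates$subject_id
  cols <- list()
  if ("imaging" %in% spec$groups) {
    if (is.null(pc_scores)) stop("spec requests imaging but `pc_scores` is NULL")
    sids <- rownames(pc_scores$X)
    orphans <- union(setdiff(ids, sids), setdiff(sids, ids))
    if (length(orphans))
      stop("join error: subject ids do not align; orphans: ",
           paste(orphans, collapse = ", "))
    cols$imaging <- pc_scores$X[match(ids, sids), , drop = FALSE]
  }
  for (g in intersect(c("clinical", "family", "tnbc"), spec$groups)) {
    want <- .group_columns[[g]]
    miss <- setdiff(want, colnames(covariates))
    if (length(miss))
      stop("covariate table lacks column(s): ", paste(miss, collapse = ", "))
    cols[[g]] <- as.matrix(covariates[, want, drop = FALSE])
  }
  X <- do.call(cbind, cols)
  rownames(X) <- ids
  X <- X[, setdiff(colnames(X), spec$exclude), drop = FALSE]
  if (ncol(X) < 1L) stop("experiment '", spec$name, "' has no predictors left")
  list(X = X, y = as.integer(covariates$label))
}

#' Cross-validation configuration
#' @param grid lambda grid (default 0--3 step 0.05)
#' @param k folds (default 5)
#' @param L repeats (default 20)
#' @param alpha penalty mix (default 1, lasso)
#' @return list
#' @export
cv_config <- function(grid = default_lambda_grid(), k = 5L, L = 20L, alpha = 1)
  list(grid = grid, k = as.integer(k), L = as.integer(L), alpha = alpha)

#' Run one experiment end to end
#'
#' Applies the estimator routing rule — at most 2 predictors: unpenalized
#' maximum likelihood; otherwise the penalized path with lambda tuned by
#' repeated cross-validation — then refits on the full cohort at the optimum
#' and derives ROC (with bootstrap CI), variable importance, confusion
#' diagnostics and the selected-variable set.  Fully seeded: the same
#' \code{rng_seed} yields byte-identical serialized results, and experiments
#' sharing a seed share CV folds.
#'
#' @param design list \code{(X, y)} from \code{\link{assemble_design}}
#' @param spec an \code{\link{experiment_spec}}
#' @param cv a \code{\link{cv_config}}
#' @param rng_seed integer seed
#' @return object of class \code{experiment_result}
#' @export
run_experiment <- function(design, spec, cv = cv_config(), rng_seed = 1L) {
  X <- design$X; y <- design$y
  unpen <- ncol(X) <= 2L
  curve <- cross_validate(X, y, grid = cv$grid, k = cv$k, L = cv$L,
                          alpha = cv$alpha,
                          rng_seed = derive_seed(rng_seed, "cv"),
                          unpenalized = unpen)
  fit <- if (unpen) fit_unpenalized_logistic(X, y)
  else fit_penalized_logistic(X, y, lambda = curve$optimal_lambda,
                              alpha = cv$alpha)
  scores <- predict_risk(fit, X)
  roc <- roc_with_ci(scores, y, rng_seed = derive_seed(rng_seed, "boot"))
  imp <- suppressWarnings(variable_importance(fit))
  conf <- confusion_diagnostics(scores, y)
  selected <- names(fit$coefficients)[fit$coefficients != 0]
  structure(list(spec = spec, estimator = if (unpen) "unpenalized" else "penalized",
                 cv = curve, fit = fit, roc = roc, importance = imp,
                 confusion = conf, selected = selected,
                 mean_cv_auc = curve$optimal_auc,
                 rng_seed = as.integer(rng_seed)),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result> '", x$spec$name, "' (", x$estimator, "): mean CV AUC ",
      round(x$mean_cv_auc, 3), " at lambda = ", x$cv$optimal_lambda,
      "; selected: ", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n", sep = "")
  invisible(x)
}

#' Rank experiments by cross-validated AUC
#'
#' @param results list of \code{experiment_result} objects on the same cohort
#' @return data.frame (name, auc, optimal_lambda, estimator, n_selected,
#'   selected) sorted by AUC descending (stable)
#' @export
compare_experiments <- function(results) {
  if (length(results) < 2L) stop("need at least 2 results to compare")
  n_sub <- vapply(results, function(r) r$confusion$TP + r$confusion$FP +
                    r$confusion$TN + r$confusion$FN, numeric(1))
  if (length(unique(n_sub)) != 1L)
    stop("comparison error: results come from cohorts of different sizes (",
         paste(unique(n_sub), collapse = ", "), ")")
  tab <- do.call(rbind, lapply(results, function(r) data.frame(
    name = r$spec$name, auc = r$mean_cv_auc,
    optimal_lambda = r$cv$optimal_lambda, estimator = r$estimator,
    n_selected = length(r$selected),
    selected = paste(r$selected, collapse = ","),
    stringsAsFactors = FALSE)))
  tab <- tab[order(-tab$auc), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Serialize an experiment result to canonical JSON
#'
#' Deterministic: identical config + seed give byte-identical output (used by
#' the reproducibility checks and the CLI).
#'
#' @param res an \code{experiment_result}
#' @return a JSON string
#' @export
experiment_result_json <- function(res) {
  as.character(jsonlite::toJSON(list(
    name = res$spec$name, groups = res$spec$groups, exclude = res$spec$exclude,
    estimator = res$estimator, rng_seed = res$rng_seed,
    grid = res$cv$grid, mean_auc = res$cv$mean_auc, se = res$cv$se,
    optimal_lambda = res$cv$optimal_lambda, mean_cv_auc = res$mean_cv_auc,
    intercept = res$fit$intercept,
    coefficients = as.list(res$fit$coefficients),
    selected = res$selected,
    importance = res$importance,
    full_data_auc = res$roc$auc, auc_ci95 = res$roc$ci95,
    confusion = unclass(res$confusion)),
    digits = NA, auto_unbox = TRUE))
}
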