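# Patch -> subject feature aggregation and PCA with the 95% explained-variance
# retention rule.  PCA is computed by economy SVD of the centered data matrix
# (exact, and cheap in the n << p regime typical here), with a deterministic
# sign convention so loadings reproduce across platforms.

#' Construct a feature matrix container
#'
#' @param X numeric matrix, one row per unit (subject or patch), named columns
#' @param labels binary outcome vector aligned with rows
#' @return object of class \code{feature_matrix}
#' @export
feature_matrix <- function(X, labels) {
  X <- as.matrix(X)
  if (anyNA(X) || !all(is.finite(X))) stop("feature matrix must have no missing entries")
  labels <- as.integer(labels)
  if (nrow(X) != length(labels)) stop("row count must equal label count")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (anyDuplicated(colnames(X))) stop("feature column names must be unique")
  structure(list(X = X, labels = labels), class = "feature_matrix")
}

#' Aggregate patch vectors to one feature vector per subject
#'
#' Mode \code{"mean"}: element-wise mean over each subject's patch vectors,
#' one row per subject.  Patch order does not matter.
#'
#' @param ps a \code{patch_set} from \code{\link{build_cohort_patches}}
#' @param mode aggregation mode; only \code{"mean"} operates at this level
#'   (for patch-level PCA see \code{\link{imaging_pc_scores}})
#' @param expected_ids optional character vector of subject ids that must all
#'   be present; a listed subject with zero patches is an error
#' @return a \code{\link{feature_matrix}} with one row per subject, rownames =
#'   subject ids
#' @export
aggregate_subject_features <- function(ps, mode = "mean", expected_ids = NULL) {
  mode <- match.arg(mode, "mean")
  ids <- unique(ps$info$subject_id)
  if (!is.null(expected_ids)) {
    zero <- setdiff(expected_ids, ids)
    if (length(zero))
      stop("aggregation error: subject(s) with zero patches: ",
           paste(zero, collapse = ", "))
  }
  grp <- factor(ps$info$subject_id, levels = ids)
  M <- rowsum(ps$X, grp) / as.vector(table(grp))
  labels <- vapply(ids, function(id)
    ps$info$label[match(id, ps$info$subject_id)], integer(1))
  colnames(M) <- paste0("vox", seq_len(ncol(M)))
  fm <- feature_matrix(M, labels)
  rownames(fm$X) <- ids
  fm
}

#' Fit centered PCA with a variance-retention rule
#'
#' Components are ordered by decreasing variance; \code{retained} is the
#' smallest m whose cumulative explained-variance ratio reaches \code{tau}.
#' Loadings carry a deterministic sign: the largest-magnitude entry of each
#' loading is positive.  Numerically null directions (singular value below
#' \code{max(d) * 1e-12}) are dropped, so \code{evr} sums to 1 over the kept
#' rank.
#'
#' @param X a \code{feature_matrix} or bare numeric matrix (rows = units)
#' @param tau explained-variance threshold in (0, 1], default 0.95
#' @return object of class \code{pca_model}: \code{mean}, \code{loadings}
#'   (p x K), \code{evr}, \code{sdev}, \code{retained}, \code{tau}
#' @export
fit_pca <- function(X, tau = 0.95) {
  if (inherits(X, "feature_matrix")) X <- X$X
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("PCA fit error: need at least 2 rows, got ", nrow(X))
  if (!(tau > 0 && tau <= 1)) stop("`tau` must lie in (0, 1]")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = 0)
  keep <- sv$d > max(sv$d[1], .Machine$double.eps) * 1e-12
  d <- sv$d[keep]
  V <- sv$v[, keep, drop = FALSE]
  # sign convention: largest-|entry| of each loading positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  vars <- d^2 / (nrow(X) - 1)
  evr <- vars / sum(vars)
  retained <- which(cumsum(evr) >= tau - 1e-12)[1]
  rownames(V) <- colnames(X)
  colnames(V) <- paste0("PC", seq_len(ncol(V)))
  structure(list(mean = mu, loadings = V, evr = evr, sdev = sqrt(vars),
                 retained = as.integer(retained), tau = tau),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model> ", length(x$evr), " components; retained ", x$retained,
      " at tau = ", x$tau, " (cum. EVR ",
      round(sum(x$evr[seq_len(x$retained)]), 4), ")\n", sep = "")
  invisible(x)
}

#' Project data onto the retained principal components
#'
#' @param model a \code{\link{pca_model}}
#' @param X a \code{feature_matrix} or matrix with the training feature columns
#' @param labels optional labels when \code{X} is a bare matrix
#' @return a \code{\link{feature_matrix}} of scores, columns PC1..PCm
#' @export
transform_pca <- function(model, X, labels = NULL) {
  if (inherits(X, "feature_matrix")) { labels <- X$labels; X <- X$X }
  X <- as.matrix(X)
  if (ncol(X) != nrow(model$loadings))
    stop("schema error: data has ", ncol(X), " feature columns, model expects ",
         nrow(model$loadings))
  m <- model$retained
  S <- sweep(X, 2L, model$mean) %*% model$loadings[, seq_len(m), drop = FALSE]
  colnames(S) <- paste0("PC", seq_len(m))
  if (is.null(labels)) labels <- rep(0L, nrow(S))
  fm <- feature_matrix(S, labels)
  rownames(fm$X) <- rownames(X)
  fm
}

#' Subject-level imaging principal-component scores
#'
#' The full imaging feature route.  Two modes:
#' \describe{
#'   \item{\code{"pca_then_mean"} (default)}{fit PCA on the patch-level matrix
#'     (rows = patches), project every patch, then average each subject's
#'     patch scores.  This is the route under which more components can be
#'     retained than there are subjects.}
#'   \item{\code{"mean"}}{average each subject's patches first, then fit PCA
#'     on the subject-level matrix (rank at most n_subjects - 1; the cheap
#'     route used at reduced test scale).}
#' }
#'
#' @param ps a \code{patch_set}
#' @param tau explained-variance threshold (default 0.95)
#' @param mode \code{"pca_then_mean"} or \code{"mean"}
#' @return list with \code{scores} (a \code{feature_matrix}, one row per
#'   subject) and \code{model} (the \code{pca_model})
#' @export
imaging_pc_scores <- function(ps, tau = 0.95,
                              mode = c("pca_then_mean", "mean")) {
  mode <- match.arg(mode)
  if (mode == "mean") {
    fm <- aggregate_subject_features(ps)
    model <- fit_pca(fm, tau = tau)
    scores <- transform_pca(model, fm)
  } else {
    X <- ps$X
    colnames(X) <- paste0("vox", seq_len(ncol(X)))
    model <- fit_pca(X, tau = tau)
    patch_scores <- transform_pca(model, X)
    ids <- unique(ps$info$subject_id)
    grp <- factor(ps$info$subject_id, levels = ids)
    M <- rowsum(patch_scores$X, grp) / as.vector(table(grp))
    labels <- vapply(ids, function(id)
      ps$info$label[match(id, ps$info$subject_id)], integer(1))
    scores <- feature_matrix(M, labels)
    rownames(scores$X) <- ids
  }
  list(scores = scores, model = model)
}

#' Serialize a PCA model to JSON (+ plain-text loading matrix sidecar)
#' @param model a \code{pca_model}
#' @param prefix path prefix; writes \code{<prefix>_pca.json} and
#'   \code{<prefix>_loadings.tsv}
#' @return invisibly, the two paths
#' @export
write_pca_model <- function(model, prefix) {
  jpath <- paste0(prefix, "_pca.json")
  lpath <- paste0(prefix, "_loadings.tsv")
  jsonlite::write_json(
    list(mean = model$mean, evr = model$evr, sdev = model$sdev,
         retained = model$retained, tau = model$tau),
    jpath, digits = NA, auto_unbox = TRUE)
  write.table(model$loadings, lpath, sep = "\t", row.names = FALSE)
  invisible(c(json = jpath, loadings = lpath))
}
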