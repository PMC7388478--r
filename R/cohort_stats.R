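# Cohort-comparison statistics: exact two-sided binomial tests
# (minimum-likelihood convention), Welch t-test from group summaries,
# Spearman correlation matrix, and empirical-probability (EP) assignment
# from family/clinical structure.

#' Exact two-sided binomial test (minimum-likelihood convention)
#'
#' The two-sided p-value sums P(X = x) over every outcome x in 0..n whose
#' point probability does not exceed P(X = k) * (1 + 1e-7), X ~ Binom(n, p0),
#' capped at 1.  This is the convention under which the cohort's published
#' prevalence comparisons (e.g. 13/16 vs 0.66 -> p = 0.292) reproduce to
#' 3 decimals.
#'
#' @param k successes, 0 <= k <= n
#' @param n trials
#' @param p0 null proportion in (0, 1)
#' @return object of class \code{binomial_test}: \code{k}, \code{n},
#'   \code{p0}, \code{p_value}
#' @export
exact_binomial_two_sided <- function(k, n, p0) {
  k <- as.integer(k); n <- as.integer(n)
  if (n < 1L || k < 0L || k > n) stop("need 0 <= k <= n with n >= 1")
  if (!(p0 > 0 && p0 < 1))
    stop("degenerate null: `p0` must lie strictly inside (0, 1)")
  d <- dbinom(0:n, n, p0)
  p <- min(1, sum(d[d <= d[k + 1L] * (1 + 1e-7)]))
  structure(list(k = k, n = n, p0 = p0, p_value = p), class = "binomial_test")
}

#' @export
print.binomial_test <- function(x, ...) {
  cat("Exact two-sided binomial test: k = ", x$k, ", n = ", x$n,
      ", null p = ", x$p0, "; p-value = ", signif(x$p_value, 4), "\n", sep = "")
  invisible(x)
}

#' Welch two-sample t-test from group summaries
#'
#' Unequal-variance statistic with Satterthwaite degrees of freedom; the form
#' used to compare age at onset between carriers and controls from printed
#' mean +/- SD summaries.
#'
#' @param m1,s1,n1 mean, SD (> 0) and size (>= 2) of group 1
#' @param m2,s2,n2 same for group 2
#' @return list with \code{statistic}, \code{df}, \code{p_value} (two-sided)
#' @export
welch_t_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (any(c(s1, s2) <= 0)) stop("parameter error: SDs must be > 0")
  if (any(c(n1, n2) < 2)) stop("parameter error: group sizes must be >= 2")
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  t_stat <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(statistic = t_stat, df = df, p_value = 2 * pt(-abs(t_stat), df))
}

#' Pairwise Spearman correlation matrix
#'
#' Rank correlation with average ranks for ties; symmetric with unit
#' diagonal.  Constant columns yield \code{NA} off-diagonal entries and are
#' listed in the \code{"constant_columns"} attribute.
#'
#' @param table data.frame or matrix of per-subject numeric variables
#'   (typically including the outcome)
#' @return symmetric correlation matrix
#' @export
spearman_matrix <- function(table) {
  M <- as.matrix(table)
  storage.mode(M) <- "double"
  if (nrow(M) < 3L) stop("need at least 3 subjects")
  const <- colnames(M)[apply(M, 2L, function(x) length(unique(x)) == 1L)]
  R <- suppressWarnings(cor(M, method = "spearman"))
  diag(R) <- 1
  attr(R, "constant_columns") <- const
  R
}

# empirical probabilities of detecting a BRCA1/2 pathogenic variant, by
# guideline criterion (max over satisfied rules; testing threshold is 10%)
.ep_values <- c(bc_and_oc = 0.484, three_bc_two_young = 0.307,
                bilateral_young = 0.248, three_bc = 0.224, tnbc = 0.112)

#' Assign the empirical probability (EP) of a BRCA1/2 variant
#'
#' Evaluates the guideline criteria on family/clinical structure and returns
#' the maximum EP over the satisfied rules:
#' \itemize{
#'   \item >= 1 breast and >= 1 ovarian cancer in the family including the
#'     index case: 0.484
#'   \item >= 3 breast cancers with >= 2 diagnosed before age 51: 0.307
#'   \item one affected breast-cancer relative plus bilateral disease in the
#'     index case (counted as three independent breast tumors): 0.307
#'   \item bilateral/contralateral disease with the index case's first tumor
#'     before age 51: 0.248
#'   \item >= 3 breast cancers at any age: 0.224
#'   \item triple-negative tumor regardless of family history: 0.112
#'   \item otherwise 0 (below the 10% testing threshold)
#' }
#' The index case always contributes one breast tumor (two when bilateral).
#' Missing ages make the age-dependent rules unsatisfied rather than erroring.
#'
#' @param subject list or one-row data.frame with fields \code{TNBC},
#'   \code{BBC}, \code{FDR.BC}, \code{FDR.OC}, \code{SDR.BC}, \code{SDR.OC},
#'   \code{TDR.BC}, \code{TDR.OC}; optional \code{age_first_tumor} (index
#'   case) and \code{n_bc_before_51} (family count incl. index)
#' @return the EP fraction (one of 0.484, 0.307, 0.248, 0.224, 0.112, or 0)
#' @export
assign_empirical_probability <- function(subject) {
  subject <- as.list(subject)
  need <- c("TNBC", "BBC", "FDR.BC", "FDR.OC", "SDR.BC", "SDR.OC",
            "TDR.BC", "TDR.OC")
  missing_f <- need[!vapply(need, function(f)
    !is.null(subject[[f]]) && !is.na(subject[[f]]), logical(1))]
  if (length(missing_f))
    stop("data error: missing required field(s): ",
         paste(missing_f, collapse = ", "))
  rel_bc <- subject$FDR.BC + subject$SDR.BC + subject$TDR.BC
  rel_oc <- subject$FDR.OC + subject$SDR.OC + subject$TDR.OC
  bbc <- subject$BBC >= 1
  index_tumors <- 1L + as.integer(bbc)
  total_bc <- rel_bc + index_tumors
  age <- subject$age_first_tumor
  n_young <- subject$n_bc_before_51
  ep <- 0
  if (total_bc >= 1 && rel_oc >= 1) ep <- max(ep, .ep_values[["bc_and_oc"]])
  if (total_bc >= 3 && !is.null(n_young) && !is.na(n_young) && n_young >= 2)
    ep <- max(ep, .ep_values[["three_bc_two_young"]])
  if (rel_bc >= 1 && bbc) ep <- max(ep, .ep_values[["three_bc_two_young"]])
  if (bbc && !is.null(age) && !is.na(age) && age < 51)
    ep <- max(ep, .ep_values[["bilateral_young"]])
  if (total_bc >= 3) ep <- max(ep, .ep_values[["three_bc"]])
  if (subject$TNBC >= 1) ep <- max(ep, .ep_values[["tnbc"]])
  ep
}
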