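# Exact binomial test (incl. the published cohort comparisons), Welch t from
# summaries, Spearman matrix, and empirical-probability assignment.

test_that("published cohort binomial p-values reproduce to 3 decimals", {
  cases <- list(list(13, 16, 0.66, 0.292),   # BRCA1 share among carriers
                list(12, 13, 0.80, 0.486),   # TNBC among BRCA1-positive
                list(5, 21, 0.14, 0.203),    # TNBC among controls
                list(6, 13, 0.441, 1.000),   # bilateral among BRCA1-positive
                list(6, 21, 0.172, 0.157))   # bilateral among controls
  for (cs in cases)
    expect_equal(round(exact_binomial_two_sided(cs[[1]], cs[[2]], cs[[3]])$p_value, 3),
                 cs[[4]], label = paste(cs[[1]], cs[[2]], cs[[3]]))
})

test_that("binomial p equals full-enumeration oracle on random cases", {
  cases <- brcaradiomics:::with_rng_seed(55, {
    n <- sample(1:30, 40, replace = TRUE)
    data.frame(n = n, k = vapply(n, function(m) sample(0:m, 1), 0L),
               p0 = round(runif(40, 0.05, 0.95), 3))
  })
  for (i in seq_len(nrow(cases))) {
    got <- exact_binomial_two_sided(cases$k[i], cases$n[i], cases$p0[i])$p_value
    want <- binom.test(cases$k[i], cases$n[i], cases$p0[i])$p.value
    expect_equal(got, min(want, 1), tolerance = 1e-12,
                 label = paste(cases$k[i], cases$n[i], cases$p0[i]))
  }
})

test_that("binomial edge behavior: mode, near-degenerate null, validation", {
  # k at the distribution mode gives p = 1
  expect_equal(exact_binomial_two_sided(6, 13, 0.441)$p_value, 1)
  expect_lte(exact_binomial_two_sided(10, 10, 0.99)$p_value, 1)
  expect_equal(exact_binomial_two_sided(10, 10, 0.999)$p_value, 1)
  expect_error(exact_binomial_two_sided(3, 5, 0), "degenerate")
  expect_error(exact_binomial_two_sided(3, 5, 1), "degenerate")
  expect_error(exact_binomial_two_sided(6, 5, 0.5), "k <= n")
})

test_that("Welch t from summaries matches a constructed-data t.test oracle", {
  # vectors engineered to exact mean/SD, so t.test is an independent route
  make <- function(m, s, n) { z <- seq_len(n); m + s * (z - mean(z)) / sd(z) }
  g1 <- make(36.8, 7, 16); g2 <- make(38, 11, 25)
  ref <- t.test(g1, g2, var.equal = FALSE)
  got <- welch_t_from_summary(36.8, 7, 16, 38, 11, 25)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(round(got$p_value, 2), 0.67)   # summary-based value for the cohort ages
  # identical groups
  same <- welch_t_from_summary(5, 2, 10, 5, 2, 10)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # p decreases monotonically in |m1 - m2|
  ps <- vapply(seq(0, 5, by = 0.5), function(d)
    welch_t_from_summary(10 + d, 2, 15, 10, 3, 20)$p_value, 0)
  expect_true(all(diff(ps) < 0))
  expect_error(welch_t_from_summary(1, 0, 5, 2, 1, 5), "SD")
  expect_error(welch_t_from_summary(1, 1, 1, 2, 1, 5), "sizes")
})

test_that("Spearman matrix: identities, rank invariance, brute-force oracle", {
  tab <- brcaradiomics:::with_rng_seed(77, data.frame(
    a = rnorm(10), b = rpois(10, 3), c = runif(10), d = rnorm(10)))
  R <- spearman_matrix(tab)
  expect_equal(diag(R), setNames(rep(1, 4), colnames(tab)))
  expect_equal(R, t(R))
  oracle <- cor(apply(as.matrix(tab), 2, rank))   # rank-then-Pearson
  expect_equal(unclass(R), oracle, tolerance = 1e-12, ignore_attr = TRUE)
  # strictly monotone transform preserves rank correlation exactly
  tab2 <- transform(tab, e = exp(a))
  R2 <- spearman_matrix(tab2)
  expect_equal(R2["a", "e"], 1.0)
  # constant column flagged, off-diagonals NA
  tab3 <- transform(tab, k = 1)
  R3 <- spearman_matrix(tab3)
  expect_equal(attr(R3, "constant_columns"), "k")
  expect_true(all(is.na(R3["k", setdiff(colnames(R3), "k")])))
  expect_equal(R3["k", "k"], 1)
  expect_error(spearman_matrix(tab[1:2, ]), "3 subjects")
})

base_subject <- function(...) {
  s <- list(TNBC = 0, BBC = 0, FDR.BC = 0, FDR.OC = 0, SDR.BC = 0,
            SDR.OC = 0, TDR.BC = 0, TDR.OC = 0)
  modifyList(s, list(...))
}

test_that("EP assignment follows the guideline rules", {
  # >= 1 BC (the index) and >= 1 OC in the family
  expect_equal(assign_empirical_probability(base_subject(FDR.OC = 1)), 0.484)
  # TNBC with empty family history
  expect_equal(assign_empirical_probability(base_subject(TNBC = 1)), 0.112)
  # one affected BC relative + bilateral index counts as three tumors
  expect_equal(assign_empirical_probability(base_subject(FDR.BC = 1, BBC = 1)), 0.307)
  # three BC cases, two before 51
  expect_equal(assign_empirical_probability(
    base_subject(FDR.BC = 2, n_bc_before_51 = 2)), 0.307)
  # three BC cases, ages unknown -> the any-age rule only
  expect_equal(assign_empirical_probability(base_subject(FDR.BC = 2)), 0.224)
  # bilateral index, first tumor before 51
  expect_equal(assign_empirical_probability(
    base_subject(BBC = 1, age_first_tumor = 44)), 0.248)
  # bilateral index alone, age unknown: two tumors, below every threshold
  expect_equal(assign_empirical_probability(base_subject(BBC = 1)), 0)
  # max over satisfied rules: OC rule dominates TNBC
  expect_equal(assign_empirical_probability(
    base_subject(TNBC = 1, SDR.OC = 1)), 0.484)
  expect_error(assign_empirical_probability(list(TNBC = 1, BBC = 0)), "FDR.BC")
})

test_that("EP is monotone: adding affected relatives never lowers it", {
  fields <- c("FDR.BC", "FDR.OC", "SDR.BC", "SDR.OC", "TDR.BC", "TDR.OC")
  subjects <- brcaradiomics:::with_rng_seed(88, lapply(1:30, function(i)
    base_subject(TNBC = rbinom(1, 1, 0.3), BBC = rbinom(1, 1, 0.3),
                 FDR.BC = rpois(1, 1), FDR.OC = rpois(1, 0.3),
                 SDR.BC = rpois(1, 0.7), SDR.OC = rpois(1, 0.2),
                 TDR.BC = rpois(1, 0.5), TDR.OC = rpois(1, 0.1),
                 n_bc_before_51 = sample(c(NA, 0:3), 1))))
  for (s in subjects) {
    ep0 <- assign_empirical_probability(s)
    for (f in fields) {
      s2 <- s; s2[[f]] <- s2[[f]] + 1
      expect_gte(assign_empirical_probability(s2), ep0)
    }
  }
})
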