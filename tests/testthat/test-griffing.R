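test_that("fit satisfies the identifiability constraints to machine precision", {
  d <- diallel_design(6, 3, 2)
  tab <- simulate_diallel(complete_config(d, seed = 21))$table
  fit <- fit_griffing(tab, d, "height")
  expect_lt(abs(sum(fit$gca)), 1e-10)
  expect_lt(max(abs(rowSums(fit$sca))), 1e-10)
  expect_equal(fit$sca, t(fit$sca))
  expect_lt(max(abs(fit$rec + t(fit$rec))), 1e-10)
  f3 <- fit_method3(tab, d, "height")$fit
  expect_lt(abs(sum(f3$gca)), 1e-10)
  expect_lt(max(abs(rowSums(f3$sca))), 1e-10)
})

test_that("noiseless single-class data are recovered exactly", {
  d <- diallel_design(5, 2, 2)
  # additive-only: s and r vanish, g recovers centered a
  cfg <- complete_config(d, mu = 3, beta_inbred = 0, tau_a = 2, tau_b = 0,
                         tau_m = 0, tau_v = 0, tau_w = 0, tau_env = 0,
                         density_slope = 0, tau_density = 0, sigma = 0,
                         seed = 22)
  sim <- simulate_diallel(cfg)
  fit <- fit_griffing(sim$table, d, "height")
  a <- sim$effects$a
  expect_equal(unname(fit$gca), unname(a - mean(a)), tolerance = 1e-10)
  expect_lt(max(abs(fit$sca)), 1e-10)
  expect_lt(max(abs(fit$rec)), 1e-10)
  # maternal-only: r_jk = m_j - m_k
  cfgm <- complete_config(d, mu = 0, beta_inbred = 0, tau_a = 0, tau_b = 0,
                          tau_m = 2, tau_v = 0, tau_w = 0, tau_env = 0,
                          density_slope = 0, tau_density = 0, sigma = 0,
                          seed = 23)
  simm <- simulate_diallel(cfgm)
  fitm <- fit_griffing(simm$table, d, "height")
  m <- simm$effects$m
  expect_equal(unname(fitm$rec), unname(outer(m, m, "-")), tolerance = 1e-10)
})

test_that("closed-form estimates match the constrained least-squares oracle", {
  set.seed(24)
  for (p in c(3, 5, 6)) {
    d <- diallel_design(p, 2, 2)
    tab <- simulate_diallel(complete_config(d, seed = p))$table
    for (method in c("I", "III")) {
      fit <- if (method == "I") fit_griffing(tab, d, "height")
             else fit_method3(tab, d, "height")$fit
      M <- fit$cell_means
      if (method == "III") diag(M) <- 0
      oracle <- griffing_ols_oracle(M, method)
      expect_equal(fit$mu, oracle$mu, tolerance = 1e-8)
      expect_equal(unname(fit$gca), oracle$gca, tolerance = 1e-8)
      expect_equal(unname(fit$sca), oracle$sca, tolerance = 1e-8)
      expect_equal(unname(fit$rec), oracle$rec, tolerance = 1e-8)
    }
  }
})

test_that("ANOVA partitions are exact and df match the skeleton", {
  d <- diallel_design(6, 3, 2)
  tab <- simulate_diallel(complete_config(d, seed = 25))$table
  an <- griffing_anova(tab, d, "height")
  expect_equal(an$df, unname(anova_dof(d)[an$source]))
  g_parts <- an$SS[an$source %in% c("GCA", "SCA", "Reciprocal")]
  expect_equal(sum(g_parts), an$SS[an$source == "Genotype"],
               tolerance = 1e-6)
  ge_parts <- an$SS[an$source %in% c("GCA x E", "SCA x E", "Reciprocal x E")]
  expect_equal(sum(ge_parts), an$SS[an$source == "G x E"], tolerance = 1e-6)
  top <- an$SS[an$source %in% c("Genotype", "Location", "G x E", "rep(E)",
                                "Error")]
  expect_equal(sum(top), an$SS[an$source == "Total"], tolerance = 1e-6)
  expect_true(all(an$SS > -1e-10))
  # noiseless additive-only data: SCA, Reciprocal, Error SS all zero
  cfg0 <- complete_config(d, mu = 1, beta_inbred = 0, tau_a = 2, tau_b = 0,
                          tau_m = 0, tau_v = 0, tau_w = 0, tau_env = 0,
                          density_slope = 0, tau_density = 0, sigma = 0,
                          seed = 26)
  an0 <- griffing_anova(simulate_diallel(cfg0)$table, d, "height")
  expect_lt(an0$SS[an0$source == "SCA"], 1e-8)
  expect_lt(an0$SS[an0$source == "Reciprocal"], 1e-8)
  expect_lt(an0$SS[an0$source == "Error"], 1e-8)
})

test_that("single-environment ANOVA omits interaction rows", {
  d <- diallel_design(4, 1, 2)
  tab <- simulate_diallel(complete_config(d, seed = 27))$table
  an <- griffing_anova(tab, d, "height")
  expect_false(any(c("Location", "G x E") %in% an$source))
  expect_equal(sum(an$df[!an$source %in%
                           c("Total", "GCA", "SCA", "Reciprocal")]),
               an$df[an$source == "Total"])
})

test_that("Baker's ratio follows its formula and monotonicity", {
  expect_equal(bakers_ratio(1, 0), 1)
  expect_equal(bakers_ratio(1, 1), 2 / 3)
  expect_equal(bakers_ratio(2, 1), 0.8)
  expect_error(bakers_ratio(0, 0), "undefined")
  ratios <- vapply(seq(0, 5, by = 0.5), function(s) bakers_ratio(2, s),
                   numeric(1))
  expect_true(all(diff(ratios) < 0))
})

test_that("Method III drops selfs and reciprocal estimates ignore level shifts", {
  d <- diallel_design(4, 1, 2)
  tab <- simulate_diallel(complete_config(d, seed = 28))$table
  m3 <- fit_method3(tab, d, "height")
  expect_equal(m3$fit$n_per_cell, 2)
  expect_equal(m3$anova$df[m3$anova$source == "Genotype"], 4 * 3 - 1)
  shifted <- tab
  shifted$height <- shifted$height + 100
  expect_equal(fit_griffing(shifted, d, "height")$rec,
               fit_griffing(tab, d, "height")$rec, tolerance = 1e-9)
  expect_error(fit_method3(tab, diallel_design(2, 1, 2), "height"),
               "Method III")
})

test_that("incomplete or unbalanced tables are rejected with guidance", {
  d <- diallel_design(3, 1, 2)
  tab <- simulate_diallel(complete_config(d, seed = 29))$table
  tab_na <- tab; tab_na$height[4] <- NA
  expect_error(fit_griffing(tab_na, d, "height"), "impute")
  expect_error(fit_griffing(tab[-1, ], d, "height"), "balanced")
})

test_that("effect t-tests behave at the null and under exact fits", {
  d <- diallel_design(6, 2, 2)
  tab <- simulate_diallel(null_config(d, seed = 30))$table
  fit <- fit_griffing(tab, d, "height")
  an <- griffing_anova(tab, d, "height")
  et <- effect_tests(fit, an)
  expect_equal(et$t, et$estimate / et$se)
  expect_true(all(et$p >= 0 & et$p <= 1))
  # a zero estimate gives t = 0, p = 1
  et0 <- et; i <- which.min(abs(et$estimate))
  expect_equal(2 * pt(0, an$df[an$source == "Error"], lower.tail = FALSE), 1)
  # noiseless data: exact fit flagged, zero SEs
  cfg0 <- complete_config(d, mu = 1, beta_inbred = 0, tau_a = 1, tau_b = 0,
                          tau_m = 0, tau_v = 0, tau_w = 0, tau_env = 0,
                          density_slope = 0, tau_density = 0, sigma = 0,
                          seed = 31)
  tab0 <- simulate_diallel(cfg0)$table
  fit0 <- fit_griffing(tab0, d, "height")
  an0 <- griffing_anova(tab0, d, "height")
  et0 <- effect_tests(fit0, an0)
  expect_true(all(et0$se == 0))
  expect_true(all(is.na(et0$p)))
  expect_true(isTRUE(attr(et0, "exact_fit")))
})

test_that("stratified per-environment fits reuse the combined estimators", {
  d <- diallel_design(4, 2, 2)
  tab <- simulate_diallel(complete_config(d, seed = 32))$table
  f1 <- fit_griffing(tab, d, "height", environment = "E1")
  tab1 <- tab[tab$environment == "E1", ]
  expect_equal(f1$gca, fit_griffing(tab1, d, "height")$gca)
  expect_equal(f1$n_per_cell, 2)
})
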