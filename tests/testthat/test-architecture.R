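test_that("degree of dominance hits its defining anchor points", {
  d <- diallel_design(2, 1, 1)
  # grids built from selfs yAA, yBB and hybrid mean yBb via the inbred class:
  # choose a and b so that self(A)=0, self(B)=4 and the hybrid sits where
  # each anchor case demands.
  anchor <- function(yBb) {
    # mu + a1 + a2 = yBb on hybrids; selfs via b deviations
    a <- c(0, 0)
    pp <- make_point_posterior(d, mu = yBb, a = a, beta_inbred = 0,
                               b = c(0 - yBb, 4 - yBb),
                               m = c(0, 0), v = 0, w = 0)
    degree_of_dominance(pp, "P1", "P2")
  }
  expect_equal(anchor(4)$mean, 1)          # y_Bb = y_BB: A dominant
  expect_equal(anchor(2)$mean, 0)          # midparent: additive
  expect_equal(anchor(0)$mean, -1)         # y_Bb = y_bb: A recessive
  expect_equal(anchor(4)$classification, "dominant")
  expect_equal(anchor(2)$classification, "additive")
  expect_equal(anchor(0)$classification, "recessive")
  expect_equal(anchor(7)$classification, "pseudo-overdominant")
})

test_that("swapping A and B negates aCR when the hybrid mean is shared", {
  d <- diallel_design(3, 1, 1)
  set.seed(81)
  pp <- make_point_posterior(
    d, mu = 5, a = rnorm(3), beta_inbred = -2, b = rnorm(3),
    m = c(0, 0, 0), v = rnorm(3), w = c(0, 0, 0), n_draws = 3)
  ab <- degree_of_dominance(pp, "P1", "P2")
  ba <- degree_of_dominance(pp, "P2", "P1")
  # aCR(A,B) + aCR(B,A) = 0 identically when y_Bb is the reciprocal average
  expect_equal(ab$draws, -ba$draws, tolerance = 1e-10)
})

test_that("degenerate selfs are excluded and reported", {
  d <- diallel_design(2, 1, 1)
  pp <- make_point_posterior(d, mu = 1, a = c(0, 0), beta_inbred = 0,
                             b = c(0, 0), m = c(0, 0), v = 0, w = 0)
  expect_error(degree_of_dominance(pp, "P1", "P2"), "coincide")
})

test_that("VarP shares plus unexplained sum to exactly 100 per draw", {
  d <- diallel_design(5, 1, 2)
  tab <- simulate_diallel(complete_config(d, seed = 82))$table
  post <- gibbs_fit(tab, d, "height", chains = 1, iterations = 500,
                    burn_in = 200, seed = 83)
  vp <- varp(post, seed = 84)
  dr <- attr(vp, "draws")
  classes <- c("a", "m", "B", "b", "v", "w")
  expect_lt(max(abs(rowSums(dr[, c(classes, "unexplained")]) - 100)), 1e-9)
  expect_equal(dr[, "total_explained"], 100 - dr[, "unexplained"])
  expect_true(all(vp$lo <= vp$mean & vp$mean <= vp$hi))
})

test_that("VarP ignores the grand mean and tracks the dominant class", {
  d <- diallel_design(5, 1, 1)
  a <- c(2, -1, 0.5, -2, 0.5)
  pp1 <- make_point_posterior(d, mu = 0, a = a, sigma2 = 0.04,
                              n_draws = 400)
  pp2 <- make_point_posterior(d, mu = 1000, a = a, sigma2 = 0.04,
                              n_draws = 400)
  v1 <- varp(pp1, seed = 85)
  v2 <- varp(pp2, seed = 85)
  expect_equal(v1$mean, v2$mean, tolerance = 1e-9)
  # additive-dominated posterior: VarP[a] is the largest class share and
  # its interval excludes zero
  row_a <- v1[v1$class == "a", ]
  others <- v1[v1$class %in% c("m", "B", "b", "v", "w"), ]
  expect_true(all(row_a$mean > others$mean))
  expect_gt(row_a$lo, 0)
})

test_that("an all-zero-effect posterior pushes everything into the unexplained share", {
  d <- diallel_design(4, 1, 1)
  pp <- make_point_posterior(d, mu = 3, a = rep(0, 4), beta_inbred = 0,
                             b = rep(0, 4), m = rep(0, 4),
                             v = rep(0, 6), w = rep(0, 6), sigma2 = 1,
                             n_draws = 2000)
  vp <- varp(pp, seed = 86)
  expect_equal(vp$mean[vp$class == "unexplained"], 100, tolerance = 1e-9)
  for (cl in c("a", "m", "B", "b", "v", "w")) {
    expect_equal(vp$mean[vp$class == cl], 0, tolerance = 1e-9)
  }
})

test_that("additive-only data classify every pair as additive end to end", {
  d <- diallel_design(4, 1, 2)
  cfg <- complete_config(d, mu = 20, beta_inbred = 0, tau_a = 5, tau_b = 0,
                         tau_m = 0, tau_v = 0, tau_w = 0, tau_env = 0,
                         density_slope = 0, tau_density = 0, sigma = 0.3,
                         seed = 87)
  tab <- simulate_diallel(cfg)$table
  post <- gibbs_fit(tab, d, "height", chains = 2, iterations = 1200,
                    burn_in = 400, seed = 88, use_density = FALSE,
                    use_location = FALSE)
  dom <- dominance_summary(post)
  expect_true(mean(dom$classification == "additive") >= 0.8)
  expect_true(all(abs(dom$mean) < 0.6))
})

test_that("correlation summaries recover known structure", {
  x <- rnorm(20)
  ec <- effect_correlations(cbind(a = x, b = x, c = -x))
  expect_equal(ec$r["a", "b"], 1)
  expect_equal(ec$r["a", "c"], -1)
  set.seed(89)
  n <- 1e4
  z <- rnorm(n); e <- rnorm(n)
  y <- 0.8 * z + sqrt(1 - 0.8^2) * e
  ec2 <- effect_correlations(cbind(z = z, y = y))
  expect_lt(abs(ec2$r["z", "y"] - 0.8), 0.02)
  expect_equal(ec2$stars["z", "y"], "***")
  # Spearman option and zero-variance flagging
  ec3 <- effect_correlations(cbind(z = z[1:50], c = rep(1, 50)),
                             method = "spearman")
  expect_true(is.na(ec3$r["z", "c"]))
})
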