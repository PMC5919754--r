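test_that("the sampler reproduces a conjugate normal-mean posterior", {
  set.seed(61)
  y <- rnorm(50, 10, 2)
  tab <- data.frame(female = "P1", male = "P2", environment = "E1",
                    block = 1L, density = 0L, yv = y)
  d <- diallel_design(2, 1, 1)
  post <- gibbs_fit(tab, d, "yv", model = "mu", chains = 2,
                    iterations = 6000, burn_in = 1000, seed = 62,
                    use_density = FALSE, use_location = FALSE,
                    sigma2_fixed = 4)
  dr <- do.call(rbind, post$chains)
  v_post <- 1 / (50 / 4 + 1 / 1000)
  m_post <- v_post * sum(y) / 4
  n_eff <- nrow(dr)  # draws are essentially independent here
  expect_lt(abs(mean(dr[, "mu"]) - m_post), 3 * sqrt(v_post / n_eff))
  expect_lt(abs(var(dr[, "mu"]) / v_post - 1), 0.05)
})

test_that("pure-noise data concentrate effect variances near zero", {
  d <- diallel_design(4, 1, 2)
  tab <- simulate_diallel(null_config(d, sigma = 1, seed = 63))$table
  post <- gibbs_fit(tab, d, "height", chains = 2, iterations = 1500,
                    burn_in = 500, seed = 64, use_density = FALSE,
                    use_location = FALSE)
  dr <- do.call(rbind, post$chains)
  expect_lt(abs(mean(dr[, "mu"]) - 10), 3 * sd(dr[, "mu"]))
  # every effect-class variance small relative to the residual variance
  taus <- dr[, grep("^tau2_", colnames(dr)), drop = FALSE]
  expect_true(all(apply(taus, 2, median) < median(dr[, "sigma2"])))
})

test_that("predicted grids obey the model algebra at point-mass posteriors", {
  d <- diallel_design(3, 1, 1)
  a <- c(1, -2, 0.5)
  # additive only: cell (j,k) = mu + a_j + a_k, symmetric
  pp <- make_point_posterior(d, mu = 10, a = a)
  g <- predicted_grid(pp)
  expect_equal(unname(g$mean), unname(10 + outer(a, a, "+")))
  expect_equal(g$mean, t(g$mean))
  # inbred penalty: diagonal sits beta_inbred below mu + 2 a_j
  pp2 <- make_point_posterior(d, mu = 10, a = a, beta_inbred = -8,
                              b = c(0, 0, 0))
  g2 <- predicted_grid(pp2)
  expect_equal(unname(diag(g2$mean)), unname(10 + 2 * a - 8))
  # maternal + asymmetric: grid(j,k) - grid(k,j) = 2(m_j - m_k) + 2 sgn w
  m <- c(0.5, -1, 0.25)
  w <- c(0.3, -0.2, 0.1)   # pairs 1:2, 1:3, 2:3
  pp3 <- make_point_posterior(d, mu = 0, a = a, m = m,
                              v = c(0, 0, 0), w = w)
  g3 <- predicted_grid(pp3)
  D <- g3$mean - t(g3$mean)
  expect_equal(D[1, 2], 2 * (m[1] - m[2]) + 2 * w[1])
  expect_equal(D[1, 3], 2 * (m[1] - m[3]) + 2 * w[2])
  expect_equal(D[2, 3], 2 * (m[2] - m[3]) + 2 * w[3])
  # with m = w = 0 the grid is symmetric
  pp4 <- make_point_posterior(d, mu = 1, a = a, m = c(0, 0, 0),
                              v = c(1, 2, 3), w = c(0, 0, 0))
  g4 <- predicted_grid(pp4)
  expect_equal(g4$mean, t(g4$mean))
})

test_that("HPD intervals are the shortest intervals of the stated mass", {
  expect_equal(unname(hpd_interval(rep(3, 200), 0.95)), c(3, 3))
  set.seed(65)
  z <- rnorm(1e6)
  h <- hpd_interval(z, 0.95)
  expect_lt(abs(h[1] + 1.96), 0.02)
  expect_lt(abs(h[2] - 1.96), 0.02)
  # 50% interval nested inside the 95% one
  h50 <- hpd_interval(z, 0.50)
  expect_gt(h50[1], h[1]); expect_lt(h50[2], h[2])
  # skewed sample: HPD starts at the mode side and beats equal tails
  x <- rexp(1e6)
  hx <- hpd_interval(x, 0.95)
  expect_lt(hx[1], 0.01)
  expect_lt(diff(hx), diff(quantile(x, c(0.025, 0.975))))
  expect_error(hpd_interval(rnorm(50), 0.95), "100 draws")
})

test_that("hybrid rankings identify dominance and degenerate orderings", {
  d <- diallel_design(3, 1, 1)
  a <- c(3, 1, -1)
  pp <- make_point_posterior(d, mu = 10, a = a, n_draws = 150)
  rk <- rank_hybrids(pp)
  expect_equal(nrow(rk), 6)   # ordered hybrids of 3 parents
  # point mass: every rank interval has zero width
  expect_equal(rk$hpd_lo, rk$hpd_hi)
  # the P1 x P2 / P2 x P1 crosses have the largest predicted value
  expect_equal(sort(rk$mean_rank[rk$cross %in% c("P1 x P2", "P2 x P1")]),
               c(1.5, 1.5))
  # exchangeable hybrids: all mean ranks near the centre
  d6 <- diallel_design(6, 1, 1)
  set.seed(66)
  # exchangeable hybrids via a fake posterior: equal means, i.i.d. parent noise
  pp6 <- make_point_posterior(d6, mu = 0, a = rep(0, 6), n_draws = 2000)
  pp6$chains[[1]][, paste0("a:", d6$parents)] <-
    matrix(rnorm(2000 * 6), 2000, 6)
  rk6 <- rank_hybrids(pp6)
  expect_true(all(abs(rk6$mean_rank - 15.5) < 1.5))
  expect_equal(mean(rk6$mean_rank), 15.5, tolerance = 1e-9)
})

test_that("Gelman-Rubin statistic flags separated chains and passes stationary ones", {
  fake <- function(chains) {
    structure(list(chains = chains), class = "diallel_posterior")
  }
  x <- matrix(rnorm(1e4), ncol = 1, dimnames = list(NULL, "x"))
  expect_equal(unname(gelman_rubin(fake(list(x, x)))), 1)
  set.seed(67)
  c1 <- matrix(rnorm(1e4), ncol = 1, dimnames = list(NULL, "x"))
  c2 <- matrix(rnorm(1e4), ncol = 1, dimnames = list(NULL, "x"))
  r_same <- gelman_rubin(fake(list(c1, c2)))
  expect_lt(r_same, 1.05)
  r_far <- gelman_rubin(fake(list(c1, c2 + 10)))
  expect_gt(r_far, 1.1)
  # independent oracle: coda's point estimate on the same chains
  co <- coda::gelman.diag(coda::mcmc.list(coda::mcmc(c1), coda::mcmc(c2)),
                          autoburnin = FALSE)
  expect_equal(unname(r_same), co$psrf[1, 1], tolerance = 0.05)
  expect_error(gelman_rubin(fake(list(c1))), "2 chains")
})

test_that("posterior summaries are equivariant under parent relabelling", {
  # relabelling permutes the coefficient columns, so the Monte-Carlo streams
  # differ; the posteriors are identical in law and the means must agree to
  # Monte-Carlo error
  d <- diallel_design(4, 1, 2)
  cfg <- complete_config(d, seed = 68, tau_env = 0)
  tab <- simulate_diallel(cfg)$table
  post1 <- gibbs_fit(tab, d, "height", chains = 2, iterations = 3000,
                     burn_in = 500, seed = 69)
  # swap labels P1 <-> P2 in the data; the design keeps its parent order
  tab2 <- tab
  tab2$female <- chartr("12", "21", tab$female)
  tab2$male <- chartr("12", "21", tab$male)
  post2 <- gibbs_fit(tab2, d, "height", chains = 2, iterations = 3000,
                     burn_in = 500, seed = 169)
  m1 <- colMeans(do.call(rbind, post1$chains))
  m2 <- colMeans(do.call(rbind, post2$chains))
  expect_equal(unname(m1["a:P1"]), unname(m2["a:P2"]), tolerance = 0.25)
  expect_equal(unname(m1["a:P2"]), unname(m2["a:P1"]), tolerance = 0.25)
  expect_equal(unname(m1["b:P3"]), unname(m2["b:P3"]), tolerance = 0.25)
  expect_equal(unname(m1["mu"]), unname(m2["mu"]), tolerance = 0.25)
})

test_that("hpd_summary returns nested 50/95 intervals", {
  d <- diallel_design(3, 1, 2)
  tab <- simulate_diallel(complete_config(d, seed = 70))$table
  post <- gibbs_fit(tab, d, "height", chains = 1, iterations = 600,
                    burn_in = 200, seed = 71)
  s <- hpd_summary(post, parameters = c("mu", "sigma2"))
  expect_equal(s$parameter, c("mu", "sigma2"))
  expect_true(all(s$hpd50_lo >= s$hpd95_lo - 1e-12))
  expect_true(all(s$hpd50_hi <= s$hpd95_hi + 1e-12))
  expect_true(all(s$hpd95_lo <= s$mean & s$mean <= s$hpd95_hi))
})
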