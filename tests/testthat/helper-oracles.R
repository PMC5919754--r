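# Independent oracles and fixture builders shared across the test files.

# Generic equality-constrained least-squares solve of the diallel effect
# model on a cell-mean matrix, via the KKT system -- deliberately ignorant of
# the closed-form estimators it checks.  Parameters: mu, g_1..p, s over
# unordered pairs (with selfs for Method I), r over ordered pairs j < k.
# Constraints: sum(g) = 0; zero row sums of s.
griffing_ols_oracle <- function(M, method = c("I", "III")) {
  method <- match.arg(method)
  p <- nrow(M)
  cells <- expand.grid(j = 1:p, k = 1:p)
  if (method == "III") cells <- cells[cells$j != cells$k, ]
  s_pairs <- expand.grid(a = 1:p, b = 1:p)
  s_pairs <- if (method == "I") s_pairs[s_pairs$a <= s_pairs$b, ]
             else s_pairs[s_pairs$a < s_pairs$b, ]
  r_pairs <- expand.grid(a = 1:p, b = 1:p)
  r_pairs <- r_pairs[r_pairs$a < r_pairs$b, ]
  s_ix <- function(a, b) {
    1 + p + which(s_pairs$a == pmin(a, b) & s_pairs$b == pmax(a, b))
  }
  r_ix <- function(a, b) {
    1 + p + nrow(s_pairs) + which(r_pairs$a == pmin(a, b) &
                                    r_pairs$b == pmax(a, b))
  }
  npar <- 1 + p + nrow(s_pairs) + nrow(r_pairs)
  X <- matrix(0, nrow(cells), npar)
  y <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    j <- cells$j[i]; k <- cells$k[i]
    X[i, 1] <- 1
    X[i, 1 + j] <- X[i, 1 + j] + 1
    X[i, 1 + k] <- X[i, 1 + k] + 1
    X[i, s_ix(j, k)] <- 1
    if (j != k) X[i, r_ix(j, k)] <- if (j < k) 1 else -1
    y[i] <- M[j, k]
  }
  C <- matrix(0, 1 + p, npar)
  C[1, 2:(1 + p)] <- 1
  for (j in 1:p) for (k in 1:p) {
    if (method == "III" && j == k) next
    C[1 + j, s_ix(j, k)] <- C[1 + j, s_ix(j, k)] + 1
  }
  KKT <- rbind(cbind(crossprod(X), t(C)),
               cbind(C, matrix(0, nrow(C), nrow(C))))
  sol <- drop(MASS::ginv(KKT) %*% c(crossprod(X, y), rep(0, nrow(C))))
  g <- sol[2:(1 + p)]
  s <- matrix(0, p, p); r <- matrix(0, p, p)
  for (i in seq_len(nrow(s_pairs))) {
    s[s_pairs$a[i], s_pairs$b[i]] <- s[s_pairs$b[i], s_pairs$a[i]] <-
      sol[1 + p + i]
  }
  for (i in seq_len(nrow(r_pairs))) {
    r[r_pairs$a[i], r_pairs$b[i]] <- sol[1 + p + nrow(s_pairs) + i]
    r[r_pairs$b[i], r_pairs$a[i]] <- -sol[1 + p + nrow(s_pairs) + i]
  }
  list(mu = sol[1], gca = g, sca = s, rec = r)
}

# Generator configuration with no missingness (complete tables).
complete_config <- function(design, ...) {
  diallel_sim_config(
    design = design, ...,
    missing_rates = stats::setNames(rep(0, length(design$environments)),
                                    design$environments))
}

# Pure-noise configuration: every systematic effect zero.
null_config <- function(design, sigma = 1, seed = 1) {
  complete_config(design, mu = 10, beta_inbred = 0, tau_a = 0, tau_b = 0,
                  tau_m = 0, tau_v = 0, tau_w = 0, tau_env = 0,
                  density_slope = 0, tau_density = 0, sigma = sigma,
                  seed = seed)
}

# Point-mass "posterior" with known parameter values, for algebraic checks
# of the posterior summaries.  Only the supplied effect classes appear.
make_point_posterior <- function(design, mu = 0, beta_inbred = NULL,
                                 a = NULL, b = NULL, m = NULL,
                                 v = NULL, w = NULL, sigma2 = 1,
                                 n_draws = 1, n_chains = 1,
                                 density_mean = 0) {
  p <- design$p
  pair_idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  pair_names <- paste(pair_idx[, "row"], pair_idx[, "col"], sep = ":")
  vals <- c(mu = mu)
  if (!is.null(beta_inbred)) vals <- c(vals, beta_inbred = beta_inbred)
  add <- function(vals, prefix, x, names) {
    if (is.null(x)) return(vals)
    stopifnot(length(x) == length(names))
    c(vals, stats::setNames(x, paste0(prefix, names)))
  }
  vals <- add(vals, "a:", a, design$parents)
  vals <- add(vals, "b:", b, design$parents)
  vals <- add(vals, "m:", m, design$parents)
  vals <- add(vals, "v:", v, pair_names)
  vals <- add(vals, "w:", w, pair_names)
  vals <- c(vals, sigma2 = sigma2)
  chain <- matrix(rep(vals, each = n_draws), n_draws, length(vals),
                  dimnames = list(NULL, names(vals)))
  structure(
    list(chains = rep(list(chain), n_chains), design = design,
         trait = "trait", model = "fullu",
         mcmc = list(chains = n_chains, iterations = n_draws,
                     burn_in = 0, thin = 1, seed = 0),
         data_info = list(n = 0, density_mean = density_mean,
                          use_density = FALSE, use_location = FALSE)),
    class = "diallel_posterior")
}
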