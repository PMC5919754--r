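#' Fit the Bayesian hierarchical diallel model by Gibbs sampling
#'
#' Decomposes plot-level phenotypes into additive parental effects
#' \eqn{a_j + a_k}, an inbred class \eqn{I\{j=k\}(\beta_{inbred} + b_j)},
#' maternal (parent-of-origin) effects \eqn{m_j - m_k}, cross-specific
#' symmetric effects \eqn{v_{jk}} (shared by reciprocals) and asymmetric
#' effects \eqn{w_{jk}} (entering with + when the female index is below the
#' male index, - otherwise), plus an ordinal planting-density covariate
#' (fixed linear slope and random per-level deviations) and a random
#' environment effect:
#' \deqn{y_i = \mu + x_i^T\beta + \sum_r u_i^{(r)} + a_{j[i]} + a_{k[i]} +
#'   I\{j=k\}(\beta_{inbred} + b_j) + m_j - m_k + I\{j\ne k\} v_{(jk)} +
#'   I\{j<k\} w_{(jk)} - I\{j>k\} w_{(jk)} + \epsilon_i}
#' Each random-effect class has its own variance \eqn{\tau^2} with a scaled
#' inverse-chi-squared prior (df 0.5, scale 1 by default); fixed effects have
#' vague N(0, 1000) priors; the residual variance has a scaled
#' inverse-chi-squared prior with df 0.5 and scale equal to the sample
#' variance of the trait.  Identifiability is by shrinkage (no hard
#' constraints); centre effects post hoc for display if desired.
#'
#' The sampler is a blocked Gibbs scheme: all fixed and random coefficients
#' are drawn jointly from their exact multivariate-normal full conditional
#' (the coefficient dimension is small, so one Cholesky per sweep is cheap
#' and avoids the slow mixing a class-by-class sweep shows between the grand
#' mean and the additive effects), then each variance from its scaled
#' inverse-chi-squared full conditional.  Rows with a missing trait value are
#' dropped, so unbalanced or incomplete tables are handled directly.
#'
#' @param table phenotype data.frame (may contain missing trait values).
#' @param design a Method I \code{\link{diallel_design}}.
#' @param trait trait column to fit.
#' @param model nested model family: \code{"mu"} (intercept and covariates
#'   only), \code{"a"} (+ additive), \code{"Bab"} (+ inbred), \code{"Babm"}
#'   (+ maternal), \code{"fullu"} (+ cross-specific symmetric and
#'   asymmetric; default).
#' @param chains,iterations,burn_in,thin MCMC control; defaults 5 chains of
#'   10000 iterations with 1000 burn-in, thin 1.
#' @param seed integer seed; chain c uses \code{seed + c - 1}.
#' @param prior_df,prior_scale scaled inverse-chi-squared prior for every
#'   random-effect variance (defaults 0.5 and 1).
#' @param fixed_prior_var prior variance of fixed effects (default 1000).
#' @param use_density,use_location include the density covariate (fixed slope
#'   + random level deviations) / the random environment effect.  Location
#'   defaults off for single-environment (stratified) data.
#' @param sigma2_fixed optional known residual variance; when supplied the
#'   residual variance is held at this value instead of being sampled
#'   (useful for conjugate checks and noiseless data).
#' @return object of class \code{"diallel_posterior"}: list with
#'   \code{chains} (list of draw matrices, one row per retained draw, named
#'   columns), \code{design}, \code{trait}, \code{model}, \code{mcmc}
#'   (control settings), and \code{data_info} (n, density mean).
#' @export
gibbs_fit <- function(table, design, trait,
                      model = c("fullu", "mu", "a", "Bab", "Babm"),
                      chains = 5, iterations = 10000, burn_in = 1000,
                      thin = 1, seed = 1,
                      prior_df = 0.5, prior_scale = 1,
                      fixed_prior_var = 1000,
                      use_density = TRUE,
                      use_location = length(design$environments) >= 2,
                      sigma2_fixed = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(design, "diallel_design"), burn_in < iterations,
            chains >= 1)
  keep <- !is.na(table[[trait]])
  if (!any(keep)) stop("no non-missing observations for trait '", trait, "'")
  table <- table[keep, , drop = FALSE]
  y <- table[[trait]]
  n <- length(y)
  p <- design$p
  j <- parent_index(table$female, design)
  k <- parent_index(table$male, design)
  self <- j == k

  pair_idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  pair_names <- paste(pair_idx[, "row"], pair_idx[, "col"], sep = ":")
  pair_of <- function(a, b) match(paste(pmin(a, b), pmax(a, b), sep = ":"),
                                  pair_names)

  # fixed-effect design matrix
  X <- matrix(1, n, 1, dimnames = list(NULL, "mu"))
  if (!model %in% c("mu", "a")) X <- cbind(X, beta_inbred = as.numeric(self))
  dens_mean <- 0
  if (use_density) {
    dens_mean <- mean(table$density)
    X <- cbind(X, beta_density = table$density)
  }

  # random-effect blocks: list of design matrices
  Z <- list()
  ind <- function(idx, q, sign = 1, rows = seq_len(n)) {
    M <- matrix(0, n, q)
    M[cbind(rows, idx)] <- sign
    M
  }
  if (model != "mu") {
    Za <- ind(j, p) + ind(k, p)
    colnames(Za) <- paste0("a:", design$parents)
    Z$a <- Za
  }
  if (!model %in% c("mu", "a")) {
    Zb <- matrix(0, n, p)
    Zb[cbind(which(self), j[self])] <- 1
    colnames(Zb) <- paste0("b:", design$parents)
    Z$b <- Zb
  }
  if (model %in% c("Babm", "fullu")) {
    Zm <- ind(j, p) - ind(k, p)
    colnames(Zm) <- paste0("m:", design$parents)
    Z$m <- Zm
  }
  if (model == "fullu") {
    hy <- which(!self)
    Zv <- matrix(0, n, length(pair_names))
    Zv[cbind(hy, pair_of(j[hy], k[hy]))] <- 1
    colnames(Zv) <- paste0("v:", pair_names)
    Zw <- matrix(0, n, length(pair_names))
    Zw[cbind(hy, pair_of(j[hy], k[hy]))] <- ifelse(j[hy] < k[hy], 1, -1)
    colnames(Zw) <- paste0("w:", pair_names)
    Z$v <- Zv
    Z$w <- Zw
  }
  if (use_location) {
    e <- length(design$environments)
    Zl <- ind(match(table$environment, design$environments), e)
    colnames(Zl) <- paste0("u_loc:", design$environments)
    Z$u_loc <- Zl
  }
  if (use_density) {
    Zd <- ind(table$density + 1L, 4L)
    colnames(Zd) <- paste0("u_dens:", 0:3)
    Z$u_dens <- Zd
  }

  W <- do.call(cbind, c(list(X), Z))
  q_fixed <- ncol(X)
  q_class <- vapply(Z, ncol, integer(1))
  class_of <- rep(names(Z), q_class)          # class of each random column
  col_class <- c(rep(".fixed", q_fixed), class_of)
  WtW <- crossprod(W)
  Wty <- drop(crossprod(W, y))
  s2_y <- stats::var(y)
  n_keep <- floor((iterations - burn_in) / thin)
  tau_names <- if (length(Z)) paste0("tau2_", names(Z)) else character(0)
  par_names <- c(colnames(W), tau_names, "sigma2")

  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    tau2 <- stats::setNames(rep(1, length(Z)), names(Z))
    sigma2 <- if (is.null(sigma2_fixed)) s2_y else sigma2_fixed
    draws <- matrix(NA_real_, n_keep, length(par_names),
                    dimnames = list(NULL, par_names))
    row <- 0L
    for (it in seq_len(iterations)) {
      # joint coefficient draw: N(A^{-1} b, A^{-1})
      prior_prec <- ifelse(col_class == ".fixed", 1 / fixed_prior_var,
                           1 / tau2[col_class])
      A <- WtW / sigma2 + diag(prior_prec, ncol(W))
      R <- tryCatch(chol(A), error = function(e) {
        warning("jittered a near-singular conditional")
        chol(A + diag(1e-8 * max(diag(A)), nrow(A)))
      })
      mu_c <- backsolve(R, backsolve(R, Wty / sigma2, transpose = TRUE))
      coefs <- drop(mu_c + backsolve(R, stats::rnorm(ncol(W))))
      resid <- y - drop(W %*% coefs)
      # variance draws
      for (c_name in names(Z)) {
        th <- coefs[col_class == c_name]
        tau2[c_name] <- (prior_df * prior_scale + sum(th^2)) /
          stats::rchisq(1, prior_df + length(th))
      }
      if (is.null(sigma2_fixed)) {
        sigma2 <- (prior_df * s2_y + sum(resid^2)) /
          stats::rchisq(1, prior_df + n)
      }
      if (it > burn_in && (it - burn_in) %% thin == 0) {
        row <- row + 1L
        draws[row, ] <- c(coefs, tau2, sigma2)
      }
    }
    draws
  }

  chains_out <- lapply(seq_len(chains), function(ci) run_chain(seed + ci - 1))
  structure(
    list(chains = chains_out, design = design, trait = trait, model = model,
         mcmc = list(chains = chains, iterations = iterations,
                     burn_in = burn_in, thin = thin, seed = seed),
         data_info = list(n = n, density_mean = dens_mean,
                          use_density = use_density,
                          use_location = use_location)),
    class = "diallel_posterior")
}

#' @export
print.diallel_posterior <- function(x, ...) {
  cat(sprintf(
    "Bayesian diallel posterior ('%s' model) for '%s': %d chain(s) x %d draws, %d parameters\n",
    x$model, x$trait, length(x$chains), nrow(x$chains[[1]]),
    ncol(x$chains[[1]])))
  invisible(x)
}

# All retained draws across chains as one matrix.
posterior_draws <- function(posterior) {
  do.call(rbind, posterior$chains)
}

# Coefficient matrix C (p^2 x n_par) such that grid cells = draws %*% t(C);
# cells in female-major order.  Random covariate groups sit at 0; density at
# its sample mean (population-level reference profile).
grid_coefficients <- function(posterior) {
  d <- posterior$design
  p <- d$p
  pn <- colnames(posterior$chains[[1]])
  C <- matrix(0, p^2, length(pn), dimnames = list(NULL, pn))
  cell <- 0L
  for (j in seq_len(p)) for (k in seq_len(p)) {
    cell <- cell + 1L
    C[cell, "mu"] <- 1
    if ("beta_density" %in% pn) {
      C[cell, "beta_density"] <- posterior$data_info$density_mean
    }
    aj <- paste0("a:", d$parents[j]); ak <- paste0("a:", d$parents[k])
    if (aj %in% pn) {
      C[cell, aj] <- C[cell, aj] + 1
      C[cell, ak] <- C[cell, ak] + 1
    }
    if (j == k) {
      if ("beta_inbred" %in% pn) C[cell, "beta_inbred"] <- 1
      bcol <- paste0("b:", d$parents[j])
      if (bcol %in% pn) C[cell, bcol] <- 1
    } else {
      mj <- paste0("m:", d$parents[j]); mk <- paste0("m:", d$parents[k])
      if (mj %in% pn) {
        C[cell, mj] <- C[cell, mj] + 1
        C[cell, mk] <- C[cell, mk] - 1
      }
      pr <- paste(min(j, k), max(j, k), sep = ":")
      if (paste0("v:", pr) %in% pn) {
        C[cell, paste0("v:", pr)] <- 1
        C[cell, paste0("w:", pr)] <- if (j < k) 1 else -1
      }
    }
  }
  C
}

#' Posterior predicted cross-mean grid
#'
#' For each retained draw, the predicted phenotype mean of every ordered
#' cross (female in rows) at the reference covariate profile: planting
#' density at its sample mean, random environment and density-level
#' deviations at zero (a population-level prediction).
#'
#' @param posterior a \code{\link{gibbs_fit}} result.
#' @return object of class \code{"predicted_grid"}: list with \code{mean}
#'   (p x p posterior-mean grid), \code{draws} (draws x p^2 matrix,
#'   female-major cell order), \code{design}.
#' @export
predicted_grid <- function(posterior) {
  stopifnot(inherits(posterior, "diallel_posterior"))
  C <- grid_coefficients(posterior)
  dr <- posterior_draws(posterior)
  cells <- dr %*% t(C)
  d <- posterior$design
  colnames(cells) <- paste(rep(d$parents, each = d$p), d$parents, sep = " x ")
  mean_grid <- matrix(colMeans(cells), d$p, d$p, byrow = TRUE,
                      dimnames = list(d$parents, d$parents))
  structure(list(mean = mean_grid, draws = cells, design = d),
            class = "predicted_grid")
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval containing the requested posterior mass,
#' by the sorted-sample sliding-window method.
#'
#' @param draws numeric vector of posterior draws (at least 100, unless the
#'   sample is a point mass).
#' @param mass posterior mass, e.g. 0.95 or 0.50.
#' @return numeric \code{c(lo, hi)}.
#' @export
hpd_interval <- function(draws, mass = 0.95) {
  stopifnot(mass > 0, mass < 1)
  draws <- draws[!is.na(draws)]
  n <- length(draws)
  if (n < 100) {
    if (n >= 1 && length(unique(draws)) == 1L) {
      return(c(lo = draws[1], hi = draws[1]))
    }
    stop("need at least 100 draws for an HPD interval")
  }
  s <- sort(draws)
  m <- max(1L, ceiling(mass * n))
  if (m >= n) return(c(lo = s[1], hi = s[n]))
  widths <- s[(m + 1):n] - s[1:(n - m)]
  i <- which.min(widths)
  c(lo = s[i], hi = s[i + m])
}

#' Summarise posterior draws with HPD intervals
#'
#' @param posterior a \code{\link{gibbs_fit}} result.
#' @param parameters optional character vector of parameter names (defaults
#'   to all).
#' @return data.frame with posterior mean, median, and 50\% and 95\% HPD
#'   bounds per parameter.
#' @export
hpd_summary <- function(posterior, parameters = NULL) {
  dr <- posterior_draws(posterior)
  if (!is.null(parameters)) dr <- dr[, parameters, drop = FALSE]
  out <- data.frame(parameter = colnames(dr),
                    mean = colMeans(dr),
                    median = apply(dr, 2, stats::median),
                    stringsAsFactors = FALSE)
  h50 <- t(apply(dr, 2, hpd_interval, mass = 0.50))
  h95 <- t(apply(dr, 2, hpd_interval, mass = 0.95))
  out$hpd50_lo <- h50[, 1]; out$hpd50_hi <- h50[, 2]
  out$hpd95_lo <- h95[, 1]; out$hpd95_hi <- h95[, 2]
  rownames(out) <- NULL
  out
}

#' Posterior hybrid rankings, overall or stratified by location
#'
#' At every retained draw the \eqn{p(p-1)} ordered hybrids (selfs excluded)
#' are ranked by predicted value, rank 1 being the largest (ties receive
#' average ranks); the posterior mean rank and 95\% HPD interval of each
#' hybrid's rank are reported.  Supply a named list of posteriors from fits
#' stratified by location to compare rankings across environments.
#'
#' @param posteriors a single \code{\link{gibbs_fit}} result or a named list
#'   of them (names taken as location labels).
#' @return data.frame with columns \code{location}, \code{cross},
#'   \code{female}, \code{male}, \code{mean_rank}, \code{hpd_lo},
#'   \code{hpd_hi}.
#' @export
rank_hybrids <- function(posteriors) {
  if (inherits(posteriors, "diallel_posterior")) {
    posteriors <- list(overall = posteriors)
  }
  if (is.null(names(posteriors))) {
    names(posteriors) <- paste0("location", seq_along(posteriors))
  }
  out <- lapply(names(posteriors), function(loc) {
    post <- posteriors[[loc]]
    d <- post$design
    g <- predicted_grid(post)
    cr <- enumerate_crosses(d)
    hyb <- which(!cr$is_self)
    cells <- g$draws[, hyb, drop = FALSE]
    ranks <- t(apply(cells, 1, function(v) rank(-v, ties.method = "average")))
    hpd <- t(apply(ranks, 2, hpd_interval, mass = 0.95))
    data.frame(location = loc,
               cross = cr$cross[hyb],
               female = cr$female_label[hyb],
               male = cr$male_label[hyb],
               mean_rank = colMeans(ranks),
               hpd_lo = hpd[, 1], hpd_hi = hpd[, 2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Gelman-Rubin potential scale reduction factors
#'
#' Standard between/within-chain variance-ratio diagnostic per scalar
#' parameter: \eqn{\hat R = \sqrt{((n-1)/n \cdot W + B/n)/W}} for chains of
#' length n with within-chain variance W and between-chain variance B,
#' truncated below at 1 (values under 1 are finite-sample artifacts, so
#' identical chains report exactly 1).
#'
#' @param posterior a \code{\link{gibbs_fit}} result with at least 2 chains.
#' @return named numeric vector of \eqn{\hat R} values.
#' @export
gelman_rubin <- function(posterior) {
  stopifnot(inherits(posterior, "diallel_posterior"))
  m <- length(posterior$chains)
  if (m < 2) stop("Gelman-Rubin diagnostic needs at least 2 chains")
  n <- nrow(posterior$chains[[1]])
  pn <- colnames(posterior$chains[[1]])
  vapply(pn, function(par) {
    x <- vapply(posterior$chains, function(ch) ch[, par], numeric(n))
    W <- mean(apply(x, 2, stats::var))
    B_over_n <- stats::var(colMeans(x))
    if (W == 0) return(1)
    max(1, sqrt(((n - 1) / n * W + B_over_n) / W))
  }, numeric(1))
}
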