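#' Configuration for the synthetic diallel generator
#'
#' The generator draws data from the same hierarchical effect structure the
#' Bayesian diallel model fits: additive parental dosage effects, an overall
#' inbred penalty with parent-specific deviations, maternal (parent-of-origin)
#' effects, cross-specific symmetric and asymmetric effects, environment
#' effects, and an ordinal planting-density covariate entering both linearly
#' and as per-level deviations.  Defaults emulate a 6-parent carrot-style
#' diallel of a height-like trait (cm scale) grown in an RCBD with 2 blocks
#' in each of 3 environments, with missingness concentrated in the first
#' environment as happens when one location suffers disease pressure.
#'
#' @param design a \code{\link{diallel_design}} (Method I).
#' @param mu grand mean.
#' @param beta_inbred overall inbred penalty (selfs vs hybrid prediction).
#' @param tau_a,tau_b,tau_m,tau_v,tau_w,tau_env SDs of the zero-mean normal
#'   effect classes (additive, parent-specific inbred, maternal, symmetric
#'   cross-specific, asymmetric cross-specific, environment).
#' @param density_slope linear fixed effect per unit of the 0-3 density score.
#' @param tau_density SD of per-level density deviations from linearity.
#' @param sigma residual SD.
#' @param density_probs probabilities of density scores 0,1,2,3.
#' @param missing_rates named per-environment probabilities that a plot's
#'   trait value is missing; default concentrates missingness in the first
#'   environment (0.30) with a light rate (0.04) in the last.
#' @param trait name of the generated trait column.
#' @param seed integer seed; all generator randomness flows from it.
#' @return object of class \code{"diallel_sim_config"}.
#' @export
diallel_sim_config <- function(design = diallel_design(6, 3, 2),
                               mu = 45, beta_inbred = -8,
                               tau_a = 4, tau_b = 4, tau_m = 2,
                               tau_v = 2, tau_w = 1, tau_env = 3,
                               density_slope = 1.5, tau_density = 0.5,
                               sigma = 4,
                               density_probs = c(0.05, 0.15, 0.4, 0.4),
                               missing_rates = NULL,
                               trait = "height",
                               seed = 1L) {
  stopifnot(inherits(design, "diallel_design"), design$method == "I")
  sds <- c(tau_a, tau_b, tau_m, tau_v, tau_w, tau_env, tau_density, sigma)
  if (any(sds < 0)) stop("effect SDs and sigma must be nonnegative")
  stopifnot(length(density_probs) == 4, all(density_probs >= 0))
  e <- length(design$environments)
  if (is.null(missing_rates)) {
    missing_rates <- stats::setNames(rep(0, e), design$environments)
    if (e >= 2) {
      missing_rates[1] <- 0.30
      missing_rates[e] <- 0.04
    }
  }
  if (is.null(names(missing_rates))) {
    names(missing_rates) <- design$environments
  }
  stopifnot(all(missing_rates >= 0 & missing_rates <= 1),
            setequal(names(missing_rates), design$environments))
  structure(
    list(design = design, mu = mu, beta_inbred = beta_inbred,
         tau_a = tau_a, tau_b = tau_b, tau_m = tau_m, tau_v = tau_v,
         tau_w = tau_w, tau_env = tau_env, density_slope = density_slope,
         tau_density = tau_density, sigma = sigma,
         density_probs = density_probs / sum(density_probs),
         missing_rates = missing_rates, trait = trait,
         seed = as.integer(seed)),
    class = "diallel_sim_config")
}

#' Draw the true effects for one synthetic diallel
#'
#' Each effect class is drawn independently zero-mean normal with its class
#' SD; \code{mu} and \code{beta_inbred} are fixed values copied from the
#' configuration.  Reproducible under the configuration seed.
#'
#' @param config a \code{\link{diallel_sim_config}}.
#' @return object of class \code{"diallel_effects"}: a list with \code{mu},
#'   \code{a}, \code{beta_inbred}, \code{b}, \code{m} (length-p vectors),
#'   \code{v}, \code{w} (named by unordered pair \code{"j:k"}, j < k),
#'   \code{env} (length-e), \code{density_slope}, \code{density_dev}
#'   (levels 0-3), and \code{sigma}.
#' @export
simulate_effects <- function(config) {
  stopifnot(inherits(config, "diallel_sim_config"))
  d <- config$design
  p <- d$p
  e <- length(d$environments)
  set.seed(config$seed)
  pair_idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  pair_names <- paste(pair_idx[, "row"], pair_idx[, "col"], sep = ":")
  eff <- list(
    mu = config$mu,
    a = stats::setNames(stats::rnorm(p, 0, config$tau_a), d$parents),
    beta_inbred = config$beta_inbred,
    b = stats::setNames(stats::rnorm(p, 0, config$tau_b), d$parents),
    m = stats::setNames(stats::rnorm(p, 0, config$tau_m), d$parents),
    v = stats::setNames(stats::rnorm(length(pair_names), 0, config$tau_v),
                        pair_names),
    w = stats::setNames(stats::rnorm(length(pair_names), 0, config$tau_w),
                        pair_names),
    env = stats::setNames(stats::rnorm(e, 0, config$tau_env), d$environments),
    density_slope = config$density_slope,
    density_dev = stats::setNames(stats::rnorm(4, 0, config$tau_density),
                                  as.character(0:3)),
    sigma = config$sigma)
  class(eff) <- "diallel_effects"
  eff
}

# Expected cell value for cross (j, k) given effects, excluding environment,
# density, and residual terms.  The asymmetric effect enters with + when the
# female index is below the male index and - otherwise.
cross_value <- function(eff, j, k) {
  val <- eff$mu + eff$a[j] + eff$a[k]
  if (j == k) {
    val <- val + eff$beta_inbred + eff$b[j]
  } else {
    pair <- paste(min(j, k), max(j, k), sep = ":")
    val <- val + (eff$m[j] - eff$m[k]) + eff$v[pair] +
      (if (j < k) 1 else -1) * eff$w[pair]
  }
  unname(val)
}

#' Simulate a complete multi-environment diallel experiment
#'
#' Generates the full balanced table (one plot per cross, environment, and
#' block: \eqn{p^2 \times e \times r} rows) from the hierarchical diallel
#' model, then removes trait values at the configured per-environment
#' missingness rates.
#'
#' @param config a \code{\link{diallel_sim_config}}.
#' @param apply_missing logical; set \code{FALSE} to keep the table complete.
#' @return list with \code{table} (phenotype data.frame), \code{effects}
#'   (the \code{\link{simulate_effects}} draw used), and \code{complete}
#'   (the table before missingness).
#' @export
simulate_diallel <- function(config, apply_missing = TRUE) {
  stopifnot(inherits(config, "diallel_sim_config"))
  d <- config$design
  eff <- simulate_effects(config)   # sets the seed; rest of stream follows
  crosses <- enumerate_crosses(d)
  grid <- expand.grid(block = seq_len(d$blocks),
                      environment = d$environments,
                      row = seq_len(nrow(crosses)),
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  cr <- crosses[grid$row, ]
  density <- sample(0:3, n, replace = TRUE, prob = config$density_probs)
  base <- mapply(function(j, k) cross_value(eff, j, k), cr$female, cr$male)
  y <- base + eff$env[grid$environment] +
    eff$density_slope * density + eff$density_dev[as.character(density)] +
    stats::rnorm(n, 0, eff$sigma)
  tab <- data.frame(
    female = cr$female_label, male = cr$male_label,
    environment = grid$environment, block = grid$block,
    density = density, stringsAsFactors = FALSE)
  tab[[config$trait]] <- unname(y)
  ord <- order(match(tab$environment, d$environments), tab$block,
               match(tab$female, d$parents), match(tab$male, d$parents))
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  complete <- tab
  if (apply_missing && any(config$missing_rates > 0)) {
    tab <- apply_missingness(tab, config$missing_rates)
  }
  list(table = tab, effects = eff, complete = complete)
}

#' Remove trait values at per-environment rates
#'
#' Missingness is trait-wise and plot-wise independent: within each
#' environment every trait value is set missing with that environment's
#' probability (missing completely at random within environment; missing at
#' random across environments).  Design columns are never touched.
#'
#' @param table phenotype data.frame.
#' @param rates named vector of probabilities, one per environment present.
#' @param seed optional integer seed; omit to continue the caller's RNG
#'   stream.
#' @return the table with trait values knocked out.
#' @export
apply_missingness <- function(table, rates, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(table$environment %in% names(rates)),
            all(rates >= 0 & rates <= 1))
  pr <- unname(rates[table$environment])
  for (tr in trait_names(table)) {
    drop <- stats::runif(nrow(table)) < pr
    table[[tr]][drop] <- NA_real_
  }
  table
}
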