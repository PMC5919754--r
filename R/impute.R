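# One Bayesian-regression PMM update of a single trait.  Type-1 matching:
# observed rows are scored with the posterior-mode coefficients, missing rows
# with a posterior draw; each missing row copies the observed value of one
# donor sampled uniformly from the `donors` observed rows with nearest
# predicted mean.  X must include an intercept; collinear columns are dropped
# via pivoted QR on the observed rows.
pmm_draw <- function(y, X, donors) {
  obs <- which(!is.na(y))
  mis <- which(is.na(y))
  if (!length(mis)) return(y)
  Xo <- X[obs, , drop = FALSE]
  qr_o <- qr(Xo)
  keep <- qr_o$pivot[seq_len(qr_o$rank)]
  Xo <- Xo[, keep, drop = FALSE]
  Xm <- X[mis, keep, drop = FALSE]
  qr_o <- qr(Xo)
  beta_hat <- qr.coef(qr_o, y[obs])
  res <- y[obs] - drop(Xo %*% beta_hat)
  nu <- max(length(obs) - qr_o$rank, 1)
  sigma2_star <- sum(res^2) / stats::rchisq(1, nu)
  R <- qr.R(qr_o)
  beta_star <- beta_hat + sqrt(sigma2_star) *
    backsolve(R, stats::rnorm(ncol(Xo)))
  yhat_obs <- drop(Xo %*% beta_hat)
  yhat_mis <- drop(Xm %*% beta_star)
  k <- min(donors, length(obs))
  for (i in seq_along(mis)) {
    d <- abs(yhat_obs - yhat_mis[i])
    pool <- order(d)[seq_len(k)]
    y[mis[i]] <- y[obs][pool[sample.int(k, 1)]]
  }
  y
}

#' Multiple imputation by chained-equations predictive mean matching
#'
#' Fills missing trait values by predictive mean matching (PMM): per sweep,
#' each incomplete trait is regressed on the predictors with a stochastic
#' (Bayesian) coefficient draw, and every missing cell copies the observed
#' value of a donor sampled from the \code{donors} observed rows with
#' nearest predicted mean -- so imputed values are always values actually
#' observed for that trait.  Predictors are the female and male parents,
#' environment, block (all as indicator contrasts), optionally the cross
#' factor, the planting-density score, and the other traits at their current
#' (observed or imputed) values; columns that make the regression
#' rank-deficient are dropped automatically.  The chained sweeps are
#' repeated \code{n_iterations} times per imputation and the final sweep's
#' values are recorded; \code{m} imputations are generated from independent
#' seed streams.
#'
#' @param table phenotype data.frame with missing trait values.
#' @param design a \code{\link{diallel_design}}.
#' @param m number of imputed data sets (default 50).
#' @param n_iterations chained-equation sweeps per imputation (default 70,
#'   comfortably past the ~40 sweeps at which the sampler typically
#'   stabilises).
#' @param donors donor-pool size (default 5).
#' @param include_cross also offer the cross factor as a predictor (dropped
#'   automatically when rank-deficient).
#' @param seed integer seed; imputation i uses \code{seed + i - 1}.
#' @return object of class \code{"imputed_set"}: list with \code{tables}
#'   (list of m completed data.frames), \code{trace} (per imputation,
#'   iteration and trait: mean and SD of the imputed values), \code{m},
#'   and \code{call_config}.
#' @export
pmm_impute <- function(table, design, m = 50, n_iterations = 70, donors = 5,
                       include_cross = TRUE, seed = 1) {
  stopifnot(m >= 2, n_iterations >= 1, donors >= 1)
  traits <- trait_names(table)
  incomplete <- traits[vapply(traits, function(t) anyNA(table[[t]]),
                              logical(1))]
  all_missing <- incomplete[vapply(incomplete,
                                   function(t) all(is.na(table[[t]])),
                                   logical(1))]
  if (length(all_missing)) {
    stop("trait(s) entirely missing, unimputable: ",
         paste(all_missing, collapse = ", "))
  }
  for (t in incomplete) {
    if (sum(!is.na(table[[t]])) < donors) {
      stop("trait '", t, "' has fewer observed rows than the donor pool")
    }
  }
  # indicator contrasts for the design factors; single-level factors drop out
  fac_cols <- function(x, levels) {
    levels <- intersect(levels, unique(x))
    if (length(levels) < 2) return(NULL)
    outer(x, levels[-1], `==`) * 1
  }
  base <- cbind(
    `(Intercept)` = 1,
    fac_cols(table$female, design$parents),
    fac_cols(table$male, design$parents),
    fac_cols(table$environment, design$environments),
    fac_cols(as.character(table$block),
             as.character(seq_len(design$blocks))),
    density = table$density)
  if (include_cross) {
    base <- cbind(base, fac_cols(paste(table$female, table$male),
                                 unique(paste(table$female, table$male))))
  }
  trace <- list()
  tables <- vector("list", m)
  for (i in seq_len(m)) {
    set.seed(seed + i - 1)
    filled <- table
    mis_idx <- lapply(incomplete, function(t) which(is.na(table[[t]])))
    names(mis_idx) <- incomplete
    for (t in incomplete) {   # hot-deck initialisation
      obs_vals <- table[[t]][!is.na(table[[t]])]
      filled[[t]][mis_idx[[t]]] <-
        sample(obs_vals, length(mis_idx[[t]]), replace = TRUE)
    }
    for (it in seq_len(n_iterations)) {
      for (t in incomplete) {
        others <- setdiff(traits, t)
        X <- cbind(base,
                   as.matrix(filled[, others, drop = FALSE]))
        y <- filled[[t]]
        y[mis_idx[[t]]] <- NA
        filled[[t]] <- pmm_draw(y, X, donors)
        imp_vals <- filled[[t]][mis_idx[[t]]]
        trace[[length(trace) + 1L]] <- data.frame(
          imputation = i, iteration = it, trait = t,
          mean = mean(imp_vals), sd = stats::sd(imp_vals),
          stringsAsFactors = FALSE)
      }
    }
    tables[[i]] <- filled
  }
  structure(
    list(tables = tables,
         trace = if (length(trace)) do.call(rbind, trace) else
           data.frame(imputation = integer(), iteration = integer(),
                      trait = character(), mean = numeric(), sd = numeric()),
         m = m,
         call_config = list(n_iterations = n_iterations, donors = donors,
                            include_cross = include_cross, seed = seed)),
    class = "imputed_set")
}

#' @export
print.imputed_set <- function(x, ...) {
  cat(sprintf("Multiply-imputed phenotype set: m = %d completed tables\n",
              x$m))
  invisible(x)
}

#' Pool a scalar estimate across imputations by Rubin's rules
#'
#' @param estimates the m point estimates.
#' @param within_variances the m squared standard errors.
#' @return object of class \code{"pooled_estimate"}: list with \code{point}
#'   (\eqn{\bar Q}), \code{within_var} (\eqn{\bar U}), \code{between_var}
#'   (B), \code{total_var} (\eqn{T = \bar U + (1 + 1/m)B}), and \code{df}
#'   (the Rubin approximation \eqn{(m-1)(1 + \bar U / ((1+1/m)B))^2};
#'   infinite when B = 0).
#' @export
rubin_pool <- function(estimates, within_variances) {
  m <- length(estimates)
  stopifnot(m >= 2, length(within_variances) == m,
            all(within_variances >= 0))
  qbar <- mean(estimates)
  ubar <- mean(within_variances)
  B <- stats::var(estimates)
  Tt <- ubar + (1 + 1 / m) * B
  df <- if (B == 0) Inf else (m - 1) * (1 + ubar / ((1 + 1 / m) * B))^2
  structure(list(point = qbar, within_var = ubar, between_var = B,
                 total_var = Tt, df = df),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("Pooled estimate %s (SE %s, df %s)\n",
              format(x$point, digits = digits),
              format(sqrt(x$total_var), digits = digits),
              format(x$df, digits = digits)))
  invisible(x)
}

#' Pool ANOVA tables across imputations
#'
#' Mean squares are averaged across the m per-imputation tables and F
#' statistics re-formed against the pooled Error mean square; the resulting
#' p-values are approximate and flagged as such.
#'
#' @param tables list of m \code{\link{griffing_anova}} tables sharing
#'   sources and df.
#' @return a pooled \code{\link{griffing_anova}}-shaped data.frame with
#'   attribute \code{approximate = TRUE}.
#' @export
pool_anova <- function(tables) {
  stopifnot(length(tables) >= 1)
  ref <- tables[[1]]
  for (tab in tables[-1]) {
    if (!identical(tab$source, ref$source) || !identical(tab$df, ref$df)) {
      stop("ANOVA tables have mismatched sources or df; cannot pool")
    }
  }
  out <- ref[, c("source", "df")]
  out$SS <- rowMeans(vapply(tables, function(t) t$SS, numeric(nrow(ref))))
  out$MS <- rowMeans(vapply(tables, function(t) t$MS, numeric(nrow(ref))))
  ms_err <- out$MS[out$source == "Error"]
  df_err <- out$df[out$source == "Error"]
  testable <- !(out$source %in% c("Error", "Total"))
  out$F <- ifelse(testable & ms_err > 0, out$MS / ms_err, NA_real_)
  out$p <- ifelse(is.na(out$F), NA_real_,
                  stats::pf(out$F, out$df, df_err, lower.tail = FALSE))
  attr(out, "approximate") <- TRUE
  attr(out, "n_per_cell") <- attr(ref, "n_per_cell")
  class(out) <- c("griffing_anova", "data.frame")
  out
}

#' Pooled Griffing analysis of a multiply-imputed data set
#'
#' Fits Griffing's Method I and its ANOVA on each completed table, pools the
#' ANOVA by \code{\link{pool_anova}} and every GCA/SCA/reciprocal effect by
#' Rubin's rules (\code{\link{rubin_pool}}), and reports pooled t-tests on
#' the Rubin degrees of freedom.
#'
#' @param imputed an \code{\link{pmm_impute}} result.
#' @param design a Method I \code{\link{diallel_design}}.
#' @param trait trait to analyse.
#' @return list with \code{effects} (data.frame: class, label, estimate, se,
#'   df, t, p, stars, between_var), \code{anova} (pooled table),
#'   \code{grand_mean}, and \code{bakers_ratio}.
#' @export
pool_griffing <- function(imputed, design, trait) {
  stopifnot(inherits(imputed, "imputed_set"))
  fits <- lapply(imputed$tables, fit_griffing, design = design, trait = trait)
  anovas <- lapply(imputed$tables, griffing_anova, design = design,
                   trait = trait)
  tests <- mapply(function(f, a) effect_tests(f, a),
                  fits, anovas, SIMPLIFY = FALSE)
  pooled_anova <- pool_anova(anovas)
  ref <- tests[[1]][, c("class", "label")]
  est <- vapply(tests, function(t) t$estimate, numeric(nrow(ref)))
  se2 <- vapply(tests, function(t) t$se^2, numeric(nrow(ref)))
  pooled <- lapply(seq_len(nrow(ref)), function(i) {
    rubin_pool(est[i, ], se2[i, ])
  })
  ref$estimate <- vapply(pooled, `[[`, numeric(1), "point")
  ref$se <- sqrt(vapply(pooled, `[[`, numeric(1), "total_var"))
  ref$df <- vapply(pooled, `[[`, numeric(1), "df")
  ref$between_var <- vapply(pooled, `[[`, numeric(1), "between_var")
  ref$t <- ifelse(ref$se > 0, ref$estimate / ref$se, NA_real_)
  ref$p <- ifelse(is.na(ref$t), NA_real_,
                  2 * stats::pt(abs(ref$t), ref$df, lower.tail = FALSE))
  ref$stars <- significance_stars(ref$p)
  list(effects = ref, anova = pooled_anova,
       grand_mean = mean(vapply(fits, `[[`, numeric(1), "mu")),
       bakers_ratio = bakers_ratio(pooled_anova))
}
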