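# Closed-form Griffing effect estimators on a p x p matrix of ordered-cross
# cell means (rows = female).  Method I uses all p^2 cells; Method III the
# off-diagonal cells only (the diagonal of M is ignored).  The identifiability
# constraints are the standard ones: sum(g) = 0; s symmetric with zero row
# sums (Method I: including the diagonal; Method III: over k != j); r
# antisymmetric.
griffing_effects <- function(M, method = c("I", "III")) {
  method <- match.arg(method)
  p <- nrow(M)
  if (method == "I") {
    rs <- rowSums(M); cs <- colSums(M); tot <- sum(M)
    mu <- tot / p^2
    g <- (rs + cs) / (2 * p) - mu
    q <- (rs + cs) / (2 * p)
    s <- (M + t(M)) / 2 - outer(q, rep(1, p)) - outer(rep(1, p), q) + tot / p^2
    r <- (M - t(M)) / 2
  } else {
    if (p < 3) stop("SCA is not estimable under Method III with p < 3")
    Mo <- M; diag(Mo) <- 0
    rs <- rowSums(Mo); cs <- colSums(Mo); tot <- sum(Mo)
    mu <- tot / (p * (p - 1))
    g <- (p * (rs + cs) - 2 * tot) / (2 * p * (p - 2))
    q <- (rs + cs) / (2 * (p - 2))
    s <- (Mo + t(Mo)) / 2 - outer(q, rep(1, p)) - outer(rep(1, p), q) +
      tot / ((p - 1) * (p - 2))
    r <- (Mo - t(Mo)) / 2
    diag(s) <- 0
  }
  names(g) <- rownames(M)
  dimnames(s) <- dimnames(r) <- dimnames(M)
  list(mu = mu, gca = g, sca = s, rec = r)
}

# Balanced complete cell-mean matrix for a trait, or an informative error.
# Returns list(M = cell means, n = observations per cell).
balanced_cell_means <- function(table, design, trait, method = "I") {
  if (method == "III") {
    table <- table[table$female != table$male, , drop = FALSE]
  }
  y <- table[[trait]]
  if (anyNA(y)) {
    stop("trait '", trait, "' has missing values; impute first (see pmm_impute)")
  }
  j <- parent_index(table$female, design)
  k <- parent_index(table$male, design)
  cnt <- table(factor(j, seq_len(design$p)), factor(k, seq_len(design$p)))
  cells <- if (method == "I") cnt else cnt[row(cnt) != col(cnt)]
  if (length(unique(as.vector(cells))) != 1L || cells[1] == 0L) {
    stop("Model I requires balanced replication: every cell needs the same ",
         "number of observations")
  }
  list(M = cell_mean_matrix(table, design, trait), n = as.integer(cells[1]))
}

#' Fit Griffing's Method I, Model I diallel model
#'
#' Fixed-effects decomposition of the ordered-cross cell means into a grand
#' mean, general combining ability (GCA) effects \eqn{g_j}, specific
#' combining ability (SCA) effects \eqn{s_{jk} = s_{kj}}, and reciprocal
#' effects \eqn{r_{jk} = -r_{kj}}:
#' \deqn{y_{jk} = \mu + g_j + g_k + s_{jk} + r_{jk} + \epsilon}
#' Estimates are the closed-form least-squares solutions under the standard
#' constraints (\eqn{\sum_j g_j = 0}; \eqn{\sum_k s_{jk} = 0} for each j;
#' antisymmetric r).  Cell means are taken over environments and blocks
#' before estimation; use \code{environment} to fit a single location.
#'
#' @param table complete, balanced phenotype data.frame (impute first if
#'   needed).
#' @param design a Method I \code{\link{diallel_design}}.
#' @param trait trait column to analyse.
#' @param environment optional single environment label for a stratified fit.
#' @return object of class \code{"griffing_fit"}: list with \code{mu},
#'   \code{gca} (length p), \code{sca} (p x p symmetric), \code{rec}
#'   (p x p antisymmetric), \code{cell_means}, \code{n_per_cell},
#'   \code{method}, \code{design}, \code{trait}.
#' @export
fit_griffing <- function(table, design, trait, environment = NULL) {
  stopifnot(inherits(design, "diallel_design"))
  if (!is.null(environment)) {
    table <- table[table$environment == environment, , drop = FALSE]
  }
  bc <- balanced_cell_means(table, design, trait, "I")
  eff <- griffing_effects(bc$M, "I")
  structure(
    c(eff, list(cell_means = bc$M, n_per_cell = bc$n, method = "I",
                design = design, trait = trait)),
    class = "griffing_fit")
}

#' @export
print.griffing_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Griffing Method %s fit for '%s' (p = %d, %d obs/cell)\n",
              x$method, x$trait, x$design$p, x$n_per_cell))
  cat("Grand mean:", format(x$mu, digits = digits), "\n\nGCA effects:\n")
  print(round(x$gca, digits))
  invisible(x)
}

#' Multi-environment Griffing ANOVA table
#'
#' The fixed-effects (Model I) analysis of variance combined over
#' environments.  The Genotype sum of squares (from entry means) partitions
#' exactly into GCA, SCA, and Reciprocal components via the fitted effects;
#' with two or more environments the Genotype x Environment interaction is
#' partitioned the same way from per-environment fits, replication is nested
#' in environment, and the Error is the within-(environment, block) residual.
#' All F-tests use the Error mean square as denominator, as appropriate for
#' a fixed-effects Model I analysis.
#'
#' @inheritParams fit_griffing
#' @param method Griffing method, \code{"I"} or \code{"III"} (Method III
#'   drops parental selfs before fitting).
#' @return data.frame of class \code{"griffing_anova"} with columns
#'   \code{source}, \code{df}, \code{SS}, \code{MS}, \code{F}, \code{p}.
#' @export
griffing_anova <- function(table, design, trait, method = c("I", "III")) {
  method <- match.arg(method)
  stopifnot(inherits(design, "diallel_design"))
  if (method == "III") {
    table <- table[table$female != table$male, , drop = FALSE]
  }
  e <- length(design$environments)
  r <- design$blocks
  p <- design$p
  bc <- balanced_cell_means(table, design, trait, method)
  if (bc$n != e * r) {
    stop("expected ", e * r, " observations per cell, found ", bc$n)
  }
  dof <- anova_dof(local({d <- design; d$method <- method; d}))
  w_g <- if (method == "I") 2 * p else 2 * (p - 2)
  off <- function(A) if (method == "I") A else A[row(A) != col(A)]
  n <- e * r

  M <- bc$M
  fit <- griffing_effects(M, method)
  y <- table[[trait]]
  ybar <- mean(y)
  ss <- c(Genotype = n * sum((off(M) - mean(off(M)))^2),
          GCA = n * w_g * sum(fit$gca^2),
          SCA = n * sum(off(fit$sca)^2),
          Reciprocal = n * sum(off(fit$rec)^2))
  if (e >= 2) {
    env_means <- tapply(y, table$environment, mean)[design$environments]
    n_env <- if (method == "I") p^2 * r else p * (p - 1) * r
    ss_loc <- n_env * sum((env_means - ybar)^2)
    ss_ge <- ss_gca_e <- ss_sca_e <- ss_rec_e <- 0
    for (env in design$environments) {
      Me <- cell_mean_matrix(table[table$environment == env, ], design, trait)
      fe <- griffing_effects(Me, method)
      de <- off(Me) - off(M) - (mean(off(Me)) - mean(off(M)))
      ss_ge <- ss_ge + r * sum(de^2)
      ss_gca_e <- ss_gca_e + r * w_g * sum((fe$gca - fit$gca)^2)
      ss_sca_e <- ss_sca_e + r * sum(off(fe$sca - fit$sca)^2)
      ss_rec_e <- ss_rec_e + r * sum(off(fe$rec - fit$rec)^2)
    }
    ss <- c(ss, Location = ss_loc, `G x E` = ss_ge, `GCA x E` = ss_gca_e,
            `SCA x E` = ss_sca_e, `Reciprocal x E` = ss_rec_e)
  }
  eb_means <- tapply(y, list(table$environment, table$block), mean)
  env_means2 <- tapply(y, table$environment, mean)
  n_cells <- if (method == "I") p^2 else p * (p - 1)
  ss_rep <- n_cells * sum((eb_means - as.vector(env_means2[rownames(eb_means)]))^2)
  ss_total <- sum((y - ybar)^2)
  explained <- ss[["Genotype"]] + ss_rep +
    (if (e >= 2) ss[["Location"]] + ss[["G x E"]] else 0)
  ss <- c(ss, `rep(E)` = ss_rep, Error = max(ss_total - explained, 0),
          Total = ss_total)

  sources <- names(dof)
  tab <- data.frame(source = sources, df = as.numeric(dof[sources]),
                    SS = as.numeric(ss[sources]), stringsAsFactors = FALSE)
  tab$MS <- ifelse(tab$df > 0, tab$SS / tab$df, NA_real_)
  ms_err <- tab$MS[tab$source == "Error"]
  df_err <- tab$df[tab$source == "Error"]
  testable <- !(tab$source %in% c("Error", "Total"))
  tab$F <- ifelse(testable & ms_err > 0, tab$MS / ms_err, NA_real_)
  tab$p <- ifelse(is.na(tab$F), NA_real_,
                  stats::pf(tab$F, tab$df, df_err, lower.tail = FALSE))
  attr(tab, "n_per_cell") <- n
  attr(tab, "method") <- method
  class(tab) <- c("griffing_anova", "data.frame")
  tab
}

#' Baker's ratio of combining-ability mean squares
#'
#' \eqn{2 MS_{GCA} / (2 MS_{GCA} + MS_{SCA})}.  Values close to one indicate
#' that hybrid performance is predictable from GCA (additive effects) alone.
#'
#' @param ms_gca,ms_sca GCA and SCA mean squares, or a single
#'   \code{\link{griffing_anova}} table as first argument.
#' @return the ratio, in (0, 1] for positive mean squares.
#' @export
bakers_ratio <- function(ms_gca, ms_sca = NULL) {
  if (inherits(ms_gca, "griffing_anova")) {
    tab <- ms_gca
    ms_sca <- tab$MS[tab$source == "SCA"]
    ms_gca <- tab$MS[tab$source == "GCA"]
  }
  stopifnot(ms_gca >= 0, ms_sca >= 0)
  if (ms_gca == 0 && ms_sca == 0) {
    stop("Baker's ratio is undefined when both mean squares are zero")
  }
  2 * ms_gca / (2 * ms_gca + ms_sca)
}

#' Fit Griffing's Method III (hybrids and reciprocals only)
#'
#' Method III excludes parental selfs, removing the upward bias they induce
#' in combining-ability variance under Method I.  Self rows present in the
#' input are dropped before fitting.
#'
#' @inheritParams fit_griffing
#' @return list with \code{fit} (a \code{"griffing_fit"} on the
#'   \eqn{p(p-1)}-entry design), \code{anova} (its ANOVA table), and
#'   \code{bakers_ratio}.
#' @export
fit_method3 <- function(table, design, trait) {
  stopifnot(inherits(design, "diallel_design"))
  if (design$p < 3) stop("SCA is not estimable under Method III with p < 3")
  hy <- table[table$female != table$male, , drop = FALSE]
  bc <- balanced_cell_means(hy, design, trait, "III")
  eff <- griffing_effects(bc$M, "III")
  fit <- structure(
    c(eff, list(cell_means = bc$M, n_per_cell = bc$n, method = "III",
                design = design, trait = trait)),
    class = "griffing_fit")
  anova <- griffing_anova(table, design, trait, method = "III")
  ms_sca <- anova$MS[anova$source == "SCA"]
  br <- if (is.na(ms_sca)) NA_real_ else bakers_ratio(anova)
  list(fit = fit, anova = anova, bakers_ratio = br)
}

# Squared-coefficient norms of each effect estimator as a linear function of
# the cell means; Var(effect) = norm2 * sigma^2 / n_per_cell.  Computed by
# applying the closed-form estimator to elementary cell-mean matrices, and
# cached per (p, method).
.griffing_norm_cache <- new.env(parent = emptyenv())
griffing_var_factors <- function(p, method) {
  key <- paste0(method, p)
  if (!is.null(.griffing_norm_cache[[key]])) {
    return(.griffing_norm_cache[[key]])
  }
  g2 <- numeric(p); s2 <- matrix(0, p, p); r2 <- matrix(0, p, p)
  cells <- if (method == "I") {
    expand.grid(seq_len(p), seq_len(p))
  } else {
    subset(expand.grid(seq_len(p), seq_len(p)), Var1 != Var2)
  }
  for (i in seq_len(nrow(cells))) {
    E <- matrix(0, p, p)
    E[cells[i, 1], cells[i, 2]] <- 1
    f <- griffing_effects(E, method)
    g2 <- g2 + f$gca^2
    s2 <- s2 + f$sca^2
    r2 <- r2 + f$rec^2
  }
  out <- list(gca = g2, sca = s2, rec = r2)
  .griffing_norm_cache[[key]] <- out
  out
}

#' t-tests for individual combining-ability effects
#'
#' Each estimated GCA, SCA, and reciprocal effect is divided by its standard
#' error (the standard Method I/III variance coefficient of the estimator
#' times the Error mean square, scaled by the number of observations averaged
#' per cell) and referred to a t distribution on the Error degrees of
#' freedom.  Stars follow the conventional thresholds (0.05, 0.01, 0.001),
#' uncorrected for multiplicity.
#'
#' @param fit a \code{\link{fit_griffing}} or Method III fit.
#' @param anova the matching \code{\link{griffing_anova}} table (for the
#'   Error mean square and df), or explicit \code{ms_error}/\code{df_error}.
#' @param ms_error,df_error Error mean square and degrees of freedom,
#'   overriding \code{anova}.
#' @return data.frame with columns \code{class} (GCA/SCA/Reciprocal),
#'   \code{label}, \code{estimate}, \code{se}, \code{t}, \code{p},
#'   \code{stars}.  With a zero Error mean square (noiseless data) the fit
#'   is exact: \code{se} is 0 and \code{t}/\code{p} are NA.
#' @export
effect_tests <- function(fit, anova = NULL, ms_error = NULL, df_error = NULL) {
  stopifnot(inherits(fit, "griffing_fit"))
  if (!is.null(anova)) {
    ms_error <- anova$MS[anova$source == "Error"]
    df_error <- anova$df[anova$source == "Error"]
  }
  if (is.null(ms_error) || is.null(df_error)) {
    stop("supply an anova table or ms_error and df_error")
  }
  p <- fit$design$p
  parents <- fit$design$parents
  vf <- griffing_var_factors(p, fit$method)
  unit <- ms_error / fit$n_per_cell
  rows <- list()
  rows$gca <- data.frame(
    class = "GCA", label = parents, estimate = unname(fit$gca),
    se = sqrt(vf$gca * unit), stringsAsFactors = FALSE)
  idx <- which(upper.tri(fit$sca, diag = fit$method == "I"), arr.ind = TRUE)
  rows$sca <- data.frame(
    class = "SCA",
    label = ifelse(idx[, 1] == idx[, 2], parents[idx[, 1]],
                   paste(parents[idx[, 1]], parents[idx[, 2]], sep = " x ")),
    estimate = fit$sca[idx], se = sqrt(vf$sca[idx] * unit),
    stringsAsFactors = FALSE)
  idx2 <- which(upper.tri(fit$rec), arr.ind = TRUE)
  rows$rec <- data.frame(
    class = "Reciprocal",
    label = paste(parents[idx2[, 1]], parents[idx2[, 2]], sep = " x "),
    estimate = fit$rec[idx2], se = sqrt(vf$rec[idx2] * unit),
    stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (ms_error > 0) {
    out$t <- out$estimate / out$se
    out$p <- 2 * stats::pt(abs(out$t), df_error, lower.tail = FALSE)
  } else {
    out$t <- NA_real_
    out$p <- NA_real_
    attr(out, "exact_fit") <- TRUE
  }
  out$stars <- significance_stars(out$p)
  out
}

#' Significance star coding
#'
#' @param p vector of p-values.
#' @return character: \code{"***"} for p <= 0.001, \code{"**"} for
#'   p <= 0.01, \code{"*"} for p <= 0.05, otherwise \code{""}.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**",
                                          ifelse(p <= 0.05, "*", ""))))
}
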