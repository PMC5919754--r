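#' Posterior degree of dominance for a parent pair
#'
#' The Comstock-Robinson degree of dominance of parent A in combination with
#' parent B, computed per posterior draw from the predicted cross-mean grid:
#' \deqn{a_{CR} = 1 - 2 (y_{BB} - y_{Bb}) / (y_{BB} - y_{bb})}
#' where \eqn{y_{BB}} is the predicted self of B, \eqn{y_{bb}} the predicted
#' self of A, and \eqn{y_{Bb}} the mean of the two reciprocal hybrid cells
#' (averaging removes maternal and asymmetric contributions from the
#' dominance signal).  \eqn{a_{CR} = -1} means A is recessive to B, 0
#' additive (codominant), 1 dominant; values beyond \eqn{\pm 1.5} indicate
#' pseudo-over/under-dominance.  Draws whose denominator is within
#' \code{eps} of zero are excluded and counted.
#'
#' A pair is classified into one of the bins pseudo-under-recessive
#' \eqn{(-\infty,-1.5)}, recessive \eqn{(-1.5,-0.5)}, additive
#' \eqn{(-0.5,0.5)}, dominant \eqn{(0.5,1.5)}, pseudo-overdominant
#' \eqn{(1.5,\infty)} only when the posterior mean, the median, and the
#' majority of draws all fall in that bin; otherwise it is unclassified.
#'
#' @param posterior a \code{\link{gibbs_fit}} result, or a
#'   \code{\link{predicted_grid}}.
#' @param A,B parent labels (or 1-based indices); A != B.
#' @param eps denominator guard; default \eqn{10^{-6}} times the posterior
#'   SD of the predicted selfs.
#' @return object of class \code{"dominance_result"}: list with \code{pair},
#'   \code{draws} (retained aCR values), \code{mean}, \code{median},
#'   \code{q95} (2.5\% and 97.5\% central quantiles), \code{classification},
#'   \code{excluded_fraction}.
#' @export
degree_of_dominance <- function(posterior, A, B, eps = NULL) {
  grid <- if (inherits(posterior, "predicted_grid")) posterior
          else predicted_grid(posterior)
  d <- grid$design
  p <- d$p
  ai <- if (is.character(A)) match(A, d$parents) else as.integer(A)
  bi <- if (is.character(B)) match(B, d$parents) else as.integer(B)
  if (is.na(ai) || is.na(bi)) stop("unknown parent label")
  if (ai == bi) stop("degree of dominance needs two distinct parents")
  cell <- function(j, k) grid$draws[, (j - 1) * p + k]
  yBB <- cell(bi, bi)
  ybb <- cell(ai, ai)
  yBb <- (cell(ai, bi) + cell(bi, ai)) / 2
  if (is.null(eps)) {
    selfs <- grid$draws[, (seq_len(p) - 1) * p + seq_len(p), drop = FALSE]
    eps <- 1e-6 * stats::sd(as.vector(selfs))
    if (!is.finite(eps) || eps == 0) eps <- 1e-12
  }
  denom <- yBB - ybb
  keep <- abs(denom) >= eps
  excluded <- 1 - mean(keep)
  if (!any(keep)) {
    stop("all draws excluded: predicted selfs of ", d$parents[ai], " and ",
         d$parents[bi], " coincide")
  }
  acr <- 1 - 2 * (yBB[keep] - yBb[keep]) / denom[keep]
  m <- mean(acr)
  med <- stats::median(acr)
  bins <- c(-Inf, -1.5, -0.5, 0.5, 1.5, Inf)
  labels <- c("pseudo-under-recessive", "recessive", "additive",
              "dominant", "pseudo-overdominant")
  bin_of <- function(x) findInterval(x, bins, rightmost.closed = TRUE)
  shares <- tabulate(bin_of(acr), nbins = 5) / length(acr)
  cls <- if (bin_of(m) == bin_of(med) && shares[bin_of(m)] > 0.5) {
    labels[bin_of(m)]
  } else "unclassified"
  structure(
    list(pair = c(A = d$parents[ai], B = d$parents[bi]),
         draws = acr, mean = m, median = med,
         q95 = stats::quantile(acr, c(0.025, 0.975), names = FALSE),
         classification = cls, excluded_fraction = excluded),
    class = "dominance_result")
}

#' @export
print.dominance_result <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Degree of dominance of %s with %s: mean %s, median %s, 95%% (%s, %s) -> %s\n",
    x$pair["A"], x$pair["B"], format(x$mean, digits = digits),
    format(x$median, digits = digits), format(x$q95[1], digits = digits),
    format(x$q95[2], digits = digits), x$classification))
  invisible(x)
}

#' Degree-of-dominance summary for every parent pair
#'
#' @param posterior a \code{\link{gibbs_fit}} result.
#' @param ... passed to \code{\link{degree_of_dominance}}.
#' @return data.frame with one row per ordered pair (A, B), A != B.
#' @export
dominance_summary <- function(posterior, ...) {
  grid <- predicted_grid(posterior)
  d <- grid$design
  pairs <- expand.grid(A = seq_len(d$p), B = seq_len(d$p))
  pairs <- pairs[pairs$A != pairs$B, ]
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    r <- degree_of_dominance(grid, pairs$A[i], pairs$B[i], ...)
    data.frame(A = r$pair["A"], B = r$pair["B"], mean = r$mean,
               median = r$median, q2.5 = r$q95[1], q97.5 = r$q95[2],
               classification = r$classification,
               excluded_fraction = r$excluded_fraction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Diallel variance projection
#'
#' Projects the posterior onto a future, complete, perfectly balanced
#' diallel of the same parents: for each retained draw the \eqn{p^2} cell
#' contributions of every inheritance class (additive a, maternal m, overall
#' inbred B, parent-specific inbred b, cross-specific symmetric v and
#' asymmetric w) are reconstructed from that draw's effects, a fresh
#' residual is added per cell, and each class's share of the total
#' phenotypic sum of squares about the grand mean is computed as the
#' covariance projection
#' \deqn{VarP_c = \sum \tilde c \,\tilde y \;/\; \sum \tilde y^2 \times 100}
#' (tildes denote centering over the \eqn{p^2} cells).  Because the class
#' contributions sum to the phenotype, the class shares plus the unexplained
#' (residual) share add to exactly 100 in every draw; shares can be negative
#' when a class contribution is negatively correlated with the total, as
#' happens for weak classes.  Covariates sit at the reference profile (they
#' are constant across cells and vanish on centering).
#'
#' @param posterior a \code{\link{gibbs_fit}} result (fullu model for all
#'   six classes; nested models project their subset).
#' @param mass credibility mass for the HPD summaries (default 0.95).
#' @param seed optional seed for the fresh residual draws.
#' @return object of class \code{"varp_result"}: data.frame with columns
#'   \code{class}, \code{mean}, \code{lo}, \code{hi} (in percent), one row
#'   per inheritance class plus \code{total_explained} and
#'   \code{unexplained}; the per-draw shares are in
#'   \code{attr(, "draws")}.
#' @export
varp <- function(posterior, mass = 0.95, seed = NULL) {
  stopifnot(inherits(posterior, "diallel_posterior"))
  if (!is.null(seed)) set.seed(seed)
  d <- posterior$design
  p <- d$p
  dr <- posterior_draws(posterior)
  pn <- colnames(dr)
  n_draw <- nrow(dr)
  cells <- expand.grid(k = seq_len(p), j = seq_len(p))[, 2:1]
  j <- cells$j; k <- cells$k
  self <- j == k
  pair <- paste(pmin(j, k), pmax(j, k), sep = ":")
  sgn <- ifelse(j < k, 1, -1)

  # per-class coefficient matrices (p^2 x n_par): contribution = draws %*% t(Cc)
  zero <- matrix(0, p^2, length(pn), dimnames = list(NULL, pn))
  Cs <- list()
  if (any(grepl("^a:", pn))) {
    C <- zero
    for (i in seq_len(p^2)) {
      C[i, paste0("a:", d$parents[j[i]])] <-
        C[i, paste0("a:", d$parents[j[i]])] + 1
      C[i, paste0("a:", d$parents[k[i]])] <-
        C[i, paste0("a:", d$parents[k[i]])] + 1
    }
    Cs$a <- C
  }
  if (any(grepl("^m:", pn))) {
    C <- zero
    for (i in which(!self)) {
      C[i, paste0("m:", d$parents[j[i]])] <- 1
      C[i, paste0("m:", d$parents[k[i]])] <- -1
    }
    Cs$m <- C
  }
  if ("beta_inbred" %in% pn) {
    C <- zero
    C[self, "beta_inbred"] <- 1
    Cs$B <- C
  }
  if (any(grepl("^b:", pn))) {
    C <- zero
    for (i in which(self)) C[i, paste0("b:", d$parents[j[i]])] <- 1
    Cs$b <- C
  }
  if (any(grepl("^v:", pn))) {
    C <- zero
    for (i in which(!self)) C[i, paste0("v:", pair[i])] <- 1
    Cs$v <- C
    C <- zero
    for (i in which(!self)) C[i, paste0("w:", pair[i])] <- sgn[i]
    Cs$w <- C
  }

  contrib <- lapply(Cs, function(C) dr %*% t(C))   # n_draw x p^2 each
  noise <- matrix(stats::rnorm(n_draw * p^2), n_draw, p^2) *
    sqrt(dr[, "sigma2"])
  total <- noise
  for (M in contrib) total <- total + M
  center <- function(M) M - rowMeans(M)
  yt <- center(total)
  denom <- rowSums(yt^2)
  share <- function(M) 100 * rowSums(center(M) * yt) / denom
  shares <- vapply(contrib, share, numeric(n_draw))
  un <- share(noise)
  draws <- cbind(shares, total_explained = 100 - un, unexplained = un)
  summ <- t(apply(draws, 2, function(x) {
    c(mean = mean(x), hpd_interval(x, mass))
  }))
  out <- data.frame(class = rownames(summ), mean = summ[, "mean"],
                    lo = summ[, "lo"], hi = summ[, "hi"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "draws") <- draws
  class(out) <- c("varp_result", "data.frame")
  out
}

#' Correlation matrix with significance tests
#'
#' Pairwise Pearson (or Spearman) correlations between the columns of a
#' numeric matrix or data.frame, with two-sided p-values and star coding.
#'
#' @param x numeric matrix or data.frame (>= 3 rows).
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return list with matrices \code{r}, \code{p}, and \code{stars}.
#'   Zero-variance columns yield NA correlations.
#' @export
effect_correlations <- function(x, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 3)
  q <- ncol(x)
  r <- diag(1, q); pv <- matrix(NA_real_, q, q)
  dimnames(r) <- dimnames(pv) <- list(colnames(x), colnames(x))
  for (i in seq_len(q - 1)) for (jj in (i + 1):q) {
    if (stats::sd(x[, i]) == 0 || stats::sd(x[, jj]) == 0) {
      r[i, jj] <- r[jj, i] <- NA_real_
      next
    }
    ct <- suppressWarnings(
      stats::cor.test(x[, i], x[, jj], method = method))
    r[i, jj] <- r[jj, i] <- unname(ct$estimate)
    pv[i, jj] <- pv[jj, i] <- ct$p.value
  }
  stars <- matrix(significance_stars(pv), q, q, dimnames = dimnames(pv))
  list(r = r, p = pv, stars = stars)
}
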