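#' Define a diallel mating design
#'
#' A full diallel crosses \code{p} inbred parents in all ordered pairwise
#' combinations.  Griffing's Method I keeps all \eqn{p^2} entries (parental
#' selfs, F1s, and reciprocal F1s); Method III keeps only the \eqn{p(p-1)}
#' F1s and reciprocals.  The design also records the evaluation structure:
#' environments (locations/years) and the number of complete blocks per
#' environment (RCBD).
#'
#' @param parents character vector of unique parent labels, or a single
#'   integer \code{p} (labels \code{P1..Pp} are generated).
#' @param environments character vector of environment labels, or a single
#'   integer \code{e}.
#' @param blocks number of complete blocks (replications) per environment.
#' @param method Griffing method, \code{"I"} (default) or \code{"III"}.
#' @return An object of class \code{"diallel_design"}: a list with elements
#'   \code{p}, \code{parents}, \code{environments}, \code{blocks},
#'   \code{method}.
#' @examples
#' d <- diallel_design(6, environments = 3, blocks = 2)
#' nrow(enumerate_crosses(d))  # 36 entries
#' @export
diallel_design <- function(parents, environments = 1, blocks = 1,
                           method = c("I", "III")) {
  method <- match.arg(method)
  if (length(parents) == 1L && is.numeric(parents)) {
    parents <- paste0("P", seq_len(parents))
  }
  parents <- as.character(parents)
  if (length(environments) == 1L && is.numeric(environments)) {
    environments <- paste0("E", seq_len(environments))
  }
  environments <- as.character(environments)
  p <- length(parents)
  e <- length(environments)
  if (p < 2L) stop("a diallel needs at least 2 parents")
  if (anyDuplicated(parents)) stop("parent labels must be unique")
  if (anyDuplicated(environments)) stop("environment labels must be unique")
  if (e < 1L) stop("need at least one environment")
  blocks <- as.integer(blocks)
  if (blocks < 1L) stop("need at least one block per environment")
  structure(
    list(p = p, parents = parents, environments = environments,
         blocks = blocks, method = method),
    class = "diallel_design")
}

#' @export
print.diallel_design <- function(x, ...) {
  n_entry <- if (x$method == "I") x$p^2 else x$p * (x$p - 1L)
  cat(sprintf(
    "Diallel design (Griffing Method %s): %d parents, %d entries,\n  %d environment(s) x %d block(s) = %d plots\n",
    x$method, x$p, n_entry, length(x$environments), x$blocks,
    n_entry * length(x$environments) * x$blocks))
  invisible(x)
}

#' Enumerate the ordered crosses of a diallel design
#'
#' Female-major (row-major) order: the female parent indexes rows of every
#' p x p grid and is listed first in cross labels.
#'
#' @param design a \code{\link{diallel_design}}.
#' @return data.frame with columns \code{female}, \code{male} (1-based parent
#'   indices), \code{female_label}, \code{male_label}, \code{is_self}, and
#'   \code{cross} (label \code{"female x male"}).  Method I gives all
#'   \eqn{p^2} ordered pairs including selfs; Method III the \eqn{p(p-1)}
#'   ordered pairs with female != male.
#' @export
enumerate_crosses <- function(design) {
  stopifnot(inherits(design, "diallel_design"))
  p <- design$p
  grid <- expand.grid(male = seq_len(p), female = seq_len(p))[, 2:1]
  if (design$method == "III") grid <- grid[grid$female != grid$male, ]
  out <- data.frame(
    female = grid$female,
    male = grid$male,
    female_label = design$parents[grid$female],
    male_label = design$parents[grid$male],
    is_self = grid$female == grid$male,
    stringsAsFactors = FALSE)
  out$cross <- paste(out$female_label, out$male_label, sep = " x ")
  rownames(out) <- NULL
  out
}

#' ANOVA degrees-of-freedom skeleton for a multi-environment diallel
#'
#' Closed-form degrees of freedom for the fixed-effects (Model I) diallel
#' analysis of variance combined over environments: the Genotype source
#' partitions into GCA, SCA, and Reciprocal; with two or more environments
#' the Genotype x Environment interaction partitions the same way, and
#' replication is nested in environment.
#'
#' @param design a \code{\link{diallel_design}}.
#' @return named numeric vector of degrees of freedom.  For Method I:
#'   Genotype \eqn{p^2-1}, GCA \eqn{p-1}, SCA \eqn{p(p-1)/2}, Reciprocal
#'   \eqn{p(p-1)/2}, Location \eqn{e-1}, GxE \eqn{(p^2-1)(e-1)} with its three
#'   sub-partitions, rep(E) \eqn{e(r-1)}, Error \eqn{e(r-1)(p^2-1)}, Total
#'   \eqn{p^2er-1}.  For Method III the Genotype df is \eqn{p(p-1)-1} with
#'   SCA df \eqn{p(p-1)/2 - p}.  Interaction rows are present only when
#'   \eqn{e \ge 2}; Error requires \eqn{r \ge 2}.
#' @examples
#' anova_dof(diallel_design(6, 3, 2))  # Genotype 35, GCA 5, SCA 15, ...
#' @export
anova_dof <- function(design) {
  stopifnot(inherits(design, "diallel_design"))
  p <- design$p
  e <- length(design$environments)
  r <- design$blocks
  if (design$method == "I") {
    n_entry <- p^2
    df_g <- p^2 - 1
    df_gca <- p - 1
    df_sca <- p * (p - 1) / 2
    df_rec <- p * (p - 1) / 2
  } else {
    n_entry <- p * (p - 1)
    df_g <- p * (p - 1) - 1
    df_gca <- p - 1
    df_sca <- p * (p - 1) / 2 - p   # = p(p-3)/2; zero at p = 3 (saturated)
    df_rec <- p * (p - 1) / 2
    if (df_sca < 0) stop("SCA is not estimable under Method III with p < 3")
  }
  out <- c(Genotype = df_g, GCA = df_gca, SCA = df_sca, Reciprocal = df_rec)
  if (e >= 2) {
    out <- c(out,
             Location = e - 1,
             `G x E` = df_g * (e - 1),
             `GCA x E` = df_gca * (e - 1),
             `SCA x E` = df_sca * (e - 1),
             `Reciprocal x E` = df_rec * (e - 1))
  }
  out <- c(out, `rep(E)` = e * (r - 1), Error = e * (r - 1) * df_g)
  c(out, Total = n_entry * e * r - 1)
}

#' Average subsample measurements within a plot
#'
#' Plot values recorded as several subsamples are averaged prior to analysis.
#' Missing subsamples are dropped (available-case mean); the plot value is
#' missing only when every subsample is missing.
#'
#' @param values numeric vector of subsample measurements (may contain NA).
#' @return the arithmetic mean of the non-missing values, or \code{NA} if all
#'   are missing.
#' @export
average_subsamples <- function(values) {
  if (all(is.na(values))) return(NA_real_)
  mean(values, na.rm = TRUE)
}

#' Declare a trait and its analysis transformation
#'
#' @param name trait (column) name.
#' @param unit measurement unit, e.g. \code{"cm"} or \code{"g"}.
#' @param transform \code{"none"} or \code{"natural_log"} (requires strictly
#'   positive observed values, as for biomass).
#' @return object of class \code{"trait_spec"}.
#' @export
trait_spec <- function(name, unit = "", transform = c("none", "natural_log")) {
  transform <- match.arg(transform)
  structure(list(name = name, unit = unit, transform = transform),
            class = "trait_spec")
}

#' Apply a trait's transformation to a phenotype table
#'
#' Applies \code{ln(x)} to the trait column when the spec requests it; a
#' no-op for \code{transform = "none"}.  Missing values stay missing.  The
#' transformation applied is recorded in \code{attr(, "transformed")} so the
#' operation is not accidentally repeated.
#'
#' @param table a phenotype data.frame (see \code{\link{read_phenotypes}}).
#' @param spec a \code{\link{trait_spec}}.
#' @return the table with the trait column transformed.
#' @export
apply_transform <- function(table, spec) {
  stopifnot(inherits(spec, "trait_spec"))
  if (!spec$name %in% names(table)) {
    stop("trait '", spec$name, "' not found in table")
  }
  done <- attr(table, "transformed")
  if (spec$transform == "natural_log" && !(spec$name %in% done)) {
    x <- table[[spec$name]]
    bad <- which(!is.na(x) & x <= 0)
    if (length(bad)) {
      stop("natural_log transform requires positive values; trait '",
           spec$name, "' is non-positive in row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    table[[spec$name]] <- log(x)
    attr(table, "transformed") <- c(done, spec$name)
  }
  table
}

#' Invert a trait transformation
#'
#' @param table a phenotype data.frame previously passed through
#'   \code{\link{apply_transform}}.
#' @param spec the same \code{\link{trait_spec}}.
#' @return the table with the trait back on its original scale.
#' @export
invert_transform <- function(table, spec) {
  stopifnot(inherits(spec, "trait_spec"))
  done <- attr(table, "transformed")
  if (spec$transform == "natural_log" && spec$name %in% done) {
    table[[spec$name]] <- exp(table[[spec$name]])
    attr(table, "transformed") <- setdiff(done, spec$name)
  }
  table
}
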