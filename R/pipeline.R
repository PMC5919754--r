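#' Run the full diallel analysis pipeline
#'
#' Executes the selected stages end to end on either a phenotype file or a
#' synthetic dataset: simulate (or read) -> impute -> Griffing (Methods I
#' and III) -> Bayesian diallel fit -> degree of dominance -> variance
#' projection -> hybrid ranks -> GGE tester selection.  All randomness flows
#' from \code{seed} through fixed per-stage offsets, so the same
#' configuration and seed reproduce identical results; when \code{outdir}
#' is given every tabular result is also written as CSV.
#'
#' @param design a Method I \code{\link{diallel_design}}.
#' @param trait trait column to analyse.
#' @param table optional phenotype data.frame (or CSV path); when absent a
#'   synthetic dataset is generated from \code{sim_config}.
#' @param sim_config a \code{\link{diallel_sim_config}} used when
#'   \code{table} is missing; defaults to the design with the generator
#'   defaults.
#' @param stages subset of
#'   \code{c("impute", "griffing", "bayes", "dominance", "varp", "rank",
#'   "gge")}.
#' @param m,n_iterations imputation control (defaults 10 sweeps of m = 10
#'   for pipeline runs; raise for production analyses).
#' @param chains,iterations,burn_in MCMC control for the Bayesian stage.
#' @param seed global seed.
#' @param outdir optional output directory for CSVs.
#' @return named list with the stage results that ran: \code{table},
#'   \code{imputed}, \code{griffing} (pooled or complete-data analysis),
#'   \code{method3}, \code{posterior}, \code{dominance}, \code{varp},
#'   \code{ranks}, \code{gge}, \code{tester}, plus \code{seed}.
#' @export
run_pipeline <- function(design, trait = "height", table = NULL,
                         sim_config = NULL,
                         stages = c("impute", "griffing", "bayes",
                                    "dominance", "varp", "rank", "gge"),
                         m = 10, n_iterations = 10,
                         chains = 2, iterations = 2000, burn_in = 500,
                         seed = 1, outdir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  out <- list(seed = seed)
  if (is.null(table)) {
    if (is.null(sim_config)) {
      sim_config <- diallel_sim_config(design = design, trait = trait,
                                       seed = seed)
    }
    sim <- simulate_diallel(sim_config)
    out$table <- sim$table
    out$true_effects <- sim$effects
  } else {
    if (is.character(table)) table <- read_phenotypes(table, design)
    out$table <- validate_phenotypes(table, design)
  }
  tab <- out$table

  analysis_tables <- list(tab)
  if ("impute" %in% stages) {
    if (anyNA(tab[, trait_names(tab), drop = FALSE])) {
      out$imputed <- pmm_impute(tab, design, m = m,
                                n_iterations = n_iterations,
                                seed = seed + 1000L)
      analysis_tables <- out$imputed$tables
    } else {
      message("no missing values; imputation stage is a pass-through")
    }
  }
  complete_one <- analysis_tables[[1]]

  if ("griffing" %in% stages) {
    if (length(analysis_tables) > 1) {
      out$griffing <- pool_griffing(out$imputed, design, trait)
    } else {
      fit <- fit_griffing(complete_one, design, trait)
      an <- griffing_anova(complete_one, design, trait)
      out$griffing <- list(fit = fit, anova = an,
                           effects = effect_tests(fit, an),
                           bakers_ratio = bakers_ratio(an))
    }
    out$method3 <- fit_method3(complete_one, design, trait)
  }
  if (any(c("bayes", "dominance", "varp", "rank") %in% stages)) {
    out$posterior <- gibbs_fit(tab, design, trait, chains = chains,
                               iterations = iterations, burn_in = burn_in,
                               seed = seed + 2000L)
  }
  if ("dominance" %in% stages) {
    out$dominance <- dominance_summary(out$posterior)
  }
  if ("varp" %in% stages) {
    out$varp <- varp(out$posterior, seed = seed + 3000L)
  }
  if ("rank" %in% stages) {
    strat <- lapply(design$environments, function(env) {
      gibbs_fit(tab[tab$environment == env, ], design, trait,
                chains = chains, iterations = iterations,
                burn_in = burn_in, seed = seed + 4000L,
                use_location = FALSE)
    })
    names(strat) <- design$environments
    out$ranks <- rank_hybrids(strat)
  }
  if ("gge" %in% stages) {
    out$gge <- gge_decompose(two_way_means(complete_one, design, trait))
    out$tester <- select_tester(out$gge)
  }

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(x, name) {
      utils::write.csv(x, file.path(outdir, paste0(name, ".csv")),
                       row.names = FALSE)
    }
    if (!is.null(out$griffing$anova)) wr(out$griffing$anova, "anova")
    if (!is.null(out$griffing$effects)) wr(out$griffing$effects, "effects")
    if (!is.null(out$dominance)) wr(out$dominance, "dominance")
    if (!is.null(out$varp)) wr(as.data.frame(out$varp), "varp")
    if (!is.null(out$ranks)) wr(out$ranks, "hybrid_ranks")
    if (!is.null(out$gge)) wr(out$gge$testers, "gge_testers")
  }
  out
}
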