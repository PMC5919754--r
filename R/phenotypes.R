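#' Read a long-format diallel phenotype file
#'
#' The single input currency of every analysis stage: one row per plot with
#' columns \code{female}, \code{male}, \code{environment}, \code{block},
#' \code{density} (ordinal 0-3 planting-density score), then one numeric
#' column per trait.  \code{"NA"} is the missing-value sentinel.
#'
#' @param path CSV file path.
#' @param design a \code{\link{diallel_design}} the rows must conform to.
#' @return a validated data.frame (see \code{\link{validate_phenotypes}}).
#' @export
read_phenotypes <- function(path, design) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA",
                         check.names = FALSE)
  validate_phenotypes(tab, design)
}

#' Write a phenotype table to CSV
#'
#' Inverse of \code{\link{read_phenotypes}}; missing values are written as
#' \code{"NA"}.
#'
#' @param table phenotype data.frame.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_phenotypes <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Validate a phenotype table against a diallel design
#'
#' Checks the required columns, that parents/environments/blocks are valid
#' under the design, that the density score is in 0-3, that trait values are
#' numeric and finite, and that no plot (cross, environment, block) is
#' duplicated.
#'
#' @param table data.frame with columns \code{female}, \code{male},
#'   \code{environment}, \code{block}, \code{density}, and trait columns.
#' @param design a \code{\link{diallel_design}}.
#' @return the table, with \code{female}/\code{male}/\code{environment}
#'   normalised to character and \code{block}/\code{density} to integer.
#' @export
validate_phenotypes <- function(table, design) {
  stopifnot(inherits(design, "diallel_design"))
  need <- c("female", "male", "environment", "block", "density")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  }
  table$female <- as.character(table$female)
  table$male <- as.character(table$male)
  table$environment <- as.character(table$environment)
  table$block <- as.integer(table$block)
  table$density <- as.integer(table$density)
  bad_parent <- !(table$female %in% design$parents &
                    table$male %in% design$parents)
  if (any(bad_parent)) {
    stop("unknown parent label in row(s) ",
         paste(utils::head(which(bad_parent), 5), collapse = ", "))
  }
  if (!all(table$environment %in% design$environments)) {
    stop("unknown environment label(s): ",
         paste(setdiff(table$environment, design$environments), collapse = ", "))
  }
  if (!all(table$block %in% seq_len(design$blocks))) {
    stop("block index outside 1..", design$blocks)
  }
  if (!all(is.na(table$density) | table$density %in% 0:3)) {
    stop("density score must be in {0,1,2,3}")
  }
  if (design$method == "III" && any(table$female == table$male)) {
    stop("Method III design admits no parental selfs")
  }
  key <- paste(table$female, table$male, table$environment, table$block)
  if (anyDuplicated(key)) {
    stop("duplicated plot row(s) at line(s) ",
         paste(utils::head(which(duplicated(key)), 5) + 1L, collapse = ", "))
  }
  for (tr in trait_names(table)) {
    x <- table[[tr]]
    if (!is.numeric(x)) stop("trait column '", tr, "' is not numeric")
    if (any(!is.na(x) & !is.finite(x))) {
      stop("non-finite value in trait '", tr, "'")
    }
  }
  table
}

#' Trait columns of a phenotype table
#'
#' @param table phenotype data.frame.
#' @return character vector of trait column names (everything after the five
#'   design columns).
#' @export
trait_names <- function(table) {
  setdiff(names(table), c("female", "male", "environment", "block", "density"))
}

#' Is a phenotype table complete for a trait?
#'
#' @param table phenotype data.frame.
#' @param trait trait column name (default: all traits).
#' @return logical.
#' @export
is_complete <- function(table, trait = trait_names(table)) {
  !anyNA(table[, trait, drop = FALSE])
}

# Parent index lookup (1-based, design order); internal.
parent_index <- function(labels, design) {
  i <- match(labels, design$parents)
  if (anyNA(i)) stop("unknown parent label")
  i
}

# p x p matrix of ordered-cross cell means for one trait, rows = female.
# Averages over environments and blocks; NA cells indicate empty cells.
cell_mean_matrix <- function(table, design, trait, environment = NULL) {
  if (!is.null(environment)) {
    table <- table[table$environment == environment, , drop = FALSE]
  }
  p <- design$p
  j <- parent_index(table$female, design)
  k <- parent_index(table$male, design)
  y <- table[[trait]]
  num <- matrix(0, p, p, dimnames = list(design$parents, design$parents))
  cnt <- matrix(0L, p, p)
  ok <- !is.na(y)
  for (i in which(ok)) {
    num[j[i], k[i]] <- num[j[i], k[i]] + y[i]
    cnt[j[i], k[i]] <- cnt[j[i], k[i]] + 1L
  }
  out <- num / cnt
  out[cnt == 0L] <- NA_real_
  out
}
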