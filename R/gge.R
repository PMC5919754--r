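#' Two-way entry-by-tester mean matrix
#'
#' The p x p matrix of ordered-cross means (over environments and blocks)
#' with parental lines as both entries (rows, the female parent) and testers
#' (columns, the male parent): the input to the GGE biplot.
#'
#' @param table phenotype data.frame; every ordered cell needs at least one
#'   observation (impute first otherwise).
#' @param design a Method I \code{\link{diallel_design}}.
#' @param trait trait to average.
#' @return p x p numeric matrix, rows = entries, columns = testers.
#' @export
two_way_means <- function(table, design, trait) {
  M <- cell_mean_matrix(table[!is.na(table[[trait]]), ], design, trait)
  if (anyNA(M)) {
    idx <- which(is.na(M), arr.ind = TRUE)[1, ]
    stop("empty cell for entry '", design$parents[idx[1]], "' x tester '",
         design$parents[idx[2]], "'; impute or complete the data first")
  }
  M
}

#' GGE biplot decomposition with tester centering and symmetric scaling
#'
#' Column-centers the two-way matrix (tester centering), takes its singular
#' value decomposition, and splits each retained singular value evenly
#' between entry and tester scores (symmetric scaling, exponent 1/2 each).
#' The "discriminativeness vs. representativeness" view is summarised per
#' tester: the Euclidean length of its score vector (discriminativeness: a
#' longer vector ranks entries more strongly) and its angle to the
#' average-tester axis, the direction of the mean tester score vector
#' (representativeness: a smaller angle means closer to the average tester,
#' i.e. minimal specific combining ability).
#'
#' @param M p x p (or rectangular) two-way matrix of means, testers in
#'   columns.
#' @param n_axes number of retained axes (default 2).
#' @return object of class \code{"gge_biplot"}: list with \code{centered},
#'   \code{entry_scores}, \code{tester_scores} (retained axes),
#'   \code{singular_values}, \code{percent_var} (all axes),
#'   \code{average_tester} (unit vector), and \code{testers} (data.frame:
#'   tester, length, angle in radians, cos, projection onto the
#'   average-tester axis).
#' @export
gge_decompose <- function(M, n_axes = 2) {
  M <- as.matrix(M)
  if (is.null(colnames(M))) colnames(M) <- paste0("T", seq_len(ncol(M)))
  if (is.null(rownames(M))) rownames(M) <- paste0("E", seq_len(nrow(M)))
  centered <- sweep(M, 2, colMeans(M))
  sv <- svd(centered)
  if (max(sv$d) <= 1e-12 * max(1, max(abs(M)))) {
    stop("degenerate matrix: all tester columns are constant after centering")
  }
  # deterministic sign: largest-magnitude coordinate of each left singular
  # vector made positive
  for (i in seq_along(sv$d)) {
    s <- sign(sv$u[which.max(abs(sv$u[, i])), i])
    if (s < 0) {
      sv$u[, i] <- -sv$u[, i]
      sv$v[, i] <- -sv$v[, i]
    }
  }
  n_axes <- min(n_axes, sum(sv$d > max(sv$d) * 1e-12))
  scale_half <- sqrt(sv$d[seq_len(n_axes)])
  entry <- sv$u[, seq_len(n_axes), drop = FALSE] %*% diag(scale_half, n_axes)
  tester <- sv$v[, seq_len(n_axes), drop = FALSE] %*% diag(scale_half, n_axes)
  rownames(entry) <- rownames(M)
  rownames(tester) <- colnames(M)
  ata <- colMeans(tester)
  ata_len <- sqrt(sum(ata^2))
  # the average-tester axis is undefined when tester vectors cancel exactly
  ata_unit <- if (ata_len > 1e-10 * max(1, max(abs(tester)))) {
    ata / ata_len
  } else {
    rep(0, length(ata))
  }
  len <- sqrt(rowSums(tester^2))
  proj <- drop(tester %*% ata_unit)
  cosang <- ifelse(len > 0, proj / len, NA_real_)
  cosang <- pmin(1, pmax(-1, cosang))
  testers <- data.frame(tester = colnames(M), length = len,
                        angle = acos(cosang), cos = cosang,
                        projection = proj, stringsAsFactors = FALSE)
  rownames(testers) <- NULL
  structure(
    list(centered = centered, entry_scores = entry, tester_scores = tester,
         singular_values = sv$d, percent_var = 100 * sv$d^2 / sum(sv$d^2),
         average_tester = ata_unit, testers = testers),
    class = "gge_biplot")
}

#' @export
print.gge_biplot <- function(x, digits = 3, ...) {
  cat(sprintf("GGE biplot: axes 1+2 explain %.1f%% of variation\n",
              sum(x$percent_var[1:min(2, length(x$percent_var))])))
  print(cbind(round(x$testers[, c("length", "angle", "projection")], digits),
              tester = x$testers$tester))
  invisible(x)
}

#' Select the best tester from a GGE biplot
#'
#' Ranks testers by the composite criterion length x cos(angle to the
#' average-tester axis) -- the projection of the tester vector onto the
#' average-tester axis -- which rewards testers that are simultaneously
#' discriminating (long vector) and representative (small angle).  Both
#' component scores are returned so the conventional visual judgment can be
#' applied as well.
#'
#' @param biplot a \code{\link{gge_decompose}} result.
#' @return list with \code{best} (tester label(s); more than one when tied,
#'   with \code{tied = TRUE}) and \code{ranking} (data.frame sorted by the
#'   composite score).
#' @export
select_tester <- function(biplot) {
  stopifnot(inherits(biplot, "gge_biplot"))
  tab <- biplot$testers
  tab$score <- tab$length * tab$cos
  tab <- tab[order(-tab$score), ]
  rownames(tab) <- NULL
  tol <- 1e-8 * max(1, tab$length)
  best <- tab$tester[tab$score >= tab$score[1] - tol]
  list(best = best, tied = length(best) > 1, ranking = tab)
}
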