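# Agreement and diagnostic-performance statistics for binary reads.

#' Rating table for agreement analysis
#'
#' @param ratings units x raters matrix of binary decisions (0/1 or
#'   logical); `NA` marks a missing rating.
#' @param truth optional per-unit binary ground truth.
#' @return A `rating_table`.
#' @export
rating_table <- function(ratings, truth = NULL) {
  ratings <- as.matrix(ratings)
  if (nrow(ratings) < 2L || ncol(ratings) < 1L) {
    stop("need at least 2 units and 1 rater", call. = FALSE)
  }
  vals <- ratings[!is.na(ratings)]
  if (!all(vals %in% c(0, 1))) {
    stop("ratings must be binary (0/1) or missing", call. = FALSE)
  }
  if (!is.null(truth)) {
    if (length(truth) != nrow(ratings)) stop("`truth` length must match units", call. = FALSE)
    if (!all(truth[!is.na(truth)] %in% c(0, 1))) stop("`truth` must be binary", call. = FALSE)
  }
  structure(list(ratings = ratings, truth = truth), class = "rating_table")
}

#' Read a ratings CSV
#'
#' Long format: columns `unit_id`, `rater_id`, `decision`, optional `truth`.
#'
#' @param path CSV file.
#' @return A [rating_table()].
#' @export
read_ratings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("unit_id", "rater_id", "decision")
  if (!all(need %in% names(df))) {
    stop(sprintf("ratings CSV needs columns: %s", paste(need, collapse = ", ")), call. = FALSE)
  }
  units <- unique(df$unit_id)
  raters <- unique(df$rater_id)
  m <- matrix(NA_real_, length(units), length(raters),
              dimnames = list(units, raters))
  m[cbind(match(df$unit_id, units), match(df$rater_id, raters))] <- df$decision
  truth <- NULL
  if ("truth" %in% names(df)) {
    tr <- tapply(df$truth, df$unit_id, function(x) unique(stats::na.omit(x))[1])
    truth <- as.numeric(tr[as.character(units)])
  }
  rating_table(m, truth)
}

#' Krippendorff's alpha for binary ratings
#'
#' Chance-corrected agreement, alpha = 1 - D_observed / D_expected, with
#' the nominal difference function and Krippendorff's pairable-values rule
#' for missing data (units with fewer than two ratings contribute nothing).
#' When disagreement is impossible (every pairable value identical,
#' D_expected = 0) alpha is undefined and reported as `NA`.
#'
#' @param table a [rating_table()] or a units x raters matrix.
#' @return A tibble with columns `alpha`, `n_units` (pairable units),
#'   `n_pairable` (pairable values), `d_observed`, `d_expected`.
#' @export
krippendorff_alpha <- function(table) {
  if (inherits(table, "rating_table")) table <- table$ratings
  r <- as.matrix(table)
  m_u <- rowSums(!is.na(r))
  use <- m_u >= 2L
  if (sum(use) < 2L) {
    stop("insufficient data: need at least 2 units with >= 2 ratings each", call. = FALSE)
  }
  r <- r[use, , drop = FALSE]
  m_u <- m_u[use]

  # coincidence matrix over categories {0, 1}
  o <- matrix(0, 2L, 2L)
  for (u in seq_len(nrow(r))) {
    vals <- r[u, !is.na(r[u, ])]
    n1 <- sum(vals == 1)
    n0 <- length(vals) - n1
    w <- 1 / (length(vals) - 1)
    o[1, 1] <- o[1, 1] + n0 * (n0 - 1) * w
    o[2, 2] <- o[2, 2] + n1 * (n1 - 1) * w
    o[1, 2] <- o[1, 2] + n0 * n1 * w
    o[2, 1] <- o[2, 1] + n1 * n0 * w
  }
  n <- sum(o)
  nc <- rowSums(o)
  d_obs <- o[1, 2] + o[2, 1]
  d_exp <- 2 * nc[1] * nc[2] / (n - 1)
  alpha <- if (d_exp == 0) NA_real_ else 1 - d_obs / d_exp

  tibble::tibble(alpha = alpha, n_units = nrow(r), n_pairable = sum(m_u),
                 d_observed = d_obs, d_expected = unname(d_exp))
}

#' Diagnostic performance from binary decisions and truth
#'
#' Standard 2x2 ratios. A metric whose denominator is empty (e.g.
#' specificity with all-positive truth) is reported as `NA`, flagged in
#' the `defined` column, never coerced to 0.
#'
#' @param decisions per-unit binary decisions.
#' @param truth per-unit binary ground truth, same length.
#' @return Tibble with columns `metric`, `value`, `defined`, plus the 2x2
#'   cell counts as attribute `"cells"`.
#' @export
diagnostic_metrics <- function(decisions, truth) {
  if (length(decisions) != length(truth)) {
    stop("`decisions` and `truth` must have equal length", call. = FALSE)
  }
  ok <- !is.na(decisions) & !is.na(truth)
  d <- as.numeric(decisions[ok])
  t <- as.numeric(truth[ok])
  if (!all(c(d, t) %in% c(0, 1))) stop("decisions and truth must be binary", call. = FALSE)

  tp <- sum(d == 1 & t == 1)
  fn <- sum(d == 0 & t == 1)
  tn <- sum(d == 0 & t == 0)
  fp <- sum(d == 1 & t == 0)

  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  vals <- c(
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    accuracy = ratio(tp + tn, tp + tn + fp + fn)
  )
  out <- tibble::tibble(metric = names(vals), value = unname(vals),
                        defined = !is.na(vals))
  attr(out, "cells") <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  out
}
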