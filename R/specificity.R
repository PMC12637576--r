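## Cell-type specificity indices for PSI profiles.
##
## Tau is the classical tissue-specificity index for expression profiles;
## it normalises each component by the profile maximum. For PSI profiles,
## which are bounded in [0, 1] and often bimodal, Tau overstates
## specificity when the dynamic range is small (e.g. a profile hovering
## near 0 everywhere but with max 0.02 still gets Tau near 1). Upsilon is
## the PSI-adapted variant: it shifts the normalisation by one unit so
## that the score measures specificity relative to the full PSI scale,
## and rescales by 2 so that a single-cell-type-exclusive profile still
## scores exactly 1.

#' Tau specificity index
#'
#' Computes the tissue/cell-type specificity index
#' \eqn{\tau = \sum_i (1 - \hat x_i) / (N - 1)} with
#' \eqn{\hat x_i = x_i / \max_i x_i}, over the non-missing entries of a
#' PSI (or expression) profile. Tau is 0 for a uniform profile and 1 for
#' a profile in which exactly one cell type is nonzero.
#'
#' @param x Numeric vector: one element's PSI across cell types. `NA`s
#'   are dropped (and reduce the effective `N`).
#' @return Scalar in \[0, 1\]. If all entries are zero the score is 0
#'   (no evidence of specificity) with attribute `degenerate = TRUE`.
#' @seealso [upsilon_score()] for the PSI-adapted variant.
#' @examples
#' tau_score(c(1, 0, 0, 0, 0))  # 1
#' tau_score(c(1, 0.5, 0))      # 0.75
#' @export
tau_score <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  check_that(n >= 2, "tau_score: need at least 2 observed cell types, got %d", n)
  m <- max(x)
  if (m <= 0) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  xhat <- x / m
  sum(1 - xhat) / (n - 1)
}

#' Upsilon specificity index for PSI profiles
#'
#' The PSI-adapted specificity index
#' \eqn{\upsilon = 2 \sum_i (1 - \hat x_i) / (N - 1)} with shifted
#' normalisation \eqn{\hat x_i = (x_i + 1) / (\max_i x_i + 1)}. Unlike
#' Tau, the shift anchors the score to the absolute PSI scale, so
#' elements with low dynamic range (e.g. PSI everywhere below 0.05)
#' score near 0 rather than near 1. Upsilon is 0 iff the profile is
#' constant and 1 iff exactly one cell type has PSI 1 and all others 0.
#'
#' @param x Numeric vector of PSI values in \[0, 1\]; `NA`s dropped.
#' @return Scalar in \[0, 1\].
#' @examples
#' upsilon_score(c(1, 0, 0, 0, 0))   # 1
#' upsilon_score(rep(0.6, 5))        # 0
#' upsilon_score(c(1, 0.5, 0))       # 0.75
#' @export
upsilon_score <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  check_that(n >= 2, "upsilon_score: need at least 2 observed cell types, got %d", n)
  check_that(all(x >= 0 & x <= 1),
             "upsilon_score: PSI values must lie in [0, 1]")
  xhat <- (x + 1) / (max(x) + 1)
  2 * sum(1 - xhat) / (n - 1)
}

#' Reverse specificity scores
#'
#' Computes Tau and Upsilon on the inverted profile `1 - x`. Forward
#' scores flag elements *included* in a single cell type; reverse scores
#' flag elements *skipped* in a single cell type but included elsewhere.
#'
#' @inheritParams upsilon_score
#' @return Named numeric vector `c(tau_rev = , upsilon_rev = )`.
#' @export
reverse_scores <- function(x) {
  c(tau_rev = as.numeric(tau_score(1 - x)),
    upsilon_rev = upsilon_score(1 - x))
}

#' Score and shortlist cell-type-specific elements
#'
#' Computes Tau, Upsilon, their reverse variants, and the per-element
#' dynamic range (max - min PSI across cell types), then applies the
#' shortlisting rules for cell-type-specific splicing: an element is
#' shortlisted if any of
#' \enumerate{
#'   \item \eqn{\upsilon \ge 0.7} or \eqn{\upsilon_{rev} \ge 0.7},
#'   \item \eqn{\tau \ge 0.7} and dynamic range \eqn{\ge 0.3},
#'   \item \eqn{\tau_{rev} \ge 0.85} and dynamic range \eqn{\ge 0.3}.
#' }
#' Shortlisted elements are ranked by decreasing Upsilon (by default the
#' larger of the forward and reverse score, so inclusion- and
#' exclusion-specific events rank comparably).
#'
#' @param psi Numeric matrix, elements x cell types (or a [psi_matrix]
#'   object, whose cell-type PSI matrix is used). `NA` entries are
#'   treated as unobserved.
#' @param upsilon_min,tau_min,tau_rev_min,range_min Rule thresholds.
#' @param min_observed Elements observed in fewer cell types than this
#'   are not scored (all scores `NA`, never shortlisted).
#' @param rank_by `"max"` (default) ranks by `pmax(upsilon, upsilon_rev)`;
#'   `"forward"` ranks by the forward Upsilon only.
#' @return A data.frame with one row per element: scores, dynamic range,
#'   `specific_celltype` (the argmax cell type of the forward or the
#'   argmin for reverse-triggered elements), `shortlisted`, and `rule`
#'   (the first triggering rule, or `NA`), sorted by the ranking score
#'   with shortlisted elements first.
#' @export
shortlist_specific <- function(psi, upsilon_min = 0.7, tau_min = 0.7,
                               tau_rev_min = 0.85, range_min = 0.3,
                               min_observed = 3, rank_by = c("max", "forward")) {
  if (inherits(psi, "psi_matrix")) psi <- psi$psi
  check_that(is.matrix(psi) && ncol(psi) >= 2,
             "shortlist_specific: need a matrix with >= 2 cell types")
  rank_by <- match.arg(rank_by)
  ids <- rownames(psi)
  if (is.null(ids)) ids <- sprintf("element_%04d", seq_len(nrow(psi)))

  score_one <- function(x) {
    n_obs <- sum(!is.na(x))
    if (n_obs < min_observed) {
      return(c(tau = NA, upsilon = NA, tau_rev = NA, upsilon_rev = NA,
               dynamic_range = NA, argmax = NA, argmin = NA))
    }
    rev <- reverse_scores(x)
    c(tau = as.numeric(tau_score(x)), upsilon = upsilon_score(x),
      rev, dynamic_range = max(x, na.rm = TRUE) - min(x, na.rm = TRUE),
      argmax = unname(which.max(x)), argmin = unname(which.min(x)))
  }
  s <- t(apply(psi, 1, score_one))
  res <- data.frame(
    element = ids,
    tau = s[, "tau"], upsilon = s[, "upsilon"],
    tau_rev = s[, "tau_rev"], upsilon_rev = s[, "upsilon_rev"],
    dynamic_range = s[, "dynamic_range"],
    stringsAsFactors = FALSE
  )
  rule1 <- !is.na(res$upsilon) &
    (res$upsilon >= upsilon_min | res$upsilon_rev >= upsilon_min)
  rule2 <- !is.na(res$tau) & res$tau >= tau_min & res$dynamic_range >= range_min
  rule3 <- !is.na(res$tau_rev) & res$tau_rev >= tau_rev_min &
    res$dynamic_range >= range_min
  res$shortlisted <- rule1 | rule2 | rule3
  res$rule <- ifelse(rule1, "upsilon",
                     ifelse(rule2, "tau_range",
                            ifelse(rule3, "tau_rev_range", NA_character_)))
  ## the triggering direction decides which cell type is "the" specific one
  rev_trig <- !is.na(res$upsilon) & res$upsilon_rev > res$upsilon
  ct <- colnames(psi)
  if (is.null(ct)) ct <- sprintf("celltype_%02d", seq_len(ncol(psi)))
  idx <- ifelse(rev_trig, s[, "argmin"], s[, "argmax"])
  res$specific_celltype <- ifelse(is.na(idx), NA_character_, ct[idx])
  score <- if (rank_by == "max") pmax(res$upsilon, res$upsilon_rev) else res$upsilon
  res$rank_score <- score
  res <- res[order(-res$shortlisted, -score, res$element), ]
  rownames(res) <- NULL
  res
}
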