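## Saturation mutagenesis analysis: position x substitution effect
## grids, Gaussian smoothing, robust z-score region calling, and PWM
## log-odds scanning of called regions.

#' Effect-size grid from a saturation mutagenesis screen
#'
#' Computes `dpsi = parent PSI - variant PSI` for every single-
#' nucleotide variant of one parent in one cell line (or cell-line
#' group) and arranges the effects on a position x substitution grid.
#' Positive effects mark mutations that *reduce* inclusion (the position
#' supports splicing); a `flip_sign` flag reports the opposite
#' convention.
#'
#' @param parent_psi Scalar PSI of the unmutated parent.
#' @param variants data.frame with columns `position` (0-based within
#'   the variable region), `alt` (substituted base), `psi` (variant
#'   PSI; `NA` = unmeasured).
#' @param length Variable-region length (positions without variants are
#'   masked).
#' @param parent_id,cell_line Metadata carried through.
#' @param flip_sign Report `variant - parent` instead.
#' @return Object of class `effect_profile`: `grid` (3 x length matrix,
#'   rows are the substitution rank, `NA`-masked), `positionwise` (mean
#'   over available substitutions), plus metadata. Feed to
#'   [smooth_profile()] and [call_sensitive_regions()].
#' @export
effect_sizes <- function(parent_psi, variants, length, parent_id = "parent",
                         cell_line = "cell", flip_sign = FALSE) {
  check_that(!is.na(parent_psi), "effect_sizes: parent PSI missing")
  check_that(all(variants$position >= 0 & variants$position < length),
             "effect_sizes: variant positions out of range")
  dpsi <- parent_psi - variants$psi
  if (flip_sign) dpsi <- -dpsi
  grid <- matrix(NA_real_, 3, length,
                 dimnames = list(paste0("sub", 1:3), NULL))
  for (pos in unique(variants$position)) {
    v <- dpsi[variants$position == pos]
    v <- v[seq_len(min(3L, base::length(v)))]
    grid[seq_along(v), pos + 1L] <- v
  }
  pw <- colMeans(grid, na.rm = TRUE)
  pw[is.nan(pw)] <- NA_real_
  out <- list(parent = parent_id, cell_line = cell_line, grid = grid,
              positionwise = pw, flip_sign = flip_sign)
  class(out) <- "effect_profile"
  out
}

#' Gaussian smoothing of a positionwise effect profile
#'
#' Discrete Gaussian convolution with reflective boundary handling. The
#' kernel is truncated at four standard deviations and normalised to sum
#' to one, so constant profiles pass through unchanged.
#'
#' @param x Numeric vector (positionwise mean effects; `NA`s are
#'   interpolated from neighbours before smoothing).
#' @param sigma Kernel standard deviation in positions (default 2).
#' @return Numeric vector, same length.
#' @export
smooth_profile <- function(x, sigma = 2) {
  n <- length(x)
  check_that(n >= 5, "smooth_profile: profile too short (length %d)", n)
  na_mask <- is.na(x)
  if (any(na_mask)) {
    idx <- which(!na_mask)
    check_that(length(idx) >= 2, "smooth_profile: profile almost entirely missing")
    x <- stats::approx(idx, x[idx], xout = seq_len(n), rule = 2)$y
  }
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  ## reflective padding
  xp <- c(x[pmin(r:1 + 1L, n)], x, x[pmax(n - (1:r), 1L)])
  sm <- stats::filter(xp, k, sides = 2)
  as.numeric(sm[(r + 1L):(r + n)])
}

#' Call mutation-sensitive regions from an effect profile
#'
#' Robust z-score block procedure: the smoothed positionwise profile is
#' standardised as `z = (smoothed - median) / (IQR / 1.349)` (the
#' normal-consistent robust scale); positions with `|z| >= z_min` are
#' marked, maximal runs of consecutive marked positions of length
#' `>= min_block` are formed, and a run is emitted as a region when the
#' absolute mean *raw* positionwise effect inside it is
#' `>= min_mean_effect`. Direction comes from the sign of the mean
#' effect (`psi_decreasing` = mutations reduce inclusion).
#'
#' @param profile An [effect_profile][effect_sizes], or a numeric
#'   positionwise profile.
#' @param z_min Z threshold (3 for cell-type-specific screens, 4 for
#'   constitutive screens).
#' @param min_block Minimum region length in positions (3 and 2
#'   respectively).
#' @param min_mean_effect Minimum |mean dPSI| inside the region
#'   (default 0.25).
#' @param sigma Smoothing bandwidth passed to [smooth_profile()].
#' @return data.frame with one row per region: `start`, `end` (0-based
#'   half-open), `mean_effect`, `peak_z`, `direction`; attribute
#'   `degenerate` is TRUE when the IQR is zero (no calls possible).
#' @export
call_sensitive_regions <- function(profile, z_min = 3, min_block = 3L,
                                   min_mean_effect = 0.25, sigma = 2) {
  raw <- if (inherits(profile, "effect_profile")) profile$positionwise
         else as.numeric(profile)
  sm <- smooth_profile(raw, sigma = sigma)
  med <- stats::median(sm)
  iqr <- stats::IQR(sm)
  empty <- data.frame(start = integer(0), end = integer(0),
                      mean_effect = numeric(0), peak_z = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE)
  if (iqr <= 0) {
    attr(empty, "degenerate") <- TRUE
    return(empty)
  }
  z <- (sm - med) / (iqr / 1.349)
  marked <- abs(z) >= z_min
  r <- rle(marked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- empty
  for (i in which(r$values & r$lengths >= min_block)) {
    span <- starts[i]:ends[i]
    me <- mean(raw[span], na.rm = TRUE)
    if (is.na(me) || abs(me) < min_mean_effect) next
    out <- rbind(out, data.frame(
      start = starts[i] - 1L, end = ends[i],
      mean_effect = me, peak_z = z[span][which.max(abs(z[span]))],
      direction = if (me > 0) "psi_decreasing" else "psi_increasing",
      stringsAsFactors = FALSE))
  }
  attr(out, "degenerate") <- FALSE
  out
}

#' PWM log-odds scan of a region sequence
#'
#' Scores each named PWM at every offset of a region (forward strand of
#' the transcribed sequence) as the sum of per-column
#' `log2(p / background)` terms, and reports hits with score
#' `>= score_min`, sorted by decreasing score.
#'
#' @param sequence Region DNA sequence.
#' @param pwms Named list of 4 x width probability matrices (rows
#'   A/C/G/T).
#' @param score_min Minimum reported log-odds score (default 10).
#' @return data.frame: `pwm`, `offset` (0-based), `score`.
#' @export
pwm_logodds_scan <- function(sequence, pwms, score_min = 10) {
  check_that(length(pwms) > 0, "pwm_logodds_scan: empty PWM set")
  check_that(!is.null(names(pwms)) && all(nzchar(names(pwms))),
             "pwm_logodds_scan: PWMs must be named")
  hits <- lapply(names(pwms), function(nm) {
    sc <- scan_pwm_logodds(sequence, pwms[[nm]])
    keep <- which(sc >= score_min)
    if (!length(keep)) return(NULL)
    data.frame(pwm = nm, offset = keep - 1L, score = sc[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(pwm = character(0), offset = integer(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  }
  out[order(-out$score), , drop = FALSE]
}

#' Read / write PWMs as tab-delimited probability matrices
#'
#' Files are position x A/C/G/T (or A/C/G/U) tables with a header row.
#'
#' @param path File path.
#' @return `read_pwm`: a 4 x width probability matrix (rows A/C/G/T).
#' @export
read_pwm <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  cols <- toupper(colnames(df))
  cols[cols == "U"] <- "T"
  check_that(all(DNA_BASES %in% cols), "read_pwm: need A/C/G/T(U) columns")
  m <- t(as.matrix(df[, match(DNA_BASES, cols)]))
  rownames(m) <- DNA_BASES
  sweep(m, 2, colSums(m), "/")
}

#' @rdname read_pwm
#' @param pwm 4 x width probability matrix.
#' @export
write_pwm <- function(pwm, path) {
  df <- as.data.frame(t(pwm))
  colnames(df) <- rownames(pwm)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
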