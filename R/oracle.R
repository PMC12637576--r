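## Ground-truth sequence-to-PSI oracle. The oracle is the synthetic
## stand-in for splicing biology: PSI is a logistic function of splice
## site strength (read from the element's own donor/acceptor sequence)
## plus contributions from motif matches, some of which are gated by the
## expression level of a trans-acting regulator in each cell type. The
## predictive model is trained against oracle output and the generative
## model is scored against it, closing the design loop without any
## experimental data.

#' Construct a ground-truth splicing oracle
#'
#' @param motifs List of motif definitions, each a list with `name`,
#'   `pwm` (4 x width probability matrix, rows A/C/G/T), `weight`
#'   (logit-scale effect of a full match; negative = silencer), `window`
#'   (`"upstream_intron"`, `"exon"`, `"downstream_intron"`, or a 0-based
#'   half-open interval in variable-region coordinates), `gated`
#'   (logical: multiply the effect by the cell type's regulator level),
#'   and optionally `midpoint`/`scale` for the match activation.
#' @param regulator_map Named numeric vector: regulator expression level
#'   per cell type (log scale, >= 0).
#' @param intercept,slope Logistic link parameters: the baseline logit
#'   PSI and the weight on the standardised splice-site score.
#' @param donor_weight,acceptor_weight Relative weights of the two
#'   splice-site scores inside the baseline.
#' @param scorer A splice-site scorer (defaults to
#'   [pwm_splice_scorer()]).
#' @return Object of class `splicing_oracle`.
#' @export
splicing_oracle <- function(motifs, regulator_map, intercept = -0.2,
                            slope = 2.2, donor_weight = 0.6,
                            acceptor_weight = 0.4, scorer = NULL) {
  check_that(all(regulator_map >= 0),
             "splicing_oracle: regulator levels must be >= 0")
  for (m in motifs) {
    check_that(all(abs(colSums(m$pwm) - 1) < 1e-6),
               "splicing_oracle: motif '%s' PWM columns must sum to 1", m$name)
  }
  if (is.null(scorer)) scorer <- pwm_splice_scorer()
  out <- list(motifs = motifs, regulator_map = regulator_map,
              intercept = intercept, slope = slope,
              donor_weight = donor_weight, acceptor_weight = acceptor_weight,
              scorer = scorer)
  class(out) <- "splicing_oracle"
  out
}

## sharp PWM around a consensus string
consensus_pwm <- function(consensus, sharp = 0.94) {
  b <- strsplit(consensus, "", fixed = TRUE)[[1]]
  pwm <- matrix((1 - sharp) / 3, 4, length(b), dimnames = list(DNA_BASES, NULL))
  pwm[cbind(match(b, DNA_BASES), seq_along(b))] <- sharp
  pwm
}

## log-odds scan of a PWM along a sequence (forward strand); returns the
## score at every admissible 0-based offset
scan_pwm_logodds <- function(sequence, pwm, background = 0.25) {
  w <- ncol(pwm)
  code <- match(strsplit(sequence, "", fixed = TRUE)[[1]], DNA_BASES)
  n <- length(code) - w + 1L
  if (n < 1L) return(numeric(0))
  lo <- log2(pmax(pwm, 1e-6) / background)
  sc <- numeric(n)
  for (j in seq_len(w)) {
    sc <- sc + lo[, j][code[seq_len(n) + j - 1L]]
  }
  sc
}

resolve_window <- function(window, element) {
  if (is.numeric(window)) return(as.integer(window))
  n <- nchar(element$variable_region)
  switch(window,
         upstream_intron = c(0L, element$exon_interval[[1]]),
         exon = c(element$exon_interval[[1]], element$exon_interval[[2]]),
         downstream_intron = c(element$exon_interval[[2]], n),
         full = c(0L, n),
         stop("unknown oracle motif window: ", window))
}

## best match activation of one motif in one element: max log-odds in
## the window squashed through a logistic centred at `midpoint`
motif_activation <- function(motif, element) {
  win <- resolve_window(motif$window, element)
  sub <- substring(element$variable_region, win[1] + 1L, win[2])
  sc <- scan_pwm_logodds(sub, motif$pwm)
  if (!length(sc)) return(0)
  smax <- max(sc)
  max_possible <- sum(apply(log2(pmax(motif$pwm, 1e-6) / 0.25), 2, max))
  midpoint <- if (!is.null(motif$midpoint)) motif$midpoint else 0.75 * max_possible
  scale <- if (!is.null(motif$scale)) motif$scale else 1
  inv_logit((smax - midpoint) / scale)
}

#' Oracle PSI for elements across cell types
#'
#' @param oracle A [splicing_oracle()].
#' @param elements A minigene element or list of elements.
#' @param celltypes Cell types to evaluate (default: all in the
#'   regulator map).
#' @return Numeric matrix, elements x cell types, PSI in \[0, 1\].
#' @export
oracle_psi <- function(oracle, elements, celltypes = NULL) {
  if (inherits(elements, "minigene_element")) elements <- list(elements)
  if (is.null(celltypes)) celltypes <- names(oracle$regulator_map)
  lv <- oracle$regulator_map[celltypes]
  dpwm <- donor_consensus_pwm()
  ## acceptor strength is read from the 17-nt core (short pyrimidine
  ## tract + NCAG + exon start), where most 3'ss information lives
  apwm <- acceptor_consensus_pwm()[, 7:23]
  logits <- t(vapply(elements, function(el) {
    ## strongest-site rule: splice-site strength is the best PWM match
    ## anywhere in the variable region
    d <- max(scan_pwm_logodds(el$variable_region, dpwm))
    a <- max(scan_pwm_logodds(el$variable_region, apwm))
    base <- oracle$donor_weight * standardise_site(d) +
      oracle$acceptor_weight * standardise_site(a)
    logit_c <- rep(oracle$intercept + oracle$slope * base, length(lv))
    for (m in oracle$motifs) {
      if (m$weight == 0) next
      act <- motif_activation(m, el)
      gate <- if (isTRUE(m$gated)) lv else rep(1, length(lv))
      logit_c <- logit_c + m$weight * act * gate
    }
    logit_c
  }, numeric(length(lv))))
  if (length(lv) == 1L) logits <- matrix(logits, ncol = 1L)
  dimnames(logits) <- list(vapply(elements, `[[`, "", "id"), celltypes)
  inv_logit(logits)
}

## splice-site log-odds scores standardised to roughly unit scale
## (centred on the typical best match of a random variable region)
standardise_site <- function(score) {
  if (is.na(score)) return(0)
  (score - 8) / 3
}

#' Default oracle used by the synthetic benchmark
#'
#' Two planted motifs: a regulator-gated intronic enhancer (consensus
#' `TGCATG`, the classic neuronal splicing-enhancer hexamer) in the
#' downstream intron, active only where the regulator is expressed, and
#' an ungated exonic silencer (consensus `TCTTCTT`). Regulator levels:
#' roughly half the cell types silent, the rest expressing at log-scale
#' levels between 1 and 3.
#'
#' @param n_celltypes Number of cell types.
#' @param seed Integer seed (controls regulator levels).
#' @return A [splicing_oracle()].
#' @export
default_oracle <- function(n_celltypes = 5L, seed = 1L) {
  lv <- with_seed(derive_seed(seed, 31L), {
    on <- sample(c(TRUE, FALSE), n_celltypes, replace = TRUE)
    if (!any(on)) on[1] <- TRUE
    if (all(on)) on[1] <- FALSE
    ifelse(on, stats::runif(n_celltypes, 1, 3), 0)
  })
  names(lv) <- sprintf("celltype_%02d", seq_len(n_celltypes))
  motifs <- list(
    list(name = "gated_enhancer", pwm = consensus_pwm("TGCATG"),
         weight = 1.6, window = "full", gated = TRUE),
    list(name = "exonic_silencer", pwm = consensus_pwm("TCTTCTT"),
         weight = -2.5, window = "full", gated = FALSE)
  )
  splicing_oracle(motifs, lv)
}

#' Simulate a library with oracle-planted motifs
#'
#' Builds a random minigene library and plants instances of the
#' oracle's motifs (drawn from their PWMs) into random positions of the
#' corresponding windows for a fraction of elements, so that sequence
#' causally determines oracle PSI.
#'
#' @param n Number of elements.
#' @param oracle A [splicing_oracle()].
#' @param seed Integer seed.
#' @param plant_fraction Fraction of elements receiving each motif
#'   (independent draws per motif).
#' @return List of elements; attribute `planted` is a logical matrix
#'   (elements x motifs).
#' @export
simulate_oracle_library <- function(n, oracle, seed = 1L,
                                    plant_fraction = 0.4) {
  els <- simulate_library(n, seed = seed)
  nm <- vapply(oracle$motifs, `[[`, "", "name")
  planted <- matrix(FALSE, n, length(nm), dimnames = list(NULL, nm))
  with_seed(derive_seed(seed, 67L), {
    for (k in seq_along(oracle$motifs)) {
      m <- oracle$motifs[[k]]
      hit <- stats::runif(n) < plant_fraction
      planted[, k] <- hit
      inst <- draw_from_pwm(m$pwm, sum(hit))
      j <- 0L
      for (i in which(hit)) {
        j <- j + 1L
        win <- resolve_window(m$window, els[[i]])
        w <- ncol(m$pwm)
        lo <- win[1]; hi <- win[2] - w
        ## keep clear of the splice-site consensus windows
        if (identical(m$window, "downstream_intron")) lo <- lo + 8L
        if (identical(m$window, "upstream_intron")) hi <- hi - 22L
        if (identical(m$window, "exon")) { lo <- lo + 4L; hi <- hi - 4L }
        if (hi <= lo) { planted[i, k] <- FALSE; next }
        at <- sample(seq(lo, hi), 1L)
        s <- els[[i]]$variable_region
        els[[i]]$variable_region <- paste0(
          substring(s, 1L, at), inst[j], substring(s, at + w + 1L))
      }
    }
  })
  attr(els, "planted") <- planted
  els
}
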