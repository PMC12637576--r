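## Minigene library construction: exon filtering, intron trimming,
## barcode assignment and saturation mutagenesis.

#' Create an exon candidate table
#'
#' @param id Character vector of candidate ids.
#' @param exon_seq,upstream_intron,downstream_intron DNA strings (5'->3'
#'   on the transcribed strand).
#' @param chrom,start,end,strand Optional genome coordinates (1-based
#'   inclusive).
#' @return data.frame of class `exon_candidates`.
#' @export
exon_candidates <- function(id, exon_seq, upstream_intron, downstream_intron,
                            chrom = NA_character_, start = NA_integer_,
                            end = NA_integer_, strand = NA_character_) {
  df <- data.frame(id = id, exon_seq = toupper(exon_seq),
                   upstream_intron = toupper(upstream_intron),
                   downstream_intron = toupper(downstream_intron),
                   chrom = chrom, start = start, end = end, strand = strand,
                   stringsAsFactors = FALSE)
  bad <- !is_valid_dna(df$exon_seq) | !is_valid_dna(df$upstream_intron) |
    !is_valid_dna(df$downstream_intron)
  check_that(!any(bad), "exon_candidates: invalid DNA alphabet in: %s",
             paste(df$id[bad], collapse = ", "))
  class(df) <- c("exon_candidates", "data.frame")
  df
}

has_stop_codon <- function(exon, frame = 0L) {
  stops <- c("TAA", "TAG", "TGA")
  n <- nchar(exon)
  starts <- seq(1L + frame, n - 2L, by = 3L)
  if (length(starts) == 0 || starts[1] > n - 2L) return(FALSE)
  codons <- substring(exon, starts, starts + 2L)
  any(codons %in% stops)
}

#' Filter exon candidates for library inclusion
#'
#' Applies the library design filters: exon length within
#' `[min_len, max_len]`, no in-frame stop codon (TAA/TAG/TGA in the
#' reporter reading frame), and no restriction-site motif on either
#' strand anywhere in the variable region (upstream intron + exon +
#' downstream intron), so that internal sites cannot interfere with
#' Golden-Gate cloning. Each rejected candidate is tagged with the first
#' failing rule, checked in the order length, stop_codon,
#' restriction_site.
#'
#' @param candidates An [exon_candidates] data.frame.
#' @param min_len,max_len Exon length bounds (nt).
#' @param restriction_motifs DNA motifs screened on both strands;
#'   default the BsmBI recognition site `CGTCTC`.
#' @param frame Reading frame of the reporter relative to the exon start
#'   (0, 1 or 2).
#' @return The input with logical column `retained` and character column
#'   `reject_reason` (`NA` for retained rows). Row order is preserved.
#' @export
filter_exons <- function(candidates, min_len = 10, max_len = 120,
                         restriction_motifs = "CGTCTC", frame = 0L) {
  check_that(nrow(candidates) > 0, "filter_exons: no candidates supplied")
  exon <- candidates$exon_seq
  len <- nchar(exon)
  variable <- paste0(candidates$upstream_intron, exon,
                     candidates$downstream_intron)
  motifs <- unique(c(restriction_motifs, revcomp(restriction_motifs)))
  hits_site <- Reduce(`|`, lapply(motifs, function(m) {
    grepl(m, variable, fixed = TRUE)
  }))
  reason <- rep(NA_character_, length(exon))
  reason[len < min_len | len > max_len] <- "length"
  stop_hit <- vapply(exon, has_stop_codon, logical(1), frame = frame)
  reason[is.na(reason) & stop_hit] <- "stop_codon"
  reason[is.na(reason) & hits_site] <- "restriction_site"
  out <- candidates
  out$retained <- is.na(reason)
  out$reject_reason <- reason
  out
}

#' Fit the constitutive-skipping pre-filter
#'
#' Fits a two-feature logistic regression (donor score, acceptor score)
#' on a pilot set of exons labelled `always_skipped` (PSI < 0.05) or
#' `always_included` (PSI >= 0.95), and picks the probability threshold
#' that maximises balanced accuracy on the pilot. Elements whose
#' predicted inclusion probability falls below the threshold are flagged
#' as predicted constitutively skipped and excluded from library
#' synthesis.
#'
#' @param donor,acceptor Numeric splice-site strength scores from any
#'   [SpliceStrengthScorer][pwm_splice_scorer] implementation.
#' @param label Factor/character with levels `always_skipped` /
#'   `always_included`.
#' @return List of class `skip_filter`: `model` (a `glm`), `threshold`,
#'   `balanced_accuracy` (training), and `predict(donor, acceptor)`
#'   giving inclusion probabilities.
#' @export
fit_skip_filter <- function(donor, acceptor, label) {
  label <- as.character(label)
  check_that(all(label %in% c("always_skipped", "always_included")),
             "fit_skip_filter: labels must be always_skipped/always_included")
  check_that(length(unique(label)) == 2,
             "fit_skip_filter: both classes must be present in the pilot set")
  y <- as.integer(label == "always_included")
  df <- data.frame(y = y, donor = donor, acceptor = acceptor)
  model <- suppressWarnings(stats::glm(y ~ donor + acceptor, data = df,
                                       family = stats::binomial()))
  p <- stats::fitted(model)
  ## threshold maximising balanced accuracy over the observed probabilities
  cand <- sort(unique(c(0, p, 1)))
  bacc <- vapply(cand, function(th) {
    pred <- as.integer(p >= th)
    sens <- if (any(y == 1)) mean(pred[y == 1] == 1) else NA_real_
    spec <- if (any(y == 0)) mean(pred[y == 0] == 0) else NA_real_
    (sens + spec) / 2
  }, numeric(1))
  threshold <- cand[which.max(bacc)]
  out <- list(model = model, threshold = threshold,
              balanced_accuracy = max(bacc),
              predict = function(donor, acceptor) {
                as.numeric(stats::predict(model,
                                          newdata = data.frame(donor = donor,
                                                               acceptor = acceptor),
                                          type = "response"))
              })
  class(out) <- "skip_filter"
  out
}

#' Construct a minigene element from an exon candidate
#'
#' Trims the flanking introns so that the variable region (upstream
#' intron + exon + downstream intron) has a fixed total length while
#' preserving minimum exon-proximal intron lengths: the downstream
#' intron is fixed at its minimum and the remainder of the budget is
#' allocated upstream, which preserves branch point and polypyrimidine
#' tract context. Trimming removes only exon-distal intronic sequence.
#' Exons too long to satisfy both minima within `total_len` keep the
#' minima and exceed the total, with `over_budget = TRUE`.
#'
#' @param candidate One row of an [exon_candidates] table (data.frame
#'   with the same columns).
#' @param total_len Target variable-region length (nt).
#' @param min_up,min_down Minimum retained intron lengths (nt).
#' @return List of class `minigene_element` with fields `id`,
#'   `variable_region`, `exon_interval` (0-based half-open within the
#'   variable region), `barcode` (`NA` until assigned), `provenance`
#'   (`"parent"`), and `over_budget`.
#' @export
construct_element <- function(candidate, total_len = 215, min_up = 75,
                              min_down = 30) {
  exon <- candidate$exon_seq
  up <- candidate$upstream_intron
  down <- candidate$downstream_intron
  exon_len <- nchar(exon)
  check_that(nchar(up) >= min_up,
             "construct_element [%s]: insufficient flank (upstream %d < %d)",
             candidate$id, nchar(up), min_up)
  check_that(nchar(down) >= min_down,
             "construct_element [%s]: insufficient flank (downstream %d < %d)",
             candidate$id, nchar(down), min_down)
  up_target <- total_len - exon_len - min_down
  over <- up_target < min_up
  if (over) up_target <- min_up
  check_that(nchar(up) >= up_target,
             "construct_element [%s]: insufficient flank (upstream %d < %d needed)",
             candidate$id, nchar(up), up_target)
  ## keep the exon-proximal ends: 3' end of the upstream intron, 5' end
  ## of the downstream intron
  up_trim <- substring(up, nchar(up) - up_target + 1L, nchar(up))
  down_trim <- substring(down, 1L, min_down)
  el <- list(id = candidate$id,
             variable_region = paste0(up_trim, exon, down_trim),
             exon_interval = c(start = up_target, end = up_target + exon_len),
             barcode = NA_character_,
             provenance = "parent",
             over_budget = over)
  class(el) <- "minigene_element"
  el
}

#' @export
print.minigene_element <- function(x, ...) {
  cat(sprintf("<minigene_element> %s: %d nt, exon [%d, %d), barcode %s%s\n",
              x$id, nchar(x$variable_region),
              x$exon_interval[1], x$exon_interval[2],
              ifelse(is.na(x$barcode), "<unassigned>", x$barcode),
              if (isTRUE(x$over_budget)) " [over budget]" else ""))
  invisible(x)
}

#' Assign barcodes from a validated whitelist
#'
#' Draws 14-nt barcodes without replacement from a whitelist,
#' deterministically under `seed`.
#'
#' @param elements List of [minigene_element][construct_element]s.
#' @param whitelist Character vector of 14-nt barcodes.
#' @param seed Integer seed.
#' @return The elements with `barcode` fields filled in.
#' @export
assign_barcodes <- function(elements, whitelist, seed = 1L) {
  check_that(all(nchar(whitelist) == 14),
             "assign_barcodes: whitelist barcodes must be 14 nt")
  check_that(!anyDuplicated(whitelist),
             "assign_barcodes: whitelist contains duplicates")
  check_that(length(whitelist) >= length(elements),
             "assign_barcodes: whitelist too small (%d barcodes for %d elements)",
             length(whitelist), length(elements))
  picked <- with_seed(seed, sample(whitelist, length(elements)))
  Map(function(el, bc) { el$barcode <- bc; el }, elements, picked)
}

#' Generate a barcode whitelist
#'
#' Random distinct 14-nt barcodes; stands in for a validated barcode set.
#'
#' @param n Number of barcodes.
#' @param seed Integer seed.
#' @return Character vector of `n` distinct 14-nt barcodes.
#' @export
barcode_whitelist <- function(n, seed = 1L) {
  with_seed(seed, {
    out <- unique(random_dna(ceiling(n * 1.05) + 8, 14))
    while (length(out) < n) out <- unique(c(out, random_dna(n, 14)))
    out[seq_len(n)]
  })
}

#' Single-nucleotide saturation mutagenesis
#'
#' Enumerates every single-nucleotide substitution of a parent element
#' within a window, yielding exactly 3 variants per position. Variants
#' inherit the parent's exon interval; provenance records position
#' (0-based within the variable region), reference and alternate base.
#'
#' @param parent A [minigene_element][construct_element].
#' @param window `"full"` or an integer `c(start, end)` 0-based
#'   half-open interval within the variable region.
#' @param mask Optional integer vector of 0-based positions to skip
#'   (e.g. positions reserved for cloning).
#' @return List of `minigene_element` variants (barcodes unassigned).
#' @export
saturation_mutagenesis <- function(parent, window = "full", mask = integer(0)) {
  seq <- parent$variable_region
  n <- nchar(seq)
  if (identical(window, "full")) window <- c(0L, n)
  check_that(window[1] >= 0 && window[2] <= n && window[2] > window[1],
             "saturation_mutagenesis: empty or out-of-bounds window")
  positions <- setdiff(seq(window[1], window[2] - 1L), as.integer(mask))
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  out <- vector("list", 3L * length(positions))
  k <- 0L
  for (pos in positions) {
    ref <- bases[pos + 1L]
    for (alt in setdiff(DNA_BASES, ref)) {
      k <- k + 1L
      mut <- bases
      mut[pos + 1L] <- alt
      el <- parent
      el$id <- sprintf("%s_p%d%s>%s", parent$id, pos, ref, alt)
      el$variable_region <- paste(mut, collapse = "")
      el$barcode <- NA_character_
      el$provenance <- sprintf("%s:%d:%s:%s", parent$id, pos, ref, alt)
      out[[k]] <- el
    }
  }
  out
}

#' Trivial PWM-based splice-site strength scorer
#'
#' A deterministic donor/acceptor scorer satisfying the
#' `SpliceStrengthScorer` interface: log-odds of a fixed consensus PWM
#' versus uniform background over a window anchored at the splice site
#' (donor: 3 exonic + 6 intronic positions; acceptor: 20 intronic + 3
#' exonic). Any external splice-site model exposing
#' `score_donor(sequence, pos)` / `score_acceptor(sequence, pos)` can be
#' used in its place.
#'
#' @return List with functions `score_donor(sequence, pos)` and
#'   `score_acceptor(sequence, pos)`, where `pos` is the 0-based
#'   position of the first intronic base (donor) or the 0-based position
#'   just past the intron (acceptor, i.e. the exon start).
#' @export
pwm_splice_scorer <- function() {
  donor_pwm <- donor_consensus_pwm()
  acceptor_pwm <- acceptor_consensus_pwm()
  score_window <- function(sequence, start0, pwm) {
    w <- ncol(pwm)
    sub <- substring(sequence, start0 + 1L, start0 + w)
    if (nchar(sub) < w || !is_valid_dna(sub)) return(NA_real_)
    b <- strsplit(sub, "", fixed = TRUE)[[1]]
    sum(log2(pmax(pwm[cbind(match(b, DNA_BASES), seq_len(w))], 1e-6) / 0.25))
  }
  list(
    score_donor = function(sequence, pos) {
      score_window(sequence, pos - 3L, donor_pwm)
    },
    score_acceptor = function(sequence, pos) {
      score_window(sequence, pos - 20L, acceptor_pwm)
    }
  )
}

## Donor consensus (exon)MAG | GTRAGT(intron): 9 columns, -3..+6
donor_consensus_pwm <- function() {
  cols <- list(
    c(A = .33, C = .36, G = .18, T = .13),  # -3
    c(A = .60, C = .13, G = .14, T = .13),  # -2
    c(A = .09, C = .04, G = .79, T = .08),  # -1
    c(A = .00, C = .00, G = 1.0, T = .00),  # +1 G
    c(A = .00, C = .00, G = .00, T = 1.0),  # +2 T
    c(A = .52, C = .03, G = .42, T = .03),  # +3
    c(A = .71, C = .08, G = .12, T = .09),  # +4
    c(A = .07, C = .06, G = .81, T = .06),  # +5
    c(A = .16, C = .15, G = .19, T = .50)   # +6
  )
  do.call(cbind, cols)
}

## Acceptor consensus: polypyrimidine tract then NCAG | (exon): 23 cols,
## -20..+3 (last 3 exonic)
acceptor_consensus_pwm <- function() {
  py <- c(A = .10, C = .31, G = .10, T = .49)
  cols <- c(rep(list(py), 15),
            list(py,                                      # -5
                 c(A = .25, C = .30, G = .20, T = .25),   # -4 N
                 c(A = .05, C = .75, G = .05, T = .15),   # -3 C
                 c(A = .97, C = .01, G = .01, T = .01),   # -2 A
                 c(A = .01, C = .01, G = .97, T = .01),   # -1 G (intron end)
                 c(A = .28, C = .14, G = .47, T = .11),   # +1 first exon base
                 c(A = .25, C = .25, G = .25, T = .25),
                 c(A = .25, C = .25, G = .25, T = .25)))
  do.call(cbind, cols)
}
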