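## Quantification of barcoded paired-end splicing amplicon reads:
## barcode/UMI extraction, junction-aware isoform classification, UMI
## deduplication, chimeric-read correction, PSI and log-ratio matrices,
## and replicate-level differential splicing.

#' Reporter context for junction classification
#'
#' The minigene reporter places the variable region between two constant
#' exons; read 1 spans the exon-exon junctions of the spliced
#' transcript. This object carries the constant exon sequences and the
#' read-1 layout needed to build and classify junction reads.
#'
#' @param upstream_exon,downstream_exon Constant exon sequences.
#' @param anchor_len Number of constant-exon bases at the start/end of
#'   read 1 (read 1 begins with the last `anchor_len` nt of the upstream
#'   constant exon).
#' @param read1_len,read2_len Read lengths (nt).
#' @return List of class `reporter_context`.
#' @export
reporter_context <- function(upstream_exon = NULL, downstream_exon = NULL,
                             anchor_len = 30L, read1_len = 217L,
                             read2_len = 60L) {
  if (is.null(upstream_exon))
    upstream_exon <- "GATCCTGAAGATCGTCCTGAGCTTCCAGAGGATCGAAGCTGTCAATGGCCAAGACCCAG"
  if (is.null(downstream_exon))
    downstream_exon <- "GTTCGAGAAGCTGGTCAACCGCATCGACACCATGATCACCAAGCTGAACTCCGACTTGG"
  check_that(nchar(upstream_exon) >= anchor_len &&
               nchar(downstream_exon) >= anchor_len,
             "reporter_context: constant exons shorter than anchor_len")
  out <- list(upstream_exon = upstream_exon, downstream_exon = downstream_exon,
              anchor_len = as.integer(anchor_len),
              read1_len = as.integer(read1_len),
              read2_len = as.integer(read2_len))
  class(out) <- "reporter_context"
  out
}

up_anchor <- function(reporter) {
  substring(reporter$upstream_exon,
            nchar(reporter$upstream_exon) - reporter$anchor_len + 1L)
}
down_anchor <- function(reporter) {
  substring(reporter$downstream_exon, 1L, reporter$anchor_len)
}

## Spliced read-1 sequences implied by an element, truncated to read1_len
included_read1 <- function(element, reporter) {
  exon <- substring(element$variable_region,
                    element$exon_interval[1] + 1L, element$exon_interval[2])
  substring(paste0(up_anchor(reporter), exon, down_anchor(reporter)),
            1L, reporter$read1_len)
}
skipped_read1 <- function(reporter) {
  substring(paste0(up_anchor(reporter), down_anchor(reporter)),
            1L, reporter$read1_len)
}
cryptic_read1 <- function(element, reporter, donor_pos, acceptor_pos = NULL) {
  ## spliced segment runs from acceptor_pos (default: annotated exon
  ## start) to donor_pos, both 0-based in variable-region coordinates
  if (is.null(acceptor_pos)) acceptor_pos <- element$exon_interval[1]
  seg <- substring(element$variable_region, acceptor_pos + 1L, donor_pos)
  substring(paste0(up_anchor(reporter), seg, down_anchor(reporter)),
            1L, reporter$read1_len)
}

#' Extract barcode and UMI from read 2
#'
#' Read 2 carries a 14-nt element barcode followed by a 10-nt UMI.
#' Barcodes are matched against a whitelist, exactly or within
#' `max_mismatch` of a unique whitelist entry; reads with ambiguous
#' (equidistant) or unmatched barcodes are dropped.
#'
#' @param read2 Character vector of read-2 sequences (length >= 24).
#' @param whitelist Character vector of 14-nt barcodes.
#' @param max_mismatch Maximum Hamming distance for rescue (default 1).
#' @return List: `index` (whitelist index per read, `NA` = dropped),
#'   `umi` (10-nt string per read), and `dropped` counts by reason
#'   (`short`, `no_match`, `ambiguous`).
#' @export
extract_barcode_umi <- function(read2, whitelist, max_mismatch = 1L) {
  n <- length(read2)
  idx <- rep(NA_integer_, n)
  short <- nchar(read2) < 24L
  bc <- substring(read2, 1L, 14L)
  umi <- substring(read2, 15L, 24L)
  idx[!short] <- match(bc[!short], whitelist)
  n_ambig <- 0L
  if (max_mismatch > 0L) {
    todo <- which(!short & is.na(idx))
    if (length(todo)) {
      ## work per unique unmatched barcode against a char matrix of the
      ## whitelist; one column comparison per barcode
      wl_mat <- do.call(cbind, strsplit(whitelist, "", fixed = TRUE))
      ubc <- unique(bc[todo])
      res <- vapply(ubc, function(b) {
        d <- colSums(wl_mat != strsplit(b, "", fixed = TRUE)[[1]])
        dmin <- min(d)
        if (dmin > max_mismatch) return(NA_integer_)
        hits <- which(d == dmin)
        if (length(hits) > 1L) return(-1L)  # ambiguous
        hits
      }, integer(1))
      mapped <- res[match(bc[todo], ubc)]
      n_ambig <- sum(mapped == -1L, na.rm = TRUE)
      mapped[!is.na(mapped) & mapped == -1L] <- NA_integer_
      idx[todo] <- mapped
    }
  }
  list(index = idx, umi = umi,
       dropped = c(short = sum(short),
                   no_match = sum(!short & is.na(idx)) - n_ambig,
                   ambiguous = n_ambig))
}

#' Classify read-1 sequences against one element
#'
#' Junction-aware classification: a read is `included` when it contains
#' both junction k-mers of the included isoform (upstream constant exon
#' to library exon, and library exon to downstream constant exon);
#' `skipped` when it contains the upstream-to-downstream constant
#' junction k-mer; otherwise a cryptic junction is resolved by exact
#' anchored matching of the spliced middle segment back into the element
#' reference, reporting the breakpoint pair; unresolvable reads are
#' `unassigned`.
#'
#' @param read1 Character vector of read-1 sequences.
#' @param element A [minigene_element][construct_element].
#' @param reporter A [reporter_context()].
#' @param anchor_k Junction k-mer length (split evenly across the
#'   junction; default 12).
#' @param require_gt_ag Require canonical GT/AG dinucleotides at
#'   inferred cryptic breakpoints (default TRUE).
#' @return data.frame with `call` (included/skipped/cryptic/unassigned),
#'   `donor_pos`, `acceptor_pos` (0-based variable-region coordinates,
#'   `NA` for annotated/constant boundaries).
#' @export
classify_reads <- function(read1, element, reporter, anchor_k = 12L,
                           require_gt_ag = TRUE) {
  half <- anchor_k %/% 2L
  ua <- up_anchor(reporter)
  da <- down_anchor(reporter)
  exon <- substring(element$variable_region,
                    element$exon_interval[1] + 1L, element$exon_interval[2])
  j_up <- paste0(substring(ua, nchar(ua) - half + 1L),
                 substring(exon, 1L, half))
  j_down <- paste0(substring(exon, nchar(exon) - half + 1L),
                   substring(da, 1L, half))
  j_skip <- paste0(substring(ua, nchar(ua) - half + 1L),
                   substring(da, 1L, half))
  call <- rep("unassigned", length(read1))
  donor <- rep(NA_integer_, length(read1))
  acceptor <- rep(NA_integer_, length(read1))
  inc <- grepl(j_up, read1, fixed = TRUE) & grepl(j_down, read1, fixed = TRUE)
  skp <- !inc & grepl(j_skip, read1, fixed = TRUE)
  call[inc] <- "included"
  call[skp] <- "skipped"
  ## cryptic resolution for the remainder: read = up_anchor + element[a, d) +
  ## down_anchor; recover (a, d) by exact match of the middle segment
  rest <- which(!inc & !skp)
  if (length(rest)) {
    A <- nchar(ua)
    for (i in rest) {
      r <- read1[i]
      if (substring(r, 1L, A) != ua) next
      body <- substring(r, A + 1L)
      ## strip the downstream constant anchor (may be truncated by read length)
      dlen <- min(nchar(da), nchar(body) - 1L)
      hit <- FALSE
      while (dlen > half && !hit) {
        if (substring(body, nchar(body) - dlen + 1L) ==
            substring(da, 1L, dlen)) hit <- TRUE else dlen <- dlen - 1L
      }
      if (!hit) next
      mid <- substring(body, 1L, nchar(body) - dlen)
      if (nchar(mid) < 1L) next
      a0 <- regexpr(mid, element$variable_region, fixed = TRUE)[1]
      if (a0 < 0) next
      a <- a0 - 1L                      # 0-based segment start
      d <- a + nchar(mid)               # 0-based position past segment end
      if (require_gt_ag) {
        gt_ok <- d == element$exon_interval[2] ||
          substring(element$variable_region, d + 1L, d + 2L) == "GT"
        ag_ok <- a == element$exon_interval[1] ||
          (a >= 2L && substring(element$variable_region, a - 1L, a) == "AG")
        if (!gt_ok || !ag_ok) next
      }
      call[i] <- "cryptic"
      donor[i] <- d
      acceptor[i] <- a
    }
  }
  data.frame(call = call, donor_pos = donor, acceptor_pos = acceptor,
             stringsAsFactors = FALSE)
}

#' UMI deduplication and isoform counting
#'
#' Collapses read-level assignments to one count per distinct
#' (element, UMI) pair within each sample. When one UMI is seen with
#' conflicting isoform calls, the majority call wins; exact ties drop
#' the UMI.
#'
#' @param assignments data.frame with columns `sample`, `element`,
#'   `umi`, `call` (one row per read; `unassigned` rows are ignored).
#' @return data.frame of class `isoform_counts` with one row per
#'   (sample, element): `included`, `skipped`, `cryptic` UMI counts.
#' @export
dedup_and_count <- function(assignments) {
  sel <- assignments$call %in% c("included", "skipped", "cryptic")
  a <- assignments[sel, , drop = FALSE]
  if (nrow(a) == 0) {
    res <- data.frame(sample = character(), element = character(),
                      included = integer(), skipped = integer(),
                      cryptic = integer(), stringsAsFactors = FALSE)
    class(res) <- c("isoform_counts", "data.frame")
    return(res)
  }
  ## one vote per read, grouped by (sample, element, umi); vectorised
  ## majority with ties dropped
  key <- paste(a$sample, a$element, a$umi, sep = "\r")
  ukey <- unique(key)
  g <- match(key, ukey)
  ng <- length(ukey)
  n_inc <- tabulate(g[a$call == "included"], ng)
  n_skp <- tabulate(g[a$call == "skipped"], ng)
  n_cry <- tabulate(g[a$call == "cryptic"], ng)
  best <- pmax(n_inc, n_skp, n_cry)
  runner <- pmax(pmin(n_inc, n_skp),
                 pmin(pmax(n_inc, n_skp), n_cry))
  keep <- best > runner                 # strict majority; ties dropped
  call <- character(ng)
  call[n_inc == best] <- "included"
  call[n_skp == best] <- "skipped"
  call[n_cry == best] <- "cryptic"
  first <- !duplicated(key)
  grp_sample <- a$sample[first]
  grp_element <- a$element[first]
  ## aggregate UMI-level calls per (sample, element)
  key2 <- paste(grp_sample, grp_element, sep = "\r")[keep]
  ukey2 <- unique(key2)
  g2 <- match(key2, ukey2)
  n2 <- length(ukey2)
  cc <- call[keep]
  first2 <- !duplicated(key2)
  res <- data.frame(sample = grp_sample[keep][first2],
                    element = grp_element[keep][first2],
                    included = tabulate(g2[cc == "included"], n2),
                    skipped = tabulate(g2[cc == "skipped"], n2),
                    cryptic = tabulate(g2[cc == "cryptic"], n2),
                    stringsAsFactors = FALSE)
  res <- res[order(res$sample, res$element), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("isoform_counts", "data.frame")
  res
}

#' Chimeric read correction
#'
#' Barcode swapping during pooled amplification attaches a read-1
#' molecule to the wrong barcode. Correction acts at three levels:
#' \enumerate{
#'   \item Read-level drop: reads whose read-1 sequence identifies a
#'     library element (included/cryptic reads contain library exon
#'     sequence) that disagrees with the barcode-implied element are
#'     discarded.
#'   \item Barcode-level removal: a barcode whose identity-resolved
#'     reads contain a *concentrated* foreign identity -- a single other
#'     element accounting for more than `1 - purity` of resolved reads
#'     -- is removed entirely, as this indicates a barcode collision
#'     rather than diffuse swapping (a 50/50 mixed barcode is removed;
#'     a barcode with a few percent of swaps spread across the library
#'     is kept).
#'   \item Count-level debiasing (applied downstream, see
#'     [quantify_reads()]): skipped chimeric reads carry no
#'     element-identifying sequence and cannot be dropped individually,
#'     so their expected count is estimated from the observed discordant
#'     (identifiable) chimeras and the pool's inclusion fraction, and
#'     subtracted from the skipped count.
#' }
#'
#' @param assignments data.frame with columns `sample`, `element` (from
#'   the barcode), `umi`, `call`, and `read1_element` (element
#'   identified from read 1; `NA` when unresolvable, e.g. skipped
#'   reads).
#' @param purity Purity threshold: a single foreign identity exceeding
#'   `1 - purity` of a barcode's resolved reads removes the barcode
#'   (default 0.9).
#' @return Cleaned assignments (same columns), with attributes
#'   `n_dropped_reads`, `removed_barcodes`, and `discordant_umis` (a
#'   data.frame of UMI-deduplicated discordant read counts per
#'   (sample, element), used for count-level debiasing).
#' @export
correct_chimeras <- function(assignments, purity = 0.9) {
  resolved <- !is.na(assignments$read1_element)
  concordant <- resolved & assignments$read1_element == assignments$element
  discordant <- resolved & !concordant
  key <- paste(assignments$sample, assignments$element, sep = "\r")
  ukey <- unique(key)
  g <- match(key, ukey)
  n_res <- tabulate(g[resolved], length(ukey))
  ## largest single foreign identity per barcode
  fkey <- paste(key[discordant], assignments$read1_element[discordant],
                sep = "\r")
  max_foreign <- rep(0L, length(ukey))
  if (length(fkey)) {
    ft <- table(fkey)
    fg <- match(sub("\r[^\r]*$", "", names(ft)), ukey)
    max_foreign <- as.integer(tapply(as.integer(ft), factor(fg, seq_along(ukey)),
                                     max, default = 0L))
    max_foreign[is.na(max_foreign)] <- 0L
  }
  bad <- n_res > 0 & max_foreign / pmax(n_res, 1L) > (1 - purity)
  bad_bc <- ukey[bad]
  ## UMI-deduplicated discordant counts (for skipped-side debiasing)
  disc <- assignments[discordant, c("sample", "element", "umi")]
  disc_umis <- if (nrow(disc)) {
    dk <- unique(paste(disc$sample, disc$element, disc$umi, sep = "\r"))
    dk2 <- sub("\r[^\r]*$", "", dk)
    tt <- table(dk2)
    parts <- strsplit(names(tt), "\r", fixed = TRUE)
    data.frame(sample = vapply(parts, `[`, "", 1L),
               element = vapply(parts, `[`, "", 2L),
               discordant = as.integer(tt), stringsAsFactors = FALSE)
  } else {
    data.frame(sample = character(), element = character(),
               discordant = integer(), stringsAsFactors = FALSE)
  }
  keep <- !discordant & !(key %in% bad_bc)
  out <- assignments[keep, , drop = FALSE]
  attr(out, "n_dropped_reads") <- sum(!keep)
  attr(out, "removed_barcodes") <- bad_bc
  attr(out, "discordant_umis") <- disc_umis
  out
}

#' Identify elements from read-1 sequence
#'
#' Builds a lookup from the exon-start k-mer that follows the upstream
#' constant anchor in included reads, and applies it to a read vector.
#' Elements whose exon-start k-mers collide are unresolvable and map to
#' `NA`.
#'
#' @param read1 Character vector of read-1 sequences.
#' @param elements List of minigene elements.
#' @param reporter A [reporter_context()].
#' @param k K-mer length (default 12).
#' @return Character vector of element ids (`NA` where unresolved).
#' @export
read1_element_identity <- function(read1, elements, reporter, k = 12L) {
  A <- reporter$anchor_len
  kmers <- vapply(elements, function(el) {
    substring(el$variable_region, el$exon_interval[1] + 1L,
              el$exon_interval[1] + k)
  }, character(1))
  ids <- vapply(elements, `[[`, "", "id")
  dup <- kmers %in% kmers[duplicated(kmers)]
  lut <- ids
  lut[dup] <- NA_character_
  obs <- substring(read1, A + 1L, A + k)
  lut[match(obs, kmers)]
}

#' Percent spliced-in from isoform counts
#'
#' PSI is the ratio of included reads to the sum of included and skipped
#' reads, computed per (element, sample) after UMI deduplication.
#' Elements with fewer than `min_umis` informative UMIs in a sample are
#' masked. Cryptic-junction counts are tallied separately and excluded
#' from the PSI denominator by default.
#'
#' @param counts An [isoform_counts][dedup_and_count] data.frame.
#' @param samples data.frame mapping `sample` to `celltype` (and
#'   optionally `replicate`). If omitted, each sample is its own cell
#'   type.
#' @param min_umis Minimum included + skipped UMIs per (element, sample).
#' @param include_cryptic Count cryptic UMIs in the denominator
#'   (default FALSE).
#' @return Object of class `psi_matrix`: list with `psi` (elements x
#'   cell types, replicate-averaged), `logratio` (same shape, see
#'   [compute_logratio()]), `replicates` (elements x samples), `samples`
#'   metadata, and `cryptic_fraction` per element.
#' @export
compute_psi <- function(counts, samples = NULL, min_umis = 10L,
                        include_cryptic = FALSE) {
  check_that(nrow(counts) > 0, "compute_psi: empty count table")
  if (is.null(samples)) {
    samples <- data.frame(sample = unique(counts$sample),
                          celltype = unique(counts$sample),
                          stringsAsFactors = FALSE)
  }
  denom <- counts$included + counts$skipped +
    if (include_cryptic) counts$cryptic else 0L
  num <- counts$included
  psi_val <- ifelse(denom >= min_umis & denom > 0, num / denom, NA_real_)
  els <- sort(unique(counts$element))
  smp <- samples$sample
  rep_mat <- matrix(NA_real_, length(els), length(smp),
                    dimnames = list(els, smp))
  rep_mat[cbind(match(counts$element, els), match(counts$sample, smp))] <- psi_val
  cts <- unique(samples$celltype)
  psi <- sapply(cts, function(ct) {
    rowMeans(rep_mat[, smp[samples$celltype == ct], drop = FALSE], na.rm = TRUE)
  })
  psi[is.nan(psi)] <- NA_real_
  psi <- matrix(psi, nrow = length(els), dimnames = list(els, cts))
  lr <- matrix(psi_to_logratio(psi), nrow = nrow(psi), dimnames = dimnames(psi))
  tot_cry <- tapply(counts$cryptic, counts$element, sum)[els]
  tot_all <- tapply(counts$included + counts$skipped + counts$cryptic,
                    counts$element, sum)[els]
  out <- list(psi = psi, logratio = lr, replicates = rep_mat,
              samples = samples,
              cryptic_fraction = as.numeric(tot_cry) /
                pmax(as.numeric(tot_all), 1))
  class(out) <- "psi_matrix"
  out
}

#' @export
print.psi_matrix <- function(x, ...) {
  cat(sprintf("<psi_matrix> %d elements x %d cell types (%d samples); %.1f%% masked\n",
              nrow(x$psi), ncol(x$psi), ncol(x$replicates),
              100 * mean(is.na(x$psi))))
  invisible(x)
}

#' Normalised log-ratio of inclusion to exclusion counts
#'
#' Scales the (included, skipped) counts of each element to a total of
#' 1,000 reads and returns `log2((I' + 1) / (E' + 1))`. The log-ratio is
#' approximately normal, unlike PSI, which makes it the working scale
#' for modelling; [logratio_to_psi()] is its exact inverse.
#'
#' @param included,skipped Non-negative counts (vectors).
#' @return Numeric vector of log-ratios; `NA` where `I + E = 0`.
#' @export
compute_logratio <- function(included, skipped) {
  tot <- included + skipped
  ip <- 1000 * included / tot
  ep <- 1000 * skipped / tot
  ifelse(tot > 0, log2((ip + 1) / (ep + 1)), NA_real_)
}

#' Convert PSI to the normalised log-ratio scale
#' @param psi PSI values in \[0, 1\].
#' @return Log-ratios `log2((1000 psi + 1) / (1000 (1 - psi) + 1))`.
#' @export
psi_to_logratio <- function(psi) {
  log2((1000 * psi + 1) / (1000 * (1 - psi) + 1))
}

#' Convert normalised log-ratios back to PSI
#'
#' Exact inverse of [psi_to_logratio()]: solves
#' `I' = (1001 * 2^L - 1) / (1 + 2^L)` and returns `I' / 1000`.
#' @param logratio Log-ratio values.
#' @return PSI values in \[0, 1\].
#' @export
logratio_to_psi <- function(logratio) {
  ip <- (1001 * 2^logratio - 1) / (1 + 2^logratio)
  ip / 1000
}

#' Differential splicing between two groups of replicates
#'
#' Per element, computes `dpsi = mean(A) - mean(B)` and a Welch t-test
#' on logit-transformed replicate PSIs, with Benjamini-Hochberg
#' correction across elements. Significance requires
#' `|dpsi| > dpsi_min` and `FDR < fdr_max`. Any test producing
#' per-element p-values can be substituted via `test_fun`.
#'
#' @param psi_a,psi_b Numeric matrices, elements x replicates (rownames
#'   are element ids and must agree).
#' @param dpsi_min,fdr_max Significance thresholds.
#' @param test_fun Function `(a, b) -> p-value` applied to logit-PSI
#'   replicate vectors; default Welch.
#' @return data.frame: `element`, `dpsi`, `p`, `fdr`, `significant`.
#' @export
call_differential <- function(psi_a, psi_b, dpsi_min = 0.1, fdr_max = 0.05,
                              test_fun = NULL) {
  check_that(ncol(psi_a) >= 2 && ncol(psi_b) >= 2,
             "call_differential: need >= 2 replicates per group")
  check_that(identical(rownames(psi_a), rownames(psi_b)),
             "call_differential: element sets must agree")
  if (is.null(test_fun)) {
    test_fun <- function(a, b) {
      if (stats::sd(c(a, b)) < 1e-12) return(1)
      tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
    }
  }
  eps <- 1e-3
  la <- logit(pmin(pmax(psi_a, eps), 1 - eps))
  lb <- logit(pmin(pmax(psi_b, eps), 1 - eps))
  p <- vapply(seq_len(nrow(psi_a)), function(i) {
    a <- la[i, !is.na(la[i, ])]
    b <- lb[i, !is.na(lb[i, ])]
    if (length(a) < 2 || length(b) < 2) return(NA_real_)
    test_fun(a, b)
  }, numeric(1))
  dpsi <- rowMeans(psi_a, na.rm = TRUE) - rowMeans(psi_b, na.rm = TRUE)
  fdr <- stats::p.adjust(p, method = "BH")
  data.frame(element = rownames(psi_a), dpsi = dpsi, p = p, fdr = fdr,
             significant = !is.na(fdr) & abs(dpsi) > dpsi_min & fdr < fdr_max,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Position frequency / weight matrix from splice-site windows
#'
#' Builds a column-stochastic base frequency matrix over a fixed window
#' around called junctions (donor: positions -3..+6 across the
#' exon/intron boundary, 9 nt; acceptor: -20..+3, 23 nt), with an
#' optional log-odds form against a uniform background.
#'
#' @param windows Character vector of window sequences, all the same
#'   length (9 for donors, 23 for acceptors).
#' @param side `"donor"` or `"acceptor"` (controls the expected width;
#'   informational).
#' @param pseudocount Added per cell before normalisation.
#' @return List: `pfm` (4 x width, rows A/C/G/T, columns sum to 1),
#'   `logodds` (log2 pfm / 0.25), `n` sites.
#' @export
splice_site_pwm <- function(windows, side = c("donor", "acceptor"),
                            pseudocount = 0) {
  side <- match.arg(side)
  check_that(length(windows) >= 1, "splice_site_pwm: no sites supplied")
  w <- unique(nchar(windows))
  check_that(length(w) == 1, "splice_site_pwm: windows must share one width")
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(windows))
  pfm <- matrix(0, 4, w, dimnames = list(DNA_BASES, NULL))
  for (b in DNA_BASES) if (b %in% rownames(cm)) pfm[b, ] <- cm[b, ]
  pfm <- pfm + pseudocount
  pfm <- sweep(pfm, 2, colSums(pfm), "/")
  list(pfm = pfm, logodds = log2(pmax(pfm, 1e-6) / 0.25),
       n = length(windows), side = side)
}

#' Full quantification pipeline from reads to counts
#'
#' Runs barcode/UMI extraction, per-element junction classification,
#' read-1 identity resolution, optional chimera correction, and UMI
#' deduplication for one or more samples.
#'
#' @param reads data.frame with columns `sample`, `read1`, `read2` (as
#'   produced by [simulate_reads()], or read from FASTQ via
#'   [read_fastq_pairs()]).
#' @param elements List of minigene elements with assigned barcodes.
#' @param reporter A [reporter_context()].
#' @param max_mismatch Barcode rescue distance.
#' @param chimera_correction Apply [correct_chimeras()] (default TRUE).
#' @param purity Barcode purity threshold for chimera correction.
#' @return An [isoform_counts][dedup_and_count] table with attribute
#'   `qc` (drop counters).
#' @export
quantify_reads <- function(reads, elements, reporter = reporter_context(),
                           max_mismatch = 1L, chimera_correction = TRUE,
                           purity = 0.9) {
  whitelist <- vapply(elements, `[[`, "", "barcode")
  check_that(!anyDuplicated(whitelist), "quantify_reads: duplicate barcodes")
  ids <- vapply(elements, `[[`, "", "id")
  ext <- extract_barcode_umi(reads$read2, whitelist, max_mismatch)
  keep <- !is.na(ext$index)
  asg <- data.frame(sample = reads$sample[keep],
                    element = ids[ext$index[keep]],
                    umi = ext$umi[keep],
                    read1 = reads$read1[keep],
                    stringsAsFactors = FALSE)
  asg$read1_element <- read1_element_identity(asg$read1, elements, reporter)
  asg$call <- "unassigned"
  asg$donor_pos <- NA_integer_
  asg$acceptor_pos <- NA_integer_
  ## reads whose read-1 identity resolves to a different element cannot
  ## match the barcode element's junctions; skip classifying them
  discordant <- !is.na(asg$read1_element) & asg$read1_element != asg$element
  skip_ref <- skipped_read1(reporter)
  groups <- split(which(!discordant), asg$element[!discordant])
  for (id in names(groups)) {
    sel <- groups[[id]]
    el <- elements[[match(id, ids)]]
    r1 <- asg$read1[sel]
    ## fast path: exact spliced-read identity, then k-mer classification
    inc_ref <- included_read1(el, reporter)
    is_inc <- r1 == inc_ref
    is_skp <- !is_inc & r1 == skip_ref
    rest <- which(!is_inc & !is_skp)
    asg$call[sel[is_inc]] <- "included"
    asg$call[sel[is_skp]] <- "skipped"
    if (length(rest)) {
      cl <- classify_reads(r1[rest], el, reporter)
      asg$call[sel[rest]] <- cl$call
      asg$donor_pos[sel[rest]] <- cl$donor_pos
      asg$acceptor_pos[sel[rest]] <- cl$acceptor_pos
    }
  }
  ## skipped reads carry no identity; never treat them as discordant
  asg$read1_element[asg$call == "skipped"] <- NA_character_
  disc_umis <- NULL
  if (chimera_correction) {
    asg <- correct_chimeras(asg, purity = purity)
    disc_umis <- attr(asg, "discordant_umis")
  }
  counts <- dedup_and_count(asg)
  if (chimera_correction && !is.null(disc_umis) && nrow(disc_umis)) {
    counts <- debias_skipped_counts(counts, disc_umis)
  }
  attr(counts, "qc") <- list(barcode_drops = ext$dropped,
                             n_reads_in = nrow(reads),
                             n_reads_assigned = nrow(asg),
                             removed_barcodes = attr(asg, "removed_barcodes"))
  counts
}

## Subtract the expected number of chimeric skipped UMIs per barcode.
## Chimeric reads are a random sample of the pool, so for every observed
## discordant (identifiable, i.e. exon-containing) chimera there are on
## average (1 - f) / f unidentifiable skipped chimeras, where f is the
## pool's inclusion fraction in that sample.
debias_skipped_counts <- function(counts, disc_umis) {
  for (s in unique(counts$sample)) {
    cs <- counts$sample == s
    f <- sum(counts$included[cs]) /
      max(sum(counts$included[cs]) + sum(counts$skipped[cs]), 1)
    if (f <= 0 || f >= 1) next
    ds <- disc_umis[disc_umis$sample == s, , drop = FALSE]
    m <- match(paste(s, ds$element), paste(s, counts$element[cs]))
    idx <- which(cs)[m]
    ok <- !is.na(idx)
    est <- round(ds$discordant[ok] * (1 - f) / f)
    counts$skipped[idx[ok]] <- pmax(counts$skipped[idx[ok]] - est, 0L)
  }
  counts
}
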