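## Synthetic-data generators: simulation configuration, beta-mixture PSI
## matrices with planted cell-type-specific elements, expression
## profiles with a planted regulator, paired-end amplicon reads with
## UMI/chimera structure, and a ground-truth sequence-to-PSI oracle that
## gives the predictive and generative models something real to learn.

#' Simulation configuration
#'
#' Bundles the knobs shared by the synthetic-data generators. Defaults
#' describe a desk-scale splicing MPRA: a bimodal PSI landscape in which
#' most exons are near-constitutively included or skipped, triplicate
#' measurements with beta-binomial replicate noise (concentration 200,
#' which reproduces replicate correlations above ~0.8 at default
#' depth), and a small fraction of elements with one cell type's PSI
#' shifted by a large planted offset.
#'
#' @param n_elements,n_celltypes,n_replicates Positive counts.
#' @param specific_fraction Fraction of elements planted as cell-type
#'   specific, in \[0, 1).
#' @param read_depth Mean reads per element per sample.
#' @param chimera_rate Fraction of reads whose barcode is swapped to a
#'   different element, in \[0, 1).
#' @param overdispersion Beta-binomial concentration for replicate noise
#'   (larger = tighter replicates).
#' @param celltype_jitter SD of logit-scale cell-type noise around each
#'   element's base PSI.
#' @param plant_offset PSI offset applied to the planted cell type
#'   (>= 0.5).
#' @param seed Integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_elements = 200L, n_celltypes = 5L,
                       n_replicates = 3L, specific_fraction = 0.1,
                       read_depth = 1000, chimera_rate = 0,
                       overdispersion = 200, celltype_jitter = 0.25,
                       plant_offset = 0.8, seed = 1L) {
  check_that(n_elements > 0 && n_celltypes > 0 && n_replicates > 0,
             "sim_config: counts must be positive")
  check_that(specific_fraction >= 0 && specific_fraction < 1,
             "sim_config: specific_fraction must be in [0, 1)")
  check_that(chimera_rate >= 0 && chimera_rate < 1,
             "sim_config: chimera_rate must be in [0, 1)")
  check_that(plant_offset >= 0.5, "sim_config: plant_offset must be >= 0.5")
  out <- list(n_elements = as.integer(n_elements),
              n_celltypes = as.integer(n_celltypes),
              n_replicates = as.integer(n_replicates),
              specific_fraction = specific_fraction,
              read_depth = read_depth, chimera_rate = chimera_rate,
              overdispersion = overdispersion,
              celltype_jitter = celltype_jitter,
              plant_offset = plant_offset, seed = as.integer(seed))
  class(out) <- "sim_config"
  out
}

## Background PSI landscape: equal mixture of Beta(0.3, 3) and
## Beta(3, 0.3), i.e. most exons near-constitutively skipped or included
rbeta_bimodal <- function(n) {
  lo <- stats::rbeta(n, 0.3, 3)
  hi <- stats::rbeta(n, 3, 0.3)
  ifelse(stats::runif(n) < 0.5, lo, hi)
}

#' Simulate a PSI matrix with planted cell-type-specific elements
#'
#' Each element gets a base PSI drawn from a bimodal beta mixture
#' concentrated near 0 and 1; cell-type values jitter around the base on
#' the logit scale. A `specific_fraction` of elements (chosen among
#' those with extreme base PSI, where a full-range shift is possible)
#' have one cell type's PSI shifted by `plant_offset` toward the
#' opposite extreme. Replicate-level PSIs add beta noise with the
#' configured concentration.
#'
#' @param config A [sim_config()].
#' @return A [psi_matrix][compute_psi]-like object (`psi`, `logratio`,
#'   `replicates`, `samples`) with attribute `labels`: a data.frame of
#'   planted elements (`element`, `celltype`, `direction`).
#' @export
simulate_psi_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_elements
    k <- config$n_celltypes
    els <- sprintf("element_%04d", seq_len(n))
    cts <- sprintf("celltype_%02d", seq_len(k))
    base <- rbeta_bimodal(n)
    eps <- 1e-3
    base_l <- logit(pmin(pmax(base, eps), 1 - eps))
    psi <- inv_logit(matrix(base_l, n, k) +
                       matrix(stats::rnorm(n * k, 0, config$celltype_jitter),
                              n, k))
    dimnames(psi) <- list(els, cts)
    n_spec <- round(config$specific_fraction * n)
    labels <- data.frame(element = character(0), celltype = character(0),
                         direction = character(0), stringsAsFactors = FALSE)
    if (n_spec > 0) {
      ## plant on extreme-base elements, where a >= 0.5 shift both fits in
      ## [0, 1] and produces a genuinely specific profile
      extreme <- which(base < 0.2 | base > 0.8)
      check_that(length(extreme) >= n_spec,
                 "simulate_psi_matrix: too few extreme-PSI elements to plant on")
      planted <- sample(extreme, n_spec)
      ct_idx <- sample.int(k, n_spec, replace = TRUE)
      up <- base[planted] < 0.5
      target <- ifelse(up, pmin(base[planted] + config$plant_offset, 0.97),
                       pmax(base[planted] - config$plant_offset, 0.03))
      psi[cbind(planted, ct_idx)] <- target
      labels <- data.frame(element = els[planted], celltype = cts[ct_idx],
                           direction = ifelse(up, "inclusion", "exclusion"),
                           stringsAsFactors = FALSE)
    }
    ## replicate-level beta noise
    samples <- data.frame(
      sample = paste0(rep(cts, each = config$n_replicates), "_r",
                      rep(seq_len(config$n_replicates), k)),
      celltype = rep(cts, each = config$n_replicates),
      replicate = rep(seq_len(config$n_replicates), k),
      stringsAsFactors = FALSE)
    conc <- config$overdispersion
    reps <- matrix(NA_real_, n, nrow(samples), dimnames = list(els, samples$sample))
    for (j in seq_len(nrow(samples))) {
      p <- psi[, samples$celltype[j]]
      p <- pmin(pmax(p, eps), 1 - eps)
      reps[, j] <- stats::rbeta(n, p * conc, (1 - p) * conc)
    }
    out <- list(psi = psi, logratio = psi_to_logratio(psi),
                replicates = reps, samples = samples,
                cryptic_fraction = rep(0, n))
    class(out) <- "psi_matrix"
    attr(out, "labels") <- labels
    out
  })
}

#' Simulate cell-type expression profiles
#'
#' Produces a genes x cell types matrix of log-scale expression values
#' in which one designated regulator gene carries the oracle's per-cell-
#' type regulator levels exactly, and all remaining genes are i.i.d.
#' noise uncorrelated with splicing.
#'
#' @param config A [sim_config()] (supplies the seed).
#' @param oracle A [splicing_oracle()] whose `regulator_map` defines the
#'   regulator levels; its cell-type names define the columns.
#' @param n_genes Total number of genes including the regulator.
#' @return Numeric matrix (genes x cell types), non-negative, with the
#'   regulator in row `"regulator"`.
#' @export
simulate_expression <- function(config, oracle, n_genes = 50L) {
  stopifnot(inherits(oracle, "splicing_oracle"))
  lv <- oracle$regulator_map
  with_seed(derive_seed(config$seed, 211L), {
    noise <- matrix(stats::rgamma((n_genes - 1L) * length(lv),
                                  shape = 2, scale = 1),
                    n_genes - 1L, length(lv))
    expr <- rbind(regulator = lv, noise)
    rownames(expr) <- c("regulator", sprintf("gene_%03d", seq_len(n_genes - 1L)))
    colnames(expr) <- names(lv)
    expr
  })
}

#' Simulate a minigene library
#'
#' Random exon candidates (exon length drawn in 20-110 nt, flanks long
#' enough to trim) run through the real construction path
#' ([construct_element()]) and barcoded from a fresh whitelist. Splice
#' site windows are seeded with consensus donor/acceptor sequences of
#' variable strength so the oracle has signal to read.
#'
#' @param n Number of elements.
#' @param seed Integer seed.
#' @param strong_sites Fraction of elements given consensus-like splice
#'   sites (the rest get weakened sites).
#' @return List of barcoded [minigene_element][construct_element]s.
#' @export
simulate_library <- function(n, seed = 1L, strong_sites = 0.7) {
  with_seed(seed, {
    exon_len <- sample(20:110, n, replace = TRUE)
    up <- random_dna(n, 170)
    down <- random_dna(n, 60)
    exon <- random_dna(n, exon_len)
    strong <- stats::runif(n) < strong_sites
    ## overwrite splice-site-proximal bases with (possibly weakened)
    ## consensus draws
    up <- paste0(substring(up, 1, 150),
                 draw_acceptor_tail(n, strong))        # last 20 nt of intron
    exon <- ifelse(exon_len >= 6,
                   paste0(substring(exon, 1, exon_len - 3),
                          draw_donor_exonic(n, strong)),
                   exon)
    down <- paste0(draw_donor_intronic(n, strong), substring(down, 7))
    cand <- exon_candidates(sprintf("element_%04d", seq_len(n)),
                            exon, up, down)
    ## strip stop codons is irrelevant here; go straight to construction
    els <- lapply(seq_len(n), function(i) construct_element(cand[i, ]))
    assign_barcodes(els, barcode_whitelist(2L * n, seed = derive_seed(seed, 7L)),
                    seed = derive_seed(seed, 8L))
  })
}

## sample n sequences from a PWM, optionally tempered toward uniform
draw_from_pwm <- function(pwm, n, temper = rep(FALSE, n)) {
  w <- ncol(pwm)
  out <- matrix("", n, w)
  for (j in seq_len(w)) {
    p_strong <- pwm[, j]
    p_weak <- 0.6 * p_strong + 0.4 * 0.25
    strong_draw <- DNA_BASES[sample.int(4, n, TRUE, prob = p_strong)]
    weak_draw <- DNA_BASES[sample.int(4, n, TRUE, prob = p_weak)]
    out[, j] <- ifelse(temper, weak_draw, strong_draw)
  }
  apply(out, 1, paste, collapse = "")
}

draw_acceptor_tail <- function(n, strong) {
  pwm <- acceptor_consensus_pwm()[, 1:20]      # intronic part
  draw_from_pwm(pwm, n, temper = !strong)
}
draw_donor_exonic <- function(n, strong) {
  pwm <- donor_consensus_pwm()[, 1:3]
  draw_from_pwm(pwm, n, temper = !strong)
}
draw_donor_intronic <- function(n, strong) {
  pwm <- donor_consensus_pwm()[, 4:9]
  draw_from_pwm(pwm, n, temper = !strong)
}

#' Simulate paired-end amplicon reads
#'
#' Draws reads for every (element, sample) pair: read 1 is the
#' junction-spanning sequence of the included or skipped isoform
#' (Bernoulli at the replicate's PSI, which is itself beta-distributed
#' around the cell-type PSI with the configured concentration, i.e.
#' beta-binomial over UMIs), and read 2 carries the 14-nt barcode
#' followed by a 10-nt UMI sampled uniformly from 4^10 space. A
#' `chimera_rate` fraction of reads keeps read 1 but receives the
#' barcode of a different random element.
#'
#' @param elements Barcoded minigene elements (unique barcodes).
#' @param psi A `psi_matrix` (or plain elements x cell types matrix)
#'   giving the true PSI per element and cell type.
#' @param config A [sim_config()]; uses `read_depth`, `chimera_rate`,
#'   `overdispersion`, `n_replicates`, `seed`.
#' @param reporter A [reporter_context()].
#' @param celltypes Subset of cell types to simulate (default: all
#'   columns of `psi`).
#' @return data.frame with columns `sample`, `celltype`, `replicate`,
#'   `read1`, `read2`, plus generator-truth columns `true_element` and
#'   `barcode_element` (differing rows are chimeras); attribute
#'   `n_chimeric`.
#' @export
simulate_reads <- function(elements, psi, config,
                           reporter = reporter_context(),
                           celltypes = NULL) {
  if (inherits(psi, "psi_matrix")) psi <- psi$psi
  ids <- vapply(elements, `[[`, "", "id")
  barcodes <- vapply(elements, `[[`, "", "barcode")
  check_that(!anyDuplicated(barcodes), "simulate_reads: duplicate barcodes")
  check_that(all(rownames(psi) %in% ids),
             "simulate_reads: psi rows missing from library")
  if (is.null(celltypes)) celltypes <- colnames(psi)
  inc_reads <- vapply(elements, included_read1, "", reporter = reporter)
  names(inc_reads) <- ids
  skp_read <- skipped_read1(reporter)
  eps <- 1e-4
  conc <- config$overdispersion
  out <- vector("list", length(celltypes) * config$n_replicates)
  k <- 0L
  with_seed(derive_seed(config$seed, 101L), {
    for (ct in celltypes) {
      for (r in seq_len(config$n_replicates)) {
        k <- k + 1L
        n_el <- nrow(psi)
        depth <- stats::rpois(n_el, config$read_depth)
        p_ct <- pmin(pmax(psi[, ct], eps), 1 - eps)
        p_rep <- stats::rbeta(n_el, p_ct * conc, (1 - p_ct) * conc)
        n_inc <- stats::rbinom(n_el, depth, p_rep)
        el_of_read <- rep(rownames(psi), depth)
        is_inc <- unlist(lapply(seq_len(n_el), function(i) {
          v <- logical(depth[i])
          if (n_inc[i] > 0) v[seq_len(n_inc[i])] <- TRUE
          v
        }), use.names = FALSE)
        nr <- length(el_of_read)
        ord <- sample.int(nr)
        el_of_read <- el_of_read[ord]
        is_inc <- is_inc[ord]
        read1 <- ifelse(is_inc, inc_reads[el_of_read], skp_read)
        ## chimeras: keep read 1, swap the barcode to another element
        bc_el <- el_of_read
        n_chim <- stats::rbinom(1L, nr, config$chimera_rate)
        if (n_chim > 0) {
          sw <- sample.int(nr, n_chim)
          other <- sample(ids, n_chim, replace = TRUE)
          clash <- other == el_of_read[sw]
          while (any(clash)) {
            other[clash] <- sample(ids, sum(clash), replace = TRUE)
            clash <- other == el_of_read[sw]
          }
          bc_el[sw] <- other
        }
        umi <- random_umis(nr)
        read2 <- paste0(barcodes[match(bc_el, ids)], umi)
        out[[k]] <- data.frame(sample = paste0(ct, "_r", r), celltype = ct,
                               replicate = r, read1 = read1, read2 = read2,
                               true_element = el_of_read,
                               barcode_element = bc_el,
                               stringsAsFactors = FALSE)
      }
    }
  })
  res <- do.call(rbind, out)
  attr(res, "n_chimeric") <- sum(res$true_element != res$barcode_element)
  res
}

## n UMIs sampled uniformly from the 4^10 space, vectorised via base-4
## digit expansion
random_umis <- function(n, len = 10L) {
  ints <- sample.int(4^len, n, replace = TRUE) - 1L
  m <- matrix("", n, len)
  for (j in seq_len(len)) {
    m[, j] <- DNA_BASES[ints %% 4L + 1L]
    ints <- ints %/% 4L
  }
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Write paired reads to FASTQ files
#'
#' @param reads data.frame from [simulate_reads()].
#' @param prefix Output path prefix; writes `<prefix>_R1.fastq[.gz]` and
#'   `<prefix>_R2.fastq[.gz]`.
#' @param gzip Compress output.
#' @return Invisibly, the two file paths.
#' @export
write_fastq_pairs <- function(reads, prefix, gzip = FALSE) {
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  f1 <- paste0(prefix, "_R1", ext)
  f2 <- paste0(prefix, "_R2", ext)
  ids <- sprintf("@%s:%07d", reads$sample, seq_len(nrow(reads)))
  for (spec in list(list(f = f1, s = reads$read1), list(f = f2, s = reads$read2))) {
    con <- if (gzip) gzfile(spec$f, "w") else file(spec$f, "w")
    writeLines(paste(ids, spec$s, "+",
                     strrep("I", nchar(spec$s)), sep = "\n"), con)
    close(con)
  }
  invisible(c(f1, f2))
}

#' Read paired FASTQ files into the in-memory read table
#'
#' @param r1,r2 FASTQ paths (read 1 = junction read, read 2 = barcode +
#'   UMI read).
#' @param sample Sample name attached to every read.
#' @return data.frame with columns `sample`, `read1`, `read2`.
#' @export
read_fastq_pairs <- function(r1, r2, sample = "sample1") {
  s1 <- Biostrings::readDNAStringSet(r1, format = "fastq")
  s2 <- Biostrings::readDNAStringSet(r2, format = "fastq")
  check_that(length(s1) == length(s2),
             "read_fastq_pairs: mate files differ in length")
  data.frame(sample = sample, read1 = as.character(s1),
             read2 = as.character(s2), stringsAsFactors = FALSE)
}
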