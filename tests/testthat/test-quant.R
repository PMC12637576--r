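## helpers: a tiny deterministic library
tiny_library <- function(n = 4, seed = 101) {
  simulate_library(n, seed = seed)
}

test_that("barcode/UMI extraction matches exactly, rescues 1-mismatch, drops ambiguity", {
  wl <- c("AAAAAAAAAAAAAA", "CCCCCCCCCCCCCC", "GGGGGGGGGGGGGG")
  umi <- "ACGTACGTAC"
  r2 <- paste0(c(wl[1],
                 sub("^A", "T", wl[1]),   # 1 mismatch from wl[1] only
                 "TTTTTTTTTTTTTT"),       # far from everything
               umi, "GGGG")
  ext <- extract_barcode_umi(r2, wl)
  expect_equal(ext$index, c(1L, 1L, NA))
  expect_equal(ext$umi, rep(umi, 3))
  ## ambiguous: equidistant between two whitelist entries at distance 1
  wl2 <- c("AAAAAAAAAAAAAA", "CAAAAAAAAAAAAG")  # differ at pos 1 and 14
  mid <- "CAAAAAAAAAAAAA"                       # distance 1 from both
  ext2 <- extract_barcode_umi(paste0(mid, umi), wl2)
  expect_true(is.na(ext2$index))
  expect_equal(unname(ext2$dropped["ambiguous"]), 1L)
  ## short read dropped
  ext3 <- extract_barcode_umi("ACGT", wl)
  expect_equal(unname(ext3$dropped["short"]), 1L)
})

test_that("junction classification recognises included, skipped and cryptic reads", {
  els <- tiny_library()
  rep_ctx <- reporter_context()
  el <- els[[1]]
  inc <- minisplice:::included_read1(el, rep_ctx)
  skp <- minisplice:::skipped_read1(rep_ctx)
  cl <- classify_reads(c(inc, skp), el, rep_ctx)
  expect_equal(cl$call, c("included", "skipped"))
  ## cryptic donor: splice 10 nt after an internal GT inside the exon
  seqv <- el$variable_region
  es <- el$exon_interval[[1]]; ee <- el$exon_interval[[2]]
  ## engineer a GT at donor position es+10 and an exact cryptic read
  substr(seqv, es + 11, es + 12) <- "GT"
  el2 <- el; el2$variable_region <- seqv
  cread <- minisplice:::cryptic_read1(el2, rep_ctx, donor_pos = es + 10)
  cl2 <- classify_reads(cread, el2, rep_ctx)
  expect_equal(cl2$call, "cryptic")
  expect_equal(cl2$donor_pos, es + 10)
  expect_equal(cl2$acceptor_pos, es)
  ## garbage read is unassigned
  cl3 <- classify_reads(strrep("ACGT", 50), el, rep_ctx)
  expect_equal(cl3$call, "unassigned")
})

test_that("UMI dedup collapses duplicates, majority-votes, and drops ties", {
  asg <- data.frame(
    sample = "s1",
    element = c(rep("e1", 5), rep("e1", 4), rep("e1", 4), "e2"),
    umi = c(rep("U1", 5), rep("U2", 4), rep("U3", 4), "U1"),
    call = c(rep("included", 5),                      # 5 reads, one UMI
             c(rep("included", 3), "skipped"),        # majority included
             c("included", "included", "skipped", "skipped"),  # tie
             "skipped"),
    stringsAsFactors = FALSE)
  res <- dedup_and_count(asg)
  e1 <- res[res$element == "e1", ]
  expect_equal(e1$included, 2L)  # U1 + U2; U3 tie dropped
  expect_equal(e1$skipped, 0L)
  expect_equal(res[res$element == "e2", "skipped"], 1L)
})

test_that("PSI computation masks low coverage and handles zero denominators", {
  counts <- data.frame(sample = "s1", element = c("a", "b", "c", "d"),
                       included = c(30L, 0L, 3L, 0L),
                       skipped = c(10L, 50L, 2L, 0L),
                       cryptic = c(0L, 0L, 0L, 5L), stringsAsFactors = FALSE)
  class(counts) <- c("isoform_counts", "data.frame")
  pm <- compute_psi(counts, min_umis = 10L)
  expect_equal(unname(pm$psi["a", 1]), 0.75)
  expect_equal(unname(pm$psi["b", 1]), 0)
  expect_true(is.na(pm$psi["c", 1]))   # below min_umis
  expect_true(is.na(pm$psi["d", 1]))   # I + E = 0
})

test_that("log-ratio normalisation matches hand arithmetic and inverts exactly", {
  expect_equal(compute_logratio(600, 200), log2(751 / 251))
  expect_equal(compute_logratio(5, 5), 0)
  expect_equal(logratio_to_psi(0), 0.5)
  withr::with_seed(31, {
    icounts <- rpois(100, 400) + 1
    ecounts <- rpois(100, 300) + 1
    lr <- compute_logratio(icounts, ecounts)
    psi <- icounts / (icounts + ecounts)
    expect_equal(logratio_to_psi(lr), psi, tolerance = 1e-9)
    expect_equal(psi_to_logratio(psi), lr, tolerance = 1e-9)
    ## orderings agree: logratio strictly increasing in PSI
    o <- order(psi)
    expect_true(all(diff(lr[o]) > -1e-12))
  })
})

test_that("differential calling enforces the joint dPSI/FDR rule", {
  withr::with_seed(41, {
    n <- 100
    base <- rbeta(n, 2, 2)
    ## plant where a full 0.5 drop fits inside [0, 1]
    planted <- which(base > 0.55)[1:10]
    a <- sapply(1:3, function(r) pmin(pmax(base + rnorm(n, 0, 0.02), 0.001), 0.999))
    b <- a + rnorm(n * 3, 0, 0.02)
    b[planted, ] <- pmin(pmax(base[planted] - 0.5, 0.001), 0.999) +
      rnorm(30, 0, 0.02)
    b <- pmin(pmax(b, 0.001), 0.999)
    rownames(a) <- rownames(b) <- sprintf("e%03d", 1:n)
    res <- call_differential(a, b)
    expect_gte(sum(res$significant[planted]), 9)
    expect_lte(sum(res$significant[-planted]), 5)
    ## identical groups: no calls
    res0 <- call_differential(a, a)
    expect_true(all(!res0$significant))
    expect_true(all(res0$dpsi == 0))
    ## large dPSI with poor FDR is not significant
    expect_true(all(!res$significant | (abs(res$dpsi) > 0.1 & res$fdr < 0.05)))
  })
  expect_error(call_differential(matrix(1, 2, 1), matrix(1, 2, 1)),
               ">= 2 replicates")
})

test_that("splice-site PWMs are column stochastic and recover a known PWM", {
  ## all-identical donors give frequency 1 at the consensus
  pwm <- splice_site_pwm(rep("CAGGTAAGT", 100), side = "donor")
  expect_equal(unname(pwm$pfm["G", 4]), 1)
  expect_equal(unname(colSums(pwm$pfm)), rep(1, 9), tolerance = 1e-12)
  ## sampling from a known PWM recovers it within TV 0.05 per column
  truth <- minisplice:::donor_consensus_pwm()
  withr::with_seed(51, {
    sites <- minisplice:::draw_from_pwm(truth, 600)
  })
  est <- splice_site_pwm(sites, side = "donor")$pfm
  tv <- apply(abs(est - truth), 2, sum) / 2
  expect_true(all(tv < 0.05))
  expect_error(splice_site_pwm(character(0)), "no sites")
})

test_that("chimera correction keeps clean barcodes and removes collisions", {
  ## 95 concordant / 5 swapped: reads dropped, barcode kept
  asg <- data.frame(sample = "s1", element = "e1",
                    umi = sprintf("U%03d", 1:100), call = "included",
                    read1_element = c(rep("e1", 95), rep("e2", 5)),
                    stringsAsFactors = FALSE)
  cc <- correct_chimeras(asg)
  expect_equal(nrow(cc), 95)
  expect_length(attr(cc, "removed_barcodes"), 0)
  expect_equal(attr(cc, "discordant_umis")$discordant, 5L)
  ## 50/50 mixed identity: barcode removed
  asg2 <- asg
  asg2$read1_element <- rep(c("e1", "e2"), 50)
  cc2 <- correct_chimeras(asg2)
  expect_equal(nrow(cc2), 0)
  expect_equal(attr(cc2, "removed_barcodes"), "s1\re1")
  ## chimera-free input passes through unchanged
  asg3 <- asg
  asg3$read1_element <- "e1"
  cc3 <- correct_chimeras(asg3)
  expect_equal(nrow(cc3), 100)
  expect_equal(attr(cc3, "n_dropped_reads"), 0L)
})

test_that("simulated reads have the promised structure", {
  cfg <- sim_config(n_elements = 4, n_celltypes = 2, n_replicates = 1,
                    read_depth = 100, seed = 61)
  els <- tiny_library(4, seed = 61)
  psi <- matrix(c(1, 1, 0.5, 0.5, 0, 0, 1, 1), 4, 2, byrow = TRUE,
                dimnames = list(vapply(els, `[[`, "", "id"),
                                c("celltype_01", "celltype_02")))
  reads <- simulate_reads(els, psi, cfg)
  rep_ctx <- reporter_context()
  ## PSI = 1 element: every read-1 is the included junction sequence
  r_el1 <- reads[reads$true_element == rownames(psi)[1], ]
  expect_true(all(r_el1$read1 == minisplice:::included_read1(els[[1]], rep_ctx)))
  ## PSI = 0 element: every read is the skipped junction
  r_el3 <- reads[reads$true_element == rownames(psi)[3], ]
  expect_true(all(r_el3$read1 == minisplice:::skipped_read1(rep_ctx)))
  ## read 2 = barcode + 10-nt UMI
  expect_true(all(nchar(reads$read2) == 24))
  expect_equal(attr(reads, "n_chimeric"), 0L)
  ## chimera generator mislabels at roughly the requested rate
  cfg2 <- sim_config(n_elements = 4, n_celltypes = 2, n_replicates = 1,
                     read_depth = 500, chimera_rate = 0.2, seed = 61)
  reads2 <- simulate_reads(els, psi, cfg2)
  frac <- attr(reads2, "n_chimeric") / nrow(reads2)
  expect_gte(frac, 0.15)
  expect_lte(frac, 0.25)
})

test_that("same seed gives byte-identical simulations", {
  cfg <- sim_config(n_elements = 30, n_celltypes = 3, seed = 71)
  m1 <- simulate_psi_matrix(cfg)
  m2 <- simulate_psi_matrix(cfg)
  expect_identical(m1$psi, m2$psi)
  expect_identical(m1$replicates, m2$replicates)
  els <- tiny_library(3, seed = 71)
  psi <- m1$psi[1:3, ]
  rownames(psi) <- vapply(els, `[[`, "", "id")
  r1 <- simulate_reads(els, psi, cfg)
  r2 <- simulate_reads(els, psi, cfg)
  expect_identical(r1$read1, r2$read1)
  expect_identical(r1$read2, r2$read2)
})

test_that("FASTQ round trip preserves reads", {
  cfg <- sim_config(n_elements = 3, n_celltypes = 1, n_replicates = 1,
                    read_depth = 50, seed = 81)
  els <- tiny_library(3, seed = 81)
  psi <- matrix(0.5, 3, 1, dimnames = list(vapply(els, `[[`, "", "id"), "ct1"))
  reads <- simulate_reads(els, psi, cfg)
  tmp <- tempfile()
  write_fastq_pairs(reads, tmp)
  back <- read_fastq_pairs(paste0(tmp, "_R1.fastq"), paste0(tmp, "_R2.fastq"))
  expect_equal(back$read1, reads$read1)
  expect_equal(back$read2, reads$read2)
  unlink(paste0(tmp, c("_R1.fastq", "_R2.fastq")))
})
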