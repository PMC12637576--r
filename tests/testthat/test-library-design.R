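make_candidates <- function(exons, up_len = 170, down_len = 60, seed = 42) {
  withr::with_seed(seed, {
    exon_candidates(sprintf("cand_%02d", seq_along(exons)), exons,
                    random_dna(length(exons), up_len),
                    random_dna(length(exons), down_len))
  })
}

## an exon with no stop codon in frame 0 and no BsmBI site
clean_exon <- function(n_codons) paste(rep("GCA", n_codons), collapse = "")

test_that("exon filters reject by length, stop codon and restriction site", {
  cands <- make_candidates(c(
    strrep("A", 9),                        # too short
    clean_exon(10),                        # 30 nt, clean
    paste0(clean_exon(5), "TAA", clean_exon(5)),  # in-frame stop
    paste0(clean_exon(5), "CGTCTC", clean_exon(5)),  # BsmBI site
    paste0(clean_exon(5), "GAGACG", clean_exon(5)),  # BsmBI on minus strand
    strrep("GCA", 41)                      # 123 nt, too long
  ))
  res <- filter_exons(cands)
  expect_equal(res$reject_reason,
               c("length", NA, "stop_codon", "restriction_site",
                 "restriction_site", "length"))
  expect_equal(res$retained, is.na(res$reject_reason))
})

test_that("exon filtering is order independent", {
  withr::with_seed(7, {
    exons <- vapply(1:30, function(i) {
      paste(sample(c("GCA", "GGT", "TCC", "TAA", "CGT"), sample(5:35, 1),
                   replace = TRUE), collapse = "")
    }, character(1))
  })
  cands <- make_candidates(exons)
  res1 <- filter_exons(cands)
  perm <- withr::with_seed(8, sample(nrow(cands)))
  res2 <- filter_exons(cands[perm, ])
  expect_equal(res2$reject_reason, res1$reject_reason[perm])
})

test_that("stop codons are only flagged in the configured frame", {
  ## TAA at offset 1 is out of frame 0 but in frame 1
  exon <- paste0("G", "TAA", clean_exon(4), "GG")
  cands <- make_candidates(exon)
  expect_true(filter_exons(cands, frame = 0L)$retained)
  expect_false(filter_exons(cands, frame = 1L)$retained)
})

test_that("trimming yields 215-nt elements with the 75/30 intron minima", {
  ## mid-length exon: total exactly 215, downstream fixed at 30
  c80 <- make_candidates(clean_exon(27))  # 81 nt
  el <- construct_element(c80[1, ])
  expect_equal(nchar(el$variable_region), 215)
  expect_equal(unname(el$exon_interval), c(215 - 81 - 30, 215 - 30))
  ## boundary: 110-nt exon leaves exactly the 75-nt upstream minimum
  c110 <- make_candidates(substr(strrep("GCA", 37), 1, 110))
  el110 <- construct_element(c110[1, ])
  expect_equal(unname(el110$exon_interval)[1], 75)
  expect_equal(nchar(el110$variable_region), 215)
  expect_false(el110$over_budget)
})

test_that("trimming keeps exon-proximal intron bases only", {
  cand <- make_candidates(clean_exon(20))  # 60-nt exon
  el <- construct_element(cand[1, ])
  up_needed <- 215 - 60 - 30
  expect_equal(substring(el$variable_region, 1, up_needed),
               substring(cand$upstream_intron[1], 170 - up_needed + 1, 170))
  expect_equal(substring(el$variable_region, up_needed + 61, 215),
               substring(cand$downstream_intron[1], 1, 30))
})

test_that("oversized exons keep the minima and exceed the total with a flag", {
  cand <- make_candidates(strrep("GCA", 40))  # 120 nt > 110
  el <- construct_element(cand[1, ])
  expect_true(el$over_budget)
  expect_equal(nchar(el$variable_region), 120 + 75 + 30)
})

test_that("insufficient flanks are rejected", {
  cand <- exon_candidates("short_flank", clean_exon(20),
                          strrep("A", 40), strrep("T", 60))
  expect_error(construct_element(cand), "insufficient flank")
})

test_that("barcode assignment draws unique barcodes deterministically", {
  cands <- make_candidates(rep(clean_exon(20), 5))
  cands$id <- paste0("e", 1:5)
  els <- lapply(seq_len(5), function(i) construct_element(cands[i, ]))
  wl <- barcode_whitelist(20, seed = 3)
  expect_equal(nchar(wl), rep(14, 20))
  a1 <- assign_barcodes(els, wl, seed = 7)
  a2 <- assign_barcodes(els, wl, seed = 7)
  bcs <- vapply(a1, `[[`, "", "barcode")
  expect_equal(anyDuplicated(bcs), 0L)
  expect_identical(bcs, vapply(a2, `[[`, "", "barcode"))
  expect_error(assign_barcodes(els, wl[1:3]), "too small")
})

test_that("saturation mutagenesis is complete, unique and window-aware", {
  cand <- make_candidates(clean_exon(20))
  el <- construct_element(cand[1, ])
  vars <- saturation_mutagenesis(el)
  expect_length(vars, 3 * 215)
  seqs <- vapply(vars, `[[`, "", "variable_region")
  expect_equal(anyDuplicated(seqs), 0L)
  ## every variant differs from the parent at exactly one position
  d <- hamming_dist(seqs, el$variable_region)
  expect_true(all(d == 1))
  ## per position, the three non-reference alleles each occur once
  prov <- do.call(rbind, strsplit(vapply(vars, `[[`, "", "provenance"), ":"))
  expect_true(all(table(prov[, 2]) == 3))
  expect_true(all(prov[, 3] != prov[, 4]))
  ## windows and masks restrict the positions
  v2 <- saturation_mutagenesis(el, window = c(10L, 20L), mask = c(12L, 13L))
  expect_length(v2, 3 * 8)
  expect_error(saturation_mutagenesis(el, window = c(5L, 5L)), "empty")
})

test_that("mutagenesis arithmetic matches the screen design audit", {
  ## 15 parents x full 215-nt windows: 3 substitutions per position
  expect_equal(15 * 3 * 215, 9675)
  ## masking 5 positions on some parents would remove 15 variants each;
  ## with parents included the library is 15 + 9660 under one mask per parent
  expect_equal(15 + (9675 - 15), 9675)
})

test_that("the skip pre-filter separates classes and honours contracts", {
  ## perfectly separable pilot
  don <- c(rnorm(60, -3), rnorm(60, 3))
  acc <- c(rnorm(60, -2), rnorm(60, 2))
  lab <- rep(c("always_skipped", "always_included"), each = 60)
  fit <- fit_skip_filter(don, acc, lab)
  expect_equal(fit$balanced_accuracy, 1)
  p <- fit$predict(don, acc)
  expect_true(all(p >= 0 & p <= 1))
  expect_error(fit_skip_filter(don[1:60], acc[1:60], lab[1:60]),
               "both classes")
})

test_that("label-shuffled pilots give chance-level balanced accuracy", {
  withr::with_seed(21, {
    don <- rnorm(120); acc <- rnorm(120)
    bacc <- vapply(1:50, function(i) {
      lab <- sample(rep(c("always_skipped", "always_included"), each = 60))
      ## held-out evaluation: fit on half, score on the other half
      fit <- fit_skip_filter(don[1:60], acc[1:60], lab[1:60])
      p <- fit$predict(don[61:120], acc[61:120])
      y <- as.integer(lab[61:120] == "always_included")
      pred <- as.integer(p >= fit$threshold)
      (mean(pred[y == 1] == 1) + mean(pred[y == 0] == 0)) / 2
    }, numeric(1))
    expect_lt(abs(mean(bacc) - 0.5), 0.1)
  })
})
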