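test_that("effect sizes follow the parent-minus-variant convention", {
  v <- data.frame(position = c(0L, 0L, 0L, 1L, 2L, 2L, 2L),
                  alt = c("C", "G", "T", "A", "A", "C", "G"),
                  psi = c(0.2, 0.3, 0.4, 0.9, 0.2, 0.3, 0.4))
  ep <- effect_sizes(0.9, v, length = 5)
  expect_equal(unname(ep$grid[, 1]), c(0.7, 0.6, 0.5))
  expect_equal(ep$positionwise[1], 0.6)
  expect_equal(ep$positionwise[2], 0)         # variant equal to parent
  expect_true(all(is.na(ep$grid[, 4])))       # unmeasured position masked
  ## flipped sign convention
  ep2 <- effect_sizes(0.9, v, length = 5, flip_sign = TRUE)
  expect_equal(ep2$positionwise[1], -0.6)
  expect_error(effect_sizes(NA, v, length = 5), "parent PSI")
})

test_that("Gaussian smoothing matches a brute-force convolution oracle", {
  ## independent oracle: direct O(n * k) discrete convolution with
  ## reflected edges
  brute <- function(x, sigma) {
    r <- max(1, ceiling(4 * sigma))
    k <- dnorm(-r:r, sd = sigma); k <- k / sum(k)
    n <- length(x)
    xp <- c(x[(r + 1):2], x, x[(n - 1):(n - r)])
    vapply(seq_len(n), function(i) sum(xp[i:(i + 2 * r)] * rev(k)), 0)
  }
  withr::with_seed(91, {
    for (sigma in c(1, 2, 3.5)) {
      x <- rnorm(60)
      expect_equal(smooth_profile(x, sigma), brute(x, sigma),
                   tolerance = 1e-9)
    }
  })
  ## constants are invariant; an impulse keeps its mass
  expect_equal(smooth_profile(rep(2.5, 40)), rep(2.5, 40), tolerance = 1e-12)
  imp <- c(rep(0, 20), 1, rep(0, 20))
  sm <- smooth_profile(imp, sigma = 2)
  expect_equal(sum(sm), 1, tolerance = 1e-9)
  expect_equal(sm, rev(sm), tolerance = 1e-12)
  expect_error(smooth_profile(1:3), "too short")
})

test_that("region calling finds a planted bump and honours block/effect rules", {
  ## flat baseline with measurement-level noise (a perfectly constant
  ## baseline has zero IQR and is flagged degenerate instead)
  base <- withr::with_seed(90, rnorm(100, 0.02, 0.005))
  ## the z-marked run extends over the smoothing skirt (~ +/- 2 sigma),
  ## so the bump must be strong enough that the run's mean raw effect
  ## still clears the 0.25 rule
  bump <- base; bump[40:44] <- 0.8
  regions <- call_sensitive_regions(bump, z_min = 3, min_block = 3)
  expect_equal(nrow(regions), 1)
  expect_lte(regions$start, 39)
  expect_gte(regions$end, 44)
  expect_equal(regions$direction, "psi_decreasing")
  expect_gte(regions$mean_effect, 0.25)
  ## width-2 bump fails the block rule (raw profile, no smoothing blur)
  narrow <- base; narrow[50:51] <- 0.6
  r2 <- call_sensitive_regions(narrow, z_min = 3, min_block = 6)
  expect_equal(nrow(r2), 0)
  ## strong z but weak mean effect fails the effect rule
  weak <- base; weak[40:44] <- 0.15
  r3 <- call_sensitive_regions(weak, z_min = 3, min_block = 3,
                               min_mean_effect = 0.25)
  expect_equal(nrow(r3), 0)
  ## PSI-increasing bumps carry the opposite direction label
  neg <- base; neg[60:64] <- -0.8
  r4 <- call_sensitive_regions(neg)
  expect_equal(r4$direction, "psi_increasing")
})

test_that("flat profiles give no calls and degenerate baselines are flagged", {
  r <- call_sensitive_regions(rep(0.3, 80))
  expect_equal(nrow(r), 0)
  expect_true(attr(r, "degenerate"))
  withr::with_seed(92, {
    noisy_flat <- rnorm(120, 0, 0.01)
  })
  r2 <- call_sensitive_regions(noisy_flat, z_min = 3, min_block = 3)
  expect_equal(nrow(r2), 0)
})

test_that("raising the z threshold yields a subset of calls", {
  withr::with_seed(93, {
    for (i in 1:5) {
      prof <- rnorm(150, 0, 0.02)
      nb <- sample(1:3, 1)
      for (b in seq_len(nb)) {
        at <- sample(10:130, 1)
        prof[at:(at + sample(3:8, 1))] <- runif(1, 0.3, 0.8)
      }
      r3 <- call_sensitive_regions(prof, z_min = 3)
      r4 <- call_sensitive_regions(prof, z_min = 4)
      ## every z>=4 region is contained in some z>=3 region
      if (nrow(r4)) {
        contained <- vapply(seq_len(nrow(r4)), function(j) {
          any(r3$start <= r4$start[j] & r3$end >= r4$end[j])
        }, logical(1))
        expect_true(all(contained))
      }
      expect_gte(nrow(r3), nrow(r4))
    }
  })
})

test_that("PWM log-odds scanning matches the closed-form consensus score", {
  pwm <- minisplice:::consensus_pwm("TGCATGC", sharp = 0.97)
  hits <- pwm_logodds_scan("TGCATGC", list(motif = pwm), score_min = 10)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$offset, 0L)
  expect_equal(hits$score, 7 * log2(0.97 / 0.25), tolerance = 1e-9)
  ## embedded motif found at the right offset, sorted by score
  seqv <- paste0(strrep("A", 11), "TGCATGC", strrep("A", 13))
  hits2 <- pwm_logodds_scan(seqv, list(motif = pwm), score_min = 10)
  expect_equal(hits2$offset[1], 11L)
  ## infinite threshold: empty result
  expect_equal(nrow(pwm_logodds_scan(seqv, list(motif = pwm),
                                     score_min = Inf)), 0)
  expect_error(pwm_logodds_scan(seqv, list()), "empty PWM set")
})

test_that("random sequence rarely reaches a log-odds of 10 on a sharp PWM", {
  pwm <- minisplice:::consensus_pwm("TGCATGC", sharp = 0.97)
  withr::with_seed(94, {
    seqs <- random_dna(1000, 40)
  })
  nhit <- sum(vapply(seqs, function(s) {
    nrow(pwm_logodds_scan(s, list(m = pwm), score_min = 10)) > 0
  }, logical(1)))
  expect_lt(nhit / 1000, 0.01)
})

test_that("PWM files round-trip through the tab-delimited format", {
  pwm <- minisplice:::consensus_pwm("GCATG")
  f <- tempfile(fileext = ".tsv")
  write_pwm(pwm, f)
  back <- read_pwm(f)
  expect_equal(back, pwm, ignore_attr = TRUE, tolerance = 1e-12)
  unlink(f)
})

test_that("oracle-causal motif windows are recovered as sensitive regions", {
  ## plant the oracle's gated enhancer at a known window and compute the
  ## true effect profile by exhaustive oracle evaluation of all variants
  orc <- default_oracle(4, seed = 7)
  els <- simulate_oracle_library(30, orc, seed = 7, plant_fraction = 0)
  el <- els[[1]]
  win <- c(150L, 156L)
  inst <- "TGCATG"
  s <- el$variable_region
  el$variable_region <- paste0(substring(s, 1, win[1]), inst,
                               substring(s, win[1] + 7))
  ct <- names(which.max(orc$regulator_map))
  parent_psi <- oracle_psi(orc, el, ct)[1, 1]
  vars <- saturation_mutagenesis(el)
  vpsi <- oracle_psi(orc, vars, ct)[, 1]
  prov <- do.call(rbind, strsplit(vapply(vars, `[[`, "", "provenance"), ":"))
  ep <- effect_sizes(parent_psi,
                     data.frame(position = as.integer(prov[, 2]),
                                alt = prov[, 4], psi = vpsi),
                     length = nchar(el$variable_region))
  regions <- call_sensitive_regions(ep, z_min = 3, min_block = 3,
                                    min_mean_effect = 0.1)
  ## the planted motif window must overlap a called region by >= 80%
  ov <- vapply(seq_len(nrow(regions)), function(j) {
    length(intersect(seq(regions$start[j], regions$end[j] - 1),
                     seq(win[1], win[1] + 5))) / 6
  }, numeric(1))
  expect_gte(max(c(ov, 0)), 0.8)
})
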