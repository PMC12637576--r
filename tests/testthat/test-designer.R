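test_that("reparameterisation is the deterministic noise transform", {
  mu <- matrix(1:6 / 2, 2)
  lv <- matrix(0, 2, 3)
  expect_equal(reparameterize(mu, lv, noise = matrix(0, 2, 3)), mu)
  expect_equal(reparameterize(mu, lv, noise = matrix(1, 2, 3)), mu + 1)
  ## non-unit variance scales the noise by exp(logvar/2)
  expect_equal(reparameterize(0, matrix(2), matrix(1)), matrix(exp(1)))
  withr::with_seed(15, {
    draws <- vapply(1:10000, function(i) reparameterize(0.7, 0.4), numeric(1))
  })
  se <- exp(0.4 / 2) / sqrt(10000)
  expect_lt(abs(mean(draws) - 0.7), 3 * se)
})

test_that("composite loss components match their closed forms", {
  ## KL of a single unit at mu = 1, logvar = 0 is exactly 1/2
  l <- vae_composite_loss(x = 1, xhat = 1 - 1e-7, mu = 1, logvar = 0,
                          teacher_pred = 0.3, y_target = 0)
  expect_equal(l$kl, 0.5)
  expect_equal(l$disc, 0.09)
  ## each component vanishes at its optimum
  l0 <- vae_composite_loss(x = c(1, 0), xhat = c(1 - 1e-9, 1e-9),
                           mu = c(0, 0), logvar = c(0, 0),
                           teacher_pred = 0.5, y_target = 0.5)
  expect_lt(l0$recon, 1e-6)
  expect_equal(l0$kl, 0)
  expect_equal(l0$disc, 0)
  expect_lt(l0$total, 1e-6)
  ## total is monotone in each weight
  l1 <- vae_composite_loss(c(1, 0), c(0.7, 0.4), c(1, -1), c(0.3, 0.3),
                           0.8, 0.2, lambda_recon = 1, lambda_kl = 0.1,
                           lambda_disc = 0.1)
  l2 <- vae_composite_loss(c(1, 0), c(0.7, 0.4), c(1, -1), c(0.3, 0.3),
                           0.8, 0.2, lambda_recon = 1, lambda_kl = 0.1,
                           lambda_disc = 0.4)
  expect_gt(l2$total, l1$total)
  expect_true(all(c(l1$recon, l1$kl, l1$disc) >= 0))
  expect_error(vae_composite_loss(1, 0.5, 0, 0, 0, 0, lambda_kl = -1),
               ">= 0")
})

test_that("transformer block gradients agree with numerical differentiation", {
  cfg <- designer_config(d_model = 8L, n_heads = 2L, d_latent = 4L,
                         ff_mult = 2L, seed = 44)
  p <- withr::with_seed(44, minisplice:::init_block_params(cfg, "enc1"))
  L <- 6L; B <- 2L
  x <- withr::with_seed(45, matrix(rnorm(8 * L * B), 8))
  R <- withr::with_seed(46, matrix(rnorm(8 * L * B), 8))
  lossfn <- function(pp, xx) {
    sum(minisplice:::block_forward(pp, "enc1", xx, L, B, cfg$n_heads)$out * R)
  }
  fw <- minisplice:::block_forward(p, "enc1", x, L, B, cfg$n_heads)
  bw <- minisplice:::block_backward(p, "enc1", fw, R)
  withr::with_seed(47, {
    for (nm in names(p)) {
      for (k in sample(length(p[[nm]]), min(3, length(p[[nm]])))) {
        eps <- 1e-6
        p2 <- p; p2[[nm]][k] <- p2[[nm]][k] + eps
        p3 <- p; p3[[nm]][k] <- p3[[nm]][k] - eps
        num <- (lossfn(p2, x) - lossfn(p3, x)) / (2 * eps)
        expect_equal(bw$grads[[nm]][k], num, tolerance = 1e-4)
      }
    }
    ## input gradient
    for (k in sample(length(x), 5)) {
      eps <- 1e-6
      x2 <- x; x2[k] <- x2[k] + eps
      x3 <- x; x3[k] <- x3[k] - eps
      num <- (lossfn(p, x2) - lossfn(p, x3)) / (2 * eps)
      expect_equal(bw$dx[k], num, tolerance = 1e-4)
    }
  })
})

## small shared fixtures for the generative tests
tiny_designer_config <- function(...) {
  designer_config(d_model = 16L, n_heads = 4L, enc_layers = 2L,
                  dec_layers = 1L, d_latent = 8L, seq_len = 60L,
                  batch = 10L, lr = 2e-3, seed = 5, ...)
}

test_that("a plain VAE (no guidance) learns to reconstruct sequences", {
  withr::with_seed(55, {
    seqs <- random_dna(60, 50)
  })
  cfg <- tiny_designer_config(epochs = 25L, lambda_disc = 0)
  m <- train_designer(seqs[1:50], ensemble = NULL, config = cfg)
  ## training loss decreased
  expect_lt(tail(m$log$total, 1), m$log$total[1])
  ## held-out reconstruction: encode, decode at the latent mean
  enc <- encode_sequences(seqs[51:60], backbone = m$encoder$backbone,
                          total_len = m$encoder$L)
  en <- minisplice:::vae_encode(m$params, cfg, enc$x, enc$L, 10L)
  de <- minisplice:::vae_decode(m$params, cfg, en$mu, enc$L, 10L)
  rec <- decode_sequences(de$logits, enc$L)
  rec_vr <- substring(rec, enc$offset + 1, enc$offset + enc$var_len)
  identity_rate <- 1 - mean(hamming_dist(rec_vr, seqs[51:60]) / 50)
  expect_gt(identity_rate, 0.95)
})

test_that("designer training is deterministic under a fixed seed", {
  withr::with_seed(56, {
    seqs <- random_dna(20, 40)
  })
  cfg <- tiny_designer_config(epochs = 2L, lambda_disc = 0)
  m1 <- train_designer(seqs, config = cfg)
  m2 <- train_designer(seqs, config = cfg)
  expect_identical(m1$log, m2$log)
  d1 <- generate_designs(m1, seqs[1:3], n_per_parent = 4, seed = 9)
  d2 <- generate_designs(m2, seqs[1:3], n_per_parent = 4, seed = 9)
  expect_identical(d1, d2)
})

test_that("generated designs are valid, length-preserving, with provenance", {
  withr::with_seed(57, {
    seqs <- stats::setNames(random_dna(12, 45), sprintf("p%02d", 1:12))
  })
  cfg <- designer_config(d_model = 16L, n_heads = 4L, enc_layers = 2L,
                         dec_layers = 1L, d_latent = 8L, seq_len = 50L,
                         batch = 10L, lr = 2e-3, seed = 5,
                         epochs = 4L, lambda_disc = 0)
  m <- train_designer(seqs, config = cfg)
  des <- generate_designs(m, seqs[1:5], n_per_parent = 8, seed = 3)
  expect_equal(nrow(des), 40)
  expect_true(all(nchar(des$sequence) == 45))
  expect_true(all(grepl("^[ACGT]+$", des$sequence)))
  expect_equal(des$n_substitutions,
               unname(hamming_dist(des$sequence, seqs[des$parent])))
  expect_equal(unname(table(des$parent)), rep(8L, 5), ignore_attr = TRUE)
})

test_that("the teacher ensemble separates guidance from the filter model", {
  withr::with_seed(58, {
    seqs <- random_dna(40, 40)
    targ <- rnorm(40)
  })
  tcfg <- predictor_config(kernels = c(5L), n_blocks = 1L,
                           channels_per_branch = 4L, pool_stride = 5L,
                           epochs = 2L, batch = 20L, seed = 58)
  ens <- train_teacher_ensemble(seqs, targ, n = 3L, config = tcfg)
  expect_length(ens$models, 3)
  expect_equal(ens$guidance_idx, 1:2)
  expect_equal(ens$filter_idx, 3L)
  expect_false(ens$filter_idx %in% ens$guidance_idx)
  ## guidance prediction is the arithmetic mean of the guidance members
  gp <- guidance_predict(ens, seqs[1:5])
  manual <- rowMeans(cbind(predict_mean_logratio(ens$models[[1]], seqs[1:5]),
                           predict_mean_logratio(ens$models[[2]], seqs[1:5])))
  expect_equal(gp, manual, tolerance = 1e-12)
  expect_error(train_teacher_ensemble(seqs, targ, n = 1L), "at least 2")
})

test_that("design filtering applies the parent-accuracy and target rules", {
  withr::with_seed(59, {
    seqs <- random_dna(30, 40)
  })
  ## teachers trained on a constant mid-level target predict PSI ~ 0.5
  tcfg <- predictor_config(kernels = c(5L), n_blocks = 1L,
                           channels_per_branch = 4L, pool_stride = 5L,
                           epochs = 3L, batch = 15L, seed = 59)
  ens <- train_teacher_ensemble(seqs, rep(0, 30), n = 2L, config = tcfg)
  parents <- stats::setNames(seqs[1:2], c("pa", "pb"))
  designs <- data.frame(design_id = c("pa_d1", "pa_d2", "pb_d1"),
                        parent = c("pa", "pa", "pb"),
                        sequence = seqs[3:5], stringsAsFactors = FALSE)
  ## parent pa measured in agreement with the filter teacher, pb not
  res <- filter_designs(designs, ens,
                        parent_measured = c(pa = 0.5, pb = 0.95),
                        parent_seqs = parents, target = "intermediate")
  expect_true(all(res$parent_ok[res$parent == "pa"]))
  expect_false(any(res$parent_ok[res$parent == "pb"]))
  expect_true(all(res$target_ok))     # predictions sit in the mid bin
  expect_equal(res$kept, res$parent_ok & res$target_ok)
  ## a high-bin request drops everything the teacher puts mid-bin
  res2 <- filter_designs(designs, ens,
                         parent_measured = c(pa = 0.5, pb = 0.5),
                         parent_seqs = parents, target = "high")
  expect_false(any(res2$kept))
})

test_that("design evaluation scores bins, targets and enrichment", {
  designs <- data.frame(design_id = paste0("d", 1:4),
                        parent = "p", sequence = "ACGT",
                        stringsAsFactors = FALSE)
  measured <- c(d1 = 0.85, d2 = 0.95, d3 = 0.5, d4 = NA)
  ev <- evaluate_designs(designs, measured, target = "high",
                         baseline_rate = 0.1)
  expect_equal(ev$per_design$success, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(ev$success_rate, 2 / 3)
  expect_equal(ev$fold_enrichment, (2 / 3) / 0.1)
  ## numeric (delta) targets require sign and magnitude
  evd <- evaluate_designs(designs, c(d1 = 0.5, d2 = 0.2, d3 = -0.5, d4 = 0.31),
                          target = 0.3)
  expect_equal(evd$per_design$success, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(psi_bin(c(0.1, 0.5, 0.9)), c("low", "intermediate", "high"))
})
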