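random_onehot <- function(L, B, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(0, 4, L * B)
    x[cbind(sample(4, L * B, TRUE), seq_len(L * B))] <- 1
    x
  })
}

test_that("compiled convolution matches the pure-R reference", {
  withr::with_seed(5, {
    for (trial in 1:3) {
      C_in <- sample(2:6, 1); C_out <- sample(2:5, 1)
      K <- sample(c(3, 5, 11), 1); L <- sample(15:40, 1); B <- sample(2:5, 1)
      x <- matrix(rnorm(C_in * L * B), C_in)
      W <- matrix(rnorm(C_out * C_in * K), C_out)
      b <- rnorm(C_out)
      fc <- minisplice:::conv1d_forward(W, b, x, L, B)
      fr <- minisplice:::conv1d_forward_ref(W, b, x, L, B)
      expect_equal(fc$out, fr$out, tolerance = 1e-12)
      dout <- matrix(rnorm(C_out * L * B), C_out)
      bc <- minisplice:::conv1d_backward(W, fc, dout)
      br <- minisplice:::conv1d_backward_ref(W, fr, dout)
      expect_equal(bc$dW, br$dW, tolerance = 1e-10)
      expect_equal(bc$db, br$db, tolerance = 1e-10)
      expect_equal(bc$dx, br$dx, tolerance = 1e-10)
    }
  })
})

test_that("trunk gradients agree with numerical differentiation", {
  L <- 18L; B <- 3L
  x <- random_onehot(L, B, seed = 6)
  y <- withr::with_seed(6, rnorm(B))
  cfg <- predictor_config(kernels = c(3L, 5L), n_blocks = 2L,
                          channels_per_branch = 3L, dropout = 0,
                          pool_stride = 2L, head_hidden = 4L, seed = 6)
  p <- withr::with_seed(6, minisplice:::init_trunk_params(cfg))
  st <- minisplice:::init_trunk_stats(cfg)
  lossfn <- function(pp) {
    fw <- minisplice:::trunk_forward(pp, st, cfg, x, L, B, training = TRUE)
    mean((fw$y - y)^2)
  }
  fw <- minisplice:::trunk_forward(p, st, cfg, x, L, B, training = TRUE)
  bw <- minisplice:::trunk_backward(p, cfg, fw, 2 * (fw$y - y) / B)
  withr::with_seed(7, {
    for (nm in names(p)) {
      ks <- sample(length(p[[nm]]), min(3, length(p[[nm]])))
      for (k in ks) {
        eps <- 1e-5
        p2 <- p; p2[[nm]][k] <- p2[[nm]][k] + eps
        p3 <- p; p3[[nm]][k] <- p3[[nm]][k] - eps
        num <- (lossfn(p2) - lossfn(p3)) / (2 * eps)
        expect_equal(bw$grads[[nm]][k], num, tolerance = 5e-3)
      }
    }
  })
})

test_that("input gradients flow through the trunk", {
  L <- 16L; B <- 2L
  x <- random_onehot(L, B, seed = 8)
  cfg <- predictor_config(kernels = c(3L), n_blocks = 1L,
                          channels_per_branch = 4L, dropout = 0,
                          pool_stride = 1L, head_hidden = 4L, seed = 8)
  p <- withr::with_seed(8, minisplice:::init_trunk_params(cfg))
  st <- minisplice:::init_trunk_stats(cfg)
  fw <- minisplice:::trunk_forward(p, st, cfg, x, L, B, training = FALSE)
  bw <- minisplice:::trunk_backward(p, cfg, fw, rep(1, B), need_dx = TRUE)
  expect_equal(dim(bw$dx), dim(x))
  ## numerical check on a few input coordinates (eval mode is smooth
  ## in the input away from ReLU kinks)
  lossfn <- function(xx) {
    sum(minisplice:::trunk_forward(p, st, cfg, xx, L, B, training = FALSE)$y)
  }
  withr::with_seed(9, {
    for (k in sample(length(x), 4)) {
      eps <- 1e-5
      x2 <- x; x2[k] <- x2[k] + eps
      x3 <- x; x3[k] <- x3[k] - eps
      num <- (lossfn(x2) - lossfn(x3)) / (2 * eps)
      expect_equal(bw$dx[k], num, tolerance = 1e-4)
    }
  })
})

test_that("one-hot encoding places the variable region and decodes back", {
  ## single base anchors the channel order
  e1 <- encode_sequences("A", total_len = 5L, offset = 0L,
                         backbone = "CCCCC")
  expect_equal(e1$x[, 1], c(1, 0, 0, 0))
  expect_true(all(colSums(e1$x) == 1))
  ## fixed total width regardless of input length
  withr::with_seed(10, {
    seqs <- random_dna(20, 215)
  })
  enc <- encode_sequences(seqs)
  expect_equal(ncol(enc$x), 250 * 20)
  expect_equal(enc$L, 250L)
  ## round trip through decode
  expect_equal(decode_sequences(enc, variable_only = TRUE), seqs)
  expect_error(encode_sequences("ANA", total_len = 10L), "unknown base")
})

test_that("pooling layers match naive implementations", {
  withr::with_seed(11, {
    C <- 5L; L <- 12L; B <- 3L
    x <- matrix(rnorm(C * L * B), C)
    arr <- array(x, c(C, L, B))
    gp <- minisplice:::gap_forward(x, L, B)
    expect_equal(gp$out, apply(arr, c(1, 3), mean), ignore_attr = TRUE)
    mp <- minisplice:::gmp_forward(x, L, B)
    expect_equal(mp$out, apply(arr, c(1, 3), max), ignore_attr = TRUE)
    ## max-pool gradient goes entirely to the argmax
    dout <- matrix(rnorm(C * B), C)
    dx <- minisplice:::gmp_backward(mp, dout)
    expect_equal(rowSums(matrix(dx, C)), rowSums(dout))
    expect_equal(sum(dx != 0), C * B)
    ## strided average pooling
    pl <- minisplice:::pool_forward(x, L, B, 3L)
    naive <- apply(array(x, c(C, 3, 4, B)), c(1, 3, 4), mean)
    expect_equal(pl$out, matrix(naive, C), ignore_attr = TRUE)
    dpo <- matrix(rnorm(C * 4 * B), C)
    dxp <- minisplice:::pool_backward(pl, dpo)
    expect_equal(sum(dxp), sum(dpo), tolerance = 1e-12)
  })
})

test_that("Adam decreases a simple quadratic and applies weight decay", {
  p <- list(W = matrix(c(5, -3), 1))
  st <- minisplice:::adam_init(p)
  for (i in 1:400) {
    g <- list(W = 2 * p$W)
    upd <- minisplice:::adam_step(p, g, st, lr = 0.05)
    p <- upd$params; st <- upd$state
  }
  expect_lt(max(abs(p$W)), 0.05)
  ## pure decay shrinks weights with zero gradient
  p2 <- list(W = matrix(1, 2, 2))
  st2 <- minisplice:::adam_init(p2)
  upd2 <- minisplice:::adam_step(p2, list(W = matrix(0, 2, 2)), st2,
                                 lr = 0.1, weight_decay = 0.5)
  expect_true(all(upd2$params$W < 1))
})
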