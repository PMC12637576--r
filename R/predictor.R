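## Predictive model for cell-type-specific splicing: a residual
## convolutional network over one-hot sequence predicts the cell-type
## mean splicing level (log-ratio scale); a fully connected expression
## encoder is fused with the sequence latent to predict each cell
## type's deviation from that mean. Prediction = mean head + deviation
## head, convertible to PSI through the exact inverse of the normalised
## log-ratio.

#' Predictor configuration
#'
#' Architecture: `n_blocks` residual blocks, each applying multi-scale
#' convolutions with kernel sizes `kernels` in parallel (channels split
#' across branches), batch normalisation, ReLU and dropout, with an
#' identity skip connection; global average pooling; a two-layer dense
#' head for the sequence-mean prediction. The expression branch encodes
#' a standardised expression profile into a latent vector that is
#' concatenated with the pooled sequence latent for the deviation head.
#'
#' @param kernels Convolution kernel sizes (one branch each).
#' @param n_blocks Number of residual blocks.
#' @param channels_per_branch Output channels per kernel branch; total
#'   trunk width is `length(kernels) * channels_per_branch`.
#' @param dropout Dropout rate after each block's normalisation.
#' @param pool_stride Average-pooling stride applied after the stem
#'   (the stem convolutions see full single-nucleotide resolution; the
#'   residual blocks then operate on the pooled positions).
#' @param pool_mode Global pooled readout fed to the dense head:
#'   `"mean"` (average over positions), `"max"` (strongest activation
#'   per channel -- matched to motif-presence signals), or
#'   `"mean_max"` (both, concatenated; default).
#' @param head_hidden Hidden width of the mean head (0 = linear
#'   readout from the pooled latent).
#' @param expr_hidden,expr_latent Expression encoder widths.
#' @param weight_decay Decoupled L2 weight decay on weight matrices.
#' @param val_frac Fraction of the training set held out for validation;
#'   the parameters with the best validation loss are kept (early
#'   stopping). 0 disables validation tracking.
#' @param lr,epochs,batch Adam learning rate, training epochs,
#'   minibatch size.
#' @param lr_decay Cosine-decay the learning rate to `lr_decay * lr`
#'   over training (1 = constant).
#' @param finetune_lr,finetune_epochs Settings for the deviation stage.
#' @param deviation_hidden Hidden width of the deviation head.
#' @param seed Integer seed controlling initialisation, batching and
#'   dropout.
#' @return List of class `predictor_config`.
#' @export
predictor_config <- function(kernels = c(5L, 11L, 21L), n_blocks = 3L,
                             channels_per_branch = 12L, dropout = 0.2,
                             pool_stride = 3L,
                             pool_mode = c("mean_max", "mean", "max"),
                             head_hidden = 64L,
                             expr_hidden = 32L, expr_latent = 16L,
                             lr = 1e-3, epochs = 20L, batch = 32L,
                             lr_decay = 0.25,
                             weight_decay = 0.02, val_frac = 0.1,
                             finetune_lr = 1e-3, finetune_epochs = 30L,
                             deviation_hidden = 64L,
                             seed = 1L) {
  out <- as.list(environment())
  out$pool_mode <- match.arg(pool_mode)
  out$trunk_channels <- length(kernels) * channels_per_branch
  out$latent_dim <- out$trunk_channels *
    (if (out$pool_mode == "mean_max") 2L else 1L)
  class(out) <- "predictor_config"
  out
}

init_trunk_params <- function(cfg) {
  C <- cfg$trunk_channels
  cb <- cfg$channels_per_branch
  p <- list()
  for (k in cfg$kernels) {
    p[[paste0("stem_W", k)]] <- winit(cb, 4L * k)
    p[[paste0("stem_b", k)]] <- numeric(cb)
  }
  p$bn0_gamma <- rep(1, C)
  p$bn0_beta <- numeric(C)
  for (i in seq_len(cfg$n_blocks)) {
    for (k in cfg$kernels) {
      p[[sprintf("blk%d_W%d", i, k)]] <- winit(cb, C * k)
      p[[sprintf("blk%d_b%d", i, k)]] <- numeric(cb)
    }
    p[[sprintf("blk%d_gamma", i)]] <- rep(1, C)
    p[[sprintf("blk%d_beta", i)]] <- numeric(C)
  }
  if (cfg$head_hidden > 0) {
    p$head_W1 <- winit(cfg$head_hidden, cfg$latent_dim)
    p$head_b1 <- numeric(cfg$head_hidden)
    ## small final-layer init: predictions start near the target mean
    p$head_W2 <- winit(1L, cfg$head_hidden) * 0.05
    p$head_b2 <- numeric(1L)
  } else {
    ## linear readout straight from the pooled latent
    p$head_W2 <- winit(1L, cfg$latent_dim) * 0.05
    p$head_b2 <- numeric(1L)
  }
  p
}

init_trunk_stats <- function(cfg) {
  C <- cfg$trunk_channels
  s <- list(bn0_mean = numeric(C), bn0_var = rep(1, C))
  for (i in seq_len(cfg$n_blocks)) {
    s[[sprintf("blk%d_mean", i)]] <- numeric(C)
    s[[sprintf("blk%d_var", i)]] <- rep(1, C)
  }
  s
}

## Full trunk + mean-head forward. x: (4, L*B).
trunk_forward <- function(p, stats, cfg, x, L, B, training = FALSE,
                          bn_momentum = 0.1) {
  cache <- list()
  outs <- list()
  for (k in cfg$kernels) {
    cv <- conv1d_forward(p[[paste0("stem_W", k)]], p[[paste0("stem_b", k)]],
                         x, L, B)
    cache[[paste0("stem_conv", k)]] <- cv
    outs[[as.character(k)]] <- cv$out
  }
  h <- do.call(rbind, outs)
  bn <- bn_forward(p$bn0_gamma, p$bn0_beta, h, training,
                   stats$bn0_mean, stats$bn0_var, momentum = bn_momentum)
  stats$bn0_mean <- bn$run_mean; stats$bn0_var <- bn$run_var
  cache$bn0 <- bn
  rl <- relu_forward(bn$out)
  cache$relu0 <- rl
  pl <- pool_forward(rl$out, L, B, cfg$pool_stride)
  cache$pool <- pl
  h <- pl$out
  Lb <- pl$Lout
  for (i in seq_len(cfg$n_blocks)) {
    outs <- list()
    for (k in cfg$kernels) {
      cv <- conv1d_forward(p[[sprintf("blk%d_W%d", i, k)]],
                           p[[sprintf("blk%d_b%d", i, k)]], h, Lb, B)
      cache[[sprintf("blk%d_conv%d", i, k)]] <- cv
      outs[[as.character(k)]] <- cv$out
    }
    g <- do.call(rbind, outs)
    bn <- bn_forward(p[[sprintf("blk%d_gamma", i)]],
                     p[[sprintf("blk%d_beta", i)]], g, training,
                     stats[[sprintf("blk%d_mean", i)]],
                     stats[[sprintf("blk%d_var", i)]],
                     momentum = bn_momentum)
    stats[[sprintf("blk%d_mean", i)]] <- bn$run_mean
    stats[[sprintf("blk%d_var", i)]] <- bn$run_var
    cache[[sprintf("blk%d_bn", i)]] <- bn
    rl <- relu_forward(bn$out)
    cache[[sprintf("blk%d_relu", i)]] <- rl
    dp <- dropout_forward(rl$out, cfg$dropout, training)
    cache[[sprintf("blk%d_drop", i)]] <- dp
    cache[[sprintf("blk%d_in", i)]] <- h
    h <- h + dp$out
  }
  latent <- NULL
  if (cfg$pool_mode %in% c("mean", "mean_max")) {
    gp <- gap_forward(h, Lb, B)
    cache$gap <- gp
    latent <- gp$out
  }
  if (cfg$pool_mode %in% c("max", "mean_max")) {
    mp <- gmp_forward(h, Lb, B)
    cache$gmp <- mp
    latent <- if (is.null(latent)) mp$out else rbind(latent, mp$out)
  }
  if (cfg$head_hidden > 0) {
    d1 <- dense_forward(p$head_W1, p$head_b1, latent)
    cache$head1 <- d1
    r1 <- relu_forward(d1$out)
    cache$head_relu <- r1
    d2 <- dense_forward(p$head_W2, p$head_b2, r1$out)
  } else {
    d2 <- dense_forward(p$head_W2, p$head_b2, latent)
  }
  cache$head2 <- d2
  list(y = as.numeric(d2$out), latent = latent, cache = cache, stats = stats)
}

## Backward through mean head + trunk. dy: numeric(B). Returns grads and
## (optionally) the gradient w.r.t. the one-hot input.
trunk_backward <- function(p, cfg, fw, dy, need_dx = FALSE) {
  cache <- fw$cache
  g <- list()
  cb <- cfg$channels_per_branch
  dd2 <- dense_backward(p$head_W2, cache$head2, matrix(dy, nrow = 1L))
  g$head_W2 <- dd2$dW; g$head_b2 <- dd2$db
  if (cfg$head_hidden > 0) {
    dr1 <- relu_backward(cache$head_relu, dd2$dx)
    dd1 <- dense_backward(p$head_W1, cache$head1, dr1)
    g$head_W1 <- dd1$dW; g$head_b1 <- dd1$db
    dlat <- dd1$dx
  } else {
    dlat <- dd2$dx
  }
  C <- cfg$trunk_channels
  dh <- switch(cfg$pool_mode,
    mean = gap_backward(cache$gap, dlat),
    max = gmp_backward(cache$gmp, dlat),
    mean_max = gap_backward(cache$gap, dlat[seq_len(C), , drop = FALSE]) +
      gmp_backward(cache$gmp, dlat[(C + 1L):(2L * C), , drop = FALSE]))
  for (i in rev(seq_len(cfg$n_blocks))) {
    ## dh flows both through the skip and through the block
    dg <- dropout_backward(cache[[sprintf("blk%d_drop", i)]], dh)
    dg <- relu_backward(cache[[sprintf("blk%d_relu", i)]], dg)
    dbn <- bn_backward(p[[sprintf("blk%d_gamma", i)]],
                       cache[[sprintf("blk%d_bn", i)]], dg)
    g[[sprintf("blk%d_gamma", i)]] <- dbn$dgamma
    g[[sprintf("blk%d_beta", i)]] <- dbn$dbeta
    dsum <- dh  # skip path
    for (bi in seq_along(cfg$kernels)) {
      k <- cfg$kernels[bi]
      rows <- ((bi - 1L) * cb + 1L):(bi * cb)
      cvb <- conv1d_backward(p[[sprintf("blk%d_W%d", i, k)]],
                             cache[[sprintf("blk%d_conv%d", i, k)]],
                             dbn$dx[rows, , drop = FALSE])
      g[[sprintf("blk%d_W%d", i, k)]] <- cvb$dW
      g[[sprintf("blk%d_b%d", i, k)]] <- cvb$db
      dsum <- dsum + cvb$dx
    }
    dh <- dsum
  }
  dh <- pool_backward(cache$pool, dh)
  dr0 <- relu_backward(cache$relu0, dh)
  dbn0 <- bn_backward(p$bn0_gamma, cache$bn0, dr0)
  g$bn0_gamma <- dbn0$dgamma
  g$bn0_beta <- dbn0$dbeta
  dx <- NULL
  for (bi in seq_along(cfg$kernels)) {
    k <- cfg$kernels[bi]
    rows <- ((bi - 1L) * cb + 1L):(bi * cb)
    cvb <- conv1d_backward(p[[paste0("stem_W", k)]],
                           cache[[paste0("stem_conv", k)]],
                           dbn0$dx[rows, , drop = FALSE],
                           need_dx = need_dx)
    g[[paste0("stem_W", k)]] <- cvb$dW
    g[[paste0("stem_b", k)]] <- cvb$db
    if (need_dx) dx <- if (is.null(dx)) cvb$dx else dx + cvb$dx
  }
  list(grads = g, dx = dx)
}

#' Pretrain the sequence trunk on mean splicing
#'
#' Trains the residual CNN to predict each sequence's mean log-ratio
#' across cell types from one-hot sequence alone, with minibatch Adam
#' and mean-squared-error loss.
#'
#' @param encoded An [encode_sequences()] object (training sequences).
#' @param y Numeric vector of targets (mean log-ratio per sequence).
#' @param config A [predictor_config()].
#' @param verbose Print per-epoch loss.
#' @return Object of class `psi_predictor` with `params`, `stats`,
#'   `config`, `encoder` (placement metadata), and `log` (per-epoch
#'   training loss).
#' @export
pretrain_predictor <- function(encoded, y, config = predictor_config(),
                               verbose = FALSE) {
  check_that(encoded$n == length(y), "pretrain_predictor: n mismatch")
  L <- encoded$L
  ## standardise targets for optimisation; predictions are mapped back
  y_mean <- mean(y)
  y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd < 1e-8) y_sd <- 1
  y <- (y - y_mean) / y_sd
  with_seed(config$seed, {
    p <- init_trunk_params(config)
    stats <- init_trunk_stats(config)
    opt <- adam_init(p)
    n <- encoded$n
    ## validation split for early stopping (best-epoch snapshot)
    n_val <- if (config$val_frac > 0) max(8L, round(config$val_frac * n)) else 0L
    val_idx <- if (n_val > 0 && n_val < n) sample.int(n, n_val) else integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)
    xval <- if (length(val_idx)) {
      encoded$x[, sample_cols(val_idx, L), drop = FALSE]
    } else NULL
    log <- numeric(config$epochs)
    val_log <- rep(NA_real_, config$epochs)
    best <- list(val = Inf, params = p, stats = stats)
    decay_floor <- if (is.null(config$lr_decay)) 1 else config$lr_decay
    for (ep in seq_len(config$epochs)) {
      ## cosine learning-rate schedule from lr to lr * lr_decay
      frac <- if (config$epochs > 1) (ep - 1) / (config$epochs - 1) else 0
      lr_ep <- config$lr * (decay_floor +
                              (1 - decay_floor) * (1 + cos(pi * frac)) / 2)
      ord <- sample(tr_idx)
      tot <- 0; nb <- 0
      for (start in seq(1L, length(ord), by = config$batch)) {
        idx <- ord[start:min(start + config$batch - 1L, length(ord))]
        B <- length(idx)
        xb <- encoded$x[, sample_cols(idx, L), drop = FALSE]
        fw <- trunk_forward(p, stats, config, xb, L, B, training = TRUE)
        stats <- fw$stats
        err <- fw$y - y[idx]
        loss <- mean(err^2)
        if (!is.finite(loss)) {
          stop("pretrain_predictor: non-finite loss at epoch ", ep,
               " (lr too high or degenerate targets)")
        }
        bw <- trunk_backward(p, config, fw, 2 * err / B)
        st <- adam_step(p, bw$grads, opt, lr = lr_ep,
                        weight_decay = config$weight_decay)
        p <- st$params; opt <- st$state
        tot <- tot + loss; nb <- nb + 1
      }
      log[ep] <- tot / nb
      if (length(val_idx)) {
        ## recalibrate BN statistics on (a subsample of) the training
        ## data before validating, so the selection criterion matches
        ## how the final model is evaluated
        cal_idx <- if (length(tr_idx) > 512L) tr_idx[seq_len(512L)] else tr_idx
        stats <- refresh_bn_stats(p, stats, config, encoded$x, L, cal_idx)
        vp <- trunk_forward(p, stats, config, xval, L, length(val_idx),
                            training = FALSE)
        val_log[ep] <- mean((vp$y - y[val_idx])^2)
        if (val_log[ep] < best$val) {
          best <- list(val = val_log[ep], params = p, stats = stats)
        }
      }
      if (verbose) {
        message(sprintf("epoch %d: mse %.4f val %.4f", ep, log[ep],
                        val_log[ep]))
      }
    }
    if (length(val_idx) && is.finite(best$val)) {
      p <- best$params
      stats <- best$stats
    } else {
      stats <- refresh_bn_stats(p, stats, config, encoded$x, L, tr_idx)
    }
    model <- list(params = p, stats = stats, config = config,
                  encoder = encoded[c("L", "offset", "var_len", "backbone")],
                  y_scale = c(mean = y_mean, sd = y_sd),
                  log = log, val_log = val_log, finetuned = FALSE)
    class(model) <- "psi_predictor"
    model
  })
}

#' @export
print.psi_predictor <- function(x, ...) {
  cat(sprintf("<psi_predictor> trunk %d ch x %d blocks (kernels %s)%s; final mse %.4f\n",
              x$config$trunk_channels, x$config$n_blocks,
              paste(x$config$kernels, collapse = "/"),
              if (x$finetuned) " + expression head" else "",
              utils::tail(x$log, 1)))
  invisible(x)
}

encode_for_model <- function(model, seqs) {
  encode_sequences(seqs, backbone = model$encoder$backbone,
                   total_len = model$encoder$L)
}

## One pass over the training sequences with momentum 1/k, turning the
## running BN moments into exact averages of the batch statistics.
refresh_bn_stats <- function(p, stats, cfg, x, L, idx) {
  chunk <- 128L
  k <- 0L
  for (start in seq(1L, length(idx), by = chunk)) {
    sel <- idx[start:min(start + chunk - 1L, length(idx))]
    k <- k + 1L
    fw <- trunk_forward(p, stats, cfg, x[, sample_cols(sel, L), drop = FALSE],
                        L, length(sel), training = TRUE, bn_momentum = 1 / k)
    stats <- fw$stats
  }
  stats
}

#' Predict the sequence-mean log-ratio
#'
#' @param model A trained [psi_predictor][pretrain_predictor].
#' @param seqs Character vector of variable-region sequences, or an
#'   `encoded_sequences` object / bare encoding matrix.
#' @param L Positions per sequence when `seqs` is a bare matrix.
#' @return Numeric vector of predicted mean log-ratios.
#' @export
predict_mean_logratio <- function(model, seqs, L = NULL) {
  if (is.character(seqs)) seqs <- encode_for_model(model, seqs)
  if (inherits(seqs, "encoded_sequences")) {
    x <- seqs$x; L <- seqs$L
  } else x <- seqs
  B <- ncol(x) / L
  ## predict in chunks to bound memory
  out <- numeric(B)
  chunk <- 256L
  for (start in seq(1L, B, by = chunk)) {
    idx <- start:min(start + chunk - 1L, B)
    fw <- trunk_forward(model$params, model$stats, model$config,
                        x[, sample_cols(idx, L), drop = FALSE], L,
                        length(idx), training = FALSE)
    out[idx] <- fw$y
  }
  out * model$y_scale["sd"] + model$y_scale["mean"]
}

## pooled sequence latents, eval mode, chunked
trunk_latents <- function(model, x, L) {
  B <- ncol(x) / L
  out <- matrix(0, model$config$latent_dim, B)
  chunk <- 256L
  for (start in seq(1L, B, by = chunk)) {
    idx <- start:min(start + chunk - 1L, B)
    fw <- trunk_forward(model$params, model$stats, model$config,
                        x[, sample_cols(idx, L), drop = FALSE], L,
                        length(idx), training = FALSE)
    out[, idx] <- fw$latent
  }
  out
}

#' Split a PSI dataset for training and evaluation
#'
#' @param psi Elements x cell types matrix (or `psi_matrix`).
#' @param mode `"by_sequence"` (split rows) or `"by_celltype"` (split
#'   columns; requires >= 5 cell types).
#' @param train_frac Training fraction (default 0.8).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test` along the
#'   chosen axis.
#' @export
split_psi_dataset <- function(psi, mode = c("by_sequence", "by_celltype"),
                              train_frac = 0.8, seed = 1L) {
  if (inherits(psi, "psi_matrix")) psi <- psi$psi
  mode <- match.arg(mode)
  n <- if (mode == "by_sequence") nrow(psi) else ncol(psi)
  if (mode == "by_celltype") {
    check_that(n >= 5, "split_psi_dataset: by_celltype needs >= 5 cell types")
  }
  check_that(n >= 2, "split_psi_dataset: nothing to split")
  with_seed(derive_seed(seed, 17L), {
    n_train <- max(1L, min(n - 1L, round(train_frac * n)))
    train <- sort(sample.int(n, n_train))
    list(train = train, test = setdiff(seq_len(n), train), mode = mode)
  })
}

#' Fine-tune with expression to predict per-cell-type deviations
#'
#' Encodes each cell type's standardised expression profile with a
#' two-layer dense encoder, concatenates the expression latent with the
#' (frozen) pooled sequence latent, and trains a two-layer deviation
#' head on the residuals `logratio[element, celltype] - mean_c
#' logratio[element, ]` by minibatch Adam / MSE. The sequence trunk is
#' kept frozen in this stage, which lets sequence latents be computed
#' once; the pretrained mean head continues to supply the sequence-mean
#' prediction.
#'
#' @param model A pretrained [psi_predictor][pretrain_predictor].
#' @param seqs Variable-region sequences of the training elements.
#' @param logratio Elements x cell types matrix of log-ratios (training
#'   targets; column names must match `expression` columns).
#' @param expression Genes x cell types expression matrix.
#' @param verbose Print per-epoch loss.
#' @return The model with expression parameters added
#'   (`finetuned = TRUE`).
#' @export
finetune_predictor <- function(model, seqs, logratio, expression,
                               verbose = FALSE) {
  cfg <- model$config
  cts <- colnames(logratio)
  check_that(all(cts %in% colnames(expression)),
             "finetune_predictor: cell type without expression profile: %s",
             paste(setdiff(cts, colnames(expression)), collapse = ", "))
  enc <- encode_for_model(model, seqs)
  lat <- trunk_latents(model, enc$x, enc$L)
  ## standardise expression per gene using training cell types
  em <- rowMeans(expression[, cts, drop = FALSE])
  es <- apply(expression[, cts, drop = FALSE], 1, stats::sd)
  es[es < 1e-8] <- 1
  zex <- (expression[, cts, drop = FALSE] - em) / es
  resid <- logratio - rowMeans(logratio, na.rm = TRUE)
  ## standardise the residual targets for optimisation
  r_sd <- stats::sd(resid, na.rm = TRUE)
  if (!is.finite(r_sd) || r_sd < 1e-8) r_sd <- 1
  resid <- resid / r_sd
  G <- nrow(expression)
  with_seed(derive_seed(cfg$seed, 91L), {
    C <- cfg$latent_dim
    dh <- cfg$deviation_hidden
    p <- list(e1_W = winit(cfg$expr_hidden, G), e1_b = numeric(cfg$expr_hidden),
              e2_W = winit(cfg$expr_latent, cfg$expr_hidden),
              e2_b = numeric(cfg$expr_latent),
              r1_W = winit(dh, C + cfg$expr_latent),
              r1_b = numeric(dh),
              r2_W = winit(1L, dh) * 0.05, r2_b = numeric(1L))
    opt <- adam_init(p)
    pairs <- which(!is.na(resid), arr.ind = TRUE)
    np <- nrow(pairs)
    log <- numeric(cfg$finetune_epochs)
    for (ep in seq_len(cfg$finetune_epochs)) {
      ord <- sample.int(np)
      tot <- 0; nb <- 0
      for (start in seq(1L, np, by = cfg$batch)) {
        idx <- ord[start:min(start + cfg$batch - 1L, np)]
        ei <- pairs[idx, 1L]; ci <- pairs[idx, 2L]
        B <- length(idx)
        xe <- zex[, ci, drop = FALSE]
        d1 <- dense_forward(p$e1_W, p$e1_b, xe)
        a1 <- relu_forward(d1$out)
        d2 <- dense_forward(p$e2_W, p$e2_b, a1$out)
        fused <- rbind(lat[, ei, drop = FALSE], d2$out)
        r1 <- dense_forward(p$r1_W, p$r1_b, fused)
        ar <- relu_forward(r1$out)
        r2 <- dense_forward(p$r2_W, p$r2_b, ar$out)
        err <- as.numeric(r2$out) - resid[cbind(ei, ci)]
        loss <- mean(err^2)
        if (!is.finite(loss)) stop("finetune_predictor: non-finite loss")
        g <- list()
        db <- dense_backward(p$r2_W, r2, matrix(2 * err / B, nrow = 1L))
        g$r2_W <- db$dW; g$r2_b <- db$db
        dar <- relu_backward(ar, db$dx)
        db <- dense_backward(p$r1_W, r1, dar)
        g$r1_W <- db$dW; g$r1_b <- db$db
        dexpr <- db$dx[(C + 1L):(C + cfg$expr_latent), , drop = FALSE]
        db <- dense_backward(p$e2_W, d2, dexpr)
        g$e2_W <- db$dW; g$e2_b <- db$db
        da1 <- relu_backward(a1, db$dx)
        db <- dense_backward(p$e1_W, d1, da1)
        g$e1_W <- db$dW; g$e1_b <- db$db
        st <- adam_step(p, g, opt, lr = cfg$finetune_lr,
                        weight_decay = cfg$weight_decay)
        p <- st$params; opt <- st$state
        tot <- tot + loss; nb <- nb + 1
      }
      log[ep] <- tot / nb
      if (verbose) message(sprintf("finetune epoch %d: mse %.4f", ep, log[ep]))
    }
    model$expr_params <- p
    model$expr_norm <- list(mean = em, sd = es, genes = rownames(expression))
    model$dev_scale <- r_sd
    model$finetune_log <- log
    model$finetuned <- TRUE
    model
  })
}

## deviation-head forward for given latents (C, B) and expression
## columns (G, B)
deviation_forward <- function(model, lat, xe) {
  p <- model$expr_params
  a1 <- pmax(p$e1_W %*% xe + p$e1_b, 0)
  e <- p$e2_W %*% a1 + p$e2_b
  fused <- rbind(lat, e)
  ar <- pmax(p$r1_W %*% fused + p$r1_b, 0)
  as.numeric(p$r2_W %*% ar + p$r2_b) * model$dev_scale
}

#' Predict PSI (and log-ratio) for sequences across cell types
#'
#' The prediction decomposes exactly as mean head + deviation head on
#' the log-ratio scale; PSI is recovered through [logratio_to_psi()]
#' and clipped to \[0, 1\]. Without a fine-tuned expression head (or
#' with `expression = NULL`) the per-cell-type predictions all equal
#' the sequence mean.
#'
#' @param model A [psi_predictor][pretrain_predictor].
#' @param seqs Variable-region sequences.
#' @param expression Genes x cell types matrix (columns are the cell
#'   types to predict; must cover the genes seen in fine-tuning).
#' @return List: `psi` and `logratio` (elements x cell types matrices),
#'   `mean_logratio` (vector).
#' @export
predict_psi <- function(model, seqs, expression = NULL) {
  enc <- encode_for_model(model, seqs)
  mean_lr <- predict_mean_logratio(model, enc, enc$L)
  if (is.null(expression) || !isTRUE(model$finetuned)) {
    cts <- if (is.null(expression)) "mean" else colnames(expression)
    lr <- matrix(mean_lr, length(seqs), length(cts),
                 dimnames = list(names(seqs), cts))
  } else {
    check_that(identical(rownames(expression), model$expr_norm$genes),
               "predict_psi: expression gene set differs from fine-tuning")
    zex <- (expression - model$expr_norm$mean) / model$expr_norm$sd
    lat <- trunk_latents(model, enc$x, enc$L)
    cts <- colnames(expression)
    dev <- sapply(seq_along(cts), function(j) {
      deviation_forward(model, lat,
                        matrix(zex[, j], nrow(zex), ncol(lat)))
    })
    lr <- matrix(mean_lr, length(seqs), length(cts)) + dev
    dimnames(lr) <- list(names(seqs), cts)
  }
  psi <- matrix(pmin(pmax(logratio_to_psi(lr), 0), 1), nrow(lr),
                dimnames = dimnames(lr))
  list(psi = psi, logratio = lr, mean_logratio = mean_lr)
}

#' In-silico saturation mutagenesis with a trained predictor
#'
#' Scores every single-nucleotide substitution of a parent element with
#' the model and returns a predicted [effect profile][effect_sizes]
#' (`dpsi = parent - variant`, same convention as the experimental
#' screen), which feeds [call_sensitive_regions()] unchanged.
#'
#' @param model A [psi_predictor][pretrain_predictor].
#' @param parent A minigene element (or a bare variable-region string).
#' @param expression Optional single-column expression matrix selecting
#'   the cell context; default uses the sequence-mean prediction.
#' @return An `effect_profile` (grid 3 x length, positionwise means).
#' @export
in_silico_mutagenesis <- function(model, parent, expression = NULL) {
  seq <- if (is.character(parent)) parent else parent$variable_region
  n <- nchar(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  var_seqs <- character(3L * n)
  alt_of <- character(3L * n)
  pos_of <- integer(3L * n)
  k <- 0L
  for (pos in seq_len(n)) {
    for (alt in setdiff(DNA_BASES, bases[pos])) {
      k <- k + 1L
      v <- bases
      v[pos] <- alt
      var_seqs[k] <- paste(v, collapse = "")
      alt_of[k] <- alt
      pos_of[k] <- pos - 1L
    }
  }
  all_seqs <- c(seq, var_seqs)
  pred <- if (is.null(expression)) {
    logratio_to_psi(predict_mean_logratio(model, all_seqs))
  } else {
    predict_psi(model, all_seqs, expression)$psi[, 1L]
  }
  pred <- pmin(pmax(pred, 0), 1)
  effect_sizes(pred[1L],
               data.frame(position = pos_of, alt = alt_of,
                          psi = pred[-1L], stringsAsFactors = FALSE),
               length = n,
               parent_id = if (is.character(parent)) "parent" else parent$id,
               cell_line = if (is.null(expression)) "mean"
                           else colnames(expression)[1L])
}
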