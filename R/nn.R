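## Minimal neural-network kernel: dense/convolution/normalisation layers
## with hand-written backward passes over BLAS-backed matrix ops, and an
## Adam optimiser. Activations are stored as (channels x positions*batch)
## matrices, column-major by position within sample, so convolutions
## reduce to im2col gathers plus one matrix multiply.

## ---- encoding -------------------------------------------------------

#' One-hot encode sequences into a channel matrix
#'
#' Encodes DNA into a 4-channel one-hot matrix of fixed width,
#' padding each sequence into a constant reporter backbone so every
#' encoded sequence has the same length (default 250). The variable
#' region is placed at a fixed offset inside the backbone.
#'
#' @param seqs Character vector of variable-region sequences.
#' @param backbone Backbone sequence of length `total_len`; variable
#'   regions overwrite it starting at `offset`. `NULL` generates a fixed
#'   default backbone.
#' @param total_len Encoded length (default 250).
#' @param offset 0-based placement offset of the variable region.
#' @return List of class `encoded_sequences`: `x` (4 x total_len*n
#'   one-hot matrix, channel order A/C/G/T), `n`, `L`, `offset`,
#'   `var_len`, `backbone`.
#' @export
encode_sequences <- function(seqs, backbone = NULL, total_len = 250L,
                             offset = NULL) {
  lens <- unique(nchar(seqs))
  check_that(length(lens) == 1L,
             "encode_sequences: sequences must share one length")
  check_that(lens <= total_len, "encode_sequences: sequences longer than %d",
             total_len)
  if (is.null(backbone)) backbone <- default_backbone(total_len)
  check_that(nchar(backbone) == total_len,
             "encode_sequences: backbone must have length %d", total_len)
  if (is.null(offset)) offset <- as.integer((total_len - lens) %/% 2)
  check_that(offset >= 0 && offset + lens <= total_len,
             "encode_sequences: variable region does not fit at offset %d", offset)
  full <- paste0(substring(backbone, 1L, offset), seqs,
                 substring(backbone, offset + lens + 1L))
  chars <- unlist(strsplit(full, "", fixed = TRUE), use.names = FALSE)
  code <- match(chars, DNA_BASES)
  check_that(!anyNA(code), "encode_sequences: unknown base in input")
  n <- length(seqs)
  x <- matrix(0, 4L, total_len * n)
  x[cbind(code, seq_along(code))] <- 1
  out <- list(x = x, n = n, L = as.integer(total_len),
              offset = as.integer(offset), var_len = lens,
              backbone = backbone)
  class(out) <- "encoded_sequences"
  out
}

#' Decode one-hot (or probability) channel matrices back to sequences
#'
#' Per-position argmax over the four channels; ties break in fixed
#' channel order A, C, G, T.
#'
#' @param x 4 x (L*n) matrix, or an `encoded_sequences` object.
#' @param L Positions per sequence (required for a bare matrix).
#' @param variable_only For `encoded_sequences` input, return only the
#'   variable region.
#' @return Character vector of sequences.
#' @export
decode_sequences <- function(x, L = NULL, variable_only = FALSE) {
  enc <- NULL
  if (inherits(x, "encoded_sequences")) {
    enc <- x
    L <- x$L
    x <- x$x
  }
  check_that(!is.null(L), "decode_sequences: L required")
  base <- DNA_BASES[max.col(t(x), ties.method = "first")]
  n <- ncol(x) / L
  seqs <- vapply(seq_len(n), function(i) {
    paste(base[((i - 1L) * L + 1L):(i * L)], collapse = "")
  }, character(1))
  if (variable_only && !is.null(enc)) {
    seqs <- substring(seqs, enc$offset + 1L, enc$offset + enc$var_len)
  }
  seqs
}

## fixed pseudo-random backbone, deterministic across sessions
default_backbone <- function(total_len = 250L) {
  with_seed(424243L, random_dna(1L, total_len))
}

## column indices of samples `which` inside a (C, L*n) matrix
sample_cols <- function(which, L) {
  as.vector(outer(seq_len(L), (which - 1L) * L, `+`))
}

## ---- optimiser ------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

## Adam with optional decoupled weight decay (AdamW)
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    upd <- lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (weight_decay > 0 && is.matrix(params[[nm]])) {
      upd <- upd + lr * weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - upd
  }
  list(params = params, state = state)
}

## ---- layers ---------------------------------------------------------

## He-scaled random matrix
winit <- function(nout, nin) {
  matrix(stats::rnorm(nout * nin, 0, sqrt(2 / nin)), nout, nin)
}

## Same-padding 1-D convolution. x: (C_in, L*B). W: (C_out, C_in*K).
## Compiled im2col + BLAS matmul; the input is cached and the im2col
## matrix is rebuilt in the backward pass (cheaper than keeping it).
conv1d_forward <- function(W, b, x, L, B) {
  list(out = .conv1d_fwd_cpp(W, b, x, L, B), x = x, L = L, B = B)
}

conv1d_backward <- function(W, cache, dout, need_dx = TRUE) {
  r <- .conv1d_bwd_cpp(W, cache$x, dout, cache$L, cache$B, need_dx)
  list(dW = r$dW, db = as.numeric(r$db),
       dx = if (need_dx) r$dx else NULL)
}

## Pure-R reference implementation (kept as the independent oracle for
## the compiled kernels).
conv1d_forward_ref <- function(W, b, x, L, B) {
  C_in <- nrow(x)
  K <- ncol(W) / C_in
  P <- (K - 1L) %/% 2L
  Lp <- L + 2L * P
  xp <- matrix(0, C_in, Lp * B)
  padded_base <- as.vector(outer(seq_len(L) + P, (seq_len(B) - 1L) * Lp, `+`))
  xp[, padded_base] <- x
  base <- as.vector(outer(seq_len(L), (seq_len(B) - 1L) * Lp, `+`))
  gidx <- rep(base, each = K) + rep.int(seq_len(K) - 1L, L * B)
  xcol <- xp[, gidx, drop = FALSE]
  dim(xcol) <- c(C_in * K, L * B)
  list(out = W %*% xcol + b, xcol = xcol, L = L, B = B, K = K, P = P,
       C_in = C_in, padded_base = padded_base, Lp = Lp)
}

conv1d_backward_ref <- function(W, cache, dout) {
  dW <- tcrossprod(dout, cache$xcol)
  db <- rowSums(dout)
  dxcol <- crossprod(W, dout)
  C_in <- cache$C_in; K <- cache$K
  L <- cache$L; B <- cache$B
  dxp <- matrix(0, C_in, cache$Lp * B)
  base <- as.vector(outer(seq_len(L), (seq_len(B) - 1L) * cache$Lp, `+`))
  for (t in seq_len(K)) {
    cols <- base + (t - 1L)
    dxp[, cols] <- dxp[, cols] + dxcol[((t - 1L) * C_in + 1L):(t * C_in), ]
  }
  list(dW = dW, db = db, dx = dxp[, cache$padded_base, drop = FALSE])
}

## Batch normalisation over columns, per channel row.
bn_forward <- function(gamma, beta, x, training, run_mean, run_var,
                       momentum = 0.1, eps = 1e-5) {
  ## momentum = 1/k over a data pass turns the running values into the
  ## exact streaming average (used for post-training recalibration)
  if (training) {
    mu <- rowMeans(x)
    v <- rowMeans((x - mu)^2)
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean
    v <- run_var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (x - mu) * inv
  list(out = gamma * xhat + beta, xhat = xhat, inv = inv,
       run_mean = run_mean, run_var = run_var, training = training)
}

bn_backward <- function(gamma, cache, dout) {
  xhat <- cache$xhat
  dgamma <- rowSums(dout * xhat)
  dbeta <- rowSums(dout)
  dxhat <- dout * gamma
  dx <- if (cache$training) {
    ## batch statistics depend on x
    cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  } else {
    ## eval mode: fixed affine transform per channel
    cache$inv * dxhat
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(x) list(out = pmax(x, 0), mask = x > 0)
relu_backward <- function(cache, dout) dout * cache$mask

dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, mask = NULL))
  mask <- matrix(stats::runif(length(x)) >= rate, nrow(x)) / (1 - rate)
  list(out = x * mask, mask = mask)
}
dropout_backward <- function(cache, dout) {
  if (is.null(cache$mask)) dout else dout * cache$mask
}

## Dense layer on (features x batch) matrices
dense_forward <- function(W, b, x) list(out = W %*% x + b, x = x)
dense_backward <- function(W, cache, dout) {
  list(dW = tcrossprod(dout, cache$x), db = rowSums(dout),
       dx = crossprod(W, dout))
}

## Global average pool (C, L*B) -> (C, B)
gap_forward <- function(x, L, B) {
  out <- x %*% kronecker(diag(B), matrix(1 / L, L, 1))
  list(out = out, L = L, B = B)
}
gap_backward <- function(cache, dout) {
  ## spread the gradient evenly over positions
  dout[, rep(seq_len(cache$B), each = cache$L), drop = FALSE] / cache$L
}

## Global max pool (C, L*B) -> (C, B); gradient routes to the argmax
gmp_forward <- function(x, L, B) {
  C <- nrow(x)
  cols <- seq(1L, by = L, length.out = B)
  best <- x[, cols, drop = FALSE]
  argpos <- matrix(1L, C, B)
  for (l in 2:L) {
    v <- x[, cols + (l - 1L), drop = FALSE]
    upd <- v > best
    best[upd] <- v[upd]
    argpos[upd] <- l
  }
  list(out = best, argpos = argpos, L = L, B = B)
}
gmp_backward <- function(cache, dout) {
  C <- nrow(dout)
  dx <- matrix(0, C, cache$L * cache$B)
  tgt <- cbind(rep(seq_len(C), cache$B),
               rep((seq_len(cache$B) - 1L) * cache$L, each = C) +
                 as.vector(cache$argpos))
  dx[tgt] <- as.vector(dout)
  dx
}

## Non-overlapping average pool along positions with stride s:
## (C, L*B) -> (C, floor(L/s)*B). Trailing positions beyond s*Lout are
## dropped.
pool_forward <- function(x, L, B, s) {
  if (s <= 1L) return(list(out = x, L = L, B = B, s = 1L, Lout = L))
  C <- nrow(x)
  Lout <- L %/% s
  keep <- as.vector(outer(seq_len(Lout * s), (seq_len(B) - 1L) * L, `+`))
  xt <- x[, keep, drop = FALSE]
  dim(xt) <- c(C * s, Lout * B)
  out <- xt[seq_len(C), , drop = FALSE]
  for (j in 2:s) out <- out + xt[((j - 1L) * C + 1L):(j * C), , drop = FALSE]
  list(out = out / s, L = L, B = B, s = s, Lout = Lout, keep = keep)
}
pool_backward <- function(cache, dout) {
  if (cache$s <= 1L) return(dout)
  C <- nrow(dout)
  s <- cache$s
  dxt <- matrix(0, C * s, ncol(dout))
  for (j in seq_len(s)) dxt[((j - 1L) * C + 1L):(j * C), ] <- dout / s
  dim(dxt) <- c(C, cache$Lout * s * cache$B)
  dx <- matrix(0, C, cache$L * cache$B)
  dx[, cache$keep] <- dxt
  dx
}

## Layer norm over rows (features) per column
ln_forward <- function(gamma, beta, x, eps = 1e-5) {
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  v <- colMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, inv, `*`)
  list(out = xhat * gamma + beta, xhat = xhat, inv = inv)
}
ln_backward <- function(gamma, cache, dout) {
  xhat <- cache$xhat
  d <- nrow(dout)
  dgamma <- rowSums(dout * xhat)
  dbeta <- rowSums(dout)
  dxhat <- dout * gamma
  dx <- sweep(dxhat, 2, colMeans(dxhat)) -
    xhat * matrix(colMeans(dxhat * xhat), nrow = d, ncol = ncol(dout),
                  byrow = TRUE)
  dx <- sweep(dx, 2, cache$inv, `*`)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

sigmoid <- function(x) 1 / (1 + exp(-x))
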