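# Minimal encoder-decoder convolutional network engine.
#
# A small U-net style network (two 2x-downsampling stages, skip
# connections, 3x3 convolutions, ReLU, 1x1 classification head) with
# hand-written backpropagation.  Feature maps are stored as (H*W) x C
# matrices in R's column-major pixel order, so every convolution becomes
# one dense matrix product (im2col) that the BLAS executes; this keeps
# CPU training of the reduced-resolution phantom models in the
# minutes range without compiled code.

# Cache of index vectors shared by all layers operating on an H x W grid.
grid_cache <- new.env(parent = emptyenv())

grid_indices <- function(H, W) {
  key <- paste(H, W, sep = "x")
  if (!is.null(grid_cache[[key]])) return(grid_cache[[key]])
  r <- rep(seq_len(H), W)
  cc <- rep(seq_len(W), each = H)
  # 3x3 neighbourhood offsets (zero padding): idx[[o]][i] = flat source
  # index for output pixel i, or 0 outside the frame.
  conv <- list()
  o <- 0L
  for (dx in -1:1) for (dy in -1:1) {
    o <- o + 1L
    rr <- r + dy; c2 <- cc + dx
    ok <- rr >= 1L & rr <= H & c2 >= 1L & c2 <= W
    idx <- integer(H * W)
    idx[ok] <- rr[ok] + (c2[ok] - 1L) * H
    conv[[o]] <- idx
  }
  out <- list(conv = conv)
  if (H %% 2L == 0L && W %% 2L == 0L) {
    H2 <- H %/% 2L; W2 <- W %/% 2L
    r2 <- rep(seq_len(H2), W2)
    c2 <- rep(seq_len(W2), each = H2)
    # 2x2 pooling: the 4 children of each coarse pixel.
    out$pool <- lapply(list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L)),
                       function(d) (2L * r2 - 1L + d[1]) + (2L * c2 - 2L + d[2]) * H)
    # Nearest-neighbour 2x upsampling: coarse source of each fine pixel.
    out$up <- ((r + 1L) %/% 2L) + (((cc + 1L) %/% 2L) - 1L) * H2
  }
  grid_cache[[key]] <- out
  out
}

im2col <- function(M, conv_idx) {
  n <- nrow(M); C <- ncol(M)
  P <- matrix(0, n, 9L * C)
  for (o in seq_len(9L)) {
    idx <- conv_idx[[o]]
    ok <- idx > 0L
    P[ok, ((o - 1L) * C + 1L):(o * C)] <- M[idx[ok], , drop = FALSE]
  }
  P
}

col2im <- function(dP, conv_idx, C) {
  n <- nrow(dP)
  dM <- matrix(0, n, C)
  for (o in seq_len(9L)) {
    idx <- conv_idx[[o]]
    ok <- idx > 0L
    dM[idx[ok], ] <- dM[idx[ok], , drop = FALSE] +
      dP[ok, ((o - 1L) * C + 1L):(o * C), drop = FALSE]
  }
  dM
}

conv3_forward <- function(M, W, b, conv_idx) {
  P <- im2col(M, conv_idx)
  Y <- P %*% W
  Y <- sweep(Y, 2L, b, "+")
  list(Y = Y, P = P)
}

conv3_backward <- function(dY, P, W, Cin, conv_idx) {
  list(dW = crossprod(P, dY), db = colSums(dY),
       dM = col2im(dY %*% t(W), conv_idx, Cin))
}

pool_forward <- function(M, pool_idx) {
  (M[pool_idx[[1]], , drop = FALSE] + M[pool_idx[[2]], , drop = FALSE] +
   M[pool_idx[[3]], , drop = FALSE] + M[pool_idx[[4]], , drop = FALSE]) / 4
}

pool_backward <- function(dY, pool_idx, n_fine) {
  dM <- matrix(0, n_fine, ncol(dY))
  for (k in 1:4) dM[pool_idx[[k]], ] <- dY / 4
  dM
}

up_forward <- function(M, up_idx) M[up_idx, , drop = FALSE]

up_backward <- function(dY, up_idx) rowsum(dY, up_idx, reorder = TRUE)

relu <- function(x) {
  x[x < 0] <- 0
  x
}

softmax_rows <- function(z) {
  m <- z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  e <- exp(z - m)
  e / rowSums(e)
}

# --- network definition ---------------------------------------------------

# Layer channel plan for base width b and Cin input channels:
#   e1a Cin->b, e1b b->b | pool | e2a b->2b, e2b 2b->2b | pool |
#   m1 2b->4b, m2 4b->4b | up+skip(2b) | d2 6b->2b | up+skip(b) |
#   d1 3b->b | head b->n_class (1x1)
unet_shapes <- function(in_ch, base, n_class) {
  b <- base
  list(e1a = c(9 * in_ch, b), e1b = c(9 * b, b),
       e2a = c(9 * b, 2 * b), e2b = c(9 * 2 * b, 2 * b),
       m1 = c(9 * 2 * b, 4 * b), m2 = c(9 * 4 * b, 4 * b),
       d2 = c(9 * 6 * b, 2 * b), d1 = c(9 * 3 * b, b),
       head = c(b, n_class))
}

unet_init <- function(in_ch, base, n_class, seed) {
  shapes <- unet_shapes(in_ch, base, n_class)
  with_seed(seed, {
    params <- lapply(shapes, function(s) {
      list(W = matrix(stats::rnorm(prod(s), sd = sqrt(2 / s[1])), s[1], s[2]),
           b = rep(0, s[2]))
    })
    params
  })
}

unet_forward <- function(params, X, H, W, keep_cache = FALSE) {
  g1 <- grid_indices(H, W)
  g2 <- grid_indices(H %/% 2L, W %/% 2L)
  g3 <- grid_indices(H %/% 4L, W %/% 4L)
  cv <- function(nm, M, g) conv3_forward(M, params[[nm]]$W, params[[nm]]$b, g$conv)
  f_e1a <- cv("e1a", X, g1);  a_e1a <- relu(f_e1a$Y)
  f_e1b <- cv("e1b", a_e1a, g1); a_e1b <- relu(f_e1b$Y)
  p1 <- pool_forward(a_e1b, g1$pool)
  f_e2a <- cv("e2a", p1, g2); a_e2a <- relu(f_e2a$Y)
  f_e2b <- cv("e2b", a_e2a, g2); a_e2b <- relu(f_e2b$Y)
  p2 <- pool_forward(a_e2b, g2$pool)
  f_m1 <- cv("m1", p2, g3); a_m1 <- relu(f_m1$Y)
  f_m2 <- cv("m2", a_m1, g3); a_m2 <- relu(f_m2$Y)
  u2 <- cbind(up_forward(a_m2, g2$up), a_e2b)
  f_d2 <- cv("d2", u2, g2); a_d2 <- relu(f_d2$Y)
  u1 <- cbind(up_forward(a_d2, g1$up), a_e1b)
  f_d1 <- cv("d1", u1, g1); a_d1 <- relu(f_d1$Y)
  z <- sweep(a_d1 %*% params$head$W, 2L, params$head$b, "+")
  out <- list(z = z, probs = softmax_rows(z))
  if (keep_cache)
    out$cache <- list(X = X, H = H, W = W,
                      f = list(e1a = f_e1a, e1b = f_e1b, e2a = f_e2a,
                               e2b = f_e2b, m1 = f_m1, m2 = f_m2,
                               d2 = f_d2, d1 = f_d1),
                      a = list(e1a = a_e1a, e1b = a_e1b, e2a = a_e2a,
                               e2b = a_e2b, m1 = a_m1, m2 = a_m2,
                               d2 = a_d2, d1 = a_d1))
  out
}

# Backward pass from the gradient dz at the (pre-softmax) head output.
unet_backward <- function(params, fwd, dz) {
  cache <- fwd$cache
  H <- cache$H; W <- cache$W
  g1 <- grid_indices(H, W)
  g2 <- grid_indices(H %/% 2L, W %/% 2L)
  g3 <- grid_indices(H %/% 4L, W %/% 4L)
  f <- cache$f; a <- cache$a
  grads <- list()
  grads$head <- list(dW = crossprod(a$d1, dz), db = colSums(dz))
  d <- dz %*% t(params$head$W)
  d <- d * (f$d1$Y > 0)
  bk <- conv3_backward(d, f$d1$P, params$d1$W, ncol(params$d1$W) * 3L, g1$conv)
  grads$d1 <- bk[c("dW", "db")]
  b <- ncol(params$e1a$W)
  d_u1 <- bk$dM[, seq_len(2L * b), drop = FALSE]
  d_skip1 <- bk$dM[, (2L * b + 1L):(3L * b), drop = FALSE]
  d <- up_backward(d_u1, g1$up)
  d <- d * (f$d2$Y > 0)
  bk <- conv3_backward(d, f$d2$P, params$d2$W, 6L * b, g2$conv)
  grads$d2 <- bk[c("dW", "db")]
  d_u2 <- bk$dM[, seq_len(4L * b), drop = FALSE]
  d_skip2 <- bk$dM[, (4L * b + 1L):(6L * b), drop = FALSE]
  d <- up_backward(d_u2, g2$up)
  d <- d * (f$m2$Y > 0)
  bk <- conv3_backward(d, f$m2$P, params$m2$W, 4L * b, g3$conv)
  grads$m2 <- bk[c("dW", "db")]
  d <- bk$dM * (f$m1$Y > 0)
  bk <- conv3_backward(d, f$m1$P, params$m1$W, 2L * b, g3$conv)
  grads$m1 <- bk[c("dW", "db")]
  d <- pool_backward(bk$dM, g2$pool, nrow(a$e2b))
  d <- d + d_skip2
  d <- d * (f$e2b$Y > 0)
  bk <- conv3_backward(d, f$e2b$P, params$e2b$W, 2L * b, g2$conv)
  grads$e2b <- bk[c("dW", "db")]
  d <- bk$dM * (f$e2a$Y > 0)
  bk <- conv3_backward(d, f$e2a$P, params$e2a$W, b, g2$conv)
  grads$e2a <- bk[c("dW", "db")]
  d <- pool_backward(bk$dM, g1$pool, nrow(a$e1b))
  d <- d + d_skip1
  d <- d * (f$e1b$Y > 0)
  bk <- conv3_backward(d, f$e1b$P, params$e1b$W, b, g1$conv)
  grads$e1b <- bk[c("dW", "db")]
  d <- bk$dM * (f$e1a$Y > 0)
  bk <- conv3_backward(d, f$e1a$P, params$e1a$W, ncol(cache$X), g1$conv)
  grads$e1a <- bk[c("dW", "db")]
  grads
}

# --- loss: cross-entropy + soft Dice --------------------------------------

# target: integer class index per pixel (1..C).  Returns loss value and
# dz (gradient at the pre-softmax head output).
seg_loss <- function(probs, target, n_class, dice_weight = 1, eps = 1) {
  n <- length(target)
  Y <- matrix(0, n, n_class)
  Y[cbind(seq_len(n), target)] <- 1
  p_t <- probs[cbind(seq_len(n), target)]
  ce <- -mean(log(pmax(p_t, 1e-12)))
  dz <- (probs - Y) / n
  loss <- ce
  if (dice_weight > 0) {
    num <- 2 * colSums(probs * Y) + eps
    den <- colSums(probs) + colSums(Y) + eps
    loss <- loss + dice_weight * (1 - mean(num / den))
    # dL/dp via the quotient rule, then through the softmax Jacobian.
    g <- -(dice_weight / n_class) *
      (2 * sweep(Y, 2L, den, "/") - matrix(num / den^2, n, n_class, byrow = TRUE))
    dz <- dz + probs * (g - rowSums(g * probs))
  }
  list(loss = loss, dz = dz)
}

# --- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  lapply(params, function(p) list(
    mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (nm in names(params)) {
    g <- grads[[nm]]
    s <- state[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    params[[nm]]$W <- params[[nm]]$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

# Sum two gradient lists (for mini-batch accumulation).
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(a)) {
    a[[nm]]$dW <- a[[nm]]$dW + b[[nm]]$dW
    a[[nm]]$db <- a[[nm]]$db + b[[nm]]$db
  }
  a
}

grads_scale <- function(a, s) {
  for (nm in names(a)) {
    a[[nm]]$dW <- a[[nm]]$dW * s
    a[[nm]]$db <- a[[nm]]$db * s
  }
  a
}
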