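# Minimal 1D convolutional network engine: im2col convolutions, Hardswish
# activations, inverted dropout, hand-written backprop, Adam. Written on base
# matrix ops (BLAS does the heavy lifting); small feature vectors (length 192)
# and modest channel counts keep this fast enough for desk-scale training.

hardswish <- function(x) {
  out <- cpp_hardswish(as.numeric(x))
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

hardswish_grad <- function(x) {
  out <- cpp_hardswish_grad(as.numeric(x))
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

dropout_mask <- function(n_row, n_col, p) {
  matrix(cpp_dropout_mask(n_row * n_col, p), n_row, n_col)
}

# X: array [B, L, Cin] -> patches [B*L, k*Cin], zero ('same') padding.
# Row r of the output corresponds to (b, l) with b varying fastest.
im2col <- function(A, k) {
  d <- dim(A)
  cpp_im2col(as.numeric(A), d[1], d[2], d[3], k)
}

col2im <- function(dP, B, L, Cin, k) {
  cpp_col2im(dP, B, L, Cin, k)
}

# Forward through one convolutional trunk.
# x: matrix [B, L]; layers: list of list(W [k*Cin, Cout], b [Cout]).
# Returns list(z = branch features [B, Z_t], cache).
trunk_forward <- function(x, layers, kernel, branch, dropout_p,
                          dropout_on, keep_cache) {
  B <- nrow(x); L <- ncol(x)
  A <- array(x, c(B, L, 1))
  caches <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    Cin <- dim(A)[3]
    P <- im2col(A, kernel)
    Z <- P %*% layers[[l]]$W +
      matrix(layers[[l]]$b, nrow(P), length(layers[[l]]$b), byrow = TRUE)
    H <- hardswish(Z)
    M <- NULL
    if (dropout_on && dropout_p > 0) {
      M <- dropout_mask(nrow(H), ncol(H), dropout_p)
      H <- H * M
    }
    if (keep_cache) caches[[l]] <- list(P = P, Z = Z, M = M, Cin = Cin)
    A <- array(H, c(B, L, ncol(H)))
  }
  C <- dim(A)[3]
  if (branch == "gap") {
    z <- matrix(0, B, C)
    for (cc in seq_len(C)) z[, cc] <- rowMeans(A[, , cc, drop = FALSE])
  } else {
    z <- A
    dim(z) <- c(B, L * C)
  }
  list(z = z, caches = caches, B = B, L = L, C = C)
}

trunk_backward <- function(dz, fwd, layers, kernel, branch) {
  B <- fwd$B; L <- fwd$L; C <- fwd$C
  if (branch == "gap") {
    dA <- array(0, c(B, L, C))
    for (cc in seq_len(C)) dA[, , cc] <- dz[, cc] / L
  } else {
    dA <- dz
    dim(dA) <- c(B, L, C)
  }
  grads <- vector("list", length(layers))
  for (l in rev(seq_along(layers))) {
    cache <- fwd$caches[[l]]
    dH <- dA
    dim(dH) <- c(B * L, dim(dA)[3])
    if (!is.null(cache$M)) dH <- dH * cache$M
    dZ <- dH * hardswish_grad(cache$Z)
    grads[[l]] <- list(W = crossprod(cache$P, dZ), b = colSums(dZ))
    dP <- tcrossprod(dZ, layers[[l]]$W)
    dA <- col2im(dP, B, L, cache$Cin, kernel)
  }
  grads
}

head_forward <- function(z, head, dropout_p, dropout_on, keep_cache) {
  Z1 <- z %*% head$W1 + matrix(head$b1, nrow(z), length(head$b1),
                               byrow = TRUE)
  H1 <- hardswish(Z1)
  M <- NULL
  if (dropout_on && dropout_p > 0) {
    M <- dropout_mask(nrow(H1), ncol(H1), dropout_p)
    H1 <- H1 * M
  }
  out <- H1 %*% head$W2 + matrix(head$b2, nrow(H1), length(head$b2),
                                 byrow = TRUE)
  cache <- if (keep_cache) list(z = z, Z1 = Z1, H1 = H1, M = M) else NULL
  list(out = out, cache = cache)
}

head_backward <- function(dout, cache, head) {
  dW2 <- crossprod(cache$H1, dout)
  db2 <- colSums(dout)
  dH1 <- tcrossprod(dout, head$W2)
  if (!is.null(cache$M)) dH1 <- dH1 * cache$M
  dZ1 <- dH1 * hardswish_grad(cache$Z1)
  dW1 <- crossprod(cache$z, dZ1)
  db1 <- colSums(dZ1)
  dz <- tcrossprod(dZ1, head$W1)
  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2), dz = dz)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}

init_weight <- function(n_in, n_out) {
  matrix(rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
}

adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(params, grads, state, lr, t, lr_scale = NULL,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    scale <- if (!is.null(lr_scale) && !is.null(lr_scale[[nm]])) {
      lr_scale[[nm]]
    } else 1
    params[[nm]] <- params[[nm]] - lr * scale * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}
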