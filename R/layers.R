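# Low-level differentiable layers.
#
# All feature maps use the array layout (H, W, C, N): height and width
# fastest, then channel, then batch. Forward functions return the output plus
# a cache; each backward consumes the cache and the upstream gradient and
# returns gradients for inputs and parameters. Convolutions are computed as
# im2col matrix products so the heavy lifting stays in BLAS.

pad_spatial <- function(X, p) {
  if (p == 0) return(X)
  d <- dim(X)
  Xp <- array(0, dim = c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  Xp[(p + 1):(p + d[1]), (p + 1):(p + d[2]), , ] <- X
  Xp
}

unpad_spatial <- function(Xp, p, H, W) {
  if (p == 0) return(Xp)
  Xp[(p + 1):(p + H), (p + 1):(p + W), , , drop = FALSE]
}

# W: (Cout) x (K*K*Cin); b: length Cout or NULL. im2col columns are ordered
# (kh, kw, c); the C++ kernels avoid the aperm/allocation churn of doing this
# slice-wise in R.
conv_forward <- function(X, W, b, K, pad) {
  d <- dim(X)
  Hout <- d[1] + 2 * pad - K + 1
  Wout <- d[2] + 2 * pad - K + 1
  Xp <- pad_spatial(X, pad)
  dp <- dim(Xp)
  col <- im2col_hwcn(Xp, dp[1], dp[2], dp[3], dp[4], K, Hout, Wout)
  outM <- tcrossprod(col, W)                        # (HWN) x Cout
  if (!is.null(b)) outM <- sweep(outM, 2, b, `+`)
  out <- swap34(outM, Hout, Wout, d[4], ncol(outM)) # -> (H, W, Cout, N)
  list(out = out,
       cache = list(col = col, dimX = d, K = K, pad = pad,
                    Hout = Hout, Wout = Wout, W = W, has_b = !is.null(b)))
}

conv_backward <- function(dOut, cache) {
  K <- cache$K; d <- cache$dimX
  Hout <- cache$Hout; Wout <- cache$Wout
  Cout <- dim(dOut)[3]
  dOutM <- matrix(swap34(dOut, Hout, Wout, Cout, d[4]),
                  nrow = Hout * Wout * d[4])        # (HWN) x Cout
  dW <- crossprod(dOutM, cache$col)
  db <- if (cache$has_b) colSums(dOutM) else NULL
  dcol <- dOutM %*% cache$W
  dXp <- col2im_hwcn(dcol, d[1] + 2 * cache$pad, d[2] + 2 * cache$pad,
                     d[3], d[4], K, Hout, Wout)
  dX <- unpad_spatial(dXp, cache$pad, d[1], d[2])
  list(dX = dX, dW = dW, db = db)
}

# Batch normalization per channel over (H, W, N); fused C++ kernels
bn_forward <- function(X, gamma, beta, run_mean, run_var,
                       training, momentum = 0.1, eps = 1e-5) {
  d <- dim(X)
  if (training) {
    st <- bn_stats_hwcn(X, d[1], d[2], d[3], d[4])
    mu <- st$mu
    va <- st$va
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * va
  } else {
    mu <- run_mean
    va <- run_var
  }
  inv_std <- 1 / sqrt(va + eps)
  fw <- bn_fwd_hwcn(X, d[1], d[2], d[3], d[4], gamma, beta, mu, inv_std)
  list(out = fw$Y,
       cache = list(xhat = fw$xhat, inv_std = inv_std, gamma = gamma,
                    dimX = d),
       run_mean = run_mean, run_var = run_var)
}

bn_backward <- function(dOut, cache) {
  d <- cache$dimX
  bn_bwd_hwcn(dOut, cache$xhat, d[1], d[2], d[3], d[4],
              cache$gamma, cache$inv_std)
}

relu_forward <- function(X) list(out = pmax(X, 0), cache = X > 0)
relu_backward <- function(dOut, cache) dOut * cache

sigmoid <- function(x) 1 / (1 + exp(-x))

# Squeeze-excitation-style channel attention.
# att parameters: W1 (C/r x C), b1, W2 (C x C/r), b2, shared by both the
# average-pool and max-pool branches.
attention_forward <- function(X, att) {
  d <- dim(X)
  HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  Xm <- matrix(X, nrow = HW)                        # columns are (c, n) pairs
  Ca <- matrix(colMeans(Xm), nrow = C)              # C x N
  amax <- max.col(t(Xm), ties.method = "first")     # argmax per (c, n)
  Cm <- matrix(Xm[cbind(amax, seq_len(C * N))], nrow = C)

  mlp <- function(inp) {
    a1 <- sweep(att$W1 %*% inp, 1, att$b1, `+`)     # (C/r) x N
    h <- pmax(a1, 0)
    z <- sweep(att$W2 %*% h, 1, att$b2, `+`)
    list(z = z, h = h, a1 = a1, inp = inp)
  }
  ma <- mlp(Ca)
  mm <- mlp(Cm)
  S <- sigmoid(ma$z + mm$z)                         # C x N
  out <- X * array(rep(as.vector(S), each = HW), dim = d)
  list(out = out, S = S,
       cache = list(X = X, S = S, ma = ma, mm = mm, amax = amax,
                    HW = HW, C = C, N = N, att = att, dimX = d))
}

attention_backward <- function(dOut, cache) {
  X <- cache$X; S <- cache$S; att <- cache$att
  HW <- cache$HW; C <- cache$C; N <- cache$N
  Sb <- array(rep(as.vector(S), each = HW), dim = cache$dimX)
  dX <- dOut * Sb
  dS <- matrix(colSums(matrix(dOut * X, nrow = HW)), nrow = C)
  dZV <- dS * S * (1 - S)

  back_mlp <- function(m, dz) {
    dW2 <- tcrossprod(dz, m$h)
    db2 <- rowSums(dz)
    dh <- crossprod(att$W2, dz)
    da1 <- dh * (m$a1 > 0)
    dW1 <- tcrossprod(da1, m$inp)
    db1 <- rowSums(da1)
    dinp <- crossprod(att$W1, da1)
    list(dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2, dinp = dinp)
  }
  ga <- back_mlp(cache$ma, dZV)
  gm <- back_mlp(cache$mm, dZV)

  # average branch spreads evenly; max branch routes to the argmax positions
  dX <- dX + array(rep(as.vector(ga$dinp) / HW, each = HW), dim = cache$dimX)
  lin <- cache$amax + (seq_len(C * N) - 1) * HW
  dX[lin] <- dX[lin] + as.vector(gm$dinp)

  list(dX = dX,
       dW1 = ga$dW1 + gm$dW1, db1 = ga$db1 + gm$db1,
       dW2 = ga$dW2 + gm$dW2, db2 = ga$db2 + gm$db2)
}

linear_forward <- function(X, W, b) {
  out <- W %*% X + b                # b recycles down each column
  list(out = out, cache = list(X = X, W = W))
}

linear_backward <- function(dOut, cache) {
  list(dX = crossprod(cache$W, dOut),
       dW = tcrossprod(dOut, cache$X),
       db = rowSums(dOut))
}

softmax_cols <- function(logits) {
  z <- sweep(logits, 2, apply(logits, 2, max), `-`)
  e <- exp(z)
  sweep(e, 2, colSums(e), `/`)
}
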