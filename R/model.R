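#' Model configuration for the multi-task residual network
#'
#' The backbone follows a fixed plan: a shared residual block (3x3
#' convolution 8->16 channels, stride 1, padding 2, channel attention, batch
#' norm, ReLU, projected identity shortcut), one residual block per task
#' (16->32 channels) whose feature maps are blended by a learnable 2x2
#' cross-fusion matrix, then per-task fully connected layers
#' flatten->128->64->head. Task A (component identification) ends in a
#' 3-way softmax; task B (concentration prediction) regresses the
#' (n-propanol, ethanol) pair. With padding 2 and kernel 3 every convolution
#' grows the spatial size by 2, so a 16x16 input reaches the flatten stage
#' at 32 x 20 x 20. No pooling or dropout is used.
#'
#' @param input_n Input spatial size (H = W), sqrt of the window width.
#' @param reduction Channel-attention bottleneck ratio r (attention operates
#'   on 16 channels; default r = 4 gives a 16->4->16 bottleneck).
#' @param use_attention,use_cross_fusion Ablation toggles.
#' @param loss \code{"dynamic"} (learnable uncertainty weighting) or
#'   \code{"sum"} (direct sum of the three losses).
#' @param sigma_init Initial (sigma_p, sigma_e, sigma_ci) for the dynamic
#'   loss; \code{c(1, 1, 1)} leaves the scales uninitialized in the sense of
#'   the MRCA-2 variant, other values encode prior experience (MRCA-1).
#' @param scale_targets Divide ppm targets by this factor inside the
#'   optimizer (predictions are always returned in ppm). 1 = raw ppm.
#' @return An \code{mrca_config} list.
#' @export
mrca_config <- function(input_n = 16, reduction = 4,
                        use_attention = TRUE, use_cross_fusion = TRUE,
                        loss = c("dynamic", "sum"), sigma_init = c(1, 1, 1),
                        scale_targets = 100) {
  loss <- match.arg(loss)
  if (16 %% reduction != 0)
    stopf("attention channels (16) not divisible by reduction %d", reduction)
  if (any(sigma_init <= 0)) stopf("sigma_init must be positive")
  structure(list(input_n = input_n, reduction = reduction,
                 use_attention = use_attention,
                 use_cross_fusion = use_cross_fusion,
                 loss = loss, sigma_init = sigma_init,
                 scale_targets = scale_targets),
            class = "mrca_config")
}

he_init <- function(nout, nin) {
  matrix(stats::rnorm(nout * nin, sd = sqrt(2 / nin)), nrow = nout)
}

#' Initialize network parameters and batch-norm state
#'
#' @param config An \code{mrca_config}.
#' @param seed Integer seed (He-normal weight draws are deterministic in it).
#' @return List with \code{params}, \code{state} (batch-norm running
#'   moments), and \code{config}.
#' @export
mrca_init <- function(config = mrca_config(), seed = 1L) {
  n <- config$input_n
  F2 <- 32 * (n + 4)^2
  r <- config$reduction
  with_seed(seed, {
    params <- list(
      conv1_W = he_init(16, 9 * 8),
      att_W1 = he_init(16 / r, 16), att_b1 = numeric(16 / r),
      att_W2 = he_init(16, 16 / r), att_b2 = numeric(16),
      bn1_gamma = rep(1, 16), bn1_beta = numeric(16),
      skip1_W = he_init(16, 8)
    )
    for (t in c("A", "B")) {
      params[[paste0("conv2", t, "_W")]] <- he_init(32, 9 * 16)
      params[[paste0("bn2", t, "_gamma")]] <- rep(1, 32)
      params[[paste0("bn2", t, "_beta")]] <- numeric(32)
      params[[paste0("skip2", t, "_W")]] <- he_init(32, 16)
      params[[paste0("fc1", t, "_W")]] <- he_init(128, F2)
      params[[paste0("fc1", t, "_b")]] <- numeric(128)
      params[[paste0("fc2", t, "_W")]] <- he_init(64, 128)
      params[[paste0("fc2", t, "_b")]] <- numeric(64)
    }
    params$fc3A_W <- he_init(3, 64); params$fc3A_b <- numeric(3)
    params$fc3B_W <- he_init(2, 64); params$fc3B_b <- numeric(2)
    params$alpha <- diag(2)                       # identity start
    if (config$loss == "dynamic")
      params$log_sigma <- log(config$sigma_init)  # (sigma_p, sigma_e, sigma_ci)
  })
  state <- list(
    bn1_mean = numeric(16), bn1_var = rep(1, 16),
    bn2A_mean = numeric(32), bn2A_var = rep(1, 32),
    bn2B_mean = numeric(32), bn2B_var = rep(1, 32)
  )
  list(params = params, state = state, config = config)
}

#' Channel attention (squeeze-excitation with average and max pooling)
#'
#' Per channel, a global average \eqn{C_a} and global maximum \eqn{C_m} are
#' pooled over the spatial axes, passed through a shared two-layer
#' bottleneck (1x1 channel-mixing transforms with a ReLU between), summed
#' and squashed by a sigmoid into per-channel weights \eqn{S \in (0,1)} that
#' multiply the input map.
#'
#' @param X Array (H, W, C, N) or (H, W, C) for a single sample.
#' @param att List with \code{W1} (C/r x C), \code{b1}, \code{W2} (C x C/r),
#'   \code{b2}.
#' @return Array of the same shape as \code{X}: \eqn{S \odot X}.
#' @export
channel_attention <- function(X, att) {
  single <- length(dim(X)) == 3
  if (single) dim(X) <- c(dim(X), 1)
  C <- dim(X)[3]
  if (nrow(att$W1) < 1 || C %% nrow(att$W1) != 0 || ncol(att$W1) != C)
    stopf("attention bottleneck incompatible with %d channels", C)
  out <- attention_forward(X, att)$out
  if (single) dim(out) <- dim(out)[1:3]
  out
}

#' Cross-fusion of two task feature maps
#'
#' Soft parameter sharing: \eqn{T_A' = \alpha_{AA} T_A + \alpha_{AB} T_B}
#' and \eqn{T_B' = \alpha_{BA} T_A + \alpha_{BB} T_B}. With \eqn{\alpha = I}
#' the fusion is an exact pass-through.
#'
#' @param TA,TB Arrays of identical shape.
#' @param alpha 2x2 numeric matrix (learnable; unconstrained).
#' @return List with elements \code{TA} and \code{TB} (the fused maps).
#' @export
cross_fusion <- function(TA, TB, alpha) {
  if (!identical(dim(TA), dim(TB))) stopf("TA and TB shapes differ")
  stopifnot(identical(dim(alpha), c(2L, 2L)))
  list(TA = alpha[1, 1] * TA + alpha[1, 2] * TB,
       TB = alpha[2, 1] * TA + alpha[2, 2] * TB)
}

#' Learnable dynamic weighted total loss
#'
#' \deqn{L = \frac{1}{2\sigma_p^2} L_p + \frac{1}{2\sigma_e^2} L_e +
#'   \frac{1}{\sigma_{ci}^2} L_{ci} + \log_{10}(\sigma_p \sigma_e \sigma_{ci})}
#' The two regression losses carry the 1/(2 sigma^2) factor and the
#' classification loss 1/sigma^2; the base-10 log product regularizes the
#' scales.
#'
#' @param Lp,Le,Lci Non-negative component losses (n-propanol MSE, ethanol
#'   MSE, classification cross-entropy).
#' @param sigma Positive length-3 vector (sigma_p, sigma_e, sigma_ci).
#' @return Scalar total loss.
#' @export
dynamic_weighted_loss <- function(Lp, Le, Lci, sigma) {
  if (any(c(Lp, Le, Lci) < 0)) stopf("component losses must be >= 0")
  if (any(sigma <= 0)) stopf("sigma must be positive")
  Lp / (2 * sigma[1]^2) + Le / (2 * sigma[2]^2) + Lci / sigma[3]^2 +
    log10(sigma[1] * sigma[2] * sigma[3])
}

# gradient of the dynamic loss wrt log sigma, given fixed component losses
dynamic_loss_grad_logsigma <- function(Lp, Le, Lci, log_sigma) {
  s2 <- exp(2 * log_sigma)
  c(-Lp / s2[1] + 1 / log(10),
    -Le / s2[2] + 1 / log(10),
    -2 * Lci / s2[3] + 1 / log(10))
}

#' Direct sum of the component losses (the MRCA-3 ablation)
#'
#' @inheritParams dynamic_weighted_loss
#' @return \code{Lp + Le + Lci}.
#' @export
sum_loss <- function(Lp, Le, Lci) {
  if (any(c(Lp, Le, Lci) < 0)) stopf("component losses must be >= 0")
  Lp + Le + Lci
}

# Full forward pass. X: (H, W, 8, N). Returns heads and caches for backprop.
# bn_momentum: running-moment update rate while training (1 = replace with
# the current batch statistics, used for post-training recalibration).
mrca_forward <- function(params, state, X, config, training = FALSE,
                         bn_momentum = 0.1) {
  d <- dim(X)
  if (d[1] != d[2]) stopf("input feature maps must be square")
  if (d[4] < 1) stopf("batch is empty")
  cache <- list()

  # convolutions carry no bias: each is followed by batch norm, which
  # absorbs any per-channel shift (the bias gradient is identically zero)
  c1 <- conv_forward(X, params$conv1_W, NULL, K = 3, pad = 2)
  cache$c1 <- c1$cache
  x1 <- c1$out
  if (config$use_attention) {
    at <- attention_forward(x1, list(W1 = params$att_W1, b1 = params$att_b1,
                                     W2 = params$att_W2, b2 = params$att_b2))
    cache$att <- at$cache
    x1 <- at$out
  }
  b1 <- bn_forward(x1, params$bn1_gamma, params$bn1_beta,
                   state$bn1_mean, state$bn1_var, training, bn_momentum)
  cache$bn1 <- b1$cache
  if (training) { state$bn1_mean <- b1$run_mean; state$bn1_var <- b1$run_var }
  sk1 <- conv_forward(pad_spatial(X, 1), params$skip1_W, NULL, K = 1, pad = 0)
  cache$sk1 <- sk1$cache
  r1 <- relu_forward(b1$out + sk1$out)
  cache$r1 <- r1$cache
  h1 <- r1$out

  h1p <- pad_spatial(h1, 1)
  branch <- list()
  for (t in c("A", "B")) {
    cv <- conv_forward(h1, params[[paste0("conv2", t, "_W")]], NULL,
                       K = 3, pad = 2)
    branch[[t]] <- cv$out
    cache[[paste0("c2", t)]] <- cv$cache
  }
  if (config$use_cross_fusion) {
    fused <- cross_fusion(branch$A, branch$B, params$alpha)
    cache$fusion_in <- branch
    branch <- list(A = fused$TA, B = fused$TB)
  }
  heads <- list()
  for (t in c("A", "B")) {
    b2 <- bn_forward(branch[[t]], params[[paste0("bn2", t, "_gamma")]],
                     params[[paste0("bn2", t, "_beta")]],
                     state[[paste0("bn2", t, "_mean")]],
                     state[[paste0("bn2", t, "_var")]], training, bn_momentum)
    cache[[paste0("bn2", t)]] <- b2$cache
    if (training) {
      state[[paste0("bn2", t, "_mean")]] <- b2$run_mean
      state[[paste0("bn2", t, "_var")]] <- b2$run_var
    }
    sk <- conv_forward(h1p, params[[paste0("skip2", t, "_W")]], NULL,
                       K = 1, pad = 0)
    cache[[paste0("sk2", t)]] <- sk$cache
    rl <- relu_forward(b2$out + sk$out)
    cache[[paste0("r2", t)]] <- rl$cache
    flat <- matrix(rl$out, ncol = d[4])
    f1 <- linear_forward(flat, params[[paste0("fc1", t, "_W")]],
                         params[[paste0("fc1", t, "_b")]])
    a1 <- relu_forward(f1$out)
    f2 <- linear_forward(a1$out, params[[paste0("fc2", t, "_W")]],
                         params[[paste0("fc2", t, "_b")]])
    a2 <- relu_forward(f2$out)
    f3 <- linear_forward(a2$out, params[[paste0("fc3", t, "_W")]],
                         params[[paste0("fc3", t, "_b")]])
    cache[[paste0("fc", t)]] <- list(f1 = f1$cache, a1 = a1$cache,
                                     f2 = f2$cache, a2 = a2$cache,
                                     f3 = f3$cache, dim_conv = dim(rl$out))
    heads[[t]] <- f3$out
  }
  probs <- softmax_cols(heads$A)
  list(logits = heads$A, probs = probs, conc = heads$B,
       cache = cache, state = state)
}

# Backward pass: head gradients in, parameter gradients out.
mrca_backward <- function(params, cache, dlogits, dconc, config,
                          bufs = NULL) {
  g <- list()
  dbranch <- list()
  for (t in c("A", "B")) {
    fc <- cache[[paste0("fc", t)]]
    dhead <- if (t == "A") dlogits else dconc
    l3 <- linear_backward(dhead, fc$f3)
    g[[paste0("fc3", t, "_W")]] <- l3$dW
    g[[paste0("fc3", t, "_b")]] <- l3$db
    da2 <- relu_backward(l3$dX, fc$a2)
    l2 <- linear_backward(da2, fc$f2)
    g[[paste0("fc2", t, "_W")]] <- l2$dW
    g[[paste0("fc2", t, "_b")]] <- l2$db
    da1 <- relu_backward(l2$dX, fc$a1)
    bname <- paste0("fc1", t, "_W")
    if (!is.null(bufs)) {
      # reuse a preallocated buffer for the largest gradient matrix
      tcrossprod_into(bufs[[bname]], da1, fc$f1$X)
      g[[bname]] <- bufs[[bname]]
      l1 <- list(dX = crossprod(fc$f1$W, da1))
    } else {
      l1 <- linear_backward(da1, fc$f1)
      g[[bname]] <- l1$dW
    }
    g[[paste0("fc1", t, "_b")]] <- rowSums(da1)
    dflat <- array(l1$dX, dim = fc$dim_conv)
    drelu <- relu_backward(dflat, cache[[paste0("r2", t)]])
    sk <- conv_backward(drelu, cache[[paste0("sk2", t)]])
    g[[paste0("skip2", t, "_W")]] <- sk$dW
    if (is.null(g$dh1p)) g$dh1p <- sk$dX else g$dh1p <- g$dh1p + sk$dX
    dbn <- bn_backward(drelu, cache[[paste0("bn2", t)]])
    g[[paste0("bn2", t, "_gamma")]] <- dbn$dgamma
    g[[paste0("bn2", t, "_beta")]] <- dbn$dbeta
    dbranch[[t]] <- dbn$dX
  }

  if (config$use_cross_fusion) {
    A_in <- cache$fusion_in$A; B_in <- cache$fusion_in$B
    a <- params$alpha
    g$alpha <- matrix(c(sum(dbranch$A * A_in), sum(dbranch$B * A_in),
                        sum(dbranch$A * B_in), sum(dbranch$B * B_in)), 2, 2)
    dA <- a[1, 1] * dbranch$A + a[2, 1] * dbranch$B
    dB <- a[1, 2] * dbranch$A + a[2, 2] * dbranch$B
    dbranch <- list(A = dA, B = dB)
  }

  dh1 <- NULL
  for (t in c("A", "B")) {
    cv <- conv_backward(dbranch[[t]], cache[[paste0("c2", t)]])
    g[[paste0("conv2", t, "_W")]] <- cv$dW
    dh1 <- if (is.null(dh1)) cv$dX else dh1 + cv$dX
  }
  # gradient that flowed into the padded copy of h1 used by the skip paths
  dH <- dim(dh1)[1]
  dh1 <- dh1 + unpad_spatial(g$dh1p, 1, dH, dH)
  g$dh1p <- NULL

  drelu1 <- relu_backward(dh1, cache$r1)
  sk1 <- conv_backward(drelu1, cache$sk1)
  g$skip1_W <- sk1$dW

  dbn1 <- bn_backward(drelu1, cache$bn1)
  g$bn1_gamma <- dbn1$dgamma
  g$bn1_beta <- dbn1$dbeta

  dx1 <- dbn1$dX
  if (config$use_attention) {
    ab <- attention_backward(dx1, cache$att)
    g$att_W1 <- ab$dW1; g$att_b1 <- ab$db1
    g$att_W2 <- ab$dW2; g$att_b2 <- ab$db2
    dx1 <- ab$dX
  }
  c1 <- conv_backward(dx1, cache$c1)
  g$conv1_W <- c1$dW
  g
}

#' Forward prediction
#'
#' @param model A list with \code{params}, \code{state}, \code{config}
#'   (from \code{mrca_init} or \code{train_mrca}).
#' @param X Array (n, n, 8, N) of feature tensors.
#' @return List with \code{probs} (3 x N softmax class probabilities, rows
#'   in \code{class_levels()} order) and \code{conc} (2 x N ppm predictions,
#'   rows n-propanol then ethanol).
#' @export
predict_mrca <- function(model, X) {
  fw <- mrca_forward(model$params, model$state, X, model$config,
                     training = FALSE)
  conc <- fw$conc * model$config$scale_targets
  rownames(conc) <- c("propanol", "ethanol")
  rownames(fw$probs) <- class_levels()
  list(probs = fw$probs, conc = conc)
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores all learnable parameters, batch-norm running
#' moments, the configuration and current sigma values in one file;
#' \code{load_checkpoint} restores them bit-faithfully.
#'
#' @param model Model list (\code{params}, \code{state}, \code{config}).
#' @param path File path.
#' @return \code{save_checkpoint}: invisibly, \code{path};
#'   \code{load_checkpoint}: the model list.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(params = model$params, state = model$state,
              config = unclass(model$config),
              sigma = if (!is.null(model$params$log_sigma))
                exp(model$params$log_sigma) else NULL)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  obj$config <- structure(obj$config, class = "mrca_config")
  obj[c("params", "state", "config")]
}
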