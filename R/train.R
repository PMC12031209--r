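#' Training options
#'
#' Optimizer defaults: Adam at learning rate 2e-3 with the batch size of 5
#' used by the backbone configuration, run for 20 epochs with a step decay
#' (x 0.15 after 60\% of the epochs). The late low-rate phase settles the
#' regression head; on the default campaign this matches much longer
#' constant-rate training.
#'
#' @param epochs Number of passes over the training set.
#' @param lr Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param lr_decay Factor applied to \code{lr} for the tail epochs (1 =
#'   constant rate).
#' @param decay_after Fraction of epochs trained at the full rate.
#' @param early_stop_patience Optional integer: stop when the mean epoch
#'   total loss has not improved for this many consecutive epochs. NULL
#'   (the default) disables early stopping.
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer.
#' @return A \code{train_config} list.
#' @export
train_config <- function(epochs = 20, lr = 2e-3, batch_size = 5,
                         lr_decay = 0.15, decay_after = 0.6,
                         early_stop_patience = NULL,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  structure(list(epochs = epochs, lr = lr, batch_size = batch_size,
                 lr_decay = lr_decay, decay_after = decay_after,
                 early_stop_patience = early_stop_patience,
                 beta1 = beta1, beta2 = beta2, eps = eps),
            class = "train_config")
}

#' Subset an \code{enose_dataset} by sample index
#'
#' @param dataset An \code{enose_dataset}.
#' @param idx Integer or logical index over samples.
#' @return The subset, still an \code{enose_dataset}.
#' @export
subset_dataset <- function(dataset, idx) {
  structure(list(
    tensors = dataset$tensors[, , , idx, drop = FALSE],
    labels = dataset$labels[idx],
    conc = dataset$conc[idx, , drop = FALSE],
    scheme_id = dataset$scheme_id[idx],
    repeat_index = dataset$repeat_index[idx],
    cycle = dataset$cycle[idx]
  ), class = "enose_dataset")
}

onehot_labels <- function(labels) {
  Y <- matrix(0, nrow = length(class_levels()), ncol = length(labels))
  Y[cbind(as.integer(labels), seq_along(labels))] <- 1
  Y
}

# component losses and head gradients for one batch
batch_losses <- function(fw, Y, yB, weights) {
  N <- ncol(Y)
  logits <- fw$logits
  zmax <- apply(logits, 2, max)
  lse <- zmax + log(colSums(exp(sweep(logits, 2, zmax, `-`))))
  Lci <- mean(lse - colSums(logits * Y))
  res <- fw$conc - yB
  Lp <- mean(res[1, ]^2)
  Le <- mean(res[2, ]^2)
  dlogits <- weights[3] * (fw$probs - Y) / N
  dconc <- rbind(weights[1] * 2 * res[1, ] / N,
                 weights[2] * 2 * res[2, ] / N)
  list(Lp = Lp, Le = Le, Lci = Lci, dlogits = dlogits, dconc = dconc)
}

#' Train the multi-task network
#'
#' Mini-batch Adam over all learnable parameters, including the loss scales
#' \eqn{\log\sigma} when the dynamic weighted loss is active. Deterministic
#' given \code{seed} (initialization and batch shuffling both derive from
#' it).
#'
#' @param dataset An \code{enose_dataset} (training samples).
#' @param config An \code{mrca_config}.
#' @param opts A \code{train_config}.
#' @param seed Integer seed.
#' @param init Optional pre-initialized model (to continue training or pin
#'   initialization across ablation arms).
#' @return List with \code{params}, \code{state}, \code{config} and
#'   \code{history} (one row per epoch: mean component losses, total loss
#'   and sigma values).
#' @export
train_mrca <- function(dataset, config = mrca_config(),
                       opts = train_config(), seed = 1L, init = NULL) {
  N <- length(dataset$labels)
  if (N == 0) stopf("empty training set")
  model <- if (is.null(init)) mrca_init(config, seed = child_seed(seed, 0))
           else init
  # deep-copy: the optimizer updates parameters in place
  params <- lapply(model$params, function(x) x + 0)
  state <- model$state
  Yall <- onehot_labels(dataset$labels)
  yBall <- t(dataset$conc[, c("propanol", "ethanol"), drop = FALSE]) /
    config$scale_targets

  m1 <- lapply(params, function(p) p * 0)
  m2 <- lapply(params, function(p) p * 0)
  bufs <- list(fc1A_W = params$fc1A_W * 0, fc1B_W = params$fc1B_W * 0)
  tstep <- 0
  hist_rows <- vector("list", opts$epochs)
  best_total <- Inf
  stale <- 0

  with_seed(child_seed(seed, 1), {
    for (ep in seq_len(opts$epochs)) {
      lr_ep <- opts$lr *
        if (ep > ceiling(opts$decay_after * opts$epochs)) opts$lr_decay else 1
      perm <- sample.int(N)
      acc <- c(Lp = 0, Le = 0, Lci = 0, total = 0)
      nb <- 0
      for (b0 in seq(1, N, by = opts$batch_size)) {
        idx <- perm[b0:min(b0 + opts$batch_size - 1, N)]
        Xb <- dataset$tensors[, , , idx, drop = FALSE]
        Yb <- Yall[, idx, drop = FALSE]
        yBb <- yBall[, idx, drop = FALSE]

        fw <- mrca_forward(params, state, Xb, config, training = TRUE)
        state <- fw$state
        if (config$loss == "dynamic") {
          sig <- exp(params$log_sigma)
          wts <- c(1 / (2 * sig[1]^2), 1 / (2 * sig[2]^2), 1 / sig[3]^2)
        } else {
          wts <- c(1, 1, 1)
        }
        bl <- batch_losses(fw, Yb, yBb, wts)
        total <- if (config$loss == "dynamic")
          dynamic_weighted_loss(bl$Lp, bl$Le, bl$Lci, exp(params$log_sigma))
        else sum_loss(bl$Lp, bl$Le, bl$Lci)

        grads <- mrca_backward(params, fw$cache, bl$dlogits, bl$dconc,
                               config, bufs = bufs)
        if (config$loss == "dynamic")
          grads$log_sigma <- dynamic_loss_grad_logsigma(
            bl$Lp, bl$Le, bl$Lci, params$log_sigma)
        if (!config$use_attention)
          grads[c("att_W1", "att_b1", "att_W2", "att_b2")] <- NULL

        tstep <- tstep + 1
        corr1 <- 1 - opts$beta1^tstep
        corr2 <- 1 - opts$beta2^tstep
        for (nm in names(grads)) {
          adam_step(params[[nm]], grads[[nm]], m1[[nm]], m2[[nm]],
                    lr_ep, opts$beta1, opts$beta2, opts$eps, corr1, corr2)
        }
        acc <- acc + c(bl$Lp, bl$Le, bl$Lci, total)
        nb <- nb + 1
      }
      sig <- if (config$loss == "dynamic") exp(params$log_sigma)
             else c(NA, NA, NA)
      hist_rows[[ep]] <- c(epoch = ep, acc / nb,
                           sigma_p = sig[1], sigma_e = sig[2],
                           sigma_ci = sig[3])
      if (!is.null(opts$early_stop_patience)) {
        ep_total <- (acc / nb)[["total"]]
        if (ep_total < best_total) {
          best_total <- ep_total
          stale <- 0
        } else {
          stale <- stale + 1
          if (stale >= opts$early_stop_patience) break
        }
      }
    }
  })
  hist_rows <- hist_rows[!vapply(hist_rows, is.null, logical(1))]
  history <- as.data.frame(do.call(rbind, hist_rows))
  names(history) <- c("epoch", "Lp", "Le", "Lci", "total",
                      "sigma_p", "sigma_e", "sigma_ci")
  # batch norm recalibration: replace the momentum-smoothed running moments
  # (noisy at batch size 5) with exact statistics over the training set
  fw <- mrca_forward(params, state, dataset$tensors, config,
                     training = TRUE, bn_momentum = 1)
  state <- fw$state
  list(params = params, state = state, config = config, history = history)
}
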