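# Shared fixtures. Heavy objects are built once per test run and memoized in
# this environment; everything is generated in code, nothing is stored.

.fixtures <- new.env(parent = emptyenv())

# default campaign + preprocessed dataset (the study conditions)
default_dataset <- function() {
  if (is.null(.fixtures$ds)) {
    camp <- generate_campaign(campaign_config(), seed = 20240901)
    .fixtures$camp <- camp
    .fixtures$ds <- suppressWarnings(preprocess_campaign(camp$recordings))
  }
  .fixtures$ds
}

default_campaign <- function() {
  default_dataset()
  .fixtures$camp
}

# tiny zero-noise bank (2 sensors worth of parameters, replicated to 8)
tiny_bank <- function(noise_sd = 0) {
  lapply(seq_len(8), function(i)
    sensor_model(paste0("t", i),
                 a_eth = 0.1 + 0.02 * i, b_eth = 0.7,
                 a_prop = 0.05 + 0.03 * i, b_prop = 0.8,
                 tau_eth = 27 + 2 * i, tau_prop = 31 + i,
                 tau_off = 40 + 3 * i, kappa = 1, noise_sd = noise_sd))
}

# short scheme: a blank then two active cycles
tiny_scheme <- function(pairs = data.frame(ethanol = c(0, 40, 80),
                                           propanol = c(0, 0, 0))) {
  exposure_scheme("T1", pairs)
}

# small random dataset for training smoke tests (random tensors, not
# simulator output, so it stays fast)
random_dataset <- function(N = 10, n = 8, seed = 1) {
  with_seed <- function(seed, code) { set.seed(seed); code }
  with_seed(seed, {
    structure(list(
      tensors = array(runif(n * n * 8 * N), dim = c(n, n, 8, N)),
      labels = factor(sample(class_levels(), N, replace = TRUE),
                      levels = class_levels()),
      conc = cbind(propanol = runif(N, 0, 100), ethanol = runif(N, 0, 100)),
      scheme_id = rep("G1", N),
      repeat_index = rep(seq_len(5), length.out = N),
      cycle = rep(1L, N)
    ), class = "enose_dataset")
  })
}

# brute-force oracles -------------------------------------------------------

oracle_peaks <- function(y) {
  out <- integer(0)
  for (i in seq_along(y)) {
    if (i > 1 && i < length(y) && y[i] > y[i - 1] && y[i] > y[i + 1])
      out <- c(out, i)
  }
  out
}

oracle_groups <- function(peaks, thr) {
  if (length(peaks) == 0) return(list())
  groups <- list(peaks[1])
  for (p in peaks[-1]) {
    last <- groups[[length(groups)]]
    if (p - last[length(last)] < thr)
      groups[[length(groups)]] <- c(last, p)
    else
      groups[[length(groups) + 1]] <- p
  }
  groups
}

oracle_window <- function(y, w, step = 1) {
  starts <- seq(1, length(y) - w, by = step)
  best_t <- NA_integer_; best_r <- -Inf
  for (t in starts) {
    r <- sum(abs(diff(y[t:(t + w)]))) / w
    if (r > best_r + 1e-12) { best_r <- r; best_t <- t }
  }
  list(tmax = best_t, rate = best_r)
}
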