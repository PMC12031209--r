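#' Simulate one sensor-array recording
#'
#' Integrates the first-order response dynamics of every sensor in the bank
#' over the scheme's exposure/recovery cycles. Each gas contributes an
#' independent relaxation component \eqn{r_g(t)} that rises toward its
#' steady-state amplitude \eqn{a_g C_g^{b_g}} during exposure (rate
#' \eqn{(1/\tau_g)(1 + \kappa C_g/100)}) and decays toward 0 during recovery
#' (rate \eqn{1/\tau_{off}}); the reported response ratio is
#' \eqn{s(t) = 1 + \sum_g r_g(t)}, optionally perturbed by multiplicative
#' Gaussian noise and a slow linear baseline drift.
#'
#' @param scheme An \code{exposure_scheme}.
#' @param bank List of 8 \code{sensor_model} objects.
#' @param seed Integer seed; the recording is deterministic given
#'   \code{(scheme, bank, seed)}.
#' @param repeat_index Repeat number carried as metadata.
#' @param drift_rate Baseline drift in response-ratio units per hour
#'   (default 0, i.e. off).
#' @return A \code{sensor_recording}: list with \code{time} (seconds),
#'   \code{response} (matrix sensors x samples), \code{schedule} (one row per
#'   cycle with sample ranges, concentrations and label), plus metadata.
#' @export
simulate_recording <- function(scheme, bank, seed = 1L, repeat_index = 1L,
                               drift_rate = 0) {
  stopifnot(inherits(scheme, "exposure_scheme"))
  if (length(bank) == 0) stopf("sensor bank is empty")
  if (nrow(scheme$pairs) == 0) stopf("empty concentration list")
  fs <- scheme$sample_rate_hz
  dt <- 1 / fs
  n_exp <- round(scheme$exposure_s * fs)
  n_rec <- round(scheme$recovery_s * fs)
  n_cycle <- n_exp + n_rec
  n_cycles <- nrow(scheme$pairs)
  total <- n_cycle * n_cycles
  time <- (seq_len(total) - 1) * dt

  # closed-form first-order relaxation within each constant-concentration
  # phase: r(t) = amp + (r0 - amp) * exp(-lambda * t)
  relax_gas <- function(conc, amp_coef, b, tau_on, tau_off, kappa) {
    r <- numeric(total)
    r0 <- 0
    for (k in seq_len(n_cycles)) {
      off <- (k - 1) * n_cycle
      for (phase in 1:2) {
        idx <- if (phase == 1) (off + 1):(off + n_exp) else
          (off + n_exp + 1):(off + n_cycle)
        c_k <- if (phase == 1) conc[k] else 0
        amp <- if (c_k > 0) amp_coef * c_k^b else 0
        lambda <- if (c_k > 0) (1 + kappa * c_k / 100) / tau_on else 1 / tau_off
        r[idx] <- amp + (r0 - amp) * exp(-lambda * dt * seq_along(idx))
        r0 <- r[idx[length(idx)]]
      }
    }
    r
  }

  response <- matrix(0, nrow = length(bank), ncol = total)
  with_seed(seed, {
    for (si in seq_along(bank)) {
      m <- bank[[si]]
      s <- 1 +
        relax_gas(scheme$pairs$ethanol, m$a_eth, m$b_eth,
                  m$tau_eth, m$tau_off, m$kappa) +
        relax_gas(scheme$pairs$propanol, m$a_prop, m$b_prop,
                  m$tau_prop, m$tau_off, m$kappa)
      if (m$noise_sd > 0) {
        # stationary AR(1) noise: slow multiplicative wander, sd = noise_sd
        phi <- m$noise_corr
        innov <- stats::rnorm(total, sd = m$noise_sd * sqrt(1 - phi^2))
        e0 <- stats::rnorm(1, sd = m$noise_sd)
        e <- as.numeric(stats::filter(innov, phi, method = "recursive",
                                      init = e0))
        s <- s * (1 + e)
      }
      if (drift_rate != 0)
        s <- s + drift_rate * time / 3600
      response[si, ] <- s
    }
  })
  rownames(response) <- vapply(bank, `[[`, "", "sensor_id")

  schedule <- data.frame(
    cycle = seq_len(n_cycles),
    start = (seq_len(n_cycles) - 1) * n_cycle + 1,
    peak_end = (seq_len(n_cycles) - 1) * n_cycle + n_exp,
    end = seq_len(n_cycles) * n_cycle,
    ethanol = scheme$pairs$ethanol,
    propanol = scheme$pairs$propanol,
    label = label_for_pair(scheme$pairs$ethanol, scheme$pairs$propanol),
    stringsAsFactors = FALSE
  )
  structure(list(
    time = time, response = response, schedule = schedule,
    scheme_id = scheme$scheme_id, repeat_index = repeat_index,
    sample_rate_hz = fs, seed = seed
  ), class = "sensor_recording")
}

#' Campaign configuration
#'
#' @param schemes List of \code{exposure_scheme}s (default the 7-scheme
#'   layout).
#' @param repeats Number of repeats per scheme (default 5).
#' @param noise_sd Sensor noise (relative sd, default 1\%); overrides the
#'   bank's values when \code{bank} is NULL.
#' @param bank Optional explicit sensor bank; default built from
#'   \code{default_sensor_bank(noise_sd)}.
#' @param drift_rate Baseline drift per hour, default 0.
#' @return A \code{campaign_config} list.
#' @export
campaign_config <- function(schemes = default_schemes(), repeats = 5,
                            noise_sd = 0.01, bank = NULL, drift_rate = 0) {
  if (is.null(bank)) bank <- default_sensor_bank(noise_sd)
  if (repeats < 1) stopf("repeats must be >= 1")
  structure(list(schemes = schemes, repeats = repeats, bank = bank,
                 drift_rate = drift_rate, noise_sd = noise_sd),
            class = "campaign_config")
}

#' Generate a full measurement campaign
#'
#' Runs every scheme \code{repeats} times with independent derived seeds.
#' Each non-blank cycle of each recording is one labeled gas response; the
#' default 7 schemes x 5 responses x 5 repeats yield 175 responses.
#'
#' @param config A \code{campaign_config}.
#' @param seed Master integer seed.
#' @return List with \code{recordings} (list of \code{sensor_recording}) and
#'   \code{manifest} (data frame, one row per labeled response).
#' @export
generate_campaign <- function(config = campaign_config(), seed = 1L) {
  stopifnot(inherits(config, "campaign_config"))
  recs <- list()
  rows <- list()
  i <- 0L
  for (sch in config$schemes) {
    for (rep_i in seq_len(config$repeats)) {
      i <- i + 1L
      rec <- simulate_recording(sch, config$bank,
                                seed = child_seed(seed, i),
                                repeat_index = rep_i,
                                drift_rate = config$drift_rate)
      recs[[i]] <- rec
      act <- rec$schedule[!is.na(rec$schedule$label), , drop = FALSE]
      if (nrow(act) > 0) {
        rows[[i]] <- data.frame(
          recording = i, scheme_id = rec$scheme_id, repeat_index = rep_i,
          cycle = act$cycle, ethanol = act$ethanol, propanol = act$propanol,
          label = act$label, stringsAsFactors = FALSE
        )
      }
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  list(recordings = recs, manifest = manifest)
}

#' Write a recording as CSV + JSON sidecar
#'
#' CSV columns are \code{time_s, s1..s8} (response ratios); the sidecar holds
#' the scheme id, schedule, labels and seed so the pair round-trips.
#'
#' @param rec A \code{sensor_recording}.
#' @param dir Output directory (created if missing).
#' @param stem File stem; default \code{scheme_repN}.
#' @return Invisibly, the CSV path.
#' @export
write_recording <- function(rec, dir, stem = NULL) {
  stopifnot(inherits(rec, "sensor_recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(stem))
    stem <- sprintf("%s_rep%d", rec$scheme_id, rec$repeat_index)
  df <- data.frame(time_s = rec$time, t(rec$response))
  names(df) <- c("time_s", paste0("s", seq_len(nrow(rec$response))))
  csv <- file.path(dir, paste0(stem, ".csv"))
  utils::write.csv(df, csv, row.names = FALSE)
  meta <- list(
    scheme_id = rec$scheme_id, repeat_index = rec$repeat_index,
    sample_rate_hz = rec$sample_rate_hz, seed = rec$seed,
    sensor_ids = rownames(rec$response),
    schedule = rec$schedule
  )
  jsonlite::write_json(meta, file.path(dir, paste0(stem, ".json")),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(csv)
}

#' Read a recording written by \code{write_recording}
#'
#' @param csv_path Path to the CSV file (the sidecar JSON is located by
#'   replacing the extension).
#' @return A \code{sensor_recording}.
#' @export
read_recording <- function(csv_path) {
  json_path <- sub("\\.csv$", ".json", csv_path)
  if (!file.exists(csv_path) || !file.exists(json_path))
    stopf("recording pair not found for '%s'", csv_path)
  df <- utils::read.csv(csv_path)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  response <- t(as.matrix(df[, -1, drop = FALSE]))
  rownames(response) <- meta$sensor_ids
  schedule <- as.data.frame(meta$schedule)
  schedule$label <- as.character(schedule$label)
  structure(list(
    time = df$time_s, response = response, schedule = schedule,
    scheme_id = meta$scheme_id, repeat_index = meta$repeat_index,
    sample_rate_hz = meta$sample_rate_hz, seed = meta$seed
  ), class = "sensor_recording")
}
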