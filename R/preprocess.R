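#' Detect local response peaks
#'
#' A peak is a strict local maximum: \code{y[p] > y[p-1]} and
#' \code{y[p] > y[p+1]}; series endpoints never qualify and plateau tops are
#' not peaks. Optional filters mirror the usual find-peaks controls:
#' \code{min_height} drops peaks below an absolute response level, and
#' \code{min_distance} greedily keeps the highest peaks such that no two kept
#' peaks are closer than the given number of samples (needed on noisy series,
#' where every noise wiggle is a strict local maximum).
#'
#' @param y Numeric series of length >= 3.
#' @param min_height Optional absolute height threshold.
#' @param min_distance Optional minimum spacing between kept peaks (samples).
#' @return Integer vector of peak indices (1-based, strictly increasing).
#' @export
detect_peaks <- function(y, min_height = NULL, min_distance = NULL) {
  n <- length(y)
  if (n < 3) stopf("series must have at least 3 samples")
  core <- y[2:(n - 1)]
  p <- which(core > y[1:(n - 2)] & core > y[3:n]) + 1L
  if (!is.null(min_height)) p <- p[y[p] >= min_height]
  if (!is.null(min_distance) && length(p) > 1) {
    ord <- p[order(y[p], p, decreasing = c(TRUE, FALSE), method = "radix")]
    kept <- integer(0)
    for (q in ord) {
      if (length(kept) == 0 || all(abs(kept - q) >= min_distance))
        kept <- c(kept, q)
    }
    p <- sort(kept)
  }
  p
}

#' Cluster peaks by index distance
#'
#' Greedy left-to-right grouping: adjacent peaks whose index gap is below
#' \code{d_threshold} fall in the same cluster; a gap of \code{d_threshold}
#' or more starts a new cluster. The threshold is set by the sampling
#' frequency and the sensor's recovery time (default 600 samples = 5 min of
#' recovery at 2 Hz).
#'
#' @param peaks Integer vector of peak indices (strictly increasing).
#' @param d_threshold Gap threshold in samples (> 0).
#' @return List of integer vectors, a partition of \code{peaks}.
#' @export
group_peaks <- function(peaks, d_threshold = 600) {
  if (d_threshold <= 0) stopf("d_threshold must be > 0")
  if (length(peaks) == 0) return(list())
  gaps <- diff(peaks)
  grp <- cumsum(c(1L, as.integer(gaps >= d_threshold)))
  unname(split(as.integer(peaks), grp))
}

#' Maximum peak per cluster
#'
#' @param grouping List of peak-index groups (from \code{group_peaks}).
#' @param y The series the peaks index into.
#' @return Integer vector with one index per group: the group's argmax of
#'   \code{y}, ties broken by the smallest index.
#' @export
max_peak_per_group <- function(grouping, y) {
  vapply(grouping, function(g) g[which.max(y[g])], integer(1))
}

#' Extract fixed-width response segments around maximum peaks
#'
#' Each segment spans \code{loffset} samples before to \code{roffset} samples
#' after the peak: \code{y[(pmax - loffset):(pmax + roffset - 1)]}, length
#' \code{loffset + roffset}. The left window covers the full 5 min response
#' phase (600 samples at 2 Hz) with margin; the right window keeps the early
#' recovery, whose end-of-response level separates mixtures of different
#' ratios. Peaks too close to either series boundary are skipped (never
#' padded) and reported via a warning.
#'
#' @param y Numeric series.
#' @param pmax_list Integer vector of reference peak indices.
#' @param loffset,roffset Offsets in samples (> 0), defaults 700 and 400.
#' @return List of segments; each has \code{pmax} and \code{values}.
#' @export
extract_segments <- function(y, pmax_list, loffset = 700, roffset = 400) {
  if (loffset <= 0 || roffset <= 0) stopf("offsets must be > 0")
  out <- list()
  skipped <- integer(0)
  for (p in pmax_list) {
    lo <- p - loffset
    hi <- p + roffset - 1
    if (lo < 1 || hi > length(y)) {
      skipped <- c(skipped, p)
      next
    }
    out[[length(out) + 1]] <- list(pmax = as.integer(p), values = y[lo:hi])
  }
  if (length(skipped) > 0)
    warning(sprintf("skipped %d boundary-clipped segment(s) at peak index(es) %s",
                    length(skipped), paste(skipped, collapse = ", ")),
            call. = FALSE)
  out
}

#' Select the maximum-variation-rate window of a segment
#'
#' Slides a window of width \code{w} over the segment in steps of \code{step}
#' samples and scores each start \eqn{t} by the variation rate
#' \eqn{R_t = \frac{1}{w}\sum_{i=t}^{t+w-1} |y_{i+1} - y_i|} (a sum of
#' \code{w} absolute first differences, consuming \code{w + 1} samples). The
#' window with maximal \eqn{R_t} is returned, ties resolved to the smallest
#' start; the extracted values are the \code{w} samples starting at the
#' chosen \eqn{t}. A step of 1 sample corresponds to the 0.5 s stride at
#' 2 Hz sampling.
#'
#' @param segment Numeric vector (or a segment list from
#'   \code{extract_segments}).
#' @param w Window width in samples (the pipeline uses perfect squares so
#'   windows reshape into square feature layers, but the operator itself
#'   accepts any width >= 2).
#' @param step Stride in samples (default 1).
#' @return List with \code{tmax} (1-based start), \code{w}, \code{rate} and
#'   \code{values}.
#' @export
max_variation_window <- function(segment, w = 256, step = 1) {
  y <- if (is.list(segment)) segment$values else segment
  if (w < 2) stopf("window width must be >= 2")
  if (length(y) < w + 1)
    stopf("segment length %d is too short for window width %d (needs >= %d)",
          length(y), w, w + 1)
  cs <- c(0, cumsum(abs(diff(y))))
  starts <- seq(1L, length(y) - w, by = step)
  rates <- (cs[starts + w] - cs[starts]) / w
  best <- starts[which.max(rates)]   # which.max takes the first maximum
  list(tmax = as.integer(best), w = as.integer(w),
       rate = max(rates), values = y[best:(best + w - 1)])
}

#' Min-max normalize a feature window onto [0, 1]
#'
#' @param values Numeric vector with \code{max > min}.
#' @param context Optional label (sensor / segment) used in the degenerate
#'   input error message.
#' @return Values affinely mapped so min is 0 and max is 1.
#' @export
minmax_normalize <- function(values, context = NULL) {
  rng <- range(values)
  if (rng[1] == rng[2])
    stopf("degenerate constant window (min = max)%s",
          if (is.null(context)) "" else paste0(" in ", context))
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Stack per-sensor windows into a multi-channel square feature tensor
#'
#' Each of the 8 normalized windows of length \code{w = n^2} is reshaped
#' row-major into an n x n layer; layers are stacked in fixed sensor order
#' along the channel axis.
#'
#' @param windows List of 8 numeric vectors, all of the same square length.
#' @return Array of dim \code{c(n, n, 8)} (height, width, channel).
#' @export
assemble_tensor <- function(windows) {
  lens <- vapply(windows, length, integer(1))
  if (length(unique(lens)) != 1)
    stopf("windows have mismatched lengths")
  w <- lens[1]
  if (!is_square(w)) stopf("window length %d is not a perfect square", w)
  n <- as.integer(round(sqrt(w)))
  out <- array(0, dim = c(n, n, length(windows)))
  for (c_i in seq_along(windows))
    out[, , c_i] <- matrix(windows[[c_i]], nrow = n, byrow = TRUE)
  out
}

#' Preprocessing parameters
#'
#' @param loffset,roffset Segment offsets in samples.
#' @param d_threshold Peak-cluster gap threshold in samples.
#' @param w Feature window width (perfect square).
#' @param step_s Window stride in seconds (converted to samples with the
#'   recording's sampling rate; 0.5 s = 1 sample at 2 Hz).
#' @param min_height,min_distance Peak filters passed to
#'   \code{detect_peaks}; the defaults (response ratio 1.3, 600 samples)
#'   reject noise-induced local maxima while keeping every true response
#'   peak of the default array.
#' @return A \code{preprocess_params} list.
#' @export
preprocess_params <- function(loffset = 700, roffset = 400, d_threshold = 600,
                              w = 256, step_s = 0.5,
                              min_height = 1.3, min_distance = 600) {
  if (!is_square(w)) stopf("w must be a perfect square")
  structure(list(loffset = loffset, roffset = roffset,
                 d_threshold = d_threshold, w = w, step_s = step_s,
                 min_height = min_height, min_distance = min_distance),
            class = "preprocess_params")
}

#' Preprocess one recording into labeled feature tensors
#'
#' Runs the full per-sensor chain (peak detection, clustering, max-peak
#' segmentation, maximum-variation-rate windowing, normalization) and stacks
#' the 8 sensors' windows into one tensor per gas-response cycle. A cycle
#' yields a sample only if every sensor contributed a segment for it.
#'
#' @param rec A \code{sensor_recording}.
#' @param params A \code{preprocess_params}.
#' @return List of samples; each has \code{tensor} (n x n x 8), \code{label},
#'   \code{conc} (named c(propanol, ethanol), ppm), \code{scheme_id},
#'   \code{repeat_index}, \code{cycle} and per-channel \code{tmax}.
#' @export
preprocess_recording <- function(rec, params = preprocess_params()) {
  stopifnot(inherits(rec, "sensor_recording"))
  step <- max(1L, as.integer(round(params$step_s * rec$sample_rate_hz)))
  n_sensors <- nrow(rec$response)
  sched <- rec$schedule
  active <- sched[!is.na(sched$label), , drop = FALSE]

  # per sensor: map each extracted segment to the cycle containing its peak
  per_sensor <- vector("list", n_sensors)
  for (si in seq_len(n_sensors)) {
    y <- rec$response[si, ]
    peaks <- detect_peaks(y, min_height = params$min_height,
                          min_distance = params$min_distance)
    groups <- group_peaks(peaks, params$d_threshold)
    pmax <- max_peak_per_group(groups, y)
    segs <- extract_segments(y, pmax, params$loffset, params$roffset)
    cyc <- vapply(segs, function(s)
      active$cycle[which(active$start <= s$pmax & s$pmax <= active$end)][1],
      integer(1))
    # one segment per cycle: if several qualify, keep the highest peak
    best <- list()
    for (j in seq_along(segs)) {
      k <- as.character(cyc[j])
      if (is.na(cyc[j])) next
      if (is.null(best[[k]]) || y[segs[[j]]$pmax] > y[best[[k]]$pmax])
        best[[k]] <- segs[[j]]
    }
    per_sensor[[si]] <- best
  }

  samples <- list()
  for (k in active$cycle) {
    segs_k <- lapply(per_sensor, function(ps) ps[[as.character(k)]])
    if (any(vapply(segs_k, is.null, logical(1)))) next
    wins <- lapply(seq_along(segs_k), function(si) {
      fw <- max_variation_window(segs_k[[si]], w = params$w, step = step)
      fw$norm <- minmax_normalize(
        fw$values, context = sprintf("sensor %d cycle %d", si, k))
      fw
    })
    row <- active[active$cycle == k, ]
    samples[[length(samples) + 1]] <- list(
      tensor = assemble_tensor(lapply(wins, `[[`, "norm")),
      label = row$label,
      conc = c(propanol = row$propanol, ethanol = row$ethanol),
      scheme_id = rec$scheme_id, repeat_index = rec$repeat_index,
      cycle = k, tmax = vapply(wins, `[[`, integer(1), "tmax")
    )
  }
  samples
}

#' Preprocess a whole campaign into a labeled dataset
#'
#' @param recordings List of \code{sensor_recording}s (e.g. from
#'   \code{generate_campaign()$recordings}).
#' @param params A \code{preprocess_params}.
#' @return An \code{enose_dataset}: list with \code{tensors} (array
#'   n x n x 8 x N), \code{labels} (factor with levels
#'   \code{class_levels()}), \code{conc} (N x 2 matrix, columns propanol and
#'   ethanol, ppm), \code{scheme_id}, \code{repeat_index}, \code{cycle}.
#' @export
preprocess_campaign <- function(recordings, params = preprocess_params()) {
  all_samples <- unlist(lapply(recordings, preprocess_recording,
                               params = params), recursive = FALSE)
  if (length(all_samples) == 0) stopf("no samples produced")
  n <- dim(all_samples[[1]]$tensor)[1]
  N <- length(all_samples)
  tensors <- array(0, dim = c(n, n, 8, N))
  for (i in seq_len(N)) tensors[, , , i] <- all_samples[[i]]$tensor
  structure(list(
    tensors = tensors,
    labels = factor(vapply(all_samples, `[[`, "", "label"),
                    levels = class_levels()),
    conc = do.call(rbind, lapply(all_samples, `[[`, "conc")),
    scheme_id = vapply(all_samples, `[[`, "", "scheme_id"),
    repeat_index = vapply(all_samples, `[[`, integer(1), "repeat_index"),
    cycle = vapply(all_samples, `[[`, integer(1), "cycle")
  ), class = "enose_dataset")
}
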