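#' Grouped fold assignment by acquisition repeat
#'
#' Folds respect acquisition groups: all responses sharing a repeat index go
#' to the same fold, so fold f's test set is (a permutation of) repeat f of
#' every scheme and train:test is exactly 4:1 with the default 5 repeats.
#'
#' @param dataset An \code{enose_dataset}.
#' @param k Number of folds (default 5).
#' @param seed Seed for the repeat-to-fold permutation.
#' @return Integer vector of fold indices (1..k), one per sample.
#' @export
make_folds <- function(dataset, k = 5, seed = 1L) {
  if (k < 2) stopf("k must be >= 2: a single fold leaves no held-out data")
  groups <- sort(unique(dataset$repeat_index))
  if (length(groups) %% k != 0)
    stopf(paste0("number of repeat groups (%d) is not divisible by k = %d; ",
                 "re-run with a k that divides it or shuffle groups manually"),
          length(groups), k)
  per <- length(groups) / k
  perm <- with_seed(seed, sample(groups))
  fold_of_group <- stats::setNames(rep(seq_len(k), each = per), perm)
  unname(fold_of_group[as.character(dataset$repeat_index)])
}

#' Grouped k-fold cross-validation
#'
#' Trains one model per fold on the remaining folds and evaluates on the
#' held-out fold; reports per-fold metrics and their mean with standard
#' error (sd across folds / sqrt(k)).
#'
#' @param dataset An \code{enose_dataset}.
#' @param config An \code{mrca_config}.
#' @param opts A \code{train_config}.
#' @param k Number of folds.
#' @param seed Master seed (fold permutation and per-fold training seeds
#'   derive from it).
#' @return List with \code{reports} (per-fold \code{metrics_report}s),
#'   \code{summary} (data frame metric / mean / se) and \code{folds}.
#' @export
cross_validate <- function(dataset, config = mrca_config(),
                           opts = train_config(), k = 5, seed = 1L) {
  folds <- make_folds(dataset, k = k, seed = child_seed(seed, 100))
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    train_set <- subset_dataset(dataset, folds != f)
    test_set <- subset_dataset(dataset, folds == f)
    fit <- train_mrca(train_set, config, opts, seed = child_seed(seed, f))
    reports[[f]] <- evaluate_model(fit, test_set)
  }
  metrics <- c("accuracy", "precision", "recall", "f1", "mae", "r2")
  vals <- sapply(metrics, function(m)
    vapply(reports, function(r) r[[m]], numeric(1)))
  summary <- data.frame(
    metric = metrics,
    mean = colMeans(vals),
    se = apply(vals, 2, stats::sd) / sqrt(k),
    row.names = NULL
  )
  list(reports = reports, summary = summary, folds = folds)
}

cv_metric <- function(cv, metric) {
  cv$summary$mean[cv$summary$metric == metric]
}

#' Window-length sweep
#'
#' Re-runs preprocessing and grouped cross-validation for each candidate
#' window width (all perfect squares), reproducing the width-versus-metrics
#' comparison. Widths longer than the available segments are skipped with a
#' warning.
#'
#' @param recordings List of \code{sensor_recording}s.
#' @param widths Integer vector of window widths; default the squares of
#'   11..17, 19, 21, 23, 25, 27.
#' @param config An \code{mrca_config} (its \code{input_n} is overridden per
#'   width).
#' @param opts A \code{train_config}.
#' @param params A \code{preprocess_params} (its \code{w} is overridden).
#' @param k,seed Cross-validation folds and master seed.
#' @return Data frame with one row per completed width: width, accuracy,
#'   f1, mae, r2.
#' @export
window_length_sweep <- function(recordings,
                                widths = c(11:17, 19, 21, 23, 25, 27)^2,
                                config = mrca_config(),
                                opts = train_config(),
                                params = preprocess_params(),
                                k = 5, seed = 1L) {
  if (!all(vapply(widths, is_square, logical(1))))
    stopf("all widths must be perfect squares")
  rows <- list()
  for (w in widths) {
    p_w <- params
    p_w$w <- w
    ds <- tryCatch(
      suppressWarnings(preprocess_campaign(recordings, p_w)),
      error = function(e) {
        warning(sprintf("width %d skipped: %s", w, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (is.null(ds)) next
    cfg_w <- config
    cfg_w$input_n <- as.integer(round(sqrt(w)))
    cv <- cross_validate(ds, cfg_w, opts, k = k, seed = seed)
    rows[[length(rows) + 1]] <- data.frame(
      width = w,
      accuracy = cv_metric(cv, "accuracy"), f1 = cv_metric(cv, "f1"),
      mae = cv_metric(cv, "mae"), r2 = cv_metric(cv, "r2")
    )
  }
  do.call(rbind, rows)
}

#' Ablation variant configurations
#'
#' Named list of \code{mrca_config}s covering the standard ablation grid:
#' MRCA-1 (experience-initialized sigma), MRCA-2 (sigma = 1), MRCA-3
#' (direct-sum loss), NO-Attention, NO-Cross, and the BaseLine with both
#' modules removed.
#'
#' @param input_n Input spatial size shared by all variants.
#' @param sigma_experience Sigma initialization for MRCA-1.
#' @return Named list of \code{mrca_config}s.
#' @export
ablation_variants <- function(input_n = 16,
                              sigma_experience = c(2, 2, 0.5)) {
  list(
    `MRCA-1` = mrca_config(input_n, sigma_init = sigma_experience),
    `MRCA-2` = mrca_config(input_n),
    `MRCA-3` = mrca_config(input_n, loss = "sum"),
    `NO Attention` = mrca_config(input_n, use_attention = FALSE),
    `NO Cross` = mrca_config(input_n, use_cross_fusion = FALSE),
    BaseLine = mrca_config(input_n, use_attention = FALSE,
                           use_cross_fusion = FALSE)
  )
}
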