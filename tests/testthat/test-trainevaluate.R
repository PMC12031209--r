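test_that("grouped folds partition the dataset 4:1 by repeat", {
  ds <- default_dataset()
  folds <- make_folds(ds, k = 5, seed = 1)
  expect_equal(sort(unique(folds)), 1:5)
  expect_equal(as.integer(table(folds)), rep(35L, 5))       # 175 / 5
  # group-respecting: a repeat never straddles folds
  expect_true(all(tapply(folds, ds$repeat_index,
                         function(f) length(unique(f))) == 1))
  # union of test folds is the whole dataset, pairwise disjoint
  idx <- lapply(1:5, function(f) which(folds == f))
  expect_equal(sort(unlist(idx)), 1:175)
  expect_equal(sum(lengths(idx)), 175)
  expect_error(make_folds(ds, k = 1), "held-out")
  expect_error(make_folds(ds, k = 3), "divisible")
})

test_that("metrics match a hand-computed 6-sample prediction table", {
  lev <- class_levels()
  labels <- factor(c("01", "01", "10", "10", "11", "11"), levels = lev)
  # predictions: sample 2 wrong (01 -> 10), sample 5 wrong (11 -> 01)
  probs <- matrix(0.05, nrow = 3, ncol = 6,
                  dimnames = list(lev, NULL))
  pick <- c("01", "10", "10", "10", "01", "11")
  for (j in 1:6) probs[pick[j], j] <- 0.9
  conc_pred <- rbind(c(10, 20, 0, 0, 52, 66),
                     c(0, 0, 38, 62, 49, 71))
  conc_true <- cbind(propanol = c(10, 20, 0, 0, 50, 70),
                     ethanol = c(0, 0, 40, 60, 50, 70))
  rep <- evaluate_predictions(probs, conc_pred, labels, conc_true)
  expect_equal(rep$accuracy, 4 / 6)
  # per class: 01: tp1 fp1 fn1 -> P=R=0.5; 10: tp2 fp1 fn0 -> P=2/3, R=1;
  # 11: tp1 fp0 fn1 -> P=1, R=0.5
  expect_equal(rep$precision, mean(c(0.5, 2 / 3, 1)))
  expect_equal(rep$recall, mean(c(0.5, 1, 0.5)))
  f1s <- c(0.5, 2 * (2 / 3) / (2 / 3 + 1), 2 * 0.5 / 1.5)
  expect_equal(rep$f1, mean(f1s))
  expect_equal(as.integer(rep$confusion), c(1L, 0L, 1L, 1L, 2L, 0L, 0L, 0L, 1L))
  # MAE: mean absolute error over all 12 target entries
  expect_equal(rep$mae, mean(abs(c(0, 0, 0, 0, 2, 4, 0, 0, 2, 2, 1, 1))))
  # pooled R2 with per-target centering
  ss_res <- sum((conc_pred[1, ] - conc_true[, 1])^2) +
    sum((conc_pred[2, ] - conc_true[, 2])^2)
  ss_tot <- sum((conc_true[, 1] - mean(conc_true[, 1]))^2) +
    sum((conc_true[, 2] - mean(conc_true[, 2]))^2)
  expect_equal(rep$r2, 1 - ss_res / ss_tot)
})

test_that("degenerate predictors hit the metric definitions exactly", {
  lev <- class_levels()
  labels <- factor(rep(lev, each = 4), levels = lev)
  probs <- onehot <- matrix(0, 3, 12)
  onehot[cbind(as.integer(labels), 1:12)] <- 1
  conc_true <- cbind(propanol = rep(c(20, 40, 60, 80), 3),
                     ethanol = rep(c(80, 60, 40, 20), 3))
  perfect <- evaluate_predictions(onehot, t(conc_true), labels, conc_true)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$r2, 1)
  expect_equal(unname(perfect$auc), rep(1, 3))
  # predicting the target mean gives R2 = 0 by definition
  mean_pred <- matrix(rep(colMeans(conc_true), 12), nrow = 2)
  at_mean <- evaluate_predictions(onehot, mean_pred, labels, conc_true)
  expect_equal(at_mean$r2, 0)
})

test_that("AUC for a class absent from the test set is undefined (NA)", {
  lev <- class_levels()
  labels <- factor(c("01", "01", "10"), levels = lev)   # no mixtures
  probs <- matrix(c(.8, .1, .1, .7, .2, .1, .2, .7, .1), 3, 3)
  conc <- cbind(propanol = c(10, 20, 0), ethanol = c(0, 0, 30))
  rep <- evaluate_predictions(probs, t(conc), labels, conc)
  expect_true(is.na(rep$auc["11"]))
  expect_false(anyNA(rep$auc[c("01", "10")]))
})

test_that("training runs, records history, and is seed-deterministic", {
  ds <- random_dataset(N = 10, n = 8, seed = 5)
  cfg <- mrca_config(input_n = 8)
  fit <- train_mrca(ds, cfg, train_config(epochs = 2), seed = 3)
  expect_equal(nrow(fit$history), 2)
  expect_true(all(is.finite(fit$history$total)))
  expect_true(all(is.finite(fit$history$Lci)))
  fit2 <- train_mrca(ds, cfg, train_config(epochs = 2), seed = 3)
  expect_identical(fit$params, fit2$params)
  fit3 <- train_mrca(ds, cfg, train_config(epochs = 2), seed = 4)
  expect_false(identical(fit3$params, fit2$params))
  expect_error(train_mrca(subset_dataset(ds, integer(0)), cfg), "empty")
})

test_that("sigma trajectory stays positive and the easy fit converges", {
  ds <- random_dataset(N = 10, n = 8, seed = 6)
  fit <- train_mrca(ds, mrca_config(input_n = 8),
                    train_config(epochs = 50), seed = 7)
  h <- fit$history
  expect_true(all(h$sigma_p > 0 & h$sigma_e > 0 & h$sigma_ci > 0))
  # total loss trends down on an easy fit (tolerant to batch noise)
  expect_lt(mean(tail(h$total, 5)), mean(head(h$total, 5)))
  expect_lt(tail(h$Lci, 1), head(h$Lci, 1))
})

test_that("the network can drive the loss near zero on a tiny batch", {
  ds <- random_dataset(N = 5, n = 8, seed = 8)
  ds$labels <- factor(c("01", "10", "11", "01", "10"),
                      levels = class_levels())
  fit <- train_mrca(ds, mrca_config(input_n = 8),
                    train_config(epochs = 200), seed = 9)
  h <- tail(fit$history, 1)
  expect_lt(h$Lci, 0.05)          # near-perfect classification
  expect_lt(h$Lp + h$Le, 0.005)   # scaled-MSE residual essentially zero
  pr <- predict_mrca(fit, ds$tensors)
  expect_equal(as.integer(apply(pr$probs, 2, which.max)),
               as.integer(ds$labels))
})

test_that("cross-validation aggregates per-fold reports", {
  ds <- random_dataset(N = 20, n = 8, seed = 10)
  cv <- cross_validate(ds, mrca_config(input_n = 8),
                       train_config(epochs = 1), k = 5, seed = 11)
  expect_length(cv$reports, 5)
  expect_equal(nrow(cv$summary), 6)
  accs <- vapply(cv$reports, `[[`, numeric(1), "accuracy")
  expect_equal(cv$summary$mean[cv$summary$metric == "accuracy"], mean(accs))
  expect_equal(cv$summary$se[cv$summary$metric == "accuracy"],
               sd(accs) / sqrt(5))
})

test_that("window sweep re-runs the pipeline per width and skips bad ones", {
  sch <- list(exposure_scheme("G1", data.frame(ethanol = c(0, 50, 100),
                                               propanol = 0)),
              exposure_scheme("G2", data.frame(ethanol = 0,
                                               propanol = c(0, 50, 100))))
  cfg <- campaign_config(schemes = sch, repeats = 5, noise_sd = 0.01)
  camp <- generate_campaign(cfg, seed = 12)
  tab <- suppressWarnings(window_length_sweep(
    camp$recordings, widths = c(16, 2000 * 2000),
    config = mrca_config(), opts = train_config(epochs = 1),
    k = 5, seed = 13))
  expect_equal(nrow(tab), 1)      # the oversized width is skipped
  expect_equal(tab$width, 16)
  expect_true(all(c("accuracy", "f1", "mae", "r2") %in% names(tab)))
  expect_error(window_length_sweep(camp$recordings, widths = c(15)),
               "perfect squares")
  # the default sweep list carries 12 candidate widths
  expect_length(eval(formals(window_length_sweep)$widths), 12)
})

test_that("early stopping halts on a stale total loss, off by default", {
  ds <- random_dataset(N = 10, n = 8, seed = 14)
  full <- train_mrca(ds, mrca_config(input_n = 8),
                     train_config(epochs = 8), seed = 15)
  expect_equal(nrow(full$history), 8)
  stopped <- train_mrca(ds, mrca_config(input_n = 8),
                        train_config(epochs = 50, lr = 0,
                                     early_stop_patience = 3),
                        seed = 15)
  # zero learning rate: loss can never improve after epoch 1
  expect_lte(nrow(stopped$history), 5)
})
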