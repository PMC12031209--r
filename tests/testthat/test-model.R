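zero_att <- function(r = 4, C = 16) {
  list(W1 = matrix(0, C / r, C), b1 = numeric(C / r),
       W2 = matrix(0, C, C / r), b2 = numeric(C))
}

rand_att <- function(r = 4, C = 16, seed = 1) {
  set.seed(seed)
  list(W1 = matrix(rnorm(C / r * C, sd = 0.5), C / r, C),
       b1 = rnorm(C / r, sd = 0.2),
       W2 = matrix(rnorm(C * C / r, sd = 0.5), C, C / r),
       b2 = rnorm(C, sd = 0.2))
}

test_that("zero-weight attention gates every element by exactly 0.5", {
  set.seed(2)
  X <- array(rnorm(6 * 6 * 16 * 3), dim = c(6, 6, 16, 3))
  out <- channel_attention(X, zero_att())
  expect_equal(out, 0.5 * X)
})

test_that("pooled statistics of a constant channel equal the constant", {
  X <- array(0, dim = c(4, 4, 16, 2))
  X[, , 3, 1] <- 7
  fw <- mrcanet:::attention_forward(X, rand_att())
  Xm <- matrix(X, nrow = 16)
  Ca <- matrix(colMeans(Xm), nrow = 16)
  expect_equal(Ca[3, 1], 7)
  Cm <- apply(X, c(3, 4), max)
  expect_equal(Cm[3, 1], 7)
})

test_that("attention weights stay in (0,1): output shrinks, sign kept", {
  set.seed(3)
  X <- array(rnorm(5 * 5 * 16 * 4), dim = c(5, 5, 16, 4))
  att <- rand_att(seed = 4)
  fw <- mrcanet:::attention_forward(X, att)
  expect_true(all(fw$S > 0 & fw$S < 1))
  expect_true(all(abs(fw$out) <= abs(X)))
  expect_true(all(sign(fw$out) == sign(X) | X == 0))
  # direct per-element recomputation of the gate
  mlp <- function(v) att$W2 %*% pmax(att$W1 %*% v + att$b1, 0) + att$b2
  for (n in 1:2) {
    Ca <- apply(X[, , , n, drop = FALSE], 3, mean)
    Cm <- apply(X[, , , n, drop = FALSE], 3, max)
    S <- 1 / (1 + exp(-(mlp(Ca) + mlp(Cm))))
    expect_equal(as.vector(fw$S[, n]), as.vector(S))
  }
})

test_that("cross-fusion mixes the task maps by the 2x2 scalar matrix", {
  set.seed(4)
  TA <- array(rnorm(3 * 3 * 2 * 2), dim = c(3, 3, 2, 2))
  TB <- array(rnorm(3 * 3 * 2 * 2), dim = c(3, 3, 2, 2))
  idf <- cross_fusion(TA, TB, diag(2))
  expect_identical(idf$TA, TA)
  expect_identical(idf$TB, TB)
  sw <- cross_fusion(TA, TB, matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(sw$TA, TB)
  expect_equal(sw$TB, TA)
  mean_a <- cross_fusion(TA, TB, matrix(0.5, 2, 2))
  expect_equal(mean_a$TA, (TA + TB) / 2)
  expect_equal(mean_a$TB, (TA + TB) / 2)
  # linearity in the inputs
  sc <- cross_fusion(2 * TA, 2 * TB, matrix(c(.3, .1, .7, .9), 2, 2))
  base <- cross_fusion(TA, TB, matrix(c(.3, .1, .7, .9), 2, 2))
  expect_equal(sc$TA, 2 * base$TA)
  expect_equal(sc$TB, 2 * base$TB)
  expect_error(cross_fusion(TA, TB[, , , 1, drop = FALSE], diag(2)),
               "shapes")
})

test_that("dynamic weighted loss matches its closed form", {
  expect_equal(dynamic_weighted_loss(2, 4, 1, c(1, 1, 1)), 4.0)
  expect_equal(dynamic_weighted_loss(1, 4, 1, c(1, 1, 10)), 3.51)
  expect_error(dynamic_weighted_loss(-1, 0, 0, c(1, 1, 1)), "losses")
  expect_error(dynamic_weighted_loss(1, 1, 1, c(0, 1, 1)), "sigma")
  expect_equal(sum_loss(2, 4, 1), 7)
  expect_equal(sum_loss(0, 0, 0), 0)
  # dynamic(sigma = 1) = sum - (Lp + Le)/2, the algebraic identity
  for (L in list(c(2, 4, 1), c(0.3, 0.9, 0.2))) {
    expect_equal(dynamic_weighted_loss(L[1], L[2], L[3], c(1, 1, 1)),
                 sum_loss(L[1], L[2], L[3]) - (L[1] + L[2]) / 2)
  }
})

test_that("loss is coercive and increasing in each component", {
  base <- dynamic_weighted_loss(1, 1, 1, c(1, 1, 1))
  expect_gt(dynamic_weighted_loss(2, 1, 1, c(1, 1, 1)), base)
  expect_gt(dynamic_weighted_loss(1, 2, 1, c(1, 1, 1)), base)
  expect_gt(dynamic_weighted_loss(1, 1, 2, c(1, 1, 1)), base)
  expect_gt(dynamic_weighted_loss(1, 1, 1, c(1e6, 1, 1)), base)
  expect_gt(dynamic_weighted_loss(1, 1, 1, c(1e-6, 1, 1)), base)
})

test_that("gradient descent on sigma_p alone finds sigma^2 = Lp ln 10", {
  # minimize Lp/(2 sigma^2) + log10(sigma) over log sigma, Lp = 1
  ls <- 0
  for (i in 1:5000) {
    g <- mrcanet:::dynamic_loss_grad_logsigma(1, 0, 0, c(ls, 0, 0))[1]
    ls <- ls - 0.01 * g
  }
  expect_equal(exp(2 * ls), log(10), tolerance = 1e-3)
})

test_that("module-level analytic gradients match numeric differentiation", {
  set.seed(6)
  # attention
  X <- array(rnorm(3 * 3 * 8 * 2), dim = c(3, 3, 8, 2))
  att <- rand_att(r = 4, C = 8, seed = 7)
  fw <- mrcanet:::attention_forward(X, att)
  G <- array(rnorm(length(fw$out)), dim = dim(fw$out))  # d(loss)/d(out)
  bk <- mrcanet:::attention_backward(G, fw$cache)
  lossA <- function(att, X) sum(mrcanet:::attention_forward(X, att)$out * G)
  eps <- 1e-6
  for (nm in c("W1", "b1", "W2", "b2")) {
    for (i in sample(length(att[[nm]]), min(5, length(att[[nm]])))) {
      ap <- att; ap[[nm]][i] <- ap[[nm]][i] + eps
      am <- att; am[[nm]][i] <- am[[nm]][i] - eps
      num <- (lossA(ap, X) - lossA(am, X)) / (2 * eps)
      ana <- bk[[paste0("d", nm)]][i]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
    }
  }
  for (i in sample(length(X), 8)) {
    Xp <- X; Xp[i] <- Xp[i] + eps
    Xm <- X; Xm[i] <- Xm[i] - eps
    num <- (lossA(att, Xp) - lossA(att, Xm)) / (2 * eps)
    expect_lt(abs(num - bk$dX[i]) / max(1e-6, abs(num) + abs(bk$dX[i])), 1e-4)
  }
  # fusion: gradients wrt alpha
  TA <- array(rnorm(8), dim = c(2, 2, 1, 2))
  TB <- array(rnorm(8), dim = c(2, 2, 1, 2))
  GA <- array(rnorm(8), dim = c(2, 2, 1, 2))
  GB <- array(rnorm(8), dim = c(2, 2, 1, 2))
  lossF <- function(a) {
    f <- cross_fusion(TA, TB, a)
    sum(f$TA * GA) + sum(f$TB * GB)
  }
  dalpha <- matrix(c(sum(GA * TA), sum(GB * TA), sum(GA * TB), sum(GB * TB)),
                   2, 2)
  a0 <- matrix(c(.8, .2, .1, .9), 2, 2)
  for (i in 1:4) {
    ap <- a0; ap[i] <- ap[i] + eps
    am <- a0; am[i] <- am[i] - eps
    num <- (lossF(ap) - lossF(am)) / (2 * eps)
    expect_lt(abs(num - dalpha[i]), 1e-6)
  }
  # dynamic loss wrt log sigma
  lsg <- c(0.3, -0.2, 0.1)
  ana <- mrcanet:::dynamic_loss_grad_logsigma(2, 4, 1, lsg)
  for (i in 1:3) {
    lp <- lsg; lp[i] <- lp[i] + eps
    lm <- lsg; lm[i] <- lm[i] - eps
    num <- (dynamic_weighted_loss(2, 4, 1, exp(lp)) -
              dynamic_weighted_loss(2, 4, 1, exp(lm))) / (2 * eps)
    expect_lt(abs(num - ana[i]) / max(1e-6, abs(num) + abs(ana[i])), 1e-4)
  }
})

test_that("forward produces the Table-style output shapes and simplex rows", {
  cfg <- mrca_config(input_n = 16)
  mod <- mrca_init(cfg, seed = 11)
  set.seed(12)
  X <- array(runif(16 * 16 * 8 * 5), dim = c(16, 16, 8, 5))
  pr <- predict_mrca(mod, X)
  expect_equal(dim(pr$probs), c(3L, 5L))
  expect_equal(dim(pr$conc), c(2L, 5L))
  expect_equal(colSums(pr$probs), rep(1, 5), tolerance = 1e-12)
  # conv arithmetic: 16 -> 18 -> 20, FC1 consumes 32*20*20 features
  expect_equal(ncol(mod$params$fc1A_W), 32 * 20 * 20)
  expect_error(mrca_forward(mod$params, mod$state,
                            array(0, dim = c(16, 12, 8, 1)), cfg),
               "square")
})

test_that("identity cross-fusion makes a fresh MRCA equal its NO-Cross twin", {
  cfg_on <- mrca_config(input_n = 8)
  cfg_off <- mrca_config(input_n = 8, use_cross_fusion = FALSE)
  mod <- mrca_init(cfg_on, seed = 21)      # alpha initialized to identity
  set.seed(22)
  X <- array(runif(8 * 8 * 8 * 3), dim = c(8, 8, 8, 3))
  f_on <- mrca_forward(mod$params, mod$state, X, cfg_on)
  f_off <- mrca_forward(mod$params, mod$state, X, cfg_off)
  expect_equal(f_on$probs, f_off$probs)
  expect_equal(f_on$conc, f_off$conc)
})

test_that("checkpoints round-trip bit-faithfully", {
  dir <- withr::local_tempdir()
  mod <- mrca_init(mrca_config(input_n = 8), seed = 31)
  path <- file.path(dir, "ck.rds")
  save_checkpoint(mod, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, mod$params)
  expect_identical(back$state, mod$state)
  expect_identical(unclass(back$config), unclass(mod$config))
})

test_that("attention bottleneck must divide the channel count", {
  expect_error(mrca_config(reduction = 5), "divisible")
  X <- array(1, dim = c(2, 2, 6, 1))
  expect_error(channel_attention(X, zero_att(r = 4, C = 16)),
               "incompatible")
})
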