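test_that("separable-convolution cost matches the closed form", {
  cc <- conv_cost(D_K = 3, M = 1, N = 32, D_F = 26)
  expect_equal(cc$Z_N, 194688)
  expect_equal(cc$ratio, 1 / 32 + 1 / 9, tolerance = 1e-12)

  expect_equal(conv_cost(1, 4, 1, 10)$ratio, 2)  # identity-kernel edge

  set.seed(20)
  for (i in 1:100) {
    s <- list(D_K = sample(1:7, 1), M = sample(1:64, 1),
              N = sample(1:128, 1), D_F = sample(1:64, 1))
    cc <- do.call(conv_cost, s)
    expect_equal(cc$Z_S / cc$Z_N, 1 / s$N + 1 / s$D_K^2, tolerance = 1e-12)
  }
})

test_that("the network emits valid 4-class distributions", {
  m <- build_network(network_spec(), dropout = 0.45, kernel_size = 3,
                     seed = 2)
  p0 <- vitiphen:::model_probs(m, matrix(0, 3, 78))
  expect_equal(dim(p0), c(3L, 4L))
  expect_equal(rowSums(p0), rep(1, 3), tolerance = 1e-6)
  set.seed(5)
  pr <- vitiphen:::model_probs(m, matrix(runif(6 * 78), 6))
  expect_equal(rowSums(pr), rep(1, 6), tolerance = 1e-6)
  expect_true(all(pr >= 0))
})

test_that("the canonical 16-block architecture stays under 1M parameters", {
  m <- build_network(network_spec(), dropout = 0.45, kernel_size = 3,
                     seed = 1)
  expect_equal(n_params(m), 428708)
  expect_lt(n_params(m), 1e6)
  m5 <- build_network(network_spec(), dropout = 0.45, kernel_size = 5,
                      seed = 1)
  expect_gt(n_params(m5), n_params(m))  # larger stem kernel only
  expect_error(build_network(network_spec(), kernel_size = 4), "3 or 5")
  expect_error(network_spec(final_feature_width = 128L), "32 or 64")
})

test_that("backpropagation matches numerical gradients", {
  model <- build_network(tiny_spec(input_h = 6L), dropout = 0,
                         kernel_size = 3L, seed = 3)
  set.seed(1)
  n <- 5
  X <- matrix(runif(n * 18), n)
  y <- sample(4, n, TRUE)
  Z <- vitiphen:::onehot_of(y)
  cfg <- loss_config(mode = "weighted_ce", weights = c(.1, .2, .3, .4),
                     adaptive = FALSE)
  A <- as_input(X)
  fw <- vitiphen:::nn_forward(model, A, n, training = TRUE)
  probs <- vitiphen:::softmax_rows(fw$out)
  grads <- vitiphen:::nn_backward(model, fw$caches,
                                  vitiphen:::loss_grad_logits(probs, Z, cfg))
  fwd_loss <- function(m) {
    f <- vitiphen:::nn_forward(m, A, n, training = TRUE)
    vitiphen:::compute_loss(vitiphen:::softmax_rows(f$out), Z, cfg)
  }
  worst <- 0
  for (li in seq_along(model$layers)) {
    for (f in vitiphen:::param_fields(model$layers[[li]]$type)) {
      P <- model$layers[[li]][[f]]
      if (is.null(P)) next
      for (i in sample(length(P), min(3, length(P)))) {
        eps <- 1e-5
        m2 <- model
        m2$layers[[li]][[f]][i] <- P[i] + eps
        l1 <- fwd_loss(m2)
        m2$layers[[li]][[f]][i] <- P[i] - eps
        l2 <- fwd_loss(m2)
        num <- (l1 - l2) / (2 * eps)
        worst <- max(worst, abs(num - grads[[li]][[f]][i]) /
                       max(1e-6, abs(num) + abs(grads[[li]][[f]][i])))
      }
    }
  }
  expect_lt(worst, 1e-3)
})

test_that("loss identities hold", {
  set.seed(2)
  logits <- matrix(rnorm(40), 10)
  probs <- vitiphen:::softmax_rows(logits)
  y <- sample(4, 10, TRUE)
  Z <- vitiphen:::onehot_of(y)

  plain <- compute_loss(probs, Z, loss_config(mode = "plain_ce"))
  expect_equal(compute_loss(probs, Z, loss_config(mode = "weighted_ce",
                                                  adaptive = FALSE)),
               plain, tolerance = 1e-9)
  expect_equal(compute_loss(probs, Z, loss_config(mode = "focal",
                                                  focal_exponent = 0)),
               plain, tolerance = 1e-9)

  unif <- matrix(0.25, 6, 4)
  expect_equal(compute_loss(unif, vitiphen:::onehot_of(rep(2, 6)),
                            loss_config(mode = "plain_ce")),
               log(4), tolerance = 1e-9)
  perfect <- vitiphen:::onehot_of(y)
  expect_lt(compute_loss(perfect, Z, loss_config(mode = "plain_ce")), 1e-10)
})

test_that("loss gradients match numerical differentiation of the loss", {
  set.seed(3)
  logits <- matrix(rnorm(20), 5)
  Z <- vitiphen:::onehot_of(sample(4, 5, TRUE))
  for (cfg in list(loss_config(mode = "plain_ce"),
                   loss_config(mode = "weighted_ce",
                               weights = c(.4, .3, .2, .1),
                               adaptive = FALSE),
                   loss_config(mode = "focal", focal_exponent = 2))) {
    probs <- vitiphen:::softmax_rows(logits)
    g <- vitiphen:::loss_grad_logits(probs, Z, cfg)
    for (i in sample(length(logits), 6)) {
      eps <- 1e-6
      zp <- logits; zp[i] <- zp[i] + eps
      zm <- logits; zm[i] <- zm[i] - eps
      num <- (compute_loss(vitiphen:::softmax_rows(zp), Z, cfg) -
                compute_loss(vitiphen:::softmax_rows(zm), Z, cfg)) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-5)
    }
  }
})

test_that("adaptive class weights respond monotonically to class error", {
  eq <- diag(c(10, 10, 10, 10))
  st <- update_class_weights(eq, "exp")
  expect_equal(st$weights, rep(0.25, 4))

  cm <- diag(c(0, 10, 10, 10)); cm[1, 2] <- 10  # class 1 fully missed
  st2 <- update_class_weights(cm, "exp")
  expect_equal(st2$error_rate, c(1, 0, 0, 0))
  expect_equal(st2$weights[1], exp(1) / (exp(1) + 3), tolerance = 1e-12)
  expect_equal(sum(st2$weights), 1)

  # identity mapping passes already-normalized error rates through
  mk <- function(mr) {
    cm <- diag(round(100 * (1 - mr)))
    for (j in 1:4) cm[j, (j %% 4) + 1] <-
        cm[j, (j %% 4) + 1] + round(100 * mr[j])
    cm
  }
  st3 <- update_class_weights(mk(c(0.2, 0.2, 0.3, 0.3)), "identity")
  expect_equal(st3$weights, c(0.2, 0.2, 0.3, 0.3), tolerance = 1e-12)

  # strictly monotone mapping: larger error -> strictly larger weight
  lo <- update_class_weights(mk(c(0.1, 0.2, 0.2, 0.2)), "exp")
  hi <- update_class_weights(mk(c(0.4, 0.2, 0.2, 0.2)), "exp")
  expect_gt(hi$weights[1], lo$weights[1])

  # absent class carries its previous recall forward
  ab <- diag(c(0, 5, 5, 5))
  prev <- update_class_weights(diag(c(5, 5, 5, 5)), "exp")
  stc <- update_class_weights(ab, "exp", prev)
  expect_equal(stc$recall[1], 1)
})

test_that("a small network overfits a 50-sample toy set", {
  set.seed(42)
  smp <- small_samples()
  idx <- sample(nrow(smp$train$X), 50)
  toy <- list(X = smp$train$X[idx, ], y = smp$train$y[idx])
  th <- list(learning_rate = 2e-3, batch_size = 16L, dropout = 0,
             kernel_size = 3L, epochs = 100L)
  fit <- train_model(toy, toy, th, loss_config(mode = "plain_ce"),
                     tiny_spec(), seed = 7)
  ev <- vitiphen:::eval_on(fit$model, toy$X, toy$y,
                           loss_config(mode = "plain_ce"))
  expect_gte(ev$accuracy, 0.98)
})

test_that("training rejects sets with an absent class, naming it", {
  smp <- small_samples()
  keep <- smp$train$y != 3
  crippled <- list(X = smp$train$X[keep, ], y = smp$train$y[keep])
  expect_error(
    train_model(crippled, smp$val,
                list(learning_rate = 1e-3, batch_size = 32L, dropout = 0.2,
                     kernel_size = 3L, epochs = 1L),
                spec = tiny_spec()),
    "veraison")
})

test_that("training is deterministic and its loss decreases early", {
  smp <- small_samples()
  th <- list(learning_rate = 1.3e-3, batch_size = 64L, dropout = 0.3,
             kernel_size = 3L, epochs = 6L)
  f1 <- train_model(smp$train, smp$val, th, loss_config(),
                    tiny_spec(), seed = 21)
  f2 <- train_model(smp$train, smp$val, th, loss_config(),
                    tiny_spec(), seed = 21)
  expect_identical(f1$history, f2$history)
  # moving-average train loss over the first epochs is decreasing
  tl <- f1$history$train_loss
  expect_lt(mean(tl[4:6]), mean(tl[1:3]))
  # adaptive weights recorded each epoch and summing to 1
  w <- as.matrix(f1$history[, paste0("w_", c("budburst", "flowering",
                                             "veraison", "harvest"))])
  expect_equal(unname(rowSums(w)), rep(1, 6), tolerance = 1e-9)
})

test_that("per-interval prediction is deterministic with unit-sum rows", {
  smp <- small_samples()
  th <- list(learning_rate = 1.3e-3, batch_size = 64L, dropout = 0.3,
             kernel_size = 3L, epochs = 4L)
  fit <- train_model(smp$train, smp$val, th, loss_config(), tiny_spec(),
                     seed = 3)
  s <- smp$val_sites[[1]]
  pr <- predict_stages(fit$model, s, smp$norm)
  expect_equal(nrow(pr), 26)
  psum <- rowSums(pr[, c("p_budburst", "p_flowering", "p_veraison",
                         "p_harvest")])
  expect_equal(psum, rep(1, 26), tolerance = 1e-6)
  expect_identical(pr, predict_stages(fit$model, s, smp$norm))
  expect_true(all(pr$stage_pred %in% c("budburst", "flowering", "veraison",
                                       "harvest")))
})

test_that("stage transitions use the interval-midpoint convention", {
  stages <- c("budburst", "budburst", "flowering", "flowering", "veraison",
              rep("harvest", 21))
  on <- transitions_from_stages(stages, season_start_doy = 1L)
  expect_equal(unname(on["flowering"]), 36)  # midpoint of interval 3
  expect_equal(unname(on["budburst"]), 8)
  expect_equal(unname(on["harvest"]), interval_midpoint_doy(6, 1))

  # degenerate single-stage sequence reports only that stage
  allf <- transitions_from_stages(rep("flowering", 26))
  expect_identical(names(allf), "flowering")

  # non-monotone noise is repaired by the running maximum
  noisy <- c("budburst", "flowering", "budburst", "flowering",
             rep("veraison", 22))
  on2 <- transitions_from_stages(noisy)
  expect_equal(unname(on2["flowering"]), interval_midpoint_doy(2, 1))
  expect_error(transitions_from_stages(c("x", rep("harvest", 25))),
               "unknown stage")
})
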