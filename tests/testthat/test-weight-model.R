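# FFNN weight regression: Levenberg-Marquardt training, stopping rules,
# prediction, node sweep, evaluation protocols.

make_ffnn <- function(theta, h, p = 13) {
  structure(list(theta = theta, hidden_nodes = h, input_dim = p,
                 log = NULL, stop_reason = "constructed"),
            class = "ffnn_model")
}

test_that("a linear target is fit to near-zero training loss", {
  set.seed(3)
  x <- matrix(runif(50 * 13), 50, 13)
  y <- 0.5 * x[, 1] + 0.2 * x[, 5] + 0.1
  m <- train_ffnn(x, y, 1, train_config(seed = 1))
  sse <- sum((predict(m, x[m$train_idx, ]) - y[m$train_idx])^2)
  expect_lt(sse, 1e-6)
})

test_that("training is bit-identical under a fixed seed", {
  set.seed(4)
  x <- matrix(runif(60 * 13), 60, 13)
  y <- rowSums(x[, 1:3]) + rnorm(60, 0, 0.05)
  m1 <- train_ffnn(x, y, 2, train_config(seed = 9))
  m2 <- train_ffnn(x, y, 2, train_config(seed = 9))
  expect_identical(m1$theta, m2$theta)
  expect_identical(m1$log, m2$log)
  m3 <- train_ffnn(x, y, 2, train_config(seed = 10))
  expect_false(identical(m1$theta, m3$theta))
})

test_that("epoch cap and accepted-step loss monotonicity hold", {
  set.seed(5)
  x <- matrix(runif(80 * 13), 80, 13)
  y <- sin(3 * x[, 1]) + x[, 2]^2 + rnorm(80, 0, 0.1)
  m1 <- train_ffnn(x, y, 3, train_config(seed = 2, max_epoch = 1))
  expect_equal(nrow(m1$log), 1)
  m <- train_ffnn(x, y, 3, train_config(seed = 2, max_epoch = 100))
  expect_lte(nrow(m$log), 100)
  expect_true(all(diff(m$log$train_sse) <= 1e-12))
})

test_that("six consecutive validation increases stop the training", {
  set.seed(101)
  x <- matrix(runif(58 * 13), 58, 13)
  y <- rnorm(58)                       # pure noise: overfits quickly
  m <- train_ffnn(x, y, 3, train_config(seed = 1))
  expect_equal(m$stop_reason, "validation")
  tail_val <- utils::tail(m$log$val_mse, 7)
  expect_true(all(diff(tail_val[-1]) >= 0) || all(diff(tail_val) > 0))
})

test_that("the recorded stop reason is always one of the three rules", {
  set.seed(6)
  x <- matrix(runif(40 * 13), 40, 13)
  for (seed in 1:3) {
    m <- train_ffnn(x, 2 * x[, 1] + rnorm(40, 0, 0.01), 2,
                    train_config(seed = seed, max_epoch = 30))
    expect_true(m$stop_reason %in% c("convergence", "validation", "max_epoch"))
    expect_lte(nrow(m$log), 30)
  }
})

test_that("prediction follows the logsig/purelin architecture", {
  # all-zero weights: prediction equals the output bias
  p <- 13; h <- 4
  theta <- rep(0, h * p + 2 * h + 1)
  theta[length(theta)] <- 7.5
  m <- make_ffnn(theta, h)
  expect_equal(predict(m, rep(0.3, 13)), 7.5)
  # saturated hidden units: prediction approaches sum(w2) + b2
  theta2 <- theta
  theta2[h * p + seq_len(h)] <- 50                  # huge hidden biases
  theta2[h * p + h + seq_len(h)] <- c(1, 2, 3, 4)   # w2
  m2 <- make_ffnn(theta2, h)
  expect_equal(predict(m2, rep(0.5, 13)), 10 + 7.5, tolerance = 1e-6)
  expect_error(predict(m, rep(0.1, 12)), "expected 13")
})

test_that("fewer samples than parameters is rejected with advice", {
  x <- matrix(runif(20 * 13), 20, 13)
  expect_error(train_ffnn(x, rnorm(20), 10, train_config()),
               "fewer hidden nodes")
})

test_that("node sweep averages runs and selects the argmin node count", {
  set.seed(8)
  x <- matrix(runif(120 * 13), 120, 13)
  y <- 40 + 30 * x[, 1] * x[, 5] + rnorm(120, 0, 0.5)
  sw1 <- node_sweep(x, y, nodes = 1:2, runs_per_node = 1, seed = 3)
  sw2 <- node_sweep(x, y, nodes = 1:2, runs_per_node = 1, seed = 3)
  expect_identical(sw1$table, sw2$table)
  expect_equal(nrow(sw1$table), 2)
  # mean over runs contract: a 2-run sweep's cell equals the mean of the
  # two corresponding single runs
  sw <- node_sweep(x, y, nodes = 2, runs_per_node = 2, seed = 3)
  singles <- vapply(1:2, function(run) {
    cfg <- train_config(seed = as.integer(3 + 1000 + run))
    model <- train_ffnn(x, y, 2, cfg)
    mean(abs(predict(model, x[model$val_idx, ]) - y[model$val_idx]))
  }, numeric(1))
  expect_equal(sw$table$mean_mae, mean(singles))
  expect_equal(sw$best_nodes, sw$table$nodes[which.min(sw$table$mean_mae)])
})

test_that("MAE evaluation matches its definition per subject and overall", {
  p <- 13; h <- 1
  theta <- rep(0, h * p + 2 * h + 1)
  theta[length(theta)] <- 60                        # constant 60 kg predictor
  m <- make_ffnn(theta, h)
  x <- matrix(0.5, 6, 13)
  ids <- rep(c("A", "B"), each = 3)
  ev <- evaluate_mae(m, x, rep(57, 6), ids)         # constant +3 bias
  expect_equal(ev$overall_mae, 3)
  expect_equal(ev$overall_std, 0)
  expect_equal(ev$per_subject$mae_kg, c(3, 3))
  ev0 <- evaluate_mae(m, x, rep(60, 6), ids)
  expect_equal(ev0$overall_mae, 0)
  expect_error(evaluate_mae(m, x, rep(60, 5), ids), "agree")
})

test_that("a trained model beats a random predictor on the mass link", {
  cohort <- sample_cohort(12, seed = 31, noise_sd_kg = 1)
  cam <- default_camera()
  df <- session_features(cohort, cam, n_frames = 6, seed = 44)
  x <- normalize_features(as.matrix(df[, 6:18]))$features
  y <- df$true_weight_kg
  m <- train_ffnn(x, y, 2, train_config(seed = 5))
  mae_model <- mean(abs(predict(m, x) - y))
  set.seed(1)
  mae_rand <- mean(abs(runif(length(y), 40, 119) - y))
  expect_lt(mae_model, mae_rand)
})

test_that("random-half generalization averages exactly n_repeats runs", {
  set.seed(9)
  x <- matrix(runif(80 * 13), 80, 13)
  y <- 50 + 20 * x[, 1] + rnorm(80, 0, 0.5)
  us1 <- unknown_subject_split(x, y, hidden_nodes = 2, seed = 7, n_repeats = 1)
  us2 <- unknown_subject_split(x, y, hidden_nodes = 2, seed = 7, n_repeats = 1)
  expect_identical(us1, us2)
  us3 <- unknown_subject_split(x, y, hidden_nodes = 2, seed = 7, n_repeats = 3)
  expect_equal(nrow(us3$per_repeat), 3)
  expect_equal(us3$mae_kg, mean(us3$per_repeat$mae_kg))
})
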