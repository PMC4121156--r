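# Single-hidden-layer feedforward network (logistic sigmoid hidden layer,
# linear output) trained by Levenberg-Marquardt with an explicit Jacobian,
# early stopping on the validation split, node sweep and MAE evaluation.

#' Training configuration for the weight network
#'
#' @param val_fraction fraction of samples held out for validation (the
#'   70/30 protocol).
#' @param patience consecutive validation-error increases allowed before
#'   early stopping.
#' @param max_epoch hard cap on accepted Levenberg-Marquardt steps.
#' @param seed seed controlling the split and the weight initialization.
#' @param lambda_init,lambda_factor initial LM damping and its multiplicative
#'   update (divided by the factor on an accepted step, multiplied on a
#'   rejected one).
#' @param grad_tol,loss_tol convergence thresholds: training stops when the
#'   gradient's max-norm falls below `grad_tol` or the relative loss change
#'   below `loss_tol`.
#' @return list of class `train_config`.
#' @export
train_config <- function(val_fraction = 0.3, patience = 6, max_epoch = 100,
                         seed = 1, lambda_init = 1e-3, lambda_factor = 10,
                         grad_tol = 1e-7, loss_tol = 1e-9) {
  if (val_fraction <= 0 || val_fraction >= 1) {
    stopf("val_fraction must lie in (0, 1)")
  }
  if (patience < 1 || max_epoch < 1) stopf("patience and max_epoch must be >= 1")
  structure(list(val_fraction = val_fraction, patience = as.integer(patience),
                 max_epoch = as.integer(max_epoch), seed = as.integer(seed),
                 lambda_init = lambda_init, lambda_factor = lambda_factor,
                 grad_tol = grad_tol, loss_tol = loss_tol),
            class = "train_config")
}

logsig <- function(z) 1 / (1 + exp(-z))

ffnn_forward <- function(theta, x, h) {
  p <- ncol(x)
  W1 <- matrix(theta[seq_len(h * p)], h, p)
  b1 <- theta[h * p + seq_len(h)]
  w2 <- theta[h * p + h + seq_len(h)]
  b2 <- theta[h * p + 2 * h + 1]
  S <- logsig(sweep(x %*% t(W1), 2, b1, "+"))
  list(yhat = as.numeric(S %*% w2 + b2), S = S, w2 = w2)
}

# Jacobian of the network output wrt the parameter vector, n x P, with the
# parameter order (vec(W1), b1, w2, b2).
ffnn_jacobian <- function(fwd, x, h) {
  p <- ncol(x)
  G <- fwd$S * (1 - fwd$S) * matrix(fwd$w2, nrow(x), h, byrow = TRUE)
  JW1 <- G[, rep(seq_len(h), p), drop = FALSE] *
    x[, rep(seq_len(p), each = h), drop = FALSE]
  cbind(JW1, G, fwd$S, 1)
}

#' Train the weight-regression network by Levenberg-Marquardt
#'
#' Minimizes the sum of squared errors on a random 70\% training split by
#' damped Gauss-Newton steps with an explicit Jacobian of the 13 -> h -> 1
#' network. Training stops at the first of: optimizer convergence (gradient
#' or relative loss change below tolerance, or damping overflow), the
#' validation error increasing for `patience` consecutive epochs, or
#' `max_epoch` accepted steps. The returned model carries the weights of the
#' best validation epoch and a per-epoch log.
#'
#' @param x numeric matrix of normalized features (samples x features, in
#'   `[0, 1]`).
#' @param y numeric target vector (kg).
#' @param hidden_nodes number of hidden units (>= 1).
#' @param config a [train_config()].
#' @return object of class `ffnn_model` with elements `theta`, `hidden_nodes`,
#'   `input_dim`, `log` (data.frame epoch/train_sse/val_mse/lambda),
#'   `stop_reason`, `train_idx`, `val_idx`.
#' @export
train_ffnn <- function(x, y, hidden_nodes, config = train_config()) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  h <- as.integer(hidden_nodes)
  if (h < 1) stopf("hidden_nodes must be >= 1")
  if (n < 10) stopf("at least 10 samples are required")
  n_par <- h * p + 2 * h + 1
  n_train <- n - max(1L, round(config$val_fraction * n))
  if (n < n_par) {
    stopf("fewer samples (%d) than network parameters (%d): use fewer hidden nodes",
          n, n_par)
  }
  with_seed(config$seed, {
    idx <- sample.int(n)
    tr <- idx[seq_len(n_train)]
    va <- idx[(n_train + 1):n]
    theta <- runif(n_par, -0.5, 0.5) / sqrt(p + 1)
  })
  xt <- x[tr, , drop = FALSE]; yt <- y[tr]
  xv <- x[va, , drop = FALSE]; yv <- y[va]

  lambda <- config$lambda_init
  fwd <- ffnn_forward(theta, xt, h)
  sse <- sum((yt - fwd$yhat)^2)
  val_mse <- function(th) {
    mean((yv - ffnn_forward(th, xv, h)$yhat)^2)
  }
  best_val <- val_mse(theta)
  best_theta <- theta
  prev_val <- best_val
  inc_run <- 0L
  log <- vector("list", config$max_epoch)
  stop_reason <- "max_epoch"
  epoch <- 0L
  while (epoch < config$max_epoch) {
    r <- yt - fwd$yhat
    J <- ffnn_jacobian(fwd, xt, h)
    g <- crossprod(J, r)
    if (max(abs(g)) < config$grad_tol) { stop_reason <- "convergence"; break }
    Hm <- crossprod(J)
    accepted <- FALSE
    while (lambda <= 1e10) {
      delta <- tryCatch(
        solve(Hm + diag(lambda, n_par), g),
        error = function(e) NULL
      )
      if (!is.null(delta)) {
        cand <- theta + as.numeric(delta)
        fwd_c <- ffnn_forward(cand, xt, h)
        sse_c <- sum((yt - fwd_c$yhat)^2)
        if (sse_c < sse) {
          rel <- (sse - sse_c) / max(sse, .Machine$double.eps)
          theta <- cand; fwd <- fwd_c
          sse_old <- sse; sse <- sse_c
          lambda <- lambda / config$lambda_factor
          accepted <- TRUE
          if (rel < config$loss_tol) stop_reason <- "convergence"
          break
        }
      }
      lambda <- lambda * config$lambda_factor
    }
    if (!accepted) { stop_reason <- "convergence"; break }
    epoch <- epoch + 1L
    v <- val_mse(theta)
    log[[epoch]] <- data.frame(epoch = epoch, train_sse = sse,
                               val_mse = v, lambda = lambda)
    if (v < best_val) { best_val <- v; best_theta <- theta }
    inc_run <- if (v > prev_val) inc_run + 1L else 0L
    prev_val <- v
    if (inc_run >= config$patience) { stop_reason <- "validation"; break }
    if (stop_reason == "convergence") break
  }
  structure(list(
    theta = best_theta, hidden_nodes = h, input_dim = p,
    log = do.call(rbind, log[seq_len(epoch)]), stop_reason = stop_reason,
    train_idx = tr, val_idx = va, best_val_mse = best_val
  ), class = "ffnn_model")
}

#' Predict body weight from normalized features
#'
#' `purelin(W2 %*% logsig(W1 x + b1) + b2)`.
#'
#' @param object an `ffnn_model`.
#' @param newdata numeric vector of length `input_dim` or a matrix with that
#'   many columns.
#' @param ... unused.
#' @return numeric vector of predictions (kg).
#' @export
predict.ffnn_model <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
  if (ncol(x) != object$input_dim) {
    stopf("expected %d features, got %d", object$input_dim, ncol(x))
  }
  ffnn_forward(object$theta, x, object$hidden_nodes)$yhat
}

#' @export
print.ffnn_model <- function(x, ...) {
  cat(sprintf("FFNN %d -> %d -> 1 (logsig/purelin), stop: %s, epochs: %d\n",
              x$input_dim, x$hidden_nodes, x$stop_reason,
              if (is.null(x$log)) 0L else nrow(x$log)))
  invisible(x)
}

#' Hidden-node sweep
#'
#' Trains `runs_per_node` networks with distinct seeds for each candidate
#' node count and averages their MAE and the standard deviation of absolute
#' errors; the best node count is the argmin of the mean MAE (smallest count
#' on ties). Evaluation uses `x_test`/`y_test` when supplied, otherwise each
#' run's own validation split.
#'
#' @param x,y training features and targets.
#' @param nodes integer vector of hidden-node counts (the full protocol is
#'   `1:40`).
#' @param runs_per_node trainings per node count (the full protocol is 10).
#' @param seed base seed; run seeds are derived deterministically from it.
#' @param x_test,y_test optional held-out evaluation set.
#' @param config base [train_config()]; its seed is overridden per run.
#' @return list of class `sweep_result` with `table` (data.frame `nodes`,
#'   `mean_mae`, `mean_std`) and `best_nodes`.
#' @export
node_sweep <- function(x, y, nodes = 1:40, runs_per_node = 10, seed = 1,
                       x_test = NULL, y_test = NULL, config = train_config()) {
  rows <- lapply(seq_along(nodes), function(i) {
    maes <- numeric(runs_per_node)
    stds <- numeric(runs_per_node)
    for (run in seq_len(runs_per_node)) {
      cfg <- config
      cfg$seed <- as.integer(seed + 1000L * i + run)
      model <- train_ffnn(x, y, nodes[i], cfg)
      if (is.null(x_test)) {
        pe <- predict(model, x[model$val_idx, , drop = FALSE]) - y[model$val_idx]
      } else {
        pe <- predict(model, as.matrix(x_test)) - y_test
      }
      maes[run] <- mean(abs(pe))
      stds[run] <- if (length(pe) > 1) sd(abs(pe)) else 0
    }
    data.frame(nodes = nodes[i], mean_mae = mean(maes), mean_std = mean(stds))
  })
  table <- do.call(rbind, rows)
  structure(list(table = table,
                 best_nodes = table$nodes[which.min(table$mean_mae)],
                 runs_per_node = runs_per_node),
            class = "sweep_result")
}

#' Overall and per-subject MAE of weight predictions
#'
#' @param model an `ffnn_model`.
#' @param x normalized feature matrix of the evaluation frames.
#' @param y true weights per frame (kg).
#' @param subject_ids subject identifier per frame.
#' @return list with `overall_mae`, `overall_std` (sd of absolute errors),
#'   and `per_subject` (data.frame `subject_id`, `real_weight_kg`, `mae_kg`,
#'   `std_kg`, `n_frames`).
#' @export
evaluate_mae <- function(model, x, y, subject_ids) {
  x <- as.matrix(x)
  if (nrow(x) == 0) stopf("empty evaluation set")
  if (length(y) != nrow(x) || length(subject_ids) != nrow(x)) {
    stopf("x, y and subject_ids must agree in length")
  }
  abs_err <- abs(predict(model, x) - y)
  per <- lapply(split(seq_along(y), subject_ids), function(ii) {
    data.frame(subject_id = subject_ids[ii[1]],
               real_weight_kg = mean(y[ii]),
               mae_kg = mean(abs_err[ii]),
               std_kg = if (length(ii) > 1) sd(abs_err[ii]) else 0,
               n_frames = length(ii))
  })
  list(overall_mae = mean(abs_err),
       overall_std = if (length(abs_err) > 1) sd(abs_err) else 0,
       per_subject = do.call(rbind, c(per, list(make.row.names = FALSE))))
}

#' Repeated random-half generalization experiment
#'
#' Splits the frames into random equal halves, trains on the first and tests
#' on the second, and averages the MAE and the standard deviation of absolute
#' errors over `n_repeats` partitions (the reference protocol uses 100).
#'
#' @param x,y features and targets per frame.
#' @param hidden_nodes node count used in every repeat.
#' @param seed base seed; deterministic per repeat.
#' @param n_repeats number of random partitions.
#' @param config base [train_config()].
#' @return list with `mae_kg`, `std_kg`, `per_repeat` data.frame.
#' @export
unknown_subject_split <- function(x, y, hidden_nodes = 27, seed = 1,
                                  n_repeats = 100, config = train_config()) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 8) stopf("too few frames for a half split")
  res <- lapply(seq_len(n_repeats), function(rep) {
    idx <- with_seed(seed + rep, sample.int(n))
    half <- floor(n / 2)
    tr <- idx[seq_len(half)]
    te <- idx[(half + 1):n]
    cfg <- config
    cfg$seed <- as.integer(seed + 7919L * rep)
    model <- train_ffnn(x[tr, , drop = FALSE], y[tr], hidden_nodes, cfg)
    err <- abs(predict(model, x[te, , drop = FALSE]) - y[te])
    data.frame(repeat_index = rep, mae_kg = mean(err), std_kg = sd(err))
  })
  per <- do.call(rbind, res)
  list(mae_kg = mean(per$mae_kg), std_kg = mean(per$std_kg), per_repeat = per)
}
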