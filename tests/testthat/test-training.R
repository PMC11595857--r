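test_that("cross-entropy matches direct evaluation of the formula", {
  # perfect prediction
  p <- diag(3)[c(1, 2, 3), ]
  expect_equal(cross_entropy_loss(p, c(0L, 1L, 2L)), 0)
  # uniform prediction: ln M for any labels
  for (M in c(2, 5, 61)) {
    pu <- matrix(1 / M, 4, M)
    expect_equal(cross_entropy_loss(pu, sample(0:(M - 1), 4, TRUE)), log(M))
  }
  # two-sample worked case against an independent scalar evaluation
  p2 <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.1, 0.8))
  expect_equal(cross_entropy_loss(p2, c(0L, 2L)), -(log(0.7) + log(0.8)) / 2)

  # the logit path agrees with the probability path and is finite on
  # extreme scores
  set.seed(61)
  logits <- matrix(rnorm(12), 3, 4)
  prob <- exp(logits) / rowSums(exp(logits))
  y <- c(0L, 3L, 1L)
  ce <- softmax_cross_entropy(logits, y)
  expect_equal(ce$loss, cross_entropy_loss(prob, y), tolerance = 1e-12)
  expect_true(is.finite(softmax_cross_entropy(logits * 1e4, y)$loss))
  # gradient of the logit path agrees with central differences
  eps <- 1e-6
  for (i in c(1, 5, 9)) {
    lp <- logits; lp[i] <- lp[i] + eps
    lm <- logits; lm[i] <- lm[i] - eps
    num <- (softmax_cross_entropy(lp, y)$loss -
            softmax_cross_entropy(lm, y)$loss) / (2 * eps)
    expect_equal(ce$grad[i], num, tolerance = 1e-6)
  }
})

test_that("malformed loss inputs are rejected", {
  p <- rbind(c(0.6, 0.4), c(0.5, 0.5))
  expect_error(cross_entropy_loss(p, c(0L, 2L)), "index 2")
  expect_error(cross_entropy_loss(p * 2, c(0L, 1L)), "sum to 1")
  expect_error(cross_entropy_loss(rbind(c(1, 0)), 1L), "zero probability")
})

test_that("seeding makes initialization and whole runs reproducible", {
  set_global_seed(2022)
  m1 <- build_esa_resnet34(tiny_arch())
  set_global_seed(2022)
  m2 <- build_esa_resnet34(tiny_arch())
  expect_identical(m1$params, m2$params)
  set_global_seed(1)
  a <- build_esa_resnet34(tiny_arch())
  set_global_seed(2)
  b <- build_esa_resnet34(tiny_arch())
  expect_false(identical(a$params["head.fc"], b$params["head.fc"]))
})

test_that("plateau scheduler halves the rate after each full plateau", {
  s <- plateau_scheduler(factor = 0.5, patience = 3, mode = "min")
  curve <- c(1.0, 0.9, 0.8, 0.8, 0.8, 0.8, 0.7, 0.7, 0.7, 0.7)
  mults <- vapply(curve, s$update, numeric(1))
  expect_equal(mults, c(1, 1, 1, 1, 1, 0.5, 0.5, 0.5, 0.5, 0.25))
  # multipliers are non-increasing and each drop is exactly x0.5
  drops <- mults[-1] / head(mults, -1)
  expect_true(all(drops %in% c(1, 0.5)))
})

test_that("early stopping halts exactly patience epochs after the last improvement", {
  # constant validation accuracy from epoch 1: stop at epoch 1 + 50
  st <- early_stopper(patience = 50, mode = "max")
  stops <- vapply(rep(0.4, 60), st$update, logical(1))
  expect_equal(which(stops)[1], 51)
  # last improvement at epoch 7: stop at epoch 57
  st2 <- early_stopper(patience = 50, mode = "max")
  curve <- c(0.1, 0.2, 0.2, 0.25, 0.25, 0.25, 0.3, rep(0.3, 60))
  stops2 <- vapply(curve, st2$update, logical(1))
  expect_equal(which(stops2)[1], 57)
  expect_equal(st2$state()$best_epoch, 7)
})

test_that("a one-epoch run yields one record, and epoch-1 loss sits near ln M", {
  ds <- tiny_synthetic(samples_per_class = 8)
  cfg <- training_config(batch_size = 20, max_epochs = 1,
                         early_stop_patience = 1, seed = 2022)
  set_global_seed(2022)
  m <- build_esa_resnet34(tiny_arch())
  fit <- train_model(m, list(x = ds$x, y = ds$y), list(x = ds$x, y = ds$y),
                     cfg)
  expect_equal(nrow(fit$history), 1)
  expect_equal(fit$stop_reason, "max_epochs")
  # five balanced classes: first-epoch loss within 10% of ln 5
  expect_lt(abs(fit$history$train_loss[1] - log(5)) / log(5), 0.10)
})

test_that("training honors the early-stop bound and returns the best state", {
  ds <- tiny_synthetic(samples_per_class = 10)
  n <- length(ds$y)
  val_ix <- seq(1, n, by = 2)
  tr <- list(x = ds$x[-val_ix, , , , drop = FALSE], y = ds$y[-val_ix])
  va <- list(x = ds$x[val_ix, , , , drop = FALSE], y = ds$y[val_ix])
  cfg <- training_config(batch_size = 25, max_epochs = 12,
                         early_stop_patience = 4, scheduler_patience = 3,
                         seed = 2022)
  set_global_seed(2022)
  m <- build_esa_resnet34(tiny_arch())
  fit <- train_model(m, tr, va, cfg)
  h <- fit$history
  expect_lte(fit$stopped_epoch, fit$best_epoch + cfg$early_stop_patience + 1)
  expect_true(all(diff(h$learning_rate) <= 1e-15))
  drops <- h$learning_rate[-1] / head(h$learning_rate, -1)
  expect_true(all(abs(drops - 1) < 1e-12 | abs(drops - 0.5) < 1e-12))
  # returned parameters reproduce the best recorded validation accuracy
  ev <- evaluate_model(fit$model, va)
  expect_equal(ev$accuracy, max(h$validation_accuracy))
  expect_equal(h$validation_accuracy[fit$best_epoch],
               max(h$validation_accuracy))
})

test_that("degenerate datasets are rejected before any compute", {
  m <- build_esa_resnet34(tiny_arch(), initialize = FALSE)
  empty <- list(x = array(0, c(0, 3, 32, 32)), y = integer(0))
  ok <- tiny_synthetic(samples_per_class = 2)
  expect_error(train_model(m, empty, ok, training_config()), "empty")
  expect_error(train_model(m, list(x = ok$x, y = ok$y + 3L), ok,
                           training_config()), "out of range")
})
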