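test_that("model configuration enforces the R9 5-mer contract", {
  cfg <- model_config()
  expect_equal(cfg$units, 128L)
  expect_equal(cfg$n_layers, 3L)
  expect_equal(cfg$batch_size, 128L)
  expect_equal(cfg$max_epochs, 30L)
  expect_error(model_config(timesteps = 9), "timesteps must be 5")
  expect_error(model_config(units = 0), "positive")
  expect_error(model_config(learning_rate = 0), "positive")
})

test_that("gru_step matches the closed-form degenerate cases", {
  p0 <- list(W_z = matrix(0, 3, 7), U_z = matrix(0, 3, 3), b_z = numeric(3),
             W_r = matrix(0, 3, 7), U_r = matrix(0, 3, 3), b_r = numeric(3),
             W_h = matrix(0, 3, 7), U_h = matrix(0, 3, 3), b_h = numeric(3))
  x <- rnorm(7)
  expect_equal(gru_step(x, numeric(3), p0), numeric(3))      # z=0.5, c=0
  v <- c(1, -2, 0.5)
  expect_equal(gru_step(x, v, p0), 0.5 * v)                   # h = (1-z) v
  expect_error(gru_step(x, numeric(4), p0), "")
})

test_that("gru_step agrees with an independent scalar-loop oracle", {
  set.seed(77)
  for (i in 1:100) {
    p <- random_gru_params(3L, 7L)
    x <- rnorm(7)
    h <- rnorm(3)
    expect_lt(max(abs(gru_step(x, h, p) - gru_step_scalar(x, h, p))), 1e-10)
  }
})

test_that("forward outputs lie on the probability simplex and are deterministic", {
  fx <- get_fixture_model()
  w <- fx$split$test
  p1 <- bigru_forward(fx$fit, w$x[1, ])
  expect_length(p1, 5L)
  expect_equal(sum(p1), 1, tolerance = 1e-9)
  expect_true(all(p1 > 0 & p1 < 1))
  expect_identical(p1, bigru_forward(fx$fit, w$x[1, ]))
  expect_identical(p1, bigru_forward(fx$fit, matrix(w$x[1, ], 5, 7, byrow = TRUE)))

  calls <- predict(fx$fit, w[1:50])
  expect_equal(nrow(calls), 50L)
  expect_true(all(calls$call %in% CLASSES))
  probs <- as.matrix(calls[, c("p_A", "p_BrdU", "p_C", "p_G", "p_T")])
  expect_equal(rowSums(probs), rep(1, 50), tolerance = 1e-9)
  expect_equal(calls$call,
               CLASSES[max.col(probs, ties.method = "first")])
})

test_that("zeroed dense weights yield the uniform distribution", {
  fx <- get_fixture_model()
  m <- fx$fit
  m$params[["dense.W"]][] <- 0
  m$params[["dense.b"]][] <- 0
  p <- bigru_forward(m, fx$split$test$x[3, ])
  expect_equal(unname(p), rep(0.2, 5))
})

test_that("backpropagation matches numeric gradients on a tiny network", {
  cfg <- model_config(units = 3L, batch_size = 4L, seed = 2L)
  set.seed(4)
  params <- nanobrdu:::init_params(cfg)
  x <- matrix(rnorm(4 * 35), 4, 35)
  Y <- diag(5)[sample(5, 4, replace = TRUE), ]
  Xf <- nanobrdu:::windows_to_seqmat(x)
  loss_fn <- function(p) {
    probs <- nanobrdu:::net_forward(p, cfg, Xf, 4L)$probs
    -mean(log(rowSums(probs * Y)))
  }
  fwd <- nanobrdu:::net_forward(params, cfg, Xf, 4L, keep_cache = TRUE)
  grads <- nanobrdu:::net_backward(params, cfg, fwd, Y)
  eps <- 1e-6
  for (nm in c("dense.W", "l1.f.W", "l2.b.U", "l3.f.U", "l1.b.b")) {
    g <- grads[[nm]]
    for (idx in sample(length(g), 4)) {
      pp <- params; pp[[nm]][idx] <- pp[[nm]][idx] + eps
      pm <- params; pm[[nm]][idx] <- pm[[nm]][idx] - eps
      num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      expect_equal(g[idx], num, tolerance = 1e-4)
    }
  }
})

test_that("training learns a separable task and early stopping triggers", {
  fx <- get_fixture_model()
  log <- fx$fit$training_log
  expect_lt(log$val_loss[nrow(log)], log$val_loss[1])
  expect_gt(log$val_acc[nrow(log)], 0.8)

  # random labels: validation loss cannot keep improving; patience 1 stops early
  set.seed(8)
  w <- fx$split$train[1:200]
  w$y <- diag(5)[sample(5, 200, replace = TRUE), ]
  colnames(w$y) <- CLASSES
  fit <- brdu_bigru(w, fx$split$validation[1:100],
                    model_config(units = 4L, max_epochs = 12L, patience = 1L,
                                 seed = 3L))
  expect_lt(nrow(fit$training_log), 12L)
  expect_error(brdu_bigru(fx$split$train[0], config = model_config(units = 4)),
               "empty")
})

test_that("training is reproducible under a fixed seed", {
  fx <- get_fixture_model()
  cfg <- model_config(units = 8L, max_epochs = 2L, seed = 21L)
  f1 <- brdu_bigru(fx$split$train[1:600], fx$split$validation[1:200], cfg)
  f2 <- brdu_bigru(fx$split$train[1:600], fx$split$validation[1:200], cfg)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$training_log, f2$training_log)
})

test_that("unlabeled windows are rejected for training", {
  fx <- get_fixture_model()
  w <- fx$split$train[1:20]
  w$y[3, ] <- NA_real_
  expect_error(brdu_bigru(w, config = model_config(units = 4)), "labels")
})

test_that("save/load round trip reproduces forward outputs bit-identically", {
  fx <- get_fixture_model()
  dir <- withr::local_tempdir()
  save_model(fx$fit, file.path(dir, "m"))
  back <- load_model(file.path(dir, "m"))
  expect_identical(back$params, fx$fit$params)
  x <- fx$split$test$x[7, ]
  expect_identical(bigru_forward(back, x), bigru_forward(fx$fit, x))
  cfgj <- jsonlite::read_json(file.path(dir, "m", "config.json"))
  expect_equal(cfgj$units, fx$fit$config$units)
  expect_equal(cfgj$timesteps, 5L)

  # tampered sidecar with a non-5-mer timestep is refused
  cfgj$timesteps <- 9L
  jsonlite::write_json(cfgj, file.path(dir, "m", "config.json"),
                       auto_unbox = TRUE)
  expect_error(load_model(file.path(dir, "m")), "timesteps")
})
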