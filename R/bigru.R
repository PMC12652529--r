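# Three-layer bidirectional GRU classifier over {A, BrdU, C, G, T}.
#
# Layers 1-2 return full 5-step sequences of concatenated forward/backward
# states; layer 3 returns the concatenation of each direction's final state,
# which feeds a dense softmax layer of five output units. Forward pass,
# backpropagation through time and the Adam optimizer are implemented with
# base-R matrix algebra; there is no external deep-learning dependency.
#
# Gate convention (the common published GRU formulation):
#   z = sigmoid(W_z x + U_z h_prev + b_z)
#   r = sigmoid(W_r x + U_r h_prev + b_r)
#   c = tanh(W_h x + U_h (r * h_prev) + b_h)
#   h = (1 - z) * h_prev + z * c

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Model configuration for the BiGRU classifier
#'
#' @param units Hidden units per GRU direction (default 128, the
#'   best-performing setting for R9 5-mer data).
#' @param n_layers Stacked BiGRU layers (default 3).
#' @param input_dim Event feature dimension (7).
#' @param timesteps Window length; fixed at 5 for R9 5-mer mode.
#' @param n_classes Output classes (5: A, BrdU, C, G, T).
#' @param batch_size Minibatch size (default 128).
#' @param max_epochs Upper bound on training epochs (default 30).
#' @param patience Early-stopping patience in epochs without validation-loss
#'   improvement (default 3); the best epoch's weights are restored.
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed Seed governing initialization and epoch shuffling.
#' @return An object of class `bigru_config`.
#' @export
model_config <- function(units = 128L, n_layers = 3L, input_dim = 7L,
                         timesteps = 5L, n_classes = 5L, batch_size = 128L,
                         max_epochs = 30L, patience = 3L,
                         learning_rate = 1e-3, seed = 1L) {
  cfg <- list(units = as.integer(units), n_layers = as.integer(n_layers),
              input_dim = as.integer(input_dim), timesteps = as.integer(timesteps),
              n_classes = as.integer(n_classes), batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs), patience = as.integer(patience),
              learning_rate = learning_rate, seed = as.integer(seed))
  for (nm in c("units", "n_layers", "input_dim", "n_classes", "batch_size",
               "max_epochs", "patience"))
    if (cfg[[nm]] < 1L) stop(sprintf("'%s' must be positive", nm), call. = FALSE)
  if (cfg$timesteps != 5L)
    stop("timesteps must be 5 in R9 5-mer mode", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be positive", call. = FALSE)
  structure(cfg, class = "bigru_config")
}

#' One GRU step
#'
#' Advances a single GRU cell by one timestep using the standard gate
#' equations (reset gate applied inside the candidate's recurrent term).
#'
#' @param x Input vector (length `in_dim`).
#' @param h_prev Previous hidden state (length `units`).
#' @param params List with input weights `W_z`, `W_r`, `W_h`
#'   (`units x in_dim`), recurrent weights `U_z`, `U_r`, `U_h`
#'   (`units x units`), and biases `b_z`, `b_r`, `b_h` (length `units`).
#' @return The new hidden state (numeric vector of length `units`).
#' @examples
#' p <- list(W_z = matrix(0, 2, 3), W_r = matrix(0, 2, 3), W_h = matrix(0, 2, 3),
#'           U_z = matrix(0, 2, 2), U_r = matrix(0, 2, 2), U_h = matrix(0, 2, 2),
#'           b_z = numeric(2), b_r = numeric(2), b_h = numeric(2))
#' gru_step(c(1, 2, 3), c(4, 4), p)  # 0.5 * h_prev with all-zero weights
#' @export
gru_step <- function(x, h_prev, params) {
  u <- length(h_prev)
  stopifnot(nrow(params$W_z) == u, ncol(params$W_z) == length(x),
            nrow(params$U_z) == u, ncol(params$U_z) == u)
  z <- sigmoid(as.numeric(params$W_z %*% x + params$U_z %*% h_prev) + params$b_z)
  r <- sigmoid(as.numeric(params$W_r %*% x + params$U_r %*% h_prev) + params$b_r)
  cc <- tanh(as.numeric(params$W_h %*% x + params$U_h %*% (r * h_prev)) + params$b_h)
  (1 - z) * h_prev + z * cc
}

# --- internal batched layers -------------------------------------------------
# Parameters are a flat named list of matrices/vectors:
#   l<k>.<f|b>.W  (in_dim x 3u, gate blocks z|r|c)
#   l<k>.<f|b>.U  (u x 3u)
#   l<k>.<f|b>.b  (3u)
#   dense.W (2u x n_classes), dense.b (n_classes)
# Minibatch sequences are flat (B*T) x dim matrices, row block t holding
# timestep t for all B windows; the heavy per-layer recursions run in the
# compiled kernels (src/gru_kernels.cpp).

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

init_params <- function(cfg) {
  u <- cfg$units
  p <- list()
  in_dim <- cfg$input_dim
  for (l in seq_len(cfg$n_layers)) {
    for (d in c("f", "b")) {
      key <- sprintf("l%d.%s", l, d)
      p[[paste0(key, ".W")]] <- glorot(in_dim, 3L * u)
      p[[paste0(key, ".U")]] <- glorot(u, 3L * u)
      p[[paste0(key, ".b")]] <- numeric(3L * u)
    }
    in_dim <- 2L * u
  }
  p[["dense.W"]] <- glorot(2L * u, cfg$n_classes)
  p[["dense.b"]] <- numeric(cfg$n_classes)
  p
}

dir_params <- function(params, l, d)
  list(W = params[[sprintf("l%d.%s.W", l, d)]],
       U = params[[sprintf("l%d.%s.U", l, d)]],
       b = params[[sprintf("l%d.%s.b", l, d)]])

softmax_rows <- function(logits) {
  m <- logits[, 1L]
  for (j in 2:ncol(logits)) m <- pmax(m, logits[, j])
  e <- exp(logits - m)
  e / rowSums(e)
}

# windows matrix (B x 35) -> flat sequence matrix ((B*5) x 7)
windows_to_seqmat <- function(x) {
  B <- nrow(x)
  Xf <- matrix(0, B * 5L, 7L)
  for (t in 1:5)
    Xf[((t - 1L) * B + 1L):(t * B), ] <- x[, ((t - 1L) * 7L + 1L):(t * 7L), drop = FALSE]
  Xf
}

# Full network forward. Xf: (B*5) x 7 flat sequence matrix.
net_forward <- function(params, cfg, Xf, B, keep_cache = FALSE) {
  u <- cfg$units
  Tn <- cfg$timesteps
  inp <- Xf
  caches <- if (keep_cache) vector("list", cfg$n_layers) else NULL
  out <- NULL
  for (l in seq_len(cfg$n_layers)) {
    pf <- dir_params(params, l, "f")
    pb <- dir_params(params, l, "b")
    f <- gru_layer_forward_cpp(inp, pf$W, pf$U, pf$b, B, Tn, FALSE, keep_cache)
    b <- gru_layer_forward_cpp(inp, pb$W, pb$U, pb$b, B, Tn, TRUE, keep_cache)
    if (keep_cache) caches[[l]] <- list(f = f, b = b, X = inp)
    if (l < cfg$n_layers) inp <- cbind(f$H, b$H)
    else out <- cbind(f$h_final, b$h_final)
  }
  logits <- out %*% params[["dense.W"]]
  logits <- logits + rep(params[["dense.b"]], each = B)
  list(probs = softmax_rows(logits), out = out, caches = caches)
}

net_backward <- function(params, cfg, fwd, Y) {
  B <- nrow(fwd$probs)
  u <- cfg$units
  Tn <- cfg$timesteps
  grads <- list()
  dlogits <- (fwd$probs - Y) / B
  grads[["dense.W"]] <- crossprod(fwd$out, dlogits)
  grads[["dense.b"]] <- colSums(dlogits)
  dout <- dlogits %*% t(params[["dense.W"]])
  dY <- NULL
  for (l in cfg$n_layers:1) {
    cl <- fwd$caches[[l]]
    pf <- dir_params(params, l, "f")
    pb <- dir_params(params, l, "b")
    if (l == cfg$n_layers) {
      gf <- gru_layer_backward_cpp(cl$X, pf$W, pf$U, cl$f$Z, cl$f$R, cl$f$C,
                                   cl$f$HP, cl$f$RH, NULL,
                                   dout[, 1:u, drop = FALSE], B, Tn, FALSE)
      gb <- gru_layer_backward_cpp(cl$X, pb$W, pb$U, cl$b$Z, cl$b$R, cl$b$C,
                                   cl$b$HP, cl$b$RH, NULL,
                                   dout[, (u + 1):(2 * u), drop = FALSE],
                                   B, Tn, TRUE)
    } else {
      gf <- gru_layer_backward_cpp(cl$X, pf$W, pf$U, cl$f$Z, cl$f$R, cl$f$C,
                                   cl$f$HP, cl$f$RH,
                                   dY[, 1:u, drop = FALSE], NULL, B, Tn, FALSE)
      gb <- gru_layer_backward_cpp(cl$X, pb$W, pb$U, cl$b$Z, cl$b$R, cl$b$C,
                                   cl$b$HP, cl$b$RH,
                                   dY[, (u + 1):(2 * u), drop = FALSE], NULL,
                                   B, Tn, TRUE)
    }
    key <- sprintf("l%d", l)
    grads[[paste0(key, ".f.W")]] <- gf$dW
    grads[[paste0(key, ".f.U")]] <- gf$dU
    grads[[paste0(key, ".f.b")]] <- as.numeric(gf$db)
    grads[[paste0(key, ".b.W")]] <- gb$dW
    grads[[paste0(key, ".b.U")]] <- gb$dU
    grads[[paste0(key, ".b.b")]] <- as.numeric(gb$db)
    dY <- gf$dX + gb$dX
  }
  grads
}

adam_update <- function(params, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

labels_required <- function(w) {
  if (is.null(w$y) || anyNA(w$y))
    stop("all windows must carry ground-truth labels for training", call. = FALSE)
  w$y
}

# Chunked forward over a window matrix; returns n x 5 probability matrix.
net_predict_probs <- function(params, cfg, x, chunk = 4096L) {
  n <- nrow(x)
  probs <- matrix(0, n, cfg$n_classes)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    Xf <- windows_to_seqmat(x[i:j, , drop = FALSE])
    probs[i:j, ] <- net_forward(params, cfg, Xf, j - i + 1L)$probs
    i <- j + 1L
  }
  probs
}

eval_loss_acc <- function(params, cfg, w) {
  probs <- net_predict_probs(params, cfg, w$x)
  y <- w$y
  py <- rowSums(probs * y)
  loss <- -mean(log(pmax(py, 1e-12)))
  acc <- mean(max.col(probs, ties.method = "first") ==
                max.col(y, ties.method = "first"))
  list(loss = loss, acc = acc)
}

#' Fit the three-layer BiGRU BrdU classifier
#'
#' Trains the sequence classifier on labeled 5-mer feature windows by
#' minimizing categorical cross-entropy with Adam, monitoring validation
#' loss with an early-stopping callback: training stops once the validation
#' loss has failed to improve for `config$patience` consecutive epochs, and
#' the parameters of the best validation epoch are restored. Initialization
#' and epoch shuffling are governed by `config$seed`, so a fit is
#' reproducible on a given machine.
#'
#' @param train Labeled [brdu_windows()] training set.
#' @param validation Labeled validation set; if `NULL`, the training loss is
#'   monitored instead.
#' @param config A [model_config()].
#' @param verbose Print one line per epoch.
#' @return An object of class `brdu_bigru`: list with `config`, `params`
#'   (named weight matrices), `training_log` (per-epoch losses and
#'   accuracies), `best_epoch` and `classes`.
#' @seealso [predict.brdu_bigru()], [save_model()], [load_model()]
#' @export
brdu_bigru <- function(train, validation = NULL, config = model_config(),
                       verbose = FALSE) {
  stopifnot(inherits(train, "brdu_windows"), inherits(config, "bigru_config"))
  if (n_windows(train) == 0L) stop("empty training set", call. = FALSE)
  Ytr <- labels_required(train)
  dimnames(Ytr) <- NULL  # keep parameter matrices free of label dimnames
  if (!is.null(validation)) {
    stopifnot(inherits(validation, "brdu_windows"))
    if (n_windows(validation) == 0L) stop("empty validation set", call. = FALSE)
    labels_required(validation)
  }
  cfg <- config
  n <- n_windows(train)

  with_seed(cfg$seed, {
    params <- init_params(cfg)
    state <- list(m = lapply(params, function(p) p * 0),
                  v = lapply(params, function(p) p * 0))
    step <- 0L
    best <- list(loss = Inf, params = params, epoch = 0L)
    stall <- 0L
    log_rows <- vector("list", cfg$max_epochs)

    for (epoch in seq_len(cfg$max_epochs)) {
      perm <- sample.int(n)
      tr_loss <- 0; tr_correct <- 0L
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- perm[start:min(start + cfg$batch_size - 1L, n)]
        Xf <- windows_to_seqmat(train$x[idx, , drop = FALSE])
        Y <- Ytr[idx, , drop = FALSE]
        fwd <- net_forward(params, cfg, Xf, length(idx), keep_cache = TRUE)
        py <- rowSums(fwd$probs * Y)
        tr_loss <- tr_loss - sum(log(pmax(py, 1e-12)))
        tr_correct <- tr_correct + sum(max.col(fwd$probs, ties.method = "first") ==
                                         max.col(Y, ties.method = "first"))
        grads <- net_backward(params, cfg, fwd, Y)
        step <- step + 1L
        upd <- adam_update(params, grads, state, cfg$learning_rate, step)
        params <- upd$params
        state <- upd$state
      }
      train_loss <- tr_loss / n
      train_acc <- tr_correct / n
      if (!is.null(validation)) {
        vl <- eval_loss_acc(params, cfg, validation)
      } else {
        vl <- list(loss = train_loss, acc = train_acc)
      }
      log_rows[[epoch]] <- data.frame(epoch = epoch, train_loss = train_loss,
                                      train_acc = train_acc,
                                      val_loss = vl$loss, val_acc = vl$acc)
      if (verbose)
        message(sprintf("epoch %2d  train loss %.4f acc %.4f | val loss %.4f acc %.4f",
                        epoch, train_loss, train_acc, vl$loss, vl$acc))
      if (vl$loss < best$loss) {
        best <- list(loss = vl$loss, params = params, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
    }

    structure(list(config = cfg, params = best$params,
                   training_log = do.call(rbind, log_rows[!vapply(log_rows, is.null, logical(1))]),
                   best_epoch = best$epoch, classes = CLASS_NAMES),
              class = "brdu_bigru")
  })
}

#' @export
print.brdu_bigru <- function(x, ...) {
  cfg <- x$config
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("BiGRU BrdU basecaller: %d layers x 2 directions x %d units, %d parameters\n",
              cfg$n_layers, cfg$units, np))
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = " ")))
  if (!is.null(x$training_log))
    cat(sprintf("  trained %d epoch(s); best validation epoch %d (loss %.4f)\n",
                nrow(x$training_log), x$best_epoch,
                x$training_log$val_loss[x$best_epoch]))
  invisible(x)
}

#' @export
summary.brdu_bigru <- function(object, ...) {
  print(object)
  cat("\nTraining log:\n")
  print(object$training_log, row.names = FALSE)
  invisible(object$training_log)
}

#' @export
coef.brdu_bigru <- function(object, ...) object$params

#' @export
plot.brdu_bigru <- function(x, ...) {
  log <- x$training_log
  graphics::matplot(log$epoch, cbind(log$train_loss, log$val_loss), type = "b",
                    pch = c(1, 19), lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "cross-entropy loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), pch = c(1, 19),
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Forward-propagate a single feature window
#'
#' @param model A fitted [brdu_bigru()].
#' @param x A `5 x 7` feature matrix (rows: offsets -2..+2) or a length-35
#'   row-major vector.
#' @return Named probability 5-vector over `[A, BrdU, C, G, T]` summing
#'   to 1.
#' @export
bigru_forward <- function(model, x) {
  stopifnot(inherits(model, "brdu_bigru"))
  if (is.matrix(x)) {
    stopifnot(nrow(x) == 5L, ncol(x) == 7L)
    x <- as.numeric(t(x))
  }
  stopifnot(length(x) == 35L)
  p <- net_predict_probs(model$params, model$config, matrix(x, 1L, 35L))
  stats::setNames(as.numeric(p), PROB_NAMES)
}

#' Call bases for feature windows
#'
#' Runs the classifier over every window and returns the argmax class call
#' together with the five class probabilities. Ties are broken in class
#' order A < BrdU < C < G < T.
#'
#' @param object A fitted [brdu_bigru()].
#' @param windows A [brdu_windows()] set.
#' @param ... Unused.
#' @return `data.frame` with columns `read_id`, `center_pos`, `center_base`,
#'   `call` (one of A/B/C/G/T, B meaning BrdU) and `p_A`, `p_BrdU`, `p_C`,
#'   `p_G`, `p_T`.
#' @export
predict.brdu_bigru <- function(object, windows, ...) {
  stopifnot(inherits(windows, "brdu_windows"))
  probs <- net_predict_probs(object$params, object$config, windows$x)
  colnames(probs) <- PROB_NAMES
  out <- data.frame(read_id = windows$read_id, center_pos = windows$center_pos,
                    center_base = windows$center_base,
                    call = CLASS_NAMES[max.col(probs, ties.method = "first")],
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(probs))
}

#' Save or load a fitted classifier
#'
#' `save_model()` writes the architecture configuration to a JSON sidecar
#' and the weights, at full precision, to a TSV so that a load/save round
#' trip reproduces forward outputs bit-identically. `load_model()` refuses
#' sidecars whose `timesteps` is not 5 (the R9 5-mer contract).
#'
#' @param model A fitted [brdu_bigru()].
#' @param path Directory to create/read.
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the restored `brdu_bigru`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "brdu_bigru"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  cfg <- unclass(model$config)
  cfg$best_epoch <- model$best_epoch
  jsonlite::write_json(cfg, file.path(path, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  w <- data.frame(
    param = rep(names(model$params), vapply(model$params, length, integer(1))),
    value = sprintf("%.17g", unlist(model$params, use.names = FALSE)),
    stringsAsFactors = FALSE
  )
  data.table::fwrite(w, file.path(path, "weights.tsv"), sep = "\t", quote = FALSE)
  data.table::fwrite(model$training_log, file.path(path, "training_log.tsv"),
                     sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  cfg_in <- jsonlite::read_json(file.path(path, "config.json"),
                                simplifyVector = TRUE)
  if (!is.null(cfg_in$timesteps) && cfg_in$timesteps != 5L)
    stop("model sidecar has timesteps != 5; only R9 5-mer models are supported",
         call. = FALSE)
  cfg <- model_config(units = cfg_in$units, n_layers = cfg_in$n_layers,
                      input_dim = cfg_in$input_dim, timesteps = cfg_in$timesteps,
                      n_classes = cfg_in$n_classes, batch_size = cfg_in$batch_size,
                      max_epochs = cfg_in$max_epochs, patience = cfg_in$patience,
                      learning_rate = cfg_in$learning_rate, seed = cfg_in$seed)
  w <- data.table::fread(file.path(path, "weights.tsv"), sep = "\t",
                         header = TRUE, data.table = FALSE)
  template <- init_params_dims(cfg)
  params <- list()
  vals <- split(as.numeric(w$value), factor(w$param, levels = names(template)))
  for (nm in names(template)) {
    d <- template[[nm]]
    v <- vals[[nm]]
    if (length(v) != prod(d))
      stop(sprintf("weights.tsv: parameter '%s' has %d values, expected %d",
                   nm, length(v), prod(d)), call. = FALSE)
    params[[nm]] <- if (length(d) == 2L) matrix(v, d[1], d[2]) else v
  }
  log_path <- file.path(path, "training_log.tsv")
  tl <- if (file.exists(log_path))
    data.table::fread(log_path, sep = "\t", header = TRUE, data.table = FALSE)
  else NULL
  structure(list(config = cfg, params = params, training_log = tl,
                 best_epoch = cfg_in$best_epoch %||% NA_integer_,
                 classes = CLASS_NAMES),
            class = "brdu_bigru")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Expected dimensions of every parameter, in serialization order.
init_params_dims <- function(cfg) {
  u <- cfg$units
  d <- list()
  in_dim <- cfg$input_dim
  for (l in seq_len(cfg$n_layers)) {
    for (dir in c("f", "b")) {
      key <- sprintf("l%d.%s", l, dir)
      d[[paste0(key, ".W")]] <- c(in_dim, 3L * u)
      d[[paste0(key, ".U")]] <- c(u, 3L * u)
      d[[paste0(key, ".b")]] <- 3L * u
    }
    in_dim <- 2L * u
  }
  d[["dense.W"]] <- c(2L * u, cfg$n_classes)
  d[["dense.b"]] <- cfg$n_classes
  d
}
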