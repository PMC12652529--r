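# Shared fixtures, built in code at test time.

CLASSES <- c("A", "B", "C", "G", "T")

# Hand-built event data.frame for one read with chosen bases.
make_read_events <- function(base_called, true_base = base_called,
                             read_id = "r1", norm_mean = NULL) {
  L <- length(base_called)
  data.frame(read_id = read_id, pos = 0:(L - 1L), base_called = base_called,
             true_base = true_base,
             norm_mean = if (is.null(norm_mean)) seq(-1, 1, length.out = L) else norm_mean,
             norm_sd = rep(0.1, L), dwell = rep(5L, L),
             stringsAsFactors = FALSE)
}

# One small, strongly separable trained classifier, shared across tests that
# need a working model (training it once keeps the suite fast).
.fixture_cache <- new.env(parent = emptyenv())

get_fixture_model <- function() {
  if (is.null(.fixture_cache$fit)) {
    pm <- build_pore_model(seed = 3, shift_magnitude = 3)
    ev <- simulate_reads(pm, sim_config(250, 150, substitution_rate = 0.5,
                                        noise_sd = 0.25, seed = 11))
    w <- extract_windows(ev, mode = "t")
    sp <- split_dataset(w, seed = 4)
    fit <- brdu_bigru(sp$train, sp$validation,
                      model_config(units = 24L, max_epochs = 8L,
                                   patience = 2L, seed = 9L))
    .fixture_cache$pm <- pm
    .fixture_cache$split <- sp
    .fixture_cache$fit <- fit
  }
  .fixture_cache
}

window_truth <- function(w) CLASSES[max.col(w$y, ties.method = "first")]

# Independent scalar-loop GRU oracle (no matrix products).
gru_step_scalar <- function(x, h, p) {
  u <- length(h)
  z <- numeric(u); r <- numeric(u)
  for (i in seq_len(u)) {
    az <- p$b_z[i]; ar <- p$b_r[i]
    for (j in seq_along(x)) {
      az <- az + p$W_z[i, j] * x[j]
      ar <- ar + p$W_r[i, j] * x[j]
    }
    for (j in seq_len(u)) {
      az <- az + p$U_z[i, j] * h[j]
      ar <- ar + p$U_r[i, j] * h[j]
    }
    z[i] <- 1 / (1 + exp(-az))
    r[i] <- 1 / (1 + exp(-ar))
  }
  hn <- numeric(u)
  for (i in seq_len(u)) {
    ac <- p$b_h[i]
    for (j in seq_along(x)) ac <- ac + p$W_h[i, j] * x[j]
    for (j in seq_len(u)) ac <- ac + p$U_h[i, j] * (r[j] * h[j])
    hn[i] <- (1 - z[i]) * h[i] + z[i] * tanh(ac)
  }
  hn
}

random_gru_params <- function(u, in_dim) {
  rm <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.5), nr, nc)
  list(W_z = rm(u, in_dim), U_z = rm(u, u), b_z = stats::rnorm(u),
       W_r = rm(u, in_dim), U_r = rm(u, u), b_r = stats::rnorm(u),
       W_h = rm(u, in_dim), U_h = rm(u, u), b_h = stats::rnorm(u))
}
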