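test_that("per-read signal normalization centers at zero and handles degenerate spread", {
  out <- normalize_read_signal(c(1, 2, 3, 4, 5))
  expect_equal(stats::median(out), 0)
  expect_equal(out, -rev(out))  # symmetric input stays symmetric
  expect_equal(stats::median(normalize_read_signal(rnorm(50))), 0)
  expect_error(normalize_read_signal(c(2, 2, 2, 2)), "zero spread")
  expect_error(normalize_read_signal(3), "at least 2")
  # MAD = 0 but sd > 0: falls back to sd scaling
  x <- c(rep(1, 10), 100)
  expect_true(all(is.finite(normalize_read_signal(x))))
})

test_that("event encoding follows the [f_m, f_d, f_l, onehot] layout", {
  v <- encode_event(list(base_called = "C", norm_mean = 0.5, norm_sd = 0.1,
                         dwell = 7))
  expect_length(v, 7L)
  expect_equal(unname(v), c(0.5, 0.1, 7, 0, 1, 0, 0))
  v2 <- encode_event(list(base_called = "T", norm_mean = -1.2, norm_sd = 0,
                          dwell = 1))
  expect_equal(unname(v2), c(-1.2, 0, 1, 0, 0, 0, 1))
  expect_error(encode_event(list(base_called = "B", norm_mean = 0, norm_sd = 0,
                                 dwell = 1)), "A/C/G/T")
  vl <- encode_event(list(base_called = "A", norm_mean = 0, norm_sd = 0,
                          dwell = 7), log_dwell = TRUE)
  expect_equal(unname(vl[3]), log1p(7))
})

test_that("window extraction yields L-4 windows and matches a brute-force re-scan", {
  set.seed(42)
  bases <- sample(c("A", "C", "G", "T"), 300, replace = TRUE)
  ev <- make_read_events(bases, norm_mean = rnorm(300))
  w <- extract_windows(ev, mode = "all")
  expect_equal(n_windows(w), 296L)
  expect_equal(ncol(w$x), 35L)

  # brute force: slice every length-5 run of the event list independently
  E <- t(vapply(seq_len(300), function(i)
    encode_event(ev[i, ]), numeric(7)))
  for (i in sample(296, 25)) {
    expect_equal(unname(w$x[i, ]), as.numeric(t(E[i:(i + 4), ])))
    expect_equal(w$center_pos[i], i + 1L)  # 0-based center
  }

  # t-middles is the subset of all-middles with a called-T center
  wt <- extract_windows(ev, mode = "t")
  n_t <- sum(bases[3:298] == "T")
  expect_equal(n_windows(wt), n_t)
  expect_true(all(wt$center_base == "T"))
  idx <- match(wt$center_pos, w$center_pos)
  expect_equal(wt$x, w$x[idx, , drop = FALSE])
})

test_that("short reads yield nothing, with a warning", {
  ev <- make_read_events(c("A", "C", "G", "T"))
  expect_warning(w <- extract_windows(ev), "shorter than 5")
  expect_equal(n_windows(w), 0L)
})

test_that("labels are one-hot over [A, BrdU, C, G, T] and unknown truth gives NA", {
  ev <- make_read_events(rep("T", 7), true_base = c("T", "T", "B", "T", ".", "T", "T"))
  w <- extract_windows(ev, mode = "all")
  expect_equal(n_windows(w), 3L)
  expect_equal(unname(w$y[1, ]), c(0, 1, 0, 0, 0))  # center pos 2 is B
  expect_equal(unname(w$y[2, ]), c(0, 0, 0, 0, 1))  # center pos 3 is T
  expect_true(all(is.na(w$y[3, ])))                 # center pos 4 unknown
})

test_that("one-hot validity holds over random simulated fixtures", {
  pm <- build_pore_model(1, 1.5)
  for (seed in 1:3) {
    ev <- simulate_reads(pm, sim_config(10, 60, substitution_rate = 0.5,
                                        seed = seed))
    w <- extract_windows(ev, mode = "all")
    for (t in 1:5) {
      oh <- w$x[, (t - 1) * 7 + 4:7, drop = FALSE]
      expect_true(all(rowSums(oh) == 1))
      expect_true(all(oh %in% c(0, 1)))
    }
    expect_true(all(rowSums(w$y) == 1))
    expect_true(all(w$x[, seq(3, 35, by = 7)] >= 1))  # dwell
    expect_true(all(w$x[, seq(2, 35, by = 7)] >= 0))  # spread
  }
})

test_that("alignment filtering applies inclusive thresholds and the flag rule", {
  rec <- data.frame(read_id = c("a", "b", "c"), mapq = c(10L, 20L, 60L),
                    aligned_len = c(300L, 300L, 300L), sam_flag = c(0L, 16L, 0L))
  expect_equal(filter_alignments(rec, 20, 0)$read_id, c("b", "c"))
  rec2 <- data.frame(read_id = c("a", "b", "c"), mapq = c(60L, 60L, 60L),
                     aligned_len = c(269L, 270L, 500L), sam_flag = 0L)
  expect_equal(filter_alignments(rec2, 0, 270)$read_id, c("b", "c"))
  expect_equal(filter_alignments(rec, 0, 0, require_flag_zero = TRUE)$read_id,
               c("a", "c"))
  expect_equal(nrow(filter_alignments(rec, 61, 0)), 0L)
  expect_equal(alignment_filter_preset("standard"),
               list(min_mapq = 20L, min_len = 270L))
  expect_equal(alignment_filter_preset("genomic"),
               list(min_mapq = 60L, min_len = 500L))
  expect_error(filter_alignments(data.frame(mapq = 70, aligned_len = 1)),
               "\\[0, 60\\]")
})

test_that("the 80/10/10 split is exact, deterministic and conserves classes", {
  pm <- build_pore_model(1, 1.5)
  ev <- simulate_reads(pm, sim_config(10, 104, substitution_rate = 0.5, seed = 6))
  w <- extract_windows(ev, mode = "all")
  expect_equal(n_windows(w), 1000L)
  sp <- split_dataset(w, seed = 5)
  expect_equal(n_windows(sp$train), 800L)
  expect_equal(n_windows(sp$validation), 100L)
  expect_equal(n_windows(sp$test), 100L)

  sp2 <- split_dataset(w, seed = 5)
  expect_identical(sp$train$center_pos, sp2$train$center_pos)
  expect_identical(sp$train$read_id, sp2$train$read_id)

  # exact partition: no overlap, union is the input
  key <- function(s) sort(paste(s$read_id, s$center_pos))
  all_keys <- c(key(sp$train), key(sp$validation), key(sp$test))
  expect_equal(sort(all_keys), sort(paste(w$read_id, w$center_pos)))

  # class counts conserved across the split
  total <- nanobrdu:::window_class_counts(w)
  parts <- nanobrdu:::window_class_counts(sp$train) +
    nanobrdu:::window_class_counts(sp$validation) +
    nanobrdu:::window_class_counts(sp$test)
  expect_equal(parts, total)
})

test_that("small and invalid splits behave as documented", {
  pm <- build_pore_model(1, 1.5)
  ev <- simulate_reads(pm, sim_config(1, 17, seed = 2))
  w <- extract_windows(ev, mode = "all")  # 13 windows
  sp <- split_dataset(w, seed = 1)
  expect_equal(c(n_windows(sp$train), n_windows(sp$validation),
                 n_windows(sp$test)), c(10L, 1L, 2L))
  expect_error(split_dataset(w[1:9]), "at least 10")
  expect_error(split_dataset(w, fractions = c(0.5, 0.2, 0.2)), "summing to 1")
})
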