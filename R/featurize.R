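# Feature and label engineering: events -> labeled 5-mer feature windows.
#
# Each event is a 7-vector [f_m, f_d, f_l, f_A, f_C, f_G, f_T]: normalized
# signal mean, spread, dwell, and the one-hot of the basecalled identity.
# A window stacks the 7-vectors of five consecutive events (offsets -2..+2)
# and, when ground truth is known, carries a 5-class one-hot label
# [f_A, f_BrdU, f_C, f_G, f_T] for the true base at the center.

FEATURE_NAMES <- c("f_m", "f_d", "f_l", "f_A", "f_C", "f_G", "f_T")
CLASS_NAMES <- c("A", "B", "C", "G", "T")
PROB_NAMES <- c("p_A", "p_BrdU", "p_C", "p_G", "p_T")

#' Normalize raw event means within a read
#'
#' Median-shift and MAD-scale a read's raw event means:
#' `(raw - median) / (1.4826 * MAD)`. Falls back to standard-deviation
#' scaling when the MAD is zero; errors when both spreads are zero.
#' Resquiggling pipelines normally perform this normalization themselves (and
#' the simulator emits already-normalized means), so this is only needed for
#' event tables flagged as un-normalized.
#'
#' @param raw_means Numeric vector of raw event means for one read (>= 2).
#' @return Normalized means with median exactly 0.
#' @export
normalize_read_signal <- function(raw_means) {
  if (length(raw_means) < 2L) stop("need at least 2 events per read", call. = FALSE)
  med <- stats::median(raw_means)
  scale <- stats::mad(raw_means)  # 1.4826 * median absolute deviation
  if (scale == 0) scale <- stats::sd(raw_means)
  if (scale == 0) stop("read signal has zero spread; cannot normalize", call. = FALSE)
  (raw_means - med) / scale
}

#' Encode one event as a 7-dimensional feature vector
#'
#' @param e A one-row event `data.frame` or a list with fields `base_called`,
#'   `norm_mean`, `norm_sd`, `dwell`.
#' @param log_dwell Apply `log1p` to dwell (off by default: dwell is fed
#'   through unchanged).
#' @return Named numeric 7-vector `[f_m, f_d, f_l, f_A, f_C, f_G, f_T]`.
#' @examples
#' encode_event(list(base_called = "C", norm_mean = 0.5, norm_sd = 0.1, dwell = 7))
#' @export
encode_event <- function(e, log_dwell = FALSE) {
  if (!e$base_called[1] %in% BASES4)
    stop("base_called must be one of A/C/G/T", call. = FALSE)
  onehot <- as.numeric(BASES4 == e$base_called[1])
  dw <- if (log_dwell) log1p(e$dwell[1]) else e$dwell[1]
  stats::setNames(c(e$norm_mean[1], e$norm_sd[1], dw, onehot), FEATURE_NAMES)
}

# Vectorized event encoding: n x 7 matrix.
encode_events <- function(events, log_dwell = FALSE) {
  bad <- which(!events$base_called %in% BASES4)
  if (length(bad))
    stop("base_called must be one of A/C/G/T", call. = FALSE)
  n <- nrow(events)
  m <- matrix(0, n, 7L, dimnames = list(NULL, FEATURE_NAMES))
  m[, 1L] <- events$norm_mean
  m[, 2L] <- events$norm_sd
  m[, 3L] <- if (log_dwell) log1p(events$dwell) else events$dwell
  m[cbind(seq_len(n), 3L + match(events$base_called, BASES4))] <- 1
  m
}

#' Construct a feature-window set
#'
#' Low-level constructor for the `brdu_windows` container; most users obtain
#' windows from [extract_windows()].
#'
#' @param x Numeric `n x 35` matrix, rows are windows, columns the five
#'   event 7-vectors in offset order -2..+2.
#' @param y Optional `n x 5` one-hot label matrix over `[A, BrdU, C, G, T]`;
#'   rows may be all-`NA` where truth is unknown, or `y` may be `NULL`.
#' @param read_id,center_pos,center_base Per-window provenance: source read,
#'   0-based center position, basecalled center base.
#' @return An object of class `brdu_windows`.
#' @export
brdu_windows <- function(x, y = NULL, read_id = character(nrow(x)),
                         center_pos = integer(nrow(x)),
                         center_base = character(nrow(x))) {
  stopifnot(is.matrix(x), ncol(x) == 35L)
  if (!is.null(y)) {
    stopifnot(is.matrix(y), ncol(y) == 5L, nrow(y) == nrow(x))
    known <- !is.na(y[, 1L])
    if (any(known)) {
      s <- rowSums(y[known, , drop = FALSE])
      ones <- rowSums(y[known, , drop = FALSE] == 1)
      if (any(s != 1) || any(ones != 1))
        stop("labels must be one-hot 5-vectors", call. = FALSE)
    }
    colnames(y) <- CLASS_NAMES
  }
  structure(list(x = x, y = y, read_id = as.character(read_id),
                 center_pos = as.integer(center_pos),
                 center_base = as.character(center_base)),
            class = "brdu_windows")
}

#' @export
print.brdu_windows <- function(x, ...) {
  n <- nrow(x$x)
  lab <- if (is.null(x$y)) 0L else sum(!is.na(x$y[, 1L]))
  cat(sprintf("%d feature windows (5 x 7 each) from %d reads; %d labeled\n",
              n, length(unique(x$read_id)), lab))
  if (lab > 0) {
    counts <- window_class_counts(x)
    cat("  class counts:", paste(sprintf("%s=%d", names(counts), counts),
                                 collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
`[.brdu_windows` <- function(x, i) {
  brdu_windows(x$x[i, , drop = FALSE],
               if (is.null(x$y)) NULL else x$y[i, , drop = FALSE],
               x$read_id[i], x$center_pos[i], x$center_base[i])
}

#' Number of windows in a window set
#' @param w A `brdu_windows` object.
#' @return Integer count.
#' @export
n_windows <- function(w) nrow(w$x)

#' Combine window sets
#' @param ... `brdu_windows` objects. Labels are kept only if every set has
#'   them.
#' @return A single `brdu_windows`.
#' @export
combine_windows <- function(...) {
  ws <- list(...)
  stopifnot(all(vapply(ws, inherits, logical(1), "brdu_windows")))
  have_y <- all(!vapply(ws, function(w) is.null(w$y), logical(1)))
  brdu_windows(do.call(rbind, lapply(ws, `[[`, "x")),
               if (have_y) do.call(rbind, lapply(ws, `[[`, "y")) else NULL,
               unlist(lapply(ws, `[[`, "read_id")),
               unlist(lapply(ws, `[[`, "center_pos")),
               unlist(lapply(ws, `[[`, "center_base")))
}

# Per-class labeled window counts, in class order.
window_class_counts <- function(w) {
  if (is.null(w$y)) return(stats::setNames(integer(5), CLASS_NAMES))
  known <- !is.na(w$y[, 1L])
  stats::setNames(as.integer(colSums(w$y[known, , drop = FALSE])), CLASS_NAMES)
}

#' Extract labeled 5-mer feature windows from an event stream
#'
#' Slides a 5-event window along each read: one window per center position
#' with two full flanks, so a read of `L` events yields `L - 4` windows.
#' Mode `"t"` keeps only windows whose center was basecalled T (the
#' thymidine-candidate restriction used for genomic and primer-extension
#' data); mode `"all"` keeps every center. The label, when the center's true
#' base is known, is its one-hot over `[A, BrdU, C, G, T]`; unknown truth
#' (`"."`) yields an `NA` label row.
#'
#' @param events Event `data.frame`; positions must be contiguous within
#'   each read. Reads shorter than 5 events yield no windows (with a
#'   warning).
#' @param mode `"all"` or `"t"`.
#' @param log_dwell Passed to the event encoder.
#' @return A [brdu_windows()] object.
#' @examples
#' pm <- build_pore_model(1, 1.5)
#' ev <- simulate_reads(pm, sim_config(3, 50, substitution_rate = 0.5, seed = 2))
#' extract_windows(ev, mode = "t")
#' @export
extract_windows <- function(events, mode = c("all", "t"), log_dwell = FALSE) {
  mode <- match.arg(mode)
  check_events(events)
  reads <- split(seq_len(nrow(events)), events$read_id)
  reads <- reads[unique(events$read_id)]  # preserve input read order
  short <- 0L
  parts <- vector("list", length(reads))
  for (k in seq_along(reads)) {
    ev <- events[reads[[k]], ]
    ev <- ev[order(ev$pos), ]
    L <- nrow(ev)
    if (L < 5L) { short <- short + 1L; next }
    if (!identical(as.integer(ev$pos), ev$pos[1] + 0:(L - 1L)))
      stop(sprintf("read %s: event positions are not contiguous", ev$read_id[1]),
           call. = FALSE)
    E <- encode_events(ev, log_dwell)
    nc <- L - 4L
    X <- cbind(E[1:nc, , drop = FALSE], E[2:(nc + 1L), , drop = FALSE],
               E[3:(nc + 2L), , drop = FALSE], E[4:(nc + 3L), , drop = FALSE],
               E[5:(nc + 4L), , drop = FALSE])
    centers <- 3:(L - 2L)
    tb <- ev$true_base[centers]
    y <- matrix(NA_real_, nc, 5L)
    known <- tb %in% CLASS_NAMES
    if (any(known)) {
      y[known, ] <- 0
      y[cbind(which(known), match(tb[known], CLASS_NAMES))] <- 1
    }
    keep <- if (mode == "t") ev$base_called[centers] == "T" else rep(TRUE, nc)
    if (!any(keep)) next
    parts[[k]] <- list(x = X[keep, , drop = FALSE], y = y[keep, , drop = FALSE],
                       read_id = rep(ev$read_id[1], sum(keep)),
                       center_pos = ev$pos[centers][keep],
                       center_base = ev$base_called[centers][keep])
  }
  if (short > 0L)
    warning(sprintf("%d read(s) shorter than 5 events yielded no windows", short))
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts))
    return(brdu_windows(matrix(numeric(), 0L, 35L),
                        matrix(numeric(), 0L, 5L), character(), integer(),
                        character()))
  y <- do.call(rbind, lapply(parts, `[[`, "y"))
  if (all(is.na(y))) y <- NULL
  brdu_windows(do.call(rbind, lapply(parts, `[[`, "x")), y,
               unlist(lapply(parts, `[[`, "read_id")),
               unlist(lapply(parts, `[[`, "center_pos")),
               unlist(lapply(parts, `[[`, "center_base")))
}

#' Filter alignment records by mapping quality, length and SAM flag
#'
#' Keeps records with `mapq >= min_mapq` and `aligned_len >= min_len`, and,
#' when `require_flag_zero` is set (the rule for selecting the
#' primer-extension strand of 2D libraries), `sam_flag == 0`. Preset
#' thresholds: `(20, 270)` for synthetic 5-mer standards, `(60, 500)` for
#' genomic reads.
#'
#' @param records `data.frame` with columns `read_id`, `mapq`, `aligned_len`
#'   and (if `require_flag_zero`) `sam_flag`.
#' @param min_mapq,min_len Thresholds (inclusive).
#' @param require_flag_zero Keep only primary forward alignments
#'   (`sam_flag == 0`).
#' @return The surviving rows (possibly zero rows).
#' @seealso [alignment_filter_preset()]
#' @export
filter_alignments <- function(records, min_mapq = 20L, min_len = 270L,
                              require_flag_zero = FALSE) {
  stopifnot(is.data.frame(records),
            all(c("mapq", "aligned_len") %in% names(records)))
  if (any(records$mapq < 0 | records$mapq > 60))
    stop("mapq must be in [0, 60]", call. = FALSE)
  keep <- records$mapq >= min_mapq & records$aligned_len >= min_len
  if (require_flag_zero) {
    if (!"sam_flag" %in% names(records))
      stop("require_flag_zero needs a 'sam_flag' column", call. = FALSE)
    keep <- keep & records$sam_flag == 0L
  }
  records[keep, , drop = FALSE]
}

#' Alignment filter presets
#'
#' @param preset `"standard"` for synthetic 5-mer reference standards
#'   (MAPQ >= 20, length >= 270) or `"genomic"` for genomic/plasmid reads
#'   (MAPQ >= 60, length >= 500).
#' @return List with `min_mapq` and `min_len`.
#' @export
alignment_filter_preset <- function(preset = c("standard", "genomic")) {
  switch(match.arg(preset),
         standard = list(min_mapq = 20L, min_len = 270L),
         genomic = list(min_mapq = 60L, min_len = 500L))
}

#' Shuffle and split windows into train / validation / test sets
#'
#' Deterministically shuffles the windows under `seed` and partitions them
#' `floor(0.8 n)` / `floor(0.1 n)` / remainder (exact partition: no overlap,
#' union is the input).
#'
#' @param windows A [brdu_windows()] object with at least 10 windows.
#' @param fractions Length-3 split fractions summing to 1 (default
#'   `c(0.8, 0.1, 0.1)`).
#' @param seed Shuffle seed.
#' @return Named list `train`, `validation`, `test` of `brdu_windows`.
#' @export
split_dataset <- function(windows, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(inherits(windows, "brdu_windows"))
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be 3 values summing to 1", call. = FALSE)
  n <- n_windows(windows)
  if (n < 10L) stop("need at least 10 windows to split", call. = FALSE)
  perm <- with_seed(seed, sample.int(n))
  n_train <- floor(fractions[1] * n)
  n_val <- floor(fractions[2] * n)
  list(train = windows[perm[seq_len(n_train)]],
       validation = windows[perm[n_train + seq_len(n_val)]],
       test = windows[perm[(n_train + n_val + 1L):n]])
}
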