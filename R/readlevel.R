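# Read-level BrdU substitution rates and bimodal-mixture relabeling.
#
# The substitution rate of a read is the fraction of its thymidine
# candidates (windows whose center was basecalled T) that the classifier
# called BrdU. Thresholding these rates separates the two modes of a mixed
# library -- fully labeled molecules vs unlabeled (e.g. renatured) ones --
# and the windows of reads judged labeled can be relabeled as BrdU-positive
# training data.

#' Read-level BrdU substitution rate for one read
#'
#' @param calls Calls `data.frame` (see [predict.brdu_bigru()]) for a single
#'   read; rows whose `center_base` is not `"T"` are ignored, since only
#'   basecalled-thymidine windows are candidates.
#' @return One-row `data.frame` with `read_id`, `n_candidates`, `n_brdu` and
#'   `rate = n_brdu / n_candidates`, or a zero-row frame (with a warning)
#'   when the read has no candidates.
#' @export
read_substitution_rate <- function(calls) {
  ids <- unique(calls$read_id)
  if (length(ids) > 1L)
    stop("read_substitution_rate() expects calls from a single read; use read_rates()",
         call. = FALSE)
  read_rates(calls)
}

#' Read-level BrdU substitution rates
#'
#' Aggregates window calls per read into the fraction of thymidine
#' candidates called BrdU. Reads with zero candidates are omitted with a
#' warning rather than assigned a rate of 0, so mixture histograms are not
#' deflated.
#'
#' @param calls Calls `data.frame` with `read_id`, `call` and (optionally)
#'   `center_base`; when `center_base` is present only rows with
#'   `center_base == "T"` count as candidates.
#' @return `data.frame` with one row per read: `read_id`, `n_candidates`,
#'   `n_brdu`, `rate`.
#' @export
read_rates <- function(calls) {
  stopifnot(is.data.frame(calls), all(c("read_id", "call") %in% names(calls)))
  all_ids <- unique(calls$read_id)
  if ("center_base" %in% names(calls)) calls <- calls[calls$center_base == "T", ]
  if (nrow(calls) == 0L) {
    if (length(all_ids))
      warning(sprintf("%d read(s) had no thymidine candidates and were skipped",
                      length(all_ids)))
    return(data.frame(read_id = character(), n_candidates = integer(),
                      n_brdu = integer(), rate = numeric()))
  }
  n_cand <- tapply(calls$call, calls$read_id, length)
  n_brdu <- tapply(calls$call == "B", calls$read_id, sum)
  ids <- names(n_cand)
  skipped <- setdiff(all_ids, ids)
  if (length(skipped))
    warning(sprintf("%d read(s) had no thymidine candidates and were skipped",
                    length(skipped)))
  out <- data.frame(read_id = ids, n_candidates = as.integer(n_cand),
                    n_brdu = as.integer(n_brdu),
                    rate = as.numeric(n_brdu) / as.numeric(n_cand),
                    stringsAsFactors = FALSE)
  out[match(intersect(all_ids, ids), out$read_id), , drop = FALSE]
}

#' Classify reads as fully BrdU-labeled by thresholding their rate
#'
#' A read is judged fully BrdU-labeled when its estimated substitution rate
#' is strictly greater than the threshold (default 12.5%, the valley between
#' the two modes of a typical labeled/unlabeled mixture). A 20-bin histogram
#' of the rates on `[0, 1]` is attached for bimodality inspection.
#'
#' @param rates `data.frame` from [read_rates()], or a numeric vector of
#'   rates.
#' @param threshold Strict decision threshold in `[0, 1]` (default 0.125).
#' @return The input with a logical `labeled` column and a `threshold`
#'   column; the binned rate histogram is in `attr(, "histogram")`.
#' @examples
#' classify_reads(data.frame(read_id = c("a", "b"), n_candidates = c(8, 8),
#'                           n_brdu = c(0, 7), rate = c(0, 0.875)))
#' @export
classify_reads <- function(rates, threshold = 0.125) {
  if (is.numeric(rates))
    rates <- data.frame(read_id = sprintf("read_%d", seq_along(rates)),
                        n_candidates = NA_integer_, n_brdu = NA_integer_,
                        rate = rates, stringsAsFactors = FALSE)
  if (any(rates$rate < 0 | rates$rate > 1))
    stop("rates must be in [0, 1]", call. = FALSE)
  rates$labeled <- rates$rate > threshold
  rates$threshold <- threshold
  attr(rates, "histogram") <- graphics::hist(rates$rate,
                                             breaks = seq(0, 1, length.out = 21L),
                                             plot = FALSE)
  rates
}

#' Bootstrap-relabel a BrdU-positive dataset using an earlier model
#'
#' Implements the positive-label construction for fully substituted
#' libraries contaminated with unlabeled molecules: featurize the events in
#' thymidine-candidate mode, call them with a model trained without this
#' dataset, estimate per-read substitution rates, keep the reads whose rate
#' exceeds the threshold, and emit their candidate windows relabeled as
#' BrdU (the true center base of every candidate in a fully labeled read is
#' assumed to be BrdU). Reads judged unlabeled are dropped.
#'
#' @param model A fitted [brdu_bigru()] trained without these events.
#' @param events Event `data.frame` of the candidate-positive dataset.
#' @param threshold Read-level rate threshold (strict; default 0.125).
#' @param log_dwell Passed to the featurizer.
#' @return A [brdu_windows()] set with every label one-hot BrdU; the
#'   per-read decisions are attached as `attr(, "decisions")`. Empty (with a
#'   warning) when no read survives.
#' @export
bootstrap_relabel <- function(model, events, threshold = 0.125,
                              log_dwell = FALSE) {
  stopifnot(inherits(model, "brdu_bigru"))
  w <- extract_windows(events, mode = "t", log_dwell = log_dwell)
  if (n_windows(w) == 0L) {
    warning("no thymidine-candidate windows in input; nothing to relabel")
    return(w)
  }
  calls <- predict(model, w)
  decisions <- classify_reads(read_rates(calls), threshold)
  keep_reads <- decisions$read_id[decisions$labeled]
  if (!length(keep_reads)) {
    warning("no read exceeded the relabeling threshold; nothing emitted")
    out <- w[integer(0)]
    attr(out, "decisions") <- decisions
    return(out)
  }
  out <- w[w$read_id %in% keep_reads]
  y <- matrix(0, n_windows(out), 5L, dimnames = list(NULL, CLASS_NAMES))
  y[, "B"] <- 1
  out$y <- y
  attr(out, "decisions") <- decisions
  out
}
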