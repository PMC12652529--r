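# Event-table TSV dialect: UTF-8, header exactly
#   read_id  pos  base_called  true_base  norm_mean  norm_sd  dwell
# pos is 0-based along the read; true_base "." means unknown (real data
# without ground truth); floats carry full precision so that a write/read
# round trip reproduces the records exactly.

EVENT_COLUMNS <- c("read_id", "pos", "base_called", "true_base",
                   "norm_mean", "norm_sd", "dwell")

#' Write an event table to TSV
#'
#' @param events Event `data.frame` (see [simulate_reads()] for the schema).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  check_events(events)
  out <- events[EVENT_COLUMNS]
  out$norm_mean <- sprintf("%.17g", out$norm_mean)
  out$norm_sd <- sprintf("%.17g", out$norm_sd)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read an event table from TSV
#'
#' Validates the header, base symbols and numeric fields; malformed rows are
#' reported with their line number. An empty table (header only) is returned
#' as a zero-row `data.frame` without error.
#'
#' @param path TSV file written by [write_event_table()] or exported from a
#'   resquiggling pipeline in the same dialect.
#' @return Event `data.frame`.
#' @export
read_event_table <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (!identical(hdr, EVENT_COLUMNS))
    stop(sprintf("bad event table header: expected '%s'",
                 paste(EVENT_COLUMNS, collapse = ", ")), call. = FALSE)
  ev <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("read_id", "base_called", "true_base")),
                          data.table = FALSE, fill = FALSE)
  if (nrow(ev) == 0L) {
    ev$pos <- integer(); ev$dwell <- integer()
    ev$norm_mean <- numeric(); ev$norm_sd <- numeric()
    return(ev[EVENT_COLUMNS])
  }
  bad_call <- which(!ev$base_called %in% BASES4)
  if (length(bad_call))
    stop(sprintf("line %d: base_called '%s' is not one of A/C/G/T (BrdU is never basecalled)",
                 bad_call[1] + 1L, ev$base_called[bad_call[1]]), call. = FALSE)
  bad_true <- which(!ev$true_base %in% c(BASES5, "."))
  if (length(bad_true))
    stop(sprintf("line %d: unknown true_base symbol '%s'",
                 bad_true[1] + 1L, ev$true_base[bad_true[1]]), call. = FALSE)
  bad_b <- which(ev$true_base == "B" & ev$base_called != "T")
  if (length(bad_b))
    stop(sprintf("line %d: true_base B must be basecalled as T", bad_b[1] + 1L),
         call. = FALSE)
  for (nm in c("pos", "norm_mean", "norm_sd", "dwell")) {
    bad <- which(!is.finite(ev[[nm]]))
    if (length(bad))
      stop(sprintf("line %d: malformed numeric field '%s'", bad[1] + 1L, nm),
           call. = FALSE)
  }
  if (any(ev$dwell < 1)) stop("dwell must be >= 1", call. = FALSE)
  if (any(ev$norm_sd < 0)) stop("norm_sd must be >= 0", call. = FALSE)
  ev
}

check_events <- function(events) {
  if (!is.data.frame(events) || !all(EVENT_COLUMNS %in% names(events)))
    stop(sprintf("events must be a data.frame with columns '%s'",
                 paste(EVENT_COLUMNS, collapse = ", ")), call. = FALSE)
  if (any(events$base_called == "B"))
    stop("base_called must never be B: a standard basecaller reports BrdU as T",
         call. = FALSE)
  invisible(events)
}

#' Write or read model calls as TSV
#'
#' Calls tables carry one row per evaluated window: `read_id`, `center_pos`,
#' `center_base`, `call` and the five class probabilities
#' `p_A, p_BrdU, p_C, p_G, p_T`.
#'
#' @param calls Calls `data.frame` from [predict.brdu_bigru()].
#' @param path File path.
#' @return `path` (write) or the calls `data.frame` (read).
#' @export
write_calls <- function(calls, path) {
  data.table::fwrite(data.table::as.data.table(calls), path, sep = "\t",
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
}
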