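#' Simulation configuration for synthetic nanopore event tables
#'
#' Describes one simulated sequencing run: how many reads, their length, the
#' per-thymidine probability of BrdU substitution, the event-level signal
#' noise, and the fraction of reads that carry substitutions at all (to build
#' bimodal mixtures of fully labeled and unlabeled molecules, as arises when
#' renatured unlabeled strands contaminate a primer-extension library).
#'
#' @param n_reads Number of reads to simulate.
#' @param read_length Bases per read; must be at least 5.
#' @param substitution_rate Probability in `[0, 1]` that each thymidine in a
#'   labeled read is replaced by BrdU.
#' @param noise_sd Event-level Gaussian noise (normalized current units)
#'   around the pore-model level.
#' @param dwell_mean Mean event dwell in raw signal samples (>= 1); dwell is
#'   drawn as `1 + Poisson(dwell_mean - 1)`.
#' @param labeled_fraction Fraction in `[0, 1]` of reads that receive
#'   substitutions at all.
#' @param basecall_error Probability that an event's called base is replaced
#'   by a uniformly chosen different canonical base. Off by default: the
#'   upstream pipeline's MAPQ filters keep residual error low.
#' @param flank_motif Optional T-free linker sequence. When set, reads are
#'   built as repeats of 5 random bases followed by this motif, emulating
#'   synthetic k-mer reference standards whose 5-mers share fixed flanking
#'   context; substitutions only occur in the random blocks. `NULL` (default)
#'   gives uniform random sequence, emulating genomic reads.
#' @param seed Integer seed; identical configurations produce byte-identical
#'   event tables.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_reads, read_length = 300L, substitution_rate = 0,
                       noise_sd = 0.5, dwell_mean = 8, labeled_fraction = 1,
                       basecall_error = 0, flank_motif = NULL, seed = 1L) {
  for (nm in c("n_reads", "read_length", "substitution_rate", "noise_sd",
               "dwell_mean", "labeled_fraction", "basecall_error", "seed"))
    stopifnot_scalar(get(nm), nm)
  if (read_length < 5L) stop("read_length must be >= 5", call. = FALSE)
  if (n_reads < 1L) stop("n_reads must be >= 1", call. = FALSE)
  for (nm in c("substitution_rate", "labeled_fraction", "basecall_error")) {
    v <- get(nm)
    if (v < 0 || v > 1) stop(sprintf("'%s' must be in [0, 1]", nm), call. = FALSE)
  }
  if (dwell_mean < 1) stop("dwell_mean must be >= 1", call. = FALSE)
  if (!is.null(flank_motif)) {
    flank_motif <- toupper(flank_motif)
    if (!grepl("^[ACG]+$", flank_motif))
      stop("flank_motif must contain only A/C/G (a T-free linker)", call. = FALSE)
  }
  structure(list(n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 substitution_rate = substitution_rate, noise_sd = noise_sd,
                 dwell_mean = dwell_mean, labeled_fraction = labeled_fraction,
                 basecall_error = basecall_error, flank_motif = flank_motif,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulation presets emulating the study designs of common BrdU datasets
#'
#' Named shortcuts for [sim_config()] matching the four experimental designs
#' the workflow is built around:
#' \describe{
#'   \item{`standards`}{Synthetic 5-mer reference standards: every read fully
#'     labeled at substitution rate 0.5 (so thymidine and BrdU are balanced
#'     among T-candidates, as when all 5^5 combinations are synthesized), with
#'     a fixed T-free flanking linker between the random 5-mers.}
#'   \item{`genomic_negative`}{BrdU-free genomic reads (cells grown without
#'     BrdU): uniform context, substitution rate 0.}
#'   \item{`fully_substituted`}{Primer-extension product with BrdU replacing
#'     all thymidine: uniform context, substitution rate 1.}
#'   \item{`mixed_rate`}{Partially labeled genomic reads at a given
#'     substitution rate (default 0.2, as in cells grown in BrdU medium).}
#'   \item{`bimodal_mixture`}{A mixture in which only `labeled_fraction` of
#'     reads are fully substituted and the rest are unlabeled, emulating
#'     renatured unlabeled strands in a primer-extension library.}
#' }
#'
#' @param preset Preset name.
#' @param n_reads,read_length,seed Passed to [sim_config()].
#' @param substitution_rate Only for `mixed_rate`.
#' @param labeled_fraction Only for `bimodal_mixture`.
#' @param ... Further overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_preset <- function(preset = c("standards", "genomic_negative",
                                  "fully_substituted", "mixed_rate",
                                  "bimodal_mixture"),
                       n_reads, read_length = 300L, seed = 1L,
                       substitution_rate = 0.2, labeled_fraction = 0.5, ...) {
  preset <- match.arg(preset)
  switch(preset,
    standards = sim_config(n_reads, read_length, substitution_rate = 0.5,
                           labeled_fraction = 1, flank_motif = "GCAGGCGA",
                           seed = seed, ...),
    genomic_negative = sim_config(n_reads, read_length, substitution_rate = 0,
                                  labeled_fraction = 0, seed = seed, ...),
    fully_substituted = sim_config(n_reads, read_length, substitution_rate = 1,
                                   labeled_fraction = 1, seed = seed, ...),
    mixed_rate = sim_config(n_reads, read_length,
                            substitution_rate = substitution_rate,
                            labeled_fraction = 1, seed = seed, ...),
    bimodal_mixture = sim_config(n_reads, read_length, substitution_rate = 1,
                                 labeled_fraction = labeled_fraction,
                                 seed = seed, ...))
}

#' Simulate resquiggled nanopore events over a pore model
#'
#' Draws reads uniformly over \{A, C, G, T\} (or with the configured linker
#' structure), substitutes thymidines with BrdU in labeled reads, and emits
#' one event per base with a normalized mean drawn around the true 5-mer's
#' pore-model level, a spread drawn around the model's level spread, and a
#' shifted-Poisson dwell. Read ends are padded with `A` context for signal
#' generation; edge positions still emit events even though they yield no
#' feature window downstream. The called base is the true base with BrdU
#' reported as T (a standard basecaller cannot emit B), optionally corrupted
#' at `basecall_error`.
#'
#' @param model A [build_pore_model()] object.
#' @param config A [sim_config()].
#' @return A `data.frame` of events with columns `read_id`, `pos` (0-based),
#'   `base_called`, `true_base`, `norm_mean`, `norm_sd`, `dwell`, ordered by
#'   read then position. Fully deterministic given `config$seed`.
#' @examples
#' pm <- build_pore_model(seed = 1, shift_magnitude = 1.5)
#' ev <- simulate_reads(pm, sim_config(n_reads = 2, read_length = 20,
#'                                     substitution_rate = 0.5, seed = 7))
#' head(ev)
#' @export
simulate_reads <- function(model, config) {
  stopifnot(inherits(model, "pore_model"), inherits(config, "sim_config"))
  n <- config$n_reads
  L <- config$read_length

  with_seed(config$seed, {
    # Sequence layout: all-random, or repeated [5 random | motif] blocks.
    if (is.null(config$flank_motif)) {
      random_mask <- rep(TRUE, L)
      template <- integer(L)
    } else {
      motif <- strsplit(config$flank_motif, "", fixed = TRUE)[[1]]
      unit_mask <- c(rep(TRUE, 5L), rep(FALSE, length(motif)))
      unit_tpl <- c(integer(5L), match(motif, BASES5))
      reps <- ceiling(L / length(unit_mask))
      random_mask <- rep(unit_mask, reps)[seq_len(L)]
      template <- rep(unit_tpl, reps)[seq_len(L)]
    }
    n_rand <- sum(random_mask)

    # Base indices into BASES5 (A=1, B=2, C=3, G=4, T=5); B never drawn.
    seqm <- matrix(rep(template, each = n), nrow = n, ncol = L)
    seqm[, random_mask] <- sample(c(1L, 3L, 4L, 5L), n * n_rand, replace = TRUE)

    labeled <- stats::runif(n) < config$labeled_fraction
    is_t <- seqm == 5L & matrix(random_mask, n, L, byrow = TRUE)
    sub <- is_t & labeled &
      matrix(stats::runif(n * L) < config$substitution_rate, n, L)
    seqm[sub] <- 2L  # T -> B

    # True 5-mer code per position, with 2 columns of A-padding per side.
    pad <- matrix(1L, n, 2L)
    P <- cbind(pad, seqm, pad)
    code <- kmer_code(P[, 1:L] - 1L, P[, 2:(L + 1L)] - 1L, P[, 3:(L + 2L)] - 1L,
                      P[, 4:(L + 3L)] - 1L, P[, 5:(L + 4L)] - 1L)

    lv <- model$level_mean[code]
    sdlv <- model$level_sd[code]
    norm_mean <- stats::rnorm(n * L, mean = lv, sd = config$noise_sd)
    norm_sd <- abs(stats::rnorm(n * L, mean = sdlv, sd = sdlv / 4))
    dwell <- 1L + stats::rpois(n * L, config$dwell_mean - 1)

    called <- seqm
    called[called == 2L] <- 5L  # BrdU basecalled as T
    if (config$basecall_error > 0) {
      err <- matrix(stats::runif(n * L) < config$basecall_error, n, L)
      # replace with a uniformly chosen different canonical base
      shift <- matrix(sample(1:3, n * L, replace = TRUE), n, L)
      canon_idx <- match(called, c(1L, 3L, 4L, 5L))  # 1..4 among A,C,G,T
      new_idx <- ((canon_idx - 1L + shift) %% 4L) + 1L
      called[err] <- c(1L, 3L, 4L, 5L)[new_idx[err]]
    }

    read_id <- sprintf("read_%05d", seq_len(n))
    data.frame(
      read_id = rep(read_id, each = L),
      pos = rep.int(0:(L - 1L), n),
      base_called = BASES5[as.vector(t(called))],
      true_base = BASES5[as.vector(t(seqm))],
      norm_mean = as.vector(t(matrix(norm_mean, n, L))),
      norm_sd = as.vector(t(matrix(norm_sd, n, L))),
      dwell = as.vector(t(matrix(dwell, n, L))),
      stringsAsFactors = FALSE
    )
  })
}

#' Oracle window classifier using simulation ground truth
#'
#' A diagnostic classifier that uses the simulator's own pore model and the
#' true flanking bases to decide, for every thymidine-candidate window
#' (called base T at the center, two full flanks), whether the center base is
#' thymidine or BrdU: it scores the observed normalized means of the five
#' events in the window against the exact expected levels under the
#' center-is-T and center-is-B hypotheses and picks the closer one (ties go
#' to T). It is useful as an implementation-independent reference for
#' read-level rate estimation; it is not a basecaller, since it peeks at the
#' true sequence context.
#'
#' @param events Simulated event `data.frame` from [simulate_reads()].
#' @param model The [build_pore_model()] object that generated the events.
#' @return A calls `data.frame` with columns `read_id`, `center_pos`,
#'   `center_base` (always `"T"`) and `call` (`"B"` or `"T"`).
#' @export
oracle_window_classifier <- function(events, model) {
  stopifnot(inherits(model, "pore_model"))
  res <- lapply(split(events, events$read_id)[unique(events$read_id)],
                function(ev) {
    ev <- ev[order(ev$pos), ]
    L <- nrow(ev)
    if (L < 5L) return(NULL)
    b <- match(ev$true_base, BASES5)
    pb <- c(1L, 1L, b, 1L, 1L)  # A-padded, 1-based positions p+2
    cand <- which(ev$base_called == "T" & seq_len(L) >= 3L & seq_len(L) <= L - 2L)
    if (!length(cand)) return(NULL)
    sse_t <- numeric(length(cand)); sse_b <- numeric(length(cand))
    a0 <- b[cand] - 1L  # 0-based index of actual center base (1=B or 4=T)
    for (o in -2:2) {
      p <- cand + o                      # event position (1-based)
      idx <- cbind(p, p + 1L, p + 2L, p + 3L, p + 4L)  # padded columns p-2..p+2
      code <- kmer_code(pb[idx[, 1]] - 1L, pb[idx[, 2]] - 1L, pb[idx[, 3]] - 1L,
                        pb[idx[, 4]] - 1L, pb[idx[, 5]] - 1L)
      w <- 5L^(2L + o)                   # positional weight of the center digit
      mu_t <- model$level_mean[code + (4L - a0) * w]
      mu_b <- model$level_mean[code + (1L - a0) * w]
      x <- ev$norm_mean[p]
      sse_t <- sse_t + (x - mu_t)^2
      sse_b <- sse_b + (x - mu_b)^2
    }
    data.frame(read_id = ev$read_id[1], center_pos = ev$pos[cand],
               center_base = "T",
               call = ifelse(sse_b < sse_t, "B", "T"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
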