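#' Enumerate all k-mers over a base alphabet
#'
#' Generates every k-mer over the given alphabet in base-`length(alphabet)`
#' positional order (first character most significant), the same order used
#' internally for pore-model lookups.
#'
#' @param alphabet Character vector of single-letter base symbols.
#' @param k K-mer length.
#' @return Character vector of `length(alphabet)^k` k-mers.
#' @examples
#' length(all_kmers())                 # 3125 five-base 5-mers
#' length(all_kmers(c("A", "C", "G", "B")))  # 1024 BrdU-context 5-mers
#' @export
all_kmers <- function(alphabet = BASES5, k = 5L) {
  alphabet <- sort(alphabet)
  g <- expand.grid(rep(list(alphabet), k), stringsAsFactors = FALSE)
  # expand.grid varies the first column fastest; we want the LAST position
  # fastest so reverse the columns before pasting.
  do.call(paste0, rev(g))
}

#' Build a synthetic 5-mer pore model with a BrdU-induced current shift
#'
#' Constructs the simulator's signal ground truth: a lookup table of expected
#' normalized current level and spread for each of the 3125 5-mers over
#' \{A, B, C, G, T\} (B = BrdU). Canonical (B-free) 5-mer levels are drawn
#' reproducibly from a standard normal, standing in for a tabulated R9 pore
#' model. Each B-containing 5-mer inherits the level of its B-to-T homolog
#' plus a displacement `shift_magnitude` weighted by where the B sits in the
#' 5-mer: weight 1 at the center position, 0.25 at each flanking position,
#' summed over all B positions. Level spreads are uniform on a small range
#' and shared with the homolog, so at `shift_magnitude = 0` the BrdU and
#' thymidine signal distributions are identical.
#'
#' @param seed Integer seed controlling the canonical level table.
#' @param shift_magnitude Non-negative BrdU-induced displacement (normalized
#'   current units) applied per position weight.
#' @param position_weights Numeric vector of 5 per-position weights for the
#'   shift; default `c(0.25, 0.25, 1, 0.25, 0.25)`.
#' @return An object of class `pore_model`: a list with `kmer_len`, `kmers`,
#'   `level_mean`, `level_sd` (both named by k-mer), `shift_magnitude`,
#'   `position_weights` and `seed`.
#' @examples
#' pm <- build_pore_model(seed = 1, shift_magnitude = 1)
#' pm$level_mean[["AABAA"]] - pm$level_mean[["AATAA"]]  # exactly 1
#' @export
build_pore_model <- function(seed = 1L, shift_magnitude = 1.5,
                             position_weights = c(0.25, 0.25, 1, 0.25, 0.25)) {
  stopifnot_scalar(shift_magnitude, "shift_magnitude")
  if (shift_magnitude < 0) stop("shift_magnitude must be >= 0", call. = FALSE)
  if (length(position_weights) != 5L || any(position_weights < 0))
    stop("position_weights must be 5 non-negative values", call. = FALSE)

  kmers <- all_kmers(BASES5, 5L)
  canon <- all_kmers(BASES4, 5L)
  lv <- with_seed(seed, {
    level <- stats::rnorm(length(canon))
    sdlv <- stats::runif(length(canon), 0.05, 0.15)
    list(level = stats::setNames(level, canon),
         sd = stats::setNames(sdlv, canon))
  })

  homolog <- gsub("B", "T", kmers, fixed = TRUE)
  chars <- matrix(unlist(strsplit(kmers, "", fixed = TRUE), use.names = FALSE),
                  ncol = 5L, byrow = TRUE)
  wsum <- as.numeric((chars == "B") %*% position_weights)

  level_mean <- stats::setNames(unname(lv$level[homolog]) + shift_magnitude * wsum, kmers)
  level_sd <- stats::setNames(unname(lv$sd[homolog]), kmers)

  structure(list(kmer_len = 5L, kmers = kmers, level_mean = level_mean,
                 level_sd = level_sd, shift_magnitude = shift_magnitude,
                 position_weights = position_weights, seed = as.integer(seed)),
            class = "pore_model")
}

#' @export
print.pore_model <- function(x, ...) {
  cat(sprintf("5-mer pore model: %d k-mers, BrdU shift %.3g (seed %d)\n",
              length(x$kmers), x$shift_magnitude, x$seed))
  cat(sprintf("  canonical level range [%.2f, %.2f], spread range [%.3f, %.3f]\n",
              min(x$level_mean), max(x$level_mean),
              min(x$level_sd), max(x$level_sd)))
  invisible(x)
}

# 1-based lookup index of a k-mer given a 0-based base-index matrix slice.
# codes: integer matrix of base indices (0 = A .. 4 = T) for 5 consecutive
# positions; returns index into all_kmers(BASES5) ordering.
kmer_code <- function(b1, b2, b3, b4, b5) {
  (((b1 * 5L + b2) * 5L + b3) * 5L + b4) * 5L + b5 + 1L
}
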