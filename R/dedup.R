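#' Bloom-filter duplicate index
#'
#' `B` bit arrays of `L` bits each, all initially zero, with `B`
#' independently seeded hash functions. Each hash maps a read sequence to a
#' position `p` in `[0, L)`; a key whose bit is already set in every array
#' is flagged as a duplicate, otherwise all `B` bits are set. Bits only
#' ever turn on, so an exact repeat of an inserted key is always caught
#' (no false negatives); false positives occur at the usual bloom collision
#' rate, for which [duplication_rate()] can correct analytically. Memory is
#' `B * L / 8` bytes regardless of how many reads pass through.
#'
#' Hash seeds default to fixed constants so that repeated runs flag the
#' identical read set.
#'
#' @param B number of arrays/hash functions (1-8)
#' @param L bits per array (default `2^26`, i.e. 8 MiB per array)
#' @param seeds optional numeric vector of `B` distinct hash seeds
#' @return a `dedup_index` object
#' @export
dedup_index <- function(B = 3L, L = 2^26, seeds = NULL) {
  if (B < 1L || B > 8L) abort("B must be in 1..8")
  if (L < 1) abort("L must be >= 1")
  if (is.null(seeds)) {
    seeds <- c(1000003, 19937, 7778777, 104729, 1299709, 15485863,
               32452843, 49979687)[seq_len(B)]
  }
  if (length(seeds) != B || anyDuplicated(seeds)) {
    abort("seeds must be B distinct values")
  }
  structure(list(ptr = cpp_bloom_new(as.integer(B), L, as.numeric(seeds)),
                 B = as.integer(B), L = L, seeds = seeds),
            class = "dedup_index")
}

#' Combined dedup key for a read pair
#'
#' Read pairs are combined into a single key -- the two sequences joined by
#' a separator outside the base alphabet -- and then treated exactly like a
#' single-end sequence. Swapped mates therefore yield different keys.
#'
#' @param seq1,seq2 sequence character vectors of the two mates
#' @return character vector of combined keys
#' @export
#' @examples
#' pair_key("ACGT", "TTTT")
pair_key <- function(seq1, seq2) {
  paste0(seq1, "|", seq2)
}

#' Check keys against the index and insert the new ones
#'
#' Mutates the index in place (it wraps external storage) and returns, per
#' key, whether it was flagged as a duplicate. Order matters: the first
#' occurrence of a key is always unique, later occurrences duplicate.
#'
#' @param index a [dedup_index()]
#' @param keys character vector of read or pair keys
#' @return logical vector, `TRUE` where the key was flagged duplicate
#' @export
dedup_check <- function(index, keys) {
  stopifnot(inherits(index, "dedup_index"))
  cpp_bloom_check_insert(index$ptr, keys)
}

#' Duplication-rate estimate from a dedup index
#'
#' The raw rate is `duplicates_flagged / reads_seen`. With
#' `correct_fp = TRUE` (default) the expected number of bloom false
#' positives -- the sum over checks of `(1 - (1 - 1/L)^u)^B`, with `u` the
#' unique keys inserted before the check -- is subtracted first, clamping
#' to `[0, 1]`.
#'
#' @param index a [dedup_index()]
#' @param correct_fp subtract the analytic false-positive expectation
#' @return duplication-rate estimate in `[0, 1]`
#' @export
duplication_rate <- function(index, correct_fp = TRUE) {
  st <- cpp_bloom_state(index$ptr)
  if (st$reads_seen == 0) abort("no reads have been checked yet")
  dup <- st$duplicates_flagged
  if (correct_fp) dup <- dup - st$expected_false_positives
  min(max(dup / st$reads_seen, 0), 1)
}

#' Dedup index counters and memory footprint
#'
#' @param index a [dedup_index()]
#' @return list with `B`, `L`, `reads_seen`, `duplicates_flagged`,
#'   `unique_inserted`, `expected_false_positives`, and `bytes` (actual
#'   bit-array allocation)
#' @export
dedup_state <- function(index) {
  cpp_bloom_state(index$ptr)
}

#' Hash a sequence into `[0, L)`
#'
#' The seeded 64-bit hash behind the dedup index, exposed for inspection.
#' Deterministic in `(sequence, seed, L)`.
#'
#' @param x character vector of keys
#' @param seed hash seed
#' @param L bucket count
#' @return numeric vector of positions in `[0, L)`
#' @export
hash_sequence <- function(x, seed = 1000003, L = 2^26) {
  if (L < 1) abort("L must be >= 1")
  cpp_hash_sequence(x, seed, L)
}

#' @export
print.dedup_index <- function(x, ...) {
  st <- cpp_bloom_state(x$ptr)
  cat(sprintf("<dedup_index> B=%d arrays x L=%.0f bits (%.1f MiB); %.0f reads seen, %.0f flagged duplicate\n",
              st$B, st$L, st$bytes / 2^20, st$reads_seen,
              st$duplicates_flagged))
  invisible(x)
}
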