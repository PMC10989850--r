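#' Paired-end overlap analysis
#'
#' Aligns read 1 against the reverse complement of read 2 without gaps to
#' recover the fragment geometry. Candidate offsets (the read-1 coordinate
#' at which the reverse-complemented read 2 begins; negative means the pair
#' read through the fragment into the adapter) are scanned in increasing
#' absolute value, non-negative before negative at ties, and the first
#' offset whose overlap reaches `min_overlap` bases with at most
#' `min(max_mismatch, floor(max_mismatch_fraction * overlap_len))`
#' mismatches is accepted. The deterministic candidate order makes the
#' search reproducible; the accepted geometry then drives read-through
#' adapter clipping, base correction, merging, and insert-size estimation
#' from this single computation.
#'
#' Defaults (`min_overlap` 30, `max_mismatch` 5, fraction 0.2) are the
#' conventional overlap-analysis settings for short-read preprocessing.
#'
#' @param r1,r2 read tibbles of synchronized mates
#' @param min_overlap minimum overlap length in bases
#' @param max_mismatch absolute mismatch cap in the overlap
#' @param max_mismatch_fraction mismatch cap as a fraction of overlap length
#' @return tibble with one row per pair: `found`, `offset`, `overlap_len`,
#'   `mismatches`, and `mismatch_positions` (list column of 1-based read-1
#'   coordinates)
#' @export
analyze_overlap <- function(r1, r2, min_overlap = 30L, max_mismatch = 5L,
                            max_mismatch_fraction = 0.2) {
  res <- cpp_overlap_analyze(r1$sequence, r2$sequence, as.integer(min_overlap),
                             as.integer(max_mismatch), max_mismatch_fraction)
  tibble(found = res$found, offset = res$offset,
         overlap_len = res$overlap_len, mismatches = res$mismatches,
         mismatch_positions = res$mismatch_positions)
}

#' Clip read-through adapters using the overlap geometry
#'
#' A negative overlap offset means both reads extend past the fragment ends
#' into adapter sequence: read 1 is truncated to the fragment
#' (`len2 + offset` bases) and read 2 likewise (`len1 + offset` bases).
#' Pairs without a negative-offset overlap are untouched.
#'
#' @param r1,r2 read tibbles
#' @param ov overlap tibble from [analyze_overlap()]
#' @return list with `r1`, `r2` (clipped tibbles) and `clipped_bases`
#'   (integer vector of adapter bases removed per pair, both mates summed)
#' @export
clip_adapters_from_overlap <- function(r1, r2, ov) {
  len1 <- nchar(r1$sequence)
  len2 <- nchar(r2$sequence)
  act <- ov$found & !is.na(ov$offset) & ov$offset < 0L
  keep1 <- ifelse(act, pmax(0L, len2 + ov$offset), len1)
  keep2 <- ifelse(act, pmax(0L, len1 + ov$offset), len2)
  clipped <- (len1 - keep1) + (len2 - keep2)
  r1$sequence <- substr(r1$sequence, 1L, keep1)
  r1$quality <- substr(r1$quality, 1L, keep1)
  r2$sequence <- substr(r2$sequence, 1L, keep2)
  r2$quality <- substr(r2$quality, 1L, keep2)
  list(r1 = r1, r2 = r2, clipped_bases = as.integer(clipped))
}

#' Quality-aware base correction in the overlap
#'
#' At each mismatch inside the overlap, when one mate's base has quality at
#' least `high_q` and the other's is below `low_q`, the low-quality base is
#' replaced by the strand-consistent base of the high-quality mate and
#' inherits its quality. Symmetric-quality mismatches are left untouched,
#' and bases outside the overlap are never modified.
#'
#' @param r1,r2 read tibbles
#' @param ov overlap tibble from [analyze_overlap()]
#' @param high_q,low_q Phred thresholds of the asymmetry criterion
#' @return list with `r1`, `r2` (corrected tibbles) and `corrected`
#'   (integer vector of corrections per pair)
#' @export
correct_bases <- function(r1, r2, ov, high_q = 30L, low_q = 15L) {
  res <- cpp_correct_bases(r1$sequence, r1$quality, r2$sequence, r2$quality,
                           ov$found, ov$offset, as.integer(high_q),
                           as.integer(low_q))
  r1$sequence <- res$seq1
  r1$quality <- res$qual1
  r2$sequence <- res$seq2
  r2$quality <- res$qual2
  list(r1 = r1, r2 = r2, corrected = res$corrected)
}

#' Merge overlapping read pairs into single fragments
#'
#' Builds one read in read-1 orientation covering the union of both mates.
#' In the overlap the higher-quality base wins (ties go to read 1); the
#' merged quality is the maximum of the two when the bases agree and the
#' chosen base's quality when they disagree. The merged length equals the
#' estimated insert size. Pairs without an overlap get `NA` rows.
#'
#' @param r1,r2 read tibbles
#' @param ov overlap tibble from [analyze_overlap()]
#' @return read tibble of merged reads (name = read-1 name, comment
#'   `merged_<len1>_<len2>`), with `NA` sequence for unmerged pairs
#' @export
merge_pairs <- function(r1, r2, ov) {
  res <- cpp_merge_pairs(r1$sequence, r1$quality, r2$sequence, r2$quality,
                         ov$found, ov$offset)
  tibble(name = r1$name,
         comment = ifelse(ov$found,
                          sprintf("merged_%d_%d", nchar(r1$sequence),
                                  nchar(r2$sequence)),
                          NA_character_),
         sequence = res$sequence, quality = res$quality)
}

#' Insert-size histogram from overlap results
#'
#' Found pairs contribute `offset + len2` (non-negative offset) or the
#' overlap length (read-through); pairs without an overlap are tallied as
#' `unknown` -- typically fragments too long for the mates to overlap.
#'
#' @param ov overlap tibble from [analyze_overlap()]
#' @param len2 read-2 lengths (recycled scalar or vector)
#' @return list with `histogram` (tibble `insert_size`, `n`) and `unknown`
#'   (count of pairs with no overlap)
#' @export
insert_size_histogram <- function(ov, len2) {
  len2 <- rep_len(len2, nrow(ov))
  ins <- ifelse(ov$found,
                ifelse(ov$offset >= 0L, ov$offset + len2, ov$overlap_len),
                NA_integer_)
  hist <- dplyr::count(tibble(insert_size = ins[!is.na(ins)]),
                       .data$insert_size)
  list(histogram = hist, unknown = sum(is.na(ins)))
}
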