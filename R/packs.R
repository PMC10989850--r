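#' Partition reads into fixed-capacity packs
#'
#' Packs are the unit of worker routing and of in-order output reassembly:
#' all packs except possibly the last hold exactly `capacity` reads, pack
#' indices are consecutive from 0, and concatenating packs by ascending
#' index reproduces the input order exactly.
#'
#' @param reads read tibble (or any data frame)
#' @param capacity pack capacity, >= 1
#' @return list of tibbles, each carrying a `pack_index` attribute
#' @export
partition_packs <- function(reads, capacity = 1000L) {
  if (capacity < 1L) abort("pack capacity must be >= 1")
  n <- nrow(reads)
  if (n == 0L) return(list())
  starts <- seq(1L, n, by = capacity)
  purrr::map(seq_along(starts), function(i) {
    pack <- reads[starts[i]:min(starts[i] + capacity - 1L, n), , drop = FALSE]
    attr(pack, "pack_index") <- i - 1L
    pack
  })
}

#' Deterministic pack-to-worker routing
#'
#' `worker_id = pack_index mod worker_count` -- a pure function of the pack
#' index, never of runtime timing, so the worker that processes a given
#' pack is fixed before any work starts. With two workers this is exactly
#' the odd/even pack alternation; reassembling outputs by pack index then
#' makes results identical for any worker count.
#'
#' @param pack_index non-negative pack index (vectorized)
#' @param worker_count number of workers, >= 1
#' @return integer worker ids in `[0, worker_count)`
#' @export
#' @examples
#' assign_worker(0:7, 2) # odd/even alternation
assign_worker <- function(pack_index, worker_count) {
  if (worker_count < 1L) abort("worker_count must be >= 1")
  if (any(pack_index < 0L)) abort("pack_index must be non-negative")
  as.integer(pack_index %% worker_count)
}
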