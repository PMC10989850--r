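#' Accumulate one-pass QC statistics over a read batch
#'
#' Builds (or extends) a mergeable accumulator of per-cycle base counts,
#' per-cycle quality sums (overall and conditioned on the called base),
#' Q20/Q30/GC totals, and 5-mer counts. All fields are plain counts, so
#' merging accumulators is exact, associative and commutative -- the
#' property that lets packs be processed on any worker and combined in any
#' order without changing the report.
#'
#' @param reads read tibble
#' @param acc optional existing `qc_accumulator` to extend
#' @param kmer_k k-mer length for the k-mer table
#' @return a `qc_accumulator` object
#' @export
qc_accumulate <- function(reads, acc = NULL, kmer_k = 5L) {
  raw <- cpp_qc_accumulate(reads$sequence, reads$quality, as.integer(kmer_k))
  new <- structure(raw, class = "qc_accumulator")
  rownames(new$base_counts) <- rownames(new$base_qual_sum) <-
    c("A", "C", "G", "T", "N")
  if (is.null(acc)) new else qc_merge(acc, new)
}

#' An empty QC accumulator (the merge identity)
#' @param kmer_k k-mer length
#' @return a `qc_accumulator` with all counters zero
#' @export
qc_empty <- function(kmer_k = 5L) {
  qc_accumulate(tibble(name = character(), sequence = character(),
                       quality = character()), kmer_k = kmer_k)
}

pad_cols <- function(m, cols) {
  if (ncol(m) >= cols) return(m)
  cbind(m, matrix(0, nrow(m), cols - ncol(m)))
}

#' Merge two QC accumulators
#'
#' Fieldwise addition after padding per-cycle structures to the common
#' cycle count. Exact for count data, hence associative and commutative.
#'
#' @param a,b `qc_accumulator` objects
#' @return the merged `qc_accumulator`
#' @export
qc_merge <- function(a, b) {
  stopifnot(inherits(a, "qc_accumulator"), inherits(b, "qc_accumulator"))
  mc <- max(a$max_cycles, b$max_cycles)
  out <- list(
    max_cycles = mc,
    base_counts = pad_cols(a$base_counts, mc) + pad_cols(b$base_counts, mc),
    base_qual_sum = pad_cols(a$base_qual_sum, mc) +
      pad_cols(b$base_qual_sum, mc),
    qual_sum = c(a$qual_sum, numeric(mc - a$max_cycles)) +
      c(b$qual_sum, numeric(mc - b$max_cycles)),
    cycle_count = c(a$cycle_count, numeric(mc - a$max_cycles)) +
      c(b$cycle_count, numeric(mc - b$max_cycles)),
    kmer_counts = a$kmer_counts + b$kmer_counts,
    total_reads = a$total_reads + b$total_reads,
    total_bases = a$total_bases + b$total_bases,
    q20_bases = a$q20_bases + b$q20_bases,
    q30_bases = a$q30_bases + b$q30_bases,
    gc_bases = a$gc_bases + b$gc_bases)
  structure(out, class = "qc_accumulator")
}

#' Per-cycle mean quality curves
#'
#' @param acc a `qc_accumulator`
#' @return tidy tibble with columns `cycle` (1-based), `base` (`A`, `C`,
#'   `G`, `T`, `N` or `mean`), and `quality` (mean Phred); cycles with no
#'   coverage are omitted
#' @export
quality_curves <- function(acc) {
  stopifnot(inherits(acc, "qc_accumulator"))
  if (acc$max_cycles == 0) {
    return(tibble(cycle = integer(), base = character(), quality = double()))
  }
  cycles <- seq_len(acc$max_cycles)
  covered <- acc$cycle_count > 0
  overall <- tibble(cycle = cycles[covered], base = "mean",
                    quality = unname(acc$qual_sum[covered] /
                                       acc$cycle_count[covered]))
  per_base <- purrr::map(c("A", "C", "G", "T", "N"), function(b) {
    cnt <- acc$base_counts[b, ]
    has <- cnt > 0
    tibble(cycle = cycles[has], base = b,
           quality = unname(acc$base_qual_sum[b, has] / cnt[has]))
  })
  bind_rows(c(list(overall), per_base))
}

#' Per-cycle base-content curves
#'
#' @param acc a `qc_accumulator`
#' @return tidy tibble with columns `cycle`, `base` (`A,C,G,T,N,GC`) and
#'   `fraction`; per cycle the five base fractions sum to 1
#' @export
content_curves <- function(acc) {
  stopifnot(inherits(acc, "qc_accumulator"))
  if (acc$max_cycles == 0) {
    return(tibble(cycle = integer(), base = character(), fraction = double()))
  }
  cycles <- seq_len(acc$max_cycles)
  covered <- acc$cycle_count > 0
  rows <- purrr::map(c("A", "C", "G", "T", "N"), function(b) {
    tibble(cycle = cycles[covered], base = b,
           fraction = unname(acc$base_counts[b, covered] /
                               acc$cycle_count[covered]))
  })
  gc <- tibble(cycle = cycles[covered], base = "GC",
               fraction = unname((acc$base_counts["C", covered] +
                                  acc$base_counts["G", covered]) /
                                   acc$cycle_count[covered]))
  bind_rows(c(rows, list(gc)))
}

#' k-mer counts as a tidy table
#'
#' @param acc a `qc_accumulator`
#' @param k the k-mer length the accumulator was built with
#' @return tibble with columns `kmer` and `count`
#' @export
kmer_table <- function(acc, k = 5L) {
  stopifnot(inherits(acc, "qc_accumulator"))
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid,
                  c(rev(replicate(k, bases, simplify = FALSE)),
                    stringsAsFactors = FALSE))
  kmers <- do.call(paste0, rev(grid))
  tibble(kmer = kmers, count = as.numeric(acc$kmer_counts))
}

#' Overrepresented-sequence analysis
#'
#' Counts every substring of the requested lengths from every `sampling`-th
#' read and flags sequences whose count reaches
#' `max(min_count, expected * multiplier)`, where the expectation assumes a
#' uniform base composition (`0.25^len` per sampled position). Flagged
#' sequences get a per-starting-cycle hit distribution, which shows whether
#' a contaminant is positionally anchored (an adapter) or uniform
#' (an abundant transcript).
#'
#' @param reads read tibble
#' @param lengths substring lengths to scan; defaults to
#'   `{10, 20, 40, 100, floor(read_len / 2)}` clipped to the read length
#' @param sampling analyse every `sampling`-th read
#' @param multiplier overrepresentation factor over the uniform expectation
#' @param min_count absolute floor on the flagging threshold
#' @return tibble with columns `sequence`, `length`, `count`, `expected`,
#'   and `cycle_hits` (list column of per-starting-cycle hit counts)
#' @export
detect_overrepresented <- function(reads, lengths = NULL, sampling = 20L,
                                   multiplier = 10, min_count = 10L) {
  if (sampling < 1L) abort("sampling must be >= 1")
  if (nrow(reads) == 0L) {
    return(tibble(sequence = character(), length = integer(),
                  count = double(), expected = double(),
                  cycle_hits = list()))
  }
  max_len <- max(nchar(reads$sequence))
  if (is.null(lengths)) {
    lengths <- unique(pmin(c(10L, 20L, 40L, 100L, max_len %/% 2L), max_len))
    lengths <- lengths[lengths >= 1L]
  }
  raw <- cpp_overrep_count(reads$sequence, as.integer(sort(lengths)),
                           as.integer(sampling))
  lens <- nchar(raw$sequence)
  pos_by_len <- setNames(raw$positions_sampled, sort(lengths))
  expected <- 0.25^lens * pos_by_len[as.character(lens)]
  flag <- raw$count >= pmax(min_count, expected * multiplier)
  if (!any(flag)) {
    return(tibble(sequence = character(), length = integer(),
                  count = double(), expected = double(),
                  cycle_hits = list()))
  }
  seqs <- raw$sequence[flag]
  hits <- cpp_overrep_cycle_hits(reads$sequence, seqs, as.integer(sampling),
                                 max_len)
  tibble(sequence = seqs, length = nchar(seqs), count = raw$count[flag],
         expected = as.numeric(expected[flag]),
         cycle_hits = purrr::map(seq_along(seqs), ~ hits[.x, ])) |>
    arrange(dplyr::desc(.data$count))
}

#' @export
print.qc_accumulator <- function(x, ...) {
  cat(sprintf("<qc_accumulator> %.0f reads, %.0f bases, %d cycles; Q20 %.2f%%, Q30 %.2f%%, GC %.2f%%\n",
              x$total_reads, x$total_bases, x$max_cycles,
              100 * x$q20_bases / max(1, x$total_bases),
              100 * x$q30_bases / max(1, x$total_bases),
              100 * x$gc_bases / max(1, x$total_bases)))
  invisible(x)
}
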