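#' Trim a fixed number of bases from read ends
#'
#' Removes the first `front` and last `tail` bases (and their qualities)
#' from every read. Over-trimming yields an empty read, which the length
#' filter removes later; it is not an error here.
#'
#' @param reads read tibble
#' @param front,tail non-negative base counts to remove from the 5'/3' end
#' @return the trimmed read tibble
#' @export
trim_global <- function(reads, front = 0L, tail = 0L) {
  if (front < 0 || tail < 0) abort("front and tail must be non-negative")
  if (front == 0L && tail == 0L) return(reads)
  len <- nchar(reads$sequence)
  start <- pmin(front + 1L, len + 1L)
  end <- pmax(len - tail, 0L)
  reads$sequence <- substr(reads$sequence, start, end)
  reads$quality <- substr(reads$quality, start, end)
  reads
}

#' Sliding-window quality trimming
#'
#' Slides a window of `window` bases over the quality string and cuts on the
#' arithmetic mean of Phred scores:
#' * `front`: drop 5' bases before the first window whose mean is at least
#'   `mean_q`;
#' * `tail`: the symmetric cut from the 3' end;
#' * `right`: scan 5' to 3' and truncate from the start of the first window
#'   whose mean falls below `mean_q`.
#'
#' Windows are truncated at the read end (a shorter trailing window is
#' averaged over the bases it covers). A read can become empty.
#'
#' @param reads read tibble
#' @param mode one of `"front"`, `"tail"`, `"right"`
#' @param window window size in bases (>= 1)
#' @param mean_q mean Phred threshold
#' @return the trimmed read tibble
#' @export
cut_by_window <- function(reads, mode = c("front", "tail", "right"),
                          window = 4L, mean_q = 20) {
  mode <- match.arg(mode)
  if (window < 1L) abort("window must be >= 1")
  keep <- cpp_window_cut(reads$quality,
                         match(mode, c("front", "tail", "right")) - 1L,
                         as.integer(window), mean_q)
  reads$sequence <- substr(reads$sequence, keep[, 1L] + 1L, keep[, 2L])
  reads$quality <- substr(reads$quality, keep[, 1L] + 1L, keep[, 2L])
  reads
}

#' Trim polyG / polyX artifact runs from read 3' ends
#'
#' Some sequencing chemistries emit spurious trailing G runs when the signal
#' is absent. A 3' run of the given base (or of the best single base for
#' `base = "any"`) of at least `min_len` bases is removed. By default one
#' mismatch per 8 bases of run length is tolerated, so artifact runs
#' interrupted by sequencing errors are still caught; `exact = TRUE`
#' requires an uninterrupted run.
#'
#' @param reads read tibble
#' @param base `"G"` (polyG), another single base, or `"any"` (polyX)
#' @param min_len minimum run length to trim
#' @param exact disallow mismatches inside the run
#' @return the trimmed read tibble
#' @export
trim_polyx <- function(reads, base = "G", min_len = 10L, exact = FALSE) {
  if (min_len < 1L) abort("min_len must be >= 1")
  b <- if (identical(base, "any")) "" else toupper(base)
  if (nzchar(b) && !b %in% c("A", "C", "G", "T")) {
    abort("base must be one of A, C, G, T or 'any'")
  }
  cut <- cpp_polyx_trim(reads$sequence, b, as.integer(min_len), !exact)
  len <- nchar(reads$sequence)
  reads$sequence <- substr(reads$sequence, 1L, len - cut)
  reads$quality <- substr(reads$quality, 1L, len - cut)
  reads
}

#' Trim 3' adapters by adapter sequence
#'
#' Finds the leftmost position where the adapter prefix matches the read
#' with at most `floor(mismatch_fraction * matchlen)` mismatches over at
#' least `min_match` aligned bases, and truncates the read from there.
#'
#' @param reads read tibble
#' @param adapter adapter sequence (non-empty)
#' @param mismatch_fraction allowed mismatch fraction of the aligned length
#' @param min_match minimum aligned bases for a hit
#' @return list with `reads` (trimmed tibble) and `trimmed` (integer vector
#'   of bases removed per read, 0 when no hit)
#' @export
trim_adapter_by_sequence <- function(reads, adapter, mismatch_fraction = 0.2,
                                     min_match = 4L) {
  if (!nzchar(adapter)) abort("adapter must be non-empty")
  pos <- cpp_adapter_find(reads$sequence, toupper(adapter),
                          mismatch_fraction, as.integer(min_match))
  len <- nchar(reads$sequence)
  hit <- pos >= 0L
  trimmed <- ifelse(hit, len - pos, 0L)
  keep <- ifelse(hit, pos, len)
  reads$sequence <- substr(reads$sequence, 1L, keep)
  reads$quality <- substr(reads$quality, 1L, keep)
  list(reads = reads, trimmed = as.integer(trimmed))
}

#' Filter configuration
#'
#' Defaults follow common practice for short-read preprocessing: a base is
#' "qualified" at Phred >= 15, a read fails when more than 40% of its bases
#' are unqualified, more than 5 N bases, or a post-trim length under 15.
#'
#' @param qualified_phred Phred threshold for a qualified base
#' @param max_unqualified_fraction maximum tolerated fraction of unqualified
#'   bases
#' @param max_n_count maximum tolerated N bases
#' @param min_length minimum read length after trimming
#' @param max_length maximum length (0 = unlimited)
#' @return a `filter_config` list
#' @export
filter_config <- function(qualified_phred = 15L, max_unqualified_fraction = 0.4,
                          max_n_count = 5L, min_length = 15L, max_length = 0L) {
  stopifnot(qualified_phred >= 0, max_unqualified_fraction >= 0,
            max_unqualified_fraction <= 1, max_n_count >= 0,
            min_length >= 0, max_length >= 0)
  structure(list(qualified_phred = as.integer(qualified_phred),
                 max_unqualified_fraction = max_unqualified_fraction,
                 max_n_count = as.integer(max_n_count),
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length)),
            class = "filter_config")
}

filter_statuses <- c("pass", "low_quality", "too_many_N", "too_short",
                     "too_long", "duplicate")

#' Evaluate read filters
#'
#' Applies the quality, N-count and length rules in a fixed order --
#' low_quality, too_many_N, too_short, too_long -- with the first failure
#' winning, so per-reason counts partition the filtered reads exactly.
#' For pairs the checks run in the same order across both mates: a pair
#' fails with the first status either mate triggers.
#'
#' @param reads read tibble (read 1 for paired input)
#' @param cfg a [filter_config()]
#' @param mate optional read tibble of mates (read 2)
#' @return factor of verdicts, one per read/pair, levels
#'   `pass, low_quality, too_many_N, too_short, too_long, duplicate`
#' @export
evaluate_filters <- function(reads, cfg = filter_config(), mate = NULL) {
  stopifnot(inherits(cfg, "filter_config"))
  code1 <- cpp_filter_eval(reads$sequence, reads$quality, cfg$qualified_phred,
                           cfg$max_unqualified_fraction, cfg$max_n_count,
                           cfg$min_length, cfg$max_length)
  code <- if (is.null(mate)) {
    code1
  } else {
    code2 <- cpp_filter_eval(mate$sequence, mate$quality, cfg$qualified_phred,
                             cfg$max_unqualified_fraction, cfg$max_n_count,
                             cfg$min_length, cfg$max_length)
    # first failing check in rule order across both mates
    ifelse(code1 == 0L, code2, ifelse(code2 == 0L, code1, pmin(code1, code2)))
  }
  factor(filter_statuses[code + 1L], levels = filter_statuses)
}

#' Extract unique molecular identifiers into read names
#'
#' For read-derived schemes the first `umi_len` bases (plus `skip` discarded
#' bases after them) are removed from the designated read(s), and the UMI is
#' appended to both mates' names as `:UMI` (`per_read` joins the two UMIs
#' with `_`). Index schemes copy the UMI from the comment's index field and
#' leave sequences untouched.
#'
#' @param r1 read tibble (read 1)
#' @param r2 optional mate tibble (read 2)
#' @param scheme one of `read1`, `read2`, `per_read`, `index1`, `index2`
#' @param umi_len UMI length for read-derived schemes
#' @param skip bases discarded after the UMI
#' @return list with `r1`, `r2` (modified tibbles; `r2` is `NULL` for
#'   single-end) and `umi` (character vector of extracted UMIs)
#' @export
extract_umi <- function(r1, r2 = NULL,
                        scheme = c("read1", "read2", "per_read",
                                   "index1", "index2"),
                        umi_len = 0L, skip = 0L) {
  scheme <- match.arg(scheme)
  if (scheme %in% c("index1", "index2")) {
    src <- if (scheme == "index1") r1 else r2
    if (is.null(src)) abort("index2 scheme requires paired input")
    if (anyNA(src$comment)) {
      abort("index UMI scheme requires a comment field on every read")
    }
    # index field: last ':'-separated token of the comment
    umi <- sub(".*:", "", src$comment)
    if (any(!grepl("^[ACGTN+]+$", umi))) {
      abort("malformed index field in comment; cannot extract UMI")
    }
  } else {
    if (umi_len < 1L) abort("umi_len must be >= 1 for read-derived schemes")
    clip <- function(reads) {
      reads$sequence <- substring(reads$sequence, umi_len + skip + 1L)
      reads$quality <- substring(reads$quality, umi_len + skip + 1L)
      reads
    }
    if (scheme == "read1") {
      umi <- substr(r1$sequence, 1L, umi_len)
      r1 <- clip(r1)
    } else if (scheme == "read2") {
      if (is.null(r2)) abort("read2 scheme requires paired input")
      umi <- substr(r2$sequence, 1L, umi_len)
      r2 <- clip(r2)
    } else {
      if (is.null(r2)) abort("per_read scheme requires paired input")
      umi <- paste0(substr(r1$sequence, 1L, umi_len), "_",
                    substr(r2$sequence, 1L, umi_len))
      r1 <- clip(r1)
      r2 <- clip(r2)
    }
  }
  r1$name <- paste0(r1$name, ":", umi)
  if (!is.null(r2)) r2$name <- paste0(r2$name, ":", umi)
  list(r1 = r1, r2 = r2, umi = umi)
}
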