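#' Read a FASTQ file into a read tibble
#'
#' Parses 4-line FASTQ records (plain or gzip, auto-detected from the
#' gzip magic bytes `0x1f 0x8b`) into a tibble with one row per read.
#' Sequences are uppercase-normalized; qualities are Phred+33 and must lie
#' in the printable ASCII range. Malformed input -- a record count not
#' divisible by four, missing `@`/`+` sentinel lines, sequence/quality
#' length mismatch, or characters outside `A,C,G,T,N` -- is a hard error
#' naming the offending record, never silently repaired.
#'
#' @param path path to a FASTQ file, optionally gzip-compressed
#' @param n_max maximum number of records to read (`Inf` for all)
#' @return a tibble with columns `name`, `comment`, `sequence`, `quality`
#' @export
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
#' read_fastq(fq)
read_fastq <- function(path, n_max = Inf) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  con <- if (is_gzip(path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- if (is.finite(n_max)) readLines(con, n = 4L * n_max) else readLines(con)
  parse_fastq_lines(lines, source = path)
}

is_gzip <- function(path) {
  magic <- readBin(path, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

parse_fastq_lines <- function(lines, source = "input") {
  n_lines <- length(lines)
  if (n_lines == 0L) {
    return(tibble(name = character(), comment = character(),
                  sequence = character(), quality = character()))
  }
  if (n_lines %% 4L != 0L) {
    abort(sprintf("truncated FASTQ in %s: %d lines leave record %d incomplete",
                  source, n_lines, n_lines %/% 4L + 1L))
  }
  idx <- seq(1L, n_lines, by = 4L)
  header <- lines[idx]
  sequence <- toupper(lines[idx + 1L])
  plus <- lines[idx + 2L]
  quality <- lines[idx + 3L]

  bad <- which(!startsWith(header, "@"))
  if (length(bad)) {
    abort(sprintf("record %d in %s: header line does not start with '@'",
                  bad[1], source))
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    abort(sprintf("record %d in %s: separator line does not start with '+'",
                  bad[1], source))
  }
  bad <- which(nchar(sequence) != nchar(quality))
  if (length(bad)) {
    abort(sprintf("record %d in %s: sequence and quality lengths differ (%d vs %d)",
                  bad[1], source, nchar(sequence[bad[1]]), nchar(quality[bad[1]])))
  }
  header <- substring(header, 2L)
  ws <- regexpr("[ \t]", header)
  name <- ifelse(ws > 0L, substr(header, 1L, ws - 1L), header)
  comment <- ifelse(ws > 0L, substring(header, ws + 1L), NA_character_)

  reads <- tibble(name = name, comment = comment,
                  sequence = sequence, quality = quality)
  bad <- cpp_first_invalid_read(reads$sequence, reads$quality)
  if (bad > 0L) {
    abort(sprintf(
      "record %d in %s: invalid base (allowed A,C,G,T,N) or quality outside Phred+33 printable range",
      bad, source))
  }
  reads
}

#' Write a read tibble as 4-line FASTQ
#'
#' Validates the read invariants (equal sequence/quality length, `A,C,G,T,N`
#' alphabet, printable Phred+33 qualities) before writing anything, then
#' emits one 4-line record per row. Output is gzip-compressed when `gzip` is
#' `TRUE`, or when it is `NA` and the path ends in `.gz`.
#'
#' @param reads tibble with columns `name`, `sequence`, `quality` and
#'   optionally `comment`
#' @param path output path
#' @param gzip `TRUE`, `FALSE`, or `NA` to infer from a `.gz` suffix
#' @param gzip_level gzip compression level 1-9
#' @return the number of records written, invisibly
#' @export
write_fastq <- function(reads, path, gzip = NA, gzip_level = 4L) {
  stopifnot(all(c("name", "sequence", "quality") %in% names(reads)))
  n <- nrow(reads)
  if (n > 0L) {
    bad <- cpp_first_invalid_read(reads$sequence, reads$quality)
    if (bad > 0L) {
      abort(sprintf("record %d violates read invariants; nothing written", bad))
    }
  }
  use_gzip <- if (is.na(gzip)) grepl("\\.gz$", path) else isTRUE(gzip)
  header <- if ("comment" %in% names(reads)) {
    ifelse(is.na(reads$comment) | reads$comment == "",
           paste0("@", reads$name),
           paste0("@", reads$name, " ", reads$comment))
  } else {
    paste0("@", reads$name)
  }
  lines <- character(4L * n)
  if (n > 0L) {
    lines[seq(1L, 4L * n, by = 4L)] <- header
    lines[seq(2L, 4L * n, by = 4L)] <- reads$sequence
    lines[seq(3L, 4L * n, by = 4L)] <- "+"
    lines[seq(4L, 4L * n, by = 4L)] <- reads$quality
  }
  con <- if (use_gzip) gzfile(path, "wb", compression = gzip_level) else file(path, "wb")
  # single writeLines for deterministic byte output
  writeLines(lines, con, sep = "\n")
  close(con)
  invisible(n)
}

#' Reverse complement of DNA sequences
#'
#' Vectorized A<->T, C<->G complement with order reversal; `N` maps to `N`.
#' Characters outside `A,C,G,T,N` are a hard error.
#'
#' @param x character vector of sequences over `A,C,G,T,N`
#' @return character vector of reverse complements
#' @export
#' @examples
#' reverse_complement(c("ACGT", "AACN"))
reverse_complement <- function(x) {
  cpp_revcomp(x)
}

#' Check that two read tibbles form synchronized mate pairs
#'
#' Mate names must share the same stem after stripping a trailing `/1` or
#' `/2` and the comment field; the first desynchronized record index is
#' reported as a hard error.
#'
#' @param r1,r2 read tibbles of equal row count
#' @return `TRUE`, invisibly
#' @export
check_mate_sync <- function(r1, r2) {
  if (nrow(r1) != nrow(r2)) {
    abort(sprintf("mate files differ in record count (%d vs %d)",
                  nrow(r1), nrow(r2)))
  }
  stem1 <- sub("/[12]$", "", r1$name)
  stem2 <- sub("/[12]$", "", r2$name)
  bad <- which(stem1 != stem2)
  if (length(bad)) {
    abort(sprintf("mate desynchronization at record %d: '%s' vs '%s'",
                  bad[1], r1$name[bad[1]], r2$name[bad[1]]))
  }
  invisible(TRUE)
}
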