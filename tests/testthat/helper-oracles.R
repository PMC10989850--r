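# Independent brute-force oracles used to validate the fast implementations.
# These deliberately use plain R loops and no code paths from the package
# internals beyond trivial accessors.

phred <- function(qual) {
  lapply(strsplit(qual, ""), function(ch) utf8ToInt(paste(ch, collapse = "")) - 33L)
}

phred1 <- function(qual) utf8ToInt(qual) - 33L

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# quadratic all-offsets overlap scorer, same candidate order as the spec:
# increasing |offset|, non-negative first at ties
oracle_overlap <- function(s1, s2, min_overlap = 30, max_mismatch = 5,
                           max_frac = 0.2) {
  s2rc <- oracle_revcomp(s2)
  len1 <- nchar(s1); len2 <- nchar(s2rc)
  c1 <- strsplit(s1, "")[[1]]; c2 <- strsplit(s2rc, "")[[1]]
  cands <- integer()
  for (a in 0:max(len1, len2)) {
    for (o in unique(c(a, -a))) {
      if (o >= 0 && o <= len1 - min_overlap) cands <- c(cands, o)
      else if (o < 0 && -o <= len2 - min_overlap) cands <- c(cands, o)
    }
  }
  for (o in cands) {
    ov <- if (o >= 0) min(len1 - o, len2) else min(len1, len2 + o)
    if (ov < min_overlap) next
    i1 <- if (o >= 0) o + seq_len(ov) else seq_len(ov)
    i2 <- if (o >= 0) seq_len(ov) else seq_len(ov) - o
    mm <- sum(c1[i1] != c2[i2])
    if (mm <= min(max_mismatch, floor(max_frac * ov))) {
      return(list(found = TRUE, offset = o, overlap_len = ov,
                  mismatches = mm))
    }
  }
  list(found = FALSE, offset = NA_integer_, overlap_len = 0L,
       mismatches = NA_integer_)
}

# sliding-window quality cut by direct scan
oracle_window_cut <- function(qual, mode, window, mean_q) {
  q <- phred1(qual)
  len <- length(q)
  wmean <- function(i) {
    idx <- i:min(i + window - 1L, len)
    mean(q[idx])
  }
  if (mode == "front") {
    for (i in seq_len(len)) if (wmean(i) >= mean_q) {
      return(substr(qual, i, len))
    }
    return("")
  }
  if (mode == "tail") {
    for (j in rev(seq_len(len))) {
      idx <- max(1L, j - window + 1L):j
      if (mean(q[idx]) >= mean_q) return(substr(qual, 1, j))
    }
    return("")
  }
  for (i in seq_len(len)) if (wmean(i) < mean_q) {
    return(substr(qual, 1, i - 1L))
  }
  qual
}

# direct-counting filter verdict
oracle_filter <- function(seq, qual, qualified = 15, max_unq = 0.4,
                          max_n = 5, min_len = 15, max_len = 0) {
  len <- nchar(seq)
  q <- if (len > 0) phred1(qual) else integer()
  if (len > 0 && sum(q < qualified) / len > max_unq) return("low_quality")
  if (sum(strsplit(seq, "")[[1]] == "N") > max_n) return("too_many_N")
  if (len < min_len) return("too_short")
  if (max_len > 0 && len > max_len) return("too_long")
  "pass"
}

# naive per-cycle QC recomputation from scratch
oracle_qc <- function(seqs, quals) {
  lens <- nchar(seqs)
  mc <- max(c(0L, lens))
  bases <- c("A", "C", "G", "T", "N")
  base_counts <- matrix(0, 5, mc, dimnames = list(bases, NULL))
  base_qual_sum <- matrix(0, 5, mc, dimnames = list(bases, NULL))
  qual_sum <- numeric(mc); cycle_count <- numeric(mc)
  q20 <- 0; q30 <- 0; gc <- 0; total <- 0
  kmer <- new.env()
  for (r in seq_along(seqs)) {
    s <- strsplit(seqs[r], "")[[1]]
    q <- phred1(quals[r])
    for (i in seq_along(s)) {
      base_counts[s[i], i] <- base_counts[s[i], i] + 1
      base_qual_sum[s[i], i] <- base_qual_sum[s[i], i] + q[i]
      qual_sum[i] <- qual_sum[i] + q[i]
      cycle_count[i] <- cycle_count[i] + 1
      total <- total + 1
      if (q[i] >= 20) q20 <- q20 + 1
      if (q[i] >= 30) q30 <- q30 + 1
      if (s[i] %in% c("C", "G")) gc <- gc + 1
    }
    if (length(s) >= 5) {
      for (i in 1:(length(s) - 4L)) {
        k <- paste(s[i:(i + 4L)], collapse = "")
        if (!grepl("N", k)) {
          assign(k, (if (exists(k, kmer)) get(k, kmer) else 0) + 1, kmer)
        }
      }
    }
  }
  list(base_counts = base_counts, base_qual_sum = base_qual_sum,
       qual_sum = qual_sum, cycle_count = cycle_count,
       total_bases = total, q20 = q20, q30 = q30, gc = gc, kmer = kmer)
}

random_reads <- function(n, len = 60, seed = NULL, q_range = c(2, 40)) {
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(
    name = sprintf("r%d", seq_len(n)),
    comment = NA_character_,
    sequence = vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = "")
    }, character(1)),
    quality = vapply(seq_len(n), function(i) {
      qs <- q_range[1]:q_range[2]
      draw <- if (length(qs) == 1L) rep(qs, len)
              else sample(qs, len, replace = TRUE)
      intToUtf8(draw + 33L)
    }, character(1)))
}
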