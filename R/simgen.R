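#' Configuration for the synthetic paired-end read generator
#'
#' Describes a simulated sequencing experiment: fragments are drawn from a
#' fresh random reference, read 1 covers the fragment 5' end and read 2 the
#' reverse-complemented 3' end. When the insert is shorter than the read
#' length the read runs through into the adapter (and then random padding),
#' which is the geometry adapter-trimming and merging stages exploit.
#' Defaults describe a typical modern short-read library: 150 bp reads,
#' inserts normally distributed around 300 bp (sd 30), a 0.1% per-base
#' substitution error rate, and per-cycle mean quality decaying linearly
#' from Q36 to Q32 with Gaussian noise (sd 2), clamped to [2, 40].
#' Adapters default to the standard Illumina TruSeq adapter sequences.
#'
#' @param seed integer seed; the whole simulation is a pure function of the
#'   configuration including this seed
#' @param n_pairs number of read pairs
#' @param read_len read length in bases
#' @param insert_mean,insert_sd insert-size normal distribution (truncated
#'   at 1)
#' @param adapter_r1,adapter_r2 adapter sequences appended after the
#'   fragment on each mate
#' @param error_rate per-base substitution probability
#' @param q_start,q_end,q_sd per-cycle mean Phred at first/last cycle and
#'   Gaussian noise sd
#' @param duplication_rate probability that a pair is an exact byte-level
#'   copy of an earlier pair (copied after error injection, so "exact
#'   duplicate" ground truth is well defined)
#' @param polyg_rate,polyg_len probability of replacing a read-1 3' tail of
#'   `polyg_len` bases with a polyG artifact run
#' @param umi_len length of a random UMI prepended to read 1 (0 = off)
#' @param ref_len length of the random reference the fragments are drawn from
#' @return a `sim_config` list
#' @export
sim_config <- function(seed = 1L, n_pairs = 1000L, read_len = 150L,
                       insert_mean = 300, insert_sd = 30,
                       adapter_r1 = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                       adapter_r2 = "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT",
                       error_rate = 0.001,
                       q_start = 36, q_end = 32, q_sd = 2,
                       duplication_rate = 0,
                       polyg_rate = 0, polyg_len = 20L,
                       umi_len = 0L, ref_len = 100000L) {
  cfg <- list(seed = as.integer(seed), n_pairs = as.integer(n_pairs),
              read_len = as.integer(read_len), insert_mean = insert_mean,
              insert_sd = insert_sd, adapter_r1 = adapter_r1,
              adapter_r2 = adapter_r2, error_rate = error_rate,
              q_start = q_start, q_end = q_end, q_sd = q_sd,
              duplication_rate = duplication_rate, polyg_rate = polyg_rate,
              polyg_len = as.integer(polyg_len), umi_len = as.integer(umi_len),
              ref_len = as.integer(ref_len))
  probs <- c(error_rate = error_rate, duplication_rate = duplication_rate,
             polyg_rate = polyg_rate)
  if (any(probs < 0 | probs > 1)) {
    abort(sprintf("probability out of [0,1]: %s",
                  names(probs)[which(probs < 0 | probs > 1)[1]]))
  }
  if (cfg$umi_len >= cfg$read_len) abort("umi_len must be < read_len")
  if (cfg$n_pairs < 0L || cfg$read_len < 1L || cfg$ref_len < 1L) {
    abort("n_pairs, read_len, ref_len must be positive")
  }
  structure(cfg, class = "sim_config")
}

random_bases <- function(n_each, pool = c("A", "C", "G", "T")) {
  # n_each: vector of string lengths; one draw stream, split per string
  total <- sum(n_each)
  if (total == 0L) return(rep("", length(n_each)))
  draws <- pool[floor(runif(total) * 4) + 1L]
  grp <- rep.int(seq_along(n_each), n_each)
  out <- rep("", length(n_each))
  has <- n_each > 0L
  out[has] <- vapply(split(draws, factor(grp, levels = seq_along(n_each)))[has],
                     paste0, character(1), collapse = "")
  out
}

#' Simulate paired-end FASTQ reads with full ground truth
#'
#' Fully deterministic for a given configuration (the caller's RNG state is
#' saved and restored). The draw order is fixed -- reference, insert sizes,
#' fragment starts, UMIs, padding, qualities, errors, polyG flags,
#' duplication flags -- so adding reads to a configuration never reshuffles
#' earlier records.
#'
#' @param config a [sim_config()]
#' @return a list of class `sim_reads` with elements `r1`, `r2` (read
#'   tibbles), `truth` (one row per pair: fragment, insert size, planted
#'   adapter bases per mate, error counts, duplicate flag and source,
#'   polyG flag, UMI), and `config`
#' @export
#' @examples
#' sim <- simulate_reads(sim_config(seed = 7, n_pairs = 5))
#' sim$truth$insert_size
simulate_reads <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  n <- config$n_pairs
  rl <- config$read_len
  if (n == 0L) {
    empty <- tibble(name = character(), comment = character(),
                    sequence = character(), quality = character())
    return(structure(list(r1 = empty, r2 = empty,
                          truth = tibble(pair = integer()),
                          config = config), class = "sim_reads"))
  }

  ## 1. reference
  reference <- random_bases(config$ref_len)

  ## 2. insert sizes, truncated normal >= 1, capped at reference length
  insert <- pmin(pmax(1L, as.integer(round(rnorm(n, config$insert_mean,
                                                 config$insert_sd)))),
                 config$ref_len)

  ## 3. fragment start positions
  start <- floor(runif(n) * (config$ref_len - insert + 1)) + 1L
  fragment <- substring(reference, start, start + insert - 1L)
  frag_rc <- cpp_revcomp(fragment)

  ## 4. UMIs
  umi <- if (config$umi_len > 0L) random_bases(rep(config$umi_len, n))
         else rep("", n)

  ## 5. read payloads: [umi +] fragment [+ adapter + padding], cut to read_len
  cap1 <- rl - config$umi_len          # bases available for fragment+adapter in R1
  adapter_bases_r1 <- pmax(0L, pmin(nchar(config$adapter_r1), cap1 - insert))
  adapter_bases_r2 <- pmax(0L, pmin(nchar(config$adapter_r2), rl - insert))
  pad1 <- pmax(0L, cap1 - insert - nchar(config$adapter_r1))
  pad2 <- pmax(0L, rl - insert - nchar(config$adapter_r2))
  padding1 <- random_bases(pad1)
  padding2 <- random_bases(pad2)
  seq1 <- substr(paste0(umi, fragment, config$adapter_r1, padding1), 1L, rl)
  seq2 <- substr(paste0(frag_rc, config$adapter_r2, padding2), 1L, rl)

  ## 6. qualities: linear per-cycle decay + Gaussian noise, clamped [2, 40]
  prof <- config$q_start +
    (config$q_end - config$q_start) * (seq_len(rl) - 1) / max(1L, rl - 1L)
  qmat1 <- matrix(as.integer(pmin(40, pmax(2, round(
    rnorm(n * rl, mean = rep(prof, each = n), sd = config$q_sd))))), n, rl)
  qmat2 <- matrix(as.integer(pmin(40, pmax(2, round(
    rnorm(n * rl, mean = rep(prof, each = n), sd = config$q_sd))))), n, rl)
  qual1 <- cpp_phred_strings(qmat1)
  qual2 <- cpp_phred_strings(qmat2)

  ## 7. substitution errors
  inject <- function(seqs) {
    if (config$error_rate <= 0) {
      return(list(seqs = seqs, n_err = integer(length(seqs))))
    }
    hit <- which(matrix(runif(n * rl) < config$error_rate, n, rl),
                 arr.ind = TRUE)
    if (nrow(hit) == 0L) {
      return(list(seqs = seqs, n_err = integer(length(seqs))))
    }
    ord <- order(hit[, 1L], hit[, 2L])
    idx <- hit[ord, 1L]; pos <- hit[ord, 2L]
    orig <- substring(seqs[idx], pos, pos)
    bases <- c("A", "C", "G", "T")
    oi <- match(orig, bases)
    repl <- bases[((oi - 1L + floor(runif(length(oi)) * 3) + 1L) %% 4L) + 1L]
    out <- cpp_substitute_bases(seqs, idx, pos, repl)
    list(seqs = out, n_err = tabulate(idx, nbins = n))
  }
  e1 <- inject(seq1)
  e2 <- inject(seq2)
  seq1 <- e1$seqs; seq2 <- e2$seqs

  ## 8. polyG artifact on read-1 tails
  polyg <- runif(n) < config$polyg_rate
  if (any(polyg)) {
    keep <- pmax(0L, rl - config$polyg_len)
    seq1[polyg] <- paste0(substr(seq1[polyg], 1L, keep),
                          strrep("G", rl - keep))
  }

  ## 9. duplication: later pairs become byte copies of earlier pairs
  is_dup <- c(FALSE, runif(n - 1L) < config$duplication_rate)
  source_idx <- rep(NA_integer_, n)
  dup_at <- which(is_dup)
  if (length(dup_at)) {
    source_idx[dup_at] <- floor(runif(length(dup_at)) * (dup_at - 1L)) + 1L
    # sequential so duplicate-of-duplicate chains stay byte-identical
    for (d in dup_at) {
      s <- source_idx[d]
      seq1[d] <- seq1[s]; qual1[d] <- qual1[s]
      seq2[d] <- seq2[s]; qual2[d] <- qual2[s]
      e1$n_err[d] <- e1$n_err[s]
      e2$n_err[d] <- e2$n_err[s]
    }
  }

  name <- sprintf("sim_%d", seq_len(n))
  r1 <- tibble(name = name, comment = NA_character_,
               sequence = seq1, quality = qual1)
  r2 <- tibble(name = name, comment = NA_character_,
               sequence = seq2, quality = qual2)
  truth <- tibble(
    pair = seq_len(n),
    fragment = fragment,
    insert_size = insert,
    adapter_bases_r1 = as.integer(adapter_bases_r1),
    adapter_bases_r2 = as.integer(adapter_bases_r2),
    n_errors_r1 = e1$n_err,
    n_errors_r2 = e2$n_err,
    is_duplicate = is_dup,
    source_index = source_idx,
    polyg = polyg,
    umi = umi)
  structure(list(r1 = r1, r2 = r2, truth = truth, config = config),
            class = "sim_reads")
}

#' Expected summary metrics from a simulation's ground truth
#'
#' Closed-form expectations over the `truth` table, used as oracles when
#' validating pipeline estimates against planted values.
#'
#' @param truth the `truth` tibble of a [simulate_reads()] result
#' @return list with `duplication_rate`, `insert_histogram` (tibble
#'   `insert_size`, `n`), `adapter_base_count` (planted adapter bases over
#'   both mates), and `error_count`
#' @export
truth_metrics <- function(truth) {
  list(
    duplication_rate = mean(truth$is_duplicate),
    insert_histogram = dplyr::count(truth, .data$insert_size),
    adapter_base_count = sum(truth$adapter_bases_r1) +
      sum(truth$adapter_bases_r2),
    error_count = sum(truth$n_errors_r1) + sum(truth$n_errors_r2)
  )
}

#' @export
print.sim_reads <- function(x, ...) {
  cat(sprintf("<sim_reads> %d pairs, read length %d, seed %d\n",
              nrow(x$truth), x$config$read_len, x$config$seed))
  invisible(x)
}
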