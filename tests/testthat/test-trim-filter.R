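mk_read <- function(seq, qual = strrep("I", nchar(seq)), name = "r") {
  tibble::tibble(name = name, comment = NA_character_, sequence = seq,
                 quality = qual)
}

test_that("global trimming removes exactly the requested bases", {
  r <- mk_read("ACGTAC", "ABCDEF")
  out <- trim_global(r, front = 1L, tail = 2L)
  expect_equal(out$sequence, "CGT")
  expect_equal(out$quality, "BCD")
  expect_identical(trim_global(r, 0L, 0L), r)
  # over-trimming yields an empty read, not an error
  short <- trim_global(mk_read("ACGTA"), front = 3L, tail = 3L)
  expect_equal(short$sequence, "")
  expect_equal(short$quality, "")
  expect_error(trim_global(r, front = -1L), "non-negative")
})

test_that("window cuts match a brute-force window scan in all modes", {
  q40 <- intToUtf8(rep(40 + 33, 7))
  r <- mk_read(strrep("A", 7), q40)
  for (mode in c("front", "tail", "right")) {
    expect_equal(cut_by_window(r, mode, 4L, 20)$quality, q40)
  }
  # all-Q2 read collapses to empty in front mode
  q2 <- intToUtf8(rep(2 + 33, 7))
  expect_equal(cut_by_window(mk_read(strrep("A", 7), q2), "front", 4L,
                             20)$sequence, "")

  # mixed-quality profile: verify against the oracle scan
  qmix <- intToUtf8(c(40, 40, 40, 2, 2, 2, 2) + 33)
  rmix <- mk_read(strrep("A", 7), qmix)
  expect_equal(cut_by_window(rmix, "right", 4L, 20)$quality,
               oracle_window_cut(qmix, "right", 4L, 20))

  set.seed(31)
  for (i in 1:60) {
    len <- sample(1:40, 1)
    qual <- intToUtf8(sample(2:40, len, replace = TRUE) + 33L)
    r <- mk_read(strrep("A", len), qual)
    for (mode in c("front", "tail", "right")) {
      w <- sample(1:6, 1)
      th <- sample(5:35, 1)
      expect_equal(cut_by_window(r, mode, w, th)$quality,
                   oracle_window_cut(qual, mode, w, th),
                   info = sprintf("mode=%s w=%d th=%d qual=%s", mode, w, th,
                                  qual))
    }
  }
})

test_that("polyG trimming removes exactly the planted 3' runs", {
  r <- mk_read(paste0("ACTT", strrep("G", 12)))
  expect_equal(trim_polyx(r, "G", 10L)$sequence, "ACTT")
  expect_equal(trim_polyx(mk_read(paste0("ACGT", strrep("G", 12))), "G",
                          10L, exact = TRUE)$sequence, "ACGT")
  expect_equal(trim_polyx(mk_read("ACGTGGG"), "G", 10L)$sequence, "ACGTGGG")

  # planted runs of 5..30: exactly those >= min_len removed (error-free runs)
  set.seed(32)
  for (run in seq(5, 30, by = 5)) {
    stem <- paste(sample(c("A", "C", "T"), 40, replace = TRUE),
                  collapse = "")
    r <- mk_read(paste0(stem, strrep("G", run)))
    out <- trim_polyx(r, "G", 10L, exact = TRUE)
    if (run >= 10) expect_equal(out$sequence, stem)
    else expect_equal(out$sequence, r$sequence)
  }
  # mismatch tolerance: 1 error per 8 bases of run still trims through
  seqs <- paste0("ACACAC", strrep("G", 7), "T", strrep("G", 8))
  expect_equal(trim_polyx(mk_read(seqs), "G", 10L)$sequence, "ACACAC")
  # exact mode stops at the interrupting T; the 8-base run is under min_len
  expect_equal(trim_polyx(mk_read(seqs), "G", 10L, exact = TRUE)$sequence,
               seqs)
  # polyX: any homopolymer qualifies
  expect_equal(trim_polyx(mk_read(paste0("ACGT", strrep("T", 11))), "any",
                          10L)$sequence, "ACG") # terminal T of ACGT joins run
})

test_that("adapter-by-sequence trimming finds planted adapters", {
  adapter <- "AGATCGGAAGAGC"
  r <- mk_read(paste0("ACGTACGTAC", adapter))
  out <- trim_adapter_by_sequence(r, adapter)
  expect_equal(out$reads$sequence, "ACGTACGTAC")
  expect_equal(out$trimmed, 13L)

  clean <- mk_read("ACGTTTTACCACTGTGATT")
  out2 <- trim_adapter_by_sequence(clean, adapter)
  expect_equal(out2$trimmed, 0L)
  expect_equal(out2$reads$sequence, clean$sequence)

  # planted at known positions with 1% base error: >= 99% of adapter bases go
  sim <- simulate_reads(sim_config(seed = 33, n_pairs = 5000,
                                   insert_mean = 100, insert_sd = 10,
                                   read_len = 150, error_rate = 0.01))
  tr <- trim_adapter_by_sequence(sim$r1, sim$config$adapter_r1)
  kept_len <- nchar(tr$reads$sequence)
  planted <- sim$truth$adapter_bases_r1
  # adapter bases remaining = read extent past the fragment, capped at planted
  remaining <- pmax(0L, pmin(kept_len - sim$truth$insert_size, planted))
  expect_gt(1 - sum(remaining) / sum(planted), 0.99)
})

test_that("filter verdicts agree with a direct-counting oracle", {
  # 41 of 100 bases below Q15 at threshold 0.40 -> low_quality
  qual <- intToUtf8(c(rep(10, 41), rep(30, 59)) + 33L)
  r <- mk_read(strrep("A", 100), qual)
  expect_equal(as.character(evaluate_filters(r)), "low_quality")
  # exactly at the threshold passes (strict inequality)
  qual2 <- intToUtf8(c(rep(10, 40), rep(30, 60)) + 33L)
  expect_equal(as.character(evaluate_filters(mk_read(strrep("A", 100), qual2))),
               "pass")
  expect_equal(as.character(evaluate_filters(mk_read("ACGNNACGTACGTACG"))),
               "pass") # 2 N <= 5

  set.seed(34)
  for (i in 1:50) {
    len <- sample(c(3:20, 40, 120), 1)
    seq <- paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
                        prob = c(0.22, 0.22, 0.22, 0.22, 0.12)),
                 collapse = "")
    qual <- intToUtf8(sample(2:40, len, replace = TRUE) + 33L)
    cfg <- filter_config(qualified_phred = 15L,
                         max_unqualified_fraction = 0.4,
                         max_n_count = 2L, min_length = 10L,
                         max_length = 100L)
    got <- as.character(evaluate_filters(mk_read(seq, qual), cfg))
    want <- oracle_filter(seq, qual, 15, 0.4, 2, 10, 100)
    expect_equal(got, want, info = paste(seq, qual))
  }
})

test_that("pair verdicts take the first failing check across both mates", {
  short <- mk_read("ACG") # too_short
  lowq <- mk_read(strrep("A", 30), intToUtf8(rep(2 + 33, 30))) # low_quality
  good <- mk_read(strrep("A", 30))
  expect_equal(as.character(evaluate_filters(short, mate = lowq)),
               "low_quality")
  expect_equal(as.character(evaluate_filters(good, mate = short)),
               "too_short")
  expect_equal(as.character(evaluate_filters(good, mate = good)), "pass")
})

test_that("UMI extraction moves bases into both mates' names", {
  r1 <- mk_read("AACCGGTT", name = "p1")
  out <- extract_umi(r1, scheme = "read1", umi_len = 4L)
  expect_equal(out$r1$sequence, "GGTT")
  expect_equal(out$r1$name, "p1:AACC")
  expect_equal(out$umi, "AACC")

  r1 <- mk_read("AAAATTTT", name = "p1")
  r2 <- mk_read("CCCCGGGG", name = "p1")
  out <- extract_umi(r1, r2, scheme = "per_read", umi_len = 4L)
  expect_equal(out$r1$name, "p1:AAAA_CCCC")
  expect_equal(out$r2$name, "p1:AAAA_CCCC")
  expect_equal(out$r1$sequence, "TTTT")
  expect_equal(out$r2$sequence, "GGGG")

  # skip bases are discarded after the UMI
  out <- extract_umi(mk_read("AACCGGTT"), scheme = "read1", umi_len = 2L,
                     skip = 2L)
  expect_equal(out$r1$sequence, "GGTT")
  expect_equal(out$umi, "AA")

  # read shorter than umi_len + skip becomes empty
  out <- extract_umi(mk_read("ACG"), scheme = "read1", umi_len = 4L)
  expect_equal(out$r1$sequence, "")

  # index scheme: UMI from comment, sequences untouched
  r1 <- mk_read("ACGT", name = "p1")
  r1$comment <- "1:N:0:ACGTTT"
  out <- extract_umi(r1, scheme = "index1", umi_len = 0L)
  expect_equal(out$r1$sequence, "ACGT")
  expect_equal(out$r1$name, "p1:ACGTTT")
  r1$comment <- NA_character_
  expect_error(extract_umi(r1, scheme = "index1"), "comment")
})

test_that("planted UMIs are recovered exactly end to end", {
  sim <- simulate_reads(sim_config(seed = 35, n_pairs = 500, umi_len = 8L,
                                   error_rate = 0))
  out <- extract_umi(sim$r1, sim$r2, scheme = "read1", umi_len = 8L)
  expect_identical(out$umi, sim$truth$umi)
  expect_identical(out$r1$name, paste0(sim$r1$name, ":", sim$truth$umi))
})

test_that("trims keep sequence and quality in lockstep", {
  sim <- simulate_reads(sim_config(seed = 36, n_pairs = 200, polyg_rate = 0.3))
  stages <- list(
    function(r) trim_global(r, 3L, 2L),
    function(r) cut_by_window(r, "right", 4L, 25),
    function(r) trim_polyx(r, "G", 10L),
    function(r) trim_adapter_by_sequence(r, "AGATCGGAAGAGC")$reads)
  r <- sim$r1
  for (f in stages) {
    r <- f(r)
    expect_true(all(nchar(r$sequence) == nchar(r$quality)))
  }
})
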