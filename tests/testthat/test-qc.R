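test_that("a two-base read accumulates hand-countable counters", {
  r <- tibble::tibble(name = "r", comment = NA_character_, sequence = "AC",
                      quality = "II") # Q40, Q40
  acc <- qc_accumulate(r)
  expect_equal(unname(acc$base_counts["A", 1]), 1)
  expect_equal(unname(acc$base_counts["C", 2]), 1)
  expect_equal(acc$qual_sum, c(40, 40))
  expect_equal(acc$q30_bases, 2)
  expect_equal(acc$total_bases, 2)
  expect_equal(acc$gc_bases, 1)
})

test_that("the empty accumulator is the merge identity", {
  reads <- random_reads(40, seed = 71)
  acc <- qc_accumulate(reads)
  merged <- qc_merge(qc_empty(), acc)
  expect_equal(merged[names(acc)], acc[names(acc)], ignore_attr = TRUE)
  merged2 <- qc_merge(acc, qc_empty())
  expect_equal(merged2[names(acc)], acc[names(acc)], ignore_attr = TRUE)
})

test_that("sharded accumulation merges to the single-pass result in any order", {
  sim <- simulate_reads(sim_config(seed = 72, n_pairs = 2000, read_len = 80))
  reads <- sim$r1
  whole <- qc_accumulate(reads)
  set.seed(720)
  shard_bounds <- sort(sample(2:1999, 7))
  shards <- split(seq_len(2000),
                  findInterval(seq_len(2000), c(1, shard_bounds)))
  accs <- lapply(shards, function(i) qc_accumulate(reads[i, ]))
  left <- Reduce(qc_merge, accs)
  right <- Reduce(qc_merge, rev(accs))
  for (f in setdiff(names(whole), "")) {
    expect_equal(left[[f]], whole[[f]], info = f)
    expect_equal(right[[f]], whole[[f]], info = f)
  }
  # associativity on a triple
  a <- accs[[1]]; b <- accs[[2]]; c <- accs[[3]]
  x <- qc_merge(a, qc_merge(b, c))
  y <- qc_merge(qc_merge(a, b), c)
  for (f in names(x)) expect_equal(x[[f]], y[[f]], info = f)
})

test_that("every accumulator statistic matches the naive recomputation", {
  reads <- random_reads(300, len = 40, seed = 73)
  # include Ns and ragged lengths
  reads$sequence[1:30] <- sub("^.", "N", reads$sequence[1:30])
  reads$sequence[31:60] <- substr(reads$sequence[31:60], 1, 25)
  reads$quality[31:60] <- substr(reads$quality[31:60], 1, 25)
  acc <- qc_accumulate(reads)
  want <- oracle_qc(reads$sequence, reads$quality)
  expect_equal(unname(acc$base_counts), unname(want$base_counts))
  expect_equal(unname(acc$base_qual_sum), unname(want$base_qual_sum))
  expect_equal(acc$qual_sum, want$qual_sum)
  expect_equal(acc$cycle_count, want$cycle_count)
  expect_equal(acc$total_bases, want$total_bases)
  expect_equal(acc$q20_bases, want$q20)
  expect_equal(acc$q30_bases, want$q30)
  expect_equal(acc$gc_bases, want$gc)
  kt <- kmer_table(acc)
  for (k in ls(want$kmer)) {
    expect_equal(kt$count[kt$kmer == k], get(k, want$kmer), info = k)
  }
  expect_equal(sum(kt$count), sum(unlist(as.list(want$kmer))))
})

test_that("conservation identities hold after any accumulation sequence", {
  reads <- random_reads(150, len = 60, seed = 74)
  acc <- qc_accumulate(reads[1:70, ])
  acc <- qc_accumulate(reads[71:150, ], acc)
  expect_equal(colSums(acc$base_counts), acc$cycle_count)
  expect_equal(sum(acc$cycle_count), acc$total_bases)
  expect_lte(acc$q30_bases, acc$q20_bases)
  expect_lte(acc$q20_bases, acc$total_bases)
})

test_that("quality curves are per-cycle means, flat for constant input", {
  r <- tibble::tibble(name = c("a", "b"), comment = NA_character_,
                      sequence = c("ACGT", "ACGT"),
                      quality = c(intToUtf8(c(30, 30, 30, 30) + 33),
                                  intToUtf8(c(20, 20, 20, 20) + 33)))
  qc <- quality_curves(qc_accumulate(r))
  mean_curve <- qc[qc$base == "mean", ]
  expect_equal(mean_curve$quality, rep(25, 4))

  flat <- random_reads(20, len = 30, seed = 75, q_range = c(40, 40))
  qf <- quality_curves(qc_accumulate(flat))
  expect_true(all(qf$quality[qf$base == "mean"] == 40))
  expect_equal(nrow(quality_curves(qc_empty())), 0L)
})

test_that("per-cycle mean quality tracks the generator's decay profile", {
  cfg <- sim_config(seed = 76, n_pairs = 25000, read_len = 100,
                    q_start = 36, q_end = 30, q_sd = 2, error_rate = 0)
  sim <- simulate_reads(cfg)
  qc <- quality_curves(qc_accumulate(sim$r1))
  mc <- qc[qc$base == "mean", ]
  prof <- 36 + (30 - 36) * (seq_len(100) - 1) / 99
  # clamping at [2,40] is far away, so the analytic mean applies
  expect_lt(max(abs(mc$quality - prof)), 0.1)
})

test_that("content curves are normalized fractions with correct GC", {
  allA <- tibble::tibble(name = "a", comment = NA_character_,
                         sequence = strrep("A", 10),
                         quality = strrep("I", 10))
  cc <- content_curves(qc_accumulate(allA))
  expect_true(all(cc$fraction[cc$base == "A"] == 1))
  expect_true(all(cc$fraction[cc$base %in% c("C", "G", "T", "N", "GC")] == 0))

  reads <- random_reads(400, len = 50, seed = 77)
  cc2 <- content_curves(qc_accumulate(reads))
  sums <- tapply(cc2$fraction[cc2$base %in% c("A", "C", "G", "T", "N")],
                 cc2$cycle[cc2$base %in% c("A", "C", "G", "T", "N")], sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  gc <- cc2[cc2$base == "GC", ]
  cg <- cc2[cc2$base == "C", "fraction"] + cc2[cc2$base == "G", "fraction"]
  expect_equal(gc$fraction, cg$fraction)
})

test_that("planted overrepresented sequences are flagged with cycle hits", {
  set.seed(78)
  motif <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                 collapse = "")
  reads <- random_reads(2000, len = 80, seed = 79)
  plant <- seq_len(600) # 30% of reads
  at <- sample(1:60, 600, replace = TRUE)
  reads$sequence[plant] <- paste0(
    substr(reads$sequence[plant], 1, at - 1), motif,
    substr(reads$sequence[plant], at + 20, 80))
  reads$sequence[plant] <- substr(paste0(reads$sequence[plant],
                                         strrep("A", 80)), 1, 80)
  hits <- detect_overrepresented(reads, lengths = 20L, sampling = 2L)
  expect_true(motif %in% hits$sequence)
  row <- hits[hits$sequence == motif, ]
  ch <- row$cycle_hits[[1]]
  expect_gt(sum(ch), 200)
  expect_true(all(which(ch > 0) <= 61))

  # purely random reads with a high multiplier: nothing flagged
  rnd <- random_reads(1000, len = 60, seed = 80)
  none <- detect_overrepresented(rnd, lengths = c(20L, 40L), sampling = 1L,
                                 multiplier = 100, min_count = 10L)
  expect_equal(nrow(none), 0L)

  empty <- detect_overrepresented(rnd[0, ])
  expect_equal(nrow(empty), 0L)
})
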