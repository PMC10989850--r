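pair_from <- function(s1, s2, name = "p") {
  list(r1 = tibble::tibble(name = name, comment = NA_character_,
                           sequence = s1,
                           quality = strrep("I", nchar(s1))),
       r2 = tibble::tibble(name = name, comment = NA_character_,
                           sequence = s2,
                           quality = strrep("I", nchar(s2))))
}

test_that("a read paired with its exact reverse complement fully overlaps", {
  set.seed(41)
  s1 <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
              collapse = "")
  p <- pair_from(s1, oracle_revcomp(s1))
  ov <- analyze_overlap(p$r1, p$r2)
  expect_true(ov$found)
  expect_equal(ov$offset, 0L)
  expect_equal(ov$overlap_len, 100L)
  expect_equal(ov$mismatches, 0L)
})

test_that("offset arithmetic recovers planted fragment geometry", {
  # 150-base fragment, 100-base reads: offset 50, overlap 50
  sim <- simulate_reads(sim_config(seed = 42, n_pairs = 40,
                                   insert_mean = 150, insert_sd = 0,
                                   read_len = 100, error_rate = 0))
  ov <- analyze_overlap(sim$r1, sim$r2)
  expect_true(all(ov$found & ov$offset == 50L & ov$overlap_len == 50L))

  # 80-base fragment, 100-base reads (read-through): offset -20, overlap 80
  sim2 <- simulate_reads(sim_config(seed = 43, n_pairs = 40,
                                    insert_mean = 80, insert_sd = 0,
                                    read_len = 100, error_rate = 0))
  ov2 <- analyze_overlap(sim2$r1, sim2$r2)
  expect_true(all(ov2$found & ov2$offset == -20L & ov2$overlap_len == 80L))
})

test_that("the accepted offset matches the quadratic all-offsets oracle", {
  sim <- simulate_reads(sim_config(seed = 44, n_pairs = 120,
                                   insert_mean = 160, insert_sd = 60,
                                   read_len = 100, error_rate = 0.01))
  ov <- analyze_overlap(sim$r1, sim$r2)
  for (i in seq_len(nrow(ov))) {
    want <- oracle_overlap(sim$r1$sequence[i], sim$r2$sequence[i])
    expect_equal(ov$found[i], want$found, info = paste("pair", i))
    if (want$found) {
      expect_equal(ov$offset[i], want$offset, info = paste("pair", i))
      expect_equal(ov$overlap_len[i], want$overlap_len)
      expect_equal(ov$mismatches[i], want$mismatches)
    }
  }
})

test_that("mismatch positions index real disagreements in R1 coordinates", {
  set.seed(45)
  frag <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                collapse = "")
  s1 <- substr(frag, 1, 100)
  s2 <- oracle_revcomp(substr(frag, 21, 120))
  # plant one disagreement at R1 position 60 (inside the 21..100 overlap)
  substr(s1, 60, 60) <- setdiff(c("A", "C", "G", "T"),
                                substr(s1, 60, 60))[1]
  p <- pair_from(s1, s2)
  ov <- analyze_overlap(p$r1, p$r2)
  expect_true(ov$found)
  expect_equal(ov$mismatch_positions[[1]], 60L)
})

test_that("read-through clipping removes exactly the overhang", {
  sim <- simulate_reads(sim_config(seed = 46, n_pairs = 60,
                                   insert_mean = 80, insert_sd = 0,
                                   read_len = 100, error_rate = 0))
  ov <- analyze_overlap(sim$r1, sim$r2)
  cl <- clip_adapters_from_overlap(sim$r1, sim$r2, ov)
  expect_true(all(nchar(cl$r1$sequence) == 80L))
  expect_identical(cl$r1$sequence, sim$truth$fragment)
  expect_identical(cl$r2$sequence,
                   as.character(reverse_complement(sim$truth$fragment)))
  expect_true(all(cl$clipped_bases == 40L))

  # non-negative offsets are a no-op by contract
  sim2 <- simulate_reads(sim_config(seed = 47, n_pairs = 30,
                                    insert_mean = 150, insert_sd = 0,
                                    read_len = 100, error_rate = 0))
  ov2 <- analyze_overlap(sim2$r1, sim2$r2)
  cl2 <- clip_adapters_from_overlap(sim2$r1, sim2$r2, ov2)
  expect_identical(cl2$r1, sim2$r1)
  expect_identical(cl2$r2, sim2$r2)
  expect_true(all(cl2$clipped_bases == 0L))
})

test_that("correction follows the quality-asymmetry rule exactly", {
  set.seed(48)
  frag <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                collapse = "")
  s1 <- frag
  s2 <- oracle_revcomp(frag)
  # disagreement at position 10: R1 Q40 vs R2 Q8 -> R2 side corrected
  bad1 <- s1
  substr(bad1, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                  substr(s1, 10, 10))[1]
  q1 <- strrep(intToUtf8(40 + 33), 100)
  q2 <- strrep(intToUtf8(40 + 33), 100)
  # the R2 base aligned to R1 position 10 sits at original position 91
  substr(q2, 91, 91) <- intToUtf8(8 + 33)
  r1 <- tibble::tibble(name = "p", comment = NA_character_, sequence = s1,
                       quality = q1)
  bad2 <- s2
  substr(bad2, 91, 91) <- setdiff(c("A", "C", "G", "T"),
                                  substr(s2, 91, 91))[1]
  r2 <- tibble::tibble(name = "p", comment = NA_character_, sequence = bad2,
                       quality = q2)
  ov <- analyze_overlap(r1, r2)
  co <- correct_bases(r1, r2, ov, high_q = 30, low_q = 15)
  expect_equal(co$corrected, 1L)
  expect_equal(co$r2$sequence, s2) # restored to the true fragment base
  expect_equal(substr(co$r2$quality, 91, 91), intToUtf8(40 + 33))
  expect_equal(co$r1$sequence, s1) # high-quality side untouched

  # symmetric qualities: no correction
  q2_sym <- strrep(intToUtf8(20 + 33), 100)
  q1_sym <- strrep(intToUtf8(20 + 33), 100)
  r1s <- r1; r1s$quality <- q1_sym
  r2s <- r2; r2s$quality <- q2_sym
  ovs <- analyze_overlap(r1s, r2s)
  cos <- correct_bases(r1s, r2s, ovs)
  expect_equal(cos$corrected, 0L)
  expect_identical(cos$r1, r1s)
  expect_identical(cos$r2, r2s)
})

test_that("correction never touches bases outside the overlap", {
  sim <- simulate_reads(sim_config(seed = 49, n_pairs = 80,
                                   insert_mean = 150, insert_sd = 10,
                                   read_len = 100, error_rate = 0.02,
                                   q_sd = 8))
  ov <- analyze_overlap(sim$r1, sim$r2)
  co <- correct_bases(sim$r1, sim$r2, ov)
  for (i in which(ov$found & ov$offset > 0)) {
    o <- ov$offset[i]
    expect_equal(substr(co$r1$sequence[i], 1, o),
                 substr(sim$r1$sequence[i], 1, o))
  }
})

test_that("merging reconstructs the fragment and respects quality ties", {
  sim <- simulate_reads(sim_config(seed = 50, n_pairs = 60,
                                   insert_mean = 150, insert_sd = 0,
                                   read_len = 100, error_rate = 0))
  ov <- analyze_overlap(sim$r1, sim$r2)
  m <- merge_pairs(sim$r1, sim$r2, ov)
  expect_identical(m$sequence, sim$truth$fragment)
  expect_true(all(nchar(m$sequence) == 150L))
  expect_equal(m$comment, rep("merged_100_100", 60))

  # full overlap of identical content: merged equals r1
  set.seed(51)
  s1 <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
              collapse = "")
  p <- pair_from(s1, oracle_revcomp(s1))
  m2 <- merge_pairs(p$r1, p$r2, analyze_overlap(p$r1, p$r2))
  expect_equal(m2$sequence, s1)

  # disagreement with Q40 (R1) vs Q10 (R2): merged base is R1's
  p3 <- pair_from(s1, oracle_revcomp(s1))
  alt <- setdiff(c("A", "C", "G", "T"), substr(s1, 40, 40))[1]
  s2alt <- oracle_revcomp(paste0(substr(s1, 1, 39), alt,
                                 substr(s1, 41, 80)))
  p3$r2$sequence <- s2alt
  p3$r2$quality <- strrep(intToUtf8(10 + 33), 80)
  m3 <- merge_pairs(p3$r1, p3$r2, analyze_overlap(p3$r1, p3$r2))
  expect_equal(substr(m3$sequence, 40, 40), substr(s1, 40, 40))
})

test_that("insert sizes follow the offset arithmetic and unknown tally", {
  ov <- tibble::tibble(found = c(TRUE, TRUE, FALSE),
                       offset = c(50L, -20L, NA),
                       overlap_len = c(100L, 80L, 0L),
                       mismatches = c(0L, 0L, NA))
  h <- insert_size_histogram(ov, len2 = 100L)
  expect_equal(h$unknown, 1L)
  expect_equal(sort(h$histogram$insert_size), c(80L, 150L))
  expect_equal(sum(h$histogram$n) + h$unknown, 3L)
})

test_that("insert-size histogram recovers the planted distribution", {
  # insert mean chosen below the len1 + len2 - min_overlap = 270 estimable
  # ceiling so the distribution mode itself is recoverable
  sim <- simulate_reads(sim_config(seed = 52, n_pairs = 20000,
                                   insert_mean = 220, insert_sd = 30,
                                   read_len = 150, error_rate = 0.001))
  ov <- analyze_overlap(sim$r1, sim$r2)
  h <- insert_size_histogram(ov, 150L)
  est <- h$histogram
  # count-weighted center tracks the truth tally of estimable pairs (the
  # estimable range is capped at len1 + len2 - min_overlap = 270, which
  # truncates the upper tail) and the mode sits in the central region
  center <- sum(est$insert_size * est$n) / sum(est$n)
  truth_est <- sim$truth$insert_size[sim$truth$insert_size >= 30 &
                                       sim$truth$insert_size <= 270]
  expect_lte(abs(center - mean(truth_est)), 1)
  expect_lte(abs(est$insert_size[which.max(est$n)] - 220L), 10L)
  # unknown fraction matches the share of inserts too long to overlap
  expect_lt(abs(h$unknown / 20000 -
                  mean(sim$truth$insert_size > 2 * 150 - 30)), 0.02)
})

test_that("merged length equals the recorded insert size whenever found", {
  sim <- simulate_reads(sim_config(seed = 53, n_pairs = 500,
                                   insert_mean = 150, insert_sd = 40,
                                   read_len = 100, error_rate = 0))
  ov <- analyze_overlap(sim$r1, sim$r2)
  m <- merge_pairs(sim$r1, sim$r2, ov)
  ins <- ifelse(ov$offset >= 0L, ov$offset + 100L, ov$overlap_len)
  found <- which(ov$found)
  expect_equal(nchar(m$sequence[found]), ins[found])
})
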