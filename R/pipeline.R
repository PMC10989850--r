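#' Pipeline configuration
#'
#' All tunables of the preprocessing pipeline in one object. Trimming
#' stages apply in a fixed order: UMI extraction, global trim, polyG/polyX
#' trim, window quality cuts, overlap-based adapter clipping and base
#' correction (paired-end), adapter-by-sequence trimming, then read
#' filters; deduplication runs at the in-order reassembly point so that
#' which copy of a duplicate survives never depends on worker scheduling.
#'
#' @param pack_capacity reads per pack (the routing/reassembly unit)
#' @param workers worker count; results are byte-identical for any value
#' @param reads_to_process cap on input records (`Inf` = all)
#' @param trim_front1,trim_tail1,trim_front2,trim_tail2 global trim bases
#' @param cut_front,cut_tail,cut_right enable sliding-window cuts
#' @param cut_window_size,cut_mean_quality window size and mean-Phred
#'   threshold for the window cuts
#' @param trim_poly_g,poly_g_min_len polyG artifact trimming of 3' tails
#' @param trim_poly_x,poly_x_min_len polyX (any homopolymer) trimming
#' @param adapter_r1,adapter_r2 adapter sequences for trimming by sequence
#'   (`NULL` = none)
#' @param adapter_mismatch_fraction mismatch tolerance of adapter matching
#' @param disable_adapter_trimming turn off all adapter trimming
#' @param umi,umi_loc,umi_len,umi_skip UMI extraction (see [extract_umi()])
#' @param overlap_min,overlap_max_mismatch,overlap_mismatch_fraction
#'   overlap-analysis acceptance thresholds (see [analyze_overlap()])
#' @param correction,correction_high_q,correction_low_q overlap-based base
#'   correction and its quality-asymmetry thresholds
#' @param merge,include_unmerged merge overlapping pairs; keep unmerged
#'   pairs in the normal outputs
#' @param filter a [filter_config()]
#' @param disable_quality_filtering,disable_length_filtering switch off the
#'   corresponding filter rules
#' @param dedup drop duplicate reads (first occurrence kept); without it
#'   duplicates are only counted for the report
#' @param dedup_B,dedup_L bloom-filter geometry (see [dedup_index()])
#' @param dedup_pre_trim key duplicates on the pre-trim sequence instead of
#'   the post-trim default
#' @param overrepresentation,overrep_sampling overrepresented-sequence
#'   analysis of sampled reads
#' @param gzip_level compression level for gzip outputs
#' @return a `scrub_config` list
#' @export
scrub_config <- function(pack_capacity = 1000L, workers = 1L,
                         reads_to_process = Inf,
                         trim_front1 = 0L, trim_tail1 = 0L,
                         trim_front2 = 0L, trim_tail2 = 0L,
                         cut_front = FALSE, cut_tail = FALSE,
                         cut_right = FALSE,
                         cut_window_size = 4L, cut_mean_quality = 20,
                         trim_poly_g = FALSE, poly_g_min_len = 10L,
                         trim_poly_x = FALSE, poly_x_min_len = 10L,
                         adapter_r1 = NULL, adapter_r2 = NULL,
                         adapter_mismatch_fraction = 0.2,
                         disable_adapter_trimming = FALSE,
                         umi = FALSE, umi_loc = "read1", umi_len = 0L,
                         umi_skip = 0L,
                         overlap_min = 30L, overlap_max_mismatch = 5L,
                         overlap_mismatch_fraction = 0.2,
                         correction = TRUE, correction_high_q = 30L,
                         correction_low_q = 15L,
                         merge = FALSE, include_unmerged = TRUE,
                         filter = filter_config(),
                         disable_quality_filtering = FALSE,
                         disable_length_filtering = FALSE,
                         dedup = FALSE, dedup_B = 3L, dedup_L = 2^26,
                         dedup_pre_trim = FALSE,
                         overrepresentation = FALSE, overrep_sampling = 20L,
                         gzip_level = 4L) {
  cfg <- as.list(environment())
  if (cfg$pack_capacity < 1L) abort("pack_capacity must be >= 1")
  if (cfg$workers < 1L) abort("workers must be >= 1")
  stopifnot(inherits(cfg$filter, "filter_config"))
  structure(cfg, class = "scrub_config")
}

effective_filter <- function(cfg) {
  f <- cfg$filter
  if (cfg$disable_quality_filtering) {
    f$max_unqualified_fraction <- 1
    f$max_n_count <- .Machine$integer.max
  }
  if (cfg$disable_length_filtering) {
    f$min_length <- 0L
    f$max_length <- 0L
  }
  f
}

# Pure per-pack transform: everything except dedup and output writing.
# Returns the pack's trimmed reads, verdicts, dedup keys, and mergeable
# statistics; identical input packs give identical results regardless of
# which worker runs them.
process_pack <- function(p1, p2, cfg) {
  paired <- !is.null(p2)
  pre1 <- qc_accumulate(p1)
  pre2 <- if (paired) qc_accumulate(p2) else NULL
  pre_key <- if (cfg$dedup_pre_trim) {
    if (paired) pair_key(p1$sequence, p2$sequence) else p1$sequence
  } else NULL

  if (cfg$umi && cfg$umi_len > 0L) {
    u <- extract_umi(p1, if (paired) p2 else NULL, scheme = cfg$umi_loc,
                     umi_len = cfg$umi_len, skip = cfg$umi_skip)
    p1 <- u$r1
    if (paired) p2 <- u$r2
  }
  p1 <- trim_global(p1, cfg$trim_front1, cfg$trim_tail1)
  if (paired) p2 <- trim_global(p2, cfg$trim_front2, cfg$trim_tail2)
  if (cfg$trim_poly_g) {
    p1 <- trim_polyx(p1, "G", cfg$poly_g_min_len)
    if (paired) p2 <- trim_polyx(p2, "G", cfg$poly_g_min_len)
  }
  if (cfg$trim_poly_x) {
    p1 <- trim_polyx(p1, "any", cfg$poly_x_min_len)
    if (paired) p2 <- trim_polyx(p2, "any", cfg$poly_x_min_len)
  }
  for (mode in c("front", "tail", "right")) {
    if (isTRUE(cfg[[paste0("cut_", mode)]])) {
      p1 <- cut_by_window(p1, mode, cfg$cut_window_size, cfg$cut_mean_quality)
      if (paired) {
        p2 <- cut_by_window(p2, mode, cfg$cut_window_size,
                            cfg$cut_mean_quality)
      }
    }
  }

  clipped_bases <- 0
  corrected <- 0
  ov <- NULL
  ins <- NULL
  merged <- NULL
  if (paired) {
    nonempty <- nchar(p1$sequence) > 0L & nchar(p2$sequence) > 0L
    ov <- tibble(found = rep(FALSE, nrow(p1)), offset = NA_integer_,
                 overlap_len = 0L, mismatches = NA_integer_,
                 mismatch_positions = list(integer()))
    if (any(nonempty)) {
      ov[nonempty, c("found", "offset", "overlap_len", "mismatches",
                     "mismatch_positions")] <-
        analyze_overlap(p1[nonempty, ], p2[nonempty, ], cfg$overlap_min,
                        cfg$overlap_max_mismatch,
                        cfg$overlap_mismatch_fraction)
    }
    ins <- insert_size_histogram(ov, nchar(p2$sequence))
    if (!cfg$disable_adapter_trimming) {
      cl <- clip_adapters_from_overlap(p1, p2, ov)
      p1 <- cl$r1
      p2 <- cl$r2
      clipped_bases <- sum(cl$clipped_bases)
      # clipped pairs now start at the fragment boundary: their overlap
      # geometry in the new coordinates is a full overlap at offset 0
      neg <- ov$found & !is.na(ov$offset) & ov$offset < 0L
      if (any(neg)) {
        ov$offset[neg] <- 0L
        ov$overlap_len[neg] <- pmin(nchar(p1$sequence),
                                    nchar(p2$sequence))[neg]
      }
    }
    if (cfg$correction) {
      co <- correct_bases(p1, p2, ov, cfg$correction_high_q,
                          cfg$correction_low_q)
      p1 <- co$r1
      p2 <- co$r2
      corrected <- sum(co$corrected)
    }
  }
  adapter_bases <- 0
  if (!cfg$disable_adapter_trimming) {
    if (!is.null(cfg$adapter_r1)) {
      tr <- trim_adapter_by_sequence(p1, cfg$adapter_r1,
                                     cfg$adapter_mismatch_fraction)
      p1 <- tr$reads
      adapter_bases <- adapter_bases + sum(tr$trimmed)
    }
    if (paired && !is.null(cfg$adapter_r2)) {
      tr <- trim_adapter_by_sequence(p2, cfg$adapter_r2,
                                     cfg$adapter_mismatch_fraction)
      p2 <- tr$reads
      adapter_bases <- adapter_bases + sum(tr$trimmed)
    }
  }
  if (paired && cfg$merge) {
    merged <- merge_pairs(p1, p2, ov)
  }

  verdict <- evaluate_filters(p1, effective_filter(cfg),
                              mate = if (paired) p2 else NULL)
  keys <- if (!is.null(pre_key)) pre_key
          else if (paired) pair_key(p1$sequence, p2$sequence)
          else p1$sequence

  list(p1 = p1, p2 = p2, merged = merged, verdict = verdict, keys = keys,
       pre1 = pre1, pre2 = pre2, insert = ins,
       clipped_bases = clipped_bases, corrected = corrected,
       adapter_bases = adapter_bases)
}

as_reads <- function(x, n_max = Inf) {
  if (is.character(x)) read_fastq(x, n_max = n_max)
  else {
    r <- as_tibble(x)
    if (is.finite(n_max) && nrow(r) > n_max) r[seq_len(n_max), ] else r
  }
}

#' Run the one-pass preprocessing pipeline
#'
#' Splits the input into fixed-capacity packs, routes each pack to its
#' worker by `pack_index mod workers`, applies the pure per-pack transform
#' (trimming, overlap operations, filtering, statistics), then reassembles
#' packs in ascending index order for deduplication and output. Because
#' routing is deterministic and the per-pack transform is pure, the output
#' files and the report are byte-identical across repeated runs and for
#' any worker count.
#'
#' @param input_r1 read-1 FASTQ path or read tibble
#' @param input_r2 optional read-2 FASTQ path or tibble (paired-end)
#' @param output_r1,output_r2 optional output FASTQ paths (`.gz` for gzip)
#' @param merged_out optional output path for merged reads
#' @param json,html optional report output paths
#' @param config a [scrub_config()]
#' @param report_title title used in the HTML report
#' @return a `scrub_result` with counters, before/after QC accumulators,
#'   insert-size histogram, duplication estimate, and output read tibbles
#' @export
run_pipeline <- function(input_r1, input_r2 = NULL, output_r1 = NULL,
                         output_r2 = NULL, merged_out = NULL, json = NULL,
                         html = NULL, config = scrub_config(),
                         report_title = "seqscrub report") {
  stopifnot(inherits(config, "scrub_config"))
  r1 <- as_reads(input_r1, config$reads_to_process)
  paired <- !is.null(input_r2)
  r2 <- if (paired) as_reads(input_r2, config$reads_to_process) else NULL
  if (paired) check_mate_sync(r1, r2)

  packs1 <- partition_packs(r1, config$pack_capacity)
  packs2 <- if (paired) partition_packs(r2, config$pack_capacity) else NULL
  n_packs <- length(packs1)

  ## worker phase: each worker processes its own packs in index order; the
  ## transform is pure, so this ordering is unobservable in the results
  results <- vector("list", n_packs)
  worker_of <- if (n_packs) assign_worker(0:(n_packs - 1L), config$workers)
               else integer()
  worker_qc1 <- vector("list", config$workers)
  worker_qc2 <- vector("list", config$workers)
  for (w in seq_len(config$workers) - 1L) {
    for (i in which(worker_of == w)) {
      res <- process_pack(packs1[[i]], if (paired) packs2[[i]] else NULL,
                          config)
      worker_qc1[[w + 1L]] <- if (is.null(worker_qc1[[w + 1L]])) res$pre1
                              else qc_merge(worker_qc1[[w + 1L]], res$pre1)
      if (paired) {
        worker_qc2[[w + 1L]] <- if (is.null(worker_qc2[[w + 1L]])) res$pre2
                                else qc_merge(worker_qc2[[w + 1L]], res$pre2)
      }
      res$pre1 <- res$pre2 <- NULL
      results[[i]] <- res
    }
  }
  qc_pre1 <- Reduce(qc_merge, Filter(Negate(is.null), worker_qc1), qc_empty())
  qc_pre2 <- if (paired) {
    Reduce(qc_merge, Filter(Negate(is.null), worker_qc2), qc_empty())
  } else NULL

  ## reassembly phase, strictly in pack-index order: filtering bookkeeping,
  ## dedup (the one order-sensitive stage), and output collection
  index <- dedup_index(B = config$dedup_B, L = config$dedup_L)
  out1 <- list(); out2 <- list(); outm <- list()
  verdicts <- factor(character(), levels = filter_statuses)
  insert_hist <- list()
  insert_unknown <- 0
  clipped_bases <- 0; corrected <- 0; adapter_bases <- 0
  for (i in seq_len(n_packs)) {
    res <- results[[i]]
    v <- res$verdict
    pass <- v == "pass"
    dup <- rep(FALSE, length(v))
    if (any(pass)) dup[pass] <- dedup_check(index, res$keys[pass])
    if (config$dedup) {
      v[pass & dup] <- "duplicate"
      pass <- v == "pass"
    }
    verdicts <- c(verdicts, v)
    if (!is.null(res$insert)) {
      insert_hist[[i]] <- res$insert$histogram
      insert_unknown <- insert_unknown + res$insert$unknown
    }
    clipped_bases <- clipped_bases + res$clipped_bases
    corrected <- corrected + res$corrected
    adapter_bases <- adapter_bases + res$adapter_bases
    if (config$merge) {
      mergeable <- pass & !is.na(res$merged$sequence)
      outm[[i]] <- res$merged[mergeable, ]
      if (config$include_unmerged) {
        out1[[i]] <- res$p1[pass & !mergeable, ]
        if (paired) out2[[i]] <- res$p2[pass & !mergeable, ]
      }
    } else {
      out1[[i]] <- res$p1[pass, ]
      if (paired) out2[[i]] <- res$p2[pass, ]
    }
    results[i] <- list(NULL)
  }
  drop_pack_attr <- function(x) {
    if (!is.null(x)) attr(x, "pack_index") <- NULL
    x
  }
  out1 <- drop_pack_attr(bind_rows(out1))
  out2 <- if (paired) drop_pack_attr(bind_rows(out2)) else NULL
  outm <- if (config$merge) drop_pack_attr(bind_rows(outm)) else NULL

  qc_post <- qc_empty()
  if (nrow(out1)) qc_post <- qc_merge(qc_post, qc_accumulate(out1))
  if (paired && nrow(out2)) qc_post <- qc_merge(qc_post, qc_accumulate(out2))
  if (!is.null(outm) && nrow(outm)) {
    qc_post <- qc_merge(qc_post, qc_accumulate(outm))
  }

  overrep <- if (config$overrepresentation) {
    detect_overrepresented(r1, sampling = config$overrep_sampling)
  } else NULL

  hist <- if (length(insert_hist)) {
    bind_rows(insert_hist) |>
      group_by(.data$insert_size) |>
      summarise(n = sum(.data$n), .groups = "drop") |>
      arrange(.data$insert_size)
  } else tibble(insert_size = integer(), n = integer())

  units <- length(verdicts) # pairs for paired-end, reads for single-end
  filter_counts <- table(verdicts)
  st <- dedup_state(index)
  result <- structure(list(
    paired = paired,
    units_in = units,
    reads_in = units * (1L + paired),
    units_out = sum(verdicts == "pass"),
    records_written = nrow(out1) + (if (paired) nrow(out2) else 0L) +
      (if (is.null(outm)) 0L else nrow(outm)),
    merged_pairs = if (is.null(outm)) 0L else nrow(outm),
    filter_counts = filter_counts,
    duplication = list(
      rate = if (st$reads_seen > 0) duplication_rate(index) else 0,
      raw_rate = if (st$reads_seen > 0) duplication_rate(index, FALSE) else 0,
      state = st),
    insert_size = list(histogram = hist, unknown = insert_unknown),
    clipped_adapter_bases = clipped_bases,
    trimmed_adapter_bases = adapter_bases,
    corrected_bases = corrected,
    qc_pre1 = qc_pre1, qc_pre2 = qc_pre2, qc_post = qc_post,
    overrepresented = overrep,
    out1 = out1, out2 = out2, merged = outm,
    config = config), class = "scrub_result")

  if (!is.null(output_r1)) {
    write_fastq(out1, output_r1, gzip_level = config$gzip_level)
  }
  if (paired && !is.null(output_r2)) {
    write_fastq(out2, output_r2, gzip_level = config$gzip_level)
  }
  if (!is.null(merged_out) && !is.null(outm)) {
    write_fastq(outm, merged_out, gzip_level = config$gzip_level)
  }
  if (!is.null(json)) writeLines(build_json(result), json)
  if (!is.null(html)) writeLines(build_html(result, title = report_title), html)
  result
}

#' @export
print.scrub_result <- function(x, ...) {
  cat(sprintf("<scrub_result> %s\n",
              if (x$paired) "paired-end" else "single-end"))
  cat(sprintf("  units in:  %d (%d reads)\n", x$units_in, x$reads_in))
  cat(sprintf("  units out: %d; records written: %d\n", x$units_out,
              x$records_written))
  fc <- x$filter_counts
  fc <- fc[fc > 0 & names(fc) != "pass"]
  if (length(fc)) {
    cat("  filtered: ",
        paste(sprintf("%s=%d", names(fc), as.integer(fc)), collapse = ", "),
        "\n", sep = "")
  }
  cat(sprintf("  duplication rate: %.4f\n", x$duplication$rate))
  if (x$paired) {
    cat(sprintf("  insert size: %d pairs estimated, %d unknown\n",
                sum(x$insert_size$histogram$n), x$insert_size$unknown))
  }
  invisible(x)
}
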