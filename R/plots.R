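#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col labs
#'   scale_y_continuous theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Tidy a pipeline result into per-verdict counts
#'
#' @param x a `scrub_result`
#' @param ... unused
#' @return tibble with columns `verdict`, `n`, `fraction`
#' @export
tidy.scrub_result <- function(x, ...) {
  tibble(verdict = names(x$filter_counts),
         n = as.integer(x$filter_counts),
         fraction = as.integer(x$filter_counts) / max(1L, x$units_in))
}

#' One-row summary of a pipeline run
#'
#' @param x a `scrub_result`
#' @param ... unused
#' @return one-row tibble: unit/read counts, Q20/Q30/GC rates before and
#'   after, duplication rate, adapter bases removed, corrected bases,
#'   merged pairs, insert-size peak
#' @export
glance.scrub_result <- function(x, ...) {
  tb_pre <- x$qc_pre1$total_bases +
    (if (x$paired) x$qc_pre2$total_bases else 0)
  q20_pre <- x$qc_pre1$q20_bases +
    (if (x$paired) x$qc_pre2$q20_bases else 0)
  q30_pre <- x$qc_pre1$q30_bases +
    (if (x$paired) x$qc_pre2$q30_bases else 0)
  gc_pre <- x$qc_pre1$gc_bases + (if (x$paired) x$qc_pre2$gc_bases else 0)
  hist <- x$insert_size$histogram
  tibble(
    paired = x$paired,
    units_in = x$units_in,
    units_out = x$units_out,
    reads_in = x$reads_in,
    records_written = x$records_written,
    bases_before = tb_pre,
    bases_after = x$qc_post$total_bases,
    q20_rate_before = if (tb_pre > 0) q20_pre / tb_pre else 0,
    q30_rate_before = if (tb_pre > 0) q30_pre / tb_pre else 0,
    gc_before = if (tb_pre > 0) gc_pre / tb_pre else 0,
    q20_rate_after = if (x$qc_post$total_bases > 0)
      x$qc_post$q20_bases / x$qc_post$total_bases else 0,
    q30_rate_after = if (x$qc_post$total_bases > 0)
      x$qc_post$q30_bases / x$qc_post$total_bases else 0,
    duplication_rate = x$duplication$rate,
    adapter_bases_removed = x$clipped_adapter_bases +
      x$trimmed_adapter_bases,
    corrected_bases = x$corrected_bases,
    merged_pairs = x$merged_pairs,
    insert_size_peak = if (nrow(hist)) hist$insert_size[which.max(hist$n)]
                       else NA_integer_,
    insert_size_unknown = x$insert_size$unknown)
}

#' Plot per-cycle quality curves
#'
#' @param x a `qc_accumulator` or `scrub_result` (uses the read-1
#'   before-filtering accumulator)
#' @return a ggplot
#' @export
plot_quality_curves <- function(x) {
  acc <- if (inherits(x, "scrub_result")) x$qc_pre1 else x
  ggplot(quality_curves(acc), aes(.data$cycle, .data$quality,
                                  colour = .data$base)) +
    geom_line() +
    labs(x = "cycle", y = "mean Phred quality", colour = NULL) +
    theme_minimal()
}

#' Plot per-cycle base-content curves
#'
#' @param x a `qc_accumulator` or `scrub_result`
#' @return a ggplot
#' @export
plot_content_curves <- function(x) {
  acc <- if (inherits(x, "scrub_result")) x$qc_pre1 else x
  ggplot(content_curves(acc), aes(.data$cycle, .data$fraction,
                                  colour = .data$base)) +
    geom_line() +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = "cycle", y = "fraction of calls", colour = NULL) +
    theme_minimal()
}

#' Plot the insert-size distribution
#'
#' @param x a `scrub_result`
#' @return a ggplot
#' @export
plot_insert_size <- function(x) {
  stopifnot(inherits(x, "scrub_result"))
  hist <- x$insert_size$histogram
  ggplot(hist, aes(.data$insert_size, .data$n)) +
    geom_col(fill = "#1f77b4") +
    labs(x = "estimated insert size (bp)", y = "read pairs",
         subtitle = sprintf("%d pairs with unknown insert size",
                            x$insert_size$unknown)) +
    theme_minimal()
}

#' @rdname plot_quality_curves
#' @param object a `qc_accumulator`
#' @param type `"quality"` or `"content"`
#' @param ... unused
#' @export
autoplot.qc_accumulator <- function(object, type = c("quality", "content"),
                                    ...) {
  type <- match.arg(type)
  if (type == "quality") plot_quality_curves(object)
  else plot_content_curves(object)
}

#' @rdname plot_quality_curves
#' @export
autoplot.scrub_result <- function(object,
                                  type = c("quality", "content", "insert"),
                                  ...) {
  type <- match.arg(type)
  switch(type,
         quality = plot_quality_curves(object),
         content = plot_content_curves(object),
         insert = plot_insert_size(object))
}
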