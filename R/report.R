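curves_to_list <- function(curves, value_col) {
  # tidy curve tibble -> named list of per-cycle numeric vectors
  split(curves[[value_col]], curves$base)[unique(curves$base)]
}

qc_block <- function(acc) {
  qc <- quality_curves(acc)
  cc <- content_curves(acc)
  list(
    total_reads = acc$total_reads,
    total_bases = acc$total_bases,
    q20_bases = acc$q20_bases,
    q30_bases = acc$q30_bases,
    q20_rate = if (acc$total_bases > 0) acc$q20_bases / acc$total_bases else 0,
    q30_rate = if (acc$total_bases > 0) acc$q30_bases / acc$total_bases else 0,
    gc_content = if (acc$total_bases > 0) acc$gc_bases / acc$total_bases else 0,
    total_cycles = acc$max_cycles,
    quality_curves = curves_to_list(qc, "quality"),
    content_curves = curves_to_list(cc, "fraction"),
    kmer_count = as.list(setNames(kmer_table(acc)$count, kmer_table(acc)$kmer))
  )
}

#' Assemble the report payload
#'
#' A single source of truth for both report formats: every count comes
#' straight from the pipeline counters and QC accumulators, in a fixed key
#' order so repeated runs serialize identically except for the timestamp.
#'
#' @param result a `scrub_result`
#' @param command optional command-line string recorded in the report
#' @return nested list ready for JSON serialization
#' @export
build_report_payload <- function(result, command = NULL) {
  stopifnot(inherits(result, "scrub_result"))
  fc <- result$filter_counts
  hist <- result$insert_size$histogram
  peak <- if (nrow(hist)) hist$insert_size[which.max(hist$n)] else NA
  overrep <- if (is.null(result$overrepresented)) NULL else {
    purrr::map(seq_len(nrow(result$overrepresented)), function(i) {
      row <- result$overrepresented[i, ]
      list(sequence = row$sequence, count = row$count,
           expected = row$expected,
           cycle_hits = as.numeric(row$cycle_hits[[1]]))
    })
  }
  payload <- list(
    schema_version = "1.0",
    summary = list(
      sequencing = if (result$paired) "paired end" else "single end",
      before_filtering = list(
        total_reads = result$reads_in,
        total_bases = result$qc_pre1$total_bases +
          (if (result$paired) result$qc_pre2$total_bases else 0),
        q20_rate = {
          tb <- result$qc_pre1$total_bases +
            (if (result$paired) result$qc_pre2$total_bases else 0)
          qb <- result$qc_pre1$q20_bases +
            (if (result$paired) result$qc_pre2$q20_bases else 0)
          if (tb > 0) qb / tb else 0
        },
        q30_rate = {
          tb <- result$qc_pre1$total_bases +
            (if (result$paired) result$qc_pre2$total_bases else 0)
          qb <- result$qc_pre1$q30_bases +
            (if (result$paired) result$qc_pre2$q30_bases else 0)
          if (tb > 0) qb / tb else 0
        },
        gc_content = {
          tb <- result$qc_pre1$total_bases +
            (if (result$paired) result$qc_pre2$total_bases else 0)
          gb <- result$qc_pre1$gc_bases +
            (if (result$paired) result$qc_pre2$gc_bases else 0)
          if (tb > 0) gb / tb else 0
        }),
      after_filtering = list(
        total_reads = result$records_written,
        total_bases = result$qc_post$total_bases,
        q20_rate = if (result$qc_post$total_bases > 0)
          result$qc_post$q20_bases / result$qc_post$total_bases else 0,
        q30_rate = if (result$qc_post$total_bases > 0)
          result$qc_post$q30_bases / result$qc_post$total_bases else 0,
        gc_content = if (result$qc_post$total_bases > 0)
          result$qc_post$gc_bases / result$qc_post$total_bases else 0)),
    filtering_result = list(
      passed_filter = as.integer(fc[["pass"]]),
      low_quality = as.integer(fc[["low_quality"]]),
      too_many_N = as.integer(fc[["too_many_N"]]),
      too_short = as.integer(fc[["too_short"]]),
      too_long = as.integer(fc[["too_long"]]),
      duplicate = as.integer(fc[["duplicate"]])),
    duplication = list(rate = result$duplication$rate,
                       raw_rate = result$duplication$raw_rate),
    adapter_cutting = list(
      clipped_by_overlap_bases = result$clipped_adapter_bases,
      trimmed_by_sequence_bases = result$trimmed_adapter_bases,
      adapter_r1 = result$config$adapter_r1,
      adapter_r2 = result$config$adapter_r2),
    correction = list(corrected_bases = result$corrected_bases),
    merging = list(merged_pairs = result$merged_pairs),
    insert_size = list(
      unknown = result$insert_size$unknown,
      peak = peak,
      sizes = hist$insert_size,
      counts = hist$n),
    read1_before_filtering = qc_block(result$qc_pre1),
    read2_before_filtering = if (result$paired) qc_block(result$qc_pre2)
                             else NULL,
    after_filtering = qc_block(result$qc_post),
    overrepresented_sequences = overrep,
    command = command,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  payload
}

#' Serialize the report payload as JSON
#'
#' Numbers are serialized losslessly and keys keep a fixed order, so two
#' runs of the same command produce identical JSON except for the
#' `timestamp` (and `command`) fields.
#'
#' @param result a `scrub_result` or a payload from
#'   [build_report_payload()]
#' @param command optional command-line string recorded in the report
#' @return a JSON string
#' @export
build_json <- function(result, command = NULL) {
  payload <- if (inherits(result, "scrub_result")) {
    build_report_payload(result, command)
  } else result
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                null = "null", na = "null", pretty = TRUE))
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

fmt_num <- function(x, digits = 4) {
  ifelse(is.na(x), "NA", formatC(x, format = "fg", digits = digits))
}

svg_curve_plot <- function(series, width = 640, height = 220, ymin = NULL,
                           ymax = NULL, colors = NULL) {
  # series: named list of numeric vectors (x = index)
  series <- series[vapply(series, length, 1L) > 0]
  if (!length(series)) return("<p>no data</p>")
  all_y <- unlist(series)
  if (is.null(ymin)) ymin <- min(all_y)
  if (is.null(ymax)) ymax <- max(all_y)
  if (ymax - ymin < 1e-12) { ymax <- ymax + 1; ymin <- ymin - 1 }
  xmax <- max(vapply(series, length, 1L))
  pal <- c("#1f77b4", "#d62728", "#2ca02c", "#ff7f0e", "#9467bd", "#111111")
  if (is.null(colors)) colors <- rep_len(pal, length(series))
  pad <- 30
  sx <- function(x) pad + (x - 1) / max(1, xmax - 1) * (width - 2 * pad)
  sy <- function(y) height - pad - (y - ymin) / (ymax - ymin) *
    (height - 2 * pad)
  lines <- purrr::map2(series, colors, function(v, col) {
    pts <- paste(sprintf("%.1f,%.1f", sx(seq_along(v)), sy(v)),
                 collapse = " ")
    sprintf('<polyline fill="none" stroke="%s" stroke-width="1.5" points="%s"></polyline>',
            col, pts)
  })
  legend <- purrr::map2(names(series), seq_along(series), function(nm, i) {
    sprintf('<text x="%d" y="%d" fill="%s" font-size="11">%s</text>',
            as.integer(pad + (i - 1) * 60), 12, colors[i], html_escape(nm))
  })
  sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d"><rect width="%d" height="%d" fill="#fbfbfb"></rect>%s%s<text x="%.0f" y="%d" font-size="10" fill="#555">%s</text><text x="%d" y="%.0f" font-size="10" fill="#555">%s</text></svg>',
          width, height, width, height, width, height,
          paste(unlist(lines), collapse = ""),
          paste(unlist(legend), collapse = ""),
          width / 2, height - 6, "cycle", 2, height / 2,
          fmt_num(ymax, 3))
}

svg_hist_plot <- function(x, y, width = 640, height = 220) {
  if (!length(x)) return("<p>no data</p>")
  pad <- 30
  xmin <- min(x); xmax <- max(x); ymax <- max(y)
  if (xmax == xmin) xmax <- xmin + 1
  sx <- function(v) pad + (v - xmin) / (xmax - xmin) * (width - 2 * pad)
  bars <- sprintf(
    '<rect x="%.1f" y="%.1f" width="%.2f" height="%.1f" fill="#1f77b4"></rect>',
    sx(x), height - pad - y / ymax * (height - 2 * pad),
    max(1, (width - 2 * pad) / (xmax - xmin + 1)),
    y / ymax * (height - 2 * pad))
  sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d"><rect width="%d" height="%d" fill="#fbfbfb"></rect>%s<text x="%.0f" y="%d" font-size="10" fill="#555">insert size (%d..%d)</text></svg>',
          width, height, width, height, width, height,
          paste(bars, collapse = ""), width / 2, height - 6,
          as.integer(xmin), as.integer(xmax))
}

html_table <- function(rows) {
  # rows: named character vector
  cells <- sprintf("<tr><td>%s</td><td>%s</td></tr>",
                   html_escape(names(rows)), html_escape(unname(rows)))
  sprintf('<table class="kv">%s</table>', paste(cells, collapse = ""))
}

#' Render the HTML quality-control report
#'
#' A self-contained single file mirroring the JSON payload: summary and
#' filtering tables plus four plot panels -- per-cycle quality curves,
#' per-cycle base-content curves, insert-size distribution with the
#' unknown category, and the overrepresented-sequence table with per-cycle
#' distributions. Plots are inline SVG; the full JSON payload is embedded
#' in a `<script type="application/json">` block so every displayed number
#' is also machine-readable from the HTML itself.
#'
#' @param result a `scrub_result`
#' @param title report title
#' @param command optional command-line string recorded in the report
#' @return a single HTML string
#' @export
build_html <- function(result, title = "seqscrub report", command = NULL) {
  stopifnot(inherits(result, "scrub_result"))
  payload <- build_report_payload(result, command)
  json <- build_json(payload)

  bf <- payload$summary$before_filtering
  af <- payload$summary$after_filtering
  summary_tbl <- html_table(c(
    "sequencing" = payload$summary$sequencing,
    "reads before filtering" = format(bf$total_reads),
    "bases before filtering" = format(bf$total_bases),
    "Q20 rate before" = fmt_num(bf$q20_rate),
    "Q30 rate before" = fmt_num(bf$q30_rate),
    "GC content before" = fmt_num(bf$gc_content),
    "reads after filtering" = format(af$total_reads),
    "bases after filtering" = format(af$total_bases),
    "Q20 rate after" = fmt_num(af$q20_rate),
    "Q30 rate after" = fmt_num(af$q30_rate),
    "duplication rate" = fmt_num(payload$duplication$rate)))
  fr <- payload$filtering_result
  filter_tbl <- html_table(c(
    "passed filter" = format(fr$passed_filter),
    "low quality" = format(fr$low_quality),
    "too many N" = format(fr$too_many_N),
    "too short" = format(fr$too_short),
    "too long" = format(fr$too_long),
    "duplicate" = format(fr$duplicate)))

  qplot <- svg_curve_plot(payload$read1_before_filtering$quality_curves,
                          ymin = 0, ymax = 42)
  cplot <- svg_curve_plot(payload$read1_before_filtering$content_curves,
                          ymin = 0, ymax = 1)
  ins <- payload$insert_size
  iplot <- if (length(ins$sizes)) {
    paste0(svg_hist_plot(ins$sizes, ins$counts),
           sprintf("<p>%d pairs with unknown insert size (mates not overlapped).</p>",
                   ins$unknown))
  } else {
    sprintf("<p>All %d pairs have unknown insert size: no overlaps were evaluated (overlap analysis disabled, no pairs overlapped, or single-end input).</p>",
            ins$unknown)
  }
  orp <- payload$overrepresented_sequences
  opanel <- if (is.null(orp)) {
    "<p>Overrepresentation analysis was not enabled for this run.</p>"
  } else if (!length(orp)) {
    "<p>No overrepresented sequences detected.</p>"
  } else {
    rows <- purrr::map(orp, function(o) {
      spark <- svg_curve_plot(list(hits = as.numeric(o$cycle_hits)),
                              width = 220, height = 48)
      sprintf("<tr><td class=\"mono\">%s</td><td>%s</td><td>%s</td><td>%s</td></tr>",
              html_escape(o$sequence), format(o$count),
              fmt_num(o$expected, 3), spark)
    })
    sprintf('<table class="kv"><tr><th>sequence</th><th>count</th><th>expected</th><th>per-cycle distribution</th></tr>%s</table>',
            paste(unlist(rows), collapse = ""))
  }

  paste0(
    '<!DOCTYPE html>\n<html xmlns="http://www.w3.org/1999/xhtml"><head>',
    '<meta charset="utf-8"></meta><title>', html_escape(title), '</title>',
    "<style>body{font-family:sans-serif;margin:2em;max-width:900px}",
    "h1{font-size:1.4em}h2{font-size:1.1em;border-bottom:1px solid #ccc}",
    "table.kv{border-collapse:collapse}table.kv td,table.kv th{border:1px solid #ddd;padding:2px 8px;font-size:0.9em}",
    ".mono{font-family:monospace}</style></head><body>",
    "<h1>", html_escape(title), "</h1>",
    '<div id="panel-summary"><h2>Summary</h2>', summary_tbl, "</div>",
    '<div id="panel-filtering"><h2>Filtering result</h2>', filter_tbl,
    "</div>",
    '<div id="panel-quality-curves"><h2>Per-cycle quality curves</h2>',
    qplot, "</div>",
    '<div id="panel-content-curves"><h2>Per-cycle base content curves</h2>',
    cplot, "</div>",
    '<div id="panel-insert-size"><h2>Insert size distribution</h2>', iplot,
    "</div>",
    '<div id="panel-overrepresented"><h2>Overrepresented sequences</h2>',
    opanel, "</div>",
    '<script type="application/json" id="report-data">', json, "</script>",
    "</body></html>")
}
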