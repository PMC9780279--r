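# Machine-readable and graphical reports of a pipeline run.

#' Write an acuity report to disk
#'
#' Writes `report.json` (curve entries, criterion, threshold, per-width RFR
#' tables and decoding summaries), `acuity_curve.csv`, a run log, and - when
#' `plots = TRUE` - an f1-versus-width bar plot and an RFR spatial map. The
#' write is atomic: everything is staged and moved into place on success.
#' JSON output is deterministic, so two runs from the same seed produce
#' byte-identical reports.
#'
#' @param curve An `acuity_curve` from [run_pipeline()].
#' @param out_dir Output directory (created/replaced).
#' @param units Optional `unit_population` for the RFR spatial map.
#' @param plots Render PNG figures.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(curve, out_dir, units = NULL, plots = FALSE) {
  staging <- paste0(out_dir, ".staging")
  if (dir.exists(staging)) unlink(staging, recursive = TRUE)
  dir.create(staging, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(staging, recursive = TRUE), add = TRUE)

  entries <- curve$entries
  if (is.null(entries))
    entries <- data.frame(bar_width = numeric(), f1_mean = numeric(),
                          f1_sd = numeric(), n_units = integer())
  payload <- list(
    criterion = curve$criterion,
    threshold_width = if (is.na(curve$threshold_width %||% NA)) NULL else curve$threshold_width,
    entries = entries,
    rfr = lapply(curve$rfr_tables, function(t) t[, c("unit_id", "rfr", "undefined")]),
    dip_tests = lapply(curve$dip_tests, function(d)
      if (is.null(d)) NULL else d[c("dip_statistic", "p_value", "n")]),
    decoding = lapply(curve$decoding_results, function(d)
      list(f1_mean = d$f1_mean, f1_sd = d$f1_sd,
           f1_per_fold = d$f1_per_fold, confusion = d$confusion,
           config = d$config))
  )
  jsonlite::write_json(payload, file.path(staging, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       null = "null")
  utils::write.csv(entries, file.path(staging, "acuity_curve.csv"),
                   row.names = FALSE)
  writeLines(c(sprintf("widths: %s", paste(entries$bar_width, collapse = ", ")),
               sprintf("units per width: %s", paste(entries$n_units, collapse = ", ")),
               sprintf("threshold: %s", curve$threshold_width %||% NA)),
             file.path(staging, "run_log.txt"))

  if (plots && nrow(entries) > 0) {
    p <- ggplot2::ggplot(entries,
                         ggplot2::aes(x = factor(.data$bar_width), y = .data$f1_mean)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$f1_mean - .data$f1_sd,
                                          ymax = .data$f1_mean + .data$f1_sd),
                             width = 0.2) +
      ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
      ggplot2::labs(x = "bar width (um)", y = "f1 score") +
      ggplot2::ylim(0, 1.05) +
      ggplot2::theme_minimal()
    ggplot2::ggsave(file.path(staging, "f1_vs_width.png"), p,
                    width = 6, height = 4, dpi = 120)
    if (!is.null(units) && length(curve$rfr_tables) > 0) {
      rfr <- curve$rfr_tables[[length(curve$rfr_tables)]]
      df <- merge(units[, c("unit_id", "x", "y")], rfr, by = "unit_id")
      p2 <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                             colour = .data$rfr)) +
        ggplot2::geom_point(size = 3) +
        ggplot2::scale_colour_gradient2(low = "grey40", mid = "white",
                                        high = "dodgerblue", limits = c(-1, 1)) +
        ggplot2::labs(x = "x (um)", y = "y (um)", colour = "RFR") +
        ggplot2::theme_minimal()
      ggplot2::ggsave(file.path(staging, "rfr_map.png"), p2,
                      width = 5, height = 4.5, dpi = 120)
    }
  }

  if (dir.exists(out_dir)) unlink(out_dir, recursive = TRUE)
  if (!file.rename(staging, out_dir))
    stop("write_report: could not move staged report into place", call. = FALSE)
  ok <- TRUE
  invisible(out_dir)
}

#' Read back a report written by [write_report()]
#' @param out_dir Report directory.
#' @return The parsed `report.json` as a list (entries as a data frame).
#' @export
read_report <- function(out_dir) {
  rep <- jsonlite::read_json(file.path(out_dir, "report.json"),
                             simplifyVector = TRUE)
  rep$entries <- as.data.frame(rep$entries, stringsAsFactors = FALSE)
  rep
}

`%||%` <- function(a, b) if (is.null(a)) b else a
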