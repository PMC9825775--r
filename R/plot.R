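#' Plot the extraction/execution timeline of a run
#'
#' Visualises the structured event log: extraction scans and per-cell jobs
#' as horizontal segments over wall-clock time, which makes the
#' producer/consumer interleaving (scan of batch i+1 overlapping batch i's
#' jobs) directly visible.
#'
#' @param run An `scbatch_run` from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_timeline <- function(run) {
  stopifnot(inherits(run, "scbatch_run"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_timeline() requires the ggplot2 package", call. = FALSE)
  ev <- run$events
  t0 <- min(ev$time)
  seg <- function(start_type, end_type, what, id_col) {
    s <- ev[ev$type == start_type, ]
    e <- ev[ev$type == end_type, ]
    key <- function(d) paste(d$batch, d[[id_col]])
    i <- match(key(s), key(e))
    tibble(what = what, lane = paste0(what, " b", s$batch,
                                      ifelse(id_col == "barcode",
                                             paste0(" ", s[[id_col]]), "")),
           start = s$time - t0, end = e$time[i] - t0)
  }
  d <- rbind(seg("scan_start", "scan_end", "scan", "batch"),
             seg("job_start", "job_end", "job", "barcode"))
  ggplot2::ggplot(d, ggplot2::aes(y = lane, yend = lane,
                                  x = start, xend = end, colour = what)) +
    ggplot2::geom_segment(linewidth = 3) +
    ggplot2::labs(x = "seconds since run start", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}
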