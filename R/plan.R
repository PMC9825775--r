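#' Partition barcodes into consecutive extraction batches
#'
#' Each pass over the pooled BAM extracts scBAMs for one batch of barcodes,
#' so a run with `n` accepted barcodes and batch size `B` performs exactly
#' `ceiling(n / B)` passes. The partition preserves order: concatenating the
#' batches reproduces `barcodes` exactly, and every batch except possibly
#' the last has exactly `batch_size` members.
#'
#' @param barcodes Ordered character vector of barcodes (no duplicates).
#' @param batch_size Positive integer.
#' @return An object of class `batch_plan` with elements `barcodes`,
#'   `batch_size` and `batches` (a list of character vectors).
#' @examples
#' plan_batches(c("b1", "b2", "b3", "b4", "b5"), 2)  # sizes 2, 2, 1
#' @export
plan_batches <- function(barcodes, batch_size) {
  if (length(batch_size) != 1L || is.na(batch_size) || batch_size < 1L ||
      batch_size != as.integer(batch_size))
    stop("batch_size must be a positive integer", call. = FALSE)
  batch_size <- as.integer(batch_size)
  barcodes <- as.character(barcodes)
  if (anyDuplicated(barcodes))
    stop("barcodes contain duplicates", call. = FALSE)
  n <- length(barcodes)
  batches <- if (n == 0L) list() else
    unname(split(barcodes, (seq_len(n) - 1L) %/% batch_size))
  structure(list(barcodes = barcodes, batch_size = batch_size,
                 batches = batches),
            class = "batch_plan")
}

#' @export
print.batch_plan <- function(x, ...) {
  cat(sprintf("<batch_plan> %d barcode(s) in %d batch(es) of size <= %d\n",
              length(x$barcodes), length(x$batches), x$batch_size))
  invisible(x)
}

#' Number of extraction passes a plan implies
#' @param plan A [plan_batches()] result.
#' @return Integer batch count, `ceiling(n / batch_size)`.
#' @export
n_batches <- function(plan) length(plan$batches)
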