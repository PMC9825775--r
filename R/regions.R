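#' Parse, validate and merge genomic regions
#'
#' Accepts samtools-style region strings (`"contig:start-end"`, 1-based
#' inclusive; a bare `"contig"` means the whole reference sequence; several
#' regions may be comma-separated or given as a character vector) or the
#' path to a BED file (0-based half-open; converted to 1-based inclusive).
#' Regions are validated against the BAM header, sorted in header contig
#' order, and overlapping or adjacent regions on the same contig are merged,
#' so no downstream record can be selected twice.
#'
#' @param x Region string(s) or a path to a BED file.
#' @param bam Path to the BAM whose header defines valid contigs.
#' @return A tibble with columns `contig`, `start`, `end` (1-based
#'   inclusive), merged and sorted.
#' @examples
#' \dontrun{
#' parse_regions("1:100-200,1:150-300", bam)   # -> one merged region 100-300
#' parse_regions("regions.bed", bam)
#' }
#' @export
parse_regions <- function(x, bam) {
  targets <- bam_targets(bam)
  if (length(x) == 1L && file.exists(x) && !grepl(":", x)) {
    gr <- rtracklayer::import(x, format = "BED")
    df <- tibble(contig = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr),
                 end = GenomicRanges::end(gr))
  } else {
    parts <- unlist(strsplit(x, ",", fixed = TRUE), use.names = FALSE)
    parts <- trimws(parts[nzchar(trimws(parts))])
    if (!length(parts)) stop("no regions given", call. = FALSE)
    df <- do.call(rbind, lapply(parts, parse_region_string, targets = targets))
    df <- as_tibble(df)
  }
  bad <- setdiff(unique(df$contig), names(targets))
  if (length(bad))
    stop("region contig(s) not present in the BAM header: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(df$start < 1L) || any(df$start > df$end))
    stop("invalid region coordinates: start must satisfy 1 <= start <= end",
         call. = FALSE)
  df$end <- pmin(df$end, targets[df$contig])

  gr <- GenomicRanges::GRanges(factor(df$contig, levels = names(targets)),
                               IRanges::IRanges(df$start, df$end))
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr))  # merges adjacent too
  tibble(contig = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr),
         end = GenomicRanges::end(gr))
}

parse_region_string <- function(s, targets) {
  if (grepl(":", s, fixed = TRUE)) {
    m <- regexec("^([^:]+):([0-9]+)-([0-9]+)$", s)
    g <- regmatches(s, m)[[1L]]
    if (length(g) != 4L)
      stop("malformed region string: '", s,
           "' (expected contig:start-end, 1-based inclusive)", call. = FALSE)
    data.frame(contig = g[[2L]], start = as.integer(g[[3L]]),
               end = as.integer(g[[4L]]), stringsAsFactors = FALSE)
  } else {
    if (!s %in% names(targets))
      stop("region contig(s) not present in the BAM header: ", s, call. = FALSE)
    data.frame(contig = s, start = 1L, end = unname(targets[[s]]),
               stringsAsFactors = FALSE)
  }
}

#' Read a barcode acceptance list
#'
#' Reads a `barcodes.tsv`-style file (plain text or gzip; one barcode per
#' line), in file order, skipping blank lines and dropping duplicates while
#' keeping each barcode's first occurrence.
#'
#' @param path Path to the list file.
#' @return Character vector of barcodes in file order.
#' @export
read_barcode_list <- function(path) {
  if (!file.exists(path))
    stop("acceptance list not readable: ", path, call. = FALSE)
  con <- gzfile(path, "rt")  # transparently handles uncompressed text too
  on.exit(close(con), add = TRUE)
  x <- trimws(readLines(con, warn = FALSE))
  x <- x[nzchar(x)]
  x <- x[!duplicated(x)]
  if (!length(x))
    stop("acceptance list contains no barcodes: ", path, call. = FALSE)
  x
}
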