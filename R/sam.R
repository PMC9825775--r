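#' Parse a single SAM-format alignment line
#'
#' Minimal record parser used by [extract_barcode()]: splits the mandatory
#' fields and collects auxiliary tags into a named character vector (tag
#' name -> value, type letter dropped).
#'
#' @param line One SAM alignment line (tab-separated, no trailing newline).
#' @return A list with elements `qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `tags` (named character vector) and `line` (the raw input).
#' @export
parse_sam_record <- function(line) {
  stopifnot(is.character(line), length(line) == 1L)
  f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (length(f) < 11L)
    stop("not a SAM alignment line (fewer than 11 fields): ",
         substr(line, 1, 60), call. = FALSE)
  tags <- character(0)
  if (length(f) > 11L) {
    aux <- f[-(1:11)]
    nm <- substr(aux, 1L, 2L)
    tags <- setNames(substr(aux, 6L, nchar(aux)), nm)
  }
  list(qname = f[[1L]], flag = as.integer(f[[2L]]), rname = f[[3L]],
       pos = as.integer(f[[4L]]), mapq = as.integer(f[[5L]]),
       cigar = f[[6L]], tags = tags, line = line)
}

sam_record_line <- function(record) {
  if (!is.null(record$line)) return(record$line)
  stop("record has no raw line; construct it with parse_sam_record()",
       call. = FALSE)
}

# Verbatim header lines of a BAM, bytes as stored (no @PG appended).
sam_header_lines <- function(bam) {
  out <- suppressWarnings(
    system2(samtools_bin(), c("view", "-H", "--no-PG", shQuote(bam)), stdout = TRUE)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L)
    stop("failed to read header of ", bam, call. = FALSE)
  as.character(out)
}

# Named integer vector of reference sequence lengths from the BAM header.
bam_targets <- function(bam) {
  h <- Rsamtools::scanBamHeader(bam)[[1L]]
  h$targets
}

# Sort order declared in @HD (e.g. "coordinate", "unsorted"); NA if absent.
bam_sort_order <- function(bam) {
  h <- Rsamtools::scanBamHeader(bam)[[1L]]$text
  hd <- h[["@HD"]]
  if (is.null(hd)) return(NA_character_)
  so <- grep("^SO:", hd, value = TRUE)
  if (!length(so)) NA_character_ else sub("^SO:", "", so[[1L]])
}

bam_index_path <- function(bam) {
  cand <- c(paste0(bam, ".bai"), sub("\\.bam$", ".bai", bam))
  hit <- cand[file.exists(cand)]
  if (length(hit)) hit[[1L]] else NULL
}

# Open a text stream of alignment record lines (no header). When `regions`
# is a tibble of merged regions and `fetch = TRUE`, uses the BAI index to
# fetch just those intervals; records spanning two disjoint merged regions
# would be emitted once per region, so callers of the fetch path must
# de-duplicate (see demux_stream).
sam_open_records <- function(bam, regions = NULL, fetch = FALSE) {
  args <- c("view", shQuote(bam))
  if (fetch) {
    stopifnot(!is.null(regions), nrow(regions) > 0L)
    args <- c(args, shQuote(sprintf("%s:%d-%d", regions$contig,
                                    regions$start, regions$end)))
  }
  pipe(paste(samtools_bin(), paste(args, collapse = " ")), "rt")
}

# Reference-aligned span width from a CIGAR string: sum of lengths of
# operations that consume the reference (M, D, N, =, X). 0 for "*".
cigar_ref_width <- function(cigar) {
  w <- integer(length(cigar))
  ok <- !is.na(cigar) & cigar != "*"
  if (any(ok)) {
    m <- gregexpr("\\d+(?=[MDN=X])", cigar[ok], perl = TRUE)
    w[ok] <- vapply(regmatches(cigar[ok], m),
                    function(x) sum(as.integer(x)), integer(1))
  }
  w
}

# Per-line overlap test against merged regions (1-based inclusive).
# Unmapped records never overlap.
lines_overlap_regions <- function(lines, regions) {
  f <- strsplit(lines, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[[2L]]), integer(1))
  rname <- vapply(f, function(x) x[[3L]], character(1))
  pos <- vapply(f, function(x) as.integer(x[[4L]]), integer(1))
  cigar <- vapply(f, function(x) x[[6L]], character(1))
  mapped <- bitwAnd(flag, 4L) == 0L & rname != "*"
  end <- pos + pmax(cigar_ref_width(cigar), 1L) - 1L
  hit <- rep(FALSE, length(lines))
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (mapped & rname == regions$contig[[i]] &
                    pos <= regions$end[[i]] & end >= regions$start[[i]])
  }
  hit
}

# Key identifying one physical record, for de-duplication in the
# index-fetch path.
sam_record_keys <- function(lines) {
  f <- strsplit(lines, "\t", fixed = TRUE)
  vapply(f, function(x) paste(x[[1L]], x[[2L]], x[[3L]], x[[4L]], x[[6L]],
                              sep = "\r"), character(1))
}

# Write header + record lines as a BAM file at `path` (must end in .bam).
write_scbam <- function(header_lines, record_lines, path) {
  stopifnot(grepl("\\.bam$", path))
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam), add = TRUE)
  writeLines(c(header_lines, record_lines), sam)
  dest <- sub("\\.bam$", "", path)
  Rsamtools::asBam(sam, dest, overwrite = TRUE, indexDestination = FALSE)
}
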