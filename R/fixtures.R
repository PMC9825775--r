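#' Describe a synthetic barcoded-BAM fixture
#'
#' The generator emulates the pooled output of a droplet scRNA-seq aligner:
#' a coordinate-sorted BAM whose reads carry cell barcodes in tags or in
#' the read name, with reads from different cells interleaved along the
#' genome (round-robin with jitter) so that batch extraction genuinely has
#' to skip over other cells' records. A configurable fraction of reads is
#' unbarcoded (no tag / no token) or carries the `-` no-barcode sentinel
#' that STARsolo emits for unassigned reads.
#'
#' @param n_barcodes Number of cells.
#' @param reads_per_barcode Reads per cell: a single count or a vector of
#'   length `n_barcodes`.
#' @param barcode_length Barcode length in bases (default 12).
#' @param gem_suffix Append the CellRanger-style `-1` GEM-well suffix.
#' @param encoding Where the barcode lives: `"tag_CB"`, `"tag_CR"`,
#'   `"tag_custom"` (see `tag_name`), `"qname_token"`
#'   (`NAME_BARCODE_UMI`), or `"mixed"` (CB and CR tags plus the QNAME
#'   token, all carrying the same value).
#' @param tag_name Tag used by `encoding = "tag_custom"`.
#' @param n_contigs,contig_length Reference layout.
#' @param unbarcoded_fraction,sentinel_fraction Approximate fractions of
#'   the total record count that carry no barcode / the `-` sentinel;
#'   their sum must be below 1.
#' @param read_length Read length in bases (simple full-match CIGAR).
#' @param seed Random seed; the same spec and seed give a byte-identical
#'   BAM.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_barcodes, reads_per_barcode, barcode_length = 12L,
                         gem_suffix = TRUE,
                         encoding = c("tag_CB", "tag_CR", "tag_custom",
                                      "qname_token", "mixed"),
                         tag_name = "XC", n_contigs = 2L,
                         contig_length = 50000L,
                         unbarcoded_fraction = 0, sentinel_fraction = 0,
                         read_length = 40L, seed = 1L) {
  encoding <- match.arg(encoding)
  stopifnot(n_barcodes >= 1L, all(reads_per_barcode >= 1L),
            length(reads_per_barcode) %in% c(1L, n_barcodes),
            barcode_length >= 4L, n_contigs >= 1L,
            contig_length > 10L * read_length,
            unbarcoded_fraction >= 0, sentinel_fraction >= 0,
            unbarcoded_fraction + sentinel_fraction < 1)
  structure(list(n_barcodes = as.integer(n_barcodes),
                 reads_per_barcode = as.integer(reads_per_barcode),
                 barcode_length = as.integer(barcode_length),
                 gem_suffix = isTRUE(gem_suffix), encoding = encoding,
                 tag_name = tag_name, n_contigs = as.integer(n_contigs),
                 contig_length = as.integer(contig_length),
                 unbarcoded_fraction = unbarcoded_fraction,
                 sentinel_fraction = sentinel_fraction,
                 read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' The barcode specification matching a fixture's encoding
#' @param spec A [fixture_spec()].
#' @return A [barcode_spec()] that recovers the truth barcodes.
#' @export
matching_barcode_spec <- function(spec) {
  switch(spec$encoding,
    tag_CB = barcode_spec("tag", tag_name = "CB"),
    tag_CR = barcode_spec("tag", tag_name = "CR"),
    tag_custom = barcode_spec("tag", tag_name = spec$tag_name),
    qname_token = barcode_spec("qname_token", delimiter = "_",
                               token_index = -2L),
    mixed = barcode_spec("tag", tag_name = "CB")
  )
}

#' Generate a synthetic barcoded BAM with a machine-readable truth table
#'
#' Writes a valid, indexed, coordinate-sorted BAM whose per-record
#' barcodes, positions and order match the returned truth table exactly.
#'
#' @param spec A [fixture_spec()].
#' @param out_bam Output BAM path (`.bam`; a `.bai` index is written
#'   alongside).
#' @param truth_path Optional path for a tab-separated copy of the truth
#'   table.
#' @return An object of class `fixture_truth`: `bam` (path), `reads` (a
#'   tibble in record order with `qname`, `status`, `barcode`, `contig`,
#'   `pos`), `barcodes` (assigned barcodes in first-appearance order),
#'   `per_barcode` (named counts), `n_unbarcoded`, `n_sentinel`, and
#'   `spec`.
#' @export
generate_fixture <- function(spec, out_bam, truth_path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"), grepl("\\.bam$", out_bam))
  if (!dir.exists(dirname(out_bam)))
    dir.create(dirname(out_bam), recursive = TRUE, showWarnings = FALSE)
  if (file.access(dirname(out_bam), 2L) != 0L)
    stop("output path is not writable: ", out_bam, call. = FALSE)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(spec$seed)

  rand_seq <- function(n, len) {
    vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""), character(1))
  }
  barcodes <- unique(rand_seq(spec$n_barcodes * 2L, spec$barcode_length))
  while (length(barcodes) < spec$n_barcodes)
    barcodes <- unique(c(barcodes, rand_seq(spec$n_barcodes, spec$barcode_length)))
  barcodes <- barcodes[seq_len(spec$n_barcodes)]
  if (spec$gem_suffix) barcodes <- paste0(barcodes, "-1")

  rpb <- rep(spec$reads_per_barcode, length.out = spec$n_barcodes)
  n_assigned <- sum(rpb)
  denom <- 1 - spec$unbarcoded_fraction - spec$sentinel_fraction
  n_unbc <- round(spec$unbarcoded_fraction * n_assigned / denom)
  n_sent <- round(spec$sentinel_fraction * n_assigned / denom)
  n_total <- n_assigned + n_unbc + n_sent

  # interleave cells along the genome: occurrence k of every cell lands
  # near slot k (round-robin), jittered so the pattern is not rigid
  owner <- c(rep(barcodes, rpb),
             rep(NA_character_, n_unbc), rep("-", n_sent))
  occ <- c(unlist(lapply(rpb, seq_len), use.names = FALSE),
           runif(n_unbc + n_sent, 0, max(rpb)))
  key <- occ + runif(n_total, 0, 0.9)
  owner <- owner[order(key)]

  # genomic slots: spread across contigs in header order, sorted positions
  per_contig <- diff(round(seq(0, n_total, length.out = spec$n_contigs + 1L)))
  contig <- rep(paste0("chr", seq_len(spec$n_contigs)), per_contig)
  maxpos <- spec$contig_length - spec$read_length
  pos <- unlist(lapply(per_contig, function(k)
    sort(sample(seq_len(maxpos), k, replace = k > maxpos))), use.names = FALSE)

  qbase <- sprintf("R%06d", seq_len(n_total))
  status <- ifelse(is.na(owner), "unbarcoded",
                   ifelse(owner == "-", "sentinel", "assigned"))
  umi <- rand_seq(n_total, 8L)
  qname <- qbase
  uses_qname <- spec$encoding %in% c("qname_token", "mixed")
  if (uses_qname) {
    tok <- ifelse(status == "assigned", owner,
                  ifelse(status == "sentinel", "-", NA))
    qname <- ifelse(status == "unbarcoded", qbase,
                    paste0(qbase, "_", tok, "_", umi))
  }

  tagval <- ifelse(status == "assigned", owner,
                   ifelse(status == "sentinel", "-", NA))
  tagfields <- character(n_total)
  mk <- function(tag) ifelse(is.na(tagval), "",
                             paste0("\t", tag, ":Z:", tagval))
  tagfields <- switch(spec$encoding,
    tag_CB = mk("CB"),
    tag_CR = mk("CR"),
    tag_custom = mk(spec$tag_name),
    qname_token = "",
    mixed = paste0(mk("CB"), mk("CR"))
  )

  seqs <- rand_seq(n_total, spec$read_length)
  qual <- strrep("I", spec$read_length)
  records <- paste0(qname, "\t0\t", contig, "\t", pos, "\t60\t",
                    spec$read_length, "M\t*\t0\t0\t", seqs, "\t", qual,
                    tagfields)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              paste0("@SQ\tSN:chr", seq_len(spec$n_contigs),
                     "\tLN:", spec$contig_length))

  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam), add = TRUE)
  writeLines(c(header, records), sam)
  dest <- sub("\\.bam$", "", out_bam)
  Rsamtools::asBam(sam, dest, overwrite = TRUE, indexDestination = FALSE)
  Rsamtools::indexBam(out_bam)

  reads <- tibble(qname = qname, status = status,
                  barcode = ifelse(status == "assigned", owner, NA_character_),
                  contig = contig, pos = as.integer(pos))
  first_seen <- unique(reads$barcode[reads$status == "assigned"])
  truth <- structure(list(
    bam = out_bam, reads = reads, barcodes = first_seen,
    per_barcode = table(reads$barcode[reads$status == "assigned"]),
    n_unbarcoded = sum(status == "unbarcoded"),
    n_sentinel = sum(status == "sentinel"),
    spec = spec
  ), class = "fixture_truth")
  if (!is.null(truth_path))
    utils::write.table(reads, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  truth
}

#' @export
print.fixture_truth <- function(x, ...) {
  cat(sprintf(paste0("<fixture_truth> %s: %d record(s), %d cell(s), ",
                     "%d unbarcoded, %d sentinel\n"),
              basename(x$bam), nrow(x$reads), length(x$barcodes),
              x$n_unbarcoded, x$n_sentinel))
  invisible(x)
}
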