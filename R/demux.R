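#' Read-accounting counters for one extraction pass
#'
#' Every record seen by a pass falls into exactly one category, so
#' `total_records = assigned + unbarcoded + rejected_by_acceptlist +
#' outside_regions`, and `assigned` equals the sum of the per-barcode
#' counts. This is the proof that the partition into scBAMs is lossless.
#'
#' @param total_records,assigned,unbarcoded,rejected_by_acceptlist,outside_regions
#'   Non-negative counts.
#' @param per_barcode Named integer vector: accepted barcode -> record count.
#' @return An object of class `demux_stats`.
#' @export
demux_stats <- function(total_records = 0L, assigned = 0L, unbarcoded = 0L,
                        rejected_by_acceptlist = 0L, outside_regions = 0L,
                        per_barcode = integer(0)) {
  x <- structure(list(total_records = as.integer(total_records),
                      assigned = as.integer(assigned),
                      unbarcoded = as.integer(unbarcoded),
                      rejected_by_acceptlist = as.integer(rejected_by_acceptlist),
                      outside_regions = as.integer(outside_regions),
                      per_barcode = per_barcode),
                 class = "demux_stats")
  stopifnot(x$total_records == x$assigned + x$unbarcoded +
              x$rejected_by_acceptlist + x$outside_regions,
            x$assigned == sum(x$per_barcode))
  x
}

#' @export
print.demux_stats <- function(x, ...) {
  cat(sprintf(paste0("<demux_stats> %d records: %d assigned to %d barcode(s), ",
                     "%d unbarcoded, %d rejected by acceptance list, ",
                     "%d outside regions\n"),
              x$total_records, x$assigned, length(x$per_barcode),
              x$unbarcoded, x$rejected_by_acceptlist, x$outside_regions))
  invisible(x)
}

#' @rdname demux_stats
#' @param x A `demux_stats` object.
#' @param ... Unused.
#' @return `tidy()` returns a tibble with one row per accepted barcode.
#' @export
tidy.demux_stats <- function(x, ...) {
  tibble(barcode = names(x$per_barcode),
         n_records = as.integer(unname(x$per_barcode)))
}

#' @rdname demux_stats
#' @export
glance.demux_stats <- function(x, ...) {
  tibble(total_records = x$total_records, assigned = x$assigned,
         unbarcoded = x$unbarcoded,
         rejected_by_acceptlist = x$rejected_by_acceptlist,
         outside_regions = x$outside_regions,
         n_barcodes = length(x$per_barcode))
}

resolve_use_index <- function(bam, regions, use_index) {
  use_index <- match.arg(use_index, c("auto", "yes", "no"))
  if (is.null(regions) || nrow(regions) == 0L) return(FALSE)
  idx <- bam_index_path(bam)
  if (use_index == "yes" && is.null(idx))
    stop("region restriction with use_index = 'yes' requires a BAI index; ",
         "run samtools index (or index_scbam()) on ", bam, call. = FALSE)
  use_index != "no" && !is.null(idx)
}

# Core single-pass streaming engine. In "explicit" mode the accepted set is
# `accept` (NULL = every barcoded read) and scBAMs are written for `batch`.
# In "discover" mode barcodes are accepted in order of first appearance (up
# to `limit`) and scBAMs are written for the first `batch_size` of them.
# Memory holds only the buffered records of the written barcodes.
demux_stream <- function(bam, spec, out_dir,
                         mode = c("explicit", "discover"),
                         batch = NULL, accept = NULL,
                         batch_size = NULL, limit = NULL,
                         regions = NULL, use_index = "auto",
                         name_template = NULL, emit_empty = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "barcode_spec"))
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2L) != 0L)
    stop("output directory is not writable: ", out_dir, call. = FALSE)

  name_template <- name_template %||% "{BAMBASE}.{BARCODE}.bam"
  bambase <- bambase_of(bam)
  header <- sam_header_lines(bam)
  fetch <- resolve_use_index(bam, regions, use_index)
  limit <- if (is.null(limit)) Inf else as.numeric(limit)

  if (mode == "explicit") {
    batch <- as.character(batch)
    if (!length(batch)) stop("batch must contain at least one barcode", call. = FALSE)
    if (anyDuplicated(batch)) stop("batch contains duplicate barcodes", call. = FALSE)
    if (!is.null(accept) && !all(batch %in% accept))
      stop("batch barcodes must be a subset of the accepted set", call. = FALSE)
  } else {
    stopifnot(!is.null(batch_size), batch_size >= 1L)
  }

  buf <- new.env(parent = emptyenv())
  counts <- integer(0)          # accepted barcode -> record count
  seen <- character(0)          # discover mode: first-appearance order
  n_total <- 0L; n_unbc <- 0L; n_out <- 0L; n_rej <- 0L
  dedup <- if (fetch) new.env(parent = emptyenv()) else NULL

  con <- sam_open_records(bam, regions = regions, fetch = fetch)
  on.exit(close(con), add = TRUE)
  repeat {
    lines <- readLines(con, n = 20000L, warn = FALSE)
    if (!length(lines)) break
    if (fetch) {
      keys <- sam_record_keys(lines)
      fresh <- !vapply(keys, function(k) {
        if (exists(k, envir = dedup, inherits = FALSE)) TRUE
        else { assign(k, TRUE, envir = dedup); FALSE }
      }, logical(1))
      lines <- lines[fresh]
      if (!length(lines)) next
    }
    n_total <- n_total + length(lines)
    bcs <- extract_barcodes_from_lines(lines, spec)
    barcoded <- !is.na(bcs)
    n_unbc <- n_unbc + sum(!barcoded)

    inregion <- barcoded
    if (!is.null(regions) && nrow(regions) > 0L && !fetch) {
      ov <- lines_overlap_regions(lines, regions)
      inregion <- barcoded & ov
      n_out <- n_out + sum(barcoded & !ov)
    }

    if (mode == "discover") {
      new <- unique(bcs[inregion])
      new <- new[!new %in% seen]
      seen <- c(seen, new)
      idx <- match(bcs, seen)
      accepted_mask <- inregion & !is.na(idx) & idx <= limit
      write_mask <- accepted_mask & idx <= min(batch_size, limit)
    } else {
      accepted_mask <- inregion &
        (if (is.null(accept)) TRUE else bcs %in% accept)
      write_mask <- inregion & bcs %in% batch
    }
    n_rej <- n_rej + sum(inregion & !accepted_mask)

    if (any(accepted_mask)) {
      tb <- table(bcs[accepted_mask])
      nm <- union(names(counts), names(tb))
      merged <- setNames(integer(length(nm)), nm)
      merged[names(counts)] <- counts
      merged[names(tb)] <- merged[names(tb)] + as.integer(tb)
      counts <- merged
    }
    if (any(write_mask)) {
      groups <- split(lines[write_mask], bcs[write_mask])
      for (bc in names(groups)) {
        cur <- if (exists(bc, envir = buf, inherits = FALSE))
          get(bc, envir = buf) else list()
        cur[[length(cur) + 1L]] <- groups[[bc]]
        assign(bc, cur, envir = buf)
      }
    }
  }

  write_set <- if (mode == "discover")
    head(seen, min(batch_size, limit)) else batch
  present <- vapply(write_set, function(bc)
    exists(bc, envir = buf, inherits = FALSE), logical(1))
  emit <- if (emit_empty) write_set else write_set[present]

  paths <- character(0)
  if (length(emit)) {
    files <- vapply(emit, function(bc)
      render_template(name_template,
                      template_context(barcode = sanitize_barcode(bc),
                                       bambase = bambase)),
      character(1))
    if (anyDuplicated(files))
      stop("scBAM filenames collide after barcode sanitization: ",
           paste(unique(files[duplicated(files)]), collapse = ", "),
           call. = FALSE)
    paths <- ifelse(startsWith(files, "/"), files,
                    file.path(out_dir, files))
    names(paths) <- emit
    for (bc in emit) {
      recs <- if (exists(bc, envir = buf, inherits = FALSE))
        unlist(get(bc, envir = buf), use.names = FALSE) else character(0)
      write_scbam(header, recs, paths[[bc]])
    }
  }

  # accepted barcodes with no records (possible with an acceptance list)
  acc_order <- if (mode == "discover") head(seen, limit) else
    (accept %||% names(counts))
  per_bc <- setNames(integer(length(acc_order)), acc_order)
  per_bc[names(counts)] <- counts
  if (mode == "explicit" && is.null(accept)) per_bc <- counts

  list(paths = paths,
       stats = demux_stats(n_total, sum(per_bc), n_unbc, n_rej, n_out, per_bc),
       barcodes = acc_order)
}

#' Enumerate accepted cell barcodes
#'
#' With an acceptance list, returns it in file order (truncated to `limit`)
#' without checking presence in the BAM. Otherwise scans the
#' (region-restricted) stream and returns distinct extractable barcodes in
#' order of first appearance, truncated to `limit`.
#'
#' @param bam Path to the pooled BAM.
#' @param spec A [barcode_spec()].
#' @param acceptlist Optional character vector of barcodes (e.g. from
#'   [read_barcode_list()]).
#' @param regions Optional merged region tibble from [parse_regions()].
#' @param limit Optional maximum number of barcodes.
#' @param use_index `"auto"` (use the BAI index for region fetch when one
#'   exists, else scan linearly), `"yes"` (require the index) or `"no"`.
#' @return Character vector of barcodes.
#' @export
enumerate_barcodes <- function(bam, spec, acceptlist = NULL, regions = NULL,
                               limit = NULL, use_index = "auto") {
  if (!is.null(limit) && (limit < 1L || limit != as.integer(limit)))
    stop("limit must be a positive integer", call. = FALSE)
  if (!is.null(acceptlist)) {
    acceptlist <- as.character(acceptlist)
    return(if (is.null(limit)) acceptlist else head(acceptlist, limit))
  }
  fetch <- resolve_use_index(bam, regions, use_index)
  lim <- if (is.null(limit)) Inf else limit
  seen <- character(0)
  dedup <- if (fetch) new.env(parent = emptyenv()) else NULL
  con <- sam_open_records(bam, regions = regions, fetch = fetch)
  on.exit(close(con), add = TRUE)
  repeat {
    lines <- readLines(con, n = 20000L, warn = FALSE)
    if (!length(lines)) break
    if (fetch) {
      keys <- sam_record_keys(lines)
      fresh <- !vapply(keys, function(k) {
        if (exists(k, envir = dedup, inherits = FALSE)) TRUE
        else { assign(k, TRUE, envir = dedup); FALSE }
      }, logical(1))
      lines <- lines[fresh]
      if (!length(lines)) next
    }
    bcs <- extract_barcodes_from_lines(lines, spec)
    keep <- !is.na(bcs)
    if (!is.null(regions) && nrow(regions) > 0L && !fetch)
      keep <- keep & lines_overlap_regions(lines, regions)
    new <- unique(bcs[keep])
    seen <- c(seen, new[!new %in% seen])
    if (length(seen) >= lim) { seen <- head(seen, lim); break }
  }
  seen
}

#' Extract scBAMs for one batch of barcodes
#'
#' Streams the pooled BAM once and writes one scBAM per batch barcode that
#' has at least one assigned record. Each scBAM's header is byte-identical
#' to the input header (no `@PG` line is appended) and its records are
#' exactly the input records whose extracted barcode equals that scBAM's
#' barcode (and overlap a region, when regions are given), in input order.
#' Secondary, supplementary and duplicate-flagged records pass through
#' untouched: filtering policy beyond barcode and region belongs to the
#' user's command.
#'
#' @inheritParams enumerate_barcodes
#' @param batch Character vector of barcodes to extract this pass.
#' @param out_dir Output directory (created if missing).
#' @param accept Optional full accepted set (for accounting); batch must be
#'   a subset. `NULL` accepts every barcoded read.
#' @param name_template scBAM filename template; `{BARCODE}` (sanitized) and
#'   `{BAMBASE}` are substituted. Default `"{BAMBASE}.{BARCODE}.bam"`.
#' @param emit_empty Write header-only scBAMs for batch barcodes with no
#'   records (default: skip them).
#' @return A list with `paths` (named character vector, barcode -> scBAM
#'   path) and `stats` (a [demux_stats()] covering the whole scanned
#'   stream).
#' @export
demux_batch <- function(bam, batch, spec, out_dir = tempfile("scbatch_"),
                        accept = NULL, regions = NULL, name_template = NULL,
                        emit_empty = FALSE, use_index = "auto") {
  res <- demux_stream(bam, spec, out_dir, mode = "explicit",
                      batch = batch, accept = accept, regions = regions,
                      use_index = use_index, name_template = name_template,
                      emit_empty = emit_empty)
  res[c("paths", "stats")]
}

#' Index an scBAM
#'
#' Creates a standard BAI index alongside the file. Requires the header to
#' declare coordinate sort order, which scBAMs inherit verbatim from the
#' pooled input.
#'
#' @param path Path to a coordinate-sorted BAM.
#' @return The index file path, invisibly.
#' @export
index_scbam <- function(path) {
  so <- bam_sort_order(path)
  if (is.na(so) || so != "coordinate")
    stop("cannot index ", path, ": header sort order is '",
         ifelse(is.na(so), "absent", so),
         "' but indexing requires coordinate sort", call. = FALSE)
  invisible(Rsamtools::indexBam(path))
}
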