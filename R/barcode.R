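#' Describe how to pull a cell barcode out of an alignment record
#'
#' A barcode specification names one of three extraction rules:
#' \describe{
#'   \item{`tag`}{read the value of a two-character auxiliary tag of type
#'     `Z` (e.g. `CB` for corrected barcodes, `CR` for raw ones).}
#'   \item{`qname_token`}{split the read name (QNAME) on a single-character
#'     delimiter and take one token. `token_index` is 0-based from the left;
#'     negative values count from the right, so `-2` is the second-to-last
#'     token -- the cell barcode position in the UMI-tools
#'     `NAME_CELLBARCODE_UMI` convention.}
#'   \item{`qname_regex`}{match a regular expression with exactly one
#'     capturing group against the QNAME; the group is the barcode.}
#' }
#'
#' @param mode One of `"tag"`, `"qname_token"`, `"qname_regex"`.
#' @param tag_name Two-character BAM tag name (mode `"tag"`).
#' @param delimiter Single-character token delimiter (mode `"qname_token"`).
#' @param token_index Signed integer token position (mode `"qname_token"`).
#' @param pattern Regular expression with exactly one capturing group
#'   (mode `"qname_regex"`).
#' @return An object of class `barcode_spec`.
#' @examples
#' barcode_spec("tag", tag_name = "CB")
#' barcode_spec("qname_token", delimiter = "_", token_index = -2)
#' @seealso [preset_spec()] for ready-made specifications,
#'   [extract_barcode()] to apply one.
#' @export
barcode_spec <- function(mode = c("tag", "qname_token", "qname_regex"),
                         tag_name = NULL, delimiter = NULL,
                         token_index = NULL, pattern = NULL) {
  mode <- match.arg(mode)
  spec <- switch(mode,
    tag = {
      if (is.null(tag_name) || !is.character(tag_name) || nchar(tag_name) != 2L)
        stop("mode 'tag' requires a two-character 'tag_name'", call. = FALSE)
      if (!is.null(delimiter) || !is.null(token_index) || !is.null(pattern))
        stop("mode 'tag' takes only 'tag_name'", call. = FALSE)
      list(mode = mode, tag_name = tag_name)
    },
    qname_token = {
      if (is.null(delimiter) || !is.character(delimiter) || nchar(delimiter) != 1L)
        stop("mode 'qname_token' requires a single-character 'delimiter'", call. = FALSE)
      if (is.null(token_index) || length(token_index) != 1L || is.na(token_index) ||
          token_index != as.integer(token_index))
        stop("mode 'qname_token' requires an integer 'token_index'", call. = FALSE)
      if (!is.null(tag_name) || !is.null(pattern))
        stop("mode 'qname_token' takes only 'delimiter' and 'token_index'", call. = FALSE)
      list(mode = mode, delimiter = delimiter, token_index = as.integer(token_index))
    },
    qname_regex = {
      if (is.null(pattern) || !is.character(pattern) || !nzchar(pattern))
        stop("mode 'qname_regex' requires a non-empty 'pattern'", call. = FALSE)
      if (n_capture_groups(pattern) != 1L)
        stop("'pattern' must contain exactly one capturing group", call. = FALSE)
      if (!is.null(tag_name) || !is.null(delimiter) || !is.null(token_index))
        stop("mode 'qname_regex' takes only 'pattern'", call. = FALSE)
      list(mode = mode, pattern = pattern)
    }
  )
  structure(spec, class = "barcode_spec")
}

#' @export
print.barcode_spec <- function(x, ...) {
  desc <- switch(x$mode,
    tag = sprintf("BAM tag %s", x$tag_name),
    qname_token = sprintf("QNAME token %d split on '%s'", x$token_index, x$delimiter),
    qname_regex = sprintf("QNAME regex capture: %s", x$pattern)
  )
  cat("<barcode_spec> ", desc, "\n", sep = "")
  invisible(x)
}

# Count unnamed/named capturing groups in a PCRE pattern by matching it
# against the empty string and inspecting the capture metadata R reports.
n_capture_groups <- function(pattern) {
  m <- tryCatch(regexpr(pattern, "", perl = TRUE),
                error = function(e) stop("invalid regular expression: ", pattern,
                                         " (", conditionMessage(e), ")", call. = FALSE))
  cs <- attr(m, "capture.start")
  if (is.null(cs)) 0L else ncol(cs)
}

#' Barcode-extraction presets for common scRNA-seq pipelines
#'
#' @param name One of `"cellranger"`, `"starsolo"` (both: corrected barcode
#'   in the `CB` tag), `"starsolo_raw"` (raw barcode in the `CR` tag), or
#'   `"umitools"` (barcode is the second-to-last `_`-delimited token of the
#'   read name, per the UMI-tools `NAME_CELLBARCODE_UMI` convention).
#' @return A [barcode_spec()].
#' @examples
#' preset_spec("starsolo")
#' preset_spec("umitools")
#' @export
preset_spec <- function(name) {
  presets <- list(
    cellranger   = barcode_spec("tag", tag_name = "CB"),
    starsolo     = barcode_spec("tag", tag_name = "CB"),
    starsolo_raw = barcode_spec("tag", tag_name = "CR"),
    umitools     = barcode_spec("qname_token", delimiter = "_", token_index = -2L)
  )
  if (length(name) != 1L || !is.character(name) || !name %in% names(presets)) {
    stop("unknown barcode preset ", deparse(substitute(name)), ": ",
         if (is.character(name)) paste0("'", name, "'") else "<non-string>",
         "; valid presets are: ", paste(names(presets), collapse = ", "),
         call. = FALSE)
  }
  presets[[name]]
}

# Sentinel values that mean "no barcode assigned". STARsolo writes CB:Z:-
# for reads it could not assign; an empty value is equally meaningless.
is_barcode_sentinel <- function(x) {
  is.na(x) | x == "" | x == "-"
}

#' Extract the cell barcode from one alignment record
#'
#' Applies a [barcode_spec()] to a parsed alignment record. A record from
#' which the rule yields nothing (absent tag, token index out of range,
#' regex non-match, empty value, or the `-` no-barcode sentinel) returns
#' `NA_character_`: such reads are "unbarcoded", never an error.
#'
#' @param record A parsed record as returned by [parse_sam_record()], or a
#'   raw SAM-format line.
#' @param spec A [barcode_spec()].
#' @return The barcode string, or `NA_character_`.
#' @examples
#' rec <- parse_sam_record(
#'   "r1\t0\tchr1\t10\t60\t5M\t*\t0\t0\tACGTA\tIIIII\tCB:Z:ACGTACGT-1")
#' extract_barcode(rec, preset_spec("starsolo"))
#' @export
extract_barcode <- function(record, spec) {
  stopifnot(inherits(spec, "barcode_spec"))
  if (is.character(record) && length(record) == 1L)
    record <- parse_sam_record(record)
  line <- record$line %||% sam_record_line(record)
  out <- extract_barcodes_from_lines(line, spec)
  out[[1L]]
}

# Vectorised extraction over raw SAM record lines; the demux hot path.
# Returns NA for unbarcoded records.
extract_barcodes_from_lines <- function(lines, spec) {
  vals <- switch(spec$mode,
    tag = {
      pat <- paste0("\t", spec$tag_name, ":Z:([^\t]*)")
      m <- regexpr(pat, lines, perl = TRUE)
      cs <- attr(m, "capture.start")[, 1L]
      cl <- attr(m, "capture.length")[, 1L]
      ifelse(m == -1L, NA_character_, substr(lines, cs, cs + cl - 1L))
    },
    qname_token = {
      qn <- sub("\t.*", "", lines)
      toks <- strsplit(qn, spec$delimiter, fixed = TRUE)
      i <- spec$token_index
      vapply(toks, function(tt) {
        t <- length(tt)
        j <- if (i >= 0L) i + 1L else t + i + 1L
        if (i >= t || i < -t) NA_character_ else tt[[j]]
      }, character(1))
    },
    qname_regex = {
      qn <- sub("\t.*", "", lines)
      m <- regexpr(spec$pattern, qn, perl = TRUE)
      cs <- attr(m, "capture.start")[, 1L]
      cl <- attr(m, "capture.length")[, 1L]
      ifelse(m == -1L, NA_character_, substr(qn, cs, cs + cl - 1L))
    }
  )
  vals[is_barcode_sentinel(vals)] <- NA_character_
  # barcodes must be usable downstream: whitespace inside one is malformed
  vals[!is.na(vals) & grepl("[[:space:]]", vals)] <- NA_character_
  vals
}

#' Sanitize a barcode for use inside a filename
#'
#' Characters outside `[A-Za-z0-9._-]` are replaced by `_`. Nucleotide
#' barcodes (with or without the CellRanger `-1` GEM-well suffix) pass
#' through unchanged.
#'
#' @param barcode Character vector of barcodes.
#' @return Character vector of filename-safe barcodes.
#' @export
sanitize_barcode <- function(barcode) {
  gsub("[^A-Za-z0-9._-]", "_", barcode)
}
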