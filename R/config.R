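#' Build a validated run configuration
#'
#' @param bam Path to the pooled, barcoded, coordinate-sorted BAM.
#' @param command Command template executed once per scBAM (see
#'   [render_command()] for the substitution rules).
#' @param barcode_source How to extract barcodes: a preset name
#'   (`"cellranger"`, `"starsolo"`, `"starsolo_raw"`, `"umitools"`), a
#'   compact rule string (`"tag:XC"`, `"qname:<delim>:<index>"`,
#'   `"regex:<pattern>"`), or a [barcode_spec()].
#' @param acceptlist Path to a barcodes.tsv-style file (plain or gzip), or a
#'   character vector of barcodes.
#' @param regions Region string(s), a BED path, or a [parse_regions()]
#'   tibble.
#' @param batch_size Barcodes extracted per pass (default 100; extracting
#'   100-200 scBAMs per pass is usually enough to keep the workers busy).
#' @param jobs Maximum number of commands running at once (default: number
#'   of detected cores).
#' @param limit Optional cap on the number of scBAMs/jobs.
#' @param file_template Optional scBAM filename template; supplying one
#'   saves the scBAMs instead of deleting them after each job.
#' @param workdir_template,stdout_template,stderr_template Optional per-job
#'   templates for the working directory and output capture files.
#' @param index Index each scBAM (BAI) before its command runs.
#' @param emit_empty Write header-only scBAMs (and schedule jobs) for
#'   accepted barcodes with no records.
#' @param fail_fast Stop launching new jobs after the first nonzero exit.
#' @param use_index `"auto"`, `"yes"` or `"no"`: whether region restriction
#'   may use the BAI index for random-access fetch.
#' @param out_dir Run-scoped directory for transient scBAMs (default: a
#'   fresh temporary directory).
#' @param event_log Optional path for the structured event log (TSV).
#' @return An object of class `run_config`.
#' @export
run_config <- function(bam, command, barcode_source = "cellranger",
                       acceptlist = NULL, regions = NULL,
                       batch_size = 100L, jobs = NULL, limit = NULL,
                       file_template = NULL, workdir_template = NULL,
                       stdout_template = NULL, stderr_template = NULL,
                       index = FALSE, emit_empty = FALSE, fail_fast = FALSE,
                       use_index = "auto", out_dir = NULL,
                       event_log = NULL) {
  if (missing(bam) || is.null(bam) || !nzchar(bam))
    stop("an input BAM is required", call. = FALSE)
  if (missing(command) || is.null(command) || !nzchar(command))
    stop("a command template is required", call. = FALSE)
  if (length(batch_size) != 1L || is.na(batch_size) || batch_size < 1L ||
      batch_size != as.integer(batch_size))
    stop("batch_size must be a positive integer", call. = FALSE)
  jobs <- jobs %||% max(1L, parallel::detectCores())
  if (length(jobs) != 1L || is.na(jobs) || jobs < 1L)
    stop("jobs must be a positive integer", call. = FALSE)
  if (!is.null(limit) && (is.na(limit) || limit < 1L))
    stop("limit must be a positive integer", call. = FALSE)

  spec <- if (inherits(barcode_source, "barcode_spec")) barcode_source
          else parse_barcode_source(barcode_source)

  structure(list(
    bam = bam, command = command,
    barcode_source = if (is.character(barcode_source)) barcode_source else NA_character_,
    spec = spec,
    acceptlist = acceptlist, regions = regions,
    batch_size = as.integer(batch_size), jobs = as.integer(jobs),
    limit = if (is.null(limit)) NULL else as.integer(limit),
    file_template = file_template, workdir_template = workdir_template,
    stdout_template = stdout_template, stderr_template = stderr_template,
    index = isTRUE(index), emit_empty = isTRUE(emit_empty),
    fail_fast = isTRUE(fail_fast), use_index = use_index,
    out_dir = out_dir, event_log = event_log
  ), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat("  bam:        ", x$bam, "\n")
  cat("  command:    ", x$command, "\n")
  cat("  batch_size: ", x$batch_size, "  jobs: ", x$jobs,
      if (!is.null(x$limit)) paste0("  limit: ", x$limit), "\n", sep = "")
  print(x$spec)
  invisible(x)
}

#' Parse a compact barcode-source string
#'
#' Accepts a preset name ([preset_spec()]), `"tag:XY"` for an arbitrary
#' two-character tag, `"qname:<delimiter>:<index>"` for a delimited QNAME
#' token (0-based; negatives count from the right), or `"regex:<pattern>"`
#' for a QNAME regular expression with one capturing group.
#'
#' @param x The source string.
#' @return A [barcode_spec()].
#' @export
parse_barcode_source <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (grepl("^tag:", x))
    return(barcode_spec("tag", tag_name = sub("^tag:", "", x)))
  if (grepl("^qname:", x)) {
    body <- sub("^qname:", "", x)
    d <- substr(body, 1L, 1L)
    idx <- substr(body, 3L, nchar(body))
    if (nchar(body) < 3L || substr(body, 2L, 2L) != ":" ||
        is.na(suppressWarnings(as.integer(idx))))
      stop("malformed qname barcode source '", x,
           "'; expected qname:<delimiter>:<index>", call. = FALSE)
    return(barcode_spec("qname_token", delimiter = d,
                        token_index = as.integer(idx)))
  }
  if (grepl("^regex:", x))
    return(barcode_spec("qname_regex", pattern = sub("^regex:", "", x)))
  preset_spec(x)
}

# serialize a spec back to the compact string form (for config files)
barcode_source_string <- function(cfg) {
  if (!is.na(cfg$barcode_source)) return(cfg$barcode_source)
  s <- cfg$spec
  switch(s$mode,
    tag = paste0("tag:", s$tag_name),
    qname_token = paste0("qname:", s$delimiter, ":", s$token_index),
    qname_regex = paste0("regex:", s$pattern))
}

#' Write / read a run configuration file
#'
#' The configuration file is a flat YAML mapping mirroring the command-line
#' flags; values given on the command line override the file. Writing then
#' reading a configuration yields an equivalent one.
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` a [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- config
  out <- list(bam = x$bam, command = x$command,
              barcode_source = barcode_source_string(x),
              acceptlist = x$acceptlist,
              regions = if (is.data.frame(x$regions))
                sprintf("%s:%d-%d", x$regions$contig, x$regions$start,
                        x$regions$end) else x$regions,
              batch_size = x$batch_size, jobs = x$jobs, limit = x$limit,
              file_template = x$file_template,
              workdir_template = x$workdir_template,
              stdout_template = x$stdout_template,
              stderr_template = x$stderr_template,
              index = x$index, emit_empty = x$emit_empty,
              fail_fast = x$fail_fast, use_index = x$use_index,
              out_dir = x$out_dir, event_log = x$event_log)
  yaml::write_yaml(out[!vapply(out, is.null, logical(1))], path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("configuration file not readable: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

# ---- command-line interface --------------------------------------------

cli_option_list <- function() {
  o <- optparse::make_option
  list(
    o(c("-i", "--bam"), type = "character", default = NULL,
      help = "Pooled, coordinate-sorted, barcoded input BAM [required]"),
    o(c("-b", "--barcode-source"), type = "character", default = NULL,
      dest = "barcode_source",
      help = paste0("Barcode extraction rule: preset (cellranger, starsolo, ",
                    "starsolo_raw, umitools), tag:XY, qname:<delim>:<index> ",
                    "(0-based, negatives from the right), or regex:<pattern> ",
                    "[default cellranger]")),
    o(c("-L", "--acceptlist"), type = "character", default = NULL,
      help = "barcodes.tsv-style acceptance list (plain or gzip)"),
    o(c("-r", "--regions"), type = "character", default = NULL,
      help = "Region string(s) contig:start-end (comma-separated) or a BED file"),
    o(c("-B", "--batch-size"), type = "integer", default = NULL,
      dest = "batch_size", help = "Barcodes extracted per pass [default 100]"),
    o(c("-j", "--jobs"), type = "integer", default = NULL,
      help = "Commands to run at once [default: all cores]"),
    o(c("-n", "--limit"), type = "integer", default = NULL,
      help = "Maximum number of scBAMs/jobs"),
    o(c("-C", "--command"), type = "character", default = NULL,
      help = "Command template; {} = scBAM path, {BARCODE}, {BAMBASE}"),
    o(c("-F", "--file-template"), type = "character", default = NULL,
      dest = "file_template",
      help = "scBAM filename template; supplying one keeps the scBAMs"),
    o(c("-D", "--workdir-template"), type = "character", default = NULL,
      dest = "workdir_template", help = "Per-job working directory template"),
    o(c("-O", "--stdout-template"), type = "character", default = NULL,
      dest = "stdout_template", help = "Per-job standard output file template"),
    o(c("-E", "--stderr-template"), type = "character", default = NULL,
      dest = "stderr_template", help = "Per-job standard error file template"),
    o("--index", action = "store_true", default = NULL,
      help = "Index each scBAM before its command runs"),
    o("--emit-empty", action = "store_true", default = NULL,
      dest = "emit_empty",
      help = "Write header-only scBAMs for accepted barcodes with no reads"),
    o("--fail-fast", action = "store_true", default = NULL,
      dest = "fail_fast",
      help = "Stop launching jobs after the first nonzero exit code"),
    o("--config", type = "character", default = NULL,
      help = "YAML configuration file mirroring these flags (CLI overrides)"),
    o("--event-log", type = "character", default = NULL, dest = "event_log",
      help = "Write the structured event log (TSV) to this path"),
    o(c("-v", "--verbose"), action = "store_true", default = NULL,
      help = "Progress messages on standard error"),
    o("--version", action = "store_true", default = NULL,
      help = "Print version and exit")
  )
}

usage_error <- function(msg) {
  stop(structure(class = c("scbatch_usage_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Parse command-line arguments into a run configuration
#'
#' Trailing positional arguments are taken as the command template when
#' `-C/--command` is not given. A `--config` YAML file supplies defaults
#' that explicit flags override.
#'
#' @param argv Character vector of arguments (as from
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return A list with elements `config` (a [run_config()]) and `verbose`.
#' @export
parse_cli <- function(argv) {
  parser <- optparse::OptionParser(
    usage = "scbatch -i pooled.bam [options] [-C] 'command template'",
    option_list = cli_option_list(), add_help_option = TRUE)
  parsed <- tryCatch(
    optparse::parse_args(parser, args = argv, positional_arguments = TRUE),
    error = function(e) usage_error(conditionMessage(e)))
  opts <- parsed$options
  if (isTRUE(opts$version)) {
    return(list(config = NULL, verbose = FALSE, version = TRUE))
  }
  if (is.null(opts$command) && length(parsed$args))
    opts$command <- paste(parsed$args, collapse = " ")
  else if (!is.null(opts$command) && length(parsed$args))
    usage_error("both -C/--command and a trailing positional command were given")

  base <- list(barcode_source = "cellranger", batch_size = 100L,
               jobs = max(1L, parallel::detectCores()))
  if (!is.null(opts$config)) {
    if (!file.exists(opts$config))
      usage_error(paste0("configuration file not readable: ", opts$config))
    base <- modifyList(base, yaml::read_yaml(opts$config))
  }
  cli_vals <- opts[!vapply(opts, is.null, logical(1))]
  cli_vals$help <- NULL; cli_vals$config <- NULL; cli_vals$version <- NULL
  verbose <- isTRUE(cli_vals$verbose); cli_vals$verbose <- NULL
  vals <- modifyList(base, cli_vals)

  if (is.null(vals$bam)) usage_error("an input BAM (-i/--bam) is required")
  if (is.null(vals$command))
    usage_error("a command template (-C/--command or trailing arguments) is required")
  cfg <- tryCatch(do.call(run_config, vals),
                  error = function(e) usage_error(conditionMessage(e)))
  list(config = cfg, verbose = verbose, version = FALSE)
}

#' Command-line entry point
#'
#' Thin wrapper used by the `exec/scbatch` script: parses arguments, runs
#' the pipeline, prints the run summary to standard error, and returns the
#' process exit status (0 success; 1 fatal error, or any job failure under
#' `--fail-fast`; 2 usage error).
#'
#' @param argv Argument vector.
#' @return Integer exit status, invisibly.
#' @export
main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  parsed <- tryCatch(parse_cli(argv), scbatch_usage_error = function(e) e)
  if (inherits(parsed, "scbatch_usage_error")) {
    message("scbatch: ", conditionMessage(parsed))
    return(invisible(2L))
  }
  if (parsed$version) {
    cat(as.character(utils::packageVersion("scbatch")), "\n")
    return(invisible(0L))
  }
  run <- tryCatch(run_pipeline(parsed$config, quiet = !parsed$verbose),
                  error = function(e) e)
  if (inherits(run, "error")) {
    message("scbatch: fatal: ", conditionMessage(run))
    return(invisible(1L))
  }
  sink(stderr()); print(run); sink()
  invisible(run$status)
}
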