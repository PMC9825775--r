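#' One rendered command bound to one scBAM
#'
#' @param barcode Cell barcode the job belongs to.
#' @param scbam_path Path to the extracted scBAM.
#' @param command Rendered shell command (non-empty).
#' @param workdir Working directory for the command (created if missing at
#'   launch).
#' @param stdout_path,stderr_path Optional files receiving the command's
#'   standard output/error; `NULL` inherits the parent's streams. Relative
#'   paths resolve in `workdir`, as a redirection written in the command
#'   itself would.
#' @param keep_scbam Keep the scBAM (and index) after the job finishes;
#'   default deletes them.
#' @param index_first Ensure a BAI index exists before the command runs.
#' @return An object of class `job_spec`.
#' @export
job_spec <- function(barcode, scbam_path, command, workdir = getwd(),
                     stdout_path = NULL, stderr_path = NULL,
                     keep_scbam = FALSE, index_first = FALSE) {
  stopifnot(is.character(command), length(command) == 1L, nzchar(command))
  structure(list(barcode = barcode, scbam_path = scbam_path,
                 command = command, workdir = workdir,
                 stdout_path = stdout_path, stderr_path = stderr_path,
                 keep_scbam = isTRUE(keep_scbam),
                 index_first = isTRUE(index_first)),
            class = "job_spec")
}

#' Execute one per-cell job
#'
#' Runs the job's command through `/bin/sh -c` in its working directory, so
#' pipes, list operators and redirection behave exactly as in an
#' interactive shell. The exit code is captured for every launched job --
#' a failing command is an outcome, not an error. On completion the scBAM
#' (and its index) are deleted unless `keep_scbam` is set.
#'
#' @param job A [job_spec()].
#' @return A list of class `job_result` with `barcode`, `exit_code`,
#'   `wall_seconds` and `reason` (`NA` unless the job failed before the
#'   command could run, e.g. an unwritable output path).
#' @export
execute_job <- function(job) {
  stopifnot(inherits(job, "job_spec"))
  t0 <- proc.time()[["elapsed"]]
  if (!dir.exists(job$workdir))
    dir.create(job$workdir, recursive = TRUE, showWarnings = FALSE)
  old <- setwd(job$workdir)
  on.exit(setwd(old), add = TRUE)

  finish <- function(code, reason = NA_character_) {
    if (!job$keep_scbam) {
      unlink(job$scbam_path)
      unlink(paste0(job$scbam_path, ".bai"))
    }
    structure(list(barcode = job$barcode, exit_code = as.integer(code),
                   wall_seconds = proc.time()[["elapsed"]] - t0,
                   reason = reason),
              class = "job_result")
  }

  if (job$index_first && is.null(bam_index_path(job$scbam_path)))
    index_scbam(job$scbam_path)

  # fail (distinctly) if a redirection target cannot be created
  for (p in c(job$stdout_path, job$stderr_path)) {
    d <- dirname(p)
    if (!dir.exists(d))
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
    ok <- dir.exists(d) && (file.exists(p) || file.create(p, showWarnings = FALSE))
    if (!ok)
      return(finish(-1L, reason = paste0("unwritable output path: ", p)))
  }

  status <- suppressWarnings(system2(
    "/bin/sh", c("-c", shQuote(job$command)),
    stdout = job$stdout_path %||% "",
    stderr = job$stderr_path %||% ""
  ))
  finish(if (is.null(status)) 0L else status)
}

# ---- bounded worker pool over forked processes -------------------------

new_pool <- function() {
  env <- new.env(parent = emptyenv())
  env$running <- list()   # pid -> mcparallel handle
  env$meta <- list()      # pid -> job metadata
  env$results <- list()   # collected job_result (or failure stubs)
  env$any_failure <- FALSE
  env
}

pool_reap <- function(pool, log) {
  if (!length(pool$running)) return(invisible(NULL))
  res <- suppressWarnings(
    parallel::mccollect(pool$running, wait = FALSE, timeout = 0)
  )
  if (is.null(res) || !length(res)) return(invisible(NULL))
  for (pid in names(res)) {
    if (!pid %in% names(pool$running)) next
    meta <- pool$meta[[pid]]
    r <- res[[pid]]
    if (!inherits(r, "job_result")) {
      msg <- if (inherits(r, "try-error")) conditionMessage(attr(r, "condition"))
             else "worker exited without a result"
      r <- structure(list(barcode = meta$barcode, exit_code = -1L,
                          wall_seconds = NA_real_, reason = msg),
                     class = "job_result")
    }
    pool$results[[length(pool$results) + 1L]] <-
      c(r, list(batch = meta$batch, scbam = meta$scbam))
    if (r$exit_code != 0L) pool$any_failure <- TRUE
    log_event(log, "job_end", batch = meta$batch, barcode = meta$barcode,
              detail = as.character(r$exit_code))
    pool$running[[pid]] <- NULL
    pool$meta[[pid]] <- NULL
  }
  invisible(NULL)
}

pool_launch <- function(pool, job, meta, max_jobs, log, poll = 0.01) {
  while (length(pool$running) >= max_jobs) {
    pool_reap(pool, log)
    if (length(pool$running) >= max_jobs) Sys.sleep(poll)
  }
  h <- parallel::mcparallel(execute_job(job))
  pid <- as.character(h$pid)
  pool$running[[pid]] <- h
  pool$meta[[pid]] <- meta
  log_event(log, "job_start", batch = meta$batch, barcode = meta$barcode)
  invisible(NULL)
}

pool_drain <- function(pool, log, poll = 0.01) {
  while (length(pool$running)) {
    pool_reap(pool, log)
    if (length(pool$running)) Sys.sleep(poll)
  }
}

# ---- structured event log ----------------------------------------------

new_event_log <- function() {
  env <- new.env(parent = emptyenv())
  env$events <- list()
  env
}

log_event <- function(log, type, batch = NA_integer_,
                      barcode = NA_character_, detail = NA_character_) {
  log$events[[length(log$events) + 1L]] <-
    list(time = as.numeric(Sys.time()), type = type,
         batch = as.integer(batch), barcode = barcode, detail = detail)
  invisible(NULL)
}

event_tibble <- function(log) {
  ev <- log$events
  tibble(time = vapply(ev, `[[`, numeric(1), "time"),
         type = vapply(ev, `[[`, character(1), "type"),
         batch = vapply(ev, `[[`, integer(1), "batch"),
         barcode = vapply(ev, `[[`, character(1), "barcode"),
         detail = vapply(ev, `[[`, character(1), "detail"))
}

# ---- full pipeline ------------------------------------------------------

#' Run the full batched extract-and-execute pipeline
#'
#' Streams the pooled BAM in `ceiling(n / batch_size)` passes, writing the
#' scBAMs of one batch per pass and executing the rendered command on each,
#' with at most `jobs` commands running concurrently. Extraction of batch
#' `i + 1` proceeds while batch `i`'s jobs run, so total wall time is
#' dominated by the first pass plus the serialized job time divided by the
#' worker count. When no acceptance list is given, barcode discovery is
#' folded into the first pass: new barcodes are indexed in order of first
#' appearance, records of the first `batch_size` of them are written out
#' immediately, and the rest are extracted on later passes.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages (default `TRUE`).
#' @return An object of class `scbatch_run`: per-job results, demultiplexing
#'   statistics, the structured event log, and counts summarising the run.
#' @examples
#' \dontrun{
#' fx <- generate_fixture(fixture_spec(n_barcodes = 5, reads_per_barcode = 20,
#'                                     seed = 1),
#'                        tempfile(fileext = ".bam"))
#' run <- run_pipeline(run_config(fx$bam, "samtools flagstat {} > /dev/null",
#'                                barcode_source = "starsolo",
#'                                batch_size = 2, jobs = 2))
#' glance(run)
#' }
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  if (!file.exists(cfg$bam))
    stop("input BAM not readable: ", cfg$bam, call. = FALSE)
  spec <- cfg$spec
  say <- function(...) if (!quiet) message(sprintf(...))

  if (cfg$index) {
    so <- bam_sort_order(cfg$bam)
    if (is.na(so) || so != "coordinate")
      stop("--index requires a coordinate-sorted input BAM (header SO is '",
           ifelse(is.na(so), "absent", so), "')", call. = FALSE)
  }

  regions <- NULL
  if (!is.null(cfg$regions)) {
    regions <- if (is.data.frame(cfg$regions)) cfg$regions
               else parse_regions(cfg$regions, cfg$bam)
  }
  accept <- NULL
  if (!is.null(cfg$acceptlist)) {
    accept <- if (length(cfg$acceptlist) == 1L && file.exists(cfg$acceptlist))
      read_barcode_list(cfg$acceptlist) else as.character(cfg$acceptlist)
  }

  keep <- !is.null(cfg$file_template)
  run_dir <- cfg$out_dir %||% tempfile("scbatch_run_")
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  scbam_dir <- if (keep) getwd() else run_dir
  name_template <- cfg$file_template %||% "{BAMBASE}.{BARCODE}.bam"
  bambase <- bambase_of(cfg$bam)

  log <- new_event_log()
  pool <- new_pool()
  launched <- 0L
  skipped_empty <- 0L
  fatal <- NULL
  stats1 <- NULL
  stop_launching <- FALSE

  schedule_batch <- function(i, paths) {
    for (bc in names(paths)) {
      pool_reap(pool, log)
      if (cfg$fail_fast && pool$any_failure) {
        stop_launching <<- TRUE
        if (!keep) { unlink(paths[[bc]]); unlink(paste0(paths[[bc]], ".bai")) }
        next
      }
      path <- paths[[bc]]
      if (cfg$index) index_scbam(path)
      ctx <- template_context(scbam_path = path, barcode = bc,
                              bambase = bambase)
      job <- job_spec(
        barcode = bc, scbam_path = path,
        command = render_command(cfg$command, ctx),
        workdir = if (!is.null(cfg$workdir_template))
          render_template(cfg$workdir_template, ctx) else getwd(),
        stdout_path = if (!is.null(cfg$stdout_template))
          render_template(cfg$stdout_template, ctx) else NULL,
        stderr_path = if (!is.null(cfg$stderr_template))
          render_template(cfg$stderr_template, ctx) else NULL,
        keep_scbam = keep, index_first = cfg$index
      )
      pool_launch(pool, job,
                  meta = list(barcode = bc, batch = i, scbam = path),
                  max_jobs = cfg$jobs, log = log)
      launched <<- launched + 1L
    }
  }

  result <- tryCatch({
    if (!is.null(accept)) {
      barcodes <- if (is.null(cfg$limit)) accept else head(accept, cfg$limit)
      plan <- plan_batches(barcodes, cfg$batch_size)
      first <- NULL
    } else {
      say("pass 1: discovering barcodes and extracting first batch")
      log_event(log, "scan_start", batch = 1L)
      first <- demux_stream(cfg$bam, spec, scbam_dir, mode = "discover",
                            batch_size = cfg$batch_size, limit = cfg$limit,
                            regions = regions, use_index = cfg$use_index,
                            name_template = name_template,
                            emit_empty = cfg$emit_empty)
      log_event(log, "scan_end", batch = 1L)
      barcodes <- first$barcodes
      plan <- plan_batches(barcodes, cfg$batch_size)
      stats1 <- first$stats
    }

    nb <- n_batches(plan)
    say("%d accepted barcode(s), %d extraction pass(es) of batch size %d",
        length(barcodes), nb, cfg$batch_size)

    for (i in seq_len(nb)) {
      if (stop_launching) break
      if (!is.null(first) && i == 1L) {
        res <- first
      } else {
        log_event(log, "scan_start", batch = i)
        res <- demux_batch(cfg$bam, plan$batches[[i]], spec,
                           out_dir = scbam_dir, accept = barcodes,
                           regions = regions, name_template = name_template,
                           emit_empty = cfg$emit_empty,
                           use_index = cfg$use_index)
        log_event(log, "scan_end", batch = i)
        if (is.null(stats1)) stats1 <- res$stats
      }
      n_batch <- if (!is.null(first) && i == 1L)
        min(cfg$batch_size, length(barcodes)) else length(plan$batches[[i]])
      skipped_empty <- skipped_empty + (n_batch - length(res$paths))
      schedule_batch(i, res$paths)
    }
    NULL
  }, error = function(e) e)

  if (inherits(result, "error")) fatal <- conditionMessage(result)
  pool_drain(pool, log)

  if (!keep) {
    leftovers <- list.files(run_dir, pattern = "\\.(bam|bai)$",
                            full.names = TRUE)
    unlink(leftovers)
  }

  rr <- pool$results
  jobs <- tibble(
    barcode = vapply(rr, `[[`, character(1), "barcode"),
    batch = vapply(rr, `[[`, integer(1), "batch"),
    scbam = vapply(rr, `[[`, character(1), "scbam"),
    exit_code = vapply(rr, `[[`, integer(1), "exit_code"),
    wall_seconds = vapply(rr, `[[`, numeric(1), "wall_seconds"),
    reason = vapply(rr, `[[`, character(1), "reason")
  )
  n_fail <- sum(jobs$exit_code != 0L)
  status <- if (!is.null(fatal)) 1L
            else if (cfg$fail_fast && n_fail > 0L) 1L else 0L

  out <- structure(list(
    jobs = jobs,
    jobs_launched = launched,
    jobs_succeeded = launched - n_fail,
    jobs_failed = n_fail,
    barcodes_skipped_empty = as.integer(skipped_empty),
    stats = stats1,
    events = event_tibble(log),
    barcodes = if (exists("barcodes", inherits = FALSE)) barcodes else character(0),
    run_dir = run_dir,
    scbam_paths = if (keep) setNames(jobs$scbam, jobs$barcode) else character(0),
    fatal = fatal,
    status = status,
    config = cfg
  ), class = "scbatch_run")

  if (!is.null(cfg$event_log))
    utils::write.table(out$events, cfg$event_log, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  out
}

#' @export
print.scbatch_run <- function(x, ...) {
  cat(sprintf(paste0("<scbatch_run> %d job(s) launched: %d succeeded, ",
                     "%d failed; %d empty barcode(s) skipped\n"),
              x$jobs_launched, x$jobs_succeeded, x$jobs_failed,
              x$barcodes_skipped_empty))
  if (!is.null(x$stats)) print(x$stats)
  if (!is.null(x$fatal)) cat("fatal:", x$fatal, "\n")
  invisible(x)
}

#' @rdname run_pipeline
#' @param x An `scbatch_run` object.
#' @param ... Unused.
#' @return `tidy()` returns the per-job tibble (one row per launched
#'   command); `glance()` a one-row run summary.
#' @export
tidy.scbatch_run <- function(x, ...) x$jobs

#' @rdname run_pipeline
#' @export
glance.scbatch_run <- function(x, ...) {
  tibble(jobs_launched = x$jobs_launched,
         jobs_succeeded = x$jobs_succeeded,
         jobs_failed = x$jobs_failed,
         barcodes_skipped_empty = x$barcodes_skipped_empty,
         extraction_passes = sum(x$events$type == "scan_start"),
         total_records = x$stats$total_records %||% NA_integer_,
         assigned = x$stats$assigned %||% NA_integer_,
         status = x$status)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
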