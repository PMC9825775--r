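make_scbam <- function(fx, bc, out = run_dir_tmp()) {
  demux_batch(fx$bam, bc, preset_spec("starsolo"), out_dir = out)$paths[[bc]]
}

test_that("execute_job captures exit codes and manages the scBAM lifecycle", {
  fx <- fx_small()
  bc <- fx$barcodes[[1]]

  p <- make_scbam(fx, bc)
  r <- execute_job(job_spec(bc, p, "exit 0", workdir = tempdir()))
  expect_s3_class(r, "job_result")
  expect_identical(r$exit_code, 0L)
  expect_false(file.exists(p))  # deleted: keep_scbam is FALSE

  p <- make_scbam(fx, bc)
  r <- execute_job(job_spec(bc, p, "exit 3", workdir = tempdir()))
  expect_identical(r$exit_code, 3L)
  expect_gte(r$wall_seconds, 0)

  p <- make_scbam(fx, bc)
  r <- execute_job(job_spec(bc, p, "true", workdir = tempdir(),
                            keep_scbam = TRUE))
  expect_true(file.exists(p))
})

test_that("pipes and redirection behave as in an interactive shell", {
  fx <- fx_small()
  bc <- fx$barcodes[[1]]
  p <- make_scbam(fx, bc)
  wd <- run_dir_tmp()
  cmd <- render_command("samtools view {} | wc -l > {BARCODE}.size",
                        template_context(p, bc, "fx"))
  r <- execute_job(job_spec(bc, p, cmd, workdir = wd))
  expect_identical(r$exit_code, 0L)
  sz <- file.path(wd, paste0(bc, ".size"))
  expect_true(file.exists(sz))
  expect_identical(as.integer(trimws(readLines(sz))), 10L)
})

test_that("an unwritable output path marks the job failed with a reason", {
  fx <- fx_small()
  bc <- fx$barcodes[[1]]
  p <- make_scbam(fx, bc)
  r <- execute_job(job_spec(bc, p, "true", workdir = tempdir(),
                            stdout_path = "/dev/null/impossible/out.txt"))
  expect_identical(r$exit_code, -1L)
  expect_match(r$reason, "unwritable")
})

run_cfg <- function(fx, ...) {
  run_config(fx$bam, barcode_source = "starsolo", ...)
}

test_that("a full run launches one job per cell over ceiling(n/B) passes", {
  fx <- fx_mid()  # 5 cells
  run <- run_pipeline(run_cfg(fx, command = "exit 0", batch_size = 2, jobs = 2))
  expect_identical(run$jobs_launched, 5L)
  expect_identical(run$jobs_succeeded, 5L)
  expect_identical(run$jobs_failed, 0L)
  expect_identical(sum(run$events$type == "scan_start"), 3L)
  expect_identical(sum(run$events$type == "scan_end"), 3L)
  expect_identical(run$status, 0L)
  expect_setequal(run$jobs$barcode, fx$barcodes)
})

test_that("--limit caps the number of scBAMs and jobs", {
  fx <- fx_mid()
  run <- run_pipeline(run_cfg(fx, command = "exit 0", batch_size = 2,
                              jobs = 2, limit = 3))
  expect_identical(run$jobs_launched, 3L)
  expect_setequal(run$jobs$barcode, fx$barcodes[1:3])
})

test_that("failing commands are recorded without aborting by default", {
  fx <- fx_mid()
  run <- run_pipeline(run_cfg(fx, command = "exit 3", batch_size = 2, jobs = 2))
  expect_identical(run$jobs_launched, 5L)
  expect_identical(run$jobs_failed, 5L)
  expect_true(all(run$jobs$exit_code == 3L))
  expect_identical(run$status, 0L)  # failures alone are not fatal
})

test_that("--fail-fast stops launching after the first nonzero exit", {
  fx <- fx_mid()
  run <- run_pipeline(run_cfg(fx, command = "exit 1", batch_size = 1, jobs = 1,
                              fail_fast = TRUE))
  expect_lt(run$jobs_launched, 5L)
  expect_gt(run$jobs_failed, 0L)
  expect_identical(run$status, 1L)
})

test_that("no more than `jobs` commands ever run concurrently", {
  fx <- fx_mid()
  wd <- run_dir_tmp()
  cmd <- paste0("date +%s.%N > {BARCODE}.start; sleep 0.3; ",
                "date +%s.%N > {BARCODE}.stop")
  run <- run_pipeline(run_cfg(fx, command = cmd, batch_size = 5, jobs = 2,
                              workdir_template = wd))
  expect_identical(run$jobs_succeeded, 5L)
  starts <- sort(as.numeric(vapply(list.files(wd, "\\.start$", full.names = TRUE),
                                   readLines, character(1))))
  stops <- sort(as.numeric(vapply(list.files(wd, "\\.stop$", full.names = TRUE),
                                  readLines, character(1))))
  expect_length(starts, 5L)
  # max concurrency: sweep over all start events
  conc <- vapply(starts, function(t) sum(starts <= t & stops > t), numeric(1))
  expect_lte(max(conc), 2)
})

test_that("extraction of the next batch overlaps running jobs", {
  fx <- fx_mid()
  run <- run_pipeline(run_cfg(fx, command = "sleep 0.5", batch_size = 2,
                              jobs = 2))
  ev <- run$events
  overlapped <- FALSE
  for (i in unique(ev$batch[ev$type == "job_start"])) {
    js <- ev$time[ev$type == "job_start" & ev$batch == i]
    je <- ev$time[ev$type == "job_end" & ev$batch == i]
    nxt <- ev$time[ev$type == "scan_start" & ev$batch == i + 1L]
    if (length(nxt) && any(nxt >= min(js) & nxt <= max(je)))
      overlapped <- TRUE
  }
  expect_true(overlapped)
})

test_that("per-job stdout/stderr templates capture the streams", {
  fx <- fx_mid()
  wd <- run_dir_tmp()
  run <- run_pipeline(run_cfg(fx, command = "echo OUT-{BARCODE}; echo ERR >&2",
                              batch_size = 5, jobs = 2,
                              workdir_template = wd,
                              stdout_template = "{BARCODE}.out",
                              stderr_template = "{BARCODE}.err"))
  expect_identical(run$jobs_succeeded, 5L)
  for (bc in fx$barcodes) {
    expect_identical(readLines(file.path(wd, paste0(bc, ".out"))),
                     paste0("OUT-", bc))
    expect_identical(readLines(file.path(wd, paste0(bc, ".err"))), "ERR")
  }
})

test_that("without a file template the run directory ends empty", {
  fx <- fx_mid()
  run <- run_pipeline(run_cfg(fx, command = "true", batch_size = 2, jobs = 2))
  expect_length(list.files(run$run_dir, pattern = "\\.(bam|bai)$"), 0L)
})

test_that("a file template keeps (and names) the scBAMs", {
  fx <- fx_small()
  keep_dir <- run_dir_tmp()
  run <- run_pipeline(run_cfg(
    fx, command = "true", batch_size = 2, jobs = 2,
    file_template = file.path(keep_dir, "{BAMBASE}.{BARCODE}.bam")))
  expect_length(list.files(keep_dir, pattern = "\\.bam$"), 3L)
  bb <- bambase_of(fx$bam)
  for (bc in fx$barcodes)
    expect_true(file.exists(file.path(keep_dir, paste0(bb, ".", bc, ".bam"))))
})

test_that("--index creates a BAI before each command runs", {
  fx <- fx_small()
  keep_dir <- run_dir_tmp()
  run <- run_pipeline(run_cfg(
    fx, command = "test -e {}.bai", batch_size = 3, jobs = 1, index = TRUE,
    file_template = file.path(keep_dir, "{BARCODE}.bam")))
  expect_identical(run$jobs_failed, 0L)
  expect_length(list.files(keep_dir, pattern = "\\.bai$"), 3L)
})

test_that("--index on an unsorted input fails before any job launches", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted", "@SQ\tSN:chr1\tLN:1000",
               "r1\t0\tchr1\t10\t60\t5M\t*\t0\t0\tACGTA\tIIIII\tCB:Z:AAAA"),
             sam)
  bam <- sub("\\.sam$", "", sam)
  Rsamtools::asBam(sam, bam, overwrite = TRUE, indexDestination = FALSE)
  expect_error(
    run_pipeline(run_config(paste0(bam, ".bam"), "true",
                            barcode_source = "starsolo", index = TRUE)),
    "coordinate")
})

test_that("acceptance lists restrict scBAMs; empty cells skipped or emitted", {
  fx <- fx_mid()
  keep_dir <- run_dir_tmp()
  accept <- c(fx$barcodes[2:3], "GHOST-1")
  run <- run_pipeline(run_cfg(
    fx, command = "true", batch_size = 10, jobs = 1, acceptlist = accept,
    file_template = file.path(keep_dir, "{BARCODE}.bam")))
  expect_setequal(run$jobs$barcode, fx$barcodes[2:3])
  expect_identical(run$barcodes_skipped_empty, 1L)

  run2 <- run_pipeline(run_cfg(fx, command = "samtools view -c {} >/dev/null",
                               batch_size = 10, jobs = 1, acceptlist = accept,
                               emit_empty = TRUE))
  expect_setequal(run2$jobs$barcode, accept)
  expect_identical(run2$jobs_failed, 0L)
})

test_that("the (barcode, content, exit code) outcome is invariant to P and B", {
  fx <- fx_mid()
  outcome <- function(B, P) {
    keep_dir <- run_dir_tmp()
    run <- run_pipeline(run_cfg(
      fx, command = "samtools view -c {} > /dev/null", batch_size = B,
      jobs = P, file_template = file.path(keep_dir, "{BARCODE}.bam")))
    df <- run$jobs[order(run$jobs$barcode), ]
    data.frame(barcode = df$barcode,
               digest = unname(tools::md5sum(df$scbam)),
               exit = df$exit_code)
  }
  base <- outcome(2, 1)
  expect_identical(outcome(3, 2), base)
  expect_identical(outcome(5, 4), base)
})
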