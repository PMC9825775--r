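spec_cb <- function() preset_spec("starsolo")

test_that("enumerate_barcodes returns first-seen order, honors limit and lists", {
  fx <- fx_small()
  expect_identical(enumerate_barcodes(fx$bam, spec_cb()), fx$barcodes)
  expect_identical(enumerate_barcodes(fx$bam, spec_cb(), limit = 2),
                   fx$barcodes[1:2])
  # acceptance list passes through untruncated and unchecked for presence
  expect_identical(
    enumerate_barcodes(fx$bam, spec_cb(),
                       acceptlist = c("NOT-IN-BAM", fx$barcodes[1])),
    c("NOT-IN-BAM", fx$barcodes[1]))
  expect_identical(
    enumerate_barcodes(fx$bam, spec_cb(),
                       acceptlist = c("b9", "b1", "b2"), limit = 2),
    c("b9", "b1"))
})

test_that("a batch's scBAMs match a naive per-barcode extraction, record for record", {
  fx <- fx_small()
  out <- run_dir_tmp()
  res <- demux_batch(fx$bam, fx$barcodes, spec_cb(), out_dir = out)
  expect_identical(sort(names(res$paths)), sort(fx$barcodes))
  for (bc in fx$barcodes) {
    got <- bam_records(res$paths[[bc]])
    expect_identical(got, oracle_extract_tag(fx$bam, bc, "CB"),
                     label = paste("naive oracle,", bc))
    expect_identical(got, samtools_d_extract(fx$bam, bc, "CB"),
                     label = paste("samtools -d oracle,", bc))
    expect_length(got, 10L)
  }
})

test_that("scBAM headers are byte-identical and records keep input order", {
  fx <- fx_mid()
  out <- run_dir_tmp()
  res <- demux_batch(fx$bam, fx$barcodes[1:3], spec_cb(), out_dir = out)
  input_header <- bam_header(fx$bam)
  input_records <- bam_records(fx$bam)
  for (p in res$paths) {
    expect_identical(bam_header(p), input_header)
    recs <- bam_records(p)
    # subsequence of the input stream: positions strictly increasing
    idx <- match(recs, input_records)
    expect_false(anyNA(idx))
    expect_true(all(diff(idx) > 0))
  }
})

test_that("demux accounting is lossless and matches the truth table", {
  fx <- fx_mid()
  out <- run_dir_tmp()
  res <- demux_batch(fx$bam, fx$barcodes, spec_cb(), out_dir = out)
  s <- res$stats
  expect_identical(s$total_records, nrow(fx$reads))
  expect_identical(s$total_records,
                   s$assigned + s$unbarcoded + s$rejected_by_acceptlist +
                     s$outside_regions)
  expect_identical(s$assigned, sum(fx$reads$status == "assigned"))
  expect_identical(s$unbarcoded, fx$n_unbarcoded + fx$n_sentinel)
  expect_identical(sum(s$per_barcode), s$assigned)
  expect_identical(as.integer(s$per_barcode[names(fx$per_barcode)]),
                   as.integer(fx$per_barcode))
  # sum of emitted scBAM record counts equals assigned
  counts <- vapply(res$paths, function(p)
    as.integer(system2("samtools", c("view", "-c", shQuote(p)), stdout = TRUE)),
    integer(1))
  expect_identical(sum(counts), s$assigned)
})

test_that("an acceptance list rejects other barcodes in the accounting", {
  fx <- fx_mid()
  out <- run_dir_tmp()
  keep <- fx$barcodes[1:2]
  res <- demux_batch(fx$bam, keep, spec_cb(), out_dir = out, accept = keep)
  s <- res$stats
  expect_identical(names(s$per_barcode), keep)
  expect_gt(s$rejected_by_acceptlist, 0L)
  expect_identical(s$total_records,
                   s$assigned + s$unbarcoded + s$rejected_by_acceptlist +
                     s$outside_regions)
})

test_that("region restriction emits exactly the overlapping records, once", {
  fx <- fx_mid()
  bc <- fx$barcodes[[1]]
  truth_bc <- fx$reads[!is.na(fx$reads$barcode) & fx$reads$barcode == bc, ]
  # span covering roughly half of this cell's reads
  cut <- sort(truth_bc$pos[truth_bc$contig == "chr1"])
  cut <- cut[ceiling(length(cut) / 2)]
  regions <- parse_regions(sprintf("chr1:1-%d", cut), fx$bam)

  # linear-scan path
  out1 <- run_dir_tmp()
  r1 <- demux_batch(fx$bam, bc, spec_cb(), out_dir = out1, regions = regions,
                    use_index = "no")
  # index-fetch path must agree record for record
  out2 <- run_dir_tmp()
  r2 <- demux_batch(fx$bam, bc, spec_cb(), out_dir = out2, regions = regions,
                    use_index = "yes")
  got1 <- bam_records(r1$paths[[bc]])
  got2 <- bam_records(r2$paths[[bc]])
  expect_identical(got1, got2)

  # oracle: region fetch + per-record barcode filter
  oracle <- samtools_d_extract(fx$bam, bc, "CB")
  f <- strsplit(oracle, "\t", fixed = TRUE)
  pos <- vapply(f, function(x) as.integer(x[4]), integer(1))
  ctg <- vapply(f, function(x) x[3], character(1))
  len <- vapply(f, function(x) as.integer(sub("M", "", x[6])), integer(1))
  keep <- ctg == "chr1" & pos <= cut & (pos + len - 1) >= 1
  expect_identical(got1, oracle[keep])
  expect_false(any(duplicated(got1)))
  # conservation holds under region restriction (linear path sees all records)
  s <- r1$stats
  expect_identical(s$total_records,
                   s$assigned + s$unbarcoded + s$rejected_by_acceptlist +
                     s$outside_regions)
  expect_gt(s$outside_regions, 0L)
})

test_that("overlapping user regions never duplicate a record", {
  fx <- fx_small()
  regions <- parse_regions("chr1:1-40000,chr1:20000-50000", fx$bam)
  expect_identical(nrow(regions), 1L)
  out <- run_dir_tmp()
  res <- demux_batch(fx$bam, fx$barcodes[[1]], spec_cb(), out_dir = out,
                     regions = regions)
  recs <- bam_records(res$paths[[1]])
  expect_false(any(duplicated(recs)))
})

test_that("requiring the index without one present is an instructive error", {
  fx <- fx_small()
  noidx <- tempfile(fileext = ".bam")
  file.copy(fx$bam, noidx)
  regions <- parse_regions("chr1:1-1000", fx$bam)
  expect_error(
    demux_batch(noidx, fx$barcodes[[1]], spec_cb(),
                out_dir = run_dir_tmp(), regions = regions,
                use_index = "yes"),
    "index")
  # auto mode falls back to a linear scan and still works
  res <- demux_batch(noidx, fx$barcodes, spec_cb(),
                     out_dir = run_dir_tmp(), regions = regions,
                     use_index = "auto")
  expect_identical(res$stats$total_records, nrow(fx$reads))
})

test_that("absent barcodes produce no scBAM unless emit_empty asks for one", {
  fx <- fx_small()
  out <- run_dir_tmp()
  res <- demux_batch(fx$bam, c(fx$barcodes[[1]], "GHOST-1"), spec_cb(),
                     out_dir = out,
                     accept = c(fx$barcodes[[1]], "GHOST-1"))
  expect_identical(names(res$paths), fx$barcodes[[1]])
  expect_identical(unname(res$stats$per_barcode["GHOST-1"]), 0L)

  res2 <- demux_batch(fx$bam, c(fx$barcodes[[1]], "GHOST-1"), spec_cb(),
                      out_dir = run_dir_tmp(),
                      accept = c(fx$barcodes[[1]], "GHOST-1"),
                      emit_empty = TRUE)
  expect_setequal(names(res2$paths), c(fx$barcodes[[1]], "GHOST-1"))
  ghost <- res2$paths[["GHOST-1"]]
  expect_length(bam_records(ghost), 0L)
  expect_identical(bam_header(ghost), bam_header(fx$bam))
  # an empty-but-valid scBAM still indexes cleanly
  expect_silent(index_scbam(ghost))
  expect_true(file.exists(paste0(ghost, ".bai")))
})

test_that("indexing an scBAM enables region fetch identical to a linear filter", {
  fx <- fx_small()
  out <- run_dir_tmp()
  res <- demux_batch(fx$bam, fx$barcodes[[1]], spec_cb(), out_dir = out)
  p <- res$paths[[1]]
  index_scbam(p)
  fetched <- as.character(system2("samtools",
                                  c("view", shQuote(p), "chr1:1-50000"),
                                  stdout = TRUE))
  linear <- bam_records(p)
  f <- vapply(strsplit(linear, "\t", fixed = TRUE), `[[`, character(1), 3)
  expect_identical(fetched, linear[f == "chr1"])
})

test_that("indexing refuses a header without coordinate sort order", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted", "@SQ\tSN:chr1\tLN:1000",
               "r1\t0\tchr1\t10\t60\t5M\t*\t0\t0\tACGTA\tIIIII\tCB:Z:AAAA"),
             sam)
  bam <- sub("\\.sam$", "", sam)
  Rsamtools::asBam(sam, bam, overwrite = TRUE, indexDestination = FALSE)
  expect_error(index_scbam(paste0(bam, ".bam")), "coordinate")
})

test_that("identical inputs and configuration give identical scBAM bytes", {
  fx <- fx_small()
  d1 <- run_dir_tmp(); d2 <- run_dir_tmp()
  r1 <- demux_batch(fx$bam, fx$barcodes, spec_cb(), out_dir = d1)
  r2 <- demux_batch(fx$bam, fx$barcodes, spec_cb(), out_dir = d2)
  m1 <- unname(tools::md5sum(sort(unname(r1$paths))))
  m2 <- unname(tools::md5sum(sort(unname(r2$paths))))
  expect_identical(m1, m2)
})

test_that("filename collisions after sanitization are refused", {
  fx <- fx_small()
  expect_error(
    demux_batch(fx$bam, c("AC GT", "AC/GT"), spec_cb(),
                out_dir = run_dir_tmp(),
                accept = c("AC GT", "AC/GT"), emit_empty = TRUE),
    "collide")
})
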