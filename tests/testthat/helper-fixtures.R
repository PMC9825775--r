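# Shared fixture cache: each named fixture is generated once per test run.
.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, spec) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    bam <- file.path(tempdir(), paste0("fx_", name, ".bam"))
    assign(name, generate_fixture(spec, bam), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

fx_small <- function() {
  # 3 cells x 10 reads, CB tags: the worked micro-example
  cached_fixture("small", fixture_spec(n_barcodes = 3, reads_per_barcode = 10,
                                       encoding = "tag_CB", seed = 7))
}

fx_mid <- function() {
  # 5 cells, mixed fractions, for accounting and pipeline tests
  cached_fixture("mid", fixture_spec(n_barcodes = 5, reads_per_barcode = 20,
                                     unbarcoded_fraction = 0.1,
                                     sentinel_fraction = 0.05,
                                     encoding = "tag_CB", seed = 11))
}

fx_accept <- function() {
  # acceptance-scale fixture: 50 cells x 200 reads
  cached_fixture("accept", fixture_spec(n_barcodes = 50,
                                        reads_per_barcode = 200,
                                        unbarcoded_fraction = 0.05,
                                        sentinel_fraction = 0.02,
                                        encoding = "tag_CB", seed = 42))
}

# ---- independent helpers (kept deliberately naive) ----------------------

# raw record lines of a BAM, in file order
bam_records <- function(bam, args = character()) {
  out <- system2("samtools", c("view", args, shQuote(bam)), stdout = TRUE)
  as.character(out)
}

bam_header <- function(bam) {
  as.character(system2("samtools", c("view", "-H", "--no-PG", shQuote(bam)),
                       stdout = TRUE))
}

# Naive one-barcode-at-a-time extraction oracle, written independently of
# the package's routing engine: scan every record line, keep those whose
# barcode (located by simple field inspection) equals `bc`.
oracle_extract_tag <- function(bam, bc, tag = "CB") {
  lines <- bam_records(bam)
  keep <- vapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    hit <- grep(paste0("^", tag, ":Z:"), f[-(1:11)], value = TRUE)
    length(hit) == 1 && substring(hit[1], 6) == bc
  }, logical(1), USE.NAMES = FALSE)
  lines[keep]
}

oracle_extract_qname_token <- function(bam, bc, delim = "_", index = -2) {
  lines <- bam_records(bam)
  keep <- vapply(lines, function(l) {
    qn <- strsplit(l, "\t", fixed = TRUE)[[1]][1]
    tok <- strsplit(qn, delim, fixed = TRUE)[[1]]
    t <- length(tok)
    if (index >= t || index < -t) return(FALSE)
    j <- if (index >= 0) index + 1 else t + index + 1
    tok[j] == bc
  }, logical(1), USE.NAMES = FALSE)
  lines[keep]
}

# samtools' own tag filter: the second, fully external oracle
samtools_d_extract <- function(bam, bc, tag = "CB") {
  as.character(system2("samtools",
                       c("view", "-d", shQuote(paste0(tag, ":", bc)),
                         shQuote(bam)), stdout = TRUE))
}

run_dir_tmp <- function() {
  d <- tempfile("scb_test_")
  dir.create(d)
  d
}
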