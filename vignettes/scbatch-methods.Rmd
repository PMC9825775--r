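---
title: "Batched per-cell BAM extraction and command execution: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Batched per-cell BAM extraction and command execution: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The procedure

`scbatch` turns a pooled, cell-barcoded, coordinate-sorted BAM into a stream
of per-cell analyses. A run is defined by a barcode-extraction rule, an
accepted barcode set, a batch size `B`, a worker count `P`, and a command
template. It proceeds as:

1. **Accepted set.** With an acceptance list (`barcodes.tsv`-style, plain or
   gzip), the accepted barcodes are the list in file order, optionally
   truncated to `--limit`. Without one, discovery is folded into the first
   extraction pass: as the stream is scanned, each new extractable barcode is
   assigned a first-appearance index; records of the first `B` barcodes are
   buffered for writing during that same pass, the rest only have their
   indices memorized. A run with `n` accepted barcodes therefore always makes
   exactly `ceiling(n / B)` passes — discovery costs no extra scan.
2. **Extraction pass.** Each pass streams the record text once (via a
   `samtools view` pipe; BAM encoding and indexing go through `Rsamtools`),
   classifies every record (assigned / unbarcoded / rejected by the accepted
   set / outside the regions), and buffers the records of the current batch's
   barcodes in memory — memory is proportional to the batch's reads, never to
   the whole file. At pass end one scBAM per non-empty batch barcode is
   written: the header is copied byte-for-byte (no `@PG` line appended) and
   records keep input order, so a coordinate-sorted input yields
   coordinate-sorted, indexable scBAMs.
3. **Execution.** Each scBAM is optionally BAI-indexed, the command template
   is rendered, and the job is handed to a pool of forked workers bounded at
   `P` concurrent commands, each run through `/bin/sh -c` in its working
   directory, so pipes, list operators and redirection work exactly as at an
   interactive prompt. While jobs run, the main process already streams the
   next pass — extraction and execution overlap, and total wall time
   approaches `first pass + serialized job time / P` once a batch's jobs
   outlast a scan. When the command exits, its exit code and wall time are
   recorded and the scBAM (plus index) is deleted — unless a filename
   template was given, which switches the run to keep-mode.
4. **Accounting.** Every scanned record is counted exactly once:
   `total = assigned + unbarcoded + rejected + outside_regions`, and the
   per-barcode counts sum to `assigned`. This ledger, the per-job results and
   a timestamped event log (scan start/end, job start/end with exit codes)
   are returned in the run summary; `tidy()` and `glance()` expose them as
   tibbles and `plot_timeline()` draws the interleaving.

## Barcode extraction rules

Three rule families cover the common encodings:

* **tag** — a two-character `Z`-type tag. Presets: `cellranger` and
  `starsolo` read `CB` (corrected barcodes), `starsolo_raw` reads `CR` (raw
  barcodes); any other tag via `tag:XY`.
* **qname_token** — split the read name on a one-character delimiter and take
  a token; indices are 0-based and negative values count from the right,
  mirroring common slicing semantics. UMI-tools appends
  `_CELLBARCODE_UMI` to the read name, so its preset is token `-2` on `_`;
  the test suite verifies the preset recovers every truth barcode from reads
  named under that convention.
* **qname_regex** — a regular expression with exactly one capturing group.

A record from which the rule yields nothing is *unbarcoded* — never an
error. That covers an absent tag, an out-of-range token, a non-matching
regex, an empty value, and the `-` sentinel STARsolo writes into `CB` for
reads it could not assign; treating `-` as a real barcode would create a
garbage pseudo-cell, so it is mapped to unbarcoded. The CellRanger `-1`
GEM-well suffix is deliberately **not** stripped: barcodes are compared as
exact strings everywhere, which keeps behaviour lossless and matches
acceptance lists produced by the same pipeline.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `batch_size` | 100 | barcodes extracted per pass. 100–200 keeps workers busy; larger values trade memory (buffered reads of the batch) for fewer passes — with enough memory one pass can do everything. |
| `jobs` | detected cores | concurrent commands. The extraction thread competes with jobs for CPU, so on small machines `cores - 1` can be slightly faster. |
| `limit` | none | cap on cells, for focused analyses or debugging. Without an acceptance list the first `limit` barcodes by first appearance are kept and later ones are counted as rejected. |
| `regions` | none | restricts records to reference intervals (1-based inclusive strings or BED, which is 0-based half-open and converted on read). Overlapping or adjacent regions are merged first, so no record can be selected twice. |
| `index` | off | BAI-index each scBAM before its command runs (variant callers require this). Refused up front if the input header is not `SO:coordinate`. |
| `emit_empty` | off | write header-only scBAMs (and run jobs) for accepted barcodes with no reads, for consumers that require one output per listed cell. |
| `fail_fast` | off | stop launching after the first nonzero exit. Off by default because per-cell analyses routinely fail on sparse cells and one bad cell must not kill thousands of jobs. |

## Templating

`{}` is replaced by the scBAM path, `{BARCODE}` by the barcode, `{BAMBASE}`
by the input filename without path or final `.bam` — plain text replacement,
every occurrence, case-sensitive, no escaping (a literal `{}` cannot appear
in a command; documented limitation inherited from the `find`/`xargs`
convention). If a command template contains **no** token, the scBAM path is
appended at the end, exactly once; the presence of *any* token suppresses
appending — the literal reading of "no replacement tokens", and the same
behaviour `xargs -I` users expect. In filename, workdir and stdout/stderr
templates `{BARCODE}` substitutes the *sanitized* barcode (characters outside
`[A-Za-z0-9._-]` become `_`; post-sanitization collisions are an error), so
default paths are shell-safe; in the command template the raw barcode is
substituted, since commands may need the exact string. Relative
stdout/stderr paths resolve in the job's working directory, as a redirection
written inside the command would.

## Numerical and degenerate-input choices

* **Region semantics.** A record overlaps a region if its reference-aligned
  span (POS through the CIGAR's reference length, i.e. `M/D/N/=/X`
  operations, matching samtools' notion) intersects it. Unmapped records are
  excluded in region mode and included (if barcoded) otherwise. When a BAI
  index exists the merged regions are fetched randomly; otherwise a linear
  scan filters — both paths are tested to produce identical scBAMs. A read
  spanning two disjoint merged regions is de-duplicated in the fetch path.
  `use_index = "yes"` instead makes a missing index an error that tells the
  user to index.
* **Accounting under index fetch.** Random access never sees records outside
  the fetched intervals, so in fetch mode the ledger covers the fetched
  stream (`outside_regions = 0`). Whole-file conservation statements use the
  linear path, where every record is scanned.
* **Empty cells.** An accepted barcode with no records produces no scBAM and
  no job by default (counted as skipped); `emit_empty` restores one output
  per listed cell. Whether a listed-but-absent barcode should produce output
  is genuinely open; skipping avoids wasting jobs on empty input.
* **Exit status.** The tool exits 0 unless a fatal error occurred; job
  failures are data (recorded per cell) and change the exit status only
  under `fail_fast`. Usage errors exit 2.
* **Determinism.** Identical input and configuration produce identical scBAM
  bytes and identical `(barcode, content, exit code)` outcomes for any `P`
  and `B`; only scheduling order varies.

## The synthetic fixture generator

`generate_fixture()` emulates the pooled output of a droplet scRNA-seq
aligner: a coordinate-sorted, indexed BAM over a small reference (default two
50 kb contigs), 12-base barcodes with the CellRanger `-1` suffix, 40 bp
single-end full-match alignments, and a machine-readable truth table. Reads
from different cells are interleaved along the genome — occurrence *k* of
every cell lands near slot *k*, jittered — so batch extraction genuinely has
to skip over other cells' records, the realistic worst case for streaming.
Configurable fractions of reads are unbarcoded or carry the `-` sentinel.
Sequence content is deterministic pseudo-random and base qualities constant:
content is irrelevant to demultiplexing, and determinism enables byte-level
tests (same spec + seed = byte-identical BAM).

What the generator does **not** emulate — and hence what passing tests do not
show about real data: paired or spliced alignments, secondary/supplementary
records, UMIs, barcode sequencing errors (no whitelist correction is
attempted anywhere), expression structure, and realistic file sizes. The
correctness properties (losslessness, header/order preservation, pass
structure, templating, scheduling) do not depend on these, but performance on
multi-gigabyte inputs is only argued structurally (single pass per batch,
bounded buffering), not measured here.

## Problem sizes used by the test suite

Oracle-equivalence and accounting checks run on fixtures up to 50 cells ×
200 reads; pass-structure checks sweep `n ∈ {1, 5, 100}` cells against
`B ∈ {1, 2, 100, 1000}`; scheduling checks use 5 cells with deliberately slow
commands (`sleep`) and 2 workers. These sizes exercise every code path —
multi-batch discovery, partial final batches, empty cells, region
boundaries — while keeping the whole suite around a minute.

## Known limitations

* CRAM input, re-sorting, re-heading and alignment are out of scope; the
  input must already be a sorted, barcoded BAM.
* Record streaming shells out to `samtools view`; `samtools` must be on
  `PATH` (BAM writing/indexing uses `Rsamtools`' htslib).
* No cluster/scheduler submission or retries — the tool is deliberately a
  single-machine `xargs` analogue that slots *into* workflow managers rather
  than replacing them.
* Commands run in a shell by design; paths with shell metacharacters inside
  user-supplied templates are the user's responsibility (default scBAM names
  are sanitized to be shell-safe).
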