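# scbatch

Run any shell command on per-cell BAM files extracted, batch by batch, from a
pooled cell-barcoded scRNA-seq BAM.

## The problem

Droplet scRNA-seq aligners (CellRanger, STARsolo, UMI-tools pipelines) write
one coordinate-sorted BAM per sample in which every cell's reads are pooled,
distinguishable only by a cell barcode — carried in an auxiliary tag (`CB`
corrected, `CR` raw) or embedded in the read name. Tooling built for bulk
sequencing (variant callers such as GATK HaplotypeCaller or Strelka2,
coverage tools, splicing tools) expects one BAM per specimen. To apply such a
tool per cell you need one BAM per barcode — thousands of them — and
generating all of them up front hits open-file-handle limits, disk churn and
memory before the analysis even starts.

`scbatch` works the way `find | xargs` does, but for cells. For `n` accepted
barcodes and a batch size `B` it performs exactly `ceiling(n / B)` streaming
passes over the pooled BAM. Each pass extracts the single-cell BAMs
("scBAMs") of one batch — headers byte-identical to the input, records in
input order — and a bounded pool of at most `P` workers runs the user's
command on each scBAM while the *next* pass is already streaming. Memory is
proportional to the batch, not the number of cells; when no acceptance list
is given, barcode discovery is folded into the first pass, so the pass count
stays `ceiling(n / B)`. Each scBAM is indexed on request, handed to the
command, and deleted when the command exits (unless a filename template asks
to keep it). Total wall time is therefore roughly
`first pass + (serialized job time) / P` once jobs are slower than a scan.

Barcodes can be taken from any BAM tag (`tag:XY`), from a delimited read-name
token (`qname:<delim>:<index>`, 0-based, negatives from the right — the
UMI-tools `NAME_CELLBARCODE_UMI` convention is `qname:_:-2`), or from a
regular expression with one capturing group (`regex:...`); presets cover
CellRanger, STARsolo (CB/CR) and UMI-tools. Runs can be restricted to an
acceptance list (`barcodes.tsv`, plain or gzip), to genomic regions (samtools
strings or BED), and to a maximum number of cells. Commands are templated
xargs-style: `{}` is the scBAM path, `{BARCODE}` the cell barcode,
`{BAMBASE}` the input name without path or `.bam`; a token-free command gets
the scBAM path appended.

## Worked example

```r
library(scbatch)

# a pooled BAM standing in for STARsolo output: 4 cells x 25 reads
fx <- generate_fixture(
  fixture_spec(n_barcodes = 4, reads_per_barcode = 25,
               unbarcoded_fraction = 0.1, encoding = "tag_CB", seed = 42),
  "pooled.bam")
fx
#> <fixture_truth> pooled.bam: 111 record(s), 4 cell(s), 11 unbarcoded, 0 sentinel

# count each cell's reads, two cells per pass, two jobs at a time
run <- run_pipeline(run_config(
  "pooled.bam", command = "samtools view -c {} > {BARCODE}.count",
  barcode_source = "starsolo", batch_size = 2, jobs = 2))
run
#> <scbatch_run> 4 job(s) launched: 4 succeeded, 0 failed; 0 empty barcode(s) skipped
#> <demux_stats> 111 records: 100 assigned to 4 barcode(s), 11 unbarcoded,
#>   0 rejected by acceptance list, 0 outside regions

tidy(run)[, c("barcode", "batch", "exit_code")]
#> # A tibble: 4 × 3
#>   barcode        batch exit_code
#>   <chr>          <int>     <int>
#> 1 ACTCGGCCTTTC-1     1         0
#> 2 GTAGAATCTTGC-1     1         0
#> 3 GTAACTCCGGAA-1     2         0
#> 4 AAAACTCCATGT-1     2         0

list.files(pattern = "count$")
#> [1] "AAAACTCCATGT-1.count" "ACTCGGCCTTTC-1.count" "GTAACTCCGGAA-1.count"
#> [4] "GTAGAATCTTGC-1.count"
```

The 111 input records split losslessly: 100 assigned across the 4 cells, 11
unbarcoded; two extraction passes of two cells each ran four jobs, every
scBAM was deleted after its `.count` file was written, and `exit_code` is
recorded per cell (a failing cell is an outcome, not an abort).

The same run from a shell, via the bundled entry point:

```sh
exec/scbatch -i pooled.bam -b starsolo -B 2 -j 2 \
    -C 'samtools view -c {} > {BARCODE}.count'
```

Per-cell variant calling is the same pattern with a bigger command, e.g.
`-C 'gatk HaplotypeCaller -I {} -O {BARCODE}.vcf.gz -R ref.fa'` plus
`--index` (callers need a BAI) and `-L barcodes.tsv` to restrict to the
filtered cell list.

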