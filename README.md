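# mitosieve

Sorting true mitochondrial reads from NuMT reads in nanopore
modified-base BAM files, using per-read CpG methylation.

## The problem

Human mitochondrial DNA (mtDNA) — a 16,569 bp circular genome — carries
essentially no CpG methylation. Nuclear mitochondrial segments (NuMTs),
mtDNA-derived sequences integrated into the nuclear genome, are
methylated like the rest of nuclear DNA. Because NuMTs can be nearly
identical in sequence to mtDNA, reads originating from them routinely
cross-map onto the mitochondrial reference, inflating apparent
heteroplasmy and producing spurious mtDNA variant calls. Alignment alone
cannot separate the two origins; methylation can.

Oxford Nanopore sequencing of native DNA calls 5mC/5hmC directly during
basecalling and records the calls in the SAM `MM`/`ML` modified-base
tags. **mitosieve** is for anyone analysing mitochondrially aligned ONT
data — heteroplasmy quantification, mtDNA assembly, mitochondrial
disease studies, or the converse hunt for recently inserted NuMTs.

## The statistic

For each read, every 5mC call on a CpG cytosine of the read's own
sequence contributes a probability decoded from its ML byte *b* as the
bin midpoint *(2b + 1)/512*. A site counts as methylated when its
probability is ≥ 0.5 (tunable), and the read's methylation level is

```
f = (# CpG sites called methylated) / (# CpG sites assessed)
```

Reads with *f* < 15% go to a `minus_m` BAM (putative mtDNA); reads with
*f* ≥ 15% go to a `plus_m` BAM (putative NuMT). The 15% default sits in
the trough of the strongly bimodal distribution of *f* seen in real
mitochondrially aligned data. Validation statistics — per-read GC/AT
skew (chrM's forward strand has GC skew near −0.35), coverage, aggregate
5mC fractions, and the overlap with an orthogonal realignment-based read
set — quantify how clean the partition is. A seeded synthetic generator
produces chrM-like references and reads with valid MM/ML tags from a
bimodal methylation mixture, so the whole pipeline is testable offline.

## Worked example

```r
library(mitosieve)

cfg <- simulation_config(n_reads = 1000, seed = 7)   # 70% mtDNA / 30% NuMT class
fx  <- simulate_fixture(cfg, "mito_demo")            # reference.fasta, reads.bam, truth.tsv
res <- split_bam(fx$bam, "mito_demo/minus.bam", "mito_demo/plus.bam",
                 report_path = "mito_demo/profiles.tsv")
print(res)
#> modBAM partition at split threshold 0.15 (site call threshold 0.5)
#>   input reads:        1000
#>   minus-m (< 0.15):     695 -> mito_demo/minus.bam
#>   plus-m  (>= 0.15):    305 -> mito_demo/plus.bam
#>   no CpG (to_minus): 0
#>   unmapped excluded:  0

summarize_bam("mito_demo/minus.bam")
#> modBAM summary (reference chrM_sim, 16569 bp)
#>   UNIQUE READS                 695
#>   Coverage                     256.6
#>   GC%                          43.93
#>   GC skew                      -0.3474
#>   AT skew                      0.089
#>   Read length (mean)           6117
#>   Read length (median)         5294
#>   Unmodified C                 173686
#>   5mC                          3486
#>   Fraction 5mC (5mC/C + 5mC)   0.01968

numt <- fx$truth$read_id[fx$truth$true_class == "numt"]
overlap_report(numt, "mito_demo/plus.bam")
#> read-set overlap: 304 of 304 reference reads in query (100.0%; query size 305)
```

The partition recovers the simulated mixture: the `minus_m` file shows
the chrM-like composition signature (GC% ≈ 44, GC skew ≈ −0.35) and a
5mC fraction near the simulated mtDNA background (~0.02), the `plus_m`
file an aggregate 5mC fraction near 0.59, and every true NuMT-class read
lands in `plus_m`. On real data the same workflow runs on a basecalled,
chrM-aligned modBAM: `strip_modification_bam()` first removes 5hmC calls,
`split_bam()` partitions, and the `minus_m` output feeds variant calling.

There is also a command-line interface (installed under
`<library>/mitosieve/exec/mitosieve`) with `screen`, `split`, `summary`,
`overlap` and `simulate` subcommands:

```sh
mitosieve split aligned.bam --split-threshold 15% --json split_log.json
```

## Documentation

The methods vignette (`vignettes/methylation-read-sorting.Rmd`) explains
the per-read statistic, the MM/ML codec and its probability semantics,
the partitioning rules, what the synthetic generator does and does not
emulate, and the package's numerical choices and limitations.
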