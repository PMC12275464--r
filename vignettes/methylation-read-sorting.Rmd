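---
title: "Sorting mitochondrial from NuMT nanopore reads by CpG methylation"
author: "mitosieve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sorting mitochondrial from NuMT nanopore reads by CpG methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitosieve)
```

## The problem

Reads sequenced from a whole-genome nanopore run and aligned to the human
mitochondrial reference are a mixture of two origins. Most come from the
mitochondrial genome itself, a 16,569 bp circular molecule that is
essentially free of CpG methylation. The rest come from NuMTs — copies of
mitochondrial sequence integrated into the nuclear genome over
evolutionary time — which are CpG-methylated like the surrounding nuclear
DNA. Because NuMTs can be nearly identical in sequence to mtDNA, alignment
alone cannot separate the two, and NuMT contamination inflates apparent
heteroplasmy and produces spurious mitochondrial variant calls.

Nanopore sequencing of native DNA reads methylation directly: a
methylation-aware basecaller annotates each read with MM/ML tags recording
where 5mC (and optionally 5hmC) was called and with what probability.
mitosieve exploits this: it quantifies CpG methylation **per read** from
the MM/ML tags and partitions the BAM at a read-level methylation
threshold into an unmethylated `minus_m` file (putative mtDNA) and a
methylated `plus_m` file (putative NuMT).

## The per-read statistic

For read $r$ with assessable CpG sites $S_r$, each site $s$ carries a 5mC
probability $p_s$ decoded from its ML byte $b_s$ as the bin midpoint
$p_s = (2 b_s + 1)/512$. A site is called methylated when
$p_s \ge \tau_{\mathrm{call}}$ (default $0.5$), and the read methylation
level is

$$ f_r \;=\; \frac{\#\{s \in S_r : p_s \ge \tau_{\mathrm{call}}\}}{|S_r|}. $$

The read is labelled `minus_m` when $f_r < \tau_{\mathrm{split}}$ and
`plus_m` when $f_r \ge \tau_{\mathrm{split}}$, with
$\tau_{\mathrm{split}} = 0.15$ by default. The boundary belongs to
`plus_m`. The 15% default sits in the trough of the strongly bimodal
distribution of $f_r$ observed in mitochondrially aligned nanopore data
(most reads near 0, a secondary mode above ~55%), so the exact value is
not critical; both thresholds are tunable.

Which sites are assessable depends on the MM dialect. Under the explicit
`?` flag, only sites the basecaller actually called enter $S_r$. Under the
implicit dialect (`.` or no flag) the SAM specification asserts uncalled
canonical bases to be unmodified, so every CpG cytosine of the read enters
the denominator and uncalled ones count as unmethylated. 5mC calls at
non-CpG positions are excluded from the statistic and reported in a
diagnostic column. CpG context is taken from the read's own sequence
(as-sequenced orientation) rather than the reference — methylation-aware
basecallers call CpG context on the read, and this keeps the tool
reference-free.

## The MM/ML codec

MM positions are delta-encoded counts of skipped canonical-base
occurrences along the read *as sequenced*; for reverse-strand alignments
the stored SEQ is reverse-complemented before decoding and positions are
reported in as-sequenced coordinates. Multi-code runs (`C+hm`) consume ML
bytes interleaved per position. `decode_mod_tags()` and
`encode_mod_tags()` are exact inverses, which the test suite enforces by
fuzzing against a brute-force pointer-walking oracle.

Two details are worth calling out:

* **Probability semantics.** An ML byte $b$ encodes the interval
  $[b/256, (b+1)/256)$; we use the midpoint. Re-binning after arithmetic
  uses the exact inverse $b = \lfloor(512p - 1)/2\rfloor$, so a merged
  probability $p_m + p_h$ maps to byte $b_m + b_h$ (capped at 255).
* **Missing ML.** A record with MM but no ML is accepted with a warning
  and probability 1.0 per call, as the SAM specification permits.

Upstream pipelines discard 5hmC before screening so that only 5mC remains.
`strip_modification()` provides two policies: `"drop"` (default) discards
the 5hmC probability mass, leaving retained calls byte-identical;
`"merge_into_m"` adds it to the 5mC call at the same position, capped at
511/512. Whether a production pipeline's adjustment drops or folds the
5hmC mass is ambiguous in common tooling descriptions; we default to
`"drop"` because the 5mCG+5hmCG basecalling models emit the two as
competing hypotheses, and discarding one should not inflate the other.

## Partitioning rules

`split_bam()` excludes unmapped records, drops secondary alignments, and
routes supplementary alignments with their primary's label so a split
read never straddles the two outputs. Reads with no assessable CpG cannot
provide evidence either way; by default they go to `minus_m` (absence of
methylation evidence matches the unmethylated class and keeps mtDNA-poor
reads available for variant calling), configurable via `no_cpg_policy`
(`to_plus`, `separate_file`, `drop`) and a `min_cpg` floor. An optional
two-sided confidence band (e.g. ignore sites with $0.33 < p < 0.67$) is
available but off by default.

## Summary statistics

`summarize_bam()` reports, per BAM: unique mapped reads; mean depth of
coverage (aligned reference bases over reference length — depth, not
breadth, which matches the magnitudes such tables usually print); mean
per-read GC%; mean per-read GC skew $(G-C)/(G+C)$ and AT skew
$(A-T)/(A+T)$; mean and median read length (the field's tables rarely say
which, so both are reported); and aggregate 5mC call counts, with
`fraction_5mc` $= n_{5mC}/(C_{\mathrm{unmod}} + n_{5mC})$ where
"unmodified C" counts assessed calls below $\tau_{\mathrm{call}}$ (not
every cytosine in the reads — only calls present in the tags are
assessable).

Skews are computed on the **aligned-orientation** sequence (the stored
SEQ) and averaged unweighted across reads. This matters: the mitochondrial
forward strand has GC skew near $-0.35$, and since reads come off both
strands, averaging as-sequenced orientations would cancel toward zero. In
aligned orientation all reads report the reference-strand skew, so a
`minus_m` partition dominated by genuine mtDNA shows the known chrM
signature while NuMT-dominated partitions drift toward nuclear values.
Reads with no G+C (or A+T) are excluded from that mean only.

`methylation_histogram()` bins read methylation percentages into
half-open 5% bins (`[0,5), [5,10), ...`, last bin closed at 100) — the
diagnostic used to justify the 15% threshold.

`overlap_report()` quantifies agreement with an orthogonal assignment
(typically: reads that realign to a nuclear reference with chrM masked).
The denominator is the orthogonal (reference) set by convention; swap the
arguments to invert it. Read ids are de-duplicated, so reads realigning
to several nuclear loci count once.

## The synthetic generator

Real validation data for this problem are whole-genome nanopore runs —
far too large to ship or rebuild — so the package carries a generator
whose defaults define the study conditions used throughout the tests:

| parameter | default | rationale |
|---|---|---|
| reference length | 16,569 bp | human mtDNA length |
| GC%, GC skew, AT skew | 44, $-0.35$, $0.10$ | human chrM forward strand |
| NuMT weight | 0.30 | matches the ~70/30 bimodal split reported for mitochondrially aligned GIAB data |
| mito-class site methylation | Beta(1, 50) | low mode, mean $\approx 0.02$ |
| NuMT-class site methylation | Beta(6, 4) | high mode, mean $0.6$ |
| read length | log-normal, $\mu=\log 6000$, $\sigma=0.8$, truncated to [500, 16,569] | multi-kb nanopore reads, capped at one genome length |
| ML bytes | methylated: 200–255; unmethylated: 0–55 | confident calls either side of $\tau_{\mathrm{call}}$ |

The reference is i.i.d. with base frequencies solved exactly from the
three composition constraints ($g = \mathrm{GC}(1+s_{GC})/2$, etc.).
Reads start uniformly on the circle; reads that wrap the origin are
written as a primary plus a supplementary record sharing the read id,
which exercises the supplementary-labelling rule. Both classes draw their
sequence from the same reference — sequence near-identity is precisely
why alignment cannot separate the origins — and differ only in
methylation. Forward and reverse alignments are emitted 50:50, with MM
referring to the as-sequenced orientation. Optionally each CpG also
receives a low-probability 5hmC call (`with_hmc = TRUE`), producing
interleaved `C+hm` runs for the stripping step.

What the generator does **not** emulate: sequencing errors (no
substitutions or indels), basecaller-correlated methylation-calling
errors (site probabilities are drawn independently within a read from
clean high/low bands), nuclear flanking sequence on NuMT reads, and
coverage biases. Passing tests therefore demonstrate that the codec,
statistic and partitioning behave correctly and recover a clean bimodal
mixture; they do not certify classification accuracy on real data, where
intermediate-confidence calls and partially methylated NuMTs blur the
modes.

## Numerical and design choices

* Threshold boundary: exactly 15% is `plus_m`.
* A site is methylated iff $p \ge 0.5$; with the generator's ML bands no
  draw lands on the boundary, and 0.5 is the natural maximum-probability
  rule for a two-class call.
* Degenerate inputs: empty BAMs produce valid empty outputs and zeroed
  accounting; sequences with no G+C give `NA` skew; reads with no CpG give
  `NA` fractions and the `no_cpg` label; an all-`no_cpg` input leaves the
  histogram empty rather than failing.
* Determinism: every simulation quantity derives from one integer seed;
  the reference and the read stream use separated seeds so the two
  functions can be called in either order.
* Problem sizes in the shipped tests: unit tests simulate 40–300 reads;
  the end-to-end checks use one 10,000-read mixture, which gives the
  recovery and histogram assertions sampling error well inside their
  tolerances.

## Known limitations

* CRAM is not supported; BAM only.
* Only `m` and `h` get special handling; ChEBI-coded modifications are
  parsed and round-tripped but never interpreted.
* Per-site (pileup/bedMethyl) aggregation across reads is out of scope,
  as are realignment, reference masking and variant calling — the
  partitioned BAMs are intended as input to existing tools for those
  steps.
* With the default generator, the `minus_m` partition's aggregate 5mC
  fraction settles near the mito-class mean of $1/51 \approx 0.02$; real
  mtDNA data sit an order of magnitude lower. Lower the low-mode mean
  (e.g. `low_mode = c(1, 500)`) to emulate that regime.
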