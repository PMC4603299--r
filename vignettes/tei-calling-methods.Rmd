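---
title: "Calling transposable-element insertions from paired-end alignments: models, parameters and design choices"
author: "teiscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TEI calling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(teiscan)
```

# The detection model

A non-reference TE insertion (TEI) at reference position $j$ produces two
mapping signatures in a paired-end alignment against the reference:

1. **Discordant anchor pairs.** A fragment with one read in the unique
   flanking sequence and the other inside the inserted element maps with
   the flank read ("anchor") at its true position and the mate placed at
   some annotated copy of the same TE family elsewhere — TE families are
   multi-copy, so the inserted sequence is similar to an annotated copy.
   The pair is no longer a proper pair: it maps across chromosomes or at
   a distance far exceeding the fragment length.
2. **Soft-clipped junction reads.** Reads crossing the junction are
   truncated by the aligner, with the longer segment mapped and the
   shorter clipped; the clip boundary sits exactly at $j$.

Given library statistics (fragment mean $F$, sd $s_F$), a forward-strand
anchor with alignment $[b, e)$ predicts an insertion in
$[e,\; b + F + s\,s_F]$, a reverse-strand anchor in
$[e - F - s\,s_F,\; b]$. The dispersion multiplier $s$ (`s_factor`)
defaults to 2, consistent with the $2 s_F$ term in the generated
interval-length cutoff; the near bound is the anchor's inner edge because
the insertion must lie downstream of the read itself.

Anchors are accepted only when they are confidently and uniquely mapped:
mapping quality at least `mapq_min` (default 15, below which in practice
only false-positive support is found), mapping quality above 0, no
alternative-hit (XA-type) entries, and no overlap with the TE annotation
— insertions inside annotated TEs are deliberately not called. The mate
may map repetitively; it contributes the set of TE names overlapped by
its primary or any alternative placement.

## Clustering and pairing

Per strand, anchors are grouped into **maximal mutually-overlapping
interval sets** — the maximal cliques of the interval-overlap graph,
enumerated by a single left-to-right sweep (for interval graphs the sweep
enumerates exactly the maximal cliques; the test suite verifies this
against an exhaustive independent clique enumeration). Each cluster's
*interval* is the intersection of its members' predicted intervals.

Two design choices here were genuinely open:

* **Interval semantics are closed.** For a well-covered insertion the
  forward cluster's intersection interval is $[j, j+x]$ and the reverse
  cluster's is $[j-y, j]$: they meet exactly at the insertion point.
  Under strict half-open semantics such clusters would never pair and
  precisely the best-supported insertions would be lost (we observed
  14/16 saturated simulated insertions dropped before adopting closed
  semantics). All overlap tests on predicted intervals — clustering,
  isolation, forward/reverse pairing — therefore treat intervals as
  closed.
* **Isolation and ambiguity are resolved by discarding.** Clusters that
  share a member anchor or whose intersection intervals overlap are all
  discarded, and a cluster whose interval overlaps several opposite-strand
  cluster intervals is dropped together with all its partners. Both rules
  favour specificity over rescuing ambiguous constellations, which is the
  package's stated bias; they also guarantee that every anchor appears in
  at most one reported cluster.

A paired forward/reverse cluster calls one insertion with site interval
$[\max(\text{fwd starts}),\; \min(\text{rev ends})]$ (the innermost
reads). When read stacks cross ($lo \ge hi$, not addressed by the
geometry above), the interval collapses to the midpoint with length 0.

## Breakpoint and zygosity

Soft-clip boundaries with clip length at least `min_clip` (default 5 bp;
shorter clips are adapter/quality noise) and position within the site
interval (padded by the grouping tolerance) are grouped greedily
left-to-right within `clip_group_tol` (3 bp) of each group's first
member. The modal position of the best-supported group is the breakpoint;
ties on support break to the leftmost group and modal ties to the
smallest position, making the election deterministic. With no clipped
read, the call keeps its interval, has no breakpoint or zygosity, and
fails the clipped-support filter.

Zygosity is $\text{clipped}/(\text{clipped}+\text{core})$, where core
reads are proper-paired reads spanning the breakpoint by at least
`core_margin` (5 bp) per side. A read clipped at the breakpoint can never
satisfy the span condition, so the two evidence classes are mutually
exclusive by construction. Both evidence classes are subject to an
equivalent edge-window loss (clips need `min_clip` on the clipped side,
cores need `core_margin` on both sides), which is why the estimator is
centred on the true allele fraction rather than biased by the asymmetry
of having two junctions per insertion: only junction reads whose longer
segment lies in the flank are counted at the site, i.e. roughly half the
crossing reads of each junction.

## Filters

Default cutoffs are pure functions of the library statistics and
fold-coverage $C$ (user-supplied, otherwise mapped bases over reference
length rounded to one decimal):

$$2 < \text{cluster\_size} < 5C \qquad 2 < \text{span} < F$$
$$R < \text{interval\_length} < 2\,(F + 2 s_F - (R - s_R)) \qquad
  2 < \text{clipped\_support} < 5C$$

with $R, s_R$ the read-length mean and sd. All comparisons are strict;
cluster-size and span bounds apply to each strand's cluster separately.
TE-name consistency between the strands is computed and reported but not
enforced by default (no published cutoff exists for it). Cutoffs are
written into the run's config file so a later `filter` invocation is
exactly reproducible. Note that at high coverage a handful of saturated
call sites genuinely fail the strict `span < F` or
`interval_length > R` bounds; this is the designed specificity/sensitivity
trade of the formula cutoffs, not an artifact.

## Somatic classification

Filtered tumor (TD) calls whose 200 bp-padded interval overlaps no raw
normal (ND) call are putative somatic insertions. For each, the ND BAM is
interrogated in a `window` (default 200 bp, centred on the breakpoint or
interval midpoint): a discordant-read fraction of at least 2% marks a
germline insertion missed by the ND caller, and mean coverage below 8X
marks an unverifiable locus; the remainder are somatic. The window
default follows the method description; parts of the original benchmark
report a 400 bp window, so the width is exposed as a parameter.
`somatic_cutoff_sweep()` re-applies the classification over cutoffs
1%–3%.

# The synthetic-data generator

`make_sim_genome()` builds a random background genome with planted TE
families: one random consensus per family, copies diverged by a
configurable per-base substitution rate (default 2%), placed with a
minimum background gap. `plant_insertions()` draws donor copies
(uniformly among annotated copies of at least 200 bp, with replacement)
and insertion loci excluding 100 bp around annotated TEs and N runs, then
assembles sample alleles:

* **Normal design** — two alleles; homozygous insertions in both,
  heterozygous in one (true allele fractions 1.0 and 0.5).
* **Tumor design** — four allele copies (2 × allele1, allele2, allele3);
  insertions carried only by allele3 have allele fraction 0.25,
  emulating a 50% cancer-cell-fraction subclone.

`simulate_aligned_reads()` draws fragments per allele proportional to
copy number with Normal$(F, s_F)$ lengths (defaults 450 ± 40 bp, 100 bp
reads) and renders each read as an alignment against the *reference*
through the allele's exact liftover: fully-flanking reads become proper
pairs; reads inside an inserted TE are placed at the donor copy with
alternative-hit entries at the other family copies (mapq 0 when
ambiguous); junction reads are soft-clipped at the insertion point with
the longer segment mapped — to the flank when the flank segment is longer
(ties to the flank), otherwise into the donor. Proper-pair flags are
assigned geometrically (FR orientation, template length within 4
fragment sds of the mean), so fragments whose inner gap swallows an
insertion become short-distance improper pairs, exactly as an aligner
would flag them.

Deliberate simplifications, and what they mean for the benchmarks:

* Placement is emulated, not realigned, so substitution errors cannot
  move a read; SEQ/QUAL are omitted (`*`) by default and only generated
  (with substitution errors, default 0.5%) for FASTQ export to a real
  aligner. Benchmarks here therefore measure the caller's geometry, not
  aligner robustness.
* Donors are copy-pasted, not cut: at this scale (30 annotated copies,
  ~220 insertions) donors must be reused, and deletion scars at donor
  loci would add noise the genome-scale design largely avoids. Insertion
  signatures are identical either way.
* All insertions are forward-orientation; no target-site duplication is
  generated by default; no indel sequencing errors or GC bias. Passing
  benchmarks consequently bound performance on clean data from above —
  results on real libraries will be somewhat worse, mirroring the gap
  between simulated and validated real-data precision that motivates
  independent validation.
* TE family copies are treated as equally good placements for the mapq-0 /
  alternative-hit model regardless of the divergence parameter, matching
  the anchor-side repetitiveness rule.

`plant_insertions()` additionally enforces a minimum spacing between
insertion loci (default 2500 bp, about five fragment lengths) so each
event is independently resolvable; at genome scale random placement makes
collisions negligible, at desk scale the spacing plays that role.

# Scoring

`score_predictions()` matches calls to truth loci one-to-one by greedy
smallest-distance matching within a 20 bp pad — the padding at which the
caller's breakpoint accuracy saturates. Zygosity classification labels a
true positive homozygous when its estimate is at least 0.75 and otherwise
assigns the nearest sub-homozygous class *present in the truth design*
(0.5, and 0.25 only for tumor designs); the threshold set is a harness
choice, as the underlying benchmark reports accuracy without defining the
classifier. The somatic harness (`benchmark_somatic_pair()`) withholds a
seed-chosen subset of germline calls from the ND call set before the
TD−ND subtraction: a desk-scale ND run at 40X has almost no spontaneous
false negatives, and withholding recreates the false-negative regime that
the classification stage exists to handle, while the classifier still
sees the real ND alignments.

# Numerical and engineering choices

* Coordinates are 0-based half-open internally, converted only at the
  GFF/BAM boundaries (GFF and table output are 1-based inclusive).
* Library statistics use the population standard deviation over the first
  $10^6$ properly paired reads (exactly predictable on fixtures;
  indistinguishable from the sample sd at scale), with fragment length
  defined as the absolute template length of proper pairs. When fewer
  pairs than `min(100, max_pairs)` are available the estimator refuses
  and a config file must be supplied.
* Genomic chunking for parallel clustering nudges each nominal bin edge
  (default 50 Mb, flag `-b`) to the nearest position spanned by no
  predicted interval. Chunked and single-pass runs are therefore
  *identical* by construction, not merely approximately so, and the
  process count cannot change results.
* All generator functions take explicit seeds; identical seeds give
  byte-identical BAM output and identical call tables.
* Degenerate inputs: empty anchor sets, empty call sets, windows with no
  reads, and zygosity with zero informative reads all return well-defined
  empty/absent values rather than errors.

# Benchmark problem sizes

The shipped benchmark (tests and `scripts/acceptance.R`) uses a 3 Mb
single-chromosome genome with 3 families × 10 copies (500–3000 bp, 2%
divergence), 75 homozygous + 75 heterozygous germline insertions, 73
tumor-only insertions at 25% allele fraction, and coverages 10X/20X/40X —
large enough that per-class rates carry ~70–220 events, small enough that
the whole benchmark re-runs in minutes on one CPU. At this scale the 20X
detection rate of 25%-allele-fraction insertions has a binomial sd of
about 4 percentage points across seeds; point estimates should be read
with that in mind.

# Known limitations

* No split-read (supplementary-alignment) evidence; soft clips only.
* Insertions nested inside annotated TEs are not called, by design.
* Inter-chromosomal breakpoint pairing (translocation-style) is out of
  scope; forward/reverse clusters pair within a chromosome.
* Elements shorter than the read length cannot be represented by the
  simulator and are hard for the caller's signatures generally.
* The zygosity estimator assumes unbiased sampling of the two alleles at
  the junction; strong GC or mappability bias at a locus will distort
  allele fractions.
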