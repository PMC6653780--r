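---
title: "peakbench: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{peakbench: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakbench)
```

# The problem

Validating a new chromatin-profiling protocol or peak caller against an
established reference is awkward at the level of raw peak coordinates: peak
boundaries are caller- and depth-dependent, and set operations on ragged
intervals are ill-posed. The standard remedy is to project every peak set
onto **fixed non-overlapping genomic windows** and to do all comparisons in
window space, where positives, negatives and set overlaps are exactly
countable. `peakbench` implements this evaluation battery — windowed
ROC/precision–recall, Jaccard clusterograms, maxgap overlap accounting,
FDR-quantile recovery, saturation analysis, replicate correlation, metagene
and peak-centered profiling — plus a seeded synthetic generator so the whole
pipeline is testable with no external data.

Coordinates are 0-based half-open everywhere (BED convention). Abutting
intervals `[x,y)`, `[y,z)` have `gap() == 0` and therefore overlap at any
maxgap ≥ 0: maxgap semantics subsume plain intersection and avoid an
off-by-one special case at interval boundaries. Strict (≥ 1 bp) intersection
is used only where stated (fragment counting over regions).

# The windowed ROC/PRC model

Tile the genome into windows of width $w$; the universe size $N$ counts every
window on every chromosome (no mappability filtering — an exclusion-list hook
exists but defaults to empty). The reference $R$ is the window set of the
replicated reference peaks at 5% FDR; each candidate window is scored
$s = \max(-\log_{10} p)$ over the peaks overlapping it — a window is
evidence-positive if its best peak is. Sweeping a descending threshold $t$,
a window is predicted positive iff $s \ge t$, giving TPR $=$ TP$/|R|$,
FPR $=$ FP$/(N - |R|)$ and precision $=$ TP/(TP+FP), one curve point per
distinct score (tied windows enter together).

**Tie completion.** Windows hit by no peak share a single sentinel worst
rank and enter in one final step, closing the ROC at (1, 1) with a straight
segment. This makes the AUC always computable, and equal to the pairwise
ranking probability $P(s_\text{pos} > s_\text{neg}) + \tfrac12 P(\text{tie})$
— the property the acceptance suite verifies against a brute-force oracle to
$10^{-9}$. But when the scored windows recall only a small fraction of $R$
before that segment, most of the area comes from an uninformative straight
line: the AUC is *unfaithful*. `roc_prc()` reports
`scored_recall_max` (TPR at the last real threshold) and sets
`auc_valid = FALSE` below a validity floor of 0.75, the recall level below
which a shallow low-input dataset cannot meaningfully be ranked.

**PRC.** `auc_pr` is the trapezoid over recall with the strictest-threshold
precision extended to recall 0. Linear PR interpolation is slightly
optimistic versus step interpolation; it is used because it is simple,
deterministic and documented. The curve's terminal point has precision
$|R|/N$ (every window predicted positive).

**p versus q.** The sweep uses the $-\log_{10} p$ column by default (a
p-value threshold sweep); `score_windows(..., score_column = "q")` switches
to FDR if desired.

# Jaccard clusterograms

Dataset similarity is the binary Jaccard index $J = |A \cap B| / |A \cup B|$
on window sets built from peaks at 5% FDR ($J = 1$ for two empty sets), and
$D = 1 - J$ is a genuine metric (triangle inequality property-tested).
A signal-weighted variant is deliberately **not** implemented: the binary
window-set definition is the one that makes the distance a metric, and the
weighted form is left as a possible extension rather than guessed at.

Clustering is agglomerative with average linkage (UPGMA) by default — the
standard choice for similarity heatmaps when the linkage is otherwise
unspecified; single and complete linkage are options. The implementation is
in-package rather than `stats::hclust` because the contract requires a
deterministic tie-break (the smallest cluster-index pair wins), so
clusterograms are reproducible across platforms; on tie-free matrices it
agrees with `hclust` exactly, which the tests use as an independent oracle.
The result is `hclust`-compatible (`cutree`, `plot` work).

# Peak-level comparisons

`find_overlaps(A, B, maxgap)` counts partner peaks (gap ≤ maxgap, the
ChIPpeakAnno-style rule with the field's typical values 100/200 bp for
point/broad fly marks and 4000 bp for broad human marks) and the connected
components of the pooled partner graph. A single "overlap percentage" is
ambiguous — the denominator could be either set or the component count — so
the report carries all three: `pctA`, `pctB` and `pct_venn`, with no silent
guess. Note that while partner hit counts are non-decreasing in maxgap,
the **component counts are not**: two components each containing both sets
can coalesce at a larger maxgap, so `components$both` may drop. The
monotonicity property is therefore asserted on hit counts only.

`merge_replicates()` implements the "present in both replicates" reference
rule: filter at the FDR cutoff, keep peaks with a cross-replicate partner,
and collapse each connected component to its coordinate union carrying the
best member $-\log_{10} p/q$. The output is self-merged by construction (no
two consensus peaks within maxgap).

`fdr_quantile_recovery()` sorts candidates by increasing FDR (stable
coordinate tie-break), splits them into near-equal blocks — remainders go to
the lowest-FDR blocks — and reports the recovered fraction per block against
a reference at the mark's maxgap. Peak-level matching is the default;
window-level matching can be emulated by passing window sets through the
overlap machinery. `saturation_recall()` measures, per subsampled depth, the
fraction of full-depth peaks recovered; the subsampling depths are free
parameters. `random_matched_regions()` draws per-template same-chromosome,
same-length uniform regions with rejection against an exclusion list
(matching is by size only — no GC or mappability matching is attempted).

Peak annotation is a deliberate simplification to three categories
(Promoter / GeneBody / DistalIntergenic) by nearest-TSS assignment of the
peak summit (midpoint when absent), with a strand-aware promoter window of
±1 kb by default; exon/intron/UTR subcategories are out of scope.

# Coverage profiling

Coverage tracks are per-chromosome run-length-encoded step functions, so
megabase synthetic genomes and real chromosomes share one code path, and
raw-track mass is conserved exactly (sum of coverage = sum of fragment
lengths, an exact invariant in the tests). RPM normalization multiplies by
$10^6/\text{total fragments}$. Both whole-fragment and midpoint piling are
provided (`coverage_from_fragments()` / `coverage_from_midpoints()`), since
upstream pipelines differ on this and the choice is not always recoverable.

`bin_track()` + `pearson_bins()` give binned replicate correlation (2000 bp
and 500 bp are typical human/fly settings). Correlation runs over **all**
bins including zeros by default; `drop_joint_zero_bins = TRUE` exists purely
for sensitivity analysis. Zero-variance input is an error, not a silent NaN.

`metagene()` uses 1000 bp flanks in 20 bp bins and 100 gene-body bins by
default; the body-bin count and flank-bin width are conventions (common
practice, not externally fixed) and all three are parameters. Minus-strand
rows are reversed so column 1 is always 5′. Genes shorter than the body-bin
count, or whose flanks cross a chromosome end, are flagged and excluded from
the mean ± SEM summary — never zero-padded, which would bias flank columns
toward zero. SEM is $\mathrm{sd}/\sqrt{n}$ over unflagged rows (0 when a
single row remains).

`log2fc_profile()` computes $\log_2\!\big((s+\psi)/(c+\psi)\big)$ per region
per bin and then averages, which is what yields a per-column SEM band; the
pseudocount $\psi = 0.1$ RPM guards zero-control bins and is configurable.
The RPM default (rather than RPKM) follows the convention of reporting
per-position read density; both normalizations of the input track are the
user's choice since the function is agnostic to units.

`peak_centered()` builds ±1 kb matrices in 10 bp bins around summits, with
rows optionally sorted by decreasing mean of a *different* track over the
row span — the cross-dataset heatmap layout (profile the new dataset, sort
by the reference's affinities). Sorting is a permutation, so row means are
sort-invariant.

# The synthetic generator

The generator is a stated world, not a tuning knob. Defaults: a 1 Mb genome
in three chromosomes (500/300/200 kb) — large enough for thousands of
evaluation windows, small enough for sub-second simulation; 200 genes with
lognormal lengths (median 2 kb); point marks as TSS ± 500 bp regions on 20%
of genes (promoter-mark-like) or broad domains of 5–20 kb; enrichment
factors $e \sim \text{lognormal}(\log 8, 0.5)$ clipped to ≥ 1 (median
8-fold, the regime where a caller should succeed); replicate noise as a
lognormal factor with $\sigma = 0.2$ on $e$; $10^5$ fragments per replicate
with lengths $\mathcal N(200, 20)$ floored at 50 bp. Fragments pick a source
with weight proportional to genome length for background and
$\text{length}_i\,(e_i' - 1)$ for region $i$ — the excess-weight form makes
$e = 1$ mean exactly "no enrichment" — then place their midpoint uniformly
in the source and extend symmetrically; this keeps per-region expected
counts closed-form testable. Point regions of adjacent sampled genes can
collide; later regions are dropped to preserve the non-overlap invariant.

Every operation takes its randomness from the config seed through a
Lehmer-mix substream (plus the replicate index for fragments), restores the
caller's RNG state, and is byte-deterministic — verified across the suite.

**What the generator does not emulate:** sequence content (no FASTA/FASTQ),
GC and mappability bias, PCR duplicates, transposase insertion bias,
chromatin-state autocorrelation beyond the planted regions, and any mapping
from cell numbers to noise parameters. A green test therefore establishes
algorithmic correctness and qualitative behaviour (ranking, recovery
direction, saturation contrast), not quantitative agreement with any real
library.

# The surrogate caller

`call_peaks_poisson()` exists to produce realistically *ranked* p/q peaks
for downstream stages; it is explicitly not a reimplementation of a
production caller (no local background, no control track, no model
selection). Fragment midpoints are counted in 200 bp windows; the
background rate is the uniform expectation $\lambda = \text{total} \cdot
w/G$; the window p-value is the Poisson upper tail $P(X \ge k)$ (computed in
log space, floored at $10^{-300}$); q-values are Benjamini–Hochberg over
**all** tiled windows — conservative and deterministic. With a q cutoff,
significant windows within one window of each other merge into peaks
carrying the best member p/q and the summit at the highest-count window.

With `q_cutoff = NULL` (the "no FDR cutoff" ROC mode) the caller emits one
scored peak per window with ≥ 1 fragment and does **not** merge: merging
unthresholded windows would chain entire chromosomes into single peaks and
collapse the p-value ranking the threshold sweep needs, and dropping
zero-count windows is exactly what lets a shallow dataset leave reference
windows unscored — reproducing the unfaithful-AUC flag end-to-end (a clean
replicate and a 120-fragment weakly enriched dataset through the same
simulate → call → consensus → ROC path separate in AUC in ≥ 95/100 seeds,
with the shallow dataset tripping `auc_valid = FALSE`).

# Pipeline and configuration

`validate_config()` reads a JSON configuration (JSON rather than YAML: the
package adds no parsing dependency beyond `jsonlite`), rejects unknown keys,
duplicate labels, missing files and role conflicts before any compute, and
logs every applied default. `run_benchmark()` composes the stages —
consensus reference, per-candidate curves, similarity clusterogram, overlap
and quantile-recovery tables — into a report directory with a manifest
carrying the package version, seed and input MD5 checksums, so silent input
drift is detectable. Inputs are never mutated; reruns are byte-identical.

# Numerical and degenerate-input choices

- Missing narrowPeak fields use the format's own −1 sentinel.
- `jaccard` of two empty sets is 1 (identical sets), keeping $1-J$ a metric.
- Empty fragment files are valid (`total = 0`); RPM normalization of an
  empty set is an error, not NaN.
- BH q-values and Poisson tails are floored at $10^{-300}$ before
  $-\log_{10}$ to avoid infinities at extreme enrichment.
- Quantile blocks put remainders in the lowest-FDR blocks; sorting is
  stable with coordinate tie-breaks, so quantile membership is reproducible.
- Rejection sampling (gene placement, matched random regions) has an
  explicit bounded budget: placement failure is an error advising a smaller
  request; region sampling accepts the last candidate with a warning after
  `max_tries`.

# Known limitations

No confidence bands on curves, no partial AUC, no mappability-aware
universes, no bootstrap support on dendrograms, no signal-weighted Jaccard,
no GC-matched null regions, no exon-level annotation, and the CLI covers the
principal stages rather than every function. BAM/bigWig adapters are not
included: fragments and coverage enter as BED/tagAlign and bedGraph text,
keeping the computational core format-agnostic and testable without binary
fixtures.
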