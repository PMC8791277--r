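---
title: "Statistical methods behind proxiscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind proxiscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxiscape)
```

`proxiscape` implements the downstream statistics of
hybridization-proximity labeling experiments: classifying which transcripts
and proteins sit near a probe-targeted nuclear RNA, asking whether the
labeled genes cluster in the genome, scoring how compartment-specific the
labeled proteome is, and characterizing the RNA-processing features
(read-through, intron retention, A-to-I editing in inverted SINEs) of the
labeled transcripts. This vignette describes the models and the design
choices; it does not report any empirical result beyond what the package's
tests and acceptance script compute.

## Coordinate and classification conventions

All coordinates are 0-based, half-open (BED convention); GTF input is
converted on read. A gene is reduced to its integer midpoint
`floor((start + end) / 2)` wherever a single coordinate is needed (window
assignment, interval overlap, intergenic distances), which keeps interval
arithmetic deterministic.

Classification thresholds are applied with **strict** inequalities, so
equality at a threshold always falls on the non-significant side:

* undetected: fewer than 5 reads in **more than** 50 % of samples
  (exactly 50 % low samples leaves a gene detectable);
* labeled transcript: fold enrichment > 1.5 **and** FDR < 1e-10;
* unlabeled transcript: fold enrichment < 1, **or** fold enrichment < 1.5
  with FDR > 0.1;
* enriched protein: fold enrichment > 2 and FDR < 0.05.

The labeled and unlabeled predicates cannot both hold (the first needs
FC > 1.5, the second FC < 1.5), so the four states partition the genes.
Detectable genes satisfying neither predicate are called AMBIGUOUS — a
term of this package, since the source framework names only the labeled
and unlabeled classes — and ambiguous genes are excluded from every
labeled-versus-unlabeled contrast.

## Exact-test machinery

The shared primitive is the one-sided Fisher exact test on the 2×2 table
(labeled-in, other-expressed-in; labeled-out, other-expressed-out),
computed as the hypergeometric upper tail P(X ≥ a). The test suite checks
it against an independent binomial-coefficient enumeration on every 2×2
table with total ≤ 30 and against `fisher.test(alternative = "greater")`.
Incidence contrasts (intron retention, inverted SINEs) use the Pearson χ²
statistic without continuity correction; when any expected cell is below 5
the exact test replaces χ² for small-sample validity.

Rank-sum tests (telomere distance, SI groups, contact intensity) are exact
by exhaustive enumeration of all group assignments for combined n ≤ 20 —
which handles ties exactly, unlike the standard exact path — and use the
tie-corrected normal approximation without continuity correction above
that.

## Genomic clustering

**Chromosome scan.** Per chromosome, the labeled count among expressed
genes is tested against the rest of the genome; q values are
Benjamini-Hochberg across chromosomes. Non-canonical contigs are pooled
into a single `chrUn` stratum by default, since unassigned contigs can
collectively carry signal that no individual contig shows.

**Sliding-window scan.** Windows of 5 Mb advance in 2.5 Mb steps anchored
at coordinate 0; the final partial window is kept so chromosome ends are
never silently dropped. Genes enter windows by midpoint only (no
fractional overlap), matching the midpoint convention of the resampling
procedure. Because the source framework annotates raw p values on its
figures without stating a window-level correction, both raw p and
genome-wide BH q are reported; selection uses q < 0.05 by default with a
`use_raw_p` switch. Selected windows form a greedy maximal non-overlapping
set in ascending p (ties: leftmost, then smallest chromosome name), making
the selection deterministic.

**Resampling null.** Chromosomes with more than one labeled gene qualify.
The real statistic is the pooled median of consecutive-midpoint distances
of labeled genes across qualifying chromosomes; each of n iterations
redraws, per chromosome, the same number of midpoints without replacement
from that chromosome's expressed genes and recomputes the pooled median.
Pooling distances across chromosomes before taking a single median follows
the procedure's literal description; a per-chromosome-median variant was
considered and rejected because it changes the statistic's meaning for
chromosomes with few labeled genes. P = (k + 1)/(n + 1) with k the count
of simulated medians **strictly** below the real one (ties count as not
smaller), so the minimum attainable p is 1/(n + 1) and the estimate is
never zero. Δmed is the median of simulated medians minus the real median
(a `delta_stat = "mean"` option exists); positive values mean
tighter-than-random clustering. An exhaustive-enumeration mode replaces
the sampler for small instances and is used by the tests to verify the
Monte-Carlo route.

**Telomere proximity.** The distance statistic is
`min(midpoint, chrom_length − midpoint)`; the underlying framework does
not name its test, so a one-sided rank-sum test (labeled distances
smaller) is this package's choice.

## Compartment-specific proteomics

Raw log2 fold enrichments versus the infusion control are clipped at 0
(LFE); the specificity index of protein j for compartment k is
SI(j,k) = LFE(j,k) / Σᵢ LFE(j,i). Rows with all-zero LFE are flagged
undefined rather than imputed, and are excluded from group tests. Defined
rows sum to exactly 1, and SI is equivariant under compartment permutation
and invariant to positive rescaling of a protein's LFE row. The
implementation is generic in the number of compartments; three is just the
motivating case. High-confidence sets require enrichment in the
compartment **and** a strict SI maximum — ties are assigned nowhere. The
capture-oligo shortlist filter keeps a protein when both capture
experiments exceed input more than 2-fold, both strictly exceed the sense
control after input normalization (strict inequality was chosen where the
source wording is ambiguous), and at least one capture signal exceeds its
sense counterpart more than 2-fold.

## Genomic context

Interval overlap uses the midpoint-in-merged-interval rule (an
`rule = "any"` switch gives ≥ 1 bp gene-body overlap), consistent with
window assignment; overlap flags are invariant under base-preserving
interval splits. Contact vectors are normalized by the per-chromosome
median of **non-zero** bins by default — zero bins typically mark
unmappable regions and would depress the median — with an
`include_zeros` flag; peaks are bins strictly above 1.5× the median, and
the whole operation is invariant to rescaling the raw vector. The contact
rank test compares labeled genes with the unlabeled expressed background
by default: the framework's phrasing compares against *all* expressed
genes, but overlapping samples break the rank-sum independence
assumption, so disjoint groups are the default and
`include_labeled_in_background = TRUE` restores the literal comparison.
Hybrid-read ranking keeps genes detected in both replicates, defines
density as reads per kb of gene and the expression-normalized number as
reads per TPM — two formulas this package had to fix, since the source
names both quantities without defining them; both are reported.

## RNA-processing features

Pol II densities are cpmk values
(`count × 1e6 / total aligned / (length / 1000)`). Matched unlabeled
controls are the largest top-k prefix of density-sorted unlabeled genes
whose prefix median is within `tol` of the labeled median, minimizing the
absolute difference first and preferring larger k on ties; `tol` is an
explicit required parameter because the matching procedure as originally
described names no tolerance. The returned subset's median offset is
attached and asserted in tests on every call.

The read-through window is 10 kb downstream of the annotated 3′ end,
strand-aware ([end, end + 10 kb) for "+", [start − 10 kb, start) for "−"),
clipped at chromosome bounds; the ratio of downstream to gene-body mean
coverage is invariant to rpm rescaling and undefined (flagged, excluded
from group statistics) at zero body coverage.

Inverted SINE pairs are two repeats of the same family on opposite strands
fully inside the region of interest; no maximum separation is imposed by
default (`same_family` and `max_gap` arguments relax or tighten the rule),
since the source names "inverted Alu SINEs" without a pairing definition.
Editing events store genomic ref/alt; the strand interpretation is applied
at filter time (ref A → alt G on "+" genes, ref T → alt C on "−" genes),
matching variant-caller output conventions. SNP subtraction is by position
only, mirroring interval-file subtraction without allele matching. The
per-repeat edited fraction uses summed alt counts over summed coverage at
**edited positions** (an all-covered-positions denominator is a documented
alternative); repeats without kept events score 0. Intron-retention flags
require ΔΨ strictly above 10 % and FDR strictly below 0.05 from the
upstream caller's per-intron table.

## The synthetic-data generator

Every analysis is exercised on generated data with planted truth; the
generator's defaults define the benchmark conditions used by the tests and
the acceptance script:

* genome: 3 chromosomes × 100 Mb, 3,000 genes with distinct
  uniform-random midpoints, fixed 2 kb spans (easy to verify density
  arithmetic by hand), log-normal TPM (meanlog 1, sdlog 1 — a realistic
  right-skewed bulk expression profile), Poisson counts over 6 samples;
* labels: 60 labeled genes, 80 % expected inside two planted 5 Mb cluster
  regions (binomially drawn, without replacement within pools);
* proteome: 300 proteins × 3 compartments, 50 planted specific per
  compartment at 2 log2 units effect over 0.3 SD noise — a clear but not
  trivial separation;
* context: exponential contact baseline with a 4× multiplicative gain on
  cluster bins; inverted Alu pairs planted downstream of 80 % of labeled
  versus 10 % of unlabeled genes; log-normal Pol II densities shifted
  2-fold for labeled genes; Poisson hybrid reads with a 5× labeled gain;
* editing: 100 true strand-consistent edits inside repeats plus 50 SNP
  contaminants at disjoint positions.

All generators are pure functions of (configuration, seed) within a given
R version; cross-version bit identity is not promised. Determinism,
capacity errors and type invariants are validated on emission, and truth
labels always accompany the data so recovery tests never re-derive them.

What the generator does **not** emulate: read-level noise (no FASTQ,
fragments or UMIs), mappability structure, GC or length biases,
correlated expression, overdispersed counts, linkage between SNPs, or
mass-spectrum level effects. Passing recovery tests therefore show that
the statistics detect the signals they target at realistic effect sizes
and that the implementations are internally consistent — not that the
pipeline is robust to every artifact of real libraries.

## Numerical choices and degenerate inputs

* All-zero 2×2 tables return p = 1; zero-marginal tables raise errors for
  χ².
* BH q values come from `p.adjust(method = "BH")` in every module.
* An all-zero contact vector, an empty library, an all-zero ppm input, a
  zero-sum SI row, and a zero-body-coverage read-through each either raise
  an informative error or return a flagged undefined value — never a
  silent NA.
* Window/bin assignment uses `floor` consistently; bins are matched by
  their start coordinate rather than positional index so partial vectors
  behave.
* Problem sizes in the test-suite recovery loops (100 seeds on the
  benchmark genome; 200 replicates at 500 resampling iterations for null
  calibration; exhaustive sweeps to N = 30 for the exact test) were chosen
  to give stable verdicts for the planted effect sizes while keeping the
  suite quick to run routinely.

## Known limitations

* The resampling null conditions on the observed per-chromosome labeled
  counts; it does not model uncertainty in the classification step itself.
* Midpoint-based overlap can miss very long genes straddling interval
  boundaries; the `any`-overlap switch is provided but changes the null
  slightly.
* The rank-sum normal approximation is used above combined n = 20 without
  continuity correction; p values very close to significance thresholds at
  moderate n should be interpreted with that in mind.
* The CLI wrapper only drives simulation and the end-to-end pipeline; the
  individual analyses are exposed as functions rather than subcommands.
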