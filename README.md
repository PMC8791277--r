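# proxiscape

Statistical toolkit for the downstream analysis of hybridization-proximity
labeling experiments — assays that biotinylate RNAs and proteins in the
molecular neighbourhood of a probe-targeted nuclear RNA (nucleolar 45S
pre-rRNA, paraspeckle NEAT1, perinucleolar-compartment PNCTR) and read the
labeled molecules out by sequencing or mass spectrometry against an
enzyme-infusion control.

`proxiscape` is aimed at computational biologists who have already run the
upstream quantification (differential-abundance tables, coverage tracks,
variant and intron-retention calls) and need the statistics that sit on top:

* **Classification** of transcripts as labeled / unlabeled / ambiguous /
  undetected from fold-enrichment and FDR against the infusion control
  (labeled: FC > 1.5 and FDR < 1e-10; unlabeled: FC < 1, or FC < 1.5 with
  FDR > 0.1; genes with < 5 reads in > 50 % of samples are undetected), and
  of proteins as enriched (FC > 2, FDR < 0.05).
* **Genomic clustering statistics**: per-chromosome one-sided Fisher exact
  tests with BH correction; a 5 Mb / 2.5 Mb sliding-window scan selecting a
  greedy maximal set of non-overlapping significant windows; a telomere
  proximity rank test; and a chromosome-matched resampling null comparing
  the pooled median intergenic distance of labeled genes with `n = 10,000`
  random same-size draws from the expressed genes of each qualifying
  chromosome,

  P = (k + 1) / (n + 1),

  where k counts simulated medians strictly below the real median, with
  Δmed = median(simulated medians) − real median as the effect size.
* **Compartment-specific proteomics**: proteins-per-million normalization
  and the specificity index

  SI(j,k) = LFE(j,k) / Σᵢ LFE(j,i),

  where LFE is the non-negative (clipped at 0) log2 fold enrichment of
  protein j in compartment i; high-confidence sets (enriched + strict SI
  maximum), SI group rank tests, and the capture-oligo shortlist filter for
  RNA-directed mass-spec tables.
* **Genomic context**: midpoint overlap of genes with interval annotations
  (e.g. nucleolus-associated domains) tested exactly; contact-vector
  normalization by the chromosome median with a strict 1.5× peak cutoff;
  contact rank tests; hybrid-read density ranking.
* **RNA-processing features**: cpmk densities and median-matched unlabeled
  control selection; strand-aware 3′ read-through ratios; inverted
  same-family SINE pair detection in downstream regions; strand-consistent
  A-to-G editing filters with SNP-position subtraction and per-repeat
  edited fractions; χ² (or exact, when counts are small)
  intron-retention incidence contrasts.
* A **synthetic-data generator** that plants every signal the analyses look
  for (clustered labeled genes, compartment-specific proteins, contact
  peaks, inverted SINE pairs, true edits plus SNP contamination) with
  ground truth attached, so the whole pipeline is testable without any of
  the original datasets.

## Worked example

```r
library(proxiscape)

cfg   <- sim_config(seed = 42)     # 3 x 100 Mb, 3,000 genes, 60 labeled,
genes <- simulate_gene_universe(cfg)  # two planted 5 Mb clusters
truth <- plant_labeled_clusters(genes, cfg)
status <- truth$status[match(genes$genes$gene_id, truth$gene_id)]

scan <- window_scan(genes, status)
print(scan)
#> window_scan: 117 windows, 2 selected (non-overlapping)
#>  chrom start     end n_labeled_in n_expressed_in         p         q selected
#>   chr2 4e+07 4.5e+07           24             50 7.783e-30 9.106e-28     TRUE
#>   chr1 4e+07 4.5e+07           24             54 8.568e-29 5.012e-27     TRUE

cluster_resampling_test(genes, status, n_iter = 10000, seed = 42)
#> Resampling null for labeled-gene clustering (monte-carlo)
#>   qualifying chromosomes: 3  labeled genes: 60
#>   real median intergenic distance: 209674 bp
#>   delta-med: 2391194 bp  (positive = tighter than random)
#>   p = (k + 1)/(n + 1) = (0 + 1)/(10000 + 1) = 9.999e-05
```

Both planted 5 Mb clusters are found: the scan selects exactly one
significant window over each planted region (24 of the 60 labeled genes in
each), and the resampling null rejects chance clustering at the smallest
attainable p for 10,000 iterations, with labeled genes packed about 2.4 Mb
tighter than random same-size draws.

The full pipeline, writing every report table (status, chromosomes,
windows, resample, telomere, si, high_confidence, overlap, contacts_norm,
hybrid_rank, editing, ir) as TSV:

```r
inp <- simulate_inputs(sim_config(seed = 1))
res <- run_pipeline(inp, outdir = "reports", seed = 1)
```

or from a shell via the thin wrapper:

```sh
Rscript inst/scripts/proxiscape.R simulate --outdir sim --seed 1
Rscript inst/scripts/proxiscape.R pipeline --outdir reports --seed 1
```

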