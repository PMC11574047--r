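# damidkit

Tissue-specific DamID analysis for R: chromatin-association profiling of
Dam-fusion proteins against a Dam-only control, and RNA polymerase DamID
(RAPID) expression calling — with a seeded synthetic-study generator so
the full pipeline is testable without any sequencing download.

## The problem

DamID fuses a protein of interest to *E. coli* Dam methyltransferase;
adenines in GATC motifs near the protein's chromatin binding sites are
methylated, and methylated **GATC fragments** (the intervals between
consecutive GATC motifs) are amplified and sequenced. An untethered
GFP::Dam sample measures plain chromatin accessibility and serves as the
denominator of every ratio. The same chemistry with Dam fused to a Pol II
subunit (RPB-6) turns gene-body methylation into a transcription proxy
(RAPID).

`damidkit` implements the complete downstream analysis used to compare a
nuclear-envelope protein (BAF-1) with a progeria-associated point mutant
in two *C. elegans* tissues:

* **Read filtering** — keep reads containing the DamID adapter
  (`CGCGGCCGAG`) whose genomic part starts at a GATC site; count reads
  per GATC fragment.
* **Normalization** — per bin or gene: add a pseudocount of 1, scale to
  relative reads per replicate, average replicates per side, form
  log2(fusion/control), and subtract the genome-wide mean:
  a centered log2 ratio track at 2 kb / 10 kb / 100 kb or gene level
  (genes extended by 500 bp on both sides).
* **Enrichment calling** — a self-contained negative-binomial Wald test
  (median-of-ratios size factors, trend-shrunk method-of-moments
  dispersions; FDR 0.05 by Benjamini–Hochberg), the stand-in for a
  DESeq2 analysis.
* **Differential association** — bins enriched for one fusion whose
  track difference exceeds 0.58 (fold change 1.5), with chromosome
  arm/center bias statistics against the autosome border table.
* **RAPID** — per-gene Pol II occupancy log2(Dam::RPB-6 / GFP::Dam),
  expressed-gene calling at FDR 0.05 against a permutation null, and
  deregulated genes with |Δlog2| > 1 reproduced in every replicate.
* **Set reports** — Venn overlaps, multi-dataset membership, and
  expression-category summaries with Wilcoxon tests.

## Worked example

The generator emulates the full study design — 2 tissues ×
{Dam::BAF-1, Dam::BAF-1(G12T), GFP::Dam} × 3 replicates over a 6 Mb toy
genome whose GATC sites are discovered, not planted:

```r
library(damidkit)

cfg    <- simulation_config(seed = 42)
genome <- simulate_genome(cfg)
genome$gm
#> GenomeModel: 6 chromosomes, 6e+06 bp, 23,638 GATC sites

dam <- simulate_damid_counts(cfg, genome)
rep <- run_binding_analysis(dam$counts, dam$samples, genome,
                            damidkit:::default_pipeline_params(seed = 42))

rep$per_tissue$hypodermis$venn
#> hypodermis: 829 genes bound by BAF-1, 820 by BAF-1(G12T);
#>   722 shared (78%), 205 specific (22%)

rep$per_tissue$hypodermis$differential_association$n
#> 5 BAF-1-preferential 10 kb bins (100% in arms),
#> 3 mutant-preferential bins (0% in arms)

rep$per_tissue$hypodermis$arm_center[["BAF-1"]]$summary
#>     group   n      q1  median     q3
#>       arm 330  0.3665  0.4743 0.5576
#>    center 170 -0.6309 -0.5381 -0.4496
#> arm vs center Wilcoxon q-value: 9.01e-75
```

The wild-type fusion sits ~1 log2 unit higher on autosome arms than in
centers (the planted arm bias is 1.0), the two fusion proteins share
most bound genes, and the differential bins recover the planted
genotype effects: wild-type-preferential bins on arms,
mutant-preferential bins in centers, mirroring the shifted-binding
phenotype the pipeline was built to detect.

The expression side follows the same pattern:

```r
rap  <- simulate_rapid_counts(cfg, genome)
erep <- run_expression_analysis(rap$counts, rap$samples, genome,
                                damidkit:::default_pipeline_params(seed = 42))
lengths(erep$per_tissue$hypodermis$expressed)   # expressed genes wt / mut
erep$per_tissue$hypodermis$n_up                 # reproducibly upregulated
erep$per_tissue$hypodermis$n_down               # reproducibly downregulated
```

Report-arithmetic helpers reproduce printed summary numbers exactly:

```r
percent_of_genome(1924, 2000, sum(ce11_chrom_lengths))  # 3.84 -> "3.8% of genome"
log2_to_fold_change(0.58)                               # 1.495 -> "fold change 1.5"
percent_change(16, 12)                                  # 25 (% reduction)
```

## Command line

```sh
Rscript -e 'damidkit::damid_cli()' simulate   --seed 7 --out sim_out
Rscript -e 'damidkit::damid_cli()' binding    --seed 7 --out binding_out
Rscript -e 'damidkit::damid_cli()' expression --seed 7 --out rapid_out
```

`simulate` writes FASTA, GFF3, per-sample fragment-count TSVs and the
sample sheet; the analysis subcommands write bedgraph tracks, enrichment
TSV/BED, gene lists, and a JSON report with the run manifest.

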