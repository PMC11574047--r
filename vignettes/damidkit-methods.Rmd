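---
title: "damidkit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{damidkit: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(damidkit)
```

This vignette is the package's own account of what it computes and why:
the measurement model, the statistical procedures, the parameters that
matter, what the synthetic generator does and does not emulate, and the
choices made where the design was genuinely open. It states no empirical
result that the test suite does not itself compute.

# The measurement

DamID tethers *E. coli* Dam methyltransferase to a chromatin protein;
GATC adenines near binding sites are methylated, methylation-specific
amplicons beginning at DpnI-cut GATC sites are sequenced, and signal is
quantified per **GATC fragment** — the interval between two consecutive
GATC motif starts. Two conventions fix all coordinate arithmetic:

* All intervals are 0-based, half-open. GFF3 input is converted from
  1-based closed on read; BED/bedgraph output is half-open.
* A GATC "site" is the motif start; a read is GATC-anchored when its
  genomic 5' end coincides with a site start. The first fragment of a
  chromosome (before any site) can seed no amplicon and is flagged
  accordingly.

Reads are retained when they contain the DamID adapter `CGCGGCCGAG`
anywhere (the adapter is searched, not required at position 0) and the
sequence 3' of its first occurrence matches the genome exactly at a
GATC site start. No mismatches are tolerated; real short-read alignment
against a reference assembly is out of scope, and the package instead
accepts externally produced fragment-count tables for real data.

# The normalization chain

For each replicate, over the chosen unit (bin of 2/10/100 kb, or gene):

1. add a pseudocount of 1 to every unit;
2. divide by the replicate total to obtain relative reads;
3. average relative reads across replicates on each side;
4. form `log2(fusion / control)` per unit;
5. subtract the genome-wide mean log2 ratio.

The pseudocount precedes scaling, and averaging happens on relative
reads *before* the ratio — both by the stated order of the procedure the
package reimplements. A `per_replicate_ratio` flag averages per-pair
log2 ratios instead, for sensitivity analysis. Centering makes the
track mean exactly zero (asserted to 1e-9), and swapping fusion and
control negates the track exactly.

Fragments are assigned to bins by fragment midpoint, so each fragment
contributes its whole count to exactly one bin and totals are conserved
across resolutions. Gene-level counting sums fragments whose midpoint
falls in the gene interval extended by 500 bp on both sides (strand
does not affect the extension); extended intervals may overlap, in
which case a fragment counts toward every covering gene.

A pseudocount of 0 is accepted as a limit case: with it, scaling a
replicate's counts by any constant leaves the track exactly unchanged.
This exact invariance is what the unit tests use; with the default
pseudocount of 1 the invariance is approximate at realistic depths.

# Enrichment calling

`nb_enrichment_test()` is a deliberate, self-contained stand-in for a
DESeq2 analysis, keeping its structural ingredients without the
dependency:

* **Size factors** — median-of-ratios over units positive in all
  samples, falling back to relative library size when none exists.
* **Dispersions** — per-unit method-of-moments estimates on normalized
  counts (with the `mean(1/s)` sampling correction), shrunk in moment
  space toward a fitted mean-dispersion trend `a0 + a1/mu` with a prior
  weight of 10 pseudo-degrees of freedom against the residual
  degrees of freedom. With one replicate per side dispersion cannot be
  estimated; the test degrades to Poisson and says so in an attribute.
* **Wald test** — per-group NB means fitted by Newton iteration with
  log link and size-factor offsets; the statistic is the log fold
  change over its Fisher-information standard error. All-zero units get
  p = 1; a group with zero total is scored as half a count so the
  statistic stays finite.
* **Direction** — p-values are two-sided; the `enriched` flag requires
  BH q below the FDR *and* fusion above control, mirroring how a
  "significantly more reads" question is asked of a two-sided test.

FDR control and power are property-tested: on seeded null simulations
(1000 bins, 3 vs 3, mean 100, dispersion 0.1) the fractions of p < 0.05
and q < 0.05 stay below 1.5x nominal, and 8-fold planted bins are
recovered at 45/50 or better. The FDR is applied genome-wide, not per
chromosome.

# Differential association and domain statistics

A bin prefers fusion A over fusion B when it is enriched for A versus
the Dam-only control *and* the difference of centered tracks exceeds
0.58 — strictly, so a difference of exactly 0.58 is excluded; 0.58 log2
units is a fold change of 1.5. The two preferential sets are disjoint
by construction.

Arm/center classification uses a per-autosome border pair
(arm | center | arm); positions below the first border or at/above the
second are "arm", the center is left-closed right-open, and bins are
classified by midpoint. The shipped border table covers the five
*C. elegans* autosomes. No usable border pair exists for chrX, so
X-linked bins are labelled `not_applicable` and excluded from
arm/center statistics rather than guessing a coordinate.

The arm bias of a preferential set is tested with a binomial test
against the genome-wide fraction of autosomal arm bins — the natural
null for "are these bins arm-enriched", chosen because the original
analysis names no specific test. Distribution comparisons between
groups of bins use two-sided Wilcoxon rank-sum tests (exact below 50
per group without ties, normal approximation with continuity and tie
correction otherwise), BH-corrected over the pair set; this wraps R's
`wilcox.test`, the same machinery the field uses, and is checked
against an exact enumeration oracle at small n.

# RAPID expression calling

Per-gene occupancy is `log2(Dam::RPB-6 / GFP::Dam)` on gene-summed,
pseudocounted relative counts, formed per replicate pair (paired by
index) and averaged. Occupancy is *not* genome-mean centered: its zero
is the accessibility baseline.

**Expressed genes.** The null distribution of occupancy is built by
permuting the fragment-to-gene assignment labels (B = 1000, seeded),
which preserves every gene's fragment count. Permuted draws are pooled
within strata of genes with similar fragment counts, whose sampling
variances are comparable. The test then uses a robust normal tail:
location = stratum median, scale = (median − lower decile)/z(0.9) of
the pooled draws, p = upper tail at the observed occupancy, BH over
genes, expressed = q < 0.05 with positive occupancy.

Two facts force the robust-tail step, and the package treats this as a
considered deviation from a plain exceedance count. First, B = 1000
bounds an exceedance p at 1e-3, which caps what BH can reject over
thousands of genes. Second, the permutation null is *competitive*: when
~10% of the genome carries real Pol II signal, permuted gene-shaped
fragment sets catch signal fragments and acquire a heavy upper tail, so
exceedance p-values for genuinely expressed genes stall near 1e-2 and
recall collapses — measured at ~0.75 against planted truth. Fitting
location and scale from the median and *lower* decile uses only the
signal-free side of the permuted distribution, mirrors the
null-mode-fitting logic of the gene-calling tool this replaces, and
stays calibrated under a global null (measured: zero false calls on a
signal-free world, p < 0.05 fraction 0.044).

**Deregulated genes.** Per gene, delta = mutant − wild-type occupancy
per replicate pair. A gene is `up` when *every* replicate delta exceeds
1 and the average does (strictly; 2-fold change), `down` symmetrically;
only genes expressed in either genotype are evaluated. Swapping the
genotypes swaps the sets exactly. With unequal replicate counts the
function refuses rather than guessing a pairing.

**Crosslink to binding.** Deregulated genes are joined with per-gene
centered binding tracks of the wild-type and mutant fusion and compared
with a two-sided paired t-test per direction class. "Excluding
outliers" is operationalized as dropping pairs whose difference lies
outside 1.5x IQR beyond the quartiles of the differences — a standard
rule chosen because no definition was stated; it is switchable
(`exclude_outliers = FALSE`). Fewer than 3 surviving pairs yields NA; a
zero-spread difference vector returns t = 0, p = 1 when all-zero and an
unbounded statistic otherwise.

# The synthetic world

The generator exists so every stage has a no-download test bed with
known truth. Its defaults *are* the stated study design, at desk scale:

| parameter | default | why |
|---|---|---|
| genome | 6 chromosomes x 1 Mb (5 autosomes + chrX) | desk-scale mirror of the worm karyotype |
| borders | 1/3 and 2/3 of each autosome | arm–center–arm partition |
| GATC density | emergent ~1/256 per bp | i.i.d. sequence; sites discovered by scanning, never planted |
| genes | 2000, lognormal length (mean 2 kb, sdlog 0.5), clamped to [0.2, 20] kb | worm-like gene sizes |
| min intergenic gap | 750 bp | see below |
| arm effect | +1 log2 on fusion samples over autosome arms | the arm-biased binding the analysis must recover |
| differential bins | 2% of autosomal 10 kb bins, ±1 log2 | planted genotype effect; in the first tissue mutant-preferential bins are drawn from centers, wild-type-preferential from arms |
| expressed genes | 200 per tissue, +2 log2 on RPB-6 over the gene's ±500 bp domain | transcription signal |
| deregulated genes | 36 up / 26 down per tissue, off→on / on→off (|Δ| = 2) | replicate-consistent deregulation |
| fusion depletion | −1 log2 over expressed domains | expressed genes avoid the nuclear envelope |
| NB dispersion | 0.1 per fragment | biological replicate noise |
| depth | 1e6 retained reads/replicate | low end of realistic libraries |
| replicates | 3 (binding), 2 (RAPID) | the study design |
| min mappable fragment | 25 bp | amplicons below primer scale are not sequenced; also makes read→fragment assignment unambiguous, so the FASTQ round trip is exact |

Three world-consistency choices deserve their reasoning on record:

* **Planted effects cover the ±500 bp methylation domain the pipeline
  measures.** Dam methylation spreads past transcript ends — that is
  why gene-level quantification extends intervals. Planting on the bare
  gene body instead dilutes every measured effect by the flank share
  (a planted occupancy of 2 reads as ~1.4), which silently turns the
  stated effect sizes into weaker ones.
* **Minimum intergenic gap 750 bp.** With a 500 bp domain extension,
  two adjacent measured domains can then share at most 250 bp of
  fragments, so spill from a neighbouring planted gene is bounded well
  below both the expression threshold and the deregulation threshold.
  Without it, genes packed at exponential gaps overlap domains heavily
  and planted truth stops being the measurable truth.
* **Deregulation does not stack.** Up-genes are off in wild type and on
  in the mutant; down-genes the reverse. Both carry |Δlog2| = 2 with a
  maximum local signal of 4x. Modelling up-genes as
  expressed-and-then-boosted (16x) makes their spill into neighbours
  mimic deregulation.

Placement is by stick-breaking: gene lengths are drawn, then the free
space is distributed as random gaps above the minimum; uniform
rejection placement cannot pack 2000 genes into 6 Mb. Gene-to-
chromosome allocation is proportional and deterministic.

What the generator does **not** emulate: mapping ambiguity and
mismatches, PCR duplicates, sequence composition bias, methylation
kinetics, fragment-length amplification bias beyond
rate ∝ length, operons, overlapping genes, and chrX-specific biology
(chrX receives no arm effect). A green recovery test therefore
establishes that the statistics recover planted structure under NB
sampling at realistic depth — not that they are robust to alignment
artefacts or library chemistry.

One stated invariance holds only in a limit: "doubling reads halves the
sampling spread" is true under Poisson noise, but NB dispersion adds a
depth-independent variance floor (at the default dispersion the floor
dominates at 1e6 reads). The variance-scaling test therefore runs at
dispersion 0, where the halving law is exact in expectation.

# Numerical conventions

* Percentages in overlap reports are rounded half away from zero, the
  convention of printed summaries (`round_half_up()`).
* The center interval of the arm/center partition is left-closed,
  right-open; bins classify by midpoint. Deterministic tie-breaking,
  stated once, used everywhere.
* BH is implemented as the literal step-up (`cummin` over descending
  p), computed in the same expression order as the brute-force oracle
  so agreement is exact to the last bit.
* All randomness flows from one root seed through fixed substreams per
  stage; reruns are byte-identical.
* Sub-25 bp fragments are excluded from the read index: they cannot be
  assigned by content (a 5 bp fragment's full sequence is one of four
  strings) and carry no reads in the simulated world.

# Known limitations

* The NB test omits DESeq2's independent filtering, Cook's-distance
  outlier handling, and fold-change shrinkage; its acceptance surface
  is FDR control and planted recovery, not bit-equality with DESeq2.
* The expressed-gene null is permutation-based with a parametric tail;
  heavy non-normality within a fragment-count stratum would miscalibrate
  it. The global-null simulation guards the regime the package targets.
* Real-data ingestion is via fragment-count tables; the built-in
  aligner is exact-match only and paired to the synthetic read emitter.
* The RAPID normalization reuses the binding chain; if an upstream
  pipeline normalizes bam files differently, gene occupancies shift by
  a monotone transform and the FDR machinery still applies, but
  absolute occupancy values are not comparable across pipelines.
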