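---
title: "utrscreen: models and methods"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{utrscreen: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utrscreen)
```

## The assay this package models

Massively parallel reporter assays (MPRAs) test thousands of candidate
regulatory sequences at once by cloning each into a common reporter and
reading the outcome by sequencing. `utrscreen` implements the computational
side of an MPRA that asks a post-transcriptional question: does a
single-nucleotide variant in a 3′ UTR change the mRNA abundance of its host
transcript? Each variant is synthesized twice — once with the reference
allele, once with the alternative — embedded in its native flanking sequence
inside the 3′ UTR of a reporter gene driven by a strong constitutive
promoter, so allele-dependent differences in steady-state mRNA reflect RNA
stability and related post-transcriptional mechanisms rather than
transcription.

Both the plasmid pool (DNA) and the transcribed output (RNA) are sequenced
with 15-nt unique molecular identifiers (UMIs), so PCR duplicates collapse to
molecule-level counts. The per-allele **activity score** is

$$A = \frac{C_{\mathrm{RNA}}}{C_{\mathrm{DNA}}},$$

the normalized RNA molecule count over the normalized DNA molecule count, and
the per-variant effect size is the **relative activity score**

$$\mathrm{lnFC} = \ln\!\frac{A_{\mathrm{alt}}}{A_{\mathrm{ref}}}.$$

A variant is called **functional** when its allele effect is significant at
Benjamini–Hochberg FDR ≤ 0.10 *and* |lnFC| ≥ 0.10. The 10% effect floor
mirrors the magnitude of effects observed for mutations inside well-known
regulatory motifs (AU-rich elements, Pumilio sites, constitutive decay
elements), which mostly exceed 10%.

## Oligo design

Synthesis oligos are always 200 nt. Three layouts are provided
(`oligo_layout()`):

| layout  | structure                                              | insert |
|---------|--------------------------------------------------------|--------|
| design1 | fwd primer (15) + EcoRI (6) + insert + BamHI (6) + rev primer (15) | 158 nt |
| design2 | fwd primer (15) + EcoRI (6) + insert + rev primer (15) | 164 nt |
| motif   | fwd primer (21) + EcoRI (6) + insert + rev primer (15) | 158 nt |

The variant sits at 0-based insert offset `floor((insert_len - 1) / 2)` — 81
for a 164-nt insert (81 nt upstream, 82 nt downstream). The insert is always
taken from the transcribed strand; minus-strand variants are assembled by
windowing the plus strand and reverse-complementing, which a property test
checks against a brute-force oracle. When the annotated UTR is too short to
center the variant, the window silently extends into flanking genomic
sequence via the genome accessor, matching how such inserts are designed in
practice; if the supplied sequence itself runs out, assembly stops with an
explicit error.

Candidate selection follows the screen's rules: population variants must be
single-nucleotide with adjusted minor allele frequency strictly below 0.01
(rare variants in the population-genetics sense); somatic candidates instead
require a catalog sample count strictly greater than 1, so each mutation has
been observed in at least two tumors. Inserts whose sequence (either strand)
contains a restriction site or subpool primer are rejected before synthesis
(`screen_sequences()`), because they would be cut or mis-primed during
cloning. `design_saturation_panel()` builds the motif-validation pool: every
position of a known motif and its 22–23-nt flanks mutated to all three
alternative bases.

## Read structure and UMI counting

Read 1 is fully structured: 15-nt UMI, 14-nt RT primer, 6-nt restriction
site, 15-nt subpool primer, then the first 100 nt of the designed sequence.
Read 2 is the reverse complement of the designed strand. `parse_read1()`
slices by fixed widths and does not validate the fixed segments (their
sequence carries no per-molecule information); reads shorter than the layout
are dropped and tallied.

Matching replaces a general aligner with a structured lookup
(`build_library_index()`, `match_to_library()`): references are short, fixed
and enumerable, so exact hashes of the read-1 fragment and of the read-2
window enumerate every candidate, and the assay's rule is applied literally —
a read pair is assigned iff it has at most one mismatch across the compared
bases and no mismatch falls on the designed SNP position of that reference.
With a single substitution, at least one mate still matches some reference
exactly, so hash probing is exhaustive; in fragment-only mode the
1-substitution neighborhood is probed explicitly. Pairs matching two
references equally well (including a mismatch at the SNP under both alleles)
are discarded and tallied as ambiguous rather than guessed. Read-2
orientation is auto-detected by trying the reverse complement first.

Deduplication keeps one read per (UMI, reference) pair; a UMI seen on two
different references counts once for each. UMIs are matched exactly — the
collision probability at $4^{15} \approx 10^9$ tags is negligible at
realistic depths, and no evidence supports 1-edit UMI clustering for this
library structure. Per-position mismatch rates (mapped reads only, terminal
15-nt primer regions excluded, uncovered positions reported as missing)
provide the library-quality profile.

## Normalization, testing and calling

Counts are quantile-normalized across replicates within each library type
(classic rank-mean normalization; tied counts receive the mean of the tied
target values). Activity uses replicate-summed normalized counts — summing
rather than averaging changes $A$ by a constant that cancels in lnFC.
Alleles with fewer than 10 deduplicated DNA molecules (summed over
replicates, configurable) are too poorly measured to score and are excluded.
When one allele has a zero count, lnFC is displayed with a 0.5 pseudocount;
the test never sees pseudocounts.

Significance comes from an explicit negative-binomial model of RNA counts as
a function of DNA counts:

$$\mathrm{RNA}_{a,r} \sim \mathrm{NB}(\mu_{a,r}, \theta), \qquad
\log \mu_{a,r} = \beta_0 + \beta_1 \cdot [a = \mathrm{alt}]
  + \log \mathrm{DNA}_{a,r},$$

with a likelihood-ratio test of $\beta_1$ against $\chi^2(1)$. One modeling
choice matters at three replicates: estimating a free dispersion per variant
from six observations makes the LRT strongly anti-conservative (we measured
12% type-I error at nominal 5%). The default therefore pools: a single
common dispersion is estimated across all (variant, allele) cells by a
method-of-moments calculation on the squared coefficient of variation of
replicate RNA/DNA ratios, minus the Poisson term; this conditional
dispersion also absorbs DNA-count sampling noise, which the offset model
needs. With the pooled value held fixed, the per-variant test is calibrated
(measured 5.2% at nominal 5%, uniform p-values). Per-variant maximum
likelihood remains available (`method = "per_variant_ml"`) for designs with
many replicates, and a Welch t-test on per-replicate log activity ratios is
the flagged fallback when a fit fails. This caller is a fully specified
replacement for external MPRA model-fitting tools, so its p-values are not
expected to reproduce any particular external implementation numerically.

## Mechanism statistics

*Sequence groups.* For each functional variant the 11-nt window around the
variant (5 nt each side) of the higher-expressed allele joins the
upregulating group and the lower-expressed allele's window the
downregulating group. Hexamer over-representation between the groups uses a
one-sided Fisher exact test per hexamer on window-containment counts with BH
correction — a deterministic, reproducible substitute for de novo motif
discovery; full PWM discovery is out of scope.

*Motif strength.* Against a position weight matrix with a uniform base
background, a window scores $S = \prod_i p_i / 0.25^n$ and a variant's
strength change is $\Delta = |S_{\mathrm{var}} - S_{\mathrm{ref}}|$. Two
nulls are provided: the same variants rescored under a column-shuffled PWM
(columns are permuted, preserving per-position information content; a
within-column shuffle is available), and count-matched nonfunctional
variants under the true PWM; each is compared to the functional deltas by a
two-sided Kolmogorov–Smirnov test. T and U are interchangeable throughout.

*Overlaps.* miRNA target sites are filtered to context++ score percentile
≥ 50 before overlap; a variant pairs with a site when its 0-based position
falls in the half-open interval. Direction bias of site-overlapping
functional variants (disrupting a repressive site should raise abundance) is
a one-tailed rank-sum test against non-overlapping functional variants; a
one-sample signed-rank alternative against zero is exposed because the
choice of comparison group is a genuine design freedom. eCLIP peak distances
use the convention: 0 inside a peak, else distance to the nearest covered
base. Predicted RBP binding deltas are consumed as input (the neural
predictor producing them is external); per RBP the functional distribution
is KS-tested against both nonfunctional and random-SNV controls and the
*maximum* of the two p-values is reported — the conservative convention.

## Permutation enrichment

The query set is the genes of the top 500 unique variants ranked by |lnFC|
across cell lines (ties broken by variant id for byte-reproducibility). Each
of `n_sets` control sets (default 10,000; reduce for desk-scale work)
replaces the query with genes sampled from the background *excluding* the
query, optionally matching each query gene's length and GC content within
±10% (the tolerance widens stepwise with a warning when no match exists).
For each term the query occurrence $k$ is compared to a normal fit of the
control occurrences: $p = 1 - \Phi((k - \mu)/\sigma)$, upper tail only,
because the question is enrichment. When $\sigma = 0$ the add-one empirical
p-value $(r+1)/(n_{\mathrm{sets}}+1)$ is used. Significance requires
FDR < 0.05 and occurrence ≥ 5. Annotations are counted as supplied — no
ontology-graph propagation. One caveat worth knowing: for a single term the
normal-fit p lives on an integer-occurrence lattice, so calibration studies
should pool over terms or instances rather than repeat one term.

## Clinical layer

A functional variant is **detrimental** if it increases an oncogene or
decreases a tumor suppressor, **benign** in the opposite cases, and
**ambiguous** when the driver role is ambiguous. Per patient, the
untranslated tumor mutational burden (uTMB) counts somatic mutations that
are also screen variants, in six categories: functional overall, functional
in driver genes, detrimental, benign, and the two nonfunctional control
counts. Patients are ranked into tertiles within a cohort (stable id order
breaks ties; group sizes differ by at most one) and the top tertile is
compared to the bottom by a standard two-sided log-rank test, the middle
excluded by default — top-versus-rest is a supported alternative since
two-group displays of tertiles leave the middle's fate open. Expression
outliers are carriers whose expression z-score against reference-homozygous
patients (at least 5, else the gene is skipped) exceeds |2|; carrier and
reference outlier proportions are compared by a two-sided Fisher exact test.
Both progression-free interval and overall survival are supported endpoints.

## The synthetic-data generator

Every pipeline input can be generated with known ground truth
(`sim_config()` and the `simulate_*` functions), fully determined by one
seed. The generator emulates: a designed library over random UTR contexts
screened for forbidden substrings; UMI families per oligo with gamma-Poisson
(negative-binomial) noise; RNA family means scaled by a per-variant baseline
and by $e^{\mathrm{lnFC}}$ for the alternative allele; PCR duplicates (mean
reads per family ≥ 1); uniform substitution errors; and a patient cohort
whose expression shifts with carried functional variants and whose
exponential survival hazard scales with uTMB, under independent uniform
censoring.

Defaults and why:

* `n_replicates = 3`, `dna_depth = rna_depth = 300` UMI families per oligo —
  three biological replicates at a depth where allele ratios are
  well-measured, the regime the calling thresholds were designed for.
* `dispersion = 0.002` — UMI deduplication removes PCR amplification noise,
  leaving family counts close to Poisson; the default adds slight
  overdispersion. No generative noise model is dictated by the assay itself,
  so this is an explicit, configurable stand-in.
* `error_rate = 0.001` per base — the order of magnitude of combined
  synthesis and sequencing error in such libraries (per-position mismatch
  rates of a few hundredths of a percent).
* `pcr_duplication_rate = 1.5` mean reads per family; effect sizes for
  functional variants default to |lnFC| ∈ [0.25, 1], with 30% of variants
  functional.
* UMIs are drawn uniformly over $4^{15}$; collisions are possible but
  negligible at these depths, so no collision repair is simulated.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: indels and structured (quality-dependent) errors,
adapter read-through, GC-dependent amplification bias, trans-factor
differences between cell types, correlated DNA/RNA sampling, and real
linkage between variants and clinical covariates. The generator validates
the pipeline's statistical behavior under its stated model, not the
biological realism of any particular dataset.

## Numerical choices and degenerate inputs

* The LRT statistic is clamped at 0 (optimizer noise can make the nested
  difference infinitesimally negative); identical allele counts short-circuit
  to statistic 0, p = 1.
* Offsets use `log(pmax(DNA, 0.5))` so a zero DNA cell in an otherwise
  covered allele cannot produce an infinite offset.
* lnFC for display adds 0.5 to normalized counts only when a count is zero;
  testing always uses raw deduplicated counts.
* Quantile normalization refuses all-zero replicate columns; the mismatch
  profile reports uncovered positions as missing rather than zero; Fisher
  tables with an empty margin return p = 1 with a flag; tertile grouping of
  identical values returns one group with a warning.
* Top-k ranking, control sampling and all Monte-Carlo operations are
  seed-deterministic; repeated runs are byte-identical.

## Problem sizes used in the test and acceptance suites

Simulated panels use 200–600 variants at depth 300 with 3 replicates for
calibration, power and recovery studies (false-positive control uses 20
redraws of a 500-variant null panel); read-level simulations use 10–30
variants at depths 10–100, which already emit 10^5–10^6 compared bases for
the error-rate checks; null-calibration studies use 200–250 repetitions.
These sizes give the statistical checks comfortable resolution (for example,
±1% on a 5% type-I rate) while keeping the full suite in the minutes range
on one core.

## Known limitations

* The caller's p-values are those of the NB-LRT defined here; they will not
  numerically match external MPRA fitting tools, though the calling
  thresholds (FDR ≤ 0.10, |lnFC| ≥ 0.10) are the same.
* Variants are tested in a fixed ~160-nt sequence context; isoform-specific
  effects and alternative polyadenylation are out of scope.
* The hexamer test finds over-represented words, not full PWMs; mapping
  hexamers to binding proteins requires a user-supplied table.
* The matcher is exact-by-construction for ≤1 mismatch but does not handle
  indels; reads with indels fall out as unmapped.
* Enrichment counts supplied annotations only; no parent-term inheritance.
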