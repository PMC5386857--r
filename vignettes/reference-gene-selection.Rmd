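---
title: "Selecting qPCR reference genes from whole transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting qPCR reference genes from whole transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

Quantitative PCR measures a target gene's expression *relative to* one or
more reference ("housekeeping") genes, so its accuracy stands or falls with
the stability of those references. Traditional references (actin, tubulin,
GAPDH, ubiquitin-conjugating enzymes, ...) are chosen by convention, and in
many species and conditions they turn out to vary substantially. When a
multi-tissue, multi-batch RNA-seq dataset exists for the study system, it
can be screened genome-wide for genes whose expression is empirically
stable — typically yielding candidates far more stable than any traditional
reference. `refstab` implements that screen, the qPCR arm used to validate
candidates, and the concordance analytics that tell you when a transcriptome
is a trustworthy guide for a planned qPCR experiment.

## The two screens

Both screens operate on a gene × sample expression matrix in FPKM (or raw
counts plus gene lengths), where the samples span tissues and
biological-replicate batches — the default design is 4 tissues × 2 batches,
i.e. 8 exchangeable columns.

**Minimum-expression filter.** Genes below `min_expression` (default 5 FPKM)
in *any* sample are removed first: a gene too weak to detect reliably is a
poor normalizer no matter how stable. The boundary is inclusive — only
values strictly below the threshold exclude — because the exclusion rule is
"lower than" the threshold.

**CV screen.** For each remaining gene the coefficient of variation
$CV = SD/\bar{x}$ is computed over all samples, with the *sample* standard
deviation ($n-1$ denominator, the default of every mainstream spreadsheet
and of R's `sd`). Genes are ranked ascending; rank ties are broken
lexicographically by gene id so output is deterministic. The conventional
cut-off for a usable reference across heterogeneous samples is CV < 0.5, but
in practice most robustly expressed genes clear it, so the informative
output is the *ranking* and the top-*n* list (default 50). A zero-mean gene
has no defined CV; it is flagged and left unranked rather than given a
sentinel value. Counting against a threshold uses strict `<`, matching the
convention "CV of < 0.5".

**Fold-change screen.** Every gene whose absolute log~2~ fold change exceeds
`fc_cutoff` in *any* of the $\binom{8}{2} = 28$ pairwise sample comparisons
is eliminated; survivors form a short list of uniformly stable genes.
Retention uses `<=`, so a gene sitting exactly at the cutoff survives
(elimination is for fold changes *greater than* the cutoff). Cutoffs are on
the log~2~ scale — the scale differential-expression tools report — and the
defaults (0.4, with 0.3 appropriate for tighter designs) are deliberately
strict: the goal is a short list, and the right value depends on how many
candidates you want. Counts are normalized to counts-per-million first;
FPKM input is taken as already depth- and length-normalized
(`normalize = "none"`). CPM is plain library-size scaling, not a trimmed
robust normalizer: stable genes are by construction not differentially
expressed, composition bias is a second-order concern at this cutoff scale,
and the `normalizer` hook accepts any substitute. The pseudocount (default
0.5, a common prior-count convention) only matters for zero counts, which
the ≥ 5 FPKM pre-filter removes in practice.

The combined fit, `screen_reference_genes()`, assigns each gene a verdict:
`STRONG` (fold-change-retained *and* within the CV top-*n*), `CV_ONLY`,
`FC_ONLY`, or `REJECTED`. The best candidates score well on both metrics.

For allotetraploids quantified with homeolog-resolved references, two
reporting conventions are provided and kept distinct: `average_homeologs()`
averages the two copies' *expression* before any statistic, while
`average_homeolog_cv()` averages the two copies' *CVs*. The latter is the
convention used when reporting a single stability number for a homeolog
pair; the former answers a different question (stability of the summed
locus) and is deliberately a separate option, since a pair of anti-varying
homeologs can have a flat sum yet be individually unstable.

## The qPCR arm

* **Technical replicates** (typically 3) are averaged as-is when their
  spread is ≤ 1 Cq. A wider trio loses its most aberrant member — defined
  here as the replicate farthest from the median of the trio, ties keeping
  the earlier-listed replicate — and the remaining two are averaged. Two
  replicates more than 1 Cq apart have no identifiable outlier; the record
  is flagged unresolvable and excluded.
* **Amplification efficiency** comes from a dilution-series standard curve:
  ordinary least squares of Cq on log~10~(relative concentration), with
  $E = 10^{1/-slope}$. $E = 2$ is perfect doubling (reported as 100%;
  competent assays usually fall between roughly 83% and 102%). Dilutions are
  entered as concentrations (1, 0.25, 0.0625, ...), not step indices; at
  least 3 points are required and a non-negative slope is an assay failure,
  not a result.
* **Relative expression** is $E^{\Delta Cq}$ with
  $\Delta Cq = Cq_{calibrator} - Cq_{sample}$. The calibrator is a
  designated biological sample run alongside every batch; each gene
  normalizes to its own Cq in that sample by default, and a named vector of
  per-gene calibrator Cq values (e.g. a single interplate-calibrator Cq
  shared by all genes) is accepted for workflows that need cross-gene
  comparability.
* **qPCR stability CV** first averages relative expression over biological
  replicates within each tissue, then takes the CV across the tissue means —
  the same statistic as the RNA-seq screen, so the two are directly
  comparable. Because a calibrator switch multiplies all of a gene's values
  by one constant, the CV is calibrator-invariant; this is what makes
  cross-platform CV comparison meaningful at all. Individual tissues can be
  excluded (a single divergent tissue, e.g. petal in floral panels, can
  dominate the CV); at least 2 tissues must remain.
* **3′/5′ integrity QC** computes $E^{Cq_{5'} - Cq_{3'}}$ from two assays on
  the same transcript ~1 kb apart; values outside 0.2–5.0 flag RNA
  degradation or incomplete reverse transcription. The exponential form
  follows directly from Cq arithmetic; $E$ defaults to 2 when the assay pair
  has no fitted efficiency.

## Concordance analytics

`replicate_concordance()` compares two batches of the same design on
per-gene means or CVs (Pearson r with the linear-model t-test p-value at
$n-2$ df); `platform_concordance()` does the same for matched RNA-seq and
qPCR summaries. Genes with mean below 1 FPKM in either batch are excluded
from batch comparisons — near-zero means make CV ratios of noise. Mean
concordance is computed on log~10~ values by default: expression means span
orders of magnitude and cross-platform scales differ, and the log
correlation is what the field's scatter plots show; a flag restores
raw-scale correlation. CVs are already dimensionless and are correlated on
the raw scale. Constant inputs leave Pearson r undefined; the report carries
`NA` with a warning rather than a fabricated value.

The practical point these analytics establish: expression *means* are robust
to moderate environmental and genetic differences between batches, while
expression *variability* is not. A transcriptome is a reliable guide to
reference-gene stability mainly for samples from a comparable environment —
otherwise screen across pooled, diverse batches.

## The synthetic study generator

`simulate_expression()` draws negative-binomial counts for a configurable
design whose defaults are the intended study conditions: 5000 genes (50
designated truly stable), 4 tissues × 2 batches, library sizes 8–12 million
fragments, gene lengths 0.5–3 kb. Per gene, log~2~ mean expression is
baseline (uniform on 2–9) plus a per-tissue effect (SD 0.8 for ordinary
genes, 0.02 for the stable subset) plus per-sample lognormal noise (SD
0.15); NB dispersions are uniform on 0.02–0.4 (0.005 for stable genes).
These choices put the bulk of genes in the few-to-hundreds FPKM range with
tissue effects large enough that unstable genes' CVs concentrate around
0.4–1, which is what multi-tissue bulk RNA-seq looks like. Batch effects act
multiplicatively on the per-sample *noise SD* of the second batch
(`batch_variance_inflation`), not on means — operationalizing the
observation that environment perturbs expression variability more than
level. An optional duplicated leaf sample mirrors designs that carry an
asymmetric ninth library.

`simulate_cq()` generates the matched qPCR arm: a panel of assayed genes
(half stable, half not), true efficiencies uniform on 1.8–2.05, 4 biological
× 3 technical replicates per tissue, Gaussian technical noise (SD 0.15
cycles), and a 1:4 dilution series per gene. Cq values are anchored to one
interplate-calibrator gene, so they carry absolute abundance differences
between genes as on a real instrument. At zero noise every downstream
computation inverts the generator exactly: `relative_expression()` recovers
expression ratios and `fit_efficiency()` recovers E to numerical precision.

What the generator does *not* emulate: length/GC bias and mappability,
homeolog cross-mapping, composition effects that would distinguish TMM from
plain CPM, tissue-correlated batch effects, amplification inhibitors, or
plate layout. Passing tests on synthetic data therefore demonstrate the
*estimators'* correctness and the screens' recovery behaviour under a known
truth — not that any particular real transcriptome is free of those
artifacts.

## Numerical and design notes

* All randomness flows from a single integer seed; fixed seed, bit-identical
  output, including the qPCR arm (offset by +1 so the two generators don't
  share a stream).
* Matrix input is strict: duplicate gene ids, missing metadata, non-numeric
  or empty cells are errors naming the offending row/column — never imputed.
  Delimiter detection accepts pure TSV or CSV and rejects ambiguous headers.
* Screens run in seconds at transcriptome scale (the pairwise screen is 28
  vectorized column comparisons); the test suite uses 20 × 8 matrices for
  oracle comparisons (tolerance 1e-12), 400–2000-gene simulations for
  behavioural checks, and the full 5000 × 8 default design for the
  recovery/enrichment checks, keeping the whole suite under a few seconds.
* Pipeline outputs are a pure function of (inputs, config, seed); every
  table carries a provenance header with the package version, a config hash
  and the seed. Reruns differ only in the timestamp line.

## Known limitations

* The fold-change screen's retained list is sensitive to the normalization
  and pseudocount convention near the cutoff; exact reproduction of a list
  computed with a different normalizer is not guaranteed (the hook exists
  for that reason).
* CV estimates from 8 samples are noisy; the ranking is a screen, not a
  significance statement, and candidates should be validated by qPCR.
* With qPCR panels of typical size (~8 genes), platform-concordance r has
  wide sampling error; treat it as qualitative agreement.
* Multi-reference normalization factors (geNorm-style M values) and
  dispersion-based differential-expression testing are out of scope.
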