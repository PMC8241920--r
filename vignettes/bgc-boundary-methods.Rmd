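---
title: "Delimiting biosynthetic gene cluster boundaries by integrated evidence"
author: "bgcbound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting biosynthetic gene cluster boundaries by integrated evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgcbound)
```

## The problem

Fungal secondary-metabolite biosynthetic gene clusters (BGCs) are contiguous
runs of co-located genes — a core scaffold-building enzyme (here a
non-reducing polyketide synthase), tailoring enzymes, regulators and
transporters. Their *interiors* are easy to find; their *edges* are not.
Motif-anchored predictors disagree by tens of kilobases on the same locus,
and two kinds of decoys make any single line of evidence unreliable:

* genes just outside the true cluster that respond to the cluster's
  pathway-specific regulator without contributing to the product, and
* genes well inside the cluster that the regulator does not control at all
  (or that have no role in the product), mimicking a cluster edge.

The azaphilone pigment locus of *Monascus ruber* M7 exhibits both decoys at
once, which is why `bgcbound` combines three independent lines of evidence
— comparative genomics, differential transcription against a regulator
knockout, and knockout metabolite phenotypes — and resolves their conflicts
with explicit rules.

## The comparative-genomics stage

### Protein similarity

All cross-genome protein pairs are scored by Smith-Waterman local alignment
(BLOSUM62; affine gaps, open 11 / extend 1, a gap of length $L$ costing
$11 + L$). Raw scores $S$ are mapped to the unit interval by self-score
normalization,

$$ s = \frac{S(a,b)}{\min\{S(a,a),\, S(b,b)\}} \in [0,1], $$

so that an exact fragment of a longer partner scores 1. This tolerance for
truncations is deliberate: annotation pipelines sometimes split one real
gene into two models, and both halves should pair with the full-length
partner at full strength. The minimum-self-score convention is a design
choice of this package; it also puts similarities on the same unit scale as
the gene-level penalties below.

Pairs are admitted into the homolog graph when their Karlin–Altschul
E-value,

$$ E = K\, m\, n\, e^{-\lambda S}, $$

falls below $10^{-10}$ ($m, n$ sequence lengths; $\lambda = 0.267$,
$K = 0.041$, the standard gapped BLOSUM62 11/1 constants). Applying the
ungapped closed form to the gapped score is a standard approximation; both
constants are configurable through `alignment_params()`. One-to-many pairs
are retained, so a split gene keeps both of its fragment edges.

A note on parameter names: the *residue-level* alignment uses gap penalties
11/1, while the *gene-level* cluster scores use −0.2 (gap), −0.2
(mismatch) and −0.3 (negative penalty). These are two different parameter
sets for two different stages; conflating them changes the method
completely.

### Seed, extension, trimming

The **seed** is the longest run of genome-A genes, contiguous in gene
order, whose members all pair into a contiguous block of genome-B genes,
with every gene of that block pairing back into the run (minimum length 3).
A split-fragment pair occupies one genome-A position covering two
consecutive genome-B positions. Ties go to the higher total similarity,
then to the leftmost block.

The seed is **extended** to a fixed window of 35 genes in each genome
(seed included), flanks split evenly with any odd remainder upstream, and
truncated silently at contig ends.

**Trimming** jointly chooses sub-spans $[i_{begin}, i_{end}]$ of the
genome-A window and $[j_{begin}, j_{end}]$ of the genome-B window
maximizing the cumulative score

$$ CB = \sum_{a \in \text{span}_A \text{ matched}} s^{best}_a \;+\;
   p^- \cdot \#\{\text{unmatched span genes, both sides}\}, $$

where a gene is *matched* when some partner lies anywhere inside the
opposing span (order-free — this is what lets a non-syntenic, shuffled
partner cluster score fully), each pair counts once, a gene with several
partners contributes its best one, and $p^- = -0.3$ is the negative
penalty. The search enumerates all $O(n^4)$ span pairs exactly (organized
so the inner loops are vectorized); at the 35-gene window width this takes
well under a second, and no dynamic-programming shortcut is needed for
correctness. Ties are broken toward the smaller total span, then leftmost —
determinism matters more here than any particular convention, and the
smaller-span preference means a gene contributing exactly zero is dropped
rather than kept.

## The expression stage

Relative expression uses the comparative-CT method with amplification
efficiency assumed exactly 2: technical replicates are averaged first
(they are not independent), then per biological replicate
$\Delta CT = CT_{gene} - CT_{ref}$, then
$\Delta\Delta CT = \overline{\Delta CT}_{case} -
\overline{\Delta CT}_{calibrator}$ and fold change $2^{-\Delta\Delta CT}$.
Undetermined CT values propagate as a detection flag and are never imputed;
a gene undetermined in the calibrator strain is classed `not_expressed`.

Significance is a two-group one-way fixed-effects ANOVA (equivalent to the
pooled t-test, $t^2 = F$) on the per-biological-replicate values,
computed on the log2 relative scale. CT values are logarithms of template
abundance, so replicate noise is homoscedastic and near-normal there;
running the F-test on the exponentiated fold-change scale makes it
detectably anticonservative under the null. Degenerate zero-variance input
returns $p = 1$ when means agree.

Classes are then assigned by fold-change cutoffs at significance
$\alpha = 0.05$: `abolished` at $fc \le 0.1$, `downregulated` at
$fc \in (0.1, 2/3]$, `upregulated` at $fc \ge 1.5$, else `unchanged`. The
source observations are qualitative ("almost completely abolished",
"moderately downregulated"), so the cutoffs are this package's
quantification, chosen so the planted effect sizes (0.02 / 0.4 / 1.0) sit
deep inside their classes; all are configurable via
`expression_thresholds()`. No multiple-testing correction is applied — the
study design reports per-gene tests at $\alpha = 0.05$.

## The knockout stage

Metabolite profiles enter as already-quantified compound tables (compounds
1–4 core pigments, 5–6 shunt products). Categories are assigned by
first-match rules: **abolished** (all cores absent, no shunt), **shunt**
(any shunt product above the detection floor), **ratio_shift** (all cores
present but some pairwise core ratio off by more than 2-fold), else
**unchanged**. The underlying evidence is qualitative HPLC traces, so the
5 % absence floor and the 2-fold tolerances are invented quantifications
(configurable, `knockout_thresholds()`), chosen with wide margins relative
to the generator's 5 % noise. The shunt rule precedes ratio comparison so
a strain accumulating derailment products is never mislabeled. Two
numerical conventions matter: the shunt detection floor scales with the
wild-type core mean, making classification invariant under a common
rescaling of both profiles; and tolerance comparisons are inclusive, so an
exactly 2-fold change is still `unchanged`. One known corner: a partial
core loss without shunt products falls through to `unchanged`, because the
rule list is ordered and `ratio_shift` requires all cores present; no
studied strain exercises this corner.

## Evidence integration

`call_bgc()` encodes the precedence *knockout > comparative genomics >
transcription*:

1. members start as the comparative span;
2. an adjacent outside gene joins only on supporting knockout evidence
   (`abolished`, `shunt`, `ratio_shift`) — regulator responsiveness alone
   never admits a gene, which is exactly how the two border decoys
   (regulated but dispensable flanking genes) are kept out;
3. an edge member is removed only when its knockout is neutral *and* its
   expression is unchanged or absent;
4. interior members are always retained — which is how unregulated
   interior genes (the C/J/K/L pattern) stay in.

`ratio_shift` counts as support but is flagged `weak` in the confidence
tier (a transporter whose loss only shifts product ratios is, at best, a
peripheral cluster member). Missing evidence is represented explicitly and
never treated as "unchanged".

## What the generators emulate — and what they do not

`generate_genome_pair()` plants a cluster with configurable per-gene
identities into random uniform-composition proteomes. Uniform residue
frequencies are adequate for a locus-scale E-value null and easier to
reason about than background-frequency models. The locus fixture
(`m7_atcc18224`) reproduces the study topology: a 20-gene locus (two
flanks each side of the 16 lettered genes) among 20 background genes;
partners for the lettered genes except three interior ones (F, O, L, whose
counterparts lie elsewhere in the partner genome); the H partner split
into two consecutive fragment genes; flanks unpartnered. Seed-block genes
(G–K) carry the highest planted identities (0.85–0.90) — the seed region
is, by construction of the real method, the most conserved stretch — and
the remaining partnered genes sit at 0.65–0.75. The non-syntenic fixture
(`pm1_nonsyntenic`) shuffles the 14 partner genes in blocks, preserving
one 3-gene block (the I–K partners) as the seeding anchor and keeping the
split-fragment unit away from the cluster ends, as in the real locus where
the mis-annotated gene is interior.

`generate_ct_table()` decomposes qPCR noise into a per-(strain, biological
replicate) sample offset (sd 0.3 CT) shared by *all* genes of that cDNA
sample, plus independent per-well technical noise (sd 0.15 CT). The shared
offset is precisely the component that reference-gene normalization
removes — that is why the comparative-CT method exists — so it shapes the
raw CT values without influencing fold changes. Gene-specific biological
variation (a gene genuinely fluctuating between replicate cultures
independently of the reference) is *not* modeled; consequently, passing
tests demonstrate correctness of the computation and robustness to
assay-level noise, not power under biological heterogeneity. Genes sharing
one physical reference well also have dependent p-values, which is why the
null-uniformity property is checked over independent simulated assays.

`generate_knockout_profiles()` applies per-strain phenotype templates
(core multipliers, shunt amounts) with 5 % multiplicative log-normal
noise. Amounts are arbitrary units; only ratios and relative floors enter
classification.

## Problem sizes and numerical choices

The test suite runs the full pipeline at the study scale (40-gene genome A
vs 34-gene genome B, 19 assayed genes × 3 × 3 replicates, 8 profile
strains) and checks the numerics against independent oracles at reduced
scale: brute-force dynamic programming for Smith-Waterman on 200 random
pairs of length ≤ 12, exhaustive span enumeration for trimming on 100
random windows of ≤ 12 genes per side, and exhaustive block enumeration
for seeding. Floating-point span-score ties are compared at an absolute
tolerance of 1e-9; similarity values are clamped to [0, 1] (an all-`X`
sequence has a non-positive self-score and normalizes to 0); local
alignment scores are clamped at 0 (the empty alignment).

## Limitations

* Single best cluster per run; no whole-genome multi-cluster scanning and
  no motif/core-gene detection — this is a boundary method, not a cluster
  *finder*.
* Two genomes only; the original study's strength of comparing against
  many genomes reduces here to the single best comparator.
* The expression stage assumes efficiency-2 amplification and a single
  reference gene.
* Knockout phenotypes are defined purely on the compound table; colony
  morphology is out of scope.
* The rule-based integrator is deliberately non-probabilistic: evidence
  conflicts are resolved by precedence, not by score fusion, so the output
  is an auditable decision, not a posterior.
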