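# bgcbound

Integrated delimitation of fungal biosynthetic gene cluster (BGC)
boundaries.

## The problem

Secondary-metabolite gene clusters — such as the azaphilone pigment
cluster of *Monascus ruber*, anchored by a non-reducing polyketide
synthase — have well-defined cores but ambiguous edges. Motif-anchored
predictors drawn on the same locus disagree by tens of kilobases, and two
decoys defeat any single line of evidence: flanking genes that respond to
the cluster's pathway-specific regulator without contributing to the
product, and interior genes the regulator does not control at all.
`bgcbound` is for genome miners and natural-product researchers who need
cluster *boundaries* they can defend: it combines three independent lines
of evidence and resolves their conflicts with explicit, auditable rules.

## The method

1. **Comparative genomics.** All-vs-all Smith-Waterman protein comparison
   between two genomes (BLOSUM62, affine gaps 11/1); pairs admitted at
   Karlin–Altschul E-value `E = K·m·n·exp(−λS) < 1e−10`; similarities
   normalized to `s = S(a,b) / min(S(a,a), S(b,b)) ∈ [0,1]`. A synteny
   *seed* — the longest gene block contiguous in both genomes and fully
   cross-linked by homolog pairs — is extended to a 35-gene candidate
   window, and both genomes' boundaries are trimmed by exhaustively
   maximizing the cumulative score

   `CB = Σ (best-partner s over matched span genes) − 0.3 · #(unmatched span genes)`,

   with matching order-free inside the spans, so non-syntenic partner
   clusters score fully.
2. **Differential transcription.** Comparative-CT (ΔΔCT) fold changes of
   locus genes in a pathway-regulator knockout vs wild type
   (`fc = 2^−ΔΔCT`), two-group one-way ANOVA on the log2 relative values,
   and per-gene classes: abolished (fc ≤ 0.1), downregulated
   (fc ≤ 2/3), upregulated (fc ≥ 1.5) at α = 0.05, else unchanged;
   undetected-in-wild-type genes are `not_expressed`.
3. **Knockout metabolite phenotypes.** Mutant compound profiles classified
   as abolished / shunt (derailment products present) / ratio_shift /
   unchanged.
4. **Consensus.** Rules with precedence knockout > comparative genomics >
   transcription: regulator-responsive but knockout-neutral border genes
   are excluded; unregulated interior genes are retained.

Seeded generators reproduce the study conditions offline: a 20-gene locus
with planted orthology (including a split-gene mis-annotation and three
unpartnered interior genes), a 14-gene non-syntenic partner cluster, a
3×3-replicate CT table with planted regulation classes, and an
8-strain knockout profile panel.

## Worked example

```r
library(bgcbound)
run <- run_all(pipeline_config(fixture = "m7_atcc18224", seed = 42))
print(run$call)
#> bgc_call: 16 genes, mrpigA..mrpigP
#> excluded:
#>   mrpigAup1 (regulated-but-ko-neutral)
#>   mrpigPdown1 (regulated-but-ko-neutral)
#>   ... and 22 gene(s) with no supporting evidence
```

The consensus call spans the 16 lettered genes `mrpigA..mrpigP`. The two
flanking genes `mrpigAup1`/`mrpigPdown1` are *downregulated* in the
regulator knockout yet excluded, because their gene knockouts leave the
pigment profile unchanged — transcriptional evidence alone never admits a
gene. The comparative stage underneath:

```r
pred <- run$prediction
paste(pred$seed$genes_a, collapse = " ")
#> [1] "mrpigG mrpigH mrpigI mrpigJ mrpigK"
round(pred$call$cb_score, 3)
#> [1] 8.575
```

The seed is the conserved five-gene block `mrpigG..mrpigK` (whose genome-B
counterpart spans six genes — one partner is split in two by a
mis-annotation), and trimming the 35-gene window maximizes CB at 8.575,
which places the boundaries at `mrpigA` and `mrpigP`. Expression results
carry per-gene fold changes and classes:

```r
run$expression[run$expression$gene %in%
                 c("mrpigA", "mrpigAup1", "mrpigC", "mrpigI"), ]
#>         gene fold_change      p_value     reg_class
#> 1     mrpigA  0.01977836 6.668188e-07     abolished
#> 2  mrpigAup1  0.42567593 5.515186e-04 downregulated
#> 4     mrpigC  1.01800426 7.940176e-01     unchanged
#> 10    mrpigI          NA           NA not_expressed
```

`mrpigC` is essential for pigment biosynthesis yet unchanged in the
regulator knockout — the interior decoy — and stays in the call because
interior members are always retained.

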