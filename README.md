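# glycolact

Longitudinal milk-glycomics analysis: glycan structure parsing, motif
quantification, compositional statistics, glyco-phylogenetics, lactation
time-course dynamics, and glycome–metabolome integration.

## The problem

Free milk oligosaccharides (MOs) are soluble glycans built by elaborating a
lactose core (Galβ1-4Glc); in species with complex milk — marine mammals in
particular — hundreds of structures arise from poly-LacNAc extension and
branching decorated by fucosylation, sialylation and sulfation. Two analysis
problems recur in longitudinal milk-glycomics studies:

1. **Structure → motif quantification.** Epitopes such as Lewis X/Y, the
   type-2 H antigen, LacdiNAc (GalNAcβ1-4GlcNAc), branched (I) vs linear (i)
   poly-LacNAc, and keratan-sulfate-like Galβ1-4GlcNAc6S units determine the
   biology, so per-glycan relative abundances must be projected onto motif
   abundances: for motif *m* and sample *s*,
   `Q(m, s) = Σ_g occ(m, g) · A(s, g)`, where `occ` counts subtree
   embeddings of the motif pattern in glycan *g* and `A` is the relative
   abundance (percent).
2. **Compositional inference over time and across omics layers.** Relative
   abundances are compositions, so the package works in centred log-ratio
   (CLR) space — `clr(x)_i = log x_i − mean(log x)`, with an optional
   per-sample scale-uncertainty term Normal(0, γ²), γ = 0.1 by default —
   for Ward clustering of samples against lactation timepoints (scored by
   ARI/NMI), ANOSIM of Aitchison beta diversities, per-motif ANOVA with
   Tukey HSD and two-stage Benjamini–Hochberg correction, degree-1
   time-series fits, Spearman cross-correlation with a paired metabolome,
   and ridge-regularized partial correlations that separate direct links
   from bystander correlations.

The package is aimed at glycomics/metabolomics researchers who need these
stages as tested, composable functions, and it ships a synthetic-cohort
generator (5 individuals × 4 lactation timepoints, planted Early/Stable/Late
glycan clusters, paired metabolome with known direct links) so every claim
the pipeline makes can be checked against ground truth.

## Worked example

```r
library(glycolact)

# a sulfated 2'-fucosyllactose: parse, inspect, annotate
g <- parse_iupac("Fucα1-2Gal6Sβ1-4Glc")
g
#> <glycan_structure> Fucα1-2Gal6Sβ1-4Glc  (3 residues)
composition_of(g)
#> <glycan_composition> Hex2Fuc1S1  size 3

lib <- milk_motif_library()
a <- annotate_motifs(parse_iupac("Fucα1-2(Neu5Acα2-6)Galβ1-4GlcNAc"), lib)
a[a > 0]
#>         Type-2 H antigen Proximal type-2 sialyl-H            Neu5Acα2-6Gal
#>                        1                        1                        1
#>               Fucα1-2Gal
#>                        1

# synthetic lactation cohort (5 individuals x days 2/7/13/18) + metabolome
co  <- simulate_cohort(cohort_design(), seed = 42)
co$table
#> <abundance_table> 20 samples x 40 features; days: 2, 7, 13, 18; individuals: 5
met <- simulate_metabolome(co, seed = 43)

res <- run_pipeline(co$table, co$structures, metabolome = met$table, seed = 7)
res
#> <glycolact_pipeline>
#>   samples: 20, motif features: 18
#>   timepoint clustering: ARI 0.271, NMI 0.472
#>   ANOSIM R 0.593 (p = 0.001)
#>   significant cross-omics pairs: 1895

head(res$timeseries[order(res$timeseries$q), c("motif", "beta", "q")], 3)
#>            motif        beta            q
#> 9  Neu5Acα2-3Gal -0.05140698 7.077954e-08
#> 5      i antigen -0.06848016 4.880290e-07
#> 11    Fucα1-2Gal -0.03433984 1.161225e-06
```

Reading the output: under the default *realistic-noise* design the Ward
clustering of CLR profiles recovers lactation timepoints only partially
(ARI 0.27 here — individual variation and sporadically detected glycans
genuinely blur the late-day contrasts), while ANOSIM still shows a clear
compositional shift across days (R = 0.59, p = 0.001). The time-series
table lists CLR-scale slopes per motif with BH-adjusted q-values; negative
slopes mark motifs declining through lactation. Under the quiet
`low_noise_design()` the same clustering recovers timepoints essentially
perfectly — that contrast is the point of having both designs.

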