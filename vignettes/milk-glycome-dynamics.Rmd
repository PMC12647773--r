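---
title: "Methods: longitudinal milk-glycomics analysis with glycolact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal milk-glycomics analysis with glycolact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycolact)
```

# Scope and model

`glycolact` analyses free milk oligosaccharide (MO) glycomes measured
longitudinally over a lactation period, together with a paired metabolome.
The motivating system is a phocid-seal-type milk glycome: a lactose core
(Galβ1-4Glc) elongated by type-2 LacNAc units (Galβ1-4GlcNAcβ1-3) into
linear and branched poly-LacNAc scaffolds, decorated by fucosylation
(α1-2 on Gal, α1-3 on GlcNAc), sialylation (Neu5Ac α2-3/α2-6) and
6-O-sulfation of GlcNAc. The pipeline covers five layers:

1. **Structures** — IUPAC-condensed parsing into rooted monosaccharide
   trees, canonical serialisation, compositions, and structural descriptors
   (size, branch points, depth, terminal residues).
2. **Motifs** — a declarative library of named epitopes matched by
   terminal-constrained subtree embedding, and abundance-weighted motif
   quantification per sample.
3. **Compositional statistics** — Winsorize → impute → centred log-ratio
   (CLR) preprocessing; alpha diversity; Aitchison beta diversity with
   ANOSIM; Mann–Whitney comparisons with adaptive FDR control.
4. **Phylogenetics and dynamics** — cosine-distance UPGMA dendrograms of
   motif profiles; Ward clustering of samples against timepoints scored by
   ARI/NMI; glycan-cluster trajectories; per-motif ANOVA with Tukey HSD;
   degree-1 time-series fits; a Wilcoxon test of whether GlcNAc6S
   suppresses chain extension.
5. **Multi-omics** — Spearman cross-correlation of CLR tables with t-test
   significance and two-stage Benjamini–Hochberg masking; ridge-regularized
   partial correlations of residuals; per-modality clustering
   informativeness; PC1 linkage between modalities.

Everything runs on synthetic cohorts with recorded ground truth, so each
stage's statistical behaviour is verifiable without external data.

# Structure representation and canonical form

A `glycan_structure` is a rooted tree: edges point child → parent, the
parent being nearer the reducing end; the root is the reducing-end residue
(Glc in the lactose core). The writer emits a canonical string: at every
branch point the subtree with more residues stays on the main chain
(outside parentheses), ties broken by the smaller attachment carbon, then
lexicographically. This matches the conventional way both
`Galβ1-4GlcNAcβ1-6(Galβ1-3)Gal…` (longer branch outside) and
`Fucα1-2(Neu5Acα2-6)Gal…` (tie; carbon 2 before carbon 6) are printed, and
makes string equality of canonical forms coincide with tree isomorphism.
Sulfates are accepted as `Gal6S` or `Gal(6S)` and emitted compactly; Greek
and ASCII anomeric letters are both accepted and Greek is emitted; `?`
marks unknown anomeric configurations or positions and, in strict
matching, compares equal to nothing except an unknown on the other side.
Composition-only records (e.g. `Neu5Ac6Hex12HexNAc10`) are supported as
abundance-table entries but are excluded from motif matching with a
warning — partially characterized structures carry no subtree information.

# Motif matching semantics

A motif is one or more pattern trees (alternation covers reducing-end
GlcNAc-or-Glc variants) plus a terminal constraint and optional
forbidden-sibling clauses. Matching enumerates **every** injective
embedding preserving residue classes (generic Hex/HexNAc wildcards),
parent/child relations, and any linkage fields known on both sides;
overlapping occurrences all count, so `quantify_motifs()` weights
abundances per occurrence (a presence-only flag is available). In strict
mode an unmodified pattern residue only matches an unmodified structure
residue — this is what separates the keratan-sulfate-like unit
(Galβ1-4GlcNAc6S) from plain LacNAc. Negative context is expressed as
forbidden siblings: the i antigen requires the internal Gal to carry no
β1-6 branch (otherwise it is the branched I antigen), and the Galili
antigen (Galα1-3Gal) forbids an α1-2 Fuc on the inner Gal (which would
make it a B antigen). The built-in library uses standard immunochemical
definitions; it includes Sd^a^ so its absence in a seal-type glycome can
be asserted positively. Matching correctness is pinned to an independent
brute-force embedding enumerator on thousands of fuzzed cases.

The `size_branch` feature set appends abundance shares by glycan size
class (≤5, 6–10, >10 residues) and branch-point count (0, 1, ≥2); the bin
edges are package choices made once for panels that range from lactose to
~14-residue structures.

# Compositional preprocessing

Relative abundances are compositions, so all clustering, regression and
correlation happens on CLR-transformed data. The pipeline is: two-sided
per-feature Winsorization (default fraction 0.05 per side — a conventional
clip; rank order is preserved); imputation of zeros/missing values;
re-closure; CLR. Two imputation modes exist: a deterministic
half-of-feature-minimum mode (the default, and the one used in every test
that asserts exact values) and an iterative random-forest mode in the
MissForest spirit, seeded, with predictions floored into (0, feature max].

The CLR scale parameter γ is implemented as a per-sample scale-uncertainty
term: after the ordinary CLR, each sample's row receives one draw from
Normal(0, γ²). γ = 0.1 is the default used by `run_pipeline()`; γ = 0
recovers the textbook transform (rows sum to zero; invariance to
per-sample rescaling) and is used wherever determinism matters. Alpha
diversity offers Shannon, Simpson and observed richness — a concrete
choice of three standard indices, not a claim about any particular
published index set. Beta diversity defaults to Aitchison distance
(Euclidean on CLR(γ=0)); Bray–Curtis on proportions is available. ANOSIM
uses vegan's rank formula with seeded permutations (default 999).
Multiple-testing correction is the two-stage (adaptive) Benjamini–Hochberg
step-up: a first BH pass at α/(1+α) estimates the null proportion, and BH
q-values are scaled by m₀/m.

# Phylogenetics, clustering, dynamics

Glyco-dendrograms are built from cosine distances between motif-abundance
profiles (or presence/absence vectors for qualitative glycomes; Jaccard
available) and agglomerated by UPGMA. Heights follow the d/2 convention,
so cophenetic distances equal merge distances and ultrametric inputs are
reconstructed exactly; labels are sorted before clustering so ties resolve
deterministically. Trees serialize to newick via ape.

Sample clustering uses Ward (`ward.D2`) on Euclidean distances of CLR
rows, cut at k = number of distinct lactation days (4 in the default
design); glycan-row clustering (optionally z-scored) mirrors the
heatmap-style analysis. Partition agreement is scored with the adjusted
Rand index (permutation model) and NMI with arithmetic-mean normalization.
Late-lactation sampling days 17/18/19 are collapsed to day 18, keeping a
four-level time design.

Per-motif ANOVA (one-way, across cluster or day groups) is followed by
Tukey HSD and two-stage BH across motifs. Time-series fits are ordinary
degree-1 least squares of CLR motif quantities against day with all
individuals pooled — no random effects, matching the plain regression the
design calls for; mixed models are out of scope.

The sulfation–extension test asks whether GlcNAc6S residues attached below
a galactose are extended (carry a child) less often than position-matched
unmodified GlcNAc. "Controlled for length" is implemented by stratifying
structures on residue count, computing the paired extended-fraction
difference per stratum, and applying a two-tailed Wilcoxon signed-rank
test over informative strata (≥5 required). Stratum pairing is the one
interpretation of length control implemented; the pairing unit is
documented here precisely because other matchings are conceivable.

# Multi-omics integration

Cross-correlation is Spearman's ρ between all (motif, metabolite) pairs of
two CLR tables, a two-tailed t-test on ρ at n−2 degrees of freedom,
two-stage BH over all pairs, and masking at q < 0.05. The compositional
correction lives entirely in the CLR transform; the association measure is
rank-based. Regularized partial correlation regresses each member of a
pair on all remaining joint features with a closed-form ridge penalty
(default 0.1 × number of remaining features) and reports Spearman's ρ of
the residuals; as the penalty grows the estimate provably returns to the
marginal ρ, and at moderate penalties it suppresses bystander correlations
mediated by other features. Modality informativeness Ward-clusters each
modality (and their unscaled concatenation) against the day labels;
optional PCA denoising projects onto leading components first ("auto"
keeps 80% cumulative variance). PC1 linkage reports each modality's PC1
variance share and the Pearson correlation of score vectors, with PC1
signs oriented to correlate positively with day (scores are defined only
up to sign).

# The synthetic study and what it does (not) show

`cohort_design()` emulates the target study: 5 individuals × 4 timepoints
(days 2, 7, 13, 18) = 20 samples; a 40-glycan panel drawn from the
poly-LacNAc grammar; glycans planted in temporal clusters with multipliers
Early = (1,0,0,0), Stable = (1,1,1,1), Late = (0,0.5,1,1.5), plus a
Sporadic group present in 30% of samples at low level; lognormal base
levels (σ = 0.8) and per-(glycan, individual) effects (σ = 0.2); Dirichlet
sampling noise at concentration 200; and a detection floor of 0.01% below
which a value is reported absent and the row re-closed — relative-abundance
MS data always carry such a floor, and without it sub-detection values
spanning orders of magnitude would dominate CLR distances in a way real
data cannot. The paired metabolome defaults to 5× the glycan feature count,
with a latent day factor driving both modalities, per-individual effects,
and `n_direct_links` metabolites tied to specific glycans. Direct links
are planted on the glycans with the largest *within-day* CLR variance: a
link to a glycan fully explained by the shared day factor would be
statistically indistinguishable from a bystander correlation, so it could
not anchor a recovery test.

Under the default (realistic-noise) design, Ward clustering recovers
timepoints only partially (ARI typically 0.3–0.6) — individual effects and
sporadic detection flicker genuinely obscure the late-day contrasts, which
mirrors the moderate clustering metrics reported for real milk glycomes.
`low_noise_design()` (no sporadic group, concentration 2000, individual
σ = 0.05, base σ = 0.4) defines the regime for parameter-recovery checks:
there, timepoint recovery is essentially perfect (occasionally a single
d13/d18 sample flips, ARI 0.86 in roughly 1 run in 30, hence recovery is
asserted as a ≥0.9 multi-seed mean with a 0.8 per-seed floor), planted
slopes are recovered with <1% bias, planted direct pairs top the
partial-correlation screen in ~94% of runs, and the sulfation-extension
gap (0.2 vs 0.8 extension probability) is detected in ~98% of runs.
Passing these tests shows the estimators recover planted structure under
the stated generative model; it does not certify performance on real data,
whose noise is not Dirichlet, whose missingness is not a sharp floor, and
whose glycan panels are far larger and correlated in ways the grammar does
not emulate.

# Numerical and design choices

* Deterministic tie-breaks everywhere tests need identity: canonical
  serialisation orders siblings by (size, position, string); UPGMA sorts
  labels first; all randomized stages take explicit seeds, and
  `run_pipeline()` derives per-stage seeds from one master seed.
* Degenerate inputs are first-class: all-zero samples, singleton ANOSIM
  groups, constant matrices in PCA, empty clusters and composition-only
  glycans raise informative errors rather than propagating NaN; constant
  motif series return slope 0 with p = 1 by convention.
* Problem sizes in the test-suite simulations (e.g. 120–500 replicates for
  FDR and type-I calibration, 1000 fuzz cases for the matching oracle,
  40-glycan panels) were chosen once as the smallest sizes at which the
  binomial confidence intervals are informative.
* Known limitations: no spectral interpretation or fragment logic; no
  mixed-effects or spline time models; no rarefaction or phylogenetic beta
  diversity; the motif library is declarative, not learned; partial
  correlations condition linearly (ridge) even though the final association
  is rank-based.
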