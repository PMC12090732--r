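---
title: "Methods: inferring host-symbiont interactions from population-level meta-transcriptomes"
author: "symbiocor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring host-symbiont interactions from population-level meta-transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The inference problem

Two maternally transmitted intracellular bacteria — a *Cardinium*-like
lineage (symbiont A) and a *Wolbachia*-like lineage (symbiont B) — share one
arthropod host but almost never co-occur stably, suggesting antagonism.
Population-level RNA-seq of whole cultures mixes reads from all three
organisms, so their interactions are not observed directly; they must be
inferred from how expression co-varies across replicate cultures under three
infection states: A-only cultures, B-only cultures, and mixed cultures
founded by combining the two. The experimental grid is eight cultures (two
A-single, two B-single, four mixed) with seven replicate flasks each.

Every statistic in the pipeline is nonparametric or permutation-based:
read counts are small-sample, overdispersed and compositional, and the
number of replicates per culture is modest, so rank statistics with exact or
Monte-Carlo permutation nulls are the appropriate tools throughout.

## Pipeline stages and their statistics

**Standardization.** Samples are equalized by rarefaction: each sample's
reads are subsampled without replacement (multivariate hypergeometric) to
the minimum sample total, preserving integer counts and the zero pattern.
The expected downsampled count is `count * min_total / total`, which the
test suite verifies against the hypergeometric moments. Rarefaction rather
than proportional rescaling keeps counts valid for rank statistics; a
single seeded draw is used (repeating and averaging would break the count
scale). Read *proportions* (symbiont/host) are always computed on
unstandardized counts, since rarefaction would erase exactly the quantity
of interest.

**Shannon diversity.** Each sample's gene-count distribution is summarized
by H = −Σ pᵢ ln pᵢ (natural log by default; the base is configurable).
H is computed on standardized counts by convention. Two-group comparisons
use Mann–Whitney; because published tables sometimes print the U statistic
and sometimes the normal deviate, both are reported. Three or more groups
use the tie-corrected Kruskal–Wallis chi-square approximation. The
diversity–diversity relationship between organisms is an ordinary
least-squares regression with F-test, confidence band and prediction band.

**Mann–Whitney with ties.** For group sizes up to 8 the two-sided p-value
is computed by full enumeration of the `choose(n1+n2, n1)` label
assignments — valid under ties, where the classical exact distribution is
not — via the doubled smaller tail of the rank sum. Larger groups use the
tie-corrected normal approximation.

**Correlation networks.** Spearman ρ is Pearson correlation of average
ranks. Significance comes from permuting one margin: exact enumeration of
all n! permutations when n ≤ 7, otherwise p = (1 + #{b : |ρᵦ| ≥ |ρ|})/(B+1)
with B = 9,999 by default for single pairs (999 for whole networks). The
+1 convention keeps p ≥ 1/(B+1) and makes "reject at α" exact at
p ≤ α. A whole network shares one permutation stream — every gene pair is
re-evaluated under the same sample reshuffles — which is both faster and
reproducible; pairs remain exchangeable because the reshuffle is applied to
whole samples. Edges are filtered at raw p < α by default, mirroring
common practice for these screens; a Benjamini–Hochberg option exists but
is off by default, so edge counts are comparable across conditions rather
than error-controlled. Outlier genes are flagged by the Tukey upper fence
(Q3 + 1.5·IQR) on their per-condition signed-edge counts; the fence
multiplier is configurable since no single convention dominates. Profile
dendrograms use Ward (ward.D2) or UPGMA linkage on Euclidean or
Bray–Curtis distances; edge lists keep significant edges at or above a
|ρ| quantile (0.75 by default).

**Distances.** Bray–Curtis d(j,k) = Σ|yᵢⱼ−yᵢₖ| / Σ(yᵢⱼ+yᵢₖ) for
standardized counts. For unstandardized counts the robust Aitchison
distance is used: each sample is transformed by the robust centered
log-ratio (log of positive counts minus the mean log over that sample's
positive counts, zeros treated as missing), and sample pairs are compared
by Euclidean distance over their shared positive features, scaled by
sqrt(n_features/n_shared) so sparser pairs remain comparable. On dense
data this reduces exactly to classical CLR + Euclidean, which the tests
verify.

**PCoA and dbRDA.** Principal coordinates come from Gower double-centering
of −D²/2; axes with eigenvalues above 1e-10 are kept, negative eigenvalues
are reported and their axes discarded (no Lingoes/Cailliez correction by
default — the common default of constrained-ordination software, and the
inertia lost is visible in the reported negative eigenvalues). dbRDA
regresses the retained coordinates on the predictors; for partial models
the conditioning variables are projected out of both coordinates and
predictors first. Explained variability is R² = constrained/total inertia
(unadjusted; an Ezekiel-style adjusted R² is also reported, since published
"R" values do not always say which they are). The permutation test permutes
rows of the (residualized) coordinates — free permutation for simple
models, residual permutation under the conditioning model for partial ones
— and compares pseudo-F = (constrained/q)/(residual/(n−q−c−1)). On
Euclidean distances the whole construction coincides with classical RDA,
which the tests verify to 1e-8 against an independent implementation.

**Forward selection.** Candidates enter by lowest marginal permutation p
(each tested as a partial model conditioned on the already-selected set),
with ties broken by larger marginal R², then column order. Selection stops
when the best p ≥ α or — after a variable is accepted — when the
cumulative adjusted R² exceeds that of the full candidate model. Published
descriptions of the double-stopping rule are ambiguous about whether the
variable that crosses the adjusted-R² ceiling is kept; applying the guard
after acceptance keeps a genuinely informative variable that single-handedly
explains more (adjusted) variance than the noise-diluted full model, while
still preventing noise accumulation afterwards.

**ANOSIM and SIMPER.** ANOSIM R = (mean between-group rank − mean
within-group rank)/(N(N−1)/4) on ranked distances; R is therefore invariant
under monotone transforms of the distances. The p-value enumerates all
distinct label arrangements when there are at most 10,000 of them (always
the case at N ≤ 8), otherwise Monte-Carlo permutation; with more than two
groups, pairwise tests are Bonferroni-adjusted. SIMPER decomposes the mean
between-group Bray–Curtis dissimilarity into per-variable contributions
(mean over between-group pairs of |yᵢⱼ−yᵢₖ| divided by the pair total);
the contributions sum to the mean dissimilarity exactly, an identity the
tests check to 1e-9.

**Differential expression.** Per-gene Mann–Whitney on standardized counts
(exact at the default 7 + 7 up to 14 + 14 design sizes; a Welch t on log2
counts is available), Benjamini–Hochberg adjustment within the organism's
gene set, and up/down/ns classification at q < α with the sign of the
pseudocount-stabilized log2 fold change (c = 0.5, small against library
totals). A nonparametric per-gene test matches the rest of the pipeline's
rank-based philosophy.

**Pathway models.** For each host pathway with at least two annotated
genes, and for each of five model conditions (each symbiont in its
single-infected cultures, each in mixed cultures, both jointly in mixed
cultures), a partial dbRDA predicts the pathway's Bray–Curtis structure
from forward-selected symbiont genes (log2-transformed, candidate pool
capped at the most variable genes), conditioning on culture identity so
between-culture host background is not credited to the symbionts. The cell
value is the selected model's R², zero when nothing enters. The pathway ×
condition matrix is clustered by K-means on the raw R² rows (columns share
the [0,1] scale, so no standardization is imposed), with k either fixed or
chosen to maximize the average silhouette over k = 2..8, and summarized by
within-group sum of squares, pseudo-F, percent variance explained and
average silhouette. A 41-name immune/regulatory pathway panel ships as the
default display-name pool for synthetic annotations.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which every downstream claim is validated.

**Design.** Eight cultures (5L, 5S single-A; 5N, 5P single-B; 5LN, 5LP,
5SN, 5SP mixed) × 7 replicates. Genome scale defaults to a desk-scale 60
host / 30 + 30 symbiont genes (the real system is ~5,841 host KEGG genes
and 882/974 symbiont genes; all counts are scalable). Counts are
gamma-Poisson: counts ~ NB(mu, size = 1/dispersion) with dispersion 0.05,
a typical biological-replicate overdispersion for bulk RNA-seq. Expected
library size is 5×10⁵ reads; symbiont A holds 8% of reads wherever present,
symbiont B 10% in its single cultures and 10% × 0.1 in mixed cultures —
the planted 10-fold drop. Symbionts absent from a culture contribute exact
zeros. Baseline gene abundances are lognormal(0, 1).

**Planted correlation structure.** Naively giving every gene a latent-factor
loading does not survive standardization: fixing each sample's total
(compositional closure) re-centers effective loadings, and the planted sign
structure washes out to ~1:1. The generator therefore plants the signal the
way dominant transcriptional programs behave in real compositions: a small
set of high-abundance **driver** genes per symbiont (driver_frac of genes,
baseline weight boosted driver_boost-fold, ~45% of the organism's reads)
responds to shared per-sample latent factors with log-scale loadings
(latent_sd). Closure then pushes every other gene's relative share the
opposite way, a signal that rank statistics detect reliably. In mixed
samples the loadings of a fraction `latent_sign_mix` (default 0.9) of
symbiont-B drivers are sign-flipped, so symbiont-A and symbiont-B genes
correlate predominantly negatively — with a small positive cluster from
driver-versus-rest pairs, qualitatively matching the minority positive
cluster seen in real data. With the flip fraction at 0.9 the realized
negative:positive significant-edge ratio is well above 5 (typically around
10–14:1). Host genes in "responsive" pathways carry signed loadings on the
same factors, making those pathways predictable from symbiont expression.

**Planted differential expression.** DE genes respond to double infection
(mixed vs single) with ±de_log2fc (default 2). Signs alternate and each
up-gene is weight-paired with its down partner (the down gene's baseline
weight is 2^lfc times the up gene's), so the organism's total output is
invariant; otherwise closure would shift every non-DE gene's share between
conditions and the unplanted genes would not be null — an artifact, not a
discovery. Driver genes are excluded from the DE pool. Per-organism DE
settings also create the directional asymmetry condition: giving symbiont A
a stronger response to B's presence than vice versa yields
R²(A-genes | B-presence) > R²(B-genes | A-presence) in almost all
replicate simulations.

**What the generator does not emulate.** Read-level error, mapping
ambiguity between the three genomes, batch or flask effects beyond NB
noise, library-size gradients correlated with condition, zero inflation
beyond NB sampling, within-culture demographic composition (infection
frequencies, sex ratios), and any phylogenetic or operon structure among
genes. Passing tests therefore demonstrate that the statistics recover the
planted population-level signal under idealized sampling — not that they
are robust to alignment artifacts or confounded designs.

**Free parameters.** Within-culture variance components are not published
for this system, so dispersion (0.05), latent scale (latent_sd = 1),
driver geometry (driver_frac = 0.04, driver_boost = 25) and the read
proportions (0.08/0.10) are the package's own choices of a realistic
regime: symbionts a few percent to a tenth of the transcriptome, drivers
comparable to a dominant operon, and replicate-level noise typical of bulk
RNA-seq. They were fixed once at design time and the defaults are the
tested study conditions.

## Numerical choices

* Permutation p-values use the +1 Monte-Carlo convention; "reject at α"
  means p ≤ α, which makes the nominal level exact on the permutation
  lattice.
* Statistic comparisons in permutation loops use a 1e-12 tolerance so exact
  ties survive floating-point round-off.
* PCoA keeps eigenvalues > 1e-10; negative eigenvalues are reported, not
  corrected.
* Forward-selection ties break by marginal R², then column order, making
  selection deterministic for a fixed seed.
* All stage seeds derive from one global seed via a fixed affine map, so
  stages are reproducible in isolation and whole-pipeline reruns are
  bit-identical (the manifest records md5 sums). Per-pathway seeds are
  keyed to the pathway identifier, not its list position, so effect
  matrices are invariant to pathway order.
* K-means uses 25 restarts under a fixed seed; k = 1 is rejected because
  the silhouette is undefined there.

## Problem sizes used by the tests

The suite validates exact oracles at enumeration scale (n ≤ 7 permutations,
N ≤ 8 label arrangements), classical-RDA equivalence at 10 samples × 8
variables, null calibration at 300–500 replicates per test, and planted
recovery on the default 60/30/30-gene, 56-sample design over 5–20 seeds —
sizes chosen so the full suite and the acceptance script each run in a few
minutes on a single core while keeping Monte-Carlo error well inside the
asserted bands.

## Known limitations

* The permutation schemes assume exchangeable samples; flask-level
  pseudo-replication within cultures is only addressed where culture
  identity is explicitly conditioned on (the pathway models).
* Raw-p edge filtering (the default) inflates the absolute number of
  significant edges; only contrasts of such counts between conditions are
  meaningful, which is how the pipeline uses them.
* The robust Aitchison distance's shared-feature scaling is undefined for
  sample pairs with disjoint positive supports; such pairs raise an error
  rather than guessing.
* Unadjusted R² in dbRDA grows with predictor count; forward-selected
  models with different df are therefore compared qualitatively, as effect
  profiles, not as calibrated effect sizes.
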