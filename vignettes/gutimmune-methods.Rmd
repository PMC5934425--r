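---
title: "Methods: joint metagenome and immune-repertoire analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint metagenome and immune-repertoire analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutimmune)
```

# Overview

`gutimmune` implements the statistics of a diet-intervention study that
profiles the same subjects twice (day 0 and day 91) on two molecular
axes: shotgun gut metagenomes and amplicon-sequenced B-/T-cell receptor
repertoires. The package takes clone tables and gene read counts as its
input boundary — read QC, alignment to germline V/D/J genes, and mapping
to a reference gene catalog happen upstream — and covers everything from
there to the final cross-domain association network. This vignette
records the models, the parameter choices, and the design decisions made
where the underlying protocols leave room.

# Repertoire statistics

A *clone* is by default a unique CDR3 amino-acid sequence together with
its V and J gene calls; isotype-resolved statistics key on the
CDR3–C–J combination instead, so one CDR3 expressed as both IgM and IgG
contributes to both classes. Nucleotide-level identity is available by
configuring the clone key.

*Diversity ratio* is unique clones over total reads. *D50* sorts clones
by count (ties broken lexicographically by clone key, for determinism)
and reports `100·X/Y` with `X` the shortest prefix reaching half the
reads; an even repertoire with an even clone count scores exactly 50.

The *delta index* measures repertoire turnover between the two
timepoints. Counts are converted to within-sample frequencies —
mathematically equivalent to the protocol of normalizing each sample to
`N₀ = 10×10⁶` reads and dividing by `N₀`, while avoiding large-integer
resampling; `N₀` is kept as a parameter for provenance only. Over the
union of clone keys the absolute frequency difference `d_c` is computed,
clones are ranked, and the top `min(1000, |union|)` values of `d_c` are
summed. Two readings of "the 1,000 most common" clones are defensible:
ranking by the difference itself (the quantity the protocol sorts by) or
by the larger of the two clone frequencies. Both yield the documented
bounds — 0 for identical samples, 2 for disjoint ones when the union
fits the window — and both are implemented; ranking by difference is the
default. Note the exact upper bound 2 requires the union of clones to
fit within the top-1,000 window (at most 500 clones per disjoint
sample); beyond that the truncated sum falls below 2.

The shared-clone "frequency" between two repertoires is not pinned down
by common usage; we use the Jaccard index over clone keys, with the
overlap coefficient as an option.

# Metagenome profiles

Relative gene abundance is the length-normalized share
`aᵢ = (xᵢ/Lᵢ)/Σⱼ(xⱼ/Lⱼ)` — the standard correction for longer genes
recruiting more reads; a no-normalization mode exists for toy inputs.
Taxon and KO profiles sum member-gene abundances. Genes lacking an
annotation are pooled into an explicit `unannotated` bucket, kept by
default so that per-sample mass is conserved exactly (and testable);
dropping the bucket with renormalization is available to match common
practice.

Shannon diversity and the Kullback–Leibler terms of the Jensen–Shannon
distance use the natural logarithm (no base is canonical here; log2 is a
switch). JSD is computed exactly with the `0·ln 0 = 0` convention and no
pseudocount, which keeps the closed forms exact — `d(P,P) = 0`,
`d([1,0],[0,1]) = √ln2` — and makes the distance a metric on the
simplex; zero-replacement smoothing is available for fidelity to
enterotyping protocols that use it.

# Enterotyping

Samples are clustered on the genus-level JSD matrix with classic
partitioning around medoids (BUILD initialization, then best-improvement
SWAP — deterministic given the matrix). The number of clusters is chosen
by the Calinski–Harabasz index computed from the distance decomposition
(`SS_total = (1/n)Σ_{i<j} d²`, `SS_within = Σ_g (1/n_g)Σ_{i<j∈g} d²`),
over k = 2…10, with ties broken toward smaller k. A perfect partition of
duplicated samples has zero within-cluster dispersion; the CH score is
reported as `Inf` and the argmax rule handles it.

The ordination is a centered, unscaled PCA of the relative abundances
(the duality-diagram default for quantitative variables); feature
scaling, `log(x+ε)` and Hellinger transforms are options. A profile that
is constant across samples has no defined explained-variance shares and
raises an error rather than returning degenerate output.

# Reporter scores

Per KO, a one-tailed Wilcoxon rank-sum test is run in each direction;
p-values are BH-adjusted *within each tail* (the two tails are not
complementary after BH, so each direction is a full independent run),
then transformed as `Z_KO = Φ⁻¹(1 − p_adj)` with p clamped to
`[1e-15, 1−1e-15]` so Z stays finite (|Z| ≤ ~7.94) without affecting
ranking. A pathway with k scored member KOs aggregates as
`Z = ΣZ_KO/√k` (the classic reporter-feature form; `1/k` averaging is
retained as a sensitivity option). The background takes 1,000 random
k-subsets of all scored KOs — drawn without replacement within a set,
from one seeded generator, with one background shared per distinct k —
and standardizes `Z_adj = (Z − μ_k)/σ_k`. Pathways are flagged at
`|Z_adj| > 1.96`, strictly. If every KO carries an identical Z (a fully
degenerate null, e.g. all adjusted p equal), the background has zero
spread and the adjusted score is defined as 0; any other zero-spread
background is an error naming the pathway.

Exact-mode policy for the rank tests: exact distributions are used
whenever both groups have fewer than 50 untied observations (rank-sum)
or up to 49 untied pairs (signed-rank); tied absolute differences are
enumerated exactly over all 2ⁿ sign patterns up to n = 12. Everything
larger uses the normal approximation with midrank tie correction,
continuity correction, and Pratt handling of zero differences.

# PERMANOVA and the association network

The single-covariate PERMANOVA Gower-centers the squared distance
matrix into `G` and computes
`F = [tr(HGH)/(m−1)] / [tr((I−H)G(I−H))/(n−m)]` from the covariate's hat
matrix (one-hot groups, or a centered column for numeric covariates) —
algebraically identical to the classic group-sum decomposition, which
the tests verify to 1e-9 against both an independent implementation and
`vegan::adonis2`. The permutation p-value uses the `(1+b)/(1+m)`
estimator so it is never zero; its attainable floor depends on the
permutation distribution (duplicated samples make many permutations
equivalent). Multi-factor sequential decomposition is out of scope: the
study design calls for one marginal test per phenotype.

Differential abundance is two-sided (no directionality is assumed a
priori), with direction reported from group medians; features constant
across the used samples are excluded with a warning since no rank test
is defined for them. Significance is called on the raw p < 0.05, as is
conventional for these screens; BH-adjusted values are emitted alongside
for the reader. The Spearman network tests species whose *mean* relative
abundance across samples exceeds 1e-7 (the filter's reference statistic
is configurable; the mean is the least surprising reading) against each
numeric immune index, with exact permutation p for n ≤ 9 and the
t-approximation otherwise.

# The synthetic cohort

The generator emulates the study design: three groups (15 study
subjects, 7 omnivorous and 7 long-term vegetarian controls), two
timepoints, subgroup labels A–F shared between real and synthetic
metadata. Species compositions come from a Dirichlet mixture: each of
the (default 3) enterotype components gets a mean composition with one
distinct dominant driver taxon — mirroring the classic
Bacteroides/Prevotella-style dominance structure — and a subject's
composition is drawn from `Dirichlet(c·S·m)` where `m` is the component
mean over `S` species and `c` (default 0.3) is the mean per-species
concentration; smaller `c` gives more individual microbiomes. Expected
gene-level read shares are species abundance × within-species gene
length share; diet effects multiply the targeted species/genus/KO in
post-diet study samples before renormalization (matching the
compositional nature of the data); read counts are multinomial at the
design depth. A frequency mode skips sampling and returns exact expected
abundances for analytic tests.

Repertoires follow a rank-frequency power law `p_r ∝ r^−α` with
α = 1.5 — typical of observed clone-size distributions — or a log-normal
alternative. Day-91 frequencies mix the persistent day-0 clones (total
mass ρ, relative sizes unchanged) with novel clones (mass 1−ρ), so in
frequency mode the delta index is exactly `(1−ρ)` times its ρ = 0 value
and strictly decreasing in ρ.

What the generator does *not* emulate: read-level errors, PCR bias,
strain-level variation, co-occurrence structure between taxa, somatic
hypermutation lineages, or any real covariance between a subject's
microbiome and repertoire. Passing tests therefore demonstrate that the
statistics recover *planted* structure under idealized sampling noise,
not that they would detect effects of comparable size in real cohorts.

# Problem sizes and calibration checks

Simulation-based checks run at desk scale, chosen to finish within
minutes while leaving the conclusions stable: catalogs of 300–2,000
genes over 30–60 species, sequencing depth 1e5 reads/sample (the
generator's default stands in for the tens of millions of reads of a
real run), repertoires of 400–10,000 clones. The test suite verifies,
among others: enterotype recovery (3 planted components, 30 samples,
concentration 0.3 — k = 3 selected and ARI ≥ 0.9 in ≥ 90% of 20 seeds),
reporter-score calibration (null flag rate 5% ± 5 points over 50 seeds ×
20 pathways; a 4-fold planted KO shift detected in the correct direction
in ≥ 80% of seeds), PERMANOVA null rejection (5% ± 3 points over 200
replicates at 999 permutations), and recovery of a 4-fold planted effect
on a prevalent species by the unpaired test in ≥ 80% of 50 cohorts at
depth 1e5 and 10 subjects per group. Rank tests, BH adjustment and JSD
are checked against exhaustive-enumeration and closed-form oracles.

# Known limitations

- The delta index's printed upper bound of 2 is only attained when the
  disjoint union fits the top-1,000 window (see above).
- PAM is a local optimizer; the tests verify single-swap local
  optimality, not global optimality.
- The reporter background assumes member KOs are exchangeable with the
  KO pool; strongly size-biased pathway maps would need a stratified
  background.
- PERMANOVA is marginal per covariate; confounded covariates are not
  adjusted for each other.
- With heavy ties (many zero-abundance KOs), rank-test approximations
  are conservative; the exact tie enumeration only covers small paired
  samples.
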