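---
title: "Methods: models, estimators and design choices in foxscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in foxscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(foxscape)
```

`foxscape` analyses dual-marker population-genetic data — diploid
microsatellite genotypes and maternally inherited mtDNA haplotypes — from
metapopulations established by multiple independent introductions. This
vignette explains the statistical machinery, the defaults and why they
were chosen, what the synthetic-data generator does and does not emulate,
and the numerically delicate corners.

## Data model

A `genotype_table` stores unordered diploid allele pairs (missing calls
are missing, never imputed; every statistic uses pairwise deletion per
locus, so an individual missing a locus leaves that locus's statistics
only). Allele labels are opaque strings except where stepwise mutation
models need integer repeat scores (`repeat_loci`). A `haplotype_counts`
table is a site × haplotype count matrix; published tables often carry
declared per-site *n* and diversity columns, which travel along as
checksums — counts are authoritative, the declared *n* is a checksum.
Geometry is planar km throughout; lon/lat input is projected with a local
equirectangular projection about the site centroid, whose distance error
at a ~1000 km study extent and mid-latitudes stays below ~1%, far inside
the uncertainty of any genetic distance used here.

## Diversity and the mtDNA F_ST partition

Gene diversity is the **uncorrected** *h* = 1 − Σ *p*ᵢ². This choice is
deliberate: it exactly reproduces published per-site values computed from
the same counts (the *n*/(*n* − 1) unbiased variant is available via
`unbiased = TRUE` but is not the default). The global mitochondrial
*F*<sub>ST</sub> is the diversity partition 1 − mean(*h*<sub>within</sub>)/
*h*<sub>total</sub>, with *h*<sub>total</sub> from the pooled counts and
the within mean unweighted over an explicit inclusion list.

Two corner cases deserve note. First, inclusion: published tables mark
small or mixed-provenance rows with a dash in the diversity column; when
a declared diversity column exists, the default inclusion list is exactly
the rows that carry a value, otherwise sites with *n* ≥ 5. Second,
corrupt rows: a row whose counts fail the declared-*n* checksum has
unreliable counts, so its within-site term falls back to the declared
diversity (with a warning) rather than propagating a number computed from
known-bad counts. Pooled totals always use the raw counts, whose column
sums are internally consistent.

## Differentiation

`weir_cockerham_theta()` implements the 1984 variance-components
estimator: per locus and allele the among-site (a), among-individual (b)
and within-individual (c) components, θ = Σa / Σ(a+b+c) over loci and
alleles. Pairwise estimates may legitimately be negative and are
preserved; only the linearized matrix *x*/(1 − *x*) clamps at zero, and
values ≥ 0.999 linearize to +Inf and are excluded (with a count) from
downstream regressions and Mantel inputs. CIs come from 1000 bootstrap
resamples of loci. The haploid analogue (`pairwise_haplotype_fst()`) uses
the corresponding mean-square form for haplotype counts. Nei's
*D*<sub>A</sub> drops a locus for a site pair when either site is untyped
there, shrinking the divisor, and retains per-locus matrices so the tree
bootstrap can resample loci.

The sex-bias ratio uses the island-model identities
*F*<sub>nuc</sub> = 1/(1 + 4*N m̄*) with *m̄* = (*m*<sub>m</sub> +
*m*<sub>f</sub>)/2, and *F*<sub>mt</sub> = 1/(1 + *N m*<sub>f</sub>)
(haploid, maternal, *N*/2 females), giving
*m*<sub>m</sub>/*m*<sub>f</sub> = [(1/*F*<sub>nuc</sub> − 1)/2 −
(1/*F*<sub>mt</sub> − 1)]/(1/*F*<sub>mt</sub> − 1). The reduction was
verified against its defining identities and the boundary cases
(symmetric migration gives 1; *F*<sub>mt</sub> at the admissibility edge
gives 0; an *F*<sub>mt</sub> below the admissible region is flagged and
floored at 0, since no nonnegative male rate is consistent with it).

## Equilibrium tests

The Hardy–Weinberg permutation test permutes alleles among individuals
within a site (preserving allele frequencies, destroying diploid pairing)
and uses multi-locus *F*<sub>IS</sub> as its statistic with the two-sided
p-value (1 + #{|stat| ≥ |obs|})/(n_perm + 1). Gametic equilibrium permutes
single-locus genotypes among individuals and uses the G log-likelihood
ratio of the two-way genotype table. Monomorphic loci are skipped with a
flag. Rice's sequential Bonferroni is Holm's method and is provided as a
thin wrapper over `p.adjust`.

## LD effective size

`ld_ne()` computes the Burrows composite disequilibrium
Δ = *n*/(*n*−1) [Σ *X*<sub>A</sub>*X*<sub>B</sub>/(2*n*) − 2*p̂*<sub>A</sub>*p̂*<sub>B</sub>]
over all retained allele pairs (alleles under the 0.05 frequency cutoff
excluded, matching standard practice), normalizes to *r̂²*, subtracts the
random-mating sampling expectation (1/S + 3.19/S² for S ≥ 30, else
0.0018 + 0.907/S + 4.44/S²) and inverts the matching quadratic to
*N̂*<sub>e</sub>; a corrected *r²* ≤ 0 yields +Inf, the estimator's honest
answer when drift LD is below sampling noise. Random mating (not
monogamy) is assumed, as mixed-parent litters argue for fox populations.
The CI is a delete-one jackknife over locus pairs on the corrected *r²*,
transformed monotonically to the *N*<sub>e</sub> scale. Calibration on
Wright–Fisher simulations (true *N*<sub>e</sub> = 50, S = 50, 13 loci)
shows majority CI coverage with the expected modest upward bias of the
point estimate at this scale.

## Bottleneck test

For each polymorphic locus with *k* alleles among *n* sampled genes, the
mutation–drift-equilibrium distribution of heterozygosity given *k*
(H<sub>eq</sub>) is simulated: Kingman coalescent genealogies with
Poisson(θ/2 × branch length) mutations, allele states propagated from the
root under IAM, SMM, or TPM (default 70% single-step; multi-step sizes
1 + Geometric with variance ≈ 30, the conventional two-phase setting).
Replicates are retained only if they produce exactly *k* alleles; to keep
that rejection efficient θ is tuned by bisection on the expected allele
count (monotone in θ), and tuned rates are memoised per (*n*, *k*, model)
on an isolated RNG substream so results are bit-reproducible under a
fixed seed regardless of cache state. Loci that cannot reach *k* alleles
within the attempt budget are dropped and logged; monomorphic loci are
excluded (H<sub>eq</sub> degenerate at 0). Significance across loci is the
two-tailed Wilcoxon signed-rank test on standardized deviations
(exact distribution for ≤ 25 loci). Type-I calibration on
coalescent-equilibrium SMM data holds the nominal 5% level; 4-founder
bottlenecks 2 generations back are detected with high power, matching the
expectation that newly founded populations show heterozygote excess.

## Trees and ordination

Neighbor joining follows Saitou–Nei with the standard Q-criterion. Two
details are pinned down because published trees depend on them: ties in Q
break toward the lexicographically smallest label pair (deterministic
topology on equidistant inputs), and a negative branch length is set to
zero with the deficit transferred to the adjacent branch of the joined
pair, preserving the path length between the joined leaves. On
tree-additive matrices NJ provably recovers the generating tree; the test
suite verifies exact recovery (topology and branch lengths) on random
additive instances up to 8 taxa, cross-checked against an independent NJ
implementation. Bootstrap support resamples loci with replacement,
recomputes *D*<sub>A</sub> and the tree, and attaches support to the
*original* tree's bipartitions (not a consensus topology), written to
Newick as internal node labels.

PCoA uses the Smouse–Peakall squared genotypic distance (0/1/2/3/4 by
shared-allele count and heterozygosity, summed over loci with pairwise
deletion), Gower double-centering, and a symmetric eigendecomposition;
axes with positive eigenvalues are returned and negative eigenvalues
reported. Pairs with no shared typed locus are imputed at the mean
squared distance with a logged count.

## Admixture model and cluster profiles

`admixture_mcmc()` is a Gibbs sampler for the classic admixture model:
allele-copy origins Z given ancestry Q and cluster frequencies P;
P from its Dirichlet full conditional (flat base prior, or the
correlated-frequencies F-model prior Dirichlet(p_A(1 − F_k)/F_k) with
Metropolis updates of the ancestral frequencies p_A and per-cluster drift
F_k); Q ~ Dirichlet(α + copy counts); and a Metropolis step on α with a
uniform prior. ln P(D) is the usual mean-minus-half-variance estimate of
the data log-likelihood over post-burn-in cycles and is reported for
comparison only — K selection here never rests on a single information
criterion, reflecting the known unreliability of pure ln P(D) maximization
under hierarchical structure.

Chains initialize by default from a k-means clustering of the individual
allele-dose matrix (`init = "kmeans"`). On strongly structured data this
lets replicate chains find the dominant posterior mode within short runs;
replicate disagreement then carries signal. A symmetric random start is
available (`init = "random"`), and the desk-scale defaults (2000 cycles)
deliberately sit far below production settings (hundreds of thousands of
cycles), which remain available through the arguments.

`align_runs_build_profiles()` integrates runs over K. Replicates within a
K are aligned by greedy maximum-correlation column matching (documented as
approximate) and averaged. A K is **multimodal** when aligned replicates
disagree on the modal cluster of more than a tolerance fraction (default
5%) of *confidently assigned* individuals (max q ≥ 0.6) — genuinely
admixed individuals wobble between modal clusters without indicating
distinct posterior modes. Multimodal levels drop out of the nesting chain
rather than terminating it, mirroring the practice of distrusting K
levels whose replicate runs diverge. A transition between consecutive
retained levels is **nested** when every higher-K cluster draws its modal
members from a single lower-K cluster (up to the tolerance) and
**informative** when it adds at least one meaningfully occupied cluster —
clusters whose modal membership does not exceed the tolerance fraction
(a lone stray individual) do not count as structure. The chosen K is the
highest level reachable through nested, informative transitions. On
hierarchical simulations (two source pools × two founder demes each) this
recovers the true K = 4 in ≥ 80% of replicates at desk scale; the
documented failure modes are a genuinely ambiguous K level (chain stops
early, conservative) and real within-deme family substructure when demes
are founded by a single pair.

Migrant classification follows the q-threshold rule: the home cluster of
a site is the modal cluster of its members (ties break toward higher mean
q, logged); an individual with q_max ≥ 0.75 is a resident or a
first-generation migrant according to whether its modal cluster is the
home cluster, and below the threshold it is admixed. Temporal composition
reports per-period mean ancestry, migrant fractions, and the L1 distance
between consecutive period compositions.

## Landscape genetics

The model-free surface regresses pairwise genetic distance on Euclidean
distance (OLS over the n(n−1)/2 pairs; infinite linearized values
excluded with a count), places each pair's residual at the arithmetic
midpoint of the two sites, and interpolates by inverse distance weighting
(default power 2, unlimited search radius, both exposed — the method's
sources are silent on both, so they are configuration, not constants;
a cell coincident with a midpoint takes that residual exactly). The
permutation null relabels sites (simultaneous row/column permutation of
the genetic matrix; permutation 1 is the identity so the observed surface
belongs to its own null set) and returns per-cell null quantiles and an
exceedance map. Default grid: 100 × 100 cells over the site bounding box
plus a 10% margin.

Effective resistance treats non-nodata raster cells as nodes of an
electrical network with 4-neighbor edges of conductance equal to the mean
of the two cells' conductances (1/resistance; the declared dialect — the
8-neighbor averaging of some circuit software is out of scope). Pairwise
effective resistance solves the grounded sparse Laplacian system, with a
Cholesky factorization per connected component; site pairs in different
components report +Inf with a warning. The dense pseudoinverse identity
R_eff(a,b) = L⁺aa + L⁺bb − 2L⁺ab serves as the test oracle (agreement to
1e-8 on random rasters). Habitat-suitability rasters invert to resistance
as 1/max(suitability, floor) with a default floor of 0.01.

Mantel tests correlate off-diagonal upper triangles, permute one matrix
by random site relabelings, and default to the one-tailed positive
p-value (1 + #{r ≥ r_obs})/(n_perm + 1) — association hypotheses about
distance matrices are directional here; two-sided is a flag away. The
partial test regresses both matrices on the conditioning matrix
element-wise and permutes the residual matrix (the residual-permutation
method). Euclidean and resistance matrices are log-transformed on request,
guarded against non-positive entries. Exhaustive enumeration of
relabelings is available for exact small-sample tests.

## The synthetic metapopulation generator

`simulate_metapopulation()` is a forward-time, individual-based simulator
with non-overlapping generations, an even sex ratio, and random union of
gametes within sites (a monogamous-pair option exists to probe the LD-Ne
mating-system assumption). Its defaults are the study conditions it
emulates: 8 founding populations (independent draws of 3 founder pairs
from one shared source pool), ~30 generations of drift at census 100,
male-biased migration (m_m = 0.04, m_f = 0.01 — a fourfold bias), 13
microsatellite loci (8-allele source ladders, SMM mutation at 5e-4,
switched off for calibration runs), and 10 source haplotypes transmitted
maternally. Migration replaces a Binomial(N_sex, m_sex) draw of residents
with immigrants from other sites with probability proportional to
1/resistance-distance (Euclidean when no landscape raster is supplied).
The truth record (realized migrant counts by generation and sex, founder
states, per-individual sampled haplotypes, the seed) supports
parameter-recovery tests; output is bit-reproducible given (config, seed).

What it does **not** emulate: overlapping generations and age structure,
uneven or varying census sizes, genotyping error and null alleles, allele
ladders with size homoplasy across loci, spatially continuous (rather
than island) population structure, and landscape change over time.
Passing calibration tests on this generator therefore demonstrates
estimator correctness under the stated model, not robustness to those
real-data complications.

## Problem sizes used in the test suite

The suite runs everything at desk scale, chosen to make each calibration
informative while keeping the whole suite comfortably runnable on one
CPU: 500-replicate type-I calibrations for the HWE and Mantel permutation
tests (n_perm = 99 inside each), 100 replicate sites for the bottleneck
type-I check (8 loci, 60 retained equilibrium replicates per locus), a
16-deme island model at 4Nm = 4 for the θ calibration, 20 Wright–Fisher
replicates for LD-Ne coverage, 20 hierarchical simulations (2 × 2 demes,
10 runs of 400 cycles each) for cluster-profile K selection, and 20
island-model replicates for the fourfold sex-bias recovery. Production
analyses would scale the MCMC and permutation counts up by one to two
orders of magnitude through the exposed arguments.

## Known limitations

- The admixture sampler is a single-chain Gibbs sampler; on weakly
  structured data short replicate runs disagree (by design this is
  detected and the level discarded), and the k-means initialization,
  while it stabilizes strong structure, makes replicate agreement at
  K levels beyond the true structure more likely than a cold start would.
- The LD-Ne corrections are the published random-mating formulas; no
  monogamy correction is applied even when the simulator breeds
  monogamously.
- The bottleneck test conditions on the observed allele count by
  rejection; for very high-diversity loci in small samples the locus may
  be dropped when the budget is exhausted.
- Greedy column matching can misalign clusters of nearly identical mean
  ancestry; the multimodality flag usually catches the consequence rather
  than the cause.
- Effective resistance is exact for the declared 4-neighbor dialect;
  numbers from 8-neighbor implementations will differ by a
  resolution-dependent factor.
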