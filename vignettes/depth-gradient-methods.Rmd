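---
title: "Methods: depth-gradient analysis of sponge holobionts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth-gradient analysis of sponge holobionts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific setting

Deep-sea sponges host dense prokaryotic communities and produce rich
secondary metabolomes; both the microbiota and the metabolome of a sponge
holobiont can shift along bathymetric gradients, where water masses with
distinct temperature and salinity stack on top of one another. `holodepth`
implements an integrative analysis of this situation: it classifies ASVs
(amplicon sequence variants) and LC-MS metabolite features by their
monotone association with depth, detects candidate water-mass *ecotypes*
(near-identical ASV pairs responding to depth in opposite directions),
summarizes community structure, models the metabolome's depth response
with OPLS regression, builds a consensus co-occurrence network from five
association estimators, and links microbes to metabolites across the two
omics layers. A synthetic-data module with a planted-truth ledger makes
every stage testable end to end without any external download.

The study design the package targets has three sponge species sampled
across roughly 240–1480 m, two of them with rich ("HMA", high microbial
abundance) and one with poor ("LMA") communities, and a water-mass
boundary near 1000 m that splits samples into "shallow" and "deep"
groups.

# Metabolome feature filtering

Untargeted LC-MS produces one intensity per *feature* (a retention-time /
m/z pair) per sample, plus pooled QC injections. Three published
filtering variants are implemented exactly:

* **cleaned** — drop features eluting in the void (retention time
  strictly below 40 s) and features whose QC coefficient of variation
  exceeds 0.30. The CV is the *sample* standard deviation (n−1 denominator,
  the metabolomics QC convention) divided by the mean of the raw QC
  intensities; a zero-mean QC series leaves the CV undefined and the
  feature is removed as unreliable. A feature at exactly 40 s is kept —
  the void rule is a strict inequality.
* **pc_group** — from a cleaned table, keep only the feature with the
  greatest cumulative signal per pc_group (a cluster of co-eluting
  adducts/isotopes of one compound). "Cumulative signal" sums over study
  samples only; QC injections are pooled material, not observations.
  Ties break deterministically to the lexicographically smaller feature
  id and are recorded in the filter report.
* **ion** — from a cleaned table, keep only features explicitly
  annotated as the protonated molecular ion `[M+H]+` (positive ESI) or
  deprotonated `[M-H]-` (negative ESI). Annotation matching normalizes
  whitespace and Unicode dash variants, so `"[M + H]+"` matches.

All three filters are idempotent, and the pc_group/ion outputs are
subsets of the cleaned output. Whether the CV should be computed on raw
or log intensities is not standardized in the field; raw intensities are
used here and stamped in the filter report.

# Depth-trend classification

For each variable (ASV relative abundance or feature intensity) the
package computes a Pearson (or Spearman) correlation with depth and a
two-sided p-value from the t transform of r on n−2 degrees of freedom.
Classes are `increasing`/`decreasing` when p ≤ α (default 0.05) and
`increasing-trend`/`decreasing-trend` for same-signed non-significant
correlations; constant variables are `none`. Benjamini–Hochberg adjusted
p-values are reported alongside the raw values over the family of
testable variables — the class rule uses the raw p, and consumers choose
which stringency to act on. Welch's unequal-variance t-test compares each
variable above vs below the 1000 m water-mass split (samples exactly at
the split go to the shallow group); undefined tests (constant variables)
are flagged and kept out of the FDR family rather than diluting it.

Correlations are computed on total-sum-scaled relative abundances. This
is a deliberate, documented choice rather than a statistical fix: under
compositional closure a strong trend in one taxon necessarily drags the
relative abundance of others, so in a *noise-free* simulation every taxon
acquires a formally significant drift. The package documents this caveat
instead of replacing the analysis with log-ratio transforms, and its
recovery tests therefore assert that all planted effects are found with
the right sign, treating planted counts as a lower bound on the
classified counts.

An ASV is "common" when its mean relative abundance strictly exceeds
0.25%; the summary reports which fraction of all reads the common set
carries.

# Sister-group ecotypes

ASVs here are fixed-length (140 nt, two concatenated 70-nt reads), so
pairwise sequence identity is ungapped positional identity — matching
positions over length; a global-alignment identity is available behind
`align = TRUE` for variable-length inputs. A *sister pair* is an
unordered ASV pair with identity ≥ 0.97 and strictly opposing depth
responses. The response can be judged from the correlation classes or
from the water-mass t-tests (`basis`), at raw or FDR-adjusted
significance (`stringency`). Whether both members must be individually
significant is genuinely open; the package defaults to the strict
both-significant rule and exposes `require_both = FALSE` for the
one-significant relaxation. Relaxing the stringency can only add pairs —
a property the test suite asserts.

# Community statistics

Alpha diversity (richness, Shannon, inverse Simpson) and Bray–Curtis
dissimilarities delegate to vegan. PERMANOVA, ordination, environmental
fitting and the two cross-omics tests are implemented in-package because
the pipeline standardizes one permutation convention everywhere: seeded
permutations with the add-one estimator p = (1 + #{permuted ≥ observed})
/ (1 + N), which can never return zero, plus exhaustive enumeration for
small n where the permutation distribution is computed exactly. vegan's
`adonis2`, `envfit`, `mantel` and `protest` serve as independent
cross-checks in the test suite, never as the computation path.

Ordination is classical metric scaling (principal coordinates) of the
double-centred squared-distance matrix rather than stress-minimizing
NMDS: it is deterministic, exactly recoverable on Euclidean geometries,
and oracle-checkable. Axis signs are canonicalized (first non-zero
loading positive) so repeated runs are identical. This is a documented
divergence from NMDS-based ordination practice; axis loadings of an NMDS
are not comparable to principal-coordinate loadings, and the package
treats published NMDS loadings as qualitative context only.

Environmental vectors are least-squares directions in the 2-D score
space with r² the squared multiple correlation; significance permutes
the variable across samples. Variance-inflation screening removes the
largest-VIF variable iteratively until all VIFs are below 10, with
perfectly collinear variables (infinite VIF) removed first.
Transformation selection computes, for each candidate transformation
(identity, relative abundance, square root, log1p, presence/absence),
the Spearman correlation between Bray–Curtis dissimilarity and pairwise
depth separation, and returns the argmax. Hierarchical clustering is
UPGMA (average linkage), exact on ultrametric input.

# OPLS depth models

The metabolome's depth response is modelled with orthogonal projections
to latent structures: X (samples × features, log1p intensities) is
mean-centred and unit-variance scaled, `n_ortho` response-orthogonal
components are extracted and removed, then a single predictive component
regresses the response. With `n_ortho = 0` the model reduces exactly to
single-component PLS1, which the tests verify against an independent
closed-form oracle at 1e-8. Model quality follows the conventional
gates: Q² from k-fold cross-validation (default seven-fold, folds a
seeded random partition, scaling re-estimated inside each training
fold), pQ2 from permuting the response (default 200 permutations; fold
assignment fixed across the loop), and the verdict *rejected* when
pQ2 > 0.05, *good* when additionally R²X > 0.9 and Q² > 0.5, else
*acceptable*. VIP scores use the predictive-component formulation
`sqrt(p)·|w|`, one of several published VIP variants, chosen because the
orthogonal-filtered weights are what the predictive component actually
uses; squared VIPs average exactly 1.

The model battery fits one model per experiment × species × filter
combination — with four chromatography/polarity experiments, three
species and three filters, exactly 36 models, matching the full factorial
design.

Defaults that matter: `n_ortho = 1` (one orthogonal component absorbs
the dominant technical factor; the component count is configurable
because no universal choice exists), unit-variance scaling (the common
default for metabolomics; centring-only is available), and 99 response
permutations inside the battery for desk-scale runtimes (200 for
standalone use).

# Consensus co-occurrence network

After a prevalence preflight (ASVs present in fewer than 3 samples are
removed; sparsity and per-ASV N_eff — the number of samples where the
ASV is present, an interpretation of the usual effective-sample guidance
— are reported), five association estimators run on the same ASV set:

1. Pearson and 2. Spearman correlations on relative abundances;
3. SparCC basis correlations from log-ratio variances under the sparse
   correlation assumption (pseudocount 1 before closure; iterative
   exclusion of the strongest pair above |rho| = 0.1, re-solving the
   basis-variance system each round); pseudo p-values from bootstrap
   resampling of samples, two-sided on the sign concentration of the
   bootstrap estimates with the add-one correction — a stability
   criterion whose resolution floor is 2/(B+1);
4. local similarity over samples ordered by depth (the design has no
   time axis, so the bathymetric gradient provides the ordering — an
   interpretation, documented here): the maximal contiguous run of
   summed products of normal scores, found by dynamic programming,
   normalized by the series length, signed by the run;
5. MIC, the maximal information coefficient: the maximum over grid
   partitions with x·y ≤ B = n^0.6 cells of normalized mutual
   information, with the y axis equipartitioned and the x axis optimized
   by dynamic programming over equal-frequency superclumps, both
   orientations searched (so the statistic is symmetric). MIC is
   unsigned; the consensus positivity vote uses the pair's Spearman sign.

Permutation-based estimators compute p against a *pooled* null — all
pairs × all permutation rounds — which is exact under pair
exchangeability for the rank-based statistics and an approximation for
Pearson, and gives a p resolution of 1/(n_pairs·n_perm + 1). At the
consensus stage each permutation-based method's p matrix is
Benjamini–Hochberg adjusted across pairs before the p ≤ 0.05 vote. This
multiplicity control is essential: the four abundance-based estimators
are strongly dependent, so raw per-pair p ≤ 0.05 voting would admit a
few dozen spurious positively-correlated pairs in any 50-taxon table
regardless of the generator. SparCC's bootstrap p is voted on raw — its
resolution floor cannot survive FDR over thousands of pairs, and it
already measures estimate stability rather than a permutation tail. An
edge requires p ≤ 0.05 in at least 4 of the 5 estimators *and* a
positive statistic in every voting estimator; lowering the vote minimum
or raising the p threshold can only add edges.

In the full pipeline the network stage runs on the reference species and,
after the prevalence filter, restricts to the `network_max_asvs` most
abundant ASVs (default 60). This is the package's problem-size choice
for the five-estimator permutation battery; the cap is configurable.
Note that with strong planted depth effects most abundant taxa genuinely
co-vary along the gradient, so the synthetic consensus network is dense
— shared environmental forcing is a real (and known) driver of
co-occurrence edges.

# Inter-omics integration

The Mantel statistic is the Pearson correlation of the off-diagonal
entries of two distance matrices (prokaryote Bray–Curtis vs metabolome
Euclidean distance on log1p, per-feature autoscaled intensities — the
transform is configurable and stamped in provenance), with samples
aligned by id. The Procrustes test superimposes two ordinations by
translation, scaling and orthogonal rotation — reflections allowed by
default, the common convention — and uses m², the normalized residual
sum of squares, as the statistic; both tests permute one configuration
with seeded add-one p-values and support exhaustive enumeration at tiny
n. Compound linking correlates every ASV with every compound signal
(Spearman), keeps the top-k (default 10) positively correlated ASVs per
compound, and compares membership across compound groups, including the
cross-group intersection.

# The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions of the analyses above.

* **Metadata** — depths uniform on 244–1476 m (the emulated collection
  span); temperature and salinity linear in depth (≈ −1.33 °C and
  −0.067 psu per km around 4.2 °C / 34.91 psu) with a `collinearity`
  parameter that interpolates between deterministic (1) and independent
  (0) hydrography; water mass labelled by the 1000 m rule.
* **ASV tables** — Dirichlet-multinomial counts: per-ASV log
  concentrations are a Gaussian baseline plus, for planted responsive
  taxa, a ±`effect_size` log-linear slope per km (signs balanced);
  per-sample Dirichlet mass `theta = 2000` gives realistic biological
  overdispersion, and library sizes are log-normal around 20,000 reads.
  The baseline spreads (sd 2.65 for HMA at 420 ASVs, 4.8 for LMA at 135)
  were calibrated once so default communities reproduce per-sample
  richness means near 190 and 30 observed ASVs. Depth effects are
  planted on taxa above a detectability floor (expected baseline count
  ≥ 20 at the reference library size): a trend on a never-observed taxon
  is not defined in the data it generates. The package's stated
  detectability bound is a slope of 4 per km on such taxa at n = 15,
  where sensitivity ≥ 0.8 at raw α = 0.05 holds in the fixed-seed suite.
  Sister pairs substitute exactly ⌊(1−identity)·L⌋ positions uniformly
  at random without indels (ASVs are fixed-length) and force opposite
  slope signs.
* **Metabolomes** — features belong to pc_groups sharing one latent
  compound signal (log-normal, optionally depth-trending) scaled by
  per-feature response factors; a shared per-sample technical factor
  (log-sd 0.4) emulates extraction/injection efficiency, the archetypal
  response-orthogonal variation an OPLS strips; exactly
  ⌈frac_void·n⌉ features elute before 40 s; a planted subset carries
  high QC variability (target CV 0.6, so the empirical CV exceeds the
  0.30 threshold in ≥ 95% of planted features at 8 QC injections); the
  realized maximal-signal member of each group is ledgered as its
  representative, and a subset of groups carries the molecular-ion
  annotation on that member.
* **Association tables** — a separate generator plants pairwise
  correlations at the log-basis level (the generative model SparCC
  assumes) and closes to compositions, so network recovery can be scored
  against known truth.

Every generator flows all randomness from one integer seed through
deterministic sub-streams, so identical seeds give byte-identical
tables. What the generator does *not* emulate: chimeras and
contamination, raw reads or spectra, retention-time drift, batch
effects beyond the single technical factor, and oceanographic structure
beyond the linear hydrography — so green tests demonstrate correctness
of the statistical machinery on data with known structure, not
robustness to every artefact of real sequencing or LC-MS runs.

# Numerical and reproducibility choices

* Permutation p-values use the add-one estimator everywhere; exhaustive
  enumeration (all n! label permutations) replaces sampling on request
  for small n. Note that a two-group label permutation test has an
  intrinsic resolution floor set by permutations that preserve the
  grouping, not merely by 1/(N+1).
* The pipeline's serialized provenance carries the configuration hash
  (MD5 of the canonical JSON, excluding the output location) and the
  seed, but no wall-clock timestamp: a re-run with the same seed and
  configuration reproduces every output file byte for byte, which the
  suite verifies.
* Degenerate inputs are flagged rather than silently dropped: constant
  variables get `NA` statistics and leave the FDR family; all-zero
  samples yield undefined distances with a warning; zero-mean QC series
  make a feature's CV undefined and the cleaned filter removes it.
* Floating-point guards: the sister-pair substitution count adds 1e-9
  before flooring (binary representation of fractions like 5/140);
  permutation hit counts compare with a 1e-12 slack so exact ties count
  as hits.

# Problem sizes

The default pipeline layout is three species (14/15/16 samples;
300/300/135 ASVs; 3/2/0 planted sister pairs), four LC-MS experiments of
120 features with 8 QC injections, 999 permutations for the community
and inter-omics tests, 99 permutations per association estimator and per
battery pQ2, and 100 SparCC bootstraps. These sizes keep a full
`run-all` plus its byte-identity re-run within a few minutes on one CPU
while leaving every statistical property testable; all of them are
configuration entries that scale up without code changes.

# Known limitations

* Compositional closure is documented, not corrected; log-ratio
  alternatives (CLR, ALR) are out of scope by design.
* The MIC search optimizes one axis by dynamic programming given an
  equipartitioned other axis (both orientations), which bounds it from
  below; quantization through equal-frequency superclumps (cap 30) can
  shave the statistic slightly for n well above the cap, uniformly for
  observed and permuted data.
* SparCC's bootstrap p measures sign stability of the estimate, not a
  null tail; it is deliberately the one unadjusted voter in the
  consensus.
* The OPLS battery's verdicts depend on the synthetic metabolome's
  covariance structure; with 40 independent compound groups the R²X > 0.9
  gate for a "good" verdict is rarely reached even when Q² is high —
  models mostly rate "acceptable", which is the honest description of
  such data.
* One-factor PERMANOVA only; constrained ordination and stepwise model
  building are out of scope.
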