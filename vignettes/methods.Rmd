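---
title: "Reconstructing post-glacial expansion and adaptation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing post-glacial expansion and adaptation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sievescape)
```

`sievescape` reconstructs how a species responded to post-glacial warming by
combining four strands of evidence: the directional footprint that a range
expansion leaves in allele-frequency spectra, hindcast distribution models
that locate glacial refugia, gene--environment turnover models that map
climate into an "adaptive composition" space, and a retrospective offset
metric -- the *glacial genomic offset* -- that quantifies how far each
present-day population has moved in that space from its refugial source.
The package is self-contained: a synthetic landscape/expansion/sieving
generator with known ground truth exercises every stage, so all claims in
this vignette are backed by the test suite or by `scripts/acceptance.R`.

## The expansion signal: psi and TDOA

Serial founder events along an expansion distort the joint site frequency
spectrum of population pairs: conditional on a derived allele being shared,
its frequency tends to be higher in the population farther from the origin,
because each founding bottleneck pushes surviving variants upward. The
directionality index for populations 1 and 2 with sample sizes $n_1, n_2$ is

$$\psi_{12} = \frac{\sum_{ij} \xi_{ij}\,(j/n_2 - i/n_1)}{\sum_{ij} \xi_{ij}},$$

summed over 2D-SFS cells with at least one derived copy in each population,
excluding only the cell fixed derived in both. Cells fixed in exactly one
population stay in the support; this follows the literal support of the
source formulation (the alternative of excluding them was considered and
rejected as unfaithful). $\psi_{12} > 0$ indicates population 2 lies farther
from the origin.

The origin itself is located by a time-difference-of-arrival (TDOA) grid
search: for a candidate origin $o$, $\psi_{ij}$ is regressed through zero on
the distance difference $d_{jo} - d_{io}$ over all population pairs, and the
candidate maximising the regression $R^2$ wins. One subtlety: $R^2$ alone is
blind to direction -- the antipode of the true origin fits equally well with
a negated slope -- so a candidate only scores when its slope is positive
(psi must increase *away* from an origin). The slope at the best candidate
measures founder-effect strength; `founder_strength()` re-expresses it as the
number of kilometres over which 1% of psi accumulates.

The psi--distance association is tested with a hand-rolled permutation
Mantel test (10,000 permutations by default, observed statistic included in
the null set). It is hand-rolled because the signed variant -- signed psi
against signed distance-from-origin differences -- involves a non-symmetric
matrix outside the scope of the standard implementations; the suite
cross-checks the symmetric case against `vegan::mantel`.

## Niche models, refugia, and colonisation

The distribution ensemble averages four presence/background classifiers --
a linear-logistic GLM, a spline-additive GAM, an L1-regularised logistic on
linear + quadratic features (the estimating structure of maximum-entropy
models, without the external binary), and a random forest -- weighted by
their out-of-fold ROC AUC under 5-fold cross-validation. Two calibration
choices matter and are deliberate: background points are drawn from
*non-presence* land cells, so no cell carries contradictory labels, and the
random-forest component uses terminal nodes of five (not one); with either
reverted, the component AUCs under label-free occurrences drift far from the
chance level 0.5 that the calibration tests require. The binarisation
threshold maximises the true skill statistic (TSS) on out-of-fold ensemble
predictions; candidate env screening retains variables with VIF < 10 and
pairwise $|r| < 0.7$, dropping the member of a violating pair with lower
random-forest importance.

Refugia are delineated by DBSCAN over hindcast presence cells (implemented
directly -- the classic region-growing formulation, ~30 lines -- as no
clustering package for it is installed here). Defaults: `eps` = two cell
diagonals, `minPts` = 5; both configurable, neither canonical.

The forward colonisation simulation walks from the Last Glacial Maximum to
the present under linearly interpolated climate. At each step each lineage's
suitability is re-projected; cells that became unsuitable for their occupant
are vacated (local extinction -- an assumption, the alternative being
persistence of sink populations); every suitable unoccupied cell joins the
lineage of its nearest occupied cell if that cell lies within the dispersal
reach `d_km` (the field-scale analogue is 12 km per century); competitive
exclusion means a cell holds one lineage and never switches while occupied.
Distance ties break to the lowest lineage index. The test suite audits every
simulated history exhaustively for the dispersal cap and exclusivity.

## Gene--environment turnover and the glacial genomic offset

Each SNP's population allele frequencies are regressed on the environmental
predictors plus spatial co-variates (longitude/latitude, or MEM1) by a
random forest of CART-style regression trees, implemented in C++ so that
split records -- predictor, split value, impurity improvement -- can be
harvested wholesale. Out-of-bag $R^2$ defines the SNP weight
$w_s = \max(R^2_s, 0)$; SNPs with non-positive $R^2$ are inactive. Per
predictor, binned split improvements are divided by the predictor's data
density in the bin ("standardise before"), cumulated into a monotone curve,
rescaled to conserve the SNP's raw total importance, and combined across
SNPs as the $w_s$-weighted mean. The resulting turnover functions rise from
0 at the observed minimum of each predictor to its weighted total
importance; `transform_environment()` maps any environment through them by
linear interpolation with endpoint clamping (201 knots per predictor by
default).

Two defaults differ from folklore, for stated reasons. `mtry` is
$\lceil 2p/3 \rceil$ rather than $p/3$: with half a dozen pre-screened
predictors, tiny `mtry` forces splits onto whichever predictor was drawn,
transferring importance from the causal variable to its spatial proxies; at
the scale this package targets the larger feature sample attributes
importance far more reliably (the classical $p/3$ remains available via the
argument). And the model is fitted to *estimated* allele frequencies (from
the finite haplotype samples), because that is what data provide; fitting
latent truth flatters the fit and distorts the $R^2$ weights.

The glacial genomic offset of a population is the Euclidean distance, in
turnover-transformed space, between its present environment-and-location
and its refugial source's LGM environment-and-location. Spatial co-variates
are retained by default so the metric absorbs isolation by distance and
expansion-associated drift alongside the climate response; the composition
PCA used for visualisation excludes them (centred, unscaled). Refugial
sources are assigned by nearest great-circle distance by default, or by
least-cost path over a resistance surface (resistance = 1/(suitability +
1e-3), Dijkstra on the 8-neighbour lattice; a deterministic, testable
substitute for random-walk commute formulations, noted as an extension
point). Assignment ties go to the larger refugium, then to a seeded draw.

The Moran's eigenvector alternative builds a neighbour graph with the
minimum-spanning-tree rule (neighbours within the longest MST edge, which
guarantees connectivity), places edge weights -- e.g. expansion-path
divergence, `1 - |A∩B| / min(|A|,|B|)` on least-cost path cell sets -- on
the doubly centred weighting matrix, and retains the positive-eigenvalue
eigenvectors. On a linear transect the leading vector is a smooth gradient
along the line (the analytic eigenvectors are sine-family and show slight
end inflections, so tests assert a gradient correlation rather than strict
monotonicity). `interpolate_mem()` spreads MEM1 across the landscape by
inverse path-distance weighting (power 2), exact at population cells.

## Validation against the site frequency spectrum

Populations that experienced the most evolutionary change should carry the
footprint of sweeps: an excess of high-frequency derived variants, i.e.
Fay & Wu's $H$ decreasing and Zeng's $E$ increasing with the offset. The
package computes $\theta_W$, $\theta_\pi$, $\theta_H$, $\theta_L$ from
unfolded spectra and the variance-standardised contrasts (Tajima's $D$;
Fu & Li's $F$ with derived singletons; $H$ normalised on
$\theta_\pi - \theta_L$, whose sign and ordering match the classical
$\theta_\pi - \theta_H = 2(\theta_\pi - \theta_L)$, also exposed
unnormalised; Zeng's $E$). Weighted ("_gf") variants weight each site's
estimator contribution by the $R^2$ of its gene--environment association,
as a weight-normalised sum so uniform weights reproduce the plain
estimators exactly; the same variance normalisations are evaluated at the
weight-normalised segregating-site count. `correlate_offset()` regresses
each statistic on the offset (OLS; Pearson r, adjusted $R^2$, F-test p),
and `elevation_contrast()` compares diversity between low- (<1000 m) and
high- (>1500 m) elevation bins and between geographically proximate
high/low pairs (default radius 20 km, contrast at least 900 m), with
two-sided Mann--Whitney U tests (sidedness is a choice; the sources are
silent).

## The synthetic world: what it emulates and what it does not

`generate_landscape()` builds a gridded region (default 10-km cells) with a
smooth elevation field, a land mask, a temperature-like variable declining
with elevation and latitude, a precipitation-like variable, and optional
smooth nuisance fields; the LGM slice subtracts an elevation- and
latitude-dependent cooling. The cooling amplitude default (3, in units of
the field's spatial standard deviation) makes the warmest glacial habitat
climatically comparable to the coldest presently occupied sites -- the
geometry of an alpine system in which refugia were alpine-like and modern
high-elevation sites still resemble them.

`simulate_expansion()` colonises suitable cells in waves with a per-step
dispersal reach, recording every cell's founding source, order and
cumulative distance. `simulate_allele_frequencies()` then drifts neutral
loci along the realised founding chains (Gaussian increments with variance
`drift_scale` $\times p(1-p)$ per colonisation edge, truncated to [0,1] --
a deliberate substitute for Wright--Fisher lineages: the tests need the
qualitative founder/sieving structure, not coalescent realism). The default
`drift_scale` of 0.005 corresponds to founding bottlenecks of roughly 100
effective founders per step. Adaptive loci model sieving as sweeps from
standing variation: the derived allele starts rare in the refugium
($p_0 \sim U(0.05, 0.35)$, consistent with polarising by the refugial
major state) and its expected frequency at a population is
$\mathrm{logit}^{-1}(\mathrm{logit}(p_{\text{drift}}) + \beta_l\, dz)$,
where $dz$ is the standardised displacement of the causal variable from
the refugial value and the per-locus effects $\beta_l$ are exponential
with mean `beta` (default 5) -- a polygenic effect-size distribution that
keeps the aggregate response graded along the whole gradient instead of
saturating at one logistic scale. The refugial reference value is the
origin cell's LGM climate, floored at the coldest occupied present-day
value (niche conservatism: the refugial optimum survives in the most
refugium-like colonised habitat; without the floor, strong-cooling
landscapes yield worlds where every locus is swept everywhere and no
spatial signal exists for any method to recover). Loci ancestrally fixed
in every population are dropped; finite haplotype samples (default 20 per
population) are drawn binomially.

What the generator does *not* emulate -- and hence what green tests do not
establish about real data -- includes linkage and recombination, coalescent
variance in drift, ascertainment of SNPs, genotype-likelihood uncertainty at
low coverage, temporally varying selection during the expansion, and
migration after colonisation. The pipeline's recovery rates on this
generator are statements about the methods' internal consistency under a
known, favourable-but-plausible model of the sieving process (which the
empirical system never reveals directly; it is inferred there, not
simulated).

## Numerical choices and degenerate inputs

* SFS statistics are undefined at $S = 0$ and returned as `NA` with a
  `defined` flag; Fu & Li's $F$ additionally needs $n > 2$.
* Psi with empty shared-derived support is `NA` with `n_sites_used = 0`;
  pair entries of the psi matrix inherit the flag.
* The TDOA score surface is flagged `no_signal` when all psi vanish.
* Constant statistics are flagged and skipped by `correlate_offset()`;
  constant environmental variables are dropped with a warning by
  `select_variables()`.
* Colonisation ties (equidistant sources) resolve to the lowest lineage
  index; refugial-assignment ties to the larger cluster, then a seeded
  draw; both documented because the sources are silent.
* All stochastic steps consume explicit integer seeds; `run_pipeline()`
  derives stage seeds from one master seed, and its written outputs are
  byte-identical across repeated runs of the same config (tested).

## Problem sizes

Default study conditions are 30 populations x 20 haplotypes, 2,000 loci of
which 10% are adaptive, on a 24 x 32 grid of 10-km cells -- the scale at
which every acceptance property is exercised. Forests use 100 trees per SNP
in the shipped tests and acceptance script (recovery rates were verified
insensitive between 100 and 500 trees; 500 remains the function default to
mirror field practice at larger SNP panels). `scripts/acceptance.R`
recomputes the oracle error of $\theta_\pi$, the worked psi example, TDOA
recovery under noise, one full pipeline run, and multi-seed recovery rates
for the offset--truth correlation, the weighted $H$/$E$ sweep signature,
and causal-variable attribution.
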