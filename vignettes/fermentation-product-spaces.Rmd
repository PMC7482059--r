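---
title: "Mass- and electron-balance product spaces for fiber fermentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass- and electron-balance product spaces for fiber fermentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermspace)
```

## The model

Fermentation of a fiber by a gut community is treated as a single net
reaction. For a panel of n chemical species over the elements C, H, O plus an
electron row, the balance matrix **M** (4 x n) holds each species' elemental
composition as a column, with the substrate negated (inputs negative). Any
net reaction the community can perform is a stoichiometric vector **s** with
**Ms = 0**; fixing one mole of fiber monomer and requiring products to be
nonnegative (a closed vessel) turns the solution set into a convex polytope.
Because no kinetic, thermodynamic or enzymatic constraints enter, the
polytope is an *upper envelope*: every real outcome lies inside it, but not
every point in it is biologically reachable.

The default panel is the substrate monomer plus acetate (C2H4O2), propionate
(C3H6O2), butyrate (C4H8O2), H2, CH4, CO2, water, and microbial biomass with
the mean composition CH1.8O0.5N0.2. SCFAs are modeled as neutral acids; no
charge states, isotopes or aqueous speciation.

## Electron accounting and the nitrogen subtlety

Two electron functionals are implemented:

* **degree of reduction** (default): 4C + H − 2O − 3N, the available
  electrons relative to CO2, H2O and NH3 (all zero);
* **total valence electrons**: 4C + H + 6O + 5N.

For any nitrogen-free species both are exact linear combinations of the C, H
and O rows (4C + H − 2O and 4C + H + 6O respectively). The electron row is
therefore *redundant* for the N-free part of the system: all the product
bounds (12 mol H2 per mol inulin, 10 per mol pectin, and so on) already
follow from elemental balance. Its only independent content is how nitrogen
is scored, which matters exactly for the biomass column.

A consequence worth stating plainly: with no nitrogen source in the panel,
the electron row forces the biomass coefficient to zero *in either mode*
(given mass balance, the electron balance reduces to a multiple of the net
nitrogen balance, and biomass is the only nitrogen carrier). The default
closed system is therefore a zero-growth envelope. When a biomass yield is
imposed with `apply_biomass_yield()`, a nitrogen source becomes necessary:

* in degree-of-reduction mode an **NH3 exchange column** is added
  automatically. Ammonia has zero reducing power under this functional, so
  nitrogen assimilation does not perturb the electron budget — this is the
  standard convention in fermentation stoichiometry, and it yields e.g.
  max H2 = (24 − 0.9 × 4.2)/2 = 10.11 mol per mol inulin at a 15% carbon
  yield;
* in total-valence mode the build fails with an explicit error unless the
  caller supplies an NH3 species, because silently adding a column whose
  valence count (8) is nonzero would change the budget in a way the caller
  should opt into.

## Conventions exposed as configuration

* **Monomer convention.** "Per mole of fiber" can mean the anhydro repeat
  unit of the polymer (inulin C6H10O5, 162.14 g/mol; pectin C6H8O6,
  176.12 g/mol) or the free monosaccharide (C6H12O6 / C6H10O7). The anhydro
  unit is the default since the dosed polymer is what the vessel receives;
  both are available everywhere a convention matters (polytopes, molar
  masses, doses).
* **Water mode.** With the anhydro convention, hydrolysis consumes water, so
  water is a free (both-signs) species by default; e.g. 1 mol inulin + 1 mol
  water gives 3 mol acetate, recorded as s(H2O) = −1 in the inputs-negative
  sign convention. The strictly closed variant (`water_mode = "nonnegative"`)
  is kept for sensitivity analysis; it reduces the acetate ceiling from 3 to
  0.5 (the residual route 1 fiber to 0.5 acetate + 1 butyrate + 1 CO2
  balances without water).
* **Input relaxation.** Products measured as net *uptake* are modeled by
  lowering one product's bound at a time to −(fraction x its closed-system
  maximum), default fraction 1/3, reflecting that no-fiber controls produce
  about a third as much as treatments; an observed control output can be
  passed as an explicit bound instead.

## Numerical choices

* **Null space**: orthonormal basis via QR (`pracma::nullspace`).
* **Linear programming**: an internal dense two-phase simplex with Bland's
  rule. The LPs here are tiny (up to ~15 variables) but equality-heavy and
  degenerate; Bland's rule guarantees termination, and redundant equality
  rows are handled by the phase-1 artificials. Every LP answer in the test
  suite is cross-checked against exhaustive vertex enumeration — two
  independent routes to the same geometry.
* **Vertex enumeration**: the affine dimension d of the constrained system is
  at most ~6 for the shipped panels, so all d-subsets of the sign constraints
  are solved as square systems (skipping singular ones at |det| < 1e-10),
  kept when feasible within 1e-9, and deduplicated at 1e-8 (infinity norm).
  Dimensions above 12 are refused as out of intended scale.
* **Tolerances**: equality/feasibility 1e-9, deduplication 1e-8, configurable
  in `polytope_config()`. Boundedness of every coordinate is certified at
  build time by LPs; an unbounded direction (possible only with pathological
  panels, e.g. a duplicated-formula exchange species) is reported with a
  certificate ray.
* **Degenerate projections**: 2D hulls that collapse to a segment or point
  are returned as such with a flag, not treated as errors.

## Ex vivo accounting

Headspace mole fractions convert to moles by the ideal gas law at the
incubation temperature (310.15 K) and an assumed 1 atm unless a measured
pressure is supplied; fiber doses convert by the monomer molar mass. Because
the slurry ferments residual substrate even without added fiber, net
production is (mean treatment − mean control)/mol fiber, per subject;
negative nets are retained as evidence of uptake. Replicate aggregation is
the arithmetic mean (median behind a flag) and the replicate spread is
propagated as sqrt(var_t/n_t + var_c/n_c)/mol fiber, reported as missing when
either side has a single replicate. Cellulose samples are parsed but excluded
from modeling by default (insoluble; indistinguishable from controls).

The paired fiber contrast uses the **exact two-sided Wilcoxon signed-rank
test**: zeros dropped with a reported count, midranks under ties, and the
null distribution computed by generating-function convolution over all 2^n
sign assignments (equivalent to brute-force enumeration, which the tests
verify up to n = 12). Nine concordant pairs give p = 2/512 = 0.00390625. An
exact sign-flip permutation test of the mean difference is available as an
alternative. We read reports of a "paired Kruskal-Wallis" on two paired
groups as this test; with n = 9 and all differences concordant it reproduces
a printed value of 0.004.

## Ordination, variance partitioning and association

PCoA is classical scaling of the Euclidean distance matrix (double-centered
Gram matrix eigendecomposition via `stats::cmdscale`), axes ordered by
eigenvalue, variance fractions over the positive eigenvalue mass.

PERMANOVA partitions the Gower-centered matrix G = −1/2 J D² J sequentially
(order as given — fiber first, then subject, mirroring the design), with
SS(term) = tr((H_k − H_{k−1}) G) for nested hat matrices and pseudo-F against
the full-model residual. The permutation scheme is unrestricted row
permutation — the design gives no strata to respect once fiber and subject
are both in the model; p = (1 + #{F* ≥ F})/(1 + N), or the exact fraction
under exhaustive enumeration (n ≤ 8). "Coefficients" separating factor
levels are the least-squares coefficients of the factor model matrix on the
centered product columns — the usual convention for identifying which
products drive a separation.

The community association uses lasso regression (`glmnet`, coordinate
descent, threshold 1e-7) of untransformed relative abundances on the
response, with the penalty chosen by **exact leave-one-out refits** over the
full penalty path — n is small, so no approximation formula is needed. A
centered-log-ratio option exists but is off by default, since compositional
transformation is a modeling decision the analysis deliberately leaves to the
caller. Coefficients are reported on the original scale; the "top" feature
is the largest |coefficient| x feature-SD (i.e. largest standardized effect),
summarized by its Pearson r and two-sided t-test p-value.

## The synthetic-data generator

The generator emulates the design of the 9-subject stool experiment so every
pipeline stage is testable without any data download:

* **Communities**: 50 taxa with log-normal abundances (sdlog 2, a
  heavy-tailed 16S-like profile), normalized to relative abundance. The
  planted hydrogen producer is modeled as a *common* taxon (raw weight
  lognormal(log 30, 0.6), giving relative abundances of roughly 2–25%,
  median ~8%): the kind of visibly abundant organism whose abundance can
  plausibly drive a community-level yield. Methanogen carriage is
  Bernoulli(0.2) per subject, the prevalence seen in population-scale
  metagenome surveys.
* **Ground truth**: each subject's outcome is a convex combination of the
  polytope's vertices with Dirichlet(1) weights, exponentially tilted toward
  high-H2 vertices in proportion to producer abundance (default effect
  strength 1.5 per mol H2 per unit abundance). The default was chosen so
  that the *expected* yield moves near-linearly across most of the feasible
  H2 range over the default abundance spread — the regime of a strong,
  visible abundance–yield association. Convexity makes every sampled vector
  exactly feasible. `stochastic = FALSE` returns the deterministic
  tilted-mixture mean (softmax weights), the generator's noiseless limit.
  Sampling is a vertex mixture, *not* uniform over the polytope interior —
  simple, exactly feasible, and sufficient for realistic profiles, but the
  marginal distribution over the polytope is not flat.
* **Fiber preferences**: inulin outcomes are tilted toward butyrate with the
  full producer effect; pectin toward acetate with 0.3x the producer effect,
  reflecting that H2 production from the more oxidized fiber is low across
  subjects. These tilts make fiber identity the dominant factor in the
  variance partition, with subject identity second.
* **Methane**: fermentative truth vectors exclude CH4-bearing vertices
  entirely (a community without methanogens makes no methane), then carriers
  convert half of their net H2 by 4 H2 + CO2 -> CH4 + 2 H2O (capped by
  available CO2) — the conversion reaction is itself balanced, so
  feasibility is preserved. Net CH4 is therefore *exactly* zero for
  non-carriers and strictly positive for carriers.
* **Measurements**: treatment amounts are (truth + baseline) x mol fiber and
  controls are the baseline alone (a random interior point per subject,
  scaled by 1/3 — controls produce about a third as much as treatments), so
  treatment-minus-control recovers the truth exactly at zero noise. Each of
  the 3 replicates is perturbed multiplicatively by lognormal(0, 0.05) —
  the ~5% assay accuracy of the gas measurements, kept positive by
  construction. The noise level is an assumption: no quantitative error
  model for the chromatography beyond that accuracy figure is available.

What the generator does *not* emulate: sequencing noise or compositional
artifacts in the abundance table (taxa are true relative abundances),
between-replicate biological drift, H2 consumption routes other than
methanogenesis (no sulfate reduction or reductive acetogenesis), and any
kinetic limitation on yields. Tests passing on synthetic data therefore
demonstrate the pipeline's correctness and calibration, not that real
communities obey the vertex-mixture law.

## Problem sizes used by the test suite

The suite exercises: the full shipped configuration grid (2 fibers x 2
conventions x 2 water modes x closed/15%-biomass/six single-input
relaxations) for conservation and LP-vs-vertex agreement; PERMANOVA
calibration over 500 null simulations at 199 permutations (10 samples, 3
products); producer recovery over 100 seeded simulations of 30 subjects x 50
taxa with exact leave-one-out lasso; and 9-subject end-to-end simulations for
the methane dichotomy and exact round-trip accounting. These sizes were
chosen to estimate the relevant rates tightly while keeping the suite quick
to run.

## Known limitations

* The polytope is an upper envelope; distance from a measured profile to the
  boundary has no kinetic interpretation.
* The uniform-slack infeasibility measure treats all products symmetrically
  on the mol/mol scale; products measured with very different precision
  would warrant weighted slack.
* Exhaustive vertex enumeration scales combinatorially; it is intentionally
  refused above affine dimension 12.
* The exact signed-rank convolution is O(n x sum of ranks); it is intended
  for the n <= 25 regime of paired subject designs.
* With only two paired groups the sequential PERMANOVA is order-dependent by
  design; reversing the factor order redistributes shared variance.
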