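---
title: "Measuring and comparing feeding niche breadths: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and comparing feeding niche breadths: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nicheBreadth)
```

This vignette is the package's account of its statistical methods: what
each estimator assumes, which tunable parameters matter and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and where the numerically delicate corners are.

## The inversed Tau index

For a host-use profile $x_1, \dots, x_n$ over the $n$ host plants
available at a location,

$$\tau_{inv} \;=\; 1 - \frac{\sum_{i=1}^{n}\bigl(1 - x_i/\max_j
x_j\bigr)}{n-1},$$

so $\tau_{inv} = 0$ when all use sits on a single plant (pure specialist)
and $\tau_{inv} = 1$ when every plant is used equally (complete
generalist). The summand form is the Yanai-style specificity statistic;
subtracting it from one orients the index toward breadth. Three
consequences worth keeping in mind:

- the index is **driven by the maximum**: profiles are compared to the
  best-used plant, not to the total, so it is invariant to rescaling
  (counts, proportions and densities all give the same value);
- **availability matters**: a plant that is available but unused
  contributes a full $(1 - 0)$ term, so widening the availability set
  strictly decreases a positive $\tau_{inv}$. The index measures breadth
  *relative to local opportunity*;
- with $n < 2$ the denominator vanishes; there is no principled value, so
  the package flags the result as undefined (`NA`) rather than forcing 0
  or 1.

For realized niches $x_i$ is the count (equivalently frequency) of
individuals on plant $i$; for fundamental niches it is the per-plant
survival proportion or the mean weight gain of survivors from a feeding
trial.

### The availability set

What counts as "available" at a location is a genuine design choice. The
default in `populationRealizedTau()` is the union of plants on which any
individual — from any population — was recorded at that location: the set
of plants demonstrably usable there. An explicit per-location plant list
(e.g. a vegetation survey) overrides the default and is the right choice
when unused-but-present hosts should count against breadth; synthetic
scenarios always pass their full plant list this way, since the generator
knows the true availability. Explicit zero-count rows are accepted in
occurrence tables and document surveys, but do not by themselves extend
the default availability set.

At the species level, `speciesRealizedBreadth()` pools counts across a
species' populations at the **genus** level (the first token of a
binomial label by default, or an explicit taxonomy map) and reports the
count of genera used alongside an auxiliary pooled $\tau_{inv}$; the
genus count is the headline species-level measure because populations of
one species often use congeneric hosts at different locations.

## Colour polymorphism: Gini–Simpson

`simpsonDiversity()` computes $1 - \sum_i p_i^2$ from morph relative
frequencies, with no small-sample correction. This variant is exactly 0
for a monomorphic sample — the property that anchors its interpretation
here — and equals $1 - 1/k$ for $k$ equally frequent morphs. Bias-corrected
variants (e.g. $\tfrac{n}{n-1}$ rescalings) do not preserve the zero
endpoint and are deliberately not offered.

## Uncertainty: percentile bootstrap

`bootstrapTauCI()` resamples **individuals**, the experiment's exchangeable
unit:

- occurrence basis: $N$ individuals are resampled with replacement from
  the empirical plant distribution, which is a single multinomial draw
  per resample (and is vectorized as such);
- trial basis: females are resampled with replacement **within their
  plant stratum**, preserving the design's per-plant sample sizes, and
  the per-plant performance profile is recomputed.

The interval is the equal-tail percentile interval of the $\tau_{inv}$
distribution over `B` resamples (default `B = 2000`, level 0.95, R's
default quantile interpolation). Percentile intervals were chosen as the
minimum-assumption construction: $\tau_{inv}$ is bounded and its
distribution is skewed near the endpoints, where normal-theory intervals
would spill outside $[0, 1]$. A trial resample can be degenerate (e.g. no
survivors anywhere, or fewer than two plants with a defined value after
collapse); such resamples are redrawn, with a cap of $10 B$ total
attempts before erroring. Everything is deterministic given `(seed, B)`,
and seeds are consumed from an isolated RNG scope so callers' streams are
not disturbed.

## Pair comparisons: permutation test

`pairTauTest()` tests the difference in $\tau_{inv}$ between the two
members of a sexual–asexual pair by pooling their individuals and
permuting membership (occurrence basis: individuals reassigned keeping
group sizes; trial basis: labels shuffled within plant strata). The
p-value is the two-sided permutation tail for $|\tau_A - \tau_B|$ with
the $+1$ correction, exact under exchangeability and making no
distributional assumption about an index that is bounded, non-normal and
max-driven. Default 9999 permutations. Bootstrap CI overlap for the two
members is reported alongside as a secondary, more conservative flag.
Comparisons on fewer than 20 individuals carry a low-power warning but
are still computed.

## PGLS under Brownian motion

Species values are not independent: close relatives resemble each other.
`brownianVCV()` builds the Brownian-motion tip covariance (entry $(i,j)$
= shared root-to-tip path length, via `ape::vcv.phylo`), and `pglsFit()`
solves the GLS normal equations through the Cholesky factor of $V$
(falling back to an SVD pseudoinverse, with a warning, if $V$ is
numerically singular). The reported correlation is

$$r = \operatorname{sign}(\hat\beta)\,\sqrt{R^2_{GLS}},$$

with $R^2_{GLS}$ computed from $V^{-1}$-weighted sums of squares about
the GLS mean — the unique definition that collapses to Pearson's $r$
when $V = I$, which the tests verify to $10^{-8}$. The slope is tested
two-sided on $n - 2$ df. No Pagel's $\lambda$ or other covariance
transformations are offered: the model is pure Brownian motion, and
branch-length rescaling provably leaves $\hat\beta$, $r$, $t$ and $p$
unchanged ($\hat\sigma^2$ absorbs the scale). Polytomies are accepted
as-is. The package never places asexual lineages on the tree itself; the
input Newick is taken as given.

## Feeding-trial models

Survival is modelled by a binomial GLM with logit link,
`survived ~ mode + plant + mode:plant`, and terms are tested
**sequentially** by deviance (likelihood-ratio) $\chi^2$ in the order
mode, plant, interaction; weight gain (survivors only, `final − initial`
mass in grams) by a two-way fixed-effects ANOVA with sequential Type I
sums of squares in the same order. A significant mode × plant interaction
is the operational signature of a fundamental-niche difference between
the pair's members. Two deliberate choices:

- **dead insects contribute to survival only.** Their mass trajectory is
  unmeasured; imputing zero gain would conflate the two responses.
- **plants tested in only one mode** cannot support interaction
  contrasts; their interaction coefficients alias away, the interaction
  df shrinks accordingly (mirroring the unequal dfs real unbalanced
  designs produce), and the affected plants are listed on the result
  object. Complete separation (cells with all-survived or all-dead at
  small $n$) is flagged in `@notes`; the LRT p-value remains valid where
  a Wald test would not.

When the fundamental $\tau_{inv}$ is computed from mean weight gains, a
negative cell mean (insects losing mass) is clamped to zero — the insect
has no measurable performance on that plant — since the index requires a
nonnegative profile; plants with no survivors drop out of the weight-gain
profile entirely.

`leveneVarTest()` is a one-way ANOVA on absolute deviations from the
group **median** (the Brown–Forsythe variant, the robust default of the
ecology toolchain; `center = "mean"` gives the classical test). If the
deviations carry no within-group variance — all-identical values, or two
observations per group — the F ratio is undefined and the result is
flagged rather than reported as an unstable number.

## The synthetic-data generator

The generator is the package's substitute for field collections and
husbandry, and defines the conditions under which the calibration tests
run:

- **Occurrences**: multinomial draws of $N$ individuals (default 500 per
  population) from a true composition $\pi$; an optional Dirichlet
  concentration `theta` adds between-population overdispersion
  ($p \sim \text{Dirichlet}(\theta\pi)$, smaller $\theta$ = noisier).
  The true $\tau_{inv}(\pi)$ is stored on the scenario.
- **Pair presets**: `genPairScenario("FNV")` restricts the sexual base
  composition (default $0.4, 0.3, 0.2, 0.1$ over four plants — a
  moderately broad niche with true $\tau_{inv} = 0.5$) to a random
  2-plant subset of its support, renormalized, emulating a clone
  freezing part of its ancestor's niche; `"GPG"` mixes the base halfway
  toward uniform, emulating a selected general-purpose clone. Keeping
  the full support (FNV) or `flatten = 0` (GPG) reproduces the base
  composition exactly.
- **Feeding trials**: the experiment's seven-plant design with 10–20
  females per (species, plant) cell, survival Bernoulli on a logit scale
  (baseline +0.5 plus plant effects spanning ±1.5; no mode effect and no
  interaction unless set), survivor weight gain normal (cell means
  0.005–0.035 g, σ = 0.01 g) truncated below at −0.05 g — insects can
  lose a little mass, not an arbitrary amount. Initial masses are
  lognormal around 0.045 g (a fourth-instar juvenile female), duration
  10 days.
- **Brownian traits**: $x \sim \text{MVN}(0, V)$,
  $y = \beta x + \varepsilon$ with
  $\varepsilon \sim \text{MVN}(0, \sigma^2 V)$, so a PGLS of $y$ on $x$
  under the same tree is correctly specified with true slope $\beta$.

One top-level seed expands arithmetically into named child streams
(occurrences, morphs, trials, per-population), so any single table can be
regenerated without replaying the others; every generator is a pure
function of (scenario, seed).

What the generator does **not** emulate: spatial structure and plant
abundance gradients, predation dynamics behind morph–host covariance
(morph frequencies are drawn independently of compositions), clonal
selection through time, measurement error in field counts, and
overdispersion beyond the Dirichlet layer. Passing calibration tests on
these data therefore validates the *statistical machinery* — index
algebra, interval coverage, test levels, effect recovery — not the
ecological fidelity of any particular field dataset.

## Problem sizes and numerical choices

The test suite runs the calibration studies at: 1000 random instances for
the index/ANOVA oracle equivalence (tolerance $10^{-10}$); 500 synthetic
datasets of $N = 500$ for bootstrap coverage (band 93–97% at the nominal
95%); 1000 Brownian null simulations on a fixed 20-tip coalescent tree
for the PGLS level (band $0.05 \pm 0.02$) and 200 replicates for slope
recovery (bias bound 0.05); 1000 null replicates of a 2 × 4 design at 20
per cell for the GLM-LRT and ANOVA interaction levels; and 200 replicates
each for FNV/GPG ordering recovery (≥ 95%). Other numerical corners:
quantile interpolation uses R's default (type 7); permutation p-values
use the $+1$ correction and a $10^{-12}$ slack on tie comparison so exact
ties count as exceedances; Tau's max needs no tie-breaking (the value,
not the index, enters the formula); tables are read with delimiter
auto-detection (tab wins over comma) and missing masses accept `""`,
`NA`, `-` on input but are always written back as empty fields.

## Known limitations

- The fundamental-niche Tau treats per-plant survival proportions as the
  profile regardless of per-cell sample size; cells with very few trials
  contribute as much as well-replicated ones (the bootstrap, which
  resamples within plant strata, is where that uncertainty surfaces).
- The permutation pair test assumes individuals are exchangeable between
  the pair's members under the null; strong within-population clustering
  would make it anticonservative.
- PGLS assumes the supplied topology and branch lengths; uncertainty in
  the tree (including where asexual lineages attach) is not propagated.
- The Gini–Simpson index is not corrected for unequal morph-sample sizes
  across populations.
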