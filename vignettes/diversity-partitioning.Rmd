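---
title: "Partitioning temporal diversity change across metacommunity scales"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning temporal diversity change across metacommunity scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divpart)
```

## The model

A metacommunity is censused repeatedly: counts `n_ijk` of species *i* in
community *k*, which belongs to habitat *j*. Communities are *nested* in
habitats, so `divpart` stores counts as a species x community matrix plus a
community-to-habitat map rather than a 3-D array — a community cannot sit
in two habitats, and the impossible states are unrepresentable by
construction.

All individuals are weighted equally (the natural weighting when the object
of study is fitness, which counts individuals). Under equal weighting the
Shannon family is the right diversity measure: alpha can never exceed
gamma, and every component is an average of per-individual rarity scores,

* `z_gamma = -log(p_i..)` — rarity of the individual's species in the
  whole region,
* `z_alpha = -log(p_{i|jk})` — rarity in its own community,
* `z_beta = z_gamma - z_alpha`,

so that `H_o = sum p_ijk z_ijko`. Gamma is the entropy of the pooled
species marginal, alpha the abundance-weighted mean within-community
entropy, and beta their difference — the mutual information between species
identity and location, hence always nonnegative. `exp(H)` is the Hill
number: the number of equally abundant species with the same entropy.
Because the partition below is additive in entropy, exponentiation turns it
into a multiplicative partition of Hill-number ratios; both scales are
reported everywhere.

## The five-term partition

Between consecutive censuses, each individual of the future census is
classified **immigrant** (its species was unobserved in that community at
the previous census) or **resident** (anything else). With immigrant
fraction `phi`, the change splits as

```
dH = phi * (H'_I - H)  +  (1 - phi) * (H'_d - H)
```

where `H'_I` and `H'_d` average future rarity scores over the
immigrant-only and resident-only abundance distributions. The resident
part is then decomposed over the conditional-probability factorisation
`p_ijk = p_i.. * p_{j|i.} * p_{k|ij}` with the *staggered* discrete product
rule

```
D(a b c z) = Da.b.c.z + a'.Db.c.z + a'.b'.Dc.z + a'.b'.c'.Dz
```

applied in the fixed order (species, habitat, community, score). The four
summands are species-, habitat-, and community-scale selection and
transmission; each is multiplied by `(1 - phi)` so the five terms sum to
`dH` *exactly* (to 1e-10 in double precision — the package's enforced
tolerance, tested on random inputs).

Why staggered? A "all-unprimed-companions" version of the discrete product
rule does not telescope: the terms would not sum to the total and the
partition would leak. Staggering restores the exact identity at the price
of an ordering convention; we fix the order to match the nesting hierarchy
(coarsest change first, scores last). The ordering is a genuine design
choice: a different order redistributes small amounts among terms but every
order telescopes, and the package uses one order consistently.

Interpretation of the terms:

* **Species selection** — covariance between the change in region-wide
  species relative abundance and the rarity score. Positive when rare
  species gain ground.
* **Habitat / community selection** — the analogues one and two levels
  down: within-species redistribution among habitats, and among communities
  within a habitat. For gamma diversity the score depends only on the
  species, so both terms vanish identically — a structural property the
  test suite asserts, not an approximation.
* **Transmission** — the change in the scores themselves, holding the
  future weights. This is the nonlinearity of entropy: strong selection
  that carries a rare species past dominance can produce almost no net
  diversity change, with transmission opposing selection in sign. The
  irruption simulation scenario reproduces exactly this regime.
* **Immigration** — the immigrant share of the change. Emigration and
  extinction need no term of their own; a vanishing species simply flows
  out through the `Dp` and `Dz` differences with finite contributions.

### Choices where the mathematics is open

* **Which distribution feeds the future scores `z'`?** Default
  `z_source = "pooled"`: scores come from the full future census
  (immigrants + residents) while the weights are conditional
  immigrant-only / resident-only distributions. This makes the
  immigrant/resident split an exact identity. The alternative
  `"resident"` conditions scores on residents only; since immigrant
  species may then carry no defined score, the immigration term is defined
  as the exact residual, so additivity is preserved in both modes.
* **Zero handling.** `0 * log 0 = 0` throughout; any product containing a
  zero probability is zero even if a paired score is undefined. Undefined
  conditionals (empty community, species absent from a habitat) are `NA`,
  never silent `0/0`, and an `NA` score meeting positive weight raises an
  error rather than propagating `NaN`.
* **Classifier granularity.** Immigrant status is a property of a
  (species, community, census) cell, not an individual: count data cannot
  distinguish a second-generation immigrant from a resident. Consequently
  every resident cell has positive previous count, which is exactly the
  support condition the staggered rule needs — the classifier and the
  decomposition are designed to fit together.
* **Log base.** All internals are in nats (the worked reference value
  `H = 0.69` for a two-species even community is `ln 2`). A `base`
  argument (and `--log-base` flag) rescales reported entropies; Hill
  numbers are base-free.
* **Tolerances.** Probability normalisation and factorisation identities
  are checked at 1e-12 relative; partition additivity at 1e-10 (sums of
  hundreds of cells accumulate more rounding than single identities).

## The bootstrap

The drift null holds the present census fixed and draws each future cell
independently from Poisson(mean = present count); 1000 replicates and
empirical 95% intervals (type-7 quantiles, documented for
bit-reproducibility) are the defaults. Each replicate re-runs the full
pipeline, classifier included. Under this null a cell empty in the present
stays empty, so the immigration term is degenerate at zero in every
replicate — a documented property of the null, not a bug; the interval for
immigration is a point at zero, and observed immigration outside it is
evidence against pure drift. Replicate *r* draws from its own substream
(a seed derived from the master seed), so results are independent of
execution order and the first *n* replicates of a longer run coincide with
a shorter run.

Calibration is tested at reduced scale (200 outer realisations x 200 inner
replicates): each continuous term's 95% interval covers its realised null
value in 95 +/- 3 percent of repetitions.

## The simulator

`simulate_metacommunity()` realises the minimal model with selection at
exactly the three scales the partition measures: between censuses the
expected count is `n * w_i * u_ij * v_ijk`, followed by half-up rounding
(deterministic mode; platform-stable integer fixtures) or a Poisson draw
(stochastic mode, sharing the bootstrap's code path so that fitness 1
reproduces the drift null *by construction*). Scheduled immigration pulses
inject counts only into cells empty at the preceding census, so the default
classifier recovers them exactly; targeting an occupied cell is refused as
ambiguous.

`scenario_library()` ships four configurations. Each confines fitness to
one scale with a symmetric construction that keeps the coarser marginals
exactly constant (e.g. every species is favoured x2 in one habitat and
disfavoured x1/2 in the other, from an initial 60/20 split, so species
totals scale identically and the species term is exactly zero). The
scenarios start from *heterogeneous* abundances deliberately: from a
perfectly even start all rarity scores are equal, selection has no variance
to act on, and its first-interval term is legitimately zero — the
heterogeneous start is what makes the active scale's term dominant from the
first interval. The `irruption` scenario (a rare species with a 30-fold
transient advantage, then the reverse) reproduces the outbreak regime in
which transmission opposes species selection.

What the simulator does *not* emulate: demographic structure, within-season
phenology, density dependence, natural enemies, or dispersal between
communities inside the region (immigration is exogenous injection, matching
the region-level immigrant definition). A green parameter-recovery test
therefore establishes that the partition attributes change to the scale
that generated it under multiplicative growth with Poisson noise — not that
any particular field system behaves like the generator.

## Limitations

* Only Shannon-based components (order-1 Hill numbers) are provided; other
  orders weight individuals unequally and break the equal-weighting logic.
* No rarefaction or coverage correction: the intended data are total
  censuses, not samples of unknown effort.
* The bootstrap quantifies drift only; alternative nulls (multinomial,
  negative binomial) would need a different resampler behind the same
  interface.
* Immigrant detection is limited to species-level novelty within a
  community; misclassified residents inflate transmission at the expense of
  selection, a caveat inherited from count-only data.
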