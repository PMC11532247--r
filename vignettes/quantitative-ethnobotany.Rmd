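---
title: "Quantitative ethnobotany: indices, perception tallies and preference modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative ethnobotany: indices, perception tallies and preference modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethnoindices)
```

## The data model

The atomic datum of a quantitative ethnobotanical survey is the *use
report*: one informant citing one plant species for one use category.
`survey()` bundles the informant universe (size `N`), the use-category
universe (size `NC`) and the deduplicated reports; duplicate
(informant, species, category) triples are collapsed at construction with a
warning, because every index below is defined on distinct triples. Species
identity is the whitespace-normalized name string — WFO identifiers are
carried as opaque strings and never resolved online.

`NC` deserves a word: published summaries of the survey we calibrate
against give both 11 and 12 use categories, so `NC` is never hard-coded.
The default is the number of categories observed in the data and every
index function accepts an override; only CVI depends on it.

## Survey design

`required_sample_size()` implements the finite-population estimator
$n = N_T / (1 + N_T e_p^2)$, rounded **up** — the source survey's frame of
227 households at $e_p = 0.05$ gives 144.82, and the conservative sampling
convention (interview the extra household rather than undershoot the
precision) yields the 145 actually surveyed. The formula has no z term;
the "95 % confidence" usually quoted with it is narrative shorthand for the
simplified estimator, so we implement exactly the formula and say so here
rather than inventing a z-based variant.

## The five indices

For species $s$: $UV = \sum_i U_i / N$ (use reports per informant, summed),
$RFC = FC_s/N$, $CII = \sum_{u} \sum_i UR_{ui}/N$,
$CVI = (NU_s/NC)(FC_s/N)\,CII$, and
$RI = (\text{citation term} + NU_s/NU_{max})/2$.

Two deliberate conventions:

- **RI citation term.** The literature's "RFC over the maximum" wording is
  ambiguous between normalizing RFC by its maximum and using it raw. In the
  calibration table, the top-RFC species carries an RI *below* another
  species' — impossible under normalization, which forces the top-RFC
  species to at least $0.5$ plus half its category share. We therefore
  default to the raw-RFC reading (`convention = "raw_rfc"`), implement both,
  and stamp the choice on every output table. Neither convention can be
  verified exactly against the reported RI column without the undeposited
  per-informant data, which is why RI values are not used as reproduction
  targets.
- **Truncation, not rounding, for index reporting.** The reported citation
  fractions are truncations (68/145 = 0.46896 prints as 0.468, 59/145 =
  0.40689 as 0.406); regression tables round instead (exp(0.151492) =
  1.1636 prints as 1.164). Both policies exist (`format_index_table()`,
  `truncate_decimal()`, `round()`) and are bound per report, never mixed.
  Indices are computed and ranked on unformatted rationals; formatting is a
  reporting step.

Under deduplicated reports UV and CII are the same number — both count
distinct (informant, category) pairs over $N$. Both columns are still
emitted because the two indices have distinct definitions (and diverge on
data models that keep repeat mentions); the identity is asserted in the
test suite rather than silently exploited.

Ranks use competition ranking (ties share the minimum rank) on unformatted
values, with display order breaking ties by species name. Reported tables
we digitized use ordinal ranks instead; the packaged fixture carries those
printed ranks verbatim as reported values.

## Capability perception tallies

Perception statements — a respondent group (frequent allopathy or herbal
users), the medicine system evaluated, a Nussbaum central capability, and
an enabler/barrier valence — are tallied per capability and cross-tabulated
over the four group × medicine cells. The tally unit is the *statement*
("instance"), not the respondent: one respondent may contribute several.
Cell counts are conserved by construction and checked in tests.

The default capability set is an **editorial reconstruction**: the source
study selected seven of Nussbaum's ten central capabilities but never
enumerates them in the available text, so our default (affiliation, bodily
health, control over one's environment, practical reasons, life, bodily
integrity, emotions) collects the capabilities its discussion actually
names, padded to seven. It must not be read as the study's exact set; every
function takes a `capabilities` argument.

## Preference model

The herbal-versus-allopathy outcome is binary (1 = prefers herbal), so the
model is a binary logistic regression, $\mathrm{logit}(P) = \beta_0 +
\beta^T x$ — an "ordinal logit" mention in the source abstract contradicts
its own methods section and is not implemented. Covariates are screened
first with variance inflation factors: $VIF_j = 1/(1 - R_j^2)$ from the
auxiliary least-squares regression of covariate $j$ on the rest, removing
one covariate at a time from the largest above 5 and recomputing, since
dropping one member of a collinear cluster typically rescues the rest.
Exact collinearity is reported as infinite VIF and excluded first.

Fitting is by iteratively reweighted least squares: Newton steps on the
log-likelihood with step-halving, so the likelihood is monotone across
iterations. Defaults: at most 50 iterations, convergence when the largest
coefficient change drops below 1e-8. Standard errors come from the inverse
observed information at the optimum; z, two-sided normal p and odds ratios
$e^\beta$ are exact functions of (estimate, SE) and satisfy their
identities to machine precision. Separation — the MLE escaping to infinity
when a covariate pattern perfectly predicts the outcome — is detected
(one-class outcomes, or coefficients diverging without the update
settling) and raised as an explicit error, never returned as silently huge
numbers. A rank-deficient design names the aliased covariate.

A "log transformation of response variables" described for this model in
the source methods is incoherent for a 0/1 outcome; we read it as an
optional transform of skewed continuous covariates and leave any such
transform to the caller rather than building it in. `ks_statistic()`
provides the one-sample Kolmogorov–Smirnov distance used for the
normality screening step.

## The synthetic-data generator

No raw field data are deposited, so the generator emulates the published
summaries; its defaults are the study conditions, chosen once:

- **Survey**: 145 informants, 51 species, 12 categories. Per-informant
  citation of the rank-$r$ species is Bernoulli with $p_r = p_1
  r^{-\gamma}$: thinning a Zipf-like rank law at the informant level gives
  distinct-informant FCs directly (Binomial$(N, p_r)$), avoiding post-hoc
  deduplication bias. $p_1 = 70/145$ anchors the top species at the
  fixture's maximum citation count; $\gamma$ is fitted from the fixture's
  rank–frequency profile by `fit_citation_exponent()` at configuration
  time (log–log least squares, ≈0.65), recorded in the config rather than
  hard-coded. Versatility: each species draws a category repertoire of
  mean size 3 (1 + Poisson, capped at NC) and each citing informant
  reports 1–3 categories from it — a scientist's plausible middle ground
  consistent with the fixture's NU-driven index spread, not an estimated
  quantity. Plant parts follow a leaf- and root-heavy share vector typical
  of medicinal-plant surveys; it is synthetic, as are preparation and
  administration labels.
- **Respondents**: covariate distributions use the published demographic
  moments (age-like continuous covariates: reported mean/SD, truncated at
  zero; binary covariates: reported shares, e.g. loan 62.29 %, knowledge
  57.42 %, family beliefs 71.63 %). Correlations default to independence
  except a configurable positive ethnicity→knowledge link (default +0.15
  probability boost) mirroring a qualitative observation; it is synthetic,
  not inferred. Slope defaults are the published regression estimates.
  Those estimates are **inconsistent with the published covariate scales**
  (they imply a degenerate all-zero outcome at the covariate means), so
  the intercept defaults to the value placing the prevalence at a target
  (0.5) for the configured means — the study reports no preference
  prevalence to calibrate against. Pass `intercept=` to override.
- **Perceptions**: statements are generated to reproduce target tally
  cells exactly (the generative inverse of the tally), so round-trip
  conservation is exact by construction and verified over random targets.

All generators are deterministic for a fixed seed and restore the caller's
RNG state. What passing tests on this synthetic data show is that the
*pipeline* is correct under the assumed structure (independent citations,
independent covariates, logistic outcome); real surveys violate these in
ways the generator does not emulate — informant clustering by village or
kinship, correlated species knowledge, interviewer effects — so synthetic
recovery results say nothing about such biases in field data.

## Numerical choices and degenerate inputs

- Index values are exact rationals up to double precision; truncation adds
  a 1e-8 fuzz so values already at the target precision pass through
  (0.29 at two places stays 0.29, despite 0.29·100 = 28.999… in binary).
- `required_sample_size` subtracts 1e-9 before `ceiling` to absorb float
  noise at integer boundaries.
- IRLS weights are floored at 1e-10; the auxiliary VIF regressions treat
  $R^2 > 1 - 10^{-12}$ as exact collinearity.
- Empty surveys yield empty index tables; uncited species have UV = CII =
  CVI = 0 and are absent from count maps; all-unknown plant parts warn and
  report `{unknown: 1}`.
- Test problem sizes (random surveys of ≤7 informants for oracle
  comparisons, 5000 respondents × 200 replicates for coverage) were chosen
  as the smallest scales at which the checked properties are
  non-trivial while keeping the suite quick to run routinely.

## Known limitations

- The reported RI/CII/CVI columns and index ranks of the calibration table
  cannot be recomputed without the undeposited raw reports; only the RFC
  column (and the citation counts behind it) is reproduced exactly.
- VIF screening drops one of two equally collinear covariates by position
  when VIFs tie exactly; the screen reports the pre-screening VIFs so the
  choice is auditable.
- The logistic model is unweighted and unclustered; village-level survey
  design effects are out of scope.
- The capability label set is configurable precisely because the source's
  exact seven-capability selection is unknown.
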