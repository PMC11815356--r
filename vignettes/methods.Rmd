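---
title: "Models and methods in inocula"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in inocula}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`inocula` analyses inoculation field experiments on wood-inhabiting fungi:
which abiotic properties of a log, and which aspects of its resident fungal
community, predict whether an introduced species establishes. This vignette
is the package's account of its statistical machinery — the models and their
assumptions, the tunable parameters and their defaults, what the synthetic
data generator does and does not emulate, and the numerical and design
choices made where several defensible options existed.

## 1. The response and the sampling units

Each target species is analysed separately. Its sampling units are its
target logs; the response is binary: 1 if the species' OTU was detected in
the log's sample one and/or two years after inoculation (an OR across
years), 0 otherwise. Detection requires at least `min_detect_reads` reads
(default 1: amplicon surveys of this kind accept detections down to a few
reads, and any larger threshold is a user choice, not a package
assumption).

Samples with fewer than 10,000 filtered reads are removed before any
analysis; the comparison is strict (`< 10000` is removed, exactly 10,000 is
kept). A log whose post-inoculation samples were both removed drops out of
the sampling units. The package additionally requires a retained
pre-inoculation sample for every modelled log — even for the
environment-only model, which does not use it — so that all ten candidate
models are fitted to the identical row set and their cross-validated AUCs
are directly comparable.

## 2. The probit engine

The core model for log $i$ of species $k$ is

$$ y_i \sim \mathrm{Bernoulli}\!\left(\Phi(x_i^\top \beta + a_{s(i)})\right),
\qquad a_s \sim N(0, \sigma^2_{site}), $$

estimated by Gibbs sampling with Albert–Chib truncated-normal data
augmentation: a latent $z_i \sim N(x_i^\top\beta + a_{s(i)}, 1)$ truncated
to $(0,\infty)$ if $y_i = 1$ and $(-\infty, 0]$ otherwise makes every
update conjugate — multivariate normal for $\beta$, univariate normal for
each site effect, inverse-gamma for $\sigma^2_{site}$. The sampler is
compiled (RcppArmadillo) and uses R's RNG, so `set.seed()`-style seeding
makes every fit reproducible; leave-one-out cross-validation refits the
model once per sampling unit, which the compiled core makes routine.

Priors (all configurable via `prior_spec()`):

* $\beta_j \sim N(0, 1)$ on standardized columns. Continuous predictors are
  standardized to mean 0, SD 1 over the modelled rows precisely so that one
  slab variance is comparable across predictors; binary presence columns
  stay 0/1.
* Spike-and-slab (models 6 and 10): each common-species coefficient is
  $\gamma_j b_j$ with $\gamma_j \sim \mathrm{Bernoulli}(\pi)$, $\pi = 0.5$,
  and an *exact point mass at zero* as the spike. $\gamma_j$ is updated
  from the marginal slab-vs-spike odds with $b_j$ integrated out, then all
  active coefficients are redrawn jointly. A point-mass spike keeps that
  marginalization closed-form; a narrow-normal spike would buy nothing
  here.
* $\sigma^2_{site} \sim \mathrm{InvGamma}(1, 1)$. With only five sites the
  likelihood carries little information about this variance, so the
  posterior has a prior-dominated floor: even when data are generated with
  no site effect the posterior mean sits near the prior mode (~0.5) rather
  than at zero. Tests therefore check that the no-effect posterior lies
  well *below* a strong-effect posterior, not that it vanishes. With more
  sites (the suite uses twelve for this check) the separation is sharp.

Defaults are 2 chains × (1000 warmup + 1000 retained) draws, thinning 1.
Convergence is summarized by split-$\hat R$ and a lag-autocorrelation ESS;
`posterior_summary()` warns when $\hat R > 1.1$. Posterior support for a
coefficient is $\max(\Pr(\beta_j > 0), \Pr(\beta_j < 0))$, flagged at 0.95.

Numerical details: truncated normals are drawn by inverse CDF with tail
probabilities clamped to $[10^{-15}, 1-10^{-15}]$ (adequate for the
moderate linear predictors these models produce); the $\beta$ draw uses
Cholesky solves of the posterior precision; perfect separation is not an
error — the proper priors keep the posterior integrable.

### Prediction

`predict_success()` averages $\Phi(x^\top\beta + a_s)$ over draws, using
the fitted site effect when the site was represented in the training data
and the prior mean 0 otherwise. In leave-one-out cross-validation every
site remains represented, so the fallback is rarely exercised.

## 3. The ten candidate models

Model 1 uses log type (two contrasts against the *broken* reference level:
felled-vs-broken and uprooted-vs-broken — the contrasts this literature
reports), decay stage (ordinal 1–5 treated as continuous) and sequencing
depth. Depth is the natural log of the mean filtered read total over the
available post-inoculation years — average-then-log. The alternative
reading (log-then-average) is implemented behind `log_first = TRUE`; the
averaged-total default was chosen because a mean of totals is the natural
"sampling effort" quantity and the two differ negligibly at these depths.
Site enters as the random intercept, never as a fixed effect.

Models 2–10 add one biotic block computed from the pre-inoculation
(resident) census: total richness; Ascomycota and Basidiomycota richness
(unassigned OTUs count toward the total only); two latent-variable scores
of a model-based ordination (presence or RRA$^{1/4}$ version); the
occurrences or RRA$^{1/4}$ of the ten most common resident species; or the
log DNA amount, $\log(\text{non-spike reads}/\text{spike reads})$, the
spike-in calibrated proxy for total fungal DNA (a pseudocount is available
for spike-free samples but off by default: a zero-spike sample indicates a
calibration failure worth an explicit error).

The ten most common species are those occupying the most target logs of
the focal species; ties break by larger total read count, then by OTU id.
The tie-break is arbitrary in substance but necessary for determinism — two
runs of the pipeline must select identical columns.

## 4. Model-based ordination

The community-composition models use a two-factor latent variable model
$g(E[y_{ij}]) = \alpha_j + u_i^\top \lambda_j$ fitted by the same Gibbs
machinery (probit augmentation for presence–absence, conjugate
Gaussian updates for fourth-root RRA). One ordination is fitted per target
species over that species' retained target logs, so scores exist exactly
for the modelled rows; fitting a single global ordination is possible with
the exported building blocks but is not the default, because per-species
fits keep the biotic predictors aligned with each model's sampling units.

The latent subspace is identified only up to rotation and reflection. The
package handles this by initializing from the truncated SVD of the centred
data and aligning every retained draw to a reference draw by orthogonal
Procrustes rotation before averaging; scores are centred per dimension. An
earlier variant constrained the loading upper triangle to zero instead,
which pins the rotation to an arbitrary leading OTU; it mixed too slowly to
recover known subspaces at practical run lengths, so the alignment approach
was adopted. OTUs occurring in fewer than two (or all but zero) of the
ordinated logs are dropped for the binary family — such columns carry no
gradient information — and a matrix left with fewer informative columns
than latent dimensions is an error naming the dropped columns.

`scores_as_predictors()` extracts per-log scores (LV1, LV2); downstream
they are standardized like any continuous predictor. The wording "latent
variable loadings" is sometimes used informally for these per-site scores;
the per-log predictors are, necessarily, the row scores.

## 5. Model comparison and variance partitioning

AUC uses the Mann–Whitney formulation via midranks (ties credited 0.5),
which equals the exhaustive pair count exactly. Leave-one-out
cross-validation refits the probit model $n$ times with fresh seeded
chains and pools the $n$ held-out predictions into one AUC.

Two properties deserve explicit statement:

* **Feature freezing.** Ordination scores, the identity of the ten most
  common species, and standardization constants are computed once on the
  full data, not per fold. This mirrors the sequential workflow the
  analysis emulates (ordinate, then use scores as predictors) and keeps
  folds comparable; a strictly per-fold protocol would measure a slightly
  different (and for ordination scores, ill-aligned) quantity. The
  regression stage — the part being validated — is fully refitted per fold.
* **Pessimistic null bias.** AUC over pooled leave-one-out predictions is
  biased *below* 0.5 when predictors carry no signal: excluding unit $i$
  removes its own contribution to the fit, so held-out predictions
  anticorrelate with the labels. Simulations in the test suite measure a
  mean null AUC near 0.35–0.39 at $n = 40$. This is a property of the
  estimator, not of the sampler (which matches an exact quadrature
  posterior to within 0.02), and it explains why uninformative
  species in analyses of this design can show AUCs well below 0.5. Users
  should read AUC differences between models, which share the bias, rather
  than distances from 0.5.

`compare_models()` reports the best model (ties to the lower id) and the
difference between the best resident-community model (ids 2–10) and the
environment-only model; negative differences are reported raw by default
and clamped at zero only in the presentation layer (`clamp_zero = TRUE`),
matching the convention of summary tables that print 0.00 when the
environment-only model wins.

Variance partitioning computes, per posterior draw, the across-unit
variance of each predictor group's contribution $\sum_{j \in g} x_{ij}
\beta_j$ (groups: environment = log type + decay stage; sequencing depth;
biotic) plus $\sigma^2_{site}$ for the site share, normalizes to sum to
one, and averages over draws. Between-group covariances are deliberately
excluded — shares are then non-negative and sum to one by construction,
at the cost of ignoring collinearity between groups; with standardized,
largely orthogonal blocks the distortion is small. The intercept
contributes no variance.

## 6. The synthetic-data generator

The generator is first-class, tested code; every downstream stage is
exercised against it. Its defaults are the study conditions of the design
it emulates:

* **Design:** 5 sites × (55 natural + 37 felled) logs; 9 species × (5
  natural + 3 felled) targets per site (= 40 targets per species, 225
  natural + 135 felled in total); 10 + 10 controls per site; 460 logs;
  65% / 35% of natural logs in decay stages 1 / 2; 50% / 50% uprooted /
  broken; felled logs all in decay stage 1. Labels are independent
  Bernoulli draws per natural log because the emulated description states
  proportions, not quotas; `exact_quota = TRUE` switches to rounded
  per-site quotas for exactly reproducible fixtures.
* **Communities:** a regional pool of 2346 OTUs with lognormal relative
  abundances (meanlog 0, sdlog 1.5). The lognormal is the standard
  community-ecology abundance default; nothing downstream depends on it
  and it is configurable. 90% of pool OTUs carry a phylum label, split
  57.0% Ascomycota / 37.9% Basidiomycota / rest other. Per-log richness is
  negative binomial with per-log-type means 59.4 (broken), 56.6
  (uprooted), 44.8 (felled) and dispersion 3 (the observed per-log ranges
  of such surveys span roughly 2–200, implying strong overdispersion). The
  design-weighted expectation of these means is 52.69 ≈ 52.7 OTUs per log.
  Present OTUs are drawn abundance-weighted without replacement, and reads
  are allocated multinomially with each present OTU receiving at least one
  read, so realized richness equals the draw.
* **Sequencing:** filtered depths are lognormal around 50,000 reads; a
  fraction 11/1380 of samples fail to low depth (uniform 1000–9999 reads),
  with an exact-count mode (`low_exact_k`) that places exactly $k$ low
  samples — the exact mode tests the filter, and is not a distributional
  claim. Spike reads are Binomial(filtered, 3%); the non-spike total is
  the filtered total minus spike reads and always equals the summed OTU
  reads.
* **Outcomes:** a two-stage observation model. Latent colonization is
  Bernoulli$(\Phi(x^\top\beta + a_{site}))$ with $x$ built from the design
  and resident census under a chosen true model; yearly detections thin
  the latent success independently with `detection_prob_per_year`
  (default 1, which collapses to "observed = colonized" — the implicit
  assumption of the emulated analysis — while letting sensitivity studies
  separate establishment from detectability). Sequencing depth is excluded
  from the true linear predictor: it is a post-census nuisance quantity,
  so its true coefficient is zero while fitted models still include it.
  Detected samples receive at least `min_target_reads` (default 4) reads
  of the target OTU; by default target OTUs never appear where they were
  not inoculated (`background_prob = 0`), matching the observation that
  target species are rare outside their inoculated logs.

What the generator does **not** emulate: PCR and primer bias, ITS length
variation, OTU-clustering artefacts, spatial structure within sites,
correlated co-occurrence beyond the low-rank structure induced by log-type
richness differences, and temporal turnover between censuses (background
communities are redrawn independently each census). Passing tests
therefore demonstrate that the *inference machinery* recovers known
processes from data of realistic shape and size — not that real communities
satisfy these simplifications.

## 7. Problem sizes and run lengths in the tests

The suite validates the sampler against an exact 401 × 401 grid-quadrature
posterior on a fixed $n = 8$ dataset (agreement within 0.05 on posterior
means); recovers coefficients at $n = 2000$ over 50 replicates (mean
absolute slope error ~0.03, 95% interval coverage within ±7 points of
nominal); checks spike-and-slab behaviour at $n = 40$ over 20 seeds
(inclusion probability > 0.8 for a true standardized effect of 1.5, mean
null-column inclusion ~0.35 against the 0.5 prior); and verifies ordination
recovery on 60 × 40 rank-2 Gaussian data (symmetric Procrustes distance
< 0.15 to the true scores). Cross-validation suites use 1 chain ×
(150–250 warmup + 150–250 draws) per fold — sizes chosen so the full suite
runs in well under a minute while Monte-Carlo error stays far inside each
test's tolerance.

## 8. Known limitations

* Single-species responses only: no joint species distribution modelling,
  no phylogenetic or trait terms, no spatial latent factors.
* The site-variance posterior is prior-dominated at five sites (§2);
  reported `sigma_site` values should be read against that floor.
* Pooled leave-one-out AUC is pessimistically biased under weak signal
  (§5); between-model differences are the meaningful quantity.
* Feature freezing means cross-validation does not penalize the feature
  construction stage; a strict per-fold protocol can be assembled from the
  exported functions when leakage is itself the question.
* The strain level (2–6 strains per species in such experiments) is
  carried as metadata only; the models address species-level success.
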