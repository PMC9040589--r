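---
title: "Inferring microbial cross-feeding networks from dynamic exometabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring microbial cross-feeding networks from dynamic exometabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossfeedr)
```

## The inference problem

In a defined microbial community, which species feeds which? Direct
observation of metabolite hand-offs is rarely possible, but two kinds of
batch monoculture experiments constrain the answer tightly:

* **fresh-medium time courses** — each species grows alone in the rich
  medium while its extracellular metabolome (the exometabolome) is sampled
  repeatedly, typically by flow-injection mass spectrometry that reports an
  intensity per annotated ion. Metabolites that rise with biomass are
  *secreted*; metabolites that fall are *consumed*.
* **spent-medium time courses** — the cell-free supernatant of a
  *producer* species (harvested in stationary phase, mixed 1:1 with fresh
  medium) becomes the growth medium for a *consumer* species. A metabolite
  that the producer secreted in fresh medium and that the consumer removes
  from the producer's spent medium is direct evidence of a cross-feeding
  edge (producer, consumer, metabolite).

`crossfeedr` implements this inference end to end: accurate-mass ion
annotation, growth-curve fitting, statistical consumption/secretion
calling with calibrated fold-change thresholds, network assembly and
statistics, element-weighted (C/N) mass-flow networks, and metabolic-module
detection — together with a seeded synthetic-data generator whose ground
truth makes every stage testable.

## The dynamic caller

For each culture, replicate intensities are averaged per time point
(replicate-level calling is available via
`caller_config(per_replicate = TRUE)`; averaging first is the default
because per-time-point replicate means are what the OD correlation is
defined against). An ion is called directional when a **trend criterion**
and a **magnitude criterion** both hold.

The trend criterion is a disjunction:

* Pearson correlation between intensity and OD with $|r| > 0.7$ and
  $p < 0.05$ (p from the exact t distribution of the sample correlation
  under $r = 0$), or
* a linear fit of intensity against time, or a log-linear ("exponential")
  fit, with $R^2 > 0.7$ and slope $p < 0.05$.

The fit branch exists because the OD correlation degrades for metabolites
exhausted before the culture reaches stationary phase (the intensity
flattens at the detection floor while OD keeps rising) and for metabolites
produced at a constant rate; a decaying or log-linear profile is still
unambiguous evidence of a monotone trend.

The magnitude criterion uses the maximum fold change relative to the first
time point: an increase of at least 1.20 supports secretion, a decrease of
magnitude at least 1.37 supports consumption. The direction of the passing
statistic (sign of $r$ or of the regression slope) must agree with the
direction of the fold change; in the rare non-monotone case where both
directions find support, the larger excursion wins. Everything else is
`unchanged`.

Fold changes are reported signed: $x_t/x_1$ when the series rises,
$-x_1/x_t$ when it falls, so the consumption threshold appears as values
at or below $-1.37$. Zero intensities are floored at half the smallest
positive value in the series and flagged (`floored`), and constant or
all-zero series are flagged `degenerate` and never called directional.

### Why 1.37 and 1.20? Dilution-series calibration

Flow-injection intensities are compressed by matrix effects: a 2-fold
concentration change does not produce a 2-fold intensity change. The
thresholds are therefore calibrated on a dilution series of the rich
medium itself. Ions genuinely derived from the medium respond to dilution
— they are kept when their Pearson correlation with the dilution factor is
below −0.75 — while instrument and solvent background ions do not and are
discarded. The consumption threshold is the mean fold change across kept
ions between the 40-fold and 80-fold dilutions (a true 2-fold decrease)
and the secretion threshold between the 20-fold and 40-fold dilutions.
On real rich-medium data this yields 1.37 and 1.20, which ship as the
defaults in `caller_config()`; on an ideal noiseless 1/dilution response,
`calibrate_thresholds()` returns exactly 2, which the tests exploit as an
oracle. Note the filter uses the raw Pearson correlation of intensity with
the dilution factor, which for an ideal 1/dilution response is only
strongly negative over a limited dilution range (about −0.93 over
20–80-fold, −0.84 over 20–160-fold); a series spanning a very wide range
dilutes the linear correlation, so the calibration windows should sit well
inside the measured range.

The same thresholds are applied to spent-medium experiments. The magnitude
criterion is a property of the measurement technology, not of the medium,
so consistency across media was chosen where the source material is silent.

## Ion annotation

Ions are measured in negative mode as singly deprotonated species
[M − H]⁻, so the expected m/z of a neutral formula is its monoisotopic
mass minus the proton mass 1.007276 Da (not the hydrogen atom mass — the
electron stays with the ion; the electron mass itself, ~0.00055 Da, is far
below the tolerance and is neglected). Every database record within the
mass tolerance (default 0.003 Da; 0.001 Da is appropriate for matching
isotope-labeled species by LC-MS) is reported: compounds with identical
formulas, such as leucine and isoleucine, are indistinguishable by
accurate mass and are all returned, sorted by absolute mass error with
alphabetical tie-breaks for reproducibility. `labeled_mz()` computes the
expected m/z of fully (or partially) ¹³C- or ¹⁵N-labeled ions from the
heavy-light mass differences (1.003355 and 0.997035 Da per atom).

## Growth physiology

OD time series are fitted with the four-parameter logistic curve
$$\mathrm{OD}(t) = A + \frac{K - A}{1 + e^{-r (t - t_0)}}$$
by Levenberg–Marquardt least squares (`minpack.lm`), initialized from the
data (baseline = min OD, plateau = max OD, inflection at the steepest
log-slope, rate from a log-linear fit of the middle of the rise) and
bounded so $K \ge A \ge 0$. The reported specific growth rate $\mu$ is the
maximum of $d\log \mathrm{OD}/dt$ along the fitted curve within the
observed time window — the per-capita rate a microbiologist means by
"growth rate" — not the shape parameter $r$; the two coincide only as
$A \to 0$. $\mu$ is located on a 512-point grid refined by golden-section
search. Fits with a span $K - A < 0.05$ OD units are flagged non-growing
with $\mu = 0$, mirroring how non-growing cultures are reported as dashes
rather than numbers.

`supplementation_effect()` compares replicate curves with and without a
supplemented metabolite: per-replicate fits, ratios of arm means for
$\mu$, maximum OD and the trapezoid-rule area under the raw OD curve
(normalized to the control mean), and two-sided t tests on the
per-replicate $\mu$ and max OD. Welch's unequal-variance form is used:
with 2–4 replicates per arm there is no basis for assuming equal
variances, and it reduces to the classical test when they are equal.
μ is computed per replicate and then averaged (rather than from a joint
fit) so that the t test's replication structure matches the ratio's.

## Network construction

Two views are assembled from the calls:

* **Fresh-medium prediction** (`predict_fresh_crossfeeding`): a metabolite
  secreted by at least one species and consumed by at least one *other*
  species is potentially cross-fed. The interaction type follows from the
  producer/consumer set sizes: one-to-one, one-to-many, many-to-one,
  many-to-many. A species may legitimately appear in both sets (overflow
  metabolism), but it contributes no self-edge, and a metabolite whose
  only producer and only consumer are the same species is excluded.
* **Spent-medium network** (`build_spent_network`): an edge (P, C, m)
  requires a secreted call for m by P in fresh medium *and* a consumed
  call for m by C in P's spent medium, with P ≠ C. Each
  (producer, consumer, metabolite) triple counts once, including when the
  same consumer takes the same metabolite from several producers' media —
  each such pair is its own interaction.

`goods_and_scores()` classifies each cross-fed metabolite as a **public
good** (two or more distinct consumers) or **private good** (exactly one),
and scores each species by its consumption:secretion interaction ratio —
low ratios mark net providers. Species that never produce have an
undefined ratio (`NA`); species that never consume score 0.

`network_statistics()` tests compound-class enrichment among public goods
with the two-sided Fisher exact test (`stats::fisher.test`, the
minimum-likelihood two-sided rule; the test suite cross-checks it against
an exhaustive hypergeometric enumeration for every 2×2 table with
$N \le 30$), excluding metabolites without a class annotation from the
2×2 table, and correlates per-species consumed-metabolite counts (species
that consume nothing count as zero) with a covariate such as genome size.

## Elemental mass-flow networks

Counting interactions treats a trace nucleobase and a near-molar organic
acid alike. When targeted quantification (mM) is available, each edge is
weighted by the element flow
$$\text{flow} = \Delta c \;[\mathrm{mM}] \times n_{\text{atoms}}(\text{element})$$
in element-mmol per liter of culture, for carbon and nitrogen separately.
The exchanged amount $\Delta c$ is the *consumer-side* decrease in the
producer's spent medium (first sampled concentration minus the minimum);
the producer-side secreted amount would overstate transfer whenever the
consumer takes only part of what was offered, and the consumer-side
decrease is what the arrows of a food web represent. Edges whose
metabolite lacks the element drop out of that element's network, edges at
or below 0.1 element-mmol/L are suppressed as visual noise (the
field-standard display cutoff), and unquantified edges are skipped with a
warning rather than imputed. Per-species provider and consumer totals
satisfy exact flow conservation: the sums of out-totals, in-totals and
edge flows coincide.

## Metabolic potential

`detect_modules()` screens a genome's ortholog list (e.g., KEGG KO ids)
against flattened metabolic-module definitions: a module is an ordered
list of steps, a step is satisfied if any of its alternative orthologs is
present, coverage is the satisfied fraction, and a module is called
present at coverage strictly greater than 50%. Nested boolean module
grammars must be flattened to this step/alternative form before use; that
keeps the detector transparent and testable.

## The synthetic-data generator

`community_spec()` / `simulate_consortium()` generate the full
experimental design — every species in fresh medium, every ordered pair in
spent medium — with known ground truth. The generative model is:

* logistic biomass, OD(t) as above, per species;
* consumption as a fraction $y \in [0,1]$ of the initially available
  amount, coupled to normalized biomass gain:
  $x(t) = x_0\,\bigl(1 - y\,\frac{\mathrm{OD}(t)-\mathrm{OD}(0)}{K-\mathrm{OD}(0)}\bigr)$;
* secretion proportional to biomass gain:
  $x(t) = x_0 + s\,(\mathrm{OD}(t)-\mathrm{OD}(0))$;
* spent medium as the exact 1:1 mixture of fresh medium and the
  producer's noiseless endpoint exometabolome at the last sampling time
  (stationary-phase harvest);
* multiplicative lognormal noise with unit mean and a chosen coefficient
  of variation applied independently per sample — ion counts are positive
  with roughly constant relative error, which a lognormal captures and an
  additive Gaussian would not. The default is 5% with 3 replicates and 10
  sampling times over 24 h, a typical design for this kind of experiment.

`random_community_spec()` draws consortium parameters from realistic
ranges (plateaus 0.8–2 OD, rates 0.5–1.5/h, inflections 3–8 h,
consumption fractions 0.5–0.95) and places each secreted product in the
fresh medium with 30% probability at a background level, as a rich
brain-heart-infusion-type medium would contain many microbially relevant
metabolites — without this, fresh-medium monocultures could never reveal
consumption of another species' product and the fresh-medium prediction
stage would be vacuous on synthetic data.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: mass-spectral artifacts (isobaric overlap,
in-source fragmentation, saturation), batch effects and drift between
replicates, medium-dependent growth physiology (growth parameters are the
same in fresh and spent media, so relative-max-OD values scatter around 1
rather than 0.5), non-monotone metabolite dynamics (transient overflow
followed by re-consumption), and annotation ambiguity (trajectories are
keyed by metabolite name, not m/z). Recovery being exact at 5% noise says
the statistical machinery is sound, not that real spectra are this clean.

## Numerical choices and degenerate inputs

* Correlation and regression p-values use the exact t distribution; no
  multiple-testing correction is applied, faithful to the method being
  reproduced (each called ion is subsequently corroborated by the
  spent-medium design rather than by FDR control).
* Log-linear fits floor non-positive intensities at half the smallest
  positive value, flagged; all-zero or constant series are flagged
  degenerate and stay `unchanged`.
* Tie-breaks are deterministic everywhere (alphabetical names, stable row
  orders), so identical inputs give byte-identical outputs.
* Fits that do not converge are flagged (`converged = FALSE`), never
  silently dropped.
* Seeds: every stochastic generator takes an explicit seed and restores
  the caller's RNG state, so library use never perturbs a session's
  random stream.

## Problem sizes

The packaged validation works at desk scale, chosen so the full test
suite and the acceptance script each run in a few minutes on one CPU:
consortia of 4–6 species (3 replicates, 10 time points), 20 noisy
replicate consortia for precision/recall, 500 random series for the
caller-vs-oracle comparison, all ~46,000 2×2 tables with $N \le 30$ for
the Fisher cross-check, and 100 random curves for logistic parameter
recovery. All sizes scale up linearly if heavier validation is wanted.

## Known limitations

* Calls are per-(species, medium) and assume monotone trends; oscillating
  metabolites (consumed, then re-secreted) will be called by their largest
  excursion only.
* The spent-medium design observes each ordered species pair through one
  producer medium; syntrophic loops requiring co-culture are invisible.
* Fresh-medium predictions are hypotheses, not evidence: a metabolite
  secreted by A and consumed by B in separate monocultures need not be
  transferred when the two actually meet.
* Absolute quantification is taken as given; the package converts and
  balances concentrations but does not model ionization response.
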