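---
title: "Models and methods behind mitoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoscreen)
```

`mitoscreen` chains five analyses that surround an in-silico campaign
against a mitotic kinase: transcriptomic/chemical connectivity ranking,
kinome selectivity scoring, single-sample scoring of an active-mitosis
gene signature, a survival-based synthetic-lethality screen, and
Chou–Talalay combination-index analysis. This vignette describes each
model, its assumptions, and the design choices taken where the methods
literature leaves the details open. Every empirical claim below is
computed by the package's own test suite on synthetic data; none is
imported from external datasets.

## The synthetic cohort: what it emulates and what it does not

`generate_cohort()` emulates a paired tumor/normal transcriptome cohort
with survival follow-up. Its generative model is deliberately the
*simplest* model satisfying the assumptions the downstream statistics
rely on:

* **Latent mitotic activity.** Each patient $i$ has
  $a_i \sim N(0, 1)$. In the tumor sample, each of the
  `n_signature_genes` planted signature genes and the anchor gene take
  the value $L a_i + s + \varepsilon$, with loading $L$
  (`factor_loading`), tumor shift $s$, and gaussian noise
  $\varepsilon \sim N(0, \sigma^2)$; matched normal samples and all
  background genes are pure noise. Two genes sharing the factor then
  correlate as $L^2/(L^2+\sigma^2)$, which the tests verify
  empirically.
* **Survival.** Exponential event times with hazard
  $\lambda_0 \exp(\beta a_i + \gamma I_i)$, where
  $I_i$ indicates that the tumor expression of both the anchor and the
  planted partner gene falls at or below the cohort median. An
  exponential baseline is the simplest law satisfying the proportional
  hazards assumption of the screen; $\lambda_0$ defaults to 1/1000 per
  day (median survival about two years at zero activity).
* **Censoring.** With probability `censor_rate` a patient is
  administratively censored at a uniform fraction of the latent event
  time. This yields the requested censoring fraction exactly in
  expectation, keeps observed times strictly positive, and leaves the
  Kaplan–Meier/Cox recovery checkable in closed form.

Expression is a continuous log-like scale with gaussian noise — *not* a
count model. Every downstream statistic here is rank- or
regression-based, so negative binomial sampling, library-size effects,
batch structure, and tumor purity are intentionally out of the model.
Passing tests therefore demonstrate correctness of the statistics and
recoverability of planted structure, not robustness to RNA-seq
artifacts. The absolute expression scale is arbitrary-but-consistent,
which suffices because the signature scoring is rank-based.

## Connectivity scoring

The query is an up/down gene signature; references are ranked profiles
(signed per-gene statistics, sorted descending, ties broken by gene id
for bit-reproducibility). `weighted_ks_es()` is the classic running-sum
statistic: hits advance by $|r|^w$ normalised over hits, misses retreat
by $1/(N-k)$, and the enrichment score is the signed maximum deviation.
The two-sided connectivity score combines
$\mathrm{wtcs} = (ES_{up} - ES_{down})/2$ when the two enrichment
scores have opposite signs and is 0 otherwise. The weight exponent
defaults to 1 (the connectivity-map convention); $w = 0$ gives the pure
rank statistic, invariant under any strictly monotone transform of the
profile scores. The test suite checks the statistic against both a
brute-force enumeration and the independent `fgsea` implementation.

Permutation significance (`preranked_gsea()`) shuffles gene labels and
uses the add-one estimator $p = (1 + \#\{|ES^*| \ge |ES|\}) /
(1 + n_{perm})$, so p-values are floored at $1/(n_{perm}+1)$ and
calibrated by construction; the suite verifies a 5% rejection rate
under random gene sets to within two points over 400 replicates.

Chemical similarity is the Tanimoto coefficient
$|A \cap B| / |A \cup B|$ on binary fingerprints only — counts or
chemistry-aware kernels are out of scope, and fingerprints are
caller-supplied bit vectors (no molecule handling). The reference
corpus of a public connectivity database is likewise out of scope: the
package implements the scoring and runs it against user or synthetic
profile collections, and raw wtcs is reported without
reference-population (tau) normalisation.

## Kinome selectivity

`s_score()` implements $S(x)$ = (nonmutant kinases with %Ctrl
strictly < $x$) / (nonmutant kinases tested). Three choices are fixed
by the definition and stated here for determinism: the inequality is
strict (a kinase exactly at the threshold is a non-hit); mutant entries
are excluded from numerator and denominator alike; and alongside the
exact fraction the conventional three-decimal rounding is reported
(17/403 prints as 0.042). Hit lists sort by ascending %Ctrl with id
tie-breaks, and the selectivity curve over a threshold grid is
nondecreasing by construction.

## Active-mitosis signature and single-sample scoring

`derive_signature()` keeps candidates that pass two independent
filters: positive correlation with the anchor across tumor samples
(Spearman by default — robust to unknown normalisation; Pearson
selectable) at Benjamini–Hochberg adjusted one-sided $p \le$ 0.05, and
tumor-over-normal elevation by a one-sided paired Wilcoxon signed-rank
test, BH-adjusted at 0.05. The paired Wilcoxon respects the matched
design without a normality assumption. "Correlated" is interpreted as
*positively* correlated, since the signature is meant to proxy mitotic
activity driven with the anchor. Correlation is computed on tumor
samples only by default (normals would dilute the tumor-driven factor;
an `corr_samples = "all"` option exists). An empty result is an error
that reports per-filter survivor counts, so threshold problems are
diagnosable.

`ssgsea_score()` is the Barbie-style integral statistic: with genes
ranked by descending expression within one sample, the score is the sum
over all positions of (weighted in-set ECDF − out-of-set ECDF), with
in-set steps proportional to $(N - j + 1)^\tau$ at position $j$. The
default $\tau = 0.25$ follows the method the name conventionally
denotes; $\tau = 0$ makes the score a pure rank statistic. Because only
within-sample ranks enter, the score is invariant under monotone
transforms of the expression values — the suite asserts bit-identical
scores after exponentiating the whole matrix. Per-cohort scores are
range-normalised to $[0,1]$ (raw scores always retained); a cohort with
fewer than two distinct raw scores cannot be range-normalised and is
returned raw with a warning tag.

Stage association uses a Jonckheere–Terpstra-style ordered trend
statistic (sum of pairwise Mann–Whitney counts over ordered group
pairs, ties at 1/2) with a seeded permutation p-value; with two groups
it reduces exactly to the Mann–Whitney U count.

## Survival screen

Kaplan–Meier curves, the two-group log-rank test, and univariate Cox
models are computed with the `survival` package (Efron tie handling),
and each is verified in the tests against hand-built product-limit and
observed-minus-expected enumerations on small instances. A separated or
non-converging Cox fit is reported as `indeterminate` rather than
raised, since a screen over many candidates must survive individual
pathological strata.

`stratified_sl_screen()` formalises the synthetic-lethality logic:

1. Patients split at the **median** anchor tumor expression (ties to
   low). Median is the default because the upstream grouping
   convention ("anchor-high" vs "anchor-low") states no cut rule;
   tertile/quartile outer-group splits are exposed.
2. Within each stratum, the candidate is dichotomised at its
   within-stratum median into a **low-expression indicator**
   (1 = at or below the median). Coding the *low* group as the exposed
   group makes the hazard ratio read in the synthetic-lethality
   direction: HR_low > 1 means "losing the candidate while the anchor
   is already low is hazardous". A continuous-covariate option (per
   unit decrease) is exposed.
3. The call rule is formalised through confidence bounds rather than a
   qualitative HR comparison: **SL-partner** iff the 95% CI lower
   bound of HR in the anchor-low stratum exceeds 1 *and* the anchor-high
   stratum shows no such significant hazard. This is conservative
   (about a 2.4% null call rate, which the suite checks stays under
   5%) and testable.

The screen is univariate by design — no clinical covariate adjustment —
matching how unadjusted per-gene hazard-ratio panels are usually
reported; multivariate adjustment is a deliberate non-goal.

## Median-effect synergy analysis

Single agents follow the median-effect model
$f_a/f_u = (D/D_m)^m$, fitted by unweighted least squares of
$\log_{10}(f_a/(1-f_a))$ on $\log_{10} D$; $m$ is the slope and
$D_m = 10^{-b_0/m}$. Fraction-affected values outside $[0.01, 0.99]$
are flagged and excluded from fits (the logit diverges at the
boundaries; the window is configurable), and a nonpositive slope flags
the fit rather than silently producing a negative-potency model. The
combination index at a measured combination point is the mutually
exclusive (two-term Loewe) form
$CI = d_1/D_{x1}(f_a) + d_2/D_{x2}(f_a)$, computed at the *measured*
fraction affected, never a model prediction; the mutually nonexclusive
third term is out of scope. Exactness properties anchor the tests:
noiseless generated curves invert to $\ge$10 significant digits, and a
combination generated with Loewe-interaction multiplier $\alpha$
returns $CI = \alpha$ at every noiseless point to $10^{-6}$ after
refitting from generated single-agent curves.

## Pipeline, problem sizes, and seeds

`run_discovery()` executes simulate → connect → kinome → amses →
slscreen → synergy from one YAML config with explicit defaults for
every tunable named above, writes plain-text outputs, and finishes with
a manifest (parameters, package version, MD5 per output) so a config +
seed pair reproduces identical hashes. Every generator takes a single
integer seed, derives its substreams from it, and restores the caller's
RNG state.

Validation problem sizes were chosen as the smallest at which the
planted effects are comfortably identifiable rather than borderline:
signature recovery runs at 300 patient pairs × 2000 genes with 120
planted genes (per-gene correlation $\approx 0.8$ at the default
loading and noise); the SL screen at 600 patients with interaction
log-hazard 0.9 (stratum-level Wald $z \approx 7$, so recovery failures
are rare); null calibrations at 400 replicates (binomial two-sigma
band of about ±2 points around 5%). The demo config is smaller still
(150 patients, 400 genes) and completes in seconds.

## Known limitations

* The synthetic cohort has no count noise, batch effects, purity
  gradients, or correlated background genes; recovery rates on it are
  upper bounds for real cohorts.
* Connectivity runs against supplied profile collections; no reference
  corpus or tau-normalisation ships with the package.
* The SL screen is univariate and dichotomises expression; power is
  sacrificed where a continuous trend exists (a continuous option is
  provided but untested against clinical confounding).
* The combination index assumes the mutually exclusive form and a
  well-estimated single-agent model; with fewer than four informative
  single-agent doses the CI inherits substantial fit variance.
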