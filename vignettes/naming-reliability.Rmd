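---
title: "Estimating the reliability of picture-naming speed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the reliability of picture-naming speed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(namerel)
```

## The problem

Picture-naming experiments measure production latencies: the time from
picture onset to the onset of the vocal response. Individual-differences
research correlates participants' mean naming speed with scores on other
cognitive tasks, which is only meaningful if naming speed is a *reliable*
trait of the participant — if relatively fast speakers are relatively fast
again on other trials, on another day, or under a task variation. `namerel`
implements the full workflow for quantifying that reliability from
trial-level data: preprocessing and exclusion, hierarchical Bayesian
estimation of the reliability correlation, a graded interpretation rule,
speed–accuracy correlation, stimulus-list balancing, and
reliability-attenuated power planning for downstream correlational designs.

Because raw voice recordings cannot be redistributed, the package ships a
synthetic-data generator that reproduces the statistical structure of such a
study with known ground truth, so that every estimator in the package can be
validated by parameter recovery.

## The hierarchical reliability model

Naming latencies are modelled as lognormal. For trial $t$ with participant
$p(t)$, item $i(t)$, and half-label $h(t) \in \{1, 2\}$ (even/odd trials,
first/second half, session, or task condition, depending on the question):

$$\log y_t \sim \mathrm{Normal}\big(\mu_{h(t)} + b_{p(t), h(t)} + u_{i(t)},\; \sigma_e\big)$$

This is a *no-intercept* parameterization: instead of a grand intercept and
a half effect, the model estimates one intercept $\mu_1, \mu_2$ per half,
and the by-participant effects mirror that structure,

$$(b_{p,1}, b_{p,2}) \sim \mathrm{MVN}\left(\mathbf{0},
\begin{pmatrix} \sigma_{b1}^2 & \rho\,\sigma_{b1}\sigma_{b2} \\
\rho\,\sigma_{b1}\sigma_{b2} & \sigma_{b2}^2 \end{pmatrix}\right).$$

The correlation $\rho$ of the by-participant effects **is** the reliability
estimand: split-half reliability for within-session splits, test-retest
reliability for the session split. Estimating $\rho$ inside the hierarchical
model rather than correlating per-participant mean latencies matters because
averaging over trials treats trial and item variability as if it were
participant signal; the resulting Pearson correlation is attenuated by trial
noise (the classical factor $\sigma_b^2 / (\sigma_b^2 + \sigma_e^2/m)$ for
$m$ trials per half, available in closed form via
`expected_naive_split_correlation()`). Partial pooling shrinks each
participant's effect toward the population mean in proportion to its noise,
which removes that attenuation. With 150 trials per session the attenuation
of the naive estimator is small (about 0.97), so the advantage of the
hierarchical estimate is modest at full session length and grows as halves
get shorter or noisier.

### Priors

All priors are regularizing and fixed by default:

* Intercepts: $\mathrm{Normal}(6.75, 1.5)$ on the log-ms scale. The prior
  median latency is $e^{6.75} \approx 854$ ms and one prior SD spans
  $\approx$ 191–3828 ms (`prior_latency_anchors()`), covering any plausible
  naming latency.
* All SDs (participant, item, residual): half-Normal(0, 1) on the log scale.
* The random-effect correlation: LKJ with $\eta = 2$. For a $2 \times 2$
  correlation matrix the LKJ density is proportional to $(1 - \rho^2)^{\eta - 1}$,
  which is exactly $(\rho + 1)/2 \sim \mathrm{Beta}(\eta, \eta)$; the
  sampler uses that scalar form directly.

The accuracy model is the binomial-link analogue: correct/error responses
with per-condition log-odds intercepts (prior $\mathrm{Normal}(0, 1.5)$),
correlated by-participant effects, and the same SD and correlation priors.
Participants with all-correct responses are handled by the partial pooling
itself — their effects shrink toward zero rather than diverging. The
accuracy model carries no item effects, mirroring the by-participant
structure used in the original analyses.

### Sampling and convergence

Models are sampled with JAGS via `rjags`. The bivariate participant effect
is written in conditional form ($b_{p,2} \mid b_{p,1}$ is univariate
normal), which avoids a matrix inversion in the sampler; SD parameters carry
a truncation floor of $10^{-3}$ (log-ms) purely so that the conditional
precision stays finite in degenerate no-variance corners. The `"default"`
preset runs 4 chains of 1000 warmup + 1000 kept iterations and requires
split-chain $\widehat{R} \le 1.01$ and effective sample size $\ge 400$ for
the correlation; the `"reduced"` preset (2 chains, 400 + 400 + 600, with
proportionally lower thresholds) is used for simulation studies and the test
suite. Non-convergence is flagged on the returned object and raised as a
warning, never silently ignored. Chains use fixed per-chain RNG seeds
derived from the spec seed, so every fit is exactly reproducible.

Credible intervals are equal-tailed 95% quantile intervals throughout.

## Graded interpretation (ROPE bands)

Rather than a single reliability cutoff, correlations are graded against
conventional bands: poor ($< .41$), moderate ($.41$–$.60$), good
($.61$–$.80$), excellent ($.81$–$1$). The decision rule uses the full
credible interval: if it lies inside one band, that interpretation is
accepted outright; if it spans several, only the *lowest* band the interval
touches is accepted ("at least moderate"). Printed two-decimal band labels
leave the gaps between, e.g., .60 and .61 unspecified; the bands are
implemented as contiguous intervals closed on the left (so .41 is already
moderate), and the boundaries are configurable in `rope_bands()`.

```{r rope}
classify_reliability(list(mean = 0.82, ci_low = 0.75, ci_high = 0.89))[1:2]
```

## Speed–accuracy correlation

Whether fast participants are fast because they sacrifice accuracy is
checked by correlating by-participant speed and accuracy effects (posterior
means extracted from the two hierarchical models) within each condition.
The correlation is estimated with `estimate_correlation()`: the likelihood
is the exact sampling density of the observed sample correlation
(`dsampcor()`, Hotelling's form evaluated through a Gauss hypergeometric
series), and the prior is a shifted and scaled Beta(3, 3) on $(-1, 1)$ —
symmetric around zero, downweighting extreme values. The posterior is
computed by numerical integration on a grid of 2001 equally spaced points,
which resolves the 95% bounds to better than $10^{-3}$; a numerically
perfect sample correlation is clamped to $\pm(1 - 10^{-9})$, which leaves
the $\rho$-likelihood intact because the offending factor is constant in
$\rho$. A negative speed–accuracy correlation (faster participants are
*more* accurate) argues against a trade-off strategy.

## Power planning under attenuation

Measurement unreliability caps observable correlations: if two measures have
reliabilities $r_{aa}$ and $r_{bb}$, a true correlation $\rho$ between the
underlying constructs appears as $\rho\sqrt{r_{aa} r_{bb}}$ (Spearman's
correction, `attenuate()`). Sample sizes are planned against this attenuated
value. `required_n()` returns the smallest integer $n$ at which the
two-sided test of zero correlation at level $\alpha$ reaches the target
power, computed from the exact sampling distribution of $r$ under the
alternative (the Fisher-$z$ approximation is available as `method =
"fisher"` and agrees within 2 participants on the planning grid). No
continuity or rounding adjustment is applied: $n$ is the exact boundary of
the integer power curve, so a case whose achieved power at some $n$ is
0.7996 — which a planning tool displaying two decimals would call 80% — is
reported as requiring $n + 1$.

```{r power}
rho_obs <- attenuate(0.3, 0.8, 0.8)
c(rho_obs = rho_obs, n = required_n(rho_obs))
unexplained_variance(0.77)
```

## The synthetic-data generator

`simulate_dataset()` emulates the design the analysis targets: 50
participants naming 150 pictures per session in two sessions a week or two
apart, every participant seeing the same items within a session in an
independently randomized order, with disjoint item lists across sessions
(the counterbalanced two-list design; `items_shared = TRUE` gives the
shared-list variant). Defaults place the latency scale at the prior center
($\mu = 6.75$ log-ms $\approx 854$ ms) with between-participant SD 0.15,
between-item SD 0.10, and residual SD 0.30 on the log scale — values in the
range typically recovered from naming studies, giving participant means a
spread of roughly $\pm 15\%$ around the grand mean. The default true
between-session correlation is 0.77, the test-retest estimate the package's
recovery studies target. Accuracy is near ceiling (3 log-odds $\approx$ 95%
correct), and disfluencies (0.6%) and no-responses (1%) are planted
independently at rates comparable to online naming data; latencies exceeding
the 3000 ms response window (measured from picture onset, matching the
2000 ms picture + 1000 ms blank trial structure) are additionally censored
to no-responses. Trials are classified with the fixed precedence
no-response > disfluency > wrong word.

The joint by-participant effect vector (speed and accuracy in both
conditions) is multivariate normal. The design identifies the speed–speed
correlation (`rho_subj`) and the within-condition speed–accuracy
correlations (`rho_speed_acc`); the accuracy–accuracy correlation is a free
parameter (`rho_acc`, default 0.5), and the cross-lagged terms are set to
the product `rho_subj * rho_speed_acc`, the structure implied by treating
the two conditions as exchangeable carriers of a common speed trait.
Positive semi-definiteness is checked before any sampling.

What the generator does *not* emulate: trial-order effects (practice,
fatigue — real naming latencies drift over a session, which is one reason
first/second splits run below even/odd splits), latency-dependent error
mechanisms (errors are planted independently of the trial's latency), and
session-level state shifts (motivation, time of day) beyond what the
participant effect correlation encodes. Passing recovery tests therefore
shows that the estimators recover the parameters of *this* data-generating
process, not that real data satisfy its assumptions.

## Validation strategy and problem sizes

The test suite validates each layer against an independent oracle: z-scoring
against a two-pass computation, the sampled matcher against exhaustive
enumeration of all perfect matchings for up to 8 items, the closed-form
naive split-half expectation against direct Monte-Carlo simulation of
participant half-means, the exact power function against a 200,000-replicate
rejection-rate simulation, the grid posterior against null coverage and the
flat-prior/large-$n$ limit, and the hierarchical model by parameter recovery
at the full study scale (50 × 150 × 2; 10 seeded replicates across true
correlations 0.5, 0.77, and 0.9 under the reduced sampler preset) — with the
requirements that posterior means land within ±0.12 of the truth, the 95%
intervals cover it in at least 90% of replicates, and the hierarchical
posterior mean beats the Pearson correlation of per-participant mean raw
latencies in mean absolute error.

## Stimulus-list balancing

`balance_lists()` reproduces the list-construction procedure: z-score the
norms (Zipf frequency, age of acquisition, H-index name agreement; sample SD
by default), form a feature vector per item, compute all pairwise cosine
similarities, sample random perfect matchings (shuffle the items, pair
adjacent ones) and keep the matching with the highest mean cosine
similarity; each pair then sends one member to each list by a per-pair fair
coin under the run seed, a detail the balance itself does not depend on.
One million samples (the default) is far more than needed for a few hundred
items to land in the extreme upper tail of the matching distribution, but
the maximum over samples is what defines the output, so the returned
matching's mean cosine is by construction at least that of every candidate
examined.

## Known limitations

* The reliability estimand is the correlation of *stable* participant
  effects under the fitted model; model misspecification (e.g., heavy-tailed
  residuals, order effects) is absorbed into the residual and can bias the
  estimate in either direction.
* JAGS's samplers mix more slowly on the correlation than gradient-based
  samplers would; the default preset's ESS floor of 400 makes runs at the
  full study size take a few minutes each.
* The exclusion report reproduces printed-percentage conventions (two
  decimals, all-trials denominator); percentages recomputed from other
  denominators (correct trials only) will differ.
* `estimate_correlation()` uses the reduced likelihood of the sample
  correlation, not a full bivariate-normal marginalization; for small $n$
  and strong priors on the margins these can differ slightly.
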