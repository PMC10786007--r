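# namerel

Reliability analysis for picture-naming response speed.

Individual-differences studies of language production correlate
participants' mean picture-naming latency with scores on other cognitive
tasks (attention, working memory, inhibition). That approach presupposes
that naming speed is a reliable property of the participant: that fast
speakers are fast again on other trials, on another day, and under task
variations. `namerel` provides the statistical machinery for testing that
assumption from trial-level naming data, and for planning correlational
studies once a reliability estimate is in hand.

## What the package computes

**Reliability as a random-effect correlation.** Log latencies of correct
trials are modelled hierarchically with one intercept per data half
(even/odd trials, first/second half, session, or task condition) and
correlated by-participant effects:

    log y_t ~ Normal(mu[h(t)] + b[p(t), h(t)] + u[i(t)], sigma_e)
    (b[p,1], b[p,2]) ~ MVN(0, Sigma),  cor(b[p,1], b[p,2]) = rho

The posterior of `rho` is the split-half (within-session) or test-retest
(between-session) reliability. Unlike the Pearson correlation of
per-participant mean latencies, the hierarchical estimate is not attenuated
by trial and item noise, because partial pooling shrinks each participant's
estimate in proportion to its noise. Priors: intercepts Normal(6.75, 1.5)
on the log scale (prior median 854 ms), half-Normal(0, 1) SDs, LKJ(2)
correlation. Models are sampled with JAGS (`rjags`).

**Graded interpretation.** Correlations are graded against conventional
bands (poor < .41 <= moderate <= .60 < good <= .80 < excellent <= 1) using a
region-of-practical-equivalence rule on the 95% credible interval: an
interval spanning several bands only licenses the lowest band it touches.

**Speed-accuracy correlation.** By-participant speed and accuracy effects
(the latter from a binomial-link hierarchical model) are correlated with an
exact reduced likelihood for the sample correlation and a shifted, scaled
Beta(3, 3) prior on (-1, 1).

**Power planning under attenuation.** Observable correlations are capped at
`rho_true * sqrt(rel_a * rel_b)` (Spearman's correction). `required_n()`
finds the smallest sample size reaching a target power for the two-sided
correlation test, using the exact sampling distribution of r.

**Stimulus-list balancing.** Two lists matched on Zipf frequency, age of
acquisition, and name agreement (H-index), built by sampling random perfect
matchings of z-scored feature vectors and keeping the set of pairings with
the highest mean cosine similarity.

**Synthetic data.** `simulate_dataset()` generates trial-level data with
the full study structure (50 participants x 150 items x 2 sessions,
lognormal latencies with crossed participant/item effects, near-ceiling
accuracy, planted disfluencies and no-responses) and known ground truth for
parameter recovery.

## Worked example

```r
library(namerel)

# simulate a two-session study with true test-retest correlation 0.77
sim <- simulate_dataset(generative_params(rho_subj = 0.77, seed = 42))

# exclude error trials, with the conventional exclusion report
filtered <- filter_trials(sim$trials)
filtered$report
#>  group response_class count percent denominator
#>      1        correct  6909   92.12        7500
#>      1     wrong_word   469    6.25        7500
#>      1     disfluency    48    0.64        7500
#>      1    no_response    74    0.99        7500
#>      2        correct  7028   93.71        7500
#>      ...

# test-retest reliability: correlation of by-participant effects across sessions
fit <- fit_reliability(filtered$trials, split_spec("session"),
                       model_spec(preset = "reduced", seed = 42))
fit
#> Hierarchical reliability fit (session1 / session2)
#> By-participant random-effect correlation:
#>   Posterior mean 0.775, 95% CI [0.641, 0.868]

classify_reliability(fit$correlation)[1:2]
#> $label
#> [1] "good"
#> $qualifier
#> [1] "at_least"
```

The posterior mean 0.775 recovers the generating correlation 0.77; the
credible interval spans the good and excellent bands, so the graded rule
only licenses "at least good" reliability. Planning a study that correlates
this measure (reliability 0.775) with, say, an operation-span score of
reliability 0.73, assuming a true correlation of 0.3:

```r
rho_obs <- attenuate(0.3, fit$correlation$mean, 0.73)
required_n(rho_obs)
#> [1] 151
```

i.e. the attenuated observable correlation is 0.226 and 151 participants
are needed for 80% power at alpha = 0.05.

The whole workflow (gating, exclusion, fitting every requested split,
grading, accuracy, power queries) can also be driven from a YAML config via
`run_pipeline()`; see `?run_config`.

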