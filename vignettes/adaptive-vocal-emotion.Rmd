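---
title: "Simulating and analysing adaptive audiovisual vocal-emotion experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing adaptive audiovisual vocal-emotion experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emostair)
```

## The scientific setting

Cochlear-implant (CI) users vary enormously in how well they recognise vocal
emotions, from near-normal to near-chance. Two experimental designs are
commonly combined to study how visual facial information changes their vocal
emotion recognition:

* a **fixed-intensity design**: every listener hears the same 256 stimuli
  (2 emotions x 8 speakers x 4 pseudowords x 4 presentation conditions) and
  accuracy is the dependent variable;
* an **adaptive design** on a voice-morph continuum: the voice's
  emotion-specific acoustic parameters are attenuated or exaggerated along an
  anger-surprise morph trajectory, giving morph levels (ML) from 60%
  (anti-caricature, hard) through 100% (original) to 140% (caricature, easy)
  in 20% steps. A staircase adjusts the morph level per condition so each
  listener hovers at 75% correct, and the *morph level needed* becomes the
  dependent variable. This removes accuracy floor/ceiling differences between
  groups and lets audiovisual effects be compared at equated auditory
  performance.

The four presentation conditions are congruent audiovisual (AV), incongruent
AV, and two auditory-only variants that differ only in the nominal timing
they inherit; the auditory-only variants are pooled in analysis.

`emostair` implements the complete pipeline as testable code: the stimulus
combinatorics, a generative observer model, the staircase, the
trial-filtering and scoring rules, the performance-matching algorithm, and
the inferential layer. No audio or video is synthesised — the morph level is
an abstract scalar difficulty axis, which is exactly the role it plays in the
statistical analysis.

## The observer model

Simulated listeners respond to a stimulus at morph level $x$ with probability

$$
p(x) \;=\; \gamma + (1 - \gamma - \lambda)\,
  F\!\left(\frac{x - \alpha}{\beta}\right),
$$

where $F$ is the standard logistic, $\gamma = 0.5$ is the 2-AFC guessing
floor, $\lambda$ the lapse rate, and $\beta$ the slope scale in ML units.
Instead of the location $\alpha$, the model is parameterised by the
**75%-correct threshold** $\theta$; $\alpha$ is solved analytically so that
$p(\theta) = 0.75$ exactly. A logistic with lapse is the standard 2-AFC form
and is consistent with the approximately linear relation between morph level
and recognition efficiency reported for this type of continuum. Thresholds
may lie outside the presentable grid: $\theta \gg 140$ produces a
chance-level listener, $\theta \ll 60$ (with $\lambda = 0$) a perfect one —
both phenotypes occur in real CI/NH cohorts.

Each observer carries one threshold per condition: an auditory baseline
$\theta_{aud}$ (shared by both auditory-only variants), a congruent threshold
$\theta_{aud} - \Delta_{benefit}$ and an incongruent threshold
$\theta_{aud} + \Delta_{cost}$, with $\Delta$s drawn from normal laws
truncated at zero.

### Default generator parameters

The defaults of `group_config()` are the study conditions the generator
emulates, fixed once:

| parameter | CI | NH | source |
|---|---|---|---|
| mean $\theta_{aud}$ | 118.9 | 80.30 | printed group means |
| SD of $\theta_{aud}$ | 22.5 | 13.6 | printed SEM x $\sqrt{25}$ |
| mean $\Delta_{benefit}$ | 21.82 | 8.26 | differences of printed condition means |
| mean $\Delta_{cost}$ | 10.86 | 15.98 | differences of printed condition means |
| SD of $\Delta$s | 10 | 10 | not identifiable from printed summaries; chosen as a realistic between-subject spread |
| slope $\beta$ | 10 ML units | 10 | model choice: transition clearly narrower than the 80-unit grid but wider than one step |
| lapse $\lambda$ | 0.02 | 0.02 | typical attentive-adult lapse rate |
| $n$ per group | 25 | 25 | study sample size |

Reaction times (measured from voice offset) are lognormal with median 1500 ms
and the `sdlog` solved so that exactly 0.87% of trials exceed the 6000 ms
exclusion cutoff — the exclusion proportion the fixed-intensity experiment
reports. The quality-of-life score (WHOQOL-BREF environmental-health domain,
4–20 scale) is generated jointly with $\theta_{aud}$ through a Gaussian
copula: the latent normal behind the QoL score has Pearson correlation
$2\sin(\pi\rho_s/6)$ with the latent normal behind $\theta_{aud}$, which
makes the population *Spearman* correlation equal to the target
$\rho_s = -0.38$ (the printed marginal correlation; negative because lower
morph levels mean better performance). Because the QoL score is a monotone
transform of its latent normal, rank structure is preserved exactly, and
$\rho_s = -1$ degenerates to a perfect monotone association.

### What the generator does not emulate

Speaker- and pseudoword-specific difficulty, listener-sex effects (the study
found none), serial dependencies (fatigue, learning), and any dependence of
$\Delta_{benefit}$ on $\theta_{aud}$ (inverse effectiveness) — the observer's
trials are conditionally independent given the design. Passing tests
therefore validate the *procedures* (staircase, scoring, matching,
inference) under a clean psychometric observer, not the richness of real
response data.

## The staircase

Each condition runs as an independent transformed up-down track over 24
four-trial rounds (96 trials/condition, 384 per session, presented
interleaved in 8 blocks of 48 with 12 slots per condition per block). After
each round of 4 trials at one level: 0–2 correct steps one grid level up
(more diagnostic information), 3 correct repeats the level, 4 correct steps
down. Levels clamp at 60 and 140. Analysis discards the first four rounds per
condition (burn-in) and summarises each condition by the mean retained round
level; the two auditory-only tracks are pooled round-by-round by their mean.

Numerical facts worth knowing about this rule:

* Its equilibrium accuracy is the solution of $P(4\ \text{correct}) =
  P(\le 2\ \text{correct})$, i.e. $4p^3 - 2p^4 = 1$, giving $p^* \approx
  0.735$ — slightly below the nominal 0.75 target. With the coarse 20%-step
  grid, simulated mid-grid observers hold about 72–73% correct in retained
  rounds. The package reports what the procedure actually delivers rather
  than asserting the nominal target.
* Threshold recovery is correspondingly good to within a fraction of a grid
  step: observers generated at $\theta_{aud} = 80.3$ recover a mean
  auditory-only level near 78–79 across 500 simulated sessions.
* A chance-level observer drifts to the 140 ceiling (median retained level
  140); a perfect observer descends to the 60 floor within two rounds.

Design choices where the procedure description is open: the starting level
is 100 (the unmanipulated original; exposed as `start_ml`); levels update
continuously within a condition's stream rather than between blocks; each
round presents 2 anger and 2 surprise items in random order with
speaker/pseudoword combinations sampled without replacement within the round,
keeping the 2-AFC unbiased inside the unit the staircase rule evaluates; and
all retained rounds (not a final subset) enter the summary.

## Scoring

* **Trial exclusion**: reaction times strictly greater than 6000 ms from
  voice offset are excluded; the boundary value is retained.
* **Benefit/cost**: congruent minus auditory-only and incongruent minus
  auditory-only, on the experiment's native scale (accuracy in the
  fixed-intensity design — positive benefit is facilitation; morph level in
  the adaptive design — negative benefit is facilitation).
* **Caricature slope**: per participant and condition, the accuracy
  difference between the highest and lowest morph level visited, divided by
  the number of 20% steps between them, using post-burn-in trials only. A
  level qualifies with at least `min_trials_per_ml = 4` retained trials (one
  full round), guarding against single-trial accuracy estimates. With fewer
  than two qualifying levels the score is missing — the natural outcome for
  listeners pinned at the 140 ceiling in a hard condition, and the analysis
  reports available-case counts rather than erroring.

## Performance matching

`match_groups()` equates auditory-only performance by iteratively removing
pairs of the lowest-performing CI user (largest morph level) and the
highest-performing NH user (smallest). "Until the difference is minimal" is
operationalised as the **global** minimum of the absolute mean difference
over all admissible removal counts, with ties broken toward retaining more
participants; a greedy variant that stops at the first local minimum is
available as a strategy option, since the two readings can differ and the
original stopping rule is not formalised. Ties among equal morph levels
remove the larger participant id first, deterministically. The implementation
is tested for exact agreement with a brute-force enumeration oracle on 1000
random instances.

## Inference

The inferential layer deliberately delegates to established routines behind a
stable surface: `t_test()` wraps Student/Welch tests (one-tailed directions
are configuration, mirroring preregistered predictions), `spearman_cor()`
wraps the midrank-based rank correlation, and `mixed_rm_anova()` fits the
balanced mixed design via the multivariate linear-model route (type-III,
sum-to-zero contrasts) and reports, per within effect, the Huynh–Feldt
epsilon (capped at 1; trivially 1 for two-level factors), the
epsilon-corrected degrees of freedom and p value, and partial eta squared
from the effect and error sums of squares. Degenerate inputs (zero variance
everywhere, constant samples) are reported as undefined results, not raised
as errors; incomplete designs fail loudly with the missing cells named. The
test suite cross-checks the ANOVA against the classical `aov()` error
stratification and a hand-coded Greenhouse–Geisser/Huynh–Feldt oracle.

No multiple-testing correction is applied anywhere, matching the analysis
this package mirrors.

### Type-I calibration

`calibrate_type1()` checks that the fixed-intensity group comparison rejects
at the nominal 5% under a null configuration. Per replicate it draws each
participant's correct count as Binomial(256, $p$) with $p$ from the
psychometric function at the 100% level — the exact distribution the
trial-level simulator induces on per-participant accuracy, by sufficiency —
then applies the two-tailed Welch test to the group means. At 10,000
replicates the empirical rate sits within half a point of 0.05.

## Problem sizes and reproducibility

The Monte-Carlo properties (staircase targeting and recovery) are evaluated
at 500 simulated sessions, which puts the standard error of the reported
accuracy near 0.06 percentage points and of the recovered threshold near
0.3 ML units; boundary medians use 200 sessions. All stochastic entry points
take an `rng_seed` and restore the caller's RNG state, so runs are
reproducible from a `run_config()` alone, and a config survives a JSON
round-trip bit-identically.

## Known limitations

* The staircase's maintained accuracy is intrinsically ~1.5–3 points below
  the nominal 75% (rule equilibrium plus grid discreteness); consumers of
  recovered thresholds should treat them as accurate to within half a grid
  step, not as unbiased estimates.
* The observer model is stationary; real listeners adapt, fatigue, and learn.
* Group-level inferential results on simulated cohorts reproduce the
  *structure* of the original analysis (which effects are tested, with which
  tests and corrections), not its empirical estimates, which came from human
  participants.
* WHOQOL-BREF scores are simulated on the 4–20 domain scale as a continuous
  quantity; real domain scores are coarser.
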