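---
title: "Variational free-energy analysis of stimulated neuronal cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variational free-energy analysis of stimulated neuronal cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vfemea)
```

## The problem

A cortical cell culture on an 8x8 multi-electrode array is stimulated once
per second at 32 fixed sites. The stimulation pattern is not arbitrary: two
hidden binary sources, each present or absent independently with
probability 1/2 in every epoch, drive the sites through a fixed likelihood.
Sites 1-16 (pool 1) fire with probability 3/4 under source 1 alone and 1/4
under source 2 alone; sites 17-32 (pool 2) have those probabilities
swapped; no site fires when both sources are absent and every site fires
when both are present. No input pattern ever repeats, so a network can only
develop source-selective responses by learning the mixing structure — a
discrete blind source separation problem.

`vfemea` implements the full analysis around this paradigm: the generative
protocol, an ideal Bayesian (active-inference) encoder, a synthetic
spike-count generator emulating the cultures, GLM/CVA detection of emerging
functional specialisation, and the mapping from detected specialisation to
empirical free energy in a variational information plane.

## The encoder model

The agent entertains a categorical posterior `Q(s) = Cat(s)` over the four
joint source states, ordered (0,0), (0,1), (1,0), (1,1), with a uniform
prior (the product of per-source Cat(0.5, 0.5) priors). Beliefs about the
likelihood mapping are Dirichlet, one concentration vector over the two
outcomes per (site, state) cell, initialised at one count per cell. Epochs
are exchangeable trials: state transitions are the identity and no
between-epoch smoothing is applied.

Per epoch the agent:

1. computes the expected log likelihood `E[ln A]` with digamma functions,
2. infers the joint state by a softmax over `ln D + sum_i lnA[i, o_i, ., .]`
   — the non-stimulated sites contribute their `o = 0` terms, because the
   absence of stimulation is informative under this mixing scheme,
3. increments the Dirichlet count of each observed outcome by the posterior
   state expectation (a Hebbian associative rule; exactly one unit of mass
   per site per epoch),
4. records the epoch free energy.

The same fixed point is reached by a neuronally interpretable relaxation:
the log expectation `v` moves along the prediction error
`eps = (ln D + lnA.o) - v` and the firing rate is `softmax(v)`. Defaults
(`step = 0.25`, `max_iter = 16`, `tol = 1e-8`) give stable convergence and
a within-epoch trace of plausible length; they are package choices, not
physiological constants, and `step = 1` reproduces one-step inference
exactly.

### Free-energy bookkeeping

`free_energy()` returns the decomposition in nats:

* inaccuracy `-s . lnA . o`,
* state complexity `s . ln s - s . ln D` (in `[0, ln 4]` under the uniform
  prior),
* parameter complexity, the KL divergence from the Dirichlet prior. The
  exact KL is the default; a truncated expression omitting the constant
  prior normaliser is also available (`param_form = "truncated"`), since
  either convention appears in discrete active-inference implementations.

One structural fact matters when reading learning curves: the parameter KL
grows without bound as counts accumulate (roughly logarithmically per
cell), so the three-term total rises over training even while inference
improves. Learning diagnostics therefore use the state-bound part,
inaccuracy plus state complexity, which is also the quantity tracked for
the empirical recordings (where parameter complexity is fixed by the
simulation and reported as zero). The per-epoch bound
`F >= -ln P(o)` — tight at the exact posterior — is checked by enumeration
over the four states in the test suite.

### Symmetry breaking and identifiability

Exactly symmetric initial counts are a fixed point of blind learning: the
posterior stays uniform and every update is distributed identically over
the four states. Default initial counts therefore carry a small uniform
jitter, `1 + U(0, 0.01)`, which stays above the unit prior and carries no
information about the true labelling. Which learned state adopts which true
state's role is decided by this jitter and the early stimuli: the four
states are exchangeable mixture components, so the learned likelihood is
identified only up to a permutation of the four states (of which a pure
source swap is a special case). `resolve_state_permutation()` aligns a
learned likelihood with a reference by best match over the 24 relabellings,
on the pool-averaged stimulation table — the natural resolution of the
protocol, since sites within a pool share a likelihood row and per-site
estimates carry binomial noise of about 0.04 at 512 epochs.

Like any mixture learner the agent occasionally settles in a poor local
optimum (roughly 1 run in 15 at 512 epochs). `run_training(restarts = n)`
runs several jitter initialisations and keeps the one with the lowest final
epoch-averaged state free energy — selection by the model's own objective,
blind to the ground truth.

## The synthetic recordings

`generate_recording()` emulates the evoked spike counts of the cultures.
The log rate of electrode `e` at epoch `t` is

    ln baseline_e + stim_gain_e * own_site_stim
      + sum_src gain_e,src * g(t) * 2 * (m_src,t - 0.5) + drift_e(t)

with Poisson counts at the resulting rate. The deviation term implements
the encoding assumption that firing-rate deviations from the mean are
proportional to the difference between posterior and flat-prior
expectations: a fully confident posterior maps to plus or minus the full
gain. In agent-driven mode `m` is the agent's (permutation-aligned)
marginal posterior and selectivity emerges as the agent's confidence grows;
in parametric mode `m` is the true source and a logistic curve `g(t)`
(midpoint mid-training, slope a tenth of the run) imposes the emergence.

Defaults are chosen as a plausible culture: baseline 5 counts per 1-s
epoch; own-site stimulation multiplies the rate by `e` (about 2.7, the
obligatory early response); 8 electrodes specialise for each source at gain
0.5 (roughly a 2.7-fold rate ratio between confident presence and absence)
with the remaining 48 null — specialisation that is distributed but
dominated by a few electrodes; slow drift as a 4-component random cosine
series with coefficient scale 0.1. What the generator deliberately omits:
spike waveforms, bursting, spontaneous inter-epoch activity, and any
nonstationarity beyond smooth drift. Passing tests on these data show the
pipeline's statistics behave correctly under the model's own assumptions;
they cannot certify robustness to biological structure the generator does
not contain (sharp state changes, electrode dropout, non-Poisson
dispersion).

Multiplicative drift also modulates the specialisation contrast itself (the
GLM removes additive drift only), so fitted specialisation can genuinely
sag late in a run — worth remembering when reading posterior traces near
the end of training.

## Detecting specialisation

For each electrode and tested source the design contains 8 interactions
between orthonormal DCT-II time columns (including the constant) and the
centred source-presence indicator; confounds are the electrode's own-site
stimulation indicator, the per-epoch total stimulation count, 32
non-constant DCT drift columns, the other source's centred main effect, and
the intercept. Using the own-site indicator plus the total count — rather
than all 32 site indicators — is the critical identifiability choice: the
full set of site indicators would reconstruct the source indicators through
the mixing scheme and absorb the effect of interest. Centring makes the
interaction partition orthogonal to the intercept.

The partial F statistic tests the interaction partition against the
confound-only model (it matches `anova()` on the nested pair to machine
precision in the tests); maps place F values at grid coordinates. P-values
come from the central F distribution with no correction across electrodes —
the output is a map, not corrected inference. F values scale with the
number of epochs, so the threshold-selection default of 80 is calibrated
for full-length (25,600-epoch) experiments and exposed as a parameter.

Three data features summarise a recording: the max-F electrode, the mean
over electrodes exceeding the threshold (refitted), and the principal
canonical variate. The CVA removes confounds from both sides, truncates
small singular directions of the response covariance (a spectral ridge),
and tests the canonical correlations with Bartlett's chi-squared
approximation, with degrees of freedom corrected for the confounds removed.
The variate's sign is arbitrary and is oriented so fitted specialisation
peaks positive. The surrogate control permutes each source train
independently — marginals preserved exactly, alignment destroyed — and is
applied at the analysis stage, as for the real recordings.

## Mapping responses to beliefs and free energy

The fitted specialisation (present-minus-absent predicted response) is
rescaled to posterior expectations: the 95th percentile of the curve over
the last quarter of training anchors posterior 1 (robust to transient
overshoot), zero specialisation maps to the flat prior 0.5, and marginals
are clipped to `[1e-3, 1 - 1e-3]` so `ln s` stays finite. At each epoch
the belief deviates towards presence when the source was in fact present
and towards absence otherwise. For a curve with no positive late signal
(surrogate fits), the absolute fluctuation magnitude anchors the scale, so
null beliefs wobble around 0.5 rather than failing. The joint is the
product of the two marginals — a mean-field choice, since each source's
encoding is estimated by a separate GLM.

Learning progress is the monotone envelope (running maximum) of the
absolute specialisation curve; the empirical envelope is regressed on the
(resampled) simulated envelope and 512 equally spaced empirical epochs are
matched to the simulation epoch of nearest progress, ties towards the
earlier epoch. Whether selected epochs should respect session boundaries is
not obvious; selection here is uniform over all epochs. The matched
simulation epoch supplies the Dirichlet counts — relabelled by the resolved
state permutation, since the simulation's private state labels must agree
with the empirical labelling before `s . lnA . o` is meaningful.

Empirical free energy per selected epoch is then
`-s . lnA . o + s . ln s + ln 4`, with parameter complexity omitted (it is
fixed by the simulation). A 32-epoch moving average (valid region only)
gives the smoothed trajectories and the information plane of accuracy
against complexity; a drop of 3 nats corresponds to an evidence odds factor
of `exp(3)`, about 20 to 1.

## A worked run

```{r closed-loop, eval = FALSE}
cfg <- run_config(seed = 1, n_sessions = 8, epochs_per_session = 256,
                  sim_epochs = 512)
man <- run_pipeline(cfg, outdir = "vfemea_run")
man
fe <- man$results$free_energy$true$free_energy
mean(fe$F[fe$epoch <= 256]) - mean(fe$F[fe$epoch > 1792])
```

The defaults of `run_config()` reproduce the full protocol (100 sessions of
256 one-second epochs, a 512-epoch analysis simulation, 512 selected
epochs, 32-epoch smoothing). The examples above, the test suite and the
acceptance script run scaled-down designs — typically 4-8 sessions of 256
epochs, 500 null electrodes for calibration, 10 replicate seeds for trend
properties — which keep every statistic well-identified while a full run
remains a single-command option.

## Numerical and design notes

* Randomness: one user seed is expanded into independent per-purpose
  streams (sources, stimuli, site map, agent initialisation, recording
  noise, surrogate permutation), so redrawing one component does not shift
  the others; the caller's RNG state is never touched.
* Exact zeros in a known likelihood enter inference as `-Inf` log
  probabilities: softmax uses max-subtraction, the relaxation clamps
  excluded states, and `0 * ln 0 = 0` throughout. Agent-side expected log
  likelihoods never reach `-Inf` because Dirichlet counts stay positive.
* Degenerate inputs: constant (zero-range) specialisation curves, constant
  responses, empty threshold selections and rank-deficient designs are
  flagged or raised explicitly rather than propagated.
* The pipeline treats the threshold-selection fallback (no electrode passes)
  by reverting to the max-F electrode so the null branch remains
  computable.

## Limitations

The analysis assumes the culture's code is read out at the epoch scale from
evoked counts; sub-epoch dynamics are only represented by the simulated
relaxation traces. Blind recovery is only defined up to state relabelling,
and the mapping of sub-asymptotic specialisation to probabilities rests on
a declared anchoring rule — alternatives (e.g. logistic calibration) would
change the absolute but not the qualitative free-energy trajectories.
Cross-culture inference beyond averaging is out of scope.
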