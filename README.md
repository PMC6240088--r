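# vfemea

Variational free-energy analysis of multi-electrode array learning
experiments.

## The scientific problem

Cortical cell cultures on an 8×8 microelectrode array receive one
stimulation pattern per second at 32 fixed sites. The patterns are
stochastic mixtures of two hidden binary sources s₁, s₂ ~ Bernoulli(1/2):
sites 1–16 fire with probability 3/4 under source 1 alone and 1/4 under
source 2 alone, sites 17–32 with those probabilities swapped, never when
both sources are absent and always when both are present. Because no
pattern repeats, a network can only respond selectively to a *source* by
learning the mixing — discrete blind source separation.

`vfemea` is for researchers who want to ask whether such recordings are
consistent with Bayesian learning. It provides:

- **the generative protocol** (`sample_sources`, `true_likelihood`,
  `sample_stimuli`, `assign_sites`), sessions of 256 one-second epochs;
- **an ideal Bayesian encoder**: a discrete-state agent with categorical
  posterior **s** over the 4 joint states and Dirichlet beliefs Dir(**a**)
  over the likelihood **A**, updated per epoch by

  - inference  **s**ₜ = σ(ln **D** + ln **A**·oₜ)  (softmax; the
    neuronal form relaxes v along the prediction error ε = ln **D** +
    ln **A**·oₜ − v),
  - learning  **a**ₜ = **a**ₜ₋₁ + oₜ ⊗ **s**ₜ  (Hebbian count
    accumulation),
  - free energy  F = −**s**·ln **A**·oₜ + **s**·ln **s** − **s**·ln **D**
    + KL[Dir(**a**) ‖ Dir(a₀)] ≥ −ln P(oₜ), in nats;

- **a synthetic spike-count generator** emulating the cultures (Poisson
  counts, log link: baseline, obligatory stimulation-evoked response, slow
  cosine drift, and source-selective deviations proportional to posterior
  minus flat-prior expectations);
- **specialisation detection**: per-electrode GLMs whose effects of
  interest are interactions between 8 DCT time components and the centred
  source indicator, with stimulation, 32 DCT drift components and the
  other source as confounds; partial F statistics, 8×8 F maps, selection by
  max-F / threshold-mean / canonical variates, and surrogate (permuted)
  source controls;
- **free-energy mapping**: fitted specialisation rescaled to posterior
  expectations, empirical and simulated learning curves matched by least
  squares on their monotone envelopes, empirical free energy
  F = −**s**·ln **A**·o + **s**·ln **s** + ln 4 at 512 equally spaced
  epochs, smoothed over 32 epochs, and trajectories in the variational
  information plane (accuracy vs complexity; 3 nats ≙ exp(3) ≈ 20:1
  evidence odds).

## Worked example

Blind learning on 512 epochs of protocol stimuli:

```r
library(vfemea)
src  <- sample_sources(8, 256, seed = 1)
stim <- sample_stimuli(src, true_likelihood(), seed = 1)
run  <- run_training(stim, n_epochs = 512, restarts = 3)
run
#> agent_run: 512 epochs
#>   mean state free energy, first 64 epochs: 17.32 nats; last 64: 10.75 nats
rp <- resolve_state_permutation(run$a)   # labels fixed only up to relabelling
round(rp$error, 3)
#> [1] 0.021
```

The epoch-averaged state free energy falls from 17.3 to 10.8 nats as the
agent learns, and the relabelled pool-averaged likelihood table reproduces
the protocol's (0, 1/4, 3/4, 1) mixing probabilities within 0.021.

The full closed loop — simulate, encode, record, detect, free-energy map,
with true and surrogate sources — is one call:

```r
cfg <- run_config(seed = 1, n_sessions = 8, epochs_per_session = 256,
                  sim_epochs = 512)
man <- run_pipeline(cfg, outdir = "vfemea_run")
man$results$detection$true$per_source[[1]]$analysis
#> specialisation_analysis (source 1): max F = 46.3 at electrode 3; ...
fe <- man$results$free_energy$true$free_energy
mean(fe$F[fe$epoch <= 256]) - mean(fe$F[fe$epoch > 1792])
#> [1] 13.15902
```

The most significant electrode is one of the synthetically specialised
ones, and the empirical free energy of the first session exceeds that of
the last by about 13 nats; on the surrogate branch no decrease occurs. All
tables are written as TSV/CSV next to a JSON manifest; figures (F map,
selective responses, smoothed free energy, information plane) mirror
machine-readable files.

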