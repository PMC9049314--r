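---
title: "Inferring subclonal selection from tumour VAF distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring subclonal selection from tumour VAF distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vafevo)
```

## The problem

A bulk-sequenced tumour biopsy yields, for every somatic point mutation, an
alternate read count and a total depth: a variant allele frequency (VAF). In
copy-neutral diploid regions of a pure tumour, mutations present in every
tumour cell (clonal) cluster near 50% VAF; neutral passenger mutations that
accumulated during growth form a low-frequency power-law ("1/f") tail; and a
subclone — a subpopulation with a growth-rate advantage — appears as an
additional peak at intermediate frequency. `vafevo` asks the inverse
question: given one noisy VAF distribution, is there ongoing positive
selection, how many detectable subclones are there (0, 1 or 2), and at what
frequencies?

The approach is synthetic supervised learning (amortized simulation-based
inference): simulate tumours whose evolutionary ground truth is known,
corrupt them with a realistic sequencing-noise model, train neural networks
to invert the mapping, and then apply the trained networks to real samples
in a single fast forward pass, with Monte Carlo dropout providing
approximate posteriors.

## Generative models

### Stochastic selection simulator

`simulate_tumour()` grows a population from one founder cell to `n_final`
cells under a rejection-kinetic branching process: a random cell is sampled,
accepted with probability proportional to its birth rate, and divides (or
dies, when a death rate is set). Each daughter draws `Poisson(mu)` new
mutations; with probability `p_driver` a mutation is a driver, receives
`s ~ Exponential(s_mean)` and multiplies the lineage's growth rate by
`(1 + s)` — fitness is multiplicative across drivers, and driver arrival is
fully stochastic (capped at `max_drivers = 3` events). Cells reference
genotypes (a genotype stores the mutations created at one division event),
so memory scales with division events rather than cells x mutations. Both
daughters mutate independently, which fixes the expected mutation yield at
`2 mu (N - 1)` — a convention the tests verify directly.

Detectable subclones are driver lineages whose VAF (cellular fraction / 2)
falls in 10–40% (cellular fraction 20–80%): below ~10% VAF a subclone merges
with the neutral tail, above ~40% with the clonal cluster. Lineages closer
than 5% VAF are merged; simulations with more than two detectable subclones
are flagged unusable for the 0/1/2 label scheme and regenerated during
paired data generation. Whether nested driver lineages count separately is
decided by VAF separation alone (maximal distinct-VAF lineages subject to
the merge gap).

The population size defaults to `N = 1000`, birth rate `log(2)`, death rate
0: the VAF distribution carries no information about absolute population
size, and a small `N` with a fixed growth rate makes desk-scale generation
of tens of thousands of simulations feasible. Downstream fitness and time
estimates are rescaled to realistic sizes by `rescale_estimates()`.

### Generative neutral sampler

Stochastic neutral simulations occasionally produce late drift peaks that
look like subclones, which would mislabel the training data. Neutral tumours
are therefore sampled generatively (`generate_neutral()`): the tail is drawn
from a Pareto distribution (shape `alpha`, scale `m`; draws above 0.5
resampled), clonal mutations are added as a point mass, and all dispersion
comes from the biopsy noise model. Two perturbations emulate features of
patient data: with probability `p_trim <= 0.1` the tail below a random
frequency in 10–30% VAF is removed (many real samples lack a clean tail),
and the clonal centre is shifted uniformly into 45–50% VAF (emulating
mild purity mis-estimation). Trimming applies to the tail only; the clonal
cluster is untouched.

The empirical table of patient-fitted Pareto shapes used in the original
study is not redistributable, so the packaged default samples
`alpha ~ lognormal(median 1, sdlog 0.35)` truncated to `[0.5, 3]` — centred
on the theoretical neutral exponent — and a user-supplied sampler can be
passed to `generate_pair()`. The scale is set to the minimum observed
frequency of the paired selection arm, which is also the Pareto maximum
likelihood estimate.

### Pairing

`generate_pair()` couples each selection simulation with a neutral
realization carrying the same clonal count, the same total mutation count,
and the identical sequencing parameters. Pairing prevents the classifier
from keying on nuisance statistics (mutation load, depth) that differ
between the two generators; the tests assert count conservation on every
pair.

### Virtual biopsy

Per mutation with true frequency `f`: depth `D_obs ~ Binomial(N, D/N)`
(mean exactly `D`), alternate reads
`R_obs ~ BetaBinomial(D_obs, f * purity, rho)`, `VAF_obs = R_obs / D_obs`,
and records with fewer than `min_alt_reads = 2` alternate reads are dropped
(the caller's detection limit; the threshold is configurable and recorded).
The beta-binomial uses the intraclass parameterization
(`a = p(1-rho)/rho`, `b = (1-p)(1-rho)/rho`), so
`Var = n p (1-p) (1 + (n-1) rho)` and `rho = 0` is exactly binomial —
stated explicitly because `rho` conventions differ between packages.
Purity acts as frequency dilution before read sampling (normal cells
contribute reference reads only).

Mutations below 0.8% true VAF are not tracked in the large generated sets
(`min_cells` floor): at 50–250x depth they cannot reach the featurization
range (see below), and dropping them bounds the per-simulation mutation
count at high mutation rates.

## Features

`featurize()` counts mutations into fixed-range histograms over 2–50% VAF at
two resolutions (k = 64 and k = 128; widths 0.0075 and 0.00375),
concatenated into a length-192 vector. A depth-conditioned lower cutoff,
`f_alt + 2 sqrt(f_alt (1 - f_alt) / c)` with `f_alt = min_alt_reads / c`
and `c` the mean depth, excludes mutations whose observed frequency is
within two binomial standard deviations of the calling limit; this
implicitly conditions the network on sequencing depth. Histograms are raw
counts by default (a density-normalized mode exists behind a flag; trained
checkpoints record which was used). Networks additionally standardize each
histogram bin (log1p scale) with statistics estimated from their training
set and stored in the checkpoint — a pure optimization device that is part
of the model, not of the features.

`tajimas_d()` and `fay_wu_h()` provide tumour-adapted site-frequency
statistics for comparison work: VAFs are treated as derived-allele
frequencies (the reference allele is ancestral, so no folding), and the
effective sample size is `n = round(mean depth)`. These conventions are this
package's; both statistics return 0 with a degenerate flag when no sites
segregate.

## Networks, training, uncertainty

Three multi-task models share one architecture family (`model_spec()`): two
parallel 1D convolutional trunks — one per histogram resolution, merged
before the task branches — with Hardswish activations, dropout probability
0.5 after every hidden layer, and fully connected (or global-average-pooled)
task branches. `M_ms` classifies P(Selection) (sigmoid, binary cross-entropy
with a configurable false-positive penalty) and P(0/1/2 subclones)
(softmax); `M_1s` and `M_2s` regress one and two subclone frequencies under
the L1 loss. The search space (1–20 conv layers, 4–32 channels, odd kernels
1–17, branch type) is validated; the packaged default — 2 conv layers of 8
channels, kernel 5, flatten + 64-unit branches — is a deliberate small
deterministic choice, since the original architecture is known only as a
search space. The engine (im2col convolutions, hand-written backprop, Adam)
is implemented in the package; parameter counts are closed-form testable.

Training (`train()`) uses Adam (learning rate at most 1e-3), minibatches of
256, a held-out validation split with early stopping (patience 3–5; a
warm-up of 10 epochs prevents transient early plateaus from triggering the
stop), a step learning-rate decay (30% of the base rate over the final
third of the budget, damping late oscillation under the L1 loss), and
restores the best-validation weights. The frequency regressors train only
on the positive-selection subset — roughly a quarter of a paired pool — so
`train_evolution_models()` gives them more epochs to equalize the
gradient-step budget across models. The `rebalance()` operation
equalizes subclone-frequency strata (two-decimal bins; two-subclone
simulations balanced on inter-subclone distance and filtered to gaps above
5% VAF) by downsampling to the minimum stratum. At desk scale
(`train_evolution_models()`, 25 000 paired simulations) rebalancing is off
by default: with a static pool the minimum-stratum rule discards most
positive simulations every epoch, and the stochastic-arrival generator
already spreads frequencies broadly. An epoch is one pass over the static
set; 14 epochs for the classifier (up to 60 for the regressors, whose pool
is smaller) give a gradient-step budget comparable to streaming training
over much larger stores. Each frequency regressor is trained twice from
independent initializations and the run with the lower validation loss is
kept — a miniature of the random-search model selection used at full
scale, which protects against occasional poor initializations.

`mc_predict()` keeps dropout active and makes `T = 50` stochastic passes;
each output's draws form an approximate posterior summarized by its mean and
89% equal-tailed interval (empirical 5.5%/94.5% quantiles).
`call_evolution()` applies the parsimony rule: selection only if the ETI
lower bound of P(Selection) exceeds 0.5, otherwise neutral with zero
subclones regardless of the subclone head; under selection the subclone
number is the class whose ETI lower bound exceeds 0.5, falling back to the
larger of the class means (ties toward fewer subclones) — the fallback is
this package's choice where the decision rule is otherwise silent.

## Real-sample post-processing

`purity_correct()` divides VAFs by purity. Because purity estimates are
themselves imperfect, `clonal_peak_adjust()` finds density peaks (Gaussian
kernel, Silverman bandwidth, 512-point grid on [0.05, 1.0]; peaks are local
maxima of the numerically differentiated density) and, if the peak closest
to 0.5 lies above 35% VAF, rescales all VAFs by `0.5 / mean` of a Gaussian
fitted to the mutations within 0.1 VAF of the peak (the plain mean is the
Gaussian MLE; the membership window and the higher-VAF tie-break at
equidistant peaks are package choices). Peaks at or below 35% are left
alone — a genuine clonal cluster must exist because tumours initiate from
already-mutated cells.

`heuristic_cluster()` assigns every mutation outward from the estimated
subclone frequencies using binomial-variance windows
`q ± eps * sqrt(q (1 - q) / c)` with `eps = 2`: above the top window is
clonal, below the lowest is tail, overlapping subclone windows split at the
midpoint; with no subclones the clonal window `0.5 ± eps * sqrt(0.25 / c)`
separates clonal from tail. An optional Gaussian-mixture refinement seeded
at the estimated frequencies sits behind a flag.

Sample inclusion follows the study filters: at least 100 mutations and at
least 60x mean effective coverage (purity x depth); `run_estimate()` warns
by default and refuses under `strict = TRUE`, so marginal samples can still
be inspected.

`tumour_age()` and `rescale_estimates()` map simulated-scale estimates to a
realistic tumour size (`N_real = 1e10` by default):
`t_s^R = t_s log(N_real)/log(N_sim)`, `t_end = log2((1 - f_sub) N)`, and
`w_R = 1 + (w - 1)(t_end - t_s)/(t_end^R - t_s^R)`.

## Transfer learning

The deterministic-subclone simulator (`simulate_deterministic()`; birth 1,
death 0.2, `N = 1e4`, 500 clonal mutations) initiates a single subclone in a
random cell when the population first reaches `2^t_s` cells and multiplies
its net growth rate by the fitness; emergence time is measured in tumour
doublings (log2 of population size at initiation), which makes it compose
with `rescale_estimates()`. Only a band of (fitness, t_s) combinations
yields detectable subclones, so `viable_param_sampler()` fits a noisy
Gaussian-process regression of viable emergence time on fitness (RBF kernel
with length scale 100 on the raw fitness scale, plus dot-product and
white-noise kernels, jitter 1e-6 — the composite GP is implemented in
closed form in the package) and samples emergence times with the predictive
noise retained, deliberately spilling over the whole detectable range.

`renovate()` performs open-set domain adaptation: the convolutional trunks
of the trained `M_ms` and `M_1s` are kept verbatim and concatenated, the
old branches are discarded, and four new fully connected branches predict
mutation rate, subclone fitness, emergence time, and cellular fraction
(subclone VAF x 2). Fine-tuning (`finetune()`) minimizes the L1 loss on
standardized targets — mutation rate and fitness are regressed on the log
scale, aligning the L1 loss with relative error for these positive
ratio-scale quantities — and subclonal tasks contribute only on
simulations whose subclone survived. Trunk weights train at a 10x reduced learning rate by
default (freezing is a flag) — the original procedure does not say whether
trunks were frozen, and a reduced rate preserves transferred structure while
allowing adaptation. At prediction time dropout is active only on the new
branches (`predict_transfer()`, default `T = 500` for single samples; bulk
evaluations use fewer passes). A degree-2 polynomial ridge map fitted on
1000 calibration simulations (`calibrate_mu()`) corrects the systematic
bias in raw mutation-rate outputs and is stored with the checkpoint.

## Study conditions at desk scale

The packaged defaults define the simulated conditions used by the tests and
the acceptance script:

* Primary paired sets: mutation rate U(5, 100) per genome per division,
  driver probability log-uniform 10^-4.5–10^-2.5, exponential
  selection-coefficient mean U(0.5, 2), clonal count U(100, 500),
  `N = 1000`; depth U(100, 150), `rho` U(0, 0.003), purity 1. 12 500
  training pairs (25 000 simulations), 2 000 held-out pairs.
* Purity-robustness grid: depth U(20, 200), `rho = 0.03`, purity
  U(0.2, 1), ±25% multiplicative error on the purity estimate; false
  positive rate assessed on neutral samples with effective depth >= 40x.
* Transfer sets: mutation rate U(5, 50), depth U(75, 200), `rho = 0.001`,
  70% of training simulations with a subclone; 25 000 fine-tuning, 1 000
  calibration and 5 000+ evaluation simulations, evaluated on detectable
  subclones (cellular fraction 20–80%).

Mutation-rate ranges are bounded above at desk scale (hypermutator regimes
with thousands of mutations per division would dominate runtime without
changing the method); the vignette's parameter choices were fixed before
the evaluation runs and are not tuned to them.

## What the synthetic data does not capture

The generators emulate diploid heterozygous SNVs only: no copy-number
events, no spatial structure, no site-specific depth profiles from real
BAMs, no mapping or base-quality error, and physical time is never
calibrated (only division counts and doublings). Passing tests therefore
demonstrate internal consistency of the method under its own generative
assumptions and noise model — evidence that the inference machinery works,
not that any particular real tumour satisfies those assumptions. On real
data the diploid restriction, purity estimates and consensus copy-number
calls dominate the error budget.

## Numerical choices and degenerate inputs

* Pareto draws above 0.5 are resampled, never clipped.
* `rho = 0` uses the exact binomial path; `p` of 0 or 1 short-circuits the
  beta draw.
* Histogram edges: the range is [0.02, 0.50) with the top edge inclusive,
  so a mutation at exactly 0.5 lands in the top bin and the histogram total
  always equals the retained-mutation count.
* Tajima's D and Fay & Wu's H return 0 with a `degenerate` flag when S = 0.
* Early stopping compares validation loss with a 1e-6 improvement margin;
  NaN loss aborts with a diagnostic rather than continuing.
* `call_evolution()` ties break toward fewer subclones (parsimony).
* Extinction in birth-death simulations retries up to 100 times before
  erroring; a subclone that drifts out is a flagged outcome, not an error.
* All stochastic entry points take explicit seeds; fixed seeds give
  bit-identical simulations, training runs and MC draws.
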