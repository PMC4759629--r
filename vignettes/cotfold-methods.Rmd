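---
title: "Modelling co-translational folding kinetics with cotfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling co-translational folding kinetics with cotfold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cotfold)
```

## The model

`cotfold` predicts whether, and when, a protein domain folds while it is
still being synthesized by the ribosome. The model couples two elementary
processes:

* **Translation elongation.** The ribosome dwells at codon `i` for an
  exponentially distributed time with mean `1/k_A,i` (amino acids per
  second). A `translation_schedule` holds the position-resolved rates and
  their cumulative mean times; `uniform_schedule()` expresses the common
  simplification that every codon translates at the cell's average rate
  (3.9 AA/s is the value measured for SFVP synthesis in CHO cells).
* **Two-state folding.** The domain of interest interconverts between
  unfolded and folded states with rates `k_F` and `k_U`, with no
  intermediates. While the nascent chain is shorter than the *folding
  onset* — the domain's last residue plus the exit-tunnel linker
  (`tunnel_length`, default 30 residues, within the 24–40 residue range
  reported experimentally) — both rates are zero; from the onset onward,
  and after release, the bulk rates apply. `build_kinetics()` expands a
  `construct()` into this two-regime rate profile.

Three views of the coupled system are provided.

**Steady-state folding-versus-length profile.** Under steady-state
translation the probability that a chain is folded at the moment it
elongates away from codon `i` obeys

    P(i) = P_eq,i + (P(i-1) - P_eq,i) * lambda_i,
    lambda_i = k_A,i / (k_A,i + k_F,i + k_U,i),

with `P(0) = 0` and `P(i) = P(i-1)` below the onset. This is the exact
two-state solution averaged over the exponential dwell. The value at the
stop codon, `P_F,Co-T`, classifies the domain: co-translational folder if
`P_F,Co-T >= 0.5` (inclusive), post-translational otherwise. Because the
stationary age of an exponential dwell is itself exponential, the
departure-time value coincides with the population-snapshot value that a
folding-versus-length assay measures; the alternative `average =
"residence"` reports the time-average over the dwell, for which
`(k_A/k) log(1 + k/k_A)` replaces `lambda_i`. The two conventions share a
plateau and differ only in the relaxation zone; both are exposed because
the literature does not fix the convention.

**Pulse-chase curve.** A radiolabelling experiment sees only chains that
incorporated label during the incorporation window `[delay, pulse +
delay)` (the `delay`, default 10 s, is the time label needs to be taken
up and charged onto tRNA; it shifts both edges of the window).
`predict_pulse_chase()` represents the steady-state initiation flux by a
dense grid of cohorts, one per initiation time. Each cohort's mean-field
trajectory fixes its residue-incorporation instants (bond formation at
the end of the dwell), hence whether and when it is labelled; its folding
probability is the *exact expectation over stochastic dwell histories*:
the arrival time at the onset codon is the sum of the first `onset - 1`
exponential dwells — a Gamma variable for uniform schedules, represented
by a moment-matched Gamma for variable ones — after which the two-state
relaxation toward `P_eq = k_F/(k_F + k_U)` proceeds with rate
`k_F + k_U`, unchanged by release. The reported curve is the mean over
labelled cohorts visible at each report time, i.e. a convex combination
of probabilities, on the chase-shifted axis (chase start = 0).

We initially placed each cohort's onset crossing at its mean arrival
time, as a pure mean-field treatment suggests; validation against the
stochastic simulator showed a systematic 0.015 dip at the plateau corner
(the arrival time of SFVP ΔC has a ~3.5 s standard deviation), so the
dispersion-averaged form above is the default and `dispersion = "none"`
retains the sharp-corner variant for comparison.

**Stochastic ground truth.** `simulate_pulse_chase_stochastic()` is an
event-driven Gillespie simulation of independent ribosome–nascent-chain
complexes: stochastic dwells (single-exponential, or the hypoexponential
pre/post-translocation model with base rates `k1 = 4.7363` and
`k2 = 22.0649` s⁻¹, per-codon rescaled at a fixed `k2/k1` ratio so every
codon keeps its schedule mean), per-residue label bookkeeping, folding
jumps, and the labelled-molecule estimator
`P_F(t) = (1/N(t)) Σ δ_t(i)`. It is the arbiter for every deterministic
result.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `k_F`, `k_U` | s⁻¹ | construct-specific | bulk folding/unfolding rates; the only folding inputs |
| `k_A` | AA s⁻¹ | 3.9 | measured average translation rate in CHO cells |
| `tunnel_length` | residues | 30 | back-derived from the four characterized constructs; 20/40 for sensitivity runs |
| `pulse`, `chase`, `delay` | s | 45, 360, 10 | the published experimental protocol |
| `dt` | s | 0.1 | cohort seeding density and report resolution only — folding relaxation is integrated exactly, so halving `dt` moves the curve by < 10⁻³ |
| `stop_default_time` | s | 0.256 | stop-codon dwell when a rate table lacks stop codons (the measured average codon time) |
| Gillespie `k_init` | s⁻¹ | schedule mean rate | with one pre-existing ribosome per length, the steady-state flux through each codon equals `k_A`; any other initiation rate would break steady state at time zero |
| Gillespie `replicates` | — | 20 | the published virtual-experiment design |

Numerical choices: time↔rate conversions are exact reciprocals; the
scaling factor χ uses the *arithmetic* mean of rates over the reference
CDS (the published convention, retained for compatibility even though
the harmonic mean governs synthesis time, so fallback values and the
stop default are rescaled by the same χ to keep the achieved mean
exact); recoding ties break to the lexicographically smallest codon;
missing sense codons default to the table mean (the occupancy-1.000
convention), with an `"error"` policy for strict use; the `> 50` residue
rule for contiguous domain segments is strict, with an inclusive flag;
DNA and RNA alphabets are both accepted and normalized to RNA
internally.

## Statistics for folding-versus-length signals

`compare_regions()` splits a per-codon signal into a baseline Region I
(first 50 codons, inside the tunnel), an expected-unfolded Region II and
an expected-folded Region III, and compares them pairwise with a
two-sided Mann–Whitney U test. Because such signals carry heavy ties at
zero, the p-value is computed by exhaustive enumeration of the
permutation distribution whenever `choose(n1 + n2, min)` is at most
5 × 10⁵ (enumeration at the literal 20 + 20 boundary would need ~10¹¹
subsets, so the cut is placed by enumerable work, not by sample size),
and otherwise by the normal approximation with midranks, tie correction
and continuity correction. Median confidence intervals use the
percentile bootstrap (100 000 replications by default; `bootstrap_n = 0`
skips them). Under a constant-plus-noise null the I-vs-II rejection rate
is ~0.05–0.06 at α = 0.05.

## What the synthetic generator emulates

`generate_fixture()` builds fully synthetic bundles: a log-normal codon
time table (64 codons, median 0.25 s), a random CDS, and a construct in
one of three timescale regimes — `fast_folder` (`P_F,Co-T > 0.95`),
`slow_folder` (`< 0.05`) and `marginal`. Marginality requires folding
and elongation to compete *over the post-onset tail*: with `k_F` within
10× of the mean `k_A`, a long tail always saturates the profile at
`P_eq`, so the generator also draws a short tail (2–5 codons) and
rejection-samples until `0.05 < P_F,Co-T < 0.95`. This is what makes the
recoding experiment meaningful: substituting every codon by its slowest
synonym can only slow translation (a monotone slowdown), never decrease
`P_F,Co-T`, and for fixtures just below 0.5 it flips the classification
from post- to co-translational — typically a handful of flips per 100
marginal fixtures.

What the fixtures do **not** emulate: codon-usage correlation along real
transcripts, ribosome traffic (collisions are deliberately outside the
model), folding intermediates, chaperone action beyond an effective
`k_F` rescaling, and the heteroscedastic noise of real
folding-versus-length data. Passing tests on fixtures therefore
demonstrate internal consistency of the kinetic machinery, not accuracy
on any particular real protein.

## Validation strategy and problem sizes

The test suite checks every closed-form claim against independent
oracles: a brute-force per-codon stochastic integrator for the
steady-state recursion (M ≤ 40, 4000 chains); the Gillespie simulator
against the deterministic pulse-chase engine for SFVP ΔC (20 replicates,
~6300 labelled molecules, agreement within 3 standard errors of the mean
at every report second — the replicate SEM is floored by the pooled
binomial standard error, since it is exactly zero wherever every
molecule is folded); pair-counting permutation enumeration for the
rank-sum test; and the Biostrings genetic code for recoding. Single- and
two-exponential dwell models agree to ≲ 0.016 sup-norm at matched means.
These sizes keep the default suite under a minute on one core while
leaving Monte-Carlo error well below every asserted tolerance.

## Known limitations

* Two-state folding only; domains with populated intermediates or
  misfolded states are outside the model.
* No ribosome–ribosome exclusion: complexes are simulated independently.
* The labelling bookkeeping in the deterministic engine is mean-field
  (label times at mean incorporation instants); the residual difference
  from the stochastic truth is below ~0.005 and is absorbed by the
  oracle comparison.
* The sinusoidal initiation option reproduces the sequential-draw
  sampling of the original virtual experiment, which is only
  approximately a non-homogeneous Poisson process; exact thinning is
  available behind `thinning = TRUE`.
* Folding-rate inputs are taken as given; predicting `k_F`/`k_U` from
  sequence or structure is out of scope.
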