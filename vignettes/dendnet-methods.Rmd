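---
title: "Methods: dendritic classification by structural plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dendritic classification by structural plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendnet)
```

## The model

A class is scored by a pair of dendritic trees. Each tree has `m` dendrites
carrying exactly `k` synaptic contacts drawn from `d` binary input
afferents; the contact counts are the only "weights" in the model, stored
as an `m x d` integer matrix whose rows sum to `k`. A dendrite `j` sees the
synaptic drive `z_j = sum_i w_ij x_i` and emits

    b(z_j) = g(z_j - z_leak_j) * (z_j - z_leak_j)^2

with `g` a Heaviside step that we take to be *inactive at the boundary*
(`g(0) = 0`), following the convention that the branch fires only when its
drive strictly exceeds the leak. `z_leak_j` is the mean drive of the
branch's initial random wiring over the training set, computed once by
`set_leak()` and frozen; it balances excitation per branch the way a tonic
inhibitory pool would, and newly grown dendrites receive their own leak
from their own initial wiring. The class score is the difference of the
excitatory and inhibitory tree outputs, and the classifier decision is
winner-take-all (WTA) over class scores. WTA ties resolve to the lowest
class index, deterministically, so that every run is reproducible.

Two readouts coexist. At test time the decision is the hard argmax. During
training the two relevant score components pass through a soft margin
function `g_margin(alpha)` that ramps linearly from 0 at `alpha <= -delta`
to 1 at `alpha >= delta`; at `delta = 0` it degenerates to a hard threshold
with value 0.5 at a tie, which makes exact ties count as errors — a useful
property, because a tied pattern is genuinely unresolved. The per-class
margins `delta` are calibrated after a first hard-readout training pass:
validation patterns of class `mu` that lose to a class `nu` contribute
their score deficit `o_nu - o_mu`, and `delta_mu` is the largest such
deficit (0 for classes with no validation errors). While the margin phase
trains, revisiting the same local minimum five times in a row shrinks all
margins to 80% of their value.

The rate model applies the same dendritic nonlinearity (including the
leak) as the spiking model; the two differ only in whether the drive is a
binary vector or a time-resolved current.

## The learning rule

Learning rewires. For each tree, a correlation map

    c_ij = < x_i * b_j(x) * sgn(y_d - y) >

(averaged over the batch, negated for the inhibitory tree) scores every
(dendrite, afferent) slot; `y` is the margin readout and `y_d` the one-hot
teacher. One iteration visits every tree in fixed order (classes
ascending, positive tree before negative) and performs one replacement
attempt: sample `n_T` active contacts uniformly (counting multiplicity),
target the one with the lowest correlation, place `n_R` silent candidate
synapses on its dendrite (uniform over afferents, without replacement
within a set), and move the contact to the candidate with the highest
correlation. Silent candidates never contribute to the classifier output,
and because `b_j` is computed from active contacts only, the same
correlation map scores active and silent synapses alike. A swap is kept if
the margin-metric training error does not increase; otherwise it is
reverted. After `n_ch = 50` consecutive rejections on a tree the loop
declares a local minimum, checkpoints the best state seen, and forces the
last candidate swap through to escape. Training stops on memorization or
after `n_min = 150` local minima, returning the best checkpoint.

Defaults follow the model's standard operating point: `n_T = 25`,
`n_R = 25`, `n_ch = 50`, `n_min = 150`. Two genuinely open readings of the procedure were resolved as follows: the error used inside
accept/reject comparisons is the margin-metric error (the readout the rule
itself prescribes), while reported errors use the hard argmax; and one
iteration makes one attempt per tree rather than one global attempt, which
spreads rewiring evenly and keeps runs deterministic given the seed.

## Adaptive growth

`adaptive_fit()` holds out a validation split (20% by default), then runs
the structural loop with a growth hook. A class *stalls* when its own
margin-metric error (over its own patterns) has not improved for `n_ch`
consecutive iterations while still being nonzero. A stalled class receives
one new dendrite on *both* trees — a fresh row of `k` random unit contacts,
with its own leak — under an eligibility rule: scheme 2 grows a stalled
class only while its error is the (weakly) highest among all classes;
scheme 1 restricts growth to classes currently among the 5 worst. The
highest-error gate is what makes synaptic resources track class
difficulty; without it, classes sitting at tiny residual plateaus siphon
dendrites away from the genuinely hard class. Validation error (hard
readout) is recorded after every addition, and growth stops once it has
increased at each of the last three additions. Adaptive training runs with
hard outputs (`delta = 0`): margin calibration is defined as a
pre-train/validate step for a fixed topology, and interleaving margin decay
with growth is not well defined, so the package keeps the two mechanisms
separate.

After growth, `convert_model_topology()` maps each class's synapse count
`s = m_adapt * k` to the capacity-maximizing factorization
`(m_opt, k_opt)` for retraining from scratch.

## Capacity theory

The number of distinguishable wirings of one dendrite is the number of
multisets of size `k` from `d` afferents, `f = C(k+d-1, k)`; a neuron with
`m` interchangeable dendrites realizes `C(f+m-1, m)` distinct functions,
for a capacity of `C_NL = 2 log2 C(f+m-1, m)` bits. `capacity_bits()`
evaluates this through `lchoose`, falling back to
`m log f - log m!` when `f` itself overflows double precision (the
relative error of that step is of order `m^2/f`, i.e. zero in practice);
an exact integer-binomial oracle covers the small domain in the tests.
`optimal_topology()` scans all integer divisor pairs `m * k = s` —
synapse counts are integers, so the continuous relaxation is not used —
and breaks ties toward larger `m` (more, thinner dendrites).

## Spiking evaluation

Learned wiring maps onto a spiking network for evaluation. Each input
spike evokes a postsynaptic current
`K(t) = I0 (exp(-t/tau_f) - exp(-t/tau_r))`; dendrites apply the same
quadratic nonlinearity to the time-resolved drive `z_j(t)`, with a
time-resolved leak `z_leak_j(t) = z_leak_j * K(t - T_syn)`, i.e. the
rate-model leak carried on the canonical noiseless single-spike waveform.
Under noiseless single-spike encoding this makes the input current of a
class exactly `K(t)^2` times its rate-model score, so the spiking decision
is a monotone transform of the rate decision up to spike-count
quantization. Each class drives a (+) and a (-) leaky integrate-and-fire
neuron with opposite currents; the decision is WTA over the spike-count
differences.

Parameters with stated defaults: `tau_V = 5` ms, `tau_u = 200` ms,
`V_thr = 0.1` mV, stimulus window `T = 200` ms, `T_syn = 100` ms; encoders
use jitter width `Delta` (single-spike) or rates `f_high = 250` Hz /
`f_low = 1` Hz (Poisson). Values the model family leaves unspecified were
fixed once here: `V_reset = -0.1` mV (`= -V_thr`, with
`u_reset = V_reset`), PSC constants `tau_f = 10` ms, `tau_r = 2` ms, and
the two numerical-resolution choices: `I0 = 2` and Euler step
`dt = 0.05` ms. The latter two are dynamic-range choices. The spike count
of an LIF neuron is approximately linear in the integrated current until
the interspike interval approaches `dt`; `I0` must be large enough that a
unit class-score difference maps to several spikes (otherwise near-zero
winning scores produce zero spikes and fall to the tie rule), while
`dt` must be small enough that the largest benchmark currents stay below
the one-spike-per-step ceiling (otherwise top scores saturate into ties).
`I0 = 2` with `dt = 0.05` ms keeps the benchmark's score range
(roughly 0.3–20) inside the resolvable regime. Threshold crossings are
handled at step boundaries; the forward-Euler counts match an exact
event-driven closed-form integrator to within one spike for constant
currents in this regime (see the test suite's oracle).

## The AER connectivity memory

Sparse wiring pays off in hardware when connectivity is stored as a
two-tier address-event table rather than a dense crossbar. The first
memory holds `d` pointer entries of `ceil(log2(H*k))` bits — cumulative
connection counts in CSR style, with the leading `a_0 = 0` kept implicit
so exactly `d` entries are stored — and the second holds `H*k` dendrite
addresses of `ceil(log2 H)` bits, grouped by afferent; multiplicities
expand to repeated entries, and the second memory is sized at `H*k`
regardless of fill. An incoming event on afferent `i` reads the pointer
pair, and `n_i = a_{i+1} - a_i` consecutive destinations. `aer_encode()` /
`aer_decode()` / `route_event()` realize the layout exactly, and
`area_report()` compares `NOB_prop = d ceil(log2(H*k)) + H k ceil(log2 H)`
against a `b`-bit crossbar `NOB_conv ≈ b H d` at a given area per bit
(0.15 um² by default).

## The synthetic benchmarks

The generator emulates thresholded handwritten-digit-style inputs with
controllable structure: each class is a set of random binary prototypes
and samples are independent bit-flip corruptions. It reproduces the
features that matter to this model family — high-dimensional sparse binary
inputs, multi-modal classes, graded class difficulty — and deliberately
not others: no pixel correlations, no smooth stroke geometry, no
class-conditional feature sharing. Passing tests therefore demonstrate the
mechanics of the algorithms, not image-domain accuracy.

Frozen study conditions, chosen once:

* **Standard benchmark** (memorization, ensembles, rate/spike agreement):
  4 classes, `d = 64`, 2 prototypes per class, 5% flip noise, 200 training
  and 200 test patterns; networks of `m = 10`, `k = 5`. Sized so a full
  train/test cycle takes well under a second.
* **Hard-class benchmark** (adaptive growth): 4 classes, `d = 40`; class 1
  is a high-variability, multi-modal category (8 prototypes, 25% flip
  noise, 200 samples), classes 2–4 are clean unimodal categories (one
  noiseless prototype, 50 samples each); initial `m = 2`, `k = 4`,
  scheme 2. The hard class must exceed the initial network's capacity —
  with an easily memorized benchmark no class ever stalls and growth never
  engages — while the easy classes must be cleanly separable so their
  errors reach zero rather than lingering on small plateaus. The
  allocation direction is a stochastic property: across random seeds the
  hard class receives the strictly largest dendrite count in roughly three
  quarters of runs, and in 9/10 of the suite's fixed seeds.

## Degenerate inputs and tie-breaking

All ties are deterministic: WTA and spike-count WTA fall to the lowest
class index, correlation ties in target/replacement selection to the first
element in sampling order, capacity ties to larger `m`, and cropping ties
to the top-left placement. An all-zero input yields zero currents and zero
scores everywhere and is classified as class 1 by the tie rule. `n_T` and
`n_R` are clamped inside the training loop to the tree's synapse count and
the afferent count, so small grown trees remain trainable under the
default candidate-set sizes.

## Known limitations

* Training cost grows with `P` and the number of trees; the loop is
  vectorized over patterns but written in pure R. The benchmark scales
  used here (hundreds of patterns, tens of dendrites) train in seconds;
  digit-scale runs (tens of thousands of patterns) would take hours.
* Spike-*timing* information is evaluation-only; there is no spike-based
  learning path, and no dendrite pruning.
* The margin decay identifies "the same minimum" by equal best errors,
  a pragmatic choice; nothing finer-grained distinguishes two minima here.
* The forward-Euler LIF undercounts spikes at currents far above the
  resolvable regime; rankings remain monotone but saturated scores can
  tie.
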