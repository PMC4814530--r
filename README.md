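# dendnet

Multiclass classification with nonlinear dendrites, binary synapses and
structural plasticity.

`dendnet` is an R implementation of a spike-pattern classifier designed for
low-precision neuromorphic hardware. Each class is represented by a pair of
dendritic trees — an excitatory (positive, PDT) and an inhibitory (negative,
NDT) tree — of `m` dendrites carrying `k` synaptic contacts each, wired
sparsely from `d` input afferents (`k << d`). A dendrite applies a lumped
quadratic nonlinearity to its summed synaptic drive,

    b(z_j) = g(z_j - z_leak,j) * (z_j - z_leak,j)^2,

where `g` is a Heaviside step and `z_leak,j` is the branch's mean activation
under its initial random wiring. The class score is
`o(x) = a_PDT(x) - a_NDT(x)` with `a(x) = sum_j b(sum_i w_ij x_i)`, and the
decision is winner-take-all over class scores. Weights `w_ij` are connection
*multiplicities* (nonnegative integers, each row summing exactly to `k`), so
the model has no analog weights at all — which is the point: learning
proceeds by **structural plasticity**, a correlation-guided rewiring rule
that replaces poorly performing synapses with the best of a set of silent
candidate synapses, escaping local minima by occasional forced swaps.

The package implements, end to end:

- the rate-based reduced model with per-class decision margins and their
  calibration/decay schedule (`dendnet_model()`, `dendnet_fit()`,
  `train_structural()`, `set_margins()`);
- class-specific **adaptive dendrite growth** with cross-validation
  stopping (`adaptive_fit()`), which allocates dendrites to the classes
  that are hardest to learn;
- **ensembles** of independently seeded classifiers combined by summing
  per-class scores before the WTA (`dendnet_ensemble()`, `ensemble_fit()`);
- the **storage-capacity theory** for neurons with nonlinear dendrites,
  `C_NL = 2 log2 C(f+m-1, m)` with `f = C(k+d-1, k)` distinct branch
  functions, and the optimal-topology search `m_opt * k_opt = s` at fixed
  synapse count (`capacity_bits()`, `optimal_topology()`,
  `convert_model_topology()`);
- a **spiking evaluation path**: double-exponential postsynaptic currents,
  time-resolved dendritic nonlinearity, paired leaky integrate-and-fire
  neurons per class and a spike-count WTA, plus jittered single-spike and
  Poisson encoders (`predict_spiking()`, `classify_spikes()`,
  `lif_simulate()`);
- the **two-tier address-event (AER) connectivity memory**: a d-entry
  pointer array over a grouped dendrite-address array, with bit and
  silicon-area accounting against a conventional crossbar
  (`aer_encode()`, `route_event()`, `nob_proposed()`, `area_report()`);
- synthetic data generators (prototype-based binary patterns, DVS-style
  event streams), image thresholding, IDX digit-file reading, event
  framing/cropping and dendrite weight-map rendering.

## Worked example

```r
library(dendnet)

ps  <- synth_patterns(seed = 42)   # 4 classes, d = 64, 200 binary patterns
te  <- synth_patterns(proto_list = ps$prototypes, seed = 43)
fit <- dendnet_fit(ps$X, ps$labels, m = 10, k = 5, seed = 1)
fit
#> Structural-plasticity fit
#> Dendritic classifier: 4 classes, 64 afferents
#>   dendrites per tree: 10 10 10 10  (k = 5 synapses/dendrite)
#>   total synapses: 400
#>   margins: 0 0 0 0
#>   training error (hard WTA): 0

mean(predict(fit$model, te$X) != te$labels)          # rate-based test error
#> [1] 0.14
spk <- predict_spiking(fit$model, te$X[1:50, ], jitter = 10)
mean(spk != te$labels[1:50])       # spiking test error, 10 ms jitter
#> [1] 0.08
```

Training memorizes the 200 patterns (error 0); with zero validation errors
the calibrated margins stay 0. The spiking path maps the same learned
wiring onto LIF neuron pairs and closely tracks the rate-based decisions.

The hardware-facing calculators reproduce their closed-form numbers:

```r
area_report(d = 784, H = 1000, k = 64)
#> Connectivity memory comparison
#>   conventional: 3,176,000 bits (794,000 weights), 470400 um^2
#>   proposed AER: 652,544 bits, 97882 um^2
#>   area reduction: 4.81x

capacity_bits(m = 10, k = 10, d = 784)
#> [1] 1445.188
optimal_topology(s = 100, d = 784)[c("m_opt", "k_opt")]
#> $m_opt [1] 25   $k_opt [1] 4
```

A thin command-line front end wraps the same functions
(`inst/scripts/dendnet`): subcommands `train`, `adapt`, `ensemble`,
`test-spikes`, `capacity`, `memreport`, `synth`, `render-weights`, all
funnelled through a single `--seed`.

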