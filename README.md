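# spikerank

Rank-controlled feedback learning in recurrent spiking networks.

## The problem

Supervised learning rules for recurrent spiking networks split into two
families.  *Error-based* rules (e-prop and relatives) broadcast the
low-dimensional output error into the network; *target-based* rules
(full-FORCE, learning through target spikes) prescribe a complete internal
activity pattern and train every neuron towards it.  `spikerank` implements
a single rule family in which the two are endpoints of one axis — the rank
`R` of the feedback matrix — while a second axis, the spike-timing
tolerance `τ⋆`, moves the code continuously between precise spike timing
and smoothed rates.

For a network of `N` leaky integrate-and-fire neurons with filtered spike
trains `s̄` (filter constant `τ⋆`), expanded readout `B⁺` (R rows) and
generalized target `Y⋆`, the weight update is

    Δw_ij = η Σ_t [ Σ_k B⁺_ki (Y⋆_k^{t+1} − Y_k^{t+1}) ] p_i^t e_j^t

with `p` the pseudo-derivative of the threshold and `e` the spike-response
(eligibility) trace.  Rewriting the target as `Y⋆ = B⁺ s̄⋆` gives the
equivalent target-propagating form with feedback matrix `D = B⁺ᵀB⁺`, and
`D = I` gives the purely local target-spike rule.  The kernel of `D`
(dimension `N − R`) is the space of internal solutions left free by
learning, which the package measures via the participation ratio of
convergence clouds — across training replicas, or from a single noisy
trial.

The package ships two benchmark tasks: **store-and-recall** (reproduce a
band-limited 3-channel trajectory from a clock input) and
**button-and-food** (clone an expert that must press a button before
collecting food — a memory-dependent navigation task), with a built-in
expert, tuning-curve state encoder, environment and reward.

## A worked example

Train a store-and-recall network at full rank with the precise-timing
(clamped, `τ⋆ → 0`) rule and inspect the result:

```r
library(spikerank)

params <- network_params(N = 100, tau_star = 0)
spec   <- store_recall_spec(T_steps = 200, seed = 42)
config <- learning_config(eta = 0.1, epochs = 500, rule = "ltts",
                          optimizer = "adam", clamped = TRUE, margin = 0.3)

run <- run_store_recall(spec, params, R = 100, config,
                        feedback_mode = "diagonal", seed = 1)
run$log
#> training_log: 500 epochs
#>   MSE: 3.031 -> 0.9874 | spike error: 875 -> 0
#>   epochs to halve initial MSE: 153
run$readout$residual
#> [1] 0.9874139
```

The spike error counts raster mismatches against the internal target
`s⋆`: it falls from 875 to 0 — the network's spike pattern has converged
to the target exactly, so the output error equals the *readout limit*
(0.9874 here), the best error the frozen pre-trained readout admits.  At low
rank (`R = 3`, `feedback_mode = "from_readout"`, unclamped) the same task
halves its output error within a few dozen epochs but leaves the spike
error high: many internal solutions produce the same behavior.

The solution-space analyses quantify that freedom:

```r
p   <- network_params(N = 60, tau_star = 2)
spec <- store_recall_spec(T_steps = 70, seed = 7)
cfg <- learning_config(eta = 0.05, epochs = 1500, optimizer = "adam")
replica_dimensionality(spec, p, ranks = c(60, 55, 50), config = cfg)
#>   rank dimensionality n_converged n_excluded
#> 1   60       0.000000           5          0
#> 2   55       1.671642           5          0
#> 3   50       2.967409           5          0
```

At full rank every converged replica lands on the same internal solution
(a zero-dimensional cloud); each drop in rank frees directions for the
replicas to spread along.

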