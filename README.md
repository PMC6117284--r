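# rivermix

Bayesian sediment source apportionment for hierarchical river networks.

`rivermix` is for catchment scientists and environmental geochemists who
fingerprint sediment sources with geochemical tracers (XRF element
concentrations) or compound-specific stable isotopes (δ¹³C of long-chain
fatty acids) and want apportionment that respects watershed structure
instead of pooling all sources basin-wide. It implements a deconvolutional
mixing-model workflow: sequential per-node Bayesian unmixing with upstream
mixtures acting as sources to downstream mixtures, followed by
deconvolution of the node posteriors over the watershed DAG into
apportionment by ultimate source class, with full uncertainty propagation.
A pooled-source baseline, a tracer-screening stage, MCMC convergence
gating, and a synthetic-data generator with exact ground-truth oracles are
included.

## The model

At each node, mixture tracer values are modelled as

    Y_ij ~ Normal( Σ_k p'_kj μ_kj , τ_j ),   p'_kj = p_k c_kj / Σ_l p_l c_lj

with a Dirichlet(α) prior on the proportion simplex `p` (one simplex per
level of a fixed factor such as season or sediment type), optional
concentration dependence `c_kj`, a per-tracer residual SD `τ_j` (uniform,
scale-aware prior), and source means/SDs `(μ, σ)` redrawn each MCMC
iteration from their closed-form normal/scaled-inverse-χ² posteriors so
source-sampling uncertainty propagates. Sampling is adaptive random-walk
Metropolis on isometric log-ratio coordinates (C++ core); convergence is
gated on the Gelman–Rubin diagnostic (reject if > 5% of monitored
variables exceed R̂ = 1.05, with one automatic retry at doubled chain
length).

Node posteriors over immediate inputs are then chained over the network:
for a class B reachable locally and through upstream node 1,

    p(B → M2) = p_B1 · p_M1 + p_B2

applied draw-by-draw (draws of independently fitted nodes paired after a
seeded permutation), yielding composite posterior distributions per node,
level and ultimate class.

## Worked example

Simulate a distributed watershed (two tributary sub-watersheds and a
main channel: M1, M2 → M3; M3, M4 → M5), fit the network sequentially,
and deconvolute:

```r
library(rivermix)

truth <- truth_spec(make_topology("distributed"), seed = 11)
dat   <- simulate_watershed(truth)

rf   <- fit_network(truth$graph, dat$mixtures, dat$sources,
                    mcmc = mcmc_settings(50000, 25000, 25, 3), seed = 11)
comp <- deconvolute(rf, seed = 11)
print(comp)
```

```
Composite apportionment over ultimate source classes ( 3000 paired draws )
node       level      source       proportion
M1         all        A            0.58 ± 0.01
...
M5         all        A            0.09 ± 0.02
M5         all        B            0.42 ± 0.02
M5         all        C            0.34 ± 0.01
M5         all        D            0.14 ± 0.01
```

Each line is the posterior mean ± SD of the proportion an ultimate source
class contributes to that node's sediment. The generator knows the truth,
and the outlet recovery is close:

```r
subset(true_composite(truth), node == "M5")
#  node level class proportion
#    M5   all     A      0.084
#    M5   all     B      0.440
#    M5   all     C      0.342
#    M5   all     D      0.134
```

Tracer screening and the pooled baseline follow the same pattern:

```r
screen_panel(dat$sources$M1, dat$mixtures$M1)       # range test + report
pooled_fit(truth$graph, dat$mixtures, dat$sources,  # classes merged
           nodes = "M5", mcmc = mcmc_settings(50000, 25000, 25, 3))
```

A thin command-line wrapper (`inst/scripts/unmix.R`) exposes
`simulate`, `screen`, `run --mode {deconv,pooled,single_node}` and
`report` subcommands with `--seed` everywhere.

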