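# bmvc — Bayesian multi-view clustering with complex inter-view relationships

Multi-view datasets pair several modalities that describe the same
underlying system — gene expression alongside methylation probes,
household-level survey records alongside the individuals who live in them.
The entities usually differ between views, and what links them is a known
but messy relationship structure: many probes per gene, many residents per
household, and entities with no counterpart at all. Most integrative
clustering methods assume a clean one-to-one correspondence; `bmvc` does
not.

`bmvc` clusters each view with its own finite Gaussian mixture while a
coupled prior over the hard assignments rewards related entities for landing
in *corresponding* clusters. For views `v = 1..V` with entities `x_vi`,
cluster labels `z_vi`, mixture weights `π_v`, a user-supplied non-negative
relationship matrix `R_vu`, a latent cluster-correspondence permutation
`C_vu`, and a latent coupling strength `φ_vu ≥ 0` per view pair:

```
p(Z | π, R, φ)  ∝  Π_v Π_i π_{v, z_vi}
                 · Π_{v<u} Π_{i,j} ( 1 + C_vu[z_vi, z_uj] · R_vu[i,j] · φ_vu )
```

Every related entity pair placed in matched clusters multiplies the prior
mass by `1 + R·φ`, so each view's clustering informs the others in
proportion to a coupling strength that is itself inferred from the data —
unrelated views simply learn `φ ≈ 0`. The normalization constant is a sum
over all joint assignments (a Markov-random-field partition function); it
factorizes over the connected components of the relationship graph and is
computed exactly when the components are small, with a Besag
pseudolikelihood fallback for denser graphs. Inference is a modified hard
EM: a coordinate-ascent E-step across views, analytical Gaussian
maximum-likelihood updates, a search over the cluster matchings `C`, a
gradient (ADAM) or black-box variational (BBVI) update of `φ`, and random
restarts with k-means++ initialization.

The package also ships the two baselines used for benchmarking
(independent hard-EM mixtures, `hgmm_fit()`, and naive consensus
clustering by feature concatenation, `consensus_fit()`), simulation
generators for shift-confounded and relation-scrambled designs, and the
evaluation statistics (adjusted Rand index, structural affinity,
convergence-rate and coupling-recovery experiment harnesses).

## Worked example

Simulate two views with two Gaussian clusters in which half of the view-2
cluster-A samples are shifted halfway toward cluster B (so view 2 alone is
confounded), related one-to-one to view 1, and fit the coupled model:

```r
library(bmvc)

sim <- gen_two_view_shift(shift_config(mu_s = 0.5),
                          topology = "complete_one_to_one", seed = 1)
fit <- fit_bmvc(sim$data, sim$relations, bmvc_config(K = 2, seed = 1, restarts = 3))
fit
#> BMVC fit (exact mode): 2 view(s), 3 restart(s)
#>   best objective: -820.29537 (restart 1)
#>   coupling strengths: view1:view2=16.12

mean_ari(fit, sim$truth)                                  # 1
mean_ari(lapply(1:2, function(v)
  hgmm_fit(sim$data$views[[v]]$X, 2, seed = v)$labels),
  sim$truth)                                              # 0.803
```

The fitted coupling strength (`φ ≈ 16`) says the views are strongly
dependent; the coupled model uses the unconfounded view to place every
shifted sample correctly (mean adjusted Rand index 1 against the generating
labels), while independent per-view mixtures misassign the shifted half
(0.803). The structural affinity map — the fraction of relations flowing
between each cross-view cluster pair — is exactly diagonal under the learned
matching:

```r
affinity_map(fit$state$z[[1]], fit$state$z[[2]],
             sim$relations$blocks[[1]]$R, matching = fit$state$C[[1]])$scores
#>      [,1] [,2]
#> [1,]    1    0
#> [2,]    0    1
```

Real data enters through TSV/CSV matrices and edge-list (or MatrixMarket)
relationship files — see `read_view_matrix()`, `read_relationships()` and
the YAML-driven command line interface `bmvc_cli()` / `exec/bmvc`
(subcommands `simulate`, `fit`, `baseline`, `evaluate`, `benchmark`).

## Package layout

- `R/model_core.R` — the coupled assignment prior, exact partition
  function, full conditionals, pseudolikelihood, joint objective
- `R/inference.R` — hard-EM engine, initialization, optimizers
- `R/baselines.R`, `R/simulation.R`, `R/evaluation.R` — baselines,
  generators, metrics and experiment harnesses
- `R/io.R`, `R/cli.R`, `exec/bmvc` — file formats and the CLI
- `vignettes/bmvc-methods.Rmd` — the model, its assumptions, all defaults
  and the reasoning behind them
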