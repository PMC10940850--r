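---
title: "Coupled multi-view clustering: model, inference and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled multi-view clustering: model, inference and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmvc)
```

## The model

A multi-view dataset consists of $V$ matrices, one per modality, whose rows
(entities) are linked across views by a known, non-negative relationship
matrix $R_{vu}$ per view pair: $R_{vu}[i,j] > 0$ when entity $i$ of view $v$
is related to entity $j$ of view $u$. Relationships may be one-to-one,
many-to-one, many-to-many, weighted, or absent for some entities — nothing
is assumed about their structure beyond non-negativity.

Each view carries its own finite mixture: mixture weights $\pi_v$ on $K_v$
components, component parameters $\theta_{vk}$ (Gaussian mean and covariance
by default; the component family is pluggable through `gaussian_base()`'s
interface), and hard assignments $z_{vi}$. Were the views independent, the
assignment prior would factorize as $\prod_v \prod_i \pi_{v,z_{vi}}$. The
coupled model multiplies this by one factor per related entity pair:

$$
p(Z \mid \pi, R, \phi) \;\propto\;
  \prod_{v}\prod_{i} \pi_{v, z_{vi}}
  \prod_{v<u}\prod_{i,j}
  \bigl(1 + C_{vu}[z_{vi}, z_{uj}]\, R_{vu}[i,j]\, \phi_{vu}\bigr),
$$

where $C_{vu}$ is a latent permutation matching clusters across the pair
(every row and column has exactly one indicator, which forces
$K_v = K_u$ for coupled pairs — a deliberately simple notion of cluster
correspondence), and $\phi_{vu} \ge 0$ is a latent per-pair coupling
strength. A related pair in matched clusters multiplies the prior mass by
$1 + R\phi$: the posterior odds of an assignment rise with both the
relation weight and the inferred strength of the inter-view dependence.
With $\phi = 0$ the model is exactly $V$ independent mixtures.

### Normalization

The right-hand side requires a partition function $\bar{Z}$ — a sum over
all $\prod_v K_v^{N_v}$ joint assignments. Two facts make this manageable:

1. **Component factorization.** Entities interact only through relation
   edges, so $\bar{Z}$ factorizes exactly over the connected components of
   the relationship graph; unrelated entities contribute a factor of one.
   When every related entity has a single relation (degree one in the union
   graph), each component is one edge and has the closed form
   $1 + w\phi \sum_k \pi_{vk}\pi_{u,m(k)}$, so exact normalization costs
   one logarithm per edge at any data size. Larger components are
   enumerated exhaustively up to a configurable cap (`enum_cap`, default
   $10^6$ states per component).
2. **Pseudolikelihood.** For graphs with large components (dense
   many-to-many blocks), the Besag pseudolikelihood — the sum over entities
   of the log full-conditional probability of their current assignment —
   replaces the normalized prior (`pseudo_log_prior()`).

`mode = "auto"` in `bmvc_config()` selects exact normalization when the
graph is edge-decomposable and the pseudolikelihood otherwise. The
pseudolikelihood is a *biased* surrogate: every edge appears in the full
conditionals of both of its endpoints, which doubles the effective coupling
and, at large $\phi$, can make configurations where the views agree
everywhere (with genuinely distinct clusters merged to manufacture
agreement) outscore the data-supported clustering. The exactly normalized
objective does not double-count and ranks such degenerate configurations
below the data-supported optimum; this is why exact normalization is
preferred whenever the relationship structure permits it, and why the
coupling strength carries a proper prior (below) when it does not.

## Priors and their defaults

- **Mixture weights**: Dirichlet with concentration `alpha` (default 1,
  i.e. flat; values above 1 smooth the weights of emptied clusters).
  `alpha >= 1` is required so the MAP stays well defined on the simplex
  boundary.
- **Coupling strengths**: half-normal on $\phi$ with scale 5 by default.
  The coupling factor saturates — a single relation at $\phi$ multiplies
  the assignment odds by $1+R\phi$, so $\phi$ beyond roughly the cluster
  count already makes one edge decisive and larger values add almost no
  modelling value while enabling the agreement-degenerate configurations
  described above. A weakly-informative half-normal leaves
  $\phi \lesssim 10$ essentially unpenalized and prices larger values
  quadratically. A log-normal option (`phi_prior = "lognormal"`) is
  available — its log-scale penalty is nearly flat at large $\phi$, which
  makes it a poor guard but a reasonable way to *encourage* strong coupling
  (set the location high) when the analysis goal is maximally aligned
  clusters; an improper flat option exists for sensitivity checks.
- **Component parameters**: the base measure used to refresh emptied
  components draws a mean from a Gaussian centred on the view's grand mean
  with the per-feature variances, and a diagonal covariance at the grand
  variances. No conjugate prior term enters the objective by default.

## Inference

`fit_bmvc()` runs a modified hard EM, per restart:

1. **E-step** — coordinate ascent across views: every entity of a view is
   reassigned to the argmax of its full conditional (component log-density
   + $\log \pi$ + coupling terms from the other views' current
   assignments). Entities within a view are conditionally independent
   given the other views, so a view updates in one vectorized pass; sweeps
   repeat (views in index order) until a full pass changes nothing or
   `estep_max_sweeps` is hit. Ties break toward the lowest cluster index.
2. **M-step, components** — analytical Gaussian MLEs per cluster
   (mean and $1/n$ covariance with a diagonal floor; singletons get the
   floor covariance; emptied clusters are redrawn from the base measure).
3. **M-step, matchings** — each pair's correspondence permutation is
   re-optimized against the (exact or pseudo) assignment prior:
   exhaustively for $K! \le 720$, by greedy best-improving pairwise row
   swaps above that. Ties keep the incumbent.
4. **M-step, weights and coupling** — mixture weights take their
   closed-form Dirichlet-MAP value from the cluster occupancies, and the
   coupling strengths are updated by ADAM on the objective through a
   softplus reparameterization ($\phi \ge 0$), or by mean-field Gaussian
   BBVI with reparameterized Monte-Carlo gradients
   (`optimizer = "bbvi"`). Gradients are analytic both for the
   pseudolikelihood and for the edge-decomposable exact objective.

Iterations stop when the relative objective improvement drops below `tol`
(default $10^{-6}$) or after `max_iter` iterations; the best of `restarts`
restarts by final objective is returned, and the whole procedure is
reproducible from the configuration seed.

### Why the mixture weights are not jointly optimized with $\phi$

The exact normalizer depends on $\pi$ through the per-edge agreement rate
$s = \sum_k \pi_{vk}\pi_{u,m(k)}$. Maximizing the normalized prior jointly
over $(\pi, \phi)$ therefore admits a second degenerate direction: skewing
the weight vectors of the two views against each other drives $s \to 0$
and inflates every observed agreement by $-\log s$, rewarding weight
configurations that have nothing to do with cluster occupancy. Pinning
$\pi$ at its closed-form occupancy MAP — the standard mixture M-step —
removes this direction entirely; `pi_update = "joint"` restores the full
joint gradient update for users who want it.

### Initialization

Two schemes are built in. `init = "kmeans"` seeds each view with k-means++
followed by Lloyd iterations, repeated `n_init = 30` times keeping the
lowest within-cluster sum of squares — effectively the deterministic
k-means solution for the view. `init = "random"` runs a single k-means
pass seeded with $K$ entities drawn uniformly at random (no k-means++
spreading, no best-of-$n$ selection), the classical "random restart"
initialization. On the simulated benchmarks the k-means++ scheme attains
the best known objective in essentially every run, while random seeding
lands in merged- or split-cluster local optima a substantial fraction of
the time — the qualitative gap that motivates k-means++ initialization as
the default. Explicit initial labelings can be supplied through
`init_labels`.

### Matching degeneracy

When an alternative correspondence permutation carries the same matched
relation weight as the incumbent — for instance when two clusters' cross-
view relations are split exactly half-and-half, as in the four-cluster
benchmark below — the matching is not identifiable from the relation
structure, and EM commits to whichever branch the initialization suggests.
The two branches differ only through borderline entities and end at nearly
(not exactly) equal objectives. At convergence the fitter therefore
evaluates every near-tied alternative matching with a short EM
re-convergence and keeps the best branch, so that runs starting on either
side of the tie report the same final optimum. The initial matching is
likewise chosen by the exhaustive search rather than fixed at the
identity, which makes the trajectory invariant to label permutations of
the initialization.

## Simulation designs

The generators reproduce three benchmark families; all of them draw
isotropic Gaussian clusters and are fully reproducible from `(config,
seed)`.

- **Two-cluster shift designs** (`gen_two_view_shift()`): two clusters A
  and B in both views with means $(0,0)$ and $(4,0)$; related samples are
  generated by the same cluster in both views; in view 2 half of the
  cluster-A samples are shifted by $s_i(\mu_B - \mu_A)$ with
  $s_i \sim N(\mu_s, 0.05)$, confounding view 2 alone. Three relationship
  topologies: a complete one-to-one bijection, a half-missing one-to-one
  case (edges for a random half of view 2), and a two-to-one case in which
  view 2 has twice as many samples mapping in pairs onto view-1 samples.
- **Binomial randomization** (`apply_binomial_randomization()`) degrades
  the inter-view dependence: each view-2 sample's generating cluster is
  resampled given its baseline cluster with probability parameter
  $p \in [0, 0.5]$. The printed form of this rule (a baseline-A sample is
  generated by A with probability $p$, otherwise by B; a baseline-B sample
  by B with probability $1-p$) routes nearly every sample to B as
  $p \to 0$ and leaves the realized labels uninformative about the
  baseline at *both* ends of the range, so it cannot express "full
  dependence at $p=0$". The operation implements that rule verbatim for
  transparency and offers `complement = TRUE` (A stays A with probability
  $1-p$), under which dependence decays monotonically from complete at
  $p=0$ to none at $p=0.5$; the coupling-recovery experiment uses the
  monotone variant, and the fitted $\phi$ indeed decreases in $p$, more
  steeply when the topology provides more relations.
- **Four-cluster confounded design** (`gen_four_cluster()`): clusters
  A–D at the corners of a $4 \times 4$ square, one-to-one relations, the
  A-to-B shift confounding as above, plus relation scrambling: half of the
  view-2 cluster-C samples are related to view-1 cluster-D samples and
  symmetrically for D. The views then genuinely disagree about the C/D
  block, which defeats consensus clustering by concatenation
  (`consensus_fit()`) while the coupled model keeps separate per-view
  interpretations.
- **Pseudo-omics replication** (`gen_pseudo_omics()`): two views derived
  from one matrix by independent additive Gaussian noise, duplication of a
  random fraction of entities in view 2 (fresh ids, independent noise, a
  recorded provenance map — duplicates make the ground truth of view 2
  undefined, so downstream agreement statistics should be computed in view
  1 only), and removal of a random fraction of relation edges.

**Numeric defaults.** Cluster standard deviation 0.5 against mean
separations of 4 (so the clusters themselves are cleanly separated and the
only ambiguity is the ambiguity the design injects — shifted samples and
scrambled relations); 100 samples per cluster per view; shift-fraction
standard deviation 0.05; shift means on a grid from 0 to 0.6, whose upper
end places shifted samples far enough from both A and B to be genuinely
confusable. All are overridable; `clamp = TRUE` truncates sampled shift
fractions to $[0,1]$.

The generators emulate the *structure* of multi-omic and survey data —
heterogeneous entity sets, partial and many-to-one relations, view-specific
confounding — not its distributional messiness: features are isotropic
Gaussian, noise is homoscedastic, relation weights are clean, and the
generating cluster count is known. Results on these benchmarks demonstrate
that the machinery behaves as designed; they do not certify performance
under heavy tails, missing data, or misspecified $K$.

## Experiment harnesses and the sizes they use

`convergence_experiment()` generates the four-cluster design once per
shift from a shift-specific seed and refits it `trials_per_shift` times
per initialization scheme, reporting the fraction of runs whose final
objective lies within relative tolerance $10^{-4}$ of the per-shift best
(pooled across schemes by default; the floating-point scale of the
objectives makes a tighter "equality" meaningless and coarser ones
indistinguishable from genuine suboptimality). The packaged experiments
use seven shifts ($0, 0.1, \dots, 0.6$) times ten trials.
`phi_recovery_experiment()` fits the two-cluster design across a grid of
randomization probabilities and reports median fitted $\phi$ per grid
point over replicate seeds. The test suite exercises both at these sizes,
plus a partition-function identity against exhaustive enumeration on one
hundred random small instances and an exact equivalence between the
$\phi$-frozen coupled model and independent per-view mixtures.

## Numerical choices

- All prior arithmetic is in the log domain; coupling factors use
  `log1p(R * phi)` so large $R\phi$ loses no precision.
- Covariance MLEs use the $1/n$ convention; diagonals are floored at
  $10^{-6}$ times the view's mean feature variance, with a jitter loop
  guaranteeing a successful Cholesky factorization. Fully degenerate
  views (zero variance) are flagged on the fit.
- E-step ties break toward the lowest cluster index; matching-search ties
  keep the incumbent. Both rules are deterministic.
- Every random draw derives from the configuration seed through a fixed
  mixing function, so fits, generators and experiment harnesses are
  bit-reproducible; seeded helpers restore the caller's RNG state.
- The weight/coupling optimizer tracks the best point seen and never
  returns a point worse than the incumbent, so the EM objective trace is
  non-decreasing up to the tolerance of the stochastic BBVI variant.

## Known limitations

- Hard assignments: cluster-membership uncertainty is not represented,
  and the E-step can stick in coordinate-wise local optima; restarts and
  k-means++ initialization are the mitigation.
- Coupled view pairs must share a cluster count, and the correspondence
  is a full permutation — partial or many-to-many cluster matchings are
  out of scope.
- The pseudolikelihood mode overstates coupling (edge double-counting);
  with dense relationship blocks and weak data signal it can prefer
  over-aligned solutions. Keep the half-normal prior scale moderate there.
- The number of clusters is user-specified; components can empty out
  (effectively selecting a smaller $K$), but nothing splits clusters.
- Exact normalization is closed-form only for degree-one relationship
  graphs; enumerable components cover small stars and cliques, and
  everything else falls back to the pseudolikelihood.
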