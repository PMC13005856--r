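---
title: "Scheduling distributions for comparative judgement: models, algorithms, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scheduling distributions for comparative judgement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cjsched)
```

## The design problem

A comparative judgement study presents judges with pairs of objects and asks
which of the two has the higher quality. The canonical analysis model is
Bradley–Terry: object $i$ carries a latent quality $\lambda_i \in \mathbb{R}$
and the probability that $i$ beats $j$ in a single comparison is

$$p_{ij} = \frac{e^{\lambda_i}}{e^{\lambda_i} + e^{\lambda_j}},
\qquad \mathrm{logit}(p_{ij}) = \lambda_i - \lambda_j .$$

With $n_{ij}$ comparisons of the pair and $Y_{ij}$ wins for $i$, the data are
binomial, $Y_{ij} \sim \mathrm{Bin}(n_{ij}, p_{ij})$, and a multivariate
normal prior $\boldsymbol\lambda \sim \mathrm{MVN}(\boldsymbol\mu, C)$
encodes what is known before data collection — spatial smoothness, an
a-priori ordering, or a posterior carried over from an earlier round.

A *static experimental design* for such a study is a **scheduling
distribution** $\mathcal{S}$: a probability distribution over the
$M = N(N-1)/2$ unordered pairs from which every comparison is drawn
independently. The design this package constructs is principal-component
based: because the likelihood depends on $\lambda$ only through pairwise
differences, the relevant prior is that of
$\lambda_{\mathrm{diff}} \sim \mathcal{N}(\nu, \Delta)$, where the $M \times M$
matrix $\Delta$ has entries

$$\mathrm{Cov}(\lambda_i - \lambda_j,\; \lambda_k - \lambda_l)
  = C_{ik} - C_{il} - C_{jk} + C_{jl}.$$

Writing $\Delta = U \Psi U^{\top}$ with eigenvalues
$\psi^{(1)} \ge \psi^{(2)} \ge \dots \ge 0$, pair $r$ receives probability

$$q_r = \frac{\sum_c \bigl(u^{(c)}_r\bigr)^2 \psi^{(c)}}{\sum_d \psi^{(d)}},$$

i.e. its share of the total prior variance of the quality differences. Pairs
whose difference is *a priori* most uncertain are compared most often; pairs
already believed similar are not over-sampled. The prior mean differences
$\nu$ are computable (`pair_mean_differences()`) but play no role in the
design, which depends on $\Delta$ alone. Note $\sum_c \psi^{(c)} (u^{(c)}_r)^2$
is the $r$-th diagonal entry of $\Delta$, so the design equals
$\mathrm{diag}(\Delta) / \mathrm{tr}(\Delta)$ — an identity the test suite
uses as an independent oracle while the implementation follows the spectral
definition.

The obstacle is scale: $\Delta$ is dense and $M \times M$, so storage grows
as $N^4$ and a full eigendecomposition as roughly $N^6$. Studies with a few
hundred objects are out of reach for the direct ("standard") method.

## The reduced-basis route

The package's scalable path rests on the factorisation
$\Delta = E\, C\, E^{\top}$, where $E$ is the sparse $M \times N$ operator
whose row for pair $(i,j)$ is $e_i - e_j$. $E$ has rank $N-1$ (its null
space is the constant vector), so $\Delta$ — despite its size — has rank at
most $N-1$. `rbd()` builds a greedy **reduced basis decomposition**
$E \approx Y T$ with $Y$ ($M \times d$) orthonormal and $T = Y^{\top} E$:

1. start from one column of $E$ (by default the first; all columns have
   identical norm $\sqrt{N-1}$, so the choice is a tie-break convention,
   and a random or user-chosen start is available);
2. at each step, orthonormalise the worst-approximated column against the
   current basis (modified Gram–Schmidt with one re-orthogonalisation pass)
   and append it;
3. stop when the largest relative column residual drops below
   $\varepsilon_R$, or after $d_{\max}$ iterations.

Residuals are monitored by the estimator
$\lVert \mathrm{col} \rVert^2 - \lVert T_{\cdot,\mathrm{col}} \rVert^2$,
exact for an orthonormal basis, with $\lVert \mathrm{col} \rVert^2 = N-1$
known in advance — so a full residual sweep costs $O(Nd)$ rather than
$O(N^2 d)$ (the offline–online split). The subtraction cancels
catastrophically once a column is essentially fully represented (the fast
estimate bottoms out near $\sqrt{\varepsilon_{\mathrm{mach}}}$), so
estimates below $10^{-4}$ are confirmed by one direct projection before
they are trusted; this keeps reported residuals meaningful down to
$10^{-12}$ and below.

`rbd_scheduling()` then forms the $d \times d$ matrix
$\widetilde C = T C T^{\top}$, eigendecomposes it as
$V \Sigma V^{\top}$, and uses $\sigma_i$ with eigenvectors $YV$ in the
design formula. The implicit approximation
$\widetilde\Delta = Y \widetilde C Y^{\top}$ is never materialised: peak
memory is $O(N^2 d)$ and the dominant cost $O(N^2 d^2)$. Two structural
guarantees make the approximation trustworthy:

* **Interlacing**: the reduced eigenvalues satisfy
  $\alpha_{i+N-d} \le \sigma_i \le \alpha_i$ against the exact eigenvalues
  $\alpha$ of $\Delta$, for every depth $d$ (`check_interlacing()` verifies
  this against a dense oracle in the tests).
* **Exact recovery**: since $\mathrm{rank}(E) = N-1$, running $d = N-1$
  iterations reproduces the exact design to machine precision; $d_{\max}$
  therefore defaults to $N-1$, and the empirical KL divergence between the
  exact and reduced designs sits at the $10^{-16}$ level.

The rank of $\Delta$ itself is predictable from $C$ (`delta_rank()`):
$\mathrm{rank}(C) - 1$ when the constant vector lies in the range of $C$,
$\mathrm{rank}(C)$ otherwise.

## Prior covariance families

Four constructors cover the common prior structures, all normalised (where
stated) to unit diagonal so every object has the same marginal prior
variance:

* `laplacian_covariance()`: $C = (D - A + I)^{-1}$ for a graph adjacency
  $A$ — a Gaussian-Markov-random-field-type smoothness prior. The $+I$
  regularisation makes the matrix positive definite for *every* graph,
  so disconnected graphs are allowed (the usual Erdős–Rényi setting
  $p = 0.5$ keeps them connected in practice, but nothing requires it).
* `toeplitz_covariance()`: $C_{ij} = \rho^{|i-j|}$ with default
  $\rho = 0.5$ — an AR(1) prior for naturally ordered objects.
* `inverse_wishart_covariance()`: one draw from an inverse-Wishart with
  identity scale, rescaled to unit diagonal — a weakly informative prior.
  The degrees of freedom are a free parameter; the default $N + 2$ is the
  smallest integer giving a finite mean, and one draw is taken per
  replicate.
* `exp_adjacency_covariance()`:
  $C = D^{-1/2} e^{A} D^{-1/2}$ with $D = \mathrm{diag}(e^{A})$ — a spatial
  walk-counting kernel giving well-connected node pairs higher prior
  covariance. The matrix exponential is computed through the symmetric
  eigendecomposition of $A$ (exact up to round-off), not by series
  truncation.

`erdos_renyi_adjacency()` supplies random graphs; `read_adjacency()` reads
an edge list for real networks.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `eps_R` | `1e-6` | relative residual tolerance of the greedy basis; the design is empirically insensitive to it anywhere in $[10^{-12}, 10^{-6}]$ |
| `d_max` | `N - 1` | iteration cap; $N-1$ guarantees exact recovery of the design |
| `init` | first column | greedy initialisation; any choice yields the same design at full depth |
| `df` | `N + 2` | inverse-Wishart degrees of freedom (unit-diagonal normalised draw) |
| `tol` (fit) | `1e-8` | gradient max-norm at which Newton ascent stops |
| `max_n` | 300 | guard on the dense `build_delta()` path against $O(N^4)$ memory |

The residual tolerance is *relative* (per-column residual divided by the
column norm $\sqrt{N-1}$), making its meaning independent of $N$.
Tolerances below about $10^{-13}$ are unattainable in double precision;
`rbd()` warns, and the sweep harness records the shortfall (cap reached or
degeneracy flag) instead of failing — mirroring the known breakdown of the
method at $\varepsilon_R \in \{10^{-14}, 10^{-16}\}$.

Tie-breaks and degeneracies are deterministic: equal residuals resolve to
the smallest column index; a candidate column whose post-projection norm
falls below $10^3 \varepsilon_{\mathrm{mach}} \sqrt{N-1}$ is treated as
numerically dependent and stops the iteration with a degeneracy flag. A
constant-covariance prior (all quality differences certain) makes the
design undefined; both design paths detect the zero (or round-off-level)
total variance and raise an explicit "degenerate prior" error rather than
dividing by zero. In the reduced path the comparison is against
$N^2 \varepsilon_{\mathrm{mach}} \max|C_{ij}|$ because $\widetilde C$
carries round-off noise of that order even when $\Delta$ is exactly zero.

## Bayesian inference and the two-phase workflow

`fit_bt_map()` maximises the log posterior (binomial likelihood + MVN
prior) by damped Newton ascent. The likelihood alone is invariant to a
constant shift of all qualities; the proper prior removes that flat
direction, so the posterior is strictly concave and the mode unique.
Convergence is declared at gradient max-norm $10^{-8}$ (cap 100
iterations; non-convergence is flagged on the returned object, not
thrown). The posterior covariance is the Laplace approximation — the
inverse negative Hessian at the mode. With no data the fit returns
$(\mu, C)$ exactly.

The two-phase classroom pattern (`two_phase_schedule()`): fit phase-1
comparisons under independent $\mathcal{N}(0, 5^2)$ priors (or any
supplied $C_0$), then feed the Laplace posterior covariance into
`rbd_scheduling()` as the phase-2 prior. Pairs whose ordering phase 1
resolved lose design probability; the update is fast enough to run in a
between-phase classroom break. The choice of MAP + Laplace (rather than
MCMC) for phase 1 is a design decision of this package: it is
deterministic, fast, and produces exactly the covariance object the design
construction needs.

## What the synthetic data emulate — and what they do not

The generators reproduce the structural features the design method cares
about: prior covariances with graph, ordering, or exchangeable structure;
comparison outcomes that are conditionally independent binomials under the
scheduling distribution. They do **not** emulate judge effects,
drift in judging standards over a session, ties or abstentions, or
misspecified priors — so a passing suite shows the algorithms are correct
under the stated model, not that the model fits any particular study.
`simulate_comparisons()` draws pair counts from a single multinomial, which
is exactly the i.i.d.-pairs sampling model of a static design.

## Problem sizes and reproducibility

The packaged simulation study runs the exact method alongside the reduced
one on $N \in \{8, 16, 32, 64\}$ with 10 replicates per covariance
structure (the sparsity sweep uses 5 replicates over
$p \in \{0.1, \dots, 0.8\}$); these sizes exercise the full algorithmic
path while keeping the cubic-in-$M$ exact method to a few seconds per
$N = 64$ replicate. Larger studies are the province of the reduced method
alone — the dense path is guarded at $N = 300$. All randomness flows from
one master seed through a documented counter scheme
(`structure`, $N$, replicate), so any single cell can be reproduced in
isolation and identical seeds give bit-identical results.

Quality-recovery checks use $N = 20$ objects, true qualities drawn from
the Toeplitz($0.5$) prior, and ten comparisons per object — the practical
rule of thumb for reliable estimates — over 50 replicates. The pinned
acceptance bound (mean Pearson correlation above 0.7) is a regression
bound chosen from pilot runs of this package, not an external claim;
typical values are near 0.87.

## Known limitations

* The design criterion is principal-component based; it is not known to be
  D- or A-optimal, and the package does not attempt optimality
  comparisons.
* The exact path is kept for validation and small studies only; its
  $O(N^4)$ memory guard is deliberate.
* Only unordered pairwise comparisons are supported — no ties, ordered
  presentations, or multi-way rankings.
* The scheduling distribution is static; it is re-computed between phases,
  not after every comparison.
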