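---
title: "Network-structured kernel machine tests for module effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-structured kernel machine tests for module effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netKM)
```

## The problem

Module-based association analysis asks whether a *group* of bio-elements
— metabolites in a pathway, genes in a co-expression module, SNPs in a
gene — is jointly associated with a continuous trait, rather than testing
each element one at a time. Elements inside a module are not exchangeable:
they regulate and interact with one another as a network, and a hub
metabolite is biologically not the same object as a peripheral one. netKM
implements kernel machine regression whose kernels encode that network
structure, plus score tests for two questions that single-module methods
cannot ask: does one module *interact* with another, and does a module
carry signal *after adjusting* for the other module?

## The model

For subject $i$ with trait $Y_i$, covariates $Z_i$ (including an
intercept) and module data vectors $X_{1i}$, $X_{2i}$:

$$Y_i = Z_i^\top\beta + h_1(X_{1i}) + h_2(X_{2i}) +
        h_{12}(X_{1i}, X_{2i}) + \varepsilon_i,
  \qquad \varepsilon_i \sim N(0, \sigma)$$

where each $h$ lives in the function space generated by a kernel. In the
equivalent mixed-model form, $h_\ell \sim N(0, \tau_\ell K_\ell)$ and
$h_{12} \sim N(0, \tau_{12} K_{12})$, so testing a module effect is
testing a variance component against its zero boundary:

* **interaction test** $H_0: \tau_{12} = 0$, with $\tau_1, \tau_2, \sigma$
  free;
* **conditional test of module 1** $H_0: \tau_1 = 0$ adjusting for module
  2 ($\tau_2, \sigma$ free), with the interaction fixed at zero
  throughout; symmetrically for module 2.

The conditional test treats $\tau_{12} = 0$ as part of both null and
alternative: it is a test of a main effect in a model without
interaction, which matches the sequential workflow below (conditional
tests are only consulted when the interaction is not significant).

## Network-structured kernels

All kernels here have the form $K(X_i, X_{i'}) = X_i^\top M X_{i'}$ for a
node-space weighting matrix $M$:

* **unstructured (linear)**: $M = I$ — every node counts equally and
  independently;
* **topology**: $M = T$, the topological overlap matrix. For distinct
  nodes, $T_{ll'} = (L_{ll'} + A_{ll'}) / (\min(k_l, k_{l'}) - A_{ll'} + 1)$
  with $A$ the binary adjacency, $L_{ll'}$ the number of shared
  neighbours, $k_l$ the degree, and $T_{ll} = 1$. $T \in [0,1]$ rewards
  pairs that are directly connected *or* embedded in the same
  neighbourhood, which makes it robust to single spurious or missing
  edges. The kernel smooths effects across network-adjacent nodes.
* **connectivity**: $M = W = \mathrm{diag}(w_l)$ with
  $w_l = \sum_{l' \ne l} T_{ll'}$, the node's total topological overlap.
  Hubs are up-weighted; this kernel bets that hub nodes drive the signal.

The between-module interaction kernel is the element-wise (Hadamard)
product $K_{12} = K_1 \circ K_2$, positive semidefinite by the Schur
product theorem. Second-order polynomial and Gaussian kernels are
available as extras; their constant term is removed so that the Hadamard
product does not smuggle main effects into the interaction kernel (the
Gaussian bandwidth defaults to the number of nodes).

In the degree $k_l$ we use the standard full degree
$\sum_{u \ne l} A_{lu}$: that is the definition under which the
normalization bound $L_{ll'} \le \min(k_l,k_{l'}) - A_{ll'}$ holds and
$T \in [0,1]$ is guaranteed.

## Numerical choices

* **Column standardization** (default on): each module column is centered
  and scaled to unit variance before the kernel product, so that
  $\tau$ scales are comparable across kernels and modules measured on
  different scales do not silently re-weight nodes.
* **Trace normalization** (default on): kernels are rescaled to trace
  $n$. The score test p-value is invariant to kernel scale (the scale is
  absorbed by $\tau$ and the matched moments), but normalization keeps EM
  step sizes comparable across kernel kinds.
* **PSD repair**: $T$ is an overlap measure, not a covariance, and for
  hub-heavy graphs it is indefinite. Because the mixed model needs valid
  covariances, negative eigenvalues of $T$ are clipped to zero before the
  kernel product; the result is flagged and a warning is raised when the
  clip is material. The same eigenvalue-floor-plus-rescale repair is
  applied to the network-implied correlation matrix of the simulator
  (star-like subgraphs make $I + A/2$ indefinite).
* **Degenerate cases**: isolated nodes give zero off-diagonal overlap
  (the TOM denominator is constructed never to hit zero); a target kernel
  that is numerically zero under the null yields $p = 1$ with a warning;
  a kernel proportional to the identity with an intercept-only design
  triggers a flat-likelihood-ridge diagnostic, since only $\tau + \sigma$
  is then identifiable.

## REML/EM estimation

Each null model is fitted by restricted maximum likelihood with an EM
update per free component,

$$\tau' = \tau + \tau^2\,\frac{Y^\top P K P Y - \mathrm{tr}(P K)}{n},$$

(and the analogue with $K = I$ for $\sigma$), where
$P = V^{-1} - V^{-1} Z (Z^\top V^{-1} Z)^{-1} Z^\top V^{-1}$ is the REML
projection at the current iterate. This update never decreases the
restricted log-likelihood, which the test suite asserts on every fit. A
plain EM step, however, approaches the $\tau = 0$ boundary only
harmonically, so the fitter extrapolates along the EM direction with
doubling step lengths and accepts the best candidate that does not
decrease the restricted log-likelihood — the monotonicity guarantee is
preserved by construction while boundary fits converge in tens rather
than thousands of iterations.

Convergence is declared when the relative change of every parameter falls
below `tol` (default `1e-6`), or when the restricted log-likelihood has
stopped improving to numerical resolution (relative gain below `1e-8`
on two consecutive iterations, which happens on flat ridges); hitting
`maxIter` (500) flags the fit with a warning instead of erroring.
Components are floored at `1e-8 * var(y)` during iteration and reported
as zero when they end at the floor.

Because every network kernel is $X M X^\top$ with at most a few dozen
columns, each kernel carries a low-rank factor $C$ with $K = CC^\top$,
and the entire fit runs on Gram matrices via the Woodbury identity: after
a one-time $O(n r^2)$ precompute, an EM iteration costs $O(r^3)$
regardless of $n$. A dense path (explicit $V$, Cholesky) backs factorless
kernels and doubles as the cross-check oracle in the tests; both paths
agree to near machine precision.

## Score tests and p-values

The score statistic for target kernel $K$ is
$T = Y^\top P K P Y / 2$ with $P$ from the corresponding null fit
($V_{12} = \tau_1 K_1 + \tau_2 K_2 + \sigma I$ for the interaction test;
$V_1 = \tau_2 K_2 + \sigma I$ for the conditional test of module 1). Under
the null it is a weighted sum of chi-squares whose weights are the
spectrum of $KP/2$ — available for free from the same small matrices the
fitter works with ($\mathrm{eig}(C^\top P C)/2$ for a factored kernel).

The default p-value evaluates that distribution's upper tail *exactly*
by Imhof's numerical integration over the fitted spectrum, the standard
practice in kernel association testing. Moment-matching alternatives are
provided behind the same interface — a four-moment match to a shifted,
scaled (possibly noncentral) chi-square (`method = "liu"`) and the
classical two-moment Satterthwaite match $\kappa\chi^2_\nu$ with
$\nu = 2e^2/v$, $\kappa = v/(2e)$, $e = \mathrm{tr}(PK)/2$,
$v = \mathrm{tr}((PK)^2)/2$ (`method = "satterthwaite"`) — and the
four-moment match is the automatic fallback where the integral cannot be
resolved (p-values below the integration resolution of about $10^{-9}$).
The choice of default is empirical: on 20-node module kernels the
two-moment match visibly distorts the global null p-value distribution
(a systematic Kolmogorov–Smirnov failure at 1000–2000 null replicates),
the four-moment match repairs most but not all of it for strongly skewed
spectra, and the exact tail is uniform. The matched-moment parameters
($\kappa$, $\nu$) are reported alongside every p-value. When $K$ has a
single non-zero eigenvalue all three methods reduce to the exact scaled
$\chi^2_1$, which the tests verify against the closed form; under the
null design the resulting p-values are uniform by a Kolmogorov–Smirnov
check.

## The simulation engine

The generator reproduces the study conditions the tests are calibrated
under:

* **Scale-free modules**: 20-node Barabási–Albert preferential-attachment
  graphs (one edge per new node, hence connected trees with hubs).
* **Non-scale-free modules**: the induced subgraphs of the 20
  highest-degree and 20 lowest-degree nodes of a 100-node scale-free
  parent (ties broken by node index) — one densely and one loosely
  connected module, neither scale-free. The parent is a static power-law
  fitness graph (exponent 2.5, mean degree 4) rather than a
  preferential-attachment graph: in a preferential-attachment graph every
  edge has an endpoint of degree above the attachment count, and the
  lowest-degree class outnumbers a module, so the bottom-degree induced
  subgraph would *always* be edgeless — leaving the connectivity kernel
  identically zero instead of the intended "loosely connected" module.
  The parent is redrawn until the bottom module has at least one edge.
* **Module data**: i.i.d. multivariate normal subjects, unit variances,
  correlation $1/2$ between directly connected nodes, zero otherwise
  (PD-repaired when needed).
* **Trait**: $\mu_i = \gamma_1 \tilde X_{1i}^\top\beta_1 +
  \gamma_2 \tilde X_{2i}^\top\beta_2 +
  \gamma_{12} \tilde X_{12,i}^\top\beta_{12}$ over the causal columns
  (and their pairwise cross-module products for the interaction), with
  effect sizes uniform on $[-0.2,-0.05] \cup [0.05,0.2]$ — $\beta_{12}$
  from the same distribution — and noise variance
  $\zeta = \widehat{\mathrm{Var}}(\mu)(1-R^2)/R^2$ so the targeted $R^2$
  holds exactly; under the global null $\mu = 0$, $\zeta = 1$.
* **Causal nodes**: the $C$ highest-degree nodes ("hub" mode) or a
  uniform draw ("random" mode), $C \in \{4, 10, 16\}$ of 20.
* **Experiments**: networks are fixed once per experiment from the design
  seed and held across replicates (the experiments model fixed module
  structures, and null calibration is robust to the particular
  realization); causal sets are likewise fixed per experiment; module
  data, effect sizes and traits are redrawn per replicate. Everything is
  reproducible bit-for-bit from the design object.

The defaults define the reference study conditions: 1000 subjects and
1000 replicates for type-I error, 250 for power, $\alpha = 0.05$. The
numeric values of the low/median/high signal levels default to
$R^2 = 0.01 / 0.02 / 0.04$, chosen once so that
desk-scale power falls in the discriminating range, and are
configuration-exposed. The test suite and the acceptance script scale the
replication counts and sample sizes down (e.g. 150–500 replicates,
200–1000 subjects) — these are the package's own desk-scale study sizes,
stated here so that reported Monte-Carlo error bands can be interpreted.

What the generator does *not* emulate: measurement error and skewed,
non-Gaussian abundance distributions; missing data; networks estimated
from the same data used for testing (double dipping); more than two
modules; binary or survival traits. Passing tests therefore show
calibration and power behaviour under an idealized Gaussian module model,
not performance on any particular real assay.

## Known limitations

* The topology and connectivity kernels encode a *prior* about where
  signal sits (smooth over the network; concentrated in hubs). When that
  prior is wrong they can lose power relative to the unstructured kernel.
  In particular, with effect sizes whose signs are random across nodes —
  as in this simulation design — network smoothing has no systematic
  alignment with a pure main-effect signal, and in our desk-scale runs
  the unstructured kernel can dominate the conditional tests under
  random causal-node placement. The structured kernels shine when causal
  nodes are hubs (connectivity) or when effects vary smoothly over the
  network (topology); they are complementary bets, and running both is
  cheap.
* Two-moment matching is accurate at conventional levels but is an
  approximation in the extreme tail; very small p-values should be read
  as orders of magnitude.
* The conditional test fixes $\tau_{12} = 0$ throughout; it is not a test
  of a main effect in the presence of an interaction.
* Hard correlation thresholding (`adjacencyFromCorrelation`, default
  threshold 0.5) is provided for data-driven networks; soft-threshold
  (weighted) adjacencies and generalized overlap variants are out of
  scope, as is module discovery itself — users supply modules.

## Sequential analysis workflow

`runAnalysis()` (and the `netkm.R` CLI) supports
`strategy = "sequential"`: run the interaction test first and consult the
conditional module tests only when the interaction is not significant at
`alpha`; with a significant interaction the marginal "module given
module" question is not well posed and the conditional tests are reported
as not run.
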