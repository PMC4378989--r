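# netKM

Kernel machine regression with **network-structured kernels** for
module-based association analysis of omics data.

## What problem does this solve?

In metabolomics, transcriptomics or genetics one often asks whether a
*module* — a set of bio-elements sharing a pathway or co-regulation
structure — is jointly associated with a continuous trait, and whether
two modules *interact*. Most module tests treat the elements of a module
as an unstructured bag. But elements live on a network: hubs are not
peripherals, and neighbours tend to act together. netKM builds that
structure into the test.

For subject $i$ with trait $Y_i$, covariates $Z_i$ and module
measurements $X_{1i}, X_{2i}$:

$$Y_i = Z_i^\top\beta + h_1(X_{1i}) + h_2(X_{2i}) + h_{12}(X_{1i},X_{2i})
 + \varepsilon_i$$

with each $h$ in the function space of a kernel. In the mixed-model form
$h_\ell \sim N(0, \tau_\ell K_\ell)$, $h_{12} \sim N(0, \tau_{12}K_{12})$,
so module tests become variance-component score tests:

* **interaction**: $H_0{:}\ \tau_{12} = 0$ with statistic
  $T = Y^\top P_{12} K_{12} P_{12} Y / 2$;
* **conditional**: e.g. $H_0{:}\ \tau_1 = 0$ adjusting for module 2,
  $T = Y^\top P_1 K_1 P_1 Y / 2$,

where $P_t = V_t^{-1} - V_t^{-1}Z(Z^\top V_t^{-1}Z)^{-1}Z^\top V_t^{-1}$
is the REML projection under the corresponding null
($V_{12} = \tau_1 K_1 + \tau_2 K_2 + \sigma I$,
$V_1 = \tau_2 K_2 + \sigma I$, ...), fitted by a monotone accelerated
EM. P-values evaluate the weighted chi-squared null distribution's exact
tail over the fitted spectrum (Imhof integration), with four- and
two-moment matching available behind the same interface.

Three kernels per module, all of the form $X M X^\top$:

| kernel | $M$ | encodes |
|---|---|---|
| linear (unstructured) | $I$ | every node equal, no structure |
| topology | TOM $T$, $T_{ll'} = \frac{L_{ll'}+A_{ll'}}{\min(k_l,k_{l'})-A_{ll'}+1}$ | smoothing across network neighbourhoods |
| connectivity | $\mathrm{diag}(\sum_{l'\ne l}T_{ll'})$ | up-weighting of hub nodes |

and the interaction kernel is the Hadamard product $K_1 \circ K_2$.
A simulation engine reproduces the type-I-error and power study designs
(scale-free Barabási–Albert modules; top/bottom-degree submodules of a
larger scale-free network; multivariate-normal module data with
correlation 1/2 along edges; hub or random causal nodes).

## Worked example

Two 20-node scale-free modules, 400 subjects, with a true module-1 main
effect (hub-causal, $R^2 = 0.1$) and no interaction:

```r
library(netKM)
set.seed(7)
net1 <- generateScaleFreeModule(20)
net2 <- generateScaleFreeModule(20)
net1
#> ModuleNetwork: 20 nodes, 19 edges
#>   degrees: min 1 / median 1 / max 9

tom1 <- topologicalOverlap(net1); tom2 <- topologicalOverlap(net2)
X1 <- simulateModuleData(net1, 400, quiet = TRUE)
X2 <- simulateModuleData(net2, 400, quiet = TRUE)
resp <- simulateResponse(X1, X2, selectCausalNodes(net1, "hub", 4),
                         selectCausalNodes(net2, "hub", 4),
                         gamma = c(1, 0, 0), r2 = 0.1)
K1 <- suppressWarnings(topologyKernel(X1, tom1))  # TOM PSD-clip warning
K2 <- suppressWarnings(topologyKernel(X2, tom2))
model <- kmModel(resp$y, K1, K2)

testConditional(model, 1)
#> Kernel machine score test: module 1 given module 2 (H0: h1 = 0)
#>   T = 2297.1206, matched kappa*chi2(df): kappa = 180.5, df = 2.006
#>   p-value = 0.00295
#>   null fit: tau1 = 0, tau2 = 0, tau12 = 0, sigma = 0.357

testInteraction(model)
#> Kernel machine score test: interaction (H0: h12 = 0)
#>   T = 541.9690, matched kappa*chi2(df): kappa = 33.64, df = 9.526
#>   p-value = 0.5595
#>   null fit: tau1 = 0.0233, tau2 = 0, tau12 = 0, sigma = 0.337
```

The conditional test of module 1 — whose hubs carry the simulated signal
— rejects ($p \approx 0.003$); the interaction test, for which no signal
was simulated, does not ($p \approx 0.56$). `tau1 = 0.0233` in the
interaction null fit is module 1's variance component absorbing its main
effect; boundary estimates are reported as 0.

File-based analyses use a config (YAML/JSON) instead:

```r
cfg <- analysisConfig(system.file("extdata", "config.yaml", package = "netKM"))
cfg$outDir <- tempdir()
runAnalysis(cfg)   # writes results.tsv, results.json, log.txt
```

and `inst/cli/netkm.R` wraps the same calls as a command line
(`test`, `simulate`, `tom` subcommands). With
`strategy = "sequential"`, conditional tests run only when the
interaction test is not significant.

Experiment runners replicate whole study designs:

```r
design <- simulationDesign(nSubjects = 300, nReplicates = 100, seed = 11)
runType1Experiment(design)          # 3 kernels x 3 tests rejection rates
```

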