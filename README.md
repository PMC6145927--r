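# statefate

Quantitative analysis of drug-tolerant persister (DTP) cell-state dynamics
in basal-like breast cancer.

Targeted therapies (MEK or PI3K/mTOR inhibitors) leave behind
low-proliferative persister cells occupying characteristic differentiation
states, read out per cell by cytokeratin-19 (luminal), cytokeratin-14
(basal/myoepithelial) and vimentin (mesenchymal) intensities. The central
question the package addresses: is a drug-induced state enrichment produced
by **Darwinian selection** (selective killing of the other state, no
interconversion) or by **cell-state transitions** (interconversion with
equal per-capita death)? It is written for computational biologists
analyzing replicate-well image-cytometry time courses, drug screens and
expression panels of such systems.

## The model

Live cells are K14hi or K14lo; dead cells are absorbing. With per-step
(12 h) probabilities of division (a), death (d) and transition (k), the
compartment vector x = (n_hi, n_lo, n_dead) follows the discrete-time
linear time-invariant system x(t+1) = A(θ)x(t),

```
        | 1 + a_hi − d_hi − k_hl        k_lh             0 |
A(θ) =  |        k_hl            1 + a_lo − d_lo − k_lh  0 |
        |        d_hi                   d_lo             1 |
```

θ is estimated per arm by constrained ℓ2-regularized least squares — the
six rates boxed to [0,1], hypothesis equalities (e.g. k_hl = k_lh = d_hi = 0
for Darwinian selection; d_hi = d_lo for transition-mediated; a_hi = a_lo
everywhere, from EdU data) eliminated exactly — with alternating
minimization over illegible (masked) well×time records. Competing
hypotheses are fitted, simulated forward, and ranked by endpoint error
|ySim − yObs| on state-proportion fold changes versus vehicle.

Around this core: marker gating against DMSO-mean thresholds, cell-state
frequency tables, Shannon diversity H′ = −Σ Pᵢ log Pᵢ, geneset-based
molecular-heterogeneity scores, drug-screen phenotype profiles with k-means
response groups, log-logistic dose–response (Emax/Einf) fits and
Chou–Talalay combination indices (CI75/CI90). A synthetic-data module
generates every input with known ground truth.

## Worked example

```r
library(statefate)

cfg <- groundTruthConfig(seed = 42)       # 15 wells/arm, 12 h grid, 72 h
gen <- generateTimecourse(cfg)
gen$timecourse
#> TimeCourse: 210 records, 30 wells, arms: DMSO, treated
#>   timepoints (h): 0, 12, 24, 36, 48, 60, 72
#>   observed: 168/210 (control arm: DMSO)

est <- estimateCompartments(gen$timecourse, transitionHypothesis())
fit <- fitDynamics(est, transitionHypothesis(), arm = "treated")
fit
#> DynamicsFit under 'transition_mediated' (lambda = 0.001)
#>      aHi      aLo      dHi      dLo      kHL      kLH
#> 0.009920 0.009920 0.016740 0.016740 0.017975 0.216115
#>   6 iterations, converged: TRUE, final objective 1.87398e+06
```

The fitted rates recover the generating treated-arm parameters (a = 0.02,
d = 0.02, k_hl = 0.005, k_lh = 0.2) from noisy data with 20% of records
masked: near-zero division (strong cytostasis), equal modest death, and a
strong K14lo→K14hi transition flux. Comparing hypotheses:

```r
compareHypotheses(gen$timecourse)
#> Hypothesis comparison on arm 'treated' (ranked by endpoint |ySim - yObs|)
#>           hypothesis endpointErrHi endpointErrLo endpointErr trajectoryRMSE
#>  transition_mediated    0.08709626   0.005316584  0.04620642     0.08025184
#>      darwinian_k14hi    1.25613898   0.479154191  0.86764659     0.72823576
#> best supported: transition_mediated
```

The transition-mediated model reproduces the observed ~3-fold K14hi
proportion enrichment at 72 h to within 0.09 on the fold-change scale; the
Darwinian model, forbidden transitions and K14hi death, misses the endpoint
by 1.26 — the data were generated by transitions, and the comparison says
so. Diversity of a state-frequency vector:

```r
shannonIndex(c(0.27, 0.20, 0.38, 0.15))
#> Shannon diversity H' = 1.3277 nats over S = 4 states
```

The full pipeline (simulate → gate → diversity → screen → dynamics) runs
from one config and writes CSV/JSON intermediates plus a manifest:

```r
runPipeline(defaultRunConfig(outDir = "out", seed = 1))
```

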