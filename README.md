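# domfuse

Multi-technique characterization of dissolved organic matter (DOM) in river
water, for aquatic chemists and environmental data analysts who combine
fluorescence, UV–Vis, electrochemical impedance spectroscopy (EIS) and
in-situ probe data into one picture of DOM composition.

The package implements the full chain:

* **EEM preprocessing** — blank subtraction, Rayleigh/Raman scatter excision
  (mask or interpolate), inner-filter screening by dilution with
  back-correction, quinine-sulfate-unit normalization.
* **Fluorescence indices** — FI (McKnight), HIX (Ohno, normalized), BIX
  (Huguet) and the Peak C/Peak T ratio (Coble windows), with replicate
  aggregation.
* **Trilinearity-constrained MCR-ALS** — the core method. A K-sample EEM
  stack is decomposed as

  D_k = S_ex C_k S_em^T + E_k,  k = 1, …, K,

  with common excitation/emission profiles S_ex, S_em and sample-specific
  diagonal contributions C_k, fitted by alternating non-negative least
  squares (exact active-set solver) with a per-component rank-1 constraint
  across the sample mode that makes the solution essentially unique
  (PARAFAC-like). Fit quality is the explained variance
  R² = 100·(1 − Σ(d−d̂)²/Σd²).
* **EIS Bode-phase PCA** — Savitzky–Golay smoothing (0th order, 15 points),
  a common 500-point log10-frequency grid over 0.1–20,000 Hz, SVD-based PCA
  with mean-centering, replicate-score averaging.
* **Multi-block fusion** — a fixed-layout fused table
  [Temp, pH, Cond | EISpc1, EISpc2 | uv254 | FI, HIX, BIX, PeakC/T |
  C1…Cnc] (5 × 16 in the standard configuration) followed by a global
  autoscaled PCA with biplot export.
* **A synthetic campaign generator** with stored ground truth (six Gaussian
  fluorophores at the canonical DOM peak positions, Cole-circuit EIS
  spectra, covarying physicochemistry) so every stage is testable without
  field data.

See `vignettes/dom-multitechnique.Rmd` for the models, conventions and
design decisions.

## Worked example

```r
library(domfuse)

out <- run_pipeline(list(seed = 4, nc = 6))
```

The pipeline simulates a 10-sample campaign (9 rivers along an altitude-like
DOM gradient + a DOM-free blank), preprocesses the EEMs in mask mode,
computes indices, fits six-component trilinear MCR-ALS, runs the EIS PCA and
the fused global PCA. Selected output from this exact run:

```
> out$indices[c(1, 3, 9, 10), 1:5]
 sample_id   fi  hix  bix peak_ct
        R1 5.81 0.58 1.21    3.02
        R3 4.96 0.58 1.31    2.54
        R9 6.01 0.56 1.33    2.11
   DOMfree 0.81 0.50 0.35    0.97

> out$mcr
<mcr_result> 6 components, 10 samples, r2 = 99.5976%, ...
  converged after 67 iterations (simplisma, trilinearity on)

> round(out$eis_pca$explained[1:2], 1)
[1] 84.2 15.7

> round(out$global_pca$model$T, 2)
          PC1   PC2
DOMfree  3.84  2.82
R3      -0.81 -1.12
R5       0.98 -2.03
R6       1.14 -1.28
R9      -5.14  1.61
```

Reading it: the MCR model explains 99.6 % of the stack's variance with six
components; the humified rivers carry high Peak C/Peak T while the blank's
single-cell ratios are noise-dominated (HIX ≈ 0.5 is its closed-form value
for a flat landscape); and on PC1 of the fused PCA the DOM-free blank and
the highest-load river R9 occupy opposite extremes — the sign itself is a
convention, the separation is the result. `out$fused` holds the 5 × 16
fused table, `out$global_pca$biplot` the score/loading pairs for plotting.

Ground-truth comparisons are available for every synthetic run:

```r
m <- match_components(out$mcr, out$campaign$truth)
m$similarity   # cosine similarity of each resolved component to its true one
```

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "domfuse",
                               load_package = "installed")'
```

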