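---
title: "Multi-technique characterization of dissolved organic matter: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-technique characterization of dissolved organic matter: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domfuse)
```

## The problem

Dissolved organic matter (DOM) in river water is a heterogeneous mixture of
humic substances, proteins and degradation products whose composition shifts
with altitude, land use and wastewater influence. No single instrument
captures it: UV--Vis absorption at 254 nm (`uv254`) tracks bulk aromaticity,
excitation--emission matrix (EEM) fluorescence resolves individual fluorophore
classes, electrochemical impedance spectroscopy (EIS) senses ionic and
dielectric behavior that optics miss, and in-situ probes give temperature, pH
and conductivity. `domfuse` implements the full chain from raw spectra to a
fused multi-block ordination, plus a synthetic campaign generator with stored
ground truth so every stage can be validated without field data.

## The trilinear EEM model

One sample's EEM is a 45 x 301 matrix on the standard grids (excitation
230--450 nm in 5 nm steps, rows; emission 250--550 nm in 1 nm steps,
columns). A K-sample campaign is modeled trilinearly:

$$\mathbf{D}_k = \mathbf{S}_{ex}\,\mathbf{C}_k\,\mathbf{S}_{em}^{T} + \mathbf{E}_k,
\qquad k = 1,\dots,K,$$

with common excitation profiles $\mathbf{S}_{ex}$ (45 x nc) and emission
profiles $\mathbf{S}_{em}^T$ (nc x 301) across samples, and a diagonal
$\mathbf{C}_k$ holding sample k's component contributions. Fit quality is the
explained variance

$$R^2 = 100\left(1 - \frac{\sum_{ijk}(d_{ijk}-\hat d_{ijk})^2}{\sum_{ijk} d_{ijk}^2}\right),$$

computed over unmasked cells only (`explained_variance()`).

## Preprocessing chain

`excise_scatter()` removes the three scatter features that violate the
trilinear model: first-order Rayleigh (em = ex), second-order Rayleigh
(em = 2 ex) and the water Raman band at a 3400 cm^-1 shift. Default
half-widths are ±15 / ±15 / ±10 nm, wide enough to fully cover the
generator's ridges; all are configurable via `preprocess_config()`.

Two excision modes are provided and the choice matters:

* **mask** (the pipeline default): excised cells are flagged and excluded
  from index peak picking and from the MCR residuals (0/1-weighted least
  squares). This is the unbiased choice: no invented values enter the fit.
* **interpolate**: excised cells are refilled by linear interpolation along
  the emission axis between their bracketing unmasked neighbors; runs
  touching an emission edge, which lack one bracket, are filled along the
  excitation axis instead (plain constant extension there was found to
  create a low-emission plateau that curve resolution picks up as a
  pseudo-component). Interpolation is required before SVD rank estimation,
  which has no missing-value notion.

The mask default exists because interpolation is *biased* wherever a real
fluorophore peak lies inside an excision band. The tyrosine-like component
(ex 270--280 nm, em 294 nm) is the canonical victim: its emission maximum
sits inside the first-order Rayleigh band for ex >= 280 nm and inside the
Raman band for ex around 265--285 nm, so a linear fill across those bands
systematically displaces its apparent peak. Excluding the cells instead
leaves the remaining (ex <= 260 nm) rows to pin the peak correctly.

The inner-filter effect is handled the way careful bench work handles it: by
dilution, not by a mathematical correction. `inner_filter_screen()` flags a
sample when A254 exceeds a threshold (default 0.05, boundary inclusive — the
conservative end of the customary 0.05--0.10 range) and suggests the
smallest power-of-two dilution that brings it back under;
`apply_dilution_correction()` rescales the recorded EEM to the undiluted
scale afterwards. `blank_subtract()` (clipped at zero, for downstream
non-negativity) and `qsu_normalize()` (division by the 0.01 mg/L quinine
sulfate standard intensity at ex 350 / em 450 nm) complete the chain.

## Fluorescence indices

Four ratio indices are computed per sample (`index_table()` aggregates
replicates as mean ± sd):

| index | definition | convention |
|---|---|---|
| FI | I(370, 470) / I(370, 520) | McKnight |
| HIX | em 435--480 / (em 300--345 + em 435--480) at ex ~254 | Ohno (normalized, bounded in [0, 1]) |
| BIX | I(310, 380) / I(310, 430) | Huguet |
| Peak C / Peak T | max over (320--360, 420--480) / max over (270--280, 330--350) | Coble windows |

Design choices: 254 nm excitation is off the 5-nm grid, so the nearest grid
point (255 nm) is used without interpolation; HIX uses the normalized form
(the classic unbounded ratio is available via `normalized = FALSE`); the
peaks are window *maxima* because "Peak C" and "Peak T" name regions, not
cells; masked cells are never read silently — single-cell indices error,
window maxima skip them. All wavelengths are argument-overridable. All four
indices are invariant to global intensity scaling, so they can be computed
before or after QSU normalization.

## MCR-ALS with the trilinearity constraint

`fit_mcr_trilinear()` operates on the augmented matrix (K samples stacked in
the excitation mode, K·45 x 301). Each alternating-least-squares cycle:

1. solves the augmented excitation-mode factor given the emission profiles
   by *exact* non-negative least squares — an active-set solver on the
   normal equations (Bro & De Jong's fast NNLS). Exact KKT solutions keep
   the unconstrained ALS monotone, unlike clip-after-solve;
2. applies trilinearity per component: the component's augmented profile is
   refolded into a 45 x K block and replaced by its best rank-1
   approximation (leading singular triplet, signs fixed non-negative, tiny
   negative residuals clipped), which simultaneously yields the common
   excitation profile and the per-sample contributions;
3. solves the emission profiles by NNLS given the constrained factor;
4. normalizes profiles to maximum 1, absorbing all magnitude into the
   contributions `C` (the "relative contribution" convention; any fixed
   convention works, this one is documented and stable).

Initialization uses SIMPLISMA-style purest emission variables
(`purest_variables()`: purity = sd/(mean + noise allowance), weighted by the
determinant of the unit-normalized Gram submatrix of the already-selected
columns — deterministic, ties to the lowest index). A random-restart mode
exists for checking rotational stability. Convergence is declared when the
relative change in lack of fit drops below 1e-6 per cycle, or the lack of
fit falls below 1e-8 % (exact fits; relative changes of a vanishing quantity
never settle). A component whose factor collapses to zero mid-iteration
(NNLS zero-lock) is reseeded from the strongest residual column.

With masks present the solver switches to 0/1-weighted least squares
per row/column; masked cells are excluded from all residuals and from
$R^2$. On trilinear data the constraint is essentially free (within half a
percentage point of the unconstrained fit) and buys uniqueness: refitting
from a different initialization recovers the same subspace, and each
component's sample-mode block is exactly rank 1 at exit.

Components are reported sorted by descending total contribution. Per-component
"% variance" is deliberately not reported: resolved components are
non-orthogonal, so per-component variances overlap and do not sum to 100;
total $R^2$ and the contribution matrix carry the same information without
the ambiguity.

`match_components()` (test harness) finds the exact best one-to-one matching
between resolved and true components by cosine similarity of the
excitation/emission profile pairs, enumerating permutations (cheap at
nc <= 8).

## EIS Bode-phase PCA

`assemble_eis_matrix()` interpolates each Bode-phase spectrum onto a common
500-point log10-spaced grid over 0.1--20,000 Hz (interpolation is linear in
log10 frequency; the phase values themselves are never transformed) and
stacks sample-major rows — the 10 x 500 matrix for the five-sample duplicate
design. Optional Savitzky--Golay smoothing (0th order, 15-point window by
default) runs per row; the filter shrinks its window symmetrically at the
edges so a constant signal is a fixed point everywhere, and order 0 is
exactly a centered moving average.

`fit_pca()` is SVD-based (deterministic and exact at these sizes; no NIPALS)
with mean-centering (EIS) or autoscaling (fusion; n−1 denominator — material
at n = 5 and therefore documented). Scores are $U\Sigma$, loadings
orthonormal, explained variance $\sigma_i^2/\sum\sigma^2$. The sign of each
loading column is fixed so its largest-magnitude entry is positive; published
score plots use arbitrary sign conventions, so comparisons should be made on
explained variance and score geometry, not raw signs.

## Multi-block fusion

`build_fused_table()` concatenates five blocks for the EIS-measured sample
subset, in fixed column order: physicochemical (Temp, pH, Cond), averaged
EIS scores (EISpc1, EISpc2), uv254, the four indices, and the nc MCR
contributions — 3+2+1+4+6 = 16 variables for the standard configuration.
Every block must cover exactly the same samples; asymmetric differences are
reported by name. MCR contributions enter as raw C-row values (not
renormalized per sample). Replicate means are used for any replicated block.
`run_global_pca()` autoscales and fits the global PCA, exporting biplot data
(sample scores + variable loadings on common axes).

`run_pipeline()` chains everything — simulate or load, preprocess, indices,
MCR, EIS PCA, fusion, global PCA — with per-stage logging, deterministic
reruns under a fixed seed, and graceful degradation (no EIS spectra: the EIS
and fusion stages are skipped with a warning). Artifacts (CSV/JSON tables,
fit report, stage log) are written when `out_dir` is set.

## The synthetic campaign generator

`simulate_campaign()` emulates a 10-sample field campaign (9 rivers along an
altitude-like DOM gradient plus a DOM-free Milli-Q blank):

* **EEMs** follow the trilinear model built from six Gaussian fluorophores at
  the canonical peak positions (C1 340/474, C2 350/430, C3 320/399,
  C4 300/354, C5 280/338, C6 270/294 nm), each with a deep-UV secondary
  excitation shoulder at 245 nm at half amplitude. Band shapes are Gaussian
  in wavelength (sigma 20 nm excitation, 30 nm emission) — bandwidths are
  generator defaults, not literature values. Contributions scale with DOM
  load through component-specific response exponents (terrestrial humics
  ~linear, anthropogenic fractions superlinear, microbial fractions
  sublinear); the distinct exponents double as the guarantee that the
  contribution columns are linearly independent, which trilinear uniqueness
  requires. A bounded ±35 % log-uniform jitter adds sample individuality
  while keeping every fraction above the noise floor.
* **Scatter and noise**: Gaussian ridges (sigma 4 nm Rayleigh, 3 nm Raman)
  sit well inside the default excision bands; i.i.d. Gaussian noise defaults
  to 1 % of the *measured* stack's maximum intensity, and a small constant
  instrument background (2 % of maximum) is present in every EEM — the blank
  keeps it, river samples lose it through blank subtraction. Samples whose
  undiluted A254 exceeds the inner-filter threshold (by construction the
  three highest-load rivers) are generated as measured diluted: contributions
  scaled down, dilution factor recorded, noise applied after dilution, for
  the preprocessing chain to undo.
* **EIS** uses a single-dispersion Cole element,
  $Z(\omega) = R_s + R_{ct}/(1+(i\omega\tau)^\alpha)$, phase = arg Z in
  degrees (in [-90, 0]). Conductivity maps inversely to $R_s$, DOM load
  lowers $\alpha$ (broader dispersion; the blank is the most ideally
  capacitive) and raises $\tau$ (slower interfacial relaxation), giving the
  ensemble two genuine variance modes. Two replicates with 0.2° phase noise
  are generated for the blank plus four rivers, matching the five-sample
  duplicate design.
* **Covariates**: uv254 is affine in DOM load, conductivity monotone
  (quadratic) in it, temperature and pH drift plausibly along the gradient.
  uv254 and conductivity rank orders equal the DOM-load rank order by
  construction.

What the generator does *not* emulate: inner-filter nonlinearity (dilution
is assumed to remove it exactly), wavelength-dependent instrument response,
correlated (non-i.i.d.) noise, pH/temperature effects on fluorescence
quantum yields, non-Gaussian (skewed) emission bands, and any physical model
of the measuring device's oxide microstructure. Passing tests on synthetic
campaigns therefore demonstrate the correctness of the algorithms under the
stated model, not instrument-level fidelity.

## Numerical choices and degenerate inputs

* Grid equality uses a 1e-9 tolerance (nm; relative for Hz). Wide-CSV EEMs
  are rows-excitation by definition; transposed files are rejected, not
  guessed.
* NNLS subproblems with numerically singular Gram matrices fall back to a
  1e-10-scaled ridge.
* `estimate_rank()` requires an interpolated (mask-free) stack. On noisy
  stacks the cumulative-squared-singular-value criterion is dominated by the
  broadband noise floor: with noise at 1 % of the stack maximum the noise
  carries a few percent of the total sum of squares, so the default 0.999
  threshold intentionally over-counts; the returned scree (singular values
  and cumulative fractions) is the object to inspect, and the gap after the
  true rank remains unmistakable.
* Under 1 % noise the emission-band argmax on the 1-nm grid has an inherent
  jitter of a few nm (a 30-nm-wide Gaussian changes by < 0.1 % over 1 nm
  near its peak, below the profile-estimate noise); excitation maxima on the
  5-nm grid are stable. Recovery tests treat excitation maxima exactly and
  emission maxima to within that jitter.
* Single-cell index reads on masked cells are errors naming the cell; zero
  denominators are undefined-result errors; fully masked emission rows stop
  interpolation with the offending excitation wavelengths listed.
* The blank keeps its measured EEM in the pipeline (it is the reference, so
  it is not subtracted from itself); its indices are computed from that
  near-flat background landscape, so its HIX sits near 0.5 (the two windows
  average the same noise) while its single-cell ratio indices are
  noise-dominated and should not be interpreted.

## Problem sizes

The package's own test suite and examples run campaign-scale problems:
K = 10 samples of 45 x 301 EEMs (a 450 x 301 augmented matrix), nc up to 6,
500-point EIS spectra in duplicate for five samples, and a 5 x 16 fused
table — the sizes of the emulated study design. A six-component masked-mode
fit converges in well under a minute on one core; three-component
experiments in seconds.

## Known limitations

* Weak samples near the detection limit can yield undefined single-cell
  indices (a zero denominator after blank subtraction and clipping); this is
  reported as an error rather than silently propagated. It is the expected
  behavior for a blank-like sample measured at 1 % full-scale noise.
* Highly collinear contribution patterns across samples (all compositions
  proportional) remove the leverage the trilinearity constraint needs for
  uniqueness; the generator avoids this by design, real campaigns may not.
* Split-half validation is not implemented (a 10-sample campaign cannot
  support it); robustness is assessed via random-restart subspace stability
  instead.
* No PARAFAC implementation is included; the trilinearity-constrained
  MCR-ALS solution plays that role.
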