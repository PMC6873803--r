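---
title: "Imaging-FCS diffusion-law analysis and acyl-chain conformer densities: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imaging-FCS diffusion-law analysis and acyl-chain conformer densities: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rafttrace)
```

`rafttrace` implements two analyses around the question of how a membrane
probe moves in, and samples, the laterally heterogeneous plasma membrane:

1. **Imaging FCS with the diffusion law.** Camera-based (TIRF) fluorescence
   correlation spectroscopy records an intensity trace in every pixel.
   Correlating each trace and fitting the imaging-FCS model yields a
   diffusion coefficient and particle number per pixel; software-binning
   pixels after acquisition enlarges the observation area, and the linear
   relation between diffusion time and effective area — the FCS diffusion
   law — has an intercept whose sign diagnoses sub-resolution membrane
   organization (free, domain-confined, or meshwork-hop diffusion).
2. **Acyl-chain conformer densities.** Fatty-acid ligands (e.g., the
   16-carbon palmitate/palmitoleate that acylate Wnt proteins) are parsed
   from PDB files, rigidly superposed on a reference over their carbon
   atoms, and the RMSDs summarized as a 20-bin, dataset-size-normalized
   distribution, read as the probability of being conformationally close to
   the reference.

A Brownian-dynamics simulator with a camera model makes the whole chain
verifiable end to end without external data.

## The imaging-FCS model

For a square (binned) pixel of side $a$ and a Gaussian PSF with $1/e^2$
radius $\omega_0$, the temporal autocorrelation of the intensity
fluctuations in one pixel is modelled as

$$G(\tau) = \frac{1}{N}\left[\frac{g(p(\tau))}{g(p(0))}\right]^2
  \left[1 + \frac{F_t}{1-F_t}\,e^{-\tau/t_f}\right] + G_\infty,
  \qquad
  g(p) = \operatorname{erf}(p) + \frac{e^{-p^2}-1}{\sqrt{\pi}\,p},
  \quad
  p(\tau) = \frac{a}{\sqrt{4 D \tau + \omega_0^2}},$$

with fit parameters $N$ (mean particle number in the observation area), $D$
(diffusion coefficient), optional triplet fraction $F_t$ and relaxation
time $t_f$, and offset $G_\infty$ (`acf_model()`). Several diffusive
components with brightnesses $B_i$ and numbers $\langle N_i\rangle$
combine with amplitudes $\alpha_i = B_i^2\langle N_i\rangle / (\sum_i
B_i \langle N_i\rangle)^2$ (`acf_model_components()`); the default is a
single component, which is also what per-pixel fits of the experimental
workflow use.

The effective observation area is the pixel convolved with the PSF,

$$A_{\mathrm{eff}} = \frac{a^2}{g(a/\omega_0)^2},$$

equal to the convolution definition $(\int W)^2 / \int W^2$ with
$W = \mathrm{square}(a) \otimes \mathrm{Gaussian}(\omega_0)$; the package
validates the closed form against numerical quadrature to better than
0.1% over $a/\omega_0 \in [0.05, 10]$. Limits: $A_{\mathrm{eff}} \to a^2$
for $\omega_0 \ll a$ and $\to \pi\omega_0^2$ for $a \ll \omega_0$.

### Correlation estimation

`compute_acf()` evaluates
$G(\tau) = \langle\delta F(t)\,\delta F(t+\tau)\rangle / \langle F\rangle^2$
on a pseudo-logarithmic lag grid (16 unit lags, then 8 lags per doubling
block, up to a quarter of the trace). Each retained lag is computed with
the exact direct estimator rather than by cascaded coarse-graining: classic
multi-tau correlators average the signal into wider bins at longer lags,
which introduces a triangular-smoothing bias relative to the direct sum.
Computing the exact estimator at multi-tau-spaced lags keeps the
logarithmic economy of the scheme while agreeing with the naive double sum
to machine precision (`acf_direct()` is the loop-based reference). Per-lag
variances come from splitting the trace into 8 contiguous segments and
taking the variance of per-segment estimates; lags longer than half a
segment inherit the largest estimated variance, and short traces fall back
to unit weights.

### Fitting and the diffusion time

`fit_acf()` performs weighted Levenberg–Marquardt least squares
(`minpack.lm`), with $N$ initialized from the first-lag amplitude, $D$ by
inverting the model at the half-decay lag, and bounds $D \in (10^{-6},
10^3)\ \mu m^2/s$, $F_t \in [0, 0.5]$. The diffusion time is defined as

$$\tau_D := A_{\mathrm{eff}} / D_{\mathrm{fit}}.$$

The experimental literature states that ACFs are "fitted to obtain the
diffusion time" without fixing the proportionality constant; this choice
makes the diffusion law exact with zero intercept and
$D_{\mathrm{eff}} = D$ for ideal free diffusion. Any other positive
constant would rescale the intercept magnitude — and therefore the
numerical threshold — but never its sign; the classification threshold is
configurable for that reason.

## The diffusion law and mode classification

`build_diffusion_law()` bins the stack at each requested factor (default
1–5), fits every super-pixel, and pools converged fits into one
$\tau_D$ per binning (median across super-pixels, variance from the median
absolute deviation; the median is robust to edge pixels where molecules
enter and leave the field). `fit_diffusion_law()` then fits

$$\tau_D(A_{\mathrm{eff}}) = \tau_0 + A_{\mathrm{eff}} / D_{\mathrm{eff}}$$

by variance-weighted least squares. The intercept classifies the mode
(`classify_mode()`): $|\tau_0| \le 0.2$ s free diffusion, $\tau_0 > +0.2$ s
domain-confined diffusion, $\tau_0 < -0.2$ s hop diffusion — the published
rule, with the threshold configurable because it is tied to the $\tau_D$
convention above. A non-positive slope is reported (flagged, with
$D_{\mathrm{eff}} = \mathrm{NA}$) rather than made fatal, since noisy
confined data can produce one. Replicates aggregate as mean ± sample SD
(n − 1) of $\tau_0$ (`aggregate_replicates()`).

## The synthetic-data generator

### Trajectories

`simulate_trajectories()` runs 2D Brownian dynamics in a periodic square
box (periodicity keeps the intensity trace stationary, which the ACF
estimator needs). Free steps are Gaussian with per-axis variance
$2 D\,\mathrm{d}t$. Two hindered regimes are built in:

* **Domain mode** — fixed, non-overlapping circular domains placed by
  rejection sampling to a target area coverage; interior diffusivity
  $D_{\mathrm{in}}$; crossings into/out of a domain accepted with
  probabilities $P_{\mathrm{enter}}$/$P_{\mathrm{exit}}$, rejected
  crossings reflected radially at the circle. This is the quasi-static
  picture of ordered membrane domains.
* **Hop mode** — a square meshwork of side $L$; compartment-boundary
  crossings accepted with probability $P_{\mathrm{hop}}$, otherwise
  reflected at the crossed line (the cytoskeleton picket-fence picture).

### Reference regime parameters

Defaults (also exposed as `regime_preset()`) represent one membrane-probe
scenario per regime at EGFP-like imaging conditions: 0.24 µm sample-plane
pixel (24 µm camera pixel, 100× objective), PSF $1/e^2$ radius 0.24 µm,
3 ms exposure, 60 particles in a 6 µm box (≈1.7 µm⁻²), 300 photons per
molecule per frame over background 10.

* free: $D = 0.5\ \mu m^2/s$, a typical membrane-protein mobility;
* domain: dense nanodomains, radius 0.1 µm (well below the pixel), 40%
  coverage, $D_{\mathrm{in}} = 0.05$, $P_{\mathrm{enter}} = 0.01$,
  $P_{\mathrm{exit}} = 0.02$. Residence times of ~1–2 s make the smallest
  observation areas exchange-dominated (the correlation time barely grows
  with area) while the largest areas are transport-dominated; the
  resulting concave $\tau_D(A_{\mathrm{eff}})$ yields intercepts of
  roughly +1 to +2.5 s, the scale reported for raft-partitioning probes.
  Sparse-strong-trap parameterizations were deliberately not used: when
  escape is fast and re-trapping frequent, trapping only renormalizes the
  long-range diffusion coefficient and the intercept is driven negative,
  which is meshwork phenomenology, not domain confinement.
* hop: mesh 1.0 µm, $P_{\mathrm{hop}} = 0.05$, giving intercepts of
  −0.3 to −0.5 s.

Free runs default to 10,000 frames; the hindered regimes to 20,000 frames
(60 s), because their slow correlation decays need lags out to ~15 s. These
sizes keep a full three-regime, five-replicate comparison within minutes on
one CPU while leaving comfortable margins on every classification.

### Camera model

`render_stack()` deposits, per frame, each particle's expected photons as
the integral of a normalized Gaussian PSF over each pixel (truncated at
$4\omega_0$, mass loss < 10⁻¹²), adds background, then applies the EMCCD
cascade: Poisson photons, gamma-distributed gain (shape = photons, scale =
`em_gain`) and additive Gaussian read noise, rounded to integer counts.
`em_gain = 1` skips the gamma stage entirely so that the degenerate setting
is exactly Poisson. When the simulation step is finer than the exposure,
frames average $\lceil\text{exposure}/\mathrm{d}t\rceil$ sub-step deposits.
The default is one sub-step per frame: the fit model assumes
instantaneous sampling, so integrating intra-frame motion would bias the
recovered $D$ relative to the model at high diffusivities; sub-stepping is
available where motion blur itself is the object of study. Stacks are
written as 16-bit multi-page TIFF with a JSON sidecar carrying $a$,
$\omega_0$, exposure, seed and a configuration hash.

### What the generator does and does not emulate

Simulated membranes are flat and 2D, the PSF purely lateral, photophysics
limited to the optional triplet flag; there is no bleaching, no axial
motion, no membrane undulation, and no attempt to reproduce live-cell
intensity statistics. Passing the end-to-end tests therefore shows that
the estimator chain is correct and that the diffusion-law sign logic
responds to genuine confinement/meshwork physics — not that any particular
biological τ₀ magnitude will be reproduced on real cells (raw stacks for
the published values are not available, and magnitudes depend on the
$\tau_D$ convention above).

## Conformer analysis

`parse_ligands()` extracts one conformer per (model, chain, residue
number, insertion code) bearing the requested residue code from PDB
ATOM/HETATM records. Alternate locations resolve per atom name to the
highest occupancy, ties to the lexicographically first altloc; elements
come from columns 77–78 with a fallback to the atom-name initial;
malformed coordinates fail with the line number. Multiple ligand copies in
one entry count as separate conformers.

`superpose_carbons()` computes the optimal proper rigid superposition
(Kabsch, via SVD with a determinant correction) over carbons matched by
name (C1…C16 by default). Reflections are forbidden — conformers are
physical molecules and chirality must be preserved. Conformers missing
named carbons are matched on the common subset and flagged; fewer than 3
matched pairs is an error (the analysis counts such exclusions).

`rmsd_density()` bins per-conformer RMSDs into 20 equal-width bins over
$[0, \max \mathrm{RMSD}]$ by default (a fixed range is available for
cross-dataset comparison) and divides counts by the dataset size — the
number of successfully superposed conformers, so that frequencies always
sum to 1. This is a normalized frequency, not a per-Å density; plots label
it accordingly. `closest_conformer()` reports the argmin RMSD, ties broken
lexicographically by source id.

The synthetic ensemble builder (`generate_conformers()`) produces
idealized carbon chains with exact bond length (1.53 Å) and angle
(111.5°), dihedrals either all-trans, drawn from the trans/gauche±
rotamers (180°, ±65°) with configurable weights, or uniform; a designated
cis bond (dihedral fixed at 0°) emulates the permanent kink of a
monounsaturated 16:1 chain. Both saturated-style and cis-kinked rotamer
ensembles span many RMSD bins — the package's check of the observation
that both saturated and monounsaturated 16-carbon chains flex from linear
to kinked, without asserting which lies closer to any reference.

## Numerical choices and edge cases

* Correlation lags start at one frame time; zero-mean traces are an error
  (undefined normalization), constant traces give $G \equiv 0$.
* Pooled $\tau_D$ uses only converged fits; fewer than 3 binnings with
  converged fits aborts the diffusion law.
* The weighted line fit falls back to unit weights when any pooled
  variance is missing or non-positive; two points interpolate exactly with
  a warning.
* Degenerate RMSD distributions (all conformers within 1e-9 Å of the
  reference) bin over $[0, 1]$ Å so the histogram stays well-defined.
* All randomness flows through R's RNG (also inside the compiled
  simulation kernels), so a seed fixes every result bitwise; pipeline
  stages derive per-stage seeds from one master seed.

## Reproducible runs

`run_pipeline()` (and the `inst/cli/rafttrace` script) orchestrates
simulate → correlate/fit → diffusion law, or the conformer analysis, from
a JSON config; every run writes CSV tables, a JSON report with config
hash, package version and seed, and a text summary. The `demo` subcommand
runs a built-in free-diffusion configuration end to end.

```{r demo, eval = FALSE}
rep <- run_pipeline(list(subcommand = "demo"), out = "demo_run", seed = 1)
rep$stages$difflaw$mode   # "free"
```

The configuration is a JSON object with a section named after the
subcommand; every key mirrors an argument of the corresponding function:

```json
{
  "subcommand": "simulate | imfcs | difflaw | conformers | demo",
  "simulate":   {"sim": {"mode": "free", "D_out": 0.5, "n_steps": 10000},
                 "optics": {"roi": [16, 16], "n_frames": 10000}},
  "imfcs":      {"stack": "out/stack.tif", "binnings": [1, 2, 3, 4, 5],
                 "pixel_size": 0.24, "psf_e2_radius": 0.24,
                 "exposure": 0.003},
  "difflaw":    {"stacks": "out/*.tif", "binnings": [1, 2, 3, 4, 5],
                 "threshold": 0.2, "label": "condition"},
  "conformers": {"ligand": "PLM", "pdb_dir": "pdbs/",
                 "reference": {"file": "ref.pdb", "code": "PLM",
                               "chain": "A", "res_seq": 1},
                 "bins": 20},
  "demo":       {"mode": "free", "n_frames": 10000}
}
```

`sim` keys map to `sim_config()`, `optics` to `optics_config()`; the
optics triple under `imfcs` is only needed for sidecar-less TIFFs. Seeds
are taken from the CLI/`run_pipeline()` master seed unless given
explicitly inside `sim`/`optics`.

## Known limitations

* The single-component fit applied to two-population (trapped + mobile)
  signals yields an effective compromise $\tau_D$; this is faithful to the
  experimental workflow but means simulated intercept magnitudes depend on
  the regime parameters, not only on their sign class.
* Hop-mode acceptance is per axis, which slightly decouples x and y
  crossings of a corner; at the step-to-mesh ratios used this is
  negligible.
* The intercept threshold (0.2 s) is meaningful only under the
  $\tau_D = A_{\mathrm{eff}}/D$ convention; other conventions require
  rescaling it.
* PDB parsing covers ATOM/HETATM/MODEL records as needed for ligand
  extraction; it is not a general mmCIF/PDB reader.
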