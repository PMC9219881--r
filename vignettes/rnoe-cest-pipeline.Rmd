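---
title: "Quantifying relayed NOE signals from CEST z-spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying relayed NOE signals from CEST z-spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnoecest)
```

## The signal chain

Chemical exchange saturation transfer (CEST) detects dilute labile protons
indirectly: saturating them with an off-resonance RF pulse reduces the water
signal through exchange. Plotting the normalized water signal $Z(\Delta\omega)
= S(\Delta\omega)/S_0$ against the saturation offset $\Delta\omega$ (ppm,
water at 0) gives the z-spectrum. The relayed nuclear Overhauser effect (rNOE)
bands at $-3.5$ and $-1.6$ ppm are small dips riding on two much larger
backgrounds — direct water saturation and the broad semisolid magnetization
transfer (MT) — so quantifying them requires a multi-stage chain. This
package implements that chain end to end:

1. **Normalization.** Raw per-offset intensities are divided by a far-offset
   reference acquisition (333 ppm for imaging, 250 ppm for NMR-tube
   homogenates) where saturation is negligible.
2. **B0 correction.** A Lorentzian is fitted to a low-power WASSR sweep
   ($-1$ to $1$ ppm, 0.1-ppm steps); its center is the per-voxel B0 offset.
   The z-spectrum is then re-interpolated (natural cubic spline, flat
   extrapolation at the edges) onto the nominal grid shifted by that offset.
3. **Background removal.** A two-pool model $Z = 1 - L_\mathrm{water} -
   L_\mathrm{MT}$ of Lorentzians
   $L(\Delta\omega) = A\,(\Gamma/2)^2 / ((\Gamma/2)^2 +
   (\Delta\omega-\delta)^2)$ is least-squares fitted using only offsets with
   $|\Delta\omega| \le 0.8$ ppm or $|\Delta\omega| \ge 6$ ppm, so that the
   labile bands at $3.5$, $2$, $-1.6$ and $-3.5$ ppm never pull on the
   background. The water center is pinned at 0 after B0 correction; the MT
   center floats in $[-3, 0]$ ppm; the MT amplitude is taken as the MT pool
   size $f_m$.
4. **AREX residual.** The gap between the measured and fitted spectra is
   converted to an exchange-rate-like quantity corrected for the water T1
   and the MT pool size:
   $$\mathrm{AREX}_{resid}(\Delta\omega) =
     \left(\frac{S_0}{S_{meas}} - \frac{S_0}{S_{fit}}\right)
     \frac{1}{T_1 (1 + f_m)},$$
   reported in % s$^{-1}$. Dips below the background give positive values.
5. **rNOE isolation.** In vivo, a single Gaussian bounded to
   $\mu \in [-3.9, -3.1]$ ppm, $\sigma \in [0.2, 1.5]$ ppm is fitted on the
   $[-6, -1]$ ppm window; its analytic area $A\sigma\sqrt{2\pi}$ is the
   rNOE($-3.5$) AUC and the trapezoidal integral of the fit residual over
   $[-1.9, -1.3]$ ppm is the rNOE($-1.6$) AUC. For homogenates, both
   components on one spectral side are fitted jointly with two Gaussians
   (negative side: rNOE($-3.5$)/rNOE($-1.6$); positive side: amide at 3.5,
   amine at 2 ppm) and both AUCs are analytic.

T1 enters step 4 from relaxometry fits: per-voxel saturation recovery
$I(t) = I_0 (1 - e^{-t/T_1})$ on the variable-TR schedule, or, for
homogenates showing two relaxation components, normalized inversion recovery
$I(t) = 1 - 2\,(x_a e^{-t/T_{1,a}} + (1-x_a) e^{-t/T_{1,b}})$ with the
population average $T_{1,avg} = x_a T_{1,a} + (1 - x_a) T_{1,b}$.

A scalar walk-through:

```{r scalar-chain}
pools <- default_brain_pools("normal")
offsets <- cest_offsets_invivo()
raw <- simulate_zspectrum(pools, offsets, noise_sd = 0.002, seed = 1)$signal * 1000

z <- normalize_zspectrum(offsets[-1], raw[-1], raw[1])
b0 <- fit_wassr(simulate_zspectrum(list(pool_spec(0, 0.5, 0.7, "water")),
                                   wassr_offsets(), noise_sd = 0.002, seed = 1))
zc <- apply_b0_correction(z, as.numeric(b0))
bg <- fit_two_pool(zc)
ar <- arex_resid(zc, bg, t1 = 1.8)
deconvolve_invivo(ar)
```

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| Two-pool fit mask | $|\Delta\omega|\le 0.8$ or $\ge 6$ | ppm | excludes every labile band while pinning water line and MT tails |
| Water FWHM bounds | 0.2–5 | ppm | direct saturation width at 0.3–0.9 µT |
| MT FWHM bounds | 5–150 | ppm | semisolid line is 1–2 orders broader than water |
| MT center bounds | $[-3, 0]$ | ppm | the MT line sits slightly upfield of water |
| rNOE($-3.5$) center bounds | $[-3.9, -3.1]$ | ppm | "approximately $-3.5$ ppm" with slack for lineshape asymmetry |
| rNOE($-1.6$) band | $[-1.9, -1.3]$ | ppm | the band that defines the rNOE($-1.6$) AUC |
| T1 bounds | 0.001–20 | s | plausible range at 7–18.8 T |
| NMR bands | ±0.03 around 0 and 0.68; 3.28–3.38; 1.45–1.65 | ppm | named singlet centers with a conservative half-width |
| Proton correction | on (×12/3) | – | TMS has 12 equivalent protons, the cholesterol C18 methyl 3 |

## What the synthetic generators emulate — and what they do not

The simulators produce every input the pipeline consumes with the
statistical structure the analysis assumes. Z-spectra are sums of
Lorentzian dips subtracted from unity — deliberately the same model family
the background fitter uses, not a Bloch–McConnell integration, so
generate-then-fit round trips are exact and test fitting machinery rather
than model mismatch. Saturation-power dependence is emulated by rescaling
pool amplitudes (`scale_pools()`), not by spin physics. Noise is additive
Gaussian on the normalized intensity, a good approximation for high-SNR
magnitude data; Rician floor effects at low SNR are not modelled. The
two-region phantom stacks carry a smooth B0 ramp, per-region T1, and a
ground-truth record of every injected parameter.

Passing tests therefore demonstrate that the chain recovers what its own
model family generates, that the background mask isolates the labile bands,
and that contrast injected at $-1.6$ ppm survives the whole voxelwise
pipeline. They cannot demonstrate robustness to super-Lorentzian MT
lineshapes, asymmetric direct saturation, motion, or B1 inhomogeneity —
none of which the generators produce.

In-vivo pool linewidths are not tabulated in the literature this package
follows; the defaults in `default_brain_pools()` are plausible fixture
values chosen once for testing, not measurements.

## Numerical choices

- **Optimizer.** All nonlinear fits use Levenberg–Marquardt
  (`minpack.lm::nls.lm`) with box constraints and tight tolerances
  (`ftol = ptol = gtol = 1e-15`), so noiseless round trips recover
  generating parameters to $10^{-6}$ (mono-exponential) and $10^{-4}$
  (bi-exponential, two-pool) relative error.
- **Multi-start.** The bi-exponential model is multi-modal: fits start from
  $x_a \in \{0.2, 0.5, 0.8\}$ crossed with T1 pairs log-spaced around the
  zero-crossing time $t_{null}/\ln 2$, and the best residual wins. The
  two-pool fit uses two starts (thin-water/broad-MT and the reverse).
- **Degeneracy.** If a mono-exponential fit matches the bi-exponential
  residual within tolerance, the fit is returned with $x_a = 1$,
  $T_{1,a} = T_{1,b}$ and a `degenerate` flag — the averaged T1 is still
  well defined. Labels are ordered $T_{1,a} \le T_{1,b}$ by a post-hoc swap.
- **Integration.** Band AUCs use trapezoidal integration with linearly
  interpolated band endpoints, making results invariant to grid spacing and
  axis direction; a `sum_spacing` compatibility mode reproduces the
  grid-dependent raw-sum reading.
- **Interpolation.** B0 correction uses a natural cubic spline; at 0.1-ppm
  sampling near water the interpolation error is negligible against the
  linewidths. Offsets shifted outside the sampled range take the edge value
  and raise a warning.
- **Degenerate inputs.** All-zero voxels, bands outside the sampled range,
  non-positive references and zero-variance groups raise errors or flags at
  the boundary of each operation rather than propagating NaN.

## Design choices where the design was open

- **Bi-exponential normalization.** The fit assumes input normalized so
  $I(\infty) = 1$. For raw curves, `normalize = TRUE` divides by the mean of
  the two longest-delay intensities; it is off by default because
  re-normalizing already-normalized data whose tail has not fully recovered
  (e.g. $T_{1,b} = 3$ s sampled to 10 s) would bias the fit.
- **rNOE($-1.6$) amplitude in vivo.** The single-Gaussian deconvolution
  defines no $-1.6$ ppm component, so its "amplitude" is taken as the
  maximum of the fit residual inside $[-1.9, -1.3]$ ppm; the rNOE($-3.5$)
  amplitude is the fitted Gaussian height.
- **Filtering stage.** The 3×3 median filter (edge-replicating, NA-aware)
  is applied to the final parameter maps, preserving per-voxel spectral
  fits; `filter_stage = "raw"` reproduces the alternative reading of
  smoothing the offset images first.
- **Group test.** The two-group comparison defaults to Welch's
  unequal-variance t-test — the safe choice for small groups of unequal
  spread — with Student and Mann–Whitney variants exposed. Stars follow the
  `*` p < 0.05, `**` p < 0.001 convention.
- **Total-lipid band.** The alkyl band defaults to 1.45–1.65 ppm; the
  narrower 1.45–1.55 ppm reading is available by configuration
  (`read_pipeline_config()`).
- **Interface.** The pipeline is exposed as R functions plus the
  `scripts/acceptance.R` driver; the operations compose naturally inside R,
  so no shell subcommand layer is provided.

## Problem sizes

The test suite and the acceptance script run entirely on simulated data:
phantoms of 64×64 voxels on the 90-offset in-vivo schedule over five seeds
for the end-to-end contrast check (smaller 12–32 voxel grids for unit
tests), 300-seed Monte-Carlo loops for bias checks, and $10^4$ replicates
at $n = 9$ per group for the type-I calibration. These sizes were chosen so
the whole suite completes in a few minutes while keeping Monte-Carlo
standard errors well below the tolerances being asserted.

## Known limitations

- The Lorentzian-sum forward model shares its family with the fitter;
  agreement on simulated data says nothing about Bloch–McConnell accuracy.
- AREX baselines are sensitive to the background fit mask: over-wide direct
  saturation windows can drive the $-1.6$ ppm baseline negative. The mask
  is exposed (`mask_near`, `mask_far`) rather than hidden.
- The glycoNOE band near $-1$ ppm is not isolated; it falls outside the
  residual band by construction.
- No registration, motion correction or B1 mapping: stacks are assumed
  geometrically consistent.
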