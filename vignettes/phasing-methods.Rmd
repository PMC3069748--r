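---
title: "Likelihood-based experimental phasing with phasekit: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likelihood-based experimental phasing with phasekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

phasekit implements, at desk scale, the computational core of automated
experimental phasing for macromolecular crystallography: from Friedel-pair
amplitudes to located anomalous-scatterer sites, likelihood phases with
Hendrickson–Lattman (HL) statistics, density-modified maps with calibrated
figures of merit, and a determined hand.  This vignette is the package's
own account of the models it fits, the parameters that matter, and the
numerical decisions behind them.

## The scientific problem

A SAD experiment measures only amplitudes: for each unique reflection $h$
the two Friedel mates $|F^+| = |F(h)|$ and $|F^-| = |F(-h)|$ with
uncertainties $\sigma^\pm$.  Anomalous scattering ($f'' > 0$ on a few
"heavy" atoms) breaks Friedel's law; the small Bijvoet differences
$\Delta F = |F^+| - |F^-|$ carry the phase information.  Phasing proceeds
in stages: estimate the heavy-substructure amplitudes $|F_A|$, locate the
sites, compute phase probability distributions from the substructure,
improve them by density modification, and resolve the enantiomorph
(hand) ambiguity.

## The joint Friedel-pair model

Everything downstream of site location rests on one generative model per
acentric reflection.  Writing $H^+ = F_H(h)$ and $H^- =
\overline{F_H(-h)}$ for the substructure structure factors expressed in a
common frame, and $U$ for the shared non-substructure channel (the
protein, plus whatever part of the heavy signal the model does not
explain),

$$ Z^+ = \beta H^+ + U + \epsilon^+ , \qquad
   Z^- = \beta H^- + U + \epsilon^- , $$

with $U$ complex Gaussian of variance $\Sigma_U$ and $\epsilon^\pm$
complex Gaussian measurement/model errors; the data are the amplitudes
$r^\pm = |Z^\pm|$.  The two observations are never reduced to a merged
$\Delta F$ with $\sigma_{\Delta F} = (\sigma_+^2 + \sigma_-^2)^{1/2}$:
they enter jointly, sharing $U$.  The unexplained heavy power $v$
contributes its normal part to $\Sigma_U$ and its anomalous part
($\kappa^2 v$, with $\kappa = f''/(f_0 + f')$) to the per-mate errors —
anti-correlated between the mates, which makes the Friedel-pair
covariance complex: $\mathrm{Cov}(Z^+, \overline{Z^-}) = \Sigma_P +
v(1-\kappa^2) + 2i\kappa v$.  This joint treatment is what the package's
reference mode (`mode = "gaussian_df"`, a Gaussian on merged Bijvoet
differences) deliberately lacks, and the test suite verifies that the
joint mode phases strictly better.

Two integration routes are used for the same model:

* **Posteriors** over the phase of $U$ are computed on a uniform
  72-point grid (5° spacing) with the amplitude of $U$ profiled out by an
  adaptive vectorized parabola search plus a Laplace curvature term.  A
  variance floor tied to the phase-grid spacing
  ($\approx (0.35\,\Delta\phi\,|\beta H|)^2$) represents the grid's own
  discretization error, so noise-free data cannot produce posteriors
  sharper than the grid can carry.
* **Marginal likelihoods** (error-model refinement, site refinement, the
  completeness check) use an essentially exact reduction of the
  bivariate Rician: one observation phase integrates analytically to a
  Bessel $I_0$; the remaining phase is integrated by a 64-point grid with
  local Laplace refinement of the top two integrand peaks, accurate from
  broad to needle-sharp ridges.  Centric reflections (phase restricted to
  $\{\varphi_0, \varphi_0 + 180^\circ\}$ with $\varphi_0 = 180^\circ
  h\cdot t$ from the centrizing operator) integrate over a real line
  instead, by adaptive trapezoid quadrature around the analytic roots of
  the amplitude equation.

Modified Bessel functions in these loops use the Abramowitz–Stegun
polynomial approximation of $\log I_0$ (relative error below $2\times
10^{-7}$, several times faster than `besselI` on multi-million-point
grids); the exact function is kept as the test oracle.

## Luzzati error parameters and the completeness check

The error model carries, per equal-population resolution shell, a
residual heavy variance $v$ and a reported Luzzati parameter

$$ D \;=\; \beta\,\sqrt{\Sigma_G^{\mathrm{model}} /
   \Sigma_G^{\mathrm{obs}}} \;\in\; [0, 1], $$

the fraction of the *observed* anomalous-difference amplitude
($\Sigma_G^{\mathrm{obs}} = \langle \Delta F^2\rangle / 2\kappa^2$, noise
included) explained by the scaled model substructure.  Because the
denominator contains the measurement noise, $D \to 1$ only on noise-free
data with a complete, correct substructure, and decreases monotonically
as noise is added — the behaviour a completeness statistic needs.

The refinement is a deliberate hybrid.  The global center scale $\beta$
is calibrated by matching the anomalous cross-moment
$\langle |\Delta F| \cdot |G_{\mathrm{model}}| \rangle$ to its model
expectation (monotone bisection).  We found that maximizing the profile
or marginal likelihood over $\beta$ on amplitude-only data overscales
partial models by 10–20% — enough to push a correct *half* substructure
above the 0.7 completeness threshold — whereas the cross-moment
estimating equation is unbiased for this scale.  The per-shell residual
variance $v$ (and optionally a global variance inflation) then *is*
maximized against the exact bivariate-Rician marginal likelihood over
work reflections.  Under the default toy conditions the resulting
statistic separates cleanly: a full correct substructure refines to
$\langle D\rangle \approx 0.92$–$0.96$ at 5% noise (1.0 noise-free), one
of two sites to $\approx 0.59$–$0.72$, and random sites to below 0.25.
The check mode declares a substructure complete when $\langle D\rangle$
exceeds 0.7, the standard default.

Heavy-site refinement maximizes the same exact marginal likelihood by
cyclic coordinate descent with parabolic line steps and a shrinking step
schedule — finite-difference quasi-Newton methods stall on the small
quadrature noise of the objective.  Note one identifiability fact the
amplitude likelihood imposes: for a single-element substructure the
Friedel-pair marginal depends on the sites only through $|G(h)|$, so a
common translation along a polar axis (the origin freedom of P2~1~) is
invisible; refined sites are assessed modulo allowed origin shifts.

## Substructure search

$|F_A|$ estimates come either from $|\Delta F|$ (the baseline), from the
posterior expectation of the heavy amplitude under the joint model (one
analytic observation-phase integration, one 64-point angular quadrature,
and a Rayleigh-quantile quadrature over the heavy amplitude; validated
against a direct 3-D Riemann sum of the same model to better than 2%
RMS), or from scaled isomorphous differences when a native set is
present.  The quasi-normalized, origin-removed $E^2 - 1$ coefficients
feed an FFT Patterson synthesis (grid spacing $d_{\min}/3$).  Each search
trial scores random translation candidates by the symmetry-minimum
function on Harker vectors, refines the best by 3-point parabola
interpolation per axis, adds further sites consistent with cross vectors,
refines occupancies by least squares on the normalized amplitudes, and is
scored by the correlation between observed and calculated normalized
heavy amplitudes.  Trials stop early when the best score exceeds 0.65 or
when, after at least five trials, a best-minus-worst deviation of 0.2
separates them (with the best at least 0.4) — the thresholds are package
choices, configurable.

## Density modification and calibrated figures of merit

Maps are synthesized with FOM-weighted coefficients $m|F|e^{i\varphi}$
(free reflections weighted zero, so their phases never feed the map),
solvent-masked by local averaging of $|\rho|$, flattened (or flipped),
and inverted back to structure factors.  The combination step multiplies
the experimental HL posterior by a von Mises term centred on the
density-modified phase with concentration $K = 2 d_{\mathrm{dm}} k
f_{\mathrm{dm}} |F| / \sigma_e$, discounted by the map-correlation
parameter $\alpha$ to $(1-\alpha)K$.  The limits pin the construction:
$\alpha = 1$ returns the experimental posterior exactly (the
log-posterior lies in the HL basis span, so the identity is exact) and
$\alpha = 0$ is classical MLHL combination.

The cross-validated error estimation is the honest part: $d_{\mathrm{dm}}$
per shell comes from the amplitude agreement between data and modified
map, and $\alpha$ from the predictive likelihood of the DM phases under
the experimental posteriors, both evaluated **only on free reflections**.
Work-set estimation (the variant cross-validation replaces) measures
mostly the feedback of the work phases through the map: it inflates
$d_{\mathrm{dm}}$ and leaves the mean figure of merit escalated above the
true $\langle\cos\Delta\varphi\rangle$; the test suite quantifies both
effects.

Two mask defaults deviate from common protein practice, deliberately.
The toy crystals place light atoms uniformly in the asymmetric unit with
no bulk solvent, so their empty volume is distributed *between* atoms at
the ~5 Å scale; a Wang-style multi-Ångström averaging radius cannot
separate atoms from voids there (flattening a perfect map would degrade
its phase agreement to ~0.83).  The defaults are therefore an averaging
radius of $0.8\,d_{\min}$ and a solvent fraction of 0.70, at which a
perfect map survives flattening essentially unchanged and the modified
map genuinely predicts phases of held-out reflections.

Hand determination runs the full phasing + density-modification loop for
both enantiomorphs and compares their cross-validated free-set predictive
log-likelihoods; a difference below 1.0 per 100 free reflections is
declared undetermined.  The wrong hand cannot mirror the observed Bijvoet
differences — mirroring the crystal would also swap the Friedel mates —
which is exactly why the discrimination works; in the $f'' = 0$ limit the
two hands are exact mirrors and undecidable.

## The synthetic crystals

The simulator is first-class, tested code: direct-summation structure
factors (no FFT approximation) with single-Gaussian form factors
$f_0(s) = Z e^{-w s^2}$ ($s = 1/d$; widths per element fitted to the
tabulated falloff near 2 Å), isotropic B-factors (light atoms uniform in
[10, 30] Å², heavy in [15, 25] Å²), per-element $f'$, $f''$ overridable
per wavelength, and Gaussian amplitude noise with per-shell
$\sigma = \mathrm{noise}\cdot\langle|F|\rangle$ (one shared draw per
centric pair).  The default problem ("toy50") is P2~1~,
$34 \times 42 \times 38$ Å, 150 carbon-surrogate atoms, two Se-like sites
with $f' = -8$, $f'' = 4$, data to 2.2 Å, 5% noise: a strong-signal toy
(overall Bijvoet ratio ≈ 0.11–0.13, comparable to a good selenium peak
dataset) whose every stage has deposited ground truth.

What the toys do **not** emulate — and hence what passing tests cannot
show about real data: bulk solvent and a compact molecular envelope,
correlated Friedel-pair errors from integration, radiation damage,
imperfect isomorphism, anisotropy, twinning, and realistic
protein-to-heavy scattering ratios (two Se among 150 carbons is ~30% of
the total intensity, far above a real Se-Met protein; it keeps every
stage solvable at desk scale).

## Problem sizes and reproducibility

All simulations in the tests and the acceptance script run at the toy50
size (~5600 unique reflections) or on a mini analogue (~1800
reflections); multi-seed claims use 6–20 independent crystals, chosen as
the smallest ensembles whose means are stable.  Every random draw flows
from one root seed through named per-step derivations, so pipeline runs
are reproducible byte for byte; the test suite asserts this on emitted
reports.

## Known limitations

Three space groups (P1, P2~1~, P2~1~2~1~2~1~); amplitudes only (no
intensity-to-amplitude conversion); no MAD joint multi-wavelength
likelihood (the best channel is selected and phased as SAD); the SIRAS
likelihood treats native and derivative error channels as independent; no
NCS handling, histogram matching or multi-crystal averaging; substructure
search is Patterson-based and intended for a handful of sites, not
selenium constellations of dozens.
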