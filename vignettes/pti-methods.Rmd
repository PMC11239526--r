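---
title: "Uniaxial permittivity tensor imaging: models, algorithms and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uniaxial permittivity tensor imaging: models, algorithms and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
physical model and its assumptions, the algorithms, every tunable parameter
with its default and rationale, what the synthetic phantoms do and do not
emulate, and the numerical conventions a maintainer needs to know. It states
no empirical result that the test suite does not itself compute.

## 1. The physical model

### Uniaxial permittivity tensor

A voxel of a uniaxial dielectric with ordinary/extraordinary refractive
indices $n_o$, $n_e$ and symmetry axis
$\hat a = (\sin\theta\cos\omega, \sin\theta\sin\omega, \cos\theta)$ has the
relative permittivity tensor

$$\bar\varepsilon = (\varepsilon_r - \Delta\varepsilon_r)\,I +
  2\Delta\varepsilon_r\, \hat a \hat a^T, \qquad
  \varepsilon_r = \tfrac12 (n_e^2 + n_o^2), \quad
  \Delta\varepsilon_r = \tfrac12 (n_e^2 - n_o^2).$$

Its eigenvalues are $\{n_o^2, n_o^2, n_e^2\}$, the non-degenerate
eigenvector is $\hat a$, and the trace is $3\varepsilon_r -
\Delta\varepsilon_r$ (`permittivity_matrix()` and the tensor-core tests
verify these identities). The optic sign is $\mathrm{sign}(\Delta
\varepsilon_r)$: positive (prolate) for membrane normals and most ordered
polymers viewed along their axis; negative (oblate) for, e.g., laser-written
nanogratings and whole axons at coarse resolution.

The quantity the inverse problem actually estimates is the scattering
potential tensor $\bar f = k_0^2(\bar\varepsilon - \varepsilon_{rm} I)$,
$k_0 = 2\pi/\lambda_0$, decomposed into seven scalar volumes
$f_{0r}, f_{0i}, f_{1c}, f_{1s}, f_{2c}, f_{2s}, f_3$ (units $\mu m^{-2}$):
$f_0$ carries the isotropic contrast (with $f_{0i}$ the absorption, always
zero for the transparent specimens modelled here), the $f_1$ pair carries
$\Delta\varepsilon_r \sin^2\theta\,(\cos,\sin)(2\omega)$, the $f_2$ pair
$\Delta\varepsilon_r \sin 2\theta\,(\cos,\sin)(\omega)$, and
$f_3 = \Delta\varepsilon_r (3\cos^2\theta - 1)$ the axial anisotropy.

### Orientation conventions

$\omega$ is an axis (not a vector) measured counterclockwise from $+x$, kept
in $[0, \pi)$ to match the color-wheel rendering convention of the field;
$\theta$ is the polar angle from $+z$, kept in $[0, \pi]$. The pair ranges
$(\omega \in [0,\pi), \theta \in [0, \pi/2])$ would cover only half of axis
space, so the package folds with the axis identity $(\omega, \theta) \equiv
(\omega + \pi, \pi - \theta)$ and reports the out-of-plane tilt as
$|\theta - \pi/2| \in [0, \pi/2]$.

### Vector Born forward model

Single scattering from the tensor potential under the first Born
approximation gives
$\vec E_{out} = \vec E_{inc} + \bar G * (\bar f\, \vec E_{inc})$,
with $\bar G$ the dyadic Green's tensor. In the angular spectrum
representation, each transverse frequency $u_\perp$ inside the propagating
band contributes the transverse projector $(I - \hat s \hat s^T)$ times the
scalar propagator $i e^{2\pi i \eta z} / (4\pi\eta)$,
$\eta = \sqrt{(n_m/\lambda_0)^2 - |u_\perp|^2}$; evanescent frequencies are
dropped. `born_scatter()` implements the open-space operator (forward and
backward branches, zero-padded convolution); the imaging simulator
`simulate_stokes()` uses the forward branch only, which is exactly the field
a microscope refocused to depth $z$ observes.

Partially coherent illumination is an incoherent sum over the discrete
source points of each pattern. Per source, the detected field is the
objective-pupil-filtered, refocused scattered field plus the transmitted
incident plane wave; the generalized Stokes volumes are the coherency
combinations $S_0 = S_{xx}+S_{yy}$, $S_1 = S_{xx}-S_{yy}$,
$S_2 = 2\,\mathrm{Re}\,S_{xy}$, $S_3 = -2\,\mathrm{Im}\,S_{xy}$ of the
transverse components. The simulator keeps the term quadratic in the
scattered field — it is nonlinear in the specimen and serves as the
reference ("truth") model for the linearized inversion throughout the tests.

Polarization conventions: incident light is right-circular,
$\vec E \propto (\hat x - i\hat y)/\sqrt 2$ with the $e^{-i\omega t}$ time
convention ($S_3 = -1$); at oblique incidence the polarization is
transported along meridians (unit s/p decomposition on the sphere). A mirror
reflection flips the handedness; the suite verifies the exact mirror
symmetry (mirrored phantom + mirrored patterns + LCP gives mirrored
$S_0, S_1$ and negated $S_2$ to machine precision).

### Linearized model and transfer functions

Dropping the quadratic coherency term linearizes the map from the seven
component spectra to the DC-subtracted Stokes spectra:
$\tilde S'_{m,\alpha}(\vec u) = \sum_\ell \tilde H_{m,\ell,\alpha}(\vec u)
\tilde f_\ell(\vec u)$, $m \in \{0,1,2\}$ (linear analyzers cannot measure
$S_3$). `compute_transfer_functions()` assembles each $\tilde H$ as the
weighted sum over source points of two cross-correlation terms
(incident$\times$scattered and its conjugate), evaluated in closed form on
the DFT lattice with Dirichlet kernels in $u_z$.

Two discretization choices make the transfer functions agree with the
simulator's linear part to machine precision — the property the weak-object
tests rely on:

- **Axial frequency snapping.** The axial frequency $\eta(\nu_\perp)$ of each
  discrete plane-wave source is snapped to the nearest axial DFT frequency
  when sampling the incident phase. This makes the discrete forward operator
  exactly diagonal in the 3D DFT basis (no spectral leakage between $u_z$
  bins); the snap error is at most $\Delta u_z / 2 = 1/(2 n_z \Delta z)$ and
  vanishes with grid size. Directions, polarization vectors and projectors
  use the exact $\eta$.
- **Background-correction folding.** The ratio-form background correction
  $(S_1/S_0) - (S_{1,bg}/S_{0,bg})$ mixes a fraction $S_{1,bg}/S_{0,bg}$ of
  the $S_0$ signal into the corrected $S_1$ at linear order whenever the
  empty-field polarization background is nonzero — which it is for every
  oblique sector (an off-axis circularly polarized wave has transverse
  $S_1 = -\tfrac12\sin^2\beta\cos 2\phi$). The transfer functions therefore
  model the *background-corrected* data:
  $H_1 \leftarrow H_1 - (S_{1,bg}/B)\,H_0$ (same for $H_2$), with the
  constants computed from the pattern itself.

With these conventions the relative mismatch between the nonlinear
simulator and the linear model is purely the quadratic term: the acceptance
suite verifies it is below 2% at permittivity contrast $10^{-3}$ and scales
down proportionally with contrast.

Thin specimens use the 2D model: the in-focus response to a specimen
confined within the depth of field is governed by the axial integral
$\int \tilde H\, du_z$ (`project_otf_2d()`, discrete sum times
$\Delta u_z$); `solve_components()` supports both modes.

## 2. The acquisition plan

`sector_patterns()` builds 1 brightfield disk (NA up to `na_illu`) plus 8
annular sectors of 90° width at 45° steps with inner NA
$0.3\,\mathrm{NA}_{illu}$ — nine patterns, which with the four-channel
analyzer camera (0°, 45°, 90°, 135°; ideal Malus rows
$\tfrac12[1, \cos 2\phi_c, \sin 2\phi_c]$) gives 36 raw 2D images per focal
plane. The exact sector layout of the original instrument is not public;
this default provides the left/right/top/bottom and diagonal asymmetries
needed to condition all seven tensor components, and everything (count,
width, inner NA, stride) is configurable. Source points are the transverse
DFT lattice samples inside each pattern; `source_stride` subsamples that
lattice deterministically to trade angular sampling density for speed (the
tests and examples use stride 2–3; convergence is in grid density, not an
accuracy dial).

## 3. The inverse algorithm

**Stage 1 — component deconvolution.** Stacking all (pattern, Stokes)
channels, the per-frequency Tikhonov solution is
$\hat f(\vec u) = (H^H H + \Lambda)^{-1} H^H \tilde S'(\vec u)$, solved by a
batched 7×7 Gaussian elimination across all frequencies. $\Lambda$ is
diagonal: `reg_iso` for $f_{0r}, f_{0i}$ and `reg_aniso` for the five
anisotropic components, both *relative* to the peak diagonal of $H^H H$ so
the weights are dimensionless. Defaults `reg_iso = 1e-3`,
`reg_aniso = 5e-3` are chosen for noise robustness (anisotropy transfers
more weakly than phase); the noiseless synthetic experiments in the tests
pass `1e-5`–`1e-8` explicitly, as appropriate for data whose only
"noise" is the model mismatch. The $\vec u = 0$ bin is unmeasured by
DC-subtracted data and is forced to zero; this is why reconstructed mean
permittivity has zero volume mean and a negative halo around objects — the
same slowly-varying-phase insensitivity partially coherent systems show.

**Stage 2 — dual-sign property extraction.** With $g_\ell = f_\ell/k_0^2$,
$a_1 = \mathrm{hypot}(g_{1c}, g_{1s}) = |\Delta\varepsilon_r|\sin^2\theta$
and $a_2 = \mathrm{hypot}(g_{2c}, g_{2s}) =
|\Delta\varepsilon_r||\sin 2\theta|$:
$\theta = \mathrm{atan2}(2a_1, a_2)$,
$|\Delta\varepsilon_r| = \sqrt{a_1^2 + (a_2/2)^2}/\sin\theta$, and for the
assumed sign $s$, $\omega = \tfrac12 \mathrm{atan2}(s\,g_{1s}, s\,g_{1c})$
with the $\pi$-ambiguity resolved by aligning $(\cos\omega, \sin\omega)$
with $s\,(g_{2c}, g_{2s})$; the mean contrast is
$g_{0r} + \Delta\varepsilon_r \cos^2\theta$. This closed form is degenerate
when the axis lies along $z$ (all signal in $g_3$, $a_1 = a_2 = 0$ up to
numerical crumbs), so the implementation also evaluates the $z$-axis branch
($\theta = 0$, $\Delta\varepsilon_r = g_3/2$) and takes it per voxel when it
reproduces the five anisotropic components essentially exactly
(recomposition residual below 1% of the component power) and better than
the main branch. The choice is deterministic and reduces to the plain
closed form everywhere the harmonics are resolvable; without it,
coarse-grained fields with axes along $z$ (the tube phantom below its
diameter) would be mis-assigned to in-plane orientations by filtering
residue. Fully degenerate voxels return
$(\Delta\varepsilon_r = 0, \omega = 0, \theta = \pi/2)$.

**Stage 3 — optic sign.** Both candidate solutions are recomposed into
components, pushed through the linear forward model, and compared with the
data; the residual energies are Gaussian-smoothed over
`optic_sign_window` (default 0.5 µm — about two resolution elements, enough
to stabilize the ratio without erasing structure boundaries) and combined
as $p_+ = r_-/(r_+ + r_-)$. The form is bounded in $[0,1]$, swapping the
branches maps $p \to 1-p$, and voxels with differential permittivity below
`anis_floor` (or with vanishing total residual) are undecidable and get
0.5. Final maps take each voxel from the higher-probability branch, ties to
positive.

## 4. Synthetic specimens: what they emulate, what they do not

All phantoms return exact per-voxel ground truth and are deterministic.

- `star_target()` — the spoke/wedge resolution target: `n_wedges` equal
  wedges whose axis rotates in steps of $360°/n_{wedges}$ (32 wedges give
  the 11.25° step used for metrology); axis along the spokes for positive
  materials, orthogonal in-plane for the written-glass convention; optional
  inclination sweep. The defaults for recovery experiments are 8 wedges of
  spoke indices $n_o = 1.525$, $n_e = 1.55$ and a thin (3-slice, ~0.4 µm)
  slab: the spoke contrast is paper-stated, and at this optical thickness
  the phantom sits inside the weak-object validity regime. The quadratic
  (scattered×scattered) term grows proportionally with thickness and shows
  up as a uniform apparent in-plane rotation of the recovered axis
  (≈5° at 0.85 µm thickness, ≈2.6° at 0.42 µm in the 32³ experiments);
  this is a property of single-scattering physics versus its
  linearization, not of the solver.
- `bead_phantom()` — hard-voxelized spheres (voxel centre inside radius;
  volume within 5% of $\pi d^3/6$ at ≥ 8 voxels/diameter), optionally with
  uniform anisotropy at a fixed 3D axis. Used for the edge-birefringence
  experiment (2 µm, $n = 1.59$ in $1.58$), accuracy sweeps (1 µm beads of
  varying index / $\Delta\varepsilon_r$) and PSF metrology.
- `tube_phantom()` — a membrane cylinder along $z$: shell voxels positive
  uniaxial with the axis along the local surface normal; lumen and outside
  isotropic. Tensor coarse-graining below the tube diameter
  (`lowpass_material()`: Gaussian-filter the seven components, then
  extract — filter-then-extract is definitional, because tensors average
  and angles do not) flips it to a negative uniaxial material with the
  axis along the tube, the scale-dependent sign inversion characteristic
  of myelinated axons.

None of the phantoms include noise, aberrations, multiple scattering,
spectral width, or instrument miscalibration. A green test therefore
establishes the correctness and internal consistency of the models and
algorithms in the weak-scattering regime — not robustness to experimental
non-idealities.

## 5. Numerical conventions and edge cases

- Arrays are `(nz, ny, nx)`, micrometres, origin at the centre voxel;
  spectra are unshifted (FFT-order) with the forward convention
  $e^{-2\pi i \vec u \cdot \vec r}$. Frequencies are cycles/µm.
- All spectral operations are circular on the grid; `born_scatter()` is the
  exception and zero-pads (default half the grid per axis) because the
  open-space integral is non-periodic. Choose `dx` so that
  $(\mathrm{NA}_{illu} + \mathrm{NA}_{obj})/\lambda_0 \le 1/(2\,dx)$, or
  shifted pupils alias.
- Stokes estimation is the exact least-squares solve of the 4-channel
  Malus model; an instrument matrix with condition number above $10^8$ is
  rejected.
- Background correction requires an empty-field acquisition (or the
  analytic `stokes_background()` for simulations); DC normalization divides
  by the per-pattern volume mean of $S_0$ and subtracts it from $S_0$ only.
- Degeneracy tolerance in the extraction algebra: $10^{-8}$ in
  $g$-component units; isotropic fallback $(0, \omega = 0, \theta = \pi/2)$.
- The effective resolution of the regularized inverse approaches the
  synthetic aperture $(\mathrm{NA}_{illu} + \mathrm{NA}_{obj})/\lambda_0$
  on noiseless data: reconstructed sub-resolution beads fit to lateral
  widths *below* the single-lens benchmark $0.5\lambda/\mathrm{NA}$, and
  quadrature PSF extraction (`fwhm_from_bead()`, which assumes the image is
  the convolution of a Gaussian PSF with the bead) can fail for beads
  comparable to the PSF because deconvolution ringing narrows the fitted
  width below the physical bead size. The function flags this instead of
  returning an imaginary width.

## 6. Known limitations

- Single scattering only: accuracy degrades with optical thickness; the
  simulator's own quadratic term is the first symptom (see the spoke
  rotation bias above). No multiple-scattering correction is attempted.
- Structures oriented near the imaging axis transfer weakly; recovered
  differential permittivity degrades as the axis approaches $z$
  (verified as a monotone trend in the inclination-sweep test), and
  regularization trades this accuracy for noise robustness.
- Ideal pupils only (no aberrations), ideal analyzer model by default
  (a measured 4×3 instrument matrix may be substituted).
- $S_3$ is never measured (linear analyzers); it exists only inside the
  simulator.
- IO is a minimal uncompressed Zarr-v2 directory store plus JSON configs;
  OME-TIFF is not supported in this environment.
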