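---
title: "Traction force and monolayer stress microscopy: models, parameters and validation"
author: "monolayerTFM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Traction force and monolayer stress microscopy: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monolayerTFM)
```

## The inverse problems

Cells adhering to a soft elastic substrate deform it; comparing fluorescent
bead images of the substrate in the tensed (cells pulling) and relaxed
(cells detached) state gives a surface deformation field $\vec u(\vec x)$.
Two inverse problems follow.

**Traction reconstruction.** On a linearly elastic substrate, deformation
and traction are related by a convolution with the elastic surface Green's
tensor, $\vec u = K \otimes \vec t$. In Fourier space this becomes a
per-wavevector $2\times2$ multiplication,
$\tilde u(\vec k) = \tilde K(\vec k)\,\tilde t(\vec k)$, which is inverted
directly (Fourier-transform traction cytometry). For an elastic half-space
$\tilde K$ is the Boussinesq tensor,
$$\tilde K = \frac{2(1+\nu)}{E k^3}\begin{pmatrix}(1-\nu)k^2+\nu k_y^2 & -\nu k_x k_y\\ -\nu k_x k_y & (1-\nu)k^2+\nu k_x^2\end{pmatrix},$$
with $E$, $\nu$ the substrate modulus and Poisson ratio. Decomposed into
the transverse and longitudinal eigenmodes, the tensor is
$\frac{2(1+\nu)}{Ek}\left[(I-\hat k\hat k) + (1-\nu)\,\hat k\hat k\right]$.
For a substrate of finite thickness $h$ bonded to a rigid support each mode
acquires a thickness factor (derived from the exact elastic-layer boundary
problem):

* transverse (antiplane shear): $\tanh(kh)$;
* longitudinal (plane strain):
  $\dfrac{(3-4\nu)\sinh(kh)\cosh(kh) + kh}{(3-4\nu)\cosh^2(kh) + (1-2\nu)^2 + (kh)^2}$.

Both approach 1 as $kh \to \infty$; the longitudinal factor is the
reciprocal of the classical layer-stiffening correction used in
finite-thickness traction microscopy. A bonded layer is stiffer than the
half-space, so both factors are below 1; ignoring them on a thin gel
overestimates tractions near the patch scale.

**Stress recovery (monolayer stress microscopy).** Tractions must be
balanced by stresses inside the cell sheet,
$t_x = \partial_x\sigma_{xx} + \partial_y\sigma_{yx}$ (cell-on-substrate
sign convention; for a tensile patch the tractions are centripetal). The
sheet is modelled as a linear plane-stress continuum discretized into one
bilinear quadrilateral element per pixel of a user-drawn traction-area
mask, each node loaded with the reaction $-\vec t\,a^2$ of the local
traction. Because the load is divided by the constitutive law on the way in
(stiffness) and multiplied on the way out (stress from strain), the sheet's
Young's modulus cancels exactly from the traction-to-stress map, and the
Poisson ratio has only a weak (few percent) influence; the conventional
$E = 1$ Pa, $\nu = 0.5$ are the defaults.

## Rigid-body handling

A free elastic sheet has three zero-energy modes. Net force is removed by
subtracting the mean force vector from every node; net torque by rotating
all force vectors through the closed-form angle
$\alpha = \arctan(-T_0/D_0)$ with $T_0 = \sum \vec r\times\vec f$,
$D_0 = \sum \vec r\cdot\vec f$ (principal root — the $\pi$-shifted root
also nulls the torque but reverses every force). The solve then imposes
whole-system conditions $\sum d_x = 0$, $\sum d_y = 0$,
$\sum (d_x r_y - d_y r_x) = 0$ appended to $K\vec d = \vec f$ and treated
as a least-squares system. Since the three constraint vectors span exactly
the rigid-body null space of $K$ and a balanced load lies in its range,
that least-squares solution is computed exactly as a sparse-Cholesky
particular solution with its rigid-body component projected out. The
classical alternative — pinning one node fully and the cross-axis
displacement of a second node on the same row — is available as
`method = "pin"`; the two differ only by a rigid motion and agree on
stresses to solver precision. (Pinning the *parallel*-axis displacement of
a same-row node, as sometimes described, cannot block rotation: rotating
about the first node moves a same-row node perpendicular to the row.)

Strains are evaluated from the shape-function derivatives at the element
centre, which for bilinear quadrilaterals equals the 2×2 Gauss average;
stresses follow from the plane-stress law and are reported as 2D sheet
stress in N/m under the unit-thickness convention.

## PIV and drift correction

Deformation fields are computed by window-wise zero-mean normalized
cross-correlation (robust to illumination differences), with the
correlation evaluated by zero-padded FFT and renormalized by the per-shift
overlap area (without this the triangular overlap weighting biases large
displacements toward zero by ~0.1 px). Sub-pixel refinement fits a
three-point Gaussian through the peak and its axis neighbours,
independently in x and y; ties at the peak break toward the smaller index.
Vectors whose peak-to-second-peak ratio falls below 1.03 (second peak
sought outside a 2-pixel neighbourhood of the first, in correlation-matrix
pixels) are replaced by the mean of valid vectors within 2 grid points —
grid units, because an image-pixel radius would contain no neighbours at
typical window spacing. Replacement iterates so filled vectors can seed
remaining gaps; a fully invalid field is an error, not a guess. Global
stage drift is estimated before PIV by cross-correlating the full images,
refined to 1/100 px by matrix-multiply DFT evaluation of the correlation
around its peak; the tensed image is shifted by the negated drift and both
images are cropped to the overlap.

Coordinate convention throughout: x = column, y = row, y increases
downward; all fields, masks and polylines share it.

## Scalar metrics

* Strain energy $U = \frac12\sum \vec u\cdot\vec t\,a^2$ (J).
* Contractility: pixel forces projected onto unit vectors toward the force
  epicenter, the least-squares intersection of the force lines of action.
  The normal equations are solved about the force-weighted centroid with a
  pseudo-inverse, so a direction left undetermined by the force geometry
  (e.g. a single collinear opposing pair) resolves to the centroid instead
  of failing. Centripetal fields give positive contractility.
* Stress scalars: per-pixel principal stresses give the maximum normal
  ($\sigma_1$), maximum shear ($(\sigma_1-\sigma_2)/2$) and mean normal
  ($(\sigma_1+\sigma_2)/2$) stress, averaged over the cell mask; the
  coefficient of variation (sd/mean of the per-pixel mean normal stress)
  measures stress heterogeneity.
* Line tension: $\vec T = \sigma\cdot\hat n$ on each cell-cell boundary
  segment, with $\sigma$ interpolated bilinearly at the segment midpoint.
  Averages are length-weighted; the normal component keeps its sign
  (tension vs. compression) while shear is reported as a magnitude — with
  this convention the average line-tension magnitude slightly exceeds the
  average normal component when shear is small, as observed in epithelial
  colonies. Cell counts for per-cell normalization are user input;
  segmentation is out of scope.

## The synthetic validation chain

`syntheticSpec()` fixes the reference experiment: a 150 um wide square
patch carrying uniform biaxial sheet stress $\sigma_0$ (zero shear) on a
400 × 400 um field at 1 um per pixel, substrate thickness 100 um, FTTC
smoothing 3 um. The chain is stress → traction (central differences of the
stress step; inward edge bands integrating to $\sigma_0$ per unit edge
length) → deformation (forward Fourier map, finite-thickness kernel) →
FTTC → FEM → scalar metrics, so every stage downstream of the analytic
field is exercised against a known ground truth. `renderBeadImages()`
additionally draws Gaussian-spot bead images displaced by the deformation
field so the PIV stage can be validated end to end; the rendered images
contain no camera noise, so PIV accuracy measured on them (≈0.1 px RMS) is
an upper bound on real-data performance, and the outlier-replacement path
is exercised with artificially corrupted windows instead.

Numerical choices worth knowing:

* The magnitude $\sigma_0$ is stored in N/m and cancels from every
  normalized recovery metric; only ratios are asserted.
* Grid spacing 1 um per pixel. Coarser spacings widen the discrete
  traction band relative to the 3 um smoothing and lower the recovered
  stress (at 4 um spacing the margin-5 recovery drops from 90% to 83%).
* Both Fourier maps default to the periodic (unpadded) evaluation, which
  makes the forward/inverse pair algebraically exact (round-trip error
  ~1e-15) and matches how the synthetic chain is defined; `pad = TRUE`
  embeds the field in a doubled domain for aperiodic data.
* The FEM solves use sparse Cholesky on ~50k degrees of freedom for the
  reference field; a full margin scan (0-20 um) runs in about two minutes
  on one CPU. Unit tests run the same chain at 128 um / 50 um patch size,
  where every solve is well under a second.

What the recovered field looks like: FTTC with 3 um smoothing blurs the
traction bands symmetrically about the patch edge. Consequently (i) a
patch-matching FEM grid (zero margin) captures only about half of the edge
force and recovers ~48% of the input stress; (ii) recovery rises steeply
with the expansion margin, plateaus near 93% of $\sigma_0$ (margins 6-10
um, maximum at 8 um, values at 4-6 um within 3% of the maximum), then
declines slowly as added sheet material dilutes the average; (iii) inside
the patch the recovered stress ramps up over ~10 um from each edge, which
depresses the patch average (90% at a 5 um margin) and contributes a
residual CV of ~0.08 even though the input is perfectly uniform. Total
contractility, by contrast, is insensitive to the blur and is recovered to
0.1%. These are properties of the stated conditions, not solver error: the
forward/inverse Fourier pair is exact to machine precision, and the FEM
reproduces uniform-strain states exactly.

## Limitations

Only in-plane (2D) tractions and stresses are computed; out-of-plane
deformation is ignored, which is adequate for nearly incompressible
substrates. The sheet model is linear, homogeneous and isotropic; the
computed FEM displacements have no physical meaning (cell and substrate
strain are not coupled) — only the stresses do. No regularized or
constrained traction variants are provided; smoothing is the only noise
control. Masks are assumed to outline one connected cell patch; the FEM
refuses disconnected masks because the rigid-body constraints assume a
single body, and interior holes are filled with a warning.
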