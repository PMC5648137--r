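---
title: "Multiscale oriented wavelet analysis of fluorescence cell movies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale oriented wavelet analysis of fluorescence cell movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(focalwave)
```

## The problem

A fluorescence time-lapse of a migrating cell carries information on
wildly different length scales at once: the outline of the whole cell
(hundreds of pixels), the elongated focal adhesions that anchor it to
the substrate (4-20 px long, a pixel or three wide), and the
sub-populations of adhesion proteins that assemble, translocate and
collide *inside* individual adhesions (a few pixels). `focalwave`
analyses all three scales with one mathematical object, the continuous
2-D wavelet transform

$$T(a, \mathbf b) = \frac{1}{a} \int d\mathbf r\, I(\mathbf r)\,
  \psi^*\!\left(\frac{\mathbf r - \mathbf b}{a}\right),$$

which filters the image $I$ at length scale $a$ while retaining
position $\mathbf b$. Two wavelet families are used: the circularly
symmetric Mexican hat $\psi(u) = (2 - |u|^2)e^{-|u|^2/2}$, and a
"stretched" anisotropic variant with axis ratio $\xi$ and orientation
$\theta$ whose elongated shape matches focal adhesions
(`psi_stretched()`; $\xi = 1$ recovers the Mexican hat exactly).  A
third, one-dimensional wavelet built from a pair of Lorentzians
(`psi_lorentzian_pair()`) serves only as a long-tailed template for 1-D
peak fitting.

## Discrete numerics

The transform is evaluated on discrete meshes (`cwt_forward()`):

* **Small scales** (default $a < 8$ px) use a 4x pixel-replicated fine
  mesh — each original pixel value is copied to a 4x4 block with no
  interpolation — because the native grid undersamples a narrow
  wavelet.
* **Large scales** (default $a > 16$ px) use a 2x2-block-mean coarse
  mesh, zero-padded with a border sized for the truncation box.  The
  cutoffs are configuration keys; the mesh-cell area
  $\Delta r \in \{1/16, 1, 4\}$ enters the sum so coefficients stay
  continuous across regimes.
* Every sum is **truncated to the box** $\mathbf b \pm 3a$ per axis.
  This is the reference semantics; the FFT path (`method = "fft"`)
  zero-pads and convolves with the *same truncated kernel* and equals
  the direct sum to roundoff.
* Evaluation is chunked over (scale, anisotropy, orientation); the
  result is independent of the chunking because each chunk is an
  independent convolution.

Two numerical choices deserve emphasis because they are easy to get
wrong:

**Demeaned analysis kernels.** Truncation at $\pm 3a$ leaves the
sampled wavelet with integral $\approx +0.63\,a^2$ instead of zero, so
a uniform image would transform to $\approx 4.4a$ rather than 0.  The
analysis kernels therefore have their box mean subtracted, which
restores the zero-mean wavelet condition *exactly on the mesh*.
Synthesis (inverse) kernels keep the printed wavelet shape.  Even so,
the truncated wavelet carries about 1% of its $L^2$ energy outside the
box, which bounds how closely the truncated transform can match an
untruncated one (measured: 4-8% of the peak coefficient in max norm on
random images).  That residual is a property of the $\pm 3a$ box
itself, not of the implementation.

**Reconstruction normalisation.** The inverse transform

$$I(\mathbf r) = \frac{1}{c}\sum_{n}\sum_{\mathbf b}
  \Delta b\, \Delta a\, a_n^{-4}\, T(a_n, \mathbf b)\,
  \psi\!\left(\frac{\mathbf r - \mathbf b}{a_n}\right)$$

resolves the identity only for the Calderon constant belonging to this
forward/inverse pair.  Writing both operations in Fourier space gives
$c = \int_0^\infty \hat\psi(ak)^2\, da/a = 2\pi^2\xi^2$ (non-unitary
transform convention).  The commonly quoted closed form
$c_\psi = \pi(1 + \xi^2)/2\xi$ — which `admissibility_constant()`
reports, and which equals $\pi$ at $\xi = 1$ — belongs to a different
normalisation *and* a different $\xi$-dependence: evaluating the
defining integral $c = \int |\hat\psi(k)|^2/|k|^2\, dk$ numerically in
the convention that yields $\pi$ for the Mexican hat gives $\pi\xi^2$
for the stretched family, a pure power, under every Fourier convention
we tried (`admissibility_numeric()` exposes this quadrature).  Because
no convention reproduces $(1+\xi^2)/2\xi$, we treat the closed form as
the *reported* admissibility constant and derive the *reconstruction*
constant from the transform pair itself, refining it numerically for
the truncated, demeaned kernels in use
(`reconstruction_constant(spec, box = 3)`, about 1.6% below the ideal
$2\pi^2$).  Broad-band round trips then reconstruct band-limited
images to ~4% relative $L^2$ error; with the closed form instead, every
reconstruction would be off by roughly $2\pi$.

## Detecting adhesions

Adhesions are detected as local maxima of the stretched-wavelet
coefficients over position, orientation (wrapped modulo 180 degrees)
and, in the variable-size mode, over the scale/anisotropy grid
($a = 4..20$, $\xi \in \{1/2, 1, 3/2\}$, 180 orientations by default).
The detection grid is evaluated on the native mesh for all scales so
that maxima can be compared across scales at identical positions.

One normalisation subtlety: the stretched wavelet has fixed *amplitude*
(value 2 at its centre) for every $\xi$, so its energy grows with
$\xi$ and raw coefficients systematically favour larger $\xi$
regardless of the underlying structure.  Measured on synthetic scenes,
raw-coefficient ranking maps every elongated blob to the largest
available $\xi$ and to roughly half its true length scale.  The
detector therefore compares family members on the unit-energy
(matched-filter) score $T/\sqrt{\xi}$ — the classical scale-normalised
response of multiscale blob detection — while reporting the raw
coefficient alongside.  The 10% acceptance threshold ("keep maxima at
least 10% of the highest maximum", applied per frame) acts on the same
score.

Accepted candidates are swept greedily in descending score; each is
placed only if its elliptical footprint — semi-axes $(a, a\xi)$
aligned with the wavelet axes; the literal reading $(a, \xi)$ would
make the minor axis independent of adhesion size and is kept only as
an option — is disjoint from every previously placed footprint.
Disjointness is decided algebraically from the characteristic cubic of
the conic pencil (two distinct positive real roots = separated), so
the result does not depend on any raster resolution.  Ties in the
sweep order are broken by lower $y$ then lower $x$ for determinism.

## Cell boundary and kinematics

The cell outline is the threshold contour of a coarse-band inverse
transform (default band $a = 20..200$ px, $\Delta a = 4$; threshold by
Otsu's method on the reconstruction, overridable as a fraction of its
maximum).  The boundary tracks the true edge to within about the
band's smallest scale.  Between frames, masks decompose exactly into
protruded ($t_1 \setminus t_0$), retracted ($t_0 \setminus t_1$) and
stable ($t_0 \cap t_1$) regions; contour stretches adjacent to moving
pixels are labelled protruding/retracting fronts.  Front velocity is
the least-squares slope of the cumulative mean normal advance
(nearest-point distance between consecutive contours averaged along
the protruding front) against time — the estimator is ours, since only
"tracking the movement of the boundary" is prescribed.  Adhesions are
assigned to regions by distance to the labelled fronts, with
`central` meaning at least 4 um from the boundary and `intersecting`
when protruding and retracting fronts are equidistant within 0.5 um.

## Intra-adhesion dynamics

For each adhesion a fixed cross-section along its major axis (one side
ending at the reference-frame boundary, the other extending an equal
length, clipped and flagged at the frame edge) is sampled with
bilinear interpolation over a window of 20 frames either side.  Each
frame's profile is fit by a constrained two-Gaussian mixture: samples
brighter than the mean of the profile extremes enter the fit,
amplitudes are box-constrained non-negative, and the baseline is the
profile minimum.

Deciding whether one or two sub-populations are present is the
delicate step.  Fitting two Gaussians to a single noisy peak splits it
arbitrarily, so a second component must pass all of: (i) amplitude at
least 5% of the larger component *and* at least 3 robust noise sigmas;
(ii) centre at least 2 px from the other (closer pairs are reported as
one merged peak at the amplitude-weighted centre); (iii) a BIC-style
comparison against a single-Gaussian model, with both models refit on
the *full* profile with a free offset — the above-cutoff samples alone
are too few to decide, and without the offset a broad spurious
component can absorb the baseline bias of taking $A_0 = \min(y)$;
(iv) a centre at least 2 px inside the profile ends.

Peaks are associated across frames by nearest centre with a 3 px/frame
jump limit, extrapolating each trajectory's recent Theil-Sen slope
(clamped to physical speeds).  A trajectory that loses its peak stays
open for up to 12 frames *only when another peak sits where it
vanished* — the occlusion signature of a collision merger — and
otherwise closes after 3 frames, so dead tracks cannot poach later
passers-by.  Frames whose effective peak count differs from both
neighbours inside a two-peak run are flagged stray and excluded from
velocity fits.  Post-processing stitches fragments that abut in time
and place, and merges duplicate tracks whose interpolated positions
co-move within the association radius.

Velocities are Theil-Sen slopes of the signed centre position
(positive = away from the cell boundary; the fixed profile geometry
makes the sign unambiguous), converted to um/min, with intervals from
the corresponding least-squares fit.  A single-breakpoint piecewise
fit flags a direction switch when it halves the residual and the legs
move oppositely at more than 0.1 um/min each.

The ten canonical behaviours (colliding pairs; one/two/three peaks
translating away; stationary-plus-translating combinations; one or two
stationary peaks; collide-then-switch; stationary with two translating
away) are classified by deterministic rules over the trajectory set.
Collisions are recognised either by a small minimum gap or by the
merger signature — a sustained approach (at least 4 px over at least 6
co-resolved frames) down to the two-peak resolution limit after which
only one track continues.  Colliding (A) and collide-with-switch (I)
are separated by what remains afterwards: a merged pair leaves one
late track, a bounced pair leaves two separating ones.  Sub-population
pairs closer than about two peak widths are genuinely unresolvable by
the mixture, so scripted scenarios space their features accordingly;
patterns outside the taxonomy are returned as `"other"` with the raw
pattern attached.

## Two-channel pole analysis

For actomyosin bundles imaged in a myosin and a vinculin channel, 1-D
profiles along the bundle axis are peak-detected by three independent
methods — smoothed-extrema prominence with Gaussian interval fits; the
second derivative with 1-D Mexican-hat fits integrated back twice
analytically; and least-squares fits of the Lorentzian-pair template —
and only peaks confirmed by all three within 2 px survive
(`peaks_consensus()`).  Each method also discards peaks below 3 robust
noise sigmas, which keeps the consensus false-positive rate on pure
noise below 0.2 peaks per profile.  The outermost consensus peaks on
each side of the bundle midpoint are the poles; same-side poles are
linked across frames and channels (pairing by side, never by
distance), velocities come from least-squares position-time fits
(positive toward the bundle centre), and the per-side difference
$\Delta v = v_{\mathrm{vinculin}} - v_{\mathrm{myosin}}$ is
histogrammed at 0.03 um/min.

## The synthetic-movie generator

Because the analyses need ground truth, `simulate_movie()` renders
scenes whose every quantity is scripted: a smooth cell whose boundary
advances at prescribed normal velocities (0.3-2 um/min range), focal
adhesions as oriented anisotropic Gaussian blobs — a deliberate model
mismatch with the detection wavelet, as with real data — intra-adhesion
clusters as 1-D Gaussians travelling along each adhesion axis
(0.04-1.1 um/min), and two-channel bundles with pole populations.
Noise follows the standard camera model, Poisson shot noise on
$g \cdot I$ followed by Gaussian read noise; "SNR 10" scenes set the
read noise to one tenth of the typical adhesion amplitude.  Rendering
is bit-reproducible under a fixed seed.

Defaults mirror typical TIRF imaging: 0.105 um/pixel, 5 s/frame.
The standard detection scene holds 20 adhesions with length scales
uniform on 4-20 px and anisotropies drawn from the same family as the
detection grid ($\xi = 1/2$ mostly, occasionally 1), amplitudes 90-110
on a read noise of 10.  Real adhesions are often narrower than the
$\xi$-grid implies for long adhesions; width then falls outside the
grid family, the grid argmax degrades toward small scales, and
orientation precision suffers — a wavelet-family limitation worth
knowing about, which the scene deliberately does not probe.
Cluster scripts use peak width 3 px (about 0.3 um) and the velocity
magnitudes above; two-channel scripts use a near-stationary regime
(0.016/0.028 um/min) and a fast converging regime (0.07/0.13 um/min,
vinculin twice myosin).

What passing these tests does *not* show: robustness to uneven
illumination, photobleaching, focus drift, boundaries with sharp
concavities, or adhesion mergers/splits — none of which the generator
emulates.

## Problem sizes and limitations

The validation suite uses frames of 64-220 px, detection grids of up
to 17 scales x 3 anisotropies x 180 orientations, 41-frame dynamics
windows and 60-frame bundle movies; these sizes exercise every code
path at full grid resolution while keeping a complete run on a single
CPU in minutes.  Larger movies stream frame by frame through the same
functions.

Known limitations: two closely spaced, nearly collinear adhesions can
merge into a single larger-scale detection whose matched-filter score
exceeds either individual's, so the greedy sweep places the merged
ellipse and suppresses both (the consequence of detecting by coefficient
maxima with non-overlap placement); no gap closing in adhesion tracking (a track ends
when unmatched, matching the consecutive-frame rule; a 1-frame
tolerance exists behind a flag); at most two concurrent
sub-populations per adhesion profile (three-peak categories are
recognised through staggered lifetimes); no merger/split modelling in
frame linking; and the coefficient maxima comparison across $\xi$
uses the unit-energy score rather than raw coefficients, as discussed
above.
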