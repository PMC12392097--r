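---
title: "Morphology, moments of inertia, and head-flick kinematics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphology, moments of inertia, and head-flick kinematics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flickmorph)
```

Many substrate-biting reef fishes end a bite with a *head flick*: a rapid
lateral (yaw) rotation of the head that tears attached food items free.
Mechanically the flick is a torque acting on a rotating head, so the head's
moment of inertia (MOI) should set how fast the flick can be, and the MOI of
everything aft of the head — the body and the median fins, the *lateral
profile* — should set how much the body recoils while the head swings.
`flickmorph` implements that analysis chain for hinged, two-segment physical
fish models: silhouette geometry to MOI, spring-driven flick simulation,
landmark-based kinematic extraction, and a statistical layer of ordinary
regressions plus phylogenetically corrected correlations. A synthetic-data
generator stands in for a collection of physical models and their high-speed
videos, so the whole pipeline is testable at the desk.

## Moments of inertia from silhouettes

A flat model of areal density $\rho$ (g/cm$^2$) rotating about a vertical
axis has

$$I \;=\; \sum_i m_i\, r_i^2 ,$$

summed over small elements of mass $m_i$ at perpendicular distance $r_i$
from the axis. `decompose_strips()` realises this by slicing a silhouette
polygon into bands parallel to the axis. Two modes exist:

* **exact** (default): each band is the exact polygon clip; band areas sum
  to the polygon area to machine precision, and $r_i$ is the clipped
  region's centroid distance. The approximation error of treating a band as
  concentrated at its centroid is $O(w^2)$ in the strip width $w$, which the
  test-suite verifies as second-order convergence.
* **rectangle**: each band is a rectangle spanning the silhouette's height
  at the band midline. This reproduces a hand-measurement protocol (marking
  rectangles on a photograph) and is kept as a fidelity mode; the exact mode
  is strictly more accurate and converges to the same limit.

Default strip widths are 0.5 cm for head and fins and 0.7 cm for the body;
densities default to 1.44 g/cm$^2$ (4 mm foamed-PVC head and body) and
0.475 g/cm$^2$ (fin sheet). Axes are chosen to match the physical setup:
the head rotates about the hinge at the head–body joint, while the body and
fins rotate about the model's centre of mass, where the mounting rod sits.
The *lateral MOI* is the body plus dorsal, anal and caudal fin MOIs about
the COM axis; the pelvic fin is computed and reported but excluded from the
sum (it contributes on the order of 1% here), and the *relative MOI* is
head MOI over lateral MOI. A partial last strip is retained — dropping it
would violate area conservation.

An independent `pixel_oracle_moi()` integrates $\rho\,r^2$ over foreground
pixels of a rasterised mask. It shares no code with the strip engine and
serves as brute-force ground truth in the tests (agreement within 1% at
0.01 cm/pixel on random convex polygons).

## Flick dynamics

The simulated apparatus stores elastic energy in a spring held by a
dissolving latch. On release a constant torque $\tau$ acts between head and
body. The head obeys $\tau = I_{head}\,\alpha$; drag-free, the time to a
stop angle $\theta$ is $t = \sqrt{2\theta I_{head}/\tau}$ and mean flick
speed is $\theta/t \propto I_{head}^{-1/2}$ — the first hypothesis's
mechanism. Conservation of angular momentum couples the two segments:

$$I_{head}\,\omega_{head} = I_{lateral}\,\omega_{body},$$

so the body counter-rotates by (relative MOI) $\times\,45^\circ$ during a
45° flick — the second hypothesis's mechanism.

`simulate_flick()` integrates both segments with a classical fixed-step
RK4 (default $dt = 10^{-5}$ s; halving $dt$ moves the crossing time by far
less than 0.01%). The spring torque acts on the head and, with opposite
sign, on the body (action–reaction). This formulation was chosen over
coupling the body to the head through the momentum-balance rate because it
makes the two readings coincide exactly in the drag-free case ($I_h\omega_h
= \tau t = I_l\omega_b$ at every instant) while behaving sensibly when
resistive torques are switched on: an optional quadratic drag
$-c\,\omega|\omega|$ per segment lengthens the flick, during which the
reaction torque keeps accelerating the body, so the measured body
displacement *exceeds* the momentum-balance prediction — the regime the
physical models displayed. Drag is off by default; the drag-free mode is
the exact analytical reference the acceptance tests pin down to $10^{-6}$.

Sign conventions: the head flicks to the model's left (positive yaw), the
body recoils negatively; angles are integrated in radians and reported in
degrees. The integration continues some 10 video frames past the stop
angle so that sampled series cross the threshold cleanly even under
digitization noise.

## Landmarks and kinematic extraction

Four landmarks are emitted per frame at 250 fps, in the ventral (yaw-plane)
view the camera records: (1) anterior head tip, (2) posterior head tip at
the hinge, (3) anterior ventral body tip, (4) posterior body tip. On a
laterally symmetric model these lie on the midline at rest, so the resting
head–body angle is zero. Trials begin 10 frames before release;
`add_measurement_noise()` perturbs every landmark with isotropic Gaussian
noise (default 0.02 cm) to emulate manual digitization.

`angles_from_landmarks()` computes the unsigned angle between the head
vector (2→1) and body vector (4→3), and the signed, unwrapped earthbound
orientation of the body vector. `flick_metrics()` then locates the first
45° crossing by linear interpolation between the bracketing frames — the
alternative of snapping to the first frame past threshold quantises time
at the frame interval and biases speeds at 250 fps — and
reports the mean head angular speed $45^\circ/(t_{end}-t_0)$ together with
the absolute body displacement between interpolated endpoints. $t_0$ is
taken from trial metadata when present, otherwise detected as the first
frame whose head–body angle exceeds 0.1°. Speeds are mean rates over the
flick, not instantaneous rates at threshold: the flick is defined by a
fixed excursion, and the time to complete it is the measured quantity.

## The synthetic study

`generate_study()` produces the full bundle the statistics consume: a
pure-birth (Yule) phylogeny rescaled to unit height with 17 tips; six
correlated, standardized traits evolved along it; one silhouette per
species; MOI summaries; and 6–10 flick trials per species.

**Trait evolution.** Each trait follows a root-conditioned
Ornstein–Uhlenbeck process on the tree. Two tips sharing time $t$ on a tree
of height $T$ have correlation

$$\frac{e^{-2\alpha (T-t)}\left(1-e^{-2\alpha t}\right)}{1-e^{-2\alpha T}},$$

which limits to Brownian motion ($t/T$) as $\alpha \to 0$ and to
independence as $\alpha \to \infty$. Cross-trait structure comes from a
fixed correlation matrix (dorsal–anal 0.9, body–caudal 0.7, head–body 0.5,
weaker elsewhere); traits receive the cross-correlation first and each
column is then given its own tree structure through the Cholesky factor of
its OU correlation. With equal OU strengths this is exactly the Kronecker
tree-by-trait covariance model; with unequal strengths it is the natural
per-trait generalisation (an exact joint model with unequal $\alpha$ has no
Kronecker form). Default $\alpha = 1$ per unit tree height: moderate
signal.

**Silhouettes.** Shapes are parametric polygon families, not traced
outlines — the analysis needs realistic MOI ranges and correlation
structure, not species-accurate geometry. The head is a trapezoid, deep at
the hinge and tapering toward the mouth, always normalised to exactly
30 cm$^2$ so that head-MOI variation reflects mass distribution alone; the
head-shape trait reaches the empirical head-MOI band 1969–3534 g cm$^2$
(about two-fold) through a saturating tanh link, reflecting a bounded range
of head elongation at fixed area, and the link is inverted analytically to
a head length. The body is a fusiform polygon whose depth trait sets a
body-MOI target inside a band chosen so the *lateral* MOI (body plus fins)
spans roughly four-fold around $10^5$–$5\times 10^5$ g cm$^2$, matching the
printed body-MOI span and the smallest relative MOI of about 0.005. Fins
are triangles/trapezoids scaled by their traits; the body dominates every
individual fin's contribution, and model geometry is anchored to the MOI
bands rather than to any particular overall length.

**Flick parameters.** Spring torque defaults to $3.2\times 10^6$
g cm$^2$ s$^{-2}$ with 2% lognormal jitter across trials, and the quadratic
drag coefficients default to 3.2 times the respective MOIs. No spring
stiffness is reported for the physical models, so the torque/drag pair is
calibrated once to place species-mean speeds inside the observed
600–1150 °/s band with body displacements of order 1–2°, roughly twice the
momentum-balance floor; these defaults are the study conditions and are
not adjusted per analysis. Landmark noise (0.02 cm) and torque jitter give
within-species speed CVs of a few percent, consistent with averaging 6–10
trials per model.

What the generator does *not* emulate: real digitization outliers,
3-D mass distribution and body girth (the models are flat plates),
pectoral fins, pitch/roll, or fluid–structure interaction. Green tests
therefore validate the analysis chain and its internal physics, not
organism-level realism.

## Statistics

`fit_ols()` is the closed-form simple regression (slope, standard errors,
adjusted $R^2$, $F(1, n-2)$, two-sided $p$), applied to species means:
flick speed on head MOI and body displacement on relative MOI. These
regressions are deliberately *non-phylogenetic*: every model is powered by
the same spring mechanism, so species identity explains no variation in the
driving forces; responses are unweighted species means across trials. A
constant response is flagged degenerate with slope 0 and $p = 1$ rather
than an error.

`phylo_pearson()` is the phylogenetically corrected Pearson correlation
used for the surface–surface MOI comparisons (on log MOIs, the scale on
which they vary by folds). For each trait it maximises the marginal
Gaussian likelihood of the OU strength $\alpha \in [0, 50]$ (mean and
variance profiled out by GLS, with the Brownian boundary $\alpha = 0$
checked explicitly), whitens the trait by the Cholesky factor of the fitted
correlation, and reports the Pearson correlation of the whitened residuals
with a two-sided $t$ approximation on $n-2$ degrees of freedom. This is a
transparent reimplementation of the OU-GLS idea rather than a port of any
particular package's estimator; its correctness surface is (i) exact
reduction to the ordinary Pearson correlation on a star phylogeny, (ii)
recovery of known cross-correlations on simulated trees (mean within 0.05
of a true 0.7 at 100 tips), and (iii) type-I error near the nominal 5% on
a deep caterpillar tree where the naive Pearson correlation is visibly
inflated. $p$-values are two-sided.

## Numerical choices and degenerate inputs

* Strip decompositions reject zero-area polygons and non-positive widths;
  empty decompositions have MOI 0.
* The 45° crossing and both displacement endpoints are linearly
  interpolated; a series that never crosses raises an explicit error, as
  does a simulation whose head cannot reach the stop angle within
  `max_time`.
* Tip correlation matrices are checked by condition number before
  factorisation; a singular matrix aborts with a diagnostic.
* All randomness flows through explicit seeds; `generate_study()` is
  byte-reproducible under a fixed seed.
* Problem sizes in the routine test-suite are deliberately small (4–8
  species, 1–3 trials, coarser $dt$); the acceptance checks run the full
  17-species default study and Monte-Carlo batches of 100–1000 replicates.

## A worked run

```{r, eval = FALSE}
study <- generate_study(seed = 1)
species_table(study)
models <- run_study_models(study)
glance(models)
correlation_table(models)
autoplot(models)
```

On the default study this yields speeds declining with head MOI (negative
slope) and displacements rising with relative MOI (positive slope), with
species-mean speeds inside 600–1150 °/s — the qualitative pattern the
physical experiments showed. The same numbers are recomputed from scratch
by `scripts/acceptance.R`.

## Known limitations

* The OU parameterisation of `phylo_pearson()` estimates each trait's
  signal separately; a joint bivariate estimator could differ numerically
  on small trees.
* Constant spring torque is an idealisation; real springs relax.
* The drag model is a lumped quadratic torque per segment, not
  hydrodynamics; it exists to span the observed displacement regime, and
  its coefficients are not identifiable from the emitted kinematics alone.
* Strip MOIs are planar: girth and thickness variation of real fishes are
  out of scope by design.
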