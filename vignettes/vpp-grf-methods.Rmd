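---
title: "Predicting per-foot ground reaction forces with a virtual pivot point"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting per-foot ground reaction forces with a virtual pivot point}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vppgrf)
```

## The problem

Force plates measure the three-dimensional ground reaction force (GRF)
under each foot, but they are confined to laboratories. Whole-body
kinematics, by contrast, can be captured almost anywhere (optical capture,
IMU suits). The Newton equation for the whole body,

$$\mathbf{F}_{COM}(t) = M\,\mathbf{a}_{COM}(t) + M g\,\hat{\mathbf{z}},$$

gives the *total* external force from kinematics alone when ground contact
is the only other external force. In single support that settles the
question: the whole force acts at the stance foot's centre of pressure
(COP). In double support, however, any split of
$\mathbf{F}_{COM}$ between the feet satisfies the equation — the problem is
under-determined. Worse, the naive split (half the force to each foot)
predicts *zero* lateral foot forces during a squat, because the lateral COM
acceleration is nearly zero; measured lateral forces are non-zero and
opposite between the feet.

The virtual pivot point (VPP) concept supplies the missing constraint:
during upright movement the per-foot GRF lines of action approximately
intersect at a point above the centre of mass. Fixing the direction of each
foot's force as the line from its COP to that point leaves only two scalar
magnitudes to determine, and the Newton equation then *over*-determines
them.

## The model

Per frame, the pipeline computes:

1. **COM force.** $\mathbf{F}_{COM} = M\,\mathbf{a}_{COM} + Mg\hat{\mathbf z}$,
   with $\mathbf a_{COM}$ from second-order central finite differences of
   the COM position (one-sided second-order stencils at the series ends,
   which are flagged and excluded from evaluation). The gravity term is
   written out explicitly: without it, quiet standing would predict zero
   GRF instead of body weight.
2. **Contact weights and COP.** Each foot is represented by 18 contact
   points. Point $i$ carries the weight
   $W_i = W\!P(z_i)\cdot W\!V(\lVert \mathbf v_{i,xy}\rVert)$, where both
   transition functions are raised-cosine ramps: $W\!P$ falls from 1 to 0
   as the point's height crosses the band $[0.8\,z_{lim},\,z_{lim}]$ with
   $z_{lim} = 0.04$ m, and $W\!V$ falls across
   $[0.15\,v_{lim},\,v_{lim}]$ with $v_{lim} = 1.3$ m/s. Outside the bands
   the functions are clamped to 1 and 0 — the only reading under which they
   are monotone transitions from full contact to none. The foot's COP is
   the $W$-weighted mean of its point positions, projected onto the ground
   plane; a total weight below 0.05 marks the foot airborne (undefined COP
   rather than a 0/0).
3. **Support phase.** Both feet defined → double support; one → single
   support; none → flight.
4. **VPP placement.** The VPP's planar position follows the force line
   through the COM,
   $\mathrm{VPP}_{xy} = \mathrm{COM}_{xy} + (\mathrm{COM}_z / F_{COM,z})\,\mathbf F_{COM,xy}$,
   and its height is $\mathrm{VPP}_z = \mathrm{VPPscale}\cdot BH$ with body
   height $BH$. Frames with $|F_{COM,z}|$ below $10^{-6}\,BW$ (flight
   transitions) are degenerate; the VPP then sits vertically above the COM
   and the frame is flagged.
5. **Force decomposition.** With unit virtual pivot vectors
   $\mathbf u_{L/R} = (\mathrm{VPP}-\mathrm{COP}_{L/R}) / \lVert\cdot\rVert$,
   the magnitudes solve
   $[\mathbf u_L\; \mathbf u_R]\,(a, b)^T = \mathbf F_{COM}$ in the
   least-squares sense. In single support the entire COM force acts at the
   stance COP; in flight both GRFs are zero.

### Assumptions

* Ground contact and gravity are the only external forces (no handrails,
  no carried loads).
* Rotational dynamics are ignored: the Newton translational equation is
  applied to the COM alone; no free moment about the vertical axis is
  predicted.
* One VPP serves all double-support frames of a movement; a single
  constant `vppscale` per trial. (There is evidence that the pivot moves
  between phases; the solver accepts a per-call scale so a time-varying
  schedule can be layered on top, but the default is constant.)

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `vppscale` | 0.9 | – | VPP height as a fraction of body height; 0.9 minimises prediction error across walking, squat and lunge |
| `z_lim` | 0.04 | m | upper edge of the position transition band |
| `v_lim` | 1.3 | m/s | upper edge of the velocity transition band |
| `w_support_threshold` | 0.05 | – | minimum summed point weight for a defined COP |
| `eps_fz` | $10^{-6} BW$ | N | degenerate-frame guard on $F_{COM,z}$ |
| `cond_limit` | $10^8$ | – | condition-number guard on the direction matrix |
| `nonneg_policy` | clamp_reassign | – | unilateral-contact handling (below) |
| `cop_cutoff`, `force_cutoff` | 40, 20 | Hz | zero-phase Butterworth cutoffs for measured COP / force channels |
| `com_cutoff` | off | Hz | optional COM smoothing before double differentiation |

## Numerical choices

**Least squares.** The 3×2 solve is implemented in closed form through the
2×2 normal equations of the two unit columns. At the default guard the
system is far from the conditioning regime where normal equations lose
accuracy (the Gram matrix of two unit vectors is `[[1, c], [c, 1]]` with
`c` their cosine; the guard trips long before `1 - c²` underflows), and the
formulation has a useful exactness property: every quantity is a dot
product, which is invariant under a sagittal reflection, so mirroring a
trial across the `y = 0` plane swaps the predicted per-foot forces
*bit-exactly*. The test suite checks the solution and its residual against
`qr.solve` and an explicit orthogonal projection.

**Non-negativity.** The ground cannot pull a foot down. If the raw
least-squares solution assigns a negative magnitude, the default policy
(`clamp_reassign`) zeroes that foot and refits the other as a 1-D
projection — one step of an active-set method, which for two unknowns is
exact. `allow_negative` retains the raw solution for comparison studies.
Frames whose pivot directions are nearly parallel (COPs nearly coincident)
are flagged and the force split 50/50 along the mean direction.

**Differentiation.** Second-order central differences; one-sided
second-order stencils at the ends. A convergence test confirms the error
falls fourfold when the sample rate doubles.

**Zero-phase filtering.** Butterworth coefficients come from
`signal::butter`; the forward–backward application is implemented in the
package with odd-reflection padding and steady-state initial conditions
(matched step response). This keeps constant signals exact to machine
precision and confines boundary transients to the discarded pad, which the
plain forward–backward recursion does not.

**Degenerate inputs.** Undefined COPs become airborne feet, not errors;
near-zero vertical COM force falls back to a VPP above the COM;
segmentation failures and malformed files raise located errors. Ties in
the scale selection break toward the smaller scale.

## The VPPscale sweep

For evaluation, predictions at each grid value (0.2 to 2.0 in steps of
0.1) are scored against reference per-foot forces by the root-mean-square
error per direction (anterior, lateral, vertical), pooled over both feet
and normalised by body weight. Pooling the feet matches the per-direction
granularity at which such errors are reported; a summed-GRF error would
hide exactly the between-feet split the method exists to predict. Across
trials the package aggregates by the median of the summed directional
RMSE and takes the grid argmin — a reproducible replacement for reading
the optimum off a plot. Movement segments enter the score: walking from
one left-foot contact to the next (a double step); squat and lunge from
the first frame the COM vertical velocity drops below −0.02 m/s to the
last frame it exceeds +0.02 m/s. The 0.02 m/s threshold is this package's
choice; it is small against peak squat velocity (≈0.3 m/s at the defaults)
yet above filtered noise.

Above the optimum the error surface flattens: raising the pivot further
changes the angle between the two pivot directions less and less, so the
decomposition becomes insensitive to the exact height — the sweep test
asserts the mean slope above 0.9 is smaller than below 0.8.

## The synthetic generator

Real force-plate data cannot ship with a package, so every stage is
exercised on generated trials whose ground truth is known by construction:

* **Squat** — feet planted symmetrically (0.35 m apart laterally), COM
  descending and ascending along a raised-cosine of depth 0.30 m over 3 s,
  two cycles between 1 s of quiet standing on either side, 120 Hz. The COM
  stands above the centroid of the two COPs, as static equilibrium
  requires.
* **Inline lunge** — the same with the feet also offset 0.60 m
  antero-posteriorly; the truth then has opposing anterior force
  components between the feet.
* **Walking** — 1.2 m/s, 0.65 m steps, each step 20 % double support,
  soles rolling heel-to-toe through a pitch profile so the contact-model
  COP travels forward under the foot; swing feet lift 8 cm with fast
  lift-off and late touchdown so detected contact stays within about three
  frames of the schedule.

Truth forces are built with the *same geometry* the solver assumes — the
decomposition along the two COP-to-VPP directions at a known scale — but
through a different numerical path (`qr.solve` per frame rather than the
closed-form normal equations). With two independent directions the
least-squares solution is unique, so a recovery test is exact and
meaningful *as a consistency check of the chain* (contact model, COP,
Newton force, placement, solve): it shows the pipeline inverts its own
generative model, not that the VPP assumption holds for real humans —
that evidence belongs to force-plate studies.

Two generator simplifications matter for interpretation. Walking is
generated with zero step width (both feet progress along `y = 0`): this
keeps the COM force exactly in the span of the two pivot directions, so
the constructed truth closes over the Newton force to machine precision
at every frame. Real gait has a finite step width and out-of-plane force
components the two-direction model can only approximate. And noise, when
requested, is additive white Gaussian position noise on the exported COM
only — real IMU error is coloured, drifting and configuration-dependent.

### Smoothing noisy kinematics

Double differentiation amplifies position noise by $\omega^2$. For white
position noise of standard deviation $\sigma$ at sample rate $f_s$, the
acceleration noise variance after a zero-phase second-order low-pass at
$f_c$ is approximately
$\sigma^2 (2\pi)^4 f_c^5 \cdot 0.83 / (f_s/2)$ — it grows with the *fifth*
power of the cutoff. The error introduced by this acceleration noise is
not direction-neutral: a lateral force error $e_y$ splits into per-foot
vertical components of magnitude $e_y h / (2w)$ (pivot height $h$, half
stance width $w$), which *grows* with the pivot height and can therefore
bias the sweep toward small scales if left unchecked. The squat signal
itself is essentially a single harmonic at $1/\text{period}$ (0.33 Hz at
the defaults), so a 1.5 Hz cutoff passes better than 99 % of its
acceleration content while, by the expression above, keeping the lateral
force noise near 2 N for $\sigma = 2$ mm — comfortably below the
per-grid-step signal differences. That is the `com_cutoff` used whenever
noisy squat kinematics enter the sweep; for faster movements the cutoff
should scale with the movement fundamental (a common rule of thumb is
4–6× the highest frequency of interest).

## Problem sizes

The shipped tests and the acceptance script run squat and lunge trials of
8 s (961 frames at 120 Hz), walking trials of about 2.3 s (274 frames),
19-point sweeps, and a 20-seed noise-recovery study — sizes at which every
stage's behaviour is already asymptotic (the round-trip error sits at
~10⁻¹⁴ relative) while the whole suite stays fast on one core.

## Known limitations

* No free moment or joint torques; no inertia-tensor (Euler) terms in the
  COM force.
* Single support bypasses the VPP entirely; if the pivot assumption is
  wanted there too, it must be layered on by the caller.
* The 18-point sole layout is a versioned package default (two heel, four
  midfoot, eight forefoot, four toe points over the sole rectangle);
  published figures of such layouts give no coordinates, so results should
  cite the layout version when the COP model matters.
* The contact model knows nothing of shoe-sole compliance or friction
  limits; forces are attributed purely geometrically.
* Measured-data preprocessing (40/20 Hz cutoffs) follows standard
  force-plate practice; mains-hum removal is left to the generic
  `median_filter` utility and is not part of the reference pipeline.
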