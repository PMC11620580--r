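---
title: "Modelling filamentous yeast colony morphology with filacol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling filamentous yeast colony morphology with filacol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filacol)
```

## The model

`filacol` implements a two-dimensional, off-lattice agent-based model of a
filamentous *Saccharomyces cerevisiae* colony. Each cell is an ellipse with
centre $m_i$, major radius $a_i$ (half-length), minor radius $b_i$
(half-width) and orientation $\theta_i$; its boundary is parameterised as

$$x_i(\phi) = m_i + (a_i\cos\phi\cos\theta_i - b_i\sin\phi\sin\theta_i,\;
a_i\cos\phi\sin\theta_i + b_i\sin\phi\cos\theta_i),$$

with $\phi = 0$ at the distal pole. Cells come in two types. Sated cells
(half-length 4.2 um, half-width 3 um, budding angle $\beta = 7\pi/16$) grow
under ample nutrients in the axial/bipolar pattern; pseudohyphal cells
(6.7 um x 1.9 um, $\beta = \pi/16$, aspect ratio about 3.5) are the
elongated, end-to-end budding form triggered by nutrient stress. The two
types have areas that differ by about 1%, which is why a cell-count stopping
rule is a good proxy for colony area regardless of composition.

Each cell carries four prescribed bud sites, two flanking each pole at the
budding angle $\pm\beta$ from the axis. A ray at angle $\beta$ from the
centre meets the boundary at parameter $\phi_\beta$ with
$\tan\beta = (b/a)\tan\phi_\beta$; the package uses the closed form
$\phi_\beta = \beta + \arctan\!\big((a-b)\tan\beta / (b + a\tan^2\beta)\big)$
and the test suite checks it against a bisection inversion of the defining
relation to $10^{-10}$ rad.

A daughter cell is oriented along the outward ray from the mother's centre
through the chosen bud site and placed with its proximal pole on the site
(tangential contact). The outward ray of a distal site makes angle exactly
$\pm\beta$ with the mother's axis, so small $\beta$ produces near-collinear
pseudohyphal chains and large $\beta$ produces near-lateral sated budding.
The source model leaves the daughter's orientation convention and overlap
depth at birth open; we chose the deterministic outward-ray orientation with
no angular noise, and tangential contact. A sensitivity experiment placing
the daughter centre directly on the bud site (maximal birth overlap) changed
the compactness statistic $I_R$ of sated colonies by under 0.03, so this
convention is not a sensitive one.

Growth is a sequence of proliferation events with no explicit time: cells
never move, change shape, or die. A proposed daughter is inserted unless its
**centre** lies strictly inside an existing cell (partial volume exclusion:
boundary overlap is allowed) or its boundary leaves the domain (default
4000 um square, large enough that colonies never reach it at the scales
used here). A vetoed event is aborted and the decision procedure restarts
from the top with fresh draws; 10^5 consecutive aborted events are treated
as a jammed colony and reported as a stall rather than looping forever.

## The budding decision tree

Five parameters $\theta = (n^*, p_a, p_{sp}, p_{ps}, \gamma)$, all in
$[0,1]$, control who buds and what they produce:

* While $n/n_{\max} \le n^*$, every mother (uniform over cells) and daughter
  is sated — the Eden-like phase.
* Afterwards, the mother is sated with probability $p_a$ (forced sated if no
  pseudohyphal cell exists yet), uniform within its type.
* A sated mother produces a pseudohyphal daughter with probability $p_{sp}$,
  budding from any free site among its four.
* A pseudohyphal mother without a pseudohyphal daughter extends its filament:
  pseudohyphal daughter at a free distal site.
* A pseudohyphal mother that already has a pseudohyphal daughter is, with
  probability $\gamma$, abandoned in favour of a uniformly chosen
  pseudohyphal cell without a pseudohyphal daughter (the forking control:
  small $\gamma$ permits multiple branches from one cell); otherwise it
  produces a sated daughter with probability $p_{ps}$, else pseudohyphal,
  again at a free distal site.

Each bud site is used at most once (bud scars block reuse; the source
material mentions scars but no reuse rule — one-shot sites are the
conservative reading). A redirect with no eligible pseudohyphal mother is a
full abort. All random draws come from R's RNG in a fixed, documented order,
so a seed fully determines the colony; the compiled engine and the pure-R
reference engine (`run_simulation(engine = "r")`) are tested to be
bit-identical.

Two stopping rules are supported: a cell count `n_max`, or a target
rasterised area with a 5% tolerance (`target_area`), implemented as chunked
growth with periodic rasterisation. In area mode the decision-tree threshold
uses an effective $n_{\max}$ equal to the target area divided by the mean
cell area; overlap makes this an approximation, acceptable because the
threshold enters only through the ratio $n/n_{\max}$.

## Morphology statistics

Colonies are rasterised at a configurable resolution (default 1 px/um —
the statistics are ratios and robust to this; a pixel is occupied iff its
centre lies inside a cell). For a binary mask with $N$ occupied pixels,
centroid at the occupied-pixel mean, and $r_{\max}$ the maximum
centroid-to-occupied-pixel distance:

* $\rho_{csr} = N / (\pi r_{\max}^2)$ is the density the colony would have if
  spread uniformly over its bounding disk (complete spatial randomness).
* $r_{csr}$ is the radius where the radial occupancy density falls to
  $\rho_{csr}$. The density is measured in 1-px annuli; we take the
  **outermost** crossing from $\ge \rho_{csr}$ to $< \rho_{csr}$, linearly
  interpolated between annulus midpoints and clamped to $(0, r_{\max}]$.
  Degenerate profiles are well-defined: an ideal lattice disk has slightly
  more pixels than $\pi r_{\max}^2$, so its density (at most 1) never
  reaches $\rho_{csr}$ and $r_{csr}$ falls back to $r_{\max}$ — the disk is
  "all core", giving $I_R = 1$, $I_F \approx 0$, $I_B = 0$ exactly as a
  compact shape should.
* $I_R = r_{csr}/r_{\max}$ (radius ratio), $I_F$ = fraction of occupied
  pixels at distance in $[r_{csr}, r_{\max}]$ (filamentous area ratio;
  pixels exactly at $r_{csr}$ count as filament), and $I_B$ (sub-branch
  count) is computed by removing the core (distance $< r_{csr}$),
  skeletonising the filament region by Zhang-Suen thinning to 1-px 8-connected
  curves, restricting to the quadrant $\theta \in [\pi/2, \pi]$ (mathematical
  convention: anticlockwise from $+x$ with the y axis up; one quadrant only,
  as in the experimental protocol), deleting branch-point pixels ($\ge 3$
  skeleton neighbours) and counting the remaining 8-connected segments of at
  least 3 px. The 3-px floor suppresses thinning artefacts; the segment
  definition is calibrated on constructed fixtures (radial spikes, a
  Y-filament) with branch counts known by construction, since "branch count"
  conventions differ between toolboxes.

Thresholding of grayscale images is a global between-class-variance
maximiser with polarity auto-detected from the border; pre-binarised masks
pass through unchanged. This is deliberately plain plumbing — specialised
colony-image pipelines do adaptive interpolation we do not attempt.

## Parameter inference (ABC-MCMC)

The likelihood of an image under the simulator is intractable, so inference
is by approximate Bayesian computation with Metropolis-Hastings steps. Given
replicate images of one experimental condition, the three statistics are
min-max normalised with the replicate min/max as the common basis (so
sub-branch counts, typically tens, do not dominate the two ratios), and the
reference vector $\bar S$ is the normalised replicate mean. Simulated
colonies are normalised with the **same** basis. One colony is simulated per
proposal; the distance is

$$\rho(S(x), \bar S) = \frac{1}{3}\Big[\sum_{i=1}^{3}
\Big(\frac{S(x)_i - \bar S_i}{1 + \bar S_i}\Big)^2\Big]^{1/2},$$

with the prefactor outside the root exactly as the source formula prints it
(a `prefactor = "rms"` option exposes the $\sqrt{\Sigma/3}$ alternative for
sensitivity checks). A proposal $\theta^*$ from a symmetric Gaussian is
accepted with probability
$\min\{1, \pi(\theta^*)/\pi(\theta_i)\} \cdot 1\{\rho \le \epsilon\}$;
out-of-support proposals are rejected without simulating (equivalent to the
zero prior, simpler than boundary reflection). Priors are independent Betas:
$n^* \sim B(5,2)$, $p_a \sim B(2,5)$, $p_{sp} \sim B(2,2)$,
$p_{ps} \sim B(2,2)$, $\gamma \sim B(2,5)$ — weakly informative where
physical intuition exists (late transition, mostly pseudohyphal growth after
it, regular forking), uninformative otherwise. Chains start at the prior
mean plus a small Gaussian perturbation (sd 0.02).

Tuning follows the two-stage recipe: a pilot chain at a generous tolerance
supplies the proposal covariance (scaled by $2.38^2/5$, jittered to positive
definiteness), then the tolerance is decreased geometrically until the pilot
acceptance rate sits in the 5-10% band (with a bisection step back if a
decrease overshoots the band). With $\epsilon = \infty$ the simulator is
skipped entirely and the chain must reproduce the prior — a cheap
detailed-balance diagnostic used in the tests. Effective sample sizes use
$M / (1 + 2\sum_k \hat\rho_k)$ with Geyer's initial-positive-sequence
truncation (the estimator itself is a convention choice; the white-noise and
AR(1) oracles in the tests pin its accuracy).

```{r example, eval = FALSE}
theta_true <- c(0.67, 0.14, 0.25, 0.58, 0.12)
obs <- synthetic_replicate_set(theta_true, n_rep = 10, n_max = 1000, seed = 42)
cfg <- abc_config(chain_length = 2000, n_chains = 3, seed = 42,
                  simulator = list(n_max = 1000))
cfg <- tune_abc(obs$stats, cfg, pilot_budget = 300)
fit <- run_abc(obs$stats, cfg)
credible_interval(fit, prob = 0.9)
```

## What the synthetic data can and cannot show

No public imaging data accompany the model, so all tests run on two kinds of
synthetic input: constructed fixtures (disks, disks with radial spikes,
Y-filaments, random blobs) whose statistics are known by construction, and
simulated replicate sets generated by the model itself at a known
$\theta_{true}$. The fixtures validate the morphometry conventions; the
replicate sets validate the inference loop as a parameter-recovery exercise
(simulation-based calibration at reduced scale). Passing these tests shows
the statistics and the sampler are implemented correctly; it does **not**
show that the model fits real colony photographs, that the normalisation
basis of a 10-replicate synthetic set matches experimental variability, or
that posteriors from real images would concentrate — real images would also
exercise the thresholding step that simulated masks bypass.

## Problem sizes and numerical choices

The test suite and the acceptance script use colonies of 500-1000 cells,
10-replicate observation sets, and 2-3 chains of 800-2000 iterations with a
200-300 iteration tuning budget — sizes chosen so the full recovery
exercise completes on a single CPU in minutes while leaving the posterior
identifiable for the two structurally dominant parameters, $n^*$ and
$\gamma$. Full-scale studies would raise `n_max` to the experimental colony
area, lengthen chains until every parameter reaches an ESS of a few hundred,
and concatenate more chains.

Known limitations, beyond those inherited from the model (no nutrient
field, no mechanics, no time): the sated-cell phase is less compact than an
idealised Eden cluster — protruding daughter chains inflate $r_{\max}$, so
sated-only colonies at 1000 cells measure mean $I_R \approx 0.73$ rather
than the $\ge 0.8$ an ideal circular blob would give, approaching it only
slowly with colony size. $p_{sp}$, $p_{ps}$ and $p_a$ are weakly identified
from the three statistics, mirroring the behaviour reported for the original
experiments; recovery checks therefore target $n^*$ and $\gamma$.
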