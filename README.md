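# filacol

Under nutrient stress, colonies of the budding yeast *Saccharomyces
cerevisiae* switch from compact, circular (Eden-like) growth of ovoid
"sated" cells to pseudohyphal growth: cells elongate to an aspect ratio of
about 3.5 and bud end-to-end from their distal pole, sending thin filaments
out from the colony to forage for nutrients. `filacol` is for researchers
who want to connect that single-cell budding behaviour to whole-colony
morphology: it provides an off-lattice agent-based simulator of the
process, image statistics that quantify filamentous morphology, and
likelihood-free Bayesian inference to recover budding parameters from
replicate colony images.

The package has three layers:

* **Simulation** — cells are ellipses (sated: 4.2 × 3 µm, budding angle
  β = 7π/16; pseudohyphal: 6.7 × 1.9 µm, β = π/16) budding from four
  prescribed sites, two flanking each pole at ±β. Five parameters
  θ = (n\*, p_a, p_sp, p_ps, γ) govern the decision tree: all growth is
  sated until the colony reaches the fraction n\* of its final size; after
  that, a sated mother is chosen with probability p_a and produces a
  pseudohyphal daughter with probability p_sp; pseudohyphal mothers extend
  filaments distally, and γ controls forking — the chance that a mother
  which already has a pseudohyphal daughter is abandoned in favour of a
  fresh branch tip. Volume exclusion is partial: an event is aborted only
  if the new cell's centre would fall strictly inside an existing cell.
* **Morphometry** — colonies (or photographs, via global thresholding) are
  reduced to binary masks, from which three statistics are computed: the
  radius ratio I_R = r_csr / r_max (fraction of the colony radius occupied
  by the compact core), the filamentous area ratio I_F (fraction of
  occupied pixels in the annulus between r_csr and r_max), and the
  sub-branch count I_B (skeleton branch segments in the upper-left
  quadrant of the filament region, by Zhang–Suen thinning).
* **Inference** — ABC-MCMC: summary statistics are min–max normalised
  against the replicate set, compared through the normalised Euclidean
  distance ρ(S(x), S̄) = (1/3)·[Σᵢ((Sᵢ − S̄ᵢ)/(1 + S̄ᵢ))²]^{1/2}, and a
  Metropolis–Hastings chain with Beta priors and a Gaussian proposal
  accepts θ\* when the simulated colony lands within a tolerance ε, tuned
  for a 5–10% acceptance rate.

## Worked example

Simulate a 1000-cell colony at θ = (0.67, 0.14, 0.25, 0.58, 0.12),
rasterise it at 1 px/µm, and measure its morphology:

```r
library(filacol)
params <- sim_params(0.67, 0.14, 0.25, 0.58, 0.12, n_max = 1000, seed = 7)
colony <- run_simulation(params)
colony
#> <colony> 1000 cells (761 sated, 239 pseudohyphal), 4496 aborted events
mask <- colony_to_mask(colony)
summarise_mask(mask)
#> <colony_stats> I_B = 5, I_F = 0.1764, I_R = 0.5620 (r_csr = 150.8, r_max = 268.3 px, N = 31148)
```

Read: the compact core reaches 56% of the colony's maximum radius
(I_R = 0.56), 17.6% of the colony's area lies in the filamentous annulus
(I_F), and the skeleton of the filament region carries 5 branch segments in
the counting quadrant (I_B). Raising n\* toward 1 suppresses filaments
(I_F → 0, I_R → 1); lowering γ makes branches fork more.

To infer parameters from replicate masks (here, synthetic replicates at a
known truth):

```r
obs <- synthetic_replicate_set(c(0.67, 0.14, 0.25, 0.58, 0.12),
                               n_rep = 10, n_max = 1000, seed = 42)
cfg <- abc_config(chain_length = 2000, n_chains = 3, seed = 42,
                  simulator = list(n_max = 1000))
cfg <- tune_abc(obs$stats, cfg)      # proposal covariance + tolerance
fit <- run_abc(obs$stats, cfg)       # 3 chains, concatenated after burn-in
credible_interval(fit, prob = 0.9)   # marginal 90% intervals
```

The methods vignette (`vignettes/colony-morphology.Rmd`) documents the
model assumptions, the morphometry conventions (annulus density crossing,
branch-segment definition, quadrant convention) and the inference design
choices in detail.

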