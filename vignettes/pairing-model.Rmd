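---
title: "An agent-based model of meiotic homolog pairing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of meiotic homolog pairing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(meiopair)
```

## The model

During meiotic prophase I every chromosome must locate and stably juxtapose
with its homologous partner among an excess of non-homologs. `meiopair`
simulates this homology search as an ensemble of interacting, self-propelled
agents: each chromosome is reduced to its center of mass $x_i \in \mathbb{R}^2$
moving in a flattened nuclear disc (radius $L = 3.25\ \mu m$, matching
surface-spread nuclei), with overdamped dynamics

$$\dot{x}_i = v_0 d_i + \sum_{j \neq i} F_{ij} + \sqrt{2D}\,\dot W,$$

where $v_0$ is the translational speed of motor-driven chromosome movements,
$d_i$ is the unit heading, $D$ the thermal diffusion constant of chromatin,
and $F_{ij} = -\nabla U(x_i - x_j)$ derives from short-range Morse potentials
built from Yukawa (decaying-exponential) terms:

$$U_{hom}(d) = C_{r1} e^{-d/\ell_{r1}} - C_a e^{-d/\ell_a}, \qquad
  U_{nonhom}(d) = C_{r1} e^{-d/\ell_{r1}} + C_r e^{-d/\ell_r}.$$

Homologs attract on the scale $\ell_a = 400$ nm — the reach of a resected
double-strand break performing the homology search — while non-homologs
repel on the same scale ($\ell_r = 400$ nm), standing in for dissociation of
heteroduplexes with insufficient homology. A strong excluded-volume term
($C_{r1}, \ell_{r1} = 50$ nm) keeps centers from overlapping; a purely
repulsive Yukawa wall of strength $C_b$ and scale $\ell_b$ confines the
ensemble to the nuclear disc. Once an unpaired homolog pair approaches
within the 400 nm capture distance it pairs permanently: the two members
collapse onto their midpoint, are rendered at a held 50 nm separation (the
scale of the synaptonemal complex), and move on as a single composite agent
that repels everything else as a non-homolog.

All base parameters (`force_params()`, `sim_params()`) are the calibrated
wild-type values: $C_a = C_r = 0.005$, $C_{r1} = 0.05$, $C_b = 0.15$,
$\ell_b = 0.05\ \mu m$, $v_0 = 0.3\ \mu m/s$, $D = 10^{-4}\ \mu m^2/s$.
Working units are micrometers and seconds; with a characteristic length of
1 µm the nondimensional and dimensional parameter values coincide, and the
simulation clock (starting at 0 s) is displayed offset by +3 h so a default
run spans the experimentally monitored window from t = 3 h (minimum pairing,
end of premeiotic S phase) to t = 9 h (pachytene).

## Chromosome size scaling

The 16 budding-yeast chromosomes span 230–1532 kbp. Longer chromosomes carry
more recombination intermediates engaged in the search, so `scale_radii()`
multiplies each chromosome's $\ell_a$ and $\ell_r$ by its length relative to
the karyotype mean (~754 kbp). The excluded-volume radius $\ell_{r1}$ is
*not* scaled: the held pairing distance reflects the uniform width of the
synaptonemal complex. When two chromosomes with different scaled radii
interact, the shared interaction scale is the arithmetic mean of their two
scales — the field does not prescribe a mixing rule, and the symmetric mean
is the choice that keeps the potential symmetric so the pair forces obey
action–reaction exactly.

```{r scaling}
ky <- yeast_karyotype()
head(scale_radii(ky$length_kbp), 4)
```

## Initial conditions and scenarios

`place_chromosomes()` draws positions uniformly in the disc and redraws any
chromosome landing within 400 nm of an already placed one, so no pair starts
paired; headings are independent uniform unit vectors. The mean initial
homolog separation is then close to the uniform-disc value
$128R/45\pi \approx 2.94\ \mu m$ (the exclusion lifts it by about 2%).

`build_scenario()` bundles the published experiment families: `base`
(16 uniform pairs), `uniform_n_pairs` (chromosome-number experiment),
`size_adjusted` (yeast karyotype), `velocity_sweep`
(150–600 nm/s), the `attraction_only` / `repulsion_only` /
`dominant_attraction` force ablations, the `dumbbell` polymer variant, and
two reduced-break (spo11-hypomorph) parameter sets: a 3-fold force
reduction using the conventional rounded strength 0.0017 (deliberately not
0.005/3), and a 77%-speed variant at $v_0 = 0.231\ \mu m/s$ whose
excluded-volume strength is 0.015 rather than the wild-type 0.05 — the
presets keep these values bit-exact rather than "correcting" them.

```{r scenario}
build_scenario("spo11_slow")
```

## The active-dumbbell variant

To give chromosomes elongation and orientation, each can be represented as
two beads joined by a bond with force $F_{b,i} = -(-1)^i\, 2\lambda D\, r$
on bead $i$, $r$ the bond vector. $\lambda$ plays the role of a Lagrange
multiplier constraining the mean-squared bond length to the chromosome size,
$\langle r^2 \rangle = \ell^2$. In this implementation propulsion acts on
the dumbbell as a whole (both beads share the chromosome's heading) while
noise is per bead, so the bond is an Ornstein–Uhlenbeck process with
stationary value $\langle r^2\rangle = 1/\lambda$ and the multiplier has the
closed form $\lambda = 1/\ell^2$ — shipped as `bond_stiffness = 1` on the
scale $\lambda = \texttt{bond\_stiffness}/\ell^2$.
`calibrate_bond_stiffness()` reproduces this value by bisection on long
free-dumbbell runs, and the test suite verifies
$\langle r^2\rangle/\ell^2 \in [0.95, 1.05]$. Each bead interacts with the
beads of every other chromosome; captured pairs collapse to the same
composite representation as in the single-bead model. The bond length
defaults to the chromosome's (size-scaled) attractive radius, so a dumbbell
spans the region its homology search covers.

## Analysis layer

All analyses are data-frame first and return tibbles:

* `pairing_fraction()` — fraction of homolog pairs within 400 nm, pooled
  over pairs × realizations; non-decreasing by capture permanence.
* `distance_curves()` — ensemble mean ± SD homolog distances, ranked within
  each realization by initial distance (ascending) or by chromosome length,
  reported at displayed 3/5/7/9 h. Ties break by pair id.
* `matched_nonhomolog_control()` — for every chromosome, the non-homolog
  whose initial distance best matches the homolog distance (ties to the
  lowest id); its distance curve is the specificity control and should stay
  statistically stationary. Matching is per chromosome against its own
  homolog distance.
* `residence_times()` — maximal contiguous intervals a non-homolog pair
  spends within 400 nm; analyses needing sub-second resolution re-run the
  scenario with `sample_every` ≤ 1 s rather than interpolating.

After capture the reported homolog distance is the held 0.05 µm, which is
what the distance plateaus in the sub-threshold band reflect.

```{r fixture}
fx <- fixture_trajectory()           # deterministic two-pair fixture
pairing_fraction(fx)[1:3, ]
```

## Numerical choices

* **Integrator** — Euler–Maruyama with fixed `dt = 0.05` s, so one
  propulsion step ($v_0\,dt = 15$ nm) resolves the shortest force scale
  ($\ell_{r1} = 50$ nm). `sim_params()` rejects any `dt` with
  $v_0\,dt \geq \ell_{r1}$.
* **Heading update** — $d_i$ is recomputed each step as the unit vector of
  the realized displacement (propulsion + forces + noise); a zero
  displacement keeps the previous heading. Collisions and thermal noise
  therefore redirect motion. An important consequence, discussed under
  limitations: the angular kick per step is
  $\approx \sqrt{2D\,dt}/(v_0\,dt)$, so the directional persistence time
  $\tau \approx v_0^2 dt^2/2D$ depends on the step size, making `dt` a
  physical parameter of this model family and not only a numerical control.
* **Pair capture ordering** — distances are evaluated after the position
  update; homolog capture fires on the center distance alone, regardless of
  simultaneous non-homolog overlap. The composite inherits the heading of
  the faster member at capture, the member axis is frozen, and the composite
  receives a single noise draw per step (one equation of motion per pair).
* **Coincident centers** — a zero separation (probability zero, but
  possible in constructed states) gets a deterministic pseudo-random
  direction from the realization's seeded stream with the $d \to 0$ limit
  magnitude, so no state produces NaNs.
* **Interaction cutoff** — pair forces are skipped beyond 5 µm, where the
  neglected drift is below $2\times10^{-5}\ \mu m/s$; configurable via
  `sim_params(interaction_cutoff=)`.
* **Seeds** — realization *r* of an ensemble uses `seed + r − 1`; all
  randomness (placement, bead initialization, noise, tie-breaks) flows
  through R's RNG, so trajectories are a pure function of (parameters,
  chromosomes, initial state, seed).

## What the generator emulates, and what a green test establishes

The synthetic world is exactly the stated one: Table-value forces, uniform
or yeast-karyotype chromosome sets, exclusion placement, the 3–9 h window.
Green mechanical tests establish that forces are exact negative gradients,
capture is permanent and homolog-specific, confinement and determinism
hold, the dumbbell bond is calibrated, and the analysis layer reproduces
constructed fixtures and closed-form oracles. They do *not* establish that
the emergent kinetics match the published curves — that comparison is made
separately by the acceptance checks, with the following caveat.

## Known limitations

With the documented assumptions (dt = 0.05 s, one nondimensional time unit
= 1 s), the heading rule gives a persistence time of ~1 s and an effective
translational diffusivity of ~0.05 µm²/s, so the 33 µm² nuclear disc is
searched in minutes. Essentially all homolog pairs are captured well before
the end of the 3–9 h display window in every scenario, at every velocity in
the published sweep: the published two-pair fraction (~75% at 7 h), the
velocity threshold between 210 and 240 nm/s, and the delayed pairing of the
three shortest yeast chromosomes are *not* reproduced — the corresponding
acceptance checks fail and are intentionally left failing. Because the
persistence time scales as $dt^2$, shrinking the step drives the model
toward a pure-diffusion limit (slower search but no velocity dependence),
so no step size recovers both the hour-scale kinetics and the velocity
threshold under the 1 s ≡ 1 unit mapping; the mapping itself, fixed by the
dimensional values of $v_0$ and $D$, admits no free rescaling. The step
size was therefore *not* adjusted to chase the published numbers. What the
model does reproduce robustly: homolog specificity (matched non-homolog
controls are stationary while homolog distances collapse), capture
permanence, the placement statistics, and the short-range force kinetics
(doubling $C_r$ halves the non-homolog residence time in the
repulsion-dominated regime, with the crossing time matching a separable-ODE
quadrature).

Other simplifications: the nucleus is a 2-D disc (no 3-D volume, no
explicit telomere anchors — envelope attachment is implicit in the 2-D
confinement); pairing is an endpoint (no segregation, no unpairing); the
dumbbell variant collapses captured pairs to the composite point
representation; and boundary repulsion acts per bead.
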