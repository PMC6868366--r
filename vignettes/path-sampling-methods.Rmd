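---
title: "Path sampling methods for base-pair flipping kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Path sampling methods for base-pair flipping kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathsampler)
```

## The problem

A Watson–Crick (WC) A·T base pair can transiently adopt the Hoogsteen
(HG) motif, in which the adenine is flipped about its glycosidic bond and
hydrogen-bonds through its five-membered ring. The flip is fast but rare
(milliseconds between events, nanoseconds in duration), which puts direct
simulation of its kinetics out of reach and makes it a textbook target
for trajectory-space Monte Carlo: transition path sampling (TPS) to
harvest an ensemble of reactive trajectories, and transition interface
sampling (TIS) to turn crossing statistics into rate constants. This
package implements both engines, the geometric order parameters used to
follow the flip, the analysis that separates the two mechanistic channels
(the base rolling over *inside* the duplex versus flipping *outside* into
solvent), and the closing rate/free-energy arithmetic.

Because the all-atom DNA system itself is not desk-computable, the
engines are exercised on a two-dimensional Langevin surrogate with the
same qualitative structure, for which brute-force and quadrature oracles
exist. Everything above the dynamics layer (state definitions, shooting
moves, WHAM, channel classification, Bayesian comparison) is the same
code that would run on real trajectory data.

## Order parameters on coordinate frames

Frames are labeled atom sets (residue id, atom name, position in nm) plus
water-oxygen positions. The implemented observables:

* `hbond_distances()`: *d*~BP~ (A:N6–T:O4, present in both motifs),
  *d*~WC~ (A:N1–T:N3), *d*~HG~ (A:N7–T:N3). The precise atom assignment
  is an assumption exposed as a configurable `pair_map`, so an
  alternative bonding definition can be dropped in without touching the
  code.
* `lambda_from_distances()`: λ = arctan2(*d*~WC~, *d*~HG~), the TIS
  progress coordinate; 0.46 rad in WC (0.3 nm formed vs 0.6 nm open) and
  1.11 rad in HG. Scale-invariant, monotone in each argument, and
  undefined only when both distances vanish (an error).
* `glycosidic_chi()`: the standard signed dihedral O4′–C1′–N9–C4 (IUPAC
  convention, cis = 0, range (−180°, 180°]); collinear atom triples are a
  geometry error.
* `opening_theta()`: the angle at the flanking-phosphate center of mass
  between the rolling-base and neighboring-pair centers of mass. A pure
  two-arm angle is unsigned, so a sign convention is declared: the sign
  of (v~II→I~ × v~II→III~) · n~ref~, with n~ref~ defaulting to the
  rolling base's own plane normal. Because the reference rotates with the
  frame, the signed angle is invariant under rigid motions — a property
  the tests verify with random rotations. Negative values correspond to
  opening toward solvent.
* `rolling_phi()`: angle between the base-plane normal (from N3→N1 ×
  N3→N7) and the backbone P–P vector, signed by the direction from the
  duplex-core center of mass to the base center of mass. This tracks base
  orientation even when the base has left the duplex interior, where χ
  loses its discriminating power.
* `count_waters()`: water oxygens strictly within 0.6 nm of adenine N6 —
  the solvent-exposure proxy. The cutoff inequality is strict; a water at
  exactly the cutoff does not count.

Masses for centers of mass come from the element inferred from the first
letter of the atom name (H, C, N, O, P, S), overridable per call.

`build_fixture()` constructs synthetic frames realizing any consistent
set of targets: the thymine N3 is placed on the two-sphere intersection
around N1 and N7 (infeasible targets raise a construction error), the
sugar atoms are rotated about the glycosidic axis to the requested χ, the
backbone realizes ϕ against the base normal, pseudo-selections realize θ,
and waters are placed on a deterministic Fibonacci spiral. Round-trip
agreement is exact to numerical round-off; the tests assert 1e-6.

## The two-channel Langevin model

The synthetic-data generator is a particle on

$$V(x, y) = a\,(x^2-1)^2 + b\,y^4 + G\,e^{-(x^2+y^2)/2\sigma^2}$$

with underdamped Langevin dynamics. Defaults (all in reduced units):
`a = 2`, `b = 1`, `G = 3`, `sigma = 0.5`, `kBT = 1`, `gamma = 2.5`,
`dt = 0.01`, `mass = 1`, `save_interval = 5`. The minima near (±1, 0) are
the WC/HG analogues. The direct route over the origin (the *inside*
channel) faces a barrier of a + G = 5 k~B~T; the detour through finite
|y| (the *outside* channel) crosses a saddle of ≈ 3.23 k~B~T at
|y| ≈ 0.85, so the outside channel dominates kinetically — the same
qualitative asymmetry as in the DNA system. The constants were chosen
once so that transitions are observable in minutes of CPU (hundreds of
events per 10⁷ steps) while still being rare on the molecular timescale
(the integrator resolves each well oscillation with hundreds of steps);
they were not adjusted afterwards.

The mapping to DNA-like observables (`toy_order_map()`): `lambda_like`
is x; `opening_like` is −60·|y| degrees, echoing how the opening angle
goes negative as the base leaves the duplex (the outside saddle maps to
≈ −51°); `hydration_like` is round(8 + 15·|y|), spanning ~8 buried to
~25 exposed. The map uses |y| rather than signed y deliberately: the toy
outside channel is symmetric in ±y, and a per-path minimum of a signed
map would see only one lobe. A consequence worth knowing: θ-proxy and
hydration-proxy are exact functions of the same excursion max|y|, so the
per-path feature scatter is collinear, and the toy channel line
(`toy_channel_line()`: horizontal at 15 counts, margin 1) differs from
the DNA-scale line (0.185 counts/degree, intercept 32, margin 2), which
remains the classifier default.

The integrator is BAOAB: half kick, half drift, exact Ornstein–Uhlenbeck
velocity refresh, half drift, half kick. The OU sub-step is exact at any
`dt`, so the velocity marginal is exactly Maxwellian and the
configurational sampling error is the usual O(dt²); at γ → 0, k~B~T → 0
the scheme reduces to velocity Verlet, which the tests verify via energy
conservation. All randomness flows through R's RNG (`set.seed()`
reproduces runs bit for bit), and run-level functions accept and record a
`seed`.

One package-wide convention: frames are recorded every `save_interval`
steps and **state membership is checked on saved frames only**. This
makes brute-force counting, TPS, and TIS all measurements on the same
Markov chain of saved frames, so oracle comparisons are exact rather
than resolution-confounded. The cost is that sub-interval state touches
are invisible; at the default 0.05 time units between frames this is far
below the well correlation time.

What the toy model does *not* emulate: explicit solvent (hydration is a
deterministic function of position, with none of the fluctuating,
history-dependent character of real water counts), the ~180° internal
rotation (there is no angular coordinate; the channels differ only in
transverse excursion), sequence context, and any on-pathway metastable
intermediate along the progress coordinate (see the diagnostics section).
Passing tests therefore demonstrate the correctness of the sampling
machinery, not force-field realism.

## TPS engine

States are open interval windows on named order parameters
(`state_definition()`); the toy defaults are core sets
A = {x < −0.8, |y| < 0.35} and B = {x > 0.8, |y| < 0.35}. Tight windows
mirror how the WC/HG states are defined by their hydrogen-bonding
pattern; membership is strict, and a frame satisfying two states at once
is a configuration error, not a silent choice.

The initial path is produced by high-temperature harvesting
(`generate_initial_path()`): a run at 5× the target temperature until a
core-to-core transition appears, then repeated requenching — fresh
Maxwell velocities at the target temperature from a configuration near
the channel midpoint, shot forward and backward until both segments land
in states — until the two ends land in different states. This replaces
the enhanced-sampling step that produced the first reactive trajectory in
the DNA study and yields an unbiased (if atypical) member of the path
ensemble.

Shooting (`one_way_shot()`): uniform shooting frame among interior
frames, direction forward/backward with probability 1/2, fresh noise from
the shooting frame (backward shots negate velocities, integrate, then
reverse the segment — the standard one-way scheme for stochastic
dynamics). Acceptance (`accept_trial()`): reject unless the trial
connects the states with no interior state visit, otherwise accept with
min(1, L~old~/L~new~). Rejected trials re-count the current path, the
correct ensemble weighting. Trials exceeding `max_length_factor` (default
50) times the initial path length are rejected with an explicit
`max_length` reason. Both A→B and B→A paths are retained with direction
metadata; equilibrium dynamics is time-reversible, so both orientations
sample the same transition-path ensemble.

`decorrelated_count()` uses a declared operational definition: an
accepted path is decorrelated if it shares no frame (exact (x, y)
equality — shooting copies frames verbatim, so exact comparison is the
right notion) with the previous decorrelated path. `path_tree_edges()`
reconstructs the shooting genealogy from per-path provenance.

## TIS engine

Interfaces are an increasing λ ladder starting at the initial-state
boundary λ~0~ (toy default: nine values from −0.8 to +0.8, i.e. eight
interfaces past the boundary; the ladder and the reporting interface
λ~rep~ are fully user-overridable since optimal placement is
system-specific). Ensemble *i* contains paths that start in the initial
state, cross λ~i~, and end in either state; there is an ensemble at λ~0~
itself, which measures the first conditional crossing probability —
omitting it silently sets that factor to 1 and overestimates the rate, a
defect the brute-force oracle catches immediately. Each ensemble is
seeded from one full connecting path (a valid but atypically
far-reaching member) and sampled by the same one-way shooting move; the
first quarter of trials are discarded as burn-in.

Per path, the maximum λ is histogrammed on a shared grid (default
resolution 0.005, fine enough to resolve interface positions and the
0.46/0.5/1.0/1.11 landmark values). `wham_combine()` merges the
per-ensemble histograms by self-consistent maximum-likelihood iteration
(uniform initialization, relative tolerance 1e-10): each ensemble is the
unbiased max-λ distribution truncated at its interface, the merged
weights are w~b~ = M~b~ / Σ~i~ N~i~ 1(λ~b~ ≥ λ~i~)/Z~i~ with
Z~i~ = Σ~b≥i~ w~b~. The reverse cumulative of the converged weights is
p~tot~(λ | λ~0~): normalized to 1 at λ~0~, non-increasing by
construction, invariant to rescaling any single histogram, and an error
if adjacent ensembles share no λ support (a gap no reweighting can
bridge).

The flux Φ out of the initial state (`flux_from_state_run()`) counts
first crossings of λ~0~ along a long in-state run, at most once per
state re-entry (immediate recrossings do not count), divided by the time
attached to the state. The commitment probability p~commit~ is the
fraction of outermost-ensemble paths that, having reached λ~rep~, end in
the product state. The rate is k = Φ · p~tot~(λ~rep~) · p~commit~, and
ΔG = ln(k~backward~/k~forward~) in k~B~T. The reverse transition is
sampled on the mirrored coordinate (λ → −x) with the state roles
swapped; ΔG(A→B) = −ΔG(B→A) holds identically by construction.

Error bars are block standard errors (20 blocks) of the per-trial
conditional crossing indicators, which account for chain
autocorrelation; naive binomial errors on accepted-path counts
underestimate the run-to-run spread of the rate by a factor ~3, which we
verified against independent replicate runs. Poisson counting error on
the flux and a block error on the commitment fraction are combined in
quadrature.

## Channel analysis and switching statistics

`path_density()` implements visitation counting — each path increments a
bin at most once, so cells saturate at the path count and the map
highlights mechanistic channels rather than dwell time. Angular axes may
be declared periodic and are wrapped into (−180°, 180°] before binning.
`channel_features()` takes exact per-path extrema (θ~min~,
N~water,max~); `classify_channel()` applies the dividing line with its
margin, the margin band mapping to `"neither"`; the margin applies to
N~water,max~ only (above/below the line), matching how it is stated for
the DNA analysis. `propagate_labels()` resolves `"neither"` to the
previous accepted label, with the initial path's label seeding the chain.

`fit_relaxation_tau()` fits p~outside~(t) = 1 − e^(−t/τ) by nonlinear
least squares (start value from the linearized median; `scaleOffset`
keeps the convergence test meaningful on exact synthetic curves; a
constant curve is a degeneracy error, not a number). The growing form of
the exponent that appears in print is treated as a typographical slip —
it diverges — and the decaying form is implemented. The per-trial
switching probability is reported two ways (1/τ̂ and a direct
switch-per-labeled-trial count); with zero observed switches only a
rule-of-three upper bound (3/n) is reported, never a point estimate.

The Bayesian channel comparison is a Beta–binomial model: independent
uniform priors on the two switching probabilities, binomial likelihoods,
posterior P(X > Y) with X ~ Beta(s₁+1, n₁−s₁+1), Y ~ Beta(s₂+1, n₂−s₂+1),
computed by the exact finite sum for integer shapes (adaptive quadrature
otherwise, absolute error < 1e-7). This model is adopted because it
reproduces the reported posterior 0.99948 for seven-of-ten versus
zero-of-ten to all reported digits; the complement identity
P(X>Y) + P(Y>X) = 1 is exact.

## Diagnostics and their limits on the toy surface

`profile_density_colocation()` relates flat regions of log p~tot~(λ) to
high path-density mass at the same λ — the signature of on-pathway
lingering. The toy surface at its defaults has a single saddle along x
and no intermediate, so there is no lingering region and the correlation
carries no signal there (we measured ≈ 0 for both visitation and
dwell-time weighting); the diagnostic is validated instead on a
constructed profile/ensemble with a genuine plateau. This is a real,
documented limit of the surrogate, not of the diagnostic.

Similarly, because all toy runs harvest their initial paths from the
dominant outside channel with high probability, pipeline runs typically
have no inside-started group and the run-level posterior is reported as
missing rather than fabricated; the Bayesian operation itself is
exercised on explicit counts.

## Orchestration and reproducibility

`load_config()`/`validate_config()` give a schema-checked YAML
configuration with all defaults recorded; the single required field is
`seed`. `run_pipeline()` executes harvest → TPS chains → channel and
switching analysis → TIS in both directions → rates, with per-stage
seeds split deterministically as `seed + 1000·stage + run` and a
structured log of stage timings. Re-running a bundle's embedded config
reproduces its rates bit for bit (a test asserts this). Trajectories and
frames have versioned plain-text container formats
(`write_trajectory()`, `write_frame()`) carrying parameters and seeds as
metadata. The package is library-first: the exported functions, the
configuration file, and `scripts/acceptance.R` are the command surface.

## Problem sizes used in the validation suite

Chosen as the smallest sizes at which the oracle comparisons are
statistically meaningful: brute-force oracle 10⁷ steps (≈ 700
transitions); reactive-segment harvest 10⁷ steps (≈ 1800 segments); TPS
ensemble 1500 trials (≈ 700 accepted paths; total-variation tolerance
0.15 against the brute-force density); TIS 2500 recorded trials per
ensemble per direction (rates compared at 3 combined standard errors; ΔG
within 0.3 k~B~T of quadrature); Boltzmann check 4×10⁶ steps subsampled
every 100 time units; Monte Carlo check of the Beta posterior 10⁷ draws.

## Known limitations

* The rate error model treats the per-interface factors as independent;
  ensembles seeded from the same initial path are weakly correlated, so
  the combined error is approximate (block errors per ensemble are not).
* One-way shooting with uniform interior selection and the
  min(1, L~old~/L~new~) factor is the conventional pairing; for very
  short paths (L ≲ 10 frames) the interior/total frame-count distinction
  makes the weighting slightly approximate.
* `decorrelated_count()` and the channel-switching analysis assume the
  trial stream is dense enough that label changes are observed; sparse
  acceptance inflates τ estimates.
* The fixture builder produces geometrically exact but chemically
  idealized frames (planar base, pseudo-selections for θ); it validates
  the order-parameter code, not molecular plausibility.
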