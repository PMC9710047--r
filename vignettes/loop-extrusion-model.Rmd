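---
title: "Simulating DNA loop extrusion with extrusim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating DNA loop extrusion with extrusim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(extrusim)
```

## The model

Cohesin and related SMC complexes organize interphase chromatin by *loop
extrusion*: a loop-extrusion factor (LEF) binds DNA, reels it in from both
sides through a pair of extrusion units, and eventually releases. Extrusion
is stalled at CTCF-bound sites in an orientation-dependent way, which is why
convergent CTCF pairs delimit TADs, produce corner "dots" and one-sided
"stripes" in Hi-C and Micro-C maps. `extrusim` samples the DNA-DNA contacts
this process generates on a one-dimensional lattice at base-pair resolution,
genome-wide, without any polymer mechanics.

The simulation state for one *cell* (an independent instance) on one
chromosome consists of:

* a set of LEFs, each a pair of extrusion units — a reverse unit moving
  3'→5' and a forward unit moving 5'→3'. The interval between them is the
  current loop; a freshly bound LEF has loop size 0.
* a set of extrusion barriers, each with a position, a blocking direction
  and a two-state (Bound/Unbound) Markov chain. A barrier derived from a
  `+`-strand CTCF motif blocks reverse-moving units; a `-` barrier blocks
  forward-moving units. A convergent `+`/`-` pair therefore stalls loop
  growth on both sides, which is what builds a dot.

The barrier chain is parameterized by the self-transition probabilities
$P_{UU}$ and $P_{BB}$. Its stationary Bound probability — the *occupancy* —
is

$$\pi_B = \frac{1 - P_{UU}}{(1 - P_{UU}) + (1 - P_{BB})},$$

so the user-facing pair $(\pi_B, P_{UU})$ fixes
$P_{BB} = 1 - (1 - P_{UU})(1 - \pi_B)/\pi_B$. Pairs with
$\pi_B < (1-P_{UU})/(2-P_{UU})$ have no valid $P_{BB}$ and are rejected (the
genetic optimizer instead clamps $P_{BB}$ to 0, because its random genotypes
roam the whole unit square). $\pi_B = 0$ pins a barrier Unbound forever,
which is also how in-silico barrier deletions are implemented.

Each epoch executes, in order: (1) activation of inactive LEFs at uniformly
drawn positions (LEFs released in epoch $t$ rebind in $t+1$); (2) indexing
of the units in genomic order; (3) contact sampling from a random subset of
active LEFs; (4) candidate-move generation; (5) one Markov step for every
barrier; (6–7) collision detection and move adjustment; (8) advancing the
units; (9) stochastic release. A LEF is released with per-epoch probability
$p = 2\,\bar{s}/\rho$, where $\bar{s}$ is the mean stride and $\rho$ the
processivity (mean DNA extruded over a lifetime), so lifetimes are geometric
with mean $\rho / (2 \bar{s})$ epochs. A LEF whose two units are both
stalled at a convergent Bound pair is released with $p$ divided by the
hard-stall multiplier, which is what lets dots accumulate.

### Collision semantics

Candidate moves are resolved against three constraints simultaneously: a
unit stops 1 bp before a Bound barrier that blocks its direction; units of
different LEFs never pass one another — two approaching units split the
remaining gap (an odd gap leaves the extra base pair to the unit ranked
first in genomic order) and a unit that runs into an already-stalled unit
stalls behind it; and chromosome ends clip moves at 0 and length − 1 without
marking a stall. The resolver applies these as a monotone relaxation over
the genomically sorted units (forward units' targets only decrease, reverse
units' only increase), which converges and preserves unit order by
construction. The test suite pins these semantics to an independent 1-bp
micro-stepping simulator on random systems of up to 10 LEFs and 100 kbp:
both implementations must produce identical positions *and* stall labels.
Co-located units (possible right after binding) are ordered reverse-first so
that an opposite-direction pair occupying one base pair diverges instead of
colliding; this corner case is conservative and unobservable at bin
resolution.

### Contacts and the banded matrix

Each epoch a fraction (default 0.025) of active LEFs is sampled. A sampled
LEF registers one *loop* contact at its anchor pair (rev, fwd) and, with the
TAD-to-loop ratio (default 1.0), *intra-TAD* contacts at positions drawn
uniformly inside the loop; `--contacts loop-only` / `tad-only` select either
channel. Contacts land in a banded symmetric matrix that stores only pixels
within `diagonal_width` of the main diagonal (half-open: a pair exactly at
the band edge is discarded and tallied). Storage is a dense
`band_rows x nbins` slab, so memory grows linearly in chromosome length.
Matrices are written as single-resolution cooler (HDF5) files with the
standard chroms/bins/pixels/indexes layout.

### Burn-in and stopping

Contact sampling is disabled during a burn-in phase in which LEFs are bound
progressively (a fraction $1/\lceil\text{lifetime}\rceil$ per epoch) and the
windowed mean loop size must stabilize: burn-in ends when the mean over the
last `burn_in_window` epochs (default 16) changes by less than
`burn_in_tolerance` (default 2%) relative to the preceding window, or at a
hard cap of 5000 epochs. The 16/0.02 pair was chosen so that, at the default
release rate (lifetime 20 epochs), burn-in spans a few LEF lifetimes; both
are configurable. The contact phase then runs until the target mean density
(default 1 contact per band pixel, split evenly across cells) or a target
epoch count is reached.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `bin_size` | 5000 | bp | Micro-C-scale resolution |
| `diagonal_width` | 3e6 | bp | TAD-scale interactions live within ~3 Mbp |
| `lef_density` | 20 | LEFs/Mbp | ~62k LEFs on a 3.1 Gbp genome |
| `processivity` | 200e3 | bp | typical cohesin processivity |
| `mean_stride` | `bin_size` | bp/unit/epoch | one bin per epoch keeps speed interpretable |
| `stride_sd_fraction` | 0.05 | – | mild stride noise; 0 gives deterministic strides |
| `contact_sampling_fraction` | 0.025 | – | decorrelates epochs from contacts |
| `tad_to_loop_ratio` | 1.0 | – | equal loop and intra-TAD channels |
| `hard_stall_multiplier` | 5 | – | direction (longer-lived hard stalls) is modeled; magnitude is a knob |
| `ncells` | 512 | – | >500 instances per chromosome |
| `target_contact_density` | 1 | contacts/pixel | default stopping criterion |

The stride law (truncated normal, rounded to bp) and the progressive-binding
schedule are deliberate, documented choices where the procedure is known
only qualitatively; both live behind configuration values rather than code
forks.

## The comparison toolkit

Matrices are compared on their *band image* (row $k$ = the $k$-th
off-diagonal; corner cells beyond the chromosome are `NA` and excluded).
`dog_transform()` applies a difference of Gaussians ($\sigma_1 = 1.0$,
$\sigma_2 = 1.6$ pixels, separable convolution with reflect padding),
`discretize()` maps values $\ge$ threshold to 1 (ties up, matching "below
the threshold to 0, all others to 1"). For every bin, the vector of pixels
leaving the diagonal along its row (and, separately, its column) is reduced
to the *stripe end* — the last non-zero pixel. `score_matrices()` counts
per-bin agreement of stripe ends between reference and target; two empty
vectors agree (penalizing correctly-empty regions would be perverse).
`pixel_accuracy()` reports the correctly-classified fraction over the union
of subdiagonal windows (default 3 Mbp) around barriers, de-duplicating
pixels shared by nearby barriers. `diagonal_correlation()` gives a Pearson
correlation per off-diagonal distance, `NA` on constant diagonals. When scoring a simulation against an experimental map, the defaults
discretize the experimental side at 1.5 and the simulated side at 0.75; both thresholds are arguments, and self-referential synthetic
comparisons use the simulated-scale threshold on both sides.

## Parameter fitting

`optimize_gw()` fits one uniform $(\pi_B, P_{UU})$ pair: each proposal runs
a genome-wide simulation, transforms and discretizes it, scores stripe-end
dissimilarity against the transformed reference, intersects horizontal
stripes with row scores and vertical stripes with column scores, and
averages; stripes are split once into disjoint training/validation halves
and only the training mean drives the minimizer. The minimizer is a compact
Gaussian-process expected-improvement loop (squared-exponential kernel,
per-dimension length scales and a noise term fitted by marginal likelihood,
latin-hypercube initial design, candidate-set EI maximization) — any
sequential model-based box minimizer satisfies the contract. Infeasible
pairs score the maximal dissimilarity 1.

`run_ga()` fits per-barrier parameters with a $(\mu, \lambda)$ evolution
strategy: individuals are two length-$N$ vectors ($\pi_B$ and $P_{UU}$),
offspring arise by two-point crossover on the concatenated genotype and
clamped Gaussian mutation, and the top $\mu$ of $\lambda$ offspring replace
the population entirely. Because the stripe score is blind to weak barriers
(no stripe either way), each barrier's score $f$ is multiplied by a penalty
$p(\pi_B) = \min\!\big(2,\; 1 + e^{-(\pi_B - 0.5)^2 / (2\cdot 0.12^2)}
+ 0.5\,e^{-(\pi_B - 1)^2 / (2\cdot 0.02^2)}\big)$ — near 2 at
mid-occupancy, falling fast toward 0 and 1, with a secondary bump
penalizing $\pi_B \approx 1$; the exact functional form is this package's
choice satisfying those stated properties, and it is configurable. $f$ is
the mean stripe-end mismatch over the rows and columns within ±10 bins of
the barrier (a window makes a single barrier's fitness graded rather than
0/½/1). Stopping: a generation cap, <1% best-fitness improvement over 25
generations, or population variability (mean per-gene SD) below 1e−3 — the
operationalization of "variability approaches 0". The island phase masks a
random stretch of $k \sim \mathrm{round}(N(25, 5))$ consecutive barriers
per island (inactive and frozen), except one island that instead replaces
weak alleles ($\pi_B < 0.5$) by $(\pi_B = 0, P_{UU} = 1)$ with all loci
mutable; islands run at $\mu = 128, \lambda = 256$ and reseed half the
mainland by fitness-proportionate sampling. The default island count is 3
(masking is only useful with at least two islands plus the weak-barrier
island); it is a free choice, not a reported value.

## What the synthetic data does and does not emulate

`toy_spec()` lays out evenly spaced convergent barrier pairs (a `+` barrier
at 25% and a `-` barrier at 75% of each segment), which yields TADs,
stripes anchored at the barriers, and corner dots — the features the
comparison toolkit measures. It does **not** emulate random polymer
contacts, compartments, distance-dependent background decay, barrier
clustering, or ChIP-seq noise; passing tests demonstrate the machinery's
correctness and sensitivity on extrusion-only signal, not performance on
experimental maps.

Recovery experiments are *self-referential*: the reference matrix is
produced by the simulator itself at known parameters, and candidate
simulations reuse the same master seed (common random numbers). Under
common random numbers the stripe-dissimilarity objective is exactly 0 at
the generating parameters and rises smoothly around them, giving a clean
basin that a 40-call optimization can localize. With independent seeds the
exact-bin stripe-end match is dominated by sampling noise at these problem
sizes — an instructive reminder that the metric rewards reproducible stripe
geometry, which desk-scale contact counts cannot pin to single bins.

Problem sizes in the test suite were chosen to exercise every code path at
desk scale: the default-configuration run uses a 5 Mbp chromosome with 4
convergent pairs and all defaults (512 cells); the Bayesian recovery uses a
2 Mbp genome, 8 cells, density 2 and 40 objective calls (truth
$\pi_B = 0.8$, recovered within ±0.1); the evolutionary recovery uses one
barrier on 0.8 Mbp with $\mu = 8, \lambda = 16$, 30 generations (truth 0.9,
tolerance ±0.15). Dot-formation tests lower the LEF density to 4/Mbp and
raise processivity to 1–2 Mbp: at the default 20 LEFs/Mbp, LEF-LEF
collisions cap loops near the mean spacing (~50 kbp), and a 500 kbp
barrier-pair dot cannot form — the in-silico analogue of why dot strength
responds to cohesin density and WAPL activity.

## Numerical and degenerate-input choices

* Coordinates are 0-based, half-open everywhere; the barrier position is
  the interval midpoint rounded down.
* Strides are drawn per unit, truncated at 0 and rounded to integer bp;
  `stride_sd_fraction = 0` makes every stride exactly the mean.
* The band edge is half-open; increments outside the band are counted, not
  silently dropped, so `total + discards` always equals the attempted
  increments.
* Per-task seeds are a pure hash of (master seed, chromosome name, cell
  index), all below $2^{31}$; results are identical for any execution order
  of the tasks, which is the whole parallelism contract. Execution is
  serial; a thread pool would change wall time only.
* Release probabilities above 1 (stride > processivity/2) are clamped with
  a warning.
* `P_{UU} = P_{BB} = 1` has no stationary distribution and is an error;
  $\pi_B \in \{0, 1\}$ take their limit values.
* The GP minimizer standardizes responses, adds a 1e−8 jitter, and falls
  back to a random proposal if the Cholesky fails.

## Known limitations

* Intra-chromosomal contacts only; no polymer background, so long-range
  (>2–3 Mbp) decay is not reproduced — consistent with extrusion-only
  modeling.
* Matrix balancing, multi-resolution (zoomified) coolers, and stripe
  *calling* are out of scope; a stripe annotation is consumed, not
  produced.
* The logistic ChIP-seq-to-occupancy mapping defaults (midpoint 1.0
  fold-change, steepness 2.0, maximum 0.9) are calibration knobs, not
  measured constants.
* Unbound barriers are fully transparent; no partial ("soft") stalls in the
  non-blocking orientation.
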