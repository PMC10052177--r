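---
title: "Order and complexity of monomer/oligomer mixtures: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Order and complexity of monomer/oligomer mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqentropy)
```

## The model

`seqentropy` scores a mixture of free monomers and oligomer chains — the kind
of population an RNA-world evolution scenario passes through — on two
coordinates: **order**, the reciprocal of a sequential entropy, and
**complexity**, a minimal-description-length estimate in bits.  Both are
defined through a thought experiment: a walk that starts at an arbitrary unit,
always moves to the nearest not-yet-visited unit, and stops after visiting all
`N` units.  Repeated over starting points and molecular rearrangements, the
ensemble of walk *sequences* (each walk read as a string over the monomer
alphabet) is a structural cross-section of the mixture.  The variety `w` of
that ensemble defines the sequential entropy `S_r = k ln w`; the size of the
smallest program reproducing the ensemble's statistics defines the
complexity.

### Sequential entropy

For the mean-field description — alphabet size `n`, composition `r_i`, mean
chain length `L` (in units), mean monomer spacing `M` between chain contacts,
chain-site accessibilities `a_j`, positional predictabilities `p_k`, total
units `N` — the entropy decomposes into three non-negative contributions per
chain encounter, with `W = N/(M + L/2)` encounters per walk:

$$ S_r/k \;=\; W\Big[\, M\sum_i r_i\ln\tfrac1{r_i}
   \;+\; \sum_j a_j\ln\tfrac1{a_j}
   \;+\; \tfrac{L}{2}\sum_k p_k\ln\tfrac1{p_k} \Big]. $$

The first term is the mixing entropy of the monomers met along the walk, the
second the variety of chain contact points, the third the unpredictability of
chain sequences (half a chain is traversed per encounter, hence the factor
`L/2`).  The grouping of `W` as a common prefactor is a deliberate reading of
the model: it is the unique grouping that reproduces all four limiting closed
forms exactly —

| limit | parameters | `S_r/k` |
|---|---|---|
| pure monomer | `L = 1, p = 1` | `N ln n` |
| crystals | `n = 1` blocks, `M = 0` | `(2N/L) ln L` |
| random chains | `M = 0, p = 1` | `(2N/L) ln L + N ln n` |
| defined chains | `M = 0, p = 0` | `(2N/L) ln L` |

— and these identities are asserted to `1e-12` relative in the test suite.
The gap between the random and defined populations, `ΔS_r = kN ln n`, is the
thermodynamic driving force towards sequence loss ("living/dead gap").

Three layers are provided: `entropy_general()` (explicit `r`, `a`, `pk`
profiles), `entropy_two_level()` (a fraction `p` of chains fully random, the
rest sharing one defined sequence), and `entropy_uniform()` (additionally
uniform `r` and `a`).  The two-level sequence term `p (L/2) W ln n` is the
population mixture of the fully random profile (entropy `ln n` per position)
and the fully defined profile (entropy 0); an *intermediate* single `pk`
profile is not in general equivalent to a two-level population, so the
reduction chain is exact only at `p = 0` and `p = 1`, which is how the tests
assert it.

### Complexity

Two concrete encodings of the chain census bound the minimal description:

* strategy (a), permutation census: enumerate all `n^L` possible sequences
  and store a per-sequence chain count, `c1 ≈ L log2 n + n^L log2(pN/(L+M))`;
* strategy (b), explicit listing: spell out each random chain,
  `c2 ≈ L log2 n + L (pN/(L+M)) log2 n`.

The reported complexity is `min(c1, c2)` with a strategy label.  Short chains
favour (a); at mole scale `c1` wins everywhere on the default grids (a tested
invariant); tiny systems with long chains flip to (b).

### Numerical choices

* **Units.**  All entropies are computed dimensionless (units of `k`) and
  converted once at the end with `k = 1.380649e-23` J/K, avoiding `1e-23`
  underflow artifacts.  `moles_to_units()` applies the exact Avogadro
  constant; when `N` is one mole the J/K figure reads as J/(K·mol).
* **Continuous `L`.**  Fractional mean chain lengths are meaningful
  (population averages); every formula is evaluated as a continuous function
  of `L`, including `ln L` for the uniform contact term and `n^L` in the
  census.  An explicit accessibility profile, when given, uses
  `ceiling(L)` slots; its sum equals `ln L` exactly only at integer `L`.
* **`0 ln(1/0) = 0`** by continuous extension, so fully defined
  predictability profiles `c(1, 0, ...)` are legal.
* **Clamping.**  A census with at most one random chain
  (`pN/(L+M) <= 1` or `p = 0`) is freely compressible: its `log2` cost is
  clamped to 0 rather than allowed to go negative/`-Inf`, so `c1` and `c2`
  degrade gracefully to the defined-chain cost `L log2 n`.
* **Overflow.**  `n^L` exceeds double precision near `L ≈ 500` for `n = 4`.
  Every estimate therefore carries its decimal log computed in the log
  domain; strategy comparison uses the logs, and the linear-scale slots are
  allowed to be `Inf`.  Where both paths are representable they agree to
  `1e-12` relative (tested).
* **Ties** between `c1` and `c2` resolve deterministically to strategy (a).

## Parameter sweeps

`sweep_random_fraction()`, `sweep_chain_length()` and
`sweep_monomer_spacing()` tabulate order/complexity trajectories on the
documented default grids (`p` from 1.00 to 0.05 in steps of 0.05; `L` from 1
to 10.5 in steps of 0.5 at `p = 0.5`; `M` from 20 to 0 in steps of 1), all at
`n = 4` and one mole of units, preserving sweep direction in the row order.
Tested qualitative shapes: order rises and complexity falls as `p` decreases
(selection alone trades complexity for order); complexity climbs six decades
as `L` grows while order dips through a shallow interior minimum (near
`L ≈ 3` under these parameters) before recovering; order and complexity rise
together as `M` falls — the near-diagonal trajectory of productive
polymerisation.  The sweeps assert monotonicity and span, not per-point curve
values, because the source diagrams print no numeric axes.

## The evolution simulator

`run_evolution()` implements a deliberately minimal mutation/selection
scheme: selection decreases the random fraction at a constant rate
(`dp/dt = -0.01` per time unit by default), and every 5 time units a mutation
event instantaneously (i) returns a fraction `f` of the defined chains to the
random pool, `p <- p + f(1 - p)`, and (ii) adds one unit to the defined
sequence.  Defaults run 50 time units, so ten cycles; `p` under the composed
cycle map is affine, `p -> (1-f)(p + 5·rate) + f`, and converges
geometrically to the fixed point `p* = (f + 5·rate(1-f))/f` (for `f = 0.3`,
`p* = 0.265/0.3 ≈ 0.883`), which the tests verify against the closed-form
iterate.

Where the scheme under-determines the bookkeeping, the package makes these
choices (isolated in one mapping function so alternatives can be swapped):

* defined chains are `length_ratio = 2` times as long as random chains, and
  random-chain length tracks the growing defined length through that fixed
  ratio;
* the walk-facing mean chain length is the number-weighted
  `L̄ = p·L_rand + (1-p)·L_def`; order is `entropy_uniform()` at `(L̄, p)`;
* complexity uses the two-length form: the defined term costs
  `L_def log2 n`, the census exponent uses `L_rand`, the census count uses
  `pN/(L̄ + M)`;
* mutation converts defined chains to random chains rather than to monomers
  (`M` stays constant — monomer dynamics are not part of the scheme);
* initial conditions default to the sweep base point (`p0 = 1`,
  `L_def0 = 20`, `M = 10`, `n = 4`, one mole), since the scheme itself states
  none;
* within a cycle selection integrates first, then the shock fires; both the
  pre-event (`cycle_end`) and post-event (`mutation`) states are recorded,
  and the final state of a run always closes a cycle.

Because absolute trends depend on these conventions, the tested assertions
are the convention-robust ones: the zigzag (order drops and complexity jumps
at every event; the reverse within every selection span), net growth of both
coordinates at 30% loss, gentler mutation beating harsher mutation on final
order, and stronger selection lifting every matched cycle-end order.  The
simulator draws no random numbers; trajectories are bit-identical across
runs.

## The microstate oracle

`build_toy_system()` places explicit chains and monomers on a 1-D integer
line (a deliberate geometry choice: the stepping rules need *some* geometry,
and 1-D keeps walks hand-checkable); `sample_walk()` is the deterministic
nearest-unvisited walk with ties broken to the lower site index;
`walk_ensemble_log_weight()` enumerates walks over all starts and a supplied
set of arrangements and returns `ln D`, the log count of distinct walk
strings.  Ensemble repetition over time is realised by enumerating
arrangements (different seeds), not by simulating dynamics — the ensemble,
not the trajectory, is what the entropy summarises.

`ln D` is our operational proxy for `ln w`; the closed forms never define `w`
operationally, so `ln D` is asserted **ordinally only**: crystals and defined
chains below pure monomer below random chains, at matched size.  The fixture
uses a two-letter alphabet at `N = 8`: there the monomer string space (70
multiset orderings) saturates under enumeration, so the ordering reflects
genuine ensemble variety; at larger alphabets the spaces are so far from
saturation that distinct-string counts merely track the number of sampled
walks and the comparison is uninformative.  Exact equality between the
crystal and defined cases holds for the closed forms but not for the toy
proxy (mid-chain starts produce sequence variants in defined chains, never in
single-type crystals), which is why only the ordering is asserted.

`multinomial_mixing_entropy()` is the exact `ln(N!/∏N_i!)` via log-gamma,
converging to the Stirling mixing term within 1% by `N = 1e4`;
`explicit_encoding_length()` realises both encoding strategies concretely on
enumerable censuses and must land within a factor 2 of `min(c1, c2)` — the
honesty bound for approximations stated with `≈`.

## What a green test does and does not establish

The synthetic world here *is* the mean-field model: closed forms evaluated at
stated parameter points, a deterministic simulator, and enumeration-scale toy
systems.  Green tests establish internal consistency (limiting cases,
reduction identities, monotonicities, fixed points) and agreement with
independent brute-force computation at tiny `N`.  They do not establish that
real prebiotic mixtures follow these trajectories: the model has no
chemistry — no base-pairing energetics, no hydrolysis, no length
distributions (a single mean `L` stands for the whole population), no
spatial structure beyond the walk abstraction, and mutation/selection rates
are stylised constants.

## Known limitations

* The order range quoted for the model calculations (0.1–0.3 K/J) is not
  reproduced as a test: under the documented sweep parameters the computed
  order spans a different interval (0.078–0.137 K/J across the three default
  sweeps), and the quoted range appears to fold in evolution runs
  whose parameterisation is not fully stated.  The package asserts shapes
  and spans, not that sentence.
* The factor `L/2` (half a chain traversed per encounter) is implemented as
  stated; its derivation is not part of the model description.
* Whether `p` is a number fraction or mass fraction of chains is ambiguous
  in the source scheme; it is treated as a number fraction throughout.
* 60% vs 50% mid-range mutation loss: both are accepted via
  `loss_fraction`; neither is privileged.
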