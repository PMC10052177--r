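# seqentropy

Order and complexity metrics for prebiotic, RNA-world style mixtures of free
nucleotide monomers and oligomer chains.

## The problem

A primordial soup at some stage of molecular evolution contains monomers next
to oligomers with partly random, partly shared ("defined") sequences.  Judging
how far evolution has progressed needs two system-level coordinates:

* **Order** — the reciprocal of a *sequential entropy* `S_r = k ln w`, where
  `w` is the variety of an ensemble of nearest-neighbour walks threading every
  unit of the system.  For a mean-field state with `n` monomer types of
  composition `r_i`, mean chain length `L`, mean monomer spacing `M` between
  chain contacts, chain-site accessibilities `a_j`, sequence predictabilities
  `p_k` and `N` total units,

  ```
  S_r / k = W [ M Σ_i r_i ln(1/r_i) + Σ_j a_j ln(1/a_j)
              + (L/2) Σ_k p_k ln(1/p_k) ],      W = N / (M + L/2).
  ```

  With a fraction `p` of fully random chains (the rest sharing one defined
  sequence), uniform composition and accessibility, this collapses to

  ```
  S_r / k = W [ M ln n + ln L + p (L/2) ln n ].
  ```

* **Complexity** — the size in bits of the smallest algorithm reproducing the
  walk-ensemble statistics (a Kolmogorov-style minimal description length),
  approximated by the smaller of a permutation-census encoding
  `c1 ≈ L log2 n + n^L log2(pN/(L+M))` and an explicit sequence list
  `c2 ≈ L log2 n + L (pN/(L+M)) log2 n`.

The package computes both coordinates from mean-field parameters, sweeps them
across `p`, `L` and `M` to produce order-versus-complexity trajectories, and
runs a deterministic periodic mutation/selection simulation in which a
constant selection rate `dp/dt` is punctuated by mutation events that lengthen
the defined sequence while returning a fraction of defined chains to the
random pool.  A brute-force microstate oracle (explicit toy arrangements on a
line, exhaustive walk enumeration, exact multinomial entropies, concrete bit
encodings) validates every closed form at enumeration scale.

## Worked example

```r
library(seqentropy)

# one mole of four monomer types, monomers only (L = 1, p = 1)
entropy_uniform(n = 4, N = moles_to_units(1), L = 1, M = 0, p = 1)
#> Sequential entropy of the walk ensemble
#>   mixing term   : 0 k
#>   contact term  : 0 k
#>   sequence term : 8.34846e+23 k
#>   S_r = 8.34846e+23 k = 11.5263 J/K   (order 1/S_r = 0.0867582 K/J)
```

`S_r = 11.5263 J/(K·mol)` is exactly the mixing entropy `R ln 4` of the four
monomer species — the low-order, low-complexity starting point.  A mixed
chain population at the sweep base point:

```r
system_complexity(n = 4, L = 20, p = 0.5, N = moles_to_units(1), M = 10)
#> Description-length complexity estimate
#>   c1 (permutation census) : 8.03608e+13 bit
#>   c2 (explicit sequences) : 4.01476e+23 bit
#>   c  = min = 8.03608e+13 bit  (strategy a, log10 c = 13.905)
```

At mole scale the permutation census (strategy a, ~81 Tbit) always beats
listing every sequence.  An evolution run with 30% sequence loss per
mutation event gains both order and complexity:

```r
traj <- run_evolution(evolution_config(loss_fraction = 0.3))
traj[traj$t %in% c(0, 50), c("t", "phase", "p", "L_def", "order_KJ", "log10_c")]
#>     t     phase      p L_def order_KJ log10_c
#> 1   0 selection 1.0000    20   0.0781  7.8938
#> 60 50 cycle_end 0.8380    29   0.0837 10.5991
#> 61 50  mutation 0.8866    30   0.0819 10.9006
```

## Command line

```sh
Rscript inst/cli/seqentropy.R entropy --n 4 --N-mol 1 --L 1 --M 0 --p 1
Rscript inst/cli/seqentropy.R sweep L --out sweep.csv
Rscript inst/cli/seqentropy.R evolve --loss 0.3 --out traj.csv
Rscript inst/cli/seqentropy.R validate --seed 7
```

Subcommands: `entropy`, `complexity`, `sweep {p|L|M}`, `evolve`, `validate`.
Flags mirror the config-file keys (`--config file.yaml`, flags win); every
run echoes its effective configuration to stderr.

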