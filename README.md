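# stereopref

Weak stereochemical binding preferences between amino acids and RNA
nucleotides — and whether they line up with the genetic code.

A long-standing hypothesis holds that the codon table reflects direct
biophysical affinities between amino acids and their cognate bases: not
all-or-none recognition, but a large number of slight preferences.
Testing this requires measuring many weak interactions and asking
whether, across the whole code, amino acids bind their cognate codonic
or anticodonic bases more often than chance allows. `stereopref`
implements that analysis as a reusable, fully testable pipeline for
structural bioinformaticians working with simulation trajectories and
NMR titrations.

## What it computes

**Binding occupancy.** A trajectory of one nucleotide with several
amino-acid copies in a periodic box is reduced to the per-frame
closest-approach distance (minimum-image convention, orthorhombic box).
Binding is the fraction of frames with distance < 5 Å, pooled across
parallel runs, with a bootstrap 95% interval obtained by resampling
runs as independent experiments.

**Volume normalisation.** Larger molecules sit within any threshold of
each other more often purely by size. The fraction of the box within
5 Å of each molecule is estimated by Monte Carlo (uniform random
points, repeated over frames to capture flexibility), and the occupancy
is divided by a volume divisor (product of the two volume fractions by
default) so systems are comparable.

**Genetic-code preference statistics.** Adjusted occupancies are ranked
within each amino acid (rank 1 = strongest). Cognate assignments are
derived from the standard code — one allocation per amino acid plus one
extra for each hexacodonic amino acid (Arg, Ser, Leu), giving 23 — and
compared to the ranks via exact binomial tests
(P(X ≥ k) with p = 1/4 for cognate-first enrichment, lower tail for
cognate-last depletion, p = 3/4 for best-with-any-cognate) and a
sum-of-ranks score S = Σ rank(cognate) whose null distribution comes
from 200,000 uniform randomised assignments. Dinucleotide schemes and a
directionality contrast (XY vs YX) are supported.

**Hydrophobicity regression.** A composite hydrophobicity rank (mean
within-scale rank across scales, 1 = most hydrophobic) and OLS
regression of binding on hydrophobicity and molecular volumes.

**NMR titration fitting.** Chemical-shift-perturbation curves are fit
to the one-site fast-exchange isotherm

Δδ = Δδ_max · [(K_D + L + P) − √((K_D + L + P)² − 4PL)] / (2P)

by bounded nonlinear least squares in a 500-fit leave-one-out ensemble
(random K_D starts, one point dropped per fit); partners are compared
by bootstrap ranking of sampled K_D values (lower K_D = stronger
binding).

Every stage is exercised end-to-end on synthetic data with known ground
truth: a two-state Markov-chain distance generator with planted
occupancy, a random-walk periodic-box trajectory generator, and an
exact-isotherm titration generator.

## Worked example

Plant strong cognate anticodon-middle-base preferences for 10 of the 20
amino acids and run the full pipeline:

```r
library(stereopref)

planted <- sort(unique(standard_code_table()$amino_acid))[1:10]
report <- run_pipeline(list(seed = 42, planted = planted,
                            n_runs = 20, n_frames = 500,
                            n_randomizations = 200000))
report
#> stereopref pipeline report (version 0.1.0)
#>   cognate-first: 14/20 amino acids (enrichment p = 2.951e-05)
#>   cognate-last:  3/23 allocations (depletion p = 0.137)
#>   best with any cognate: 19/20 (p = 0.02431)
#>   sum-of-ranks 39.0 (null mean 57.5; beats 100.0% of draws)
```

The 10 planted amino acids (plus a few lucky unplanted ones) rank their
cognate anticodon middle base first — 14 of 20, far beyond the 5
expected by chance (enrichment p = 3×10⁻⁵) — and the sum-of-ranks score
of 39 sits below essentially every randomised assignment (null mean
57.5 over 23 allocations).

Individual stages are available directly:

```r
binomial_preference_test(10, 20, 0.25, "upper")
#> [1] 0.01386442

middle_base_usage()       # U is the anticodon middle base for 7 of 20
#> A C G U
#> 5 5 4 7

tc <- gen_titration(KD = 2, dmax = 0.1, noise_sd = 0.002, seed = 7)
fit_ensemble(tc, seed = 8)
#> K_D = 2.16 mM [95% range 2.13-2.2] from 500 fits (0 failed)
```

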