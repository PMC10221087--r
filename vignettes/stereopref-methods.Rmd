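---
title: "Models and methods behind stereopref"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stereopref}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stereopref)
```

`stereopref` quantifies weak binding preferences between the 20
proteinogenic amino acids and RNA nucleotides, and asks whether those
preferences align with cognate codon/anticodon assignments in the
genetic code. This vignette documents the models, the tunable
parameters and their defaults, the synthetic-data generators used for
validation, and the numerical and design choices that were genuinely
open.

## The binding statistic

The primitive observable is the per-frame *closest-approach distance*:
the minimum over amino-acid copies of the minimum-image Euclidean
distance between any (selected) atom of the nucleotide and any atom of
the copy, in an orthorhombic periodic box (triclinic cells are out of
scope). Binding occupancy is the fraction of frames with distance
strictly below a threshold, 5 Å by default — a single cutoff wide
enough to cover the distinct binding modes observed near 1.9, 2.5 and
4 Å while excluding the free-in-solution regime, where the closest
unbound amino acid sits around 5.5 Å away. The comparison is strict
(`< 5`) rather than `<=`; the boundary has measure zero for continuous
distances, but the choice is fixed and documented for bit
reproducibility.

Parallel runs are pooled by frames (a run with more frames contributes
more), so the point estimate is the frame-weighted mean of per-run
fractions. Uncertainty comes from a percentile bootstrap that
resamples *runs* with replacement (100,000 resamples by default):
between-run variability is the relevant error scale because frames
within a run are strongly autocorrelated. A single run is rejected
rather than silently producing a zero-width interval.

## Volume normalisation

Under a purely geometric null (no interaction), expected occupancy
grows with molecular size. The size proxy is the *volume fraction*:
the fraction of the box within the threshold of any atom of the
molecule, estimated by Monte Carlo with 100,000 uniform points
(default) repeated over 150 sampled frames to capture flexibility.
One point cloud is shared across frames, so the reported 95% range
over frames reflects conformational flexibility rather than
point-sampling noise; a rigid molecule therefore has an exactly
zero-width range. The Monte Carlo standard error of the mean is
governed by the number of points.

The adjusted binding measure divides occupancy by a divisor built from
the amino-acid and nucleotide volume fractions. Whether the original
procedure divided by one combined volume or by both is ambiguous, so
the divisor mode is explicit: `product` (default), `sum`, or
`aa_only`. The product mode best linearised the geometric null in
pilot synthetic tests. Adjusted values are comparable across systems
only under a fixed mode.

## Genetic-code statistics

The standard code ships built-in (61 sense codons; stop codons
excluded everywhere; selenocysteine and pyrrolysine not modelled) and
can be overridden by a tabular file for reassignment experiments.

**Anticodon convention.** "Anticodon base 1" is ambiguous in the
field. The default convention writes the anticodon 5'→3' as the
reverse complement of the codon, so anticodon base 1 pairs with codon
base 3; an `aligned` convention (anticodon base *i* = complement of
codon base *i*) is available behind a switch, because joint elevation
of codon-1 and anticodon-1 scores is convention-dependent. Under both
conventions the anticodon *middle* base is the Watson–Crick complement
of the codon middle base, which is the position most analyses use.
Under the default convention the anticodon-1 cognate set inherits the
degenerate third codon base and can contain several bases; rank
statistics then use the best (minimum) rank in the set.

**Allocations.** Preferences are scored per *allocation*: one per
amino acid plus one extra per hexacodonic amino acid (Arg, Ser, Leu,
whose six codons span two codon families), 23 in total. For Arg and
Leu both families share the anticodon middle base; Ser's differ
(UCN vs AGY).

**Tests.** Three exact binomial tests are exposed with explicit
(k, n, p, tail) parameterizations rather than a hard-coded recipe:
cognate-first enrichment (upper tail, p = 1/4, counted per amino acid,
n = 20), cognate-last depletion (lower tail, counted per allocation,
n = 23), and best-with-at-least-one-cognate across codon/anticodon
positions 1–2 (upper tail, p = 3/4). The sum-of-ranks score adds the
cognate rank over allocations (bounds 20–80 for 20 single allocations;
minimum 23 with hexacodonic expansion) and is referred to a null of
200,000 independent uniform rank assignments. "Stronger than x% of
randomised assignments" counts null sums *strictly greater* than the
observed (lower sum = stronger preference); the fraction of null sums
≤ observed serves as the enrichment p-value. Ties propagate as average
ranks, and a row has a strict first choice only when a unique entry
holds rank 1. For dinucleotide schemes, an amino acid's multiple
cognate dinucleotides are never assigned identical ranks in one null
draw (sampled without replacement within the amino acid); requesting
that constraint for mononucleotides is warned about and ignored. No
multiple-testing correction is applied across charge states or
positions, matching the original analysis.

## Hydrophobicity

The composite hydrophobicity rank averages within-scale ranks
(1 = most hydrophobic, ties averaged) across scales, making it
invariant to monotone transformations of any scale and robust to
scale-to-scale variance. Each scale carries an orientation flag since
compilations mix hydrophobicity and hydrophilicity conventions. The
package ships four widely used public scales (Kyte–Doolittle,
Hopp–Woods, Eisenberg, Janin) as fixtures; the exact 43-scale
compilation behind the published composite is external data and can be
supplied as tabular files. Binding–hydrophobicity relationships use
ordinary least squares with explicit collinearity rejection (rank
deficiency, reported with a condition number); per-scale comparisons
are a loop over single-covariate fits.

## NMR titration fitting

The one-site fast-exchange isotherm predicts the observed shift change
as Δδ_max times the bound fraction of the observed species, using the
exact quadratic solution for the complex concentration. K_D is treated
in concentration units (mM) throughout: the published start interval
"0.5–1.5 M⁻¹" is dimensionally inconsistent for a dissociation
constant, so the start interval is configurable with a 0.5–1.5 mM
default. The fitting ensemble follows the published protocol: 500
fits, each dropping one uniformly chosen datapoint, Δδ_max started at
0, K_D started uniformly in the interval, both parameters bounded
below by 0 with no upper bound (Levenberg–Marquardt via
`minpack.lm::nlsLM`). Non-convergent fits — unspecified in the
original protocol — are recorded and excluded, with the failure count
reported; if all fail, the fit is rejected.

One property of the protocol deserves emphasis: the 95% range of the
leave-one-out ensemble (`KD_range95`) tracks single-point influence
and understates full sampling variability by roughly √n. In recovery
simulations at 5% noise it covered the true K_D in well under half of
replicates. The package therefore also reports a jackknife standard
error and normal-theory interval (`KD_se`, `KD_ci95`) computed from
the per-dropped-point group means, which achieved ~92% coverage in the
same simulations. Both are reported; the ensemble range remains the
faithful reproduction of the published summary.

Partner comparison samples one K_D per ensemble per draw (10,000
draws) and ranks ascending — lower K_D is stronger binding — reporting
best and worst fractions plus the full pairwise win matrix, since
published percentages could arise from either summary. Fits are
reported per proton probe and never averaged across probes: probes sit
at different positions on the nucleobase and demonstrably disagree.

## Synthetic data: what it emulates, and what it does not

`gen_distance_series` emulates the *reduced* output of the box
simulations: a two-state Markov chain (geometric dwells, default mean
bound dwell 20 frames) with stationary bound probability equal to the
requested occupancy; bound frames draw from a truncated-Gaussian
mixture at 1.9/2.5/4.0 Å (weights 0.3/0.4/0.3, the mode locations
being the only published constraint) and free frames from N(5.5, 1) Å
left-truncated at the threshold. Because the two distributions are
separated exactly at the threshold, the planted occupancy is exact
ground truth for the estimator. Defaults follow the study design
where stated — 100 parallel runs, a 40 Å box, 10 amino-acid copies —
and use 10,000 frames per run where the study does not state a count.
Distances are emitted directly rather than derived from coordinates:
statistical correctness and geometric correctness are validated
separately, the latter by `gen_box_trajectory` (rigid random-walk
clusters with optional square-well Metropolis attraction, uniform
stationary distribution at zero attraction).

What passing these tests does *not* show: real trajectories have
force-field physics, solvent, ions, continuous binding kinetics and
autocorrelation structure that no two-state chain reproduces, and real
titrations have baseline drift and probe-specific artefacts beyond
i.i.d. Gaussian noise. The synthetic suite validates the estimators
and statistics, not the simulations or spectroscopy.

## Pipeline and reproducibility

`run_pipeline()` executes simulate/ingest → distances → occupancy →
volume adjustment → ranks → preference statistics from a single
configuration (R list or YAML), embeds the resolved configuration and
package version in the report, and is byte-deterministic given the
configuration: every stochastic stage draws from an explicit sub-seed
of the master seed, and exported functions restore the caller's RNG
state. Stage failures abort with the stage named. In synthetic mode, a
planted set of amino acids receives elevated occupancy (default 0.45
vs a 0.15 base) on the first cognate anticodon-middle base, with small
positive occupancy jitter elsewhere so that unplanted rows have a
uniformly random strict best binder.

Validation problem sizes were chosen to exercise each estimator at
meaningful precision: occupancy recovery at 10⁵ pooled frames (≈3
chain-aware standard errors ≈ 0.02), bootstrap coverage over 100–200
replicate datasets of 100 runs, randomization nulls at 20,000–200,000
draws, and K_D recovery with 500-fit ensembles over 0.5–50 mM at
0.002 ppm noise on the published concentration design (P = 0.1 mM,
ligand 0.1–100 mM).

## Known limitations

- Orthorhombic boxes only; no solvent-excluded-surface volumes (the
  Monte Carlo threshold volume is the operative size proxy).
- Ring-atom subsets are configuration, not hard-coded chemistry: the
  ring-nitrogen reduction is a crude but published representation, and
  the exact atom selection is left to the caller's annotation.
- The hexacodonic "best rank in cognate set" convention for degenerate
  anticodon-1 sets is one defensible reading of an underspecified
  procedure; it is applied uniformly and stated here.
- No dwell-time/kinetic analysis below the threshold; all binding
  modes are integrated, as in the source analysis.
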