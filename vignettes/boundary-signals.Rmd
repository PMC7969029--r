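---
title: "Profiling structural and energetic signals at exon–intron boundaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling structural and energetic signals at exon–intron boundaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`splicescape` treats a genomic boundary window as a sequence of
dinucleotide steps and asks whether the physico-chemical trajectory of the
DNA — 28 structural parameters and 3 energies, one value per step class —
departs from its exon-interior baseline as the sequence crosses a splice
junction. The underlying assumptions are:

* **Step additivity.** Each parameter is a property of a dinucleotide step
  alone; context beyond two bases is ignored. This is the standard
  nearest-neighbour approximation used for DNA shape and thermodynamic
  lookups, and it is what makes a per-position profile a simple table
  lookup followed by smoothing.
* **Strand symmetry of the duplex.** A step read 5′→3′ on one strand is
  the reverse-complement step on the other, so the 16 dinucleotides
  collapse into 10 classes (`canonical_step()`). When building tables from
  observations we pool occurrences exactly as read, without flipping the
  sign of strand-asymmetric parameters (tilt, shift, buckle, tip,
  y-displacement, shear); a `sign_correct` flag in `build_table()` enables
  the alternative convention. Pooling-as-read is the simpler convention
  and the one consistent with reading every occurrence 5′→3′; users whose
  observation sets encode signed asymmetric parameters should opt in to
  sign correction.
* **Angular quantities need circular statistics.** Backbone torsions, the
  sugar phase and the rotational helical/base parameters are angles;
  averaging 359° and 1° must give 0°, not 180°. `circular_mean()`
  implements the mean direction of unit vectors and refuses to answer when
  the resultant length falls below `1e-8` (opposed angles have no mean
  direction). Pucker amplitude, translations and energies are linear.
  The angular flags live in `parameter_descriptors()`.

## Window geometry and conventions

Windows are `2F + 1` nt with signed positions `−F..+F` and the anchor at
0. For exon→intron windows (Dataset I) the anchor is the exon's last base;
for intron→exon windows (Dataset II) the exon's first base; controls
(Dataset III) are centred on the midpoints of exons longer than 1000 nt.
Coordinates are GTF-style 1-based inclusive on input and BED-style 0-based
half-open on output.

Extraction is strand-aware by default: minus-strand windows are
reverse-complemented so that every sequence reads 5′→3′ in gene
orientation and donors/acceptors appear as `GT`/`AG`. This is the only
orientation in which a cross-dataset consensus is meaningful; a
`stranded = FALSE` mode reproduces naive reference-strand extraction for
comparison. Boundaries with no adjacent intron (transcript-terminal exon
ends and starts) are dropped by default (`internal_only`), since a
"junction" window without an intron on the proper side is a category
error; the flag restores them.

A 25-bp smoothing window covers 24 steps, so a 401-nt window yields
377 profile points. The window-to-position mapping is a genuine free
choice — the smoothed value could be labelled by its window's first,
central or last base — and we default to **centre** (`window start + 12`),
which keeps junction-crossing features symmetric around position 0;
`assign_positions()` exposes all three. With `F = 200` and centre
alignment, profiles span −188..+188, which comfortably covers both the
±30 junction vector and the ±(120..180) control vectors.

`N` bases are handled by masking: any step containing an `N` contributes
nothing to the window means (an all-masked window is `NA`); an
`impute` policy substitutes the parameter's mean over all 16 dinucleotides
instead. Masking is the default because imputation quietly biases profiles
toward the table centre.

## Normalisation and error bars

Pooled profiles report the mean and `sd/√n` per position; the SEM uses the
sample (n−1) standard deviation by default, with a population option. For
the joint all-parameters view, each parameter's *pooled average profile*
is min–max normalised to [0, 1]. Normalisation is deliberately a plotting
transform only: per-sequence statistics (enclosed areas, correlations) use
raw table-unit values, so detection results do not depend on the scale of
the display. A degenerate profile (max = min) normalises to a constant 0.5
with a warning rather than erroring, so batch plots stay defined.

## The detection rule, stated and measured

Per sequence and parameter, the junction vector (61 values, −30..+30) is
compared with a control vector 150 positions toward the exon interior
(upstream for Dataset I, downstream for Dataset II). Their dissimilarity
is the trapezoidal integral of `|v₁ − v₂|` over unit-spaced positions —
symmetric, non-negative and zero iff the vectors are identical; a
rectangle-sum alternative is available. A sequence is called as carrying a
signal when its area strictly exceeds `mean − 2·sd` of the area
distribution.

Implemented literally, this rule is **permissive by construction**: for
any i.i.d. Gaussian area sample it flags `Φ(2) ≈ 97.7%` of sequences, and
the test suite pins the implementation to that number at n = 10⁵. We keep
the literal rule (with strict inequality, which makes the sd = 0
degenerate case well-defined and yields zero detections plus a warning)
because it is the stated procedure; a calibrated null would require
comparing each junction's area against the *control dataset's* area
distribution, and that variant is easy to build from the exported pieces
(`call_signals()` accepts any area vector and threshold multiplier) but is
deliberately not the default.

## Correlations and grouping

Position-specific Pearson correlations are computed between parameters'
average profiles over the 11 integer positions −35..−25 (the upstream
shoulder where profiles move together). Parameters constant within the
window get `NA`, never 0 — an undefined correlation is not a zero one.
Since Pearson correlation is affine-invariant, it does not matter whether
raw or normalised average profiles are supplied; two parameters whose
tables are exact affine transforms of each other correlate at exactly ±1
through the whole encode–smooth–correlate chain, and the tests exploit
this as an end-to-end oracle.

For the two-group clustering, each profile is scored by
`mean(profile over −30..−20) − mean(profile over an exon-side baseline
window)` (default −188..−100): rising profiles near −25 form group I,
falling ones group II. The published scaling formula for the group plots
is printed with unbalanced parentheses; the only reading containing both
operations is `(x − mean(x)) / (max(x) − min(x))`, which is what
`scale_for_grouping()` implements (output mean exactly 0). Five parameters
(y-displacement, opening, delta, stacking and solvation energy) are
excluded from grouping by convention (`grouping_excluded_parameters()`);
delta remains available to the correlation analysis, where it does appear
in strongly-correlated pairs. Near-zero scores are labelled excluded with
a borderline flag rather than forced into a group.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` + `generate_junction_dataset()` produce windows with:

* distinct exon (52% GC) and intron (43% GC, pyrimidine-enriched)
  compositions — enough contrast to create the composition step a real
  junction shows, without attempting isochore realism;
* a degenerate donor consensus over −3..+6 (`MAG|GTRAGT`-like, `GT` at
  +1/+2 with probability ≈ 0.99 × 0.955) and an acceptor consensus over
  −5..0 (pyrimidine run into `YAG|`), with a `strength` dial down to
  uniform;
* for Dataset II, a branch-point adenine at a uniform offset 18–40 nt
  upstream of the acceptor and a polypyrimidine tract (85% C/T) between
  the branch point and position −5;
* optionally, a planted property bump: within a span (default −30..+30),
  bases are resampled from a first-order Markov chain exponentially tilted
  toward high-value steps of a target parameter, with the tilt solved by
  root-finding so the expected step value shifts by a requested number of
  table units (default 0.75 of the achievable headroom). Amplitude 0
  provably reduces to the untilted chain; unreachable amplitudes are
  refused. An alternative `offset` mechanism leaves sequences intact and
  instead returns an additive table-space track for
  `profile_dataset(offset = )`, for experiments where the signal should
  live in the table rather than the sequence.

Everything is deterministic given the spec's mandatory seed.

The generator does **not** simulate codon structure, repeats, isochores,
splicing enhancers/silencers, or any transcript-level process. Passing
tests on this synthetic data therefore demonstrate that the *pipeline*
recovers known statistical structure (consensus probabilities to binomial
accuracy, planted bumps as localised profile deviations, flat controls);
they say nothing about whether real junctions carry such signals — that
requires a real annotation, genome, and a property table with real
provenance.

## Numerical choices

* Moving averages use running sums (exact for the tested tolerances;
  oracle-checked against the naive loop at 1e−12).
* The enclosed area uses trapezoid weights `(½, 1, …, 1, ½)`; it is a
  pseudometric on equal-length vectors (symmetry, non-negativity, triangle
  inequality are property-tested).
* Table TSVs round-trip at 12 significant digits (`%.12g`).
* The tilted-chain solver shifts exponents row-wise before exponentiating,
  so tables with large values (e.g. solvation energies ~−180 kcal/mol)
  cannot overflow.
* Ties at the detection threshold do not exist by construction (strict
  inequality); ties between top bases in the consensus caller resolve by
  the fixed A<C<G<T order inherited from `order()`.

## Test problem sizes

The suite exercises the numerics on ~5000 randomised oracle instances and
runs the statistical-recovery checks at n = 10⁴ junction sequences (5
parameters), n = 10³ controls, and 10⁵-sample rule calibration; the
full-width runs use 401-nt windows throughout. Two documented checks are
intentionally strict: the ten-fold planted-to-null area margin and the
"controls within ±2 SEM everywhere" band. The margin supremum under
composition-bias planting with the default compositions is just below
ten-fold (the flat null's area is driven by the same step-indicator
variance that caps the achievable tilt), and a pointwise 2-SEM band over
377 smoothed positions is exceeded by pure noise about half the time
(~16 effectively independent positions at the 95% level). Both checks are
kept as stated and their outcomes reported as measured; the surrounding
weaker properties (localisation at ≥5× SEM, multi-fold area separation)
hold with wide margins.

## Known limitations

* The shipped default property table is a synthetic stand-in with
  representative B-DNA values; it supports testing and demonstration, not
  structural inference. Build or load a real table for science.
* Exon-level deduplication treats an exon shared by many transcripts as
  one boundary; transcript-level counting is available via
  `dedup = FALSE` but inflates shared junctions.
* The detection rule is self-referential (threshold from the same area
  distribution it classifies) and permissive, as quantified above.
* Information-content and consensus calls assume independent positions; no
  motif model is fitted.
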