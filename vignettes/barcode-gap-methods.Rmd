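---
title: "Barcode-gap PCI: models, parameters and design choices"
author: "barcodeGap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Barcode-gap PCI: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeGap)
```

## The question the package answers

A DNA barcode is useful when sequence distance alone can place a new
specimen in the right species. The operational criterion implemented here
is the *barcode gap*: a species with at least two samples displays a gap
when its largest within-species sequence distance is strictly smaller
than its smallest distance to any sample of another species. The
*probability of correct identification* (PCI) is the fraction of species
(with at least two samples) displaying a gap, reported with a Wilson
score confidence interval. Species represented by a single sample never
enter the denominator, but they do serve as interspecific neighbors —
"decoys" that can break another species' gap. This makes the PCI a
deliberately stringent statistic: deeper sampling can only add decoys,
so it tends to fall, not rise, as a survey grows.

Because the gap decision compares distances only by order, the PCI is
invariant under any strictly increasing transform applied to all finite
distances. That single observation explains an otherwise surprising
empirical pattern: for a fixed alignment type, every classical
evolutionary distance (JC69, K2P, F81, TN93, …) produces exactly the
p-distance PCI whenever it orders the relevant pairs the same way, which
one-parameter transforms of p do exactly, and multi-statistic transforms
do in practice. The package asserts the exact-transform version as a
property test and verifies the empirical version on simulated data.

## Alignment model

All pairwise alignment uses affine gap scoring: a gap of length $k$
costs $o + k e$ (the first gap column pays $o + e$). This is the legacy
NCBI BLAST convention; scoring tools differ on this point, so the
convention is fixed here and the shipped schemes are expressed in it.
Two schemes are built in:

* `ncbiScheme()` — match $+1$, mismatch $-3$, $o = 5$, $e = 2$ (legacy
  `blastn` defaults);
* `ucscScheme()` — the HOXD70 substitution matrix with $o = 400$,
  $e = 30$ (BLASTZ defaults).

These are the canonical tool defaults; any other scheme can be supplied
from a small YAML file (`readScoringScheme()`). IUPAC ambiguity codes
score as the scheme's worst substitution against everything, themselves
included — a conservative, deterministic choice.

Three alignment variants share the scoring model:

* **global** (Needleman–Wunsch): whole length of both sequences, end
  gaps penalized;
* **semi-global**: the whole of one sequence against a subsequence of
  the other, flanking end gaps of the host free (contributing exactly
  zero, not a reduced penalty); both orientations are evaluated and the
  better returned;
* **local** (Smith–Waterman): best substring pair; the empty alignment
  is admissible, so scores are floored at zero.

For every pair the scores obey local ≥ semi-global ≥ global, since each
relaxes the previous one's constraints. A fourth route takes an
externally built multiple sequence alignment (the package never builds
MSAs) and extracts, for any two rows, the *implied* pairwise alignment:
keep both rows, delete columns gapped in both. Implied alignments carry
no score by default and feed evolutionary distances; they can be
re-scored under a scheme (`scoreAlignment()`) when alignment distances
are wanted on the MSA route — whether the original analyses scored MSA
pairs this way is not recoverable, so the option exists but is not the
default.

Among co-optimal tracebacks the aligner deterministically prefers the
diagonal move, then a gap in the subject, then a gap in the pattern; the
score, which is all downstream logic consumes, is tie-free. A
brute-force enumerator (`bruteForceAlignScore()`, sequences ≤ 12 bases)
is shipped as the independent reference the dynamic programming is
tested against; the test suite also cross-checks against
`Biostrings::pairwiseAlignment()`.

## Distances

Distances come in two families. The *alignment distance* is simply the
negated alignment score — the simplest order-reversing transform of
similarity. No length normalization is applied by default (how the
original similarity-to-distance conversion was done is not documented in
the sources this design follows, so the plain sign flip is the recorded
assumption); a length-normalized variant sits behind
`normalize = TRUE` for sensitivity analyses. Since the gap logic uses
only order, the choice matters only when it changes the ranking of
pairs.

*Evolutionary distances* transform site-pattern frequencies observed at
*compared sites*: columns holding an unambiguous base in both rows
(pairwise deletion, per pair — never complete deletion across the
dataset, because each pair has its own alignment). With $p$ the
differing fraction, $P$ the transition and $Q$ the transversion
fraction:

* p-distance: $p$;
* JC69: $-\tfrac34 \ln(1 - \tfrac43 p)$;
* K2P: $-\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q)$;
* F81 and TN93: the standard closed forms with base frequencies
  estimated from the compared sites of the pair.

Where a logarithm argument is non-positive the transform is undefined;
the package returns $+\infty$ rather than an error or NaN, and
$+\infty$ compares as larger than every finite distance. This keeps the
gap logic well defined on saturated decoy pairs, and extends the strict
gap rule naturally: a species whose nearest non-member sits at
$+\infty$ has a gap exactly when its own maximum intraspecific distance
is finite (`Inf < Inf` is false). Additional models plug in through
`registerDistanceModel()`; the five built-ins cover the standard
one-to-four-parameter ladder, and the invariance property makes the
exact roster immaterial for PCI purposes.

The closed forms are cross-validated against `ape::dist.dna()` in the
test suite.

## PCI estimation

`speciesGaps()` scans a `DistanceMatrix`: per eligible species, the
maximum over within-species pairs and the minimum over (member,
non-member) pairs, with the strict `<` rule (ties fail — two identical
sequences shared by different species then correctly break both gaps).
`pci()` counts gap species $k$ among eligible species $n$ and attaches
the closed-form Wilson score interval, using the exact normal quantile
($z \approx 1.959964$ at 95%, not 1.96 — the difference can move a
two-decimal rounding). Reported tables round to two decimals; raw
values stay in the objects.

`pciTable()` runs the full grid (alignment types × schemes × distance
kinds), sharing one alignment pass per (type, scheme) cell across all
distance kinds, and optionally emits the per-species gap details of
every combination.

For comparing PCIs between conditions and for the expert-agreement
analysis, the package uses the two-sided Fisher exact test on 2×2
species-count tables (`fisherExact2x2()`, `pciDifferenceTest()`). The
two-sided convention is the usual "sum of outcomes no more likely than
observed" rule, matching `stats::fisher.test`; tail doubling is
available behind `method = "doubling"`. Which exact two-proportion
procedure the original analyses used is not recoverable, so the Fisher
test — the minimal exact choice for small species counts — is the
documented assumption. P-values are reported raw; a user-supplied
Bonferroni factor can be applied at reporting time
(`runCompare(..., bonferroniFactor = )`), never silently.

## The simulator: what it emulates, what it does not

`simulateDataset()` generates ITS-like datasets with known truth on a
star phylogeny: one random root; per species, a prefix of the root at a
drawn length (default 384–936 bp, the length spread reported for these
genera) mutated at the species divergence rate; per sample, the species
ancestor mutated at the within-species rate; indel events (default
0.005 events/site, geometric lengths, mean 3 bp) strike at both levels.
Substitutions replace a base with one of the other three, uniformly by
default (`kappa = 1`); raising `kappa` introduces transition bias so
that K2P-vs-p differences become exercisable. The default species-count
distribution (42% singletons, geometric tail capped at 30) mirrors the
skewed sampling typical of regional fungal surveys, and an optional
cryptic pair (on by default) splits one nominal species into short- and
long-ITS1 lineages separated by a ~390 bp insertion, reproducing the
within-label length dimorphism that unmasks cryptic species in real
surveys.

Defaults for the divergence rates are 0.02 substitutions/site within
species and 0.30 between species — a separable regime in which the
pipeline should identify essentially every species. The replicated
checks in the test suite run 20 seeded datasets of 10 species × 5
samples at exactly these rates: mean PCI under global alignment with
p-distance is required to reach 0.95, and with the within-species rate
raised to the between-species rate (labels carrying no signal) to stay
below 0.2. A star phylogeny suffices because the gap logic never uses
tree topology; what the simulator does *not* emulate is rDNA-specific
biology — concerted evolution, secondary structure, chimeras — or
GenBank-style annotation error, so passing simulations demonstrate
correctness of the pipeline, not field performance of any real marker.

All randomness flows through R's seeded generator from a single integer
seed; the same seed reproduces output byte for byte.

## Numerical and design notes

* Gap convention: first gap column pays open + extend. Published
  parameter tables for the original scoring systems are not available
  in the accessible text, so the shipped schemes are the tools'
  canonical defaults and are documented as an assumption.
* Semi-global free end gaps contribute exactly zero score.
* Distance matrices store `Inf` (never NaN, never an exception) for
  saturated transforms.
* The 2×2 test sums hypergeometric densities with the same
  `1 + 1e-7` relative slack as `stats::fisher.test`, avoiding
  floating-point ties at the observed density.
* Problem sizes in the replicated suite (20 replicates, 10 species × 5
  samples, full-length 384–936 bp sequences) were chosen as the
  smallest replicated design in which the distribution-level claims
  (distance-kind invariance, semi-global ≡ global, parameter recovery)
  are decidable with no sampling ambiguity.
* The external-MSA route in the replicated checks uses mafft
  (FFT-NS-2); any aligner producing aligned FASTA works, since the MSA
  is consumed, not built.

## Known limitations

* Alignment is exact dynamic programming — quadratic time and memory
  per pair; no banding, vectorization or heuristic seeding. Datasets of
  a few hundred sequences are comfortable; thousands are not the target.
* `alignment_score` distances are not metrics and are only meaningful
  within one (alignment type, scheme) cell.
* Expert-agreement flags are species-level inputs; the package
  validates consistency but cannot audit the judgment itself.
* The simulator's star phylogeny produces no within-species population
  structure; PCI estimates on simulated data are therefore optimistic
  relative to surveys with strong geographic structure.
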