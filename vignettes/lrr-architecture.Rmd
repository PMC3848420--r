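---
title: "Annotating RI-like leucine-rich repeat architectures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating RI-like leucine-rich repeat architectures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrrscan)
```

## The problem

Leucine-rich repeats (LRRs) of the ribonuclease-inhibitor-like (RI-like)
subfamily are 28-29 residue tandem repeats whose concave face carries a short
beta strand (the `LxxLxLxx[N/C]xL` motif, with L standing for the aliphatic
class L/I/V) and whose convex face is alpha-helical.  In RI itself the
repeats come in two types, A and B, that strictly alternate along the chain,
and many tandem copies curve the protein into a horseshoe or, for very long
repeat runs such as the LRR domain of the NOD-like receptor NLRC5, into a
closed multi-turn solenoid.  Annotating such an architecture from sequence
means answering four questions that this package operationalizes:

1. *Where are the repeats, and of which type?* (consensus scoring +
   segmentation)
2. *How do exon boundaries relate to the repeat frame?* (exon phasing and
   typical/atypical classification)
3. *Which functional motifs anchor the domain architecture?* (Walker A/B,
   Sensor 1, AxP, winged-helix consensus, NLS basic clusters, cysteine
   capping spacings)
4. *What does the repeat count imply geometrically?* (full-circle
   bookkeeping and a coarse C-alpha solenoid model)

## Consensus model and scoring

A consensus pattern is a fixed-length (28 or 29) list of per-position residue
classes.  Classes follow the standard synonym groups: aliphatic `{L,I,V}`,
hydroxyl `{S,T}`, acid/amide `{E,D,Q,N}`, basic `{R,K}`, nonpolar `o`,
glycine `g`, and the wildcard `x`.  A window's score is the unweighted
fraction of constrained positions whose residue belongs to the position's
class; there is no log-odds weighting because the underlying annotation
criterion is presence/absence of consensus residues, not a trained profile.

The two shipped repeat types encode the RI-like skeleton and differ the way
alternating repeat types do in RI: `type1` is a 28-mer with asparagine at
the strand position, `type2` is a 29-mer with cysteine there and one
inserted wildcard on the convex side (insertion site column 16, recorded as
pattern metadata).  The literal published consensus strings for any
particular protein family can be substituted wholesale via
`read_pattern_config()`; the defaults are deliberately data, not code.

```{r}
default_type_patterns()$type1
```

### The fit threshold

`lrr_config()$min_score` defaults to **0.8**.  This value is calibrated from
the exact distribution of per-column class matches (a convolution of
Bernoulli variables with the class background probabilities): a noise-free
consensus repeat scores 1.0 and passes with margin even after point
mutations at rates up to ~5%, while for a residue-shuffled sequence of
repeat-rich composition (aliphatic-class frequency ~0.35) the probability of
any window reaching 0.8 is about 5e-3 per protein.  At 0.6 the same
computation admits roughly one spurious window per shuffled protein, which
would defeat the shuffled-null property the segmenter is designed to have;
0.6-0.7 remains a reasonable exploratory range for diverged repeats, exposed
as `--min-score` on the command line.  `threshold_sensitivity()` reports the
fitting-repeat count across the whole grid so a reported count can be judged
against this choice.

## Segmentation

Candidate windows (every start, every pattern, score at least the threshold)
are chained by dynamic programming into the maximum-objective set of
non-overlapping windows.  The objective is the sum of window scores plus an
adjacency bonus (0.1) when repeats are exactly tandem and an alternation
bonus (0.05) when consecutive chained repeats differ in type.  The bonuses
are small by design: they break ties in favor of the biologically expected
tandem, alternating layout without ever outweighing a 0.05 score difference
times one window.  Ties between equal-objective chains resolve toward the
chain whose first repeat starts earlier, making segmentation fully
deterministic.  Inter-repeat gaps of 10-27 residues are emitted as
*atypical* segments - degenerate repeats worth reporting - rather than
silently skipped; shorter gaps are noise and longer gaps are treated as
non-repeat sequence.

## Exon phasing and classification

The phase of an exon is the consensus column at which its first encoded
residue falls, computed inside the consensus-fitting repeat that contains
the exon start (1-based, matching consensus column numbering).  For
repeat-encoding genes the expectation is a single modal phase; the package's
default expectation is column 6.  An exon is a *typical* LRR when its
length matches a pattern length (28/29) and its peptide reaches the score
threshold against the pattern **rotated to the exon frame**
(`rotate_pattern()`): an exon starting at column 6 sees columns
`6..28, 1..5`, the tail of its own repeat followed by the head of the next.
"Too short and/or did not fit" is implemented literally as the disjunction
(length < 28) OR (score < threshold), and the per-exon `reason` column
reports which branch fired without asserting any aggregate split.  The final
exon is exempted as the C-terminal capping repeat when 30-40 residues long,
mirroring the capping repeats of the RI family, which are longer than
internal repeats (36 residues in the emulated receptor vs 34 in RI).

## Motif scanning

Three modes cover the motifs that anchor NLR domain architectures.  Literal
motifs (Walker A `GKAGMGKT`, Walker B `LLIFDGLDEAL`, winged-helix `FYAKDI`)
are exact substring searches.  Class patterns (`[AG]xxxxGK[ST]` and the
four-hydrophobic `DxxDE` Walker generalizations) reuse the pattern
compiler.  Spacing motifs locate anchor-residue chains with exact gaps: the
N-terminal LRR capping signature `Cx23Cx5Cx6Cx12C` spans 51 residues from
first to last cysteine.  Two deliberate limitations: Sensor 1 (`TSR`) and
AxP (`AVP`) are too short to scan de novo, so they are restricted to their
domain spans (NACHT, small-helical) and reported there; and "cysteine-rich
region" is exposed only as rolling Cys counts (`cys_density()`), because no
density criterion exists that would justify a classifier.  Basic
nuclear-localization clusters are maximal windows (at most 14 residues)
containing at least 5 K/R, merged and trimmed to their basic residues -
like all NLS prediction, this has genuine false positives on random
sequence, which is why downstream consumers match clusters against expected
coordinates rather than assuming uniqueness.

## Solenoid geometry

`full_turns(n, params)` is simply `n / repeats_per_turn`.  The default
`repeats_per_turn = 21.5` is *calibrated to the claim* that 43 repeats close
exactly two circles - it is not a measured quantity, and the RI-like
horseshoe preset (`ri_preset()`, ~16 repeats per 0.7 turn) is provided as
the structurally grounded alternative.  `build_solenoid()` places repeat `i`
on angular sector `2*pi*i/repeats_per_turn` at height `i * rise_per_repeat`
(defaults: rise 4.8 A, radius 30 A), and within each repeat the chain loops
once around the local cross-section of the solenoid, the way an LRR's
strand-loop-helix traverses its repeat.  The cross-section radius is solved
so the mean squared C-alpha spacing is exactly 3.8 A^2; a closed-form
estimate is refined by one-dimensional root finding because the outside of a
toroidal coil travels farther than the inside (a cos^2 term that does not
average out).  Residual bond-length variation is below 0.02 A for the
default geometry, within the 3.8 +/- 0.1 A contract, and repeat centroid
heights rise by exactly `rise_per_repeat` by construction.  PDB output is
C-alpha-only, single chain, fixed-width v3.3 records; the format's 4-digit
residue field limits traces to 9999 residues.

## What the synthetic generator emulates - and what it does not

`generate_protein()` produces ground-truth-labelled proteins with the
statistical structure the analysis assumes: tandem 28/29-residue repeats
sampled from the consensus (constrained positions uniform within their
class), strict type alternation, point mutations at a configurable
per-position rate (within-class with probability 0.5 by default), degenerate
short slots, planted motifs in the flanks, and exon tables whose boundaries
sit at a configured consensus phase.  Unconstrained positions and flanks
draw from Swiss-Prot-like background frequencies rather than a uniform
alphabet: uniform composition over-weights heavy aromatics and yields a
1866-residue protein of ~221 kDa, whereas natural composition reproduces the
~204 kDa scale of the emulated receptor; a `"uniform"` option remains for
null experiments.  Flanks are cysteine-depleted by default so planted
Cys-spacing motifs are unambiguous, and the NLRC5 mimic clears K/R from a
buffer around its planted NLS for the same reason.

The `nlrc5_mimic_config()` preset mirrors the published architecture
end-to-end: 1866 residues, 43 repeat slots numbered as exons 7-49, seven
degenerate slots at exons 11/12/16/17/21/26/30, a 36-residue C-terminal
capping repeat, and all functional motifs at their published coordinates
(NLS 121-134, Walker A 228, Walker B 303, Sensor 1 345, AxP 404, FYAKDI
475, His491, capping cysteines 648-698).

What passing tests on this material does **not** show: real LRR proteins
have correlated (not i.i.d.) substitution patterns, insertions/deletions
that shift the repeat frame, diverged repeats near the detection boundary,
and database exon annotations with their own error modes.  On the real
receptor the alignment-based repeat count (33) and the exon-based count (36)
disagree precisely because the methods weigh such imperfections differently;
in the mimic, where repeats are planted from the same consensus the scorer
uses, the two counts coincide by construction (36).  The mimic validates the
*machinery* - recovery of a known architecture - not the biological
uncertainty between 33 and 43 repeats, which only crystal structures can
resolve.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere; the 0-based half-open
  conversion helpers are internal and round-trip exactly.
* Molecular weights use average residue masses (one water added per chain);
  predicted masses of large proteins are conventionally quoted on this
  scale, and a `x_mass` hook covers sequences with unknown residues.
* Unknown residues (`X`) are rejected by default since class matching is
  undefined for them; `allow_unknown` admits them for I/O purposes.
* Degenerate inputs: sequences shorter than one repeat segment to an empty
  annotation (not an error); fewer than two fitting repeats make the
  alternation fraction `NA` with a warning; an all-wildcard pattern scores 0.
* The 29-mer's insertion site is pattern metadata (default column 16,
  immediately before the convex-side block); scoring always uses the
  explicit per-column classes, so the choice affects reporting only.
* Problem sizes used by the shipped studies: boundary recovery uses 20
  seeds of 8-repeat proteins at mutation rate 0.05; the shuffled null uses
  100 seeds; the goodness-of-fit check on the mutation process uses 200
  seeds.  These sizes give the binomial margins the corresponding
  properties assert (e.g. at least 95% recovery) while keeping the default
  test run fast.

## Known limitations

* The repeat period is fixed by the pattern set (28/29); de novo period
  inference and nested/interrupted repeat domains are out of scope.
* Exon protein spans must be supplied (TSV contract); genome-coordinate
  arithmetic is limited to the `exon_spans_from_cds()` convenience.
* The solenoid model visualizes repeat topology; it is not a homology model
  and carries no side chains or secondary structure records.
* Default consensus strings approximate the RI-like subfamily; for
  family-specific work, replace the pattern config with the family's
  published consensus.
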