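---
title: "Correlating super-short tandem repeat densities with genomic features"
author: "sstrscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlating super-short tandem repeat densities with genomic features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sstrscape)
```

## The method

Super-short tandem repeats (SSTRs) are maximal tandem repeats with a 1 bp
or 2 bp repeat unit and a total length of 2 to 12 bp. They are far too
frequent to study one locus at a time, so the unit of analysis here is the
*local density*: each chromosome is cut into fixed 100 kbp segments, every
maximal SSTR occurrence is assigned to the segment containing its start
position, and the per-segment count divided by the segment size gives one
density track per (repeat unit, total length) combination — 16 units times
11 lengths, 176 tracks. These tracks are compared to feature tracks
(G+C content, coverage by gene categories, retrotransposon count density)
with the Pearson correlation coefficient, per chromosome and then averaged
over chromosomes with an unweighted mean.

Three rules define an SSTR occurrence:

* **Maximality.** Only the longest run is counted, at its full length:
  `AGAGAG` is one occurrence of unit AG at length 6; the contained `AGAG`,
  `AG`, and the rotated-phase `GAGA` are not counted. Runs longer than
  12 bp are dropped entirely (they are conventional STRs, not SSTRs), not
  truncated to 12.
* **Phase.** A run's unit is its first two bases, so AG-runs and GA-runs
  are distinct tracks. Mononucleotide runs use the homodinucleotide labels
  AA/CC/GG/TT, which gives exactly 16 units. Odd total lengths are legal
  in both period classes (`GAG` is unit GA at length 3).
* **Breaks.** Any non-ACGT character (N or another ambiguity code)
  terminates a run and can never be inside one.

The 16 units fall into four motif groups by the strong (G/C) or weak
(A/T) identity of the two unit positions — SS, WW, SW, WS — and the
central empirical observation the pipeline is built to expose is that the
groups behave coherently: SS tracks correlate positively with G+C, WW
tracks negatively, and the mixed groups alternate with length parity,
because the G+C content of a mixed-unit repeat itself oscillates with
length (66.7% for a length-3 SW repeat, exactly 50% at even lengths).

## Segments, filters, and features

Segments are equal-sized; a trailing remainder shorter than the segment
size is dropped rather than padded, so every density shares one
denominator. Two filters remove segments from all correlations: overlap
(by at least 1 bp) with an excluded region such as a centromere, and a
sequencing-gap fraction strictly above 1% (a segment at exactly 1% N is
kept, following the strict reading of the threshold). G+C is computed over
unambiguous bases only, so small amounts of N do not depress it; larger N
runs are handled by the gap filter.

Gene categories come from GenBank feature tables. Genic is the
strand-ignored union of all `gene` records and intergenic its complement,
so the two tile the chromosome. Gene records are classed with precedence
*pseudogene > protein-coding > non-protein-coding*: the pseudo qualifier is
explicit, protein-coding requires an overlapping mRNA or CDS record, and
non-protein-coding is the residual class. The precedence for a
pseudo-qualified gene that also contains a CDS is a design choice: the
pseudo qualifier is the annotator's explicit statement, while mRNA/CDS
overlap is only circumstantial evidence, so the explicit label wins. Exons
per class are the unions of the class's defining sub-features clipped to
the class's genes; introns are the remainder. Coverage (the fraction of a
segment's bases inside a category, clipped at segment boundaries) is used
for genes because gene lengths span orders of magnitude; count density is
used for retrotransposons, which are shorter and more uniform.

Retrotransposon families are taken from RepeatMasker's class/family
column with prefix matching (Alu matches AluY, AluSx, ...): SINE/Alu,
SINE/MIR, LINE/L1, LINE/L2, and the LTR class as a whole.

## The masking correction

SINE Alu elements carry poly-A stretches (an A-rich linker between the
two monomers, and the tail), so segments rich in Alu copies are
mechanically rich in long (A)~n~ runs. To ask whether a correlation
survives with the repeat content *inside* a family removed, the per-segment
counts are adjusted as

adjusted(s, k) = raw(s, k) − inside(s, k) + L~retro~(s) · d̄(k),

where inside(s, k) counts occurrences starting inside a family element,
L~retro~(s) is the family's total element length overlapping the segment,
and d̄(k) is the chromosome-wide mean density of the key over non-excluded
segments. The correction term exists because plain subtraction would
systematically depress counts in element-rich segments even when the
family carries no enrichment at all; with occurrences placed uniformly at
random the whole adjustment is zero in expectation, which is the property
that pins the formula down (the tests verify it by simulation). Negative
adjusted counts are floored at zero. One known consequence: for keys with
essentially *no* background occurrences outside the family (in synthetic
genomes, the longest poly-A keys), the adjusted track is dominated by the
correction term and therefore tracks element coverage; interpretation of
masked correlations is only meaningful where background density exists.
d̄ uses non-excluded segments only, because excluded segments never enter
any correlation.

## The first-order Markov null

A correlation between an SSTR track and, say, G+C is only interesting if
it exceeds what nucleotide composition alone would produce. The null model
is a first-order Markov chain fitted *per segment* (initial distribution
from base frequencies; transition matrix from consecutive ACGT pair counts
with a pseudocount of 1 per cell, which keeps rows proper in extreme
segments). Fitting per segment preserves the G+C profile along the
chromosome, so the null retains composition-driven correlation and
destroys everything else.

For each of M = 100 realizations, every segment is re-simulated from its
model, scanned, and the resulting tracks are correlated with the fixed
feature track; the z-score is (r~emp~ − mean r~model~) / sd r~model~, with
the standard deviation always taken across realizations (the variance
across realizations, not across segments, is the chosen reading of
"variance of the modelled results"; the alternative is noted but not
implemented). Cells with zero null variance report a missing z rather than
a fabricated one, and |z| ≥ 3 is the two-sided significance flag — a
deliberately conservative, explicit choice. The closed-form expectation
`expected_sstr_counts()` (exact position marginals pi·T^t, automatic
breaks at the sequence ends) can replace the Monte-Carlo mean via
`analytic_mean = TRUE`; the variance always comes from simulation.

## What the synthetic generator emulates

`generate_genome()` writes the same four formats the readers consume,
plus a manifest of every planted object, and is byte-reproducible from its
seed. It emulates, per chromosome: a linear G+C gradient across segments
(default 0.35 to 0.55, the realistic isochore-scale range, with ±0.01
jitter); planted SSTR insertions whose per-segment Poisson rates couple
linearly to the segment's G+C (defaults: the four SS units coupled
positively and the four WW units negatively at lengths 2–4, 20 insertions
per segment at mid-G+C, coupling ±0.8 — strong enough that sign recovery
is unambiguous at 50 segments per chromosome); three gene classes written
as GenBank features with the class-defining children (mRNA/CDS, ncRNA,
pseudo-qualified misc_RNA); five retrotransposon families, where Alu-like
elements are built as monomer + poly-A linker + monomer + poly-A tail with
linker and tail lengths of 8–12 bp so the planted runs stay inside the
scannable range, placed on random strands (minus-strand copies carry
poly-T); N runs long enough to trip the 1% gap filter; and a central
centromere interval written to the exclusion BED.

Planted SSTRs overwrite background bases (coordinates stay stable) with
breaking flanks on both sides so each survives as a maximal run of exactly
the planted length; collisions are retried a bounded number of times and
then skipped with a log message. The background is i.i.d. at the target
G+C rather than Markov — deliberately, so that a first-order model fitted
to it is correct by construction and the planted runs are the only
non-null signal.

What the generator does *not* emulate: real repeat-family sequence models,
evolutionary divergence between element copies, isochore structure beyond
a smooth gradient, chromatin- or replication-associated composition
effects, and annotation noise. A passing pipeline on synthetic data
therefore demonstrates that the machinery recovers planted structure of
the stated kind — not that any particular biological conclusion holds on a
real genome.

## Numerical choices and scale

* Default scale is 2 chromosomes × 5 Mbp (50 segments of 100 kbp each):
  large enough for stable correlations (null |r| ≲ 3/√50 ≈ 0.42 per
  chromosome, halved by averaging), small enough that the full pipeline
  runs in about a minute. Test fixtures use 1 Mbp with 50 kbp segments;
  null-calibration experiments use 100 segments of 5 kbp, where z-score
  calibration is scale-free.
* Element-to-segment assignment is by start position, for SSTRs (≤ 12 bp,
  so boundary effects are negligible) and retrotransposon counts alike;
  the assignment is deterministic and order-independent.
* Zero-variance tracks give missing correlations, never 0; chromosome
  averages are means over the chromosomes where a cell is defined.
* Pearson r is clipped to [−1, 1] against floating-point drift; ties and
  degenerate inputs (empty annotation, empty repeat file, chromosome
  shorter than one segment) all produce empty-but-typed results rather
  than errors.
* Monte-Carlo comparisons in the tests floor the empirical standard error
  at the Poisson value sqrt(E)/sqrt(reps), so cells whose expected counts
  are far below one occurrence per run cannot divide by a zero variance
  estimate.

## Limitations

Only period-1 and period-2 units are scanned; approximate or interrupted
repeats are out of scope, as are repeats longer than 12 bp. GenBank
parent/child relations are inferred from interval overlap (flat files
carry no explicit links), so unusual nested annotations can misclassify a
gene. The chromosome average is unweighted, which on real karyotypes gives
short chromosomes the same vote as long ones. The significance machinery
reports per-cell z-scores without any multiple-testing adjustment across
the 176 × features grid; users testing many cells should correct
accordingly.
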