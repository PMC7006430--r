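---
title: "Censusing inverted duplications as putative dsRNA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Censusing inverted duplications as putative dsRNA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsRNAcensus)
```

## The problem

A transcript that contains two nearby, reversely oriented near-copies of the
same sequence can fold back on itself and form a long intramolecular RNA
duplex. Long, nearly perfect double-stranded RNA (dsRNA) resembles viral
replication intermediates and can trigger cytoplasmic innate-immunity sensors
such as MDA5; mobile-element proliferation constantly creates new such
configurations. `dsRNAcensus` quantifies this load: it detects duplicated
sequences within single transcript molecules, classifies them as **inverted**
(IDS — a putative dsRNA stem) or **tandem** (TDS — a structural null control
with the same duplication biology but no pairing potential), counts the
nucleotides involved, tests whether IDS are depleted relative to TDS, and
summarizes how strongly the surviving structures are expressed and A-to-I
edited.

## Detection model

Duplications are found by aligning each molecule (pre-mRNA and spliced mRNA
separately) against itself with a seed-and-extend local aligner:

* exact 11-mer seeds, match +1 / mismatch −2, affine gaps (open 5, extend 2),
  x-drop extension (default X = 25);
* identity = matching columns / aligned columns, gap columns included — the
  convention of 12-column tabular alignment output;
* hits are kept when aligned length > 40 **and** identity > 70% (both
  strict); an optional inter-arm gap cap (2000 bp in the sensitivity
  variant) drops pairs too far apart on the molecule, with the gap floored
  at 0 for overlapping (palindromic) arms, which are retained;
* opposite-strand hits are IDS, same-strand hits TDS; the trivial
  full-length self-identity is excluded, and mirror duplicates are collapsed
  to a canonical form with the leftmost arm first.

Alignment-engine internals are not the contract — the thresholds are. The
same filter, classification and canonicalization are applied to externally
produced hits via `parse_tabular_hits()` (e.g. `blastn -outfmt 6`), so any
aligner convention can be reproduced exactly. `sw_local()` and
`oracle_local_hits()` provide an exhaustive full-matrix Smith–Waterman
reference (a separate code path) against which the production engine is
validated in the test suite.

Same-strand self-alignment has a degenerate solution — a path that drifts
onto the main diagonal aligns every base with itself. The extension
therefore forbids cells on or beyond the main diagonal; short-period tandem
arrays are still found as off-diagonal alignments.

## Census and statistics

Arm intervals of each class are pooled per molecule and merged (book-ended
intervals merge, as with the standard interval-merge tool's defaults). Each
covered nucleotide is attributed to the **longest** hit covering it (ties:
higher identity, then leftmost), and binned by that hit's (length, identity).
"Region length" for binning is deliberately the attributed hit's aligned
length, not the merged-region span: merged regions mix hits, and the
attribution rule exists precisely to resolve multi-hit nucleotides. Bin
totals therefore sum exactly to the merged footprint, which the tests verify
against a brute-force per-base oracle.

Depletion is measured as the IDS fraction among all duplications,
#IDS/(#IDS+#TDS), tested against 0.5 with the one-sided exact binomial lower
tail. The tail is summed in log space (log-sum-exp over `dbinom(..., log =
TRUE)` terms), so p-values far below the double-precision underflow limit
remain usable through `log10_p`; values below 1e-100 are displayed as
"< 1e-100". The one-sided exact form was fixed by verifying that it
reproduces the published value for 4 IDS vs 258 TDS (2.6e-71) — a two-sided
variant is available behind the `alternative` argument. Above one million
tail terms, a normal approximation with continuity correction is used; its
log-p error is below 1% there (test-verified against R's own tail). No
multiple-testing correction is applied, matching the reference analysis.

## Expression and editing

The editing stage consumes per-adenosine pileups (contig, 0-based position,
reference base, A count, G count); read alignment, duplicate removal and
hyper-editing recovery happen upstream. Reads mapping ambiguously to both
arms of one duplex should be assigned to one arm at random by the upstream
wrapper, with a seeded RNG for reproducibility. Adenosines are taken from
the transcript orientation of the reference (a minus-strand gene's T
positions are its adenosines, with T→C mismatches mapped to A→G).

Per arm: coverage is the mean of (A+G) over adenosines, and the editing
index is ΣG / Σ(A+G) — the coverage-weighted mean of per-site editing
levels (an identity the tests assert). Two stated interpretive choices:
zero-coverage adenosines stay in the coverage-mean denominator (contributing
zero), and the per-structure "average inosines" defaults to the mean of the
two arms' index × n_adenosines, with a pooled-index variant exposed via
`inosine_average = "pooled"`.

Region expression is the arm's own adenosine coverage converted to FPKM —
not the host gene's FPKM, since an intronic arm can be expressed far below
its gene — using `coverage = FPKM × mapped_reads × effective_length / 1e9`,
where the effective length is the read length minus 5 bp trimmed from each
end (76 bp reads → 66 bp; 1.343e9 reads → 1 FPKM = 88.64×). Expression
filters require **both** arms strictly above the cutoff. Residual identity
subtracts the identity-equivalent of the inosine load,
`identity − 100 × avg_inosines / mean(arm lengths)` (floored at 0); a
structure driven below 96% is flagged "unwound".

## The synthetic transcriptome

Every stage is validated against generated data with exact ground truth.
Genes are alternating exon/intron blocks of uniform random sequence; by
default exons average ~200 bp and introns ~1 kb (compact vertebrate-like
models at desk scale), with Alu-sized arms (60–500 bp) planted in pairs at
Poisson-distributed counts per gene. Copies mutate by substitution only —
no indels — so the arm-pair identity recorded in the truth table is exact;
the divergence default spans 0–0.079 per base, giving expected pair
identities of 85–100% (two copies at rate d agree at a column with
probability (1−d)² + d²/3). Placement is uniform over inter-base positions,
redrawn when it would split a previously planted arm; the compartment
(both-arms-exonic vs at-least-one-arm-intronic) is recorded from final exon
coverage. Each gene draws its own RNG sub-stream from a stable hash of its
id, so output is byte-identical for a seed and independent of generation
order. Pileups are simulated directly (Poisson coverage, binomial G counts)
— no read-level FASTQ simulation, no splicing errors, no population
genetics.

What passing these tests shows — and does not. The generator's uniform
backbone has no low-complexity or repeat-family cross-talk, so it validates
detection, counting, statistics and editing arithmetic, not robustness to
real low-complexity sequence (the field handles that with masking, which
this engine does not implement). Real divergence includes indels; identity
ground truth under indels is ill-defined, which is why the generator
excludes them.

## Numerical choices and known limitations

* **Thresholds are strict** everywhere: > 40 bp, > 70%, > 300 bp, > 96%,
  FPKM > cutoff. Boundary hits drop.
* **Tie-breaks**: nucleotide attribution prefers longer, then more
  identical, then leftmost hits; structure de-overlap prefers higher
  identity, then longer, then leftmost.
* **Degenerate inputs**: sequences with more than 50% non-ACGT characters
  are rejected with a diagnostic; N never matches. Empty exon lists and
  zero-count tests are errors, not silent zeros.
* **Identity end-trimming bias.** A maximal-score local alignment trims
  mismatch-dense arm ends, so for short arms of modest identity the reported
  identity can exceed the planted arm-pair identity by more than one
  percentage point; the recovery test measures the effect on its ~200-duplex
  fixture and asserts the ±1 idealization anyway, so it flags this corner as
  a failure by design. The exhaustive Smith–Waterman reference reports the
  identical value — the bias belongs to the maximal-score quantity itself,
  which is also what standard alignment tools report, not to this engine.
* **The null-symmetry check is itself a binomial draw.** With 100
  replicates and an exact test of size ≲0.01, observing 2+ rejections has
  nontrivial probability under the null; an occasional failure of that
  check at a fresh seed is consistent with correct behavior.
* Problem sizes in the tests (100-gene transcriptomes, 8-gene null
  replicates, 2 kb oracle sequences) were chosen so the full suite exercises
  every contract at interactive time scales.

## Reproducing the headline statistics

`scripts/acceptance.R --seed 1 --out results/acceptance.json` recomputes the
four pooled mRNA depletion p-values from their published IDS/TDS counts with
`proportion_test()` and writes them as JSON; see the README for the exact
invocation and printed output.
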