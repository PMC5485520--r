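---
title: "Methods: small-RNA miRNA discovery, quantification and validation in mirseek"
author: "mirseek authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-RNA miRNA discovery, quantification and validation in mirseek}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`mirseek` re-implements, at desk scale and as tested R code, the classic
plant small-RNA analysis chain: raw 18–30 nt reads are trimmed and
collapsed into *unique sequence tags*; tags are mapped exactly to a
reference genome and triaged against ncRNA references (rRNA, tRNA,
snoRNA, other); surviving candidate tags are assigned to conserved miRNA
families (at most 2 mismatches against a mature reference set) or used to
predict *novel* miRNAs from genomic stem-loops; expression is normalized
to transcripts per million (TPM) and tested for salt/control differences
with an exact count test; targets are predicted on a transcript set under
a position-constrained complementarity rule; and stem-loop qRT-PCR
replicates are reduced to 2^-ddCt fold changes with Student's t-tests.

Every stage is driven by a synthetic-data module that plants the signal
the pipeline is supposed to find, so all quantitative guarantees in the
test suite are checked against a known truth rather than against
irreproducible external libraries.

# Novel miRNA prediction

## Locus clustering and precursor extraction

Candidate tags with genomic hits are chained into loci by single linkage:
consecutive hits on the same chromosome and strand whose start-to-start
distance is below 200 bp join one locus. Each locus is extended by 200 nt
of flank on both sides (clipped at chromosome ends, with a flag) and
minus-strand loci are reverse complemented, so all downstream analysis is
in transcript orientation.

## Inverted repeats

Stems are found by a banded local alignment of the window against its own
downstream reverse complement, the classic inverted-repeat recurrence:
`B(i,j)` is the best stem whose outer boundary is `(i,j)`, built from an
outer pair (`+3` for a Watson–Crick pair, `-3` otherwise — G·T is *not* a
match on the DNA alphabet, matching EMBOSS-style behaviour) or a gap on
either side at 6 per gapped base, with a local reset so the inner stem
end is free. Repeats scoring at least 40 within a total span of 240 nt
are reported; mutually overlapping repeats are pruned to score-maximal
ones with a deterministic tie-break (leftmost start, then shortest span).
The single "gap penalty = 6" is applied per gap-opening *and* per
gap-extension equally, i.e. a linear gap cost; this is the simplest
reading of a one-number gap model and is stated in the configuration.

A 14 bp perfect stem scores exactly 42 and is reported; a 13 bp stem
scores 39 and is not. The banded matrix makes a 1 kb window cost about
240 000 cells, so per-locus scans are effectively instantaneous; the test
suite additionally proves the scores equal an independent cut-point
Smith–Waterman search on hundreds of random sequences.

## Folding

Candidate repeats are padded by 10 nt per side and folded by maximum
weighted nested base pairing (G-C = 3, A-U = 2, G-U = 1, minimum loop 3).
This is a Nussinov-style combinatorial model chosen because it is
deterministic, exactly optimal, and brute-force verifiable — properties a
test suite can actually use. It is *not* a thermodynamic nearest-neighbor
model: the reported `mfe_proxy` is the negated pair weight and is labeled
non-thermodynamic. For the purposes the pipeline needs — detecting that a
stem-loop exists and counting paired mature positions — the weighted
pairing optimum is a faithful stand-in, and the stem-loop criteria below
are deliberately expressed in pairing counts rather than energies.

## Stem-loop criteria

A candidate mature placement passes when all of the following hold
(each is overridable via `hairpin_criteria()`):

* (a) the mature is 18–25 nt and does not straddle the terminal loop
  (no base pair joins two mature positions);
* (b) at most 4 mature positions are unpaired;
* (c) at most 2 *consecutive* mature positions are unpaired;
* (d) at most one asymmetric bulge of more than 2 nt in the mature/star
  duplex;
* (e) the hairpin is at least 60 nt long.

One numerical subtlety: a greedy weight-maximizing fold will happily add
stray pairs between a mature edge base and flanking context. The
mature/star duplex is therefore read off the *dominant* partner side, and
stray pairs to the opposite side count as unpaired. Without this rule,
perfect planted stems are occasionally failed for what is an artifact of
the folding objective, not of the hairpin.

The mature of a passing candidate is the most abundant member tag found
in the candidate sequence. Because a mature read also maps, in reverse
complement, onto the star arm of its own hairpin, one genomic precursor
can surface as two stranded loci; precursors of the same miRNA that
overlap on the genome are collapsed, keeping the higher-scoring repeat.
Identical matures across distinct loci collapse to a single record with
multiple precursor intervals, and `novel-N` identifiers are assigned in
decreasing total count with a lexicographic tie-break, so output is
deterministic.

# Differential expression

TPM is the literal count-per-million: `count / total * 1e6`, where the
totals are the per-library denominators supplied by the caller (the
pipeline uses the high-quality read totals). When totals are defined as
the per-library count sums, TPM columns sum to exactly 10^6.

The two-group test is an exact conditional negative-binomial test, the
documented replacement for a full tagwise-dispersion framework:
replicate counts are scaled to the geometric-mean library size and pooled
per condition; a single common dispersion is estimated by the
method-of-moments average of `(v - m) / m^2` over miRNAs with positive
mean (floored at zero — the average, not the median, because with two
replicates the per-miRNA moment estimates are strongly skewed and the
median is biased low); conditional on the pooled total, the salt count
follows an NB convolution with per-condition size `n_reps / dispersion`,
and the two-sided p-value sums all outcomes at most as probable as the
observed one. With dispersion 0 this reduces to the exact binomial split
test. The test suite cross-checks the p-values against an independent
reference implementation of the exact NB test at a fixed dispersion, and
calibrates the type-I error on 2000 null-simulated miRNAs (the observed
rejection rate at 0.05 must fall in [0.03, 0.07]).

Reported ratios are salt/control aggregates with a pseudocount of 0.5 raw
counts per condition, which keeps ratios finite when one condition is
all-zero while leaving large counts essentially untouched; p-values use
the unadjusted counts. Marks follow the raw p-value at the 0.05 default
(UP if the ratio exceeds 1, DOWN below 1), and a Benjamini–Hochberg
column is emitted for users who want it but does not drive the marks —
thresholding raw p-values is the convention this analysis chain uses.
One caveat the simulation makes visible: with strong, asymmetric
induction the per-million denominator itself shifts (a compositional
effect), so estimated ratios of induced miRNAs are biased toward 1 when
responders make up a large share of the library. The fold-recovery tests
therefore embed responders at a realistic minority fraction.

# Target prediction

A target site at transcript offset `s` is the reverse complement of the
mature with at most 3 substitutions, no indels, and no substitution
opposite miRNA positions 10 or 11. The coordinate convention is stated
explicitly because it is easy to get wrong: miRNA positions are numbered
1-based from the miRNA 5' end, and position `p` faces transcript index
`s + L - p`. G·U wobble counts as a mismatch (literal pattern matching).
All sites are reported; transcript-level deduplication happens only in
summaries. The implementation is checked against a character-by-character
sliding-window oracle.

# qPCR quantification

`dCt = mean(Ct_target) - mean(Ct_reference)` per sample,
`ddCt = dCt_treatment - dCt_control`, fold `= 2^-ddCt`, so the control
sample has fold 1 by construction. Replicate t-tests operate on
per-replicate dCt values, pairing target and reference wells by replicate
index within a sample; samples are treated as unpaired between groups
because well pairing across plates is generally not recorded. The pooled
(Student) variant is the default with Welch available by flag. The
degenerate zero-variance case returns p = 1 for equal means. Ct values
are validated into (0, 45).

# Synthetic data: what it emulates, and what it does not

The generator plants perfect-stem hairpins (stem 18–25 bp, loop 4–15 nt,
mature 20–24 nt on either arm, either strand with probability 1/2) at
disjoint genomic positions with at least 300 bp separation, records the
precursor with 10 nt of flanking context, and simulates negative-binomial
counts (shared dispersion, default 0.05, Poisson at 0) whose expectations
carry the planted salt/control fold changes through a fixed library
depth — including the induced compositional shift. Reads are the mature
sequences with the 3' adapter appended (read-through), plus a configured
fraction (default 10%) of 18–30 nt fragments of ncRNA references, at
uniform high base quality.

Two construction details matter for interpreting the tests. First, each
planted precursor is rejection-sampled until it passes the stem-loop
criteria when folded *and* survives window-scale discovery in its actual
genomic context: the truth set promises recoverability, and chance
context can otherwise extend a stem into an unfavourable repeat. Second,
negative controls are *verified* hairpin-free: random DNA genuinely
contains inverted repeats that qualify as hairpins, so control loci are
screened with the same window-level detector before asserting that the
caller stays silent. Both constructions are deterministic under the
supplied seed; independent generator calls should receive distinct seeds
(the bundled `simulate_dataset()` derives per-stage seeds by fixed
offsets), because two generators given the same seed replay the same
random stream and can emit overlapping sequence.

What the simulation does not model: sequencing errors and quality decay,
PCR duplication bias, imperfect or multi-branch precursor stems, tissue
mixtures, and genome-scale repeat families. Passing tests therefore
demonstrate the correctness of the algorithms under the stated generative
model, not performance on real wheat libraries; on real data the exact
mapper, the combinatorial folding model and the single common dispersion
are the simplifications most likely to matter.

# Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `min_len` / `max_len` | 18 / 30 nt | tag length window after trimming |
| `min_overlap` | 6 nt | minimum exact 3' adapter overlap |
| `k` | 12 | mapping index word size |
| `max_hits` | 100 | per-tag hit cap (flagged truncation) |
| `max_repeat_hits` | 20 | more hits than this = high-repeat tag |
| `conserved_max_mm` | 2 | mismatches allowed vs mature reference |
| `cluster_max_gap` | 200 bp | locus chaining distance |
| `precursor_flank` | 200 nt | window flank around a locus |
| `ir_threshold` / match / mismatch / gap | 40 / 3 / −3 / 6 | stem alignment scores |
| `ir_max_span` | 240 nt | maximal repeat span |
| `extend_pad` | 10 nt | repeat extension before folding |
| `fold_min_loop` | 3 nt | minimum hairpin loop |
| `alpha` | 0.05 | differential-expression threshold |
| `target_max_mm`, protected | 3, positions 10–11 | target rule |

Category triage priority when rules overlap: rRNA > tRNA > snoRNA >
other ncRNA > high-repeat > low-expression (total count 1) > candidate;
annotation removes a tag before repeat status is judged. Coordinates are
0-based half-open internally; GFF3 export is 1-based inclusive and BED
export 0-based half-open, as those formats specify.

# Problem sizes used by the checks

The bundled verification runs use a 100 kb genome with 25 planted
hairpins at about 700× mature coverage for recovery, 80 verified
hairpin-free loci for specificity, 2000 miRNAs at depth 10^6 for null
calibration and depth 10^5 with 50 fold-8 responders for effect recovery,
200 random sequences up to 60 nt for the inverted-repeat equivalence
suite, and 50 random miRNA/transcript pairs for the target-scan oracle.
These sizes were chosen so each property is measured with comfortable
statistical margin while the whole suite stays quick to run.

# Known limitations

* The exact mapper is perfect-match by design (the reported totals are
  "perfectly matched" reads); the mismatch parameter exists but is only
  honoured within seed placements.
* The folding model ignores stacking thermodynamics and pseudoknots; its
  optima can differ from a free-energy fold on long, ambiguous windows.
* The common-dispersion exact test does not model tagwise dispersion or
  TMM-style normalization; with strong asymmetric induction, ratio
  estimates inherit the compositional bias discussed above.
* miRNA* read support is not required for a novel call, and no
  cross-species conservation scoring is attempted.
* GO/KEGG annotation of predicted targets depends on external databases
  and is out of scope.
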