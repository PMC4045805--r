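---
title: "Tracing the processing fidelity of an artificial miRNA precursor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing the processing fidelity of an artificial miRNA precursor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amiRtrace)
```

## The question

Artificial microRNAs (amiRNAs) are 21-nt guides substituted into a natural
miRNA precursor backbone to silence chosen genes. The miR319a backbone is
the most widely used in plants, and it is unusual: its long fold-back is
matured *loop to base* — DICER-LIKE 1 first cuts below the terminal loop and
then cuts three more times at roughly 21-nt intervals toward the base, so
the hairpin releases several small-RNA duplexes, not just the intended
amiRNA/amiRNA\* pair. `amiRtrace` quantifies how faithful that maturation
is from three kinds of evidence: a deep-sequenced small RNA library, 5'-RACE
fragments of cleaved targets and processing intermediates, and the
thermodynamics of guide/target pairing. The package also ships a seeded
simulator of the whole generative process, so every analysis stage can be
validated end-to-end without any sequencing data.

## Blocks: where on the hairpin did a read come from?

Reads that map perfectly to the precursor are grouped into *blocks*, named
after the miR319-family convention: `B1`/`B1*` is the amiRNA/amiRNA\* duplex
at the hairpin base, `B2`/`B2*` the loop-proximal duplex, `B3`/`B3*` the
regions in between. Each block has a *representative* (its most abundant
read; ties go to the longer, then lexicographically smaller sequence).
Membership uses an overlap/extension rule on precursor coordinates:

* overlap with the representative interval strictly greater than 15 nt
  (operationalized as >= 16, the literal reading), and
* no more than 6 nt of extension beyond the representative at either end.

When several blocks qualify, the largest overlap wins and ties go to the
left-most block. A seventh category, `B3+`, is evaluated *before* the
generic rule: reads that start in `B3` but whose 3' ends stretch into the
middle of `B1` would otherwise be swallowed by `B1`'s extension allowance.
Proportions are computed over read counts, with the denominator defaulting
to all precursor-matched reads (a flag restricts it to assigned reads only).

The correctness of `assign_block()` is established against a brute-force
oracle that evaluates the predicate directly for every placement of every
18–32-nt read on a 200-nt toy precursor.

## 3'-tailed variants: 5GMC + tail

A class of reads fails perfect mapping because of non-templated 3'
nucleotides. `decompose_tail()` splits such a read into its *5' genome-
matched component* (5GMC) — the longest prefix occurring exactly in the
precursor, left-most occurrence on ties — and the remaining 1–3-nt *tail*.
Maximality of the prefix guarantees the first tail base differs from the
next templated base, so the split is unique; the one undecidable case is a
read running off the precursor 3' terminus, where appended bases are, by
convention, tail. Reads whose 5GMC would be shorter than 17 nt or whose
tail would exceed 3 nt are reported as `unexplained`, never silently
dropped: the 17/3 bounds are empirical observations encoded as defaults,
not laws. Tail composition is read-weighted and reported in the RNA
alphabet (T counted as U), matching how such tables are printed (DNA) and
discussed (RNA).

Running the packaged 27-variant amiRchs1 table through decomposition and
block assignment yields per-block tailed-read totals of 116 (`B1`),
142 (`B1*`), 311 (`B2`) and 12 (`B3+`); the 11-variant phy-miR319a table
yields 501 (`B1`) and 23 (`B1*`) with a tail composition of
84% U, 14% C, 2% G at whole-percent rounding. These equalities are asserted
in the test suite, with the composition verified beforehand by an
independent hand tally over the printed rows (604 U, 100 C, 12 G of 716
weighted tail nucleotides).

## Precursor scaffolds (and why they are synthetic)

The full amiRchs1 precursor sequence was never published. The packaged
`amirchs1_scaffold()` therefore *reconstructs* the analysable context in
code: the 5' arm from the overlap-PCR primers (reverse complement of primer
IV merged with primer III over their 25-nt overlap), the 3' arm from the
reverse complement of primer II merged with primer I, and the
backbone-derived `B2`/`B3` segments from the sequenced tailed reads
themselves, which fix the junction running from `B2` through `B3` into
`B1`. The star-side `B2*`/`B3*` segments and the terminal loop carry no
reads and are synthetic filler, chosen not to collide with any read prefix.
The phy-miR319a scaffold is built the same way from its printed 5GMCs.
Every result above is a property of the read/junction context these
scaffolds preserve, not of the invented filler; the fixture tests verify
that each block representative equals the scaffold at its stated interval
and that all 38 printed variants decompose with zero unexplained reads.

## Cleavage sites and processing intermediates

A cleavage position is encoded as the first nucleotide of the downstream
fragment — the observable a 5'-RACE adapter ligates to. RACE fragments are
anchored by an exact match of their 5'-terminal 20-mer (configurable;
unmatched fragments are counted as non-specific amplification products).
For a guide of length $L$ aligned at target offset $o$, guide position $p$
pairs target position $o + L - p$, so canonical slicer cleavage between the
bases opposite guide positions 10 and 11 predicts a downstream fragment
starting at $o + L - 10$. `classify_sites()` partitions clone counts into
at/upstream/downstream of that position. On the hairpin itself,
`intermediate_profile()` orders sites by distance from the annotated loop,
reports successive spacings, flags those outside 20–23 nt, and calls the
direction loop-to-base when all sites lie on one arm.

## Duplex thermodynamics and target criteria

`align_duplex()` performs the gap-free antiparallel pairing used by plant
target-search tools ("direction: reverse, no gaps"), classifying each guide
position as WC, GU wobble, or mismatch. The free-energy model is a
nearest-neighbor sum:

$$\Delta G = \Delta G_{init} + \sum_{\text{stacks}} \Delta G_{NN}
  + n_{MM}\,\delta_{MM} + \sum_{\text{terminal A:U/G:U}} 0.50$$

with the published Turner 2004 stacked-pair free energies at 37 °C
(including G:U wobbles), duplex initiation +4.10 kcal/mol, and a terminal
A:U/G:U penalty of +0.50 kcal/mol. Each mismatched position is charged a
flat internal-loop-like penalty $\delta_{MM} = 3.0$ kcal/mol; bulges are not
modelled because the alignment is gap-free. The penalty was set above the
worst-case stabilization two lost G:U/G:U stacks could represent
(2 × 1.3 kcal/mol), which makes the model provably monotone: adding a
mismatch can never lower $\Delta G$. That monotonicity, and the identity
`energy_fraction(perfect) == 100`, are asserted as properties.

Two deliberate choices here:

* **Temperature.** The reference scale is 37 °C. The 21-nt amiRchs1 guide
  bound to its perfect complement scores −37.50 kcal/mol on this table; the
  value printed for the same duplex in the originating study was −37.02
  kcal/mol, a 0.48 kcal/mol (1.3%) offset attributable to the parameter
  generation of the web tool used there (older parameter sets and dangling-
  end conventions span −37.0 to −37.6 for this duplex). We report, not
  hide, this residual. A `temperature` argument exists, but since no
  enthalpy table is packaged, non-reference temperatures attach an explicit
  limitation note instead of silently rescaling; a 23 °C rescaling by
  ΔH − TΔS would shift this duplex to about −44 kcal/mol, far from any
  printed value, which is why the reference scale is the default.
* **G:U handling.** Wobbles pair for energy and do not count as mismatches
  in the positional criteria (they are reported separately); a strict mode
  counts them as mismatches. This mirrors how wobble and mismatch are
  treated as distinct categories in target descriptions while the classical
  criteria speak only of "mismatch".

Design-rule checking (`check_design_rules()`) covers the classical backbone
rules: 21 nt, U at position 1, A at position 10, no target mismatch at
positions 2 and 12, and 5' instability. The study that introduced these
rules never operationalized "5' instability"; here it is the 5-position
duplex window at the guide 5' end binding more weakly (higher ΔG, stacks
only) than the 3'-end window — the window length 5 is a documented default.
Target scanning (`scan_targets()`) evaluates every offset of every
transcript against the empirical criteria — no mismatch at positions 10–11,
at most one in 2–12, at most 4 downstream of 13 with no more than two in a
row, and at least 70% of the perfect-complement energy — and is checked
against an exhaustive per-offset oracle.

## What the simulator emulates — and what it does not

`simulate_processing()` draws cut spacings of 21 nt plus a jitter on
{−1, 0, +1, +2} (probabilities 0.15/0.55/0.20/0.10, a scenario chosen once
to put most mass on 21 while covering the observed 20–23-nt range),
excises duplex partners with a 2-nt 3' overhang, samples reads by
multinomial block proportions, appends 1–3-nt tails with a configurable
nucleotide spectrum (default 45% U / 28% A / 16% C / 11% G, the
uridine-dominated spectrum reported for amiRNA-derived tails), and
generates RACE fragments with a configurable canonical-end accuracy.
Default block proportions in examples (e.g. 43% `B1`) echo the reported
dominance of the intended amiRNA without claiming the unpublished exact
figure bar heights.

Two simulator conventions matter for interpretation. First, the 5' arm
products are placed by mirror symmetry about the loop, which is only an
approximation of true base-pairing geometry on an asymmetric hairpin —
adequate for generating block-structured libraries, not for structure
prediction. Second, by default the first tail base is resampled when it
equals the next templated base ("anti-ambiguity" mode), which makes
decomposition recovery exact and testable; the realistic mode admits
ambiguous tails, for which recall below 100% is expected because an
ambiguous tail base is indistinguishable from template. Recovery tests
therefore compare observed tail composition against the generator's
*conditional* expectation, not naively against the configured spectrum.

What passing simulation tests show is that the analysis inverts the
generative model it encodes — block proportions, tail spectra, spacing and
cleavage accuracy are recovered within 3σ sampling tolerances at depths of
10^4–10^5 (problem sizes chosen to make sampling error, not runtime, the
binding constraint). What they do not show: robustness to sequencing error
beyond the quality filter, to genomic multi-mapping outside the precursor,
or to RNA-structure-dependent processing heterogeneity — real libraries
contain all three.

## Numerical and interface conventions

Coordinates are 1-based inclusive everywhere; antisense hits are reported
on the sense strand. Sequences are held internally as DNA (printed tables
use DNA) and converted to RNA where the field's prose does. The quality
rule "Q < 20" is ambiguous between per-base and mean; the default is mean
Phred with a `min` mode available. Reads lacking a 3' adapter are kept and
flagged, since discarding them is a policy, not a fact, of the upstream
kits. The abundance floor "more than five reads" is operationalized as
count >= 5 because the printed variant tables contain 5-read rows.
Multi-hit reads count fully at every hit so tallies stay integral. All
randomness flows through explicit seeds, and the simulator restores the
global RNG state it found.

## Orchestration

`run_pipeline()` chains the stages and writes the report tables
(size distribution, precursor hits, block assignments and proportions,
tailed-variant tables, tail composition, optional cleavage classification
and scan hits) plus a run log; reruns with the same configuration and seed
are byte-identical. The package deliberately exposes its functionality as
an R API plus this vignette rather than a shell entry point: the intended
user is an analyst in an R session, and the pipeline function is the
single-command equivalent of a CLI `run` subcommand.

## Known limitations

* The precursor scaffolds are reconstructions; coordinates on them are
  internally consistent but are not positions on the true plasmid-derived
  precursor.
* The energy model has no enthalpy term, no bulges, no coaxial or
  dangling-end terms; it is a ranking and criteria-gating tool, not a
  replacement for partition-function cofolding.
* Deep-library scale claims (raw read counts in the millions, proportions
  measured on full libraries, EST-database target counts) are outside what
  desk-scale fixtures can reproduce and are not asserted anywhere.
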