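---
title: "Methods: comparative mitogenome characterization with mitochar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative mitogenome characterization with mitochar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitochar)
library(dplyr)
```

## Scope and data model

`mitochar` computes the descriptive and evolutionary statistics that make up
a standard comparative characterization of an animal mitochondrial genome:
partitioned base composition with AT/GC strand skews, codon usage and RSCU
under the vertebrate mitochondrial code, a circular gene-layout ledger of
intergenic spacers (IGS) and overlaps, control-region domain segmentation
with motif scanning, Nei–Gojobori (1986) Ka/Ks, and distance-based
phylogenetics with strict-clock node dating.

The central container is `annotated_genome()`: a (usually circular)
sequence plus a feature tibble with 1-based inclusive coordinates, exactly
as annotation tables print them. Strands are `H` (heavy, deposited) and `L`
(light); `extract_feature_sequence()` returns the coding strand (L-strand
features reverse complemented) and supports origin-wrapping features on
circular genomes. All user-facing results are tibbles so analyses chain
with the pipe; trees are `ape::phylo` objects, the field's standard
container.

A 38-feature ring-necked pheasant (*Phasianus colchicus*) annotation and its
published per-partition composition ship as plain-text fixtures
(`pheasant_feature_table()`, `pheasant_composition_table()`); they double as
the default gene-order template of the synthetic generator.

## Composition and skews

Percentages are computed over non-N residues only; N is excluded from both
numerator and denominator. The skews are

$$\mathrm{AT\ skew} = \frac{A - T}{A + T}, \qquad
  \mathrm{GC\ skew} = \frac{G - C}{G + C},$$

computed on counts but invariant to using percentages (a ratio). A zero
denominator yields `NA` (an undefined-skew sentinel), not an error.

`partition_report()` mirrors the conventional table layout: whole genome,
concatenated PCGs, PCG codon positions 1–3, tRNA and rRNA concatenations,
individual rRNAs, control region, and (when segmented) CR domains I–III.
Two conventions needed fixing because published tables rarely state them:

* **Strand policy.** Per-gene and concatenated partitions default to the
  coding (mRNA-sense) strand, so L-strand genes such as ND6 are reverse
  complemented before counting; the whole-genome row always uses the
  deposited H strand. `strand_policy = "as_deposited"` switches everything
  to the H strand.
* **Codon-position slices** drop incomplete trailing codons
  (`floor(length/3)` codons per gene).

Reports round percentages to 2 decimals and skews to 4 — the precision of
published tables — at the report layer only; raw values are kept
internally. Note that recomputing a skew from percentages that were
themselves rounded to 2 decimals can move the 4th decimal of the skew by
one unit relative to a count-based computation; the package's tests treat
that last-digit wobble as agreement.

## Gene layout: the adjacency ledger

For features sorted by start, `adjacency_ledger()` reports for each
adjacent ordered pair the signed spacer

$$\mathrm{igs} = \mathrm{start}_{down} - \mathrm{end}_{up} - 1$$

on deposited-strand coordinates, with the closing last→first pair wrapped
modulo the genome length. Positive values are gaps, negative values
overlaps, and a shared single boundary (end = next start) gives −1, as in
the tRNA-Phe/12S rows of avian tables. The ledger deliberately mixes
strands in one coordinate frame, again following the printed convention.
On any circular genome whose features do not doubly cover a position the
ledger satisfies the exact closure identity

$$\sum \mathrm{length}_i + \sum \mathrm{igs}_i = L.$$

Overlap motifs (e.g. the conserved 10-bp ATP8/ATP6 and 7-bp ND4L/ND4
overlaps) are extracted 5′→3′ on the deposited strand.

## Codon usage and RSCU

The vertebrate mitochondrial code (NCBI table 2) is used throughout: ATA is
Met, TGA is Trp, and AGA/AGG are termination codons — required for the AGG
stop seen on avian COI. Start codons are {ATG, GTG}. `codon_tally()` counts
every complete codon including complete terminators; 1–2 nt incomplete
tails (stops completed by polyadenylation, printed `T--`/`TA-`) are
excluded, so the total equals $\sum \lfloor \mathrm{length}/3 \rfloor$.
This convention reproduces the published total of 3796 codons for the 13
pheasant PCGs, including genes like ND3 whose printed length (352) is not a
multiple of 3 — the floor rule plus a recorded tail, no special case.

RSCU is count divided by the uniform-usage expectation within the
synonymous family, $\mathrm{RSCU}(c) = n_c / (\bar n_{fam})$; families sum
to their size whenever used. Leucine splits into CTN (`Leu`) and TTR
(`Leu2`), serine into TCN (`Ser`) and AGY (`Ser2`), matching the usual
RSCU figure axes; stops are excluded from families and reported separately.

## Control region

`segment_domains()` anchors the three-domain organization of the vertebrate
control region on recognizable motifs rather than on alignment to external
references: domain I runs from the CR start to the end of the best hit of
the I/II anchor (default: the 25-nt CSB1-like block), domain III starts at
the II/III anchor when configured and otherwise at the start of the poly-C
run (the OH-adjacent landmark, longest C homopolymer ≥ 6, leftmost on
ties), and domain II is everything between. The three domains always tile
the CR exactly. Published avian coordinates place the poly-C run a few
nucleotides before the stated II/III boundary; since no second anchor is
printed, the package resolves the ambiguity by starting domain III at the
poly-C run and reports are flagged accordingly by the recorded anchor
positions.

`find_motif()` is a plain ungapped sliding-window scan with identity
$= 100 \times$ matches/|motif|, hits sorted by identity then start. Only
the two motifs actually printed for the pheasant (goose hairpin, CSB1-like
block) ship as defaults; ETAS1/ETAS2 and box C–F consensus sequences vary
by lineage and are user-supplied config, which is why the package does not
attempt to reproduce published ETAS similarity percentages.

## Ka/Ks (NG86)

`ng86_kaks()` implements the Nei–Gojobori (1986) counting method from
scratch:

1. **Sites.** Each codon position contributes the fraction of its
   single-nucleotide mutants that are synonymous, with stop-creating
   mutants excluded from the denominator; $N + S = 3 \times$ codons.
   Site counts of the two sequences are averaged.
2. **Differences.** For each differing codon pair, all orderings of the
   changed positions are enumerated with equal weight; orderings passing
   through a stop codon are discarded. If every ordering is blocked (e.g.
   AAA↔TGA under this code, where both intermediates TAA and AGA are
   stops), the pair contributes its raw per-position differences
   classified by direct single-position synonymy on the first codon —
   a documented, unit-tested fallback.
3. **Correction.** $p_N = N_d/N$ and $p_S = S_d/S$ are Jukes–Cantor
   corrected, $d = -\tfrac34 \ln(1 - \tfrac43 p)$; the ratio is undefined
   when $K_s = 0$ or a proportion saturates ($p \ge 3/4$).

Ratios below 1 are called purifying, above 1 positive, and within a
configurable band |ratio − 1| < 0.05 neutral (reporting only; no
significance test is attached). Codons containing gaps or ambiguity
characters are dropped pairwise. The whole computation runs off
precomputed 64×64 lookup tables, so genome-scale comparisons are cheap,
and the tables are verified against exhaustive pathway enumeration in the
test suite.

## Distances, trees, dating

`pairwise_distance()` provides the p-distance and the Kimura two-parameter
distance $d = -\tfrac12\ln\big((1-2P-Q)\sqrt{1-2Q}\big)$ with transitions
defined as A↔G and C↔T; sites with N or gaps in either sequence are
excluded pairwise, and a non-positive log argument raises a saturation
error rather than returning a number.

Tree construction delegates to the standard implementations — `ape::nj`
(Saitou–Nei Q-criterion, exact on additive matrices) and average-linkage
`stats::hclust` for UPGMA — behind `tree_build()`; negative NJ branch
lengths are clamped to zero with the deficit moved to the sibling branch
(toggleable). Monophyly testing roots on a supplied outgroup first.

`strict_clock_dates()` replaces full Bayesian dating with the strict-clock
linear model it reduces to on an ultrametric tree: node depth is
proportional to age, the substitution rate is the least-squares fit of
calibration-node depth against calibration age through the origin
(interval calibrations collapsed to midpoints, e.g. a 7.1–9.6 Mya split
used at 8.35), and every node age is depth/rate. With one calibration this
is exact scaling; mutually inconsistent calibrations trigger a warning
with relative residuals. Ages are invariant to rescaling all branch
lengths, and dating is intended for ultrametric (UPGMA) trees — NJ trees
are for topology only. This is a deliberate simplification, not a
reimplementation of MCMC dating, which is why absolute published node ages
are out of scope.

## Synthetic data: what it emulates, and what it does not

`generate_genome()` emits a circular genome realizing the standard avian
38-feature order with known ground truth. Choices worth recording:

* **Composition targeting** fills each feature on its coding strand by an
  exact-count draw (largest-remainder integer counts, shuffled), debiting
  the residues of any planted motif from the target before filling. The
  realized composition of a partition therefore matches its target to
  rounding, comfortably inside the ±1.5 percentage-point tolerance the
  tests assert. Default targets are the published per-partition values
  for the pheasant (PCG, tRNA, rRNA, CR-domain-wise).
* **Planting order**: features are filled first, then PCG start/stop
  codons, then overlap motifs — so an overlapping downstream neighbour
  cannot erase an upstream gene's planted stop. Incomplete stops are
  planted as a non-stop final codon (`ACA`) plus the printed 1–2 nt tail.
  The planted overlap motifs are consistent with the start/stop plan by
  construction (ATGAACCTAA carries ATP6's ATG and ATP8's TAA; ATGCTAA
  carries ND4's ATG and ND4L's TAA).
* The planted poly-C run is flanked by non-C guard bases so background
  fill cannot extend it and shift the II/III boundary.
* One private, explicitly seeded RNG stream per generator call; the
  caller's `.Random.seed` is untouched and equal seeds give byte-identical
  output.

`evolve_codon_pair()` evolves two lineages from a stop-free ancestor by
sequential proposal–acceptance: random codon/position/base (transitions
weighted κ), stop-creating proposals rejected, synonymous proposals
accepted with probability min(1, 1/ω) and non-synonymous with min(1, ω).
For ω ≤ 1 this is the textbook "accept non-synonymous with probability ω"
scheme; the synonymous thinning extension makes ω > 1 (positive selection)
representable, which a pure acceptance scheme cannot reach — needed for
monotone recovery checks across ω ∈ {0.1, 0.5, 1, 2}. `t` is the expected
number of proposals per codon per lineage; realized substitution counts
are logged as truth so recovery tests compare against what actually
happened, not against asymptotics. Recovery simulations use κ = 1 because
the unweighted NG86 site counts are only unbiased without transition bias;
this is a property of the estimator, not of the generator.

`simulate_alignment_on_tree()` evolves i.i.d. sites under K80 down a tree
using the closed-form transition probabilities per branch.

What the generators do **not** emulate: among-site rate variation,
compositional heterogeneity across lineages, indels, tandem repeats, and
real tRNA/rRNA secondary structure. Passing tests therefore demonstrate
algorithmic correctness on data matching the stated model, not robustness
to every feature of real mitogenomes.

## Problem sizes and numerical choices

The test suite runs the heavier checks at sizes chosen to make sampling
noise negligible while keeping a full run under a minute on one core:
ω-recovery at 10,000 codons × 20 seeds (mean within 10% of the generating
ω), neighbor-joining topology recovery on 100 seeded 4-taxon replicates of
1,000 K2P-simulated sites (≥95% required; 100% observed), strict-clock age
recovery to 1e−9 (machine precision observed), and ledger-closure/RSCU
invariants over 100 generated genomes. Ties in motif identity break to the
smaller start; NJ ties follow `ape::nj`. The `scripts/acceptance.R` script
recomputes the same quantities end to end and writes them as JSON.

## Known limitations

* Ka/Ks is NG86 only; no maximum-likelihood or model-averaged estimator,
  no sliding windows, no significance test on the purifying-selection
  call.
* The control-region segmentation depends on configured anchors; genomes
  whose CSB1-like block diverges below the identity threshold produce an
  explicit segmentation-failed error rather than a guess.
* Strict-clock dating assumes rate constancy and an ultrametric input;
  it reports calibration residuals but does not model calibration
  uncertainty.
* De-novo annotation, alignment, bootstrap support, and Bayesian
  inference are out of scope; annotations and alignments are inputs.
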