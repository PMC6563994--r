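---
title: "Methods and design notes for troutmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for troutmir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the scientific model behind each stage of the
pipeline, the parameters that matter, and the design choices made where
the methodology left the design genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The annotation problem

Small RNA-seq of a non-model fish cannot be annotated against a curated
species-specific miRNA registry. The pipeline therefore combines three
evidence channels per unique tag: (i) matches to mature miRNA reference
sets from a *specific* species (here the zebrafish-style `dre-` set) and
from *selected* related species; (ii) exact genome placement of the
reference ("gene placement") and of the tag itself; (iii) structural
plausibility of the surrounding locus as a precursor hairpin. The
decision tree yields the labels gp1a–gp4b documented in `?classify`;
`gp1c` is a secondary multi-locus flag rather than a partition label, so
read-count tables always sum to the mappable total.

Contaminant screening (mRNA → other RNA families → repeats, first match
wins) precedes miRNA matching, so a tag matching both an rRNA fragment
and a mature miRNA is counted as contaminant. That ordering follows the
screen-first convention of vendor pre-filters; its consequence is a
conservative miRNA count.

### Matching tolerances

Database matching is 5'-anchored with at most one mismatch in positions
1–16 (bowtie seed semantics), exact match beyond position 16, and a 3'
length difference of at most 2 nt. The 3' tolerance mirrors the dominant
mode of isomiR variation and matches the simulator's jitter model; the
exact-beyond-16 rule is a design choice where the underlying convention
is silent, kept strict so that chance cross-species hits do not inflate
gp1/gp2 counts.

## The hairpin model

Folding is a dynamic program over non-crossing pairs restricted to a
*single stem-loop* topology — one nested run of pairs, bulges and
interior loops allowed, multibranch structures excluded. The restriction
is deliberate: all eleven precursor criteria presuppose one stem and one
loop, and admitting multiloops would only create structures the criteria
cannot score.

The energy model is additive:

* consecutive pairs contribute the shipped nearest-neighbor stack term
  (`stack_energy_table()`, kcal/mol at 37 °C). Watson-Crick/Watson-Crick
  stacks carry the standard unified values; stacks involving G:U wobbles
  use a condensed approximation (−1.3 single wobble, −0.5 double) rather
  than the full context-dependent tables — adequate because every
  consumer of the energy is a threshold (−15 for precursors, −20 for
  duplexes) far from the approximation error;
* the terminal loop costs a constant +3.0, and each bulge/interior loop
  costs +3.0 plus 0.5 per unpaired nucleotide, capped at 30 nt per strand
  per interruption (`fold_params()`). The linear per-nucleotide term
  keeps the optimizer from bridging large unrelated segments through
  bulges, which in turn protects the ≤ 12 nt stem-bulge criterion from
  being violated by spurious stem extensions.

Windows are mature ± 80 nt flanks, truncated silently (but recorded) at
contig ends. The DP is implemented in C++ (`src/fold.cpp`); the test
suite checks it against an independently coded exhaustive-recursion
oracle on windows up to 40 nt, where the two are provably equivalent
searches of the same structure space, and a perfect inverted repeat is
checked against its hand-summed stack energies.

"Errors" in criteria 7 and 9 are defined as unpaired mature positions; a
"biased bulge" (criterion 8) is an interruption with unpaired nucleotides
on only one strand; a bulge's size is the larger of its two unpaired
runs. These terms have no fixed field-wide definition; the choices are
isolated inside `hairpin_criteria()` so they can be swapped without
touching the decision tree.

## Differential expression

Counts are normalized with literal median-of-ratios size factors
(median over all-nonzero miRNAs of count over per-miRNA geometric mean),
rescaled to geometric mean 1; when no miRNA is nonzero everywhere the
stage falls back to total-count scaling with a warning. Testing is
Welch's t on log2(normalized + 0.5), two-sided, called at raw p < 0.05
with BH-adjusted values reported alongside — the published analysis used
raw p, and the adjusted column is provided for transparency. An optional
negative-binomial Wald variant delegates to DESeq2.

Two calibration facts, both measured by the test suite, are worth
knowing:

* the Welch-on-log-counts test is *conservative* at n = 3 per group
  (rejection rate ≈ 0.03 at nominal 0.05 under the negative-binomial
  null with dispersion 0.1) — a property of the prescribed method, not a
  defect of the implementation;
* depth invariance (scaling one sample's counts by c leaving results
  unchanged) is exact except for the pseudocount's interaction with the
  geometric-mean-1 anchoring, which rescales normalized counts globally
  by c^(1/n); significance calls and directions are unaffected and the
  numerical effect is ~10⁻⁴ at realistic depths.

Heat-map ordering uses average-linkage clustering on Euclidean distances
of row-z-scored log2 counts, with rows pre-sorted by id so equal
distances resolve deterministically.

## Target prediction

The duplex scanner aligns the miRNA read 3'→5' against sliding UTR
windows (window width = miRNA length + 10, stride 1) with an affine-gap
local DP. Default residue scores (+5 match, +1 G:U, −3 mismatch, −9/−4
gaps, positions 2–8 scaled ×4) follow the published miRanda convention;
only the acceptance thresholds S > 140 and ΔG < −20 kcal/mol are fixed
by the method, and both are strict inequalities. ΔG is computed from the
*alignment trace itself* (stacks over consecutive paired positions,
penalties for interruptions), not from an independent fold, so S and ΔG
always describe the same physical duplex. Overlapping passing windows
are merged keeping the max-S representative, so one physical site is
never double-counted.

## Enrichment

One-sided hypergeometric over-representation per GO term against the
genome background, BH across tested terms; terms with fewer than 2
background genes are excluded as uninformative (configurable). Discrete
one-sided p-values are super-uniform by construction, so the null
calibration test checks (a) rejection ≤ nominal at several levels and
(b) exact uniformity of the randomized-PIT transform, rather than a raw
KS test that would reject any discrete test.

## qPCR validation statistics

Standard curves are OLS fits of Cq on log10 dilution with efficiency
E = (10^(−1/slope) − 1)·100, reported to one decimal and flagged outside
90–110 % or at R² ≤ 0.98. NORMA-Gene normalization minimizes, over
per-sample multiplicative factors, the summed squared deviation of
log-expression from each gene's cross-sample mean; the closed-form
solution (each factor a geometric mean of within-gene ratios) is anchored
to geometric mean 1, and the test suite cross-checks it against a
numerical optimizer of the same objective. Column scaling by c is undone
up to the predictable global factor c^(1/m) introduced by that anchor.
Grubbs removes at most one outlier per group at the two-sided t-based
critical value. The one-tailed Welch direction is caller-supplied — the
design fixes the direction per contrast but no general rule exists.
ANOVA accepts two groups (where F equals the squared pooled t, used as a
cross-check) although the design's typical use is the three SI/SD/SS
groups.

## What the synthetic data emulates — and what it does not

The generator plants, per requested group label, evidence that forces
that label under the decision tree: specific-species matures at known
loci (gp1a, alternating strands), selected-species matures at novel loci
(gp1b), database variants one substitution away from a genome-placed
mature inside an engineered hairpin cassette (gp2a) or inside
pairing-incapable A/C flanks (gp2b), unplaced matures with and without a
previously described trout record (gp3a/gp3b), and database-free loci
with and without qualifying hairpins (gp4a/gp4b). Engineered hairpins
carry two G:U wobbles opposite the mature so the star arm is not an
exact reverse complement (as in real precursors, and so each mature has
exactly one exact genomic placement); every engineered cassette is
verified by folding before acceptance, and the generator fails loudly
rather than emit unsound truth.

Reads are the mature plus 3' isomiR jitter (offsets −2…+2 with mode 0,
concentrating insert lengths on the 19–23 nt mode) plus the 3' adapter at
uniformly high base quality; counts are negative-binomial with
configurable mean (default 200 reads/miRNA/sample) and dispersion
(default 0.1), n = 3 per group, with differential miRNAs split
symmetrically across groups at 2-fold by default. Adapterless reads
(5 %) and contaminant fragments (10 %) emulate the removed-read classes
of real libraries.

Deliberately *not* emulated: sequencing errors, 5' isomiRs,
multibranch-foldable loci, species-accurate genome content, and realistic
sequencing depth (defaults produce tens of thousands of reads per run so
the full pipeline and its tests execute in seconds to a couple of
minutes on one CPU; depth is configurable). Passing tests therefore
demonstrate correctness of the decision logic, folding, scoring and
statistics under the assumed generative model — not robustness to base
call errors or to annotation ambiguity in real genomes.

## Numerical choices and degenerate inputs

* Percentages are rounded half-up to one decimal, matching the published
  accounting tables' display convention.
* Adapter search takes the best-scoring semi-global match; ties break to
  the rightmost adapter start (longest insert), so chance internal
  matches never truncate genuine miRNA sequence. Empty reads flag
  no-adapter rather than erroring.
* Zero-variance DE rows with equal means return p = 1 by convention;
  zero-variance with unequal means return p = 0. Equal-mean zero-variance
  one-tailed Welch returns p = 0.5.
* Fold ties and alignment ties resolve to the first-scanned optimum
  (fixed scan order), making every output deterministic; the pipeline's
  end-to-end byte-identity under a fixed seed is asserted by test.
* Empty inputs (zero-depth libraries, empty UTRs, empty target sets)
  produce valid empty outputs, with a warning where the result is a
  table whose emptiness is scientifically meaningful.
* Seeds: a single integer seed; per-sample simulation streams use fixed
  small offsets from it, keeping all derived seeds well below 2³¹.

## Known limitations

The internal folder is a reduced thermodynamic model (single stem-loop,
condensed wobble stacks, linear loop penalties): it ranks hairpin
candidates reliably but its ΔG values are not substitutes for full
partition-function folding — hence the ingestion path for external
RNAfold-dialect structures. The contaminant screen is exact-substring
against supplied references, a stand-in for proprietary vendor filters.
GO enrichment does not propagate the GO graph. Published absolute read
counts from the original study depend on its raw data, reference builds
and vendor pre-filter and are out of reach of a synthetic rebuild; the
package instead verifies the arithmetic layer of those tables and all
method properties against independent oracles.
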