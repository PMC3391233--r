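---
title: "Methods: surveying CCCH zinc-finger gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveying CCCH zinc-finger gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccchsurvey)
```

`ccchsurvey` implements the standard analysis recipe of a genome-wide
CCCH zinc-finger family survey. This vignette is the package's account of
the models and procedures it implements, the parameters that matter, the
numerical decisions taken where the field's conventions are silent, and the
limits of what the synthetic validation can show.

## The motif model

A CCCH zinc finger is matched by the degenerate-spacer consensus

$$\mathrm{C\!-\!X_a\!-\!C\!-\!X_b\!-\!C\!-\!X_3\!-\!H}, \qquad
  4 \le a \le 17,\; 4 \le b \le 6,$$

where X is any residue. The canonical plant consensus caps $a$ at 15; the
default upper bound here is 17 because a rare $\mathrm{C\!-\!X_{17}}$
variant occurs in maize, and the bounds are configuration
(`ccch_bounds()`), not constants. The unknown-residue code X may occupy a
spacer position but never an anchor C or H: the anchors define the motif's
zinc-coordination chemistry, the spacers do not.

**Overlap resolution.** On real sequences several (C, C, C, H) index
quadruples can satisfy the bounds while sharing residues. HMM-based tools
resolve this internally and do not expose a rule, so the scanner needs an
explicit one: enumerate every candidate quadruple, then accept greedily by
(leftmost start, then smallest total span, then smallest $a$, then smallest
$b$), discarding candidates that overlap an accepted hit. The rule is
deterministic and favors compact motifs; `tests/` verify it against
exhaustive enumeration on sequences up to 80 residues.

**Class tallies and logos.** Classes are named by their spacer signature
(e.g. `C-X8-C-X5-C-X3-H`); percentages are reported to one decimal with
half-up rounding, the convention of published survey tables. Logo profiles
are per-column residue frequencies with information content
$R = \log_2 20 - H$ (Shannon entropy in bits, no small-sample correction);
combined logos of classes differing only in $a$ are right-justified on the
second C so the variable-length first spacer absorbs the offset.

## Phylogeny and grouping

Alignments are consumed, not constructed (any aligner can produce the
input). Distances are uncorrected p-distances under **pairwise deletion**:
each pair is compared over the columns where both rows are ungapped, which
keeps patchily-aligned family members comparable; a Poisson-corrected
variant is available behind `model = "poisson"`. A pair with zero
comparable columns has no defined distance and blocks tree building with an
explicit error.

Neighbor joining is implemented classically with two policies made
explicit:

- **Tie-breaking**: when several pairs minimize the Q criterion, the
  lexicographically lowest pair of cluster labels is joined (a cluster is
  labeled by its alphabetically first taxon). NJ ties are common on small
  or symmetric matrices and an unstated tie-break makes runs
  irreproducible.
- **Negative branches**: negative length estimates are clamped to zero
  with the deficit moved to the sibling edge, conserving path lengths.

On additive matrices the tree's path metric reproduces the input exactly
(tested to 1e-8 on random trees, with `ape::nj` as an independent
topological cross-check).

**Bootstrap.** Columns are resampled with replacement, the full
distance-plus-NJ pipeline is re-run, and each internal edge's support is
the percentage of replicate trees containing the same leaf bipartition
(canonicalized, so support is invariant to input order and to the arbitrary
rooting). One master seed drives the replicate stream; a fixed seed and
replicate count reproduce supports exactly. Replicates in which resampling
leaves some pair with no comparable sites are dropped from the denominator.

**Groups.** Family groups are the maximal clades whose subtending edge
support passes the threshold (default strict > 50%, with an inclusive
option, since both phrasings are common). An unrooted tree has no preferred
root, and the maximal-clade rule depends on where one stands: the package
therefore evaluates rooting at every internal node and on every internal
edge, and keeps the rooting that leaves the fewest taxa ungrouped, then
yields the most groups (ties broken by enumeration order, so the choice is
deterministic). For a family with $k \ge 3$ well-separated subfamilies this
recovers each subfamily as its own group; with exactly two subfamilies the
two clades flanking the deep split are returned. Note that when deep
backbone edges are themselves well supported, maximal clades merge adjacent
subfamilies — that is a property of the rule, not a defect of the
implementation, and it is why the grouping of a real family remains partly
a judgment call.

Sister pairs (cherries) are two-taxon sides of internal bipartitions for
unrooted trees, and two-leaf clades for genuinely rooted input.

## Duplicate pairs, Ka/Ks and dating

**Tandem** means same chromosome and separated by at most five gene loci.
"Separated by five or fewer loci" is read as *at most five intervening
loci* (`|index difference| - 1 <= 5`); the alternative reading (index
difference at most 5) is exposed via `convention = "index"` because the
published clusters are adjacent genes, consistent with either reading, and
the convention must be explicit to be reproducible. **Segmental** means the
two genes fall by coordinate containment inside the two mates of one
duplicated-block pairing, in either orientation; the block catalogue is an
input, since block detection is a genome-scale analysis of its own. Tandem
takes precedence when both rules match, as tandem clusters can also sit on
duplicated blocks.

**Ka/Ks** uses Nei-Gojobori (1986) counting: per-codon synonymous site
fractions averaged over both sequences (single-nucleotide changes to stop
codons count as nonsynonymous and stay in the denominator of three sites
per position); differences counted by averaging over all minimal
substitution pathways between each codon pair, excluding pathways that
cross a stop codon (falling back to all pathways if every one is blocked);
Jukes-Cantor correction $d = -\tfrac34\log(1 - \tfrac43 p)$, undefined and
flagged when $p \ge 3/4$. The estimator is validated against a naive
pathway-enumeration oracle to 1e-12. Published survey tables often come
from closed-source tools that do not name their algorithm; for validation
against such a table the printed Ka and Ks columns are treated as inputs,
which insulates the ratio, selection-call and dating arithmetic from the
estimator choice.

Selection calls: ratio < 1 purifying, = 1 neutral, > 1 positive, undefined
when Ks = 0 (an infinite ratio is not propagated). Duplication age is
$T = K_s / (2\lambda)$ in Mya with $\lambda = 6.5\times10^{-9}$
synonymous substitutions per site per year, the standard grass clock;
ratios are reported to three decimals and dates to two, matching the print
precision of published tables.

## Promoter elements

Promoters are the 2,000 bases immediately 5' of the translation start on
the coding strand (reverse-complemented for minus-strand genes, truncated
with a warning at chromosome ends). The element lexicon ships as an
editable TSV with PLACE-style cores — ABRE `ACGTG` and DRE/CRT `RCCGAC` —
because published surveys name the element classes but rarely the exact
strings they matched; anyone can substitute their own patterns. Scanning
honors IUPAC degeneracy, reports *all* occurrences on both strands
(overlaps included, unlike the protein scanner, because element counts are
positional), uses 1-based sense-strand coordinates for both strands, and
never matches N. Published per-gene element counts are not reproduction
targets here, since they depend on the unstated pattern set.

## qPCR expression

Relative expression follows the `2^-ddCt` method: per replicate,
$\Delta C_T = C_{T,\text{target}} - C_{T,\text{reference}}$, then
$\Delta\Delta C_T$ against the calibrator condition's mean
$\Delta C_T$ (replicates are not paired across conditions because plate
designs do not define such a pairing). The reported point estimate is
$2^{-\overline{\Delta\Delta C_T}}$, computed as a difference of means so
the calibrator's fold is *exactly* 1 — the "normalized to 1" convention —
while the SE is computed over per-replicate fold values, because published
error bars annotate fold-change plots (a log-scale SE is available).
Biological and technical replicates are carried in a `replicate_type`
column and pooled by default, since published designs often mix them
without stating the aggregation. Plate offsets shared by target and
reference cancel exactly.

## The synthetic-data generators

Every analysis stage has a generator that plants known content and
rejection-samples only the background:

- **Proteomes**: planted motifs are written as anchor residues with
  spacers and background drawn uniformly from the 20 residues; the
  background is resampled (up to 10,000 attempts) until scanning recovers
  exactly the planted set. Uniform composition is the simplest null and is
  configurable.
- **CDS pairs**: a stop-free ancestor drawn codon-uniform over the 61
  non-stop codons (avoiding composition artifacts in site counting), with
  exact planted counts of single synonymous and nonsynonymous
  substitutions in distinct codons.
- **Gene orders**: deterministic chromosome slots with planted tandem
  gaps and segmental placements inside mated blocks; contradictory plans
  are rejected.
- **Promoters**: planted elements are concrete instantiations of their
  IUPAC pattern (reverse-complemented for minus-strand plantings);
  accidental background matches are erased by resampling only the
  offending windows, never planted content.
- **Ct tables**: target Ct values encode the planted fold changes
  exactly; Gaussian noise of chosen SD is added per measurement.
- **Alignments**: each planted clade gets an independent random ancestor
  and members differ from it by a few substitutions, so between-clade
  signal dwarfs within-clade signal.

All generators are deterministic given a seed (byte-identical outputs).
What they deliberately do *not* emulate: realistic residue/codon
composition, indels and alignment error, rate heterogeneity, codon-usage
bias, intron structure, or amplification-efficiency variation in qPCR.
Passing round-trip tests therefore shows that the pipeline's arithmetic and
bookkeeping are correct under clean conditions; it does not certify
performance on noisy real data.

## The packaged demo

`make_demo()` writes a complete survey-sized bundle: 68 proteins with 180
planted motifs distributed as in a maize-scale family (98 + 45 in the two
common classes, 36 across four uncommon classes, one 17-spacer motif, one
seven-motif protein), a 20-taxon three-clade alignment, 17 duplicate pairs
(15 segmental across 10 chromosomes, 2 tandem), 12 promoters with 0-6
planted elements each, and a 7-gene Ct table with noise SD 0.15 — sizes
chosen so the full survey runs in seconds while still exercising every
stage at family scale. The demo's problem sizes (200 bootstrap replicates,
300-codon CDS pairs, 2,000-bp promoters) match the defaults used
throughout the tests and the acceptance script.

## Numerical and degenerate-input policies

- Empty sequences scan to empty hit sets; illegal residues/bases error
  with their position.
- Distances with no comparable sites are `NA` and block tree building by
  name.
- Bootstrap with zero replicates returns a tree with undefined support.
- Ks = 0 yields an undefined selection call rather than an infinite ratio.
- Percentages use half-up rounding (so 54.35 prints as 54.4), ratios three
  decimals, dates two.
- All tabular outputs carry a commented provenance header (package
  version, parameters, seed).

## Known limitations

- The overlap-resolution policy is a repository decision; HMM-based
  scanners may parse a cysteine cluster differently, so motif *counts*
  match published surveys only insofar as those tools agree with the
  greedy compact-parse rule.
- p-distance NJ is assumption-light but not model-based; groups from
  deeply diverged families may differ from likelihood methods.
- The maximal-supported-clade grouping merges subfamilies whenever deep
  backbone edges are well supported (see above).
- NG86 with equal pathway weights is the classical estimator; maximum
  likelihood codon models (YN00/codeml) are out of scope.
- Promoter scanning is exact-pattern matching, not PWM scoring, and the
  default lexicon is a minimal two-core set.
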