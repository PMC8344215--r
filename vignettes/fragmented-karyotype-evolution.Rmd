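---
title: "Fragmented mitochondrial karyotype evolution: models and methods"
author: "MitoKaryo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragmented mitochondrial karyotype evolution: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MitoKaryo)
```

## The biological problem

In most bilaterian animals the mitochondrial (mt) genome is a single
circular chromosome with 37 genes whose order is nearly frozen over
hundreds of millions of years. In the sucking lice of eutherian mammals
the mt genome has fragmented into many small circular *minichromosomes*,
each carrying a short coding region (1--8 genes) and one non-coding
region (NCR, the control region). These karyotypes are strikingly
labile: congeneric species differ in minichromosome number, gene
content and gene order, and most of that variation is carried by tRNA
genes, which translocate between minichromosomes far more often than
protein-coding or rRNA genes do. The striking regularity is *where*
the moving tRNAs land: overwhelmingly at the two junctions between the
coding region and the NCR.

MitoKaryo provides the machinery to quantify this: a data model and file
format for fragmented karyotypes, parsimony reconstruction of ancestral
karyotypes on a fixed phylogeny, detection and classification of tRNA
translocation events, a site census giving the expected probability of
NCR-adjacent insertion under a uniform null, pooled t tests of expected
vs observed adjacency, and a forward simulator with a controllable
NCR-destination bias for validating the whole chain.

## Karyotype representation

A karyotype is a set of circular minichromosomes. Each minichromosome is
stored in a *canonical linearization*: the gene sequence read 5'-to-3' on
the majority strand starting immediately downstream of the NCR, with the
NCR implicit at both ends. This is exactly how arrangement strings such
as `S1-S2-rrnS-C` are conventionally written, and it makes equality of
circular gene orders a plain vector comparison: the NCR anchors both the
rotation and the strand. A `~` prefix (e.g. `~nad1`) marks a gene
transcribed opposite to the majority strand; it is the plain-text
counterpart of the underline used in print.

The *backbone* of a minichromosome is its protein-coding and rRNA genes
with the tRNAs stripped. Backbones are the stable identities of
minichromosome types: in the bundled louse data every within-genus
difference is a tRNA placement, while all backbones coincide.

```{r karyotypes}
d <- louseData()
rec <- d$karyotypes[["Polyplax_reclinata"]]
rec
sharedMinichromosomes(rec, d$karyotypes[["Polyplax_spinulosa"]])[
  c("n_shared", "differing_genes")]
```

## Placement states are gap-level

To decide whether a tRNA has moved, each tRNA unit is assigned a
*placement state*: the host minichromosome's backbone key, the nearest
*stable* element (backbone gene or NCR) on each side, and the unit's
orientation. Co-resident tRNAs in the same backbone gap are deliberately
ignored. The coarser, gap-level state is essential: when trnT left the
`nad1--nad3` gap of *P. reclinata*, the immediate neighbour of trnG
changed, but trnG itself did not move. Scoring immediate neighbours
would miscount such bystanders; scoring gaps reproduces exactly the
published lists of moving genes at all three comparison depths (8 genes
within *Polyplax*, 5 at the ancestor level, 19 across the other genera).

The consequence is a documented blind spot: a reshuffle of tRNAs
*within* one backbone gap, or a move between the two ends of the same
gap, is not scored as a translocation. No such case occurs in the louse
data, and the simulator only generates between-minichromosome moves.

Two tRNAs form a *cluster unit* when they are adjacent in the same order
in every karyotype where they co-occur (the S1--S2 cluster is the
motivating case). Clustering genes that never move is harmless; the unit
inherits a single placement state.

## Ancestral inference

The reconstruction uses two nomination rules on a fixed rooted tree. A
placement state is a candidate for the ingroup ancestor when

1. it occurs in at least one ingroup taxon *and* at least one
   non-ingroup taxon, or
2. it occurs in every ingroup taxon with data (taxa with missing data do
   not vote).

Backbone characters are resolved first; tRNA placements are then
resolved conditional on the backbone, because the backbone distribution
is far more stable than tRNA positions. Competing candidates are ranked
by the minimal number of state changes needed on the ingroup subtree
with the root fixed to the candidate, computed exactly by dynamic
programming with unit change costs (any placement can mutate to any
other in one step; no rearrangement-distance model is imposed, matching
how changes are counted in this literature). Exact ties are *reported*,
never broken: the result carries one karyotype variant per tied
resolution.

One design choice was genuinely open. For the S1--S2 cluster of
*Polyplax*, neither rule nominates any candidate: the `rrnS`-side
placement occurs in two of the three ingroup species and nowhere
outside, the `nad1`-side placement in one, and all non-ingroup species
carry a third (ancestral) placement. When that happens, every placement
observed in the ingroup competes by change count. Here the two ingroup
placements tie at one change each, which is precisely the published
ambiguity; accepting the outside placement instead would cost two
changes and is correctly rejected by the count.

```{r inference}
res <- inferAncestor(d$tree, d$karyotypes, d$ingroup,
                     pairs = d$pairs,
                     pairAncestor = d$mrca_sucking_lice,
                     ancestorLabel = "MRCA Polyplax")
res
alternatives(res)
```

### Outgroup evidence without full outgroup karyotypes

Complete karyotypes are bundled only for the three *Polyplax* species
and the two reference ancestors. The twelve non-*Polyplax* species are
documented by an *arrangement-pair table*: one row per moving gene with
its ancestral-context string, derived arrangement string, species and
genus. Rule-1 evidence is computed per character from that table plus
the ancestral karyotype: a species' placement state for a unit comes
from its own derived arrangement when the unit moved, from another
derived arrangement that carried the unit along, or from the ancestral
arrangement with that species' relocated genes removed. This mirrors
the presence/absence character matrices such analyses are based on, and
avoids fabricating complete karyotypes that the source data cannot
support (some printed arrangement strings for the same species are
mutually inconsistent at the whole-genome level, but each is a valid
per-character statement).

## Translocation events and their classification

`detectEvents()` compares a derived karyotype against an ancestor with
the same backbone set; a unit whose placement state differs is an event.
Destination classes are binary: *adjacent* when the unit flanks the NCR
(first or last in the linearization), *intergenic* otherwise. An
insertion a short distance inside the NCR (the trnP case of
*P. asiatica*) is written at the boundary in the karyotype format and
scores as adjacent, which is how such cases are scored in this
literature. Reciprocal anticodon swaps (L1/L2, S1/S2 exchanging
identities by anticodon mutation rather than physical movement) are
flagged `identity_swap`; they count among "genes that changed position"
but are excluded from translocation and adjacency statistics.

Two counting conventions coexist, matching the two analysis depths:

* **Within a genus** every species contributes its own event
  (`ancestorEvents(..., variantMode = "union")`). When the ancestor is
  ambiguous, events are pooled over the equally parsimonious variants,
  so the S1--S2 move contributes three events: one species moved it
  under one variant, the other two under the other. Scoring each
  species only against its best-fitting variant would make an
  ambiguous unit vanish from the statistics entirely, which is both
  counterintuitive and contrary to how the ambiguity is tallied in the
  source analyses.
* **Across genera** (the pair-table analysis) events shared by
  congeneric species with the same moving gene and destination are
  merged into one (`groupEvents()`): a translocation inherited from a
  within-genus ancestor is one evolutionary event. Species of different
  genera never merge.

## The site census

Under a uniform null, a translocating unit can land in any of the
karyotype's insertion slots: a minichromosome with $g$ genes offers
$g + 1$ slots, two of them NCR-adjacent, so a karyotype with $G$ placed
genes on $M$ minichromosomes has $2M$ adjacent and $G - M$ intergenic
slots. The expected adjacency probability is the adjacent fraction of
slots after adjusting for the unit itself:

* **T4 convention** (used for the within-genus and ancestor-level
  tables): if the unit currently flanks the NCR, its departure converts
  one adjacent slot to intergenic; a cluster of $k$ genes removes
  $k - 1$ intergenic slots because it cannot be split. Class counts
  always sum to the total.
* **T8 convention** (used for the across-genera per-gene table): the
  unit's own slot is removed from its class numerator, and the
  denominator drops by one only for NCR-resident units. For
  intergenic-resident units the two class probabilities then do not sum
  to one; the convention is reproduced as used and flagged where
  reported rather than silently corrected.

The ancestor-level census runs on overridden base counts (22 adjacent,
24 intergenic, total 46, i.e. 35 placed genes on 11 minichromosomes):
the reference ancestral karyotype was tallied with two genes unplaced,
and the override records those printed counts without guessing which
genes they were. These conventions were reverse-engineered against every
printed cell of the three published tables and are pinned by tests.

```{r census}
anc <- variants(res)[[1]]
censusSites(anc, "A")                 # 21/48 = 43.75 %
censusSites(anc, c("S1", "S2"))      # cluster: 21/47
```

## The pooled t test and printed precision

Expected and observed adjacency percentages are compared with a
two-sample Student's t test with pooled variance,
$t = (\bar{x}-\bar{y}) / \sqrt{s_p^2 (1/n_1 + 1/n_2)}$, two-tailed, with
$n_1 + n_2 - 2$ degrees of freedom. A zero pooled variance with equal
means gives $t = 0$ (the implementation defines the degenerate case;
that is why the statistic is computed from the formula, with
`stats::t.test(var.equal = TRUE)` serving as an independent cross-check
in the test suite). Probabilities are carried at full precision
internally, but the headline t statistics are computed from inputs
rounded to the precision at which such tables are printed (two decimals
for expected, one for observed columns): the historical values were
computed from printed tables, and the reproduction follows suit, with
full-precision values retained alongside.

```{r ttest}
rep <- runReproduce()
rep$polyplax_t$t       # -118.61978
rep$mrca_t$t           # -212.13726 as printed (exact value -212.137255)
rep$nonpolyplax_t$t    # -1.60738
```

## The simulator

`simulateTree()` evolves a root karyotype along a rooted tree. Per
branch the event count is Poisson(`event_rate`) with equal weight per
branch (no branch lengths: none are used anywhere in the analysis). An
event picks a uniformly random tRNA unit (an adjacent 2-tRNA block with
probability `cluster_prob`), removes it, and reinserts it on a
*different* minichromosome --- between-minichromosome movement is the
process under study --- inverting it with probability `inversion_prob`.
The destination is a two-component mixture: with probability `ncr_bias`
a uniform draw from the NCR-adjacent slots, otherwise a uniform draw
from all available slots. `ncr_bias = 0` is the unbiased null and
`ncr_bias = 1` fully directional. Identity swaps occur per branch with
probability `swap_prob`. Destination minichromosomes are limited to
eight genes, the capacity observed in real fragmented genomes. Backbone
genes never move and minichromosomes never split or merge, matching the
within-genus regime the statistics address.

Each branch draws from an RNG stream seeded deterministically from the
run seed and the branch's tip set, so identical configurations reproduce
identical datasets and an untouched subtree is unaffected by extending
the tree elsewhere. The event log records every move's true destination
slot and class; replaying the log on the root reproduces every tip
exactly, which the test suite asserts.

The simulator's defaults are illustrative: no per-lineage translocation
rates have been estimated for these lice, so `event_rate = 0.5` per
branch is merely of the order implied by the small per-species event
counts, and the remaining defaults are small nuisance probabilities.
Calibration experiments always set these explicitly.

What the simulator does *not* emulate: minichromosome splits and
mergers, backbone rearrangement, gene loss, NCR length or sequence
dynamics, copy-number variation, and rate heterogeneity across lineages.
Passing round-trip and calibration tests therefore validates the
detection-and-statistics chain under the pure translocation model, not
the full complexity of real louse genomes.

## Calibration: what the statistics can and cannot see

`calibrationExperiment()` simulates replicate datasets, runs detection,
the adjacency table and the pooled t test, and tallies rejections.
Two findings are worth stating because the tests pin them:

* **The test is anti-conservative under the null.** The pooled t test
  treats per-unit rows as independent observations; with a handful of
  events per unit the observed column is extremely coarse (0/50/100 %),
  and the empirical rejection rate at nominal $\alpha = 0.05$ is about
  0.20 on a three-taxon tree at one event per branch (frozen as a
  5000-replicate Monte-Carlo reference; the 500-replicate suite checks
  against its exact binomial band). The headline within-genus and
  ancestor-level results do not lean on marginal significance --- every
  observed event there is NCR-adjacent --- but the p values should be
  read with this in mind.
* **High rates under-capture adjacency.** Only one gene can flank each
  NCR end at a time, so a later arrival at a boundary pushes an earlier
  one inward. The calibration therefore reports both the true logged
  destination fraction (`mean_destination_adjacent`, exactly 1 when
  `ncr_bias = 1`) and the fraction the detector sees in the final
  karyotypes (`mean_observed_adjacent`, lower at high rates). The same
  push-aside effect is the standing explanation for why the deepest,
  across-genera comparison shows the weakest observed adjacency signal.

Rejection rates are non-decreasing in `ncr_bias` (checked at 0, 0.5 and
1 with shared seeds), and under the null the realized adjacency fraction
of 10,000 single-event draws from the ancestral karyotype stays within
three standard errors of the census expectation 22/48. The simulator
restricts destinations to other minichromosomes, which perturbs the
per-event adjacency probability by well under one percentage point on
this karyotype --- inside that band.

Problem sizes used by the shipped tests: 500 calibration replicates per
bias level on a three-taxon tree, 10,000 null draws, and exhaustive
brute-force parsimony oracles on trees of up to six leaves. The full
deterministic reproduction runs in about a second.

## Numerical and degenerate-input choices

* Ties in candidate ranking are expanded into variants, never broken by
  order; all enumeration orders are canonicalized (taxa sorted) so
  results are invariant to input order.
* Incomplete karyotypes are first-class: missing genes yield `NA`
  placement states, which abstain from both nomination rules and from
  change counting.
* A tRNA-only minichromosome projects to an empty backbone and is
  retained as a flagged placeholder; such minichromosomes exist in real
  lice (e.g. a T-D-H arrangement) even though none occurs in the
  bundled complete karyotypes, so the behaviour is defensive.
* `detectEvents()` refuses karyotype pairs with different backbone
  sets: split/merger analysis is a different problem and silently
  mixing it into tRNA statistics would corrupt them.
* The empty-document, duplicate-gene, unknown-token and oversized
  minichromosome cases are distinct parse errors naming the offending
  line.

## Known limitations

* Placement states cannot see within-gap reshuffles (above).
* The across-genera analysis inherits whatever under-capture the real
  data contain; the package reproduces, it does not correct.
* The census override for the sucking-louse ancestor encodes printed
  totals whose two unplaced genes are not identifiable from the source;
  the uncertainty is confined to that constant.
* The pooled t test's independence assumption is violated by
  construction (rows share the same karyotype); the calibration
  quantifies the resulting size inflation rather than replacing the
  test, since reproducing the published analysis is the point.
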