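---
title: "Methods: detecting and testing independent CNE losses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and testing independent CNE losses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cneloss)
```

This vignette is the package's account of its science: the loss-detection
model and its assumptions, the parsimony and null-model machinery, the
choices made where the design was genuinely open, and what the synthetic
data generator does and does not emulate.

## 1. The three-state loss model

Every CNE × species cell takes one of three states.

* `CONSERVED` — at least `min_overlap` bp (default 1 bp) of the species'
  alignment overlaps the element. The default is deliberately permissive:
  partial alignment demonstrates the element has not been completely
  lost, and no threshold for "partial loss" is claimed. The cutoff is a
  configurable argument because any other choice would be equally
  defensible.
* `LOST` — only callable in *loss-search* species (high-coverage,
  trace-backed genomes). Requires the absence of aligning sequence to be
  embedded in a syntenic context: aligning flank blocks upstream and
  downstream on one query scaffold in consistent order and orientation,
  no assembly gap intersecting the query inter-flank interval, and no
  sequence-similarity hit for the element anywhere in that species'
  genome or unassembled reads.
* `MISSING` — every other form of absence. Missing data is a first-class
  state, never silently coerced: a cell failing a loss filter carries
  exactly one reason code with fixed precedence
  (`no_flank` → `not_cosyntenic` → `assembly_gap` → `similarity_hit`),
  so audits are deterministic. Absence in presence-only or outgroup
  genomes is always `MISSING(low_coverage_species)`.

Two detection choices are not dictated by the printed filter rules and
are therefore explicit arguments:

* **Flank definition.** Evidence rows carry the nearest aligning blocks
  up/downstream; both must lie on one query scaffold with strand-consistent
  order, else `not_cosyntenic`. Negative-strand blocks are oriented before
  distances are computed, so all distances are non-negative along the
  query.
* **Similarity hits demote to `MISSING`, not `CONSERVED`.** A trace or
  genome hit means the element may survive elsewhere (translocation) or
  the assembly may be wrong; neither an orthologous conservation claim
  nor a loss claim is safe.

## 2. Parsimony with missing data

Losses are placed by Dollo-style parsimony: a CNE present in the
ancestor can only be lost, never regained. For one CNE, prune `MISSING`
leaves and take every maximal all-`LOST` clade; each clade receives one
loss event on a single branch. Equivalently (and how the code computes
it): a node *qualifies* when its subtree contains no `CONSERVED` leaf
and at least one `LOST` leaf; the loss branches are the qualifying nodes
whose parent does not qualify. Two inferred branches are therefore always
separated by at least one conserving species — the definition of
*independent* losses.

**Open choice — nested candidate branches.** When a `LOST` leaf has only
`MISSING` relatives the event is placeable on several nested branches.
The default rule (`rule = "ancestral"`) reports the most ancestral
consistent branch, so a loss on an internal branch has loss *or missing
data* for all its descendants; `rule = "shallow"` reports the MRCA of
the `LOST` leaves only. Both are implemented because the two natural
readings of the procedure differ exactly here; `ancestral` is the
default because it is the semantics under which internal-branch losses
are displayed and counted in this type of screen. All eligibility and
simulation machinery respects whichever rule is chosen.

Correctness is tested against an independent brute-force oracle: on 50
random 6-leaf trees × all 3^6 status vectors, the inferred set must (i)
have brute-force-minimal event count, (ii) be a valid cover, and (iii)
satisfy the ancestral tie rule.

## 3. Eligibility, the exact expectation, and N_A

For branch A, `L_A` is the number of observed loss events on A and `N_A`
the number of CNEs *with the potential for an inferable loss on A*: the
singleton combination {A} must be valid for the CNE's missing-data set —
no `MISSING` leaf below A **and** a non-missing separator leaf below A's
parent. The second condition matters: if, say, rat is missing, a mouse
loss would be re-inferred on the mouse–rat ancestor, so that CNE cannot
contribute a mouse-branch event. Defining `N_A` this way makes the exact
expectation and the reassignment simulation two estimators of the same
quantity; with the looser "no missing data below A" denominator the
simulation mean systematically exceeds the exact expectation by a few
percent, which is how this choice was diagnosed.

The expected number of CNEs lost independently in branches A and B is
`f_A · f_B · N_AB` with `f = L/N`, and `N_AB` the number of CNEs for
which the pair {A, B} is jointly valid (this also enforces a conserving
separator, e.g. a mouse–rat-ancestor + guinea-pig loss requires a
non-missing kangaroo rat). `E_2` sums over all valid pairs; `E_3` over
valid triples. Expectations for k ≥ 4 are not computed (the simulation
still counts such CNEs).

`is_valid_combination()` — label the combination's leaves `LOST`,
re-infer, demand the identical branch set — is the single source of
truth; the vectorized eligibility codepaths are proven equivalent to it
in the test suite.

## 4. The constrained reassignment simulation

Each iteration rebuilds the observed loss events on random CNEs:

1. All labels start `conserved`; the observed events are sorted by depth
   of the node the loss branch ends in (ascending — the relative
   evolutionary order; root has depth 0). Equal depths break by branch
   name, then input index, for reproducibility.
2. Each event is assigned to a uniformly drawn CNE, rejecting draws where
   (i) a species of the event is already lost on that CNE, (ii) the event
   conflicts with the CNE's missing data, or (iii) parsimony would
   re-infer a different branch (a mouse loss followed by a rat loss on
   the same CNE would merge into the ancestor).
3. After `max_reject = 1000` rejections the valid CNEs are enumerated
   exactly and the event placed uniformly among them — termination is
   guaranteed and the conditional distribution is unchanged, since both
   procedures are uniform over the same valid set.

By construction every iteration reproduces the input events exactly; the
implementation nevertheless re-infers every touched CNE each iteration
(a single batched matrix operation) and stops on any discrepancy. The
incremental validity check used in the hot loop — each assigned branch
must keep a conserved leaf below its parent outside the lost∪missing
set — is mathematically the same maximality condition that defines the
inference, and is additionally tested against `is_valid_combination()`.

Summary statistics: z = (observed − simulation mean)/simulation sd, and
the add-one empirical P-value `(1 + #{sim ≥ obs}) / (1 + iterations)`,
so 10,000 iterations with no exceedance report P = 1/10001 < 1e-4. The
event order is a parameter (`depth`, `reverse`, `random`); the test
suite checks the resulting distributions are statistically
indistinguishable.

A known limitation, inherited from following the simulation rules
verbatim: an *observed* internal-branch event whose descendant data are
partially missing (possible only for branches spanning presence-only
species) cannot be re-assigned under validity rule (ii). Such events are
excluded from the frequency tables with a warning; they cannot arise
from the package's own generator.

## 5. Catalog filters and their boundaries

All thresholds keep their printed forms exactly: length ≥ 70 bp
(inclusive), Blastx E < 0.01 rejects, second BLAT score ≥ 40 rejects,
highly-conserved subset requires RS fraction > 0.5 (strict) and phyloP
P < 1e-20 (strict), pre-mammalian ancestry requires ≥ 80% aligned length
(inclusive). Coordinates are 0-based half-open (BED) throughout.
Portions within 100 bp of exons are trimmed and every resulting fragment
re-enters the ≥ 70 bp check — the length rule describes the *final* set,
so it is re-applied after trimming. The removal rules commute; only
trim-before-length is ordered, and the report assigns one reason per
element by a fixed documented precedence. Mitochondrial, random and
haplotype sequences are removed via a configurable chromosome-name
pattern.

## 6. Assembly validation and control regions

A loss region (query inter-flank interval) is `validated` when a single
mapped read spans it plus 50 bp on each side; regions ≥ 500 bp are
`too_long` for typical ~800 bp Sanger reads (strict bound: 500 bp is
excluded). Read mapping criteria are applied upstream; the operation
consumes placements. Control regions of exactly the loss-region size are
drawn uniformly over all gap-free placements by exact enumeration of
feasible start positions (no rejection sampling), which makes the
uniformity provable and the chi-square goodness-of-fit test in the suite
a check of the implementation, not of luck.

## 7. Downstream analyses

* **Window clustering**: 5 Mb windows, 100 kb step (the step is not
  dictated by the procedure; 100 kb gives sub-window resolution and is
  configurable), counts by CNE midpoint, ties share ranks.
* **Separate events**: adjacent CNEs lost in the same species pair count
  as separate events only when an intervening CNE is conserved in both
  species; otherwise one large deletion could explain both.
* **Nearest TSS**: by absolute distance from the CNE midpoint (anchor
  configurable to `edge`), orientation-independent because enhancers act
  orientation-independently; exact ties go to the smaller coordinate and
  are flagged.
* **Gene-loss association**: ortholog-table entries recorded as `gap`
  are excluded from assessment (a gene absent due to an assembly gap is
  not evidence of gene loss).
* **Size matching**: for each independently lost CNE, one same-length
  CNE is drawn without replacement from the no-loss and lineage-specific
  pools; length is a confounder of both constraint and ancestry, and
  exact multiset matching removes it entirely (unmatched lengths are an
  error, not a silent approximation).
* **Comparisons**: Wilcoxon rank-sum for continuous features (length,
  RS fraction), chi-square for proportions (extreme constraint bin,
  default RS > 0.6; pre-mammalian ancestry). Constant features are
  skipped with a note rather than returning meaningless P-values.

## 8. The synthetic data generator

The generator works purely at the coordinate/evidence level — sequence
content and nucleotide-level evolution are not simulated, by design.
What it emulates, with defaults chosen as the study conditions:

* **Tree**: 12 leaves — seven loss-search mammals (mouse, rat, guinea
  pig, cow, horse, dog, elephant), two presence-only rodents/lagomorphs,
  three outgroups — with literature-plausible neutral branch lengths
  (substitutions/site).
* **Loss process**: per CNE × capable branch, probability
  `base_rate × branch length × propensity`. `base_rate = 0.05` per unit
  branch length yields per-branch loss frequencies of ~0.5–1.75% —
  the "around 1%" regime. Propensity is a *relative* weight with mean 1
  (hotspot default: 10% of CNEs at 10-fold weight; a gamma option gives
  smooth heterogeneity), so the marginal frequency does not move with
  the propensity model. Drawn event sets that parsimony would merge are
  rejected, so planted events are exactly re-inferable.
* **Element lengths**: lognormal, median ~181 bp, mean ~238 bp,
  truncated at 70 bp. **Deletions**: lognormal, median ~2.9 kb, always
  at least the element length + 20 bp; the query inter-flank distance is
  drawn U(50, 450) bp so most loss regions are short enough for
  spanning-read validation. Reference distance = deletion + query
  distance, making `deletion_analysis()` exact on artifact-free cells.
* **Missing data**: per-species rates by role (loss-search 2%,
  presence-only 12%, outgroup 6%), independent per cell by default, with
  a correlated whole-scaffold option (real assemblies lose contiguous
  regions; the independent default is the simpler null). Missing cells
  in loss-search species are realized as one of the four artifact types
  with configurable mixture; a conserved outgroup is always retained,
  as the catalog guarantees.
* **Side tables**: spanning reads for 99% of short loss regions (split
  reads otherwise), TSS and ortholog tables with 2% gene absence and 1%
  assembly-gap entries.

What passing tests on this generator *do not* show about real data:
alignment quality, mapping artifacts correlated with sequence content,
repeat-driven mis-assembly, non-independence of losses in genomic
neighborhoods (beyond planted hotspots), and rate variation along a
branch. The generator validates the logic and the statistics, not the
upstream genomics.

## 9. Problem sizes and numerical conventions

The test suite runs the oracle battery at 50 topologies × 729 status
vectors; simulation conservation on 20 fixtures × 1,000 iterations;
cross-method agreement on 10 uniform datasets of 2,000 CNEs (1,000
iterations each); calibration on 100 replicates of 500 CNEs; hotspot
recovery on 20 datasets of 5,000 CNEs; deletion recovery on a 4,000-CNE
dataset (≥ 200 planted losses). These sizes were chosen so each property
is measured with comfortable statistical margin while the suite stays
quick to run routinely.

Conventions: all randomness flows from explicit integer seeds, and each
simulation iteration derives its own substream so results do not depend
on execution order; ties in any deterministic ordering break
lexicographically by node/branch name; degenerate inputs (empty event
lists, zero-variance features, sd = 0 null distributions) return flagged
values or informative errors rather than NaNs.
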