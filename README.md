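# cneloss

Detection and statistical analysis of conserved non-coding element (CNE)
losses across a mammalian phylogeny.

## The problem

CNEs are genomic regions that evolve under purifying selection yet do not
code for protein; many act as *cis*-regulatory elements, and their complete
loss in a lineage can accompany phenotypic change. Calling a CNE "lost" in
a species from a multiple genome alignment is error-prone: assembly gaps,
missing flanking alignments, low-coverage genomes and element
translocations all mimic loss. And once clean per-species loss calls
exist, the interesting biological question is distributional: are CNEs
lost *independently* in two or more lineages more often than a uniform
loss process would predict?

`cneloss` implements the full chain for researchers in comparative and
regulatory genomics:

1. **Catalog filtering** (`apply_cne_filters()`): candidate conserved
   elements are cleaned with the standard inclusion rules — length
   ≥ 70 bp after trimming 100 bp exon-flank margins, no exon / ncRNA /
   transposon / pseudogene overlap, no Blastx protein hit at E < 0.01, no
   second self-BLAT hit with score ≥ 40, and alignment to at least one
   outgroup species (so the element is ancestral, not recently gained).
2. **Loss detection** (`build_status_matrix()`): each CNE × species cell
   becomes `CONSERVED`, `LOST` or `MISSING`. `LOST` requires co-syntenic
   aligning flanks up- and downstream, no assembly gap between them, and
   no sequence similarity anywhere in the genome or the unassembled
   sequencing reads. Anything else that is not aligned is `MISSING` with a
   machine-readable reason code — neither loss nor conservation is claimed.
3. **Parsimony inference** (`infer_loss_branches()`): each loss is placed
   on a branch of the species tree by Dollo-style parsimony that treats
   `MISSING` as uninformative; losses in sister species merge into a
   single ancestral event, and two inferred branches are always separated
   by at least one conserving species.
4. **The null models** (`cne_loss_test()`): with per-branch loss
   frequencies `f_A = L_A / N_A` (events observed on branch A over CNEs
   with the *potential* for an inferable loss on A given their missing
   data), the expected number of CNEs lost independently in branches A and
   B is `f_A · f_B · N_AB`, summed over all valid lineage combinations
   (`E_2`; `E_3` analogously for triples). A constrained Monte-Carlo
   simulation reassigns the observed events to random eligible CNEs —
   preserving every per-branch event count and the parsimony identity of
   every event — and yields the z-score and an add-one empirical P-value
   for the observed counts.
5. **Downstream characterization**: sliding-window clustering of
   independently lost CNEs, separate-event verification via intervening
   conserved elements, nearest-TSS gene-loss association, and
   size-matched comparisons of length, constraint and evolutionary
   ancestry (pleiotropy proxies) between loss groups.
6. **Synthetic data** (`generate_dataset()`): a coordinate-level generator
   that emits every input the pipeline reads, with planted ground truth
   (per-branch events, deletion sizes, missing masks, artifact labels), so
   each stage is testable end-to-end without any external download.

## Worked example

```r
library(cneloss)

cfg <- sim_config(seed = 7, n_cnes = 2000)   # default study conditions
ds  <- generate_dataset(cfg)
st  <- build_status_matrix(ds$cnes, ds$evidence, ds$gaps, ds$hits, ds$tree)
fit <- cne_loss_test(st, ds$tree, iterations = 2000, seed = 7)
fit
```

```
Independent CNE loss test
  CNEs: 2000;  loss events: 143;  CNEs with >=1 loss: 132
 k observed expected sim_mean sim_sd sim_max     z     p
 2       11     3.54     3.45  1.728      13  4.37 0.001
 3        0     0.04     0.04  0.203       2 -0.21 1.000
  (z: standard deviations above the simulation average; P: add-one empirical)
```

Eleven CNEs are lost twice independently where the uniform-loss null
expects ~3.5 (exact expectation 3.54, simulation mean 3.45 — the two
routes agree), an excess of 4.4 standard deviations with empirical
P ≈ 0.001: loss propensity is heterogeneous across CNEs, as planted by
the generator's default hotspot model. `summary(fit)` adds per-branch
loss frequencies and the per-lineage-combination table; `coef(fit)`
returns the frequencies; `plot(fit)` draws the simulated null
distribution with the observed count marked.

```r
loss_frequency_vs_branch_length(fit$stats, ds$tree)
#> r = 0.95, t = 9.21, df = 9, P = 7.1e-06
```

Per-branch loss frequency scales with neutral branch length, as expected
when losses accumulate roughly clock-like along each lineage.

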