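# corekin

Classification of kinase-like protein superfamilies from a shared structural
core domain.

Eukaryotic protein kinases (EPKs) and the far more diverse eukaryotic-like
kinases (ELKs — small-molecule kinases such as aminoglycoside
phosphotransferases, choline kinases and homoserine kinases) share a common
structural core: the Hanks & Hunter subdomains I–V, VIa, VIb, VII and IX,
carrying the invariant catalytic machinery (the β3 lysine, C-helix glutamate,
catalytic-loop aspartate and the magnesium-binding DFG motif). `corekin` is a
toolkit for analysing such superfamilies in that common coordinate system:

* **hierarchical profile alignment** — position-specific log-odds profiles
  (Henikoff position-based weights, BLOSUM62-mixture pseudocounts) arranged
  in a subgroup hierarchy; each database sequence is locally aligned to its
  best-scoring profile and mapped through a curated template onto the shared
  core columns, losslessly (insert segments between core blocks are kept);
* **identity clustering** — greedy CD-HIT-style clustering of core rows at a
  fractional-identity threshold with representative selection;
* **Bayesian partitioning with pattern selection** — a Gibbs sampler that
  jointly infers each sequence's subgroup and, for every node of a predefined
  subgroup hierarchy, the set of core columns (with biochemical residue
  classes) that most discriminate the node's *foreground* (sequences in its
  subtree) from its *background* (the rest of its parent's subtree);
* **contrast hierarchical alignments (CHA)** — fixed-width renderings showing
  pattern positions, foreground/background match frequencies in integer
  tenths (`!` = 100%), the virtual (redundancy-down-weighted) alignment
  sizes, insertion/deletion lines and semi-log divergence bars;
* **consensus phylogenetics** — neighbor joining on normalized BLOSUM62 score
  distances, column bootstrap, and the extended-majority-rule consensus
  (all >50% bipartitions plus compatible minority bipartitions in frequency
  order);
* **substrate-specificity calls** — the DFG+1 rule for aminoglycoside
  phosphotransferases (acidic DFG+1 → APH2, substrate pattern OH-NH2-OH;
  basic DFG+1 → APH3, OH-OH-NH2) and catalytic-loop basic-residue scanning;
* **a synthetic-superfamily simulator** — generates superfamilies with known
  subgroup structure, invariant catalytic columns, planted discriminating
  residues and variable-length inserts, so every stage is testable by
  parameter recovery.

## The core statistic

For a node with foreground match count/total (f, F) and background (b, B) at
a column, the column contrast is the log Bayes factor of two independent
binomial match rates against one shared rate, under conjugate Beta(½, ½)
priors (counts are sequence-weighted and real-valued):

    log BF = log B(f+½, F−f+½) + log B(b+½, B−b+½)
           − log B(f+b+½, (F−f)+(B−b)+½) − log B(½, ½)

A node's score sums the contrast over its pattern columns minus a per-column
prior penalty `−log ρ + log L + log |sets|` (geometric pattern-size prior plus
uniform column- and residue-set-choice terms — the built-in multiple-testing
correction). The sampler alternates resampling sequence assignments
(∝ exp(Δscore/T)) and per-column pattern membership, annealing T linearly to
zero and then proceeding greedily.

## Worked example

```r
library(corekin)

cfg <- superfamily_config(n_groups = 4, seqs_per_group = 50,
                          patterns_per_group = 5,
                          fg_match_prob = 0.95, bg_match_prob = 0.05,
                          rng_seed = 7)
sf <- generate_superfamily(cfg)
spec <- hierarchy_spec(c("root", "G1", "G2", "G3", "G4"),
                       c(NA, "root", "root", "root", "root"),
                       seeds = lapply(split(sf$sequences$id, sf$sequences$group),
                                      head, 3))
res <- run_mcbpps(sf$alignment, spec, n_sweeps = 30, burn_in = 15, rng_seed = 1)
head(subset(res$report, node == "G1"), 5)
#>  node rank column residue_set fg_match bg_match contrast
#>    G1    1     47           R     98.3      2.6 90.37943
#>    G1    2     30           D     98.3      4.7 83.07765
#>    G1    3     20           S     94.5      3.7 77.99268
#>    G1    4     44           Q     92.0      5.0 69.49771
#>    G1    5     33           L     88.7      4.3 66.46315
mean(res$assignments[sf$sequences$id] == sf$sequences$group)
#> [1] 1
```

The report lists, for subgroup G1, the discriminating core columns the
sampler selected (1-based), each column's residue class, the weighted
percentage of foreground and background sequences matching it, and the log
contrast. Here the five reported columns are exactly the five planted ones
(truth: 20, 30, 33, 44, 47) and every sequence is assigned to its true
group. The matching contrast alignment:

```r
doc <- render_cha(sf$alignment, res$state, "G1",
                  head(sf$sequences$id[sf$sequences$group == "G1"], 2))
print(doc)
#>                         1         11        21        31        41        51
#> divergence              000000000000000000070010010007006100000000060070010010000000
#> pattern                                    *         *  *          *  *
#> G1_seq001               ENFEKSYIEVDPAGDYKRHSAASIDANRKDLHLFDEIPADFGIQEMRNATKVTVRDNPPE
#> G1_seq002               EQIPKKENQFIFISFLMVVSPFNLDKVDQDLKLYKITQFDFGGQKSRKPEQTFLEVITTF
#> fg (49.1 wt/50)         1111!1111111111111191111!11119118111011!!!191191111111111111
#> bg (150.9 wt/150)       0000!0000000000011000000!00000100000000!!!100000000000010000
#> insertions              000000000000007000000000000000000080000000000000000000000000
#> deletions               000000000000000000000000000000000000000000000000000000000000
```

The `*` markers sit on the selected pattern columns; the frequency lines give
integer-tenths match frequencies (`!` = 100% — visible at the invariant
catalytic columns 5, 25 and the DFG motif at 40–42, matched by foreground and
background alike); the labels carry the virtual weighted sequence counts
(49.1 of 50 foreground, 150.9 of 150 background); the insertion line shows
the two simulated insert points.

The same pipeline is scriptable end to end from a YAML config
(`inst/extdata/demo_config.yaml`) via `run_pipeline()`, or from a shell
through the thin wrapper `inst/scripts/corekin.R`
(`Rscript corekin.R run-all --config demo_config.yaml --out artifacts/`).

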