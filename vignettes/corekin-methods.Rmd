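---
title: "Models and methods behind corekin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind corekin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corekin)
```

`corekin` analyses kinase-like superfamilies — eukaryotic protein kinases
(EPKs) and the small-molecule eukaryotic-like kinases (ELKs) — in the
coordinate system of their shared structural core (Hanks & Hunter subdomains
I–V, VIa, VIb, VII, IX). This vignette documents the models, the defaults
and why they were chosen, what the synthetic-data generator does and does not
emulate, and the package's known limitations.

## The core alignment container

A `CoreAlignment` stores, per sequence, a residue or gap at each of L fixed
core columns, plus the insert segments that fall between core columns (keyed
by the preceding core column; key 0 means before the first column). This
makes core mapping lossless by construction: `degap()` interleaves core
residues and inserts and must reproduce the raw sequence exactly. Every
pipeline stage preserves this invariant and the test suite asserts it for
every generated dataset. Coordinates are 1-based in every report and output.

## Sequence weighting and the virtual alignment size

Redundancy is removed with Henikoff & Henikoff position-based weights: at
each column a sequence receives `1/(r s)` (r distinct non-gap residues in the
column, s sequences sharing its residue), summed over columns. Raw weights
are normalized to sum to the *effective sequence number*, estimated as the
number of greedy single-linkage clusters at 62% identity — the classic
profile-HMM rule. A fully redundant alignment therefore counts as one virtual
sequence while n unrelated sequences count as n; this effective count is the
"virtual number of aligned sequences" printed on contrast-alignment frequency
lines, and all pattern-sampler counts are weighted by these weights. An
earlier candidate (mean distinct residues per column) was rejected because it
saturates at 20 and suppresses genuine evidence in diverse alignments.

## Profiles and alignment

Profiles are per-column log2-odds of pseudocount-smoothed weighted residue
frequencies over the BLOSUM62 marginal background. Pseudocounts are a
substitution-matrix mixture: the column prior is the BLOSUM62 conditional
distribution (reconstructed from the half-bit scores via
`q(a|b) ∝ p_a 2^(s_ab/2)`) averaged under the observed frequencies, blended
with mass `pseudocount_strength` (default 5) against the weighted observed
count. Consensus calls take the weighted plurality residue, ties broken
alphabetically for determinism; a column that is majority-gap emits a gap so
that core columns stay dense.

Sequences are aligned to profiles with a local (Smith–Waterman) affine-gap
dynamic program (compiled code); a gap run of length k costs
`open + (k−1)·extend`, defaults 11/1 in bits, following common practice for
protein search tools. Traceback is deterministic (diagonal preferred, then
insertion, then deletion; first-maximum end cell). The DP is verified against
exhaustive enumeration of all monotone matchings for instances up to length
8. A match is *significant* at a configurable bit-score cutoff (default 25
bits); below it a sequence is reported unclassified, never an error. Ties
between equally scoring profiles go to the deeper node of the hierarchy, then
to name order.

The template alignment maps each profile's columns to root core columns;
profile columns at which the root row is gapped, and all locally unaligned
residues, become insert segments attached to the preceding core column —
a deterministic convention matching how inter-subdomain inserts are drawn
between conserved blocks. Profile refinement alternates, per round: rebuild
weighted group profiles, recompute group consensus rows, rebuild the
template, re-align each group's sequences, and count changed core rows. On
data drawn exactly from the group profiles with conserved terminal columns
the procedure is at a fixed point after one round; local end-trimming ties
can otherwise flip single rows between rounds, which the change counter makes
visible.

## Identity clustering

Identity is the fraction of co-occupied core columns (both rows non-gap) with
identical residues; inserts are excluded since the clusters are defined on
the core domain. Clustering is greedy longest-first (CD-HIT style): rows are
scanned by descending ungapped length and join the first representative at or
above the threshold (default 0.60), else found a new cluster. This is
deterministic and yields the two properties the tests assert: every member
reaches its representative at the threshold, and the cluster count is
monotone in the threshold.

## Bayesian partitioning with pattern selection

Given a master core alignment and a predefined subgroup hierarchy (single
root; leaves carry sequences; internal "?" groups acquire membership through
their subtrees), every non-root node contrasts its *foreground* (sequences
currently assigned to its subtree) against its *background* (the remaining
sequences of its parent's subtree), so `|fg| + |bg| = |subtree(parent)|`
always. A node's pattern is a set of core columns, each with a residue set
drawn from a fixed biochemical catalog (acidic {D,E}, basic {K,R} and
{K,R,H}, hydroxyl {S,T}, amide {N,Q}, hydrophobic {I,L,V,M}, aromatic
{F,Y,W} and {F,Y,W,H}, plus singletons) and required to contain the node's
seed-consensus residue at that column.

**Column score.** The evidence that a column discriminates is the log Bayes
factor of two independent binomial match rates versus one shared rate under
Jeffreys Beta(0.5, 0.5) priors, computed in closed form from weighted
(real-valued) counts and cross-checked in the tests against numerical
integration. Gaps count as non-matches. Only foreground-enriched columns are
eligible.

**Pattern prior.** Each pattern column carries the penalty
`log ρ − log L − log |eligible sets|` with ρ = 0.2: a geometric size prior
plus uniform choice priors over which column and which residue set. The
choice terms are the Bayesian multiple-testing correction implied by
selecting patterns "at randomly selected positions": without them, a sampler
free to reassign sequences can amplify noise columns on pattern-free data
into self-consistent spurious patterns. With them, the null calibration in
the test suite (i.i.d. groups, no planted columns) recovers a median of at
most one column per node.

**Sampling.** Because the node score is additive and independent across
pattern columns, the pattern-move kernel factorizes: each column's inclusion
is Gibbs-resampled (probability `sigmoid(score/T)`, residue set softmax in
the contrast), which has the same stationary distribution as add/remove/swap
Metropolis proposals and becomes exactly greedy at T = 0. Assignments of
non-seed sequences are resampled leaf-wise with probability
`∝ exp(Δ total score / T)`; seed sequences never move. The temperature decays
linearly from `t0` (default 3) to zero over `burn_in` sweeps and the run
continues greedily, returning the best state visited after burn-in. During
burn-in the column/set-choice penalty terms ramp in linearly with the
annealing (the geometric term always applies): early sweeps can thus seed
patterns from the weak signals available before the partition has sorted
itself, and the full prior prunes anything that fails to grow real support by
the time the schedule reaches zero. At T = 0 both phases are coordinate
ascent, so the total log-score is non-decreasing — a property the tests
assert over 50 greedy sweeps. Runs are deterministic given `rng_seed`.

Initialization is random (uniform leaf assignments, random eligible
patterns); a seed-contrast initialization is available (`init = "seed"`) but
is not the default, because contrasts computed from three-sequence seed
alignments are dominated by small-sample coincidences and measurably do not
improve convergence.

## Contrast hierarchical alignments

Frequency glyphs use the integer-tenths rule: `floor(10·f)` as a digit, with
`!` reserved for exact 100% (weighted frequency ≥ 1 − 1e-9); bins are closed
on the left, so 0.999 renders `9`. At pattern columns the match target is the
pattern residue set; elsewhere it is the foreground's weighted majority
residue. Insertion and deletion lines show the weighted fraction of
foreground sequences with an insert after, or a gap at, each column, through
the same glyph rule. Divergence bars use the per-weighted-sequence contrast —
the Bernoulli Kullback–Leibler divergence KL(fg‖bg), the large-sample limit
of the column contrast per foreground sequence, floored at zero when the
foreground is not enriched and with background rates clamped to
[0.005, 0.995] — mapped through `log10(1 + m)` and clipped to the maximum bar
height (semi-log scaling). Column information content is
`log2 20 − H(column)` on the weighted, pseudocount-free distribution. Text
and HTML renders encode identical frequencies; HTML colors pattern-matching
residues by their biochemical class.

## Trees and consensus

The in-house tree method is distance-based neighbor joining — re-implementing
a maximum-likelihood search is explicitly out of scope — over the normalized
score distance `1 − (S − S_rand)/(S_max − S_rand)` on co-occupied core
columns (S summed BLOSUM62 score, S_max mean self-score, S_rand the
background expectation), clipped at zero. NJ uses deterministic tie-breaking
and clamps negative branch lengths to zero; it is exact on additive matrices,
which the tests verify on random additive trees up to 12 taxa (topology and
path lengths) and cross-check against an independent implementation.
Bootstrap replicates resample core columns with replacement, excluding
columns with more than 50% gaps for distance stability; the replicate count
is a parameter with no canonical value. The extended-majority-rule consensus
sorts bipartitions by frequency (ties by first occurrence), always includes
those above 50%, then greedily admits lower-frequency bipartitions compatible
with everything already accepted; node labels carry support as the percentage
of input trees containing the bipartition.

## Substrate specificity

Motif locations are template-annotation driven (core-column spans for the
glycine-rich loop, β3 lysine, C-helix glutamate, catalytic loop and the
DFG region including DFG+1); sequences are never scanned by regular
expression, because the motifs are positions, not strings. The DFG+1 rule:
aspartate (observed in the DFGD and DFTD motifs) gives an APH2 call with the
OH-NH2-OH substrate pattern; arginine (DFGR, DNGR) gives APH3 with OH-OH-NH2.
Glutamate and lysine are accepted as charge-class extrapolations of the
observed residues and flagged as such in the output; everything else is
unassigned, keeping the class label and substrate motif in strict bijection.
The catalytic-loop flag reports `basic-KR` if any K/R occurs in the annotated
loop span (the hallmark of protein-phosphorylating kinases), else `basic-H`
for a histidine (suggestive of peptide phosphorylation capacity in some ELK
families), else `none`. Annotation is independent of classification: a
sequence left unassigned by the sampler still receives motif calls.

## The synthetic generator

`generate_superfamily()` emulates the features downstream stages depend on:
a tree of groups; invariant catalytic-motif columns shared by all sequences
(VAIK/HRD/DFG analogs — defaults K5, D25, D40-F41-G42 on a 60-column core);
per-group planted pattern columns, disjoint from each other and from the
catalytic columns, carried by subtree members with probability
`fg_match_prob` and by non-members with `bg_match_prob` (exactly: a
non-match draws from the background distribution excluding the pattern
residue); i.i.d. BLOSUM62-marginal background elsewhere; and uniform-length
insert segments at fixed points between conserved blocks. Patterns are
inherited down the tree, mirroring foreground-as-subtree semantics.

It deliberately does **not** simulate phylogenetic substitution processes (no
rate matrices or branch lengths — groups are exchangeable samples),
insertions with biased composition, gapped core columns (deletions are
exercised with constructed fixtures instead), or correlated columns.
Parameter recovery on this generator therefore demonstrates correctness of
the inference machinery, not performance on real superfamilies, where
phylogenetic correlation inflates pattern evidence and the effective-sequence
correction matters far more.

Generator defaults model the study conditions used throughout the tests:
4 groups, 5 planted columns per group at fg 0.95 / bg 0.05, 3 seed sequences
per group. The recovery experiments run at 100 sequences per group and the
null calibration at 50 per group over 10 seeds; sampler schedules (sweeps 40,
burn-in 25 for recovery; 30/20 for the null) keep a full suite run within a
couple of minutes on one CPU while leaving wide convergence margins.

## Numerical choices and degenerate inputs

Consensus ties: alphabetical. Assignment ties at T = 0: the current
assignment is kept if optimal (coordinate ascent), else the first optimal
leaf. Contrast with an empty foreground or background is defined as 0 inside
the sampler; the exported `column_contrast()` requires positive totals.
All-gap columns emit gap consensus and are excluded from weighting and
bootstrap pools. `freq_to_glyph()` rejects inputs outside [0, 1];
`'!'` requires weighted frequency within 1e-9 of 1. Profile duplication
invariance holds to 1e-9. The RNG is R's default; every stochastic entry
point takes an explicit seed and never falls back to wall-clock state.

## The pipeline interface

`run_pipeline()` executes any prefix of
simulate → align → cluster → bpps → cha → tree → classify from a YAML config
(see `inst/extdata/demo_config.yaml`), writing every artifact with a manifest
(config hash, seed) and logging per-stage row counts to stderr and `run.log`.
Config problems raise `corekin_config_error`, data problems
`corekin_data_error`; the thin wrapper `inst/scripts/corekin.R` maps these to
exit codes 2 and 3. Stage outputs are pure functions of (inputs, config,
seed); the tests assert byte-identical reruns.

## Limitations

* The hierarchy is input, never inferred; novel-subgroup detection is out of
  scope, as is structural alignment (the curated template is an input).
* The sampler's priors, penalty and annealing schedule are this package's own
  documented choices; they are not claims about any other implementation's
  internals.
* NJ trees are distance-based; for publication-grade phylogenies export the
  core alignment (`write_phylip_alignment()`) to an external ML tool and feed
  the resulting trees back through `extended_majority_consensus()`.
* CHA HTML output is a faithful data rendering, not publication-quality
  graphics.
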