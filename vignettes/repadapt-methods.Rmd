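---
title: "Models and methods behind repadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind repadapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(repadapt)
```

This vignette is the package's own account of its statistics: what each
method assumes, which knobs matter, how the synthetic-data generator is
built and calibrated, and where the genuinely open design choices were
resolved. No number quoted here is asserted anywhere except where the test
suite or `scripts/acceptance.R` computes it.

## Data model

The unit of replication is the *well*: one population founded from a known
ancestral genotype carrying a single first-step *background* mutation, later
sampled by sequencing a few clonal isolates. A dataset is a long table of
isolate × mutation calls (`read_mutation_table()`), with mutations keyed as
`position + ancestral base + derived base` (`1910aG`). All coordinates are
1-based inclusive. Calls are assumed to be *de novo relative to the well's
ancestor*: upstream read processing, variant calling and its coverage
thresholds are out of scope. Wells with fewer than four sequenced isolates
are removed by `apply_well_qc()` (tunable `min_isolates`, default 4), since
with three or fewer isolates the well-level mutation union and the within-
well tree are dominated by sampling noise.

A *reversion* is the back-mutation restoring the wild-type base at the
well's own background site; it is represented as an ordinary mutation record
plus the `is_reversion_key()` relation, so every analysis can include or
exclude reversions by flag (both variants are informative: reversion
opportunity is background-specific by construction, which is exactly the
kind of signal the epistasis tests should not silently absorb).

Contamination screening (`flag_contamination()`) implements the two
sequence-internal red flags — own background mutation lost *and* another
catalogued background mutation gained in the same isolate. The two further
forensic criteria used in plate experiments (haplotype links to a specific
neighboring well; rarity of reversion in that background) require cross-well
sequence forensics and are intentionally not automated.

## Parallelism

`pairwise_parallelism()` scores a pair of wells by the mean of the two
directed proportions of shared mutations. Two identity levels are offered:

* **nucleotide** — identical keys;
* **cluster** — a mutation of well *i* counts as "found in *j*" when *j*
  carries any mutation in the same regulatory feature, or the same codon of
  the same gene (`cluster_keys()`; for sites inside two overlapping genes
  the leftmost gene provides the codon label, deterministically).

The cluster level keeps the denominator at the number of nucleotide
mutations and coarsens only the matching relation. Written this way the
cluster level is monotone: every nucleotide match is also a cluster match,
so cluster-level *P<sub>ij</sub>* ≥ nucleotide-level *P<sub>ij</sub>* for
every pair — a property the test suite asserts across simulated datasets.
The alternative reading (map each set through the cluster function and apply
the set formula) loses that guarantee whenever one well carries two members
of the same cluster, which is precisely the situation a promoter hotspot
creates; we therefore use the per-mutation matching reading.

Two deliberate conventions:

* A pair in which one well has an empty mutation set (possible after feature
  exclusion) is *missing*, not zero — zero would conflate "nothing to share"
  with "nothing shared".
* The grand within-background mean is the **unweighted mean of the
  per-background means**, not the pooled pair mean, because backgrounds
  contribute unequal pair counts after QC removal; its SE is taken over the
  background means.

`background_effect_test()` partitions the sum of squares of the
within-background *P<sub>ij</sub>* values into between- and within-background
components; `R` is the between share (defined as 0 when all values are
equal). Because every well participates in many pairs, the values are not
independent and no F distribution applies; the null is generated by permuting
the well-to-background labels, which preserves the dependence structure of
the *P* matrix while breaking any background effect. `n_perm` defaults to
9,999; permutation p-values use the add-one estimator `(1 + #{R* ≥ R}) /
(n_perm + 1)`, so p = 0 is impossible. The same machinery drives the
within/between ratio test (`within_between_test()`, one-tailed for
ratio ≥ observed).

`occurrence_spectrum()` reports, per mutation, its well count, well
frequency, and squared frequency — the probability that two wells picked at
random both carry it — plus the unweighted mean squared frequency;
`group_features` pools all mutations of a feature into one identity first.

## Epistasis

**Mutation × background LRT.** Presence is scored at the *well* level
(mutation in ≥ 1 isolate), because the replicate is the well. For mutation
*k*: the null likelihood uses the pooled Bernoulli MLE across all *N* wells,
the alternative uses per-background MLEs; ΔlnL<sub>k</sub> ≥ 0 by
construction and Λ = Σ<sub>k</sub> ΔlnL<sub>k</sub> exactly (additivity is
asserted in tests). Mutations present in zero or all wells saturate both
models, contribute exactly zero, and are flagged. Asymptotic χ² theory is
unreliable here (many mutations sit at low counts), so the p-value comes
from well-label permutation. `stepwise_influential()` removes the mutation
with the largest ΔlnL (ties broken by lexicographic key), reruns the whole
test, and repeats until p ≥ α (default 0.05), returning the removal order
with the p-value after each removal.

**Reversion LRT.** Per-background binomial counts of reverted wells over
available wells (unequal totals allowed); 2Λ is referred to χ² with B − 1
degrees of freedom. With 9 backgrounds the counts are few but the χ²
approximation is the conventional choice for this nested binomial pair.

**Co-occurrence.** Reversions and singletons (well count < 2) are removed
first — the question is not pertinent to them. The unit of co-occurrence is
the isolate; the statistic is the number of wells in which a pair shares at
least one isolate. The null rewires each mutation independently while
preserving (i) its well count and (ii) its per-well isolate counts: the
occupancy pattern is placed on a freshly sampled well set and isolates are
resampled within wells (when a sampled well is too small for a count, counts
are reassigned to wells in decreasing-size order — a rare, size-feasibility
fallback). A simpler single-stage isolate shuffle is available
(`two_stage = FALSE`) for sensitivity analysis. P-values are two-tailed
(2 × min of the add-one tail estimates, capped at 1) so both attraction and
repulsion register. Pairs with p < 0.05 that co-occur exactly once are
dropped as the most obvious false positives. Mirroring exploratory practice,
`p` is uncorrected; a Benjamini–Hochberg column (`p_bh`) is emitted as a
clearly labeled extension. Blocks (e.g. all D-promoter mutations) aggregate
any-member co-occurrence, and the block-versus-itself row counts wells where
one isolate carries two *distinct* members.

## Within-well trees and dynamics

`build_tree()` reconstructs the well's clonal structure from the unique
observed genotypes, rooted at the ancestral (empty de novo) genotype.
Compatibility is the four-gamete condition against a known ancestral state:
no mutation pair may show the (1,0), (0,1) and (1,1) carrier patterns
simultaneously. For compatible matrices, inserting each genotype's
mutations — globally ordered by decreasing isolate count, ties lexicographic —
into a prefix tree yields the unique perfect phylogeny (each mutation labels
exactly one edge; reconstruction is invariant to isolate input order).
Unsampled intermediates appear as unobserved internal nodes.

For incompatible matrices the package initially builds the same greedy
prefix tree but then runs an exact search when the problem is small: in a
gains-only model, an optimal tree always exists whose internal nodes are
intersections of observed genotypes (a branching node can be raised to the
intersection of the genotypes below it without increasing total gains), so
the search enumerates subsets of the intersection-closure and lets every
node adopt its cheapest strict-subset parent — subset ordering makes cycles
impossible. The exact route runs when the closure adds at most 12 candidate
nodes and there are at most 30 mutations (`exact = TRUE` in the result);
beyond that the greedy tree is returned and flagged. We chose exactness over
the pure greedy heuristic after finding the greedy tree suboptimal on a
noticeable fraction of random incompatible toys; the test suite checks the
returned homoplasy count against an independent Dreyfus–Wagner oracle.
Homoplasy is the number of repeated edge labels; reversion keys are ordinary
derived characters.

`classify_dynamics()` partitions wells into four archetypes, tested in
order: all isolates identical (`fixed_identical`); every observed genotype
within one mutation of the shared core (`interference_star`, the classic
one-step clonal-interference pattern); observed genotypes totally ordered by
inclusion (`sequential_chain`); anything else (`branched_multistep`).

`classify_adaptive()` marks a mutation adaptive when it arises in ≥ 2 wells
independently, or when it rises unaccompanied: carried by
`min_isolates_for_rise` isolates (default 2 of the typical five — chosen as
the smallest count that is not a singleton observation; exposed because the
appropriate threshold depends on the sequencing depth per well) in a well
whose tree contains an edge where the mutation is the sole gain between the
root or an observed genotype and an observed genotype. The event-weighted
totals (each mutation multiplied by its well count) are reported alongside.

## Selection coefficients and lysis curves

`estimate_selection()` fits, per replicate, an OLS regression of log mutant
frequency on generations (default two generations per passage, matching
serial-transfer growth) and averages the replicate slopes; the SE is over
replicates. A pooled fit with shared intercept would weight time points
unequally across replicates; averaging replicate slopes matches the stated
"average over the six replicate estimates" design and keeps replicates
exchangeable. Frequencies of exactly 0 or 1 make the log transform
undefined; such replicates are excluded with a warning rather than patched
with pseudo-counts.

`summarize_lysis()` averages burst counts over replicates per genotype and
time point. "Titer begins to rise" is operationalized as the first time
point opening a run of `sustain` consecutive means above `threshold` × the
pre-rise baseline (the mean of the first `baseline_window` time-point
means). Defaults: threshold 2× (a doubling is comfortably outside counting
noise at typical plaque counts), baseline window 5 points, sustain 2 —
requiring persistence because a single Poisson spike in a count assay is not
a rise; diagnosing planted-truth simulations showed the one-point rule fires
early on isolated spikes. Delays are differences of lysis times on a shared
time grid and are reported with the threshold used.

## The synthetic-data generator

`simulate_dataset()` draws, per well: a truncated-Poisson number of de novo
mutations *m* (λ and support configurable); *m* distinct identities with
probability ∝ `plogis(qlogis(p_k) + δ_{k,b})`, so `δ` is an additive
background effect on the log-odds scale; a genotype tree grown by uniform
attachment (each new mutation attaches to a uniformly chosen existing
genotype, with attachments that would put two members of one exclusivity
group on the same root-to-leaf path rejected — different clades of one well
may still carry different group members, matching the isolate-level
exclusivity pattern); an optional reversion lineage with background-specific
probability; and `n` isolates sampled uniformly with replacement from the
non-root genotypes. One master seed drives deterministic per-(background,
well) substreams, so enlarging the design leaves earlier wells untouched.
The truth record stores every tree, attachment, reversion and sampled node.

Design choice: a generative uniform-attachment model replaces a
fitness-explicit Wright–Fisher simulation. The analyses consume only sampled
genotypes, and uniform attachment already produces all four dynamics
archetypes; a population simulator would add parameters the tests cannot
identify.

`study_preset()` fixes the study conditions: 9 backgrounds × 8 wells ×
5 isolates, 110 candidate mutations on the synthetic genome of
`synthetic_phage_annotation()` (a 5,577 nt microvirus-like layout with an
overlapping D/E gene pair, a D-promoter at 1909–1935 and a J-terminator —
all but the genome length and promoter interval invented, and labeled
synthetic), λ = 4.5 on [2, 9], a seven-member D-promoter exclusivity group
whose two hotspots have incidence 0.78 and 0.40, six moderate mutations
(0.05–0.10, four carrying planted δ of +2 to +3 on specific backgrounds),
and 97 rare mutations at 0.012/0.007. Reversion probabilities are 7/8 for
F416, zero for three backgrounds and 0.2 for the rest (15 expected reverted
wells of 72). The rare-mutation incidence was set once, in a pilot, so that
roughly 90% of wells carry a group member while most mutations land in four
or fewer wells; with five sampled isolates some lineages go unsequenced, so
the *observed* group coverage plateaus near 0.87 and the observed per-well
mutation union (~3.7) runs below the generated *m* (mean ≈ 4.66 after
truncation). Tests therefore check generated counts against the
truncated-Poisson oracle and observed coverage against a ±0.06 band around
0.9. Within-well genotype-frequency data do not exist for calibration, so
archetype frequencies are matched only qualitatively; fully swept wells in
particular are rarer under uniform attachment than in the motivating data.

What passing tests on this preset do **not** show about real data: the
generator has no linkage between wells, no mutation-rate heterogeneity along
the genome beyond the incidence vector, no within-well selection
differentials, and isolate sampling is uniform over genotypes rather than
over cell frequencies. Conclusions about method calibration (type-I error,
parameter recovery) transfer; conclusions about biological effect sizes do
not.

## Numerical choices

* Permutation/bootstrap p-values always use the add-one estimator; all
  randomized functions accept a `seed` and reproduce results exactly.
* Likelihoods use the x·log x → 0 convention at zero counts; per-mutation
  ΔlnL values are clipped at zero against floating-point negatives.
* Stepwise ties on ΔlnL break lexicographically by key.
* Degenerate inputs: all-equal *P* values give R = 0; a zero
  between-background mean makes the within/between ratio undefined (means
  are still reported, with a warning); wells empty after exclusion propagate
  as missing pairs.
* The exact parsimony search caps at 12 closure candidates / 30 mutations;
  beyond that `exact = FALSE` marks the greedy fallback.

## Problem sizes used by the test suite

Calibration experiments run 200 null datasets (4 backgrounds × 4 wells × 4
isolates, 25 mutations) at 199 permutations per test; power experiments run
100 datasets of the frozen planted-effect design (6 × 8 × 6, K = 30, planted
δ = +8 on a 0.01-incidence mutation); tree-reconstruction checks cover 500+
simulated wells and a fixture set of ≤ 6-mutation toys solved exhaustively.
These sizes were chosen to keep Monte-Carlo error well inside the asserted
bands while the full suite stays fast enough to run routinely.

## Known limitations

* The reproduction of the motivating study's published counts requires its
  deposited isolate spreadsheet, which the package does not redistribute;
  the corresponding acceptance test states exactly where to place the files.
* The supplementary randomization schemes of the original analyses are not
  printed in the main text; the label-permutation and marginal-preserving
  rewiring nulls here are the implementer's reading and are flagged as such.
* Whether "silent" should include intergenic non-regulatory changes is
  ambiguous; `annotate_mutation()` reports `functional_class = "silent"`
  with a separate `coding` flag so either counter can be formed.
* Newick serialization uses a small internal writer because genotype trees
  contain unsampled degree-2 nodes that `phylo` objects do not carry
  reliably; `ape` is used in tests to confirm the strings parse.
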