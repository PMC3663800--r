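---
title: "Classification-based analysis of paired miRNA/mRNA expression: models and methods"
author: "capeRNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classification-based analysis of paired miRNA/mRNA expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capeRNA)
```

## The problem

A miRNA that represses a target mRNA should leave a characteristic footprint
in paired expression profiles: samples in which the miRNA is high should show
the target low, and vice versa. Global correlation methods average this
signal over all samples; the approach implemented here instead classifies
**each sample individually** into discrete expression states and asks, per
putative interaction, how well the state pattern agrees with the experimental
groups. The package takes (a) a log-normalized miRNA matrix, (b) a
log-normalized mRNA matrix with a probe-to-gene map, (c) a catalog of
putative miRNA-target pairs (in practice from validated databases and
prediction intersections; catalog construction is out of scope), and (d)
sample group labels, and produces a ranked table of differentially regulated
interactions plus a bootstrapped estimate of how well they separate the
groups.

## Discretizing expression into low/medium/high states

All values are exponentiated (`exp(v)`) so that fold changes are well
defined; the analysis then only ever uses the *absolute fold change*

$$\mathrm{afc}(a, b) = \frac{\max(a, b)}{\min(a, b)} \ge 1,$$

which makes every downstream quantity invariant to a constant shift of the
log-scale data (equivalently, to a global rescaling). Two values are
*similarly expressed* when their afc is at most a neighborhood threshold $n$,
and *differentially expressed* when it exceeds a fold threshold $f > n \ge 1$.

For one probe with values $V$ ($|V| = m$ samples), every ordered pair of
distinct observed values $a < b$ is a candidate pair of *representatives*,
with neighborhoods $A = \{x \in V : \mathrm{afc}(x, a) \le n\}$ and $B$
likewise. A candidate pair is scored by

$$s(a, b) = |A \cup B| \cdot
  \frac{|A \cup B|}{p_A \, p_B} \cdot
  \frac{\min(|A|, |B|)}{\max(|A|, |B|)},
  \qquad p_A = \mathrm{afc}\!\left(a, \overline{A}\right),$$

where $\overline{A}$ is the mean of $A$ and all cardinalities count samples
(multiset semantics: duplicated values contribute once per sample). The two
coverage factors make data coverage count quadratically; the balance factor
discourages one-member-versus-everything splits; the penalties $p_A, p_B \ge
1$ discount representatives far from their neighborhood's center, and enter
only one of the two coverage factors so they stay subordinate to coverage.
The *final score* applies the separation constraint: it is $s(a, b)$ when
$\mathrm{afc}(a, b) > f$ and $0$ otherwise. The score's scale — counts, not
fractions — matters because the probe filter downstream compares it against
$t \cdot m$.

The global maximizer over all candidate pairs and all configured $(f, n)$
pairs defines the classification. Ties are broken deterministically: larger
joint coverage, then the earlier threshold pair, then the smallest $(a, b)$.
Boundaries are $b_1 = \max(A)$ and $b_2 = \min(B)$, switched if they cross;
a sample is `L` when $v \le b_1$, `H` when $v \ge b_2$, otherwise `M`, with
`L` taking precedence in the degenerate case $b_1 = b_2$. When no candidate
pair satisfies the separation constraint (a constant probe, or one whose
values all lie within a factor $f$), the best score is 0 and every sample is
assigned `M`: with no evidence of two expression levels, no sample is
extreme, and the probe is removed by the score filter anyway.

The candidate search is exhaustive over the $O(m^2)$ ordered pairs of
observed values, vectorized via membership-matrix cross products; an
independent plain-loop implementation of the same search backs the test
suite, and the two agree exactly (score, chosen thresholds, and states) on
hundreds of randomized probes.

### Threshold pairs and filter parameters

The configuration (`cape_config()`) carries the tunables; all are
dimensionless:

| parameter | default | meaning |
|---|---|---|
| `threshold_pairs` | (2.0, 1.5), (1.5, 1.25) | candidate $(f, n)$ pairs, fold-change scale |
| `probe_score_factor` $t$ | 0.5 | probes kept when best score $> t \cdot m$ |
| `medium_ratio_max` $r_M$ | 0.5 | rows dropped when the `M` fraction exceeds this |
| `undefined_freq_max` $u$ | 0.5 | interactions dropped when the undefined fraction exceeds this |
| `correlation_cutoff` | −0.4 | keep interactions with $\rho \le$ cutoff in ≥ 1 group |
| `present_call_min_fraction` | 0.20 | minimum present-call fraction per probe |

The threshold-pair list and the three filter parameters are package defaults
chosen to be reasonable on two-level log-expression data; when reproducing a
specific study they should be set to that study's values, which is why the
YAML configuration treats all four as mandatory keys. Both
frequency filters are strict ("exceeds"), so a row with exactly the
threshold fraction survives — the worked examples in the tests pin this down.

## Interaction states and differential regulation

Per sample, an interaction's state is the concatenation of the miRNA state
and the gene state, in that order, over the nine-state alphabet
$S = \{LH, HL, LM, HM, MH, ML, HH, LL, MM\}$, grouped as

- $S_{compHL} = \{HL, ML, HM\}$ — miRNA up, target down;
- $S_{compLH} = \{LH, MH, LM\}$ — miRNA down, target up;
- $S_{undef} = \{HH, LL, MM\}$ — no interpretation under the repression
  hypothesis.

mRNA probes mapping to the same gene are aggregated per sample by the modal
state with tie preference `L`, `H`, then `M`. The medium-ratio filter is
applied to the rows that feed interaction construction — miRNA probe rows
and aggregated gene rows — since `filter_by_medium_ratio()` is
level-agnostic it can equally be applied to raw probe matrices when a
probe-level reading is preferred. Interactions whose undefined fraction
exceeds $u$ are removed; the survivors are the *regulated* set.

Between two predefined groups, an interaction is *differentially regulated*
when the modal state of one group lies in $S_{compHL}$ and the other in
$S_{compLH}$. On modal ties the package resolves toward an interpretable
state: a comp state beats a tied undefined state, while a tie spanning both
comp sets disqualifies the interaction. The first draft treated every tie as
disqualifying, but that systematically discards strongly regulated
interactions — when the discretizer sub-splits one expression level (common
for a large group under the tighter threshold pair), half of that group's
samples land in an undefined state and produce exact comp-versus-undefined
ties. Undefined states are defined by their *lack* of biological meaning, so
letting them veto an interpretable modal state is the wrong reading.

## Ranking by partition agreement

Each interaction's states induce an *expected partition* of the samples into
$G_{HL}$, $G_{LH}$ and $G_{undef}$ by comp-set membership. Agreement with
the two experimental groups is measured by the pair-counting Jaccard index

$$J = \frac{N_{11}}{N_{11} + N_{10} + N_{01}},$$

counting unordered sample pairs co-clustered in both, only the first, or
only the second partition. This is the standard cluster-validity form and
the natural choice here because the two partitions have different block
counts (three expected blocks, two experimental groups); the three-block
expected partition is compared directly, with no merging of $G_{undef}$ into
either side. When no pair is co-clustered anywhere, $J$ is defined as 0 (no
agreement evidence). The implementation uses the contingency-table identity
$N_{11} = \sum_{ij} \binom{n_{ij}}{2}$; the tests verify it against explicit
pair enumeration on a thousand random partition pairs. Interactions are
ranked by decreasing $J$ with lexicographic tie-breaks, so the ranking is
fully deterministic.

## Correlation filter

Within each experimental group (two or three, mirroring tumor-only versus
full collectives), Spearman's $\rho$ (midrank ties) is computed between the
miRNA and the gene's log expression, the gene summarized as the mean of its
probes on the log scale. An interaction survives when $\rho \le -0.4$
(inclusive) in at least one group; an undefined $\rho$ (constant vector)
never satisfies the criterion.

## The vote-counting classifier and its bootstrap evaluation

A model built from the ranked list at a Jaccard threshold stores, per
selected interaction, the comp set containing the reference ("first")
group's modal state. A sample votes once per model interaction with an
available state: for the reference group when its state lies in the model's
comp set, for the other group when it lies in the opposite set, and not at
all on undefined states. The predicted label is the reference group iff its
votes strictly dominate; ties predict the non-reference group — conservative
toward the "negative" class, and the reason a chance-level classifier shows
complementary biases in sensitivity and specificity rather than 0.5/0.5.
Models can also be drawn uniformly without replacement from a Jaccard range
(`build_random_model()`), reproducibly under a seed.

The bootstrap protocol halves each group without replacement (odd groups put
the extra sample in training), runs the full analysis independently on the
training and the test halves, builds the model from the training ranking,
and classifies the test samples from their own interaction states. Model
interactions absent from the test-side regulated set are skipped in voting,
and a test sample with no available model interaction falls to the tie rule
— the minimal reading of "computed and classified separately for each
training and each test set"; re-running differential *selection* on the test
side would leak the test labels into the evaluation and is deliberately not
done. Replicate $r$ uses seed $\mathrm{base} + r$, so replicates are
individually reproducible and independent of execution order. Replicates
whose training half yields no model at a threshold are recorded as skipped;
means are unweighted over the non-skipped replicates, with sensitivity,
specificity and FPR defined with the reference group as positive.

## Embedding, clustering, PCA

For sample-level exploration, interaction states are substituted by the
antisymmetric numeric code (`LH` → −1, `MH`/`LM` → −0.5, `LL`/`MM`/`HH` → 0,
`HM`/`ML` → 0.5, `HL` → 1), inter-sample distances are city-block, and the
distance matrix is clustered with Ward's method (`hclust(method =
"ward.D2")`, the Lance–Williams Ward update applied to the provided
dissimilarities). Ward's criterion classically presumes squared Euclidean
input; applying it to city-block distances follows the method being
reproduced — fidelity over orthodoxy — and the dendrogram should be read as
exploratory. PCA treats the $N \times N$ distance matrix as $N$ observations
in $N$ dimensions, centers columns (no scaling), and fixes each component's
sign so its largest-magnitude loading is positive, making coordinates
reproducible; explained-variance fractions sum to 1 by construction.

## The synthetic benchmark

`simulate_dataset()` generates the study conditions used throughout the
tests: 24 samples in three groups of 8 (two tumor stages and a normal group,
contrasted tumor versus normal), a 500-pair catalog with 50 planted
interactions, level separation of 2 natural-log units ($e^2$-fold), and
within-state noise sd 0.2 on the log scale. Planted pairs are bimodal with
the miRNA and target on opposite levels per sample; decoys sit at a single
level (pools of 150 decoy miRNAs × 200 decoy genes shared across the 450
decoy pairs). Half of the planted pairs' noise variance
(`anticorr_share = 0.5`) is a per-sample latent shift applied with opposite
signs to the miRNA and the target; this gives planted pairs a within-group
Spearman correlation around −0.5 so the correlation filter is actually
exercisable on synthetic data, while keeping the total within-state sd
exactly at `noise_sd` — modelled as a variance share rather than an extra
additive term precisely so the stated noise condition holds. A
`flip_fraction` knob flips individual samples' side assignment per planted
pair (per-sample biological heterogeneity); at 0.5 the group association is
erased, which is the package's pure-noise fixture.

The generator emulates what the algorithm assumes — two log-expression
levels, additive Gaussian within-level noise, a fixed catalog — and nothing
else. It does not model batch or dye effects, probe cross-hybridization,
intensity-dependent variance, correlated decoys, or realistic miRNA target
multiplicity. Passing the benchmark therefore demonstrates that the
implementation recovers planted structure under its own model assumptions,
not that the method performs equivalently on real microarray data.

## Problem sizes and determinism

The test suite and the acceptance script run the benchmark at the sizes
above: the discretizer-versus-brute-force check uses 200 random probes of up
to 10 samples, the Jaccard check 1000 random partition pairs of up to 12
samples, the strong-effect bootstrap 100 replicates and the pure-noise
bootstrap 50 — sizes at which the exhaustive oracles are exact and the whole
suite completes in a few minutes on one core. Every stochastic step
(generator, splits, random models) is seeded explicitly, and identical
inputs give bit-identical outputs; the deterministic tie-breaks in the
discretizer, the ranking and the aggregation exist for exactly this reason.

## Known limitations

- The discretizer assumes at most two genuine expression levels; multi-modal
  probes are forced into low/high plus a medium band.
- The score filter, medium-ratio and undefined-frequency defaults are
  package choices, not universal constants; studies should set them
  deliberately.
- Group sizes below ~3 per half make the bootstrap's per-replicate rates
  coarse (steps of 1/2 or 1/3), so means should be read accordingly.
- The correlation filter needs ≥ 3 samples per group for a defined rank
  correlation and treats gene expression as the unweighted mean over probes.
- With block-level (two-state) data the within-group correlation of a
  genuinely regulated pair can be weak; on real data the filter is a
  stringency knob, and on synthetic data it is only meaningful because the
  generator plants within-group anticorrelation.
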