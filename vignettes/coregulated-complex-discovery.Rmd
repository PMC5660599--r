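---
title: "Discovering co-regulated protein complexes from tumor proteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering co-regulated protein complexes from tumor proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coregcomplex)
```

## The problem

Mass-spectrometry proteomics can now quantify thousands of proteins across
dozens of tumor samples. Subunits of a stable protein complex tend to rise and
fall together across such samples — partly through shared transcriptional
programs, and partly through post-transcriptional mechanisms such as
degradation of unassembled subunits. `coregcomplex` exploits this: it searches
for disjoint sets of proteins that are simultaneously (i) highly co-expressed
across tumor proteomes and (ii) densely connected on a protein–protein
interaction (PPI) network, and then quantifies how those complexes behave —
which are over- or under-expressed in particular tumor subtypes, and which
lose abundance *in trans* when one subunit is mutated or deleted ("collateral
loss").

Neither evidence source suffices alone. Co-expression without interaction
evidence picks up co-regulated but physically unrelated programs (e.g. shared
chromosomal location or a common transcription factor); interaction density
without co-expression picks up hub neighborhoods and transient interactions.
The central design rule, enforced everywhere in the pipeline, is therefore
**dual evidence**: a protein set is only ever reported, and a clustering move
is only ever accepted, when both evidence scores support it.

## The model

### Pair evidence as log-likelihood ratios

For every pair of proteins two raw features are computed:

* the Pearson correlation $r_{AB}$ of their expression profiles over
  pairwise-complete samples (`pairwise_correlation()`), and
* a shared-partner score on the PPI network (`weight_network()`): with the
  two proteins themselves excluded from both neighbor sets and from the
  universe of $N$ remaining network nodes, the upper-tail hypergeometric
  probability of observing at least the shared number of partners given the
  two degrees, reported as $-\log_{10} p$. Only directly interacting pairs
  are scored — interaction evidence is gated on an edge.

Each feature is calibrated into a log-likelihood ratio for co-complex
membership against a reference catalogue (`fit_llr_model()`). Positive
training pairs are co-annotated in a reference complex of at most 30 subunits
(larger assemblies would dominate the pair counts); negatives are sampled
from measured pairs at 300 negatives per positive, a ratio consistent with
estimates of the density of the human interactome. A logistic regression of
the label on the single feature gives the posterior $\hat p(f)$, and because
the class ratio is fixed by construction, the exact Bayes identity

$$\mathrm{LLR}(f) \;=\; \operatorname{logit}\hat p(f) - \operatorname{logit}(\text{prior})
  \;=\; \beta_0 + \beta_1 f + \log(\text{ratio})$$

equals $\log P(f \mid \text{co-complex}) - \log P(f \mid \text{background})$
with no binning or density estimation of the background. This closed form is
the package's one deliberate reinterpretation of the usual
"$P_\text{within}/P_\text{background}$" recipe: it is numerically stable,
monotone in the feature, and exactly additive. A pair lacking an evidence
source (undefined correlation, or no edge) contributes an LLR of 0 from that
source — neutral, not a penalty.

Two calibration details matter. First, the background for the *interaction*
model is the set of **all** measured pairs, not the set of edges: negatives
are sampled from all pairs and a non-interacting pair carries a
shared-partner feature of 0 (`default_feature = 0`). Calibrating against
edges only conditions away the very enrichment that makes interaction
evidence informative and, on sparse networks, caps the negative pool so low
that genuinely shared-partner edges end up with negative LLRs. Second, the
realized negative:positive ratio (after availability truncation) is used for
the prior, so the identity above stays exact.

The integrated score of a protein set $S$ is the sum of
$\mathrm{LLR}_\text{expr} + \mathrm{LLR}_\text{int}$ over all unordered pairs
in $S$ (`score_set()`).

### Constrained agglomerative search

`discover_complexes()` seeds clusters greedily from all interacting pairs and
all 3-cliques whose expression LLR *and* interaction LLR are both positive,
taking the best-scoring candidate, discarding overlapping candidates, and
repeating; everything else starts as a singleton. Refinement then iterates
three moves — merging two clusters, removing one protein into a singleton,
and switching one protein between clusters — always applying the move with
the largest integrated gain, and **only** accepting moves that increase both
evidence scores. The search stops when no move qualifies.

The move semantics follow the constraint's intent: merge candidates are
restricted to cluster pairs joined by at least one network edge and switch
targets to clusters containing an interaction partner of the moving protein,
because a move without any cross edge cannot increase the interaction score.
Ties are broken deterministically (lexicographic order of the sorted member
identifiers at seeding; a fixed enumeration order for moves), so reruns with
identical inputs are byte-identical. The inner loop is compiled (Rcpp) and
caches per-cluster row sums of the pair-LLR matrix, making merge deltas
$O(\min(|A|,|B|))$ and remove/switch deltas $O(1)$; an iteration cap
(default 10,000 moves) guards against pathological inputs.

### Empirical FDR by gene-label shuffling

Some interacting protein sets will be co-expressed by chance. To calibrate
this, the full discovery is rerun on randomized inputs in which the
gene-identifier-to-expression-profile assignment is shuffled while the
network stays fixed (`estimate_fdr()`; default 100 randomizations, the tests
and the acceptance script use 25). For every observed cluster-score threshold
$t$, the FDR is the mean number of genes assigned to clusters scoring
$\geq t$ in the randomized runs divided by the corresponding count in the
real run, regularized by a running minimum to be non-increasing in $t$. The
reported catalogue is all clusters of at least two proteins at the smallest
threshold achieving FDR $\leq$ 10% (configurable). The LLR models are fitted
once on the real data and reused across randomizations: refitting on shuffled
data would degenerate the expression model and make thresholds incomparable
across runs. Randomization counts genes, not clusters, so one large spurious
cluster is penalized in proportion to its size.

## Downstream statistics

**Subtype-specific complex expression** (`subtype_complex_enrichment()`) is a
rank-based variant of 1D annotation enrichment: per subtype, each protein's
median expression in the subtype minus its median elsewhere forms a ranked
list, and each complex with more than two measured members is tested
two-sidedly (Mann–Whitney) for sitting at one extreme of that list. The
effect size is the rank-biserial correlation $s = 2U/(n_1 n_2) - 1 \in
[-1, 1]$, an operationalization that shares the range and sign convention of
the s-score used with 1D enrichment. BH correction is applied across all
complex-by-subtype tests as one family.

**Collateral loss** (`complex_collateral_test()`): protein abundances are
converted to within-sample ranks (rank 1 = lowest; ties averaged; missing
values excluded), the per-sample mean rank of the complex members is computed
with the altered gene excluded, and a one-sided Mann–Whitney test asks
whether altered samples sit lower. For deletion-containing alteration modes,
members on the same chromosome as the altered gene are also excluded so that
co-deletion in *cis* cannot masquerade as a *trans* complex effect; in
mutation-only mode just the altered gene is excluded, since point mutations
do not co-occur along a chromosome arm. Genes require at least three altered
samples to be tested (the hemizygous-deletion analyses this mirrors used the
same floor), and all (gene, complex) tests form one BH family per alteration
mode. Rank statistics make the test invariant to any monotone transform of
the expression scale.

**Alteration profiles** (`build_alteration_profile()`): GISTIC-style calls
of −2 mean homozygous deletion and −1 hemizygous deletion; damaging mutations
are missense, splice-site, insertion, deletion and nonsense calls —
synonymous and unclassified events never count.

**Catalogue overlap** (`catalogue_overlap()`) reports, per discovered
complex, the best-overlapping reference complex by upper-tail hypergeometric
test over the universe of genes present in both the expression data and the
network, with Jaccard and coverage, BH-corrected.

**Isogenic differential expression**
(`isogenic_differential_expression()`) reproduces the label-free pipeline for
an engineered knockout-versus-parental comparison: technical replicates are
averaged, missing intensities are imputed with each sample's minimum observed
intensity (a missing protein is assumed at or below the detection limit),
values are log2-transformed, and each protein gets a two-sided Welch t-test
with BH correction.

## The synthetic test bed

`simulate_dataset()` generates the full input bundle with known ground truth.
Each planted complex follows a one-factor model: member $g$ has expression
$x_g = a f_c + \varepsilon$ with unit-normal factor and noise and loading
$a = \sqrt{r/(1-r)}$, so the expected within-member correlation is exactly
the configured $r$ (the default 0.7 matches the strength of co-regulation the
discovery method is designed for; the realized mean tracks the target to
within sampling error, which the tests check at $n = 2000$ samples). Members
are wired with probability 0.9, background edges are uniform over non-planted
pairs, and missingness is completely at random with per-gene rates drawn from
U(0, 0.3) — the upper end of what the 40% missing filter tolerates.

The default study conditions — 1,000 genes, 60 samples, 25 complexes of 3–12
subunits, 2,000 background edges — are a desk-scale stand-in for a tumor
proteome cohort: large enough for hub effects, triangles and chance
correlation to appear, small enough that a full discovery with 25 FDR
randomizations runs in well under a minute. Subtype shifts and collateral
events are expressed in SD units of each gene's marginal distribution so
power targets transfer across configurations. Collateral events depress the
altered gene in both the protein and the mRNA matrix but depress its complex
partners in the protein matrix only — encoding the post-transcriptional
signature (protein-level, not mRNA-level, partner loss) the method is meant
to detect. Two decoy classes probe the dual-evidence constraint: correlated
sets without planted edges, and fully wired cliques without correlation.

What the generator does **not** emulate: intensity-dependent (informative)
missingness, batch effects, segment-level copy-number structure, overlapping
complexes, and isoform-level variation. Passing tests therefore demonstrate
the statistical machinery under the model's assumptions, not performance on
any particular real cohort.

For LLR calibration in the benchmarks, the training reference is the planted
truth perturbed by dropping and adding 20% of members per complex
(`perturb_reference()`), emulating an imperfect curated catalogue rather than
granting the method oracle knowledge.

## Numerical and design choices

* Correlations require at least `min_overlap = 10` pairwise-complete samples
  (Pearson on fewer is noise-dominated); pairs below the floor, or with zero
  variance over the overlap, contribute zero expression evidence.
* The missing filter drops genes missing in strictly more than 40% of
  samples; exactly 40% is kept. Isoform collapse (missing-ignoring mean per
  sample) runs before the filter, so isoform-level missingness can be rescued
  by averaging.
* Hypergeometric tails are computed in log space and capped at
  $-\log_{10} p = 300$; the two degree arguments are ordered canonically so
  the score is bit-exactly symmetric.
* Mann–Whitney p-values are exact (null U distribution) for
  $n_1 + n_2 \le 12$ without ties, otherwise a normal approximation with tie
  and continuity corrections; all values tied gives $p = 1$.
* Perfect separation in LLR calibration falls back to a ridge-penalized fit.
* Greedy seeding does not re-score 3-cliques after removals (candidates are
  static); refinement compensates. Clusters below the FDR threshold are
  pruned whole, not gene by gene.
* FDR thresholds are evaluated exactly at the observed real cluster scores —
  there is no information between them.

## Known limitations

Complexes whose members share no interaction partners at all (for example a
three-protein complex wired as a path, with no triangle) cannot satisfy the
dual-evidence seeding filter and are unrecoverable by design — on sparse
synthetic networks this is the dominant failure mode behind the measured
recall. Overlapping complexes and complex isoforms are out of scope: each
protein belongs to at most one reported complex. The empirical FDR inherits
Monte-Carlo noise from the number of randomizations; 25 randomizations bound
it adequately at desk scale but 100 (the default) is preferable when runtime
allows.
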