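---
title: "Reconstructing clonal evolution from diagnosis to relapse with clonemix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing clonal evolution from diagnosis to relapse with clonemix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A paired tumour design — the same patient sampled at diagnosis, at remission
and again at relapse, each deeply sequenced — makes it possible to ask which
subpopulations of tumour cells (clones) survived therapy, which were
eradicated, and what the survivors acquired on the way to relapse. The raw
signal is, per somatic variant $i$, a pair of read counts $(X_i, N_i)$ at
each timepoint: $X_i$ mutant reads out of $N_i$ total. For a heterozygous
mutation in a copy-neutral diploid region, carried by a fraction $f$ of
tumour cells in a sample of tumour purity $u$, the expected mutant allele
fraction (MAF) is $u \cdot f / 2$. Mutations born in the same clone share a
carrier fraction, so their MAFs cluster; clusters, converted back to cell
fractions, can be assembled into a lineage.

`clonemix` implements this entire workflow: presence calling and
categorisation of variants, coverage-aware binomial mixture clustering with
AIC model selection, purity estimation, greedy lineage construction with
population accounting, relapse-founder mapping, biological resolution of
ambiguous parentage, compound binomial tests of cluster distinctness,
detection-power calculations, read-level screening of low-frequency mutant
evidence, and a synthetic generator that produces ground-truth clonal
architectures for validating all of the above.

## The binomial mixture model

Variants are first split into three categories by presence calls
(`classify_presence()`): *diagnosis-specific*, *relapse-specific* and
*shared*. Presence at a timepoint requires MAF $\ge$ 0.01 **and** at least 3
mutant reads; 0.01 is the detection floor at the deep combined coverages
this design assumes (the package's power calculator makes that concrete:
`detection_power(883, 0.01)` $\approx 0.99$).

Within a category, mutant counts are modelled as a finite mixture of
binomials,

$$X_i \sim \sum_{k=1}^{K} \lambda_k \,\mathrm{Binom}(N_i, p_k),$$

where $p_k$ is the MAF centre of cluster $k$ and $\lambda_k$ its mixing
weight. Because the binomial variance shrinks with depth, a variant covered
2,000-fold constrains the centres far more than one covered 100-fold — this
is the "coverage-aware" property that separates this model from naive
clustering of MAF ratios. For shared variants the model is multiplicative:
each cluster carries an independent diagnosis centre and relapse centre and
a variant's likelihood is the product of its two binomial terms
(`fit_shared_mixture()`). This is what separates a founder cluster from a
minor rising cluster when both are clonal at relapse but differ at
diagnosis.

Fitting is by EM. The E-step computes responsibilities in log space; the
M-step updates each centre as the responsibility-weighted pooled MAF
$\sum_i z_{ik} X_i / \sum_i z_{ik} N_i$ (for $K = 1$ this gives the pooled
MAF exactly, a closed form the tests exploit). Initialisation uses centre
quantiles of the raw MAFs plus 10 jittered restarts from a seeded
generator, keeping the best-likelihood solution — deterministic under a
seed, robust to the occasional bad start. Convergence is declared when the
log-likelihood improves by less than $10^{-8}$ (or at 500 iterations);
centres are clamped to $[10^{-6}, 1 - 10^{-6}]$ to avoid degenerate
likelihoods; the log-likelihood trace is retained and asserted
non-decreasing in the test suite.

**Model selection.** $K$ is chosen by minimising
$\mathrm{AIC} = 2k - 2\ln L$ over $K = 1 \ldots K_{\max}$, ties toward
smaller $K$. The free-parameter counts are $k = 2K - 1$ for the
timepoint-specific model ($K$ centres, $K-1$ free weights) and $k = 3K - 1$
for the shared model ($2K$ centres, $K-1$ weights) — standard mixture
counting that matches the models' actual parameterisation.

A property worth stating plainly, because it shapes what validation can
promise: AIC is a liberal criterion for mixtures. At the depths this design
targets (~800-fold), the binomial likelihood is precise enough that a
cluster whose members happen to scatter slightly bimodally can support a
genuine maximum-likelihood split into two centres a few hundredths apart,
and the likelihood gain occasionally exceeds AIC's penalty. In repeated
simulations under the generator's default conditions this selects one
spurious extra cluster in roughly one fit in twelve; the recovery rates
reported by `scripts/acceptance.R` quantify it exactly. In practice this
criterion is usually tempered by manual review of the resulting lineages;
`clonemix` instead propagates the consequence honestly — an
overfit split either nests harmlessly (both halves attach at the same
place) or produces a pigeonhole contradiction that surfaces as an explicit
infeasibility error, never a silently wrong tree.

## Purity

`estimate_purity()` clusters one timepoint's diploid coding SNV counts with
the same binomial mixture and returns twice the highest cluster centre
among centres $\le 0.5$: clonal heterozygous mutations sit at MAF $= u/2$,
and centres above 0.5 indicate loss of heterozygosity rather than the
clonal diploid peak. If every centre exceeds 0.5 the estimator refuses
(that input cannot be what the model assumes). This step is often done with
a Gaussian model-based clustering of raw MAFs; `clonemix` instead reuses its
own coverage-aware binomial mixture with the identical estimator definition,
and the test suite cross-checks the two routes against each other.

## Lineage construction

`cluster_cell_fraction()` converts centres to cell fractions,
$f = \min(1, 2 \cdot \mathrm{MAF} / u)$, warning when a centre materially
exceeds the clonal expectation $u/2$.

`build_lineage()` is a greedy allocator built on the pigeonhole (sum) rule:
within a lineage, sibling subclones cannot jointly exceed their parent.
Shared clusters are processed first in descending diagnosis fraction — the
largest is the founder clone, ancestral to both timepoints. Each subsequent
cluster becomes a clone attached to the established clone with the largest
residual (unallocated) population, which is then debited by the newcomer's
fraction. Diagnosis-specific clusters follow by the same rule;
relapse-specific clusters are attached analogously using relapse fractions
and relapse residuals.

Three design choices were genuinely open:

* **Feasibility is checked at both timepoints for shared clusters.** A
  shared cluster persists, so its parent must accommodate it at diagnosis
  *and* at relapse; parent preference still follows the diagnosis residual.
  Without this, a noisy relapse fraction can silently drive a relapse
  residual far negative; with it, the same situation either finds the
  consistent parent or fails loudly.
* **Tie-breaking.** Exact residual ties go to the clone nearer the founder
  (parsimony), then lexicographically — reconstruction is fully
  deterministic, and every multi-candidate attachment is recorded as an
  ambiguity rather than discarded.
* **Slack $\varepsilon = 0.05$** (absolute cell fraction, configurable) on
  all pigeonhole comparisons, matching sampling noise of cluster centres at
  these depths. A cluster no candidate can hold within $\varepsilon$ is an
  explicit infeasibility error naming the cluster.

A clone whose population is entirely explained by its descendants at both
timepoints (residual below the 1% detection floor) is flagged `inferred`:
the classic case is a founder seen only through its children, which the
evidence requires but the sample cannot display as its own population.

**Relapse founders.** A diagnosis clone's lineage survived therapy iff every
cluster on its path is shared — a diagnosis-specific cluster anywhere on the
path means that lineage died. `map_relapse_founders()` takes the deepest
surviving clones as the relapse progenitors, one founder edge each; two or
more edges is a dual-lineage relapse, and the edge table carries dominance
flags so a reversal of clonal dominance between timepoints can be read off
directly.

**Ambiguity resolution.** `resolve_ambiguity()` re-runs the greedy
allocation and, wherever several parents could hold a cluster within
$\varepsilon$, applies two biological filters before the default
largest-residual choice: (1) *mutual exclusivity* — a candidate whose path
already carries an activating driver in the same gene or pathway as the
child is rejected (two activating hits in one pathway on one lineage path
are implausible; e.g. multiple hotspot mutations of the same kinase belong
in sibling clones); (2) *mutation spectrum* — candidates whose
lineage-specific transition/transversion spectrum differs significantly
from the child's (two-sided Fisher exact test, $p < 0.05$) are rejected,
which is decisive in mismatch-repair-deficient hypermutators where late
clusters are ~99% transitions against a ~77% background. Whatever remains
unresolved is annotated with all retained alternatives — never silently
dropped.

**SVs and CNVs** cannot be quantified from capture read depth, so
`place_sv_cnv()` places them by rule: ancestral/predominant by default
(fusions are typically initiating events), subclonal-at-diagnosis when deep
capture finds an event WGS missed, or when a manual review flag overrides an
automated relapse-specific call; contradictory flag combinations are errors.

## Distinctness of low-frequency clusters

When a relapse cluster is absent at diagnosis, one must ask whether it was
truly absent or merely below detection as part of a low-MAF parent. With
parent MAF $\alpha$ and per-site coverages $N_i$, the per-site probability
of seeing zero mutant reads by chance is $(1-\alpha)^{N_i}$
(`misclassification_p()`); sites with $p \le 0.05$ are individually
"unlikely to be misclassified", and the compound P value is the upper
binomial tail $P(X \ge x \mid n, 0.05)$ over the $n$ sites
(`compound_distinctness_p()`). Both thresholds are inclusive; tails are
computed in log space and remain stable down to $p \sim 10^{-300}$. One
numerical caution: per-site probabilities depend on the *actual* per-site
coverage, not a summary minimum — at exactly 520-fold and $\alpha = 0.01$
the per-site value is $(0.99)^{520} = 0.0054$, and smaller quoted per-site
values for such configurations imply per-site coverages above that minimum.
The compound value for five such sites ($0.05^5 \approx 3\times10^{-7}$) is
insensitive to this, since all five sites clear the 0.05 cutoff either way.

## Read-level screening

Low-MAF presence calls ultimately rest on a handful of reads, so
`screen_site()` re-examines each mutant-supporting read: PCR duplicates are
dropped; each read is locally realigned (Smith–Waterman, match +2, mismatch
−1, gap open −3, gap extend −1 — chosen to prefer one short gap over
scattered mismatches, the artefact mode the check targets) against the
reference window, and a read whose best alignment restores the reference
base was an alignment artefact; a read whose variant base is the *strict*
minimum of base quality in a 5-bp window is a sequencing-error "valley"
(ties pass — flat-quality reads should not be discarded); and if every
surviving read lies in the overlap of its mate pair, the site's support is
a fragment-level artefact and fails as a whole. Presence requires at least
3 surviving non-duplicate reads. The alignment is validated in the test
suite against an independent brute-force affine-gap dynamic program on
short fixtures.

## The synthetic generator

`simulate_case()` emulates the study conditions the analysis assumes, and
its defaults are fixed at those conditions rather than tuned per
experiment: mean depth 883 (deep exome plus targeted-capture coverage
combined) with Poisson-distributed per-variant totals (only a mean
fold-coverage is assumed; Poisson is the standard parameter-free choice,
and a deliberate idealisation — real capture depth is overdispersed); purity 0.9 at both timepoints (typical high-blast
leukaemia); a founder plus diagnosis subclones of which one survives —
by default the *minor* subclone, with diagnosis cell fraction drawn from
5–18%, matching the observation that rising clones are usually minor
(median ~7%); 8–15 mutations per cluster (observed median ~11 per clone);
mutational spectra at 77% transitions, or 99% for relapse-specific clusters
in hypermutator mode; remission counts clean by default, with an optional
residual-disease MAF for minimal-residual-disease scenarios. Cluster
centres competing within one mixture fit are kept $\ge 0.05$ apart on the
MAF scale so that model selection has a well-posed answer (configurable
down to adversarial overlap). Mutant reads are drawn
$\mathrm{Binom}(N, u \cdot f / 2)$ — diploid heterozygous SNVs only.

What passing recovery tests on this generator shows, therefore, is that the
pipeline correctly inverts its own generative assumptions at realistic
depth and architecture. What it does not show: robustness to copy-number
change under the variant (such loci are excluded by the diploid flag),
overdispersed depth, sample swaps, or mutation clusters closer than the
separation floor.

## Problem sizes and reproducibility

Every stochastic step is seeded; a pipeline run is byte-reproducible from
its config echo, and the simulator is byte-identical under a fixed
configuration and seed. The validation suite and the acceptance script use
100-seed replications for recovery metrics (100 variants across three
clusters for centre recovery; the generator's default five-cluster
architecture for end-to-end lineage recovery) — large enough that the
recovery rates are stable to a few percent, small enough to run comfortably
on a laptop. `scripts/acceptance.R --seed <s> --out <path>` recomputes all
headline quantities from scratch.

## Known limitations

* Non-diploid variants are carried through ingestion but excluded from
  clustering; there is no CNV-aware multiplicity model.
* Exactly two tumour timepoints; no multi-sample generalisation.
* The greedy allocator is order-dependent by design; it does not search
  tree space, and with `resolve_ambiguity()`
  it reconsiders parentage only within the recorded feasible candidates.
* AIC's liberality at deep coverage (discussed above) bounds achievable
  model-selection accuracy at around 90–95% per fit under the default
  conditions; consumers needing conservative cluster counts should inspect
  the per-K candidate table in every fit object.
* Population sizes can be displayed either as fractions of all cells or of
  tumour cells; `clonemix` emits purity-normalised cell fractions (fractions
  of tumour cells) throughout. When a relapse founder maps to multiple
  diagnosis clones, the diagnosis-side fractions are reported per edge
  without reapportioning.
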