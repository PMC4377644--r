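# clonemix

Reconstruction of tumour clonal architecture and its evolution between
diagnosis and relapse from deep-sequencing read counts, for cancer genomics
analysts working with paired (diagnosis / remission / relapse) tumour
samples — the design used to study how leukaemic subclones rise and fall
under therapy.

## What it computes

For each somatic variant $i$ the input is a pair of read counts
$(X_i, N_i)$ per timepoint: $X_i$ mutant reads of $N_i$ total. For a
heterozygous mutation in a copy-neutral diploid region carried by a cell
fraction $f$ in a sample of purity $u$, the expected mutant allele fraction
(MAF) is $u f / 2$. `clonemix` turns these counts into a clonal lineage:

* **Presence and category** — a mutant allele is present at a timepoint
  when MAF ≥ 0.01 and ≥ 3 mutant reads support it; the two tumour calls
  categorise each variant as diagnosis-specific, relapse-specific or
  shared.
* **Coverage-aware clustering** — mutant counts are modelled as
  $X_i \sim \sum_k \lambda_k\,\mathrm{Binom}(N_i, p_k)$, fitted by EM; for
  shared variants each cluster has a diagnosis and a relapse centre and the
  per-variant likelihood is the product of the two binomial terms. The
  number of clusters is selected by $\mathrm{AIC} = 2k - 2\ln L$.
* **Purity** — twice the highest cluster centre ≤ 0.5 among diploid coding
  SNVs, per timepoint.
* **Lineage** — clusters become clones with cell fractions
  $f = 2\,\mathrm{MAF}/u$; a greedy allocator attaches each cluster to the
  established clone with the largest residual population (the pigeonhole
  sum rule), maps relapse founders to surviving diagnosis clones, and
  resolves ambiguous parentage by driver mutual exclusivity and
  transition/transversion spectrum tests.
* **Statistics** — detection power $P(X \ge r \mid N, \mathrm{MAF})$;
  compound binomial tests of whether a cluster absent at diagnosis is
  distinct from a putative low-MAF parent; Fisher exact comparison of
  mutation spectra.
* **Read-level screening** — Smith–Waterman realignment of
  mutant-supporting reads, quality-valley and mate-overlap artefact
  filters, and the ≥ 3 non-duplicate read rule.
* **Synthetic generator** — clone trees with ground truth (cell fractions,
  purity, cluster memberships, spectra, hypermutator mode) for validating
  recovery; every stochastic step is seeded.

See the methods vignette (`vignettes/clonal-evolution.Rmd`) for models,
parameter choices and known limitations.

## Worked example

Simulate a case with the default architecture (founder + two diagnosis
subclones of which the minor one survives, two relapse-specific clones,
~883× coverage, purity 0.9) and reconstruct it:

```r
library(clonemix)
rep <- run_pipeline(list(simulate = list(seed = 42), seed = 42, K_max = 4))
print(rep)
#> clonemix run report (version 0.1.0)
#>   58 variants; purity dx 0.906 / rel 0.907
#>   clusters:
#>  label     category center_dx center_rel n_variants cf_dx cf_rel
#>     s1       shared    0.4531      0.455         11 1.000  1.000
#>     s2       shared    0.0735      0.458         11 0.162  1.000
#>     d1  dx_specific    0.3139      0.000         15 0.693  0.000
#>     r1 rel_specific    0.0000      0.448         12 0.000  0.987
#>     r2 rel_specific    0.0000      0.188          9 0.000  0.414
#> Clonal lineage: 5 clones, founder cluster 's1' (epsilon 0.05)
#>  clone_id cluster     category cf_dx cf_rel parent_dx parent_rel inferred
#>   clone_1      s1       shared 1.000  1.000      <NA>       <NA>    FALSE
#>   clone_2      s2       shared 0.162  1.000        s1         s1    FALSE
#>   clone_3      d1  dx_specific 0.693  0.000        s1       <NA>    FALSE
#>   clone_4      r1 rel_specific 0.000  0.987      <NA>         s2    FALSE
#>   clone_5      r2 rel_specific 0.000  0.414      <NA>         r1    FALSE
#> Relapse founder edge(s):
#>  clone_id cluster cf_dx cf_rel dominant_dx dominant_rel
#>   clone_2      s2 0.162      1        TRUE         TRUE
#>   distinctness of r1 from diagnosis alpha 0.07346: compound P = 2.44e-16
#>   distinctness of r2 from diagnosis alpha 0.07346: compound P = 1.95e-12
```

Reading the report: the founder cluster `s1` (MAF ≈ 0.45 at both
timepoints, i.e. clonal at purity 0.9) anchors the tree. The predominant
diagnosis lineage `d1` (69% of tumour cells) was eradicated — its cluster
is diagnosis-specific — while the minor shared cluster `s2` (16% of cells
at diagnosis) rose to clonality at relapse and is the single relapse
founder edge. The relapse-specific clusters `r1` and `r2` nest under it as
a chain. The distinctness lines report the compound binomial test that the
relapse clusters were genuinely absent at diagnosis rather than hiding
inside the rising clone's low-MAF cluster (compound P ≈ 2×10⁻¹⁶: distinct).
Against the simulator's ground truth, `score_recovery(rep)` confirms the
assignment (adjusted Rand index 1.0, topology and founder edge recovered).

Single quantities are just as direct:

```r
detection_power(883, 0.01)   # 0.993053 — power at 883x for MAF 0.01
cluster_distinct_from(0.01, coverages = rep(520, 5))$compound_p  # 3.125e-07
```

A thin command-line wrapper for shell use is at
`inst/scripts/clonemix-cli.R` (`run`, `simulate`, `power` subcommands).

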