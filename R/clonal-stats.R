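#' Power to detect a low-frequency mutation at a given sequencing depth
#'
#' Probability that a mutation present at mutant allele fraction `maf` yields
#' at least `min_reads` mutant reads when the site is sequenced to `coverage`
#' total reads, under binomial sampling of reads. This is the detection power
#' of a presence call that requires a minimum mutant read count.
#'
#' @param coverage Total read depth at the site (positive integer; vectorised).
#' @param maf True mutant allele fraction, in (0, 1].
#' @param min_reads Minimum number of mutant reads required to call the
#'   mutation present (default 3 non-duplicate reads).
#' @return Probability of detection, `P(X >= min_reads)` with
#'   `X ~ Binomial(coverage, maf)`.
#' @examples
#' detection_power(187, 0.01)  # ~0.288 at exome-like depth
#' detection_power(883, 0.01)  # ~0.993 at combined deep coverage
#' @seealso [misclassification_p()], [cluster_distinct_from()]
#' @export
detection_power <- function(coverage, maf, min_reads = 3) {
  stopifnot(all(coverage >= 1), all(coverage == round(coverage)),
            all(maf >= 0), all(maf <= 1), .is_count(min_reads, min = 1L))
  if (any(maf == 0)) {
    warning("maf = 0: detection power is 0")
  }
  pbinom(min_reads - 1, size = coverage, prob = maf, lower.tail = FALSE)
}

#' Probability of observing zero mutant reads from a low-frequency cluster
#'
#' If a mutation truly belongs to a cluster with mutant allele fraction
#' `alpha`, the probability that a site covered by `coverage` reads shows no
#' mutant read at all is `P(X = 0) = (1 - alpha)^coverage`. A small value
#' means a zero-read observation is unlikely under membership in that
#' cluster, i.e. the mutation was probably not "misclassified" as absent.
#'
#' @param coverage Total read depth at the site (vectorised).
#' @param alpha Putative cluster mutant allele fraction, in \[0, 1\].
#' @return `P(X = 0 | coverage, alpha)`.
#' @examples
#' misclassification_p(520, 0.01)
#' @export
misclassification_p <- function(coverage, alpha) {
  stopifnot(all(coverage >= 1), all(coverage == round(coverage)),
            all(alpha >= 0), all(alpha <= 1))
  dbinom(0, size = coverage, prob = alpha)
}

#' Compound binomial P value for cluster distinctness
#'
#' Given per-site probabilities that a zero-read observation arose by chance
#' from a putative parent cluster, count the sites deemed "unlikely to be
#' misclassified" (per-site p <= `threshold`) and compute the upper-tail
#' binomial probability of seeing at least that many such sites if each site
#' independently had probability `threshold` of being flagged. A small
#' compound P value indicates the cluster as a whole is distinct from the
#' putative parent.
#'
#' @param per_snv_p Numeric vector of per-site probabilities.
#' @param threshold Per-site cutoff for "unlikely to be misclassified"
#'   (default 0.05, inclusive).
#' @return An object of class `"distinctness"`: a list with `n_snvs`,
#'   `n_unlikely` (x), `per_snv_p`, `threshold`, `compound_p`
#'   (`P(X >= x | n, threshold)`; 1 when x = 0), and `alpha` (NA here; set by
#'   [cluster_distinct_from()]).
#' @examples
#' # 14 of 38 sites individually unlikely -> compound P ~ 2e-9
#' compound_distinctness_p(c(rep(0.01, 14), rep(0.5, 24)))
#' @export
compound_distinctness_p <- function(per_snv_p, threshold = 0.05) {
  stopifnot(length(per_snv_p) >= 1L, all(per_snv_p >= 0), all(per_snv_p <= 1),
            .is_fraction(threshold, open_lo = TRUE, open_hi = TRUE))
  n <- length(per_snv_p)
  x <- sum(per_snv_p <= threshold)
  compound_p <- if (x == 0L) 1 else
    pbinom(x - 1, size = n, prob = threshold, lower.tail = FALSE)
  structure(
    list(n_snvs = n, n_unlikely = x, per_snv_p = per_snv_p,
         threshold = threshold, compound_p = compound_p, alpha = NA_real_),
    class = "distinctness"
  )
}

#' Test whether a cluster of absent-at-diagnosis mutations is distinct from a
#' putative parent cluster
#'
#' For a set of mutations with zero mutant reads at one timepoint, asks
#' whether that is compatible with the mutations actually belonging to a
#' low-frequency parent cluster with mutant allele fraction `parent_alpha`.
#' Composes [misclassification_p()] per site with
#' [compound_distinctness_p()] across sites.
#'
#' @param parent_alpha Mutant allele fraction of the putative parent cluster
#'   at the timepoint where the mutations were not observed.
#' @param coverages Total read depths of the zero-read sites.
#' @param mut_reads Observed mutant read counts (must all be zero; the test is
#'   defined for absent alleles). Defaults to zeros.
#' @param threshold Per-site cutoff passed to [compound_distinctness_p()].
#' @return A `"distinctness"` object (see [compound_distinctness_p()]) with
#'   `alpha` set to `parent_alpha`.
#' @examples
#' cluster_distinct_from(0.01, coverages = rep(520, 5))
#' @export
cluster_distinct_from <- function(parent_alpha, coverages,
                                  mut_reads = rep(0L, length(coverages)),
                                  threshold = 0.05) {
  stopifnot(.is_fraction(parent_alpha), length(coverages) >= 1L)
  if (any(mut_reads > 0)) {
    stop("cluster_distinct_from() is defined for alleles absent (0 mutant reads) ",
         "at the tested timepoint; found non-zero mutant read counts")
  }
  res <- compound_distinctness_p(misclassification_p(coverages, parent_alpha),
                                 threshold = threshold)
  res$alpha <- parent_alpha
  res
}

#' @export
print.distinctness <- function(x, ...) {
  cat("Cluster distinctness test\n")
  if (!is.na(x$alpha)) cat(sprintf("  putative parent MAF (alpha): %g\n", x$alpha))
  cat(sprintf("  sites: %d; unlikely to be misclassified (p <= %g): %d\n",
              x$n_snvs, x$threshold, x$n_unlikely))
  cat(sprintf("  compound P value P(X >= %d | %d, %g) = %.3g\n",
              x$n_unlikely, x$n_snvs, x$threshold, x$compound_p))
  invisible(x)
}

.TRANSITIONS <- c("A>G", "G>A", "C>T", "T>C")

#' Summarise the transition/transversion spectrum of a set of substitutions
#'
#' Transitions are purine-purine or pyrimidine-pyrimidine changes (A<->G,
#' C<->T); everything else is a transversion. The transition fraction of a
#' mutation cluster shifts markedly under mismatch-repair-deficient
#' hypermutation and is used as evidence when resolving lineage ambiguity.
#'
#' @param snvs Character vector of single-base substitutions written
#'   `"ref>alt"`, e.g. `"C>T"`.
#' @param label Optional label for the set.
#' @return An object of class `"spectrum_summary"`: list with `label`,
#'   `transitions`, `transversions`, `transition_fraction`.
#' @examples
#' transition_fraction(c("A>G", "C>T", "G>C"))
#' @export
transition_fraction <- function(snvs, label = NA_character_) {
  stopifnot(length(snvs) >= 1L, is.character(snvs))
  ok <- grepl("^[ACGT]>[ACGT]$", snvs) &
    substr(snvs, 1L, 1L) != substr(snvs, 3L, 3L)
  if (!all(ok)) {
    stop("not single-base substitutions: ",
         paste(unique(snvs[!ok]), collapse = ", "))
  }
  ts <- sum(snvs %in% .TRANSITIONS)
  tv <- length(snvs) - ts
  structure(
    list(label = label, transitions = ts, transversions = tv,
         transition_fraction = ts / (ts + tv)),
    class = "spectrum_summary"
  )
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("Mutation spectrum%s: %d transitions / %d transversions (Ts fraction %.3f)\n",
              if (is.na(x$label)) "" else paste0(" [", x$label, "]"),
              x$transitions, x$transversions, x$transition_fraction))
  invisible(x)
}

#' Compare the mutation spectra of two SNV sets
#'
#' Two-sided Fisher's exact test on the 2x2 table of transition and
#' transversion counts. Used to decide whether a mutation cluster's spectrum
#' is consistent with a candidate parental lineage.
#'
#' @param set_a,set_b `"spectrum_summary"` objects (see
#'   [transition_fraction()]) or length-2 numeric vectors
#'   `c(transitions, transversions)`.
#' @return The two-sided exact P value.
#' @examples
#' spectrum_test(c(97, 1), c(77, 23))
#' @export
spectrum_test <- function(set_a, set_b) {
  as_counts <- function(s) {
    if (inherits(s, "spectrum_summary")) c(s$transitions, s$transversions)
    else {
      stopifnot(is.numeric(s), length(s) == 2L, all(s >= 0))
      s
    }
  }
  a <- as_counts(set_a)
  b <- as_counts(set_b)
  if (sum(a) == 0 || sum(b) == 0) stop("both SNV sets must be non-empty")
  fisher.test(matrix(c(a, b), nrow = 2L, byrow = TRUE))$p.value
}
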