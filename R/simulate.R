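# Synthetic clonal-architecture generator.
#
# Emulates the data structure the analysis assumes: a clone tree with cell
# fractions at diagnosis and relapse, tumour purity per sample, per-variant
# total depths (Poisson around a configured mean), and mutant read counts
# drawn Binomial(N, purity * carrier_fraction / 2) for diploid heterozygous
# SNVs. Ground truth (tree, fractions, cluster membership) is returned for
# recovery scoring.

#' Configuration for the synthetic clonal-architecture generator
#'
#' Defaults describe a typical deeply sequenced diagnosis/relapse pair: a
#' founder clone plus diagnosis subclones of which one minor subclone
#' (diagnosis cell fraction drawn from 5-18%) survives therapy and founds
#' the relapse; combined sequencing depth averaging 883-fold; transition
#' fraction 0.77 for ordinary mutational spectra and 0.99 for
#' mismatch-repair-deficient hypermutators; tumour purity 0.9 at both
#' timepoints; 8-15 mutations per cluster; remission counts clean (no
#' residual disease) unless `residual_maf` is set.
#'
#' @param n_clones_dx Number of diagnosis clones including the founder
#'   (>= 1).
#' @param n_clones_rel Number of relapse-specific clones (>= 1), nested as a
#'   chain under the surviving diagnosis clone.
#' @param purity_dx,purity_rel Tumour purity per sample, in (0, 1].
#' @param mean_coverage Mean total read depth per variant and timepoint.
#' @param muts_per_cluster Length-2 integer range of mutations per cluster.
#' @param surviving_clone_rank `"minor"` (default) or `"major"`: whether the
#'   diagnosis subclone that seeds the relapse is the smallest or the
#'   predominant subclone.
#' @param hypermutator If `TRUE`, relapse-specific clusters use the elevated
#'   transition fraction `transition_prob_hyper`.
#' @param transition_prob_normal,transition_prob_hyper Transition fractions
#'   for ordinary and hypermutated spectra.
#' @param residual_maf Mutant allele fraction of shared-lineage mutations in
#'   the remission sample (minimal residual disease; default 0).
#' @param min_center_sep Minimum separation, on the MAF scale, enforced
#'   between cluster centres that compete within the same mixture fit
#'   (default 0.05). Lower it deliberately to create adversarial overlap.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_clones_dx = 3L, n_clones_rel = 2L,
                       purity_dx = 0.9, purity_rel = 0.9,
                       mean_coverage = 883,
                       muts_per_cluster = c(8L, 15L),
                       surviving_clone_rank = c("minor", "major"),
                       hypermutator = FALSE,
                       transition_prob_normal = 0.77,
                       transition_prob_hyper = 0.99,
                       residual_maf = 0,
                       min_center_sep = 0.05,
                       seed = 1L) {
  surviving_clone_rank <- match.arg(surviving_clone_rank)
  stopifnot(.is_count(n_clones_dx, min = 1L), .is_count(n_clones_rel, min = 1L),
            .is_fraction(purity_dx, open_lo = TRUE),
            .is_fraction(purity_rel, open_lo = TRUE),
            is.numeric(mean_coverage), mean_coverage > 0,
            length(muts_per_cluster) == 2L,
            all(muts_per_cluster >= 1), muts_per_cluster[1] <= muts_per_cluster[2],
            is.logical(hypermutator),
            .is_fraction(transition_prob_normal),
            .is_fraction(transition_prob_hyper),
            .is_fraction(residual_maf),
            is.numeric(min_center_sep), min_center_sep >= 0,
            .is_count(abs(seed)))
  structure(
    list(n_clones_dx = as.integer(n_clones_dx),
         n_clones_rel = as.integer(n_clones_rel),
         purity_dx = purity_dx, purity_rel = purity_rel,
         mean_coverage = mean_coverage,
         muts_per_cluster = as.integer(muts_per_cluster),
         surviving_clone_rank = surviving_clone_rank,
         hypermutator = hypermutator,
         transition_prob_normal = transition_prob_normal,
         transition_prob_hyper = transition_prob_hyper,
         residual_maf = residual_maf,
         min_center_sep = min_center_sep,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Decreasing cell-fraction ladder for k sibling subclones: the predominant
# child takes most of the tumour, later siblings shrink geometrically.
.sibling_ladder <- function(k) {
  upper <- 0.72 * 0.42^(seq_len(k) - 1L)
  lower <- 0.65 * upper
  cbind(lower, upper)
}

#' Simulate a ground-truth clone tree with cell fractions at two timepoints
#'
#' Architecture: a founder clone (cell fraction 1 at both timepoints,
#' carrying the shared founder mutation cluster) with `n_clones_dx - 1`
#' sibling subclones at diagnosis. Exactly one diagnosis clone -- the
#' smallest or largest subclone per `surviving_clone_rank`, or the founder
#' itself when there are no subclones -- survives therapy: its cluster is
#' shared and clonal at relapse, while its siblings' clusters are
#' diagnosis-specific. `n_clones_rel` relapse-specific clones form a chain
#' under the surviving clone, the first clonal at relapse and descendants
#' with nested decreasing fractions. Cell fractions are drawn so that
#' cluster centres competing within one mixture fit are separated by at
#' least `min_center_sep` on the MAF scale; configurations for which this
#' cannot be achieved raise an error.
#'
#' @param config A [sim_config()].
#' @return An object of class `"sim_truth"`: list with `clones` (data frame
#'   `clone`, `parent`, `cluster`, `category`, `cf_dx`, `cf_rel`; fractions
#'   are total cell fractions including descendants), `surviving_clone`,
#'   `category_of_cluster`, purities, and the `config` echo.
#' @export
simulate_lineage <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    k_sib <- config$n_clones_dx - 1L
    sep_cf_dx <- 2 * config$min_center_sep / config$purity_dx
    sep_cf_rel <- 2 * config$min_center_sep / config$purity_rel
    for (attempt in seq_len(500L)) {
      ok <- TRUE
      # diagnosis siblings; the surviving subclone is the smallest ("minor",
      # the typical rising clone, dx fraction 5-18%) or the largest
      if (k_sib > 0L) {
        if (config$surviving_clone_rank == "minor") {
          surv_cf <- runif(1, 0.05, 0.18)
          others <- if (k_sib > 1L) {
            lad <- .sibling_ladder(k_sib - 1L)
            sort(runif(k_sib - 1L, lad[, 1L], lad[, 2L]), decreasing = TRUE)
          } else numeric(0)
          sibs <- c(others, surv_cf)
          surv_idx <- k_sib
        } else {
          surv_cf <- runif(1, 0.5, 0.72)
          others <- if (k_sib > 1L) {
            lad <- 0.4 * .sibling_ladder(k_sib - 1L)
            sort(runif(k_sib - 1L, lad[, 1L], lad[, 2L]), decreasing = TRUE)
          } else numeric(0)
          sibs <- c(surv_cf, others)
          surv_idx <- 1L
        }
        if (sum(sibs) > 0.98) ok <- FALSE
        # dx-side separation: sibling centres against each other and founder
        cdx <- config$purity_dx * c(1, sibs) / 2
        if (min(dist(cdx)) < config$min_center_sep - 1e-12) ok <- FALSE
      } else {
        sibs <- numeric(0); surv_idx <- 0L
      }
      # relapse-specific chain fractions (first clonal)
      rel_cf <- 1
      if (config$n_clones_rel > 1L) {
        more <- numeric(config$n_clones_rel - 1L)
        hi <- 0.7
        for (j in seq_along(more)) {
          more[j] <- runif(1, 0.45 * hi, hi)
          hi <- 0.6 * more[j]
        }
        rel_cf <- c(1, more)
      }
      crel <- config$purity_rel * rel_cf / 2
      if (length(crel) > 1L && min(dist(crel)) < config$min_center_sep - 1e-12)
        ok <- FALSE
      if (ok) break
      if (attempt == 500L) {
        stop("infeasible configuration: could not draw nested cell fractions ",
             "with the requested cluster-centre separation")
      }
    }

    n_dx <- config$n_clones_dx
    clone <- paste0("clone_", seq_len(n_dx + config$n_clones_rel))
    cluster <- paste0("cl_", letters[seq_along(clone)])
    parent <- c(NA_character_, rep(clone[1L], max(0L, k_sib)),
                character(config$n_clones_rel))
    surviving <- if (k_sib == 0L) clone[1L] else clone[1L + surv_idx]
    parent[n_dx + 1L] <- surviving
    if (config$n_clones_rel > 1L) {
      parent[(n_dx + 2L):(n_dx + config$n_clones_rel)] <-
        clone[(n_dx + 1L):(n_dx + config$n_clones_rel - 1L)]
    }
    category <- c("shared",
                  if (k_sib > 0L) rep("dx_specific", k_sib),
                  rep("rel_specific", config$n_clones_rel))
    if (k_sib > 0L) category[1L + surv_idx] <- "shared"
    cf_dx <- c(1, sibs, rep(0, config$n_clones_rel))
    cf_rel <- rep(0, length(clone))
    cf_rel[category == "shared"] <- 1
    cf_rel[(n_dx + 1L):(n_dx + config$n_clones_rel)] <- rel_cf

    clones <- data.frame(clone = clone, parent = parent, cluster = cluster,
                         category = category, cf_dx = cf_dx, cf_rel = cf_rel,
                         stringsAsFactors = FALSE)
    structure(
      list(clones = clones,
           surviving_clone = surviving,
           category_of_cluster = setNames(category, cluster),
           purity_dx = config$purity_dx, purity_rel = config$purity_rel,
           config = config),
      class = "sim_truth"
    )
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("Simulated clonal architecture: %d clones (%d clusters), surviving clone %s\n",
              nrow(x$clones), nrow(x$clones), x$surviving_clone))
  print(x$clones, row.names = FALSE)
  invisible(x)
}

#' Simulate per-variant read counts from a ground-truth clone tree
#'
#' For each cluster, draws a number of variants from the configured range;
#' per variant and timepoint, total depth is Poisson with the configured
#' mean and mutant reads are `Binomial(N, purity * carrier_fraction / 2)`
#' (diploid heterozygous SNVs), where the carrier fraction is the total cell
#' fraction of the clone that introduced the cluster. Remission counts use
#' `residual_maf` for shared-lineage clusters (0 by default). Substitution
#' types come from [simulate_spectrum()]; relapse-specific clusters use the
#' hypermutator transition fraction when configured.
#'
#' @param truth A `"sim_truth"` from [simulate_lineage()].
#' @param config The same [sim_config()].
#' @param depth Optional depth override: a single total-read value used for
#'   every variant and timepoint instead of Poisson sampling (0 gives
#'   all-zero counts).
#' @return A canonical variant table (see [read_variants()]) with one extra
#'   column `cluster` holding the ground-truth cluster label. The `cluster`
#'   column is the truth annotation and is not part of the TSV dialect.
#' @export
simulate_reads <- function(truth, config, depth = NULL) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  .with_seed(config$seed + 1L, {
    cl <- truth$clones
    n_per <- sample(seq(config$muts_per_cluster[1L], config$muts_per_cluster[2L]),
                    nrow(cl), replace = TRUE)
    rows <- vector("list", nrow(cl))
    pos0 <- 0L
    for (j in seq_len(nrow(cl))) {
      nm <- n_per[j]
      p_ts <- if (config$hypermutator && cl$category[j] == "rel_specific") {
        config$transition_prob_hyper
      } else config$transition_prob_normal
      subs <- simulate_spectrum(nm, p_ts)
      draw <- function(cf, purity) {
        N <- if (is.null(depth)) rpois(nm, config$mean_coverage) else rep(as.integer(depth), nm)
        X <- rbinom(nm, N, purity * cf / 2)
        list(N = N, X = X)
      }
      dx <- draw(cl$cf_dx[j], config$purity_dx)
      rel <- draw(cl$cf_rel[j], config$purity_rel)
      rem_maf <- if (cl$category[j] == "shared") config$residual_maf else 0
      Nrem <- if (is.null(depth)) rpois(nm, config$mean_coverage) else rep(as.integer(depth), nm)
      Xrem <- rbinom(nm, Nrem, rem_maf)
      rows[[j]] <- data.frame(
        case_id = "SIM", chrom = "chr1",
        pos = pos0 + seq_len(nm) * 100L,
        ref = substr(subs, 1L, 1L), alt = substr(subs, 3L, 3L),
        dx_mut = dx$X, dx_tot = dx$N,
        rel_mut = rel$X, rel_tot = rel$N,
        rem_mut = Xrem, rem_tot = Nrem,
        diploid = TRUE, gene = NA_character_, effect = NA_character_,
        pathway = NA_character_,
        cluster = cl$cluster[j], stringsAsFactors = FALSE
      )
      pos0 <- pos0 + nm * 100L
    }
    do.call(rbind, rows)
  })
}

#' Simulate single-base substitution types with a given transition fraction
#'
#' Each SNV is a transition (A>G, G>A, C>T, T>C, uniformly) with probability
#' `transition_prob`, otherwise one of the eight transversions uniformly.
#'
#' @param n_snvs Number of substitutions.
#' @param transition_prob Probability of a transition, in \[0, 1\].
#' @param seed Optional seed (when `NULL`, draws from the current stream, as
#'   when called inside [simulate_reads()]).
#' @return Character vector of substitutions, `"ref>alt"`.
#' @examples
#' simulate_spectrum(5, 0.99, seed = 1)
#' @export
simulate_spectrum <- function(n_snvs, transition_prob, seed = NULL) {
  stopifnot(.is_count(n_snvs, min = 1L), .is_fraction(transition_prob))
  transversions <- c("A>C", "A>T", "C>A", "C>G", "G>C", "G>T", "T>A", "T>G")
  gen <- function() {
    is_ts <- runif(n_snvs) < transition_prob
    out <- character(n_snvs)
    out[is_ts] <- sample(.TRANSITIONS, sum(is_ts), replace = TRUE)
    out[!is_ts] <- sample(transversions, sum(!is_ts), replace = TRUE)
    out
  }
  if (is.null(seed)) gen() else .with_seed(seed, gen())
}

#' Simulate a complete case: ground truth plus variant table
#'
#' Convenience wrapper running [simulate_lineage()] then [simulate_reads()].
#'
#' @param config A [sim_config()].
#' @return List with `truth` (the `"sim_truth"`, with
#'   `cluster_of_variant` filled in) and `variants` (the variant table).
#' @examples
#' sim <- simulate_case(sim_config(seed = 7))
#' head(sim$variants)
#' @export
simulate_case <- function(config) {
  truth <- simulate_lineage(config)
  variants <- simulate_reads(truth, config)
  truth$cluster_of_variant <- setNames(variants$cluster, .variant_key(variants))
  list(truth = truth, variants = variants)
}
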