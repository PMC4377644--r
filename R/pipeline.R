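# End-to-end orchestration: simulate/ingest -> categorise -> cluster ->
# purity -> lineage -> distinctness/spectrum statistics -> report.

#' Run the full clonal-evolution pipeline
#'
#' Stages: (1) obtain variants, either by simulating a case (`config$simulate`
#' holds [sim_config()] arguments) or by reading a table (`config$input` with
#' `path`, `format`, and for VCF a `sample_map`); (2) categorise variants as
#' diagnosis-specific / relapse-specific / shared ([classify_presence()]);
#' (3) fit binomial mixtures per category to diploid variants, selecting K by
#' AIC ([select_model()]); (4) estimate purity per timepoint
#' ([estimate_purity()]); (5) convert cluster centres to cell fractions
#' ([cluster_cell_fraction()]) and build the lineage ([build_lineage()],
#' [map_relapse_founders()], [resolve_ambiguity()] with per-cluster spectra);
#' (6) test relapse-specific clusters absent at diagnosis for distinctness
#' from the surviving clone's diagnosis cluster ([cluster_distinct_from()]).
#' Every stochastic step is seeded from `config$seed`, so a report is fully
#' reproducible from its config echo.
#'
#' @param config A list (or path to a YAML/JSON file) with elements:
#'   `simulate` (list of [sim_config()] arguments), `variants` (an in-memory
#'   canonical variant data frame) or `input` (list with `path`, `format`,
#'   optional `sample_map`); optional thresholds
#'   `maf_floor` (0.01), `min_reads` (3), `K_max` (6), `epsilon` (0.05),
#'   `distinctness_threshold` (0.05), `restarts` (10); `seed` (required);
#'   optional `outdir` to write stage artifacts (cluster table TSV, tree
#'   JSON/DOT/TSV, summary JSON).
#' @return An object of class `"run_report"`: list with `config`,
#'   `variants` (with presence calls, categories and cluster assignments),
#'   `clusters` (per-cluster table: label, category, centres, cell
#'   fractions, n variants), `fits`, `purity` (dx and rel summaries),
#'   `tree` (resolved `"lineage_tree"` with founder edges), `distinctness`
#'   tests, `spectra`, `truth` (when simulated) and the package `version`.
#' @examples
#' rep <- run_pipeline(list(simulate = list(seed = 42), seed = 42))
#' rep$clusters
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("config$seed is required: every stochastic stage is seeded")
  thr <- list(maf_floor = 0.01, min_reads = 3L, K_max = 6L, epsilon = 0.05,
              distinctness_threshold = 0.05, restarts = 10L)
  for (nm in names(thr)) if (!is.null(config[[nm]])) thr[[nm]] <- config[[nm]]
  stopifnot(thr$maf_floor > 0, thr$maf_floor < 1, thr$min_reads >= 1,
            thr$K_max >= 1, thr$epsilon >= 0,
            thr$distinctness_threshold > 0, thr$distinctness_threshold < 1)

  # --- stage 1: inputs ---
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    sim <- simulate_case(do.call(sim_config, sim_args))
    truth <- sim$truth
    variants <- sim$variants
  } else if (!is.null(config$variants)) {
    variants <- config$variants
  } else if (!is.null(config$input)) {
    inp <- config$input
    variants <- read_variants(inp$path, format = inp$format %||% "tsv",
                              sample_map = inp$sample_map)
  } else {
    stop("config must contain 'simulate', 'variants' or 'input'")
  }
  if (nrow(variants) == 0L) stop("empty variant table: nothing to analyse")

  # --- stage 2: presence calls and categories ---
  variants <- classify_presence(variants, maf_floor = thr$maf_floor,
                                min_reads = thr$min_reads)
  variants <- variants[!is.na(variants$category), , drop = FALSE]
  if (nrow(variants) == 0L) stop("no variant present in either tumour sample")

  # --- stage 3: mixture fits per category (diploid variants only) ---
  dip <- variants[variants$diploid, , drop = FALSE]
  fits <- list()
  grp <- function(cat) dip[dip$category == cat, , drop = FALSE]
  g <- grp("dx_specific")
  if (nrow(g) > 0L) {
    fits$dx_specific <- select_model(
      data.frame(mut = g$dx_mut, total = g$dx_tot),
      K_max = thr$K_max, model = "specific", seed = config$seed + 11L,
      restarts = thr$restarts)
  }
  g <- grp("rel_specific")
  if (nrow(g) > 0L) {
    fits$rel_specific <- select_model(
      data.frame(mut = g$rel_mut, total = g$rel_tot),
      K_max = thr$K_max, model = "specific", seed = config$seed + 12L,
      restarts = thr$restarts)
  }
  g <- grp("shared")
  if (nrow(g) > 0L) {
    fits$shared <- select_model(
      data.frame(mut_dx = g$dx_mut, tot_dx = g$dx_tot,
                 mut_rel = g$rel_mut, tot_rel = g$rel_tot),
      K_max = thr$K_max, model = "shared", seed = config$seed + 13L,
      restarts = thr$restarts)
  }
  if (is.null(fits$shared)) {
    stop("no shared diploid variants: cannot anchor a diagnosis-relapse lineage")
  }

  # --- stage 4: purity per timepoint ---
  at_dx <- dip[dip$present_dx, , drop = FALSE]
  at_rel <- dip[dip$present_rel, , drop = FALSE]
  purity <- list(
    dx = estimate_purity(at_dx$dx_mut, at_dx$dx_tot, K_max = thr$K_max,
                         seed = config$seed + 21L, restarts = thr$restarts),
    rel = estimate_purity(at_rel$rel_mut, at_rel$rel_tot, K_max = thr$K_max,
                          seed = config$seed + 22L, restarts = thr$restarts)
  )

  # --- stage 5: cluster table, spectra, lineage ---
  assemble <- function(cat, fit) {
    if (is.null(fit)) return(NULL)
    g <- grp(cat)
    lab <- paste0(substr(cat, 1L, 1L), seq_len(fit$K))
    if (fit$model == "shared") {
      cen_dx <- fit$centers[, "dx"]; cen_rel <- fit$centers[, "rel"]
    } else if (cat == "dx_specific") {
      cen_dx <- fit$centers; cen_rel <- rep(0, fit$K)
    } else {
      cen_dx <- rep(0, fit$K); cen_rel <- fit$centers
    }
    data.frame(label = lab, category = cat,
               center_dx = cen_dx, center_rel = cen_rel,
               n_variants = as.integer(table(factor(fit$assignments,
                                                    levels = seq_len(fit$K)))),
               stringsAsFactors = FALSE)
  }
  clusters <- rbind(assemble("shared", fits$shared),
                    assemble("dx_specific", fits$dx_specific),
                    assemble("rel_specific", fits$rel_specific))
  suppress_superclonal <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("super-clonal", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  }
  clusters$cf_dx <- ifelse(
    clusters$category == "rel_specific", 0,
    suppress_superclonal(cluster_cell_fraction(clusters$center_dx,
                                               purity$dx$purity)))
  clusters$cf_rel <- ifelse(
    clusters$category == "dx_specific", 0,
    suppress_superclonal(cluster_cell_fraction(clusters$center_rel,
                                               purity$rel$purity)))

  # per-variant cluster assignment and per-cluster spectra
  variants$cluster_fit <- NA_character_
  for (cat in names(fits)) {
    idx <- which(variants$diploid & variants$category == cat)
    variants$cluster_fit[idx] <-
      paste0(substr(cat, 1L, 1L), fits[[cat]]$assignments)
  }
  spectra_list <- lapply(clusters$label, function(lb) {
    vv <- variants[!is.na(variants$cluster_fit) & variants$cluster_fit == lb, ]
    if (nrow(vv) == 0L) return(NULL)
    sp <- transition_fraction(paste0(vv$ref, ">", vv$alt), label = lb)
    data.frame(cluster = lb, transitions = sp$transitions,
               transversions = sp$transversions,
               transition_fraction = sp$transition_fraction)
  })
  spectra <- do.call(rbind, spectra_list)

  drivers <- NULL
  if (any(!is.na(variants$pathway) & !is.na(variants$cluster_fit))) {
    dv <- variants[!is.na(variants$pathway) & !is.na(variants$cluster_fit), ]
    drivers <- data.frame(cluster = dv$cluster_fit, gene = dv$gene,
                          pathway = dv$pathway, stringsAsFactors = FALSE)
  }

  tree <- build_lineage(clusters[, c("label", "category", "cf_dx", "cf_rel")],
                        epsilon = thr$epsilon)
  tree <- map_relapse_founders(tree)
  tree <- resolve_ambiguity(tree, drivers = drivers, spectra = spectra,
                            p_threshold = thr$distinctness_threshold)

  # --- stage 6: distinctness of relapse clusters absent at diagnosis ---
  distinctness <- list()
  surv <- tree$founder_edges$cluster[1L]
  surv_alpha <- clusters$center_dx[clusters$label == surv]
  rel_labels <- clusters$label[clusters$category == "rel_specific"]
  for (lb in rel_labels) {
    vv <- variants[!is.na(variants$cluster_fit) & variants$cluster_fit == lb &
                     variants$dx_mut == 0, ]
    if (nrow(vv) == 0L || surv_alpha <= 0) next
    distinctness[[lb]] <- cluster_distinct_from(
      surv_alpha, vv$dx_tot, threshold = thr$distinctness_threshold)
  }

  report <- structure(
    list(config = c(config, list(thresholds = thr)),
         variants = variants, clusters = clusters, fits = fits,
         purity = purity, tree = tree, distinctness = distinctness,
         spectra = spectra, truth = truth,
         version = as.character(packageVersion("clonemix"))),
    class = "run_report"
  )

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$outdir, f)
    write.table(clusters, out("clusters.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    vv <- variants
    write.table(vv, out("variants_annotated.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    export_tree(tree, "json", out("tree.json"))
    export_tree(tree, "dot", out("tree.dot"))
    export_tree(tree, "tsv", out("tree.tsv"))
    jsonlite::write_json(
      list(seed = config$seed, version = report$version,
           purity = list(dx = purity$dx$purity, rel = purity$rel$purity),
           n_variants = nrow(variants),
           K = lapply(fits, `[[`, "K"),
           thresholds = thr),
      out("summary.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_report <- function(x, ...) {
  cat("clonemix run report (version ", x$version, ")\n", sep = "")
  cat(sprintf("  %d variants; purity dx %.3f / rel %.3f\n",
              nrow(x$variants), x$purity$dx$purity, x$purity$rel$purity))
  cat("  clusters:\n")
  print(x$clusters, row.names = FALSE, digits = 3)
  print(x$tree)
  for (nm in names(x$distinctness)) {
    d <- x$distinctness[[nm]]
    cat(sprintf("  distinctness of %s from diagnosis alpha %.4g: compound P = %.3g\n",
                nm, d$alpha, d$compound_p))
  }
  invisible(x)
}

#' Export a lineage tree to JSON, DOT or fish-plot TSV
#'
#' JSON serialises the full tree (round-trips through [import_tree()]); DOT
#' renders diagnosis and relapse as two ranked columns with founder edges
#' crossing between them; TSV emits `(clone, timepoint, fraction, parent)`
#' rows for external fish-plot-style tools.
#'
#' @param tree A `"lineage_tree"`.
#' @param format `"json"`, `"dot"` or `"tsv"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_tree <- function(tree, format = c("json", "dot", "tsv"), path) {
  stopifnot(inherits(tree, "lineage_tree"))
  format <- match.arg(format)
  cl <- tree$clones
  if (format == "json") {
    payload <- list(clones = cl, epsilon = tree$epsilon,
                    founder = tree$founder,
                    ambiguity = tree$ambiguity,
                    founder_edges = tree$founder_edges)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  } else if (format == "dot") {
    node <- function(i, tp) {
      frac <- if (tp == "dx") cl$cf_dx[i] else cl$cf_rel[i]
      sprintf("  \"%s_%s\" [label=\"%s\\n%s %.0f%%\"%s];",
              cl$cluster[i], tp, cl$cluster[i],
              if (tp == "dx") "D" else "R", 100 * frac,
              if (cl$inferred[i]) " style=dashed" else "")
    }
    lines <- c("digraph lineage {", "  rankdir=LR;")
    dx_idx <- which(cl$cf_dx > 0 | cl$category != "rel_specific")
    rel_idx <- which(cl$cf_rel > 0 | cl$category != "dx_specific")
    lines <- c(lines,
               "  subgraph cluster_dx { label=\"diagnosis\";",
               vapply(dx_idx, node, character(1), tp = "dx"), "  }",
               "  subgraph cluster_rel { label=\"relapse\";",
               vapply(rel_idx, node, character(1), tp = "rel"), "  }")
    for (i in seq_len(nrow(cl))) {
      if (!is.na(cl$parent_dx[i]) && i %in% dx_idx) {
        lines <- c(lines, sprintf("  \"%s_dx\" -> \"%s_dx\";",
                                  cl$parent_dx[i], cl$cluster[i]))
      }
      if (!is.na(cl$parent_rel[i]) && i %in% rel_idx) {
        lines <- c(lines, sprintf("  \"%s_rel\" -> \"%s_rel\";",
                                  cl$parent_rel[i], cl$cluster[i]))
      }
    }
    if (!is.null(tree$founder_edges)) {
      for (j in seq_len(nrow(tree$founder_edges))) {
        lines <- c(lines, sprintf(
          "  \"%s_dx\" -> \"%s_rel\" [style=bold, color=red];",
          tree$founder_edges$cluster[j], tree$founder_edges$cluster[j]))
      }
    }
    writeLines(c(lines, "}"), path)
  } else {
    long <- rbind(
      data.frame(clone = cl$cluster, timepoint = "diagnosis",
                 fraction = cl$cf_dx, parent = cl$parent_dx),
      data.frame(clone = cl$cluster, timepoint = "relapse",
                 fraction = cl$cf_rel, parent = cl$parent_rel))
    write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a lineage tree exported as JSON
#'
#' @param path Path to a JSON file written by [export_tree()].
#' @return The `"lineage_tree"`.
#' @export
import_tree <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cl <- as.data.frame(payload$clones, stringsAsFactors = FALSE)
  for (nm in c("parent_dx", "parent_rel")) cl[[nm]] <- as.character(cl[[nm]])
  amb <- payload$ambiguity
  if (length(amb) == 0L) amb <- list() else amb <- lapply(amb, as.list)
  fe <- payload$founder_edges
  if (!is.null(fe)) fe <- as.data.frame(fe, stringsAsFactors = FALSE)
  structure(
    list(clones = cl, epsilon = payload$epsilon, ambiguity = amb,
         founder = payload$founder, founder_edges = fe),
    class = "lineage_tree"
  )
}

#' Score how well a pipeline run recovered the simulated ground truth
#'
#' Matches fitted clusters to true clusters by majority variant membership,
#' then reports: whether the number of clusters per category is right;
#' root-mean-square error of the recovered MAF centres against the true
#' expected centres (`purity * carrier_fraction / 2`); adjusted Rand index
#' of the hard cluster assignments; whether the recovered lineage topology
#' (parent mapping over true clusters) matches; and whether the surviving
#' clone / relapse founder edge was recovered.
#'
#' @param report A `"run_report"` from a simulated [run_pipeline()] run.
#' @param truth The matching `"sim_truth"` (defaults to `report$truth`).
#' @return List with `k_match`, `center_rmse`, `ari`, `topology_match`,
#'   `founder_match`, and the `cluster_map` used.
#' @export
score_recovery <- function(report, truth = report$truth) {
  stopifnot(inherits(report, "run_report"), inherits(truth, "sim_truth"))
  v <- report$variants
  v <- v[!is.na(v$cluster_fit), , drop = FALSE]
  true_lab <- v$cluster
  fit_lab <- v$cluster_fit
  ari <- adjusted_rand_index(true_lab, fit_lab)

  # majority-vote map: fitted cluster -> true cluster
  map <- vapply(split(true_lab, fit_lab), function(tl)
    names(sort(table(tl), decreasing = TRUE))[1L], character(1))
  k_match <- length(unique(map)) == nrow(truth$clones) &&
    length(map) == nrow(truth$clones)

  # centre RMSE against the true expected MAFs of the matched clusters
  tr <- truth$clones
  exp_dx <- setNames(truth$purity_dx * tr$cf_dx / 2, tr$cluster)
  exp_rel <- setNames(truth$purity_rel * tr$cf_rel / 2, tr$cluster)
  cl <- report$clusters
  errs <- numeric(0)
  for (i in seq_len(nrow(cl))) {
    tc <- map[cl$label[i]]
    if (is.na(tc)) next
    if (cl$category[i] != "rel_specific")
      errs <- c(errs, cl$center_dx[i] - exp_dx[tc])
    if (cl$category[i] != "dx_specific")
      errs <- c(errs, cl$center_rel[i] - exp_rel[tc])
  }
  center_rmse <- sqrt(mean(errs^2))

  # topology: recovered parent over true cluster labels
  topology_match <- k_match
  if (k_match) {
    rc <- report$tree$clones
    true_parent_cluster <- setNames(
      tr$cluster[match(tr$parent, tr$clone)], tr$cluster)
    for (i in seq_len(nrow(rc))) {
      tc <- map[rc$cluster[i]]
      par <- if (rc$category[i] == "rel_specific") rc$parent_rel[i] else rc$parent_dx[i]
      tp <- if (is.na(par)) NA_character_ else map[par]
      if (!identical(unname(tp), unname(true_parent_cluster[tc]))) {
        topology_match <- FALSE
        break
      }
    }
  }

  surv_true <- tr$cluster[tr$clone == truth$surviving_clone]
  fe <- report$tree$founder_edges
  founder_match <- !is.null(fe) && nrow(fe) == 1L &&
    identical(unname(map[fe$cluster[1L]]), surv_true)

  list(k_match = k_match, center_rmse = center_rmse, ari = ari,
       topology_match = topology_match, founder_match = founder_match,
       cluster_map = map)
}
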