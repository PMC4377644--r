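# Clonal lineage reconstruction from mutation clusters.
#
# Each mutation cluster defines a clone (the clone that introduced it); the
# clone's total cell fraction is the combined frequency of all cells carrying
# the cluster. Lineages are built greedily: shared clusters in descending
# diagnosis fraction (the highest defines the founder), then
# diagnosis-specific clusters, each attached to the established clone with
# the largest residual (unallocated) population, whose residual is then
# reduced by the newcomer's fraction -- the pigeonhole sum rule. The shared
# hierarchy is carried over to the relapse side, residuals recomputed from
# relapse fractions, and relapse-specific clusters attached the same way.

#' Convert a cluster MAF centre to a clone cell fraction
#'
#' For diploid heterozygous mutations, a cluster carried by a fraction f of
#' tumour cells in a sample of purity u has expected mutant allele fraction
#' `u * f / 2`; inverting gives `f = 2 * MAF / u`, capped at 1. Centres
#' materially above the clonal expectation `u / 2` (by more than 0.1) draw a
#' warning: they suggest loss of heterozygosity or a purity underestimate.
#'
#' @param center_maf Cluster MAF centre(s), vectorised.
#' @param purity Tumour purity of the sample, in (0, 1].
#' @return Cell fraction(s) in \[0, 1\].
#' @examples
#' cluster_cell_fraction(0.233, 1.0)  # mutation carried by ~47% of cells
#' @export
cluster_cell_fraction <- function(center_maf, purity) {
  stopifnot(.is_fraction(purity, open_lo = TRUE),
            all(center_maf >= 0), all(center_maf <= 1))
  if (any(center_maf > purity / 2 + 0.1)) {
    warning("cluster centre exceeds the clonal heterozygous expectation ",
            "purity/2 by more than 0.1 (super-clonal); cell fraction capped at 1")
  }
  pmin(1, 2 * center_maf / purity)
}

# Greedy attachment engine. `clusters`: data.frame(label, category, cf_dx,
# cf_rel). `chooser(child_label, candidates, state)` picks a parent label
# from the feasible `candidates` (ordered by decreasing residual). Returns
# the node table plus the per-attachment candidate record.
.build_greedy <- function(clusters, epsilon, chooser = NULL) {
  stopifnot(is.data.frame(clusters),
            all(c("label", "category", "cf_dx", "cf_rel") %in% names(clusters)))
  if (anyDuplicated(clusters$label)) stop("duplicate cluster labels")
  bad_cat <- setdiff(clusters$category, c("shared", "dx_specific", "rel_specific"))
  if (length(bad_cat) > 0L) stop("unknown category: ", paste(bad_cat, collapse = ", "))
  stopifnot(all(clusters$cf_dx >= 0), all(clusters$cf_dx <= 1),
            all(clusters$cf_rel >= 0), all(clusters$cf_rel <= 1))
  if (!any(clusters$category == "shared")) {
    stop("no shared cluster: a common founder between diagnosis and relapse ",
         "is required (shared clusters anchor the lineage)")
  }
  if (is.null(chooser)) chooser <- function(child, candidates, state) candidates[1L]

  lab <- clusters$label
  nd <- nrow(clusters)
  st <- list(
    label = lab, category = clusters$category,
    cf_dx = setNames(clusters$cf_dx, lab),
    cf_rel = setNames(clusters$cf_rel, lab),
    parent_dx = setNames(rep(NA_character_, nd), lab),
    parent_rel = setNames(rep(NA_character_, nd), lab),
    residual_dx = setNames(rep(NA_real_, nd), lab),
    residual_rel = setNames(rep(NA_real_, nd), lab),
    depth_dx = setNames(rep(NA_integer_, nd), lab),
    depth_rel = setNames(rep(NA_integer_, nd), lab),
    established_dx = character(0), established_rel = character(0),
    ambiguity = list()
  )

  ord2 <- function(x, key) x[order(-key[x], x)]   # desc fraction, label tie-break
  shared <- ord2(lab[st$category == "shared"], st$cf_dx)
  dxspec <- ord2(lab[st$category == "dx_specific"], st$cf_dx)
  relspec <- ord2(lab[st$category == "rel_specific"], st$cf_rel)

  # A shared child must fit inside its parent's residual population at BOTH
  # timepoints (the pigeonhole rule holds at each timepoint); specific
  # clusters are constrained only where they exist. Parent preference is by
  # residual at the attachment side (diagnosis for shared clusters).
  attach_one <- function(st, child, side) {
    cat_child <- st$category[match(child, st$label)]
    cf <- if (side == "dx") st$cf_dx[child] else st$cf_rel[child]
    est <- if (side == "dx") st$established_dx else st$established_rel
    res <- if (side == "dx") st$residual_dx else st$residual_rel
    feas <- est[res[est] >= cf - epsilon]
    if (cat_child == "shared") {
      feas <- feas[st$residual_rel[feas] >= st$cf_rel[child] - epsilon]
    }
    if (length(feas) == 0L) {
      stop("lineage infeasible: cluster '", child, "' (fraction ",
           signif(cf, 3), " at ", side, ") exceeds every candidate parent's ",
           "residual population by more than epsilon = ", epsilon)
    }
    # preference order: residual desc, then shorter path to founder, then label
    dep <- if (side == "dx") st$depth_dx else st$depth_rel
    feas <- feas[order(-res[feas], dep[feas], feas)]
    pick <- chooser(child, feas, st)
    if (length(feas) > 1L) {
      st$ambiguity[[child]] <- list(side = side, candidates = feas,
                                    selected = pick,
                                    residuals = unname(res[feas]))
    }
    if (side == "dx") {
      st$parent_dx[child] <- pick
      st$residual_dx[pick] <- st$residual_dx[pick] - cf
      st$residual_dx[child] <- cf
      st$depth_dx[child] <- st$depth_dx[pick] + 1L
      st$established_dx <- c(st$established_dx, child)
      if (cat_child == "shared") {
        # shared clusters persist: mirror the attachment on the relapse side
        st$parent_rel[child] <- pick
        st$residual_rel[pick] <- st$residual_rel[pick] - st$cf_rel[child]
        st$residual_rel[child] <- st$cf_rel[child]
        st$depth_rel[child] <- st$depth_rel[pick] + 1L
        st$established_rel <- c(st$established_rel, child)
      }
    } else {
      st$parent_rel[child] <- pick
      st$residual_rel[pick] <- st$residual_rel[pick] - cf
      st$residual_rel[child] <- cf
      st$depth_rel[child] <- st$depth_rel[pick] + 1L
      st$established_rel <- c(st$established_rel, child)
    }
    st
  }

  # --- diagnosis: shared clusters, founder first, then dx-specific ---
  founder <- shared[1L]
  st$residual_dx[founder] <- st$cf_dx[founder]
  st$residual_rel[founder] <- st$cf_rel[founder]
  st$depth_dx[founder] <- 0L
  st$depth_rel[founder] <- 0L
  st$established_dx <- founder
  st$established_rel <- founder
  for (child in c(shared[-1L], dxspec)) st <- attach_one(st, child, "dx")

  # --- relapse: relapse-specific clusters onto the persisting (shared) clones ---
  for (child in relspec) st <- attach_one(st, child, "rel")
  st
}

.tree_from_state <- function(st, epsilon) {
  lab <- st$label
  clones <- data.frame(
    clone_id = paste0("clone_", seq_along(lab)),
    cluster = lab,
    category = st$category,
    cf_dx = unname(st$cf_dx[lab]),
    cf_rel = unname(st$cf_rel[lab]),
    parent_dx = unname(st$parent_dx[lab]),
    parent_rel = unname(st$parent_rel[lab]),
    residual_dx = unname(st$residual_dx[lab]),
    residual_rel = unname(st$residual_rel[lab]),
    stringsAsFactors = FALSE
  )
  # an established clone whose population is fully taken up by descendants at
  # both timepoints is inferred (below the ~1% detection level as its own
  # population), e.g. a founder seen only through its children
  clones$inferred <- !is.na(clones$residual_dx) &
    pmax(clones$residual_dx, 0) < 0.01 &
    (is.na(clones$residual_rel) | pmax(clones$residual_rel, 0) < 0.01) &
    clones$cluster %in% c(clones$parent_dx, clones$parent_rel)
  structure(
    list(clones = clones, epsilon = epsilon, ambiguity = st$ambiguity,
         founder = clones$cluster[is.na(clones$parent_dx) &
                                    clones$category == "shared"][1L],
         founder_edges = NULL),
    class = "lineage_tree"
  )
}

#' Build the diagnosis and relapse clonal lineage from mutation clusters
#'
#' Greedy reconstruction with population accounting: shared clusters are
#' processed first in descending diagnosis cell fraction -- the largest is
#' the founder clone, ancestral to everything at both timepoints -- and each
#' subsequent cluster is attached to the established clone with the largest
#' residual (not-yet-allocated) population, which is then reduced by the
#' newcomer's fraction. Diagnosis-specific clusters are added the same way.
#' The shared hierarchy is carried to the relapse side with residuals
#' recomputed from relapse fractions, and relapse-specific clusters are
#' attached analogously. A cluster whose fraction exceeds every candidate's
#' residual by more than `epsilon` makes the lineage infeasible (error).
#' Attachments with more than one feasible parent are recorded as ambiguous
#' (see [resolve_ambiguity()]).
#'
#' @param clusters Data frame with columns `label`, `category` (one of
#'   `"shared"`, `"dx_specific"`, `"rel_specific"`), `cf_dx`, `cf_rel`
#'   (cell fractions at each timepoint, 0 where absent).
#' @param epsilon Slack on the pigeonhole sum rule, in absolute cell
#'   fraction (default 0.05, matching sampling noise at deep coverage).
#' @return An object of class `"lineage_tree"`: list with `clones` (data
#'   frame: `clone_id`, `cluster`, `category`, fractions, `parent_dx`,
#'   `parent_rel` as cluster labels, residuals, `inferred` flag), `founder`,
#'   `ambiguity` (per-cluster candidate parents), `epsilon`.
#' @examples
#' cl <- data.frame(label = c("a", "b", "c"),
#'                  category = c("shared", "shared", "rel_specific"),
#'                  cf_dx = c(1, 0.5, 0), cf_rel = c(1, 1, 0.6))
#' build_lineage(cl)
#' @export
build_lineage <- function(clusters, epsilon = 0.05) {
  stopifnot(is.numeric(epsilon), epsilon >= 0)
  st <- .build_greedy(clusters, epsilon)
  .tree_from_state(st, epsilon)
}

#' Map relapse founder clones to their diagnosis progenitors
#'
#' A diagnosis clone's lineage survived therapy iff every cluster on its
#' path from the founder is shared (a diagnosis-specific cluster anywhere on
#' the path means that lineage was eradicated). The surviving clones deepest
#' in the tree -- those without a surviving child -- are the progenitors of
#' the relapse; each is one founder edge. Multiple progenitors constitute a
#' dual-lineage relapse.
#'
#' @param tree A `"lineage_tree"` from [build_lineage()].
#' @return The tree with `founder_edges` filled in: a data frame with one
#'   row per surviving diagnosis clone (`clone_id`, `cluster`, `cf_dx`,
#'   `cf_rel`, `dominant_dx`, `dominant_rel` flags for dominance-reversal
#'   inspection).
#' @export
map_relapse_founders <- function(tree) {
  stopifnot(inherits(tree, "lineage_tree"))
  cl <- tree$clones
  path_all_shared <- function(lab) {
    while (!is.na(lab)) {
      i <- match(lab, cl$cluster)
      if (cl$category[i] != "shared") return(FALSE)
      lab <- cl$parent_dx[i]
    }
    TRUE
  }
  surviving <- cl$cluster[vapply(cl$cluster, path_all_shared, logical(1))]
  if (length(surviving) == 0L) {
    stop("no relapse founder shares a cluster with any diagnosis clone; ",
         "a common preleukaemic ancestral origin is required")
  }
  leaves <- surviving[!vapply(surviving, function(s)
    any(cl$parent_dx[match(surviving, cl$cluster)] == s, na.rm = TRUE),
    logical(1))]
  idx <- match(leaves, cl$cluster)
  edges <- data.frame(
    clone_id = cl$clone_id[idx], cluster = leaves,
    cf_dx = cl$cf_dx[idx], cf_rel = cl$cf_rel[idx],
    stringsAsFactors = FALSE
  )
  edges$dominant_dx <- edges$cf_dx == max(edges$cf_dx)
  edges$dominant_rel <- edges$cf_rel == max(edges$cf_rel)
  tree$founder_edges <- edges[order(-edges$cf_dx, edges$cluster), ]
  rownames(tree$founder_edges) <- NULL
  tree
}

#' Resolve ambiguous parent assignments with biological evidence
#'
#' Re-runs the greedy attachment, and wherever more than one established
#' clone could accommodate a cluster (residual within `epsilon` of its
#' fraction) applies two rules before falling back to the default
#' largest-residual parent: (1) mutual exclusivity -- candidate parents whose
#' lineage path already carries an activating driver in the same gene or
#' pathway as the child's cluster are rejected; (2) mutation spectrum --
#' among the remaining candidates, those whose lineage-specific cluster
#' spectrum differs significantly from the child's (two-sided Fisher exact
#' test on the transition/transversion table, p < `p_threshold`) are
#' rejected. Unresolved ambiguity is annotated, never silently dropped: all
#' retained alternatives appear in the returned tree's `ambiguity` entry.
#'
#' @param tree A `"lineage_tree"` (its `clones` and `epsilon` are reused).
#' @param drivers Optional data frame of activating driver annotations:
#'   columns `cluster`, `gene`, `pathway` (either may be `NA`).
#' @param spectra Optional data frame of per-cluster spectra: columns
#'   `cluster`, `transitions`, `transversions`.
#' @param p_threshold Significance level for the spectrum test (default
#'   0.05).
#' @return A new `"lineage_tree"` with rule-informed parents; each
#'   `ambiguity` entry gains `rule` (`"mutual_exclusivity"`, `"spectrum"` or
#'   `"default"`), `alternatives` (candidates still viable after the rules)
#'   and `spectrum_p` values where computed. Founder edges are recomputed if
#'   they were present.
#' @export
resolve_ambiguity <- function(tree, drivers = NULL, spectra = NULL,
                              p_threshold = 0.05) {
  stopifnot(inherits(tree, "lineage_tree"))
  cl <- tree$clones
  clusters <- data.frame(label = cl$cluster, category = cl$category,
                         cf_dx = cl$cf_dx, cf_rel = cl$cf_rel,
                         stringsAsFactors = FALSE)
  notes <- list()

  driver_keys <- function(lab) {
    if (is.null(drivers)) return(character(0))
    d <- drivers[drivers$cluster == lab, , drop = FALSE]
    c(stats::na.omit(d$gene),
      if (!is.null(d$pathway)) stats::na.omit(d$pathway))
  }
  path_clusters <- function(lab, st) {
    out <- character(0)
    while (!is.na(lab)) {
      out <- c(out, lab)
      lab <- st$parent_dx[lab]
    }
    out
  }
  spec_counts <- function(lab) {
    if (is.null(spectra)) return(NULL)
    s <- spectra[spectra$cluster == lab, , drop = FALSE]
    if (nrow(s) != 1L) return(NULL)
    c(s$transitions, s$transversions)
  }

  chooser <- function(child, candidates, st) {
    if (length(candidates) == 1L) return(candidates)
    note <- list(candidates = candidates, rule = "default",
                 spectrum_p = NULL)
    viable <- candidates
    # rule 1: mutual exclusivity of activating drivers on one lineage path
    child_keys <- driver_keys(child)
    if (length(child_keys) > 0L) {
      conflicted <- vapply(viable, function(cand) {
        anc <- path_clusters(cand, st)
        any(unlist(lapply(anc, driver_keys)) %in% child_keys)
      }, logical(1))
      if (any(conflicted) && !all(conflicted)) {
        viable <- viable[!conflicted]
        note$rule <- "mutual_exclusivity"
      }
    }
    # rule 2: consistent mutation spectrum
    child_spec <- spec_counts(child)
    if (!is.null(child_spec) && length(viable) > 1L) {
      pvals <- vapply(viable, function(cand) {
        cs <- spec_counts(cand)
        if (is.null(cs)) NA_real_ else spectrum_test(child_spec, cs)
      }, numeric(1))
      note$spectrum_p <- pvals
      keep <- !is.na(pvals) & pvals >= p_threshold
      if (any(keep) && !all(keep | is.na(pvals))) {
        viable <- viable[keep]
        note$rule <- if (note$rule == "default") "spectrum" else note$rule
      }
    }
    pick <- viable[1L]
    note$selected <- pick
    note$alternatives <- setdiff(viable, pick)
    note$resolved <- length(viable) == 1L
    notes[[child]] <<- note
    pick
  }

  st <- .build_greedy(clusters, tree$epsilon, chooser)
  out <- .tree_from_state(st, tree$epsilon)
  for (nm in names(notes)) {
    base <- if (nm %in% names(out$ambiguity)) out$ambiguity[[nm]] else list()
    out$ambiguity[[nm]] <- c(base[setdiff(names(base), names(notes[[nm]]))],
                             notes[[nm]])
  }
  if (!is.null(tree$founder_edges)) out <- map_relapse_founders(out)
  out
}

#' Qualitative clonal placement of a structural variant or CNV
#'
#' SVs and CNVs cannot be placed quantitatively from read depth, so
#' placement is rule-based: by default an event is assigned to the
#' predominant/ancestral clone (oncogenic fusions are typically initiating
#' events), with two exceptions. (1) An event detected at diagnosis by deep
#' capture sequencing but missed by WGS is subclonal at diagnosis. (2) An
#' event classified relapse-specific by automated calling but found
#' subclonal at diagnosis on manual review of raw array probe intensities is
#' also subclonal at diagnosis. An event with diagnosis evidence cannot
#' simultaneously carry the manual relapse-specific override (error), and an
#' event detected nowhere is contradictory (error).
#'
#' @param event List with elements `event_id`, `type` (`"SV"` or `"CNV"`),
#'   `detected` (named logical flags among `dx_wgs`, `dx_capture`,
#'   `rel_wgs`, `rel_capture`; missing flags are taken as `FALSE`), and
#'   optional `manual_dx_subclonal` flag.
#' @return Placement label: `"ancestral"`, `"subclonal_dx"` or
#'   `"rel_specific"`.
#' @examples
#' place_sv_cnv(list(event_id = "fusion1", type = "SV",
#'                   detected = c(dx_wgs = TRUE, dx_capture = TRUE,
#'                                rel_wgs = TRUE)))
#' @export
place_sv_cnv <- function(event) {
  stopifnot(is.list(event), !is.null(event$detected))
  flags <- c(dx_wgs = FALSE, dx_capture = FALSE,
             rel_wgs = FALSE, rel_capture = FALSE)
  unknown <- setdiff(names(event$detected), names(flags))
  if (length(unknown) > 0L) stop("unknown detection flag: ",
                                 paste(unknown, collapse = ", "))
  flags[names(event$detected)] <- event$detected
  manual <- isTRUE(event$manual_dx_subclonal)
  det_dx <- flags["dx_wgs"] || flags["dx_capture"]
  det_rel <- flags["rel_wgs"] || flags["rel_capture"]
  if (!det_dx && !det_rel) {
    stop("contradictory flags for event '", event$event_id,
         "': not detected by any assay at any timepoint")
  }
  if (det_dx && manual) {
    stop("contradictory flags for event '", event$event_id,
         "': manual relapse-specific override set but event has diagnosis evidence")
  }
  if (det_dx) {
    if (flags["dx_capture"] && !flags["dx_wgs"]) "subclonal_dx" else "ancestral"
  } else {
    if (manual) "subclonal_dx" else "rel_specific"
  }
}

#' @export
print.lineage_tree <- function(x, ...) {
  cl <- x$clones
  cat(sprintf("Clonal lineage: %d clones, founder cluster '%s' (epsilon %.3g)\n",
              nrow(cl), x$founder, x$epsilon))
  show <- cl[, c("clone_id", "cluster", "category", "cf_dx", "cf_rel",
                 "parent_dx", "parent_rel", "inferred")]
  print(show, row.names = FALSE, digits = 3)
  if (!is.null(x$founder_edges)) {
    cat("Relapse founder edge(s):\n")
    print(x$founder_edges, row.names = FALSE, digits = 3)
  }
  amb <- x$ambiguity
  if (length(amb) > 0L) {
    for (nm in names(amb)) {
      a <- amb[[nm]]
      cat(sprintf("  ambiguity: cluster '%s' parents {%s}, selected '%s'%s\n",
                  nm, paste(a$candidates, collapse = ", "), a$selected,
                  if (!is.null(a$rule)) paste0(" by ", a$rule) else ""))
    }
  }
  invisible(x)
}
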