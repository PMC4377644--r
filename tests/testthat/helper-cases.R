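# Deterministic worked-case variant tables. Counts are exact expectations
# (round(maf * depth)) rather than sampled, so clustering and lineage
# reconstruction on them have a unique right answer.

make_variants <- function(n = 3) {
  data.frame(
    case_id = "CASE1", chrom = paste0("chr", seq_len(n)), pos = seq_len(n) * 100L,
    ref = rep("A", n), alt = rep("G", n),
    dx_mut = rep(40L, n), dx_tot = rep(400L, n),
    rel_mut = rep(200L, n), rel_tot = rep(400L, n),
    rem_mut = rep(0L, n), rem_tot = rep(400L, n),
    diploid = TRUE, gene = NA_character_, effect = NA_character_,
    pathway = NA_character_, stringsAsFactors = FALSE
  )
}

make_case_table <- function(layout, depth = 880L, case_id = "CASE") {
  rows <- lapply(seq_len(nrow(layout)), function(i) {
    n <- layout$n[i]
    data.frame(
      case_id = case_id, chrom = "chr1",
      pos = i * 10000L + seq_len(n),
      ref = "C", alt = "T",
      dx_mut = as.integer(round(layout$maf_dx[i] * depth)), dx_tot = depth,
      rel_mut = as.integer(round(layout$maf_rel[i] * depth)), rel_tot = depth,
      rem_mut = 0L, rem_tot = depth,
      diploid = TRUE, gene = NA_character_, effect = NA_character_,
      pathway = NA_character_, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# Minor-survivor case: shared founder cluster c (clonal both timepoints),
# predominant dx-specific lineage a, two minor clones b and d each carrying
# an activating JAK2 mutation (as does a), with d's lineage surviving and
# relapse-specific clusters e (clonal) and f (subclonal) nested under it.
minor_survivor_case_variants <- function() {
  layout <- data.frame(
    cluster = c("c", "a", "b", "d", "e", "f"),
    maf_dx = c(0.50, 0.47, 0.01, 0.02, 0, 0),
    maf_rel = c(0.50, 0, 0, 0.50, 0.50, 0.165),
    n = c(12L, 12L, 8L, 8L, 10L, 10L)
  )
  v <- make_case_table(layout, case_id = "MINOR_SURVIVOR")
  v$cluster_true <- rep(layout$cluster, layout$n)
  # one activating JAK-STAT driver in each of the competing clusters
  for (cl in c("a", "b", "d")) {
    i <- which(v$cluster_true == cl)[1L]
    v$gene[i] <- "JAK2"; v$pathway[i] <- "JAK_STAT"
  }
  v
}

# Dual-lineage case: shared ancestral cluster a with two shared sibling
# clusters b and c that both persist to relapse with reversed dominance
# (predominant 75% falling to 8%, minor 12.5% expanding to 84%);
# relapse-specific cluster d rides the expanded c lineage. Cluster centres
# competing in one fit respect the package's 0.05 MAF separation floor.
dual_lineage_case_variants <- function() {
  layout <- data.frame(
    cluster = c("a", "b", "c", "d"),
    maf_dx = c(0.50, 0.375, 0.0625, 0),
    maf_rel = c(0.50, 0.04, 0.42, 0.42),
    n = c(10L, 10L, 10L, 10L)
  )
  v <- make_case_table(layout, case_id = "DUAL_LINEAGE")
  v$cluster_true <- rep(layout$cluster, layout$n)
  v
}
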