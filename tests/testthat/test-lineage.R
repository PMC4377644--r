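test_that("cell fraction conversion inverts the diploid heterozygous MAF", {
  expect_equal(cluster_cell_fraction(0.5, 1.0), 1.0)
  expect_equal(cluster_cell_fraction(0.06, 0.24), 0.5)
  expect_equal(cluster_cell_fraction(0.233, 1.0), 0.466)
  expect_warning(cf <- cluster_cell_fraction(0.48, 0.5), "super-clonal")
  expect_equal(cf, 1.0)
})

test_that("a single shared cluster yields one founder clone and no children", {
  tr <- build_lineage(data.frame(label = "a", category = "shared",
                                 cf_dx = 1, cf_rel = 1))
  expect_equal(nrow(tr$clones), 1L)
  expect_equal(tr$founder, "a")
  expect_true(is.na(tr$clones$parent_dx))
  expect_equal(tr$clones$residual_dx, 1)
})

test_that("nested shared fractions produce a chain with correct residuals", {
  cl <- data.frame(label = c("a", "b", "c"), category = "shared",
                   cf_dx = c(1, 0.6, 0.2), cf_rel = c(1, 0.6, 0.2))
  tr <- build_lineage(cl)
  expect_equal(tr$clones$parent_dx, c(NA, "a", "b"))
  expect_equal(tr$clones$residual_dx, c(0.4, 0.4, 0.2))
  expect_equal(tr$clones$residual_rel, c(0.4, 0.4, 0.2))
})

test_that("exact residual ties resolve toward the clone nearer the founder", {
  # after attaching b, residuals of a and b are both 0.5; c prefers the founder
  cl <- data.frame(label = c("a", "b", "c"), category = "shared",
                   cf_dx = c(1, 0.5, 0.2), cf_rel = c(1, 0.5, 0.2))
  tr <- build_lineage(cl)
  expect_equal(tr$clones$parent_dx[3], "a")
  expect_equal(tr$ambiguity$c$candidates, c("a", "b"))
})

test_that("an infeasible cluster names itself in the error", {
  # 'big' persists clonally at relapse but no candidate parent has the
  # relapse population to hold it
  cl <- data.frame(label = c("a", "big"), category = "shared",
                   cf_dx = c(1, 0.9), cf_rel = c(0.5, 0.9))
  expect_error(build_lineage(cl), "big")
  expect_error(build_lineage(data.frame(label = "r", category = "rel_specific",
                                        cf_dx = 0, cf_rel = 1)),
               "shared")
})

test_that("minor-survivor architecture reconstructs with an inferred founder", {
  cl <- minor_survivor_clusters()
  drivers <- data.frame(cluster = c("a", "b", "d"), gene = "JAK2",
                        pathway = "JAK_STAT", stringsAsFactors = FALSE)
  tr <- resolve_ambiguity(map_relapse_founders(build_lineage(cl)),
                          drivers = drivers)
  clo <- tr$clones
  rownames(clo) <- clo$cluster
  # founder carries the top shared cluster; fully explained by descendants
  expect_equal(tr$founder, "c")
  expect_true(clo["c", "inferred"])
  # three detectable diagnosis clones under the founder; activating JAK2
  # mutations forced into sibling clones, never stacked on one path
  expect_equal(clo["a", "parent_dx"], "c")
  expect_equal(clo["b", "parent_dx"], "c")
  expect_equal(clo["d", "parent_dx"], "c")
  expect_equal(tr$ambiguity$b$rule, "mutual_exclusivity")
  # the minor shared cluster d survives and seeds nested relapse clones
  expect_equal(tr$founder_edges$cluster, "d")
  expect_equal(clo["e", "parent_rel"], "d")
  expect_equal(clo["f", "parent_rel"], "e")
})

test_that("dual-lineage architecture yields two founder edges with dominance reversal", {
  tr <- map_relapse_founders(build_lineage(dual_lineage_clusters()))
  fe <- tr$founder_edges
  expect_equal(nrow(fe), 2L)
  expect_setequal(fe$cluster, c("b", "c"))
  b <- fe[fe$cluster == "b", ]; cc <- fe[fe$cluster == "c", ]
  expect_true(b$dominant_dx && !b$dominant_rel)
  expect_true(cc$dominant_rel && !cc$dominant_dx)
  # the relapse-specific cluster nests under the lineage that expanded
  expect_equal(tr$clones$parent_rel[tr$clones$cluster == "d"], "c")
})

test_that("spectrum evidence re-parents an ambiguous relapse cluster", {
  cl <- data.frame(
    label = c("a", "b", "c", "d", "e"),
    category = c("shared", "shared", "rel_specific", "rel_specific",
                 "rel_specific"),
    cf_dx = c(1, 0.08, 0, 0, 0),
    cf_rel = c(1, 1, 1, 0.52, 0.30),
    stringsAsFactors = FALSE
  )
  base <- build_lineage(cl)
  # e fits under both c (residual 0.48) and d (residual 0.52); default is d
  expect_equal(base$clones$parent_rel[base$clones$cluster == "e"], "d")
  expect_setequal(base$ambiguity$e$candidates, c("c", "d"))
  # hypermutator-like spectrum: e matches c (77% transitions), differs from d
  spectra <- data.frame(cluster = c("c", "d", "e"),
                        transitions = c(77, 98, 76),
                        transversions = c(23, 1, 24))
  res <- resolve_ambiguity(base, spectra = spectra)
  expect_equal(res$clones$parent_rel[res$clones$cluster == "e"], "c")
  expect_equal(res$ambiguity$e$rule, "spectrum")
  expect_true(res$ambiguity$e$spectrum_p["d"] < 0.05)
  # with no evidence the ambiguity is retained and reported, not hidden
  res2 <- resolve_ambiguity(base)
  expect_equal(res2$ambiguity$e$rule, "default")
  expect_false(res2$ambiguity$e$resolved)
  expect_gt(length(res2$ambiguity$e$alternatives), 0)
})

test_that("lineage construction is deterministic", {
  cl <- minor_survivor_clusters()
  t1 <- build_lineage(cl)
  t2 <- build_lineage(cl)
  expect_identical(t1$clones, t2$clones)
})

test_that("pigeonhole conservation holds on reconstructed simulated cases", {
  for (s in c(4, 9, 15)) {
    r <- run_pipeline(list(simulate = list(seed = s), seed = s, K_max = 4))
    clo <- r$tree$clones
    expect_true(all(clo$residual_dx >= -r$tree$epsilon, na.rm = TRUE))
    expect_true(all(clo$residual_rel >= -r$tree$epsilon, na.rm = TRUE))
    # residual equals total minus allocated children
    for (i in seq_len(nrow(clo))) {
      kids_dx <- clo$cf_dx[!is.na(clo$parent_dx) & clo$parent_dx == clo$cluster[i]]
      if (!is.na(clo$residual_dx[i])) {
        expect_equal(clo$residual_dx[i], clo$cf_dx[i] - sum(kids_dx),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("SV/CNV placement follows the default-ancestral rule with exceptions", {
  # fusion seen by every assay at both timepoints
  expect_equal(place_sv_cnv(list(event_id = "fus", type = "SV",
                                 detected = c(dx_wgs = TRUE, dx_capture = TRUE,
                                              rel_wgs = TRUE, rel_capture = TRUE))),
               "ancestral")
  # capture-positive, WGS-negative at diagnosis: subclonal at diagnosis
  expect_equal(place_sv_cnv(list(event_id = "del", type = "SV",
                                 detected = c(dx_capture = TRUE, dx_wgs = FALSE,
                                              rel_wgs = TRUE))),
               "subclonal_dx")
  # relapse-only evidence
  expect_equal(place_sv_cnv(list(event_id = "cnv", type = "CNV",
                                 detected = c(rel_wgs = TRUE))),
               "rel_specific")
  # manual review override for automated relapse-specific calls
  expect_equal(place_sv_cnv(list(event_id = "cnv2", type = "CNV",
                                 detected = c(rel_wgs = TRUE),
                                 manual_dx_subclonal = TRUE)),
               "subclonal_dx")
  expect_error(place_sv_cnv(list(event_id = "none", type = "SV",
                                 detected = c(dx_wgs = FALSE))),
               "contradictory")
  expect_error(place_sv_cnv(list(event_id = "clash", type = "SV",
                                 detected = c(dx_wgs = TRUE, rel_wgs = TRUE),
                                 manual_dx_subclonal = TRUE)),
               "contradictory")
})
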