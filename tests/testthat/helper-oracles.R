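# Independent oracles used to validate the package's implementations.
# These deliberately share no code with the package: brute-force dynamic
# programming, dense grids and exhaustive enumeration only.

# Affine-gap Smith-Waterman by straightforward three-matrix DP, returning the
# best local score and one optimal subject->pattern column mapping. Scoring
# mirrors the package's stated scheme: match +2, mismatch -1, gap open -3
# (first gap base), extend -1 per further base.
oracle_local_align <- function(pattern, subject,
                               match = 2, mismatch = -1,
                               gap_open = 3, gap_ext = 1) {
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  np <- length(p); ns <- length(s)
  NEG <- -1e9
  M <- matrix(0, np + 1, ns + 1)        # alignment ends in match/mismatch
  Ix <- matrix(NEG, np + 1, ns + 1)     # ends in gap in subject (insertion)
  Iy <- matrix(NEG, np + 1, ns + 1)     # ends in gap in pattern (deletion)
  best <- 0; best_ij <- c(0L, 0L)
  for (i in seq_len(np)) {
    for (j in seq_len(ns)) {
      sc <- if (p[i] == s[j]) match else mismatch
      M[i + 1, j + 1] <- max(0, M[i, j], Ix[i, j], Iy[i, j]) + sc
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_ext,
                              Ix[i, j + 1] - gap_ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_ext,
                              Iy[i + 1, j] - gap_ext)
      if (M[i + 1, j + 1] > best) {
        best <- M[i + 1, j + 1]; best_ij <- c(i, j)
      }
    }
  }
  # traceback from the best cell through M/Ix/Iy
  cols <- list()   # list of c(pattern_index or NA, subject_index or NA)
  i <- best_ij[1]; j <- best_ij[2]
  state <- "M"
  while (i > 0 && j > 0) {
    if (state == "M") {
      if (M[i + 1, j + 1] <= 0) break
      cols[[length(cols) + 1]] <- c(i, j)
      sc <- if (p[i] == s[j]) match else mismatch
      prev <- M[i + 1, j + 1] - sc
      if (abs(prev) < 1e-9) { i <- i - 1; j <- j - 1; break }
      if (abs(prev - M[i, j]) < 1e-9) state <- "M"
      else if (abs(prev - Ix[i, j]) < 1e-9) state <- "Ix"
      else state <- "Iy"
      i <- i - 1; j <- j - 1
    } else if (state == "Ix") {
      cols[[length(cols) + 1]] <- c(i, NA)
      if (abs(Ix[i + 1, j + 1] - (M[i, j + 1] - gap_open - gap_ext)) < 1e-9) state <- "M"
      i <- i - 1
    } else {
      cols[[length(cols) + 1]] <- c(NA, j)
      if (abs(Iy[i + 1, j + 1] - (M[i + 1, j] - gap_open - gap_ext)) < 1e-9) state <- "M"
      j <- j - 1
    }
  }
  cols <- rev(cols)
  list(score = best, columns = cols)
}

# The read base the oracle alignment places at subject position `site`
# ("-" when deleted, NA when not covered).
oracle_base_at <- function(pattern, subject, site, ...) {
  al <- oracle_local_align(pattern, subject, ...)
  p <- strsplit(pattern, "")[[1]]
  for (col in al$columns) {
    if (!is.na(col[2]) && col[2] == site) {
      return(if (is.na(col[1])) "-" else p[col[1]])
    }
  }
  NA_character_
}

# Best log-likelihood of a K-cluster binomial mixture over a dense grid of
# centres and weights (specific model). Feasible only for tiny n and K <= 2.
oracle_grid_loglik <- function(x, n, K, p_grid = seq(0.01, 0.99, by = 0.01),
                               w_grid = seq(0.05, 0.95, by = 0.05)) {
  loglik <- function(p, w) {
    sum(vapply(seq_along(x), function(i) {
      log(sum(w * dbinom(x[i], n[i], p)))
    }, numeric(1)))
  }
  if (K == 1) {
    return(max(vapply(p_grid, function(p) loglik(p, 1), numeric(1))))
  }
  best <- -Inf
  for (p1 in p_grid) for (p2 in p_grid) {
    if (p2 < p1) next
    for (w in w_grid) {
      ll <- loglik(c(p1, p2), c(w, 1 - w))
      if (ll > best) best <- ll
    }
  }
  best
}

# Exact two-sided Fisher P value for a 2x2 table by hypergeometric
# enumeration: sum of P(tables as or less probable than observed) with fixed
# margins.
oracle_fisher_2x2 <- function(a, b, c, d) {
  m <- a + b; n_ <- c + d; k <- a + c
  lo <- max(0, k - n_); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) dhyper(x, m, n_, k), numeric(1))
  obs <- dhyper(a, m, n_, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# --- shared fixtures -------------------------------------------------------

# Worked-example cluster geometry of a case where a minor shared cluster
# survives therapy: founder (a: dx-specific predominant lineage sits beside
# it), clusters c (shared founder), a/b dx-specific, d minor shared rising,
# e/f relapse-specific (e clonal at relapse, f subclonal).
minor_survivor_clusters <- function() {
  data.frame(
    label = c("c", "a", "b", "d", "e", "f"),
    category = c("shared", "dx_specific", "dx_specific", "shared",
                 "rel_specific", "rel_specific"),
    cf_dx = c(1.0, 0.97, 0.01, 0.02, 0, 0),
    cf_rel = c(1.0, 0, 0, 1.0, 1.0, 0.67),
    stringsAsFactors = FALSE
  )
}

# Dual-lineage geometry: ancestral shared cluster a, two shared sibling
# clusters b and c that both persist, with clonal dominance reversed at
# relapse; relapse-specific d nests under the c lineage.
dual_lineage_clusters <- function() {
  data.frame(
    label = c("a", "b", "c", "d"),
    category = c("shared", "shared", "shared", "rel_specific"),
    cf_dx = c(1.0, 0.75, 0.125, 0),
    cf_rel = c(1.0, 0.08, 0.92, 0),
    stringsAsFactors = FALSE
  )
}
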