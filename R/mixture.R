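# Coverage-aware binomial mixture models for mutant allele fractions.
#
# Timepoint-specific model: X_i ~ sum_k lambda_k Binom(N_i, p_k).
# Shared (multiplicative) model for variants present at both timepoints:
# each cluster k has a diagnosis centre and a relapse centre and the
# per-variant likelihood is the product of the two binomial terms.

.clamp_center <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

# One EM run. `logdens(p)` returns the n x K matrix of per-variant,
# per-cluster log densities for centre parameterisation `p`;
# `mstep(z)` returns updated centres from responsibilities z.
.em_run <- function(n_obs, K, p0, logdens, mstep,
                    max_iter = 500L, tol = 1e-8) {
  p <- p0
  lambda <- rep(1 / K, K)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  z <- matrix(1 / K, n_obs, K)
  for (it in seq_len(max_iter)) {
    lw <- sweep(logdens(p), 2L, log(lambda), "+")
    ll_i <- .logsumexp_rows(lw)
    ll <- sum(ll_i)
    z <- exp(lw - ll_i)
    ll_trace <- c(ll_trace, ll)
    if (it > 1L && abs(ll - ll_old) < tol) break
    ll_old <- ll
    lambda <- colMeans(z)
    lambda[lambda < 1e-12] <- 1e-12
    lambda <- lambda / sum(lambda)
    p <- mstep(z, p)
  }
  list(p = p, lambda = lambda, z = z, loglik = ll_trace[length(ll_trace)],
       loglik_trace = ll_trace, iterations = length(ll_trace))
}

# Initial centres: a deterministic quantile-of-MAF start plus `restarts`
# jittered variants of it.
.init_centers <- function(maf, K, restarts) {
  base <- .clamp_center(as.numeric(quantile(maf, probs = seq_len(K) / (K + 1))))
  inits <- list(base)
  for (r in seq_len(restarts)) {
    inits[[r + 1L]] <- .clamp_center(base + runif(K, -0.05, 0.05))
  }
  inits
}

.new_mixture_fit <- function(model, best, K, n_obs, n_params, order_key) {
  ord <- order(order_key, decreasing = TRUE)
  centers <- if (is.matrix(best$p)) best$p[ord, , drop = FALSE] else best$p[ord]
  z <- best$z[, ord, drop = FALSE]
  # argmax responsibility; ties go to the smaller index after sorting
  # centres descending by diagnosis MAF
  assignments <- max.col(z, ties.method = "first")
  structure(
    list(model = model, K = K,
         centers = centers,
         weights = best$lambda[ord],
         responsibilities = z,
         assignments = assignments,
         loglik = best$loglik,
         loglik_trace = best$loglik_trace,
         aic = 2 * n_params - 2 * best$loglik,
         n_params = n_params,
         n_variants = n_obs,
         iterations = best$iterations),
    class = "mixture_fit"
  )
}

#' Fit a binomial mixture to mutant/total read counts at one timepoint
#'
#' Models mutant read counts as `X_i ~ sum_k lambda_k Binomial(N_i, p_k)` and
#' fits the K cluster centres `p_k` (cluster mutant allele fractions) and
#' mixing weights `lambda_k` by expectation-maximisation. Because the
#' binomial likelihood weights each variant by its own read depth, deeply
#' covered variants constrain the centres more than shallow ones. Intended
#' for variants in copy-neutral diploid regions, where a heterozygous
#' mutation carried by a fraction f of cells in a sample of purity u has an
#' expected mutant allele fraction of `u * f / 2`.
#'
#' @param x,n Integer vectors of mutant and total read counts (same length).
#' @param K Number of clusters (1 <= K <= number of variants).
#' @param seed Seed for the jittered restarts.
#' @param restarts Number of jittered restarts in addition to the
#'   deterministic quantile initialisation (default 10); the best-likelihood
#'   solution is kept.
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood
#'   improves by less than `tol` or after `max_iter` iterations.
#' @return An object of class `"mixture_fit"` with elements `model`
#'   (`"specific"`), `K`, `centers` (cluster MAFs, sorted decreasing),
#'   `weights`, `responsibilities` (n x K), `assignments` (hard labels),
#'   `loglik`, `loglik_trace`, `aic` (with `2K - 1` free parameters),
#'   `n_variants`.
#' @examples
#' set.seed(1)
#' n <- rpois(60, 800)
#' x <- rbinom(60, n, rep(c(0.45, 0.05), each = 30))
#' fit_specific_mixture(x, n, K = 2)$centers
#' @export
fit_specific_mixture <- function(x, n, K, seed = 1L, restarts = 10L,
                                 max_iter = 500L, tol = 1e-8) {
  stopifnot(length(x) == length(n), length(x) >= 1L,
            all(n >= 1), all(x >= 0), all(x <= n), .is_count(K, min = 1L))
  if (K > length(x)) stop("K (", K, ") exceeds the number of variants (", length(x), ")")
  logdens <- function(p) {
    matrix(vapply(p, function(pk) dbinom(x, n, pk, log = TRUE),
                  numeric(length(x))), nrow = length(x))
  }
  mstep <- function(z, p_old) {
    den <- colSums(z * n)
    num <- colSums(z * x)
    .clamp_center(ifelse(den > 0, num / den, p_old))
  }
  best <- .with_seed(seed, {
    inits <- .init_centers(x / n, K, restarts)
    fits <- lapply(inits, function(p0)
      .em_run(length(x), K, p0, logdens, mstep, max_iter, tol))
    fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  })
  .new_mixture_fit("specific", best, K, length(x),
                   n_params = 2L * K - 1L, order_key = best$p)
}

#' Fit a multiplicative binomial mixture to shared variants
#'
#' For variants present at both diagnosis and relapse, each cluster k is
#' parameterised by an independent diagnosis centre and relapse centre, and a
#' variant's likelihood under cluster k is the product of the two binomial
#' terms. This separates clusters that coincide at one timepoint but differ
#' at the other (e.g. a founder cluster and a minor rising cluster that are
#' both clonal at relapse).
#'
#' @param x_dx,n_dx Mutant and total read counts at diagnosis.
#' @param x_rel,n_rel Mutant and total read counts at relapse.
#' @inheritParams fit_specific_mixture
#' @return A `"mixture_fit"` with `model = "shared"` and `centers` a K x 2
#'   matrix (columns `dx`, `rel`), rows sorted by decreasing diagnosis
#'   centre; AIC uses `3K - 1` free parameters.
#' @examples
#' set.seed(1)
#' nd <- rpois(40, 800); nr <- rpois(40, 800)
#' xd <- rbinom(40, nd, rep(c(0.45, 0.01), each = 20))
#' xr <- rbinom(40, nr, 0.45)
#' fit_shared_mixture(xd, nd, xr, nr, K = 2)$centers
#' @export
fit_shared_mixture <- function(x_dx, n_dx, x_rel, n_rel, K, seed = 1L,
                               restarts = 10L, max_iter = 500L, tol = 1e-8) {
  m <- length(x_dx)
  stopifnot(length(n_dx) == m, length(x_rel) == m, length(n_rel) == m, m >= 1L,
            all(n_dx >= 1), all(n_rel >= 1),
            all(x_dx >= 0), all(x_dx <= n_dx),
            all(x_rel >= 0), all(x_rel <= n_rel),
            .is_count(K, min = 1L))
  if (K > m) stop("K (", K, ") exceeds the number of variants (", m, ")")
  logdens <- function(p) {
    matrix(vapply(seq_len(nrow(p)), function(k) {
      dbinom(x_dx, n_dx, p[k, 1L], log = TRUE) +
        dbinom(x_rel, n_rel, p[k, 2L], log = TRUE)
    }, numeric(m)), nrow = m)
  }
  mstep <- function(z, p_old) {
    dd <- colSums(z * n_dx); dr <- colSums(z * n_rel)
    pd <- ifelse(dd > 0, colSums(z * x_dx) / dd, p_old[, 1L])
    pr <- ifelse(dr > 0, colSums(z * x_rel) / dr, p_old[, 2L])
    cbind(.clamp_center(pd), .clamp_center(pr))
  }
  best <- .with_seed(seed, {
    inits_dx <- .init_centers(x_dx / n_dx, K, restarts)
    inits_rel <- .init_centers(x_rel / n_rel, K, restarts)
    fits <- lapply(seq_along(inits_dx), function(i)
      .em_run(m, K, cbind(inits_dx[[i]], inits_rel[[i]]),
              logdens, mstep, max_iter, tol))
    fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  })
  # sort by diagnosis centre, relapse centre as tie-break
  key <- best$p[, 1L] + 1e-9 * best$p[, 2L]
  fit <- .new_mixture_fit("shared", best, K, m,
                          n_params = 3L * K - 1L, order_key = key)
  colnames(fit$centers) <- c("dx", "rel")
  fit
}

#' Fit mixtures for K = 1..K_max and select the best model by AIC
#'
#' Fits the binomial mixture ([fit_specific_mixture()] or
#' [fit_shared_mixture()]) for each candidate number of clusters and returns
#' the fit minimising `AIC = 2k - 2 ln(L)`; ties are broken toward smaller K.
#'
#' @param counts A data frame of read counts. For `model = "specific"`,
#'   columns `mut` and `total`; for `model = "shared"`, columns `mut_dx`,
#'   `tot_dx`, `mut_rel`, `tot_rel`.
#' @param K_max Largest number of clusters to consider (capped at the number
#'   of variants).
#' @param model `"specific"` (one timepoint) or `"shared"` (both).
#' @inheritParams fit_specific_mixture
#' @return The winning `"mixture_fit"`, with an extra element `candidates`: a
#'   data frame of `K`, `loglik`, `aic` for every candidate fit.
#' @examples
#' set.seed(1)
#' n <- rpois(60, 800)
#' x <- rbinom(60, n, rep(c(0.45, 0.05), each = 30))
#' select_model(data.frame(mut = x, total = n), K_max = 4)$K
#' @export
select_model <- function(counts, K_max = 6L, model = c("specific", "shared"),
                         seed = 1L, restarts = 10L, max_iter = 500L,
                         tol = 1e-8) {
  model <- match.arg(model)
  stopifnot(is.data.frame(counts), nrow(counts) >= 1L, .is_count(K_max, min = 1L))
  n_var <- nrow(counts)
  ks <- seq_len(min(K_max, n_var))
  fits <- lapply(ks, function(K) {
    if (model == "specific") {
      fit_specific_mixture(counts$mut, counts$total, K, seed = seed + K,
                           restarts = restarts, max_iter = max_iter, tol = tol)
    } else {
      fit_shared_mixture(counts$mut_dx, counts$tot_dx,
                         counts$mut_rel, counts$tot_rel, K, seed = seed + K,
                         restarts = restarts, max_iter = max_iter, tol = tol)
    }
  })
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  best_i <- 1L
  for (i in seq_along(ks)) {
    if (aics[i] < aics[best_i] - 1e-9) best_i <- i  # strict: ties keep smaller K
  }
  fit <- fits[[best_i]]
  fit$candidates <- data.frame(
    K = ks,
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    aic = aics
  )
  fit
}

#' Estimate tumour purity from diploid coding SNV allele fractions
#'
#' Clusters the mutant allele fractions of diploid heterozygous coding SNVs
#' at one timepoint with the binomial mixture ([select_model()]) and
#' estimates purity as twice the highest cluster centre among centres
#' <= 0.5. The rationale: clonal heterozygous mutations sit at MAF =
#' purity / 2, and centres above 0.5 indicate loss of heterozygosity or
#' copy-number effects rather than the clonal diploid peak.
#'
#' @param x,n Mutant and total read counts at one timepoint for diploid
#'   coding SNVs.
#' @param K_max,seed,restarts Passed to [select_model()].
#' @return An object of class `"purity_summary"`: list with `purity` (capped
#'   at 1), `cluster_centers`, `K`, and the underlying `fit`.
#' @examples
#' set.seed(1)
#' n <- rpois(50, 800)
#' x <- rbinom(50, n, 0.45)   # clonal het SNVs in a 90%-pure sample
#' estimate_purity(x, n)$purity
#' @export
estimate_purity <- function(x, n, K_max = 6L, seed = 1L, restarts = 10L) {
  stopifnot(length(x) >= 1L)
  fit <- select_model(data.frame(mut = x, total = n), K_max = K_max,
                      model = "specific", seed = seed, restarts = restarts)
  eligible <- fit$centers[fit$centers <= 0.5 + 1e-9]
  if (length(eligible) == 0L) {
    stop("all cluster centres exceed 0.5; purity is undefined ",
         "(suggests non-diploid loci or loss of heterozygosity in the input)")
  }
  structure(
    list(purity = min(1, 2 * max(eligible)),
         cluster_centers = fit$centers, K = fit$K, fit = fit),
    class = "purity_summary"
  )
}

#' @export
print.purity_summary <- function(x, ...) {
  cat(sprintf("Estimated tumour purity: %.3f (2 x highest cluster centre <= 0.5)\n",
              x$purity))
  cat("  cluster centres:", paste(sprintf("%.3f", x$cluster_centers), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Binomial mixture fit (%s model): K = %d, n = %d variants\n",
              x$model, x$K, x$n_variants))
  if (is.matrix(x$centers)) {
    for (k in seq_len(x$K)) {
      cat(sprintf("  cluster %d: centre dx %.4f / rel %.4f, weight %.3f\n",
                  k, x$centers[k, 1L], x$centers[k, 2L], x$weights[k]))
    }
  } else {
    for (k in seq_len(x$K)) {
      cat(sprintf("  cluster %d: centre %.4f, weight %.3f\n",
                  k, x$centers[k], x$weights[k]))
    }
  }
  cat(sprintf("  loglik %.2f, AIC %.2f (%d free parameters, %d EM iterations)\n",
              x$loglik, x$aic, x$n_params, x$iterations))
  invisible(x)
}
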