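#' Fit a 1-D Gaussian mixture to major-allele ploidy
#'
#' Expectation-maximisation fit of a univariate Gaussian mixture to the
#' cohort's major-allele ploidies, the clustering step behind genome
#' doubling detection.  The number of components is selected by
#' minimum BIC over `K_candidates`.  Initialisation is k-means++-style
#' seeded sampling of data points as starting means, with `n_restarts`
#' restarts; convergence is declared when the log-likelihood improves
#' by less than `tol`.  Component variances are floored at `var_floor`
#' so that degenerate cohorts (all samples identical) remain
#' well-defined.
#'
#' The feature is major-allele ploidy rather than total ploidy because
#' haploidised-then-doubled genomes sit near total ploidy 2 but
#' major-allele ploidy 2, and such genomes are genome doubled.
#'
#' @param psi_major Numeric vector of per-sample major-allele ploidies
#'   (see [major_ploidy()]); at least 10 values.
#' @param K_candidates Component counts to try; default `1:3`.
#' @param n_restarts EM restarts per K; default 20.
#' @param tol Log-likelihood convergence tolerance; default 1e-8.
#' @param var_floor Minimum component variance; default 1e-4.
#' @param seed Seed for the restart initialisations.
#' @return Object of class `ploidy_mixture`: list with `K`, `means`,
#'   `variances`, `weights`, `loglik`, `loglik_trace` (per iteration of
#'   the winning run), `bic` (named by K, selected K minimal), and the
#'   input data.
#' @export
fit_ploidy_mixture <- function(psi_major, K_candidates = 1:3,
                               n_restarts = 20, tol = 1e-8,
                               var_floor = 1e-4, seed = 1) {
  x <- as.numeric(psi_major)
  n <- length(x)
  if (n < 10L)
    stop("mixture fitting needs >= 10 samples; use the fallback ",
         "threshold rule (call_gd with fit = NULL)", call. = FALSE)
  set.seed(as.integer(seed))
  best_by_K <- list()
  bic <- stats::setNames(rep(NA_real_, length(K_candidates)),
                         K_candidates)
  for (K in K_candidates) {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- .em_1d(x, K, tol = tol, var_floor = var_floor)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    # parameters: K means + K variances + (K - 1) free weights
    bic[as.character(K)] <- -2 * best$loglik + (3 * K - 1) * log(n)
    best_by_K[[as.character(K)]] <- best
  }
  K_sel <- K_candidates[which.min(bic)]
  fit <- best_by_K[[as.character(K_sel)]]
  structure(list(K = K_sel, means = fit$means,
                 variances = fit$variances, weights = fit$weights,
                 loglik = fit$loglik, loglik_trace = fit$trace,
                 bic = bic, data = x),
            class = "ploidy_mixture")
}

# one EM run with k-means++-style initial means drawn from the data
.em_1d <- function(x, K, tol, var_floor, max_iter = 500L) {
  n <- length(x)
  mu <- numeric(K)
  mu[1L] <- x[sample.int(n, 1L)]
  if (K > 1L) for (k in 2:K) {
    d2 <- vapply(x, function(v) min((v - mu[1:(k - 1L)])^2), numeric(1L))
    mu[k] <- if (sum(d2) == 0) x[sample.int(n, 1L)] else
      x[sample.int(n, 1L, prob = d2)]
  }
  sig2 <- rep(max(stats::var(x) / K, var_floor), K)
  if (is.na(sig2[1L])) sig2 <- rep(var_floor, K)
  w <- rep(1 / K, K)
  trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(K), function(k)
      w[k] * stats::dnorm(x, mu[k], sqrt(sig2[k])), numeric(n))
    dens <- matrix(dens, nrow = n)
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d == 0] <- .Machine$double.xmin
    ll <- sum(log(rowsum_d))
    trace <- c(trace, ll)
    resp <- dens / rowsum_d
    nk <- colSums(resp)
    nk[nk == 0] <- .Machine$double.eps
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sig2 <- pmax(colSums(resp * (outer(x, mu, "-")^2)) / nk, var_floor)
    if (ll - ll_old < tol && it > 1L) break
    ll_old <- ll
  }
  list(means = mu, variances = sig2, weights = w, loglik = ll,
       trace = trace)
}

#' Call genome doubling per sample
#'
#' With a [fit_ploidy_mixture()] fit, a sample is genome doubled iff
#' its maximum-posterior mixture component has mean major-allele
#' ploidy at or above `boundary` (default 1.6, between the theoretical
#' diploid value 1 and doubled value 2, with margin for noise).
#' Without a fit — small cohorts, where mixture fits are unstable —
#' the fallback rule thresholds each sample's own major-allele ploidy
#' at the same boundary.
#'
#' @param profiles `data.frame` from [ploidy_profile()] (needs
#'   `sample_id` and `major_ploidy`).
#' @param fit Optional `ploidy_mixture`; `NULL` selects the fallback.
#' @param boundary GD decision boundary on major-allele ploidy.
#' @return `data.frame` with `sample_id`, `major_ploidy`, `gd`,
#'   `component_mean`, `posterior`, `method`.
#' @export
call_gd <- function(profiles, fit = NULL, boundary = 1.6) {
  psi <- profiles$major_ploidy
  if (is.null(fit)) {
    out <- data.frame(sample_id = profiles$sample_id,
                      major_ploidy = psi, gd = psi >= boundary,
                      component_mean = psi, posterior = NA_real_,
                      method = "fallback_threshold",
                      stringsAsFactors = FALSE)
    return(out)
  }
  stopifnot(inherits(fit, "ploidy_mixture"))
  post <- vapply(seq_len(fit$K), function(k)
    fit$weights[k] * stats::dnorm(psi, fit$means[k],
                                  sqrt(fit$variances[k])),
    numeric(length(psi)))
  post <- matrix(post, nrow = length(psi))
  denom <- rowSums(post)
  denom[denom == 0] <- .Machine$double.xmin
  post <- post / denom
  comp <- max.col(post, ties.method = "first")
  data.frame(sample_id = profiles$sample_id, major_ploidy = psi,
             gd = fit$means[comp] >= boundary,
             component_mean = fit$means[comp],
             posterior = post[cbind(seq_along(comp), comp)],
             method = "mixture", stringsAsFactors = FALSE)
}

#' Call partial haploidisation
#'
#' A sample exhibits partial haploidisation iff strictly more than 50%
#' of its autosomal genome is in LOH; exactly 50% is not HP.
#'
#' @param loh_fraction Numeric vector of LOH genome fractions.
#' @param threshold Decision threshold; default 0.5.
#' @return Logical vector.
#' @export
#' @examples
#' call_hp(c(0.49, 0.5, 0.51))  # FALSE FALSE TRUE
call_hp <- function(loh_fraction, threshold = 0.5) {
  loh_fraction > threshold
}

#' GD and HP for a whole segment table
#'
#' Convenience pipeline: ploidy profiles, mixture fit (when the cohort
#' has at least `min_cohort` samples, otherwise the fallback threshold
#' rule) and the per-sample GD and HP calls.
#'
#' @param segments Validated multi-sample segment `data.frame`.
#' @param boundary GD boundary on major-allele ploidy; default 1.6.
#' @param min_cohort Minimum cohort size for mixture-based calling;
#'   default 10.
#' @param seed Seed for the mixture fit.
#' @return `data.frame`: one row per sample with `sample_id`, `ploidy`,
#'   `major_ploidy`, `loh_fraction`, `gd`, `hp`, `component_mean`,
#'   `posterior`, `method`.  The mixture fit (or `NULL`) is attached as
#'   attribute `"fit"`.
#' @export
call_gd_hp <- function(segments, boundary = 1.6, min_cohort = 10,
                       seed = 1) {
  prof <- ploidy_profile(segments)
  fit <- if (nrow(prof) >= min_cohort)
    fit_ploidy_mixture(prof$major_ploidy, seed = seed) else NULL
  gd <- call_gd(prof, fit, boundary = boundary)
  out <- data.frame(sample_id = prof$sample_id, ploidy = prof$ploidy,
                    major_ploidy = prof$major_ploidy,
                    loh_fraction = prof$loh_fraction,
                    gd = gd$gd, hp = call_hp(prof$loh_fraction),
                    component_mean = gd$component_mean,
                    posterior = gd$posterior, method = gd$method,
                    stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  out
}

#' GD x HP co-occurrence summary
#'
#' Cross-tabulates the GD and HP calls and reports the fraction of HP
#' samples that are also GD (in the motivating cohort this fraction is
#' 1: haploidisation was always followed by doubling).
#'
#' @param calls `data.frame` with logical `gd` and `hp` columns.
#' @return List with `table` (2x2 matrix, GD in rows), `n_hp_not_gd`
#'   and `frac_hp_with_gd` (`NaN` when no HP samples).
#' @export
hp_gd_cooccurrence <- function(calls) {
  tab <- matrix(c(sum(calls$gd & calls$hp), sum(calls$gd & !calls$hp),
                  sum(!calls$gd & calls$hp), sum(!calls$gd & !calls$hp)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(gd = c("GD", "noGD"),
                                hp = c("HP", "noHP")))
  list(table = tab, n_hp_not_gd = tab["noGD", "HP"],
       frac_hp_with_gd = tab["GD", "HP"] / sum(tab[, "HP"]))
}
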