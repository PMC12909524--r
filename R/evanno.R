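#' Evanno delta-K from a table of replicate run log-likelihoods
#'
#' Given replicate log-probabilities lnP(D) for consecutive K values (from
#' any structure-inference program or from [admixture_em()] restarts),
#' computes the mean L(K), sample standard deviation s(K), first difference
#' L'(K) = L(K) - L(K-1), second difference |L''(K)| = |L'(K+1) - L'(K)|,
#' and the per-K statistic \eqn{\Delta K = |L''(K)| / s(K)}. The supported
#' cluster number is the K with the largest defined delta-K. Delta-K is
#' undefined (flagged `NA`) where s(K) = 0; by construction it cannot be
#' evaluated at the smallest or largest K, so the method never supports
#' K = 1.
#'
#' @param runs data.frame with columns `K` and `lnP` (one row per replicate
#'   run); at least 3 consecutive K values with >= 2 replicates each.
#' @return object of class `evanno_table`: data.frame with columns `K`,
#'   `n_runs`, `mean_lnP`, `sd_lnP`, `L_prime`, `abs_L_doubleprime`,
#'   `delta_K`, plus attribute `optimal_K`.
#' @export
evanno_delta_k <- function(runs) {
  stopifnot(is.data.frame(runs), all(c("K", "lnP") %in% names(runs)))
  ks <- sort(unique(runs$K))
  if (length(ks) < 3L || !all(diff(ks) == 1))
    stop("at least 3 consecutive K values are required")
  n_runs <- vapply(ks, function(k) sum(runs$K == k), integer(1))
  if (any(n_runs < 2L))
    stop("at least 2 replicate runs per K are required")
  L <- vapply(ks, function(k) mean(runs$lnP[runs$K == k]), numeric(1))
  s <- vapply(ks, function(k) stats::sd(runs$lnP[runs$K == k]), numeric(1))
  m <- length(ks)
  Lp <- c(NA, diff(L))                         # L'(K), defined from 2nd K
  Lpp <- rep(NA_real_, m)
  if (m >= 3L) Lpp[2:(m - 1)] <- abs(Lp[3:m] - Lp[2:(m - 1)])
  dK <- ifelse(!is.na(Lpp) & s > 0, Lpp / s, NA_real_)
  tab <- data.frame(K = ks, n_runs = n_runs, mean_lnP = L, sd_lnP = s,
                    L_prime = Lp, abs_L_doubleprime = Lpp, delta_K = dK)
  opt <- if (all(is.na(dK))) NA_integer_ else ks[which.max(dK)]
  structure(tab, class = c("evanno_table", "data.frame"), optimal_K = opt)
}

#' @export
print.evanno_table <- function(x, ...) {
  NextMethod()
  cat(sprintf("Supported K (largest delta-K): %s\n",
              attr(x, "optimal_K")))
  invisible(x)
}
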