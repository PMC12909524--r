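#' Allele-sharing (p-) distance matrix
#'
#' For each accession pair, over loci where both are called, the shared
#' allele count per locus is the multiset intersection of the two allele
#' pairs (0, 1 or 2); the distance is 1 minus the proportion of shared
#' alleles, \eqn{d = 1 - \sum_l s_l / (2 L_{compared})}. A semimetric on
#' [0, 1]: zero iff the profiles agree on every mutually called locus.
#'
#' @param genotypes accessions x markers genotype matrix.
#' @return object of class `allele_sharing_dist`: list with `d` (symmetric
#'   matrix, `NA` where no loci could be compared), `n_loci_compared`
#'   (symmetric count matrix) and `labels`. Accessions with zero called loci
#'   are excluded with a warning.
#' @export
allele_sharing_distance <- function(genotypes) {
  gm <- as_genotype_matrix(genotypes)
  called_any <- rowSums(!is.na(gm)) > 0L
  if (any(!called_any)) {
    warning(sprintf("excluding %d accession(s) with zero called loci: %s",
                    sum(!called_any), paste(rownames(gm)[!called_any], collapse = ", ")))
    gm <- gm[called_any, , drop = FALSE]
  }
  n <- nrow(gm)
  if (n < 2L) stop("at least two accessions with called genotypes are required")
  L <- ncol(gm)

  # per-locus allele-count matrices: for each locus, counts of each observed
  # allele per accession (biallelic in practice; general here)
  a1 <- matrix(substr(gm, 1L, 1L), n, L)
  a2 <- matrix(substr(gm, 2L, 2L), n, L)
  counts <- vector("list", L)
  for (l in seq_len(L)) {
    als <- sort(unique(c(a1[, l], a2[, l])))
    als <- als[!is.na(als)]
    cm <- vapply(als, function(a) (a1[, l] == a) + (a2[, l] == a),
                 numeric(n))
    counts[[l]] <- matrix(cm, nrow = n)   # n x n_alleles, NA rows = missing
  }

  d <- matrix(0, n, n, dimnames = list(rownames(gm), rownames(gm)))
  ncmp <- matrix(0L, n, n, dimnames = dimnames(d))
  diag(ncmp) <- as.integer(rowSums(!is.na(gm)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- 0; compared <- 0L
      for (l in seq_len(L)) {
        ci <- counts[[l]][i, ]; cj <- counts[[l]][j, ]
        if (anyNA(ci) || anyNA(cj)) next
        shared <- shared + sum(pmin(ci, cj))
        compared <- compared + 1L
      }
      ncmp[i, j] <- ncmp[j, i] <- compared
      d[i, j] <- d[j, i] <- if (compared == 0L) NA_real_ else 1 - shared / (2 * compared)
    }
  }
  structure(list(d = d, n_loci_compared = ncmp, labels = rownames(gm)),
            class = "allele_sharing_dist")
}

#' @export
as.dist.allele_sharing_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$d, diag = diag, upper = upper)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]); negative branch-length
#' estimates are clamped to zero and flagged. Exact on additive distances.
#'
#' @param dist an `allele_sharing_dist`, [stats::dist] or symmetric matrix.
#' @return an [ape] `phylo` tree; attribute `clamped_branches` gives how many
#'   negative branch lengths were set to 0.
#' @export
nj_tree <- function(dist) {
  d <- if (inherits(dist, "allele_sharing_dist")) dist$d
       else if (inherits(dist, "dist")) as.matrix(dist)
       else as.matrix(dist)
  if (anyNA(d)) {
    bad <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
    stop(sprintf("undefined distances for pairs: %s",
                 paste(apply(bad, 1L, function(r)
                   paste(rownames(d)[r[1]], colnames(d)[r[2]], sep = "/")),
                   collapse = ", ")))
  }
  if (nrow(d) < 3L) stop("neighbor joining requires at least 3 taxa")
  tree <- ape::nj(stats::as.dist(d))
  neg <- tree$edge.length < 0
  tree$edge.length[neg] <- 0
  attr(tree, "clamped_branches") <- sum(neg)
  tree
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples loci (marker columns) with replacement `B` times, rebuilds the
#' allele-sharing NJ tree for each replicate, and scores every internal
#' bipartition of the point-estimate tree by the percentage of replicates
#' containing it ([ape::prop.clades()]). Replicates yielding undefined
#' distances are dropped from the denominator.
#'
#' @param genotypes accessions x markers genotype matrix (>= 4 accessions).
#' @param B number of bootstrap replicates.
#' @param seed integer seed.
#' @return the point-estimate `phylo` tree with `node.label` set to support
#'   percentages and attribute `n_effective_replicates`.
#' @export
bootstrap_support <- function(genotypes, B = 1000, seed = 1) {
  if (B < 1) stop("B must be at least 1")
  gm <- as_genotype_matrix(genotypes)
  if (nrow(gm) < 4L) stop("bootstrap support requires at least 4 accessions")
  set.seed(seed)
  point <- nj_tree(allele_sharing_distance(gm))
  reps <- vector("list", B)
  ok <- logical(B)
  for (b in seq_len(B)) {
    cols <- sample.int(ncol(gm), replace = TRUE)
    tr <- tryCatch(nj_tree(allele_sharing_distance(gm[, cols, drop = FALSE])),
                   error = function(e) NULL)
    if (!is.null(tr)) { reps[[b]] <- tr; ok[b] <- TRUE }
  }
  reps <- reps[ok]
  cnt <- ape::prop.clades(point, reps, rooted = FALSE)
  cnt[is.na(cnt)] <- 0L
  point$node.label <- round(100 * cnt / length(reps))
  attr(point, "n_effective_replicates") <- length(reps)
  point
}

#' Principal component analysis of a genotype matrix
#'
#' Codes genotypes as minor-allele dosage (0/1/2), mean-imputes missing
#' values per marker, column-centers, and eigendecomposes the covariance.
#'
#' @param genotypes accessions x markers genotype matrix.
#' @param n_components number of components to return.
#' @return list with `coordinates` (n x n_components), `var_explained`
#'   (fractions of total variance, non-increasing) and `sdev` (all singular
#'   values / sqrt(n-1)). Constant markers are dropped; an all-constant
#'   matrix is an error.
#' @export
genotype_pca <- function(genotypes, n_components = 2) {
  dos <- genotype_dosage(genotypes)
  for (j in seq_len(ncol(dos))) {
    mis <- is.na(dos[, j])
    if (all(mis)) { dos[, j] <- 0; next }
    dos[mis, j] <- mean(dos[!mis, j])
  }
  keep <- apply(dos, 2L, function(x) stats::var(x) > 0)
  if (!any(keep)) stop("degenerate input: all markers are constant")
  dos <- dos[, keep, drop = FALSE]
  dos <- scale(dos, center = TRUE, scale = FALSE)
  p <- stats::prcomp(dos, center = FALSE, scale. = FALSE)
  n_components <- min(n_components, ncol(p$x))
  varfrac <- p$sdev^2 / sum(p$sdev^2)
  list(coordinates = p$x[, seq_len(n_components), drop = FALSE],
       var_explained = varfrac[seq_len(n_components)],
       sdev = p$sdev)
}

#' Fit the admixture model by EM
#'
#' Maximizes the binomial admixture log-likelihood
#' \deqn{\ell = \sum_{il} g_{il}\log q_{il} + (2-g_{il})\log(1-q_{il}),
#'   \qquad q_{il} = \sum_k Q_{ik} P_{kl},}
#' over row-stochastic ancestry proportions Q (n x K) and subpopulation
#' allele frequencies P (K x L) by alternating multiplicative EM updates,
#' from seeded random starts (Dirichlet(1) rows of Q, uniform P). Missing
#' genotypes are skipped. The best of `n_restarts` runs by final
#' log-likelihood is returned. This is a desk-scale maximum-likelihood
#' fitter for the same admixture likelihood that MCMC samplers such as
#' STRUCTURE explore; it does not emulate their priors or output format.
#'
#' @param genotypes accessions x markers genotype matrix, or a numeric
#'   dosage matrix (0/1/2, `NA` missing).
#' @param K number of source populations (1 <= K <= n).
#' @param seed integer seed (restart r uses `seed + r - 1`).
#' @param tol convergence tolerance on the log-likelihood increment.
#' @param max_iter maximum EM iterations per restart.
#' @param n_restarts number of random restarts.
#' @return object of class `admixture_fit`: list with `Q`, `P`, `loglik`,
#'   `loglik_trace` (non-decreasing), `converged`, `K`, `restart_logliks`.
#' @export
admixture_em <- function(genotypes, K, seed = 1, tol = 1e-6,
                         max_iter = 2000, n_restarts = 5) {
  G <- if (is.numeric(genotypes)) {
    g <- as.matrix(genotypes)
    if (is.null(rownames(g))) rownames(g) <- paste0("acc", seq_len(nrow(g)))
    g
  } else genotype_dosage(genotypes)
  n <- nrow(G); L <- ncol(G)
  if (K < 1 || K != round(K)) stop("invalid configuration: K must be a positive integer")
  if (K > n) stop("invalid configuration: K exceeds the number of accessions")
  obs <- !is.na(G)
  if (!any(obs)) stop("no called genotypes")
  Gz <- G; Gz[!obs] <- 0
  Hz <- 2 - G; Hz[!obs] <- 0
  L_i <- rowSums(obs)
  eps <- 1e-6

  run_em <- function(rseed) {
    set.seed(rseed)
    Q <- matrix(stats::rgamma(n * K, 1), n, K); Q <- Q / rowSums(Q)
    P <- matrix(stats::runif(K * L, 0.05, 0.95), K, L)
    trace <- numeric(0)
    ll_old <- -Inf; converged <- FALSE
    for (it in seq_len(max_iter)) {
      Qm <- Q %*% P
      Qm <- pmin(pmax(Qm, eps), 1 - eps)
      A <- Gz / Qm; B <- Hz / (1 - Qm)
      # log-likelihood at current parameters
      ll <- sum((Gz * log(Qm) + Hz * log(1 - Qm))[obs])
      trace <- c(trace, ll)
      if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
      ll_old <- ll
      # EM updates
      Qn <- Q * (A %*% t(P) + B %*% t(1 - P))
      Q <- Qn / (2 * pmax(L_i, 1))
      Q <- Q / rowSums(Q)
      Nm <- P * (t(Q) %*% A)
      Dm <- (1 - P) * (t(Q) %*% B)
      P <- Nm / (Nm + Dm)
      P[!is.finite(P)] <- 0.5
      P <- pmin(pmax(P, eps), 1 - eps)
    }
    list(Q = Q, P = P, loglik = trace[length(trace)], trace = trace,
         converged = converged)
  }

  fits <- lapply(seq_len(n_restarts), function(r) run_em(seed + r - 1L))
  lls <- vapply(fits, `[[`, numeric(1), "loglik")
  best <- fits[[which.max(lls)]]
  dimnames(best$Q) <- list(rownames(G), paste0("pop", seq_len(K)))
  dimnames(best$P) <- list(paste0("pop", seq_len(K)), colnames(G))
  structure(list(Q = best$Q, P = best$P, loglik = best$loglik,
                 loglik_trace = best$trace, converged = best$converged,
                 K = K, restart_logliks = lls),
            class = "admixture_fit")
}
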