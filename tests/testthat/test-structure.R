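test_that("allele-sharing distance counts shared alleles per locus", {
  gm <- rbind(a1 = c("AA", "AG", "CC", "GT"),
              a2 = c("AA", "AA", "TT", "GT"))
  colnames(gm) <- paste0("m", 1:4)
  d <- allele_sharing_distance(gm)
  expect_equal(d$d["a1", "a2"], 1 - 5 / 8)   # shared: 2 + 1 + 0 + 2
  expect_equal(d$d["a1", "a1"], 0)
  expect_equal(d$n_loci_compared["a1", "a2"], 4L)
  # identical accessions
  gm2 <- rbind(x = gm[1, ], y = gm[1, ])
  expect_equal(allele_sharing_distance(gm2)$d["x", "y"], 0)
  # one allele difference at 1 of 31 loci
  g31 <- matrix("AA", 2, 31, dimnames = list(c("u", "v"), paste0("m", 1:31)))
  g31["v", 31] <- "AG"
  expect_equal(allele_sharing_distance(g31)$d["u", "v"], 1 - 61 / 62)
})

test_that("the distance is a semimetric on [0,1] and honors pairwise deletion", {
  for (seed in 1:20) {
    sim <- simulate_population(n_accessions = 10, n_markers = 12,
                               missing_rate = 0.1, seed = seed)
    d <- allele_sharing_distance(sim$genotypes)$d
    expect_true(all(diag(d) == 0))
    expect_equal(d, t(d))
    expect_true(all(d[!is.na(d)] >= 0 & d[!is.na(d)] <= 1))
  }
  # zero-overlap pair flagged undefined
  gm <- rbind(p = c("AA", NA), q = c(NA, "GG"), r = c("AA", "GG"))
  colnames(gm) <- c("m1", "m2")
  d <- allele_sharing_distance(gm)
  expect_true(is.na(d$d["p", "q"]))
  expect_error(nj_tree(d), "undefined")
})

test_that("neighbor joining solves the 3-taxon closed form", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- nj_tree(d)
  bl <- stats::setNames(tree$edge.length, tree$tip.label[tree$edge[, 2]])
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 2, 3))
})

test_that("NJ recovers random additive trees exactly", {
  set.seed(77)
  for (i in 1:50) {
    n <- sample(4:10, 1)
    true <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    d <- ape::cophenetic.phylo(true)
    est <- nj_tree(d[true$tip.label, true$tip.label])
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(true), est)), 0)
    dd <- ape::cophenetic.phylo(est)[true$tip.label, true$tip.label]
    expect_equal(dd, d, tolerance = 1e-8)
  }
})

test_that("equidistant taxa produce a clamped or zero internal branch", {
  d <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  tree <- nj_tree(d)
  internal <- tree$edge[, 2] > length(tree$tip.label)
  expect_true(any(tree$edge.length[internal] <= 1e-12))
})

test_that("bootstrap support finds a strongly differentiated split and is reproducible", {
  sim <- simulate_population(n_accessions = 16, n_markers = 80, n_subpops = 2,
                             fst = 0.4, dirichlet_alpha = 0.05,
                             missing_rate = 0, seed = 21)
  lab <- apply(sim$truth$admixture_Q, 1, which.max)
  # relabel so the subpopulation split is the clade {pop-1 accessions}
  tr <- bootstrap_support(sim$genotypes, B = 100, seed = 5)
  grp <- rownames(sim$genotypes)[lab == 1]
  if (length(grp) >= 2 && length(grp) <= 14) {
    mrca <- ape::getMRCA(tr, grp)
    desc <- ape::extract.clade(tr, mrca)$tip.label
    node_idx <- mrca - length(tr$tip.label)
    if (setequal(desc, grp)) expect_gte(tr$node.label[node_idx], 95)
  }
  tr2 <- bootstrap_support(sim$genotypes, B = 100, seed = 5)
  expect_identical(tr$node.label, tr2$node.label)
  # B = 1: supports are all 0 or 100
  tr3 <- bootstrap_support(sim$genotypes, B = 1, seed = 6)
  expect_true(all(tr3$node.label %in% c(0, 100)))
})

test_that("PCA coordinates behave spectrally and ignore marker order", {
  sim <- simulate_population(n_accessions = 30, n_markers = 40, fst = 0.2,
                             missing_rate = 0.05, seed = 31)
  p <- genotype_pca(sim$genotypes, 5)
  expect_true(all(diff(p$var_explained) <= 1e-12))
  expect_lte(sum(p$var_explained), 1 + 1e-12)
  # duplicated accessions land on the same point
  gm2 <- rbind(sim$genotypes, dup = sim$genotypes[1, ])
  p2 <- genotype_pca(gm2, 2)
  expect_equal(unname(p2$coordinates["dup", ]),
               unname(p2$coordinates[rownames(sim$genotypes)[1], ]))
  # marker reordering changes nothing but component signs
  perm <- sample(ncol(sim$genotypes))
  p3 <- genotype_pca(sim$genotypes[, perm], 2)
  for (j in 1:2) {
    sign_free_gap <- min(max(abs(p3$coordinates[, j] - p$coordinates[, j])),
                         max(abs(p3$coordinates[, j] + p$coordinates[, j])))
    expect_lt(sign_free_gap, 1e-8)
  }
  expect_error(genotype_pca(matrix("AA", 4, 3)), "degenerate")
})

test_that("PCA separates simulated subpopulations", {
  sim <- simulate_population(n_accessions = 105, n_markers = 200, n_subpops = 3,
                             fst = 0.25, dirichlet_alpha = 0.1,
                             missing_rate = 0, seed = 5)
  p <- genotype_pca(sim$genotypes, 2)
  truth_lab <- apply(sim$truth$admixture_Q, 1, which.max)
  set.seed(1)
  km <- stats::kmeans(p$coordinates, centers = 3, nstart = 20)
  # best label permutation
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  acc <- max(vapply(perms, function(pp) mean(pp[km$cluster] == truth_lab),
                    numeric(1)))
  expect_gte(acc, 0.9)
})

test_that("EM admixture reduces to allele frequencies at K = 1", {
  sim <- simulate_population(n_accessions = 25, n_markers = 15,
                             missing_rate = 0.05, seed = 41)
  fit <- admixture_em(sim$genotypes, K = 1, seed = 2, n_restarts = 2)
  expect_equal(unname(fit$Q[, 1]), rep(1, 25))
  dos <- kasprint:::genotype_dosage(sim$genotypes)
  phat <- colMeans(dos, na.rm = TRUE) / 2
  expect_equal(unname(fit$P[1, ]), unname(phat), tolerance = 1e-4)
  # closed-form binomial log-likelihood on the model's frequency domain
  phat <- pmin(pmax(phat, 1e-6), 1 - 1e-6)
  obs <- !is.na(dos)
  q <- matrix(rep(phat, each = 25), 25)
  ll <- sum((dos * log(q) + (2 - dos) * log(1 - q))[obs])
  expect_equal(fit$loglik, ll, tolerance = 1e-6)
})

test_that("EM log-likelihood ascends and nests across K", {
  sim <- simulate_population(n_accessions = 40, n_markers = 30, fst = 0.2,
                             missing_rate = 0.02, seed = 43)
  f1 <- admixture_em(sim$genotypes, K = 1, seed = 3, n_restarts = 2)
  f2 <- admixture_em(sim$genotypes, K = 2, seed = 3, n_restarts = 3)
  expect_true(all(diff(f1$loglik_trace) > -1e-8))
  expect_true(all(diff(f2$loglik_trace) > -1e-8))
  expect_gte(f2$loglik, f1$loglik - 1e-6)
  expect_true(all(abs(rowSums(f2$Q) - 1) < 1e-9))
  expect_error(admixture_em(sim$genotypes, K = 41), "K exceeds")
})

test_that("Evanno delta-K reproduces the hand-worked table", {
  runs <- data.frame(K = rep(1:4, each = 3),
                     lnP = c(-1000, -1002, -998,
                             -900, -902, -898,
                             -880, -884, -876,
                             -878, -874, -882))
  ev <- evanno_delta_k(runs)
  expect_equal(ev$delta_K[ev$K == 2], 40)
  expect_equal(ev$delta_K[ev$K == 3], 4.5)
  expect_equal(attr(ev, "optimal_K"), 2)
  expect_true(is.na(ev$delta_K[ev$K == 1]) && is.na(ev$delta_K[ev$K == 4]))
})

test_that("degenerate Evanno inputs are flagged, not fatal", {
  # identical replicates at K = 3: sd = 0, delta-K undefined there
  runs <- data.frame(K = rep(1:4, each = 2),
                     lnP = c(-10, -12, -8, -9, -7, -7, -6.5, -7.5))
  ev <- evanno_delta_k(runs)
  expect_true(is.na(ev$delta_K[ev$K == 3]))
  # linear mean likelihood: all second differences zero
  runs2 <- data.frame(K = rep(1:4, each = 2),
                      lnP = c(-40, -42, -30, -32, -20, -22, -10, -12))
  ev2 <- evanno_delta_k(runs2)
  expect_equal(ev2$delta_K[ev2$K %in% 2:3], c(0, 0))
  expect_error(evanno_delta_k(data.frame(K = c(1, 1, 2, 2), lnP = 1:4)),
               "3 consecutive")
  expect_error(evanno_delta_k(data.frame(K = 1:3, lnP = 1:3)), "2 replicate")
})
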