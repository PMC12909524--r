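#' Simulate an admixed diploid genotype panel
#'
#' Generates a germplasm-panel-like genotype matrix under a Balding-Nichols
#' island model with admixture. Per marker, an ancestral minor-allele
#' frequency p is drawn uniformly from `ancestral_maf_range`; each of the K
#' subpopulations draws its own frequency from
#' \eqn{Beta(p(1-F)/F, (1-p)(1-F)/F)} (equal to p when F = 0). Each accession
#' receives admixture proportions \eqn{Q_i \sim Dirichlet(\alpha 1_K)}; its
#' allele frequency at marker l is \eqn{q_{il} = \sum_k Q_{ik} P_{kl}} and its
#' genotype is Binomial(2, q) copies of the alternate allele, reported as an
#' unordered allele pair. Missingness is applied completely at random per
#' cell.
#'
#' Defaults mirror the black-locust study panel: 105 accessions, 31 markers,
#' three subpopulations, mean per-marker missing rate 1.8%.
#'
#' @param n_accessions,n_markers panel dimensions.
#' @param n_subpops number of source subpopulations K (>= 1).
#' @param fst Balding-Nichols differentiation F in [0, 1).
#' @param dirichlet_alpha admixture concentration (small = near-pure ancestry).
#' @param ancestral_maf_range interval within (0, 0.5] for ancestral
#'   minor-allele frequencies.
#' @param missing_rate per-cell MCAR missingness fraction in [0, 1).
#' @param seed integer seed; the simulation is reproducible bit-for-bit.
#' @return list of class `population_sim` with elements
#'   * `genotypes`: accessions x markers character matrix with `NA` missing;
#'   * `truth`: list with `ancestral_freqs` (length L), `subpop_freqs`
#'     (K x L), `admixture_Q` (n x K, rows sum to 1), `true_genotypes`
#'     (pre-missingness matrix), `dosage` (true alternate-allele counts) and
#'     `alleles` (data.frame marker/ref/alt).
#' @export
simulate_population <- function(n_accessions = 105, n_markers = 31,
                                n_subpops = 3, fst = 0.15,
                                dirichlet_alpha = 0.2,
                                ancestral_maf_range = c(0.05, 0.5),
                                missing_rate = 0.018, seed = 1) {
  check_count <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || x < 1 || x != round(x))
      stop(sprintf("invalid configuration: %s must be a positive integer", nm), call. = FALSE)
  }
  check_count(n_accessions, "n_accessions")
  check_count(n_markers, "n_markers")
  check_count(n_subpops, "n_subpops")
  if (!is.numeric(fst) || fst < 0 || fst >= 1)
    stop("invalid configuration: fst must lie in [0, 1)", call. = FALSE)
  if (!is.numeric(dirichlet_alpha) || dirichlet_alpha <= 0)
    stop("invalid configuration: dirichlet_alpha must be positive", call. = FALSE)
  if (length(ancestral_maf_range) != 2L || ancestral_maf_range[1] <= 0 ||
      ancestral_maf_range[2] > 0.5 || diff(ancestral_maf_range) < 0)
    stop("invalid configuration: ancestral_maf_range must be an interval within (0, 0.5]", call. = FALSE)
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 1)
    stop("invalid configuration: missing_rate must lie in [0, 1)", call. = FALSE)

  n <- n_accessions; L <- n_markers; K <- n_subpops
  set.seed(seed)

  acc <- sprintf("acc%03d", seq_len(n))
  mk <- sprintf("m%03d", seq_len(L))

  # ref/alt letters per marker
  pairs <- t(vapply(seq_len(L), function(i) sample(c("A", "C", "G", "T"), 2L),
                    character(2L)))
  alleles <- data.frame(marker = mk, ref = pairs[, 1L], alt = pairs[, 2L],
                        stringsAsFactors = FALSE)

  p_anc <- stats::runif(L, ancestral_maf_range[1], ancestral_maf_range[2])
  P <- matrix(0, K, L, dimnames = list(paste0("pop", seq_len(K)), mk))
  if (fst == 0) {
    P[] <- rep(p_anc, each = K)
  } else {
    shape <- (1 - fst) / fst
    for (k in seq_len(K)) P[k, ] <- stats::rbeta(L, p_anc * shape, (1 - p_anc) * shape)
  }

  Q <- matrix(stats::rgamma(n * K, shape = dirichlet_alpha), n, K,
              dimnames = list(acc, rownames(P)))
  Q <- Q / rowSums(Q)

  q_il <- Q %*% P                      # individual alternate-allele freqs
  dosage <- matrix(stats::rbinom(n * L, 2L, as.vector(q_il)), n, L,
                   dimnames = list(acc, mk))

  gt <- matrix(NA_character_, n, L, dimnames = list(acc, mk))
  for (j in seq_len(L)) {
    a <- c(alleles$ref[j], alleles$alt[j])
    gt[, j] <- c(canonical_genotype(a[1], a[1]),
                 canonical_genotype(a[1], a[2]),
                 canonical_genotype(a[2], a[2]))[dosage[, j] + 1L]
  }

  observed <- gt
  if (missing_rate > 0) {
    drop <- matrix(stats::runif(n * L) < missing_rate, n, L)
    observed[drop] <- NA_character_
  }

  structure(list(
    genotypes = observed,
    truth = list(ancestral_freqs = stats::setNames(p_anc, mk),
                 subpop_freqs = P, admixture_Q = Q,
                 true_genotypes = gt, dosage = dosage, alleles = alleles),
    config = list(n_accessions = n, n_markers = L, n_subpops = K, fst = fst,
                  dirichlet_alpha = dirichlet_alpha,
                  ancestral_maf_range = ancestral_maf_range,
                  missing_rate = missing_rate, seed = seed)),
    class = "population_sim")
}

#' Simulate an endpoint-fluorescence KASP plate
#'
#' Places each called sample of one biallelic marker on the FAM/HEX plane at
#' `signal_amplitude` times the unit vector of its genotype's centroid angle
#' (defaults 0 deg for the FAM-allele homozygote, 45 deg for heterozygotes,
#' 90 deg for the HEX-allele homozygote) plus isotropic Gaussian noise.
#' No-template controls, dropout wells and missing input calls sit at the
#' origin with the same noise. Fluorescence cannot be negative: coordinates
#' are clipped at 0.
#'
#' @param calls character vector of genotype calls for one marker (`NA`
#'   allowed, treated as failed amplification); names are used as sample ids.
#' @param allele_x,allele_y FAM- and HEX-linked alleles; inferred from the
#'   calls (alphabetical order) when omitted.
#' @param centroid_angles three strictly increasing angles in degrees within
#'   [0, 90] for X-homozygote, heterozygote, Y-homozygote clusters.
#' @param signal_amplitude cluster distance from the origin.
#' @param noise_sd isotropic Gaussian noise sd (must be < amplitude).
#' @param n_ntc number of no-template control wells appended.
#' @param dropout_rate fraction of sample wells failing to amplify.
#' @param marker_id assay identifier stored on the plate.
#' @param seed integer seed.
#' @return list with `plate` (a `fluorescence_plate`: data.frame well,
#'   sample, fam, hex, is_ntc with assay attributes) and `truth` (data.frame
#'   sample, genotype, dropout).
#' @export
simulate_plate <- function(calls, allele_x = NULL, allele_y = NULL,
                           centroid_angles = c(0, 45, 90),
                           signal_amplitude = 1, noise_sd = 0.05,
                           n_ntc = 2, dropout_rate = 0,
                           marker_id = "marker", seed = 1) {
  if (length(centroid_angles) != 3L || any(diff(centroid_angles) <= 0) ||
      centroid_angles[1] < 0 || centroid_angles[3] > 90)
    stop("invalid configuration: centroid_angles must be strictly increasing within [0, 90]", call. = FALSE)
  if (noise_sd >= signal_amplitude)
    stop("invalid configuration: noise_sd must be smaller than signal_amplitude", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate > 1)
    stop("invalid configuration: dropout_rate must lie in [0, 1]", call. = FALSE)

  obs <- unique(as.vector(split_alleles(calls)))
  obs <- sort(obs[!is.na(obs)])
  if (length(obs) > 2L)
    stop("unsupported marker: more than two distinct alleles in calls", call. = FALSE)
  if (is.null(allele_x)) allele_x <- obs[1] %||% "A"
  if (is.null(allele_y)) allele_y <- if (length(obs) >= 2L) setdiff(obs, allele_x)[1] else "G"
  bad <- setdiff(obs, c(allele_x, allele_y))
  if (length(bad))
    stop("unsupported marker: call alleles outside {allele_x, allele_y}", call. = FALSE)

  set.seed(seed)
  n <- length(calls)
  ids <- names(calls) %||% sprintf("S%03d", seq_len(n))

  hom_x <- canonical_genotype(allele_x, allele_x)
  het   <- canonical_genotype(allele_x, allele_y)
  hom_y <- canonical_genotype(allele_y, allele_y)
  ang <- rep(NA_real_, n)
  ang[calls == hom_x] <- centroid_angles[1]
  ang[calls == het]   <- centroid_angles[2]
  ang[calls == hom_y] <- centroid_angles[3]

  dropout <- stats::runif(n) < dropout_rate
  amplified <- !dropout & !is.na(ang)
  theta <- ang * pi / 180
  fam <- ifelse(amplified, signal_amplitude * cos(theta), 0)
  hex <- ifelse(amplified, signal_amplitude * sin(theta), 0)
  fam <- fam + stats::rnorm(n, 0, noise_sd)
  hex <- hex + stats::rnorm(n, 0, noise_sd)

  ntc_fam <- stats::rnorm(n_ntc, 0, noise_sd)
  ntc_hex <- stats::rnorm(n_ntc, 0, noise_sd)

  plate <- data.frame(
    well = sprintf("W%03d", seq_len(n + n_ntc)),
    sample = c(ids, rep(NA_character_, n_ntc)),
    fam = pmax(0, c(fam, ntc_fam)),
    hex = pmax(0, c(hex, ntc_hex)),
    is_ntc = c(rep(FALSE, n), rep(TRUE, n_ntc)),
    stringsAsFactors = FALSE)
  plate <- structure(plate, class = c("fluorescence_plate", "data.frame"),
                     marker_id = marker_id, allele_x = allele_x,
                     allele_y = allele_y,
                     centroid_angles = centroid_angles)
  truth <- data.frame(sample = ids, genotype = unname(calls),
                      dropout = dropout, stringsAsFactors = FALSE)
  list(plate = plate, truth = truth)
}
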