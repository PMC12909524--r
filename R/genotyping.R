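#' Normalize a fluorescence plate against its no-template controls
#'
#' Subtracts the per-channel mean NTC intensity from every well (negative
#' results clipped to 0) and records the post-normalization NTC statistics
#' used by the no-call gate of [call_genotypes()].
#'
#' @param plate a `fluorescence_plate` data.frame (`well`, `sample`, `fam`,
#'   `hex`, `is_ntc`), e.g. from [simulate_plate()] or [read_plate_csv()].
#' @return the plate with shifted intensities and attributes `normalized`,
#'   `ntc_stats` (per-channel mean/sd and NTC magnitude mean/sd).
#' @export
normalize_plate <- function(plate) {
  stopifnot(is.data.frame(plate), all(c("fam", "hex", "is_ntc") %in% names(plate)))
  if (!any(plate$is_ntc))
    stop("gating error: at least one no-template control well is required", call. = FALSE)
  if (any(!is.finite(plate$fam)) || any(!is.finite(plate$hex)))
    stop("intensities must be finite")
  ntc <- plate[plate$is_ntc, ]
  plate$fam <- pmax(0, plate$fam - mean(ntc$fam))
  plate$hex <- pmax(0, plate$hex - mean(ntc$hex))
  post_ntc <- plate[plate$is_ntc, ]
  mag <- sqrt(post_ntc$fam^2 + post_ntc$hex^2)
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  attr(plate, "ntc_stats") <- list(
    fam_mean = mean(ntc$fam), hex_mean = mean(ntc$hex),
    fam_sd = sd0(ntc$fam), hex_sd = sd0(ntc$hex),
    mag_mean = mean(mag), mag_sd = sd0(mag))
  attr(plate, "normalized") <- TRUE
  plate
}

# Deterministic 1-D Lloyd k-means from fixed initial centers.
# Empty clusters retain their previous center; returns assignments + centers.
lloyd_1d <- function(x, centers, max_iter = 100L) {
  assign_old <- rep(0L, length(x))
  for (it in seq_len(max_iter)) {
    d <- abs(outer(x, centers, "-"))
    assign_new <- max.col(-d, ties.method = "first")
    if (identical(assign_new, assign_old)) break
    assign_old <- assign_new
    for (k in seq_along(centers)) {
      if (any(assign_new == k)) centers[k] <- mean(x[assign_new == k])
    }
  }
  list(cluster = assign_old, centers = centers)
}

# Mean silhouette width for a 1-D clustering (Euclidean). A singleton with
# positive distance to its nearest foreign cluster is perfectly separated
# and contributes 1 (rare genotype classes must not penalize the split).
silhouette_1d <- function(x, cluster) {
  ks <- sort(unique(cluster))
  if (length(ks) < 2L) return(NA_real_)
  n <- length(x)
  s <- numeric(n)
  d <- abs(outer(x, x, "-"))
  for (i in seq_len(n)) {
    own <- cluster == cluster[i]
    b <- min(vapply(ks[ks != cluster[i]],
                    function(k) mean(d[i, cluster == k]), numeric(1)))
    if (sum(own) == 1L) { s[i] <- if (b > 0) 1 else 0; next }
    a <- sum(d[i, own]) / (sum(own) - 1L)
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Call genotypes from endpoint FAM/HEX fluorescence
#'
#' Wells whose signal magnitude falls below the NTC gate
#' (NTC magnitude mean + `min_magnitude_sds` x NTC magnitude sd) are
#' no-calls. The remaining wells are clustered on their fluorescence angle
#' theta = atan2(hex, fam) by deterministic 1-D k-means for k in 1..`k_max`,
#' initialized at fixed canonical angles (pi/4 for k = 1; pi/8, 3pi/8 for
#' k = 2; pi/8, pi/4, 3pi/8 for k = 3). k = 2 and 3 are scored by mean
#' silhouette width; k = 1 by angular tightness 1 - sd(theta)/(pi/8)
#' (floored at 0), so a single compact cluster beats any split of it.
#' Clusters are labeled by mean angle: lowest = FAM-allele homozygote,
#' highest = HEX-allele homozygote, middle (k = 3) = heterozygote; with two
#' clusters each maps to its nearest canonical angle (0, 45, 90 degrees).
#'
#' @param plate a `fluorescence_plate`; normalized with [normalize_plate()]
#'   first if it is not already.
#' @param allele_x,allele_y FAM- and HEX-linked alleles; default from the
#'   plate's assay attributes.
#' @param min_magnitude_sds no-call gate width in NTC magnitude sds.
#' @param k_max maximum number of clusters considered (<= 3 for a biallelic
#'   assay).
#' @return object of class `genotype_callset`: list with `calls` (named
#'   genotype strings, `NA` = no-call), `cluster` (per-sample index, `NA`
#'   for no-calls), `centers_deg` (cluster mean angles), `quality` (list:
#'   `n_clusters`; `min_gap_deg`, the narrowest empty angular band between
#'   adjacent clusters — nearest-point margin, the quantity a plate reader
#'   shows as cluster separation; `nocall_frac`; `n_samples`), `marker_id`,
#'   `alleles`. An all-no-call plate yields zero clusters (failed-assay
#'   signal consumed by [triage_assay()]), not an error.
#' @export
call_genotypes <- function(plate, allele_x = NULL, allele_y = NULL,
                           min_magnitude_sds = 6, k_max = 3) {
  if (!isTRUE(attr(plate, "normalized"))) plate <- normalize_plate(plate)
  allele_x <- allele_x %||% attr(plate, "allele_x") %||% "X"
  allele_y <- allele_y %||% attr(plate, "allele_y") %||% "Y"
  k_max <- min(k_max, 3L)
  ntc <- attr(plate, "ntc_stats")
  wells <- plate[!plate$is_ntc, , drop = FALSE]
  ids <- wells$sample
  n <- nrow(wells)

  mag <- sqrt(wells$fam^2 + wells$hex^2)
  gate <- ntc$mag_mean + min_magnitude_sds * ntc$mag_sd
  called <- mag > gate

  calls <- stats::setNames(rep(NA_character_, n), ids)
  cluster <- stats::setNames(rep(NA_integer_, n), ids)
  genos <- c(canonical_genotype(allele_x, allele_x),
             canonical_genotype(allele_x, allele_y),
             canonical_genotype(allele_y, allele_y))
  canon <- c(0, pi / 4, pi / 2)

  centers_deg <- numeric(0)
  if (any(called)) {
    theta <- atan2(wells$hex[called], wells$fam[called])
    inits <- list(pi / 4, c(pi / 8, 3 * pi / 8), c(pi / 8, pi / 4, 3 * pi / 8))
    fits <- vector("list", k_max)
    score <- rep(-Inf, k_max)
    for (k in seq_len(k_max)) {
      fit <- lloyd_1d(theta, inits[[k]])
      fits[[k]] <- fit
      n_eff <- length(unique(fit$cluster))
      if (n_eff < k) next                       # degenerate split
      if (k == 1L) {
        spread <- if (length(theta) > 1L) stats::sd(theta) else 0
        score[k] <- max(0, 1 - spread / (pi / 8))
      } else {
        score[k] <- silhouette_1d(theta, fit$cluster)
      }
    }
    best_k <- which.max(score)
    fit <- fits[[best_k]]
    ord <- order(fit$centers)
    centers_sorted <- fit$centers[ord]
    rank_of <- match(seq_along(ord), ord)        # cluster index -> rank
    # map ranked clusters to genotype slots 1..3
    if (best_k == 3L) {
      slot <- 1:3
    } else if (best_k == 1L) {
      slot <- which.min(abs(canon - centers_sorted[1]))
    } else {
      slot <- vapply(centers_sorted, function(a) which.min(abs(canon - a)), integer(1))
      if (slot[1] == slot[2]) slot <- if (slot[1] <= 2L) c(slot[1], slot[1] + 1L) else c(slot[1] - 1L, slot[1])
    }
    cl <- rank_of[fit$cluster]
    cluster[called] <- cl
    calls[called] <- genos[slot[cl]]
    centers_deg <- centers_sorted * 180 / pi
    # inter-cluster margin: empty angular band between adjacent clusters
    if (best_k >= 2L) {
      margins <- vapply(seq_len(best_k - 1L), function(r)
        min(theta[cl == r + 1L]) - max(theta[cl == r]), numeric(1))
      gap_deg <- min(margins) * 180 / pi
    }
  }

  gaps <- if (length(centers_deg) >= 2L) gap_deg else Inf
  structure(list(calls = calls, cluster = cluster, centers_deg = centers_deg,
                 quality = list(n_clusters = length(centers_deg),
                                min_gap_deg = gaps,
                                nocall_frac = mean(!called),
                                n_samples = n),
                 marker_id = attr(plate, "marker_id") %||% "marker",
                 alleles = c(x = allele_x, y = allele_y)),
            class = "genotype_callset")
}

#' Triage a KASP assay from its call-set quality
#'
#' Classifies an assay as `core` (clear, polymorphic clusters),
#' `indistinct_or_failed` (inter-cluster margin narrower than `min_gap_deg`
#' degrees, or no-call fraction above `max_nocall`, or nothing called), or
#' `monomorphic` (a single clean genotype class).
#'
#' @param callset a `genotype_callset`.
#' @param min_gap_deg minimum angular gap between cluster centers (degrees).
#' @param max_nocall maximum tolerated no-call fraction.
#' @return object of class `assay_triage`: list with `status` and `reasons`.
#' @export
triage_assay <- function(callset, min_gap_deg = 15, max_nocall = 0.2) {
  stopifnot(inherits(callset, "genotype_callset"))
  q <- callset$quality
  reasons <- character(0)
  if (q$n_clusters == 0L) reasons <- c(reasons, "no wells called")
  if (q$nocall_frac > max_nocall)
    reasons <- c(reasons, sprintf("no-call fraction %.2f > %.2f", q$nocall_frac, max_nocall))
  if (q$n_clusters >= 2L && q$min_gap_deg < min_gap_deg)
    reasons <- c(reasons, sprintf("minimal cluster gap %.1f deg < %.1f deg", q$min_gap_deg, min_gap_deg))
  status <- if (length(reasons)) "indistinct_or_failed"
    else if (length(unique(callset$calls[!is.na(callset$calls)])) == 1L) "monomorphic"
    else "core"
  if (status == "monomorphic") reasons <- "single genotype class called"
  structure(list(status = status, reasons = reasons), class = "assay_triage")
}

#' Concordance and error rate across replicate call-sets
#'
#' Samples carrying a no-call in any replicate are excluded (set
#' `count_nocall_discordant = TRUE` to count them as discordant instead).
#' With `denominator = "samples"` (default) concordance is the fraction of
#' compared samples called identically across *all* replicates; with
#' `"pairs"` it is the fraction of concordant replicate pairs over all
#' samples x replicate-pairs. The error rate is 1 - concordance.
#'
#' @param callsets list of >= 2 `genotype_callset`s (or named call vectors)
#'   for the same samples.
#' @param denominator `"samples"` or `"pairs"`.
#' @param count_nocall_discordant treat any no-call as a discordance.
#' @return list with `concordance`, `error_rate`, `n_samples`, `n_compared`.
#' @export
replicate_concordance <- function(callsets, denominator = c("samples", "pairs"),
                                  count_nocall_discordant = FALSE) {
  denominator <- match.arg(denominator)
  if (length(callsets) < 2L) stop("at least two replicate call-sets are required")
  calls <- lapply(callsets, function(cs) if (inherits(cs, "genotype_callset")) cs$calls else cs)
  ids <- Reduce(intersect, lapply(calls, names))
  if (length(ids) == 0L) stop("replicates share no sample ids")
  mat <- vapply(calls, function(x) x[ids], character(length(ids)))
  complete <- rowSums(is.na(mat)) == 0L
  use <- if (count_nocall_discordant) rep(TRUE, length(ids)) else complete
  n_compared <- sum(use)
  if (n_compared == 0L) stop("no fully called samples to compare")
  if (denominator == "samples") {
    same <- apply(mat[use, , drop = FALSE], 1L, function(r) {
      if (anyNA(r)) return(FALSE)
      length(unique(r)) == 1L
    })
    conc <- mean(same)
  } else {
    prs <- utils::combn(ncol(mat), 2L)
    agree <- total <- 0L
    for (j in seq_len(ncol(prs))) {
      a <- mat[use, prs[1, j]]; b <- mat[use, prs[2, j]]
      eq <- ifelse(is.na(a) | is.na(b), FALSE, a == b)
      agree <- agree + sum(eq); total <- total + length(eq)
    }
    conc <- agree / total
  }
  list(concordance = conc, error_rate = 1 - conc,
       n_samples = length(ids), n_compared = n_compared)
}

#' Read a fluorescence plate CSV
#'
#' Expected columns: `well`, `sample`, `fam`, `hex`, `is_ntc`.
#'
#' @param path CSV file.
#' @param marker_id,allele_x,allele_y assay metadata attached as attributes.
#' @return a `fluorescence_plate` data.frame.
#' @export
read_plate_csv <- function(path, marker_id = "marker",
                           allele_x = NULL, allele_y = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("well", "sample", "fam", "hex", "is_ntc") %in% names(df)))
  df$is_ntc <- as.logical(df$is_ntc)
  structure(df, class = c("fluorescence_plate", "data.frame"),
            marker_id = marker_id, allele_x = allele_x, allele_y = allele_y)
}
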