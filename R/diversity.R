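#' Allele frequencies of one marker
#'
#' Frequencies are computed over called genotypes only: each called diploid
#' contributes two allele observations, so \eqn{p_i = n_i / (2 n_{called})}.
#'
#' @param genotypes character vector of unordered two-letter genotype calls
#'   (e.g. `"AA"`, `"AG"`), `NA` for missing.
#' @return named numeric vector of allele frequencies, sorted by decreasing
#'   frequency (ties by allele name); sums to 1.
#' @export
allele_frequencies <- function(genotypes) {
  al <- split_alleles(genotypes)
  al <- al[!is.na(al)]
  if (length(al) == 0L) {
    stop("undefined statistic: no called genotypes", call. = FALSE)
  }
  tab <- table(al)
  p <- as.numeric(tab) / sum(tab)
  names(p) <- names(tab)
  p[order(-p, names(p))]
}

#' Minor allele frequency
#'
#' @inheritParams allele_frequencies
#' @return frequency of the rarer allele (0 for a monomorphic marker).
#' @export
minor_allele_frequency <- function(genotypes) {
  p <- allele_frequencies(genotypes)
  if (length(p) == 1L) 0 else unname(min(p))
}

# Interpret a bare numeric as a frequency vector: a single value p in [0, 1]
# is the biallelic shorthand c(p, 1 - p); longer vectors must sum to 1.
as_freq_vector <- function(freqs) {
  if (!is.numeric(freqs)) stop("freqs must be numeric")
  if (any(freqs < 0 | freqs > 1)) stop("frequencies must lie in [0, 1]")
  if (length(freqs) == 1L) freqs <- c(freqs, 1 - freqs)
  if (abs(sum(freqs) - 1) > 1e-6) stop("frequencies must sum to 1")
  freqs
}

#' Gene diversity (expected heterozygosity)
#'
#' \deqn{D = 1 - \sum_i p_i^2}
#' the probability that two alleles drawn at random differ. For a biallelic
#' locus the maximum is 0.5 at p = 0.5. No small-sample correction is applied
#' (the \eqn{n/(n-1)} correction is available via `corrected = TRUE` with the
#' number of sampled alleles `n_alleles`).
#'
#' @param freqs allele-frequency vector, or a single minor-allele frequency
#'   (biallelic shorthand).
#' @param corrected apply the unbiased \eqn{n/(n-1)} correction.
#' @param n_alleles number of sampled alleles (2 x called individuals);
#'   required when `corrected = TRUE`.
#' @return gene diversity in [0, 1].
#' @export
gene_diversity <- function(freqs, corrected = FALSE, n_alleles = NULL) {
  p <- as_freq_vector(freqs)
  d <- 1 - sum(p^2)
  if (corrected) {
    if (is.null(n_alleles)) stop("n_alleles required for corrected gene diversity")
    d <- d * n_alleles / (n_alleles - 1)
  }
  d
}

#' Polymorphism information content (PIC)
#'
#' Botstein's measure
#' \deqn{PIC = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2,}
#' which for a biallelic locus reduces to \eqn{2pq - 2p^2q^2} with maximum
#' 0.375 at p = 0.5. PIC never exceeds gene diversity.
#'
#' @inheritParams gene_diversity
#' @return PIC value in [0, 1].
#' @export
pic <- function(freqs) {
  p <- as_freq_vector(freqs)
  p2 <- p^2
  cross <- (sum(p2)^2 - sum(p2^2)) / 2   # sum_{i<j} p_i^2 p_j^2
  1 - sum(p2) - 2 * cross
}

#' Observed heterozygosity of one marker
#'
#' Fraction of called individuals that are heterozygous.
#'
#' @inheritParams allele_frequencies
#' @export
observed_heterozygosity <- function(genotypes) {
  het <- is_heterozygote(genotypes)
  het <- het[!is.na(het)]
  if (length(het) == 0L) stop("undefined statistic: no called genotypes", call. = FALSE)
  mean(het)
}

#' Missing rate of one marker
#'
#' @inheritParams allele_frequencies
#' @param n_total total number of assayed accessions (denominator); defaults
#'   to `length(genotypes)`.
#' @return fraction missing in [0, 1] (tables print it as a percentage at
#'   2 decimal places).
#' @export
missing_rate <- function(genotypes, n_total = length(genotypes)) {
  if (n_total == 0) stop("undefined statistic: n_total is 0", call. = FALSE)
  n_called <- sum(!is.na(genotypes))
  if (n_total < n_called) stop("n_total smaller than the number of called genotypes")
  (n_total - n_called) / n_total
}

#' Per-marker diversity table with panel means
#'
#' Computes, for every marker of a genotype matrix, the minor allele
#' frequency, gene diversity, observed heterozygosity, PIC, missing rate and
#' number of called accessions, plus the arithmetic column means — the shape
#' of a published marker-diversity table with its trailing Mean row.
#'
#' @param genotypes accessions x markers character matrix of genotype calls.
#' @param n_total denominator for the missing rate (defaults to the number of
#'   rows).
#' @return object of class `panel_summary`: list with `per_marker`
#'   (data.frame, one row per marker in input order) and `means` (named
#'   numeric vector). Markers with zero called genotypes get `NA` statistics
#'   and are excluded from the means.
#' @export
summarize_markers <- function(genotypes, n_total = NULL) {
  gm <- as_genotype_matrix(genotypes)
  n_total <- n_total %||% nrow(gm)
  rows <- lapply(colnames(gm), function(m) {
    g <- gm[, m]
    n_called <- sum(!is.na(g))
    if (n_called == 0L) {
      return(data.frame(marker = m, maf = NA_real_, gene_diversity = NA_real_,
                        heterozygosity = NA_real_, pic = NA_real_,
                        missing_rate = missing_rate(g, n_total),
                        n_called = 0L))
    }
    p <- allele_frequencies(g)
    data.frame(marker = m,
               maf = if (length(p) == 1L) 0 else unname(min(p)),
               gene_diversity = gene_diversity(p),
               heterozygosity = observed_heterozygosity(g),
               pic = pic(p),
               missing_rate = missing_rate(g, n_total),
               n_called = n_called)
  })
  per_marker <- do.call(rbind, rows)
  num <- per_marker[, c("maf", "gene_diversity", "heterozygosity", "pic", "missing_rate")]
  means <- colMeans(num, na.rm = TRUE)
  structure(list(per_marker = per_marker, means = means, n_total = n_total),
            class = "panel_summary")
}

#' @export
print.panel_summary <- function(x, ...) {
  tab <- x$per_marker
  for (col in c("maf", "gene_diversity", "heterozygosity", "pic")) {
    tab[[col]] <- round_half_up(tab[[col]], 3)
  }
  tab$missing_rate <- sprintf("%.2f%%", round_half_up(100 * tab$missing_rate, 2))
  print(tab, row.names = FALSE)
  m <- x$means
  cat(sprintf("Mean  maf %.3f  gene diversity %.3f  heterozygosity %.3f  pic %.3f  missing %.2f%%\n",
              round_half_up(m[["maf"]], 3), round_half_up(m[["gene_diversity"]], 3),
              round_half_up(m[["heterozygosity"]], 3), round_half_up(m[["pic"]], 3),
              round_half_up(100 * m[["missing_rate"]], 2)))
  invisible(x)
}

#' Reference diversity table of the 31-marker KASP panel
#'
#' The published per-marker diversity summary of the 31 core KASP markers
#' (black locust germplasm panel, 105 accessions): minor allele frequency,
#' gene diversity, observed heterozygosity, PIC and missing rate, shipped as
#' plain CSV in `inst/extdata`.
#'
#' @return data.frame with columns `marker`, `maf`, `gene_diversity`,
#'   `heterozygosity`, `pic`, `missing_pct`.
#' @export
kasp_panel_reference <- function() {
  path <- system.file("extdata", "kasp_panel_diversity.csv", package = "kasprint",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
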