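# Internal helpers shared across modules.

MISSING_GT <- NA_character_

#' Round half away from zero
#'
#' Report-layer rounding used for printed tables: ties go up (0.0005 -> 0.001),
#' unlike [base::round()]'s round-half-even. A small epsilon guards against
#' binary representation of decimal ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# Canonical unordered genotype string from two allele characters ("G","A" -> "AG").
canonical_genotype <- function(a1, a2) {
  paste0(pmin(a1, a2), pmax(a1, a2))
}

# Split genotype strings ("AG") into a 2-row character matrix of alleles;
# missing genotypes give NA columns.
split_alleles <- function(gt) {
  out <- matrix(NA_character_, nrow = 2L, ncol = length(gt))
  ok <- !is.na(gt)
  if (any(ok)) {
    out[1L, ok] <- substr(gt[ok], 1L, 1L)
    out[2L, ok] <- substr(gt[ok], 2L, 2L)
  }
  out
}

is_heterozygote <- function(gt) {
  ifelse(is.na(gt), NA, substr(gt, 1L, 1L) != substr(gt, 2L, 2L))
}

# Coerce genotype input (matrix or data.frame, accessions x markers) to a
# character matrix with row/col names.
as_genotype_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) stop("genotypes must be a matrix or data.frame (accessions x markers)")
  storage.mode(x) <- "character"
  x[x %in% c("", "NA", "--", "./.")] <- NA_character_
  if (is.null(rownames(x))) rownames(x) <- paste0("acc", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("m", seq_len(ncol(x)))
  x
}

# Dosage coding of the panel minor allele (0/1/2, NA = missing) per marker.
# Returns numeric matrix with the same dimnames plus attr "counted_allele".
genotype_dosage <- function(gm) {
  gm <- as_genotype_matrix(gm)
  dos <- matrix(NA_real_, nrow(gm), ncol(gm), dimnames = dimnames(gm))
  counted <- character(ncol(gm))
  for (j in seq_len(ncol(gm))) {
    al <- split_alleles(gm[, j])
    tab <- table(al[!is.na(al)])
    if (length(tab) == 0L) { counted[j] <- NA_character_; next }
    # minor allele = least frequent; deterministic tie-break by allele name
    ord <- order(tab, names(tab))
    minor <- names(tab)[ord[1L]]
    counted[j] <- minor
    dos[, j] <- colSums(al == minor)
  }
  attr(dos, "counted_allele") <- counted
  dos
}

`%||%` <- function(a, b) if (is.null(a)) b else a
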