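#' Write a minimal VCF v4.2 fixture
#'
#' Emits a header-plus-GT VCF for small variant tables, chiefly to exercise
#' the screening cascade (e.g. by injecting neighbor variants at chosen
#' offsets around a target SNP to trip the flanking-variant rule).
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` and optionally `id`; must be sorted by (chrom, pos).
#' @param genotypes optional variants x samples character matrix of unordered
#'   allele pairs (e.g. `"AG"`) or `NA`; column names are sample ids.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_toy_vcf <- function(variants, path, genotypes = NULL) {
  stopifnot(is.data.frame(variants))
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(variants)))
    stop("variants must have columns chrom, pos, ref, alt")
  n <- nrow(variants)
  if (n > 0L) {
    ord <- order(variants$chrom, variants$pos)
    if (!identical(ord, seq_len(n)))
      stop("unsorted records: variants must be ordered by (chrom, pos)")
  }
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  header <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  has_gt <- !is.null(genotypes) && NCOL(genotypes) > 0L
  if (has_gt) {
    genotypes <- as.matrix(genotypes)
    if (nrow(genotypes) != n) stop("genotypes must have one row per variant")
    samples <- colnames(genotypes) %||% sprintf("S%03d", seq_len(ncol(genotypes)))
    header <- c(header, "FORMAT", samples)
  }
  lines <- c(lines, paste(header, collapse = "\t"))
  if (n > 0L) {
    ids <- variants$id %||% rep(".", n)
    body <- vapply(seq_len(n), function(i) {
      fields <- c(variants$chrom[i], variants$pos[i], ids[i],
                  variants$ref[i], variants$alt[i], ".", "PASS", ".")
      if (has_gt) {
        al <- c(variants$ref[i], variants$alt[i])
        gt <- vapply(genotypes[i, ], function(g) {
          if (is.na(g)) return("./.")
          idx <- match(c(substr(g, 1, 1), substr(g, 2, 2)), al) - 1L
          if (anyNA(idx)) stop(sprintf("genotype %s uses alleles absent from record %d", g, i))
          paste(sort(idx), collapse = "/")
        }, character(1))
        fields <- c(fields, "GT", gt)
      }
      paste(fields, collapse = "\t")
    }, character(1))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Parse a VCF into variant records and a genotype matrix
#'
#' Reads a VCF v4.x (via \pkg{vcfR}), keeps biallelic single-nucleotide
#' records only, and decodes GT fields to unordered allele pairs. Records
#' that are multi-allelic, indels, or symbolic are skipped and counted.
#'
#' @param path VCF file (plain or gzipped).
#' @return list with `variants` (data.frame chrom, pos, id, ref, alt),
#'   `genotypes` (accessions x markers character matrix, `NA` = missing or
#'   no samples in the file -> NULL) and `n_skipped`.
#' @export
parse_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n_in <- nrow(fix)
  if (n_in == 0L) {
    return(list(variants = data.frame(chrom = character(), pos = integer(),
                                      id = character(), ref = character(),
                                      alt = character(), stringsAsFactors = FALSE),
                genotypes = NULL, n_skipped = 0L))
  }
  keep <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skipped <- sum(!keep)
  if (n_skipped > 0L)
    message(sprintf("parse_vcf: skipped %d multi-allelic or non-SNP record(s)", n_skipped))
  fix <- fix[keep, , drop = FALSE]
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, "_", fix$POS), fix$ID)
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         id = ids, ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)

  genotypes <- NULL
  if (ncol(v@gt) > 1L && nrow(variants) > 0L) {
    gt_raw <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
    n_var <- nrow(variants)
    samples <- colnames(gt_raw)
    genotypes <- matrix(NA_character_, length(samples), n_var,
                        dimnames = list(samples, variants$id))
    for (i in seq_len(n_var)) {
      al <- c(variants$ref[i], variants$alt[i])
      g <- gt_raw[i, ]
      toks <- strsplit(g, "[/|]")
      genotypes[, i] <- vapply(toks, function(tk) {
        if (length(tk) != 2L || anyNA(tk) || any(tk == ".")) return(NA_character_)
        idx <- suppressWarnings(as.integer(tk)) + 1L
        if (anyNA(idx) || any(idx < 1L) || any(idx > 2L)) return(NA_character_)
        canonical_genotype(al[idx[1]], al[idx[2]])
      }, character(1))
    }
  }
  list(variants = variants, genotypes = genotypes, n_skipped = n_skipped)
}
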