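#' Filter thresholds for the SNP screening cascade
#'
#' Defaults follow the published screen: MAF strictly greater than 0.05,
#' missing rate at most 0.2, PIC strictly greater than 0.3, and no other
#' variant within 100 bp on either side.
#'
#' @param maf_min exclusive minor-allele-frequency floor.
#' @param missing_max inclusive missing-rate ceiling.
#' @param pic_min exclusive PIC floor.
#' @param flank_bp exclusion half-window in bp around each locus.
#' @export
filter_thresholds <- function(maf_min = 0.05, missing_max = 0.2,
                              pic_min = 0.3, flank_bp = 100) {
  vals <- c(maf_min = maf_min, missing_max = missing_max, pic_min = pic_min)
  if (any(vals < 0 | vals > 1)) stop("rate thresholds must lie in [0, 1]")
  if (flank_bp < 0) stop("flank_bp must be non-negative")
  structure(list(maf_min = maf_min, missing_max = missing_max,
                 pic_min = pic_min, flank_bp = flank_bp),
            class = "filter_thresholds")
}

#' Four-stage SNP filter cascade
#'
#' Applies, in order: (1) MAF > `maf_min`; (2) missing rate <= `missing_max`;
#' (3) PIC > `pic_min`; (4) no *other input* variant (including loci that
#' failed earlier stages) within `flank_bp` bp on either side on the same
#' chromosome. MAF and PIC are computed on called genotypes only; the missing
#' rate denominator is the full sample count.
#'
#' @param variants data.frame (`chrom`, `pos`, `id`, `ref`, `alt`) sorted by
#'   (chrom, pos), as from [parse_vcf()].
#' @param genotypes accessions x markers genotype matrix whose columns match
#'   `variants$id`.
#' @param thresholds a [filter_thresholds()] object.
#' @return list with `variants` (survivors), `genotypes` (matching columns),
#'   `counts` (named survivor counts after each stage, starting at `input`)
#'   and `stats` (per-input-marker data.frame of maf, missing rate, pic and
#'   the four predicate flags).
#' @export
filter_cascade <- function(variants, genotypes, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  n <- nrow(variants)
  empty_counts <- c(input = 0L, maf = 0L, missing = 0L, pic = 0L, flank = 0L)
  if (n == 0L) {
    return(list(variants = variants, genotypes = genotypes,
                counts = empty_counts, stats = NULL))
  }
  if (is.unsorted(order(variants$chrom, variants$pos)))
    stop("variants must be sorted by (chrom, pos)")
  gm <- as_genotype_matrix(genotypes)
  if (!all(variants$id %in% colnames(gm)))
    stop("genotype matrix lacks columns for some variants")
  gm <- gm[, variants$id, drop = FALSE]

  stats <- data.frame(id = variants$id, chrom = variants$chrom,
                      pos = variants$pos, maf = NA_real_,
                      missing_rate = NA_real_, pic = NA_real_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    g <- gm[, i]
    stats$missing_rate[i] <- missing_rate(g, nrow(gm))
    if (any(!is.na(g))) {
      p <- allele_frequencies(g)
      stats$maf[i] <- if (length(p) == 1L) 0 else unname(min(p))
      stats$pic[i] <- pic(p)
    } else {
      stats$maf[i] <- 0
      stats$pic[i] <- 0
    }
  }

  # flanking predicate against the FULL input list
  isolated <- vapply(seq_len(n), function(i) {
    same <- variants$chrom == variants$chrom[i]
    d <- abs(variants$pos[same] - variants$pos[i])
    sum(d <= thresholds$flank_bp) == 1L   # itself only
  }, logical(1))

  stats$pass_maf <- stats$maf > thresholds$maf_min
  stats$pass_missing <- stats$missing_rate <= thresholds$missing_max
  stats$pass_pic <- stats$pic > thresholds$pic_min
  stats$pass_flank <- isolated

  s1 <- stats$pass_maf
  s2 <- s1 & stats$pass_missing
  s3 <- s2 & stats$pass_pic
  s4 <- s3 & stats$pass_flank
  counts <- c(input = n, maf = sum(s1), missing = sum(s2),
              pic = sum(s3), flank = sum(s4))
  list(variants = variants[s4, , drop = FALSE],
       genotypes = gm[, s4, drop = FALSE],
       counts = counts, stats = stats)
}

#' Select chromosomally spaced, high-PIC markers
#'
#' Greedy per-chromosome pick: the highest-PIC locus first, then repeatedly
#' the next-highest PIC among loci at least `min_gap_bp` from everything
#' already selected on that chromosome, until `per_chrom_quota` markers are
#' chosen or candidates run out. Ties broken by (chrom, pos); input order is
#' irrelevant (sorted internally).
#'
#' @param retained data.frame with columns `id`, `chrom`, `pos`, `pic`
#'   (e.g. the survivor rows of [filter_cascade()]'s `stats`).
#' @param per_chrom_quota markers to keep per chromosome.
#' @param min_gap_bp minimum spacing between selected loci.
#' @return the selected rows, sorted by (chrom, pos).
#' @export
select_spaced_markers <- function(retained, per_chrom_quota, min_gap_bp = 0) {
  stopifnot(all(c("id", "chrom", "pos", "pic") %in% names(retained)))
  if (per_chrom_quota == 0L || nrow(retained) == 0L)
    return(retained[integer(0), , drop = FALSE])
  retained <- retained[order(retained$chrom, retained$pos), , drop = FALSE]
  picked <- logical(nrow(retained))
  for (ch in unique(retained$chrom)) {
    idx <- which(retained$chrom == ch)
    ord <- idx[order(-retained$pic[idx], retained$pos[idx])]
    sel_pos <- numeric(0)
    for (i in ord) {
      if (length(sel_pos) >= per_chrom_quota) break
      if (all(abs(retained$pos[i] - sel_pos) >= min_gap_bp) || length(sel_pos) == 0L) {
        picked[i] <- TRUE
        sel_pos <- c(sel_pos, retained$pos[i])
      }
    }
  }
  retained[picked, , drop = FALSE]
}

#' Extract the flanking sequence context of a SNP
#'
#' Returns the closed window `[pos - flank_bp, pos + flank_bp]` (1-based) of
#' the reference, uppercased — 201 bases at the default 100-bp flank. Windows
#' overhanging a contig end are truncated and flagged.
#'
#' @param reference a [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param chrom sequence name.
#' @param pos 1-based SNP position.
#' @param ref_allele expected base at `pos`; mismatch raises an error.
#' @param flank_bp flank length on each side.
#' @return object of class `snp_context`: list with `seq` (character),
#'   `center` (1-based index of the SNP within `seq`), `truncated` flag,
#'   `chrom`, `pos`.
#' @export
extract_flanks <- function(reference, chrom, pos, ref_allele = NULL,
                           flank_bp = 100) {
  if (is.character(reference) && length(reference) == 1L)
    reference <- Biostrings::readDNAStringSet(reference)
  stopifnot(methods::is(reference, "DNAStringSet"))
  nm <- sub("\\s.*$", "", names(reference))
  hit <- match(chrom, nm)
  if (is.na(hit)) stop(sprintf("chromosome '%s' not found in reference", chrom))
  len <- Biostrings::width(reference)[hit]
  if (pos < 1L || pos > len)
    stop(sprintf("position %d outside sequence '%s' (length %d)", pos, chrom, len))
  lo <- max(1L, pos - flank_bp)
  hi <- min(len, pos + flank_bp)
  seq <- toupper(as.character(Biostrings::subseq(reference[[hit]], lo, hi)))
  center <- pos - lo + 1L
  if (!is.null(ref_allele) && substr(seq, center, center) != toupper(ref_allele))
    stop(sprintf("reference mismatch at %s:%d: found %s, expected %s",
                 chrom, pos, substr(seq, center, center), ref_allele))
  structure(list(seq = seq, center = center,
                 truncated = (hi - lo + 1L) < (2L * flank_bp + 1L),
                 chrom = chrom, pos = pos),
            class = "snp_context")
}

# Universal KASP tail sequences (5' ends of the two allele-specific forwards).
KASP_FAM_TAIL <- "GAAGGTGACCAAGTTCATGCT"
KASP_HEX_TAIL <- "GAAGGTCGGAGTCAACGGATT"

#' Assemble a tailed KASP assay record
#'
#' Builds the two allele-specific forward primers (universal FAM/HEX tails
#' prepended to a 20-base genomic arm ending at the SNP, terminal base set to
#' the ref or alt allele) and a placeholder common reverse primer (the
#' reverse complement of a 20-base window starting 30 bases downstream of the
#' SNP). No thermodynamic optimization is attempted: the record captures
#' assay structure, not a lab-ready design.
#'
#' @param variant list or one-row data.frame with `id` (or `marker_id`),
#'   `ref`, `alt`.
#' @param context a `snp_context` from [extract_flanks()] centered on the SNP.
#' @param arm_length allele-specific arm length (bases, including the SNP).
#' @param reverse_offset distance downstream of the SNP where the reverse
#'   primer window starts.
#' @param reverse_length reverse primer length.
#' @return object of class `kasp_assay`: list with `marker_id`, `fam_primer`,
#'   `hex_primer`, `common_reverse`, `allele_fam`, `allele_hex`, `context`.
#' @export
build_kasp_assay <- function(variant, context, arm_length = 20,
                             reverse_offset = 30, reverse_length = 20) {
  stopifnot(inherits(context, "snp_context"))
  id <- variant$id %||% variant$marker_id %||% "assay"
  seq <- context$seq
  ctr <- context$center
  if (ctr < arm_length)
    stop("insufficient context upstream of the SNP for the allele-specific arm")
  if (nchar(seq) < ctr + reverse_offset + reverse_length - 1L)
    stop("insufficient context downstream of the SNP for the reverse primer window")
  if (substr(seq, ctr, ctr) != toupper(variant$ref))
    stop("context center does not match the ref allele")
  arm <- substr(seq, ctr - arm_length + 1L, ctr)
  fam_arm <- paste0(substr(arm, 1L, arm_length - 1L), toupper(variant$ref))
  hex_arm <- paste0(substr(arm, 1L, arm_length - 1L), toupper(variant$alt))
  rev_window <- substr(seq, ctr + reverse_offset, ctr + reverse_offset + reverse_length - 1L)
  common_rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rev_window)))
  structure(list(marker_id = id,
                 fam_primer = paste0(KASP_FAM_TAIL, fam_arm),
                 hex_primer = paste0(KASP_HEX_TAIL, hex_arm),
                 common_reverse = common_rev,
                 allele_fam = toupper(variant$ref),
                 allele_hex = toupper(variant$alt),
                 context = seq),
            class = "kasp_assay")
}
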