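# Fixture builders shared across test files. Everything is generated in code;
# no binary fixtures.

# One marker column with exact genotype-class counts.
make_marker_column <- function(n_hom_major, n_het, n_hom_minor, n_missing = 0,
                               major = "A", minor = "G") {
  g <- c(rep(paste0(major, major), n_hom_major),
         rep(paste0(min(major, minor), max(major, minor)), n_het),
         rep(paste0(minor, minor), n_hom_minor),
         rep(NA_character_, n_missing))
  stats::setNames(g, sprintf("acc%03d", seq_along(g)))
}

# The five-record screening toy set: one locus failing each cascade stage
# plus one clean survivor. 50 accessions.
#   r1 MAF 0.04            (fails stage 1)
#   r2 missing 0.26        (fails stage 2; MAF fine among called)
#   r3 MAF 0.20, PIC 0.269 (fails stage 3)
#   r4 clean stats but r3 sits 50 bp away (fails stage 4)
#   r5 MAF 0.30, no missing, isolated (survives)
make_cascade_toyset <- function() {
  n <- 50L
  col <- function(maj, het, mnr, mis, a = "A", b = "G")
    make_marker_column(maj, het, mnr, mis, a, b)
  g <- cbind(
    r1 = col(46, 4, 0, 0),            # minor count 4/100
    r2 = col(22, 11, 4, 13, "C", "T"),
    r3 = col(32, 16, 2, 0),           # minor 20/100
    r4 = col(25, 20, 5, 0, "C", "A"),
    r5 = col(26, 18, 6, 0, "G", "T")  # minor 30/100
  )
  variants <- data.frame(
    chrom = c("chr1", "chr2", "chr3", "chr3", "chr4"),
    pos = c(500L, 800L, 1000L, 1050L, 2000L),
    id = c("r1", "r2", "r3", "r4", "r5"),
    ref = c("A", "C", "A", "C", "G"),
    alt = c("G", "T", "G", "A", "T"),
    stringsAsFactors = FALSE)
  list(variants = variants, genotypes = g)
}

# Random fingerprint database over two-letter genotypes.
random_db <- function(n, m, seed, missing_rate = 0) {
  set.seed(seed)
  genos <- c("AA", "AG", "GG")
  mat <- matrix(sample(genos, n * m, replace = TRUE), n, m,
                dimnames = list(sprintf("acc%02d", seq_len(n)),
                                sprintf("mk%02d", seq_len(m))))
  if (missing_rate > 0) mat[runif(n * m) < missing_rate] <- NA_character_
  build_fingerprint_db(mat)
}

# Exhaustive minimum fully-discriminating subset size (NA if none).
exhaustive_min_subset <- function(db) {
  m <- length(db$marker_order)
  n <- nrow(db$profiles)
  for (k in seq_len(m)) {
    for (idx in utils::combn(m, k, simplify = FALSE)) {
      if (discrimination_count(db, db$marker_order[idx]) == n) return(k)
    }
  }
  NA_integer_
}

# Brute-force re-check of the four cascade predicates for one marker column.
cascade_predicates <- function(variants, gm, i, th) {
  g <- gm[, variants$id[i]]
  al <- unlist(strsplit(g[!is.na(g)], ""))
  tab <- table(al)
  p <- as.numeric(tab) / sum(tab)
  maf <- if (length(p) < 2) 0 else min(p)
  miss <- mean(is.na(g))
  picv <- 1 - sum(p^2) - (sum(p^2)^2 - sum(p^4))
  same <- which(variants$chrom == variants$chrom[i])
  nb <- any(abs(variants$pos[setdiff(same, i)] - variants$pos[i]) <= th$flank_bp)
  c(maf = maf > th$maf_min, miss = miss <= th$missing_max,
    pic = picv > th$pic_min, flank = !nb)
}
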