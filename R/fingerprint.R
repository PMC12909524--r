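#' Build a DNA fingerprint database
#'
#' Stores the multilocus genotype profile of every accession over an ordered
#' marker list, verbatim — missing calls are preserved, never imputed.
#'
#' @param genotypes accessions x markers genotype matrix; accession ids
#'   (rownames) must be unique.
#' @param provenance free-text metadata.
#' @return object of class `fingerprint_db`: list with `marker_order`,
#'   `profiles` (character matrix) and `provenance`.
#' @export
build_fingerprint_db <- function(genotypes, provenance = "") {
  gm <- as_genotype_matrix(genotypes)
  if (anyDuplicated(rownames(gm)))
    stop("duplicate accession ids in fingerprint database")
  structure(list(marker_order = colnames(gm), profiles = gm,
                 provenance = provenance),
            class = "fingerprint_db")
}

# mismatches and compared-locus count between two profiles (mutually called
# loci only)
profile_mismatch <- function(a, b) {
  both <- !is.na(a) & !is.na(b)
  c(mismatches = sum(a[both] != b[both]), loci_compared = sum(both))
}

#' Find near-duplicate accession pairs
#'
#' All unordered accession pairs differing at no more than `max_mismatch`
#' mutually called loci — the fingerprint-level signal of clones, synonymous
#' lots or labeling errors.
#'
#' @param db a `fingerprint_db`.
#' @param max_mismatch maximum mismatch count to report.
#' @return data.frame with columns `acc1`, `acc2`, `mismatches`,
#'   `loci_compared`, sorted by mismatch count.
#' @export
find_duplicates <- function(db, max_mismatch = 1) {
  stopifnot(inherits(db, "fingerprint_db"))
  pr <- db$profiles
  n <- nrow(pr)
  out <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        mm <- profile_mismatch(pr[i, ], pr[j, ])
        if (mm["mismatches"] <= max_mismatch) {
          out[[length(out) + 1L]] <- data.frame(
            acc1 = rownames(pr)[i], acc2 = rownames(pr)[j],
            mismatches = unname(mm["mismatches"]),
            loci_compared = unname(mm["loci_compared"]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(acc1 = character(), acc2 = character(),
                      mismatches = integer(), loci_compared = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$mismatches, res$acc1, res$acc2), , drop = FALSE]
}

#' Number of distinct multilocus profiles under a marker subset
#'
#' Missing calls compare equal to missing and unequal to any call, so a
#' missing cell keeps a profile distinct from an otherwise identical called
#' profile.
#'
#' @param db a `fingerprint_db`.
#' @param markers character vector of marker ids (subset of `marker_order`);
#'   the empty subset collapses everything to one profile.
#' @return count of distinct profiles.
#' @export
discrimination_count <- function(db, markers) {
  stopifnot(inherits(db, "fingerprint_db"))
  unknown <- setdiff(markers, db$marker_order)
  if (length(unknown))
    stop(sprintf("unknown marker id(s): %s", paste(unknown, collapse = ", ")))
  if (length(markers) == 0L) return(1L)
  sub <- db$profiles[, markers, drop = FALSE]
  sub[is.na(sub)] <- "·"
  length(unique(apply(sub, 1L, paste, collapse = "|")))
}

#' Greedy minimal discriminating marker selection
#'
#' Iteratively adds the marker separating the largest number of not-yet
#' separated accession pairs; a pair is separated by a marker only where
#' both accessions are called and differ. Ties are broken by higher PIC,
#' then by marker order. Selection stops when every pair is separated or no
#' marker adds separation. The efficiency curve records, per step, the
#' number of distinct multilocus profiles and the fraction of separated
#' pairs — both non-decreasing.
#'
#' @param db a `fingerprint_db`.
#' @param pic_values optional named PIC vector for tie-breaking; computed
#'   from the database genotypes when omitted.
#' @return list with `markers` (ordered selection), `curve` (data.frame:
#'   step, marker, n_distinct, pairs_separated, frac_pairs_separated) and
#'   `unseparated_pairs` (data.frame of terminally unseparable pairs).
#' @export
greedy_core_markers <- function(db, pic_values = NULL) {
  stopifnot(inherits(db, "fingerprint_db"))
  pr <- db$profiles
  n <- nrow(pr); mks <- db$marker_order
  if (n < 2L) stop("at least two accessions are required")
  if (is.null(pic_values)) {
    pic_values <- vapply(mks, function(m) {
      g <- pr[, m]
      if (all(is.na(g))) return(0)
      pic(allele_frequencies(g))
    }, numeric(1))
  }
  prs <- utils::combn(n, 2L)
  n_pairs <- ncol(prs)
  # separation matrix: markers x pairs
  sep <- matrix(FALSE, length(mks), n_pairs, dimnames = list(mks, NULL))
  for (m in seq_along(mks)) {
    g <- pr[, m]
    a <- g[prs[1, ]]; b <- g[prs[2, ]]
    sep[m, ] <- !is.na(a) & !is.na(b) & a != b
  }
  uncovered <- rep(TRUE, n_pairs)
  chosen <- character(0)
  curve <- list()
  remaining <- mks
  repeat {
    gains <- rowSums(sep[remaining, uncovered, drop = FALSE])
    if (all(gains == 0)) break
    ord <- order(-gains, -pic_values[remaining], match(remaining, mks))
    best <- remaining[ord[1L]]
    chosen <- c(chosen, best)
    uncovered <- uncovered & !sep[best, ]
    remaining <- setdiff(remaining, best)
    curve[[length(curve) + 1L]] <- data.frame(
      step = length(chosen), marker = best,
      n_distinct = discrimination_count(db, chosen),
      pairs_separated = n_pairs - sum(uncovered),
      frac_pairs_separated = 1 - sum(uncovered) / n_pairs,
      stringsAsFactors = FALSE)
    if (!any(uncovered) || !length(remaining)) break
  }
  unsep <- which(uncovered)
  unseparated <- data.frame(acc1 = rownames(pr)[prs[1, unsep]],
                            acc2 = rownames(pr)[prs[2, unsep]],
                            stringsAsFactors = FALSE)
  list(markers = chosen,
       curve = if (length(curve)) do.call(rbind, curve) else
         data.frame(step = integer(), marker = character(),
                    n_distinct = integer(), pairs_separated = integer(),
                    frac_pairs_separated = numeric()),
       unseparated_pairs = unseparated)
}

#' Match an unknown profile against a fingerprint database
#'
#' Counts mismatches over mutually called loci against every database entry.
#' The query is declared matched only to an entry with zero mismatches over
#' at least `min_overlap` compared loci; otherwise the verdict is
#' `"no match"` (an unregistered genotype) or `"insufficient data"` when no
#' entry reaches the overlap floor.
#'
#' @param db a `fingerprint_db`.
#' @param profile named genotype vector over (a subset of) the database's
#'   markers, `NA` for missing.
#' @param min_overlap minimum mutually called loci for a match verdict.
#' @param query_id identifier recorded in the report.
#' @return object of class `match_report`: list with `query`, `verdict`
#'   (matched entry id, `"no match"` or `"insufficient data"`) and `nearest`
#'   (data.frame of all entries ranked by mismatches then decreasing
#'   overlap).
#' @export
match_query <- function(db, profile, min_overlap = 20, query_id = "query") {
  stopifnot(inherits(db, "fingerprint_db"))
  full <- stats::setNames(rep(NA_character_, length(db$marker_order)),
                          db$marker_order)
  if (is.null(names(profile)) && length(profile) == length(full)) {
    full[] <- as.character(profile)
  } else {
    unknown <- setdiff(names(profile), db$marker_order)
    if (length(unknown))
      stop(sprintf("query uses unknown marker id(s): %s", paste(unknown, collapse = ", ")))
    full[names(profile)] <- as.character(profile)
  }
  pr <- db$profiles
  mm <- t(vapply(seq_len(nrow(pr)), function(i) profile_mismatch(pr[i, ], full),
                 numeric(2)))
  nearest <- data.frame(accession = rownames(pr),
                        mismatches = as.integer(mm[, 1]),
                        loci_compared = as.integer(mm[, 2]),
                        stringsAsFactors = FALSE)
  nearest <- nearest[order(nearest$mismatches, -nearest$loci_compared,
                           nearest$accession), , drop = FALSE]
  eligible <- nearest$loci_compared >= min_overlap
  verdict <- if (!any(eligible)) "insufficient data"
    else if (any(eligible & nearest$mismatches == 0L))
      nearest$accession[eligible & nearest$mismatches == 0L][1L]
    else "no match"
  structure(list(query = query_id, verdict = verdict, nearest = nearest,
                 min_overlap = min_overlap),
            class = "match_report")
}

#' Fingerprint heatmap color code
#'
#' The fixed fingerprint-matrix legend: homozygous AA yellow, GG orange,
#' CC blue, TT purple; any heterozygote green; missing grey.
#'
#' @param genotype character vector of genotype calls (`NA` = missing).
#' @return character vector of color names.
#' @export
genotype_color <- function(genotype) {
  hom <- c(AA = "yellow", GG = "orange", CC = "blue", TT = "purple")
  out <- ifelse(is.na(genotype), "grey",
                ifelse(genotype %in% names(hom), unname(hom[genotype]),
                       ifelse(is_heterozygote(genotype), "green", "grey")))
  unname(out)
}

#' Export the color-coded fingerprint matrix
#'
#' Writes the fingerprint as CSV in publication orientation (rows = markers,
#' columns = accessions, missing cells empty) together with a color-legend
#' CSV mapping genotype classes to the fixed heatmap palette. An image can
#' optionally be rendered with base graphics.
#'
#' @param db a `fingerprint_db`.
#' @param path output CSV path.
#' @param legend_path legend CSV path.
#' @param render_png optional PNG path; when given, a color-coded matrix
#'   image is drawn.
#' @return `path`, invisibly.
#' @export
export_fingerprint_matrix <- function(db, path,
                                      legend_path = paste0(path, ".legend.csv"),
                                      render_png = NULL) {
  stopifnot(inherits(db, "fingerprint_db"))
  mat <- t(db$profiles)                         # markers x accessions
  out <- as.data.frame(mat, stringsAsFactors = FALSE)
  out[is.na(out)] <- ""
  out <- cbind(marker = rownames(mat), out)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  legend <- data.frame(
    class = c("AA", "GG", "CC", "TT", "heterozygous", "missing"),
    color = c("yellow", "orange", "blue", "purple", "green", "grey"),
    stringsAsFactors = FALSE)
  utils::write.csv(legend, legend_path, row.names = FALSE, quote = FALSE)
  if (!is.null(render_png)) {
    cols <- c(yellow = "#F2C94C", orange = "#E67E22", blue = "#2D9CDB",
              purple = "#9B51E0", green = "#27AE60", grey = "#BDBDBD")
    cmat <- matrix(genotype_color(mat), nrow(mat), ncol(mat))
    grDevices::png(render_png, width = 40 * ncol(mat) + 200,
                   height = 24 * nrow(mat) + 100)
    graphics::par(mar = c(6, 6, 1, 1))
    graphics::image(seq_len(ncol(mat)), seq_len(nrow(mat)),
                    t(matrix(match(cmat, names(cols)), nrow(mat))),
                    col = cols, zlim = c(1, length(cols)),
                    axes = FALSE, xlab = "", ylab = "")
    graphics::axis(1, seq_len(ncol(mat)), colnames(mat), las = 2, cex.axis = 0.6)
    graphics::axis(2, seq_len(nrow(mat)), rownames(mat), las = 2, cex.axis = 0.6)
    grDevices::dev.off()
  }
  invisible(path)
}

#' Read a fingerprint matrix CSV back into a database
#'
#' Inverse of [export_fingerprint_matrix()].
#'
#' @param path CSV written by [export_fingerprint_matrix()].
#' @param provenance free-text metadata.
#' @return a `fingerprint_db`.
#' @export
read_fingerprint_csv <- function(path, provenance = "") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  mk <- df$marker
  mat <- as.matrix(df[, setdiff(names(df), "marker"), drop = FALSE])
  mat[mat == ""] <- NA_character_
  rownames(mat) <- mk
  build_fingerprint_db(t(mat), provenance = provenance)
}
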