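test_that("fingerprint databases store profiles verbatim", {
  sim <- simulate_population(n_accessions = 105, n_markers = 31, seed = 17)
  db <- build_fingerprint_db(sim$genotypes, provenance = "synthetic panel")
  expect_equal(dim(db$profiles), c(105L, 31L))
  expect_equal(db$marker_order, colnames(sim$genotypes))
  # missing cells preserved as missing, never imputed
  expect_identical(is.na(db$profiles), is.na(sim$genotypes))
  gm <- sim$genotypes
  rownames(gm)[2] <- rownames(gm)[1]
  expect_error(build_fingerprint_db(gm), "duplicate")
})

test_that("fingerprint CSV export round-trips and ships the six-class legend", {
  gm <- rbind(a = c("AA", "AG", "CC", NA),
              b = c("GG", "CT", "TT", "GG"))
  colnames(gm) <- paste0("mk", 1:4)
  db <- build_fingerprint_db(gm)
  path <- withr::local_tempfile(fileext = ".csv")
  export_fingerprint_matrix(db, path)
  back <- read_fingerprint_csv(path)
  expect_identical(back$profiles, db$profiles)
  legend <- utils::read.csv(paste0(path, ".legend.csv"), stringsAsFactors = FALSE)
  expect_equal(nrow(legend), 6L)
  expect_equal(legend$color[match(c("AA", "GG", "CC", "TT"), legend$class)],
               c("yellow", "orange", "blue", "purple"))
  expect_equal(legend$color[legend$class == "heterozygous"], "green")
  expect_equal(legend$color[legend$class == "missing"], "grey")
})

test_that("the color code maps every genotype class as published", {
  expect_equal(genotype_color(c("AA", "GG", "CC", "TT")),
               c("yellow", "orange", "blue", "purple"))
  expect_equal(genotype_color(c("AG", "CT", "GT")), rep("green", 3))
  expect_equal(genotype_color(NA_character_), "grey")
})

test_that("near-duplicate pairs are found at the configured mismatch budget", {
  gm <- rbind(u = c("AA", "AG", "GG"), v = c("AA", "AG", "GG"),
              w = c("AA", "AA", "GG"), x = c("GG", "AA", "AA"))
  colnames(gm) <- paste0("mk", 1:3)
  db <- build_fingerprint_db(gm)
  d0 <- find_duplicates(db, max_mismatch = 0)
  expect_equal(nrow(d0), 1L)
  expect_equal(d0$mismatches, 0L)
  d1 <- find_duplicates(db, max_mismatch = 1)
  expect_setequal(paste(d1$acc1, d1$acc2),
                  c("u v", "u w", "v w"))
  # the one-locus pair appears at budget 1 but not at 0
  expect_false(any(d0$acc1 == "u" & d0$acc2 == "w"))
})

test_that("duplicate reports agree with a brute-force recount on random dbs", {
  for (seed in 1:50) {
    db <- random_db(n = 8, m = 6, seed = seed, missing_rate = 0.1)
    rep1 <- find_duplicates(db, max_mismatch = 1)
    # quadratic oracle
    cnt <- 0L
    pr <- db$profiles
    for (i in 1:7) for (j in (i + 1):8) {
      both <- !is.na(pr[i, ]) & !is.na(pr[j, ])
      if (sum(pr[i, both] != pr[j, both]) <= 1L) cnt <- cnt + 1L
    }
    expect_equal(nrow(rep1), cnt)
  }
})

test_that("greedy marker selection solves the worked three-marker case", {
  gm <- cbind(M1 = c("AA", "AA", "GG", "GG"),
              M2 = c("AA", "GG", "AA", "GG"),
              M3 = c("AA", "AA", "AA", "GG"))
  rownames(gm) <- paste0("a", 1:4)
  db <- build_fingerprint_db(gm)
  res <- greedy_core_markers(db)
  expect_equal(sort(res$markers), c("M1", "M2"))
  expect_equal(res$curve$n_distinct[nrow(res$curve)], 4L)
  expect_equal(exhaustive_min_subset(db), 2L)
  expect_equal(nrow(res$unseparated_pairs), 0L)
})

test_that("degenerate databases are handled: one informative marker, clones", {
  gm <- cbind(M1 = c("AA", "AG", "GG"), M2 = c("AA", "AA", "AA"))
  rownames(gm) <- paste0("a", 1:3)
  res <- greedy_core_markers(build_fingerprint_db(gm))
  expect_equal(res$markers, "M1")
  gm2 <- cbind(M1 = c("AA", "AA"), M2 = c("GG", "GG"))
  rownames(gm2) <- c("c1", "c2")
  res2 <- greedy_core_markers(build_fingerprint_db(gm2))
  expect_equal(nrow(res2$unseparated_pairs), 1L)
})

test_that("discrimination counts respect missing-call semantics", {
  sim <- simulate_population(n_accessions = 12, n_markers = 6,
                             missing_rate = 0, seed = 19)
  db <- build_fingerprint_db(sim$genotypes)
  expect_equal(discrimination_count(db, character(0)), 1L)
  expect_error(discrimination_count(db, "nope"), "unknown marker")
  # missing differs from any call but equals missing
  gm <- rbind(a = c("AA", NA), b = c("AA", "AG"), c = c("AA", NA))
  colnames(gm) <- c("m1", "m2")
  dbm <- build_fingerprint_db(gm)
  expect_equal(discrimination_count(dbm, c("m1", "m2")), 2L)
})

test_that("efficiency curves are monotone and greedy is near-exhaustive on small dbs", {
  for (seed in 1:25) {
    db <- random_db(n = sample(4:8, 1), m = sample(3:6, 1), seed = 100 + seed)
    res <- greedy_core_markers(db)
    expect_true(all(diff(res$curve$n_distinct) >= 0))
    expect_true(all(diff(res$curve$pairs_separated) >= 0))
    n <- nrow(db$profiles)
    if (discrimination_count(db, db$marker_order) == n) {
      expect_equal(res$curve$n_distinct[nrow(res$curve)], n)
      expect_gte(length(res$markers), exhaustive_min_subset(db))
    }
  }
})

test_that("query matching identifies stored entries and rejects novel profiles", {
  sim <- simulate_population(n_accessions = 20, n_markers = 31,
                             missing_rate = 0, seed = 23)
  db <- build_fingerprint_db(sim$genotypes)
  # stored profile with two loci dropped: matched with 29 compared loci
  q <- db$profiles[4, ]
  q[c(3, 10)] <- NA
  rep1 <- match_query(db, q)
  expect_equal(rep1$verdict, rownames(db$profiles)[4])
  expect_equal(rep1$nearest$loci_compared[1], 29L)
  expect_equal(rep1$nearest$mismatches[1], 0L)
  # one-locus mutation of a stored profile: no match, nearest at 1 mismatch
  q2 <- db$profiles[4, ]
  q2[5] <- if (q2[5] == "AA") "GG" else "AA"
  rep2 <- match_query(db, q2)
  expect_equal(rep2$verdict, "no match")
  expect_equal(rep2$nearest$mismatches[1], 1L)
  # overlap below the floor
  q3 <- db$profiles[4, ]
  q3[1:25] <- NA
  expect_equal(match_query(db, q3)$verdict, "insufficient data")
  # every stored profile matches itself
  for (i in c(1, 7, 20)) {
    expect_equal(match_query(db, db$profiles[i, ])$verdict,
                 rownames(db$profiles)[i])
  }
})
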