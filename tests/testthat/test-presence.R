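test_that("coverage vectors count overlaps, clip and conserve mass", {
  expect_identical(coverageCounts(buildCoverageVector(emptyHits(), 5)),
                   rep(0L, 5))
  h <- randomHits(2)
  h$q_start <- c(1L, 2L); h$q_end <- c(3L, 5L)
  expect_identical(coverageCounts(buildCoverageVector(h, 5)),
                   c(1L, 2L, 2L, 1L, 1L))
  h1 <- h[1, ]; h1$q_start <- 4L; h1$q_end <- 9L
  expect_warning(cv <- buildCoverageVector(h1, 5), "clipped")
  expect_identical(coverageCounts(cv), c(0L, 0L, 0L, 1L, 1L))
  h2 <- h; h2$query_id <- c("a", "b")
  expect_error(buildCoverageVector(h2, 5), "mix query ids")
  # conservation: sum(counts) equals total clipped interval length,
  # and the vector equals the brute-force per-position counter
  set.seed(77)
  for (i in 1:50) {
    hh <- randomHits(sample(0:30, 1))
    cv <- coverageCounts(buildCoverageVector(hh, 50L))
    expect_identical(cv, bruteCoverage(hh, 50L))
    expect_identical(sum(cv),
                     sum(pmin(hh$q_end, 50L) - pmax(hh$q_start, 1L) + 1L))
  }
})

test_that("decoy filter removes only out-competed overlapping hits", {
  t <- randomHits(1); t$subject_id <- "s1"; t$strand <- "+"
  t$s_start <- 100L; t$s_end <- 400L; t$evalue <- 1e-20
  d <- t; d$evalue <- 1e-30
  attr(d, "provenance") <- "internal"
  expect_identical(nrow(decoyFilter(t, d)$retained), 0L)
  d$evalue <- 1e-10
  expect_identical(nrow(decoyFilter(t, d)$retained), 1L)
  # equal e-values keep the target ("lower" is strict)
  d$evalue <- 1e-20
  expect_identical(nrow(decoyFilter(t, d)$retained), 1L)
  expect_identical(nrow(decoyFilter(t, d, tiePolicy = "drop")$retained), 0L)
  # partial overlap below the fraction threshold does not remove
  d$evalue <- 1e-30; d$s_start <- 350L; d$s_end <- 650L
  expect_identical(nrow(decoyFilter(t, d, overlapFraction = 0.5)$retained), 1L)
  # opposite strand is ignored when sameStrand is required
  d$s_start <- 100L; d$s_end <- 400L; d$strand <- "-"
  expect_identical(nrow(decoyFilter(t, d)$retained), 1L)
  expect_identical(nrow(decoyFilter(t, d, sameStrand = FALSE)$retained), 0L)
  # provenance mixing is rejected
  db <- d; attr(db, "provenance") <- "blast"
  expect_error(decoyFilter(t, db), "provenance")
})

test_that("decoy filter laws: identity, monotonicity, idempotence", {
  set.seed(123)
  for (i in 1:40) {
    t <- randomHits(sample(1:15, 1))
    d <- randomHits(sample(0:15, 1), queryId = "decoy")
    extra <- randomHits(sample(1:10, 1), queryId = "decoy")
    # identity with empty decoys
    expect_identical(decoyFilter(t, emptyHits())$retained, t)
    r1 <- decoyFilter(t, d)$retained
    # monotone: more decoys never grow the retained set
    r2 <- decoyFilter(t, rbind(d, extra))$retained
    expect_true(nrow(r2) <= nrow(r1))
    expect_true(all(paste(r2$s_start, r2$s_end) %in%
                    paste(r1$s_start, r1$s_end)))
    # idempotent: refiltering retained hits removes nothing
    r3 <- decoyFilter(r1, d)$retained
    expect_identical(nrow(r3), nrow(r1))
  }
})

test_that("presence calls anchor on the LBD and flag DBD-only signal", {
  # full-length exact coverage -> present with fraction 1
  h <- randomHits(1); h$q_start <- 1L; h$q_end <- 200L; h$evalue <- 1e-50
  call <- callPresence(h, 200L, lbd = c(96L, 200L), dbd = c(1L, 66L))
  expect_identical(call$status, "present")
  expect_equal(call$lbd_fraction, 1.0)
  # no hits -> absent with zero fractions
  call0 <- callPresence(emptyHits(), 200L, lbd = c(96L, 200L),
                        dbd = c(1L, 66L))
  expect_identical(call0$status, "absent")
  expect_equal(call0$lbd_fraction, 0)
  expect_true(is.na(call0$best_evalue))
  # hits confined to the DBD -> ambiguous
  hD <- h; hD$q_start <- 1L; hD$q_end <- 66L
  callD <- callPresence(hD, 200L, lbd = c(96L, 200L), dbd = c(1L, 66L))
  expect_identical(callD$status, "ambiguous")
  # hits above the e-value cutoff are ignored
  hE <- h; hE$evalue <- 1e-3
  expect_identical(callPresence(hE, 200L, lbd = c(96L, 200L))$status,
                   "absent")
  expect_error(callPresence(h, 200L, lbd = NULL), "LBD")
})

test_that("matrix assembly follows tree leaf order and validates species", {
  mk <- function(counts) new("CoverageVector", queryId = "q",
                             counts = as.integer(counts))
  vecs <- list(C = mk(c(1, 0, 2)), A = mk(c(0, 0, 0)), B = mk(c(3, 1, 0)))
  m <- assembleMatrix(vecs, "((A,B),C);")
  expect_identical(speciesOrder(m), c("A", "B", "C"))
  expect_identical(coverageCounts(m)["B", ], c(3L, 1L, 0L))
  # input order does not matter
  m2 <- assembleMatrix(vecs[c("B", "C", "A")], "((A,B),C);")
  expect_identical(coverageCounts(m2), coverageCounts(m))
  # species not in the tree is an error naming the offender
  expect_error(assembleMatrix(c(vecs, list(Z = mk(1:3))), "((A,B),C);"),
               "Z")
  # tree leaves without data are skipped with a warning
  expect_warning(m3 <- assembleMatrix(vecs[c("A", "B")], "((A,B),C);"),
                 "C")
  expect_identical(speciesOrder(m3), c("A", "B"))
  # length mismatch is an error
  bad <- c(vecs[1:2], list(C = mk(c(1, 2))))
  expect_error(assembleMatrix(bad, "((A,B),C);"), "length")
})

test_that("reciprocal best hits require mutual unique bests", {
  A <- Biostrings::AAStringSet(c(a1 = "MKVLAHEWRRTY"))
  B <- Biostrings::AAStringSet(c(b1 = "MKVLAHEWRRTY"))
  r <- reciprocalBestHits(A, B)
  expect_identical(r$pairs$a_id, "a1")
  expect_identical(r$pairs$b_id, "b1")
  # a1's best is b1 but b1's best is a2 -> no pair for a1
  A2 <- Biostrings::AAStringSet(c(a1 = "MKVLAHEWRRTY",
                                  a2 = "MKVLAHEWRRTYGGG"))
  B2 <- Biostrings::AAStringSet(c(b1 = "MKVLAHEWRRTYGGG"))
  r2 <- reciprocalBestHits(A2, B2)
  expect_identical(r2$pairs$a_id, "a2")
  expect_false("a1" %in% r2$pairs$a_id)
  # tie on the best partner -> no pair, flagged ambiguous
  B3 <- Biostrings::AAStringSet(c(b1 = "MKVLAHEWRRTY",
                                  b2 = "MKVLAHEWRRTY"))
  r3 <- reciprocalBestHits(A, B3)
  expect_identical(nrow(r3$pairs), 0L)
  expect_true("a1" %in% r3$ambiguous)
  expect_error(reciprocalBestHits(
    Biostrings::AAStringSet(c(x = "MK", x = "MK")), B), "duplicate")
})

test_that("heat-map TSV twin round-trips the matrix", {
  m <- new("CoverageMatrix", queryId = "q", species = c("A", "B"),
           counts = matrix(0:9, nrow = 2, byrow = TRUE,
                           dimnames = list(c("A", "B"), NULL)))
  pre <- file.path(withr::local_tempdir(), "hm")
  renderHeatmap(m, pre)
  expect_true(file.exists(paste0(pre, ".png")))
  m2 <- readCoverageMatrix(paste0(pre, ".tsv"))
  expect_identical(coverageCounts(m2), coverageCounts(m))
  expect_identical(speciesOrder(m2), speciesOrder(m))
  expect_identical(queryId(m2), "q")
  # all-zero matrix renders without error
  mz <- new("CoverageMatrix", queryId = "q", species = "A",
            counts = matrix(0L, 1, 5, dimnames = list("A", NULL)))
  expect_no_error(renderHeatmap(mz, file.path(withr::local_tempdir(), "z")))
  expect_error(renderHeatmap(new("CoverageMatrix", queryId = "q",
                                 species = character(),
                                 counts = matrix(integer(), 0, 5)), pre),
               "empty")
})
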