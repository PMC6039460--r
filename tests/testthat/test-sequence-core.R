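test_that("readFasta parses headers, wraps, normalizes case and validates", {
  tf <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1 scaffold one", "acgt", ">s2", "ACGT", "acGT"), tf)
  x <- readFasta(tf)
  expect_s4_class(x, "DNAStringSet")
  expect_identical(names(x), c("s1", "s2"))
  expect_identical(as.character(x[["s1"]]), "ACGT")
  expect_identical(as.character(x[["s2"]]), "ACGTACGT")

  writeLines(c(">p1", "MKVLAJ"), tf)
  expect_error(readFasta(tf, type = "protein"), "invalid amino-acid")

  writeLines(c(">e1", ""), tf)
  expect_error(readFasta(tf), "empty sequence.*e1")

  writeLines(c(">r1", "ACGRYT"), tf)
  expect_warning(x <- readFasta(tf, type = "dna"), "mapped to N")
  expect_identical(as.character(x[[1]]), "ACGNNT")
  expect_error(readFasta(tf, type = "dna", iupacToN = FALSE), "IUPAC")

  expect_error(readFasta(file.path(tempdir(), "nope.fa")), "not found")
})

test_that("six-frame translation uses the standard code with stop and X", {
  fr <- sixFrameTranslate("ATGGCCTGA")
  labels <- vapply(fr, `[[`, character(1), "label")
  prots <- vapply(fr, `[[`, character(1), "protein")
  expect_identical(prots[labels == "+1"], "MA*")
  # reverse complement of ATGGCCTGA is TCAGGCCAT -> SGH
  expect_identical(prots[labels == "-1"], "SGH")
  # codons with N emit X
  frN <- sixFrameTranslate("ATGGNCTGA")
  expect_identical(frN[[1]]$protein, "MX*")
  # shorter than 3: all frames empty, no error
  expect_true(all(vapply(sixFrameTranslate("AC"), `[[`,
                         character(1), "protein") == ""))
})

test_that("residue-to-nucleotide coordinate maps are correct and bijective", {
  expect_equal(residueToNt(2, "+", 1, 9), cbind(start = 4L, end = 6L))
  # minus strand residue 1 frame 1 of a 9-mer is forward bases 7-9
  expect_equal(residueToNt(1, "-", 1, 9), cbind(start = 7L, end = 9L))
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    strand <- sample(c("+", "-"), 1)
    f <- sample(1:3, 1)
    ncod <- (n - f + 1L) %/% 3L
    if (ncod < 1L) next
    r <- seq_len(ncod)
    nt <- residueToNt(r, strand, f, n)
    for (k in r) {
      back <- ntToResidue(nt[k, "start"]:nt[k, "end"], strand, f, n)
      expect_true(all(back == k))
    }
  }
})

test_that("smithWaterman matches examples and handles empty input", {
  sp <- scoringParams()
  r <- smithWaterman("AAA", "AAA", sp)
  expect_equal(r$score, 12)  # 3 x A/A = +4 in BLOSUM62
  expect_equal(c(r$aStart, r$aEnd, r$bStart, r$bEnd), c(1, 3, 1, 3))
  expect_equal(smithWaterman("MKV", "", sp)$score, 0)
  # self-alignment equals the sum of diagonal scores
  set.seed(3)
  for (i in 1:10) {
    a <- randomAA(sample(5:60, 1))
    diag <- sum(sp@matrix[cbind(strsplit(a, "")[[1]], strsplit(a, "")[[1]])])
    expect_equal(smithWaterman(a, a, sp)$score, diag)
  }
})

test_that("alignment scores equal the independent exhaustive-DP oracle", {
  sp <- scoringParams()
  set.seed(2024)
  for (i in 1:60) {
    a <- randomAA(sample(3:200, 1))
    b <- randomAA(sample(3:200, 1))
    mine <- smithWaterman(a, b, sp)$score
    oracle <- Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
      substitutionMatrix = sp@matrix, gapOpening = sp@gapOpen,
      gapExtension = sp@gapExtend))
    expect_identical(mine, oracle)
  }
})

test_that("karlin e-value obeys its algebra and monotonicity", {
  sp <- scoringParams()
  # lambda * S = ln(K m n)  =>  e-value exactly 1
  s1 <- log(sp@K * 430 * 1e6) / sp@lambda
  expect_equal(karlinEvalue(s1, 430, 1e6, sp), 1.0)
  # doubling n doubles the e-value
  expect_equal(karlinEvalue(80, 430, 2e6, sp),
               2 * karlinEvalue(80, 430, 1e6, sp))
  # direct evaluation at the documented operating point
  expect_equal(karlinEvalue(100, 430, 1e6, sp),
               0.041 * 430 * 1e6 * exp(-26.7))
  expect_error(karlinEvalue(10, 0, 100, sp), "positive")
  # monotone decreasing in score over random parameter draws
  set.seed(9)
  for (i in 1:50) {
    p <- scoringParams(lambda = runif(1, 0.1, 0.5), K = runif(1, 0.01, 0.3))
    s <- sort(runif(2, 10, 300))
    expect_gt(karlinEvalue(s[1], 100, 1e5, p),
              karlinEvalue(s[2], 100, 1e5, p))
  }
  # scoreForEvalue inverts karlinEvalue
  expect_equal(karlinEvalue(scoreForEvalue(1e-5, 200, 1e6, sp),
                            200, 1e6, sp), 1e-5)
})

test_that("translated search finds planted genes on both strands", {
  sp <- scoringParams()
  prot <- randomProtein(100, seed = 21)
  gene <- reverseTranslate(prot, "first_codon")
  bg <- randomDna(2500, 0.42, seed = 22)
  fwd <- paste0(substr(bg, 1, 400), gene, substr(bg, 401, 2500))
  g <- Biostrings::DNAStringSet(c(sc1 = fwd))
  h <- translatedSearch(prot, g, sp)
  expect_gte(nrow(h), 1L)
  expect_identical(h$q_start[1], 1L)
  expect_identical(h$q_end[1], 100L)
  expect_identical(h$s_start[1], 401L)
  expect_identical(h$s_end[1], 700L)
  expect_identical(h$strand[1], "+")
  expect_identical(hitProvenance(h), "internal")

  # strand symmetry: searching the reverse complement mirrors coordinates
  rc <- Biostrings::DNAStringSet(c(sc1 = as.character(
    Biostrings::reverseComplement(g[[1]]))))
  h2 <- translatedSearch(prot, rc, sp)
  n <- nchar(fwd)
  expect_identical(h2$strand[1], "-")
  expect_identical(h2$s_start[1], n - h$s_end[1] + 1L)
  expect_identical(h2$s_end[1], n - h$s_start[1] + 1L)
  expect_identical(h2$q_start[1], h$q_start[1])
  expect_equal(h2$score[1], h$score[1])

  # random genome with no planted gene: stringent threshold, no hits
  gr <- Biostrings::DNAStringSet(c(sc1 = randomDna(3000, 0.42, seed = 33)))
  h3 <- translatedSearch(prot, gr, sp, maxEvalue = 1e-8)
  expect_identical(nrow(h3), 0L)
})

test_that("tabular hit files round-trip with strand normalization", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("q1", "s1", "95.0", "67", "3", "0", "1", "67",
                     "300", "100", "1e-20", "120.5"), collapse = "\t"), tf)
  h <- parseBlastTabular(tf)
  expect_identical(h$s_start, 100L)
  expect_identical(h$s_end, 300L)
  expect_identical(h$strand, "-")
  expect_identical(h$q_start, 1L)
  expect_identical(hitProvenance(h), "blast")

  # empty file -> empty list
  writeLines(character(0), tf)
  expect_identical(nrow(parseBlastTabular(tf)), 0L)

  # malformed input is reported with a line number
  writeLines("q1\ts1\tonly-three", tf)
  expect_error(parseBlastTabular(tf), "12")
  writeLines(paste(c("q1", "s1", "95.0", "67", "3", "0", "one", "67",
                     "300", "100", "1e-20", "120.5"), collapse = "\t"), tf)
  expect_error(parseBlastTabular(tf), "non-numeric")

  # round trip through write/parse preserves coordinates and statistics
  set.seed(5)
  h0 <- randomHits(20)
  writeBlastTabular(h0, tf)
  h1 <- parseBlastTabular(tf)
  expect_identical(h1$s_start, h0$s_start)
  expect_identical(h1$s_end, h0$s_end)
  expect_identical(h1$strand, h0$strand)
  expect_identical(h1$q_start, h0$q_start)
  expect_equal(h1$evalue, h0$evalue)
})
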