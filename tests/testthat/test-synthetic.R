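test_that("reverse translation round-trips through frame +1", {
  nt <- reverseTranslate("MA*", "first_codon")
  expect_identical(nchar(nt), 9L)
  expect_identical(sixFrameTranslate(nt)[[1]]$protein, "MA*")
  expect_error(reverseTranslate("MXA"), "ambiguous")
  # reproducible under a fixed seed
  a <- reverseTranslate("MKVLAHE", "random_synonymous", seed = 5)
  b <- reverseTranslate("MKVLAHE", "random_synonymous", seed = 5)
  expect_identical(a, b)
  # round trip for random proteins
  set.seed(50)
  for (i in 1:25) {
    p <- randomAA(sample(5:80, 1))
    nt <- reverseTranslate(p, "random_synonymous", seed = i)
    expect_identical(sixFrameTranslate(nt)[[1]]$protein, p)
  }
})

test_that("mutation is seeded, rate-faithful and identity at zero", {
  s <- randomDna(1000, 0.42, seed = 60)
  expect_identical(mutateSeq(s, 0, 0, seed = 1), s)
  expect_identical(mutateSeq(s, 0.2, 0.01, seed = 2),
                   mutateSeq(s, 0.2, 0.01, seed = 2))
  # mean substitutions across seeded replicates within 4 sigma of
  # Binomial(n, d)
  d <- 0.1; n <- 1000L; reps <- 200L
  subs <- vapply(seq_len(reps), function(i) {
    m <- mutateSeq(s, d, 0, seed = 1000 + i)
    sum(strsplit(m, "")[[1]] != strsplit(s, "")[[1]])
  }, numeric(1))
  sigma <- sqrt(n * d * (1 - d) / reps)
  expect_lt(abs(mean(subs) - n * d), 4 * sigma)
})

test_that("panel simulation plants a consistent, recoverable truth", {
  p <- fixtureProteins()
  pat <- c(a = "target_present", b = "target_absent", c = "split_flanks")
  sim <- simulatePanel(p$flank5, p$target, p$decoy, p$flank3, pat,
                       divergence = 0, indelRate = 0, seed = 9)
  truth <- sim$truth
  # truth coordinates extract to the planted genes: translating the
  # planted target recovers the source protein at divergence 0
  tr <- truth[truth$species_id == "a" & truth$feature == "target", ]
  g <- sim$genomes[["a"]]
  gene <- Biostrings::subseq(g[[tr$scaffold_id]], tr$start, tr$end)
  expect_identical(as.character(Biostrings::translate(gene)), p$target)
  # the decoy is planted in every species
  expect_identical(sum(truth$feature == "decoy"), 3L)
  # split_flanks puts flank3 on its own scaffold
  f3 <- truth[truth$species_id == "c" & truth$feature == "flank3", ]
  f5 <- truth[truth$species_id == "c" & truth$feature == "flank5", ]
  expect_false(f3$scaffold_id == f5$scaffold_id)
  # zero-divergence screening recovers the pattern exactly
  res <- screenPanel(sim$genomes, p$target, p$decoy, p$flank5, p$flank3,
                     lbd = p$lbd, dbd = p$dbd, withSynteny = FALSE)
  got <- setNames(res$calls$status, res$calls$species_id)
  expect_identical(got[c("a", "b", "c")],
                   c(a = "present", b = "absent", c = "present"))
  # determinism
  sim2 <- simulatePanel(p$flank5, p$target, p$decoy, p$flank3, pat,
                        divergence = 0, indelRate = 0, seed = 9)
  expect_identical(as.character(sim2$genomes[["a"]]),
                   as.character(sim$genomes[["a"]]))
  # scaffold too short is rejected with the required minimum
  expect_error(simulatePanel(p$flank5, p$target, p$decoy, p$flank3, pat,
                             scaffoldLength = 100L, seed = 1),
               "need >=")
})

test_that("truth tables round-trip losslessly", {
  p <- fixtureProteins()
  sim <- simulatePanel(p$flank5, p$target, p$decoy, p$flank3,
                       c(a = "target_present"), divergence = 0.05,
                       indelRate = 0, seed = 3)
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeTruthTable(sim$truth, tf)
  back <- readTruthTable(tf)
  expect_identical(back$start, sim$truth$start)
  expect_identical(back$feature, sim$truth$feature)
  expect_identical(back$scaffold_id, sim$truth$scaffold_id)
})

test_that("promoter simulation plants exactly what it records", {
  sim <- simulatePromoter(length = 3000L,
                          planted = data.frame(
                            kind = c("XRE", "DR", "IR"),
                            position = c(100L, 500L, 900L),
                            spacer = c(0L, 4L, 6L),
                            strand = "+"),
                          seed = 77)
  expect_identical(nchar(sim$seq), 3000L)
  expect_identical(nrow(sim$truth), 3L)
  # the planted word sits at the recorded coordinates
  for (i in seq_len(3)) {
    tr <- sim$truth[i, ]
    expect_identical(substr(sim$seq, tr$start, tr$end), tr$word)
  }
  # an exact planted XRE is found by the scanner at its position
  xre <- sim$truth[sim$truth$kind == "XRE", ]
  hits <- scanConsensus(sim$seq, orientations = "forward")
  expect_true(xre$start %in% hits$position)
  # zero plantings give an empty truth table
  sim0 <- simulatePromoter(length = 500L, seed = 5)
  expect_identical(nrow(sim0$truth), 0L)
  # overlapping plantings are rejected
  expect_error(simulatePromoter(length = 1000L,
                                planted = data.frame(
                                  kind = c("DR", "DR"),
                                  position = c(100L, 105L),
                                  spacer = c(4L, 4L), strand = "+"),
                                seed = 1),
               "overlap")
})

test_that("promoter windows extract with strand orientation and clipping", {
  g <- Biostrings::DNAStringSet(c(chr = randomDna(30000, 0.42, seed = 88)))
  plus <- data.frame(gene_id = "g", species_id = "s", scaffold_id = "chr",
                     start = 20001L, end = 21000L, strand = "+",
                     stringsAsFactors = FALSE)
  pr <- extractPromoter(g, plus, window = 13000L)
  expect_identical(length(pr), 13000L)
  expect_identical(as.character(pr),
                   as.character(Biostrings::subseq(g[["chr"]], 7001, 20000)))
  # minus-strand locus (descending-coordinate notation in annotation
  # tables): promoter is the reverse complement of the region upstream
  # in gene orientation
  minus <- plus; minus$strand <- "-"; minus$start <- 5000L; minus$end <- 6000L
  prM <- extractPromoter(g, minus, window = 13000L)
  expect_identical(length(prM), 13000L)
  expect_identical(as.character(prM),
                   as.character(Biostrings::reverseComplement(
                     Biostrings::subseq(g[["chr"]], 6001, 19000))))
  # clipping at the scaffold edge
  near <- plus; near$start <- 501L
  expect_warning(prC <- extractPromoter(g, near, window = 13000L),
                 "clipped")
  expect_identical(length(prC), 500L)
  expect_error(extractPromoter(g, within(plus, scaffold_id <- "nope")),
               "unknown scaffold")
})
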