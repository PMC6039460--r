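# Independent brute-force oracles, deliberately naive and separate from
# the package's implementation paths.

AA20_TEST <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
               "K", "M", "F", "P", "S", "T", "W", "Y", "V")

randomAA <- function(n) paste(sample(AA20_TEST, n, replace = TRUE),
                              collapse = "")

# per-position membership counter for coverage vectors
bruteCoverage <- function(hits, queryLength) {
  vapply(seq_len(queryLength), function(i)
    sum(hits$q_start <= i & hits$q_end >= i), integer(1))
}

# window-by-window degenerate motif scan against the expanded word set
bruteScan <- function(seq, pattern, orientation) {
  words <- expandIupac(pattern)
  w <- nchar(pattern)
  n <- nchar(seq)
  if (w > n) return(integer(0))
  revStr <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  compStr <- function(s) chartr("ACGTN", "TGCAN", s)
  t <- switch(orientation,
              forward = seq,
              reverse = revStr(seq),
              complement = compStr(seq),
              reverse_complement = compStr(revStr(seq)))
  win <- substring(t, seq_len(n - w + 1L), seq_len(n - w + 1L) + w - 1L)
  i <- which(win %in% words)
  if (orientation %in% c("reverse", "reverse_complement"))
    sort(n - i - w + 2L) else i
}

# random hit table over a toy genome, for filter/coverage properties
randomHits <- function(nHits, queryLength = 50L,
                       scaffolds = c("s1", "s2"), queryId = "q") {
  if (nHits == 0L) return(emptyHits())
  qs <- sample.int(queryLength, nHits, replace = TRUE)
  qe <- pmin(queryLength, qs + sample.int(20L, nHits, replace = TRUE))
  ss <- sample.int(5000L, nHits, replace = TRUE)
  se <- ss + 3L * (qe - qs + 1L) - 1L
  h <- data.frame(query_id = queryId,
                  subject_id = sample(scaffolds, nHits, replace = TRUE),
                  q_start = qs, q_end = qe, s_start = ss, s_end = se,
                  strand = sample(c("+", "-"), nHits, replace = TRUE),
                  frame = 1L, score = runif(nHits, 30, 200),
                  bitscore = 0, evalue = 10^runif(nHits, -40, -6),
                  stringsAsFactors = FALSE)
  attr(h, "provenance") <- "internal"
  h
}

mkLocus <- function(scaffold, start, end, gene = "g", species = "sp") {
  data.frame(gene_id = gene, species_id = species, scaffold_id = scaffold,
             start = as.integer(start), end = as.integer(end),
             strand = "+", source = "user_table",
             score = NA_real_, stringsAsFactors = FALSE)
}

# shared small protein set for planted-gene fixtures
fixtureProteins <- function() {
  list(target = randomProtein(200, seed = 101),
       decoy = paralogProtein(randomProtein(200, seed = 101), 0.2,
                              seed = 102),
       flank5 = randomProtein(150, seed = 103),
       flank3 = randomProtein(150, seed = 104),
       lbd = c(96L, 200L), dbd = c(1L, 66L))
}
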