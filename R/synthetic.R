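AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")

#' Random background DNA
#'
#' I.i.d. bases at the requested GC content. All generators in this
#' module are pure functions of their inputs and seed; the seed is
#' mandatory so there is no silent nondeterminism.
#'
#' @param n length.
#' @param gc GC content in (0, 1).
#' @param seed integer seed.
#' @return character DNA sequence.
#' @export
randomDna <- function(n, gc = 0.42, seed) {
  stopifnot(gc > 0, gc < 1)
  set.seed(seed)
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Random protein and diverged paralog
#'
#' \code{randomProtein} draws residues uniformly from the 20 amino
#' acids; \code{paralogProtein} substitutes each residue with the given
#' probability to a uniformly chosen different residue, emulating a
#' paralog at a controlled amino-acid distance (e.g. a decoy receptor in
#' the same subfamily as the target).
#'
#' @param n protein length.
#' @param seed integer seed.
#' @return character protein sequence.
#' @export
randomProtein <- function(n, seed) {
  set.seed(seed)
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

#' @rdname randomProtein
#' @param protein source protein (character).
#' @param divergence per-residue substitution probability.
#' @export
paralogProtein <- function(protein, divergence, seed) {
  set.seed(seed)
  ch <- strsplit(protein, "")[[1]]
  hit <- runif(length(ch)) < divergence
  for (i in which(hit & ch %in% AA20))
    ch[i] <- sample(setdiff(AA20, ch[i]), 1)
  paste(ch, collapse = "")
}

#' Reverse-translate a protein into a coding nucleotide sequence
#'
#' The frame +1 translation of the output equals the input protein
#' exactly. \code{*} maps to a stop codon. \code{X} is rejected as
#' ambiguous.
#'
#' @param protein character protein sequence (20 amino acids plus
#'   \code{*}).
#' @param codonPolicy \code{"first_codon"} (alphabetically first codon of
#'   each residue; deterministic) or \code{"random_synonymous"}.
#' @param seed integer seed (required for \code{random_synonymous}).
#' @return character nucleotide sequence.
#' @export
reverseTranslate <- function(protein,
                             codonPolicy = c("first_codon",
                                             "random_synonymous"),
                             seed = NULL) {
  codonPolicy <- match.arg(codonPolicy)
  ch <- strsplit(protein, "")[[1]]
  if (any(ch == "X")) stop("residue X is ambiguous and cannot be reverse-translated")
  gc <- Biostrings::GENETIC_CODE
  byAA <- split(names(gc), unname(gc))
  bad <- setdiff(ch, names(byAA))
  if (length(bad)) stop("invalid residue(s): ", paste(unique(bad), collapse = ","))
  if (codonPolicy == "first_codon") {
    codons <- vapply(ch, function(a) sort(byAA[[a]])[1], character(1))
  } else {
    if (is.null(seed)) stop("seed required for random_synonymous")
    set.seed(seed)
    codons <- vapply(ch, function(a) {
      cs <- byAA[[a]]
      cs[sample.int(length(cs), 1)]
    }, character(1))
  }
  paste(codons, collapse = "")
}

#' Mutate a nucleotide sequence
#'
#' Each site is substituted independently with probability
#' \code{divergence} to a uniformly chosen different base (no
#' transition/transversion bias -- a deliberate simplification that
#' keeps the Binomial oracle exact). Indels initiate per site with
#' probability \code{indelRate}; each is an insertion or deletion with
#' equal probability and geometric length (p = 0.5). Fixed seed, fixed
#' output.
#'
#' @param seq character DNA sequence.
#' @param divergence per-site substitution probability in [0, 0.5).
#' @param indelRate per-site indel initiation probability (>= 0).
#' @param seed integer seed.
#' @return character DNA sequence.
#' @export
mutateSeq <- function(seq, divergence, indelRate = 0, seed) {
  stopifnot(divergence >= 0, divergence < 0.5, indelRate >= 0)
  set.seed(seed)
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  if (n == 0L) return("")
  sub <- which(runif(n) < divergence & ch %in% DNA_BASES)
  for (i in sub) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1)
  if (indelRate > 0) {
    ev <- which(runif(n) < indelRate)
    if (length(ev)) {
      pieces <- as.list(ch)
      for (i in ev) {
        len <- rgeom(1, 0.5) + 1L
        if (runif(1) < 0.5) {
          ins <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
          pieces[[i]] <- paste0(ins, pieces[[i]])
        } else {
          for (j in i:min(n, i + len - 1L)) pieces[[j]] <- ""
        }
      }
      return(paste(unlist(pieces), collapse = ""))
    }
  }
  paste(ch, collapse = "")
}

plantGene <- function(background, gene, at) {
  # replace background bases starting at `at` with the gene sequence
  stopifnot(at + nchar(gene) - 1L <= nchar(background))
  paste0(substr(background, 1L, at - 1L), gene,
         substr(background, at + nchar(gene), nchar(background)))
}

#' Simulate a genome panel with planted genes in controlled synteny
#'
#' For every species, plants mutationally diverged copies of four coding
#' genes into background scaffolds: the two flanks in order (with the
#' target between them iff the species' pattern is
#' \code{target_present}), and the decoy paralog on its own scaffold in
#' every species, so the decoy filter is always exercised.
#' \code{split_flanks} places flank5 (plus the target) and flank3 on
#' different scaffolds, the arrangement a fragmented assembly produces.
#' All genes are planted on the plus strand; planted coordinates, the
#' pattern and parameters are recorded in the truth table.
#'
#' @param flank5,target,decoy,flank3 character protein sequences.
#' @param pattern named character vector, species id ->
#'   \code{"target_present"} / \code{"target_absent"} /
#'   \code{"split_flanks"}.
#' @param divergence per-nucleotide substitution probability in
#'   [0, 0.5).
#' @param indelRate per-site indel initiation probability.
#' @param scaffoldLength length of the main scaffold; must fit the
#'   planted block (validated, with the required minimum reported).
#' @param gcContent background GC content.
#' @param seed integer seed (mandatory).
#' @return list with \code{genomes} (named list of named
#'   \code{DNAStringSet}) and \code{truth} (data.frame: species_id,
#'   feature, scaffold_id, start, end, strand, pattern).
#' @export
simulatePanel <- function(flank5, target, decoy, flank3, pattern,
                          divergence = 0.15, indelRate = 0.001,
                          scaffoldLength = 6000L, gcContent = 0.42,
                          seed) {
  margin <- 400L; gap <- 300L
  lens <- vapply(list(flank5, target, flank3), nchar, integer(1)) * 3L
  need <- 2L * margin + 2L * gap + sum(lens)
  if (scaffoldLength < need)
    stop("scaffoldLength too short for the planted block; need >= ", need)
  genomes <- list(); truthRows <- list()
  proteins <- list(flank5 = flank5, target = target, decoy = decoy,
                   flank3 = flank3)
  for (si in seq_along(pattern)) {
    sp <- names(pattern)[si]
    pat <- pattern[[si]]
    spSeed <- seed + 1000L * si
    genes <- lapply(seq_along(proteins), function(k)
      mutateSeq(reverseTranslate(proteins[[k]], "first_codon"),
                divergence, indelRate, spSeed + k))
    names(genes) <- names(proteins)
    sc1 <- randomDna(scaffoldLength, gcContent, spSeed + 11L)
    scSplit <- randomDna(margin * 2L + nchar(genes$flank3), gcContent,
                         spSeed + 12L)
    scDecoy <- randomDna(margin * 2L + nchar(genes$decoy), gcContent,
                         spSeed + 13L)
    loci <- list()
    pos <- margin
    sc1seq <- plantGene(sc1, genes$flank5, pos)
    loci$flank5 <- c("sc1", pos, pos + nchar(genes$flank5) - 1L)
    pos <- pos + nchar(genes$flank5) + gap
    if (pat == "target_present" || pat == "split_flanks") {
      if (pat == "target_present" || TRUE) {
        # split_flanks keeps flank5 + target together (the hake-like case)
      }
      sc1seq <- plantGene(sc1seq, genes$target, pos)
      loci$target <- c("sc1", pos, pos + nchar(genes$target) - 1L)
      pos <- pos + nchar(genes$target) + gap
    }
    if (pat == "split_flanks") {
      scSplit <- plantGene(scSplit, genes$flank3, margin)
      loci$flank3 <- c("sc_split", margin,
                       margin + nchar(genes$flank3) - 1L)
    } else {
      sc1seq <- plantGene(sc1seq, genes$flank3, pos)
      loci$flank3 <- c("sc1", pos, pos + nchar(genes$flank3) - 1L)
    }
    scDecoy <- plantGene(scDecoy, genes$decoy, margin)
    loci$decoy <- c("sc_decoy", margin, margin + nchar(genes$decoy) - 1L)
    g <- Biostrings::DNAStringSet(c(sc1 = sc1seq, sc_decoy = scDecoy))
    if (pat == "split_flanks")
      g <- c(g, Biostrings::DNAStringSet(c(sc_split = scSplit)))
    names(g) <- paste0(sp, "_", names(g))
    genomes[[sp]] <- g
    for (fn in names(loci))
      truthRows[[length(truthRows) + 1L]] <- data.frame(
        species_id = sp, feature = fn,
        scaffold_id = paste0(sp, "_", loci[[fn]][1]),
        start = as.integer(loci[[fn]][2]), end = as.integer(loci[[fn]][3]),
        strand = "+", pattern = pat, stringsAsFactors = FALSE)
  }
  list(genomes = genomes, truth = do.call(rbind, truthRows))
}

#' Simulate a promoter with planted response elements
#'
#' Background i.i.d. at the requested GC content; XRE plantings are
#' words drawn uniformly from the expanded consensus, DR/IR/ER plantings
#' are consensus half-sites in the corresponding arrangement with the
#' stated spacer (spacer bases drawn from the background). Minus-strand
#' plantings insert the reverse complement of the element. Overlapping
#' plantings are an error.
#'
#' @param length promoter length (default 13000).
#' @param gcContent background GC content.
#' @param planted data.frame with columns kind (\code{XRE}/\code{DR}/
#'   \code{IR}/\code{ER}), position (1-based start; NA for random
#'   non-overlapping placement), spacer (ignored for XRE), strand.
#' @param pattern degenerate XRE consensus.
#' @param pwm a [HalfSitePWM-class] whose consensus forms the half-sites.
#' @param seed integer seed (mandatory).
#' @param sequenceId id used in the truth table.
#' @return list with \code{seq} (character) and \code{truth}
#'   (data.frame: sequence_id, kind, start, end, spacer, strand, word).
#' @export
simulatePromoter <- function(length = 13000L, gcContent = 0.42,
                             planted = NULL, pattern = "KNGCGTGM",
                             pwm = halfSitePWM(), seed,
                             sequenceId = "promoter") {
  bg <- randomDna(length, gcContent, seed)
  if (is.null(planted) || !nrow(planted))
    return(list(seq = bg, truth = data.frame(
      sequence_id = character(), kind = character(), start = integer(),
      end = integer(), spacer = integer(), strand = character(),
      word = character(), stringsAsFactors = FALSE)))
  set.seed(seed + 1L)
  words <- expandIupac(pattern)
  hs <- pwmConsensus(pwm)
  rcHs <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(hs)))
  mkWord <- function(kind, spacer) {
    spc <- if (spacer > 0L)
      paste(sample(DNA_BASES, spacer, replace = TRUE,
                   prob = c((1 - gcContent) / 2, gcContent / 2,
                            gcContent / 2, (1 - gcContent) / 2)),
            collapse = "") else ""
    switch(kind,
           XRE = sample(words, 1),
           DR = paste0(hs, spc, hs),
           IR = paste0(hs, spc, rcHs),
           ER = paste0(rcHs, spc, hs))
  }
  occupied <- matrix(integer(0), ncol = 2)
  rows <- list(); seq <- bg
  for (i in seq_len(nrow(planted))) {
    kind <- planted$kind[i]
    spacer <- if (kind == "XRE") 0L else as.integer(planted$spacer[i])
    strand <- if ("strand" %in% names(planted)) planted$strand[i] else "+"
    word <- mkWord(kind, spacer)
    if (strand == "-")
      word <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(word)))
    wlen <- nchar(word)
    posGiven <- planted$position[i]
    if (is.na(posGiven)) {
      for (try in 1:1000) {
        cand <- sample.int(length - wlen + 1L, 1)
        if (!any(cand <= occupied[, 2] & cand + wlen - 1L >= occupied[, 1])) {
          posGiven <- cand; break
        }
      }
      if (is.na(posGiven)) stop("could not place feature without overlap")
    }
    pos <- as.integer(posGiven)
    if (pos < 1L || pos + wlen - 1L > length)
      stop("planted feature out of bounds")
    if (any(pos <= occupied[, 2] & pos + wlen - 1L >= occupied[, 1]))
      stop("planted features overlap")
    occupied <- rbind(occupied, c(pos, pos + wlen - 1L))
    seq <- plantGene(seq, word, pos)
    rows[[i]] <- data.frame(sequence_id = sequenceId, kind = kind,
                            start = pos, end = pos + wlen - 1L,
                            spacer = spacer, strand = strand, word = word,
                            stringsAsFactors = FALSE)
  }
  list(seq = seq, truth = do.call(rbind, rows))
}

#' Read / write truth tables
#'
#' Truth tables are plain TSVs with a single \code{#}-prefixed header
#' line; round-tripping is lossless.
#'
#' @param truth a truth data.frame.
#' @param path file path.
#' @export
writeTruthTable <- function(truth, path) {
  con <- file(path, "w")
  writeLines(paste0("#", paste(names(truth), collapse = "\t")), con)
  write.table(truth, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname writeTruthTable
#' @export
readTruthTable <- function(path) {
  lines <- readLines(path)
  cols <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  body <- lines[-1]
  tab <- as.data.frame(do.call(rbind, strsplit(body, "\t", fixed = TRUE)),
                       stringsAsFactors = FALSE)
  names(tab) <- cols
  for (cc in intersect(c("start", "end", "spacer"), cols))
    tab[[cc]] <- as.integer(tab[[cc]])
  tab
}
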