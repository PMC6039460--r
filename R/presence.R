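#' Build a per-residue coverage vector from hits
#'
#' \code{counts[i]} = number of hits whose query interval contains residue
#' \code{i}. Query intervals reaching outside \code{[1, queryLength]} are
#' clipped with a warning, not rejected.
#'
#' @param hits hit data.frame sharing one \code{query_id}.
#' @param queryLength length of the query protein (> 0).
#' @return a [CoverageVector-class].
#' @examples
#' h <- emptyHits()
#' coverageCounts(buildCoverageVector(h, 5))  # all zero
#' @export
buildCoverageVector <- function(hits, queryLength) {
  stopifnot(queryLength > 0)
  qid <- unique(hits$query_id)
  if (length(qid) > 1L)
    stop("hits mix query ids: ", paste(qid, collapse = ", "))
  if (length(qid) == 0L) qid <- "query"
  counts <- integer(queryLength)
  if (nrow(hits)) {
    s <- pmax(hits$q_start, 1L)
    e <- pmin(hits$q_end, queryLength)
    if (any(hits$q_start < 1L | hits$q_end > queryLength))
      warning("query interval(s) clipped to [1, ", queryLength, "]")
    keep <- s <= e
    # difference array: O(hits + length)
    d <- integer(queryLength + 1L)
    for (k in which(keep)) {
      d[s[k]] <- d[s[k]] + 1L
      d[e[k] + 1L] <- d[e[k] + 1L] - 1L
    }
    counts <- cumsum(d[seq_len(queryLength)])
  }
  new("CoverageVector", queryId = qid, counts = as.integer(counts))
}

#' Remove target hits out-competed by a decoy paralog
#'
#' A target hit is removed iff some decoy hit on the same scaffold (and
#' same strand, when required) overlaps it on subject nucleotide
#' coordinates by at least \code{overlapFraction} of the shorter interval
#' AND has a strictly lower e-value. This implements subject-side
#' competition: the decoy must claim the same genomic segment, so true
#' target loci in species carrying both genes are not erased. E-values
#' are only compared within one provenance (engine).
#'
#' @param targetHits,decoyHits hit data.frames over the same genome with
#'   the same provenance tag.
#' @param overlapFraction minimum overlap as a fraction of the shorter
#'   interval, in (0, 1] (default 0.5).
#' @param sameStrand require decoy and target hit on the same strand
#'   (default TRUE).
#' @param tiePolicy \code{"keep"} (default: equal e-values keep the
#'   target, "lower" is read strictly) or \code{"drop"}.
#' @return a list with \code{retained} (input order preserved) and
#'   \code{removed} (with a \code{reason} column naming the decoy hit).
#' @export
decoyFilter <- function(targetHits, decoyHits, overlapFraction = 0.5,
                        sameStrand = TRUE,
                        tiePolicy = c("keep", "drop")) {
  tiePolicy <- match.arg(tiePolicy)
  if (overlapFraction <= 0 || overlapFraction > 1)
    stop("overlapFraction must be in (0, 1]")
  if (nrow(targetHits) && nrow(decoyHits) &&
      !identical(hitProvenance(targetHits), hitProvenance(decoyHits)))
    stop("mixed e-value provenance: statistics are not comparable")
  drop <- logical(nrow(targetHits))
  reason <- character(nrow(targetHits))
  for (i in seq_len(nrow(targetHits))) {
    t <- targetHits[i, ]
    cand <- decoyHits[decoyHits$subject_id == t$subject_id, , drop = FALSE]
    if (sameStrand && nrow(cand))
      cand <- cand[cand$strand == t$strand, , drop = FALSE]
    for (j in seq_len(nrow(cand))) {
      d <- cand[j, ]
      ov <- min(t$s_end, d$s_end) - max(t$s_start, d$s_start) + 1L
      if (ov <= 0L) next
      shorter <- min(t$s_end - t$s_start, d$s_end - d$s_start) + 1L
      if (ov / shorter < overlapFraction) next
      beats <- d$evalue < t$evalue ||
        (tiePolicy == "drop" && d$evalue == t$evalue)
      if (beats) {
        drop[i] <- TRUE
        reason[i] <- sprintf("decoy %s:%d-%d e=%.3g",
                             d$subject_id, d$s_start, d$s_end, d$evalue)
        break
      }
    }
  }
  removed <- targetHits[drop, , drop = FALSE]
  if (nrow(removed)) removed$reason <- reason[drop]
  retained <- targetHits[!drop, , drop = FALSE]
  attr(retained, "provenance") <- hitProvenance(targetHits)
  list(retained = retained, removed = removed)
}

#' Call gene presence from domain coverage
#'
#' Presence is anchored on the ligand-binding domain (LBD): the
#' DNA-binding domain cross-matches between receptor families, so
#' DBD-only coverage is reported as \code{ambiguous} rather than
#' \code{present}. A gene is \code{present} when the fraction of LBD
#' residues covered by at least one hit (with e-value at most
#' \code{maxEvalue}) reaches \code{minLbdFraction}.
#'
#' @param hits (filtered) hit data.frame for one species and one query.
#' @param queryLength query protein length.
#' @param lbd,dbd length-2 integer vectors, 1-based inclusive residue
#'   ranges of the two domains; \code{lbd} is required.
#' @param speciesId,geneId ids recorded in the call.
#' @param minLbdFraction presence threshold on LBD coverage (default 0.3).
#' @param maxEvalue hits above this e-value are ignored (default 1e-5).
#' @return one-row data.frame: species_id, gene_id, status
#'   (present/absent/ambiguous), lbd_fraction, dbd_fraction, n_hits,
#'   best_evalue (NA when no hits).
#' @export
callPresence <- function(hits, queryLength, lbd, dbd = NULL,
                         speciesId = "species", geneId = "gene",
                         minLbdFraction = 0.3, maxEvalue = 1e-5) {
  if (is.null(lbd) || length(lbd) != 2L || lbd[1] > lbd[2] ||
      lbd[1] < 1L || lbd[2] > queryLength)
    stop("a valid LBD annotation within [1, queryLength] is required")
  use <- hits[hits$evalue <= maxEvalue, , drop = FALSE]
  cv <- coverageCounts(buildCoverageVector(use, queryLength))
  covered <- cv >= 1L
  lbdFrac <- mean(covered[lbd[1]:lbd[2]])
  dbdFrac <- if (!is.null(dbd)) mean(covered[dbd[1]:dbd[2]]) else NA_real_
  status <- if (lbdFrac >= minLbdFraction) "present"
    else if (!is.na(dbdFrac) && dbdFrac >= minLbdFraction) "ambiguous"
    else "absent"
  data.frame(species_id = speciesId, gene_id = geneId, status = status,
             lbd_fraction = lbdFrac, dbd_fraction = dbdFrac,
             n_hits = nrow(use),
             best_evalue = if (nrow(use)) min(use$evalue) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Assemble coverage vectors into a tree-ordered matrix
#'
#' Rows follow the left-to-right (depth-first) leaf order of the guide
#' phylogeny, restricted to species with data. Species present in the
#' vectors but absent from the tree are an error; tree leaves without
#' vectors are skipped with a warning.
#'
#' @param vectors named list of [CoverageVector-class] (names = species).
#' @param tree a Newick string, path to a Newick file, or an
#'   \code{ape::phylo} object.
#' @return a [CoverageMatrix-class].
#' @export
assembleMatrix <- function(vectors, tree) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree)
            else ape::read.tree(text = tree)
  }
  leaves <- tree$tip.label
  sp <- names(vectors)
  missing <- setdiff(sp, leaves)
  if (length(missing))
    stop("species absent from tree: ", paste(missing, collapse = ", "))
  qids <- unique(vapply(vectors, queryId, character(1)))
  if (length(qids) != 1L)
    stop("vectors mix query ids: ", paste(qids, collapse = ", "))
  lens <- vapply(vectors, function(v) length(coverageCounts(v)), integer(1))
  if (length(unique(lens)) != 1L)
    stop("coverage vectors differ in length")
  ord <- leaves[leaves %in% sp]
  skipped <- setdiff(leaves, sp)
  if (length(skipped))
    warning("tree leaves without coverage data skipped: ",
            paste(skipped, collapse = ", "))
  m <- do.call(rbind, lapply(vectors[ord], coverageCounts))
  rownames(m) <- ord
  new("CoverageMatrix", queryId = qids, species = ord, counts = m)
}

#' Reciprocal best hits between two proteomes
#'
#' All-vs-all local alignment in both directions; a pair (a, b) is
#' reported iff b is a's unique best-scoring partner and a is b's.
#' Proteins whose best score is tied are recorded as ambiguous and form
#' no pair.
#'
#' @param proteomeA,proteomeB named \code{AAStringSet}s (unique ids).
#' @param params [ScoringParams-class].
#' @return a list with \code{pairs} (data.frame a_id, b_id, a_best_score,
#'   b_best_score) and \code{ambiguous} (character ids with tied bests).
#' @export
reciprocalBestHits <- function(proteomeA, proteomeB,
                               params = scoringParams()) {
  if (!length(proteomeA) || !length(proteomeB))
    stop("both proteomes must be non-empty")
  idsA <- names(proteomeA); idsB <- names(proteomeB)
  if (anyDuplicated(idsA) || anyDuplicated(idsB))
    stop("duplicate ids within a proteome")
  S <- matrix(0, length(idsA), length(idsB), dimnames = list(idsA, idsB))
  for (i in seq_along(idsA))
    for (j in seq_along(idsB))
      S[i, j] <- smithWaterman(as.character(proteomeA[[i]]),
                               as.character(proteomeB[[j]]), params)$score
  ambiguous <- character()
  bestB <- rep(NA_character_, length(idsA)); names(bestB) <- idsA
  for (i in seq_along(idsA)) {
    mx <- max(S[i, ])
    w <- which(S[i, ] == mx)
    if (length(w) == 1L) bestB[i] <- idsB[w] else ambiguous <- c(ambiguous, idsA[i])
  }
  bestA <- rep(NA_character_, length(idsB)); names(bestA) <- idsB
  for (j in seq_along(idsB)) {
    mx <- max(S[, j])
    w <- which(S[, j] == mx)
    if (length(w) == 1L) bestA[j] <- idsA[w] else ambiguous <- c(ambiguous, idsB[j])
  }
  rows <- list()
  for (i in seq_along(idsA)) {
    b <- bestB[idsA[i]]
    if (is.na(b)) next
    if (!is.na(bestA[b]) && bestA[b] == idsA[i])
      rows[[length(rows) + 1L]] <- data.frame(
        a_id = idsA[i], b_id = b,
        a_best_score = S[idsA[i], b], b_best_score = S[idsA[i], b],
        stringsAsFactors = FALSE)
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(a_id = character(), b_id = character(),
               a_best_score = numeric(), b_best_score = numeric())
  list(pairs = pairs, ambiguous = unique(ambiguous))
}

#' Write a coverage matrix as TSV (and read it back)
#'
#' The TSV twin of the heat map is the source of truth for tests: a
#' single \code{#}-prefixed header line (\code{#species}, then one column
#' per query residue), one row per species in matrix order.
#'
#' @param matrix a [CoverageMatrix-class].
#' @param path output path.
#' @return \code{path} invisibly; \code{readCoverageMatrix} returns the
#'   [CoverageMatrix-class].
#' @export
writeCoverageMatrix <- function(matrix, path) {
  con <- file(path, "w")
  on.exit(close(con))
  header <- paste(c("#species", paste0("r", seq_len(ncol(matrix@counts)))),
                  collapse = "\t")
  writeLines(c(paste0("#query=", matrix@queryId), header), con)
  for (i in seq_along(matrix@species))
    writeLines(paste(c(matrix@species[i], matrix@counts[i, ]),
                     collapse = "\t"), con)
  invisible(path)
}

#' @rdname writeCoverageMatrix
#' @export
readCoverageMatrix <- function(path) {
  lines <- readLines(path)
  qid <- sub("^#query=", "", lines[1])
  body <- lines[!startsWith(lines, "#")]
  parts <- strsplit(body, "\t", fixed = TRUE)
  sp <- vapply(parts, `[`, character(1), 1L)
  m <- do.call(rbind, lapply(parts, function(p) as.integer(p[-1])))
  rownames(m) <- sp
  new("CoverageMatrix", queryId = qid, species = sp, counts = m)
}

#' Render a coverage matrix as a heat map
#'
#' Writes a raster image (one row per species, one column per query
#' residue, color by count) plus the TSV twin of the matrix.
#'
#' @param matrix a [CoverageMatrix-class] (non-empty).
#' @param outPrefix path prefix; writes \code{<prefix>.png} and
#'   \code{<prefix>.tsv}.
#' @param domains optional named list of residue ranges (e.g. DBD/LBD)
#'   drawn as guides.
#' @return invisible character vector of the two file paths.
#' @export
renderHeatmap <- function(matrix, outPrefix, domains = NULL) {
  if (length(matrix@species) == 0L) stop("empty matrix")
  tsv <- paste0(outPrefix, ".tsv")
  png <- paste0(outPrefix, ".png")
  writeCoverageMatrix(matrix, tsv)
  m <- matrix@counts
  grDevices::png(png, width = 900,
                 height = 200 + 14 * nrow(m), res = 96)
  op <- graphics::par(mar = c(4, 8, 2, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  z <- t(m[rev(seq_len(nrow(m))), , drop = FALSE])
  pal <- grDevices::hcl.colors(max(2L, max(m) + 1L), "YlOrRd", rev = TRUE)
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = z,
                  col = pal, axes = FALSE, xlab = "query residue",
                  ylab = "", main = matrix@queryId)
  graphics::axis(1)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(matrix@species),
                 las = 2, cex.axis = 0.6)
  if (!is.null(domains))
    for (d in domains) graphics::abline(v = d, lty = 2)
  invisible(c(png, tsv))
}
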