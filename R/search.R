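HIT_COLUMNS <- c("query_id", "subject_id", "q_start", "q_end",
                 "s_start", "s_end", "strand", "frame",
                 "score", "bitscore", "evalue")

#' An empty hit table
#'
#' Hits are plain data.frames with columns \code{query_id},
#' \code{subject_id}, \code{q_start}/\code{q_end} (1-based inclusive
#' residue coordinates on the query protein), \code{s_start}/\code{s_end}
#' (1-based inclusive forward-strand nucleotide coordinates,
#' \code{s_start <= s_end}), \code{strand}, \code{frame} (1-3 on the
#' indicated strand, NA for parsed tabular input), \code{score},
#' \code{bitscore} and \code{evalue}. The attribute \code{provenance}
#' records which engine produced the e-values (\code{"internal"} or
#' \code{"blast"}); e-values are only comparable within one engine.
#'
#' @param provenance e-value provenance tag.
#' @return a zero-row hit data.frame.
#' @export
emptyHits <- function(provenance = "internal") {
  h <- data.frame(query_id = character(), subject_id = character(),
                  q_start = integer(), q_end = integer(),
                  s_start = integer(), s_end = integer(),
                  strand = character(), frame = integer(),
                  score = numeric(), bitscore = numeric(),
                  evalue = numeric(), stringsAsFactors = FALSE)
  attr(h, "provenance") <- provenance
  h
}

#' E-value provenance of a hit table
#' @param hits a hit data.frame.
#' @return the provenance tag (default \code{"internal"} if untagged).
#' @export
hitProvenance <- function(hits) {
  p <- attr(hits, "provenance")
  if (is.null(p)) "internal" else p
}

#' Translated search of a protein query against a genome
#'
#' Aligns the query locally against all six frame translations of every
#' scaffold and reports alignments passing the e-value threshold as hits
#' with residue coordinates mapped back to forward-strand nucleotide
#' coordinates. Multiple non-overlapping alignments per (scaffold, frame)
#' are found by iteratively masking the subject span of each accepted
#' alignment, so fragmented gene models yield multiple hits (as a
#' heuristic translated BLAST search would).
#'
#' @param query protein query (character, \code{AAString}, or a named
#'   length-1 \code{AAStringSet}).
#' @param genome a named \code{DNAStringSet} of scaffolds.
#' @param params [ScoringParams-class].
#' @param maxEvalue report hits with e-value at or below this (default
#'   1e-5; the search space is the total nucleotide length of the
#'   genome).
#' @param queryId id recorded in hits (defaults to the query's name, or
#'   \code{"query"}).
#' @param maxHitsPerFrame cap on masked re-searches per scaffold frame.
#' @return hits sorted by ascending e-value, provenance
#'   \code{"internal"}. An empty table is a valid outcome.
#' @export
translatedSearch <- function(query, genome, params = scoringParams(),
                             maxEvalue = 1e-5, queryId = NULL,
                             maxHitsPerFrame = 8L) {
  if (is(query, "AAStringSet")) {
    if (is.null(queryId)) queryId <- names(query)[1]
    query <- as.character(query[[1]])
  }
  query <- as.character(query)
  if (!nzchar(query)) stop("empty query")
  if (length(genome) == 0L) stop("empty genome")
  if (is.null(queryId)) queryId <- "query"
  if (is.null(names(genome)))
    stop("genome scaffolds must be named")
  m <- nchar(query)
  nSpace <- sum(Biostrings::width(genome))
  minScore <- scoreForEvalue(maxEvalue, m, nSpace, params)
  rows <- list()
  for (sc in names(genome)) {
    frames <- sixFrameTranslate(genome[[sc]])
    for (fr in frames) {
      if (!nzchar(fr$protein)) next
      mask <- rep(FALSE, nchar(fr$protein))
      for (iter in seq_len(maxHitsPerFrame)) {
        aln <- smithWaterman(query, fr$protein, params, maskB = mask)
        if (aln$score < minScore || length(aln$bStart) == 0L) break
        ntA <- residueToNt(aln$bStart, fr$strand, fr$frame, fr$n)
        ntB <- residueToNt(aln$bEnd, fr$strand, fr$frame, fr$n)
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = queryId, subject_id = sc,
          q_start = aln$aStart, q_end = aln$aEnd,
          s_start = min(ntA[, "start"], ntB[, "start"]),
          s_end = max(ntA[, "end"], ntB[, "end"]),
          strand = fr$strand, frame = fr$frame,
          score = aln$score,
          bitscore = bitScore(aln$score, params),
          evalue = karlinEvalue(aln$score, m, nSpace, params),
          stringsAsFactors = FALSE)
        mask[aln$bStart:aln$bEnd] <- TRUE
      }
    }
  }
  h <- if (length(rows)) do.call(rbind, rows) else emptyHits("internal")
  h <- h[order(h$evalue, h$subject_id, h$s_start), , drop = FALSE]
  rownames(h) <- NULL
  attr(h, "provenance") <- "internal"
  h
}

#' Parse 12-column tabular homology-search output
#'
#' Reads the standard tab-separated format (qseqid, sseqid, pident,
#' length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore). Subject coordinates with sstart > send are normalized to
#' \code{s_start <= s_end} with strand \code{"-"}. Lines starting with
#' \code{#} are skipped.
#'
#' @param path path to the tabular file.
#' @return a hit data.frame (provenance \code{"blast"}); \code{score} is
#'   set to the bit score (raw scores are not in the format) and
#'   \code{frame} to NA.
#' @export
parseBlastTabular <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(emptyHits("blast"))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L))
    stop("expected 12 tab-separated columns, got ", nf[nf != 12L][1],
         " at line ", which(nf != 12L)[1])
  tab <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(tab) <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")
  numcols <- c("pident", "length", "mismatch", "gapopen", "qstart",
               "qend", "sstart", "send", "evalue", "bitscore")
  for (cc in numcols) {
    v <- suppressWarnings(as.numeric(tab[[cc]]))
    if (anyNA(v))
      stop("non-numeric value in column ", cc, " at line ",
           which(is.na(v))[1])
    tab[[cc]] <- v
  }
  minus <- tab$sstart > tab$send
  h <- data.frame(
    query_id = tab$qseqid, subject_id = tab$sseqid,
    q_start = as.integer(tab$qstart), q_end = as.integer(tab$qend),
    s_start = as.integer(ifelse(minus, tab$send, tab$sstart)),
    s_end = as.integer(ifelse(minus, tab$sstart, tab$send)),
    strand = ifelse(minus, "-", "+"), frame = NA_integer_,
    score = tab$bitscore, bitscore = tab$bitscore,
    evalue = tab$evalue, stringsAsFactors = FALSE)
  attr(h, "provenance") <- "blast"
  h
}

#' Write hits as 12-column tabular output
#'
#' Inverse of [parseBlastTabular()]: subject coordinates are emitted
#' descending for minus-strand hits. Identity/mismatch/gapopen counts are
#' not tracked by the internal engine and are written as 0; the aligned
#' length column is the query interval length.
#'
#' @param hits a hit data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBlastTabular <- function(hits, path) {
  minus <- hits$strand == "-"
  out <- data.frame(
    hits$query_id, hits$subject_id,
    0, hits$q_end - hits$q_start + 1L, 0, 0,
    hits$q_start, hits$q_end,
    ifelse(minus, hits$s_end, hits$s_start),
    ifelse(minus, hits$s_start, hits$s_end),
    hits$evalue, hits$bitscore)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
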