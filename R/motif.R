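IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Expand a degenerate IUPAC consensus into exact words
#'
#' The default pattern \code{KNGCGTGM} is the extended xenobiotic
#' response element (XRE) consensus bound by the aryl hydrocarbon
#' receptor; it expands to K(2) x N(4) x M(2) = 16 exact words.
#'
#' @param pattern a string over IUPAC nucleotide codes.
#' @return character vector of all matching exact words; its length is
#'   the product of the per-code set sizes.
#' @examples
#' length(expandIupac("KNGCGTGM"))  # 16
#' @export
expandIupac <- function(pattern) {
  ch <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(ch, names(IUPAC_SETS))
  if (length(bad))
    stop("invalid IUPAC code(s): ", paste(unique(bad), collapse = ","))
  grid <- expand.grid(rev(lapply(ch, function(c) IUPAC_SETS[[c]])),
                      stringsAsFactors = FALSE)
  sort(apply(grid[, rev(seq_along(ch)), drop = FALSE], 1, paste,
             collapse = ""))
}

#' Scan a sequence for a degenerate consensus in several orientations
#'
#' Reports every window matching the pattern. Orientations transform the
#' scanned sequence: \code{forward} (as is), \code{reverse} (reversed),
#' \code{complement} (complemented in place), and
#' \code{reverse_complement}; the default set is forward/reverse/
#' complement. Positions are always reported as the 1-based start of the
#' matched window on the forward strand. Windows containing \code{N}
#' never match. With \code{dedupe} (default), hits identical in position
#' (hence in matched genomic window) across orientations are reported
#' once with all orientations comma-joined.
#'
#' @param seq a \code{DNAString} or character sequence.
#' @param pattern IUPAC consensus (default \code{"KNGCGTGM"}).
#' @param orientations non-empty subset of \code{c("forward", "reverse",
#'   "complement", "reverse_complement")}.
#' @param dedupe merge cross-orientation duplicate windows.
#' @param sequenceId id recorded in hits.
#' @param motifName motif label (default \code{"XRE"}).
#' @return data.frame: sequence_id, position, orientation, matched_word
#'   (the forward-strand window), motif_name.
#' @export
scanConsensus <- function(seq, pattern = "KNGCGTGM",
                          orientations = c("forward", "reverse",
                                           "complement"),
                          dedupe = TRUE, sequenceId = "seq",
                          motifName = "XRE") {
  allOri <- c("forward", "reverse", "complement", "reverse_complement")
  if (!length(orientations)) stop("empty orientation set")
  orientations <- match.arg(orientations, allOri, several.ok = TRUE)
  d <- Biostrings::DNAString(as.character(seq))
  n <- length(d)
  w <- nchar(pattern)
  if (w > n)
    return(data.frame(sequence_id = character(), position = integer(),
                      orientation = character(), matched_word = character(),
                      motif_name = character(), stringsAsFactors = FALSE))
  fwd <- as.character(d)
  rows <- list()
  for (ori in orientations) {
    subject <- switch(ori,
      forward = d,
      reverse = Biostrings::reverse(d),
      complement = Biostrings::complement(d),
      reverse_complement = Biostrings::reverseComplement(d))
    m <- Biostrings::matchPattern(pattern, subject, fixed = "subject")
    st <- Biostrings::start(m)
    if (!length(st)) next
    pos <- if (ori %in% c("reverse", "reverse_complement"))
      n - st - w + 2L else st
    word <- substring(fwd, pos, pos + w - 1L)
    keep <- !grepl("N", word, fixed = TRUE)
    if (!any(keep)) next
    rows[[ori]] <- data.frame(
      sequence_id = sequenceId, position = pos[keep],
      orientation = ori, matched_word = word[keep],
      motif_name = motifName, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(sequence_id = character(), position = integer(),
                      orientation = character(), matched_word = character(),
                      motif_name = character(), stringsAsFactors = FALSE))
  h <- do.call(rbind, rows)
  h <- h[order(h$position, match(h$orientation, allOri)), , drop = FALSE]
  if (dedupe && nrow(h)) {
    merged <- lapply(split(h, h$position), function(g) {
      g1 <- g[1, , drop = FALSE]
      g1$orientation <- paste(unique(g$orientation), collapse = ",")
      g1
    })
    h <- do.call(rbind, merged)
    h <- h[order(h$position), , drop = FALSE]
  }
  rownames(h) <- NULL
  h
}
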