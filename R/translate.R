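#' Six-frame translation with coordinate maps
#'
#' Translates a nucleotide sequence in frames +1, +2, +3 (forward strand)
#' and -1, -2, -3 (reverse complement), using the standard genetic code.
#' Stop codons are emitted as \code{*}; codons containing \code{N} emit
#' \code{X}. Sequences shorter than 3 yield empty frames without error.
#'
#' @param seq a \code{DNAString} or character nucleotide sequence.
#' @return a list of six entries, each a list with \code{label} (e.g.
#'   \code{"+2"}), \code{strand} (\code{"+"}/\code{"-"}), \code{frame}
#'   (1, 2, 3: offset on the indicated strand), \code{protein}
#'   (character), and \code{n} (nucleotide length) for coordinate
#'   mapping via [residueToNt()].
#' @examples
#' sixFrameTranslate("ATGGCCTGA")[[1]]$protein  # "MA*"
#' @export
sixFrameTranslate <- function(seq) {
  d <- Biostrings::DNAString(as.character(seq))
  n <- length(d)
  rc <- Biostrings::reverseComplement(d)
  out <- vector("list", 6L)
  k <- 0L
  for (strand in c("+", "-")) {
    src <- if (strand == "+") d else rc
    for (f in 1:3) {
      k <- k + 1L
      len <- n - f + 1L
      ncod <- if (len >= 3L) len %/% 3L else 0L
      prot <- if (ncod > 0L) {
        sub <- Biostrings::subseq(src, f, f + 3L * ncod - 1L)
        as.character(Biostrings::translate(sub, if.fuzzy.codon = "X"))
      } else ""
      out[[k]] <- list(label = paste0(strand, f), strand = strand,
                       frame = f, protein = prot, n = n)
    }
  }
  out
}

#' Map a translated residue back to forward-strand nucleotides
#'
#' For residue \code{r} (1-based) of the translation in the given frame,
#' returns the 1-based forward-strand coordinates of its codon.
#'
#' @param r residue index (vectorized).
#' @param strand \code{"+"} or \code{"-"}.
#' @param frame 1, 2 or 3 (offset on the indicated strand).
#' @param n nucleotide length of the source sequence.
#' @return a two-column matrix (start, end), forward-strand 1-based
#'   inclusive, start <= end.
#' @export
residueToNt <- function(r, strand, frame, n) {
  if (strand == "+") {
    s <- frame + 3L * (r - 1L)
    cbind(start = s, end = s + 2L)
  } else {
    e <- n - frame - 3L * (r - 1L) + 1L
    cbind(start = e - 2L, end = e)
  }
}

#' Map a forward-strand nucleotide to its residue in a frame
#'
#' Inverse of [residueToNt()] over positions covered by complete codons;
#' returns NA for positions outside the frame's codons.
#'
#' @param pos forward-strand nucleotide position (vectorized).
#' @inheritParams residueToNt
#' @return integer residue indices (NA where unmapped).
#' @export
ntToResidue <- function(pos, strand, frame, n) {
  if (strand == "+") {
    r <- (pos - frame) %/% 3L + 1L
    off <- pos - frame
  } else {
    r <- (n - frame + 1L - pos) %/% 3L + 1L
    off <- n - frame + 1L - pos
  }
  r[off < 0L] <- NA_integer_
  ncod <- max(0L, (n - frame + 1L) %/% 3L)
  r[!is.na(r) & r > ncod] <- NA_integer_
  r
}
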