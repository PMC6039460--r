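#' Default protein scoring matrix
#'
#' BLOSUM62 with two adjustments suited to translated searches against
#' imperfect assemblies: \code{X} (unknown residue, e.g. from N-containing
#' codons) scores 0 against everything, and \code{*} (stop codon inside a
#' reading frame) scores a flat penalty (default -4) instead of truncating
#' the frame, because low-coverage assemblies contain errors and real hits
#' are often fragmented.
#'
#' @param stopScore score of \code{*} against anything (default -4).
#' @param xScore score of \code{X} against anything (default 0).
#' @return a numeric substitution matrix.
#' @export
defaultScoringMatrix <- function(stopScore = -4, xScore = 0) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  keep <- c(AA_ALPHABET)
  m <- m[keep, keep]
  m["X", ] <- xScore; m[, "X"] <- xScore
  m["*", ] <- stopScore; m[, "*"] <- stopScore
  m
}

#' Construct scoring parameters
#'
#' @param matrix substitution matrix (default [defaultScoringMatrix()]).
#' @param matrixName identifier for the matrix.
#' @param gapOpen,gapExtend affine gap penalties; a gap of length L costs
#'   \code{gapOpen + L * gapExtend} (so 10/1 reproduces BLAST's 11/1).
#' @param lambda,K Karlin-Altschul parameters; defaults are the published
#'   gapped BLOSUM62 11/1 constants (0.267, 0.041).
#' @return a [ScoringParams-class] object.
#' @export
scoringParams <- function(matrix = defaultScoringMatrix(),
                          matrixName = "BLOSUM62",
                          gapOpen = 10, gapExtend = 1,
                          lambda = 0.267, K = 0.041) {
  new("ScoringParams", matrix = matrix, matrixName = matrixName,
      gapOpen = gapOpen, gapExtend = gapExtend, lambda = lambda, K = K)
}

encodeAA <- function(seq, matrix) {
  ch <- strsplit(as.character(seq), "")[[1]]
  code <- match(ch, rownames(matrix)) - 1L
  if (anyNA(code))
    stop("residue(s) not covered by the substitution matrix: ",
         paste(unique(ch[is.na(code)]), collapse = ","))
  code
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman-Gotoh alignment with affine gaps. Tie-breaking is
#' deterministic (first-maximum end cell; traceback prefers diagonal,
#' then gap-in-subject, then gap-in-query). Empty input yields score 0
#' and empty ranges.
#'
#' @param a,b protein sequences (character or \code{AAString}).
#' @param params a [ScoringParams-class] object.
#' @param maskB optional logical vector along \code{b}; \code{TRUE}
#'   positions are excluded from any alignment.
#' @return a list with \code{score}, 1-based inclusive \code{aStart},
#'   \code{aEnd}, \code{bStart}, \code{bEnd}, and gapped \code{alignedA},
#'   \code{alignedB} strings.
#' @examples
#' sp <- scoringParams()
#' smithWaterman("HEAGAWGHEE", "PAWHEAE", sp)$score
#' @export
smithWaterman <- function(a, b, params = scoringParams(), maskB = NULL) {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b))
    return(list(score = 0, aStart = integer(0), aEnd = integer(0),
                bStart = integer(0), bEnd = integer(0),
                alignedA = "", alignedB = ""))
  m <- params@matrix
  ca <- encodeAA(a, m); cb <- encodeAA(b, m)
  if (is.null(maskB)) maskB <- rep(FALSE, length(cb))
  r <- .sw_align(ca, cb, m, params@gapOpen, params@gapExtend, maskB)
  if (r$score <= 0)
    return(list(score = 0, aStart = integer(0), aEnd = integer(0),
                bStart = integer(0), bEnd = integer(0),
                alignedA = "", alignedB = ""))
  achr <- strsplit(a, "")[[1]]; bchr <- strsplit(b, "")[[1]]
  alnA <- ifelse(is.na(r$a_idx), "-", achr[r$a_idx])
  alnB <- ifelse(is.na(r$b_idx), "-", bchr[r$b_idx])
  list(score = r$score,
       aStart = r$a_start, aEnd = r$a_end,
       bStart = r$b_start, bEnd = r$b_end,
       alignedA = paste(alnA, collapse = ""),
       alignedB = paste(alnB, collapse = ""))
}

#' Karlin-Altschul e-value
#'
#' Expected number of chance local alignments scoring at least
#' \code{score} in a search of a query of length \code{m} against a
#' space of length \code{n}: \eqn{E = K m n e^{-\lambda S}}. Strictly
#' decreasing in score, strictly increasing in \code{m} and \code{n}.
#'
#' @param score raw alignment score.
#' @param m query length (> 0).
#' @param n search-space length (> 0).
#' @param params a [ScoringParams-class] carrying \eqn{\lambda} and K.
#' @return the e-value (non-negative real).
#' @export
karlinEvalue <- function(score, m, n, params = scoringParams()) {
  if (any(m <= 0) || any(n <= 0))
    stop("m and n must be positive")
  params@K * m * n * exp(-params@lambda * score)
}

#' Bit score of a raw alignment score
#' @inheritParams karlinEvalue
#' @return the normalized (bit) score.
#' @export
bitScore <- function(score, params = scoringParams()) {
  (params@lambda * score - log(params@K)) / log(2)
}

#' Raw score needed for a given e-value
#'
#' Inverse of [karlinEvalue()]: the smallest score whose e-value does not
#' exceed \code{evalue} in an m x n search space.
#' @param evalue target e-value.
#' @inheritParams karlinEvalue
#' @return a raw score threshold.
#' @export
scoreForEvalue <- function(evalue, m, n, params = scoringParams()) {
  (log(params@K * m * n) - log(evalue)) / params@lambda
}
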