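#' Scoring parameters for translated homology search
#'
#' Bundles the substitution matrix and affine gap penalties used by the
#' local-alignment engine together with the Karlin-Altschul parameters
#' (\eqn{\lambda}, \eqn{K}) that convert raw scores into e-values.
#' A gap of length \eqn{L} costs \code{gapOpen + L * gapExtend}, so the
#' classic BLOSUM62 11/1 scheme corresponds to \code{gapOpen = 10},
#' \code{gapExtend = 1}.
#'
#' @slot matrix numeric substitution matrix with identical row/column names
#'   covering the amino-acid alphabet in use (including \code{X} and
#'   \code{*}).
#' @slot matrixName character, identifier of the matrix.
#' @slot gapOpen,gapExtend positive numbers; \code{gapExtend <= gapOpen}.
#' @slot lambda,K positive reals, Karlin-Altschul statistics of the scoring
#'   system. Defaults are the published gapped BLOSUM62 11/1 constants.
#'
#' @seealso [scoringParams()], [karlinEvalue()], [smithWaterman()]
#' @export
setClass("ScoringParams",
  representation(matrix = "matrix", matrixName = "character",
                 gapOpen = "numeric", gapExtend = "numeric",
                 lambda = "numeric", K = "numeric"))

setValidity("ScoringParams", function(object) {
  msg <- character()
  m <- object@matrix
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    msg <- c(msg, "substitution matrix must have identical row and column names")
  if (object@gapOpen <= 0 || object@gapExtend <= 0)
    msg <- c(msg, "gap penalties must be positive")
  if (object@gapExtend > object@gapOpen)
    msg <- c(msg, "gapExtend must not exceed gapOpen")
  if (object@lambda <= 0 || object@K <= 0)
    msg <- c(msg, "lambda and K must be positive")
  if (length(msg)) msg else TRUE
})

#' Per-residue hit coverage of a query protein
#'
#' For one query protein, \code{counts[i]} is the number of homology hits
#' whose query interval overlaps residue \eqn{i}. Coverage vectors are the
#' unit of evidence for gene presence/absence: a retained gene shows broad
#' coverage across the ligand-binding domain, while cross-family noise
#' concentrates on the DNA-binding domain.
#'
#' @slot queryId character, id of the query protein.
#' @slot counts non-negative integer vector, one entry per query residue.
#' @export
setClass("CoverageVector",
  representation(queryId = "character", counts = "integer"))

setValidity("CoverageVector", function(object) {
  if (length(object@queryId) != 1L) return("queryId must be a single string")
  if (any(object@counts < 0L)) return("counts must be non-negative")
  TRUE
})

#' Tree-ordered matrix of coverage vectors
#'
#' One row per species, one column per query residue, rows ordered by the
#' left-to-right leaf order of a guide phylogeny. This is the data behind
#' a presence/absence heat map.
#'
#' @slot queryId character, shared query id of all rows.
#' @slot species character vector of species ids in tree leaf order.
#' @slot counts integer matrix, \code{length(species)} rows.
#' @export
setClass("CoverageMatrix",
  representation(queryId = "character", species = "character",
                 counts = "matrix"))

setValidity("CoverageMatrix", function(object) {
  if (nrow(object@counts) != length(object@species))
    return("one row per species required")
  if (!is.null(rownames(object@counts)) &&
      !identical(rownames(object@counts), object@species))
    return("row names must equal species order")
  TRUE
})

#' Position weight matrix for a nuclear-receptor half-site
#'
#' Probability matrix over A/C/G/T for a single binding half-site
#' (canonical consensus \code{AGGTCA}). Rows are positions and sum to 1;
#' pseudocounts keep every entry positive so log emissions are finite.
#'
#' @slot name character.
#' @slot probs numeric matrix, width x 4, columns named A,C,G,T; each row
#'   sums to 1 within 1e-9 and all entries are positive.
#' @slot pseudocount positive real used at construction.
#' @export
setClass("HalfSitePWM",
  representation(name = "character", probs = "matrix",
                 pseudocount = "numeric"))

setValidity("HalfSitePWM", function(object) {
  p <- object@probs
  if (ncol(p) != 4L || !identical(colnames(p), c("A", "C", "G", "T")))
    return("probs must have columns A,C,G,T")
  if (any(p <= 0)) return("all probabilities must be positive (pseudocounts)")
  if (any(abs(rowSums(p) - 1) > 1e-9)) return("rows must sum to 1")
  if (object@pseudocount <= 0) return("pseudocount must be positive")
  TRUE
})

#' Hidden Markov model for nuclear-receptor response elements
#'
#' A background state plus three match-state chains for the direct-repeat
#' (DR), inverted-repeat (IR) and everted-repeat (ER) arrangements of a
#' half-site, separated by a bounded spacer emitting background
#' composition. Entering each chain from the background has a small fixed
#' probability (default 0.01), so the background self-transition is
#' \eqn{1 - 3 \times entry} (0.97 at the default).
#'
#' Slots hold the flattened state graph consumed by the C-level decoders:
#' \code{states} is a data.frame with columns \code{name}, \code{chain}
#' (\code{bg}/\code{DR}/\code{IR}/\code{ER}), \code{role}
#' (\code{bg}/\code{hs1}/\code{spacer}/\code{hs2}); \code{logEmis} is
#' nstates x 4; \code{edges} has integer columns \code{from}, \code{to}
#' (1-based state indices) and numeric \code{logp}.
#'
#' @slot states data.frame describing each state.
#' @slot logEmis numeric matrix of log emission probabilities (A,C,G,T).
#' @slot edges data.frame of transitions.
#' @slot logPi numeric vector, initial log distribution.
#' @slot halfSite [HalfSitePWM-class] the chains emit.
#' @slot entryProb numeric, per-chain entry probability.
#' @slot spacerRanges named list of length-2 integer vectors (min, max).
#' @slot background numeric 4-vector of background emission probabilities.
#' @export
setClass("NRScanHMM",
  representation(states = "data.frame", logEmis = "matrix",
                 edges = "data.frame", logPi = "numeric",
                 halfSite = "HalfSitePWM", entryProb = "numeric",
                 spacerRanges = "list", background = "numeric"))

setValidity("NRScanHMM", function(object) {
  ns <- nrow(object@states)
  if (nrow(object@logEmis) != ns) return("logEmis rows must match states")
  if (length(object@logPi) != ns) return("logPi length must match states")
  if (3 * object@entryProb >= 1) return("3 * entryProb must be < 1")
  # outgoing transition mass of every state sums to 1
  p <- exp(object@edges$logp)
  mass <- tapply(p, factor(object@edges$from, levels = seq_len(ns)), sum)
  mass[is.na(mass)] <- 0
  if (any(abs(mass - 1) > 1e-9))
    return("outgoing transition probabilities must sum to 1 for every state")
  if (abs(sum(object@background) - 1) > 1e-9)
    return("background emissions must sum to 1")
  TRUE
})

#' @describeIn ScoringParams-class compact display
#' @param object a \code{ScoringParams} object
#' @export
setMethod("show", "ScoringParams", function(object) {
  cat("ScoringParams:", object@matrixName,
      sprintf("gap %g/%g, lambda=%g, K=%g\n",
              object@gapOpen, object@gapExtend, object@lambda, object@K))
})

#' @describeIn CoverageVector-class compact display
#' @param object a \code{CoverageVector} object
#' @export
setMethod("show", "CoverageVector", function(object) {
  cat(sprintf("CoverageVector for %s (%d residues, %d covered)\n",
              object@queryId, length(object@counts),
              sum(object@counts > 0L)))
})

#' @describeIn CoverageMatrix-class compact display
#' @param object a \code{CoverageMatrix} object
#' @export
setMethod("show", "CoverageMatrix", function(object) {
  cat(sprintf("CoverageMatrix for %s: %d species x %d residues\n",
              object@queryId, length(object@species), ncol(object@counts)))
})

#' @describeIn NRScanHMM-class compact display
#' @param object an \code{NRScanHMM} object
#' @export
setMethod("show", "NRScanHMM", function(object) {
  cat(sprintf(
    "NRScanHMM: %d states, entry probability %g (background self %.4g)\n",
    nrow(object@states), object@entryProb, 1 - 3 * object@entryProb))
})

#' Accessors for coverage objects
#'
#' @param x a [CoverageVector-class] or [CoverageMatrix-class]
#' @return \code{coverageCounts} returns the integer counts (vector or
#'   matrix); \code{queryId} the query id; \code{speciesOrder} the row
#'   order of a matrix.
#' @export
setGeneric("coverageCounts", function(x) standardGeneric("coverageCounts"))

#' @rdname coverageCounts
#' @export
setMethod("coverageCounts", "CoverageVector", function(x) x@counts)

#' @rdname coverageCounts
#' @export
setMethod("coverageCounts", "CoverageMatrix", function(x) x@counts)

#' @rdname coverageCounts
#' @export
setGeneric("queryId", function(x) standardGeneric("queryId"))

#' @rdname coverageCounts
#' @export
setMethod("queryId", "CoverageVector", function(x) x@queryId)

#' @rdname coverageCounts
#' @export
setMethod("queryId", "CoverageMatrix", function(x) x@queryId)

#' @rdname coverageCounts
#' @export
setGeneric("speciesOrder", function(x) standardGeneric("speciesOrder"))

#' @rdname coverageCounts
#' @export
setMethod("speciesOrder", "CoverageMatrix", function(x) x@species)
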