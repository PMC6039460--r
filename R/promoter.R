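#' Extract the upstream promoter window of a gene locus
#'
#' For a plus-strand locus, returns forward-strand bases
#' \code{[start - window, start - 1]}; for a minus-strand locus, the
#' reverse complement of \code{[end + 1, end + window]}. Either way the
#' result reads 5' to 3' relative to the gene, ending just before its
#' first base. Windows reaching past a scaffold edge are clipped with a
#' warning. The default window of 13,000 bases matches common practice
#' for regulatory-region scans of cytochrome P450 promoters.
#'
#' @param genome named \code{DNAStringSet}.
#' @param locus one-row locus data.frame (scaffold_id, start, end,
#'   strand), as from [locateGene()] or [readLocusTable()].
#' @param window upstream window size in bases (default 13000).
#' @return a \code{DNAString}; attribute \code{clipped} reports how many
#'   bases were lost to the scaffold edge.
#' @export
extractPromoter <- function(genome, locus, window = 13000L) {
  sc <- locus$scaffold_id
  if (!sc %in% names(genome))
    stop("unknown scaffold: ", sc)
  chrom <- genome[[sc]]
  n <- length(chrom)
  if (locus$strand == "+") {
    from <- locus$start - window
    to <- locus$start - 1L
    clipped <- max(0L, 1L - from)
    from <- max(1L, from)
    out <- if (to >= from) Biostrings::subseq(chrom, from, to)
           else Biostrings::DNAString("")
  } else {
    from <- locus$end + 1L
    to <- locus$end + window
    clipped <- max(0L, to - n)
    to <- min(n, to)
    out <- if (to >= from)
      Biostrings::reverseComplement(Biostrings::subseq(chrom, from, to))
      else Biostrings::DNAString("")
  }
  if (clipped > 0L)
    warning("promoter window clipped by ", clipped,
            " base(s) at the scaffold edge")
  attr(out, "clipped") <- clipped
  out
}
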