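NT_ALPHABET <- c("A", "C", "G", "T", "N")
IUPAC_EXTRA <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "U")
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V", "X", "*")

#' Read a FASTA file of nucleotide or protein sequences
#'
#' Wraps [Biostrings::readBStringSet()] with the package's alphabet
#' conventions: ids are the first whitespace-delimited token of each
#' header, sequences are normalized to uppercase, and alphabets are
#' validated. Nucleotide sequences are restricted to A/C/G/T/N; other
#' IUPAC ambiguity codes are mapped to \code{N} with a warning by default
#' (set \code{iupacToN = FALSE} to reject them instead). Protein
#' sequences may use the 20 amino acids plus \code{X} and \code{*}.
#'
#' @param path path to a FASTA file.
#' @param type \code{"auto"} (default) guesses nucleotide vs protein from
#'   composition; \code{"dna"} or \code{"protein"} force the type.
#' @param iupacToN map non-ACGTN IUPAC nucleotide codes to \code{N}
#'   (default \code{TRUE}); if \code{FALSE} such codes raise an error.
#' @return a [Biostrings::DNAStringSet] or [Biostrings::AAStringSet].
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">s1 a scaffold", "acgtACGT"), tf)
#' readFasta(tf)
#' @export
readFasta <- function(path, type = c("auto", "dna", "protein"),
                      iupacToN = TRUE) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(raw), "[ \t]+"), `[`, character(1), 1L)
  seqs <- toupper(as.character(raw))
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("record(s) with empty sequence: ", paste(ids[empty], collapse = ", "))
  if (type == "auto") {
    frac <- vapply(seqs, function(s) {
      ch <- strsplit(s, "")[[1]]
      mean(ch %in% NT_ALPHABET)
    }, numeric(1))
    type <- if (all(frac >= 0.9)) "dna" else "protein"
  }
  if (type == "dna") {
    bad <- character()
    for (i in seq_along(seqs)) {
      ch <- strsplit(seqs[i], "")[[1]]
      extra <- ch %in% IUPAC_EXTRA
      if (any(extra)) {
        if (!iupacToN)
          stop("non-ACGTN IUPAC code(s) in record ", ids[i])
        ch[extra] <- "N"
        seqs[i] <- paste(ch, collapse = "")
        bad <- c(bad, ids[i])
      }
      if (!all(ch %in% c(NT_ALPHABET, "N")))
        stop("invalid nucleotide character(s) in record ", ids[i])
    }
    if (length(bad))
      warning("ambiguity codes mapped to N in: ", paste(unique(bad), collapse = ", "))
    out <- Biostrings::DNAStringSet(seqs)
  } else {
    for (i in seq_along(seqs)) {
      ch <- strsplit(seqs[i], "")[[1]]
      if (!all(ch %in% AA_ALPHABET))
        stop("invalid amino-acid character(s) in record ", ids[i], ": ",
             paste(unique(ch[!ch %in% AA_ALPHABET]), collapse = ","))
    }
    out <- Biostrings::AAStringSet(seqs)
  }
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param x a \code{DNAStringSet} or \code{AAStringSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(x, path) {
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
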