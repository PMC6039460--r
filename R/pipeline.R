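#' Screen a genome panel for target-gene presence with synteny backup
#'
#' The full per-species pipeline: translated search with the target and
#' decoy queries, decoy-competition filtering, coverage-based presence
#' calls anchored on the ligand-binding domain, flank location and
#' synteny classification, and the reconciliation report.
#'
#' @param genomes named list (species -> named \code{DNAStringSet}).
#' @param target,decoy,flank5,flank3 character protein sequences.
#' @param lbd,dbd residue ranges of the target's domains (length-2).
#' @param params [ScoringParams-class].
#' @param minLbdFraction,maxEvalue presence thresholds (see
#'   [callPresence()]).
#' @param useDecoyFilter disable to measure the filter's effect.
#' @param withSynteny also run flank location / synteny classification
#'   (default TRUE).
#' @return list with \code{calls}, \code{verdicts}, \code{report}
#'   (data.frames; \code{verdicts}/\code{report} NULL when
#'   \code{withSynteny = FALSE}) and \code{vectors} (named list of
#'   [CoverageVector-class]).
#' @export
screenPanel <- function(genomes, target, decoy, flank5, flank3,
                        lbd, dbd = NULL, params = scoringParams(),
                        minLbdFraction = 0.3, maxEvalue = 1e-5,
                        useDecoyFilter = TRUE, withSynteny = TRUE) {
  calls <- list(); verdicts <- list(); vectors <- list()
  for (sp in names(genomes)) {
    g <- genomes[[sp]]
    tHits <- translatedSearch(target, g, params, maxEvalue,
                              queryId = "target")
    if (useDecoyFilter) {
      dHits <- translatedSearch(decoy, g, params, maxEvalue,
                                queryId = "decoy")
      tHits <- decoyFilter(tHits, dHits)$retained
    }
    calls[[sp]] <- callPresence(tHits, nchar(target), lbd = lbd,
                                dbd = dbd, speciesId = sp,
                                geneId = "target",
                                minLbdFraction = minLbdFraction,
                                maxEvalue = maxEvalue)
    vectors[[sp]] <- buildCoverageVector(tHits, nchar(target))
    if (withSynteny) {
      up <- locateGene(flank5, g, params, maxEvalue,
                       speciesId = sp, geneId = "flank5")
      dn <- locateGene(flank3, g, params, maxEvalue,
                       speciesId = sp, geneId = "flank3")
      tg <- locateGene(target, g, params, maxEvalue,
                       speciesId = sp, geneId = "target")
      verdicts[[sp]] <- assessSynteny(up, tg, dn)
    }
  }
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL
  verdicts <- if (withSynteny) do.call(rbind, verdicts) else NULL
  if (!is.null(verdicts)) rownames(verdicts) <- NULL
  report <- if (withSynteny) syntenyReport(verdicts, calls) else NULL
  list(calls = calls, verdicts = verdicts, report = report,
       vectors = vectors)
}
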