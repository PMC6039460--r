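#' Locate a gene on genome scaffolds by translated search
#'
#' Runs [translatedSearch()] and consolidates hits into a single locus:
#' hits are grouped by (scaffold, strand), sorted by subject coordinate
#' and chained greedily (a new chain starts when the gap to the previous
#' hit exceeds \code{maxGap}); the chain with the highest total score
#' wins and its span is the locus. Returns NULL when nothing passes the
#' threshold -- absence is a valid result.
#'
#' @param query protein query (see [translatedSearch()]).
#' @param genome named \code{DNAStringSet}.
#' @param params [ScoringParams-class].
#' @param maxEvalue reporting threshold.
#' @param maxGap maximum subject-coordinate gap (nt) bridged within one
#'   chain (default 5000).
#' @param speciesId,geneId ids recorded in the locus.
#' @return one-row data.frame (gene_id, species_id, scaffold_id, start,
#'   end, strand, source, score) or NULL.
#' @export
locateGene <- function(query, genome, params = scoringParams(),
                       maxEvalue = 1e-5, maxGap = 5000L,
                       speciesId = "species", geneId = "gene") {
  hits <- translatedSearch(query, genome, params, maxEvalue,
                           queryId = geneId)
  if (!nrow(hits)) return(NULL)
  best <- NULL
  for (key in unique(paste(hits$subject_id, hits$strand))) {
    g <- hits[paste(hits$subject_id, hits$strand) == key, , drop = FALSE]
    g <- g[order(g$s_start), , drop = FALSE]
    chain <- 1L
    id <- integer(nrow(g))
    id[1] <- chain
    for (i in seq_len(nrow(g))[-1]) {
      if (g$s_start[i] - max(g$s_end[seq_len(i - 1L)][id[seq_len(i - 1L)] == chain]) > maxGap)
        chain <- chain + 1L
      id[i] <- chain
    }
    for (cc in unique(id)) {
      ch <- g[id == cc, , drop = FALSE]
      sc <- sum(ch$score)
      if (is.null(best) || sc > best$score)
        best <- list(scaffold = ch$subject_id[1], strand = ch$strand[1],
                     start = min(ch$s_start), end = max(ch$s_end),
                     score = sc)
    }
  }
  data.frame(gene_id = geneId, species_id = speciesId,
             scaffold_id = best$scaffold, start = best$start,
             end = best$end, strand = best$strand,
             source = "internal_search", score = best$score,
             stringsAsFactors = FALSE)
}

#' Classify a target locus by the placement of its two flanks
#'
#' Exhaustive classification of the conserved flank5-target-flank3 block:
#' \itemize{
#'   \item both flanks on one scaffold and the target on that scaffold
#'     between the flank intervals: \code{target_present_in_block}
#'     (a target overlapping a flank interval is classified present with
#'     an \code{overlap_warning}, conservative toward presence);
#'   \item both flanks on one scaffold, target absent or elsewhere:
#'     \code{block_intact_target_absent};
#'   \item flanks on different scaffolds: \code{unresolved_split}
#'     (regardless of the target -- fragmented assemblies cannot resolve
#'     the block);
#'   \item either flank not found: \code{flank_missing}.
#' }
#' "Between" is judged on scaffold coordinates irrespective of strand and
#' flank order, since the block may be inverted in an assembly.
#'
#' @param upstream,target,downstream one-row locus data.frames as from
#'   [locateGene()] (or NULL when not found).
#' @return one-row data.frame: species_id, status, upstream_scaffold,
#'   downstream_scaffold, intervening_span (nt between the inner ends of
#'   the flank intervals when on one scaffold, else NA), overlap_warning.
#' @export
assessSynteny <- function(upstream, target, downstream) {
  sp <- unique(c(upstream$species_id, target$species_id,
                 downstream$species_id))
  if (length(sp) > 1L)
    stop("loci mix species ids: ", paste(sp, collapse = ", "))
  if (length(sp) == 0L) sp <- NA_character_
  up <- upstream; dn <- downstream
  res <- data.frame(species_id = sp, status = NA_character_,
                    upstream_scaffold = if (is.null(up)) NA_character_ else up$scaffold_id,
                    downstream_scaffold = if (is.null(dn)) NA_character_ else dn$scaffold_id,
                    intervening_span = NA_integer_,
                    overlap_warning = FALSE, stringsAsFactors = FALSE)
  if (is.null(up) || is.null(dn)) {
    res$status <- "flank_missing"
    return(res)
  }
  if (up$scaffold_id != dn$scaffold_id) {
    res$status <- "unresolved_split"
    return(res)
  }
  left <- if (up$start <= dn$start) up else dn
  right <- if (up$start <= dn$start) dn else up
  res$intervening_span <- as.integer(max(0, right$start - left$end - 1))
  if (is.null(target) || target$scaffold_id != up$scaffold_id) {
    res$status <- "block_intact_target_absent"
    return(res)
  }
  strictlyBetween <- target$start > left$end && target$end < right$start
  overlapsFlank <- (target$start <= left$end && target$end >= left$start) ||
                   (target$start <= right$end && target$end >= right$start)
  inside <- target$end > left$end && target$start < right$start
  if (strictlyBetween) {
    res$status <- "target_present_in_block"
  } else if (overlapsFlank && inside) {
    res$status <- "target_present_in_block"
    res$overlap_warning <- TRUE
  } else {
    res$status <- "block_intact_target_absent"
  }
  res
}

#' Reconcile presence calls with synteny verdicts
#'
#' One row per species: the coverage-based call, the synteny verdict and
#' an agreement flag. \code{present} agrees with
#' \code{target_present_in_block}, \code{absent} with
#' \code{block_intact_target_absent}; every other combination is
#' \code{unconfirmed}. Species with a call but no verdict get verdict
#' \code{not_assessed}.
#'
#' @param verdicts data.frame of rows from [assessSynteny()].
#' @param presenceCalls data.frame of rows from [callPresence()].
#' @param path optional TSV output path (single \code{#} header line).
#' @return the reconciliation data.frame.
#' @export
syntenyReport <- function(verdicts, presenceCalls, path = NULL) {
  rows <- lapply(seq_len(nrow(presenceCalls)), function(i) {
    call <- presenceCalls[i, ]
    v <- verdicts[verdicts$species_id == call$species_id, , drop = FALSE]
    verdict <- if (nrow(v)) v$status[1] else "not_assessed"
    agreement <- if (call$status == "present" &&
                     verdict == "target_present_in_block") "agree"
      else if (call$status == "absent" &&
               verdict == "block_intact_target_absent") "agree"
      else "unconfirmed"
    data.frame(species_id = call$species_id, presence = call$status,
               synteny = verdict, agreement = agreement,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    con <- file(path, "w")
    writeLines(paste0("#", paste(names(out), collapse = "\t")), con)
    write.table(out, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    close(con)
  }
  out
}

#' Read / write gene locus tables
#'
#' TSV with a single \code{#}-prefixed header line and columns gene_id,
#' species_id, scaffold_id, start, end, strand. User-supplied tables
#' (source \code{user_table}) can override internal search for annotated
#' genomes.
#'
#' @param path file path.
#' @return data.frame of loci.
#' @export
readLocusTable <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  header <- sub("^#", "", lines[1])
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  body <- lines[-1]
  if (!length(body))
    return(data.frame(gene_id = character(), species_id = character(),
                      scaffold_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      source = character(), stringsAsFactors = FALSE))
  tab <- as.data.frame(do.call(rbind, strsplit(body, "\t", fixed = TRUE)),
                       stringsAsFactors = FALSE)
  names(tab) <- cols
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  if (any(tab$start > tab$end)) stop("locus with start > end")
  tab$source <- "user_table"
  tab
}

#' @rdname readLocusTable
#' @param loci data.frame of loci.
#' @export
writeLocusTable <- function(loci, path) {
  cols <- c("gene_id", "species_id", "scaffold_id", "start", "end", "strand")
  con <- file(path, "w")
  writeLines(paste0("#", paste(cols, collapse = "\t")), con)
  write.table(loci[, cols], con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(path)
}
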