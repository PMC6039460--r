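DNA_BASES <- c("A", "C", "G", "T")

revcompPWM <- function(p) {
  # reverse positions, swap A<->T and C<->G columns
  q <- p[rev(seq_len(nrow(p))), c("T", "G", "C", "A"), drop = FALSE]
  colnames(q) <- DNA_BASES
  rownames(q) <- NULL
  q
}

pwmConsensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm@probs, 1, which.max)], collapse = "")
}

#' Construct a half-site position weight matrix
#'
#' Either from an explicit probability matrix, or as a sharp consensus
#' PWM: the consensus base gets probability \eqn{1 - 3\epsilon} and each
#' other base \eqn{\epsilon}, with \eqn{\epsilon} equal to the
#' pseudocount. The default consensus \code{AGGTCA} is the canonical
#' nuclear-receptor binding half-site.
#'
#' @param consensus half-site consensus (default \code{"AGGTCA"});
#'   ignored when \code{probs} is given.
#' @param probs optional width x 4 probability matrix (columns A,C,G,T).
#' @param pseudocount \eqn{\epsilon} (default 0.01).
#' @param name label for the matrix.
#' @return a [HalfSitePWM-class].
#' @export
halfSitePWM <- function(consensus = "AGGTCA", probs = NULL,
                        pseudocount = 0.01, name = consensus) {
  if (is.null(probs)) {
    ch <- strsplit(toupper(consensus), "")[[1]]
    stopifnot(all(ch %in% DNA_BASES))
    probs <- matrix(pseudocount, nrow = length(ch), ncol = 4,
                    dimnames = list(NULL, DNA_BASES))
    for (i in seq_along(ch))
      probs[i, ch[i]] <- 1 - 3 * pseudocount
  } else {
    if (is.null(colnames(probs))) colnames(probs) <- DNA_BASES
    probs <- (probs + pseudocount) / rowSums(probs + pseudocount)
  }
  new("HalfSitePWM", name = name, probs = probs, pseudocount = pseudocount)
}

#' Read a half-site PWM from a 4-column tab-separated file
#'
#' One row per position; columns A, C, G, T (header optional, \code{#}
#' comments ignored). Values may be counts or probabilities; rows are
#' normalized after adding the pseudocount.
#'
#' @param path file path.
#' @inheritParams halfSitePWM
#' @export
readHalfSitePWM <- function(path, pseudocount = 0.01, name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (grepl("[A-Za-z]", lines[1])) lines <- lines[-1]
  m <- do.call(rbind, lapply(strsplit(lines, "\t"), as.numeric))
  colnames(m) <- DNA_BASES
  halfSitePWM(probs = m, pseudocount = pseudocount, name = name)
}

#' Build the nuclear-receptor response-element HMM
#'
#' A background state plus three match-state chains for direct (DR),
#' inverted (IR) and everted (ER) repeats of the half-site:
#' \itemize{
#'   \item DR emits half-site, spacer, half-site in the same orientation;
#'   \item IR emits half-site, spacer, then the reverse-complemented PWM;
#'   \item ER emits the reverse-complemented PWM, spacer, half-site.
#' }
#' Spacer states emit background composition, with a uniform choice among
#' the allowed spacer lengths. The background enters each chain with
#' probability \code{entryProb}, so its self-transition is
#' \eqn{1 - 3 \times entryProb} (0.97 at the default 0.01).
#'
#' @param halfSite a [HalfSitePWM-class] (default sharp \code{AGGTCA}).
#' @param entryProb per-chain entry probability (< 1/3; default 0.01).
#' @param spacerRanges named list with DR, IR, ER length-2 (min, max)
#'   spacer ranges; the defaults 0-8 cover the named configurations
#'   DR3/DR4/DR5, IR6 and ER6/ER8.
#' @param background length-4 emission probabilities (A,C,G,T) of the
#'   background and spacer states.
#' @return an [NRScanHMM-class].
#' @export
buildNrHmm <- function(halfSite = halfSitePWM(), entryProb = 0.01,
                       spacerRanges = list(DR = c(0L, 8L), IR = c(0L, 8L),
                                           ER = c(0L, 8L)),
                       background = rep(0.25, 4)) {
  if (3 * entryProb >= 1) stop("entryProb must be below 1/3")
  for (r in spacerRanges)
    if (r[1] < 0L || r[1] > r[2]) stop("invalid spacer range")
  w <- nrow(halfSite@probs)
  pwm <- halfSite@probs
  rcp <- revcompPWM(pwm)
  chains <- list(DR = list(hs1 = pwm, hs2 = pwm),
                 IR = list(hs1 = pwm, hs2 = rcp),
                 ER = list(hs1 = rcp, hs2 = pwm))
  name <- "bg"; chain <- "bg"; role <- "bg"
  emis <- matrix(background, nrow = 1)
  from <- integer(); to <- integer(); p <- numeric()
  idx <- function(nm) match(nm, name)
  addState <- function(nm, ch, rl, e) {
    name <<- c(name, nm); chain <<- c(chain, ch); role <<- c(role, rl)
    emis <<- rbind(emis, e)
    length(name)
  }
  addEdge <- function(a, b, pr) {
    from <<- c(from, a); to <<- c(to, b); p <<- c(p, pr)
  }
  addEdge(1L, 1L, 1 - 3 * entryProb)
  for (cn in names(chains)) {
    rng <- as.integer(spacerRanges[[cn]])
    smin <- rng[1]; smax <- rng[2]; K <- smax - smin + 1L
    hs1 <- vapply(seq_len(w), function(i)
      addState(sprintf("%s_hs1_%d", cn, i), cn, "hs1",
               chains[[cn]]$hs1[i, ]), numeric(1))
    sps <- if (smax > 0L) vapply(seq_len(smax), function(j)
      addState(sprintf("%s_sp_%d", cn, j), cn, "spacer", background),
      numeric(1)) else integer(0)
    hs2 <- vapply(seq_len(w), function(i)
      addState(sprintf("%s_hs2_%d", cn, i), cn, "hs2",
               chains[[cn]]$hs2[i, ]), numeric(1))
    addEdge(1L, hs1[1], entryProb)
    for (i in seq_len(w - 1L)) addEdge(hs1[i], hs1[i + 1L], 1)
    # leave hs1: spacer length L uniform on {smin..smax}
    if (smin == 0L) {
      addEdge(hs1[w], hs2[1], 1 / K)
      if (smax >= 1L) addEdge(hs1[w], sps[1], 1 - 1 / K)
    } else {
      addEdge(hs1[w], sps[1], 1)
    }
    if (smax >= 1L) for (j in seq_len(smax)) {
      if (j < smin) {
        addEdge(sps[j], sps[j + 1L], 1)
      } else {
        h <- 1 / (smax - j + 1)
        addEdge(sps[j], hs2[1], h)
        if (j < smax) addEdge(sps[j], sps[j + 1L], 1 - h)
      }
    }
    for (i in seq_len(w - 1L)) addEdge(hs2[i], hs2[i + 1L], 1)
    addEdge(hs2[w], 1L, 1)
  }
  colnames(emis) <- DNA_BASES
  states <- data.frame(name = name, chain = chain, role = role,
                       stringsAsFactors = FALSE)
  edges <- data.frame(from = from, to = to, logp = log(p))
  logPi <- c(0, rep(-Inf, length(name) - 1L))
  new("NRScanHMM", states = states, logEmis = log(emis), edges = edges,
      logPi = logPi, halfSite = halfSite, entryProb = entryProb,
      spacerRanges = lapply(spacerRanges, as.integer),
      background = background)
}

encodeDNA <- function(seq) {
  ch <- strsplit(toupper(as.character(seq)), "")[[1]]
  code <- match(ch, c(DNA_BASES, "N")) - 1L
  if (anyNA(code)) stop("invalid nucleotide character in sequence")
  code
}

hmmArgs <- function(hmm, obs) {
  list(obs = obs, logEmis = hmm@logEmis,
       efrom = as.integer(hmm@edges$from - 1L),
       eto = as.integer(hmm@edges$to - 1L),
       elp = hmm@edges$logp, logPi = hmm@logPi)
}

#' Total log-likelihood of a sequence under the HMM
#'
#' Forward algorithm in log space. \code{N} bases are score-neutral
#' (emission probability 1 in every state).
#'
#' @param hmm an [NRScanHMM-class].
#' @param seq nucleotide sequence.
#' @return log probability of the sequence.
#' @export
forwardLogLik <- function(hmm, seq) {
  a <- hmmArgs(hmm, encodeDNA(seq))
  .hmm_forward(a$obs, a$logEmis, a$efrom, a$eto, a$elp, a$logPi)
}

#' Posterior chain occupancy per position
#'
#' Forward-backward decoding: for every position, the posterior
#' probability of being in the background or in each match chain. This
#' is the independent check on Viterbi site calls.
#'
#' @inheritParams forwardLogLik
#' @return an n x 4 matrix with columns bg, DR, IR, ER.
#' @export
posteriorDecode <- function(hmm, seq) {
  a <- hmmArgs(hmm, encodeDNA(seq))
  post <- .hmm_posterior(a$obs, a$logEmis, a$efrom, a$eto, a$elp, a$logPi)
  groups <- c("bg", "DR", "IR", "ER")
  out <- sapply(groups, function(g)
    rowSums(post[, hmm@states$chain == g, drop = FALSE]))
  colnames(out) <- groups
  out
}

decodeOneStrand <- function(hmm, obs, sequenceId, strand, n) {
  a <- hmmArgs(hmm, obs)
  v <- .hmm_viterbi(a$obs, a$logEmis, a$efrom, a$eto, a$elp, a$logPi)
  path <- v$path + 1L
  ch <- hmm@states$chain[path]
  role <- hmm@states$role[path]
  r <- rle(ch)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  w <- nrow(hmm@halfSite@probs)
  bgSelf <- log(1 - 3 * hmm@entryProb)
  logBgEmit <- log(hmm@background)
  rows <- list()
  for (k in which(r$values != "bg")) {
    s <- starts[k]; e <- ends[k]
    # only complete chain traversals (start of hs1 .. end of hs2)
    if (role[s] != "hs1" || role[e] != "hs2") next
    if (hmm@states$name[path[s]] != sprintf("%s_hs1_1", r$values[k])) next
    if (hmm@states$name[path[e]] != sprintf("%s_hs2_%d", r$values[k], w)) next
    spacer <- sum(role[s:e] == "spacer")
    # path log-prob over the span (emissions + internal transitions)
    lp <- 0
    for (t in s:e) {
      if (obs[t] != 4L) lp <- lp + hmm@logEmis[path[t], obs[t] + 1L]
      if (t < e) {
        eidx <- which(hmm@edges$from == path[t] & hmm@edges$to == path[t + 1L])
        lp <- lp + hmm@edges$logp[eidx[1]]
      }
    }
    span <- e - s + 1L
    bgLp <- sum(ifelse(obs[s:e] == 4L, 0, logBgEmit[obs[s:e] + 1L])) +
      (span - 1L) * bgSelf
    fs <- if (strand == "+") s else n - e + 1L
    fe <- if (strand == "+") e else n - s + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      sequence_id = sequenceId, configuration = r$values[k],
      start = fs, end = fe, spacer_length = spacer,
      log_odds = lp - bgLp, strand = strand,
      contains_n = any(obs[s:e] == 4L), stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' Viterbi scan for nuclear-receptor response elements
#'
#' Decodes the most probable state path and reports each complete
#' traversal of a match chain as one element, with its configuration
#' (DR/IR/ER), spacer length, and log-odds (path log-probability minus
#' the background log-probability over the same span). With
#' \code{bothStrands} the reverse complement is decoded too, hits are
#' mapped back to forward coordinates, and duplicate same-span
#' same-configuration hits are merged (keeping the + strand copy).
#'
#' @param hmm an [NRScanHMM-class].
#' @param seq nucleotide sequence (\code{N} allowed; spans containing N
#'   are flagged in the \code{contains_n} column).
#' @param bothStrands also decode the reverse complement (default TRUE).
#' @param sequenceId id recorded in hits.
#' @return data.frame: sequence_id, configuration, start, end,
#'   spacer_length, log_odds, strand, contains_n.
#' @export
viterbiScan <- function(hmm, seq, bothStrands = TRUE,
                        sequenceId = "seq") {
  d <- Biostrings::DNAString(as.character(seq))
  n <- length(d)
  obs <- encodeDNA(d)
  out <- decodeOneStrand(hmm, obs, sequenceId, "+", n)
  if (bothStrands) {
    obsRc <- encodeDNA(Biostrings::reverseComplement(d))
    out2 <- decodeOneStrand(hmm, obsRc, sequenceId, "-", n)
    out <- rbind(out, out2)
  }
  if (is.null(out))
    return(data.frame(sequence_id = character(), configuration = character(),
                      start = integer(), end = integer(),
                      spacer_length = integer(), log_odds = numeric(),
                      strand = character(), contains_n = logical(),
                      stringsAsFactors = FALSE))
  key <- paste(out$configuration, out$start, out$end)
  out <- out[order(out$start, match(out$strand, c("+", "-"))), , drop = FALSE]
  out <- out[!duplicated(paste(out$configuration, out$start, out$end)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize response-element composition of a promoter
#'
#' Counts XRE motif hits and DR/IR/ER element hits for one sequence and
#' reports their relative fractions. Promoters without any hit report
#' zero counts and NA fractions, flagged by \code{defined = FALSE}.
#'
#' @param motifHits data.frame from [scanConsensus()].
#' @param nrHits data.frame from [viterbiScan()].
#' @param sequenceId the sequence to summarize.
#' @return one-row data.frame: sequence_id, n_xre, n_dr, n_ir, n_er,
#'   frac_xre, frac_dr, frac_ir, frac_er, defined.
#' @export
summarizeComposition <- function(motifHits, nrHits, sequenceId) {
  mh <- motifHits[motifHits$sequence_id == sequenceId, , drop = FALSE]
  nh <- nrHits[nrHits$sequence_id == sequenceId, , drop = FALSE]
  counts <- c(XRE = nrow(mh),
              DR = sum(nh$configuration == "DR"),
              IR = sum(nh$configuration == "IR"),
              ER = sum(nh$configuration == "ER"))
  total <- sum(counts)
  fr <- if (total > 0) counts / total else rep(NA_real_, 4)
  data.frame(sequence_id = sequenceId,
             n_xre = counts[["XRE"]], n_dr = counts[["DR"]],
             n_ir = counts[["IR"]], n_er = counts[["ER"]],
             frac_xre = fr[[1]], frac_dr = fr[[2]], frac_ir = fr[[3]],
             frac_er = fr[[4]], defined = total > 0,
             stringsAsFactors = FALSE)
}
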