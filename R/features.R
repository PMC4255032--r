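#' Detect a target site duplication from insertion flanks
#'
#' Finds the longest exact string (between `minLen` and `maxLen` nt) that is
#' both a suffix of the left flank and a prefix of the right flank -- the
#' duplicated target site framing an insertion. When no duplication is
#' found the flanks are classified: `polyA_region` when either 20-nt
#' abutting window is at least 80% A (or 80% T), `AT_rich_region` when a
#' 30-nt abutting window is at least 85% A+T, otherwise `not_detected`.
#'
#' @param leftFlank,rightFlank Flank strings immediately 5' and 3' of the
#'   insertion (each should be at least `maxLen` nt; shorter flanks trigger
#'   a warning and a capped search).
#' @param minLen,maxLen TSD length bounds (defaults 2 and 25 nt).
#' @return A list: `sequence` (TSD string or `""`), `length`, `class`
#'   (one of `"TSD"`, `"polyA_region"`, `"AT_rich_region"`,
#'   `"not_detected"`).
#' @export
findTSD <- function(leftFlank, rightFlank, minLen = 2L, maxLen = 25L) {
  lf <- asSeqString(leftFlank); rf <- asSeqString(rightFlank)
  nl <- nchar(lf); nr <- nchar(rf)
  if (nl < minLen || nr < minLen) {
    warning("flank too short for TSD search")
    return(list(sequence = "", length = 0L, class = "not_detected"))
  }
  capped <- min(maxLen, nl, nr)  # shorter flanks just cap the search
  tsd <- ""
  for (L in seq(capped, minLen)) {
    suf <- substr(lf, nl - L + 1L, nl)
    if (suf == substr(rf, 1L, L)) { tsd <- suf; break }
  }
  if (nchar(tsd) >= minLen)
    return(list(sequence = tsd, length = nchar(tsd), class = "TSD"))
  frac <- function(s, letters, need) {
    if (nchar(s) < need) return(0)  # classification needs the full window
    x <- strsplit(s, "")[[1]]
    mean(x %in% letters)
  }
  l20 <- substr(lf, max(1L, nl - 19L), nl); r20 <- substr(rf, 1L, 20L)
  if (frac(l20, "A", 20L) >= 0.8 || frac(r20, "A", 20L) >= 0.8 ||
      frac(l20, "T", 20L) >= 0.8 || frac(r20, "T", 20L) >= 0.8)
    return(list(sequence = "", length = 0L, class = "polyA_region"))
  l30 <- substr(lf, max(1L, nl - 29L), nl); r30 <- substr(rf, 1L, 30L)
  if (frac(l30, c("A", "T"), 30L) >= 0.85 ||
      frac(r30, c("A", "T"), 30L) >= 0.85)
    return(list(sequence = "", length = 0L, class = "AT_rich_region"))
  list(sequence = "", length = 0L, class = "not_detected")
}

#' TSD detection around a called insertion interval
#'
#' A refined insertion interval (the gap block of a filled/empty alignment)
#' contains the inserted element *plus one copy* of the target site
#' duplication, and its placement is ambiguous wherever the sequence
#' repeats across the breakpoint (the block can slide through equal
#' characters, exactly like indel normalization). This wrapper therefore
#' explores, at every equivalent placement of the block, three TSD
#' configurations: (O) both copies outside the interval (classic
#' suffix/prefix, [findTSD()]; the interval is then the bare element, as at
#' a solo-LTR site), (A) the leading `t` nt of the block equal the `t` nt
#' following it (block = TSD + element), and (B) the trailing `t` nt of the
#' block equal the `t` nt preceding it (block = element + TSD). The longest
#' duplication wins; ties prefer configuration O, then A, then the smallest
#' placement shift. The returned `ins_start`/`ins_end` give the element
#' interval with the duplicated copy excluded, which is the length
#' convention of the per-insertion reports.
#'
#' @param seq Full carrier sequence (character or `DNAString`).
#' @param insStart,insEnd 1-based called insertion interval on `seq`.
#' @param minLen,maxLen TSD length bounds.
#' @param maxShift Maximum placement shift explored in each direction
#'   (default `maxLen`).
#' @param flankWidth Flank width handed to [findTSD()].
#' @param wobble Additional placement shifts explored unconditionally
#'   (default 0): called boundaries from heuristic extension can be off by
#'   a few nt even where the sequence does not repeat, so a small window
#'   of off-by-`wobble` placements is always tested (a duplication found
#'   there must still match exactly, so the false-positive cost is the
#'   chance of a random t-mer match).
#' @param independentEnds Scan start/end displacements independently
#'   (for intervals from heuristic extension or local alignment, whose two
#'   boundaries err independently); placements are visited by increasing
#'   total displacement and the scan stops at the first level with a
#'   duplication.
#' @return As [findTSD()], plus `ins_start`, `ins_end` (element interval at
#'   the chosen placement), `shift` and `config`.
#' @export
insertionTSD <- function(seq, insStart, insEnd, minLen = 2L, maxLen = 25L,
                         maxShift = maxLen, flankWidth = 40L, wobble = 0L,
                         independentEnds = FALSE) {
  s <- asSeqString(seq)
  n <- nchar(s)
  ch <- function(i) substr(s, i, i)
  shifts <- 0L
  st <- insStart; en <- insEnd
  k <- 0L  # slide right: first block char equals char after block
  while (k < maxShift && en + 1L <= n && ch(st) == ch(en + 1L)) {
    st <- st + 1L; en <- en + 1L; k <- k + 1L
    shifts <- c(shifts, k)
  }
  st <- insStart; en <- insEnd
  k <- 0L  # slide left
  while (k < maxShift && st - 1L >= 1L && ch(st - 1L) == ch(en)) {
    st <- st - 1L; en <- en - 1L; k <- k + 1L
    shifts <- c(shifts, -k)
  }
  if (wobble > 0L) shifts <- union(shifts, seq(-wobble, wobble))
  shifts <- shifts[insStart + shifts >= 1L & insEnd + shifts <= n]
  if (independentEnds) {
    # boundaries from heuristic (non-alignment) intervals can be off by a
    # few nt on each side independently; scan (ds, de) displacement pairs
    # by increasing total displacement and stop at the first level that
    # yields a duplication
    best <- NULL
    evalPlacement <- function(st, en) {
      res <- list()
      lf <- substr(s, max(1L, st - flankWidth), st - 1L)
      rf <- substr(s, en + 1L, min(n, en + flankWidth))
      r <- suppressWarnings(findTSD(lf, rf, minLen = minLen,
                                    maxLen = maxLen))
      r$ins_start <- st; r$ins_end <- en; r$shift <- 0L; r$config <- "O"
      res[[1]] <- r
      res
    }
    for (lev in 0:(2L * wobble)) {
      levBest <- NULL
      for (ds in seq(-min(lev, wobble), min(lev, wobble))) {
        de <- lev - abs(ds)
        for (deSgn in unique(c(de, -de))) {
          st <- insStart + ds; en <- insEnd + deSgn
          if (st < 1L || en > n || en <= st) next
          for (r in evalPlacement(st, en)) {
            if (r$class == "TSD" &&
                (is.null(levBest) || r$length > levBest$length))
              levBest <- r
          }
        }
      }
      if (!is.null(levBest)) { best <- levBest; break }
    }
    if (is.null(best))
      best <- list(sequence = "", length = 0L, class = "not_detected",
                   ins_start = insStart, ins_end = insEnd, shift = 0L,
                   config = "O")
    return(best)
  }
  best <- NULL
  rankConfig <- c(O = 3L, A = 2L, B = 1L)
  consider <- function(cand) {
    if (is.null(best)) return(TRUE)
    if ((cand$class == "TSD") != (best$class == "TSD"))
      return(cand$class == "TSD")
    if (cand$class != "TSD") return(FALSE)
    if (cand$length != best$length) return(cand$length > best$length)
    if (cand$config != best$config)
      return(rankConfig[[cand$config]] > rankConfig[[best$config]])
    FALSE
  }
  for (sh in shifts[order(abs(shifts), sign(shifts))]) {
    st <- insStart + sh; en <- insEnd + sh
    blockLen <- en - st + 1L
    lf <- substr(s, max(1L, st - flankWidth), st - 1L)
    rf <- substr(s, en + 1L, min(n, en + flankWidth))
    # configuration O: both TSD copies outside the interval
    r <- suppressWarnings(findTSD(lf, rf, minLen = minLen, maxLen = maxLen))
    r$ins_start <- st; r$ins_end <- en; r$shift <- sh; r$config <- "O"
    if (consider(r)) best <- r
    # configurations A and B: one TSD copy inside the block edge
    tmax <- min(maxLen, blockLen - 1L, n - en)
    if (tmax >= minLen) {
      for (t in seq(tmax, minLen)) {
        if (substr(s, st, st + t - 1L) == substr(s, en + 1L, en + t)) {
          cand <- list(sequence = substr(s, st, st + t - 1L), length = t,
                       class = "TSD", ins_start = st + t, ins_end = en,
                       shift = sh, config = "A")
          if (consider(cand)) best <- cand
          break
        }
      }
    }
    tmax <- min(maxLen, blockLen - 1L, st - 1L)
    if (tmax >= minLen) {
      for (t in seq(tmax, minLen)) {
        if (substr(s, en - t + 1L, en) == substr(s, st - t, st - 1L)) {
          cand <- list(sequence = substr(s, en - t + 1L, en), length = t,
                       class = "TSD", ins_start = st, ins_end = en - t,
                       shift = sh, config = "B")
          if (consider(cand)) best <- cand
          break
        }
      }
    }
  }
  if (is.null(best)) {
    best <- list(sequence = "", length = 0L, class = "not_detected",
                 ins_start = insStart, ins_end = insEnd, shift = 0L,
                 config = "O")
  }
  if (is.null(best$config)) best$config <- "O"
  best
}

#' Detect terminal repeats (LTRs or TIRs) of an element
#'
#' Aligns the 5' and 3' terminal windows of the element (each
#' `min(1500, length/2)` nt) locally against each other, in direct
#' orientation (long terminal repeats) and in reverse complement (terminal
#' inverted repeats). A repeat is accepted when the aligned length is at
#' least `minLtr`, identity at least `minIdentity`, and the repeat ends
#' fall within `endSlack` of the element termini.
#'
#' @param elementSeq Element sequence (>= `2 * minLtr` nt).
#' @param minLtr Minimum repeat length (default 100 nt).
#' @param minIdentity Identity floor (default 0.80).
#' @param endSlack Maximum distance of the repeat from the element termini
#'   (default 50 nt).
#' @return `NULL`, or a list: `type` ("LTR" or "TIR"), `left_start`,
#'   `left_end`, `right_start`, `right_end` (element coordinates),
#'   `length` (aligned length), `identity`, `score`.
#' @export
detectLTRs <- function(elementSeq, minLtr = 100L, minIdentity = 0.80,
                       endSlack = 50L) {
  s <- asSeqString(elementSeq)
  n <- nchar(s)
  if (n < 2L * minLtr) return(NULL)
  w <- min(1500L, n %/% 2L)
  left <- substr(s, 1L, w)
  right <- substr(s, n - w + 1L, n)
  off <- n - w  # element offset of the right window
  cand <- list()
  # direct repeat (LTR)
  al <- .alignLocal(left, right)
  alen <- max(al$p_end - al$p_start, al$s_end - al$s_start) + 1L
  if (alen >= minLtr && al$identity >= minIdentity &&
      al$p_start - 1L <= endSlack && (w - al$s_end) <= endSlack) {
    cand$LTR <- list(type = "LTR",
                     left_start = al$p_start, left_end = al$p_end,
                     right_start = off + al$s_start,
                     right_end = off + al$s_end,
                     length = alen, identity = al$identity,
                     score = al$score)
  }
  # inverted repeat (TIR): on the reverse complement of the right window
  # the element's 3' terminus maps to position 1, so the repeat must START
  # within the slack
  ali <- .alignLocal(left, revComp(right))
  aleni <- max(ali$p_end - ali$p_start, ali$s_end - ali$s_start) + 1L
  if (aleni >= minLtr && ali$identity >= minIdentity &&
      ali$p_start - 1L <= endSlack && ali$s_start - 1L <= endSlack) {
    # rc(right) position i corresponds to right-window position w - i + 1
    cand$TIR <- list(type = "TIR",
                     left_start = ali$p_start, left_end = ali$p_end,
                     right_start = off + (w - ali$s_end + 1L),
                     right_end = off + (w - ali$s_start + 1L),
                     length = aleni, identity = ali$identity,
                     score = ali$score)
  }
  if (!length(cand)) return(NULL)
  cand[[which.max(vapply(cand, function(z) z$score, numeric(1)))]]
}

#' Call a solo-LTR recombination event
#'
#' Given a species-specific LTR-element call whose terminal repeats were
#' detected, tests whether the orthologous empty site is in fact a solo
#' LTR: the empty-site sequence must align to one LTR with identity at
#' least `minIdentity` and length within `lenTol` of the LTR, and both
#' structures must be framed by the same TSD string -- the signature of
#' homologous recombination between the element's two LTRs.
#'
#' @param elementSeq The filled element sequence.
#' @param ltrPair Result of [detectLTRs()] on `elementSeq` (type "LTR").
#' @param emptySiteSeq Sequence around the orthologous empty site, in the
#'   carrier orientation.
#' @param tsd TSD string of the filled call (`NA` when undetected).
#' @param minIdentity Identity floor for LTR-vs-solo (default 0.90).
#' @param lenTol Relative length tolerance (default 0.1).
#' @return `NULL`, or a list: `solo_start`, `solo_end` (on
#'   `emptySiteSeq`), `ltr_identity_to_solo`, `shared_tsd`.
#' @export
callSoloLTR <- function(elementSeq, ltrPair, emptySiteSeq, tsd = NA,
                        minIdentity = 0.90, lenTol = 0.1) {
  if (is.null(ltrPair) || ltrPair$type != "LTR") return(NULL)
  elem <- asSeqString(elementSeq)
  site <- asSeqString(emptySiteSeq)
  ltr <- substr(elem, ltrPair$left_start, ltrPair$left_end)
  al <- .alignLocal(ltr, site)
  alen <- al$s_end - al$s_start + 1L
  if (al$identity < minIdentity) return(NULL)
  if (abs(alen - nchar(ltr)) > lenTol * nchar(ltr)) return(NULL)
  soloTSD <- insertionTSD(site, al$s_start, al$s_end, wobble = 8L,
                          independentEnds = TRUE)
  if (is.na(tsd) || !nzchar(tsd)) return(NULL)
  if (soloTSD$class != "TSD" || soloTSD$sequence != tsd) return(NULL)
  list(solo_start = soloTSD$ins_start, solo_end = soloTSD$ins_end,
       ltr_identity_to_solo = al$identity, shared_tsd = tsd)
}

#' Decompose a composite insertion into TE components
#'
#' Tiles the insertion with non-overlapping library hits, greedily by
#' descending alignment score, and searches nested TSDs at each component's
#' extremities. A decomposition covering less than `minCoverage` of the
#' insertion is reported as partial.
#'
#' @param insertionSeq Insertion sequence.
#' @param library A [TELibrary-class].
#' @param minCoverage Coverage floor below which the decomposition is
#'   flagged partial (default 0.6).
#' @param maxOverlap Maximum tolerated overlap between accepted components
#'   (nt, default 10).
#' @param min_len,max_div Annotation filters (defaults 100 nt / 0.20).
#' @return A list: `components` (data.frame: `consensus_id`,
#'   `superfamily`, `start`, `end`, `strand`, `divergence`, `tsd`),
#'   `coverage`, `partial`.
#' @export
decomposeComposite <- function(insertionSeq, library, minCoverage = 0.6,
                               maxOverlap = 10L, min_len = 100L,
                               max_div = 0.20) {
  s <- asSeqString(insertionSeq)
  ann <- annotateRepeats(s, library, seqId = "insertion",
                         min_len = min_len, max_div = max_div,
                         mask = IRanges::IRanges())
  ins <- ann$insertions
  comps <- NULL
  if (nrow(ins)) {
    ins <- ins[order(-ins$score), , drop = FALSE]
    acc <- IRanges::IRanges()
    keep <- logical(nrow(ins))
    for (i in seq_len(nrow(ins))) {
      iv <- IRanges::IRanges(ins$span_start[i], ins$span_end[i])
      ov <- IRanges::intersect(IRanges::reduce(acc), iv)
      if (sum(IRanges::width(ov)) <= maxOverlap) {
        keep[i] <- TRUE
        acc <- c(acc, iv)
      }
    }
    comps <- ins[keep, , drop = FALSE]
    comps <- comps[order(comps$span_start), , drop = FALSE]
  }
  if (is.null(comps) || nrow(comps) == 0L) {
    return(list(components = data.frame(), coverage = 0, partial = TRUE))
  }
  tsds <- character(nrow(comps))
  for (i in seq_len(nrow(comps))) {
    r <- insertionTSD(s, comps$span_start[i], comps$span_end[i])
    tsds[i] <- if (r$class == "TSD") r$sequence else ""
  }
  cov <- sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(comps$span_start, comps$span_end)))) / nchar(s)
  list(components = data.frame(
         consensus_id = comps$consensus_id,
         superfamily = comps$superfamily,
         start = comps$span_start, end = comps$span_end,
         strand = comps$strand, divergence = comps$divergence,
         tsd = tsds, stringsAsFactors = FALSE),
       coverage = cov, partial = cov < minCoverage)
}

#' Copy number of an element in genomic sequences
#'
#' Counts local-alignment hits of the query in the target sequences with
#' the classical family filters: hit length at least `minLenFrac` of the
#' query length and identity at least `minIdentity`. `n_high` additionally
#' requires identity at or above `highIdentity`. Hits overlapping more than
#' 50% are collapsed to the best-scoring one per locus.
#'
#' @param query Query element sequence (>= 100 nt).
#' @param targetSeqs Named list / character vector / `DNAStringSet` of
#'   target sequences.
#' @param minLenFrac Minimum hit length as a fraction of the query length
#'   (default 0.80).
#' @param minIdentity Minimum identity (default 0.80).
#' @param highIdentity Identity threshold of the high-identity count
#'   (default 0.98).
#' @param k Seed length (default 12).
#' @param xdrop X-drop for hit extension (default 50; more permissive than
#'   annotation so diverged copies are not truncated).
#' @return A list: `n_total`, `n_high`, `hits` (data.frame of retained
#'   hits).
#' @export
copyNumber <- function(query, targetSeqs, minLenFrac = 0.80,
                       minIdentity = 0.80, highIdentity = 0.98,
                       k = 12L, xdrop = 50L) {
  q <- asSeqString(query)
  if (nchar(q) < 100L) stop("query must be at least 100 nt")
  if (is(targetSeqs, "DNAStringSet")) targetSeqs <- as.character(targetSeqs)
  if (is.character(targetSeqs)) targetSeqs <- as.list(targetSeqs)
  if (is.null(names(targetSeqs)))
    names(targetSeqs) <- paste0("target", seq_along(targetSeqs))
  allHits <- list()
  for (nm in names(targetSeqs)) {
    t <- asSeqString(targetSeqs[[nm]])
    gh <- kmerHashes(seqCodes(t), k)
    gdt <- data.table(h = gh, g_pos = seq_along(gh))
    gdt <- gdt[!is.na(gdt$h)]
    setkey(gdt, h)
    cand <- .candidateAnchors(gdt, q, "query", k)
    if (is.null(cand)) next
    rows <- vector("list", nrow(cand))
    for (j in seq_len(nrow(cand))) {
      rows[[j]] <- extendHit(t, q, cand$g_pos[j], cand$c_pos[j],
                             strand = cand$strand[j], k = k,
                             xdrop = xdrop, seqId = nm,
                             consensusId = "query")
    }
    allHits[[nm]] <- do.call(rbind, rows)
  }
  hits <- do.call(rbind, allHits)
  empty <- list(n_total = 0L, n_high = 0L, hits = .emptyHits())
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  hits <- hits[(hits$g_end - hits$g_start + 1L) >= minLenFrac * nchar(q) &
                 hits$identity >= minIdentity, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  # collapse hits overlapping > 50% (per target sequence), keeping the best
  keep <- rep(TRUE, nrow(hits))
  ord <- order(-hits$score)
  for (ii in seq_along(ord)) {
    i <- ord[ii]
    if (!keep[i]) next
    later <- ord[-seq_len(ii)]
    later <- later[keep[later] & hits$seq_id[later] == hits$seq_id[i]]
    if (!length(later)) next
    ov <- pmin(hits$g_end[later], hits$g_end[i]) -
      pmax(hits$g_start[later], hits$g_start[i]) + 1L
    wmin <- pmin(hits$g_end[later] - hits$g_start[later] + 1L,
                 hits$g_end[i] - hits$g_start[i] + 1L)
    keep[later[ov > 0.5 * wmin]] <- FALSE
  }
  hits <- hits[keep, , drop = FALSE]
  list(n_total = nrow(hits),
       n_high = sum(hits$identity >= highIdentity),
       hits = hits)
}

#' Transcriptome representation of an element
#'
#' Number of distinct transcripts carrying at least one local-alignment hit
#' of the query with hit length at least `minHitLen` nt and identity at
#' least `minIdentity`.
#'
#' @param query Element sequence.
#' @param transcripts Named list / character vector / `DNAStringSet` of
#'   transcript sequences.
#' @param minHitLen Minimum hit length (default 80 nt).
#' @param minIdentity Minimum identity (default 0.95).
#' @param k Prefilter seed length (default 12); transcripts sharing fewer
#'   than 2 exact seeds with the query (either strand) are skipped.
#' @return Integer count of qualifying transcripts.
#' @export
expressionHits <- function(query, transcripts, minHitLen = 80L,
                           minIdentity = 0.95, k = 12L) {
  q <- asSeqString(query)
  if (is(transcripts, "DNAStringSet")) transcripts <- as.character(transcripts)
  if (is.character(transcripts)) transcripts <- as.list(transcripts)
  if (length(transcripts) == 0L) return(0L)
  qh <- kmerHashes(seqCodes(q), k)
  qrh <- kmerHashes(seqCodes(revComp(q)), k)
  qset <- unique(c(qh[!is.na(qh)], qrh[!is.na(qrh)]))
  n <- 0L
  for (tr in transcripts) {
    t <- asSeqString(tr)
    th <- kmerHashes(seqCodes(t), k)
    if (sum(th %in% qset, na.rm = TRUE) < 2L) next
    hitF <- .alignLocal(q, t)
    hitR <- .alignLocal(revComp(q), t)
    hit <- if (hitF$score >= hitR$score) hitF else hitR
    alen <- hit$s_end - hit$s_start + 1L
    if (alen >= minHitLen && hit$identity >= minIdentity) n <- n + 1L
  }
  n
}

#' Cluster element copies into high-identity subfamilies
#'
#' Single-linkage clustering of sequences under pairwise global-alignment
#' identity at or above `idThreshold`. Pairs with a length ratio below 0.8
#' or no shared 20-mer are assigned identity 0 without alignment (they
#' cannot reach subfamily-level identity).
#'
#' @param seqs Named character vector / list / `DNAStringSet` of element
#'   sequences.
#' @param idThreshold Identity threshold (default 0.98).
#' @return A list: `clusters` (list of name vectors), `identity`
#'   (symmetric matrix of computed pairwise identities).
#' @export
clusterSubfamily <- function(seqs, idThreshold = 0.98) {
  if (is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  seqs <- lapply(as.list(seqs), asSeqString)
  n <- length(seqs)
  if (n == 0L) stop("at least one sequence required")
  nms <- names(seqs) %||% paste0("seq", seq_len(n))
  names(seqs) <- nms
  idm <- matrix(0, n, n, dimnames = list(nms, nms))
  diag(idm) <- 1
  hashes <- lapply(seqs, function(s) {
    h <- kmerHashes(seqCodes(s), 20L)
    unique(h[!is.na(h)])
  })
  parent <- seq_len(n)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        li <- nchar(seqs[[i]]); lj <- nchar(seqs[[j]])
        if (min(li, lj) / max(li, lj) < 0.8) next
        if (!any(hashes[[i]] %in% hashes[[j]])) next
        g <- .alignGlobal(seqs[[i]], seqs[[j]])
        pv <- strsplit(g$pattern, "")[[1]]
        sv <- strsplit(g$subject, "")[[1]]
        ng <- pv != "-" & sv != "-"
        ident <- if (any(ng)) sum(pv[ng] == sv[ng]) / sum(ng) else 0
        idm[i, j] <- idm[j, i] <- ident
        if (ident >= idThreshold) {
          ri <- findRoot(i); rj <- findRoot(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), findRoot, integer(1))
  cl <- split(nms, match(roots, unique(roots)))
  names(cl) <- NULL
  list(clusters = cl, identity = idm)
}

#' Structural feature table for specific insertion calls
#'
#' Builds the per-call feature table (insertion identifier, length, TSD,
#' element notes from the library metadata, copy numbers in the analyzed
#' sequences, transcriptome hits, genomic context), one row per specific
#' call -- the per-insertion structural report of the comparison.
#'
#' @param callSet An [InsertionCalls-class].
#' @param genomeA,genomeB The genome sequences (named sets).
#' @param library The [TELibrary-class].
#' @param transcripts Optional transcript set for [expressionHits()].
#' @param genesA,genesB Optional gene models (GFF3 paths or `GRanges`) for
#'   [genomicContext()].
#' @param copyNumberScan Compute copy numbers (default TRUE; the dominant
#'   cost of the feature stage).
#' @return A data.frame with one row per specific call.
#' @export
featureTable <- function(callSet, genomeA, genomeB, library,
                         transcripts = NULL, genesA = NULL, genesB = NULL,
                         copyNumberScan = TRUE) {
  sp <- specificCalls(callSet)
  getSeq <- function(genome, id) {
    if (is.character(genome) && !is.null(names(genome))) return(genome[[id]])
    as.character(genome[[id]])
  }
  n <- nrow(sp)
  if (n == 0L) {
    return(data.frame(call_id = integer(0), species = character(0),
                      seq_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      superfamily = character(0), tsd = character(0),
                      tsd_class = character(0), stringsAsFactors = FALSE))
  }
  out <- sp[, c("call_id", "species", "seq_id", "start", "end", "length",
                "superfamily", "consensus_id", "strand", "divergence",
                "tsd", "tsd_class", "refined", "solo_ltr")]
  out$copy_total <- NA_integer_
  out$copy_high98 <- NA_integer_
  out$transcript_hits <- NA_integer_
  out$ltr_detected <- FALSE
  out$ltr_length <- NA_integer_
  out$ltr_identity <- NA_real_
  out$composite <- NA_character_
  out$notes <- NA_character_
  info <- consensusInfo(library)
  targets <- c(as.list(as.character(
    if (is.character(genomeA)) genomeA else as.character(genomeA))),
    as.list(as.character(
      if (is.character(genomeB)) genomeB else as.character(genomeB))))
  for (i in seq_len(n)) {
    carrier <- if (sp$species[i] == "A") getSeq(genomeA, sp$seq_id[i])
               else getSeq(genomeB, sp$seq_id[i])
    elem <- toupper(substr(carrier, sp$start[i], sp$end[i]))
    meta <- info[info$id == sp$consensus_id[i], , drop = FALSE]
    out$notes[i] <- sprintf("%s;%s", meta$te_class[1],
                            if (isTRUE(meta$is_autonomous[1])) "autonomous"
                            else "non-autonomous")
    if (nchar(elem) >= 200L) {
      lp <- detectLTRs(elem)
      if (!is.null(lp)) {
        out$ltr_detected[i] <- TRUE
        out$ltr_length[i] <- lp$length
        out$ltr_identity[i] <- lp$identity
        out$notes[i] <- paste0(out$notes[i], ";", lp$type)
      }
    }
    dec <- decomposeComposite(elem, library)
    if (nrow(dec$components) >= 2L) {
      out$composite[i] <- paste(sprintf("%s(%s)", dec$components$consensus_id,
                                        dec$components$strand),
                                collapse = "/")
    }
    if (copyNumberScan && nchar(elem) >= 100L) {
      cn <- copyNumber(elem, targets)
      out$copy_total[i] <- cn$n_total
      out$copy_high98[i] <- cn$n_high
    }
    if (!is.null(transcripts)) {
      out$transcript_hits[i] <- expressionHits(elem, transcripts)
    }
  }
  ctx <- genomicContext(sp, genesA = genesA, genesB = genesB)
  out$position_class <- ctx$location_class
  out$distance_kb <- ctx$distance_kb
  out$nearest_gene <- ctx$gene_id
  out
}
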