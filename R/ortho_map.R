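#' Orthology map between two sequence sets
#'
#' Chained anchor correspondence between intervals of genome A and genome
#' B, the automated counterpart of selecting best megablast hits and
#' reading fragment coordinates off the main alignment diagonals. Supports
#' coordinate liftover in both directions.
#'
#' @slot fragments data.frame of orthologous fragments: `fragment_id`,
#'   `a_seq`, `a_start`, `a_end`, `b_seq`, `b_start`, `b_end`,
#'   `orientation` (+/-), `mean_identity`, `score` (1-based inclusive).
#' @slot anchors data.frame of chained anchors: `fragment_id`, `a_start`,
#'   `a_end`, `b_start`, `b_end`, `strand`, `length`, `identity`.
#' @slot maxGap Maximum inter-anchor gap (nt) a position may be
#'   interpolated across.
#' @export
setClass("OrthoMap",
  representation(fragments = "data.frame", anchors = "data.frame",
                 maxGap = "numeric"))

setValidity("OrthoMap", function(object) {
  fr <- object@fragments
  need <- c("fragment_id", "a_seq", "a_start", "a_end", "b_seq", "b_start",
            "b_end", "orientation", "mean_identity")
  if (!all(need %in% names(fr)))
    return("fragments is missing required columns")
  if (nrow(fr) && any(fr$a_end < fr$a_start | fr$b_end < fr$b_start))
    return("fragment intervals must satisfy start <= end")
  TRUE
})

setMethod("show", "OrthoMap", function(object) {
  fr <- object@fragments
  cat(sprintf("OrthoMap: %d fragment(s), %d anchor(s)\n",
              nrow(fr), nrow(object@anchors)))
  if (nrow(fr)) {
    cat(sprintf("  total aligned span on A: %d nt; mean identity %.4f\n",
                sum(fr$a_end - fr$a_start + 1L),
                sum((fr$a_end - fr$a_start + 1) * fr$mean_identity) /
                  sum(fr$a_end - fr$a_start + 1)))
    print(head(fr, 8), row.names = FALSE)
  }
  invisible(NULL)
})

#' @rdname OrthoMap-class
#' @param x An `OrthoMap`.
#' @export
orthoFragments <- function(x) x@fragments

#' @rdname OrthoMap-class
#' @export
orthoAnchors <- function(x) x@anchors

#' Find high-identity anchors between two sequences
#'
#' Maximal exact matches of at least `seedLen` nt on both strands, found by
#' exact k-mer hashing and same-diagonal run collapsing, then merged across
#' isolated substitutions while the anchor identity stays at or above
#' `minIdentity`. Over-represented seeds (more than `maxOcc` occurrences in
#' either sequence) are ignored.
#'
#' @param a,b Nucleotide sequences (character or `DNAString`).
#' @param seedLen Seed length (>= 16 recommended at genome scale; smaller
#'   values are allowed for small inputs).
#' @param minIdentity Identity floor for merged anchors.
#' @param maxOcc Seed occurrence cap (repeat filter).
#' @return A data.frame of anchors: `a_start`, `a_end`, `b_start`, `b_end`
#'   (forward coordinates on each sequence, 1-based inclusive), `strand`,
#'   `length` (span on `a`), `identity`.
#' @export
findAnchors <- function(a, b, seedLen = 20L, minIdentity = 0.95,
                        maxOcc = 10L) {
  a <- asSeqString(a); b <- asSeqString(b)
  k <- as.integer(seedLen)
  if (k < 8L) stop("seedLen must be >= 8")
  if (k > 26L) stop("seedLen must be <= 26")
  Lb <- nchar(b)
  ha <- kmerHashes(seqCodes(a), k)
  hb <- kmerHashes(seqCodes(b), k)
  hbr <- kmerHashes(seqCodes(revComp(b)), k)
  adt <- data.table(h = ha, a_pos = seq_along(ha))[!is.na(ha)]
  bdt <- rbind(
    data.table(h = hb, b_pos = seq_along(hb), strand = "+"),
    data.table(h = hbr, b_pos = Lb - seq_along(hbr) - k + 2L, strand = "-"))
  bdt <- bdt[!is.na(bdt$h)]
  # occurrence cap
  aocc <- adt[, list(na = .N), by = "h"]
  bocc <- bdt[, list(nb = .N), by = "h"]
  bad <- unique(c(aocc$h[aocc$na > maxOcc], bocc$h[bocc$nb > maxOcc]))
  if (length(bad)) {
    adt <- adt[!adt$h %in% bad]
    bdt <- bdt[!bdt$h %in% bad]
  }
  m <- adt[bdt, on = "h", allow.cartesian = TRUE, nomatch = NULL]
  if (nrow(m) == 0L) {
    return(data.frame(a_start = integer(0), a_end = integer(0),
                      b_start = integer(0), b_end = integer(0),
                      strand = character(0), length = integer(0),
                      identity = numeric(0)))
  }
  m[, diag := ifelse(strand == "+", a_pos - b_pos, a_pos + b_pos)]
  setorder(m, strand, diag, a_pos)
  n <- nrow(m)
  newRun <- c(TRUE, m$strand[-1] != m$strand[-n] | m$diag[-1] != m$diag[-n] |
                (m$a_pos[-1] - m$a_pos[-n]) > k)
  m[, run := cumsum(newRun)]
  runs <- m[, list(strand = strand[1], diag = diag[1],
                   a_min = min(a_pos), a_max = max(a_pos) + k - 1L),
            by = "run"]
  # merge same-diagonal runs across isolated substitutions while identity
  # stays >= minIdentity (the gap between two runs on one diagonal is a
  # substitution stretch of known length)
  setorder(runs, strand, diag, a_min)
  out <- list()
  nr <- nrow(runs)
  i <- 1L
  widx <- 0L
  resA0 <- integer(nr); resA1 <- integer(nr); resD <- numeric(nr)
  resS <- character(nr); resMM <- integer(nr)
  while (i <= nr) {
    s0 <- runs$a_min[i]; s1 <- runs$a_max[i]
    mm <- 0L
    j <- i + 1L
    while (j <= nr && runs$strand[j] == runs$strand[i] &&
           runs$diag[j] == runs$diag[i]) {
      gap <- runs$a_min[j] - s1 - 1L
      if (gap < 0L) gap <- 0L
      newLen <- runs$a_max[j] - s0 + 1L
      newMM <- mm + gap
      if ((newLen - newMM) / newLen >= minIdentity) {
        s1 <- runs$a_max[j]; mm <- newMM
        j <- j + 1L
      } else break
    }
    widx <- widx + 1L
    resA0[widx] <- s0; resA1[widx] <- s1
    resMM[widx] <- mm
    resS[widx] <- runs$strand[i]; resD[widx] <- runs$diag[i]
    i <- j
  }
  len <- resA1[1:widx] - resA0[1:widx] + 1L
  strand <- resS[1:widx]; d <- resD[1:widx]
  a_start <- resA0[1:widx]; a_end <- resA1[1:widx]
  # for "-", d = a_pos + b_pos over window *starts*; converting a run's end
  # coordinates to b window coordinates needs the k-1 window-width shift
  b_start <- ifelse(strand == "+", a_start - d, d - a_end + k - 1L)
  b_end <- ifelse(strand == "+", a_end - d, d - a_start + k - 1L)
  keep <- len >= k
  data.frame(a_start = a_start, a_end = a_end,
             b_start = as.integer(b_start), b_end = as.integer(b_end),
             strand = strand, length = len,
             identity = (len - resMM[1:widx]) / len,
             stringsAsFactors = FALSE)[keep, , drop = FALSE]
}

# chain feasibility and step penalty: anchor i may follow anchor j
# (j before i on a) when both inter-anchor gaps are at most maxGap and the
# anchors stay monotone on both sequences. Diagonal wobble beyond
# maxDiagDrift is allowed -- a one-sided gap is exactly what an insertion
# polymorphism looks like -- but is penalized in the chain score so
# colinear paths win whenever one exists.
.chainStep <- function(aS_i, aE_i, bS_i, bE_i, aS_j, aE_j, bS_j, bE_j,
                       strand, maxDiagDrift, maxGap, overlapSlack = 50L) {
  gapA <- aS_i - aE_j - 1L
  ok <- aS_i > aS_j & gapA <= maxGap & gapA >= -overlapSlack
  if (strand == "+") {
    gapB <- bS_i - bE_j - 1L
    ok <- ok & bS_i > bS_j & gapB <= maxGap & gapB >= -overlapSlack
  } else {
    gapB <- bS_j - bE_i - 1L
    ok <- ok & bE_i < bE_j & gapB <= maxGap & gapB >= -overlapSlack
  }
  drift <- abs(gapA - gapB)
  pen <- ifelse(drift <= maxDiagDrift, 0, 0.02 * drift)
  list(ok = ok, penalty = pen)
}

# best chain (max total length*identity minus step penalties) over anchors
# of one strand; returns indices in chain order, or NULL
.bestChain <- function(an, strand, maxDiagDrift, maxGap) {
  idx <- which(an$strand == strand)
  if (!length(idx)) return(NULL)
  an <- an[idx, , drop = FALSE]
  o <- order(an$a_start, an$a_end)
  an <- an[o, , drop = FALSE]
  idx <- idx[o]
  n <- nrow(an)
  w <- an$length * an$identity
  dp <- w
  prev <- rep(NA_integer_, n)
  maxLen <- max(an$a_end - an$a_start + 1L)
  for (i in seq_len(n)) {
    if (i == 1L) next
    # predecessors must satisfy a_end >= a_start_i - maxGap - 1; bound the
    # scan window using the sorted a_start order
    jlo <- findInterval(an$a_start[i] - maxGap - 1L - maxLen,
                        an$a_start) + 1L
    if (jlo >= i) next
    js <- jlo:(i - 1L)
    js <- js[an$a_end[js] >= an$a_start[i] - maxGap - 1L]
    if (!length(js)) next
    st <- .chainStep(an$a_start[i], an$a_end[i], an$b_start[i],
                     an$b_end[i], an$a_start[js], an$a_end[js],
                     an$b_start[js], an$b_end[js], strand, maxDiagDrift,
                     maxGap)
    js <- js[st$ok]
    if (!length(js)) next
    cand <- dp[js] - st$penalty[st$ok]
    bi <- which.max(cand)
    if (cand[bi] > 0) {
      dp[i] <- w[i] + cand[bi]
      prev[i] <- js[bi]
    }
  }
  end <- which.max(dp)
  chain <- integer(0)
  i <- end
  while (!is.na(i)) { chain <- c(i, chain); i <- prev[i] }
  list(indices = idx[chain], score = dp[end])
}

#' Chain anchors into orthologous fragments
#'
#' Finds the highest-scoring colinear chains of anchors (weight = anchor
#' length x identity) under per-step diagonal-drift and gap constraints.
#' Chains are extracted best-first; a secondary chain is kept only when its
#' a-interval does not overlap an already accepted fragment, giving a set
#' of non-overlapping fragments on sequence A. Ties break to the leftmost
#' a-coordinate.
#'
#' @param anchors Anchor data.frame from [findAnchors()] (one sequence
#'   pair).
#' @param maxDiagDrift Maximum per-step diagonal drift (nt).
#' @param maxGap Maximum per-step gap on either sequence (nt).
#' @param minChainScore Minimum chain score for a fragment to be reported.
#' @param aSeq,bSeq Sequence identifiers stored in the fragment table.
#' @return A data.frame of fragments with their chained anchors as an
#'   attribute `"anchors"` (columns as in [OrthoMap-class]).
#' @export
chainDiagonals <- function(anchors, maxDiagDrift = 200L, maxGap = 10000L,
                           minChainScore = 50, aSeq = "A", bSeq = "B") {
  emptyFr <- data.frame(fragment_id = integer(0), a_seq = character(0),
                        a_start = integer(0), a_end = integer(0),
                        b_seq = character(0), b_start = integer(0),
                        b_end = integer(0), orientation = character(0),
                        mean_identity = numeric(0), score = numeric(0),
                        stringsAsFactors = FALSE)
  emptyAn <- cbind(data.frame(fragment_id = integer(0)),
                   anchors[0, , drop = FALSE])
  if (nrow(anchors) == 0L) {
    attr(emptyFr, "anchors") <- emptyAn
    return(emptyFr)
  }
  remaining <- anchors
  remaining$.row <- seq_len(nrow(anchors))
  chains <- list(); chainScores <- numeric(0)
  acceptedCov <- IRanges::IRanges()  # anchor coverage of accepted chains
  repeat {
    if (nrow(remaining) == 0L) break
    best <- NULL
    for (s in intersect(c("+", "-"), unique(remaining$strand))) {
      ch <- .bestChain(remaining, s, maxDiagDrift, maxGap)
      if (!is.null(ch) && (is.null(best) || ch$score > best$score ||
                           (ch$score == best$score &&
                            remaining$a_start[ch$indices[1]] <
                            remaining$a_start[best$indices[1]])))
        best <- ch
    }
    if (is.null(best) || best$score < minChainScore) break
    ch <- remaining[best$indices, , drop = FALSE]
    chIv <- IRanges::IRanges(ch$a_start, ch$a_end)
    # a secondary chain is kept when its anchors do not overlap anchors of
    # already accepted chains AND, if it sits inside an accepted chain's
    # inter-anchor gap, its b-interval fills the corresponding b-side gap
    # (true for a nested inversion, false for repeat-induced noise between
    # non-orthologous loci); fragments are split around kept nested chains
    # below
    keep <- !any(IRanges::overlapsAny(chIv, acceptedCov))
    if (keep && length(chains)) {
      s0 <- min(ch$a_start); e0 <- max(ch$a_end)
      for (C in chains) {
        if (s0 >= min(C$a_start) && e0 <= max(C$a_end)) {
          nC <- nrow(C)
          k <- which(C$a_end[-nC] < s0 & C$a_start[-1] > e0)
          if (!length(k)) { keep <- FALSE; break }
          k <- k[1]
          # inner edges of the bracketing anchors' b intervals (for a "-"
          # chain the b coordinate decreases with a)
          if (C$strand[1] == "+") {
            bLo <- C$b_end[k]; bHi <- C$b_start[k + 1]
          } else {
            bLo <- C$b_end[k + 1]; bHi <- C$b_start[k]
          }
          if (min(ch$b_start) <= bLo || max(ch$b_end) >= bHi) {
            keep <- FALSE; break
          }
        }
      }
    }
    if (keep) {
      ch <- ch[order(ch$a_start), , drop = FALSE]
      chains[[length(chains) + 1L]] <- ch
      chainScores <- c(chainScores, best$score)
      acceptedCov <- IRanges::reduce(c(acceptedCov, chIv))
    }
    remaining <- remaining[-best$indices, , drop = FALSE]
    # anchors overlapping accepted anchor coverage can only yield
    # discarded chains; drop them before the next extraction
    if (nrow(remaining) && length(acceptedCov)) {
      aIv <- IRanges::IRanges(remaining$a_start, remaining$a_end)
      remaining <- remaining[!IRanges::overlapsAny(aIv, acceptedCov), ,
                             drop = FALSE]
    }
  }
  if (!length(chains)) {
    attr(emptyFr, "anchors") <- emptyAn
    return(emptyFr)
  }
  # split a chain wherever another accepted chain lies inside one of its
  # inter-anchor gaps (a nested inversion or translocated block), so the
  # reported fragments are non-overlapping on sequence a
  spans <- lapply(chains, function(ch) c(min(ch$a_start), max(ch$a_end)))
  pieces <- list(); pieceScores <- numeric(0)
  for (ci in seq_along(chains)) {
    ch <- chains[[ci]]
    n <- nrow(ch)
    cut <- rep(FALSE, max(0L, n - 1L))
    for (cj in seq_along(chains)) {
      if (cj == ci) next
      sp <- spans[[cj]]
      if (sp[1] >= spans[[ci]][1] && sp[2] <= spans[[ci]][2] && n > 1L) {
        k <- which(ch$a_end[-n] < sp[1] & ch$a_start[-1] > sp[2])
        cut[k] <- TRUE
      }
    }
    if (!any(cut)) {
      pieces[[length(pieces) + 1L]] <- ch
      pieceScores <- c(pieceScores, chainScores[ci])
    } else {
      run <- cumsum(c(0L, cut))
      for (r in unique(run)) {
        part <- ch[run == r, , drop = FALSE]
        pieces[[length(pieces) + 1L]] <- part
        pieceScores <- c(pieceScores, sum(part$length * part$identity))
      }
    }
  }
  frags <- list(); chl <- list()
  for (k in seq_along(pieces)) {
    ch <- pieces[[k]]
    frags[[k]] <- data.frame(
      fragment_id = k, a_seq = aSeq,
      a_start = min(ch$a_start), a_end = max(ch$a_end),
      b_seq = bSeq, b_start = min(ch$b_start), b_end = max(ch$b_end),
      orientation = ch$strand[1],
      mean_identity = sum(ch$length * ch$identity) / sum(ch$length),
      score = pieceScores[k], stringsAsFactors = FALSE)
    chl[[k]] <- cbind(data.frame(fragment_id = k),
                      ch[, setdiff(names(ch), ".row"), drop = FALSE])
  }
  fr <- do.call(rbind, frags)
  an <- do.call(rbind, chl)
  ord <- order(fr$a_start)
  old <- fr$fragment_id[ord]
  fr <- fr[ord, , drop = FALSE]
  fr$fragment_id <- seq_len(nrow(fr))  # renumber left to right on a
  an$fragment_id <- match(an$fragment_id, old)
  rownames(fr) <- NULL; rownames(an) <- NULL
  attr(fr, "anchors") <- an
  attr(fr, "chain_scores") <- chainScores  # DP scores of extracted chains
  fr
}

#' Build an orthology map between two genome sequence sets
#'
#' Runs [findAnchors()] and [chainDiagonals()] for every sequence pair and
#' collects the resulting fragments into an [OrthoMap-class].
#'
#' @param a,b Named [Biostrings::DNAStringSet] objects (or named character
#'   vectors) for genomes A and B.
#' @param seedLen,minIdentity,maxOcc See [findAnchors()].
#' @param maxDiagDrift,maxGap,minChainScore See [chainDiagonals()].
#' @return An [OrthoMap-class].
#' @export
buildOrthoMap <- function(a, b, seedLen = 20L, minIdentity = 0.95,
                          maxOcc = 10L, maxDiagDrift = 200L,
                          maxGap = 10000L, minChainScore = 50) {
  if (is.character(a)) a <- Biostrings::DNAStringSet(a)
  if (is.character(b)) b <- Biostrings::DNAStringSet(b)
  if (is.null(names(a))) names(a) <- paste0("A", seq_along(a))
  if (is.null(names(b))) names(b) <- paste0("B", seq_along(b))
  frl <- list(); anl <- list()
  for (ia in seq_along(a)) {
    for (ib in seq_along(b)) {
      anc <- findAnchors(a[[ia]], b[[ib]], seedLen = seedLen,
                         minIdentity = minIdentity, maxOcc = maxOcc)
      fr <- chainDiagonals(anc, maxDiagDrift = maxDiagDrift,
                           maxGap = maxGap, minChainScore = minChainScore,
                           aSeq = names(a)[ia], bSeq = names(b)[ib])
      ch <- attr(fr, "anchors")
      frl[[length(frl) + 1L]] <- fr
      anl[[length(anl) + 1L]] <- cbind(
        data.frame(a_seq = rep(names(a)[ia], nrow(ch)),
                   b_seq = rep(names(b)[ib], nrow(ch))), ch)
    }
  }
  fr <- do.call(rbind, frl)
  an <- do.call(rbind, anl)
  # global fragment ids
  if (nrow(fr)) {
    key <- paste(fr$a_seq, fr$b_seq, fr$fragment_id)
    ankey <- paste(an$a_seq, an$b_seq, an$fragment_id)
    fr$fragment_id <- seq_len(nrow(fr))
    an$fragment_id <- fr$fragment_id[match(ankey, key)]
  }
  rownames(fr) <- NULL; rownames(an) <- NULL
  new("OrthoMap", fragments = fr, anchors = an, maxGap = as.numeric(maxGap))
}

#' Lift a coordinate across an orthologous fragment
#'
#' Positions inside an anchor map exactly; positions between anchors are
#' linearly interpolated, but only when the inter-anchor gap is at most
#' `maxGap` and the gap lengths on the two sequences agree within 20%
#' (otherwise the position is reported unmapped, which avoids false
#' empty-site calls inside rearrangements).
#'
#' @param om An [OrthoMap-class].
#' @param pos Position to lift (1-based).
#' @param from `"a"` or `"b"`: which genome `pos` lives on.
#' @param seqId Sequence name on the `from` side (may be omitted when the
#'   map has a single sequence pair).
#' @param fragmentId Restrict to one fragment (otherwise the fragment
#'   containing `pos` is located automatically).
#' @return A list with `pos` (lifted position or `NA`), `mapped` (logical),
#'   `seq_id` (target sequence) and `fragment_id`.
#' @export
liftCoordinate <- function(om, pos, from = c("a", "b"), seqId = NULL,
                           fragmentId = NULL) {
  from <- match.arg(from)
  fr <- om@fragments
  if (!is.null(fragmentId)) {
    fr <- fr[fr$fragment_id == fragmentId, , drop = FALSE]
  } else {
    sCol <- if (from == "a") "a_seq" else "b_seq"
    s0 <- if (from == "a") fr$a_start else fr$b_start
    s1 <- if (from == "a") fr$a_end else fr$b_end
    sel <- pos >= s0 & pos <= s1
    if (!is.null(seqId)) sel <- sel & fr[[sCol]] == seqId
    fr <- fr[sel, , drop = FALSE]
  }
  unmapped <- list(pos = NA_integer_, mapped = FALSE, seq_id = NA_character_,
                   fragment_id = NA_integer_)
  if (nrow(fr) == 0L) return(unmapped)
  fr <- fr[1L, , drop = FALSE]
  if (from == "a") {
    if (pos < fr$a_start || pos > fr$a_end) stop("pos outside fragment")
  } else {
    if (pos < fr$b_start || pos > fr$b_end) stop("pos outside fragment")
  }
  an <- om@anchors[om@anchors$fragment_id == fr$fragment_id, , drop = FALSE]
  ori <- fr$orientation
  if (from == "a") {
    p0 <- an$a_start; p1 <- an$a_end
    if (ori == "+") { q0 <- an$b_start; q1 <- an$b_end }
    else { q0 <- an$b_end; q1 <- an$b_start }  # q decreases with p
    tgt <- fr$b_seq
  } else {
    p0 <- an$b_start; p1 <- an$b_end
    if (ori == "+") { q0 <- an$a_start; q1 <- an$a_end }
    else { q0 <- an$a_end; q1 <- an$a_start }
    tgt <- fr$a_seq
  }
  o <- order(p0)
  p0 <- p0[o]; p1 <- p1[o]; q0 <- q0[o]; q1 <- q1[o]
  inA <- which(pos >= p0 & pos <= p1)
  sgn <- if (ori == "+") 1L else -1L
  if (length(inA)) {
    i <- inA[1L]
    q <- q0[i] + sgn * (pos - p0[i])
    return(list(pos = as.integer(q), mapped = TRUE, seq_id = tgt,
                fragment_id = fr$fragment_id))
  }
  i <- findInterval(pos, p0)  # anchor before pos
  if (i < 1L || i > length(p0)) return(unmapped)
  if (i == length(p0)) return(unmapped)  # past last anchor inside interval
  gapP <- p0[i + 1L] - p1[i] - 1L
  gapQ <- abs(q0[i + 1L] - q1[i]) - 1L
  if (gapP > om@maxGap) return(unmapped)
  if (abs(gapP - gapQ) > max(10, 0.2 * max(gapP, gapQ)))
    return(unmapped)
  frac <- (pos - p1[i]) / (gapP + 1)
  q <- q1[i] + sgn * as.integer(round(frac * (gapQ + 1)))
  list(pos = as.integer(q), mapped = TRUE, seq_id = tgt,
       fragment_id = fr$fragment_id)
}

#' Write / read the orthologous fragment table
#'
#' `writeFragmentTable` exports the fragment coordinates (1-based
#' inclusive, both genomes, with orientation and mean identity).
#' `writeOrthoMap`/`readOrthoMap` additionally persist the anchors so a map
#' can be reloaded for liftover.
#'
#' @param om An [OrthoMap-class].
#' @param path Output TSV path (for `writeOrthoMap`, a path prefix:
#'   `<path>.fragments.tsv` and `<path>.anchors.tsv`).
#' @return The path(s), invisibly; `readOrthoMap` returns an
#'   [OrthoMap-class].
#' @export
writeFragmentTable <- function(om, path) {
  fr <- om@fragments
  out <- data.frame(a_seq = fr$a_seq, a_start = fr$a_start, a_end = fr$a_end,
                    b_seq = fr$b_seq, b_start = fr$b_start, b_end = fr$b_end,
                    orientation = fr$orientation,
                    mean_identity = sprintf("%.4f", fr$mean_identity))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFragmentTable
#' @export
writeOrthoMap <- function(om, path) {
  fp <- paste0(path, ".fragments.tsv")
  ap <- paste0(path, ".anchors.tsv")
  fr <- om@fragments
  fr$mean_identity <- sprintf("%.6f", fr$mean_identity)
  fr$score <- sprintf("%.3f", fr$score)
  write.table(fr, fp, sep = "\t", quote = FALSE, row.names = FALSE)
  an <- om@anchors
  an$identity <- sprintf("%.6f", an$identity)
  write.table(an, ap, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fp, ap))
}

#' @rdname writeFragmentTable
#' @param maxGap Interpolation gap limit restored into the map.
#' @export
readOrthoMap <- function(path, maxGap = 10000) {
  fr <- read.delim(paste0(path, ".fragments.tsv"), stringsAsFactors = FALSE)
  an <- read.delim(paste0(path, ".anchors.tsv"), stringsAsFactors = FALSE)
  fr$mean_identity <- as.numeric(fr$mean_identity)
  fr$score <- as.numeric(fr$score)
  an$identity <- as.numeric(an$identity)
  fr$a_seq <- as.character(fr$a_seq); fr$b_seq <- as.character(fr$b_seq)
  an$a_seq <- as.character(an$a_seq); an$b_seq <- as.character(an$b_seq)
  new("OrthoMap", fragments = fr, anchors = an, maxGap = as.numeric(maxGap))
}
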