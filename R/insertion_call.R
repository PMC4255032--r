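# IUPAC-safe scoring matrix: N (and every other ambiguity letter) scores as
# a mismatch against everything, so assembly N-stretches can never produce
# spurious matched columns.
.subMatrix <- function(match = 1, mismatch = -2) {
  letters <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K", "V", "H",
               "D", "B", "N")
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m)[1:4] <- match
  m
}

.alignGlobal <- function(a, b, match = 1, mismatch = -2, gapOpen = 5,
                         gapExt = 1) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "global",
    substitutionMatrix = .subMatrix(match, mismatch),
    gapOpening = gapOpen, gapExtension = gapExt)
  list(pattern = as.character(Biostrings::alignedPattern(pa)),
       subject = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

.alignLocal <- function(a, b, match = 1, mismatch = -2, gapOpen = 5,
                        gapExt = 1) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "local",
    substitutionMatrix = .subMatrix(match, mismatch),
    gapOpening = gapOpen, gapExtension = gapExt)
  pstr <- as.character(Biostrings::alignedPattern(pa))
  sstr <- as.character(Biostrings::alignedSubject(pa))
  pv <- strsplit(pstr, "")[[1]]; sv <- strsplit(sstr, "")[[1]]
  nongap <- pv != "-" & sv != "-"
  list(pattern = pstr, subject = sstr, score = Biostrings::score(pa),
       p_start = Biostrings::start(Biostrings::pattern(pa)),
       p_end = Biostrings::end(Biostrings::pattern(pa)),
       s_start = Biostrings::start(Biostrings::subject(pa)),
       s_end = Biostrings::end(Biostrings::subject(pa)),
       matches = sum(nongap & pv == sv),
       aligned_cols = sum(nongap),
       identity = if (any(nongap)) sum(nongap & pv == sv) / sum(nongap) else 0)
}

# per-fragment anchor index for fast repeated liftover
.fragmentIndex <- function(om) {
  an <- om@anchors
  lapply(split(an, an$fragment_id), function(ch) {
    ch[order(ch$a_start), , drop = FALSE]
  })
}

# lift one position through a fragment's anchors.
# side: "a" (pos on A) or "b"; mode "strict" applies the gap-concordance
# rule, "nearest" always returns a position (clamping to the nearest anchor
# edge when interpolation is not allowed) -- used for window extraction.
.liftPoint <- function(ch, ori, pos, side = "a", mode = "strict",
                       maxGap = 10000) {
  if (side == "a") {
    p0 <- ch$a_start; p1 <- ch$a_end
    if (ori == "+") { q0 <- ch$b_start; q1 <- ch$b_end }
    else { q0 <- ch$b_end; q1 <- ch$b_start }
    o <- order(p0)
  } else {
    if (ori == "+") {
      p0 <- ch$b_start; p1 <- ch$b_end; q0 <- ch$a_start; q1 <- ch$a_end
    } else {
      p0 <- ch$b_start; p1 <- ch$b_end; q0 <- ch$a_end; q1 <- ch$a_start
    }
    o <- order(p0)
  }
  p0 <- p0[o]; p1 <- p1[o]; q0 <- q0[o]; q1 <- q1[o]
  sgn <- if (ori == "+") 1L else -1L
  n <- length(p0)
  if (pos < p0[1]) {
    return(if (mode == "nearest") q0[1] - sgn * (p0[1] - pos) else NA_integer_)
  }
  if (pos > p1[n]) {
    return(if (mode == "nearest") q1[n] + sgn * (pos - p1[n]) else NA_integer_)
  }
  i <- findInterval(pos, p0)
  if (pos <= p1[i]) {  # inside anchor i
    return(as.integer(q0[i] + sgn * (pos - p0[i])))
  }
  gapP <- p0[i + 1L] - p1[i] - 1L
  gapQ <- abs(q0[i + 1L] - q1[i]) - 1L
  concordant <- gapP <= maxGap &&
    abs(gapP - gapQ) <= max(10, 0.2 * max(gapP, gapQ))
  if (!concordant && mode == "strict") return(NA_integer_)
  frac <- (pos - p1[i]) / (gapP + 1)
  as.integer(q1[i] + sgn * round(frac * (gapQ + 1)))
}

#' Pair annotated insertions across the orthology map
#'
#' Lists the annotations of the two genomes "face to face": an insertion in
#' A is shared when its lifted span overlaps an insertion in B of the same
#' superfamily with reciprocal overlap at or above the threshold. Matching
#' is 1-to-1, greedy by descending overlap; remaining insertions become
#' species-specific candidates. Annotations outside every orthologous
#' fragment are excluded with a warning.
#'
#' @param annA,annB Insertion tables (the `insertions` element of
#'   [annotateRepeats()]) for genome A and genome B.
#' @param om An [OrthoMap-class] built from the same sequences.
#' @param minReciprocalOverlap Pairing threshold (default 0.5).
#' @return A list with `shared` (data.frame of pairs: element ids, lifted
#'   reciprocal overlap, superfamily, fragment), `unpaired_a`,
#'   `unpaired_b` (candidate tables with `fragment_id`), `excluded_a`,
#'   `excluded_b`.
#' @export
pairAnnotations <- function(annA, annB, om, minReciprocalOverlap = 0.5) {
  fr <- om@fragments
  fidx <- .fragmentIndex(om)
  locate <- function(ins, side) {
    s0 <- if (side == "a") fr$a_start else fr$b_start
    s1 <- if (side == "a") fr$a_end else fr$b_end
    sq <- if (side == "a") fr$a_seq else fr$b_seq
    vapply(seq_len(nrow(ins)), function(i) {
      j <- which(sq == ins$seq_id[i] & ins$span_start[i] >= s0 &
                   ins$span_end[i] <= s1)
      if (length(j)) fr$fragment_id[j[1]] else NA_integer_
    }, integer(1))
  }
  annA$fragment_id <- if (nrow(annA)) locate(annA, "a") else integer(0)
  annB$fragment_id <- if (nrow(annB)) locate(annB, "b") else integer(0)
  exA <- annA[is.na(annA$fragment_id), , drop = FALSE]
  exB <- annB[is.na(annB$fragment_id), , drop = FALSE]
  if (nrow(exA) || nrow(exB))
    warning(sprintf("%d annotation(s) outside orthologous fragments excluded",
                    nrow(exA) + nrow(exB)))
  annA <- annA[!is.na(annA$fragment_id), , drop = FALSE]
  annB <- annB[!is.na(annB$fragment_id), , drop = FALSE]
  # lift every A span to B ("nearest" mode: pairing only needs overlap)
  liftA <- matrix(NA_integer_, nrow(annA), 2)
  for (i in seq_len(nrow(annA))) {
    f <- annA$fragment_id[i]
    ori <- fr$orientation[fr$fragment_id == f]
    ch <- fidx[[as.character(f)]]
    x1 <- .liftPoint(ch, ori, annA$span_start[i], "a", "nearest", om@maxGap)
    x2 <- .liftPoint(ch, ori, annA$span_end[i], "a", "nearest", om@maxGap)
    liftA[i, ] <- sort(c(x1, x2))
  }
  # candidate pairs
  pairs <- NULL
  if (nrow(annA) && nrow(annB)) {
    cand <- list()
    for (i in seq_len(nrow(annA))) {
      f <- annA$fragment_id[i]
      bseq <- fr$b_seq[fr$fragment_id == f]
      js <- which(annB$seq_id == bseq &
                    annB$superfamily == annA$superfamily[i] &
                    annB$span_start <= liftA[i, 2] &
                    annB$span_end >= liftA[i, 1])
      if (!length(js)) next
      ov <- pmin(liftA[i, 2], annB$span_end[js]) -
        pmax(liftA[i, 1], annB$span_start[js]) + 1L
      wA <- liftA[i, 2] - liftA[i, 1] + 1L
      wB <- annB$span_end[js] - annB$span_start[js] + 1L
      # the native (unlifted) A width caps the reciprocal overlap:
      # interpolation across a one-sided gap can stretch a lifted span
      # over a much larger element, which must not count as reciprocal
      wOrig <- annA$span_end[i] - annA$span_start[i] + 1L
      rec <- pmin(ov / wA, ov / wB, wOrig / wB, wB / wOrig)
      ok <- rec >= minReciprocalOverlap
      if (any(ok))
        cand[[length(cand) + 1L]] <- data.frame(
          ia = i, ib = js[ok], reciprocal_overlap = rec[ok])
    }
    if (length(cand)) pairs <- do.call(rbind, cand)
  }
  shared <- data.frame(a_element_id = integer(0), b_element_id = integer(0),
                       superfamily = character(0), consensus_id = character(0),
                       fragment_id = integer(0),
                       reciprocal_overlap = numeric(0))
  usedA <- logical(nrow(annA)); usedB <- logical(nrow(annB))
  if (!is.null(pairs) && nrow(pairs)) {
    pairs <- pairs[order(-pairs$reciprocal_overlap, pairs$ia, pairs$ib), ,
                   drop = FALSE]
    keep <- logical(nrow(pairs))
    for (r in seq_len(nrow(pairs))) {
      if (!usedA[pairs$ia[r]] && !usedB[pairs$ib[r]]) {
        keep[r] <- TRUE
        usedA[pairs$ia[r]] <- TRUE
        usedB[pairs$ib[r]] <- TRUE
      }
    }
    pairs <- pairs[keep, , drop = FALSE]
    shared <- data.frame(
      a_element_id = annA$element_id[pairs$ia],
      b_element_id = annB$element_id[pairs$ib],
      superfamily = annA$superfamily[pairs$ia],
      consensus_id = annA$consensus_id[pairs$ia],
      fragment_id = annA$fragment_id[pairs$ia],
      reciprocal_overlap = pairs$reciprocal_overlap)
  }
  list(shared = shared,
       unpaired_a = annA[!usedA, , drop = FALSE],
       unpaired_b = annB[!usedB, , drop = FALSE],
       excluded_a = exA, excluded_b = exB)
}

#' Refine insertion boundaries from filled and empty site windows
#'
#' Globally aligns the filled window (carrier species, insertion plus
#' flanks) to the empty window (other species) with affine gap penalties;
#' the insertion is the single maximal gap block in the empty sequence. The
#' call is flagged unrefined when the flanking alignment identity drops
#' below `flankIdentityFloor` on either side.
#'
#' @param filled,empty Nucleotide window strings (filled = insertion span
#'   plus `flank` nt on each side; empty = lifted site plus flanks).
#' @param flank Flank width used to build the windows (nt).
#' @param minLen Minimum gap-block length accepted as an insertion
#'   (default 100, matching the annotation length filter).
#' @param flankIdentityFloor Per-side flanking identity floor (default
#'   0.90).
#' @param match,mismatch,gapOpen,gapExt Alignment scores.
#' @return A list: `found` (was a gap block >= `minLen` present),
#'   `ins_start`, `ins_end` (1-based positions of the insertion within
#'   `filled`), `length`, `empty_pos` (position in `empty` after which the
#'   insertion sits), `refined` (flank identities passed), `flank_identity`
#'   (length-2 numeric), `score`.
#' @export
refineBoundaries <- function(filled, empty, flank = 500L, minLen = 100L,
                             flankIdentityFloor = 0.90,
                             match = 1, mismatch = -2, gapOpen = 25,
                             gapExt = 1) {
  filled <- asSeqString(filled); empty <- asSeqString(empty)
  al <- .alignGlobal(filled, empty, match, mismatch, gapOpen, gapExt)
  pv <- strsplit(al$pattern, "")[[1]]
  sv <- strsplit(al$subject, "")[[1]]
  gap <- sv == "-"
  if (!any(gap))
    return(list(found = FALSE, refined = FALSE, reason = "no_gap_block"))
  r <- rle(gap)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gi <- which(r$values)
  best <- gi[which.max(r$lengths[gi])]
  blockLen <- r$lengths[best]
  if (blockLen < minLen)
    return(list(found = FALSE, refined = FALSE, reason = "gap_block_short",
                best_gap = blockLen))
  c0 <- starts[best]; c1 <- ends[best]
  fpos <- cumsum(pv != "-")
  epos <- cumsum(sv != "-")
  insStart <- fpos[c0]; insEnd <- fpos[c1]
  emptyPos <- if (c0 > 1L) epos[c0 - 1L] else 0L
  flankIdent <- function(cols) {
    ng <- cols[pv[cols] != "-" & sv[cols] != "-"]
    if (!length(ng)) return(0)
    sum(pv[ng] == sv[ng]) / length(ng)
  }
  idL <- if (c0 > 1L) flankIdent(seq_len(c0 - 1L)) else 0
  idR <- if (c1 < length(pv)) flankIdent((c1 + 1L):length(pv)) else 0
  list(found = TRUE,
       ins_start = insStart, ins_end = insEnd,
       length = insEnd - insStart + 1L,
       empty_pos = emptyPos,
       refined = idL >= flankIdentityFloor && idR >= flankIdentityFloor,
       flank_identity = c(idL, idR),
       score = al$score)
}

#' Flag candidate insertions opposite assembly N-stretches
#'
#' A candidate is an assembly artifact when its empty-site window contains
#' a run composed of at least `nFrac` N whose length matches the insertion
#' length within `lenTol` (draft-assembly gaps mimic insertions almost
#' exactly length-matched).
#'
#' @param emptyWindow Window string around the lifted empty site.
#' @param insertionLen Candidate insertion length (nt).
#' @param nFrac Minimum N fraction of the run (default 0.9).
#' @param lenTol Relative length tolerance (default 0.1).
#' @return Logical flag; attribute `"n_run"` carries the matched run length
#'   when TRUE.
#' @export
isAssemblyArtifact <- function(emptyWindow, insertionLen, nFrac = 0.9,
                               lenTol = 0.1) {
  s <- asSeqString(emptyWindow)
  x <- strsplit(s, "")[[1]] == "N"
  if (!any(x)) return(FALSE)
  r <- rle(x)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values],
                     n = r$lengths[r$values])
  # greedily merge adjacent N runs while the merged N fraction stays >= nFrac
  i <- 1L
  merged <- list()
  while (i <= nrow(runs)) {
    s0 <- runs$start[i]; e0 <- runs$end[i]; nn <- runs$n[i]
    j <- i + 1L
    while (j <= nrow(runs)) {
      nn2 <- nn + runs$n[j]
      len2 <- runs$end[j] - s0 + 1L
      if (nn2 / len2 >= nFrac) { e0 <- runs$end[j]; nn <- nn2; j <- j + 1L }
      else break
    }
    merged[[length(merged) + 1L]] <- c(len = e0 - s0 + 1L)
    i <- j
  }
  lens <- vapply(merged, function(z) z[["len"]], numeric(1))
  hit <- abs(lens - insertionLen) <= lenTol * insertionLen
  if (any(hit)) {
    out <- TRUE
    attr(out, "n_run") <- lens[which(hit)[1]]
    out
  } else FALSE
}

#' Count shared insertions per superfamily
#'
#' Counts are computed on the species-A record of each pair (shared
#' insertions are estimated on one genome only, to avoid double counting
#' split-hit artifacts on the other).
#'
#' @param shared Shared-pair data.frame from [pairAnnotations()] (or an
#'   [InsertionCalls-class]).
#' @return A data.frame with columns `superfamily` and `n`, with a final
#'   `total` row.
#' @export
countShared <- function(shared) {
  if (is(shared, "InsertionCalls")) shared <- shared@shared
  if (nrow(shared) == 0L) {
    return(data.frame(superfamily = "total", n = 0L))
  }
  tab <- table(shared$superfamily)
  df <- data.frame(superfamily = names(tab), n = as.integer(tab))
  df <- df[order(df$superfamily), , drop = FALSE]
  rbind(df, data.frame(superfamily = "total", n = nrow(shared)))
}

#' Insertion call set
#'
#' Result container of [callInsertions()]: species-specific insertion
#' calls with refined boundaries, TSDs and artifact flags, the shared
#' pairs, and a full accounting of every annotated insertion inside the
#' orthologous fragments.
#'
#' @slot calls data.frame of candidate evaluations, one row per unpaired
#'   annotated insertion (columns include `call_id`, `species`, `seq_id`,
#'   `start`, `end`, `length`, `status`, `refined`, `tsd`, `tsd_class`,
#'   `empty_seq_id`, `empty_pos`, `superfamily`, ...).
#' @slot shared data.frame of shared pairs (see [pairAnnotations()]).
#' @slot accounting data.frame of per-status counts by species.
#' @slot analyzedBp Total aligned fragment span on genome A (nt) used as
#'   the denominator of the divergence summary.
#' @slot params List of calling parameters.
#' @export
setClass("InsertionCalls",
  representation(calls = "data.frame", shared = "data.frame",
                 accounting = "data.frame", analyzedBp = "numeric",
                 params = "list"))

setMethod("show", "InsertionCalls", function(object) {
  sp <- object@calls[object@calls$status == "specific", , drop = FALSE]
  cat(sprintf(
    "InsertionCalls: %d shared pair(s); %d specific call(s) (A: %d, B: %d)\n",
    nrow(object@shared), nrow(sp), sum(sp$species == "A"),
    sum(sp$species == "B")))
  cat(sprintf("analyzed span on A: %.3f Mb\n", object@analyzedBp / 1e6))
  print(object@accounting, row.names = FALSE)
  invisible(NULL)
})

#' @rdname InsertionCalls-class
#' @param x An `InsertionCalls`.
#' @export
insertionCalls <- function(x) x@calls

#' @rdname InsertionCalls-class
#' @export
specificCalls <- function(x) {
  x@calls[x@calls$status == "specific", , drop = FALSE]
}

#' @rdname InsertionCalls-class
#' @export
sharedPairs <- function(x) x@shared

#' @rdname InsertionCalls-class
#' @export
analyzedBp <- function(x) x@analyzedBp

#' Call species-specific TE insertions between two genomes
#'
#' The full filled/empty-site protocol: pair annotations across the
#' orthology map, evaluate every unpaired insertion as a candidate
#' (assembly-artifact screen, boundary refinement by global alignment of
#' filled and empty windows, TSD detection with placement sliding), and
#' detect solo-LTR recombination events for LTR-element calls whose empty
#' site matches one LTR.
#'
#' @param annA,annB Annotation results (lists from [annotateRepeats()]) for
#'   genome A and B.
#' @param om [OrthoMap-class] between the genomes.
#' @param genomeA,genomeB The sequences (named `DNAStringSet` or named
#'   character vectors) the annotations refer to.
#' @param library The [TELibrary-class] used for annotation.
#' @param flank Window flank width for refinement (nt, default 500).
#' @param minReciprocalOverlap Pairing threshold (default 0.5).
#' @param minLen Minimum refined insertion length (default 100 nt).
#' @param flankIdentityFloor Refinement flank identity floor (default 0.90).
#' @param nFrac,lenTol Assembly-artifact screen parameters, see
#'   [isAssemblyArtifact()].
#' @return An [InsertionCalls-class].
#' @export
callInsertions <- function(annA, annB, om, genomeA, genomeB, library,
                           flank = 500L, minReciprocalOverlap = 0.5,
                           minLen = 100L, flankIdentityFloor = 0.90,
                           nFrac = 0.9, lenTol = 0.1) {
  gA <- lapply(as.list(as.character(
    if (is.character(genomeA)) genomeA else as.character(genomeA))), toupper)
  gB <- lapply(as.list(as.character(
    if (is.character(genomeB)) genomeB else as.character(genomeB))), toupper)
  if (is.null(names(gA))) names(gA) <- names(genomeA)
  if (is.null(names(gB))) names(gB) <- names(genomeB)
  fr <- om@fragments
  fidx <- .fragmentIndex(om)
  pr <- pairAnnotations(annA$insertions, annB$insertions, om,
                        minReciprocalOverlap = minReciprocalOverlap)

  evalCandidate <- function(ins, species) {
    # ins: one row of an insertion table with fragment_id
    f <- ins$fragment_id
    frow <- fr[fr$fragment_id == f, , drop = FALSE]
    ori <- frow$orientation
    ch <- fidx[[as.character(f)]]
    if (species == "A") {
      carrier <- gA[[ins$seq_id]]; otherSeqId <- frow$b_seq
      other <- gB[[otherSeqId]]; side <- "a"
    } else {
      carrier <- gB[[ins$seq_id]]; otherSeqId <- frow$a_seq
      other <- gA[[otherSeqId]]; side <- "b"
    }
    s <- ins$span_start; e <- ins$span_end
    fw0 <- max(1L, s - flank); fw1 <- min(nchar(carrier), e + flank)
    filled <- substr(carrier, fw0, fw1)
    l1 <- .liftPoint(ch, ori, max(1L, s - 1L), side, "nearest", om@maxGap)
    l2 <- .liftPoint(ch, ori, min(nchar(carrier), e + 1L), side, "nearest",
                     om@maxGap)
    bl <- min(l1, l2); br <- max(l1, l2)
    ew0 <- max(1L, bl - flank); ew1 <- min(nchar(other), br + flank)
    empty <- substr(other, ew0, ew1)
    # carrier orientation for the empty window
    flipped <- (species == "A" && ori == "-") ||
      (species == "B" && ori == "-")
    if (flipped) empty <- revComp(empty)
    out <- list(filled_offset = fw0, empty_offset = ew0,
                empty_flipped = flipped, empty_seq_id = otherSeqId,
                empty_window = empty, filled_window = filled,
                lift_left = bl, lift_right = br)
    art <- isAssemblyArtifact(empty, e - s + 1L, nFrac = nFrac,
                              lenTol = lenTol)
    if (isTRUE(art)) {
      out$status <- "artifact"
      out$n_run <- attr(art, "n_run")
      return(out)
    }
    rb <- refineBoundaries(filled, empty, flank = flank, minLen = minLen,
                           flankIdentityFloor = flankIdentityFloor)
    if (!rb$found) {
      out$status <- "rejected"
      out$reason <- rb$reason
      return(out)
    }
    out$status <- "specific"
    out$refined <- rb$refined
    out$ins_start <- fw0 + rb$ins_start - 1L
    out$ins_end <- fw0 + rb$ins_end - 1L
    out$length <- rb$length
    out$flank_identity <- rb$flank_identity
    # empty-site position in the *other* genome's forward coordinates
    ep <- ew0 + rb$empty_pos - 1L
    if (flipped) ep <- ew0 + (nchar(empty) - rb$empty_pos) - 1L
    out$empty_pos <- ep
    # TSD from the refined filled interval; when the exact placement shows
    # neither a duplication nor a poly-A/AT-rich context, allow small
    # independent boundary displacements (refinement can be off by a few
    # nt at degenerate breakpoints)
    tsd <- insertionTSD(carrier, out$ins_start, out$ins_end)
    if (tsd$class == "not_detected") {
      t2 <- insertionTSD(carrier, out$ins_start, out$ins_end, wobble = 4L,
                         independentEnds = TRUE)
      if (t2$class == "TSD") tsd <- t2
    }
    out$tsd <- tsd$sequence
    out$tsd_class <- tsd$class
    out$tsd_start <- tsd$ins_start
    out$tsd_end <- tsd$ins_end
    out
  }

  rowsFor <- function(up, species) {
    if (nrow(up) == 0L) return(NULL)
    res <- vector("list", nrow(up))
    for (i in seq_len(nrow(up))) {
      ev <- evalCandidate(up[i, , drop = FALSE], species)
      res[[i]] <- data.frame(
        species = species, seq_id = up$seq_id[i],
        element_id = up$element_id[i],
        consensus_id = up$consensus_id[i],
        superfamily = up$superfamily[i],
        strand = up$strand[i],
        fragment_id = up$fragment_id[i],
        span_start = up$span_start[i], span_end = up$span_end[i],
        divergence = up$divergence[i],
        n_components = up$n_components[i],
        status = ev$status,
        refined = ev$refined %||% NA,
        start = ev$tsd_start %||% ev$ins_start %||% NA_integer_,
        end = ev$tsd_end %||% ev$ins_end %||% NA_integer_,
        length = if (!is.null(ev$tsd_start)) ev$tsd_end - ev$tsd_start + 1L
                 else ev$length %||% NA_integer_,
        empty_seq_id = ev$empty_seq_id,
        empty_pos = ev$empty_pos %||% NA_integer_,
        tsd = ev$tsd %||% NA_character_,
        tsd_class = ev$tsd_class %||% NA_character_,
        n_run = ev$n_run %||% NA_real_,
        reject_reason = ev$reason %||% NA_character_,
        flank_identity_l = (ev$flank_identity %||% c(NA_real_, NA_real_))[1],
        flank_identity_r = (ev$flank_identity %||% c(NA_real_, NA_real_))[2],
        solo_ltr = FALSE, solo_identity = NA_real_,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, res)
  }

  calls <- rbind(rowsFor(pr$unpaired_a, "A"), rowsFor(pr$unpaired_b, "B"))
  if (is.null(calls)) {
    calls <- data.frame(species = character(0), seq_id = character(0),
                        element_id = integer(0), status = character(0),
                        stringsAsFactors = FALSE)
  } else {
    calls <- calls[order(calls$species, calls$seq_id, calls$span_start), ,
                   drop = FALSE]
    rownames(calls) <- NULL
    calls$call_id <- seq_len(nrow(calls))
  }

  # solo-LTR recombination screening for specific LTR-element calls.
  # The refined interval is the filled/empty difference (internal region
  # plus one LTR), so LTR detection and TSD search use the full annotated
  # element span instead.
  info <- consensusInfo(library)
  ltrIds <- info$id[!is.na(info$ltr_length)]
  spec <- which(calls$status == "specific" & calls$consensus_id %in% ltrIds)
  for (i in spec) {
    carrier <- if (calls$species[i] == "A") gA[[calls$seq_id[i]]]
               else gB[[calls$seq_id[i]]]
    other <- if (calls$species[i] == "A") gB[[calls$empty_seq_id[i]]]
             else gA[[calls$empty_seq_id[i]]]
    elem <- substr(carrier, calls$span_start[i], calls$span_end[i])
    lp <- detectLTRs(elem)
    if (is.null(lp) || lp$type != "LTR") next
    spanTSD <- insertionTSD(carrier, calls$span_start[i],
                            calls$span_end[i], wobble = 8L,
                            independentEnds = TRUE)
    ltrLen <- lp$length
    w0 <- max(1L, calls$empty_pos[i] - ltrLen - 200L)
    w1 <- min(nchar(other), calls$empty_pos[i] + ltrLen + 200L)
    emptySite <- substr(other, w0, w1)
    ev <- callSoloLTR(elem, lp, emptySite,
                      tsd = if (spanTSD$class == "TSD") spanTSD$sequence
                            else NA)
    if (!is.null(ev)) {
      calls$solo_ltr[i] <- TRUE
      calls$solo_identity[i] <- ev$ltr_identity_to_solo
      # for a recombination event the element of record is the full
      # LTR-to-LTR span, framed by the span-level TSD
      calls$start[i] <- calls$span_start[i]
      calls$end[i] <- calls$span_end[i]
      calls$length[i] <- calls$span_end[i] - calls$span_start[i] + 1L
      calls$tsd[i] <- spanTSD$sequence
      calls$tsd_class[i] <- spanTSD$class
      # reclassify the counterpart annotation (the solo LTR itself, which
      # shows up as a rejected -- or occasionally mis-refined -- candidate
      # at the orthologous site)
      j <- which(calls$species != calls$species[i] &
                   calls$seq_id == calls$empty_seq_id[i] &
                   calls$status %in% c("rejected", "specific") &
                   calls$consensus_id == calls$consensus_id[i] &
                   abs((calls$span_start + calls$span_end) / 2 -
                         calls$empty_pos[i]) < ltrLen + 500)
      if (length(j)) calls$status[j] <- "solo_ltr_counterpart"
    }
  }

  acc <- as.data.frame(table(species = calls$species, status = calls$status))
  names(acc)[3] <- "n"
  analyzed <- if (nrow(fr)) sum(fr$a_end - fr$a_start + 1) else 0
  new("InsertionCalls", calls = calls, shared = pr$shared,
      accounting = acc, analyzedBp = as.numeric(analyzed),
      params = list(flank = flank,
                    minReciprocalOverlap = minReciprocalOverlap,
                    minLen = minLen,
                    flankIdentityFloor = flankIdentityFloor,
                    nFrac = nFrac, lenTol = lenTol,
                    excluded_a = nrow(pr$excluded_a),
                    excluded_b = nrow(pr$excluded_b)))
}

#' Export insertion calls
#'
#' `writeCallsBED` writes specific calls as BED6 (0-based half-open,
#' score = divergence x 1000); `writeCallsJSON` writes one JSON record per
#' candidate with status, TSD and empty-site coordinates; `writeCallsTSV`
#' writes the full candidate table (1-based inclusive).
#'
#' @param x An [InsertionCalls-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeCallsBED <- function(x, path) {
  sp <- specificCalls(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# BED6: 0-based half-open; score = divergence x 1000", con)
  if (nrow(sp)) {
    lines <- sprintf("%s\t%d\t%d\tte%04d\t%d\t%s",
                     sp$seq_id, sp$start - 1L, sp$end, sp$element_id,
                     as.integer(round(sp$divergence * 1000)), sp$strand)
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname writeCallsBED
#' @export
writeCallsJSON <- function(x, path) {
  df <- x@calls
  jsonlite::write_json(df, path, auto_unbox = FALSE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writeCallsBED
#' @export
writeCallsTSV <- function(x, path) {
  df <- x@calls
  num <- vapply(df, is.numeric, logical(1))
  for (cn in names(df)[num]) {
    if (cn %in% c("divergence", "solo_identity", "flank_identity_l",
                  "flank_identity_r"))
      df[[cn]] <- ifelse(is.na(df[[cn]]), NA, sprintf("%.4f", df[[cn]]))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
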