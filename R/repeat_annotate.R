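#' @importFrom data.table data.table setkey setorder := .N rbindlist as.data.table
NULL

.emptyHits <- function() {
  data.frame(seq_id = character(0), g_start = integer(0), g_end = integer(0),
             strand = character(0), consensus_id = character(0),
             c_start = integer(0), c_end = integer(0),
             identity = numeric(0), divergence = numeric(0),
             score = numeric(0), stringsAsFactors = FALSE)
}

# k-mer table of a consensus on both strands: columns h, c_pos, strand
.consensusKmers <- function(cons, k) {
  s <- asSeqString(cons)
  L <- nchar(s)
  fwd <- kmerHashes(seqCodes(s), k)
  rcs <- revComp(s)
  rev <- kmerHashes(seqCodes(rcs), k)
  dt <- rbind(
    data.table(h = fwd, c_pos = seq_along(fwd), strand = "+"),
    data.table(h = rev, c_pos = L - seq_along(rev) - k + 2L, strand = "-"))
  dt[!is.na(dt$h)]
}

#' Exact k-mer seed matches between a sequence and a TE library
#'
#' Every exact k-mer shared between the query sequence and a consensus (on
#' either strand) yields one anchor. Anchors whose genomic k-mer window lies
#' fully inside a low-complexity mask interval are dropped.
#'
#' @param seq Query nucleotide sequence (character or `DNAString`).
#' @param library A [TELibrary-class].
#' @param k Seed length; must satisfy `8 <= k <= 16`.
#' @param mask Optional [IRanges::IRanges] of masked intervals (e.g. from
#'   [maskLowComplexity()]).
#' @return A data.frame with columns `g_pos` (1-based start on the query),
#'   `consensus_id`, `c_pos` (1-based start of the matched window on the
#'   consensus, forward coordinates), `strand`.
#' @export
seedMatches <- function(seq, library, k = 12L, mask = NULL) {
  if (k < 8L || k > 16L) stop("k must be between 8 and 16")
  s <- asSeqString(seq)
  gh <- kmerHashes(seqCodes(s), k)
  gdt <- data.table(h = gh, g_pos = seq_along(gh))
  gdt <- gdt[!is.na(gdt$h)]
  out <- vector("list", length(library))
  ids <- consensusIds(library)
  for (i in seq_along(ids)) {
    cdt <- .consensusKmers(consensusSeq(library, ids[i]), k)
    hitdt <- gdt[cdt, on = "h", allow.cartesian = TRUE, nomatch = NULL]
    if (nrow(hitdt)) {
      hitdt[, `:=`(consensus_id = ids[i], h = NULL)]
      out[[i]] <- hitdt
    }
  }
  res <- rbindlist(out)
  if (is.null(res) || nrow(res) == 0L) {
    return(data.frame(g_pos = integer(0), consensus_id = character(0),
                      c_pos = integer(0), strand = character(0)))
  }
  if (!is.null(mask) && length(mask)) {
    anc <- IRanges::IRanges(start = res$g_pos, width = k)
    inside <- IRanges::overlapsAny(anc, mask, type = "within")
    res <- res[!inside]
  }
  setorder(res, g_pos, consensus_id, c_pos)
  as.data.frame(res[, c("g_pos", "consensus_id", "c_pos", "strand")])
}

#' Extend a seed anchor into a local repeat hit
#'
#' Banded gapped extension with x-drop termination in both directions from
#' an exact k-mer anchor, BLASTN-style. Identity is computed from the final
#' alignment as matches over aligned non-gap columns; divergence is
#' `1 - identity`.
#'
#' @param seq Genomic sequence (character or `DNAString`).
#' @param consensus Consensus sequence (character or `DNAString`).
#' @param gPos,cPos 1-based start of the exact seed on `seq` and on the
#'   consensus (forward coordinates; for `strand = "-"` the genomic window
#'   must equal the reverse complement of the consensus window).
#' @param strand `"+"` or `"-"`.
#' @param k Seed length.
#' @param match,mismatch,gapOpen,gapExt,xdrop Alignment scores (defaults
#'   match +1, mismatch -2, gap open 5, gap extension 1, x-drop 20).
#' @param band Band half-width around the seed diagonal.
#' @param seqId,consensusId Identifiers copied into the output record.
#' @return A one-row data.frame (a repeat hit) with columns `seq_id`,
#'   `g_start`, `g_end`, `strand`, `consensus_id`, `c_start`, `c_end`,
#'   `identity`, `divergence`, `score`.
#' @export
extendHit <- function(seq, consensus, gPos, cPos, strand = "+", k = 12L,
                      match = 1L, mismatch = -2L, gapOpen = 5L, gapExt = 1L,
                      xdrop = 20L, band = 50L,
                      seqId = "seq", consensusId = "consensus") {
  sFull <- if (is.character(seq) && length(seq) == 1L) seq
           else asSeqString(seq)
  cs <- asSeqString(consensus)
  L <- nchar(cs)
  # the extension is bounded by the consensus length plus the band, so
  # only a window of the genome needs to cross into the C++ kernel
  pad <- L + band + 16L
  w0 <- max(1L, gPos - pad)
  w1 <- min(nchar(sFull), gPos + k - 1L + pad)
  s <- toupper(substr(sFull, w0, w1))
  gPos <- gPos - w0 + 1L
  gword <- substr(s, gPos, gPos + k - 1L)
  if (strand == "+") {
    cword <- substr(cs, cPos, cPos + k - 1L)
    if (gword != cword) stop("anchor is not an exact seed match")
    r <- cpp_xdrop_extend(s, cs, gPos, cPos, k, match, mismatch,
                          gapOpen, gapExt, xdrop, band)
    cStart <- r$b_start; cEnd <- r$b_end
  } else {
    cword <- revComp(substr(cs, cPos, cPos + k - 1L))
    if (gword != cword) stop("anchor is not an exact seed match")
    crc <- revComp(cs)
    bPos <- L - (cPos + k - 1L) + 1L
    r <- cpp_xdrop_extend(s, crc, gPos, bPos, k, match, mismatch,
                          gapOpen, gapExt, xdrop, band)
    cStart <- L - r$b_end + 1L; cEnd <- L - r$b_start + 1L
  }
  r$a_start <- r$a_start + w0 - 1L
  r$a_end <- r$a_end + w0 - 1L
  data.frame(seq_id = seqId, g_start = r$a_start, g_end = r$a_end,
             strand = strand, consensus_id = consensusId,
             c_start = cStart, c_end = cEnd,
             identity = r$identity, divergence = 1 - r$identity,
             score = r$score, stringsAsFactors = FALSE)
}

#' Filter repeat hits by length and divergence
#'
#' Keeps hits with genomic length `>= min_len` and divergence to the
#' consensus `<= max_div` (both bounds inclusive). Hits lying fully inside a
#' low-complexity mask interval are removed.
#'
#' @param hits A repeat-hit data.frame (see [extendHit()]).
#' @param min_len Minimum genomic hit length in nt (default 100).
#' @param max_div Maximum divergence fraction (default 0.20).
#' @param mask Optional [IRanges::IRanges] of masked intervals.
#' @return The filtered data.frame.
#' @export
filterHits <- function(hits, min_len = 100L, max_div = 0.20, mask = NULL) {
  if (min_len < 0 || max_div < 0) stop("thresholds must be >= 0")
  if (nrow(hits) == 0L) return(hits)
  keep <- (hits$g_end - hits$g_start + 1L) >= min_len &
    hits$divergence <= max_div
  if (!is.null(mask) && length(mask)) {
    rng <- IRanges::IRanges(start = hits$g_start, end = hits$g_end)
    keep <- keep & !IRanges::overlapsAny(rng, mask, type = "within")
  }
  hits[keep, , drop = FALSE]
}

# pairwise merge predicate used by mergeSplitHits (and, independently, by
# the brute-force closure oracle in the tests): can two hits of the same
# seq/consensus/strand group belong to the same element? Vectorized over j.
.hitsMergeablePair <- function(gs_i, ge_i, cs_i, ce_i, strand_i,
                               gs_j, ge_j, cs_j, ce_j,
                               maxGenomeGap, maxConsOverlap) {
  # caller guarantees gs_i <= gs_j
  gapG <- gs_j - ge_i - 1L
  ok <- gapG <= maxGenomeGap & gapG >= -(maxConsOverlap + 1L)
  if (strand_i == "+") {
    ok & cs_j >= ce_i - maxConsOverlap
  } else {
    ok & ce_j <= cs_i + maxConsOverlap
  }
}

#' Merge split hits into annotated insertions
#'
#' Hits with the same consensus and strand whose genomic gap is at most
#' `maxGenomeGap` and whose consensus coordinates advance consistently
#' (overlap at most `maxConsOverlap`) are merged, transitively, into a
#' single insertion with a common element number -- the automated
#' counterpart of counting close collinear fragments of one element as a
#' unique insertion.
#'
#' @param hits A repeat-hit data.frame for one or more sequences.
#' @param maxGenomeGap Maximum genomic gap between merged components (nt).
#' @param maxConsOverlap Maximum overlap on the consensus (nt) still deemed
#'   "advancing".
#' @param library Optional [TELibrary-class] used to attach superfamily
#'   labels.
#' @return A list with `insertions` (one row per merged insertion:
#'   `element_id`, `seq_id`, `consensus_id`, `superfamily`, `strand`,
#'   `span_start`, `span_end`, `n_components`, `total_length`,
#'   `divergence`, `score`) and `hits` (the input hits with an added
#'   `element_id` column). Insertions are sorted by `seq_id`, `span_start`.
#' @export
mergeSplitHits <- function(hits, maxGenomeGap = 5000L, maxConsOverlap = 50L,
                           library = NULL) {
  if (nrow(hits) == 0L) {
    ins <- data.frame(element_id = integer(0), seq_id = character(0),
                      consensus_id = character(0), superfamily = character(0),
                      strand = character(0), span_start = integer(0),
                      span_end = integer(0), n_components = integer(0),
                      total_length = integer(0), divergence = numeric(0),
                      score = numeric(0), stringsAsFactors = FALSE)
    return(list(insertions = ins, hits = cbind(hits, element_id = integer(0))))
  }
  hits <- hits[order(hits$seq_id, hits$g_start, hits$g_end), , drop = FALSE]
  rownames(hits) <- NULL
  grp <- paste(hits$seq_id, hits$consensus_id, hits$strand, sep = "\r")
  comp <- integer(nrow(hits))  # global component id
  nextComp <- 0L
  for (g in unique(grp)) {
    idx <- which(grp == g)
    m <- length(idx)
    gs <- hits$g_start[idx]; ge <- hits$g_end[idx]
    cs <- hits$c_start[idx]; ce <- hits$c_end[idx]
    str1 <- hits$strand[idx[1]]
    parent <- seq_len(m)
    findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (m > 1L) {
      for (i in seq_len(m - 1L)) {
        # hits are sorted by g_start; only downstream hits within the
        # genomic gap window can merge with i
        js <- which(gs > ge[i] + maxGenomeGap + 1L)
        jmax <- if (length(js)) min(js) - 1L else m
        if (jmax <= i) next
        js <- (i + 1L):jmax
        ok <- .hitsMergeablePair(gs[i], ge[i], cs[i], ce[i], str1,
                                 gs[js], ge[js], cs[js], ce[js],
                                 maxGenomeGap, maxConsOverlap)
        for (j in js[ok]) {
          ri <- findRoot(i); rj <- findRoot(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    roots <- vapply(seq_len(m), findRoot, integer(1))
    comp[idx] <- nextComp + match(roots, unique(roots))
    nextComp <- nextComp + length(unique(roots))
  }
  agg <- lapply(split(seq_len(nrow(hits)), comp), function(ii) {
    h <- hits[ii, , drop = FALSE]
    data.frame(
      seq_id = h$seq_id[1], consensus_id = h$consensus_id[1],
      strand = h$strand[1],
      span_start = min(h$g_start), span_end = max(h$g_end),
      n_components = nrow(h),
      total_length = sum(h$g_end - h$g_start + 1L),
      divergence = sum((h$g_end - h$g_start + 1L) * h$divergence) /
        sum(h$g_end - h$g_start + 1L),
      score = sum(h$score), stringsAsFactors = FALSE)
  })
  ins <- do.call(rbind, agg)
  compOf <- as.integer(names(agg))
  ord <- order(ins$seq_id, ins$span_start, ins$span_end)
  ins <- ins[ord, , drop = FALSE]
  ins$element_id <- seq_len(nrow(ins))
  rownames(ins) <- NULL
  eidOfComp <- setNames(ins$element_id, compOf[ord])
  hits$element_id <- as.integer(eidOfComp[as.character(comp)])
  ins$superfamily <- if (!is.null(library)) {
    unname(superfamilyOf(library)[ins$consensus_id])
  } else NA_character_
  ins <- ins[, c("element_id", "seq_id", "consensus_id", "superfamily",
                 "strand", "span_start", "span_end", "n_components",
                 "total_length", "divergence", "score")]
  list(insertions = ins, hits = hits)
}

# Candidate-cluster seeding: collapse all seed anchors of one consensus
# into same-diagonal runs, then chain nearby runs into candidate regions,
# and return one representative anchor per candidate. This keeps the number
# of gapped extensions proportional to the number of true copies.
.candidateAnchors <- function(gdt, cons, consId, k,
                              runJoin = 12L, clusterGap = 150L,
                              diagDrift = 30L,
                              minClusterKmers = 4L, minRunSpan = 20L) {
  cdt <- .consensusKmers(cons, k)
  hit <- gdt[cdt, on = "h", allow.cartesian = TRUE, nomatch = NULL]
  if (nrow(hit) == 0L) return(NULL)
  hit[, diag := ifelse(strand == "+", g_pos - c_pos, g_pos + c_pos)]
  setorder(hit, strand, diag, g_pos)
  newRun <- c(TRUE, hit$strand[-1] != hit$strand[-nrow(hit)] |
                hit$diag[-1] != hit$diag[-nrow(hit)] |
                (hit$g_pos[-1] - hit$g_pos[-nrow(hit)]) > runJoin)
  hit[, run := cumsum(newRun)]
  runs <- hit[, list(strand = strand[1], diag = diag[1],
                     g_min = min(g_pos), g_max = max(g_pos) + k - 1L,
                     c_rep = c_pos[(.N + 1L) %/% 2L],
                     g_rep = g_pos[(.N + 1L) %/% 2L],
                     kcount = .N), by = "run"]
  setorder(runs, strand, g_min)
  n <- nrow(runs)
  newCl <- c(TRUE, runs$strand[-1] != runs$strand[-n] |
               (runs$g_min[-1] - runs$g_max[-n]) > clusterGap |
               abs(runs$diag[-1] - runs$diag[-n]) > diagDrift)
  runs[, cl := cumsum(newCl)]
  cand <- runs[, list(strand = strand[1],
                      kmers = sum(kcount),
                      bestSpan = max(g_max - g_min + 1L),
                      bestRun = .I[which.max(kcount)][1]), by = "cl"]
  cand <- cand[cand$kmers >= minClusterKmers | cand$bestSpan >= minRunSpan]
  if (nrow(cand) == 0L) return(NULL)
  data.frame(g_pos = runs$g_rep[cand$bestRun],
             c_pos = runs$c_rep[cand$bestRun],
             strand = cand$strand,
             consensus_id = consId, stringsAsFactors = FALSE)
}

# drop hits to the same consensus that duplicate a better hit (>90% overlap
# of the smaller one)
.dedupeHits <- function(hits) {
  if (nrow(hits) <= 1L) return(hits)
  keep <- rep(TRUE, nrow(hits))
  ord <- order(-hits$score)
  rng <- IRanges::IRanges(start = hits$g_start, end = hits$g_end)
  for (ii in seq_along(ord)) {
    i <- ord[ii]
    if (!keep[i]) next
    later <- ord[-seq_len(ii)]
    later <- later[keep[later] & hits$consensus_id[later] == hits$consensus_id[i] &
                     hits$seq_id[later] == hits$seq_id[i]]
    if (!length(later)) next
    ov <- IRanges::pintersect(rep(rng[i], length(later)), rng[later],
                              resolve.empty = "max.start")
    wmin <- pmin(IRanges::width(rng[later]), IRanges::width(rng[i]))
    dup <- IRanges::width(ov) > 0.9 * wmin
    keep[later[dup]] <- FALSE
  }
  hits[keep, , drop = FALSE]
}

#' Annotate TE copies in a genomic sequence
#'
#' Full annotation of one sequence against a consensus library: exact k-mer
#' seeding, collapse of seeds into candidate regions, banded x-drop
#' extension, length / divergence filtering, removal of hits inside
#' low-complexity masked intervals, and merging of split hits into
#' insertions with common element numbers.
#'
#' @param seq Genomic sequence (character or `DNAString`).
#' @param library A [TELibrary-class].
#' @param seqId Sequence identifier used in the output.
#' @param k Seed length (default 12).
#' @param match,mismatch,gapOpen,gapExt,xdrop,band Extension scores, see
#'   [extendHit()].
#' @param min_len,max_div Hit filters, see [filterHits()].
#' @param maxGenomeGap,maxConsOverlap Merge parameters, see
#'   [mergeSplitHits()].
#' @param mask Low-complexity mask; `NULL` (default) computes it with
#'   [maskLowComplexity()]; pass an empty `IRanges` to disable masking.
#' @return As [mergeSplitHits()]: a list with `insertions` and `hits`.
#' @export
annotateRepeats <- function(seq, library, seqId = "seq", k = 12L,
                            match = 1L, mismatch = -2L, gapOpen = 5L,
                            gapExt = 1L, xdrop = 20L, band = 50L,
                            min_len = 100L, max_div = 0.20,
                            maxGenomeGap = 5000L, maxConsOverlap = 50L,
                            mask = NULL) {
  s <- asSeqString(seq)
  if (is.null(mask)) mask <- maskLowComplexity(s)
  gh <- kmerHashes(seqCodes(s), k)
  gdt <- data.table(h = gh, g_pos = seq_along(gh))
  gdt <- gdt[!is.na(gdt$h)]
  if (length(mask)) {
    anc <- IRanges::IRanges(start = gdt$g_pos, width = k)
    gdt <- gdt[!IRanges::overlapsAny(anc, mask, type = "within")]
  }
  setkey(gdt, h)
  ids <- consensusIds(library)
  allHits <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    cons <- consensusSeq(library, ids[i])
    cand <- .candidateAnchors(gdt, cons, ids[i], k)
    if (is.null(cand)) next
    rows <- vector("list", nrow(cand))
    for (j in seq_len(nrow(cand))) {
      rows[[j]] <- extendHit(s, cons, cand$g_pos[j], cand$c_pos[j],
                             strand = cand$strand[j], k = k,
                             match = match, mismatch = mismatch,
                             gapOpen = gapOpen, gapExt = gapExt,
                             xdrop = xdrop, band = band,
                             seqId = seqId, consensusId = ids[i])
    }
    allHits[[i]] <- do.call(rbind, rows)
  }
  hits <- do.call(rbind, allHits)
  if (is.null(hits)) hits <- .emptyHits()
  hits <- .dedupeHits(hits)
  hits <- filterHits(hits, min_len = min_len, max_div = max_div, mask = mask)
  mergeSplitHits(hits, maxGenomeGap = maxGenomeGap,
                 maxConsOverlap = maxConsOverlap, library = library)
}

#' Write / read repeat annotation tables
#'
#' The TSV mirrors RepeatMasker-style output (1-based inclusive
#' coordinates): `seq`, `begin`, `end`, `strand`, `repeat_id`,
#' `superfamily`, `cons_begin`, `cons_end`, `pct_div`, `element_id`.
#'
#' @param annot Result of [annotateRepeats()] / [mergeSplitHits()].
#' @param path Output file path.
#' @return `path` invisibly (`writeAnnotationTSV`); a list with
#'   `insertions` and `hits` (`readAnnotationTSV`).
#' @export
writeAnnotationTSV <- function(annot, path) {
  h <- annot$hits
  df <- data.frame(seq = h$seq_id, begin = h$g_start, end = h$g_end,
                   strand = h$strand, repeat_id = h$consensus_id,
                   superfamily = annot$insertions$superfamily[
                     match(h$element_id, annot$insertions$element_id)],
                   cons_begin = h$c_start, cons_end = h$c_end,
                   pct_div = fmt2(100 * h$divergence),
                   element_id = h$element_id, score = h$score,
                   stringsAsFactors = FALSE)
  df <- df[order(df$seq, df$begin, df$element_id), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAnnotationTSV
#' @param library Optional [TELibrary-class] to re-attach superfamilies.
#' @export
readAnnotationTSV <- function(path, library = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  hits <- data.frame(seq_id = as.character(df$seq), g_start = df$begin,
                     g_end = df$end, strand = df$strand,
                     consensus_id = df$repeat_id,
                     c_start = df$cons_begin, c_end = df$cons_end,
                     identity = 1 - df$pct_div / 100,
                     divergence = df$pct_div / 100,
                     score = df$score, stringsAsFactors = FALSE)
  # regroup by stored element ids
  grp <- split(seq_len(nrow(hits)), df$element_id)
  agg <- lapply(grp, function(ii) {
    h <- hits[ii, , drop = FALSE]
    data.frame(element_id = df$element_id[ii[1]],
               seq_id = h$seq_id[1], consensus_id = h$consensus_id[1],
               superfamily = df$superfamily[ii[1]], strand = h$strand[1],
               span_start = min(h$g_start), span_end = max(h$g_end),
               n_components = nrow(h),
               total_length = sum(h$g_end - h$g_start + 1L),
               divergence = sum((h$g_end - h$g_start + 1L) * h$divergence) /
                 sum(h$g_end - h$g_start + 1L),
               score = sum(h$score), stringsAsFactors = FALSE)
  })
  ins <- do.call(rbind, agg)
  ins <- ins[order(ins$seq_id, ins$span_start), , drop = FALSE]
  rownames(ins) <- NULL
  hits$element_id <- df$element_id
  if (!is.null(library))
    ins$superfamily <- unname(superfamilyOf(library)[ins$consensus_id])
  list(insertions = ins, hits = hits)
}

#' Export annotated insertions as GFF3
#'
#' Insertions are written as `dispersed_repeat` features with attributes
#' `ID` (element id), `superfamily` and `divergence`.
#'
#' @param annot Result of [annotateRepeats()].
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
writeAnnotationGFF3 <- function(annot, path) {
  ins <- annot$insertions
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(ins)) {
    lines <- sprintf(
      "%s\ttepoly\tdispersed_repeat\t%d\t%d\t%.0f\t%s\t.\tID=te%04d;superfamily=%s;divergence=%s",
      ins$seq_id, ins$span_start, ins$span_end, ins$score, ins$strand,
      ins$element_id, ins$superfamily, fmt2(100 * ins$divergence))
    writeLines(lines, con)
  }
  invisible(path)
}
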