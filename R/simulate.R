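#' Configuration of the synthetic genome-pair simulator
#'
#' Builds and validates the parameter set of the simulator. The defaults
#' emulate the statistical structure of a comparison between two genomes at
#' ~98.7% nucleotide identity: shared TE insertions at ~540 per Mb planted
#' in the common ancestor, species-specific insertions planted after the
#' split (recent, hence near-identical to their consensus), 5'-truncated
#' LINE copies, TSDs of a few nt, a fraction of poly-A-tailed LINE
#' insertions, one endogenous retrovirus with near-identical LTRs whose
#' orthologous site is a solo LTR, and N-stretch assembly artifacts that
#' length-match a real insertion in the other genome.
#'
#' @param seed Mandatory integer seed; every downstream draw derives from
#'   it.
#' @param ancestorLength Ancestor length in nt (default 1e6).
#' @param gc GC content of the ancestor (default 0.42).
#' @param substitutionRate Target pairwise substitution divergence between
#'   the two genomes (default 0.013); each lineage receives half.
#' @param smallIndelRate Pairwise small-indel rate (default
#'   `substitutionRate / 10`), geometric lengths of mean ~3 nt.
#' @param sharedTEDensity Shared insertions per Mb of ancestor (default
#'   540).
#' @param specificTECount Species-specific insertions per species (default
#'   100, i.e. 200 in total).
#' @param tsdLenRange TSD length range (default c(2, 10)).
#' @param polyAFraction Fraction of LINE plants that get a poly-A tail
#'   instead of a TSD (default 0.15).
#' @param specLenMeanlog,specLenSdlog,specLenRange Log-normal parameters
#'   and clipping range of specific insertion lengths (defaults
#'   `log(1100)`, 0.8, c(225, 5091)).
#' @param sharedLenMeanlog,sharedLenSdlog Log-normal parameters of shared
#'   insertion lengths (defaults `log(600)`, 0.7; clipped to
#'   [120, consensus length]).
#' @param sharedDivMax,specDivMax Maximum divergence-to-consensus of
#'   planted copies (defaults 0.15 and 0.05).
#' @param nStretchCount N-stretch artifact mimics (default 20): a TE
#'   insertion planted in genome B paired with a length-matched N run in
#'   genome A.
#' @param ervRecombination Plant one full ERV in genome B whose orthologous
#'   site in genome A is a solo LTR (default TRUE).
#' @param ervDivergence Divergence applied to the ERV copy and the solo LTR
#'   (default 0.005, so the two element LTRs are ~99% identical).
#' @param minEventSpacing Minimum ancestor distance between insertion
#'   points (default 300 nt).
#' @param endMargin Event-free margin at the ancestor ends (default
#'   2000 nt).
#' @param library A [TELibrary-class]; defaults to [demoTELibrary()].
#' @return A validated list of class `simulationConfig`.
#' @export
simulationConfig <- function(seed,
                             ancestorLength = 1e6L,
                             gc = 0.42,
                             substitutionRate = 0.013,
                             smallIndelRate = substitutionRate / 10,
                             sharedTEDensity = 540,
                             specificTECount = 100L,
                             tsdLenRange = c(2L, 10L),
                             polyAFraction = 0.15,
                             specLenMeanlog = log(1100),
                             specLenSdlog = 0.8,
                             specLenRange = c(225L, 5091L),
                             sharedLenMeanlog = log(600),
                             sharedLenSdlog = 0.7,
                             sharedDivMax = 0.15,
                             specDivMax = 0.05,
                             nStretchCount = 20L,
                             ervRecombination = TRUE,
                             ervDivergence = 0.005,
                             minEventSpacing = 300L,
                             endMargin = 2000L,
                             library = demoTELibrary()) {
  if (missing(seed) || !is.numeric(seed) || is.na(seed))
    stop("seed is mandatory")
  stopifnot(ancestorLength > 0, gc >= 0, gc <= 1,
            substitutionRate >= 0, substitutionRate <= 1,
            smallIndelRate >= 0, smallIndelRate <= 1,
            sharedTEDensity >= 0, specificTECount >= 0,
            length(tsdLenRange) == 2, tsdLenRange[1] >= 2,
            polyAFraction >= 0, polyAFraction <= 1,
            nStretchCount >= 0, minEventSpacing >= 0)
  cfg <- list(seed = as.integer(seed),
              ancestorLength = as.integer(ancestorLength), gc = gc,
              substitutionRate = substitutionRate,
              smallIndelRate = smallIndelRate,
              sharedTEDensity = sharedTEDensity,
              specificTECount = as.integer(specificTECount),
              tsdLenRange = as.integer(tsdLenRange),
              polyAFraction = polyAFraction,
              specLenMeanlog = specLenMeanlog,
              specLenSdlog = specLenSdlog,
              specLenRange = as.integer(specLenRange),
              sharedLenMeanlog = sharedLenMeanlog,
              sharedLenSdlog = sharedLenSdlog,
              sharedDivMax = sharedDivMax, specDivMax = specDivMax,
              nStretchCount = as.integer(nStretchCount),
              ervRecombination = isTRUE(ervRecombination),
              ervDivergence = ervDivergence,
              minEventSpacing = as.integer(minEventSpacing),
              endMargin = as.integer(endMargin),
              library = library)
  # feasibility: all insertion points plus spacing must fit the ancestor
  nev <- round(cfg$sharedTEDensity * cfg$ancestorLength / 1e6) +
    2L * cfg$specificTECount + cfg$nStretchCount +
    as.integer(cfg$ervRecombination)
  if (nev * cfg$minEventSpacing + 2L * cfg$endMargin >= cfg$ancestorLength)
    stop("overlapping programmed events: ancestor too short for the ",
         "requested event count and spacing")
  class(cfg) <- "simulationConfig"
  cfg
}

#' Simulate an ancestral sequence
#'
#' I.i.d. bases at the configured GC content, reproducible under the
#' configured seed.
#'
#' @param config A [simulationConfig()].
#' @return A nucleotide string of length `config$ancestorLength`.
#' @export
simulateAncestor <- function(config) {
  withSeed(config$seed, randomDNA(config$ancestorLength, config$gc))
}

.emptyManifest <- function() {
  data.frame(event_id = integer(0), event_type = character(0),
             consensus_id = character(0), superfamily = character(0),
             strand = character(0), tsd = character(0),
             tsd_class = character(0), truncation = numeric(0),
             divergence = numeric(0), elem_length = integer(0),
             a_start = integer(0), a_end = integer(0),
             b_start = integer(0), b_end = integer(0),
             a_empty_pos = integer(0), b_empty_pos = integer(0),
             seq_a = character(0), seq_b = character(0),
             stringsAsFactors = FALSE)
}

# construct the element copy of one planting event (uses the current RNG
# stream). The TSD itself is host sequence and is added at planting time:
# integration at a site whose next tsdLen bases are T turns ...L T R...
# into ...L T E T R..., i.e. the novel material is element + one duplicate
# of T inserted downstream of the existing copy.
.makeElem <- function(consSeq, truncationFrac, divergence, strand,
                      polyA = FALSE) {
  L <- nchar(consSeq)
  cut <- as.integer(floor(truncationFrac * L))
  elem <- substr(consSeq, cut + 1L, L)  # 5'-truncated
  elem <- mutateSubstitutions(elem, divergence)
  if (strand == "-") elem <- revComp(elem)
  if (polyA) {
    tail <- strrep("A", sample(10:30, 1L))
    list(core = paste0(elem, tail), elem_len = nchar(elem),
         tsd_class = "polyA_region", wantTSD = FALSE)
  } else {
    list(core = elem, elem_len = nchar(elem), tsd_class = "TSD",
         wantTSD = TRUE)
  }
}

#' Plant a single TE insertion into a sequence
#'
#' Plants one element copy with a target site duplication: the `tsdLen`
#' host bases immediately after `pos` form the target site, and the novel
#' material -- the (possibly 5'-truncated, point-mutated) consensus copy
#' followed by a duplicate of the target site -- is inserted downstream of
#' the existing copy, so the element ends up framed by the duplicated
#' site. Coordinates of every downstream manifest event are shifted and
#' the new event is appended with its exact final coordinates. Intended
#' for constructing small test genomes; the full simulator uses the same
#' construction internally.
#'
#' @param seq Carrier sequence (character).
#' @param manifest A truth manifest data.frame (possibly empty; see
#'   [simulateGenomePair()] for the schema). Coordinates in the columns of
#'   the carrier `species` are updated through the edit.
#' @param consensus Consensus sequence (character) of the element.
#' @param pos Insertion site: the target site starts at `pos + 1`
#'   (`0 <= pos <= nchar(seq) - tsdLen`).
#' @param tsdLen TSD length (nt); 0 plants without a duplication.
#' @param truncationFrac 5'-truncation fraction in [0, 1).
#' @param divergence Per-site substitution divergence applied to the copy.
#' @param strand Planting strand.
#' @param polyA Plant with a poly-A tail instead of a TSD.
#' @param consensusId,superfamily Labels recorded in the manifest.
#' @param species `"A"` or `"B"`: which genome's coordinate columns this
#'   sequence corresponds to.
#' @param eventType Manifest event type.
#' @return A list: `seq` (edited sequence) and `manifest` (updated; the
#'   event's `start`/`end` cover the novel inserted block, element first).
#' @export
plantInsertion <- function(seq, manifest, consensus, pos, tsdLen = 4L,
                           truncationFrac = 0, divergence = 0,
                           strand = "+", polyA = FALSE,
                           consensusId = "consensus",
                           superfamily = "Unknown", species = "A",
                           eventType = paste0("specific_", species)) {
  s <- asSeqString(seq)
  if (polyA) tsdLen <- 0L
  if (pos < 0L || pos > nchar(s) - tsdLen) stop("pos out of range")
  if (truncationFrac < 0 || truncationFrac >= 1)
    stop("truncationFrac must be in [0, 1)")
  if (is.null(manifest) || nrow(manifest) == 0L) manifest <- .emptyManifest()
  el <- .makeElem(asSeqString(consensus), truncationFrac, divergence,
                  strand, polyA = polyA)
  core <- el$core
  if (tsdLen > 0L)
    pos <- .probeSiteStr(s, pos, tsdLen, substr(core, 1L, 1L),
                         substr(core, nchar(core), nchar(core)))
  tsd <- if (tsdLen > 0L) substr(s, pos + 1L, pos + tsdLen) else ""
  block <- paste0(core, tsd)
  insertAfter <- pos + tsdLen
  blockLen <- nchar(block)
  out <- paste0(substr(s, 1L, insertAfter), block,
                substr(s, insertAfter + 1L, nchar(s)))
  scol <- if (species == "A") c("a_start", "a_end") else c("b_start", "b_end")
  sq <- if (species == "A") "seq_a" else "seq_b"
  for (cn in scol) {
    shift <- !is.na(manifest[[cn]]) & manifest[[cn]] > insertAfter
    manifest[[cn]][shift] <- manifest[[cn]][shift] + blockLen
  }
  ev <- .emptyManifest()[0, ]
  ev[1, "event_id"] <- max(c(0L, manifest$event_id)) + 1L
  ev$event_type <- eventType
  ev$consensus_id <- consensusId
  ev$superfamily <- superfamily
  ev$strand <- strand
  ev$tsd <- tsd
  ev$tsd_class <- el$tsd_class
  ev$truncation <- truncationFrac
  ev$divergence <- divergence
  ev$elem_length <- el$elem_len
  ev[[scol[1]]] <- insertAfter + 1L
  ev[[scol[2]]] <- insertAfter + blockLen
  ev[[sq]] <- block
  manifest <- rbind(manifest, ev)
  manifest <- manifest[order(pmin(manifest$a_start, manifest$b_start,
                                  na.rm = TRUE)), , drop = FALSE]
  rownames(manifest) <- NULL
  list(seq = out, manifest = manifest)
}

# choose an insertion site whose context keeps the maximal target-site
# duplication equal to the programmed one: the base preceding the target
# site must differ from the element's last base and the base following
# the duplicated copy from the element's first base, otherwise the
# realized duplication is coincidentally longer than planted. Probes
# sites pos, pos+1, ... and returns the first unambiguous one (the
# element itself is never altered).
.probeSiteVec <- function(xvec, pos, t, coreFirst, coreLast,
                          maxProbe = 20L) {
  n <- length(xvec)
  for (d in 0:maxProbe) {
    pp <- pos + d
    if (pp < 1L || pp + t + 1L > n) break
    if (xvec[pp] != coreLast && xvec[pp + t + 1L] != coreFirst)
      return(pp)
  }
  pos
}

.probeSiteStr <- function(s, pos, t, coreFirst, coreLast, maxProbe = 20L) {
  n <- nchar(s)
  for (d in 0:maxProbe) {
    pp <- pos + d
    if (pp < 1L || pp + t + 1L > n) break
    if (substr(s, pp, pp) != coreLast &&
        substr(s, pp + t + 1L, pp + t + 1L) != coreFirst)
      return(pp)
  }
  pos
}

# apply substitutions at `rate` per site; returns character VECTOR form
.subCharVec <- function(x, rate) {
  hit <- which(runif(length(x)) < rate & x %in% c("A", "C", "G", "T"))
  if (length(hit)) {
    alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
    pick <- sample.int(3L, length(hit), replace = TRUE)
    x[hit] <- substring(alt[x[hit]], pick, pick)
  }
  x
}

# sample small indels outside protected intervals; returns a data.frame
# (pos, len, type) with type "ins" (insert after pos) / "del" (delete
# pos..pos+len-1), non-overlapping and sorted
.sampleIndels <- function(n, rate, protect, meanLen = 3) {
  count <- rbinom(1L, n, rate)
  if (count == 0L)
    return(data.frame(pos = integer(0), len = integer(0),
                      type = character(0)))
  pos <- sort(sample.int(n, count))
  len <- 1L + rgeom(count, 1 / meanLen)
  type <- ifelse(runif(count) < 0.5, "ins", "del")
  iv <- IRanges::IRanges(start = pos, end = ifelse(type == "del",
                                                   pos + len - 1L, pos))
  ok <- !IRanges::overlapsAny(iv, protect) & (pos + len) <= n
  df <- data.frame(pos = pos, len = len, type = type)[ok, , drop = FALSE]
  # drop overlapping successive deletions
  if (nrow(df) > 1L) {
    keep <- rep(TRUE, nrow(df))
    lastEnd <- -1L
    for (i in seq_len(nrow(df))) {
      s0 <- df$pos[i]
      e0 <- if (df$type[i] == "del") df$pos[i] + df$len[i] - 1L else df$pos[i]
      if (s0 <= lastEnd) keep[i] <- FALSE else lastEnd <- e0
    }
    df <- df[keep, , drop = FALSE]
  }
  df
}

# apply indels to a char vector; returns list(x = new char vector,
# map = function(ancestor positions) -> new positions)
.applyIndels <- function(x, indels) {
  n <- length(x)
  if (nrow(indels) == 0L) {
    return(list(x = x, map = function(p) as.integer(p)))
  }
  pieces <- list()
  cur <- 1L
  bndPos <- integer(nrow(indels)); bndOff <- integer(nrow(indels))
  off <- 0L
  for (i in seq_len(nrow(indels))) {
    p <- indels$pos[i]; l <- indels$len[i]
    if (indels$type[i] == "ins") {
      pieces[[length(pieces) + 1L]] <- x[cur:p]
      pieces[[length(pieces) + 1L]] <- strsplit(
        randomDNA(l, 0.5), "", fixed = TRUE)[[1L]]
      cur <- p + 1L
      off <- off + l
    } else {
      if (p > cur) pieces[[length(pieces) + 1L]] <- x[cur:(p - 1L)]
      cur <- p + l
      off <- off - l
    }
    bndPos[i] <- p; bndOff[i] <- off
  }
  if (cur <= n) pieces[[length(pieces) + 1L]] <- x[cur:n]
  newx <- unlist(pieces, use.names = FALSE)
  delStart <- indels$pos
  delLen <- ifelse(indels$type == "del", indels$len, 0L)
  map <- function(p) {
    i <- findInterval(p, bndPos)
    res <- as.integer(p + ifelse(i == 0L, 0L, bndOff[pmax(i, 1L)]))
    # clamp positions inside deletions and enforce monotonicity
    inDel <- i >= 1L & delLen[pmax(i, 1L)] > 0L &
      p < delStart[pmax(i, 1L)] + delLen[pmax(i, 1L)]
    if (any(inDel)) {
      j <- pmax(i[inDel], 1L)
      res[inDel] <- as.integer(delStart[j] - 1L +
                                 ifelse(j == 1L, 0L, bndOff[j - 1L]))
    }
    pmax(res, 1L)
  }
  list(x = newx, map = map)
}

#' Simulate a genome pair with planted, manifest-recorded TE events
#'
#' Full simulation: ancestor generation, planting of shared insertions in
#' the ancestor, speciation (independent substitutions and small indels
#' per lineage at half the pairwise rates, with indels excluded from
#' planted blocks so manifest coordinates stay exact), planting of
#' species-specific insertions (after lineage mutation: they are
#' post-speciation events and carry exact TSDs), one programmed ERV /
#' solo-LTR recombination pair, and N-stretch artifact mimics
#' (length-matched N runs in genome A opposite real insertions planted in
#' genome B).
#'
#' @param config A [simulationConfig()].
#' @return A list of class `teSimulation`: `genomeA`, `genomeB` (named
#'   character vectors, `chrA` / `chrB`), `manifest` (the truth manifest:
#'   one row per event with final 1-based inclusive block coordinates
#'   `a_start`/`a_end`/`b_start`/`b_end`, empty-site positions, TSD,
#'   truncation, divergence and the realized block sequences
#'   `seq_a`/`seq_b`), `library`, `config`.
#' @export
simulateGenomePair <- function(config) {
  stopifnot(inherits(config, "simulationConfig"))
  lib <- config$library
  info <- as.data.frame(consensusInfo(lib))
  withSeed(config$seed, {
    anc <- randomDNA(config$ancestorLength, config$gc)

    nShared <- round(config$sharedTEDensity * config$ancestorLength / 1e6)
    nSpecA <- config$specificTECount
    nSpecB <- config$specificTECount
    nMimic <- config$nStretchCount
    nErv <- as.integer(config$ervRecombination)
    nev <- nShared + nSpecA + nSpecB + nMimic + nErv

    # insertion points in the original ancestor frame, minimum spacing
    usable <- config$ancestorLength - 2L * config$endMargin -
      nev * config$minEventSpacing
    u <- sort(runif(nev))
    pts <- config$endMargin + round(usable * u) +
      config$minEventSpacing * (seq_len(nev) - 1L)
    types <- sample(c(rep("shared", nShared), rep("specific_A", nSpecA),
                      rep("specific_B", nSpecB), rep("n_artifact", nMimic),
                      rep("solo_ltr_recombination", nErv)))

    # family pool (ERV reserved for the programmed recombination event)
    pool <- info[info$id != "CoeERV1", , drop = FALSE]
    poolW <- c(`CR1-Coe` = 0.45, `L1-Coe` = 0.10, `L2-Coe` = 0.05,
               `CoeG-SINE` = 0.10, `LF-SINE` = 0.08, `Coe-SINE2` = 0.07,
               `Gypsy-Coe` = 0.05, `MITE-Coe` = 0.10)
    poolW <- poolW[pool$id]
    poolW[is.na(poolW)] <- 0.05
    drawEvent <- function(type, allowPolyA = TRUE) {
      cid <- sample(pool$id, 1L, prob = poolW)
      consSeq <- consensusSeq(lib, cid)
      L <- nchar(consSeq)
      isLINE <- info$te_order[info$id == cid] %in% "LINE"
      if (type == "shared") {
        target <- round(exp(rnorm(1L, config$sharedLenMeanlog,
                                  config$sharedLenSdlog)))
        target <- max(120L, min(target, L))
        div <- runif(1L, 0, config$sharedDivMax)
      } else {
        target <- round(exp(rnorm(1L, config$specLenMeanlog,
                                  config$specLenSdlog)))
        target <- max(config$specLenRange[1],
                      min(target, config$specLenRange[2], L))
        div <- runif(1L, 0, config$specDivMax)
      }
      trunc <- if (isLINE || info$superfamily[info$id == cid] == "Gypsy")
        1 - target / L else 0
      trunc <- max(0, min(trunc, 0.95))
      polyA <- allowPolyA && isLINE && runif(1L) < config$polyAFraction
      tsdLen <- sample(config$tsdLenRange[1]:config$tsdLenRange[2], 1L)
      strand <- sample(c("+", "-"), 1L)
      list(consensus_id = cid,
           superfamily = info$superfamily[info$id == cid],
           truncation = trunc, divergence = div,
           tsdLen = tsdLen, strand = strand,
           el = .makeElem(consSeq, trunc, div, strand, polyA))
    }

    events <- vector("list", nev)
    for (i in seq_len(nev)) {
      t <- types[i]
      if (t == "solo_ltr_recombination") {
        # ancestral ERV insertion followed by a species-A recombination
        # that leaves a single LTR; the shared TSD is ancestral host
        # sequence, shielded from lineage substitutions so the event
        # instantiates the recombination signature exactly
        ervSeq <- consensusSeq(lib, "CoeERV1")
        ltrLen <- info$ltr_length[info$id == "CoeERV1"]
        ervCopy <- mutateSubstitutions(ervSeq, config$ervDivergence)
        solo <- mutateSubstitutions(substr(ervSeq, 1L, ltrLen),
                                    config$ervDivergence)
        events[[i]] <- list(
          type = t, pos = pts[i], consensus_id = "CoeERV1",
          superfamily = "ERV", strand = "+", tsd_class = "TSD",
          truncation = 0, divergence = config$ervDivergence,
          tsdLen = 4L, wantTSD = TRUE,
          coreA = solo, coreB = ervCopy,
          elemLenA = nchar(solo), elemLenB = nchar(ervCopy))
      } else {
        d <- drawEvent(t, allowPolyA = t != "n_artifact")
        el <- d$el
        ev <- list(type = t, pos = pts[i], consensus_id = d$consensus_id,
                   superfamily = d$superfamily, strand = d$strand,
                   tsd_class = el$tsd_class, truncation = d$truncation,
                   divergence = d$divergence,
                   tsdLen = if (el$wantTSD) d$tsdLen else 0L,
                   wantTSD = el$wantTSD)
        if (t == "shared") {
          ev$coreShared <- el$core; ev$elemLen <- el$elem_len
        } else if (t == "specific_A") {
          ev$coreA <- el$core; ev$elemLenA <- el$elem_len
        } else if (t == "specific_B") {
          ev$coreB <- el$core; ev$elemLenB <- el$elem_len
        } else {  # n_artifact: real TE in B, length-matched N run in A
          ev$coreB <- el$core; ev$elemLenB <- el$elem_len
          ev$coreA <- strrep("N", el$elem_len + ev$tsdLen)
          ev$mimic <- TRUE
        }
        events[[i]] <- ev
      }
    }

    # plant shared blocks into the ancestor (single ascending pass). The
    # target site is the tsdLen host bases after pos; the novel material
    # (element + duplicated site) goes in right after the existing copy.
    ord <- order(vapply(events, function(e) e$pos, numeric(1)))
    events <- events[ord]
    pieces <- list(); cur <- 1L; off <- 0L
    for (i in seq_along(events)) {
      e <- events[[i]]
      if (e$type == "shared") {
        t <- e$tsdLen
        core <- e$coreShared
        pos <- e$pos
        if (t > 0L)
          pos <- .probeSiteStr(anc, pos, t, substr(core, 1L, 1L),
                               substr(core, nchar(core), nchar(core)))
        tsd <- if (t > 0L) substr(anc, pos + 1L, pos + t) else ""
        block <- paste0(core, tsd)
        pieces[[length(pieces) + 1L]] <- substr(anc, cur, pos + t)
        pieces[[length(pieces) + 1L]] <- block
        events[[i]]$tsd <- tsd
        events[[i]]$anc_start <- pos + t + off + 1L
        events[[i]]$anc_end <- pos + t + off + nchar(block)
        off <- off + nchar(block)
        cur <- pos + t + 1L
      } else {
        # site start in the ancestor2 frame (target site = pos2+1 ..
        # pos2+tsdLen)
        events[[i]]$pos2 <- e$pos + off
      }
    }
    pieces[[length(pieces) + 1L]] <- substr(anc, cur, nchar(anc))
    anc2 <- paste(unlist(pieces), collapse = "")
    anc2vec <- strsplit(anc2, "", fixed = TRUE)[[1L]]

    # the recombination event's site must be unambiguous for BOTH its
    # structures (full element and solo LTR) and identical in the two
    # lineages, so the probe runs once on the shielded ancestral bases
    for (i in seq_along(events)) {
      e <- events[[i]]
      if (e$type != "solo_ltr_recombination") next
      t <- e$tsdLen
      for (d in 0:20) {
        pp <- e$pos2 + d
        if (pp + t + 1L > length(anc2vec)) break
        firsts <- c(substr(e$coreA, 1L, 1L), substr(e$coreB, 1L, 1L))
        lasts <- c(substr(e$coreA, nchar(e$coreA), nchar(e$coreA)),
                   substr(e$coreB, nchar(e$coreB), nchar(e$coreB)))
        if (!anc2vec[pp] %in% lasts && !anc2vec[pp + t + 1L] %in% firsts) {
          events[[i]]$pos2 <- pp
          break
        }
      }
    }

    protect <- IRanges::IRanges(
      start = vapply(events, function(e)
        if (e$type == "shared") e$anc_start - 5L else e$pos2 - 5L,
        numeric(1)),
      end = vapply(events, function(e)
        if (e$type == "shared") e$anc_end + 5L
        else e$pos2 + e$tsdLen + 5L, numeric(1)))
    soloSites <- unlist(lapply(events, function(e)
      if (e$type == "solo_ltr_recombination")
        (e$pos2 + 1L):(e$pos2 + e$tsdLen) else NULL))

    speciateOne <- function() {
      x0 <- .subCharVec(anc2vec, config$substitutionRate / 2)
      if (length(soloSites)) x0[soloSites] <- anc2vec[soloSites]
      indels <- .sampleIndels(length(x0), config$smallIndelRate / 2, protect)
      ai <- .applyIndels(x0, indels)
      # x0: post-substitution, pre-indel characters (ancestor2 frame);
      # shared-block expected sequences are read from it independently of
      # the downstream coordinate bookkeeping
      list(x = ai$x, map = ai$map, x0 = x0)
    }
    spA <- speciateOne()
    spB <- speciateOne()

    # assemble each genome: lineage-mutated ancestor2 plus species blocks,
    # each block = element core + duplicate of the lineage's own target
    # site (read from the mutated sequence, so carrier TSD copies are
    # exact)
    assemble <- function(sp, side) {
      recs <- list()
      for (i in seq_along(events)) {
        e <- events[[i]]
        core <- if (side == "A") e$coreA else e$coreB
        if (e$type == "shared" || is.null(core)) next
        isN <- side == "A" && isTRUE(e$mimic)
        wantT <- isTRUE(e$wantTSD) && !isN
        recs[[length(recs) + 1L]] <- list(
          i = i, p = sp$map(e$pos2), core = core,
          t = if (wantT) e$tsdLen else 0L,
          fixedSite = e$type == "solo_ltr_recombination")
      }
      o <- order(vapply(recs, function(r) r$p, numeric(1)))
      recs <- recs[o]
      n <- length(sp$x)
      pieces <- list(); cur <- 1L; offs <- 0L
      m <- length(recs)
      starts <- integer(m); blocks <- character(m); tsds <- character(m)
      evIdx <- integer(m); insAfter <- integer(m)
      for (k in seq_len(m)) {
        r <- recs[[k]]
        core <- r$core
        p <- r$p
        if (r$t > 0L && !isTRUE(r$fixedSite)) {
          # keep the maximal duplication equal to the programmed target
          # site (probe nearby sites; the element is never altered)
          p <- .probeSiteVec(sp$x, p, r$t, substr(core, 1L, 1L),
                             substr(core, nchar(core), nchar(core)))
        }
        tsd <- if (r$t > 0L)
          paste(sp$x[(p + 1L):(p + r$t)], collapse = "") else ""
        block <- paste0(core, tsd)
        ia <- p + r$t
        pieces[[length(pieces) + 1L]] <-
          if (ia >= cur) paste(sp$x[cur:ia], collapse = "") else ""
        pieces[[length(pieces) + 1L]] <- block
        starts[k] <- ia + offs + 1L
        blocks[k] <- block; tsds[k] <- tsd
        evIdx[k] <- r$i; insAfter[k] <- ia
        offs <- offs + nchar(block)
        cur <- ia + 1L
      }
      pieces[[length(pieces) + 1L]] <- paste(sp$x[cur:n], collapse = "")
      list(seq = paste(unlist(pieces), collapse = ""), starts = starts,
           blocks = blocks, tsds = tsds, evIdx = evIdx,
           insAfter = insAfter)
    }
    asmA <- assemble(spA, "A")
    asmB <- assemble(spB, "B")

    # final coordinate of an ancestor2 position: indel map plus the total
    # length of species blocks inserted strictly before it
    liftA <- function(p2) {
      p <- spA$map(p2)
      as.integer(p + sum(nchar(asmA$blocks)[asmA$insAfter <= p - 1L]))
    }
    liftB <- function(p2) {
      p <- spB$map(p2)
      as.integer(p + sum(nchar(asmB$blocks)[asmB$insAfter <= p - 1L]))
    }

    # build the manifest
    rows <- vector("list", length(events))
    evid <- 0L
    for (i in seq_along(events)) {
      e <- events[[i]]
      evid <- evid + 1L
      r <- .emptyManifest()[0, ]
      r[1, "event_id"] <- evid
      r$event_type <- e$type
      r$consensus_id <- e$consensus_id
      r$superfamily <- e$superfamily
      r$strand <- e$strand
      r$tsd_class <- e$tsd_class
      r$truncation <- e$truncation
      r$divergence <- e$divergence
      if (e$type == "shared") {
        r$tsd <- e$tsd
        r$elem_length <- e$elemLen
        r$a_start <- liftA(e$anc_start)
        r$a_end <- r$a_start + (e$anc_end - e$anc_start)
        r$b_start <- liftB(e$anc_start)
        r$b_end <- r$b_start + (e$anc_end - e$anc_start)
        r$seq_a <- paste(spA$x0[e$anc_start:e$anc_end], collapse = "")
        r$seq_b <- paste(spB$x0[e$anc_start:e$anc_end], collapse = "")
      } else {
        kA <- which(asmA$evIdx == i)
        kB <- which(asmB$evIdx == i)
        if (length(kA)) {
          r$a_start <- asmA$starts[kA]
          r$a_end <- r$a_start + nchar(asmA$blocks[kA]) - 1L
          r$seq_a <- asmA$blocks[kA]
        } else {
          r$a_empty_pos <- liftA(e$pos2)
        }
        if (length(kB)) {
          r$b_start <- asmB$starts[kB]
          r$b_end <- r$b_start + nchar(asmB$blocks[kB]) - 1L
          r$seq_b <- asmB$blocks[kB]
        } else {
          r$b_empty_pos <- liftB(e$pos2)
        }
        # carrier TSD (for the solo event both lineages share the
        # ancestral site, so the two TSDs are identical)
        r$tsd <- if (isTRUE(e$mimic) || e$type == "specific_B" ||
                     e$type == "solo_ltr_recombination") {
          if (length(kB)) asmB$tsds[kB] else ""
        } else {
          if (length(kA)) asmA$tsds[kA] else ""
        }
        r$elem_length <- e$elemLenB %||% e$elemLenA
      }
      rows[[evid]] <- r
    }
    manifest <- if (length(rows)) do.call(rbind, rows) else .emptyManifest()
    manifest <- manifest[order(manifest$event_id), , drop = FALSE]
    rownames(manifest) <- NULL

    res <- list(genomeA = c(chrA = asmA$seq), genomeB = c(chrB = asmB$seq),
                manifest = manifest, library = lib, config = config)
    class(res) <- "teSimulation"
    res
  })
}

#' @export
print.teSimulation <- function(x, ...) {
  tab <- table(x$manifest$event_type)
  cat(sprintf("teSimulation: genomes %d / %d nt; %d events (%s)\n",
              nchar(x$genomeA[[1]]), nchar(x$genomeB[[1]]),
              nrow(x$manifest),
              paste(names(tab), as.integer(tab), sep = ":",
                    collapse = ", ")))
  invisible(x)
}

#' Write / read a truth manifest
#'
#' JSON round trip of the simulator's ground-truth manifest with schema
#' validation on read (required columns, numeric coordinates, start <= end;
#' violations are reported with the offending event id).
#'
#' @param manifest Manifest data.frame.
#' @param path JSON file path.
#' @return `writeTruth`: `path` invisibly; `readTruth`: the manifest.
#' @export
writeTruth <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = FALSE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  df <- jsonlite::fromJSON(path)
  if (length(df) == 0L) return(.emptyManifest())
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("event_id", "event_type", "consensus_id", "a_start", "a_end",
            "b_start", "b_end", "tsd", "elem_length")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("manifest schema violation: missing column(s) ",
         paste(miss, collapse = ", "))
  for (cn in c("a_start", "a_end", "b_start", "b_end", "elem_length")) {
    df[[cn]] <- suppressWarnings(as.integer(df[[cn]]))
  }
  badA <- which(!is.na(df$a_start) & !is.na(df$a_end) &
                  df$a_end < df$a_start)
  badB <- which(!is.na(df$b_start) & !is.na(df$b_end) &
                  df$b_end < df$b_start)
  bad <- sort(unique(c(badA, badB)))
  if (length(bad))
    stop(sprintf("manifest schema violation: end < start for event(s) %s",
                 paste(df$event_id[bad], collapse = ", ")))
  df
}

#' Score pipeline calls against a simulation truth manifest
#'
#' Matches specific calls to planted events by reciprocal overlap (>= 0.5)
#' on the carrier genome and computes recall, precision, the fraction of
#' N-stretch artifact mimics flagged, exact TSD recovery among TSD-bearing
#' plants, and whether the programmed solo-LTR recombination event was
#' recovered.
#'
#' @param callSet An [InsertionCalls-class] from running the pipeline on
#'   the simulated pair.
#' @param manifest The simulation truth manifest.
#' @param minElemLength Only planted events with `elem_length` at or above
#'   this enter the recall denominator (default 0: all).
#' @return A list: `recall`, `precision`, `n_truth`, `n_calls`,
#'   `n_matched`, `artifact_flagged_fraction`, `tsd_exact_fraction`,
#'   `n_tsd_bearing`, `solo_recovered`, `false_positives` (data.frame).
#' @export
scorePipeline <- function(callSet, manifest, minElemLength = 0L) {
  calls <- specificCalls(callSet)
  truth <- manifest[manifest$event_type %in%
                      c("specific_A", "specific_B",
                        "solo_ltr_recombination"), , drop = FALSE]
  truth$carrier <- ifelse(!is.na(truth$b_start) &
                            truth$event_type != "shared", "B", "A")
  truth$carrier[truth$event_type == "specific_A"] <- "A"
  truth$carrier[truth$event_type == "specific_B"] <- "B"
  truth$carrier[truth$event_type == "solo_ltr_recombination"] <- "B"
  truth <- truth[truth$elem_length >= minElemLength, , drop = FALSE]
  tStart <- ifelse(truth$carrier == "A", truth$a_start, truth$b_start)
  tEnd <- ifelse(truth$carrier == "A", truth$a_end, truth$b_end)
  matchedTruth <- rep(NA_integer_, nrow(truth))
  matchedCall <- rep(NA_integer_, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    cand <- which(truth$carrier == calls$species[i] &
                    tStart <= calls$end[i] & tEnd >= calls$start[i])
    if (!length(cand)) next
    ov <- pmin(tEnd[cand], calls$end[i]) - pmax(tStart[cand],
                                                calls$start[i]) + 1L
    rec <- pmin(ov / (tEnd[cand] - tStart[cand] + 1L),
                ov / (calls$end[i] - calls$start[i] + 1L))
    j <- cand[which.max(rec)]
    if (max(rec) >= 0.5 && is.na(matchedTruth[j])) {
      matchedTruth[j] <- i
      matchedCall[i] <- j
    }
  }
  nMatched <- sum(!is.na(matchedTruth))
  recall <- if (nrow(truth)) nMatched / nrow(truth) else NA_real_
  precision <- if (nrow(calls)) sum(!is.na(matchedCall)) / nrow(calls)
               else NA_real_
  # artifact mimics
  mims <- manifest[manifest$event_type == "n_artifact", , drop = FALSE]
  allCalls <- insertionCalls(callSet)
  flagged <- 0L
  for (i in seq_len(nrow(mims))) {
    hit <- which(allCalls$species == "B" & allCalls$status == "artifact" &
                   allCalls$span_start <= mims$b_end[i] &
                   allCalls$span_end >= mims$b_start[i])
    if (length(hit)) flagged <- flagged + 1L
  }
  # TSD recovery over TSD-bearing plants
  tsdIdx <- which(truth$tsd_class == "TSD" & nzchar(truth$tsd))
  tsdOK <- 0L
  for (j in tsdIdx) {
    i <- matchedTruth[j]
    if (!is.na(i) && !is.na(calls$tsd[i]) &&
        calls$tsd[i] == truth$tsd[j]) tsdOK <- tsdOK + 1L
  }
  solo <- manifest[manifest$event_type == "solo_ltr_recombination", ,
                   drop = FALSE]
  soloRec <- FALSE
  if (nrow(solo)) {
    j <- which(truth$event_type == "solo_ltr_recombination")
    i <- matchedTruth[j]
    soloRec <- length(i) == 1L && !is.na(i) && isTRUE(calls$solo_ltr[i])
  }
  fp <- calls[is.na(matchedCall), , drop = FALSE]
  list(recall = recall, precision = precision,
       n_truth = nrow(truth), n_calls = nrow(calls), n_matched = nMatched,
       artifact_flagged_fraction = if (nrow(mims)) flagged / nrow(mims)
                                   else NA_real_,
       tsd_exact_fraction = if (length(tsdIdx)) tsdOK / length(tsdIdx)
                            else NA_real_,
       n_tsd_bearing = length(tsdIdx),
       solo_recovered = soloRec,
       false_positives = fp)
}

#' Synthetic gene models and transcripts for a simulated pair
#'
#' Generates optional annotation tracks for a simulation: simple gene
#' models (gene bodies with 3-5 exons, placed so exons avoid planted TE
#' blocks) for each genome, and a transcript set drawn from genome B --
#' spliced gene transcripts plus fragments of planted TE copies, so both
#' the genomic-context and the transcriptome-representation columns of the
#' feature table can be exercised offline.
#'
#' @param sim A `teSimulation` from [simulateGenomePair()].
#' @param nGenes Genes per genome (default 8).
#' @param nTETranscripts TE-derived transcripts (default 10), each a
#'   fragment (>= 100 nt) of a planted element in genome B.
#' @param seed RNG seed (defaults to the simulation seed + 1000).
#' @return A list: `genesA`, `genesB` ([GenomicRanges::GRanges] with
#'   `type` gene/exon and `gene_id`), `transcripts` (named character
#'   vector).
#' @export
simulateAnnotationTracks <- function(sim, nGenes = 8L, nTETranscripts = 10L,
                                     seed = sim$config$seed + 1000L) {
  stopifnot(inherits(sim, "teSimulation"))
  m <- sim$manifest
  withSeed(seed, {
    mkGenes <- function(genome, seqname, blocks) {
      n <- nchar(genome)
      genes <- list()
      for (g in seq_len(nGenes)) {
        len <- sample(3000:8000, 1L)
        if (n < len + 2000L) break
        st <- sample.int(n - len - 1000L, 1L) + 500L
        nex <- sample(3:5, 1L)
        exStarts <- sort(sample.int(len - 300L, nex)) + st
        exEnds <- exStarts + sample(100:250, nex, replace = TRUE)
        # exons must not overlap planted TE blocks
        if (length(blocks) &&
            any(IRanges::overlapsAny(IRanges::IRanges(exStarts, exEnds),
                                     blocks))) next
        genes[[length(genes) + 1L]] <- list(
          id = sprintf("%s_g%02d", seqname, g),
          start = st, end = st + len, exStarts = exStarts, exEnds = exEnds)
      }
      if (!length(genes)) {
        return(GenomicRanges::GRanges())
      }
      rows <- do.call(rbind, lapply(genes, function(gn) {
        rbind(data.frame(start = gn$start, end = gn$end, type = "gene",
                         gene_id = gn$id),
              data.frame(start = gn$exStarts, end = gn$exEnds,
                         type = "exon", gene_id = gn$id))
      }))
      gr <- GenomicRanges::GRanges(seqname,
                                   IRanges::IRanges(rows$start, rows$end))
      gr$type <- rows$type
      gr$gene_id <- rows$gene_id
      gr
    }
    blocksA <- IRanges::IRanges(m$a_start[!is.na(m$a_start)],
                                m$a_end[!is.na(m$a_start)])
    blocksB <- IRanges::IRanges(m$b_start[!is.na(m$b_start)],
                                m$b_end[!is.na(m$b_start)])
    genesA <- mkGenes(sim$genomeA[[1]], names(sim$genomeA), blocksA)
    genesB <- mkGenes(sim$genomeB[[1]], names(sim$genomeB), blocksB)
    # transcripts: spliced exons of B genes ...
    tr <- character(0)
    if (length(genesB)) {
      for (gid in unique(genesB$gene_id)) {
        ex <- genesB[genesB$type == "exon" & genesB$gene_id == gid]
        tr[[paste0("tx_", gid)]] <- paste(vapply(seq_along(ex), function(i)
          substr(sim$genomeB[[1]], GenomicRanges::start(ex)[i],
                 GenomicRanges::end(ex)[i]), ""), collapse = "")
      }
    }
    # ... plus fragments of planted TE copies in B
    carriers <- which(!is.na(m$b_start) & nzchar(m$seq_b %||% "") &
                        m$event_type != "n_artifact" &
                        (m$b_end - m$b_start + 1L) >= 150L)
    if (length(carriers)) {
      pick <- sample(carriers, min(nTETranscripts, length(carriers)))
      for (i in seq_along(pick)) {
        ev <- pick[i]
        blk <- m$seq_b[ev]
        L <- nchar(blk)
        fl <- sample(100:min(L, 600), 1L)
        st <- sample.int(L - fl + 1L, 1L)
        tr[[sprintf("tx_te%03d", m$event_id[ev])]] <- substr(blk, st,
                                                             st + fl - 1L)
      }
    }
    list(genesA = genesA, genesB = genesB, transcripts = tr)
  })
}
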