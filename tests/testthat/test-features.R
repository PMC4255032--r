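test_that("TSD search returns the longest suffix-prefix duplication", {
  r <- findTSD("CCTGAGAT", "AGATGGTC")
  expect_equal(r$sequence, "AGAT")
  expect_equal(r$length, 4L)
  expect_equal(r$class, "TSD")

  expect_equal(findTSD("GCGC", "TTAA")$class, "not_detected")

  # both "AT" and "ATAT" qualify: the longest wins, matching an
  # exhaustive search over all suffix-prefix pairs
  r2 <- findTSD("CCATAT", "ATATGG")
  expect_equal(r2$sequence, "ATAT")
  expect_equal(r2$sequence, bruteForceTSD("CCATAT", "ATATGG"))

  # random flanks against the exhaustive oracle
  for (seed in 1:6) {
    lf <- fixedSeq(30, seed + 300)
    rf <- fixedSeq(30, seed + 400)
    got <- findTSD(lf, rf)
    want <- bruteForceTSD(lf, rf)
    if (nchar(want) >= 2) expect_equal(got$sequence, want)
    else expect_false(got$class == "TSD")
  }

  expect_warning(findTSD("A", "A"), "short")
})

test_that("poly-A and AT-rich contexts are classified when no TSD exists", {
  pA <- findTSD(paste0(fixedSeq(20, 1, gc = 0.6), strrep("A", 20)),
                "GCGCGCGCGCGCGCGCGCGCGCGCG")
  expect_equal(pA$class, "polyA_region")
  at <- findTSD(paste0(fixedSeq(10, 2, gc = 0.9), strrep("TA", 15)),
                "GCGCGCGCGCGCGCGCGCGCGCGCG")
  expect_true(at$class %in% c("AT_rich_region", "polyA_region"))
})

test_that("TSD detection handles the one-copy-inside-block convention", {
  # filled = L T E T R; the called block is E plus one copy of T
  L <- fixedSeq(200, 11); R <- fixedSeq(200, 12)
  tsdStr <- "GATC"; E <- fixedSeq(500, 13)
  # guard ambiguity by construction
  substr(E, 1, 1) <- if (substr(R, 1, 1) == "A") "C" else "A"
  substr(E, 500, 500) <- if (substr(L, 200, 200) == "G") "T" else "G"
  s <- paste0(L, tsdStr, E, tsdStr, R)
  # block [E T]: positions 205..708
  r <- insertionTSD(s, 205L, 708L)
  expect_equal(r$sequence, tsdStr)
  expect_equal(r$ins_start, 205L)
  expect_equal(r$ins_end, 704L)  # the element alone
  # block [T E]: positions 201..704
  r2 <- insertionTSD(s, 201L, 704L)
  expect_equal(r2$sequence, tsdStr)
  expect_equal(r2$ins_start, 205L)
  # exact element with both copies outside
  r3 <- insertionTSD(s, 205L, 704L)
  expect_equal(r3$sequence, tsdStr)
  expect_equal(r3$config, "O")
  # result is invariant under what lies far beyond the flanks
  s2 <- paste0(fixedSeq(300, 14), s, fixedSeq(300, 15))
  r4 <- insertionTSD(s2, 505L, 1008L)
  expect_equal(r4$sequence, tsdStr)
})

test_that("terminal repeat detection finds LTRs and TIRs", {
  ltr <- fixedSeq(300, 21)
  core <- fixedSeq(2000, 22)
  elem <- paste0(ltr, core, ltr)
  lp <- detectLTRs(elem)
  expect_equal(lp$type, "LTR")
  expect_gte(lp$length, 295L)
  expect_equal(lp$identity, 1)
  expect_lte(lp$left_start, 5L)
  expect_gte(lp$right_end, nchar(elem) - 5L)

  # 6 substitutions in the right copy: identity ~0.98, within 0.02 of the
  # independent full-DP identity of the two repeat copies
  ltr2 <- ltr
  for (i in c(10, 60, 110, 160, 210, 260))
    substr(ltr2, i, i) <- c(A = "C", C = "G", G = "T", T = "A")[
      substr(ltr2, i, i)]
  elem2 <- paste0(ltr, core, ltr2)
  lp2 <- detectLTRs(elem2)
  expect_lt(abs(lp2$identity - 0.98), 0.01)
  expect_lt(abs(lp2$identity - oracleIdentity(ltr, ltr2)), 0.02)

  # shuffled sequence: nothing
  expect_null(detectLTRs(fixedSeq(2600, 23)))

  # terminal inverted repeats
  tir <- fixedSeq(120, 24)
  mite <- paste0(tir, fixedSeq(400, 25), tepoly:::revComp(tir))
  lpt <- detectLTRs(mite)
  expect_equal(lpt$type, "TIR")
})

test_that("solo-LTR events require LTR identity, length and a shared TSD", {
  ltr <- fixedSeq(300, 26)
  core <- fixedSeq(2000, 27)
  elem <- paste0(ltr, core, ltr)
  lp <- detectLTRs(elem)
  tsdStr <- "AGAT"
  site <- paste0(fixedSeq(150, 28), tsdStr, ltr, tsdStr, fixedSeq(150, 29))
  ev <- callSoloLTR(elem, lp, site, tsd = tsdStr)
  expect_false(is.null(ev))
  expect_equal(ev$shared_tsd, tsdStr)
  expect_gte(ev$ltr_identity_to_solo, 0.99)

  # unrelated sequence of LTR length: no event
  bad <- paste0(fixedSeq(150, 30), fixedSeq(300, 31), fixedSeq(150, 32))
  expect_null(callSoloLTR(elem, lp, bad, tsd = tsdStr))
  # same LTR but a different TSD: no event
  site2 <- paste0(fixedSeq(150, 33), "TTTT", ltr, "TTTT", fixedSeq(150, 34))
  expect_null(callSoloLTR(elem, lp, site2, tsd = tsdStr))
})

test_that("composite insertions decompose into ordered components", {
  lib <- demoLib()
  s1 <- consensusSeq(lib, "LF-SINE")
  s2 <- consensusSeq(lib, "CoeG-SINE")
  comp <- paste0(s1, s2, s1)
  d <- decomposeComposite(comp, lib)
  expect_equal(nrow(d$components), 3L)
  expect_equal(d$components$consensus_id, c("LF-SINE", "CoeG-SINE", "LF-SINE"))
  expect_equal(length(unique(d$components$strand[c(1, 3)])), 1L)
  expect_gte(d$coverage, 0.95)
  expect_false(d$partial)

  single <- decomposeComposite(s1, lib)
  expect_equal(nrow(single$components), 1L)
})

test_that("greedy tiling stays within 10% of the exhaustive optimum", {
  lib <- demoLib()
  parts <- tepoly:::withSeed(61, {
    ids <- sample(c("LF-SINE", "CoeG-SINE", "Coe-SINE2"), 4, replace = TRUE)
    lapply(ids, function(id) {
      cs <- consensusSeq(lib, id)
      st <- sample.int(nchar(cs) - 149L, 1L)
      substr(cs, st, st + sample(149:250, 1L))
    })
  })
  comp <- paste(unlist(parts), collapse = "")
  d <- decomposeComposite(comp, lib)
  # exhaustive oracle over the candidate hit set
  ann <- annotateRepeats(comp, lib, seqId = "x", mask = IRanges::IRanges())
  ins <- ann$insertions
  n <- nrow(ins)
  bestScore <- 0
  for (msk in 0:(2^n - 1)) {
    sel <- which(bitwAnd(msk, 2^(seq_len(n) - 1)) > 0)
    if (!length(sel)) next
    iv <- IRanges::IRanges(ins$span_start[sel], ins$span_end[sel])
    ovl <- sum(IRanges::width(iv)) -
      sum(IRanges::width(IRanges::reduce(iv)))
    if (ovl > 10L * length(sel)) next
    bestScore <- max(bestScore, sum(ins$score[sel]))
  }
  gotScore <- sum(ins$score[match(
    paste(d$components$start, d$components$end),
    paste(ins$span_start, ins$span_end))], na.rm = TRUE)
  expect_gte(gotScore, 0.9 * bestScore)
})

test_that("copy number applies the family filters and collapses loci", {
  lib <- demoLib()
  q <- substr(consensusSeq(lib, "LF-SINE"), 1, 400)
  target <- paste0(fixedSeq(500, 41), q, fixedSeq(300, 42), q,
                   fixedSeq(300, 43), q, fixedSeq(300, 44),
                   substr(q, 1, 280), fixedSeq(500, 45))
  cn <- copyNumber(q, c(t1 = target))
  expect_equal(cn$n_total, 3L)  # the 70%-length copy fails the length filter
  expect_equal(cn$n_high, 3L)

  # query present only at its own locus
  solo <- paste0(fixedSeq(400, 46), q, fixedSeq(400, 47))
  cn2 <- copyNumber(q, c(t1 = solo))
  expect_equal(cn2$n_total, 1L)
  expect_equal(cn2$n_high, 1L)
})

test_that("copy number matches an iterative local-alignment oracle and is monotone", {
  lib <- demoLib()
  q <- substr(consensusSeq(lib, "CoeG-SINE"), 1, 300)
  target <- tepoly:::withSeed(62, {
    copies <- lapply(runif(6, 0.85, 0.99), function(idv)
      tepoly:::mutateSubstitutions(q, 1 - idv))
    paste0(fixedSeq(200, 48),
           paste(vapply(copies, function(cp)
             paste0(cp, tepoly:::randomDNA(150, 0.42)), ""), collapse = ""),
           fixedSeq(200, 49))
  })
  cn <- copyNumber(q, c(t = target))
  # oracle: iterative best local alignment with masking of found loci
  tt <- target
  found <- 0L
  repeat {
    pa <- Biostrings::pairwiseAlignment(
      pattern = q, subject = tt, type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -2),
      gapOpening = 5, gapExtension = 1)
    alen <- Biostrings::width(Biostrings::subject(pa))
    ident <- Biostrings::nmatch(pa) /
      (Biostrings::nmatch(pa) + Biostrings::nmismatch(pa))
    if (alen < 0.8 * nchar(q) || ident < 0.8) break
    found <- found + 1L
    st <- Biostrings::start(Biostrings::subject(pa))
    en <- Biostrings::end(Biostrings::subject(pa))
    substr(tt, st, en) <- strrep("N", en - st + 1L)
  }
  expect_equal(cn$n_total, found)
  # monotone in both thresholds
  expect_lte(copyNumber(q, c(t = target), minIdentity = 0.9)$n_total,
             cn$n_total)
  expect_lte(copyNumber(q, c(t = target), minLenFrac = 0.95)$n_total,
             cn$n_total)
})

test_that("expression hits count distinct transcripts above the thresholds", {
  q <- fixedSeq(600, 51)
  tr1 <- paste0(fixedSeq(100, 52), substr(q, 101, 200), fixedSeq(100, 53))
  tr2 <- paste0(substr(q, 301, 420), fixedSeq(150, 54))
  tr3 <- paste0(fixedSeq(120, 55), substr(q, 1, 79))  # 79 nt: below cutoff
  expect_equal(expressionHits(q, list(t1 = tr1, t2 = tr2)), 2L)
  expect_equal(expressionHits(q, list(t3 = tr3)), 0L)
  expect_equal(expressionHits(q, list()), 0L)
})

test_that("subfamily clustering is single linkage at 98% identity", {
  a <- fixedSeq(600, 56)
  expect_equal(length(clusterSubfamily(c(x = a, y = a, z = a))$clusters), 1L)

  b <- tepoly:::withSeed(57, tepoly:::mutateSubstitutions(a, 0.012))
  c_ <- tepoly:::withSeed(58, tepoly:::mutateSubstitutions(b, 0.012))
  cl <- clusterSubfamily(c(a = a, b = b, c = c_))
  expect_lt(cl$identity["a", "c"], 0.99)
  expect_gte(cl$identity["a", "b"], 0.98)
  expect_equal(length(cl$clusters), 1L)  # chained through b

  d <- fixedSeq(600, 59)
  cl2 <- clusterSubfamily(c(a = a, d = d))
  expect_equal(length(cl2$clusters), 2L)
  expect_error(clusterSubfamily(character(0)), "at least one")
})
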