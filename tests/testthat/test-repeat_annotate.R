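test_that("seed matching finds every shared k-mer on both strands", {
  lib <- demoLib()
  cons <- consensusSeq(lib, "CR1-Coe")
  word <- substr(cons, 501, 540)  # 40-nt exact substring
  s <- paste0(fixedSeq(100, 1), word, fixedSeq(100, 2))
  anc <- seedMatches(s, lib, k = 12L)
  fwd <- anc[anc$consensus_id == "CR1-Coe" & anc$strand == "+", ]
  expect_gte(nrow(fwd), 29L)  # 40 - 12 + 1 positions
  expect_true(all(fwd$g_pos >= 95 & fwd$g_pos <= 132))

  s2 <- paste0(fixedSeq(100, 3), tepoly:::revComp(word), fixedSeq(100, 4))
  anc2 <- seedMatches(s2, lib, k = 12L)
  expect_gte(sum(anc2$consensus_id == "CR1-Coe" & anc2$strand == "-"), 29L)

  expect_error(seedMatches(s, lib, k = 4L), "between 8 and 16")
})

test_that("absence of shared k-mers yields no anchors (exhaustive check)", {
  lib <- TELibrary(c(tiny = fixedSeq(120, 11)), "CR1")
  s <- fixedSeq(150, 99)
  # oracle: exhaustive k-mer set intersection on both strands
  kmers <- function(x, k) {
    n <- nchar(x)
    if (n < k) return(character(0))
    vapply(1:(n - k + 1), function(i) substr(x, i, i + k - 1), "")
  }
  cons <- consensusSeq(lib, "tiny")
  shared <- intersect(kmers(s, 12),
                      c(kmers(cons, 12), kmers(tepoly:::revComp(cons), 12)))
  anc <- seedMatches(s, lib, k = 12L)
  expect_equal(nrow(anc) == 0L, length(shared) == 0L)
  expect_equal(length(shared), 0L)  # random 150 vs 120 nt share no 12-mer
})

test_that("seed extension recovers planted copies and their divergence", {
  lib <- demoLib()
  cons <- consensusSeq(lib, "CR1-Coe")
  copy <- substr(cons, 1001, 1500)  # 500 nt exact
  # force mismatching flank bases at both boundaries so the exact copy is
  # maximal by construction
  left <- fixedSeq(200, 21); right <- fixedSeq(200, 22)
  fix <- function(fl, at, avoid) {
    if (substr(fl, at, at) == avoid)
      substr(fl, at, at) <- setdiff(c("A", "C", "G", "T"), avoid)[1]
    fl
  }
  left <- fix(left, 200, substr(cons, 1000, 1000))
  right <- fix(right, 1, substr(cons, 1501, 1501))
  s <- paste0(left, copy, right)
  h <- extendHit(s, cons, gPos = 301L, cPos = 1101L, strand = "+")
  expect_equal(h$g_start, 201L)
  expect_equal(h$g_end, 700L)
  expect_equal(h$identity, 1.0)
  expect_equal(h$divergence, 0.0)

  # 10% substitutions: divergence near 0.10 and within 0.02 of the
  # Smith-Waterman identity computed by an independent aligner
  mut <- tepoly:::withSeed(7, tepoly:::mutateSubstitutions(copy, 0.10))
  s2 <- paste0(left, mut, right)
  anc <- seedMatches(s2, TELibrary(c(`CR1-Coe` = cons), "CR1"), k = 12L)
  anc <- anc[anc$strand == "+", ][1, ]
  h2 <- extendHit(s2, cons, anc$g_pos, anc$c_pos, strand = "+")
  expect_lt(abs(h2$divergence - 0.10), 0.03)
  pa <- Biostrings::pairwiseAlignment(
    pattern = mut, subject = substr(cons, 901, 1600), type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -2),
    gapOpening = 5, gapExtension = 1)
  oid <- Biostrings::nmatch(pa) / (Biostrings::nmatch(pa) +
                                     Biostrings::nmismatch(pa))
  expect_lt(abs(h2$identity - oid), 0.02)
  # extension score never below the seed score
  expect_gte(h2$score, 12L)
})

test_that("hit filters apply inclusive length and divergence bounds", {
  mk <- function(len, div) {
    data.frame(seq_id = "s", g_start = 1000L, g_end = 1000L + len - 1L,
               strand = "+", consensus_id = "c", c_start = 1L,
               c_end = len, identity = 1 - div, divergence = div,
               score = len, stringsAsFactors = FALSE)
  }
  expect_equal(nrow(filterHits(mk(99L, 0.05))), 0L)
  expect_equal(nrow(filterHits(mk(100L, 0.20))), 1L)
  expect_equal(nrow(filterHits(mk(150L, 0.201))), 0L)
  expect_equal(nrow(filterHits(mk(100L, 0.05)[0, ])), 0L)
})

test_that("split hits merge into unique insertions with a common element id", {
  two <- data.frame(
    seq_id = "s", g_start = c(1000L, 2000L), g_end = c(1500L, 2520L),
    strand = "+", consensus_id = "CR1-X",
    c_start = c(1L, 481L), c_end = c(500L, 1000L),
    identity = 0.95, divergence = 0.05, score = c(400, 420),
    stringsAsFactors = FALSE)
  m <- mergeSplitHits(two)
  expect_equal(nrow(m$insertions), 1L)
  expect_equal(m$insertions$n_components, 2L)
  expect_equal(m$insertions$span_start, 1000L)
  expect_equal(m$insertions$span_end, 2520L)
  expect_equal(unique(m$hits$element_id), 1L)

  # different consensus: no merge
  two2 <- two
  two2$consensus_id <- c("CR1-X", "L1-Y")
  expect_equal(nrow(mergeSplitHits(two2)$insertions), 2L)
})

test_that("merging equals the brute-force transitive closure on random hits", {
  for (seed in c(3, 9, 27)) {
    hits <- tepoly:::withSeed(seed, {
      n <- 7L
      gs <- sort(sample(1000:20000, n))
      len <- sample(120:600, n, replace = TRUE)
      cs <- sample(1:800, n, replace = TRUE)
      data.frame(seq_id = "s", g_start = gs, g_end = gs + len,
                 strand = "+", consensus_id = "CR1-X",
                 c_start = cs, c_end = cs + len,
                 identity = 0.9, divergence = 0.1, score = len,
                 stringsAsFactors = FALSE)
    })
    m <- mergeSplitHits(hits, maxGenomeGap = 5000L, maxConsOverlap = 50L)
    comp <- bruteForceClosure(hits, 5000L, 50L)
    # same partition: element ids group hits exactly like the closure
    got <- m$hits$element_id[order(m$hits$g_start)]
    want <- comp[order(hits$g_start)]
    expect_equal(length(unique(got)), length(unique(want)))
    expect_equal(as.integer(factor(got, levels = unique(got))),
                 as.integer(factor(want, levels = unique(want))))
    # no hit lost or duplicated
    expect_equal(sum(m$insertions$n_components), nrow(hits))
  }
})

test_that("zero-substitution simulation is annotated at full recall", {
  cfg <- simulationConfig(seed = 77L, ancestorLength = 40000L,
                          substitutionRate = 0, smallIndelRate = 0,
                          sharedTEDensity = 250, specificTECount = 0L,
                          nStretchCount = 0L, ervRecombination = FALSE,
                          sharedDivMax = 0)
  sim <- simulateGenomePair(cfg)
  ann <- annotateRepeats(sim$genomeA[[1]], sim$library, seqId = "chrA")
  m <- sim$manifest
  planted <- m[m$elem_length >= 100, ]
  for (i in seq_len(nrow(planted))) {
    hit <- which(ann$insertions$span_start <= planted$a_end[i] &
                   ann$insertions$span_end >= planted$a_start[i] &
                   ann$insertions$consensus_id == planted$consensus_id[i])
    expect_equal(length(hit), 1L)
    expect_equal(ann$insertions$divergence[hit], 0)
  }
})
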