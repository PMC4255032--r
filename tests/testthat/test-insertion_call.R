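# build a toy genome pair by planting into a common backbone
.toyPair <- function(seed = 55L) {
  lib <- demoLib()
  backbone <- fixedSeq(20000, seed)
  sine <- consensusSeq(lib, "LF-SINE")
  # shared insertion at 4000 in both; A-specific at 9000; B-specific at 14000
  mkA <- plantInsertion(backbone, NULL, sine, 4000L, tsdLen = 4L,
                        consensusId = "LF-SINE", superfamily = "LF-SINE",
                        species = "A", eventType = "shared")
  mkA <- plantInsertion(mkA$seq, mkA$manifest, consensusSeq(lib, "CoeG-SINE"),
                        9000L + 548L, tsdLen = 5L, consensusId = "CoeG-SINE",
                        superfamily = "CoeG-SINE", species = "A")
  mkB <- plantInsertion(backbone, NULL, sine, 4000L, tsdLen = 4L,
                        consensusId = "LF-SINE", superfamily = "LF-SINE",
                        species = "B", eventType = "shared")
  mkB <- plantInsertion(mkB$seq, mkB$manifest, consensusSeq(lib, "Coe-SINE2"),
                        14000L + 548L, tsdLen = 3L, consensusId = "Coe-SINE2",
                        superfamily = "SINE", species = "B")
  list(a = mkA$seq, b = mkB$seq, lib = lib,
       manifestA = mkA$manifest, manifestB = mkB$manifest)
}

test_that("face-to-face pairing separates shared and specific insertions", {
  tp <- .toyPair()
  annA <- annotateRepeats(tp$a, tp$lib, seqId = "A")
  annB <- annotateRepeats(tp$b, tp$lib, seqId = "B")
  om <- buildOrthoMap(c(A = tp$a), c(B = tp$b))
  pr <- pairAnnotations(annA$insertions, annB$insertions, om)
  expect_equal(nrow(pr$shared), 1L)
  expect_equal(pr$shared$superfamily, "LF-SINE")
  expect_equal(nrow(pr$unpaired_a), 1L)
  expect_equal(pr$unpaired_a$superfamily, "CoeG-SINE")
  expect_equal(nrow(pr$unpaired_b), 1L)
})

test_that("greedy 1-to-1 pairing matches the optimal assignment when nested", {
  # two A insertions lifted over one B insertion: exactly one pairs
  annA <- data.frame(
    element_id = 1:2, seq_id = "A", consensus_id = "c",
    superfamily = "CR1", strand = "+",
    span_start = c(1000L, 1100L), span_end = c(1900L, 1700L),
    n_components = 1L, total_length = c(901L, 601L),
    divergence = 0.01, score = c(900, 600))
  annB <- data.frame(
    element_id = 1L, seq_id = "B", consensus_id = "c",
    superfamily = "CR1", strand = "+",
    span_start = 1050L, span_end = 1800L,
    n_components = 1L, total_length = 751L, divergence = 0.01, score = 750)
  om <- new("OrthoMap",
            fragments = data.frame(fragment_id = 1L, a_seq = "A",
                                   a_start = 1L, a_end = 5000L,
                                   b_seq = "B", b_start = 1L, b_end = 5000L,
                                   orientation = "+", mean_identity = 1,
                                   score = 5000),
            anchors = data.frame(fragment_id = 1L, a_seq = "A", b_seq = "B",
                                 a_start = 1L, a_end = 5000L,
                                 b_start = 1L, b_end = 5000L,
                                 strand = "+", length = 5000L,
                                 identity = 1),
            maxGap = 10000)
  pr <- pairAnnotations(annA, annB, om)
  expect_equal(nrow(pr$shared), 1L)
  expect_equal(nrow(pr$unpaired_a), 1L)
  # brute-force optimal 1-to-1 assignment on this instance also pairs one
  expect_equal(nrow(pr$shared) + nrow(pr$unpaired_a), 2L)
})

test_that("boundary refinement extracts the maximal empty-side gap block", {
  filled <- paste0("AAAA", strrep("T", 10), "GGGG")
  empty <- "AAAAGGGG"
  rb <- refineBoundaries(filled, empty, flank = 4L, minLen = 5L)
  expect_true(rb$found)
  expect_equal(rb$ins_start, 5L)
  expect_equal(rb$ins_end, 14L)

  rb2 <- refineBoundaries(empty, empty, flank = 4L, minLen = 5L)
  expect_false(rb2$found)
})

test_that("refined boundaries land within 5 nt of the planted truth", {
  lib <- demoLib()
  backbone <- fixedSeq(4000, 71)
  pl <- plantInsertion(backbone, NULL, consensusSeq(lib, "CoeG-SINE"),
                       2000L, tsdLen = 4L, divergence = 0,
                       consensusId = "CoeG-SINE", species = "A")
  filledG <- pl$seq
  ev <- pl$manifest[1, ]
  emptyG <- tepoly:::withSeed(72, tepoly:::mutateSubstitutions(backbone, 0.013))
  filled <- substr(filledG, ev$a_start - 500, ev$a_end + 500)
  empty <- substr(emptyG, ev$a_start - 500, ev$a_start + 500)
  rb <- refineBoundaries(filled, empty, flank = 500L)
  expect_true(rb$found)
  expect_true(rb$refined)
  gs <- ev$a_start - 500 + rb$ins_start - 1
  ge <- ev$a_start - 500 + rb$ins_end - 1
  expect_lte(abs(gs - ev$a_start), 5L)
  expect_lte(abs(ge - ev$a_end), 5L)
  # oracle: the naive full-DP global aligner finds the same block
  o <- tepoly:::cpp_align_full(filled, empty, 1L, -2L, 25L, 1L, FALSE)
  sv <- strsplit(o$aligned_b, "")[[1]]
  r <- rle(sv == "-")
  expect_equal(max(r$lengths[r$values]), rb$ins_end - rb$ins_start + 1L)
})

test_that("assembly N-stretches are recognized by length matching", {
  w <- paste0(fixedSeq(300, 81), strrep("N", 1000), fixedSeq(300, 82))
  expect_true(isAssemblyArtifact(w, 1000L))
  expect_false(isAssemblyArtifact(paste0(fixedSeq(600, 83)), 1000L))
  w2 <- paste0(fixedSeq(300, 84), strrep("N", 400), fixedSeq(300, 85))
  expect_false(isAssemblyArtifact(w2, 1000L))
  # interrupted run still counts when the N fraction stays high
  w3 <- paste0(fixedSeq(300, 86), strrep("N", 500), "ACGT",
               strrep("N", 496), fixedSeq(300, 87))
  expect_true(isAssemblyArtifact(w3, 1000L))
})

test_that("shared counting is keyed by superfamily with a total row", {
  sh <- data.frame(a_element_id = 1:4, b_element_id = 1:4,
                   superfamily = c("CR1", "CR1", "CR1", "Gypsy"),
                   consensus_id = "x", fragment_id = 1L,
                   reciprocal_overlap = 1)
  tab <- countShared(sh)
  expect_equal(tab$n[tab$superfamily == "CR1"], 3L)
  expect_equal(tab$n[tab$superfamily == "Gypsy"], 1L)
  expect_equal(tab$n[tab$superfamily == "total"], 4L)
  expect_equal(countShared(sh[0, ])$n, 0L)
})

test_that("shared counts on a clean simulation equal the planted counts", {
  cfg <- simulationConfig(seed = 91L, ancestorLength = 40000L,
                          substitutionRate = 0, smallIndelRate = 0,
                          sharedTEDensity = 300, specificTECount = 2L,
                          nStretchCount = 0L, ervRecombination = FALSE,
                          sharedDivMax = 0, specDivMax = 0)
  sim <- simulateGenomePair(cfg)
  annA <- annotateRepeats(sim$genomeA[[1]], sim$library, seqId = "chrA")
  annB <- annotateRepeats(sim$genomeB[[1]], sim$library, seqId = "chrB")
  om <- buildOrthoMap(sim$genomeA, sim$genomeB)
  cs <- suppressWarnings(callInsertions(annA, annB, om, sim$genomeA,
                                        sim$genomeB, sim$library))
  truthTab <- table(sim$manifest$superfamily[
    sim$manifest$event_type == "shared" & sim$manifest$elem_length >= 100])
  got <- countShared(cs)
  for (fam in names(truthTab)) {
    expect_equal(got$n[got$superfamily == fam], as.integer(truthTab[[fam]]),
                 info = fam)
  }
})

test_that("every annotated insertion inside fragments is accounted for", {
  p <- smallPipeline()
  cs <- p$calls
  total <- sum(cs@accounting$n) + 2L * nrow(cs@shared)
  annCount <- nrow(p$annA$insertions) + nrow(p$annB$insertions) -
    cs@params$excluded_a - cs@params$excluded_b
  expect_equal(total, annCount)
  # all N-stretch mimics are flagged and excluded from specific calls
  m <- p$sim$manifest
  mims <- m[m$event_type == "n_artifact", ]
  calls <- insertionCalls(cs)
  for (i in seq_len(nrow(mims))) {
    hit <- calls[calls$species == "B" &
                   calls$span_start <= mims$b_end[i] &
                   calls$span_end >= mims$b_start[i], ]
    expect_true(all(hit$status == "artifact"))
    expect_gte(nrow(hit), 1L)
  }
})
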