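test_that("ancestor simulation is seed-deterministic with correct composition", {
  cfg <- simulationConfig(seed = 5L, ancestorLength = 50000L,
                          specificTECount = 5L, nStretchCount = 1L)
  expect_identical(simulateAncestor(cfg), simulateAncestor(cfg))

  cfgGC <- simulationConfig(seed = 6L, ancestorLength = 5000L, gc = 1,
                            sharedTEDensity = 0, specificTECount = 0L,
                            nStretchCount = 0L, ervRecombination = FALSE,
                            endMargin = 100L)
  expect_true(grepl("^[GC]+$", simulateAncestor(cfgGC)))

  cfg5 <- simulationConfig(seed = 7L, ancestorLength = 300000L, gc = 0.5)
  a <- simulateAncestor(cfg5)
  gcFrac <- mean(strsplit(a, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gcFrac - 0.5), 0.004)  # well within the binomial CI
})

test_that("planting produces TSD-framed, consensus-faithful copies", {
  lib <- demoLib()
  cons <- consensusSeq(lib, "L2-Coe")  # 2400 nt
  backbone <- fixedSeq(6000, 65)
  pl <- plantInsertion(backbone, NULL, cons, 3000L, tsdLen = 4L,
                       consensusId = "L2-Coe", species = "A")
  ev <- pl$manifest[1, ]
  s <- pl$seq
  # element flanked by the duplicated 4-mer
  elem <- substr(s, ev$a_start, ev$a_start + ev$elem_length - 1L)
  left4 <- substr(s, ev$a_start - 4L, ev$a_start - 1L)
  right4 <- substr(s, ev$a_start + ev$elem_length,
                   ev$a_start + ev$elem_length + 3L)
  expect_equal(left4, ev$tsd)
  expect_equal(right4, ev$tsd)
  expect_equal(elem, cons)  # divergence 0: identity 1 to the consensus

  # 50% truncation of a 2.4 kb consensus leaves its 1.2 kb 3' half
  pl2 <- plantInsertion(backbone, NULL, cons, 3000L, tsdLen = 4L,
                        truncationFrac = 0.5, species = "A")
  ev2 <- pl2$manifest[1, ]
  expect_equal(ev2$elem_length, 1200L)
  elem2 <- substr(pl2$seq, ev2$a_start, ev2$a_start + 1199L)
  expect_equal(elem2, substr(cons, 1201, 2400))

  # planted divergence: realized mismatch fraction near the target
  pl3 <- tepoly:::withSeed(66, plantInsertion(backbone, NULL, cons, 3000L,
                                              tsdLen = 4L, divergence = 0.10,
                                              species = "A"))
  ev3 <- pl3$manifest[1, ]
  elem3 <- substr(pl3$seq, ev3$a_start, ev3$a_start + ev3$elem_length - 1L)
  mm <- mean(strsplit(elem3, "")[[1]] != strsplit(cons, "")[[1]])
  expect_lt(abs(mm - 0.10), 0.02)

  expect_error(plantInsertion(backbone, NULL, cons, -1L), "range")
  expect_error(plantInsertion(backbone, NULL, cons, 10L,
                              truncationFrac = 1), "truncationFrac")
})

test_that("speciation with zero rates and no events leaves genomes identical", {
  cfg <- simulationConfig(seed = 8L, ancestorLength = 30000L,
                          substitutionRate = 0, smallIndelRate = 0,
                          sharedTEDensity = 100, specificTECount = 0L,
                          nStretchCount = 0L, ervRecombination = FALSE)
  sim <- simulateGenomePair(cfg)
  expect_identical(sim$genomeA[[1]], sim$genomeB[[1]])
})

test_that("per-species specific counts match the configuration", {
  sim <- smallSim()
  m <- sim$manifest
  expect_equal(sum(m$event_type == "specific_A"), 6L)
  expect_equal(sum(m$event_type == "specific_B"), 6L)
  expect_equal(sum(m$event_type == "n_artifact"), 2L)
  expect_equal(sum(m$event_type == "solo_ltr_recombination"), 1L)
})

test_that("pairwise identity outside events matches the configured rate", {
  cfg <- simulationConfig(seed = 9L, ancestorLength = 200000L,
                          substitutionRate = 0.013, smallIndelRate = 0,
                          sharedTEDensity = 0, specificTECount = 0L,
                          nStretchCount = 0L, ervRecombination = FALSE)
  sim <- simulateGenomePair(cfg)
  a <- strsplit(sim$genomeA[[1]], "")[[1]]
  b <- strsplit(sim$genomeB[[1]], "")[[1]]
  expect_equal(length(a), length(b))
  div <- mean(a != b)
  expect_lt(abs(div - 0.013), 0.0012)
})

test_that("manifest coordinates index the exact planted subsequences", {
  sim <- smallSim()
  m <- sim$manifest
  gA <- sim$genomeA[[1]]; gB <- sim$genomeB[[1]]
  for (i in seq_len(nrow(m))) {
    if (!is.na(m$a_start[i]))
      expect_identical(substr(gA, m$a_start[i], m$a_end[i]), m$seq_a[i])
    if (!is.na(m$b_start[i]))
      expect_identical(substr(gB, m$b_start[i], m$b_end[i]), m$seq_b[i])
  }
  # events sorted and within bounds
  expect_true(all(is.na(m$a_end) | m$a_end <= nchar(gA)))
  expect_true(all(is.na(m$b_end) | m$b_end <= nchar(gB)))
})

test_that("identical seeds give identical genomes and manifests", {
  cfg <- simulationConfig(seed = 10L, ancestorLength = 30000L,
                          specificTECount = 3L, nStretchCount = 1L)
  s1 <- simulateGenomePair(cfg)
  s2 <- simulateGenomePair(cfg)
  expect_identical(s1$genomeA, s2$genomeA)
  expect_identical(s1$genomeB, s2$genomeB)
  expect_identical(s1$manifest, s2$manifest)
})

test_that("truth manifests survive a JSON round trip and reject bad schemas", {
  sim <- smallSim()
  f <- tempfile(fileext = ".json")
  writeTruth(sim$manifest, f)
  back <- readTruth(f)
  expect_equal(nrow(back), nrow(sim$manifest))
  expect_equal(back$a_start, sim$manifest$a_start)
  expect_equal(back$tsd, sim$manifest$tsd)

  writeTruth(sim$manifest[0, ], f)
  expect_equal(nrow(readTruth(f)), 0L)

  bad <- sim$manifest
  bad$a_end[3] <- bad$a_start[3] - 10L
  writeTruth(bad, f)
  expect_error(readTruth(f), as.character(bad$event_id[3]))
})

test_that("synthetic annotation tracks feed context and expression analyses", {
  sim <- smallSim()
  trk <- simulateAnnotationTracks(sim, nGenes = 6L, nTETranscripts = 5L)
  expect_gt(length(trk$genesA), 0L)
  expect_gt(length(trk$transcripts), 0L)
  # exons avoid planted blocks by construction
  m <- sim$manifest
  exA <- trk$genesA[trk$genesA$type == "exon"]
  blocksA <- IRanges::IRanges(m$a_start[!is.na(m$a_start)],
                              m$a_end[!is.na(m$a_start)])
  expect_false(any(IRanges::overlapsAny(GenomicRanges::ranges(exA), blocksA)))
  # a TE-derived transcript is found by the expression scan of its element
  teTx <- trk$transcripts[grepl("^tx_te", names(trk$transcripts))]
  expect_gt(length(teTx), 0L)
  ev <- as.integer(sub("tx_te", "", names(teTx)[1]))
  blk <- m$seq_b[m$event_id == ev]
  expect_gte(expressionHits(blk, teTx[1]), 1L)
  # genomic context classifies calls against the generated models
  sp <- specificCalls(smallPipeline()$calls)
  ctx <- genomicContext(sp, genesA = trk$genesA, genesB = trk$genesB)
  expect_equal(nrow(ctx), nrow(sp))
  expect_true(all(ctx$location_class %in%
                    c("intron", "exon_overlap", "intergenic")))
})
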