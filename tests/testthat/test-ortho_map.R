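test_that("identical and reverse-complement sequences anchor end to end", {
  a <- fixedSeq(10000, 31)
  anc <- findAnchors(a, a, seedLen = 20L)
  expect_equal(nrow(anc), 1L)
  expect_equal(anc$a_start, 1L)
  expect_equal(anc$a_end, 10000L)
  expect_equal(anc$b_start, 1L)
  expect_equal(anc$b_end, 10000L)
  expect_equal(anc$identity, 1)

  anc2 <- findAnchors(a, tepoly:::revComp(a), seedLen = 20L)
  expect_equal(nrow(anc2), 1L)
  expect_equal(anc2$strand, "-")
  expect_equal(anc2$b_start, 1L)
  expect_equal(anc2$b_end, 10000L)
})

test_that("anchors tile a 1.3%-diverged copy and match exhaustive runs", {
  a <- fixedSeq(6000, 32)
  b <- tepoly:::withSeed(33, tepoly:::mutateSubstitutions(a, 0.013))
  anc <- findAnchors(a, b, seedLen = 20L)
  cov <- sum(anc$length[anc$strand == "+"])
  expect_gte(cov / nchar(a), 0.95)

  # oracle on a small pair: same-diagonal exact runs >= seedLen from a
  # direct character comparison (substitution-only divergence keeps
  # everything on the main diagonal)
  a2 <- substr(a, 1, 800)
  b2 <- substr(b, 1, 800)
  eq <- strsplit(a2, "")[[1]] == strsplit(b2, "")[[1]]
  r <- rle(eq)
  runLens <- r$lengths[r$values]
  maxRun <- max(runLens)
  anc2 <- findAnchors(a2, b2, seedLen = 20L, minIdentity = 1)
  expect_equal(max(anc2$length), maxRun)
  expect_setequal(anc2$length[anc2$length >= 20], runLens[runLens >= 20])
})

test_that("colinear anchors chain into one fragment; inversions split it", {
  a <- fixedSeq(10000, 34)
  b <- paste0(substr(a, 1, 4000),
              tepoly:::revComp(substr(a, 4001, 6000)),
              substr(a, 6001, 10000))
  anc <- findAnchors(a, b, seedLen = 20L)
  fr <- chainDiagonals(anc, aSeq = "a", bSeq = "b")
  expect_equal(nrow(fr), 3L)
  expect_equal(fr$orientation[order(fr$a_start)], c("+", "-", "+"))

  fr1 <- chainDiagonals(findAnchors(a, a, seedLen = 20L))
  expect_equal(nrow(fr1), 1L)
})

test_that("chain score equals the exhaustive chaining optimum", {
  for (seed in c(12, 40)) {
    anc <- tepoly:::withSeed(seed, {
      n <- 12L
      as <- sort(sample(1:5000, n))
      len <- sample(30:200, n, replace = TRUE)
      bs <- as + sample(-300:300, n, replace = TRUE)
      data.frame(a_start = as, a_end = as + len - 1L,
                 b_start = bs, b_end = bs + len - 1L,
                 strand = "+", length = len,
                 identity = round(runif(n, 0.9, 1), 3))
    })
    got <- chainDiagonals(anc, minChainScore = 1)
    oracle <- exhaustiveChainScore(anc, "+", 200L, 10000L)
    expect_equal(max(attr(got, "chain_scores")), oracle, tolerance = 1e-9)
  }
})

test_that("liftover maps exactly inside anchors and refuses discordant gaps", {
  a <- fixedSeq(5000, 36)
  om <- buildOrthoMap(c(A = a), c(B = a))
  r <- liftCoordinate(om, 1234L, from = "a")
  expect_true(r$mapped)
  expect_equal(r$pos, 1234L)
  rt <- liftCoordinate(om, r$pos, from = "b")
  expect_equal(rt$pos, 1234L)

  # minus orientation: position p maps to (n - p + 1)
  om2 <- buildOrthoMap(c(A = a), c(B = tepoly:::revComp(a)))
  r2 <- liftCoordinate(om2, 11L, from = "a")
  expect_true(r2$mapped)
  expect_equal(r2$pos, nchar(a) - 11L + 1L)

  # a one-sided 6 kb gap (insertion in A) is length-discordant: interior
  # positions are unmapped
  b3 <- paste0(substr(a, 1, 2500), substr(a, 2501, 5000))
  a3 <- paste0(substr(a, 1, 2500), fixedSeq(6000, 37), substr(a, 2501, 5000))
  om3 <- buildOrthoMap(c(A = a3), c(B = b3))
  expect_equal(nrow(orthoFragments(om3)), 1L)
  r3 <- liftCoordinate(om3, 2500L + 3000L, from = "a")
  expect_false(r3$mapped)
  expect_error(liftCoordinate(om3, 2000L, from = "a", fragmentId = 1L),
               NA)
})

test_that("liftover round trip stays within local anchor spacing", {
  p <- smallPipeline()
  om <- p$om
  fr <- orthoFragments(om)[1, ]
  pts <- round(seq(fr$a_start + 1000, fr$a_end - 1000, length.out = 25))
  for (x in pts) {
    f <- liftCoordinate(om, x, from = "a")
    if (!f$mapped) next
    back <- liftCoordinate(om, f$pos, from = "b")
    if (!back$mapped) next
    expect_lte(abs(back$pos - x), 50L)
  }
  # total chained anchor length never exceeds either sequence length
  an <- orthoAnchors(om)
  expect_lte(sum(an$length),
             min(nchar(p$sim$genomeA[[1]]), nchar(p$sim$genomeB[[1]])))
})

test_that("fragment tables and ortho maps survive a file round trip", {
  p <- smallPipeline()
  pref <- tempfile()
  writeOrthoMap(p$om, pref)
  om2 <- readOrthoMap(pref)
  expect_equal(orthoFragments(om2)$a_start, orthoFragments(p$om)$a_start)
  expect_equal(nrow(orthoAnchors(om2)), nrow(orthoAnchors(p$om)))
  r1 <- liftCoordinate(p$om, 5000L, from = "a")
  r2 <- liftCoordinate(om2, 5000L, from = "a")
  expect_equal(r1$pos, r2$pos)
})
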