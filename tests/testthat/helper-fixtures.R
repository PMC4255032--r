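# Shared fixtures, built in code. Expensive objects (a small simulated
# genome pair and its pipeline products) are computed once per test run.

.fixcache <- new.env(parent = emptyenv())

fixedSeq <- function(n, seed, gc = 0.42) {
  r <- tepoly:::withSeed(seed, tepoly:::randomDNA(n, gc))
  r
}

demoLib <- function() {
  if (is.null(.fixcache$lib)) .fixcache$lib <- demoTELibrary(42L)
  .fixcache$lib
}

# small genome pair exercising every event type
smallSim <- function() {
  if (is.null(.fixcache$sim)) {
    cfg <- simulationConfig(seed = 101L, ancestorLength = 80000L,
                            specificTECount = 6L, nStretchCount = 2L,
                            sharedTEDensity = 450)
    .fixcache$sim <- simulateGenomePair(cfg)
  }
  .fixcache$sim
}

smallPipeline <- function() {
  if (is.null(.fixcache$pipe)) {
    sim <- smallSim()
    annA <- annotateRepeats(sim$genomeA[[1]], sim$library, seqId = "chrA")
    annB <- annotateRepeats(sim$genomeB[[1]], sim$library, seqId = "chrB")
    om <- buildOrthoMap(sim$genomeA, sim$genomeB)
    cs <- suppressWarnings(
      callInsertions(annA, annB, om, sim$genomeA, sim$genomeB, sim$library))
    .fixcache$pipe <- list(sim = sim, annA = annA, annB = annB, om = om,
                           calls = cs)
  }
  .fixcache$pipe
}

# independent full-DP identity via the naive unbanded aligner
oracleIdentity <- function(a, b, local = TRUE) {
  r <- tepoly:::cpp_align_full(a, b, 1L, -2L, 5L, 1L, local)
  r$identity
}

# brute-force transitive closure of the pairwise merge predicate, by
# breadth-first search over the full pairwise adjacency (independent of the
# union-find in mergeSplitHits)
bruteForceClosure <- function(hits, maxGenomeGap, maxConsOverlap) {
  n <- nrow(hits)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      hi <- hits[i, ]; hj <- hits[j, ]
      if (hi$seq_id != hj$seq_id || hi$consensus_id != hj$consensus_id ||
          hi$strand != hj$strand) next
      if (hi$g_start > hj$g_start) { tmp <- hi; hi <- hj; hj <- tmp }
      gapG <- hj$g_start - hi$g_end - 1L
      ok <- gapG <= maxGenomeGap && gapG >= -(maxConsOverlap + 1L)
      ok <- ok && if (hi$strand == "+") {
        hj$c_start >= hi$c_end - maxConsOverlap
      } else {
        hj$c_end <= hi$c_start + maxConsOverlap
      }
      if (ok) adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

# exhaustive best-chain oracle over all anchor subsets (<= ~30 anchors),
# same feasibility and penalty rule as the chaining DP but computed by
# depth-first enumeration
exhaustiveChainScore <- function(anchors, strand, maxDiagDrift, maxGap) {
  an <- anchors[anchors$strand == strand, , drop = FALSE]
  an <- an[order(an$a_start, an$a_end), , drop = FALSE]
  n <- nrow(an)
  if (n == 0L) return(-Inf)
  w <- an$length * an$identity
  best <- -Inf
  recurse <- function(last, score) {
    best <<- max(best, score)
    from <- if (is.na(last)) 1L else last + 1L
    if (from > n) return()
    for (i in from:n) {
      if (is.na(last)) {
        recurse(i, score + w[i])
      } else {
        st <- tepoly:::.chainStep(
          an$a_start[i], an$a_end[i], an$b_start[i], an$b_end[i],
          an$a_start[last], an$a_end[last], an$b_start[last],
          an$b_end[last], strand, maxDiagDrift, maxGap)
        if (st$ok) recurse(i, score + w[i] - st$penalty)
      }
    }
  }
  recurse(NA, 0)
  best
}

# exhaustive search over suffix-prefix pairs (TSD oracle)
bruteForceTSD <- function(lf, rf, minLen = 2L, maxLen = 25L) {
  best <- ""
  for (L in minLen:min(maxLen, nchar(lf), nchar(rf))) {
    suf <- substr(lf, nchar(lf) - L + 1L, nchar(lf))
    if (suf == substr(rf, 1L, L) && L > nchar(best)) best <- suf
  }
  best
}
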