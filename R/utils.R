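#' @useDynLib tepoly, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats runif rnorm rbinom rgeom rlnorm setNames
#' @importFrom utils write.table read.delim
NULL

# base -> 2-bit code lookup (A=0, C=1, G=2, T=3, anything else NA)
.BASE_CODE <- local({
  v <- rep(NA_integer_, 256)
  v[utf8ToInt("A")] <- 0L; v[utf8ToInt("a")] <- 0L
  v[utf8ToInt("C")] <- 1L; v[utf8ToInt("c")] <- 1L
  v[utf8ToInt("G")] <- 2L; v[utf8ToInt("g")] <- 2L
  v[utf8ToInt("T")] <- 3L; v[utf8ToInt("t")] <- 3L
  v
})

# coerce DNAString / DNAStringSet element / character to a plain upper-case
# character scalar
asSeqString <- function(x) {
  if (is(x, "DNAString") || is(x, "DNAStringSet")) {
    if (is(x, "DNAStringSet")) {
      stopifnot(length(x) == 1L)
      x <- x[[1L]]
    }
    return(toupper(as.character(x)))
  }
  stopifnot(is.character(x), length(x) == 1L)
  toupper(x)
}

seqCodes <- function(seq) {
  .BASE_CODE[utf8ToInt(asSeqString(seq))]
}

# rolling 2-bit k-mer hash; numeric (exact for k <= 26); NA where the window
# contains a non-ACGT character
kmerHashes <- function(codes, k) {
  n <- length(codes)
  if (n < k) return(numeric(0))
  h <- numeric(n - k + 1L)
  for (j in seq_len(k)) {
    h <- h + as.numeric(codes[j:(n - k + j)]) * 4^(k - j)
  }
  h
}

revComp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(asSeqString(seq))))
}

# run an expression under a temporary RNG seed, restoring the caller's RNG
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# random DNA string of length n at a given GC content
randomDNA <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# apply point substitutions at the given per-site rate; returns the string
mutateSubstitutions <- function(seq, rate) {
  s <- asSeqString(seq)
  if (rate <= 0 || nchar(s) == 0L) return(s)
  x <- strsplit(s, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(x)) < rate & x %in% c("A", "C", "G", "T"))
  if (length(hit)) {
    alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
    x[hit] <- vapply(x[hit], function(b) {
      i <- sample.int(3L, 1L)
      substr(alt[[b]], i, i)
    }, character(1L), USE.NAMES = FALSE)
  }
  paste(x, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt1 <- function(x) formatC(x, format = "f", digits = 1)
fmt2 <- function(x) formatC(x, format = "f", digits = 2)
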