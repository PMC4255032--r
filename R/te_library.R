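#' @import S4Vectors
#' @import IRanges
NULL

# Controlled vocabulary of TE classification tokens (class / order /
# superfamily in the Wicker scheme, plus lineage-specific SINE families that
# are conventionally used as library labels).
.WICKER_VOCAB <- data.frame(
  superfamily = c(
    "CR1", "L1", "L2", "RTE", "R2", "Rex1", "Jockey", "I", "Deu",
    "Penelope", "SINE", "tRNA-SINE", "CoeG-SINE", "LF-SINE",
    "Gypsy", "Copia", "BEL", "DIRS", "ERV", "ERV1",
    "hAT", "Tc1-Mariner", "PIF-Harbinger", "PiggyBac", "Mutator",
    "CACTA", "Merlin", "Transib", "Crypton", "Helitron", "Maverick",
    "MITE", "MITE-like", "Unknown"),
  te_class = c(rep("I", 20), rep("II", 13), NA),
  te_order = c(rep("LINE", 9), "PLE", rep("SINE", 4), rep("LTR", 6),
               rep("TIR", 8), "Crypton", "Helitron", "Maverick",
               "TIR", "TIR", NA),
  stringsAsFactors = FALSE
)

#' Controlled vocabulary of TE superfamily tokens
#'
#' Returns the classification table (superfamily token, class, order) that
#' [readTELibrary()] validates consensus headers against.
#'
#' @return A data.frame with columns `superfamily`, `te_class`, `te_order`.
#' @export
teSuperfamilies <- function() .WICKER_VOCAB

#' TE consensus library
#'
#' Container for a transposable-element consensus library: one nucleotide
#' consensus per entry together with its classification (superfamily token
#' from [teSuperfamilies()]), autonomy flag and, for LTR elements, the
#' declared LTR length.
#'
#' @slot sequences A [Biostrings::DNAStringSet] of consensus sequences,
#'   named by consensus id.
#' @slot info A [S4Vectors::DataFrame] with one row per consensus and
#'   columns `id`, `superfamily`, `te_class`, `te_order`, `is_autonomous`,
#'   `ltr_length` (NA when not applicable).
#' @export
setClass("TELibrary",
  representation(sequences = "DNAStringSet", info = "DataFrame"))

setValidity("TELibrary", function(object) {
  msgs <- character(0)
  ids <- object@info$id
  if (length(object@sequences) != nrow(object@info))
    msgs <- c(msgs, "sequences and info must have the same length")
  if (anyDuplicated(ids))
    msgs <- c(msgs, sprintf("duplicated consensus id: %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (length(object@sequences) && any(Biostrings::width(object@sequences) < 50))
    msgs <- c(msgs, "all consensus sequences must be at least 50 nt")
  bad <- setdiff(object@info$superfamily, .WICKER_VOCAB$superfamily)
  if (length(bad))
    msgs <- c(msgs, sprintf(
      "unknown superfamily token(s): %s (allowed: %s)",
      paste(bad, collapse = ", "),
      paste(.WICKER_VOCAB$superfamily, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct a TE consensus library
#'
#' @param sequences Named [Biostrings::DNAStringSet] (or named character
#'   vector) of consensus sequences.
#' @param superfamily Character vector of superfamily tokens, one per
#'   consensus (see [teSuperfamilies()]).
#' @param is_autonomous Logical vector (recycled), whether the element
#'   encodes its own transposition machinery.
#' @param ltr_length Integer vector (recycled), declared LTR length in nt
#'   for LTR elements, NA otherwise.
#' @return A [TELibrary-class] object.
#' @examples
#' lib <- TELibrary(c(`CR1-X` = paste(rep("ACGT", 30), collapse = "")),
#'                  superfamily = "CR1")
#' @export
TELibrary <- function(sequences, superfamily,
                      is_autonomous = NA, ltr_length = NA_integer_) {
  if (is.character(sequences))
    sequences <- Biostrings::DNAStringSet(sequences)
  ids <- names(sequences)
  if (is.null(ids) && length(sequences))
    stop("consensus sequences must be named")
  n <- length(sequences)
  info <- S4Vectors::DataFrame(
    id = as.character(ids %||% character(0)),
    superfamily = rep_len(as.character(superfamily), n),
    is_autonomous = rep_len(as.logical(is_autonomous), n),
    ltr_length = rep_len(as.integer(ltr_length), n))
  m <- match(info$superfamily, .WICKER_VOCAB$superfamily)
  info$te_class <- .WICKER_VOCAB$te_class[m]
  info$te_order <- .WICKER_VOCAB$te_order[m]
  info <- info[, c("id", "superfamily", "te_class", "te_order",
                   "is_autonomous", "ltr_length")]
  new("TELibrary", sequences = sequences, info = info)
}

setMethod("show", "TELibrary", function(object) {
  cat(sprintf("TELibrary with %d consensus sequence(s)\n",
              length(object@sequences)))
  if (length(object@sequences)) {
    df <- as.data.frame(object@info)
    df$length_nt <- Biostrings::width(object@sequences)
    print(head(df, 10), row.names = FALSE)
    if (nrow(df) > 10) cat(sprintf("... and %d more\n", nrow(df) - 10))
  }
  invisible(NULL)
})

#' @describeIn TELibrary-class Number of consensus entries.
#' @param x,object A `TELibrary`.
#' @export
setMethod("length", "TELibrary", function(x) length(x@sequences))

#' Accessors for TELibrary
#'
#' @param x A [TELibrary-class] object.
#' @param id Consensus id (for `consensusSeq`).
#' @return `consensusIds`: character vector of ids; `consensusSeqs`: the
#'   `DNAStringSet`; `consensusInfo`: the classification `DataFrame`;
#'   `consensusSeq`: a single consensus as a character string;
#'   `superfamilyOf`: named character vector mapping id to superfamily.
#' @export
consensusIds <- function(x) as.character(x@info$id)

#' @rdname consensusIds
#' @export
consensusSeqs <- function(x) x@sequences

#' @rdname consensusIds
#' @export
consensusInfo <- function(x) x@info

#' @rdname consensusIds
#' @export
consensusSeq <- function(x, id) {
  i <- match(id, consensusIds(x))
  if (is.na(i)) stop(sprintf("unknown consensus id '%s'", id))
  toupper(as.character(x@sequences[[i]]))
}

#' @rdname consensusIds
#' @export
superfamilyOf <- function(x) {
  setNames(as.character(x@info$superfamily), x@info$id)
}

#' Read a TE consensus library from FASTA
#'
#' Classification is taken from RepeatMasker-style headers (`id#superfamily`)
#' or, preferentially, from a sidecar TSV with columns `id`, `class`,
#' `order`, `superfamily` (optional columns `is_autonomous`, `ltr_length`).
#' When both are present the sidecar wins.
#'
#' @param path Path to the library FASTA file.
#' @param sidecar Optional path to the classification TSV.
#' @return A [TELibrary-class].
#' @export
readTELibrary <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stop(sprintf("library FASTA not found: %s", path))
  if (file.size(path) == 0L) {
    warning("empty library FASTA; returning an empty library")
    return(TELibrary(Biostrings::DNAStringSet(), character(0)))
  }
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop(sprintf(
      "malformed FASTA in '%s': %s", path, conditionMessage(e))))
  if (length(seqs) == 0L) {
    warning("empty library FASTA; returning an empty library")
    return(TELibrary(Biostrings::DNAStringSet(), character(0)))
  }
  hdr <- sub("\\s.*$", "", names(seqs))
  ids <- sub("#.*$", "", hdr)
  fams <- ifelse(grepl("#", hdr, fixed = TRUE), sub("^[^#]*#", "", hdr),
                 "Unknown")
  auton <- rep(NA, length(ids))
  ltr <- rep(NA_integer_, length(ids))
  if (!is.null(sidecar)) {
    sc <- read.delim(sidecar, stringsAsFactors = FALSE)
    if (!all(c("id", "superfamily") %in% names(sc)))
      stop("sidecar TSV must have columns 'id' and 'superfamily'")
    m <- match(ids, sc$id)
    fams[!is.na(m)] <- sc$superfamily[m[!is.na(m)]]
    if ("is_autonomous" %in% names(sc))
      auton[!is.na(m)] <- as.logical(sc$is_autonomous[m[!is.na(m)]])
    if ("ltr_length" %in% names(sc))
      ltr[!is.na(m)] <- as.integer(sc$ltr_length[m[!is.na(m)]])
  }
  if (anyDuplicated(ids))
    stop(sprintf("duplicate consensus id(s) in library: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  names(seqs) <- ids
  TELibrary(seqs, superfamily = fams, is_autonomous = auton, ltr_length = ltr)
}

#' Write a TE consensus library to FASTA (and optional sidecar TSV)
#'
#' @param x A [TELibrary-class].
#' @param path Output FASTA path; headers are `id#superfamily`.
#' @param sidecar Optional path for the classification TSV.
#' @return `path`, invisibly.
#' @export
writeTELibrary <- function(x, path, sidecar = NULL) {
  seqs <- x@sequences
  names(seqs) <- paste0(x@info$id, "#", x@info$superfamily)
  Biostrings::writeXStringSet(seqs, path)
  if (!is.null(sidecar)) {
    df <- data.frame(id = x@info$id, class = x@info$te_class,
                     order = x@info$te_order,
                     superfamily = x@info$superfamily,
                     is_autonomous = x@info$is_autonomous,
                     ltr_length = x@info$ltr_length)
    write.table(df, sidecar, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Mask low-complexity sequence
#'
#' Flags simple-repeat / low-complexity regions with a DUST-style triplet
#' over-representation score: for each window the score is
#' `sum(c_t * (c_t - 1) / 2) / (n_triplets - 1)` over triplet counts `c_t`;
#' windows scoring above `threshold` are masked and overlapping masked
#' windows are merged. Annotation anchors falling inside masked intervals
#' are discarded downstream.
#'
#' @param seq Nucleotide sequence (character or `DNAString`).
#' @param window Window size in nt (>= 8); default 64.
#' @param threshold Score threshold above which a window is masked;
#'   default 2.0.
#' @param step Window step; default `window / 2`.
#' @return An [IRanges::IRanges] of masked intervals (sorted,
#'   non-overlapping, within sequence bounds). Sequences shorter than
#'   `window` yield an empty mask.
#' @examples
#' maskLowComplexity(strrep("AT", 60))
#' @export
maskLowComplexity <- function(seq, window = 64L, threshold = 2.0,
                              step = window %/% 2L) {
  if (window < 8L) stop("window must be >= 8")
  s <- asSeqString(seq)
  n <- nchar(s)
  if (n < window) return(IRanges::IRanges())
  codes <- seqCodes(s)
  trip <- codes[1:(n - 2)] * 16L + codes[2:(n - 1)] * 4L + codes[3:n] + 1L
  starts <- unique(c(seq(1L, n - window + 1L, by = step), n - window + 1L))
  hit <- logical(length(starts))
  for (i in seq_along(starts)) {
    w <- trip[starts[i]:(starts[i] + window - 3L)]
    w <- w[!is.na(w)]
    if (length(w) < 4L) next
    ct <- tabulate(w, nbins = 64L)
    sc <- sum(ct * (ct - 1) / 2) / (length(w) - 1)
    hit[i] <- sc > threshold
  }
  if (!any(hit)) return(IRanges::IRanges())
  IRanges::reduce(IRanges::IRanges(start = starts[hit],
                                   width = window))
}

#' Bundled demonstration TE consensus library
#'
#' Builds a small synthetic consensus library (LINEs, SINEs, an LTR
#' retrotransposon, an endogenous retrovirus with terminal LTRs, and a
#' MITE with terminal inverted repeats) used by the simulator and the
#' examples. Sequences are random at fixed seed, so the library is fully
#' reproducible and carries no biological sequence content.
#'
#' @param seed RNG seed controlling the library sequences.
#' @return A [TELibrary-class] with 9 entries.
#' @export
demoTELibrary <- function(seed = 42L) {
  withSeed(seed, {
    gc <- 0.42
    ltr <- randomDNA(462, gc)
    erv_internal <- randomDNA(3705, gc)
    tir <- randomDNA(25, gc)
    mite_core <- randomDNA(175, gc)
    seqs <- c(
      `CR1-Coe`   = randomDNA(4500, gc),
      `L1-Coe`    = randomDNA(3500, gc),
      `L2-Coe`    = randomDNA(2400, gc),
      `CoeG-SINE` = randomDNA(320, gc),
      `LF-SINE`   = randomDNA(540, gc),
      `Coe-SINE2` = randomDNA(260, gc),
      `Gypsy-Coe` = randomDNA(2500, gc),
      `CoeERV1`   = paste0(ltr, erv_internal, ltr),
      `MITE-Coe`  = paste0(tir, mite_core, revComp(tir)))
    TELibrary(
      seqs,
      superfamily = c("CR1", "L1", "L2", "CoeG-SINE", "LF-SINE", "SINE",
                      "Gypsy", "ERV", "MITE"),
      is_autonomous = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE,
                        FALSE),
      ltr_length = c(NA, NA, NA, NA, NA, NA, NA, 462L, NA))
  })
}
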