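#' @importFrom tools md5sum
NULL

.writeFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

.readFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

# provenance log: versions, parameters, input checksums. Deliberately no
# timestamps, so identical runs produce byte-identical output trees.
.writeProvenance <- function(outdir, stage, params, inputs = character(0)) {
  prov <- list(
    tool = "tepoly",
    version = as.character(utils::packageVersion("tepoly")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    stage = stage,
    params = unclass(params),
    input_md5 = as.list(md5sum(inputs[file.exists(inputs)])))
  jsonlite::write_json(prov, file.path(outdir,
                                       sprintf("provenance_%s.json", stage)),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' Pipeline stage: simulate a genome pair
#'
#' Runs [simulateGenomePair()] and writes the genome FASTAs, the consensus
#' library (FASTA plus classification sidecar) and the truth manifest into
#' `outdir`.
#'
#' @param config A [simulationConfig()].
#' @param outdir Output directory.
#' @return The simulation object, invisibly.
#' @export
runSimulate <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateGenomePair(config)
  .writeFasta(sim$genomeA, file.path(outdir, "genomeA.fa"))
  .writeFasta(sim$genomeB, file.path(outdir, "genomeB.fa"))
  writeTELibrary(sim$library, file.path(outdir, "library.fa"),
                 sidecar = file.path(outdir, "library.tsv"))
  writeTruth(sim$manifest, file.path(outdir, "truth.json"))
  cfg <- sim$config; cfg$library <- NULL
  .writeProvenance(outdir, "simulate", cfg)
  invisible(sim)
}

#' Pipeline stage: annotate TE copies in a genome
#'
#' Annotates every sequence of a FASTA file against the library and writes
#' the RepeatMasker-style TSV and a GFF3 of merged insertions.
#'
#' @param genomeFasta Path to the genome FASTA.
#' @param libraryFasta Path to the library FASTA (id#superfamily headers).
#' @param outPrefix Output path prefix (`<outPrefix>.tsv`,
#'   `<outPrefix>.gff3`).
#' @param librarySidecar Optional classification sidecar TSV.
#' @param ... Passed to [annotateRepeats()].
#' @return The annotation (list with `insertions`, `hits`), invisibly.
#' @export
runAnnotate <- function(genomeFasta, libraryFasta, outPrefix,
                        librarySidecar = NULL, ...) {
  lib <- readTELibrary(libraryFasta, sidecar = librarySidecar)
  seqs <- .readFasta(genomeFasta)
  anns <- lapply(names(seqs), function(nm)
    annotateRepeats(seqs[[nm]], lib, seqId = nm, ...))
  ann <- list(
    insertions = do.call(rbind, lapply(anns, `[[`, "insertions")),
    hits = do.call(rbind, lapply(anns, `[[`, "hits")))
  # renumber element ids globally
  if (nrow(ann$insertions)) {
    key <- paste(ann$insertions$seq_id, ann$insertions$element_id)
    hkey <- paste(ann$hits$seq_id, ann$hits$element_id)
    ann$insertions$element_id <- seq_len(nrow(ann$insertions))
    ann$hits$element_id <- ann$insertions$element_id[match(hkey, key)]
  }
  writeAnnotationTSV(ann, paste0(outPrefix, ".tsv"))
  writeAnnotationGFF3(ann, paste0(outPrefix, ".gff3"))
  .writeProvenance(dirname(outPrefix), basename(outPrefix),
                   list(...), c(genomeFasta, libraryFasta))
  invisible(ann)
}

#' Pipeline stage: build the orthology map
#'
#' @param fastaA,fastaB Genome FASTA paths.
#' @param outPrefix Output prefix (`<outPrefix>.fragments.tsv`,
#'   `<outPrefix>.anchors.tsv`, plus the Table-S1-style
#'   `<outPrefix>.table.tsv`).
#' @param ... Passed to [buildOrthoMap()].
#' @return The [OrthoMap-class], invisibly.
#' @export
runMap <- function(fastaA, fastaB, outPrefix, ...) {
  a <- .readFasta(fastaA); b <- .readFasta(fastaB)
  om <- buildOrthoMap(a, b, ...)
  writeOrthoMap(om, outPrefix)
  writeFragmentTable(om, paste0(outPrefix, ".table.tsv"))
  .writeProvenance(dirname(outPrefix), basename(outPrefix), list(...),
                   c(fastaA, fastaB))
  invisible(om)
}

#' Pipeline stage: call species-specific insertions
#'
#' @param annPrefixA,annPrefixB Annotation prefixes from [runAnnotate()].
#' @param mapPrefix Ortho-map prefix from [runMap()].
#' @param fastaA,fastaB Genome FASTA paths.
#' @param libraryFasta,librarySidecar Library paths.
#' @param outPrefix Output prefix (`<outPrefix>.calls.tsv`, `.bed`,
#'   `.json`, `.shared.tsv`).
#' @param ... Passed to [callInsertions()].
#' @return The [InsertionCalls-class], invisibly.
#' @export
runCall <- function(annPrefixA, annPrefixB, mapPrefix, fastaA, fastaB,
                    libraryFasta, outPrefix, librarySidecar = NULL, ...) {
  lib <- readTELibrary(libraryFasta, sidecar = librarySidecar)
  annA <- readAnnotationTSV(paste0(annPrefixA, ".tsv"), library = lib)
  annB <- readAnnotationTSV(paste0(annPrefixB, ".tsv"), library = lib)
  om <- readOrthoMap(mapPrefix)
  gA <- .readFasta(fastaA); gB <- .readFasta(fastaB)
  cs <- callInsertions(annA, annB, om, gA, gB, lib, ...)
  writeCallsTSV(cs, paste0(outPrefix, ".calls.tsv"))
  writeCallsBED(cs, paste0(outPrefix, ".bed"))
  writeCallsJSON(cs, paste0(outPrefix, ".json"))
  sh <- cs@shared
  sh$reciprocal_overlap <- sprintf("%.4f", sh$reciprocal_overlap)
  write.table(sh, paste0(outPrefix, ".shared.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  .writeProvenance(dirname(outPrefix), paste0(basename(outPrefix), "_call"),
                   list(...), c(fastaA, fastaB, libraryFasta))
  invisible(cs)
}

#' Run the whole comparative pipeline on a simulated genome pair
#'
#' End-to-end protocol on one simulation: annotate both genomes against
#' the library, build the orthology map, pair annotations face to face and
#' call species-specific insertions, characterize them structurally, score
#' against the truth manifest, and render the reports. All intermediate
#' files are written under `outdir`.
#'
#' @param config A [simulationConfig()] (or an existing `teSimulation`).
#' @param outdir Output directory.
#' @param copyNumberScan Run the copy-number scan in the feature stage
#'   (default FALSE; it dominates feature-stage runtime on large
#'   simulations).
#' @param transcripts Optional transcript set for the expression column.
#' @return A list: `sim`, `annA`, `annB`, `om`, `calls`
#'   ([InsertionCalls-class]), `features`, `divsum`, `score` (from
#'   [scorePipeline()]), `files`.
#' @export
runAll <- function(config, outdir, copyNumberScan = FALSE,
                   transcripts = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- if (inherits(config, "teSimulation")) config
         else runSimulate(config, outdir)
  if (inherits(config, "teSimulation")) {
    .writeFasta(sim$genomeA, file.path(outdir, "genomeA.fa"))
    .writeFasta(sim$genomeB, file.path(outdir, "genomeB.fa"))
    writeTELibrary(sim$library, file.path(outdir, "library.fa"),
                   sidecar = file.path(outdir, "library.tsv"))
    writeTruth(sim$manifest, file.path(outdir, "truth.json"))
  }
  lib <- sim$library
  annA <- annotateRepeats(sim$genomeA[[1]], lib, seqId = names(sim$genomeA))
  annB <- annotateRepeats(sim$genomeB[[1]], lib, seqId = names(sim$genomeB))
  writeAnnotationTSV(annA, file.path(outdir, "annotA.tsv"))
  writeAnnotationTSV(annB, file.path(outdir, "annotB.tsv"))
  writeAnnotationGFF3(annA, file.path(outdir, "annotA.gff3"))
  writeAnnotationGFF3(annB, file.path(outdir, "annotB.gff3"))
  om <- buildOrthoMap(sim$genomeA, sim$genomeB)
  writeOrthoMap(om, file.path(outdir, "orthomap"))
  writeFragmentTable(om, file.path(outdir, "orthomap.table.tsv"))
  cs <- callInsertions(annA, annB, om, sim$genomeA, sim$genomeB, lib)
  writeCallsTSV(cs, file.path(outdir, "calls.tsv"))
  writeCallsBED(cs, file.path(outdir, "calls.bed"))
  writeCallsJSON(cs, file.path(outdir, "calls.json"))
  feats <- featureTable(cs, sim$genomeA, sim$genomeB, lib,
                        transcripts = transcripts,
                        copyNumberScan = copyNumberScan)
  divsum <- divergenceSummary(cs, sharedCount = nrow(cs@shared))
  files <- writeSummaryReport(cs, feats, divsum,
                              file.path(outdir, "reports"))
  score <- scorePipeline(cs, sim$manifest)
  jsonlite::write_json(
    score[c("recall", "precision", "n_truth", "n_calls",
            "artifact_flagged_fraction", "tsd_exact_fraction",
            "solo_recovered")],
    file.path(outdir, "reports", "truth_score.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- sim$config; cfg$library <- NULL
  .writeProvenance(outdir, "run_all",
                   c(cfg, list(copyNumberScan = copyNumberScan)))
  list(sim = sim, annA = annA, annB = annB, om = om, calls = cs,
       features = feats, divsum = divsum, score = score,
       files = c(files, file.path(outdir, "reports", "truth_score.json")))
}
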