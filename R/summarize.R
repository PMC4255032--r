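#' Headline divergence statistics of a genome comparison
#'
#' Computes the summary statistics of the insertion-polymorphism analysis:
#' per-species counts, base pairs and percentages of the analyzed span
#' contributed by species-specific insertions, the combined percentage
#' (both as raw quotient and as the sum of the per-species percentages each
#' rounded to two decimals, which is how such numbers are conventionally
#' added up in print), the density of shared insertions per Mb (raw, and
#' rounded to the nearest ten for prose), and length statistics.
#'
#' @param calls Either an [InsertionCalls-class] (its specific calls are
#'   used) or a data.frame with columns `species` and `length_nt` (one row
#'   per specific insertion).
#' @param sharedCount Number of insertions shared by the two genomes.
#' @param analyzedBp Total analyzed span in nt (> 0). Defaults to
#'   [analyzedBp()] when `calls` is an `InsertionCalls`.
#' @return A list of class `divergenceSummary`: `analyzed_bp`,
#'   `shared_count`, `species` (vector of labels), `specific_counts`,
#'   `specific_bp`, `specific_kb` (rounded to 0.1), `specific_pct_raw`,
#'   `specific_pct` (rounded to 2 decimals), `combined_pct_raw`,
#'   `combined_pct_rounded`, `shared_density_per_mb`,
#'   `shared_density_rounded10`, `mean_length`, `min_length`,
#'   `max_length`.
#' @export
divergenceSummary <- function(calls, sharedCount, analyzedBp = NULL) {
  if (is(calls, "InsertionCalls")) {
    if (is.null(analyzedBp)) analyzedBp <- calls@analyzedBp
    sp <- specificCalls(calls)
    df <- data.frame(species = sp$species, length_nt = sp$length)
  } else {
    df <- as.data.frame(calls)
    stopifnot(all(c("species", "length_nt") %in% names(df)))
  }
  if (is.null(analyzedBp) || analyzedBp <= 0)
    stop("analyzedBp must be > 0")
  speciesLevels <- sort(unique(as.character(df$species)))
  if (length(speciesLevels) == 0L) speciesLevels <- c("A", "B")
  cnt <- vapply(speciesLevels, function(s) sum(df$species == s), integer(1))
  bp <- vapply(speciesLevels, function(s)
    sum(df$length_nt[df$species == s]), numeric(1))
  pctRaw <- 100 * bp / analyzedBp
  pct <- round(pctRaw, 2)
  dens <- sharedCount / (analyzedBp / 1e6)
  res <- list(
    analyzed_bp = analyzedBp,
    shared_count = sharedCount,
    species = speciesLevels,
    specific_counts = cnt,
    specific_bp = bp,
    specific_kb = round(bp / 1000, 1),
    specific_pct_raw = pctRaw,
    specific_pct = pct,
    combined_pct_raw = round(sum(pctRaw), 2),
    combined_pct_rounded = round(sum(pct), 2),
    shared_density_per_mb = dens,
    shared_density_rounded10 = round(dens, -1),
    mean_length = if (nrow(df)) round(mean(df$length_nt)) else 0,
    min_length = if (nrow(df)) min(df$length_nt) else 0,
    max_length = if (nrow(df)) max(df$length_nt) else 0)
  class(res) <- "divergenceSummary"
  res
}

#' @export
print.divergenceSummary <- function(x, ...) {
  cat(sprintf("Analyzed span: %.3f Mb; shared insertions: %d (~%d per Mb)\n",
              x$analyzed_bp / 1e6, x$shared_count,
              as.integer(x$shared_density_rounded10)))
  for (i in seq_along(x$species)) {
    cat(sprintf(
      "  %s: %d specific insertion(s), %.1f kb, %.2f%% of analyzed span\n",
      x$species[i], x$specific_counts[i], x$specific_kb[i],
      x$specific_pct[i]))
  }
  cat(sprintf(
    "combined: %.2f%% (sum of rounded per-species values; raw %.2f%%)\n",
    x$combined_pct_rounded, x$combined_pct_raw))
  cat(sprintf("specific insertion length: mean %d, range %d-%d nt\n",
              x$mean_length, x$min_length, x$max_length))
  invisible(x)
}

#' Extrapolate species-specific insertion counts genome-wide
#'
#' Scales the average per-species count of specific insertions observed in
#' the analyzed fraction of the genome up to the whole genome, with a
#' reporting band obtained by rounding the estimate down and up to the
#' nearest half leading decade (e.g. an estimate of 6,750 is reported as
#' the 6,500-7,000 band).
#'
#' @param avgSpecificPerSpecies Average number of species-specific
#'   insertions per species in the analyzed regions.
#' @param fractionAnalyzed Fraction of the genome analyzed (0 < f <= 1).
#' @return A list: `per_species` (point estimate), `combined`
#'   (2 x per-species), `band` (length-2 numeric), `band_combined`.
#' @export
extrapolateGenome <- function(avgSpecificPerSpecies, fractionAnalyzed) {
  if (!is.numeric(fractionAnalyzed) || fractionAnalyzed <= 0 ||
      fractionAnalyzed > 1)
    stop("fractionAnalyzed must be in (0, 1]")
  est <- avgSpecificPerSpecies / fractionAnalyzed
  band <- if (est > 0) {
    step <- 10^floor(log10(est)) / 2
    c(floor(est / step) * step, ceiling(est / step) * step)
  } else c(0, 0)
  list(per_species = est, combined = 2 * est, band = band,
       band_combined = 2 * band)
}

# import gene models from a GFF3 path or pass a GRanges through
.importGenes <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) x <- rtracklayer::import(x)
  x
}

#' Genomic context of insertion calls
#'
#' Classifies each call as intronic or intergenic relative to gene models
#' and reports the distance to the closest exon boundary (rounded to
#' 0.1 kb) and the corresponding gene. Calls strictly inside a gene body
#' and not overlapping an exon are intronic. When two exons are
#' equidistant, the one with the lower coordinate is reported. With no gene
#' models on the carrier sequence the distance is unbounded and rendered as
#' `">"`.
#'
#' @param calls A data.frame with columns `species`, `seq_id`, `start`,
#'   `end` (e.g. [specificCalls()]) .
#' @param genesA,genesB Gene models for the two genomes: GFF3 file paths or
#'   `GRanges` with `type` (`gene`/`exon`) and `ID`/`Parent` attributes;
#'   `NULL` when unavailable.
#' @return A data.frame with one row per call: `location_class`
#'   (`intron`, `exon_overlap` or `intergenic`), `distance_kb`,
#'   `distance_label`, `gene_id`.
#' @export
genomicContext <- function(calls, genesA = NULL, genesB = NULL) {
  gA <- .importGenes(genesA)
  gB <- .importGenes(genesB)
  n <- nrow(calls)
  out <- data.frame(location_class = rep("intergenic", n),
                    distance_kb = rep(NA_real_, n),
                    distance_label = rep(">", n),
                    gene_id = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  for (i in seq_len(n)) {
    gm <- if (calls$species[i] == "A") gA else gB
    if (is.null(gm)) next
    typ <- as.character(gm$type)
    genes <- gm[typ == "gene"]
    exons <- gm[typ == "exon"]
    genes <- genes[as.character(GenomicRanges::seqnames(genes)) ==
                     calls$seq_id[i]]
    exons <- exons[as.character(GenomicRanges::seqnames(exons)) ==
                     calls$seq_id[i]]
    if (length(exons) == 0L) next
    callRange <- GenomicRanges::GRanges(
      calls$seq_id[i], IRanges::IRanges(calls$start[i], calls$end[i]))
    inGene <- length(genes) > 0 &&
      any(IRanges::overlapsAny(callRange, genes, type = "within"))
    onExon <- any(IRanges::overlapsAny(callRange, exons))
    out$location_class[i] <- if (inGene && !onExon) "intron"
      else if (onExon) "exon_overlap" else "intergenic"
    d <- GenomicRanges::distance(callRange, exons)
    j <- which(d == min(d, na.rm = TRUE))
    if (length(j) > 1L)  # tie: lower coordinate wins
      j <- j[which.min(GenomicRanges::start(exons)[j])]
    out$distance_kb[i] <- round(d[j] / 1000, 1)
    out$distance_label[i] <- fmt1(d[j] / 1000)
    gid <- exons$gene_id %||% exons$Parent %||% exons$ID
    if (!is.null(gid)) out$gene_id[i] <- as.character(unlist(gid[j])[1])
  }
  out
}

#' Render the comparison reports
#'
#' Writes the shared/specific count table (per superfamily), the
#' per-insertion structural feature table, a JSON summary and a Markdown
#' summary into `dir`. Output is byte-deterministic for identical inputs:
#' fixed ordering, fixed rounding, no timestamps.
#'
#' @param callSet An [InsertionCalls-class].
#' @param features Feature table from [featureTable()] (may be `NULL`).
#' @param divsum A `divergenceSummary` (from [divergenceSummary()]).
#' @param dir Output directory (created if needed).
#' @param extrapolation Optional result of [extrapolateGenome()].
#' @return Character vector of the files written, invisibly.
#' @export
writeSummaryReport <- function(callSet, features, divsum, dir,
                               extrapolation = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  # Table 1 analogue: per-superfamily shared and specific counts
  sharedTab <- countShared(callSet@shared)
  sp <- specificCalls(callSet)
  fams <- sort(unique(c(sharedTab$superfamily[sharedTab$superfamily != "total"],
                        sp$superfamily)))
  t1 <- data.frame(
    superfamily = fams,
    shared = vapply(fams, function(f)
      sum(callSet@shared$superfamily == f), integer(1)),
    specific_A = vapply(fams, function(f)
      sum(sp$superfamily == f & sp$species == "A"), integer(1)),
    specific_B = vapply(fams, function(f)
      sum(sp$superfamily == f & sp$species == "B"), integer(1)))
  t1 <- rbind(t1, data.frame(superfamily = "total",
                             shared = nrow(callSet@shared),
                             specific_A = sum(sp$species == "A"),
                             specific_B = sum(sp$species == "B")))
  f <- file.path(dir, "table1_counts.tsv")
  write.table(t1, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  if (!is.null(features)) {
    f <- file.path(dir, "table2_features.tsv")
    fx <- features
    for (cn in c("divergence", "ltr_identity"))
      if (cn %in% names(fx)) fx[[cn]] <- ifelse(
        is.na(fx[[cn]]), NA, sprintf("%.4f", as.numeric(fx[[cn]])))
    write.table(fx, f, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
    files <- c(files, f)
  }

  js <- list(
    analyzed_bp = divsum$analyzed_bp,
    shared_count = divsum$shared_count,
    shared_density_per_mb = divsum$shared_density_per_mb,
    shared_density_rounded10 = divsum$shared_density_rounded10,
    species = divsum$species,
    specific_counts = as.list(setNames(divsum$specific_counts,
                                       divsum$species)),
    specific_kb = as.list(setNames(divsum$specific_kb, divsum$species)),
    specific_pct = as.list(setNames(divsum$specific_pct, divsum$species)),
    combined_pct_rounded = divsum$combined_pct_rounded,
    combined_pct_raw = divsum$combined_pct_raw,
    mean_length = divsum$mean_length,
    min_length = divsum$min_length,
    max_length = divsum$max_length)
  if (!is.null(extrapolation)) js$extrapolation <- extrapolation
  f <- file.path(dir, "summary.json")
  jsonlite::write_json(js, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, f)

  f <- file.path(dir, "summary.md")
  con <- file(f, "w")
  lines <- c(
    "# TE insertion polymorphism summary",
    "",
    sprintf("- analyzed span: %.3f Mb", divsum$analyzed_bp / 1e6),
    sprintf("- shared insertions: %d (~%d per Mb)", divsum$shared_count,
            as.integer(divsum$shared_density_rounded10)),
    sprintf("- specific insertions: %s",
            paste(sprintf("%s: %d (%.1f kb, %.2f%%)", divsum$species,
                          divsum$specific_counts, divsum$specific_kb,
                          divsum$specific_pct), collapse = "; ")),
    sprintf("- combined contribution to divergence: %.2f%% (raw %.2f%%)",
            divsum$combined_pct_rounded, divsum$combined_pct_raw),
    sprintf("- specific insertion length: mean %d nt, range %d-%d nt",
            divsum$mean_length, divsum$min_length, divsum$max_length))
  if (!is.null(extrapolation)) {
    lines <- c(lines, sprintf(
      "- genome-wide extrapolation: %.0f specific insertions per species (band %.0f-%.0f)",
      extrapolation$per_species, extrapolation$band[1],
      extrapolation$band[2]))
  }
  writeLines(lines, con)
  close(con)
  files <- c(files, f)
  invisible(files)
}
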