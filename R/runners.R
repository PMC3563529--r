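# Stage runners behind the command-line wrapper (inst/scripts/
# barcode_pci.R).  Each logs record/pair/species counts at its boundary
# and writes plain TSV so every number in a report is auditable.

.logCounts <- function(...) message("[barcodeGap] ", ...)

#' Run the simulation stage
#'
#' Generates a dataset with \code{\link{simulateDataset}} and writes
#' \code{sequences.fasta}, \code{metadata.tsv} and \code{truth.tsv} into
#' \code{outDir}.  Identical parameters and seed give byte-identical
#' files.
#'
#' @param paramsFile Optional YAML file of \code{\link{simulationParams}}
#'   arguments (keys as argument names).
#' @param outDir Output directory (created if needed).
#' @param ... Arguments passed to \code{\link{simulationParams}},
#'   overriding the file.
#' @return Invisibly, the written file paths.
#' @export
runSimulate <- function(outDir, paramsFile = NULL, ...) {
    args <- list(...)
    if (!is.null(paramsFile)) {
        if (!file.exists(paramsFile))
            bgStop("no such params file: ", paramsFile)
        fromFile <- yaml::read_yaml(paramsFile)
        args <- utils::modifyList(fromFile, args)
    }
    params <- do.call(simulationParams, args)
    sim <- simulateDataset(params)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    fasta <- file.path(outDir, "sequences.fasta")
    meta <- file.path(outDir, "metadata.tsv")
    truth <- file.path(outDir, "truth.tsv")
    writeDataset(sim$dataset, fasta, meta)
    utils::write.table(sim$truth, truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    .logCounts("simulated ", length(sim$dataset), " records, ",
               length(unique(speciesLabels(sim$dataset))), " species")
    invisible(c(fasta = fasta, metadata = meta, truth = truth))
}

#' Run the distance stage
#'
#' Loads a dataset, computes one distance matrix per (alignment type,
#' scheme, distance kind) combination of the configuration and writes
#' each as a square TSV named
#' \code{distances_<type>_<scheme>_<kind>.tsv}.
#'
#' @param fasta,metadata Dataset input paths (see
#'   \code{\link{readBarcodeDataset}}).
#' @param config An \code{\link{analysisConfig}}.
#' @param outDir Output directory.
#' @return Invisibly, the written file paths.
#' @export
runDistances <- function(fasta, metadata, config, outDir) {
    config <- .validateConfig(config)
    dataset <- readBarcodeDataset(fasta, metadata)
    .logCounts("read ", length(dataset), " records (",
               length(unique(speciesLabels(dataset))), " species)")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    paths <- character(0)
    for (type in config$alignmentTypes) {
        for (scheme in config$schemes) {
            stats <- .pairStats(dataset, type, scheme, config$msa)
            .logCounts(type, "/", schemeName(scheme), ": aligned ",
                       nrow(stats), " pairs")
            for (kind in config$distanceKinds) {
                dm <- .distanceMatrixFromStats(stats, dataset, type, kind,
                                               scheme, config$msa,
                                               config$normalizeScores)
                f <- file.path(outDir, sprintf("distances_%s_%s_%s.tsv",
                                               type, schemeName(scheme),
                                               kind))
                writeDistanceMatrix(dm, f)
                paths <- c(paths, f)
            }
        }
    }
    invisible(paths)
}

#' Run the PCI stage
#'
#' Computes the PCI grid with \code{\link{pciTable}} and writes
#' \code{pci_summary.tsv} (one row per combination),
#' \code{species_gaps.tsv} (per-species gap details for every
#' combination) and \code{pci_grid.json} (the same grid as JSON).
#'
#' @inheritParams runDistances
#' @return Invisibly, the grid summary data.frame.
#' @export
runPci <- function(fasta, metadata, config, outDir) {
    config <- .validateConfig(config)
    dataset <- readBarcodeDataset(fasta, metadata)
    eligible <- sum(speciesCounts(dataset) >= 2L)
    .logCounts("read ", length(dataset), " records; ", eligible,
               " species eligible for PCI")
    if (eligible == 0L) bgStop("no species with at least two samples")
    res <- pciTable(dataset, config, details = TRUE)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(res$summary, file.path(outDir, "pci_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$species, file.path(outDir, "species_gaps.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(res$summary, file.path(outDir, "pci_grid.json"),
                         dataframe = "rows", digits = NA)
    invisible(res$summary)
}

#' Run the comparison stage
#'
#' From a per-species gap table (\code{species_gaps.tsv} of one grid
#' combination, or any table with \code{species} and \code{has_gap}
#' columns) and per-species expert flags, builds the expert-vs-barcode
#' 2x2 table and reports the Fisher exact p-value; optionally a
#' user-supplied Bonferroni factor is applied (capped at 1).
#'
#' @param gapsFile TSV with columns \code{species} and \code{has_gap}.
#' @param flagsFile TSV with columns \code{species} and
#'   \code{expert_agreement} (\code{agree}/\code{disagree}).
#' @param outFile Output TSV report path.
#' @param bonferroniFactor Multiplicative p-value correction (>= 1).
#' @return Invisibly, a list with the table and the p-values.
#' @export
runCompare <- function(gapsFile, flagsFile, outFile,
                       bonferroniFactor = 1) {
    for (f in c(gapsFile, flagsFile))
        if (!file.exists(f)) bgStop("no such file: ", f)
    gaps <- utils::read.delim(gapsFile, stringsAsFactors = FALSE)
    flags <- utils::read.delim(flagsFile, stringsAsFactors = FALSE)
    if (!all(c("species", "expert_agreement") %in% colnames(flags)))
        bgStop("flags file needs columns species and expert_agreement")
    if (!is.logical(gaps$has_gap))
        gaps$has_gap <- tolower(as.character(gaps$has_gap)) %in%
            c("true", "1", "yes")
    tab <- expertVsItsTable(gaps, stats::setNames(flags$expert_agreement,
                                                  flags$species))
    p <- fisherExact2x2(tab)
    pAdj <- min(1, p * bonferroniFactor)
    report <- data.frame(
        expert = rep(rownames(tab), each = 2),
        its = rep(colnames(tab), times = 2),
        count = as.integer(t(tab)))
    report$p_value <- p
    report$p_adjusted <- pAdj
    report$bonferroni_factor <- bonferroniFactor
    utils::write.table(report, outFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    .logCounts("Fisher exact p = ", format(p, digits = 4),
               " (adjusted ", format(pAdj, digits = 4), ")")
    invisible(list(table = tab, p_value = p, p_adjusted = pAdj))
}
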