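#' Analysis configuration for the PCI grid
#'
#' Declares which alignment types, scoring schemes and distance kinds the
#' grid spans, the confidence level of the Wilson intervals, and (when the
#' MSA route is included) the externally computed alignment.
#'
#' @param alignmentTypes Subset of \code{"global"}, \code{"semiglobal"},
#'   \code{"local"}, \code{"msa_implied"}.
#' @param schemes List of \linkS4class{ScoringScheme} objects (default:
#'   the shipped NCBI and UCSC schemes).
#' @param distanceKinds Distance kinds; \code{"alignment_score"} and any
#'   registered evolutionary model.
#' @param confidence Wilson interval confidence level.
#' @param msa An \linkS4class{MsaBlock}; required when
#'   \code{"msa_implied"} is among the types.
#' @param normalizeScores Length-normalize alignment-score distances?
#' @return A validated configuration list of class \code{"AnalysisConfig"}.
#' @seealso \code{\link{pciTable}}
#' @export
analysisConfig <- function(alignmentTypes = c("global", "semiglobal",
                                              "local"),
                           schemes = list(ncbiScheme(), ucscScheme()),
                           distanceKinds = c("alignment_score", "p"),
                           confidence = 0.95,
                           msa = NULL,
                           normalizeScores = FALSE) {
    structure(list(alignmentTypes = alignmentTypes, schemes = schemes,
                   distanceKinds = distanceKinds, confidence = confidence,
                   msa = msa, normalizeScores = isTRUE(normalizeScores)),
              class = "AnalysisConfig")
}

.validateConfig <- function(config) {
    if (!inherits(config, "AnalysisConfig"))
        bgStop("config must come from analysisConfig()")
    if (!length(config$alignmentTypes) || !length(config$distanceKinds) ||
        !length(config$schemes))
        bgStop("alignmentTypes, schemes and distanceKinds must be non-empty")
    bad <- setdiff(config$alignmentTypes, .ALIGNMENT_TYPES)
    if (length(bad))
        bgStop("unknown alignment type(s): ", paste(bad, collapse = ", "))
    for (s in config$schemes)
        if (!is(s, "ScoringScheme"))
            bgStop("schemes must be ScoringScheme objects")
    for (k in setdiff(config$distanceKinds, "alignment_score"))
        .getModel(k)
    if ("msa_implied" %in% config$alignmentTypes &&
        !is(config$msa, "MsaBlock"))
        bgStop("msa_implied requires an MsaBlock (msa = ...)")
    if (config$confidence <= 0 || config$confidence >= 1)
        bgStop("confidence must lie in (0, 1)")
    config
}

#' Read an analysis configuration from a YAML file
#'
#' Recognized keys: \code{alignment_types}, \code{distance_kinds},
#' \code{confidence}, \code{normalize_scores}, \code{msa} (path to an
#' aligned FASTA), \code{schemes} (list of paths to scheme YAML files, or
#' the names \code{"ncbi"} / \code{"ucsc"} for the shipped defaults).
#'
#' @param path Path to a YAML file.
#' @return An \code{\link{analysisConfig}}.
#' @export
readAnalysisConfig <- function(path) {
    if (!file.exists(path)) bgStop("no such config file: ", path)
    y <- yaml::read_yaml(path)
    schemes <- lapply(y$schemes %||% list("ncbi", "ucsc"), function(s) {
        if (identical(s, "ncbi")) return(ncbiScheme())
        if (identical(s, "ucsc")) return(ucscScheme())
        readScoringScheme(s)
    })
    analysisConfig(
        alignmentTypes = y$alignment_types %||% c("global", "semiglobal",
                                                  "local"),
        schemes = schemes,
        distanceKinds = y$distance_kinds %||% c("alignment_score", "p"),
        confidence = y$confidence %||% 0.95,
        msa = if (!is.null(y$msa)) readAlignedFasta(y$msa) else NULL,
        normalizeScores = isTRUE(y$normalize_scores))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
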