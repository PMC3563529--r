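#' @import methods
#' @importFrom Biostrings DNAStringSet readBStringSet writeXStringSet width
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
NULL

.SOURCE_LEVELS <- c("genbank", "local")
.EXPERT_LEVELS <- c("agree", "disagree", "unknown")
.ALIGNMENT_TYPES <- c("global", "semiglobal", "local", "msa_implied")

#' Specimen dataset for barcode analysis
#'
#' A \code{BarcodeDataset} bundles unaligned DNA sequences with per-sample
#' metadata: the species label (an exact string, never parsed), the genus,
#' the data source (\code{"genbank"} or \code{"local"}) and a per-species
#' expert-agreement flag (\code{"agree"}, \code{"disagree"} or
#' \code{"unknown"}).  Records keep the order of the FASTA file they were
#' loaded from.
#'
#' @slot sequences A \linkS4class{DNAStringSet}, named by sample id.
#' @slot sampleData A \link[S4Vectors]{DataFrame} with columns
#'   \code{sample_id}, \code{species}, \code{genus}, \code{source} and
#'   \code{expert_agreement}, one row per sequence, in sequence order.
#'
#' @seealso \code{\link{readBarcodeDataset}}, \code{\link{partitionDataset}},
#'   \code{\link{distanceMatrix}}
#' @export
setClass("BarcodeDataset",
    representation(sequences = "DNAStringSet", sampleData = "DataFrame"))

setValidity("BarcodeDataset", function(object) {
    seqs <- object@sequences
    md <- object@sampleData
    msgs <- character()
    need <- c("sample_id", "species", "genus", "source", "expert_agreement")
    if (!all(need %in% colnames(md)))
        return(paste("sampleData must have columns:",
                     paste(need, collapse = ", ")))
    if (length(seqs) != nrow(md))
        msgs <- c(msgs, "one metadata row per sequence required")
    if (length(seqs)) {
        if (is.null(names(seqs)) || !identical(names(seqs), md$sample_id))
            msgs <- c(msgs, "sequence names must equal sampleData$sample_id")
        if (anyDuplicated(md$sample_id))
            msgs <- c(msgs, paste("duplicate sample ids:",
                paste(unique(md$sample_id[duplicated(md$sample_id)]),
                      collapse = ", ")))
        if (any(Biostrings::width(seqs) == 0))
            msgs <- c(msgs, paste("empty sequence for:",
                paste(md$sample_id[Biostrings::width(seqs) == 0],
                      collapse = ", ")))
        if (!all(md$source %in% .SOURCE_LEVELS))
            msgs <- c(msgs, paste0("source must be one of {",
                paste(.SOURCE_LEVELS, collapse = ", "), "}"))
        if (!all(md$expert_agreement %in% .EXPERT_LEVELS))
            msgs <- c(msgs, paste0("expert_agreement must be one of {",
                paste(.EXPERT_LEVELS, collapse = ", "), "}"))
        # expert agreement is a species-level property
        bad <- vapply(split(md$expert_agreement, md$species),
                      function(x) length(unique(x)) > 1L, logical(1))
        if (any(bad))
            msgs <- c(msgs, paste("inconsistent expert_agreement within species:",
                paste(names(bad)[bad], collapse = ", ")))
    }
    if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Affine-gap alignment scoring scheme
#'
#' Substitution scores plus affine gap parameters.  A gap of length
#' \code{k} costs \code{gapOpen + k * gapExtend} score units, subtracted
#' from the alignment score (so the first gap column pays
#' \code{gapOpen + gapExtend}).
#'
#' @slot name Scheme name, e.g. \code{"ncbi"} or \code{"ucsc"}.
#' @slot substitution Symmetric numeric matrix of substitution scores with
#'   residue dimnames; at least \code{A,C,G,T}.
#' @slot gapOpen,gapExtend Non-negative gap costs in score units.
#'
#' @seealso \code{\link{ncbiScheme}}, \code{\link{ucscScheme}},
#'   \code{\link{readScoringScheme}}
#' @export
setClass("ScoringScheme",
    representation(name = "character", substitution = "matrix",
                   gapOpen = "numeric", gapExtend = "numeric"))

setValidity("ScoringScheme", function(object) {
    s <- object@substitution
    if (is.null(rownames(s)) || is.null(colnames(s)))
        return("substitution matrix needs residue dimnames")
    if (!identical(rownames(s), colnames(s)))
        return("substitution matrix must have identical row and column names")
    if (!all(c("A", "C", "G", "T") %in% rownames(s)))
        return("substitution matrix must cover A, C, G, T")
    if (!isTRUE(all.equal(s, t(s))))
        return("substitution matrix must be symmetric")
    if (length(object@gapOpen) != 1L || object@gapOpen < 0)
        return("gapOpen must be a single non-negative number")
    if (length(object@gapExtend) != 1L || object@gapExtend < 0)
        return("gapExtend must be a single non-negative number")
    TRUE
})

#' Pairwise alignment of two DNA sequences
#'
#' Two gapped strings of equal length plus the optimal score under a
#' \linkS4class{ScoringScheme}.  Alignments extracted from a multiple
#' sequence alignment (\code{type "msa_implied"}) carry no score
#' (\code{NA}); they feed evolutionary distances only, unless re-scored
#' explicitly.
#'
#' @slot pattern,subject Gapped strings over the DNA alphabet plus
#'   \code{"-"}; equal length, no column gapped in both.
#' @slot score Alignment score (\code{NA} for \code{msa_implied}).
#' @slot type One of \code{"global"}, \code{"semiglobal"}, \code{"local"},
#'   \code{"msa_implied"}.
#'
#' @seealso \code{\link{globalAlign}}, \code{\link{impliedPairwise}},
#'   \code{\link{pDistance}}
#' @export
setClass("BarcodeAlignment",
    representation(pattern = "character", subject = "character",
                   score = "numeric", type = "character"))

setValidity("BarcodeAlignment", function(object) {
    if (length(object@pattern) != 1L || length(object@subject) != 1L)
        return("pattern and subject must be single strings")
    if (nchar(object@pattern) != nchar(object@subject))
        return("gapped strings must have equal length")
    if (!object@type %in% .ALIGNMENT_TYPES)
        return(paste("type must be one of:",
                     paste(.ALIGNMENT_TYPES, collapse = ", ")))
    TRUE
})

#' Multiple sequence alignment block
#'
#' Equal-length gapped rows from an externally computed multiple sequence
#' alignment (the package consumes MSAs, it does not build them).
#'
#' @slot rows Named character vector of equal-length gapped strings.
#'
#' @seealso \code{\link{readAlignedFasta}}, \code{\link{impliedPairwise}},
#'   \code{\link{gapFraction}}
#' @export
setClass("MsaBlock", representation(rows = "character"))

setValidity("MsaBlock", function(object) {
    r <- object@rows
    if (!length(r)) return("MSA block has no rows")
    if (is.null(names(r)) || anyDuplicated(names(r)))
        return("rows must carry unique names")
    w <- nchar(r)
    if (length(unique(w)) != 1L)
        return(paste0("ragged alignment: row lengths ",
                      paste(paste0(names(r), "=", w), collapse = ", ")))
    TRUE
})

#' All-pairs sequence distance matrix
#'
#' Symmetric matrix of pairwise sequence distances over one dataset, with
#' sample labels, a species label per sample, and the distance kind.
#' \code{Inf} marks pairs where a model transform is undefined
#' (saturation); \code{Inf} compares as larger than every finite distance
#' in the barcode-gap logic.
#'
#' @slot values Symmetric numeric matrix with sample-id dimnames.
#' @slot species Character vector of species labels, named by sample id.
#' @slot kind Distance kind, e.g. \code{"p"}, \code{"jc69"}, \code{"k2p"},
#'   \code{"f81"}, \code{"tn93"} or \code{"alignment_score"}.
#'
#' @seealso \code{\link{distanceMatrix}}, \code{\link{speciesGaps}},
#'   \code{\link{pci}}
#' @export
setClass("DistanceMatrix",
    representation(values = "matrix", species = "character",
                   kind = "character"))

setValidity("DistanceMatrix", function(object) {
    v <- object@values
    if (nrow(v) != ncol(v)) return("values must be square")
    if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
        return("values must carry identical row and column labels")
    if (!identical(names(object@species), rownames(v)))
        return("species must be named by the matrix labels")
    fin <- v[is.finite(v)]
    if (length(fin) && any(fin < 0) && object@kind != "alignment_score")
        return("negative distances are not allowed for evolutionary kinds")
    if (any(v != t(v), na.rm = TRUE)) return("values must be symmetric")
    TRUE
})

#' PCI point estimate with Wilson score interval
#'
#' The barcode-gap probability of correct identification: the fraction of
#' species with at least two samples whose maximum intraspecific distance
#' falls strictly below their minimum interspecific distance, together
#' with its Wilson score confidence interval.
#'
#' @slot k Number of species displaying a barcode gap.
#' @slot n Number of species with at least two samples.
#' @slot estimate \code{k/n}.
#' @slot confLow,confHigh Wilson interval bounds.
#' @slot halfWidth \code{(confHigh - confLow) / 2}.
#' @slot confidence Confidence level, default 0.95.
#'
#' @seealso \code{\link{pci}}, \code{\link{wilsonInterval}}
#' @export
setClass("PciSummary",
    representation(k = "integer", n = "integer", estimate = "numeric",
                   confLow = "numeric", confHigh = "numeric",
                   halfWidth = "numeric", confidence = "numeric"))

setValidity("PciSummary", function(object) {
    if (object@n < 1L) return("n must be at least 1")
    if (object@k < 0L || object@k > object@n) return("k must lie in [0, n]")
    if (object@confLow < 0 || object@confHigh > 1 ||
        object@confLow > object@confHigh)
        return("confidence bounds must satisfy 0 <= low <= high <= 1")
    TRUE
})
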