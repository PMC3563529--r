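#' @rdname BarcodeDataset-class
#' @param x,object A \linkS4class{BarcodeDataset} (or other object for the
#'   shared generics).
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname BarcodeDataset-class
#' @export
setGeneric("speciesLabels", function(x) standardGeneric("speciesLabels"))

#' @rdname BarcodeDataset-class
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname BarcodeDataset-class
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname ScoringScheme-class
#' @param x A \linkS4class{ScoringScheme}.
#' @export
setGeneric("schemeName", function(x) standardGeneric("schemeName"))

#' @rdname ScoringScheme-class
#' @export
setGeneric("gapOpen", function(x) standardGeneric("gapOpen"))

#' @rdname ScoringScheme-class
#' @export
setGeneric("gapExtend", function(x) standardGeneric("gapExtend"))

#' @rdname ScoringScheme-class
#' @export
setGeneric("substitutionScores",
    function(x) standardGeneric("substitutionScores"))

#' @rdname BarcodeAlignment-class
#' @param x A \linkS4class{BarcodeAlignment}.
#' @export
setGeneric("alignedPattern", function(x) standardGeneric("alignedPattern"))

#' @rdname BarcodeAlignment-class
#' @export
setGeneric("alignedSubject", function(x) standardGeneric("alignedSubject"))

#' @rdname BarcodeAlignment-class
#' @export
setGeneric("alignmentScore", function(x) standardGeneric("alignmentScore"))

#' @rdname BarcodeAlignment-class
#' @export
setGeneric("alignmentType", function(x) standardGeneric("alignmentType"))

#' @rdname MsaBlock-class
#' @param x An \linkS4class{MsaBlock}.
#' @export
setGeneric("msaRows", function(x) standardGeneric("msaRows"))

#' Gap fraction of a multiple sequence alignment
#'
#' The number of gap characters divided by the total number of characters
#' (\code{rows * columns}) of the alignment block.  MSAs of length-variable
#' markers such as fungal ITS are typically gap-dominated, which is why the
#' implied-pairwise route discards so many columns per pair.
#'
#' @param x An \linkS4class{MsaBlock}.
#' @return A number in \code{[0, 1]}.
#' @examples
#' m <- MsaBlock(c(a = "A---", b = "ACGT"))
#' gapFraction(m)  # 3/8
#' @export
setGeneric("gapFraction", function(x) standardGeneric("gapFraction"))

#' @rdname DistanceMatrix-class
#' @param x A \linkS4class{DistanceMatrix}.
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @rdname DistanceMatrix-class
#' @export
setGeneric("distanceKind", function(x) standardGeneric("distanceKind"))

#' Barcode-gap PCI of a distance matrix
#'
#' @param x A \linkS4class{DistanceMatrix}, or a per-species gap table as
#'   returned by \code{\link{speciesGaps}}.
#' @param confidence Confidence level for the Wilson score interval.
#' @return A \linkS4class{PciSummary}.
#' @seealso \code{\link{speciesGaps}}, \code{\link{wilsonInterval}}
#' @export
setGeneric("pci", function(x, confidence = 0.95) standardGeneric("pci"))
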