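.alignOne <- function(a, b, scheme, type) {
    .assertScalarString(a, "a")
    .assertScalarString(b, "b")
    stopifnot(is(scheme, "ScoringScheme"))
    a <- .normalizeDna(a)
    b <- .normalizeDna(b)
    r <- cpp_align_pair(a, b, .fullScoreMatrix(scheme), scheme@gapOpen,
                        scheme@gapExtend, type)
    new("BarcodeAlignment", pattern = r$pattern, subject = r$subject,
        score = r$score, type = type)
}

#' Optimal pairwise alignment under affine gap scoring
#'
#' Three alignment variants over the same affine-gap scoring model (gap of
#' length \code{k} costs \code{gapOpen + k * gapExtend}):
#' \describe{
#'   \item{\code{globalAlign}}{Needleman-Wunsch: the whole length of both
#'     sequences is aligned and end gaps are penalized.}
#'   \item{\code{semiglobalAlign}}{the whole of one sequence is aligned
#'     against a subsequence of the other, with the end gaps flanking the
#'     contained sequence contributing zero; both orientations are
#'     evaluated and the better one returned.}
#'   \item{\code{localAlign}}{Smith-Waterman: the best-scoring pair of
#'     subsequences; the empty alignment is admissible, so the score is
#'     never negative.}
#' }
#' For every pair and scheme the scores obey
#' \code{local >= semiglobal >= global}.  Among co-optimal tracebacks the
#' diagonal move is preferred over a gap in the subject over a gap in the
#' pattern, so alignments are reproducible; the score itself is tie-free.
#'
#' @param a,b DNA strings (non-empty; IUPAC ambiguity codes allowed and
#'   scored as mismatches).
#' @param scheme A \linkS4class{ScoringScheme}.
#' @return A \linkS4class{BarcodeAlignment}.
#' @examples
#' aln <- globalAlign("ACGT", "ACGA", ncbiScheme())
#' alignmentScore(aln)      # 0: three matches, one mismatch
#' localAlign("ACGT", "ACGA", ncbiScheme())  # score 3, "ACG" / "ACG"
#' @export
globalAlign <- function(a, b, scheme) .alignOne(a, b, scheme, "global")

#' @rdname globalAlign
#' @export
semiglobalAlign <- function(a, b, scheme) .alignOne(a, b, scheme, "semiglobal")

#' @rdname globalAlign
#' @export
localAlign <- function(a, b, scheme) .alignOne(a, b, scheme, "local")

#' Brute-force reference alignment score
#'
#' Exhaustively enumerates every admissible alignment (all monotone paths;
#' for semi-global and local, additionally all substring placements) and
#' returns the best affine-gap score.  Exponential cost, restricted to
#' sequences of at most 12 bases; this is the independent reference the
#' dynamic-programming aligner is validated against, not a tool for data.
#'
#' @inheritParams globalAlign
#' @param type \code{"global"}, \code{"semiglobal"} or \code{"local"}.
#' @return The optimal score (a single number).
#' @export
bruteForceAlignScore <- function(a, b, scheme,
                                 type = c("global", "semiglobal", "local")) {
    type <- match.arg(type)
    stopifnot(is(scheme, "ScoringScheme"))
    cpp_enum_align_score(.normalizeDna(a), .normalizeDna(b),
                         .fullScoreMatrix(scheme), scheme@gapOpen,
                         scheme@gapExtend, type)
}

#' Re-score a fixed alignment under a scheme
#'
#' Applies affine-gap scoring to an existing alignment without
#' re-optimizing: matches and mismatches score by the substitution table,
#' every gap run (end gaps included) costs \code{gapOpen + k * gapExtend}.
#' Mainly useful to attach an alignment-distance score to the implied
#' pairwise alignments of an MSA.
#'
#' @param aln A \linkS4class{BarcodeAlignment}.
#' @param scheme A \linkS4class{ScoringScheme}.
#' @return The score of the fixed alignment.
#' @export
scoreAlignment <- function(aln, scheme) {
    stopifnot(is(aln, "BarcodeAlignment"), is(scheme, "ScoringScheme"))
    cpp_score_fixed(aln@pattern, aln@subject, .fullScoreMatrix(scheme),
                    scheme@gapOpen, scheme@gapExtend)
}

#' @rdname BarcodeAlignment-class
#' @export
setMethod("alignedPattern", "BarcodeAlignment", function(x) x@pattern)

#' @rdname BarcodeAlignment-class
#' @export
setMethod("alignedSubject", "BarcodeAlignment", function(x) x@subject)

#' @rdname BarcodeAlignment-class
#' @export
setMethod("alignmentScore", "BarcodeAlignment", function(x) x@score)

#' @rdname BarcodeAlignment-class
#' @export
setMethod("alignmentType", "BarcodeAlignment", function(x) x@type)

setMethod("show", "BarcodeAlignment", function(object) {
    cat("BarcodeAlignment (", object@type, "), score ",
        format(object@score), ", ", nchar(object@pattern), " columns\n",
        sep = "")
    trim <- function(s) if (nchar(s) > 60)
        paste0(substr(s, 1, 57), "...") else s
    cat(" ", trim(object@pattern), "\n ", trim(object@subject), "\n")
})
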