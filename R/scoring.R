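.IUPAC_AMBIG <- c("M", "R", "W", "S", "Y", "K", "V", "H", "D", "B", "N")
.DNA_ALPHABET <- c("A", "C", "G", "T", .IUPAC_AMBIG)

#' Construct an alignment scoring scheme
#'
#' Either give a \code{match}/\code{mismatch} score pair or a full
#' substitution matrix over (at least) \code{A,C,G,T}.  Gap costs follow
#' the legacy NCBI BLAST convention: a gap of length \code{k} costs
#' \code{gapOpen + k * gapExtend}.
#'
#' IUPAC ambiguity codes are scored conservatively: any residue pair
#' involving an ambiguity code receives the mismatch score (for a
#' match/mismatch scheme) or the matrix minimum (for a matrix scheme).
#'
#' @param name Scheme name.
#' @param gapOpen,gapExtend Non-negative gap costs in score units.
#' @param match,mismatch Scores for identical / differing bases
#'   (alternative to \code{substitution}).
#' @param substitution 4x4 (or larger) symmetric score matrix with residue
#'   dimnames.
#' @return A \linkS4class{ScoringScheme}.
#' @examples
#' scoringScheme("toy", match = 1, mismatch = -1, gapOpen = 2, gapExtend = 1)
#' @export
scoringScheme <- function(name, gapOpen, gapExtend, match = NULL,
                          mismatch = NULL, substitution = NULL) {
    .assertScalarString(name, "name")
    if (is.null(substitution)) {
        if (is.null(match) || is.null(mismatch))
            bgStop("give either match/mismatch or a substitution matrix")
        bases <- c("A", "C", "G", "T")
        substitution <- matrix(mismatch, 4, 4, dimnames = list(bases, bases))
        diag(substitution) <- match
    }
    new("ScoringScheme", name = name, substitution = substitution,
        gapOpen = as.numeric(gapOpen), gapExtend = as.numeric(gapExtend))
}

#' Shipped default scoring schemes
#'
#' \code{ncbiScheme()} is the legacy NCBI blastn default for DNA:
#' match +1, mismatch -3, gap open 5, gap extend 2.
#' \code{ucscScheme()} is the UCSC BLASTZ default: the HOXD70 substitution
#' matrix with gap open 400 and gap extend 30.  These are the canonical
#' defaults of the two tools; analyses that need other parameters can load
#' a scheme from a config file with \code{\link{readScoringScheme}}.
#'
#' @return A \linkS4class{ScoringScheme}.
#' @examples
#' gapOpen(ncbiScheme())
#' substitutionScores(ucscScheme())["A", "G"]
#' @export
ncbiScheme <- function() {
    scoringScheme("ncbi", match = 1, mismatch = -3, gapOpen = 5,
                  gapExtend = 2)
}

#' @rdname ncbiScheme
#' @export
ucscScheme <- function() {
    bases <- c("A", "C", "G", "T")
    hoxd70 <- matrix(c(
          91, -114,  -31, -123,
        -114,  100, -125,  -31,
         -31, -125,  100, -114,
        -123,  -31, -114,   91), 4, 4, byrow = TRUE,
        dimnames = list(bases, bases))
    scoringScheme("ucsc", substitution = hoxd70, gapOpen = 400,
                  gapExtend = 30)
}

#' Read a scoring scheme from a YAML config file
#'
#' The file holds \code{name}, \code{gap_open}, \code{gap_extend} and
#' either \code{match} + \code{mismatch} or a 16-entry \code{substitution}
#' block (nested mapping base -> base -> score).
#'
#' @param path Path to a YAML file.
#' @return A \linkS4class{ScoringScheme}.
#' @export
readScoringScheme <- function(path) {
    if (!file.exists(path)) bgStop("no such scheme file: ", path)
    y <- yaml::read_yaml(path)
    for (f in c("name", "gap_open", "gap_extend"))
        if (is.null(y[[f]])) bgStop("scheme file misses field '", f, "'")
    if (!is.null(y$substitution)) {
        bases <- sort(names(y$substitution))
        sub <- matrix(NA_real_, length(bases), length(bases),
                      dimnames = list(bases, bases))
        for (r in bases) for (cc in names(y$substitution[[r]]))
            sub[r, cc] <- as.numeric(y$substitution[[r]][[cc]])
        if (anyNA(sub)) bgStop("incomplete substitution table in ", path)
        scoringScheme(y$name, substitution = sub, gapOpen = y$gap_open,
                      gapExtend = y$gap_extend)
    } else {
        if (is.null(y$match) || is.null(y$mismatch))
            bgStop("scheme file needs match/mismatch or a substitution table")
        scoringScheme(y$name, match = y$match, mismatch = y$mismatch,
                      gapOpen = y$gap_open, gapExtend = y$gap_extend)
    }
}

# Full IUPAC-extended score matrix handed to the C++ aligner.  Ambiguity
# codes score as the worst substitution in the scheme against everything,
# themselves included.
.fullScoreMatrix <- function(scheme) {
    sub <- scheme@substitution
    have <- rownames(sub)
    alpha <- union(have, .DNA_ALPHABET)
    worst <- min(sub)
    full <- matrix(worst, length(alpha), length(alpha),
                   dimnames = list(alpha, alpha))
    full[have, have] <- sub
    full
}

#' @rdname ScoringScheme-class
#' @export
setMethod("schemeName", "ScoringScheme", function(x) x@name)

#' @rdname ScoringScheme-class
#' @export
setMethod("gapOpen", "ScoringScheme", function(x) x@gapOpen)

#' @rdname ScoringScheme-class
#' @export
setMethod("gapExtend", "ScoringScheme", function(x) x@gapExtend)

#' @rdname ScoringScheme-class
#' @export
setMethod("substitutionScores", "ScoringScheme", function(x) x@substitution)

setMethod("show", "ScoringScheme", function(object) {
    cat("ScoringScheme '", object@name, "': gap open ", object@gapOpen,
        ", gap extend ", object@gapExtend, "\n", sep = "")
    print(object@substitution)
})
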