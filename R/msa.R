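#' @rdname MsaBlock-class
#' @param rows Named character vector of equal-length gapped strings (or a
#'   named \code{DNAStringSet}/\code{BStringSet}).
#' @export
MsaBlock <- function(rows) {
    if (!is.character(rows)) {
        nm <- names(rows)
        rows <- as.character(rows)
        names(rows) <- nm
    }
    rows <- toupper(rows)
    obj <- try(new("MsaBlock", rows = rows), silent = TRUE)
    if (inherits(obj, "try-error"))
        bgStop(conditionMessage(attr(obj, "condition")))
    obj
}

#' Read a multiple sequence alignment from aligned FASTA
#'
#' Rows must all have the same (gapped) length; a ragged alignment is a
#' hard error reporting the row ids and lengths.  The MSA is produced by
#' an external aligner; this package only consumes it.
#'
#' @param path Path to an aligned FASTA file.
#' @return An \linkS4class{MsaBlock}.
#' @export
readAlignedFasta <- function(path) {
    if (!file.exists(path)) bgStop("no such aligned FASTA file: ", path)
    raw <- Biostrings::readBStringSet(path)
    if (!length(raw)) bgStop("aligned FASTA file has no records: ", path)
    rows <- .normalizeDna(as.character(raw))
    names(rows) <- sub("\\s.*$", "", names(raw))
    MsaBlock(rows)
}

#' @rdname MsaBlock-class
#' @export
setMethod("msaRows", "MsaBlock", function(x) x@rows)

#' @rdname MsaBlock-class
#' @param x An \linkS4class{MsaBlock}.
#' @export
setMethod("length", "MsaBlock", function(x) length(x@rows))

#' @rdname MsaBlock-class
#' @export
setMethod("dim", "MsaBlock",
    function(x) c(length(x@rows), nchar(x@rows[[1]])))

setMethod("show", "MsaBlock", function(object) {
    d <- dim(object)
    cat("MsaBlock:", d[1], "rows x", d[2], "columns; gap fraction",
        round(gapFraction(object), 3), "\n")
})

#' @rdname gapFraction
#' @export
setMethod("gapFraction", "MsaBlock", function(x) {
    total <- sum(nchar(x@rows))
    gaps <- sum(nchar(gsub("[^-.]", "", x@rows)))
    gaps / total
})

#' Implied pairwise alignment of two MSA rows
#'
#' A multiple sequence alignment contains an implicit global pairwise
#' alignment for every pair of its rows: keep the two rows, delete the
#' columns where both are gapped.  The result carries no score
#' (\code{alignmentScore} is \code{NA}); use \code{\link{scoreAlignment}}
#' to attach one under a scheme if alignment distances are wanted on the
#' MSA route.
#'
#' @param msa An \linkS4class{MsaBlock}.
#' @param i,j Distinct row indices or row names.
#' @return A \linkS4class{BarcodeAlignment} with type \code{"msa_implied"}.
#' @examples
#' m <- MsaBlock(c(x = "A-CG", y = "AT-G"))
#' impliedPairwise(m, "x", "y")
#' @export
impliedPairwise <- function(msa, i, j) {
    stopifnot(is(msa, "MsaBlock"))
    idx <- function(k) {
        if (is.character(k)) k <- match(k, names(msa@rows))
        if (is.na(k) || k < 1 || k > length(msa@rows))
            bgStop("no such MSA row")
        as.integer(k)
    }
    i <- idx(i); j <- idx(j)
    if (i == j) bgStop("i and j must name distinct rows")
    a <- strsplit(msa@rows[[i]], "", fixed = TRUE)[[1]]
    b <- strsplit(msa@rows[[j]], "", fixed = TRUE)[[1]]
    keep <- !(a %in% c("-", ".") & b %in% c("-", "."))
    if (!any(keep))
        bgStop("rows ", names(msa@rows)[i], " and ", names(msa@rows)[j],
               " share no non-gap columns")
    new("BarcodeAlignment",
        pattern = paste(a[keep], collapse = ""),
        subject = paste(b[keep], collapse = ""),
        score = NA_real_, type = "msa_implied")
}

#' Map dataset records onto MSA rows
#'
#' MSAs are often computed on deduplicated sequences; each record is
#' matched to the row whose degapped sequence equals the record's sequence
#' exactly, so duplicate samples share a row.
#'
#' @param msa An \linkS4class{MsaBlock}.
#' @param dataset A \linkS4class{BarcodeDataset}.
#' @return Integer vector: for each record, its MSA row index.
#' @export
msaRowMap <- function(msa, dataset) {
    stopifnot(is(msa, "MsaBlock"), is(dataset, "BarcodeDataset"))
    degapped <- gsub("[-.]", "", msa@rows)
    hit <- match(as.character(dataset@sequences), degapped)
    if (anyNA(hit))
        bgStop("record(s) with no exact-match MSA row: ",
               paste(sampleIds(dataset)[is.na(hit)], collapse = ", "))
    stats::setNames(hit, sampleIds(dataset))
}
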