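#' Cross-classify expert agreement against the ITS barcode gap
#'
#' Builds the 2x2 species-count table comparing the likelihood of expert
#' morphological misidentification (rows: experts agree / disagree) with
#' misidentification by the barcode marker (columns: barcode gap present /
#' absent).  The expert assessment is a subjective species-level judgment
#' supplied as input; it is never computed.
#'
#' @param gapResults A per-species gap table as returned by
#'   \code{\link{speciesGaps}}.
#' @param expertFlags Named character vector mapping every species in
#'   \code{gapResults} to \code{"agree"} or \code{"disagree"}.
#' @return An integer 2x2 matrix with dimnames; rows \code{agree},
#'   \code{disagree}, columns \code{gap}, \code{no_gap}.
#' @examples
#' gaps <- data.frame(species = c("a", "b", "c"),
#'     has_gap = c(TRUE, FALSE, TRUE))
#' expertVsItsTable(gaps, c(a = "agree", b = "agree", c = "disagree"))
#' @export
expertVsItsTable <- function(gapResults, expertFlags) {
    if (!is.data.frame(gapResults) ||
        !all(c("species", "has_gap") %in% colnames(gapResults)))
        bgStop("gapResults must have columns species and has_gap")
    if (!nrow(gapResults)) bgStop("empty gap table")
    flags <- expertFlags[gapResults$species]
    bad <- is.na(flags) | !flags %in% c("agree", "disagree")
    if (any(bad))
        bgStop("species without an agree/disagree flag: ",
               paste(gapResults$species[bad], collapse = ", "))
    tab <- matrix(0L, 2, 2,
                  dimnames = list(expert = c("agree", "disagree"),
                                  its = c("gap", "no_gap")))
    for (r in seq_len(nrow(gapResults))) {
        i <- if (flags[r] == "agree") 1L else 2L
        j <- if (gapResults$has_gap[r]) 1L else 2L
        tab[i, j] <- tab[i, j] + 1L
    }
    tab
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact p-value by summation of hypergeometric outcomes: with margins
#' fixed, every table whose probability does not exceed that of the
#' observed table (up to a 1e-7 relative tolerance) contributes
#' (\code{method = "minlike"}, the common convention).
#' \code{method = "doubling"} instead doubles the smaller one-sided tail,
#' capped at 1.  Tables with a zero margin have \code{p = 1}.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param method Two-sided convention; see Details.
#' @return The p-value in (0, 1].
#' @examples
#' fisherExact2x2(matrix(c(3, 1, 1, 3), 2))
#' @export
fisherExact2x2 <- function(table, method = c("minlike", "doubling")) {
    method <- match.arg(method)
    if (!is.matrix(table) || !identical(dim(table), c(2L, 2L)) ||
        any(table < 0) || any(table != round(table)))
        bgStop("table must be a 2x2 matrix of non-negative counts")
    if (sum(table) < 1) bgStop("table total must be at least 1")
    k <- table[1, 1]
    m <- sum(table[1, ])              # row-1 margin
    nn <- sum(table[2, ])             # row-2 margin
    cc <- sum(table[, 1])             # column-1 margin
    if (m == 0 || nn == 0 || cc == 0 || sum(table[, 2]) == 0)
        return(1)
    support <- max(0, cc - nn):min(cc, m)
    dens <- stats::dhyper(support, m, nn, cc)
    obs <- stats::dhyper(k, m, nn, cc)
    if (method == "minlike") {
        p <- sum(dens[dens <= obs * (1 + 1e-07)])
    } else {
        lower <- sum(dens[support <= k])
        upper <- sum(dens[support >= k])
        p <- min(1, 2 * min(lower, upper))
    }
    min(1, p)
}

#' Compare two PCI estimates
#'
#' Two-sided Fisher exact test on the success/failure table
#' \code{rbind(c(k1, n1 - k1), c(k2, n2 - k2))}: did the fraction of
#' species displaying a barcode gap differ between two conditions (e.g.
#' local vs. global alignment, or GenBank vs. locally collected data)?
#'
#' @param k1,n1 Gap count and eligible-species count under condition 1.
#' @param k2,n2 Same under condition 2.
#' @param method Passed to \code{\link{fisherExact2x2}}.
#' @return The two-sided p-value.
#' @examples
#' pciDifferenceTest(13, 35, 13, 35)  # identical proportions: p = 1
#' @export
pciDifferenceTest <- function(k1, n1, k2, n2,
                              method = c("minlike", "doubling")) {
    for (v in list(k1, n1, k2, n2))
        if (length(v) != 1L || !is.finite(v) || v < 0 || v != round(v))
            bgStop("counts must be single non-negative integers")
    if (k1 > n1 || k2 > n2) bgStop("k must not exceed n")
    fisherExact2x2(matrix(as.integer(c(k1, k2, n1 - k1, n2 - k2)), 2, 2),
                   method = match.arg(method))
}
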