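#' Wilson score interval for a binomial proportion
#'
#' Closed-form Wilson interval for \code{k} successes in \code{n} trials,
#' with \code{z} the exact normal quantile for the requested confidence
#' (about 1.959964 at 95\%, not 1.96 -- the difference can perturb
#' two-decimal rounding in edge cases).  This is the interval behind the
#' PCI error bars.
#'
#' @param k Number of successes, \code{0 <= k <= n}.
#' @param n Number of trials, \code{n >= 1}.
#' @param confidence Confidence level in (0, 1).
#' @return Named numeric vector \code{c(low, high, halfWidth)} with
#'   \code{halfWidth = (high - low) / 2}.
#' @examples
#' round(wilsonInterval(13, 35)[["halfWidth"]], 2)  # 0.15
#' @export
wilsonInterval <- function(k, n, confidence = 0.95) {
    if (length(n) != 1L || !is.finite(n) || n < 1)
        bgStop("n must be a positive count")
    if (length(k) != 1L || !is.finite(k) || k < 0 || k > n)
        bgStop("k must lie in [0, n]")
    if (confidence <= 0 || confidence >= 1)
        bgStop("confidence must lie in (0, 1)")
    z <- stats::qnorm(1 - (1 - confidence) / 2)
    p <- k / n
    den <- 1 + z^2 / n
    center <- (p + z^2 / (2 * n)) / den
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    c(low = max(0, center - hw), high = min(1, center + hw),
      halfWidth = hw)
}

#' Barcode-gap outcome for the species of a distance matrix
#'
#' A species with at least two samples displays a barcode gap when its
#' maximum intraspecific distance is strictly less than its minimum
#' interspecific distance; ties fail.  The minimum interspecific distance
#' is taken against every sample of every other species, singletons
#' (decoy species) included.  Because \code{Inf < Inf} is false, a species
#' whose nearest non-member sits at \code{Inf} has a gap exactly when its
#' own maximum intraspecific distance is finite -- the consistent
#' extension of the strict rule to saturated distances.
#'
#' \code{speciesGaps} evaluates every eligible species;
#' \code{speciesGap} one species (at least two samples required -- the
#' caller must filter, singletons serve as decoys only).
#'
#' @param x A \linkS4class{DistanceMatrix}.
#' @param species A species label present with >= 2 samples.
#' @return \code{speciesGaps}: a data.frame with columns \code{species},
#'   \code{n_samples}, \code{max_intra}, \code{min_inter},
#'   \code{has_gap}.  \code{speciesGap}: a one-row version of the same.
#' @export
speciesGaps <- function(x) {
    stopifnot(is(x, "DistanceMatrix"))
    sp <- x@species
    counts <- table(sp)
    eligible <- names(counts)[counts >= 2L]
    rows <- lapply(eligible, function(s) .gapOne(x, s))
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(species = character(), n_samples = integer(),
                          max_intra = numeric(), min_inter = numeric(),
                          has_gap = logical())
    rownames(out) <- NULL
    out
}

#' @rdname speciesGaps
#' @export
speciesGap <- function(x, species) {
    stopifnot(is(x, "DistanceMatrix"))
    .assertScalarString(species, "species")
    if (!species %in% x@species)
        bgStop("species not present: ", species)
    if (sum(x@species == species) < 2L)
        bgStop("species '", species,
               "' has a single sample; singletons are decoys only")
    .gapOne(x, species)
}

.gapOne <- function(x, s) {
    idx <- which(x@species == s)
    v <- x@values
    intra <- v[idx, idx, drop = FALSE]
    maxIntra <- max(intra[upper.tri(intra)])
    minInter <- min(v[idx, -idx, drop = FALSE])
    data.frame(species = s, n_samples = length(idx),
               max_intra = maxIntra, min_inter = minInter,
               has_gap = maxIntra < minInter,
               stringsAsFactors = FALSE)
}

#' @rdname pci
#' @export
setMethod("pci", "DistanceMatrix", function(x, confidence = 0.95) {
    gaps <- speciesGaps(x)
    if (!nrow(gaps))
        bgStop("no species with at least two samples")
    .pciFromCounts(sum(gaps$has_gap), nrow(gaps), confidence)
})

#' @rdname pci
#' @export
setMethod("pci", "data.frame", function(x, confidence = 0.95) {
    if (!"has_gap" %in% colnames(x))
        bgStop("expected a species gap table with a has_gap column")
    if (!nrow(x)) bgStop("no species with at least two samples")
    .pciFromCounts(sum(x$has_gap), nrow(x), confidence)
})

.pciFromCounts <- function(k, n, confidence = 0.95) {
    w <- wilsonInterval(k, n, confidence)
    new("PciSummary", k = as.integer(k), n = as.integer(n),
        estimate = k / n, confLow = unname(w["low"]),
        confHigh = unname(w["high"]), halfWidth = unname(w["halfWidth"]),
        confidence = confidence)
}

#' @rdname PciSummary-class
#' @param object A \linkS4class{PciSummary}.
#' @export
setMethod("show", "PciSummary", function(object) {
    cat(sprintf("PCI = %.2f+-%.2f (%d/%d species, %g%% Wilson CI %.2f-%.2f)\n",
                object@estimate, object@halfWidth, object@k, object@n,
                100 * object@confidence, object@confLow, object@confHigh))
})

#' @rdname PciSummary-class
#' @param x A \linkS4class{PciSummary}.
#' @param ... Ignored.
#' @export
setMethod("as.data.frame", "PciSummary", function(x, ...) {
    data.frame(k = x@k, n = x@n, pci = x@estimate, conf_low = x@confLow,
               conf_high = x@confHigh, half_width = x@halfWidth,
               confidence = x@confidence)
})

#' PCI grid over alignment types, schemes and distance kinds
#'
#' Runs the full barcode-efficacy comparison: for every combination in the
#' configuration, all pairs are aligned, distances computed, per-species
#' barcode gaps determined and the PCI with its Wilson interval estimated.
#' Pair alignment is shared across distance kinds within one (type,
#' scheme) cell, so adding kinds is cheap.
#'
#' @param dataset A \linkS4class{BarcodeDataset}.
#' @param config An \code{\link{analysisConfig}}.
#' @param details Also return the per-species gap table of every
#'   combination?
#' @return With \code{details = FALSE} a data.frame with one row per
#'   combination (columns \code{alignment_type}, \code{scheme},
#'   \code{distance_kind}, \code{k}, \code{n}, \code{pci},
#'   \code{conf_low}, \code{conf_high}, \code{half_width}); otherwise a
#'   list with elements \code{summary} (that data.frame) and
#'   \code{species} (the long per-species gap table).
#' @export
pciTable <- function(dataset, config, details = FALSE) {
    stopifnot(is(dataset, "BarcodeDataset"))
    config <- .validateConfig(config)
    grid <- list()
    detail <- list()
    for (type in config$alignmentTypes) {
        for (si in seq_along(config$schemes)) {
            scheme <- config$schemes[[si]]
            sname <- schemeName(scheme)
            # one alignment pass per (type, scheme); msa pairs are
            # scheme-free, so compute them once under the first scheme
            if (type == "msa_implied" && si > 1L) {
                stats <- attr(grid, "msaStats")
            } else {
                stats <- .pairStats(dataset, type, scheme, config$msa)
                if (type == "msa_implied") attr(grid, "msaStats") <- stats
            }
            for (kind in config$distanceKinds) {
                dm <- .distanceMatrixFromStats(stats, dataset, type, kind,
                                               scheme, config$msa,
                                               config$normalizeScores)
                gaps <- speciesGaps(dm)
                s <- .pciFromCounts(sum(gaps$has_gap), nrow(gaps),
                                    config$confidence)
                grid[[length(grid) + 1L]] <- cbind(
                    data.frame(alignment_type = type, scheme = sname,
                               distance_kind = kind),
                    as.data.frame(s))
                if (details)
                    detail[[length(detail) + 1L]] <- cbind(
                        data.frame(alignment_type = type, scheme = sname,
                                   distance_kind = kind), gaps)
            }
        }
    }
    summary <- do.call(rbind, grid)
    rownames(summary) <- NULL
    if (!details) return(summary)
    species <- do.call(rbind, detail)
    rownames(species) <- NULL
    list(summary = summary, species = species)
}
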