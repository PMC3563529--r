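# Registry of evolutionary distance models.  Each model maps a stats
# data.frame (columns compared, diffs, tsAG, tsCT, tv, nA, nC, nG, nT) to
# a numeric vector of distances; undefined transforms yield +Inf, never an
# exception, so saturated decoy pairs stay usable in the gap logic.
.distModels <- new.env(parent = emptyenv())

.logPos <- function(x) log(ifelse(is.finite(x) & x > 0, x, NA))

.safeInf <- function(d, p) {
    d[!is.finite(d) | is.nan(d)] <- Inf
    d[p == 0] <- 0
    d
}

.modelP <- function(s) s$diffs / s$compared

.modelJc69 <- function(s) {
    p <- .modelP(s)
    arg <- 1 - 4 * p / 3
    .safeInf(-0.75 * .logPos(arg), p)
}

.modelK2p <- function(s) {
    p <- .modelP(s)
    P <- (s$tsAG + s$tsCT) / s$compared
    Q <- s$tv / s$compared
    a1 <- 1 - 2 * P - Q
    a2 <- 1 - 2 * Q
    .safeInf(-0.5 * .logPos(a1) - 0.25 * .logPos(a2), p)
}

.modelF81 <- function(s) {
    p <- .modelP(s)
    tot <- 2 * s$compared
    B <- 1 - ((s$nA / tot)^2 + (s$nC / tot)^2 + (s$nG / tot)^2 +
              (s$nT / tot)^2)
    arg <- ifelse(B > 0, 1 - p / B, -1)
    .safeInf(-B * .logPos(arg), p)
}

.modelTn93 <- function(s) {
    p <- .modelP(s)
    tot <- 2 * s$compared
    pa <- s$nA / tot; pc <- s$nC / tot; pg <- s$nG / tot; pt <- s$nT / tot
    pr <- pa + pg; py <- pc + pt
    P1 <- s$tsAG / s$compared
    P2 <- s$tsCT / s$compared
    Q <- s$tv / s$compared
    k1 <- 2 * pa * pg / pr
    k2 <- 2 * pc * pt / py
    k3 <- 2 * (pr * py - pa * pg * py / pr - pc * pt * pr / py)
    w1 <- 1 - pr * P1 / (2 * pa * pg) - Q / (2 * pr)
    w2 <- 1 - py * P2 / (2 * pc * pt) - Q / (2 * py)
    w3 <- 1 - Q / (2 * pr * py)
    t1 <- ifelse(k1 > 0, -k1 * .logPos(w1), ifelse(P1 > 0, Inf, 0))
    t2 <- ifelse(k2 > 0, -k2 * .logPos(w2), ifelse(P2 > 0, Inf, 0))
    t3 <- ifelse(k3 > 0, -k3 * .logPos(w3), ifelse(Q > 0, Inf, 0))
    .safeInf(t1 + t2 + t3, p)
}

#' Register an evolutionary distance model
#'
#' Plug-in point for additional distance transforms.  The model function
#' receives a data.frame of per-pair site-pattern counts with columns
#' \code{compared} (unambiguous compared sites), \code{diffs} (differing
#' compared sites), \code{tsAG}, \code{tsCT} (transitions), \code{tv}
#' (transversions) and \code{nA}, \code{nC}, \code{nG}, \code{nT} (base
#' counts over both rows at compared sites), and must return one
#' non-negative distance per row, using \code{Inf} where the transform is
#' undefined.
#'
#' Built-in models: \code{"p"}, \code{"jc69"}, \code{"k2p"}, \code{"f81"},
#' \code{"tn93"}.  Since the barcode-gap decision depends only on the
#' ordering of distances, any model that is a strictly increasing
#' transform of p-distance yields identical PCI values.
#'
#' @param name Model name.
#' @param fun The model function.
#' @return Invisibly, \code{name}.
#' @export
registerDistanceModel <- function(name, fun) {
    .assertScalarString(name, "name")
    stopifnot(is.function(fun))
    assign(name, fun, envir = .distModels)
    invisible(name)
}

#' @rdname registerDistanceModel
#' @export
distanceModels <- function() sort(ls(.distModels))

.getModel <- function(name) {
    if (!exists(name, envir = .distModels, inherits = FALSE))
        bgStop("unknown distance model '", name, "'; available: ",
               paste(distanceModels(), collapse = ", "))
    get(name, envir = .distModels, inherits = FALSE)
}

.registerBuiltinModels <- function() {
    registerDistanceModel("p", .modelP)
    registerDistanceModel("jc69", .modelJc69)
    registerDistanceModel("k2p", .modelK2p)
    registerDistanceModel("f81", .modelF81)
    registerDistanceModel("tn93", .modelTn93)
}

#' Alignment distance of a scored alignment
#'
#' The negated alignment score: an order-reversing transform of
#' similarity, used for ranking and barcode-gap comparisons only (it is
#' not a metric).  With \code{normalize = TRUE} the score is divided by
#' the number of alignment columns first, for sensitivity analyses where
#' sequence length should not dominate.
#'
#' @param aln A scored \linkS4class{BarcodeAlignment}.
#' @param normalize Divide the score by the alignment length first?
#' @return A single number.
#' @export
alignmentDistance <- function(aln, normalize = FALSE) {
    stopifnot(is(aln, "BarcodeAlignment"))
    if (is.na(aln@score))
        bgStop("alignment carries no score; use scoreAlignment() first")
    if (normalize) -aln@score / max(1L, nchar(aln@pattern)) else -aln@score
}

.alnCounts <- function(aln) {
    as.data.frame(cpp_pair_counts(aln@pattern, aln@subject))
}

#' p-distance of a pairwise alignment
#'
#' The proportion of compared sites at which the two rows differ.
#' Compared sites are the columns holding an unambiguous base in both
#' rows; gapped or ambiguous columns are excluded (pairwise deletion).
#'
#' @param aln A \linkS4class{BarcodeAlignment}.
#' @return A number in \code{[0, 1]}.
#' @examples
#' pDistance(globalAlign("ACGT", "ACGA", ncbiScheme()))  # 0.25
#' @export
pDistance <- function(aln) {
    stopifnot(is(aln, "BarcodeAlignment"))
    s <- .alnCounts(aln)
    if (s$compared == 0)
        bgStop("no unambiguous compared sites; p-distance undefined")
    s$diffs / s$compared
}

#' Evolutionary distance of a pairwise alignment
#'
#' Model transform of the observed site-pattern frequencies of one
#' pairwise alignment: e.g. \code{jc69 = -(3/4) log(1 - 4p/3)} and
#' \code{k2p = -(1/2) log(1 - 2P - Q) - (1/4) log(1 - 2Q)} with transition
#' proportion \code{P} and transversion proportion \code{Q}.  Where the
#' logarithm argument is non-positive (saturation) the distance is
#' \code{+Inf}, which compares as larger than every finite distance.
#'
#' @param aln A \linkS4class{BarcodeAlignment}.
#' @param model A registered model name; see
#'   \code{\link{registerDistanceModel}}.
#' @return A non-negative number, possibly \code{Inf}.
#' @export
evolutionaryDistance <- function(aln, model = "p") {
    stopifnot(is(aln, "BarcodeAlignment"))
    s <- .alnCounts(aln)
    if (s$compared == 0)
        bgStop("no unambiguous compared sites; distance undefined")
    .getModel(model)(s)
}

# Batch pair statistics for a dataset under one alignment route.
.pairStats <- function(dataset, alignmentType, scheme = NULL, msa = NULL) {
    seqs <- as.character(dataset@sequences)
    n <- length(seqs)
    if (n < 2L) bgStop("need at least two records")
    if (alignmentType == "msa_implied") {
        if (is.null(msa)) bgStop("msa_implied requires an MsaBlock")
        rows <- msa@rows[msaRowMap(msa, dataset)]
        stats <- cpp_msa_pair_stats(unname(rows))
    } else {
        if (is.null(scheme)) bgStop("pairwise alignment requires a scheme")
        stats <- cpp_all_pair_stats(seqs, .fullScoreMatrix(scheme),
                                    scheme@gapOpen, scheme@gapExtend,
                                    alignmentType)
    }
    ij <- which(upper.tri(diag(n)), arr.ind = TRUE)
    ij <- ij[order(ij[, "row"], ij[, "col"]), , drop = FALSE]
    cbind(data.frame(i = ij[, "row"], j = ij[, "col"]),
          as.data.frame(stats))
}

.squareFromPairs <- function(values, n, labels, diagValue) {
    m <- matrix(0, n, n, dimnames = list(labels, labels))
    m[cbind(rep(seq_len(n - 1), times = (n - 1):1),
            unlist(lapply(seq_len(n - 1), function(i) (i + 1):n)))] <- values
    m <- m + t(m)
    diag(m) <- diagValue
    m
}

#' All-pairs distance matrix of a dataset
#'
#' Aligns every unordered pair of records under one alignment type and
#' turns each alignment into a distance.  For the pairwise types
#' (\code{"global"}, \code{"semiglobal"}, \code{"local"}) a
#' \linkS4class{ScoringScheme} drives the alignment; for
#' \code{"msa_implied"} an externally computed \linkS4class{MsaBlock}
#' supplies the implied global pairwise alignments (records are matched to
#' MSA rows by exact degapped sequence, so duplicates share a row).
#'
#' Evolutionary kinds (\code{"p"}, \code{"jc69"}, \code{"k2p"},
#' \code{"f81"}, \code{"tn93"}, plus anything registered) use pairwise
#' deletion and return \code{Inf} on saturated transforms; the diagonal is
#' 0.  Kind \code{"alignment_score"} is the negated alignment score; for
#' \code{msa_implied} it requires a scheme to re-score the implied
#' alignments.
#'
#' @param dataset A \linkS4class{BarcodeDataset}.
#' @param alignmentType One of \code{"global"}, \code{"semiglobal"},
#'   \code{"local"}, \code{"msa_implied"}.
#' @param kind Distance kind.
#' @param scheme A \linkS4class{ScoringScheme} (pairwise types, and
#'   \code{msa_implied} with \code{kind = "alignment_score"}).
#' @param msa An \linkS4class{MsaBlock} (for \code{"msa_implied"}).
#' @param normalize For \code{kind = "alignment_score"}: divide scores by
#'   alignment length before negating.
#' @return A \linkS4class{DistanceMatrix}.
#' @examples
#' sim <- simulateDataset(simulationParams(nSpecies = 3,
#'     samplesPerSpecies = 2, seed = 7))
#' dm <- distanceMatrix(sim$dataset, "global", kind = "p",
#'     scheme = ncbiScheme())
#' speciesGaps(dm)
#' @export
distanceMatrix <- function(dataset,
                           alignmentType = c("global", "semiglobal",
                                             "local", "msa_implied"),
                           kind = "p", scheme = NULL, msa = NULL,
                           normalize = FALSE) {
    stopifnot(is(dataset, "BarcodeDataset"))
    alignmentType <- match.arg(alignmentType)
    .assertScalarString(kind, "kind")
    st <- .pairStats(dataset, alignmentType, scheme, msa)
    .distanceMatrixFromStats(st, dataset, alignmentType, kind, scheme, msa,
                             normalize)
}

# shared by distanceMatrix() and pciTable() (which reuses one stats table
# for several kinds)
.distanceMatrixFromStats <- function(st, dataset, alignmentType, kind,
                                     scheme = NULL, msa = NULL,
                                     normalize = FALSE) {
    ids <- sampleIds(dataset)
    n <- length(ids)
    if (kind == "alignment_score") {
        score <- st$score
        if (alignmentType == "msa_implied") {
            if (is.null(scheme))
                bgStop("alignment_score on msa_implied needs a scheme")
            rows <- msa@rows[msaRowMap(msa, dataset)]
            full <- .fullScoreMatrix(scheme)
            score <- mapply(function(i, j)
                cpp_score_fixed(rows[[i]], rows[[j]], full,
                                scheme@gapOpen, scheme@gapExtend),
                st$i, st$j)
        }
        vals <- if (normalize) -score / pmax(1, st$ncol) else -score
        # self-similarity is maximal under a positive-match scheme, so the
        # diagonal is each row's minimum
        full <- .fullScoreMatrix(scheme)
        self <- vapply(as.character(dataset@sequences), function(s) {
            ch <- strsplit(s, "", fixed = TRUE)[[1]]
            sum(full[cbind(ch, ch)])
        }, numeric(1))
        diagv <- if (normalize)
            -self / pmax(1, Biostrings::width(dataset@sequences)) else -self
        values <- .squareFromPairs(vals, n, ids, diagv)
    } else {
        bad <- st$compared == 0
        if (any(bad))
            bgStop("no unambiguous compared sites for pair(s): ",
                   paste(paste0(ids[st$i[bad]], "/", ids[st$j[bad]]),
                         collapse = ", "))
        vals <- .getModel(kind)(st)
        values <- .squareFromPairs(vals, n, ids, 0)
    }
    new("DistanceMatrix", values = values,
        species = stats::setNames(speciesLabels(dataset), ids),
        kind = kind)
}

#' @rdname DistanceMatrix-class
#' @export
setMethod("sampleLabels", "DistanceMatrix",
    function(x) rownames(x@values))

#' @rdname DistanceMatrix-class
#' @export
setMethod("speciesLabels", "DistanceMatrix", function(x) x@species)

#' @rdname DistanceMatrix-class
#' @export
setMethod("distanceKind", "DistanceMatrix", function(x) x@kind)

#' @rdname DistanceMatrix-class
#' @export
setMethod("dim", "DistanceMatrix", function(x) dim(x@values))

#' @rdname DistanceMatrix-class
#' @export
setMethod("as.matrix", "DistanceMatrix", function(x, ...) x@values)

setMethod("show", "DistanceMatrix", function(object) {
    n <- nrow(object@values)
    cat("DistanceMatrix (", object@kind, "): ", n, " samples, ",
        length(unique(object@species)), " species, ",
        sum(is.infinite(object@values)) / 2, " saturated pairs\n", sep = "")
})

#' Write / read a distance matrix as square TSV
#'
#' \code{writeDistanceMatrix} writes a square tab-separated matrix with a
#' label header row and label first column.  \code{readDistanceMatrix}
#' reads that format, and also a PHYLIP-style square matrix (count line,
#' then label + row values).  Species labels are not stored in either
#' format and must be re-supplied on read for gap analysis.
#'
#' @param x A \linkS4class{DistanceMatrix}.
#' @param path File path.
#' @param species Named character vector (label -> species) to attach on
#'   read; optional.
#' @param kind Distance kind to record on read.
#' @return \code{readDistanceMatrix} returns a
#'   \linkS4class{DistanceMatrix}; \code{writeDistanceMatrix} its input,
#'   invisibly.
#' @export
writeDistanceMatrix <- function(x, path) {
    stopifnot(is(x, "DistanceMatrix"))
    df <- data.frame(label = rownames(x@values), x@values,
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(x)
}

#' @rdname writeDistanceMatrix
#' @export
readDistanceMatrix <- function(path, species = NULL, kind = "unknown") {
    if (!file.exists(path)) bgStop("no such distance matrix file: ", path)
    first <- readLines(path, n = 1L)
    if (grepl("^\\s*[0-9]+\\s*$", first)) {
        # PHYLIP square: first line is the sample count
        n <- as.integer(trimws(first))
        tab <- utils::read.table(path, skip = 1, header = FALSE,
                                 stringsAsFactors = FALSE)
        if (nrow(tab) != n || ncol(tab) != n + 1L)
            bgStop("malformed PHYLIP square matrix in ", path)
        labels <- as.character(tab[[1]])
        m <- as.matrix(tab[, -1, drop = FALSE])
    } else {
        tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                                 stringsAsFactors = FALSE)
        labels <- as.character(tab[[1]])
        m <- as.matrix(tab[, -1, drop = FALSE])
    }
    dimnames(m) <- list(labels, labels)
    mode(m) <- "numeric"
    if (is.null(species))
        species <- stats::setNames(rep(NA_character_, length(labels)),
                                   labels)
    new("DistanceMatrix", values = m,
        species = species[labels], kind = kind)
}
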