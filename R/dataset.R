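#' Read unaligned DNA sequences from a FASTA file
#'
#' Sequences are uppercased and RNA \code{U} is mapped to \code{T}.
#' Records keep file order.  Empty sequences and duplicate ids are hard
#' errors naming the offending records.
#'
#' @param path Path to a FASTA file.
#' @return A named \linkS4class{DNAStringSet} in file order.
#' @export
readFasta <- function(path) {
    if (!file.exists(path)) bgStop("no such FASTA file: ", path)
    raw <- Biostrings::readBStringSet(path)
    if (!length(raw)) bgStop("FASTA file has no records: ", path)
    ids <- sub("\\s.*$", "", names(raw))
    if (anyDuplicated(ids))
        bgStop("duplicate FASTA ids: ",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
    empty <- Biostrings::width(raw) == 0
    if (any(empty))
        bgStop("empty sequence for FASTA record(s): ",
               paste(ids[empty], collapse = ", "))
    out <- Biostrings::DNAStringSet(.normalizeDna(as.character(raw)))
    names(out) <- ids
    out
}

#' Assemble a dataset from FASTA sequences and a metadata table
#'
#' The metadata is a tab-separated table with a header row and columns
#' \code{sample_id}, \code{species}, \code{genus}, \code{source}
#' (\code{genbank}/\code{local}) and \code{expert_agreement}
#' (\code{agree}/\code{disagree}/\code{unknown}).  Every FASTA id must
#' appear exactly once; species labels are taken as literal strings, and
#' the expert flag must be consistent across all records of one species.
#'
#' @param fasta Path to an unaligned FASTA file.
#' @param metadata Path to the tab-separated metadata table.
#' @return A \linkS4class{BarcodeDataset} in FASTA order.
#' @seealso \code{\link{BarcodeDataset}}, \code{\link{partitionDataset}}
#' @export
readBarcodeDataset <- function(fasta, metadata) {
    seqs <- readFasta(fasta)
    if (!file.exists(metadata)) bgStop("no such metadata file: ", metadata)
    md <- utils::read.delim(metadata, header = TRUE, sep = "\t",
                            colClasses = "character",
                            stringsAsFactors = FALSE)
    need <- c("sample_id", "species", "genus", "source", "expert_agreement")
    miss <- setdiff(need, colnames(md))
    if (length(miss))
        bgStop("metadata misses column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(md$sample_id))
        bgStop("duplicate metadata sample_id: ",
               paste(unique(md$sample_id[duplicated(md$sample_id)]),
                     collapse = ", "))
    absent <- setdiff(names(seqs), md$sample_id)
    if (length(absent))
        bgStop("FASTA id(s) missing from metadata: ",
               paste(absent, collapse = ", "))
    orphan <- setdiff(md$sample_id, names(seqs))
    if (length(orphan))
        bgStop("metadata row(s) without a sequence: ",
               paste(orphan, collapse = ", "))
    md <- md[match(names(seqs), md$sample_id), , drop = FALSE]
    BarcodeDataset(seqs, md)
}

#' @rdname BarcodeDataset-class
#' @param sequences A named \linkS4class{DNAStringSet}.
#' @param sampleData A data.frame or DataFrame of per-sample metadata with
#'   columns \code{sample_id}, \code{species}, \code{genus}, \code{source},
#'   \code{expert_agreement}, in sequence order.
#' @export
BarcodeDataset <- function(sequences, sampleData) {
    if (is.character(sequences))
        sequences <- Biostrings::DNAStringSet(.normalizeDna(sequences))
    md <- S4Vectors::DataFrame(sampleData)
    rownames(md) <- NULL
    obj <- try(new("BarcodeDataset", sequences = sequences, sampleData = md),
               silent = TRUE)
    if (inherits(obj, "try-error"))
        bgStop(conditionMessage(attr(obj, "condition")))
    obj
}

#' Partition a dataset on a metadata field
#'
#' Returns the records whose \code{field} equals \code{value}; species
#' present only through excluded records vanish from the subset.  The
#' empty result is permitted.  Partitions over the distinct values of one
#' field are disjoint and jointly exhaust the dataset.
#'
#' @param x A \linkS4class{BarcodeDataset}.
#' @param field \code{"source"} or \code{"expert_agreement"}.
#' @param value The value to keep.
#' @return A \linkS4class{BarcodeDataset}.
#' @examples
#' sim <- simulateDataset(simulationParams(nSpecies = 3,
#'     samplesPerSpecies = 2, seed = 1))
#' partitionDataset(sim$dataset, "source", "local")
#' @export
partitionDataset <- function(x, field = c("source", "expert_agreement"),
                             value) {
    stopifnot(is(x, "BarcodeDataset"))
    field <- match.arg(field)
    .assertScalarString(value, "value")
    keep <- x@sampleData[[field]] == value
    x[keep]
}

#' @rdname BarcodeDataset-class
#' @export
setMethod("sampleIds", "BarcodeDataset", function(x) x@sampleData$sample_id)

#' @rdname BarcodeDataset-class
#' @export
setMethod("speciesLabels", "BarcodeDataset",
    function(x) x@sampleData$species)

#' @rdname BarcodeDataset-class
#' @export
setMethod("sequences", "BarcodeDataset", function(x) x@sequences)

#' @rdname BarcodeDataset-class
#' @export
setMethod("sampleData", "BarcodeDataset", function(x) x@sampleData)

#' @rdname BarcodeDataset-class
#' @export
setMethod("length", "BarcodeDataset", function(x) length(x@sequences))

#' @rdname BarcodeDataset-class
#' @param i Index, logical mask or vector of sample ids.
#' @param j,drop,... Ignored (matrix-style subsetting is not supported).
#' @export
setMethod("[", "BarcodeDataset", function(x, i, j, ..., drop = TRUE) {
    if (is.character(i)) i <- match(i, x@sampleData$sample_id)
    new("BarcodeDataset", sequences = x@sequences[i],
        sampleData = x@sampleData[i, , drop = FALSE])
})

#' Per-species sample counts
#'
#' @param x A \linkS4class{BarcodeDataset}.
#' @return A named integer vector, one entry per species label.
#' @export
speciesCounts <- function(x) {
    stopifnot(is(x, "BarcodeDataset"))
    tab <- table(x@sampleData$species)
    stats::setNames(as.integer(tab), names(tab))
}

setMethod("show", "BarcodeDataset", function(object) {
    md <- object@sampleData
    n <- length(object)
    nsp <- length(unique(md$species))
    single <- sum(table(md$species) == 1L)
    cat("BarcodeDataset:", n, "records,", nsp, "species (",
        single, "singletons )\n")
    if (n) {
        w <- Biostrings::width(object@sequences)
        cat("  sequence lengths:", min(w), "-", max(w), "bp\n")
        cat("  source:", paste(names(table(md$source)), table(md$source),
                               collapse = ", "), "\n")
    }
})

#' Write a dataset as FASTA plus metadata TSV
#'
#' @param x A \linkS4class{BarcodeDataset}.
#' @param fasta,metadata Output paths.
#' @return Invisibly, \code{x}.
#' @export
writeDataset <- function(x, fasta, metadata) {
    stopifnot(is(x, "BarcodeDataset"))
    Biostrings::writeXStringSet(x@sequences, fasta)
    utils::write.table(as.data.frame(x@sampleData), metadata, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(x)
}
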