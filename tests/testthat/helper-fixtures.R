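# Small in-code fixtures shared across the suite.

writeTempFasta <- function(lines) {
    f <- tempfile(fileext = ".fasta")
    writeLines(lines, f)
    f
}

writeTempTsv <- function(df) {
    f <- tempfile(fileext = ".tsv")
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
}

randSeq <- function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = "")
}

# a six-record dataset over three species, mixed sources
toyDataset <- function() {
    seqs <- c(x1 = "ACGTACGTAC", x2 = "ACGTACGTAT",
              y1 = "TTTTACGCCC", y2 = "TTTTACGCCA",
              z1 = "GGGGCATTGG", z2 = "GGGGCATTGA")
    md <- data.frame(
        sample_id = names(seqs),
        species = rep(c("Hypoxylon alpha", "Hypoxylon beta",
                        "Annulohypoxylon gamma"), each = 2),
        genus = rep(c("Hypoxylon", "Hypoxylon", "Annulohypoxylon"),
                    each = 2),
        source = c("genbank", "local", "genbank", "genbank", "local",
                   "local"),
        expert_agreement = rep(c("agree", "disagree", "agree"), each = 2),
        stringsAsFactors = FALSE)
    BarcodeDataset(seqs, md)
}

# hand-built DistanceMatrix from a symmetric matrix and species labels
makeDistanceMatrix <- function(values, species, kind = "p") {
    labels <- paste0("s", seq_len(nrow(values)))
    dimnames(values) <- list(labels, labels)
    new("DistanceMatrix", values = values,
        species = stats::setNames(species, labels), kind = kind)
}

# species-structured block matrix: within-species distance `intra`,
# between-species distance `inter`, counts per species as given
blockMatrix <- function(counts, intra, inter, kind = "p") {
    species <- rep(paste0("sp", seq_along(counts)), counts)
    n <- length(species)
    v <- matrix(inter, n, n)
    for (s in unique(species)) {
        idx <- which(species == s)
        v[idx, idx] <- intra
    }
    diag(v) <- 0
    makeDistanceMatrix(v, species, kind)
}
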