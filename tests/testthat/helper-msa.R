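# External MSA for the msa_implied route; mafft (FFT-NS-2 defaults) plays
# the role the study's progressive aligner played.
# Gap-scattering stand-in for an aligner: inserts random gaps into each
# row and pads to equal width.  Geometrically a valid MSA (each row degaps
# to its input), with no biological meaning -- used for structural
# properties that must hold for ANY alignment.
runMafftStub <- function(raw) {
    gapped <- vapply(raw, function(s) {
        ch <- strsplit(s, "")[[1]]
        for (g in seq_len(sample(0:3, 1))) {
            at <- sample(length(ch) + 1L, 1L) - 1L
            ch <- append(ch, rep("-", sample(1:3, 1)), after = at)
        }
        paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
    w <- max(nchar(gapped))
    gapped <- vapply(gapped, function(s)
        paste0(s, strrep("-", w - nchar(s))), character(1),
        USE.NAMES = FALSE)
    names(gapped) <- paste0("r", seq_along(gapped))
    MsaBlock(gapped)
}

runMafft <- function(seqs) {
    fa <- tempfile(fileext = ".fa")
    out <- tempfile(fileext = ".afa")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fa)
    status <- system2("mafft", c("--quiet", "--retree", "2", shQuote(fa)),
                      stdout = out)
    if (!identical(status, 0L)) stop("mafft failed")
    readAlignedFasta(out)
}
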