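# classed error helper so callers (notably the command-line wrapper) can
# distinguish bad input from internal failure
bgStop <- function(..., class = "barcodeGap_input") {
    stop(errorCondition(paste0(...), class = c(class, "barcodeGap_error")))
}

.assertScalarString <- function(x, what) {
    if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
        bgStop(what, " must be a single non-empty string")
}

# DNA normalization applied to every sequence on load: uppercase, RNA 'U'
# mapped to 'T'
.normalizeDna <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))
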