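# The replicated simulation grid used by several distribution-level
# checks: 20 seeded datasets of 10 species x 5 samples at the reference
# divergence setting (within-species substitution rate 0.02, species
# divergence 0.30), run through the full PCI grid (four alignment types,
# NCBI scoring, five distance kinds).  Computed once per session and
# cached, since several tests interrogate different aspects of the same
# replicated experiment.
.gridCache <- new.env(parent = emptyenv())

gridSeeds <- function() 101:120

gridParams <- function(seed, intraRate = 0.02) {
    simulationParams(nSpecies = 10, samplesPerSpecies = 5,
                     intraRate = intraRate, interRate = 0.30,
                     crypticPair = FALSE, seed = seed)
}

replicatedPciGrid <- function() {
    if (!is.null(.gridCache$grid)) return(.gridCache$grid)
    kinds <- c("p", "jc69", "k2p", "f81", "tn93")
    res <- lapply(gridSeeds(), function(sd) {
        sim <- simulateDataset(gridParams(sd))
        msa <- runMafft(sequences(sim$dataset))
        cfg <- analysisConfig(
            alignmentTypes = c("global", "semiglobal", "local",
                               "msa_implied"),
            schemes = list(ncbiScheme()),
            distanceKinds = kinds,
            msa = msa)
        cbind(seed = sd, pciTable(sim$dataset, cfg))
    })
    .gridCache$grid <- do.call(rbind, res)
    .gridCache$grid
}

# PCI of the same 20 seeds at matched intra/inter divergence (labels
# carry no signal), global alignment + p-distance only
equalRatePcis <- function() {
    if (!is.null(.gridCache$equal)) return(.gridCache$equal)
    .gridCache$equal <- vapply(gridSeeds(), function(sd) {
        sim <- simulateDataset(gridParams(sd, intraRate = 0.30))
        dm <- distanceMatrix(sim$dataset, "global", kind = "p",
                             scheme = ncbiScheme())
        pci(dm)@estimate
    }, numeric(1))
    .gridCache$equal
}
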