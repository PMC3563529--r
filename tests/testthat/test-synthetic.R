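test_that("parameter validation enforces the simulator's assumptions", {
    expect_error(simulationParams(nSpecies = 0), "positive")
    expect_error(simulationParams(intraRate = 0.4, interRate = 0.2),
                 "intraRate <= interRate")
    expect_error(simulationParams(interRate = 0.8), "0.75")
    expect_error(simulationParams(indelRate = 1), "indelRate")
})

test_that("the same seed reproduces the dataset byte for byte", {
    p <- simulationParams(nSpecies = 4, samplesPerSpecies = 3,
                          lengthRange = c(100, 200), seed = 77)
    s1 <- simulateDataset(p)
    s2 <- simulateDataset(p)
    expect_identical(as.character(sequences(s1$dataset)),
                     as.character(sequences(s2$dataset)))
    expect_identical(s1$truth, s2$truth)
    d1 <- tempfile(); d2 <- tempfile()
    writeDataset(s1$dataset, file.path(d1), file.path(paste0(d1, ".tsv")))
    writeDataset(s2$dataset, file.path(d2), file.path(paste0(d2, ".tsv")))
    expect_identical(readLines(d1), readLines(d2))
    # a different seed gives different sequences
    s3 <- simulateDataset(simulationParams(nSpecies = 4,
        samplesPerSpecies = 3, lengthRange = c(100, 200), seed = 78))
    expect_false(identical(as.character(sequences(s1$dataset)),
                           as.character(sequences(s3$dataset))))
})

test_that("degenerate rates give identical conspecific samples and PCI 1", {
    sim <- simulateDataset(simulationParams(
        nSpecies = 5, samplesPerSpecies = 3, intraRate = 0,
        interRate = 0.3, indelRate = 0, lengthRange = c(150, 250),
        crypticPair = FALSE, seed = 5))
    sp <- split(as.character(sequences(sim$dataset)),
                speciesLabels(sim$dataset))
    for (s in sp) expect_length(unique(s), 1L)
    dm <- distanceMatrix(sim$dataset, "global", kind = "p",
                         scheme = ncbiScheme())
    gaps <- speciesGaps(dm)
    expect_true(all(gaps$max_intra == 0))
    expect_equal(pci(dm)@estimate, 1)
})

test_that("substitution machinery behaves at the extremes", {
    set.seed(61)
    expect_identical(mutateSequence("ACGTACGT", 0, 0), "ACGTACGT")
    out <- mutateSequence(strrep("A", 500), 1, 0)
    expect_false(grepl("A", out, fixed = TRUE))
    expect_identical(nchar(out), 500L)
})

test_that("realized Hamming fraction estimates the substitution rate", {
    set.seed(62)
    L <- 10000
    rate <- 0.05
    a <- randSeq(L)
    b <- mutateSequence(a, rate, 0)
    ham <- mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    se <- sqrt(rate * (1 - rate) / L)
    expect_lt(abs(ham - rate), 3 * se)
    # and the p-distance of the aligned pair sees the same fraction
    aln <- globalAlign(a, b, ncbiScheme())
    expect_equal(pDistance(aln), ham, tolerance = 1e-12)
})

test_that("transition bias shows up when kappa is raised", {
    set.seed(63)
    a <- randSeq(20000)
    b <- mutateSequence(a, 0.1, 0, kappa = 8)
    aln <- new("BarcodeAlignment", pattern = a, subject = b,
               score = NA_real_, type = "msa_implied")
    s <- barcodeGap:::.alnCounts(aln)
    P <- (s$tsAG + s$tsCT) / s$compared
    Q <- s$tv / s$compared
    expect_gt(P / Q, 2)   # kappa = 8 -> expected ratio 4
    expect_gt(evolutionaryDistance(aln, "k2p"),
              evolutionaryDistance(aln, "p"))
})

test_that("the cryptic pair yields a bimodal length split within one label", {
    sim <- simulateDataset(simulationParams(
        nSpecies = 6, samplesPerSpecies = 6, lengthRange = c(300, 500),
        crypticPair = list(insertLength = 390L, at = 100L), seed = 64))
    cr <- unique(sim$truth$true_species[sim$truth$lineage == "B"])
    expect_length(cr, 1L)
    lens <- Biostrings::width(sequences(sim$dataset))[
        speciesLabels(sim$dataset) == cr]
    split <- lens > mean(range(lens))
    expect_true(any(split) && any(!split))
    # the two length classes are separated by roughly the insert length
    expect_gt(min(lens[split]) - max(lens[!split]), 390 / 2)
    # and the class assignment matches the lineage truth
    lineage <- sim$truth$lineage[sim$truth$true_species == cr]
    expect_identical(unname(split), lineage == "B")
})

test_that("PCI decreases as within-species divergence approaches the species divergence", {
    rates <- c(0.01, 0.1, 0.3)
    pcis <- vapply(rates, function(r) {
        sim <- simulateDataset(simulationParams(
            nSpecies = 5, samplesPerSpecies = 3,
            lengthRange = c(200, 300), intraRate = r, interRate = 0.3,
            crypticPair = FALSE, seed = 65))
        dm <- distanceMatrix(sim$dataset, "global", kind = "p",
                             scheme = ncbiScheme())
        pci(dm)@estimate
    }, numeric(1))
    expect_true(all(diff(pcis) <= 0))
    expect_gt(pcis[1], pcis[3])
})

test_that("generated metadata is loader-valid and survey-structured", {
    sim <- simulateDataset(simulationParams(seed = 66))
    ds <- sim$dataset
    expect_s4_class(ds, "BarcodeDataset")   # validity ran in constructor
    counts <- speciesCounts(ds)
    expect_identical(length(counts), 35L)
    expect_true(any(counts == 1L))          # decoys present
    w <- Biostrings::width(sequences(ds))
    expect_true(all(w >= 200))              # indels jitter the 384-936 draw
    expect_true(all(sort(unique(sampleData(ds)$source)) %in%
                    c("genbank", "local")))
})
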