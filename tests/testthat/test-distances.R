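ns <- ncbiScheme()

test_that("alignment distance is the negated score", {
    aln <- globalAlign("ACGT", "ACGT", ns)
    expect_equal(alignmentDistance(aln), -4)
    expect_equal(alignmentDistance(globalAlign("ACGT", "ACGA", ns)), 0)
    expect_equal(alignmentDistance(aln, normalize = TRUE), -1)
    expect_error(alignmentDistance(impliedPairwise(
        MsaBlock(c(a = "AC", b = "AC")), 1, 2)), "no score")
})

test_that("p-distance uses pairwise deletion of gapped and ambiguous sites", {
    expect_equal(pDistance(globalAlign("ACGT", "ACGA", ns)), 0.25)
    m <- MsaBlock(c(a = "AC-T", b = "ACGT"))
    expect_equal(pDistance(impliedPairwise(m, 1, 2)), 0)
    m2 <- MsaBlock(c(a = "ACNT", b = "ACGT"))
    expect_equal(pDistance(impliedPairwise(m2, 1, 2)), 0)
    # no comparable sites at all is an error
    m3 <- MsaBlock(c(a = "A-", b = "-A"))
    expect_error(pDistance(impliedPairwise(m3, 1, 2)), "compared sites")
})

test_that("model transforms follow their closed forms", {
    ident <- globalAlign("ACGT", "ACGT", ns)
    for (k in c("p", "jc69", "k2p", "f81", "tn93"))
        expect_equal(evolutionaryDistance(ident, k), 0)
    # one transversion in four sites: P = 0, Q = 0.25
    aln <- globalAlign("ACGT", "ACGA", ns)
    expect_equal(evolutionaryDistance(aln, "k2p"),
                 -0.5 * log(1 - 0.25) - 0.25 * log(1 - 0.5))
    expect_equal(evolutionaryDistance(aln, "jc69"),
                 -0.75 * log(1 - 4 * 0.25 / 3))
    # p = 0.75 saturates the JC69 transform
    sat <- impliedPairwise(MsaBlock(c(a = "ACGT", b = "CAGG")), 1, 2)
    expect_equal(pDistance(sat), 0.75)
    expect_identical(evolutionaryDistance(sat, "jc69"), Inf)
})

test_that("all five models agree with an independent implementation", {
    skip_if_not_installed("ape")
    set.seed(31)
    models <- c(p = "raw", jc69 = "JC69", k2p = "K80", f81 = "F81",
                tn93 = "TN93")
    for (rep in 1:15) {
        n <- 400
        a <- sample(c("a", "c", "g", "t"), n, replace = TRUE)
        b <- a
        hit <- sample(n, sample(20:120, 1))
        b[hit] <- sample(c("a", "c", "g", "t"), length(hit),
                         replace = TRUE)
        bin <- ape::as.DNAbin(rbind(a, b))
        aln <- new("BarcodeAlignment",
                   pattern = toupper(paste(a, collapse = "")),
                   subject = toupper(paste(b, collapse = "")),
                   score = NA_real_, type = "msa_implied")
        for (k in names(models)) {
            ref <- as.numeric(ape::dist.dna(bin, model = models[[k]],
                                            pairwise.deletion = TRUE))
            expect_equal(evolutionaryDistance(aln, k), ref,
                         tolerance = 1e-10, info = k)
        }
    }
})

test_that("model-corrected distances dominate p-distance", {
    set.seed(32)
    for (rep in 1:20) {
        a <- randSeq(200)
        b <- mutateSequence(a, runif(1, 0, 0.4))
        aln <- globalAlign(a, b, ns)
        p <- pDistance(aln)
        expect_gte(evolutionaryDistance(aln, "jc69"), p)
        expect_gte(evolutionaryDistance(aln, "k2p"), p)
    }
})

test_that("distance matrices are symmetric, zero-diagonal and consistent", {
    seqs <- c(a = "ACGTACGTGG", b = "ACGTACGTGG", cc = "ACGTACGTGG")
    md <- data.frame(sample_id = names(seqs), species = "One sp",
                     genus = "One", source = "local",
                     expert_agreement = "agree")
    ds <- BarcodeDataset(seqs, md)
    dm <- distanceMatrix(ds, "global", kind = "jc69", scheme = ns)
    expect_true(all(as.matrix(dm) == 0))

    ds2 <- toyDataset()
    dm2 <- distanceMatrix(ds2, "global", kind = "p", scheme = ns)
    v <- as.matrix(dm2)
    expect_identical(v, t(v))
    expect_true(all(diag(v) == 0))
    aln <- globalAlign(as.character(sequences(ds2))[1],
                       as.character(sequences(ds2))[2], ns)
    expect_equal(v["x1", "x2"], pDistance(aln))

    # jc69 is a strictly increasing transform of p where finite
    dmj <- distanceMatrix(ds2, "global", kind = "jc69", scheme = ns)
    p <- v[upper.tri(v)]
    j <- as.matrix(dmj)[upper.tri(v)]
    expect_true(all(j >= p))
    fin <- is.finite(j)
    ord <- order(p[fin])
    expect_true(all(diff(j[fin][ord]) >= 0))
})

test_that("a pair with no compared sites fails loudly with its ids", {
    seqs <- c(ok1 = "ACGTACGT", ok2 = "ACGTACGA", far = "TTTTTTTT")
    md <- data.frame(sample_id = names(seqs),
                     species = c("A b", "A b", "C d"), genus = "X",
                     source = "local", expert_agreement = "agree")
    ds <- BarcodeDataset(seqs, md)
    # local alignment of A-runs vs T-runs is empty -> no compared sites
    seqs2 <- c(a = "AAAA", b = "TTTT")
    md2 <- data.frame(sample_id = names(seqs2),
                      species = c("A b", "C d"), genus = "X",
                      source = "local", expert_agreement = "agree")
    ds2 <- BarcodeDataset(seqs2, md2)
    expect_error(distanceMatrix(ds2, "local", kind = "p", scheme = ns),
                 "a/b")
    # the same pair is fine under global alignment
    dm <- distanceMatrix(ds2, "global", kind = "p", scheme = ns)
    expect_equal(as.matrix(dm)["a", "b"], 1)
})

test_that("alignment-score matrices put each row's minimum on the diagonal", {
    ds <- toyDataset()
    dm <- distanceMatrix(ds, "global", kind = "alignment_score",
                         scheme = ns)
    v <- as.matrix(dm)
    for (i in seq_len(nrow(v)))
        expect_equal(min(v[i, ]), v[i, i])
})

test_that("distance matrices round-trip through TSV and read PHYLIP square", {
    ds <- toyDataset()
    dm <- distanceMatrix(ds, "global", kind = "p", scheme = ns)
    f <- tempfile(fileext = ".tsv")
    writeDistanceMatrix(dm, f)
    back <- readDistanceMatrix(f, species = speciesLabels(dm), kind = "p")
    expect_equal(as.matrix(back), as.matrix(dm))
    # PHYLIP-style square
    f2 <- tempfile()
    v <- as.matrix(dm)
    con <- file(f2, "w")
    writeLines(as.character(nrow(v)), con)
    for (i in seq_len(nrow(v)))
        writeLines(paste(c(rownames(v)[i], format(v[i, ])),
                         collapse = " "), con)
    close(con)
    back2 <- readDistanceMatrix(f2, species = speciesLabels(dm),
                                kind = "p")
    expect_equal(as.matrix(back2), as.matrix(dm), tolerance = 1e-6)
})

test_that("custom models can be registered and used", {
    registerDistanceModel("twice_p", function(s) 2 * s$diffs / s$compared)
    expect_true("twice_p" %in% distanceModels())
    aln <- globalAlign("ACGT", "ACGA", ns)
    expect_equal(evolutionaryDistance(aln, "twice_p"), 0.5)
    expect_error(evolutionaryDistance(aln, "no_such"), "unknown distance")
})
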