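ns <- ncbiScheme()

test_that("worked examples under NCBI-default scoring", {
    expect_equal(alignmentScore(globalAlign("ACGT", "ACGT", ns)), 4)
    # one match minus a length-1 gap: 1 - (5 + 2)
    expect_equal(alignmentScore(globalAlign("A", "AG", ns)), -6)
    # three matches + one mismatch beat any gapped alternative
    expect_equal(alignmentScore(globalAlign("ACGT", "ACGA", ns)), 0)
    # "ACG" sits inside "TTACGTT" with free flanks
    sg <- semiglobalAlign("TTACGTT", "ACG", ns)
    expect_equal(alignmentScore(sg), 3)
    expect_identical(gsub("-", "", alignedSubject(sg)), "ACG")
    # local trims the trailing mismatch
    expect_equal(alignmentScore(localAlign("ACGT", "ACGA", ns)), 3)
    # all-mismatch pair: empty local alignment, score floored at 0
    la <- localAlign("AAAA", "TTTT", ns)
    expect_equal(alignmentScore(la), 0)
    expect_identical(alignedPattern(la), "")
    # identical sequences need no end gaps
    expect_equal(alignmentScore(semiglobalAlign("ACGT", "ACGT", ns)),
                 alignmentScore(globalAlign("ACGT", "ACGT", ns)))
})

test_that("dynamic programming equals exhaustive enumeration on random short pairs", {
    set.seed(42)
    schemes <- list(ns, ucscScheme())
    for (rep in 1:150) {
        a <- randSeq(sample(1:6, 1))
        b <- randSeq(sample(1:6, 1))
        for (sc in schemes) {
            scores <- vapply(c("global", "semiglobal", "local"),
                function(ty) {
                    dp <- switch(ty,
                        global = globalAlign(a, b, sc),
                        semiglobal = semiglobalAlign(a, b, sc),
                        local = localAlign(a, b, sc))
                    expect_equal(alignmentScore(dp),
                                 bruteForceAlignScore(a, b, sc, ty),
                                 info = paste(a, b, schemeName(sc), ty))
                    alignmentScore(dp)
                }, numeric(1))
            # relaxation ordering: local >= semiglobal >= global
            expect_true(scores["local"] >= scores["semiglobal"] - 1e-12)
            expect_true(scores["semiglobal"] >= scores["global"] - 1e-12)
        }
    }
})

test_that("scores are symmetric in the two sequences", {
    set.seed(7)
    for (rep in 1:25) {
        a <- randSeq(sample(3:20, 1))
        b <- randSeq(sample(3:20, 1))
        for (f in list(globalAlign, semiglobalAlign, localAlign))
            expect_equal(alignmentScore(f(a, b, ns)),
                         alignmentScore(f(b, a, ns)))
    }
})

test_that("self-alignment is gap-free with the sum of match scores", {
    set.seed(8)
    for (sc in list(ns, ucscScheme())) {
        a <- randSeq(30)
        aln <- globalAlign(a, a, sc)
        ch <- strsplit(a, "")[[1]]
        expect_equal(alignmentScore(aln),
                     sum(substitutionScores(sc)[cbind(ch, ch)]))
        expect_false(grepl("-", alignedPattern(aln), fixed = TRUE))
    }
})

test_that("aligner agrees with Biostrings::pairwiseAlignment", {
    set.seed(9)
    bioScore <- function(a, b, sc, type) {
        m <- substitutionScores(sc)
        Biostrings::pairwiseAlignment(
            a, b, substitutionMatrix = m, gapOpening = gapOpen(sc),
            gapExtension = gapExtend(sc), type = type, scoreOnly = TRUE)
    }
    for (rep in 1:40) {
        a <- randSeq(sample(8:40, 1))
        b <- randSeq(sample(8:40, 1))
        for (sc in list(ns, ucscScheme())) {
            expect_equal(alignmentScore(globalAlign(a, b, sc)),
                         bioScore(a, b, sc, "global"))
            expect_equal(alignmentScore(localAlign(a, b, sc)),
                         max(0, bioScore(a, b, sc, "local")))
            # semi-global = better of the two one-sided free-end variants
            expect_equal(alignmentScore(semiglobalAlign(a, b, sc)),
                         max(bioScore(b, a, sc, "global-local"),
                             bioScore(a, b, sc, "global-local")))
        }
    }
})

test_that("degapping an alignment recovers the inputs", {
    set.seed(10)
    for (rep in 1:20) {
        a <- randSeq(sample(5:30, 1))
        b <- randSeq(sample(5:30, 1))
        g <- globalAlign(a, b, ns)
        expect_identical(gsub("-", "", alignedPattern(g)), a)
        expect_identical(gsub("-", "", alignedSubject(g)), b)
        s <- semiglobalAlign(a, b, ns)
        expect_identical(gsub("-", "", alignedPattern(s)), a)
        expect_identical(gsub("-", "", alignedSubject(s)), b)
        # no column may be gapped in both rows
        cols <- cbind(strsplit(alignedPattern(g), "")[[1]],
                      strsplit(alignedSubject(g), "")[[1]])
        expect_false(any(cols[, 1] == "-" & cols[, 2] == "-"))
        l <- localAlign(a, b, ns)
        expect_true(grepl(gsub("-", "", alignedPattern(l)), a, fixed = TRUE))
        expect_true(grepl(gsub("-", "", alignedSubject(l)), b, fixed = TRUE))
    }
})

test_that("IUPAC ambiguity codes score as mismatches", {
    # N vs N and N vs A both take the mismatch score
    expect_equal(alignmentScore(globalAlign("AN", "AN", ns)), 1 - 3)
    expect_equal(alignmentScore(globalAlign("N", "A", ns)), -3)
    # under a matrix scheme ambiguity pairs take the matrix minimum
    expect_equal(alignmentScore(globalAlign("N", "A", ucscScheme())),
                 min(substitutionScores(ucscScheme())))
})

test_that("re-scoring a fixed alignment reproduces the optimal score", {
    set.seed(12)
    for (rep in 1:10) {
        a <- randSeq(sample(5:25, 1))
        b <- randSeq(sample(5:25, 1))
        g <- globalAlign(a, b, ns)
        expect_equal(scoreAlignment(g, ns), alignmentScore(g))
    }
})

test_that("scoring schemes load from YAML config files", {
    f <- tempfile(fileext = ".yaml")
    writeLines(c("name: custom", "match: 2", "mismatch: -1",
                 "gap_open: 3", "gap_extend: 1"), f)
    sc <- readScoringScheme(f)
    expect_identical(schemeName(sc), "custom")
    expect_equal(alignmentScore(globalAlign("ACGT", "ACGT", sc)), 8)
    f2 <- tempfile(fileext = ".yaml")
    writeLines(c("name: mat", "gap_open: 4", "gap_extend: 2",
                 "substitution:",
                 "  A: {A: 5, C: -4, G: -4, T: -4}",
                 "  C: {A: -4, C: 5, G: -4, T: -4}",
                 "  G: {A: -4, C: -4, G: 5, T: -4}",
                 "  T: {A: -4, C: -4, G: -4, T: 5}"), f2)
    sc2 <- readScoringScheme(f2)
    expect_equal(substitutionScores(sc2)["A", "A"], 5)
    expect_error(readScoringScheme(tempfile()), "no such scheme")
})
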