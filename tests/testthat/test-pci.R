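test_that("Wilson interval matches the score-test inversion in stats::prop.test", {
    set.seed(41)
    for (rep in 1:50) {
        n <- sample(1:200, 1)
        k <- sample(0:n, 1)
        w <- wilsonInterval(k, n)
        ref <- suppressWarnings(
            stats::prop.test(k, n, correct = FALSE))$conf.int
        expect_equal(unname(w["low"]), ref[1], tolerance = 1e-9)
        expect_equal(unname(w["high"]), ref[2], tolerance = 1e-9)
        expect_equal(unname(w["halfWidth"]), (ref[2] - ref[1]) / 2,
                     tolerance = 1e-9)
    }
})

test_that("Wilson interval boundary behavior and input checks", {
    w0 <- wilsonInterval(0, 10)
    expect_equal(unname(w0["low"]), 0)
    expect_true(w0["high"] < 1)
    wn <- wilsonInterval(10, 10)
    expect_equal(unname(wn["high"]), 1)
    expect_true(wn["low"] > 0)
    expect_error(wilsonInterval(1, 0), "positive")
    expect_error(wilsonInterval(5, 3), "0, n")
    expect_error(wilsonInterval(1, 10, confidence = 1.2), "confidence")
})

test_that("species gap rule: strict inequality, ties fail, decoys count as neighbors", {
    # species X close pair, far neighbor
    v <- matrix(0.10, 3, 3)
    v[1, 2] <- v[2, 1] <- 0.01
    diag(v) <- 0
    dm <- makeDistanceMatrix(v, c("X a", "X a", "Y b"))
    g <- speciesGap(dm, "X a")
    expect_equal(g$max_intra, 0.01)
    expect_equal(g$min_inter, 0.10)
    expect_true(g$has_gap)
    # tie: max_intra == min_inter fails
    v2 <- matrix(0.05, 3, 3); diag(v2) <- 0
    dm2 <- makeDistanceMatrix(v2, c("X a", "X a", "Y b"))
    expect_false(speciesGap(dm2, "X a")$has_gap)
    # the singleton decoy itself is not assessable
    expect_error(speciesGap(dm, "Y b"), "decoys")
    expect_error(speciesGap(dm, "Z c"), "not present")
})

test_that("hand-written 6x6 matrix matches exhaustive pair enumeration", {
    v <- matrix(c(
        0.00, 0.02, 0.20, 0.30, 0.25, 0.28,
        0.02, 0.00, 0.21, 0.31, 0.26, 0.29,
        0.20, 0.21, 0.00, 0.15, 0.24, 0.27,
        0.30, 0.31, 0.15, 0.00, 0.23, 0.22,
        0.25, 0.26, 0.24, 0.23, 0.00, 0.40,
        0.28, 0.29, 0.27, 0.22, 0.40, 0.00), 6, 6)
    sp <- c("A a", "A a", "B b", "B b", "C c", "C c")
    dm <- makeDistanceMatrix(v, sp)
    gaps <- speciesGaps(dm)
    # A: max_intra .02 < min_inter .20 -> gap
    # B: max_intra .15 < min_inter .20? inter of B = {.20,.21,.30,.31,.24,.27,.23,.22} min .20 -> gap
    # C: max_intra .40 > min_inter .22 -> no gap
    expect_identical(gaps$has_gap, c(TRUE, TRUE, FALSE))
    expect_equal(gaps$max_intra, c(0.02, 0.15, 0.40))
    expect_equal(gaps$min_inter, c(0.20, 0.20, 0.22))
})

test_that("gap outcomes agree with a brute-force scan on random matrices", {
    set.seed(43)
    for (rep in 1:15) {
        m <- sample(6:20, 1)
        sp <- sample(paste("Sp", letters[1:5]), m, replace = TRUE)
        v <- matrix(0, m, m)
        v[upper.tri(v)] <- round(runif(m * (m - 1) / 2, 0, 0.5), 3)
        v <- v + t(v)
        dm <- makeDistanceMatrix(v, sp)
        gaps <- speciesGaps(dm)
        for (r in seq_len(nrow(gaps))) {
            idx <- which(sp == gaps$species[r])
            intra <- inter <- c()
            for (i in seq_len(m)) for (j in seq_len(m)) {
                if (i >= j) next
                if (i %in% idx && j %in% idx) intra <- c(intra, v[i, j])
                else if (xor(i %in% idx, j %in% idx))
                    inter <- c(inter, v[i, j])
            }
            expect_equal(gaps$max_intra[r], max(intra))
            expect_equal(gaps$min_inter[r], min(inter))
            expect_identical(gaps$has_gap[r], max(intra) < min(inter))
        }
    }
})

test_that("saturated distances extend the strict rule consistently", {
    # nearest non-member at Inf: gap iff max_intra finite
    v <- matrix(Inf, 3, 3); diag(v) <- 0
    v[1, 2] <- v[2, 1] <- 0.1
    dm <- makeDistanceMatrix(v, c("X a", "X a", "Y b"))
    expect_true(speciesGap(dm, "X a")$has_gap)
    v[1, 2] <- v[2, 1] <- Inf   # Inf < Inf is false
    dm2 <- makeDistanceMatrix(v, c("X a", "X a", "Y b"))
    expect_false(speciesGap(dm2, "X a")$has_gap)
})

test_that("PCI arithmetic and boundary cases", {
    expect_equal(pci(blockMatrix(c(3, 3, 1), 0.01, 0.3))@estimate, 1)
    s <- pci(blockMatrix(c(3, 3), 0.3, 0.3))   # ties fail everywhere
    expect_equal(s@estimate, 0)
    expect_gte(s@confLow, 0)
    expect_lte(s@confHigh, 1)
})

test_that("adding a decoy can only shrink min_inter, so PCI never rises", {
    set.seed(44)
    for (rep in 1:10) {
        m <- 12
        sp <- rep(paste("Sp", 1:4), each = 3)
        v <- matrix(0, m, m)
        v[upper.tri(v)] <- runif(m * (m - 1) / 2, 0, 0.5)
        v <- v + t(v)
        dm <- makeDistanceMatrix(v, sp)
        before <- speciesGaps(dm)
        # append one singleton decoy with random distances
        v2 <- rbind(cbind(v, runif(m, 0, 0.5)), 0)
        v2[m + 1, ] <- v2[, m + 1]
        v2[m + 1, m + 1] <- 0
        dm2 <- makeDistanceMatrix(v2, c(sp, "Decoy x"))
        after <- speciesGaps(dm2)
        expect_identical(before$species, after$species)
        expect_true(all(after$min_inter <= before$min_inter))
        expect_lte(pci(dm2)@estimate, pci(dm)@estimate)
    }
})

test_that("PCI is invariant under strictly increasing transforms of finite distances", {
    set.seed(45)
    for (rep in 1:10) {
        m <- 14
        sp <- sample(paste("Sp", 1:5), m, replace = TRUE)
        v <- matrix(0, m, m)
        v[upper.tri(v)] <- runif(m * (m - 1) / 2, 0, 0.6)
        v <- v + t(v)
        v[1, 2] <- v[2, 1] <- Inf   # keep a saturated pair in play
        dm <- makeDistanceMatrix(v, sp)
        w <- v
        fin <- is.finite(w)
        w[fin] <- exp(w[fin]) + 3 * w[fin]   # strictly increasing
        diag(w) <- 0
        dmT <- makeDistanceMatrix(w, sp)
        expect_identical(speciesGaps(dm)$has_gap, speciesGaps(dmT)$has_gap)
    }
})

test_that("PciSummary prints the conventional two-decimal summary line", {
    s <- barcodeGap:::.pciFromCounts(13, 35)
    expect_output(show(s), "PCI = 0.37\\+-0.15 \\(13/35 species")
})

test_that("the PCI grid shares gap counts across evolutionary kinds", {
    set.seed(46)
    sim <- simulateDataset(simulationParams(
        nSpecies = 5, samplesPerSpecies = 3, lengthRange = c(150, 250),
        seed = 46))
    cfg <- analysisConfig(alignmentTypes = c("global", "semiglobal",
                                             "local"),
                          schemes = list(ncbiScheme()),
                          distanceKinds = c("p", "jc69", "alignment_score"))
    grid <- pciTable(sim$dataset, cfg, details = TRUE)
    expect_identical(nrow(grid$summary), 9L)
    for (ty in unique(grid$summary$alignment_type)) {
        sub <- grid$summary[grid$summary$alignment_type == ty, ]
        expect_equal(sub$k[sub$distance_kind == "p"],
                     sub$k[sub$distance_kind == "jc69"])
        expect_equal(sub$n[sub$distance_kind == "p"],
                     sub$n[sub$distance_kind == "jc69"])
    }
    expect_true(all(c("species", "max_intra", "min_inter", "has_gap")
                    %in% colnames(grid$species)))
    # an unknown kind or a missing MSA is rejected up front
    expect_error(pciTable(sim$dataset,
        analysisConfig(distanceKinds = "nope")), "unknown distance")
    expect_error(pciTable(sim$dataset,
        analysisConfig(alignmentTypes = "msa_implied",
                       distanceKinds = "p")), "MsaBlock")
})
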