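#' Parameters for the ITS-like dataset simulator
#'
#' The defaults emulate the structure of a mixed barcode survey of the
#' Annulohypoxylon/Hypoxylon ITS marker: around 35 species with 1--30
#' samples each (many singleton "decoy" species), ancestral sequence
#' lengths between 384 and 936 bp, modest within-species divergence,
#' strong between-species divergence, occasional indels, and (optionally,
#' on by default) one nominal species split into two cryptic lineages that
#' differ by a long insertion, producing a bimodal length distribution
#' within one label.
#'
#' @param nSpecies Number of species.
#' @param samplesPerSpecies Either a single integer (every species gets
#'   that many samples) or a list with elements \code{singletonProb}
#'   (probability a species is a singleton decoy), \code{meanExtra} (mean
#'   of the geometric number of samples beyond the first for
#'   non-singletons) and \code{max} (cap on samples per species).
#' @param lengthRange Ancestral sequence length range in bp.
#' @param intraRate Expected substitutions per site between a sample and
#'   its species ancestor.
#' @param interRate Expected substitutions per site between a species
#'   ancestor and the shared root; must be >= \code{intraRate}, and both
#'   below 0.75.
#' @param indelRate Indel events per site (applied at both the species and
#'   the sample level).
#' @param indelMeanLength Mean indel length in bp (geometric).
#' @param kappa Transition/transversion weight for substitutions; 1 gives
#'   uniform (Jukes-Cantor-like) replacement, larger values make K2P and
#'   p-distance diverge.
#' @param crypticPair Emulate a cryptic species pair?  \code{TRUE} splits
#'   the first multi-sample species into a short and a long lineage
#'   differing by an insertion of \code{insertLength} bp; or a list with
#'   elements \code{insertLength} and \code{at} (insertion position).
#' @param genbankFraction Probability that a record is flagged
#'   \code{source = "genbank"} rather than \code{"local"}.
#' @param expertDisagreeFraction Probability that a species is flagged
#'   \code{expert_agreement = "disagree"}.
#' @param seed Integer seed; the simulation is fully reproducible given
#'   the seed (same seed, byte-identical output).
#' @return A validated parameter list of class \code{"SimulationParams"}.
#' @seealso \code{\link{simulateDataset}}
#' @export
simulationParams <- function(nSpecies = 35,
                             samplesPerSpecies = list(singletonProb = 0.42,
                                                      meanExtra = 6,
                                                      max = 30),
                             lengthRange = c(384, 936),
                             intraRate = 0.02,
                             interRate = 0.30,
                             indelRate = 0.005,
                             indelMeanLength = 3,
                             kappa = 1,
                             crypticPair = TRUE,
                             genbankFraction = 0.5,
                             expertDisagreeFraction = 0.25,
                             seed = 1L) {
    if (length(nSpecies) != 1L || nSpecies < 1)
        bgStop("nSpecies must be a positive integer")
    if (intraRate < 0 || interRate < intraRate)
        bgStop("rates must satisfy 0 <= intraRate <= interRate")
    if (interRate >= 0.75)
        bgStop("substitution rates must be below 0.75")
    if (indelRate < 0 || indelRate >= 1)
        bgStop("indelRate must lie in [0, 1)")
    if (length(lengthRange) != 2L || lengthRange[1] < 1 ||
        lengthRange[2] < lengthRange[1])
        bgStop("lengthRange must be an increasing pair of lengths")
    if (isTRUE(crypticPair)) crypticPair <- list(insertLength = 390L,
                                                 at = 100L)
    structure(list(nSpecies = as.integer(nSpecies),
                   samplesPerSpecies = samplesPerSpecies,
                   lengthRange = as.integer(lengthRange),
                   intraRate = intraRate, interRate = interRate,
                   indelRate = indelRate,
                   indelMeanLength = indelMeanLength, kappa = kappa,
                   crypticPair = crypticPair,
                   genbankFraction = genbankFraction,
                   expertDisagreeFraction = expertDisagreeFraction,
                   seed = as.integer(seed)),
              class = "SimulationParams")
}

#' Mutate a DNA sequence
#'
#' Each site is substituted independently with probability \code{subRate}
#' by a base drawn from the three alternatives (transitions weighted by
#' \code{kappa}), so the expected Hamming fraction at retained sites
#' equals \code{subRate}.  Indel events then strike at rate
#' \code{indelRate} per site, each inserting or deleting (equal odds) a
#' geometric number of bases with mean \code{indelMeanLength}.  Uses the
#' R random number stream; seed the stream (or call through
#' \code{\link{simulateDataset}}) for reproducibility.
#'
#' @param seq A DNA string over \code{A,C,G,T}.
#' @param subRate Substitution probability per site, in [0, 1].
#' @param indelRate Indel events per site, in [0, 1).
#' @param kappa Transition/transversion weight (1 = uniform).
#' @param indelMeanLength Mean indel length.
#' @return The mutated DNA string (never empty).
#' @examples
#' set.seed(1)
#' mutateSequence("ACGTACGT", 0.5, 0)
#' @export
mutateSequence <- function(seq, subRate, indelRate = 0, kappa = 1,
                           indelMeanLength = 3) {
    .assertScalarString(seq, "seq")
    if (subRate < 0 || subRate > 1) bgStop("subRate must lie in [0, 1]")
    if (indelRate < 0 || indelRate >= 1)
        bgStop("indelRate must lie in [0, 1)")
    x <- strsplit(seq, "", fixed = TRUE)[[1]]
    L <- length(x)
    hit <- which(stats::runif(L) < subRate & x %in% c("A", "C", "G", "T"))
    if (length(hit)) {
        transition <- c(A = "G", G = "A", C = "T", T = "C")
        for (i in hit) {
            alt <- setdiff(c("A", "C", "G", "T"), x[i])
            w <- ifelse(alt == transition[[x[i]]], kappa, 1)
            x[i] <- sample(alt, 1L, prob = w)
        }
    }
    if (indelRate > 0) {
        nEv <- stats::rbinom(1L, length(x), indelRate)
        if (nEv > 0) {
            pos <- sort(sample(length(x), nEv))
            for (p in rev(pos)) {      # right to left keeps positions valid
                len <- 1L + stats::rgeom(1L, 1 / indelMeanLength)
                if (stats::runif(1L) < 0.5) {
                    ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
                    x <- append(x, ins, after = p)
                } else {
                    drop <- p:min(p + len - 1L, length(x))
                    if (length(drop) < length(x)) x <- x[-drop]
                }
            }
        }
    }
    paste(x, collapse = "")
}

.randomSeq <- function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

.drawSampleCounts <- function(spec, nSpecies) {
    if (is.numeric(spec) && length(spec) == 1L)
        return(rep(as.integer(spec), nSpecies))
    single <- stats::runif(nSpecies) < spec$singletonProb
    extra <- stats::rgeom(nSpecies, 1 / (1 + spec$meanExtra))
    counts <- ifelse(single, 1L, pmin(spec$max, 2L + extra))
    as.integer(counts)
}

#' Simulate an ITS-like barcode dataset with known truth
#'
#' Star-phylogeny generator: one random root sequence; each species
#' ancestor is a prefix of the root (drawn length within
#' \code{lengthRange}) mutated at \code{interRate}; each sample is the
#' species ancestor mutated at \code{intraRate}; indels strike at both
#' levels.  Everything is driven by a single seeded random stream, so a
#' fixed seed reproduces the dataset byte for byte.  Source and
#' expert-agreement flags are drawn per record and per species
#' respectively so that the partition and contingency machinery can be
#' exercised; re-assign them for specific designs.
#'
#' @param params A \code{\link{simulationParams}} object.
#' @return A list with elements \code{dataset} (a
#'   \linkS4class{BarcodeDataset}) and \code{truth} (a data.frame with one
#'   row per record: \code{sample_id}, \code{true_species},
#'   \code{lineage}, \code{ancestral_length}).
#' @examples
#' sim <- simulateDataset(simulationParams(nSpecies = 4,
#'     samplesPerSpecies = 3, seed = 42))
#' sim$dataset
#' @export
simulateDataset <- function(params) {
    if (!inherits(params, "SimulationParams"))
        params <- do.call(simulationParams, as.list(params))
    set.seed(params$seed)
    root <- .randomSeq(params$lengthRange[2])
    counts <- .drawSampleCounts(params$samplesPerSpecies, params$nSpecies)

    genus <- ifelse(seq_len(params$nSpecies) %% 2 == 0,
                    "Annulohypoxylon", "Hypoxylon")
    species <- sprintf("%s simulatum%02d", genus, seq_len(params$nSpecies))
    expert <- ifelse(stats::runif(params$nSpecies) <
                         params$expertDisagreeFraction,
                     "disagree", "agree")

    crypticIdx <- NA_integer_
    if (is.list(params$crypticPair)) {
        multi <- which(counts >= 2L)
        if (length(multi)) crypticIdx <- multi[1]
    }

    ids <- character(0); seqs <- character(0)
    md <- list(); truth <- list()
    rec <- 0L
    for (s in seq_len(params$nSpecies)) {
        L <- sample(params$lengthRange[1]:params$lengthRange[2], 1L)
        anc <- mutateSequence(substr(root, 1L, L), params$interRate,
                              params$indelRate, params$kappa,
                              params$indelMeanLength)
        ancLong <- NULL
        if (identical(s, crypticIdx)) {
            ins <- .randomSeq(params$crypticPair$insertLength)
            at <- min(params$crypticPair$at, nchar(anc))
            ancLong <- paste0(substr(anc, 1L, at), ins,
                              substr(anc, at + 1L, nchar(anc)))
        }
        for (k in seq_len(counts[s])) {
            rec <- rec + 1L
            lineage <- "A"
            base <- anc
            if (!is.null(ancLong) && k > counts[s] / 2) {
                base <- ancLong
                lineage <- "B"
            }
            seqs[rec] <- mutateSequence(base, params$intraRate,
                                        params$indelRate, params$kappa,
                                        params$indelMeanLength)
            ids[rec] <- sprintf("S%04d", rec)
            md[[rec]] <- data.frame(
                sample_id = ids[rec], species = species[s],
                genus = genus[s],
                source = if (stats::runif(1L) < params$genbankFraction)
                    "genbank" else "local",
                expert_agreement = expert[s],
                stringsAsFactors = FALSE)
            truth[[rec]] <- data.frame(
                sample_id = ids[rec], true_species = species[s],
                lineage = lineage, ancestral_length = nchar(base),
                stringsAsFactors = FALSE)
        }
    }
    dataset <- BarcodeDataset(stats::setNames(seqs, ids),
                              do.call(rbind, md))
    list(dataset = dataset, truth = do.call(rbind, truth))
}
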