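# direct binomial-coefficient enumeration of the two-sided Fisher exact
# p-value -- the independent reference for fisherExact2x2()
enumFisherP <- function(a, b, cc, d) {
    m <- a + b; n <- cc + d; k1 <- a + cc; N <- m + n
    if (m == 0 || n == 0 || k1 == 0 || k1 == N) return(1)
    supp <- max(0, k1 - n):min(k1, m)
    probs <- choose(m, supp) * choose(n, k1 - supp) / choose(N, k1)
    pObs <- choose(m, a) * choose(n, cc) / choose(N, k1)
    sum(probs[probs <= pObs * (1 + 1e-07)])
}

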