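# Shared fixtures, generated in code.

# build a GenotypeSet from strings: mkG(c(M1 = "A/B C/C", F1 = "A/A B/C"),
# loci = c("L1", "L2")); "?" encodes an unknown allele
mkG <- function(x, loci) {
  parse1 <- function(s) {
    calls <- strsplit(strsplit(s, " +")[[1]], "/", fixed = TRUE)
    stopifnot(length(calls) == length(loci))
    out <- do.call(cbind, calls)
    out[out == "?"] <- NA
    out
  }
  rows <- lapply(x, parse1)
  a1 <- do.call(rbind, lapply(rows, function(m) m[1L, ]))
  a2 <- do.call(rbind, lapply(rows, function(m) m[2L, ]))
  dimnames(a1) <- dimnames(a2) <- list(names(x), loci)
  GenotypeSet(a1, a2)
}

# build an AlleleFreqTable from a named list of named numeric vectors
mkF <- function(...) {
  new("AlleleFreqTable", freqs = list(...), source = "pooled")
}

# the synthetic default marker panel, shared across tests (14 loci,
# ~21 alleles/locus, mean He ~0.88)
defaultFreqs <- genAlleleFreqs(synthConfig(), seed = 101)

# independent moment oracle (direct formula evaluation)
oracleMoments <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  c(mean = m,
    variance = sum((v - m)^2) / (n - 1),
    skewness = (sum((v - m)^3) / n) / (sum((v - m)^2) / n)^1.5)
}
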