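# Independent oracles, coded directly from the defining formulas and kept
# free of the package's own counting machinery.

ACGT <- c("A", "C", "G", "T")

# Proportion of differing sites among columns where both sequences carry
# an unambiguous base (pairwise deletion), from per-site loops.
oracle_p_distance <- function(a, b) {
  ok <- a %in% ACGT & b %in% ACGT
  sum(a[ok] != b[ok]) / sum(ok)
}

# Line-by-line TN93 closed form: purine-transition proportion P1,
# pyrimidine-transition proportion P2, transversion proportion Q, base
# frequencies supplied externally (pooled over the alignment).
oracle_tn93 <- function(a, b, freqs) {
  ok <- a %in% ACGT & b %in% ACGT
  aa <- a[ok]; bb <- b[ok]
  n <- sum(ok)
  P1 <- sum((aa == "A" & bb == "G") | (aa == "G" & bb == "A")) / n
  P2 <- sum((aa == "C" & bb == "T") | (aa == "T" & bb == "C")) / n
  Q <- sum(aa != bb) / n - P1 - P2
  gA <- freqs["A"]; gC <- freqs["C"]; gG <- freqs["G"]; gT <- freqs["T"]
  gR <- gA + gG
  gY <- gC + gT
  term1 <- -(2 * gA * gG / gR) * log(1 - gR / (2 * gA * gG) * P1 -
                                       Q / (2 * gR))
  term2 <- -(2 * gT * gC / gY) * log(1 - gY / (2 * gT * gC) * P2 -
                                       Q / (2 * gY))
  term3 <- -2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY) *
    log(1 - Q / (2 * gR * gY))
  unname(term1 + term2 + term3)
}

# Kimura 2-parameter closed form (the TN93 limit under equal base
# frequencies with equal transition rates).
oracle_k80 <- function(P, Q) {
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

# Pearson correlation written out from sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}

# Random alignment descended from a common ancestor, optionally with
# ambiguity codes and gaps.
rand_alignment <- function(n = 8, L = 60, sub_rate = 0.05, amb_rate = 0,
                           gap_rate = 0, locus = "rand") {
  root <- sample(ACGT, L, replace = TRUE)
  m <- t(vapply(seq_len(n), function(i) {
    s <- root
    hit <- which(runif(L) < sub_rate)
    s[hit] <- sample(ACGT, length(hit), replace = TRUE)
    if (amb_rate > 0) {
      hit <- which(runif(L) < amb_rate)
      s[hit] <- sample(c("N", "R", "Y", "W"), length(hit), replace = TRUE)
    }
    if (gap_rate > 0) {
      hit <- which(runif(L) < gap_rate)
      s[hit] <- "-"
    }
    s
  }, character(L)))
  rownames(m) <- sprintf("t%02d", seq_len(n))
  locus_alignment(m, locus)
}

# Small labelled symmetric matrix from random points (Euclidean), a valid
# distance matrix for Mantel/PCoA tests.
rand_euclid_dm <- function(n = 10, dim = 2, level = "trait",
                           labels = sprintf("u%02d", seq_len(n))) {
  pts <- matrix(rnorm(n * dim), n)
  dist_matrix(as.matrix(dist(pts)), labels, level)
}
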