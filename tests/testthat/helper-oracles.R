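# Brute-force oracles that loop over individual allele observations.
# Deliberately naive re-implementations, kept independent of the package's
# vectorised code paths.

# expand counts into a vector of allele labels
.alleles_of <- function(n_a, n_b) c(rep("A", n_a), rep("B", n_b))

# probability that two draws with replacement differ, by full enumeration
oracle_pi <- function(n_a, n_b) {
  al <- .alleles_of(n_a, n_b)
  n <- length(al)
  if (n == 0) return(NA_real_)
  diff_pairs <- 0L
  for (i in seq_len(n)) for (j in seq_len(n))
    if (al[i] != al[j]) diff_pairs <- diff_pairs + 1L
  diff_pairs / (n * n)
}

# per-site F_ST by looping over subpopulations; counts is a list of
# c(n_a, n_b) per subpopulation
oracle_fst <- function(counts) {
  num <- 0
  den_w <- 0
  pooled <- c(0L, 0L)
  for (cc in counts) {
    n_j <- sum(cc)
    pi_j <- oracle_pi(cc[1L], cc[2L])
    num <- num + n_j^2 * pi_j
    den_w <- den_w + n_j^2
    pooled <- pooled + cc
  }
  pi_pooled <- oracle_pi(pooled[1L], pooled[2L])
  if (is.na(pi_pooled) || pi_pooled == 0) return(NA_real_)
  1 - num / (pi_pooled * den_w)
}

# realized per-site differentiation from latent subpopulation frequencies,
# using population diversities 2 f (1 - f) and allele-count weights
oracle_fst_from_freqs <- function(f1, f2, n1, n2) {
  pi1 <- 2 * f1 * (1 - f1)
  pi2 <- 2 * f2 * (1 - f2)
  fbar <- (n1 * f1 + n2 * f2) / (n1 + n2)
  pip <- 2 * fbar * (1 - fbar)
  ifelse(pip > 0, 1 - (n1^2 * pi1 + n2^2 * pi2) / (pip * (n1^2 + n2^2)), NA_real_)
}
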