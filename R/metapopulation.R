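# Forward-time multi-deme Wright-Fisher simulator with migration driven by a
# dispersal/connectivity matrix. Used for the end-to-end seascape experiment
# (gene flow proportional to simulated larval connectivity) and for
# calibration fixtures where migration, not splits, structures the data.

#' Simulate a metapopulation with gene flow proportional to connectivity
#'
#' Allele frequencies at independent biallelic-like loci drift forward in
#' time in `n` demes of size `Ne`, exchanging migrants according to a
#' migration matrix derived from the supplied connectivity matrix: off-
#' diagonal migration rates are `m_scale` times the (row-normalised)
#' connectivity, the remainder staying home. After `generations` of
#' drift-migration, diploid genotypes are sampled from each deme's
#' frequencies under Hardy-Weinberg.
#'
#' @param C connectivity [matrix_table()] or plain square matrix (rows =
#'   source demes); entries are per-generation dispersal probabilities.
#' @param Ne diploid deme size.
#' @param generations drift generations from the common ancestral pool.
#' @param n_loci independent loci to simulate.
#' @param n_alleles allelic states per locus (initial frequencies from
#'   normalised exponentials, i.e. a flat Dirichlet).
#' @param m_scale multiplier on the off-diagonal connectivity entries
#'   (migration is `m_scale * C[i, j]`, capped so a deme keeps at least 10%
#'   of its gene pool each generation).
#' @param sample_size diploid individuals sampled per deme.
#' @return A [genotype_table()] with one population per deme.
#' @export
simulate_metapopulation <- function(C, Ne = 500, generations = 50,
                                    n_loci = 8, n_alleles = 4,
                                    m_scale = 1, sample_size = 30) {
  m <- if (inherits(C, "matrix_table")) C$mat else as.matrix(C)
  n <- nrow(m)
  labs <- rownames(m)
  if (is.null(labs)) labs <- paste0("D", seq_len(n))
  M <- m_scale * m
  diag(M) <- 0
  rs <- rowSums(M)
  over <- rs > 0.9
  if (any(over)) M[over, ] <- M[over, ] * 0.9 / rs[over]
  diag(M) <- 1 - rowSums(M)
  # frequencies: demes x alleles per locus
  a1 <- matrix(NA_integer_, n * sample_size, n_loci)
  a2 <- matrix(NA_integer_, n * sample_size, n_loci)
  for (l in seq_len(n_loci)) {
    p0 <- rexp(n_alleles); p0 <- p0 / sum(p0)
    P <- matrix(rep(p0, each = n), n, n_alleles)
    for (g in seq_len(generations)) {
      P <- M %*% P                       # migration (backward-rate form)
      for (i in seq_len(n)) {
        draw <- rmultinom(1, 2 * Ne, P[i, ])
        P[i, ] <- draw / (2 * Ne)        # drift
      }
    }
    for (i in seq_len(n)) {
      rows <- (i - 1) * sample_size + seq_len(sample_size)
      g1 <- sample.int(n_alleles, sample_size, replace = TRUE, prob = P[i, ])
      g2 <- sample.int(n_alleles, sample_size, replace = TRUE, prob = P[i, ])
      a1[rows, l] <- 100L + 2L * pmin(g1, g2)
      a2[rows, l] <- 100L + 2L * pmax(g1, g2)
    }
  }
  pop <- rep(labs, each = sample_size)
  genotype_table(paste0(pop, "_", rep(seq_len(sample_size), n)), pop,
                 paste0("locus", seq_len(n_loci)), a1, a2)
}

#' Pairwise theta matrix over all populations
#'
#' Convenience wrapper computing Weir-Cockerham theta for every population
#' pair (no permutations).
#'
#' @param genotypes a [genotype_table()].
#' @return A symmetric [matrix_table()].
#' @export
pairwise_theta <- function(genotypes) {
  pops <- unique(genotypes$population)
  th <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)[-length(pops)]) for (j in (i + 1):length(pops)) {
    v <- theta_from_table(genotypes, pops[c(i, j)])
    th[i, j] <- th[j, i] <- if (is.na(v)) 0 else v
  }
  matrix_table(th, symmetric = TRUE)
}
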