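# shared fixture builders (everything generated in code; no stored data)

# small alignment with explicit sequences
make_alignment <- function(seqs, pops, ids = NULL) {
  if (is.null(ids)) ids <- paste0("s", seq_along(seqs))
  seq_alignment(ids, pops, seqs)
}

# random alignment: n sequences of length L mutated from one ancestor
random_alignment <- function(n, L, n_pops = 2, mut_prob = 0.05) {
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    s <- anc
    k <- rbinom(1, L, mut_prob)
    if (k > 0) {
      pos <- sample.int(L, k)
      s[pos] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    }
    paste(s, collapse = "")
  }, character(1))
  make_alignment(seqs, rep(paste0("P", seq_len(n_pops)), length.out = n))
}

# diploid genotypes drawn under HWE from given allele frequencies
hwe_genotypes <- function(n, freqs, pops = "P", loci = "L1") {
  n_loci <- length(loci)
  alleles <- 100 + seq_along(freqs)
  a1 <- matrix(NA_integer_, n * length(pops), n_loci)
  a2 <- matrix(NA_integer_, n * length(pops), n_loci)
  for (l in seq_len(n_loci)) {
    g1 <- sample(alleles, n * length(pops), replace = TRUE, prob = freqs)
    g2 <- sample(alleles, n * length(pops), replace = TRUE, prob = freqs)
    a1[, l] <- pmin(g1, g2); a2[, l] <- pmax(g1, g2)
  }
  pop <- rep(pops, each = n)
  genotype_table(paste0(pop, "_", seq_len(n * length(pops))), pop, loci,
                 a1, a2)
}

# all-water velocity field with constant (u0, v0) everywhere
constant_field <- function(u0, v0, nx = 80, ny = 20, dx_km = 5,
                           t_end_h = 24 * 40, habitat = NULL) {
  if (is.null(habitat))
    habitat <- list(A = c(3 + (4:5) * nx))
  structure(list(nx = nx, ny = ny, dx_km = dx_km, times = c(0, t_end_h),
                 u = array(u0, c(nx, ny, 2)), v = array(v0, c(nx, ny, 2)),
                 mask = matrix(TRUE, nx, ny),
                 depth = matrix(50, nx, ny), habitat = habitat,
                 max_habitat_depth = 100),
            class = "velocity_field")
}
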