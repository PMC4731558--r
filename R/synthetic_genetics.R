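# Coalescent sequence and microsatellite simulators used both as the
# synthetic-data generator and as the simulation engine for ABC, neutrality
# test p-values and the bottleneck test.

#' Simulation parameters for the synthetic-data generators
#'
#' @param mu_seq mtDNA mutation rate per site per generation.
#' @param tn93_freqs base frequencies (A, C, G, T); default mildly AT-rich as
#'   typical of arthropod mitochondrial COI.
#' @param kappa1,kappa2 purine (A<->G) and pyrimidine (C<->T) transition /
#'   transversion rate ratios of the TN93 model.
#' @param alpha_sim gamma shape for among-site rate heterogeneity
#'   (`Inf` disables it).
#' @param mu_ms microsatellite mutation rate per locus per generation.
#' @param p_gsm geometric parameter of the generalised stepwise mutation
#'   model; step size k has `P(k) = p(1-p)^(k-1)`, so `p_gsm = 1` is the
#'   strict single-step model.
#' @param msat_bound reflecting bound (repeat units) on allele-size drift away
#'   from the ancestral size.
#' @param ancestral_size ancestral allele size in repeat units.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(mu_seq = 5e-7,
                       tn93_freqs = c(A = 0.3, C = 0.15, G = 0.2, T = 0.35),
                       kappa1 = 6, kappa2 = 6, alpha_sim = 0.5,
                       mu_ms = 5e-4, p_gsm = 0.78, msat_bound = 40,
                       ancestral_size = 100) {
  stopifnot(mu_seq >= 0, mu_ms >= 0, p_gsm > 0, p_gsm <= 1,
            all(tn93_freqs > 0), alpha_sim > 0, msat_bound > 0)
  tn93_freqs <- tn93_freqs / sum(tn93_freqs)
  names(tn93_freqs) <- c("A", "C", "G", "T")
  structure(list(mu_seq = mu_seq, tn93_freqs = tn93_freqs, kappa1 = kappa1,
                 kappa2 = kappa2, alpha_sim = alpha_sim, mu_ms = mu_ms,
                 p_gsm = p_gsm, msat_bound = msat_bound,
                 ancestral_size = ancestral_size),
            class = "sim_params")
}

# TN93 conditional replacement probabilities: P(new base | mutation at a site
# currently in base b), proportional to the off-diagonal entries of the TN93
# rate matrix Q[b, .] with Q[b,j] = freq_j * (kappa1 for A<->G, kappa2 for
# C<->T, 1 otherwise).
tn93_replacement_matrix <- function(freqs, kappa1, kappa2) {
  bases <- c("A", "C", "G", "T")
  M <- matrix(0, 4, 4, dimnames = list(bases, bases))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    k <- 1
    if ((bases[i] == "A" && bases[j] == "G") ||
        (bases[i] == "G" && bases[j] == "A")) k <- kappa1
    if ((bases[i] == "C" && bases[j] == "T") ||
        (bases[i] == "T" && bases[j] == "C")) k <- kappa2
    M[i, j] <- k * freqs[j]
  }
  M / rowSums(M)
}

#' Simulate aligned sequences under a demographic scenario
#'
#' Generates one coalescent genealogy under `scenario` and drops mutations on
#' it under TN93 with gamma rate heterogeneity across sites: each site gets a
#' relative rate multiplier drawn once from Gamma(alpha, alpha); mutation
#' events occur along a branch of length `t` as Poisson with mean
#' `mu_seq * t * sum(site rates)`, hit sites proportionally to their rate, and
#' replace the current base using the TN93 exchange probabilities.
#'
#' @param scen a [scenario()].
#' @param params a [sim_params()].
#' @param sample_sizes named integer vector: sequences sampled per population.
#' @param L alignment length (bp).
#' @param size_changes optional data frame (`time`, `pop`, `ne`) of
#'   piecewise-constant size changes (looking backwards from the present).
#' @return A [seq_alignment()].
#' @export
simulate_sequences <- function(scen, params, sample_sizes, L,
                               size_changes = NULL) {
  stopifnot(L > 0)
  g <- sim_genealogy(sample_sizes, scen, size_changes)
  rel <- if (is.finite(params$alpha_sim)) {
    rgamma(L, shape = params$alpha_sim, rate = params$alpha_sim)
  } else rep(1, L)
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, L, replace = TRUE, prob = params$tn93_freqs)
  repl <- tn93_replacement_matrix(params$tn93_freqs, params$kappa1,
                                  params$kappa2)
  # store per-node sparse differences from the ancestral sequence; parents
  # have higher node indices, so a descending sweep visits parents first
  diffs <- vector("list", max(2 * g$n_tips - 1, 1))
  diffs[[g$root]] <- list(pos = integer(0), base = character(0))
  tot_rate <- sum(rel)
  for (v in seq(2 * g$n_tips - 2, 1)) {
    if (g$n_tips == 1) break
    d <- diffs[[g$parent[v]]]
    nmut <- rpois(1, params$mu_seq * g$length[v] * tot_rate)
    if (nmut > 0) {
      pos <- sample.int(L, nmut, replace = TRUE, prob = rel)
      cur_pos <- d$pos; cur_base <- d$base
      for (s in pos) {
        i <- match(s, cur_pos)
        old <- if (is.na(i)) anc[s] else cur_base[i]
        new <- sample(bases, 1, prob = repl[old, ])
        if (is.na(i)) { cur_pos <- c(cur_pos, s); cur_base <- c(cur_base, new) }
        else cur_base[i] <- new
      }
      d <- list(pos = cur_pos, base = cur_base)
    }
    diffs[[v]] <- d
  }
  out <- character(g$n_tips)
  for (i in seq_len(g$n_tips)) {
    s <- anc
    d <- diffs[[i]]
    if (length(d$pos)) s[d$pos] <- d$base
    out[i] <- paste(s, collapse = "")
  }
  ids <- paste0(g$tip_pop, "_", stats::ave(seq_len(g$n_tips), g$tip_pop,
                                           FUN = seq_along))
  seq_alignment(ids, g$tip_pop, out)
}

# simulate one locus of gene-copy allele sizes on a genealogy (GSM);
# parents have higher node indices, so a single descending sweep suffices
sim_msat_copies <- function(g, params) {
  nn <- 2 * g$n_tips - 1
  size <- numeric(nn)
  b <- params$msat_bound
  if (g$n_tips == 1) return(params$ancestral_size)
  nmut <- rpois(nn - 1, params$mu_ms * g$length[seq_len(nn - 1)])
  total <- sum(nmut)
  all_steps <- if (total > 0) {
    (rgeom(total, params$p_gsm) + 1L) *
      ifelse(runif(total) < 0.5, -1L, 1L)
  } else integer(0)
  pos <- 0L
  for (v in seq(nn - 1, 1)) {
    x <- size[g$parent[v]]
    if (nmut[v] > 0) {
      for (s in all_steps[pos + seq_len(nmut[v])]) {
        x <- x + s
        if (x > b) x <- 2 * b - x
        if (x < -b) x <- -2 * b - x
      }
      pos <- pos + nmut[v]
    }
    size[v] <- x
  }
  params$ancestral_size + size[seq_len(g$n_tips)]
}

#' Simulate diploid microsatellite genotypes under a demographic scenario
#'
#' Allele sizes evolve on independent coalescent genealogies (one per locus)
#' under the generalised stepwise mutation model: mutation counts are Poisson
#' along branches and each mutation moves the allele by `k` repeat units up or
#' down, `k` geometric with parameter `p_gsm`. Sizes reflect at
#' `ancestral_size +- msat_bound`. Two gene copies per individual are sampled
#' within each population and paired at random.
#'
#' @inheritParams simulate_sequences
#' @param n_loci number of loci.
#' @return A [genotype_table()].
#' @export
simulate_microsatellites <- function(scen, params, sample_sizes, n_loci = 4,
                                     size_changes = NULL) {
  copies <- 2L * sample_sizes
  n_ind <- sum(sample_sizes)
  a1 <- matrix(NA_integer_, n_ind, n_loci)
  a2 <- matrix(NA_integer_, n_ind, n_loci)
  pop_of_ind <- rep(names(sample_sizes), times = sample_sizes)
  for (l in seq_len(n_loci)) {
    g <- sim_genealogy(copies, scen, size_changes)
    sz <- sim_msat_copies(g, params)
    # pair consecutive gene copies within each population into individuals
    row0 <- 0L
    for (p in names(sample_sizes)) {
      idx <- which(g$tip_pop == p)
      idx <- sample(idx)                       # random pairing
      np <- sample_sizes[[p]]
      x1 <- sz[idx[seq_len(np) * 2 - 1]]
      x2 <- sz[idx[seq_len(np) * 2]]
      a1[row0 + seq_len(np), l] <- pmin(x1, x2)
      a2[row0 + seq_len(np), l] <- pmax(x1, x2)
      row0 <- row0 + np
    }
  }
  ids <- paste0(pop_of_ind, "_", stats::ave(seq_len(n_ind), pop_of_ind,
                                            FUN = seq_along))
  genotype_table(ids, pop_of_ind, paste0("locus", seq_len(n_loci)), a1, a2)
}

#' Mask genotypes with null alleles
#'
#' Each gene copy is independently relabelled "null" with the per-locus,
#' per-population probability `r`. A heterozygote with one null copy appears
#' homozygous for its visible allele; a genotype with two null copies appears
#' missing. No new visible alleles are ever created.
#'
#' @param genotypes a [genotype_table()].
#' @param r_table numeric matrix (populations x loci, dimnames required) or a
#'   single number applied everywhere; values in `[0, 1)`.
#' @return A masked [genotype_table()].
#' @export
apply_null_alleles <- function(genotypes, r_table) {
  pops <- unique(genotypes$population)
  loci <- genotypes$loci
  if (length(r_table) == 1) {
    r_table <- matrix(r_table, length(pops), length(loci),
                      dimnames = list(pops, loci))
  }
  if (any(r_table < 0) || any(r_table >= 1))
    stop("null-allele frequencies must be in [0, 1)")
  a1 <- genotypes$a1; a2 <- genotypes$a2
  for (i in seq_along(genotypes$ids)) {
    p <- genotypes$population[i]
    for (l in seq_along(loci)) {
      if (is.na(a1[i, l])) next
      r <- r_table[p, loci[l]]
      if (r == 0) next
      null1 <- runif(1) < r
      null2 <- runif(1) < r
      if (null1 && null2) { a1[i, l] <- NA; a2[i, l] <- NA }
      else if (null1) a1[i, l] <- a2[i, l]
      else if (null2) a2[i, l] <- a1[i, l]
    }
  }
  genotype_table(genotypes$ids, genotypes$population, loci, a1, a2)
}

#' Mask genotypes with lineage-linked (genetic) null alleles
#'
#' Unlike [apply_null_alleles()], which hides each gene copy independently,
#' this operation emulates the genetic origin of null alleles: a primer-site
#' mutation carried by particular allelic lineages. Per locus, random allele
#' classes are designated null until their pooled frequency reaches
#' approximately `r`; every copy of a null class then fails to amplify, so
#' null-class frequencies drift apart between populations like any other
#' allele. One visible copy leaves an apparent homozygote; two null copies
#' leave a missing genotype.
#'
#' @param genotypes a [genotype_table()].
#' @param r target pooled null-allele frequency per locus.
#' @return A list: `genotypes` (masked table) and `null_classes` (per-locus
#'   integer vectors of the masked allele values).
#' @export
apply_null_lineages <- function(genotypes, r = 0.4) {
  stopifnot(r >= 0, r < 1)
  a1 <- genotypes$a1; a2 <- genotypes$a2
  null_classes <- vector("list", length(genotypes$loci))
  names(null_classes) <- genotypes$loci
  for (l in seq_along(genotypes$loci)) {
    copies <- c(a1[, l], a2[, l])
    copies <- copies[!is.na(copies)]
    tab <- table(copies)
    freqs <- as.numeric(tab) / length(copies)
    vals <- as.numeric(names(tab))
    ord <- sample(length(vals))
    cum <- cumsum(freqs[ord])
    ns <- if (r == 0) numeric(0) else
      vals[ord[seq_len(which.min(abs(cum - r)))]]
    null_classes[[l]] <- ns
    n1 <- a1[, l] %in% ns; n2 <- a2[, l] %in% ns
    both <- n1 & n2; one1 <- n1 & !n2; one2 <- n2 & !n1
    a1[one1, l] <- a2[one1, l]
    a2[one2, l] <- a1[one2, l]
    a1[both, l] <- NA; a2[both, l] <- NA
  }
  list(genotypes = genotype_table(genotypes$ids, genotypes$population,
                                  genotypes$loci, a1, a2),
       null_classes = null_classes)
}
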