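# Microsatellite statistics: diversity, Hardy-Weinberg and linkage tests,
# rarefied allelic richness, EM null-allele estimation, Weir-Cockerham theta
# with and without the ENA null-allele correction, and the TPM bottleneck
# heterozygosity-excess test.

# allele counts (gene copies) at one locus within one population
allele_counts <- function(genotypes, locus, population) {
  rows <- genotypes$population == population
  a <- c(genotypes$a1[rows, locus], genotypes$a2[rows, locus])
  a <- a[!is.na(a)]
  table(a)
}

#' Per-locus, per-population diversity statistics
#'
#' Expected heterozygosity is Nei's unbiased estimator
#' `He = (2n/(2n-1)) (1 - sum p_a^2)`; `Ho` is the observed heterozygote
#' fraction; `F_IS = 1 - Ho/He` (undefined at monomorphic loci).
#'
#' @param genotypes a [genotype_table()].
#' @return A data frame with one row per locus x population: `locus`, `pop`,
#'   `N` (genotyped individuals), `Na` (alleles), `Ho`, `He`, `Fis`.
#' @export
locus_pop_stats <- function(genotypes) {
  pops <- unique(genotypes$population)
  out <- expand.grid(locus = genotypes$loci, pop = pops,
                     stringsAsFactors = FALSE)
  out$N <- NA_integer_; out$Na <- NA_integer_
  out$Ho <- NA_real_; out$He <- NA_real_; out$Fis <- NA_real_
  for (r in seq_len(nrow(out))) {
    l <- out$locus[r]; p <- out$pop[r]
    rows <- genotypes$population == p & !is.na(genotypes$a1[, l])
    n <- sum(rows)
    out$N[r] <- n
    if (n == 0) next
    a1 <- genotypes$a1[rows, l]; a2 <- genotypes$a2[rows, l]
    cnt <- table(c(a1, a2))
    pr <- cnt / sum(cnt)
    out$Na[r] <- length(cnt)
    out$Ho[r] <- mean(a1 != a2)
    he <- if (n > 1) 2 * n / (2 * n - 1) * (1 - sum(pr^2)) else NA_real_
    out$He[r] <- if (length(cnt) == 1) 0 else he
    out$Fis[r] <- if (length(cnt) == 1 || is.na(he) || he == 0) NA_real_
                  else 1 - out$Ho[r] / he
  }
  out
}

# F_IS statistic used by the permutation HWE test (NA -> 0 for monomorphic)
fis_stat <- function(a1, a2) {
  n <- length(a1)
  cnt <- table(c(a1, a2))
  if (length(cnt) < 2) return(NA_real_)
  pr <- cnt / sum(cnt)
  he <- 2 * n / (2 * n - 1) * (1 - sum(pr^2))
  1 - mean(a1 != a2) / he
}

#' Permutation test of Hardy-Weinberg equilibrium
#'
#' Gene copies are shuffled into new diploid genotypes (preserving allele
#' counts) and `F_IS` recomputed; reported are the two-sided p
#' (`|F*| >= |F|`) and the one-sided heterozygote-deficit p (`F* >= F`),
#' both with the `(b+1)/(m+1)` correction.
#'
#' @param genotypes a [genotype_table()].
#' @param locus locus name.
#' @param population population label.
#' @param n_perm permutations.
#' @return A list: `fis`, `p_two`, `p_deficit`, `n`.
#' @export
hwe_test <- function(genotypes, locus, population, n_perm = 1000) {
  rows <- genotypes$population == population & !is.na(genotypes$a1[, locus])
  n <- sum(rows)
  if (n < 5) stop("need >= 5 non-missing genotypes")
  a1 <- genotypes$a1[rows, locus]; a2 <- genotypes$a2[rows, locus]
  obs <- fis_stat(a1, a2)
  if (is.na(obs)) return(list(fis = NA_real_, p_two = 1, p_deficit = 1, n = n))
  copies <- c(a1, a2)
  b_two <- 0L; b_def <- 0L
  for (r in seq_len(n_perm)) {
    s <- sample(copies)
    f <- fis_stat(s[1:n], s[(n + 1):(2 * n)])
    if (is.na(f)) f <- 0
    if (abs(f) >= abs(obs)) b_two <- b_two + 1L
    if (f >= obs) b_def <- b_def + 1L
  }
  list(fis = obs, p_two = (b_two + 1) / (n_perm + 1),
       p_deficit = (b_def + 1) / (n_perm + 1), n = n)
}

# log-likelihood G of a two-way contingency table
g_statistic <- function(tab) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  idx <- tab > 0
  2 * sum(tab[idx] * log(tab[idx] / E[idx]))
}

#' Permutation test of genotypic linkage disequilibrium
#'
#' Association between the genotypes at two loci, summed over populations:
#' the statistic is the log-likelihood-ratio G of the genotype x genotype
#' contingency table (per population), and the null distribution comes from
#' shuffling the second locus's genotypes among individuals within each
#' population.
#'
#' @param genotypes a [genotype_table()].
#' @param locus_pair character vector of two locus names.
#' @param n_perm permutations.
#' @return A list: `G`, `p`.
#' @export
ld_test <- function(genotypes, locus_pair, n_perm = 1000) {
  l1 <- locus_pair[1]; l2 <- locus_pair[2]
  keep <- !is.na(genotypes$a1[, l1]) & !is.na(genotypes$a1[, l2])
  if (sum(keep) < 5) stop("need >= 5 individuals genotyped at both loci")
  pop <- genotypes$population[keep]
  g1 <- paste(genotypes$a1[keep, l1], genotypes$a2[keep, l1], sep = "/")
  g2 <- paste(genotypes$a1[keep, l2], genotypes$a2[keep, l2], sep = "/")
  per_pop_g <- function(gg2) {
    tot <- 0
    for (p in unique(pop)) {
      tab <- table(g1[pop == p], gg2[pop == p])
      if (nrow(tab) > 1 && ncol(tab) > 1) tot <- tot + g_statistic(tab)
    }
    tot
  }
  obs <- per_pop_g(g2)
  if (obs == 0) return(list(G = 0, p = 1))
  b <- 0L
  for (r in seq_len(n_perm)) {
    g2p <- g2
    for (p in unique(pop)) {
      idx <- which(pop == p)
      g2p[idx] <- g2[sample(idx)]
    }
    if (per_pop_g(g2p) >= obs) b <- b + 1L
  }
  list(G = obs, p = (b + 1) / (n_perm + 1))
}

#' Rarefied allelic richness
#'
#' Expected number of alleles in a subsample of `g` gene copies:
#' `Ar(g) = sum_a [1 - C(Ng - N_a, g) / C(Ng, g)]` with `Ng` sampled gene
#' copies and `N_a` copies of allele `a` (the standard hypergeometric
#' rarefaction estimator).
#'
#' @param genotypes a [genotype_table()].
#' @param g rarefaction size in gene copies (default 34, i.e. 17 diploids).
#' @return A data frame: `locus`, `pop`, `Ng`, `Ar`.
#' @export
allelic_richness <- function(genotypes, g = 34) {
  pops <- unique(genotypes$population)
  out <- expand.grid(locus = genotypes$loci, pop = pops,
                     stringsAsFactors = FALSE)
  out$Ng <- NA_integer_; out$Ar <- NA_real_
  for (r in seq_len(nrow(out))) {
    cnt <- allele_counts(genotypes, out$locus[r], out$pop[r])
    Ng <- sum(cnt)
    out$Ng[r] <- Ng
    if (Ng < g)
      stop("rarefaction size ", g, " exceeds the ", Ng,
           " gene copies of population ", out$pop[r], " at locus ",
           out$locus[r])
    out$Ar[r] <- sum(1 - exp(lchoose(Ng - as.numeric(cnt), g) - lchoose(Ng, g)))
  }
  out
}

#' EM estimation of null-allele frequency
#'
#' Expectation-maximisation under Hardy-Weinberg with one null-allele class
#' and a genotyping-failure probability (blanks are a mixture of null
#' homozygotes and technical failures). Observed homozygotes are apportioned
#' between true homozygotes and visible/null heterozygotes; blanks between
#' null homozygotes and failures; frequencies (including the null) are
#' re-estimated until convergence.
#'
#' @param genotypes a [genotype_table()].
#' @param locus locus name.
#' @param population population label.
#' @param tol convergence tolerance on the frequency updates.
#' @param max_iter iteration cap.
#' @param estimate_failures estimate a separate technical-failure probability
#'   (`beta`) alongside the null class (default). With `FALSE` every blank is
#'   attributed to a null homozygote, the variant used inside the ENA
#'   correction where a free failure rate is confounded with frequent nulls.
#' @return A list: `r` (null-allele frequency), `beta` (failure probability),
#'   `freqs` (visible-allele frequencies, summing with `r` to 1),
#'   `converged`, `iterations`.
#' @export
null_allele_em <- function(genotypes, locus, population, tol = 1e-8,
                           max_iter = 2000, estimate_failures = TRUE) {
  rows <- which(genotypes$population == population)
  a1 <- genotypes$a1[rows, locus]; a2 <- genotypes$a2[rows, locus]
  n_tot <- length(rows)
  miss <- is.na(a1)
  n_blank <- sum(miss)
  if (n_blank == n_tot) stop("all observations missing at ", locus, " in ",
                             population)
  a1 <- a1[!miss]; a2 <- a2[!miss]
  if (length(a1) < 5) stop("need >= 5 non-missing genotypes")
  alleles <- sort(unique(c(a1, a2)))
  k <- length(alleles)
  het <- a1 != a2
  hom_allele <- a1[!het]
  p <- rep((1 - 0.1) / k, k); names(p) <- alleles
  r <- 0.1; beta <- 0.01
  it <- 0L; converged <- FALSE
  het_counts <- table(factor(c(a1[het], a2[het]), levels = alleles))
  hom_counts <- table(factor(hom_allele, levels = alleles))
  while (it < max_iter) {
    it <- it + 1L
    # E-step
    copies <- as.numeric(het_counts)            # hets: both copies visible
    w_hom <- p[as.character(alleles)] / (p[as.character(alleles)] + 2 * r)
    copies <- copies + as.numeric(hom_counts) * (1 + w_hom)
    null_copies <- sum(as.numeric(hom_counts) * (1 - w_hom))
    if (estimate_failures) {
      denom <- beta + (1 - beta) * r^2
      pr_blank_null <- if (denom > 0) (1 - beta) * r^2 / denom else 0
      e_null_hom <- if (n_blank > 0) n_blank * pr_blank_null else 0
    } else {
      e_null_hom <- n_blank
    }
    e_fail <- n_blank - e_null_hom
    null_copies <- null_copies + 2 * e_null_hom
    # M-step
    n_eff <- n_tot - e_fail
    tot <- 2 * n_eff
    p_new <- copies / tot
    r_new <- null_copies / tot
    beta_new <- if (estimate_failures) min(max(e_fail / n_tot, 0), 0.999)
                else 0
    delta <- max(abs(c(p_new - p, r_new - r, beta_new - beta)))
    p <- p_new; r <- r_new; beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(r = unname(r), beta = beta, freqs = setNames(as.numeric(p), alleles),
       converged = converged, iterations = it)
}

#' Null-allele frequencies for every locus and population
#'
#' @param genotypes a [genotype_table()].
#' @param ... passed to [null_allele_em()].
#' @return A data frame: `locus`, `pop`, `r`, `converged`.
#' @export
null_allele_table <- function(genotypes, ...) {
  pops <- unique(genotypes$population)
  out <- expand.grid(locus = genotypes$loci, pop = pops,
                     stringsAsFactors = FALSE)
  out$r <- NA_real_; out$converged <- NA
  for (i in seq_len(nrow(out))) {
    fit <- tryCatch(null_allele_em(genotypes, out$locus[i], out$pop[i], ...),
                    error = function(e) NULL)
    if (!is.null(fit)) { out$r[i] <- fit$r; out$converged[i] <- fit$converged }
  }
  out
}

# summed WC components for all alleles of one locus given per-pop frequency
# and heterozygosity matrices (pops x alleles)
wc_locus_sums <- function(n_i, p_mat, h_mat) {
  r <- length(n_i)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- colSums(n_i * p_mat) / (r * nbar)
  s2 <- colSums(n_i * sweep(p_mat, 2, pbar)^2) / ((r - 1) * nbar)
  hbar <- colSums(n_i * h_mat) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(num = sum(a), den = sum(a + b + cc))
}

# genotype-based frequency/heterozygosity matrices for one locus
locus_freq_het <- function(genotypes, pops, l) {
  pop_all <- genotypes$population
  ok <- pop_all %in% pops & !is.na(genotypes$a1[, l])
  n_i <- vapply(pops, function(p) sum(ok & pop_all == p), numeric(1))
  if (any(n_i < 2)) return(NULL)
  x1 <- genotypes$a1[ok, l]; x2 <- genotypes$a2[ok, l]
  pp <- pop_all[ok]
  alleles <- sort(unique(c(x1, x2)))
  if (length(alleles) < 2) return(NULL)
  A <- length(alleles)
  p_mat <- matrix(0, length(pops), A)
  h_mat <- matrix(0, length(pops), A)
  for (k in seq_along(pops)) {
    sel <- pp == pops[k]
    y1 <- match(x1[sel], alleles); y2 <- match(x2[sel], alleles)
    p_mat[k, ] <- (tabulate(y1, A) + tabulate(y2, A)) / (2 * n_i[k])
    het <- y1 != y2
    h_mat[k, ] <- (tabulate(y1[het], A) + tabulate(y2[het], A)) / n_i[k]
  }
  list(n_i = n_i, p_mat = p_mat, h_mat = h_mat, alleles = alleles)
}

# multilocus theta from a genotype table restricted to given populations
theta_from_table <- function(genotypes, pops) {
  num <- 0; den <- 0
  for (l in genotypes$loci) {
    fh <- locus_freq_het(genotypes, pops, l)
    if (is.null(fh)) next
    s <- wc_locus_sums(fh$n_i, fh$p_mat, fh$h_mat)
    num <- num + s["num"]; den <- den + s["den"]
  }
  if (den == 0) return(NA_real_)
  unname(num / den)
}

#' Weir-Cockerham theta (F-ST) with permutation test
#'
#' Multi-locus, multi-allele theta: per-allele variance components summed
#' over alleles and loci, `theta = sum a / sum (a+b+c)`. Significance by
#' permuting individuals between the two populations.
#'
#' @param genotypes a [genotype_table()].
#' @param pair character vector of two population labels.
#' @param n_perm permutations (0 skips the test).
#' @return A list: `theta`, `p`.
#' @export
theta_fst <- function(genotypes, pair, n_perm = 1000) {
  obs <- theta_from_table(genotypes, pair)
  if (is.na(obs)) stop("no shared polymorphic loci between ",
                       paste(pair, collapse = " and "))
  p <- NA_real_
  if (n_perm > 0) {
    idx <- which(genotypes$population %in% pair)
    b <- 0L
    gt <- genotypes
    for (rp in seq_len(n_perm)) {
      gt$population[idx] <- sample(genotypes$population[idx])
      th <- theta_from_table(gt, pair)
      if (!is.na(th) && th >= obs) b <- b + 1L
    }
    p <- (b + 1) / (n_perm + 1)
  }
  list(theta = obs, p = p)
}

#' ENA-corrected theta
#'
#' Recomputes Weir-Cockerham theta treating the null allele as an additional
#' allelic state with its EM-estimated frequency: per population and locus
#' the visible allele frequencies are the EM estimates (which sum with `r`
#' to 1), and heterozygosity terms use their Hardy-Weinberg expectations
#' under the corrected frequencies (observed heterozygosity being itself
#' biased by the nulls). Reported alongside the uncorrected theta.
#'
#' @param genotypes a [genotype_table()].
#' @param null_estimates data frame from [null_allele_table()] (rows
#'   `locus`, `pop`, `r`); `NULL` to estimate internally.
#' @param pair character vector of two population labels.
#' @return A list: `theta_ena`, `theta_uncorrected`.
#' @export
theta_fst_ena <- function(genotypes, null_estimates = NULL, pair) {
  if (is.null(null_estimates)) null_estimates <- null_allele_table(genotypes)
  num <- 0; den <- 0
  for (l in genotypes$loci) {
    ests <- lapply(pair, function(p) {
      row <- null_estimates$locus == l & null_estimates$pop == p
      if (!any(row) || is.na(null_estimates$r[row][1])) NULL
      else tryCatch(null_allele_em(genotypes, l, p,
                                   estimate_failures = FALSE),
                    error = function(e) NULL)
    })
    if (any(vapply(ests, is.null, logical(1)))) {
      warning("missing null estimate at ", l, "; locus used uncorrected")
      ests <- NULL
    }
    r_max <- if (is.null(ests)) 0 else max(vapply(ests, `[[`, numeric(1), "r"))
    if (is.null(ests) || r_max < 1e-3) {
      # no appreciable nulls: genotype-based components as uncorrected
      fh <- locus_freq_het(genotypes, pair, l)
      if (is.null(fh)) next
      s <- wc_locus_sums(fh$n_i, fh$p_mat, fh$h_mat)
      num <- num + s["num"]; den <- den + s["den"]
      next
    }
    n_i <- vapply(pair, function(p)
      sum(genotypes$population == p & !is.na(genotypes$a1[, l])), numeric(1))
    if (any(n_i < 2)) next
    # null as an extra shared allelic state; EM frequencies sum with r to 1
    alleles <- sort(unique(unlist(lapply(ests, function(e)
      as.numeric(names(e$freqs))))))
    A <- length(alleles) + 1
    if (A < 2) next
    p_mat <- matrix(0, length(pair), A)
    for (k in seq_along(pair)) {
      v <- ests[[k]]$freqs[as.character(alleles)]
      v[is.na(v)] <- 0
      p_mat[k, ] <- c(unname(v), ests[[k]]$r)
    }
    h_mat <- 2 * p_mat * (1 - p_mat)   # HWE expectation under corrected freqs
    s <- wc_locus_sums(n_i, p_mat, h_mat)
    num <- num + s["num"]; den <- den + s["den"]
  }
  theta_ena <- if (den == 0) NA_real_ else unname(num / den)
  list(theta_ena = theta_ena,
       theta_uncorrected = theta_from_table(genotypes, pair))
}

# --- bottleneck heterozygosity-excess test ---------------------------------

# simulate allele sizes for n gene copies under the two-phase model at
# scaled mutation rate theta (coalescent units); returns the sample
sim_tpm_sample <- function(n, theta, p_smm, q_geom) {
  g <- sim_tree_topology(n)
  sizes <- rep(0L, n)
  muts <- rpois(length(g$len), theta / 2 * g$len)
  for (e in seq_along(muts)) {
    if (muts[e] == 0) next
    multi <- runif(muts[e]) > p_smm
    mag <- ifelse(multi, rgeom(muts[e], q_geom) + 1L, 1L)
    step <- sum(mag * sample(c(-1L, 1L), muts[e], replace = TRUE))
    sizes[g$tipsets[[e]]] <- sizes[g$tipsets[[e]]] + step
  }
  sizes
}

unbiased_het <- function(copies) {
  ng <- length(copies)
  pr <- table(copies) / ng
  ng / (ng - 1) * (1 - sum(pr^2))
}

#' Heterozygosity-excess bottleneck test (TPM)
#'
#' For each polymorphic locus in `population`, coalescent samples of the same
#' gene-copy count are simulated under the two-phase mutation model (a
#' fraction `p_smm` of mutations are single-step; the rest are multi-step
#' with geometrically distributed magnitude whose variance is `variance`);
#' the scaled mutation rate is tuned so the expected allele count matches the
#' observation, and simulations are retained only when the allele count
#' matches exactly, giving the mutation-drift equilibrium heterozygosity
#' (`Heq`) distribution. The one-tailed Wilcoxon signed-rank test across loci
#' on `He - mean(Heq)` detects heterozygosity excess (the bottleneck
#' signature); the deficit tail is also reported.
#'
#' @param genotypes a [genotype_table()].
#' @param population population label.
#' @param p_smm proportion of single-step mutations (default 0.8, the middle
#'   of the conventional 70-90% range).
#' @param variance variance of the multi-step change magnitude (default 20,
#'   middle of the conventional 10-30 range).
#' @param n_iter simulation iterations per locus.
#' @return A list with the per-locus table (`He`, `Heq_mean`, `Heq_sd`,
#'   `std_diff`), `p_excess`, `p_deficit` and the settings.
#' @export
bottleneck_test <- function(genotypes, population, p_smm = 0.8, variance = 20,
                            n_iter = 1000) {
  # geometric parameter from the stated multi-step variance:
  # magnitude ~ 1 + Geom(q); var = (1-q)/q^2 solved for q
  q_geom <- (-1 + sqrt(1 + 4 * variance)) / (2 * variance)
  rows <- genotypes$population == population
  loci_stats <- list()
  for (l in genotypes$loci) {
    a <- c(genotypes$a1[rows, l], genotypes$a2[rows, l])
    a <- a[!is.na(a)]
    k_obs <- length(unique(a))
    if (k_obs < 2) next
    n <- length(a)
    he <- unbiased_het(a)
    # tune theta so that E[#alleles] ~ k_obs (bisection on log-theta)
    lo <- -4; hi <- 6
    for (step in 1:12) {
      mid <- (lo + hi) / 2
      ks <- replicate(40, length(unique(sim_tpm_sample(n, exp(mid), p_smm,
                                                       q_geom))))
      if (mean(ks) < k_obs) lo <- mid else hi <- mid
    }
    theta <- exp((lo + hi) / 2)
    heq <- numeric(0)
    for (it in seq_len(n_iter)) {
      s <- sim_tpm_sample(n, theta, p_smm, q_geom)
      if (length(unique(s)) == k_obs) heq <- c(heq, unbiased_het(s))
    }
    if (length(heq) < 20) next         # conditioning failed; skip locus
    loci_stats[[l]] <- data.frame(
      locus = l, k = k_obs, He = he, Heq_mean = mean(heq),
      Heq_sd = sd(heq), std_diff = (he - mean(heq)) / sd(heq))
  }
  if (length(loci_stats) < 2)
    stop("need >= 2 usable polymorphic loci for the Wilcoxon test")
  tab <- do.call(rbind, loci_stats)
  d <- tab$He - tab$Heq_mean
  p_exc <- wilcox.test(d, alternative = "greater", exact = TRUE)$p.value
  p_def <- wilcox.test(d, alternative = "less", exact = TRUE)$p.value
  list(table = tab, p_excess = p_exc, p_deficit = p_def,
       p_smm = p_smm, variance = variance, n_iter = n_iter)
}
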