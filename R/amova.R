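# Analysis of molecular variance on squared molecular distances (Excoffier,
# Smouse & Quattro framework) and the derived fixation indices, with
# permutation significance.

# expand a haplotype table into per-individual haplotype indices + pop labels
hap_individuals <- function(haplotable, populations = NULL) {
  counts <- haplotable$counts
  if (!is.null(populations)) counts <- counts[, populations, drop = FALSE]
  hap <- integer(0); pop <- character(0)
  for (p in colnames(counts)) {
    for (h in which(counts[, p] > 0)) {
      hap <- c(hap, rep(h, counts[h, p]))
      pop <- c(pop, rep(p, counts[h, p]))
    }
  }
  list(hap = hap, pop = pop)
}

# two-level AMOVA variance components from a squared-distance matrix between
# individuals and a population factor
amova2_components <- function(D2, pop) {
  N <- length(pop)
  pops <- unique(pop)
  P <- length(pops)
  ss_total <- sum(D2) / (2 * N)
  ss_within <- 0
  n_p <- numeric(P)
  for (k in seq_len(P)) {
    idx <- which(pop == pops[k])
    n_p[k] <- length(idx)
    ss_within <- ss_within + sum(D2[idx, idx]) / (2 * n_p[k])
  }
  ss_among <- ss_total - ss_within
  df_a <- P - 1; df_w <- N - P
  sigma_w <- ss_within / df_w
  n_prime <- (N - sum(n_p^2) / N) / df_a
  sigma_a <- (ss_among / df_a - sigma_w) / n_prime
  list(ss_total = ss_total, ss_among = ss_among, ss_within = ss_within,
       sigma_a = sigma_a, sigma_w = sigma_w,
       phi_st = sigma_a / (sigma_a + sigma_w))
}

#' Pairwise Phi-ST with permutation tests
#'
#' For every population pair an AMOVA variance decomposition on squared model
#' distances between individual sequences yields
#' `Phi_ST = sigma2_among / (sigma2_among + sigma2_within)`; significance is
#' the proportion of permutations (individuals reshuffled between the two
#' populations) with a statistic at least as large, with the `(b+1)/(m+1)`
#' correction. Negative estimates are retained.
#'
#' @param haplotable a [collapse_haplotypes()] table.
#' @param model a [distance_model()]; distances enter squared.
#' @param n_perm number of permutations per pair.
#' @param populations optional subset/order of populations.
#' @return A [matrix_table()] with `mat` = Phi-ST and `p` = permutation
#'   p-values.
#' @export
pairwise_phist <- function(haplotable, model = distance_model("tn93", 0.023),
                           n_perm = 1000, populations = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  pops <- populations %||% colnames(haplotable$counts)
  if (length(pops) < 2) stop("need >= 2 populations")
  Dh <- haplotype_distances(haplotable, model)^2
  phi <- matrix(NA_real_, length(pops), length(pops),
                dimnames = list(pops, pops))
  pv <- phi
  diag(phi) <- 0; diag(pv) <- NA
  for (ia in 1:(length(pops) - 1)) for (ib in (ia + 1):length(pops)) {
    ind <- hap_individuals(haplotable, pops[c(ia, ib)])
    D2 <- Dh[ind$hap, ind$hap, drop = FALSE]
    obs <- amova2_components(D2, ind$pop)$phi_st
    b <- 0L
    labels <- ind$pop
    for (r in seq_len(n_perm)) {
      perm <- sample(labels)
      if (isTRUE(amova2_components(D2, perm)$phi_st >= obs)) b <- b + 1L
    }
    phi[ia, ib] <- phi[ib, ia] <- obs
    pv[ia, ib] <- pv[ib, ia] <- (b + 1) / (n_perm + 1)
  }
  matrix_table(phi, p = pv, symmetric = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hierarchical (three-level) AMOVA
#'
#' Decomposes molecular variance among groups of populations (`sigma2_a`),
#' among populations within groups (`sigma2_b`) and within populations
#' (`sigma2_c`), yielding `F_CT = sigma2_a / total`,
#' `F_SC = sigma2_b / (sigma2_b + sigma2_c)` and
#' `F_ST = (sigma2_a + sigma2_b) / total`. Significance by permutation:
#' whole populations among groups for `F_CT`, individuals among populations
#' within their group for `F_SC`, individuals among populations across the
#' whole sample for `F_ST`.
#'
#' @param haplotable a [collapse_haplotypes()] table.
#' @param groups named character vector mapping population label -> group
#'   label (must cover >= 2 groups).
#' @param model a [distance_model()].
#' @param n_perm permutations per test.
#' @return A list with the variance components, the three fixation indices
#'   and their permutation p-values.
#' @export
amova_hierarchical <- function(haplotable, groups,
                               model = distance_model("tn93", 0.023),
                               n_perm = 1000) {
  pops <- names(groups)
  if (length(unique(groups)) < 2) stop("need >= 2 groups")
  Dh <- haplotype_distances(haplotable, model)^2
  ind <- hap_individuals(haplotable, pops)
  D2 <- Dh[ind$hap, ind$hap, drop = FALSE]
  comp <- amova3_components(D2, ind$pop, groups)
  # F_CT: permute populations among groups (keeping group sizes)
  b_ct <- 0L
  for (r in seq_len(n_perm)) {
    g_perm <- setNames(sample(unname(groups)), names(groups))
    if (isTRUE(amova3_components(D2, ind$pop, g_perm)$f_ct >= comp$f_ct))
      b_ct <- b_ct + 1L
  }
  # F_SC: permute individuals among populations within groups
  b_sc <- 0L
  for (r in seq_len(n_perm)) {
    pop_perm <- ind$pop
    for (g in unique(groups)) {
      in_g <- which(groups[ind$pop] == g)
      pop_perm[in_g] <- sample(ind$pop[in_g])
    }
    if (isTRUE(amova3_components(D2, pop_perm, groups)$f_sc >= comp$f_sc))
      b_sc <- b_sc + 1L
  }
  # F_ST: permute individuals across the whole sample
  b_st <- 0L
  for (r in seq_len(n_perm)) {
    if (isTRUE(amova3_components(D2, sample(ind$pop), groups)$f_st >= comp$f_st))
      b_st <- b_st + 1L
  }
  c(comp, list(p_ct = (b_ct + 1) / (n_perm + 1),
               p_sc = (b_sc + 1) / (n_perm + 1),
               p_st = (b_st + 1) / (n_perm + 1)))
}

# three-level variance components (groups / populations / individuals)
amova3_components <- function(D2, pop, groups) {
  N <- length(pop)
  pops <- unique(pop)
  P <- length(pops)
  grp_of_pop <- groups[pops]
  grps <- unique(unname(grp_of_pop))
  G <- length(grps)
  ss_total <- sum(D2) / (2 * N)
  ss_wp <- 0; n_p <- setNames(numeric(P), pops)
  for (p in pops) {
    idx <- which(pop == p)
    n_p[p] <- length(idx)
    ss_wp <- ss_wp + sum(D2[idx, idx]) / (2 * n_p[p])
  }
  ss_wg <- 0; n_g <- setNames(numeric(G), grps)
  for (g in grps) {
    idx <- which(grp_of_pop[pop] == g)
    n_g[g] <- length(idx)
    ss_wg <- ss_wg + sum(D2[idx, idx]) / (2 * n_g[g])
  }
  ss_ag <- ss_total - ss_wg            # among groups
  ss_ap <- ss_wg - ss_wp               # among pops within groups
  df_ag <- G - 1; df_ap <- P - G; df_wp <- N - P
  sigma_c <- ss_wp / df_wp
  sum_np2_by_g <- vapply(grps, function(g) {
    sum(n_p[names(grp_of_pop)[grp_of_pop == g]]^2) / n_g[g]
  }, numeric(1))
  n1 <- (N - sum(sum_np2_by_g)) / df_ap
  n2 <- (sum(sum_np2_by_g) - sum(n_p^2) / N) / df_ag
  n3 <- (N - sum(n_g^2) / N) / df_ag
  sigma_b <- (ss_ap / df_ap - sigma_c) / n1
  sigma_a <- (ss_ag / df_ag - sigma_c - n2 * sigma_b) / n3
  sigma_a <- unname(sigma_a); sigma_b <- unname(sigma_b)
  total <- sigma_a + sigma_b + sigma_c
  list(ss_total = unname(ss_total), ss_among_groups = unname(ss_ag),
       ss_among_pops = unname(ss_ap), ss_within = unname(ss_wp),
       sigma_a = sigma_a, sigma_b = sigma_b, sigma_c = sigma_c,
       f_ct = sigma_a / total, f_sc = sigma_b / (sigma_b + sigma_c),
       f_st = (sigma_a + sigma_b) / total)
}
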