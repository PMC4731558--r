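# Demographic-expansion and neutrality machinery: sudden-expansion mismatch
# fit with parametric bootstrap, Tajima's D and Fu's Fs with coalescent
# significance, and the minimum spanning haplotype network.

# --- small coalescent helpers (single population) --------------------------

# neutral single-population genealogy on the coalescent time scale (units of
# 2N generations); per-branch lengths, subtree sizes and tip sets
sim_tree_topology <- function(n) {
  ids <- as.list(seq_len(n))
  birth <- numeric(n)
  t <- 0
  len <- numeric(2 * n - 2); size <- integer(2 * n - 2)
  tipsets <- vector("list", 2 * n - 2)
  m <- 0L
  while (length(ids) > 1) {
    kk <- length(ids)
    t <- t + rexp(1, kk * (kk - 1) / 2)
    pick <- sample.int(kk, 2)
    for (q in pick) {
      m <- m + 1L
      len[m] <- t - birth[q]
      tipsets[[m]] <- ids[[q]]
      size[m] <- length(ids[[q]])
    }
    merged <- c(ids[[pick[1]]], ids[[pick[2]]])
    ids[[pick[1]]] <- merged
    birth[pick[1]] <- t
    ids[[pick[2]]] <- NULL
    birth <- birth[-pick[2]]
  }
  list(len = len[seq_len(m)], size = size[seq_len(m)],
       tipsets = tipsets[seq_len(m)])
}

#' Tajima's D with coalescent significance
#'
#' `D = (pi - S/a1) / sqrt(e1*S + e2*S*(S-1))` with the standard Tajima
#' constants, where `pi` is the mean pairwise difference count and `S` the
#' number of segregating sites within the population. The p-value is the
#' lower-tail probability from neutral coalescent simulations conditional on
#' `n` and `S` (the `S` observed mutations are placed on simulated genealogies
#' proportionally to branch length).
#'
#' @param haplotable a [collapse_haplotypes()] table.
#' @param population population label, or `NULL` for the pooled sample.
#' @param n_sim number of coalescent simulations for the p-value (0 skips it).
#' @return A list: `D`, `p` (P(D* <= D)), `S`, `pi` (mean pairwise
#'   differences), `n`, `defined`.
#' @export
tajimas_d <- function(haplotable, population = NULL, n_sim = 1000) {
  counts <- if (is.null(population)) rowSums(haplotable$counts)
            else haplotable$counts[, population]
  n <- sum(counts)
  keep <- counts > 0
  seqs <- haplotable$seqs[keep]
  S <- count_segregating(seqs)
  pi_bar <- mean_pairwise_differences(haplotable, population)
  if (n < 4 || S == 0)
    return(list(D = NA_real_, p = NA_real_, S = S, pi = pi_bar, n = n,
                defined = FALSE))
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  D <- (pi_bar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  p <- NA_real_
  if (n_sim > 0) {
    b <- 0L
    for (r in seq_len(n_sim)) {
      tr <- sim_tree_topology(n)
      muts <- as.vector(rmultinom(1, S, prob = tr$len))
      k_bar <- sum(muts * tr$size * (n - tr$size)) / choose(n, 2)
      Ds <- (k_bar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
      if (Ds <= D) b <- b + 1L
    }
    p <- (b + 1) / (n_sim + 1)
  }
  list(D = D, p = p, S = S, pi = pi_bar, n = n, defined = TRUE)
}

count_segregating <- function(seqs) {
  if (length(seqs) < 2) return(0L)
  M <- do.call(rbind, strsplit(seqs, ""))
  sum(vapply(seq_len(ncol(M)), function(s) {
    obs <- unique(M[, s]); obs <- obs[obs %in% c("A", "C", "G", "T")]
    length(obs) > 1
  }, logical(1)))
}

# unsigned Stirling numbers of the first kind |s(n, k)| for k = 1..n
stirling1_row <- function(n) {
  row <- 1                              # n = 1: |s(1,1)| = 1
  if (n == 1) return(row)
  for (m in 2:n) {
    new <- numeric(m)
    new[1] <- (m - 1) * row[1]
    if (m > 2) new[2:(m - 1)] <- row[1:(m - 2)] + (m - 1) * row[2:(m - 1)]
    new[m] <- 1
    row <- new
  }
  row
}

#' Ewens distribution of the number of alleles
#'
#' `P(K = k | theta, n) = |s(n,k)| theta^k / (theta)_n` with unsigned Stirling
#' numbers of the first kind and the rising factorial `(theta)_n`.
#'
#' @param n sample size.
#' @param theta scaled mutation parameter.
#' @return Numeric vector of probabilities for `k = 1..n`.
#' @export
ewens_allele_probs <- function(n, theta) {
  stopifnot(n >= 1, theta > 0)
  s <- stirling1_row(n)
  logp <- log(s) + (1:n) * log(theta) -
    sum(log(theta + 0:(n - 1)))
  exp(logp)
}

#' Fu's Fs with coalescent significance
#'
#' `S' = P(K >= k_obs | theta_pi)` from the Ewens sampling formula with
#' `theta_pi` the mean pairwise difference count, and
#' `Fs = ln(S' / (1 - S'))`. The p-value is the proportion of neutral
#' coalescent simulations at `theta = theta_pi` with `Fs* <= Fs` (Fu's
#' convention: small/negative Fs indicates haplotype excess, the expansion
#' signature).
#'
#' @inheritParams tajimas_d
#' @return A list: `Fs` (`-Inf`/`Inf` sentinels possible), `p`, `k_obs`,
#'   `theta_pi`, `n`, `defined`.
#' @export
fus_fs <- function(haplotable, population = NULL, n_sim = 1000) {
  counts <- if (is.null(population)) rowSums(haplotable$counts)
            else haplotable$counts[, population]
  n <- sum(counts)
  k_obs <- sum(counts > 0)
  theta <- mean_pairwise_differences(haplotable, population)
  if (n < 2 || is.na(theta) || theta <= 0)
    return(list(Fs = NA_real_, p = NA_real_, k_obs = k_obs, theta_pi = theta,
                n = n, defined = FALSE))
  Sp <- sum(ewens_allele_probs(n, theta)[k_obs:n])
  Fs <- if (Sp >= 1) -Inf else if (Sp <= 0) Inf else log(Sp / (1 - Sp))
  # note: S' = 1 exactly when k_obs = 1 -> Fs = -Inf sentinel; we flip the
  # sentinel sign to +Inf there since k = 1 is the *least* star-like outcome
  if (k_obs == 1) Fs <- Inf
  p <- NA_real_
  if (n_sim > 0 && is.finite(Fs)) {
    b <- 0L
    for (r in seq_len(n_sim)) {
      sim <- sim_ewens_k(n, theta)
      Sp_s <- sum(ewens_allele_probs(n, sim$theta_hat)[sim$k:n])
      Fs_s <- if (Sp_s >= 1) Inf else log(Sp_s / (1 - Sp_s))
      if (Fs_s <= Fs) b <- b + 1L
    }
    p <- (b + 1) / (n_sim + 1)
  }
  list(Fs = Fs, p = p, k_obs = k_obs, theta_pi = theta, n = n,
       defined = TRUE)
}

# one neutral coalescent draw: infinite-sites mutations at rate theta/2 per
# lineage (coalescent time scale); returns the simulated haplotype count and
# pi estimate. Each mutated branch separates its subtree's tips from the
# rest, so the distinct mutation profiles give the haplotype classes.
sim_ewens_k <- function(n, theta) {
  g <- sim_tree_topology(n)
  mut_on <- rpois(length(g$len), theta / 2 * g$len)
  cls <- rep("", n)
  for (e in seq_along(g$len)) {
    if (mut_on[e] > 0)
      cls[g$tipsets[[e]]] <- paste0(cls[g$tipsets[[e]]], ",", e)
  }
  k <- length(unique(cls))
  theta_hat <- sum(mut_on * g$size * (n - g$size)) / choose(n, 2)
  if (theta_hat <= 0) theta_hat <- 1e-9
  list(k = k, theta_hat = theta_hat)
}

# --- sudden-expansion mismatch model ---------------------------------------

# equilibrium mismatch probabilities F_i(theta) = theta^i / (1+theta)^(i+1)
mismatch_equilibrium <- function(i, theta) {
  exp(i * log(theta) - (i + 1) * log1p(theta))
}

#' Expected mismatch distribution under sudden expansion
#'
#' The Rogers-Harpending model: a population at mutation-scaled size `theta0`
#' jumps to `theta1` at mutational time `tau` before present;
#' `F_i = F^eq_i(theta1) + exp(-tau (theta1+1)/theta1) *
#' sum_j (tau^j / j!) (F^eq_{i-j}(theta0) - F^eq_{i-j}(theta1))`.
#'
#' @param i vector of difference classes (0, 1, ...).
#' @param tau mutational time of the expansion.
#' @param theta0,theta1 pre-/post-expansion scaled sizes.
#' @return Expected relative frequencies.
#' @export
expected_mismatch <- function(i, tau, theta0, theta1) {
  th0 <- max(theta0, 1e-12); th1 <- max(theta1, 1e-12)
  vapply(i, function(ii) {
    jj <- 0:ii
    corr <- sum(exp(jj * log(max(tau, 1e-300)) - lgamma(jj + 1)) *
                  (mismatch_equilibrium(ii - jj, th0) -
                     mismatch_equilibrium(ii - jj, th1)))
    if (tau == 0) corr <- mismatch_equilibrium(ii, th0) -
        mismatch_equilibrium(ii, th1)
    mismatch_equilibrium(ii, th1) + exp(-tau * (th1 + 1) / th1) * corr
  }, numeric(1))
}

#' Fit the sudden-expansion model to a mismatch distribution
#'
#' Least-squares fit of `(tau, theta0, theta1)` to the expected
#' sudden-expansion mismatch curve, with `SSD` the sum of squared deviations
#' and Harpending's raggedness `R` of the observed histogram. `p(SSD)` and
#' `p(R)` come from a parametric bootstrap: coalescent samples of the same
#' size are simulated under the fitted two-epoch history, refitted, and the
#' proportion of simulated `SSD*` (resp. `R*`) at least as large as observed
#' is reported.
#'
#' @param histogram observed mismatch relative frequencies (classes from 0).
#' @param n sample size behind the histogram (needed for the bootstrap).
#' @param n_boot bootstrap replicates (0 skips p-values).
#' @return A list: `tau`, `theta0`, `theta1`, `SSD`, `raggedness`, `p_ssd`,
#'   `p_rag`, `converged`.
#' @export
fit_sudden_expansion <- function(histogram, n = NULL, n_boot = 0) {
  x <- as.numeric(histogram)
  if (sum(x > 0) < 1 || length(x) < 2)
    stop("histogram needs at least two difference classes")
  i <- seq_along(x) - 1
  mean_d <- sum(i * x)
  obj <- function(par) {
    tau <- exp(par[1]); th0 <- exp(par[2]); th1 <- exp(par[2]) + exp(par[3])
    sum((x - expected_mismatch(i, tau, th0, th1))^2)
  }
  start <- c(log(max(mean_d, 0.1)), log(0.5), log(50))
  fit <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  tau <- exp(fit$par[1]); th0 <- exp(fit$par[2])
  th1 <- exp(fit$par[2]) + exp(fit$par[3])
  out <- list(tau = tau, theta0 = th0, theta1 = th1, SSD = fit$value,
              raggedness = raggedness(x),
              p_ssd = NA_real_, p_rag = NA_real_,
              converged = fit$convergence == 0)
  if (n_boot > 0) {
    if (is.null(n)) stop("bootstrap requires the sample size n")
    b_ssd <- 0L; b_rag <- 0L
    for (r in seq_len(n_boot)) {
      h_sim <- sim_expansion_mismatch(n, tau, th0, th1)
      fit_s <- tryCatch(fit_sudden_expansion(h_sim, n = NULL, n_boot = 0),
                        error = function(e) NULL)
      if (is.null(fit_s)) next
      if (fit_s$SSD >= out$SSD) b_ssd <- b_ssd + 1L
      if (fit_s$raggedness >= out$raggedness) b_rag <- b_rag + 1L
    }
    out$p_ssd <- (b_ssd + 1) / (n_boot + 1)
    out$p_rag <- (b_rag + 1) / (n_boot + 1)
  }
  out
}

# simulate one mismatch histogram for n sequences under the two-epoch
# history (tau, theta0, theta1), infinite sites
sim_expansion_mismatch <- function(n, tau, theta0, theta1) {
  # time scale: coalescent units of the *current* population (theta1);
  # mutations at rate theta1/2 per lineage; expansion at tau/theta1 units,
  # ancestral size rescaled by theta0/theta1
  g <- sim_tree_topology_2epoch(n, t_switch = tau / theta1,
                                size_ratio = theta0 / theta1)
  mut_on <- rpois(length(g$len), theta1 / 2 * g$len)
  counts <- numeric(0)
  D <- matrix(0, n, n)
  for (e in seq_along(g$len)) {
    if (mut_on[e] == 0) next
    inset <- seq_len(n) %in% g$tipsets[[e]]
    D[inset, !inset] <- D[inset, !inset] + mut_on[e]
    D[!inset, inset] <- D[!inset, inset] + mut_on[e]
  }
  d <- D[upper.tri(D)]
  tab <- tabulate(d + 1, nbins = max(d) + 1)
  tab / length(d)
}

sim_tree_topology_2epoch <- function(n, t_switch, size_ratio) {
  ids <- as.list(seq_len(n))
  birth <- numeric(n)
  t <- 0
  len <- numeric(2 * n - 2); size <- integer(2 * n - 2)
  tipsets <- vector("list", 2 * n - 2)
  m <- 0L
  while (length(ids) > 1) {
    kk <- length(ids)
    rate <- kk * (kk - 1) / 2
    scale <- if (t >= t_switch) size_ratio else 1
    w <- rexp(1, rate / scale)
    if (t < t_switch && t + w > t_switch) {
      # restart the draw in the ancestral epoch (memorylessness)
      t <- t_switch
      next
    }
    t <- t + w
    pick <- sample.int(kk, 2)
    for (q in pick) {
      m <- m + 1L
      len[m] <- t - birth[q]
      tipsets[[m]] <- ids[[q]]
      size[m] <- length(ids[[q]])
    }
    merged <- c(ids[[pick[1]]], ids[[pick[2]]])
    ids[[pick[1]]] <- merged
    birth[pick[1]] <- t
    ids[[pick[2]]] <- NULL
    birth <- birth[-pick[2]]
  }
  list(len = len[seq_len(m)], size = size[seq_len(m)],
       tipsets = tipsets[seq_len(m)])
}

# --- minimum spanning haplotype network ------------------------------------

#' Minimum spanning tree over haplotypes
#'
#' Kruskal's algorithm on pairwise Hamming distances with a deterministic
#' tie-break: edges are taken in increasing order of (distance, lower index,
#' higher index), so repeated runs and input reorderings give the same tree
#' weight (and the same tree whenever weights are unique).
#'
#' @param haplotable a [collapse_haplotypes()] table.
#' @return A data frame of edges: `from`, `to` (haplotype labels), `steps`
#'   (mutational steps), with attribute `total_steps`.
#' @export
haplotype_mst <- function(haplotable) {
  H <- length(haplotable$seqs)
  if (H < 2) stop("need >= 2 haplotypes")
  D <- haplotype_distances(haplotable, distance_model("hamming"))
  prs <- which(upper.tri(D), arr.ind = TRUE)
  ord <- order(D[upper.tri(D)], prs[, 1], prs[, 2])
  parent <- seq_len(H)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  edges <- data.frame(from = character(0), to = character(0),
                      steps = numeric(0))
  labs <- rownames(haplotable$counts)
  for (e in ord) {
    i <- prs[e, 1]; j <- prs[e, 2]
    ri <- find(i); rj <- find(j)
    if (ri != rj) {
      parent[ri] <- rj
      edges <- rbind(edges, data.frame(from = labs[i], to = labs[j],
                                       steps = D[i, j]))
      if (nrow(edges) == H - 1) break
    }
  }
  attr(edges, "total_steps") <- sum(edges$steps)
  edges
}
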