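# Approximate Bayesian computation for invasion-scenario choice: uniform
# priors over demographic parameters, coalescent simulation of summary
# statistics, rejection, and weighted polychotomous logistic regression.

#' Uniform prior bounds for ABC simulations
#'
#' @param ne_bounds diploid effective-size bounds (default the sequence-run
#'   range 1e4-1e5; use 1e4-2e5 for microsatellite runs).
#' @param mu_seq_bounds sequence mutation-rate bounds (per site per
#'   generation).
#' @param mu_ms_bounds microsatellite mutation-rate bounds (per locus per
#'   generation).
#' @param t_bounds split-time bounds (generations).
#' @return A list of class `prior_set`.
#' @export
prior_set <- function(ne_bounds = c(1e4, 1e5),
                      mu_seq_bounds = c(1e-8, 1e-6),
                      mu_ms_bounds = c(1e-4, 1e-3),
                      t_bounds = c(10, 10000)) {
  for (b in list(ne_bounds, mu_seq_bounds, mu_ms_bounds, t_bounds))
    if (length(b) != 2 || b[1] > b[2]) stop("invalid prior bounds")
  structure(list(ne_bounds = ne_bounds, mu_seq_bounds = mu_seq_bounds,
                 mu_ms_bounds = mu_ms_bounds, t_bounds = t_bounds),
            class = "prior_set")
}

#' Define a scenario template (topology without parameter values)
#'
#' @param id scenario identifier.
#' @param populations population labels.
#' @param events data frame `derived`, `source` describing the introduction
#'   tree (forward in time each derived population buds off its source).
#' @return A list of class `scenario_template`.
#' @export
scenario_template <- function(id, populations, events) {
  events <- as.data.frame(events)
  structure(list(id = id, populations = as.character(populations),
                 events = events), class = "scenario_template")
}

#' Ship-with-package invasion scenario library
#'
#' Four global scenarios contrasting candidate native regions (Argentina,
#' Pacific US, Europe) with sequential-introduction chains, plus two regional
#' Baltic scenarios (colonisation south-to-north through the North Sea vs a
#' Ponto-Caspian origin of the northern Baltic). Population codes: AR
#' Argentina, PU Pacific US, JP Japan, BL Black Sea, CS Caspian Sea, FR
#' France, BA Baltic, SA Skagerrak, BAS/BAN southern/northern Baltic.
#'
#' @return A named list of [scenario_template()]s
#'   (`global1`..`global4`, `baltic1`, `baltic2`).
#' @export
invasion_scenarios <- function() {
  ev <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(derived = m[, 1], source = m[, 2])
  }
  glob <- c("AR", "PU", "JP", "BL", "CS", "FR", "BA")
  list(
    global1 = scenario_template("global1", glob, ev(
      "PU", "AR", "JP", "PU", "BL", "JP", "CS", "BL", "FR", "AR", "BA", "FR")),
    global2 = scenario_template("global2", glob, ev(
      "JP", "PU", "BL", "JP", "CS", "BL", "AR", "PU", "FR", "AR", "BA", "FR")),
    global3 = scenario_template("global3", glob, ev(
      "FR", "AR", "BA", "FR", "BL", "BA", "CS", "BL", "PU", "AR", "JP", "PU")),
    global4 = scenario_template("global4", glob, ev(
      "AR", "FR", "BA", "FR", "BL", "FR", "CS", "BL", "PU", "AR", "JP", "PU")),
    baltic1 = scenario_template("baltic1", c("SA", "CS", "BAS", "BAN"), ev(
      "CS", "SA", "BAS", "SA", "BAN", "BAS")),
    baltic2 = scenario_template("baltic2", c("SA", "CS", "BAS", "BAN"), ev(
      "CS", "SA", "BAS", "SA", "BAN", "CS")))
}

#' Draw one parameter set from the priors
#'
#' Independent uniform draws for every population's Ne, every event time and
#' the mutation rate; draws whose event times violate the scenario's
#' ancestry ordering (a population must exist before it can seed another) are
#' rejected and redrawn.
#'
#' @param template a [scenario_template()].
#' @param priors a [prior_set()].
#' @param marker `"COI"` or `"microsatellite"` (selects the mutation-rate
#'   prior).
#' @return A list: `ne` (named), `times` (named by derived population), `mu`.
#' @export
sample_prior <- function(template, priors, marker = c("COI", "microsatellite")) {
  marker <- match.arg(marker)
  mu_b <- if (marker == "COI") priors$mu_seq_bounds else priors$mu_ms_bounds
  ne <- setNames(runif(length(template$populations), priors$ne_bounds[1],
                       priors$ne_bounds[2]), template$populations)
  ev <- template$events
  attempts <- 0L
  repeat {
    times <- setNames(runif(nrow(ev), priors$t_bounds[1], priors$t_bounds[2]),
                      ev$derived)
    ok <- TRUE
    for (i in seq_len(nrow(ev))) {
      src <- ev$source[i]
      # ties allowed so degenerate (constant) priors remain drawable
      if (src %in% ev$derived && times[src] < times[ev$derived[i]]) {
        ok <- FALSE; break
      }
    }
    if (ok || nrow(ev) == 0) break
    attempts <- attempts + 1L
    if (attempts > 100000L)
      stop("could not draw event times consistent with the scenario ordering")
  }
  list(ne = ne, times = times,
       mu = runif(1, mu_b[1], mu_b[2]))
}

draw_to_scenario <- function(template, draw) {
  ev <- template$events
  ev$time <- unname(draw$times[ev$derived])
  scenario(template$populations, ev, draw$ne, id = template$id)
}

# summary statistics of a sequence alignment, fixed ordering
coi_summary <- function(alignment, pops) {
  ht <- collapse_haplotypes(alignment)
  counts <- ht$counts[, pops, drop = FALSE]
  D <- haplotype_distances(ht, distance_model("hamming"))
  within_k <- vapply(pops, function(p) {
    x <- mean_pairwise_differences(ht, p); if (is.na(x)) 0 else x
  }, numeric(1))
  nhap <- colSums(counts > 0)
  stats <- c(setNames(nhap, paste0("nhap_", pops)),
             setNames(within_k, paste0("pi_", pops)))
  for (i in 1:(length(pops) - 1)) for (j in (i + 1):length(pops)) {
    ci <- counts[, i]; cj <- counts[, j]
    ni <- sum(ci); nj <- sum(cj)
    between <- sum((ci %o% cj) * D) / (ni * nj)
    ind <- hap_individuals(ht, pops[c(i, j)])
    fst <- tryCatch({
      ph <- amova2_components(D[ind$hap, ind$hap, drop = FALSE]^2, ind$pop)$phi_st
      if (is.finite(ph)) ph else 0
    }, error = function(e) 0)
    stats <- c(stats,
               setNames(fst, paste0("fst_", pops[i], "_", pops[j])),
               setNames(between, paste0("dxy_", pops[i], "_", pops[j])))
  }
  stats
}

# summary statistics of a genotype table, fixed ordering
msat_summary <- function(genotypes, pops) {
  lp <- locus_pop_stats(genotypes)
  mean_na <- vapply(pops, function(p)
    mean(lp$Na[lp$pop == p], na.rm = TRUE), numeric(1))
  mean_he <- vapply(pops, function(p)
    mean(lp$He[lp$pop == p], na.rm = TRUE), numeric(1))
  mean_na[is.na(mean_na)] <- 0; mean_he[is.na(mean_he)] <- 0
  stats <- c(setNames(mean_na, paste0("na_", pops)),
             setNames(mean_he, paste0("he_", pops)))
  mean_size <- function(p, l) {
    rows <- genotypes$population == p
    mean(c(genotypes$a1[rows, l], genotypes$a2[rows, l]), na.rm = TRUE)
  }
  for (i in 1:(length(pops) - 1)) for (j in (i + 1):length(pops)) {
    fst <- theta_from_table(subset_populations(genotypes, pops[c(i, j)]),
                            pops[c(i, j)])
    if (is.na(fst)) fst <- 0
    dmu2 <- mean(vapply(genotypes$loci, function(l)
      (mean_size(pops[i], l) - mean_size(pops[j], l))^2, numeric(1)),
      na.rm = TRUE)
    if (is.na(dmu2)) dmu2 <- 0
    stats <- c(stats,
               setNames(fst, paste0("fst_", pops[i], "_", pops[j])),
               setNames(dmu2, paste0("dmu2_", pops[i], "_", pops[j])))
  }
  stats
}

subset_populations <- function(genotypes, pops) {
  keep <- genotypes$population %in% pops
  genotype_table(genotypes$ids[keep], genotypes$population[keep],
                 genotypes$loci,
                 genotypes$a1[keep, , drop = FALSE],
                 genotypes$a2[keep, , drop = FALSE])
}

#' Simulate one summary-statistic vector under a scenario
#'
#' @param template a [scenario_template()].
#' @param draw a [sample_prior()] draw.
#' @param sample_sizes named integer vector (individuals for microsatellites,
#'   sequences for COI) per population.
#' @param marker `"COI"` or `"microsatellite"`.
#' @param L sequence length (COI only).
#' @param n_loci locus count (microsatellites only).
#' @return Named numeric statistic vector with a fixed schema.
#' @export
simulate_summary <- function(template, draw, sample_sizes,
                             marker = c("COI", "microsatellite"),
                             L = 694, n_loci = 4) {
  marker <- match.arg(marker)
  scen <- draw_to_scenario(template, draw)
  pops <- template$populations
  if (marker == "COI") {
    prm <- sim_params(mu_seq = draw$mu)
    aln <- simulate_sequences(scen, prm, sample_sizes, L)
    coi_summary(aln, pops)
  } else {
    prm <- sim_params(mu_ms = draw$mu)
    gt <- simulate_microsatellites(scen, prm, sample_sizes, n_loci)
    msat_summary(gt, pops)
  }
}

#' Build an ABC reference table
#'
#' @param templates named list of [scenario_template()]s (all sharing the
#'   same population list).
#' @param priors a [prior_set()], or a list of one [prior_set()] per template
#'   (e.g. to give scenarios disjoint split-time priors).
#' @param n_per_scenario simulations per scenario.
#' @inheritParams simulate_summary
#' @return A data frame: `scenario` plus one column per summary statistic.
#' @export
build_reference_table <- function(templates, priors, n_per_scenario,
                                  sample_sizes,
                                  marker = c("COI", "microsatellite"),
                                  L = 694, n_loci = 4) {
  marker <- match.arg(marker)
  per_scenario <- !inherits(priors, "prior_set")
  rows <- list()
  for (ti in seq_along(templates)) {
    tmpl <- templates[[ti]]
    pri <- if (per_scenario) priors[[ti]] else priors
    for (r in seq_len(n_per_scenario)) {
      draw <- sample_prior(tmpl, pri, marker)
      st <- simulate_summary(tmpl, draw, sample_sizes, marker, L, n_loci)
      rows[[length(rows) + 1]] <- c(list(scenario = tmpl$id), as.list(st))
    }
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}

#' ABC posterior scenario probabilities
#'
#' Statistics are standardised by the reference table's means and standard
#' deviations; the `tolerance` fraction of simulations closest to the
#' observation (Euclidean distance) is retained; scenario posterior
#' probabilities come from a weighted polychotomous (multinomial) logistic
#' regression of the scenario indicator on the statistic differences, with
#' Epanechnikov weights in the distance and a small ridge penalty, evaluated
#' at zero difference. The raw rejection-frequency posterior is also
#' returned, and is the fallback if the regression fails.
#'
#' @param reference_table from [build_reference_table()].
#' @param observed_stats named statistic vector with the table's schema.
#' @param tolerance retained fraction, in (0, 1].
#' @return A list: `posterior` (named, sums to 1), `rejection` (named),
#'   `n_retained`, `method`.
#' @export
abc_posterior <- function(reference_table, observed_stats, tolerance = 0.01) {
  if (tolerance <= 0 || tolerance > 1) stop("tolerance must be in (0, 1]")
  scen <- factor(reference_table$scenario)
  if (nlevels(scen) < 2) stop("need >= 2 scenarios")
  stat_cols <- setdiff(names(reference_table), "scenario")
  X <- as.matrix(reference_table[, stat_cols, drop = FALSE])
  mu <- colMeans(X); sdev <- apply(X, 2, sd)
  sdev[sdev == 0 | !is.finite(sdev)] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  z_obs <- (observed_stats[stat_cols] - mu) / sdev
  d <- sqrt(rowSums(sweep(Z, 2, z_obs)^2))
  n_keep <- max(2, ceiling(tolerance * nrow(Z)))
  keep <- order(d)[seq_len(n_keep)]
  rejection <- prop.table(table(scen[keep]))
  rejection <- setNames(as.numeric(rejection), names(rejection))
  levs <- levels(scen)
  missing_scen <- setdiff(levs, names(rejection)[rejection > 0])
  if (length(missing_scen))
    warning("scenario(s) absent from the retained set: ",
            paste(missing_scen, collapse = ", "))
  rej_full <- setNames(numeric(length(levs)), levs)
  rej_full[names(rejection)] <- rejection
  dmax <- max(d[keep])
  w <- 1 - (d[keep] / (dmax * (1 + 1e-12)))^2
  w[w <= 0] <- min(w[w > 0], 1e-6)
  df <- data.frame(scenario = droplevels(scen[keep]),
                   sweep(Z[keep, , drop = FALSE], 2, z_obs))
  post <- tryCatch({
    if (nlevels(df$scenario) < 2) stop("one scenario retained")
    fit <- nnet::multinom(scenario ~ ., data = df, weights = w,
                          decay = 1e-4, trace = FALSE, maxit = 300,
                          MaxNWts = 5000)
    nd <- as.data.frame(as.list(setNames(rep(0, length(stat_cols)),
                                         stat_cols)))
    pr <- predict(fit, newdata = nd, type = "probs")
    if (is.null(dim(pr))) {
      # two-class fit returns P(second level)
      pr <- setNames(c(1 - pr, pr), levels(df$scenario))
    }
    full <- setNames(numeric(length(levs)), levs)
    full[names(pr)] <- pr
    list(p = full / sum(full), method = "logistic")
  }, error = function(e) list(p = rej_full, method = "rejection-fallback"))
  list(posterior = post$p, rejection = rej_full, n_retained = n_keep,
       method = post$method)
}

#' Prior predictive check
#'
#' Locates the observed statistic vector relative to the simulated cloud:
#' reports the quantile of its distance to the cloud centroid among the
#' simulated points' own distances, flagging observations outside the 99%
#' envelope.
#'
#' @param reference_table from [build_reference_table()].
#' @param observed_stats named statistic vector.
#' @return A list: `quantile`, `outside_99`.
#' @export
prior_predictive_check <- function(reference_table, observed_stats) {
  stat_cols <- setdiff(names(reference_table), "scenario")
  X <- as.matrix(reference_table[, stat_cols, drop = FALSE])
  mu <- colMeans(X); sdev <- apply(X, 2, sd)
  sdev[sdev == 0 | !is.finite(sdev)] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  ctr <- colMeans(Z)
  d_sim <- sqrt(rowSums(sweep(Z, 2, ctr)^2))
  z_obs <- (observed_stats[stat_cols] - mu) / sdev
  d_obs <- sqrt(sum((z_obs - ctr)^2))
  q <- mean(d_sim < d_obs)
  list(quantile = q, outside_99 = q > 0.99)
}
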