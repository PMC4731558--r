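# End-to-end orchestration: run every analysis stage on a dataset bundle and
# emit report tables (diversity, pairwise differentiation, expansion and
# neutrality, haplotype network, AMOVA, connectivity, Mantel correlations)
# plus a manifest.

#' Default run configuration
#'
#' @param seed master seed for all stochastic stages.
#' @param n_perm permutation count (differentiation and Mantel tests).
#' @param n_sim coalescent simulations for neutrality-test p-values.
#' @param n_boot parametric bootstrap replicates for the expansion fit.
#' @param fdr_alpha nominal FDR level for the differentiation matrix.
#' @param rarefaction_g rarefaction size in gene copies.
#' @param particles particles per locality for the dispersal stage.
#' @param generations multi-generation connectivity steps.
#' @param pld_days pelagic-larval-duration bounds (days).
#' @param dt_minutes tracking time step (minutes).
#' @return A named list.
#' @export
run_config <- function(seed = 1, n_perm = 199, n_sim = 200, n_boot = 0,
                       fdr_alpha = 0.05, rarefaction_g = 34,
                       particles = 200, generations = c(16, 32),
                       pld_days = c(20, 30), dt_minutes = 60) {
  stopifnot(n_perm >= 1, n_sim >= 0, particles >= 1, all(generations >= 1))
  list(seed = seed, n_perm = n_perm, n_sim = n_sim, n_boot = n_boot,
       fdr_alpha = fdr_alpha, rarefaction_g = rarefaction_g,
       particles = particles, generations = generations,
       pld_days = pld_days, dt_minutes = dt_minutes)
}

#' Diversity report table
#'
#' One row per population with the mtDNA columns (N, haplotypes, private
#' haplotypes, private/N, h, pi) and, when genotypes are supplied, the
#' microsatellite columns (N, He, Ho, Ar). Rounding: h to 3 decimals, pi to
#' 4, private/N to 2; a TOTAL row sums the sample sizes.
#'
#' @param haplotable a [collapse_haplotypes()] table.
#' @param genotypes optional [genotype_table()].
#' @param rarefaction_g rarefaction size for Ar.
#' @return A data frame.
#' @export
report_diversity <- function(haplotable, genotypes = NULL,
                             rarefaction_g = 34) {
  pops <- colnames(haplotable$counts)
  priv <- rowSums(haplotable$counts > 0) == 1
  out <- data.frame(
    population = pops,
    N = as.integer(haplotable$n[pops]),
    n_hapl = colSums(haplotable$counts[, pops, drop = FALSE] > 0),
    n_private = vapply(pops, function(p)
      sum(haplotable$counts[, p] > 0 & priv), integer(1)))
  out$priv_per_N <- round(out$n_private / out$N, 2)
  out$h <- round(vapply(pops, function(p)
    haplotype_diversity(haplotable$counts[, p]), numeric(1)), 3)
  out$pi <- round(vapply(pops, function(p)
    nucleotide_diversity(haplotable, p), numeric(1)), 4)
  if (!is.null(genotypes)) {
    lp <- locus_pop_stats(genotypes)
    g_ok <- min(tapply(2 * lp$N, lp$pop, min)[pops], na.rm = TRUE)
    g_use <- min(rarefaction_g, g_ok)
    ar <- allelic_richness(genotypes, g = g_use)
    out$N_msat <- vapply(pops, function(p) {
      v <- lp$N[lp$pop == p]; if (length(v)) as.integer(max(v)) else NA_integer_
    }, integer(1))
    out$He <- round(vapply(pops, function(p)
      mean(lp$He[lp$pop == p], na.rm = TRUE), numeric(1)), 3)
    out$Ho <- round(vapply(pops, function(p)
      mean(lp$Ho[lp$pop == p], na.rm = TRUE), numeric(1)), 3)
    out$Ar <- round(vapply(pops, function(p)
      mean(ar$Ar[ar$pop == p], na.rm = TRUE), numeric(1)), 1)
  }
  total <- out[1, ]
  total[1, ] <- NA
  total$population <- "TOTAL"
  total$N <- sum(out$N)
  if (!is.null(genotypes)) total$N_msat <- sum(out$N_msat, na.rm = TRUE)
  rbind(out, total)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a dataset bundle (as produced by
#' [make_reference_dataset()] or assembled from the readers) and writes
#' publication-style report tables to `out_dir`: diversity per population, the
#' pairwise differentiation matrix (Phi-ST below the diagonal, ENA-corrected
#' theta above) with permutation p-values and FDR flags, per-population
#' mismatch/neutrality results, the haplotype-network edge list, a
#' hierarchical AMOVA over the locality groups, dispersal connectivity
#' (single and multi-generation, min-symmetrized) and the Mantel
#' correlations of linearized Phi-ST with shipping distance and with minimum
#' multi-generation connectivity. A JSON manifest records configuration and
#' the producer of every output.
#'
#' Stages that need at least two populations are skipped with a notice on
#' degenerate input.
#'
#' @param bundle list with `alignment`, `genotypes`, `localities`,
#'   `shipping`, `field` (any but `alignment` may be `NULL`).
#' @param out_dir output directory.
#' @param config a [run_config()].
#' @return Invisibly, a list with every computed object and the manifest.
#' @export
run_all <- function(bundle, out_dir, config = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  manifest <- list(package = "seapopgen",
                   version = as.character(utils::packageVersion("seapopgen")),
                   seed = config$seed, config = config, outputs = list())
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e)))
  }
  ht <- stage("collapse", collapse_haplotypes(bundle$alignment))
  res$haplotable <- ht
  # --- diversity table -----------------------------------------------------
  div <- stage("diversity", report_diversity(ht, bundle$genotypes,
                                             config$rarefaction_g))
  write.csv(div, file.path(out_dir, "diversity.csv"), row.names = FALSE)
  manifest$outputs$diversity.csv <- "report_diversity"
  res$diversity <- div
  pops <- colnames(ht$counts)
  multi_pop <- length(pops) >= 2
  if (!multi_pop)
    message("single population: differentiation stages skipped")
  # --- pairwise differentiation -------------------------------------------
  if (multi_pop) {
    phist <- stage("phist", pairwise_phist(ht, n_perm = config$n_perm))
    fdr <- fdr_adjust(phist$p[upper.tri(phist$p)], config$fdr_alpha)
    combined <- phist$mat
    if (!is.null(bundle$genotypes)) {
      ne <- stage("null-alleles", null_allele_table(bundle$genotypes))
      write.csv(ne, file.path(out_dir, "null_alleles.csv"), row.names = FALSE)
      manifest$outputs$null_alleles.csv <- "null_allele_table"
      gpops <- intersect(pops, unique(bundle$genotypes$population))
      for (i in seq_along(gpops)) for (j in seq_along(gpops)) {
        if (i < j) {
          th <- stage("theta-ena",
                      theta_fst_ena(bundle$genotypes, ne, gpops[c(i, j)]))
          combined[gpops[i], gpops[j]] <- th$theta_ena
        }
      }
      res$null_alleles <- ne
    }
    write_matrix_csv(matrix_table(round(combined, 3)),
                     file.path(out_dir, "differentiation_matrix.csv"))
    write_matrix_csv(matrix_table(phist$p),
                     file.path(out_dir, "phist_pvalues.csv"))
    manifest$outputs$differentiation_matrix.csv <-
      "pairwise_phist + theta_fst_ena"
    res$phist <- phist; res$fdr <- fdr
  }
  # --- mismatch / neutrality ----------------------------------------------
  neut <- stage("neutrality", {
    rows <- lapply(pops, function(p) {
      if (ht$n[p] < 4) return(NULL)
      h <- mismatch_distribution(ht, p)
      fit <- tryCatch(fit_sudden_expansion(h, n = ht$n[p],
                                           n_boot = config$n_boot),
                      error = function(e) NULL)
      td <- tajimas_d(ht, p, n_sim = config$n_sim)
      fs <- fus_fs(ht, p, n_sim = config$n_sim)
      data.frame(population = p, S = td$S,
                 tajima_D = td$D, p_D = td$p,
                 fu_Fs = fs$Fs, p_Fs = fs$p, Fs_signif = !is.na(fs$p) &
                   fs$p < 0.02,
                 tau = if (is.null(fit)) NA else fit$tau,
                 raggedness = if (is.null(fit)) NA else fit$raggedness,
                 p_ssd = if (is.null(fit)) NA else fit$p_ssd,
                 p_rag = if (is.null(fit)) NA else fit$p_rag)
    })
    do.call(rbind, rows)
  })
  write.csv(neut, file.path(out_dir, "neutrality.csv"), row.names = FALSE)
  manifest$outputs$neutrality.csv <-
    "mismatch_distribution + fit_sudden_expansion + tajimas_d + fus_fs"
  res$neutrality <- neut
  # --- haplotype network ---------------------------------------------------
  if (length(ht$seqs) >= 2) {
    mst <- stage("mst", haplotype_mst(ht))
    utils::write.table(mst, file.path(out_dir, "haplotype_mst.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    manifest$outputs$haplotype_mst.tsv <- "haplotype_mst"
    res$mst <- mst
  }
  # --- AMOVA ---------------------------------------------------------------
  if (multi_pop && !is.null(bundle$localities) &&
      length(unique(bundle$localities$group)) >= 2) {
    groups <- setNames(bundle$localities$group, bundle$localities$name)
    groups <- groups[names(groups) %in% pops]
    am <- stage("amova", amova_hierarchical(ht, groups,
                                            n_perm = config$n_perm))
    am_df <- data.frame(level = c("among_groups", "among_pops_within",
                                  "within_pops"),
                        sigma2 = c(am$sigma_a, am$sigma_b, am$sigma_c),
                        index = c(am$f_ct, am$f_sc, am$f_st),
                        p = c(am$p_ct, am$p_sc, am$p_st))
    write.csv(am_df, file.path(out_dir, "amova.csv"), row.names = FALSE)
    manifest$outputs$amova.csv <- "amova_hierarchical"
    res$amova <- am
  }
  # --- dispersal -----------------------------------------------------------
  if (!is.null(bundle$field)) {
    spec <- release_spec(particles_per_locality = config$particles,
                         pld_days = config$pld_days,
                         dt_minutes = config$dt_minutes)
    ep <- stage("advect", advect(bundle$field, spec))
    C1 <- stage("connectivity", connectivity(ep, bundle$field$habitat))
    write_matrix_csv(C1, file.path(out_dir, "connectivity_G1.csv"))
    manifest$outputs$connectivity_G1.csv <- "advect + connectivity"
    res$connectivity <- C1
    sym <- list()
    for (G in config$generations) {
      CG <- multigeneration(C1, G)
      SG <- symmetrize_min(CG)
      write_matrix_csv(CG, file.path(out_dir,
                                     sprintf("connectivity_G%d.csv", G)))
      write_matrix_csv(SG, file.path(out_dir,
                                     sprintf("connectivity_G%d_min.csv", G)))
      sym[[as.character(G)]] <- SG
    }
    manifest$outputs$connectivity_multigen <- "multigeneration + symmetrize_min"
    res$connectivity_min <- sym
  }
  # --- Mantel correlations -------------------------------------------------
  if (multi_pop && length(pops) >= 4 && !is.null(res$phist)) {
    lin <- slatkin_linearize(res$phist$mat)
    mrows <- list()
    if (!is.null(bundle$shipping)) {
      ibd <- stage("ibd", ibd_report(matrix_table(lin),
                                     bundle$shipping, config$n_perm))
      mrows$ibd <- data.frame(test = "IBD_shipping", r = ibd$mantel$r,
                              p = ibd$mantel$p, tail = ibd$mantel$tail)
      res$ibd <- ibd
    }
    if (!is.null(res$connectivity_min) &&
        all(pops %in% rownames(res$connectivity_min[[1]]$mat))) {
      for (G in names(res$connectivity_min)) {
        S <- res$connectivity_min[[G]]$mat[pops, pops]
        cr <- stage("connectivity-mantel",
                    connectivity_report(matrix_table(lin), matrix_table(S,
                      symmetric = TRUE), config$n_perm))
        mrows[[paste0("conn", G)]] <-
          data.frame(test = paste0("connectivity_G", G), r = cr$mantel$r,
                     p = cr$mantel$p, tail = cr$mantel$tail)
        res[[paste0("conn_mantel_G", G)]] <- cr
      }
    }
    if (length(mrows)) {
      mt <- do.call(rbind, mrows)
      write.csv(mt, file.path(out_dir, "mantel.csv"), row.names = FALSE)
      manifest$outputs$mantel.csv <- "mantel (ibd_report, connectivity_report)"
      res$mantel_table <- mt
    }
  }
  manifest$config_hash <- substr(paste(
    as.hexmode(utils::head(utf8ToInt(paste(deparse(config), collapse = "")),
                           64)), collapse = ""), 1, 32)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  res$manifest <- manifest
  invisible(res)
}
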