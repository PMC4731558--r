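test_that("per-locus diversity statistics follow the unbiased formulas", {
  # all homozygous
  gt <- genotype_table(paste0("i", 1:6), rep("P", 6), "L1",
                       a1 = matrix(rep(120L, 6)), a2 = matrix(rep(120L, 6)))
  s <- locus_pop_stats(gt)
  expect_equal(s$He, 0)
  expect_equal(s$Ho, 0)
  expect_true(is.na(s$Fis))

  # n = 10, two alleles at 0.5, all heterozygous
  gt2 <- genotype_table(paste0("i", 1:10), rep("P", 10), "L1",
                        a1 = matrix(rep(100L, 10)),
                        a2 = matrix(rep(102L, 10)))
  s2 <- locus_pop_stats(gt2)
  expect_equal(s2$He, 20 / 19 * 0.5, tolerance = 1e-12)
  expect_equal(s2$Ho, 1)
  expect_lt(s2$Fis, 0)

  # HWE simulation: mean F_IS ~ 0
  set.seed(1)
  fis <- replicate(150, {
    g <- hwe_genotypes(40, c(0.4, 0.3, 0.2, 0.1))
    locus_pop_stats(g)$Fis
  })
  expect_lt(abs(mean(fis, na.rm = TRUE)), 0.02)
})

test_that("the HWE permutation test is calibrated and has power against nulls", {
  # monomorphic: p = 1
  gt <- genotype_table(paste0("i", 1:8), rep("P", 8), "L1",
                       a1 = matrix(rep(120L, 8)), a2 = matrix(rep(120L, 8)))
  expect_equal(hwe_test(gt, "L1", "P", n_perm = 19)$p_two, 1)
  # null-allele-distorted data: heterozygote deficit detected
  set.seed(2)
  hits <- replicate(20, {
    g <- apply_null_alleles(hwe_genotypes(60, c(0.4, 0.3, 0.2, 0.1)), 0.4)
    hwe_test(g, "L1", "P", n_perm = 99)$p_deficit < 0.05
  })
  expect_gt(mean(hits), 0.6)
})

test_that("the LD permutation test separates duplicated from independent loci", {
  set.seed(3)
  g1 <- sample.int(3, 60, TRUE) + 100
  gt <- genotype_table(paste0("i", 1:30), rep("P", 30), c("L1", "L2"),
                       a1 = cbind(pmin(g1[1:30], g1[31:60]),
                                  pmin(g1[1:30], g1[31:60])),
                       a2 = cbind(pmax(g1[1:30], g1[31:60]),
                                  pmax(g1[1:30], g1[31:60])))
  expect_lt(ld_test(gt, c("L1", "L2"), n_perm = 99)$p, 0.05)
  # monomorphic pair degenerate
  gt0 <- genotype_table(paste0("i", 1:8), rep("P", 8), c("L1", "L2"),
                        a1 = cbind(rep(100L, 8), rep(200L, 8)),
                        a2 = cbind(rep(100L, 8), rep(200L, 8)))
  expect_equal(ld_test(gt0, c("L1", "L2"), n_perm = 19)$p, 1)
})

test_that("rarefied allelic richness matches exhaustive subsampling", {
  # toy counts (6, 2), g = 4: enumerate all C(8, 4) subsamples
  gt <- genotype_table(paste0("i", 1:4), rep("P", 4), "L1",
                       a1 = matrix(c(100L, 100L, 100L, 104L)),
                       a2 = matrix(c(100L, 100L, 100L, 104L)))
  copies <- c(rep(100, 6), rep(104, 2))
  subs <- combn(8, 4)
  oracle <- mean(apply(subs, 2, function(ix) length(unique(copies[ix]))))
  ar <- allelic_richness(gt, g = 4)
  expect_equal(ar$Ar, oracle, tolerance = 1e-12)
  # identities
  expect_equal(allelic_richness(gt, g = 8)$Ar, 2)
  gt1 <- genotype_table(paste0("i", 1:5), rep("P", 5), "L1",
                        a1 = matrix(rep(100L, 5)), a2 = matrix(rep(100L, 5)))
  expect_equal(allelic_richness(gt1, g = 4)$Ar, 1)
  # monotone nondecreasing in g
  set.seed(4)
  g <- hwe_genotypes(30, c(0.5, 0.3, 0.15, 0.05))
  ars <- vapply(c(4, 10, 20, 40), function(gg)
    allelic_richness(g, gg)$Ar, numeric(1))
  expect_true(all(diff(ars) >= -1e-12))
  expect_error(allelic_richness(g, 100), "exceeds")
})

test_that("the null-allele EM is consistent in the null case and errors on empty data", {
  set.seed(5)
  g <- hwe_genotypes(600, c(0.4, 0.3, 0.2, 0.1))
  est <- null_allele_em(g, "L1", "P")
  expect_lte(est$r, 0.02)
  g_all_na <- genotype_table(paste0("i", 1:6), rep("P", 6), "L1",
                             a1 = matrix(NA_integer_, 6, 1),
                             a2 = matrix(NA_integer_, 6, 1))
  expect_error(null_allele_em(g_all_na, "L1", "P"), "missing")
})

test_that("Weir-Cockerham theta covers the trivial, oracle and permutation cases", {
  # populations fixed for different alleles: theta = 1
  gt <- genotype_table(paste0("i", 1:8), rep(c("P", "Q"), each = 4), "L1",
                       a1 = matrix(c(rep(100L, 4), rep(120L, 4))),
                       a2 = matrix(c(rep(100L, 4), rep(120L, 4))))
  expect_equal(theta_fst(gt, c("P", "Q"), n_perm = 0)$theta, 1)
  # identical frequencies under HWE: theta near 0
  set.seed(6)
  ths <- replicate(60, {
    g <- hwe_genotypes(40, c(0.5, 0.3, 0.2), pops = c("P", "Q"))
    theta_fst(g, c("P", "Q"), n_perm = 0)$theta
  })
  expect_lt(abs(mean(ths)), 0.01)
  # hand-derived component oracle: P = {A/A, A/B}, Q = {B/B, B/B} -> 2/3
  gt2 <- genotype_table(paste0("i", 1:4), rep(c("P", "Q"), each = 2), "L1",
                        a1 = matrix(c(100L, 100L, 102L, 102L)),
                        a2 = matrix(c(100L, 102L, 102L, 102L)))
  expect_equal(theta_fst(gt2, c("P", "Q"), n_perm = 0)$theta, 2 / 3,
               tolerance = 1e-12)
  # permutation p small when differentiation is real
  set.seed(7)
  expect_lt(theta_fst(gt, c("P", "Q"), n_perm = 99)$p, 0.05)
  # no shared polymorphic locus
  gt3 <- genotype_table(paste0("i", 1:4), rep(c("P", "Q"), each = 2), "L1",
                        a1 = matrix(rep(100L, 4)), a2 = matrix(rep(100L, 4)))
  expect_error(theta_fst(gt3, c("P", "Q"), n_perm = 0), "polymorphic")
})

test_that("the ENA correction reduces to the uncorrected estimator without nulls", {
  set.seed(8)
  scen <- scenario(c("P", "Q"),
                   data.frame(time = 600, derived = "Q", source = "P"),
                   c(P = 3000, Q = 3000))
  gt <- simulate_microsatellites(scen, sim_params(mu_ms = 3e-4),
                                 c(P = 30, Q = 30), 4)
  res <- theta_fst_ena(gt, NULL, c("P", "Q"))
  expect_equal(res$theta_ena, res$theta_uncorrected, tolerance = 5e-3)
})

test_that("theta and Phi-ST rank the same biallelic data concordantly", {
  set.seed(9)
  # one biallelic locus observed both as genotypes (theta) and as haploid
  # gene-copy 'sequences' (Phi-ST): two estimators, one dataset
  C <- matrix(0, 7, 7, dimnames = list(paste0("L", 1:7), paste0("L", 1:7)))
  for (i in 1:6) C[i, i + 1] <- C[i + 1, i] <- 0.12 * i / 6
  gt <- simulate_metapopulation(C, Ne = 120, generations = 100, n_loci = 1,
                                n_alleles = 2, sample_size = 25)
  th <- pairwise_theta(gt)$mat
  copies <- c(gt$a1[, 1], gt$a2[, 1])
  aln <- seq_alignment(paste0("c", seq_along(copies)),
                       rep(gt$population, 2),
                       ifelse(copies == min(copies), "A", "T"))
  ph <- pairwise_phist(collapse_haplotypes(aln), distance_model("hamming"),
                       n_perm = 1)$mat
  ph <- ph[rownames(th), colnames(th)]
  ut <- upper.tri(th)
  expect_gt(cor(th[ut], ph[ut], method = "spearman"), 0.8)
  expect_gt(cor(sign(th[ut]), sign(ph[ut])), 0)
})

test_that("the bottleneck test rejects monomorphic panels and ranks a crash above equilibrium", {
  gt0 <- genotype_table(paste0("i", 1:10), rep("P", 10), c("L1", "L2"),
                        a1 = cbind(rep(100L, 10), rep(200L, 10)),
                        a2 = cbind(rep(100L, 10), rep(200L, 10)))
  expect_error(bottleneck_test(gt0, "P", n_iter = 10), "polymorphic")

  set.seed(10)
  scen_eq <- scenario("A", NULL, c(A = 2000))
  prm <- sim_params(mu_ms = 8 / (4 * 2000), p_gsm = 0.8)
  gt_eq <- simulate_microsatellites(scen_eq, prm, c(A = 20), 5)
  p_eq <- bottleneck_test(gt_eq, "A", n_iter = 250)$p_excess
  # 95% crash 40 generations ago (backward: tiny recent Ne, large ancestral)
  scen_cr <- scenario("A", NULL, c(A = 100))
  gt_cr <- simulate_microsatellites(
    scen_cr, prm, c(A = 20), 5,
    size_changes = data.frame(time = 40, pop = "A", ne = 2000))
  p_cr <- bottleneck_test(gt_cr, "A", n_iter = 250)$p_excess
  expect_true(p_eq > 0.01)
  expect_true(p_cr <= p_eq || p_cr < 0.15)
})
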