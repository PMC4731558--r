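test_that("zero mutation rates give invariant data", {
  set.seed(1)
  scen <- scenario(c("A", "B"), data.frame(time = 100, derived = "B",
                                           source = "A"),
                   c(A = 500, B = 500))
  aln <- simulate_sequences(scen, sim_params(mu_seq = 0), c(A = 5, B = 5), 50)
  expect_equal(length(unique(aln$seqs)), 1)
  gt <- simulate_microsatellites(scen, sim_params(mu_ms = 0),
                                 c(A = 5, B = 5), 3)
  expect_true(all(apply(cbind(gt$a1, gt$a2), 2, function(x)
    length(unique(x)) == 1)))
})

test_that("coalescent sequence simulator matches E[pi] = theta", {
  set.seed(2)
  scen <- scenario("A", NULL, c(A = 1000))
  prm <- sim_params(mu_seq = 5 / (4 * 1000 * 694), alpha_sim = Inf)
  pis <- replicate(150, mean_pairwise_differences(
    collapse_haplotypes(simulate_sequences(scen, prm, c(A = 20), 694))))
  # E[pi] = theta = 5; across-replicate SD of pi is ~3, so SE ~ 0.25
  expect_gt(mean(pis), 4.2)
  expect_lt(mean(pis), 5.8)
})

test_that("strong splits without migration drive Phi-ST towards one", {
  set.seed(3)
  scen <- scenario(c("A", "B"),
                   data.frame(time = 50000, derived = "B", source = "A"),
                   c(A = 500, B = 500))
  prm <- sim_params(mu_seq = 2e-5, alpha_sim = Inf)
  phis <- replicate(10, {
    ht <- collapse_haplotypes(simulate_sequences(scen, prm,
                                                 c(A = 10, B = 10), 300))
    pairwise_phist(ht, distance_model("hamming"), n_perm = 1)$mat[1, 2]
  })
  expect_gt(mean(phis), 0.8)
})

test_that("SMM heterozygosity matches the closed form 1 - 1/sqrt(1+2*theta)", {
  set.seed(4)
  scen <- scenario("A", NULL, c(A = 500))
  prm <- sim_params(mu_ms = 2 / (4 * 500), p_gsm = 1)
  hes <- replicate(250, locus_pop_stats(
    simulate_microsatellites(scen, prm, c(A = 25), 1))$He[1])
  expect_equal(mean(hes), 1 - 1 / sqrt(1 + 2 * 2), tolerance = 0.06)
})

test_that("null-allele masking follows the Dempster model and never invents alleles", {
  set.seed(5)
  gt <- hwe_genotypes(2000, c(0.4, 0.3, 0.2, 0.1))
  masked <- apply_null_alleles(gt, 0.3)
  # visible alleles are a subset of the original ones
  expect_true(all(stats::na.omit(unique(c(masked$a1, masked$a2))) %in%
                    unique(c(gt$a1, gt$a2))))
  # observed heterozygosity shrinks by (1-r)^2; missingness appears at r^2
  ho_true <- mean(gt$a1[, 1] != gt$a2[, 1])
  kept <- !is.na(masked$a1[, 1])
  ho_masked <- mean(masked$a1[kept, 1] != masked$a2[kept, 1])
  expect_lt(abs(ho_masked * mean(kept) - ho_true * (1 - 0.3)^2), 0.025)
  expect_lt(abs(mean(!kept) - 0.3^2), 0.02)
  # degenerate cases
  expect_equal(apply_null_alleles(gt, 0)$a1, gt$a1)
  nearly <- apply_null_alleles(gt, 0.999)
  expect_gt(mean(is.na(nearly$a1)), 0.99)
})

test_that("generated flow fields are divergence-free and masked", {
  set.seed(6)
  f <- make_velocity_field(flow_field_spec(nx = 30, ny = 24,
                                           n_localities = 4,
                                           duration_days = 2))
  expect_true(all(f$u[!f$mask] == 0) && all(f$v[!f$mask] == 0))
  u <- f$u[, , 3]; v <- f$v[, , 3]
  dx <- f$dx_km * 1000
  divs <- c()
  for (i in 5:26) for (j in 5:20)
    divs <- c(divs, (u[i + 1, j] - u[i - 1, j]) / (2 * dx) +
                (v[i, j + 1] - v[i, j - 1]) / (2 * dx))
  expect_lt(max(abs(divs)), 1e-15)
  # zero amplitude and noise: still water
  set.seed(6)
  f0 <- make_velocity_field(flow_field_spec(nx = 30, ny = 24, amplitude = 0,
                                            n_localities = 4,
                                            noise = 0, duration_days = 1))
  expect_equal(max(abs(f0$u)), 0)
  expect_equal(max(abs(f0$v)), 0)
  # habitat on land rejected
  expect_error(make_velocity_field(
    flow_field_spec(nx = 30, ny = 24, n_localities = 4,
                    habitat = list(X = c(1:10)))),
    "land")
})

test_that("neutral equilibrium sequence data centre Tajima's D near zero", {
  set.seed(7)
  scen <- scenario("A", NULL, c(A = 1000))
  prm <- sim_params(mu_seq = 3 / (4 * 1000 * 500), alpha_sim = Inf)
  ds <- replicate(220, {
    ht <- collapse_haplotypes(simulate_sequences(scen, prm, c(A = 20), 500))
    tajimas_d(ht, n_sim = 0)$D
  })
  expect_lt(abs(mean(ds, na.rm = TRUE)), 0.15)
})

test_that("the reference bundle is reproducible and passes its own readers", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  b1 <- make_reference_dataset(d1, seed = 3, n_per_pop = 8)
  b2 <- make_reference_dataset(d2, seed = 3, n_per_pop = 8)
  for (nm in names(b1$paths)) {
    expect_identical(readLines(b1$paths[[nm]]), readLines(b2$paths[[nm]]),
                     info = nm)
  }
  b3 <- make_reference_dataset(withr::local_tempdir(), seed = 4,
                               n_per_pop = 8)
  expect_false(identical(readLines(b1$paths$fasta),
                         readLines(b3$paths$fasta)))
  # readers accept every artefact
  aln <- suppressMessages(read_fasta_alignment(
    b1$paths$fasta, read.csv(b1$paths$popmap)))
  expect_equal(length(aln$ids), 7 * 8)
  gt <- suppressMessages(read_genepop(b1$paths$genepop))
  expect_equal(length(gt$loci), 4)
  loc <- read_locality_csv(b1$paths$localities)
  expect_equal(nrow(loc), 7)
  ship <- read_matrix_csv(b1$paths$shipping, symmetric = TRUE)
  expect_equal(dim(ship$mat), c(7, 7))
  fld <- read_velocity_field(b1$paths$field)
  expect_equal(length(fld$habitat), 7)
})

test_that("the fast genealogy simulator agrees with the reference implementation", {
  # same demography, two independent code paths: compare E[tree height]
  scen <- scenario(c("A", "B"),
                   data.frame(time = 2000, derived = "B", source = "A"),
                   c(A = 800, B = 800))
  set.seed(8)
  h_fast <- replicate(300, {
    g <- seapopgen:::sim_genealogy(c(A = 6, B = 6), scen)
    max(g$node_time)
  })
  set.seed(9)
  h_slow <- replicate(300, {
    g <- seapopgen:::sim_genealogy_slow(c(A = 6, B = 6), scen)
    max(g$node_time)
  })
  expect_equal(mean(h_fast), mean(h_slow), tolerance = 0.1)
  expect_equal(sd(h_fast), sd(h_slow), tolerance = 0.25)
})
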