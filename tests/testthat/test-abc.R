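test_that("prior draws respect bounds, ordering constraints and uniformity", {
  pri <- prior_set(t_bounds = c(10, 10000))
  tmpl <- invasion_scenarios()$global1
  set.seed(1)
  draws <- replicate(300, sample_prior(tmpl, pri)$times, simplify = FALSE)
  times <- do.call(rbind, draws)
  expect_true(all(times >= 10 & times <= 10000))
  # ancestry ordering: a population must exist before seeding another
  ev <- tmpl$events
  violations <- sum(vapply(draws, function(d) {
    sum(vapply(seq_len(nrow(ev)), function(i) {
      ev$source[i] %in% ev$derived && d[ev$source[i]] <= d[ev$derived[i]]
    }, logical(1)))
  }, numeric(1)))
  expect_equal(violations, 0)
  # degenerate bounds give constants
  prid <- prior_set(t_bounds = c(500, 500))
  expect_true(all(sample_prior(tmpl, prid)$times == 500))
  # uniformity of an unconstrained margin (root's direct daughter "PU")
  set.seed(2)
  pri2 <- prior_set()
  t2 <- replicate(2000, sample_prior(
    scenario_template("x", c("A", "B"),
                      data.frame(derived = "B", source = "A")), pri2)$times)
  expect_gt(stats::ks.test((t2 - 10) / (10000 - 10), "punif")$p.value, 0.01)
})

test_that("simulated summary statistics have a fixed schema and degenerate limits", {
  tmpl <- scenario_template("x", c("A", "B"),
                            data.frame(derived = "B", source = "A"))
  pri <- prior_set()
  set.seed(3)
  draw <- sample_prior(tmpl, pri, "microsatellite")
  draw$mu <- 0
  s0 <- simulate_summary(tmpl, draw, c(A = 8, B = 8), "microsatellite",
                         n_loci = 3)
  expect_equal(unname(s0[c("he_A", "he_B", "fst_A_B", "dmu2_A_B")]),
               rep(0, 4))
  expect_equal(unname(s0[c("na_A", "na_B")]), c(1, 1))
  draw2 <- sample_prior(tmpl, pri, "microsatellite")
  s1 <- simulate_summary(tmpl, draw2, c(A = 8, B = 8), "microsatellite",
                         n_loci = 3)
  expect_identical(names(s1), names(s0))
  # COI schema
  draw3 <- sample_prior(tmpl, pri, "COI")
  sc <- simulate_summary(tmpl, draw3, c(A = 6, B = 6), "COI", L = 200)
  expect_identical(names(sc),
                   c("nhap_A", "nhap_B", "pi_A", "pi_B", "fst_A_B",
                     "dxy_A_B"))
})

test_that("reference tables are reproducible with exact per-scenario counts", {
  tmpl1 <- scenario_template("s1", c("A", "B"),
                             data.frame(derived = "B", source = "A"))
  tmpl2 <- scenario_template("s2", c("A", "B"),
                             data.frame(derived = "B", source = "A"))
  pri <- prior_set()
  set.seed(4)
  ref <- build_reference_table(list(tmpl1, tmpl2), pri, 30, c(A = 6, B = 6),
                               marker = "microsatellite", n_loci = 2)
  expect_equal(nrow(ref), 60)
  expect_equal(as.vector(table(ref$scenario)), c(30L, 30L))
  set.seed(4)
  ref2 <- build_reference_table(list(tmpl1, tmpl2), pri, 30, c(A = 6, B = 6),
                                marker = "microsatellite", n_loci = 2)
  expect_identical(ref, ref2)
  # standardisation sanity
  stat_cols <- setdiff(names(ref), "scenario")
  Z <- scale(as.matrix(ref[, stat_cols]))
  mu <- colMeans(Z[, apply(Z, 2, function(x) !all(is.na(x)))], na.rm = TRUE)
  expect_true(all(abs(mu) < 1e-10))
})

test_that("ABC posteriors sum to one and are symmetric for exchangeable scenarios", {
  tmpl1 <- scenario_template("s1", c("A", "B"),
                             data.frame(derived = "B", source = "A"))
  tmpl2 <- scenario_template("s2", c("A", "B"),
                             data.frame(derived = "B", source = "A"))
  pri <- prior_set()
  set.seed(5)
  ref <- build_reference_table(list(tmpl1, tmpl2), pri, 150, c(A = 8, B = 8),
                               marker = "microsatellite", n_loci = 3)
  post1 <- numeric(30)
  for (r in 1:30) {
    draw <- sample_prior(tmpl1, pri, "microsatellite")
    obs <- simulate_summary(tmpl1, draw, c(A = 8, B = 8), "microsatellite",
                            n_loci = 3)
    p <- suppressWarnings(abc_posterior(ref, obs, tolerance = 0.05))
    expect_equal(sum(p$posterior), 1, tolerance = 1e-9)
    expect_true(all(p$posterior >= 0))
    post1[r] <- p$posterior["s1"]
  }
  # exchangeable generative processes: mean posterior near 1/2
  expect_lt(abs(mean(post1) - 0.5), 0.15)
})

test_that("the prior predictive check locates observations in the cloud", {
  tmpl <- scenario_template("s1", c("A", "B"),
                            data.frame(derived = "B", source = "A"))
  pri <- prior_set()
  set.seed(6)
  ref <- build_reference_table(list(tmpl, tmpl), pri, 40, c(A = 6, B = 6),
                               marker = "microsatellite", n_loci = 2)
  row1 <- unlist(ref[1, -1])
  q1 <- prior_predictive_check(ref, row1)
  expect_lt(q1$quantile, 0.9)
  far <- row1 + 100
  q2 <- prior_predictive_check(ref, far)
  expect_equal(q2$quantile, 1)
  expect_true(q2$outside_99)
})

test_that("the shipped scenario library is internally consistent", {
  lib <- invasion_scenarios()
  expect_equal(length(lib), 6)
  for (tmpl in lib) {
    # exactly one root; events form a tree over the populations
    roots <- setdiff(tmpl$populations, tmpl$events$derived)
    expect_equal(length(roots), 1)
    expect_true(all(tmpl$events$source %in% tmpl$populations))
    # a drawn parameter set instantiates a valid scenario
    set.seed(7)
    draw <- sample_prior(tmpl, prior_set())
    scen <- seapopgen:::draw_to_scenario(tmpl, draw)
    expect_s3_class(scen, "scenario")
  }
})
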