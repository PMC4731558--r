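test_that("haplotype collapsing merges identical sequences and classifies sites", {
  aln <- make_alignment(c("AAA", "AAA", "AAA"), rep("P1", 3))
  ht <- collapse_haplotypes(aln)
  expect_equal(length(ht$seqs), 1)
  expect_equal(unname(ht$counts[1, "P1"]), 3L)

  aln2 <- make_alignment(c("AAA", "AAT", "AAT"), rep("P1", 3))
  ht2 <- collapse_haplotypes(aln2)
  expect_equal(length(ht2$seqs), 2)
  expect_equal(sort(unname(ht2$counts[, "P1"])), c(1L, 2L))
  expect_equal(ht2$n_polymorphic, 1)
  expect_equal(ht2$n_transversions, 1)   # A<->T
  expect_equal(ht2$n_transitions, 0)

  # brute-force string dedup oracle on a random fixture
  set.seed(1)
  aln3 <- random_alignment(40, 60, n_pops = 3, mut_prob = 0.02)
  ht3 <- collapse_haplotypes(aln3)
  expect_equal(length(ht3$seqs), length(unique(aln3$seqs)))
  expect_equal(unname(colSums(ht3$counts)),
               as.vector(table(aln3$population)[colnames(ht3$counts)]))
})

test_that("haplotype diversity follows Nei's formula", {
  expect_equal(round(haplotype_diversity(c(6, 1)), 3), 0.286)
  expect_equal(round(haplotype_diversity(c(5, 1, 1)), 3), 0.524)
  expect_equal(haplotype_diversity(c(9)), 0)
  expect_equal(haplotype_diversity(c(1, 1, 1, 1)), 1)
  expect_true(is.na(haplotype_diversity(c(1))))
})

test_that("nucleotide diversity matches the double-sum oracle", {
  # all identical
  ht <- collapse_haplotypes(make_alignment(rep("ACGT", 4), rep("P", 4)))
  expect_equal(nucleotide_diversity(ht), 0)
  # counts (6, 1), haplotypes differing at 2 of 694 sites
  base <- paste(rep("A", 694), collapse = "")
  var2 <- paste0("TT", substr(base, 3, 694))
  aln <- make_alignment(c(rep(base, 6), var2), rep("P", 7))
  ht2 <- collapse_haplotypes(aln)
  # oracle: (n/(n-1)) * sum_{k != l} x_k x_l d_kl / L evaluated directly
  oracle <- (7 / 6) * 2 * (6 / 7) * (1 / 7) * 2 / 694
  expect_equal(nucleotide_diversity(ht2), oracle, tolerance = 1e-12)
  expect_equal(round(oracle, 6), 0.000823)
  # two singletons differing everywhere
  ht3 <- collapse_haplotypes(make_alignment(c("AAAA", "TTTT"), rep("P", 2)))
  expect_equal(nucleotide_diversity(ht3), 1)
})

test_that("TN93 distances match ape and the gamma correction is monotone", {
  set.seed(2)
  a <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
             collapse = "")
  bb <- strsplit(a, "")[[1]]
  idx <- sample(400, 30)
  bb[idx] <- sample(c("A", "C", "G", "T"), 30, replace = TRUE)
  b <- paste(bb, collapse = "")
  bin <- ape::as.DNAbin(list(x = strsplit(tolower(a), "")[[1]],
                             y = strsplit(tolower(b), "")[[1]]))
  expect_equal(tn93_gamma_distance(a, b, distance_model("tn93", Inf)),
               as.numeric(ape::dist.dna(bin, model = "TN93")),
               tolerance = 1e-9)
  for (al in c(0.5, 0.023)) {
    expect_equal(tn93_gamma_distance(a, b, distance_model("tn93", al)),
                 as.numeric(ape::dist.dna(bin, model = "TN93", gamma = al)),
                 tolerance = 1e-9)
  }
  # gamma correction strictly inflates the distance
  expect_gt(tn93_gamma_distance(a, b, distance_model("tn93", 0.023)),
            tn93_gamma_distance(a, b, distance_model("tn93", Inf)))
  expect_equal(tn93_gamma_distance(a, a), 0)

  # independent formula oracle: one A<->G transition in 400 sites, equal
  # base frequencies, alpha = 0.023
  s1 <- paste(rep(c("A", "C", "G", "T"), 100), collapse = "")
  s2 <- paste0("G", substr(s1, 2, 400))
  f <- rep(0.25, 4); gR <- 0.5; gY <- 0.5
  P1 <- 1 / 400; Q <- 0
  w1 <- 1 - gR * P1 / (2 * f[1] * f[3])
  al <- 0.023
  d_oracle <- 2 * f[1] * f[3] / gR * al * (w1^(-1 / al) - 1)
  expect_equal(tn93_gamma_distance(s1, s2, distance_model("tn93", al,
                                                          freqs = f)),
               d_oracle, tolerance = 1e-12)

  # pairwise deletion and saturation guards
  expect_error(tn93_gamma_distance("NNNN", "ACGT"), "comparable")
  expect_error(seapopgen:::seq_distance("NNNN", "ACGT",
                                        distance_model("hamming")),
               "comparable")
})

test_that("mismatch distributions equal the brute-force pair count", {
  ht <- collapse_haplotypes(make_alignment(rep("ACGTACGT", 5), rep("P", 5)))
  expect_equal(unname(mismatch_distribution(ht)), 1)

  ht2 <- collapse_haplotypes(make_alignment(c("AAAA", "TTTA"), rep("P", 2)))
  m2 <- mismatch_distribution(ht2)
  expect_equal(unname(m2[length(m2)]), 1)
  expect_equal(names(m2)[length(m2)], "3")

  set.seed(3)
  aln <- random_alignment(15, 40, n_pops = 1, mut_prob = 0.1)
  ht3 <- collapse_haplotypes(aln)
  got <- mismatch_distribution(ht3, "P1")
  # O(n^2) oracle over raw sequences
  chars <- strsplit(aln$seqs, "")
  diffs <- c()
  for (i in 1:14) for (j in (i + 1):15)
    diffs <- c(diffs, sum(chars[[i]] != chars[[j]]))
  oracle <- tabulate(diffs + 1, nbins = max(diffs) + 1) / length(diffs)
  expect_equal(unname(got), oracle)
})

test_that("raggedness uses the appended-zero-class convention", {
  expect_equal(raggedness(c(0, 0.5, 0.5)), 0.5)
  expect_equal(raggedness(c(1)), 1)           # single spike vs appended zero
})

test_that("Slatkin linearization is the monotone map x/(1-x)", {
  expect_equal(slatkin_linearize(0), 0)
  expect_equal(slatkin_linearize(0.5), 1)
  expect_equal(round(slatkin_linearize(0.167), 4), 0.2005)
  expect_equal(slatkin_linearize(1), Inf)
  expect_equal(slatkin_linearize(-0.1), -0.1 / 1.1)
  x <- seq(-0.9, 0.9, by = 0.05)
  expect_true(all(diff(slatkin_linearize(x)) > 0))
})

test_that("FDR adjustment reproduces the hand-applied step-up rule", {
  res <- fdr_adjust(c(0.01, 0.04, 0.03, 0.005), alpha = 0.05)
  # sorted p: .005 <= .0125, .01 <= .025, .03 <= .0375, .04 <= .05 -> all in
  expect_true(all(res$reject))
  expect_equal(res$threshold, 0.04)
  res2 <- fdr_adjust(rep(0.001, 10), 0.05)
  expect_true(all(res2$reject))
  res3 <- fdr_adjust(numeric(0))
  expect_equal(length(res3$adjusted), 0)
  res4 <- fdr_adjust(c(0.5, 0.9, 0.2), 0.05)
  expect_false(any(res4$reject))
})

test_that("the haplotype MST is minimal, deterministic and order-invariant", {
  ht <- collapse_haplotypes(make_alignment(c("AAAA", "AAAT", "AATT"),
                                           rep("P", 3)))
  mst <- haplotype_mst(ht)
  expect_equal(attr(mst, "total_steps"), 2)
  expect_equal(sort(mst$steps), c(1, 1))

  # exhaustive spanning-tree oracle over all Pruefer sequences, n <= 7
  set.seed(4)
  aln <- random_alignment(12, 25, n_pops = 1, mut_prob = 0.15)
  ht2 <- collapse_haplotypes(aln)
  H <- min(length(ht2$seqs), 7)
  sub <- make_alignment(ht2$seqs[1:H], rep("P", H))
  ht_sub <- collapse_haplotypes(sub)
  D <- haplotype_distances(ht_sub, distance_model("hamming"))
  labs <- rownames(ht_sub$counts)
  D <- D[labs, labs]
  best <- Inf
  prufer_len <- H - 2
  grids <- do.call(expand.grid, rep(list(seq_len(H)), max(prufer_len, 0)))
  for (r in seq_len(max(nrow(grids), 1))) {
    pruf <- if (prufer_len > 0) as.integer(grids[r, ]) else integer(0)
    # decode Pruefer sequence to an edge list
    degree <- rep(1L, H) + tabulate(pruf, H)
    w <- 0
    pr <- pruf
    avail <- rep(TRUE, H)
    for (s in seq_len(max(prufer_len, 0))) {
      leaf <- which(avail & degree == 1L)[1]
      w <- w + D[leaf, pr[1]]
      degree[leaf] <- 0L; avail[leaf] <- FALSE
      degree[pr[1]] <- degree[pr[1]] - 1L
      pr <- pr[-1]
    }
    last <- which(avail & degree >= 1L)
    w <- w + D[last[1], last[2]]
    best <- min(best, w)
  }
  mst2 <- haplotype_mst(ht_sub)
  expect_equal(attr(mst2, "total_steps"), best)

  # input-order invariance of the tree weight; repeated runs identical
  perm <- sample(H)
  ht_perm <- collapse_haplotypes(make_alignment(ht_sub$seqs[perm],
                                                rep("P", H)))
  expect_equal(attr(haplotype_mst(ht_perm), "total_steps"), best)
  expect_identical(haplotype_mst(ht_sub), haplotype_mst(ht_sub))
})
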