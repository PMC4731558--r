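# seapopgen

Population genetics and seascape connectivity for marine invasions.

Invasive fouling species such as bay barnacles spread both on ship hulls and
as drifting larvae, and the two dispersal modes leave different genetic
footprints. `seapopgen` implements the full analysis chain used to tease
them apart from multi-locality samples:

* **mtDNA sequence statistics** — haplotype collapsing, Nei's haplotype
  diversity `h = (n/(n-1))(1 - Σ p_k²)`, nucleotide diversity π, TN93+Γ
  distances, pairwise Φ_ST and hierarchical AMOVA (F_CT, F_SC, F_ST) with
  permutation tests, Slatkin linearization x/(1−x), mismatch-distribution
  fits of the sudden-expansion model (τ, θ₀, θ₁, SSD, Harpending's
  raggedness), Tajima's D and Fu's F_S with coalescent significance, BH
  false-discovery-rate control, and the minimum spanning haplotype network.
* **Microsatellite statistics** — H_E/H_O/F_IS, permutation tests of
  Hardy–Weinberg equilibrium and linkage disequilibrium, rarefied allelic
  richness, EM estimation of null-allele frequencies, Weir–Cockerham θ with
  and without the ENA null-allele correction, and the TPM
  heterozygosity-excess bottleneck test.
* **ABC scenario choice** — coalescent simulation of invasion scenarios
  (population-split trees, no migration) under uniform priors, conventional
  marker-specific summary statistics (including Goldstein's dμ²), rejection
  plus weighted polychotomous logistic regression posteriors, and a prior
  predictive check.
* **Larval dispersal** — RK4 Lagrangian particle tracking on gridded
  velocity fields, single-generation connectivity matrices
  (C_ij = fraction of locality *i*'s larvae ending in locality *j*),
  multi-generation stepping-stone connectivity C^G, and min-symmetrization.
* **Seascape correlation** — Mantel tests of linearized differentiation
  against geographic (shipping) distance and against minimum oceanographic
  connectivity.
* **Synthetic data** — a coalescent engine with splits and size changes,
  TN93+Γ sequence and GSM microsatellite simulators, two null-allele
  masking models, divergence-free gyre velocity fields, a forward-time
  metapopulation simulator, and a one-call Baltic-like reference bundle —
  so every stage is testable without any external download.

## Worked example

Generate the synthetic reference study (seven coastal localities, sequences,
genotypes with null alleles, shipping distances and a velocity field) and
run the whole pipeline:

```r
library(seapopgen)
bundle <- make_reference_dataset(tempfile("ref"), seed = 1, n_per_pop = 20)
res <- run_all(bundle, tempdir(),
               run_config(seed = 1, n_perm = 199, n_sim = 200,
                          particles = 200, dt_minutes = 180))
res$diversity[, c("population", "N", "n_hapl", "priv_per_N",
                  "h", "pi", "He", "Ho", "Ar")]
```

```
 population   N n_hapl priv_per_N     h     pi    He    Ho  Ar
        SAL  20      6       0.05 0.674 0.0027 0.794 0.646 7.4
        KIE  20      7       0.15 0.868 0.0075 0.736 0.579 7.7
        TOR  20      4       0.00 0.284 0.0032 0.810 0.605 7.9
        EST  20     13       0.40 0.942 0.0062 0.852 0.637 8.5
        ORE  20      7       0.00 0.800 0.0062 0.852 0.629 8.4
        UME  20      7       0.10 0.795 0.0065 0.840 0.583 7.9
        BOT  20      5       0.00 0.732 0.0068 0.868 0.740 9.1
      TOTAL 140     NA         NA    NA     NA    NA    NA  NA
```

One row per locality: sample size, haplotype count, the fraction of private
haplotypes, haplotype (h) and nucleotide (π) diversity from the sequences,
and expected/observed heterozygosity plus rarefied allelic richness from
the genotypes. The most distant pair along the colonisation chain is
clearly differentiated while the Mantel tests relate the whole matrix to
geography and to ocean transport:

```r
res$phist$mat[1, 7]      # Phi-ST, first vs northernmost locality
#> 0.238   (permutation p = 0.02)
res$mantel_table
#>              test          r     p     tail
#>      IBD_shipping  0.742     0.005 positive
#>  connectivity_G16 -0.301     0.070 negative
#>  connectivity_G32 -0.254     0.150 negative
```

Under this seed's colonisation-history-dominated data, shipping distance
explains differentiation (r = 0.74, one-tailed p = 0.005) and minimum
connectivity correlates negatively as hypothesised. `run_all()` also writes
every table (diversity, differentiation matrix with Φ_ST and ENA-corrected
θ, mismatch/neutrality report, MST edge list, AMOVA, connectivity matrices,
Mantel results) as CSV plus a JSON manifest into the output directory.

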