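# One-call generator of a complete Baltic-like synthetic study: sequences,
# genotypes with null alleles, localities, shipping distances and a velocity
# field, reproducible from a single seed.

#' Generate the reference synthetic dataset
#'
#' Writes a complete regional fixture to `dir`: seven coastal localities on a
#' gyre-driven shelf sea, mtDNA sequences and microsatellite genotypes
#' simulated under a south-to-north stepping-stone colonisation history,
#' per-locus null-allele masking, a shipping-distance matrix and a synthetic
#' velocity field. All randomness flows from `seed`.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param n_per_pop sequences/individuals sampled per locality.
#' @param L sequence length (bp).
#' @param n_loci microsatellite loci.
#' @param null_r baseline null-allele frequency applied to all but the last
#'   locus (the last stays clean, mirroring panels where one locus is
#'   null-free).
#' @return Invisibly, a list of the written file paths plus the in-memory
#'   objects.
#' @export
make_reference_dataset <- function(dir, seed = 1, n_per_pop = 24, L = 694,
                                   n_loci = 4, null_r = 0.25) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  pops <- c("SAL", "KIE", "TOR", "EST", "ORE", "UME", "BOT")
  # south-to-north stepping-stone colonisation out of the first locality
  events <- data.frame(
    derived = pops[-1],
    source = pops[-length(pops)],
    time = round(seq(3000, 300, length.out = length(pops) - 1)))
  ne <- setNames(rep(3e4, length(pops)), pops)
  scen <- scenario(pops, events, ne, id = "reference")
  prm <- sim_params(mu_seq = 4e-8, mu_ms = 1e-4)
  sizes <- setNames(rep(n_per_pop, length(pops)), pops)
  aln <- simulate_sequences(scen, prm, sizes, L)
  gt <- simulate_microsatellites(scen, prm, sizes, n_loci)
  r_tab <- matrix(null_r, length(pops), n_loci,
                  dimnames = list(pops, gt$loci))
  r_tab[, n_loci] <- 0
  gt_masked <- apply_null_alleles(gt, r_tab)
  field <- make_velocity_field(flow_field_spec(n_localities = length(pops)))
  names(field$habitat) <- pops
  # locality coordinates: along-coast arrangement (synthetic degrees)
  loc <- data.frame(name = pops,
                    lon = seq(11, 21, length.out = length(pops)),
                    lat = seq(55, 64, length.out = length(pops)),
                    group = c(rep("Baltic-S", 4), rep("Baltic-N", 3)))
  loc$cells <- unname(field$habitat[pops])
  # shipping distances: cumulative along-coast km with small detours
  along <- cumsum(c(0, round(runif(length(pops) - 1, 120, 420))))
  D <- abs(outer(along, along, "-"))
  dimnames(D) <- list(pops, pops)
  paths <- list(
    fasta = file.path(dir, "sequences.fasta"),
    popmap = file.path(dir, "population_map.csv"),
    genepop = file.path(dir, "genotypes.gen"),
    localities = file.path(dir, "localities.csv"),
    shipping = file.path(dir, "shipping_km.csv"),
    field = file.path(dir, "velocity_field.txt"))
  write_fasta_alignment(aln, paths$fasta)
  write.csv(data.frame(id = aln$ids, population = aln$population),
            paths$popmap, row.names = FALSE, quote = FALSE)
  write_genepop(gt_masked, paths$genepop)
  write_locality_csv(loc, paths$localities)
  write_matrix_csv(matrix_table(D, symmetric = TRUE), paths$shipping)
  write_velocity_field(field, paths$field)
  invisible(list(paths = paths, alignment = aln, genotypes = gt_masked,
                 genotypes_clean = gt, localities = loc,
                 shipping = matrix_table(D, symmetric = TRUE), field = field,
                 scenario = scen))
}
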