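# Sequence-based statistics on mtDNA haplotypes: haplotype collapsing,
# diversity indices, model distances and mismatch distributions.

#' Collapse an alignment into a haplotype table
#'
#' Identical sequences (exact string match over the full alignment, ambiguous
#' characters included as written) are merged into haplotypes; counts are
#' tallied per population. The table also records the number of polymorphic
#' sites and their transition/transversion classification (sites with more
#' than two observed bases count in both tallies per observed change type).
#'
#' @param alignment a [seq_alignment()].
#' @return An object of class `haplotype_table`: `seqs` (one representative
#'   per haplotype, most frequent first), `counts` (haplotypes x populations),
#'   `n` (per-population sample sizes), `L`, `n_polymorphic`,
#'   `n_transitions`, `n_transversions`.
#' @export
collapse_haplotypes <- function(alignment) {
  if (length(alignment$seqs) == 0) stop("empty alignment")
  u <- unique(alignment$seqs)
  pops <- unique(alignment$population)
  counts <- matrix(0L, length(u), length(pops),
                   dimnames = list(paste0("H", seq_along(u)), pops))
  hap_idx <- match(alignment$seqs, u)
  for (i in seq_along(hap_idx))
    counts[hap_idx[i], alignment$population[i]] <-
      counts[hap_idx[i], alignment$population[i]] + 1L
  ord <- order(-rowSums(counts))
  u <- u[ord]; counts <- counts[ord, , drop = FALSE]
  rownames(counts) <- paste0("H", seq_along(u))
  # site classification
  M <- do.call(rbind, strsplit(u, ""))
  ts <- tv <- poly <- 0L
  purines <- c("A", "G")
  for (s in seq_len(ncol(M))) {
    obs <- unique(M[, s]); obs <- obs[obs %in% c("A", "C", "G", "T")]
    if (length(obs) < 2) next
    poly <- poly + 1L
    prs <- combn(obs, 2)
    for (k in seq_len(ncol(prs))) {
      if (sum(prs[, k] %in% purines) == 1) tv <- tv + 1L else ts <- ts + 1L
    }
  }
  structure(list(seqs = u, counts = counts, n = colSums(counts),
                 L = alignment$L, n_polymorphic = poly,
                 n_transitions = ts, n_transversions = tv),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("Haplotype table:", length(x$seqs), "haplotypes,",
      ncol(x$counts), "populations,", x$L, "bp;",
      x$n_polymorphic, "polymorphic sites\n")
  invisible(x)
}

#' Nei's haplotype diversity
#'
#' `h = (n/(n-1)) * (1 - sum p_k^2)`: the sample-size-corrected probability
#' that two randomly drawn sequences carry different haplotypes.
#'
#' @param counts vector of haplotype counts within one population.
#' @return `h` in `[0, 1]` (`NA` when `n < 2`).
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Declare a molecular distance model
#'
#' @param name `"hamming"` (raw site-difference counts), `"p"` (proportion of
#'   differing sites) or `"tn93"` (Tamura-Nei 1993, optionally
#'   gamma-corrected).
#' @param alpha gamma shape for among-site rate variation (`Inf` = no
#'   correction); only used by `"tn93"`.
#' @param freqs base frequencies (A, C, G, T) for TN93, or `NULL` to use
#'   frequencies observed across the compared sequences.
#' @return A list of class `distance_model`.
#' @export
distance_model <- function(name = c("hamming", "p", "tn93"), alpha = Inf,
                           freqs = NULL) {
  name <- match.arg(name)
  stopifnot(alpha > 0)
  if (!is.null(freqs)) {
    stopifnot(length(freqs) == 4, all(freqs > 0))
    freqs <- freqs / sum(freqs)
  }
  structure(list(name = name, alpha = alpha, freqs = freqs),
            class = "distance_model")
}

# split sequences to comparable site matrix with pairwise deletion applied in
# the pairwise functions below
seq_to_chars <- function(s) strsplit(toupper(s), "")[[1]]

#' Tamura-Nei (1993) distance with gamma rate correction
#'
#' Sites with `N` or `-` in either sequence are excluded (pairwise deletion).
#' With a finite gamma shape `alpha`, every `-log(w)` term of the TN93 formula
#' is replaced by `alpha * (w^(-1/alpha) - 1)`; as `alpha -> Inf` the plain
#' TN93 distance is recovered. Distances are per site.
#'
#' @param seq_a,seq_b aligned sequences (equal length).
#' @param model a [distance_model()] with `name = "tn93"` (the `alpha` and
#'   `freqs` fields are honoured).
#' @return Nonnegative distance (substitutions/site).
#' @export
tn93_gamma_distance <- function(seq_a, seq_b, model = distance_model("tn93")) {
  a <- seq_to_chars(seq_a); b <- seq_to_chars(seq_b)
  if (length(a) != length(b)) stop("sequences have different lengths")
  keep <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(keep)) stop("zero comparable sites after pairwise deletion")
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  f <- model$freqs
  if (is.null(f)) {
    tab <- table(factor(c(a, b), levels = c("A", "C", "G", "T")))
    f <- as.numeric(tab) / sum(tab)
    if (any(f == 0)) f <- (f * sum(tab) + 0.5) / (sum(tab) + 2)  # guard
  }
  names(f) <- c("A", "C", "G", "T")
  gR <- f["A"] + f["G"]; gY <- f["C"] + f["T"]
  P1 <- sum((a == "A" & b == "G") | (a == "G" & b == "A")) / n
  P2 <- sum((a == "C" & b == "T") | (a == "T" & b == "C")) / n
  Q <- sum((a %in% c("A", "G")) != (b %in% c("A", "G"))) / n
  w1 <- 1 - gR * P1 / (2 * f["A"] * f["G"]) - Q / (2 * gR)
  w2 <- 1 - gY * P2 / (2 * f["C"] * f["T"]) - Q / (2 * gY)
  w3 <- 1 - Q / (2 * gR * gY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0)
    stop("saturation: TN93 log/power argument non-positive")
  neglog <- function(w) {
    if (is.finite(model$alpha)) model$alpha * (w^(-1 / model$alpha) - 1)
    else -log(w)
  }
  d <- 2 * f["A"] * f["G"] / gR * neglog(w1) +
    2 * f["C"] * f["T"] / gY * neglog(w2) +
    2 * (gR * gY - f["A"] * f["G"] * gY / gR - f["C"] * f["T"] * gR / gY) *
      neglog(w3)
  unname(d)
}

# pairwise distance between two sequences under a model; hamming returns raw
# counts, p and tn93 are per-site
seq_distance <- function(seq_a, seq_b, model) {
  if (model$name == "tn93") return(tn93_gamma_distance(seq_a, seq_b, model))
  a <- seq_to_chars(seq_a); b <- seq_to_chars(seq_b)
  keep <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(keep)) stop("zero comparable sites after pairwise deletion")
  d <- sum(a[keep] != b[keep])
  if (model$name == "p") d / sum(keep) else d
}

#' Pairwise distance matrix between haplotypes
#'
#' @param haplotable a [collapse_haplotypes()] table.
#' @param model a [distance_model()].
#' @return A symmetric numeric matrix (haplotypes x haplotypes).
#' @export
haplotype_distances <- function(haplotable, model = distance_model("hamming")) {
  H <- length(haplotable$seqs)
  D <- matrix(0, H, H, dimnames = list(rownames(haplotable$counts),
                                       rownames(haplotable$counts)))
  if (H < 2) return(D)
  for (i in 1:(H - 1)) for (j in (i + 1):H) {
    D[i, j] <- D[j, i] <- seq_distance(haplotable$seqs[i], haplotable$seqs[j],
                                       model)
  }
  D
}

#' Nucleotide diversity
#'
#' `pi = (n/(n-1)) * sum_{k != l} x_k x_l d_kl / L` under the Hamming model
#' (raw site differences divided by the alignment length); for per-site model
#' distances (`p`, `tn93`) the division by `L` is dropped since `d` is already
#' per site.
#'
#' @param haplotable a [collapse_haplotypes()] table.
#' @param population population label (column of the count matrix), or `NULL`
#'   to pool all populations.
#' @param model a [distance_model()].
#' @return Per-site nucleotide diversity (`NA` when `n < 2`).
#' @export
nucleotide_diversity <- function(haplotable, population = NULL,
                                 model = distance_model("hamming")) {
  counts <- if (is.null(population)) rowSums(haplotable$counts)
            else haplotable$counts[, population]
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  keep <- counts > 0
  D <- haplotype_distances(haplotable, model)[keep, keep, drop = FALSE]
  x <- counts[keep] / n
  s <- sum((x %o% x) * D)              # ordered pairs; diagonal d=0
  s <- if (model$name == "hamming") s / haplotable$L else s
  n / (n - 1) * s
}

#' Mean pairwise difference counts within a population
#'
#' @inheritParams nucleotide_diversity
#' @return Mean number of raw site differences over all sequence pairs.
#' @export
mean_pairwise_differences <- function(haplotable, population = NULL) {
  counts <- if (is.null(population)) rowSums(haplotable$counts)
            else haplotable$counts[, population]
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  keep <- counts > 0
  D <- haplotype_distances(haplotable, distance_model("hamming"))
  D <- D[keep, keep, drop = FALSE]
  cnt <- counts[keep]
  tot <- sum((cnt %o% cnt) * D) / 2    # unordered pairs
  tot / choose(n, 2)
}

#' Mismatch distribution
#'
#' Relative frequencies of pairwise raw site-difference counts `i = 0..d_max`
#' over all `C(n,2)` sequence pairs within one population. Mismatch theory is
#' defined on observed differences, so no model correction is applied.
#'
#' @inheritParams nucleotide_diversity
#' @return Named numeric vector of relative frequencies (names `0..d_max`).
#' @export
mismatch_distribution <- function(haplotable, population = NULL) {
  counts <- if (is.null(population)) rowSums(haplotable$counts)
            else haplotable$counts[, population]
  n <- sum(counts)
  if (n < 2) stop("need n >= 2 sequences")
  keep <- which(counts > 0)
  D <- haplotype_distances(haplotable, distance_model("hamming"))
  dmax <- 0
  tab <- numeric(haplotable$L + 1)
  for (ii in seq_along(keep)) for (jj in seq_len(ii)) {
    i <- keep[ii]; j <- keep[jj]
    npairs <- if (i == j) choose(counts[i], 2) else counts[i] * counts[j]
    if (npairs == 0) next
    d <- D[i, j]
    tab[d + 1] <- tab[d + 1] + npairs
    dmax <- max(dmax, d)
  }
  x <- tab[seq_len(dmax + 1)] / choose(n, 2)
  names(x) <- 0:dmax
  x
}

#' Harpending's raggedness index
#'
#' `R = sum_{i=1}^{d+1} (x_i - x_{i-1})^2` over the mismatch frequencies
#' `x_0..x_d`, with an empty class `x_{d+1} = 0` appended beyond the largest
#' observed difference.
#'
#' @param histogram mismatch relative frequencies starting at 0 differences.
#' @return Raggedness value.
#' @export
raggedness <- function(histogram) {
  x <- c(as.numeric(histogram), 0)
  sum(diff(x)^2)
}

#' Slatkin linearization of a fixation index
#'
#' `x / (1 - x)`, making differentiation approximately linear in distance
#' under stepping-stone models. Negative estimates pass through unchanged in
#' sign; values `>= 1` map to `Inf`.
#'
#' @param value fixation index (scalar, vector or matrix).
#' @return Transformed value(s) of the same shape.
#' @export
slatkin_linearize <- function(value) {
  out <- ifelse(value >= 1, Inf, value / (1 - value))
  if (is.matrix(value)) dimnames(out) <- dimnames(value)
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR control over a family of p-values.
#'
#' @param p_values numeric vector of p-values.
#' @param alpha nominal FDR level.
#' @return A list: `adjusted` (BH-adjusted p-values), `reject` (logical),
#'   `threshold` (the data-dependent raw-p rejection threshold; 0 when
#'   nothing is rejected).
#' @export
fdr_adjust <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0)
    return(list(adjusted = numeric(0), reject = logical(0), threshold = 0))
  adj <- p.adjust(p_values, method = "BH")
  m <- length(p_values)
  ord <- sort(p_values)
  ok <- which(ord <= seq_len(m) / m * alpha)
  threshold <- if (length(ok)) ord[max(ok)] else 0
  list(adjusted = adj, reject = p_values <= threshold & length(ok) > 0,
       threshold = threshold)
}
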