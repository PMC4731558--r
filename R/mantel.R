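# Mantel tests relating genetic differentiation to geographic distance
# (isolation by distance) and to oceanographic connectivity.

#' Mantel test between two distance matrices
#'
#' Pearson correlation over the `n(n-1)/2` off-diagonal pairs; the null
#' distribution permutes the row/column order of `B` jointly. P-values carry
#' the `(b+1)/(m+1)` correction: two-tailed uses `|r*| >= |r|`, one-tailed
#' uses the signed comparison in the hypothesised direction.
#'
#' @param A,B symmetric matrices (or [matrix_table()]s) with matching labels,
#'   `>= 4` localities.
#' @param n_perm permutations.
#' @param tail `"two"`, `"positive"` or `"negative"`.
#' @return A list of class `mantel_result`: `r`, `p`, `n_perm`, `tail`, `n`.
#' @export
mantel <- function(A, B, n_perm = 1000, tail = c("two", "positive",
                                                 "negative")) {
  tail <- match.arg(tail)
  a <- if (inherits(A, "matrix_table")) A$mat else as.matrix(A)
  b <- if (inherits(B, "matrix_table")) B$mat else as.matrix(B)
  if (!identical(dim(a), dim(b))) stop("matrix dimensions differ")
  if (!is.null(rownames(a)) && !is.null(rownames(b))) {
    if (!setequal(rownames(a), rownames(b))) stop("label mismatch")
    b <- b[rownames(a), rownames(a)]
  }
  n <- nrow(a)
  if (n < 4) stop("need >= 4 localities")
  ut <- upper.tri(a)
  if (sd(a[ut]) == 0 || sd(b[ut]) == 0)
    return(structure(list(r = NA_real_, p = NA_real_, n_perm = n_perm,
                          tail = tail, n = n, constant = TRUE),
                     class = "mantel_result"))
  r_obs <- cor(a[ut], b[ut])
  cnt <- 0L
  for (k in seq_len(n_perm)) {
    o <- sample.int(n)
    r_p <- cor(a[ut], b[o, o][ut])
    hit <- switch(tail,
                  two = abs(r_p) >= abs(r_obs),
                  positive = r_p >= r_obs,
                  negative = r_p <= r_obs)
    if (hit) cnt <- cnt + 1L
  }
  structure(list(r = r_obs, p = (cnt + 1) / (n_perm + 1), n_perm = n_perm,
                 tail = tail, n = n, constant = FALSE),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (%s-tailed, %d localities): r = %.4f, p = %.4g (%d permutations)\n",
              x$tail, x$n, x$r, x$p, x$n_perm))
  invisible(x)
}

# long-format pair table of two matrices' off-diagonal values
pair_table <- function(a, b, names = c("x", "y")) {
  labs <- rownames(a)
  ut <- which(upper.tri(a), arr.ind = TRUE)
  out <- data.frame(from = labs[ut[, 1]], to = labs[ut[, 2]],
                    a[upper.tri(a)], b[upper.tri(b)])
  names(out)[3:4] <- names
  out
}

#' Isolation-by-distance report
#'
#' One-tailed (positive) Mantel test of linearized genetic differentiation
#' against geographic (shipping) distance in km, plus the pair table behind
#' the scatter.
#'
#' @param genetic_matrix linearized differentiation ([matrix_table()] or
#'   matrix; apply [slatkin_linearize()] upstream).
#' @param geographic_matrix distances in km, same labels.
#' @param n_perm permutations.
#' @param tail test direction (default `"positive"`, the IBD hypothesis).
#' @return A list: `mantel` (a `mantel_result`) and `pairs` (data frame).
#' @export
ibd_report <- function(genetic_matrix, geographic_matrix, n_perm = 1000,
                       tail = "positive") {
  m <- mantel(genetic_matrix, geographic_matrix, n_perm, tail)
  a <- if (inherits(genetic_matrix, "matrix_table")) genetic_matrix$mat
       else as.matrix(genetic_matrix)
  b <- if (inherits(geographic_matrix, "matrix_table")) geographic_matrix$mat
       else as.matrix(geographic_matrix)
  b <- b[rownames(a), rownames(a)]
  list(mantel = m, pairs = pair_table(a, b, c("linearized_fst", "distance_km")))
}

#' Connectivity-vs-differentiation report
#'
#' One-tailed (negative) Mantel test of linearized genetic differentiation
#' against minimum multi-generation oceanographic connectivity
#' (min-symmetrized upstream), plus the pair table.
#'
#' @param genetic_matrix linearized differentiation.
#' @param connectivity_matrix symmetric connectivity.
#' @param n_perm permutations.
#' @param tail default `"negative"` (more connected pairs are expected to be
#'   less differentiated).
#' @param log_transform take `log10` of positive connectivities first
#'   (default `FALSE`).
#' @return A list: `mantel` and `pairs`.
#' @export
connectivity_report <- function(genetic_matrix, connectivity_matrix,
                                n_perm = 1000, tail = "negative",
                                log_transform = FALSE) {
  b <- if (inherits(connectivity_matrix, "matrix_table"))
    connectivity_matrix$mat else as.matrix(connectivity_matrix)
  if (log_transform) {
    floor_val <- min(b[b > 0]) / 10
    b <- log10(pmax(b, floor_val))
  }
  m <- mantel(genetic_matrix, b, n_perm, tail)
  a <- if (inherits(genetic_matrix, "matrix_table")) genetic_matrix$mat
       else as.matrix(genetic_matrix)
  b <- b[rownames(a), rownames(a)]
  list(mantel = m,
       pairs = pair_table(a, b, c("linearized_fst", "connectivity")))
}
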