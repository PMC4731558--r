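#' @keywords internal
"_PACKAGE"

#' @importFrom stats optim rbinom rgamma rgeom rnorm runif rpois rmultinom
#'   sd cor quantile p.adjust wilcox.test rexp setNames aggregate complete.cases
#' @importFrom utils read.csv write.csv head combn
NULL

# ---------------------------------------------------------------------------
# Sequence alignments
# ---------------------------------------------------------------------------

#' Construct a sequence alignment object
#'
#' Container for an aligned set of haploid sequences (one locus, e.g. a COI
#' fragment) with per-sample population labels.
#'
#' @param ids character vector of unique sample identifiers.
#' @param population character vector of population labels, same length.
#' @param seqs character vector of aligned sequences over `A,C,G,T,N,-`
#'   (case-insensitive), all the same length.
#' @return An object of class `seq_alignment` with elements `ids`,
#'   `population`, `seqs` and `L` (alignment length in bp).
#' @export
seq_alignment <- function(ids, population, seqs) {
  ids <- as.character(ids)
  population <- as.character(population)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs) || length(population) != length(seqs))
    stop("ids, population and seqs must have equal length")
  if (anyDuplicated(ids)) stop("sample ids must be unique")
  if (any(!nzchar(population)) || anyNA(population))
    stop("population labels must be nonempty")
  L <- unique(nchar(seqs))
  if (length(L) != 1)
    stop("alignment error: sequences have unequal lengths (",
         paste(sort(unique(nchar(seqs))), collapse = ", "), ")")
  if (L == 0 || length(seqs) == 0) stop("input error: empty alignment")
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad))
    stop("invalid residues in sequences: ", paste(ids[bad], collapse = ", "))
  structure(list(ids = ids, population = population, seqs = seqs, L = L),
            class = "seq_alignment")
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat("Sequence alignment:", length(x$ids), "samples x", x$L, "bp;",
      length(unique(x$population)), "populations\n")
  invisible(x)
}

#' Read a FASTA alignment with a population map
#'
#' @param path path to a FASTA file of aligned sequences.
#' @param population_map named character vector or two-column data frame
#'   (`id`, `population`) assigning each sample to a population.
#' @param unknown how to treat samples missing from the map: `"error"`
#'   (default) or `"UNKNOWN"` (assign the literal label `UNKNOWN`).
#' @return A [seq_alignment()].
#' @export
read_fasta_alignment <- function(path, population_map,
                                 unknown = c("error", "UNKNOWN")) {
  unknown <- match.arg(unknown)
  if (!file.exists(path)) stop("input error: file not found: ", path)
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0) stop("input error: empty FASTA file: ", path)
  seqs <- vapply(as.character(dna), function(s) paste(toupper(s), collapse = ""),
                 character(1))
  ids <- names(dna)
  if (is.data.frame(population_map)) {
    population_map <- setNames(as.character(population_map[[2]]),
                               as.character(population_map[[1]]))
  }
  pop <- unname(population_map[ids])
  if (anyNA(pop)) {
    missing_ids <- ids[is.na(pop)]
    if (unknown == "error")
      stop("samples lacking a population mapping: ",
           paste(missing_ids, collapse = ", "))
    pop[is.na(pop)] <- "UNKNOWN"
  }
  message(sprintf("read_fasta_alignment: parsed %d samples from %s",
                  length(ids), path))
  seq_alignment(ids, pop, seqs)
}

#' Write an alignment to FASTA
#'
#' @param alignment a [seq_alignment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(alignment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(alignment$ids)) {
    writeLines(c(paste0(">", alignment$ids[i]), alignment$seqs[i]), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# GENEPOP genotype tables
# ---------------------------------------------------------------------------

#' Construct a genotype table
#'
#' Diploid codominant genotypes (allele calls as positive integers, e.g.
#' fragment sizes or repeat counts) for a set of individuals at one or more
#' loci. Missing calls are `NA`.
#'
#' @param ids character vector of individual identifiers.
#' @param population per-individual population labels.
#' @param loci character vector of locus names.
#' @param a1,a2 integer matrices (`length(ids)` x `length(loci)`) holding the
#'   two allele calls per genotype; both `NA` where the genotype is missing.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(ids, population, loci, a1, a2) {
  ids <- as.character(ids); population <- as.character(population)
  loci <- as.character(loci)
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (nrow(a1) != length(ids) || ncol(a1) != length(loci) ||
      !identical(dim(a1), dim(a2)))
    stop("allele matrices must be n_individuals x n_loci")
  if (any(xor(is.na(a1), is.na(a2))))
    stop("half-missing genotypes: both alleles must be present or both NA")
  if (any(a1 <= 0, na.rm = TRUE) || any(a2 <= 0, na.rm = TRUE))
    stop("allele values must be positive integers")
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  structure(list(ids = ids, population = population, loci = loci,
                 a1 = a1, a2 = a2),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("Genotype table:", length(x$ids), "individuals x", length(x$loci),
      "loci;", length(unique(x$population)), "populations\n")
  invisible(x)
}

#' Read a GENEPOP file
#'
#' Accepts the GENEPOP 4.x dialect: a title line, one locus name per line (or
#' comma-separated), `POP` separators, and per-individual lines
#' `name , 120140 0902...` with concatenated 2- or 3-digit allele codes.
#' The digit width is detected per locus and must be consistent within the
#' file; `000`/`00` codes decode to missing.
#'
#' @param path path to a GENEPOP text file.
#' @return A [genotype_table()] whose population labels are taken from the
#'   first individual name in each `POP` block (GENEPOP convention).
#' @export
read_genepop <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stop("format error: truncated GENEPOP file")
  body <- lines[-1]                      # drop title
  is_pop <- toupper(trimws(body)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("format error: no POP separator found")
  locus_lines <- body[seq_len(first_pop - 1)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0) stop("format error: no locus names")
  recs <- body[seq(first_pop, length(body))]
  pop_idx <- cumsum(toupper(trimws(recs)) == "POP")
  ind_lines <- recs[toupper(trimws(recs)) != "POP"]
  ind_pop_idx <- pop_idx[toupper(trimws(recs)) != "POP"]
  n <- length(ind_lines)
  if (n == 0) stop("format error: no individuals")
  ids <- character(n); codes <- vector("list", n)
  for (i in seq_len(n)) {
    parts <- strsplit(ind_lines[i], ",")[[1]]
    if (length(parts) < 2) stop("format error: missing comma in line: ",
                                ind_lines[i])
    ids[i] <- trimws(parts[1])
    codes[[i]] <- strsplit(trimws(paste(parts[-1], collapse = " ")),
                           "[[:space:]]+")[[1]]
    if (length(codes[[i]]) != length(loci))
      stop("format error: expected ", length(loci), " genotypes, got ",
           length(codes[[i]]), " for individual ", ids[i])
  }
  code_mat <- do.call(rbind, codes)
  widths <- nchar(code_mat)
  a1 <- matrix(NA_integer_, n, length(loci))
  a2 <- matrix(NA_integer_, n, length(loci))
  for (j in seq_along(loci)) {
    w <- unique(widths[, j])
    if (length(w) != 1 || !(w %in% c(4L, 6L)))
      stop("format error: mixed or invalid allele-code widths at locus ",
           loci[j])
    d <- w / 2
    x1 <- as.integer(substr(code_mat[, j], 1, d))
    x2 <- as.integer(substr(code_mat[, j], d + 1, w))
    x1[x1 == 0L] <- NA_integer_; x2[x2 == 0L] <- NA_integer_
    # one null code renders the whole call missing (unordered pair)
    miss <- is.na(x1) | is.na(x2)
    x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
    a1[, j] <- pmin(x1, x2); a2[, j] <- pmax(x1, x2)
  }
  # population label = name of the first individual per block (convention)
  pop_labels <- tapply(ids, ind_pop_idx, function(v) v[1])
  population <- unname(pop_labels[as.character(ind_pop_idx)])
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  message(sprintf("read_genepop: parsed %d individuals, %d loci, %d POP blocks from %s",
                  n, length(loci), max(ind_pop_idx), path))
  genotype_table(ids, population, loci, a1, a2)
}

#' Write a genotype table in GENEPOP format
#'
#' @param genotypes a [genotype_table()].
#' @param path output path.
#' @param digits allele-code width, 2 or 3 (default 3).
#' @param title title line.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(genotypes, path, digits = 3,
                          title = "seapopgen genotype export") {
  stopifnot(digits %in% c(2, 3))
  fmt <- paste0("%0", digits, "d")
  if (any(genotypes$a1 >= 10^digits, na.rm = TRUE) ||
      any(genotypes$a2 >= 10^digits, na.rm = TRUE))
    stop("allele values do not fit in ", digits, "-digit codes")
  enc <- function(x) ifelse(is.na(x), paste(rep("0", digits), collapse = ""),
                            sprintf(fmt, x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(genotypes$loci, con)
  pops <- unique(genotypes$population)
  for (p in pops) {
    writeLines("POP", con)
    rows <- which(genotypes$population == p)
    for (i in rows) {
      g <- paste0(enc(genotypes$a1[i, ]), enc(genotypes$a2[i, ]))
      writeLines(paste0(genotypes$ids[i], " , ", paste(g, collapse = " ")), con)
    }
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Labelled matrices and locality tables
# ---------------------------------------------------------------------------

#' Construct a labelled square matrix (optionally with p-values)
#'
#' @param mat square numeric matrix with row/column names.
#' @param p optional matrix of p-values with the same dimensions.
#' @param symmetric logical; validate symmetry.
#' @return An object of class `matrix_table` (a list with `labels`, `mat`,
#'   `p`).
#' @export
matrix_table <- function(mat, p = NULL, symmetric = FALSE) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("format error: matrix is not square")
  labels <- rownames(mat)
  if (is.null(labels)) labels <- paste0("L", seq_len(nrow(mat)))
  dimnames(mat) <- list(labels, labels)
  if (symmetric && !isTRUE(all.equal(mat, t(mat), tolerance = 1e-8,
                                     check.attributes = FALSE)))
    stop("validation error: matrix is not symmetric")
  if (!is.null(p)) {
    p <- as.matrix(p)
    if (!identical(dim(p), dim(mat)))
      stop("p-value matrix dimensions do not match")
    dimnames(p) <- dimnames(mat)
  }
  structure(list(labels = labels, mat = mat, p = p, symmetric = symmetric),
            class = "matrix_table")
}

#' Read a labelled square matrix from CSV
#'
#' Expects a header row and a leading label column matching the header.
#'
#' @param path CSV path.
#' @param symmetric require symmetry (validation error otherwise).
#' @return A [matrix_table()].
#' @export
read_matrix_csv <- function(path, symmetric = FALSE) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  labels <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(m) != ncol(m))
    stop("format error: matrix is ", nrow(m), "x", ncol(m), ", not square")
  storage.mode(m) <- "double"
  rownames(m) <- labels
  if (!identical(labels, colnames(m)))
    stop("format error: row labels do not match column labels")
  matrix_table(m, symmetric = symmetric)
}

#' Write a labelled square matrix to CSV
#'
#' Floats are written with 6 significant digits.
#'
#' @param mt a [matrix_table()] or plain named matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(mt, path) {
  m <- if (inherits(mt, "matrix_table")) mt$mat else as.matrix(mt)
  out <- data.frame(label = rownames(m), signif(m, 6), check.names = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a locality table from CSV
#'
#' Columns: `name`, `lon`, `lat`, `group`, and optionally `cells`
#' (semicolon-separated linear grid-cell indices of the habitat cells).
#'
#' @param path CSV path.
#' @return A data frame with a `cells` list-column of integer vectors.
#' @export
read_locality_csv <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "lon", "lat", "group")
  if (!all(need %in% names(df)))
    stop("format error: locality CSV needs columns ",
         paste(need, collapse = ", "))
  if (anyDuplicated(df$name)) stop("validation error: locality names not unique")
  if (any(df$lon < -180 | df$lon > 360 | df$lat < -90 | df$lat > 90))
    stop("validation error: coordinates out of range")
  df$cells <- if ("cells" %in% names(df)) {
    lapply(strsplit(as.character(df$cells), ";"), as.integer)
  } else rep(list(integer(0)), nrow(df))
  df
}

#' Write a locality table to CSV
#'
#' @param localities data frame as returned by [read_locality_csv()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_locality_csv <- function(localities, path) {
  df <- localities
  df$cells <- vapply(df$cells, paste, character(1), collapse = ";")
  write.csv(df[, c("name", "lon", "lat", "group", "cells")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}
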