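# Lagrangian particle tracking of larvae on gridded velocity fields, reduced
# to single- and multi-generation connectivity matrices between habitat
# localities.

#' Specify a particle release
#'
#' @param particles_per_locality total particles released from each locality
#'   (spread evenly over its cells and the release times).
#' @param release_hours vector of release times (hours from the start of the
#'   velocity record); the default spreads releases across a full gyre
#'   oscillation period so both current directions are sampled.
#' @param pld_days length-2 vector: bounds of the uniform pelagic larval
#'   duration (days).
#' @param dt_minutes tracking time step (minutes).
#' @return A list of class `release_spec`.
#' @export
release_spec <- function(particles_per_locality = 470,
                         release_hours = seq(0, 216, by = 24),
                         pld_days = c(20, 30), dt_minutes = 15) {
  stopifnot(particles_per_locality >= 1, pld_days[1] <= pld_days[2],
            dt_minutes > 0, all(release_hours >= 0))
  structure(list(particles_per_locality = particles_per_locality,
                 release_hours = release_hours, pld_days = pld_days,
                 dt_minutes = dt_minutes),
            class = "release_spec")
}

# bilinear interpolation of a node-centred nx x ny slice at positions (km);
# node (i,j) sits at ((i-0.5)*dx, (j-0.5)*dx); outside-domain queries clamp
interp_bilinear <- function(slice, x, y, dx_km) {
  nx <- nrow(slice); ny <- ncol(slice)
  fx <- pmin(pmax(x / dx_km - 0.5, 0), nx - 1)
  fy <- pmin(pmax(y / dx_km - 0.5, 0), ny - 1)
  i0 <- pmin(floor(fx) + 1, nx - 1); j0 <- pmin(floor(fy) + 1, ny - 1)
  tx <- fx - (i0 - 1); ty <- fy - (j0 - 1)
  s00 <- slice[cbind(i0, j0)];     s10 <- slice[cbind(i0 + 1, j0)]
  s01 <- slice[cbind(i0, j0 + 1)]; s11 <- slice[cbind(i0 + 1, j0 + 1)]
  (1 - tx) * (1 - ty) * s00 + tx * (1 - ty) * s10 +
    (1 - tx) * ty * s01 + tx * ty * s11
}

# velocity (m/s) at positions and absolute time t_hours, with linear temporal
# interpolation between stored slices
field_velocity <- function(field, x, y, t_hours) {
  times <- field$times
  nt <- length(times)
  t_hours <- min(max(t_hours, times[1]), times[nt])
  k0 <- min(max(findInterval(t_hours, times), 1), nt - 1)
  w <- (t_hours - times[k0]) / (times[k0 + 1] - times[k0])
  u <- (1 - w) * interp_bilinear(field$u[, , k0], x, y, field$dx_km) +
    w * interp_bilinear(field$u[, , k0 + 1], x, y, field$dx_km)
  v <- (1 - w) * interp_bilinear(field$v[, , k0], x, y, field$dx_km) +
    w * interp_bilinear(field$v[, , k0 + 1], x, y, field$dx_km)
  list(u = u, v = v)
}

cell_of <- function(field, x, y) {
  i <- pmin(pmax(ceiling(x / field$dx_km), 1), field$nx)
  j <- pmin(pmax(ceiling(y / field$dx_km), 1), field$ny)
  (j - 1L) * field$nx + i
}

cell_centre <- function(field, cells) {
  i <- (cells - 1L) %% field$nx + 1L
  j <- (cells - 1L) %/% field$nx + 1L
  list(x = (i - 0.5) * field$dx_km, y = (j - 0.5) * field$dx_km)
}

#' Advect larvae through a velocity field
#'
#' Integrates `dx/dt = u(x, t)` for every particle with classical 4th-order
#' Runge-Kutta at the tracking time step, using bilinear spatial and linear
#' temporal interpolation of the stored velocity slices. Each particle draws
#' an independent uniform pelagic larval duration (PLD) within the configured
#' bounds and its endpoint is its position when that PLD expires. Land
#' encounters are resolved free-slip: a sub-step that would land a particle on
#' a land cell keeps only the along-shore component (x-only or y-only move),
#' or holds the particle in place in a dead end.
#'
#' @param field a `velocity_field` from [make_velocity_field()] or
#'   [read_velocity_field()].
#' @param spec a [release_spec()].
#' @return A data frame with one row per particle: `locality`, release
#'   position (`x0`, `y0`, km), endpoint (`x`, `y`), `end_cell` and `pld_days`.
#' @export
advect <- function(field, spec) {
  max_pld_h <- spec$pld_days[2] * 24
  horizon <- max(spec$release_hours) + max_pld_h
  if (horizon > max(field$times) + 1e-9)
    stop("horizon too short: field record ends at ", max(field$times),
         " h but releases need ", horizon, " h")
  locs <- field$habitat
  parts <- list()
  for (nm in names(locs)) {
    cells <- locs[[nm]]
    if (any(!field$mask[cells])) stop("release on land in locality ", nm)
    n <- spec$particles_per_locality
    slots <- expand.grid(cell = cells, t0 = spec$release_hours)
    idx <- rep(seq_len(nrow(slots)), length.out = n)
    cc <- cell_centre(field, slots$cell[idx])
    parts[[nm]] <- data.frame(locality = nm, x0 = cc$x, y0 = cc$y,
                              t0 = slots$t0[idx])
  }
  P <- do.call(rbind, parts)
  rownames(P) <- NULL
  P$pld_days <- runif(nrow(P), spec$pld_days[1], spec$pld_days[2])
  x <- P$x0; y <- P$y0
  end_h <- P$t0 + P$pld_days * 24
  dt_h <- spec$dt_minutes / 60
  t_grid <- seq(0, max(end_h) + dt_h, by = dt_h)
  km_per_h <- 3.6                     # (m/s) -> km/h
  for (s in seq_len(length(t_grid) - 1)) {
    t <- t_grid[s]
    active <- which(P$t0 <= t & end_h > t)
    if (!length(active)) next
    h <- dt_h
    xa <- x[active]; ya <- y[active]
    k1 <- field_velocity(field, xa, ya, t)
    k2 <- field_velocity(field, xa + 0.5 * h * k1$u * km_per_h,
                         ya + 0.5 * h * k1$v * km_per_h, t + 0.5 * h)
    k3 <- field_velocity(field, xa + 0.5 * h * k2$u * km_per_h,
                         ya + 0.5 * h * k2$v * km_per_h, t + 0.5 * h)
    k4 <- field_velocity(field, xa + h * k3$u * km_per_h,
                         ya + h * k3$v * km_per_h, t + h)
    # particles settling inside this step integrate only to their own PLD
    h_i <- pmin(h, end_h[active] - t)
    dx <- h_i / 6 * (k1$u + 2 * k2$u + 2 * k3$u + k4$u) * km_per_h
    dy <- h_i / 6 * (k1$v + 2 * k2$v + 2 * k3$v + k4$v) * km_per_h
    xn <- xa + dx; yn <- ya + dy
    on_land <- !field$mask[cell_of(field, xn, yn)]
    if (any(on_land)) {
      w <- which(on_land)
      ok_x <- field$mask[cell_of(field, xn[w], ya[w])]
      xn[w] <- ifelse(ok_x, xn[w], xa[w])
      yn[w] <- ya[w]
      ok_y <- field$mask[cell_of(field, xn[w], yn[w] + dy[w])]
      yn[w] <- ifelse(ok_y, yn[w] + dy[w], yn[w])
    }
    x[active] <- xn; y[active] <- yn
  }
  P$x <- x; P$y <- y
  P$end_cell <- cell_of(field, x, y)
  P[, c("locality", "x0", "y0", "x", "y", "end_cell", "pld_days")]
}

#' Reduce particle endpoints to a connectivity matrix
#'
#' `C[i, j]` is the fraction of particles released at locality `i` whose end
#' position falls inside locality `j` (including `i` itself: self-
#' recruitment). Particles ending outside every locality are lost, so rows sum
#' to at most 1.
#'
#' @param endpoints data frame from [advect()].
#' @param localities named list of disjoint cell-index vectors (e.g.
#'   `field$habitat`).
#' @return A [matrix_table()] of dispersal probabilities.
#' @export
connectivity <- function(endpoints, localities) {
  all_cells <- unlist(localities)
  if (anyDuplicated(all_cells)) stop("spec error: overlapping localities")
  nms <- names(localities)
  C <- matrix(0, length(nms), length(nms), dimnames = list(nms, nms))
  for (i in nms) {
    rows <- endpoints$locality == i
    n_i <- sum(rows)
    for (j in nms)
      C[i, j] <- sum(endpoints$end_cell[rows] %in% localities[[j]]) / n_i
  }
  matrix_table(C)
}

#' Multi-generation stepping-stone connectivity
#'
#' Chains single-generation dispersal over `G` events, summing over all
#' possible stepping-stone routes: the matrix power `C^G`.
#'
#' @param C a connectivity [matrix_table()] or plain matrix.
#' @param G number of generations (positive integer).
#' @return A [matrix_table()].
#' @export
multigeneration <- function(C, G) {
  if (G < 1) stop("G must be >= 1")
  m <- if (inherits(C, "matrix_table")) C$mat else as.matrix(C)
  out <- diag(nrow(m))
  base <- m
  g <- as.integer(G)
  while (g > 0) {                      # exponentiation by squaring
    if (g %% 2L == 1L) out <- out %*% base
    base <- base %*% base
    g <- g %/% 2L
  }
  dimnames(out) <- dimnames(m)
  matrix_table(out)
}

#' Symmetrise a matrix by pairwise minima
#'
#' `S[i,j] = min(M[i,j], M[j,i])`; the diagonal is preserved. Used to make
#' (asymmetric) connectivity comparable with symmetric genetic distances.
#'
#' @param M a [matrix_table()] or plain square matrix.
#' @return A symmetric [matrix_table()].
#' @export
symmetrize_min <- function(M) {
  m <- if (inherits(M, "matrix_table")) M$mat else as.matrix(M)
  s <- pmin(m, t(m))
  diag(s) <- diag(m)
  matrix_table(s, symmetric = TRUE)
}
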