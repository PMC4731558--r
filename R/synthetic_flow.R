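# Synthetic velocity fields: a divergence-free, time-varying double-gyre
# derived from a discrete stream function over a masked grid. Stands in for
# archived circulation-model output so dispersal runs are reproducible from a
# seed.

#' Specify a synthetic flow field
#'
#' @param nx,ny grid dimensions (cells).
#' @param dx_km grid spacing (km); default 3.7 as for a ~1/30 degree regional
#'   model.
#' @param dt_hours cadence of stored velocity slices (hours); default 3.
#' @param duration_days length of the stored record (days).
#' @param amplitude gyre stream-function amplitude (m^2/s); sets the velocity
#'   scale (~amplitude * pi / (ny * dx)).
#' @param period_days period of the gyre oscillation (days).
#' @param noise relative amplitude of the seeded random stream-function
#'   perturbation (0 disables it).
#' @param land_border width (cells) of the land frame around the domain.
#' @param habitat named list of localities, each an integer vector of 10
#'   linear cell indices (column-major over the nx x ny grid). `NULL` lays out
#'   default coastal localities.
#' @param n_localities number of default habitat localities when
#'   `habitat = NULL`.
#' @param max_habitat_depth habitat depth cutoff (m); cells deeper than this
#'   cannot be habitat (deep basins are anoxic for settling larvae).
#' @return A list of class `flow_field_spec`.
#' @export
flow_field_spec <- function(nx = 40, ny = 30, dx_km = 3.7, dt_hours = 3,
                            duration_days = 40, amplitude = 1200,
                            period_days = 10, noise = 0.9, land_border = 2,
                            habitat = NULL, n_localities = 7,
                            max_habitat_depth = 100) {
  stopifnot(dx_km > 0, dt_hours > 0, duration_days > 0, nx > 2 * land_border + 4,
            ny > 2 * land_border + 4)
  structure(list(nx = nx, ny = ny, dx_km = dx_km, dt_hours = dt_hours,
                 duration_days = duration_days, amplitude = amplitude,
                 period_days = period_days, noise = noise,
                 land_border = land_border, habitat = habitat,
                 n_localities = n_localities,
                 max_habitat_depth = max_habitat_depth),
            class = "flow_field_spec")
}

# default depth profile: shallow shelf near the southern coast deepening
# northwards, with a deep central basin
default_bathymetry <- function(nx, ny, land_border) {
  depth <- matrix(0, nx, ny)
  for (j in seq_len(ny)) {
    frac <- (j - land_border) / (ny - 2 * land_border)
    depth[, j] <- pmax(0, 15 + 260 * frac * (1 - frac) * 4 * 0.6)
  }
  # shallower near east/west coasts
  for (i in seq_len(nx)) {
    fx <- (i - land_border) / (nx - 2 * land_border)
    depth[i, ] <- depth[i, ] * pmin(1, 4 * fx * (1 - fx) + 0.3)
  }
  # coastal shelf: the two water rows fringing each shore stay shallow
  shelf <- c(land_border + 1:2, ny - land_border - 1:0)
  shelf <- shelf[shelf >= 1 & shelf <= ny]
  depth[, shelf] <- pmin(depth[, shelf], 70)
  depth
}

#' Generate a synthetic velocity field
#'
#' Builds a discrete stream function `psi` (an oscillating double gyre plus a
#' smooth seeded perturbation), and derives `u = -dpsi/dy`, `v = +dpsi/dx` by
#' central differences, so the same central-difference divergence vanishes
#' identically at interior water nodes. Land cells carry zero velocity.
#'
#' @param spec a [flow_field_spec()].
#' @return An object of class `velocity_field`: grid metadata, `times`
#'   (hours), arrays `u`, `v` (`nx x ny x n_times`, m/s), logical water `mask`,
#'   `depth` (m) and the `habitat` list of cell-index vectors.
#' @export
make_velocity_field <- function(spec) {
  nx <- spec$nx; ny <- spec$ny; b <- spec$land_border
  mask <- matrix(FALSE, nx, ny)
  mask[(b + 1):(nx - b), (b + 1):(ny - b)] <- TRUE
  depth <- default_bathymetry(nx, ny, b)
  depth[!mask] <- 0
  times <- seq(0, spec$duration_days * 24, by = spec$dt_hours)
  dx_m <- spec$dx_km * 1000
  xg <- ((seq_len(nx)) - 0.5) / nx
  yg <- ((seq_len(ny)) - 0.5) / ny
  # random smooth perturbation: low-order Fourier modes, each oscillating
  # with its own period and phase so the time-mean flow is (near) zero and
  # along-coast currents reverse -- larvae make excursions both ways
  nmodes <- 3
  kx <- sample(1:3, nmodes, replace = TRUE)
  ky <- sample(1:3, nmodes, replace = TRUE)
  ph <- runif(nmodes, 0, 2 * pi)
  period_m <- runif(nmodes, 0.4, 1.2) * spec$period_days * 24
  tphase <- runif(nmodes, 0, 2 * pi)
  amp <- rnorm(nmodes, 0, spec$noise * spec$amplitude / nmodes)
  u <- array(0, c(nx, ny, length(times)))
  v <- array(0, c(nx, ny, length(times)))
  for (k in seq_along(times)) {
    phase <- 2 * pi * times[k] / (spec$period_days * 24)
    psi <- outer(sin(2 * pi * xg), sin(pi * yg)) *
      spec$amplitude * sin(phase)
    for (m in seq_len(nmodes)) {
      psi <- psi + amp[m] * cos(2 * pi * times[k] / period_m[m] + tphase[m]) *
        outer(sin(pi * kx[m] * xg + ph[m]), sin(pi * ky[m] * yg))
    }
    # central differences (one-sided at domain edges; edges are land anyway)
    dpsi_dy <- (psi[, c(2:ny, ny)] - psi[, c(1, 1:(ny - 1))]) /
      ((col(psi)[, c(2:ny, ny)] - col(psi)[, c(1, 1:(ny - 1))]) * dx_m)
    dpsi_dx <- (psi[c(2:nx, nx), ] - psi[c(1, 1:(nx - 1)), ]) /
      ((row(psi)[c(2:nx, nx), ] - row(psi)[c(1, 1:(nx - 1)), ]) * dx_m)
    uk <- -dpsi_dy; vk <- dpsi_dx
    uk[!mask] <- 0; vk[!mask] <- 0
    u[, , k] <- uk; v[, , k] <- vk
  }
  habitat <- spec$habitat
  if (is.null(habitat)) {
    habitat <- default_habitat(mask, depth, spec$max_habitat_depth,
                               spec$n_localities)
  }
  for (nm in names(habitat)) {
    cells <- habitat[[nm]]
    if (any(!mask[cells]))
      stop("spec error: habitat locality ", nm, " contains land cells")
    if (any(depth[cells] > spec$max_habitat_depth))
      stop("spec error: habitat locality ", nm, " deeper than cutoff")
  }
  structure(list(nx = nx, ny = ny, dx_km = spec$dx_km, times = times,
                 u = u, v = v, mask = mask, depth = depth, habitat = habitat,
                 max_habitat_depth = spec$max_habitat_depth),
            class = "velocity_field")
}

# place n localities of 10 cells (5x2 patches) along the shallow southern
# coastal strip, evenly spaced in x
default_habitat <- function(mask, depth, max_depth, n) {
  nx <- nrow(mask); ny <- ncol(mask)
  ok <- mask & depth <= max_depth & depth > 0
  jrow <- which.max(apply(ok, 2, any))      # first water row from the south
  first_x <- which.max(apply(ok, 1, any))
  last_x <- nx + 1 - which.max(apply(ok[nx:1, , drop = FALSE], 1, any))
  spacing <- if (n > 1) floor((last_x - first_x - 4) / (n - 1)) else 0
  if (spacing < 5 && n > 1)
    stop("spec error: grid too small for ", n, " disjoint 5x2 localities")
  xs <- first_x + (seq_len(n) - 1) * spacing
  habitat <- list()
  for (k in seq_len(n)) {
    cells <- as.vector(outer(xs[k] + 0:4, (jrow + 0:1 - 1) * nx, "+"))
    habitat[[paste0("L", k)]] <- cells
  }
  habitat
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("Velocity field: %d x %d cells (%.1f km), %d slices every %g h, %d localities\n",
              x$nx, x$ny, x$dx_km, length(x$times), diff(x$times[1:2]),
              length(x$habitat)))
  invisible(x)
}

#' Write / read a velocity field as plain text
#'
#' Gridded container with dimensions x, y, time and variables u, v, depth,
#' mask, serialised as a small header plus long-format CSV blocks.
#'
#' @param field a `velocity_field`.
#' @param path output path.
#' @return `path` (writer) or a `velocity_field` (reader).
#' @export
write_velocity_field <- function(field, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# seapopgen velocity field v1",
    paste0("nx,", field$nx), paste0("ny,", field$ny),
    paste0("dx_km,", field$dx_km),
    paste0("max_habitat_depth,", field$max_habitat_depth),
    paste0("times_hours,", paste(field$times, collapse = ";")),
    paste0("habitat,", paste(vapply(names(field$habitat), function(nm)
      paste0(nm, ":", paste(field$habitat[[nm]], collapse = ";")),
      character(1)), collapse = "|")),
    paste0("mask,", paste(as.integer(field$mask), collapse = ";")),
    paste0("depth,", paste(signif(field$depth, 6), collapse = ";"))), con)
  for (k in seq_along(field$times)) {
    writeLines(paste0("u,", k, ",", paste(signif(field$u[, , k], 6),
                                          collapse = ";")), con)
    writeLines(paste0("v,", k, ",", paste(signif(field$v[, , k], 6),
                                          collapse = ";")), con)
  }
  invisible(path)
}

#' @rdname write_velocity_field
#' @export
read_velocity_field <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (lines[1] != "# seapopgen velocity field v1")
    stop("format error: not a seapopgen velocity field file")
  kv <- function(key) {
    ln <- lines[startsWith(lines, paste0(key, ","))][1]
    sub(paste0("^", key, ","), "", ln)
  }
  nx <- as.integer(kv("nx")); ny <- as.integer(kv("ny"))
  dx_km <- as.numeric(kv("dx_km"))
  times <- as.numeric(strsplit(kv("times_hours"), ";")[[1]])
  hab_raw <- strsplit(kv("habitat"), "|", fixed = TRUE)[[1]]
  habitat <- lapply(hab_raw, function(h)
    as.integer(strsplit(strsplit(h, ":")[[1]][2], ";")[[1]]))
  names(habitat) <- vapply(hab_raw, function(h) strsplit(h, ":")[[1]][1],
                           character(1))
  mask <- matrix(as.integer(strsplit(kv("mask"), ";")[[1]]) == 1L, nx, ny)
  depth <- matrix(as.numeric(strsplit(kv("depth"), ";")[[1]]), nx, ny)
  u <- array(0, c(nx, ny, length(times)))
  v <- array(0, c(nx, ny, length(times)))
  for (ln in lines[grepl("^[uv],", lines)]) {
    parts <- strsplit(ln, ",")[[1]]
    k <- as.integer(parts[2])
    vals <- matrix(as.numeric(strsplit(parts[3], ";")[[1]]), nx, ny)
    if (parts[1] == "u") u[, , k] <- vals else v[, , k] <- vals
  }
  structure(list(nx = nx, ny = ny, dx_km = dx_km, times = times, u = u,
                 v = v, mask = mask, depth = depth, habitat = habitat,
                 max_habitat_depth = as.numeric(kv("max_habitat_depth"))),
            class = "velocity_field")
}
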