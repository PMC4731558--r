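test_that("still water keeps particles at their release points", {
  set.seed(1)
  f <- constant_field(0, 0, habitat = list(A = c(163, 164), B = c(200, 201)))
  ep <- advect(f, release_spec(10, release_hours = 0, pld_days = c(1, 2),
                               dt_minutes = 120))
  expect_equal(ep$x, ep$x0)
  expect_equal(ep$y, ep$y0)
  C <- connectivity(ep, f$habitat)
  expect_equal(unname(C$mat), diag(2))
})

test_that("constant flow displaces particles by exactly u * PLD", {
  set.seed(2)
  f <- constant_field(0.1, 0)
  ep <- advect(f, release_spec(4, release_hours = 0, pld_days = c(20, 20),
                               dt_minutes = 60))
  # 0.1 m/s * 20 d * 86400 s/d = 172.8 km
  expect_equal(ep$x - ep$x0, rep(172.8, 4), tolerance = 1e-9)
  expect_equal(ep$y, ep$y0)
})

test_that("RK4 conserves the radius of a solid-body rotation to 0.1%", {
  nx <- 60; ny <- 60; dx <- 2
  cx <- nx * dx / 2; cy <- ny * dx / 2
  omega <- 2 * pi / (5 * 86400)          # one orbit per 5 days
  xs <- ((1:nx) - 0.5) * dx; ys <- ((1:ny) - 0.5) * dx
  u <- outer(xs, ys, function(x, y) -omega * (y - cy) * 1000)
  v <- outer(xs, ys, function(x, y) omega * (x - cx) * 1000)
  f <- structure(list(nx = nx, ny = ny, dx_km = dx, times = c(0, 24 * 10),
                      u = array(rep(u, 2), c(nx, ny, 2)),
                      v = array(rep(v, 2), c(nx, ny, 2)),
                      mask = matrix(TRUE, nx, ny),
                      depth = matrix(50, nx, ny),
                      habitat = list(A = seapopgen:::cell_of(
                        structure(list(nx = nx, ny = ny, dx_km = dx),
                                  class = "velocity_field"), cx + 20, cy)),
                      max_habitat_depth = 100), class = "velocity_field")
  set.seed(3)
  ep <- advect(f, release_spec(1, release_hours = 0, pld_days = c(5, 5),
                               dt_minutes = 15))
  r0 <- sqrt((ep$x0 - cx)^2 + (ep$y0 - cy)^2)
  r1 <- sqrt((ep$x - cx)^2 + (ep$y - cy)^2)
  expect_lt(abs(r1 - r0) / r0, 1e-3)
  # after one full orbit the particle returns near its start
  expect_lt(sqrt((ep$x - ep$x0)^2 + (ep$y - ep$y0)^2), 0.05 * r0)
})

test_that("connectivity matches brute-force point-in-cell counting and conserves mass", {
  set.seed(4)
  f <- make_velocity_field(flow_field_spec(duration_days = 8))
  ep <- advect(f, release_spec(40, release_hours = 0, pld_days = c(3, 6),
                               dt_minutes = 180))
  C <- connectivity(ep, f$habitat)
  # oracle: direct counting
  for (i in names(f$habitat)) {
    rows <- ep$locality == i
    for (j in names(f$habitat)) {
      expect_equal(C$mat[i, j],
                   mean(ep$end_cell[rows] %in% f$habitat[[j]]))
    }
  }
  # mass conservation: retained + lost = 1 per row
  lost <- vapply(names(f$habitat), function(i) {
    rows <- ep$locality == i
    mean(!ep$end_cell[rows] %in% unlist(f$habitat))
  }, numeric(1))
  expect_equal(unname(rowSums(C$mat) + lost), rep(1, 7), tolerance = 1e-12)
  # overlapping localities rejected
  bad <- f$habitat
  bad[[2]][1] <- bad[[1]][1]
  expect_error(connectivity(ep, bad), "overlapping")
  # same seed, same endpoints
  set.seed(5)
  e1 <- advect(f, release_spec(10, release_hours = 0, pld_days = c(3, 4),
                               dt_minutes = 240))
  set.seed(5)
  e2 <- advect(f, release_spec(10, release_hours = 0, pld_days = c(3, 4),
                               dt_minutes = 240))
  expect_identical(e1, e2)
})

test_that("multi-generation connectivity is the matrix power with its invariants", {
  C <- matrix(c(0.5, 0.3, 0.2,
                0.2, 0.6, 0.2,
                0.3, 0.1, 0.6), 3, byrow = TRUE,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(multigeneration(C, 1)$mat, C)
  # explicit two-step path sums
  two <- matrix(0, 3, 3, dimnames = dimnames(C))
  for (i in 1:3) for (j in 1:3)
    two[i, j] <- sum(C[i, ] * C[, j])
  expect_equal(multigeneration(C, 2)$mat, two, tolerance = 1e-14)
  # row-stochastic closure
  expect_equal(unname(rowSums(multigeneration(C, 16)$mat)), rep(1, 3),
               tolerance = 1e-12)
  expect_error(multigeneration(C, 0), "G must be")
  # adding a route never decreases any multi-generation entry
  C2 <- C * 0.9
  C3 <- C2; C3["a", "c"] <- C3["a", "c"] + 0.05
  expect_true(all(multigeneration(C3, 8)$mat >= multigeneration(C2, 8)$mat -
                    1e-15))
})

test_that("min-symmetrization takes pairwise minima and preserves the diagonal", {
  M <- matrix(c(0.9, 0.3, 0.2, 0.1, 0.8, 0.05, 0.6, 0.4, 0.7), 3,
              byrow = TRUE, dimnames = list(1:3, 1:3))
  S <- symmetrize_min(M)$mat
  expect_equal(S[1, 2], 0.1)
  expect_equal(S[2, 1], 0.1)
  expect_equal(diag(S), diag(M))
  expect_true(all(S <= M + 1e-15))
  sym <- (M + t(M)) / 2
  expect_equal(symmetrize_min(sym)$mat, sym)
})
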