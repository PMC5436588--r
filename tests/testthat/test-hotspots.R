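# a fully-land lattice grid for weight fixtures
lattice_grid <- function(n) {
  square_grid(n * 5, 5)
}

test_that("contiguity weights have the expected neighbour counts", {
  g <- lattice_grid(4)
  rc <- retained_cells(g)
  wq <- build_weights(g, "queen")
  interior <- which(rc$col == 2 & rc$row == 2)
  expect_equal(sum(wq[interior, ] > 0), 9)
  expect_equal(Matrix::diag(wq), rep(1, nrow(rc)))
  wr <- build_weights(g, "rook")
  corner <- which(rc$col == 1 & rc$row == 1)
  expect_equal(sum(wr[corner, ] > 0), 3)
  expect_true(Matrix::isSymmetric(wq))
})

test_that("queen neighbours match a brute-force geometric adjacency oracle", {
  sim <- small_sim()
  g <- sim$grid
  rc <- retained_cells(g)
  w <- build_weights(g, "queen")
  for (i in sample(seq_len(nrow(rc)), 25)) {
    # shares at least a corner: both coordinate offsets within one cell size
    touch <- abs(rc$cx - rc$cx[i]) <= 5 + 1e-9 & abs(rc$cy - rc$cy[i]) <= 5 + 1e-9
    expect_equal(which(w[i, ] > 0), which(touch))
  }
})

test_that("distance-band weights warn on isolated cells", {
  g <- lattice_grid(3)
  expect_error(build_weights(g, "distance_band"), "band")
  warns <- capture_warnings(build_weights(g, "distance_band", band = 2))
  expect_true(any(grepl("isolated|self-only", warns)))
  w <- build_weights(g, "distance_band", band = 5.1)
  rc <- retained_cells(g)
  interior <- which(rc$col == 2 & rc$row == 2)
  expect_equal(sum(w[interior, ] > 0), 5)  # rook neighbourhood at this band
})

test_that("gi_star matches the printed-formula oracle on a random field", {
  g <- lattice_grid(8)
  w <- build_weights(g, "queen")
  set.seed(4)
  x <- rnorm(64)
  z <- gi_star(x, w)$z
  expect_equal(z, gi_star_oracle(x, as.matrix(w)), tolerance = 1e-10)
})

test_that("a constant field yields an explicit undefined flag", {
  g <- lattice_grid(3)
  w <- build_weights(g, "queen")
  res <- gi_star(rep(2.5, 9), w)
  expect_true(attr(res, "undefined"))
  expect_true(all(is.na(res$z)))
  expect_error(gi_star(c(1, NA, 3, rep(0, 6)), w), "finite")
})

test_that("gi_star is location-invariant, scale-equivariant and antisymmetric", {
  g <- lattice_grid(5)
  w <- build_weights(g, "queen")
  set.seed(9)
  x <- rnorm(25)
  z <- gi_star(x, w)$z
  expect_equal(gi_star(x + 100, w)$z, z, tolerance = 1e-9)
  expect_equal(gi_star(3 * x, w)$z, z, tolerance = 1e-9)
  expect_equal(gi_star(-x, w)$z, -z, tolerance = 1e-12)
})

test_that("a single high cell is the field's hottest location", {
  g <- lattice_grid(5)
  w <- build_weights(g, "queen")
  rc <- retained_cells(g)
  x <- numeric(25)
  center <- which(rc$col == 3 & rc$row == 3)
  x[center] <- 1
  z <- gi_star(x, w)$z
  expect_equal(z[center], max(z))  # ties with its immediate neighbours allowed
  expect_gt(z[center], 0)
})

test_that("classification uses the two-sided normal thresholds", {
  z <- c(-3, -2.2, -1.7, 0, 1.7, 2.2, 3)
  expect_equal(as.character(classify_gi(z)),
               c("cold99", "cold95", "cold90", "ns", "hot90", "hot95", "hot99"))
  expect_equal(as.character(classify_gi(c(-1.645, 1.96))), c("cold90", "hot95"))
})

test_that("permutation null keeps the significant fraction near nominal", {
  g <- lattice_grid(10)
  w <- build_weights(g, "queen")
  set.seed(123)
  x <- rnorm(100)
  rates <- replicate(300, mean(abs(gi_star(sample(x), w)$z) > 1.96))
  expect_gt(mean(rates), 0.035)
  expect_lt(mean(rates), 0.065)
})

test_that("hotspot_report flags an implanted low-value block as a cold cluster", {
  g <- lattice_grid(10)
  rc <- retained_cells(g)
  set.seed(6)
  x <- rnorm(100, 0, 0.1)
  block <- rc$col %in% 4:6 & rc$row %in% 4:6
  x[block] <- x[block] - 1
  rep <- hotspot_report(g, x)
  expect_true(all(rep$z[block] < 0))
  expect_true(all(rep$class[block] == "cold99"))
  expect_true(all(c("cx", "cy") %in% names(rep)))
})
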