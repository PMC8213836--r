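test_that("hexagon centers form a triangular lattice with spacing 2r inside the square", {
  g <- build_hex_grid(10, 2.5)
  expect_s3_class(g, "hex_grid")
  # nearest-neighbour spacing is exactly 2r = 5 nm
  d <- as.matrix(dist(g$centers))
  diag(d) <- Inf
  expect_equal(min(d), 5, tolerance = 1e-12)
  # all centers strictly inside the square
  expect_true(all(g$centers >= 0 & g$centers < 10))
})

test_that("center count matches the areal density side^2 / (2 sqrt(3) r^2)", {
  g <- build_hex_grid(1000, 2.5)
  # independent enumeration: walk the lattice rows arithmetically
  r <- 2.5; s <- 5; row_h <- r * sqrt(3)
  n_expected <- 0L
  j <- 0L
  repeat {
    y <- r + j * row_h
    if (y >= 1000) break
    x0 <- r + (j %% 2) * r
    n_expected <- n_expected + sum(seq(x0, 1000, by = s) < 1000)
    j <- j + 1L
  }
  expect_identical(nrow(g$centers), as.integer(n_expected))
  analytic <- 1000^2 / (2 * sqrt(3) * 2.5^2)
  expect_lt(abs(nrow(g$centers) - analytic) / analytic, 0.02)
})

test_that("degenerate grid dimensions are rejected", {
  expect_error(build_hex_grid(1, 2.5), "at least")
  expect_error(build_hex_grid(-10, 2.5), "positive")
  expect_error(build_hex_grid(100, 0), "positive")
})

test_that("occupancy probability is the squared in-radius ratio, clamped at 1", {
  expect_equal(occupancy_probability(50, 2.5), 0.01)
  expect_equal(occupancy_probability(200, 2.5), 0.000625)
  expect_equal(occupancy_probability(5, 2.5), 1)
  expect_equal(occupancy_probability(3, 2.5), 1) # clamp
  # hexagon areas cancel: explicit area ratio gives the same number
  hex_area <- function(r) 2 * sqrt(3) * r^2
  expect_equal(occupancy_probability(50, 2.5), hex_area(2.5) / hex_area(25))
  expect_error(occupancy_probability(-1), "positive")
  expect_error(occupancy_probability(0), "positive")
})

test_that("lever placement realizes the target density and respects the grid", {
  g <- build_hex_grid(3000, 2.5)
  f <- place_levers(g, 200, seed = 11)
  # binomial count check: mean N*p, sd sqrt(N*p*(1-p)), 4 sd band
  N <- nrow(g$centers)
  p <- 0.000625
  expect_lt(abs(nrow(f$anchors) - N * p), 4 * sqrt(N * p * (1 - p)))
  # anchors are a subset of grid centers
  key <- function(m) paste(m[, 1], m[, 2])
  expect_true(all(key(f$anchors) %in% key(g$centers)))
  expect_equal(f$occupancy_p, p)
})

test_that("d = 2r occupies every center and d < 2r is rejected", {
  g <- build_hex_grid(50, 2.5)
  f <- place_levers(g, 5, seed = 1)
  expect_identical(nrow(f$anchors), nrow(g$centers))
  expect_error(place_levers(g, 4, seed = 1), "at least")
})

test_that("placement is reproducible under the same seed", {
  g <- build_hex_grid(800, 2.5)
  f1 <- place_levers(g, 100, seed = 42)
  f2 <- place_levers(g, 100, seed = 42)
  expect_identical(f1$anchors, f2$anchors)
  f3 <- place_levers(g, 100, seed = 43)
  expect_false(identical(f1$anchors, f3$anchors))
})

test_that("no two levers are closer than 5 nm at the default in-radius", {
  g <- build_hex_grid(600, 2.5)
  for (seed in 1:20) {
    f <- place_levers(g, 50, seed = seed)
    d <- dist(f$anchors)
    expect_gte(min(d), 5 - 1e-9)
  }
})

test_that("realized lever density converges to 1 / (2 sqrt(3) (d/2)^2) over seeds", {
  g <- build_hex_grid(1500, 2.5)
  d <- 100
  counts <- vapply(1:20, function(s) nrow(place_levers(g, d, s)$anchors),
                   numeric(1))
  N <- nrow(g$centers); p <- occupancy_probability(d)
  se <- sqrt(N * p * (1 - p) / 20)
  expect_lt(abs(mean(counts) - N * p), 4 * se)
  # areal density in levers/nm^2
  dens <- mean(counts) / 1500^2
  expect_equal(dens, 1 / (2 * sqrt(3) * (d / 2)^2), tolerance = 0.05)
})

test_that("placement depends only on center order: translating the grid translates the field", {
  g <- build_hex_grid(400, 2.5)
  g2 <- g
  g2$centers <- g$centers + 5 # one full lattice vector along x
  f1 <- place_levers(g, 50, seed = 7)
  f2 <- place_levers(g2, 50, seed = 7)
  expect_equal(f2$anchors, f1$anchors + 5)
})

test_that("lever fields round-trip through CSV plus JSON sidecar", {
  g <- build_hex_grid(400, 2.5)
  f <- place_levers(g, 50, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_lever_field(f, path)
  f2 <- read_lever_field(path)
  expect_equal(unname(f2$anchors), unname(f$anchors))
  expect_equal(f2$mean_distance_nm, 50)
  expect_equal(f2$seed, 3L)
  expect_equal(f2$side_length_nm, 400)
})
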