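test_that("a single lever can only collect singly bound molecules", {
  f <- make_field(cbind(10, 10))
  s <- saturate_binding(f, crosslinker_preset("441"), seed = 1)
  expect_equal(nrow(s$molecules), 2) # two sites, one molecule each
  expect_true(all(is.na(s$molecules$lever_b)))
  expect_equal(nrow(s$bridges), 0)
  expect_equal(interlinked_fraction(s), 0)
})

test_that("two levers within reach end up fully interlinked by one bridge pair", {
  f <- make_field(cbind(c(0, 50), c(0, 0)))
  for (seed in 1:5) {
    s <- saturate_binding(f, crosslinker_preset("441"), seed = seed)
    # every molecule bridges the only reachable pair, so the bridge SET has
    # exactly one element and all four sites go to doubly bound molecules
    expect_equal(nrow(s$bridges), 1)
    expect_equal(sort(c(s$bridges)), c(1, 2))
    expect_equal(nrow(s$molecules), 2)
    expect_equal(sum(is.na(s$molecules$lever_b)), 0)
    expect_equal(interlinked_fraction(s), 1)
  }
})

test_that("levers beyond reach never get bridged", {
  f <- make_field(cbind(c(0, 150), c(0, 0)))
  s <- saturate_binding(f, crosslinker_preset("841"), seed = 9) # reach 82
  expect_equal(nrow(s$bridges), 0)
  expect_equal(nrow(s$molecules), 4) # 4 sites, all singly bound
  expect_equal(interlinked_fraction(s), 0)
})

test_that("interlinked fraction counts chains and isolated levers correctly", {
  # chain A-B, B-C among 4 levers; D isolated
  s <- make_state(lever_a = c(1, 2), lever_b = c(2, 3), n_levers = 4)
  expect_equal(interlinked_fraction(s), 0.75)
  s0 <- make_state(lever_a = c(1, 2), lever_b = c(NA, NA), n_levers = 4)
  expect_equal(interlinked_fraction(s0), 0)
})

test_that("saturation consumes every binding site exactly", {
  g <- build_hex_grid(1200, 2.5)
  for (seed in 1:5) {
    f <- place_levers(g, 100, seed = seed)
    s <- saturate_binding(f, crosslinker_preset("841"), seed = seed + 100)
    sites_consumed <- sum(2L - is.na(s$molecules$lever_b))
    expect_identical(sites_consumed, 2L * s$n_levers)
    # no self-bridges, all bridges within reach
    expect_true(all(s$molecules$lever_a != s$molecules$lever_b, na.rm = TRUE))
    if (nrow(s$bridges) > 0) {
      d <- sqrt(rowSums((f$anchors[s$bridges[, 1], , drop = FALSE] -
                         f$anchors[s$bridges[, 2], , drop = FALSE])^2))
      expect_true(all(d <= max_reach(crosslinker_preset("841"))))
    }
    expect_lte(interlinked_fraction(s), 1)
  }
})

test_that("optimized simulator replays the literal brute-force rule exactly", {
  for (i in 1:100) {
    set.seed(i)
    n <- sample(2:8, 1)
    anchors <- cbind(runif(n, 0, 250), runif(n, 0, 250))
    spec <- crosslinker_preset(sample(c("441", "841", "mAb_combo"), 1))
    seed <- 1000 + i
    s <- saturate_binding(make_field(anchors), spec, seed = seed)
    o <- oracle_saturate(anchors, max_reach(spec), seed = seed)
    expect_identical(s$molecules$lever_a, o[, 1])
    expect_identical(s$molecules$lever_b, o[, 2])
    expect_identical(bridge_set(s$molecules$lever_a, s$molecules$lever_b),
                     bridge_set(o[, 1], o[, 2]))
  }
})

test_that("replicate runs are bit-for-bit reproducible from the base seed", {
  r1 <- run_replicates(200, crosslinker_preset("441"), n_surfaces = 2,
                       n_repeats = 3, base_seed = 5)
  r2 <- run_replicates(200, crosslinker_preset("441"), n_surfaces = 2,
                       n_repeats = 3, base_seed = 5)
  expect_identical(r1$replicates, r2$replicates)
  expect_equal(r1$n, 6)
  # single replicate equals a direct composition of the sub-operations
  r0 <- run_replicates(200, crosslinker_preset("441"), n_surfaces = 1,
                       n_repeats = 1, base_seed = 5)
  g <- build_hex_grid(r0$side_nm, 2.5)
  f <- place_levers(g, 200, seed = derive_seed(5, "surface", 1))
  s <- saturate_binding(f, crosslinker_preset("441"),
                        seed = derive_seed(5, "binding", 1, 1))
  expect_equal(r0$replicates$fraction_interlinked[1], interlinked_fraction(s))
})

test_that("interlinking nearly vanishes when levers are far sparser than the reach", {
  # d = 10 x reach: the chance of a second lever within reach is tiny
  r <- run_replicates(1000, crosslinker_preset("441"), n_surfaces = 5,
                      n_repeats = 2, base_seed = 2, side_nm = 6000)
  expect_lt(r$mean, 0.05)
})

test_that("site-weighted initial draw is available and differs in RNG stream use", {
  f <- make_field(cbind(c(0, 50, 200), c(0, 0, 0)))
  s1 <- saturate_binding(f, crosslinker_preset("441"), seed = 3,
                         initial_draw = "lever")
  s2 <- saturate_binding(f, crosslinker_preset("441"), seed = 3,
                         initial_draw = "site")
  # both saturate all sites regardless of the draw rule
  for (s in list(s1, s2)) {
    expect_identical(sum(2L - is.na(s$molecules$lever_b)), 6L)
  }
})

test_that("the curve sweep returns one summary row per spec-distance cell", {
  specs <- list(crosslinker_preset("441"), crosslinker_preset("841"))
  cv <- crosslink_curve(specs, distances = c(100, 200), n_surfaces = 2,
                        n_repeats = 2, base_seed = 4)
  expect_equal(nrow(cv), 4)
  expect_true(all(cv$mean >= 0 & cv$mean <= 1))
  reps <- attr(cv, "replicates")
  expect_equal(nrow(reps), 4 * 4)
  expect_named(reps, c("spec", "mean_distance_nm", "replicate",
                       "fraction_interlinked"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_crosslink_curve(cv, path)
  expect_true(file.exists(path))
  smry <- read.csv(sub("\\.csv$", "_summary.csv", path))
  expect_equal(nrow(smry), 4)
})

test_that("empty fields and invalid specs are rejected", {
  f <- make_field(cbind(numeric(0), numeric(0)))
  expect_error(saturate_binding(f, crosslinker_preset("441"), 1), "empty")
  expect_error(crosslink_curve(distances = c(-50)), "positive")
  expect_error(run_replicates(100, crosslinker_preset("441"), n_surfaces = 0),
               "at least 1")
})
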