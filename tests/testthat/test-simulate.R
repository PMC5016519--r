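reg1 <- region(0, 1000, 0, 1000)  # 1 um^2, keeps Monte-Carlo loops cheap

test_that("CSR counts are Poisson(intensity * area) and uniform in the window", {
  expect_equal(nrow(simulate_csr(0, reg1, seed = 1)), 0)
  expect_error(simulate_csr(-1, reg1, seed = 1), "non-negative")

  counts <- vapply(1:200, function(s) nrow(simulate_csr(1000, reg1, seed = s)),
                   double(1))
  # mean of 200 Poisson(1000) draws: within 3 * sqrt(1000/200) of 1000
  expect_lt(abs(mean(counts) - 1000), 3 * sqrt(1000 / 200))
  t <- simulate_csr(1000, reg1, seed = 3)
  expect_true(all(t$x >= 0 & t$x < 1000 & t$y >= 0 & t$y < 1000))
  expect_true(all(t$frame >= 1 & t$frame <= 20000))
})

test_that("Neyman-Scott offspring collapse onto parents when sigma is 0", {
  p <- neyman_scott_params(parent_intensity = 20, offspring_sigma = 0)
  sim <- simulate_neyman_scott(p, reg1, seed = 5)
  par <- sim$truth$parents
  expect_equal(sim$locs$x, par$x[sim$truth$assignment])
  expect_equal(sim$locs$y, par$y[sim$truth$assignment])
})

test_that("Neyman-Scott localization count matches the compound-Poisson mean", {
  # unconditioned: E[count] = parent_intensity * area * offspring_mean
  p <- neyman_scott_params(parent_intensity = 40, offspring_mean = 5,
                           offspring_sigma = 8, condition_on_detection = FALSE)
  counts <- vapply(1:200, function(s) nrow(simulate_neyman_scott(p, reg1, seed = s)$locs),
                   double(1))
  expected <- 40 * 1 * 5
  # var of compound Poisson count = lambda * E[N^2] = lambda * (mu + mu^2)
  se <- sqrt(40 * (5 + 25) / 200)
  expect_lt(abs(mean(counts) - expected), 3.5 * se)
})

test_that("density-matched Neyman-Scott honours the conditional offspring mean", {
  p <- neyman_scott_params(loc_intensity = 1000)
  expect_equal(p$mean_per_parent, 5 / (1 - exp(-5)))
  expect_equal(p$parent_intensity * p$mean_per_parent, 1000)
  counts <- vapply(1:100, function(s) nrow(simulate_neyman_scott(p, reg1, seed = s)$locs),
                   double(1))
  expect_lt(abs(mean(counts) - 1000), 3 * sd(counts) / sqrt(100))
})

test_that("blinking scenes reproduce the conditional Poisson blink statistics", {
  # mean localizations per fluorophore ~ 5 / (1 - exp(-5)) ~ 5.034
  per_fluor <- unlist(lapply(1:30, function(s) {
    sc <- simulate_blinking_scene(3, region = reg1, seed = s)
    tabulate(sc$truth$assignment)
  }))
  per_fluor <- per_fluor[per_fluor > 0]
  expect_lt(abs(mean(per_fluor) - 5 / (1 - exp(-5))),
            3 * sd(per_fluor) / sqrt(length(per_fluor)))

  # reference regime: 2 fluorophores/um^2 keeps localization density << 20/um^2
  sc <- simulate_blinking_scene(2, region = reg55(), seed = 1)
  expect_lt(nrow(sc$locs) / 25, 20)

  # zero precision: all localizations of one fluorophore coincide
  sc0 <- simulate_blinking_scene(5, precision_sigma = 0, region = reg1, seed = 2)
  spread <- tapply(sc0$locs$x, sc0$truth$assignment, function(v) diff(range(v)))
  expect_true(all(spread == 0))
})

test_that("blink frames are unique per fluorophore unless the stack overflows", {
  sc <- simulate_blinking_scene(5, region = reg1, seed = 9)
  dup <- tapply(sc$locs$frame, sc$truth$assignment, anyDuplicated)
  expect_true(all(dup == 0))
  expect_warning(
    simulate_blinking_scene(5, blink_mean = 10, n_frames = 2, region = reg1, seed = 1),
    "with replacement")
})

test_that("double membranes superpose two independent equal layers", {
  expect_equal(nrow(simulate_double_membrane(0, reg1, seed = 1)), 0)
  counts <- vapply(1:200, function(s) nrow(simulate_double_membrane(500, reg1, seed = s)),
                   double(1))
  expect_lt(abs(mean(counts) - 1000), 3 * sqrt(1000 / 200))
})

test_that("vesicle fields add an exact disc contribution to the background", {
  r <- region(0, 2000, 0, 2000)
  base <- simulate_csr(500, r, seed = 4)
  pure <- simulate_vesicle_field(500, 0, 100, 50, r, seed = 4)
  expect_equal(as.data.frame(pure), as.data.frame(base))   # no vesicles = CSR

  v <- simulate_vesicle_field(500, vesicle_count = 7, vesicle_radius = 100,
                              vesicle_loc_count = 50, region = r, seed = 4)
  expect_equal(nrow(v), nrow(base) + 7 * 50)
  expect_true(all(v$x >= 0 & v$x < 2000 & v$y >= 0 & v$y < 2000))
  expect_error(simulate_vesicle_field(500, 1, 0, 10, r, seed = 1), "positive")
})

test_that("every generator is bit-reproducible under a fixed seed", {
  p <- neyman_scott_params(loc_intensity = 300)
  pairs <- list(
    list(simulate_csr(400, reg1, seed = 42), simulate_csr(400, reg1, seed = 42)),
    list(simulate_neyman_scott(p, reg1, seed = 42)$locs,
         simulate_neyman_scott(p, reg1, seed = 42)$locs),
    list(simulate_blinking_scene(3, region = reg1, seed = 42)$locs,
         simulate_blinking_scene(3, region = reg1, seed = 42)$locs),
    list(simulate_double_membrane(200, reg1, seed = 42),
         simulate_double_membrane(200, reg1, seed = 42)),
    list(simulate_vesicle_field(200, 3, 50, 20, reg1, seed = 42),
         simulate_vesicle_field(200, 3, 50, 20, reg1, seed = 42))
  )
  for (pr in pairs) expect_identical(pr[[1]], pr[[2]])
})

test_that("generated coordinates always lie inside the stated region", {
  p <- neyman_scott_params(loc_intensity = 800, offspring_sigma = 25)
  for (s in 1:5) {
    ns <- simulate_neyman_scott(p, reg1, seed = s)$locs
    expect_true(all(ns$x >= 0 & ns$x < 1000 & ns$y >= 0 & ns$y < 1000))
    bs <- simulate_blinking_scene(4, precision_sigma = 25, region = reg1, seed = s)$locs
    expect_true(all(bs$x >= 0 & bs$x < 1000 & bs$y >= 0 & bs$y < 1000))
  }
})

test_that("degenerate Neyman-Scott (sigma 0, one offspring) behaves like its parents", {
  # with exactly-one offspring conditioning approximated by a tiny mean,
  # conditioned counts are almost surely 1 and the process inherits CSR
  p <- neyman_scott_params(parent_intensity = 500, offspring_mean = 1e-8,
                           offspring_sigma = 0)
  sim <- simulate_neyman_scott(p, reg1, seed = 8)
  expect_true(all(tabulate(sim$truth$assignment) <= 1))
  r <- region(0, 1000, 0, 1000)
  rc <- ripley_h(sim$locs, r, distances = seq(10, 100, 10), seed = 1, edge = "guard")
  expect_lt(max(abs(rc$h)), 15)  # no clustering structure at parent density
})
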