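# Two points 10 nm apart in a window of area 100*pi nm^2: with m = n = 2 the
# double sum is 2 for d > 10 and 0 for d < 10, so K = A and h = 10 - d, or
# h = -d below the pair distance.
test_that("the two-point configuration evaluates the estimator by hand", {
  r <- region(0, 10 * pi, 0, 10)
  t <- loc_table(x = c(10, 20), y = c(5, 5), frame = c(0L, 1L))
  rc <- ripley_h(t, r, distances = c(9, 11), m = 2, seed = 1)
  expect_equal(rc$h[rc$d == 11], -1)
  expect_equal(rc$h[rc$d == 9], -9)
  expect_equal(rc$K[rc$d == 11], 100 * pi)
  expect_equal(rc$K[rc$d == 9], 0)
})

test_that("the subset estimator matches the all-pairs oracle", {
  r <- region(0, 2000, 0, 2000)
  t <- simulate_csr(500, r, seed = 2)  # ~2000 points
  grid <- seq(20, 200, 20)
  h_all <- ripley_h_allpairs(t$x, t$y, region_area(r), grid)

  # full-subset call must agree exactly with the oracle
  rc_full <- ripley_h(t, r, distances = grid, m = nrow(t), seed = 1)
  expect_equal(rc_full$h, h_all, tolerance = 1e-10)

  # m = 500 subset: pointwise within 3 Monte-Carlo SEs of the oracle
  rc_sub <- ripley_h(t, r, distances = grid, m = 500, seed = 7)
  n <- nrow(t); A <- region_area(r)
  set.seed(7)
  for (k in seq_along(grid)) {
    counts <- neighbor_counts_at(t$x, t$y, seq_len(n), grid[k])
    se_K <- A / (n - 1) * sd(counts) / sqrt(500) * sqrt(1 - 500 / n)
    se_h <- se_K / (2 * sqrt(pi * max(rc_sub$K[k], se_K)))
    expect_lt(abs(rc_sub$h[k] - h_all[k]), 3 * se_h + 1e-9)
  }
})

test_that("averaging many subsets converges to the all-pairs value", {
  r <- region(0, 1500, 0, 1500)
  t <- simulate_csr(400, r, seed = 3)  # ~900 points
  grid <- c(50, 150)
  h_all <- ripley_h_allpairs(t$x, t$y, region_area(r), grid)
  hs <- vapply(1:100, function(s) {
    ripley_h(t, r, distances = grid, m = 300, seed = s)$h
  }, double(2))
  for (k in 1:2) {
    se <- sd(hs[k, ]) / sqrt(100)
    expect_lt(abs(mean(hs[k, ]) - h_all[k]), 3 * se + 0.05)
  }
})

test_that("CSR fields give mean h near zero with interior test points", {
  r <- region(0, 3000, 0, 3000)
  grid <- seq(10, 300, 10)
  curves <- lapply(1:12, function(s) {
    ripley_h(simulate_csr(500, r, seed = 100 + s), r, distances = grid,
             m = 500, seed = s, edge = "guard")
  })
  env <- ripley_envelope(curves)
  se <- (env$upper - env$mean_h) / qt(0.975, 11)
  expect_true(all(abs(env$mean_h) <= 3.5 * se + 0.05))
})

test_that("h is invariant under translation and 90-degree rotation", {
  r <- region(0, 1200, 0, 1200)
  t <- simulate_csr(300, r, seed = 5)
  grid <- seq(20, 200, 20)
  base <- ripley_h(t, r, distances = grid, m = 200, seed = 9)

  shift <- loc_table(x = t$x + 5000, y = t$y - 300, frame = t$frame)
  r_shift <- region(5000, 6200, -300, 900)
  expect_equal(ripley_h(shift, r_shift, distances = grid, m = 200, seed = 9)$h,
               base$h, tolerance = 1e-9)

  rot <- loc_table(x = t$y, y = 1200 - t$x, frame = t$frame)
  r_rot <- region(0, 1200, 0, 1200)
  expect_equal(ripley_h(rot, r_rot, distances = grid, m = 200, seed = 9)$h,
               base$h, tolerance = 1e-9)
})

test_that("duplicated points do not diverge: identical pairs score zero", {
  r <- region(0, 1000, 0, 1000)
  t <- simulate_csr(300, r, seed = 6)
  dup <- validate_loc_table(dplyr::bind_rows(t, t))
  grid <- seq(20, 100, 20)
  h1 <- ripley_h(t, r, distances = grid, m = nrow(t), seed = 1)$h
  h2 <- ripley_h(dup, r, distances = grid, m = nrow(dup), seed = 1)$h
  expect_true(all(is.finite(h2)))
  # with every point doubled, counts double and (n - 1) ~ doubles: K barely moves
  expect_lt(max(abs(h2 - h1)), 2)
})

test_that("ripley_h validates its preconditions", {
  r <- region(0, 1000, 0, 1000)
  t <- simulate_csr(100, r, seed = 1)
  expect_error(ripley_h(t, r, m = nrow(t) + 1), "exceeds")
  expect_error(ripley_h(t, r, distances = c(30, 20)), "increasing")
  expect_error(ripley_h(loc_table(x = 1, y = 1, frame = 0L), r), "at least 2")
  out <- loc_table(x = c(10, 2000), y = c(10, 10), frame = c(0L, 1L))
  expect_error(ripley_h(out, r), "inside the region")
  expect_error(ripley_h(t, r, distances = seq(100, 600, 100), edge = "guard"),
               "no interior test points")
})

test_that("envelopes aggregate replicates with t-based intervals", {
  r <- region(0, 1500, 0, 1500)
  grid <- seq(20, 100, 20)
  c1 <- ripley_h(simulate_csr(400, r, seed = 1), r, distances = grid, seed = 1)
  env_same <- ripley_envelope(list(c1, c1, c1))
  expect_equal(env_same$lower, env_same$upper)
  expect_equal(env_same$mean_h, c1$h)

  c2 <- ripley_h(simulate_csr(400, r, seed = 2), r, distances = grid, seed = 2)
  env <- ripley_envelope(list(c1, c2))
  expect_true(all(env$lower <= env$mean_h & env$mean_h <= env$upper))
  manual_se <- apply(cbind(c1$h, c2$h), 1, sd) / sqrt(2)
  expect_equal(env$upper, env$mean_h + qt(0.975, 1) * manual_se)

  c3 <- ripley_h(simulate_csr(400, r, seed = 3), r, distances = grid[-1], seed = 3)
  expect_error(ripley_envelope(list(c1, c3)), "identical distance grid")
  expect_error(ripley_envelope(list(c1)), "at least 2")
})

test_that("a Neyman-Scott envelope shows the blink peak where CSR shows none", {
  r <- region(0, 3000, 0, 3000)
  grid <- seq(4, 80, 4)
  p <- neyman_scott_params(loc_intensity = 800)
  ns_curves <- lapply(1:5, function(s) {
    ripley_h(simulate_neyman_scott(p, r, seed = s)$locs, r,
             distances = grid, m = 500, seed = s, edge = "guard")
  })
  ns_env <- ripley_envelope(ns_curves)
  expect_true(all(ns_env$lower[ns_env$d >= 12 & ns_env$d <= 48] > 0))
  pk <- peak_distance(ns_env, c(8, 60))
  expect_gte(pk$d_star, 12)
  expect_lte(pk$d_star, 40)
  expect_false(pk$at_boundary)
})

test_that("peak extraction follows argmax semantics with boundary flags", {
  env <- tibble::tibble(d = seq(10, 100, 2),
                        mean_h = -(seq(10, 100, 2) - 24)^2)
  pk <- peak_distance(env, c(10, 100))
  expect_equal(pk$d_star, 24)
  expect_false(pk$at_boundary)

  mono <- tibble::tibble(d = seq(10, 100, 10), mean_h = -seq(10, 100, 10))
  pk2 <- peak_distance(mono, c(20, 90))
  expect_equal(pk2$d_star, 20)
  expect_true(pk2$at_boundary)

  tie <- tibble::tibble(d = c(10, 20, 30), mean_h = c(0, 5, 5))
  expect_equal(peak_distance(tie)$d_star, 20)  # ties break to the smaller d
})

test_that("null comparison flags excursions only where they belong", {
  r <- region(0, 3000, 0, 3000)
  grid <- seq(10, 200, 10)
  csr_curves <- lapply(1:5, function(s) {
    ripley_h(simulate_csr(800, r, seed = 200 + s), r, distances = grid,
             m = 500, seed = s, edge = "guard")
  })
  csr_env <- ripley_envelope(csr_curves)

  # a CSR replicate against the CSR null: excursions at ~chance rate only
  self_curves <- lapply(6:10, function(s) {
    ripley_h(simulate_csr(800, r, seed = 200 + s), r, distances = grid,
             m = 500, seed = s, edge = "guard")
  })
  cmp_self <- compare_to_nulls(ripley_envelope(self_curves), csr_env)
  frac_out <- mean(cmp_self$flags$above_csr | cmp_self$flags$below_csr)
  expect_lt(frac_out, 0.5)

  # Neyman-Scott data against the CSR null: excursion covering the blink scale
  p <- neyman_scott_params(loc_intensity = 800)
  ns_env <- ripley_envelope(lapply(1:5, function(s) {
    ripley_h(simulate_neyman_scott(p, r, seed = 20 + s)$locs, r,
             distances = grid, m = 500, seed = s, edge = "guard")
  }))
  cmp_ns <- compare_to_nulls(ns_env, csr_env)
  exc <- cmp_ns$excursions
  above <- exc[exc$direction == "above" & exc$null == "csr", ]
  expect_gte(nrow(above), 1)
  expect_true(any(above$d_from <= 30 & above$d_to >= 30))

  # vesicle projections against the Neyman-Scott null: excursions beyond 30 nm
  ves_env <- ripley_envelope(lapply(1:5, function(s) {
    v <- simulate_vesicle_field(700, 40, 100, 60, r, seed = 40 + s)
    ripley_h(v, r, distances = grid, m = 500, seed = s, edge = "guard")
  }))
  cmp_v <- compare_to_nulls(ves_env, csr_env, ns_env)
  above_ns <- cmp_v$excursions[cmp_v$excursions$null == "neyman_scott" &
                               cmp_v$excursions$direction == "above", ]
  expect_gte(nrow(above_ns), 1)
  expect_gt(max(above_ns$d_to), 30)

  expect_error(compare_to_nulls(ns_env, ripley_envelope(self_curves[1:2])[-1, ]),
               "identical distance grid")
})
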