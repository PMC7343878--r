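test_that("degenerate partitions yield the single forced fixed point", {
  fps <- fixed_points(a = 0.3, p = 0.3, rho = 0.4, K = 10)
  expect_equal(nrow(fps), 1L)
  expect_equal(fps$r_star, 0.3)
  expect_equal(fps$stability, "stable")

  # with a = 0 the inactive state is always an equilibrium
  fps <- fixed_points(a = 0, p = 0.6, rho = 0.4, K = 10)
  expect_true(any(abs(fps$r_star) < 1e-8))
})

test_that("roots match an independent uniroot-based solver", {
  solve_ref <- function(a, p, rho, K) {
    h <- function(r) a + (p - a) * F_poisson(r, K, rho) - r
    grid <- seq(a, p, length.out = 20001)
    hv <- vapply(grid, h, numeric(1))
    roots <- grid[abs(hv) < 1e-12]
    for (i in which(hv[-1] * hv[-length(hv)] < 0))
      roots <- c(roots, uniroot(h, c(grid[i], grid[i + 1]),
                                tol = 1e-12)$root)
    sort(roots)
  }
  set.seed(31)
  for (k in 1:10) {
    p <- runif(1, 0.3, 1)
    a <- runif(1, 0.01, p * 0.8)
    rho <- runif(1, 0.1, 0.9)
    fps <- fixed_points(a, p, rho, K = 10)
    ref <- solve_ref(a, p, rho, 10)
    expect_equal(nrow(fps), length(ref))
    expect_equal(fps$r_star, ref, tolerance = 1e-6)
  }
})

test_that("stable and unstable fixed points alternate along r", {
  set.seed(77)
  for (k in 1:10) {
    p <- runif(1, 0.3, 1)
    a <- runif(1, 0.01, p * 0.8)
    fps <- fixed_points(a, p, rho = runif(1, 0.1, 0.9), K = 10)
    expect_gte(nrow(fps), 1L)
    lab <- fps$stability[fps$stability != "semi-stable"]
    if (length(lab) > 1)
      expect_true(all(lab[-1] != lab[-length(lab)]))
  }
})

test_that("folds bracket the three-root region of the bistable window", {
  folds <- saddle_node("a", c(0.01, 0.4), p = 0.67, rho = 0.4, K = 10)
  expect_equal(nrow(folds), 2L)
  f <- sort(folds$location)
  inside <- fixed_points(mean(f), 0.67, 0.4, 10)
  expect_equal(nrow(inside), 3L)
  below <- fixed_points(f[1] - 0.03, 0.67, 0.4, 10)
  above <- fixed_points(f[2] + 0.03, 0.67, 0.4, 10)
  expect_equal(nrow(below), 1L)
  expect_equal(nrow(above), 1L)
})

test_that("a monotone branch produces no folds", {
  # without contingent individuals the fixed point tracks a exactly
  folds <- saddle_node("rho", c(0.1, 0.9), a = 0.3, p = 0.3, K = 10,
                       n_scan = 11)
  expect_equal(nrow(folds), 0L)
  # very hard thresholds suppress multiplicity altogether
  folds <- saddle_node("a", c(0.01, 0.5), p = 0.56, rho = 0.9, K = 10,
                       n_scan = 21)
  expect_equal(nrow(folds), 0L)
})

test_that("the threshold fraction itself crosses a fold (hysteresis band in rho)", {
  folds <- saddle_node("rho", c(0.2, 0.6), a = 0.16, p = 0.67, K = 10,
                       n_scan = 21)
  expect_gte(nrow(folds), 1L)
})

test_that("the min-stable surface equals a on the diagonal and is monotone", {
  a_values <- c(0.05, 0.12, 0.18, 0.25)
  p_values <- c(0.25, 0.45, 0.67)
  s <- min_stable_surface(a_values, p_values, rho = 0.4, K = 10,
                          n_grid = 1001)
  expect_equal(s["0.25", "0.25"], 0.25, tolerance = 1e-6)
  expect_true(all(is.na(s[a_values > 0.25, "0.25"])))
  # nondecreasing along a (columns) and p (rows)
  for (j in seq_along(p_values)) {
    col <- s[, j]
    expect_true(all(diff(col[!is.na(col)]) >= -1e-8))
  }
  for (i in seq_along(a_values)) {
    row <- s[i, ]
    expect_true(all(diff(row[!is.na(row)]) >= -1e-8))
  }
  # harder thresholds cannot raise the smallest stable fixed point
  s_hard <- min_stable_surface(a_values, p_values, rho = 0.6, K = 10,
                               n_grid = 1001)
  expect_true(all(s_hard <= s + 1e-8, na.rm = TRUE))
})

test_that("the smallest stable fixed point jumps inside the reported a-window", {
  a_grid <- seq(0.10, 0.30, by = 0.01)
  vals <- sapply(a_grid, function(a) {
    fps <- fixed_points(a, 0.67, 0.4, 10, n_grid = 2001)
    min(fps$r_star[fps$stability == "stable"])
  })
  jump <- which.max(diff(vals))
  expect_gt(max(diff(vals)), 0.2)        # a genuine discontinuity
  expect_gte(a_grid[jump], 0.15)
  expect_lte(a_grid[jump + 1], 0.22)
  # a row below the cusp varies smoothly
  vals_smooth <- sapply(seq(0.05, 0.4, by = 0.01), function(a) {
    fps <- fixed_points(a, 0.58, 0.4, 10, n_grid = 2001)
    min(fps$r_star[fps$stability == "stable"])
  })
  expect_lt(max(diff(vals_smooth)), 0.05)
})

test_that("a cusp exists at moderate thresholds and vanishes at extreme ones", {
  cp <- cusp_point(seq(0.55, 0.7, by = 0.05), rho = 0.4, K = 10,
                   n_scan = 21, n_grid = 1001)
  expect_lt(cp$p_c, 1)
  expect_gt(cp$p_c, 0.5)
  expect_true(cp$a_c > 0.1 && cp$a_c < 0.3)

  expect_warning(
    none <- cusp_point(c(0.5, 0.9), rho = 0.95, K = 10,
                       n_scan = 15, n_grid = 1001),
    "no bistable")
  expect_true(is.na(none$p_c))

  # a grid below the folds region finds nothing either
  expect_warning(low <- cusp_point(0.3, rho = 0.4, K = 10, n_scan = 15,
                                   n_grid = 1001),
                 "no bistable")
  expect_true(is.na(low$p_c))
})

test_that("hysteresis appears exactly where the model is bistable", {
  # unique fixed point throughout: sweeps coincide, zero loop area
  h0 <- hysteresis("a", c(0.02, 0.4), p = 0.56, rho = 0.8, K = 10,
                   steps = 31, n_grid = 2001)
  expect_equal(h0$r_up, h0$r_down, tolerance = 1e-9)
  expect_equal(attr(h0, "area"), 0, tolerance = 1e-9)

  # across the folds the up and down traces split between the fold points
  h1 <- hysteresis("a", c(0.02, 0.4), p = 0.67, rho = 0.4, K = 10,
                   steps = 41, n_grid = 2001)
  expect_gt(attr(h1, "area"), 0.01)
  folds <- sort(saddle_node("a", c(0.02, 0.4), p = 0.67, rho = 0.4,
                            K = 10)$location)
  gap <- abs(h1$r_up - h1$r_down) > 1e-6
  expect_true(all(h1$value[gap] >= folds[1] - 0.01))
  expect_true(all(h1$value[gap] <= folds[2] + 0.01))

  # hysteresis also shows within a band of threshold fractions
  h2 <- hysteresis("rho", c(0.25, 0.55), a = 0.16, p = 0.67, K = 10,
                   steps = 31, n_grid = 2001)
  expect_gt(attr(h2, "area"), 0.001)
})

test_that("analytic fixed points predict the microscopic ensemble mean", {
  fps <- fixed_points(a = 0.3, p = 0.56, rho = 0.2, K = 10)
  stable <- fps$r_star[fps$stability == "stable"]
  expect_equal(length(stable), 1L)  # monostable configuration
  sw <- sweep_final_share(1e4, K = 10, rho_values = 0.2, a_values = 0.3,
                          p_values = 0.56, n = 5, seed = 17)
  expect_lt(abs(mean(sw$r_star) - stable), 0.05)
})
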