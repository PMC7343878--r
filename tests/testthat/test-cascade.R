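test_that("ER generation matches its binomial sampling law", {
  # N = 2, K = 1 forces ell = 1: the single edge always exists
  net <- er_network(2, K = 1, seed = 1)
  expect_equal(sum(net$degree), 2)

  for (seed in 1:5) {
    net <- er_network(3000, K = 8, seed = seed)
    # no self-loops or multi-edges, symmetric 0/1 adjacency
    expect_equal(Matrix::diag(net$adj), rep(0, 3000))
    expect_true(all(net$adj@x %in% 1))
    expect_equal(as.numeric(Matrix::norm(net$adj - Matrix::t(net$adj), "M")), 0)
    # mean degree within 5 standard errors of ell * (N - 1)
    ell <- net$meta$ell
    se <- sqrt(4 * choose(3000, 2) * ell * (1 - ell)) / 3000
    expect_lt(abs(mean(net$degree) - ell * 2999), 5 * se)
  }

  # ell supplied directly, the reference parameterisation
  net <- er_network(5000, ell = 9e-5, seed = 1)
  expect_equal(net$meta$K, 9e-5 * 4999)

  expect_error(er_network(1000), class = "parameter_error")
  expect_error(er_network(1000, K = 5, ell = 0.1), class = "parameter_error")
  expect_error(er_network(1, K = 0.5), class = "parameter_error")
})

test_that("identical seeds reproduce networks and assignments bit for bit", {
  n1 <- er_network(500, K = 6, seed = 7)
  n2 <- er_network(500, K = 6, seed = 7)
  expect_identical(n1$adj, n2$adj)

  part <- population_partition(500, a = 0.1, p = 0.5)
  g1 <- assign_groups(n1, part, seed = 3)
  g2 <- assign_groups(n2, part, seed = 3)
  expect_identical(g1$labels, g2$labels)
})

test_that("group assignment hits the partition counts exactly, every draw", {
  net <- er_network(1000, K = 5, seed = 2)
  part <- population_partition(1000, A = 37, P = 412)
  for (seed in 1:10) {
    g <- assign_groups(net, part, seed = seed)
    tab <- table(g$labels)
    expect_equal(as.integer(tab[c("certain", "contingent", "never")]),
                 c(37, 412 - 37, 1000 - 412))
  }
  # degenerate partitions
  all_cert <- assign_groups(net, population_partition(1000, A = 1000, P = 1000))
  expect_true(all(all_cert$labels == "certain"))
  none <- assign_groups(net, population_partition(1000, A = 0, P = 0))
  expect_true(all(none$labels == "never"))
  expect_error(assign_groups(net, population_partition(900, A = 1, P = 2)),
               class = "partition_error")
})

test_that("hand-enumerated miniature cascades come out exactly", {
  gs <- tiny_graphs()

  star <- network_from_edges(gs$star$N, gs$star$edges)
  tr <- run_cascade(star, as_group_assignment(gs$star$labels), rho = 0.5)
  expect_equal(attr(tr, "r_star"), 1)
  expect_equal(attr(tr, "t_max"), 2L)

  # the middle path node sees exactly half its neighbours active: a tie,
  # and ties never activate
  path <- network_from_edges(gs$path$N, gs$path$edges)
  tr <- run_cascade(path, as_group_assignment(gs$path$labels), rho = 0.5)
  expect_equal(attr(tr, "r_star"), 1 / 3)
  tr <- run_cascade(path, as_group_assignment(gs$path$labels), rho = 0.4)
  expect_equal(attr(tr, "r_star"), 2 / 3)

  # zero-degree contingent nodes can never activate, even at rho = 0
  iso <- network_from_edges(gs$isolated$N, gs$isolated$edges)
  tr <- run_cascade(iso, as_group_assignment(gs$isolated$labels), rho = 0)
  expect_equal(attr(tr, "r_star"), 1 / 2)
  expect_equal(attr(tr, "t_max"), 1L)

  # without contingent nodes the final share equals a for any rho
  net <- er_network(200, K = 5, seed = 9)
  part <- population_partition(200, A = 30, P = 30)
  for (rho in c(0, 0.5, 1)) {
    tr <- run_cascade(net, assign_groups(net, part, seed = 1), rho)
    expect_equal(attr(tr, "r_star"), 30 / 200)
  }
})

test_that("cascades are irreversible and close with a repeated state", {
  net <- er_network(800, K = 8, seed = 11)
  part <- population_partition(800, a = 0.05, p = 0.6)
  grp <- assign_groups(net, part, seed = 12)
  tr <- run_cascade(net, grp, rho = 0.25)
  expect_true(all(diff(tr$R) >= 0))
  n <- nrow(tr)
  expect_equal(tr$R[n], tr$R[n - 1L])
  expect_gte(attr(tr, "r_star"), part$a)
  expect_lte(attr(tr, "r_star"), part$p)
})

test_that("final active sets are monotone in the certain seed and in rho", {
  net <- er_network(600, K = 7, seed = 21)
  set.seed(22)
  potential <- sample.int(600, 360)
  cert2 <- sample(potential, 60)
  cert1 <- sample(cert2, 20)  # nested certain sets
  mk <- function(cert) {
    labels <- rep("never", 600)
    labels[potential] <- "contingent"
    labels[cert] <- "certain"
    as_group_assignment(labels)
  }
  act1 <- attr(run_cascade(net, mk(cert1), rho = 0.3), "active")
  act2 <- attr(run_cascade(net, mk(cert2), rho = 0.3), "active")
  expect_true(all(act2[act1]))  # smaller seed's cascade is contained

  # harder thresholds reach fewer nodes, on the same network and assignment
  grp <- mk(cert2)
  prev <- NULL
  for (rho in c(0.1, 0.3, 0.6, 0.9)) {
    act <- attr(run_cascade(net, grp, rho), "active")
    if (!is.null(prev)) expect_true(all(prev[act]))
    prev <- act
  }
})

test_that("the simulator agrees with the brute-force reference on tiny graphs", {
  cases <- c(tiny_graphs(), lapply(1:10, function(s) random_tiny_graph(8L, s)))
  for (g in cases) {
    net <- network_from_edges(g$N, g$edges)
    grp <- as_group_assignment(g$labels)
    for (rho in c(0, 0.2, 0.5, 0.8, 1)) {
      ref <- brute_cascade(g$N, g$edges, g$labels, rho)
      tr <- run_cascade(net, grp, rho)
      expect_equal(tr$R, ref$R)
      expect_equal(as.vector(attr(tr, "active")), as.vector(ref$active))
    }
  }
})

test_that("ensemble sweeps stay inside [a, p] and are seed-reproducible", {
  sw <- sweep_final_share(300, K = 6, rho_values = c(0.2, 0.8),
                          a_values = c(0.05, 0.3), p_values = c(0.3, 0.6),
                          n = 4, seed = 5)
  expect_true(all(sw$r_star >= sw$a - 1e-12))
  expect_true(all(sw$r_star <= sw$p + 1e-12))

  # cells with a = p give r* = a exactly in every replicate
  diag_cells <- sw[sw$a == sw$p, ]
  expect_gt(nrow(diag_cells), 0)
  expect_equal(diag_cells$r_star, diag_cells$a)

  sw2 <- sweep_final_share(300, K = 6, rho_values = c(0.2, 0.8),
                           a_values = c(0.05, 0.3), p_values = c(0.3, 0.6),
                           n = 4, seed = 5)
  expect_identical(sw, sw2)

  s <- summary(sw)
  expect_true(all(c("a", "p", "rho", "median_r_star") %in% names(s)))
})
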