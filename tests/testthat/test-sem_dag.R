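test_that("linear_sem validates structure", {
  expect_error(linear_sem(data.frame(parent = c("A", "B"), child = c("B", "A"),
                                     coefficient = c(1, 1)),
                          variances = c(A = 1, B = 1)), "cycle")
  expect_error(linear_sem(data.frame(parent = "A", child = "B",
                                     coefficient = 1),
                          variances = c(A = 1)), "variance")
  expect_error(linear_sem(data.frame(parent = "A", child = "B",
                                     coefficient = 1),
                          variances = c(A = 1, B = 0)), "positive")
})

test_that("implied moments follow the structural recursion", {
  # no edges: covariance is the diagonal of exogenous variances
  empty <- linear_sem(data.frame(parent = character(0), child = character(0),
                                 coefficient = numeric(0)),
                      variances = c(A = 2, B = 3))
  expect_equal(implied_moments(empty)$covariance,
               diag(c(2, 3)), ignore_attr = TRUE)
  # single edge X -> Y with coefficient b: Var(Y) = b^2 + 1, Cov = b
  b <- 1.4
  one <- linear_sem(data.frame(parent = "X", child = "Y", coefficient = b),
                    variances = c(X = 1, Y = 1))
  mom <- implied_moments(one)
  expect_equal(mom$covariance["Y", "Y"], b^2 + 1)
  expect_equal(mom$covariance["X", "Y"], b)
})

test_that("the three-wave panel DAG reproduces the baseline process law", {
  p <- dgp_params(theta = 1)
  sem <- build_fig1_sem(p)
  expect_equal(nrow(sem$edges), 15L)  # 3 waves x 5 edge families
  mom <- implied_moments(sem)
  # Cov(X0, Y0) = beta(delta^2 + theta^2 + 1) + gamma delta + theta
  expect_equal(mom$covariance["X0", "Y0"], 3.75)
  expect_equal(unname(mom$means[paste0("Y", 0:2)]), c(0.5, 1, 1.5))
  # positive semi-definite
  expect_gt(min(eigen(mom$covariance, symmetric = TRUE)$values), -1e-10)
  # implied covariance matches a large simulation entrywise within 3 SEs
  n <- 200000
  sim <- simulate_sem(sem, n, seed = 99L)
  S <- cov(sim)
  V <- mom$covariance
  tol <- 3 * sqrt((outer(diag(V), diag(V)) + V^2) / n)
  expect_true(all(abs(S - V[colnames(S), colnames(S)]) <
                    tol[colnames(S), colnames(S)] + 1e-12))
  # removing U removes the only cross-wave connector
  p0 <- dgp_params(theta = 0, u_effect_on_y = 0)
  expect_equal(implied_moments(build_fig1_sem(p0))$covariance["X0", "X1"], 0)
})

test_that("total effects by path tracing match the DAG claims and a DFS oracle", {
  p <- dgp_params(beta = 1.3, gamma = 0.7, delta = 0.4, theta = 0.9)
  sem <- build_fig1_sem(p)
  dY1 <- sem_contrast("dY1", "Y1", "Y0")
  dY2 <- sem_contrast("dY2", "Y2", "Y1")
  expect_equal(total_effect(sem, "X0", dY1), -1.3)
  expect_equal(total_effect(sem, "X0", dY2), 0)
  expect_equal(total_effect(sem, "X1", dY2), -1.3)
  expect_equal(total_effect(sem, "X1", "Y1"), 1.3)
  for (pair in list(c("Z0", "Y0"), c("U", "Y2"), c("X0", "Y2"),
                    c("Z1", "X1"))) {
    expect_equal(total_effect(sem, pair[1], pair[2]),
                 dfs_total_effect(sem, pair[1], pair[2]),
                 label = paste(pair, collapse = "->"))
  }
  expect_error(total_effect(sem, "X9", "Y0"), "unknown")
})

test_that("population regressions recover the theoretical estimand of each model", {
  p <- dgp_params(beta = 1.3, gamma = 0.7, theta = 0.6)
  sem <- build_fig1_sem(p)
  dY1 <- sem_contrast("dY1", "Y1", "Y0")
  dY2 <- sem_contrast("dY2", "Y2", "Y1")
  dX1 <- sem_contrast("dX1", "X1", "X0")
  dZ1 <- sem_contrast("dZ1", "Z1", "Z0")
  cc <- regression_from_covariance(sem, dY1, list(dX1, dZ1))
  expect_equal(unname(cc), c(1 - 0.5, 1.3, 0.7), tolerance = 1e-12)
  cs <- regression_from_covariance(sem, dY1, list("X0", "Z0"))
  expect_equal(unname(cs[["X0"]]), -1.3 / (0.6^2 + 1), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(cs[["X0"]], 1.3)))
  expect_false(isTRUE(all.equal(cs[["X0"]], -1.3)))
  lg <- regression_from_covariance(sem, dY2, list(dX1, dZ1))
  expect_equal(unname(lg[["dX1"]]), -1.3 / 2, tolerance = 1e-12)
  expect_error(regression_from_covariance(sem, dY1, list(dX1, dX1)),
               "collinear")
})

test_that("population regressions agree with OLS on data simulated from the SEM", {
  sem <- build_fig1_sem(dgp_params(theta = 1))
  sim <- as.data.frame(simulate_sem(sem, 1000000, seed = 123L))
  dY1 <- sem_contrast("dY1", "Y1", "Y0")
  dY2 <- sem_contrast("dY2", "Y2", "Y1")
  dX1 <- sem_contrast("dX1", "X1", "X0")
  dZ1 <- sem_contrast("dZ1", "Z1", "Z0")
  models <- list(
    list(pop = regression_from_covariance(sem, dY1, list(dX1, dZ1)),
         y = sim$Y1 - sim$Y0, X = cbind(1, sim$X1 - sim$X0, sim$Z1 - sim$Z0)),
    list(pop = regression_from_covariance(sem, dY1, list("X0", "Z0")),
         y = sim$Y1 - sim$Y0, X = cbind(1, sim$X0, sim$Z0)),
    list(pop = regression_from_covariance(sem, dY2, list(dX1, dZ1)),
         y = sim$Y2 - sim$Y1, X = cbind(1, sim$X1 - sim$X0, sim$Z1 - sim$Z0)))
  for (m in models) {
    fit <- fit_ols(m$y, m$X, term_names = names(m$pop))
    expect_true(all(abs(fit$coefficients - m$pop) < 0.01))
  }
})

test_that("wave-equal heterogeneity loadings cancel; unequal loadings bias the slope", {
  two_wave_sem <- function(load0, load1) {
    edges <- data.frame(
      parent = c("Z0", "Z0", "X0", "U", "U", "Z1", "Z1", "X1", "U", "U"),
      child = c("X0", "Y0", "Y0", "X0", "Y0", "X1", "Y1", "Y1", "X1", "Y1"),
      coefficient = c(0.5, 1, 1, 1, load0, 0.5, 1, 1, 1, load1))
    vars <- c("U", "Z0", "X0", "Y0", "Z1", "X1", "Y1")
    linear_sem(edges, stats::setNames(rep(1, 7), vars))
  }
  # unconstrained form of the concurrent model: dY ~ X0 + X1 + Z0 + Z1.
  # The backdoor paths through U into Y0 and into Y1 cancel exactly when the
  # two outcome loadings of U agree, giving the (-beta, beta) pair on
  # (X0, X1); unequal loadings leave net confounding.
  reg_unconstrained <- function(sem) {
    regression_from_covariance(sem, sem_contrast("dY", "Y1", "Y0"),
                               list("X0", "X1", "Z0", "Z1"))
  }
  for (load in c(0.3, 1, 2.5)) {
    co <- reg_unconstrained(two_wave_sem(load, load))
    expect_equal(unname(co[["X0"]]), -1, tolerance = 1e-12)
    expect_equal(unname(co[["X1"]]), 1, tolerance = 1e-12)
  }
  co_uneq <- reg_unconstrained(two_wave_sem(0.2, 1.8))
  expect_gt(abs(co_uneq[["X0"]] - (-1)), 0.1)
  # the differenced slope itself is insensitive here: with equal loadings of
  # U on the exposure at both waves, u drops out of the exposure change
  reg_diff <- function(sem) {
    regression_from_covariance(
      sem, sem_contrast("dY", "Y1", "Y0"),
      list(sem_contrast("dX", "X1", "X0"),
           sem_contrast("dZ", "Z1", "Z0")))[["dX"]]
  }
  expect_equal(reg_diff(two_wave_sem(0.2, 1.8)), 1, tolerance = 1e-12)
})

test_that("backdoor enumeration reproduces the five listed paths with their statuses", {
  sem <- build_fig1_sem(dgp_params(theta = 1))
  dY1 <- sem_contrast("dY1", "Y1", "Y0")
  paths <- enumerate_noncausal_paths(sem, "X0", dY1,
                                     conditioning = c("Z0", "X1", "Z1"))
  want <- data.frame(
    path = c("X0 <- Z0 -> Y0",                  # blocked by Z0
             "X0 <- U -> Y0",                   # open (cancels against next)
             "X0 <- U -> Y1",                   # open
             "X0 <- U -> X1 -> Y1",             # blocked by X1
             "X0 <- U -> X1 <- Z1 -> Y1"),      # collider X1 opened, Z1 blocks
    status = c("blocked", "open", "open", "blocked", "blocked"),
    blocked_by = c("Z0", "", "", "X1", "Z1"))
  for (k in seq_len(nrow(want))) {
    row <- paths[paths$path == want$path[k], ]
    expect_equal(nrow(row), 1L, label = want$path[k])
    expect_equal(row$status, want$status[k], label = want$path[k])
    expect_equal(row$blocked_by, want$blocked_by[k], label = want$path[k])
  }
  # components carry the +1/-1 contrast weight
  expect_equal(unique(paths$weight[paths$component == "Y0"]), -1)
  # every returned path starts with an arrow into the cause
  expect_true(all(startsWith(paths$path, "X0 <- ")))
  expect_error(enumerate_noncausal_paths(sem, "X0", dY1, "X0"), "condition")
})

test_that("the full simple backdoor path count matches an exhaustive igraph oracle", {
  sem <- build_fig1_sem(dgp_params(theta = 1))
  paths <- enumerate_noncausal_paths(sem, "X0", sem_contrast("dY1", "Y1", "Y0"))
  g <- igraph::graph_from_data_frame(sem$edges[, c("parent", "child")],
                                     directed = TRUE)
  count_backdoor <- function(target) {
    ap <- igraph::all_simple_paths(igraph::as_undirected(g), from = "X0",
                                   to = target)
    # keep paths whose first step traverses an edge pointing into X0
    sum(vapply(ap, function(pth) {
      first <- igraph::as_ids(pth)[2]
      igraph::are_adjacent(g, first, "X0") &&
        !igraph::are_adjacent(g, "X0", first)
    }, logical(1)))
  }
  expect_equal(sum(paths$component == "Y1"), count_backdoor("Y1"))
  expect_equal(sum(paths$component == "Y0"), count_backdoor("Y0"))
  # a single-edge DAG has no backdoor paths at all
  tiny <- linear_sem(data.frame(parent = "X", child = "Y", coefficient = 1),
                     variances = c(X = 1, Y = 1))
  expect_equal(nrow(enumerate_noncausal_paths(tiny, "X", "Y")), 0L)
})

test_that("a SEM survives a plain-text round trip", {
  sem <- build_fig1_sem(dgp_params(beta = 1.25, theta = 0.3))
  f <- withr::local_tempfile(fileext = ".txt")
  write_sem(sem, f)
  back <- read_sem(f)
  m1 <- implied_moments(sem)
  m2 <- implied_moments(back)
  expect_equal(m2$covariance[rownames(m1$covariance), colnames(m1$covariance)],
               m1$covariance, tolerance = 1e-12)
  expect_equal(m2$means[names(m1$means)], m1$means, tolerance = 1e-12)
})
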