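test_that("package enumeration counts and ids are correct", {
  full <- enumerate_packages()
  expect_length(full, 287L)
  expect_length(enumerate_packages(2, 2, 0), 8L)
  expect_length(enumerate_packages(1, 1, 2), 15L)

  ids <- vapply(full, `[[`, character(1), "id")
  expect_false(anyDuplicated(ids) > 0)

  # count formula against explicit set construction for small menus
  for (menu in list(c(0, 0, 1), c(1, 0, 3), c(2, 1, 2), c(3, 3, 2))) {
    pkgs <- enumerate_packages(menu[1], menu[2], menu[3])
    expect_length(
      pkgs, (menu[1] + 1) * (menu[2] + 1) * 2^menu[3] - 1
    )
    sig <- vapply(pkgs, function(p) {
      paste(c(p$oil, p$cube, p$vas_regions), collapse = "|")
    }, character(1))
    expect_false(anyDuplicated(sig) > 0)
  }

  # the national-only subset of the full menu has 8 combinations
  n_national <- sum(vapply(full, function(p) length(p$vas_regions) == 0L,
                           logical(1)))
  expect_equal(n_national, 8L)
})

test_that("discounted sums follow the stated exponent conventions", {
  expect_equal(discounted_sum(c(3, 4, 5), 0), 12)
  expect_equal(discounted_sum(c(5, 0, 0), 0.03, offset = 0), 5 / 1.03)
  v <- 7
  # geometric-series closed form, cost convention (first year undiscounted)
  closed <- v * (1 - 1.03^-10) / (1 - 1.03^-1)
  expect_equal(discounted_sum(rep(v, 10), 0.03, offset = 1), closed)
  # benefit convention is the cost convention divided by (1+r)
  expect_equal(discounted_sum(rep(v, 10), 0.03, offset = 0), closed / 1.03)
  expect_error(discounted_sum(1:3, -1.5), "rate")
})

test_that("the target grid starts at 1% and steps by 2.5% of the pool", {
  g <- build_target_grid(100)
  expect_length(g$levels, 40L)
  expect_equal(g$levels[1], 1)
  expect_equal(diff(g$levels), rep(2.5, 39))
  expect_true(all(diff(g$levels) > 0))

  g1 <- build_target_grid(100, n_levels = 1)
  expect_equal(g1$levels, 1)

  gbig <- build_target_grid(38.1e6)
  expect_equal(gbig$levels[1], 381000)
  expect_equal(gbig$levels[40], 38.1e6 * (0.01 + 0.975))
  expect_error(build_target_grid(0), "positive")
})

test_that("least-cost selection and tie-breaking are exact", {
  toy <- data.frame(
    id = c("a", "b", "c"), dcov = c(5, 8, 12), dcost = c(1, 2, 2.5),
    n_programs = c(1, 1, 2), stringsAsFactors = FALSE
  )
  expect_equal(least_cost_package(toy, 10)$package_id, "c")
  expect_equal(least_cost_package(toy, 0)$package_id, "a")
  r <- least_cost_package(toy, 13)
  expect_false(r$feasible)
  expect_true(is.na(r$package_id))

  # equal cost: higher coverage wins; then fewer programs; then id
  ties <- data.frame(
    id = c("z", "y", "x"), dcov = c(10, 10, 12), dcost = c(2, 2, 2),
    n_programs = c(1, 1, 1), stringsAsFactors = FALSE
  )
  expect_equal(least_cost_package(ties, 5)$package_id, "x")
  ties2 <- data.frame(
    id = c("z", "y"), dcov = c(10, 10), dcost = c(2, 2),
    n_programs = c(2, 1), stringsAsFactors = FALSE
  )
  expect_equal(least_cost_package(ties2, 5)$package_id, "y")
  ties3 <- ties2
  ties3$n_programs <- c(1, 1)
  expect_equal(least_cost_package(ties3, 5)$package_id, "y")

  expect_error(least_cost_package(toy[0, ], 1), "empty")
})

test_that("optimizer equals exhaustive search on random toy menus", {
  for (seed in 1:12) {
    evals <- toy_evaluations(sample(3:15, 1), seed)
    targets <- runif(8, 0, 110)
    for (tg in targets) {
      got <- least_cost_package(evals, tg)
      want <- brute_force_least_cost(evals, tg)
      if (is.na(want)) {
        expect_false(got$feasible)
      } else {
        expect_equal(got$package_id, want)
      }
    }
    # the vectorized Monte Carlo solver agrees with the reference solver
    idx <- vaoptim:::solve_targets(evals$dcov, evals$dcost,
                                   evals$n_programs, evals$id, targets)
    for (k in seq_along(targets)) {
      want <- brute_force_least_cost(evals, targets[k])
      if (is.na(want)) {
        expect_true(is.na(idx[k]))
      } else {
        expect_equal(evals$id[idx[k]], want)
      }
    }
  }
})

test_that("frontier cost is non-decreasing and meets its targets", {
  for (seed in 20:24) {
    evals <- toy_evaluations(12, seed)
    grid <- build_target_grid(max(evals$dcov), n_levels = 15)
    f <- frontier(evals, grid)
    feas <- f[f$feasible, ]
    expect_true(all(diff(feas$discounted_cost) >= -1e-9))
    expect_true(all(feas$achieved_coverage >= feas$target))
    # infeasible levels, if any, sit above the max achievable coverage
    expect_true(all(f$target[!f$feasible] > max(evals$dcov)))
  }
})

test_that("adding a package to the menu never worsens the frontier", {
  for (seed in 30:34) {
    evals <- toy_evaluations(10, seed)
    extra <- toy_evaluations(1, seed + 100)
    extra$id <- "extra"
    grid <- seq(5, 95, by = 10)
    f0 <- frontier(evals, grid)
    f1 <- frontier(rbind(evals, extra), grid)
    both <- f0$feasible & f1$feasible
    expect_true(all(f1$feasible >= f0$feasible))
    expect_true(all(f1$discounted_cost[both] <=
                      f0$discounted_cost[both] + 1e-9))
  }
})

test_that("fitted frontier is monotone with targets on the 1%/2.5% grid", {
  fit <- tiny_fit()
  f <- fit$frontier
  expect_equal(nrow(f), 40L)
  expect_equal(f$target, fit$grid$levels)
  expect_equal(fit$grid$pct_of_pool, 0.01 + 0.025 * (0:39))
  feas <- f[f$feasible, ]
  expect_gt(nrow(feas), 5L)
  expect_true(all(diff(feas$discounted_cost) >= -1e-9))
  expect_true(all(feas$achieved_coverage >= feas$target))
  expect_true(all(
    feas$cost_per_child ==
      feas$discounted_cost / feas$achieved_coverage
  ))
})
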