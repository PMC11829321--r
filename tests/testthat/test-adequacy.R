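test_that("household density is intake per 1000 kcal", {
  expect_equal(household_density(500, 2000), 250)
  expect_equal(household_density(0, 1500), 0)
  expect_equal(household_density(300, 1500), 200)
  expect_error(household_density(100, 0), "energy")
  expect_error(household_density(-1, 100), "non-negative")
})

test_that("critical density subtracts the VAS daily equivalent, clamped", {
  expect_equal(critical_density(275, 1000), 275)
  expect_equal(critical_density(275, 1000, 167), 108)
  expect_equal(critical_density(150, 900, 167), 0)
  expect_error(critical_density(0, 1000), "positive")
  expect_error(critical_density(200, 1000, -5), "non-negative")
})

test_that("fortification adds vehicle consumption times the average level", {
  p <- generate_programs()
  oc <- p[p$id == "oil_current", ]
  expect_equal(lsff_added_intake(20, oc), 20 * 17.5 * 0.39 * 0.85)
  c15 <- p[p$id == "cube_15", ]
  expect_equal(lsff_added_intake(2.5, c15), 2.5 * 48 * 0.75)  # 90
  expect_equal(lsff_added_intake(0, c15), 0)
  expect_error(lsff_added_intake(5, p[p$id == "vas_O", ]), "LSFF")
})

test_that("scenario density adds active programs and rejects duplicates", {
  p <- generate_programs()
  hh <- data.frame(va_ugRAE_day = 500, energy_kcal_day = 2000,
                   oil_g_day = 20, cube_g_day = 2.5)
  expect_equal(scenario_density(hh, p), 250)
  oil_add <- 20 * 17.5 * 0.39 * 0.85
  expect_equal(scenario_density(hh, p, "oil_current"),
               1000 * (500 + oil_add) / 2000)
  expect_equal(scenario_density(hh, p, c("oil_current", "cube_15")),
               1000 * (500 + oil_add + 90) / 2000)
  expect_error(scenario_density(hh, p, c("oil_current", "oil_improved")),
               "at most one oil")
  expect_error(scenario_density(hh, p, c("cube_15", "cube_30")),
               "at most one oil and one cube")
  expect_error(scenario_density(hh, p, "nonsense"), "unknown program")
})

test_that("VAS assignment follows regional coverage and the seed", {
  regions <- burkina_regions()
  regions$vas_coverage <- c(0, 1, 0.7, 0.5, 0.5)
  n <- 10000L
  survey <- data.frame(region_id = rep(c("O", "C", "N"), each = n))
  flags <- assign_vas(survey, regions, seed = 11L)
  expect_true(all(!flags[survey$region_id == "O"]))
  expect_true(all(flags[survey$region_id == "C"]))
  phat <- mean(flags[survey$region_id == "N"])
  se <- sqrt(0.7 * 0.3 / n)
  expect_lt(abs(phat - 0.7), 3 * se)
  expect_identical(flags, assign_vas(survey, regions, seed = 11L))
})

test_that("prevalence matches per-child enumeration and tie handling", {
  # tie counts as adequate
  expect_equal(
    inadequacy_prevalence(c(100, 300, 200), c(200, 200, 200)),
    1 / 3
  )
  # weighted count: weight-1 child inadequate, weight-3 child adequate
  expect_equal(inadequacy_prevalence(c(100, 300), c(200, 200), c(1, 3)),
               0.25)
  expect_equal(inadequacy_prevalence(c(500, 400), c(200, 300)), 0)
  expect_error(inadequacy_prevalence(numeric(0), numeric(0)), "empty")

  # brute-force oracle on random small rosters
  set.seed(7)
  for (k in 1:20) {
    n <- sample(1:20, 1)
    dens <- runif(n, 0, 400)
    crit <- runif(n, 0, 400)
    w <- runif(n, 0.5, 2)
    manual <- sum(w * (dens < crit)) / sum(w)  # explicit enumeration
    expect_equal(inadequacy_prevalence(dens, crit, w), manual)
  }
})

test_that("adding programs never raises prevalence (coverage monotone)", {
  b <- tiny_bundle()
  fit <- tiny_fit()
  prev <- fit$prevalence$prev
  # along each axis (oil, cube, VAS), prevalence is non-increasing
  for (r in dimnames(prev)[[1]]) {
    for (v in 1:2) {
      expect_true(all(diff(prev[r, , 1, v]) <= 1e-12))
      expect_true(all(diff(prev[r, 1, , v]) <= 1e-12))
    }
    expect_true(all(prev[r, , , 2] <= prev[r, , , 1] + 1e-12))
  }
  expect_true(all(prev >= 0 & prev <= 1))
})

test_that("package coverage dominates subset coverage year by year", {
  fit <- tiny_fit()
  cs <- fit$coverage_streams
  mem <- fit$membership
  set.seed(13)
  pairs_checked <- 0L
  for (attempt in seq_len(20000L)) {
    if (pairs_checked >= 30L) break
    i <- sample(nrow(mem), 1)
    j <- sample(nrow(mem), 1)
    if (i == j) next
    if (all(mem[i, ] <= mem[j, ])) {  # package i is a subset of package j
      expect_true(all(cs[j, ] >= cs[i, ] - 1e-9))
      pairs_checked <- pairs_checked + 1L
    }
  }
  expect_gte(pairs_checked, 10L)
})

test_that("joint coverage is not the sum of single-program coverages", {
  p <- generate_programs("R1")
  s <- straddle_survey()
  crit <- critical_density(s$ear_ugRAE_day, s$energy_req_kcal_day)
  base <- inadequacy_prevalence(scenario_density(s, p), crit)
  oil <- inadequacy_prevalence(scenario_density(s, p, "oil_current"), crit)
  cube <- inadequacy_prevalence(scenario_density(s, p, "cube_15"), crit)
  both <- inadequacy_prevalence(
    scenario_density(s, p, c("oil_current", "cube_15")), crit
  )
  cov_oil <- base - oil
  cov_cube <- base - cube
  cov_both <- base - both
  expect_equal(cov_oil, 0)
  expect_equal(cov_cube, 0)
  expect_equal(cov_both, 1)
  expect_true(cov_both != cov_oil + cov_cube)
})

test_that("benefit streams respect program start years", {
  # hand-built prevalence table: baseline 0.94, each program cuts it by 0.1
  regions <- "R1"
  prev <- array(
    0.94, dim = c(1, 3, 3, 2),
    dimnames = list(regions, c("none", "oil_current", "oil_improved"),
                    c("none", "cube_15", "cube_30"), c("no_vas", "vas"))
  )
  prev[1, 2, 1, 1] <- 0.84   # oil current alone
  prev[1, 3, 1, 1] <- 0.80   # oil improved alone
  prev[1, 1, 2, 1] <- 0.84   # cube 15 alone
  ptab <- list(prev = prev, baseline = c(R1 = 0.94), regions = regions,
               oil_levels = dimnames(prev)[[2]],
               cube_levels = dimnames(prev)[[3]])
  pop <- matrix(1e6, 1, 10, dimnames = list("R1", NULL))
  programs <- generate_programs("R1")

  ef_cube <- vaoptim:::coverage_stream(
    list(oil = NA_character_, cube = "cube_15", vas_regions = character(0)),
    ptab, pop, programs
  )
  expect_equal(ef_cube[1:2], c(0, 0))
  expect_equal(ef_cube[3:10], rep(0.1 * 1e6, 8))

  ef_oi <- vaoptim:::coverage_stream(
    list(oil = "oil_improved", cube = NA_character_,
         vas_regions = character(0)),
    ptab, pop, programs
  )
  expect_equal(ef_oi[1], 0)
  expect_equal(ef_oi[2:10], rep(0.14 * 1e6, 9))

  ef_oc <- vaoptim:::coverage_stream(
    list(oil = "oil_current", cube = NA_character_,
         vas_regions = character(0)),
    ptab, pop, programs
  )
  expect_equal(ef_oc, rep(0.1 * 1e6, 10))
})

test_that("fitted package coverage honours the delayed start years", {
  fit <- tiny_fit()
  cs <- fit$coverage_streams
  expect_equal(unname(cs["cube_30", 1:2]), c(0, 0))
  expect_gt(cs["cube_30", 3], 0)
  expect_equal(unname(cs["oil_improved", 1]), 0)
  expect_gt(cs["oil_improved", 2], 0)
  expect_gt(cs["oil_current", 1], 0)
  expect_gt(cs["VAS(O)", 1], 0)
  expect_true(all(cs >= 0))
})
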