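# Shared fixtures, built in code and memoized for the test run.

.fixtures <- new.env(parent = emptyenv())

tiny_config <- function(seed = 42L) {
  synthetic_config(seed = seed, n_households_per_region = 80L)
}

tiny_bundle <- function() {
  if (is.null(.fixtures$bundle)) {
    .fixtures$bundle <- generate_bundle(tiny_config())
  }
  .fixtures$bundle
}

tiny_fit <- function() {
  if (is.null(.fixtures$fit)) {
    b <- tiny_bundle()
    .fixtures$fit <- va_optimize(b$survey, b$regions, seed = 42L)
  }
  .fixtures$fit
}

# One-child survey designed so that neither fortification vehicle alone
# lifts the household diet over the child's critical density but both
# together do: coverage is jointly, not additively, determined.
straddle_survey <- function() {
  data.frame(
    household_id = "h1", region_id = "R1", weight = 1,
    energy_kcal_day = 2000, va_ugRAE_day = 300,
    oil_g_day = 20, cube_g_day = 1,
    child_id = "h1_c1", child_age_months = 24, child_sex = "male",
    ear_ugRAE_day = 210, energy_req_kcal_day = 1000,
    stringsAsFactors = FALSE
  )
}

# Random toy evaluation table for optimizer cross-checks.
toy_evaluations <- function(n, seed) {
  set.seed(seed)
  data.frame(
    id = sprintf("pkg%02d", seq_len(n)),
    dcov = round(runif(n, 0, 100), 2),
    dcost = round(runif(n, 1, 50), 2),
    n_programs = sample(1:4, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# Independent brute-force oracle for the least-cost problem: filter, then
# scan for the minimum under the documented tie-break, no sorting shortcuts.
brute_force_least_cost <- function(evals, target) {
  best <- NULL
  for (i in seq_len(nrow(evals))) {
    if (evals$dcov[i] < target) next
    if (is.null(best)) {
      best <- i
      next
    }
    a <- evals[i, ]
    b <- evals[best, ]
    better <- (a$dcost < b$dcost) ||
      (a$dcost == b$dcost && a$dcov > b$dcov) ||
      (a$dcost == b$dcost && a$dcov == b$dcov &&
         a$n_programs < b$n_programs) ||
      (a$dcost == b$dcost && a$dcov == b$dcov &&
         a$n_programs == b$n_programs && a$id < b$id)
    if (better) best <- i
  }
  if (is.null(best)) NA_character_ else evals$id[best]
}
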