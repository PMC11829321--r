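# Synthetic EHCVM-style household survey generator. Household vitamin A
# density is lognormal (right-skewed, strictly positive) with its log-mean
# calibrated by bisection so that the simulated child-level baseline
# inadequacy in each macro-region matches the region's target prevalence.
# Vehicle (oil, bouillon cube) consumption is zero for non-reached households
# and gamma-distributed otherwise. Children inherit the household diet's
# density; requirements come from a configurable table.

#' Configuration for the synthetic survey generator
#'
#' Defaults encode the study conditions the analysis assumes: 400 households
#' per macro-region (2000 nationally), bouillon reach varying by region
#' around a national 82% (95% in the Sahel-containing North, 70% in the
#' Cascades-containing West), moderate oil reach, lognormal household energy
#' and vitamin A density, and 0--3 children per household.
#'
#' @param seed Integer seed; the whole bundle is a deterministic function of
#'   it.
#' @param n_households_per_region Households simulated per macro-region.
#' @param regions Region table giving per-region target baseline inadequacy
#'   and VAS coverage (default [burkina_regions()]).
#' @param cube_reach,oil_reach Named per-region fractions of households
#'   consuming each vehicle (names = region ids), or a single number.
#' @param mean_vehicle_intake Named vector `c(oil = , cube = )`, mean g/day
#'   among consuming households.
#' @param vehicle_shape Gamma shape for consumption amounts (both vehicles).
#' @param energy_meanlog,energy_sdlog Lognormal parameters for household
#'   daily energy intake (kcal/day).
#' @param density_sdlog Lognormal log-sd of household vitamin A density; the
#'   log-mean is calibrated per region.
#' @param children_prob Probabilities of 0, 1, 2, 3 children per household.
#' @param requirements Child requirement table (see
#'   [default_requirements()]).
#' @param calibration_tol Absolute tolerance on the per-region baseline
#'   inadequacy reached by calibration (default 0.005, half the contractual
#'   ±1 percentage point). Because prevalence moves in steps of one child,
#'   the effective tolerance is floored at `1 / n_children` in the region.
#' @param max_iter Bisection iteration cap before calibration errors out.
#' @return An object of class `"synthetic_config"` (a named list).
#' @export
synthetic_config <- function(seed = 1L,
                             n_households_per_region = 400L,
                             regions = burkina_regions(),
                             cube_reach = c(O = 0.85, C = 0.80, N = 0.95,
                                            E = 0.78, W = 0.70),
                             oil_reach = 0.55,
                             mean_vehicle_intake = c(oil = 25, cube = 8),
                             vehicle_shape = 2,
                             energy_meanlog = log(9000),
                             energy_sdlog = 0.35,
                             density_sdlog = 0.6,
                             children_prob = c(0.25, 0.40, 0.25, 0.10),
                             requirements = default_requirements(),
                             calibration_tol = 0.005,
                             max_iter = 100L) {
  regions <- validate_regions(regions)
  expand_reach <- function(x, name) {
    if (length(x) == 1L && is.null(names(x))) {
      x <- setNames(rep(x, nrow(regions)), regions$region_id)
    }
    if (!all(regions$region_id %in% names(x))) {
      stop(sprintf("`%s` must name every region", name), call. = FALSE)
    }
    check_fraction(x, name)
    x[regions$region_id]
  }
  cfg <- list(
    seed = as.integer(seed),
    n_households_per_region = as.integer(n_households_per_region),
    regions = regions,
    cube_reach = expand_reach(cube_reach, "cube_reach"),
    oil_reach = expand_reach(oil_reach, "oil_reach"),
    mean_vehicle_intake = mean_vehicle_intake,
    vehicle_shape = vehicle_shape,
    energy_meanlog = energy_meanlog,
    energy_sdlog = energy_sdlog,
    density_sdlog = density_sdlog,
    children_prob = children_prob / sum(children_prob),
    requirements = requirements,
    calibration_tol = calibration_tol,
    max_iter = as.integer(max_iter)
  )
  stopifnot(cfg$n_households_per_region >= 1L,
            all(cfg$mean_vehicle_intake > 0),
            cfg$vehicle_shape > 0, cfg$density_sdlog > 0,
            cfg$energy_sdlog > 0, length(cfg$children_prob) == 4L)
  structure(cfg, class = "synthetic_config")
}

# Calibrate the lognormal log-mean of household density so the child-level
# baseline inadequacy matches `target`. prevalence(mu) is a non-increasing
# step function of mu, so bisection on a wide bracket converges; the best mu
# seen is accepted if within tolerance, else calibration fails loudly.
calibrate_density_meanlog <- function(z_hh, hh_of_child, crit, target,
                                      sdlog, tol, max_iter, region_id) {
  prev_at <- function(mu) {
    dens <- exp(mu + sdlog * z_hh)
    mean(dens[hh_of_child] < crit)
  }
  # prevalence moves in steps of 1/n_children, so the reachable accuracy is
  # bounded by the sample's granularity
  tol <- max(tol, 1 / length(crit))
  lo <- log(1)      # essentially everyone inadequate
  hi <- log(20000)  # essentially no one inadequate
  best_mu <- NA_real_
  best_gap <- Inf
  for (k in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    p <- prev_at(mid)
    gap <- abs(p - target)
    if (gap < best_gap) {
      best_gap <- gap
      best_mu <- mid
    }
    if (gap <= tol) break
    if (p > target) lo <- mid else hi <- mid
  }
  if (best_gap > tol) {
    stop(sprintf(
      "density calibration failed for region %s: best gap %.4f > tol %.4f",
      region_id, best_gap, tol
    ), call. = FALSE)
  }
  best_mu
}

#' Generate a synthetic household survey
#'
#' Draws households and their child rosters region by region, then calibrates
#' each region's vitamin A density distribution so the simulated child-level
#' baseline inadequacy (no programs, no supplementation) matches the
#' region's target to within the configured tolerance. The calibration step
#' is deterministic given the draws, so identical seeds yield byte-identical
#' surveys.
#'
#' @param config A [synthetic_config()].
#' @return Survey data frame, one row per child, with household fields
#'   repeated: `household_id`, `region_id`, `weight`, `energy_kcal_day`,
#'   `va_ugRAE_day`, `oil_g_day`, `cube_g_day`, `child_id`,
#'   `child_age_months`, `child_sex`, `ear_ugRAE_day`,
#'   `energy_req_kcal_day`. Attributes `n_households` (households drawn,
#'   including childless ones) and `density_meanlog` (calibrated per-region
#'   log-means) are attached.
#' @export
generate_households <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  regions <- config$regions
  with_seed(config$seed, {
    out <- vector("list", nrow(regions))
    meanlog <- setNames(numeric(nrow(regions)), regions$region_id)
    n_households <- 0L
    for (ri in seq_len(nrow(regions))) {
      r <- regions$region_id[ri]
      n <- config$n_households_per_region
      n_households <- n_households + n

      energy <- exp(rnorm(n, config$energy_meanlog, config$energy_sdlog))
      z <- rnorm(n)  # density z-scores; location calibrated below
      draw_vehicle <- function(reach, mean_g) {
        consumed <- runif(n) < reach
        amt <- rgamma(n, shape = config$vehicle_shape,
                      rate = config$vehicle_shape / mean_g)
        ifelse(consumed, amt, 0)
      }
      oil_g <- draw_vehicle(config$oil_reach[[r]],
                            config$mean_vehicle_intake[["oil"]])
      cube_g <- draw_vehicle(config$cube_reach[[r]],
                             config$mean_vehicle_intake[["cube"]])
      n_children <- sample(0:3, n, replace = TRUE,
                           prob = config$children_prob)
      hh_of_child <- rep(seq_len(n), n_children)
      nc <- length(hh_of_child)
      if (nc == 0L) {
        stop(sprintf("region %s drew no children; increase sample size", r),
             call. = FALSE)
      }
      age <- sample(6:59, nc, replace = TRUE)
      sex <- sample(c("male", "female"), nc, replace = TRUE)
      req <- child_requirements(age, sex, config$requirements)
      crit <- critical_density(req$ear_ugRAE_day, req$energy_req_kcal_day)

      mu <- calibrate_density_meanlog(
        z, hh_of_child, crit, regions$baseline_inadequacy[ri],
        config$density_sdlog, config$calibration_tol, config$max_iter, r
      )
      meanlog[[r]] <- mu
      dens <- exp(mu + config$density_sdlog * z)
      va <- dens * energy / 1000

      hh_id <- sprintf("%s_h%04d", r, seq_len(n))
      child_seq <- sequence(n_children[n_children > 0])
      out[[ri]] <- data.frame(
        household_id = hh_id[hh_of_child],
        region_id = r,
        weight = 1,
        energy_kcal_day = energy[hh_of_child],
        va_ugRAE_day = va[hh_of_child],
        oil_g_day = oil_g[hh_of_child],
        cube_g_day = cube_g[hh_of_child],
        child_id = paste0(hh_id[hh_of_child], "_c", child_seq),
        child_age_months = age,
        child_sex = sex,
        ear_ugRAE_day = req$ear_ugRAE_day,
        energy_req_kcal_day = req$energy_req_kcal_day,
        stringsAsFactors = FALSE
      )
    }
    survey <- do.call(rbind, out)
    rownames(survey) <- NULL
    attr(survey, "n_households") <- n_households
    attr(survey, "density_meanlog") <- meanlog
    survey
  })
}

#' Generate synthetic per-program cost profiles
#'
#' Builds activity-based cost profiles with the structure the cost model
#' assumes: bouillon programs pay start-up costs in years 1--2 and operate
#' for 8 years; the improved oil program pays start-up in year 1 and operates
#' for 9; the current oil program and all VAS programs have no start-up and
#' operate for all 10 years. Costs are split across government, industry and
#' premix components; VAS costs are per-child operational outlays large
#' enough that any single VAS program costs more over the horizon than any
#' LSFF program. Magnitudes are synthetic placeholders at nationally
#' plausible scale.
#'
#' @param regions Region table (for VAS program sizing).
#' @param scale Multiplier applied to all LSFF cost magnitudes (default 1 =
#'   USD).
#' @param vas_cost_per_child USD per covered child per year for VAS delivery
#'   (personnel, capsules, distribution; default 1.10).
#' @return Cost-profile data frame with columns `program_id`, `stakeholder`
#'   (`"government"`, `"industry"`, `"premix"`), `phase` (`"startup"` /
#'   `"operational"`), `annual_cost_usd`, `population_scaled` (0/1) and
#'   `startup_years`.
#' @export
generate_cost_profiles <- function(regions = burkina_regions(), scale = 1,
                                   vas_cost_per_child = 1.10) {
  stopifnot(scale > 0, vas_cost_per_child > 0)
  regions <- validate_regions(regions)
  row <- function(id, stk, phase, cost, scaled, startup) {
    data.frame(program_id = id, stakeholder = stk, phase = phase,
               annual_cost_usd = cost, population_scaled = scaled,
               startup_years = startup, stringsAsFactors = FALSE)
  }
  lsff <- rbind(
    row("oil_current", "government", "operational", 80000 * scale, 1L, 0L),
    row("oil_current", "industry", "operational", 150000 * scale, 1L, 0L),
    row("oil_improved", "government", "startup", 300000 * scale, 0L, 1L),
    row("oil_improved", "industry", "startup", 400000 * scale, 0L, 1L),
    row("oil_improved", "government", "operational", 100000 * scale, 1L, 1L),
    row("oil_improved", "industry", "operational", 200000 * scale, 1L, 1L),
    row("cube_15", "government", "startup", 250000 * scale, 0L, 2L),
    row("cube_15", "industry", "startup", 350000 * scale, 0L, 2L),
    row("cube_15", "government", "operational", 50000 * scale, 1L, 2L),
    row("cube_15", "industry", "operational", 80000 * scale, 1L, 2L),
    row("cube_15", "premix", "operational", 500000 * scale, 1L, 2L),
    row("cube_30", "government", "startup", 250000 * scale, 0L, 2L),
    row("cube_30", "industry", "startup", 350000 * scale, 0L, 2L),
    row("cube_30", "government", "operational", 50000 * scale, 1L, 2L),
    row("cube_30", "industry", "operational", 100000 * scale, 1L, 2L),
    row("cube_30", "premix", "operational", 1000000 * scale, 1L, 2L)
  )
  vas <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    annual <- regions$pop_2023[i] * regions$vas_coverage[i] *
      vas_cost_per_child
    row(paste0("vas_", regions$region_id[i]), "government", "operational",
        annual, 1L, 0L)
  }))
  validate_cost_profiles(rbind(lsff, vas))
}

#' Generate the full synthetic analysis bundle
#'
#' Convenience wrapper producing every input the downstream stages need:
#' the survey, the region table, the program menu, and per-program cost
#' profiles. The bundle is a deterministic function of `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return List with elements `survey`, `regions`, `programs`,
#'   `cost_profiles`, `config`.
#' @export
generate_bundle <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  list(
    survey = generate_households(config),
    regions = config$regions,
    programs = generate_programs(config$regions$region_id),
    cost_profiles = generate_cost_profiles(config$regions),
    config = config
  )
}

#' Write / read a synthetic bundle to a directory
#'
#' Writes `households.csv`, `programs.yaml`, `costs.csv` and
#' `demography.csv`, the plain-text interface consumed unmodified by the
#' downstream stages.
#'
#' @param bundle A bundle from [generate_bundle()].
#' @param dir Output directory (created if needed).
#' @return `write_bundle()` returns `dir` invisibly; `read_bundle()` returns
#'   a bundle list (without the generating config).
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(bundle$survey, file.path(dir, "households.csv"),
            row.names = FALSE)
  write_programs(bundle$programs, file.path(dir, "programs.yaml"))
  write_cost_profiles(bundle$cost_profiles, file.path(dir, "costs.csv"))
  write_demography(bundle$regions, file.path(dir, "demography.csv"))
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  list(
    survey = read.csv(file.path(dir, "households.csv"),
                      stringsAsFactors = FALSE),
    regions = read_demography(file.path(dir, "demography.csv")),
    programs = read_programs(file.path(dir, "programs.yaml")),
    cost_profiles = read_cost_profiles(file.path(dir, "costs.csv"))
  )
}
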