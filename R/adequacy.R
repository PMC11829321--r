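# Dietary adequacy engine. A child is vitamin A-inadequate when the vitamin A
# density of the household diet (µg RAE per 1000 kcal) falls strictly below
# the child's critical density (age- and sex-specific EAR divided by energy
# requirement, per 1000 kcal). Fortification adds vehicle-borne vitamin A to
# the household diet; supplementation (VAS) is incorporated by subtracting a
# daily-equivalent 167 µg RAE from the child's requirement before forming the
# critical density, which needs no assumption about the child's energy share.

#' Vitamin A density of a household diet
#'
#' @param va_ugRAE_day Apparent daily household vitamin A intake (µg RAE).
#' @param energy_kcal_day Apparent daily household energy intake (kcal,
#'   strictly positive).
#' @return Density in µg RAE per 1000 kcal: `1000 * va / energy`.
#' @examples
#' household_density(500, 2000)  # 250
#' @export
household_density <- function(va_ugRAE_day, energy_kcal_day) {
  if (any(!is.finite(energy_kcal_day)) || any(energy_kcal_day <= 0)) {
    stop("energy intake must be strictly positive", call. = FALSE)
  }
  if (any(va_ugRAE_day < 0)) {
    stop("vitamin A intake must be non-negative", call. = FALSE)
  }
  1000 * va_ugRAE_day / energy_kcal_day
}

#' Critical vitamin A density of a child
#'
#' The density a household diet must reach for the child's vitamin A
#' requirement to be met at the child's energy requirement. Receipt of
#' high-dose supplementation is handled by subtracting its daily-equivalent
#' intake from the requirement (clamped at zero).
#'
#' @param ear_ugRAE_day Estimated average requirement (µg RAE/day, > 0).
#' @param energy_req_kcal_day Energy requirement (kcal/day, > 0).
#' @param vas_adjust_ugRAE Daily-equivalent vitamin A from supplementation
#'   (µg RAE/day, default 0; 167 for a VAS recipient).
#' @return Critical density in µg RAE per 1000 kcal:
#'   `1000 * max(ear - vas_adjust, 0) / energy_req`.
#' @examples
#' critical_density(275, 1000)        # 275
#' critical_density(275, 1000, 167)   # 108
#' @export
critical_density <- function(ear_ugRAE_day, energy_req_kcal_day,
                             vas_adjust_ugRAE = 0) {
  if (any(ear_ugRAE_day <= 0) || any(energy_req_kcal_day <= 0)) {
    stop("requirements must be strictly positive", call. = FALSE)
  }
  if (any(vas_adjust_ugRAE < 0)) {
    stop("vas_adjust must be non-negative", call. = FALSE)
  }
  1000 * pmax(ear_ugRAE_day - vas_adjust_ugRAE, 0) / energy_req_kcal_day
}

#' Additional vitamin A intake from one fortification program
#'
#' Multiplies household vehicle consumption by the program's expected average
#' fortification level: statutory level (mg/kg, read as µg/g) attenuated by
#' compliance (share of the vehicle supply fortified) and the relative level
#' achieved versus the standard.
#'
#' @param vehicle_g_day Household daily consumption of the program's vehicle
#'   (g/day).
#' @param program One row of a program table (see [generate_programs()]);
#'   must be an LSFF program.
#' @return Added intake in µg RAE/day.
#' @examples
#' p <- generate_programs()
#' lsff_added_intake(20, p[p$id == "oil_current", ])  # 20*17.5*0.39*0.85
#' @export
lsff_added_intake <- function(vehicle_g_day, program) {
  stopifnot(is.data.frame(program), nrow(program) == 1L)
  if (program$kind != "LSFF") {
    stop("`program` must be an LSFF program", call. = FALSE)
  }
  if (!program$vehicle %in% c("oil", "cube")) {
    stop("unknown fortification vehicle: ", program$vehicle, call. = FALSE)
  }
  if (any(vehicle_g_day < 0)) {
    stop("vehicle consumption must be non-negative", call. = FALSE)
  }
  vehicle_g_day * program$fortification_mg_kg * program$compliance *
    program$relative_level
}

#' Household diet density under a set of active fortification programs
#'
#' Adds each active LSFF program's vehicle-borne vitamin A to the household's
#' apparent intake and recomputes the density; fortification does not change
#' energy intake. At most one oil and one cube program may be active.
#'
#' @param survey Survey table (one row per child; see
#'   [generate_households()]) or any data frame with `va_ugRAE_day`,
#'   `energy_kcal_day`, `oil_g_day`, `cube_g_day`.
#' @param programs Program table.
#' @param lsff_ids Character vector of active LSFF program ids (possibly
#'   empty).
#' @return Numeric vector of scenario densities (µg RAE per 1000 kcal), one
#'   per row of `survey`.
#' @export
scenario_density <- function(survey, programs, lsff_ids = character()) {
  rows <- programs[match(lsff_ids, programs$id), , drop = FALSE]
  if (anyNA(rows$id)) {
    stop("unknown program id in `lsff_ids`", call. = FALSE)
  }
  if (sum(rows$vehicle == "oil") > 1L || sum(rows$vehicle == "cube") > 1L) {
    stop("at most one oil and one cube program may be active", call. = FALSE)
  }
  added <- rep(0, nrow(survey))
  for (i in seq_len(nrow(rows))) {
    g <- survey[[paste0(rows$vehicle[i], "_g_day")]]
    added <- added + lsff_added_intake(g, rows[i, , drop = FALSE])
  }
  household_density(survey$va_ugRAE_day + added, survey$energy_kcal_day)
}

#' Randomly assign VAS receipt to children
#'
#' Each child is independently flagged as receiving supplementation with
#' probability equal to its macro-region's coverage rate. The draw is made
#' once per seed and is intended to be reused across scenarios and years.
#'
#' @param survey Survey table (one row per child) with a `region_id` column.
#' @param regions Region table supplying per-region `vas_coverage`.
#' @param seed Integer seed making the assignment reproducible.
#' @return Logical vector, one element per child row.
#' @export
assign_vas <- function(survey, regions, seed = 1L) {
  regions <- validate_regions(regions)
  cov <- setNames(regions$vas_coverage, regions$region_id)
  if (!all(survey$region_id %in% names(cov))) {
    stop("survey contains region ids absent from the region table",
         call. = FALSE)
  }
  with_seed(seed, {
    p <- cov[survey$region_id]
    runif(nrow(survey)) < p
  })
}

#' Weighted prevalence of vitamin A inadequacy
#'
#' Fraction of children whose household scenario density lies strictly below
#' their critical density; ties count as adequate.
#'
#' @param density Scenario density per child (µg RAE per 1000 kcal).
#' @param critical Critical density per child.
#' @param weights Optional survey weights (default equal).
#' @return Weighted prevalence in \[0, 1\].
#' @export
inadequacy_prevalence <- function(density, critical, weights = NULL) {
  n <- length(density)
  if (n == 0L) stop("empty child list", call. = FALSE)
  stopifnot(length(critical) == n)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  weighted.mean(density < critical, weights)
}

# Precompute per-region inadequacy prevalence for every LSFF combination x
# VAS state. Returns a list with a 4-d array prev[region, oil, cube, vas]
# (oil/cube level 1 = absent) and the per-region baseline prevalence.
prevalence_table <- function(survey, programs, vas_flags,
                             regions = sort(unique(survey$region_id))) {
  oil_ids <- programs$id[programs$kind == "LSFF" & programs$vehicle == "oil"]
  cube_ids <- programs$id[programs$kind == "LSFF" & programs$vehicle == "cube"]
  oil_levels <- c("none", oil_ids)
  cube_levels <- c("none", cube_ids)
  stopifnot(length(vas_flags) == nrow(survey))

  prev <- array(
    NA_real_,
    dim = c(length(regions), length(oil_levels), length(cube_levels), 2L),
    dimnames = list(regions, oil_levels, cube_levels, c("no_vas", "vas"))
  )
  for (r in regions) {
    idx <- survey$region_id == r
    sub <- survey[idx, , drop = FALSE]
    w <- sub$weight
    crit0 <- critical_density(sub$ear_ugRAE_day, sub$energy_req_kcal_day)
    # VAS daily equivalent taken from the region's VAS program if present.
    vrow <- programs[programs$kind == "VAS" & programs$scope == r, ,
                     drop = FALSE]
    equiv <- if (nrow(vrow)) vrow$vas_daily_equiv_ugRAE[1] else 167
    crit1 <- ifelse(
      vas_flags[idx],
      critical_density(sub$ear_ugRAE_day, sub$energy_req_kcal_day, equiv),
      crit0
    )
    for (i in seq_along(oil_levels)) {
      for (j in seq_along(cube_levels)) {
        ids <- c(oil_levels[i], cube_levels[j])
        ids <- ids[ids != "none"]
        dens <- scenario_density(sub, programs, ids)
        prev[r, i, j, 1L] <- inadequacy_prevalence(dens, crit0, w)
        prev[r, i, j, 2L] <- inadequacy_prevalence(dens, crit1, w)
      }
    }
  }
  list(
    prev = prev,
    baseline = setNames(prev[, 1L, 1L, 1L], regions),
    regions = regions,
    oil_levels = oil_levels,
    cube_levels = cube_levels
  )
}

#' Per-region effective coverage of a set of active programs
#'
#' Effective coverage is the reduction, relative to the no-program baseline,
#' in the prevalence of child vitamin A inadequacy achieved by the active
#' programs. Programs only ever add vitamin A, so it is non-negative.
#'
#' @param ptab Prevalence table from the internal adequacy engine (built by
#'   [va_optimize()]; also available via `prevalence_table`-style summaries).
#' @param oil,cube Active LSFF program id or `"none"`.
#' @param vas_regions Character vector of regions whose VAS program is
#'   active.
#' @return Named numeric vector of per-region effective-coverage fractions.
#' @keywords internal
effective_coverage_fraction <- function(ptab, oil = "none", cube = "none",
                                        vas_regions = character()) {
  i <- match(oil, ptab$oil_levels)
  j <- match(cube, ptab$cube_levels)
  if (is.na(i) || is.na(j)) stop("unknown LSFF program id", call. = FALSE)
  vapply(ptab$regions, function(r) {
    v <- if (r %in% vas_regions) 2L else 1L
    ptab$baseline[[r]] - ptab$prev[r, i, j, v]
  }, numeric(1))
}

# Annual effective-coverage stream (children covered per year) for one
# package. A program contributes only from its first benefit year: in earlier
# years it is evaluated as if absent, so e.g. a cube-only package yields zero
# coverage in years 1-2.
coverage_stream <- function(pkg, ptab, pop_mat, programs, horizon = 10L) {
  fb <- setNames(programs$first_benefit_year, programs$id)
  ef <- numeric(horizon)
  for (t in seq_len(horizon)) {
    oil <- if (!is.na(pkg$oil) && t >= fb[[pkg$oil]]) pkg$oil else "none"
    cube <- if (!is.na(pkg$cube) && t >= fb[[pkg$cube]]) pkg$cube else "none"
    vas <- pkg$vas_regions[vapply(
      pkg$vas_regions,
      function(r) t >= fb[[paste0("vas_", r)]],
      logical(1)
    )]
    frac <- effective_coverage_fraction(ptab, oil, cube, vas)
    ef[t] <- sum(frac * pop_mat[names(frac), t])
  }
  ef
}
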