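# Macro-region demography: child population projection over the planning
# horizon and population-weighted national aggregates.

#' Default macro-region table for Burkina Faso
#'
#' Five agroecological/economic macro-regions with the number of children
#' 6--59 months of age in the model base year (2023) and the year after the
#' horizon's end (2033), the baseline prevalence of dietary vitamin A
#' inadequacy among children under household diets alone, and the overall
#' reach of the existing vitamin A supplementation (VAS) platform in each
#' macro-region.
#'
#' Populations and inadequacy prevalences are published aggregates; the VAS
#' coverage rates are model inputs for which the package ships plausible
#' synthetic defaults (campaign plus routine-clinic reach, 70--85% by
#' macro-region). Replace them with survey-based rates where available.
#'
#' @return A data frame with one row per macro-region and columns
#'   `region_id`, `name`, `admin_regions` (semicolon-separated),
#'   `pop_2023`, `pop_2033`, `baseline_inadequacy`, `vas_coverage`.
#' @examples
#' burkina_regions()
#' @export
burkina_regions <- function() {
  df <- data.frame(
    region_id = c("O", "C", "N", "E", "W"),
    name = c("Ouagadougou", "Center", "North", "East", "West"),
    admin_regions = c(
      "Ouagadougou",
      "Centre-Ouest;Centre-Sud;Plateau-Central",
      "Centre-Nord;Nord;Sahel",
      "Est;Centre-Est",
      "Boucle-de-Mouhoun;Hauts-Bassins;Cascades;Sud-Ouest"
    ),
    pop_2023 = c(464940, 552273, 753577, 542860, 933013),
    pop_2033 = c(546000, 648559, 884960, 637506, 1095680),
    baseline_inadequacy = c(0.88, 0.96, 0.99, 0.88, 0.95),
    vas_coverage = c(0.85, 0.75, 0.70, 0.80, 0.78),
    stringsAsFactors = FALSE
  )
  validate_regions(df)
}

#' Validate a macro-region table
#'
#' Checks the structural invariants a demography table must satisfy before it
#' can drive population projection and adequacy modelling.
#'
#' @param regions A data frame with columns `region_id`, `pop_2023`,
#'   `pop_2033`, `baseline_inadequacy`, `vas_coverage` (and optionally
#'   `name`, `admin_regions`).
#' @return The validated data frame, invisibly usable in pipelines.
#' @export
validate_regions <- function(regions) {
  stopifnot(is.data.frame(regions))
  needed <- c("region_id", "pop_2023", "pop_2033",
              "baseline_inadequacy", "vas_coverage")
  missing <- setdiff(needed, names(regions))
  if (length(missing)) {
    stop("region table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(regions) == 0L) stop("region table is empty", call. = FALSE)
  if (anyDuplicated(regions$region_id)) {
    stop("duplicated region_id in region table", call. = FALSE)
  }
  if (any(regions$pop_2023 <= 0) || any(regions$pop_2033 <= 0)) {
    stop("child populations must be strictly positive", call. = FALSE)
  }
  check_fraction(regions$baseline_inadequacy, "baseline_inadequacy")
  check_fraction(regions$vas_coverage, "vas_coverage")
  regions
}

#' Project a child population over the planning horizon
#'
#' Interpolates annual child counts between the base-year anchor (year 1) and
#' the anchor for the year following the horizon's end, using a constant
#' annual growth rate `g = (final / base)^(1 / horizon) - 1` (geometric
#' interpolation, the default) or linear interpolation.
#'
#' @param base Child population in year 1 (strictly positive).
#' @param final Child population implied at year `horizon + 1` (strictly
#'   positive).
#' @param horizon Number of in-horizon years (default 10).
#' @param method `"geometric"` (constant growth rate, default) or `"linear"`.
#' @return Numeric vector of length `horizon`; element t is the population in
#'   year t, with element 1 equal to `base`.
#' @examples
#' project_population(3246663, 3812705)   # growth rate ~1.62%/yr
#' @export
project_population <- function(base, final, horizon = 10L,
                               method = c("geometric", "linear")) {
  method <- match.arg(method)
  if (!is.finite(base) || !is.finite(final) || base <= 0 || final <= 0) {
    stop("populations must be strictly positive", call. = FALSE)
  }
  if (horizon < 1L) stop("horizon must be at least 1", call. = FALSE)
  t <- seq_len(horizon)
  if (method == "geometric") {
    g <- (final / base)^(1 / horizon) - 1
    base * (1 + g)^(t - 1)
  } else {
    base + (final - base) * (t - 1) / horizon
  }
}

#' Project all macro-region populations
#'
#' @param regions A validated macro-region table (see [burkina_regions()]).
#' @inheritParams project_population
#' @return A matrix with one row per region (rownames `region_id`) and one
#'   column per in-horizon year.
#' @export
project_populations <- function(regions, horizon = 10L,
                                method = c("geometric", "linear")) {
  regions <- validate_regions(regions)
  method <- match.arg(method)
  out <- t(vapply(
    seq_len(nrow(regions)),
    function(i) project_population(regions$pop_2023[i], regions$pop_2033[i],
                                   horizon, method),
    numeric(horizon)
  ))
  rownames(out) <- regions$region_id
  out
}

#' Per-year population index relative to year 1
#'
#' @param series Numeric vector of annual populations (year 1 first).
#' @return `series / series[1]`, so element 1 is exactly 1.
#' @export
population_index <- function(series) {
  if (length(series) < 1L || any(series <= 0)) {
    stop("population series must be positive and non-empty", call. = FALSE)
  }
  series / series[1]
}

#' Population-weighted national prevalence
#'
#' Aggregates regional prevalences to a national figure using child
#' populations as weights.
#'
#' @param pop Numeric vector of regional child populations.
#' @param prev Numeric vector of regional prevalences (same length).
#' @return `sum(pop * prev) / sum(pop)`.
#' @examples
#' r <- burkina_regions()
#' weighted_national_prevalence(r$pop_2023, r$baseline_inadequacy)
#' @export
weighted_national_prevalence <- function(pop, prev) {
  if (length(pop) == 0L) stop("empty region list", call. = FALSE)
  if (length(pop) != length(prev)) {
    stop("`pop` and `prev` must have the same length", call. = FALSE)
  }
  if (any(pop < 0)) stop("populations must be non-negative", call. = FALSE)
  check_fraction(prev, "prev")
  sum(pop * prev) / sum(pop)
}

#' Total number of children across macro-regions
#'
#' @param pop Numeric vector of regional child populations.
#' @return Their sum.
#' @export
total_children <- function(pop) {
  if (length(pop) == 0L) stop("empty region list", call. = FALSE)
  if (any(pop < 0)) stop("populations must be non-negative", call. = FALSE)
  sum(pop)
}

#' Read / write a demography table
#'
#' CSV layout: columns `region_id`, `name`, `admin_regions`
#' (semicolon-separated), `pop_2023`, `pop_2033`, `baseline_inadequacy`,
#' `vas_coverage`, with header, UTF-8.
#'
#' @param path File path.
#' @return `read_demography()` returns the validated region table;
#'   `write_demography()` returns `path` invisibly.
#' @export
read_demography <- function(path) {
  validate_regions(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_demography
#' @param regions Region table to write.
#' @export
write_demography <- function(regions, path) {
  write.csv(validate_regions(regions), path, row.names = FALSE)
  invisible(path)
}
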